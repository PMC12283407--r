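#' Simulate an absolute copy-number profile with known ground truth
#'
#' Draws random segment boundaries per chromosome and assigns integer
#' copy-number states so that (i) every integer state from 1 to the
#' rounded target ploidy is present (chromosomally unstable tumors
#' occupy all intermediate states, and the tissue-mode fit filter
#' requires it), (ii) at least `min_state1` bp sit at copy number 1 (so
#' a whole-genome shift is distinguishable from the truth via the
#' homozygous-loss filter), and (iii) the length-weighted mean copy
#' number matches the target ploidy within `ploidy_tol`.
#'
#' @param genome a [genome_table()].
#' @param ploidy target ploidy (length-weighted mean copy number).
#' @param n_segments approximate total number of segments.
#' @param seed RNG seed.
#' @param focal_amps number of short (about 1.5 Mb) high-level
#'   amplification segments to plant.
#' @param osc_runs number of oscillating two-state chains (length 5) to
#'   plant.
#' @param ploidy_tol tolerance on the realized mean copy number.
#' @param min_state1 minimum genome length at copy number 1.
#' @return An absolute-space [cn_profile()]; the `truth` attribute
#'   records the target and realized ploidy.
#' @export
simulate_absolute_profile <- function(genome = toy_genome(), ploidy = 3.0,
                                      n_segments = 40, seed = 1,
                                      focal_amps = 0, osc_runs = 0,
                                      ploidy_tol = 0.04, min_state1 = 1.2e7) {
  rp <- max(1, round(ploidy))
  with_seed(seed, {
    total <- sum(genome$length)
    seg <- do.call(rbind, lapply(seq_len(nrow(genome)), function(ci) {
      len <- genome$length[ci]
      n_c <- max(2, round(n_segments * len / total))
      br <- sort(round(stats::runif(n_c - 1, 0.02, 0.98) * len))
      br <- br[c(TRUE, diff(br) > 1e6)]
      bounds <- c(0, br, len)
      data.frame(chrom = genome$chrom[ci], start = bounds[-length(bounds)],
                 end = bounds[-1], stringsAsFactors = FALSE)
    }))
    n <- nrow(seg)
    states <- pmax(1, rp + sample(c(-2, -1, 0, 0, 0, 1, 1, 2), n,
                                  replace = TRUE))
    # guarantee presence of every state 1..rp
    anchor <- sample(n, rp)
    states[anchor] <- seq_len(rp)
    len <- seg$end - seg$start
    # guarantee enough genome at copy number 1
    while (sum(len[states == 1]) < min_state1) {
      free <- setdiff(which(states != 1), anchor)
      if (!length(free)) break
      states[sample(free, 1)] <- 1
    }
    # nudge states until the realized mean matches the target ploidy
    for (iter in seq_len(5000)) {
      m <- sum(states * len) / sum(len)
      if (abs(m - ploidy) <= ploidy_tol) break
      i <- sample(setdiff(seq_len(n), anchor), 1)
      cand <- states[i] + if (m < ploidy) 1L else -1L
      if (cand < 1) next
      if (states[i] == 1 &&
          sum(len[states == 1]) - len[i] < min_state1) next
      states[i] <- cand
    }
    if (focal_amps > 0) {
      for (k in seq_len(focal_amps)) {
        slen <- seg$end - seg$start
        big <- which(slen > 6e6)
        if (!length(big)) break
        i <- sample(big, 1)
        a0 <- seg$start[i] + round(slen[i] / 3)
        a1 <- a0 + 1.5e6
        pieces <- seg[c(i, i, i), ]
        pieces$end[1] <- a0
        pieces$start[2] <- a0
        pieces$end[2] <- a1
        pieces$start[3] <- a1
        seg <- rbind(seg[-i, , drop = FALSE], pieces)
        states <- c(states[-i], states[i], rp + sample(4:7, 1), states[i])
      }
    }
    ord <- order(match(seg$chrom, genome$chrom), seg$start)
    seg <- seg[ord, , drop = FALSE]
    states <- states[ord]
    if (osc_runs > 0) {
      for (k in seq_len(osc_runs)) {
        ch <- sample(genome$chrom, 1)
        idx <- which(seg$chrom == ch)
        if (length(idx) >= 5) {
          run <- idx[seq_len(5)]
          states[run] <- rep(c(rp, rp + 1), length.out = 5)
        }
      }
    }
    # fine-tune one boundary at a time so the length-weighted mean lands
    # exactly on the target ploidy (truth then sits exactly on the fitting
    # grid when the target does)
    len <- seg$end - seg$start
    total_len <- sum(len)
    for (i in seq_len(nrow(seg) - 1)) {
      resid <- sum(states * len) / total_len - ploidy
      if (abs(resid) < 1e-12) break
      if (seg$chrom[i] != seg$chrom[i + 1]) next
      a <- states[i]
      b <- states[i + 1]
      if (a == b) next
      delta <- -resid * total_len / (a - b)
      delta <- max(min(delta, len[i + 1] - 5e5), -(len[i] - 5e5))
      seg$end[i] <- seg$end[i] + delta
      seg$start[i + 1] <- seg$start[i + 1] + delta
      len <- seg$end - seg$start
    }
    seg$value <- as.numeric(states)
    seg$n_bins <- pmax(1L, as.integer(round((seg$end - seg$start) / 5e4)))
    prof <- cn_profile(seg, genome, "absolute")
    attr(prof, "truth") <- list(
      ploidy_target = ploidy,
      ploidy_realized = sum(prof$value * seg_len(prof)) / sum(seg_len(prof)),
      seed = seed)
    prof
  })
}

smooth_track <- function(pos, chrom_index, center, amp, period) {
  center + amp * sin(2 * pi * pos / period + chrom_index)
}

#' Simulate binned read counts from an absolute profile
#'
#' Forward model of the tumor/normal mixture: the expected read count of
#' a bin is proportional to `purity * aCN + 2 * (1 - purity)`, scaled so
#' the genome-wide mean equals `depth`. Optional GC bias multiplies the
#' expectation by `exp(gc_bias(gc))`. Count noise is Poisson, negative
#' binomial (overdispersion `0.1` by default), or none.
#'
#' @param profile an absolute-space [cn_profile()] (the tumor truth).
#' @param purity tumor cell fraction.
#' @param depth mean reads per bin.
#' @param bin_size bin width in bp.
#' @param noise `"poisson"`, `"negbinom"` or `"none"`.
#' @param overdispersion negative-binomial overdispersion (variance =
#'   mu + overdispersion * mu^2).
#' @param gc_bias optional function of GC content returning a log-scale
#'   bias.
#' @param seed RNG seed.
#' @return A [cn_bins()] table with `count` filled; the `truth`
#'   attribute holds the per-bin absolute copy number and expected
#'   counts.
#' @export
simulate_binned_counts <- function(profile, purity = 1, depth = 100,
                                   bin_size = 5e4,
                                   noise = c("poisson", "negbinom", "none"),
                                   overdispersion = 0.1, gc_bias = NULL,
                                   seed = 1) {
  noise <- match.arg(noise)
  genome <- profile_genome(profile)
  with_seed(seed, {
    bins <- do.call(rbind, lapply(unique(profile$chrom), function(ch) {
      len <- genome_length(genome, ch)
      starts <- seq(0, len - 1, by = bin_size)
      data.frame(chrom = ch, start = starts,
                 end = pmin(starts + bin_size, len),
                 stringsAsFactors = FALSE)
    }))
    acn <- numeric(nrow(bins))
    for (ch in unique(bins$chrom)) {
      i <- bins$chrom == ch
      s <- profile[profile$chrom == ch, , drop = FALSE]
      acn[i] <- rebin_weighted(s$start, s$end, s$value,
                               bins$start[i], bins$end[i])
    }
    keep <- !is.na(acn)
    bins <- bins[keep, , drop = FALSE]
    acn <- acn[keep]
    # GC and replication timing vary on a fine scale (tens of bins),
    # essentially independent of the megabase-scale copy-number segments,
    # as in real bin annotation tracks
    ci <- match(bins$chrom, genome$chrom)
    mid <- (bins$start + bins$end) / 2
    gc <- pmin(0.75, pmax(0.25,
                          smooth_track(mid, ci, 0.45, 0.06, 1.3e6) +
                            stats::rnorm(nrow(bins), 0, 0.02)))
    rt <- smooth_track(mid, ci, 0, 1, 2.1e6) +
      stats::rnorm(nrow(bins), 0, 0.2)
    mix <- purity * acn + 2 * (1 - purity)
    expected <- depth * mix / mean(mix)
    if (!is.null(gc_bias)) expected <- expected * exp(gc_bias(gc))
    count <- switch(noise,
                    poisson = stats::rpois(length(expected), expected),
                    negbinom = stats::rnbinom(length(expected),
                                              mu = expected,
                                              size = 1 / overdispersion),
                    none = expected)
    out <- cn_bins(bins$chrom, bins$start, bins$end, gc = gc,
                   mappability = 1, reptiming = rt, count = count)
    attr(out, "truth") <- list(acn = acn, expected = expected,
                               purity = purity, seed = seed)
    out
  })
}

#' Simulate copy-number feature events from planted signature weights
#'
#' Generative inverse of the encoding: each event picks a mixture
#' component with probability proportional to the planted mixture of
#' signature definitions (`t(M) %*% weights`), then draws its value from
#' that component's density (back-transforming log10-scale components).
#' Encoding the resulting catalog and decomposing it recovers the
#' planted weights up to posterior crosstalk between neighbouring
#' components.
#'
#' @param model a signature model list (`matrix` + `mixture`).
#' @param weights non-negative planted signature weights (normalised
#'   internally).
#' @param n_events number of events to draw.
#' @param seed RNG seed.
#' @return A `cn_features` catalog; the `truth` attribute holds the
#'   normalised planted weights.
#' @export
simulate_signature_events <- function(model, weights, n_events, seed = 1) {
  M <- model$matrix
  mm <- model$mixture
  if (length(weights) != nrow(M)) stop("weights must match signatures")
  if (any(weights < 0)) stop("weights must be non-negative")
  w <- weights / sum(weights)
  probs <- as.numeric(t(M) %*% w)
  feats <- stats::setNames(vector("list", length(unique(mm$feature))),
                           unique(mm$feature))
  for (f in names(feats)) feats[[f]] <- numeric(0)
  if (n_events > 0) {
    with_seed(seed, {
      comp <- sample(nrow(mm), n_events, replace = TRUE, prob = probs)
      for (i in seq_len(nrow(mm))) {
        k <- sum(comp == i)
        if (!k) next
        val <- if (mm$family[i] == "gaussian") {
          v <- stats::rnorm(k, mm$mean[i], mm$sd[i])
          if (mm$scale[i] == "log10") 10^v else v
        } else {
          stats::rpois(k, mm$lambda[i])
        }
        feats[[mm$feature[i]]] <- c(feats[[mm$feature[i]]], val)
      }
    })
  }
  structure(feats, class = "cn_features",
            truth = list(weights = stats::setNames(w, rownames(M)),
                         seed = seed))
}

#' Simulate a capture panel, panel of normals and biased counts
#'
#' Places clustered target intervals on the genome, computes a
#' similarity covariate per bin (exponential-decay proximity to
#' targets), generates `n_normals` normal samples whose off-target
#' counts carry the similarity bias with known log-scale slope `beta`,
#' and generates one tumor sample on `profile` carrying the same
#' similarity bias plus optional GC and replication-timing biases, with
#' on-target reads removed (bins overlapped by targets are depleted
#' proportionally to their overlap fraction).
#'
#' @param profile tumor truth, an absolute-space [cn_profile()].
#' @param purity tumor cell fraction of the sample.
#' @param n_targets number of target intervals.
#' @param target_size target width in bp.
#' @param beta log-scale similarity-bias slope.
#' @param gc_slope,rt_slope optional log-scale GC / replication-timing
#'   bias coefficients for the tumor sample.
#' @param n_normals panel-of-normals size.
#' @param depth mean off-target reads per bin.
#' @param bin_size bin width.
#' @param seed RNG seed.
#' @return A list with `panel` ([panel_design()]), `pon`
#'   ([build_pon()]), `bins` (tumor [cn_bins()]), `normal_counts`
#'   (matrix), and `truth` (planted `beta`, per-bin similarity covariate
#'   `z`, per-bin log bias).
#' @export
simulate_panel <- function(profile, purity = 0.6, n_targets = 150,
                           target_size = 1000, beta = 0.4, gc_slope = 0,
                           rt_slope = 0, n_normals = 40, depth = 100,
                           bin_size = 5e4, seed = 1) {
  genome <- profile_genome(profile)
  base <- simulate_binned_counts(profile, purity = purity, depth = depth,
                                 bin_size = bin_size, noise = "none",
                                 seed = seed)
  truth_bins <- attr(base, "truth")
  with_seed(seed + 1, {
    panel <- NULL
    if (n_targets > 0) {
      n_clusters <- max(1, round(n_targets / 4))
      ci <- sample(nrow(genome), n_clusters, replace = TRUE)
      centers <- data.frame(
        chrom = genome$chrom[ci],
        pos = round(stats::runif(n_clusters) * 0.9 * genome$length[ci]))
      tg <- centers[sample(n_clusters, n_targets, replace = TRUE), ]
      tg$start <- pmax(0, round(tg$pos + stats::rnorm(n_targets, 0, 1.5e5)))
      tg$end <- tg$start + target_size
      lim <- genome_length(genome, tg$chrom)
      tg$end <- pmin(tg$end, lim)
      tg <- tg[tg$end > tg$start, ]
      panel <- panel_design(tg[, c("chrom", "start", "end")])
    } else {
      panel <- panel_design(data.frame(chrom = genome$chrom[1],
                                       start = 0, end = 1))[0, ]
      class(panel) <- c("panel_design", "data.frame")
    }
    mid <- (base$start + base$end) / 2
    z <- numeric(nrow(base))
    if (nrow(panel)) {
      for (ch in unique(panel$chrom)) {
        i <- which(base$chrom == ch)
        tg <- panel[panel$chrom == ch, ]
        tmid <- (tg$start + tg$end) / 2
        for (j in i) {
          z[j] <- sum(exp(-abs(mid[j] - tmid) / 5e4))
        }
      }
    }
    if (stats::sd(z) > 0) z <- (z - mean(z)) / stats::sd(z)
    log_bias <- beta * z
    normal_counts <- matrix(
      stats::rpois(nrow(base) * n_normals,
                   rep(depth * exp(log_bias), n_normals)),
      nrow = nrow(base))
    pon <- build_pon(normal_counts, base)
    sample_bias <- log_bias + gc_slope * (base$gc - mean(base$gc)) +
      rt_slope * base$reptiming
    expected <- attr(base, "truth")$expected * exp(sample_bias)
    b <- annotate_overlaps(base, panel)
    expected <- expected * (1 - b$overlap_fraction)
    b$count <- stats::rpois(length(expected), expected)
    attr(b, "truth") <- c(truth_bins,
                          list(beta = beta, z = z, log_bias = log_bias))
    list(panel = panel, pon = pon, bins = b,
         normal_counts = normal_counts,
         truth = list(beta = beta, z = z, log_bias = log_bias,
                      purity = purity))
  })
}

#' Simulate a clinical cohort with a planted hazard ratio
#'
#' Generates a patient table and treatment-line table for a two-arm
#' phase 3 emulation. Patients are randomised between an experimental
#' index line (containing the therapy of interest) and a control index
#' line (one of five standard-of-care monotherapies); a biomarker label
#' marks each patient resistant or sensitive. Failure times are
#' exponential with the hazard multiplied by `true_hr` for resistant
#' patients in the experimental arm; censoring is exponential at a rate
#' chosen to give approximately `censor_rate` censored patients. Failure
#' is recorded as a death date so TTF computed from the tables recovers
#' the planted times.
#'
#' @param n number of patients.
#' @param true_hr planted hazard ratio (resistant x experimental vs
#'   the rest).
#' @param therapy experimental therapy class.
#' @param resistant_frac fraction of biomarker-resistant patients.
#' @param censor_rate approximate fraction censored.
#' @param median_ttf baseline median TTF in days.
#' @param n_years number of treatment-year levels.
#' @param year_imbalance difference in experimental-arm propensity
#'   across years (0 = balanced).
#' @param seed RNG seed.
#' @return A list with `patients`, `lines` and `truth`.
#' @export
simulate_cohort <- function(n = 200, true_hr = 4, therapy = "taxane",
                            resistant_frac = 0.5, censor_rate = 0.2,
                            median_ttf = 180, n_years = 3,
                            year_imbalance = 0, seed = 1) {
  soc <- c("gemcitabine", "topotecan", "cyclophosphamide", "vinorelbine",
           "etoposide")
  exp_drug <- switch(therapy, taxane = "paclitaxel",
                     anthracycline = "doxorubicin",
                     platinum = "carboplatin",
                     stop("unknown therapy"))
  with_seed(seed, {
    id <- sprintf("P%03d", seq_len(n))
    year <- sample(seq_len(n_years), n, replace = TRUE)
    p_exp <- pmin(0.9, pmax(0.1,
                            0.5 + year_imbalance *
                              (year - mean(seq_len(n_years)))))
    arm <- ifelse(stats::runif(n) < p_exp, "experimental", "control")
    resistant <- stats::runif(n) < resistant_frac
    diagnosis <- round(stats::runif(n, 0, 1000))
    age <- round(stats::runif(n, 40, 80))
    start <- diagnosis + 30
    rate0 <- log(2) / median_ttf
    rate <- rate0 * ifelse(resistant & arm == "experimental", true_hr, 1)
    t_fail <- stats::rexp(n, rate)
    t_cens <- if (censor_rate > 0) {
      stats::rexp(n, rate0 * censor_rate / (1 - censor_rate))
    } else rep(Inf, n)
    event <- t_fail <= t_cens
    obs <- pmin(t_fail, t_cens)
    death <- ifelse(event, start + round(obs) + 1, NA_real_)
    followup <- ifelse(event, death, start + round(obs) + 1)
    patients <- data.frame(
      id = id, diagnosis = diagnosis, age = age,
      age_group = ifelse(age < 65, "<65", ">=65"),
      stage = "III", grade = 3,
      last_followup = followup,
      death = death,
      biomarker = ifelse(resistant, "resistant", "sensitive"),
      year = 2010 + year, stringsAsFactors = FALSE)
    lines <- data.frame(
      patient = id,
      drugs = ifelse(arm == "experimental", exp_drug,
                     soc[1 + (seq_len(n) %% length(soc))]),
      start = start, end = start + 120, cycles = 6L, line_number = 1L,
      biopsy = start - 10, stringsAsFactors = FALSE)
    list(patients = patients, lines = lines,
         truth = list(hr = true_hr, arm = arm, resistant = resistant,
                      t_fail = t_fail, event = event, seed = seed))
  })
}
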