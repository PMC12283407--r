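#' Drug dictionary and therapy classes
#'
#' Maps drug-name synonyms to canonical names and groups canonical names
#' into therapy classes. Maintenance therapies are handled as covariate
#' flags, not treatment lines, and are ignored when counting
#' monotherapies.
#'
#' @return A list with `synonyms` (named character), `classes` (named
#'   list of canonical drug vectors) and `maintenance` (character).
#' @export
default_drug_dictionary <- function() {
  list(
    synonyms = c("taxol" = "paclitaxel",
                 "abraxane" = "paclitaxel",
                 "caelyx" = "doxorubicin",
                 "pld" = "doxorubicin",
                 "pegylated liposomal doxorubicin" = "doxorubicin",
                 "adriamycin" = "doxorubicin"),
    classes = list(
      platinum = c("cisplatin", "carboplatin", "oxaliplatin"),
      taxane = c("paclitaxel", "docetaxel", "cabazitaxel"),
      anthracycline = c("doxorubicin", "epirubicin", "daunorubicin")),
    maintenance = c("niraparib", "olaparib", "bevacizumab", "letrozole"))
}

split_drugs <- function(drugs, dict) {
  lapply(strsplit(tolower(drugs), "\\s*[,+;]\\s*"), function(d) {
    d <- trimws(d)
    mapped <- dict$synonyms[d]
    d[!is.na(mapped)] <- mapped[!is.na(mapped)]
    d
  })
}

line_has_class <- function(lines, therapy, dict) {
  drugs <- dict$classes[[therapy]]
  if (is.null(drugs)) stop("unknown therapy class: ", therapy)
  vapply(split_drugs(lines$drugs, dict), function(d) any(d %in% drugs),
         logical(1))
}

line_is_mono <- function(lines, dict) {
  vapply(split_drugs(lines$drugs, dict), function(d) {
    active <- setdiff(d, dict$maintenance)
    length(active) == 1
  }, logical(1))
}

mono_drug <- function(lines, dict) {
  vapply(split_drugs(lines$drugs, dict), function(d) {
    active <- setdiff(d, dict$maintenance)
    if (length(active) == 1) active else NA_character_
  }, character(1))
}

as_days <- function(x) as.numeric(x)

#' Time to treatment failure
#'
#' For each treatment line, the failure event is the earliest of the
#' patient's next treatment-line start and the death/progression date;
#' TTF is the event date minus the line start. Lines with no failure
#' event are censored at the patient's last follow-up. The rule is
#' pluggable through `event_date_fn`, which receives the line row and
#' patient row and may return a custom event date (or `NA`).
#'
#' @param lines treatment-line `data.frame` (`patient`, `drugs`, `start`,
#'   `end`, `cycles`, `line_number`); dates may be `Date` or numeric
#'   days.
#' @param patients patient `data.frame` (`id`, `diagnosis`,
#'   `last_followup`, optional `death`).
#' @param event_date_fn optional override of the failure-date rule.
#' @return `data.frame` with `patient`, `line_number`, `ttf` (days) and
#'   `censored`.
#' @export
compute_ttf <- function(lines, patients, event_date_fn = NULL) {
  pid <- match(lines$patient, patients$id)
  if (anyNA(pid)) stop("treatment line for unknown patient")
  start <- as_days(lines$start)
  followup <- as_days(patients$last_followup)[pid]
  death <- if ("death" %in% names(patients))
    as_days(patients$death)[pid] else rep(NA_real_, nrow(lines))
  ttf <- numeric(nrow(lines))
  censored <- logical(nrow(lines))
  for (i in seq_len(nrow(lines))) {
    if (!is.null(event_date_fn)) {
      ev <- as_days(event_date_fn(lines[i, ], patients[pid[i], ]))
    } else {
      later <- start[lines$patient == lines$patient[i]]
      later <- later[later > start[i]]
      ev <- suppressWarnings(min(c(later, death[i]), na.rm = TRUE))
      if (!is.finite(ev)) ev <- NA_real_
    }
    if (is.na(ev)) {
      ttf[i] <- followup[i] - start[i]
      censored[i] <- TRUE
    } else {
      ttf[i] <- ev - start[i]
      censored[i] <- FALSE
    }
    if (ttf[i] < 0) stop("negative TTF for patient ", lines$patient[i])
  }
  data.frame(patient = lines$patient, line_number = lines$line_number,
             ttf = ttf, censored = censored, stringsAsFactors = FALSE)
}

exposure_ok <- function(lines, min_cycles = 3, min_days = 28) {
  dur <- as_days(lines$end) - as_days(lines$start)
  lines$cycles >= min_cycles | dur >= min_days
}

#' Construct the experimental arm
#'
#' Selects, per patient, the treatment line closest to diagnosis that
#' contains the chemotherapy of interest (alone or in combination),
#' passes the exposure filter (at least `min_cycles` cycles OR a
#' duration of at least `min_days` days), optionally follows a biopsy,
#' and optionally contains no platinum (the relapsed-ovarian
#' configuration).
#'
#' @param lines treatment-line table.
#' @param therapy therapy class name.
#' @param dict a drug dictionary.
#' @param require_biopsy_link keep only lines with a linked biopsy.
#' @param exclude_platinum drop lines that also contain platinum.
#' @param min_cycles,min_days exposure filter.
#' @return The selected lines with an `arm = "experimental"` column.
#' @export
assign_experimental <- function(lines, therapy,
                                dict = default_drug_dictionary(),
                                require_biopsy_link = FALSE,
                                exclude_platinum = FALSE,
                                min_cycles = 3, min_days = 28) {
  keep <- line_has_class(lines, therapy, dict)
  if (exclude_platinum && therapy != "platinum")
    keep <- keep & !line_has_class(lines, "platinum", dict)
  keep <- keep & exposure_ok(lines, min_cycles, min_days)
  if (require_biopsy_link) {
    if (is.null(lines$biopsy)) stop("no biopsy column to link on")
    keep <- keep & !is.na(lines$biopsy)
  }
  sel <- lines[keep, , drop = FALSE]
  if (nrow(sel)) {
    first <- tapply(seq_len(nrow(sel)), sel$patient,
                    function(i) i[which.min(sel$line_number[i])])
    sel <- sel[sort(as.integer(first)), , drop = FALSE]
  }
  sel$arm <- rep("experimental", nrow(sel))
  rownames(sel) <- NULL
  sel
}

#' Construct the control arm from standard-of-care monotherapies
#'
#' Removes lines containing the therapy of interest, removes all lines
#' of patients already in the experimental arm, restricts to
#' monotherapies (exactly one non-maintenance drug after synonym
#' mapping), ranks the monotherapy drugs by line frequency and keeps
#' lines whose drug is among the `n_top` most frequent (frequency ties
#' broken lexicographically), then applies the exposure filter.
#'
#' @param lines treatment-line table.
#' @param therapy therapy class name of the experimental arm.
#' @param experimental the experimental arm from [assign_experimental()].
#' @param dict a drug dictionary.
#' @param n_top number of standard-of-care monotherapies to keep.
#' @param exclude_platinum drop platinum lines from the candidates.
#' @param min_cycles,min_days exposure filter.
#' @return The control lines with an `arm = "control"` column.
#' @export
assign_control <- function(lines, therapy, experimental,
                           dict = default_drug_dictionary(), n_top = 5,
                           exclude_platinum = FALSE,
                           min_cycles = 3, min_days = 28) {
  keep <- !line_has_class(lines, therapy, dict)
  if (exclude_platinum)
    keep <- keep & !line_has_class(lines, "platinum", dict)
  keep <- keep & !(lines$patient %in% experimental$patient)
  cand <- lines[keep, , drop = FALSE]
  cand <- cand[line_is_mono(cand, dict), , drop = FALSE]
  if (!nrow(cand)) stop("control arm empty")
  drug <- mono_drug(cand, dict)
  freq <- table(drug)
  ranked <- names(freq)[order(-as.numeric(freq), names(freq))]
  top <- utils::head(ranked, n_top)
  cand <- cand[drug %in% top, , drop = FALSE]
  cand <- cand[exposure_ok(cand, min_cycles, min_days), , drop = FALSE]
  if (!nrow(cand)) stop("control arm empty")
  cand$arm <- "control"
  attr(cand, "soc") <- top
  rownames(cand) <- NULL
  cand
}

#' Finalise an emulated cohort
#'
#' Combines the arms, keeps one treatment line per patient (the first
#' viable line by start date, experimental lines taking priority when a
#' patient somehow appears in both), computes TTF, and applies the late
#' follow-up exclusion: patients whose clinical follow-up does not
#' extend beyond `followup_min` days past the end of their last
#' treatment line are excluded when that last line's TTF exceeds
#' `ttf_max` days — an apparently very long treatment success that is
#' not backed by at least a year of subsequent follow-up cannot be
#' trusted. A CONSORT-style per-rule exclusion count is attached as the
#' `flow` attribute.
#'
#' @param experimental,control arm tables from [assign_experimental()]
#'   and [assign_control()].
#' @param patients patient table.
#' @param all_lines the full treatment-line table (for the last-line TTF
#'   rule); defaults to the union of the two arms.
#' @param followup_min,ttf_max thresholds in days (365 and 730).
#' @return Analysis cohort `data.frame`: one row per patient with `arm`,
#'   `ttf`, `event`, covariates from the patient table.
#' @export
finalize_cohort <- function(experimental, control, patients,
                            all_lines = NULL, followup_min = 365,
                            ttf_max = 730) {
  arms <- rbind(experimental, control)
  if (!nrow(arms)) stop("no patients in either arm")
  if (is.null(all_lines)) all_lines <- arms[, setdiff(names(arms), "arm")]
  n_in <- length(unique(arms$patient))
  # one line per patient, first viable; experimental priority on ties
  pri <- ifelse(arms$arm == "experimental", 0, 1)
  ord <- order(arms$patient, pri, as_days(arms$start))
  arms <- arms[ord, , drop = FALSE]
  arms <- arms[!duplicated(arms$patient), , drop = FALSE]
  tt <- compute_ttf(arms, patients)
  pid <- match(arms$patient, patients$id)
  # TTF of each patient's last treatment line, and follow-up beyond its end
  last_stats <- vapply(arms$patient, function(p) {
    pl <- all_lines[all_lines$patient == p, , drop = FALSE]
    pl <- pl[which.max(as_days(pl$start)), , drop = FALSE]
    fu <- as_days(patients$last_followup[patients$id == p]) -
      as_days(pl$end)
    c(compute_ttf(pl, patients)$ttf, fu)
  }, numeric(2))
  drop_fu <- last_stats[2, ] <= followup_min & last_stats[1, ] > ttf_max
  cohort <- data.frame(patient = arms$patient, arm = arms$arm,
                       line_number = arms$line_number,
                       start = arms$start, ttf = tt$ttf,
                       event = !tt$censored, stringsAsFactors = FALSE)
  extra <- setdiff(names(patients), c("id"))
  for (col in extra) cohort[[col]] <- patients[[col]][pid]
  cohort <- cohort[!drop_fu, , drop = FALSE]
  rownames(cohort) <- NULL
  attr(cohort, "flow") <- c(patients_in_arms = n_in,
                            excluded_followup_rule = sum(drop_fu),
                            analyzed = nrow(cohort))
  cohort
}

#' Stabilized inverse probability weights
#'
#' Propensity of experimental assignment is estimated by empirical
#' frequency within each level of a categorical covariate (year of
#' treatment by default); the stabilized weight of a patient is the
#' marginal probability of their arm divided by the conditional
#' probability given their covariate level. Levels where one arm has
#' zero propensity are an error.
#'
#' @param cohort finalized cohort with an `arm` column.
#' @param covariate name of the categorical covariate column.
#' @return Numeric weights aligned with the cohort rows.
#' @export
ipw_weights <- function(cohort, covariate = "year") {
  if (!covariate %in% names(cohort))
    stop("covariate column not found: ", covariate)
  lev <- as.character(cohort[[covariate]])
  exp_flag <- cohort$arm == "experimental"
  p_marg <- mean(exp_flag)
  w <- numeric(nrow(cohort))
  for (l in unique(lev)) {
    i <- lev == l
    p_cond <- mean(exp_flag[i])
    if (p_cond == 0 || p_cond == 1)
      stop("zero propensity in covariate level: ", l)
    w[i] <- ifelse(exp_flag[i], p_marg / p_cond,
                   (1 - p_marg) / (1 - p_cond))
  }
  w
}

#' Run an emulated biomarker trial
#'
#' Thin interface to weighted, stratified Cox proportional-hazards
#' estimation (the `survival` package). For a phase 3 design the
#' experimental-vs-control hazard ratio is estimated within each
#' biomarker group; for a phase 2 single-arm design the
#' resistant-vs-sensitive hazard ratio is estimated within the treated
#' patients. The proportional-hazards assumption is checked with
#' `survival::cox.zph` and its global p-value reported.
#'
#' @param cohort finalized cohort with `ttf`, `event`, `arm` and a
#'   biomarker column.
#' @param design `"phase3_rct"` or `"phase2_single_arm"`.
#' @param biomarker name of the biomarker column (values `"resistant"`/
#'   `"sensitive"`).
#' @param strata optional name of a column to stratify on (e.g. age
#'   group).
#' @param covariates optional character vector of adjustment columns.
#' @param weights optional IPW weights (robust variance is used when
#'   given).
#' @return A list of class `emulation_result` with `design`, `fits` (a
#'   `data.frame` of hazard ratios with 95\% CI, p-value, PH-test
#'   p-value and group sizes) and `cohort`.
#' @export
run_emulation <- function(cohort, design = c("phase3_rct",
                                             "phase2_single_arm"),
                          biomarker = "biomarker", strata = NULL,
                          covariates = NULL, weights = NULL) {
  design <- match.arg(design)
  rhs <- function(main) {
    terms <- c(main, covariates,
               if (!is.null(strata)) sprintf("strata(%s)", strata))
    paste(terms, collapse = " + ")
  }
  fit_one <- function(dat, main, wts) {
    dat$.main <- dat[[main]]
    form <- stats::as.formula(paste("survival::Surv(ttf, event) ~",
                                    rhs(".main")))
    fit <- survival::coxph(form, data = dat, weights = wts,
                           robust = !is.null(wts))
    sm <- summary(fit)
    i <- grep("^.main", rownames(sm$conf.int))[1]
    zph <- tryCatch(survival::cox.zph(fit)$table["GLOBAL", "p"],
                    error = function(e) NA_real_)
    data.frame(hr = sm$conf.int[i, "exp(coef)"],
               lcl = sm$conf.int[i, "lower .95"],
               ucl = sm$conf.int[i, "upper .95"],
               p = sm$coefficients[i, ncol(sm$coefficients)],
               zph_p = zph, n = nrow(dat), events = sum(dat$event))
  }
  if (design == "phase3_rct") {
    if (length(unique(cohort$arm)) < 2)
      stop("phase 3 design needs both arms")
    cohort$arm <- stats::relevel(factor(cohort$arm), ref = "control")
    groups <- unique(cohort[[biomarker]])
    fits <- do.call(rbind, lapply(groups, function(g) {
      i <- cohort[[biomarker]] == g
      cbind(group = g, fit_one(cohort[i, ], "arm",
                               if (is.null(weights)) NULL else weights[i]))
    }))
  } else {
    treated <- cohort[cohort$arm == "experimental", , drop = FALSE]
    if (!nrow(treated)) stop("no treated patients for phase 2 design")
    treated$.bm <- stats::relevel(factor(treated[[biomarker]]),
                                  ref = "sensitive")
    fits <- cbind(group = "treated", fit_one(treated, ".bm", NULL))
  }
  rownames(fits) <- NULL
  structure(list(design = design, fits = fits, cohort = cohort,
                 weights = weights),
            class = "emulation_result")
}

#' @export
print.emulation_result <- function(x, ...) {
  cat("emulation_result (", x$design, ")\n", sep = "")
  print(x$fits, digits = 3)
  invisible(x)
}

#' Required sample size for a survival contrast
#'
#' Schoenfeld's events formula: the number of failure events needed to
#' detect a hazard ratio `hr` at one-tailed level `alpha` with the given
#' power and allocation fraction `p` is
#' \eqn{(z_{1-\alpha} + z_{power})^2 / (\ln hr)^2 / (p (1 - p))};
#' the required enrolment is the event count divided by the expected
#' event fraction.
#'
#' @param hr hazard ratio to detect (not 1).
#' @param alpha one-tailed significance level.
#' @param power target power.
#' @param allocation fraction allocated to the experimental arm.
#' @param event_fraction expected fraction of patients with an event.
#' @return A list with `events` and `n` (both rounded up).
#' @export
power_required_n <- function(hr, alpha = 0.05, power = 0.8,
                             allocation = 0.5, event_fraction = 1) {
  if (hr == 1) stop("hazard ratio of 1 is undetectable at any sample size")
  if (allocation <= 0 || allocation >= 1) stop("allocation must be in (0,1)")
  z <- stats::qnorm(1 - alpha) + stats::qnorm(power)
  events <- z^2 / (log(hr)^2 * allocation * (1 - allocation))
  list(events = ceiling(events), n = ceiling(events / event_fraction))
}
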