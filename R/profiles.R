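#' Binned read-count tables
#'
#' The bin table is the entry point of the shallow whole-genome pipeline:
#' fixed-width genomic bins (50 kb by default throughout the package)
#' annotated with GC content, mappability and replication timing, plus a
#' raw read count and, after correction, a relative copy-number value.
#'
#' @param chrom,start,end bin coordinates (0-based, half-open).
#' @param gc,mappability per-bin fractions in `[0, 1]`.
#' @param reptiming real-valued replication-timing covariate.
#' @param count non-negative read count (may be `NA` before counting).
#' @param value relative or absolute copy number (optional).
#' @return A `data.frame` of class `cn_bins`.
#' @export
cn_bins <- function(chrom, start, end, gc = NA_real_, mappability = 1,
                    reptiming = 0, count = NA_real_, value = NA_real_) {
  b <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                  end = as.numeric(end), gc = gc, mappability = mappability,
                  reptiming = reptiming, count = count, value = value,
                  stringsAsFactors = FALSE)
  validate_bins(b)
  class(b) <- c("cn_bins", "data.frame")
  b
}

validate_bins <- function(b) {
  if (any(b$end <= b$start)) stop("bins must have end > start")
  ok_frac <- function(x) all(is.na(x) | (x >= 0 & x <= 1))
  if (!ok_frac(b$gc)) stop("gc must be in [0, 1]")
  if (!ok_frac(b$mappability)) stop("mappability must be in [0, 1]")
  for (ch in unique(b$chrom)) {
    s <- b[b$chrom == ch, ]
    if (is.unsorted(s$start, strictly = TRUE))
      stop("bins on ", ch, " are not sorted")
    if (any(s$start[-1] < s$end[-nrow(s)]))
      stop("bins on ", ch, " overlap")
  }
  invisible(b)
}

#' Segmented copy-number profiles
#'
#' The lingua franca of the pipeline: an ordered, non-overlapping set of
#' genomic segments, each with one copy-number value, in either relative
#' (depth-normalised) or absolute (chromosome-copy) space.
#'
#' @param segments a `data.frame` with columns `chrom`, `start`, `end`,
#'   `value`, and optionally `n_bins` (number of bins supporting each
#'   segment; defaults to 1).
#' @param genome a [genome_table()].
#' @param space `"relative"` or `"absolute"`.
#' @return A `data.frame` of class `cn_profile` with attributes `genome`
#'   and `space`.
#' @export
cn_profile <- function(segments, genome, space = c("relative", "absolute")) {
  space <- match.arg(space)
  seg <- as.data.frame(segments)
  req <- c("chrom", "start", "end", "value")
  if (!all(req %in% names(seg)))
    stop("segments need columns ", paste(req, collapse = ", "))
  if (is.null(seg$n_bins)) seg$n_bins <- 1L
  seg <- seg[, c("chrom", "start", "end", "value", "n_bins")]
  seg$chrom <- as.character(seg$chrom)
  if (!all(is.finite(seg$value))) stop("segment values must be finite")
  if (any(seg$end <= seg$start)) stop("segments must have end > start")
  if (space == "absolute" && any(seg$value < 0))
    stop("absolute copy number must be >= 0")
  ord <- order(match(seg$chrom, genome$chrom), seg$start)
  seg <- seg[ord, , drop = FALSE]
  rownames(seg) <- NULL
  for (ch in unique(seg$chrom)) {
    s <- seg[seg$chrom == ch, ]
    if (any(s$start[-1] < s$end[-nrow(s)]))
      stop("segments on ", ch, " overlap")
    if (any(s$end > genome_length(genome, ch)))
      stop("segment on ", ch, " extends past chromosome end")
  }
  attr(seg, "genome") <- genome
  attr(seg, "space") <- space
  class(seg) <- c("cn_profile", "data.frame")
  seg
}

#' @export
print.cn_profile <- function(x, ...) {
  cat(sprintf("cn_profile: %d segments on %d chromosomes (%s space)\n",
              nrow(x), length(unique(x$chrom)), attr(x, "space")))
  print.data.frame(utils::head(as.data.frame(x), 8))
  if (nrow(x) > 8) cat("...\n")
  invisible(x)
}

profile_genome <- function(p) attr(p, "genome")
profile_space <- function(p) attr(p, "space")
seg_len <- function(p) p$end - p$start

# replace the segment table but keep genome/space attributes
rebuild_profile <- function(seg, template, space = profile_space(template)) {
  cn_profile(seg, profile_genome(template), space)
}

#' Correct binned counts for GC content and mappability
#'
#' Fits the expected read count as a smooth function of GC content and
#' mappability (two-dimensional LOESS), divides observed counts by the
#' fitted expectation, and median-normalises so that the genome-wide
#' median relative copy number equals 1. Bins whose mappability falls
#' below `min_mappability` are masked and dropped from the output. When
#' fewer than 100 usable bins (or no usable covariate variation) are
#' available, a median-ratio normalisation is used instead of LOESS.
#'
#' @param bins a [cn_bins()] table with counts and annotation.
#' @param span LOESS span.
#' @param min_mappability mask bins below this mappability.
#' @return The usable bins with `value` filled with relative copy number.
#' @export
correct_counts <- function(bins, span = 0.65, min_mappability = 0.5) {
  if (anyNA(bins$count)) stop("counts missing: annotate counts first")
  if (all(bins$count == 0)) stop("empty profile: all counts are zero")
  if (anyNA(bins$gc) || anyNA(bins$mappability))
    stop("gc/mappability annotation missing")
  keep <- bins$mappability >= min_mappability
  b <- bins[keep, , drop = FALSE]
  if (nrow(b) == 0) stop("empty profile: all bins masked")
  n_gc <- length(unique(b$gc))
  n_map <- length(unique(b$mappability))
  if (nrow(b) >= 100 && n_gc >= 10) {
    form <- if (n_map >= 10) count ~ gc + mappability else count ~ gc
    fit <- stats::loess(form, data = b, span = span, degree = 2,
                        family = "symmetric",
                        control = stats::loess.control(surface = "direct"))
    expected <- stats::predict(fit, newdata = b)
    expected[!is.finite(expected) | expected <= 0] <- stats::median(b$count)
  } else {
    expected <- rep(stats::median(b$count), nrow(b))
  }
  val <- b$count / expected
  b$value <- val / stats::median(val)
  class(b) <- c("cn_bins", "data.frame")
  b
}

#' Merge adjacent segments with similar copy number
#'
#' Greedy left-to-right smoothing: walking along each chromosome, a
#' segment is absorbed into the running segment when its value is within
#' `tol` of the running length-weighted mean; otherwise the running
#' segment is emitted and restarted. Comparing against the running mean
#' (rather than the previous raw value) prevents unbounded drift along
#' near-monotone chains. The pass is repeated until no adjacent pair is
#' within `tol`, so the post-condition holds exactly. Merged segments
#' span any gaps between their members; values are length-weighted
#' means of the member segments.
#'
#' @param profile a [cn_profile()].
#' @param tol maximum absolute copy-number difference to merge (default
#'   0.1, the harmonisation smoothing tolerance).
#' @return A smoothed `cn_profile`.
#' @export
smooth_merge <- function(profile, tol = 0.1) {
  if (tol < 0) stop("tol must be >= 0")
  seg <- as.data.frame(profile)
  repeat {
    out <- do.call(rbind, lapply(split(seg, seg$chrom), smooth_merge_chrom,
                                 tol = tol))
    out <- out[order(match(out$chrom, profile_genome(profile)$chrom),
                     out$start), , drop = FALSE]
    if (nrow(out) == nrow(seg)) break
    seg <- out
  }
  rebuild_profile(out, profile)
}

smooth_merge_chrom <- function(s, tol) {
  if (nrow(s) <= 1) return(s)
  out <- s[0, ]
  cur <- s[1, ]
  cur_w <- cur$end - cur$start
  for (i in 2:nrow(s)) {
    nxt <- s[i, ]
    w <- nxt$end - nxt$start
    if (abs(nxt$value - cur$value) <= tol) {
      cur$value <- (cur$value * cur_w + nxt$value * w) / (cur_w + w)
      cur$end <- nxt$end
      cur$n_bins <- cur$n_bins + nxt$n_bins
      cur_w <- cur_w + w
    } else {
      out <- rbind(out, cur)
      cur <- nxt
      cur_w <- w
    }
  }
  rbind(out, cur)
}

#' Harmonise a profile onto a 30 kb segmentation grid
#'
#' High-resolution profiles (e.g. from allele-specific WGS callers) are
#' re-binned into 30 kb bins, each bin taking the overlap-length-weighted
#' average of the segments spanning it; adjacent equal-valued bins are
#' merged back into segments. Re-binning can manufacture artificial
#' segments of exactly one bin (30 kb) at segment boundaries, so segments
#' of exactly 30 kb length are removed, and finally [smooth_merge()] with
#' a 0.1 copy-number tolerance is applied. The operation is idempotent on
#' profiles already aligned to the grid with no 30 kb segments.
#'
#' @param profile an absolute-space [cn_profile()].
#' @param bin_size grid size in bp.
#' @param tol smoothing tolerance passed to [smooth_merge()].
#' @return A harmonised `cn_profile`.
#' @export
resegment_30kb <- function(profile, bin_size = 30000, tol = 0.1) {
  if (profile_space(profile) != "absolute")
    stop("resegment_30kb expects an absolute-space profile")
  genome <- profile_genome(profile)
  pieces <- lapply(unique(profile$chrom), function(ch) {
    s <- profile[profile$chrom == ch, , drop = FALSE]
    len <- genome_length(genome, ch)
    starts <- seq(0, len - 1, by = bin_size)
    ends <- pmin(starts + bin_size, len)
    val <- rebin_weighted(s$start, s$end, s$value, starts, ends)
    covered <- !is.na(val)
    if (!any(covered)) return(NULL)
    merge_equal_bins(ch, starts[covered], ends[covered], val[covered])
  })
  seg <- do.call(rbind, pieces)
  if (is.null(seg) || nrow(seg) == 0)
    return(rebuild_profile(profile[0, ], profile))
  seg <- seg[(seg$end - seg$start) != bin_size, , drop = FALSE]
  if (nrow(seg) == 0) return(rebuild_profile(seg, profile))
  smooth_merge(rebuild_profile(seg, profile), tol = tol)
}

# overlap-length-weighted average of segment values per bin; NA where
# a bin has no overlap with any segment
rebin_weighted <- function(seg_start, seg_end, seg_value, bin_start, bin_end) {
  val <- rep(NA_real_, length(bin_start))
  for (i in seq_along(bin_start)) {
    ov <- pmin(seg_end, bin_end[i]) - pmax(seg_start, bin_start[i])
    hit <- ov > 0
    if (any(hit))
      val[i] <- sum(seg_value[hit] * ov[hit]) / sum(ov[hit])
  }
  val
}

merge_equal_bins <- function(chrom, starts, ends, values, eps = 1e-9) {
  brk <- c(TRUE, abs(diff(values)) > eps | starts[-1] != ends[-length(ends)])
  grp <- cumsum(brk)
  data.frame(chrom = chrom,
             start = tapply(starts, grp, min),
             end = tapply(ends, grp, max),
             value = tapply(values, grp, function(v) v[1]),
             n_bins = as.integer(table(grp)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Weighted genome instability index
#'
#' Per chromosome, the fraction of covered length whose rounded copy
#' number differs from the rounded sample ploidy (the length-weighted
#' mean copy number); wGII is the unweighted mean of those fractions over
#' chromosomes, so small chromosomes count as much as large ones.
#' Rounding is R's round-half-to-even.
#'
#' @param profile an absolute-space [cn_profile()].
#' @return wGII in `[0, 1]`.
#' @export
wgii <- function(profile) {
  if (nrow(profile) == 0) stop("empty profile")
  if (profile_space(profile) != "absolute")
    stop("wgii expects an absolute-space profile")
  len <- seg_len(profile)
  ploidy <- round(sum(profile$value * len) / sum(len))
  frac <- vapply(split(seq_len(nrow(profile)), profile$chrom), function(i) {
    l <- len[i]
    sum(l[round(profile$value[i]) != ploidy]) / sum(l)
  }, numeric(1))
  mean(frac)
}

#' Genome-wide copy-number difference between two profiles
#'
#' The percentage of the jointly covered genome length on which the two
#' profiles disagree in rounded (integer) copy number. This is the
#' profile-concordance metric used to compare copy-number calls from
#' different assays of the same tumor.
#'
#' @param p1,p2 absolute-space [cn_profile()]s on the same genome.
#' @return Percent difference in `[0, 100]`.
#' @export
profile_difference <- function(p1, p2) {
  if (profile_space(p1) != "absolute" || profile_space(p2) != "absolute")
    stop("profile_difference expects absolute-space profiles")
  joint <- 0
  differ <- 0
  for (ch in intersect(unique(p1$chrom), unique(p2$chrom))) {
    a <- p1[p1$chrom == ch, ]
    b <- p2[p2$chrom == ch, ]
    for (i in seq_len(nrow(a))) {
      ov <- pmin(a$end[i], b$end) - pmax(a$start[i], b$start)
      hit <- which(ov > 0)
      if (!length(hit)) next
      joint <- joint + sum(ov[hit])
      neq <- round(a$value[i]) != round(b$value[hit])
      differ <- differ + sum(ov[hit][neq])
    }
  }
  if (joint == 0) stop("profiles have disjoint coverage")
  100 * differ / joint
}
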