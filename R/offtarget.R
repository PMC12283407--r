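#' Annotate bins with capture-target overlaps
#'
#' For each bin, computes the fraction of the bin covered by panel target
#' intervals and the number of distinct target intervals intersecting it.
#' Off-target copy-number calling needs these to decide which bins are
#' dominated by on-target signal.
#'
#' @param bins a [cn_bins()] table.
#' @param panel a [panel_design()] (merged target intervals).
#' @return The bins with `overlap_fraction`, `overlap_count`,
#'   `bias_score` (initialised to 0) and `pseudocount` columns added.
#' @export
annotate_overlaps <- function(bins, panel) {
  frac <- numeric(nrow(bins))
  cnt <- integer(nrow(bins))
  for (ch in unique(bins$chrom)) {
    idx <- which(bins$chrom == ch)
    tg <- panel[panel$chrom == ch, , drop = FALSE]
    if (!nrow(tg)) next
    for (i in idx) {
      ov <- pmin(tg$end, bins$end[i]) - pmax(tg$start, bins$start[i])
      hit <- ov > 0
      cnt[i] <- sum(hit)
      frac[i] <- sum(ov[hit]) / (bins$end[i] - bins$start[i])
    }
  }
  bins$overlap_fraction <- frac
  bins$overlap_count <- cnt
  if (is.null(bins$bias_score)) bins$bias_score <- 0
  bins$pseudocount <- FALSE
  bins
}

#' Build panel-of-normals bin statistics
#'
#' Summarises off-target counts across a set of normal samples on a
#' common bin grid: per-bin mean and coefficient of variation, plus a
#' usability flag. A bin is usable when at least `min_nonzero_frac` of
#' the normals have a nonzero count and the coefficient of variation is
#' below `max_cv`.
#'
#' @param count_matrix numeric matrix, bins x normal samples (>= 2
#'   columns).
#' @param bins the [cn_bins()] grid the counts live on.
#' @param min_nonzero_frac,max_cv usability criteria.
#' @return A `data.frame` of class `normal_panel` with columns `chrom`,
#'   `start`, `end`, `mean`, `cv`, `usable`.
#' @export
build_pon <- function(count_matrix, bins, min_nonzero_frac = 0.9,
                      max_cv = 1.0) {
  if (ncol(count_matrix) < 2) stop("panel of normals needs >= 2 samples")
  if (nrow(count_matrix) != nrow(bins)) stop("count matrix does not match bins")
  m <- rowMeans(count_matrix)
  s <- apply(count_matrix, 1, stats::sd)
  cv <- ifelse(m > 0, s / m, Inf)
  usable <- rowMeans(count_matrix > 0) >= min_nonzero_frac & cv < max_cv
  out <- data.frame(chrom = bins$chrom, start = bins$start, end = bins$end,
                    mean = m, cv = cv, usable = usable,
                    stringsAsFactors = FALSE)
  class(out) <- c("normal_panel", "data.frame")
  out
}

check_pon_grid <- function(bins, pon) {
  if (nrow(bins) != nrow(pon) ||
      !all(bins$chrom == pon$chrom & bins$start == pon$start &
             bins$end == pon$end))
    stop("panel-of-normals grid does not match the bin grid")
  invisible(TRUE)
}

#' Filter off-target bins
#'
#' Keeps bins that are usable in the panel of normals, have strictly less
#' than `max_fraction` of their width covered by targets, and are hit by
#' at most `max_count` distinct target intervals. Exclusion counts per
#' rule are attached as the `removed` attribute.
#'
#' @param bins annotated bins from [annotate_overlaps()].
#' @param pon a [build_pon()] table on the same grid.
#' @param max_fraction overlap-fraction cutoff (strict `<`).
#' @param max_count maximum overlap count (inclusive).
#' @return The retained bins.
#' @export
filter_bins <- function(bins, pon, max_fraction = 0.25, max_count = 10) {
  check_pon_grid(bins, pon)
  by_frac <- bins$overlap_fraction >= max_fraction
  by_count <- bins$overlap_count > max_count
  by_pon <- !pon$usable
  keep <- !(by_frac | by_count | by_pon)
  out <- bins[keep, , drop = FALSE]
  attr(out, "removed") <- c(overlap_fraction = sum(by_frac),
                            overlap_count = sum(by_count),
                            pon_unusable = sum(by_pon))
  attr(out, "pon") <- pon[keep, , drop = FALSE]
  out
}

#' Fill target-overlapped bins with pseudocounts
#'
#' On-target reads are excluded before counting, so bins partially
#' covered by targets are depleted. Such bins receive a pseudocount
#' equal to the panel-of-normals per-bin mean off-target count, rescaled
#' by the ratio of the sample's median off-target depth (over
#' overlap-free bins) to the panel's median over the same bins.
#'
#' @param bins filtered bins from [filter_bins()].
#' @param pon panel-of-normals rows aligned with `bins` (defaults to the
#'   rows carried by [filter_bins()]).
#' @return Bins with pseudocounts filled and flagged.
#' @export
fill_pseudocounts <- function(bins, pon = attr(bins, "pon")) {
  if (is.null(pon)) stop("panel-of-normals rows required")
  free <- bins$overlap_count == 0
  if (!any(free)) stop("no overlap-free bins to estimate sample depth")
  ratio <- stats::median(bins$count[free]) / stats::median(pon$mean[free])
  hit <- bins$overlap_count > 0
  bins$count[hit] <- pon$mean[hit] * ratio
  bins$pseudocount <- hit
  bins
}

#' Correct target-similarity bias in off-target counts
#'
#' Regions with high sequence similarity to the capture targets attract
#' spuriously high off-target coverage. Each bin carries a standardized
#' `bias_score` quantifying that excess (see [similarity_bias_score()]);
#' a single linear model of log-counts on the score is fitted across
#' usable bins and the fitted component divided out, leaving bins with
#' score 0 unchanged.
#'
#' @param bins bins with `bias_score` and counts.
#' @return Bins with corrected counts; the fitted slope is attached as
#'   the `bias_slope` attribute.
#' @export
bias_correct <- function(bins) {
  if (is.null(bins$bias_score)) stop("bias_score not populated")
  ok <- bins$count > 0
  if (sum(ok) < 3 || stats::sd(bins$bias_score[ok]) == 0) {
    warning("degenerate bias regression: correction skipped")
    attr(bins, "bias_slope") <- 0
    return(bins)
  }
  fit <- stats::lm(log(count) ~ bias_score, data = bins[ok, ])
  slope <- stats::coef(fit)[["bias_score"]]
  bins$count <- bins$count / exp(slope * bins$bias_score)
  attr(bins, "bias_slope") <- slope
  bins
}

#' Standardized target-similarity score from the panel of normals
#'
#' The normals carry no copy-number signal, so systematic excess in
#' their off-target coverage near target-similar regions is a direct
#' readout of the similarity bias. The score is the per-bin log panel
#' mean, centred and scaled to unit variance over usable bins (bins with
#' zero panel mean get score 0). The definition is isolated here so
#' alternative scores can be swapped in.
#'
#' @param pon a [build_pon()] table.
#' @return Numeric score vector aligned with the panel rows.
#' @export
similarity_bias_score <- function(pon) {
  s <- rep(0, nrow(pon))
  ok <- pon$usable & pon$mean > 0
  lx <- log(pon$mean[ok])
  if (stats::sd(lx) > 0) s[ok] <- (lx - mean(lx)) / stats::sd(lx)
  s
}

#' LOESS correction for GC content and replication timing
#'
#' Two sequential univariate LOESS passes on log-counts (GC first, then
#' replication timing), each dividing out the fitted trend re-centred so
#' the genome-wide median count is preserved. With fewer than 100 usable
#' bins, or a constant covariate, the corresponding pass is skipped with
#' a warning.
#'
#' @param bins bins with `gc` and `reptiming` annotated.
#' @param span LOESS span.
#' @return Bins with corrected counts.
#' @export
loess_correct <- function(bins, span = 0.75) {
  for (covariate in c("gc", "reptiming")) {
    x <- bins[[covariate]]
    ok <- bins$count > 0 & !is.na(x)
    if (sum(ok) < 100) {
      warning("fewer than 100 usable bins: ", covariate, " pass skipped")
      next
    }
    if (length(unique(x[ok])) < 10) next  # constant covariate: identity
    df <- data.frame(lc = log(bins$count[ok]), x = x[ok])
    fit <- stats::loess(lc ~ x, data = df, span = span, degree = 2,
                        family = "symmetric")
    trend <- stats::predict(fit, newdata = data.frame(x = x))
    trend[!is.finite(trend)] <- stats::median(trend, na.rm = TRUE)
    med_in <- stats::median(bins$count)
    bins$count <- bins$count / exp(trend)
    bins$count <- bins$count * med_in / stats::median(bins$count)
  }
  bins
}

#' Off-target copy-number calling pipeline
#'
#' Runs the full panel path: target-overlap annotation, bin filtering
#' against the panel of normals, pseudocount filling, similarity-bias
#' correction, GC/replication-timing LOESS correction, median
#' normalisation to relative copy number, penalized changepoint
#' segmentation, and a purity/ploidy fit constrained around the anchor
#' fit from the paired sample. Errors from any stage are re-raised with
#' the stage name.
#'
#' @param bins raw off-target [cn_bins()] counts.
#' @param panel a [panel_design()].
#' @param pon a [build_pon()] table on the bin grid.
#' @param anchor anchor purity/ploidy (list with `purity`, `ploidy`), or
#'   `NULL` for an unconstrained tissue-mode grid search.
#' @param genome a [genome_table()].
#' @param penalty optional segmentation penalty.
#' @return A list with `profile` (absolute-space [cn_profile()]), `fit`
#'   (the `acn_fit`), and `bins` (the corrected bins).
#' @export
offtarget_pipeline <- function(bins, panel, pon, anchor = NULL, genome = NULL,
                               penalty = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("offtarget stage '", name, "': ", conditionMessage(e),
           call. = FALSE))
  }
  b <- stage("annotate_overlaps", annotate_overlaps(bins, panel))
  b$bias_score <- similarity_bias_score(pon)
  b <- stage("filter_bins", filter_bins(b, pon))
  b <- stage("fill_pseudocounts", fill_pseudocounts(b))
  b <- stage("bias_correct", bias_correct(b))
  b <- stage("loess_correct", loess_correct(b))
  b$value <- b$count / stats::median(b$count)
  rel <- stage("segment_profile",
               segment_profile(b, penalty = penalty, genome = genome))
  fit <- if (is.null(anchor)) {
    stage("grid_search_fit", grid_search_fit(rel, mode = "tissue"))
  } else {
    stage("constrained_fit", constrained_fit(rel, anchor, mode = "tissue"))
  }
  list(profile = apply_fit(rel, fit), fit = fit, bins = b)
}
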