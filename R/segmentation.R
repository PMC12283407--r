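#' Segment a binned copy-number profile
#'
#' Piecewise-constant fit of per-bin relative copy number by penalized
#' least-squares changepoint search (PELT with a squared-error segment
#' cost), run independently per chromosome so segments never cross
#' chromosome boundaries. Segment values are the means of their member
#' bins. The changepoint engine is pluggable through `method`.
#'
#' The default penalty is `2 * sigma^2 * log(n)` per chromosome (a
#' BIC-type penalty), with `sigma` estimated robustly from the median
#' absolute deviation of first differences; pass `penalty` to override.
#'
#' @param bins a [cn_bins()] table with `value` filled.
#' @param penalty positive changepoint penalty (in squared-error units);
#'   `NULL` for the data-driven default.
#' @param genome a [genome_table()]; defaults to one spanning the bins.
#' @param method changepoint engine; only `"pelt"` is built in.
#' @return A relative-space [cn_profile()].
#' @export
segment_profile <- function(bins, penalty = NULL, genome = NULL,
                            method = c("pelt")) {
  method <- match.arg(method)
  if (anyNA(bins$value)) stop("bin values missing: run correct_counts first")
  if (nrow(bins) < 2) stop("need at least 2 bins to segment")
  if (!is.null(penalty) && penalty <= 0) stop("penalty must be positive")
  if (is.null(genome)) {
    ends <- tapply(bins$end, bins$chrom, max)
    genome <- genome_table(names(ends), as.numeric(ends),
                           pmax(1, as.numeric(ends) / 2))
  }
  chroms <- unique(bins$chrom)
  seg <- do.call(rbind, lapply(chroms, function(ch) {
    b <- bins[bins$chrom == ch, , drop = FALSE]
    x <- b$value
    pen <- penalty
    if (is.null(pen)) {
      sigma2 <- (stats::mad(diff(x)) / sqrt(2))^2
      pen <- max(2 * sigma2 * log(length(x)), 1e-9)
    }
    ends_idx <- if (length(x) == 1) integer(0) else pelt_mean(x, pen)
    bounds <- c(0, ends_idx, length(x))
    data.frame(chrom = ch,
               start = b$start[bounds[-length(bounds)] + 1],
               end = b$end[bounds[-1]],
               value = vapply(seq_len(length(bounds) - 1), function(k) {
                 mean(x[(bounds[k] + 1):bounds[k + 1]])
               }, numeric(1)),
               n_bins = diff(bounds),
               stringsAsFactors = FALSE)
  }))
  cn_profile(seg, genome, "relative")
}

# PELT changepoint search for a piecewise-constant mean with squared
# error cost; returns the sorted indices of the last element of each
# segment except the final one. Pruning keeps the search near-linear.
pelt_mean <- function(x, penalty) {
  n <- length(x)
  if (n < 2) return(integer(0))
  S1 <- c(0, cumsum(x))
  S2 <- c(0, cumsum(x * x))
  f <- c(-penalty, rep(Inf, n))
  prev <- vector("list", n + 1)
  prev[[1]] <- integer(0)
  cand <- 1L # candidate segment start points (1-based)
  for (t in seq_len(n)) {
    len <- t - cand + 1
    cost <- S2[t + 1] - S2[cand] - (S1[t + 1] - S1[cand])^2 / len
    total <- f[cand] + cost + penalty
    best <- which.min(total)
    f[t + 1] <- total[best]
    s <- cand[best]
    prev[[t + 1]] <- c(prev[[s]], s - 1L)
    keep <- (total - penalty) <= f[t + 1]
    cand <- c(cand[keep], t + 1L)
  }
  cps <- prev[[n + 1]]
  as.integer(cps[cps > 0])
}
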