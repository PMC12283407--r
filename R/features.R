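#' Extract copy-number features from an absolute profile
#'
#' Computes the five copy-number feature distributions that the CIN
#' signature encoding is built on:
#' \describe{
#'   \item{segsize}{length in bp of every segment.}
#'   \item{changepoint}{absolute copy-number difference at every
#'     boundary between adjacent segments on the same chromosome.}
#'   \item{bp10MB}{breakpoint counts in non-overlapping 10 Mb tiles;
#'     tiles without breakpoints contribute no event.}
#'   \item{bpchrarm}{breakpoint counts per chromosome arm (arms without
#'     breakpoints contribute no event); requires the genome table's arm
#'     boundaries.}
#'   \item{osCN}{lengths (in segments) of maximal chains of at least 3
#'     consecutive segments whose rounded copy numbers alternate between
#'     exactly two states; chains are broken at arm boundaries.}
#' }
#'
#' @param profile an absolute-space [cn_profile()].
#' @param genome a [genome_table()]; defaults to the profile's.
#' @return A list of class `cn_features` with one numeric vector per
#'   feature.
#' @export
extract_features <- function(profile, genome = profile_genome(profile)) {
  if (profile_space(profile) != "absolute")
    stop("extract_features expects an absolute-space profile")
  if (is.null(genome)) stop("genome table with arm boundaries required")
  segsize <- seg_len(profile)
  changepoint <- numeric(0)
  bp10 <- numeric(0)
  bparm <- numeric(0)
  oscn <- numeric(0)
  for (ch in unique(profile$chrom)) {
    s <- profile[profile$chrom == ch, , drop = FALSE]
    if (nrow(s) >= 2) {
      changepoint <- c(changepoint, abs(diff(s$value)))
      bp_pos <- s$end[-nrow(s)]
      tile <- floor(bp_pos / 1e7)
      bp10 <- c(bp10, as.numeric(table(tile)))
      arm <- genome_arm(genome, ch, bp_pos)
      bparm <- c(bparm, as.numeric(table(arm)))
    }
    arm_grp <- genome_arm(genome, ch, s$start)
    for (a in unique(arm_grp)) {
      oscn <- c(oscn, oscillating_chains(round(s$value[arm_grp == a])))
    }
  }
  structure(list(segsize = segsize, changepoint = changepoint,
                 bp10MB = bp10, bpchrarm = bparm, osCN = oscn),
            class = "cn_features")
}

# maximal runs of >= min_len consecutive values alternating between
# exactly two distinct states; returns run lengths in segments
oscillating_chains <- function(v, min_len = 3) {
  out <- numeric(0)
  n <- length(v)
  i <- 1
  while (i <= n - 1) {
    if (v[i] == v[i + 1]) {
      i <- i + 1
      next
    }
    j <- i + 1
    while (j + 1 <= n && v[j + 1] == v[j - 1]) j <- j + 1
    if (j - i + 1 >= min_len) out <- c(out, j - i + 1)
    i <- j
  }
  out
}

#' @export
print.cn_features <- function(x, ...) {
  cat("cn_features:",
      paste(sprintf("%s=%d", names(x), lengths(x)), collapse = ", "), "\n")
  invisible(x)
}
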