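#' Genome tables
#'
#' A genome table records, for every chromosome, its length and the
#' position of the centromere (used as the p/q arm boundary). It is
#' required by arm-aware operations: breakpoint counts per chromosome
#' arm, oscillating-chain detection, and the weighted genome instability
#' index. All coordinates in the package are 0-based, half-open.
#'
#' @param chrom character vector of chromosome names.
#' @param length chromosome lengths in base pairs.
#' @param arm_boundary centromere position; must lie strictly inside the
#'   chromosome.
#' @return A `data.frame` of class `genome_table` with columns `chrom`,
#'   `length`, `arm_boundary`.
#' @export
genome_table <- function(chrom, length, arm_boundary) {
  stopifnot(length(chrom) == length(length),
            length(chrom) == length(arm_boundary))
  if (anyDuplicated(chrom))
    stop("duplicated chromosome names in genome table")
  if (any(length <= 0))
    stop("chromosome lengths must be positive")
  if (any(arm_boundary <= 0 | arm_boundary >= length))
    stop("arm boundary must lie strictly inside the chromosome")
  gt <- data.frame(chrom = as.character(chrom),
                   length = as.numeric(length),
                   arm_boundary = as.numeric(arm_boundary),
                   stringsAsFactors = FALSE)
  class(gt) <- c("genome_table", "data.frame")
  gt
}

#' Toy genome for simulation and testing
#'
#' Four chromosomes of 50 Mb each with an off-center arm boundary. Small
#' enough that grid searches, segmentations and end-to-end simulations
#' run in seconds, while retaining multiple chromosomes and arms so every
#' arm-aware feature is exercised.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_length length of each chromosome in bp.
#' @param arm_fraction relative position of the arm boundary.
#' @return A `genome_table`.
#' @export
toy_genome <- function(n_chrom = 4, chrom_length = 5e7, arm_fraction = 0.45) {
  genome_table(chrom = paste0("chr", seq_len(n_chrom)),
               length = rep(chrom_length, n_chrom),
               arm_boundary = rep(round(arm_fraction * chrom_length), n_chrom))
}

#' hg19 genome table
#'
#' Chromosome lengths and centromere positions for the hg19 human
#' reference, read from the arm table shipped with the package.
#'
#' @return A `genome_table` with 24 chromosomes (chr1-chr22, chrX, chrY).
#' @export
hg19_genome <- function() {
  path <- system.file("extdata", "hg19_arms.tsv", package = "cinresist",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  genome_table(tab$chrom, tab$length, tab$arm_boundary)
}

# Lookup helpers ---------------------------------------------------------

genome_length <- function(genome, chrom) {
  idx <- match(chrom, genome$chrom)
  if (anyNA(idx)) stop("chromosome not in genome table: ",
                       paste(unique(chrom[is.na(idx)]), collapse = ", "))
  genome$length[idx]
}

genome_arm <- function(genome, chrom, pos) {
  idx <- match(chrom, genome$chrom)
  if (anyNA(idx)) stop("chromosome not in genome table")
  ifelse(pos < genome$arm_boundary[idx], "p", "q")
}
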