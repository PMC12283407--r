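#' Read and write SEG-style segment tables
#'
#' Segment tables are tab-separated files with columns `chrom`, `start`,
#' `end`, `value` and optionally `n_bins`. On disk, coordinates are
#' 1-based inclusive (SEG convention); internally the package uses
#' 0-based half-open coordinates, so `read_segments` subtracts 1 from
#' `start` and `write_segments` adds it back. `read_segments` followed by
#' `write_segments` (and vice versa) is the identity.
#'
#' @param path file path.
#' @param genome a [genome_table()].
#' @param space `"relative"` or `"absolute"`.
#' @return `read_segments` returns a [cn_profile()]; `write_segments`
#'   returns `path` invisibly.
#' @export
read_segments <- function(path, genome, space = c("relative", "absolute")) {
  space <- match.arg(space)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("chrom", "start", "end", "value")
  if (!all(req %in% names(tab)))
    stop("segment table needs columns ", paste(req, collapse = ", "))
  tab$start <- tab$start - 1
  cn_profile(tab, genome, space)
}

#' @rdname read_segments
#' @param profile a [cn_profile()] to write.
#' @export
write_segments <- function(profile, path) {
  out <- as.data.frame(profile)
  out$start <- out$start + 1
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a bin table
#'
#' Bin tables are tab-separated with columns `chrom`, `start`, `end` and
#' any of `gc`, `mappability`, `reptiming`, `count`, `value`. Bin-table
#' coordinates are 0-based half-open on disk (BED-like), matching the
#' internal convention.
#'
#' @param path file path.
#' @return A [cn_bins()] table.
#' @export
read_bins <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("chrom", "start", "end")
  if (!all(req %in% names(tab)))
    stop("bin table needs columns ", paste(req, collapse = ", "))
  grab <- function(col, default) {
    if (col %in% names(tab)) as.numeric(tab[[col]]) else default
  }
  cn_bins(tab$chrom, tab$start, tab$end,
          gc = grab("gc", NA_real_),
          mappability = grab("mappability", 1),
          reptiming = grab("reptiming", 0),
          count = grab("count", NA_real_),
          value = grab("value", NA_real_))
}

#' @rdname read_bins
#' @param bins a [cn_bins()] table to write.
#' @export
write_bins <- function(bins, path) {
  utils::write.table(as.data.frame(bins), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read BED intervals
#'
#' Reads the first three columns of a BED file (0-based half-open) into a
#' sorted, per-chromosome merged interval table, the representation used
#' for capture-panel target regions.
#'
#' @param path BED file path.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, sorted
#'   and merged per chromosome (class `panel_design`).
#' @export
read_bed <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           comment.char = "#")
  panel_design(data.frame(chrom = tab[[1]], start = as.numeric(tab[[2]]),
                          end = as.numeric(tab[[3]]),
                          stringsAsFactors = FALSE))
}

#' Panel target intervals
#'
#' Sorts and merges overlapping target intervals per chromosome.
#'
#' @param intervals `data.frame` with `chrom`, `start`, `end`.
#' @return A `panel_design` data frame.
#' @export
panel_design <- function(intervals) {
  if (any(intervals$end <= intervals$start))
    stop("intervals must have end > start")
  out <- do.call(rbind, lapply(split(intervals, intervals$chrom), function(s) {
    s <- s[order(s$start), , drop = FALSE]
    merged <- s[1, c("chrom", "start", "end")]
    if (nrow(s) > 1) {
      for (i in 2:nrow(s)) {
        j <- nrow(merged)
        if (s$start[i] <= merged$end[j]) {
          merged$end[j] <- max(merged$end[j], s$end[i])
        } else {
          merged <- rbind(merged, s[i, c("chrom", "start", "end")])
        }
      }
    }
    merged
  }))
  rownames(out) <- NULL
  class(out) <- c("panel_design", "data.frame")
  out
}
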