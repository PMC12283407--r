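# Run expr with a temporarily fixed RNG state, restoring the caller's.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Synthetic 17-signature model
#'
#' A deterministic, clearly synthetic stand-in for a real CIN signature
#' definition: 17 signatures (CX1-CX17) over 19 mixture components
#' spanning the five copy-number features (gaussian components on log10
#' segment size and on copy-number changepoints; poisson components on
#' the three count features). Component locations are well separated so
#' the sum-of-posterior encoding is close to a hard assignment, and the
#' signature matrix has full row rank, so planted exposures are
#' recoverable. Real definition matrices and mixture components are
#' drop-in replacements via [load_signature_model()].
#'
#' @param n_signatures number of signatures (default 17).
#' @param seed seed for the deterministic construction.
#' @return A list with `matrix` (K x C, rows summing to 1), `mixture`
#'   (a [mixture_model()]), `thresholds` (synthetic per-signature
#'   activity thresholds) and `name`.
#' @export
synthetic_signature_model <- function(n_signatures = 17, seed = 13) {
  comp <- rbind(
    data.frame(feature = "segsize", family = "gaussian",
               mean = seq(4.4, 7.6, by = 0.4), sd = 0.09,
               lambda = NA, scale = "log10"),
    data.frame(feature = "changepoint", family = "gaussian",
               mean = c(1, 2, 3, 4, 5, 6), sd = 0.15, lambda = NA,
               scale = "identity"),
    data.frame(feature = "bp10MB", family = "poisson", mean = NA, sd = NA,
               lambda = c(2, 12, 45), scale = "identity"),
    data.frame(feature = "bpchrarm", family = "poisson", mean = NA, sd = NA,
               lambda = c(2, 14, 50), scale = "identity"),
    data.frame(feature = "osCN", family = "poisson", mean = NA, sd = NA,
               lambda = c(3, 15, 45), scale = "identity"))
  for (f in unique(comp$feature)) {
    i <- comp$feature == f
    comp$component[i] <- paste0(f, "_", seq_len(sum(i)))
  }
  C <- nrow(comp)
  K <- n_signatures
  # Each candidate signature concentrates most of each feature block on
  # one "primary" component; the final set is a greedy minimum-coherence
  # selection from a large candidate pool, so signatures stay mutually
  # distinguishable and planted exposures are recoverable from realistic
  # event counts.
  M <- with_seed(seed, {
    blocks <- split(seq_len(C), comp$feature)[unique(comp$feature)]
    pool_n <- 4000
    pool <- t(vapply(seq_len(pool_n), function(i) {
      fw <- 0.1 + stats::rgamma(length(blocks), 2)
      fw <- fw / sum(fw)
      row <- numeric(C)
      for (bi in seq_along(blocks)) {
        idx <- blocks[[bi]]
        wts <- stats::rgamma(length(idx), 0.08)
        p <- sample(seq_along(idx), 1)
        wts[p] <- wts[p] + 6
        row[idx] <- fw[bi] * wts / sum(wts)
      }
      row / sum(row)
    }, numeric(C)))
    unit <- pool / sqrt(rowSums(pool^2))
    sel <- sample(pool_n, 1)
    for (k in seq_len(K - 1)) {
      cc <- unit %*% t(unit[sel, , drop = FALSE])
      worst <- apply(cc, 1, max)
      worst[sel] <- Inf
      sel <- c(sel, which.min(worst))
    }
    pool[sel, , drop = FALSE]
  })
  rownames(M) <- paste0("CX", seq_len(K))
  colnames(M) <- comp$component
  comp$weight <- colMeans(M)
  for (f in unique(comp$feature)) {
    i <- comp$feature == f
    comp$weight[i] <- comp$weight[i] / sum(comp$weight[i])
  }
  thresholds <- stats::setNames(
    with_seed(seed + 1, round(stats::runif(K, 0.005, 0.03), 4)),
    rownames(M))
  list(matrix = M,
       mixture = mixture_model(comp[, c("feature", "component", "family",
                                        "mean", "sd", "lambda", "weight",
                                        "scale")]),
       thresholds = thresholds,
       name = "synthetic-17")
}

#' Read and write signature models as TSV
#'
#' A signature model directory holds `signature_matrix.tsv` (signatures
#' in rows, components in columns) and `mixture_components.tsv` (one row
#' per component), and optionally `thresholds.tsv` (columns `signature`,
#' `threshold`). Real definition matrices in the same layout are used
#' unchanged.
#'
#' @param dir directory containing the TSV files.
#' @return A signature model list as in [synthetic_signature_model()].
#' @export
load_signature_model <- function(dir) {
  M <- as.matrix(utils::read.delim(file.path(dir, "signature_matrix.tsv"),
                                   row.names = 1, check.names = FALSE))
  comp <- utils::read.delim(file.path(dir, "mixture_components.tsv"),
                            stringsAsFactors = FALSE)
  mm <- mixture_model(comp)
  if (!identical(colnames(M), mm$component))
    stop("signature matrix columns do not match mixture components")
  thr <- NULL
  tpath <- file.path(dir, "thresholds.tsv")
  if (file.exists(tpath)) {
    tt <- utils::read.delim(tpath, stringsAsFactors = FALSE)
    thr <- stats::setNames(tt$threshold, tt$signature)
  }
  list(matrix = M, mixture = mm, thresholds = thr, name = basename(dir))
}

#' Read a scaling model from TSV
#'
#' Scaling models (per-signature mean and standard deviation of a
#' reference cohort) are configuration inputs: the package ships clearly
#' synthetic stand-ins (`scaling_pan_synthetic.tsv`,
#' `scaling_brca_synthetic.tsv` under `extdata`), and models derived from
#' real cohorts are drop-in replacements in the same layout.
#'
#' @param path TSV with columns `signature`, `mean`, `sd`.
#' @return A `scaling_model` data frame as from [fit_scaling()].
#' @export
load_scaling_model <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (any(tab$sd <= 0)) stop("scaling sd must be positive")
  class(tab) <- c("scaling_model", "data.frame")
  tab
}

#' @rdname load_signature_model
#' @param model a signature model list.
#' @export
write_signature_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(cbind(signature = rownames(model$matrix),
                           as.data.frame(model$matrix)),
                     file.path(dir, "signature_matrix.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(model$mixture),
                     file.path(dir, "mixture_components.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(model$thresholds)) {
    utils::write.table(data.frame(signature = names(model$thresholds),
                                  threshold = model$thresholds),
                       file.path(dir, "thresholds.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
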