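#' Mixture-component models for copy-number features
#'
#' Each copy-number feature is summarised by a fixed, ordered set of
#' mixture components (gaussian for continuous features, poisson for
#' counts). The component order defines the coordinates of the
#' sum-of-posterior encoding, so it must match the signature definition
#' matrix column order. Continuous features may be modelled on a
#' transformed scale (`scale` column: `"identity"` or `"log10"`);
#' event values are transformed before density evaluation.
#'
#' @param components `data.frame` with columns `feature`, `component`
#'   (unique id), `family` (`"gaussian"` or `"poisson"`), `mean`, `sd`,
#'   `lambda`, `weight`, `scale`.
#' @return A `data.frame` of class `cn_mixture`.
#' @export
mixture_model <- function(components) {
  req <- c("feature", "component", "family", "mean", "sd", "lambda",
           "weight", "scale")
  if (!all(req %in% names(components)))
    stop("components need columns ", paste(req, collapse = ", "))
  if (!all(components$family %in% c("gaussian", "poisson")))
    stop("unsupported component family")
  if (any(components$weight < 0)) stop("component weights must be >= 0")
  if (anyDuplicated(components$component)) stop("duplicate component ids")
  rownames(components) <- NULL
  class(components) <- c("cn_mixture", "data.frame")
  components
}

component_density <- function(mm_rows, x) {
  vapply(seq_len(nrow(mm_rows)), function(i) {
    if (mm_rows$family[i] == "gaussian") {
      stats::dnorm(x, mm_rows$mean[i], mm_rows$sd[i])
    } else {
      stats::dpois(round(x), mm_rows$lambda[i])
    }
  }, numeric(length(x)))
}

#' Sum-of-posterior encoding of copy-number features
#'
#' For every event of feature \eqn{f}, the posterior probability over
#' \eqn{f}'s mixture components is computed (proportional to component
#' weight times density at the event value) and the posteriors are summed
#' per component across events. The resulting vector of length C (total
#' components) is the sample's encoding; the block of components
#' belonging to feature \eqn{f} sums to the number of events of
#' \eqn{f}. Events with zero total density receive a uniform posterior
#' with a warning.
#'
#' @param features a [extract_features()] catalog (or compatible list).
#' @param mm a [mixture_model()].
#' @return Named numeric vector of length `nrow(mm)`.
#' @export
encode_posteriors <- function(features, mm) {
  enc <- stats::setNames(numeric(nrow(mm)), mm$component)
  for (f in unique(mm$feature)) {
    x <- features[[f]]
    if (is.null(x))
      stop("feature ", f, " missing from the catalog")
    if (!length(x)) next
    rows <- which(mm$feature == f)
    sub <- mm[rows, , drop = FALSE]
    if (sub$scale[1] == "log10") x <- log10(x)
    dens <- component_density(sub, x)              # events x components
    if (is.null(dim(dens))) dens <- matrix(dens, nrow = length(x))
    post <- sweep(dens, 2, sub$weight, `*`)
    tot <- rowSums(post)
    if (any(tot == 0)) {
      warning("event(s) with zero density under feature ", f,
              ": uniform posterior used")
      post[tot == 0, ] <- 1 / ncol(post)
      tot[tot == 0] <- 1
    }
    enc[rows] <- colSums(post / tot)
  }
  enc
}

#' Signature activities by non-negative linear decomposition
#'
#' Solves the non-negative least-squares problem
#' \eqn{\min_w \|v - M^T w\|_2, w \ge 0} for a sample encoding \eqn{v}
#' and signature definition matrix \eqn{M} (signatures x components,
#' rows summing to 1), then normalises the exposures to sum to 1. This
#' is the linear-combination-decomposition step that turns an encoding
#' into per-signature activities.
#'
#' @param encoding numeric vector of length C (non-negative).
#' @param M signature matrix (K x C) with rownames naming signatures.
#' @return A named `activity_vector` (state `"raw"`); an all-zero
#'   encoding yields all-zero activities with the `no_cin` attribute set.
#' @export
lcd <- function(encoding, M) {
  if (length(encoding) != ncol(M))
    stop("encoding length does not match signature matrix columns")
  if (any(encoding < 0)) stop("encoding must be non-negative")
  if (all(encoding == 0)) {
    return(activity_vector(stats::setNames(numeric(nrow(M)), rownames(M)),
                           state = "raw", no_cin = TRUE))
  }
  w <- pracma::lsqnonneg(t(M), as.numeric(encoding))$x
  if (sum(w) == 0) {
    return(activity_vector(stats::setNames(numeric(nrow(M)), rownames(M)),
                           state = "raw", no_cin = TRUE))
  }
  activity_vector(stats::setNames(w / sum(w), rownames(M)), state = "raw")
}

#' Activity vectors
#'
#' Per-sample activities of the K signatures, tagged with their state:
#' `raw` (non-negative, summing to 1), `thresholded` (small activities
#' zeroed, no renormalisation, so the sum is at most 1) or `scaled`
#' (z-scores, unconstrained).
#'
#' @param x named numeric vector.
#' @param state one of `"raw"`, `"thresholded"`, `"scaled"`.
#' @param no_cin flag set when the sample had no copy-number events.
#' @return A numeric vector of class `activity_vector`.
#' @export
activity_vector <- function(x, state = c("raw", "thresholded", "scaled"),
                            no_cin = FALSE) {
  state <- match.arg(state)
  structure(x, state = state, no_cin = no_cin, class = "activity_vector")
}

#' @export
print.activity_vector <- function(x, ...) {
  cat("activity_vector (", attr(x, "state"), ")\n", sep = "")
  print(round(unclass(x), 4))
  invisible(x)
}

#' Apply per-signature activity thresholds
#'
#' Activities strictly below their signature-specific threshold are set
#' to 0; activities at or above the threshold are kept unchanged. No
#' renormalisation is performed, keeping thresholding monotone in the
#' input activities.
#'
#' @param a a raw [activity_vector()].
#' @param thresholds named numeric vector of per-signature thresholds.
#' @return A thresholded `activity_vector`.
#' @export
apply_thresholds <- function(a, thresholds) {
  if (any(thresholds < 0)) stop("thresholds must be >= 0")
  thr <- thresholds[names(a)]
  if (anyNA(thr)) stop("thresholds missing for some signatures")
  out <- ifelse(unclass(a) < thr, 0, unclass(a))
  activity_vector(stats::setNames(out, names(a)), state = "thresholded",
                  no_cin = attr(a, "no_cin"))
}

#' Fit a cohort scaling model
#'
#' Per-signature mean and standard deviation over a (subset of a)
#' reference cohort; used to z-score activities so one decision
#' threshold transfers across tumor types. The classifiers use two such
#' models: one fitted on BRCA1/2-mutant cases (platinum) and one fitted
#' on the whole reference cohort (taxane).
#'
#' @param activities numeric matrix, samples x signatures.
#' @param subset optional logical/integer selector of samples.
#' @param cohort label stored with the model.
#' @return A `data.frame` of class `scaling_model` with columns
#'   `signature`, `mean`, `sd`.
#' @export
fit_scaling <- function(activities, subset = NULL, cohort = "cohort") {
  a <- if (is.null(subset)) activities else activities[subset, , drop = FALSE]
  if (nrow(a) < 2) stop("scaling needs at least 2 samples")
  mu <- colMeans(a)
  sdv <- apply(a, 2, stats::sd)
  if (any(sdv == 0))
    stop("zero standard deviation for signature ",
         paste(colnames(a)[sdv == 0], collapse = ", "))
  out <- data.frame(signature = colnames(a), mean = mu, sd = sdv,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "cohort") <- cohort
  class(out) <- c("scaling_model", "data.frame")
  out
}

#' Z-score activities with a scaling model
#'
#' @param a an [activity_vector()].
#' @param scaling a [fit_scaling()] model.
#' @return A scaled `activity_vector`.
#' @export
scale_activities <- function(a, scaling) {
  idx <- match(names(a), scaling$signature)
  if (anyNA(idx)) stop("scaling model missing some signatures")
  z <- (unclass(a) - scaling$mean[idx]) / scaling$sd[idx]
  activity_vector(stats::setNames(z, names(a)), state = "scaled",
                  no_cin = attr(a, "no_cin"))
}

#' Cosine similarity between activity vectors
#'
#' \eqn{a \cdot b / (\|a\| \|b\|)}; defined as 0 when either vector is
#' all-zero.
#'
#' @param a,b numeric vectors over the same signature set.
#' @return Cosine similarity in `[-1, 1]`.
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have the same length")
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' Signature activities for a profile, end to end
#'
#' Convenience wrapper: feature extraction, sum-of-posterior encoding,
#' non-negative decomposition, and (optionally) thresholding.
#'
#' @param profile an absolute-space [cn_profile()].
#' @param model a signature model list with elements `matrix` (K x C)
#'   and `mixture` (a [mixture_model()]), e.g. from
#'   [synthetic_signature_model()] or [load_signature_model()].
#' @param thresholds optional named thresholds; when given the returned
#'   vector is thresholded.
#' @return An [activity_vector()].
#' @export
signature_activities <- function(profile, model, thresholds = NULL) {
  feats <- extract_features(profile)
  enc <- encode_posteriors(feats, model$mixture)
  a <- lcd(enc, model$matrix)
  if (!is.null(thresholds)) a <- apply_thresholds(a, thresholds)
  a
}
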