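#' Transform relative to absolute copy number
#'
#' Under the tumor/normal mixing model, the relative copy number of bin
#' \eqn{j} is \eqn{rCN_j = d (purity \cdot aCN_j + 2 (1 - purity))},
#' where \eqn{d = r / (ploidy \cdot purity + 2 (1 - purity))} is a depth
#' constant computed from the sample mean relative copy number \eqn{r}.
#' Two inversion variants are provided:
#' \describe{
#'   \item{`consistent` (default)}{\eqn{aCN_j = (rCN_j / d - 2 (1 -
#'     purity)) / purity}, the exact algebraic inverse of the mixing
#'     model: a pure diploid sample with \eqn{rCN = r = 1} maps to
#'     \eqn{aCN = 2}.}
#'   \item{`printed`}{the same expression with an additional trailing
#'     \eqn{-2} term. Under this form an average bin at purity 1 maps to
#'     \eqn{ploidy - 2}, which is inconsistent with the definition of
#'     \eqn{d}; the variant is retained so the published form can be
#'     reproduced verbatim, but it is not the default.}
#' }
#'
#' @param rcn numeric vector of per-bin relative copy number.
#' @param purity tumor cell fraction in `(0, 1]`.
#' @param ploidy average tumor copy number, `> 0`.
#' @param r sample mean relative copy number, `> 0`.
#' @param variant `"consistent"` or `"printed"`.
#' @return Per-bin absolute copy number.
#' @export
relative_to_absolute <- function(rcn, purity, ploidy, r,
                                 variant = c("consistent", "printed")) {
  variant <- match.arg(variant)
  if (purity <= 0 || purity > 1) stop("purity must be in (0, 1]")
  if (ploidy <= 0) stop("ploidy must be positive")
  if (r <= 0) stop("r must be positive")
  d <- depth_constant(r, purity, ploidy)
  if (d <= 0) stop("non-positive depth constant")
  acn <- (rcn / d - 2 * (1 - purity)) / purity
  if (variant == "printed") acn <- acn - 2
  acn
}

depth_constant <- function(r, purity, ploidy) {
  r / (ploidy * purity + 2 * (1 - purity))
}

#' Goodness of fit of absolute copy number to integer states
#'
#' The mean squared deviation of per-bin absolute copy number from the
#' nearest integer: \eqn{e = (1/J) \sum_j (aCN_j - round(aCN_j))^2}.
#' Rounding is round-half-to-even (R's `round`). A good purity/ploidy
#' fit places most of the genome near integer states, so `fit_error`
#' is the grid-search objective.
#'
#' @param acn per-bin absolute copy number.
#' @param weights optional non-negative weights (e.g. bins per segment).
#' @return Non-negative mean squared error.
#' @export
fit_error <- function(acn, weights = NULL) {
  if (length(acn) == 0) stop("need at least one bin")
  dev2 <- (acn - round(acn))^2
  if (is.null(weights)) mean(dev2) else sum(dev2 * weights) / sum(weights)
}

#' Purity/ploidy grid search
#'
#' Evaluates every (purity, ploidy) combination on the grid, transforming
#' the segmented relative copy-number profile to absolute space and
#' scoring it with [fit_error()] (weighted by bins per segment). The
#' default grid spans purities 0.05 to 1 in 0.01 increments and ploidies
#' 1.8 to 8 in 0.1 increments. Two filters exclude implausible fits:
#' \itemize{
#'   \item `homozygous_loss_excess`: more than `max_homozygous_loss`
#'     (default 10 Mb) of the genome at rounded copy number 0 or below;
#'   \item `missing_integer_state` (`mode = "tissue"` only): no segment
#'     at some integer copy-number state between 1 and the rounded
#'     candidate ploidy.
#' }
#' `mode = "pure_model"` fixes purity at 1 (cell lines and organoids are
#' taken as 100\% pure) and searches over ploidy only; the integer-state
#' filter is not applied in this mode. Admissible fits are ranked by
#' error, ties broken by lower ploidy then higher purity.
#'
#' @param profile a relative-space [cn_profile()].
#' @param mode `"tissue"` or `"pure_model"`.
#' @param purity_grid,ploidy_grid candidate values.
#' @param variant transformation variant, see [relative_to_absolute()].
#' @param max_homozygous_loss maximum tolerated genome length (bp) at
#'   rounded copy number <= 0.
#' @return An object of class `acn_fit`: a list with `best` (the top
#'   admissible fit), `fits` (the full ranked admissible grid),
#'   `excluded` (per-filter exclusion counts), `r`, `mode`, `variant`.
#' @export
grid_search_fit <- function(profile, mode = c("tissue", "pure_model"),
                            purity_grid = seq(0.05, 1, by = 0.01),
                            ploidy_grid = seq(1.8, 8, by = 0.1),
                            variant = c("consistent", "printed"),
                            max_homozygous_loss = 1e7) {
  mode <- match.arg(mode)
  variant <- match.arg(variant)
  if (nrow(profile) == 0) stop("empty profile")
  if (!length(purity_grid) || !length(ploidy_grid)) stop("empty grid")
  if (mode == "pure_model") purity_grid <- 1
  vals <- profile$value
  w <- as.numeric(profile$n_bins)
  len <- seg_len(profile)
  r <- sum(vals * len) / sum(len)
  if (r <= 0) stop("non-positive mean relative copy number")

  grid <- expand.grid(purity = purity_grid, ploidy = ploidy_grid,
                      KEEP.OUT.ATTRS = FALSE)
  d <- depth_constant(r, grid$purity, grid$ploidy)
  # aCN matrix: one row per grid point, one column per segment
  acn <- outer(1 / (d * grid$purity), vals) - 2 * (1 - grid$purity) / grid$purity
  if (variant == "printed") acn <- acn - 2
  states <- round(acn)
  dev2 <- (acn - states)^2
  err <- as.numeric(dev2 %*% w) / sum(w)
  hl_len <- as.numeric((states <= 0) %*% len)
  flag_hl <- hl_len > max_homozygous_loss
  flag_state <- rep(FALSE, nrow(grid))
  if (mode == "tissue") {
    max_state <- max(1, round(max(grid$ploidy)))
    present <- vapply(seq_len(max_state), function(k) {
      rowSums(states == k) > 0
    }, logical(nrow(grid)))
    need <- outer(round(grid$ploidy), seq_len(max_state), ">=")
    flag_state <- rowSums(need & !present) > 0
  }
  fits <- data.frame(purity = grid$purity, ploidy = grid$ploidy, d = d,
                     error = err, n_bins = sum(w),
                     homozygous_loss_excess = flag_hl,
                     missing_integer_state = flag_state)
  admissible <- fits[!flag_hl & !flag_state, , drop = FALSE]
  if (nrow(admissible) == 0) {
    stop(sprintf(paste0("no admissible fit: %d/%d excluded by homozygous",
                        " loss, %d/%d by missing integer state"),
                 sum(flag_hl), nrow(fits), sum(flag_state), nrow(fits)))
  }
  ord <- order(admissible$error, admissible$ploidy, -admissible$purity)
  admissible <- admissible[ord, , drop = FALSE]
  rownames(admissible) <- NULL
  structure(list(best = admissible[1, ], fits = admissible,
                 excluded = c(homozygous_loss_excess = sum(flag_hl),
                              missing_integer_state = sum(flag_state)),
                 r = r, mode = mode, variant = variant),
            class = "acn_fit")
}

#' @export
print.acn_fit <- function(x, ...) {
  cat(sprintf("acn_fit (%s, %s): purity %.2f, ploidy %.1f, error %.4g\n",
              x$mode, x$variant, x$best$purity, x$best$ploidy, x$best$error))
  invisible(x)
}

#' Purity/ploidy fit constrained around an anchor fit
#'
#' Restricts the grid search to a window around a fit obtained from a
#' paired sample (e.g. the matched shallow-WGS fit when calling copy
#' number from panel off-target reads): ploidy within `ploidy_window`
#' and purity within `purity_window` of the anchor, intersected with the
#' global grid. With zero windows the anchor's own (purity, ploidy) is
#' re-scored on the new profile. The returned fit carries a
#' `boundary_solution` flag when the optimum sits on the window edge,
#' signalling that the truth may lie outside the window.
#'
#' @param profile a relative-space [cn_profile()].
#' @param anchor a list or one-row data frame with `purity` and `ploidy`.
#' @param ploidy_window,purity_window half-widths of the search window.
#' @param ... passed to [grid_search_fit()].
#' @return An `acn_fit` object.
#' @export
constrained_fit <- function(profile, anchor, ploidy_window = 0.2,
                            purity_window = 0.05, ...) {
  full_purity <- seq(0.05, 1, by = 0.01)
  full_ploidy <- seq(1.8, 8, by = 0.1)
  pg <- if (purity_window == 0) anchor$purity else
    full_purity[abs(full_purity - anchor$purity) <= purity_window + 1e-9]
  Pg <- if (ploidy_window == 0) anchor$ploidy else
    full_ploidy[abs(full_ploidy - anchor$ploidy) <= ploidy_window + 1e-9]
  if (!length(pg) || !length(Pg))
    stop("restricted grid is empty around the anchor")
  fit <- grid_search_fit(profile, purity_grid = pg, ploidy_grid = Pg, ...)
  on_edge <- (length(pg) > 1 &&
                fit$best$purity %in% range(pg) &&
                !fit$best$purity %in% range(full_purity)) ||
             (length(Pg) > 1 &&
                fit$best$ploidy %in% range(Pg) &&
                !fit$best$ploidy %in% range(full_ploidy))
  fit$boundary_solution <- on_edge
  fit$anchor <- c(purity = anchor$purity, ploidy = anchor$ploidy)
  fit
}

#' Convert a segmented relative profile to absolute space with a fit
#'
#' Applies [relative_to_absolute()] segment-wise using a fitted purity
#' and ploidy, clamping tiny negative values to zero.
#'
#' @param profile a relative-space [cn_profile()].
#' @param fit an `acn_fit` or anything with `purity` and `ploidy`.
#' @param variant transformation variant.
#' @return An absolute-space [cn_profile()].
#' @export
apply_fit <- function(profile, fit, variant = c("consistent", "printed")) {
  variant <- match.arg(variant)
  best <- if (inherits(fit, "acn_fit")) fit$best else fit
  r <- if (inherits(fit, "acn_fit")) fit$r else {
    len <- seg_len(profile)
    sum(profile$value * len) / sum(len)
  }
  seg <- as.data.frame(profile)
  seg$value <- pmax(0, relative_to_absolute(seg$value, best$purity,
                                            best$ploidy, r, variant))
  cn_profile(seg, profile_genome(profile), "absolute")
}
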