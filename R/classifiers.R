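#' Resistance calls
#'
#' A therapy-specific resistant/sensitive decision with a
#' machine-readable rationale recording which rule fired.
#'
#' @param therapy `"platinum"`, `"taxane"` or `"anthracycline"`.
#' @param call `"resistant"` or `"sensitive"`.
#' @param rationale short rule trace, e.g. `"no_CIN"` or `"CX2>CX3"`.
#' @param inputs named list of the values the rule saw.
#' @return A list of class `resistance_call`.
#' @export
resistance_call <- function(therapy, call, rationale, inputs = list()) {
  stopifnot(therapy %in% c("platinum", "taxane", "anthracycline"),
            call %in% c("resistant", "sensitive"),
            nzchar(rationale))
  structure(list(therapy = therapy, call = call, rationale = rationale,
                 inputs = inputs), class = "resistance_call")
}

#' @export
print.resistance_call <- function(x, ...) {
  cat(sprintf("%s: %s (%s)\n", x$therapy, x$call, x$rationale))
  invisible(x)
}

#' Detect chromosomal instability
#'
#' Two rules are available. `any_thresholded_signature` (the default)
#' declares CIN when any thresholded signature activity is positive.
#' `min_segments` declares CIN when the post-smoothing segment count of
#' the profile reaches `n` (default 20), a purely structural criterion
#' independent of the signature model.
#'
#' @param x a thresholded [activity_vector()] (activity rule) or a
#'   [cn_profile()] (segment rule).
#' @param rule `"any_thresholded_signature"` or `"min_segments"`.
#' @param n minimum segment count for the `min_segments` rule.
#' @return `TRUE` if CIN is detected.
#' @export
detect_cin <- function(x, rule = c("any_thresholded_signature",
                                   "min_segments"), n = 20) {
  rule <- match.arg(rule)
  if (rule == "any_thresholded_signature") {
    if (!inherits(x, "activity_vector"))
      stop("activity rule needs an activity_vector")
    any(unclass(x) > 0)
  } else {
    if (!inherits(x, "cn_profile"))
      stop("min_segments rule needs a cn_profile")
    nrow(x) >= n
  }
}

#' Platinum resistance classifier
#'
#' Tumors without detectable CIN are classified resistant. Among CIN
#' tumors, resistance is called when the scaled activity of CX2 exceeds
#' that of CX3 (both signatures reflect impaired homologous
#' recombination, but only the CX3 form confers platinum sensitivity).
#' Activities must be z-scored with the BRCA1/2-mutant reference
#' scaling. Ties (CX2 equal to CX3) resolve to sensitive: the rule is a
#' strict inequality.
#'
#' @param scaled a scaled [activity_vector()] (BRCA-mutant scaling).
#' @param cin logical from [detect_cin()].
#' @return A [resistance_call()].
#' @export
classify_platinum <- function(scaled, cin) {
  if (!cin)
    return(resistance_call("platinum", "resistant", "no_CIN"))
  need <- c("CX2", "CX3")
  if (!all(need %in% names(scaled)))
    stop("scaled activities must include CX2 and CX3")
  cx2 <- unclass(scaled)[["CX2"]]
  cx3 <- unclass(scaled)[["CX3"]]
  if (cx2 > cx3) {
    resistance_call("platinum", "resistant", "CX2>CX3",
                    list(CX2 = cx2, CX3 = cx3))
  } else {
    resistance_call("platinum", "sensitive", "CX2<=CX3",
                    list(CX2 = cx2, CX3 = cx3))
  }
}

#' Taxane resistance classifier
#'
#' Tumors without detectable CIN are classified resistant. Among CIN
#' tumors, resistance is called when the pan-cohort z-scored CX5
#' activity is strictly below 0; a value of exactly 0 is sensitive.
#'
#' @param scaled a scaled [activity_vector()] (pan-cohort scaling).
#' @param cin logical from [detect_cin()].
#' @return A [resistance_call()].
#' @export
classify_taxane <- function(scaled, cin) {
  if (!cin)
    return(resistance_call("taxane", "resistant", "no_CIN"))
  if (!"CX5" %in% names(scaled))
    stop("scaled activities must include CX5")
  cx5 <- unclass(scaled)[["CX5"]]
  if (cx5 < 0) {
    resistance_call("taxane", "resistant", "CX5<0", list(CX5 = cx5))
  } else {
    resistance_call("taxane", "sensitive", "CX5>=0", list(CX5 = cx5))
  }
}

#' Anthracycline resistance classifier
#'
#' Resistance is called when any of the three focal-amplification
#' signatures exceeds its threshold: CX8 > 0.01, CX9 > 0.009 or
#' CX13 > 0.009 on raw activities (strict inequalities: an activity
#' exactly at the threshold is sensitive). There is no CIN gate: a
#' sample with all-zero activities is sensitive.
#'
#' @param raw a raw (or thresholded) [activity_vector()].
#' @param thresholds named thresholds for CX8, CX9, CX13.
#' @return A [resistance_call()].
#' @export
classify_anthracycline <- function(raw,
                                   thresholds = c(CX8 = 0.01, CX9 = 0.009,
                                                  CX13 = 0.009)) {
  sigs <- names(thresholds)
  if (!all(sigs %in% names(raw)))
    stop("activities must include ", paste(sigs, collapse = ", "))
  vals <- unclass(raw)[sigs]
  over <- vals > thresholds
  if (any(over)) {
    fired <- sigs[over]
    resistance_call("anthracycline", "resistant",
                    paste(sprintf("%s>%g", fired, thresholds[fired]),
                          collapse = "|"),
                    as.list(vals))
  } else {
    resistance_call("anthracycline", "sensitive", "no_amplification_signature",
                    as.list(vals))
  }
}

#' Classify a sample for all three therapies
#'
#' @param raw raw [activity_vector()].
#' @param scaled_brca activities scaled with the BRCA-mutant model.
#' @param scaled_pan activities scaled with the pan-cohort model.
#' @param cin logical CIN flag.
#' @return Named list of [resistance_call()]s.
#' @export
classify_all <- function(raw, scaled_brca, scaled_pan, cin) {
  list(platinum = classify_platinum(scaled_brca, cin),
       taxane = classify_taxane(scaled_pan, cin),
       anthracycline = classify_anthracycline(raw))
}

#' Calibrate an activity threshold against drug-response AUC
#'
#' Mirrors the cell-line calibration of the taxane biomarker: samples
#' with activity strictly below a candidate threshold are predicted
#' resistant, and the mean dose-response AUC (higher AUC = more
#' resistant) of that predicted-resistant set is the objective. Candidate
#' thresholds are the observed activity values; only candidates whose
#' predicted-resistant fraction lies within `rate_bounds` (the expected
#' clinical resistance rate) are admissible. The admissible threshold
#' maximising the mean AUC is returned, ties resolving to the smaller
#' threshold.
#'
#' @param activities per-sample signature activity.
#' @param response per-sample AUC on a common scale.
#' @param rate_bounds admissible predicted-resistant fraction (inclusive).
#' @return A list with `threshold`, `mean_auc`, `resistant_fraction`.
#' @export
calibrate_threshold_response <- function(activities, response,
                                         rate_bounds = c(0.30, 0.60)) {
  if (length(activities) < 10) stop("need at least 10 samples")
  if (length(activities) != length(response))
    stop("activities and response must align")
  cand <- sort(unique(activities))
  frac <- vapply(cand, function(t) mean(activities < t), numeric(1))
  ok <- frac >= rate_bounds[1] & frac <= rate_bounds[2]
  if (!any(ok))
    stop(sprintf(paste0("no threshold reaches a resistant fraction in ",
                        "[%.2f, %.2f]; achievable range is [%.2f, %.2f]"),
                 rate_bounds[1], rate_bounds[2], min(frac), max(frac)))
  mean_auc <- vapply(cand, function(t) {
    sel <- activities < t
    if (!any(sel)) -Inf else mean(response[sel])
  }, numeric(1))
  mean_auc[!ok] <- -Inf
  best <- which(mean_auc == max(mean_auc))[1]  # ties: smaller threshold
  list(threshold = cand[best], mean_auc = mean_auc[best],
       resistant_fraction = frac[best])
}

#' Calibrate per-signature thresholds against IC50 ranks
#'
#' Mirrors the organoid/spheroid calibration of the anthracycline
#' biomarker: the `n_expected_resistant` samples with the highest IC50
#' are labelled resistant, and for each candidate signature a threshold
#' is grid-scanned over the observed activities to maximise the accuracy
#' of the rule "activity strictly above threshold implies resistant".
#' Ties resolve to the threshold with higher specificity, then to the
#' larger threshold (the most conservative caller).
#'
#' @param activities numeric matrix, samples x candidate signatures.
#' @param ic50 per-sample IC50 (higher = more resistant).
#' @param n_expected_resistant number of samples to label resistant.
#' @return Named list per signature with `threshold` and `accuracy`.
#' @export
calibrate_threshold_rank <- function(activities, ic50, n_expected_resistant) {
  if (nrow(activities) != length(ic50))
    stop("activities and ic50 must align")
  n <- length(ic50)
  if (n_expected_resistant < 0 || n_expected_resistant > n)
    stop("n_expected_resistant out of range")
  labels <- rank(-ic50, ties.method = "first") <= n_expected_resistant
  out <- lapply(colnames(activities), function(sig) {
    a <- activities[, sig]
    cand <- sort(unique(a))
    stats <- vapply(cand, function(t) {
      pred <- a > t
      acc <- mean(pred == labels)
      spec <- if (any(!labels)) mean(!pred[!labels]) else 1
      c(acc, spec)
    }, numeric(2))
    ord <- order(-stats[1, ], -stats[2, ], -cand)
    best <- ord[1]
    list(threshold = cand[best], accuracy = stats[1, best])
  })
  stats::setNames(out, colnames(activities))
}
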