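#' Guideline values and index weights
#'
#' Bundles the per-metal grade-III groundwater guideline concentrations
#' (used as `Si` in the WQI and as the maximum allowable concentration
#' `Hmac` in the PEI) with the integer significance weights `wi` of the
#' WQI. Defaults ship with the package and are fully overridable.
#'
#' @param guideline_ug_L named numeric vector of guideline values, ug/L.
#' @param weights named positive numeric vector of WQI weights.
#' @return object of class `index_standards`.
#' @export
index_standards <- function(guideline_ug_L = default_guidelines(),
                            weights = default_weights()) {
  guideline_ug_L <- unlist(guideline_ug_L)
  weights <- unlist(weights)
  if (any(guideline_ug_L <= 0)) stop("guideline values must be > 0")
  if (any(weights <= 0)) stop("weights must be > 0")
  structure(list(guideline_ug_L = guideline_ug_L, weights = weights),
            class = "index_standards")
}

#' Default grade-III guideline concentrations (ug/L)
#'
#' Cr 50, Mn 100, Fe 300, Cu 1000, Zn 1000, Cd 5, Pb 100 -- the grade-III
#' limits of the Chinese groundwater quality standard (GB/T 14848-2017) as
#' commonly tabulated for these seven metals.
#'
#' @return named numeric vector.
#' @export
default_guidelines <- function() {
  c(Cr = 50, Mn = 100, Fe = 300, Cu = 1000, Zn = 1000, Cd = 5, Pb = 100)
}

#' Default WQI weights
#'
#' Integer significance scores by the usual health-significance convention
#' (most toxic metals weighted 5, essential/low-toxicity metals lower).
#' Override via [index_standards()] when study-specific weights exist.
#'
#' @return named numeric vector.
#' @export
default_weights <- function() {
  c(Cr = 5, Mn = 4, Fe = 1, Cu = 2, Zn = 2, Cd = 5, Pb = 5)
}

#' Relative weights Wi = wi / sum(wi)
#'
#' @param weights positive numeric vector of raw weights.
#' @return numeric vector summing to 1.
#' @export
relative_weights <- function(weights) {
  weights <- unlist(weights)
  if (!length(weights)) stop("empty weight set")
  if (any(weights <= 0)) stop("weights must be > 0")
  weights / sum(weights)
}

classify_wqi <- function(x) {
  # < 50 excellent; [50, 100) good; [100, 200) poor; [200, 300] very poor;
  # > 300 unfit -- the closed upper edge at 300 follows the stated bands
  ifelse(x < 50, "excellent",
         ifelse(x < 100, "good",
                ifelse(x < 200, "poor",
                       ifelse(x <= 300, "very poor", "unfit for drinking"))))
}

classify_pei <- function(x) {
  # low (< 40), medium (40 <= PEI <= 80), high (> 80): closed upper bound
  ifelse(x < 40, "low", ifelse(x <= 80, "medium", "high"))
}

check_standards_cover <- function(table, standards) {
  missing_g <- setdiff(table$metals, names(standards$guideline_ug_L))
  if (length(missing_g)) {
    stop(sprintf("no guideline value for metal '%s'", missing_g[1]))
  }
  missing_w <- setdiff(table$metals, names(standards$weights))
  if (length(missing_w)) {
    stop(sprintf("no weight for metal '%s'", missing_w[1]))
  }
}

#' Water quality index
#'
#' For each site, WQI = sum_i Wi * qi with Wi the relative weight and
#' qi = 100 * Ci / Si the concentration-to-guideline rating. Both Ci and Si
#' are in ug/L, so the ratio is unit-invariant. Sites are banded:
#' excellent (< 50), good (50-100), poor (100-200), very poor (200-300),
#' unfit for drinking (> 300); edges are half-open so the five classes
#' partition the line.
#'
#' @param table a [concentration_table()].
#' @param standards an [index_standards()].
#' @return object of class `wqi_result`: per-site data.frame (`site_id`,
#'   `wqi`, `class`), sub-index matrix, relative weights, and per-metal
#'   percent contributions to the mean WQI.
#' @export
wqi <- function(table, standards = index_standards()) {
  stopifnot(inherits(table, "conc_table"))
  check_standards_cover(table, standards)
  si <- standards$guideline_ug_L[table$metals]
  wrel <- relative_weights(standards$weights[table$metals])
  q <- sweep(table$values, 2, si, "/") * 100
  sub <- sweep(q, 2, wrel, "*")
  total <- rowSums(sub)
  res <- structure(list(
    per_site = data.frame(site_id = table$site_ids, wqi = total,
                          class = classify_wqi(total), row.names = NULL),
    sub_index = sub,
    relative_weights = wrel,
    metals = table$metals), class = c("wqi_result", "index_result"))
  res$metal_contribution <- index_contributions(res)
  res
}

#' Pollution evaluation index
#'
#' PEI (also written HEI) = sum_i Hc_i / Hmac_i, the unweighted sum of
#' concentration-to-guideline ratios. Banding: low (< 40), medium
#' (40 <= PEI <= 80), high (> 80).
#'
#' @inheritParams wqi
#' @return object of class `pei_result`, same layout as [wqi()].
#' @export
pei <- function(table, standards = index_standards()) {
  stopifnot(inherits(table, "conc_table"))
  missing_g <- setdiff(table$metals, names(standards$guideline_ug_L))
  if (length(missing_g)) {
    stop(sprintf("no guideline value for metal '%s'", missing_g[1]))
  }
  hmac <- standards$guideline_ug_L[table$metals]
  sub <- sweep(table$values, 2, hmac, "/")
  total <- rowSums(sub)
  res <- structure(list(
    per_site = data.frame(site_id = table$site_ids, pei = total,
                          class = classify_pei(total), row.names = NULL),
    sub_index = sub,
    metals = table$metals), class = c("pei_result", "index_result"))
  res$metal_contribution <- index_contributions(res)
  res
}

#' Per-metal percent contribution to a mean index
#'
#' Metal m's contribution is the mean over sites of its sub-term divided by
#' the mean index, times 100; contributions sum to 100. Undefined (all NA)
#' when the mean index is zero.
#'
#' @param result a `wqi_result` or `pei_result`.
#' @return named numeric vector of percentages.
#' @export
index_contributions <- function(result) {
  stopifnot(inherits(result, "index_result"))
  sub_means <- colMeans(result$sub_index)
  denom <- sum(sub_means)
  if (denom == 0) {
    return(setNames(rep(undefined_marker(), length(sub_means)),
                    names(sub_means)))
  }
  sub_means / denom * 100
}
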