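# Deterministic calculators for assay scoring rubrics.

#' Immunohistochemistry composite score
#'
#' Final score = staining intensity (0-3) x proportion of positive tumor
#' cells (0-4); scores 0-3 are called low expression, 4-12 high.
#'
#' @param intensity integer 0-3 (none / weak / moderate / strong staining).
#' @param proportion integer 0-4 (see [proportion_bin()]).
#' @return a data.frame with `intensity`, `proportion`, `final` and `level`
#'   (factor `low`/`high`). Vectorized.
#' @export
ihc_score <- function(intensity, proportion) {
  if (any(!intensity %in% 0:3)) stopf("intensity must be in 0:3")
  if (any(!proportion %in% 0:4)) stopf("proportion must be in 0:4")
  final <- as.integer(intensity) * as.integer(proportion)
  data.frame(intensity = as.integer(intensity),
             proportion = as.integer(proportion),
             final = final,
             level = factor(ifelse(final <= 3, "low", "high"),
                            levels = c("low", "high")))
}

#' Bin percent positive cells into the IHC proportion score
#'
#' 0 = negative, 1 = 10% or less, 2 = 11-50%, 3 = 51-80%, 4 = 80% or more.
#' The published bins overlap at exactly 80%; the higher bin wins there
#' ("80% or more" being the more specific clause).
#'
#' @param percent_positive percentage in \[0, 100\]. Vectorized.
#' @return integer score 0-4.
#' @export
proportion_bin <- function(percent_positive) {
  if (any(percent_positive < 0 | percent_positive > 100))
    stopf("percent_positive must lie in [0, 100]")
  ifelse(percent_positive == 0, 0L,
  ifelse(percent_positive >= 80, 4L,
  ifelse(percent_positive > 50, 3L,
  ifelse(percent_positive > 10, 2L, 1L))))
}

#' Xenograft tumor volume
#'
#' Ellipsoid approximation from caliper measurements: `(L x W^2) / 2`.
#'
#' @param L,W length and width (mm); `L >= W` expected (warned otherwise,
#'   still computed). Vectorized.
#' @return volume in mm^3.
#' @export
tumor_volume <- function(L, W) {
  if (any(L < 0 | W < 0)) stopf("L and W must be >= 0")
  if (any(W > L)) warnf("W > L for %d measurement(s); check orientation",
                        sum(W > L))
  L * W^2 / 2
}

#' Percent wound closure
#'
#' `100 * (1 - area_t / area_t0)`: the percentage decrease of the wound gap
#' between time 0 and time t.
#'
#' @param area_t0 initial wound area (> 0).
#' @param area_t wound area at time t; values above `area_t0` are clipped
#'   to it with a warning. Vectorized.
#' @return percent closed in \[0, 100\].
#' @export
wound_closure <- function(area_t0, area_t) {
  if (any(area_t0 <= 0)) stopf("area_t0 must be > 0")
  if (any(area_t < 0)) stopf("area_t must be >= 0")
  over <- area_t > area_t0
  if (any(over)) {
    warnf("area_t exceeds area_t0 for %d measurement(s); clipped (0%% closure)",
          sum(over))
    area_t <- pmin(area_t, area_t0)
  }
  100 * (1 - area_t / area_t0)
}
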