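#' Coefficients of the logistic species distribution model
#'
#' The fixed model applied throughout the pipeline, on the logit scale:
#' \deqn{logit(p) = \beta_0 + \beta_d \cdot deciduous + \beta_w \cdot
#'   wetland + \beta_f \cdot footprint + \beta_{wsi} \cdot WSI +
#'   \beta_{gs} \cdot GS}
#' The defaults are the published white-tailed deer model values:
#' intercept -10.12, deciduous 4.98, wetland -3.11, footprint 9.79,
#' winter severity -0.07 per index point, growing season 0.11 per day.
#' The model is configuration here; refitting from data lives in
#' [fit_sdm()] for parameter-recovery checks.
#'
#' @param intercept,deciduous,wetland,footprint,wsi,gs coefficients on
#'   the logit scale.
#' @return Named numeric vector of class `sdm_coefficients`.
#' @export
sdm_coefficients <- function(intercept = -10.12, deciduous = 4.98,
                             wetland = -3.11, footprint = 9.79,
                             wsi = -0.07, gs = 0.11) {
  out <- c(intercept = intercept, deciduous = deciduous, wetland = wetland,
           footprint = footprint, wsi = wsi, gs = gs)
  if (!all(is.finite(out))) stopf("sdm_coefficients: all must be finite")
  class(out) <- "sdm_coefficients"
  out
}

#' Predicted probability of presence on a landscape
#'
#' Evaluates the linear predictor of the logistic model on each cell of a
#' decadal landscape and converts it with the inverse logit
#' `p = exp(lp) / (1 + exp(lp))`. Deterministic; probabilities are
#' strictly inside (0, 1) for finite covariates.
#'
#' @param landscape a `decadal_landscape` from [assemble_landscape()] (any
#'   data frame with the five covariate columns works).
#' @param coef an [sdm_coefficients()] vector.
#' @return A `prediction_grid` data frame `cell_id`, `p`, carrying the
#'   landscape's decade label as attribute `"decade"`.
#' @export
predict_probability <- function(landscape, coef = sdm_coefficients()) {
  check_columns(landscape,
                c("cell_id", "prop_deciduous", "prop_wetland",
                  "prop_footprint", "wsi_mean", "gs_mean"), "landscape")
  x <- as.matrix(landscape[, c("prop_deciduous", "prop_wetland",
                               "prop_footprint", "wsi_mean", "gs_mean")])
  bad <- which(!is.finite(x), arr.ind = TRUE)
  if (nrow(bad))
    stopf("predict_probability: non-finite covariate(s) in cell(s): %s",
          paste(unique(landscape$cell_id[bad[, 1]]), collapse = ", "))
  lp <- coef[["intercept"]] +
    x %*% c(coef[["deciduous"]], coef[["wetland"]], coef[["footprint"]],
            coef[["wsi"]], coef[["gs"]])
  out <- data.frame(cell_id = landscape$cell_id, p = plogis(as.vector(lp)))
  attr(out, "decade") <- attr(landscape, "decade")
  class(out) <- c("prediction_grid", class(out))
  out
}

#' Convert probabilities to presence at a threshold
#'
#' Presence is called where `p >= threshold` (inclusive, matching the
#' convention that probability exactly at the prevalence threshold is a
#' presence).
#'
#' @param grid a `prediction_grid` (or any data frame with `cell_id`, `p`).
#' @param threshold probability threshold in (0, 1); the training-data
#'   prevalence (0.73 in the reference analysis) is the recommended
#'   choice.
#' @return Data frame `cell_id`, `presence` (logical).
#' @export
classify_presence <- function(grid, threshold) {
  check_columns(grid, c("cell_id", "p"), "grid")
  check_number(threshold, "threshold", lower = 0, upper = 1)
  out <- data.frame(cell_id = grid$cell_id, presence = grid$p >= threshold)
  attr(out, "decade") <- attr(grid, "decade")
  attr(out, "threshold") <- threshold
  out
}

#' Prevalence of presences in an observation set
#'
#' Number of presences divided by the number of observations, at full
#' precision (rounding is for display only). Used as the
#' probability-to-presence threshold.
#'
#' @param observations logical/0-1 vector, or a data frame with a
#'   `presence` column.
#' @return Proportion in `[0, 1]`.
#' @examples
#' prevalence(c(rep(1, 218), rep(0, 81))) # 218/299 = 0.729...
#' @export
prevalence <- function(observations) {
  if (is.data.frame(observations)) {
    check_columns(observations, "presence", "observations")
    observations <- observations$presence
  }
  if (!length(observations)) stopf("prevalence: empty observation set")
  obs <- as.logical(observations)
  if (anyNA(obs)) stopf("prevalence: observations must be TRUE/FALSE or 0/1")
  mean(obs)
}
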