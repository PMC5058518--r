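#' Confusion counts at a probability threshold
#'
#' Records with predicted probability at or above `threshold` are called
#' presences (inclusive, the same convention as [classify_presence()]).
#'
#' @param observed logical/0-1 vector of observed presence.
#' @param prob predicted probabilities in `[0, 1]`.
#' @param threshold probability threshold.
#' @return Named integer vector `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(observed, prob, threshold) {
  obs <- as.logical(observed)
  if (!length(obs)) stopf("confusion_counts: empty observation set")
  if (length(obs) != length(prob))
    stopf("confusion_counts: `observed` and `prob` lengths differ")
  if (anyNA(obs) || anyNA(prob)) stopf("confusion_counts: NA input")
  pred <- prob >= threshold
  c(tp = sum(pred & obs), fp = sum(pred & !obs),
    tn = sum(!pred & !obs), fn = sum(!pred & obs))
}

#' True skill statistic
#'
#' `TSS = sensitivity + specificity - 1`, in `[-1, 1]`; 0 is no better
#' than chance and values above 0.5 are conventionally read as high
#' predictive power.
#'
#' @param sensitivity,specificity rates in `[0, 1]`.
#' @return The statistic.
#' @examples
#' tss(0.79, 0.84) # 0.63
#' @export
tss <- function(sensitivity, specificity) {
  check_prob(sensitivity, "sensitivity")
  check_prob(specificity, "specificity")
  sensitivity + specificity - 1
}

#' Area under the ROC curve (rank formulation)
#'
#' The probability that a randomly selected presence receives a higher
#' predicted probability than a randomly selected absence, with ties
#' counting one half --- computed from the rank-sum (Mann--Whitney)
#' identity, which equals brute-force counting over all
#' presence-by-absence pairs.
#'
#' @param observed logical/0-1 vector; must contain both classes.
#' @param prob predicted probabilities (any scores work: AUC is invariant
#'   under strictly monotone transforms).
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(observed, prob) {
  obs <- as.logical(observed)
  if (anyNA(obs) || anyNA(prob)) stopf("auc: NA input")
  n1 <- sum(obs); n0 <- sum(!obs)
  if (n1 == 0L || n0 == 0L)
    stopf("auc: need at least one presence and one absence")
  r <- rank(prob, ties.method = "average")
  (sum(r[obs]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Calibration regression of observations on predicted probabilities
#'
#' Fits a binomial GLM (logit link) of observed presence/absence on the
#' predicted probability --- the raw probability, exactly as the
#' validation protocol states; set `regressor = "logit"` for the common
#' alternative of regressing on the logit of the prediction. Perfect
#' calibration corresponds to the fitted curve lying on the identity;
#' with the raw-probability regressor even a perfectly calibrated model
#' has slope near 5 (the local slope of the logit on mid-range
#' probabilities) rather than 1.
#'
#' @param observed logical/0-1 vector; both classes must be present.
#' @param prob predicted probabilities.
#' @param regressor `"probability"` (default) or `"logit"`.
#' @return List of class `calibration_fit` with `intercept`, `slope`,
#'   `fitted` (function mapping probability to fitted occupancy),
#'   `separation` (logical; coefficients unbounded), `degenerate`
#'   (logical; constant regressor, slope reported as 0), `converged`,
#'   and the underlying `glm` object as `model`.
#' @export
calibration_fit <- function(observed, prob,
                            regressor = c("probability", "logit")) {
  regressor <- match.arg(regressor)
  obs <- as.logical(observed)
  if (anyNA(obs) || anyNA(prob)) stopf("calibration_fit: NA input")
  if (length(unique(obs)) < 2L)
    stopf("calibration_fit: need both presences and absences")
  x <- if (regressor == "logit") qlogis(pmin(pmax(prob, 1e-12),
                                             1 - 1e-12)) else prob

  if (isTRUE(all.equal(max(x), min(x)))) {
    # uninformative constant predictions: slope 0 by convention, flagged
    fit0 <- glm(obs ~ 1, family = binomial())
    out <- list(intercept = unname(coef(fit0)[1]), slope = 0,
                separation = FALSE, degenerate = TRUE,
                converged = fit0$converged, regressor = regressor,
                model = fit0)
  } else {
    separation <- FALSE
    fit <- withCallingHandlers(
      glm(obs ~ x, family = binomial(),
          control = list(epsilon = 1e-10, maxit = 100)),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
          separation <<- TRUE
        invokeRestart("muffleWarning")
      })
    if (max(abs(coef(fit))) > 1e3) separation <- TRUE
    out <- list(intercept = unname(coef(fit)[1]),
                slope = unname(coef(fit)[2]),
                separation = separation, degenerate = FALSE,
                converged = fit$converged, regressor = regressor,
                model = fit)
  }
  trans <- if (regressor == "logit") {
    function(p) qlogis(pmin(pmax(p, 1e-12), 1 - 1e-12))
  } else identity
  out$fitted <- function(p) plogis(out$intercept + out$slope * trans(p))
  class(out) <- "calibration_fit"
  out
}

#' Bootstrap standard deviations of sensitivity and specificity
#'
#' Nonparametric bootstrap over the validation records: records are
#' resampled with replacement, the two rates recomputed at `threshold`,
#' and their standard deviations across replicates reported. Replicates
#' where a rate's denominator is empty are dropped for that rate; sets
#' with a single observed class yield `NA` for the undefined rate and a
#' flag.
#'
#' @inheritParams confusion_counts
#' @param reps number of bootstrap replicates (>= 100; 1000 matches
#'   standard practice).
#' @param seed integer seed for reproducibility.
#' @return List `sens_sd`, `spec_sd`, `degenerate` (TRUE when a rate was
#'   undefined in the original data).
#' @export
resample_rate_sd <- function(observed, prob, threshold, reps = 1000L,
                             seed = 1L) {
  reps <- check_count(reps, "reps", lower = 100L)
  obs <- as.logical(observed)
  n <- length(obs)
  if (n == 0L) stopf("resample_rate_sd: empty observation set")
  pred <- prob >= threshold
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  sens <- spec <- rep(NA_real_, reps)
  for (r in seq_len(reps)) {
    i <- sample.int(n, n, replace = TRUE)
    o <- obs[i]; pr <- pred[i]
    if (any(o)) sens[r] <- sum(pr & o) / sum(o)
    if (any(!o)) spec[r] <- sum(!pr & !o) / sum(!o)
  }
  list(sens_sd = if (any(obs)) sd(sens, na.rm = TRUE) else NA_real_,
       spec_sd = if (any(!obs)) sd(spec, na.rm = TRUE) else NA_real_,
       degenerate = !any(obs) || !any(!obs))
}

# preserve caller RNG state around seeded internals
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Accuracy statistics table for one validation set
#'
#' One row of the standard accuracy table: sample size, number of
#' presences, prevalence, AUC, TSS, sensitivity and specificity with
#' bootstrap standard deviations.
#'
#' @inheritParams resample_rate_sd
#' @param label optional data-set label for the row.
#' @return One-row data frame with columns `data_set`, `n`, `n_presence`,
#'   `prevalence`, `auc`, `tss`, `sensitivity`, `sens_sd`,
#'   `specificity`, `spec_sd`.
#' @export
validation_stats <- function(observed, prob, threshold, reps = 1000L,
                             seed = 1L, label = "validation") {
  cc <- confusion_counts(observed, prob, threshold)
  sens <- if (cc["tp"] + cc["fn"] > 0)
    unname(cc["tp"] / (cc["tp"] + cc["fn"])) else NA_real_
  spec <- if (cc["tn"] + cc["fp"] > 0)
    unname(cc["tn"] / (cc["tn"] + cc["fp"])) else NA_real_
  obs <- as.logical(observed)
  a <- if (any(obs) && any(!obs)) auc(obs, prob) else NA_real_
  sds <- resample_rate_sd(obs, prob, threshold, reps, seed)
  data.frame(data_set = label, n = length(obs), n_presence = sum(obs),
             prevalence = prevalence(obs), auc = a,
             tss = if (is.na(sens) || is.na(spec)) NA_real_
                   else tss(sens, spec),
             sensitivity = sens, sens_sd = sds$sens_sd,
             specificity = spec, spec_sd = sds$spec_sd)
}

#' Refit the species distribution model from observations
#'
#' Maximum-likelihood logistic regression of presence/absence on the
#' five landscape covariates --- used for parameter-recovery checks on
#' synthetic data and for calibration experiments, not to replace the
#' fixed published coefficients.
#'
#' @param data data frame with columns `presence`, `prop_deciduous`,
#'   `prop_wetland`, `prop_footprint`, `wsi_mean`, `gs_mean`.
#' @return List of class `sdm_fit` with `coefficients` (an
#'   [sdm_coefficients()]), `se` (standard errors in the same order),
#'   `separation`, `converged` and the `glm` object as `model`.
#' @export
fit_sdm <- function(data) {
  check_columns(data, c("presence", "prop_deciduous", "prop_wetland",
                        "prop_footprint", "wsi_mean", "gs_mean"), "data")
  obs <- as.logical(data$presence)
  if (length(unique(obs)) < 2L)
    stopf("fit_sdm: need both presences and absences")
  X <- cbind(1, data$prop_deciduous, data$prop_wetland,
             data$prop_footprint, data$wsi_mean, data$gs_mean)
  if (qr(X)$rank < ncol(X))
    stopf("fit_sdm: design matrix is rank deficient")
  separation <- FALSE
  fit <- withCallingHandlers(
    glm(obs ~ prop_deciduous + prop_wetland + prop_footprint + wsi_mean +
          gs_mean, family = binomial(), data = data,
        control = list(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w)))
        separation <<- TRUE
      invokeRestart("muffleWarning")
    })
  b <- coef(fit)
  out <- list(
    coefficients = sdm_coefficients(b[1], b[2], b[3], b[4], b[5], b[6]),
    se = sqrt(diag(vcov(fit))),
    separation = separation, converged = fit$converged, model = fit)
  class(out) <- "sdm_fit"
  out
}

#' Sticky township aggregation of survey observations
#'
#' Survey records are summarized per township such that a township is
#' scored a presence from its first recorded presence onward: absences
#' recorded after a presence are treated as false absences and the
#' township remains a presence. Intended as preprocessing for validation
#' observation tables collected over multiple survey years.
#'
#' @param obs data frame with columns `township_id`, `year`, `presence`.
#' @return Data frame `township_id`, `year`, `presence` with the sticky
#'   rule applied, one row per surveyed township-year.
#' @export
aggregate_townships <- function(obs) {
  check_columns(obs, c("township_id", "year", "presence"), "obs")
  obs <- obs[order(obs$township_id, obs$year), ]
  # any presence within a township-year, then sticky across years
  key <- paste(obs$township_id, obs$year, sep = "\r")
  agg <- rowsum(as.numeric(obs$presence), key) > 0
  parts <- do.call(rbind, strsplit(rownames(agg), "\r", fixed = TRUE))
  out <- data.frame(township_id = type.convert(parts[, 1], as.is = TRUE),
                    year = as.integer(parts[, 2]),
                    presence = as.vector(agg))
  out <- out[order(out$township_id, out$year), ]
  out$presence <- as.logical(
    unlist(tapply(out$presence, out$township_id, cummax), use.names = FALSE))
  rownames(out) <- NULL
  out
}
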