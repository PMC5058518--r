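test_that("confusion counts partition records at an inclusive threshold", {
  obs <- c(TRUE, TRUE, FALSE, FALSE)
  prob <- c(0.9, 0.2, 0.8, 0.1)
  expect_equal(confusion_counts(obs, prob, 0.5),
               c(tp = 1L, fp = 1L, tn = 1L, fn = 1L))
  # perfect predictions
  expect_equal(confusion_counts(obs, c(0.9, 0.8, 0.1, 0.2), 0.5)[c("fp", "fn")],
               c(fp = 0L, fn = 0L))
  # threshold zero: everything called present
  cc0 <- confusion_counts(obs, prob, 0)
  expect_equal(unname(cc0["tn"]), 0L)
  expect_equal(unname(cc0["fp"]), 2L)

  # 10-record fixture against exhaustive enumeration
  set.seed(14)
  o <- runif(10) < 0.5
  p <- runif(10)
  cc <- confusion_counts(o, p, 0.4)
  pred <- p >= 0.4
  expect_equal(cc, c(tp = sum(pred & o), fp = sum(pred & !o),
                     tn = sum(!pred & !o), fn = sum(!pred & o)))
  expect_equal(sum(cc), 10L)
})

test_that("TSS is sensitivity plus specificity minus one", {
  expect_equal(tss(0.79, 0.84), 0.63, tolerance = 1e-12)
  expect_equal(tss(0.96, 0.62), 0.58, tolerance = 1e-12)
  expect_equal(tss(1, 1), 1)
  expect_equal(tss(0.5, 0.5), 0)
  expect_error(tss(1.2, 0.5), "must be in")
})

test_that("rank AUC equals pair counting and is invariant to monotone maps", {
  # perfectly separated
  expect_equal(auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1)
  # all ties
  expect_equal(auc(c(1, 1, 0, 0), rep(0.4, 4)), 0.5)
  # 6-record fixture vs brute force
  o <- c(1, 0, 1, 0, 1, 0)
  p <- c(0.9, 0.9, 0.5, 0.3, 0.2, 0.2)
  expect_equal(auc(o, p), auc_bruteforce(o, p), tolerance = 1e-15)
  # monotone transform invariance
  set.seed(15)
  o2 <- runif(60) < 0.4
  p2 <- runif(60)
  expect_equal(auc(o2, p2), auc(o2, qlogis(p2)), tolerance = 1e-12)
  expect_equal(auc(o2, p2), auc(o2, p2^3), tolerance = 1e-12)
  # independent reference implementation
  expect_equal(auc(o2, p2),
               as.numeric(pROC::auc(pROC::roc(o2, p2, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
  expect_error(auc(rep(TRUE, 4), runif(4)), "at least one")
})

test_that("calibration fit matches an independent Newton optimizer", {
  set.seed(16)
  p <- c(0.05, 0.2, 0.35, 0.5, 0.6, 0.75, 0.85, 0.95)
  y <- c(0, 0, 1, 0, 1, 1, 0, 1)
  fit <- calibration_fit(y, p)
  oracle <- logistic_newton(y, p)
  expect_equal(fit$intercept, oracle[1], tolerance = 1e-6)
  expect_equal(fit$slope, oracle[2], tolerance = 1e-6)
  expect_false(fit$separation)
  expect_false(fit$degenerate)
  # fitted() maps probability through the estimated curve
  expect_equal(fit$fitted(0.5), plogis(oracle[1] + oracle[2] * 0.5),
               tolerance = 1e-6)
})

test_that("degenerate and separated calibration inputs are flagged", {
  y <- c(0, 1, 0, 1, 1)
  flat <- calibration_fit(y, rep(0.4, 5))
  expect_true(flat$degenerate)
  expect_equal(flat$slope, 0)

  sep <- calibration_fit(c(0, 0, 0, 1, 1, 1),
                         c(0.1, 0.2, 0.3, 0.7, 0.8, 0.9))
  expect_true(sep$separation)
  expect_error(calibration_fit(rep(1, 5), runif(5)), "both")
})

test_that("logit-regressor calibration recovers identity on consistent data", {
  set.seed(17)
  p <- runif(4000, 0.05, 0.95)
  y <- rbinom(4000, 1, p)
  fit <- calibration_fit(y, p, regressor = "logit")
  expect_equal(fit$slope, 1, tolerance = 0.12)
  expect_equal(fit$intercept, 0, tolerance = 0.15)
})

test_that("bootstrap rate SDs are seeded and match the binomial scale", {
  set.seed(18)
  n <- 2000
  obs <- runif(n) < 0.6
  prob <- ifelse(obs, 0.8, 0.3) + runif(n, -0.25, 0.25)
  a <- resample_rate_sd(obs, prob, 0.5, reps = 500, seed = 42)
  b <- resample_rate_sd(obs, prob, 0.5, reps = 500, seed = 42)
  expect_identical(a, b)

  # large-n binomial approximation sqrt(p(1-p)/n)
  cc <- confusion_counts(obs, prob, 0.5)
  sens <- unname(cc["tp"] / (cc["tp"] + cc["fn"]))
  n1 <- sum(obs)
  expect_equal(a$sens_sd, sqrt(sens * (1 - sens) / n1), tolerance = 0.2)
  spec <- unname(cc["tn"] / (cc["tn"] + cc["fp"]))
  n0 <- sum(!obs)
  expect_equal(a$spec_sd, sqrt(spec * (1 - spec) / n0), tolerance = 0.2)

  # all-presence degenerate set
  d <- resample_rate_sd(rep(TRUE, 20), runif(20), 0.5, reps = 100, seed = 1)
  expect_true(d$degenerate)
  expect_true(is.na(d$spec_sd))
})

test_that("validation stats assemble the accuracy-table row consistently", {
  set.seed(19)
  land <- simulate_sdm_data(400)
  p <- predict_probability(land)$p
  row <- validation_stats(land$presence, p, 0.73, reps = 200, seed = 2,
                          label = "synthetic")
  expect_equal(row$n, 400)
  expect_equal(row$prevalence, mean(land$presence))
  expect_equal(row$tss, row$sensitivity + row$specificity - 1,
               tolerance = 1e-12)
  expect_equal(row$auc, auc(land$presence, p))
  expect_gt(row$auc, 0.7)  # the generating model discriminates its own data
})

test_that("SDM refit flags rank deficiency and converges on training-size data", {
  set.seed(20)
  land <- simulate_sdm_data(299)
  # design mimicking the training data: prevalence around 0.73
  fit <- fit_sdm(land)
  expect_true(fit$converged)
  expect_length(fit$se, 6)

  dup <- land
  dup$prop_wetland <- dup$prop_deciduous
  expect_error(fit_sdm(dup), "rank deficient")
})

test_that("township aggregation keeps presences sticky across years", {
  obs <- data.frame(
    township_id = c(1, 1, 1, 2, 2, 3, 3, 3),
    year = c(1971, 1975, 1980, 1972, 1979, 1971, 1974, 1978),
    presence = c(FALSE, TRUE, FALSE, FALSE, FALSE, TRUE, FALSE, TRUE))
  agg <- aggregate_townships(obs)
  # township 1: absence, then presence, later absence treated as false
  expect_equal(agg$presence[agg$township_id == 1], c(FALSE, TRUE, TRUE))
  expect_equal(agg$presence[agg$township_id == 2], c(FALSE, FALSE))
  expect_equal(agg$presence[agg$township_id == 3], c(TRUE, TRUE, TRUE))
  # two surveys of one township-year collapse to any-presence
  obs2 <- data.frame(township_id = 5, year = c(1971, 1971),
                     presence = c(FALSE, TRUE))
  expect_equal(aggregate_townships(obs2)$presence, TRUE)
})
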