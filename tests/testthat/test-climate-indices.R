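test_that("WSI counts qualifying days with strict thresholds", {
  # every day qualifies: full 181-day window (non-leap spring)
  s <- daily_series("1980-11-01", "1981-04-30", tmin = -30, tmean = -25,
                    snow = 50)
  expect_identical(compute_wsi(s, 1980), 181L)
  # leap spring: 182 days
  s2 <- daily_series("1983-11-01", "1984-04-30", tmin = -30, tmean = -25,
                     snow = 50)
  expect_identical(compute_wsi(s2, 1983), 182L)
  # nothing qualifies
  s3 <- daily_series("1980-11-01", "1981-04-30", tmin = 0, tmean = 2,
                     snow = 0)
  expect_identical(compute_wsi(s3, 1980), 0L)
  # thresholds are strict: exactly -17.7 / exactly 38 do not count
  s4 <- daily_series("1980-11-01", "1981-04-30", tmin = -17.7, tmean = -10,
                     snow = 38)
  expect_identical(compute_wsi(s4, 1980), 0L)
  s4$tmin[1] <- -17.71
  s4$snow_cm[2] <- 38.01
  expect_identical(compute_wsi(s4, 1980), 2L)
})

test_that("WSI counts a both-criteria day once (constructed enumeration)", {
  s <- daily_series("1980-11-01", "1981-04-30", tmin = 0, tmean = 2,
                    snow = 0)
  s$tmin[1:40] <- -20           # cold only
  s$snow_cm[41:70] <- 50        # snow only
  s$tmin[71:80] <- -20          # both
  s$snow_cm[71:80] <- 50
  # brute-force day enumeration oracle
  oracle <- sum(s$tmin < -17.7 | s$snow_cm > 38)
  expect_identical(oracle, 80L)
  expect_identical(compute_wsi(s, 1980), 80L)
})

test_that("WSI errors on gaps instead of imputing", {
  s <- daily_series("1980-11-01", "1981-04-30", tmin = -30, tmean = -25)
  s <- s[-c(10, 50), ]
  expect_error(compute_wsi(s, 1980), "missing day")
  expect_error(compute_wsi(s, 1980), "1980-11-10")
})

test_that("WSI is monotone under colder/snowier perturbations and bounded", {
  set.seed(11)
  for (i in 1:20) {
    s <- daily_series("1980-11-01", "1981-04-30",
                      tmin = runif(181, -25, 0), tmean = 0,
                      snow = runif(181, 0, 60))
    s$tmean <- s$tmin + 5
    w0 <- compute_wsi(s, 1980)
    expect_gte(w0, 0); expect_lte(w0, 181)
    s2 <- s
    k <- sample(181, 30)
    s2$tmin[k] <- s2$tmin[k] - runif(30, 0, 15)
    s2$snow_cm[k] <- s2$snow_cm[k] + runif(30, 0, 20)
    expect_gte(compute_wsi(s2, 1980), w0)
  }
})

test_that("growing season matches calendar enumeration on constructed series", {
  base <- daily_series("1981-01-01", "1981-12-31", tmin = 10, tmean = 2)
  # no qualifying onset run: tmean < 5 all year
  expect_identical(compute_growing_season(base, 1981), 0L)

  # onset run begins Apr 10; first tmin <= -2 after Aug 1 is Sep 30
  s <- base
  on <- s$date >= as.Date("1981-04-10")
  s$tmean[on] <- 10
  s$tmin[s$date == as.Date("1981-09-30")] <- -2
  expect_identical(compute_growing_season(s, 1981),
                   as.integer(as.Date("1981-09-30") - as.Date("1981-04-10")))
  expect_identical(compute_growing_season(s, 1981), 173L)

  # shifting the qualifying run one day later shortens the season by 1
  s2 <- base
  s2$tmean[s2$date >= as.Date("1981-04-11")] <- 10
  s2$tmin[s2$date == as.Date("1981-09-30")] <- -2
  expect_identical(compute_growing_season(s2, 1981), 172L)

  # a 4-day warm spell does not start the season
  s3 <- s
  s3$tmean[s3$date >= as.Date("1981-04-05") &
             s3$date <= as.Date("1981-04-08")] <- 10
  s3$tmean[s3$date == as.Date("1981-04-09")] <- 2
  expect_identical(compute_growing_season(s3, 1981), 173L)

  # no qualifying frost: season runs to Dec 31
  s4 <- base
  s4$tmean[s4$date >= as.Date("1981-04-10")] <- 10
  expect_identical(compute_growing_season(s4, 1981),
                   as.integer(as.Date("1981-12-31") - as.Date("1981-04-10")))

  # cold days before Aug 1 do not end the season
  s5 <- s
  s5$tmin[s5$date == as.Date("1981-06-15")] <- -10
  expect_identical(compute_growing_season(s5, 1981), 173L)
})

test_that("cumulative mean is an inclusive arithmetic mean with gap errors", {
  ann <- data.frame(cell_id = 1L, year = 1961:1963,
                    value = c(100, 110, 120))
  expect_equal(cumulative_mean(ann, 1961, 1961)$mean, 100)
  expect_equal(cumulative_mean(ann, 1961, 1963)$mean, 110)
  expect_error(cumulative_mean(ann, 1960, 1963), "missing years")

  set.seed(3)
  v <- rnorm(42, 100, 20)
  ann2 <- data.frame(cell_id = 7L, year = 1961:2002, value = v)
  expect_equal(cumulative_mean(ann2, 1961, 2002)$mean, sum(v) / 42,
               tolerance = 1e-12)

  # convexity: extending by a decade moves the mean toward that decade
  m1 <- cumulative_mean(ann2, 1961, 1990)$mean
  m2 <- cumulative_mean(ann2, 1961, 2000)$mean
  dec_mean <- mean(v[31:40])
  expect_true((m2 - m1) * (dec_mean - m1) >= 0)
  expect_lte(abs(m2 - m1), abs(dec_mean - m1))
})

test_that("trend fitting is exact OLS with a floored extrapolation", {
  ann <- data.frame(cell_id = 1L, year = 1961:2002,
                    value = 200 - 1.5 * (1961:2002 - 1961))
  tr <- fit_trend(ann)
  expect_equal(tr$slope, -1.5, tolerance = 1e-12)
  expect_equal(tr$intercept, 200, tolerance = 1e-10)
  expect_equal(tr$reference_year, 1961)

  const <- data.frame(cell_id = 1L, year = 1961:1970, value = 5)
  expect_equal(fit_trend(const)$slope, 0)

  # independent oracle: stats::lm on the same data
  set.seed(21)
  noisy <- data.frame(cell_id = 1L, year = 1961:2002,
                      value = 150 - 0.8 * (1961:2002 - 1961) +
                        rnorm(42, 0, 5))
  tr2 <- fit_trend(noisy)
  ref <- stats::lm(value ~ I(year - 1961), data = noisy)
  expect_equal(tr2$slope, unname(coef(ref)[2]), tolerance = 1e-9)
  expect_equal(tr2$intercept, unname(coef(ref)[1]), tolerance = 1e-9)

  expect_error(fit_trend(data.frame(cell_id = 1, year = 1:2, value = 1:2)),
               "need >= 3")

  # extrapolation: identity at the reference year, flooring below zero
  expect_equal(extrapolate_trend(tr2, 1961)$value, tr2$intercept)
  steep <- data.frame(cell_id = 1L, slope = -2.248, intercept = 100,
                      reference_year = 2000L)
  expect_equal(extrapolate_trend(steep, 2050)$value, 0)  # 100 - 112.4 < 0
  flat <- data.frame(cell_id = 1L, slope = 0, intercept = 42,
                     reference_year = 2000L)
  expect_equal(extrapolate_trend(flat, 2500)$value, 42)
  expect_equal(extrapolate_trend(steep, 2010, cap = 70)$value, 70)
})

test_that("per-cell annual index tables agree with the single-cell path", {
  cfg <- synthetic_config(grid_rows = 2, grid_cols = 2, years = 1961:1966,
                          seed = 5)
  cl <- generate_climate(cfg)
  w <- annual_wsi(cl)
  g <- annual_growing_season(cl)
  # winters computable: 1961..1965; calendar years 1961..1966
  expect_setequal(unique(w$year), 1961:1965)
  expect_setequal(unique(g$year), 1961:1966)
  one <- cl[cl$cell_id == 3L, ]
  expect_identical(w$value[w$cell_id == 3L & w$year == 1963],
                   compute_wsi(one, 1963))
  expect_identical(g$value[g$cell_id == 3L & g$year == 1964],
                   compute_growing_season(one, 1964))
})
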