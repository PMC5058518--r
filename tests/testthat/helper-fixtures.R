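# shared fixture builders and independent oracles

# daily series over an inclusive date range with constant defaults
daily_series <- function(from, to, tmin = 0, tmean = 5, snow = 0,
                         cell_id = 1L) {
  d <- seq(as.Date(from), as.Date(to), by = "day")
  data.frame(cell_id = cell_id, date = d,
             tmin = rep_len(tmin, length(d)),
             tmean = rep_len(tmean, length(d)),
             snow_cm = rep_len(snow, length(d)))
}

# a small covariate landscape built directly (bypassing the composer)
toy_landscape <- function(dec, wet, fp, wsi, gs, decade = NULL) {
  n <- max(lengths(list(dec, wet, fp, wsi, gs)))
  out <- data.frame(cell_id = seq_len(n),
                    prop_deciduous = rep_len(dec, n),
                    prop_wetland = rep_len(wet, n),
                    prop_footprint = rep_len(fp, n),
                    wsi_mean = rep_len(wsi, n),
                    gs_mean = rep_len(gs, n))
  attr(out, "decade") <- decade
  out
}

# random landscape on n cells, covariates inside the training ranges
random_landscape <- function(n, decade = NULL) {
  lc <- reconcile_landcover(fp <- runif(n, 0, 0.9),
                            runif(n, 0, 0.9), runif(n, 0, 0.13))
  toy_landscape(lc$prop_deciduous, lc$prop_wetland, fp,
                runif(n, 66.87, 193.94), runif(n, 142.6, 178.1), decade)
}

# brute-force AUC: count presence/absence pairs, ties worth one half
auc_bruteforce <- function(observed, prob) {
  obs <- as.logical(observed)
  pp <- prob[obs]; pa <- prob[!obs]
  cmp <- outer(pp, pa, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# independent logistic MLE via Newton-Raphson on the raw likelihood
logistic_newton <- function(y, x, tol = 1e-12, maxit = 200) {
  X <- cbind(1, x)
  b <- c(0, 0)
  for (i in seq_len(maxit)) {
    p <- plogis(X %*% b)
    g <- crossprod(X, y - p)
    H <- crossprod(X, X * as.vector(p * (1 - p)))
    step <- solve(H, g)
    b <- b + step
    if (max(abs(step)) < tol) break
  }
  as.vector(b)
}

# join-count clustering statistic: rook-adjacent occupied pairs divided
# by their expectation for the same number of occupied cells placed at
# random (ratio ~1 for random patterns, >1 for clustered ones)
join_count_ratio <- function(cells_with_fp, rows, cols) {
  m <- matrix(FALSE, rows, cols)
  r <- (cells_with_fp - 1L) %/% cols + 1L
  cc <- (cells_with_fp - 1L) %% cols + 1L
  m[cbind(r, cc)] <- TRUE
  observed <- sum(m[-rows, ] & m[-1, ]) + sum(m[, -cols] & m[, -1])
  n_edges <- (rows - 1) * cols + rows * (cols - 1)
  k <- length(unique(cells_with_fp)); n <- rows * cols
  expected <- n_edges * (k / n) * ((k - 1) / (n - 1))
  observed / expected
}

# simulate presence/absence from the published coefficients on random
# covariates spanning the training ranges
simulate_sdm_data <- function(n, coef = sdm_coefficients()) {
  land <- random_landscape(n)
  p <- predict_probability(land, coef)$p
  land$presence <- runif(n) < p
  land
}
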