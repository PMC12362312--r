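# Iterative random-forest threshold imputation.

test_that("initial mean imputation rounds item means at 0.5", {
  x <- rbind(c(1, 0, NA), c(1, NA, 0), c(1, 0, 1), c(0, 1, 1), c(NA, 1, 1))
  out <- initial_impute(x)
  expect_false(anyNA(out))
  expect_equal(out[5, 1], 1)  # item mean 0.75 -> 1
  expect_equal(out[2, 2], 1)  # item mean 0.50 -> 1
  expect_equal(out[1, 3], 1)  # item mean 0.75 -> 1
  obs <- !is.na(x)
  expect_identical(out[obs], x[obs])
  complete <- matrix(c(0, 1, 1, 0), 2)
  expect_identical(initial_impute(complete), complete)
  expect_error(initial_impute(rbind(c(NA, 1), c(NA, 0))), "no observed")
})

test_that("items are visited in ascending-missingness order", {
  x <- matrix(1, 5, 3)
  x[1:3, 1] <- NA; x[1, 3] <- NA
  expect_identical(order_variables(x), c(3L, 1L))
  x2 <- matrix(c(NA, 1, NA, 1, NA, 1), 2, 3)
  expect_identical(order_variables(x2), 1:3)  # equal counts: original order
  expect_identical(order_variables(matrix(1, 3, 3)), integer(0))
})

test_that("threshold mapping matches its brute-force oracle on a dense grid", {
  expect_equal(threshold_map(0.97, 0.30, 0.95), 1)
  expect_true(is.na(threshold_map(0.50, 0.30, 0.70)))
  expect_equal(threshold_map(0.50, 0.50, 0.70), 0)  # RFTI: p = 0.5 -> 0

  p <- seq(0, 1, by = 0.005)
  grid <- rbind(threshold_grid(0.05, "RFDTI"), threshold_grid(0.05, "RFTI"))
  for (r in seq_len(nrow(grid))) {
    expect_identical(threshold_map(p, grid$tau_l[r], grid$tau_u[r]),
                     naive_threshold_map(p, grid$tau_l[r], grid$tau_u[r]))
  }

  # raising tau_u never adds 1s; narrowing the band never adds NAs
  p_frozen <- withr::with_seed(5, runif(200))
  ones <- sapply(seq(0.5, 0.95, 0.05), function(tu)
    sum(threshold_map(p_frozen, 0.3, tu) == 1, na.rm = TRUE))
  expect_true(all(diff(ones) <= 0))
  nas <- sapply(seq(0.05, 0.45, 0.05), function(tl)
    sum(is.na(threshold_map(p_frozen, tl, 0.8))))
  expect_true(all(diff(nas) <= 0))
})

test_that("the change statistic counts state flips among masked cells", {
  old <- c(0, 1, NA, 0, 1, 1, 0, NA, 1, 0)
  new <- c(0, 1, NA, 0, 1, 1, 0, NA, 0, 0)   # one change among ten
  mask <- rep(TRUE, 10)
  expect_equal(imputation_delta(new, old, mask), 0.1)
  expect_equal(imputation_delta(old, old, mask), 0)
  expect_equal(imputation_delta(1 - ifelse(is.na(old), 0, old),
                                ifelse(is.na(old), 0, old), mask), 1)
  expect_error(imputation_delta(new, old, rep(FALSE, 10)), "nothing to impute")

  # random matrices against the brute-force counter
  withr::with_seed(6, {
    for (i in 1:20) {
      a <- matrix(sample(c(0, 1, NA), 60, replace = TRUE), 6)
      b <- matrix(sample(c(0, 1, NA), 60, replace = TRUE), 6)
      m <- matrix(sample(c(TRUE, FALSE), 60, replace = TRUE, prob = c(.7, .3)), 6)
      if (!any(m)) next
      expect_equal(imputation_delta(a, b, m), naive_delta(a, b, m))
    }
  })
})

test_that("the adapted person-fit index matches hand-computed cases", {
  q <- diag(2)
  # consistent row: response equals ideal response -> 0
  r0 <- rci_c(matrix(c(1, 0), 1), matrix(c(1, 0), 1), q,
              s = c(0.1, 0.1), g = c(0.2, 0.2))
  expect_equal(r0$rci, 0)

  # single item, Y = 1 where ideal = 0, P = g = 0.2 -> ln 4
  q1 <- matrix(1, 1, 1)
  r1 <- rci_c(matrix(1, 1, 1), matrix(0, 1, 1), q1, s = 0.1, g = 0.2)
  expect_equal(r1$rci, log(4), tolerance = 1e-12)

  # single item, Y = 0 where ideal = 1, P = 1 - s = 0.9 -> ln 9
  r2 <- rci_c(matrix(0, 1, 1), matrix(1, 1, 1), q1, s = 0.1, g = 0.2)
  expect_equal(r2$rci, log(9), tolerance = 1e-12)

  # NA cells drop out of both numerator and m_i
  y <- matrix(c(1, NA), 1)
  r3 <- rci_c(y, matrix(c(0, 0), 1), diag(2), s = c(0.1, 0.1), g = c(0.2, 0.2))
  expect_equal(r3$m, 1)
  expect_equal(r3$rci, log(4), tolerance = 1e-12)

  expect_equal(rci_c_mean(c(0, log(4))), log(4) / 2)
  expect_equal(rci_c_mean(c(0.3, NA)), 0.3)
  expect_error(rci_c_mean(NA_real_), "no examinee")
})

test_that("the stopping rule returns the right iteration", {
  # fabricated probability traces exercising the Delta rule directly
  x <- matrix(1, 4, 3); x[1:2, 1] <- NA
  mask_idx <- which(is.na(x))
  init <- initial_impute(x)[mask_idx]            # both filled with 1
  mk_trace <- function(ps) list(get = function(i) {
    m <- matrix(NA_real_, 4, 3); m[mask_idx] <- ps[[i]]; m
  })
  # Delta trace (1, 0.5, then rises to 1): stop at the increase, keep iter 2
  tr <- mk_trace(list(c(0.1, 0.1), c(0.1, 0.9), c(0.9, 0.1)))
  path <- rfdti:::run_threshold_path(tr, x, mask_idx, init, 0.3, 0.7, 10)
  expect_equal(path$iteration, 2)
  expect_equal(path$states, c(0, 1))
  expect_equal(path$deltas, c(1, 0.5, 1))
  # Delta reaches 0: return that iteration
  tr2 <- mk_trace(list(c(0.1, 0.9), c(0.1, 0.9)))
  path2 <- rfdti:::run_threshold_path(tr2, x, mask_idx, init, 0.3, 0.7, 10)
  expect_equal(path2$iteration, 2)
  expect_equal(path2$deltas, c(0.5, 0))
})

test_that("a single forest pass yields valid, reproducible probabilities", {
  d <- make_missing_data("MCAR", 0.2, n = 100, j = 10, k = 3, seed = 49)
  p1 <- rf_pass(d$x_miss, rf_config = list(num.trees = 25), seed = 5)
  mask <- is.na(d$x_miss)
  expect_true(all(is.na(p1$probs[!mask])))
  expect_true(all(p1$probs[mask] >= 0 & p1$probs[mask] <= 1))
  expect_false(anyNA(p1$working))
  # chained update rounds the probabilities at 0.5
  expect_equal(unname(p1$working[mask]), unname((p1$probs[mask] >= 0.5) * 1))
  p2 <- rf_pass(d$x_miss, rf_config = list(num.trees = 25), seed = 5)
  expect_identical(p1$probs, p2$probs)

  # constant observed response short-circuits to that constant
  x <- d$x_miss
  x[!is.na(x[, 3]), 3] <- 1
  p3 <- rf_pass(x, rf_config = list(num.trees = 10), seed = 6)
  expect_true(all(p3$probs[is.na(x[, 3]), 3] == 1))
})

test_that("iterative imputation preserves observed cells and the mask bound", {
  d <- make_missing_data("MCAR", 0.2, n = 150, j = 15, k = 3, seed = 51)
  out <- iterate_impute(d$x_miss, 0.3, 0.7,
                        rf_config = list(num.trees = 30), seed = 99)
  obs <- !is.na(d$x_miss)
  expect_identical(out[obs], d$x_miss[obs])
  expect_true(all(which(is.na(out)) %in% which(is.na(d$x_miss))))
  # determinism under a fixed seed
  out2 <- iterate_impute(d$x_miss, 0.3, 0.7,
                         rf_config = list(num.trees = 30), seed = 99)
  expect_identical(out, out2)
})

test_that("a dynamic grid pinned to tau_l = 0.5 reproduces RFTI bit-exactly", {
  d <- make_missing_data("MCAR", 0.15, n = 120, j = 12, k = 3, seed = 53)
  cfg <- list(num.trees = 30)
  pinned <- threshold_grid(0.1, "RFTI")
  a <- select_thresholds(d$x_miss, d$q, pinned, cfg, seed = 7)
  b <- rfti(d$x_miss, d$q, stepV = 0.1, rf_config = cfg, seed = 7)
  expect_identical(a$imputed, b$imputed)
  expect_identical(a$thresholds, b$thresholds)
  expect_equal(a$grid_table, b$grid_table)
})

test_that("threshold selection is self-consistent and handles single grids", {
  d <- make_missing_data("MCAR", 0.15, n = 150, j = 12, k = 3, seed = 57)
  cfg <- list(num.trees = 30)
  one <- data.frame(tau_l = 0.3, tau_u = 0.7)
  res <- select_thresholds(d$x_miss, d$q, one, cfg, seed = 3)
  expect_equal(unname(res$thresholds), c(0.3, 0.7))
  expect_equal(res$remaining_missing_rate, mean(is.na(res$imputed)))

  # recomputing the index from the returned matrix reproduces rci_mean
  fit <- suppressWarnings(fit_dina_em(res$imputed, d$q))
  prof <- estimate_profiles_map(fit)
  rci <- rci_c(res$imputed, prof, d$q, fit$s, fit$g)
  expect_equal(rci_c_mean(rci$rci), res$rci_mean, tolerance = 1e-12)

  # RFTI grids only ever contain tau_l = 0.5
  expect_true(all(threshold_grid(0.05, "RFTI")$tau_l == 0.5))
  g <- threshold_grid(0.05, "RFDTI")
  expect_true(all(g$tau_l > 0 & g$tau_l < 0.5))
  expect_true(all(g$tau_u >= 0.5 & g$tau_u < 1))
  expect_equal(nrow(g), 90)
})

test_that("full RFDTI output is reproducible under a fixed seed", {
  d <- make_missing_data("MNAR", 0.2, n = 120, j = 12, k = 3, seed = 61)
  cfg <- list(num.trees = 25)
  r1 <- rfdti(d$x_miss, d$q, stepV = 0.1, rf_config = cfg, seed = 11)
  r2 <- rfdti(d$x_miss, d$q, stepV = 0.1, rf_config = cfg, seed = 11)
  expect_identical(r1$imputed, r2$imputed)
  expect_identical(r1$thresholds, r2$thresholds)
  expect_equal(r1$grid_table, r2$grid_table)
  expect_equal(r1$rci_mean, min(r1$grid_table$rci_mean, na.rm = TRUE))
})
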