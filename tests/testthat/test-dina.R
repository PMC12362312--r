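# DINA generation and EM estimation.

test_that("item response function follows the conjunctive rule", {
  expect_equal(dina_irf(c(1, 1), c(1, 1), s = 0.1, g = 0.2), 0.9)
  expect_equal(dina_irf(c(0, 0), c(1, 1), s = 0.1, g = 0.2), 0.2)
  # missing one required attribute collapses to guessing
  expect_equal(dina_irf(c(1, 0, 1), c(1, 1, 0), s = 0.1, g = 0.2), 0.2)
  expect_error(dina_irf(c(1, 0), c(1, 1, 0), 0.1, 0.2), "length")
})

test_that("irf matches a brute-force conjunction oracle for K <= 4", {
  for (k in 2:4) {
    patterns <- attribute_patterns(k)
    q <- generate_q_matrix(8, k, seed = k)
    for (c_i in seq_len(nrow(patterns))) {
      for (j_i in seq_len(nrow(q))) {
        eta <- naive_eta(patterns[c_i, ], q[j_i, ])
        expect_equal(dina_irf(patterns[c_i, ], q[j_i, ], 0.12, 0.18),
                     if (eta == 1) 0.88 else 0.18)
      }
    }
  }
})

test_that("dichotomized MVN profiles have the right margins and association", {
  p1 <- simulate_attribute_profiles(1e5, 1, seed = 42)
  expect_equal(mean(p1), 0.5, tolerance = 0.02)

  p0 <- simulate_attribute_profiles(1e5, 3, rho = 0, seed = 43)
  phis <- cor(p0)[upper.tri(diag(3))]
  expect_true(all(abs(phis) < 0.02))

  # closed form for a bivariate normal dichotomized at its mean:
  # P11 = 1/4 + arcsin(rho)/(2*pi) = 1/3 at rho = 0.5, so phi = 1/3
  p5 <- simulate_attribute_profiles(5e5, 2, rho = 0.5, seed = 44)
  expect_equal(cor(p5)[1, 2], 1 / 3, tolerance = 0.01)

  expect_error(simulate_attribute_profiles(10, 3, rho = -0.6),
               "positive-definite")
})

test_that("random Q-matrices satisfy their invariants", {
  q <- generate_q_matrix(30, 4, seed = 7)
  expect_true(all(q %in% c(0, 1)))
  expect_true(all(rowSums(q) >= 1))
  expect_true(all(colSums(q) >= 1))
  expect_identical(q, generate_q_matrix(30, 4, seed = 7))

  # mean row sum of Bernoulli(0.5)^k conditioned on not-all-zero:
  # (k/2) / (1 - 2^-k) = 2.1333 at k = 4
  sums <- withr::with_seed(8, {
    replicate(2000, mean(rowSums(generate_q_matrix(30, 4))))
  })
  expect_equal(mean(sums), 2.1333, tolerance = 0.02)
})

test_that("simulated responses follow the DINA probabilities", {
  d <- make_dina_data(n = 50, j = 10, k = 3, seed = 5,
                      s = rep(1e-9, 10), g = rep(1e-9, 10))
  eta <- rfdti:::ideal_responses(d$profiles, d$q)
  expect_identical(d$x, eta)          # vanishing noise: ideal responses
  expect_false(anyNA(d$x))

  # Monte Carlo check of P(X = 1 | eta = 1) = 1 - s
  prof <- matrix(1, 1e5, 2)
  q <- rbind(c(1, 1), diag(2))
  x <- simulate_dina_responses(prof, q, s = rep(0.1, 3), g = rep(0.2, 3),
                               seed = 9)
  expect_equal(mean(x[, 1]), 0.9, tolerance = 0.005)
  expect_error(simulate_dina_responses(prof, q, s = rep(0, 3), g = rep(0.2, 3)),
               "strictly inside")
})

test_that("EM recovers parameters in the noiseless identifiable limit", {
  d <- make_dina_data(n = 500, j = 12, k = 3, seed = 11,
                      s = rep(1e-9, 12), g = rep(1e-9, 12))
  fit <- suppressWarnings(fit_dina_em(d$x, d$q))
  expect_true(all(fit$s <= 0.01))
  expect_true(all(fit$g <= 0.01))
  expect_identical(estimate_profiles_map(fit), d$profiles)
  expect_true(all(diff(fit$loglik_trace) >= -1e-8))
})

test_that("EM agrees with a direct likelihood optimizer on a small dataset", {
  d <- make_dina_data(n = 250, j = 8, k = 2, seed = 13)
  fit <- fit_dina_em(d$x, d$q, tol = 1e-7)

  # independent route: direct BFGS maximization of the same marginal
  # likelihood over logit-transformed (s, g, prior)
  patterns <- attribute_patterns(2)
  eta <- rfdti:::ideal_responses(patterns, d$q)
  j <- ncol(d$x)
  negll <- function(par) {
    s <- plogis(par[1:j]); g <- plogis(par[j + 1:j])
    pr <- exp(c(par[2 * j + 1:3], 0)); pr <- pr / sum(pr)
    p1 <- eta * rep(1 - s, each = nrow(eta)) +
      (1 - eta) * rep(g, each = nrow(eta))
    ll <- (d$x == 1) %*% t(log(p1)) + (d$x == 0) %*% t(log(1 - p1))
    ll <- sweep(ll, 2, log(pr), "+")
    mx <- apply(ll, 1, max)
    -sum(mx + log(rowSums(exp(ll - mx))))
  }
  start <- c(qlogis(rep(0.1, j)), qlogis(rep(0.2, j)), rep(0, 3))
  opt <- optim(start, negll, method = "BFGS", control = list(maxit = 500))
  s_hat <- plogis(opt$par[1:j]); g_hat <- plogis(opt$par[j + 1:j])

  expect_lt(max(abs(fit$s - s_hat)), 0.02)
  expect_lt(max(abs(fit$g - g_hat)), 0.02)
})

test_that("missing cells carry no item information in the EM fit", {
  d <- make_dina_data(n = 400, j = 15, k = 3, seed = 17)
  fit1 <- fit_dina_em(d$x, d$q, tol = 1e-7)
  padded <- rbind(d$x, matrix(NA_real_, 5, ncol(d$x)))
  fit2 <- fit_dina_em(padded, d$q, tol = 1e-7)
  expect_lt(max(abs(fit1$s - fit2$s)), 1e-6)
  expect_lt(max(abs(fit1$g - fit2$g)), 1e-6)
  # an all-NA examinee's posterior is the prior
  for (r in nrow(d$x) + 1:5) {
    expect_equal(unname(fit2$posterior[r, ]), unname(fit2$prior),
                 tolerance = 1e-12)
  }
  expect_equal(sum(fit2$prior), 1, tolerance = 1e-10)
  expect_equal(unname(rowSums(fit2$posterior)), rep(1, nrow(padded)),
               tolerance = 1e-10)
})

test_that("parameter bias shrinks with the sample size", {
  mae <- vapply(c(500, 2000), function(n) {
    errs <- vapply(1:3, function(r) {
      d <- make_dina_data(n = n, j = 30, k = 3, seed = 100 * r)
      fit <- fit_dina_em(d$x, d$q)
      mean(abs(c(fit$s - d$s, fit$g - d$g)))
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  expect_lt(mae[2], mae[1])
})

test_that("MAP ties break to the lexicographically smaller pattern", {
  patterns <- attribute_patterns(2)
  post <- matrix(c(0.25, 0.25, 0.25, 0.25,
                   0.1, 0.4, 0.4, 0.1), 2, 4, byrow = TRUE)
  fit <- structure(list(posterior = post, patterns = patterns),
                   class = "dina_fit")
  prof <- estimate_profiles_map(fit)
  expect_equal(prof[1, ], c(0, 0))  # full tie: smallest pattern
  expect_equal(prof[2, ], c(0, 1))  # (0,1) before (1,0)
})
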