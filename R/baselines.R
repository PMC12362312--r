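# Traditional comparison imputers: person mean (PM), two-way (TW), EM under
# a multivariate-normal working model, and multiple imputation by chained
# logistic regression. All leave observed cells untouched and return fully
# complete 0/1 matrices.

#' Person-mean imputation
#'
#' Each missing cell is replaced by the examinee's mean over their observed
#' items, rounded half-up to 0/1.
#'
#' @param x response matrix over \{0, 1, NA\}.
#' @return A complete binary matrix.
#' @export
impute_pm <- function(x) {
  x <- check_response_matrix(x)
  if (!anyNA(x)) return(x)
  pm <- rowMeans(x, na.rm = TRUE)
  if (anyNA(pm)) stop("an examinee has no observed responses")
  for (i in which(rowSums(is.na(x)) > 0)) {
    x[i, is.na(x[i, ])] <- round_half_up(pm[i])
  }
  x
}

#' Two-way imputation
#'
#' Missing cell (i, j) is replaced by `PM_i + IM_j - GM` (person mean plus
#' item mean minus grand mean, all over observed cells), clipped to
#' \[0, 1\] and rounded half-up.
#'
#' @inheritParams impute_pm
#' @export
impute_tw <- function(x) {
  x <- check_response_matrix(x)
  if (!anyNA(x)) return(x)
  pm <- rowMeans(x, na.rm = TRUE)
  im <- colMeans(x, na.rm = TRUE)
  if (anyNA(pm)) stop("an examinee has no observed responses")
  if (anyNA(im)) stop("an item has no observed responses")
  gm <- mean(x, na.rm = TRUE)
  idx <- which(is.na(x), arr.ind = TRUE)
  tw <- clamp(pm[idx[, 1]] + im[idx[, 2]] - gm, 0, 1)
  x[idx] <- round_half_up(tw)
  x
}

#' EM imputation under a normal working model
#'
#' Treats the item columns as multivariate normal; the E-step fills missing
#' cells with their conditional expectations given the observed cells and
#' the M-step re-estimates the mean vector and (ridge-regularized)
#' covariance. On convergence the expectations are clipped to \[0, 1\] and
#' rounded half-up. Deterministic given the tolerances.
#'
#' @inheritParams impute_pm
#' @param tol convergence tolerance on parameter change (default 1e-5).
#' @param max_iter maximum EM iterations (default 500).
#' @param ridge covariance ridge (default 1e-4).
#' @return A complete binary matrix, with the working-model observed-data
#'   log-likelihood trace in attribute `"loglik_trace"`.
#' @export
impute_em <- function(x, tol = 1e-5, max_iter = 500, ridge = 1e-4) {
  x <- check_response_matrix(x)
  if (!anyNA(x)) return(x)
  n <- nrow(x); j <- ncol(x)
  miss <- is.na(x)
  if (any(colSums(!miss) == 0)) stop("an item has no observed responses")

  patterns <- apply(miss, 1, function(r) paste(as.integer(r), collapse = ""))
  groups <- split(seq_len(n), patterns)

  filled <- initial_impute_numeric(x)
  mu <- colMeans(filled)
  sigma <- cov(filled) * (n - 1) / n + diag(ridge, j)
  loglik_trace <- numeric(0)

  for (it in seq_len(max_iter)) {
    cond_cov <- matrix(0, j, j)
    loglik <- 0
    for (rows in groups) {
      mis <- which(miss[rows[1], ])
      obs <- setdiff(seq_len(j), mis)
      xo <- filled[rows, obs, drop = FALSE]
      so <- sigma[obs, obs, drop = FALSE]
      cho <- tryCatch(chol(so), error = function(e)
        stop("singular working covariance despite ridge"))
      centered <- sweep(xo, 2, mu[obs])
      # observed-data log-likelihood of this pattern group
      zi <- backsolve(cho, t(centered), transpose = TRUE)
      loglik <- loglik - 0.5 * sum(zi^2) -
        length(rows) * (sum(log(diag(cho))) + 0.5 * length(obs) * log(2 * pi))
      if (length(mis)) {
        b <- sigma[mis, obs, drop = FALSE] %*% chol2inv(cho)
        pred <- sweep(centered %*% t(b), 2, mu[mis], "+")
        filled[rows, mis] <- pred
        cmm <- sigma[mis, mis, drop = FALSE] -
          b %*% sigma[obs, mis, drop = FALSE]
        cond_cov[mis, mis] <- cond_cov[mis, mis] + length(rows) * cmm
      }
    }
    loglik_trace <- c(loglik_trace, loglik)
    mu_new <- colMeans(filled)
    centered_all <- sweep(filled, 2, mu_new)
    sigma_new <- (crossprod(centered_all) + cond_cov) / n + diag(ridge, j)
    delta <- max(abs(c(mu_new - mu, sigma_new - sigma)))
    mu <- mu_new; sigma <- sigma_new
    if (delta < tol) break
  }

  out <- x
  out[miss] <- round_half_up(clamp(filled[miss], 0, 1))
  attr(out, "loglik_trace") <- loglik_trace
  out
}

# Numeric item-mean fill (no rounding), the EM starting point.
initial_impute_numeric <- function(x) {
  means <- colMeans(x, na.rm = TRUE)
  for (jj in which(colSums(is.na(x)) > 0)) {
    x[is.na(x[, jj]), jj] <- means[jj]
  }
  x
}

#' Multiple imputation by chained logistic regression
#'
#' Creates `m` completed datasets. Each chain initializes missing cells by
#' resampling the item's observed values, then cycles `burnin` times over
#' the incomplete items in ascending-missingness order: a weighted logistic
#' regression of the item's observed cells on the other items is fitted
#' under Bayesian-bootstrap (Dirichlet) case weights, and each missing cell
#' is redrawn as Bernoulli from the predicted probability. Perfect
#' separation falls back to a ridge-penalized fit.
#'
#' Downstream pooling averages evaluation metrics across the `m` datasets.
#'
#' @inheritParams impute_pm
#' @param m number of imputed datasets (default 20).
#' @param burnin chained-equation cycles per dataset (default 10).
#' @param seed optional integer seed.
#' @return An object of class `mi_result`: list with `datasets` (length-m
#'   list of complete binary matrices) and `m`.
#' @export
impute_mi <- function(x, m = 20, burnin = 10, seed = NULL) {
  x <- check_response_matrix(x)
  n <- nrow(x); j <- ncol(x)
  miss <- is.na(x)
  if (any(colSums(!miss) == 0)) stop("an item has no observed responses")
  ord <- order_variables(x)

  with_optional_seed(seed, {
    datasets <- vector("list", m)
    for (d in seq_len(m)) {
      working <- x
      for (s in ord) {
        mis_rows <- which(miss[, s])
        obs_vals <- x[!miss[, s], s]
        working[mis_rows, s] <- sample(obs_vals, length(mis_rows), replace = TRUE)
      }
      if (length(ord)) {
        for (cycle in seq_len(burnin)) {
          for (s in ord) {
            obs_rows <- which(!miss[, s])
            mis_rows <- which(miss[, s])
            y <- x[obs_rows, s]
            if (length(unique(y)) < 2) {
              working[mis_rows, s] <- y[1]
              next
            }
            xo <- cbind(1, working[obs_rows, -s, drop = FALSE])
            w <- rexp(length(obs_rows))
            w <- w / mean(w)                     # Bayesian bootstrap
            beta <- fit_weighted_logistic(xo, y, w)
            eta <- cbind(1, working[mis_rows, -s, drop = FALSE]) %*% beta
            working[mis_rows, s] <- rbinom(length(mis_rows), 1, plogis(eta))
          }
        }
      }
      datasets[[d]] <- working
    }
    structure(list(datasets = datasets, m = m), class = "mi_result")
  })
}

# Weighted logistic fit with a ridge-penalized IRLS fallback on separation
# or non-convergence.
fit_weighted_logistic <- function(xmat, y, w) {
  fit <- suppressWarnings(
    stats::glm.fit(xmat, y, weights = w, family = stats::binomial()))
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  if (!fit$converged || any(abs(beta) > 20)) {
    beta <- ridge_logistic(xmat, y, w, lambda = 0.1)
  }
  beta
}

# Minimal ridge-penalized IRLS (intercept unpenalized).
ridge_logistic <- function(xmat, y, w, lambda = 0.1, iter = 25) {
  p <- ncol(xmat)
  pen <- diag(lambda, p); pen[1, 1] <- 0
  beta <- rep(0, p)
  for (i in seq_len(iter)) {
    mu <- plogis(drop(xmat %*% beta))
    wt <- w * mu * (1 - mu) + 1e-10
    z <- drop(xmat %*% beta) + (y - mu) / (mu * (1 - mu) + 1e-10)
    xtw <- t(xmat * wt)
    beta_new <- tryCatch(solve(xtw %*% xmat + pen, xtw %*% z),
                         error = function(e) beta)
    if (max(abs(beta_new - beta)) < 1e-8) { beta <- drop(beta_new); break }
    beta <- drop(beta_new)
  }
  beta
}

#' @export
print.mi_result <- function(x, ...) {
  cat(sprintf("Multiple imputation: %d completed datasets (%d x %d)\n",
              x$m, nrow(x$datasets[[1]]), ncol(x$datasets[[1]])))
  invisible(x)
}
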