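# DINA model: data generation, marginal-maximum-likelihood EM estimation on
# possibly-incomplete 0/1 response matrices, and MAP attribute classification.

#' All attribute patterns for K attributes
#'
#' Returns the 2^K binary mastery patterns in lexicographic order (row c is
#' the K-bit binary representation of c - 1, first attribute most
#' significant). This ordering is the tie-breaking order used by
#' [estimate_profiles_map()].
#'
#' @param k number of attributes.
#' @return A 2^K x K binary matrix.
#' @export
attribute_patterns <- function(k) {
  stopifnot(k >= 1)
  m <- as.matrix(expand.grid(rep(list(c(0, 1)), k))[, k:1, drop = FALSE])
  dimnames(m) <- NULL
  # expand.grid varies the first factor fastest; after reversing columns the
  # rows are already in lexicographic order of the bit-vector.
  m
}

# Ideal (conjunctive) responses: eta[c, j] = 1 iff pattern c masters every
# attribute required by item j.
ideal_responses <- function(patterns, q) {
  hit <- patterns %*% t(q)               # attributes mastered among required
  need <- rowSums(q)
  t(t(hit) == need) * 1
}

#' DINA item response function
#'
#' Probability of a correct response for one examinee profile on one item:
#' `1 - s` when the profile masters every required attribute (ideal response
#' eta = 1, computed as the conjunctive product over required attributes),
#' `g` otherwise.
#'
#' @param profile binary K-vector of attribute mastery.
#' @param q_row binary K-vector of the item's required attributes.
#' @param s,g the item's slipping and guessing probabilities.
#' @return A single probability.
#' @export
dina_irf <- function(profile, q_row, s, g) {
  if (length(profile) != length(q_row)) {
    stop("profile and q_row must have the same length")
  }
  stopifnot(all(profile %in% c(0, 1)), all(q_row %in% c(0, 1)),
            s > 0, s < 1, g > 0, g < 1)
  eta <- prod(profile^q_row)
  if (eta == 1) 1 - s else g
}

#' Simulate correlated attribute profiles
#'
#' Draws each examinee's latent vector from a K-variate standard normal with
#' exchangeable correlation `rho` and dichotomizes at 0 (mastery iff the
#' latent value is >= 0), the standard way of generating correlated binary
#' mastery profiles.
#'
#' @param n number of examinees.
#' @param k number of attributes.
#' @param rho common off-diagonal correlation (default 0.5).
#' @param seed optional integer seed.
#' @return An n x k binary matrix.
#' @export
simulate_attribute_profiles <- function(n, k, rho = 0.5, seed = NULL) {
  stopifnot(n >= 1, k >= 1)
  if (k > 1 && (rho <= -1 / (k - 1) || rho >= 1)) {
    stop("rho implies a non-positive-definite correlation matrix")
  }
  sigma <- matrix(rho, k, k)
  diag(sigma) <- 1
  with_optional_seed(seed, {
    z <- MASS::mvrnorm(n, mu = rep(0, k), Sigma = sigma)
    z <- matrix(z, nrow = n, ncol = k)
    (z >= 0) * 1
  })
}

#' Generate a random Q-matrix
#'
#' Entries are independent Bernoulli(0.5) (a U(0,1) draw dichotomized at
#' 0.5). Rows that would leave an item measuring no attribute are redrawn;
#' if any attribute ends up measured by no item the whole matrix is redrawn.
#'
#' @param j number of items.
#' @param k number of attributes (j >= k).
#' @param seed optional integer seed.
#' @return A j x k binary matrix.
#' @export
generate_q_matrix <- function(j, k, seed = NULL) {
  stopifnot(j >= k, k >= 1)
  with_optional_seed(seed, {
    for (attempt in 1:1000) {
      q <- matrix(rbinom(j * k, 1, 0.5), j, k)
      for (r in seq_len(j)) {
        tries <- 0
        while (sum(q[r, ]) == 0) {
          q[r, ] <- rbinom(k, 1, 0.5)
          tries <- tries + 1
          if (tries > 1000) stop("Q-matrix row redraw limit exceeded")
        }
      }
      if (all(colSums(q) > 0)) return(q)
    }
    stop("Q-matrix redraw limit exceeded")
  })
}

#' Draw DINA item parameters
#'
#' Slipping and guessing parameters drawn independently from U(min, max);
#' the default range keeps 1 - s > g for every item.
#'
#' @param j number of items.
#' @param min,max uniform range (defaults 0.05, 0.25).
#' @param seed optional integer seed.
#' @return A list with numeric vectors `s` and `g` of length j.
#' @export
simulate_item_params <- function(j, min = 0.05, max = 0.25, seed = NULL) {
  stopifnot(j >= 1, min > 0, max < 1, min <= max)
  with_optional_seed(seed, list(s = runif(j, min, max), g = runif(j, min, max)))
}

#' Simulate DINA responses
#'
#' For each examinee and item the correct-response probability from the DINA
#' item response function is compared to a uniform draw; the response is 1
#' when the probability is at least the draw.
#'
#' @param profiles n x k binary profile matrix.
#' @param q j x k Q-matrix.
#' @param s,g item parameter vectors in (0, 1).
#' @param seed optional integer seed.
#' @return A complete n x j binary response matrix.
#' @export
simulate_dina_responses <- function(profiles, q, s, g, seed = NULL) {
  q <- check_q_matrix(q)
  if (ncol(profiles) != ncol(q)) stop("profiles and Q-matrix disagree on K")
  if (length(s) != nrow(q) || length(g) != nrow(q)) {
    stop("item parameter length must equal the number of items")
  }
  if (any(s <= 0 | s >= 1 | g <= 0 | g >= 1)) {
    stop("item parameters must lie strictly inside (0, 1)")
  }
  p <- dina_probabilities(profiles, q, s, g)
  with_optional_seed(seed, {
    u <- matrix(runif(length(p)), nrow(p), ncol(p))
    (u <= p) * 1
  })
}

#' True correct-response probabilities under the DINA model
#'
#' @inheritParams simulate_dina_responses
#' @return An n x j matrix of probabilities.
#' @export
dina_probabilities <- function(profiles, q, s, g) {
  eta <- ideal_responses(profiles, q)    # n x j
  sweep(eta, 2, 1 - s, "*") + sweep(1 - eta, 2, g, "*")
}

#' Fit the DINA model by EM
#'
#' Marginal-maximum-likelihood EM over all 2^K latent classes with an
#' unstructured class prior. Missing cells contribute nothing to the
#' likelihood (their item terms are skipped), so remaining `NA`s after a
#' threshold imputation are simply ignored. Estimates are clamped to
#' \[1e-4, 1 - 1e-4\] each M-step. Monotonicity (1 - s > g) is checked but
#' not enforced; violations are reported via `monotonicity_ok`.
#'
#' @param x response matrix over \{0, 1, NA\}; every item needs at least one
#'   observed cell.
#' @param q Q-matrix.
#' @param tol convergence tolerance on the largest absolute parameter change
#'   (default 1e-4).
#' @param max_iter maximum EM iterations (default 1000).
#' @return An object of class `dina_fit`: item parameters `s`, `g`, class
#'   `prior`, per-examinee `posterior`, `loglik_trace`, `converged`.
#' @export
fit_dina_em <- function(x, q, tol = 1e-4, max_iter = 1000) {
  x <- check_response_matrix(x)
  q <- check_q_matrix(q)
  if (ncol(x) != nrow(q)) stop("response matrix and Q-matrix disagree on J")
  n <- nrow(x); j <- ncol(x); k <- ncol(q)
  obs <- !is.na(x)
  if (any(colSums(obs) == 0)) stop("every item needs at least one observed cell")
  x1 <- (x == 1) & obs; x1[is.na(x1)] <- FALSE
  x0 <- (x == 0) & obs; x0[is.na(x0)] <- FALSE
  x1 <- x1 * 1; x0 <- x0 * 1

  degenerate <- vapply(seq_len(j), function(jj) {
    v <- x[obs[, jj], jj]; length(unique(v)) < 2
  }, logical(1))
  if (any(degenerate)) {
    warning(sprintf("%d item(s) have all-identical observed responses; estimates clamped",
                    sum(degenerate)))
  }

  patterns <- attribute_patterns(k)
  eta <- ideal_responses(patterns, q)    # C x J
  cc <- nrow(patterns)
  s <- rep(0.1, j); g <- rep(0.2, j)
  prior <- rep(1 / cc, cc)
  eps <- 1e-4
  loglik_trace <- numeric(0)
  converged <- FALSE

  for (it in seq_len(max_iter)) {
    p1 <- eta * (1 - s)[col(eta)] + (1 - eta) * g[col(eta)]  # C x J
    p1 <- clamp(p1, eps, 1 - eps)
    ll <- x1 %*% t(log(p1)) + x0 %*% t(log1p(-p1))           # N x C
    ll <- sweep(ll, 2, log(prior), "+")
    mx <- apply(ll, 1, max)
    w <- exp(ll - mx)
    rs <- rowSums(w)
    post <- w / rs
    loglik_trace <- c(loglik_trace, sum(mx + log(rs)))

    m_obs <- t(post) %*% obs             # C x J expected observed counts
    m_x1 <- t(post) %*% x1
    n1 <- colSums(eta * m_obs); r1 <- colSums(eta * m_x1)
    n0 <- colSums((1 - eta) * m_obs); r0 <- colSums((1 - eta) * m_x1)
    s_new <- clamp(ifelse(n1 > 0, 1 - r1 / n1, s), eps, 1 - eps)
    g_new <- clamp(ifelse(n0 > 0, r0 / n0, g), eps, 1 - eps)
    prior_new <- clamp(colMeans(post), eps, 1 - eps)
    prior_new <- prior_new / sum(prior_new)

    delta <- max(abs(c(s_new - s, g_new - g, prior_new - prior)))
    s <- s_new; g <- g_new; prior <- prior_new
    if (delta < tol) { converged <- TRUE; break }
  }

  # final posterior under the converged parameters
  p1 <- clamp(eta * (1 - s)[col(eta)] + (1 - eta) * g[col(eta)], eps, 1 - eps)
  ll <- x1 %*% t(log(p1)) + x0 %*% t(log1p(-p1))
  ll <- sweep(ll, 2, log(prior), "+")
  mx <- apply(ll, 1, max)
  w <- exp(ll - mx)
  post <- w / rowSums(w)

  mono_ok <- all(1 - s > g)
  if (!mono_ok) {
    warning("estimated parameters violate 1 - s > g for some item(s)")
  }
  structure(list(s = s, g = g, prior = prior, posterior = post,
                 patterns = patterns, eta = eta,
                 loglik_trace = loglik_trace, converged = converged,
                 monotonicity_ok = mono_ok, n_iter = length(loglik_trace)),
            class = "dina_fit")
}

#' @export
print.dina_fit <- function(x, ...) {
  cat(sprintf("DINA fit: %d items, %d attributes (%d classes)\n",
              length(x$s), ncol(x$patterns), nrow(x$patterns)))
  cat(sprintf("  EM %s after %d iterations, loglik %.3f\n",
              if (x$converged) "converged" else "did not converge",
              x$n_iter, tail(x$loglik_trace, 1)))
  cat(sprintf("  mean s = %.3f, mean g = %.3f\n", mean(x$s), mean(x$g)))
  invisible(x)
}

#' MAP attribute profiles
#'
#' Per examinee, the attribute pattern with maximal posterior probability.
#' Exact ties go to the lexicographically smallest pattern, so repeated runs
#' are deterministic. Examinees with no observed responses fall back to the
#' prior mode.
#'
#' @param fit a [fit_dina_em()] result.
#' @return An N x K binary matrix of MAP profiles.
#' @export
estimate_profiles_map <- function(fit) {
  stopifnot(inherits(fit, "dina_fit"))
  idx <- max.col(fit$posterior, ties.method = "first")
  fit$patterns[idx, , drop = FALSE]
}

#' @importFrom utils tail
NULL
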