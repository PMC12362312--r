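# Iterative random-forest imputation with dynamic dichotomization
# thresholds. Per missing cell the forest predicts a class-1 probability;
# probabilities at or above tau_u become 1, at or below tau_l become 0, and
# cells in between stay NA (high imputation uncertainty). The threshold
# pair is chosen by minimizing the mean adapted response conformity index
# (RCI_C-bar) of the imputed data under a DINA fit.
#
# A consequence of the chained-update scheme: the working matrix that feeds
# the forests always carries the 0.5-rounded probability for every missing
# cell (threshold-0 cells have p <= tau_l < 0.5 and threshold-1 cells have
# p >= tau_u >= 0.5, so rounding agrees with the mapped value, and
# threshold-NA cells carry the rounded probability by construction). The
# per-iteration probability trace is therefore identical for every
# threshold pair under the same seed, and the grid search computes it once.

#' Initial mean imputation
#'
#' Fills each missing cell with the item's observed mean rounded to 0/1
#' (mean >= 0.5 gives 1); the starting point of the iterative scheme.
#'
#' @param x response matrix over \{0, 1, NA\}.
#' @return A complete binary matrix; observed cells unchanged.
#' @export
initial_impute <- function(x) {
  x <- check_response_matrix(x)
  if (!anyNA(x)) return(x)
  means <- colMeans(x, na.rm = TRUE)
  if (anyNA(means)) stop("an item has no observed values")
  fill <- (means >= 0.5) * 1
  for (jj in which(colSums(is.na(x)) > 0)) {
    x[is.na(x[, jj]), jj] <- fill[jj]
  }
  x
}

#' Imputation order of the items
#'
#' Items with missing values sorted by ascending missing count (ties keep
#' the original column order); complete items are excluded.
#'
#' @param x response matrix.
#' @return An integer vector of column indices (possibly empty).
#' @export
order_variables <- function(x) {
  x <- check_response_matrix(x)
  counts <- colSums(is.na(x))
  idx <- which(counts > 0)
  idx[order(counts[idx])]
}

#' Map predicted probabilities to imputed values
#'
#' `1` when `p >= tau_u`, `0` when `p <= tau_l`, `NA` otherwise. The fixed
#' lower-threshold variant (RFTI) is the special case `tau_l = 0.5`, under
#' which `p = 0.5` maps to 0 (unless `tau_u = 0.5`, where the 1-branch is
#' checked first).
#'
#' @param p probability vector in \[0, 1\].
#' @param tau_l,tau_u lower and upper thresholds, `tau_l <= 0.5 <= tau_u`.
#' @return A vector over \{0, 1, NA\}.
#' @export
threshold_map <- function(p, tau_l, tau_u) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE), tau_l <= 0.5, tau_u >= 0.5)
  out <- rep(NA_real_, length(p))
  out[p >= tau_u] <- 1
  out[is.na(out) & p <= tau_l] <- 0
  out
}

#' Change fraction between successive imputations
#'
#' The fraction of originally-missing cells whose state in \{0, 1, NA\}
#' differs between two candidate imputations; the stopping statistic of the
#' iterative scheme.
#'
#' @param new,old matrices (or vectors) over \{0, 1, NA\} of equal shape.
#' @param mask logical matrix (or vector), TRUE at originally-missing cells.
#' @return A number in \[0, 1\].
#' @export
imputation_delta <- function(new, old, mask) {
  stopifnot(length(new) == length(old), length(new) == length(mask))
  n_cells <- sum(mask)
  if (n_cells == 0) stop("no originally-missing cells: nothing to impute")
  a <- new[mask]; b <- old[mask]
  changed <- (is.na(a) != is.na(b)) | (!is.na(a) & !is.na(b) & a != b)
  sum(changed) / n_cells
}

# ---------------------------------------------------------------------------
# Probability trace engine
# ---------------------------------------------------------------------------

# One chained pass over the incomplete items: train a forest per item on
# its originally-observed cells, predict the missing cells, update the
# working matrix column-by-column. Returns the probability matrix (values
# at originally-missing cells only) and the updated working matrix.
rf_single_pass <- function(x, mask, ord, working, item_seeds, n_trees, mtry) {
  if (is.null(colnames(working))) {
    colnames(working) <- paste0("V", seq_len(ncol(working)))
  }
  pm <- matrix(NA_real_, nrow(x), ncol(x))
  for (pos in seq_along(ord)) {
    s <- ord[pos]
    obs_rows <- which(!mask[, s])
    mis_rows <- which(mask[, s])
    y_obs <- x[obs_rows, s]
    if (length(unique(y_obs)) < 2) {
      p <- rep(y_obs[1], length(mis_rows))
    } else {
      fit <- ranger::ranger(
        x = working[obs_rows, -s, drop = FALSE],
        y = factor(y_obs, levels = c(0, 1)),
        num.trees = n_trees, mtry = mtry,
        num.threads = 1, seed = item_seeds[pos],
        respect.unordered.factors = FALSE)
      # class-1 probability = fraction of trees voting 1
      votes <- predict(fit, data = working[mis_rows, -s, drop = FALSE],
                       num.threads = 1, predict.all = TRUE)$predictions
      votes <- matrix(votes, nrow = length(mis_rows))
      p <- rowMeans(votes == 2L)   # level index 2 is class "1"
    }
    pm[mis_rows, s] <- p
    working[mis_rows, s] <- (p >= 0.5) * 1  # chained update
  }
  list(probs = pm, working = working)
}

#' One random-forest imputation pass
#'
#' Runs a single chained pass of the iterative scheme: per incomplete item
#' (ascending missingness), a classification forest is trained on the
#' item's originally-observed cells with the other items' current working
#' values as predictors, and each originally-missing cell receives the
#' fraction of trees voting for a correct response. The working matrix is
#' updated column-by-column with the 0.5-rounded probabilities.
#'
#' @param x the original response matrix over \{0, 1, NA\}.
#' @param working complete binary working matrix (defaults to
#'   [initial_impute()] of `x`).
#' @param rf_config forest options, see [iterate_impute()].
#' @param seed optional integer seed.
#' @return A list: `probs` (probabilities at the originally-missing cells,
#'   `NA` elsewhere) and `working` (the updated working matrix).
#' @export
rf_pass <- function(x, working = initial_impute(x), rf_config = list(),
                    seed = NULL) {
  x <- check_response_matrix(x)
  stopifnot(all(dim(working) == dim(x)), !anyNA(working))
  ord <- order_variables(x)
  with_optional_seed(seed, {
    rf_single_pass(x, is.na(x), ord, working,
                   item_seeds = sample.int(.Machine$integer.max,
                                           max(1, length(ord))),
                   n_trees = rf_config$num.trees %||% 100,
                   mtry = rf_config$mtry %||% max(1, floor(sqrt(ncol(x) - 1))))
  })
}

# Lazily extendable sequence of per-pass probability matrices. Forest seeds
# for all (pass, item) pairs are pre-drawn so extending the trace is
# deterministic. Must be created inside the caller's seed scope.
rf_trace <- function(x, rf_config) {
  mask <- is.na(x)
  ord <- order_variables(x)
  n_trees <- rf_config$num.trees %||% 100
  max_iter <- rf_config$max_iter %||% 10
  mtry <- rf_config$mtry %||% max(1, floor(sqrt(ncol(x) - 1)))
  seeds <- matrix(sample.int(.Machine$integer.max, max_iter * max(1, length(ord))),
                  nrow = max_iter)
  env <- new.env(parent = emptyenv())
  env$working <- initial_impute(x)
  env$probs <- list()

  env$get <- function(i) {
    while (length(env$probs) < i) {
      pass <- length(env$probs) + 1L
      step <- rf_single_pass(x, mask, ord, env$working, seeds[pass, ],
                             n_trees, mtry)
      env$working <- step$working
      env$probs[[pass]] <- step$probs
    }
    env$probs[[i]]
  }
  env
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run the threshold mapping + Delta stopping rule along a probability
# trace. Returns the chosen candidate states at the masked cells, the
# iteration it came from, and the Delta trace.
run_threshold_path <- function(trace, x, mask_idx, init_states, tau_l, tau_u,
                               max_iter) {
  old <- init_states
  prev_cand <- NULL
  prev_delta <- Inf
  deltas <- numeric(0)
  for (i in seq_len(max_iter)) {
    p <- trace$get(i)[mask_idx]
    cand <- threshold_map(p, tau_l, tau_u)
    d <- imputation_delta(cand, old, rep(TRUE, length(cand)))
    deltas <- c(deltas, d)
    if (d == 0) {
      return(list(states = cand, iteration = i, deltas = deltas))
    }
    if (i >= 2 && d > prev_delta) {
      return(list(states = prev_cand, iteration = i - 1L, deltas = deltas))
    }
    prev_cand <- cand
    prev_delta <- d
    old <- cand
  }
  list(states = prev_cand %||% cand, iteration = max_iter, deltas = deltas)
}

#' Iterative random-forest imputation at a fixed threshold pair
#'
#' Starting from the mean-imputed matrix, each pass trains one
#' classification forest per incomplete item (observed cells as response,
#' the other items' current working values as predictors, updated
#' column-by-column within the pass) and maps the predicted probabilities
#' of the originally-missing cells through [threshold_map()]. Iteration
#' stops when the change fraction Delta first increases (the previous
#' candidate is returned), when Delta reaches 0, or at `max_iter`.
#'
#' @param x response matrix with at least one `NA`.
#' @param tau_l,tau_u the threshold pair.
#' @param rf_config list of forest options: `num.trees` (default 100),
#'   `mtry` (default floor(sqrt(J - 1))), `max_iter` (default 10).
#' @param seed optional integer seed.
#' @return The matrix with originally-missing cells imputed to \{0, 1, NA\};
#'   observed cells unchanged.
#' @export
iterate_impute <- function(x, tau_l, tau_u, rf_config = list(), seed = NULL) {
  x <- check_response_matrix(x)
  if (!anyNA(x)) stop("x has no missing cells")
  with_optional_seed(seed, {
    trace <- rf_trace(x, rf_config)
    mask_idx <- which(is.na(x))
    init <- initial_impute(x)[mask_idx]
    path <- run_threshold_path(trace, x, mask_idx, init, tau_l, tau_u,
                               rf_config$max_iter %||% 10)
    out <- x
    out[mask_idx] <- path$states
    out
  })
}

# ---------------------------------------------------------------------------
# Adapted response conformity person-fit index
# ---------------------------------------------------------------------------

#' Per-person adapted response conformity index
#'
#' For each examinee, the mean over their nonmissing items of the absolute
#' log discrepancy between the (observed or imputed) response and the ideal
#' response of the estimated profile: items where the response matches the
#' ideal response contribute 0; a 1 where the ideal response is 0
#' contributes |ln((1 - P)/P)| and a 0 where it is 1 contributes
#' |ln(P/(1 - P))|, with P the DINA correct-response probability of the
#' estimated profile (clamped away from 0 and 1 for the logs).
#'
#' @param y response matrix over \{0, 1, NA\} (observed plus imputed).
#' @param profiles N x K matrix of estimated attribute profiles.
#' @param q Q-matrix.
#' @param s,g estimated item parameters.
#' @return A list: `rci` (per-person values, `NA` for persons with no
#'   nonmissing item), `m` (nonmissing counts).
#' @export
rci_c <- function(y, profiles, q, s, g) {
  y <- check_response_matrix(y)
  q <- check_q_matrix(q)
  stopifnot(nrow(profiles) == nrow(y), ncol(profiles) == ncol(q),
            length(s) == nrow(q), length(g) == nrow(q))
  eta <- ideal_responses(profiles, q)                       # N x J ideal
  p <- clamp(dina_probabilities(profiles, q, s, g), 1e-6, 1 - 1e-6)
  contrib <- matrix(0, nrow(y), ncol(y))
  i10 <- !is.na(y) & y == 1 & eta == 0
  i01 <- !is.na(y) & y == 0 & eta == 1
  contrib[i10] <- abs(log((1 - p[i10]) / p[i10]))
  contrib[i01] <- abs(log(p[i01] / (1 - p[i01])))
  m <- rowSums(!is.na(y))
  if (any(m == 0)) {
    warning("examinee(s) with no nonmissing item excluded from RCI")
  }
  rci <- ifelse(m > 0, rowSums(contrib) / m, NA_real_)
  list(rci = rci, m = m)
}

#' Mean adapted response conformity index
#'
#' Arithmetic mean of the per-person values over examinees with at least
#' one nonmissing item; the quantity minimized by the threshold search.
#'
#' @param rci per-person values (persons with `NA` are excluded).
#' @return A single nonnegative number.
#' @export
rci_c_mean <- function(rci) {
  v <- rci[!is.na(rci)]
  if (length(v) == 0) stop("no examinee with a nonmissing item")
  mean(v)
}

# ---------------------------------------------------------------------------
# Threshold grid search
# ---------------------------------------------------------------------------

#' Threshold grid
#'
#' Candidate threshold pairs spaced by `step`: lower thresholds
#' `step, 2 step, ...` strictly below 0.5 and upper thresholds from 0.5 up
#' to but excluding 1. The RFTI grid fixes the lower threshold at 0.5.
#'
#' @param step grid increment (default 0.05).
#' @param mode `"RFDTI"` (both thresholds dynamic) or `"RFTI"`.
#' @return A data frame with columns `tau_l` and `tau_u`.
#' @export
threshold_grid <- function(step = 0.05, mode = c("RFDTI", "RFTI")) {
  mode <- match.arg(mode)
  stopifnot(step > 0, step < 0.5)
  tau_u <- seq(0.5, 1 - 1e-9, by = step)
  tau_u <- tau_u[tau_u < 1]
  tau_l <- if (mode == "RFTI") 0.5 else {
    v <- seq(step, 0.5 - 1e-9, by = step)
    v[v < 0.5]
  }
  grid <- expand.grid(tau_l = tau_l, tau_u = tau_u, KEEP.OUT.ATTRS = FALSE)
  grid[order(grid$tau_l, grid$tau_u), , drop = FALSE]
}

#' Select the optimal threshold pair
#'
#' For every pair in the grid, runs the iterative forest imputation (the
#' probability trace is shared across pairs, which is exactly equivalent to
#' running each pair separately under the same seed), fits the DINA model
#' to the imputed matrix (remaining `NA`s ignored), classifies examinees by
#' MAP, and scores the imputation by the mean adapted response conformity
#' index. The pair with the smallest index wins; ties prefer the smaller
#' remaining missing rate, then the larger `tau_l`, then the smaller
#' `tau_u`.
#'
#' @param x response matrix with missing cells.
#' @param q Q-matrix.
#' @param grid a [threshold_grid()] data frame.
#' @param rf_config forest options, see [iterate_impute()].
#' @param seed optional integer seed.
#' @param dina_tol,dina_max_iter EM settings for the per-pair DINA refits.
#' @return An object of class `rf_imputation`: `imputed` matrix,
#'   `thresholds`, `rci_mean`, `remaining_missing_rate`, `grid_table`.
#' @export
select_thresholds <- function(x, q, grid, rf_config = list(), seed = NULL,
                              dina_tol = 1e-4, dina_max_iter = 1000) {
  x <- check_response_matrix(x)
  q <- check_q_matrix(q)
  if (!anyNA(x)) stop("x has no missing cells")
  max_iter <- rf_config$max_iter %||% 10

  with_optional_seed(seed, {
    trace <- rf_trace(x, rf_config)
    mask_idx <- which(is.na(x))
    init <- initial_impute(x)[mask_idx]

    cache <- new.env(parent = emptyenv())   # DINA/RCI results per candidate
    rows <- vector("list", nrow(grid))
    best <- NULL
    for (r in seq_len(nrow(grid))) {
      tl <- grid$tau_l[r]; tu <- grid$tau_u[r]
      path <- run_threshold_path(trace, x, mask_idx, init, tl, tu, max_iter)
      key <- paste(ifelse(is.na(path$states), "N", path$states), collapse = "")
      res <- cache[[key]]
      if (is.null(res)) {
        imp <- x
        imp[mask_idx] <- path$states
        res <- tryCatch({
          fit <- suppressWarnings(fit_dina_em(imp, q, tol = dina_tol,
                                              max_iter = dina_max_iter))
          prof <- estimate_profiles_map(fit)
          rci <- rci_c(imp, prof, q, fit$s, fit$g)
          list(ok = TRUE, rci_mean = rci_c_mean(rci$rci),
               remaining = mean(is.na(imp)), imputed = imp)
        }, error = function(e) list(ok = FALSE, msg = conditionMessage(e)))
        cache[[key]] <- res
      }
      if (!res$ok) {
        warning(sprintf("DINA fit failed for (tau_l=%.2f, tau_u=%.2f): %s",
                        tl, tu, res$msg))
        rows[[r]] <- data.frame(tau_l = tl, tau_u = tu, rci_mean = NA_real_,
                                remaining_missing_rate = NA_real_,
                                n_iterations = path$iteration, failed = TRUE)
        next
      }
      rows[[r]] <- data.frame(tau_l = tl, tau_u = tu, rci_mean = res$rci_mean,
                              remaining_missing_rate = res$remaining,
                              n_iterations = path$iteration, failed = FALSE)
      cand <- list(tau_l = tl, tau_u = tu, rci_mean = res$rci_mean,
                   remaining = res$remaining, imputed = res$imputed)
      if (is.null(best) || better_threshold(cand, best)) best <- cand
    }
    if (is.null(best)) stop("DINA estimation failed for every threshold pair")
    grid_table <- do.call(rbind, rows)
    structure(list(imputed = best$imputed,
                   thresholds = c(tau_l = best$tau_l, tau_u = best$tau_u),
                   rci_mean = best$rci_mean,
                   remaining_missing_rate = best$remaining,
                   grid_table = grid_table),
              class = "rf_imputation")
  })
}

# Ordering on grid candidates: smaller RCI mean, then smaller remaining
# missing rate, then larger tau_l, then smaller tau_u.
better_threshold <- function(a, b) {
  if (a$rci_mean != b$rci_mean) return(a$rci_mean < b$rci_mean)
  if (a$remaining != b$remaining) return(a$remaining < b$remaining)
  if (a$tau_l != b$tau_l) return(a$tau_l > b$tau_l)
  a$tau_u < b$tau_u
}

#' Random forest dynamic threshold imputation (RFDTI)
#'
#' Builds the dynamic grid over both thresholds from `stepV` and selects
#' the pair minimizing the mean adapted response conformity index.
#'
#' @param x response matrix with missing cells.
#' @param q Q-matrix.
#' @param stepV grid increment (default 0.05).
#' @param rf_config forest options, see [iterate_impute()].
#' @param seed optional integer seed.
#' @return An `rf_imputation` object; see [select_thresholds()].
#' @export
rfdti <- function(x, q, stepV = 0.05, rf_config = list(), seed = NULL) {
  select_thresholds(x, q, threshold_grid(stepV, "RFDTI"), rf_config, seed)
}

#' Random forest threshold imputation (RFTI)
#'
#' The fixed-lower-threshold predecessor of [rfdti()]: `tau_l` is pinned at
#' 0.5 (every probability at or below 0.5 becomes 0) and only the upper
#' threshold is searched.
#'
#' @inheritParams rfdti
#' @export
rfti <- function(x, q, stepV = 0.05, rf_config = list(), seed = NULL) {
  select_thresholds(x, q, threshold_grid(stepV, "RFTI"), rf_config, seed)
}

#' @export
print.rf_imputation <- function(x, ...) {
  cat(sprintf("Random-forest threshold imputation: tau_l = %.2f, tau_u = %.2f\n",
              x$thresholds["tau_l"], x$thresholds["tau_u"]))
  cat(sprintf("  RCI_C mean %.4f, remaining missing rate %.2f%% (grid of %d pairs)\n",
              x$rci_mean, 100 * x$remaining_missing_rate, nrow(x$grid_table)))
  invisible(x)
}
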