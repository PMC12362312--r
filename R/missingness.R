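# Missingness generators: MCAR, MAR, MNAR and MIXED mechanisms imposed on a
# complete response matrix, restricted to a random subsample of examinees so
# some examinees keep complete records (which helps train the forests).

#' Seven-fractile MAR scheme
#'
#' The ability-proxy distribution is split at the 5th, 15th, 30th, 70th,
#' 85th and 95th percentiles; each fractile's deletion rate is the target
#' missing rate times its multiplier. The fractile widths dotted with the
#' multipliers equal 1 exactly, so the average rate stays at the target.
#'
#' @return A list with `breaks`, `multipliers` and `weights`.
#' @export
mar_scheme <- function() {
  list(breaks = c(0.05, 0.15, 0.30, 0.70, 0.85, 0.95),
       multipliers = c(1.50, 1.35, 1.15, 1.00, 0.85, 0.65, 0.50),
       weights = c(0.05, 0.10, 0.15, 0.40, 0.15, 0.10, 0.05))
}

#' Select the examinee subsample that receives missingness
#'
#' @param n number of examinees.
#' @param fraction subsample fraction (default 0.8).
#' @param seed optional integer seed.
#' @return A sorted integer vector of floor(fraction * n) distinct indices.
#' @export
select_subsample <- function(n, fraction = 0.8, seed = NULL) {
  stopifnot(n >= 1, fraction > 0, fraction <= 1)
  m <- floor(fraction * n)
  with_optional_seed(seed, sort(sample.int(n, m)))
}

#' Impose MCAR missingness
#'
#' Each cell of each subsampled examinee is deleted independently with
#' probability `mr`; rows outside the subsample stay complete.
#'
#' @param x complete binary response matrix.
#' @param mr target missing proportion in (0, 1), relative to the
#'   subsample's cells.
#' @param subsample integer row indices receiving missingness.
#' @param seed optional integer seed.
#' @return The matrix with `NA`s inserted.
#' @export
apply_mcar <- function(x, mr, subsample, seed = NULL) {
  x <- check_response_matrix(x, require_complete = TRUE)
  if (mr <= 0 || mr >= 1) stop("mr must lie strictly inside (0, 1)")
  with_optional_seed(seed, {
    for (i in subsample) {
      drop <- runif(ncol(x)) < mr
      x[i, drop] <- NA
    }
    x
  })
}

# Fractile index (1..7) for each score given percentile breaks computed on
# `scores`; a score equal to a break goes to the higher fractile.
assign_fractiles <- function(scores, breaks) {
  if (length(unique(scores)) == 1) {
    warning("degenerate ability proxy (all scores equal); middle fractile used")
    return(rep(4L, length(scores)))
  }
  z <- (scores - mean(scores)) / stats::sd(scores)  # order-preserving
  cuts <- stats::quantile(z, probs = breaks, names = FALSE, type = 7)
  idx <- rep(1L, length(z))
  for (b in cuts) idx <- idx + (z >= b)
  idx
}

#' Impose MAR missingness
#'
#' For each target item the ability proxy is the examinee's number-correct
#' score on all other items. Subsampled examinees are assigned to seven
#' fractiles by percentiles of the (standardized) proxy, and each cell is
#' deleted with probability `mr` times the fractile multiplier, so
#' lower-scoring examinees omit more.
#'
#' @inheritParams apply_mcar
#' @param scheme a [mar_scheme()] list.
#' @export
apply_mar <- function(x, mr, subsample, scheme = mar_scheme(), seed = NULL) {
  x <- check_response_matrix(x, require_complete = TRUE)
  if (mr <= 0 || mr >= 1) stop("mr must lie strictly inside (0, 1)")
  out <- x
  total <- rowSums(x)
  with_optional_seed(seed, {
    for (jj in seq_len(ncol(x))) {
      proxy <- total[subsample] - x[subsample, jj]
      frac <- assign_fractiles(proxy, scheme$breaks)
      rate <- clamp(mr * scheme$multipliers[frac], 0, 1)
      drop <- runif(length(subsample)) < rate
      out[subsample[drop], jj] <- NA
    }
    out
  })
}

# Choose which items an examinee omits: draw uniforms, delete where
# u > p + eps; adjust eps until exactly `target` items are deleted.
mnar_select_items <- function(p_row, target, step = 0.01, max_rounds = 1e4) {
  j <- length(p_row)
  if (target == 0) return(integer(0))
  if (target >= j) return(seq_len(j))
  eps <- 0
  for (round in seq_len(max_rounds)) {
    drop <- runif(j) > p_row + eps
    d <- sum(drop)
    if (d == target) return(which(drop))
    # too many omissions -> raise eps (deletion less likely), too few -> lower
    eps <- eps + if (d > target) step else -step
  }
  stop("MNAR epsilon adjustment did not reach the target count")
}

#' Impose MNAR missingness
#'
#' Per subsampled examinee the omission count is `round(mr * J)`. Items are
#' deleted when a uniform draw exceeds the examinee's correct-response
#' probability plus an offset epsilon (initially 0) that is adjusted by
#' `step` and the draws regenerated until the omission count matches the
#' target exactly, so harder items (low p) are omitted more often.
#'
#' @inheritParams apply_mcar
#' @param p_true N x J matrix of correct-response probabilities from the
#'   generating model.
#' @param step epsilon adjustment increment (default 0.01).
#' @export
apply_mnar <- function(x, mr, subsample, p_true, step = 0.01, seed = NULL) {
  x <- check_response_matrix(x, require_complete = TRUE)
  if (mr <= 0 || mr >= 1) stop("mr must lie strictly inside (0, 1)")
  stopifnot(all(dim(p_true) == dim(x)))
  target <- round_half_up(mr * ncol(x))
  with_optional_seed(seed, {
    for (i in subsample) {
      x[i, mnar_select_items(p_true[i, ], target, step)] <- NA
    }
    x
  })
}

#' Impose MIXED missingness
#'
#' Per-examinee omission counts come from the MAR fractile scheme (proxy =
#' total number-correct score): `round(mr * multiplier * J)`. Which items
#' are omitted is then decided by the MNAR epsilon procedure, so the
#' mechanism mixes ability-dependent volume with difficulty-dependent item
#' selection.
#'
#' @inheritParams apply_mnar
#' @param scheme a [mar_scheme()] list.
#' @export
apply_mixed <- function(x, mr, subsample, p_true, scheme = mar_scheme(),
                        step = 0.01, seed = NULL) {
  x <- check_response_matrix(x, require_complete = TRUE)
  if (mr <= 0 || mr >= 1) stop("mr must lie strictly inside (0, 1)")
  stopifnot(all(dim(p_true) == dim(x)))
  with_optional_seed(seed, {
    frac <- assign_fractiles(rowSums(x)[subsample], scheme$breaks)
    counts <- round_half_up(mr * scheme$multipliers[frac] * ncol(x))
    counts <- pmin(counts, ncol(x))
    for (ii in seq_along(subsample)) {
      i <- subsample[ii]
      x[i, mnar_select_items(p_true[i, ], counts[ii], step)] <- NA
    }
    x
  })
}

#' Apply a missingness mechanism by name
#'
#' Convenience dispatcher used by the simulation driver.
#'
#' @inheritParams apply_mnar
#' @param mechanism one of "MCAR", "MAR", "MNAR", "MIXED".
#' @param fraction subsample fraction (default 0.8).
#' @export
apply_missingness <- function(x, mechanism, mr, p_true = NULL, fraction = 0.8,
                              seed = NULL) {
  mechanism <- match.arg(toupper(mechanism), c("MCAR", "MAR", "MNAR", "MIXED"))
  with_optional_seed(seed, {
    sub <- select_subsample(nrow(x), fraction)
    switch(mechanism,
      MCAR = apply_mcar(x, mr, sub),
      MAR = apply_mar(x, mr, sub),
      MNAR = apply_mnar(x, mr, sub, p_true),
      MIXED = apply_mixed(x, mr, sub, p_true))
  })
}
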