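# Internal helpers shared across modules.

# Clamp values into [lo, hi].
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Round half away from zero (base round() is half-to-even); used for
# omission counts and for dichotomizing imputed expectations.
round_half_up <- function(x) floor(x + 0.5)

# Run `expr` under a fixed seed without disturbing the caller's RNG state;
# when seed is NULL, use the session RNG as-is (standard R convention).
with_optional_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# Deterministic 32-bit child seed from a master seed and integer tags, so
# each simulation component gets its own reproducible stream.
child_seed <- function(seed, ...) {
  h <- as.double(seed) %% 2147483647
  for (v in c(...)) {
    h <- (h * 31 + (as.double(v) %% 2147483647)) %% 2147483647
  }
  as.integer(h) + 1L
}

# Validate a response matrix: numeric N x J over {0, 1, NA}.
check_response_matrix <- function(x, require_complete = FALSE) {
  if (!is.matrix(x)) x <- as.matrix(x)
  storage.mode(x) <- "double"
  vals <- x[!is.na(x)]
  if (length(vals) && !all(vals %in% c(0, 1))) {
    stop("response matrix must contain only 0, 1 and NA")
  }
  if (require_complete && anyNA(x)) {
    stop("a complete response matrix (no NA) is required here")
  }
  x
}

# Validate a Q-matrix: J x K binary, no all-zero row or column.
check_q_matrix <- function(q) {
  if (!is.matrix(q)) q <- as.matrix(q)
  storage.mode(q) <- "double"
  if (anyNA(q) || !all(q %in% c(0, 1))) stop("Q-matrix entries must be 0 or 1")
  if (any(rowSums(q) == 0)) stop("Q-matrix has an item measuring no attribute")
  if (any(colSums(q) == 0)) stop("Q-matrix has an attribute measured by no item")
  q
}

# Missingness mask (TRUE where NA).
na_mask <- function(x) is.na(x)

# Proportion of NA cells over the whole matrix.
#' Remaining missing rate of a response matrix
#'
#' Proportion of cells that are `NA`, relative to all `N x J` cells. After a
#' threshold-based imputation this is the share of deliberately un-imputed
#' low-certainty cells.
#'
#' @param x response matrix over \{0, 1, NA\}.
#' @return A proportion in \[0, 1\].
#' @export
remaining_missing_rate <- function(x) {
  x <- check_response_matrix(x)
  mean(is.na(x))
}
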