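# Fixture builders shared across test files. Everything is generated in
# code under fixed seeds; no stored data.

# Complete DINA dataset with known truth. An identity submatrix is embedded
# in Q so the attribute classes are identifiable in the noiseless limit.
make_dina_data <- function(n = 300, j = 30, k = 3, seed = 1, s = NULL,
                           g = NULL, rho = 0.5, identifiable = TRUE) {
  q <- generate_q_matrix(j, k, seed = seed + 1)
  if (identifiable) q[seq_len(k), ] <- diag(k)
  profiles <- simulate_attribute_profiles(n, k, rho = rho, seed = seed + 2)
  if (is.null(s) || is.null(g)) {
    pars <- simulate_item_params(j, seed = seed + 3)
    if (is.null(s)) s <- pars$s
    if (is.null(g)) g <- pars$g
  }
  x <- simulate_dina_responses(profiles, q, s, g, seed = seed + 4)
  list(q = q, profiles = profiles, s = s, g = g, x = x,
       p = dina_probabilities(profiles, q, s, g))
}

# One incomplete dataset under a named mechanism.
make_missing_data <- function(mechanism = "MCAR", mr = 0.1, n = 300, j = 30,
                              k = 3, seed = 1) {
  d <- make_dina_data(n, j, k, seed)
  d$x_miss <- apply_missingness(d$x, mechanism, mr, p_true = d$p,
                                seed = seed + 5)
  d
}

# Brute-force threshold mapping oracle: a scalar loop written independently
# of the vectorized implementation.
naive_threshold_map <- function(p, tau_l, tau_u) {
  vapply(p, function(pp) {
    if (pp >= tau_u) 1 else if (pp <= tau_l) 0 else NA_real_
  }, numeric(1))
}

# Brute-force state-change counter for the Delta statistic.
naive_delta <- function(new, old, mask) {
  cells <- which(mask)
  changed <- 0
  for (idx in cells) {
    a <- new[idx]; b <- old[idx]
    same <- (is.na(a) && is.na(b)) || (!is.na(a) && !is.na(b) && a == b)
    if (!same) changed <- changed + 1
  }
  changed / length(cells)
}

# Brute-force conjunctive ideal response.
naive_eta <- function(profile, q_row) {
  out <- 1
  for (kk in seq_along(q_row)) {
    if (q_row[kk] == 1 && profile[kk] == 0) out <- 0
  }
  out
}
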