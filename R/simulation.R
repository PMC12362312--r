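# Factorial simulation driver: generate DINA data, impose a missingness
# mechanism, impute with each requested method, refit the DINA model and
# score attribute classification against the generating truth.

#' Impute a single dataset with a named method
#'
#' Dispatcher over the six implemented methods. For `"mi"` the pooled
#' metrics are computed downstream by averaging over the completed
#' datasets; here the full [impute_mi()] result is returned.
#'
#' @param x response matrix with missing cells.
#' @param q Q-matrix (needed by the threshold methods).
#' @param method one of "rfdti", "rfti", "pm", "tw", "em", "mi".
#' @param stepV threshold grid increment (default 0.05).
#' @param rf_config forest options, see [iterate_impute()].
#' @param m number of MI datasets (default 20).
#' @param seed optional integer seed.
#' @return A complete or partially-imputed matrix; an `rf_imputation`
#'   object for the threshold methods; an `mi_result` for MI.
#' @export
impute_method <- function(x, q = NULL, method, stepV = 0.05,
                          rf_config = list(), m = 20, seed = NULL) {
  method <- match.arg(tolower(method),
                      c("rfdti", "rfti", "pm", "tw", "em", "mi"))
  if (method %in% c("rfdti", "rfti") && is.null(q)) {
    stop("the threshold methods require a Q-matrix")
  }
  switch(method,
    rfdti = rfdti(x, q, stepV, rf_config, seed),
    rfti = rfti(x, q, stepV, rf_config, seed),
    pm = impute_pm(x),
    tw = impute_tw(x),
    em = impute_em(x),
    mi = impute_mi(x, m = m, seed = seed))
}

#' Simulation configuration
#'
#' @param mechanisms subset of MCAR, MAR, MNAR, MIXED.
#' @param proportions missingness proportions.
#' @param sample_sizes examinee counts.
#' @param n_attributes attribute counts.
#' @param n_items test length (default 30).
#' @param replications replications per condition (default 100).
#' @param methods imputation methods to compare.
#' @param stepV threshold grid increment.
#' @param rf_config forest options.
#' @param mi_m number of MI datasets.
#' @param master_seed master seed for the whole study.
#' @return A `sim_config` list.
#' @export
sim_config <- function(mechanisms = c("MCAR", "MAR", "MNAR", "MIXED"),
                       proportions = seq(0.1, 0.5, by = 0.1),
                       sample_sizes = c(500, 1000, 2000),
                       n_attributes = 3:8,
                       n_items = 30,
                       replications = 100,
                       methods = c("rfdti", "rfti", "pm", "tw", "em", "mi"),
                       stepV = 0.05,
                       rf_config = list(),
                       mi_m = 20,
                       master_seed = 1L) {
  structure(list(mechanisms = toupper(mechanisms), proportions = proportions,
                 sample_sizes = sample_sizes, n_attributes = n_attributes,
                 n_items = n_items, replications = replications,
                 methods = tolower(methods), stepV = stepV,
                 rf_config = rf_config, mi_m = mi_m,
                 master_seed = as.integer(master_seed)),
            class = "sim_config")
}

# Score one imputed matrix: refit DINA, MAP-classify, compare to truth.
score_imputed <- function(imp, q, truth) {
  fit <- suppressWarnings(fit_dina_em(imp, q))
  prof <- estimate_profiles_map(fit)
  list(pca = pattern_accuracy(prof, truth),
       aca = attribute_accuracy(prof, truth),
       remaining = mean(is.na(imp)),
       converged = fit$converged)
}

#' Run one replication of one condition
#'
#' Generates a Q-matrix, attribute profiles, item parameters and complete
#' responses; imposes the condition's missingness; imputes with each
#' requested method; refits the DINA model per imputed dataset and scores
#' classification accuracy against the generating profiles. A method
#' failure marks that method non-converged rather than aborting the run.
#' Child seeds are derived deterministically per component, so adding a
#' method does not perturb the others' randomness.
#'
#' @param cfg a [sim_config()].
#' @param mechanism,mr,n,k the condition.
#' @param rep_index replication number.
#' @return A data frame with one row per method.
#' @export
run_condition <- function(cfg, mechanism, mr, n, k, rep_index = 1) {
  mech_id <- match(toupper(mechanism), c("MCAR", "MAR", "MNAR", "MIXED"))
  cond <- c(mech_id, round(100 * mr), n, k, rep_index)
  seed_for <- function(tag) child_seed(cfg$master_seed, cond, tag)

  q <- generate_q_matrix(cfg$n_items, k, seed = seed_for(1))
  profiles <- simulate_attribute_profiles(n, k, rho = 0.5, seed = seed_for(2))
  pars <- simulate_item_params(cfg$n_items, seed = seed_for(3))
  x_full <- simulate_dina_responses(profiles, q, pars$s, pars$g,
                                    seed = seed_for(4))
  p_true <- dina_probabilities(profiles, q, pars$s, pars$g)
  x_miss <- apply_missingness(x_full, mechanism, mr, p_true = p_true,
                              seed = seed_for(5))

  rows <- lapply(seq_along(cfg$methods), function(mi) {
    method <- cfg$methods[mi]
    res <- tryCatch({
      imp <- impute_method(x_miss, q, method, stepV = cfg$stepV,
                           rf_config = cfg$rf_config, m = cfg$mi_m,
                           seed = seed_for(10 + mi))
      if (inherits(imp, "mi_result")) {
        scores <- lapply(imp$datasets, score_imputed, q = q, truth = profiles)
        list(pca = mean(vapply(scores, `[[`, 0, "pca")),
             aca = mean(vapply(scores, `[[`, 0, "aca")),
             remaining = 0,
             converged = all(vapply(scores, `[[`, TRUE, "converged")))
      } else {
        if (inherits(imp, "rf_imputation")) imp <- imp$imputed
        score_imputed(imp, q, profiles)
      }
    }, error = function(e) list(pca = NA_real_, aca = NA_real_,
                                remaining = NA_real_, converged = FALSE))
    data.frame(mechanism = toupper(mechanism), mr = mr, n = n, k = k,
               method = method, replication = rep_index,
               pca = res$pca, aca = res$aca,
               remaining_missing_rate = res$remaining,
               converged = res$converged)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run a (sub-)grid of simulation conditions
#'
#' @param cfg a [sim_config()].
#' @param verbose print progress per condition.
#' @return A tidy data frame: one row per condition x method x replication.
#' @export
run_simulation <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "sim_config"))
  out <- list()
  for (mech in cfg$mechanisms) for (mr in cfg$proportions)
    for (n in cfg$sample_sizes) for (k in cfg$n_attributes) {
      if (verbose) {
        message(sprintf("condition %s mr=%.2f n=%d k=%d", mech, mr, n, k))
      }
      for (r in seq_len(cfg$replications)) {
        out[[length(out) + 1]] <- run_condition(cfg, mech, mr, n, k, r)
      }
    }
  do.call(rbind, out)
}

#' Aggregate replication-level results
#'
#' Means over converged replications, keyed by mechanism, proportion and
#' method.
#'
#' @param results output of [run_simulation()] (or rbind-ed
#'   [run_condition()] rows).
#' @return A data frame of condition-level means with a replication count
#'   column `r_converged`.
#' @export
aggregate_results <- function(results) {
  ok <- results[results$converged & !is.na(results$pca), , drop = FALSE]
  agg <- aggregate(cbind(pca, aca, remaining_missing_rate) ~
                     mechanism + mr + method, data = ok, FUN = mean)
  cnt <- aggregate(cbind(r_converged = pca) ~ mechanism + mr + method,
                   data = ok, FUN = length)
  merge(agg, cnt, by = c("mechanism", "mr", "method"))
}
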