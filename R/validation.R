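#' Parametric bootstrap of the maximum-likelihood machinery
#'
#' Simulates `n_datasets` islands under known ("generating") parameters,
#' refits the model to each, and summarises bias and precision of the
#' estimators, including derived quantities such as per-class net
#' diversification `lambda_c - mu`.  The headline precision analysis uses
#' 2000 replicates ("full scale"); a 50-replicate desk preset is the
#' default.
#'
#' @param model a [model_spec()].
#' @param generating_params named list of [parameter_set()] per class used
#'   to simulate.
#' @param M,class_fractions,island_age design of the simulated datasets.
#' @param n_datasets number of simulated datasets (default 50).
#' @param n_starts optimisation starts per refit.
#' @param seed integer seed; replicate r uses sub-seed `seed + r`, so the
#'   report is invariant to execution order.
#' @param maxit simplex iteration cap per start.
#' @param condition optional acceptance predicate for the simulated
#'   datasets (see [condition_n_colonisations()]); rejected simulations are
#'   re-drawn.  The refit likelihood is not conditioned, matching the way
#'   the model is fitted to real data.
#' @return an object of class `bootstrap_report`: `estimates` (one row per
#'   refitted replicate), `medians`, `intervals` (2.5/97.5 percentiles),
#'   `bias` (median minus truth), `truth`, `failures`, and an `unreliable`
#'   flag when more than 20 percent of refits failed.
#' @export
bootstrap_fit <- function(model, generating_params, M,
                          class_fractions = c(all = 1), island_age,
                          n_datasets = 50L, n_starts = 10L, seed = 1L,
                          maxit = 500L, condition = NULL) {
  stopifnot(n_datasets >= 1)
  layout <- param_layout(model)
  pnames <- vapply(layout, `[[`, "", "name")
  truth <- truth_vector(model, generating_params)
  rows <- vector("list", n_datasets)
  failures <- character()
  for (r in seq_len(n_datasets)) {
    d <- if (is.null(condition))
      simulate_island(generating_params, M, class_fractions, island_age,
                      seed = seed + r)$dataset
    else
      simulate_ensemble(generating_params, M, class_fractions, island_age,
                        n_replicates = 1L, condition = condition,
                        seed = seed + r)$outcomes[[1]]$dataset
    fit <- tryCatch(fit_model(d, model, n_starts = n_starts,
                              seed = seed + 100000L + r, maxit = maxit),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      failures <- c(failures, sprintf("replicate %d: %s", r,
                                      conditionMessage(fit)))
      next
    }
    rows[[r]] <- c(replicate = r, fit$estimates[pnames],
                   loglik = fit$loglik)
  }
  est <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  est <- as.data.frame(est)
  est <- add_derived_net_div(est, model)
  stats_cols <- setdiff(names(est), c("replicate", "loglik"))
  medians <- vapply(est[stats_cols], median, numeric(1))
  intervals <- t(vapply(est[stats_cols], quantile, numeric(2),
                        probs = c(0.025, 0.975)))
  truth_all <- c(truth, derived_truth_net_div(model, truth))
  structure(list(
    model = model, truth = truth_all, n_datasets = n_datasets,
    estimates = est, medians = medians, intervals = intervals,
    bias = medians - truth_all[names(medians)],
    failures = failures,
    unreliable = length(failures) > 0.2 * n_datasets),
    class = "bootstrap_report")
}

truth_vector <- function(model, params_by_class) {
  layout <- param_layout(model)
  vapply(layout, function(row) {
    cl <- row$classes[[1]][1]
    params_by_class[[cl]][[row$par]]
  }, numeric(1), USE.NAMES = FALSE) |>
    setNames(vapply(layout, `[[`, "", "name"))
}

# per-class net diversification columns where both rates exist in the table
add_derived_net_div <- function(est, model) {
  for (cl in model$classes) {
    lc <- intersect(c(sprintf("lambda_c[%s]", cl), "lambda_c"), names(est))[1]
    mu <- intersect(c(sprintf("mu[%s]", cl), "mu"), names(est))[1]
    if (!is.na(lc) && !is.na(mu))
      est[[sprintf("net_div[%s]", cl)]] <- est[[lc]] - est[[mu]]
  }
  est
}

derived_truth_net_div <- function(model, truth) {
  out <- numeric()
  for (cl in model$classes) {
    lc <- intersect(c(sprintf("lambda_c[%s]", cl), "lambda_c"),
                    names(truth))[1]
    mu <- intersect(c(sprintf("mu[%s]", cl), "mu"), names(truth))[1]
    if (!is.na(lc) && !is.na(mu))
      out[sprintf("net_div[%s]", cl)] <- truth[[lc]] - truth[[mu]]
  }
  out
}

#' @export
print.bootstrap_report <- function(x, ...) {
  cat("parametric bootstrap of model", x$model$name, ":",
      nrow(x$estimates), "/", x$n_datasets, "replicates refitted\n")
  tab <- data.frame(truth = x$truth[names(x$medians)],
                    median = x$medians,
                    q2.5 = x$intervals[, 1], q97.5 = x$intervals[, 2],
                    bias = x$bias)
  print(signif(tab, 4))
  if (x$unreliable)
    cat("WARNING: more than 20% of refits failed; report unreliable\n")
  invisible(x)
}

#' Monte-Carlo likelihood oracle
#'
#' Estimates the probability (or, for records with observed times, the
#' binned density) of a data-entry pattern by brute-force simulation, as an
#' independent cross-check of the master-equation likelihood.  Patterns
#' follow the five data-entry types; the hidden species count is matched
#' exactly (`n_missing`).
#'
#' For status 2 the pattern is matched on an island window equal to the
#' record's upper bound, mirroring the likelihood's convention that nothing
#' is assumed about the species before the bound.
#'
#' @param status data-entry type 1-5.
#' @param params a [parameter_set()].
#' @param island_age island age (My); for status 2, pass the upper bound.
#' @param n_sims number of simulated mainland species.
#' @param n_missing hidden species count to match exactly.
#' @param k number of phylogeny lineages (statuses 4-5; 1 = no branching,
#'   2 = one branching).
#' @param colonisation_age,branching_age bin centres (My before present) for
#'   timed patterns; `NULL` leaves the corresponding time unconstrained.
#' @param bin_width width of the time bins (My).
#' @param seed optional integer seed.
#' @return a list: `estimate`, `se`, `n_matching`, `n_sims`, and `wide`
#'   flag when no simulation matched (the interval is then uninformative).
#' @export
mc_likelihood_oracle <- function(status, params, island_age, n_sims,
                                 n_missing = 0L, k = 1L,
                                 colonisation_age = NULL,
                                 branching_age = NULL, bin_width = 0.1,
                                 seed = NULL) {
  stopifnot(status %in% 1:5)
  if (!is.null(seed)) set.seed(seed)
  p <- params
  density_scale <- 1
  if (status %in% 1:3) {
    sims <- .cpp_sim_categories(p$gamma, p$lambda_c, p$lambda_a, p$mu,
                                p$K_prime, island_age, n_sims)
    pop <- sims[, 1] == 1
    nend <- sims[, 2]
    col_age <- island_age - sims[, 3]
    match <- switch(status,
      `1` = !pop & nend == 0,
      `2` = pop & nend == n_missing,
      `3` = pop & nend == n_missing)
    if (status == 3L && !is.null(colonisation_age)) {
      match <- match & abs(col_age - colonisation_age) <= bin_width / 2
      density_scale <- bin_width
    }
  } else {
    sims <- .cpp_sim_clade_pattern(p$gamma, p$lambda_c, p$lambda_a, p$mu,
                                   p$K_prime, island_age, n_sims)
    pop <- sims[, 1] == 1
    nend <- sims[, 2]
    nclades <- sims[, 3]
    tc_age <- island_age - sims[, 4]
    crown_age <- ifelse(sims[, 5] < 0, NA_real_, island_age - sims[, 5])
    nprim <- sims[, 6]
    match <- (if (status == 4L) !pop else pop) &
      nprim == k & (nend - nprim) == n_missing &
      (if (k >= 2) !is.na(crown_age) else is.na(crown_age))
    if (!is.null(colonisation_age)) {
      match <- match & abs(tc_age - colonisation_age) <= bin_width / 2
      density_scale <- density_scale * bin_width
    }
    if (!is.null(branching_age)) {
      match <- match & !is.na(crown_age) &
        abs(crown_age - branching_age) <= bin_width / 2
      density_scale <- density_scale * bin_width
    }
  }
  nm <- sum(match)
  phat <- nm / n_sims
  list(estimate = phat / density_scale,
       se = sqrt(phat * (1 - phat) / n_sims) / density_scale,
       n_matching = nm, n_sims = n_sims, wide = nm == 0)
}
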