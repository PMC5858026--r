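#' Example group fit on simulated data
#'
#' Simulates the canonical validation dataset — `n_subjects` subjects with
#' `n_trials` trials each, 4 confidence levels, type 2 criteria at
#' ±(0.5, 1, 1.5), type 1 criterion 0, per-subject d' ~ Normal(2, 0.2) and a
#' fixed generative meta-d'/d' — then fits the hierarchical model and
#' summarises the posterior of group efficiency.
#'
#' @param seed Integer seed for data generation and MCMC.
#' @param n_subjects,n_trials Group size and trials per subject. Defaults
#'   20 and 400.
#' @param mratio Generative meta-d'/d'. Default 0.8.
#' @param n_chains,n_samples,n_burnin Sampler settings passed to
#'   [fit_metad_group()].
#' @return A list with `fit` (the `metad_group_fit`) and `summary` (a
#'   one-row tibble: generative value, posterior mean of meta-d'/d', 95% CI,
#'   R-hat, DIC).
#' @export
run_example_fit <- function(seed = 1, n_subjects = 20, n_trials = 400,
                            mratio = 0.8, n_chains = 3, n_samples = 10000,
                            n_burnin = 1000) {
  grp <- simulate_group(n_subjects = n_subjects, n_trials = n_trials,
                        d_prime_mean = 2, d_prime_sd = 0.2, c = 0,
                        c2 = c(0.5, 1, 1.5), mratio = mratio, seed = seed)
  fit <- fit_metad_group(grp, n_chains = n_chains, n_samples = n_samples,
                         n_burnin = n_burnin, seed = sub_seed(seed, 1L, 20L))
  g <- glance(fit)
  list(fit = fit,
       summary = dplyr::bind_cols(tibble::tibble(true_mratio = mratio), g))
}

#' Parameter-recovery grid over generative efficiency levels
#'
#' For each level of generative meta-d'/d', simulates an independent group
#' and fits the hierarchical model, recording the posterior mean, credible
#' interval and whether the interval covers the generative value.
#'
#' @param levels Generative meta-d'/d' levels. Default the seven-level grid
#'   `c(0.5, 0.75, 1, 1.25, 1.5, 1.75, 2)`.
#' @inheritParams run_example_fit
#' @return A tibble with one row per level: `true_mratio`, `mean_mratio`,
#'   `ci_lo`, `ci_hi`, `covered`, `rhat_mu`.
#' @export
run_recovery_grid <- function(levels = c(0.5, 0.75, 1, 1.25, 1.5, 1.75, 2),
                              seed = 1, n_subjects = 20, n_trials = 400,
                              n_chains = 3, n_samples = 3000,
                              n_burnin = 1000) {
  rows <- purrr::imap(levels, function(lev, i) {
    res <- run_example_fit(seed = sub_seed(seed, i, 30L),
                           n_subjects = n_subjects, n_trials = n_trials,
                           mratio = lev, n_chains = n_chains,
                           n_samples = n_samples, n_burnin = n_burnin)
    g <- res$summary
    tibble::tibble(true_mratio = lev, mean_mratio = g$mean_mratio,
                   ci_lo = g$ci_lo, ci_hi = g$ci_hi,
                   covered = g$ci_lo <= lev & lev <= g$ci_hi,
                   rhat_mu = g$rhat_mu)
  })
  dplyr::bind_rows(rows)
}

#' False-positive-rate comparison of fitting procedures
#'
#' Replicates the method-comparison design: groups of `n_subjects` subjects
#' are simulated at a known generative meta-d'/d' for each combination of
#' type 1 d' and trial count (2 confidence levels; the single type 2
#' criterion pair placed at ±`c2_rel * d_prime`). Each group is fit three
#' ways: per-subject MLE and SSE (padding 0.25) followed by a one-sample
#' t-test of the fitted ratios against the generative value, and the
#' hierarchical model (no padding) with the decision rule that the
#' symmetric 95% credible interval excludes the generative value. The
#' false-positive rate per cell and method is the fraction of replicates in
#' which the test (incorrectly) rejects.
#'
#' @param d_levels Type 1 d' values. Default `c(0.5, 1, 2)`.
#' @param trial_counts Trials per subject. Default
#'   `c(20, 50, 100, 200, 400)`.
#' @param c2_rel Type 2 criterion placement relative to d'. Default 1.
#' @param n_reps Replicates per cell (>= 1; 20 by default, 100 for a
#'   full-scale run).
#' @param true_mratio Generative (null) meta-d'/d'. Default 1.
#' @param n_subjects Subjects per simulated group. Default 20.
#' @param n_chains,n_samples,n_burnin Sampler settings for the hierarchical
#'   fits (reduced by default to keep sweeps tractable).
#' @param seed Integer seed.
#' @return A tibble with one row per (d', trial count, method):
#'   `d_prime`, `n_trials`, `method`, `fpr`, `n_reps`, plus a `rejected`
#'   list-column of the per-replicate 0/1 flags.
#' @export
run_fpr_experiment <- function(d_levels = c(0.5, 1, 2),
                               trial_counts = c(20, 50, 100, 200, 400),
                               c2_rel = 1, n_reps = 20, true_mratio = 1,
                               n_subjects = 20, n_chains = 3,
                               n_samples = 3000, n_burnin = 500,
                               seed = 1) {
  stopifnot(n_reps >= 1)
  grid <- tidyr::expand_grid(d_prime = d_levels, n_trials = trial_counts)
  cells <- purrr::pmap(grid, function(d_prime, n_trials) {
    flags <- purrr::map(seq_len(n_reps), function(rep) {
      rep_seed <- sub_seed(seed, rep,
                           40L + 100L * match(d_prime, d_levels) +
                             match(n_trials, trial_counts))
      grp <- simulate_group(n_subjects = n_subjects, n_trials = n_trials,
                            d_prime_mean = d_prime, d_prime_sd = 0,
                            c = 0, c2 = c2_rel * d_prime,
                            mratio = true_mratio, seed = rep_seed)
      point_reject <- function(method) {
        fits <- suppressWarnings(
          fit_metad_subjects(grp, method = method, padding = 0.25)
        )
        # subjects with degenerate padded rates (d' exactly 0) are dropped
        tt <- stats::t.test(stats::na.omit(fits$mratio), mu = true_mratio)
        as.integer(tt$p.value < 0.05)
      }
      hier_fit <- fit_metad_group(grp, n_chains = n_chains,
                                  n_samples = n_samples,
                                  n_burnin = n_burnin,
                                  seed = sub_seed(rep_seed, 1L, 50L))
      ci <- calc_ci(exp(hier_fit$samples$mu_logMratio))
      c(mle = point_reject("mle"), sse = point_reject("sse"),
        hmetad = as.integer(ci$lo > true_mratio || ci$hi < true_mratio))
    })
    flags <- do.call(rbind, flags)
    purrr::map(c("mle", "sse", "hmetad"), function(m) {
      tibble::tibble(d_prime = d_prime, n_trials = n_trials, method = m,
                     fpr = mean(flags[, m]), n_reps = n_reps,
                     rejected = list(flags[, m]))
    }) |> dplyr::bind_rows()
  })
  dplyr::bind_rows(cells)
}
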