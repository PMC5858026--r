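test_that("rhat behaves on analytic cases", {
  expect_equal(rhat(matrix(5, nrow = 10, ncol = 3)), 1)  # constant chains
  set.seed(3)
  iid <- matrix(rnorm(4e4), ncol = 4)  # same stationary distribution
  expect_gte(rhat(iid), 1)
  expect_lt(rhat(iid), 1.01)
  sep <- cbind(rnorm(200, 0), rnorm(200, 10))  # designed failure
  expect_gt(rhat(sep), 1.1)
  expect_error(rhat(matrix(1:3, ncol = 1)), "2 chains")
  # independent cross-check against coda's implementation
  set.seed(9)
  x <- matrix(rnorm(6000, sd = 2), ncol = 3)
  gd <- coda::gelman.diag(coda::mcmc.list(apply(x, 2, coda::mcmc,
                                                simplify = FALSE)),
                          autoburnin = FALSE)$psrf[1]
  expect_equal(rhat(x), gd, tolerance = 0.01)
})

test_that("credible intervals follow the percentile and shortest-window definitions", {
  ci <- calc_ci(1:1000)
  expect_equal(ci$lo, 25.975)   # linear-interpolation percentile (type 7)
  expect_equal(ci$hi, 975.025)
  expect_equal(ci$kind, "ci")
  expect_error(calc_ci(1:10), "40 samples")

  set.seed(5)
  sym <- rnorm(5e4)
  ci_s <- calc_ci(sym); hdi_s <- calc_hdi(sym)
  expect_equal(ci_s$lo, hdi_s$lo, tolerance = 0.05)
  expect_equal(ci_s$hi, hdi_s$hi, tolerance = 0.05)

  skw <- rexp(5e4)
  ci_e <- calc_ci(skw); hdi_e <- calc_hdi(skw)
  expect_lt(hdi_e$hi - hdi_e$lo, ci_e$hi - ci_e$lo)  # skew: HDI shorter
  # HDI window really contains the stated mass
  expect_gte(mean(skw >= hdi_e$lo & skw <= hdi_e$hi), 0.95)
})

test_that("DIC matches the conjugate normal-mean oracle", {
  expect_equal(dic(rep(123.4, 100), 123.4), 123.4)  # constant: p_D = 0
  # y_i ~ N(theta, 1) with a flat-limit prior: posterior theta ~ N(ybar, 1/n),
  # deviance D(theta) = sum((y - theta)^2) + n log(2 pi), p_D = 1
  set.seed(11)
  n <- 50
  y <- rnorm(n, 1.5, 1)
  theta <- rnorm(2e5, mean(y), sqrt(1 / n))
  dev <- vapply(theta, function(t) sum((y - t)^2) + n * log(2 * pi),
                numeric(1))
  dev_at_mean <- sum((y - mean(theta))^2) + n * log(2 * pi)
  closed_form <- (sum((y - mean(y))^2) + 1 + n * log(2 * pi)) + 1
  expect_equal(dic(dev, dev_at_mean), closed_form, tolerance = 0.05)
  expect_equal(mean(dev) - dev_at_mean, 1, tolerance = 0.05)  # p_D
})

test_that("the hierarchical fit enforces its structural invariants", {
  grp <- simulate_group(n_subjects = 6, n_trials = 150, mratio = 0.9,
                        seed = 61)
  fit <- suppressWarnings(
    fit_metad_group(grp, n_samples = 800, n_burnin = 400, seed = 7)
  )
  pooled <- do.call(rbind, lapply(fit$mcmc, as.matrix))
  # parameter expansion bookkeeping holds per sample
  for (s in 1:6) {
    expect_equal(pooled[, paste0("logMratio[", s, "]")],
                 pooled[, "mu_logMratio"] +
                   pooled[, "xi"] * pooled[, paste0("delta[", s, "]")],
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
  expect_equal(pooled[, "sigma_M"],
               abs(pooled[, "xi"]) * pooled[, "sigma_delta"],
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_true(all(pooled[, "sigma_M"] >= 0))
  # subject criteria respect the ordinal constraint in every sample
  cs1 <- pooled[, paste0("cS1[1,", 1:3, "]")]
  cs2 <- pooled[, paste0("cS2[1,", 1:3, "]")]
  expect_true(all(cs1[, 1] <= cs1[, 2] & cs1[, 2] <= cs1[, 3]))
  expect_true(all(cs2[, 1] <= cs2[, 2] & cs2[, 2] <= cs2[, 3]))
  metac1 <- fit$type1$c_rel[1] * exp(pooled[, "logMratio[1]"]) *
    fit$type1$d_prime[1]
  expect_true(all(cs1[, 3] <= metac1 & metac1 <= cs2[, 1]))
  # summaries are well formed
  expect_true(all(is.finite(fit$rhat$rhat)))
  expect_true(is.finite(fit$dic))
  expect_equal(nrow(fit$samples), 3 * 800)
  g <- glance(fit)
  expect_true(g$mean_mratio > 0)
  td <- tidy(fit)
  expect_true("mratio" %in% td$term)
})

test_that("determinism: identical seeds give identical posterior summaries", {
  grp <- simulate_group(n_subjects = 4, n_trials = 100, seed = 71)
  f1 <- suppressWarnings(fit_metad_group(grp, n_samples = 400,
                                         n_burnin = 300, seed = 42))
  f2 <- suppressWarnings(fit_metad_group(grp, n_samples = 400,
                                         n_burnin = 300, seed = 42))
  expect_equal(glance(f1)$mean_mratio, glance(f2)$mean_mratio,
               tolerance = 1e-6)
  expect_equal(f1$dic, f2$dic, tolerance = 1e-6)
})

test_that("zero high-confidence-error cells fit without padding or error", {
  # high efficiency + few trials leaves high-confidence error cells empty
  grp <- simulate_group(n_subjects = 5, n_trials = 60, mratio = 1,
                        seed = 83)
  zeros <- vapply(grp$counts, function(cc) any(c(cc$nR_S1, cc$nR_S2) == 0),
                  logical(1))
  expect_true(any(zeros))
  fit <- suppressWarnings(
    fit_metad_group(grp, n_samples = 500, n_burnin = 300, seed = 3)
  )
  expect_s3_class(fit, "metad_group_fit")
  expect_true(is.finite(glance(fit)$mean_mratio))
})

test_that("subjects with undefined relative criterion are flagged and excluded", {
  good <- simulate_group(n_subjects = 2, n_trials = 200, seed = 91)$counts
  flat <- confidence_counts(c(10, 10, 10, 10, 10, 10, 10, 10),
                            c(10, 10, 10, 10, 10, 10, 10, 10))  # d' = 0
  expect_warning(
    fit <- suppressMessages(
      fit_metad_group(c(good, list(flat)), n_samples = 300, n_burnin = 200,
                      seed = 5)
    ),
    "[Ee]xcluded"
  )
  expect_equal(fit$spec$n_subjects, 2)
  expect_true(any(fit$type1$excluded))
})

test_that("subject-level posteriors track single-subject MLE at large n", {
  grp <- simulate_group(n_subjects = 2, n_trials = 2e4,
                        mratio = c(0.6, 1.2), seed = 97)
  fit <- suppressWarnings(
    fit_metad_group(grp, n_samples = 1500, n_burnin = 500, seed = 13)
  )
  pooled <- do.call(rbind, lapply(fit$mcmc, as.matrix))
  mle <- fit_metad_subjects(grp, method = "mle")
  for (s in 1:2) {
    post_m <- mean(exp(pooled[, paste0("logMratio[", s, "]")]))
    expect_equal(post_m, mle$mratio[s], tolerance = 0.1)
  }
})

test_that("group difference is null for identical posteriors and detects real effects", {
  grp <- simulate_group(n_subjects = 4, n_trials = 100, seed = 19)
  fit <- suppressWarnings(fit_metad_group(grp, n_samples = 400,
                                          n_burnin = 300, seed = 2))
  d0 <- group_difference(fit, fit)
  expect_true(all(d0$samples == 0))
  expect_false(d0$excludes_zero)

  ga <- simulate_group(n_subjects = 10, n_trials = 300, mratio = 1.0,
                       seed = 23)
  gb <- simulate_group(n_subjects = 10, n_trials = 300, mratio = 0.6,
                       seed = 24)
  fa <- suppressWarnings(fit_metad_group(ga, n_samples = 1500,
                                         n_burnin = 500, seed = 6))
  fb <- suppressWarnings(fit_metad_group(gb, n_samples = 1500,
                                         n_burnin = 500, seed = 7))
  d <- group_difference(fa, fb)
  expect_true(d$excludes_zero)
  expect_gt(mean(d$samples), 0)
})

test_that("difference interval is calibrated for identically simulated groups", {
  contains0 <- vapply(1:20, function(rep) {
    ga <- simulate_group(n_subjects = 6, n_trials = 150, mratio = 0.8,
                         seed = 3000 + 2 * rep)
    gb <- simulate_group(n_subjects = 6, n_trials = 150, mratio = 0.8,
                         seed = 3001 + 2 * rep)
    fa <- suppressWarnings(fit_metad_group(ga, n_samples = 700,
                                           n_burnin = 400,
                                           seed = 5000 + rep))
    fb <- suppressWarnings(fit_metad_group(gb, n_samples = 700,
                                           n_burnin = 400,
                                           seed = 6000 + rep))
    !group_difference(fa, fb)$excludes_zero
  }, logical(1))
  expect_gte(mean(contains0), 0.9)
})

test_that("near-empty data leave the group posterior prior-dominated", {
  # one trial per stimulus per subject. Note even single extreme-confidence
  # trials inform the multinomial likelihood slightly, so the posterior is
  # not literally the Normal(0, 1) prior on mu_logMratio; it must however
  # remain wide, overlap the prior bulk, and keep (near-)prior spread.
  hi <- confidence_counts(c(1, 0, 0, 0), c(0, 0, 0, 1))
  lo <- confidence_counts(c(0, 1, 0, 0), c(0, 0, 1, 0))
  fit <- suppressWarnings(suppressMessages(
    fit_metad_group(list(hi, lo, hi, lo), n_samples = 3000, n_burnin = 500,
                    seed = 17)
  ))
  mu <- fit$samples$mu_logMratio
  expect_gt(stats::sd(mu), 0.7)          # prior SD is 1
  ci <- calc_ci(mu)
  expect_lt(ci$lo, 0)                    # prior centre stays credible
  expect_gt(ci$hi - ci$lo, 2.5)          # width near the prior (3.92)
})

test_that("bivariate fit recovers perfect and null dependence", {
  biv <- simulate_group_bivariate(n_subjects = 30, n_trials = 200, rho = 0,
                                  mu_logm = c(0, 0), sd_logm = c(0.6, 0.6),
                                  seed = 27)
  f0 <- suppressWarnings(
    fit_metad_correlation(biv$counts_1, biv$counts_2, n_samples = 800,
                          n_burnin = 400, seed = 8)
  )
  ci <- calc_ci(f0$samples$rho)
  expect_true(ci$lo < 0 & ci$hi > -0.55)  # centred near 0, CI spans it
  expect_lt(abs(mean(f0$samples$rho)), 0.45)

  fdup <- suppressWarnings(
    fit_metad_correlation(biv$counts_1, biv$counts_1, n_samples = 800,
                          n_burnin = 400, seed = 9)
  )
  expect_gt(mean(fdup$samples$rho), 0.85)  # duplicated task: rho near 1
})

test_that("correlation fit validates its inputs", {
  biv <- simulate_group_bivariate(n_subjects = 5, n_trials = 60, seed = 33)
  expect_error(fit_metad_correlation(biv$counts_1[1:4], biv$counts_2[1:4]),
               "at least 5")
  expect_error(fit_metad_correlation(biv$counts_1, biv$counts_2[1:4]),
               "equal lengths|same subjects")
})
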