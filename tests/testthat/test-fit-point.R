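test_that("type 2 log-likelihood matches term-by-term summation", {
  set.seed(8)
  for (i in 1:20) {
    par <- random_metad_params()
    k <- par$k
    cc <- confidence_counts(rpois(2 * k, 10), rpois(2 * k, 10))
    lk <- prob_lookup(type2_probs(par))
    # direct summation over (stim, resp, conf) cells
    ll <- 0
    for (stim in c("S1", "S2")) {
      v <- if (stim == "S1") cc$nR_S1 else cc$nR_S2
      cells <- data.frame(resp = rep(c("S1", "S2"), each = k),
                          conf = c(k:1, 1:k), n = v)
      for (r in seq_len(nrow(cells))) {
        if (cells$n[r] > 0) {
          ll <- ll + cells$n[r] *
            log(lk[[paste(stim, cells$resp[r], cells$conf[r])]])
        }
      }
    }
    expect_equal(loglik_type2(par, cc), ll, tolerance = 1e-10)
  }
})

test_that("zero counts contribute zero likelihood even at zero probability", {
  par <- metad_params(1, 0, cS1 = c(-1, -1), cS2 = c(0.5, 1))
  k <- 3
  zero <- confidence_counts(rep(0, 2 * k), rep(0, 2 * k))
  expect_equal(loglik_type2(par, zero), 0)
  # the tied cS1 pair makes the middle "S1"-response confidence cell
  # (vector position 2) probability exactly 0: a positive count there sinks
  # the likelihood, a zero count does not
  hit0 <- confidence_counts(c(5, 0, 5, 5, 5, 5), c(5, 0, 5, 5, 5, 5))
  expect_true(is.finite(loglik_type2(par, hit0)))
  hit1 <- confidence_counts(c(0, 1, 0, 0, 0, 0), c(0, 0, 0, 0, 0, 0))
  expect_identical(loglik_type2(par, hit1), -Inf)
})

test_that("counts proportional to the model are maximized at the true meta-d'", {
  par <- metad_params(1.6, 0.1, cS1 = 0.1 - c(1.2, 0.6), cS2 = 0.1 + c(0.6, 1.2))
  lk <- prob_lookup(type2_probs(par))
  k <- 3
  n_per_class <- 1000
  cell_n <- function(stim) {
    resp <- rep(c("S1", "S2"), each = k); conf <- c(k:1, 1:k)
    vapply(seq_len(2 * k), function(i) {
      n_per_class * lk[[paste(stim, resp[i], conf[i])]]
    }, numeric(1))
  }
  cc <- confidence_counts(cell_n("S1"), cell_n("S2"))
  ll_at <- function(md) {
    loglik_type2(metad_params(md, par$meta_c, par$cS1, par$cS2), cc)
  }
  ll_true <- ll_at(1.6)
  for (md in c(1.2, 1.4, 1.5, 1.7, 1.8, 2.0)) {
    expect_lt(ll_at(md), ll_true)
  }
})

test_that("MLE recovers the generative efficiency on large ideal-observer data", {
  cc <- metad_sim(1e5, d_prime = 2, c = 0, mratio = 1, seed = 17)
  f <- fit_metad_mle(cc)
  expect_true(f$converged)
  expect_equal(f$mratio, 1, tolerance = 0.05)
  expect_equal(f$type1$d_prime, 2, tolerance = 0.05)
})

test_that("MLE on the worked vectors matches a grid-plus-polish oracle", {
  cc <- tutorial_counts()
  fit <- fit_metad_mle(cc)
  # independent oracle: direct criterion parameterization with an ordering
  # penalty, Nelder-Mead over a coarse meta-d' grid, then joint refinement
  padded <- confidence_counts(cc$nR_S1 + 0.25, cc$nR_S2 + 0.25)
  t1 <- type1_stats(padded)
  k <- cc$k
  nll <- function(v) {
    md <- v[1]; mc <- t1$c_rel * md
    cs1 <- v[2:k]; cs2 <- v[(k + 1):(2 * k - 1)]
    if (is.unsorted(c(cs1, mc, cs2))) return(1e10)
    ll <- loglik_type2(metad_params(md, mc, cs1, cs2), padded)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  best <- NULL
  for (md in seq(0.5, 4, by = 0.25)) {
    mc <- t1$c_rel * md
    v0 <- c(md, mc - rev(seq_len(k - 1)) * 0.5, mc + seq_len(k - 1) * 0.5)
    r <- stats::optim(v0, nll, method = "Nelder-Mead",
                      control = list(maxit = 3000, reltol = 1e-12))
    if (is.null(best) || r$value < best$value) best <- r
  }
  for (i in 1:5) {
    best <- stats::optim(best$par, nll, method = "Nelder-Mead",
                         control = list(maxit = 5000, reltol = 1e-14))
  }
  expect_equal(fit$meta_d, best$par[1], tolerance = 1e-3)
  expect_equal(c(fit$params$cS1, fit$params$cS2), best$par[-1],
               tolerance = 1e-3, ignore_attr = TRUE)
  expect_equal(fit$logL, -best$value, tolerance = 1e-6)
})

test_that("returned fits respect the ordering and criterion-tying constraints", {
  set.seed(23)
  for (i in 1:10) {
    cc <- metad_sim(80, d_prime = runif(1, 0.5, 2.5), c = runif(1, -0.3, 0.3),
                    mratio = runif(1, 0.4, 1.6), seed = 100 + i)
    for (f in list(fit_metad_mle(cc), fit_metad_sse(cc))) {
      ord <- c(f$params$cS1, f$params$meta_c, f$params$cS2)
      expect_false(is.unsorted(ord))
      expect_equal(f$params$meta_c / f$params$meta_d, f$type1$c_rel,
                   tolerance = 1e-6)
    }
  }
})

test_that("SSE and MLE agree on large ideal-observer data", {
  cc <- metad_sim(1e5, d_prime = 2, c = 0, mratio = 1, seed = 19)
  m <- fit_metad_mle(cc)
  s <- fit_metad_sse(cc)
  expect_equal(m$mratio, s$mratio, tolerance = 0.02)
})

test_that("SSE objective is finite with padded zero cells and optimal at its optimum", {
  cc <- confidence_counts(c(40, 10, 0, 0, 0, 0), c(0, 0, 0, 5, 15, 30))
  s <- fit_metad_sse(cc)
  expect_true(is.finite(s$logL))
  # definitional check: SSE at the SSE optimum <= SSE at the MLE solution
  m <- fit_metad_mle(cc)
  sse_at <- function(f) metasdt:::.sse_type2(f$params,
                                             confidence_counts(cc$nR_S1 + 0.25,
                                                               cc$nR_S2 + 0.25))
  expect_lte(sse_at(s), sse_at(m) + 1e-10)
})

test_that("mean fitted efficiency is consistent over many simulated subjects", {
  grp <- simulate_group(n_subjects = 100, n_trials = 1e4, mratio = 0.8,
                        seed = 29)
  fits <- fit_metad_subjects(grp, method = "mle")
  expect_lt(abs(mean(fits$mratio) - 0.8), 0.03)
})

test_that("padded point fits are biased at low trial counts and low d'", {
  grp <- simulate_group(n_subjects = 40, n_trials = 20, d_prime_mean = 0.5,
                        d_prime_sd = 0, c2 = 0.5, mratio = 1, seed = 37)
  fits <- suppressWarnings(fit_metad_subjects(grp, method = "mle"))
  # subjects whose padded rates coincide exactly (d' = 0) are skipped
  m <- mean(fits$mratio, na.rm = TRUE)
  # the padding-induced misestimation seen at 20 trials/subject: the group
  # mean is well away from the generative ratio of 1
  expect_gt(abs(m - 1), 0.1)
})

test_that("tidy and glance summarise point fits", {
  f <- fit_metad_mle(tutorial_counts())
  td <- tidy(f)
  expect_named(td, c("term", "estimate"))
  expect_equal(nrow(td), 2 + 2 * (f$params$k - 1))
  g <- glance(f)
  expect_equal(g$method, "mle")
  expect_equal(g$n_trials, 332)
})
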