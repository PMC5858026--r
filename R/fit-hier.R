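# JAGS model for hierarchical estimation of group-level log(meta-d'/d').
#
# Per subject, type 1 d' and c are fixed at their point estimates (black-dot
# nodes); the subject's meta-level sensitivity is exp(logM_s) * d'_s, with
# logM_s = mu_logMratio + xi * delta_s (parameter expansion: the redundant
# multiplier xi improves mixing of the hierarchical scale; sigma_M is
# recovered post hoc as |xi| * sigma_delta). Subject type 2 criteria get
# per-criterion-index group priors, mirrored across response sides, and are
# kept in their ordinal relationship by truncation at meta_c plus sorting.
# Each stimulus class's 2k counts are multinomial with cell probabilities
# P(resp | stim; d', c) * P(conf | stim, resp; meta-d', meta-c, c2); cells
# are floored at 1e-5 against phi() underflow (dmulti renormalizes).
.jags_group_model <- function(k) {
  mid_s1 <- if (k > 2) "
      for (m in 2:(K-1)) {
        pS1c[s,i,m] <- phi(cS1[s,m] - mus[s,i]) - phi(cS1[s,m-1] - mus[s,i])
      }" else ""
  mid_s2 <- if (k > 2) "
      for (m in 2:(K-1)) {
        pS2c[s,i,m] <- phi(cS2[s,m] - mus[s,i]) - phi(cS2[s,m-1] - mus[s,i])
      }" else ""
  paste0("
model {
  mu_logMratio ~ dnorm(0, 1)
  sigma_delta ~ dnorm(0, 1) T(0,)
  xi ~ dbeta(1, 1)
  lambda_delta <- pow(sigma_delta, -2)
  sigma_M <- abs(xi) * sigma_delta
  for (j in 1:(K-1)) {
    mu_c2[j] ~ dnorm(0, 0.01)
    sigma_c2[j] ~ dnorm(0, 0.01) T(0,)
    lambda_c2[j] <- pow(sigma_c2[j], -2)
  }
  for (s in 1:S) {
    delta[s] ~ dnorm(0, lambda_delta)
    logMratio[s] <- mu_logMratio + xi * delta[s]
    metad[s] <- exp(logMratio[s]) * d1[s]
    metac[s] <- cratio[s] * metad[s]
    mus[s,1] <- -metad[s] / 2
    mus[s,2] <- metad[s] / 2
    for (j in 1:(K-1)) {
      cS1_raw[s,j] ~ dnorm(-mu_c2[K-j], lambda_c2[K-j]) T(, metac[s])
      cS2_raw[s,j] ~ dnorm(mu_c2[j], lambda_c2[j]) T(metac[s], )
    }
    cS1[s,1:(K-1)] <- sort(cS1_raw[s,1:(K-1)])
    cS2[s,1:(K-1)] <- sort(cS2_raw[s,1:(K-1)])
    for (i in 1:2) {
      CA[s,i] <- phi(metac[s] - mus[s,i])
      CAc[s,i] <- phi(mus[s,i] - metac[s])
      pS1c[s,i,1] <- phi(cS1[s,1] - mus[s,i])", mid_s1, "
      pS1c[s,i,K] <- CA[s,i] - phi(cS1[s,K-1] - mus[s,i])
      pS2c[s,i,1] <- phi(cS2[s,1] - mus[s,i]) - CA[s,i]", mid_s2, "
      pS2c[s,i,K] <- phi(mus[s,i] - cS2[s,K-1])
      for (m in 1:K) {
        pr[s,i,m]   <- max(pRS1[s,i] * pS1c[s,i,m] /
                             max(CA[s,i], 1.0E-10), 1.0E-5)
        pr[s,i,K+m] <- max((1 - pRS1[s,i]) * pS2c[s,i,m] /
                             max(CAc[s,i], 1.0E-10), 1.0E-5)
      }
    }
    counts_S1[s,1:(2*K)] ~ dmulti(pr[s,1,1:(2*K)], n1[s])
    counts_S2[s,1:(2*K)] ~ dmulti(pr[s,2,1:(2*K)], n2[s])
  }
}")
}

# Per-subject type 1 point estimates for the hierarchical fits (no padding;
# subjects with degenerate rates get rate-only padding 1/(2k), logged).
# Subjects whose d' point estimate is not positive are excluded with a
# warning: meta-d' enters the model as exp(logM) * d', so d' = 0 leaves c'
# undefined and d' < 0 forces meta-d' <= 0 regardless of the confidence
# data, sending the subject's logM likelihood monotonically to -Inf.
# Efficiency is not identifiable without above-chance type 1 performance.
.hier_type1 <- function(counts_list) {
  rows <- purrr::imap(counts_list, function(cc, nm) {
    padded <- FALSE
    t1 <- tryCatch(suppressWarnings(type1_stats(cc, padding = 0)),
                   error = function(e) NULL)
    if (is.null(t1)) {
      padded <- TRUE
      message("subject ", nm, ": hit or false-alarm rate at 0/1; applied ",
              "padding 1/(2k) to the type 1 rate computation only.")
      t1 <- suppressWarnings(type1_stats(cc, padding = 1 / (2 * cc$k)))
    }
    excluded <- is.nan(t1$c_rel) || t1$d_prime <= 0
    if (excluded) {
      warning("subject ", nm, " has d' <= 0; metacognitive efficiency is ",
              "not identifiable without above-chance type 1 performance. ",
              "Excluded from the hierarchical fit.", call. = FALSE)
    }
    tibble::tibble(subject = nm, d_prime = t1$d_prime, c = t1$c,
                   c_rel = t1$c_rel, padded = padded, excluded = excluded)
  })
  dplyr::bind_rows(rows)
}

# Extract "name[i]" / "name[i,j]" / "name[i,j,t]" columns of a pooled
# samples matrix into an array with sample index first.
.extract_array <- function(mat, name, dims) {
  idx <- expand.grid(lapply(dims, seq_len))
  cols <- paste0(name, "[", do.call(paste, c(idx, sep = ",")), "]")
  missing <- setdiff(cols, colnames(mat))
  if (length(missing) > 0) {
    stop("monitored parameter columns missing: ", missing[1], call. = FALSE)
  }
  array(mat[, cols], dim = c(nrow(mat), dims))
}

# Deviance trace (-2 log multinomial likelihood, full density including
# combinatorial constants and the fixed type 1 response factors) computed in
# R from monitored subject-level samples. Mirrors the JAGS model's 1e-5 cell
# floor and renormalization so plug-in and sampled deviances share one
# definition. Returns the per-sample trace; .deviance_at() gives the plug-in
# value for one parameter setting.
.deviance_trace <- function(logM, cS1, cS2, d1, cratio, counts_list) {
  n_samp <- nrow(logM)
  S <- length(counts_list)
  k <- counts_list[[1]]$k
  dev <- numeric(n_samp)
  for (s in seq_len(S)) {
    cc <- counts_list[[s]]
    n_cells <- c(cc$nR_S1, cc$nR_S2)
    const <- sum(lgamma(sum(cc$nR_S1) + 1), -lgamma(cc$nR_S1 + 1),
                 lgamma(sum(cc$nR_S2) + 1), -lgamma(cc$nR_S2 + 1))
    metad <- exp(logM[, s]) * d1[s]
    metac <- cratio[s] * metad
    pRS1 <- c(stats::pnorm(cratio[s] * d1[s] + d1[s] / 2),
              stats::pnorm(cratio[s] * d1[s] - d1[s] / 2))
    ll <- rep(const, n_samp)
    for (i in 1:2) {
      mu <- (if (i == 1) -1 else 1) * metad / 2
      edges_lo <- cbind(-Inf, matrix(cS1[, s, ], n_samp), metac)
      edges_hi <- cbind(metac, matrix(cS2[, s, ], n_samp), Inf)
      plo <- stats::pnorm(edges_lo - mu)
      qhi <- stats::pnorm(edges_hi - mu, lower.tail = FALSE)
      raw1 <- plo[, -1, drop = FALSE] - plo[, -(k + 1), drop = FALSE]
      raw2 <- qhi[, 1:k, drop = FALSE] - qhi[, 2:(k + 1), drop = FALSE]
      ca <- plo[, k + 1]
      cac <- qhi[, 1]
      p <- cbind(pRS1[i] * raw1 / pmax(ca, 1e-10),
                 (1 - pRS1[i]) * raw2 / pmax(cac, 1e-10))
      p <- pmax(p, 1e-5)
      p <- p / rowSums(p)
      n_i <- if (i == 1) cc$nR_S1 else cc$nR_S2
      nz <- n_i > 0
      if (any(nz)) {
        ll <- ll + log(p[, nz, drop = FALSE]) %*% n_i[nz]
      }
    }
    dev <- dev + as.numeric(-2 * ll)
  }
  dev
}

.chain_inits <- function(n_chains, seed, S, k, c1, n_tasks = 1) {
  lapply(seq_len(n_chains), function(ch) {
    shift <- 0.2 * (ch - (n_chains + 1) / 2)
    ini <- list(
      .RNG.name = "base::Mersenne-Twister",
      .RNG.seed = sub_seed(seed, ch, 10L)
    )
    if (n_tasks == 1) {
      ini$mu_logMratio <- shift
      ini$sigma_delta <- 0.5
      ini$xi <- 0.5
      ini$delta <- rep(0, S)
      ini$mu_c2 <- rep(0.5, k - 1)
      ini$sigma_c2 <- rep(0.5, k - 1)
      ini$cS1_raw <- outer(c1, seq_len(k - 1), function(cc, j) cc - 0.3 * j)
      ini$cS2_raw <- outer(c1, seq_len(k - 1), function(cc, j) cc + 0.3 * j)
    } else {
      ini$mu_M <- rep(shift, 2)
      ini$lam_M <- rep(4, 2)
      ini$rho <- 0
      ini$logM <- matrix(shift, S, 2)
      ini$mu_c2 <- matrix(0.5, k - 1, 2)
      ini$sigma_c2 <- matrix(0.5, k - 1, 2)
      ini$cS1_raw <- array(rep(outer(c1[, 1], seq_len(k - 1),
                                     function(cc, j) cc - 0.3 * j), 2),
                           dim = c(S, k - 1, 2))
      ini$cS2_raw <- array(rep(outer(c1[, 1], seq_len(k - 1),
                                     function(cc, j) cc + 0.3 * j), 2),
                           dim = c(S, k - 1, 2))
      for (t in 1:2) {
        ini$cS1_raw[, , t] <- outer(c1[, t], seq_len(k - 1),
                                    function(cc, j) cc - 0.3 * j)
        ini$cS2_raw[, , t] <- outer(c1[, t], seq_len(k - 1),
                                    function(cc, j) cc + 0.3 * j)
      }
    }
    ini
  })
}

.run_jags <- function(model_string, data, inits, n_chains, n_burnin,
                      n_samples, monitors) {
  con <- textConnection(model_string)
  on.exit(close(con), add = TRUE)
  model <- rjags::jags.model(con, data = data, inits = inits,
                             n.chains = n_chains,
                             n.adapt = max(500, n_burnin %/% 2),
                             quiet = TRUE)
  remaining <- n_burnin - max(500, n_burnin %/% 2)
  if (remaining > 0) stats::update(model, remaining, progress.bar = "none")
  rjags::coda.samples(model, monitors, n.iter = n_samples,
                      progress.bar = "none")
}

#' Hierarchical Bayesian estimation of group metacognitive efficiency
#'
#' Fits the hierarchical type 2 SDT model by MCMC (JAGS): each subject's
#' type 1 d' and criterion are fixed at their point estimates (no edge
#' correction — the multinomial likelihood handles zero cells naturally),
#' subject-level log(meta-d'/d') values are partially pooled under a
#' group-level Gaussian with mean `mu_logMratio` ~ Normal(0, 1), and the
#' hierarchical scale uses parameter expansion (`logM_s = mu + xi * delta_s`,
#' `delta_s` ~ Normal(0, sigma_delta), `xi` ~ Beta(1, 1); `sigma_M` is
#' recovered per sample as `|xi| * sigma_delta`). Type 2 criteria get
#' per-criterion-index group priors Normal(±mu_c2, sigma_c2) with
#' `mu_c2` ~ Normal(0, 10) and `sigma_c2` ~ half-Normal(10), mirrored across
#' response sides, constrained to their ordinal relationship.
#'
#' Convergence is not enforced: R-hat is computed for every monitored
#' parameter and a warning is issued when any exceeds 1.1.
#'
#' @param data Confidence counts for >= 2 subjects, in any form accepted by
#'   [as_counts_list()].
#' @param n_chains Number of MCMC chains (>= 2). Default 3.
#' @param n_samples Retained samples per chain. Default 10000.
#' @param n_burnin Adaptation + burn-in iterations per chain. Default 1000.
#' @param seed Integer seed controlling chain RNGs and initial values.
#' @return A `metad_group_fit` object with elements `samples` (tibble of
#'   group-level draws: chain, iteration, `mu_logMratio`, `sigma_M`,
#'   `sigma_delta`, `xi`, `mu_c2_*`, `sigma_c2_*`), `mcmc` (the raw coda
#'   `mcmc.list`), `rhat` (tibble), `dic`, `p_d`, `deviance` (per-sample
#'   trace), `type1` (per-subject point estimates) and `spec`. Has `tidy()`,
#'   `glance()` and `autoplot()` methods.
#' @examples
#' \donttest{
#' grp <- simulate_group(n_subjects = 8, n_trials = 200, mratio = 0.8,
#'                       seed = 1)
#' fit <- fit_metad_group(grp, n_samples = 1000, n_burnin = 500, seed = 1)
#' glance(fit)
#' }
#' @export
fit_metad_group <- function(data, n_chains = 3, n_samples = 10000,
                            n_burnin = 1000, seed = NULL) {
  counts_list <- as_counts_list(data)
  if (length(counts_list) < 2) {
    stop("the hierarchical model requires at least 2 subjects.",
         call. = FALSE)
  }
  stopifnot(n_chains >= 2, n_burnin >= 1, n_samples > n_burnin)
  if (is.null(seed)) seed <- sample.int(2^30, 1)
  k <- counts_list[[1]]$k
  if (!all(vapply(counts_list, function(x) x$k, integer(1)) == k)) {
    stop("all subjects must share the same number of rating levels.",
         call. = FALSE)
  }

  type1 <- .hier_type1(counts_list)
  keep <- !type1$excluded
  counts_list <- counts_list[keep]
  t1 <- type1[keep, ]
  S <- length(counts_list)
  if (S < 2) {
    stop("fewer than 2 subjects remain after exclusions.", call. = FALSE)
  }

  jags_data <- list(
    S = S, K = k,
    counts_S1 = do.call(rbind, lapply(counts_list, `[[`, "nR_S1")),
    counts_S2 = do.call(rbind, lapply(counts_list, `[[`, "nR_S2")),
    n1 = vapply(counts_list, function(x) sum(x$nR_S1), numeric(1)),
    n2 = vapply(counts_list, function(x) sum(x$nR_S2), numeric(1)),
    d1 = t1$d_prime,
    cratio = t1$c_rel,
    pRS1 = cbind(stats::pnorm(t1$c + t1$d_prime / 2),
                 stats::pnorm(t1$c - t1$d_prime / 2))
  )
  inits <- .chain_inits(n_chains, seed, S, k, t1$c)
  monitors <- c("mu_logMratio", "sigma_M", "sigma_delta", "xi", "mu_c2",
                "sigma_c2", "delta", "logMratio", "cS1", "cS2")
  mcmc <- .run_jags(.jags_group_model(k), jags_data, inits, n_chains,
                    n_burnin, n_samples, monitors)

  pooled <- do.call(rbind, lapply(mcmc, as.matrix))
  rhat_tbl <- tibble::tibble(
    parameter = colnames(pooled),
    rhat = vapply(colnames(pooled), function(p) {
      rhat(sapply(mcmc, function(ch) as.numeric(ch[, p])))
    }, numeric(1))
  )
  if (any(rhat_tbl$rhat >= 1.1, na.rm = TRUE)) {
    worst <- rhat_tbl[which.max(rhat_tbl$rhat), ]
    warning(sum(rhat_tbl$rhat >= 1.1, na.rm = TRUE), " parameter(s) have ",
            "R-hat >= 1.1 (worst: ", worst$parameter, " = ",
            signif(worst$rhat, 3), "; mu_logMratio = ",
            signif(rhat_tbl$rhat[rhat_tbl$parameter == "mu_logMratio"], 4),
            "). Criterion-scale nuisance parameters mix slowly; inspect ",
            "`$rhat` and consider more samples.", call. = FALSE)
  }

  logM <- .extract_array(pooled, "logMratio", S)
  cS1 <- .extract_array(pooled, "cS1", c(S, k - 1))
  cS2 <- .extract_array(pooled, "cS2", c(S, k - 1))
  dev <- .deviance_trace(logM, cS1, cS2, t1$d_prime, t1$c_rel, counts_list)
  dev_at_mean <- .deviance_trace(
    matrix(colMeans(logM), 1), array(apply(cS1, c(2, 3), mean),
                                     c(1, S, k - 1)),
    array(apply(cS2, c(2, 3), mean), c(1, S, k - 1)),
    t1$d_prime, t1$c_rel, counts_list
  )
  dic_val <- dic(dev, dev_at_mean)

  group_cols <- c("mu_logMratio", "sigma_M", "sigma_delta", "xi",
                  grep("^(mu_c2|sigma_c2)\\[", colnames(pooled), value = TRUE))
  samples <- tibble::as_tibble(pooled[, group_cols, drop = FALSE],
                               .name_repair = function(x) {
                                 gsub("\\[(\\d+)\\]", "_\\1", x)
                               })
  samples <- dplyr::bind_cols(
    tibble::tibble(chain = rep(seq_len(n_chains), each = n_samples),
                   iteration = rep(seq_len(n_samples), n_chains)),
    samples
  )

  structure(list(
    samples = samples,
    mcmc = mcmc,
    rhat = rhat_tbl,
    dic = dic_val,
    p_d = mean(dev) - dev_at_mean,
    deviance = dev,
    type1 = type1,
    spec = list(n_chains = n_chains, n_samples = n_samples,
                n_burnin = n_burnin, seed = seed, k = k, n_subjects = S)
  ), class = "metad_group_fit")
}

#' @export
print.metad_group_fit <- function(x, ...) {
  g <- glance(x)
  cat("<metad_group_fit>", x$spec$n_subjects, "subjects,", x$spec$n_chains,
      "chains x", x$spec$n_samples, "samples\n")
  cat(sprintf("  group meta-d'/d': mean %.3f, 95%% CI [%.3f, %.3f]\n",
              g$mean_mratio, g$ci_lo, g$ci_hi))
  cat(sprintf("  R-hat(mu_logMratio) = %.3f  DIC = %.1f\n",
              g$rhat_mu, g$dic))
  invisible(x)
}

#' @export
tidy.metad_group_fit <- function(x, ...) {
  group_pars <- setdiff(names(x$samples), c("chain", "iteration"))
  rows <- purrr::map(group_pars, function(p) {
    v <- x$samples[[p]]
    ci <- calc_ci(v)
    hdi <- calc_hdi(v)
    rh_name <- gsub("_(\\d+)$", "[\\1]", p)
    tibble::tibble(term = p, estimate = mean(v), std.error = stats::sd(v),
                   ci_lo = ci$lo, ci_hi = ci$hi,
                   hdi_lo = hdi$lo, hdi_hi = hdi$hi,
                   rhat = x$rhat$rhat[match(rh_name, x$rhat$parameter)])
  })
  mr <- exp(x$samples$mu_logMratio)
  ci <- calc_ci(mr); hdi <- calc_hdi(mr)
  dplyr::bind_rows(
    tibble::tibble(term = "mratio", estimate = mean(mr),
                   std.error = stats::sd(mr), ci_lo = ci$lo, ci_hi = ci$hi,
                   hdi_lo = hdi$lo, hdi_hi = hdi$hi,
                   rhat = x$rhat$rhat[match("mu_logMratio",
                                            x$rhat$parameter)]),
    dplyr::bind_rows(rows)
  )
}

#' @export
glance.metad_group_fit <- function(x, ...) {
  mr <- exp(x$samples$mu_logMratio)
  ci <- calc_ci(mr)
  tibble::tibble(
    mean_mratio = mean(mr),
    ci_lo = ci$lo, ci_hi = ci$hi,
    rhat_mu = x$rhat$rhat[match("mu_logMratio", x$rhat$parameter)],
    dic = x$dic, p_d = x$p_d,
    n_subjects = x$spec$n_subjects,
    n_samples = x$spec$n_chains * x$spec$n_samples
  )
}

#' Gelman–Rubin potential scale reduction factor
#'
#' Compares within-chain and between-chain variance of several MCMC chains
#' for one parameter: \eqn{\hat{R} = \sqrt{((n-1)/n \, W + B/n) / W}}, where
#' W is the mean within-chain variance and B/n the variance of the chain
#' means. Values near 1 indicate the chains sample the same distribution;
#' values above 1.1 suggest non-convergence. If every chain is constant
#' (zero variance everywhere), 1 is returned by convention.
#'
#' @param samples An iterations x chains matrix, a `coda::mcmc.list`, or a
#'   list of equal-length numeric vectors (one per chain). At least 2 chains
#'   of at least 4 draws.
#' @return The potential scale reduction factor (a single number).
#' @export
rhat <- function(samples) {
  if (inherits(samples, "mcmc.list")) {
    samples <- sapply(samples, as.numeric)
  }
  if (is.list(samples)) samples <- do.call(cbind, samples)
  samples <- as.matrix(samples)
  if (ncol(samples) < 2 || nrow(samples) < 4) {
    stop("rhat requires >= 2 chains of >= 4 draws each.", call. = FALSE)
  }
  n <- nrow(samples)
  w <- mean(apply(samples, 2, stats::var))
  b_n <- stats::var(colMeans(samples))
  if (w == 0) {
    return(if (b_n == 0) 1 else Inf)
  }
  sqrt(((n - 1) / n * w + b_n) / w)
}

#' Symmetric credible interval from posterior samples
#'
#' The central interval bounded by the 2.5% and 97.5% percentiles (for
#' `level = 0.95`), using the default linear-interpolation percentile
#' convention (type 7).
#'
#' @param samples Numeric vector of at least 40 posterior draws.
#' @param level Interval mass. Default 0.95.
#' @return A one-row tibble with columns `lo`, `hi`, `level`, `kind`.
#' @export
calc_ci <- function(samples, level = 0.95) {
  stopifnot(is.numeric(samples), level > 0, level < 1)
  if (length(samples) < 40) {
    stop("at least 40 samples are required for a credible interval.",
         call. = FALSE)
  }
  q <- stats::quantile(samples, c((1 - level) / 2, 1 - (1 - level) / 2),
                       names = FALSE, type = 7)
  tibble::tibble(lo = q[1], hi = q[2], level = level, kind = "ci")
}

#' Highest-density interval from posterior samples
#'
#' The shortest window containing `level` of the sorted samples — not
#' necessarily symmetric, and narrower than the central interval for skewed
#' posteriors.
#'
#' @inheritParams calc_ci
#' @return A one-row tibble with columns `lo`, `hi`, `level`, `kind`.
#' @export
calc_hdi <- function(samples, level = 0.95) {
  stopifnot(is.numeric(samples), level > 0, level < 1)
  if (length(samples) < 40) {
    stop("at least 40 samples are required for a credible interval.",
         call. = FALSE)
  }
  x <- sort(samples)
  n <- length(x)
  m <- ceiling(level * n)
  widths <- x[m:n] - x[1:(n - m + 1)]
  i <- which.min(widths)
  tibble::tibble(lo = x[i], hi = x[i + m - 1], level = level, kind = "hdi")
}

#' Deviance information criterion from a deviance trace
#'
#' DIC = mean posterior deviance + p_D, with the effective number of
#' parameters p_D = mean deviance - deviance at the posterior mean of the
#' parameters. Lower is better; p_D conventions differ across software
#' (this one uses the plug-in definition, not half the deviance variance),
#' so DIC values are comparable only within one convention.
#'
#' @param deviance Numeric vector: deviance recorded at each retained
#'   sample.
#' @param deviance_at_mean Deviance evaluated at the posterior mean of the
#'   parameters, computed with the same deviance definition.
#' @return The DIC (a single number).
#' @export
dic <- function(deviance, deviance_at_mean) {
  stopifnot(is.numeric(deviance), length(deviance) >= 1,
            is.numeric(deviance_at_mean), length(deviance_at_mean) == 1)
  mean_dev <- mean(deviance)
  mean_dev + (mean_dev - deviance_at_mean)
}

#' Posterior difference in group metacognitive efficiency
#'
#' Elementwise difference of the pooled `mu_logMratio` samples of two group
#' fits (group A minus group B, in log units). If the two posteriors have
#' different numbers of samples they are paired at random under a fixed
#' seed. Reports the symmetric credible interval of the difference and
#' whether it excludes 0.
#'
#' @param fit_a,fit_b `metad_group_fit` objects.
#' @param level Credible-interval mass. Default 0.95.
#' @param seed Seed for the random pairing when sample counts differ.
#' @return A `metad_group_diff` object: list with `samples` (difference
#'   draws), `ci` (tibble), and `excludes_zero`.
#' @export
group_difference <- function(fit_a, fit_b, level = 0.95, seed = 1) {
  stopifnot(inherits(fit_a, "metad_group_fit"),
            inherits(fit_b, "metad_group_fit"))
  for (f in list(fit_a, fit_b)) {
    rh <- f$rhat$rhat[match("mu_logMratio", f$rhat$parameter)]
    if (is.finite(rh) && rh >= 1.1) {
      warning("a group fit has R-hat(mu_logMratio) >= 1.1; the difference ",
              "posterior may be unreliable.", call. = FALSE)
    }
  }
  a <- fit_a$samples$mu_logMratio
  b <- fit_b$samples$mu_logMratio
  if (length(a) != length(b)) {
    local_seed(seed)
    n <- min(length(a), length(b))
    a <- a[sample.int(length(a), n)]
    b <- b[sample.int(length(b), n)]
  }
  d <- a - b
  ci <- calc_ci(d, level = level)
  structure(list(samples = d, ci = ci,
                 excludes_zero = ci$lo > 0 || ci$hi < 0),
            class = "metad_group_diff")
}

#' @export
print.metad_group_diff <- function(x, ...) {
  cat("<metad_group_diff> difference in mu_logMratio (log units)\n")
  cat(sprintf("  mean %.3f, %g%% CI [%.3f, %.3f] — %s 0\n",
              mean(x$samples), 100 * x$ci$level, x$ci$lo, x$ci$hi,
              if (x$excludes_zero) "excludes" else "contains"))
  invisible(x)
}

# JAGS model for the bivariate (two-task) extension: per-subject
# log-efficiencies for the two tasks are joint draws from a bivariate
# Gaussian whose correlation rho is the estimand. No parameter expansion.
.jags_corr_model <- function(k) {
  mid_s1 <- if (k > 2) "
      for (m in 2:(K-1)) {
        pS1c[s,i,m,t] <- phi(cS1[s,m,t] - mus[s,i,t]) - phi(cS1[s,m-1,t] - mus[s,i,t])
      }" else ""
  mid_s2 <- if (k > 2) "
      for (m in 2:(K-1)) {
        pS2c[s,i,m,t] <- phi(cS2[s,m,t] - mus[s,i,t]) - phi(cS2[s,m-1,t] - mus[s,i,t])
      }" else ""
  paste0("
model {
  for (t in 1:2) {
    mu_M[t] ~ dnorm(0, 1)
    lam_M[t] ~ dgamma(0.001, 0.001)
    sigma_M[t] <- 1 / sqrt(lam_M[t])
    for (j in 1:(K-1)) {
      mu_c2[j,t] ~ dnorm(0, 0.01)
      sigma_c2[j,t] ~ dnorm(0, 0.01) T(0,)
      lambda_c2[j,t] <- pow(sigma_c2[j,t], -2)
    }
  }
  rho ~ dunif(-1, 1)
  Sig[1,1] <- pow(sigma_M[1], 2)
  Sig[2,2] <- pow(sigma_M[2], 2)
  Sig[1,2] <- rho * sigma_M[1] * sigma_M[2]
  Sig[2,1] <- Sig[1,2]
  TI[1:2,1:2] <- inverse(Sig[1:2,1:2])
  for (s in 1:S) {
    logM[s,1:2] ~ dmnorm(mu_M[1:2], TI[1:2,1:2])
    for (t in 1:2) {
      metad[s,t] <- exp(logM[s,t]) * d1[s,t]
      metac[s,t] <- cratio[s,t] * metad[s,t]
      mus[s,1,t] <- -metad[s,t] / 2
      mus[s,2,t] <- metad[s,t] / 2
      for (j in 1:(K-1)) {
        cS1_raw[s,j,t] ~ dnorm(-mu_c2[K-j,t], lambda_c2[K-j,t]) T(, metac[s,t])
        cS2_raw[s,j,t] ~ dnorm(mu_c2[j,t], lambda_c2[j,t]) T(metac[s,t], )
      }
      cS1[s,1:(K-1),t] <- sort(cS1_raw[s,1:(K-1),t])
      cS2[s,1:(K-1),t] <- sort(cS2_raw[s,1:(K-1),t])
      for (i in 1:2) {
        CA[s,i,t] <- phi(metac[s,t] - mus[s,i,t])
        CAc[s,i,t] <- phi(mus[s,i,t] - metac[s,t])
        pS1c[s,i,1,t] <- phi(cS1[s,1,t] - mus[s,i,t])", mid_s1, "
        pS1c[s,i,K,t] <- CA[s,i,t] - phi(cS1[s,K-1,t] - mus[s,i,t])
        pS2c[s,i,1,t] <- phi(cS2[s,1,t] - mus[s,i,t]) - CA[s,i,t]", mid_s2, "
        pS2c[s,i,K,t] <- phi(mus[s,i,t] - cS2[s,K-1,t])
        for (m in 1:K) {
          pr[s,i,m,t]   <- max(pRS1[s,i,t] * pS1c[s,i,m,t] /
                                 max(CA[s,i,t], 1.0E-10), 1.0E-5)
          pr[s,i,K+m,t] <- max((1 - pRS1[s,i,t]) * pS2c[s,i,m,t] /
                                 max(CAc[s,i,t], 1.0E-10), 1.0E-5)
        }
      }
      counts_S1[s,1:(2*K),t] ~ dmulti(pr[s,1,1:(2*K),t], n1[s,t])
      counts_S2[s,1:(2*K),t] ~ dmulti(pr[s,2,1:(2*K),t], n2[s,t])
    }
  }
}")
}

#' Cross-domain correlation of metacognitive efficiency
#'
#' Joint hierarchical model for the same subjects measured in two tasks
#' (domains): the pair of subject-level log-efficiencies is drawn from a
#' bivariate Gaussian whose correlation coefficient `rho` is estimated along
#' with per-task group means. Priors: `mu_M` ~ Normal(0, 1) per task,
#' `sigma_M` via precision ~ Gamma(0.001, 0.001) (inverse-square-root
#' gamma on the SD), `rho` ~ Uniform(-1, 1). Uncertainty in each subject's
#' efficiency propagates into the correlation estimate, unlike correlating
#' point estimates. No parameter expansion is used in this variant.
#'
#' @param data1,data2 Confidence counts for the same subjects in task 1 and
#'   task 2 (any form accepted by [as_counts_list()]; >= 5 subjects, equal
#'   lengths, matched order).
#' @inheritParams fit_metad_group
#' @return A `metad_corr_fit` object with elements `samples` (tibble:
#'   chain, iteration, `rho`, `mu_logMratio_1`, `mu_logMratio_2`,
#'   `sigma_M_1`, `sigma_M_2`), `mcmc`, `rhat`, `dic`, `type1` (per task)
#'   and `spec`. Has `tidy()` and `glance()` methods.
#' @export
fit_metad_correlation <- function(data1, data2, n_chains = 3,
                                  n_samples = 10000, n_burnin = 1000,
                                  seed = NULL) {
  cl1 <- as_counts_list(data1)
  cl2 <- as_counts_list(data2)
  if (length(cl1) != length(cl2)) {
    stop("both tasks must contain the same subjects (equal lengths).",
         call. = FALSE)
  }
  if (length(cl1) < 5) {
    stop("the correlation model requires at least 5 subjects.",
         call. = FALSE)
  }
  stopifnot(n_chains >= 2, n_burnin >= 1, n_samples > n_burnin)
  if (is.null(seed)) seed <- sample.int(2^30, 1)
  k <- cl1[[1]]$k
  ks <- vapply(c(cl1, cl2), function(x) x$k, integer(1))
  if (!all(ks == k)) {
    stop("all subjects and tasks must share the same number of rating ",
         "levels.", call. = FALSE)
  }

  t1a <- .hier_type1(cl1)
  t1b <- .hier_type1(cl2)
  if (any(t1a$excluded) || any(t1b$excluded)) {
    drop <- t1a$excluded | t1b$excluded
    warning(sum(drop), " subject(s) excluded from both tasks (d' = 0 in ",
            "at least one task).", call. = FALSE)
    cl1 <- cl1[!drop]; cl2 <- cl2[!drop]
    t1a <- t1a[!drop, ]; t1b <- t1b[!drop, ]
  }
  S <- length(cl1)
  if (S < 5) stop("fewer than 5 subjects remain after exclusions.",
                  call. = FALSE)

  jags_data <- list(
    S = S, K = k,
    counts_S1 = array(c(do.call(rbind, lapply(cl1, `[[`, "nR_S1")),
                        do.call(rbind, lapply(cl2, `[[`, "nR_S1"))),
                      dim = c(S, 2 * k, 2)),
    counts_S2 = array(c(do.call(rbind, lapply(cl1, `[[`, "nR_S2")),
                        do.call(rbind, lapply(cl2, `[[`, "nR_S2"))),
                      dim = c(S, 2 * k, 2)),
    n1 = cbind(vapply(cl1, function(x) sum(x$nR_S1), numeric(1)),
               vapply(cl2, function(x) sum(x$nR_S1), numeric(1))),
    n2 = cbind(vapply(cl1, function(x) sum(x$nR_S2), numeric(1)),
               vapply(cl2, function(x) sum(x$nR_S2), numeric(1))),
    d1 = cbind(t1a$d_prime, t1b$d_prime),
    cratio = cbind(t1a$c_rel, t1b$c_rel),
    pRS1 = array(c(stats::pnorm(t1a$c + t1a$d_prime / 2),
                   stats::pnorm(t1a$c - t1a$d_prime / 2),
                   stats::pnorm(t1b$c + t1b$d_prime / 2),
                   stats::pnorm(t1b$c - t1b$d_prime / 2)),
                 dim = c(S, 2, 2))
  )
  inits <- .chain_inits(n_chains, seed, S, k, cbind(t1a$c, t1b$c),
                        n_tasks = 2)
  monitors <- c("rho", "mu_M", "sigma_M", "logM", "cS1", "cS2")
  mcmc <- .run_jags(.jags_corr_model(k), jags_data, inits, n_chains,
                    n_burnin, n_samples, monitors)

  pooled <- do.call(rbind, lapply(mcmc, as.matrix))
  rhat_tbl <- tibble::tibble(
    parameter = colnames(pooled),
    rhat = vapply(colnames(pooled), function(p) {
      rhat(sapply(mcmc, function(ch) as.numeric(ch[, p])))
    }, numeric(1))
  )
  if (any(rhat_tbl$rhat >= 1.1, na.rm = TRUE)) {
    worst <- rhat_tbl[which.max(rhat_tbl$rhat), ]
    warning(sum(rhat_tbl$rhat >= 1.1, na.rm = TRUE), " parameter(s) have ",
            "R-hat >= 1.1 (worst: ", worst$parameter, " = ",
            signif(worst$rhat, 3), "; rho = ",
            signif(rhat_tbl$rhat[rhat_tbl$parameter == "rho"], 4),
            "). Inspect `$rhat` and consider more samples.", call. = FALSE)
  }

  logM <- .extract_array(pooled, "logM", c(S, 2))
  cS1 <- .extract_array(pooled, "cS1", c(S, k - 1, 2))
  cS2 <- .extract_array(pooled, "cS2", c(S, k - 1, 2))
  slice_task <- function(a, t) array(a[, , , t], dim = dim(a)[1:3])
  dev <- .deviance_trace(logM[, , 1], slice_task(cS1, 1), slice_task(cS2, 1),
                         t1a$d_prime, t1a$c_rel, cl1) +
    .deviance_trace(logM[, , 2], slice_task(cS1, 2), slice_task(cS2, 2),
                    t1b$d_prime, t1b$c_rel, cl2)
  at_mean <- function(task, t1x, clx) {
    .deviance_trace(
      matrix(colMeans(logM[, , task]), 1),
      array(apply(slice_task(cS1, task), c(2, 3), mean), c(1, S, k - 1)),
      array(apply(slice_task(cS2, task), c(2, 3), mean), c(1, S, k - 1)),
      t1x$d_prime, t1x$c_rel, clx
    )
  }
  dev_at_mean <- at_mean(1, t1a, cl1) + at_mean(2, t1b, cl2)
  dic_val <- dic(dev, dev_at_mean)

  samples <- tibble::tibble(
    chain = rep(seq_len(n_chains), each = n_samples),
    iteration = rep(seq_len(n_samples), n_chains),
    rho = pooled[, "rho"],
    mu_logMratio_1 = pooled[, "mu_M[1]"],
    mu_logMratio_2 = pooled[, "mu_M[2]"],
    sigma_M_1 = pooled[, "sigma_M[1]"],
    sigma_M_2 = pooled[, "sigma_M[2]"]
  )

  structure(list(
    samples = samples,
    mcmc = mcmc,
    rhat = rhat_tbl,
    dic = dic_val,
    deviance = dev,
    type1 = list(task1 = t1a, task2 = t1b),
    spec = list(n_chains = n_chains, n_samples = n_samples,
                n_burnin = n_burnin, seed = seed, k = k, n_subjects = S)
  ), class = "metad_corr_fit")
}

#' @export
print.metad_corr_fit <- function(x, ...) {
  ci <- calc_ci(x$samples$rho)
  cat("<metad_corr_fit>", x$spec$n_subjects, "subjects, two tasks\n")
  cat(sprintf("  rho: mean %.3f, 95%% CI [%.3f, %.3f]\n",
              mean(x$samples$rho), ci$lo, ci$hi))
  invisible(x)
}

#' @export
tidy.metad_corr_fit <- function(x, ...) {
  pars <- c("rho", "mu_logMratio_1", "mu_logMratio_2", "sigma_M_1",
            "sigma_M_2")
  dplyr::bind_rows(purrr::map(pars, function(p) {
    v <- x$samples[[p]]
    ci <- calc_ci(v); hdi <- calc_hdi(v)
    tibble::tibble(term = p, estimate = mean(v), std.error = stats::sd(v),
                   ci_lo = ci$lo, ci_hi = ci$hi,
                   hdi_lo = hdi$lo, hdi_hi = hdi$hi)
  }))
}

#' @export
glance.metad_corr_fit <- function(x, ...) {
  ci <- calc_ci(x$samples$rho)
  tibble::tibble(
    rho = mean(x$samples$rho), ci_lo = ci$lo, ci_hi = ci$hi,
    rhat_rho = x$rhat$rhat[match("rho", x$rhat$parameter)],
    dic = x$dic, n_subjects = x$spec$n_subjects,
    n_samples = x$spec$n_chains * x$spec$n_samples
  )
}
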