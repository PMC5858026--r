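# Seed handling: all simulators take an integer `seed` and restore the
# caller's RNG state on exit, so seeded calls are reproducible without
# clobbering the session RNG.
local_seed <- function(seed, envir = parent.frame()) {
  if (is.null(seed)) return(invisible(NULL))
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  expr <- if (has_old) {
    bquote(assign(".Random.seed", .(old), envir = globalenv()))
  } else {
    quote(if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  }
  do.call(on.exit, list(expr, add = TRUE), envir = envir)
  invisible(NULL)
}

# Deterministic sub-seed for (seed, subject index, stream); keeps subject
# draws reproducible independent of how many subjects are simulated.
sub_seed <- function(seed, s, stream = 1L) {
  as.integer((as.numeric(seed) * 48271 + s * 7919 + stream * 104729) %%
               2147483629)
}

#' Simulate confidence counts with independent control of d' and meta-d'
#'
#' Generates one subject's confidence-count pair from a two-stage type 2 SDT
#' model. First, the four type 1 response-class sizes (hits, misses, false
#' alarms, correct rejections) are drawn from the binomial distributions
#' implied by `d_prime` and `c` under the equal-variance Gaussian model;
#' trials are split equally between S1 and S2 stimuli (an odd trial goes to
#' S2). Second, each class's confidence counts are drawn from the
#' multinomial with cell probabilities given by [type2_probs()] evaluated at
#' meta-d' = `mratio * d_prime`, meta-c = `(c/d') * meta-d'`, and type 2
#' criteria placed at `meta_c + c2` ("S2" side) and `meta_c - rev(c2_S1)`
#' ("S1" side). This decouples type 1 performance from the fidelity of
#' confidence: `mratio` is the generative metacognitive efficiency.
#'
#' @param n_trials Total number of trials (>= 2).
#' @param d_prime Generative type 1 sensitivity (> 0).
#' @param c Type 1 criterion.
#' @param c2 Ascending positive offsets of the k-1 "S2" type 2 criteria from
#'   meta_c. Default `c(0.5, 1, 1.5)` (4 rating levels).
#' @param mratio Target meta-d'/d' (> 0).
#' @param seed Integer seed; identical seeds give identical counts.
#' @param c2_S1 Optional offsets for the "S1" side; defaults to mirroring
#'   `c2`.
#' @return A [confidence_counts()] object.
#' @examples
#' metad_sim(n_trials = 400, d_prime = 2, c = 0, mratio = 0.8, seed = 1)
#' @export
metad_sim <- function(n_trials, d_prime, c = 0, c2 = c(0.5, 1, 1.5),
                      mratio = 1, seed = NULL, c2_S1 = c2) {
  if (!is.numeric(n_trials) || n_trials < 2) {
    stop("`n_trials` must be at least 2.", call. = FALSE)
  }
  if (!is.numeric(mratio) || mratio <= 0) {
    stop("`mratio` must be positive.", call. = FALSE)
  }
  if (d_prime <= 0) {
    stop("`d_prime` must be positive (c' = c/d' must be defined).",
         call. = FALSE)
  }
  if (is.unsorted(c2) || any(c2 <= 0) || is.unsorted(c2_S1) || any(c2_S1 <= 0)) {
    stop("`c2` and `c2_S1` must be ascending positive offsets.",
         call. = FALSE)
  }
  local_seed(seed)
  n_s1 <- floor(n_trials / 2)
  n_s2 <- n_trials - n_s1
  hr <- stats::pnorm(d_prime / 2 - c)
  far <- stats::pnorm(-d_prime / 2 - c)
  n_hit <- stats::rbinom(1, n_s2, hr)
  n_miss <- n_s2 - n_hit
  n_fa <- stats::rbinom(1, n_s1, far)
  n_cr <- n_s1 - n_fa

  meta_d <- mratio * d_prime
  meta_c <- (c / d_prime) * meta_d
  par <- metad_params(meta_d, meta_c,
                      cS1 = meta_c - rev(c2_S1), cS2 = meta_c + c2)
  tab <- .t2p_table(par)
  k <- par$k
  draw <- function(n, p) {
    if (n == 0) return(rep(0, k))
    if (anyNA(p)) {
      stop("confidence probabilities are degenerate (a response region ",
           "has vanishing mass) for meta_d = ", signif(meta_d, 4),
           "; the requested parameters are too extreme to simulate.",
           call. = FALSE)
    }
    as.numeric(stats::rmultinom(1, n, p))
  }
  cr <- draw(n_cr, tab$S1$rS1)      # stim S1, resp S1 (correct rejection)
  fa <- draw(n_fa, tab$S1$rS2)      # stim S1, resp S2 (false alarm)
  miss <- draw(n_miss, tab$S2$rS1)  # stim S2, resp S1 (miss)
  hit <- draw(n_hit, tab$S2$rS2)    # stim S2, resp S2 (hit)
  # resp S1 cells are ordered conf k..1; resp S2 cells conf 1..k
  confidence_counts(nR_S1 = c(rev(cr), fa), nR_S2 = c(rev(miss), hit))
}

#' Simulate a group of subjects with heterogeneous d'
#'
#' Draws each subject's type 1 sensitivity from Normal(`d_prime_mean`,
#' `d_prime_sd`) (floored at 0.1 so the contract is total) and simulates
#' their confidence counts with [metad_sim()]. Every subject consumes
#' independent sub-seeds derived deterministically from `seed` and the
#' subject index, so subject `s`'s data do not depend on `n_subjects`.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param n_trials Trials per subject.
#' @param d_prime_mean,d_prime_sd Mean and SD of the per-subject d' draws.
#' @param c Type 1 criterion shared by all subjects.
#' @param c2 Type 2 criterion offsets, as in [metad_sim()].
#' @param mratio Generative meta-d'/d'; either a scalar shared by the group
#'   or a vector of length `n_subjects`.
#' @param seed Integer seed.
#' @return A tibble with one row per subject: `subject`, `d_prime` (true
#'   generative value), `mratio` (true), and a `counts` list-column of
#'   [confidence_counts()].
#' @examples
#' simulate_group(n_subjects = 3, n_trials = 400, mratio = 0.8, seed = 1)
#' @export
simulate_group <- function(n_subjects, n_trials, d_prime_mean = 2,
                           d_prime_sd = 0.2, c = 0, c2 = c(0.5, 1, 1.5),
                           mratio = 0.8, seed = NULL) {
  stopifnot(n_subjects >= 1, d_prime_sd >= 0)
  if (!length(mratio) %in% c(1L, n_subjects)) {
    stop("`mratio` must have length 1 or `n_subjects`.", call. = FALSE)
  }
  mratio <- rep_len(mratio, n_subjects)
  if (is.null(seed)) seed <- sample.int(2^30, 1)
  rows <- purrr::map(seq_len(n_subjects), function(s) {
    local_seed(sub_seed(seed, s, 1L))
    d_s <- max(stats::rnorm(1, d_prime_mean, d_prime_sd), 0.1)
    cc <- metad_sim(n_trials, d_s, c = c, c2 = c2, mratio = mratio[s],
                    seed = sub_seed(seed, s, 2L))
    tibble::tibble(subject = s, d_prime = d_s, mratio = mratio[s],
                   counts = list(cc))
  })
  dplyr::bind_rows(rows)
}

#' Simulate two tasks with correlated metacognitive efficiencies
#'
#' Per-subject log-efficiencies for the two tasks are drawn from a bivariate
#' Gaussian with means `mu_logm`, SDs `sd_logm` and correlation `rho`;
#' per-task d' is drawn independently from Normal(`d_prime_mean`,
#' `d_prime_sd`). Confidence counts are then generated per task with
#' [metad_sim()].
#'
#' @inheritParams simulate_group
#' @param mu_logm,sd_logm Length-2 (or scalar) means and SDs of the
#'   bivariate Gaussian over log(meta-d'/d').
#' @param rho Generative correlation between the two log-efficiencies.
#' @return A tibble with one row per subject: `subject`, `d_prime_1`,
#'   `d_prime_2`, `logm_1`, `logm_2`, and list-columns `counts_1`,
#'   `counts_2`.
#' @export
simulate_group_bivariate <- function(n_subjects, n_trials,
                                     mu_logm = c(0.8, 0.8),
                                     sd_logm = c(0.5, 0.5), rho = 0.6,
                                     d_prime_mean = 2, d_prime_sd = 0.2,
                                     c = 0, c2 = c(0.5, 1, 1.5),
                                     seed = NULL) {
  stopifnot(n_subjects >= 1, abs(rho) <= 1)
  mu_logm <- rep_len(mu_logm, 2)
  sd_logm <- rep_len(sd_logm, 2)
  if (is.null(seed)) seed <- sample.int(2^30, 1)
  rows <- purrr::map(seq_len(n_subjects), function(s) {
    local_seed(sub_seed(seed, s, 3L))
    z <- stats::rnorm(2)
    logm1 <- mu_logm[1] + sd_logm[1] * z[1]
    logm2 <- mu_logm[2] + sd_logm[2] * (rho * z[1] + sqrt(1 - rho^2) * z[2])
    d1 <- max(stats::rnorm(1, d_prime_mean, d_prime_sd), 0.1)
    d2 <- max(stats::rnorm(1, d_prime_mean, d_prime_sd), 0.1)
    cc1 <- metad_sim(n_trials, d1, c = c, c2 = c2, mratio = exp(logm1),
                     seed = sub_seed(seed, s, 4L))
    cc2 <- metad_sim(n_trials, d2, c = c, c2 = c2, mratio = exp(logm2),
                     seed = sub_seed(seed, s, 5L))
    tibble::tibble(subject = s, d_prime_1 = d1, d_prime_2 = d2,
                   logm_1 = logm1, logm_2 = logm2,
                   counts_1 = list(cc1), counts_2 = list(cc2))
  })
  dplyr::bind_rows(rows)
}

#' Trial-level observer with noisy confidence
#'
#' Simulates an observer whose decision is based on the evidence sample `x`
#' (Normal(±d'/2, 1), decision `x > c`), but whose confidence rating is
#' based on `x + Normal(0, noise_sd)` — Gaussian noise corrupts the internal
#' state underpinning confidence but not the decision itself. The noisy
#' value is binned by the confidence criteria on the chosen-response side of
#' `c` (`c + c2` for "S2" responses, mirrored for "S1"); noisy values that
#' cross to the other side of `c` are clamped to the lowest-confidence bin,
#' since the decision is not revisited. With `noise_sd = 0` this is the
#' ideal type 2 observer, for which meta-d' equals d'.
#'
#' @inheritParams metad_sim
#' @param noise_sd Standard deviation of the confidence noise (>= 0).
#' @return A [confidence_counts()] object.
#' @export
simulate_noisy_confidence <- function(n_trials, d_prime, c = 0,
                                      c2 = c(0.5, 1, 1.5), noise_sd = 0,
                                      seed = NULL) {
  stopifnot(noise_sd >= 0, n_trials >= 2)
  if (is.unsorted(c2) || any(c2 <= 0)) {
    stop("`c2` must be ascending positive offsets.", call. = FALSE)
  }
  local_seed(seed)
  k <- length(c2) + 1L
  n_s1 <- floor(n_trials / 2)
  n_s2 <- n_trials - n_s1
  stim <- rep(c(-1, 1), c(n_s1, n_s2))            # -1 = S1, +1 = S2
  x <- stats::rnorm(n_trials, stim * d_prime / 2, 1)
  resp_s2 <- x > c
  x2 <- x + stats::rnorm(n_trials, 0, noise_sd)
  conf <- integer(n_trials)
  up_edges <- c + c2
  lo_edges <- c - rev(c2)
  # confidence = 1 + number of same-side criteria exceeded; cross-side
  # values clamp to confidence 1.
  conf[resp_s2] <- 1L + rowSums(outer(x2[resp_s2], up_edges, `>`))
  conf[!resp_s2] <- 1L + rowSums(outer(x2[!resp_s2], lo_edges, `<`))
  cell <- ifelse(resp_s2, k + conf, k + 1L - conf)  # position in 2k vector
  nR_S1 <- tabulate(cell[stim == -1], nbins = 2 * k)
  nR_S2 <- tabulate(cell[stim == 1], nbins = 2 * k)
  confidence_counts(nR_S1, nR_S2)
}
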