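#' Type 1 signal detection statistics from confidence counts
#'
#' Computes sensitivity d', criterion c, and the relative criterion
#' c' = c/d' from the response margins of a confidence-count pair, using the
#' standard equal-variance Gaussian formulae
#' \deqn{d' = \Phi^{-1}(HR) - \Phi^{-1}(FAR), \quad
#'       c = -\tfrac{1}{2}(\Phi^{-1}(HR) + \Phi^{-1}(FAR))}
#' where HR is the probability of an "S2" response to an S2 stimulus and FAR
#' the probability of an "S2" response to an S1 stimulus.
#'
#' When `padding > 0` it is added to every one of the 4k count cells before
#' rates are computed (the generalisation of the log-linear correction for
#' zero cells). With `padding = 0`, a hit or false-alarm rate of exactly 0 or
#' 1 is an error. When d' = 0 the relative criterion is undefined and
#' returned as `NaN` with a warning, so group pipelines can skip the subject.
#'
#' @param counts A [confidence_counts()] object.
#' @param padding Non-negative constant added to every cell before computing
#'   rates. Default 0.
#' @return A one-row tibble with columns `d_prime`, `c`, `c_rel`, `hr`,
#'   `far`.
#' @examples
#' cc <- confidence_counts(c(100, 50, 20, 10, 5, 1), c(3, 7, 8, 12, 27, 89))
#' type1_stats(cc)
#' @export
type1_stats <- function(counts, padding = 0) {
  stopifnot(is_confidence_counts(counts))
  if (!is.numeric(padding) || length(padding) != 1 || padding < 0) {
    stop("`padding` must be a single non-negative number.", call. = FALSE)
  }
  k <- counts$k
  s1 <- counts$nR_S1 + padding
  s2 <- counts$nR_S2 + padding
  hr <- sum(s2[(k + 1):(2 * k)]) / sum(s2)
  far <- sum(s1[(k + 1):(2 * k)]) / sum(s1)
  if (padding == 0 && (hr %in% c(0, 1) || far %in% c(0, 1))) {
    stop("hit or false-alarm rate is exactly 0 or 1; supply `padding > 0` ",
         "(e.g. padding = 1/(2 * k)) to apply an edge correction.",
         call. = FALSE)
  }
  d_prime <- stats::qnorm(hr) - stats::qnorm(far)
  c1 <- -0.5 * (stats::qnorm(hr) + stats::qnorm(far))
  if (d_prime == 0) {
    warning("d' is exactly 0; relative criterion c' = c/d' is undefined ",
            "(returned as NaN).", call. = FALSE)
    c_rel <- NaN
  } else {
    c_rel <- c1 / d_prime
  }
  tibble::tibble(d_prime = d_prime, c = c1, c_rel = c_rel, hr = hr, far = far)
}

#' Meta-level SDT parameter set
#'
#' Bundles the generative parameters of the type 2 observer model: the
#' meta-level sensitivity `meta_d`, the meta-level type 1 criterion `meta_c`
#' (anchored to the observed type 1 bias through meta-c' = c', i.e.
#' `meta_c = c_rel * meta_d`), and the response-conditional type 2 criteria.
#' `cS1` are the k-1 criteria for "S1" responses (ascending, all at most
#' `meta_c`); `cS2` the k-1 criteria for "S2" responses (ascending, all at
#' least `meta_c`). The concatenation `(cS1, meta_c, cS2)` must be
#' nondecreasing; ties are permitted.
#'
#' @param meta_d Meta-level sensitivity (z-units).
#' @param meta_c Meta-level type 1 criterion (z-units).
#' @param cS1,cS2 Ascending numeric vectors of k-1 type 2 criteria.
#' @return An object of class `metad_params`.
#' @export
metad_params <- function(meta_d, meta_c, cS1, cS2) {
  if (length(cS1) != length(cS2)) {
    stop("`cS1` and `cS2` must have the same length (k - 1).", call. = FALSE)
  }
  if (length(cS1) < 1) {
    stop("at least one type 2 criterion per response is required (k >= 2).",
         call. = FALSE)
  }
  all_c <- c(cS1, meta_c, cS2)
  if (anyNA(all_c) || is.na(meta_d)) {
    stop("parameters must not contain missing values.", call. = FALSE)
  }
  if (is.unsorted(all_c)) {
    stop("criteria violate the ordinal constraint: (cS1, meta_c, cS2) ",
         "must be nondecreasing.", call. = FALSE)
  }
  structure(list(meta_d = meta_d, meta_c = meta_c,
                 cS1 = as.numeric(cS1), cS2 = as.numeric(cS2),
                 k = length(cS1) + 1L),
            class = "metad_params")
}

#' @export
print.metad_params <- function(x, ...) {
  cat("<metad_params> meta_d =", format(x$meta_d, digits = 4),
      " meta_c =", format(x$meta_c, digits = 4), "\n")
  cat("  cS1:", format(x$cS1, digits = 4), "\n")
  cat("  cS2:", format(x$cS2, digits = 4), "\n")
  invisible(x)
}

# Conditional type 2 probability cells for one stimulus mean.
# Returns list(rS1 = p[conf 1..k | resp S1], rS2 = p[conf 1..k | resp S2]).
# Region below meta_c belongs to "S1" responses, partitioned by cS1;
# confidence increases away from meta_c on both sides.
.t2p_one_stim <- function(mu, meta_d, meta_c, cS1, cS2) {
  k <- length(cS1) + 1L
  lo <- c(-Inf, cS1, meta_c)            # k + 1 edges below/at meta_c
  hi <- c(meta_c, cS2, Inf)             # k + 1 edges at/above meta_c
  # lower tails for the region below meta_c, upper tails above: keeps the
  # cell/mass ratios well defined far into the tails (large |meta_d|).
  p_lo <- stats::pnorm(lo - mu)
  q_hi <- stats::pnorm(hi - mu, lower.tail = FALSE)
  mass_s1 <- p_lo[k + 1]                # P(resp = S1 | stim)
  mass_s2 <- q_hi[1]
  # cells below meta_c, left to right = conf k .. conf 1
  cells_s1 <- diff(p_lo)
  # cells above meta_c, left to right = conf 1 .. conf k
  cells_s2 <- q_hi[1:k] - q_hi[2:(k + 1)]
  list(rS1 = rev(cells_s1) / mass_s1,
       rS2 = cells_s2 / mass_s2,
       mass_s1 = mass_s1, mass_s2 = mass_s2)
}

# Full conditional table as a plain list indexed [[stim]][[resp]],
# each a length-k probability vector over confidence 1..k.
.t2p_table <- function(params) {
  mu <- c(S1 = -params$meta_d / 2, S2 = params$meta_d / 2)
  out <- lapply(mu, .t2p_one_stim, meta_d = params$meta_d,
                meta_c = params$meta_c, cS1 = params$cS1, cS2 = params$cS2)
  names(out) <- c("S1", "S2")
  out
}

#' Type 2 confidence probabilities implied by a meta-level SDT model
#'
#' Under the equal-variance Gaussian observer, evidence on S1-stimulus trials
#' is distributed Normal(-meta_d/2, 1) and on S2 trials Normal(+meta_d/2, 1).
#' The evidence axis is partitioned by `(cS1, meta_c, cS2)`; the probability
#' of confidence level `y` given stimulus and response is the Gaussian mass
#' of the corresponding cell, renormalised by the total mass of the response
#' region (below `meta_c` for "S1" responses, above for "S2"). Confidence
#' increases with distance from `meta_c` on both sides.
#'
#' @param params A [metad_params()] object.
#' @return A tibble with columns `stimulus`, `response`, `confidence`,
#'   `prob`; within each (stimulus, response) pair the probabilities sum
#'   to 1.
#' @examples
#' p <- metad_params(meta_d = 2, meta_c = 0,
#'                   cS1 = c(-1.5, -1, -0.5), cS2 = c(0.5, 1, 1.5))
#' type2_probs(p)
#' @export
type2_probs <- function(params) {
  stopifnot(inherits(params, "metad_params"))
  tab <- .t2p_table(params)
  k <- params$k
  out <- tidyr::expand_grid(stimulus = c("S1", "S2"),
                            response = c("S1", "S2"),
                            confidence = seq_len(k))
  out$prob <- purrr::pmap_dbl(out, function(stimulus, response, confidence) {
    tab[[stimulus]][[paste0("r", response)]][confidence]
  })
  if (anyNA(out$prob)) {
    stop("type 2 probabilities are undefined (NaN) for these parameters; ",
         "a response region has vanishing probability mass.", call. = FALSE)
  }
  out
}

# Per-confidence counts of correct and incorrect trials, response-collapsed.
.acc_by_conf <- function(counts) {
  k <- counts$k
  conf <- seq_len(k)
  # resp S1 cells run conf k..1 over indices 1..k; resp S2 cells conf 1..k
  # over indices (k+1)..2k.
  correct <- rev(counts$nR_S1[1:k]) + counts$nR_S2[(k + 1):(2 * k)]
  incorrect <- counts$nR_S1[(k + 1):(2 * k)] + rev(counts$nR_S2[1:k])
  tibble::tibble(confidence = conf, correct = correct, incorrect = incorrect)
}

#' Type 2 ROC points from confidence counts
#'
#' The response-collapsed type 2 ROC relates the conditional probabilities
#' of high confidence given a correct versus an incorrect type 1 decision:
#' point `y` has coordinates `FAR2 = P(conf >= y | incorrect)` and
#' `HR2 = P(conf >= y | correct)`. Cumulating over thresholds from `k + 1`
#' (no rating qualifies) down to 1 gives `k + 1` points from (0, 0) to
#' (1, 1).
#'
#' @param counts A [confidence_counts()] object with at least one correct
#'   and one incorrect trial.
#' @return A tibble with columns `threshold`, `far2`, `hr2`, ordered from
#'   (0, 0) to (1, 1).
#' @export
type2_roc <- function(counts) {
  stopifnot(is_confidence_counts(counts))
  acc <- .acc_by_conf(counts)
  n_cor <- sum(acc$correct)
  n_inc <- sum(acc$incorrect)
  if (n_cor == 0 || n_inc == 0) {
    stop("type 2 ROC requires at least one correct and one incorrect trial.",
         call. = FALSE)
  }
  k <- counts$k
  hr2 <- rev(cumsum(rev(acc$correct))) / n_cor
  far2 <- rev(cumsum(rev(acc$incorrect))) / n_inc
  tibble::tibble(threshold = (k + 1):1,
                 far2 = c(0, far2[k:1]),
                 hr2 = c(0, hr2[k:1]))
}

#' Area under the type 2 ROC
#'
#' Trapezoidal area under the response-collapsed type 2 ROC — a
#' non-parametric measure of metacognitive sensitivity: how well confidence
#' ratings discriminate correct from incorrect decisions. 0.5 indicates
#' chance-level metacognition, 1 perfect discrimination.
#'
#' @inheritParams type2_roc
#' @return A single number in \[0, 1\].
#' @export
auroc2 <- function(counts) {
  roc <- type2_roc(counts)
  sum(diff(roc$far2) * (utils::head(roc$hr2, -1) + utils::tail(roc$hr2, -1)) / 2)
}
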