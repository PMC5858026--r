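# Shared fixtures and independent oracles used across test files.

# The worked count-vector pair from the data-preparation walkthrough
# (3 rating levels).
tutorial_counts <- function() {
  confidence_counts(c(100, 50, 20, 10, 5, 1), c(3, 7, 8, 12, 27, 89))
}

# Quadrature oracle for the type 2 probability table: numerical integration
# of the Gaussian evidence densities over each criterion bin, renormalised
# by the integrated response-region mass. Independent of the package's
# closed-form pnorm construction.
oracle_type2_probs <- function(meta_d, meta_c, cS1, cS2) {
  k <- length(cS1) + 1L
  rows <- list()
  for (stim in c("S1", "S2")) {
    mu <- if (stim == "S1") -meta_d / 2 else meta_d / 2
    cell <- function(a, b) {
      if (a >= b) return(0)
      stats::integrate(function(x) stats::dnorm(x, mu, 1), a, b,
                       rel.tol = 1e-12, abs.tol = 1e-13)$value
    }
    lo <- c(-Inf, cS1, meta_c)
    hi <- c(meta_c, cS2, Inf)
    s1_cells <- mapply(cell, lo[1:k], lo[2:(k + 1)])   # conf k..1
    s2_cells <- mapply(cell, hi[1:k], hi[2:(k + 1)])   # conf 1..k
    rows[[stim]] <- rbind(
      data.frame(stimulus = stim, response = "S1", confidence = 1:k,
                 prob = rev(s1_cells) / sum(s1_cells)),
      data.frame(stimulus = stim, response = "S2", confidence = 1:k,
                 prob = s2_cells / sum(s2_cells))
    )
  }
  out <- rbind(rows$S1, rows$S2)
  out[order(out$stimulus, out$response, out$confidence), ]
}

# Random valid meta-level parameter settings for property tests.
random_metad_params <- function(k = sample(2:5, 1)) {
  meta_d <- stats::runif(1, -2, 3)
  meta_c <- stats::runif(1, -0.5, 0.5)
  metad_params(
    meta_d, meta_c,
    cS1 = meta_c - rev(cumsum(stats::runif(k - 1, 0.05, 1))),
    cS2 = meta_c + cumsum(stats::runif(k - 1, 0.05, 1))
  )
}

# Probability table as a lookup vector keyed by (stim, resp, conf) for
# term-by-term comparisons.
prob_lookup <- function(tbl) {
  stats::setNames(tbl$prob, paste(tbl$stimulus, tbl$response,
                                  tbl$confidence))
}
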