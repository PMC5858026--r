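#' Multinomial type 2 log-likelihood
#'
#' Log-likelihood of a confidence-count pair under the type 2 observer
#' model: the sum over (confidence, stimulus, response) cells of
#' `n * log P(conf | stim, resp)`, with probabilities from [type2_probs()].
#' Cells with zero counts contribute 0 even when their model probability is
#' 0; the result is `-Inf` only when a positive count meets a zero
#' probability.
#'
#' @param params A [metad_params()] object.
#' @param counts A [confidence_counts()] object (counts may be non-integer,
#'   e.g. after padding).
#' @return The log-likelihood (a single number, possibly `-Inf`).
#' @export
loglik_type2 <- function(params, counts) {
  stopifnot(inherits(params, "metad_params"), is_confidence_counts(counts))
  if (params$k != counts$k) {
    stop("`params` and `counts` disagree on the number of rating levels.",
         call. = FALSE)
  }
  tab <- .t2p_table(params)
  k <- counts$k
  # cell layout of each 2k vector: conf k..1 for resp S1, conf 1..k for S2
  p_s1 <- c(rev(tab$S1$rS1), tab$S1$rS2)
  p_s2 <- c(rev(tab$S2$rS1), tab$S2$rS2)
  n <- c(counts$nR_S1, counts$nR_S2)
  p <- c(p_s1, p_s2)
  nz <- n > 0
  if (any(nz & p == 0)) return(-Inf)
  sum(n[nz] * log(p[nz]))
}

# Assemble metad_params from the optimizer's unconstrained parameter vector:
# theta = (meta_d, log-increments a[1..k-1] above meta_c, b[1..k-1] below).
# meta_c is tied to meta_d through the type 1 bias: meta_c = c_rel * meta_d.
.theta_to_params <- function(theta, k, c_rel) {
  meta_d <- theta[1]
  meta_c <- c_rel * meta_d
  a <- exp(theta[2:k])
  b <- exp(theta[(k + 1):(2 * k - 1)])
  metad_params(meta_d, meta_c,
               cS1 = meta_c - rev(cumsum(b)),
               cS2 = meta_c + cumsum(a))
}

# Deterministic multi-start settings: scale factors on the d'-anchored
# starting meta_d and initial log-spacings of the criteria.
.fit_starts <- function(d_prime, k) {
  scales <- c(1, 0.5, 1.5, 0.25, 1)
  spacings <- c(log(0.5), log(0.5), log(0.5), log(0.3), log(1))
  lapply(seq_along(scales), function(i) {
    c(d_prime * scales[i], rep(spacings[i], 2 * (k - 1)))
  })
}

.fit_point <- function(counts, padding, objective, method_name) {
  stopifnot(is_confidence_counts(counts))
  k <- counts$k
  padded <- confidence_counts(counts$nR_S1 + padding, counts$nR_S2 + padding)
  t1 <- type1_stats(padded, padding = 0)
  if (is.nan(t1$c_rel)) {
    stop("type 1 d' is exactly 0 after padding; meta-level criterion is ",
         "undefined and the fit cannot proceed.", call. = FALSE)
  }
  obj <- function(theta) {
    par <- .theta_to_params(theta, k, t1$c_rel)
    v <- objective(par, padded)
    if (!is.finite(v)) 1e12 else v
  }
  best <- NULL
  for (start in .fit_starts(t1$d_prime, k)) {
    res <- tryCatch(
      stats::optim(start, obj, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-8)),
      error = function(e) NULL
    )
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) {
    warning("optimizer failed from every start; returning the first start ",
            "unoptimized with converged = FALSE.", call. = FALSE)
    theta <- .fit_starts(t1$d_prime, k)[[1]]
    best <- list(par = theta, value = obj(theta), convergence = 1L)
  }
  par <- .theta_to_params(best$par, k, t1$c_rel)
  structure(list(
    type1 = t1,
    params = par,
    meta_d = par$meta_d,
    mratio = par$meta_d / t1$d_prime,
    logL = if (method_name == "mle") -best$value else best$value,
    converged = best$convergence == 0,
    padding_used = padding,
    method = method_name,
    counts = counts
  ), class = "metad_fit")
}

#' Single-subject meta-d' by constrained maximum likelihood
#'
#' Estimates meta-d' and the 2(k-1) response-conditional type 2 criteria by
#' maximizing the multinomial type 2 likelihood ([loglik_type2()]), subject
#' to the constraints that the meta-level relative criterion equals the
#' observed type 1 relative criterion (meta-c' = c') and that the criteria
#' stand in their ordinal relationship. The constraint is enforced by
#' construction: criteria are parameterized as meta_c plus cumulative
#' positive increments, and meta_c is tied to meta_d via c'. Type 1 d' and c
#' are first computed from the (padded) counts and held fixed.
#'
#' Optimization uses quasi-Newton (BFGS) refinement from 5 deterministic
#' starts; the best is returned, with `converged` from the optimizer.
#'
#' @param counts A [confidence_counts()] object.
#' @param padding Edge-correction constant added to all 4k cells before
#'   fitting. Default 0.25.
#' @return A `metad_fit` object: a list with `type1` (tibble of d', c, c'),
#'   `params` (fitted [metad_params()]), `meta_d`, `mratio`, `logL`,
#'   `converged`, `padding_used`, `method`. Has [tidy()][generics::tidy] and
#'   [glance()][generics::glance] methods.
#' @examples
#' cc <- metad_sim(2000, d_prime = 2, mratio = 0.8, seed = 1)
#' fit <- fit_metad_mle(cc)
#' glance(fit)
#' @export
fit_metad_mle <- function(counts, padding = 0.25) {
  .fit_point(counts, padding,
             objective = function(par, cc) -loglik_type2(par, cc),
             method_name = "mle")
}

# Sum of squared differences between observed and model conditional type 2
# probabilities, over (stim, resp) cells whose response totals are nonzero.
.sse_type2 <- function(params, counts) {
  tab <- .t2p_table(params)
  k <- counts$k
  sse <- 0
  for (stim in c("S1", "S2")) {
    v <- if (stim == "S1") counts$nR_S1 else counts$nR_S2
    obs <- list(rS1 = rev(v[1:k]), rS2 = v[(k + 1):(2 * k)])
    for (resp in c("rS1", "rS2")) {
      tot <- sum(obs[[resp]])
      if (tot > 0) {
        sse <- sse + sum((obs[[resp]] / tot - tab[[stim]][[resp]])^2)
      }
    }
  }
  sse
}

#' Single-subject meta-d' by sum-of-squared error
#'
#' As [fit_metad_mle()], but minimizing the sum of squared differences
#' between observed and model type 2 conditional probabilities
#' P(conf | stim, resp), computed on the padded counts, over the same
#' constrained parameter space. Cells are unweighted: each (stimulus,
#' response, confidence) cell with a nonzero response total contributes its
#' squared probability error equally, regardless of how many trials fall in
#' that response class.
#'
#' @inheritParams fit_metad_mle
#' @return A `metad_fit` object; `logL` holds the minimized SSE value.
#' @export
fit_metad_sse <- function(counts, padding = 0.25) {
  .fit_point(counts, padding, objective = .sse_type2, method_name = "sse")
}

#' @export
print.metad_fit <- function(x, ...) {
  cat("<metad_fit> method =", toupper(x$method),
      " padding =", x$padding_used, "\n")
  cat(sprintf("  d' = %.3f  c = %.3f  meta-d' = %.3f  meta-d'/d' = %.3f\n",
              x$type1$d_prime, x$type1$c, x$meta_d, x$mratio))
  cat(sprintf("  %s = %.4f  converged = %s\n",
              if (x$method == "mle") "logL" else "SSE", x$logL, x$converged))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.metad_fit <- function(x, ...) {
  k <- x$params$k
  tibble::tibble(
    term = c("meta_d", "meta_c", paste0("cS1_", seq_len(k - 1)),
             paste0("cS2_", seq_len(k - 1))),
    estimate = c(x$meta_d, x$params$meta_c, x$params$cS1, x$params$cS2)
  )
}

#' @export
glance.metad_fit <- function(x, ...) {
  tibble::tibble(
    d_prime = x$type1$d_prime, c = x$type1$c, meta_d = x$meta_d,
    mratio = x$mratio, logL = x$logL, converged = x$converged,
    method = x$method, padding = x$padding_used,
    n_trials = n_trials(x$counts)
  )
}

#' Fit every subject of a counts table
#'
#' Maps [fit_metad_mle()] or [fit_metad_sse()] over the subjects of a counts
#' tibble (or list) and binds the one-row [glance()] summaries.
#'
#' @param data Counts in any form accepted by [as_counts_list()].
#' @param method `"mle"` or `"sse"`.
#' @param padding Edge-correction constant, as in [fit_metad_mle()].
#' @return A tibble with one row per subject (`subject` plus the `glance`
#'   columns) and a `fit` list-column holding the full `metad_fit` objects.
#' @export
fit_metad_subjects <- function(data, method = c("mle", "sse"),
                               padding = 0.25) {
  method <- match.arg(method)
  fitter <- if (method == "mle") fit_metad_mle else fit_metad_sse
  cl <- as_counts_list(data)
  rows <- purrr::imap(cl, function(cc, nm) {
    f <- tryCatch(fitter(cc, padding = padding), error = function(e) e)
    if (inherits(f, "error")) {
      warning("subject ", nm, " could not be fit (", conditionMessage(f),
              "); returning NA estimates for this subject.", call. = FALSE)
      return(dplyr::bind_cols(
        tibble::tibble(subject = nm, d_prime = NA_real_, c = NA_real_,
                       meta_d = NA_real_, mratio = NA_real_,
                       logL = NA_real_, converged = FALSE, method = method,
                       padding = padding, n_trials = n_trials(cc)),
        tibble::tibble(fit = list(NULL))
      ))
    }
    dplyr::bind_cols(tibble::tibble(subject = nm), glance(f),
                     tibble::tibble(fit = list(f)))
  })
  dplyr::bind_rows(rows)
}
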