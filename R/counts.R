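#' Confidence-rating count vectors
#'
#' Container for the raw data of a type 2 signal detection analysis: counts
#' of each (response, confidence) cell conditional on the presented stimulus
#' class. `nR_S1` holds counts following S1 stimuli, `nR_S2` counts following
#' S2 stimuli. Both vectors have length `2k`, where `k` is the number of
#' confidence levels, and follow the standard ordering convention:
#'
#' * entry 1: highest-confidence "S1" response
#' * entry `k`: lowest-confidence "S1" response
#' * entry `k + 1`: lowest-confidence "S2" response
#' * entry `2k`: highest-confidence "S2" response
#'
#' @param nR_S1,nR_S2 Non-negative numeric vectors of equal, even length
#'   `2k` with `k >= 2`.
#' @return An object of class `confidence_counts`: a list with elements
#'   `nR_S1`, `nR_S2` and `k`.
#' @examples
#' confidence_counts(c(100, 50, 20, 10, 5, 1), c(3, 7, 8, 12, 27, 89))
#' @export
confidence_counts <- function(nR_S1, nR_S2) {
  nR_S1 <- as.numeric(nR_S1)
  nR_S2 <- as.numeric(nR_S2)
  if (length(nR_S1) != length(nR_S2)) {
    stop("`nR_S1` and `nR_S2` must have equal length.", call. = FALSE)
  }
  n <- length(nR_S1)
  if (n %% 2 != 0 || n < 4) {
    stop("count vectors must have even length 2k with k >= 2, got length ",
         n, ".", call. = FALSE)
  }
  if (anyNA(nR_S1) || anyNA(nR_S2)) {
    stop("count vectors must not contain missing values.", call. = FALSE)
  }
  if (any(nR_S1 < 0) || any(nR_S2 < 0)) {
    stop("counts must be non-negative.", call. = FALSE)
  }
  structure(list(nR_S1 = nR_S1, nR_S2 = nR_S2, k = n %/% 2L),
            class = "confidence_counts")
}

#' @export
print.confidence_counts <- function(x, ...) {
  cat("<confidence_counts> k =", x$k, "rating levels,",
      sum(x$nR_S1) + sum(x$nR_S2), "trials\n")
  cat("  nR_S1:", x$nR_S1, "\n")
  cat("  nR_S2:", x$nR_S2, "\n")
  invisible(x)
}

is_confidence_counts <- function(x) inherits(x, "confidence_counts")

#' Coerce various inputs to a list of confidence_counts
#'
#' Accepts a single `confidence_counts`, a bare list of them, or a data frame
#' with either a `counts` list-column (as returned by [simulate_group()] and
#' [trials_to_counts()]) or wide columns `nR_S1_1 ... nR_S1_2k`,
#' `nR_S2_1 ... nR_S2_2k` (as written by [write_counts_csv()]).
#'
#' @param data Input in any of the accepted forms.
#' @return A named list of `confidence_counts`, one per subject.
#' @export
as_counts_list <- function(data) {
  if (is_confidence_counts(data)) {
    return(list(`1` = data))
  }
  if (is.data.frame(data)) {
    if ("counts" %in% names(data)) {
      out <- data$counts
      stopifnot(all(vapply(out, is_confidence_counts, logical(1))))
      names(out) <- if ("subject" %in% names(data)) {
        as.character(data$subject)
      } else {
        as.character(seq_along(out))
      }
      return(out)
    }
    s1_cols <- grep("^nR_S1_\\d+$", names(data), value = TRUE)
    s2_cols <- grep("^nR_S2_\\d+$", names(data), value = TRUE)
    if (length(s1_cols) == 0 || length(s1_cols) != length(s2_cols)) {
      stop("data frame must contain a `counts` list-column or matched ",
           "`nR_S1_*` / `nR_S2_*` columns.", call. = FALSE)
    }
    s1_cols <- s1_cols[order(as.integer(sub("^nR_S1_", "", s1_cols)))]
    s2_cols <- s2_cols[order(as.integer(sub("^nR_S2_", "", s2_cols)))]
    out <- lapply(seq_len(nrow(data)), function(i) {
      confidence_counts(as.numeric(data[i, s1_cols]),
                        as.numeric(data[i, s2_cols]))
    })
    names(out) <- if ("subject" %in% names(data)) {
      as.character(data$subject)
    } else {
      as.character(seq_len(nrow(data)))
    }
    return(out)
  }
  if (is.list(data) && all(vapply(data, is_confidence_counts, logical(1)))) {
    if (is.null(names(data))) names(data) <- as.character(seq_along(data))
    return(data)
  }
  stop("cannot interpret `data` as confidence counts.", call. = FALSE)
}

#' Convert a list of counts to a wide tibble
#'
#' One row per subject, columns `subject`, `nR_S1_1 ... nR_S1_2k`,
#' `nR_S2_1 ... nR_S2_2k`. The inverse of the wide form accepted by
#' [as_counts_list()].
#'
#' @param counts A `confidence_counts`, list of them, or tibble with a
#'   `counts` list-column.
#' @return A tibble in wide count format.
#' @export
counts_to_wide <- function(counts) {
  cl <- as_counts_list(counts)
  k2 <- 2L * cl[[1]]$k
  rows <- purrr::imap(cl, function(cc, nm) {
    if (2L * cc$k != k2) {
      stop("all subjects must share the same number of rating levels.",
           call. = FALSE)
    }
    v <- c(cc$nR_S1, cc$nR_S2)
    names(v) <- c(paste0("nR_S1_", seq_len(k2)), paste0("nR_S2_", seq_len(k2)))
    tibble::as_tibble_row(c(list(subject = nm), as.list(v)))
  })
  dplyr::bind_rows(rows)
}

#' Total number of trials in a counts object
#' @param counts A `confidence_counts`.
#' @return Integer trial count.
#' @export
n_trials <- function(counts) {
  stopifnot(is_confidence_counts(counts))
  sum(counts$nR_S1) + sum(counts$nR_S2)
}
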