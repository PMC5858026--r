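# Accept "S1"/"S2", 0/1, or 1/2 codings for stimulus / response columns and
# normalize to "S1"/"S2".
.normalize_side <- function(x, col) {
  x_chr <- toupper(trimws(as.character(x)))
  out <- dplyr::case_when(
    x_chr %in% c("S1", "0") ~ "S1",
    x_chr %in% c("S2", "1") ~ "S2",
    TRUE ~ NA_character_
  )
  if (anyNA(out)) {
    bad <- which(is.na(out))
    stop("column `", col, "` contains values other than S1/S2 (or 0/1) at ",
         "rows ", paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) ", ..." else "", ".", call. = FALSE)
  }
  out
}

#' Assemble confidence-count vectors from a trial-level table
#'
#' Converts a table with one row per trial into per-subject count-vector
#' pairs following the standard ordering convention (see
#' [confidence_counts()]): for each subject and stimulus class, cell
#' `(response, confidence)` counts are placed so that entry 1 is the
#' highest-confidence "S1" response and entry 2k the highest-confidence
#' "S2" response. Expanding the counts back to trials preserves the joint
#' (stimulus, response, confidence) contingency table.
#'
#' @param data A data frame with columns `stimulus`, `response` (coded
#'   `S1`/`S2` or `0`/`1`), `confidence` (integers `1..k`), and optionally
#'   `subject`. No missing values are allowed.
#' @param k Number of confidence levels. Default: inferred as
#'   `max(confidence)` (at least 2).
#' @return A tibble with one row per subject: `subject`, `n_trials`, and a
#'   `counts` list-column of [confidence_counts()].
#' @examples
#' trials <- tibble::tibble(stimulus = c("S1", "S1", "S2", "S2"),
#'                          response = c("S1", "S2", "S2", "S2"),
#'                          confidence = c(2, 1, 2, 2))
#' trials_to_counts(trials, k = 2)
#' @export
trials_to_counts <- function(data, k = NULL) {
  stopifnot(is.data.frame(data))
  required <- c("stimulus", "response", "confidence")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ",
         paste(missing_cols, collapse = ", "), ".", call. = FALSE)
  }
  if (nrow(data) == 0) {
    if (is.null(k)) {
      stop("`k` must be given for an empty trial table.", call. = FALSE)
    }
    return(tibble::tibble(subject = "1", n_trials = 0L,
                          counts = list(confidence_counts(rep(0, 2 * k),
                                                          rep(0, 2 * k)))))
  }
  if (!"subject" %in% names(data)) data$subject <- "1"
  if (anyNA(data[c("subject", required)])) {
    stop("trial table contains missing values.", call. = FALSE)
  }
  if (is.null(k)) k <- max(2L, max(data$confidence))
  conf <- data$confidence
  if (!is.numeric(conf) || any(conf != round(conf)) ||
      any(conf < 1 | conf > k)) {
    bad <- which(!is.numeric(conf) | conf != round(conf) | conf < 1 |
                   conf > k)
    stop("`confidence` must contain integers in 1..", k,
         "; offending rows: ", paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) ", ..." else "",
         ". Continuous ratings must be binned first (see ",
         "bin_confidence_quantiles()).", call. = FALSE)
  }
  stim <- .normalize_side(data$stimulus, "stimulus")
  resp <- .normalize_side(data$response, "response")
  # position in the 2k vector: resp S1 -> k + 1 - conf, resp S2 -> k + conf
  cell <- ifelse(resp == "S2", k + conf, k + 1L - conf)
  df <- tibble::tibble(subject = data$subject, stim = stim, cell = cell)
  out <- df |>
    dplyr::group_by(.data$subject) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      counts = list(confidence_counts(
        tabulate(.data$cell[.data$stim == "S1"], nbins = 2 * k),
        tabulate(.data$cell[.data$stim == "S2"], nbins = 2 * k)
      )),
      .groups = "drop"
    )
  out
}

#' Expand confidence counts back into a trial table
#'
#' The inverse of [trials_to_counts()] up to row order: one row per trial
#' with `stimulus`, `response`, `confidence`.
#'
#' @param counts A [confidence_counts()] object.
#' @return A tibble with `stimulus`, `response`, `confidence` columns.
#' @export
counts_to_trials <- function(counts) {
  stopifnot(is_confidence_counts(counts))
  k <- counts$k
  cells <- tibble::tibble(
    response = rep(c("S1", "S2"), each = k),
    confidence = c(k:1, 1:k)
  )
  one_stim <- function(v, stim) {
    idx <- rep(seq_len(2 * k), times = v)
    tibble::tibble(stimulus = stim, response = cells$response[idx],
                   confidence = cells$confidence[idx])
  }
  dplyr::bind_rows(one_stim(counts$nR_S1, "S1"), one_stim(counts$nR_S2, "S2"))
}

#' Bin continuous confidence ratings into quantile bins
#'
#' Computes empirical quantile edges of `values` and assigns each value an
#' integer bin 1..`n_bins` (1 = lowest confidence). Values tied with a bin
#' edge are assigned to the lower bin. Intended to be applied per subject
#' (confidence-scale usage is idiosyncratic), e.g. inside
#' `dplyr::mutate()` after `dplyr::group_by(subject)`.
#'
#' @param values Numeric vector of continuous ratings.
#' @param n_bins Number of bins (>= 2). There must be at least `n_bins`
#'   distinct values.
#' @return An integer vector of bins, same length as `values`.
#' @examples
#' bin_confidence_quantiles(1:100, 4)
#' @export
bin_confidence_quantiles <- function(values, n_bins) {
  stopifnot(is.numeric(values), n_bins >= 2)
  if (length(unique(values)) < n_bins) {
    stop("fewer than ", n_bins, " distinct rating values; use fewer bins.",
         call. = FALSE)
  }
  edges <- stats::quantile(values, probs = seq_len(n_bins - 1) / n_bins,
                           names = FALSE, type = 7)
  bins <- 1L + vapply(values, function(v) sum(v > edges), integer(1))
  bins
}

#' Read / write multi-subject counts CSV
#'
#' The on-disk format is one row per subject with a `subject` column and
#' wide count columns `nR_S1_1 ... nR_S1_2k`, `nR_S2_1 ... nR_S2_2k`
#' (comma-separated, header required, UTF-8).
#'
#' @param path File path.
#' @return `read_counts_csv()` returns a tibble with `subject` and a
#'   `counts` list-column; `write_counts_csv()` returns `path` invisibly.
#' @export
read_counts_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  cl <- as_counts_list(df)
  tibble::tibble(subject = names(cl), counts = unname(cl))
}

#' @rdname read_counts_csv
#' @param counts Counts in any form accepted by [as_counts_list()].
#' @export
write_counts_csv <- function(counts, path) {
  wide <- counts_to_wide(counts)
  utils::write.csv(wide, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
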