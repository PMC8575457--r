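#' Construct a spike train
#'
#' One extracellular recording trial: the merged spike times of all OSNs in
#' a sensillum (spike sorting is not attempted) together with the stimulus
#' timing. Odor reaches the antenna `delay` seconds after nominal stimulus
#' onset because of the air path, so all analysis windows are anchored at
#' *delivery* = `stimulus_onset + delivery_delay`.
#'
#' @param spike_times Numeric vector of spike times in seconds, sorted
#'   ascending, non-negative.
#' @param stimulus_onset Nominal stimulus onset time (s).
#' @param delivery_delay Air-path delay between onset and odor delivery (s);
#'   default 0.2.
#' @param window Length of the counting window (s); default 0.5, matching a
#'   500 ms odor pulse.
#' @param baseline_offset How far before delivery the baseline window starts
#'   (s); default 2.
#' @param span Recorded span `[0, span]` in seconds, or `NULL` for an
#'   unbounded recording (no upper-bound check).
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(spike_times, stimulus_onset, delivery_delay = 0.2,
                        window = 0.5, baseline_offset = 2, span = NULL) {
  spike_times <- as.numeric(spike_times)
  if (anyNA(spike_times)) stop("spike times must not be NA")
  if (is.unsorted(spike_times)) stop("spike times must be sorted ascending")
  if (length(spike_times) && spike_times[1] < 0) {
    stop("spike times must be non-negative")
  }
  if (!is.numeric(window) || window <= 0) stop("'window' must be > 0")
  structure(list(spike_times = spike_times, stimulus_onset = stimulus_onset,
                 delivery_delay = delivery_delay, window = window,
                 baseline_offset = baseline_offset, span = span),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("Spike train: %d spikes, onset %.3g s (+%.3g s delay), window %.3g s\n",
              length(x$spike_times), x$stimulus_onset, x$delivery_delay, x$window))
  invisible(x)
}

count_in_window <- function(times, start, end) {
  # half-open [start, end): a spike exactly on a shared boundary is counted once
  sum(times >= start & times < end)
}

#' Windowed spike-count response
#'
#' Converts a spike train to an odor response in spikes/s: the number of
#' spikes in a 500 ms window at stimulus delivery, minus the number of
#' spikes in an equal window 2 s before delivery, doubled. Both windows are
#' half-open `[start, end)`. The result may be negative (odor-evoked
#' suppression) and is an even integer when the input counts are integers.
#'
#' @param train A [spike_train()].
#' @return Response in spikes/s.
#' @export
count_response <- function(train) {
  if (!inherits(train, "spike_train")) stop("'train' must be a spike_train")
  delivery <- train$stimulus_onset + train$delivery_delay
  stim_start <- delivery
  stim_end <- delivery + train$window
  base_start <- delivery - train$baseline_offset
  base_end <- base_start + train$window
  if (base_start < 0) {
    stop(sprintf("baseline window [%.3g, %.3g) starts before the recording",
                 base_start, base_end))
  }
  if (!is.null(train$span) && stim_end > train$span) {
    stop(sprintf("stimulus window [%.3g, %.3g) extends beyond the recorded span (%.3g s)",
                 stim_start, stim_end, train$span))
  }
  n_stim <- count_in_window(train$spike_times, stim_start, stim_end)
  n_base <- count_in_window(train$spike_times, base_start, base_end)
  2 * (n_stim - n_base)
}

#' Solvent correction
#'
#' Subtracts, from the response to a diluted odor, the response of the same
#' sensillum to the corresponding solvent alone (water for the acids;
#' paraffin oil for pyridine and octanol). A missing value on either side
#' propagates to a missing corrected response.
#'
#' @param odor_response Response(s) to the diluted odor, spikes/s.
#' @param solvent_response Response(s) to the solvent alone, spikes/s.
#' @param odor,solvent Optional identifiers; when both are given together
#'   with `panel`, the solvent is checked against the panel's solvent map.
#' @param panel Optional [odor_panel()] used for the mismatch check.
#' @return Corrected response(s), spikes/s.
#' @export
solvent_correct <- function(odor_response, solvent_response, odor = NULL,
                            solvent = NULL, panel = NULL) {
  if (!is.null(panel) && !is.null(odor) && !is.null(solvent)) {
    expected <- panel$solvent_map[[odor]]
    if (is.null(expected)) stop("odor '", odor, "' not in panel")
    if (!identical(expected, solvent)) {
      stop(sprintf("solvent mismatch for '%s': expected '%s', got '%s'",
                   odor, expected, solvent))
    }
  }
  odor_response - solvent_response
}

#' Per-sensillum max-normalization
#'
#' Divides the solvent-corrected responses of one sensillum by that
#' sensillum's maximal response, so the best odor maps to exactly 1 (ties at
#' the maximum all map to 1; missing cells are preserved). A row whose
#' responses are all missing or all `<= 0` cannot be normalized.
#'
#' @param row Numeric vector of corrected responses (spikes/s), `NA` for
#'   missing.
#' @return Normalized vector, or an error if the row is non-normalizable
#'   (use [normalize_rows()] to drop such rows with a warning instead).
#' @export
normalize_max <- function(row) {
  ok <- !is.na(row)
  if (!any(ok) || max(row[ok]) <= 0) {
    stop("row is non-normalizable: all responses missing or <= 0")
  }
  row / max(row[ok])
}

#' Max-normalize every row of a response matrix
#'
#' Applies [normalize_max()] per sensillum. Non-normalizable rows (all
#' missing or all `<= 0`) are excluded with a warning naming them.
#'
#' @param mat A [response_matrix()] of solvent-corrected responses.
#' @return A `response_matrix` of normalized responses.
#' @export
normalize_rows <- function(mat) {
  if (!inherits(mat, "response_matrix")) stop("'mat' must be a response_matrix")
  bad <- apply(unclass(mat), 1L, function(r) {
    ok <- !is.na(r)
    !any(ok) || max(r[ok]) <= 0
  })
  if (any(bad)) {
    warning("excluding ", sum(bad), " non-normalizable row(s): ",
            paste(utils::head(rownames(mat)[bad], 5L), collapse = ", "),
            call. = FALSE)
  }
  kept <- unclass(mat)[!bad, , drop = FALSE]
  out <- t(apply(kept, 1L, normalize_max))
  colnames(out) <- colnames(mat)
  response_matrix(out, genotype = attr(mat, "genotype")[!bad],
                  sensillum = attr(mat, "sensillum")[!bad],
                  panel = attr(mat, "panel"))
}

#' z-score one sensillum's responses
#'
#' Centers and scales the responses of one sensillum across odors: each
#' response minus the mean of all that sensillum's responses, divided by
#' their sample standard deviation (N-1 denominator). Missing cells are
#' excluded from the mean and SD and preserved in the output.
#'
#' @param row Numeric vector of corrected responses, `NA` for missing.
#' @param name Optional row name used in error messages.
#' @return z-scored vector: non-missing entries have mean 0 and sample SD 1.
#' @export
zscore_row <- function(row, name = NULL) {
  ok <- !is.na(row)
  lab <- if (is.null(name)) "" else paste0(" '", name, "'")
  if (sum(ok) < 2L) {
    stop("row", lab, " has fewer than 2 non-missing values")
  }
  s <- stats::sd(row[ok])
  if (!is.finite(s) || s == 0) {
    stop("row", lab, " has zero variance; cannot z-score")
  }
  (row - mean(row[ok])) / s
}

#' z-score every row of a response matrix
#'
#' @param mat A [response_matrix()] of solvent-corrected responses.
#' @return A `response_matrix` of z-scored responses (same shape and
#'   missing mask). A zero-variance row is an error naming the row.
#' @export
zscore_rows <- function(mat) {
  if (!inherits(mat, "response_matrix")) stop("'mat' must be a response_matrix")
  out <- t(vapply(seq_len(nrow(mat)),
                  function(i) zscore_row(unclass(mat)[i, ], rownames(mat)[i]),
                  numeric(ncol(mat))))
  colnames(out) <- colnames(mat)
  response_matrix(out, genotype = attr(mat, "genotype"),
                  sensillum = attr(mat, "sensillum"),
                  panel = attr(mat, "panel"))
}
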