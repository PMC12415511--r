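#' Baseline-correct epochs
#'
#' Subtracts, per trial and electrode, the mean voltage of the pre-event
#' interval (times below 0 ms). The operation is idempotent.
#'
#' @param epochs An [epoch_set].
#' @return The corrected [epoch_set].
#' @export
baseline_correct <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  pre <- which(epochs$times < 0)
  if (!length(pre)) abort("Epochs do not include a pre-event interval.")
  base <- apply(epochs$voltage[, , pre, drop = FALSE], c(1, 2), mean)
  epochs$voltage <- sweep(epochs$voltage, c(1, 2), base)
  epochs
}

# Windowed peak-to-peak range check: TRUE if any `span_ms` window of x has
# range `cmp` `limit` ("lt" for flatline, "gt" for excursion).
window_range_hits <- function(x, span_samples, limit, cmp) {
  w <- min(span_samples, length(x))
  hi <- zoo::rollmax(x, w, align = "left")
  lo <- -zoo::rollmax(-x, w, align = "left")
  rng <- hi - lo
  if (cmp == "lt") any(rng < limit) else any(rng > limit)
}

#' Artifact rejection of epochs
#'
#' An epoch is rejected when any rule fires on any cluster electrode:
#' absolute amplitude beyond `amp_limit` (+-100 microvolts); flatline —
#' peak-to-peak activity below `flat_min` (0.5 microvolts) within any
#' `flat_span` (100 ms) window; excursion — a voltage difference above
#' `diff_limit` (200 microvolts) within any `diff_span` (200 ms) window;
#' or a voltage step above `step_limit` (50 microvolts) between
#' consecutive samples. Apply after [baseline_correct()].
#'
#' @param epochs An [epoch_set].
#' @param amp_limit,flat_min,flat_span,diff_limit,diff_span,step_limit
#'   Rule thresholds (microvolts; spans in ms).
#' @return The retained [epoch_set]; the rejection log (epoch index, first
#'   rule fired) is attached as the `"rejections"` attribute.
#' @export
qc_epochs <- function(epochs, amp_limit = 100, flat_min = 0.5,
                      flat_span = 100, diff_limit = 200, diff_span = 200,
                      step_limit = 50) {
  stopifnot(inherits(epochs, "epoch_set"))
  dt <- 1000 / epochs$sfreq
  flat_w <- max(2L, round(flat_span / dt) + 1L)
  diff_w <- max(2L, round(diff_span / dt) + 1L)
  n <- n_epochs(epochs)
  rule <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    for (e in seq_along(epochs$electrodes)) {
      x <- epochs$voltage[i, e, ]
      r <- if (any(abs(x) > amp_limit)) "amplitude"
        else if (window_range_hits(x, flat_w, flat_min, "lt")) "flatline"
        else if (window_range_hits(x, diff_w, diff_limit, "gt")) "difference"
        else if (any(abs(diff(x)) > step_limit)) "step"
        else NA_character_
      if (!is.na(r)) { rule[i] <- r; break }
    }
  }
  keep <- is.na(rule)
  out <- subset_epochs(epochs, which(keep))
  attr(out, "rejections") <- tibble::tibble(
    epoch = which(!keep), rule = rule[!keep])
  out
}

#' Condition-unweighted composite waveform
#'
#' Pools the cluster electrodes, forms the per-condition grand average
#' (mean over participants of per-participant condition means), and
#' averages the condition waveforms with equal weight regardless of their
#' trial counts. The result is the composite used to locate component
#' peaks without biasing the window toward the better-sampled condition.
#'
#' @param epochs A baseline-corrected [epoch_set].
#' @param condition_col Name of the condition column in the epoch trial
#'   keys (default `"condition"`).
#' @param conditions Expected condition levels; defaults to the levels
#'   present in the data. A level with no epochs is an error naming it.
#' @param by_participant Average within participants before the grand
#'   average (default TRUE; set FALSE for single-subject use).
#' @return A tibble of class `composite_waveform` with columns `time` and
#'   `amplitude`; per-condition grand averages are attached as the
#'   `"condition_ga"` attribute.
#' @export
composite_waveform <- function(epochs, condition_col = "condition",
                               conditions = NULL, by_participant = TRUE) {
  stopifnot(inherits(epochs, "epoch_set"))
  cond <- epochs$trials[[condition_col]]
  if (is.null(cond)) abort(sprintf("Column '%s' not found.", condition_col))
  pooled <- apply(epochs$voltage, c(1, 3), mean) # trials x samples
  levels <- if (is.null(conditions)) sort(unique(cond)) else conditions
  ga <- purrr::map(levels, function(lv) {
    idx <- which(cond == lv)
    if (!length(idx)) abort(sprintf("Condition '%s' has no epochs.", lv))
    if (by_participant && "participant_id" %in% names(epochs$trials)) {
      pid <- epochs$trials$participant_id[idx]
      per <- rowsum(pooled[idx, , drop = FALSE], pid) /
        as.vector(table(pid)[sort(unique(pid))])
      colMeans(per)
    } else {
      colMeans(pooled[idx, , drop = FALSE])
    }
  })
  names(ga) <- levels
  comp <- Reduce(`+`, ga) / length(ga)
  out <- tibble::tibble(time = epochs$times, amplitude = comp)
  class(out) <- c("composite_waveform", class(out))
  attr(out, "condition_ga") <- ga
  out
}

#' Derive the scoring window from a composite waveform
#'
#' Locates the component peak — the minimum of the composite (negative
#' polarity) — within an a priori search window, and returns the
#' single-trial extraction window `peak +- half_width`. Ties resolve to
#' the earliest latency; endpoint minima are permitted unless
#' `strict_local = TRUE`, in which case only samples that are strictly
#' below both neighbors qualify (falling back to the window minimum when
#' no strict local minimum exists). Canonical search windows are
#' 200-350 ms post-feedback for the FRN and 0-100 ms post-response for
#' the ERN/CRN.
#'
#' @param composite A [composite_waveform()] or any data frame with `time`
#'   and `amplitude` columns.
#' @param search Numeric length-2 search window in ms.
#' @param half_width Half-width of the extraction window in ms.
#' @param strict_local Require a strictly local minimum (default FALSE).
#' @return An object of class `scoring_window`: list with `peak_latency`
#'   and `window` (`c(lower, upper)` in ms).
#' @examples
#' comp <- data.frame(time = 0:600, amplitude = (0:600 - 261)^2)
#' find_peak_window(comp, search = c(200, 350))$window # 231 291
#' @export
find_peak_window <- function(composite, search = c(200, 350),
                             half_width = 30, strict_local = FALSE) {
  stopifnot(is.numeric(search), length(search) == 2L)
  if (search[1] < min(composite$time) || search[2] > max(composite$time)) {
    abort("Search window lies outside the epoch extent.")
  }
  idx <- which(composite$time >= search[1] & composite$time <= search[2])
  amp <- composite$amplitude[idx]
  cand <- seq_along(amp)
  if (strict_local) {
    interior <- cand[cand > 1 & cand < length(amp)]
    strict <- interior[amp[interior] < amp[interior - 1] &
                         amp[interior] < amp[interior + 1]]
    if (length(strict)) cand <- strict
  }
  best <- cand[which.min(amp[cand])]
  peak <- composite$time[idx[best]]
  structure(list(peak_latency = peak,
                 window = c(peak - half_width, peak + half_width)),
            class = "scoring_window")
}

#' @export
print.scoring_window <- function(x, ...) {
  cat(sprintf("<scoring_window> peak %g ms, extraction %g..%g ms\n",
              x$peak_latency, x$window[1], x$window[2]))
  invisible(x)
}

#' Score single-trial amplitudes
#'
#' Mean voltage over the extraction window, per retained trial and cluster
#' electrode.
#'
#' @param epochs A baseline-corrected, QC'ed [epoch_set].
#' @param window A [find_peak_window()] result or numeric `c(lower, upper)`
#'   in ms.
#' @return A tibble with the epoch trial keys plus `electrode` and
#'   `amplitude` (one row per trial x electrode).
#' @export
score_trials <- function(epochs, window) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (inherits(window, "scoring_window")) window <- window$window
  stopifnot(is.numeric(window), length(window) == 2L)
  if (window[1] < min(epochs$times) || window[2] > max(epochs$times)) {
    abort("Extraction window exceeds the epoch extent.")
  }
  idx <- which(epochs$times >= window[1] & epochs$times <= window[2])
  scores <- apply(epochs$voltage[, , idx, drop = FALSE], c(1, 2), mean)
  keys <- dplyr::mutate(epochs$trials, epoch = dplyr::row_number())
  out <- tidyr::expand_grid(epoch = seq_len(nrow(keys)),
                            electrode = epochs$electrodes)
  out$amplitude <- as.vector(t(scores))
  dplyr::left_join(out, keys, by = "epoch") |>
    dplyr::relocate("amplitude", .after = dplyr::last_col())
}

#' Run the full scoring pipeline for one agency condition
#'
#' Convenience wrapper chaining [baseline_correct()], [qc_epochs()],
#' [composite_waveform()], [find_peak_window()] and [score_trials()].
#' Scoring is intended to run separately per agency condition (component
#' latency may differ between active and observational learning) but never
#' per group or valence.
#'
#' @param epochs An [epoch_set].
#' @param search A priori search window in ms (FRN: `c(200, 350)`
#'   post-feedback; ERN/CRN: `c(0, 100)` post-response).
#' @param qc Apply artifact rejection (default TRUE).
#' @param ... Passed to [find_peak_window()].
#' @return The [score_trials()] tibble, with the derived
#'   `scoring_window` and the QC rejection log attached as attributes
#'   `"window"` and `"rejections"`.
#' @export
score_erp <- function(epochs, search = c(200, 350), qc = TRUE, ...) {
  epochs <- baseline_correct(epochs)
  rej <- NULL
  if (qc) {
    epochs <- qc_epochs(epochs)
    rej <- attr(epochs, "rejections")
  }
  comp <- composite_waveform(epochs)
  win <- find_peak_window(comp, search = search, ...)
  out <- score_trials(epochs, win)
  attr(out, "window") <- win
  attr(out, "rejections") <- rej
  out
}
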