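#' Flag valid trials
#'
#' A trial is valid when a response was made and its RT is at least 200 ms;
#' no-response trials and rushed responses (RT < 200 ms) are invalid. The
#' boundary is strict: RT = 200 ms is valid. Observational learning trials
#' carry no own response and are therefore flagged invalid here; analyses
#' that use them (vicarious value updates) do not go through this filter.
#'
#' @param trials Trial table with `chosen` and `rt` columns.
#' @return The input with a logical `valid` column added.
#' @export
filter_valid <- function(trials) {
  if (any(trials$rt < 0, na.rm = TRUE)) {
    abort("Negative RTs found; the trial table is corrupt.")
  }
  dplyr::mutate(trials,
                valid = !is.na(.data$chosen) & !is.na(.data$rt) &
                  .data$rt >= 200)
}

#' Code objective choice accuracy
#'
#' A choice is correct when the chosen stimulus is the member of its pair
#' with the higher win probability.
#'
#' @param trials Trial table.
#' @param design The [task_design()] supplying the win probabilities.
#' @return The input with a logical `correct` column (NA when no choice was
#'   made).
#' @export
code_accuracy <- function(trials, design = task_design()) {
  best <- correct_stimulus(trials$pair, design)
  dplyr::mutate(trials, correct = ifelse(is.na(.data$chosen), NA,
                                         .data$chosen == best))
}

#' Code win-stay/lose-shift with previous-feedback authenticity
#'
#' For active learning trials, each valid repeat encounter of a stimulus
#' pair is coded against the most recent valid prior encounter of that pair
#' (intervening invalid encounters are skipped): `shift` records whether
#' the choice switched; `prev_feedback_valence` is the feedback received on
#' that previous encounter; `prev_feedback_authenticity` is `"authentic"`
#' when that feedback aligned with the previous choice's accuracy (win
#' after a correct choice, loss after an incorrect one) and `"misleading"`
#' for probabilistic deviations (win after incorrect, loss after correct).
#'
#' @param trials Trial table (one or more participants); only active
#'   learning trials are coded.
#' @param design The [task_design()] used for accuracy coding.
#' @return A tibble of active learning trials with `valid`, `correct`,
#'   `shift` (`"stay"`/`"shift"`), `prev_feedback_valence` and
#'   `prev_feedback_authenticity` columns; the shift columns are NA on
#'   first or invalid encounters.
#' @export
code_wsls <- function(trials, design = task_design()) {
  if (!"session" %in% names(trials)) trials$session <- 1L
  trials |>
    dplyr::filter(.data$agency == "active", .data$phase == "learning") |>
    filter_valid() |>
    code_accuracy(design) |>
    dplyr::group_by(.data$participant_id, .data$session) |>
    dplyr::group_modify(~ code_wsls_one(.x)) |>
    dplyr::ungroup()
}

code_wsls_one <- function(df) {
  df <- dplyr::arrange(df, .data$trial)
  n <- nrow(df)
  shift <- rep(NA_character_, n)
  prev_val <- rep(NA_character_, n)
  prev_auth <- rep(NA_character_, n)
  last <- list() # per pair: index of last valid encounter
  for (i in seq_len(n)) {
    if (!df$valid[i]) next
    p <- df$pair[i]
    j <- last[[p]]
    if (!is.null(j)) {
      shift[i] <- if (df$chosen[i] == df$chosen[j]) "stay" else "shift"
      prev_val[i] <- df$feedback[j]
      aligned <- (df$feedback[j] == "win" && isTRUE(df$correct[j])) ||
        (df$feedback[j] == "loss" && isFALSE(df$correct[j]))
      prev_auth[i] <- if (aligned) "authentic" else "misleading"
    }
    last[[p]] <- i
  }
  df$shift <- shift
  df$prev_feedback_valence <- prev_val
  df$prev_feedback_authenticity <- prev_auth
  df
}

#' Sensitivity to misleading feedback (delta scores)
#'
#' Per participant, computes shift rates in the four previous-feedback
#' valence x authenticity cells and the difference scores
#' `delta = shift(misleading) - shift(authentic)` within each valence.
#' Effective adaptation to the probabilistic schedule implies
#' `delta_win > 0` (shift more after misleading than authentic wins) and
#' `delta_loss < 0` (shift less after misleading than authentic losses);
#' larger absolute values indicate better differentiation between
#' misleading and authentic feedback.
#'
#' @param coded Output of [code_wsls()].
#' @return A tibble with one row per participant: the four cell shift
#'   rates, `delta_win` and `delta_loss`. Empty cells yield NA with a
#'   warning.
#' @export
delta_sensitivity <- function(coded) {
  cells <- coded |>
    dplyr::filter(!is.na(.data$shift)) |>
    dplyr::group_by(.data$participant_id, .data$prev_feedback_valence,
                    .data$prev_feedback_authenticity) |>
    dplyr::summarise(shift_rate = mean(.data$shift == "shift"),
                     n = dplyr::n(), .groups = "drop") |>
    tidyr::pivot_wider(
      id_cols = "participant_id",
      names_from = c("prev_feedback_valence", "prev_feedback_authenticity"),
      values_from = "shift_rate")
  for (cl in c("win_authentic", "win_misleading", "loss_authentic",
               "loss_misleading")) {
    if (!cl %in% names(cells)) cells[[cl]] <- NA_real_
  }
  if (anyNA(cells[c("win_authentic", "win_misleading", "loss_authentic",
                    "loss_misleading")])) {
    warn("Empty valence x authenticity cells; delta scores set to NA.")
  }
  dplyr::mutate(cells,
                delta_win = .data$win_misleading - .data$win_authentic,
                delta_loss = .data$loss_misleading - .data$loss_authentic)
}

# Find the learning breakpoint in a logical accuracy sequence: the first
# index i such that the `window` trials before i have mean accuracy
# strictly above `acquisition` and the mean accuracy from i to the end
# stays strictly above `stability`. Returns NA when no candidate passes.
find_breakpoint <- function(acc, window = 10, acquisition = 0.9,
                            stability = 0.65) {
  n <- length(acc)
  if (n <= window) return(NA_integer_)
  for (i in (window + 1L):n) {
    if (mean(acc[(i - window):(i - 1L)]) > acquisition &&
        mean(acc[i:n]) > stability) {
      return(i)
    }
  }
  NA_integer_
}

#' Segment trials into pre- and post-learning status
#'
#' For each participant and stimulus pair, searches the valid learning
#' trials for the point at which the contingency was acquired: the first
#' position where mean accuracy over the preceding `window` valid trials
#' strictly exceeds `acquisition` (0.9 by default, which with a 10-trial
#' window forces 10/10), accepted only if mean accuracy over all remaining
#' trials stays strictly above `stability`; otherwise the search continues
#' at the next candidate. The first trial after a qualifying window is the
#' first post-learning trial. Pairs with no valid breakpoint remain
#' entirely pre-learning. Invalid trials are skipped (not counted as
#' incorrect) and inherit the status of their position in time.
#'
#' @param trials Trial table; accuracy is coded internally via
#'   [code_accuracy()].
#' @param design The [task_design()] used for accuracy coding.
#' @param window Sliding-window length in valid trials.
#' @param acquisition Strict lower bound on the window mean accuracy.
#' @param stability Strict lower bound on the remaining-trials mean.
#' @param phases Which phases to segment over (learning only by default,
#'   matching response-locked analyses of learning-phase choices).
#' @return The selected trials with a `learning_status` column
#'   (`"pre"`/`"post"`). Breakpoints (trial index of the first
#'   post-learning trial per participant x pair, NA if never learned) are
#'   attached as the `"breakpoints"` attribute and also available via
#'   [learning_breakpoints()].
#' @export
learning_status <- function(trials, design = task_design(), window = 10,
                            acquisition = 0.9, stability = 0.65,
                            phases = "learning") {
  if (!"session" %in% names(trials)) trials$session <- 1L
  df <- trials |>
    dplyr::filter(.data$phase %in% phases) |>
    filter_valid() |>
    code_accuracy(design)
  out <- df |>
    dplyr::group_by(.data$participant_id, .data$session, .data$pair) |>
    dplyr::group_modify(function(g, key) {
      g <- dplyr::arrange(g, .data$trial)
      vi <- which(g$valid & !is.na(g$correct))
      bp_pos <- find_breakpoint(g$correct[vi], window, acquisition,
                                stability)
      g$learning_status <- "pre"
      g$bp_trial <- NA_integer_
      if (!is.na(bp_pos)) {
        bp_trial <- g$trial[vi[bp_pos]]
        g$learning_status[g$trial >= bp_trial] <- "post"
        g$bp_trial <- bp_trial
      }
      g
    }) |>
    dplyr::ungroup()
  bps <- out |>
    dplyr::distinct(.data$participant_id, .data$session, .data$pair,
                    breakpoint_trial = .data$bp_trial)
  out$bp_trial <- NULL
  attr(out, "breakpoints") <- bps
  out
}

#' @rdname learning_status
#' @param coded Output of [learning_status()].
#' @export
learning_breakpoints <- function(coded) {
  bp <- attr(coded, "breakpoints")
  if (is.null(bp)) abort("`coded` must come from learning_status().")
  bp
}
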