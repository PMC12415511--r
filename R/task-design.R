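#' Define the probabilistic selection task design
#'
#' The task interleaves learning blocks (feedback presented) with test blocks
#' (no feedback), followed by a transfer phase pairing the best and worst
#' learning stimuli with all stimuli they were not previously paired with.
#' Within each stimulus pair the win probabilities are reciprocal
#' (they sum to 1), defaulting to 80/20, 70/30 and 60/40 for pairs A/B, C/D
#' and E/F. With all defaults a session comprises 400 trials:
#' 4 x 60 learning + 4 x 30 test + 40 transfer, in the order
#' L1, T1, L2, T2, L3, T3, L4, T4, transfer.
#'
#' @param n_learning_blocks Number of learning blocks.
#' @param learning_block_len Trials per learning block (must be divisible by
#'   the number of learning pairs).
#' @param n_test_blocks Number of test blocks.
#' @param test_block_len Trials per test block (must be divisible by the
#'   number of learning pairs).
#' @param transfer_len Trials in the transfer phase (must be divisible by the
#'   number of transfer pairs, 8; use 0 for no transfer phase).
#' @param win_prob Named vector of per-stimulus win probabilities. Pairs are
#'   formed from consecutive stimuli (1st/2nd, 3rd/4th, ...) and must be
#'   reciprocal within a pair.
#' @param win_points,loss_points Score bookkeeping for win and loss feedback.
#'   These do not enter the learning model, which codes reward as 1/0.
#' @param catch_rate Probability that an observational learning trial is
#'   followed by an attention catch prompt.
#'
#' @return An object of class `task_design`.
#' @examples
#' d <- task_design()
#' sum(total_trials(d)) # 400
#' @export
task_design <- function(n_learning_blocks = 4, learning_block_len = 60,
                        n_test_blocks = 4, test_block_len = 30,
                        transfer_len = 40,
                        win_prob = c(A = 0.8, B = 0.2, C = 0.7,
                                     D = 0.3, E = 0.6, F = 0.4),
                        win_points = 20, loss_points = -10,
                        catch_rate = 0.1) {
  if (is.null(names(win_prob)) || anyDuplicated(names(win_prob)) ||
      length(win_prob) %% 2L != 0L) {
    abort("`win_prob` must be a named vector over an even number of stimuli.")
  }
  if (any(win_prob < 0 | win_prob > 1)) {
    abort("`win_prob` entries must be probabilities in [0, 1].")
  }
  stims <- names(win_prob)
  n_pairs <- length(stims) %/% 2L
  pair_idx <- matrix(seq_along(stims), nrow = 2L)
  recip <- win_prob[pair_idx[1L, ]] + win_prob[pair_idx[2L, ]]
  if (any(abs(recip - 1) > 1e-12)) {
    abort("Within-pair win probabilities must be reciprocal (sum to 1).")
  }
  check_range(catch_rate, "catch_rate", 0, 1)

  learning_pairs <- paste(stims[pair_idx[1L, ]], stims[pair_idx[2L, ]],
                          sep = "/")
  # Transfer pairs: best and worst stimulus combined with every stimulus
  # they were not previously paired with.
  others <- stims[-(1:2)]
  transfer_pairs <- c(paste(stims[1L], others, sep = "/"),
                      paste(stims[2L], others, sep = "/"))

  if (learning_block_len %% n_pairs != 0L) {
    abort("`learning_block_len` must be divisible by the number of learning pairs.")
  }
  if (test_block_len %% n_pairs != 0L) {
    abort("`test_block_len` must be divisible by the number of learning pairs.")
  }
  if (transfer_len > 0L && transfer_len %% length(transfer_pairs) != 0L) {
    abort("`transfer_len` must be divisible by the number of transfer pairs.")
  }

  structure(
    list(n_learning_blocks = n_learning_blocks,
         learning_block_len = learning_block_len,
         n_test_blocks = n_test_blocks, test_block_len = test_block_len,
         transfer_len = transfer_len, win_prob = win_prob,
         stimuli = stims, learning_pairs = learning_pairs,
         transfer_pairs = transfer_pairs, win_points = win_points,
         loss_points = loss_points, catch_rate = catch_rate),
    class = "task_design"
  )
}

#' @export
print.task_design <- function(x, ...) {
  cat("<task_design>", total_trials(x), "trials:",
      x$n_learning_blocks, "x", x$learning_block_len, "learning +",
      x$n_test_blocks, "x", x$test_block_len, "test +",
      x$transfer_len, "transfer\n")
  cat("  win probabilities:",
      paste(names(x$win_prob), x$win_prob, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Total number of trials implied by a task design
#'
#' @param design A [task_design()].
#' @return Integer trial count.
#' @export
total_trials <- function(design) {
  stopifnot(inherits(design, "task_design"))
  design$n_learning_blocks * design$learning_block_len +
    design$n_test_blocks * design$test_block_len + design$transfer_len
}

#' Enumerate the trial schedule for one session
#'
#' Expands a [task_design()] into a fully ordered trial table: alternating
#' learning and test blocks followed by the transfer phase, with each
#' eligible pair appearing equally often within every block and left/right
#' stimulus placement randomized per trial. Within-block pair order is an
#' unconstrained shuffle.
#'
#' @param design A [task_design()].
#' @param seed Optional integer seed; when given the schedule is fully
#'   reproducible.
#' @return A tibble with columns `phase` ("learning", "test", "transfer"),
#'   `block`, `trial`, `pair`, `stim_left`, `stim_right`.
#' @export
build_trial_schedule <- function(design = task_design(), seed = NULL) {
  stopifnot(inherits(design, "task_design"))
  with_seed_if(seed, {
    blocks <- list()
    for (b in seq_len(design$n_learning_blocks)) {
      blocks[[length(blocks) + 1L]] <- tibble::tibble(
        phase = "learning", block = b,
        pair = sample(rep(design$learning_pairs,
                          design$learning_block_len /
                            length(design$learning_pairs))))
      if (b <= design$n_test_blocks) {
        blocks[[length(blocks) + 1L]] <- tibble::tibble(
          phase = "test", block = b,
          pair = sample(rep(design$learning_pairs,
                            design$test_block_len /
                              length(design$learning_pairs))))
      }
    }
    if (design$transfer_len > 0L) {
      blocks[[length(blocks) + 1L]] <- tibble::tibble(
        phase = "transfer", block = 1L,
        pair = sample(rep(design$transfer_pairs,
                          design$transfer_len /
                            length(design$transfer_pairs))))
    }
    out <- dplyr::bind_rows(blocks)
    stim <- strsplit(out$pair, "/", fixed = TRUE)
    first_left <- runif(nrow(out)) < 0.5
    out$stim_left <- ifelse(first_left, vapply(stim, `[`, "", 1L),
                            vapply(stim, `[`, "", 2L))
    out$stim_right <- ifelse(first_left, vapply(stim, `[`, "", 2L),
                             vapply(stim, `[`, "", 1L))
    out$trial <- seq_len(nrow(out))
    dplyr::select(out, "phase", "block", "trial", "pair",
                  "stim_left", "stim_right")
  })
}

#' Sample feedback for choices of one stimulus
#'
#' Draws win/loss feedback from the design's probabilistic schedule, as the
#' simulator does on every learning trial: a choice of stimulus `s` wins
#' with probability `win_prob[s]`.
#'
#' @param stimulus Stimulus label (e.g. `"A"`).
#' @param n Number of draws.
#' @param design A [task_design()].
#' @param seed Optional integer seed.
#' @return Integer vector of length `n`; 1 = win, 0 = loss.
#' @examples
#' mean(draw_feedback("A", 1e4, seed = 1)) # ~0.80
#' @export
draw_feedback <- function(stimulus, n = 1, design = task_design(),
                          seed = NULL) {
  stopifnot(inherits(design, "task_design"))
  if (!stimulus %in% design$stimuli) {
    abort(sprintf("Unknown stimulus '%s'.", stimulus))
  }
  with_seed_if(seed, rbinom(n, 1L, design$win_prob[[stimulus]]))
}

# Win probability lookup for a chosen stimulus; the "correct" member of a
# pair is the one with the higher win probability.
pair_members <- function(pair) strsplit(pair, "/", fixed = TRUE)

correct_stimulus <- function(pair, design) {
  mem <- pair_members(pair)
  vapply(mem, function(m) m[which.max(design$win_prob[m])], "")
}
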