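# Independent oracles, deliberately written as naive loops with their own
# data handling so they share no code path with the package internals.

# Brute-force session NLL: named value list, explicit if/else trial loop.
nll_oracle <- function(trials, alpha_pos, alpha_neg, beta, dynamics = "cipc",
                       dynpar = 0, q0 = 0.5) {
  stims <- unique(unlist(strsplit(trials$pair, "/", fixed = TRUE)))
  q <- as.list(rep(q0, length(stims)))
  names(q) <- stims
  nll <- 0
  for (i in seq_len(nrow(trials))) {
    ch <- trials$chosen[i]
    members <- strsplit(trials$pair[i], "/", fixed = TRUE)[[1]]
    if (trials$phase[i] == "learning") {
      if (!is.na(ch) && trials$feedback[i] %in% c("win", "loss")) {
        r <- if (trials$feedback[i] == "win") 1 else 0
        a <- if (r == 1) alpha_pos else alpha_neg
        q[[ch]] <- q[[ch]] + a * (r - q[[ch]])
      }
    } else {
      ok <- !is.na(ch) && !is.na(trials$rt[i]) && trials$rt[i] >= 200
      if (ok) {
        un <- members[members != ch]
        p <- 1 / (1 + exp(-beta * (q[[ch]] - q[[un]])))
        nll <- nll - log(p)
        if (dynamics == "cipc") {
          q[[ch]] <- q[[ch]] + dynpar * (1 - q[[ch]])
          q[[un]] <- q[[un]] - dynpar * q[[un]]
        } else if (dynamics == "decay") {
          q[[ch]] <- q[[ch]] + dynpar * (q0 - q[[ch]])
          q[[un]] <- q[[un]] + dynpar * (q0 - q[[un]])
        }
      }
    }
  }
  nll
}

# Exhaustive learning-breakpoint scan: evaluates every candidate index with
# vectorized means instead of the package's running search.
breakpoint_oracle <- function(acc, window = 10, acquisition = 0.9,
                              stability = 0.65) {
  n <- length(acc)
  if (n <= window) return(NA_integer_)
  cands <- (window + 1L):n
  win_ok <- vapply(cands,
                   function(i) mean(acc[(i - window):(i - 1L)]) > acquisition,
                   logical(1))
  rem_ok <- vapply(cands, function(i) mean(acc[i:n]) > stability, logical(1))
  hit <- cands[win_ok & rem_ok]
  if (length(hit)) hit[1] else NA_integer_
}

# Small hand-buildable trial table for likelihood tests.
toy_session <- function(phase, pair, chosen, feedback, rt = 500,
                        participant_id = "T1") {
  tibble::tibble(
    participant_id = participant_id, group = "HC", agency = "active",
    session = 1L, phase = phase,
    block = 1L, trial = seq_along(phase), pair = pair,
    stim_left = vapply(strsplit(pair, "/"), `[`, "", 1L),
    stim_right = vapply(strsplit(pair, "/"), `[`, "", 2L),
    side_of_choice = "left", chosen = chosen, feedback = feedback,
    rt = rt, points_delta = 0L, catch = FALSE)
}

# Random small session through the simulator, for oracle cross-checks.
random_small_session <- function(seed) {
  d <- task_design(n_learning_blocks = 2, learning_block_len = 12,
                   n_test_blocks = 2, test_block_len = 6, transfer_len = 8)
  set.seed(seed)
  ag <- agent_params(alpha_pos = runif(1, .05, .95),
                     alpha_neg = runif(1, .05, .95),
                     beta = runif(1, 0, 8), epsilon = runif(1, 0, .4),
                     p_no_response = 0.05, p_rushed = 0.05)
  list(trials = simulate_active_session(d, ag, seed = seed + 1),
       agent = ag)
}
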