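#' Reinforcement-learning model registry
#'
#' Candidate models differ along two axes: one versus two (valence-specific)
#' learning rates, and the dynamics of stimulus values on feedback-free
#' (test/transfer) choices — `static` (unchanged), `decay` (relaxation
#' toward the initial value at rate gamma) or `cipc` (choice-induced
#' preference change at rate epsilon, spreading the chosen and unchosen
#' values toward the bounds). `"dual_cipc"` — two learning rates plus
#' CIPC — is the reference winning variant.
#'
#' Learning rates and the CIPC/decay rates are bounded in `[0, 1]`. The
#' inverse temperature is bounded in `[0, beta_max]` with a default of 10:
#' on the `[0, 1]` value scale a logit of 10 already makes choices
#' essentially deterministic, and a looser box admits a degenerate
#' low-learning-rate/high-temperature ridge in the held-out-phase
#' likelihood that corrupts parameter recovery (see the methods vignette).
#'
#' @param id Model id string, one of `"single_static"`, `"dual_static"`,
#'   `"single_cipc"`, `"dual_cipc"`, `"dual_decay"`.
#' @param beta_max Upper box bound for the inverse temperature.
#' @return For `rl_model()`, an object of class `rl_model` with the
#'   parameter names and box bounds; for `rl_models()`, a tibble listing
#'   the registry.
#' @export
rl_model <- function(id = "dual_cipc", beta_max = 10) {
  if (inherits(id, "rl_model")) return(id)
  reg <- list(
    single_static = list(n_rates = 1L, dynamics = "static",
                         params = c("alpha", "beta")),
    dual_static   = list(n_rates = 2L, dynamics = "static",
                         params = c("alpha_pos", "alpha_neg", "beta")),
    single_cipc   = list(n_rates = 1L, dynamics = "cipc",
                         params = c("alpha", "beta", "epsilon")),
    dual_cipc     = list(n_rates = 2L, dynamics = "cipc",
                         params = c("alpha_pos", "alpha_neg", "beta",
                                    "epsilon")),
    dual_decay    = list(n_rates = 2L, dynamics = "decay",
                         params = c("alpha_pos", "alpha_neg", "beta",
                                    "gamma")))
  if (!id %in% names(reg)) {
    abort(sprintf("Unknown model id '%s'. Available: %s.", id,
                  paste(names(reg), collapse = ", ")))
  }
  m <- reg[[id]]
  check_range(beta_max, "beta_max", 1e-6, Inf)
  lower <- rep(0, length(m$params))
  upper <- ifelse(m$params == "beta", beta_max, 1)
  names(lower) <- names(upper) <- m$params
  structure(list(id = id, n_rates = m$n_rates, dynamics = m$dynamics,
                 params = m$params, lower = lower, upper = upper,
                 k = length(m$params), q0 = 0.5),
            class = "rl_model")
}

#' @rdname rl_model
#' @export
rl_models <- function() {
  ids <- c("single_static", "dual_static", "single_cipc", "dual_cipc",
           "dual_decay")
  tibble::tibble(
    id = ids,
    n_learning_rates = purrr::map_int(ids, ~ rl_model(.x)$n_rates),
    dynamics = purrr::map_chr(ids, ~ rl_model(.x)$dynamics),
    k = purrr::map_int(ids, ~ rl_model(.x)$k))
}

#' Delta-rule value update
#'
#' Updates a stimulus value after feedback: `q + alpha * (r - q)`, with
#' `alpha = alpha_pos` for win feedback (reward 1) and `alpha = alpha_neg`
#' for loss feedback (reward 0). With reward coded 1/0 and values in
#' `(0, 1)`, gating by feedback valence and by prediction-error sign are
#' equivalent.
#'
#' @param q Current value(s) in `[0, 1]`.
#' @param r Reward, 0 or 1 (vectorized).
#' @param alpha_pos,alpha_neg Learning rates in `[0, 1]`.
#' @return Updated value(s).
#' @examples
#' q_update(0.5, 0, alpha_neg = 0.2) # 0.4
#' @export
q_update <- function(q, r, alpha_pos = 0.4, alpha_neg = alpha_pos) {
  if (any(q < 0 | q > 1)) abort("`q` must lie in [0, 1].")
  if (!all(r %in% c(0, 1))) abort("`r` must be 0 (loss) or 1 (win).")
  check_range(alpha_pos, "alpha_pos", 0, 1)
  check_range(alpha_neg, "alpha_neg", 0, 1)
  alpha <- ifelse(r == 1, alpha_pos, alpha_neg)
  q + alpha * (r - q)
}

#' Value dynamics after a feedback-free choice
#'
#' After a valid choice without external feedback, values evolve according
#' to the model's feedback-free dynamics: `static` leaves them unchanged;
#' `decay` relaxes both the chosen and unchosen value toward the initial
#' value `q0` by factor `par`; `cipc` spreads them toward the bounds —
#' the chosen value moves toward 1 and the unchosen toward 0 by rate `par`.
#'
#' @param q_chosen,q_unchosen Current values in `[0, 1]`.
#' @param dynamics `"static"`, `"decay"` or `"cipc"`.
#' @param par Rate parameter in `[0, 1]` (gamma for decay, epsilon for
#'   CIPC; ignored for static).
#' @param q0 Initial value that `decay` relaxes toward.
#' @return Named numeric vector `c(q_chosen, q_unchosen)`.
#' @examples
#' feedbackfree_update(0.6, 0.4, "cipc", 0.5) # 0.8, 0.2
#' @export
feedbackfree_update <- function(q_chosen, q_unchosen,
                                dynamics = c("static", "decay", "cipc"),
                                par = 0, q0 = 0.5) {
  dynamics <- match.arg(dynamics)
  check_range(par, "par", 0, 1)
  out <- switch(dynamics,
    static = c(q_chosen, q_unchosen),
    decay = c(q_chosen + par * (q0 - q_chosen),
              q_unchosen + par * (q0 - q_unchosen)),
    cipc = c(q_chosen + par * (1 - q_chosen),
             q_unchosen - par * q_unchosen))
  names(out) <- c("q_chosen", "q_unchosen")
  out
}

#' Softmax choice probability
#'
#' Probability of choosing the left option given the two values and the
#' inverse temperature: the logistic of `beta * (q_left - q_right)`.
#'
#' @param q_left,q_right Option values.
#' @param beta Inverse temperature, >= 0.
#' @return Probability in `(0, 1)` (0.5 when the values are equal or
#'   `beta = 0`).
#' @export
choice_prob <- function(q_left, q_right, beta) {
  check_range(beta, "beta", 0, Inf)
  plogis(beta * (q_left - q_right))
}

# Encode one participant-session trial table into the integer vectors the
# C++ core consumes. Validates ordering and single-session input.
encode_session <- function(trials, design = NULL) {
  needed <- c("participant_id", "phase", "trial", "pair", "chosen",
              "feedback", "rt")
  missing_cols <- setdiff(needed, names(trials))
  if (length(missing_cols)) {
    abort(paste("Missing columns:", paste(missing_cols, collapse = ", ")))
  }
  key <- unique(trials$participant_id)
  ses <- if ("session" %in% names(trials)) unique(trials$session) else 1L
  if (length(key) != 1L || length(ses) != 1L) {
    abort("`trials` must contain exactly one participant-session.")
  }
  if (is.unsorted(trials$trial, strictly = TRUE)) {
    abort("`trials` must be ordered by trial index.")
  }
  stims <- sort(unique(unlist(pair_members(trials$pair))))
  mem <- pair_members(trials$pair)
  chosen_i <- ifelse(is.na(trials$chosen), 0L,
                     match(trials$chosen, stims))
  unchosen <- purrr::map2_chr(mem, trials$chosen, function(m, ch) {
    if (is.na(ch)) NA_character_ else setdiff(m, ch)[1]
  })
  unchosen_i <- ifelse(is.na(unchosen), 0L, match(unchosen, stims))
  phase_i <- match(trials$phase, c("learning", "test", "transfer"))
  reward_i <- dplyr::case_match(trials$feedback, "win" ~ 1L, "loss" ~ 0L,
                                .default = -1L)
  valid <- !is.na(trials$chosen) & !is.na(trials$rt) & trials$rt >= 200
  list(phase = phase_i, chosen = chosen_i, unchosen = unchosen_i,
       reward = reward_i, valid = as.integer(valid),
       stimuli = stims, n_stim = length(stims))
}

expand_params <- function(model, params) {
  p <- as.list(params)
  if (model$n_rates == 1L) {
    p$alpha_pos <- p$alpha
    p$alpha_neg <- p$alpha
  }
  dynpar <- switch(model$dynamics, static = 0,
                   decay = p$gamma, cipc = p$epsilon)
  list(alpha_pos = p$alpha_pos, alpha_neg = p$alpha_neg, beta = p$beta,
       dyn = match(model$dynamics, c("static", "decay", "cipc")) - 1L,
       dynpar = dynpar)
}

#' Session negative log-likelihood
#'
#' Evaluates a model's negative log-likelihood for one participant-session.
#' Values start at `q0` for every stimulus; learning-phase outcomes (own or
#' observed) update them by the delta rule; every valid test/transfer
#' choice contributes `-log` of its softmax probability and then triggers
#' the model's feedback-free update. Invalid trials (no response or rushed,
#' RT < 200 ms) contribute nothing.
#'
#' @param trials Trial table of a single participant-session, time-ordered.
#' @param model An [rl_model()] or model id string.
#' @param params Named numeric vector with the model's parameters.
#' @return The NLL as a single number, with attribute `n_ll` giving the
#'   number of likelihood (valid test/transfer) trials.
#' @export
session_nll <- function(trials, model = "dual_cipc", params) {
  model <- rl_model(model)
  missing_p <- setdiff(model$params, names(params))
  if (length(missing_p)) {
    abort(paste("Missing parameters:", paste(missing_p, collapse = ", ")))
  }
  enc <- encode_session(trials)
  ep <- expand_params(model, params)
  res <- rl_session_core(enc$phase, enc$chosen, enc$unchosen, enc$reward,
                         enc$valid, ep$alpha_pos, ep$alpha_neg, ep$beta,
                         ep$dyn, ep$dynpar, model$q0, enc$n_stim, FALSE)
  structure(res$nll, n_ll = res$n_ll)
}

#' Fit an RL model to one participant-session
#'
#' Bounded local optimization (L-BFGS-B) of the session NLL from `n_starts`
#' Latin-hypercube initializations within the parameter box; the best
#' converged start wins. All starts are recorded for diagnostics.
#'
#' @inheritParams session_nll
#' @param n_starts Number of multistart initializations.
#' @param seed Integer seed for the start design.
#' @return An object of class `rl_fit` with elements `model`, `par` (best
#'   parameters), `nll`, `n_ll`, `bic` (`k * log(n_ll) + 2 * nll`) and
#'   `starts` (per-start tibble). Has [tidy()] and [glance()] methods.
#' @export
fit_rl <- function(trials, model = "dual_cipc", n_starts = 20, seed = 1) {
  model <- rl_model(model)
  enc <- encode_session(trials)
  if (sum(enc$valid[enc$phase > 1L]) < 1L) {
    abort("No valid test/transfer trials to fit on.")
  }
  obj <- function(theta) {
    names(theta) <- model$params
    ep <- expand_params(model, theta)
    rl_session_core(enc$phase, enc$chosen, enc$unchosen, enc$reward,
                    enc$valid, ep$alpha_pos, ep$alpha_neg, ep$beta,
                    ep$dyn, ep$dynpar, model$q0, enc$n_stim, FALSE)$nll
  }
  k <- model$k
  starts <- with_seed_if(seed, lhs::randomLHS(n_starts, k))
  # Spread beta starts over the interior of its box.
  scale_lo <- ifelse(model$params == "beta", 0.1, 0.02)
  scale_hi <- ifelse(model$params == "beta",
                     0.9 * model$upper[["beta"]], 0.98)
  fits <- purrr::map(seq_len(n_starts), function(s) {
    theta0 <- scale_lo + starts[s, ] * (scale_hi - scale_lo)
    res <- tryCatch(
      optim(theta0, obj, method = "L-BFGS-B", lower = model$lower,
            upper = model$upper, control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(res)) {
      return(list(par = rep(NA_real_, k), nll = Inf, conv = FALSE))
    }
    list(par = res$par, nll = res$value, conv = res$convergence == 0L)
  })
  nlls <- purrr::map_dbl(fits, "nll")
  if (!any(is.finite(nlls))) {
    abort("All optimization starts failed; check the input trials.")
  }
  best <- fits[[which.min(nlls)]]
  par <- best$par
  names(par) <- model$params
  n_ll <- sum(enc$valid[enc$phase > 1L])
  start_log <- tibble::tibble(
    start = seq_len(n_starts), nll = nlls,
    converged = purrr::map_lgl(fits, "conv"))
  structure(
    list(model = model, par = par, nll = best$nll, n_ll = n_ll,
         bic = k * log(n_ll) + 2 * best$nll, starts = start_log),
    class = "rl_fit")
}

#' @export
print.rl_fit <- function(x, ...) {
  cat("<rl_fit>", x$model$id, "| NLL", round(x$nll, 3),
      "| BIC", round(x$bic, 3), "| n_ll", x$n_ll, "\n")
  print(round(x$par, 4))
  invisible(x)
}

#' @rdname fit_rl
#' @param x An `rl_fit` object.
#' @param ... Unused.
#' @export
tidy.rl_fit <- function(x, ...) {
  tibble::tibble(term = names(x$par), estimate = unname(x$par))
}

#' @rdname fit_rl
#' @export
glance.rl_fit <- function(x, ...) {
  tibble::tibble(model = x$model$id, k = x$model$k, n_ll = x$n_ll,
                 nll = x$nll, bic = x$bic,
                 n_starts = nrow(x$starts),
                 n_converged = sum(x$starts$converged))
}

#' Compare RL models by summed BIC
#'
#' Fits each candidate model to every participant-session in `trials`
#' (active and observational sessions are fitted separately) and ranks the
#' models by total BIC across fits; the lowest total wins.
#'
#' @param trials Trial table covering one or more participant-sessions.
#' @param models Character vector of model ids (>= 2).
#' @inheritParams fit_rl
#' @return A tibble with one row per model (`model`, `k`, `total_bic`,
#'   `n_fits`, `rank`, `winner`), ranked by total BIC. Per-session BICs
#'   are attached as the `"by_session"` attribute.
#' @export
compare_rl_models <- function(trials,
                              models = c("single_static", "dual_static",
                                         "dual_decay", "dual_cipc"),
                              n_starts = 20, seed = 1) {
  if (length(models) < 2L) abort("Provide at least two model ids.")
  if (!"session" %in% names(trials)) trials$session <- 1L
  sessions <- dplyr::group_split(trials, .data$participant_id,
                                 .data$agency, .data$session)
  per <- purrr::map_dfr(sessions, function(ss) {
    purrr::map_dfr(models, function(m) {
      f <- fit_rl(ss, m, n_starts = n_starts, seed = seed)
      tibble::tibble(participant_id = ss$participant_id[1],
                     agency = ss$agency[1], session = ss$session[1],
                     model = m, nll = f$nll, bic = f$bic)
    })
  })
  out <- per |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(total_bic = sum(.data$bic), n_fits = dplyr::n(),
                     .groups = "drop") |>
    dplyr::mutate(k = purrr::map_int(.data$model, ~ rl_model(.x)$k),
                  .after = "model") |>
    dplyr::arrange(.data$total_bic) |>
    dplyr::mutate(rank = dplyr::row_number(),
                  winner = .data$rank == 1L)
  attr(out, "by_session") <- per
  out
}

#' Extract latent model quantities per trial
#'
#' Replays the fitted model over the session and returns, per trial, the
#' pre-update values of the chosen and unchosen stimulus, the signed
#' prediction error `pe = r - q_chosen` (feedback trials only), the
#' salience (unsigned) prediction error `spe = |pe|` together with its
#' mean-centered version `spe_c` (for regression use), and the predictive
#' accuracy index `dq = q_chosen - q_unchosen`.
#'
#' @param fit An [fit_rl()] result (or a named parameter vector via
#'   `params`).
#' @param trials The same participant-session the model was fitted to.
#' @param params Optional named parameters overriding `fit$par`.
#' @param model Model id, used only when `fit` is `NULL`.
#' @return A tibble keyed by `participant_id`, `trial` with the latent
#'   columns described above.
#' @export
extract_latents <- function(fit = NULL, trials, params = NULL,
                            model = "dual_cipc") {
  if (!is.null(fit)) {
    stopifnot(inherits(fit, "rl_fit"))
    model <- fit$model
    params <- fit$par
  }
  model <- rl_model(model)
  enc <- encode_session(trials)
  ep <- expand_params(model, params)
  res <- rl_session_core(enc$phase, enc$chosen, enc$unchosen, enc$reward,
                         enc$valid, ep$alpha_pos, ep$alpha_neg, ep$beta,
                         ep$dyn, ep$dynpar, model$q0, enc$n_stim, TRUE)
  spe <- abs(res$pe)
  tibble::tibble(
    participant_id = trials$participant_id,
    agency = if ("agency" %in% names(trials)) trials$agency else NA_character_,
    trial = trials$trial, phase = trials$phase, pair = trials$pair,
    chosen = trials$chosen, feedback = trials$feedback,
    q_chosen = res$q_chosen, q_unchosen = res$q_unchosen,
    pe = res$pe, spe = spe,
    spe_c = spe - mean(spe, na.rm = TRUE),
    dq = res$q_chosen - res$q_unchosen,
    p_choice = res$p_choice)
}
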