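#' Reinforcement-learning agent parameters
#'
#' Agents learn stimulus values with a delta rule using separate learning
#' rates for win and loss feedback, choose via a softmax with inverse
#' temperature `beta`, and revalue chosen/unchosen options after
#' feedback-free choices at the choice-induced preference change (CIPC)
#' rate `epsilon`. Reward is coded 1/0 internally so values stay
#' interpretable as win probabilities; the task's point payoffs are score
#' bookkeeping only.
#'
#' @param alpha_pos,alpha_neg Learning rates in `[0, 1]` for win and loss
#'   feedback.
#' @param beta Softmax inverse temperature, >= 0.
#' @param epsilon CIPC rate in `[0, 1]` applied after valid feedback-free
#'   (test/transfer) choices.
#' @param rt_mean,rt_sd Response-time distribution (ms) for valid responses
#'   (normal, truncated below at the 200 ms validity bound).
#' @param p_no_response Probability of omitting a response on a trial.
#' @param p_rushed Probability of a rushed response (RT drawn uniformly from
#'   50-199 ms, below the validity bound).
#' @param q_init Initial stimulus value; either a scalar or a named vector
#'   over stimuli.
#' @return An object of class `agent_params`.
#' @export
agent_params <- function(alpha_pos = 0.4, alpha_neg = 0.3, beta = 5,
                         epsilon = 0.1, rt_mean = 450, rt_sd = 120,
                         p_no_response = 0.01, p_rushed = 0.01,
                         q_init = 0.5) {
  check_range(alpha_pos, "alpha_pos", 0, 1)
  check_range(alpha_neg, "alpha_neg", 0, 1)
  check_range(beta, "beta", 0, Inf)
  check_range(epsilon, "epsilon", 0, 1)
  check_range(rt_mean, "rt_mean", 1e-9, Inf)
  check_range(rt_sd, "rt_sd", 0, Inf)
  check_range(p_no_response, "p_no_response", 0, 1)
  check_range(p_rushed, "p_rushed", 0, 1)
  structure(list(alpha_pos = alpha_pos, alpha_neg = alpha_neg, beta = beta,
                 epsilon = epsilon, rt_mean = rt_mean, rt_sd = rt_sd,
                 p_no_response = p_no_response, p_rushed = p_rushed,
                 q_init = q_init),
            class = "agent_params")
}

# Draw one valid RT from a normal truncated below at 200 ms.
draw_rt <- function(mean, sd) {
  if (sd <= 0) return(max(mean, 200))
  qnorm(runif(1, pnorm(200, mean, sd), 1), mean, sd)
}

init_q <- function(agent, design) {
  q <- rep(0.5, length(design$stimuli))
  names(q) <- design$stimuli
  qi <- agent$q_init
  if (length(qi) == 1L && is.null(names(qi))) {
    q[] <- qi
  } else {
    q[names(qi)] <- qi
  }
  q
}

empty_session <- function(n) {
  list(chosen = character(n), side = character(n), feedback = character(n),
       rt = rep(NA_real_, n), points = integer(n), catch = logical(n))
}

#' Simulate one active learning session
#'
#' The agent chooses on every trial via a softmax over its running stimulus
#' values. On learning trials, feedback is sampled from the chosen
#' stimulus's win probability and values update by the delta rule
#' ([q_update()]); on test and transfer trials no feedback is given and the
#' agent's values change only through choice-induced preference change
#' ([feedbackfree_update()], applied after each valid choice). Omitted and
#' rushed responses occur at the agent's configured rates; omitted learning
#' trials yield no feedback and no update.
#'
#' @param design A [task_design()].
#' @param agent An [agent_params()].
#' @param seed Integer seed; the session is fully reproducible.
#' @param participant_id,group,session Identifiers carried into the output.
#' @return A tibble of trial records with columns `participant_id`, `group`,
#'   `agency`, `session`, `phase`, `block`, `trial`, `pair`, `stim_left`,
#'   `stim_right`, `side_of_choice`, `chosen`, `feedback`, `rt`,
#'   `points_delta`, `catch`.
#' @export
simulate_active_session <- function(design = task_design(),
                                    agent = agent_params(), seed = 1,
                                    participant_id = "P01", group = "HC",
                                    session = 1L) {
  stopifnot(inherits(design, "task_design"), inherits(agent, "agent_params"))
  with_seed_if(seed, {
    sched <- build_trial_schedule(design)
    q <- init_q(agent, design)
    out <- empty_session(nrow(sched))
    for (i in seq_len(nrow(sched))) {
      left <- sched$stim_left[i]; right <- sched$stim_right[i]
      if (runif(1) < agent$p_no_response) {
        out$chosen[i] <- NA_character_; out$side[i] <- NA_character_
        out$feedback[i] <- "none"
        next
      }
      p_left <- plogis(agent$beta * (q[[left]] - q[[right]]))
      go_left <- runif(1) < p_left
      ch <- if (go_left) left else right
      out$chosen[i] <- ch
      out$side[i] <- if (go_left) "left" else "right"
      rushed <- runif(1) < agent$p_rushed
      out$rt[i] <- if (rushed) runif(1, 50, 199) else
        draw_rt(agent$rt_mean, agent$rt_sd)
      if (sched$phase[i] == "learning") {
        win <- runif(1) < design$win_prob[[ch]]
        out$feedback[i] <- if (win) "win" else "loss"
        out$points[i] <- if (win) design$win_points else design$loss_points
        q[[ch]] <- q_update(q[[ch]], as.numeric(win),
                            agent$alpha_pos, agent$alpha_neg)
      } else {
        out$feedback[i] <- "none"
        if (!rushed) {
          un <- setdiff(c(left, right), ch)
          upd <- feedbackfree_update(q[[ch]], q[[un]], "cipc",
                                     agent$epsilon)
          q[[ch]] <- upd[["q_chosen"]]; q[[un]] <- upd[["q_unchosen"]]
        }
      }
    }
    assemble_session(sched, out, participant_id, group, "active", session)
  })
}

#' Simulate one observational session yoked to an active session
#'
#' Learning-phase choices and feedback are copied from the yoked active
#' session; the observer makes no response on those trials but learns
#' vicariously from the observed outcomes with its own learning rates.
#' Attention catch prompts are inserted after observational learning trials
#' at the design's `catch_rate`. Test and transfer trials require active
#' responding and are generated from the observer's own (vicariously
#' learned) values, exactly as in [simulate_active_session()].
#'
#' @param design A [task_design()]; must match the design of `observed`.
#' @param observed Trial table of a completed active session (same design).
#' @param agent The observer's [agent_params()].
#' @inheritParams simulate_active_session
#' @return A tibble of trial records (same columns as
#'   [simulate_active_session()]).
#' @export
simulate_observer_session <- function(design = task_design(), observed,
                                      agent = agent_params(), seed = 1,
                                      participant_id = "P02", group = "HC",
                                      session = 1L) {
  stopifnot(inherits(design, "task_design"), inherits(agent, "agent_params"))
  if (nrow(observed) != total_trials(design) ||
      !identical(observed$phase[observed$phase == "learning"],
                 rep("learning", design$n_learning_blocks *
                       design$learning_block_len)) ||
      !all(observed$pair %in% c(design$learning_pairs,
                                design$transfer_pairs))) {
    abort("`observed` does not match `design` (trial count, phases or pairs differ).")
  }
  with_seed_if(seed, {
    learn_idx <- which(observed$phase == "learning")
    sched <- build_trial_schedule(design)
    # Learning trials replay the yoked source exactly (pair, sides, choice,
    # feedback); only test/transfer trials are re-scheduled for the observer.
    sched[learn_idx, c("pair", "stim_left", "stim_right")] <-
      observed[learn_idx, c("pair", "stim_left", "stim_right")]
    q <- init_q(agent, design)
    out <- empty_session(nrow(sched))
    for (i in seq_len(nrow(sched))) {
      left <- sched$stim_left[i]; right <- sched$stim_right[i]
      if (sched$phase[i] == "learning") {
        ch <- observed$chosen[i]
        out$chosen[i] <- ch
        out$side[i] <- observed$side_of_choice[i]
        out$feedback[i] <- observed$feedback[i]
        out$catch[i] <- runif(1) < design$catch_rate
        if (!is.na(ch) && out$feedback[i] != "none") {
          win <- out$feedback[i] == "win"
          out$points[i] <- if (win) design$win_points else design$loss_points
          q[[ch]] <- q_update(q[[ch]], as.numeric(win),
                              agent$alpha_pos, agent$alpha_neg)
        }
        next
      }
      if (runif(1) < agent$p_no_response) {
        out$chosen[i] <- NA_character_; out$side[i] <- NA_character_
        out$feedback[i] <- "none"
        next
      }
      p_left <- plogis(agent$beta * (q[[left]] - q[[right]]))
      go_left <- runif(1) < p_left
      ch <- if (go_left) left else right
      out$chosen[i] <- ch
      out$side[i] <- if (go_left) "left" else "right"
      rushed <- runif(1) < agent$p_rushed
      out$rt[i] <- if (rushed) runif(1, 50, 199) else
        draw_rt(agent$rt_mean, agent$rt_sd)
      out$feedback[i] <- "none"
      if (!rushed) {
        un <- setdiff(c(left, right), ch)
        upd <- feedbackfree_update(q[[ch]], q[[un]], "cipc", agent$epsilon)
        q[[ch]] <- upd[["q_chosen"]]; q[[un]] <- upd[["q_unchosen"]]
      }
    }
    assemble_session(sched, out, participant_id, group, "observational",
                     session)
  })
}

assemble_session <- function(sched, out, participant_id, group, agency,
                             session) {
  tibble::tibble(
    participant_id = participant_id, group = group, agency = agency,
    session = as.integer(session), phase = sched$phase,
    block = sched$block, trial = sched$trial, pair = sched$pair,
    stim_left = sched$stim_left, stim_right = sched$stim_right,
    side_of_choice = out$side, chosen = out$chosen,
    feedback = out$feedback, rt = out$rt,
    points_delta = out$points, catch = out$catch)
}

#' Specify a simulated cohort
#'
#' Defines group sizes and the per-group distributions of agent parameters.
#' Defaults mirror a three-group clinical comparison (27 OCD, 27 HC, 29 SAD
#' participants), with the OCD group given a lower positive learning rate
#' and a lower inverse temperature so that impaired accuracy and more
#' indecisive (shift-prone) choice behavior are recoverable downstream.
#'
#' @param n_per_group Named integer vector of group sizes.
#' @param means Named list (one entry per group) of mean `alpha_pos`,
#'   `alpha_neg`, `beta`, `epsilon`.
#' @param sds Between-participant SDs of the same parameters (shared across
#'   groups; parameters are truncated to their bounds).
#' @param rt_mean,rt_sd,p_no_response,p_rushed Response model shared by all
#'   agents.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(OCD = 27, HC = 27, SAD = 29),
                        means = list(
                          OCD = c(alpha_pos = 0.25, alpha_neg = 0.30,
                                  beta = 3.0, epsilon = 0.10),
                          HC  = c(alpha_pos = 0.40, alpha_neg = 0.30,
                                  beta = 5.0, epsilon = 0.10),
                          SAD = c(alpha_pos = 0.28, alpha_neg = 0.30,
                                  beta = 3.2, epsilon = 0.10)),
                        sds = c(alpha_pos = 0.08, alpha_neg = 0.08,
                                beta = 1.0, epsilon = 0.04),
                        rt_mean = 450, rt_sd = 120,
                        p_no_response = 0.01, p_rushed = 0.01) {
  if (is.null(names(n_per_group)) || !all(names(n_per_group) %in% names(means))) {
    abort("Every group in `n_per_group` needs an entry in `means`.")
  }
  structure(list(n_per_group = n_per_group, means = means, sds = sds,
                 rt_mean = rt_mean, rt_sd = rt_sd,
                 p_no_response = p_no_response, p_rushed = p_rushed),
            class = "cohort_spec")
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Simulate a full cohort (two sessions per participant)
#'
#' Every participant completes one active and one observational session,
#' with session order counterbalanced across participants. Each
#' observational session is yoked to the active session of the preceding
#' participant in the roster (circularly), emulating a yoked design in
#' which observers replay a previous active learner's trial sequence.
#' Per-participant agent parameters are drawn from the group distributions
#' in `spec` and truncated to their bounds.
#'
#' @param spec A [cohort_spec()].
#' @param design A [task_design()].
#' @param seed Master integer seed; the full cohort table is reproducible.
#' @return A tibble of trial records for all participants and sessions. The
#'   drawn per-participant parameters are attached as the `"agents"`
#'   attribute (a tibble), for use in recovery studies.
#' @export
simulate_cohort <- function(spec = cohort_spec(), design = task_design(),
                            seed = 1) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(design, "task_design"))
  with_seed_if(seed, {
    groups <- rep(names(spec$n_per_group), spec$n_per_group)
    n <- length(groups)
    ids <- sprintf("P%03d", seq_len(n))
    agents <- purrr::map2(groups, seq_len(n), function(g, i) {
      m <- spec$means[[g]]
      agent_params(
        alpha_pos = clamp(rnorm(1, m[["alpha_pos"]], spec$sds[["alpha_pos"]]), 0.01, 0.99),
        alpha_neg = clamp(rnorm(1, m[["alpha_neg"]], spec$sds[["alpha_neg"]]), 0.01, 0.99),
        beta = clamp(rnorm(1, m[["beta"]], spec$sds[["beta"]]), 0.1, 50),
        epsilon = clamp(rnorm(1, m[["epsilon"]], spec$sds[["epsilon"]]), 0, 0.8),
        rt_mean = spec$rt_mean, rt_sd = spec$rt_sd,
        p_no_response = spec$p_no_response, p_rushed = spec$p_rushed)
    })
    seeds <- matrix(sample.int(.Machine$integer.max - 1L, 2L * n), ncol = 2L)
    active <- purrr::map(seq_len(n), function(i) {
      simulate_active_session(design, agents[[i]], seed = seeds[i, 1L],
                              participant_id = ids[i], group = groups[i],
                              session = if (i %% 2L == 1L) 1L else 2L)
    })
    observational <- purrr::map(seq_len(n), function(i) {
      src <- active[[if (i == 1L) n else i - 1L]]
      simulate_observer_session(design, src, agents[[i]],
                                seed = seeds[i, 2L],
                                participant_id = ids[i], group = groups[i],
                                session = if (i %% 2L == 1L) 2L else 1L)
    })
    out <- dplyr::bind_rows(dplyr::bind_rows(active),
                            dplyr::bind_rows(observational))
    out <- dplyr::arrange(out, .data$participant_id, .data$session,
                          .data$trial)
    attr(out, "agents") <- tibble::tibble(
      participant_id = ids, group = groups,
      alpha_pos = purrr::map_dbl(agents, "alpha_pos"),
      alpha_neg = purrr::map_dbl(agents, "alpha_neg"),
      beta = purrr::map_dbl(agents, "beta"),
      epsilon = purrr::map_dbl(agents, "epsilon"))
    out
  })
}
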