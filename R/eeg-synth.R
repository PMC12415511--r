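#' Generative model for synthetic single-trial ERP epochs
#'
#' Describes the statistical structure the scoring and regression stages
#' assume: a negative Gaussian-bump component at a fixed latency over a
#' fronto-central cluster, whose single-trial amplitude carries a feedback
#' valence effect (attenuated for observational agency), a prediction-error
#' coupling, and per-participant offsets, on top of baseline drift and
#' noise. The bump shape is normalized so that its mean over the
#' `latency +- 30 ms` extraction window equals 1; amplitude parameters are
#' therefore expressed directly in scored microvolts.
#'
#' @param latency Component peak latency in ms (post-event).
#' @param width Gaussian bump SD in ms.
#' @param baseline_amp Component amplitude (microvolts) for the reference
#'   condition (win feedback / correct response); negative-going.
#' @param valence_effect Loss-minus-win amplitude difference in microvolts
#'   (negative for a loss-larger negativity).
#' @param obs_attenuation Multiplier in `[0, 1]` applied to
#'   `valence_effect` on observational trials; 1 preserves the active
#'   valence effect (no agency difference), 0 removes valence coding.
#' @param spe_slope Microvolts per unit salience prediction error, applied
#'   with the sign of the feedback valence (so it couples to the signed
#'   prediction error).
#' @param participant_sd SD of per-participant DC offsets (removed by
#'   baseline correction).
#' @param noise_sd SD of the shared cluster noise (white, microvolts); 0
#'   gives noiseless epochs.
#' @param elec_noise_sd SD of small independent per-electrode noise.
#' @param drift_slope Linear baseline drift in microvolts per second.
#' @param artifact_rates Named rates (`spike`, `flat`, `jump`, `step`) at
#'   which epochs are injected with artifacts violating the corresponding
#'   QC rule.
#' @param sfreq Sampling rate in Hz.
#' @return An object of class `erp_gen_model`.
#' @export
erp_gen_model <- function(latency = 260, width = 25, baseline_amp = -5,
                          valence_effect = -3, obs_attenuation = 0.5,
                          spe_slope = 0, participant_sd = 1, noise_sd = 6,
                          elec_noise_sd = 1, drift_slope = 0,
                          artifact_rates = c(spike = 0, flat = 0,
                                             jump = 0, step = 0),
                          sfreq = 500) {
  check_range(obs_attenuation, "obs_attenuation", 0, 1)
  stopifnot(width > 0, sfreq > 0, all(artifact_rates >= 0),
            all(artifact_rates <= 1), participant_sd >= 0, noise_sd >= 0,
            elec_noise_sd >= 0)
  structure(list(latency = latency, width = width,
                 baseline_amp = baseline_amp,
                 valence_effect = valence_effect,
                 obs_attenuation = obs_attenuation, spe_slope = spe_slope,
                 participant_sd = participant_sd, noise_sd = noise_sd,
                 elec_noise_sd = elec_noise_sd, drift_slope = drift_slope,
                 artifact_rates = artifact_rates, sfreq = sfreq),
            class = "erp_gen_model")
}

default_cluster <- c("Fz", "FCz", "FC1", "FC2", "Cz")

#' Generate synthetic single-trial epochs
#'
#' Builds an [epoch_set] for the supplied trials: each epoch is baseline
#' drift plus a negative Gaussian bump whose amplitude follows the
#' generative model (valence effect, agency attenuation, prediction-error
#' coupling from `latents`) plus shared and per-electrode noise.
#' A configurable fraction of epochs is injected with artifacts that
#' violate each QC rule of [qc_epochs()].
#'
#' @param trials Trial table; for feedback-locked epochs, rows with
#'   feedback `"win"`/`"loss"`; for response-locked epochs, rows with a
#'   response and a `correct` column (see [code_accuracy()]).
#' @param gen An [erp_gen_model()].
#' @param latents Optional [extract_latents()] output aligned to `trials`
#'   (matched by `participant_id` and `trial`); required when
#'   `gen$spe_slope != 0`.
#' @param lock `"feedback"` or `"response"`; for response locking the
#'   condition is choice accuracy (`incorrect` playing the role of loss).
#' @param electrodes Electrode cluster labels.
#' @param seed Integer seed; generation is fully reproducible.
#' @return An [epoch_set].
#' @export
generate_epochs <- function(trials, gen = erp_gen_model(), latents = NULL,
                            lock = c("feedback", "response"),
                            electrodes = default_cluster, seed = 1) {
  lock <- match.arg(lock)
  stopifnot(inherits(gen, "erp_gen_model"))
  if (lock == "feedback") {
    trials <- dplyr::filter(trials, .data$feedback %in% c("win", "loss"))
    neg_cond <- trials$feedback == "loss"
  } else {
    if (!"correct" %in% names(trials)) {
      abort("Response-locked generation needs a `correct` column (code_accuracy()).")
    }
    trials <- dplyr::filter(trials, !is.na(.data$chosen),
                            !is.na(.data$correct))
    neg_cond <- !trials$correct
  }
  n <- nrow(trials)
  if (n == 0L) abort("No eligible trials to generate epochs for.")

  spe_signed <- rep(0, n)
  if (!is.null(latents)) {
    key_t <- paste(trials$participant_id, trials$trial)
    key_l <- paste(latents$participant_id, latents$trial)
    idx <- match(key_t, key_l)
    if (anyNA(idx)) abort("`latents` are not aligned to `trials`.")
    pe <- latents$pe[idx]
    pe[is.na(pe)] <- 0
    spe_signed <- pe # |pe| signed by valence equals the signed pe
  } else if (gen$spe_slope != 0) {
    abort("`latents` must be supplied when `spe_slope` is non-zero.")
  }

  dt <- 1000 / gen$sfreq
  times <- seq(-200, 600, by = dt)
  ns <- length(times)
  shape <- exp(-(times - gen$latency)^2 / (2 * gen$width^2))
  win_idx <- which(times >= gen$latency - 30 & times <= gen$latency + 30)
  shape <- shape / mean(shape[win_idx])

  agency <- if ("agency" %in% names(trials)) trials$agency else
    rep("active", n)
  v_eff <- gen$valence_effect *
    ifelse(agency == "observational", gen$obs_attenuation, 1)

  with_seed_if(seed, {
    pid <- trials$participant_id
    offsets <- rnorm(length(unique(pid)), 0, gen$participant_sd)
    names(offsets) <- unique(pid)
    amp <- gen$baseline_amp + ifelse(neg_cond, v_eff, 0) +
      gen$spe_slope * spe_signed
    volt <- array(0, dim = c(n, length(electrodes), ns))
    drift <- gen$drift_slope * (times / 1000)
    for (i in seq_len(n)) {
      shared <- amp[i] * shape + offsets[[pid[i]]] + drift +
        if (gen$noise_sd > 0) rnorm(ns, 0, gen$noise_sd) else 0
      for (e in seq_along(electrodes)) {
        volt[i, e, ] <- shared +
          if (gen$elec_noise_sd > 0) rnorm(ns, 0, gen$elec_noise_sd) else 0
      }
    }
    # Artifact injection, one epoch at a time, one rule per draw.
    art <- rep(NA_character_, n)
    rates <- gen$artifact_rates
    for (i in seq_len(n)) {
      for (rule in names(rates)) {
        if (rates[[rule]] > 0 && runif(1) < rates[[rule]]) {
          v <- matrix(volt[i, , ], nrow = length(electrodes))
          volt[i, , ] <- inject_artifact(v, rule, times)
          art[i] <- rule
          break
        }
      }
    }
    keys <- dplyr::select(trials, dplyr::any_of(
      c("participant_id", "group", "agency", "session", "phase", "block",
        "trial", "pair", "chosen", "feedback", "rt")))
    keys$condition <- if (lock == "feedback") trials$feedback else
      ifelse(neg_cond, "incorrect", "correct")
    keys$injected_artifact <- art
    epoch_set(volt, times, electrodes, lock, gen$sfreq, keys)
  })
}

inject_artifact <- function(v, rule, times) {
  ns <- ncol(v)
  mid <- ns %/% 2L
  switch(rule,
    spike = { v[, mid] <- v[, mid] + 150; v },
    flat = matrix(0.01 * sin(seq_len(ns) / ns), nrow = nrow(v),
                  ncol = ns, byrow = TRUE),
    jump = v + matrix(seq(0, 250, length.out = ns), nrow = nrow(v),
                      ncol = ns, byrow = TRUE),
    step = { v[, mid:ns] <- v[, mid:ns] + 80; v },
    v)
}

#' Single-trial epoch container
#'
#' A lightweight container for per-trial voltage arrays: a numeric array
#' `voltage` of dimension trials x electrodes x samples, the time axis in
#' ms relative to the locking event, the electrode labels, and a tibble of
#' trial keys linking every epoch to exactly one task trial.
#'
#' @param voltage Numeric array, trials x electrodes x samples.
#' @param times Numeric vector of sample times (ms).
#' @param electrodes Character vector of electrode labels.
#' @param lock `"feedback"` or `"response"`.
#' @param sfreq Sampling rate (Hz).
#' @param trials Tibble of trial keys, one row per epoch.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(voltage, times, electrodes, lock, sfreq, trials) {
  stopifnot(length(dim(voltage)) == 3L,
            dim(voltage)[3] == length(times),
            dim(voltage)[2] == length(electrodes),
            dim(voltage)[1] == nrow(trials))
  structure(list(voltage = voltage, times = times, electrodes = electrodes,
                 lock = lock, sfreq = sfreq, trials = trials),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat("<epoch_set>", dim(x$voltage)[1], "epochs x",
      length(x$electrodes), "electrodes x", length(x$times),
      sprintf("samples (%s-locked, %g Hz, %g..%g ms)\n", x$lock, x$sfreq,
              min(x$times), max(x$times)))
  invisible(x)
}

#' @export
dim.epoch_set <- function(x) dim(x$voltage)

#' Number of epochs
#' @param x An [epoch_set].
#' @return Integer epoch count.
#' @export
n_epochs <- function(x) dim(x$voltage)[1]

# Subset an epoch_set by epoch index.
subset_epochs <- function(x, idx) {
  epoch_set(x$voltage[idx, , , drop = FALSE], x$times, x$electrodes,
            x$lock, x$sfreq, x$trials[idx, , drop = FALSE])
}

#' Long-format view of an epoch set
#'
#' @param x An [epoch_set].
#' @param ... Unused.
#' @return A tibble with one row per epoch x electrode x sample:
#'   `epoch`, trial keys, `electrode`, `time`, `voltage`.
#' @export
tidy.epoch_set <- function(x, ...) {
  d <- dim(x$voltage)
  out <- tibble::tibble(
    epoch = rep(seq_len(d[1]), times = d[2] * d[3]),
    electrode = rep(rep(x$electrodes, each = d[1]), times = d[3]),
    time = rep(x$times, each = d[1] * d[2]),
    voltage = as.vector(x$voltage))
  keys <- dplyr::mutate(x$trials, epoch = dplyr::row_number())
  dplyr::left_join(out, keys, by = "epoch")
}
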