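noiseless_gen <- function(...) {
  erp_gen_model(noise_sd = 0, elec_noise_sd = 0, participant_sd = 0, ...)
}

test_that("epoch generation is deterministic and correctly dimensioned", {
  s <- simulate_active_session(seed = 3)
  gen <- erp_gen_model()
  e1 <- generate_epochs(s, gen, seed = 8)
  e2 <- generate_epochs(s, gen, seed = 8)
  expect_identical(e1, e2)
  expect_equal(dim(e1), c(sum(s$feedback != "none"), 5, 401))
  expect_equal(range(e1$times), c(-200, 600))
  expect_equal(nrow(e1$trials), n_epochs(e1))
  long <- tidy(e1)
  expect_equal(nrow(long), prod(dim(e1)))
  # spot-check the long view against the array
  expect_equal(long$voltage[long$epoch == 2 & long$electrode == "Cz" &
                              long$time == 0],
               e1$voltage[2, 5, which(e1$times == 0)])
})

test_that("artifact injection matches the configured rates in expectation", {
  s <- simulate_active_session(seed = 3)
  gen <- erp_gen_model(artifact_rates = c(spike = 0.1, flat = 0.1,
                                          jump = 0, step = 0))
  e <- generate_epochs(s, gen, seed = 9)
  n <- n_epochs(e)
  counts <- table(factor(e$trials$injected_artifact,
                         levels = c("spike", "flat")))
  # spike drawn first at rate .1; flat at .1 of the remainder
  expect_lt(abs(counts[["spike"]] / n - 0.1), 3 * sqrt(0.1 * 0.9 / n))
  expect_lt(abs(counts[["flat"]] / n - 0.09), 3 * sqrt(0.09 * 0.91 / n))
})

test_that("baseline correction centers the pre-event interval and is idempotent", {
  s <- simulate_active_session(seed = 3)
  e <- generate_epochs(s, erp_gen_model(noise_sd = 3), seed = 10)
  b1 <- baseline_correct(e)
  pre <- b1$times < 0
  base_means <- apply(b1$voltage[, , pre], c(1, 2), mean)
  expect_lt(max(abs(base_means)), 1e-12)
  b2 <- baseline_correct(b1)
  expect_equal(b2$voltage, b1$voltage)
  # a constant epoch becomes all-zero
  const <- epoch_set(array(7, c(1, 1, 11)), seq(-200, 0, by = 20), "FCz",
                     "feedback", 50, tibble::tibble(trial = 1))
  expect_true(all(baseline_correct(const)$voltage == 0))
})

test_that("each QC rule fires on its crafted violation and spares clean epochs", {
  times <- seq(-200, 600, by = 2)
  ns <- length(times)
  mk <- function(x) epoch_set(array(rep(x, each = 1), c(1, 1, ns)), times,
                              "FCz", "feedback", 500,
                              tibble::tibble(trial = 1))
  clean <- sin(times / 40) * 5
  spike <- clean; spike[200] <- 120
  flat <- rep(0.01, ns)
  # 250 uV rise within 150 ms, riding on a small oscillation so neither
  # the flatline nor the step rule fires first
  drifty <- pmin(pmax(times, 0), 150) / 150 * 250 + sin(times / 40) * 2
  steppy <- clean; steppy[200:ns] <- steppy[200:ns] + 80

  expect_equal(n_epochs(qc_epochs(mk(clean))), 1)
  r_spike <- qc_epochs(mk(spike))
  expect_equal(n_epochs(r_spike), 0)
  expect_equal(attr(r_spike, "rejections")$rule, "amplitude")
  expect_equal(attr(qc_epochs(mk(flat)), "rejections")$rule, "flatline")
  # the 250 uV sweep violates both the absolute and the windowed-difference
  # rule; relaxing the amplitude limit isolates the latter
  expect_equal(attr(qc_epochs(mk(drifty)), "rejections")$rule, "amplitude")
  expect_equal(attr(qc_epochs(mk(drifty), amp_limit = 300),
                    "rejections")$rule, "difference")
  expect_equal(attr(qc_epochs(mk(steppy)), "rejections")$rule, "step")
})

test_that("the composite waveform weights conditions equally", {
  times <- seq(-200, 600, by = 2)
  ns <- length(times)
  mk_set <- function(n_win, n_loss) {
    volt <- array(NA_real_, c(n_win + n_loss, 1, ns))
    for (i in seq_len(n_win)) volt[i, 1, ] <- 2
    for (i in seq_len(n_loss)) volt[n_win + i, 1, ] <- -4
    epoch_set(volt, times, "FCz", "feedback", 500,
              tibble::tibble(participant_id = "P1",
                             trial = seq_len(n_win + n_loss),
                             condition = rep(c("win", "loss"),
                                             c(n_win, n_loss))))
  }
  comp_bal <- composite_waveform(mk_set(10, 10))
  expect_true(all(comp_bal$amplitude == -1))
  # 90/10 imbalance leaves the composite unchanged
  comp_imb <- composite_waveform(mk_set(18, 2))
  expect_equal(comp_imb$amplitude, comp_bal$amplitude)
  # identical grand averages reproduce themselves
  same <- mk_set(5, 5)
  same$voltage[] <- 3
  expect_true(all(composite_waveform(same)$amplitude == 3))
  # an expected condition with no epochs is a named error
  win_only <- mk_set(5, 5)
  win_only$trials$condition <- "win"
  expect_error(composite_waveform(win_only, conditions = c("win", "loss")),
               "'loss' has no epochs")
})

test_that("peak search returns the printed extraction windows", {
  comp <- tibble::tibble(time = 0:600,
                         amplitude = (0:600 - 261)^2 / 1e3 - 5)
  w <- find_peak_window(comp, search = c(200, 350))
  expect_equal(w$peak_latency, 261)
  expect_equal(w$window, c(231, 291))

  comp2 <- tibble::tibble(time = -200:600,
                          amplitude = (-200:600 - 19)^2 / 1e3)
  w2 <- find_peak_window(comp2, search = c(0, 100))
  expect_equal(w2$window, c(-11, 49))

  # monotone composite: earliest (left-edge) latency wins
  mono <- tibble::tibble(time = 0:600, amplitude = 0:600)
  expect_equal(find_peak_window(mono, c(200, 350))$peak_latency, 200)
  # ties resolve to the earliest sample
  tied <- tibble::tibble(time = 0:600, amplitude = rep(1, 601))
  expect_equal(find_peak_window(tied, c(200, 350))$peak_latency, 200)
  expect_error(find_peak_window(comp, c(-300, 350)), "outside")
})

test_that("scoring returns window means per trial and electrode", {
  times <- seq(-200, 600, by = 2)
  ns <- length(times)
  const <- epoch_set(array(-3, c(1, 2, ns)), times, c("Fz", "Cz"),
                     "feedback", 500, tibble::tibble(trial = 1))
  sc <- score_trials(const, c(231, 291))
  expect_equal(nrow(sc), 2)
  expect_true(all(sc$amplitude == -3))
  expect_error(score_trials(const, c(500, 700)), "exceeds")

  # a noiseless bump scores as the analytic window mean of its shape
  gen <- noiseless_gen(latency = 260, width = 25, baseline_amp = -6,
                       valence_effect = 0)
  s <- simulate_active_session(seed = 3)
  e <- generate_epochs(s[s$feedback == "win", ], gen, seed = 1)
  in_win <- times >= 230 & times <= 290
  shape <- exp(-(times - 260)^2 / (2 * 25^2))
  expected <- -6 * mean(shape[in_win]) / mean(shape[in_win]) # = -6
  sc2 <- score_trials(baseline_correct(e), c(230, 290))
  expect_equal(unique(round(sc2$amplitude, 9)), round(expected, 9))
  # a window fully off the bump scores ~baseline
  sc3 <- score_trials(baseline_correct(e), c(-200, -140))
  expect_lt(max(abs(sc3$amplitude)), 1e-9)
})

test_that("the noiseless valence effect survives the pipeline exactly", {
  s <- simulate_active_session(seed = 5)
  gen <- noiseless_gen(latency = 260, width = 25, baseline_amp = -5,
                       valence_effect = -3)
  e <- baseline_correct(generate_epochs(s, gen, seed = 2))
  comp <- composite_waveform(e)
  w <- find_peak_window(comp, c(200, 350))
  expect_equal(w$peak_latency, 260)
  sc <- score_trials(e, w)
  m <- tapply(sc$amplitude, sc$condition, mean)
  expect_equal(unname(m[["loss"]] - m[["win"]]), -3, tolerance = 1e-12)
})

test_that("observational attenuation = 1 preserves the valence effect", {
  spec <- cohort_spec(n_per_group = c(HC = 2))
  tr <- simulate_cohort(spec, seed = 6)
  gen <- noiseless_gen(valence_effect = -3, obs_attenuation = 1)
  e <- baseline_correct(generate_epochs(tr, gen, seed = 3))
  sc <- score_trials(e, c(230, 290))
  by_ag <- dplyr::summarise(
    dplyr::group_by(sc, agency, condition),
    amp = mean(amplitude), .groups = "drop")
  d_active <- diff(by_ag$amp[by_ag$agency == "active"])
  d_obs <- diff(by_ag$amp[by_ag$agency == "observational"])
  expect_equal(d_active, d_obs, tolerance = 1e-12)
})
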