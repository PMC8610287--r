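make_gt <- function(spiking = spiking_relu(1, 0.5)) {
  standard_neuron(2, nl_linear(), spiking = spiking)
}

test_that("trials are bit-identical under a repeated seed", {
  pop <- shared_pop()
  nrn <- make_gt()
  stim <- stimulus_spec("tone", 5, itd = 0)
  t1 <- generate_trial(nrn, pop, stim, seed = 7, psp_gain = 0.5)
  t2 <- generate_trial(nrn, pop, stim, seed = 7, psp_gain = 0.5)
  expect_identical(t1$v, t2$v)
  expect_identical(t1$spike_times, t2$spike_times)
  t3 <- generate_trial(nrn, pop, stim, seed = 8, psp_gain = 0.5)
  expect_false(identical(t1$v, t3$v))
})

test_that("noiseless spikeless traces carry exactly the model PSP", {
  pop <- shared_pop()
  nrn <- make_gt()
  stim <- stimulus_spec("tone", 5, itd = 0)
  tr <- generate_trial(nrn, pop, stim, seed = 1, noise_sd = 0,
                       psp_gain = 0.3, spikes = FALSE)
  v_true <- 0.3 * sum(vapply(nrn$subunits, subunit_response, numeric(1),
                             pop = pop,
                             rates = tone_response(pop, 5, 0)))
  expect_equal(median_psp(tr), -65 + v_true, tolerance = 1e-12)
})

test_that("median PSP resists inserted action potentials", {
  # constant -60 mV trace with 5 spike waveforms: median moves < 0.5 mV
  dt <- 0.05
  tt <- seq(0, 100, by = dt)
  v <- rep(-60, length(tt))
  wf <- icxfreq:::spike_waveform(dt)
  for (ts in c(15, 25, 35, 45, 55)) {
    i <- which.min(abs(tt - ts))
    idx <- i:(i + length(wf) - 1)
    v[idx] <- v[idx] + wf
  }
  expect_lt(abs(median_psp(list(t = tt, v = v)) + 60), 0.5)
  # plain median semantics and window guard
  expect_equal(median_psp(list(t = c(12, 20, 29, 34), v = c(1, 2, 100, -9)),
                          onset = 10, window = 20), 2)
  expect_error(median_psp(list(t = seq(0, 40), v = rep(0, 41))), "window")
})

test_that("silent stimuli leave the median at baseline on average", {
  pop <- iccl_population(bf_range = c(4, 6), bf_step = 0.5)
  nrn <- make_gt()
  stim <- stimulus_spec("tone", 5, itd = 0, level_scale = 0)
  meds <- vapply(1:60, function(s)
    median_psp(generate_trial(nrn, pop, stim, seed = s, noise_sd = 1,
                              spikes = FALSE)),
    numeric(1))
  se <- sd(meds) / sqrt(length(meds))
  expect_lt(abs(mean(meds) + 65), 3 * se + 0.05)
})

test_that("trial averages combine medians and spike counts", {
  fake_trial <- function(level) list(t = seq(0, 100, 0.5),
                                     v = rep(level, 201), spike_times = c(1, 2))
  set <- structure(list(trials = list(lapply(c(-60, -58, -56), fake_trial))),
                   class = "recording_set")
  avg <- trial_average(set, 1)
  expect_equal(avg$psp_mv, -58)
  expect_equal(avg$spike_count, 2)
  set$trials[[1]] <- set$trials[[1]][1:2]
  expect_error(trial_average(set, 1), "3 trials")
})

test_that("trial averaging shrinks the PSP estimator as 1/sqrt(k)", {
  pop <- iccl_population(bf_range = c(4, 6), bf_step = 0.5)
  nrn <- make_gt()
  stim <- stimulus_spec("tone", 5, itd = 0)
  meds <- matrix(vapply(1:300, function(s)
    median_psp(generate_trial(nrn, pop, stim, seed = 2000 + s, noise_sd = 1,
                              psp_gain = 0.5, spikes = FALSE)),
    numeric(1)), nrow = 3)
  sd1 <- sd(meds[1, ])
  sd3 <- sd(colMeans(meds))
  expect_equal(sd3 / sd1, 1 / sqrt(3), tolerance = 0.25)
})

test_that("V_add sums baseline-referenced tone responses", {
  expect_equal(v_add(c(-60, -60), -60), 0)
  expect_equal(v_add(c(-57, -56), -60), 7)
  expect_equal(v_add(-55, -60), 5)
  expect_error(v_add(c(-61, -55), -60), "v_min")
})

test_that("experiments are deterministic and sublinear at the main peak", {
  cfgs <- list(
    list(subunit_nl = list(kind = "linear")),
    list(subunit_nl = list(kind = "power", p = 2)),
    list(subunit_nl = list(kind = "sigmoid", s0 = 1, s1 = 0.3, s2 = 10)))
  for (cfg in cfgs) {
    cfg$itd_grid <- seq(-120, 120, by = 30)
    e1 <- build_experiment(cfg, seed = 5)
    ipk <- which.max(e1$vadd_vstack$v_add)
    expect_lt(e1$vadd_vstack$v_stack[ipk], e1$vadd_vstack$v_add[ipk])
  }
  cfg <- cfgs[[1]]; cfg$itd_grid <- seq(-120, 120, by = 30)
  e2 <- build_experiment(cfg, seed = 5)
  e1 <- build_experiment(cfg, seed = 5)
  expect_identical(e1$vadd_vstack, e2$vadd_vstack)
  expect_identical(e1$scatter, e2$scatter)
})

test_that("experiment tables land on disk with metadata", {
  cfg <- list(itd_grid = seq(-90, 90, by = 30), n_trials = 3)
  e <- build_experiment(cfg, seed = 3)
  dir <- tempfile()
  write_experiment(e, dir)
  expect_true(all(file.exists(file.path(dir,
    c("tuning.csv", "vadd_vstack.csv", "spiking_scatter.csv",
      "metadata.json")))))
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"))
  expect_equal(meta$seed, 3)
})

test_that("spiking-nonlinearity parameters are recovered from scatters", {
  # ground truths read back from the full recording pipeline:
  # 50 stimuli (5 tone frequencies x 10 ITDs), 5 trials, 0.5 mV noise
  base <- list(freqs = c(3.5, 4.25, 5, 5.75, 6.5),
               itd_grid = seq(-135, 135, by = 30),
               noise_sd = 0.5, n_trials = 5)
  recover <- function(spiking, model, truth) {
    cfg <- c(base, list(spiking = spiking))
    est <- rowMeans(sapply(c(2, 9, 16), function(seed) {
      e <- build_experiment(cfg, seed = seed)
      tones <- e$tuning$kind == "tone"
      fit_model(e$scatter$x[tones], e$scatter$y[tones], model)$params[names(truth)]
    }))
    abs(est - truth) / abs(truth)
  }
  err_relu <- recover(list(kind = "relu", a0 = 2, a1 = 0.5), "relu",
                      c(a0 = 2, a1 = 0.5))
  expect_lt(max(err_relu), 0.1)
  err_sig <- recover(list(kind = "sigmoid", c0 = 8, c1 = 0.8, c2 = 6),
                     "spiking_sigmoid", c(c0 = 8, c1 = 0.8, c2 = 6))
  expect_lt(max(err_sig), 0.1)
})

test_that("subthreshold ground-truth classes are recovered end to end", {
  base <- list(itd_grid = seq(-240, 240, by = 30), n_trials = 5,
               noise_sd = 0.5,
               spiking = list(kind = "relu", a0 = 0.5, a1 = 0.1))
  lin_cfg <- c(base, list(subunit_nl = list(kind = "linear")))
  sat_cfg <- c(base, list(subunit_nl = list(kind = "sigmoid", s0 = 1,
                                            s1 = 0.35, s2 = 8)))
  sat_wins <- character(0)
  for (seed in c(4, 14, 24)) {
    # linear ground truth: the V_add-V_stack relation has no systematic
    # curvature (relative quadratic departure below 5% of the linear span)
    e <- build_experiment(lin_cfg, seed = seed)
    fq <- fit_model(e$vadd_vstack$v_add, e$vadd_vstack$v_stack, "quadratic")
    span <- diff(range(e$vadd_vstack$v_add))
    curvature <- abs(fq$params[["b2"]]) * span^2
    expect_lt(curvature / (abs(fq$params[["b1"]]) * span), 0.05)
    # saturating ground truth: classified, and never as linear
    e2 <- build_experiment(sat_cfg, seed = seed)
    sat_wins <- c(sat_wins, compare_models(e2$vadd_vstack$v_add,
                                           e2$vadd_vstack$v_stack)$winner)
  }
  sat_concl <- sat_wins[sat_wins != "inconclusive"]
  expect_gt(length(sat_concl), 0)
  expect_true(all(sat_concl %in% c("quadratic", "stack_sigmoid")))
})
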