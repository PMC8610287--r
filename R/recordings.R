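#' Specify an acoustic stimulus
#'
#' Tones, tone stacks (two or three simultaneous tones at matched overall
#' level) and broadband noise, all dichotic with a single ITD.
#'
#' @param kind `"tone"`, `"tone_stack"` or `"broadband"`.
#' @param freqs tone frequencies, kHz (1 for a tone, 2-3 distinct values
#'   for a stack; ignored for broadband).
#' @param itd stimulus ITD, microseconds.
#' @param duration stimulus duration, ms (> 60 so the analysis window
#'   fits; default 100).
#' @param level_scale overall stimulus level in \[0, 1\].
#' @return an object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(kind = c("tone", "tone_stack", "broadband"),
                          freqs = numeric(), itd = 0, duration = 100,
                          level_scale = 1) {
  kind <- match.arg(kind)
  if (kind == "tone") stopifnot(length(freqs) == 1)
  if (kind == "tone_stack")
    stopifnot(length(freqs) %in% 2:3, !anyDuplicated(freqs))
  stopifnot(duration > 60, level_scale >= 0, level_scale <= 1)
  structure(list(kind = kind, freqs = freqs, itd = itd,
                 duration = duration, level_scale = level_scale),
            class = "stimulus_spec")
}

# ICcl rate vector for a stimulus.  Stack components carry level 1/m each
# so the overall level matches the single tones; rates add across
# components.  `level_exponent` is the sound-level-to-rate exponent
# (rates scale as level^gamma; 1 = proportional).
stimulus_rates <- function(pop, stim, freq_tuning_width = 0.5,
                           level_exponent = 1) {
  lev <- function(l) l^level_exponent
  switch(stim$kind,
    tone = tone_response(pop, stim$freqs, stim$itd,
                         level_scale = lev(stim$level_scale),
                         freq_tuning_width = freq_tuning_width),
    tone_stack = {
      m <- length(stim$freqs)
      Reduce(`+`, lapply(stim$freqs, function(f)
        tone_response(pop, f, stim$itd,
                      level_scale = lev(stim$level_scale / m),
                      freq_tuning_width = freq_tuning_width)))
    },
    broadband = lev(stim$level_scale) * as.vector(iccl_rates(pop, stim$itd)))
}

# Noiseless model PSP (model units) of a two-layer neuron for a stimulus.
true_psp <- function(neuron, pop, stim, freq_tuning_width = 0.5,
                     level_exponent = 1) {
  rates <- stimulus_rates(pop, stim, freq_tuning_width, level_exponent)
  sum(vapply(neuron$subunits, subunit_response, numeric(1),
             pop = pop, rates = rates))
}

# Stereotyped biphasic action-potential waveform (2 ms, ~+40 mV peak with
# a small afterhyperpolarization), sampled at dt.
spike_waveform <- function(dt, peak = 40) {
  tt <- seq(0, 2, by = dt)
  peak * exp(-((tt - 0.4) / 0.18)^2) - 0.2 * peak * exp(-((tt - 1.1) / 0.35)^2)
}

# Exact-discretization Ornstein-Uhlenbeck noise with stationary SD `sd`
# and correlation time `tau` (ms).
ou_noise <- function(n, dt, sd, tau) {
  if (sd == 0) return(rep(0, n))
  rho <- exp(-dt / tau)
  x <- numeric(n)
  innov <- stats::rnorm(n, 0, sd)
  x[1] <- innov[1]
  s <- sqrt(1 - rho^2)
  for (i in 2:n) x[i] <- x[i - 1] * rho + s * innov[i]
  x
}

#' Generate one synthetic intracellular trial
#'
#' Produces a membrane-potential trace emulating an in vivo sharp-electrode
#' recording: baseline plus the ground-truth two-layer PSP (scaled to mV,
#' with 5-ms linear rise/fall envelopes), Ornstein-Uhlenbeck membrane
#' noise, and - when the ground-truth neuron has a spiking nonlinearity -
#' spikes drawn as an inhomogeneous Poisson process whose instantaneous
#' rate is the spiking nonlinearity of the instantaneous depolarization,
#' normalized per stimulus window; each spike adds a stereotyped 2-ms
#' waveform.  Fully reproducible from `seed`.
#'
#' @param neuron ground-truth [two_layer_neuron()].
#' @param pop an [iccl_population()].
#' @param stim a [stimulus_spec()].
#' @param seed integer seed for this trial.
#' @param noise_sd OU noise SD, mV (default 1).
#' @param baseline resting potential, mV.
#' @param psp_gain mV of somatic PSP per model drive unit.
#' @param dt sampling interval, ms (default 0.05).
#' @param ou_tau OU correlation time, ms.
#' @param freq_tuning_width ICcl Gaussian frequency tuning width, kHz.
#' @param refractory absolute refractory period for spike generation, ms.
#' @param level_exponent sound-level-to-rate exponent (1 = proportional).
#' @param spikes logical; disable to generate purely subthreshold traces.
#' @return an object of class `recording_trial`: list with `t`, `v`,
#'   `spike_times`, `seed`, `stim`.
#' @export
generate_trial <- function(neuron, pop, stim, seed, noise_sd = 1,
                           baseline = -65, psp_gain = 1, dt = 0.05,
                           ou_tau = 5, freq_tuning_width = 0.5,
                           refractory = 1, level_exponent = 1,
                           spikes = TRUE) {
  stopifnot(inherits(stim, "stimulus_spec"), noise_sd >= 0)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  tt <- seq(0, stim$duration, by = dt)
  n <- length(tt)
  v_true <- psp_gain * true_psp(neuron, pop, stim, freq_tuning_width,
                                level_exponent)
  env <- pmin(1, pmin(tt / 5, (stim$duration - tt) / 5))
  env <- pmax(env, 0)
  v <- baseline + env * v_true + ou_noise(n, dt, noise_sd, ou_tau)

  spike_times <- numeric(0)
  if (spikes && !is.null(neuron$spiking)) {
    # normalize by the envelope-integrated (effective) stimulus window so
    # that the expected count at steady depolarization V equals f(V)
    t_eff <- sum(env) * dt
    lam <- spike_rate(neuron$spiking, v - baseline) / t_eff  # events/ms
    p <- pmin(1, lam * dt)
    cand <- which(stats::runif(n) < p)
    if (length(cand)) {
      keep <- cand[1]
      for (i in cand[-1])
        if (tt[i] - tt[keep[length(keep)]] >= refractory) keep <- c(keep, i)
      spike_times <- tt[keep]
      wf <- spike_waveform(dt)
      for (i in keep) {
        idx <- i:min(n, i + length(wf) - 1)
        v[idx] <- v[idx] + wf[seq_along(idx)]
      }
    }
  }
  structure(list(t = tt, v = v, spike_times = spike_times, seed = seed,
                 stim = stim), class = "recording_trial")
}

#' Median PSP of a trial
#'
#' Median of the membrane potential over the analysis window
#' `[onset, onset + window)` (default: the 50 ms of the response starting
#' 10 ms after sound onset).  The median makes the measure robust to the
#' brief action-potential waveforms riding on the PSP.
#'
#' @param trial a `recording_trial` (or any list with `t` and `v`).
#' @param onset window start after sound onset, ms.
#' @param window window length, ms.
#' @return median membrane potential, mV.
#' @export
median_psp <- function(trial, onset = 10, window = 50) {
  if (onset + window > max(trial$t) + 1e-9)
    stop("analysis window [", onset, ", ", onset + window,
         ") extends beyond the trace (", max(trial$t), " ms)")
  sel <- trial$t >= onset & trial$t < onset + window
  stats::median(trial$v[sel])
}

#' Generate a full set of trials for a battery of stimuli
#'
#' @param neuron ground-truth [two_layer_neuron()].
#' @param pop an [iccl_population()].
#' @param stimuli list of [stimulus_spec()] objects.
#' @param n_trials trials per stimulus (3-5).
#' @param seed base seed; per-trial seeds are derived deterministically.
#' @param ... passed to [generate_trial()].
#' @return an object of class `recording_set`: list with `trials` (list of
#'   per-stimulus lists of `recording_trial`), `stimuli`, `ground_truth`.
#' @export
generate_recording_set <- function(neuron, pop, stimuli, n_trials = 4,
                                   seed = 1, ...) {
  stopifnot(n_trials >= 3, n_trials <= 5)
  trials <- vector("list", length(stimuli))
  k <- 0L
  for (s in seq_along(stimuli)) {
    trials[[s]] <- lapply(seq_len(n_trials), function(r) {
      generate_trial(neuron, pop, stimuli[[s]],
                     seed = (seed + 1009L * (k + r)) %% 2147483647L, ...)
    })
    k <- k + n_trials
  }
  structure(list(trials = trials, stimuli = stimuli, ground_truth = neuron),
            class = "recording_set")
}

#' Trial-averaged response to one stimulus
#'
#' Mean over trials of the per-trial median PSP, plus the mean spike
#' count.
#'
#' @param set a `recording_set`.
#' @param stimulus stimulus index into `set$stimuli`.
#' @param onset,window analysis window passed to [median_psp()].
#' @return list with `psp_mv` and `spike_count`.
#' @export
trial_average <- function(set, stimulus, onset = 10, window = 50) {
  tr <- set$trials[[stimulus]]
  if (is.null(tr) || length(tr) < 3)
    stop("fewer than 3 trials available for stimulus ", stimulus)
  list(psp_mv = mean(vapply(tr, median_psp, numeric(1),
                            onset = onset, window = window)),
       spike_count = mean(vapply(tr, function(x) length(x$spike_times),
                                 numeric(1))))
}

#' Linear prediction of a tone-stack response
#'
#' `V_add` is the sum of the responses to the individual tones, each
#' referenced to the minimum membrane potential recorded during
#' stimulation:
#' \deqn{V_{add} = \sum_k (V_k - V_{min}).}
#' By convention `v_min` is the minimum trial-averaged PSP across all
#' stimuli and ITDs of the experiment, so that all relative responses are
#' nonnegative.
#'
#' @param tone_psps trial-averaged median PSPs to the individual tones at
#'   one ITD, mV.
#' @param v_min experiment-wide minimum trial-averaged PSP, mV.
#' @return `V_add` on the relative (v_min-referenced) scale, mV.
#' @export
v_add <- function(tone_psps, v_min) {
  if (any(tone_psps < v_min - 1e-9))
    stop("a tone response lies below v_min; v_min must be the minimum ",
         "over all stimuli of the experiment")
  sum(tone_psps - v_min)
}

#' Run a complete synthetic tone-stack experiment
#'
#' Orchestrates the full analysis pipeline on synthetic data: builds the
#' ICcl population and a ground-truth two-layer neuron, presents each
#' tone individually and the tone stack at every ITD (matched overall
#' level: each of the m stack components at level 1/m), generates 3-5
#' noisy trials per stimulus, extracts trial-averaged median PSPs and
#' spike counts, and assembles the V_add-V_stack scatter and the
#' spiking scatter consumed by [compare_models()].
#'
#' The ground-truth PSP is scaled so that the largest noiseless response
#' across all stimuli equals `target_amplitude_mv` above baseline.
#'
#' @param config list (or YAML/JSON path, see [read_config()]) with any of:
#'   `sigma` (subunit weight width, kHz; default 2), `subunit_nl`
#'   (`list(kind = "linear")`, `list(kind = "power", p = )` or
#'   `list(kind = "sigmoid", s0 = , s1 = , s2 = , s3 = )`), `n_subunits`
#'   (10), `cf_spread` (0), `spiking` (`list(kind = "relu", a0 = , a1 = )`
#'   or `list(kind = "sigmoid", c0 = , c1 = , c2 = , alpha = )`), `freqs`
#'   (c(4.5, 5.5)), `itd_grid` (-240..240 us step 30), `n_trials` (4),
#'   `noise_sd` (1 mV), `baseline` (-65 mV), `target_amplitude_mv` (12),
#'   `freq_tuning_width` (0.5 kHz), `level_exponent` (1; sound-level-to-
#'   rate exponent).
#' @param seed base seed.
#' @return an object of class `icx_experiment`: list with `tuning`
#'   (per-stimulus trial-averaged ITD tuning data frame), `vadd_vstack`
#'   (data frame `itd_us`, `v_add`, `v_stack`, per-tone relative
#'   responses), `scatter` (spiking scatter: depolarization vs mean spike
#'   count), `v_min`, `psp_gain`, `ground_truth`, `config`.
#' @export
build_experiment <- function(config = list(), seed = 1) {
  config <- read_config(config)
  dflt <- list(sigma = 2, subunit_nl = list(kind = "linear"),
               n_subunits = 10, cf_spread = 0,
               spiking = list(kind = "relu", a0 = 1, a1 = 0.5),
               freqs = c(4.5, 5.5),
               itd_grid = seq(-240, 240, by = 30), n_trials = 4,
               noise_sd = 1, baseline = -65, target_amplitude_mv = 12,
               freq_tuning_width = 0.5, level_exponent = 1)
  config <- utils::modifyList(dflt, config)

  pop <- iccl_population()
  nlspec <- config$subunit_nl
  nl <- switch(nlspec$kind,
               linear = nl_linear(),
               power = nl_power(nlspec$p),
               sigmoid = nl_sigmoid(nlspec$s0, nlspec$s1, nlspec$s2,
                                    nlspec$s3 %||% 0),
               stop("unknown subunit_nl kind: ", nlspec$kind))
  spk <- config$spiking
  spiking <- if (is.null(spk)) NULL else switch(spk$kind,
    relu = spiking_relu(spk$a0, spk$a1),
    sigmoid = spiking_sigmoid(spk$c0, spk$c1, spk$c2, spk$alpha %||% -Inf),
    stop("unknown spiking kind: ", spk$kind))
  neuron <- standard_neuron(config$sigma, nl, n = config$n_subunits,
                            spread = config$cf_spread, spiking = spiking)

  # a stack stimulus needs 2-3 components; with more tone frequencies the
  # experiment characterizes the spiking nonlinearity only
  m <- length(config$freqs)
  with_stack <- m %in% 2:3
  stimuli <- list()
  for (f in config$freqs)
    for (itd in config$itd_grid)
      stimuli[[length(stimuli) + 1]] <- stimulus_spec("tone", f, itd)
  if (with_stack)
    for (itd in config$itd_grid)
      stimuli[[length(stimuli) + 1]] <- stimulus_spec("tone_stack",
                                                      config$freqs, itd)
  stim_tab <- data.frame(
    kind = vapply(stimuli, function(s) s$kind, character(1)),
    freq = vapply(stimuli, function(s)
      if (s$kind == "tone") s$freqs else NA_real_, numeric(1)),
    itd = vapply(stimuli, function(s) s$itd, numeric(1)))

  # deterministic PSP scale: largest noiseless response across stimuli
  v_true <- vapply(stimuli, true_psp, numeric(1), neuron = neuron, pop = pop,
                   freq_tuning_width = config$freq_tuning_width,
                   level_exponent = config$level_exponent)
  psp_gain <- config$target_amplitude_mv / max(v_true)

  set <- generate_recording_set(neuron, pop, stimuli,
                                n_trials = config$n_trials, seed = seed,
                                noise_sd = config$noise_sd,
                                baseline = config$baseline,
                                psp_gain = psp_gain,
                                freq_tuning_width = config$freq_tuning_width,
                                level_exponent = config$level_exponent)
  avg <- lapply(seq_along(stimuli), function(s) trial_average(set, s))
  stim_tab$psp_mv <- vapply(avg, `[[`, numeric(1), "psp_mv")
  stim_tab$spike_count <- vapply(avg, `[[`, numeric(1), "spike_count")

  v_min <- min(stim_tab$psp_mv)
  vv <- if (!with_stack) NULL else
    do.call(rbind, lapply(config$itd_grid, function(itd) {
    tone_psps <- vapply(config$freqs, function(f)
      stim_tab$psp_mv[stim_tab$kind == "tone" & stim_tab$freq == f &
                      stim_tab$itd == itd], numeric(1))
    stack_psp <- stim_tab$psp_mv[stim_tab$kind == "tone_stack" &
                                 stim_tab$itd == itd]
    out <- data.frame(itd_us = itd,
                      v_add = v_add(tone_psps, v_min),
                      v_stack = stack_psp - v_min)
    for (k in seq_len(m)) out[[paste0("v_tone", k)]] <- tone_psps[k] - v_min
    out
  }))

  scatter <- data.frame(x = stim_tab$psp_mv - config$baseline,
                        y = stim_tab$spike_count)

  structure(list(tuning = stim_tab, vadd_vstack = vv, scatter = scatter,
                 v_min = v_min, psp_gain = psp_gain, ground_truth = neuron,
                 config = config, seed = seed),
            class = "icx_experiment")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.icx_experiment <- function(x, ...) {
  cat("Synthetic ICx tone-stack experiment:",
      length(x$config$freqs), "tones at",
      paste(x$config$freqs, collapse = "/"), "kHz,",
      length(x$config$itd_grid), "ITDs,",
      x$config$n_trials, "trials/stimulus\n")
  if (!is.null(x$vadd_vstack))
    cat(sprintf("v_min = %.2f mV; main-peak V_add = %.2f, V_stack = %.2f mV\n",
                x$v_min, max(x$vadd_vstack$v_add),
                x$vadd_vstack$v_stack[which.max(x$vadd_vstack$v_add)]))
  invisible(x)
}

#' Write experiment tables as CSV
#'
#' Writes `tuning.csv`, `vadd_vstack.csv` and `spiking_scatter.csv` into
#' a directory, plus `metadata.json` describing configuration and scale.
#'
#' @param exp an `icx_experiment`.
#' @param dir output directory (created if missing).
#' @export
write_experiment <- function(exp, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(exp$tuning, file.path(dir, "tuning.csv"), row.names = FALSE)
  if (!is.null(exp$vadd_vstack))
    utils::write.csv(exp$vadd_vstack, file.path(dir, "vadd_vstack.csv"),
                     row.names = FALSE)
  utils::write.csv(exp$scatter, file.path(dir, "spiking_scatter.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(config = exp$config, seed = exp$seed,
                            v_min = exp$v_min, psp_gain = exp$psp_gain),
                       file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
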