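test_that("morphology ranges are enforced and corner combos rejected", {
  m <- icx_morphology()
  expect_equal(nrow(m$spines), 40)
  expect_true(all(m$spines$diam >= 0.1 & m$spines$diam <= 0.4))
  expect_error(icx_morphology(soma_diam = 40), "soma")
  expect_error(icx_morphology(dendrite_diam = 2), "dendrites")
  expect_error(icx_morphology(spine_diam = 0.1, spine_length = 80), "corner")
  expect_error(icx_morphology(spine_diam = 0.4, spine_length = 2), "corner")
  # jitter reproducible from seed
  expect_identical(icx_morphology(seed = 3)$spines,
                   icx_morphology(seed = 3)$spines)
})

test_that("config guards conductance range and time step", {
  expect_error(cable_config(g_pas = 0.05), "g_pas")
  expect_error(cable_config(dt = 0.1), "dt")
  cfg <- cable_config(g_pas = list(soma = 0.001, dendrite = 0.002,
                                   spine = 0.0005))
  cell <- build_cable(icx_morphology(), cfg)
  expect_equal(sum(cell$comps$gpas_us[cell$comps$section == "soma"]), 0.001)
  expect_equal(sum(cell$comps$gpas_us[cell$comps$section == "dend1"]), 0.002)
})

test_that("input rates follow the two-tone tuning equation", {
  expect_equal(input_rate(5, 0, 4.5, 5.5, 0, 0), 0.01)
  expect_equal(input_rate(4.5, 0, 4.5, 5.5, 0.3, 0), 0.31)
  # anti-preferred ITD of fin1 (half period) leaves only the floor
  half <- 1000 / (2 * 4.5)
  expect_equal(input_rate(4.5, half, 4.5, 5.5, 0.3, 0), 0.01, tolerance = 1e-9)
  expect_gte(input_rate(8, 0, 4.5, 5.5, 1, 1), 0.01)
})

test_that("Poisson trains have the right mean and exponential intervals", {
  expect_identical(poisson_train(0, 100), numeric(0))
  counts <- vapply(1:1000, function(s)
    length(poisson_train(0.1, 100, seed = s)), numeric(1))
  se <- sd(counts) / sqrt(1000)
  expect_lt(abs(mean(counts) - 10), 3 * se)
  gaps <- unlist(lapply(1:50, function(s)
    diff(poisson_train(0.2, 200, seed = 500 + s))))
  expect_gt(stats::ks.test(gaps, "pexp", 0.2)$p.value, 0.01)
  expect_identical(poisson_train(0.1, 100, seed = 4),
                   poisson_train(0.1, 100, seed = 4))
})

test_that("synaptic conductance kernels match their closed forms", {
  expect_equal(ampa_conductance(10, 10, 2e-3), 2e-3)
  expect_equal(ampa_conductance(10 + 4.5, 10, 2e-3), 2e-3 * exp(-1))
  expect_equal(ampa_conductance(9.99, 10, 2e-3), 0)
  expect_equal(ampa_conductance(12, c(10, 11), 1e-3),
               1e-3 * (exp(-2 / 4.5) + exp(-1 / 4.5)))
  expect_equal(nmda_conductance(0, mg = 1), 1 / (1 + 1 / 3.57))
  expect_equal(nmda_conductance(0, mg = 1), 0.7812, tolerance = 1e-3)
  expect_equal(nmda_conductance(-40, mg = 0), 1)
  expect_lt(nmda_conductance(-120, mg = 1), 0.003)
  expect_error(nmda_conductance(0, mg = -1), "mg")
})

test_that("a synapse-free cable rests exactly at the leak reversal", {
  cell <- build_cable(icx_morphology(), cable_config(duration = 30))
  tr <- simulate_cable(cell)
  expect_equal(max(abs(tr$v + 65)), 0, tolerance = 1e-10)
})

test_that("small-signal AMPA responses scale linearly with weight", {
  cell <- build_cable(icx_morphology(), cable_config(duration = 60))
  peak_at <- function(w) {
    res <- icxfreq:::cable_run_cpp(
      as.integer(cell$comps$parent) - 1L, cell$comps$cm_nf,
      cell$comps$gpas_us, cell$comps$gax_us, -65,
      as.integer(cell$spine_base[1]) - 1L, 0L, w, 0,
      4.5, 0.35, 0.015, 1, 1, 1,
      5, 0L, 1L, 0.025, 1600L, -65,
      numeric(nrow(cell$comps)), as.integer(cell$soma) - 1L)
    max(res$v[, 1]) + 65
  }
  p1 <- peak_at(1e-5); p2 <- peak_at(1e-4)
  expect_equal(p2 / p1, 10, tolerance = 0.02)
})

test_that("steady-state soma deflection matches continuous cable theory", {
  # soma plus one dendrite (one tiny spine contributes a lumped leak);
  # oracle: finite sealed cable with a point admittance load, two-port
  # composition, against the discrete solver at fine spatial grid
  cfg <- cable_config(g_pas = list(soma = 0.001, dendrite = 0.002,
                                   spine = 1e-4),
                      dend_nseg = 60, spine_nseg = 1, duration = 400)
  morph <- icx_morphology(n_dendrites = 1, dendrite_length = 200,
                          dendrite_diam = 5, spines_per_dendrite = 1,
                          spine_diam = 0.1, spine_length = 2,
                          spine_jitter = 0)
  cell <- build_cable(morph, cfg)
  i_inj <- 0.05  # nA
  tr <- simulate_cable(cell, i_soma = i_inj)
  deflection <- tr$v[nrow(tr$v), 1] + 65

  # continuous-cable oracle (units: cm, S, ohm)
  ra_spec <- 100                      # ohm cm
  d <- 5e-4; L <- 200e-4              # cm
  area <- pi * d * L
  g_spec <- 0.002e-6 / area           # S/cm^2
  r_a <- 4 * ra_spec / (pi * d^2)     # ohm/cm
  g_m <- g_spec * pi * d              # S/cm
  lambda <- 1 / sqrt(r_a * g_m)
  yc <- 1 / (r_a * lambda)
  seg_in <- function(l, yl) yc * (yl + yc * tanh(l / lambda)) /
                            (yc + yl * tanh(l / lambda))
  x0 <- 0.5 * L                       # spine sits mid-dendrite
  y_spine <- 1e-4 * 1e-6              # lumped spine leak, S
  y_distal <- seg_in(L - x0, 0)
  y_dend <- seg_in(x0, y_distal + y_spine)
  g_soma <- 0.001e-6
  rin <- 1 / (g_soma + y_dend)        # ohm
  expect_equal(deflection, i_inj * 1e-9 * rin * 1e3, tolerance = 0.02)
})

test_that("halving the time step changes the soma trace by < 0.1 mV RMS", {
  ps <- compartmental_preset("ampa_spine")
  stim <- list(fin1 = 4.5, fin2 = 5.5, itd = 0, w1 = 0.25, w2 = 0.25)
  t1 <- simulate_cable(ps$cell, ps$synapses, stim, seed = 5, dt = 0.025)
  t2 <- simulate_cable(ps$cell, ps$synapses, stim, seed = 5, dt = 0.0125)
  v1 <- t1$v[, 1]
  v2 <- t2$v[seq(1, nrow(t2$v), by = 2), 1]
  expect_lt(sqrt(mean((v1 - v2)^2)), 0.1)
})

test_that("widely separated tones combine additively at tiny weights", {
  morph <- icx_morphology(dendrite_diam = 5)
  cell <- build_cable(morph, cable_config(g_pas = 0.01))
  syn <- place_synapses(cell, "ampa", "dendrite", weight = 2e-5,
                        freqs = c(3, 7))
  med <- function(w1, w2, seed_off = 0) {
    meds <- vapply(1:10, function(r) {
      tr <- simulate_cable(cell, syn,
                           stim = list(fin1 = 3, fin2 = 7, itd = 0,
                                       w1 = w1, w2 = w2),
                           seed = 40 + seed_off + r)
      median_psp(list(t = tr$t, v = tr$v[, 1]))
    }, numeric(1))
    mean(meds) + 65
  }
  v1 <- med(0.25, 0, 0); v2 <- med(0, 0.25, 100); v12 <- med(0.25, 0.25, 200)
  expect_equal(v12, v1 + v2, tolerance = 0.05 * (v1 + v2) / v12)
})

test_that("matched/mismatched split applies a strict 3-mV rule", {
  expect_true(matched_mismatch_split(5, 5))
  expect_false(matched_mismatch_split(5, 8))     # exactly 3 -> mismatched
  expect_true(matched_mismatch_split(5, 7.9))
})

test_that("mismatched tone strengths concentrate on side peaks", {
  ps <- compartmental_preset("ampa_spine")
  res <- combination_experiment(ps$cell, ps$synapses, w1 = ps$w1, w2 = ps$w2,
                                trials = 3, seed = 2)
  d <- res$responses
  main <- abs(d$itd_us - d$itd_us[which.max(d$v_add)]) <= 30
  side <- abs(d$itd_us) >= 150
  expect_gt(mean(!d$matched[side]), mean(!d$matched[main]))
})

test_that("input clustering does not change the combination", {
  morph <- icx_morphology(dendrite_diam = 5)
  cell <- build_cable(morph, cable_config(g_pas = 0.001))
  run <- function(mode) {
    syn <- place_synapses(cell, "ampa", "spine", weight = 2e-3,
                          assignment = mode)
    combination_experiment(cell, syn, trials = 8, seed = 3,
                           itd_grid = seq(-210, 210, by = 60))
  }
  rc <- run("clustered"); ri <- run("interleaved")
  expect_lt(sqrt(mean((rc$responses$v_stack - ri$responses$v_stack)^2)), 1)
  expect_true(rc$classification == ri$classification ||
              "inconclusive" %in% c(rc$classification, ri$classification))
})

test_that("growing synaptic weight never reverts nonlinear to linear", {
  morph <- icx_morphology(dendrite_diam = 5)
  cell <- build_cable(morph, cable_config(g_pas = 0.001))
  cls <- vapply(c(2e-4, 1e-3, 4e-3), function(w) {
    syn <- place_synapses(cell, "ampa", "spine", weight = w)
    combination_experiment(cell, syn, trials = 3, seed = 6,
                           itd_grid = seq(-210, 210, by = 60))$classification
  }, character(1))
  concl <- cls[cls != "inconclusive"]
  nonlin <- concl != "linear"
  expect_true(all(diff(nonlin) >= 0))
})
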