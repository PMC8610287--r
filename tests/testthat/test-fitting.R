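test_that("noiseless data recover generating parameters for all five forms", {
  x <- seq(-2, 4, length.out = 21)
  cases <- list(
    linear = c(b0 = 1, b1 = 2),
    quadratic = c(b0 = 0.5, b1 = 0.1, b2 = 0.05),
    relu = c(a0 = 2, a1 = 3),
    spiking_sigmoid = c(c0 = 8, c1 = 1.5, c2 = 1, alpha = -Inf),
    stack_sigmoid = c(b0 = 0.5, b1 = 0.6, b2 = 6, b3 = 2, b4 = 1))
  for (model in names(cases)) {
    par <- cases[[model]]
    y <- predict_fit(model, par, x)
    fit <- fit_model(x, y, model)
    finite <- is.finite(par)
    expect_equal(fit$params[finite], par[finite], tolerance = 1e-4,
                 label = paste(model, "params"))
    expect_lt(fit$rss, 1e-8)
  }
})

test_that("exact linear interpolation yields zero residual and coefficients", {
  x <- seq(0, 10)
  fit <- fit_model(x, 1 + 2 * x, "linear")
  expect_equal(unname(fit$params), c(1, 2), tolerance = 1e-12)
  expect_equal(fit$rss, 0, tolerance = 1e-12)
})

test_that("quadratic fit matches the normal-equations oracle", {
  set.seed(3)
  x <- runif(25, -5, 5)
  y <- 0.5 + 0.1 * x + 0.05 * x^2 + rnorm(25, 0, 0.3)
  fit <- fit_model(x, y, "quadratic")
  oracle <- unname(coef(lm(y ~ x + I(x^2))))
  expect_equal(unname(fit$params), oracle, tolerance = 1e-6)
})

test_that("ReLU threshold enumeration finds rectified optima", {
  # half the points rectified to zero
  x <- seq(-5, 5, length.out = 24)
  y <- pmax(0, -1 + 0.8 * x)
  fit <- fit_model(x, y, "relu")
  expect_equal(unname(fit$params), c(-1, 0.8), tolerance = 1e-6)
  expect_equal(spike_rate(spiking_relu(fit$params[["a0"]], fit$params[["a1"]]),
                          -fit$params[["a0"]] / fit$params[["a1"]]), 0)
})

test_that("adjusted R-squared matches hand-computed values and guards", {
  expect_equal(adjusted_r2(0, 10, 20, 3), 1)
  expect_equal(adjusted_r2(1, 10, 5, 1), 1 - (1 / 3) / (10 / 4))
  expect_equal(adjusted_r2(1, 10, 5, 1), 0.8667, tolerance = 1e-4)
  expect_equal(adjusted_r2(10, 10, 12, 0), 0)
  expect_error(adjusted_r2(1, 10, 4, 3), "n > p \\+ 1")
})

test_that("LOOCV equals the brute-force oracle on random small datasets", {
  ctrl <- fit_control(min_n = 2)
  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(8:12, 1)
    x <- sort(runif(n, -3, 6))
    y <- 0.5 * x + rnorm(n)
    for (model in c("linear", "quadratic")) {
      expect_equal(loocv_mse(x, y, model, control = ctrl),
                   naive_loocv(x, y, model, ctrl), tolerance = 1e-8)
    }
  }
  # iterative form: package loop vs independent loop, same protocol
  set.seed(99)
  x <- sort(runif(12, -4, 8))
  y <- predict_fit("stack_sigmoid", c(b0 = 0, b1 = 0.3, b2 = 4, b3 = 1.5, b4 = 2),
                   x) + rnorm(12, 0, 0.2)
  expect_equal(loocv_mse(x, y, "stack_sigmoid", control = ctrl),
               naive_loocv(x, y, "stack_sigmoid", ctrl), tolerance = 1e-8)
})

test_that("LOOCV brute force on three collinear-free points gives 3", {
  # points (0,0), (1,1), (2,0): held-out squared errors are 4, 1, 4
  x <- c(0, 1, 2); y <- c(0, 1, 0)
  expect_equal(loocv_mse(x, y, "linear", control = fit_control(min_n = 3)),
               3)
  expect_equal(loocv_mse(x, y, "linear", control = fit_control(min_n = 3)),
               naive_loocv(x, y, "linear"))
  # exact line: every refit reproduces it
  expect_equal(loocv_mse(x, 2 * x + 1, "linear",
                         control = fit_control(min_n = 3)), 0)
})

test_that("winner selection demands dominance on both metrics", {
  mk <- function(r2, cv) structure(list(adjusted_r2 = r2, loocv_mse = cv),
                                   class = "icx_fit")
  expect_equal(select_model(list(a = mk(0.9, 1), b = mk(0.8, 2)))$winner, "a")
  expect_equal(select_model(list(a = mk(0.9, 2), b = mk(0.8, 1)))$winner,
               "inconclusive")
  expect_equal(select_model(list(a = mk(0.7, 3), b = mk(0.9, 1),
                                 c = mk(0.8, 2)))$winner, "b")
})

test_that("redundant parameters cannot raise RSS but can lower adjusted R2", {
  set.seed(5)
  x <- seq(-3, 3, length.out = 15)
  y <- 1 + 0.5 * x + rnorm(15, 0, 0.05)
  f1 <- fit_model(x, y, "linear")
  f2 <- fit_model(x, y, "quadratic")
  expect_lte(f2$rss, f1$rss + 1e-12)
  tss <- sum((y - mean(y))^2)
  expect_lt(adjusted_r2(f2$rss, tss, 15, 3) - adjusted_r2(f1$rss, tss, 15, 2),
            (f1$rss - f2$rss) / tss + 1e-12)
})

test_that("model recovery holds on noisy synthetic scatters", {
  # replicated x design (two observations per input level), mirroring the
  # repeated V_add values that symmetric ITD tuning produces
  run_class <- function(gen, params, n_rep = 25) {
    wins <- vapply(seq_len(n_rep), function(r) {
      set.seed(100 + r)
      x <- rep(seq(0, 12, length.out = 15), 2)
      y0 <- predict_fit(gen, params, x)
      y <- y0 + rnorm(length(x), 0, 0.1 * diff(range(y0)))
      compare_models(x, y)$winner
    }, character(1))
    wins[wins != "inconclusive"]
  }
  # distinctly nonlinear generators are recovered reliably
  quad <- run_class("quadratic", c(b0 = 0.3, b1 = -0.1, b2 = 0.06))
  expect_gte(mean(quad == "quadratic"), 0.75)
  sig <- run_class("stack_sigmoid", c(b0 = 0.2, b1 = 0.15, b2 = 7,
                                      b3 = 1.2, b4 = 6))
  expect_gte(mean(sig == "stack_sigmoid"), 0.9)
  # a linear generator is, at worst, the modal conclusive assignment:
  # flexible competitors can dominate by chance on individual replicates
  lin <- run_class("linear", c(b0 = 1, b1 = 0.6))
  expect_gt(length(lin), 0)
  expect_equal(names(which.max(table(lin))), "linear")
  expect_gte(mean(lin == "linear"), 0.5)
})

test_that("sparse responses are flagged for exclusion", {
  x <- seq(1, 20)
  y <- c(rep(0, 15), 1, 2, 1, 0, 0)
  expect_true(sparse_response(x, y))
  expect_false(sparse_response(x, x))
  # pure noise: no candidate reaches the adjusted-R2 floor
  set.seed(8)
  cmp <- compare_models(rnorm(20), rnorm(20), models = c("linear", "quadratic"))
  expect_true(cmp$excluded)
})

test_that("comparisons serialize to JSON", {
  d <- make_scatter("linear", c(b0 = 0, b1 = 1), n = 15, seed = 2)
  cmp <- compare_models(d$x, d$y, models = c("linear", "quadratic"))
  path <- tempfile(fileext = ".json")
  write_fits(cmp, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$winner, cmp$winner)
  expect_equal(back$fits$linear$params$b1,
               unname(cmp$fits$linear$params["b1"]), tolerance = 1e-12)
})
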