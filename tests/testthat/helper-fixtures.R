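# Shared fixtures built in code at test time.

# Rectified-cosine ITD curve: the b -> 0 limit of the ICcl tuning form,
# (1 + cos(2 pi bf itd/1000))/2, period 1000/bf microseconds.
rectified_cosine_curve <- function(bf = 5, itds = seq(-250, 250, by = 5)) {
  itd_curve(itds, (1 + cos(2 * pi * bf * itds / 1000)) / 2)
}

# Piecewise-linear curve through (itd, value) knots on a 5-us grid.
knot_curve <- function(knots_itd, knots_val, step = 5) {
  itds <- seq(min(knots_itd), max(knots_itd), by = step)
  itd_curve(itds, approx(knots_itd, knots_val, xout = itds)$y)
}

# Default population shared across two-layer tests (bf 0.5-10 step 0.1,
# single best-ITD column at 0).
shared_pop <- local({
  pop <- NULL
  function() {
    if (is.null(pop)) pop <<- iccl_population()
    pop
  }
})

# Deterministic pseudo-random scatter from a generating model plus
# Gaussian noise.
make_scatter <- function(model, params, n = 30, xlim = c(-5, 15),
                         noise_frac = 0.1, seed = 1) {
  set.seed(seed)
  x <- sort(runif(n, xlim[1], xlim[2]))
  y0 <- predict_fit(model, params, x)
  y <- y0 + rnorm(n, 0, noise_frac * diff(range(y0)))
  list(x = x, y = y, y0 = y0)
}

# Naive leave-one-out oracle for loocv_mse.  For the polynomial models
# the held-out refits go through stats::lm (an implementation independent
# of the package's lm.fit-based path); for the iterative models the same
# initialization protocol must be used, so the refit goes through
# fit_model while the loop/bookkeeping stays independent.
naive_loocv <- function(x, y, model, control = fit_control(min_n = 2)) {
  errs <- vapply(seq_along(x), function(i) {
    xi <- x[-i]; yi <- y[-i]
    pred <- if (model == "linear") {
      unname(predict(stats::lm(yi ~ xi), newdata = data.frame(xi = x[i])))
    } else if (model == "quadratic") {
      unname(predict(stats::lm(yi ~ xi + I(xi^2)),
                     newdata = data.frame(xi = x[i])))
    } else {
      f <- fit_model(xi, yi, model, control = control)
      predict_fit(model, f$params, x[i])
    }
    (y[i] - pred)^2
  }, numeric(1))
  mean(errs)
}
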