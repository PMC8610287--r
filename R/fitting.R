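#' Candidate nonlinearity model forms
#'
#' Five response models are available for fitting (input `x`, output `y`):
#' \describe{
#'   \item{`linear`}{`b0 + b1 x` (2 parameters)}
#'   \item{`quadratic`}{`b0 + b1 x + b2 x^2` (3)}
#'   \item{`relu`}{`max(0, a0 + a1 x)`, threshold `-a0/a1` (2)}
#'   \item{`spiking_sigmoid`}{`0` for `x < alpha`, else
#'     `c0 / (1 + exp(-c1 (x - c2)))` (4)}
#'   \item{`stack_sigmoid`}{`b0 + b1 x + b2 / (1 + exp(-b3 (x - b4)))`,
#'     a linear term plus a standard sigmoid (5)}
#' }
#' `relu` and `spiking_sigmoid` are the spiking-nonlinearity candidates
#' (membrane potential to spike count); `linear`, `quadratic` and
#' `stack_sigmoid` are the candidates for the V_add-V_stack relation.
#'
#' @name fit_models
#' @keywords internal
NULL

fit_param_count <- c(linear = 2L, quadratic = 3L, relu = 2L,
                     spiking_sigmoid = 4L, stack_sigmoid = 5L)

#' Predict from a fitted (or hand-specified) model
#'
#' @param model model name (see `fit_models`).
#' @param params named parameter vector for that model.
#' @param x input values.
#' @return predicted response.
#' @export
predict_fit <- function(model, params, x) {
  p <- as.list(params)
  switch(model,
         linear = p$b0 + p$b1 * x,
         quadratic = p$b0 + p$b1 * x + p$b2 * x^2,
         relu = pmax(0, p$a0 + p$a1 * x),
         spiking_sigmoid = ifelse(x < p$alpha, 0,
                                  p$c0 / (1 + exp(-p$c1 * (x - p$c2)))),
         stack_sigmoid = p$b0 + p$b1 * x + p$b2 / (1 + exp(-p$b3 * (x - p$b4))),
         stop("unknown model: ", model))
}

#' Fitting control parameters
#'
#' @param min_n minimum number of data points accepted by [fit_model()]
#'   (the default 8 keeps leave-one-out estimates stable; relax for
#'   pedagogical micro-examples).
#' @param maxiter,ftol,ptol passed to [minpack.lm::nls.lm()].
#' @param n_alpha number of hard-threshold candidates profiled when
#'   fitting the `spiking_sigmoid` model.
#' @return list of class `fit_control`.
#' @export
fit_control <- function(min_n = 8, maxiter = 200, ftol = 1e-12, ptol = 1e-12,
                        n_alpha = 8) {
  structure(list(min_n = min_n, maxiter = maxiter, ftol = ftol, ptol = ptol,
                 n_alpha = n_alpha), class = "fit_control")
}

# Polynomial least squares via lm.fit (exact minimizer, no iteration).
fit_poly <- function(x, y, degree) {
  X <- stats::poly(x, degree = degree, raw = TRUE)
  X <- cbind(1, X)
  cf <- stats::lm.fit(X, y)$coefficients
  cf[is.na(cf)] <- 0
  stats::setNames(as.numeric(cf), paste0("b", 0:degree))
}

# Exact ReLU fit: with a1 > 0 the active set {x : a0 + a1 x > 0} is an
# upper tail of the sorted inputs, so enumerating suffixes and solving
# each quadratic subproblem in closed form finds the global MSE minimum
# deterministically.
fit_relu_exact <- function(x, y) {
  n <- length(x)
  ord <- order(x)
  xs <- x[ord]; ys <- y[ord]
  best <- NULL; best_rss <- Inf
  consider <- function(a0, a1) {
    r <- y - pmax(0, a0 + a1 * x)
    rss <- sum(r^2)
    if (rss < best_rss - 1e-15 ||
        (abs(rss - best_rss) <= 1e-15 && !is.null(best) &&
         (a0 < best[1] || (a0 == best[1] && a1 < best[2])))) {
      best_rss <<- rss; best <<- c(a0 = unname(a0), a1 = unname(a1))
    }
  }
  for (k in 1:(n - 1)) {           # active suffix xs[k..n], need >= 2 points
    if (n - k + 1 < 2) break
    xi <- xs[k:n]; yi <- ys[k:n]
    if (length(unique(xi)) < 2) next
    cf <- stats::lm.fit(cbind(1, xi), yi)$coefficients
    if (!all(is.finite(cf)) || cf[2] <= 0) next
    consider(cf[1], cf[2])
  }
  # degenerate fallbacks: everything rectified to zero, or no rectification
  cf <- stats::lm.fit(cbind(1, x), y)$coefficients
  if (all(is.finite(cf)) && cf[2] > 0) consider(cf[1], cf[2])
  consider(-1, 1e-6)               # ~zero everywhere for x < 1e6
  list(params = best, rss = best_rss, converged = TRUE)
}

# TRUE when a precedes b in lexicographic order.
lex_less <- function(a, b) {
  d <- which(a != b)
  length(d) > 0 && a[d[1]] < b[d[1]]
}

# Levenberg-Marquardt with a deterministic multi-start protocol:
# moment-based start plus a fixed 3x3 perturbation grid; best final MSE
# wins, ties broken by lexicographic parameter order.  Positivity of
# slope parameters is enforced by log-parameterization.
lm_multistart <- function(residual_fn, starts, control, lower = NULL,
                          upper = NULL) {
  npar <- length(starts[[1]])
  if (is.null(lower)) lower <- rep(-Inf, npar)
  if (is.null(upper)) upper <- rep(Inf, npar)
  best <- NULL; best_rss <- Inf; any_ok <- FALSE
  for (s in starts) {
    s <- pmin(pmax(s, lower), upper)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = s, fn = residual_fn,
                         lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = control$maxiter, ftol = control$ftol,
                           ptol = control$ptol)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (!is.finite(rss)) next
    any_ok <- TRUE
    par <- unlist(fit$par)
    if (rss < best_rss - 1e-12 ||
        (abs(rss - best_rss) <= 1e-12 && !is.null(best) && lex_less(par, best))) {
      best_rss <- rss; best <- par
    }
  }
  list(params = best, rss = best_rss, converged = any_ok)
}

fit_spiking_sigmoid <- function(x, y, control) {
  n <- length(x)
  # profile the hard threshold over a fixed candidate grid, fitting the
  # logistic parameters for each candidate
  qs <- stats::quantile(x, probs = seq(0.05, 0.6, length.out = control$n_alpha - 1),
                        names = FALSE, type = 7)
  alphas <- c(-Inf, qs)
  c2_span <- max(stats::sd(x), .Machine$double.eps)
  best <- NULL; best_rss <- Inf; best_alpha <- -Inf
  for (alpha in alphas) {
    resid_fn <- function(p) {
      c0 <- p[1]; c1 <- exp(p[2]); c2 <- p[3]
      y - ifelse(x < alpha, 0, c0 / (1 + exp(-c1 * (x - c2))))
    }
    base <- c(max(y), log(4 / (diff(range(x)) + .Machine$double.eps)),
              stats::median(x))
    starts <- list(base)
    for (f in c(-1, 0, 1)) for (g in c(-1, 0, 1)) {
      if (f == 0 && g == 0) next
      starts[[length(starts) + 1]] <- base + c(0, f * log(3), g * 0.5 * c2_span)
    }
    c1_max <- 10 / (stats::sd(x) + .Machine$double.eps)
    res <- lm_multistart(resid_fn, starts, control,
                         lower = c(0, log(1e-4), -Inf),
                         upper = c(Inf, log(c1_max), Inf))
    if (res$converged && res$rss < best_rss) {
      best_rss <- res$rss; best <- res$params; best_alpha <- alpha
    }
  }
  if (is.null(best)) return(list(params = NULL, rss = Inf, converged = FALSE))
  list(params = c(c0 = unname(best[1]), c1 = unname(exp(best[2])),
                  c2 = unname(best[3]), alpha = best_alpha),
       rss = best_rss, converged = TRUE)
}

fit_stack_sigmoid <- function(x, y, control) {
  lin <- fit_poly(x, y, 1)
  amp <- diff(range(y)); if (amp == 0) amp <- 1
  b4_grid <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  b3_base <- 2 / (stats::sd(x) + .Machine$double.eps)
  base <- c(lin[["b0"]], lin[["b1"]], amp, log(b3_base), b4_grid[2])
  starts <- list(base)
  for (f in c(-1, 0, 1)) for (g in 1:3) {
    if (f == 0 && g == 2) next
    starts[[length(starts) + 1]] <-
      c(lin[["b0"]], lin[["b1"]], amp, log(b3_base) + f * log(3), b4_grid[g])
  }
  resid_fn <- function(p)
    y - (p[1] + p[2] * x + p[3] / (1 + exp(-exp(p[4]) * (x - p[5]))))
  # the sigmoid transition (width ~ 4/b3) may not be sharper than a
  # fraction of the data spread: steeper fits are step functions that
  # chase single noisy points rather than a saturating response
  b3_max <- 10 / (stats::sd(x) + .Machine$double.eps)
  res <- lm_multistart(resid_fn, starts, control,
                       lower = c(-Inf, -Inf, -Inf, log(1e-4), min(x)),
                       upper = c(Inf, Inf, Inf, log(b3_max), max(x)))
  if (!res$converged) return(list(params = NULL, rss = Inf, converged = FALSE))
  p <- res$params
  list(params = c(b0 = unname(p[1]), b1 = unname(p[2]), b2 = unname(p[3]),
                  b3 = unname(exp(p[4])), b4 = unname(p[5])),
       rss = res$rss, converged = TRUE)
}

#' Fit a candidate nonlinearity model to scatter data
#'
#' Parameters are jointly fit by minimizing the mean squared error.
#' Linear and quadratic models are solved in closed form; the rectified
#' linear model by exact enumeration of the rectification breakpoint; the
#' sigmoid families by Levenberg-Marquardt with a deterministic
#' multi-start protocol (moment-based start plus a fixed 3x3 perturbation
#' grid, ties broken lexicographically), so repeated fits of the same data
#' are bit-identical.
#'
#' @param x,y equal-length numeric vectors (e.g. trial-averaged median
#'   membrane potential and spike count, or V_add and V_stack).
#' @param model one of `"linear"`, `"quadratic"`, `"relu"`,
#'   `"spiking_sigmoid"`, `"stack_sigmoid"`.
#' @param control a [fit_control()].
#' @return an object of class `icx_fit`: list with `model`, `params`,
#'   `rss`, `n`, `p` (parameter count), `converged`.
#' @export
fit_model <- function(x, y, model = c("linear", "quadratic", "relu",
                                      "spiking_sigmoid", "stack_sigmoid"),
                      control = fit_control()) {
  model <- match.arg(model)
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y),
            all(is.finite(x)), all(is.finite(y)))
  if (length(x) < control$min_n)
    stop("need at least ", control$min_n, " data points (got ", length(x),
         "); relax via fit_control(min_n=)")
  res <- switch(model,
    linear = {
      par <- fit_poly(x, y, 1)
      list(params = par, rss = sum((y - predict_fit("linear", par, x))^2),
           converged = TRUE)
    },
    quadratic = {
      par <- fit_poly(x, y, 2)
      list(params = par, rss = sum((y - predict_fit("quadratic", par, x))^2),
           converged = TRUE)
    },
    relu = fit_relu_exact(x, y),
    spiking_sigmoid = fit_spiking_sigmoid(x, y, control),
    stack_sigmoid = fit_stack_sigmoid(x, y, control))
  structure(list(model = model, params = res$params, rss = res$rss,
                 n = length(x), p = fit_param_count[[model]],
                 converged = res$converged),
            class = "icx_fit")
}

#' @export
print.icx_fit <- function(x, ...) {
  cat("Model:", x$model, if (!x$converged) "(NOT converged)", "\n")
  if (!is.null(x$params)) print(round(x$params, 6))
  cat("RSS:", format(x$rss), " n:", x$n, " params:", x$p, "\n")
  invisible(x)
}

#' Adjusted R-squared
#'
#' \deqn{R^2_{adj} = 1 - \frac{RSS/(n - p - 1)}{TSS/(n - 1)}}
#' penalizing models with more parameters.
#'
#' @param rss residual sum of squares (>= 0).
#' @param tss total sum of squares (> 0).
#' @param n number of data points.
#' @param p number of model parameters; requires `n > p + 1`.
#' @return adjusted R-squared (<= 1).
#' @export
adjusted_r2 <- function(rss, tss, n, p) {
  stopifnot(rss >= 0, tss > 0)
  if (n <= p + 1)
    stop("adjusted R-squared undefined: need n > p + 1 (n = ", n,
         ", p = ", p, ")")
  1 - (rss / (n - p - 1)) / (tss / (n - 1))
}

#' Leave-one-out cross-validation MSE
#'
#' Refits the model on all but one point and scores the squared
#' prediction error at the held-out point; the LOOCV MSE is the average
#' over all n points.  Every refit uses the same deterministic
#' initialization protocol as [fit_model()].
#'
#' @inheritParams fit_model
#' @return average held-out squared prediction error; carries attribute
#'   `failed` (count of non-converged refits) when any refit fails.
#' @export
loocv_mse <- function(x, y, model, control = fit_control()) {
  n <- length(x)
  if (n < control$min_n)
    stop("need at least ", control$min_n, " data points for LOOCV")
  sub_control <- control
  sub_control$min_n <- max(2, control$min_n - 1)
  errs <- numeric(n); failed <- 0L
  for (i in seq_len(n)) {
    fit <- fit_model(x[-i], y[-i], model, control = sub_control)
    if (!fit$converged || is.null(fit$params)) {
      failed <- failed + 1L; errs[i] <- NA_real_; next
    }
    errs[i] <- (y[i] - predict_fit(model, fit$params, x[i]))^2
  }
  out <- mean(errs, na.rm = failed > 0)
  if (failed > 0) attr(out, "failed") <- failed
  out
}

#' Flag sparse-response data unsuited to nonlinearity fitting
#'
#' Operational analogue of excluding neurons whose fits are not
#' significant: data are flagged when fewer than `min_bins` distinct input
#' bins carry a nonzero response, or (checked in [compare_models()]) when
#' the best candidate's adjusted R-squared falls below `r2_floor`.
#'
#' @param x,y scatter data.
#' @param min_bins minimum distinct x values with nonzero y.
#' @return logical.
#' @export
sparse_response <- function(x, y, min_bins = 8) {
  length(unique(x[y != 0])) < min_bins
}

#' Fit and compare candidate models on one data set
#'
#' Fits each candidate, computes adjusted R-squared and LOOCV MSE, and
#' names a winner only when one candidate has both the strictly largest
#' adjusted R-squared and the strictly smallest LOOCV MSE; otherwise the
#' comparison is `"inconclusive"`.
#'
#' @inheritParams fit_model
#' @param models character vector of candidate model names (>= 2).
#' @param r2_floor exclusion threshold on the best adjusted R-squared
#'   (see [sparse_response()]); `NA` result fields flag excluded data.
#' @return an object of class `model_comparison`: list with `fits`
#'   (per-candidate `icx_fit` augmented with `adjusted_r2`, `loocv_mse`),
#'   `winner`, `excluded`.
#' @export
compare_models <- function(x, y, models = c("linear", "quadratic", "stack_sigmoid"),
                           control = fit_control(), r2_floor = 0.2) {
  stopifnot(length(models) >= 2)
  tss <- sum((y - mean(y))^2)
  fits <- lapply(models, function(m) {
    f <- fit_model(x, y, m, control = control)
    f$adjusted_r2 <- if (f$converged) adjusted_r2(f$rss, tss, f$n, f$p) else -Inf
    f$loocv_mse <- if (f$converged) as.numeric(loocv_mse(x, y, m, control = control))
                   else Inf
    f
  })
  names(fits) <- models
  winner <- select_model(fits)$winner
  excluded <- sparse_response(x, y) ||
    max(vapply(fits, `[[`, numeric(1), "adjusted_r2")) < r2_floor
  structure(list(fits = fits, winner = winner, excluded = excluded),
            class = "model_comparison")
}

#' Select the winning model from a set of fits
#'
#' @param fits named list of `icx_fit` objects carrying `adjusted_r2` and
#'   `loocv_mse` fields (>= 2 candidates).
#' @return a `model_comparison` (without data-dependent exclusion flags);
#'   `winner` is a candidate name or `"inconclusive"`.
#' @export
select_model <- function(fits) {
  stopifnot(length(fits) >= 2)
  r2 <- vapply(fits, `[[`, numeric(1), "adjusted_r2")
  cv <- vapply(fits, `[[`, numeric(1), "loocv_mse")
  winner <- "inconclusive"
  for (i in seq_along(fits)) {
    if (all(r2[i] > r2[-i]) && all(cv[i] < cv[-i])) {
      winner <- names(fits)[i]
      break
    }
  }
  structure(list(fits = fits, winner = winner, excluded = NA),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  tab <- data.frame(
    model = names(x$fits),
    adjusted_r2 = vapply(x$fits, `[[`, numeric(1), "adjusted_r2"),
    loocv_mse = vapply(x$fits, `[[`, numeric(1), "loocv_mse"))
  print(tab, row.names = FALSE)
  cat("winner:", x$winner,
      if (isTRUE(x$excluded)) "(data flagged sparse/poorly fit)", "\n")
  invisible(x)
}

#' Write a model comparison as JSON
#'
#' @param comparison a `model_comparison`.
#' @param path output path.
#' @export
write_fits <- function(comparison, path) {
  out <- list(
    winner = comparison$winner,
    excluded = comparison$excluded,
    fits = lapply(comparison$fits, function(f)
      list(model = f$model, params = as.list(f$params), rss = f$rss,
           adjusted_r2 = f$adjusted_r2, loocv_mse = f$loocv_mse)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
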