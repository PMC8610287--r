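#' ITD tuning-width parameter of an ICcl neuron
#'
#' Neurons in the lateral shell of the central nucleus of the inferior
#' colliculus (ICcl) have approximately sinusoidal ITD tuning whose
#' half-width, as a fraction of the period of the best frequency, narrows
#' with best frequency.  The concentration parameter `b` of the
#' exponential-of-cosine tuning curve (see [itd_tuning()]) is set as the
#' smaller root of a quadratic in `b` that reproduces that relationship:
#'
#' \deqn{b = \frac{q_1 - \sqrt{q_1^2 - 4 q_0 (q_2 - q_3\,\mathrm{bf})}}{2 q_0}}
#'
#' with default coefficients `q0 = 2.8`, `q1 = 17`, `q2 = 24.12`,
#' `q3 = 2.44` and `bf` in kHz.  Near the top of the frequency range
#' (bf above about 9.9 kHz) the root becomes non-positive; it is clamped
#' at `eps` so that tuning degenerates gracefully to near-sinusoidal.
#'
#' @param bf best frequency in kHz, in \[0.5, 10\]; vectorized.
#' @param coef named numeric vector of the four quadratic coefficients
#'   `c(q0, q1, q2, q3)`.
#' @param eps lower clamp for the root (default 0.01).
#' @return concentration parameter(s) `b > 0`, non-increasing in `bf`.
#' @examples
#' concentration_param(5)   # ~0.809
#' concentration_param(1)   # ~1.822
#' concentration_param(10)  # clamped at 0.01
#' @export
concentration_param <- function(bf, coef = c(q0 = 2.8, q1 = 17, q2 = 24.12, q3 = 2.44),
                                eps = 0.01) {
  stopifnot(is.numeric(bf), all(is.finite(bf)))
  if (any(bf < 0.5 - 1e-9) || any(bf > 10 + 1e-9))
    stop("best frequency out of the modelled range [0.5, 10] kHz: ",
         paste(bf[bf < 0.5 | bf > 10], collapse = ", "))
  q <- as.numeric(coef)
  disc <- q[2]^2 - 4 * q[1] * (q[3] - q[4] * bf)
  if (any(disc < 0))
    stop("negative discriminant in the tuning-width quadratic at bf = ",
         paste(bf[disc < 0], collapse = ", "), " kHz; check coefficients")
  b <- (q[2] - sqrt(disc)) / (2 * q[1])
  pmax(b, eps)
}

#' Normalized ITD tuning of an ICcl neuron
#'
#' Exponential-of-cosine (circular, von Mises-like) ITD tuning,
#' normalized to \[0, 1\]:
#' \deqn{r(\mathrm{ITD}) = \frac{e^{b\cos(2\pi\,\mathrm{bf}\,(\mathrm{ITD}-\mathrm{ITD}_0))} - e^{-b}}
#'                              {e^{b} - e^{-b}}}
#' ITD is taken in microseconds and `bf` in kHz; internally ITD is
#' converted to ms so that `bf * itd` is in cycles.  The curve peaks at 1
#' when `itd == best_itd` and is periodic with period `1000/bf` microseconds.
#'
#' @param itd ITD in microseconds; vectorized.
#' @param bf best frequency, kHz.
#' @param b concentration parameter (> 0); defaults to
#'   [concentration_param()] of `bf`.
#' @param best_itd preferred ITD in microseconds.
#' @return normalized rate(s) in \[0, 1\].
#' @export
itd_tuning <- function(itd, bf, b = concentration_param(bf), best_itd = 0) {
  stopifnot(is.numeric(itd), all(is.finite(itd)), b > 0)
  x <- b * cos(2 * pi * bf * (itd - best_itd) / 1000)
  (exp(x) - exp(-b)) / (exp(b) - exp(-b))
}

#' Construct a single ICcl neuron
#'
#' @param bf best frequency, kHz, in \[0.5, 10\].
#' @param best_itd preferred ITD, microseconds, in \[-250, 250\].
#' @param b tuning-width concentration parameter; default from
#'   [concentration_param()].
#' @return an object of class `iccl_neuron` (a named list).
#' @export
iccl_neuron <- function(bf, best_itd = 0, b = concentration_param(bf)) {
  stopifnot(length(bf) == 1, length(best_itd) == 1, length(b) == 1)
  if (bf < 0.5 || bf > 10) stop("bf must lie in [0.5, 10] kHz")
  if (best_itd < -250 || best_itd > 250) stop("best_itd must lie in [-250, 250] us")
  if (!is.finite(b) || b <= 0) stop("b must be positive")
  structure(list(bf = bf, best_itd = best_itd, b = b), class = "iccl_neuron")
}

#' Build a grid population of ICcl input neurons
#'
#' Lays neurons on a regular (bf x best ITD) grid, bf-major (best ITD
#' varies fastest within a best-frequency block).  Each neuron's tuning
#' width is set from its best frequency by [concentration_param()].
#' The default is the configuration used for two-layer simulations: best
#' frequencies 0.5 to 10 kHz in 0.1-kHz steps and a single best-ITD
#' column at 0 microseconds (all inputs tuned to the same ITD).
#'
#' @param bf_range length-2 numeric, kHz, within \[0.5, 10\].
#' @param itd_range length-2 numeric, microseconds, within \[-250, 250\].
#' @param bf_step,itd_step grid steps (kHz, microseconds); must be > 0.
#' @param coef,eps passed to [concentration_param()].
#' @return an `iccl_population`: a list with a data frame `neurons`
#'   (columns `bf`, `best_itd`, `b`) plus the grid parameters.
#' @examples
#' pop <- iccl_population()
#' nrow(pop$neurons)  # 96 best frequencies x 1 ITD column
#' @export
iccl_population <- function(bf_range = c(0.5, 10), itd_range = c(0, 0),
                            bf_step = 0.1, itd_step = 10,
                            coef = c(q0 = 2.8, q1 = 17, q2 = 24.12, q3 = 2.44),
                            eps = 0.01) {
  stopifnot(length(bf_range) == 2, length(itd_range) == 2,
            bf_step > 0, itd_step > 0)
  if (bf_range[1] < 0.5 - 1e-9 || bf_range[2] > 10 + 1e-9)
    stop("bf_range must lie within [0.5, 10] kHz")
  if (itd_range[1] < -250 || itd_range[2] > 250)
    stop("itd_range must lie within [-250, 250] us")
  bfs <- seq(bf_range[1], bf_range[2], by = bf_step)
  itds <- seq(itd_range[1], itd_range[2], by = itd_step)
  if (!length(bfs) || !length(itds)) stop("empty ICcl grid")
  grid <- expand.grid(best_itd = itds, bf = bfs)[, c("bf", "best_itd")]
  grid$b <- concentration_param(grid$bf, coef = coef, eps = eps)
  structure(list(neurons = grid, bf_step = bf_step, itd_step = itd_step,
                 bf_range = bf_range, itd_range = itd_range, coef = coef),
            class = "iccl_population")
}

#' @export
print.iccl_population <- function(x, ...) {
  cat("ICcl population:", nrow(x$neurons), "neurons;",
      "bf", x$bf_range[1], "-", x$bf_range[2], "kHz (step", x$bf_step, "),",
      "best ITD", x$itd_range[1], "-", x$itd_range[2], "us\n")
  invisible(x)
}

#' @export
as.data.frame.iccl_population <- function(x, ...) {
  data.frame(index = seq_len(nrow(x$neurons)),
             bf_khz = x$neurons$bf,
             best_itd_us = x$neurons$best_itd,
             b = x$neurons$b)
}

#' Population rate matrix over an ITD grid (broadband stimulation)
#'
#' Evaluates every neuron's normalized ITD tuning at every stimulus ITD.
#'
#' @param pop an [iccl_population()].
#' @param itd_grid stimulus ITDs, microseconds.
#' @return matrix, `length(itd_grid)` rows x neurons columns, values in \[0, 1\].
#' @export
iccl_rates <- function(pop, itd_grid) {
  stopifnot(inherits(pop, "iccl_population"))
  nn <- pop$neurons
  vapply(seq_len(nrow(nn)), function(i)
    itd_tuning(itd_grid, nn$bf[i], nn$b[i], nn$best_itd[i]),
    numeric(length(itd_grid)))
}

#' Response of an ICcl neuron to a pure tone
#'
#' Tone responses multiply the broadband ITD tuning by a Gaussian
#' frequency-tuning factor centred on the neuron's best frequency, and by
#' a level scale.  ICcl ITD tuning is similar for tones and noise, so the
#' ITD factor is shared with [itd_tuning()].
#'
#' @param neuron an [iccl_neuron()], or an [iccl_population()] (then all
#'   neurons are evaluated and a vector is returned).
#' @param tone_freq tone frequency, kHz.
#' @param itd stimulus ITD, microseconds.
#' @param level_scale stimulus level in \[0, 1\].
#' @param freq_tuning_width Gaussian frequency-tuning width, kHz (> 0).
#' @return normalized rate(s).
#' @export
tone_response <- function(neuron, tone_freq, itd, level_scale = 1,
                          freq_tuning_width = 0.5) {
  stopifnot(freq_tuning_width > 0, level_scale >= 0, level_scale <= 1)
  if (inherits(neuron, "iccl_population")) {
    nn <- neuron$neurons
    ftf <- exp(-0.5 * ((tone_freq - nn$bf) / freq_tuning_width)^2)
    itf <- vapply(seq_len(nrow(nn)), function(i)
      itd_tuning(itd, nn$bf[i], nn$b[i], nn$best_itd[i]), numeric(1))
    return(level_scale * ftf * itf)
  }
  stopifnot(inherits(neuron, "iccl_neuron"))
  level_scale * exp(-0.5 * ((tone_freq - neuron$bf) / freq_tuning_width)^2) *
    itd_tuning(itd, neuron$bf, neuron$b, neuron$best_itd)
}

#' Read an ICcl population specification from a config file
#'
#' Accepts YAML or JSON with any of the fields `bf_range`, `itd_range`,
#' `bf_step`, `itd_step`, `coef`, `eps`; missing fields take the
#' [iccl_population()] defaults.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file, or a list with
#'   the same fields.
#' @return an `iccl_population`.
#' @export
iccl_population_from_config <- function(path) {
  cfg <- read_config(path)
  args <- cfg[intersect(names(cfg),
                        c("bf_range", "itd_range", "bf_step", "itd_step",
                          "coef", "eps"))]
  args <- lapply(args, unlist)
  do.call(iccl_population, args)
}

# Shared structured-config reader (YAML or JSON by extension; lists pass
# through unchanged).
read_config <- function(path) {
  if (is.list(path)) return(path)
  stopifnot(is.character(path), length(path) == 1, file.exists(path))
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else
    yaml::read_yaml(path)
}
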