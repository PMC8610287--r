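#' Sampled ITD tuning curve
#'
#' A light container pairing strictly increasing ITDs (microseconds) with
#' finite response values (mV or arbitrary units).
#'
#' @param itds ITD sample points, microseconds, strictly increasing,
#'   length >= 5.
#' @param values responses at those ITDs.
#' @param meta optional source label.
#' @return an object of class `itd_curve`.
#' @export
itd_curve <- function(itds, values, meta = "") {
  stopifnot(is.numeric(itds), is.numeric(values),
            length(itds) == length(values), length(itds) >= 5,
            all(is.finite(itds)), all(is.finite(values)),
            all(diff(itds) > 0))
  structure(list(itds = as.numeric(itds), values = as.numeric(values),
                 meta = meta), class = "itd_curve")
}

#' @export
print.itd_curve <- function(x, ...) {
  cat("ITD tuning curve", if (nzchar(x$meta)) paste0("(", x$meta, ")"),
      ":", length(x$itds), "points,",
      sprintf("ITD %g..%g us, values %.4g..%.4g\n",
              min(x$itds), max(x$itds), min(x$values), max(x$values)))
  invisible(x)
}

#' @export
as.data.frame.itd_curve <- function(x, ...) {
  data.frame(itd_us = x$itds, value = x$values)
}

#' Read/write ITD tuning curves as CSV (columns `itd_us`, `value`)
#' @param path CSV file path.
#' @return an `itd_curve`.
#' @export
read_itd_curve <- function(path) {
  d <- utils::read.csv(path)
  itd_curve(d$itd_us, d$value, meta = basename(path))
}

#' @rdname read_itd_curve
#' @param curve an `itd_curve`.
#' @export
write_itd_curve <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' Experimental population statistics for ICx subthreshold ITD tuning
#'
#' Mean and standard deviation of side-peak suppression (percent) and
#' half-width (microseconds) of in vivo intracellular ITD tuning curves,
#' used to z-score model output.  Defaults are the published values for
#' the barn-owl ICx population (SPS 23.18 +/- 12.27 %, HW 75.17 +/- 17.12 us).
#'
#' @param sps_mean,sps_sd SPS mean and SD, percent.
#' @param hw_mean,hw_sd HW mean and SD, microseconds.
#' @return an object of class `population_stats`.
#' @export
icx_population_stats <- function(sps_mean = 23.18, sps_sd = 12.27,
                                 hw_mean = 75.17, hw_sd = 17.12) {
  stopifnot(sps_sd > 0, hw_sd > 0)
  structure(list(sps_mean = sps_mean, sps_sd = sps_sd,
                 hw_mean = hw_mean, hw_sd = hw_sd),
            class = "population_stats")
}

# Index of the main peak: global maximum, ties broken by smallest |ITD|.
main_peak_index <- function(itds, values) {
  ipk <- which(values == max(values))
  ipk[which.min(abs(itds[ipk]))]
}

# Local maxima on the sampled grid: strictly greater than both
# neighbours, after optional 3-point moving-average smoothing.
local_maxima <- function(values, smooth = FALSE) {
  if (smooth && length(values) >= 3) {
    v <- values
    values <- c(v[1], (v[-c(1, 2)] + v[-c(1, length(v))] + v[-c(length(v) - 1, length(v))]) / 3,
                v[length(v)])
  }
  n <- length(values)
  which(values[2:(n - 1)] > values[1:(n - 2)] &
        values[2:(n - 1)] > values[3:n]) + 1L
}

#' Half-width of the main ITD-tuning peak
#'
#' Width of the main peak at half height, where height is measured from
#' the curve minimum to the maximum and the half-level crossings on either
#' flank are located by linear interpolation between grid samples.  The
#' main peak is the global maximum; ties are broken toward 0 microseconds.
#' The result is invariant to positive affine transforms of the response.
#'
#' @param curve an [itd_curve()].
#' @return half-width in microseconds (> 0).
#' @export
half_width <- function(curve) {
  stopifnot(inherits(curve, "itd_curve"))
  itds <- curve$itds; v <- curve$values
  half <- (max(v) + min(v)) / 2
  ipk <- main_peak_index(itds, v)
  li <- ipk
  while (li > 1 && v[li - 1] > half) li <- li - 1
  if (li == 1 && v[1] > half)
    stop("half level never crossed on the left side of the main peak")
  ri <- ipk
  while (ri < length(v) && v[ri + 1] > half) ri <- ri + 1
  if (ri == length(v) && v[ri] > half)
    stop("half level never crossed on the right side of the main peak")
  # v[li] > half >= v[li-1]; interpolate within the bracketing intervals
  xl <- if (li == 1) itds[1] else
    itds[li - 1] + (half - v[li - 1]) / (v[li] - v[li - 1]) * (itds[li] - itds[li - 1])
  xr <- if (ri == length(v)) itds[ri] else
    itds[ri] + (half - v[ri]) / (v[ri + 1] - v[ri]) * (itds[ri + 1] - itds[ri])
  xr - xl
}

#' Side-peak suppression of an ITD tuning curve
#'
#' Percentage by which the largest secondary local maximum falls below the
#' main peak.  The default (`method = "range"`) normalizes by the full
#' response range,
#' \deqn{\mathrm{SPS} = 100\,\frac{R_{main} - R_{side}}{R_{main} - R_{min}},}
#' so a periodic curve with equal peaks scores 0 and a side peak at
#' baseline scores 100.  `method = "peak"` normalizes by the main-peak
#' value instead (an alternate convention in the literature).  When the
#' sampled window contains no secondary local maximum the result is `NA`
#' with attribute `reason`.
#'
#' @param curve an [itd_curve()].
#' @param method `"range"` (default) or `"peak"`.
#' @param smooth logical; apply 3-point smoothing before locating local
#'   maxima (off by default).
#' @return SPS in percent (0-100), or `NA` when undefined.
#' @export
side_peak_suppression <- function(curve, method = c("range", "peak"),
                                  smooth = FALSE) {
  stopifnot(inherits(curve, "itd_curve"))
  method <- match.arg(method)
  itds <- curve$itds; v <- curve$values
  ipk <- main_peak_index(itds, v)
  peaks <- local_maxima(v, smooth = smooth)
  side <- setdiff(peaks, ipk)
  # a tied global max elsewhere still counts as a (fully unsuppressed) side peak
  ties <- setdiff(which(v == max(v)), ipk)
  side <- union(side, intersect(ties, peaks))
  if (!length(side)) {
    out <- NA_real_
    attr(out, "reason") <- "no secondary local maximum in the ITD window"
    return(out)
  }
  r_main <- v[ipk]; r_side <- max(v[side]); r_min <- min(v)
  denom <- if (method == "range") r_main - r_min else r_main
  if (denom <= 0) {
    out <- NA_real_
    attr(out, "reason") <- "degenerate (flat or non-positive) curve"
    return(out)
  }
  100 * (r_main - r_side) / denom
}

#' Z-score of a tuning metric against the experimental population
#'
#' @param x metric value (SPS in percent or HW in microseconds).
#' @param stats an [icx_population_stats()].
#' @param which `"sps"` or `"hw"`.
#' @return dimensionless z-score `(x - mean)/sd`.
#' @export
zscore <- function(x, stats = icx_population_stats(), which = c("sps", "hw")) {
  stopifnot(inherits(stats, "population_stats"))
  which <- match.arg(which)
  if (which == "sps") (x - stats$sps_mean) / stats$sps_sd
  else (x - stats$hw_mean) / stats$hw_sd
}

#' Tuning metrics of a curve as a JSON-ready record
#'
#' Convenience wrapper computing HW, SPS and their z-scores.
#'
#' @param curve an [itd_curve()].
#' @param stats an [icx_population_stats()].
#' @param sps_method passed to [side_peak_suppression()].
#' @return a list `{hw_us, sps_pct, sps_missing, z_hw, z_sps}`.
#' @export
tuning_metrics <- function(curve, stats = icx_population_stats(),
                           sps_method = "range") {
  hw <- half_width(curve)
  sps <- side_peak_suppression(curve, method = sps_method)
  list(hw_us = hw,
       sps_pct = as.numeric(sps),
       sps_missing = is.na(sps),
       z_hw = zscore(hw, stats, "hw"),
       z_sps = if (is.na(sps)) NA_real_ else zscore(as.numeric(sps), stats, "sps"))
}
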