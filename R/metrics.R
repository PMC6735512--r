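#' Spectral configuration for the signal-to-clutter ratio
#'
#' @param f_c cut-off (Hz) separating the perfusion signal band from the
#'   motion/noise clutter band; must lie below the Nyquist rate `f_s / 2`.
#' @param f_s TIC sampling frequency, Hz.
#' @param psd_method `"periodogram"` (raw) or `"averaged"` (8-segment
#'   Bartlett average).
#' @return list of class `spectral_config`.
#' @export
spectral_config <- function(f_c = 0.15, f_s,
                            psd_method = c("periodogram", "averaged")) {
  psd_method <- match.arg(psd_method)
  if (!(f_c > 0 && f_c < f_s / 2))
    stop("need 0 < f_c < f_s/2")
  structure(list(f_c = f_c, f_s = f_s, psd_method = psd_method),
            class = "spectral_config")
}

#' Signal-to-clutter ratio of a TIC
#'
#' `10 log10` of the ratio of integrated power spectral density below the
#' cut-off (DC excluded) to that between the cut-off and Nyquist. Gated
#' TICs, whose timestamps are nonuniform, are evaluated at their mean
#' sampling rate. Capped at +/- 120 dB when one band is numerically zero.
#'
#' @param x a [tic()] with at least 16 samples.
#' @param cfg a [spectral_config()]; when omitted, the default cut-off with
#'   `f_s` taken from the TIC's mean sampling rate.
#' @return SCR in dB.
#' @export
scr <- function(x, cfg = NULL) {
  stopifnot(inherits(x, "tic"))
  y <- x$intensity
  if (length(y) < 16L) stop("need at least 16 samples")
  if (all(y == 0)) stop("all-zero TIC")
  fs <- 1 / mean(diff(x$timestamps))
  if (is.null(cfg)) cfg <- spectral_config(f_s = fs)
  ps <- if (cfg$psd_method == "averaged") averaged_periodogram(y, fs)
        else raw_periodogram(y, fs)
  sig <- ps$freq > 0 & ps$freq <= cfg$f_c
  clu <- ps$freq > cfg$f_c & ps$freq <= fs / 2
  num <- sum(ps$power[sig]); den <- sum(ps$power[clu])
  if (den <= 0 && num <= 0) stop("all-zero spectrum")
  if (den <= 0) return(120)
  if (num <= 0) return(-120)
  max(min(10 * log10(num / den), 120), -120)
}

#' Mean square error between two TICs
#'
#' The curves are linearly resampled onto their overlapping time span at
#' the coarser of the two sampling rates, then the mean squared difference
#' is taken. Symmetric in its arguments.
#'
#' @param a,b [tic()] objects with overlapping time spans.
#' @return the MSE (squared intensity units).
#' @export
tic_mse <- function(a, b) {
  stopifnot(inherits(a, "tic"), inherits(b, "tic"))
  lo <- max(min(a$timestamps), min(b$timestamps))
  hi <- min(max(a$timestamps), max(b$timestamps))
  if (hi <= lo) stop("no temporal overlap")
  dt <- max(mean(diff(a$timestamps)), mean(diff(b$timestamps)))
  grid <- seq(lo, hi, by = dt)
  ya <- stats::approx(a$timestamps, a$intensity, grid)$y
  yb <- stats::approx(b$timestamps, b$intensity, grid)$y
  mean((ya - yb)^2)
}

#' Probability density of a parameter map's values
#'
#' Histogram of the valid cells over the given bin edges, normalized to
#' sum to one.
#'
#' @param values numeric matrix (or vector) of map values.
#' @param mask logical validity mask (same shape); `NULL` = all valid.
#' @param bins bin count used when `edges` is `NULL` (default 256, matching
#'   the encoding levels).
#' @param edges optional shared bin edges (length `bins + 1`).
#' @return list `bins`, `edges`, `density` (sums to 1).
#' @export
value_density <- function(values, mask = NULL, bins = 256L, edges = NULL) {
  v <- if (is.null(mask)) as.numeric(values) else values[mask]
  if (length(v) == 0L) stop("empty mask: no valid cells")
  if (is.null(edges)) {
    rng <- range(v)
    if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
    edges <- seq(rng[1], rng[2], length.out = bins + 1L)
  }
  idx <- findInterval(v, edges, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  list(bins = length(counts), edges = edges,
       density = counts / sum(counts))
}

# shared-edge density pair over the union range of two maps
density_pair <- function(a, b, bins = 256L) {
  va <- a$values[a$mask]; vb <- b$values[b$mask]
  if (length(va) == 0L || length(vb) == 0L) stop("empty mask")
  rng <- if (!is.null(a$dynamic_range) && !is.null(b$dynamic_range) &&
             isTRUE(all(a$dynamic_range == b$dynamic_range)))
    a$dynamic_range else range(c(va, vb))
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  edges <- seq(rng[1], rng[2], length.out = bins + 1L)
  list(p_a = value_density(a$values, a$mask, edges = edges)$density,
       p_b = value_density(b$values, b$mask, edges = edges)$density,
       edges = edges)
}

check_same_parameter <- function(a, b) {
  stopifnot(inherits(a, "fpi_map"), inherits(b, "fpi_map"))
  if (!identical(a$parameter, b$parameter))
    stop("maps mix parameters: ", a$parameter, " vs ", b$parameter)
}

#' Density mean square error between two parameter maps
#'
#' Mean over bins of the squared difference of the two value-probability
#' densities, scaled by 1e6 (densities are small; the scale is fixed and
#' documented). Maps should share a normalization range (see
#' [normalize_shared_range()]); otherwise the union value range is used.
#'
#' @param a,b `fpi_map`s of the same parameter.
#' @param bins histogram bins, default 256.
#' @return scaled density MSE.
#' @export
fpi_mse <- function(a, b, bins = 256L) {
  check_same_parameter(a, b)
  dp <- density_pair(a, b, bins)
  mean((dp$p_a - dp$p_b)^2) * 1e6
}

#' Correlation between two parameter maps' value densities
#'
#' Pearson correlation of the two densities over shared bins; for lists of
#' map pairs the mean over pairs is returned.
#'
#' @param a,b `fpi_map`s of one parameter, or equal-length lists of maps
#'   (pairwise; the mean R is returned).
#' @param bins histogram bins, default 256.
#' @return correlation in `[-1, 1]`.
#' @export
fpi_correlation <- function(a, b, bins = 256L) {
  if (is.list(a) && !inherits(a, "fpi_map")) {
    stopifnot(length(a) == length(b))
    return(mean(mapply(fpi_correlation, a, b,
                       MoreArgs = list(bins = bins))))
  }
  check_same_parameter(a, b)
  dp <- density_pair(a, b, bins)
  if (stats::sd(dp$p_a) == 0 || stats::sd(dp$p_b) == 0)
    stop("zero-variance density")
  stats::cor(dp$p_a, dp$p_b)
}

#' Mean noise coefficient of a colour-coded map
#'
#' For each RGB channel the noise coefficient is `100 * sd / mean` over the
#' valid cells (population standard deviation); the MNC is the mean of the
#' three channel coefficients. A proxy for visible map noise.
#'
#' @param map an `fpi_map` with `rgb` filled.
#' @return MNC in percent.
#' @export
mnc <- function(map) {
  stopifnot(inherits(map, "fpi_map"))
  if (is.null(map$rgb)) stop("encode the map first (rgb missing)")
  if (!any(map$mask)) stop("empty mask: no valid cells")
  cv <- vapply(1:3, function(ch) {
    v <- map$rgb[, , ch][map$mask]
    m <- mean(v)
    s <- sqrt(mean((v - m)^2))
    if (s == 0) return(0)            # constant channel: no noise
    if (m <= 0) stop("channel ", ch, " has zero mean over valid cells")
    100 * s / m
  }, numeric(1))
  mean(cv)
}
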