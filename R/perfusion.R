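#' Estimate the six hemodynamic parameters of a TIC
#'
#' Threshold-crossing conventions: the baseline is the mean of samples
#' before arrival (resolved by a two-pass fixed point: start from the first
#' sample, locate arrival, recompute the baseline from the pre-arrival
#' samples, relocate arrival); `PV = max - baseline`; `t_peak` is the
#' earliest argmax; `t_arrival` is the time intensity first reaches
#' `baseline + arrival_fraction * PV`, refined to sub-sample precision by
#' linear interpolation between the bracketing samples (gated TICs sample
#' once per breathing cycle, so sample-quantized times would be coarse);
#' `WIT = t_peak - t_arrival`; `WOT` is
#' the first post-peak return below the same threshold (or the remaining
#' acquisition with `washout_complete = FALSE` when the falling phase is
#' only partly recorded); `AUC` is the trapezoidal integral of the
#' baseline-subtracted curve (clipped at zero) from arrival to washout (or
#' acquisition) end; `WIR = PV / WIT`, `WOR = PV / WOT`.
#'
#' @param x a filtered [tic()] with at least 5 samples.
#' @param arrival_fraction threshold fraction of the peak, default 0.10.
#' @return object of class `perfusion_params` with fields `WIT`, `WOT`,
#'   `PV`, `AUC`, `WIR`, `WOR`, `t_arrival`, `t_peak`, `washout_complete`,
#'   `defined`. A flat TIC (zero peak) or a degenerate wash-in/out span is
#'   flagged `defined = FALSE` with zeroed parameters rather than NaNs.
#' @export
estimate_perfusion_params <- function(x, arrival_fraction = 0.10) {
  stopifnot(inherits(x, "tic"))
  if (!x$filtered) stop("TIC must be filtered before parameter estimation")
  y <- x$intensity; t <- x$timestamps
  if (length(y) < 5L) stop("need at least 5 samples")
  undefined <- structure(list(WIT = 0, WOT = 0, PV = 0, AUC = 0, WIR = 0,
                              WOR = 0, t_arrival = 0, t_peak = 0,
                              washout_complete = FALSE, defined = FALSE),
                         class = "perfusion_params")
  baseline <- y[1]
  i_arr <- 1L
  for (pass in 1:2) {
    pv <- max(y) - baseline
    if (pv <= 0) return(undefined)
    thr <- baseline + arrival_fraction * pv
    i_arr <- which(y >= thr)[1]
    baseline <- if (i_arr > 1L) mean(y[seq_len(i_arr - 1L)]) else y[1]
  }
  pv <- max(y) - baseline
  if (pv <= 0) return(undefined)
  thr <- baseline + arrival_fraction * pv
  i_arr <- which(y >= thr)[1]
  i_peak <- which.max(y)                         # earliest on ties
  # sub-sample crossing times by linear interpolation between the
  # bracketing samples (exact when the crossing falls on a sample)
  t_arr <- if (i_arr > 1L)
    t[i_arr - 1L] + (thr - y[i_arr - 1L]) / (y[i_arr] - y[i_arr - 1L]) *
      (t[i_arr] - t[i_arr - 1L])
  else t[1L]
  t_peak <- t[i_peak]
  wit <- t_peak - t_arr
  if (wit <= 0) return(undefined)
  post <- which(seq_along(y) > i_peak & y <= thr)
  washout_complete <- length(post) > 0L
  if (washout_complete) {
    j <- post[1]
    t_out <- t[j - 1L] + (thr - y[j - 1L]) / (y[j] - y[j - 1L]) *
      (t[j] - t[j - 1L])
  } else t_out <- t[length(y)]
  wot <- t_out - t_peak
  if (wot <= 0) return(undefined)
  tt <- c(t_arr, t[t > t_arr & t < t_out], t_out)
  yy <- stats::approx(t, y, tt)$y
  auc <- pracma::trapz(tt, pmax(yy - baseline, 0))
  structure(list(WIT = wit, WOT = wot, PV = pv, AUC = auc,
                 WIR = pv / wit, WOR = pv / wot,
                 t_arrival = t_arr, t_peak = t_peak,
                 washout_complete = washout_complete, defined = TRUE),
            class = "perfusion_params")
}

perfusion_parameter_names <- c("WIT", "WOT", "PV", "AUC", "WIR", "WOR")

#' Build all six parameter maps from a TIC grid
#'
#' Runs [estimate_perfusion_params()] once per grid cell (filtering the
#' grid first if needed) and rasterizes each parameter. Cells whose TIC is
#' flat or degenerate are set to 0 and recorded in the validity mask.
#'
#' @param grid a `tic_grid`.
#' @param arrival_fraction see [estimate_perfusion_params()].
#' @param dwma_window filter window applied if the grid is unfiltered.
#' @param phase_label optional label carried into the maps.
#' @return named list of six `fpi_map` objects (fields `parameter`,
#'   `values`, `mask`, `phase_label`; normalization/RGB unset).
#' @export
build_parameter_maps <- function(grid, arrival_fraction = 0.10,
                                 dwma_window = 5L, phase_label = NA) {
  stopifnot(inherits(grid, "tic_grid"))
  if (!grid$filtered) grid <- dwma_filter(grid, dwma_window)
  d <- dim(grid$intensity)
  vals <- lapply(perfusion_parameter_names,
                 function(p) matrix(0, d[1], d[2]))
  names(vals) <- perfusion_parameter_names
  mask <- matrix(FALSE, d[1], d[2])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    pp <- estimate_perfusion_params(grid_tic(grid, i, j), arrival_fraction)
    if (pp$defined) {
      mask[i, j] <- TRUE
      for (p in perfusion_parameter_names) vals[[p]][i, j] <- pp[[p]]
    }
  }
  lapply(perfusion_parameter_names, function(p)
    structure(list(parameter = p, values = vals[[p]], mask = mask,
                   phase_label = phase_label, normalized = NULL,
                   rgb = NULL, dynamic_range = NULL),
              class = "fpi_map"))  |> stats::setNames(perfusion_parameter_names)
}

#' Build one parameter map from a TIC grid
#'
#' @inheritParams build_parameter_maps
#' @param parameter one of `"WIT"`, `"WOT"`, `"PV"`, `"AUC"`, `"WIR"`,
#'   `"WOR"`.
#' @return a single `fpi_map`.
#' @export
build_parameter_map <- function(grid, parameter, arrival_fraction = 0.10,
                                dwma_window = 5L, phase_label = NA) {
  parameter <- match.arg(parameter, perfusion_parameter_names)
  build_parameter_maps(grid, arrival_fraction, dwma_window,
                       phase_label)[[parameter]]
}

#' Restrict a condition's maps to its perfusion region
#'
#' With noisy data almost every cell yields a nominally defined TIC, so
#' map evaluation is restricted to the perfusion region: cells whose peak
#' value reaches `fraction` of the map's robust maximum (99th percentile of
#' defined-cell PV). The rule is derived from the PV map and applied to all
#' six maps of the condition jointly.
#'
#' @param maps named list of the six `fpi_map`s from
#'   [build_parameter_maps()].
#' @param fraction detection threshold as a fraction of the robust peak
#'   enhancement, default 0.2.
#' @return the list, with every map's `mask` replaced by the perfusion
#'   region.
#' @export
perfusion_region <- function(maps, fraction = 0.2) {
  pv <- maps$PV
  if (is.null(pv)) stop("maps must include the PV map")
  valid <- pv$mask & pv$values > 0
  if (!any(valid)) return(maps)
  thr <- fraction * stats::quantile(pv$values[valid], 0.99, names = FALSE)
  region <- valid & pv$values >= thr
  lapply(maps, function(m) { m$mask <- region; m })
}

#' Normalize a set of maps to a shared dynamic range
#'
#' The comparison maps of one parameter (e.g. gated, ungated, static) are
#' adjusted to the same dynamic range: `(lo, hi)` is the min/max over the
#' valid cells of the union, and each map's 256-level quantization
#' `round(255 * clip((v - lo)/(hi - lo), 0, 1))` uses it.
#'
#' @param maps a list of `fpi_map`s sharing one parameter name (a single
#'   map normalizes over its own range).
#' @param probs quantile pair defining the shared range over the pooled
#'   valid cells; the default `c(0, 1)` is the plain min/max. The pipeline
#'   uses `c(0.01, 0.99)` so a handful of corrupted outlier cells cannot
#'   compress everyone else's encoding.
#' @return the list, with `normalized` and `dynamic_range` filled.
#' @export
normalize_shared_range <- function(maps, probs = c(0, 1)) {
  if (inherits(maps, "fpi_map")) maps <- list(maps)
  pars <- unique(vapply(maps, `[[`, "", "parameter"))
  if (length(pars) != 1L)
    stop("maps mix parameters: ", paste(pars, collapse = ", "))
  vals <- unlist(lapply(maps, function(m) m$values[m$mask]))
  if (length(vals) == 0L) vals <- 0
  rng <- stats::quantile(vals, probs, names = FALSE)
  lo <- rng[1]; hi <- rng[2]
  lapply(maps, function(m) {
    z <- if (hi > lo) (m$values - lo) / (hi - lo) else m$values * 0
    m$normalized <- matrix(as.integer(round(255 * pmin(pmax(z, 0), 1))),
                           nrow(m$values), ncol(m$values))
    m$dynamic_range <- c(lo, hi)
    m
  })
}

#' The package's 256-entry colour lookup table
#'
#' A fixed blue-cyan-green-yellow-red table shipped as a CSV asset so RGB
#' encodings are bit-reproducible; every level maps to a distinct RGB
#' triple (the table is injective).
#'
#' @return 256 x 3 integer matrix, channels 0..255.
#' @export
dmfpi_lut <- function() {
  f <- system.file("extdata", "lut_jet256.csv", package = "dmfpi",
                   mustWork = TRUE)
  as.matrix(utils::read.csv(f))
}

#' Encode a normalized map as a 256-level RGB image
#'
#' `rgb[i, j, ] = lut[normalized[i, j] + 1, ]`; invalid cells are rendered
#' black. Optionally nearest-neighbour upsampled for overlay display.
#'
#' @param map an `fpi_map` with `normalized` filled (see
#'   [normalize_shared_range()]).
#' @param lut 256 x 3 table, default [dmfpi_lut()].
#' @param upsample integer pixel replication factor (display only).
#' @return the map with `rgb` filled (H x W x 3, values 0..255).
#' @export
encode_rgb <- function(map, lut = dmfpi_lut(), upsample = 1L) {
  stopifnot(inherits(map, "fpi_map"))
  if (is.null(map$normalized)) stop("normalize the map first")
  if (!all(dim(lut) == c(256L, 3L))) stop("lut must be 256 x 3")
  d <- dim(map$normalized)
  rgb <- array(0, c(d[1], d[2], 3))
  lev <- map$normalized + 1L
  for (ch in 1:3) {
    plane <- matrix(lut[lev, ch], d[1], d[2])
    plane[!map$mask] <- 0
    rgb[, , ch] <- plane
  }
  if (upsample > 1L) {
    ri <- rep(seq_len(d[1]), each = upsample)
    ci <- rep(seq_len(d[2]), each = upsample)
    rgb <- rgb[ri, ci, , drop = FALSE]
  }
  map$rgb <- rgb
  map
}
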