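#' Flatten a DCEUS sequence to its frame-by-pixel data matrix
#'
#' Row `t` of the matrix is frame `t` flattened row-major (pixel
#' `(row, col)` lands in column `(row - 1) * N + col`), so each column is
#' the raw time-intensity curve of one pixel. Per-column temporal means are
#' recorded for centering before decomposition.
#'
#' @param seq a [dceus_sequence()].
#' @return object of class `data_matrix`: `values` (T x M*N), `means`
#'   (column means), `n_rows`, `n_cols`, `timestamps`.
#' @export
flatten_sequence <- function(seq) {
  stopifnot(inherits(seq, "dceus_sequence"))
  M <- seq$n_rows; N <- seq$n_cols; T_ <- seq$n_frames
  # (col, row, t) column-major flatten puts pixel (row, col) at col + (row-1)*N
  Y <- t(matrix(aperm(seq$frames, c(2, 1, 3)), M * N, T_))
  structure(list(values = Y, means = colMeans(Y),
                 n_rows = M, n_cols = N,
                 timestamps = seq_timestamps(seq)),
            class = "data_matrix")
}

#' Restore frames from a data matrix
#'
#' Inverse of [flatten_sequence()]; exact round trip.
#'
#' @param mat a `data_matrix`.
#' @return `M x N x T` array.
#' @export
unflatten_matrix <- function(mat) {
  stopifnot(inherits(mat, "data_matrix"))
  aperm(array(t(mat$values), c(mat$n_cols, mat$n_rows, nrow(mat$values))),
        c(2, 1, 3))
}

#' PCA decomposition of a centered DCEUS data matrix
#'
#' Decomposes the per-pixel mean-centered matrix into `p` orthonormal
#' temporal components with spatial weighting vectors, ordered by
#' non-increasing explained variance. This is the covariance
#' eigendecomposition of the frame sequence; numerically it is carried out
#' as an SVD of the centered matrix for small inputs and as an
#' eigendecomposition of the T x T temporal Gram matrix for large ones
#' (identical results, chosen for speed). Sign convention: each component's
#' largest-magnitude element is positive, so decompositions are
#' reproducible across runs and platforms.
#'
#' @param mat a `data_matrix` from [flatten_sequence()].
#' @param p number of components to retain, `2 <= p <= min(T, M*N)`.
#' @param method `"auto"` (default), `"svd"`, or `"gram"`.
#' @return object of class `pca_result`: `components` (T x p, orthonormal
#'   columns), `weights` (M*N x p spatial weighting vectors, scaled by the
#'   singular values), `singular_values`, `explained_variance` (fractions,
#'   non-increasing, summing to <= 1), `p`, `timestamps`.
#' @export
pca_decompose <- function(mat, p = 4L, method = c("auto", "svd", "gram")) {
  stopifnot(inherits(mat, "data_matrix"))
  method <- match.arg(method)
  Y <- mat$values
  T_ <- nrow(Y); q <- ncol(Y)
  if (p < 2 || p > min(T_, q))
    stop("p must satisfy 2 <= p <= min(T, M*N)")
  Yc <- sweep(Y, 2L, mat$means, `-`)
  total_var <- sum(Yc^2)
  if (total_var == 0) stop("all-zero centered matrix: constant sequence")
  if (method == "auto") method <- if (min(T_, q) <= 256L) "svd" else "gram"
  if (method == "svd") {
    s <- svd(Yc, nu = p, nv = 0)
    comps <- s$u
    d <- s$d[seq_len(p)]
  } else {
    e <- eigen(tcrossprod(Yc), symmetric = TRUE)
    comps <- e$vectors[, seq_len(p), drop = FALSE]
    d <- sqrt(pmax(e$values[seq_len(p)], 0))
  }
  weights <- crossprod(Yc, comps)   # = d_i * v_i per column
  # deterministic sign: largest-|element| of each temporal component positive
  for (i in seq_len(p)) {
    j <- which.max(abs(comps[, i]))
    if (comps[j, i] < 0) {
      comps[, i] <- -comps[, i]
      weights[, i] <- -weights[, i]
    }
  }
  structure(list(components = comps, weights = weights,
                 singular_values = d,
                 explained_variance = d^2 / total_var,
                 p = as.integer(p), timestamps = mat$timestamps),
            class = "pca_result")
}

#' Extract the respiratory kinetic curve from a PCA decomposition
#'
#' Out-of-plane breathing motion concentrates in the second principal
#' component of the frame sequence (the first carries the global bolus
#' kinetics), so the respiratory curve is that component scaled by its
#' singular value, making its amplitude reflect the variance it explains.
#' If the chosen component has no concentrated spectral peak (its
#' segment-averaged periodogram maximum is below 5x the median power) a
#' warning `"no respiratory component detected"` is emitted.
#'
#' @param pca a `pca_result` with `p >= 2`.
#' @param timestamps frame times (s); defaults to those recorded in `pca`.
#' @param component 1-based component index, default 2.
#' @return object of class `respiratory_curve`: `r`, `timestamps`,
#'   `smoothed`, `smoothing_window`, `dominant_frequency` (NA until
#'   estimated).
#' @export
extract_respiratory_curve <- function(pca, timestamps = NULL,
                                      component = 2L) {
  stopifnot(inherits(pca, "pca_result"))
  if (pca$p < component)
    stop("decomposition has fewer than ", component, " components")
  if (is.null(timestamps)) timestamps <- pca$timestamps
  r <- pca$singular_values[component] * pca$components[, component]
  ps <- averaged_periodogram(r, 1 / mean(diff(timestamps)))
  pw <- ps$power[ps$freq > 0]
  if (max(pw) < 5 * stats::median(pw))
    warning("no respiratory component detected")
  structure(list(r = r, timestamps = timestamps, smoothed = FALSE,
                 smoothing_window = NA_integer_,
                 dominant_frequency = NA_real_),
            class = "respiratory_curve")
}

# one-sided raw periodogram; power in arbitrary units, freq in Hz
raw_periodogram <- function(y, fs) {
  T_ <- length(y)
  P <- Mod(stats::fft(y))^2 / T_
  k <- 0:(T_ %/% 2)
  list(freq = k * fs / T_, power = P[k + 1])
}

# Bartlett-averaged periodogram (8 segments) for peak-presence testing:
# averaging tames the heavy tail of single-periodogram noise bins
averaged_periodogram <- function(y, fs, segments = 8L) {
  T_ <- length(y)
  L <- max(16L, T_ %/% segments)
  n <- T_ %/% L
  if (n < 2L) return(raw_periodogram(y, fs))
  acc <- NULL
  for (i in seq_len(n)) {
    seg <- y[((i - 1) * L + 1):(i * L)]
    p <- raw_periodogram(seg - mean(seg), fs)
    acc <- if (is.null(acc)) p$power else acc + p$power
  }
  list(freq = (0:(L %/% 2)) * fs / L, power = acc / n)
}

#' Smooth a respiratory curve with a zero-phase moving average
#'
#' Centered (zero-phase) moving average; at the edges the window is
#' truncated to the available samples. The default pipeline window,
#' `round(0.25 * frame_rate / dominant_frequency)` forced odd, passes the
#' respiratory fundamental while suppressing frame-to-frame noise.
#'
#' @param curve a `respiratory_curve`.
#' @param window odd window length in frames, `1 <= window <= T`.
#' @return smoothed `respiratory_curve` (`smoothed = TRUE`).
#' @export
smooth_curve <- function(curve, window) {
  stopifnot(inherits(curve, "respiratory_curve"))
  T_ <- length(curve$r)
  if (window < 1 || window > T_ || window %% 2 != 1)
    stop("window must be odd and within [1, T]")
  curve$r <- moving_average(curve$r, window)
  curve$smoothed <- TRUE
  curve$smoothing_window <- as.integer(window)
  curve
}

moving_average <- function(y, window) {
  if (window == 1L) return(y)
  T_ <- length(y); h <- (window - 1L) %/% 2L
  cs <- c(0, cumsum(y))
  lo <- pmax(seq_len(T_) - h, 1L)
  hi <- pmin(seq_len(T_) + h, T_)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Narrowband refinement of a respiratory curve
#'
#' Zero-phase (forward-backward) second-order Butterworth band-pass around
#' the curve's dominant frequency. Breathing harmonics and slow
#' bolus-envelope leakage in the extracted component distort the waveform
#' and shift its extrema by several frames; restricting to a band around
#' the fundamental leaves extremum timing to the breathing cycle alone.
#'
#' @param curve a `respiratory_curve` whose `dominant_frequency` is set
#'   (see [estimate_dominant_frequency()]).
#' @param band relative band edges as multiples of the dominant frequency,
#'   default `c(0.6, 1.6)`; the upper edge is clamped below Nyquist.
#' @return the curve, band-passed, with `smoothed = TRUE`.
#' @importFrom signal butter filtfilt
#' @export
bandpass_curve <- function(curve, band = c(0.6, 1.6)) {
  stopifnot(inherits(curve, "respiratory_curve"))
  if (is.na(curve$dominant_frequency))
    stop("estimate the dominant frequency first")
  fs <- 1 / mean(diff(curve$timestamps))
  lo <- band[1] * curve$dominant_frequency
  hi <- min(band[2] * curve$dominant_frequency, 0.9 * fs / 2)
  if (hi <= lo) stop("band collapses below the Nyquist rate")
  bw <- signal::butter(2, c(lo, hi) / (fs / 2), type = "pass")
  curve$r <- signal::filtfilt(bw$b, bw$a, curve$r - mean(curve$r))
  curve$smoothed <- TRUE
  curve
}

#' Estimate the dominant frequency of a respiratory curve
#'
#' Maximum non-DC bin of the raw periodogram, refined by parabolic
#' interpolation over the peak bin and its two neighbours.
#'
#' @param curve a `respiratory_curve` with at least 16 samples.
#' @return the curve, with `dominant_frequency` (Hz) filled.
#' @export
estimate_dominant_frequency <- function(curve) {
  stopifnot(inherits(curve, "respiratory_curve"))
  y <- curve$r
  if (length(y) < 16L) stop("need at least 16 samples")
  if (all(y == 0)) stop("flat spectrum: all-zero curve")
  fs <- 1 / mean(diff(curve$timestamps))
  ps <- raw_periodogram(y - mean(y), fs)
  pw <- ps$power; pw[1] <- 0                      # exclude DC
  k <- which.max(pw)
  f <- ps$freq[k]
  if (k > 2L && k < length(pw)) {
    a <- pw[k - 1]; b <- pw[k]; c <- pw[k + 1]
    den <- a - 2 * b + c
    if (den < 0) {
      delta <- 0.5 * (a - c) / den
      f <- f + delta * fs / length(y)
    }
  }
  curve$dominant_frequency <- f
  curve
}

#' Detect end-of-inspiration / end-of-expiration phases
#'
#' Zero-crossing dual-phase detection on the first-order derivative of the
#' smoothed respiratory curve: a + to - sign change of the first difference
#' marks a local maximum, - to + a local minimum; runs of exact zeros
#' collapse to their midpoint. Extrema closer than `min_separation` frames
#' to a stronger same-class extremum are dropped, and strict alternation is
#' enforced by keeping only the more extreme of consecutive same-class
#' detections. By default curve maxima map to EOI (the orientation of an
#' eigenvector is physically ambiguous; use `swap_phases` to flip).
#'
#' @param curve a smoothed `respiratory_curve`.
#' @param min_separation minimum frames between same-class extrema; default
#'   half a period of the dominant frequency.
#' @param swap_phases logical; map curve maxima to EOE instead of EOI.
#' @param exclude_boundary logical; drop extrema within `min_separation`
#'   frames of either end of the series, whose flanks are truncated (and,
#'   after zero-phase filtering, carry edge transients). Off by default.
#' @return object of class `phase_detection`: `eoi_frames`, `eoe_frames`
#'   (1-based frame indices), `n_cycles`.
#' @export
detect_phases <- function(curve, min_separation = NULL,
                          swap_phases = FALSE, exclude_boundary = FALSE) {
  stopifnot(inherits(curve, "respiratory_curve"))
  if (!curve$smoothed)
    stop("curve must be smoothed before phase detection")
  r <- curve$r
  if (is.null(min_separation)) {
    if (is.na(curve$dominant_frequency))
      curve <- estimate_dominant_frequency(curve)
    fs <- 1 / mean(diff(curve$timestamps))
    min_separation <- round(0.5 * fs / curve$dominant_frequency)
  }
  d <- diff(r)
  s <- sign(d)
  nz <- which(s != 0)
  maxima <- integer(0); minima <- integer(0)
  if (length(nz) >= 2L) {
    for (i in seq_len(length(nz) - 1L)) {
      a <- nz[i]; b <- nz[i + 1L]
      if (s[a] == s[b]) next
      idx <- as.integer(round((a + 1L + b) / 2))  # midpoint of any zero run
      if (s[a] > 0) maxima <- c(maxima, idx) else minima <- c(minima, idx)
    }
  }
  prune <- function(idx, strength) {
    # drop extrema within min_separation of a stronger same-class one
    if (length(idx) < 2L) return(idx)
    keep <- rep(TRUE, length(idx))
    ord <- order(strength[idx], decreasing = TRUE)
    for (j in ord) {
      if (!keep[j]) next
      close <- which(keep & abs(idx - idx[j]) < min_separation &
                       seq_along(idx) != j)
      keep[close] <- FALSE
    }
    sort(idx[keep])
  }
  maxima <- prune(maxima, r)
  minima <- prune(minima, -r)
  if (length(maxima) < 1L || length(minima) < 1L)
    stop("fewer than one full cycle detected")
  # enforce alternation: among consecutive same-class extrema keep the
  # more extreme
  repeat {
    all_idx <- c(maxima, minima)
    cls <- rep(c(1L, 2L), c(length(maxima), length(minima)))
    o <- order(all_idx); all_idx <- all_idx[o]; cls <- cls[o]
    run <- which(diff(cls) == 0)
    if (length(run) == 0L) break
    j <- run[1]
    v <- if (cls[j] == 1L) r[all_idx[c(j, j + 1L)]] else -r[all_idx[c(j, j + 1L)]]
    drop_idx <- all_idx[c(j, j + 1L)][which.min(v)]
    if (cls[j] == 1L) maxima <- setdiff(maxima, drop_idx)
    else minima <- setdiff(minima, drop_idx)
    if (length(maxima) < 1L || length(minima) < 1L)
      stop("fewer than one full cycle detected")
  }
  if (exclude_boundary) {
    T_ <- length(r)
    keep <- function(idx) idx[idx > min_separation & idx <= T_ - min_separation]
    maxima <- keep(maxima); minima <- keep(minima)
    if (length(maxima) < 1L || length(minima) < 1L)
      stop("fewer than one full cycle detected")
  }
  eoi <- if (swap_phases) minima else maxima
  eoe <- if (swap_phases) maxima else minima
  structure(list(eoi_frames = eoi, eoe_frames = eoe,
                 n_cycles = min(length(eoi), length(eoe)),
                 min_separation = min_separation),
            class = "phase_detection")
}

#' Gate a sequence at one respiratory phase
#'
#' Selects exactly the frames at the detected extrema of the requested
#' class, keeping their original (nonuniform, roughly one-per-cycle)
#' timestamps.
#'
#' @param seq a [dceus_sequence()].
#' @param phases a `phase_detection`.
#' @param label `"eoi"` or `"eoe"`.
#' @return object of class `gated_subsequence`: `frames` (M x N x K),
#'   `source_indices`, `timestamps`, `phase_label`, `pixel_spacing`.
#' @export
gate_sequence <- function(seq, phases, label = c("eoi", "eoe")) {
  stopifnot(inherits(seq, "dceus_sequence"),
            inherits(phases, "phase_detection"))
  label <- match.arg(label)
  idx <- if (label == "eoi") phases$eoi_frames else phases$eoe_frames
  if (length(idx) == 0L) stop("empty phase list")
  if (any(idx < 1L | idx > seq$n_frames))
    stop("phase indices outside the sequence")
  structure(list(frames = seq$frames[, , idx, drop = FALSE],
                 source_indices = idx,
                 timestamps = seq_timestamps(seq)[idx],
                 phase_label = label,
                 pixel_spacing = seq$pixel_spacing),
            class = "gated_subsequence")
}
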