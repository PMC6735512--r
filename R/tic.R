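#' Time-intensity curve object
#'
#' @param intensity mean video intensity per time point (non-negative).
#' @param timestamps strictly increasing times, s.
#' @param roi `(row0, col0, height, width)` rectangle in pixels (1-based).
#' @param filtered logical; set by [dwma_filter()].
#' @return object of class `tic`.
#' @export
tic <- function(intensity, timestamps, roi = NULL, filtered = FALSE) {
  if (length(intensity) != length(timestamps))
    stop("intensity and timestamps must have equal length")
  if (any(diff(timestamps) <= 0))
    stop("timestamps must be strictly increasing")
  if (any(intensity < 0)) stop("intensities must be non-negative")
  structure(list(intensity = as.numeric(intensity),
                 timestamps = as.numeric(timestamps),
                 roi = roi, filtered = filtered), class = "tic")
}

frames_and_times <- function(x) {
  if (inherits(x, "dceus_sequence"))
    list(frames = x$frames, timestamps = seq_timestamps(x))
  else if (inherits(x, "gated_subsequence"))
    list(frames = x$frames, timestamps = x$timestamps)
  else stop("expected a dceus_sequence or gated_subsequence")
}

#' Extract the TIC grid of a sequence
#'
#' Tiles the image with non-overlapping `roi_size` x `roi_size` cells
#' (default 3 x 3; trailing rows/columns that do not fill a cell are
#' excluded) and takes the arithmetic mean of each cell per frame.
#'
#' @param x a [dceus_sequence()] or [gate_sequence()] output.
#' @param roi_size cell side in pixels, >= 1.
#' @return object of class `tic_grid`: `intensity` (grid_rows x grid_cols x
#'   K array), `timestamps`, `roi_size`, `filtered`.
#' @export
extract_tic_grid <- function(x, roi_size = 3L) {
  ft <- frames_and_times(x)
  d <- dim(ft$frames)
  if (roi_size < 1L) stop("roi_size must be >= 1")
  gr <- d[1] %/% roi_size; gc <- d[2] %/% roi_size
  if (gr < 1L || gc < 1L) stop("image smaller than one ROI")
  A <- ft$frames[seq_len(gr * roi_size), seq_len(gc * roi_size), ,
                 drop = FALSE]
  # strided accumulation along rows then columns
  R <- array(0, c(gr, gc * roi_size, d[3]))
  for (i in seq_len(roi_size))
    R <- R + A[seq(i, by = roi_size, length.out = gr), , , drop = FALSE]
  G <- array(0, c(gr, gc, d[3]))
  for (j in seq_len(roi_size))
    G <- G + R[, seq(j, by = roi_size, length.out = gc), , drop = FALSE]
  structure(list(intensity = G / roi_size^2, timestamps = ft$timestamps,
                 roi_size = as.integer(roi_size), filtered = FALSE),
            class = "tic_grid")
}

#' Pull one cell's TIC out of a grid
#'
#' @param grid a `tic_grid`.
#' @param i,j grid cell indices (1-based).
#' @return a [tic()] whose `roi` is the cell's pixel rectangle.
#' @export
grid_tic <- function(grid, i, j) {
  stopifnot(inherits(grid, "tic_grid"))
  rs <- grid$roi_size
  tic(grid$intensity[i, j, ], grid$timestamps,
      roi = c((i - 1) * rs + 1, (j - 1) * rs + 1, rs, rs),
      filtered = grid$filtered)
}

#' Extract the TIC of a rectangular ROI
#'
#' @param x a [dceus_sequence()] or gated subsequence.
#' @param rect `(row0, col0, height, width)`, 1-based, within bounds.
#' @return a [tic()].
#' @export
extract_tic_roi <- function(x, rect) {
  ft <- frames_and_times(x)
  d <- dim(ft$frames)
  r0 <- rect[1]; c0 <- rect[2]; h <- rect[3]; w <- rect[4]
  if (r0 < 1 || c0 < 1 || h < 1 || w < 1 ||
      r0 + h - 1 > d[1] || c0 + w - 1 > d[2])
    stop("ROI rectangle out of image bounds")
  sub <- ft$frames[r0:(r0 + h - 1), c0:(c0 + w - 1), , drop = FALSE]
  tic(apply(sub, 3, mean), ft$timestamps, roi = rect)
}

# normalized triangular kernel of odd length w: 1,2,...,(w+1)/2,...,2,1
triangle_kernel <- function(window) {
  half <- (window + 1L) %/% 2L
  k <- c(seq_len(half), rev(seq_len(half - 1L)))
  k / sum(k)
}

# two cascaded triangular-weighted passes along rows of X (time x series),
# window truncated (weights renormalized) at the edges
dwma_mat <- function(X, window) {
  if (window == 1L) return(X)
  K <- nrow(X)
  if (window > K) stop("window longer than the TIC")
  k <- triangle_kernel(window)
  h <- (window - 1L) %/% 2L
  pass <- function(Z) {
    out <- stats::filter(Z, k, sides = 2)
    out <- matrix(as.numeric(out), K, ncol(Z))
    for (e in c(seq_len(h), (K - h + 1L):K)) {       # truncated edges
      lo <- max(1L, e - h); hi <- min(K, e + h)
      kk <- k[(lo - e + h + 1L):(hi - e + h + 1L)]
      out[e, ] <- crossprod(Z[lo:hi, , drop = FALSE], kk / sum(kk))
    }
    out
  }
  pmax(pass(pass(X)), 0)
}

#' Dual-weighted moving-average TIC denoising
#'
#' Two cascaded passes of a centered triangular-weighted moving average
#' (weights `1, 2, ..., ceiling(w/2), ..., 2, 1`, normalized; the "dual" is
#' the two weighted passes). Edges are handled by truncating the window and
#' renormalizing the weights, so constant signals pass unchanged and output
#' never goes negative. Suppresses speckle/thermal clutter and partly
#' recirculation ripple without model fitting.
#'
#' @param x a [tic()] or a `tic_grid` (every cell filtered at once).
#' @param window odd window length in samples, default 5.
#' @return the input object, filtered (`filtered = TRUE`).
#' @export
dwma_filter <- function(x, window = 5L) {
  if (window < 1L || window %% 2L != 1L) stop("window must be odd and >= 1")
  if (inherits(x, "tic")) {
    x$intensity <- as.numeric(
      dwma_mat(matrix(x$intensity, ncol = 1), window))
    x$filtered <- TRUE
  } else if (inherits(x, "tic_grid")) {
    d <- dim(x$intensity)
    Xt <- t(matrix(x$intensity, d[1] * d[2], d[3]))   # time x cells
    x$intensity <- array(t(dwma_mat(Xt, window)), d)
    x$filtered <- TRUE
  } else stop("expected a tic or tic_grid")
  x
}

#' Write a TIC grid as a long-format CSV
#'
#' Columns `roi_row, roi_col, time_s, intensity`.
#'
#' @param grid a `tic_grid`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_tic_grid <- function(grid, path) {
  stopifnot(inherits(grid, "tic_grid"))
  d <- dim(grid$intensity)
  df <- data.frame(
    roi_row = rep(seq_len(d[1]), times = d[2] * d[3]),
    roi_col = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    time_s = rep(grid$timestamps, each = d[1] * d[2]),
    intensity = as.numeric(grid$intensity))
  write_table(df, path)
}
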