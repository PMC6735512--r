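#' dmfpi: respiratory-gated dual-phase perfusion imaging for DCEUS
#'
#' Quantitative perfusion analysis of dynamic contrast-enhanced ultrasound
#' (DCEUS) cine loops acquired under free breathing: PCA extraction of the
#' respiratory kinetic curve, derivative zero-crossing dual-phase gating,
#' gated time-intensity-curve (TIC) analysis, six-parameter perfusion map
#' reconstruction, evaluation metrics, and a synthetic flow-phantom
#' simulator with motion-frozen ground-truth loops.
#'
#' @keywords internal
"_PACKAGE"

#' Construct a DCEUS sequence object
#'
#' A `dceus_sequence` holds a grayscale cine loop as a numeric array of
#' dimension `c(M, N, T)` (row, column, frame) together with the timing and
#' spatial metadata every downstream stage needs. Intensities are
#' dimensionless video levels; they are never rescaled on construction.
#'
#' @param frames numeric array `M x N x T` (or a list of `T` equal-sized
#'   matrices); all values must be finite and non-negative.
#' @param frame_rate acquisition frame rate in Hz (> 0).
#' @param pixel_spacing pixel spacing in mm/pixel; length 1 (isotropic) or 2
#'   `(row, col)`.
#' @param t0 acquisition start time in seconds (default 0).
#' @param mode_label `"contrast"` or `"fundamental"` imaging mode tag.
#' @return object of class `dceus_sequence` with elements `frames`,
#'   `n_frames`, `n_rows`, `n_cols`, `frame_rate`, `pixel_spacing`, `t0`,
#'   `mode_label`.
#' @examples
#' seq <- dceus_sequence(array(1, c(4, 4, 3)), frame_rate = 10)
#' seq_timestamps(seq)
#' @export
dceus_sequence <- function(frames, frame_rate, pixel_spacing = c(1, 1),
                           t0 = 0, mode_label = c("contrast", "fundamental")) {
  mode_label <- match.arg(mode_label)
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1L)
      stop("inconsistent frame shapes in sequence")
    frames <- array(unlist(frames, use.names = FALSE),
                    dim = c(dims[[1]], length(frames)))
  }
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("frames must be an M x N x T array or a list of matrices")
  d <- dim(frames)
  if (d[3] < 2L) stop("fewer than 2 frames")
  if (d[1] < 3L || d[2] < 3L) stop("frames must be at least 3 x 3 pixels")
  if (!all(is.finite(frames)) || any(frames < 0))
    stop("intensities must be finite and non-negative")
  storage.mode(frames) <- "double"
  if (!is.numeric(frame_rate) || length(frame_rate) != 1L || frame_rate <= 0)
    stop("frame_rate must be a positive scalar (Hz)")
  if (length(pixel_spacing) == 1L) pixel_spacing <- rep(pixel_spacing, 2L)
  if (any(pixel_spacing <= 0)) stop("pixel_spacing must be positive (mm)")
  structure(list(frames = frames,
                 n_frames = d[3], n_rows = d[1], n_cols = d[2],
                 frame_rate = frame_rate,
                 pixel_spacing = as.numeric(pixel_spacing),
                 t0 = t0, mode_label = mode_label),
            class = "dceus_sequence")
}

#' Frame timestamps of a sequence
#'
#' @param seq a `dceus_sequence`.
#' @return numeric vector `t0 + (k - 1)/frame_rate`, k = 1..T, seconds.
#' @export
seq_timestamps <- function(seq) {
  stopifnot(inherits(seq, "dceus_sequence"))
  seq$t0 + (seq_len(seq$n_frames) - 1) / seq$frame_rate
}

#' @export
print.dceus_sequence <- function(x, ...) {
  cat(sprintf("<dceus_sequence> %d frames of %d x %d @ %.3g Hz (%s mode)\n",
              x$n_frames, x$n_rows, x$n_cols, x$frame_rate, x$mode_label))
  cat(sprintf("  pixel spacing %.3g x %.3g mm, t0 = %.3g s, intensity range [%.3g, %.3g]\n",
              x$pixel_spacing[1], x$pixel_spacing[2], x$t0,
              min(x$frames), max(x$frames)))
  invisible(x)
}

#' Sequence acquisition metadata
#'
#' Sidecar metadata describing how a loop was acquired. `dynamic_range` and
#' `mechanical_index` are informational and not used in computation.
#'
#' @param frame_rate Hz, > 0.
#' @param pixel_spacing mm/pixel, > 0 (scalar or `(row, col)`).
#' @param dynamic_range dB (informational).
#' @param mechanical_index dimensionless (informational).
#' @param mode_label `"contrast"` or `"fundamental"`.
#' @return object of class `sequence_metadata`.
#' @export
sequence_metadata <- function(frame_rate, pixel_spacing = 1,
                              dynamic_range = NA_real_,
                              mechanical_index = NA_real_,
                              mode_label = c("contrast", "fundamental")) {
  mode_label <- match.arg(mode_label)
  if (frame_rate <= 0) stop("frame_rate must be > 0")
  if (any(pixel_spacing <= 0)) stop("pixel_spacing must be > 0")
  structure(list(frame_rate = frame_rate, pixel_spacing = pixel_spacing,
                 dynamic_range = dynamic_range,
                 mechanical_index = mechanical_index,
                 mode_label = mode_label),
            class = "sequence_metadata")
}
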