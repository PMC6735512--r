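#' Read a DCEUS cine loop from disk
#'
#' Accepts a multi-frame grayscale TIFF stack or a directory of ordered
#' single-frame images (TIFF or PNG, sorted by file name). Color frames are
#' converted to grayscale by the channel mean. Stored intensities are
#' preserved as-is: integer TIFF samples are read unnormalized, so an 8-bit
#' stack yields values in 0..255.
#'
#' @param path file path of a multi-frame TIFF, or a directory of frames.
#' @param meta a [sequence_metadata()] giving at least the frame rate.
#' @param t0 acquisition start time (s).
#' @return a [dceus_sequence()].
#' @export
read_sequence <- function(path, meta, t0 = 0) {
  stopifnot(inherits(meta, "sequence_metadata"))
  if (!file.exists(path)) stop("file not found: ", path)
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(tif|tiff|png)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) < 2L) stop("fewer than 2 frames in directory ", path)
    frames <- lapply(files, read_frame)
  } else {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("tif", "tiff"))
      stop("unsupported container '", ext,
           "': supply a multi-frame TIFF or a directory of frames")
    frames <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(frames)) frames <- list(frames)
    if (length(frames) < 2L) stop("fewer than 2 frames in ", path)
    frames <- lapply(frames, to_gray)
  }
  dims <- unique(lapply(frames, dim))
  if (length(dims) != 1L) stop("inconsistent frame shapes in ", path)
  dceus_sequence(frames, frame_rate = meta$frame_rate,
                 pixel_spacing = meta$pixel_spacing, t0 = t0,
                 mode_label = meta$mode_label)
}

read_frame <- function(f) {
  ext <- tolower(tools::file_ext(f))
  img <- if (ext == "png") png::readPNG(f) * 255 else
    tiff::readTIFF(f, as.is = TRUE)
  to_gray(img)
}

# channel-mean grayscale conversion; idempotent on 2-D input
to_gray <- function(img) {
  if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
  img
}

#' Write a grayscale stack or RGB map stack to disk
#'
#' Grayscale sequences go to a lossless multi-frame TIFF at 8 or 16 bits;
#' re-reading returns bit-identical arrays. TIFF stores integer video
#' levels, so non-integer data must be quantized by the caller first
#' (e.g. `round()`); an error says so rather than silently losing
#' precision. RGB maps (values 0..255, array `H x W x 3` or list thereof)
#' go to 8-bit PNG.
#'
#' @param x a [dceus_sequence()], an `M x N x T` array, or for PNG output an
#'   RGB array / list of RGB arrays.
#' @param path output file path; extension selects the format (.tif/.tiff or
#'   .png; lists of RGB maps are written as `path` with an index suffix).
#' @return the path(s) written, invisibly.
#' @export
write_image_stack <- function(x, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    maps <- if (is.list(x)) x else list(x)
    if (length(maps) == 0L) stop("empty map list")
    paths <- character(length(maps))
    for (i in seq_along(maps)) {
      m <- maps[[i]]
      if (length(dim(m)) != 3L || dim(m)[3] != 3L)
        stop("PNG output expects H x W x 3 RGB arrays with values 0..255")
      p <- if (length(maps) == 1L) path else
        sub("\\.png$", sprintf("_%03d.png", i), path, ignore.case = TRUE)
      png::writePNG(m / 255, p)
      paths[i] <- p
    }
    return(invisible(paths))
  }
  if (!ext %in% c("tif", "tiff")) stop("unsupported output format: ", ext)
  if (inherits(x, "dceus_sequence")) x <- x$frames
  if (!is.array(x) || length(dim(x)) != 3L || dim(x)[3] < 1L)
    stop("empty or invalid sequence")
  frames <- lapply(seq_len(dim(x)[3]), function(t) x[, , t])
  mx <- max(x)
  if (any(x != round(x)) || mx > 65535)
    stop("TIFF stores integer video levels up to 16 bits; ",
         "quantize the sequence first (e.g. round())")
  bits <- if (mx <= 255) 8L else 16L
  scale <- 2^bits - 1
  ok <- tiff::writeTIFF(lapply(frames, function(f) f / scale),
                        path, bits.per.sample = bits)
  if (!ok) stop("unwritable path: ", path)
  invisible(path)
}

#' Write tabular records or a metrics report
#'
#' Rectangular tables are written as CSV with a header row at full double
#' precision; named lists (e.g. metric reports) as JSON.
#'
#' @param records a data frame / matrix (CSV) or a named list (JSON).
#' @param path output path; `.json` selects JSON.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  if (tolower(tools::file_ext(path)) == "json") {
    jsonlite::write_json(records, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(path))
  }
  if (is.list(records) && !is.data.frame(records)) {
    n <- unique(lengths(records))
    if (length(n) != 1L) stop("ragged rows: columns differ in length")
    records <- as.data.frame(records)
  }
  if (is.matrix(records)) records <- as.data.frame(records)
  if (!is.data.frame(records)) stop("records must be tabular or a named list")
  utils::write.csv(format(records, digits = 17, trim = TRUE, scientific = NA),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Default analysis configuration
#'
#' @return named list of the documented pipeline defaults: `p` (retained PCA
#'   components), `roi_size` (TIC grid cell, pixels), `f_c` (SCR cut-off, Hz),
#'   `smoothing_window` (frames; `NULL` = derived from the dominant
#'   respiratory frequency), `min_separation` (frames; `NULL` = derived),
#'   `arrival_fraction` (threshold fraction of peak for arrival/washout),
#'   `dwma_window` (TIC filter window in samples, for full-rate TICs),
#'   `dwma_window_gated` (window for gated TICs, which carry roughly one
#'   sample per breathing cycle, so the filter must span far fewer samples
#'   to cover a comparable time), `colormap`, `resp_component`
#'   (1-based PCA component index used as the respiratory curve),
#'   `swap_phases`, `linearize` (optional log-decompression; off),
#'   `density_bins`, `seed`.
#' @export
default_config <- function() {
  list(p = 4L, roi_size = 3L, f_c = 0.15, smoothing_window = NULL,
       min_separation = NULL, arrival_fraction = 0.10, dwma_window = 5L,
       dwma_window_gated = 3L,
       colormap = "jet256", resp_component = 2L, swap_phases = FALSE,
       linearize = FALSE, density_bins = 32L, seed = 1L)
}

#' Load and validate a pipeline configuration file
#'
#' Reads YAML or JSON, merges with [default_config()], and validates. Unknown
#' keys are rejected so typos surface immediately.
#'
#' @param path YAML or JSON file; an empty file yields the full defaults.
#' @return validated configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- if (tolower(tools::file_ext(path)) == "json")
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- default_config()
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(user)] <- user
  validate_config(cfg)
}

validate_config <- function(cfg) {
  chk <- function(ok, field, msg)
    if (!isTRUE(ok)) stop("config field '", field, "': ", msg)
  chk(is.numeric(cfg$p) && cfg$p >= 2, "p",
      "must be >= 2 so the second component exists")
  chk(is.numeric(cfg$roi_size) && cfg$roi_size >= 1, "roi_size",
      "must be a positive integer")
  chk(is.numeric(cfg$f_c) && cfg$f_c > 0, "f_c", "must be > 0 (Hz)")
  chk(is.numeric(cfg$arrival_fraction) && cfg$arrival_fraction > 0 &&
        cfg$arrival_fraction < 1, "arrival_fraction", "must be in (0, 1)")
  chk(is.numeric(cfg$dwma_window) && cfg$dwma_window >= 1 &&
        cfg$dwma_window %% 2 == 1, "dwma_window", "must be odd and >= 1")
  chk(is.numeric(cfg$dwma_window_gated) && cfg$dwma_window_gated >= 1 &&
        cfg$dwma_window_gated %% 2 == 1, "dwma_window_gated",
      "must be odd and >= 1")
  chk(is.null(cfg$smoothing_window) ||
        (is.numeric(cfg$smoothing_window) && cfg$smoothing_window >= 1),
      "smoothing_window", "must be NULL or >= 1")
  chk(is.numeric(cfg$resp_component) && cfg$resp_component >= 1,
      "resp_component", "must be >= 1")
  chk(is.numeric(cfg$density_bins) && cfg$density_bins >= 2,
      "density_bins", "must be >= 2")
  cfg$p <- as.integer(cfg$p); cfg$roi_size <- as.integer(cfg$roi_size)
  cfg
}
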