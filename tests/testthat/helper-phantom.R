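# A desk-sized phantom for unit tests: same structure as the default
# protocol (bolus-dominant first component, respiration second) at a
# fraction of the cost. 56 x 56 pixels, 10 Hz, 40 s, 0.5 Hz breathing.
small_phantom <- function(seed = 42, noise = noise_params(),
                          resp_amplitude = 0.3, out_of_plane = NULL,
                          flow = TRUE, ...) {
  phantom_config(
    image_size = c(56L, 56L), vessel_diameter = 1.8, wall_thickness = 0.5,
    pixel_spacing = 0.1, resp_frequency = 0.5,
    resp_amplitude = resp_amplitude,
    bolus = bolus_params(t_arrival = 4, A = 4000, mu = 2.2, sigma = 0.5),
    noise = noise, frame_rate = 10, duration = 40,
    flow_delay_span = if (flow) 2 else 0,
    flow_amp_drop = if (flow) 0.5 else 0,
    flow_mu_span = if (flow) 0.7 else 0,
    out_of_plane = out_of_plane, seed = seed, ...)
}

# alternate-phase anatomy scaled to the small phantom
small_out_of_plane <- function() {
  list(list(offset = c(0.7, 0.55), radius = 0.45,
            bolus = bolus_params(t_arrival = 10, A = 3000, mu = 1.7)),
       list(offset = c(0.35, -0.8), radius = 0.35,
            bolus = bolus_params(t_arrival = 4, A = 1e-6, mu = 2.2,
                                 baseline = 3)),
       list(offset = c(-0.55, 0.35), radius = 0.3,
            bolus = bolus_params(t_arrival = 2, A = 1600, mu = 1.3)))
}

no_noise <- function() noise_params(enabled = FALSE)

# bare respiratory-curve object for operations that take one directly
make_curve <- function(r, fs, smoothed = FALSE) {
  structure(list(r = r, timestamps = (seq_along(r) - 1) / fs,
                 smoothed = smoothed, smoothing_window = NA_integer_,
                 dominant_frequency = NA_real_),
            class = "respiratory_curve")
}

# filtered tic from raw samples (window-1 filter marks it filtered
# without altering values)
make_tic <- function(y, t = seq_along(y) - 1, filtered = TRUE) {
  x <- tic(y, t)
  if (filtered) x <- dwma_filter(x, 1L)
  x
}

# minimal fpi_map for metric tests
make_map <- function(values, mask = NULL, parameter = "PV") {
  values <- as.matrix(values)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(values), ncol(values))
  structure(list(parameter = parameter, values = values, mask = mask,
                 phase_label = NA, normalized = NULL, rgb = NULL,
                 dynamic_range = NULL),
            class = "fpi_map")
}
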