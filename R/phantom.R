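#' Bolus kinetics parameters
#'
#' Log-normal bolus model, the standard parametric form for DCEUS first-pass
#' kinetics. For `t > t_arrival` the lumen intensity is
#' `baseline + A / ((t - t_arrival) * sigma * sqrt(2*pi)) *
#'  exp(-(log(t - t_arrival) - mu)^2 / (2 * sigma^2))`;
#' at or before arrival it is `baseline`. `A` is the area above baseline
#' (intensity·s), `mu`/`sigma` set the shape: the peak sits at
#' `t_arrival + exp(mu - sigma^2)`.
#'
#' @param t_arrival bolus arrival time (s), >= 0.
#' @param A area above baseline (intensity·s), > 0.
#' @param mu log-scale location (dimensionless).
#' @param sigma log-scale width (dimensionless), > 0.
#' @param baseline pre-contrast intensity.
#' @return list of class `bolus_params`.
#' @export
bolus_params <- function(t_arrival = 10, A = 12000, mu = 3.3, sigma = 0.5,
                         baseline = 5) {
  if (sigma <= 0 || A <= 0 || t_arrival < 0 || baseline < 0)
    stop("invalid bolus parameters: need sigma > 0, A > 0, t_arrival >= 0")
  structure(list(t_arrival = t_arrival, A = A, mu = mu, sigma = sigma,
                 baseline = baseline), class = "bolus_params")
}

#' Noise model parameters
#'
#' Multiplicative log-normal speckle (unit mean, log-sd `speckle_sigma`)
#' followed by additive Gaussian thermal noise, clipped at zero.
#'
#' @param speckle_sigma log-sd of the multiplicative speckle field, >= 0.
#' @param additive_sigma sd of the additive noise (intensity units), >= 0.
#' @param enabled logical; disable for noise-free ground truth.
#' @return list of class `noise_params`.
#' @export
noise_params <- function(speckle_sigma = 0.2, additive_sigma = 2,
                         enabled = TRUE) {
  if (speckle_sigma < 0 || additive_sigma < 0)
    stop("noise sigmas must be >= 0")
  structure(list(speckle_sigma = speckle_sigma,
                 additive_sigma = additive_sigma, enabled = enabled),
            class = "noise_params")
}

#' Flow-phantom configuration
#'
#' Describes a synthetic DCEUS acquisition of a vessel cross-section
#' (mimicked hepatic vein) with bolus wash-in/wash-out, periodic out-of-plane
#' deformation, and speckle. Defaults reproduce the in vitro protocol: a
#' 5 mm diameter / 1.5 mm wall vessel at 0.1 mm/pixel on 128 x 128 frames,
#' 21.3 Hz frame rate, 120 s acquisition, 0.27 Hz sinusoidal respiration.
#' Out-of-plane motion is emulated in 2-D as coupled displacement plus
#' scaling of the vessel ellipse — what a slice through a tube looks like as
#' the tube sweeps through the imaging plane.
#'
#' @param image_size `(M, N)` pixels.
#' @param vessel_center `(row, col)` in pixels (1-based, may be fractional).
#' @param vessel_diameter lumen diameter, mm.
#' @param wall_thickness wall thickness, mm.
#' @param pixel_spacing mm/pixel (isotropic).
#' @param resp_frequency respiration frequency, Hz; must be below the frame
#'   Nyquist rate.
#' @param resp_amplitude fractional modulation of vessel size and position in
#'   `[0, 1]`; axes scale by `1 + resp_amplitude * m(t)` and the center is
#'   displaced by `resp_amplitude * m(t)` lumen radii (rows; half that along
#'   columns), where `m(t)` is the motion state.
#' @param bolus a [bolus_params()].
#' @param noise a [noise_params()].
#' @param frame_rate Hz.
#' @param duration acquisition length, s; must cover >= 2 respiratory cycles.
#' @param edge_softness width (mm) of the linear intensity ramp at the
#'   lumen and wall boundaries, emulating the finite beam/point-spread
#'   width; pixels more than half a ramp inside a boundary take the pure
#'   compartment value exactly.
#' @param flow_delay_span laminar-profile transit delay (s): the bolus at
#'   normalized lumen radius `rho` arrives `flow_delay_span * rho^2` later
#'   than on the axis (parabolic velocity profile; 0 = plug flow).
#' @param flow_amp_drop fractional bolus amplitude drop at the wall: the
#'   area parameter scales by `1 - flow_amp_drop * rho^2` (0 = uniform).
#' @param flow_mu_span radial dispersion: the log-scale location grows by
#'   `flow_mu_span * rho^2` toward the wall, stretching wash-in/wash-out
#'   times of slow near-wall streamlines by `exp(flow_mu_span * rho^2)`
#'   (0 = no dispersion).
#' @param out_of_plane alternate-phase anatomy: structures that slide into
#'   the imaging plane during expiration, so that at end-of-expiration
#'   different anatomy (neighbouring vessel sections with their own bolus
#'   kinetics, a non-perfused gallbladder) occupies part of the slice.
#'   A list of structures, each `list(offset = (row, col) mm from the
#'   vessel center, radius = mm, bolus = bolus_params())`; a flat `bolus`
#'   (tiny area) models a non-perfused structure. Visibility of all
#'   structures is `max(-m(t), 0)`: fully present at the EOE extreme,
#'   absent at EOI. `NULL` or an empty list disables them.
#' @param seed integer RNG seed.
#' @return list of class `phantom_config`.
#' @export
phantom_config <- function(image_size = c(128L, 128L),
                           vessel_center = NULL,
                           vessel_diameter = 5, wall_thickness = 1.5,
                           pixel_spacing = 0.1,
                           resp_frequency = 0.27, resp_amplitude = 0.3,
                           bolus = bolus_params(), noise = noise_params(),
                           frame_rate = 21.3, duration = 120,
                           edge_softness = 0.3,
                           flow_delay_span = 5, flow_amp_drop = 0.5,
                           flow_mu_span = 1.0,
                           out_of_plane = list(
                             list(offset = c(2.0, 1.6), radius = 1.2,
                                  bolus = bolus_params(t_arrival = 35,
                                                       A = 20000, mu = 2.8)),
                             list(offset = c(1.0, -2.2), radius = 1.0,
                                  bolus = bolus_params(t_arrival = 10,
                                                       A = 1e-6, mu = 3,
                                                       baseline = 3)),
                             list(offset = c(-1.5, 1.0), radius = 1.2,
                                  bolus = bolus_params(t_arrival = 4,
                                                       A = 1200, mu = 2.4))),
                           seed = 1L) {
  if (is.null(vessel_center)) vessel_center <- (image_size + 1) / 2
  if (resp_frequency >= frame_rate / 2)
    stop("resp_frequency must be below the frame Nyquist rate")
  if (duration * resp_frequency < 2)
    stop("duration must cover at least 2 respiratory cycles")
  if (resp_amplitude < 0 || resp_amplitude > 1)
    stop("resp_amplitude must be in [0, 1]")
  structure(list(image_size = as.integer(image_size),
                 vessel_center = as.numeric(vessel_center),
                 vessel_diameter = vessel_diameter,
                 wall_thickness = wall_thickness,
                 pixel_spacing = pixel_spacing,
                 resp_frequency = resp_frequency,
                 resp_amplitude = resp_amplitude,
                 bolus = bolus, noise = noise,
                 frame_rate = frame_rate, duration = duration,
                 edge_softness = edge_softness,
                 flow_delay_span = flow_delay_span,
                 flow_amp_drop = flow_amp_drop,
                 flow_mu_span = flow_mu_span,
                 out_of_plane = out_of_plane, seed = as.integer(seed),
                 wall_level = 80, background_level = 10),
            class = "phantom_config")
}

#' Analytic bolus intensity
#'
#' @param t time(s) in seconds (vectorized).
#' @param params a [bolus_params()].
#' @return intensity at `t`; `baseline` at or before arrival.
#' @export
bolus_intensity <- function(t, params) {
  stopifnot(inherits(params, "bolus_params"))
  x <- t - params$t_arrival
  out <- rep(params$baseline, length(t))
  pos <- x > 0
  if (any(pos)) {
    xp <- x[pos]
    out[pos] <- params$baseline +
      params$A / (xp * params$sigma * sqrt(2 * pi)) *
      exp(-(log(xp) - params$mu)^2 / (2 * params$sigma^2))
  }
  out
}

#' Respiratory motion state
#'
#' Sinusoidal motion surrogate `sin(2*pi*resp_frequency*t)`: `+1` is the
#' end-of-inspiration extreme, `-1` end-of-expiration.
#'
#' @param t time(s), s.
#' @param cfg a [phantom_config()].
#' @return motion scalar(s) in `[-1, 1]`.
#' @export
motion_state <- function(t, cfg) {
  sin(2 * pi * cfg$resp_frequency * t)
}

# vessel geometry at a given motion state: axis scale + center displacement
phantom_geometry <- function(m, cfg) {
  r_lumen <- cfg$vessel_diameter / 2 / cfg$pixel_spacing
  r_wall <- r_lumen + cfg$wall_thickness / cfg$pixel_spacing
  s <- 1 + cfg$resp_amplitude * m
  list(center = cfg$vessel_center +
         cfg$resp_amplitude * m * r_lumen * c(1, 0.5),
       r_lumen = r_lumen * s, r_wall = r_wall * s)
}

#' Render a single phantom frame
#'
#' The vessel is a disc (lumen at the analytic bolus intensity) inside a
#' bright wall annulus on a dim background; its radius and center follow
#' [motion_state()]. Compartment boundaries are blended over a linear ramp
#' of width `edge_softness` (beam-width emulation); pixels deeper than half
#' a ramp inside the lumen carry the analytic bolus intensity exactly.
#' Speckle and additive noise are applied when enabled.
#'
#' @param t frame time, s.
#' @param cfg a [phantom_config()].
#' @param seed optional integer; when given, the frame's noise is drawn from
#'   a fresh stream seeded with it (identical calls give identical frames).
#'   When `NULL`, the current RNG stream is consumed.
#' @param motion optional motion-state override in `[-1, 1]` (used to freeze
#'   the extreme phases); default `motion_state(t, cfg)`.
#' @return `M x N` numeric frame.
#' @export
render_frame <- function(t, cfg, seed = NULL, motion = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  m <- if (is.null(motion)) motion_state(t, cfg) else motion
  g <- phantom_geometry(m, cfg)
  M <- cfg$image_size[1]; N <- cfg$image_size[2]
  soft <- max(cfg$edge_softness / cfg$pixel_spacing, 1e-9)
  if (g$center[1] - g$r_wall < 1 + soft || g$center[1] + g$r_wall > M - soft ||
      g$center[2] - g$r_wall < 1 + soft || g$center[2] + g$r_wall > N - soft)
    stop("vessel leaves image bounds at this motion state")
  d <- sqrt(outer((seq_len(M) - g$center[1])^2,
                  (seq_len(N) - g$center[2])^2, `+`))
  clip01 <- function(x) pmin(pmax(x, 0), 1)
  w_lumen <- clip01((g$r_lumen - d) / soft + 0.5)
  w_wall <- clip01((g$r_wall - d) / soft + 0.5) - w_lumen
  frame <- w_lumen * lumen_field(t, d, g$r_lumen, cfg) +
    w_wall * cfg$wall_level +
    (1 - w_lumen - w_wall) * cfg$background_level
  if (length(cfg$out_of_plane) && m < 0) {
    for (st in cfg$out_of_plane) {
      w_op <- -m * op_mask(st, cfg, soft)
      frame <- frame * (1 - w_op) + w_op * bolus_intensity(t, st$bolus)
    }
  }
  if (cfg$noise$enabled) {
    n <- M * N
    if (cfg$noise$speckle_sigma > 0)
      frame <- frame * exp(stats::rnorm(n, -cfg$noise$speckle_sigma^2 / 2,
                                        cfg$noise$speckle_sigma))
    if (cfg$noise$additive_sigma > 0)
      frame <- frame + stats::rnorm(n, 0, cfg$noise$additive_sigma)
    frame[frame < 0] <- 0
  }
  frame
}

# per-pixel lumen intensity with the laminar flow profile: at normalized
# radius rho the bolus arrives flow_delay_span * rho^2 later, its area
# parameter scales by (1 - flow_amp_drop * rho^2), and its log-scale
# location grows by flow_mu_span * rho^2 (slow near-wall streamlines
# disperse more, stretching their wash-in/wash-out)
lumen_field <- function(t, d, r_lumen, cfg) {
  b <- cfg$bolus
  rho2 <- pmin((d / r_lumen)^2, 1)
  x <- t - b$t_arrival - cfg$flow_delay_span * rho2
  val <- array(b$baseline, dim(d))
  pos <- x > 0
  if (any(pos)) {
    amp <- b$A * (1 - cfg$flow_amp_drop * rho2[pos])
    mu_eff <- b$mu + cfg$flow_mu_span * rho2[pos]
    xp <- x[pos]
    val[pos] <- b$baseline + amp / (xp * b$sigma * sqrt(2 * pi)) *
      exp(-(log(xp) - mu_eff)^2 / (2 * b$sigma^2))
  }
  val
}

render_loop <- function(times, cfg, motion = NULL) {
  M <- cfg$image_size[1]; N <- cfg$image_size[2]
  frames <- array(0, c(M, N, length(times)))
  for (k in seq_along(times))
    frames[, , k] <- render_frame(times[k], cfg, motion = motion)
  dceus_sequence(frames, frame_rate = cfg$frame_rate,
                 pixel_spacing = cfg$pixel_spacing, mode_label = "contrast")
}

#' Simulate a DCEUS acquisition with ground truth
#'
#' Renders the free-breathing (moving) loop plus the two motion-frozen static
#' control loops at the end-of-inspiration (motion pinned at +1) and
#' end-of-expiration (-1) extremes, sharing the bolus kinetics but with
#' independent noise. Ground truth carries the analytic motion series, the
#' frame indices of its extrema, and per-pixel perfusion parameter maps
#' computed from the noise-free analytic TIC.
#'
#' @param cfg a [phantom_config()].
#' @param arrival_fraction threshold fraction used for the truth parameter
#'   conventions (matches [estimate_perfusion_params()]).
#' @param static_phases which motion-frozen control loops to render
#'   (subset of `c("eoi", "eoe")`); rendering order is moving, EOI, EOE, so
#'   skipping a later loop leaves the earlier ones bit-identical.
#' @return list with elements `moving` (a [dceus_sequence()]) and `truth`
#'   (class `phantom_truth`: `respiratory_curve`, `eoi_frames`, `eoe_frames`,
#'   `static_eoi`, `static_eoe`, `true_params`, `true_param_maps`,
#'   `lumen_mask` per phase).
#' @export
simulate_dceus <- function(cfg, arrival_fraction = 0.10,
                           static_phases = c("eoi", "eoe")) {
  stopifnot(inherits(cfg, "phantom_config"))
  set.seed(cfg$seed)
  T_ <- round(cfg$duration * cfg$frame_rate)
  times <- (seq_len(T_) - 1) / cfg$frame_rate
  moving <- render_loop(times, cfg)
  static_eoi <- if ("eoi" %in% static_phases)
    render_loop(times, cfg, motion = 1) else NULL
  static_eoe <- if ("eoe" %in% static_phases)
    render_loop(times, cfg, motion = -1) else NULL

  resp <- motion_state(times, cfg)
  # analytic extrema of the sinusoid, mapped to the nearest frame
  period <- 1 / cfg$resp_frequency
  t_max <- seq(period / 4, max(times), by = period)
  t_min <- seq(3 * period / 4, max(times), by = period)
  nearest <- function(tt) vapply(tt, function(x) which.min(abs(times - x)), 1L)
  truth <- structure(list(
    respiratory_curve = resp,
    timestamps = times,
    eoi_frames = nearest(t_max),
    eoe_frames = nearest(t_min),
    static_eoi = static_eoi,
    static_eoe = static_eoe,
    true_params = analytic_perfusion_params(cfg$bolus, cfg$duration,
                                            arrival_fraction),
    lumen_mask = list(eoi = lumen_mask(cfg, 1), eoe = lumen_mask(cfg, -1))
  ), class = "phantom_truth")
  truth$true_param_maps <- list(eoi = truth_param_maps(cfg, 1, truth$true_params),
                                eoe = truth_param_maps(cfg, -1, truth$true_params))
  list(moving = moving, truth = truth)
}

# per-pixel ground-truth parameter maps at a pinned motion state: the flow
# profile shifts times by flow_delay_span * rho^2 and scales amplitudes by
# (1 - flow_amp_drop * rho^2); wall/background pixels are zero (undefined)
truth_param_maps <- function(cfg, m, base) {
  g <- phantom_geometry(m, cfg)
  M <- cfg$image_size[1]; N <- cfg$image_size[2]
  d <- sqrt(outer((seq_len(M) - g$center[1])^2,
                  (seq_len(N) - g$center[2])^2, `+`))
  msk <- lumen_mask(cfg, m)
  rho2 <- pmin((d / g$r_lumen)^2, 1)
  s <- 1 - cfg$flow_amp_drop * rho2          # amplitude factor
  k <- exp(cfg$flow_mu_span * rho2)          # time-stretch factor
  shift <- cfg$flow_delay_span * rho2        # transit delay
  t0 <- cfg$bolus$t_arrival
  list(WIT = base$WIT * k * msk, WOT = base$WOT * k * msk,
       PV = base$PV * s / k * msk, AUC = base$AUC * s * msk,
       WIR = base$WIR * s / k^2 * msk, WOR = base$WOR * s / k^2 * msk,
       t_arrival = (t0 + shift + (base$t_arrival - t0) * k) * msk,
       t_peak = (t0 + shift + (base$t_peak - t0) * k) * msk)
}

# soft occupancy mask of one out-of-plane structure (fixed in the image;
# only its visibility follows the motion state)
op_mask <- function(st, cfg, soft) {
  ctr <- cfg$vessel_center + st$offset / cfg$pixel_spacing
  r <- st$radius / cfg$pixel_spacing
  M <- cfg$image_size[1]; N <- cfg$image_size[2]
  d <- sqrt(outer((seq_len(M) - ctr[1])^2, (seq_len(N) - ctr[2])^2, `+`))
  pmin(pmax((r - d) / soft + 0.5, 0), 1)
}

# pixels that carry the pure lumen value (inside the edge ramp)
lumen_mask <- function(cfg, m) {
  g <- phantom_geometry(m, cfg)
  M <- cfg$image_size[1]; N <- cfg$image_size[2]
  soft <- cfg$edge_softness / cfg$pixel_spacing
  d2 <- outer((seq_len(M) - g$center[1])^2, (seq_len(N) - g$center[2])^2, `+`)
  msk <- d2 <= (g$r_lumen - soft / 2)^2
  if (length(cfg$out_of_plane) && m < 0)
    for (st in cfg$out_of_plane)
      msk <- msk & op_mask(st, cfg, max(soft, 1e-9)) == 0
  msk
}

# perfusion parameters of the analytic noise-free bolus curve, using the
# same threshold conventions as the estimator, on a dense (1 ms) grid
analytic_perfusion_params <- function(bolus, duration,
                                      arrival_fraction = 0.10) {
  t <- seq(0, duration, by = 1e-3)
  y <- bolus_intensity(t, bolus)
  b <- bolus$baseline
  t_peak <- bolus$t_arrival + exp(bolus$mu - bolus$sigma^2)
  pv <- bolus_intensity(t_peak, bolus) - b
  thr <- b + arrival_fraction * pv
  t_arr <- t[which(y >= thr)[1]]
  post <- which(t > t_peak & y <= thr)
  washout_complete <- length(post) > 0
  t_out <- if (washout_complete) t[post[1]] else max(t)
  sel <- t >= t_arr & t <= t_out
  auc <- pracma::trapz(t[sel], pmax(y[sel] - b, 0))
  wit <- t_peak - t_arr
  wot <- t_out - t_peak
  list(WIT = wit, WOT = wot, PV = pv, AUC = auc,
       WIR = pv / wit, WOR = pv / wot,
       t_arrival = t_arr, t_peak = t_peak,
       washout_complete = washout_complete)
}
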