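test_that("flattening follows the row-major pixel contract and inverts", {
  frames <- array(seq_len(3 * 3 * 4), c(3, 3, 4))
  s <- dceus_sequence(frames, frame_rate = 2)
  m <- flatten_sequence(s)
  expect_equal(dim(m$values), c(4L, 9L))
  # pixel (row, col) sits in column (row - 1) * N + col
  for (row in 1:3) for (col in 1:3)
    expect_equal(m$values[2, (row - 1) * 3 + col], frames[row, col, 2])
  expect_identical(unflatten_matrix(m), frames + 0)
  # constant sequences center to zero (and cannot be decomposed)
  cm <- flatten_sequence(dceus_sequence(array(7, c(3, 3, 4)), 2))
  expect_equal(max(abs(sweep(cm$values, 2, cm$means))), 0)
  expect_error(pca_decompose(cm, 2), "all-zero")
})

test_that("PCA matches a dense covariance-eigendecomposition oracle", {
  # property sweep over random shapes, both numerical routes
  set.seed(101)
  for (rep in 1:30) {
    T_ <- sample(4:20, 1)
    M <- sample(3:4, 1); N <- sample(3:5, 1)
    frames <- array(abs(rnorm(M * N * T_)), c(M, N, T_))
    mat <- flatten_sequence(dceus_sequence(frames, 5))
    p <- sample(2:min(T_, M * N), 1)
    fit <- pca_decompose(mat, p, method = sample(c("svd", "gram"), 1))
    # oracle: eigendecomposition of the temporal covariance
    Yc <- sweep(mat$values, 2, colMeans(mat$values))
    e <- eigen(tcrossprod(Yc), symmetric = TRUE)
    ev_oracle <- pmax(e$values, 0) / sum(Yc^2)
    expect_equal(fit$explained_variance, ev_oracle[seq_len(p)],
                 tolerance = 1e-8)
    for (i in seq_len(p)) {
      if (ev_oracle[i] < 1e-10) next
      expect_equal(abs(sum(fit$components[, i] * e$vectors[, i])), 1,
                   tolerance = 1e-8)
    }
    # orthonormal components, weights carry the singular values
    # (skip numerically zero singular values)
    G <- crossprod(fit$components)
    expect_lt(max(abs(G - diag(p))), 1e-8)
    nz <- fit$singular_values > 1e-6 * fit$singular_values[1]
    expect_equal(sqrt(colSums(fit$weights[, nz, drop = FALSE]^2)),
                 fit$singular_values[nz], tolerance = 1e-8)
  }
})

test_that("PCA edge cases: rank one, full rank, sign convention", {
  set.seed(7)
  c1 <- rnorm(8); w1 <- rnorm(9)
  frames <- array(0, c(3, 3, 8))
  for (t in 1:8) frames[, , t] <- matrix(10 + w1 * c1[t], 3, 3, byrow = TRUE)
  mat <- flatten_sequence(dceus_sequence(abs(frames), 4))
  fit <- pca_decompose(mat, 2)
  expect_gte(fit$explained_variance[1], 1 - 1e-10)
  # requesting every component reconstructs all variance
  set.seed(8)
  f2 <- array(abs(rnorm(3 * 3 * 6)), c(3, 3, 6))
  m2 <- flatten_sequence(dceus_sequence(f2, 4))
  full <- pca_decompose(m2, 6)
  expect_gte(sum(full$explained_variance), 1 - 1e-10)
  # each component's largest-magnitude element is positive
  for (i in seq_len(full$p))
    expect_gt(full$components[which.max(abs(full$components[, i])), i], 0)
  expect_error(pca_decompose(m2, 1), "p must")
  expect_error(pca_decompose(m2, 7), "p must")
})

test_that("the second component carries the phantom's breathing kinetics", {
  sim <- simulate_dceus(small_phantom(), static_phases = character(0))
  pca <- pca_decompose(flatten_sequence(sim$moving), 4)
  curve <- extract_respiratory_curve(pca)
  expect_lt(abs(mean(curve$r)), 1e-8)
  curve <- estimate_dominant_frequency(curve)
  bin <- 10 / sim$moving$n_frames
  expect_lt(abs(curve$dominant_frequency - 0.5), bin)
  # smoothed curve tracks the true motion series up to sign
  sm <- smooth_curve(curve, 5)
  expect_gt(abs(cor(sm$r, sim$truth$respiratory_curve)), 0.9)
})

test_that("a motion-free loop yields no respiratory component", {
  # plug flow keeps the bolus rank one and additive-only noise keeps
  # component 2 spectrally flat (multiplicative speckle would create a
  # genuine bolus-envelope mode with concentrated low-frequency power)
  sim <- simulate_dceus(
    small_phantom(resp_amplitude = 0, flow = FALSE,
                  noise = noise_params(speckle_sigma = 0,
                                       additive_sigma = 2)),
    static_phases = character(0))
  pca <- pca_decompose(flatten_sequence(sim$moving), 4)
  expect_warning(extract_respiratory_curve(pca), "no respiratory component")
})

test_that("zero-phase smoothing preserves DC and attenuates as a sinc", {
  y <- rnorm(50)
  sm1 <- smooth_curve(make_curve(y, 10), 1)
  expect_identical(sm1$r, y)
  expect_true(sm1$smoothed)
  cst <- smooth_curve(make_curve(rep(3.5, 40), 10), 7)
  expect_equal(cst$r, rep(3.5, 40))
  # window = period/10: closed-form moving-average gain at the tone
  fs <- 100; f <- 1; w <- 11
  t <- (0:4999) / fs
  sm <- smooth_curve(make_curve(sin(2 * pi * f * t), fs), w)
  gain <- sin(pi * f * w / fs) / (w * sin(pi * f / fs))
  interior <- 500:4500
  amp <- max(abs(sm$r[interior]))
  expect_equal(amp, gain, tolerance = 0.02 * gain)
  expect_error(smooth_curve(make_curve(rnorm(10), 1), 4), "odd")
})

test_that("dominant-frequency estimation hits known tones", {
  t <- seq(0, 120, by = 1 / 21.3); t <- t[-length(t)]
  c1 <- estimate_dominant_frequency(make_curve(sin(2 * pi * 0.27 * t), 21.3))
  expect_lt(abs(c1$dominant_frequency - 0.27), 0.005)
  t2 <- seq(0, 60, by = 0.1); t2 <- t2[-length(t2)]
  c2 <- estimate_dominant_frequency(make_curve(sin(2 * pi * 0.5 * t2), 10))
  expect_lt(abs(c2$dominant_frequency - 0.5), 0.01)
  # the stronger of two tones wins
  y <- 2 * sin(2 * pi * 0.2 * t2) + sin(2 * pi * 0.4 * t2)
  c3 <- estimate_dominant_frequency(make_curve(y, 10))
  expect_lt(abs(c3$dominant_frequency - 0.2), 0.01)
  expect_error(estimate_dominant_frequency(make_curve(rep(0, 64), 10)),
               "all-zero")
})

test_that("derivative zero-crossing detection finds alternating extrema", {
  fs <- 20; t <- seq(0, 10 - 1e-9, by = 1 / fs)
  curve <- make_curve(sin(2 * pi * t), fs, smoothed = TRUE)
  det <- detect_phases(curve, min_separation = 10)
  expect_equal(length(det$eoi_frames), 10L)
  expect_equal(length(det$eoe_frames), 10L)
  # detections at the analytic extrema (+-1 frame)
  expect_true(all(abs(det$eoi_frames - (seq(0.25, 9.25, 1) * fs + 1)) <= 1))
  expect_true(all(abs(det$eoe_frames - (seq(0.75, 9.75, 1) * fs + 1)) <= 1))
  merged <- sort(c(det$eoi_frames, det$eoe_frames))
  expect_true(all(diff(merged %in% det$eoi_frames) != 0))
  # plateaus collapse to their midpoint
  plat <- make_curve(c(0:5, rep(5, 5), 5:0, 0:4), 1, smoothed = TRUE)
  d2 <- detect_phases(plat, min_separation = 3)
  expect_equal(d2$eoi_frames[1], 9L)  # middle of the 7-sample plateau
  # degenerate inputs
  expect_error(detect_phases(make_curve(1:50, 1, smoothed = TRUE), 5),
               "fewer than one full cycle")
  expect_error(detect_phases(make_curve(sin(1:50), 1, smoothed = FALSE), 5),
               "smoothed")
})

test_that("gating selects exactly the detected frames with timestamps", {
  frames <- array(runif(3 * 3 * 30), c(3, 3, 30))
  s <- dceus_sequence(frames, frame_rate = 10)
  det <- structure(list(eoi_frames = c(6L, 16L, 26L),
                        eoe_frames = c(11L, 21L), n_cycles = 2L),
                   class = "phase_detection")
  g <- gate_sequence(s, det, "eoi")
  expect_equal(g$timestamps, c(0.5, 1.5, 2.5))
  expect_identical(g$frames, frames[, , c(6, 16, 26)])
  g2 <- gate_sequence(s, det, "eoe")
  expect_length(intersect(g$source_indices, g2$source_indices), 0)
  det$eoe_frames <- integer(0)
  expect_error(gate_sequence(s, det, "eoe"), "empty")
})

test_that("phantom gating matches the analytic extrema", {
  sim <- simulate_dceus(small_phantom(), static_phases = character(0))
  pca <- pca_decompose(flatten_sequence(sim$moving), 4)
  curve <- estimate_dominant_frequency(extract_respiratory_curve(pca))
  det <- detect_phases(smooth_curve(curve, 5))
  det <- dmfpi:::orient_phases(det, sim$truth)
  n_cyc <- floor(40 * 0.5)
  expect_lte(abs(length(det$eoi_frames) - n_cyc), 2)
  hits <- vapply(det$eoi_frames, function(k)
    min(abs(sim$truth$eoi_frames - k)), numeric(1))
  expect_gte(mean(hits <= 1), 0.9)
})
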