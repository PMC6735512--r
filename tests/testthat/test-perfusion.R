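triangle_tic <- function() {
  t <- 0:30
  y <- ifelse(t <= 10, 10 * t, 100 - 5 * (t - 10))
  make_tic(y, t)
}

test_that("triangle TIC recovers the closed-form parameters exactly", {
  pp <- estimate_perfusion_params(triangle_tic(), arrival_fraction = 0.10)
  expect_true(pp$defined)
  expect_equal(pp$PV, 100)
  expect_equal(pp$t_arrival, 1)
  expect_equal(pp$t_peak, 10)
  expect_equal(pp$WIT, 9)
  expect_equal(pp$WOT, 18)
  expect_true(pp$washout_complete)
  expect_equal(pp$WIR, 100 / 9)
  expect_equal(pp$WOR, 100 / 18)
  # trapezoid oracle over [1, 28]: analytic area of the sampled
  # piecewise-linear curve
  expect_equal(pp$AUC, 495 + 990)
})

test_that("estimation is offset-invariant and intensity-linear", {
  base <- estimate_perfusion_params(triangle_tic())
  t <- 0:30
  y <- ifelse(t <= 10, 10 * t, 100 - 5 * (t - 10))
  shifted <- estimate_perfusion_params(make_tic(y + 40, t))
  expect_equal(shifted$PV, base$PV)
  expect_equal(shifted$WIT, base$WIT)
  expect_equal(shifted$WOT, base$WOT)
  expect_equal(shifted$AUC, base$AUC)
  scaled <- estimate_perfusion_params(make_tic(3 * y, t))
  expect_equal(scaled$PV, 3 * base$PV)
  expect_equal(scaled$AUC, 3 * base$AUC)
  expect_equal(scaled$WIR, 3 * base$WIR)
  expect_equal(scaled$WOR, 3 * base$WOR)
  expect_equal(scaled$WIT, base$WIT)
  expect_equal(scaled$WOT, base$WOT)
})

test_that("degenerate TICs are flagged undefined, not NaN", {
  flat <- estimate_perfusion_params(make_tic(rep(5, 10)))
  expect_false(flat$defined)
  expect_false(anyNA(unlist(flat)))
  expect_error(estimate_perfusion_params(make_tic(1:3)), "5 samples")
  expect_error(estimate_perfusion_params(tic(1:10, 0:9)), "filtered")
  # incomplete washout is truncated at acquisition end and flagged
  t <- 0:20
  inc <- estimate_perfusion_params(make_tic(c(rep(0, 5), seq(0, 100, 20),
                                              rep(95, 10)), t))
  expect_false(inc$washout_complete)
  expect_equal(inc$WOT, 20 - inc$t_peak)
})

test_that("noise-free phantom lumen maps recover the analytic truth", {
  cfg <- small_phantom(noise = no_noise())
  sim <- simulate_dceus(cfg, static_phases = "eoi")
  g <- extract_tic_grid(sim$truth$static_eoi, 3)
  maps <- build_parameter_maps(g, dwma_window = 1)
  truth <- sim$truth$true_param_maps$eoi
  msk <- sim$truth$lumen_mask$eoi
  # grid cells fully inside the lumen
  cell_full <- extract_tic_grid(
    dceus_sequence(array(msk, c(dim(msk), 2)) + 0, 1), 3)$intensity[, , 1] == 1
  frame_dt <- 1 / cfg$frame_rate
  truth_cell <- function(m) extract_tic_grid(
    dceus_sequence(array(m, c(dim(m), 2)), 1), 3)$intensity[, , 1]
  pv_t <- truth_cell(truth$PV); wit_t <- truth_cell(truth$WIT)
  tp_t <- truth_cell(truth$t_peak)
  expect_gt(sum(cell_full), 10)
  # the truth map is per-pixel; averaging a curved radial profile over a
  # 3x3 cell biases the cell's own peak slightly below the pixel mean
  expect_lt(max(abs(maps$PV$values[cell_full] / pv_t[cell_full] - 1)), 0.03)
  expect_lt(max(abs(maps$WIT$values[cell_full] - wit_t[cell_full])),
            2 * frame_dt + 0.02 * max(wit_t))
  tp_est <- vapply(seq_len(nrow(pv_t)), function(i)
    vapply(seq_len(ncol(pv_t)), function(j)
      estimate_perfusion_params(dwma_filter(grid_tic(g, i, j), 1))$t_peak,
      numeric(1)), numeric(ncol(pv_t)))
  tp_est <- t(tp_est)
  expect_lt(max(abs(tp_est[cell_full] - tp_t[cell_full])), 2 * frame_dt)
})

test_that("map building records validity and keeps the grid shape", {
  cst <- dceus_sequence(array(6, c(9, 9, 8)), 2)
  maps <- build_parameter_maps(extract_tic_grid(cst, 3))
  expect_equal(dim(maps$WIT$values), c(3L, 3L))
  expect_false(any(maps$WIT$mask))
  expect_true(all(maps$WIT$values == 0))
  # phantom: lumen cells defined, background cells not (noise-free)
  cfg <- small_phantom(noise = no_noise())
  sim <- simulate_dceus(cfg, static_phases = "eoi")
  m <- build_parameter_maps(extract_tic_grid(sim$truth$static_eoi, 3),
                            dwma_window = 1)
  msk <- sim$truth$lumen_mask$eoi
  lumen_cells <- extract_tic_grid(
    dceus_sequence(array(msk, c(dim(msk), 2)) + 0, 1), 3)$intensity[, , 1] == 1
  corner_cells <- matrix(FALSE, nrow(m$PV$mask), ncol(m$PV$mask))
  corner_cells[1:2, 1:2] <- TRUE
  expect_true(all(m$PV$mask[lumen_cells]))
  expect_false(any(m$PV$mask[corner_cells]))
})

test_that("perfusion region keeps enhancing cells only", {
  sim <- simulate_dceus(small_phantom(), static_phases = "eoi")
  maps <- build_parameter_maps(extract_tic_grid(sim$truth$static_eoi, 3))
  reg <- perfusion_region(maps)
  msk <- sim$truth$lumen_mask$eoi
  lumen_cells <- extract_tic_grid(
    dceus_sequence(array(msk, c(dim(msk), 2)) + 0, 1), 3)$intensity[, , 1] == 1
  expect_gt(mean(reg$PV$mask[lumen_cells]), 0.9)
  corner <- reg$PV$mask[1:2, ]
  expect_false(any(corner))
  expect_true(all(vapply(reg, function(m) identical(m$mask, reg$PV$mask),
                         logical(1))))
})

test_that("shared-range normalization follows the 256-level rule", {
  a <- make_map(matrix(seq(0, 1, length.out = 16), 4))
  b <- make_map(matrix(seq(0, 2, length.out = 16), 4))
  nm <- normalize_shared_range(list(a, b))
  expect_equal(nm[[1]]$dynamic_range, c(0, 2))
  # value 1 encodes to level 127 or 128 under round(255 * 0.5)
  lev1 <- nm[[1]]$normalized[4, 4]
  expect_true(lev1 %in% c(127L, 128L))
  expect_equal(nm[[2]]$normalized[4, 4], 255L)
  # identical maps encode identically; a single map uses its own range
  nm2 <- normalize_shared_range(list(a, a))
  expect_identical(nm2[[1]]$normalized, nm2[[2]]$normalized)
  single <- normalize_shared_range(a)[[1]]
  expect_equal(single$dynamic_range, c(0, 1))
  expect_error(normalize_shared_range(list(a, make_map(matrix(1, 2, 2),
                                                       parameter = "WIT"))),
               "mix")
})

test_that("RGB encoding uses the lookup table and blacks out invalid cells", {
  lut <- dmfpi_lut()
  expect_equal(dim(lut), c(256L, 3L))
  expect_equal(nrow(unique(lut)), 256L)            # injective
  expect_true(all(lut >= 0 & lut <= 255))
  m <- make_map(matrix(0, 3, 3))
  m$mask[1, 1] <- FALSE
  m <- normalize_shared_range(m)[[1]]
  enc <- encode_rgb(m)
  expect_true(all(enc$rgb[1, 1, ] == 0))           # invalid cell black
  expect_equal(enc$rgb[2, 2, ], unname(lut[1, ]))  # level 0 colour
  # an identity-gray lut reproduces the normalized levels
  gray <- cbind(0:255, 0:255, 0:255)
  v <- make_map(matrix(seq(3, 9, length.out = 9), 3))
  v <- normalize_shared_range(v)[[1]]
  gv <- encode_rgb(v, gray)
  expect_equal(gv$rgb[, , 1], v$normalized + 0)
  # lut inversion recovers the levels exactly
  enc2 <- encode_rgb(v)
  key <- paste(lut[, 1], lut[, 2], lut[, 3])
  dec <- matrix(match(paste(enc2$rgb[, , 1], enc2$rgb[, , 2],
                            enc2$rgb[, , 3]), key) - 1L, 3, 3)
  expect_identical(dec, v$normalized)
  expect_error(encode_rgb(v, lut[1:100, ]), "256")
  # upsampling replicates pixels
  up <- encode_rgb(v, upsample = 2L)
  expect_equal(dim(up$rgb)[1:2], c(6L, 6L))
  expect_equal(up$rgb[1, 1, ], up$rgb[2, 2, ])
})
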