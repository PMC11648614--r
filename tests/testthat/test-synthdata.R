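# Synthetic-data generator: adsorption kinetics, cap geometry, ground truth.

test_that("adsorption trace follows first-order kinetics in both limits", {
  t <- seq(0, 100, 10)
  expect_equal(simulate_adsorption_trace(adsorption_params(0, 0.01, 0.05), t),
               rep(0, length(t)))
  # linear limit: k_on*l = 0.01 A.U./(nM s), c_b = 100 nM, t = 30 s
  lin <- adsorption_params(c_b = 100, k_on = 0.01, k_off = 0)
  expect_equal(simulate_adsorption_trace(lin, 30), 30)
  # rate of accumulation proportional to bulk concentration
  sat1 <- simulate_adsorption_trace(adsorption_params(100, 0.01, 0.02), t)
  sat2 <- simulate_adsorption_trace(adsorption_params(200, 0.01, 0.02), t)
  expect_equal(sat2[-1] / sat1[-1], rep(2, length(t) - 1))
  expect_equal(sat1[1], 0)
  expect_true(all(diff(sat1) > 0))
  # saturating form approaches k_on c_b l / k_off
  expect_equal(simulate_adsorption_trace(adsorption_params(100, 0.01, 0.02),
                                         1e6), 50)
})

test_that("adsorption parameter validation rejects negative rates", {
  expect_error(adsorption_params(-1, 0.01), ">=")
  expect_error(adsorption_params(100, 0.01, -0.1), ">=")
  lin <- adsorption_params(100, 0.01)
  expect_error(simulate_adsorption_trace(lin, c(5, 3)), "non-decreasing")
  expect_error(simulate_adsorption_trace(lin, c(-1, 3)), "after 0")
})

test_that("cap volume matches 2-D quadrature of the height field", {
  for (case in list(c(a = 0.8, th = 55), c(a = 0.3, th = 90))) {
    a <- case["a"]
    th <- case["th"] * pi / 180
    R <- a / sin(th)
    h0 <- R * cos(th)
    g <- seq(-a, a, length.out = 801)
    d2 <- outer(g^2, g^2, "+")
    h <- sqrt(pmax(R^2 - d2, 0)) - h0
    h[d2 > a^2 | h < 0] <- 0
    v_quad <- sum(h) * (g[2] - g[1])^2
    expect_equal(spherical_cap_volume(a, case["th"]), v_quad,
                 tolerance = 1e-3, ignore_attr = TRUE)
  }
})

test_that("rendered caps integrate to peak_density x cap volume", {
  geom <- condensate_geometry(contact_angle = 55, peak_density = 1000)
  fld <- render_condensate_field(geom, 0.8, image_shape = c(64L, 64L),
                                 pixel_size = 0.05,
                                 centers = cbind(1.6, 1.6))
  expect_equal(fld$table$intensity_au,
               1000 * spherical_cap_volume(0.8, 55), tolerance = 0.01)
  expect_equal(sum(fld$image), fld$table$intensity_au)
})

test_that("fixed contact angle gives V ratio 8 when area ratio is 4", {
  geom <- condensate_geometry(contact_angle = 60, peak_density = 500)
  fld <- render_condensate_field(geom, c(0.4, 0.8),
                                 image_shape = c(96L, 96L), pixel_size = 0.05,
                                 centers = rbind(c(1.2, 1.2), c(3.4, 3.4)))
  expect_equal(fld$table$area_um2[2] / fld$table$area_um2[1], 4)
  expect_equal(fld$table$intensity_au[2] / fld$table$intensity_au[1], 8,
               tolerance = 0.01)
})

test_that("empty and over-crowded condensate fields are handled", {
  geom <- condensate_geometry()
  fld <- render_condensate_field(geom, numeric(0), image_shape = c(32L, 32L))
  expect_equal(sum(fld$image), 0)
  expect_equal(nrow(fld$table), 0)
  expect_error(render_condensate_field(geom, rep(1.0, 50),
                                       image_shape = c(64L, 64L),
                                       pixel_size = 0.1, rng_seed = 1),
               "crowded|too large")
})

test_that("same seed reproduces the stack bit for bit", {
  s1 <- small_sim(seed = 9)
  s2 <- small_sim(seed = 9)
  expect_identical(s1$series$frames, s2$series$frames)
  expect_identical(s1$truth$birth_log, s2$truth$birth_log)
  s3 <- small_sim(seed = 10)
  expect_false(identical(s1$series$frames, s3$series$frames))
})

test_that("noise-free pre-nucleation frames equal baseline + adsorption trace", {
  sim <- generate_timelapse(
    simulation_config(seed = 2, image_shape = c(48L, 48L), n_frames = 12,
                      noise_sd = 0, noise_cv = 0, c_crit_surface = Inf),
    adsorption_params(c_b = 100, k_on = 0.005))
  mt <- mean_intensity_trace(sim$series)
  tk <- sim$series$times
  expected <- 80 + simulate_adsorption_trace(
    adsorption_params(100, 0.005), tk)
  expect_equal(mt, expected)
  expect_true(all(diff(mt) >= 0))
  expect_equal(nrow(sim$truth$birth_log), 0)
  expect_identical(sim$truth$true_t_nucleation, Inf)
})

test_that("doubling bulk concentration halves the true nucleation time", {
  s1 <- small_sim(seed = 4, c_b = 125)
  s2 <- small_sim(seed = 4, c_b = 250)
  expect_equal(s1$truth$true_t_nucleation / 2, s2$truth$true_t_nucleation)
})

test_that("ground-truth nucleation is the first crossing of c_crit", {
  sim <- small_sim(seed = 5)
  tk <- sim$series$times
  layer <- simulate_adsorption_trace(adsorption_params(250, 0.005), tk)
  t_nuc <- sim$truth$true_t_nucleation
  expect_true(all(layer[tk < t_nuc] < sim$truth$true_c_crit))
  expect_true(all(sim$truth$birth_log$time >= t_nuc))
})

test_that("dissolution shrinks every condensate to zero by the reversal time", {
  sim <- generate_timelapse(
    simulation_config(seed = 6, image_shape = c(96L, 96L), n_frames = 44,
                      dissolution_start = 120),
    adsorption_params(c_b = 250, k_on = 0.005))
  expect_true(is.finite(sim$truth$true_t_reversal))
  expect_gt(sim$truth$true_t_reversal, 120)
  # frames after full dissolution hold no segmentable condensates
  last <- sim$series$frames[, , n_frames(sim$series)]
  expect_equal(max(segment_condensates(last)), 0)
  # whereas the no-dissolution twin keeps them
  sim2 <- generate_timelapse(
    simulation_config(seed = 6, image_shape = c(96L, 96L), n_frames = 44),
    adsorption_params(c_b = 250, k_on = 0.005))
  last2 <- sim2$series$frames[, , n_frames(sim2$series)]
  expect_gt(max(segment_condensates(last2)), 10)
})

test_that("stack round-trips through TIFF + JSON sidecar", {
  sim <- generate_timelapse(
    simulation_config(seed = 3, image_shape = c(32L, 32L), n_frames = 6),
    adsorption_params(c_b = 250, k_on = 0.005))
  dir <- withr::local_tempdir()
  write_acquisition_series(sim$series, dir)
  back <- read_acquisition_series(dir)
  expect_equal(back$times, sim$series$times)
  expect_equal(back$c_b, 250)
  # 16-bit quantisation: relative error bounded by scale / 2^16
  expect_equal(back$frames, sim$series$frames,
               tolerance = 1 / 2^15)
})
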