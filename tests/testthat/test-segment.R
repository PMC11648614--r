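# Segmentation, condensate tables and the layer index.

test_that("uniform frame segments to zero condensates", {
  frame <- matrix(100, 64, 64)
  expect_equal(max(segment_condensates(frame)), 0)
  set.seed(1)
  noisy <- matrix(rnorm(64 * 64, 100, 3), 64, 64)
  expect_equal(max(segment_condensates(noisy)), 0)
})

test_that("disjoint supra-threshold disks are labelled one-to-one", {
  df <- disk_frame(n_disks = 7)
  mask <- segment_condensates(df$frame)
  expect_equal(max(mask), 7)
  tab <- tabulate_condensates(df$frame, mask, pixel_size = 1,
                              background_level = 100)
  # centroids within 1 px of the disk centers (um = px here)
  got <- tab[order(tab$y_um, tab$x_um), ]
  want <- df$centers[order(df$centers$row, df$centers$col), ]
  expect_true(all(abs(got$y_um - (want$row - 1)) < 1))
  expect_true(all(abs(got$x_um - (want$col - 1)) < 1))
})

test_that("frames before nucleation hold no condensates at default noise", {
  sim <- small_sim(seed = 11)
  pre <- which(sim$series$times < sim$truth$true_t_nucleation)
  f <- sim$series$frames[, , pre[length(pre)]]
  expect_equal(max(segment_condensates(f)), 0)
})

test_that("condensate table arithmetic is exact on a constructed label", {
  frame <- matrix(7, 20, 20)   # background 7
  frame[3:12, 5:14] <- 12      # 100-px square at background + 5
  mask <- segment_condensates(frame, background_level = 7, k_sigma = 0.5)
  expect_equal(max(mask), 1)
  tab <- tabulate_condensates(frame, mask, pixel_size = 0.1,
                              background_level = 7)
  expect_equal(tab$area_um2, 1.0)
  expect_equal(tab$intensity_au, 500)
  expect_equal(tab$r_eq_um, sqrt(1 / pi), tolerance = 1e-12)
  expect_equal(tab$r_eq_um, 0.564, tolerance = 1e-3)
  # background above all pixels clamps V at zero
  tab2 <- tabulate_condensates(frame, mask, pixel_size = 0.1,
                               background_level = 1000)
  expect_equal(tab2$intensity_au, 0)
})

test_that("segmented cap intensity matches the generator's truth", {
  geom <- condensate_geometry(contact_angle = 60, peak_density = 2000)
  fld <- render_condensate_field(geom, 0.9, image_shape = c(64L, 64L),
                                 pixel_size = 0.05,
                                 centers = cbind(1.6, 1.6))
  mask <- segment_condensates(fld$image + 1, background_level = 1,
                              k_sigma = 0)
  tab <- tabulate_condensates(fld$image + 1, mask, pixel_size = 0.05,
                              background_level = 1)
  expect_equal(max(mask), 1)
  expect_equal(tab$intensity_au, fld$table$intensity_au, tolerance = 0.05)
  expect_equal(tab$intensity_au,
               2000 * spherical_cap_volume(0.9, 60), tolerance = 0.05)
})

test_that("auto background is shift-stable for segmentation", {
  df <- disk_frame(n_disks = 5, bg = 120, bg_sd = 4, amp = 100)
  m1 <- segment_condensates(df$frame)
  m2 <- segment_condensates(df$frame + 37)
  expect_identical(unclass(m1) > 0, unclass(m2) > 0)
})

test_that("number density trace is counts over area", {
  sim <- small_sim(seed = 12)
  counts <- c(0L, 0L, 3L, 8L, 10L)
  masks <- lapply(counts, function(k) {
    m <- matrix(0L, 4, 4)
    if (k > 0) m[seq_len(k)] <- seq_len(k)
    m
  })
  series <- acquisition_series(array(0, c(4, 4, 5)), times = (0:4) * 5,
                               pixel_size = 1)
  tr <- number_density_trace(series, masks, field_area = 100)
  expect_equal(tr$density, c(0, 0, 0.03, 0.08, 0.10))
  # all-empty masks give an all-zero trace
  tr0 <- number_density_trace(series, lapply(1:5, function(i) matrix(0L, 4, 4)),
                              field_area = 100)
  expect_equal(tr0$density, rep(0, 5))
})

test_that("final condensate count matches the ground-truth birth log", {
  sim <- small_sim(seed = 13)
  masks <- segment_series(sim$series)
  tr <- number_density_trace(sim$series, masks)
  expect_equal(tr$count[length(tr$count)], nrow(sim$truth$birth_log))
})

test_that("layer index hits the exact monolayer and cap limits", {
  area <- exp(seq(log(0.2), log(2), length.out = 30))
  mono <- data.frame(area_um2 = area, intensity_au = 350 * area)
  expect_equal(suppressWarnings(layer_index(mono))$alpha, 1.0, tolerance = 1e-10)
  caps <- data.frame(area_um2 = area, intensity_au = 120 * area^1.5)
  expect_equal(suppressWarnings(layer_index(caps))$alpha, 1.5, tolerance = 1e-10)
})

test_that("layer index is scale-invariant and guards degenerate input", {
  area <- exp(seq(log(0.2), log(2), length.out = 25))
  set.seed(3)
  tab <- data.frame(area_um2 = area,
                    intensity_au = 90 * area^1.3 * exp(rnorm(25, 0, 0.05)))
  a1 <- layer_index(tab)$alpha
  tab2 <- data.frame(area_um2 = 10 * tab$area_um2,
                     intensity_au = 10^1.3 * tab$intensity_au)
  expect_equal(layer_index(tab2)$alpha, a1, tolerance = 1e-10)
  expect_error(layer_index(tab[1:2, ]), "at least 3")
  flat <- data.frame(area_um2 = rep(1, 5), intensity_au = 1:5)
  expect_error(layer_index(flat), "variation")
  # non-positive intensities are excluded and counted
  tab3 <- rbind(tab, data.frame(area_um2 = 1, intensity_au = 0))
  fit <- layer_index(tab3)
  expect_equal(fit$n_excluded, 1)
  expect_equal(fit$n_condensates, 25)
})

test_that("rendered cap field recovers alpha = 1.5 over a decade of radii", {
  radii <- exp(seq(log(0.15), log(1.5), length.out = 36))
  geom <- condensate_geometry(contact_angle = 60, peak_density = 1000)
  fld <- render_condensate_field(geom, radii, image_shape = c(300L, 300L),
                                 pixel_size = 0.1, rng_seed = 21)
  fit <- layer_index(fld$table)
  expect_equal(fit$alpha, 1.5, tolerance = 0.05 / 1.5)
  expect_lt(abs(fit$alpha - 1.5), 2 * max(fit$alpha_se, 0.01))
})

test_that("summed condensate intensity never exceeds the frame total", {
  sim <- small_sim(seed = 14)
  f <- sim$series$frames[, , n_frames(sim$series)]
  mask <- segment_condensates(f)
  bg <- attr(mask, "background")
  tab <- tabulate_condensates(f, mask, pixel_size = 0.1)
  expect_lte(sum(tab$intensity_au), sum(pmax(f - bg, 0)))
})
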