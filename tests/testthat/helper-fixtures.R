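# Shared fixtures built in code.

# A compact acquisition for unit tests: same physics as the default study
# conditions, smaller field and shorter horizon so single-stack checks stay
# fast. Bulk 250 nM nucleates at 80 s here.
small_sim <- function(seed = 1, c_b = 250, ...) {
  generate_timelapse(
    simulation_config(seed = seed, image_shape = c(96L, 96L), n_frames = 36,
                      ...),
    adsorption_params(c_b = c_b, k_on = 0.005))
}

# Frame with disjoint supra-threshold disks on a noisy background; returns
# the frame and the disk centers (px).
disk_frame <- function(n_disks = 7, shape = c(128L, 128L), r_px = 5,
                       bg = 100, bg_sd = 3, amp = 80, seed = 42) {
  set.seed(seed)
  frame <- matrix(stats::rnorm(prod(shape), bg, bg_sd), shape[1], shape[2])
  # centers on a jittered grid so disks never touch
  k <- ceiling(sqrt(n_disks))
  step <- floor(min(shape) / (k + 1))
  pos <- expand.grid(row = step * seq_len(k), col = step * seq_len(k))
  pos <- pos[seq_len(n_disks), ]
  for (i in seq_len(n_disks)) {
    rows <- pmax(1, pos$row[i] - r_px):pmin(shape[1], pos$row[i] + r_px)
    cols <- pmax(1, pos$col[i] - r_px):pmin(shape[2], pos$col[i] + r_px)
    d2 <- outer((rows - pos$row[i])^2, (cols - pos$col[i])^2, "+")
    frame[rows, cols] <- frame[rows, cols] + amp * (d2 <= r_px^2)
  }
  list(frame = frame, centers = pos)
}

# Histogram object straight from a vector of log-intensity draws.
hist_from_draws <- function(x, n_bins = 100) {
  rng <- range(x)
  edges <- seq(rng[1] - 1e-9, rng[2] + 1e-9, length.out = n_bins + 1)
  m <- matrix(exp(x), nrow = 1)
  log_intensity_histogram(m, edges, floor_eps = 1e-12)
}
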