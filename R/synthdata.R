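# Synthetic time-lapse generator --------------------------------------------
#
# Emulates the imaging experiment the detectors are built for: a protein
# solution at bulk concentration c_b is exposed to a supported lipid bilayer
# at t = 0; molecules adsorb with first-order kinetics so the mean surface
# intensity rises; once the (noise-free) adsorbed-layer intensity crosses a
# critical surface concentration, condensates nucleate and grow as spherical
# caps of fixed contact angle; optionally a late dissolution phase shrinks
# every condensate back to nothing. Stacks come with full ground truth so
# detector accuracy can be scored exactly.

#' First-order adsorption parameters
#'
#' Parameters of Langmuir-type surface binding. The adsorbed-layer intensity
#' follows \eqn{c_s(t) = (k_{on} c_b l / k_{off}) (1 - e^{-k_{off} t})}, with
#' the linear limit \eqn{c_s(t) = k_{on} c_b l \, t} when `k_off = 0`. The
#' early-time accumulation rate is proportional to the bulk concentration in
#' either form.
#'
#' @param c_b bulk concentration (nM).
#' @param k_on association rate constant (A.U. per nM per second, lumped with
#'   the conversion length `l` into the gain `k_on * c_b * l`).
#' @param k_off dissociation rate constant (per second); `0` selects the
#'   unsaturated linear limit.
#' @param l bulk-to-surface conversion length (um); kept as an explicit
#'   factor so the symbols match the kinetic model, but only the product
#'   `k_on * l` is identifiable.
#' @return An object of class `adsorption_params`.
#' @export
adsorption_params <- function(c_b, k_on, k_off = 0, l = 1) {
  .assert_scalar_num(c_b, "c_b", min = 0)
  .assert_scalar_num(k_on, "k_on", min = 0)
  .assert_scalar_num(k_off, "k_off", min = 0)
  .assert_scalar_num(l, "l", min = 0)
  structure(list(c_b = c_b, k_on = k_on, k_off = k_off, l = l),
            class = "adsorption_params")
}

#' Simulate a noise-free adsorbed-layer intensity trace
#'
#' @param params an [adsorption_params()] object.
#' @param t_grid non-decreasing vector of times (s), starting at or after 0.
#' @return Numeric vector of surface intensities (A.U.), one per time point;
#'   zero at `t = 0` and non-decreasing.
#' @examples
#' p <- adsorption_params(c_b = 100, k_on = 0.01)
#' simulate_adsorption_trace(p, c(0, 10, 20, 30))
#' @export
simulate_adsorption_trace <- function(params, t_grid) {
  if (!inherits(params, "adsorption_params"))
    stop("'params' must be an adsorption_params object")
  if (!is.numeric(t_grid) || length(t_grid) == 0L)
    stop("'t_grid' must be a non-empty numeric vector")
  if (any(t_grid < 0)) stop("'t_grid' must start at or after 0")
  if (is.unsorted(t_grid)) stop("'t_grid' must be non-decreasing")
  gain <- params$k_on * params$c_b * params$l
  if (params$k_off > 0) {
    (gain / params$k_off) * (1 - exp(-params$k_off * t_grid))
  } else {
    gain * t_grid
  }
}

# time at which the noise-free layer crosses `level`; Inf if never
.adsorption_crossing_time <- function(params, level) {
  gain <- params$k_on * params$c_b * params$l
  if (!is.finite(level)) return(Inf)
  if (level <= 0) return(0)
  if (gain <= 0) return(Inf)
  if (params$k_off > 0) {
    plateau <- gain / params$k_off
    if (level >= plateau) return(Inf)
    -log(1 - level / plateau) / params$k_off
  } else {
    level / gain
  }
}

#' Spherical-cap condensate geometry
#'
#' Condensates are modelled as spherical caps sitting on the bilayer with a
#' fixed contact angle, so that cap volume scales with footprint area to the
#' power 3/2 — the multilayer limit of the layer index. The contact angle is
#' restricted to (0, 90] degrees: beyond 90 the cap overhangs its contact
#' line and the projected-column rendering used here no longer integrates to
#' the cap volume.
#'
#' @param contact_angle contact angle in degrees, in (0, 90].
#' @param peak_density condensed-phase intensity per unit volume
#'   (A.U. per um^3); a rendered pixel carries `peak_density` times the cap
#'   column volume above that pixel.
#' @param growth_rate footprint-radius growth speed after nucleation (um/s);
#'   growth is linear and capped at the condensate's mature radius.
#' @param r_max median mature footprint radius (um).
#' @param r_max_cv coefficient of variation of the per-condensate mature
#'   radius (log-normal around `r_max`, clamped to `[r_max/2, 2 r_max]`);
#'   real condensate populations have a broad size distribution, and the
#'   spread is what makes the layer-index fit on a single frame
#'   well-posed.
#' @return An object of class `condensate_geometry`.
#' @export
condensate_geometry <- function(contact_angle = 60, peak_density = 1e6,
                                growth_rate = 0.08, r_max = 0.35,
                                r_max_cv = 0.3) {
  .assert_scalar_num(contact_angle, "contact_angle")
  if (contact_angle <= 0 || contact_angle > 90)
    stop("'contact_angle' must be in (0, 90] degrees")
  .assert_scalar_num(peak_density, "peak_density", min = 0)
  .assert_scalar_num(growth_rate, "growth_rate", min = 0)
  .assert_scalar_num(r_max, "r_max", min = 0)
  .assert_scalar_num(r_max_cv, "r_max_cv", min = 0)
  structure(list(contact_angle = contact_angle, peak_density = peak_density,
                 growth_rate = growth_rate, r_max = r_max,
                 r_max_cv = r_max_cv),
            class = "condensate_geometry")
}

#' Volume of a spherical cap from its footprint radius
#'
#' Closed form \eqn{V = \pi a^3 (2 - 3\cos\theta + \cos^3\theta) /
#' (3 \sin^3\theta)} for contact angle \eqn{\theta} and footprint (contact
#' line) radius \eqn{a}. At fixed \eqn{\theta}, \eqn{V \propto a^3} while the
#' footprint area is \eqn{\pi a^2}, hence \eqn{V \propto A^{1.5}}.
#'
#' @param a footprint radius (um), vectorised.
#' @param contact_angle contact angle in degrees, in (0, 90].
#' @return Cap volume(s) in um^3.
#' @export
spherical_cap_volume <- function(a, contact_angle) {
  if (any(a < 0)) stop("footprint radius must be non-negative")
  th <- contact_angle * pi / 180
  pi * a^3 * (2 - 3 * cos(th) + cos(th)^3) / (3 * sin(th)^3)
}

# Render one cap into `img` (matrix, row i ~ y = (i-1)*px, col j ~ x).
# 4x4 supersampling per pixel; pixel value += density * column volume.
# Returns list(img, v = rendered integrated intensity of this cap).
.render_cap <- function(img, cx, cy, a, contact_angle, density, pixel_size) {
  th <- contact_angle * pi / 180
  R <- a / sin(th)
  h0 <- R * cos(th)
  px <- pixel_size
  i0 <- max(1L, floor((cy - a) / px) + 1L)
  i1 <- min(nrow(img), ceiling((cy + a) / px) + 1L)
  j0 <- max(1L, floor((cx - a) / px) + 1L)
  j1 <- min(ncol(img), ceiling((cx + a) / px) + 1L)
  if (i0 > i1 || j0 > j1) return(list(img = img, v = 0))
  off <- c(-3, -1, 1, 3) / 8 * px
  ii <- i0:i1
  jj <- j0:j1
  y <- (ii - 1) * px
  x <- (jj - 1) * px
  H <- matrix(0, length(ii), length(jj))
  for (oy in off) {
    dy2 <- (y + oy - cy)^2
    for (ox in off) {
      dx2 <- (x + ox - cx)^2
      d2 <- outer(dy2, dx2, "+")
      h <- sqrt(pmax(R^2 - d2, 0)) - h0
      h[d2 > a^2 | h < 0] <- 0
      H <- H + h
    }
  }
  patch <- density * (H / 16) * px^2
  img[ii, jj] <- img[ii, jj] + patch
  list(img = img, v = sum(patch))
}

# Place disks of given radii uniformly at random without overlap.
# Returns matrix of centers (x_um, y_um); errors if the field is too crowded.
.place_disks <- function(radii, field_um, margin, min_gap, max_tries = 500L) {
  n <- length(radii)
  cx <- numeric(n)
  cy <- numeric(n)
  ord <- order(radii, decreasing = TRUE) # large ones first: easier packing
  for (k in seq_len(n)) {
    i <- ord[k]
    r <- radii[i]
    lo <- r + margin
    hix <- field_um[1] - r - margin
    hiy <- field_um[2] - r - margin
    if (hix <= lo || hiy <= lo)
      stop("condensate radius too large for the field")
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      px <- stats::runif(1, lo, hix)
      py <- stats::runif(1, lo, hiy)
      if (k == 1L) {
        ok <- TRUE
      } else {
        prev <- ord[seq_len(k - 1L)]
        ok <- all((cx[prev] - px)^2 + (cy[prev] - py)^2 >
                    (radii[prev] + r + min_gap)^2)
      }
      if (ok) {
        cx[i] <- px
        cy[i] <- py
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("field too crowded: could not place all condensates without overlap")
  }
  cbind(x_um = cx, y_um = cy)
}

#' Render a field of spherical-cap condensates
#'
#' Places condensates of the given footprint radii uniformly at random
#' without overlap (rejection sampling) and renders each as the column
#' volume of a spherical cap, anti-aliased by 4x supersampling, so that a
#' condensate's rendered integrated intensity equals `peak_density` times
#' its cap volume up to pixel discretisation.
#'
#' @param geometry a [condensate_geometry()] object.
#' @param footprint_radii vector of footprint radii (um), all positive.
#' @param image_shape integer c(rows, cols) in pixels.
#' @param pixel_size pixel edge length (um).
#' @param centers optional n x 2 matrix of (x_um, y_um) centers; when given,
#'   placement sampling is skipped.
#' @param rng_seed optional integer seed for reproducible placement.
#' @return list with `image` (matrix, A.U.) and `table`, a data.frame of the
#'   ground truth per condensate: id, x_um, y_um, radius_um, area_um2
#'   (footprint pi a^2), intensity_au (rendered integrated intensity) and
#'   volume_um3 (closed-form cap volume).
#' @export
render_condensate_field <- function(geometry, footprint_radii,
                                    image_shape = c(256L, 256L),
                                    pixel_size = 0.1,
                                    centers = NULL, rng_seed = NULL) {
  if (!inherits(geometry, "condensate_geometry"))
    stop("'geometry' must be a condensate_geometry object")
  img <- matrix(0, image_shape[1], image_shape[2])
  n <- length(footprint_radii)
  if (n == 0L) {
    return(list(image = img,
                table = data.frame(id = integer(), x_um = numeric(),
                                   y_um = numeric(), radius_um = numeric(),
                                   area_um2 = numeric(),
                                   intensity_au = numeric(),
                                   volume_um3 = numeric())))
  }
  if (any(footprint_radii <= 0)) stop("footprint radii must be positive")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  field_um <- (image_shape - 1L) * pixel_size
  if (is.null(centers)) {
    centers <- .place_disks(footprint_radii, field_um,
                            margin = 0, min_gap = pixel_size)
  } else {
    centers <- as.matrix(centers)
    if (nrow(centers) != n) stop("'centers' must have one row per radius")
  }
  v <- numeric(n)
  for (i in seq_len(n)) {
    res <- .render_cap(img, centers[i, 1], centers[i, 2], footprint_radii[i],
                       geometry$contact_angle, geometry$peak_density,
                       pixel_size)
    img <- res$img
    v[i] <- res$v
  }
  list(image = img,
       table = data.frame(id = seq_len(n),
                          x_um = centers[, 1], y_um = centers[, 2],
                          radius_um = footprint_radii,
                          area_um2 = pi * footprint_radii^2,
                          intensity_au = v,
                          volume_um3 = spherical_cap_volume(
                            footprint_radii, geometry$contact_angle)))
}

#' Simulation configuration for a synthetic acquisition
#'
#' Defaults describe the study conditions the detectors are validated under:
#' a 12.8 x 12.8 um field imaged at 0.1 um/px every 5 s for 54 frames, a
#' critical surface concentration of 100 A.U., a finite density of
#' nucleation sites consumed with per-site rate `nucleation_rate` once the
#' adsorbed layer crosses the critical level, and mixed additive + shot +
#' multiplicative pixel noise on top of a constant camera baseline.
#'
#' @param frame_interval acquisition interval (s).
#' @param n_frames number of frames.
#' @param image_shape integer c(rows, cols) in pixels.
#' @param pixel_size pixel edge length (um).
#' @param baseline constant camera/background offset added to every pixel
#'   (A.U.).
#' @param noise_sd additive Gaussian read-noise sd (A.U.).
#' @param shot_gain optional shot-noise gain: adds variance
#'   `shot_gain * signal` (Gaussian approximation of Poisson noise);
#'   disabled by default because the multiplicative term dominates at the
#'   signal levels simulated here.
#' @param noise_cv coefficient of variation of the log-normal multiplicative
#'   (illumination / detector gain) noise, the dominant term: it keeps the
#'   log-intensity peak width roughly level-independent, as in real
#'   EMCCD/sCMOS data.
#' @param c_crit_surface critical surface concentration (A.U.) at which
#'   nucleation begins; `Inf` disables condensation.
#' @param site_density areal density of nucleation sites (per um^2).
#' @param nucleation_rate per-site nucleation rate above threshold (per s);
#'   the initial areal nucleation rate is `site_density * nucleation_rate`
#'   and decays as sites are consumed.
#' @param dissolution_start optional time (s, on the kinetics clock) after
#'   which all condensates shrink at `dissolution_rate`; `NULL` for none.
#' @param dissolution_rate radius shrink speed during dissolution (um/s).
#' @param acquisition_delay seconds of kinetics elapsed before frame 0 (the
#'   experimental delay between bulk addition and acquisition start).
#' @param seed integer; fully determines the stack.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(frame_interval = 5, n_frames = 54,
                              image_shape = c(128L, 128L), pixel_size = 0.1,
                              baseline = 80, noise_sd = 2, shot_gain = 0,
                              noise_cv = 0.15,
                              c_crit_surface = 100, site_density = 0.6,
                              nucleation_rate = 0.25,
                              dissolution_start = NULL,
                              dissolution_rate = 0.08,
                              acquisition_delay = 0, seed = 1L) {
  .assert_scalar_num(frame_interval, "frame_interval", min = 0)
  .assert_scalar_num(n_frames, "n_frames", min = 1)
  .assert_scalar_num(pixel_size, "pixel_size", min = 0)
  .assert_scalar_num(baseline, "baseline", min = 0)
  .assert_scalar_num(noise_sd, "noise_sd", min = 0)
  .assert_scalar_num(shot_gain, "shot_gain", min = 0)
  .assert_scalar_num(noise_cv, "noise_cv", min = 0)
  if (!is.numeric(c_crit_surface) || length(c_crit_surface) != 1L ||
      is.na(c_crit_surface) || c_crit_surface < 0)
    stop("'c_crit_surface' must be a non-negative number (Inf allowed)")
  .assert_scalar_num(site_density, "site_density", min = 0)
  .assert_scalar_num(nucleation_rate, "nucleation_rate", min = 0)
  if (!is.null(dissolution_start))
    .assert_scalar_num(dissolution_start, "dissolution_start", min = 0)
  .assert_scalar_num(dissolution_rate, "dissolution_rate", min = 0)
  .assert_scalar_num(acquisition_delay, "acquisition_delay", min = 0)
  .assert_scalar_num(seed, "seed")
  structure(list(frame_interval = frame_interval,
                 n_frames = as.integer(n_frames),
                 image_shape = as.integer(image_shape),
                 pixel_size = pixel_size, baseline = baseline,
                 noise_sd = noise_sd, shot_gain = shot_gain,
                 noise_cv = noise_cv, c_crit_surface = c_crit_surface,
                 site_density = site_density,
                 nucleation_rate = nucleation_rate,
                 dissolution_start = dissolution_start,
                 dissolution_rate = dissolution_rate,
                 acquisition_delay = acquisition_delay,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Construct an acquisition series
#'
#' The unit of analysis: a time-ordered stack of frames with frame interval,
#' pixel size and bulk-concentration metadata.
#'
#' @param frames numeric array of dimension (rows, cols, n_frames), A.U.
#' @param times frame times (s) on the acquisition clock (frame 0 at 0 s).
#' @param pixel_size pixel edge length (um).
#' @param c_b bulk concentration metadata (nM), or `NA`.
#' @param baseline camera/background offset metadata (A.U.).
#' @return An object of class `acquisition_series`.
#' @export
acquisition_series <- function(frames, times, pixel_size, c_b = NA_real_,
                               baseline = 0) {
  if (length(dim(frames)) != 3L)
    stop("'frames' must be a 3-d array (rows, cols, frames)")
  if (dim(frames)[3] != length(times))
    stop("one time per frame required")
  structure(list(frames = frames, times = as.numeric(times),
                 frame_interval = if (length(times) > 1L)
                   stats::median(diff(times)) else NA_real_,
                 pixel_size = pixel_size, c_b = c_b, baseline = baseline),
            class = "acquisition_series")
}

#' @export
print.acquisition_series <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("acquisition_series: %d frames of %d x %d px, dt = %g s, %g um/px",
              d[3], d[1], d[2], x$frame_interval, x$pixel_size))
  if (is.finite(x$c_b)) cat(sprintf(", c_b = %g nM", x$c_b))
  cat("\n")
  invisible(x)
}

#' Number of frames in an acquisition series
#' @param series an [acquisition_series()].
#' @return integer frame count.
#' @export
n_frames <- function(series) dim(series$frames)[3]

#' Mean pixel intensity per frame
#' @param series an [acquisition_series()].
#' @return numeric vector, one mean intensity (A.U.) per frame.
#' @export
mean_intensity_trace <- function(series) {
  apply(series$frames, 3, mean)
}

#' Generate a synthetic prewetting time-lapse with ground truth
#'
#' Each frame is the sum of the noise-free adsorbed-layer level at that
#' time, the camera baseline, every condensate born after the layer crossed
#' the critical surface concentration (rendered as spherical caps growing at
#' the geometry's rate), and pixel noise. With `dissolution_start` set, all
#' condensates shrink to zero afterwards, so late frames are unimodal again.
#' The first `acquisition_delay` seconds of kinetics are discarded: frame
#' times in the returned series start at 0 on the acquisition clock while
#' the ground-truth times are on the kinetics clock.
#'
#' @param config a [simulation_config()].
#' @param adsorption an [adsorption_params()].
#' @param geometry a [condensate_geometry()].
#' @return list with `series` (an [acquisition_series()]) and `truth`, a
#'   `synthetic_ground_truth` list carrying `true_t_nucleation` (s, kinetics
#'   clock; `Inf` if never), `true_c_crit`, `true_alpha` (1.5, the cap
#'   geometry law), `true_t_reversal` (s or `NA`, the extinction of the
#'   last condensate), `birth_log` (data.frame id, time, x_um, y_um,
#'   r_mature) and `seed`.
#' @export
generate_timelapse <- function(config = simulation_config(),
                               adsorption = adsorption_params(100, 0.005),
                               geometry = condensate_geometry()) {
  if (!inherits(config, "simulation_config"))
    stop("'config' must be a simulation_config object")
  if (!inherits(adsorption, "adsorption_params"))
    stop("'adsorption' must be an adsorption_params object")
  if (!inherits(geometry, "condensate_geometry"))
    stop("'geometry' must be a condensate_geometry object")
  set.seed(config$seed)
  dt <- config$frame_interval
  nT <- config$n_frames
  tk <- config$acquisition_delay + (seq_len(nT) - 1) * dt # kinetics clock
  layer <- simulate_adsorption_trace(adsorption, tk)
  t_nuc <- .adsorption_crossing_time(adsorption, config$c_crit_surface)

  shp <- config$image_shape
  field_um <- (shp - 1L) * config$pixel_size
  area_um2 <- prod(field_um)
  D <- config$dissolution_start

  # nucleation-site positions, birth times and mature cap radii
  births <- data.frame(id = integer(), time = numeric(),
                       x_um = numeric(), y_um = numeric(),
                       r_mature = numeric())
  if (is.finite(t_nuc) && t_nuc <= max(tk) &&
      config$site_density > 0 && config$nucleation_rate > 0) {
    n_sites <- round(config$site_density * area_um2)
    if (n_sites > 0) {
      sig_ln <- sqrt(log(1 + geometry$r_max_cv^2))
      r_mat <- geometry$r_max * exp(stats::rnorm(n_sites, 0, sig_ln))
      r_mat <- pmin(pmax(r_mat, geometry$r_max / 2), 2 * geometry$r_max)
      pos <- tryCatch(
        .place_disks(r_mat, field_um, margin = 0,
                     min_gap = config$pixel_size),
        error = function(e) stop("field too crowded for the requested ",
                                 "nucleation site density"))
      tb <- t_nuc + stats::rexp(n_sites, rate = config$nucleation_rate)
      keep <- tb <= max(tk) & (if (is.null(D)) TRUE else tb < D)
      if (any(keep)) {
        o <- order(tb[keep])
        births <- data.frame(id = seq_len(sum(keep)),
                             time = tb[keep][o],
                             x_um = pos[keep, 1][o],
                             y_um = pos[keep, 2][o],
                             r_mature = r_mat[keep][o])
      }
    }
  }

  g <- geometry$growth_rate
  gd <- config$dissolution_rate

  frames <- array(0, dim = c(shp[1], shp[2], nT))
  static_img <- matrix(0, shp[1], shp[2]) # cache of fully-grown condensates
  is_static <- rep(FALSE, nrow(births))
  npx <- prod(shp)
  for (f in seq_len(nT)) {
    t <- tk[f]
    sig <- matrix(config$baseline + layer[f], shp[1], shp[2])
    if (nrow(births) > 0) {
      if (is.null(D) || t <= D) {
        r <- pmin(g * pmax(t - births$time, 0), births$r_mature)
        mature <- r >= births$r_mature & !is_static
        for (i in which(mature)) {
          res <- .render_cap(static_img, births$x_um[i], births$y_um[i],
                             births$r_mature[i], geometry$contact_angle,
                             geometry$peak_density, config$pixel_size)
          static_img <- res$img
        }
        is_static <- is_static | mature
        sig <- sig + static_img
        for (i in which(!is_static & r > 0)) {
          res <- .render_cap(sig, births$x_um[i], births$y_um[i], r[i],
                             geometry$contact_angle, geometry$peak_density,
                             config$pixel_size)
          sig <- res$img
        }
      } else {
        r_at_D <- pmin(g * pmax(D - births$time, 0), births$r_mature)
        r <- pmax(r_at_D - gd * (t - D), 0)
        for (i in which(r > 0)) {
          res <- .render_cap(sig, births$x_um[i], births$y_um[i], r[i],
                             geometry$contact_angle, geometry$peak_density,
                             config$pixel_size)
          sig <- res$img
        }
      }
    }
    noisy <- sig * exp(config$noise_cv * stats::rnorm(npx)) +
      config$noise_sd * stats::rnorm(npx)
    if (config$shot_gain > 0)
      noisy <- noisy + sqrt(config$shot_gain * pmax(sig, 0)) *
        stats::rnorm(npx)
    frames[, , f] <- noisy
  }

  t_reversal <- NA_real_
  if (!is.null(D) && nrow(births) > 0 && gd > 0) {
    r_at_D <- pmin(g * pmax(D - births$time, 0), births$r_mature)
    t_reversal <- D + max(r_at_D) / gd
  }

  series <- acquisition_series(frames, times = tk - config$acquisition_delay,
                               pixel_size = config$pixel_size,
                               c_b = adsorption$c_b,
                               baseline = config$baseline)
  truth <- structure(list(true_t_nucleation = t_nuc,
                          true_c_crit = config$c_crit_surface,
                          true_alpha = 1.5,
                          true_t_reversal = t_reversal,
                          birth_log = births,
                          seed = config$seed),
                     class = "synthetic_ground_truth")
  list(series = series, truth = truth)
}
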