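#' Synthetic vessel geometry
#'
#' Builds a named vessel-tree preset inside a rectangular field of view.
#' Each vessel is a centerline polyline (depth z, lateral x, in micrometres),
#' a tube radius, and a Poiseuille peak velocity; flow runs along the
#' polyline in vertex order.
#'
#' Presets:
#' * `straight` -- one horizontal tube at mid depth.
#' * `sinusoid` -- one horizontal tube with sinusoidal meander.
#' * `semicircle` -- a half-circle arc of curve radius `r_curve_um`.
#' * `bifurcation` -- a parent vessel splitting into two daughters at a
#'   shared junction.
#' * `cortical_column` -- one descending (surface to depth: arteriole-like)
#'   and one ascending vessel, for directional-splitting tests.
#'
#' @param preset preset name (see above).
#' @param fov_um field of view `c(z, x)` in micrometres (default matches the
#'   default 128 x 128 grid at 19.712 um spacing).
#' @param radius_um tube radius in micrometres.
#' @param peak_velocity_mms Poiseuille centerline (peak) velocity in mm/s.
#' @param r_curve_um curve radius of the `semicircle` preset.
#' @param n_points centerline sampling density.
#' @return object of class `vessel_geometry`: list of vessels
#'   (`centerline` n x 2 matrix `(z_um, x_um)`, `radius_um`,
#'   `peak_velocity_mms`) plus the field of view.
#' @export
make_vessel_tree <- function(preset = c("straight", "sinusoid", "semicircle",
                                        "bifurcation", "cortical_column"),
                             fov_um = c(2523.1, 2523.1),
                             radius_um = 25, peak_velocity_mms = 8,
                             r_curve_um = 200, n_points = 200) {
  preset <- match.arg(preset)
  if (radius_um <= 0) stop("radii must be positive")
  if (peak_velocity_mms <= 0) stop("peak velocity must be positive")
  zc <- fov_um[1] / 2
  xc <- fov_um[2] / 2
  margin <- 0.1 * fov_um[2]
  line_pts <- function(p0, p1, n = n_points) {
    t <- seq(0, 1, length.out = n)
    cbind(z_um = p0[1] + t * (p1[1] - p0[1]),
          x_um = p0[2] + t * (p1[2] - p0[2]))
  }
  vessels <- switch(preset,
    straight = list(list(
      centerline = line_pts(c(zc, margin), c(zc, fov_um[2] - margin)),
      radius_um = radius_um, peak_velocity_mms = peak_velocity_mms)),
    sinusoid = {
      x <- seq(margin, fov_um[2] - margin, length.out = n_points)
      amp <- 0.12 * fov_um[1]
      z <- zc + amp * sin(2 * pi * (x - margin) / (fov_um[2] - 2 * margin) * 3)
      list(list(centerline = cbind(z_um = z, x_um = x),
                radius_um = radius_um, peak_velocity_mms = peak_velocity_mms))
    },
    semicircle = {
      th <- seq(0, pi, length.out = n_points)
      list(list(
        centerline = cbind(z_um = zc - r_curve_um * sin(th),
                           x_um = xc + r_curve_um * cos(th)),
        radius_um = radius_um, peak_velocity_mms = peak_velocity_mms))
    },
    bifurcation = {
      junction <- c(zc, xc)
      list(
        list(centerline = line_pts(c(zc, margin), junction),
             radius_um = radius_um, peak_velocity_mms = peak_velocity_mms),
        list(centerline = line_pts(junction, c(zc - 0.25 * fov_um[1],
                                               fov_um[2] - margin)),
             radius_um = radius_um * 0.8,
             peak_velocity_mms = peak_velocity_mms * 0.75),
        list(centerline = line_pts(junction, c(zc + 0.25 * fov_um[1],
                                               fov_um[2] - margin)),
             radius_um = radius_um * 0.8,
             peak_velocity_mms = peak_velocity_mms * 0.75))
    },
    cortical_column = {
      zm <- 0.1 * fov_um[1]
      list(
        # descending: z increases (superficial -> deep), arteriole-like
        list(centerline = line_pts(c(zm, xc - 0.15 * fov_um[2]),
                                   c(fov_um[1] - zm, xc - 0.15 * fov_um[2])),
             radius_um = radius_um, peak_velocity_mms = peak_velocity_mms),
        # ascending: z decreases (deep -> superficial), venule-like
        list(centerline = line_pts(c(fov_um[1] - zm, xc + 0.15 * fov_um[2]),
                                   c(zm, xc + 0.15 * fov_um[2])),
             radius_um = radius_um,
             peak_velocity_mms = peak_velocity_mms * 0.7))
    })
  for (v in vessels) {
    cl <- v$centerline
    if (any(cl[, 1] < 0 | cl[, 1] > fov_um[1] | cl[, 2] < 0 | cl[, 2] > fov_um[2]))
      stop("vessel centerline outside field of view")
  }
  structure(list(vessels = vessels, fov_um = fov_um, preset = preset),
            class = "vessel_geometry")
}

#' @export
print.vessel_geometry <- function(x, ...) {
  cat(sprintf("<vessel_geometry> preset '%s': %d vessel(s), FOV %.0f x %.0f um\n",
              x$preset, length(x$vessels), x$fov_um[1], x$fov_um[2]))
  invisible(x)
}

#' Phantom rendering configuration
#'
#' Parameters of the synthetic IQ renderer. Defaults state the emulated
#' acquisition: Gaussian bubble echoes with log-normal amplitude spread
#' (sdlog 0.3, so overlapping unequal echoes occur), a low-rank slowly
#' varying tissue-clutter background much brighter than the bubbles,
#' depth-increasing additive circular complex noise, and cardiac-frequency
#' amplitude modulation at 7 Hz (420 BPM, matching reported mouse heart
#' rates) of clutter and bubble amplitude.
#'
#' @param bubble_rate expected new bubbles entering per frame (Poisson).
#' @param psf_sigma_um Gaussian echo sigmas `c(axial, lateral)` in um.
#' @param bubble_amp median bubble peak amplitude (a.u.).
#' @param bubble_amp_sdlog log-normal sdlog of bubble amplitudes.
#' @param clutter_rank number of clutter components (0 disables clutter).
#' @param clutter_amp clutter RMS amplitude (a.u.); tissue >> bubbles.
#' @param noise_sigma additive complex-noise sigma at the surface (a.u.);
#'   0 disables noise.
#' @param noise_depth_slope fractional noise gain per full depth: the
#'   per-depth gain is `g(z) = 1 + slope * z / z_max`.
#' @param cardiac_freq_hz cardiac modulation frequency (Hz).
#' @param cardiac_mod modulation depth in `[0, 1)`; 0 disables pulsatility.
#' @param seed integer random seed; identical config => identical stack.
#' @return object of class `phantom_config`.
#' @export
phantom_config <- function(bubble_rate = 2, psf_sigma_um = c(40, 30),
                           bubble_amp = 1, bubble_amp_sdlog = 0.3,
                           clutter_rank = 4, clutter_amp = 30,
                           noise_sigma = 0.05, noise_depth_slope = 1,
                           cardiac_freq_hz = 7, cardiac_mod = 0.1,
                           seed = 1L) {
  if (clutter_rank < 0) stop("clutter rank must be >= 0")
  if (cardiac_mod < 0 || cardiac_mod >= 1) stop("modulation depth must be in [0, 1)")
  if (any(psf_sigma_um <= 0)) stop("PSF sigmas must be positive")
  structure(as.list(environment()), class = "phantom_config")
}

#' Simulate ground-truth microbubble tracks through a vessel tree
#'
#' Bubbles enter each vessel as a Poisson process, are seeded at a radial
#' offset drawn uniformly over the circular cross-sectional area
#' (offset `R * sqrt(u)` with a random sign for the in-plane side), advected along
#' the centerline at the laminar Poiseuille speed
#' `v(r) = v_peak * (1 - r^2 / R^2)`. The radial position is fixed for the
#' bubble's lifetime, so each track has one scalar true speed; averaged over
#' many bubbles the true speed tends to `v_peak / 2` (area average of the
#' parabola).
#'
#' @param geom a `vessel_geometry`.
#' @param duration_s record duration in seconds.
#' @param frame_rate frames per second.
#' @param bubble_rate expected bubbles entering per frame (all vessels
#'   together; split across vessels in proportion to vessel length).
#' @param seed integer seed (reproducible).
#' @return object of class `ground_truth_tracks`: data.frame with columns
#'   `bubble_id, vessel, frame, z_um, x_um, speed_mms`, plus attributes
#'   `frame_rate` and `n_entered`.
#' @export
simulate_tracks <- function(geom, duration_s, frame_rate = 1000,
                            bubble_rate = 2, seed = 1L) {
  stopifnot(inherits(geom, "vessel_geometry"))
  if (length(geom$vessels) == 0) stop("empty geometry")
  if (duration_s <= 0) stop("duration must be positive")
  if (bubble_rate <= 0) stop("bubble rate must be positive")
  set.seed(as.integer(seed))
  n_fr <- round(duration_s * frame_rate)
  # arc-length parameterization per vessel
  vinfo <- lapply(geom$vessels, function(v) {
    cl <- v$centerline
    seg <- diff(cl)
    len <- sqrt(rowSums(seg^2))
    s <- c(0, cumsum(len))
    list(cl = cl, s = s, total = s[length(s)], R = v$radius_um,
         vp = v$peak_velocity_mms)
  })
  lens <- vapply(vinfo, function(v) v$total, numeric(1))
  pv <- lens / sum(lens)
  n_new <- stats::rpois(n_fr, bubble_rate)
  total_bubbles <- sum(n_new)
  if (total_bubbles == 0)
    return(structure(data.frame(bubble_id = integer(), vessel = integer(),
                                frame = integer(), z_um = numeric(),
                                x_um = numeric(), speed_mms = numeric()),
                     frame_rate = frame_rate, n_entered = 0L,
                     class = c("ground_truth_tracks", "data.frame")))
  entry_frame <- rep.int(seq_len(n_fr), n_new)
  vessel_id <- sample.int(length(vinfo), total_bubbles, replace = TRUE, prob = pv)
  u <- stats::runif(total_bubbles)
  side <- sample(c(-1, 1), total_bubbles, replace = TRUE)
  fr_l <- z_l <- x_l <- vector("list", total_bubbles)
  n_pts <- integer(total_bubbles)
  speed_b <- numeric(total_bubbles)
  for (b in seq_len(total_bubbles)) {
    vi <- vinfo[[vessel_id[b]]]
    r <- vi$R * sqrt(u[b])
    speed <- vi$vp * (1 - (r / vi$R)^2)           # mm/s, fixed per bubble
    speed_b[b] <- speed
    step_um <- speed * 1000 / frame_rate          # um per frame
    n_steps <- if (step_um > 0) floor(vi$total / step_um) else 0
    frames <- entry_frame[b] + 0:n_steps
    frames <- frames[frames <= n_fr]
    if (length(frames) == 0) next
    s_pos <- (seq_along(frames) - 1) * step_um
    pos <- .polyline_point(vi$cl, vi$s, s_pos)
    # offset perpendicular to local tangent, fixed signed radial position
    off <- side[b] * r
    fr_l[[b]] <- frames
    z_l[[b]] <- pos$z + off * pos$nz
    x_l[[b]] <- pos$x + off * pos$nx
    n_pts[b] <- length(frames)
  }
  out <- data.frame(bubble_id = rep.int(seq_len(total_bubbles), n_pts),
                    vessel = rep.int(vessel_id, n_pts),
                    frame = unlist(fr_l, use.names = FALSE),
                    z_um = unlist(z_l, use.names = FALSE),
                    x_um = unlist(x_l, use.names = FALSE),
                    speed_mms = rep.int(speed_b, n_pts))
  structure(out, frame_rate = frame_rate, n_entered = total_bubbles,
            class = c("ground_truth_tracks", "data.frame"))
}

# interpolate points (and unit normals) at arc positions s_pos along polyline
.polyline_point <- function(cl, s, s_pos) {
  idx <- findInterval(s_pos, s, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), nrow(cl) - 1L)
  seg_len <- s[idx + 1L] - s[idx]
  t <- ifelse(seg_len > 0, (s_pos - s[idx]) / seg_len, 0)
  z <- cl[idx, 1] + t * (cl[idx + 1L, 1] - cl[idx, 1])
  x <- cl[idx, 2] + t * (cl[idx + 1L, 2] - cl[idx, 2])
  tz <- (cl[idx + 1L, 1] - cl[idx, 1]) / ifelse(seg_len > 0, seg_len, 1)
  tx <- (cl[idx + 1L, 2] - cl[idx, 2]) / ifelse(seg_len > 0, seg_len, 1)
  list(z = z, x = x, nz = -tx, nx = tz)   # normal = tangent rotated 90 deg
}

#' Render a synthetic IQ stack from ground-truth tracks
#'
#' Linear superposition of (i) one 2D Gaussian echo per bubble per frame at
#' its true position, with a fixed random phase and log-normal amplitude per
#' bubble; (ii) a rank-`clutter_rank` tissue background (smooth random
#' spatial patterns times slowly varying temporal envelopes), optionally
#' amplitude-modulated at the cardiac frequency; and (iii) additive circular
#' complex noise whose sigma follows the stated depth profile.
#'
#' @param tracks a `ground_truth_tracks` table (may be empty).
#' @param cfg a `phantom_config`.
#' @param grid list with `nz`, `nx`, `spacing_um` (scalar or `c(z, x)`).
#' @param frame_rate frames per second (defaults to the tracks' attribute).
#' @param n_frames number of frames (defaults to max frame in `tracks`).
#' @return an `iq_stack`.
#' @export
render_iq <- function(tracks, cfg = phantom_config(),
                      grid = list(nz = 128, nx = 128, spacing_um = 19.712),
                      frame_rate = NULL, n_frames = NULL) {
  stopifnot(inherits(cfg, "phantom_config"))
  sp <- grid$spacing_um
  if (length(sp) == 1L) sp <- rep(sp, 2L)
  if (is.null(frame_rate)) frame_rate <- attr(tracks, "frame_rate")
  if (is.null(frame_rate)) stop("frame_rate not supplied and not on tracks")
  if (is.null(n_frames)) n_frames <- if (nrow(tracks)) max(tracks$frame) else 0L
  if (n_frames < 1) stop("need at least one frame")
  nz <- grid$nz; nx <- grid$nx
  if (nrow(tracks)) {
    if (max(tracks$z_um) > (nz - 1) * sp[1] + 3 * cfg$psf_sigma_um[1] ||
        max(tracks$x_um) > (nx - 1) * sp[2] + 3 * cfg$psf_sigma_um[2])
      stop("grid/track mismatch: tracks extend far outside the grid")
  }
  # independent sub-streams so that clutter/noise realizations are shared
  # across renders of different track subsets (linearity invariant) and
  # per-bubble draws are keyed by bubble id
  seed <- as.integer(cfg$seed)
  set.seed(seed)
  t_s <- (seq_len(n_frames) - 1) / frame_rate
  cardiac <- if (cfg$cardiac_mod > 0) {
    1 + cfg$cardiac_mod * cos(2 * pi * cfg$cardiac_freq_hz * t_s)
  } else rep(1, n_frames)

  stack <- array(0i, dim = c(nz, nx, n_frames))

  # --- clutter: sum over components of smooth spatial pattern x slow envelope
  if (cfg$clutter_rank > 0) {
    zg <- seq_len(nz) / nz
    xg <- seq_len(nx) / nx
    for (k in seq_len(cfg$clutter_rank)) {
      fz <- stats::runif(1, 0.5, 2.5); fx <- stats::runif(1, 0.5, 2.5)
      ph <- stats::runif(4, 0, 2 * pi)
      pat <- outer(cos(2 * pi * fz * zg + ph[1]) + 0.5 * sin(2 * pi * 0.5 * fz * zg + ph[2]),
                   cos(2 * pi * fx * xg + ph[3]) + 0.5 * sin(2 * pi * 0.5 * fx * xg + ph[4]))
      pat <- pat * exp(1i * stats::runif(1, 0, 2 * pi))
      # slow temporal envelopes: the first component carries the static
      # tissue mean; higher components are zero-mean slow motion modes
      # (random low-frequency phases), so the planted components have
      # comparable energy and distinct temporal directions
      # respiratory-scale motion (well below the 4-10 Hz cardiac search
      # band even after squaring in the power signal)
      f_slow <- stats::runif(3, 0.3, 1.8)
      a_slow <- stats::rnorm(3, 0, 0.3)
      dc <- if (k == 1) 1 else 0
      env0 <- dc + colSums(a_slow * sin(outer(2 * pi * f_slow, t_s) +
                                        stats::runif(3, 0, 2 * pi)))
      amp <- cfg$clutter_amp * stats::runif(1, 0.5, 1) /
        sqrt(mean(Mod(pat)^2) * max(mean(env0^2), 1e-12))
      env <- amp * env0 * cardiac
      for (t in seq_len(n_frames)) stack[, , t] <- stack[, , t] + pat * env[t]
    }
  }

  # --- bubbles
  if (nrow(tracks)) {
    set.seed(seed + 1L)
    max_id <- max(tracks$bubble_id)
    # two uniforms per id, interleaved, so draws for id i do not depend on
    # how many ids a particular render happens to contain
    u <- matrix(stats::runif(2L * max_id), nrow = 2L)
    amp_b <- cfg$bubble_amp * stats::qlnorm(u[1, ], 0, cfg$bubble_amp_sdlog)
    phase_b <- exp(2i * pi * u[2, ])
    names(amp_b) <- names(phase_b) <- as.character(seq_len(max_id))
    sz <- cfg$psf_sigma_um[1]; sx <- cfg$psf_sigma_um[2]
    hz <- ceiling(3 * sz / sp[1]); hx <- ceiling(3 * sx / sp[2])
    keep <- tracks$frame <= n_frames
    tr <- tracks[keep, , drop = FALSE]
    for (r in seq_len(nrow(tr))) {
      zc <- tr$z_um[r] / sp[1] + 1   # fractional pixel index
      xc <- tr$x_um[r] / sp[2] + 1
      iz <- max(1L, floor(zc) - hz):min(nz, ceiling(zc) + hz)
      ix <- max(1L, floor(xc) - hx):min(nx, ceiling(xc) + hx)
      if (!length(iz) || !length(ix)) next
      gz <- exp(-((iz - zc) * sp[1])^2 / (2 * sz^2))
      gx <- exp(-((ix - xc) * sp[2])^2 / (2 * sx^2))
      bid <- as.character(tr$bubble_id[r])
      a <- amp_b[[bid]] * phase_b[[bid]] * cardiac[tr$frame[r]]
      stack[iz, ix, tr$frame[r]] <- stack[iz, ix, tr$frame[r]] + a * outer(gz, gx)
    }
  }

  # --- depth-dependent circular complex noise
  if (cfg$noise_sigma > 0) {
    set.seed(seed + 2L)
    g <- 1 + cfg$noise_depth_slope * (seq_len(nz) - 1) / (nz - 1)
    sig <- cfg$noise_sigma * g
    nzx <- nz * nx * n_frames
    noise <- complex(real = stats::rnorm(nzx), imaginary = stats::rnorm(nzx)) / sqrt(2)
    noise <- array(noise, dim = c(nz, nx, n_frames)) * sig  # recycles over z
    stack <- stack + noise
  }

  iq_stack(stack, spacing_um = sp, frame_rate = frame_rate)
}

#' Render a synthetic two-channel fluorescence histology image
#'
#' Emulates a stained coronal section: a FITC (vessel) channel in which
#' vessel skeletons are dilated to wall-like rings, and an amyloid (plaque)
#' channel with disk-shaped deposits placed uniformly per region. A smooth
#' multiplicative illumination field (vignetting) is applied to both channels
#' so that global thresholding is biased while an adaptive threshold is not,
#' and a fraction of the plaque signal bleeds into the FITC channel (the
#' motivation for the morphometric exclusion mask). Ground-truth
#' positive-area fractions are recorded per channel and region.
#'
#' @param plaque_density plaques per mm^2, one value per region (recycled).
#' @param regions named list of logical region masks (same shape); default a
#'   single region covering the full image.
#' @param size_px image size `c(rows, cols)`.
#' @param um_per_px pixel pitch in micrometres.
#' @param n_vessels number of synthetic vessel skeleton curves.
#' @param vessel_radius_px vessel outer radius in pixels (ring wall ~ 40%).
#' @param plaque_radius_px range of plaque radii, pixels.
#' @param bleed fraction of plaque intensity added into the FITC channel.
#' @param illumination logical: apply the vignetting field.
#' @param noise_sd additive Gaussian noise sd (intensity units, image in
#'   `[0, 1]`).
#' @param seed integer seed.
#' @return object of class `histo_image`: list with `fitc` and `abeta`
#'   intensity matrices in `[0, 1]`, `um_per_px`, `regions`, ground-truth masks
#'   (`truth_fitc`, `truth_abeta`) and a `truth` data.frame of positive-area
#'   fractions (percent) per region and channel.
#' @export
render_histology <- function(plaque_density, regions = NULL,
                             size_px = c(384, 384), um_per_px = 4,
                             n_vessels = 8, vessel_radius_px = 4,
                             plaque_radius_px = c(4, 10), bleed = 0.5,
                             illumination = TRUE, noise_sd = 0.015,
                             seed = 1L) {
  if (any(plaque_density < 0)) stop("plaque density must be non-negative")
  set.seed(as.integer(seed))
  nr <- size_px[1]; nc <- size_px[2]
  if (is.null(regions)) regions <- list(all = matrix(TRUE, nr, nc))
  plaque_density <- rep_len(plaque_density, length(regions))

  # vessel skeletons: smooth random curves across the image
  skel <- matrix(FALSE, nr, nc)
  for (v in seq_len(n_vessels)) {
    x <- seq_len(nc)
    y0 <- stats::runif(1, 0.1, 0.9) * nr
    amp <- stats::runif(1, 0.02, 0.2) * nr
    per <- stats::runif(1, 0.5, 2)
    ph <- stats::runif(1, 0, 2 * pi)
    y <- round(y0 + amp * sin(2 * pi * per * x / nc + ph))
    ok <- y >= 1 & y <= nr
    skel[cbind(y[ok], x[ok])] <- TRUE
  }
  outer_m <- .binary_dilate(skel, vessel_radius_px)
  inner_m <- .binary_dilate(skel, max(1, round(0.6 * vessel_radius_px)))
  ring <- outer_m & !inner_m
  vessel_mask <- outer_m

  # plaques: disks placed uniformly per region, but extravascular (amyloid
  # deposits sit in the parenchyma): centres avoid a dilated vessel zone
  abeta_mask <- matrix(FALSE, nr, nc)
  rg <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  avoid <- .binary_dilate(outer_m, max(2L, round(max(plaque_radius_px)) + 1L))
  for (i in seq_along(regions)) {
    reg <- regions[[i]]
    area_mm2 <- sum(reg) * (um_per_px / 1000)^2
    n_pl <- stats::rpois(1, plaque_density[i] * area_mm2)
    if (n_pl == 0) next
    cand <- which(reg & !avoid)
    if (!length(cand)) cand <- which(reg)
    ctr <- sample(cand, n_pl, replace = TRUE)
    for (c0 in ctr) {
      rr <- stats::runif(1, plaque_radius_px[1], plaque_radius_px[2])
      r0 <- rg$row[c0]; cc0 <- rg$col[c0]
      ir <- max(1, floor(r0 - rr)):min(nr, ceiling(r0 + rr))
      ic <- max(1, floor(cc0 - rr)):min(nc, ceiling(cc0 + rr))
      d2 <- outer((ir - r0)^2, (ic - cc0)^2, "+")
      abeta_mask[ir, ic] <- abeta_mask[ir, ic] | (d2 <= rr^2)
    }
  }

  base <- 0.15
  fitc <- base + 0.7 * ring + bleed * 0.7 * abeta_mask
  abeta <- base + 0.8 * abeta_mask
  if (illumination) {
    rr <- (seq_len(nr) - nr / 2) / nr
    cc <- (seq_len(nc) - nc / 2) / nc
    field <- outer(1 - 0.8 * rr^2, 1 - 0.8 * cc^2) * (1 + 0.3 * outer(rr, rep(1, nc)))
    fitc <- fitc * field
    abeta <- abeta * field
  }
  fitc <- pmin(pmax(fitc + stats::rnorm(nr * nc, 0, noise_sd), 0), 1.5)
  abeta <- pmin(pmax(abeta + stats::rnorm(nr * nc, 0, noise_sd), 0), 1.5)

  truth <- do.call(rbind, lapply(seq_along(regions), function(i) {
    reg <- regions[[i]]
    data.frame(region = names(regions)[i] %||% as.character(i),
               channel = c("fitc", "abeta"),
               fraction_pct = c(100 * sum(ring & reg) / sum(reg),
                                100 * sum(abeta_mask & reg) / sum(reg)))
  }))
  structure(list(fitc = fitc, abeta = abeta, um_per_px = um_per_px,
                 regions = regions, truth_fitc = ring,
                 truth_abeta = abeta_mask, vessel_mask = vessel_mask,
                 truth = truth),
            class = "histo_image")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert a ground-truth track table to track objects
#'
#' Turns each bubble's true position sequence into an `ulm_track`, giving a
#' noise-free oracle path into the map/metric modules.
#'
#' @param truth a `ground_truth_tracks` table.
#' @param frame_rate frames per second (defaults to the table's attribute).
#' @param min_len drop bubbles observed for fewer centroids than this.
#' @return list of `ulm_track`.
#' @export
truth_to_tracks <- function(truth, frame_rate = NULL, min_len = 2L) {
  if (is.null(frame_rate)) frame_rate <- attr(truth, "frame_rate")
  by_b <- split(truth[, c("frame", "z_um", "x_um")], truth$bubble_id)
  by_b <- by_b[vapply(by_b, nrow, integer(1)) >= min_len]
  lapply(by_b, function(p) {
    rownames(p) <- NULL
    new_track(p, frame_rate)
  })
}

#' Empty ground-truth track table
#'
#' Convenience constructor for rendering bubble-free stacks (clutter/noise
#' only), e.g. for heart-rate or noise-profile phantoms.
#'
#' @param frame_rate frames per second attribute to attach.
#' @return zero-row `ground_truth_tracks`.
#' @export
empty_tracks <- function(frame_rate = 1000) {
  structure(data.frame(bubble_id = integer(), vessel = integer(),
                       frame = integer(), z_um = numeric(), x_um = numeric(),
                       speed_mms = numeric()),
            frame_rate = frame_rate, n_entered = 0L,
            class = c("ground_truth_tracks", "data.frame"))
}

# disk dilation of a logical matrix by shifting (small radii only)
.binary_dilate <- function(mask, radius) {
  if (radius <= 0) return(mask)
  out <- mask
  nr <- nrow(mask); nc <- ncol(mask)
  for (dr in -radius:radius) {
    for (dc in -radius:radius) {
      if (dr * dr + dc * dc > radius * radius || (dr == 0 && dc == 0)) next
      sr <- max(1, 1 - dr):min(nr, nr - dr)
      sc <- max(1, 1 - dc):min(nc, nc - dc)
      out[sr + dr, sc + dc] <- out[sr + dr, sc + dc] | mask[sr, sc]
    }
  }
  out
}
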