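# Regional and single-vessel quantification on the super-resolved maps:
# vascularity (perfused area fraction), median flow velocity, sum-of-angles
# tortuosity, arteriole/venule directional splitting, and Poiseuille profile
# fitting across manually chosen vessel cross-sections.

#' Vascularity index of an ROI
#'
#' Percentage of ROI pixels containing at least one accumulated microbubble
#' trajectory (binarized density raster).
#'
#' @param map a `vascular_map`.
#' @param roi an `roi_polygon` or logical mask of the map's shape.
#' @return percentage in `[0, 100]`.
#' @export
vascularity <- function(map, roi) {
  mask <- .roi_mask(roi, map)
  if (!any(mask)) stop("empty ROI mask")
  100 * sum(map$density[mask] >= 1L) / sum(mask)
}

#' Median flow velocity of an ROI
#'
#' Median of the velocity raster over perfused (density >= 1) ROI pixels.
#'
#' @inheritParams vascularity
#' @return velocity in mm/s.
#' @export
median_velocity <- function(map, roi) {
  mask <- .roi_mask(roi, map)
  v <- map$velocity[mask & map$density >= 1L]
  if (!length(v)) stop("no perfused pixels in ROI")
  stats::median(v)
}

.roi_mask <- function(roi, map) {
  mask <- if (inherits(roi, "roi_polygon")) roi$mask else roi
  if (!identical(dim(mask), dim(map$density)))
    stop("ROI mask and map grid differ in shape")
  mask
}

#' Sum-of-angles tortuosity metric (SOAM)
#'
#' Sum over interior centroids of the absolute angle (radians) between
#' successive step vectors, divided by the total path length in millimetres.
#' Zero for a straight track; for a densely sampled circular arc of radius R
#' it converges to `1/R` (per mm). Zero-length steps are dropped with a
#' warning.
#'
#' @param track an `ulm_track` or matrix/data.frame of positions
#'   (`z_um`, `x_um`) in order.
#' @return tortuosity in rad/mm (reported as a.u.).
#' @export
soam <- function(track) {
  pts <- if (is.data.frame(track)) cbind(track$z_um, track$x_um) else as.matrix(track)
  if (nrow(pts) < 3) stop("need at least 3 centroids")
  steps <- diff(pts)
  len <- sqrt(rowSums(steps^2))
  if (any(len == 0)) {
    warning("zero-length steps dropped")
    steps <- steps[len > 0, , drop = FALSE]
    len <- len[len > 0]
  }
  if (nrow(steps) < 2) stop("degenerate track (all steps zero)")
  n <- nrow(steps)
  dot <- rowSums(steps[-n, , drop = FALSE] * steps[-1, , drop = FALSE])
  cosang <- pmin(pmax(dot / (len[-n] * len[-1]), -1), 1)
  ang <- acos(cosang)
  sum(ang) / (sum(len) / 1000)
}

#' Mean SOAM over the tracks of an ROI
#'
#' Tracks belong to the ROI if the majority of their centroids fall inside
#' the mask.
#'
#' @param tracks list of `ulm_track`.
#' @param roi `roi_polygon` (or logical mask plus `spacing_um` attr).
#' @param spacing_um map grid spacing (defaults to the ROI's grid).
#' @return mean SOAM (a.u., rad/mm) over qualifying tracks with >= 3
#'   centroids; `NA` if none qualify.
#' @export
roi_soam <- function(tracks, roi, spacing_um = NULL) {
  sel <- tracks_in_roi(tracks, roi, spacing_um)
  vals <- vapply(tracks[sel], function(tr) {
    if (nrow(tr) >= 3) soam(tr) else NA_real_
  }, numeric(1))
  vals <- vals[!is.na(vals)]
  if (!length(vals)) return(NA_real_)
  mean(vals)
}

#' Which tracks belong to an ROI (majority-of-centroids rule)
#'
#' @inheritParams roi_soam
#' @return logical vector over `tracks`.
#' @export
tracks_in_roi <- function(tracks, roi, spacing_um = NULL) {
  if (inherits(roi, "roi_polygon")) {
    mask <- roi$mask
    sp <- roi$grid$spacing_um
  } else {
    mask <- roi
    sp <- spacing_um
    if (is.null(sp)) stop("spacing_um required with a raw mask")
  }
  if (length(sp) > 1L) sp <- sp[1]
  nz <- nrow(mask); nx <- ncol(mask)
  vapply(tracks, function(tr) {
    iz <- pmin(pmax(round(tr$z_um / sp) + 1L, 1L), nz)
    ix <- pmin(pmax(round(tr$x_um / sp) + 1L, 1L), nx)
    mean(mask[cbind(iz, ix)]) > 0.5
  }, logical(1))
}

#' Split ROI tracks into arteriole and venule subsets by flow direction
#'
#' Flow from the cortical surface into the brain (mean track velocity vector
#' with positive component along the surface normal) is classified as
#' arteriole flow; flow toward the surface as venule flow. Tracks with a zero
#' mean vector are excluded (and counted).
#'
#' @param tracks list of `ulm_track`.
#' @param roi `roi_polygon`; only its tracks (majority rule) are classified.
#' @param surface_normal unit vector `(z, x)` pointing from the surface into
#'   the brain; defaults to the ROI's `surface_normal`.
#' @return list with `arteriole`, `venule` (lists of tracks), `excluded`
#'   (count) and `index` (per input track: "arteriole", "venule", "excluded"
#'   or `NA` if outside the ROI).
#' @export
split_arteriole_venule <- function(tracks, roi, surface_normal = NULL) {
  if (is.null(surface_normal) && inherits(roi, "roi_polygon"))
    surface_normal <- roi$surface_normal
  if (is.null(surface_normal)) stop("surface_normal required")
  surface_normal <- surface_normal / sqrt(sum(surface_normal^2))
  sel <- tracks_in_roi(tracks, roi)
  lab <- rep(NA_character_, length(tracks))
  for (i in which(sel)) {
    vz <- mean(attr(tracks[[i]], "vz_mms"))
    vx <- mean(attr(tracks[[i]], "vx_mms"))
    s <- vz * surface_normal[1] + vx * surface_normal[2]
    lab[i] <- if (s > 0) "arteriole" else if (s < 0) "venule" else "excluded"
  }
  list(arteriole = tracks[!is.na(lab) & lab == "arteriole"],
       venule = tracks[!is.na(lab) & lab == "venule"],
       excluded = sum(!is.na(lab) & lab == "excluded"),
       index = lab)
}

#' Velocity profile across a vessel cross-section
#'
#' For every track step that crosses the oriented line segment, record the
#' crossing offset along the segment and the step speed; offsets are binned
#' at `bin_um` and the per-bin maximum and mean crossing speeds reported.
#'
#' @param tracks list of `ulm_track`.
#' @param segment 2 x 2 matrix: rows are the segment endpoints `(z_um,
#'   x_um)`; the segment should span the vessel perpendicular to flow.
#' @param bin_um offset bin width (default one 4.928 um map pixel).
#' @return object of class `vessel_profile`: data.frame `(offset_um, v_max,
#'   v_mean, n)` with bin centres, plus attributes `segment` and `bin_um`.
#' @export
vessel_profile <- function(tracks, segment, bin_um = 4.928) {
  segment <- as.matrix(segment)
  stopifnot(identical(dim(segment), c(2L, 2L)))
  s0 <- segment[1, ]; s1 <- segment[2, ]
  sv <- s1 - s0
  slen <- sqrt(sum(sv^2))
  if (slen <= 0) stop("degenerate segment")
  offs <- numeric(0); spd <- numeric(0)
  for (tr in tracks) {
    if (nrow(tr) < 2) next
    sp_step <- attr(tr, "speed_mms")
    for (s in seq_len(nrow(tr) - 1)) {
      p0 <- c(tr$z_um[s], tr$x_um[s])
      p1 <- c(tr$z_um[s + 1], tr$x_um[s + 1])
      hit <- .seg_intersect(p0, p1, s0, s1)
      if (!is.null(hit)) {
        offs <- c(offs, hit * slen)
        spd <- c(spd, sp_step[s])
      }
    }
  }
  if (!length(offs)) stop("no track crosses the segment")
  bins <- floor(offs / bin_um)
  agg_max <- tapply(spd, bins, max)
  agg_mean <- tapply(spd, bins, mean)
  agg_n <- tapply(spd, bins, length)
  b <- as.numeric(names(agg_max))
  out <- data.frame(offset_um = (b + 0.5) * bin_um,
                    v_max = as.numeric(agg_max),
                    v_mean = as.numeric(agg_mean),
                    n = as.integer(agg_n))
  out <- out[order(out$offset_um), ]
  rownames(out) <- NULL
  structure(out, segment = segment, bin_um = bin_um,
            class = c("vessel_profile", "data.frame"))
}

# intersection parameter along (s0, s1) if segment (p0, p1) crosses it,
# else NULL
.seg_intersect <- function(p0, p1, s0, s1) {
  r <- p1 - p0
  s <- s1 - s0
  denom <- r[1] * s[2] - r[2] * s[1]
  if (abs(denom) < 1e-12) return(NULL)   # parallel
  q <- s0 - p0
  t <- (q[1] * s[2] - q[2] * s[1]) / denom   # along track step
  u <- (q[1] * r[2] - q[2] * r[1]) / denom   # along segment
  if (t >= 0 && t < 1 && u >= 0 && u <= 1) u else NULL
}

#' Fit a parabolic (Poiseuille) profile to per-bin maximum velocities
#'
#' Least-squares fit of `v(r) = v_peak (1 - ((r - center)/radius)^2)` via the
#' quadratic normal equations (closed form): the fitted quadratic
#' `a + b r + c r^2` must be concave (`c < 0`), otherwise the profile is
#' flagged as degenerate (flat profile, radius unbounded).
#'
#' @param profile a `vessel_profile` (>= 3 populated bins).
#' @return list with `v_peak_mms`, `center_um`, `radius_um`, `residual_rms`.
#' @export
fit_parabola <- function(profile) {
  if (nrow(profile) < 3) stop("need at least 3 populated bins")
  r <- profile$offset_um
  v <- profile$v_max
  X <- cbind(1, r, r^2)
  fit <- stats::lm.fit(X, v)
  cf <- fit$coefficients
  curv_floor <- -1e-10 * max(abs(v)) / max(abs(r), 1)^2
  if (!all(is.finite(cf)) || cf[3] >= curv_floor)
    stop("profile is not concave: radius unbounded (flat or noisy profile)")
  center <- -cf[2] / (2 * cf[3])
  v_peak <- cf[1] + cf[2] * center + cf[3] * center^2
  if (v_peak <= 0) stop("fitted peak velocity is not positive")
  radius <- sqrt(-v_peak / cf[3])
  list(v_peak_mms = unname(v_peak), center_um = unname(center),
       radius_um = unname(radius),
       residual_rms = sqrt(mean(fit$residuals^2)))
}

#' Regional metric table for one map + track set
#'
#' Computes the three regional metrics (vascularity %, median velocity,
#' mean SOAM) and the track count for each ROI, for all tracks and -- where
#' the ROI has a surface normal -- for the arteriole and venule subsets.
#'
#' @param map a `vascular_map`.
#' @param tracks list of `ulm_track` used to build `map`.
#' @param rois list of `roi_polygon`.
#' @param grid map grid (for re-accumulating subsets).
#' @return data.frame with columns `region, subset, vascularity_pct,
#'   median_velocity_mms, soam, n_tracks`.
#' @export
roi_metrics <- function(map, tracks, rois, grid) {
  rows <- list()
  for (roi in rois) {
    subsets <- list(all = tracks[tracks_in_roi(tracks, roi)])
    if (!is.null(roi$surface_normal)) {
      sp <- split_arteriole_venule(tracks, roi)
      subsets$arteriole <- sp$arteriole
      subsets$venule <- sp$venule
    }
    for (nm in names(subsets)) {
      trs <- subsets[[nm]]
      m <- if (nm == "all") map else accumulate(trs, grid)
      vasc <- tryCatch(vascularity(m, roi), error = function(e) NA_real_)
      vel <- tryCatch(median_velocity(m, roi), error = function(e) NA_real_)
      so <- if (length(trs)) {
        vals <- vapply(trs, function(tr) if (nrow(tr) >= 3) soam(tr) else NA_real_,
                       numeric(1))
        if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
      } else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        region = roi$label, subset = nm, vascularity_pct = vasc,
        median_velocity_mms = vel, soam = so, n_tracks = length(trs))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
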