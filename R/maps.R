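# Super-resolved vascular rasters. Tracks are accumulated as lines, not
# isolated points: each step between consecutive centroids is rasterized with
# a supercover line (every pixel the segment passes through), which is what
# turns sparse centroids into continuous vessels.

#' Supercover line between two points (pixel indices)
#'
#' Grid traversal (Amanatides-Woo): returns every pixel the segment from
#' `a` to `b` passes through, inclusive of both endpoints. Coordinates are
#' continuous pixel positions (1-based, pixel centres at integers).
#'
#' @param a,b numeric length-2 vectors `(row, col)`.
#' @return integer matrix with columns `row`, `col`.
#' @keywords internal
.supercover_line <- function(a, b) {
  # work in cell coordinates: cell (i, j) spans [i - 0.5, i + 0.5)
  pos <- a
  cell <- round(a)
  end_cell <- round(b)
  d <- b - a
  cells <- list(cell)
  step <- sign(d)
  if (all(cell == end_cell)) return(matrix(cell, ncol = 2,
                                           dimnames = list(NULL, c("row", "col"))))
  t_max <- numeric(2)
  t_delta <- numeric(2)
  for (k in 1:2) {
    if (d[k] == 0) {
      t_max[k] <- Inf
      t_delta[k] <- Inf
    } else {
      boundary <- cell[k] + step[k] * 0.5
      t_max[k] <- (boundary - a[k]) / d[k]
      t_delta[k] <- abs(1 / d[k])
    }
  }
  guard <- sum(abs(end_cell - cell)) + 4
  while (any(cell != end_cell) && guard > 0) {
    k <- if (t_max[1] <= t_max[2]) 1L else 2L
    cell[k] <- cell[k] + step[k]
    t_max[k] <- t_max[k] + t_delta[k]
    cells[[length(cells) + 1L]] <- cell
    guard <- guard - 1
  }
  m <- do.call(rbind, cells)
  colnames(m) <- c("row", "col")
  m
}

#' Accumulate tracks into a super-resolved vascular map
#'
#' Each track is rasterized step by step with supercover lines at the map
#' grid resolution. Per track, every visited pixel counts once toward the
#' density raster (a track passing a pixel is one visit); the velocity raster
#' is the visit-weighted mean of step speeds, and the direction raster the
#' visit-weighted mean 2D flow vector (unit step direction scaled by speed),
#' whose axial component's sign distinguishes descending from ascending flow.
#'
#' @param tracks list of `ulm_track` (positions in micrometres).
#' @param grid list with `nz`, `nx` and `spacing_um` (scalar, isotropic;
#'   default the 4.928 um map grid).
#' @return object of class `vascular_map`: list with integer `density`,
#'   `velocity` (mm/s, `NA` where density is 0), `dir_z`, `dir_x` (mean flow
#'   vector, mm/s, 0 where density is 0) and `spacing_um`.
#' @export
accumulate <- function(tracks, grid = list(nz = 509, nx = 509, spacing_um = 4.928)) {
  nz <- grid$nz; nx <- grid$nx
  sp <- grid$spacing_um
  if (length(sp) > 1L) sp <- sp[1]
  density <- matrix(0L, nz, nx)
  speed_sum <- matrix(0, nz, nx)
  dirz_sum <- matrix(0, nz, nx)
  dirx_sum <- matrix(0, nz, nx)
  clipped <- FALSE
  for (tr in tracks) {
    if (nrow(tr) < 2) next
    vz <- attr(tr, "vz_mms"); vx <- attr(tr, "vx_mms")
    sp_step <- attr(tr, "speed_mms")
    # per-track accumulators keyed by pixel linear index
    px <- integer(0)
    s_acc <- numeric(0); z_acc <- numeric(0); x_acc <- numeric(0); n_acc <- integer(0)
    for (s in seq_len(nrow(tr) - 1)) {
      a <- c(tr$z_um[s] / sp + 1, tr$x_um[s] / sp + 1)
      b <- c(tr$z_um[s + 1] / sp + 1, tr$x_um[s + 1] / sp + 1)
      cells <- .supercover_line(a, b)
      ok <- cells[, 1] >= 1 & cells[, 1] <= nz & cells[, 2] >= 1 & cells[, 2] <= nx
      if (!all(ok)) clipped <- TRUE
      cells <- cells[ok, , drop = FALSE]
      if (!nrow(cells)) next
      lin <- as.integer((cells[, 2] - 1) * nz + cells[, 1])
      idx <- match(lin, px)
      new <- is.na(idx)
      if (any(new)) {
        px <- c(px, lin[new])
        s_acc <- c(s_acc, numeric(sum(new)))
        z_acc <- c(z_acc, numeric(sum(new)))
        x_acc <- c(x_acc, numeric(sum(new)))
        n_acc <- c(n_acc, integer(sum(new)))
        idx <- match(lin, px)
      }
      s_acc[idx] <- s_acc[idx] + sp_step[s]
      z_acc[idx] <- z_acc[idx] + vz[s]
      x_acc[idx] <- x_acc[idx] + vx[s]
      n_acc[idx] <- n_acc[idx] + 1L
    }
    if (!length(px)) next
    density[px] <- density[px] + 1L
    speed_sum[px] <- speed_sum[px] + s_acc / n_acc
    dirz_sum[px] <- dirz_sum[px] + z_acc / n_acc
    dirx_sum[px] <- dirx_sum[px] + x_acc / n_acc
  }
  if (clipped) warning("track(s) extended outside the map grid; clipped")
  .vascular_map(density, speed_sum, dirz_sum, dirx_sum, sp)
}

.vascular_map <- function(density, speed_sum, dirz_sum, dirx_sum, spacing_um) {
  velocity <- speed_sum / density
  velocity[density == 0L] <- NA_real_
  dir_z <- dirz_sum / pmax(density, 1L)
  dir_x <- dirx_sum / pmax(density, 1L)
  structure(list(density = density, velocity = velocity,
                 dir_z = dir_z, dir_x = dir_x, spacing_um = spacing_um,
                 speed_sum = speed_sum, dirz_sum = dirz_sum,
                 dirx_sum = dirx_sum),
            class = "vascular_map")
}

#' @export
print.vascular_map <- function(x, ...) {
  cat(sprintf("<vascular_map> %d x %d px @ %.3f um, %d perfused px, %d visits\n",
              nrow(x$density), ncol(x$density), x$spacing_um,
              sum(x$density > 0), sum(x$density)))
  invisible(x)
}

#' Merge two vascular maps
#'
#' Pixelwise merge equivalent to accumulating the union of the two track
#' sets: densities add; velocity and direction rasters re-weight by visits.
#'
#' @param a,b `vascular_map`s on identical grids.
#' @return merged `vascular_map`.
#' @export
merge_maps <- function(a, b) {
  stopifnot(identical(dim(a$density), dim(b$density)),
            isTRUE(all.equal(a$spacing_um, b$spacing_um)))
  .vascular_map(a$density + b$density,
                a$speed_sum + b$speed_sum,
                a$dirz_sum + b$dirz_sum,
                a$dirx_sum + b$dirx_sum,
                a$spacing_um)
}

#' Write the map rasters to 32-bit TIFF files
#'
#' One float32 TIFF per raster (`density`, `velocity`, `dir_z`, `dir_x`);
#' `NA` velocity is written as 0.
#'
#' @param map a `vascular_map`.
#' @param prefix output path prefix; files are `<prefix>_<raster>.tif`.
#' @return invisibly, the written paths.
#' @export
write_map_tiff <- function(map, prefix) {
  v <- map$velocity
  v[is.na(v)] <- 0
  paths <- c(density = paste0(prefix, "_density.tif"),
             velocity = paste0(prefix, "_velocity.tif"),
             dir_z = paste0(prefix, "_dir_z.tif"),
             dir_x = paste0(prefix, "_dir_x.tif"))
  write_tiff(map$density + 0, paths["density"], sample_format = "float")
  write_tiff(v, paths["velocity"], sample_format = "float")
  write_tiff(map$dir_z, paths["dir_z"], sample_format = "float")
  write_tiff(map$dir_x, paths["dir_x"], sample_format = "float")
  invisible(paths)
}

#' Render a map raster to PNG for inspection
#'
#' Simple linear grayscale (or signed blue/red for direction) rendering.
#'
#' @param map a `vascular_map`.
#' @param path output PNG path.
#' @param what raster to render.
#' @export
render_map_png <- function(map, path, what = c("density", "velocity", "dir_z")) {
  what <- match.arg(what)
  m <- switch(what, density = sqrt(map$density),
              velocity = { v <- map$velocity; v[is.na(v)] <- 0; v },
              dir_z = map$dir_z)
  grDevices::png(path, width = ncol(m), height = nrow(m))
  op <- graphics::par(mar = c(0, 0, 0, 0))
  on.exit({ graphics::par(op); grDevices::dev.off() })
  if (what == "dir_z") {
    lim <- max(abs(m), 1e-9)
    cols <- grDevices::colorRampPalette(c("blue", "black", "red"))(255)
    graphics::image(t(m)[, nrow(m):1], col = cols, zlim = c(-lim, lim),
                    axes = FALSE, useRaster = TRUE)
  } else {
    graphics::image(t(m)[, nrow(m):1], col = grDevices::gray.colors(255, 0, 1),
                    axes = FALSE, useRaster = TRUE)
  }
  invisible(path)
}
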