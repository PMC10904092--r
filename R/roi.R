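# Regions of interest: a closed smooth curve through user-placed control
# vertices (Hobby's spline, the curve interpolation used by METAFONT-style
# path syntax), rasterized to a pixel mask by even-odd filling.

# Hobby's velocity function: distance from an endpoint to its Bezier control
# point, as a fraction of chord length, for departure/arrival angles (theta,
# phi) at tension 1.
.hobby_velocity <- function(theta, phi) {
  a <- sqrt(2)
  b <- 1 / 16
  c1 <- (3 - sqrt(5)) / 2
  num <- 2 + a * (sin(theta) - b * sin(phi)) * (sin(phi) - b * sin(theta)) *
    (cos(theta) - cos(phi))
  den <- 3 * (1 + (1 - c1) * cos(theta) + c1 * cos(phi))
  num / den
}

#' Smooth closed curve through control vertices (Hobby's algorithm)
#'
#' Solves the mock-curvature equations for the tangent direction at every
#' control vertex (tension 1, closed cycle) and emits the resulting chain of
#' cubic Bezier segments, densely sampled. The curve passes exactly through
#' every control vertex and is curvature-continuous in the linearized sense
#' that defines the method.
#'
#' @param vertices n x 2 matrix of control vertices `(z_um, x_um)`, n >= 3,
#'   no duplicate adjacent vertices (the closing edge counts as adjacent).
#' @param closed must be `TRUE` (only closed ROI outlines are supported).
#' @param n_per_segment samples per Bezier segment (>= 20).
#' @return matrix of curve points `(z_um, x_um)`; the first point is
#'   `vertices[1, ]` and the curve wraps (last sample != first).
#' @export
hobby_curve <- function(vertices, closed = TRUE, n_per_segment = 24L) {
  vertices <- as.matrix(vertices)
  n <- nrow(vertices)
  if (n < 3) stop("need at least 3 vertices")
  if (!isTRUE(closed)) stop("only closed curves are supported")
  if (n_per_segment < 20L) n_per_segment <- 20L
  nxt <- c(2:n, 1)
  chord <- vertices[nxt, , drop = FALSE] - vertices
  d <- sqrt(rowSums(chord^2))
  if (any(d < 1e-12)) stop("duplicate adjacent vertices")
  ang <- atan2(chord[, 2], chord[, 1])   # angle in (z, x) plane
  prv <- c(n, 1:(n - 1))
  # turning angle at vertex k: between incoming chord (k-1) and outgoing (k)
  psi <- ang - ang[prv]
  psi <- ((psi + pi) %% (2 * pi)) - pi
  # mock curvature equations, tension 1, closed cycle:
  # d_k theta_{k-1} + 2 (d_k + d_{k-1}) theta_k + d_{k-1} theta_{k+1}
  #   = -(2 psi_k d_k + psi_{k+1} d_{k-1})
  A <- matrix(0, n, n)
  rhs <- numeric(n)
  for (k in seq_len(n)) {
    km <- prv[k]; kp <- nxt[k]
    A[k, km] <- A[k, km] + d[k]
    A[k, k] <- A[k, k] + 2 * (d[k] + d[km])
    A[k, kp] <- A[k, kp] + d[km]
    rhs[k] <- -(2 * psi[k] * d[k] + psi[kp] * d[km])
  }
  theta <- solve(A, rhs)
  phi <- -psi - theta    # arrival angle at vertex k (segment k-1)
  t_seq <- seq(0, 1, length.out = n_per_segment + 1L)[-(n_per_segment + 1L)]
  pts <- vector("list", n)
  for (k in seq_len(n)) {
    kp <- nxt[k]
    th <- theta[k]
    ph <- phi[kp]
    dir_out <- ang[k] + th
    dir_in <- ang[k] - ph     # tangent angle at arrival vertex
    r <- d[k] * .hobby_velocity(th, ph)
    s <- d[k] * .hobby_velocity(ph, th)
    p0 <- vertices[k, ]
    p3 <- vertices[kp, ]
    p1 <- p0 + r * c(cos(dir_out), sin(dir_out))
    p2 <- p3 - s * c(cos(dir_in), sin(dir_in))
    u <- t_seq
    b <- cbind((1 - u)^3, 3 * u * (1 - u)^2, 3 * u^2 * (1 - u), u^3)
    pts[[k]] <- b %*% rbind(p0, p1, p2, p3)
  }
  out <- do.call(rbind, pts)
  colnames(out) <- c("z_um", "x_um")
  out
}

#' Rasterize a closed curve to a pixel mask (even-odd fill)
#'
#' A pixel centre is inside if a ray from it crosses the polygonal outline an
#' odd number of times (scanline crossing count, half-open edge rule so
#' shared vertices are not double-counted).
#'
#' @param curve matrix of points `(z_um, x_um)` describing a closed outline
#'   (last point connects back to the first).
#' @param grid list with `nz`, `nx`, `spacing_um` (scalar).
#' @return logical matrix `[nz, nx]`.
#' @export
rasterize_roi <- function(curve, grid) {
  curve <- as.matrix(curve)
  if (nrow(curve) < 3) stop("open or degenerate curve")
  if (sum((curve[1, ] - curve[nrow(curve), ])^2) < 1e-18) {
    curve <- curve[-nrow(curve), , drop = FALSE]   # drop duplicated closure
  }
  nz <- grid$nz; nx <- grid$nx
  sp <- grid$spacing_um
  if (length(sp) > 1L) sp <- sp[1]
  zs <- curve[, 1]; xs <- curve[, 2]
  z2 <- c(zs[-1], zs[1]); x2 <- c(xs[-1], xs[1])
  mask <- matrix(FALSE, nz, nx)
  # scan over rows (constant z = pixel-centre depth), crossing count in x
  for (i in seq_len(nz)) {
    zc <- (i - 1) * sp
    crosses <- (zs <= zc & z2 > zc) | (z2 <= zc & zs > zc)
    if (!any(crosses)) next
    t <- (zc - zs[crosses]) / (z2[crosses] - zs[crosses])
    xc <- xs[crosses] + t * (x2[crosses] - xs[crosses])
    xc <- sort(xc)
    for (p in seq(1, length(xc) - 1, by = 2)) {
      j1 <- ceiling(xc[p] / sp - 1e-9) + 1L
      j2 <- floor(xc[p + 1] / sp + 1e-9) + 1L
      if (j2 >= j1) {
        j1 <- max(j1, 1L); j2 <- min(j2, nx)
        if (j1 <= j2) mask[i, j1:j2] <- TRUE
      }
    }
  }
  mask
}

#' ROI polygon: control vertices, Hobby outline and raster mask
#'
#' @param vertices_um control vertices (n x 2, `(z_um, x_um)`).
#' @param grid map grid (list `nz`, `nx`, `spacing_um`).
#' @param label region label, e.g. `"IC"`, `"EC"`, `"HC"` or custom.
#' @param surface_normal optional unit vector `(z, x)` pointing from the
#'   cortical surface into the brain (needed for arteriole/venule splitting).
#' @return object of class `roi_polygon` with `vertices_um`, `curve`,
#'   `mask`, `label`, `surface_normal`, `grid`.
#' @export
roi_polygon <- function(vertices_um, grid, label = "custom",
                        surface_normal = NULL) {
  curve <- hobby_curve(vertices_um)
  mask <- rasterize_roi(curve, grid)
  if (!any(mask)) stop("ROI mask has zero area on this grid")
  if (!is.null(surface_normal)) {
    surface_normal <- surface_normal / sqrt(sum(surface_normal^2))
  }
  structure(list(vertices_um = as.matrix(vertices_um), curve = curve,
                 mask = mask, label = label, surface_normal = surface_normal,
                 grid = grid),
            class = "roi_polygon")
}

#' @export
print.roi_polygon <- function(x, ...) {
  cat(sprintf("<roi_polygon> '%s': %d vertices, mask area %d px\n",
              x$label, nrow(x$vertices_um), sum(x$mask)))
  invisible(x)
}

#' Read / write ROI definitions as JSON
#'
#' The JSON schema is a list of objects with fields `label`,
#' `vertices_um` (n x 2 array) and optional `surface_normal`.
#'
#' @param path JSON file path.
#' @param grid map grid used to rasterize each ROI.
#' @return list of `roi_polygon`.
#' @export
read_rois <- function(path, grid) {
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.data.frame(spec)) spec <- split(spec, seq_len(nrow(spec)))
  lapply(spec, function(s) {
    v <- matrix(unlist(s$vertices_um), ncol = 2, byrow = FALSE)
    sn <- s$surface_normal
    if (is.list(sn)) sn <- unlist(sn)
    roi_polygon(v, grid, label = s$label %||% "custom",
                surface_normal = if (length(sn)) as.numeric(sn) else NULL)
  })
}

#' @rdname read_rois
#' @param rois list of `roi_polygon`.
#' @export
write_rois <- function(rois, path) {
  out <- lapply(rois, function(r) {
    list(label = r$label, vertices_um = unclass(r$vertices_um),
         surface_normal = r$surface_normal)
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
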