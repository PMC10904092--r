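#' Gaussian point-spread-function model
#'
#' The system PSF is modelled as an elliptical 2D Gaussian with independent
#' axial and lateral sigmas (micrometres).
#'
#' @param sigma_um `c(axial, lateral)` Gaussian sigmas in micrometres.
#' @param amplitude peak amplitude (a.u.).
#' @param residual_rms fit residual (populated by [fit_psf()]).
#' @return object of class `psf_model`.
#' @export
psf_model <- function(sigma_um, amplitude = 1, residual_rms = NA_real_) {
  if (any(sigma_um <= 0)) stop("PSF sigmas must be positive")
  structure(list(sigma_um = as.numeric(sigma_um), amplitude = amplitude,
                 residual_rms = residual_rms),
            class = "psf_model")
}

#' @export
print.psf_model <- function(x, ...) {
  cat(sprintf("<psf_model> sigma (axial, lateral) = (%.2f, %.2f) um, amp %.3g\n",
              x$sigma_um[1], x$sigma_um[2], x$amplitude))
  invisible(x)
}

#' Rasterize a PSF model onto a grid
#'
#' Odd-sized kernel with its peak exactly at the geometric centre pixel.
#'
#' @param psf a `psf_model`.
#' @param spacing_um pixel spacing `c(axial, lateral)` or scalar.
#' @param radius_sigmas kernel half-extent in sigmas.
#' @return numeric matrix with odd dimensions.
#' @export
psf_kernel <- function(psf, spacing_um, radius_sigmas = 3) {
  if (length(spacing_um) == 1L) spacing_um <- rep(spacing_um, 2L)
  hz <- max(1L, ceiling(radius_sigmas * psf$sigma_um[1] / spacing_um[1]))
  hx <- max(1L, ceiling(radius_sigmas * psf$sigma_um[2] / spacing_um[2]))
  gz <- exp(-((-hz:hz) * spacing_um[1])^2 / (2 * psf$sigma_um[1]^2))
  gx <- exp(-((-hx:hx) * spacing_um[2])^2 / (2 * psf$sigma_um[2]^2))
  psf$amplitude * outer(gz, gx)
}

#' Fit the empirical PSF from bubble patches
#'
#' Least-squares fit of `A exp(-(z-z0)^2/2sz^2 - (x-x0)^2/2sx^2) + b` to each
#' magnitude patch (Nelder-Mead from moment-based starts); the model sigmas
#' are the medians across patches that converged. Patches whose fit fails or
#' diverges are excluded; at least one must survive.
#'
#' @param patches list of magnitude matrices, each containing one dominant
#'   isolated bubble (>= 3 patches).
#' @param spacing_um pixel spacing `c(axial, lateral)` or scalar.
#' @return a `psf_model` with `residual_rms` = mean across kept patches;
#'   attribute `n_used` gives the number of patches kept.
#' @export
fit_psf <- function(patches, spacing_um) {
  if (length(patches) < 3) stop("need at least 3 patches")
  if (length(spacing_um) == 1L) spacing_um <- rep(spacing_um, 2L)
  fits <- lapply(patches, function(p) {
    tryCatch(.fit_gauss2d(p, spacing_um), error = function(e) NULL)
  })
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("PSF fit diverged on all patches")
  fits <- fits[ok]
  sig <- vapply(fits, function(f) f$sigma_um, numeric(2))
  amp <- stats::median(vapply(fits, function(f) f$amplitude, numeric(1)))
  rms <- mean(vapply(fits, function(f) f$rms, numeric(1)))
  out <- psf_model(apply(sig, 1, stats::median), amplitude = amp,
                   residual_rms = rms)
  attr(out, "n_used") <- sum(ok)
  out
}

.fit_gauss2d <- function(patch, spacing_um) {
  if (!all(is.finite(patch))) stop("non-finite patch")
  if (max(patch) <= min(patch)) stop("flat patch")
  z <- (seq_len(nrow(patch)) - 1) * spacing_um[1]
  x <- (seq_len(ncol(patch)) - 1) * spacing_um[2]
  w <- pmax(patch - min(patch), 0)
  sw <- sum(w)
  z0 <- sum(w * z) / sw                       # z varies along rows
  x0 <- sum(t(w) * x) / sw
  sz0 <- sqrt(max(sum(w * (z - z0)^2) / sw, spacing_um[1]^2 / 12))
  sx0 <- sqrt(max(sum(t(w) * (x - x0)^2) / sw, spacing_um[2]^2 / 12))
  zz <- matrix(z, nrow(patch), ncol(patch))
  xx <- matrix(x, nrow(patch), ncol(patch), byrow = TRUE)
  obj <- function(par) {
    a <- par[1]; b <- par[2]; mz <- par[3]; mx <- par[4]
    sz <- exp(par[5]); sx <- exp(par[6])
    m <- a * exp(-(zz - mz)^2 / (2 * sz^2) - (xx - mx)^2 / (2 * sx^2)) + b
    sum((m - patch)^2)
  }
  start <- c(max(patch) - min(patch), min(patch), z0, x0, log(sz0), log(sx0))
  fit <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  sig <- exp(fit$par[5:6])
  if (fit$par[1] <= 0 || any(!is.finite(sig)) ||
      any(sig > 10 * max(diff(range(z)), diff(range(x)))))
    stop("fit diverged")
  list(sigma_um = sig, amplitude = fit$par[1],
       rms = sqrt(fit$value / length(patch)))
}

#' Separate overlapping bubbles into sparse component frames
#'
#' Matching pursuit against the PSF: iteratively take the global maximum of
#' the residual magnitude frame, record a detection, subtract the
#' amplitude-scaled PSF there, and stop when the residual maximum falls below
#' `threshold`. Detections are then partitioned round-robin (in order of
#' decreasing amplitude) into component frames such that no two detections
#' within one component are closer than `min_sep_fwhm` times the PSF FWHM;
#' each component frame is the clean re-render of its detections.
#'
#' @param frame magnitude matrix (post-SVD, upsampling not required).
#' @param psf a `psf_model`.
#' @param spacing_um pixel spacing of `frame`.
#' @param threshold residual stopping level; default 25% of the frame
#'   maximum.
#' @param max_iters maximum pursuit iterations.
#' @param min_sep_fwhm minimum intra-component separation in PSF FWHMs.
#' @return list of component frames (possibly empty); attribute
#'   `detections` is a data.frame `(z_um, x_um, amplitude, component)`.
#' @export
separate_bubbles <- function(frame, psf, spacing_um, threshold = NULL,
                             max_iters = 100L, min_sep_fwhm = 2) {
  if (length(spacing_um) == 1L) spacing_um <- rep(spacing_um, 2L)
  if (is.null(threshold)) threshold <- 0.25 * max(frame)
  kern <- psf_kernel(psf, spacing_um) / psf$amplitude
  hz <- (nrow(kern) - 1L) %/% 2L
  hx <- (ncol(kern) - 1L) %/% 2L
  res <- frame
  det <- list()
  prev_max <- Inf
  for (it in seq_len(max_iters)) {
    m <- max(res)
    if (m < threshold || m <= 0) break
    if (m > prev_max * 1.5) stop("matching pursuit diverged (residual growth)")
    prev_max <- m
    p <- arrayInd(which.max(res), dim(res))
    iz <- max(1L, p[1] - hz):min(nrow(res), p[1] + hz)
    ix <- max(1L, p[2] - hx):min(ncol(res), p[2] + hx)
    res[iz, ix] <- res[iz, ix] - m * kern[iz - p[1] + hz + 1L, ix - p[2] + hx + 1L]
    det[[it]] <- c(z = (p[1] - 1) * spacing_um[1], x = (p[2] - 1) * spacing_um[2],
                   amp = m)
  }
  if (length(det) == 0) return(structure(list(), detections = NULL))
  det <- as.data.frame(do.call(rbind, det))
  names(det) <- c("z_um", "x_um", "amplitude")
  det <- det[order(-det$amplitude), , drop = FALSE]
  fwhm <- 2 * sqrt(2 * log(2)) * max(psf$sigma_um)
  min_d2 <- (min_sep_fwhm * fwhm)^2
  comp_of <- integer(nrow(det))
  comps <- list()   # positions per component
  for (i in seq_len(nrow(det))) {
    placed <- FALSE
    for (ci in seq_along(comps)) {
      d2 <- (comps[[ci]][, 1] - det$z_um[i])^2 + (comps[[ci]][, 2] - det$x_um[i])^2
      if (all(d2 >= min_d2)) {
        comps[[ci]] <- rbind(comps[[ci]], c(det$z_um[i], det$x_um[i]))
        comp_of[i] <- ci
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      comps[[length(comps) + 1L]] <- matrix(c(det$z_um[i], det$x_um[i]), 1)
      comp_of[i] <- length(comps)
    }
  }
  det$component <- comp_of
  frames <- lapply(seq_along(comps), function(ci) {
    f <- matrix(0, nrow(frame), ncol(frame))
    for (i in which(comp_of == ci)) {
      pz <- round(det$z_um[i] / spacing_um[1]) + 1L
      px <- round(det$x_um[i] / spacing_um[2]) + 1L
      iz <- max(1L, pz - hz):min(nrow(f), pz + hz)
      ix <- max(1L, px - hx):min(ncol(f), px + hx)
      f[iz, ix] <- f[iz, ix] +
        det$amplitude[i] * kern[iz - pz + hz + 1L, ix - px + hx + 1L]
    }
    f
  })
  structure(frames, detections = det)
}

# natural-cubic-spline interpolation matrix from n input samples (spacing
# `h_in`) onto the output grid (spacing `h_out`, same origin); cached
.spline_cache <- new.env(parent = emptyenv())
.spline_matrix <- function(n, h_in, h_out) {
  key <- paste(n, h_in, h_out, sep = "|")
  if (!is.null(.spline_cache[[key]])) return(.spline_cache[[key]])
  x_in <- (seq_len(n) - 1) * h_in
  x_out <- seq(0, x_in[n], by = h_out)
  M <- vapply(seq_len(n), function(i) {
    e <- numeric(n); e[i] <- 1
    stats::spline(x_in, e, xout = x_out, method = "natural")$y
  }, numeric(length(x_out)))
  .spline_cache[[key]] <- M
  M
}

#' Upsample a frame by 2D cubic-spline interpolation
#'
#' Separable natural cubic splines onto an isotropic target grid (default the
#' 4.928 um map grid). Values at the original sample locations are preserved
#' exactly (spline interpolation). The interpolation is a fixed linear map,
#' precomputed per (size, spacing) pair, so per-frame cost is two small
#' matrix products.
#'
#' @param frame numeric matrix.
#' @param in_spacing_um input pixel spacing (scalar or `c(axial, lateral)`).
#' @param out_spacing_um output isotropic spacing; must be <= input spacing.
#' @return upsampled matrix; attribute `spacing_um` carries the new spacing.
#' @export
upsample_frame <- function(frame, in_spacing_um, out_spacing_um = 4.928) {
  if (length(in_spacing_um) == 1L) in_spacing_um <- rep(in_spacing_um, 2L)
  if (out_spacing_um <= 0 || any(in_spacing_um <= 0))
    stop("spacings must be positive")
  if (any(out_spacing_um > in_spacing_um + 1e-12))
    stop("output spacing must be <= input spacing")
  if (all(abs(in_spacing_um - out_spacing_um) < 1e-12)) {
    attr(frame, "spacing_um") <- rep(out_spacing_um, 2L)
    return(frame)
  }
  Mz <- .spline_matrix(nrow(frame), in_spacing_um[1], out_spacing_um)
  Mx <- .spline_matrix(ncol(frame), in_spacing_um[2], out_spacing_um)
  out <- Mz %*% frame %*% t(Mx)
  attr(out, "spacing_um") <- rep(out_spacing_um, 2L)
  out
}

# zero-normalized cross-correlation of `frame` with kernel (odd dims);
# returns a map the size of `frame`, NA where the window leaves the frame
.zncc <- function(frame, kern) {
  nf <- dim(frame); nk <- dim(kern)
  if (any(nk > nf)) stop("PSF kernel larger than frame")
  k0 <- kern - mean(kern)
  k_norm <- sqrt(sum(k0^2))
  if (k_norm == 0) stop("flat kernel")
  n_win <- prod(nk)
  # FFT cross-correlation (kernel not flipped): valid size nf - nk + 1
  sz <- c(stats::nextn(nf[1] + nk[1] - 1, c(2, 3, 5)),
          stats::nextn(nf[2] + nk[2] - 1, c(2, 3, 5)))
  pad <- function(m) {
    p <- matrix(0, sz[1], sz[2]); p[seq_len(nrow(m)), seq_len(ncol(m))] <- m; p
  }
  F1 <- stats::fft(pad(frame))
  num_full <- Re(stats::fft(F1 * Conj(stats::fft(pad(k0))), inverse = TRUE)) / prod(sz)
  # local sums of frame and frame^2 over the kernel window via integral images
  s1 <- .box_sum(frame, nk)
  s2 <- .box_sum(frame^2, nk)
  denom2 <- pmax(s2 - s1^2 / n_win, 0)
  valid <- num_full[seq_len(nf[1] - nk[1] + 1), seq_len(nf[2] - nk[2] + 1)]
  ncc_valid <- valid / (sqrt(denom2) * k_norm)
  ncc_valid[denom2 <= (1e-12 * max(s2, 1))] <- 0
  ncc_valid <- pmin(pmax(ncc_valid, -1), 1)
  out <- matrix(NA_real_, nf[1], nf[2])
  hz <- (nk[1] - 1L) %/% 2L; hx <- (nk[2] - 1L) %/% 2L
  out[(hz + 1):(nf[1] - hz), (hx + 1):(nf[2] - hx)] <- ncc_valid
  out
}

# sums over sliding window of size nk (valid positions) via cumsum integral
.box_sum <- function(m, nk) {
  ii <- apply(apply(m, 2, cumsum), 1, cumsum)  # transposed integral image
  ii <- t(ii)
  ii <- rbind(0, cbind(0, ii))
  nr <- nrow(m) - nk[1] + 1L
  ncl <- ncol(m) - nk[2] + 1L
  r1 <- seq_len(nr); c1 <- seq_len(ncl)
  ii[r1 + nk[1], c1 + nk[2], drop = FALSE] - ii[r1, c1 + nk[2], drop = FALSE] -
    ii[r1 + nk[1], c1, drop = FALSE] + ii[r1, c1, drop = FALSE]
}

# 8-connected regional maxima of `m` (NA treated as -Inf); ties within a
# plateau resolved to the lexicographically first pixel
.regional_maxima <- function(m) {
  mm <- m
  mm[is.na(mm)] <- -Inf
  nr <- nrow(mm); nc <- ncol(mm)
  big <- matrix(-Inf, nr + 2L, nc + 2L)
  big[2:(nr + 1), 2:(nc + 1)] <- mm
  ctr <- big[2:(nr + 1), 2:(nc + 1)]
  is_max <- ctr > -Inf
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- big[2:(nr + 1) + dr, 2:(nc + 1) + dc]
    # strict inequality against earlier neighbours breaks plateau ties
    if (dr < 0 || (dr == 0 && dc < 0)) {
      is_max <- is_max & (ctr > nb)
    } else {
      is_max <- is_max & (ctr >= nb)
    }
  }
  which(is_max, arr.ind = TRUE)
}

#' Localize microbubbles in one upsampled frame
#'
#' Zero-normalized 2D cross-correlation of the magnitude frame with the PSF
#' kernel; candidate pixels are 8-connected regional maxima of the
#' correlation map with coefficient at or above `ncc_threshold`; each
#' candidate is refined to sub-pixel precision by per-axis quadratic
#' (parabolic) interpolation of the correlation peak.
#'
#' @param frame magnitude matrix (already upsampled).
#' @param psf a `psf_model`.
#' @param spacing_um pixel spacing of `frame` (scalar or pair); defaults to
#'   the `spacing_um` attribute left by [upsample_frame()].
#' @param ncc_threshold minimum correlation coefficient (default 0.6).
#' @return data.frame `(z_um, x_um, ncc)`, zero rows if nothing qualifies.
#' @export
localize_frame <- function(frame, psf, spacing_um = NULL, ncc_threshold = 0.6) {
  if (is.null(spacing_um)) spacing_um <- attr(frame, "spacing_um")
  if (is.null(spacing_um)) stop("spacing_um required")
  if (length(spacing_um) == 1L) spacing_um <- rep(spacing_um, 2L)
  kern <- psf_kernel(psf, spacing_um)
  ncc <- .zncc(frame, kern)
  if (ncc_threshold > 1) {
    return(data.frame(z_um = numeric(), x_um = numeric(), ncc = numeric()))
  }
  pk <- .regional_maxima(ncc)
  if (nrow(pk)) pk <- pk[ncc[pk] >= ncc_threshold, , drop = FALSE]
  if (!nrow(pk)) {
    return(data.frame(z_um = numeric(), x_um = numeric(), ncc = numeric()))
  }
  nr <- nrow(frame); nc <- ncol(frame)
  # per-axis quadratic interpolation of the correlation peak: the NCC peak
  # is broad relative to the 4.928 um grid, so a plain 3x3 weighted centroid
  # stays essentially pinned to the grid (~0.6 px median bias), which in
  # turn biases frame-to-frame speeds; the parabolic vertex of the three
  # samples bracketing the maximum removes that quantization
  para <- function(m1, m0, p1) {
    den <- m1 - 2 * m0 + p1
    if (!is.finite(den) || den >= 0) return(0)
    max(min(0.5 * (m1 - p1) / den, 0.5), -0.5)
  }
  zs <- xs <- cs <- numeric(nrow(pk))
  for (i in seq_len(nrow(pk))) {
    r <- pk[i, 1]; c <- pk[i, 2]
    dz <- if (r > 1 && r < nr && !anyNA(ncc[(r - 1):(r + 1), c]))
      para(ncc[r - 1, c], ncc[r, c], ncc[r + 1, c]) else 0
    dx <- if (c > 1 && c < nc && !anyNA(ncc[r, (c - 1):(c + 1)]))
      para(ncc[r, c - 1], ncc[r, c], ncc[r, c + 1]) else 0
    zs[i] <- (r - 1 + dz) * spacing_um[1]
    xs[i] <- (c - 1 + dx) * spacing_um[2]
    cs[i] <- ncc[r, c]
  }
  data.frame(z_um = zs, x_um = xs, ncc = cs)
}

#' Localize microbubbles in every frame of a stack
#'
#' Convenience wrapper: per frame, take the magnitude, optionally run
#' [separate_bubbles()], upsample each (component) frame to the map grid and
#' run [localize_frame()]. Localizations from all components of one frame are
#' pooled.
#'
#' @param stack a clutter-filtered `iq_stack`.
#' @param psf a `psf_model`.
#' @param out_spacing_um target isotropic grid spacing (default 4.928).
#' @param ncc_threshold correlation threshold.
#' @param separate logical: apply bubble separation before localization.
#' @param separation_threshold forwarded to [separate_bubbles()] (`NULL` =
#'   per-frame default of 25% of the frame maximum).
#' @return data.frame `(frame, z_um, x_um, ncc)`.
#' @export
localize_stack <- function(stack, psf, out_spacing_um = 4.928,
                           ncc_threshold = 0.6, separate = FALSE,
                           separation_threshold = NULL) {
  stopifnot(inherits(stack, "iq_stack"))
  nt <- n_frames(stack)
  res <- vector("list", nt)
  for (t in seq_len(nt)) {
    mag <- Mod(stack$data[, , t])
    frames <- if (separate) {
      separate_bubbles(mag, psf, stack$spacing_um,
                       threshold = separation_threshold)
    } else list(mag)
    locs <- lapply(frames, function(f) {
      up <- upsample_frame(f, stack$spacing_um, out_spacing_um)
      localize_frame(up, psf, ncc_threshold = ncc_threshold)
    })
    locs <- do.call(rbind, locs)
    if (!is.null(locs) && nrow(locs)) {
      locs$frame <- t
      res[[t]] <- locs[, c("frame", "z_um", "x_um", "ncc")]
    }
  }
  out <- do.call(rbind, res)
  if (is.null(out)) out <- data.frame(frame = integer(), z_um = numeric(),
                                      x_um = numeric(), ncc = numeric())
  rownames(out) <- NULL
  out
}
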