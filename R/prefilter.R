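# Clutter/noise separation on the Casorati matrix. The stack [nz, nx, nt] is
# reshaped to X (space x time); because nt << nz*nx in practice, the
# decomposition works through the nt x nt Gram matrix X^H X: its eigenvectors
# are the temporal singular vectors and the eigenvalues the squared singular
# values. Tissue occupies the leading (high-energy, temporally coherent)
# components; bubbles and noise the trailing ones.

.casorati <- function(stack) {
  d <- dim(stack$data)
  matrix(stack$data, nrow = d[1] * d[2], ncol = d[3])
}

.temporal_svd <- function(X) {
  G <- crossprod(Conj(X), X)            # X^H X, Hermitian nt x nt
  e <- eigen(G, symmetric = TRUE)
  sv <- sqrt(pmax(Re(e$values), 0))
  list(singular_values = sv, V = e$vectors)
}

#' SVD clutter filter
#'
#' Removes the leading singular components (tissue clutter) of the
#' space-by-time Casorati matrix. The cutoff is either fixed or selected
#' adaptively from the singular-value spectrum (see
#' [adaptive_rank_select()]); the filtered stack is the reconstruction from
#' components with index strictly greater than the cutoff.
#'
#' @param stack an `iq_stack` with at least 2 frames.
#' @param rank_mode `"adaptive"` or `"fixed"`.
#' @param rank cutoff for `rank_mode = "fixed"` (0 returns the input
#'   unchanged); must be < number of frames.
#' @param n_spatial number of leading spatial singular vectors to retain in
#'   the decomposition object (for inspection).
#' @return list with `stack` (filtered `iq_stack`) and `decomposition`
#'   (class `svd_decomposition`: `singular_values` descending, `cutoff`,
#'   temporal vectors `V`, and a few spatial vectors reshaped to images).
#' @export
svd_filter <- function(stack, rank_mode = c("adaptive", "fixed"), rank = NULL,
                       n_spatial = 6L) {
  rank_mode <- match.arg(rank_mode)
  stopifnot(inherits(stack, "iq_stack"))
  d <- dim(stack$data)
  if (d[3] < 2) stop("need at least 2 frames")
  X <- .casorati(stack)
  ts <- .temporal_svd(X)
  cutoff <- if (rank_mode == "fixed") {
    if (is.null(rank)) stop("rank_mode = 'fixed' requires `rank`")
    if (rank >= d[3]) stop("rank must be < n_frames")
    as.integer(rank)
  } else {
    adaptive_rank_select(ts$singular_values)
  }
  if (cutoff > 0) {
    Vc <- ts$V[, seq_len(cutoff), drop = FALSE]
    Xf <- X - (X %*% Vc) %*% Conj(t(Vc))
  } else {
    Xf <- X
  }
  n_sp <- min(n_spatial, d[3])
  sv_safe <- pmax(ts$singular_values[seq_len(n_sp)], .Machine$double.eps)
  U <- sweep(X %*% ts$V[, seq_len(n_sp), drop = FALSE], 2, sv_safe, "/")
  spatial <- lapply(seq_len(n_sp), function(k) matrix(U[, k], d[1], d[2]))
  dec <- structure(list(singular_values = ts$singular_values,
                        cutoff = cutoff, V = ts$V, spatial = spatial),
                   class = "svd_decomposition")
  list(stack = iq_stack(array(Xf, dim = d), stack$spacing_um, stack$frame_rate),
       decomposition = dec)
}

#' @export
print.svd_decomposition <- function(x, ...) {
  cat(sprintf("<svd_decomposition> %d components, cutoff %d (removed %.1f%% energy)\n",
              length(x$singular_values), x$cutoff,
              100 * sum(x$singular_values[seq_len(x$cutoff)]^2) /
                sum(x$singular_values^2)))
  invisible(x)
}

#' Adaptive singular-value cutoff (log-spectrum knee)
#'
#' Selects the tissue/bubble cutoff as the most prominent knee of the
#' log10 singular-value spectrum: the index after which the largest
#' multiplicative drop (largest gap between consecutive log10 values)
#' occurs. Tissue clutter concentrates orders of magnitude of energy in a
#' few leading components, so the tissue/bubble boundary is the dominant
#' log-gap; a chord-to-curve distance rule is not used because a slowly
#' decaying bubble/noise tail moves the global chord knee far into the
#' tail (see the methods vignette). The gap must be prominent -- at least
#' 0.15 decades and 3x the median gap -- otherwise the spectrum is flagged
#' degenerate (all-equal or log-linear spectra have no knee).
#'
#' @param singular_values non-increasing, non-negative, length >= 8.
#' @return integer cutoff in `[1, n)`.
#' @export
adaptive_rank_select <- function(singular_values) {
  n <- length(singular_values)
  if (n < 8) stop("need at least 8 singular values")
  sv <- pmax(singular_values, max(singular_values) * 1e-15)
  y <- log10(sv)
  if (diff(range(y)) < 1e-12) stop("degenerate spectrum: all singular values equal")
  gaps <- -diff(y)                       # >= 0 up to numerical error
  gmax <- max(gaps)
  if (gmax < 0.15 || gmax < 3 * stats::median(gaps))
    stop("degenerate spectrum: no prominent knee (log-spectrum is near-linear)")
  # the tissue/bubble boundary is the LAST prominent gap: clutter components
  # may be separated by large internal gaps, but below the boundary the
  # bubble/noise spectrum decays gently
  prominent <- which(gaps >= pmax(0.15, 0.5 * gmax))
  cutoff <- max(prominent)
  as.integer(min(max(cutoff, 1L), n - 1L))
}

#' Noise profile over depth
#'
#' Per-depth amplitude gain of the additive noise of a clutter-filtered
#' stack, estimated as the per-depth median magnitude over all lateral
#' positions and frames (median-smoothed over 9 depth samples, normalized to
#' mean 1). Bubbles are sparse in space-time, so the median tracks the
#' Rayleigh noise level, which is proportional to the noise sigma at each
#' depth. (An estimator based on the trailing quartile of singular
#' components was tried first but is biased: the adaptively fitted leading
#' components absorb proportionally more variance at noisier depths, which
#' compresses the recovered profile.)
#'
#' @param stack an `iq_stack` (clutter already removed).
#' @return object of class `noise_profile` (positive numeric vector, one gain
#'   per depth sample).
#' @export
estimate_noise_profile <- function(stack) {
  d <- dim(stack$data)
  g <- apply(matrix(Mod(stack$data), nrow = d[1]), 1, stats::median)
  g <- stats::runmed(g, k = min(9L, 2L * (d[1] %/% 2L) - 1L))
  g <- pmax(g / mean(g), 1e-6)
  noise_profile(g)
}

#' @rdname estimate_noise_profile
#' @param gain positive per-depth gain vector.
#' @export
noise_profile <- function(gain) {
  if (any(gain <= 0)) stop("noise profile must be strictly positive")
  jump <- abs(diff(gain)) / pmax(gain[-length(gain)], .Machine$double.eps)
  if (any(jump > 0.5)) stop("noise profile not smooth (sample-to-sample jump > 50%)")
  structure(as.numeric(gain), class = "noise_profile")
}

#' Depth noise equalization
#'
#' Divides the stack depth-wise by the per-depth noise gain so that bubble
#' intensity (and residual noise) is comparable through the whole imaging
#' depth. If no profile is supplied it is estimated with
#' [estimate_noise_profile()].
#'
#' @param stack an `iq_stack`.
#' @param profile optional `noise_profile` (length = number of depth
#'   samples).
#' @return equalized `iq_stack` with the profile attached as attribute
#'   `noise_profile`.
#' @export
noise_equalize <- function(stack, profile = NULL) {
  stopifnot(inherits(stack, "iq_stack"))
  d <- dim(stack$data)
  if (is.null(profile)) profile <- estimate_noise_profile(stack)
  if (length(profile) != d[1]) stop("profile length must equal depth samples")
  if (any(profile <= 0)) stop("noise profile must be strictly positive")
  out <- stack$data / as.numeric(profile)   # recycles along depth (dim 1)
  res <- iq_stack(out, stack$spacing_um, stack$frame_rate)
  attr(res, "noise_profile") <- profile
  res
}

#' Power-Doppler image
#'
#' Pixelwise temporal mean of `|IQ|^2` of a (clutter-filtered) stack;
#' proportional to local blood volume.
#'
#' @param stack an `iq_stack` with at least one frame.
#' @return non-negative matrix `[nz, nx]`.
#' @export
power_doppler <- function(stack) {
  stopifnot(inherits(stack, "iq_stack"))
  d <- dim(stack$data)
  if (d[3] < 1) stop("empty stack")
  rowMeans(matrix(Mod(stack$data)^2, nrow = d[1] * d[2])) |>
    matrix(nrow = d[1], ncol = d[2])
}

#' Heart-rate estimate from power-Doppler pulsatility
#'
#' The per-frame spatial-mean power series is detrended and its periodogram
#' searched for a peak inside the physiological band; the heart rate is 60
#' times the peak frequency, refined by quadratic interpolation of the
#' log-periodogram around the peak bin.
#'
#' @param stack an `iq_stack` (record length of at least 2 s recommended).
#' @param band_bpm search band in beats per minute.
#' @param min_prominence required ratio of peak power to the median in-band
#'   power; below this the series is considered flat and an error is raised.
#' @return heart rate in BPM.
#' @export
estimate_heart_rate <- function(stack, band_bpm = c(240, 600),
                                min_prominence = 8) {
  stopifnot(inherits(stack, "iq_stack"))
  d <- dim(stack$data)
  s <- colMeans(matrix(Mod(stack$data)^2, nrow = d[1] * d[2]))
  n <- length(s)
  if (n < 2 * stack$frame_rate)
    warning("record shorter than 2 s; heart-rate resolution will be poor")
  s <- s - mean(s)
  tt <- seq_along(s)
  s <- stats::lm.fit(cbind(1, tt), s)$residuals   # linear detrend
  pg <- Mod(stats::fft(s))^2 / n
  freq <- (seq_len(n) - 1) * stack$frame_rate / n
  half <- seq(2L, floor(n / 2))
  in_band <- half[freq[half] * 60 >= band_bpm[1] & freq[half] * 60 <= band_bpm[2]]
  if (length(in_band) < 3) stop("record too short for the requested band")
  p_band <- pg[in_band]
  if (max(p_band) <= 0 || max(p_band) < min_prominence * stats::median(p_band))
    stop("no pulsatility peak above the noise floor")
  k <- in_band[which.max(p_band)]
  # quadratic interpolation on log power around the peak bin
  delta <- 0
  if (k > 2 && k < floor(n / 2)) {
    lp <- log(pmax(pg[(k - 1):(k + 1)], .Machine$double.xmin))
    den <- lp[1] - 2 * lp[2] + lp[3]
    if (den < 0) delta <- 0.5 * (lp[1] - lp[3]) / den
    delta <- max(min(delta, 0.5), -0.5)
  }
  60 * (k - 1 + delta) * stack$frame_rate / n
}
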