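#' Beamformed IQ frame stack
#'
#' Container for a stack of beamformed in-phase/quadrature (IQ) ultrasound
#' frames, the raw input of the ULM pipeline. Frames are complex matrices on
#' a regular (depth z, lateral x) grid acquired at a fixed frame rate.
#'
#' Coordinate convention (used throughout the package): axial `z` increases
#' with depth, lateral `x` increases rightward; positions are in micrometres
#' relative to the top-left pixel centre, so pixel `(i, j)` sits at
#' `((i-1) * dz, (j-1) * dx)`.
#'
#' @param data complex (or numeric) 3D array `[nz, nx, n_frames]`.
#' @param spacing_um pixel spacing in micrometres, length-2 `c(axial, lateral)`
#'   or a scalar for isotropic grids.
#' @param frame_rate frame rate in Hz.
#' @return An object of class `iq_stack`.
#' @export
iq_stack <- function(data, spacing_um, frame_rate) {
  if (length(dim(data)) != 3L) stop("`data` must be a 3D array [nz, nx, n_frames]")
  if (!is.complex(data)) storage.mode(data) <- "complex"
  if (any(!is.finite(Re(data))) || any(!is.finite(Im(data))))
    stop("IQ data must be finite")
  if (length(spacing_um) == 1L) spacing_um <- rep(spacing_um, 2L)
  if (any(spacing_um <= 0)) stop("pixel spacing must be positive")
  if (frame_rate <= 0) stop("frame rate must be positive")
  structure(
    list(data = data, spacing_um = as.numeric(spacing_um),
         frame_rate = as.numeric(frame_rate)),
    class = "iq_stack"
  )
}

#' @export
print.iq_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<iq_stack> %d x %d px (%.3f x %.3f um), %d frames @ %g Hz\n",
    d[1], d[2], x$spacing_um[1], x$spacing_um[2], d[3], x$frame_rate))
  invisible(x)
}

#' @export
dim.iq_stack <- function(x) dim(x$data)

n_frames <- function(stack) dim(stack$data)[3]

#' Total signal energy of an IQ stack
#'
#' Sum of squared magnitudes over all pixels and frames; used for the energy
#' partition checks around SVD filtering.
#'
#' @param stack an `iq_stack`.
#' @return scalar energy.
#' @export
iq_energy <- function(stack) sum(Mod(stack$data)^2)

#' Write / read an IQ stack as flat binary + JSON sidecar
#'
#' Portable runtime storage for IQ stacks: a little-endian float32 binary
#' file with interleaved real/imaginary samples in R array order, plus a
#' JSON header (`<path>.json`) carrying dimensions, pixel spacing and frame
#' rate. (No HDF5 binding is assumed to be available.)
#'
#' @param stack an `iq_stack`.
#' @param path output path for the binary payload.
#' @return `write_iq` returns `path` invisibly; `read_iq` returns an
#'   `iq_stack`.
#' @export
write_iq <- function(stack, path) {
  stopifnot(inherits(stack, "iq_stack"))
  d <- dim(stack$data)
  interleaved <- as.vector(rbind(Re(stack$data), Im(stack$data)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(interleaved, con, size = 4L, endian = "little")
  hdr <- list(format = "ulmr-iq-f32", dim = d,
              pixel_spacing_um = stack$spacing_um,
              frame_rate_hz = stack$frame_rate)
  jsonlite::write_json(hdr, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_iq
#' @export
read_iq <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  d <- as.integer(hdr$dim)
  n <- prod(d)
  con <- file(path, "rb")
  on.exit(close(con))
  raw <- readBin(con, "numeric", n = 2L * n, size = 4L, endian = "little")
  m <- matrix(raw, nrow = 2L)
  iq_stack(array(complex(real = m[1, ], imaginary = m[2, ]), dim = d),
           spacing_um = hdr$pixel_spacing_um, frame_rate = hdr$frame_rate_hz)
}

#' Write the magnitude of an IQ stack as a multi-page 32-bit TIFF
#'
#' Inspection output: one float32 grayscale page per frame.
#'
#' @param stack an `iq_stack`.
#' @param path output TIFF path.
#' @param frames optional frame indices to write (default all).
#' @export
write_iq_tiff <- function(stack, path, frames = NULL) {
  stopifnot(inherits(stack, "iq_stack"))
  if (is.null(frames)) frames <- seq_len(n_frames(stack))
  pages <- lapply(frames, function(t) Mod(stack$data[, , t]))
  write_tiff(pages, path, sample_format = "float")
}
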