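# Two-channel fluorescence histology quantification: segmentation of
# positive staining with an adaptive (sliding-window median) threshold --
# robust to uneven illumination and vignetting -- plus a morphometric
# exclusion mask that removes vessel-channel components dominated by plaque
# bleed-through, and positive-area fractions per ROI.

#' Adaptive median threshold
#'
#' A pixel is positive iff its intensity exceeds `factor` times the median
#' intensity within the centered `window_px` x `window_px` neighbourhood
#' (reflected borders). Because the local median tracks smooth illumination
#' fields, the segmentation is invariant to them -- and to any global
#' multiplicative rescaling of the image.
#'
#' Intensities are quantized to 16 bits over the image range for the median
#' computation (exact for integer-valued 8/16-bit input).
#'
#' @param channel non-negative numeric matrix.
#' @param window_px odd window size >= 3 (default 101).
#' @param factor threshold multiplier (default 1.5).
#' @return logical mask; attribute `median_image` holds the local medians on
#'   the intensity scale of the input.
#' @export
adaptive_threshold <- function(channel, window_px = 101L, factor = 1.5) {
  if (!all(is.finite(channel)) || any(channel < 0))
    stop("channel must be finite and non-negative")
  if (window_px %% 2 == 0 || window_px < 3) stop("window must be odd and >= 3")
  if (window_px > min(dim(channel))) stop("window larger than image")
  lo <- min(channel); hi <- max(channel)
  if (hi <= lo) {
    med <- channel
  } else {
    is_int <- all(channel == round(channel)) && hi <= 65535
    if (is_int) {
      q <- matrix(as.integer(channel), nrow(channel))
      medq <- .cpp_window_median(q, as.integer(window_px))
      med <- medq + 0.0
    } else {
      scale <- 65535 / (hi - lo)
      q <- matrix(as.integer(round((channel - lo) * scale)), nrow(channel))
      medq <- .cpp_window_median(q, as.integer(window_px))
      med <- medq / scale + lo
    }
  }
  mask <- channel > factor * med
  attr(mask, "median_image") <- med
  mask
}

#' Morphometric exclusion of bleed-through components
#'
#' Plaque fluorescence bleeds into the vessel (FITC) channel; connected
#' components of the FITC mask whose area overlap with the plaque mask
#' exceeds `overlap_frac` are removed.
#'
#' @param fitc_mask,abeta_mask co-registered logical masks.
#' @param overlap_frac maximum tolerated overlap fraction (default 0.5).
#' @return cleaned FITC mask (logical).
#' @export
morphometric_exclude <- function(fitc_mask, abeta_mask, overlap_frac = 0.5) {
  if (!identical(dim(fitc_mask), dim(abeta_mask))) stop("mask shape mismatch")
  lab <- .cpp_label_components(fitc_mask)
  n <- max(lab)
  if (n == 0) return(fitc_mask)
  area <- tabulate(lab[lab > 0], nbins = n)
  ov <- tabulate(lab[lab > 0 & abeta_mask], nbins = n)
  drop <- which(ov / area > overlap_frac)
  out <- fitc_mask
  if (length(drop)) out[lab %in% drop] <- FALSE
  out
}

#' Positive-area fraction
#'
#' Percentage of ROI pixels that are positive in the mask.
#'
#' @param mask logical matrix.
#' @param roi optional logical ROI mask (default: whole image).
#' @return percentage in `[0, 100]`.
#' @export
positive_area_fraction <- function(mask, roi = NULL) {
  if (is.null(roi)) roi <- matrix(TRUE, nrow(mask), ncol(mask))
  if (!identical(dim(mask), dim(roi))) stop("mask shape mismatch")
  if (!any(roi)) stop("empty ROI")
  100 * sum(mask & roi) / sum(roi)
}

#' Quantify a two-channel histology image
#'
#' Full histology path: adaptive threshold per channel, morphometric
#' exclusion on the vessel channel, positive-area fractions per region.
#'
#' @param histo a `histo_image` (see [render_histology()]) or a list with
#'   `fitc`, `abeta` matrices and optional `regions`.
#' @param window_px,factor adaptive-threshold parameters.
#' @param overlap_frac morphometric exclusion parameter.
#' @return data.frame `(region, channel, fraction_pct)` plus the masks as
#'   attributes `fitc_mask` and `abeta_mask`.
#' @export
histo_quant <- function(histo, window_px = 101L, factor = 1.5,
                        overlap_frac = 0.5) {
  regions <- histo$regions %||% list(all = matrix(TRUE, nrow(histo$fitc),
                                                  ncol(histo$fitc)))
  abeta_mask <- adaptive_threshold(histo$abeta, window_px, factor)
  fitc_mask <- adaptive_threshold(histo$fitc, window_px, factor)
  fitc_mask <- morphometric_exclude(fitc_mask, abeta_mask, overlap_frac)
  out <- do.call(rbind, lapply(seq_along(regions), function(i) {
    reg <- regions[[i]]
    data.frame(region = names(regions)[i] %||% as.character(i),
               channel = c("fitc", "abeta"),
               fraction_pct = c(positive_area_fraction(fitc_mask, reg),
                                positive_area_fraction(abeta_mask, reg)))
  }))
  attr(out, "fitc_mask") <- fitc_mask
  attr(out, "abeta_mask") <- abeta_mask
  out
}
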