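#' Quantisation configuration
#'
#' The default catalogue is extracted at seven gray levels:
#' 4, 8, 16, 32, 64, 128 and 256 bins. Bins are equal-width over the
#' in-VOI min-max range by default (`bounds = "voi_min_max"`), which makes
#' quantised-texture features invariant to global SUV rescaling; a
#' fixed-bounds mode is available for absolute-SUV binning.
#'
#' @param levels_list Ordered bin counts, each >= 2.
#' @param bounds `"voi_min_max"` or `"fixed"`.
#' @param fixed_range Length-2 numeric range used when `bounds = "fixed"`.
#' @return An object of class `quant_config`.
#' @export
quant_config <- function(levels_list = c(4, 8, 16, 32, 64, 128, 256),
                         bounds = c("voi_min_max", "fixed"),
                         fixed_range = NULL) {
  bounds <- match.arg(bounds)
  stop_if(any(levels_list < 2), "every gray level must be >= 2")
  stop_if(bounds == "fixed" && (is.null(fixed_range) ||
          length(fixed_range) != 2 || diff(fixed_range) <= 0),
          "fixed bounds require an increasing length-2 fixed_range")
  structure(list(levels_list = as.integer(levels_list), bounds = bounds,
                 fixed_range = fixed_range),
            class = "quant_config")
}

#' Quantise a VOI to G gray levels
#'
#' Equal-width binning of the in-mask values:
#' `label = ceiling(G * (v - min) / (max - min))`, clamped to `[1, G]`
#' (so the minimum maps to label 1). A constant-valued VOI maps entirely
#' to label 1. Labels are 0 outside the mask. Quantisation is monotone:
#' label order preserves value order within the VOI.
#'
#' @param volume A [pet_volume()], or any 3D numeric array (e.g. a wavelet
#'   sub-band).
#' @param mask A [voi_mask()] or logical array aligned to `volume`.
#' @param G Number of gray levels (>= 2).
#' @param bounds,fixed_range See [quant_config()].
#' @return An object of class `quantised_voi`: list with `labels` (integer
#'   array, 0 outside mask), `G`, and `source_stats` (in-VOI min/max).
#' @export
quantise <- function(volume, mask, G, bounds = "voi_min_max",
                     fixed_range = NULL) {
  arr <- if (inherits(volume, "pet_volume")) volume$voxels else volume
  m <- as_mask_array(mask, dim(arr))
  stop_if(!any(m), "empty mask")
  stop_if(G < 2, "G must be >= 2")
  G <- as.integer(G)
  vals <- arr[m]
  rng <- if (identical(bounds, "fixed")) fixed_range else range(vals)
  labels <- array(0L, dim(arr))
  if (diff(rng) == 0) {
    labels[m] <- 1L
  } else {
    lb <- ceiling(G * (vals - rng[1]) / (rng[2] - rng[1]))
    labels[m] <- as.integer(pmin(pmax(lb, 1L), G))
  }
  structure(list(labels = labels, G = G,
                 source_stats = c(min = min(vals), max = max(vals))),
            class = "quantised_voi")
}
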