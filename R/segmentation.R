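#' Segmentation parameters
#'
#' Defaults follow routine FDG-PET practice: delineation starts at 40% of
#' SUVmax, is lowered in 5%-point steps when the VOI visibly under-covers
#' the tumor (operationalised here as coverage of a reference extent), with
#' a 20% floor, and lesions below 5 ml are excluded from analysis.
#'
#' @param initial_fraction Starting threshold as a fraction of SUVmax.
#' @param fraction_step Decrement applied per adaptation step.
#' @param min_fraction Lowest threshold fraction allowed.
#' @param min_volume_ml Minimum lesion volume (ml) for inclusion.
#' @param coverage_fraction Required coverage of the reference extent for
#'   [adapt_threshold()] to stop lowering the threshold.
#' @return An object of class `seg_params`.
#' @export
seg_params <- function(initial_fraction = 0.40, fraction_step = 0.05,
                       min_fraction = 0.20, min_volume_ml = 5.0,
                       coverage_fraction = 0.90) {
  stop_if(!(min_fraction > 0 && min_fraction <= initial_fraction &&
            initial_fraction < 1),
          "need 0 < min_fraction <= initial_fraction < 1")
  stop_if(min_volume_ml <= 0, "min_volume_ml must be > 0")
  structure(list(initial_fraction = initial_fraction,
                 fraction_step = fraction_step,
                 min_fraction = min_fraction,
                 min_volume_ml = min_volume_ml,
                 coverage_fraction = coverage_fraction),
            class = "seg_params")
}

#' Tumor VOI mask
#'
#' @param mask Logical 3D array on the PET grid.
#' @param threshold_fraction_used Fraction of SUVmax used, if threshold-derived.
#' @param manually_edited Whether manual edits were applied.
#' @param coverage_ok `FALSE` flags that [adapt_threshold()] reached its
#'   floor without covering the reference extent.
#' @return An object of class `voi_mask`.
#' @export
voi_mask <- function(mask, threshold_fraction_used = NA_real_,
                     manually_edited = FALSE, coverage_ok = TRUE) {
  stop_if(length(dim(mask)) != 3, "mask must be a 3D array")
  if (!is.logical(mask)) mask <- mask != 0
  structure(list(mask = mask,
                 threshold_fraction_used = threshold_fraction_used,
                 manually_edited = manually_edited,
                 coverage_ok = coverage_ok),
            class = "voi_mask")
}

#' @export
print.voi_mask <- function(x, ...) {
  cat(sprintf("<voi_mask> %d voxels, threshold fraction %s%s%s\n",
              sum(x$mask),
              ifelse(is.na(x$threshold_fraction_used), "-",
                     format(x$threshold_fraction_used)),
              if (x$manually_edited) ", manually edited" else "",
              if (!x$coverage_ok) ", UNDER-COVERAGE WARNING" else ""))
  invisible(x)
}

#' Lesion volume in ml
#' @param mask A [voi_mask()] or logical array.
#' @param spacing Voxel spacing (mm).
#' @return Volume in ml.
#' @export
voi_volume_ml <- function(mask, spacing) {
  m <- if (inherits(mask, "voi_mask")) mask$mask else mask
  sum(m != 0) * voxel_volume_ml(spacing)
}

#' Adaptive-threshold tumor segmentation
#'
#' Grows the 26-connected component containing the seed voxel among voxels
#' with `SUV >= fraction * SUVmax`, where SUVmax is the global maximum of
#' the seed's component (iterated to a fixed point: threshold from the
#' volume-global maximum first, then re-referenced to the component's own
#' maximum until stable). Deterministic: identical inputs give identical
#' masks.
#'
#' @param volume A [pet_volume()] in SUV.
#' @param seed Integer voxel index `c(i, j, k)` inside the lesion.
#' @param params A [seg_params()].
#' @param fraction Threshold fraction; defaults to `params$initial_fraction`.
#' @return A [voi_mask()] with `threshold_fraction_used` recorded.
#' @export
threshold_segment <- function(volume, seed, params = seg_params(),
                              fraction = params$initial_fraction) {
  stop_if(!inherits(volume, "pet_volume"), "volume must be a pet_volume")
  stop_if(!volume$is_suv, "volume must be in SUV units")
  v <- volume$voxels
  dm <- dim(v)
  seed <- as.integer(seed)
  stop_if(length(seed) != 3 || any(seed < 1) || any(seed > dm),
          "seed voxel is outside the volume")
  ref_max <- max(v)
  repeat {
    thr <- fraction * ref_max
    above <- v >= thr
    stop_if(!above[seed[1], seed[2], seed[3]],
            "seed voxel falls below the threshold; empty component")
    lab <- label_components(above, connectivity = 26)
    comp <- lab == lab[seed[1], seed[2], seed[3]]
    new_max <- max(v[comp])
    if (new_max == ref_max) break
    ref_max <- new_max
  }
  voi_mask(comp, threshold_fraction_used = fraction)
}

#' Lower the threshold until the VOI covers a reference extent
#'
#' Operationalises the visual under-coverage check of semi-automatic
#' delineation: starting at `initial_fraction` the threshold is lowered by
#' `fraction_step` until the segmented VOI covers at least
#' `coverage_fraction` of `reference_extent` (a coarse anatomical truth
#' mask, e.g. CT-derived) or the floor `min_fraction` is reached, in which
#' case the returned mask carries `coverage_ok = FALSE`.
#'
#' @inheritParams threshold_segment
#' @param reference_extent A [voi_mask()] or logical array of the expected
#'   tumor extent.
#' @return A [voi_mask()] with the final threshold fraction recorded.
#' @export
adapt_threshold <- function(volume, seed, reference_extent,
                            params = seg_params()) {
  ref <- as_mask_array(reference_extent, dim(volume$voxels))
  stop_if(!any(ref), "reference extent is empty")
  frac <- params$initial_fraction
  repeat {
    m <- threshold_segment(volume, seed, params, fraction = frac)
    cov <- sum(m$mask & ref) / sum(ref)
    if (cov >= params$coverage_fraction) return(m)
    nxt <- frac - params$fraction_step
    if (nxt < params$min_fraction - 1e-9) {
      m$coverage_ok <- FALSE
      warning(sprintf(
        "coverage %.2f below %.2f at floor fraction %.2f; mask flagged",
        cov, params$coverage_fraction, frac), call. = FALSE)
      return(m)
    }
    frac <- nxt
  }
}

#' Apply manual voxel edits to a VOI
#'
#' Set union/difference with the supplied voxel index sets, mirroring the
#' manual adjustment step used when a threshold VOI bleeds into adjacent
#' physiologic uptake (e.g. myocardium). The single-component property is
#' re-checked and reported via the `n_components` attribute, not enforced.
#'
#' @param mask A [voi_mask()].
#' @param add,remove Voxel index matrices (`n x 3`, 1-based), or `NULL`.
#' @return The edited [voi_mask()] with `manually_edited = TRUE`.
#' @export
apply_manual_edits <- function(mask, add = NULL, remove = NULL) {
  stop_if(!inherits(mask, "voi_mask"), "mask must be a voi_mask")
  m <- mask$mask
  dm <- dim(m)
  chk <- function(ix) {
    if (is.null(ix) || nrow(ix) == 0) return(NULL)
    ix <- matrix(as.integer(ix), ncol = 3)
    stop_if(any(ix < 1) || any(ix[, 1] > dm[1]) || any(ix[, 2] > dm[2]) ||
            any(ix[, 3] > dm[3]), "edit voxel outside the grid")
    ix
  }
  add <- chk(add); remove <- chk(remove)
  if (!is.null(add)) m[add] <- TRUE
  if (!is.null(remove)) m[remove] <- FALSE
  out <- voi_mask(m, threshold_fraction_used = mask$threshold_fraction_used,
                  manually_edited = TRUE, coverage_ok = mask$coverage_ok)
  attr(out, "n_components") <- if (any(m)) max(label_components(m)) else 0L
  out
}

#' Minimum-volume inclusion gate
#'
#' Lesions below `min_volume_ml` are excluded from radiomics analysis
#' (small lesions are unreliable at PET resolution). The gate is inclusive:
#' a lesion of exactly `min_volume_ml` is accepted.
#'
#' @param mask A [voi_mask()] or logical array.
#' @param volume The aligned [pet_volume()] (supplies voxel spacing).
#' @param min_volume_ml Gate in ml (default 5).
#' @return `TRUE` (accept) or `FALSE` (reject).
#' @export
gate_min_volume <- function(mask, volume, min_volume_ml = 5.0) {
  stop_if(!inherits(volume, "pet_volume"), "volume must be a pet_volume")
  voi_volume_ml(mask, volume$spacing) >= min_volume_ml
}
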