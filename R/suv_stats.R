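#' Routine PET variables over a tumor VOI
#'
#' Computes SUVmax, SUVmean, SUVpeak, metabolic tumor volume (MTV, ml) and
#' total lesion glycolysis (TLG = SUVmean x MTV).
#'
#' SUVpeak is the maximum, over in-mask voxels, of the mean SUV within a
#' sphere of `peak_kernel_ml` (default ~1 ml) centred on the voxel. The
#' sphere is built in physical units from the voxel spacing (radius
#' `(3V / 4 pi)^(1/3)`, centre-to-centre distances) and is restricted to
#' in-mask voxels, which guarantees `suv_peak <= suv_max`.
#'
#' @param volume A [pet_volume()] in SUV.
#' @param mask A [voi_mask()] (or logical array) aligned to `volume`.
#' @param peak_kernel_ml Peak-sphere volume in ml.
#' @return An object of class `suv_stats`: list with `suv_max`, `suv_mean`,
#'   `suv_peak`, `mtv`, `tlg`.
#' @export
compute_suv_stats <- function(volume, mask, peak_kernel_ml = 1.0) {
  stop_if(!inherits(volume, "pet_volume"), "volume must be a pet_volume")
  m <- as_mask_array(mask, dim(volume$voxels))
  stop_if(!any(m), "empty mask")
  v <- volume$voxels
  vals <- v[m]
  sp <- volume$spacing
  mtv <- sum(m) * voxel_volume_ml(sp)

  ## peak: sphere offsets within radius r (mm), mm distances between centres
  r <- (3 * peak_kernel_ml * 1000 / (4 * pi))^(1 / 3)
  rng <- lapply(sp, function(s) seq(-floor(r / s), floor(r / s)))
  offs <- as.matrix(expand.grid(dx = rng[[1]], dy = rng[[2]], dz = rng[[3]]))
  dist <- sqrt((offs[, 1] * sp[1])^2 + (offs[, 2] * sp[2])^2 +
               (offs[, 3] * sp[3])^2)
  offs <- offs[dist <= r, , drop = FALSE]
  acc <- array(0, dim(v)); cnt <- array(0, dim(v))
  for (k in seq_len(nrow(offs))) {
    d <- offs[k, ]
    acc <- acc + shift_array(v * m, d, fill = 0)
    cnt <- cnt + shift_array(array(as.numeric(m), dim(m)), d, fill = 0)
  }
  peak_map <- acc / pmax(cnt, 1)
  suv_peak <- max(peak_map[m & cnt > 0])

  out <- list(suv_max = max(vals), suv_mean = mean(vals), suv_peak = suv_peak,
              mtv = mtv, tlg = mean(vals) * mtv)
  class(out) <- "suv_stats"
  out
}

#' @export
print.suv_stats <- function(x, ...) {
  cat(sprintf(
    "SUVmax %.3g  SUVmean %.3g  SUVpeak %.3g  MTV %.3g ml  TLG %.3g\n",
    x$suv_max, x$suv_mean, x$suv_peak, x$mtv, x$tlg))
  invisible(x)
}

#' @export
as.data.frame.suv_stats <- function(x, ...) {
  data.frame(suv_max = x$suv_max, suv_mean = x$suv_mean,
             suv_peak = x$suv_peak, mtv = x$mtv, tlg = x$tlg)
}

## accept voi_mask or plain logical/0-1 array; check alignment
as_mask_array <- function(mask, dm) {
  m <- if (inherits(mask, "voi_mask")) mask$mask else mask
  stop_if(is.null(dim(m)) || length(dim(m)) != 3, "mask must be a 3D array")
  stop_if(!all(dim(m) == dm), "mask is not aligned to the volume grid")
  if (!is.logical(m)) m <- m != 0
  m
}
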