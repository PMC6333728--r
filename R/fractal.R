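#' Box-counting fractal dimension of a mask boundary
#'
#' The boundary voxels (mask voxels with at least one exposed face) are
#' covered by cubic boxes of side `eps = 1, 2, 4, ...` voxels (the ladder
#' stops at the largest power of two not exceeding the mask array's largest
#' dimension); the dimension is the least-squares slope of
#' `log N(eps)` against `log(1 / eps)`. The ladder is capped at a quarter
#' of the largest array dimension so that the fit reflects small-scale
#' scaling rather than the object's overall extent. A surface-like
#' boundary gives a value near 2; a single voxel gives 0.
#'
#' @param mask A [voi_mask()] or logical 3D array.
#' @return Box-counting dimension (numeric scalar).
#' @export
fractal_dimension <- function(mask) {
  m <- if (inherits(mask, "voi_mask")) mask$mask else mask
  stop_if(!any(m), "empty mask")
  bnd <- m & !(shift_array(m, c(1, 0, 0), FALSE) &
               shift_array(m, c(-1, 0, 0), FALSE) &
               shift_array(m, c(0, 1, 0), FALSE) &
               shift_array(m, c(0, -1, 0), FALSE) &
               shift_array(m, c(0, 0, 1), FALSE) &
               shift_array(m, c(0, 0, -1), FALSE))
  co <- arrayInd(which(bnd), dim(m))
  sizes <- 2^(0:max(0, floor(log2(max(dim(m)) / 4))))
  stop_if(length(sizes) < 3,
          "fewer than 3 box sizes available; mask array too small")
  nbox <- vapply(sizes, function(s) {
    keys <- floor((co - 1) / s)
    nrow(unique(keys))
  }, 0)
  stats::coef(stats::lm(log(nbox) ~ log(1 / sizes)))[[2]]
}
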