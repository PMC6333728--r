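#' One-level undecimated 3D wavelet decomposition
#'
#' Separable stationary (undecimated) discrete wavelet transform with
#' Daubechies-2 filters, applied once along each axis, yielding the eight
#' sub-bands LLL ... HHH (letter order = x, y, z axis). Sub-bands keep the
#' input grid size, so the VOI mask applies unchanged -- the usual choice
#' for radiomics sub-band textures. Filters are scaled by `1/sqrt(2)` per
#' axis, so with `boundary = "periodic"` the transform is orthonormal and
#' sub-band energies sum exactly to the input energy; `"symmetric"`
#' (default) reflects the signal at the edges (half-sample symmetry), which
#' avoids wrap-around artefacts at the cost of exact energy conservation
#' near the boundary.
#'
#' @param volume A [pet_volume()] or 3D numeric array.
#' @param boundary `"symmetric"` (default) or `"periodic"`.
#' @return Named list of eight 3D arrays (`LLL`, `LLH`, ..., `HHH`).
#' @export
wavelet_decompose <- function(volume, boundary = c("symmetric", "periodic")) {
  boundary <- match.arg(boundary)
  arr <- if (inherits(volume, "pet_volume")) volume$voxels else volume
  stop_if(length(dim(arr)) != 3, "volume must be a 3D array")
  fl <- db2_filters()
  stop_if(any(dim(arr) < length(fl$h)),
          "volume smaller than the filter length along some axis")
  bands <- stats::setNames(list(arr), "")
  for (ax in 1:3) {
    nxt <- list()
    for (bi in seq_along(bands)) {
      nm <- names(bands)[bi]
      nxt[[paste0(nm, "L")]] <- filter_axis(bands[[bi]], fl$h, ax, boundary)
      nxt[[paste0(nm, "H")]] <- filter_axis(bands[[bi]], fl$g, ax, boundary)
    }
    bands <- nxt
  }
  ## names built as x-filter first; reorder to canonical LLL..HHH
  bands[order(names(bands))][c("LLL", "LLH", "LHL", "LHH",
                               "HLL", "HLH", "HHL", "HHH")]
}

## Daubechies-2 orthonormal pair, rescaled by 1/sqrt(2) for an orthonormal
## undecimated transform (lowpass taps then sum to 1).
db2_filters <- function() {
  s3 <- sqrt(3)
  h <- c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2))
  g <- c(h[4], -h[3], h[2], -h[1])      # quadrature mirror
  list(h = h / sqrt(2), g = g / sqrt(2))
}

## filter along one axis: y[i] = sum_m f[m] x[i + m - 1], with periodic
## wrap or half-sample symmetric reflection at the ends.
filter_axis <- function(arr, f, axis, boundary) {
  n <- dim(arr)[axis]
  out <- array(0, dim(arr))
  for (m in seq_along(f)) {
    idx <- seq_len(n) + (m - 1L)
    if (boundary == "periodic") {
      idx <- ((idx - 1L) %% n) + 1L
    } else {
      over <- idx > n
      idx[over] <- 2L * n + 1L - idx[over]    # reflect: n, n-1, ...
    }
    out <- out + f[m] * index_axis(arr, idx, axis)
  }
  out
}

## arr indexed by `idx` along `axis`, other axes untouched
index_axis <- function(arr, idx, axis) {
  switch(axis,
         arr[idx, , , drop = FALSE],
         arr[, idx, , drop = FALSE],
         arr[, , idx, drop = FALSE])
}
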