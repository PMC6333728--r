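## internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)

## voxel volume in ml (spacing in mm; 1 ml = 1000 mm^3)
voxel_volume_ml <- function(spacing) prod(spacing) / 1000

## the 13 unique 3D direction pairs at Chebyshev distance 1
direction_set_13 <- function() {
  dirs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  dirs <- dirs[!(dirs$dx == 0 & dirs$dy == 0 & dirs$dz == 0), ]
  ## keep one of each +/- pair: first nonzero component positive
  keep <- apply(dirs, 1, function(d) {
    nz <- d[d != 0]
    nz[1] > 0
  })
  as.matrix(dirs[keep, , drop = FALSE])
}

## all 26 neighbour offsets
offset_set_26 <- function() {
  o <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  as.matrix(o[!(o$dx == 0 & o$dy == 0 & o$dz == 0), , drop = FALSE])
}

## shift a 3D array by integer offset d (length 3); out-of-range entries
## become `fill`.  shift_array(a, d)[i] == a[i + d] where defined.
shift_array <- function(a, d, fill = 0L) {
  dm <- dim(a)
  out <- array(fill, dm)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    n <- dm[ax]
    if (d[ax] >= 0) {
      dst[[ax]] <- seq_len(n - d[ax])
      src[[ax]] <- seq_len(n - d[ax]) + d[ax]
    } else {
      dst[[ax]] <- seq_len(n + d[ax]) - d[ax]
      src[[ax]] <- seq_len(n + d[ax])
    }
    if (length(src[[ax]]) == 0) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

## label 26- (or 6-) connected components of a logical 3D array.
## Returns an integer array; 0 = background, components numbered from 1.
label_components <- function(mask, connectivity = 26) {
  stopifnot(length(dim(mask)) == 3, connectivity %in% c(6, 26))
  dm <- dim(mask)
  idx <- which(mask)
  lab <- array(0L, dm)
  if (length(idx) == 0) return(lab)
  offs <- if (connectivity == 26) offset_set_26() else
    matrix(c(1, 0, 0, -1, 0, 0, 0, 1, 0, 0, -1, 0, 0, 0, 1, 0, 0, -1),
           ncol = 3, byrow = TRUE)
  co <- arrayInd(idx, dm)
  lut <- integer(prod(dm))           # linear index -> position in idx
  lut[idx] <- seq_along(idx)
  labv <- integer(length(idx))
  cur <- 0L
  nx <- dm[1]; nxy <- dm[1] * dm[2]
  for (s in seq_along(idx)) {
    if (labv[s] != 0L) next
    cur <- cur + 1L
    labv[s] <- cur
    frontier <- s
    while (length(frontier)) {
      cc <- co[frontier, , drop = FALSE]
      nb <- do.call(rbind, lapply(seq_len(nrow(offs)), function(k)
        cbind(cc[, 1] + offs[k, 1], cc[, 2] + offs[k, 2], cc[, 3] + offs[k, 3])))
      ok <- nb[, 1] >= 1 & nb[, 1] <= dm[1] &
            nb[, 2] >= 1 & nb[, 2] <= dm[2] &
            nb[, 3] >= 1 & nb[, 3] <= dm[3]
      nb <- nb[ok, , drop = FALSE]
      if (!nrow(nb)) break
      lin <- (nb[, 3] - 1L) * nxy + (nb[, 2] - 1L) * nx + nb[, 1]
      j <- lut[lin]
      j <- unique(j[j > 0L])
      j <- j[labv[j] == 0L]
      if (length(j)) labv[j] <- cur
      frontier <- j
    }
  }
  lab[idx] <- labv
  lab
}
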