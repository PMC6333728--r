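## 3D texture matrix builders.
##
## All four builders operate on a quantised VOI (labels 1..G inside the
## mask, 0 outside).  Directional matrices (GLCM, GLRLM) aggregate counts
## over the 13 unique direction pairs in 3D before any statistic is taken
## (merged-matrix strategy); zone and neighbourhood matrices (GLSZM, NGTDM)
## use full 26-connectivity.  Offsets are taken in index space at distance
## 1 voxel with no physical-distance correction for anisotropic voxels.

#' Gray-level co-occurrence matrix (3D, merged directions)
#'
#' Counts of label pairs at the given voxel offset distance over all 13
#' unique 3D directions, symmetrised (each ordered pair counted both ways).
#' Pairs with either voxel outside the mask are excluded.
#'
#' @param q A [quantise()]d VOI.
#' @param distance Offset magnitude in voxels (default 1).
#' @return A `G x G` symmetric integer matrix of pair counts.
#' @export
compute_glcm <- function(q, distance = 1) {
  stopifnot(inherits(q, "quantised_voi"), distance >= 1)
  G <- q$G
  lab <- q$labels
  M <- matrix(0, G, G)
  dirs <- direction_set_13()
  for (k in seq_len(nrow(dirs))) {
    d <- dirs[k, ] * distance
    nb <- shift_array(lab, d, fill = 0L)
    a <- lab[lab > 0L & nb > 0L]
    b <- nb[lab > 0L & nb > 0L]
    if (length(a))
      M <- M + matrix(tabulate((a - 1L) * G + b, nbins = G * G), G, G,
                      byrow = TRUE)
  }
  M + t(M)
}

#' Gray-level run-length matrix (3D, merged directions)
#'
#' Maximal runs of equal labels within the mask along each of the 13 unique
#' 3D directions; counts aggregated over directions. The voxel-count
#' identity `sum(R[i, j] * j) = 13 * n_voxels` holds by construction (every
#' in-mask voxel lies in exactly one run per direction).
#'
#' @param q A [quantise()]d VOI.
#' @return A `G x Rmax` integer matrix; entry `(i, j)` counts runs of level
#'   `i` and length `j`.
#' @export
compute_glrlm <- function(q) {
  stopifnot(inherits(q, "quantised_voi"))
  G <- q$G
  lab <- q$labels
  dm <- dim(lab)
  dirs <- direction_set_13()
  maxrun <- max(dm)
  counts <- matrix(0, G, maxrun)
  inm <- lab > 0L
  for (k in seq_len(nrow(dirs))) {
    d <- dirs[k, ]
    nxt <- shift_array(lab, d, fill = 0L)        # label at v + d
    prv <- shift_array(lab, -d, fill = 0L)       # label at v - d
    cont <- inm & nxt == lab                     # run continues at v
    starts <- which(inm & prv != lab)            # run starts
    if (!length(starts)) next
    co <- arrayInd(starts, dm)
    len <- rep(1L, length(starts))
    lev <- lab[starts]
    alive <- seq_along(starts)
    cur <- co
    while (length(alive)) {
      lin <- (cur[alive, 3, drop = TRUE] - 1L) * dm[1] * dm[2] +
             (cur[alive, 2, drop = TRUE] - 1L) * dm[1] +
              cur[alive, 1, drop = TRUE]
      go <- cont[lin]
      adv <- alive[go]
      if (!length(adv)) break
      len[adv] <- len[adv] + 1L
      cur[adv, 1] <- cur[adv, 1] + d[1]
      cur[adv, 2] <- cur[adv, 2] + d[2]
      cur[adv, 3] <- cur[adv, 3] + d[3]
      alive <- adv
    }
    for (r in seq_len(max(len)))
      if (any(sel <- len == r))
        counts[, r] <- counts[, r] + tabulate(lev[sel], nbins = G)
  }
  counts[, seq_len(max(c(1, which(colSums(counts) > 0)))), drop = FALSE]
}

#' Gray-level size-zone matrix (3D, 26-connected zones)
#'
#' Zones are 26-connected components of equal-label voxels within the mask;
#' entry `(i, s)` counts zones of level `i` and size `s` voxels. The
#' voxel-count identity `sum(Z[i, s] * s) = n_voxels` holds by construction.
#'
#' @param q A [quantise()]d VOI.
#' @return A `G x Smax` integer matrix of zone counts.
#' @export
compute_glszm <- function(q) {
  stopifnot(inherits(q, "quantised_voi"))
  G <- q$G
  lab <- q$labels
  sizes_by_level <- lapply(sort(unique(lab[lab > 0L])), function(i) {
    comp <- label_components(lab == i, connectivity = 26)
    list(level = i, sizes = tabulate(comp[comp > 0L]))
  })
  smax <- max(1L, unlist(lapply(sizes_by_level, function(z) z$sizes)))
  Z <- matrix(0, G, smax)
  for (z in sizes_by_level)
    for (s in z$sizes)
      Z[z$level, s] <- Z[z$level, s] + 1
  Z
}

#' Neighbourhood gray-tone difference matrix (3D, 26-neighbour)
#'
#' For each occupied level `i`, `s_i` sums `|i - Abar|` over in-mask voxels
#' of level `i`, where `Abar` is the mean label of the voxel's in-mask
#' 26-neighbours. Voxels with no in-mask neighbour are excluded from the
#' counted total `n`. Occupancy probabilities `p_i` sum to 1.
#'
#' @param q A [quantise()]d VOI.
#' @return An object of class `ngtdm`: list with `levels` (1..G), `s`, `p`,
#'   `n` (counted voxels).
#' @export
compute_ngtdm <- function(q) {
  stopifnot(inherits(q, "quantised_voi"))
  G <- q$G
  lab <- q$labels
  inm <- lab > 0L
  num <- array(0, dim(lab)); den <- array(0, dim(lab))
  offs <- offset_set_26()
  for (k in seq_len(nrow(offs))) {
    d <- offs[k, ]
    num <- num + shift_array(lab * inm, d, fill = 0)
    den <- den + shift_array(array(as.numeric(inm), dim(lab)), d, fill = 0)
  }
  use <- inm & den > 0
  n <- sum(use)
  s <- numeric(G); cnt <- integer(G)
  if (n > 0) {
    abar <- num[use] / den[use]
    lv <- lab[use]
    diffs <- abs(lv - abar)
    for (i in unique(lv)) {
      s[i] <- sum(diffs[lv == i])
      cnt[i] <- sum(lv == i)
    }
  }
  structure(list(levels = seq_len(G), s = s,
                 p = if (n > 0) cnt / n else numeric(G), n = n),
            class = "ngtdm")
}
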