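## Statistics derived from the texture matrices.
##
## Degenerate single-level VOIs are handled via limits where those exist
## (variances 0, complexity 0, contrast 0); statistics that have no finite
## limit (e.g. GLCM correlation with zero marginal variance) are returned
## as NA and recorded as missing by the extraction layer -- never silent NaN.

#' GLCM statistics
#' @param M A `G x G` co-occurrence count matrix (see [compute_glcm()]).
#' @return Named numeric vector of 22 GLCM features.
#' @export
glcm_features <- function(M) {
  G <- nrow(M)
  p <- M / sum(M)
  i <- row(p); j <- col(p)
  px <- rowSums(p); py <- colSums(p)
  mu_x <- sum(seq_len(G) * px); mu_y <- sum(seq_len(G) * py)
  sd_x <- sqrt(sum((seq_len(G) - mu_x)^2 * px))
  sd_y <- sqrt(sum((seq_len(G) - mu_y)^2 * py))
  ## diagonal / cross-diagonal marginals
  pxy_sum <- vapply(2:(2 * G), function(k) sum(p[i + j == k]), 0)  # k = 2..2G
  kk_s <- 2:(2 * G)
  pxy_dif <- vapply(0:(G - 1), function(k) sum(p[abs(i - j) == k]), 0)
  kk_d <- 0:(G - 1)
  ent <- function(w) { w <- w[w > 0]; -sum(w * log2(w)) }
  hxy <- ent(p)
  pp <- px[i] * py[j]
  hxy1 <- -sum(p[pp > 0] * log2(pp[pp > 0]))
  hxy2 <- ent(pp)
  hx <- ent(px); hy <- ent(py)
  da <- sum(kk_d * pxy_dif)
  sa <- sum(kk_s * pxy_sum)
  c(
    Autocorrelation  = sum(i * j * p),
    ClusterProminence = sum((i + j - mu_x - mu_y)^4 * p),
    ClusterShade     = sum((i + j - mu_x - mu_y)^3 * p),
    ClusterTendency  = sum((i + j - mu_x - mu_y)^2 * p),
    Contrast         = sum((i - j)^2 * p),
    Correlation      = if (sd_x > 0 && sd_y > 0)
                         (sum(i * j * p) - mu_x * mu_y) / (sd_x * sd_y)
                       else NA_real_,
    DifferenceAverage  = da,
    DifferenceEntropy  = ent(pxy_dif),
    DifferenceVariance = sum((kk_d - da)^2 * pxy_dif),
    Dissimilarity    = sum(abs(i - j) * p),
    Energy           = sum(p^2),
    Entropy          = hxy,
    Homogeneity      = sum(p / (1 + (i - j)^2)),
    InverseDifference = sum(p / (1 + abs(i - j))),
    Idmn             = sum(p / (1 + (i - j)^2 / G^2)),
    Idn              = sum(p / (1 + abs(i - j) / G)),
    Imc1             = if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy)
                       else NA_real_,
    Imc2             = sqrt(pmax(0, 1 - exp(-2 * (hxy2 - hxy)))),
    MaxProbability   = max(p),
    SumAverage       = sa,
    SumEntropy       = ent(pxy_sum),
    SumVariance      = sum((kk_s - sa)^2 * pxy_sum)
  )
}

#' GLRLM statistics
#' @param R A `G x Rmax` run-count matrix (see [compute_glrlm()]).
#' @return Named numeric vector of 16 GLRLM features.
#' @export
glrlm_features <- function(R) {
  G <- nrow(R); J <- ncol(R)
  i <- row(R); j <- col(R)
  Nr <- sum(R)
  Np <- sum(R * j)                    # voxel count x directions
  pr <- R / Nr
  mu_i <- sum(i * pr); mu_j <- sum(j * pr)
  c(
    ShortRunEmphasis   = sum(R / j^2) / Nr,
    LongRunEmphasis    = sum(R * j^2) / Nr,
    GrayLevelNonUniformity   = sum(rowSums(R)^2) / Nr,
    GrayLevelNonUniformityNorm = sum(rowSums(R)^2) / Nr^2,
    RunLengthNonUniformity   = sum(colSums(R)^2) / Nr,
    RunLengthNonUniformityNorm = sum(colSums(R)^2) / Nr^2,
    RunPercentage      = Nr / Np,
    GrayLevelVariance  = sum((i - mu_i)^2 * pr),
    RunLengthVariance  = sum((j - mu_j)^2 * pr),
    RunEntropy         = { w <- pr[pr > 0]; -sum(w * log2(w)) },
    LowGrayLevelRunEmphasis  = sum(R / i^2) / Nr,
    HighGrayLevelRunEmphasis = sum(R * i^2) / Nr,
    ShortRunLowGrayLevelEmphasis  = sum(R / (i^2 * j^2)) / Nr,
    ShortRunHighGrayLevelEmphasis = sum(R * i^2 / j^2) / Nr,
    LongRunLowGrayLevelEmphasis   = sum(R * j^2 / i^2) / Nr,
    LongRunHighGrayLevelEmphasis  = sum(R * i^2 * j^2) / Nr
  )
}

#' GLSZM statistics
#'
#' `SzVarianc` is the size-zone variance: with `p(i, s)` the fraction of
#' zones having level `i` and size `s` and `mu = sum(p * s)`, it returns
#' `sum(p * (s - mu)^2)` -- the spread of zone sizes irrespective of gray
#' level.
#'
#' @param Z A `G x Smax` zone-count matrix (see [compute_glszm()]).
#' @return Named numeric vector of 16 GLSZM features.
#' @export
glszm_features <- function(Z) {
  G <- nrow(Z); S <- ncol(Z)
  i <- row(Z); s <- col(Z)
  Nz <- sum(Z)
  stop_if(Nz == 0, "zero zones")
  Np <- sum(Z * s)
  pz <- Z / Nz
  mu_i <- sum(i * pz); mu_s <- sum(s * pz)
  c(
    SmallZoneEmphasis  = sum(Z / s^2) / Nz,
    LargeZoneEmphasis  = sum(Z * s^2) / Nz,
    GrayLevelNonUniformity   = sum(rowSums(Z)^2) / Nz,
    GrayLevelNonUniformityNorm = sum(rowSums(Z)^2) / Nz^2,
    ZoneSizeNonUniformity    = sum(colSums(Z)^2) / Nz,
    ZoneSizeNonUniformityNorm = sum(colSums(Z)^2) / Nz^2,
    ZonePercentage     = Nz / Np,
    GrayLevelVariance  = sum((i - mu_i)^2 * pz),
    SzVarianc          = sum((s - mu_s)^2 * pz),
    ZoneEntropy        = { w <- pz[pz > 0]; -sum(w * log2(w)) },
    LowGrayLevelZoneEmphasis  = sum(Z / i^2) / Nz,
    HighGrayLevelZoneEmphasis = sum(Z * i^2) / Nz,
    SmallZoneLowGrayLevelEmphasis  = sum(Z / (i^2 * s^2)) / Nz,
    SmallZoneHighGrayLevelEmphasis = sum(Z * i^2 / s^2) / Nz,
    LargeZoneLowGrayLevelEmphasis  = sum(Z * s^2 / i^2) / Nz,
    LargeZoneHighGrayLevelEmphasis = sum(Z * i^2 * s^2) / Nz
  )
}

#' Size-zone variance of a GLSZM
#'
#' Convenience accessor for the `SzVarianc` statistic (one of the two
#' published signature constituents); see [glszm_features()].
#'
#' @param Z A zone-count matrix.
#' @return The size-zone variance (numeric scalar).
#' @export
glszm_size_zone_variance <- function(Z) {
  unname(glszm_features(Z)["SzVarianc"])
}

#' NGTDM statistics (Amadasun-King)
#'
#' Coarseness, contrast, busyness, complexity and strength. `Complex` is
#' the complexity statistic
#' `sum_{i,j} |i - j| / (n (p_i + p_j)) * (p_i s_i + p_j s_j)` over
#' occupied levels -- the other published signature constituent. All five
#' are 0 in the single-level limit.
#'
#' @param ng An [compute_ngtdm()] result.
#' @return Named numeric vector of 5 NGTDM features.
#' @export
ngtdm_features <- function(ng) {
  stopifnot(inherits(ng, "ngtdm"))
  stop_if(ng$n == 0, "zero counted voxels")
  occ <- which(ng$p > 0)
  p <- ng$p[occ]; s <- ng$s[occ]; iv <- ng$levels[occ]
  n <- ng$n
  Ng <- length(occ)
  eps <- .Machine$double.eps
  coarse <- 1 / max(sum(p * s), eps)
  if (Ng > 1) {
    ii <- rep(iv, times = Ng); jj <- rep(iv, each = Ng)
    pi_ <- rep(p, times = Ng); pj_ <- rep(p, each = Ng)
    si_ <- rep(s, times = Ng); sj_ <- rep(s, each = Ng)
    contrast <- sum(pi_ * pj_ * (ii - jj)^2) / (Ng * (Ng - 1)) * sum(s) / n
    denb <- sum(abs(ii * pi_ - jj * pj_))   # i = j terms vanish
    busy <- if (denb > 0) sum(p * s) / denb else 0
    complexity <- sum(abs(ii - jj) / (n * (pi_ + pj_)) * (pi_ * si_ + pj_ * sj_))
    strength <- if (sum(s) > 0) sum((pi_ + pj_) * (ii - jj)^2) / sum(s) else 0
  } else {
    contrast <- 0; busy <- 0; complexity <- 0; strength <- 0
  }
  c(Coarseness = coarse, Contrast = contrast, Busyness = busy,
    Complex = complexity, Strength = strength)
}

#' NGTDM complexity
#'
#' Convenience accessor for the `Complex` statistic; see [ngtdm_features()].
#'
#' @param ng An [compute_ngtdm()] result.
#' @return The complexity value (numeric scalar).
#' @export
ngtdm_complexity <- function(ng) unname(ngtdm_features(ng)["Complex"])
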