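## Catalogue assembly: 665 named features per gray level.
##
## Composition (per gray level G):
##   original VOI: 19 first-order + 10 shape + 1 fractal
##                 + 22 GLCM + 16 GLRLM + 16 GLSZM + 5 NGTDM        =  89
##   8 undecimated wavelet sub-bands x
##     (13 first-order + 22 GLCM + 16 GLRLM + 16 GLSZM + 5 NGTDM)   = 576
##   total                                                          = 665
## Shape, fractal and the wavelet transform are gray-level independent and
## are computed once, then repeated across gray levels (each gray level's
## feature set is self-contained, as in the original 665 x 7 design).

CATALOGUE_VERSION <- "petrad-665-v1"

wavelet_band_names <- function() c("LLL", "LLH", "LHL", "LHH",
                                   "HLL", "HLH", "HHL", "HHH")

fo_names_full <- function() c("Mean", "Variance", "Sd", "Skewness",
  "Kurtosis", "Energy", "Rms", "Entropy", "Uniformity", "Mad", "Min",
  "Max", "Range", "Median", "P10", "P25", "P75", "P90", "Iqr")
fo_names_reduced <- function() fo_names_full()[1:13]
shape_names <- function() c("VoxelCount", "VolumeMl", "SurfaceAreaFace",
  "SurfaceArea", "SurfaceToVolume", "Sphericity", "Compactness1",
  "Compactness2", "SphericalDisproportion", "MaxDiameter3D")
glcm_names <- function() c("Autocorrelation", "ClusterProminence",
  "ClusterShade", "ClusterTendency", "Contrast", "Correlation",
  "DifferenceAverage", "DifferenceEntropy", "DifferenceVariance",
  "Dissimilarity", "Energy", "Entropy", "Homogeneity",
  "InverseDifference", "Idmn", "Idn", "Imc1", "Imc2", "MaxProbability",
  "SumAverage", "SumEntropy", "SumVariance")
glrlm_names <- function() c("ShortRunEmphasis", "LongRunEmphasis",
  "GrayLevelNonUniformity", "GrayLevelNonUniformityNorm",
  "RunLengthNonUniformity", "RunLengthNonUniformityNorm",
  "RunPercentage", "GrayLevelVariance", "RunLengthVariance", "RunEntropy",
  "LowGrayLevelRunEmphasis", "HighGrayLevelRunEmphasis",
  "ShortRunLowGrayLevelEmphasis", "ShortRunHighGrayLevelEmphasis",
  "LongRunLowGrayLevelEmphasis", "LongRunHighGrayLevelEmphasis")
glszm_names <- function() c("SmallZoneEmphasis", "LargeZoneEmphasis",
  "GrayLevelNonUniformity", "GrayLevelNonUniformityNorm",
  "ZoneSizeNonUniformity", "ZoneSizeNonUniformityNorm", "ZonePercentage",
  "GrayLevelVariance", "SzVarianc", "ZoneEntropy",
  "LowGrayLevelZoneEmphasis", "HighGrayLevelZoneEmphasis",
  "SmallZoneLowGrayLevelEmphasis", "SmallZoneHighGrayLevelEmphasis",
  "LargeZoneLowGrayLevelEmphasis", "LargeZoneHighGrayLevelEmphasis")
ngtdm_names <- function() c("Coarseness", "Contrast", "Busyness",
  "Complex", "Strength")

#' Names of the default feature catalogue
#'
#' @param G Gray level whose `_<G>gl` suffix to append.
#' @return Character vector of 665 unique feature names.
#' @export
catalogue_names <- function(G) {
  tex <- function(prefix) c(paste0("GLCM_", glcm_names()),
                            paste0("GLRLM_", glrlm_names()),
                            paste0("GLSZM_", glszm_names()),
                            paste0("NGTDM_", ngtdm_names()))
  base <- c(paste0("Stats_", fo_names_full()),
            paste0("Shape_", shape_names()),
            "Fractal_BoxDim",
            tex())
  wav <- unlist(lapply(wavelet_band_names(), function(b)
    paste0("W", b, "_", c(paste0("Stats_", fo_names_reduced()), tex()))))
  paste0(c(base, wav), "_", G, "gl")
}

## texture features for one quantised VOI; returns the 59 texture values
texture_block <- function(q) {
  c(setNames(glcm_features(compute_glcm(q)),
             paste0("GLCM_", glcm_names())),
    setNames(glrlm_features(compute_glrlm(q)),
             paste0("GLRLM_", glrlm_names())),
    setNames(glszm_features(compute_glszm(q)),
             paste0("GLSZM_", glszm_names())),
    setNames(ngtdm_features(compute_ngtdm(q)),
             paste0("NGTDM_", ngtdm_names())))
}

#' Extract the full radiomics catalogue at every gray level
#'
#' Computes the default 665-feature catalogue at each gray level of
#' `config` (default 4, 8, 16, 32, 64, 128, 256). Features that cannot be
#' computed (e.g. wavelet sub-bands on a VOI whose bounding box is shorter
#' than the filter, or statistics without a defined degenerate limit) are
#' returned as `NA` with the reason recorded in the `missing_reasons`
#' attribute; the name/count invariant is enforced regardless.
#'
#' @param volume A [pet_volume()] in SUV.
#' @param mask A [voi_mask()] or logical array (should have passed
#'   [gate_min_volume()]).
#' @param config A [quant_config()].
#' @param boundary Wavelet boundary mode (see [wavelet_decompose()]).
#' @return A list of `feature_set` objects, one per gray level: named
#'   numeric vectors of length 665 with attributes `gray_level` and
#'   `catalogue_version`.
#' @export
extract_all <- function(volume, mask, config = quant_config(),
                        boundary = "symmetric") {
  stop_if(!inherits(volume, "pet_volume"), "volume must be a pet_volume")
  m <- as_mask_array(mask, dim(volume$voxels))
  stop_if(!any(m), "empty mask")
  sp <- volume$spacing
  vals <- volume$voxels[m]

  shp <- setNames(shape_features(m, sp), paste0("Shape_", shape_names()))
  frac <- tryCatch(c(Fractal_BoxDim = fractal_dimension(m)),
                   error = function(e) {
                     structure(c(Fractal_BoxDim = NA_real_),
                               reason = conditionMessage(e))
                   })

  ## wavelet sub-bands restricted to the VOI bounding box (padded), once
  bb <- apply(arrayInd(which(m), dim(m)), 2, range)
  box_ok <- all(bb[2, ] - bb[1, ] + 1 >= 4)
  bands <- NULL
  if (box_ok) {
    sub <- volume$voxels[bb[1, 1]:bb[2, 1], bb[1, 2]:bb[2, 2],
                         bb[1, 3]:bb[2, 3], drop = FALSE]
    msub <- m[bb[1, 1]:bb[2, 1], bb[1, 2]:bb[2, 2], bb[1, 3]:bb[2, 3],
              drop = FALSE]
    bands <- wavelet_decompose(sub, boundary = boundary)
  }

  out <- lapply(config$levels_list, function(G) {
    nm <- catalogue_names(G)
    v <- setNames(rep(NA_real_, length(nm)), nm)
    reasons <- character()
    put <- function(x) {
      names(x) <- paste0(names(x), "_", G, "gl")
      v[names(x)] <<- x
    }
    q <- quantise(volume, m, G, bounds = config$bounds,
                  fixed_range = config$fixed_range)
    put(setNames(first_order_features(vals, q), paste0("Stats_", fo_names_full())))
    put(shp)
    put(frac)
    if (!is.null(attr(frac, "reason")))
      reasons[paste0("Fractal_BoxDim_", G, "gl")] <- attr(frac, "reason")
    put(texture_block(q))
    if (box_ok) {
      for (b in names(bands)) {
        bvals <- bands[[b]][msub]
        bq <- quantise(bands[[b]], msub, G)
        put(setNames(first_order_features(bvals, bq, reduced = TRUE),
                     paste0("W", b, "_Stats_", fo_names_reduced())))
        bt <- texture_block(bq)
        put(setNames(unname(bt), paste0("W", b, "_", names(bt))))
      }
    } else {
      reasons["wavelet"] <- "VOI bounding box shorter than filter length"
    }
    miss <- names(v)[is.na(v)]
    for (nm_m in setdiff(miss, names(reasons)))
      reasons[nm_m] <- "undefined for this VOI (degenerate statistic)"
    structure(v, gray_level = G, catalogue_version = CATALOGUE_VERSION,
              missing_reasons = reasons, class = "feature_set")
  })
  names(out) <- paste0("G", config$levels_list)
  out
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %d features at %d gray levels (%s); %d missing\n",
              length(x), attr(x, "gray_level"), attr(x, "catalogue_version"),
              sum(is.na(x))))
  invisible(x)
}

#' Feature sets as a one-row-per-gray-level data frame
#'
#' @param sets A list of feature sets from [extract_all()].
#' @param patient_id Optional id column value.
#' @return A data.frame, one row per gray level, columns = feature names.
#' @export
feature_table <- function(sets, patient_id = NA_character_) {
  do.call(rbind, lapply(sets, function(fs) {
    df <- as.data.frame(as.list(unclass(fs)), check.names = FALSE)
    cbind(data.frame(patient_id = patient_id,
                     gray_level = attr(fs, "gray_level")), df)
  }))
}
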