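#' Phantom specification
#'
#' Defaults describe a medium-large FDG-avid lung lesion on a routine
#' whole-body PET grid: ~30 ml sphere (radius 19.3 mm) of SUV 10 on a
#' SUV-1 background, 4 mm isotropic voxels, intra-tumor heterogeneity as
#' a Gaussian random field with 8 mm correlation length and amplitude 2
#' SUV, and mild acquisition noise (SD 0.1 SUV).
#'
#' @param grid_shape Voxel grid dimensions.
#' @param spacing Voxel spacing (mm).
#' @param background_suv Background uptake (SUV).
#' @param tumor_center Voxel index of the sphere centre (default: grid
#'   centre).
#' @param tumor_radius_mm Sphere radius (mm).
#' @param tumor_suv_max Tumor base uptake (SUV).
#' @param texture_correlation_length Heterogeneity correlation length (mm).
#' @param texture_amplitude Heterogeneity SD (SUV); 0 = uniform tumor.
#' @param noise_sd Additive Gaussian noise SD (SUV).
#' @param seed Integer seed; generation is fully reproducible.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(32, 32, 32), spacing = c(4, 4, 4),
                         background_suv = 1, tumor_center = NULL,
                         tumor_radius_mm = 19.3, tumor_suv_max = 10,
                         texture_correlation_length = 8,
                         texture_amplitude = 2, noise_sd = 0.1, seed = 1) {
  stop_if(tumor_radius_mm <= 0, "radius must be > 0")
  stop_if(noise_sd < 0 || texture_amplitude < 0,
          "noise and texture amplitudes must be >= 0")
  tumor_center <- tumor_center %||% ceiling(grid_shape / 2)
  ## sphere must fit inside the grid
  ext <- tumor_radius_mm / spacing
  stop_if(any(tumor_center - ext < 1) || any(tumor_center + ext > grid_shape),
          "tumor does not fit inside the grid")
  structure(list(grid_shape = as.integer(grid_shape), spacing = spacing,
                 background_suv = background_suv,
                 tumor_center = tumor_center,
                 tumor_radius_mm = tumor_radius_mm,
                 tumor_suv_max = tumor_suv_max,
                 texture_correlation_length = texture_correlation_length,
                 texture_amplitude = texture_amplitude,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a phantom PET volume with known tumor truth
#'
#' A hard-edged sphere of elevated uptake on a uniform background, with
#' smooth intra-tumor texture (a Gaussian random field of the requested
#' correlation length, unit-SD-normalised and scaled by the amplitude,
#' added inside the tumor only) plus independent voxel noise; the result
#' is clipped at 0. The truth mask is the analytic sphere (voxel centres
#' within the radius).
#'
#' @param spec A [phantom_spec()].
#' @return List with `volume` (a [pet_volume()]), `mask` (truth
#'   [voi_mask()]) and `spec`.
#' @export
make_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  dm <- spec$grid_shape
  sp <- spec$spacing
  ax <- lapply(1:3, function(a) ((seq_len(dm[a])) - spec$tumor_center[a]) * sp[a])
  dx2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
  inside <- dx2 <= spec$tumor_radius_mm^2
  v <- array(spec$background_suv, dm)
  v[inside] <- spec$tumor_suv_max
  if (spec$texture_amplitude > 0) {
    g <- gaussian_random_field(dm, sp, spec$texture_correlation_length)
    v[inside] <- v[inside] + spec$texture_amplitude * g[inside]
  }
  if (spec$noise_sd > 0) v <- v + rnorm(length(v), sd = spec$noise_sd)
  v <- pmax(v, 0)
  dim(v) <- dm
  list(volume = pet_volume(v, sp, scanner_meta = scanner_meta(
         slice_thickness = sp[3], matrix_rows = dm[1], matrix_cols = dm[2])),
       mask = voi_mask(inside), spec = spec)
}

## stationary Gaussian random field via FFT filtering of white noise with
## a Gaussian kernel of SD `corr_len` mm; normalised to unit variance
gaussian_random_field <- function(dm, spacing, corr_len) {
  w <- array(rnorm(prod(dm)), dm)
  freq_axis <- function(n, d) {
    k <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) / (n * d)
    k
  }
  kx <- freq_axis(dm[1], spacing[1])
  ky <- freq_axis(dm[2], spacing[2])
  kz <- freq_axis(dm[3], spacing[3])
  k2 <- outer(outer(kx^2, ky^2, `+`), kz^2, `+`)
  filt <- exp(-2 * pi^2 * corr_len^2 * k2)
  g <- Re(fft(fft(w) * filt, inverse = TRUE)) / prod(dm)
  g / sd(g)
}

#' Cohort specification
#'
#' Defaults target the scale of a mid-size NSCLC radiomics cohort: 300
#' patients, 50 candidate features at 64 gray levels of which two carry
#' the survival signal at about HR 1.8 per standard deviation (one
#' adverse, one protective, mirroring the published signature's signs),
#' baseline median survival 25 months, light random loss to follow-up
#' and an administrative cut-off at 85 months.
#'
#' @param n_patients Cohort size.
#' @param n_features Number of feature columns generated.
#' @param gray_level Gray-level suffix used in feature names.
#' @param true_features Names (without suffix) of the informative features.
#' @param true_weights Log-hazard weights per SD of those features.
#' @param baseline_median_months Median survival at the centred linear
#'   predictor.
#' @param censor_rate Exponential loss-to-follow-up rate (per month).
#' @param admin_cutoff_months Administrative censoring time.
#' @param feature_rho AR(1) correlation between adjacent noise features.
#' @param stage_distribution Probabilities of stages I, II, III.
#' @param scanner_pool List of [scanner_meta()] to sample from.
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 300, n_features = 50, gray_level = 64,
                        true_features = c("GLSZM_SzVarianc",
                                          "NGTDM_Complex"),
                        true_weights = c(log(1.8), -log(1.8)),
                        baseline_median_months = 25,
                        censor_rate = 0.001, admin_cutoff_months = 85,
                        feature_rho = 0.3,
                        stage_distribution = c(I = 0.18, II = 0.25,
                                               III = 0.57),
                        scanner_pool = default_scanner_pool(),
                        seed = 1) {
  stop_if(n_patients < 1, "n_patients must be >= 1")
  stop_if(length(true_features) != length(true_weights),
          "true_features and true_weights must match")
  stop_if(n_features < length(true_features), "too few features")
  stop_if(abs(sum(stage_distribution) - 1) > 1e-8,
          "stage probabilities must sum to 1")
  structure(list(n_patients = as.integer(n_patients),
                 n_features = as.integer(n_features),
                 gray_level = as.integer(gray_level),
                 true_features = true_features,
                 true_weights = true_weights,
                 baseline_median_months = baseline_median_months,
                 censor_rate = censor_rate,
                 admin_cutoff_months = admin_cutoff_months,
                 feature_rho = feature_rho,
                 stage_distribution = stage_distribution,
                 scanner_pool = scanner_pool, seed = as.integer(seed)),
            class = "cohort_spec")
}

default_scanner_pool <- function() {
  list(scanner_meta("Siemens", "Biograph 64 mCT", 3, 256, 256),
       scanner_meta("GE", "Discovery ST", 3.27, 128, 128),
       scanner_meta("Philips", "Gemini TF TOF 16", 4, 144, 144),
       scanner_meta("CTI", "ECAT HR+", 5.15, 128, 128))
}

#' Simulate a survival cohort with a known prognostic signal
#'
#' Feature vectors are multivariate normal with an AR(1) correlation
#' structure; the designated features carry the stated log-hazard weights
#' (per SD, applied to standardised features and centred). Survival times
#' are exponential with rate `log(2) / baseline_median * exp(lp)`;
#' censoring is independent exponential at `censor_rate` truncated at the
#' administrative cut-off. Stage and scanner are drawn from the stated
#' distributions. The `truth` attribute records every latent quantity.
#'
#' @param spec A [cohort_spec()].
#' @return A [cohort_table()] with attribute `truth` (list: `lp`,
#'   `weights`, `latent_times`, `censor_times`).
#' @export
make_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_patients; p <- spec$n_features
  ## AR(1) correlated normals via sequential construction
  Z <- matrix(rnorm(n * p), n, p)
  X <- Z
  if (spec$feature_rho != 0 && p > 1)
    for (j in 2:p)
      X[, j] <- spec$feature_rho * X[, j - 1] +
                sqrt(1 - spec$feature_rho^2) * Z[, j]
  fnames <- c(spec$true_features,
              sprintf("Feat%03d", seq_len(p - length(spec$true_features))))
  colnames(X) <- paste0(fnames, "_", spec$gray_level, "gl")
  ## give features loosely feature-like scales (positive, heterogeneous)
  scales <- exp(seq(log(1), log(50), length.out = p))
  Xs <- sweep(X, 2, scales, `*`)
  Xs <- sweep(Xs, 2, 3 * scales, `+`)    # mostly positive values
  lp <- drop(scale(X[, seq_along(spec$true_weights), drop = FALSE]) %*%
             spec$true_weights)
  lp <- lp - mean(lp)
  rate <- log(2) / spec$baseline_median_months * exp(lp)
  t_event <- rexp(n, rate)
  t_cens <- if (spec$censor_rate > 0) rexp(n, spec$censor_rate) else
    rep(Inf, n)
  t_cens <- pmin(t_cens, spec$admin_cutoff_months)
  os <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)
  stage <- sample(names(spec$stage_distribution), n, replace = TRUE,
                  prob = spec$stage_distribution)
  sc <- spec$scanner_pool[sample(length(spec$scanner_pool), n,
                                 replace = TRUE)]
  clinical <- data.frame(
    patient_id = sprintf("P%04d", seq_len(n)),
    os_months = os, event = event, stage = stage,
    volume_ml = exp(rnorm(n, log(35), 0.6)),
    suv_max = exp(rnorm(n, log(15), 0.4)),
    scanner_manufacturer = vapply(sc, `[[`, "", "manufacturer"),
    scanner_model = vapply(sc, `[[`, "", "model"),
    slice_thickness = vapply(sc, `[[`, 0, "slice_thickness"))
  feats <- cbind(data.frame(patient_id = clinical$patient_id),
                 as.data.frame(Xs))
  out <- cohort_table(clinical, feats)
  attr(out, "truth") <- list(lp = lp, weights = spec$true_weights,
                             features = spec$true_features,
                             latent_times = t_event, censor_times = t_cens)
  out
}

#' Write a self-contained fixture bundle
#'
#' Emits, into an existing directory: the phantom volume and truth mask as
#' NIfTI, the synthetic cohort as `clinical.csv` + `features.csv`, the
#' published signature as `model.json`, and a `manifest.csv` of files,
#' seeds and MD5 hashes (stable across runs with the same seeds).
#'
#' @param out_dir Existing writable directory.
#' @param phantom A [phantom_spec()].
#' @param cohort A [cohort_spec()].
#' @return Invisibly, the manifest data.frame.
#' @export
write_fixture_bundle <- function(out_dir, phantom = phantom_spec(),
                                 cohort = cohort_spec()) {
  stop_if(!dir.exists(out_dir), "output directory does not exist: ", out_dir)
  ph <- make_phantom(phantom)
  co <- make_cohort(cohort)
  fvol <- file.path(out_dir, "phantom.nii.gz")
  fmask <- file.path(out_dir, "mask.nii.gz")
  write_nifti_volume(ph$volume, fvol)
  write_nifti_volume(ph$mask, fmask, spacing = ph$volume$spacing)
  fc <- feature_cols(co)
  clin <- co[, setdiff(names(co), fc)]
  fclin <- file.path(out_dir, "clinical.csv")
  write.csv(clin, fclin, row.names = FALSE)
  ffeat <- file.path(out_dir, "features.csv")
  write.csv(co[, c("patient_id", fc)], ffeat, row.names = FALSE)
  fmod <- file.path(out_dir, "model.json")
  file.copy(system.file("extdata", "fvx_published.json", package = "petrad",
                        mustWork = TRUE), fmod, overwrite = TRUE)
  files <- c(fvol, fmask, fclin, ffeat, fmod)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         phantom_seed = phantom$seed,
                         cohort_seed = cohort$seed)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
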