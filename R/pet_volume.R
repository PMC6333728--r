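#' Scanner metadata
#'
#' Acquisition metadata carried alongside a PET volume, used by the
#' scanner-invariance assessment ([pca_invariance()]) and written to
#' cohort tables.
#'
#' @param manufacturer,model Character descriptors of the PET/CT system.
#' @param slice_thickness Slice thickness in mm.
#' @param matrix_rows,matrix_cols Reconstruction matrix size (>= 1).
#' @return An object of class `scanner_meta`.
#' @export
scanner_meta <- function(manufacturer = "unknown", model = "unknown",
                         slice_thickness = NA_real_,
                         matrix_rows = 128L, matrix_cols = 128L) {
  stop_if(matrix_rows < 1 || matrix_cols < 1,
          "matrix_rows and matrix_cols must be >= 1")
  structure(list(manufacturer = manufacturer, model = model,
                 slice_thickness = slice_thickness,
                 matrix_rows = as.integer(matrix_rows),
                 matrix_cols = as.integer(matrix_cols)),
            class = "scanner_meta")
}

#' PET volume container
#'
#' A 3D voxel grid of standardized uptake values (SUV) with its geometry.
#' Axis order is fixed: `dim = c(nx, ny, nz)`, x fastest, z the slice axis;
#' the physical position of voxel `(i, j, k)` (1-based) is
#' `origin + (c(i, j, k) - 1) * spacing` mm.
#'
#' @param voxels 3D numeric array. When `is_suv = TRUE` values must be
#'   finite and non-negative.
#' @param spacing Voxel spacing `(dx, dy, dz)` in mm, all > 0.
#' @param origin Physical coordinate (mm) of voxel `(1, 1, 1)`.
#' @param scanner_meta A [scanner_meta()] object.
#' @param is_suv Logical; `FALSE` marks a raw activity volume (kBq/ml) still
#'   requiring [convert_to_suv()].
#' @return An object of class `pet_volume`.
#' @export
pet_volume <- function(voxels, spacing, origin = c(0, 0, 0),
                       scanner_meta = petrad::scanner_meta(),
                       is_suv = TRUE) {
  stop_if(length(dim(voxels)) != 3, "voxels must be a 3D array")
  stop_if(length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0),
          "spacing must be three positive numbers (mm)")
  stop_if(any(!is.finite(voxels)), "voxels must be finite")
  stop_if(isTRUE(is_suv) && any(voxels < 0), "SUV voxels must be >= 0")
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), scanner_meta = scanner_meta,
                 is_suv = isTRUE(is_suv)),
            class = "pet_volume")
}

#' @export
print.pet_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<pet_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm%s\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              if (x$is_suv) " (SUV)" else " (raw activity)"))
  cat(sprintf("  range [%.3g, %.3g]; scanner %s %s\n",
              min(x$voxels), max(x$voxels),
              x$scanner_meta$manufacturer, x$scanner_meta$model))
  invisible(x)
}

#' Load a PET volume from disk
#'
#' NIfTI (`.nii` / `.nii.gz`) volumes are read with their header geometry.
#' DICOM series input is not supported by this package; convert the series
#' to NIfTI (e.g. with dcm2niix) first.
#'
#' @param path File path (NIfTI) to read.
#' @param format `"nifti"` or `"dicom_series"` (the latter errors).
#' @param is_suv Whether voxel values are already SUV-calibrated.
#' @param scanner_meta Optional [scanner_meta()] to attach.
#' @return A [pet_volume()].
#' @export
load_volume <- function(path, format = c("nifti", "dicom_series"),
                        is_suv = TRUE, scanner_meta = petrad::scanner_meta()) {
  format <- match.arg(format)
  if (format == "dicom_series")
    stop("DICOM series input is not supported; convert the series to NIfTI ",
         "(one volume per scan) and use format = \"nifti\"", call. = FALSE)
  stop_if(!file.exists(path), "file not found: ", path)
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)
  stop_if(length(sp) < 3 || any(!is.finite(sp[1:3])) || any(sp[1:3] <= 0),
          "NIfTI header carries no usable voxel spacing")
  xf <- RNifti::xform(img)
  orig <- if (is.matrix(xf) && all(dim(xf) == c(4, 4))) xf[1:3, 4] else c(0, 0, 0)
  arr <- as.array(img)
  stop_if(length(dim(arr)) != 3, "expected a single 3D volume, got dim ",
          paste(dim(arr), collapse = "x"))
  arr <- array(as.numeric(arr), dim(arr))   # drop header attributes
  pet_volume(arr, spacing = abs(sp[1:3]), origin = orig,
             scanner_meta = scanner_meta, is_suv = is_suv)
}

#' Write a volume or mask as NIfTI
#'
#' Voxel values round-trip bit-exactly (float64 for volumes, uint8 for
#' masks); spacing and origin are stored in the sform.
#'
#' @param x A [pet_volume()] or [voi_mask()].
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @param spacing,origin Geometry used when `x` is a `voi_mask` (masks carry
#'   no geometry of their own; pass the PET volume's).
#' @return `path`, invisibly.
#' @export
write_nifti_volume <- function(x, path, spacing = NULL, origin = NULL) {
  if (inherits(x, "pet_volume")) {
    arr <- x$voxels; sp <- x$spacing; orig <- x$origin; dt <- "double"
  } else if (inherits(x, "voi_mask")) {
    stop_if(is.null(spacing), "spacing is required to write a mask")
    arr <- array(as.integer(x$mask), dim(x$mask))
    sp <- spacing; orig <- origin %||% c(0, 0, 0); dt <- "uint8"
  } else stop("x must be a pet_volume or voi_mask", call. = FALSE)
  attr(arr, "pixdim") <- sp
  img <- RNifti::asNifti(arr, datatype = dt)
  aff <- diag(c(sp, 1)); aff[1:3, 4] <- orig
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Convert a raw activity volume to body-weight SUV
#'
#' `SUV = C / (D(t) / W)` with `C` the tissue concentration (kBq/ml),
#' `D(t) = D0 * 2^(-t / T1/2)` the injected dose (kBq) decay-corrected over
#' the uptake interval, and `W` the body weight (kg). Body-weight SUV only;
#' lean-mass and body-surface variants are out of scope.
#'
#' @param volume A [pet_volume()] with `is_suv = FALSE`, voxels in kBq/ml.
#' @param injected_dose_mbq Injected activity in MBq (> 0).
#' @param body_weight_kg Body weight in kg (> 0).
#' @param decay_interval_min Minutes between injection (dose assay) and scan.
#' @param half_life_min Isotope half-life in minutes (default 18F: 109.77).
#' @return A [pet_volume()] in SUV.
#' @export
convert_to_suv <- function(volume, injected_dose_mbq, body_weight_kg,
                           decay_interval_min = 0, half_life_min = 109.77) {
  stop_if(!inherits(volume, "pet_volume"), "volume must be a pet_volume")
  stop_if(!is.finite(injected_dose_mbq) || injected_dose_mbq <= 0,
          "injected dose must be > 0")
  stop_if(!is.finite(body_weight_kg) || body_weight_kg <= 0,
          "body weight must be > 0")
  dose_kbq <- injected_dose_mbq * 1000 * 2^(-decay_interval_min / half_life_min)
  suv <- volume$voxels / (dose_kbq / body_weight_kg)
  pet_volume(suv, volume$spacing, volume$origin, volume$scanner_meta,
             is_suv = TRUE)
}
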