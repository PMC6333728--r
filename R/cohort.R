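#' Assemble a per-patient cohort table
#'
#' Joins a clinical table (survival, stage, volume, scanner metadata) with
#' a wide feature table (one row per patient, columns named
#' `<Feature>_<G>gl`). The result is a plain `data.frame` carrying the
#' feature column names in the `feature_cols` attribute.
#'
#' @param clinical data.frame with columns `patient_id`, `os_months`,
#'   `event` (1 = death), and optionally `stage`, `volume_ml`, SUV
#'   statistics and scanner columns.
#' @param features data.frame with `patient_id` plus feature columns.
#' @return A `cohort_table` data.frame.
#' @export
cohort_table <- function(clinical, features = NULL) {
  stop_if(!all(c("patient_id", "os_months", "event") %in% names(clinical)),
          "clinical table needs patient_id, os_months, event")
  stop_if(anyDuplicated(clinical$patient_id) > 0, "duplicate patient_id")
  stop_if(any(clinical$os_months < 0), "os_months must be >= 0")
  stop_if(!all(clinical$event %in% c(0, 1)), "event must be 0/1")
  df <- clinical
  fcols <- character()
  if (!is.null(features)) {
    stop_if(anyDuplicated(features$patient_id) > 0,
            "duplicate patient_id in features")
    df <- merge(clinical, features, by = "patient_id", sort = FALSE)
    stop_if(nrow(df) != nrow(clinical),
            "clinical and feature tables do not cover the same patients")
    fcols <- setdiff(names(features), "patient_id")
  }
  fcols <- union(fcols, grep("_[0-9]+gl$", names(df), value = TRUE))
  attr(df, "feature_cols") <- fcols
  class(df) <- c("cohort_table", "data.frame")
  df
}

feature_cols <- function(cohort) {
  fc <- attr(cohort, "feature_cols")
  if (is.null(fc)) grep("_[0-9]+gl$", names(cohort), value = TRUE) else fc
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> %d patients, %d events, %d feature columns\n",
              nrow(x), sum(x$event), length(feature_cols(x))))
  invisible(x)
}
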