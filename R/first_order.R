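#' First-order intensity statistics over a VOI
#'
#' Moment statistics are population moments (denominator `n`); skewness is
#' `m3 / m2^(3/2)` and kurtosis is plain (non-excess) `m4 / m2^2`, both 0
#' for a constant VOI. Entropy (bits) and uniformity are computed on the
#' quantised histogram supplied via `q`; percentiles use the default
#' (type 7) quantile definition.
#'
#' @param values Numeric vector of in-VOI intensities (raw SUV or wavelet
#'   sub-band values).
#' @param q Optional [quantise()]d VOI supplying the histogram for entropy
#'   and uniformity; if `NULL` those two are NA.
#' @param reduced If `TRUE`, return the 13-feature sub-band set (no
#'   median/percentiles); otherwise the full 19-feature set.
#' @return Named numeric vector (19 or 13 features).
#' @export
first_order_features <- function(values, q = NULL, reduced = FALSE) {
  stop_if(length(values) == 0, "empty VOI")
  n <- length(values)
  m <- mean(values)
  m2 <- mean((values - m)^2)
  skew <- if (m2 > 0) mean((values - m)^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean((values - m)^4) / m2^2 else 0
  if (!is.null(q)) {
    cnt <- tabulate(q$labels[q$labels > 0L], nbins = q$G)
    pr <- cnt / sum(cnt)
    pr <- pr[pr > 0]
    entropy <- -sum(pr * log2(pr))
    uniformity <- sum(pr^2)
  } else {
    entropy <- NA_real_; uniformity <- NA_real_
  }
  base <- c(
    Mean = m,
    Variance = m2,
    Sd = sqrt(m2),
    Skewness = skew,
    Kurtosis = kurt,
    Energy = sum(values^2),
    Rms = sqrt(mean(values^2)),
    Entropy = entropy,
    Uniformity = uniformity,
    Mad = mean(abs(values - m)),
    Min = min(values),
    Max = max(values),
    Range = diff(range(values))
  )
  if (reduced) return(base)
  qs <- quantile(values, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE)
  c(base,
    Median = qs[3], P10 = qs[1], P25 = qs[2], P75 = qs[4], P90 = qs[5],
    Iqr = qs[4] - qs[2])
}
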