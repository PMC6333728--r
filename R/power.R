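#' Sample size for a two-arm survival comparison
#'
#' Events-driven sample size for a log-rank/Cox comparison of two
#' equal-sized arms. The number of events required uses the Freedman
#' formula
#' \deqn{D = (z_{1-\alpha/2} + z_{1-\beta})^2 (1 + HR)^2 / (1 - HR)^2,}
#' and is converted to patients through per-arm event probabilities under
#' an exponential survival model: the reference arm has hazard
#' `log(2) / median_survival`, the high-risk arm that hazard times `HR`;
#' each patient's administrative follow-up is uniform on
#' `[0, 2 * median_followup]` (uniform accrual with analysis at study
#' end, so the median follow-up equals `median_followup`), with an
#' additional independent exponential loss-to-follow-up hazard
#' `censor_rate`. With `P_i` the event probability in arm `i`, the total
#' is `N = ceiling(D/2 / P_1) + ceiling(D/2 / P_2)`.
#'
#' For an exponential event hazard `a`, loss hazard `c` and follow-up
#' uniform on `[0, T]`, the event probability has the closed form
#' `P = a/(a+c) * (1 - (1 - exp(-(a+c)T)) / ((a+c)T))` with
#' `T = 2 * median_followup`.
#'
#' @param hr Hazard ratio between the arms (> 0, != 1).
#' @param alpha Two-sided type-I error (default 0.05).
#' @param beta Type-II error (default 0.25, i.e. 75% power).
#' @param median_survival Reference-arm median survival (years).
#' @param median_followup Median administrative follow-up (years).
#' @param censor_rate Exponential loss-to-follow-up rate (per year).
#' @param allocation Allocation ratio; only 1 (1:1) is supported.
#' @return An object of class `power_result`: list with `n_total`,
#'   `n_per_arm`, `events_required`, `p_event` (per arm) and the inputs.
#' @export
power_sample_size <- function(hr, alpha = 0.05, beta = 0.25,
                              median_survival, median_followup,
                              censor_rate = 0, allocation = 1) {
  stop_if(!is.finite(hr) || hr <= 0, "hr must be > 0")
  stop_if(hr == 1, "hr = 1 gives an infinite sample size")
  stop_if(!(alpha > 0 && alpha < 1 && beta > 0 && beta < 1),
          "alpha and beta must be in (0, 1)")
  stop_if(allocation != 1, "only 1:1 allocation is supported")
  stop_if(median_survival <= 0 || median_followup <= 0,
          "medians must be > 0")
  stop_if(censor_rate < 0, "censor_rate must be >= 0")
  z <- qnorm(1 - alpha / 2) + qnorm(1 - beta)
  D <- z^2 * (1 + hr)^2 / (1 - hr)^2
  lam <- log(2) / median_survival
  Tmax <- 2 * median_followup
  p_event <- function(a) {
    tot <- a + censor_rate
    a / tot * (1 - (1 - exp(-tot * Tmax)) / (tot * Tmax))
  }
  P <- c(high_risk = p_event(lam * max(hr, 1 / hr)),
         reference = p_event(lam))
  n_arm <- ceiling(D / 2 / P)
  structure(list(n_total = sum(n_arm), n_per_arm = n_arm,
                 events_required = ceiling(D), events_raw = D,
                 p_event = P,
                 inputs = list(hr = hr, alpha = alpha, beta = beta,
                               median_survival = median_survival,
                               median_followup = median_followup,
                               censor_rate = censor_rate)),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf(
    "Two-arm log-rank sample size: N = %d (%d + %d), %d events required\n",
    x$n_total, x$n_per_arm[1], x$n_per_arm[2], x$events_required))
  cat(sprintf("  HR %.3g, alpha %.3g (two-sided), power %.0f%%\n",
              x$inputs$hr, x$inputs$alpha, 100 * (1 - x$inputs$beta)))
  invisible(x)
}
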