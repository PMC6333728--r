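mini_cohort <- function(times, events, ...) {
  cohort_table(data.frame(patient_id = as.character(seq_along(times)),
                          os_months = times, event = events, ...))
}

test_that("Kaplan-Meier equals empirical survival without censoring", {
  co <- mini_cohort(c(1, 2, 3, 4), rep(1, 4))
  km <- km_logrank(co, groups = rep("all", 4))
  expect_equal(summary(km$fit, times = c(1, 2, 3, 4))$surv,
               c(0.75, 0.50, 0.25, 0))
  ## general case: 1 - ECDF at event times
  set.seed(8)
  t2 <- round(rexp(40, 1 / 20), 3)
  co2 <- mini_cohort(t2, rep(1, 40))
  km2 <- km_logrank(co2, rep("all", 40))
  st <- sort(unique(t2))
  expect_equal(summary(km2$fit, times = st)$surv,
               1 - stats::ecdf(t2)(st))
})

test_that("log-rank is null for duplicated groups and matches a
           hand-tabulated observed-minus-expected oracle", {
  co <- mini_cohort(rep(c(3, 6, 9, 14, 20), 2), rep(1, 10))
  km <- km_logrank(co, groups = rep(c("a", "b"), each = 5))
  expect_equal(km$logrank_chisq, 0)
  expect_equal(km$logrank_p, 1)

  ## label swap leaves the statistic unchanged
  t3 <- c(2, 4, 5, 7, 8, 10, 11, 13, 16, 21)
  ev <- c(1, 1, 0, 1, 1, 1, 0, 1, 1, 1)
  g <- rep(c("x", "y"), 5)
  co3 <- mini_cohort(t3, ev)
  k1 <- km_logrank(co3, g)
  k2 <- km_logrank(co3, ifelse(g == "x", "y", "x"))
  expect_equal(k1$logrank_chisq, k2$logrank_chisq)

  ## brute-force O-E accumulation over distinct event times
  oe <- 0; vv <- 0
  for (tt in sort(unique(t3[ev == 1]))) {
    at_risk <- t3 >= tt
    d <- sum(t3 == tt & ev == 1)
    n <- sum(at_risk); n1 <- sum(at_risk & g == "x")
    d1 <- sum(t3 == tt & ev == 1 & g == "x")
    oe <- oe + d1 - d * n1 / n
    if (n > 1) vv <- vv + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  expect_equal(k1$logrank_chisq, oe^2 / vv)
  expect_error(km_logrank(co3, rep("only", 10)), NA)
  expect_error(km_logrank(mini_cohort(1:3, c(0, 0, 0)), rep("a", 3)),
               "no events")
})

test_that("Cox regression recovers a planted hazard ratio and gives C = 1
           for a perfectly concordant predictor", {
  set.seed(12)
  n <- 2000
  x <- rbinom(n, 1, 0.5)
  t0 <- rexp(n, 0.04 * exp(log(2) * x))
  co <- mini_cohort(pmin(t0, 60), as.integer(t0 <= 60), x = x)
  fit <- cox_fit(co, "x", mode = "multivariable")
  expect_lt(abs(fit$table$hr - 2) / 2, 0.1)
  expect_true(fit$table$hr_lo < 2 && 2 < fit$table$hr_hi)

  ## no censoring, risk = -time ordering: perfect concordance
  set.seed(13)
  tt <- sort(rexp(100, 1 / 10))
  co2 <- mini_cohort(tt, rep(1, 100), risk = rev(seq_len(100)))
  fit2 <- cox_fit(co2, "risk")
  expect_equal(fit2$table$c_index, 1)
  expect_gt(length(fit2$flags), 0)   # separation is flagged, not fatal

  expect_error(cox_fit(co2, "nope"), "missing covariate")
  co2$flat <- 1
  expect_error(cox_fit(co2, "flat"), "constant")
})

test_that("univariate mode fits each covariate separately", {
  set.seed(14)
  n <- 300
  a <- rnorm(n); b <- rnorm(n)
  t0 <- rexp(n, 0.05 * exp(0.5 * a))
  co <- mini_cohort(pmin(t0, 40), as.integer(t0 <= 40), a = a, b = b)
  uni <- cox_fit(co, c("a", "b"), mode = "univariate")
  expect_equal(nrow(uni$table), 2)
  expect_lt(uni$table$p[1], 0.001)
  sep_a <- cox_fit(co, "a", mode = "multivariable")
  expect_equal(uni$table$hr[1], sep_a$table$hr[1])
})

test_that("backward stepwise keeps the informative covariate and drops
           noise", {
  set.seed(15)
  n <- 500
  fvx <- rnorm(n); stage <- sample(1:3, n, TRUE)
  mtv <- exp(rnorm(n)); tlg <- mtv * exp(rnorm(n, 0, 0.2))
  t0 <- rexp(n, 0.04 * exp(0.6 * fvx))
  co <- mini_cohort(pmin(t0, 60), as.integer(t0 <= 60),
                    fvx = fvx, stage = stage, mtv = mtv, tlg = tlg)
  sw <- stepwise_multivariable(co, c("fvx", "stage", "mtv", "tlg"))
  expect_true("fvx" %in% sw$retained)
  expect_true(all(c(sw$retained, sw$removed) %in%
                  c("fvx", "stage", "mtv", "tlg")))
  expect_error(stepwise_multivariable(co, character()), "empty")
})

test_that("the power calculation reproduces its planning inputs and is
           monotone in effect size and power", {
  p <- power_sample_size(hr = 1.78, alpha = 0.05, beta = 0.25,
                         median_survival = 2.92, median_followup = 2.17,
                         censor_rate = 0.012)
  expect_equal(p$n_total, 203)
  expect_error(power_sample_size(1, 0.05, 0.25, 2.92, 2.17, 0.012),
               "infinite")
  ns <- vapply(c(1.3, 1.5, 1.78, 2.2), function(h)
    power_sample_size(h, 0.05, 0.25, 2.92, 2.17, 0.012)$n_total, 0)
  expect_true(all(diff(ns) < 0))
  nb <- vapply(c(0.4, 0.25, 0.15, 0.05), function(b)
    power_sample_size(1.78, 0.05, b, 2.92, 2.17, 0.012)$n_total, 0)
  expect_true(all(diff(nb) > 0))
})

test_that("ICC: identical raters give 1, known variance ratio is recovered,
           and the mean-squares oracle agrees", {
  set.seed(16)
  subj <- rnorm(40)
  expect_equal(icc(cbind(subj, subj, subj))$icc, 1)
  expect_error(icc(matrix(1, 5, 3)), "constant")
  expect_error(icc(matrix(rnorm(5), 5, 1)), "raters")

  ## subject variance 9, error variance 1 -> ICC ~ 0.9
  set.seed(17)
  s <- rnorm(500, sd = 3)
  ratings <- cbind(s + rnorm(500), s + rnorm(500), s + rnorm(500))
  expect_lt(abs(icc(ratings, "two_way_agreement")$icc - 0.9), 0.03)

  ## independent ANOVA-table oracle (hand-built mean squares)
  set.seed(18)
  R <- matrix(rnorm(12 * 4), 12, 4) + rnorm(12)
  n <- nrow(R); k <- ncol(R)
  gm <- mean(R)
  msr <- k * sum((rowMeans(R) - gm)^2) / (n - 1)
  msc <- n * sum((colMeans(R) - gm)^2) / (k - 1)
  sse <- sum((R - outer(rowMeans(R), rep(1, k)) -
              outer(rep(1, n), colMeans(R)) + gm)^2)
  mse <- sse / ((n - 1) * (k - 1))
  expect_equal(icc(R, "two_way_agreement")$icc,
               (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n))
  expect_equal(icc(R, "two_way_consistency")$icc,
               (msr - mse) / (msr + (k - 1) * mse))
})

test_that("PCA invariance: null grouping gives a ratio near 1, a planted
           batch shift inflates it", {
  set.seed(19)
  n <- 500
  clin <- data.frame(patient_id = as.character(1:n),
                     os_months = rexp(n, 1 / 24), event = 1,
                     scanner_manufacturer = sample(c("A", "B", "C"), n,
                                                   TRUE))
  feats <- data.frame(patient_id = clin$patient_id,
                      GLSZM_SzVarianc_64gl = rnorm(n, 10, 2),
                      NGTDM_Complex_64gl = rnorm(n, 300, 60))
  co <- cohort_table(clin, feats)
  pv <- pca_invariance(co, "scanner_manufacturer")
  expect_gt(pv$variance_ratio, 0.5)
  expect_lt(pv$variance_ratio, 2.0)
  expect_equal(sum(pv$explained_variance), 1)

  co2 <- co
  shift <- co2$scanner_manufacturer == "A"
  co2$GLSZM_SzVarianc_64gl[shift] <- co2$GLSZM_SzVarianc_64gl[shift] + 10
  pv2 <- pca_invariance(co2, "scanner_manufacturer")
  expect_gt(pv2$variance_ratio, 10)

  co3 <- co; co3$GLSZM_SzVarianc_64gl <- 1
  expect_error(pca_invariance(co3, "scanner_manufacturer"),
               "zero-variance")
})
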