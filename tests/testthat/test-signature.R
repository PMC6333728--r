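test_that("published signature weights match the frozen constants and the
           arithmetic of the score", {
  fvx <- fvx_published()
  w <- coef(fvx)
  expect_equal(unname(w["GLSZM_SzVarianc_64gl"]), 0.128)
  expect_equal(unname(w["NGTDM_Complex_64gl"]), -0.018)
  feats <- c(GLSZM_SzVarianc_64gl = 100, NGTDM_Complex_64gl = 50)
  expect_equal(score_fv(fvx, feats), 0.128 * 100 - 0.018 * 50)  # 11.9
  expect_equal(score_fv(fvx, feats), 11.9)
  expect_equal(score_fv(fvx, c(GLSZM_SzVarianc_64gl = 0,
                               NGTDM_Complex_64gl = 0)), 0)
})

test_that("scoring is linear and term-order invariant, and errors on
           missing terms", {
  fvx <- fvx_published()
  set.seed(2)
  df <- data.frame(GLSZM_SzVarianc_64gl = runif(10, 0, 100),
                   NGTDM_Complex_64gl = runif(10, 0, 500))
  s1 <- score_fv(fvx, df)
  expect_equal(score_fv(fvx, df * 3), 3 * s1)
  flipped <- fv_model(fvx$terms[2:1, ], provenance = "published_fvx")
  expect_equal(score_fv(flipped, df), s1)
  expect_error(score_fv(fvx, df[, 1, drop = FALSE]),
               "NGTDM_Complex_64gl")
  expect_equal(predict(fvx, df), s1)
})

test_that("volume screening normalises volume-tracking features and leaves
           independent or constant ones untouched", {
  set.seed(31)
  n <- 200
  clin <- data.frame(patient_id = as.character(1:n),
                     os_months = rexp(n, 1 / 24),
                     event = rbinom(n, 1, 0.7),
                     volume_ml = exp(rnorm(n, log(35), 0.6)))
  feats <- data.frame(patient_id = clin$patient_id,
                      Proxy_64gl = clin$volume_ml,
                      Indep_64gl = rnorm(n),
                      Const_64gl = 1)
  co <- cohort_table(clin, feats)
  out <- volume_screen_normalise(co)
  rep <- out$report
  expect_true(rep$normalised[rep$feature == "Proxy_64gl"])
  expect_equal(unique(out$cohort$Proxy_64gl), 1)   # feature / volume = 1
  expect_false(rep$normalised[rep$feature == "Indep_64gl"])
  expect_identical(out$cohort$Indep_64gl, co$Indep_64gl)
  expect_true(is.na(rep$rho[rep$feature == "Const_64gl"]))

  ## idempotent once the normalised feature no longer tracks volume
  out2 <- volume_screen_normalise(out$cohort)
  expect_false(out2$report$normalised[out2$report$feature == "Proxy_64gl"])
  expect_error(volume_screen_normalise(co[1:2, ]), "3 patients")
})

test_that("feature correlation matrix is symmetric with unit diagonal and
           exact for duplicated/negated columns", {
  set.seed(77)
  n <- 60
  clin <- data.frame(patient_id = as.character(1:n),
                     os_months = rexp(n, 1 / 24), event = 1)
  x <- rnorm(n)
  feats <- data.frame(patient_id = clin$patient_id, A_64gl = x,
                      B_64gl = x, C_64gl = -x, D_64gl = rnorm(n))
  R <- feature_correlation_matrix(cohort_table(clin, feats))
  expect_equal(R, t(R))
  expect_equal(unname(diag(R)), rep(1, 4))
  expect_equal(R["A_64gl", "B_64gl"], 1)
  expect_equal(R["A_64gl", "C_64gl"], -1)
  expect_lt(abs(R["A_64gl", "D_64gl"]), 0.5)
})

test_that("LASSO-Cox discovery recovers planted features and is
           seed-reproducible; pure-noise cohorts give sparse models", {
  hits <- 0
  for (s in 1:10) {
    co <- make_cohort(cohort_spec(seed = s))
    m <- fv_discover(co, 64, seed = s)
    w <- coef(m)
    if (all(c("GLSZM_SzVarianc_64gl", "NGTDM_Complex_64gl") %in% names(w)) &&
        w["GLSZM_SzVarianc_64gl"] > 0 && w["NGTDM_Complex_64gl"] < 0)
      hits <- hits + 1
  }
  expect_gte(hits, 9)

  ## bit-for-bit reproducibility under a fixed seed
  co <- make_cohort(cohort_spec(seed = 4))
  m1 <- fv_discover(co, 64, seed = 11)
  m2 <- fv_discover(co, 64, seed = 11)
  expect_identical(m1$terms, m2$terms)

  ## null cohorts at the 1-SE penalty are empty or near-empty
  sparse <- 0
  for (s in 1:10) {
    co0 <- make_cohort(cohort_spec(true_weights = c(0, 0), seed = 100 + s))
    m0 <- suppressWarnings(fv_discover(co0, 64, seed = s, rule = "1se"))
    if (nrow(m0$terms) <= 2) sparse <- sparse + 1
  }
  expect_gte(sparse, 8)

  few_events <- make_cohort(cohort_spec(n_patients = 40,
                                        admin_cutoff_months = 4, seed = 1))
  expect_error(fv_discover(few_events, 64), "events")
})

test_that("model selection prefers the informative gray level and breaks
           ties toward parsimony and lower gray level", {
  co <- make_cohort(cohort_spec(seed = 21))
  good <- fv_discover(co, 64, seed = 21)
  noise <- fv_model(data.frame(feature = "Feat001", gray_level = 64,
                               weight = 1e-6), provenance = "discovered")
  best <- select_optimal_fv(list(noise, good), co, seed = 1)
  expect_identical(best$terms, good$terms)
  expect_identical(select_optimal_fv(list(good), co)$terms, good$terms)

  ## exact tie: same score, fewer terms wins
  a <- fv_model(data.frame(feature = "GLSZM_SzVarianc", gray_level = 64,
                           weight = 1), provenance = "discovered")
  b <- fv_model(data.frame(feature = c("GLSZM_SzVarianc", "Feat001"),
                           gray_level = 64, weight = c(1, 0)),
                provenance = "discovered")
  pick <- select_optimal_fv(list(b, a), co, seed = 1)
  expect_equal(nrow(pick$terms), 1)
  expect_error(select_optimal_fv(list(), co), "empty")
})

test_that("dichotomisation: median ties to low, Youden separates a perfect
           score, optimal log-rank dominates the median split", {
  set.seed(55)
  co <- make_cohort(cohort_spec(n_patients = 120, seed = 55))
  sc <- c(1, 2, 3, 4)
  d <- dichotomise(sc, co[1:4, ], "median")
  expect_equal(as.character(d$groups), c("low", "low", "high", "high"))
  ## ties at the median go low
  d2 <- dichotomise(c(1, 2, 2, 4), co[1:4, ], "median")
  expect_equal(as.character(d2$groups), c("low", "low", "low", "high"))

  ## a score that exactly orders death-before-median-survival
  truth <- attr(co, "truth")
  sc3 <- truth$lp + rnorm(120, sd = 1e-9)
  d3 <- dichotomise(sc3, co, "youden")
  expect_true(is.finite(d3$cutoff))
  expect_equal(nlevels(d3$groups), 2)

  d4 <- dichotomise(sc3, co, "optimal_logrank")
  stat_of <- function(cut) {
    g <- factor(sc3 > cut, c(FALSE, TRUE))
    survival::survdiff(survival::Surv(co$os_months, co$event) ~ g)$chisq
  }
  expect_gte(stat_of(d4$cutoff), stat_of(median(sc3)) - 1e-9)
  ## both groups respect the 10% floor
  expect_gte(min(table(d4$groups)), 12)

  expect_error(dichotomise(rep(1, 10), co[1:10, ], "median"), "identical")
})
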