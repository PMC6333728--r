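#' Kaplan-Meier curves and two-group log-rank test
#'
#' Product-limit estimator per group plus the log-rank chi-square and
#' p-value comparing the groups.
#'
#' @param cohort A [cohort_table()] (needs >= 1 event).
#' @param groups Factor/vector of group labels aligned with `cohort`.
#' @return An object of class `km_fit`: list with `fit` (a
#'   [survival::survfit] object), `logrank_chisq`, `logrank_p`, `groups`.
#' @export
km_logrank <- function(cohort, groups) {
  stop_if(sum(cohort$event) < 1, "no events")
  groups <- as.factor(groups)
  stop_if(any(table(groups) == 0), "empty group")
  y <- survival::Surv(cohort$os_months, cohort$event)
  fit <- survival::survfit(y ~ groups)
  if (nlevels(groups) >= 2) {
    sd <- survival::survdiff(y ~ groups)
    chisq <- sd$chisq
    p <- pchisq(chisq, df = nlevels(groups) - 1, lower.tail = FALSE)
  } else {
    chisq <- NA_real_; p <- NA_real_
  }
  structure(list(fit = fit, logrank_chisq = chisq, logrank_p = p,
                 groups = groups),
            class = "km_fit")
}

#' @export
print.km_fit <- function(x, ...) {
  print(x$fit)
  if (!is.na(x$logrank_p))
    cat(sprintf("log-rank chi-square %.4g, p = %.4g\n",
                x$logrank_chisq, x$logrank_p))
  invisible(x)
}

#' @export
plot.km_fit <- function(x, ...) {
  plot(x$fit, col = seq_len(nlevels(x$groups)),
       xlab = "Time (months)", ylab = "Overall survival", ...)
  graphics::legend("topright", legend = levels(x$groups),
                   col = seq_len(nlevels(x$groups)), lty = 1, bty = "n")
  invisible(x)
}

#' Cox proportional-hazards regression with Wald inference
#'
#' Partial-likelihood maximisation with the Efron tie approximation.
#' `mode = "univariate"` fits each covariate separately;
#' `"multivariable"` fits them jointly. Hazard ratios carry two-sided 95%
#' Wald confidence intervals; Harrell's C is computed on each fit's linear
#' predictor.
#'
#' @param cohort A [cohort_table()] (needs >= 10 events).
#' @param covariates Character vector of column names (numeric, finite,
#'   non-constant).
#' @param mode `"univariate"` or `"multivariable"`.
#' @return An object of class `cox_fit_result`: `table` (covariate, hr,
#'   hr_lo, hr_hi, p, c_index) and `flags` (recorded fitter warnings, e.g.
#'   separation or non-convergence).
#' @export
cox_fit <- function(cohort, covariates,
                    mode = c("univariate", "multivariable")) {
  mode <- match.arg(mode)
  stop_if(length(covariates) == 0, "no covariates")
  stop_if(sum(cohort$event) < 10, "need >= 10 events")
  for (cv in covariates) {
    stop_if(is.null(cohort[[cv]]), "missing covariate column: ", cv)
    stop_if(any(!is.finite(cohort[[cv]])), "non-finite covariate: ", cv)
    stop_if(length(unique(cohort[[cv]])) < 2, "constant covariate: ", cv)
  }
  flags <- character()
  one_fit <- function(vars) {
    f <- stats::as.formula(paste("survival::Surv(os_months, event) ~",
                                 paste(vars, collapse = " + ")))
    ## possible separation / non-convergence is recorded, not raised
    fit <- withCallingHandlers(
      survival::coxph(f, data = cohort, ties = "efron"),
      warning = function(w) {
        flags <<- c(flags, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    s <- summary(fit)
    data.frame(covariate = rownames(s$coefficients),
               hr = s$coefficients[, "exp(coef)"],
               hr_lo = s$conf.int[, "lower .95"],
               hr_hi = s$conf.int[, "upper .95"],
               p = s$coefficients[, "Pr(>|z|)"],
               c_index = unname(s$concordance["C"]),
               row.names = NULL)
  }
  if (mode == "univariate") {
    fits <- lapply(covariates, one_fit)
    tab <- do.call(rbind, fits)
  } else {
    tab <- one_fit(covariates)
  }
  structure(list(table = tab, mode = mode, flags = flags),
            class = "cox_fit_result")
}

#' @export
print.cox_fit_result <- function(x, ...) {
  cat(sprintf("Cox regression (%s, Efron ties)\n", x$mode))
  print(x$table, digits = 4)
  invisible(x)
}

#' Backward stepwise multivariable Cox selection
#'
#' All candidates enter as continuous covariates; the one with the
#' largest Wald p-value is removed while that p exceeds `alpha` (0.05),
#' and the removal order plus the final joint fit are reported.
#'
#' @param cohort A [cohort_table()].
#' @param candidates Character vector of candidate covariate columns.
#' @param alpha Retention threshold on the Wald p-value.
#' @return List with `retained`, `removed` (in removal order), `fit` (the
#'   final [cox_fit()] result, or NULL if nothing survived).
#' @export
stepwise_multivariable <- function(cohort, candidates, alpha = 0.05) {
  stop_if(length(candidates) == 0, "empty candidate set")
  vars <- candidates
  removed <- character()
  while (length(vars) > 0) {
    fit <- cox_fit(cohort, vars, mode = "multivariable")
    worst <- which.max(fit$table$p)
    if (fit$table$p[worst] <= alpha) break
    removed <- c(removed, vars[worst])
    vars <- vars[-worst]
  }
  list(retained = vars, removed = removed,
       fit = if (length(vars)) cox_fit(cohort, vars, "multivariable")
             else NULL)
}

#' Intraclass correlation coefficient (two-way models)
#'
#' Single-rating ICC from the two-way mean-squares decomposition of a
#' complete subject x rater matrix: `two_way_agreement` is ICC(2,1)
#' (raters a random sample; absolute agreement),
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`;
#' `two_way_consistency` is ICC(3,1), `(MSR - MSE) / (MSR + (k-1) MSE)`.
#'
#' @param ratings Numeric matrix, subjects in rows, raters in columns
#'   (>= 2 of each, no missing values).
#' @param model `"two_way_agreement"` or `"two_way_consistency"`.
#' @return An object of class `icc_result`: list with `icc`, `model`,
#'   `n_subjects`, `n_raters`.
#' @export
icc <- function(ratings, model = c("two_way_agreement",
                                   "two_way_consistency")) {
  model <- match.arg(model)
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  stop_if(n < 2 || k < 2, "need >= 2 subjects and >= 2 raters")
  stop_if(any(!is.finite(ratings)), "ratings must be complete and finite")
  stop_if(stats::var(as.vector(ratings)) == 0,
          "constant rating matrix; ICC undefined")
  d <- data.frame(y = as.vector(ratings),
                  subj = factor(rep(seq_len(n), times = k)),
                  rater = factor(rep(seq_len(k), each = n)))
  ## F-test warnings on perfect fits are irrelevant; only mean squares used
  ms <- suppressWarnings(anova(aov(y ~ subj + rater, data = d)))
  msr <- ms["subj", "Mean Sq"]
  msc <- ms["rater", "Mean Sq"]
  mse <- ms["Residuals", "Mean Sq"]
  val <- if (model == "two_way_agreement")
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  else
    (msr - mse) / (msr + (k - 1) * mse)
  structure(list(icc = val, model = model, n_subjects = n, n_raters = k),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC (%s) = %.4f  [%d subjects x %d raters]\n",
              x$model, x$icc, x$n_subjects, x$n_raters))
  invisible(x)
}

#' PCA-based scanner-invariance assessment
#'
#' Centred (and scaled) principal component analysis of the signature's
#' constituent features; invariance to an acquisition grouping (e.g.
#' manufacturer) is summarised as the mean over PC1-PC2 of the
#' between-group to within-group mean-square ratio of the component
#' scores: values near 1 indicate scanner-invariant features, large values
#' a batch effect.
#'
#' @param cohort A [cohort_table()].
#' @param grouping Name of the grouping column (scanner metadata).
#' @param features Feature columns to analyse; defaults to the published
#'   signature constituents at 64 gray levels.
#' @param scale. Scale features to unit variance before PCA (default TRUE).
#' @return An object of class `pca_invariance`: `explained_variance`,
#'   `scores`, `group_centroids`, `variance_ratio` (NA for one group).
#' @export
pca_invariance <- function(cohort, grouping,
                           features = c("GLSZM_SzVarianc_64gl",
                                        "NGTDM_Complex_64gl"),
                           scale. = TRUE) {
  stop_if(nrow(cohort) < 3, "need >= 3 patients")
  stop_if(is.null(cohort[[grouping]]), "missing grouping column: ", grouping)
  miss <- setdiff(features, names(cohort))
  stop_if(length(miss) > 0, "missing feature column(s): ",
          paste(miss, collapse = ", "))
  X <- as.matrix(cohort[, features, drop = FALSE])
  stop_if(any(apply(X, 2, var) == 0), "zero-variance feature")
  g <- factor(cohort[[grouping]])
  pc <- prcomp(X, center = TRUE, scale. = scale.)
  npc <- min(2, ncol(pc$x))
  sc <- pc$x[, seq_len(npc), drop = FALSE]
  ratio <- if (nlevels(g) >= 2) {
    mean(vapply(seq_len(npc), function(j) {
      ms <- anova(aov(sc[, j] ~ g))
      ms["g", "Mean Sq"] / ms["Residuals", "Mean Sq"]
    }, 0))
  } else NA_real_
  cent <- aggregate(sc, list(group = g), mean)
  structure(list(
    explained_variance = pc$sdev^2 / sum(pc$sdev^2),
    scores = sc, group_centroids = cent, variance_ratio = ratio,
    grouping = grouping), class = "pca_invariance")
}

#' @export
print.pca_invariance <- function(x, ...) {
  cat(sprintf("PCA invariance by %s: variance ratio %.3f\n", x$grouping,
              x$variance_ratio))
  cat("explained variance:",
      paste(sprintf("%.1f%%", 100 * x$explained_variance), collapse = " "),
      "\n")
  invisible(x)
}
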