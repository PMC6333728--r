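#' Volume-invariance screening and normalisation
#'
#' Radiomics features that merely restate tumor volume carry no texture
#' information. For each feature the Spearman rank correlation with
#' `volume_ml` is computed across patients; features with
#' `|rho| >= threshold` (default 0.7) are replaced by `feature / volume`.
#' Zero-variance features have undefined rho and are left untouched (and
#' logged in the report).
#'
#' @param cohort A [cohort_table()] with a `volume_ml` column.
#' @param threshold Spearman threshold in (0, 1].
#' @return List with `cohort` (transformed) and `report` (data.frame of
#'   feature, rho, normalised flag).
#' @export
volume_screen_normalise <- function(cohort, threshold = 0.7) {
  stop_if(!(threshold > 0 && threshold <= 1), "threshold must be in (0, 1]")
  stop_if(nrow(cohort) < 3, "need at least 3 patients")
  stop_if(is.null(cohort$volume_ml) || any(cohort$volume_ml <= 0),
          "cohort needs positive volume_ml")
  fc <- feature_cols(cohort)
  rho <- vapply(fc, function(f) {
    x <- cohort[[f]]
    if (length(unique(x)) < 2) return(NA_real_)
    suppressWarnings(cor(x, cohort$volume_ml, method = "spearman"))
  }, 0)
  norm <- !is.na(rho) & abs(rho) >= threshold
  out <- cohort
  for (f in fc[norm]) out[[f]] <- out[[f]] / out$volume_ml
  list(cohort = out,
       report = data.frame(feature = fc, rho = unname(rho),
                           normalised = unname(norm),
                           row.names = NULL))
}

#' Pairwise Spearman correlation of features
#'
#' Symmetric unit-diagonal matrix for heatmap rendering / collinearity
#' review; constant features yield NA entries.
#'
#' @param cohort A [cohort_table()].
#' @return A symmetric correlation matrix.
#' @export
feature_correlation_matrix <- function(cohort) {
  stop_if(nrow(cohort) < 3, "need at least 3 patients")
  X <- as.matrix(cohort[, feature_cols(cohort), drop = FALSE])
  R <- suppressWarnings(cor(X, method = "spearman"))
  const <- apply(X, 2, function(x) length(unique(x)) < 2)
  R[const, ] <- NA; R[, const] <- NA
  diag(R) <- 1
  R
}

#' Feature-vector model
#'
#' A (feature, gray level, weight) list defining a linear prognostic score.
#' The published instance FVX is
#' `0.128 * GLSZM_SzVarianc_64gl - 0.018 * NGTDM_Complex_64gl`
#' (see [fvx_published()]).
#'
#' @param terms data.frame with columns `feature`, `gray_level`, `weight`.
#' @param provenance `"published_fvx"` or `"discovered"`.
#' @param ... Extra fields stored on the object (e.g. the cv fit).
#' @return An object of class `fv_model`.
#' @export
fv_model <- function(terms, provenance = c("discovered", "published_fvx"),
                     ...) {
  provenance <- match.arg(provenance)
  stop_if(!all(c("feature", "gray_level", "weight") %in% names(terms)),
          "terms needs feature, gray_level, weight")
  key <- paste0(terms$feature, "_", terms$gray_level, "gl")
  stop_if(anyDuplicated(key) > 0, "duplicate features in model terms")
  structure(c(list(terms = terms, provenance = provenance), list(...)),
            class = "fv_model")
}

#' @export
print.fv_model <- function(x, ...) {
  cat(sprintf("<fv_model> (%s) %d term(s)\n", x$provenance, nrow(x$terms)))
  if (nrow(x$terms))
    for (r in seq_len(nrow(x$terms)))
      cat(sprintf("  %+0.4g * %s_%dgl\n", x$terms$weight[r],
                  x$terms$feature[r], x$terms$gray_level[r]))
  invisible(x)
}

#' @export
coef.fv_model <- function(object, ...) {
  setNames(object$terms$weight,
           paste0(object$terms$feature, "_", object$terms$gray_level, "gl"))
}

#' @export
predict.fv_model <- function(object, newdata, ...) score_fv(object, newdata)

#' The published two-feature prognostic signature (FVX)
#'
#' Loads the shipped model file: size-zone variance of the GLSZM at 64
#' gray levels weighted `+0.128` and NGTDM complexity at 64 gray levels
#' weighted `-0.018`.
#'
#' @return An `fv_model` with provenance `"published_fvx"`.
#' @export
fvx_published <- function() {
  path <- system.file("extdata", "fvx_published.json", package = "petrad",
                      mustWork = TRUE)
  j <- jsonlite::fromJSON(path)
  fv_model(j$terms, provenance = j$provenance)
}

#' Score patients with a feature-vector model
#'
#' `score = sum(weight * feature value)`; exactly linear and independent
#' of term order.
#'
#' @param model An [fv_model()].
#' @param features Either a cohort/data.frame with `<Feature>_<G>gl`
#'   columns (one row per patient) or a single `feature_set` / named
#'   vector.
#' @return Numeric score(s).
#' @export
score_fv <- function(model, features) {
  stop_if(!inherits(model, "fv_model"), "model must be an fv_model")
  key <- paste0(model$terms$feature, "_", model$terms$gray_level, "gl")
  if (is.data.frame(features)) {
    miss <- setdiff(key, names(features))
    stop_if(length(miss) > 0, "missing model term(s): ",
            paste(miss, collapse = ", "))
    X <- as.matrix(features[, key, drop = FALSE])
  } else {
    v <- unclass(features)
    miss <- setdiff(key, names(v))
    stop_if(length(miss) > 0, "missing model term(s): ",
            paste(miss, collapse = ", "))
    X <- matrix(v[key], nrow = 1, dimnames = list(NULL, key))
  }
  drop(X %*% model$terms$weight)
}

#' LASSO-Cox feature-vector discovery at one gray level
#'
#' L1-penalised Cox partial likelihood over the features of one gray
#' level; the penalty is chosen by cross-validated partial-likelihood
#' deviance (`rule = "min"` default, `"1se"` available). Features are
#' standardised internally; reported weights are on the original feature
#' scale. Reproducible given `seed` (fold assignment is the only
#' randomness).
#'
#' @param cohort A [cohort_table()] (needs >= 20 events).
#' @param gray_level Gray level whose `_<G>gl` features to use.
#' @param cv_folds Number of cross-validation folds (default 10).
#' @param seed Integer seed for fold assignment.
#' @param rule `"min"` or `"1se"` penalty rule.
#' @return An [fv_model()] (possibly with zero terms, with a warning)
#'   carrying the `cv.glmnet` fit in `$cvfit` and the chosen `$lambda`.
#' @export
fv_discover <- function(cohort, gray_level, cv_folds = 10, seed = 1,
                        rule = c("min", "1se")) {
  rule <- match.arg(rule)
  fc <- grep(paste0("_", gray_level, "gl$"), feature_cols(cohort),
             value = TRUE)
  stop_if(length(fc) < 2, "need >= 2 features at gray level ", gray_level)
  stop_if(sum(cohort$event) < 1, "no events in cohort")
  stop_if(sum(cohort$event) < 20,
          "need >= 20 events for stable penalised selection")
  X <- as.matrix(cohort[, fc, drop = FALSE])
  y <- survival::Surv(cohort$os_months, cohort$event)
  set.seed(seed)
  foldid <- sample(rep(seq_len(cv_folds), length.out = nrow(X)))
  cvfit <- glmnet::cv.glmnet(X, y, family = "cox", foldid = foldid,
                             standardize = TRUE)
  lam <- if (rule == "min") cvfit$lambda.min else cvfit$lambda.1se
  b <- as.numeric(coef(cvfit, s = lam))
  nz <- which(b != 0)
  if (!length(nz))
    warning("all weights zero at the chosen penalty; empty model",
            call. = FALSE)
  terms <- data.frame(
    feature = sub(paste0("_", gray_level, "gl$"), "", fc[nz]),
    gray_level = rep(as.integer(gray_level), length(nz)),
    weight = b[nz])
  fv_model(terms, provenance = "discovered", cvfit = cvfit, lambda = lam,
           gray_level = as.integer(gray_level))
}

#' Select the best feature vector across gray levels
#'
#' Ranks candidate models by cross-validated Harrell C-index of their
#' score on the training cohort (folds only partition the evaluation;
#' weights stay fixed). Ties break toward fewer terms, then lower gray
#' level.
#'
#' @param models List of [fv_model()]s (e.g. one per gray level).
#' @param cohort The training [cohort_table()].
#' @param cv_folds Evaluation folds (default 5).
#' @param seed Fold-assignment seed.
#' @return The winning `fv_model`, with its `cv_cindex` attached.
#' @export
select_optimal_fv <- function(models, cohort, cv_folds = 5, seed = 1) {
  stop_if(length(models) == 0, "empty candidate list")
  y <- survival::Surv(cohort$os_months, cohort$event)
  set.seed(seed)
  foldid <- sample(rep(seq_len(cv_folds), length.out = nrow(cohort)))
  cidx <- vapply(models, function(m) {
    if (nrow(m$terms) == 0) return(NA_real_)
    sc <- score_fv(m, cohort)
    if (length(unique(sc)) < 2) return(NA_real_)
    mean(vapply(seq_len(cv_folds), function(k) {
      sel <- foldid == k
      survival::concordance(y[sel] ~ sc[sel], reverse = TRUE)$concordance
    }, 0), na.rm = TRUE)
  }, 0)
  stop_if(all(is.na(cidx)), "no scorable candidate model")
  nterms <- vapply(models, function(m) nrow(m$terms), 0L)
  glev <- vapply(models, function(m)
    if (nrow(m$terms)) min(m$terms$gray_level) else Inf, 0)
  ord <- order(-cidx, nterms, glev, na.last = TRUE)
  best <- models[[ord[1]]]
  best$cv_cindex <- cidx[ord[1]]
  best
}

#' Dichotomise a continuous score into risk groups
#'
#' * `median`: split at the sample median; scores equal to the median go
#'   to the low-score group.
#' * `youden`: Youden's J on the ROC of the score against death before the
#'   cohort's median overall survival (patients censored before the median
#'   OS are not evaluable and are excluded from the ROC; all patients are
#'   classified by the resulting cutoff).
#' * `optimal_logrank`: maximally selected log-rank statistic over
#'   interior candidate cutoffs leaving at least 10% of the cohort in each
#'   group.
#'
#' @param scores Numeric per-patient scores.
#' @param cohort A [cohort_table()] aligned with `scores`.
#' @param method `"median"`, `"youden"` or `"optimal_logrank"`.
#' @param min_group_frac Group-size floor for `optimal_logrank`.
#' @return List with `groups` (factor `low`/`high`), `cutoff`, `method`.
#' @export
dichotomise <- function(scores, cohort,
                        method = c("median", "youden", "optimal_logrank"),
                        min_group_frac = 0.10) {
  method <- match.arg(method)
  stop_if(length(scores) < 2, "need >= 2 patients")
  stop_if(length(unique(scores)) < 2, "all scores identical")
  stop_if(length(scores) != nrow(cohort), "scores do not match the cohort")
  cutoff <- switch(method,
    median = median(scores),
    youden = {
      med_os <- median(cohort$os_months)
      evaluable <- cohort$event == 1 | cohort$os_months >= med_os
      died_early <- cohort$event == 1 & cohort$os_months < med_os
      stop_if(length(unique(died_early[evaluable])) < 2,
              "median-survival label is degenerate")
      roc <- pROC::roc(response = died_early[evaluable],
                       predictor = scores[evaluable],
                       levels = c(FALSE, TRUE), direction = "<",
                       quiet = TRUE)
      as.numeric(pROC::coords(roc, "best", best.method = "youden",
                              ret = "threshold")[1, 1])
    },
    optimal_logrank = {
      n <- length(scores)
      cand <- sort(unique(scores))
      cand <- cand[-length(cand)]                 # interior splits: > c
      keep <- vapply(cand, function(cc) {
        hi <- sum(scores > cc)
        hi >= ceiling(min_group_frac * n) &&
          (n - hi) >= ceiling(min_group_frac * n)
      }, TRUE)
      cand <- cand[keep]
      stop_if(length(cand) == 0, "no admissible cutoff under the group floor")
      stat <- vapply(cand, function(cc) {
        g <- factor(scores > cc, levels = c(FALSE, TRUE))
        survival::survdiff(survival::Surv(cohort$os_months, cohort$event)
                           ~ g)$chisq
      }, 0)
      cand[which.max(stat)]
    })
  groups <- factor(ifelse(scores > cutoff, "high", "low"),
                   levels = c("low", "high"))
  list(groups = groups, cutoff = cutoff, method = method)
}
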