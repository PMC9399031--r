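feature_columns <- function(table) {
  setdiff(names(table), c("subject_id", "label", "dataset"))
}

#' Standardise a feature table
#'
#' Centers every feature to mean 0 and scales to unit variance using the
#' moments of *this table only*. When a model trained on one dataset is
#' applied to another acquired differently, each dataset must be
#' standardised with its own moments — never reuse training moments on
#' the test set.
#'
#' @param table a feature tibble with `subject_id`/`label` columns and
#'   numeric features.
#' @return The standardised tibble.
#' @export
standardize <- function(table) {
  feats <- feature_columns(table)
  for (f in feats) {
    v <- table[[f]]
    s <- sd(v)
    if (!is.finite(s) || s == 0) {
      abort(sprintf("Feature '%s' is constant and cannot be standardised.", f))
    }
    table[[f]] <- (v - mean(v)) / s
  }
  table
}

#' Mean imputation of missing values
#'
#' Replaces each missing entry by the observed mean of its feature;
#' observed entries are untouched, so every feature's observed mean is
#' preserved exactly.
#'
#' @param table a feature tibble, possibly with `NA` entries.
#' @return The imputed tibble (numeric features).
#' @export
impute_mean <- function(table) {
  feats <- feature_columns(table)
  for (f in feats) {
    v <- as.numeric(table[[f]])
    miss <- is.na(v)
    if (all(miss)) abort(sprintf("Feature '%s' has no observed values.", f))
    if (any(miss)) v[miss] <- mean(v[!miss])
    table[[f]] <- v
  }
  table
}

#' Area under the ROC curve (percent)
#'
#' The probability that a randomly chosen positive subject receives a
#' higher score than a randomly chosen negative one, with ties counted as
#' half, reported on the 0--100 scale.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels binary labels (0/1), both classes present.
#' @return AUROC in percent.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) abort("Length mismatch.")
  npos <- sum(labels == 1L); nneg <- sum(labels == 0L)
  if (npos == 0L || nneg == 0L) abort("Both classes must be present.")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - npos * (npos + 1) / 2) / (npos * nneg) * 100
}

#' Threshold classification metrics
#'
#' Sensitivity, specificity and balanced accuracy at a fixed decision
#' threshold on the scores, together with the threshold-free AUROC, all
#' in percent.
#'
#' @inheritParams auroc
#' @param threshold scores strictly above `threshold` are called positive
#'   (default 0.5, the convention for predicted probabilities).
#' @return An `evaluation_report` tibble with one row: `auroc`,
#'   `sensitivity`, `specificity`, `balanced_accuracy`, `threshold`.
#' @export
classification_metrics <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  a <- auroc(scores, labels)
  pred <- as.integer(scores > threshold)
  sens <- 100 * sum(pred == 1L & labels == 1L) / sum(labels == 1L)
  spec <- 100 * sum(pred == 0L & labels == 0L) / sum(labels == 0L)
  structure(
    tibble(
      auroc = a, sensitivity = sens, specificity = spec,
      balanced_accuracy = (sens + spec) / 2, threshold = threshold
    ),
    class = c("evaluation_report", class(tibble()))
  )
}

#' Compare two matched AUROC series
#'
#' Two-sided paired test on replicate-matched AUROC differences. The
#' default is a paired t-test; `method = "bootstrap"` uses a percentile
#' bootstrap of the mean difference instead. Degenerate cases: identical
#' series give p = 1; a constant nonzero difference gives p ~ 0.
#'
#' @param paired_aurocs_a,paired_aurocs_b numeric vectors matched by
#'   replicate.
#' @param method `"t"` (default) or `"bootstrap"`.
#' @param n_boot bootstrap resamples when `method = "bootstrap"`.
#' @return Two-sided p-value.
#' @export
compare_auroc <- function(paired_aurocs_a, paired_aurocs_b,
                          method = c("t", "bootstrap"), n_boot = 2000L) {
  if (length(paired_aurocs_a) != length(paired_aurocs_b)) {
    abort("AUROC series must have equal length (matched replicates).")
  }
  method <- match.arg(method)
  d <- paired_aurocs_a - paired_aurocs_b
  d <- d[is.finite(d)]
  if (length(d) < 2L) abort("Need at least 2 finite paired differences.")
  if (sd(d) == 0) return(if (mean(d) == 0) 1 else 0)
  if (method == "t") {
    return(t.test(d)$p.value)
  }
  m <- mean(d)
  boots <- vapply(seq_len(n_boot), function(i) {
    mean(d[sample.int(length(d), replace = TRUE)])
  }, numeric(1))
  p <- 2 * min(mean(boots <= 0), mean(boots >= 0))
  min(1, max(p, 1 / n_boot))
}

# Stratified fold assignment: labels are split per class and folds are
# dealt cyclically after a shuffle, keeping the class ratio in each fold.
stratified_folds <- function(labels, folds) {
  foldid <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    foldid[idx] <- rep_len(seq_len(folds), length(idx))
  }
  foldid
}

# Shared logarithmic penalty grid: 20 points over four decades below the
# smallest penalty that zeroes every coefficient on the full data.
lasso_lambda_grid <- function(X, y, n_points = 20L, decades = 4) {
  fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 1, nlambda = 5,
                        standardize = FALSE)
  lmax <- max(fit$lambda)
  10^seq(log10(lmax), log10(lmax) - decades, length.out = n_points)
}

#' Bootstrap-LASSO feature selection
#'
#' For each of `n_boot` bootstrap replicates: resample subjects with
#' replacement (redrawing if a single class is drawn), choose the L1
#' penalty by stratified `folds`-fold cross-validation on the resample
#' over a fixed logarithmic grid (20 points spanning four decades) using
#' the one-standard-error parsimony rule, fit
#' the L1-penalised logistic regression at the selected penalty, record
#' which coefficients are nonzero, and score the fit by AUROC on the
#' out-of-bag subjects. Selection probability is the fraction of
#' replicates in which a feature's coefficient was nonzero; the mean
#' coefficient is averaged over those replicates only. AUROC summaries
#' are on the percent scale. Features are expected to be standardised
#' beforehand (see [standardize()]); no internal rescaling is applied.
#'
#' @param table standardised feature tibble with a binary `label`.
#' @param n_boot number of bootstrap replicates (reference protocol:
#'   1000).
#' @param folds inner cross-validation folds, default 5.
#' @param seed master seed; replicate `b` uses `seed + b`.
#' @param lambda optional fixed penalty grid (overrides the automatic
#'   grid).
#' @param score_mode `"oob"` (default) scores each replicate on its
#'   out-of-bag subjects; `"cv"` records the replicate's best inner
#'   cross-validated AUROC instead.
#' @return A `selection_result` with elements `selection` (tibble:
#'   `feature`, `selection_probability`, `mean_coefficient`),
#'   `replicates` (tibble: `replicate`, `auroc`, `lambda`, `n_selected`),
#'   `auroc_mean`, `auroc_sd`, `n_boot`, `score_mode`, `n_redrawn`.
#' @export
bootstrap_lasso <- function(table, n_boot = 1000L, folds = 5L, seed = 1L,
                            lambda = NULL, score_mode = c("oob", "cv")) {
  score_mode <- match.arg(score_mode)
  n_boot <- as.integer(n_boot)
  if (n_boot < 1L) abort("`n_boot` must be at least 1.")
  feats <- feature_columns(table)
  X <- as.matrix(table[, feats])
  y <- as.integer(table$label)
  if (length(unique(y)) != 2L) abort("Both classes must be present.")
  n <- nrow(X)
  if (is.null(lambda)) {
    lambda <- with_seed(seed, lasso_lambda_grid(X, y))
  }
  sel_count <- setNames(numeric(length(feats)), feats)
  coef_sum <- setNames(numeric(length(feats)), feats)
  rep_auroc <- rep(NA_real_, n_boot)
  rep_lambda <- rep(NA_real_, n_boot)
  rep_nsel <- rep(NA_integer_, n_boot)
  n_redrawn <- 0L
  for (b in seq_len(n_boot)) {
    res <- with_seed(seed + b, {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(y[idx])) == 2L) break
        n_redrawn <- n_redrawn + 1L  # expr runs in this frame; plain assignment
      }
      yb <- y[idx]
      foldid <- stratified_folds(yb, folds)
      cvfit <- glmnet::cv.glmnet(
        X[idx, , drop = FALSE], yb, family = "binomial", alpha = 1,
        lambda = lambda, foldid = foldid, standardize = FALSE,
        type.measure = if (score_mode == "cv") "auc" else "deviance"
      )
      cf <- as.numeric(coef(cvfit, s = "lambda.1se"))[-1]
      oob <- setdiff(seq_len(n), unique(idx))
      sc <- if (score_mode == "cv") {
        100 * max(cvfit$cvm)
      } else if (length(oob) >= 2L && length(unique(y[oob])) == 2L) {
        pr <- predict(cvfit, newx = X[oob, , drop = FALSE],
                      s = "lambda.1se", type = "response")
        auroc(as.numeric(pr), y[oob])
      } else NA_real_
      list(cf = cf, sc = sc, lam = cvfit$lambda.1se)
    })
    nz <- res$cf != 0
    sel_count[nz] <- sel_count[nz] + 1
    coef_sum[nz] <- coef_sum[nz] + res$cf[nz]
    rep_auroc[b] <- res$sc
    rep_lambda[b] <- res$lam
    rep_nsel[b] <- sum(nz)
  }
  selection <- tibble(
    feature = feats,
    selection_probability = as.numeric(sel_count) / n_boot,
    mean_coefficient = ifelse(sel_count > 0, coef_sum / sel_count, NA_real_)
  )
  structure(
    list(
      selection = selection,
      replicates = tibble(replicate = seq_len(n_boot), auroc = rep_auroc,
                          lambda = rep_lambda, n_selected = rep_nsel),
      auroc_mean = mean(rep_auroc, na.rm = TRUE),
      auroc_sd = sd(rep_auroc[!is.na(rep_auroc)]),
      n_boot = n_boot, folds = folds, seed = seed,
      score_mode = score_mode, n_redrawn = n_redrawn
    ),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d bootstrap replicates (%s scoring)\n",
              x$n_boot, x$score_mode))
  cat(sprintf("  AUROC %.2f (SD %.2f)\n", x$auroc_mean, x$auroc_sd))
  top <- dplyr::arrange(x$selection,
                        dplyr::desc(.data$selection_probability))
  print(head(top, 5))
  invisible(x)
}

#' @export
tidy.selection_result <- function(x, ...) {
  dplyr::arrange(x$selection, dplyr::desc(.data$selection_probability),
                 dplyr::desc(abs(.data$mean_coefficient)))
}

#' @export
glance.selection_result <- function(x, ...) {
  tibble(
    auroc_mean = x$auroc_mean, auroc_sd = x$auroc_sd,
    n_boot = x$n_boot, folds = x$folds,
    score_mode = x$score_mode, n_redrawn = x$n_redrawn
  )
}

#' @export
autoplot.selection_result <- function(object, ...) {
  df <- tidy(object)
  df$feature <- factor(df$feature, levels = rev(df$feature))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$selection_probability,
                                   y = .data$feature)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Selection probability", y = NULL) +
    ggplot2::xlim(0, 1) +
    ggplot2::theme_minimal()
}

#' Rank features by selection probability
#'
#' @param result a [bootstrap_lasso()] result.
#' @param k number of features to return; ties in probability are broken
#'   by mean absolute coefficient.
#' @return Character vector of `k` feature names.
#' @export
rank_features <- function(result, k) {
  stopifnot(inherits(result, "selection_result"))
  if (k > nrow(result$selection)) abort("`k` exceeds the number of features.")
  if (k <= 0) return(character(0))
  tidy(result)$feature[seq_len(k)]
}

#' Fit a simplified logistic classifier
#'
#' Unpenalised logistic regression on a named subset of (standardised)
#' features. If the fit does not converge or shows quasi-complete
#' separation (any |coefficient| > 15 on standardised inputs), the model
#' falls back to a negligible ridge penalty (lambda = 1e-4) with a
#' warning, which bounds the coefficients without materially changing the
#' decision boundary.
#'
#' @param train standardised feature tibble with binary `label`.
#' @param features character vector of feature names to use.
#' @return A `simplified_model` exposing `coefficients` (intercept first),
#'   `features` and `fallback_ridge`.
#' @export
fit_simplified <- function(train, features) {
  missing_f <- setdiff(features, names(train))
  if (length(missing_f)) {
    abort(sprintf("Features not in table: %s", paste(missing_f, collapse = ", ")))
  }
  X <- as.matrix(train[, features, drop = FALSE])
  y <- as.integer(train$label)
  fit <- suppressWarnings(glm(y ~ X, family = binomial()))
  sep <- !fit$converged || any(abs(coef(fit)[-1]) > 15)
  if (sep) {
    warn("Quasi-separation detected; refitting with a negligible ridge penalty.")
    Xr <- if (ncol(X) == 1L) cbind(X, 0) else X  # glmnet needs >= 2 columns
    rfit <- glmnet::glmnet(Xr, y, family = "binomial", alpha = 0,
                           lambda = 1e-4, standardize = FALSE)
    cf <- as.numeric(coef(rfit))[seq_len(ncol(X) + 1L)]
  } else {
    cf <- as.numeric(coef(fit))
  }
  structure(
    list(coefficients = setNames(cf, c("(Intercept)", features)),
         features = features, fallback_ridge = sep),
    class = "simplified_model"
  )
}

#' @export
print.simplified_model <- function(x, ...) {
  cat(sprintf("<simplified_model> %d features%s\n", length(x$features),
              if (x$fallback_ridge) " (ridge fallback)" else ""))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
predict.simplified_model <- function(object, newdata, type = "response", ...) {
  X <- as.matrix(newdata[, object$features, drop = FALSE])
  eta <- drop(object$coefficients[1] + X %*% object$coefficients[-1])
  if (type == "link") eta else plogis(eta)
}

#' @export
tidy.simplified_model <- function(x, ...) {
  tibble(term = names(x$coefficients), estimate = as.numeric(x$coefficients))
}

#' @export
glance.simplified_model <- function(x, ...) {
  tibble(n_features = length(x$features), fallback_ridge = x$fallback_ridge)
}

#' Evaluate a fitted classifier on a test table
#'
#' Scores the model on an independently standardised test table and
#' reports AUROC, sensitivity, specificity and balanced accuracy at the
#' given probability threshold.
#'
#' @param model a [fit_simplified()] model.
#' @param test standardised test tibble containing the model features and
#'   `label`.
#' @param threshold probability threshold, default 0.5.
#' @return An `evaluation_report` tibble (see [classification_metrics()]).
#' @export
evaluate_model <- function(model, test, threshold = 0.5) {
  p <- predict(model, test)
  classification_metrics(p, test$label, threshold)
}
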