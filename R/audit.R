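#' Extract the maximal all-zero submatrix of rarely seen genera
#'
#' Reproduces the empty-submatrix construction used to demonstrate
#' normalization leakage: keep only genera present (count > 0) in strictly
#' fewer than `prevalence_threshold` samples, then keep only samples whose
#' raw counts are zero for every retained genus. The result is maximal: no
#' further sample can be added without introducing a non-zero raw count.
#'
#' @param counts Non-negative integer matrix, samples x genera, dimnames set.
#' @param prevalence_threshold Integer >= 1; default 50.
#' @return A list of class `empty_submatrix_index` with `sample_ids`,
#'   `genus_ids`, `prevalence_threshold`.
#' @export
extract_empty_submatrix <- function(counts, prevalence_threshold = 50L) {
  stopifnot(is.matrix(counts))
  check_scalar(prevalence_threshold, "prevalence_threshold", 1,
               integerish = TRUE)
  prevalence <- colSums(counts > 0)
  keep_g <- which(prevalence < prevalence_threshold)
  keep_s <- which(rowSums(counts[, keep_g, drop = FALSE] > 0) == 0)
  structure(
    list(sample_ids = rownames(counts)[keep_s],
         genus_ids = colnames(counts)[keep_g],
         prevalence_threshold = as.integer(prevalence_threshold)),
    class = "empty_submatrix_index"
  )
}

#' Populate an empty submatrix with normalized values
#'
#' Looks up, for every (sample, genus) pair retained by
#' [extract_empty_submatrix()], the corresponding cell of a normalized
#' matrix. Every raw count in the result's footprint is zero, so any
#' class signal in the populated values was introduced by normalization.
#'
#' @param index An `empty_submatrix_index`.
#' @param normalized A `normalized_matrix` (or a plain real matrix with
#'   dimnames) aligned to the same identifiers.
#' @return Real matrix of dimension `length(sample_ids) x length(genus_ids)`.
#' @export
populate_from_normalized <- function(index, normalized) {
  stopifnot(inherits(index, "empty_submatrix_index"))
  vals <- if (inherits(normalized, "normalized_matrix")) {
    normalized$values
  } else {
    normalized
  }
  missing_s <- setdiff(index$sample_ids, rownames(vals))
  missing_g <- setdiff(index$genus_ids, colnames(vals))
  if (length(missing_s) > 0 || length(missing_g) > 0) {
    stop("identifiers absent from the normalized matrix: ",
         paste(c(missing_s, missing_g), collapse = ", "), call. = FALSE)
  }
  vals[index$sample_ids, index$genus_ids, drop = FALSE]
}

auroc_rank <- function(labels, scores) {
  # Wilcoxon rank-sum identity; used as the no-signal fallback guard
  r <- rank(scores)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (lv in unique(labels)) {
    idx <- sample(which(labels == lv))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

fit_predict <- function(x_train, y_train, x_test, backend, seed) {
  if (backend == "xgboost") {
    dtrain <- xgboost::xgb.DMatrix(x_train, label = y_train)
    bst <- xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = 3,
                    eta = 0.1, nthread = 1, seed = seed),
      data = dtrain, nrounds = 200, verbose = 0
    )
    stats::predict(bst, xgboost::xgb.DMatrix(x_test))
  } else {
    if (!requireNamespace("glmnet", quietly = TRUE)) {
      stop("backend 'glmnet' requires the glmnet package", call. = FALSE)
    }
    fit <- glmnet::glmnet(x_train, y_train, family = "binomial",
                          alpha = 0, lambda = 0.01)
    as.numeric(stats::predict(fit, x_test, type = "response"))
  }
}

#' One-vs-rest classifier audit with cross-validated AUROC
#'
#' For each class, trains a one-vs-rest classifier (gradient-boosted trees,
#' 200 rounds, depth 3, learning rate 0.1; or a ridge-penalized logistic
#' model) under stratified cross-validation and reports out-of-fold AUROC
#' plus sensitivity, specificity, PPV and NPV at the probability-0.5
#' operating point. High AUROC on a matrix whose raw counts were all zero
#' is direct evidence of information leakage.
#'
#' Feature columns that are numerically constant (variation at rounding
#' noise relative to magnitude) are dropped; if none remain, every class is
#' reported with AUROC 0.5 and flagged `"no signal"`. Classes with fewer
#' members than `cv_folds` are reported as skipped.
#'
#' @param values Real feature matrix, samples x features.
#' @param labels Class label per sample (character or factor).
#' @param cv_folds Number of stratified folds (default 5).
#' @param seed Integer seed controlling fold assignment and the learner.
#' @param backend `"xgboost"` (default) or `"glmnet"`.
#' @param threshold Probability cut-off for the operating point.
#' @return A data.frame of class `audit_report`: one row per class with
#'   `class`, `n_pos`, `n_neg`, `auroc`, `sensitivity`, `specificity`,
#'   `ppv`, `npv`, `flag` (`""`, `"no signal"`, or `"skipped"`).
#' @export
one_vs_all_audit <- function(values, labels, cv_folds = 5L, seed = 1L,
                             backend = c("xgboost", "glmnet"),
                             threshold = 0.5) {
  backend <- match.arg(backend)
  stopifnot(is.matrix(values), nrow(values) == length(labels))
  check_scalar(cv_folds, "cv_folds", 2, integerish = TRUE)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2) {
    stop("need at least two classes", call. = FALSE)
  }

  keep <- which(!apply(values, 2, is_constant_col))
  no_signal <- length(keep) == 0
  x <- values[, keep, drop = FALSE]

  withr::local_seed(seed)
  rows <- lapply(classes, function(cl) {
    y <- labels == cl
    n_pos <- sum(y)
    n_neg <- sum(!y)
    base <- data.frame(class = cl, n_pos = n_pos, n_neg = n_neg,
                       auroc = NA_real_, sensitivity = NA_real_,
                       specificity = NA_real_, ppv = NA_real_,
                       npv = NA_real_, flag = "", stringsAsFactors = FALSE)
    if (n_pos < cv_folds || n_neg < cv_folds) {
      base$flag <- "skipped"
      return(base)
    }
    if (no_signal) {
      base$auroc <- 0.5
      base$flag <- "no signal"
      return(base)
    }
    fold <- stratified_folds(y, cv_folds)
    scores <- numeric(length(y))
    for (f in seq_len(cv_folds)) {
      tr <- fold != f
      scores[!tr] <- fit_predict(x[tr, , drop = FALSE], as.numeric(y[tr]),
                                 x[!tr, , drop = FALSE], backend, seed)
    }
    base$auroc <- as.numeric(pROC::auc(
      pROC::roc(response = y, predictor = scores, direction = "<",
                levels = c(FALSE, TRUE), quiet = TRUE)))
    pred <- scores >= threshold
    tp <- sum(pred & y); fp <- sum(pred & !y)
    tn <- sum(!pred & !y); fn <- sum(!pred & y)
    base$sensitivity <- tp / n_pos
    base$specificity <- tn / n_neg
    base$ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    base$npv <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
    base
  })
  out <- do.call(rbind, rows)
  class(out) <- c("audit_report", "data.frame")
  out
}

#' Sensitivity and whole-cohort error fraction of a single-threshold rule
#'
#' Evaluates the rule "label a sample positive when its value is on
#' `positive_side` of `threshold`", reporting sensitivity (TP / positives)
#' and the error fraction with *all* samples as denominator (FP / total) -
#' the convention used when a published rule's false-positive count is
#' quoted against the full cohort size.
#'
#' @param values Real vector.
#' @param labels Logical (or 0/1) vector; `TRUE` = positive class.
#' @param threshold Cut-off value.
#' @param positive_side `"le"` (value <= threshold is called positive) or
#'   `"gt"` (value > threshold).
#' @return List with `sensitivity` and `error_fraction`.
#' @export
threshold_rule_metrics <- function(values, labels, threshold,
                                   positive_side = c("le", "gt")) {
  positive_side <- match.arg(positive_side)
  stopifnot(length(values) == length(labels), length(values) > 0)
  labels <- as.logical(labels)
  if (!any(labels)) stop("labels contain no positives", call. = FALSE)
  pred <- if (positive_side == "le") values <= threshold else
    values > threshold
  list(
    sensitivity = sum(pred & labels) / sum(labels),
    error_fraction = sum(pred & !labels) / length(values)
  )
}

#' Group identical values and report group sizes
#'
#' Exact (bit-level) equality grouping, no tolerance: normalization leaks
#' manifest as many samples sharing bit-identical normalized values, so
#' duplicated-value multiplicity is itself a diagnostic.
#'
#' @param values Real vector.
#' @return A data.frame with columns `value` and `size`, ordered by
#'   decreasing size (ties by value); sizes sum to `length(values)`.
#' @export
value_multiplicity <- function(values) {
  if (length(values) == 0) {
    return(data.frame(value = numeric(0), size = integer(0)))
  }
  # match() compares doubles by exact value, avoiding the precision loss a
  # character-based table would introduce
  u <- unique(values)
  out <- data.frame(value = u, size = tabulate(match(values, u),
                                               nbins = length(u)))
  out <- out[order(-out$size, out$value), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-feature leakage score
#'
#' Restricted to samples whose raw count is zero, the score is the best
#' one-vs-rest single-threshold balanced accuracy over classes, thresholds
#' and sides, in `[0.5, 1]`. A value near 1 means the normalized values of
#' raw-zero samples separate a class almost perfectly - the signature of a
#' label imprint. Returns 0.5 when fewer than two classes remain after the
#' restriction (including the no-zero-count case).
#'
#' @param raw_column Integer vector of raw counts.
#' @param normalized_column Real vector of normalized values, aligned.
#' @param labels Class label per sample.
#' @return Scalar in `[0.5, 1]`.
#' @export
leakage_score <- function(raw_column, normalized_column, labels) {
  stopifnot(length(raw_column) == length(normalized_column),
            length(raw_column) == length(labels))
  zero <- raw_column == 0
  v <- normalized_column[zero]
  l <- as.character(labels)[zero]
  if (length(unique(l)) < 2) return(0.5)
  cuts <- sort(unique(v))
  cand <- c(-Inf, (cuts[-1] + cuts[-length(cuts)]) / 2, Inf)
  best <- 0.5
  for (cl in unique(l)) {
    y <- l == cl
    np <- sum(y); nn <- sum(!y)
    for (thr in cand) {
      le <- v <= thr
      bacc_le <- (sum(le & y) / np + sum(!le & !y) / nn) / 2
      best <- max(best, bacc_le, 1 - bacc_le)
    }
  }
  best
}

#' Per-feature leakage diagnostics
#'
#' Combines [leakage_score()] and [value_multiplicity()] for every genus
#' column of a raw/normalized matrix pair.
#'
#' @param raw Integer matrix, samples x genera.
#' @param normalized A `normalized_matrix` or real matrix aligned to `raw`.
#' @param labels Class label per sample.
#' @return A data.frame with `feature`, `leakage_score`,
#'   `max_dup_group` (largest identical-value group size).
#' @export
feature_audit <- function(raw, normalized, labels) {
  vals <- if (inherits(normalized, "normalized_matrix")) {
    normalized$values
  } else normalized
  stopifnot(identical(dim(raw), dim(vals)))
  data.frame(
    feature = colnames(raw),
    leakage_score = vapply(seq_len(ncol(raw)), function(j) {
      leakage_score(raw[, j], vals[, j], labels)
    }, numeric(1)),
    max_dup_group = vapply(seq_len(ncol(raw)), function(j) {
      max(value_multiplicity(vals[, j])$size)
    }, integer(1)),
    stringsAsFactors = FALSE
  )
}
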