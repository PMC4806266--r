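#' RBF-SVM hyperparameters
#'
#' @param C Positive cost parameter.
#' @param gamma Positive RBF kernel width (distinct from the firefly light
#'   absorption coefficient).
#' @param class_weighting Balance classes by inverse frequency during
#'   training (off by default).
#' @return An object of class `svm_params`.
#' @export
svm_params <- function(C = 64, gamma = 0.03125, class_weighting = FALSE) {
  if (!is_scalar_num(C) || C <= 0) stop("C must be positive", call. = FALSE)
  if (!is_scalar_num(gamma) || gamma <= 0) {
    stop("gamma must be positive", call. = FALSE)
  }
  structure(list(C = C, gamma = gamma,
                 class_weighting = isTRUE(class_weighting)),
            class = "svm_params")
}

# Min-max scaling of each column to [-1, 1], fitted on training rows only.
# Constant columns map to 0.
minmax_fit <- function(x) {
  list(min = apply(x, 2, min), max = apply(x, 2, max))
}

minmax_apply <- function(fit, x) {
  span <- fit$max - fit$min
  out <- sweep(x, 2, fit$min)
  out <- sweep(out, 2, ifelse(span > 0, span, 1), "/")
  out <- 2 * out - 1
  out[, span == 0] <- 0
  out
}

#' Classification metrics from a confusion matrix
#'
#' Sensitivity `TP / (TP + FN)`, specificity `TN / (TN + FP)`, accuracy
#' `(TP + TN) / total` and the Matthews correlation coefficient
#' `(TP * TN - FP * FN) / sqrt((TP + FN)(TP + FP)(TN + FP)(TN + FN))`.
#' Any metric whose denominator is zero is reported as 0.
#'
#' @param tp,tn,fp,fn Non-negative confusion counts (not all zero).
#' @return A list with `sn`, `sp`, `acc`, `mcc`.
#' @export
compute_metrics <- function(tp, tn, fp, fn) {
  counts <- c(tp, tn, fp, fn)
  if (any(counts < 0) || anyNA(counts)) {
    stop("confusion counts must be non-negative", call. = FALSE)
  }
  if (sum(counts) == 0) {
    stop("all confusion counts are zero; nothing was evaluated",
         call. = FALSE)
  }
  safe_div <- function(num, den) if (den > 0) num / den else 0
  denom <- sqrt(prod(c(tp + fn, tp + fp, tn + fp, tn + fn)))
  list(
    sn = safe_div(tp, tp + fn),
    sp = safe_div(tn, tn + fp),
    acc = safe_div(tp + tn, sum(counts)),
    mcc = safe_div(tp * tn - fp * fn, denom)
  )
}

#' Rank-based area under the ROC curve
#'
#' The probability that a uniformly chosen positive outscores a uniformly
#' chosen negative, with ties counted half (equivalent to the Mann-Whitney
#' statistic).
#'
#' @param scores Real-valued decision scores.
#' @param labels Binary labels, both classes present.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop("AUC requires both classes", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Train an RBF-kernel SVM on a feature matrix
#'
#' Fits a min-max scaler (to \[-1, 1\]) on the training rows, then a C-SVC
#' with Gaussian kernel via libsvm. The scaler travels with the model so
#' prediction-time inputs are transformed with training statistics only.
#'
#' @param x Training feature matrix.
#' @param y Binary labels (both classes present).
#' @param params An [svm_params()] object.
#' @return An object of class `sulfire_model`.
#' @export
svm_train <- function(x, y, params = svm_params()) {
  y <- as.integer(y)
  if (length(unique(y)) < 2) {
    stop("training labels contain a single class", call. = FALSE)
  }
  scaler <- minmax_fit(x)
  xs <- minmax_apply(scaler, x)
  weights <- NULL
  if (params$class_weighting) {
    tab <- table(factor(y, levels = c(0, 1)))
    weights <- as.numeric(length(y) / (2 * tab))
    names(weights) <- names(tab)
  }
  fit <- e1071::svm(xs, factor(y, levels = c(0, 1)), type = "C-classification",
                    kernel = "radial", cost = params$C, gamma = params$gamma,
                    scale = FALSE, class.weights = weights)
  structure(list(fit = fit, scaler = scaler, params = params,
                 feature_names = colnames(x), n_features = ncol(x)),
            class = "sulfire_model")
}

#' Predict decision scores or classes from a trained model
#'
#' Decision scores are libsvm signed margins oriented so that larger values
#' favour the positive (sulfated) class; classes are the libsvm decisions at
#' threshold 0.
#'
#' @param object A `sulfire_model`.
#' @param newdata Feature matrix with the model's feature width.
#' @param type `"score"` or `"class"`.
#' @param ... Unused.
#' @return Numeric scores or integer 0/1 classes, one per row.
#' @export
predict.sulfire_model <- function(object, newdata, type = c("score", "class"),
                                  ...) {
  type <- match.arg(type)
  if (!is.matrix(newdata)) newdata <- matrix(newdata, nrow = 1)
  if (ncol(newdata) != object$n_features) {
    stop("newdata has ", ncol(newdata), " features, model expects ",
         object$n_features, call. = FALSE)
  }
  xs <- minmax_apply(object$scaler, newdata)
  pred <- predict(object$fit, xs, decision.values = TRUE)
  if (type == "class") return(as.integer(as.character(pred)))
  dv <- attr(pred, "decision.values")
  oriented <- if (startsWith(colnames(dv)[1], "1/")) dv[, 1] else -dv[, 1]
  unname(oriented)
}

# Stratified fold assignment: within each class, indices are shuffled and
# dealt round-robin so every fold holds both classes whenever each class
# count >= k.
make_folds <- function(y, k, seed = 1) {
  y <- as.integer(y)
  counts <- table(factor(y, levels = c(0, 1)))
  if (any(counts < k)) {
    stop("each class needs at least ", k, " samples for ", k,
         "-fold cross-validation; reduce the number of folds", call. = FALSE)
  }
  folds <- integer(length(y))
  with_seed(seed, {
    for (cls in c(0L, 1L)) {
      idx <- sample(which(y == cls))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Stratified k-fold cross-validation of the RBF-SVM
#'
#' Folds are stratified and seeded. In each iteration the scaler and SVM are
#' fitted on the training folds only; sensitivity, specificity, accuracy,
#' MCC and AUC (on decision scores) are computed on the held-out fold and
#' the report averages the per-fold values.
#'
#' @param x Feature matrix.
#' @param y Binary labels; each class must have at least `folds` samples.
#' @param params An [svm_params()].
#' @param folds Number of folds (default 10).
#' @param seed Seed controlling the fold assignment.
#' @return An object of class `metrics_report`: mean `sn`, `sp`, `acc`,
#'   `mcc`, `auc`, plus `folds` and the `per_fold` breakdown.
#' @export
cross_validate <- function(x, y, params = svm_params(), folds = 10,
                           seed = 1) {
  y <- as.integer(y)
  if (nrow(x) != length(y)) {
    stop("number of rows of x must match length of y", call. = FALSE)
  }
  assign <- make_folds(y, folds, seed = seed)
  per_fold <- lapply(seq_len(folds), function(f) {
    test <- assign == f
    model <- svm_train(x[!test, , drop = FALSE], y[!test], params)
    scores <- predict(model, x[test, , drop = FALSE], type = "score")
    classes <- predict(model, x[test, , drop = FALSE], type = "class")
    truth <- y[test]
    m <- compute_metrics(tp = sum(classes == 1 & truth == 1),
                         tn = sum(classes == 0 & truth == 0),
                         fp = sum(classes == 1 & truth == 0),
                         fn = sum(classes == 0 & truth == 1))
    m$auc <- roc_auc(scores, truth)
    as.data.frame(m)
  })
  per_fold <- do.call(rbind, per_fold)
  per_fold$fold <- seq_len(folds)
  structure(list(
    sn = mean(per_fold$sn), sp = mean(per_fold$sp),
    acc = mean(per_fold$acc), mcc = mean(per_fold$mcc),
    auc = mean(per_fold$auc),
    folds = folds, seed = seed, params = params, per_fold = per_fold
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "%d-fold CV: SN %.4f  SP %.4f  ACC %.4f  MCC %.4f  AUC %.4f\n",
    x$folds, x$sn, x$sp, x$acc, x$mcc, x$auc))
  invisible(x)
}

#' Persist a trained model (with scaler and provenance) to disk
#'
#' @param model A `sulfire_model`.
#' @param path Destination file.
#' @export
save_model <- function(model, path) {
  if (!inherits(model, "sulfire_model")) {
    stop("model must be a sulfire_model", call. = FALSE)
  }
  saveRDS(list(format = "sulfire_model", version = 1L, model = model), path)
  invisible(path)
}

#' Load a model written by [save_model()], verifying its integrity
#'
#' @param path Model file.
#' @return The `sulfire_model`.
#' @export
load_model <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e) {
    stop("model file '", path, "' is unreadable or truncated: ",
         conditionMessage(e), call. = FALSE)
  })
  if (!is.list(obj) || !identical(obj$format, "sulfire_model") ||
      !inherits(obj$model, "sulfire_model")) {
    stop("model file '", path, "' failed the integrity check", call. = FALSE)
  }
  obj$model
}
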