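#' Run the full selection-and-training pipeline on an encoded dataset
#'
#' Executes the complete modelling chain on a feature matrix: a stratified
#' train/hold-out split, relative entropy ranking on the training split, a
#' hyperparameter grid search, incremental feature selection to the MCC
#' peak, discrete firefly refinement of the peak subset with joint (C,
#' gamma) optimization, a final SVM fit on the training split, and hold-out
#' evaluation. Every stochastic step is seeded from `seed`, so a re-run
#' with the same inputs reproduces all numbers.
#'
#' @param x Feature matrix (n x 472 for the default encoder).
#' @param y Binary labels.
#' @param seed Master seed.
#' @param holdout_fraction Fraction of samples held out for the final
#'   evaluation (stratified; default 0.3).
#' @param n_bins Histogram bins for the relative entropy ranking.
#' @param grid_step Step of the `log2` hyperparameter grids (default 4; use
#'   2 for the fine grid).
#' @param cv_folds Folds for grid search and IFS cross-validation.
#' @param ifs_max_k Largest ranked prefix evaluated during IFS.
#' @param dfa Configuration of the firefly refinement; `NULL` disables it
#'   and keeps the IFS peak subset with the grid-searched parameters.
#' @param dfa_cv_folds Folds of the cross-validation inside the firefly
#'   fitness evaluator (smaller than `cv_folds` to bound cost).
#' @return An object of class `sulfire_fit` with the ranking, IFS table,
#'   peak, firefly result, selected feature indices, final model and
#'   hold-out metrics.
#' @export
run_pipeline <- function(x, y, seed = 1, holdout_fraction = 0.3,
                         n_bins = 20, grid_step = 4, cv_folds = 5,
                         ifs_max_k = 30,
                         dfa = dfa_config(group_size = 20,
                                          max_generation = 30,
                                          seed = seed + 1),
                         dfa_cv_folds = 3) {
  y <- as.integer(y)
  split <- with_seed(seed, {
    test <- logical(length(y))
    for (cls in c(0L, 1L)) {
      idx <- which(y == cls)
      test[sample(idx, round(holdout_fraction * length(idx)))] <- TRUE
    }
    test
  })
  x_tr <- x[!split, , drop = FALSE]
  y_tr <- y[!split]
  x_te <- x[split, , drop = FALSE]
  y_te <- y[split]

  ranking <- rank_features(x_tr, y_tr, n_bins = n_bins)
  grid <- grid_search_svm(x_tr, y_tr,
                          c_log2 = seq(-5, 15, by = grid_step),
                          gamma_log2 = seq(-15, 5, by = grid_step),
                          folds = cv_folds, seed = seed + 2)
  ifs <- run_ifs(x_tr, y_tr, ranking, params = grid$best, folds = cv_folds,
                 seed = seed + 3, max_k = ifs_max_k)
  peak <- select_peak(ifs)

  if (!is.null(dfa)) {
    candidates <- peak$features
    evaluator <- function(mask, C, gamma) {
      cols <- candidates[as.logical(mask)]
      cross_validate(x_tr[, cols, drop = FALSE], y_tr,
                     svm_params(C = C, gamma = gamma),
                     folds = dfa_cv_folds, seed = seed + 4)$mcc
    }
    dfa_result <- dfa_optimize(evaluator, n = length(candidates),
                               config = dfa)
    selected <- candidates[as.logical(dfa_result$best_mask)]
    final_params <- svm_params(C = dfa_result$best_C,
                               gamma = dfa_result$best_gamma)
  } else {
    dfa_result <- NULL
    selected <- peak$features
    final_params <- grid$best
  }

  model <- svm_train(x_tr[, selected, drop = FALSE], y_tr, final_params)
  scores <- predict(model, x_te[, selected, drop = FALSE], type = "score")
  classes <- predict(model, x_te[, selected, drop = FALSE], type = "class")
  holdout <- compute_metrics(tp = sum(classes == 1 & y_te == 1),
                             tn = sum(classes == 0 & y_te == 0),
                             fp = sum(classes == 1 & y_te == 0),
                             fn = sum(classes == 0 & y_te == 1))
  holdout$auc <- roc_auc(scores, y_te)

  structure(list(
    seed = seed,
    ranking = ranking,
    grid = grid,
    ifs = ifs,
    peak = peak,
    dfa = dfa_result,
    selected_features = selected,
    selected_names = colnames(x)[selected],
    model = model,
    holdout = holdout,
    n_train = sum(!split), n_test = sum(split)
  ), class = "sulfire_fit")
}

#' @export
print.sulfire_fit <- function(x, ...) {
  cat("sulfire pipeline fit\n")
  cat(sprintf("  train/test: %d/%d samples\n", x$n_train, x$n_test))
  cat(sprintf("  IFS peak: k = %d (CV MCC %.4f)\n", x$peak$k, x$peak$mcc))
  cat(sprintf("  selected features: %d\n", length(x$selected_features)))
  cat(sprintf("  SVM: C = %.6g, gamma = %.6g\n", x$model$params$C,
              x$model$params$gamma))
  cat(sprintf("  hold-out: SN %.4f  SP %.4f  ACC %.4f  MCC %.4f  AUC %.4f\n",
              x$holdout$sn, x$holdout$sp, x$holdout$acc, x$holdout$mcc,
              x$holdout$auc))
  invisible(x)
}

#' Score every tyrosine of new proteins with a fitted pipeline
#'
#' Encodes each tyrosine window of the query proteins with the same
#' 472-feature encoder, restricts to the fitted feature subset and returns
#' per-site decision scores and calls. Proteins without tyrosines yield no
#' rows.
#'
#' @param fit A `sulfire_fit` from [run_pipeline()].
#' @param fasta Path to the query FASTA.
#' @param profiles_dir Directory with `<id>.pssm` / `.ss2` / `.diso` files.
#' @param xi Window half-width used at training time.
#' @return Data frame with `protein_id`, `position`, `score`, `call`.
#' @export
predict_sites <- function(fit, fasta, profiles_dir, xi = 4) {
  proteins <- read_fasta(fasta)
  windows <- build_windows(proteins,
                           data.frame(protein_id = character(),
                                      position = integer(),
                                      label = integer()),
                           window_config(xi))
  if (nrow(windows) == 0) {
    return(data.frame(protein_id = character(), position = integer(),
                      score = numeric(), call = integer(),
                      stringsAsFactors = FALSE))
  }
  profiles <- load_profiles(profiles_dir, unique(windows$protein_id))
  enc <- encode_dataset(windows, profiles, xi = xi)
  xs <- enc$x[, fit$selected_features, drop = FALSE]
  data.frame(
    protein_id = enc$windows$protein_id,
    position = enc$windows$center,
    score = predict(fit$model, xs, type = "score"),
    call = predict(fit$model, xs, type = "class"),
    stringsAsFactors = FALSE
  )
}
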