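#' Grid search over RBF-SVM hyperparameters
#'
#' Exhaustive search over `log2(C)` and `log2(gamma)` grids, scoring each
#' combination by mean cross-validated MCC with a shared fold assignment so
#' combinations are compared on identical splits. Ties keep the first
#' combination in iteration order (ascending C, then ascending gamma), which
#' makes the result deterministic.
#'
#' @param x Feature matrix.
#' @param y Binary labels.
#' @param c_log2 Grid of `log2(C)` values (default -5 to 15, step 2).
#' @param gamma_log2 Grid of `log2(gamma)` values (default -15 to 5, step 2).
#' @param folds,seed Cross-validation settings.
#' @return A list with `best` (an [svm_params()]) and `table` (one row per
#'   combination with its mean MCC).
#' @export
grid_search_svm <- function(x, y, c_log2 = seq(-5, 15, by = 2),
                            gamma_log2 = seq(-15, 5, by = 2),
                            folds = 10, seed = 1) {
  grid <- expand.grid(gamma_log2 = gamma_log2, c_log2 = c_log2)[, 2:1]
  mcc <- vapply(seq_len(nrow(grid)), function(k) {
    cross_validate(x, y,
                   svm_params(C = 2^grid$c_log2[k],
                              gamma = 2^grid$gamma_log2[k]),
                   folds = folds, seed = seed)$mcc
  }, numeric(1))
  grid$mcc <- mcc
  best <- which.max(mcc)
  list(best = svm_params(C = 2^grid$c_log2[best],
                         gamma = 2^grid$gamma_log2[best]),
       table = grid)
}

#' Incremental feature selection over a ranked feature list
#'
#' For each prefix length k of the ranked list, cross-validates the SVM on
#' the first k ranked features and records the mean metrics, producing the
#' IFS table whose peak identifies the pre-selected feature subset.
#'
#' @param x Feature matrix.
#' @param y Binary labels.
#' @param ranking A `ranked_features` object from [rank_features()].
#' @param params SVM hyperparameters held fixed across prefixes.
#' @param folds,seed Cross-validation settings (the same fold assignment is
#'   reused for every prefix).
#' @param max_k Largest prefix evaluated (defaults to the full list).
#' @return An object of class `ifs_table`: a data frame with columns `k`,
#'   `sn`, `sp`, `acc`, `mcc`, `auc`, carrying provenance attributes
#'   `seed`, `folds` and `params`.
#' @export
run_ifs <- function(x, y, ranking, params = svm_params(), folds = 10,
                    seed = 1, max_k = nrow(ranking)) {
  if (nrow(x) == 0 || ncol(x) == 0) {
    stop("feature matrix is empty; nothing to select", call. = FALSE)
  }
  max_k <- min(max_k, nrow(ranking))
  records <- lapply(seq_len(max_k), function(k) {
    cols <- ranking$feature[seq_len(k)]
    rep <- cross_validate(x[, cols, drop = FALSE], y, params,
                          folds = folds, seed = seed)
    data.frame(k = k, sn = rep$sn, sp = rep$sp, acc = rep$acc,
               mcc = rep$mcc, auc = rep$auc)
  })
  out <- do.call(rbind, records)
  attr(out, "seed") <- seed
  attr(out, "folds") <- folds
  attr(out, "params") <- params
  attr(out, "ranking") <- ranking
  class(out) <- c("ifs_table", "data.frame")
  out
}

#' Locate the IFS peak
#'
#' Returns the smallest prefix length achieving the maximum mean MCC,
#' together with the corresponding feature indices.
#'
#' @param table An `ifs_table`.
#' @return A list with `k`, `mcc` and `features` (column indices of the
#'   original matrix).
#' @export
select_peak <- function(table) {
  if (!inherits(table, "ifs_table") || nrow(table) == 0) {
    stop("select_peak needs a non-empty IFS table", call. = FALSE)
  }
  best <- which.max(table$mcc)   # first maximum = smallest k
  ranking <- attr(table, "ranking")
  list(k = table$k[best], mcc = table$mcc[best],
       features = ranking$feature[seq_len(table$k[best])])
}

#' Write an IFS table as TSV
#'
#' @param table An `ifs_table`.
#' @param path Output path.
#' @export
write_ifs_tsv <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
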