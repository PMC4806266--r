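#' Symmetric Kullback-Leibler divergence between class-conditional samples
#'
#' Estimates the class-conditional densities of one feature with a shared
#' equal-width histogram over the pooled range, applies add-one smoothing to
#' both class counts, normalizes to probabilities p and q and returns the
#' symmetric divergence
#' `sum(p * log(p / q)) + sum(q * log(q / p))` (natural log). A feature that
#' is constant over the pooled sample has zero divergence by definition.
#'
#' @param pos_values Feature values in the positive class (non-empty).
#' @param neg_values Feature values in the negative class (non-empty).
#' @param n_bins Number of histogram bins (>= 2).
#' @return Non-negative finite divergence.
#' @export
kl_symmetric <- function(pos_values, neg_values, n_bins = 20) {
  if (length(pos_values) == 0 || length(neg_values) == 0) {
    stop("both classes must be non-empty", call. = FALSE)
  }
  if (!all(is.finite(pos_values)) || !all(is.finite(neg_values))) {
    stop("feature values must be finite", call. = FALSE)
  }
  if (n_bins < 2) stop("n_bins must be at least 2", call. = FALSE)
  pooled <- range(c(pos_values, neg_values))
  if (pooled[1] == pooled[2]) return(0)
  breaks <- seq(pooled[1], pooled[2], length.out = n_bins + 1)
  bin <- function(v) {
    idx <- findInterval(v, breaks, rightmost.closed = TRUE,
                        all.inside = TRUE)
    tabulate(idx, nbins = n_bins)
  }
  p <- bin(pos_values) + 1
  q <- bin(neg_values) + 1
  p <- p / sum(p)
  q <- q / sum(q)
  sum(p * log(p / q)) + sum(q * log(q / p))
}

#' Rank features by symmetric K-L divergence (relative entropy selection)
#'
#' Scores every column of the feature matrix with [kl_symmetric()] and
#' returns the feature list ordered by decreasing divergence, ties broken by
#' the smaller column index.
#'
#' @param x Feature matrix (n samples x N features).
#' @param y Binary labels (both classes present).
#' @param n_bins Histogram bins passed to [kl_symmetric()].
#' @return An object of class `ranked_features`: a data frame with columns
#'   `rank`, `feature` (column index), `name` and `score`.
#' @export
rank_features <- function(x, y, n_bins = 20) {
  y <- as.integer(y)
  if (nrow(x) != length(y)) {
    stop("number of rows of x must match length of y", call. = FALSE)
  }
  if (length(unique(y)) < 2) {
    stop("both classes must be present to rank features", call. = FALSE)
  }
  pos <- y == 1
  scores <- vapply(seq_len(ncol(x)), function(j) {
    kl_symmetric(x[pos, j], x[!pos, j], n_bins = n_bins)
  }, numeric(1))
  ord <- order(-scores, seq_along(scores))
  out <- data.frame(
    rank = seq_along(ord),
    feature = ord,
    name = if (!is.null(colnames(x))) colnames(x)[ord] else as.character(ord),
    score = scores[ord],
    stringsAsFactors = FALSE
  )
  class(out) <- c("ranked_features", "data.frame")
  out
}

#' Write a feature ranking as TSV
#'
#' @param ranking A `ranked_features` object.
#' @param path Output path.
#' @export
write_ranking_tsv <- function(ranking, path) {
  utils::write.table(as.data.frame(ranking)[, c("rank", "name", "score")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
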