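#' Encode the evolutionary-conservation block (400 features)
#'
#' Aggregates the window-aligned PSSM rows into a 20 x 20 matrix M whose cell
#' (i, j) is the sum, over window positions whose native residue is type i,
#' of that position's log-odds score in substitution column j. Padding
#' positions (native residue X) contribute nothing. The matrix is flattened
#' native-residue-major over the canonical alphabet.
#'
#' @param residues Window residue string (length `2 * xi + 1`, X for padding).
#' @param rows Window-aligned PSSM rows: a `(2 * xi + 1) x 20` matrix in
#'   canonical column order, as produced by [slice_profile()].
#' @return Numeric vector of length 400.
#' @export
encode_pssm_block <- function(residues, rows) {
  chars <- strsplit(residues, "")[[1]]
  if (!is.matrix(rows) || nrow(rows) != length(chars) || ncol(rows) != 20) {
    stop("PSSM rows must be a ", length(chars), " x 20 matrix", call. = FALSE)
  }
  m <- matrix(0, nrow = 20, ncol = 20,
              dimnames = list(AA_CANONICAL, AA_CANONICAL))
  for (p in seq_along(chars)) {
    if (chars[p] == "X") next
    i <- match(chars[p], AA_CANONICAL)
    if (is.na(i)) {
      stop("residue '", chars[p], "' outside the amino-acid alphabet",
           call. = FALSE)
    }
    m[i, ] <- m[i, ] + rows[p, ]
  }
  as.vector(t(m))
}

#' Encode the secondary-structure block (9 features)
#'
#' For each state a in (H, E, C) over the non-padded window positions:
#' `Tnum_a` is the state count, `Avelen_a` the count divided by the number of
#' maximal contiguous runs of a (0 when the state is absent), and `Comper_a`
#' the percentage of non-padded positions in state a (0 when every position
#' is padded). Padded positions break runs and are excluded from all three
#' statistics.
#'
#' @param states Character vector of window-aligned states over H/E/C.
#' @param padded Logical vector flagging padded positions.
#' @return Numeric vector of length 9, ordered
#'   `Tnum_H, Tnum_E, Tnum_C, Avelen_H, Avelen_E, Avelen_C,
#'    Comper_H, Comper_E, Comper_C`.
#' @export
encode_ss_block <- function(states, padded = rep(FALSE, length(states))) {
  if (length(states) != length(padded)) {
    stop("states and padded flags differ in length", call. = FALSE)
  }
  if (!all(states[!padded] %in% SS_STATES)) {
    stop("secondary-structure states must be H, E or C", call. = FALSE)
  }
  eff <- ifelse(padded, NA_character_, states)
  runs <- rle(eff)
  t_num <- vapply(SS_STATES, function(a) sum(eff == a, na.rm = TRUE), 0)
  n_runs <- vapply(SS_STATES, function(a) {
    sum(!is.na(runs$values) & runs$values == a)
  }, 0)
  ave_len <- ifelse(n_runs > 0, t_num / n_runs, 0)
  total <- sum(t_num)
  com_per <- if (total > 0) 100 * t_num / total else rep(0, 3)
  unname(c(t_num, ave_len, com_per))
}

#' Encode the native-disorder block (9 features)
#'
#' One feature per window position, N- to C-terminal: the per-residue
#' disorder probability, 0 at padded positions.
#'
#' @param probabilities Window-aligned disorder probabilities (padding
#'   already zeroed by [slice_profile()]).
#' @param width Expected window length.
#' @return Numeric vector of length `width`.
#' @export
encode_disorder_block <- function(probabilities, width = 9) {
  if (length(probabilities) != width) {
    stop("expected ", width, " disorder probabilities, got ",
         length(probabilities), call. = FALSE)
  }
  as.numeric(probabilities)
}

#' Encode the physicochemical block (54 features)
#'
#' For each window position (outer) and each of the six property scales
#' (inner), the scale value of the residue at that position; the padding
#' code X maps to 0 in every scale.
#'
#' @param residues Window residue string.
#' @param scales Named list of six residue scales, see [physchem_scales()].
#' @return Numeric vector of length `6 * nchar(residues)`.
#' @export
encode_physchem_block <- function(residues, scales = physchem_scales()) {
  chars <- strsplit(residues, "")[[1]]
  bad <- setdiff(chars, AA_ALPHABET)
  if (length(bad) > 0) {
    stop("residues outside the amino-acid alphabet: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  out <- vapply(chars, function(ch) {
    vapply(scales, function(sc) if (ch == "X") 0 else unname(sc[ch]),
           numeric(1))
  }, numeric(length(scales)))
  as.vector(out)
}

#' Fuse the four feature blocks into one 472-dimensional vector
#'
#' Concatenates the blocks in layout order (pssm, ss, disorder, physchem)
#' after checking each block's width against [feature_layout()].
#'
#' @param pssm,ss,disorder,physchem Numeric block vectors.
#' @param xi Window half-width.
#' @return Named numeric vector of length 472 (for `xi = 4`).
#' @export
fuse_blocks <- function(pssm, ss, disorder, physchem, xi = 4) {
  layout <- feature_layout(xi)
  widths <- c(pssm = length(pssm), ss = length(ss),
              disorder = length(disorder), physchem = length(physchem))
  for (b in layout$block) {
    if (widths[[b]] != layout$width[layout$block == b]) {
      stop("block '", b, "' has width ", widths[[b]], ", expected ",
           layout$width[layout$block == b], call. = FALSE)
    }
  }
  v <- c(pssm, ss, disorder, physchem)
  if (!all(is.finite(v))) {
    stop("fused feature vector contains non-finite values", call. = FALSE)
  }
  names(v) <- feature_names(xi)
  v
}

#' Encode one window against its protein's profiles
#'
#' @param window One row of a window table.
#' @param profile List with elements `pssm`, `ss`, `diso` for the window's
#'   protein.
#' @param xi Window half-width.
#' @param scales Physicochemical scales.
#' @return Named numeric feature vector of length 472.
#' @export
encode_window <- function(window, profile, xi = 4,
                          scales = physchem_scales()) {
  ps <- slice_profile(profile$pssm, window, xi)
  ss <- slice_profile(profile$ss, window, xi)
  di <- slice_profile(profile$diso, window, xi)
  fuse_blocks(
    pssm = encode_pssm_block(window$residues, ps$scores),
    ss = encode_ss_block(ss$states, ss$padded),
    disorder = encode_disorder_block(di$probabilities, width = 2 * xi + 1),
    physchem = encode_physchem_block(window$residues, scales),
    xi = xi
  )
}

#' Encode a window table into the fused feature matrix
#'
#' Rows are ordered deterministically by protein id then position, matching
#' the window table produced by [build_windows()].
#'
#' @param windows Window table from [build_windows()].
#' @param profiles Named list from [load_profiles()].
#' @param xi Window half-width.
#' @param scales Physicochemical scales.
#' @return A list with `x` (n x 472 matrix, feature names as column names,
#'   `protein:position` row names), `y` (integer labels) and `windows`.
#' @export
encode_dataset <- function(windows, profiles, xi = 4,
                           scales = physchem_scales()) {
  ord <- order(windows$protein_id, windows$center)
  windows <- windows[ord, , drop = FALSE]
  missing <- setdiff(unique(windows$protein_id), names(profiles))
  if (length(missing) > 0) {
    stop("no profiles available for protein(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  nm <- feature_names(xi)
  row_ids <- if (nrow(windows) > 0) {
    paste0(windows$protein_id, ":", windows$center)
  } else {
    character(0)
  }
  x <- matrix(0, nrow = nrow(windows), ncol = length(nm),
              dimnames = list(row_ids, nm))
  for (k in seq_len(nrow(windows))) {
    x[k, ] <- encode_window(windows[k, ], profiles[[windows$protein_id[k]]],
                            xi = xi, scales = scales)
  }
  list(x = x, y = as.integer(windows$label), windows = windows)
}

#' Write a feature matrix with labels as TSV
#'
#' @param dataset List from [encode_dataset()].
#' @param path Output path.
#' @export
write_feature_tsv <- function(dataset, path) {
  df <- data.frame(window = rownames(dataset$x), dataset$x,
                   label = dataset$y, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature TSV written by [write_feature_tsv()]
#'
#' @param path Input path.
#' @return A list with `x` and `y` as in [encode_dataset()].
#' @export
read_feature_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  x <- as.matrix(df[, setdiff(names(df), c("window", "label")), drop = FALSE])
  rownames(x) <- df$window
  list(x = x, y = as.integer(df$label))
}
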