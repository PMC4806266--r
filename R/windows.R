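#' Read protein sequences from a FASTA file
#'
#' Sequences are uppercased and validated against the 21-letter alphabet
#' (the 20 standard residues plus the dummy code X). Any other character is
#' rejected with an error naming the offending record.
#'
#' @param path Path to a FASTA file.
#' @return A data frame with columns `id` and `sequence`, one row per record.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  if (file.size(path) == 0) {
    return(data.frame(id = character(), sequence = character(),
                      stringsAsFactors = FALSE))
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      stop("failed to parse FASTA file '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  for (k in seq_along(seqs)) {
    if (!nzchar(ids[k])) {
      stop("malformed FASTA header for record ", k, " in '", path, "'",
           call. = FALSE)
    }
    if (!nzchar(seqs[k])) {
      stop("empty sequence for FASTA record '", ids[k], "'", call. = FALSE)
    }
    bad <- setdiff(strsplit(seqs[k], "")[[1]], AA_ALPHABET)
    if (length(bad) > 0) {
      stop("record '", ids[k], "' contains characters outside the amino-acid ",
           "alphabet: ", paste(unique(bad), collapse = ", "), call. = FALSE)
    }
  }
  data.frame(id = unname(ids), sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Read site annotations
#'
#' Accepts a headerless TSV with either three columns
#' (`protein_id`, `position`, `label` with label in \{0, 1\}) or two columns
#' (`protein_id`, `position`), in which case every listed position is a
#' positive and all other tyrosines become negatives downstream.
#'
#' @param path Path to the annotation TSV.
#' @return A data frame with columns `protein_id`, `position`, `label`.
#' @export
read_site_annotations <- function(path) {
  if (!file.exists(path)) {
    stop("annotation file not found: ", path, call. = FALSE)
  }
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", comment.char = "#")
  if (ncol(tab) == 2) {
    tab$V3 <- "1"
  } else if (ncol(tab) != 3) {
    stop("annotation file must have 2 or 3 tab-separated columns, found ",
         ncol(tab), call. = FALSE)
  }
  pos <- suppressWarnings(as.integer(tab[[2]]))
  lab <- suppressWarnings(as.integer(tab[[3]]))
  if (anyNA(pos) || any(pos < 1)) {
    stop("annotation positions must be positive integers", call. = FALSE)
  }
  if (anyNA(lab) || !all(lab %in% c(0L, 1L))) {
    stop("annotation labels must be 0 or 1", call. = FALSE)
  }
  data.frame(protein_id = tab[[1]], position = pos, label = lab,
             stringsAsFactors = FALSE)
}

#' Extract tyrosine-centred peptide windows from one protein
#'
#' Every tyrosine in the sequence yields one window of length `2 * xi + 1`
#' centred on it; positions in `annotated_positions` (1-based, must point at
#' tyrosines) are labelled 1, all other tyrosines 0. Windows that run past a
#' protein terminus are padded with the dummy code X so all windows share the
#' same length.
#'
#' @param protein A list or one-row data frame with fields `id` and
#'   `sequence`.
#' @param config A [window_config()].
#' @param annotated_positions Integer vector of 1-based sulfated-tyrosine
#'   positions (may be empty).
#' @return A data frame with columns `protein_id`, `center` (1-based),
#'   `residues` and `label`, ordered by position.
#' @export
#' @examples
#' extract_windows(list(id = "p1", sequence = "YAAAAAAA"),
#'                 window_config(), annotated_positions = 1L)
extract_windows <- function(protein, config = window_config(),
                            annotated_positions = integer()) {
  id <- as.character(protein$id)
  seqchars <- strsplit(toupper(as.character(protein$sequence)), "")[[1]]
  n <- length(seqchars)
  xi <- config$xi
  annotated_positions <- as.integer(annotated_positions)

  for (p in annotated_positions) {
    if (is.na(p) || p < 1 || p > n) {
      stop("annotated position ", p, " is out of range for protein '", id,
           "' (length ", n, ")", call. = FALSE)
    }
    if (seqchars[p] != "Y") {
      stop("annotated position ", p, " in protein '", id, "' is '",
           seqchars[p], "', not a tyrosine", call. = FALSE)
    }
  }

  centers <- which(seqchars == "Y")
  if (length(centers) == 0) {
    return(data.frame(protein_id = character(), center = integer(),
                      residues = character(), label = integer(),
                      stringsAsFactors = FALSE))
  }
  residues <- vapply(centers, function(ctr) {
    idx <- (ctr - xi):(ctr + xi)
    chars <- ifelse(idx >= 1 & idx <= n, seqchars[pmax(pmin(idx, n), 1)], "X")
    paste(chars, collapse = "")
  }, character(1))
  data.frame(
    protein_id = id,
    center = centers,
    residues = residues,
    label = as.integer(centers %in% annotated_positions),
    stringsAsFactors = FALSE
  )
}

#' Build the window table for a whole dataset
#'
#' Applies [extract_windows()] to every protein, using the annotation table
#' to assign labels. Explicit 3-column annotations are checked for
#' consistency; tyrosines absent from the annotation file are negatives.
#' Duplicate residue strings carrying conflicting labels are kept, with a
#' warning.
#'
#' @param proteins Data frame from [read_fasta()].
#' @param annotations Data frame from [read_site_annotations()].
#' @param config A [window_config()].
#' @param downsample_negatives Optional positive number: keep at most this
#'   many negatives per positive (seeded sampling via `seed`). `NULL` (the
#'   default) keeps all negatives.
#' @param seed Seed used only when down-sampling negatives.
#' @return A data frame of windows ordered by protein id then position.
#' @export
build_windows <- function(proteins, annotations, config = window_config(),
                          downsample_negatives = NULL, seed = 1) {
  unknown <- setdiff(annotations$protein_id, proteins$id)
  if (length(unknown) > 0) {
    stop("annotations reference unknown proteins: ",
         paste(unique(unknown), collapse = ", "), call. = FALSE)
  }
  out <- lapply(seq_len(nrow(proteins)), function(k) {
    ann <- annotations[annotations$protein_id == proteins$id[k], , drop = FALSE]
    extract_windows(proteins[k, ], config,
                    annotated_positions = ann$position[ann$label == 1])
  })
  windows <- do.call(rbind, out)
  windows <- windows[order(windows$protein_id, windows$center), , drop = FALSE]
  rownames(windows) <- NULL

  dup <- tapply(windows$label, windows$residues, function(v) length(unique(v)))
  if (any(dup > 1)) {
    warning("kept ", sum(dup > 1),
            " duplicated window sequence(s) with conflicting labels")
  }
  if (!is.null(downsample_negatives)) {
    n_pos <- sum(windows$label == 1)
    keep_n <- ceiling(downsample_negatives * n_pos)
    neg_idx <- which(windows$label == 0)
    if (length(neg_idx) > keep_n) {
      keep <- with_seed(seed, sort(sample(neg_idx, keep_n)))
      windows <- windows[sort(c(which(windows$label == 1), keep)), ,
                         drop = FALSE]
      rownames(windows) <- NULL
    }
  }
  windows
}
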