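#' Read a PSI-BLAST ASCII PSSM file
#'
#' Parses the matrix block of a file produced with PSI-BLAST's
#' `-out_ascii_pssm` option: a header line listing the 20 residue columns,
#' then one row per residue carrying the position index, the residue letter
#' and at least 20 integer log-odds scores (the weighted-percentage columns,
#' when present, are ignored). The column order is taken from the file header
#' and the scores are re-ordered to the canonical alphabet.
#'
#' @param path Path to the PSSM file.
#' @param protein_id Identifier to attach; defaults to the file base name.
#' @return An object of class `pssm_profile`: a list with `protein_id`,
#'   `scores` (L x 20 numeric matrix, canonical column order) and `residues`
#'   (length-L character string).
#' @export
read_pssm <- function(path, protein_id = NULL) {
  if (!file.exists(path)) stop("PSSM file not found: ", path, call. = FALSE)
  if (is.null(protein_id)) {
    protein_id <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path, warn = FALSE)

  header_at <- NA_integer_
  column_order <- NULL
  for (k in seq_along(lines)) {
    tok <- strsplit(trimws(lines[k]), "\\s+")[[1]]
    if (length(tok) >= 20 && all(tok[1:20] %in% AA_CANONICAL)) {
      header_at <- k
      column_order <- tok[1:20]
      break
    }
  }
  if (is.na(header_at)) {
    stop("no PSSM column header found in '", path, "'", call. = FALSE)
  }
  if (anyDuplicated(column_order)) {
    stop("duplicated residue letters in PSSM header of '", path, "'",
         call. = FALSE)
  }

  scores <- list()
  residues <- character()
  expect_pos <- 1L
  for (k in seq(header_at + 1L, length(lines))) {
    if (k > length(lines)) break
    line <- trimws(lines[k])
    if (!nzchar(line)) break
    tok <- strsplit(line, "\\s+")[[1]]
    if (!grepl("^[0-9]+$", tok[1])) break
    if (length(tok) < 22) {
      stop("PSSM row on line ", k, " of '", path, "' has fewer than 20 score ",
           "columns", call. = FALSE)
    }
    if (as.integer(tok[1]) != expect_pos) {
      stop("PSSM row on line ", k, " of '", path, "' has position ", tok[1],
           ", expected ", expect_pos, call. = FALSE)
    }
    if (!(toupper(tok[2]) %in% AA_ALPHABET)) {
      stop("PSSM row on line ", k, " of '", path, "' has residue '", tok[2],
           "' outside the amino-acid alphabet", call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(tok[3:22]))
    if (anyNA(vals)) {
      stop("non-numeric PSSM score on line ", k, " of '", path, "'",
           call. = FALSE)
    }
    residues[expect_pos] <- toupper(tok[2])
    scores[[expect_pos]] <- vals
    expect_pos <- expect_pos + 1L
  }
  if (length(scores) == 0) {
    stop("no PSSM rows found in '", path, "'", call. = FALSE)
  }
  m <- do.call(rbind, scores)
  colnames(m) <- column_order
  m <- m[, AA_CANONICAL, drop = FALSE]
  structure(list(protein_id = protein_id, scores = m,
                 residues = paste(residues, collapse = "")),
            class = "pssm_profile")
}

#' Read a PSIPRED .ss2 secondary-structure file
#'
#' Parses the PSIPRED vertical format: comment lines starting with `#`, then
#' one row per residue with index, residue letter, state letter (H, E or C)
#' and, optionally, the three per-class confidence scores (coil, helix,
#' strand order in the file).
#'
#' @inheritParams read_pssm
#' @return An object of class `ss2_profile`: a list with `protein_id`,
#'   `states` (length-L string over H/E/C), `residues` and `confidences`
#'   (L x 3 matrix with columns C, H, E, or `NULL` when absent).
#' @export
read_ss2 <- function(path, protein_id = NULL) {
  if (!file.exists(path)) stop("ss2 file not found: ", path, call. = FALSE)
  if (is.null(protein_id)) protein_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  rows <- list()
  for (k in seq_along(lines)) {
    line <- trimws(lines[k])
    if (!nzchar(line) || startsWith(line, "#")) next
    tok <- strsplit(line, "\\s+")[[1]]
    if (length(tok) < 3) {
      stop("malformed ss2 row on line ", k, " of '", path, "'", call. = FALSE)
    }
    state <- toupper(tok[3])
    if (!(state %in% SS_STATES)) {
      stop("unknown secondary-structure state '", tok[3], "' on line ", k,
           " of '", path, "' (expected H, E or C)", call. = FALSE)
    }
    conf <- rep(NA_real_, 3)
    if (length(tok) >= 6) {
      conf <- suppressWarnings(as.numeric(tok[4:6]))
      if (anyNA(conf)) {
        stop("non-numeric confidence on line ", k, " of '", path, "'",
             call. = FALSE)
      }
    }
    rows[[length(rows) + 1L]] <- list(res = toupper(tok[2]), state = state,
                                      conf = conf)
  }
  if (length(rows) == 0) {
    stop("no secondary-structure rows found in '", path, "'", call. = FALSE)
  }
  conf <- do.call(rbind, lapply(rows, `[[`, "conf"))
  colnames(conf) <- c("C", "H", "E")
  if (all(is.na(conf))) conf <- NULL
  structure(list(
    protein_id = protein_id,
    states = paste(vapply(rows, `[[`, character(1), "state"), collapse = ""),
    residues = paste(vapply(rows, `[[`, character(1), "res"), collapse = ""),
    confidences = conf
  ), class = "ss2_profile")
}

#' Read a DISOPRED-style per-residue disorder file
#'
#' Parses rows of the form `index residue mark probability` (4 columns, the
#' mark being `*` for disordered and `.` for ordered) or
#' `index residue probability` (3 columns, calls derived by thresholding the
#' probability at 0.5). Comment lines starting with `#` are skipped.
#'
#' @inheritParams read_pssm
#' @return An object of class `diso_profile`: a list with `protein_id`,
#'   `residues`, `probabilities` (numeric in \[0, 1\]) and `calls`
#'   (integer 0/1).
#' @export
read_disorder <- function(path, protein_id = NULL) {
  if (!file.exists(path)) {
    stop("disorder file not found: ", path, call. = FALSE)
  }
  if (is.null(protein_id)) protein_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  res <- character(); prob <- numeric(); call <- integer()
  for (k in seq_along(lines)) {
    line <- trimws(lines[k])
    if (!nzchar(line) || startsWith(line, "#")) next
    tok <- strsplit(line, "\\s+")[[1]]
    if (length(tok) == 4) {
      if (!(tok[3] %in% c("*", "."))) {
        stop("unknown disorder mark '", tok[3], "' on line ", k, " of '",
             path, "'", call. = FALSE)
      }
      p <- suppressWarnings(as.numeric(tok[4]))
      mark <- as.integer(tok[3] == "*")
    } else if (length(tok) == 3) {
      p <- suppressWarnings(as.numeric(tok[3]))
      mark <- NA_integer_
    } else {
      stop("malformed disorder row on line ", k, " of '", path, "'",
           call. = FALSE)
    }
    if (is.na(p) || p < 0 || p > 1) {
      stop("disorder probability outside [0, 1] on line ", k, " of '", path,
           "'", call. = FALSE)
    }
    res <- c(res, toupper(tok[2]))
    prob <- c(prob, p)
    call <- c(call, if (is.na(mark)) as.integer(p >= 0.5) else mark)
  }
  if (length(prob) == 0) {
    stop("no disorder rows found in '", path, "'", call. = FALSE)
  }
  structure(list(protein_id = protein_id,
                 residues = paste(res, collapse = ""),
                 probabilities = prob, calls = call),
            class = "diso_profile")
}

#' Slice a per-protein profile to a site window
#'
#' Returns the `2 * xi + 1` profile rows aligned to the window positions.
#' Window positions outside the protein (the X-padded termini) yield neutral
#' values: an all-zero PSSM row, a coil state flagged as padded (excluded
#' from secondary-structure statistics downstream) or a disorder probability
#' of 0.
#'
#' @param profile A `pssm_profile`, `ss2_profile` or `diso_profile`.
#' @param window One row of a window table (fields `protein_id`, `center`).
#' @param xi Window half-width.
#' @return A list with a `padded` logical vector plus `scores` (PSSM),
#'   `states` (ss2) or `probabilities` (disorder).
#' @export
slice_profile <- function(profile, window, xi = 4) {
  UseMethod("slice_profile")
}

slice_positions <- function(profile_id, profile_len, window, xi) {
  if (!identical(as.character(profile_id), as.character(window$protein_id))) {
    stop("profile for protein '", profile_id, "' does not match window from ",
         "protein '", window$protein_id, "'", call. = FALSE)
  }
  idx <- (window$center - xi):(window$center + xi)
  list(idx = idx, padded = idx < 1 | idx > profile_len)
}

#' @export
slice_profile.pssm_profile <- function(profile, window, xi = 4) {
  s <- slice_positions(profile$protein_id, nrow(profile$scores), window, xi)
  rows <- matrix(0, nrow = length(s$idx), ncol = 20,
                 dimnames = list(NULL, AA_CANONICAL))
  inside <- !s$padded
  rows[inside, ] <- profile$scores[s$idx[inside], , drop = FALSE]
  list(scores = rows, padded = s$padded)
}

#' @export
slice_profile.ss2_profile <- function(profile, window, xi = 4) {
  chars <- strsplit(profile$states, "")[[1]]
  s <- slice_positions(profile$protein_id, length(chars), window, xi)
  states <- rep("C", length(s$idx))
  states[!s$padded] <- chars[s$idx[!s$padded]]
  list(states = states, padded = s$padded)
}

#' @export
slice_profile.diso_profile <- function(profile, window, xi = 4) {
  s <- slice_positions(profile$protein_id, length(profile$probabilities),
                       window, xi)
  probs <- rep(0, length(s$idx))
  probs[!s$padded] <- profile$probabilities[s$idx[!s$padded]]
  list(probabilities = probs, padded = s$padded)
}

#' Load the three profile files for a set of proteins
#'
#' Files are located as `<dir>/<id>.pssm`, `<dir>/<id>.ss2` and
#' `<dir>/<id>.diso` unless a manifest data frame (columns `protein_id`,
#' `pssm`, `ss2`, `diso` holding paths) overrides the convention.
#'
#' @param dir Directory containing the profile files.
#' @param ids Character vector of protein identifiers.
#' @param manifest Optional manifest data frame overriding file locations.
#' @return A named list (one entry per id) of lists with elements `pssm`,
#'   `ss`, `diso`.
#' @export
load_profiles <- function(dir, ids, manifest = NULL) {
  out <- lapply(ids, function(id) {
    paths <- if (!is.null(manifest)) {
      row <- manifest[manifest$protein_id == id, , drop = FALSE]
      if (nrow(row) != 1) {
        stop("manifest has no entry for protein '", id, "'", call. = FALSE)
      }
      c(pssm = row$pssm, ss2 = row$ss2, diso = row$diso)
    } else {
      c(pssm = file.path(dir, paste0(id, ".pssm")),
        ss2 = file.path(dir, paste0(id, ".ss2")),
        diso = file.path(dir, paste0(id, ".diso")))
    }
    missing <- paths[!file.exists(paths)]
    if (length(missing) > 0) {
      stop("missing profile file(s) for protein '", id, "': ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    list(pssm = read_pssm(paths[["pssm"]], protein_id = id),
         ss = read_ss2(paths[["ss2"]], protein_id = id),
         diso = read_disorder(paths[["diso"]], protein_id = id))
  })
  names(out) <- ids
  out
}
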