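# Shared fixture builders: tiny profile files and in-memory profile objects
# assembled in code, so the suite carries no stored binary data.

canonical <- sulfire:::AA_CANONICAL

write_fixture_pssm <- function(path, residues, scores,
                               column_order = canonical) {
  chars <- strsplit(residues, "")[[1]]
  stopifnot(nrow(scores) == length(chars), ncol(scores) == 20)
  lines <- c(
    "",
    "Last position-specific scoring matrix computed",
    paste0("    ", paste(column_order, collapse = "  "), "  ",
           paste(column_order, collapse = "  "))
  )
  for (p in seq_along(chars)) {
    lines <- c(lines, paste(c(p, chars[p], scores[p, ], rep(0L, 20)),
                            collapse = " "))
  }
  writeLines(c(lines, ""), path)
  path
}

write_fixture_ss2 <- function(path, residues, states) {
  chars <- strsplit(residues, "")[[1]]
  st <- strsplit(states, "")[[1]]
  lines <- c("# PSIPRED VFORMAT", "")
  for (p in seq_along(chars)) {
    lines <- c(lines, sprintf("%d %s %s 0.1 0.8 0.1", p, chars[p], st[p]))
  }
  writeLines(lines, path)
  path
}

write_fixture_diso <- function(path, residues, probs, marks = NULL) {
  chars <- strsplit(residues, "")[[1]]
  lines <- "# disorder"
  for (p in seq_along(chars)) {
    lines <- c(lines, if (is.null(marks)) {
      sprintf("%d %s %.4f", p, chars[p], probs[p])
    } else {
      sprintf("%d %s %s %.4f", p, chars[p], marks[p], probs[p])
    })
  }
  writeLines(lines, path)
  path
}

# In-memory profile triple for a protein, bypassing file IO where a test
# only exercises encoders.
make_profiles <- function(id, sequence, scores = NULL, states = NULL,
                          probs = NULL) {
  n <- nchar(sequence)
  if (is.null(scores)) scores <- matrix(0, n, 20,
                                        dimnames = list(NULL, canonical))
  colnames(scores) <- canonical
  if (is.null(states)) states <- strrep("C", n)
  if (is.null(probs)) probs <- rep(0, n)
  list(
    pssm = structure(list(protein_id = id, scores = scores,
                          residues = sequence), class = "pssm_profile"),
    ss = structure(list(protein_id = id, states = states,
                        residues = sequence, confidences = NULL),
                   class = "ss2_profile"),
    diso = structure(list(protein_id = id, residues = sequence,
                          probabilities = probs,
                          calls = as.integer(probs >= 0.5)),
                     class = "diso_profile")
  )
}

# Balanced two-class toy matrix where the first feature equals the label
# and the rest are seeded noise.
toy_separable <- function(n = 60, p = 4, seed = 42) {
  set.seed(seed)
  y <- rep(c(0L, 1L), each = n / 2)
  x <- matrix(rnorm(n * p), n, p)
  x[, 1] <- y + rnorm(n, sd = 0.01)
  colnames(x) <- paste0("f", seq_len(p))
  list(x = x, y = y)
}
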