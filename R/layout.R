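# Canonical residue alphabet: the PSI-BLAST PSSM column order. All PSSM
# matrices are re-ordered to this alphabet on parse, so every encoder and
# feature name downstream shares one fixed convention.
AA_CANONICAL <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# 21-letter alphabet: the 20 standard residues plus the dummy padding code X.
AA_ALPHABET <- c(AA_CANONICAL, "X")

SS_STATES <- c("H", "E", "C")

#' Window geometry for site-centred peptides
#'
#' A window spans `xi` residues on each side of the candidate tyrosine, so its
#' length is `2 * xi + 1`. The default `xi = 4` gives the 9-residue window
#' used throughout the package.
#'
#' @param xi Non-negative integer half-width of the window.
#' @return A list with elements `xi` and `window_length`.
#' @export
#' @examples
#' window_config()          # 9-residue window
#' window_config(xi = 7)    # 15-residue window
window_config <- function(xi = 4) {
  if (length(xi) != 1 || is.na(xi) || xi < 0 || xi != as.integer(xi)) {
    stop("xi must be a single non-negative integer", call. = FALSE)
  }
  xi <- as.integer(xi)
  structure(list(xi = xi, window_length = 2L * xi + 1L),
            class = "window_config")
}

#' Six physicochemical residue scales
#'
#' Standard published per-residue property scales for the six properties used
#' by the physicochemical feature block: hydrophilicity (Hopp-Woods),
#' flexibility (Bhaskaran-Ponnuswamy average flexibility), accessibility
#' (Janin transfer free energy), polarity (Grantham), exposed surface
#' (Chothia accessible surface area in a tripeptide, A^2) and turns
#' (Chou-Fasman beta-turn propensity). The padding code X maps to 0 in every
#' scale.
#'
#' @return A named list of six named numeric vectors, each covering the 20
#'   standard residues.
#' @export
physchem_scales <- function() {
  make <- function(...) {
    v <- c(...)
    stopifnot(setequal(names(v), AA_CANONICAL))
    v[AA_CANONICAL]
  }
  list(
    hydrophilicity = make(
      A = -0.5, R = 3.0, N = 0.2, D = 3.0, C = -1.0, Q = 0.2, E = 3.0,
      G = 0.0, H = -0.5, I = -1.8, L = -1.8, K = 3.0, M = -1.3, F = -2.5,
      P = 0.0, S = 0.3, T = -0.4, W = -3.4, Y = -2.3, V = -1.5),
    flexibility = make(
      A = 0.357, R = 0.529, N = 0.463, D = 0.511, C = 0.346, Q = 0.493,
      E = 0.497, G = 0.544, H = 0.323, I = 0.462, L = 0.365, K = 0.466,
      M = 0.295, F = 0.314, P = 0.509, S = 0.507, T = 0.444, W = 0.305,
      Y = 0.420, V = 0.386),
    accessibility = make(
      A = 0.3, R = -1.4, N = -0.5, D = -0.6, C = 0.9, Q = -0.7, E = -0.7,
      G = 0.3, H = -0.1, I = 0.7, L = 0.5, K = -1.8, M = 0.4, F = 0.5,
      P = -0.3, S = -0.1, T = -0.2, W = 0.3, Y = -0.4, V = 0.6),
    polarity = make(
      A = 8.1, R = 10.5, N = 11.6, D = 13.0, C = 5.5, Q = 10.5, E = 12.3,
      G = 9.0, H = 10.4, I = 5.2, L = 4.9, K = 11.3, M = 5.7, F = 5.2,
      P = 8.0, S = 9.2, T = 8.6, W = 5.4, Y = 6.2, V = 5.9),
    exposed_surface = make(
      A = 115, R = 225, N = 160, D = 150, C = 135, Q = 180, E = 190,
      G = 75, H = 195, I = 175, L = 170, K = 200, M = 185, F = 210,
      P = 145, S = 115, T = 140, W = 255, Y = 230, V = 155),
    turns = make(
      A = 0.66, R = 0.95, N = 1.56, D = 1.46, C = 1.19, Q = 0.98, E = 0.74,
      G = 1.56, H = 0.95, I = 0.47, L = 0.59, K = 1.01, M = 0.60, F = 0.60,
      P = 1.52, S = 1.43, T = 0.96, W = 0.96, Y = 1.14, V = 0.50)
  )
}

#' Fixed block layout of the fused feature vector
#'
#' The fused descriptor concatenates four contiguous blocks in a fixed order:
#' `pssm` (20x20 aggregated substitution scores, 400 features), `ss`
#' (secondary-structure statistics, 9), `disorder` (per-position disorder
#' probabilities, 9) and `physchem` (6 scales x 9 positions, 54), for a total
#' of 472 features.
#'
#' @param xi Window half-width; the per-position blocks scale with
#'   `2 * xi + 1`.
#' @return A data frame with columns `block`, `offset` (0-based start),
#'   `width` and `share_pct` (percentage of the fused vector).
#' @export
feature_layout <- function(xi = 4) {
  w <- 2L * xi + 1L
  widths <- c(pssm = 400L, ss = 9L, disorder = w, physchem = 6L * w)
  total <- sum(widths)
  data.frame(
    block = names(widths),
    offset = cumsum(c(0L, unname(widths[-length(widths)]))),
    width = unname(widths),
    share_pct = unname(100 * widths / total),
    stringsAsFactors = FALSE
  )
}

#' Names of the 472 fused features
#'
#' PSSM features are named `pssm_<i>_to_<j>` for native residue `i` and
#' substitution column `j`, flattened native-residue-major over the canonical
#' alphabet. Secondary-structure features are the nine Eq.-style statistics
#' `ss_Tnum_*`, `ss_Avelen_*`, `ss_Comper_*` over H, E, C. Disorder features
#' are `diso_pos<k>` (N- to C-terminal window position). Physicochemical
#' features are `phys_<scale>_pos<k>`, position-major.
#'
#' @param xi Window half-width.
#' @return Character vector of feature names (length 472 for `xi = 4`).
#' @export
feature_names <- function(xi = 4) {
  w <- 2L * xi + 1L
  pssm <- as.vector(t(outer(AA_CANONICAL, AA_CANONICAL,
                            function(i, j) paste0("pssm_", i, "_to_", j))))
  ss <- c(paste0("ss_Tnum_", SS_STATES),
          paste0("ss_Avelen_", SS_STATES),
          paste0("ss_Comper_", SS_STATES))
  diso <- paste0("diso_pos", seq_len(w))
  phys <- as.vector(vapply(seq_len(w), function(p) {
    paste0("phys_", names(physchem_scales()), "_pos", p)
  }, character(6)))
  c(pssm, ss, diso, phys)
}
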