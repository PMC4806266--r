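#' Configuration of the synthetic benchmark generator
#'
#' The generator emulates a desk-scale tyrosine-sulfation study: random
#' protein sequences, PSI-BLAST-style PSSM files with integer log-odds
#' noise, PSIPRED-style secondary-structure files with run-structured
#' states, DISOPRED-style disorder probabilities and a site annotation TSV.
#' Class signal is planted in profile space — for positive (sulfated)
#' windows the configured PSSM columns of the central tyrosine row and/or
#' disorder probabilities at configured window positions are shifted by the
#' requested number of pooled standard deviations — so parsers and encoders
#' sit on the tested path.
#'
#' @param n_proteins Number of proteins (default 60).
#' @param length_range Protein length range (default 90-130).
#' @param tyrosine_density Per-position probability of a tyrosine
#'   (default 0.1; inflated relative to natural composition so a small
#'   protein set yields several hundred candidate windows).
#' @param positive_fraction Fraction of tyrosines annotated as sulfated
#'   (default 0.2, i.e. a 1:4 positive:negative imbalance).
#' @param planted Data frame with columns `feature` (names of the form
#'   `pssm_Y_to_<j>` or `diso_pos<k>`) and `shift` (class-conditional mean
#'   shift in pooled-SD units). The default plants ten features at shift 2:
#'   seven PSSM substitution columns of the central tyrosine and the three
#'   central disorder positions.
#' @param pssm_sd Standard deviation of the integer PSSM noise (default 2).
#' @param diso_sd Standard deviation of the disorder noise (default 0.08).
#' @param seed Mandatory seed; the whole output tree is a deterministic
#'   function of the configuration.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_proteins = 60, length_range = c(90, 130),
                       tyrosine_density = 0.1, positive_fraction = 0.2,
                       planted = default_planted_features(),
                       pssm_sd = 2, diso_sd = 0.08, seed) {
  if (positive_fraction <= 0 || positive_fraction >= 1) {
    stop("positive_fraction must be in (0, 1)", call. = FALSE)
  }
  if (!all(is.finite(planted$shift))) {
    stop("planted shifts must be finite", call. = FALSE)
  }
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  if (!is_scalar_num(seed)) {
    stop("a scalar seed is mandatory", call. = FALSE)
  }
  structure(list(n_proteins = as.integer(n_proteins),
                 length_range = as.integer(length_range),
                 tyrosine_density = tyrosine_density,
                 positive_fraction = positive_fraction,
                 planted = planted, pssm_sd = pssm_sd, diso_sd = diso_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Default planted feature set: ten features at shift 2 pooled SDs
#'
#' @return Data frame with columns `feature` and `shift`.
#' @export
default_planted_features <- function() {
  data.frame(
    feature = c(paste0("pssm_Y_to_", c("A", "R", "N", "D", "C", "Q", "E")),
                paste0("diso_pos", 4:6)),
    shift = 2.0,
    stringsAsFactors = FALSE
  )
}

# Split the planted table into the two supported planting channels.
parse_planted <- function(planted) {
  pssm_cols <- character()
  diso_pos <- integer()
  shifts_pssm <- numeric()
  shifts_diso <- numeric()
  for (k in seq_len(nrow(planted))) {
    f <- planted$feature[k]
    if (grepl("^pssm_Y_to_[A-Z]$", f)) {
      col <- sub("^pssm_Y_to_", "", f)
      if (!(col %in% AA_CANONICAL)) {
        stop("unknown PSSM column in planted feature '", f, "'",
             call. = FALSE)
      }
      pssm_cols <- c(pssm_cols, col)
      shifts_pssm <- c(shifts_pssm, planted$shift[k])
    } else if (grepl("^diso_pos[1-9]$", f)) {
      diso_pos <- c(diso_pos, as.integer(sub("^diso_pos", "", f)))
      shifts_diso <- c(shifts_diso, planted$shift[k])
    } else {
      stop("planting is supported for features of the form pssm_Y_to_<j> ",
           "or diso_pos<k>; got '", f, "'", call. = FALSE)
    }
  }
  list(pssm_cols = pssm_cols, pssm_shift = shifts_pssm,
       diso_pos = diso_pos, diso_shift = shifts_diso)
}

write_pssm_file <- function(path, id, seqchars, scores) {
  lines <- c(
    "",
    paste("Last position-specific scoring matrix computed, weighted",
          "observed percentages rounded down, information per position, and",
          "relative weight of gapless real matches to pseudocounts"),
    paste0("           ", paste(sprintf("%3s", rep(AA_CANONICAL, 2)),
                                collapse = " "))
  )
  for (p in seq_along(seqchars)) {
    # second group of 20 columns mimics the weighted-percentage block
    lines <- c(lines, paste0(
      sprintf("%5d %s ", p, seqchars[p]),
      paste(sprintf("%3d", scores[p, ]), collapse = " "), " ",
      paste(sprintf("%3d", rep(0L, 20)), collapse = " "),
      sprintf("  %.2f %.2f", 0, 0)))
  }
  writeLines(c(lines, ""), path)
}

write_ss2_file <- function(path, id, seqchars, states) {
  conf <- t(vapply(states, function(s) {
    v <- c(C = 0.1, H = 0.1, E = 0.1)
    v[s] <- 0.8
    v
  }, numeric(3)))
  lines <- c("# PSIPRED VFORMAT (synthetic)", "")
  for (p in seq_along(seqchars)) {
    lines <- c(lines, sprintf("%4d %s %s  %6.3f %6.3f %6.3f", p, seqchars[p],
                              states[p], conf[p, "C"], conf[p, "H"],
                              conf[p, "E"]))
  }
  writeLines(lines, path)
}

write_diso_file <- function(path, id, seqchars, probs) {
  lines <- c("# synthetic per-residue disorder predictions", "#")
  for (p in seq_along(seqchars)) {
    # the mark is derived from the probability as printed, so files stay
    # internally consistent at the 0.5 threshold
    pr <- round(probs[p], 2)
    lines <- c(lines, sprintf("%5d %s %s %5.2f", p, seqchars[p],
                              if (pr >= 0.5) "*" else ".", pr))
  }
  writeLines(lines, path)
}

#' Generate a synthetic benchmark dataset on disk
#'
#' Writes `proteins.fasta`, `sites.tsv` (3-column annotations) and one
#' `.pssm`/`.ss2`/`.diso` file per protein under `out_dir/profiles`, in the
#' exact dialects the package parsers read. The output tree is a
#' deterministic function of the configuration (same seed, byte-identical
#' files).
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return A list with `fasta`, `annotations`, `profiles_dir` and
#'   `manifest` (data frame of every file with its md5 checksum), plus the
#'   `config`.
#' @export
simulate_dataset <- function(config = sim_config(seed = 1), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  profiles_dir <- file.path(out_dir, "profiles")
  dir.create(profiles_dir, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    stop("cannot create output directory '", out_dir, "'", call. = FALSE)
  }
  plant <- parse_planted(config$planted)
  non_y <- setdiff(AA_CANONICAL, "Y")
  y_row <- match("Y", AA_CANONICAL)

  # Planted deltas are calibrated so the ENCODED class-mean difference lands
  # at the configured pooled-SD shift. Two effects matter: (i) a pssm_Y_to_*
  # feature sums over every tyrosine in the window (not just the centre), so
  # its noise variance scales with the expected tyrosine count; (ii) windows
  # overlap, so a planted residue of one site leaks into neighbouring
  # windows of either class ("crosstalk"), inflating the pooled variance by
  # q * (1 - q) * delta^2 where q is the leak probability.
  xi_w <- 4L
  exp_y_per_window <- 1 + 2 * xi_w * config$tyrosine_density
  base_var_pssm <- config$pssm_sd^2 * exp_y_per_window
  q_p <- min(0.5, 2 * xi_w * config$tyrosine_density *
               config$positive_fraction)
  pssm_delta_for <- function(shift) {
    denom <- 1 - shift^2 * q_p * (1 - q_p)
    if (denom <= 0.05) denom <- 0.05
    shift * sqrt(base_var_pssm / denom)
  }
  # only about half the tyrosines neighbouring a planted residue read it at
  # one of their own planted offsets, hence the 0.5 factor
  q_d <- min(0.5, 0.5 * (length(plant$diso_pos) + 1) *
               config$tyrosine_density * config$positive_fraction)
  diso_delta_for <- function(shift) {
    denom <- (1 - q_d)^2 - shift^2 * q_d * (1 - q_d)
    if (denom <= 0.05) denom <- 0.05
    shift * config$diso_sd / sqrt(denom)
  }

  with_seed(config$seed, {
    fasta_lines <- character()
    ann <- list()
    manifest <- list()
    for (k in seq_len(config$n_proteins)) {
      id <- sprintf("synp%03d", k)
      len <- sample(seq(config$length_range[1], config$length_range[2]), 1)
      seqchars <- sample(non_y, len, replace = TRUE)
      is_y <- stats::runif(len) < config$tyrosine_density
      seqchars[is_y] <- "Y"
      y_pos <- which(seqchars == "Y")
      pos_sites <- y_pos[stats::runif(length(y_pos)) <
                           config$positive_fraction]

      # base PSSM noise: integer log-odds
      scores <- matrix(as.integer(round(stats::rnorm(len * 20, 0,
                                                     config$pssm_sd))),
                       nrow = len, ncol = 20)
      colnames(scores) <- AA_CANONICAL
      # plant: shift the central tyrosine row of positive windows
      for (p in pos_sites) {
        for (ci in seq_along(plant$pssm_cols)) {
          delta <- as.integer(round(pssm_delta_for(plant$pssm_shift[ci])))
          col <- match(plant$pssm_cols[ci], AA_CANONICAL)
          scores[p, col] <- scores[p, col] + delta
        }
      }

      # secondary structure: run-structured states, no class signal
      states <- character(len)
      p <- 1L
      while (p <= len) {
        run <- min(len - p + 1L, sample(2:8, 1))
        states[p:(p + run - 1L)] <- sample(SS_STATES, 1)
        p <- p + run
      }

      # disorder probabilities with planted positive-window shifts
      probs <- pmin(pmax(stats::rnorm(len, 0.25, config$diso_sd), 0), 1)
      for (p in pos_sites) {
        for (ci in seq_along(plant$diso_pos)) {
          r <- p + plant$diso_pos[ci] - 5L   # window offset -> residue
          if (r >= 1 && r <= len) {
            probs[r] <- min(max(
              0.25 + diso_delta_for(plant$diso_shift[ci]) +
                stats::rnorm(1, 0, config$diso_sd), 0), 1)
          }
        }
      }

      fasta_lines <- c(fasta_lines, paste0(">", id),
                       paste(seqchars, collapse = ""))
      if (length(y_pos) > 0) {
        ann[[k]] <- data.frame(protein_id = id, position = y_pos,
                               label = as.integer(y_pos %in% pos_sites),
                               stringsAsFactors = FALSE)
      }
      write_pssm_file(file.path(profiles_dir, paste0(id, ".pssm")), id,
                      seqchars, scores)
      write_ss2_file(file.path(profiles_dir, paste0(id, ".ss2")), id,
                     seqchars, states)
      write_diso_file(file.path(profiles_dir, paste0(id, ".diso")), id,
                      seqchars, probs)
    }
    fasta_path <- file.path(out_dir, "proteins.fasta")
    writeLines(fasta_lines, fasta_path)
    ann <- do.call(rbind, ann)
    ann_path <- file.path(out_dir, "sites.tsv")
    utils::write.table(ann, ann_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    files <- c(fasta_path, ann_path,
               list.files(profiles_dir, full.names = TRUE))
    manifest <- data.frame(path = files,
                           md5 = unname(tools::md5sum(files)),
                           stringsAsFactors = FALSE)
    list(fasta = fasta_path, annotations = ann_path,
         profiles_dir = profiles_dir, manifest = manifest, config = config)
  })
}

#' Load and encode a simulated dataset
#'
#' Convenience wrapper: reads the FASTA, annotations and profiles written by
#' [simulate_dataset()] and returns the encoded feature matrix.
#'
#' @param sim Return value of [simulate_dataset()].
#' @param xi Window half-width.
#' @return A list with `x`, `y` and `windows`, as from [encode_dataset()].
#' @export
encode_simulated <- function(sim, xi = 4) {
  proteins <- read_fasta(sim$fasta)
  annotations <- read_site_annotations(sim$annotations)
  windows <- build_windows(proteins, annotations, window_config(xi))
  profiles <- load_profiles(sim$profiles_dir, proteins$id)
  encode_dataset(windows, profiles, xi = xi)
}
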