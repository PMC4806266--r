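#' Configuration for the discrete firefly algorithm
#'
#' Candidate solutions ("fireflies") carry a real-valued position over n
#' feature dimensions plus two continuous hyperparameter dimensions
#' (`log2(C)`, `log2(gamma)`). Feature bits are sampled from the sigmoid of
#' the position each time a firefly moves; brighter (fitter) fireflies
#' attract dimmer ones with attractiveness `beta0 * exp(-absorption * r^m)`
#' decaying over Euclidean distance r.
#'
#' @param group_size Population size (default 100).
#' @param randomness Scale `alpha` of the uniform random step (default 0.9).
#' @param absorption Light absorption coefficient `gamma` of the
#'   attractiveness decay (default 0.5); unrelated to the SVM kernel width.
#' @param max_generation Number of generations (default 1000).
#' @param beta0 Base attractiveness at distance 0.
#' @param distance_exponent Exponent m >= 1 in the attractiveness decay.
#' @param w_mcc,w_size Fitness weights for the cross-validated MCC and the
#'   fraction of features left out; must be in \[0, 1\] and sum to 1.
#' @param c_log2_range,gamma_log2_range Search ranges for `log2(C)` and
#'   `log2(gamma)`.
#' @param seed Seed for the optimizer's random stream.
#' @return An object of class `dfa_config`.
#' @export
dfa_config <- function(group_size = 100, randomness = 0.9, absorption = 0.5,
                       max_generation = 1000, beta0 = 1,
                       distance_exponent = 2, w_mcc = 0.9, w_size = 0.1,
                       c_log2_range = c(-5, 15),
                       gamma_log2_range = c(-15, 5), seed = 1) {
  if (group_size < 2) stop("group_size must be at least 2", call. = FALSE)
  if (max_generation < 1) {
    stop("max_generation must be at least 1", call. = FALSE)
  }
  if (distance_exponent < 1) {
    stop("distance_exponent must be >= 1", call. = FALSE)
  }
  if (w_mcc < 0 || w_size < 0 || abs(w_mcc + w_size - 1) > 1e-12) {
    stop("w_mcc and w_size must be non-negative and sum to 1", call. = FALSE)
  }
  structure(list(group_size = as.integer(group_size),
                 randomness = randomness, absorption = absorption,
                 max_generation = as.integer(max_generation), beta0 = beta0,
                 distance_exponent = distance_exponent,
                 w_mcc = w_mcc, w_size = w_size,
                 c_log2_range = c_log2_range,
                 gamma_log2_range = gamma_log2_range,
                 seed = as.integer(seed)),
            class = "dfa_config")
}

#' Euclidean distance between two firefly positions
#'
#' @param a,b Position vectors of equal length (feature dims plus the two
#'   hyperparameter dims).
#' @return Non-negative distance.
#' @export
firefly_distance <- function(a, b) {
  if (length(a) != length(b)) {
    stop("positions differ in length", call. = FALSE)
  }
  sqrt(sum((a - b)^2))
}

#' Attractiveness at distance r
#'
#' `beta0 * exp(-absorption * r^m)`: full attractiveness at distance 0,
#' decaying monotonically for positive absorption.
#'
#' @param r Non-negative distance.
#' @param beta0 Base attractiveness.
#' @param absorption Light absorption coefficient.
#' @param m Distance exponent (>= 1).
#' @return Attractiveness value.
#' @export
firefly_attractiveness <- function(r, beta0 = 1, absorption = 0.5, m = 2) {
  beta0 * exp(-absorption * r^m)
}

#' Sigmoid probability that a position component maps to bit 1
#'
#' @param x Real position component(s).
#' @return `1 / (1 + exp(-x))`, vectorized.
#' @export
firefly_bit_probability <- function(x) {
  stats::plogis(x)
}

#' Stochastically discretize position components into feature bits
#'
#' Each component becomes 1 with probability equal to its sigmoid value,
#' using the current RNG stream.
#'
#' @param x Real position components (feature dims only).
#' @return Integer 0/1 vector.
#' @export
discretize_position <- function(x) {
  as.integer(stats::runif(length(x)) < firefly_bit_probability(x))
}

#' Move one firefly toward a brighter one
#'
#' `x_i <- x_i + beta0 * exp(-absorption * r^2) * (x_j - x_i)
#'  + alpha * (U(0,1) - 1/2)` per dimension, with the two hyperparameter
#' dimensions clipped back into their configured ranges.
#'
#' @param xi Position of the moving (dimmer) firefly.
#' @param xj Position of the brighter firefly.
#' @param config A [dfa_config()].
#' @return The updated position for firefly i.
#' @export
firefly_move <- function(xi, xj, config) {
  if (length(xi) != length(xj)) {
    stop("positions differ in length", call. = FALSE)
  }
  r <- firefly_distance(xi, xj)
  beta <- firefly_attractiveness(r, config$beta0, config$absorption,
                                 config$distance_exponent)
  out <- xi + beta * (xj - xi) +
    config$randomness * (stats::runif(length(xi)) - 0.5)
  d <- length(out)
  out[d - 1] <- min(max(out[d - 1], config$c_log2_range[1]),
                    config$c_log2_range[2])
  out[d] <- min(max(out[d], config$gamma_log2_range[1]),
                config$gamma_log2_range[2])
  out
}

#' Fitness of a candidate solution
#'
#' `w_mcc * MCC + w_size * (1 - n_selected / n)`: rewards predictive
#' performance and parsimony jointly.
#'
#' @param mcc Cross-validated MCC of the masked feature subset, in
#'   \[-1, 1\].
#' @param mask Integer/logical feature mask with at least one active bit.
#' @param config A [dfa_config()].
#' @return Fitness value.
#' @export
dfa_fitness <- function(mcc, mask, config) {
  mask <- as.integer(mask)
  if (sum(mask) == 0) {
    stop("mask has no active features; repair it before scoring",
         call. = FALSE)
  }
  config$w_mcc * mcc + config$w_size * (1 - sum(mask) / length(mask))
}

#' Discrete firefly optimization of a feature mask and SVM hyperparameters
#'
#' Runs the discrete firefly algorithm over `n` feature bits plus the two
#' continuous hyperparameter dimensions. Fireflies start uniform in
#' \[-1, 1\] per feature dimension and uniform over the hyperparameter
#' ranges. Each generation every firefly moves (sequentially) toward every
#' brighter one; after each move its mask is re-sampled through the sigmoid,
#' empty masks are repaired by activating one random bit, and the solution
#' is re-evaluated. The brightest firefly takes a pure random-walk step.
#' Evaluations are cached by mask plus hyperparameters rounded to six
#' significant digits.
#'
#' @param evaluator Function `(mask, C, gamma) -> MCC in [-1, 1]`; must be
#'   deterministic given its inputs (e.g. seeded cross-validation).
#' @param n Number of feature bits (>= 1).
#' @param config A [dfa_config()].
#' @return An object of class `dfa_result`: `best_mask`, `best_C`,
#'   `best_gamma`, `best_fitness`, `trace` (best-so-far per generation),
#'   `n_evaluations` and the `config`.
#' @export
dfa_optimize <- function(evaluator, n, config = dfa_config()) {
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  g <- config$group_size
  d <- n + 2L

  cache <- new.env(parent = emptyenv())
  n_eval <- 0L
  evaluate <- function(mask, c_log2, g_log2) {
    C <- 2^c_log2
    gam <- 2^g_log2
    key <- paste(c(mask, signif(C, 6), signif(gam, 6)), collapse = ",")
    if (!is.null(cache[[key]])) return(cache[[key]])
    mcc <- evaluator(mask, C, gam)
    n_eval <<- n_eval + 1L
    fit <- dfa_fitness(mcc, mask, config)
    cache[[key]] <- fit
    fit
  }

  with_seed(config$seed, {
    pos <- matrix(0, nrow = g, ncol = d)
    pos[, seq_len(n)] <- stats::runif(g * n, -1, 1)
    pos[, n + 1] <- stats::runif(g, config$c_log2_range[1],
                                 config$c_log2_range[2])
    pos[, n + 2] <- stats::runif(g, config$gamma_log2_range[1],
                                 config$gamma_log2_range[2])
    masks <- matrix(0L, nrow = g, ncol = n)
    light <- numeric(g)

    repair <- function(mask) {
      if (sum(mask) == 0) mask[sample.int(length(mask), 1)] <- 1L
      mask
    }

    best <- list(fitness = -Inf, mask = NULL, c_log2 = NA, g_log2 = NA)
    note_best <- function(i) {
      if (light[i] > best$fitness) {
        best <<- list(fitness = light[i], mask = masks[i, ],
                      c_log2 = pos[i, n + 1], g_log2 = pos[i, n + 2])
      }
    }

    for (i in seq_len(g)) {
      masks[i, ] <- repair(discretize_position(pos[i, seq_len(n)]))
      light[i] <- evaluate(masks[i, ], pos[i, n + 1], pos[i, n + 2])
      note_best(i)
    }

    trace <- numeric(config$max_generation)
    for (t in seq_len(config$max_generation)) {
      for (i in seq_len(g)) {
        for (j in seq_len(g)) {
          if (j == i || light[j] <= light[i]) next
          pos[i, ] <- firefly_move(pos[i, ], pos[j, ], config)
          masks[i, ] <- repair(discretize_position(pos[i, seq_len(n)]))
          light[i] <- evaluate(masks[i, ], pos[i, n + 1], pos[i, n + 2])
          note_best(i)
        }
      }
      # the brightest firefly has no attractor; it explores by random walk
      b <- which.max(light)
      pos[b, ] <- pos[b, ] +
        config$randomness * (stats::runif(d) - 0.5)
      pos[b, n + 1] <- min(max(pos[b, n + 1], config$c_log2_range[1]),
                           config$c_log2_range[2])
      pos[b, n + 2] <- min(max(pos[b, n + 2], config$gamma_log2_range[1]),
                           config$gamma_log2_range[2])
      masks[b, ] <- repair(discretize_position(pos[b, seq_len(n)]))
      light[b] <- evaluate(masks[b, ], pos[b, n + 1], pos[b, n + 2])
      note_best(b)
      trace[t] <- best$fitness
    }

    structure(list(
      best_mask = best$mask,
      best_C = 2^best$c_log2,
      best_gamma = 2^best$g_log2,
      best_fitness = best$fitness,
      trace = trace,
      n_evaluations = n_eval,
      config = config
    ), class = "dfa_result")
  })
}

#' @export
print.dfa_result <- function(x, ...) {
  cat(sprintf(
    "discrete firefly result: %d/%d features, C = %.6g, gamma = %.6g, fitness = %.4f (%d evaluations)\n",
    sum(x$best_mask), length(x$best_mask), x$best_C, x$best_gamma,
    x$best_fitness, x$n_evaluations))
  invisible(x)
}
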