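# Synthetic score generator.
#
# Emulates the statistical structure the method assumes: strictly positive
# raw scores, approximately Gaussian, with per-function profile means
# separated enough that downstream beta clusters give pairwise disjoint
# intervals. Function k's own column mean sits at
# base_mean + k * separation * noise_sd, so adjacent functions' profiles are
# `separation` within-function sds apart. The stagger matters: with equal
# elevation for every function the corpus is permutation-symmetric and the
# class means of beta coincide exactly, so no separation would ever reach
# the beta line.

#' Simulation specification
#'
#' @param n_functions number of candidate functions (>= 3).
#' @param seqs_per_function training sequences per function.
#' @param separation distance between adjacent functions' score-profile
#'   means, in units of `noise_sd`; 0 makes all functions exchangeable.
#' @param noise_sd within-function score standard deviation (bit-score
#'   units).
#' @param base_mean baseline column mean (bit-score units).
#' @param score_floor scores are truncated below at this value (>= 0),
#'   honouring the positivity of raw bit scores.
#' @param seed RNG seed.
#' @return a list of class `simulation_spec`.
#' @export
simulation_spec <- function(n_functions = 3, seqs_per_function = 30,
                            separation = 6, noise_sd = 1, base_mean = 10,
                            score_floor = 0, seed = 1) {
  if (n_functions < 3) stop("n_functions must be >= 3 (axiom min|A| = 3)", call. = FALSE)
  if (seqs_per_function < 1) stop("seqs_per_function must be positive", call. = FALSE)
  if (separation < 0) stop("separation must be >= 0", call. = FALSE)
  if (noise_sd <= 0) stop("noise_sd must be positive", call. = FALSE)
  if (score_floor < 0) stop("score_floor must be >= 0", call. = FALSE)
  structure(
    list(
      n_functions = as.integer(n_functions),
      seqs_per_function = as.integer(seqs_per_function),
      separation = separation, noise_sd = noise_sd, base_mean = base_mean,
      score_floor = score_floor, seed = as.integer(seed)
    ),
    class = "simulation_spec"
  )
}

#' Generate a labeled synthetic score matrix
#'
#' @param spec a [simulation_spec()], or arguments passed to it via `...`.
#' @param ... used when `spec` is missing.
#' @return list with `scores` (a [score_matrix()]) and `labels` (named
#'   character vector aligned with the rows).
#' @examples
#' sim <- simulate_scores(simulation_spec(seqs_per_function = 5, seed = 42))
#' sim$scores
#' @export
simulate_scores <- function(spec = NULL, ...) {
  spec <- spec %||% simulation_spec(...)
  stopifnot(inherits(spec, "simulation_spec"))
  n <- spec$n_functions
  m_k <- spec$seqs_per_function
  m <- n * m_k
  fun_labels <- paste0("F", seq_len(n))
  row_fun <- rep(seq_len(n), each = m_k)
  mu <- matrix(spec$base_mean, nrow = m, ncol = n)
  for (k in seq_len(n)) {
    mu[row_fun == k, k] <- spec$base_mean + k * spec$separation * spec$noise_sd
  }
  values <- with_local_seed(spec$seed, {
    mu + matrix(stats::rnorm(m * n, sd = spec$noise_sd), nrow = m)
  })
  values <- pmax(values, spec$score_floor)
  ids <- sprintf("seq_%03d", seq_len(m))
  dimnames(values) <- list(ids, fun_labels)
  list(
    scores = score_matrix(values),
    labels = stats::setNames(fun_labels[row_fun], ids),
    spec = spec
  )
}

#' Tiny hand-authored regression fixtures
#'
#' Small worked examples with expected values computed by hand and frozen,
#' used as a regression corpus:
#' \describe{
#'   \item{`constant`}{all scores equal; every POP column is constant, so
#'     every standardized value and every beta is 0.}
#'   \item{`three-singletons`}{three sequences, three functions, one
#'     sequence per function; each centroid equals that sequence's beta.}
#'   \item{`planted-outlier`}{one cluster of four tight sequences plus one
#'     planted far-off member; exactly that member is flagged.}
#' }
#'
#' @param name fixture name.
#' @return list with `scores`, `labels`, and `expected` (fixture-specific
#'   frozen values).
#' @export
make_worked_fixture <- function(name = c("constant", "three-singletons", "planted-outlier")) {
  name <- match.arg(name)
  if (name == "constant") {
    v <- matrix(7, nrow = 4, ncol = 3,
      dimnames = list(paste0("s", 1:4), c("F1", "F2", "F3"))
    )
    list(
      scores = score_matrix(v),
      labels = stats::setNames(c("F1", "F1", "F2", "F3"), paste0("s", 1:4)),
      expected = list(
        raw_zeta = 7, beta = c(s1 = 0, s2 = 0, s3 = 0, s4 = 0),
        centroids = c(F1 = 0, F2 = 0, F3 = 0), all_columns_constant = TRUE
      )
    )
  } else if (name == "three-singletons") {
    v <- matrix(
      c(
        10, 1, 1,
        1, 20, 1,
        1, 1, 30
      ),
      nrow = 3, byrow = TRUE,
      dimnames = list(paste0("s", 1:3), c("F1", "F2", "F3"))
    )
    # Hand-worked: raw POP rows (mean4) are (5.5, 3.25, 3.25),
    # (5.75, 10.5, 5.75), (8.25, 8.25, 15.5); column z-scores summed give
    # the betas below. Centroids equal the betas (singleton clusters).
    list(
      scores = score_matrix(v),
      labels = stats::setNames(c("F1", "F2", "F3"), paste0("s", 1:3)),
      expected = list(
        raw_zeta = matrix(
          c(
            5.5, 3.25, 3.25,
            5.75, 10.5, 5.75,
            8.25, 8.25, 15.5
          ),
          nrow = 3, byrow = TRUE
        ),
        beta = c(s1 = -2.5175565, s2 = -0.0132197, s3 = 2.5307762),
        centroids = c(F1 = -2.5175565, F2 = -0.0132197, F3 = 2.5307762)
      )
    )
  } else {
    v <- matrix(
      c(
        10.0, 1.0, 1.0,
        10.2, 1.1, 0.9,
        9.8, 0.9, 1.1,
        10.1, 1.0, 1.0,
        1.0, 1.0, 10.0,
        1.0, 14.0, 1.0,
        1.2, 14.2, 1.1,
        1.0, 1.0, 18.0,
        0.9, 1.1, 18.2
      ),
      nrow = 9, byrow = TRUE,
      dimnames = list(paste0("s", 1:9), c("F1", "F2", "F3"))
    )
    list(
      scores = score_matrix(v),
      labels = stats::setNames(
        c("F1", "F1", "F1", "F1", "F1", "F2", "F2", "F3", "F3"),
        paste0("s", 1:9)
      ),
      expected = list(outlier_cluster = "F1", flagged = "s5")
    )
  }
}
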