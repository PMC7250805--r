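# POP feature construction.
#
# Step chain: raw score matrix (sequences x functions) -> raw POP values (one
# per pair-of-pairs) -> column-wise z-standardization across the training
# corpus -> per-sequence beta-value (row sum of standardized POP scores).
# Standardization is per POP ordinal across sequences: standardizing within a
# sequence would force every beta to zero identically, destroying the
# clustering stage.

#' Construct a score matrix
#'
#' Wraps a numeric matrix of raw profile-HMM bit scores (rows = sequences,
#' columns = candidate functions). Raw scores are required non-negative;
#' HMMER can emit small negative bit scores, which are clamped to 0 with a
#' warning unless `clamp_negative = FALSE`.
#'
#' @param values numeric matrix, sequences x functions, at least 3 columns.
#' @param sequence_ids character vector of row identifiers (defaults to
#'   rownames, then seq_1..seq_m).
#' @param labels character vector of function identifiers (defaults to
#'   colnames); must be unique.
#' @param clamp_negative clamp negative scores to 0 (default `TRUE`).
#' @return an object of class `score_matrix`: list with `values`,
#'   `sequence_ids`, `labels`.
#' @examples
#' m <- matrix(c(10, 1, 1, 1, 12, 2), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("s1", "s2"), c("F1", "F2", "F3")))
#' score_matrix(m)
#' @export
score_matrix <- function(values, sequence_ids = NULL, labels = NULL,
                         clamp_negative = TRUE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (ncol(values) < 3) {
    stop("a score matrix needs >= 3 function columns (axiom min|A| = 3)",
      call. = FALSE
    )
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("score matrix contains missing or non-finite values", call. = FALSE)
  }
  sequence_ids <- sequence_ids %||% rownames(values) %||%
    paste0("seq_", seq_len(nrow(values)))
  labels <- labels %||% colnames(values) %||%
    paste0("F", seq_len(ncol(values)))
  if (anyDuplicated(labels)) {
    stop("function labels must be unique", call. = FALSE)
  }
  if (length(sequence_ids) != nrow(values) || length(labels) != ncol(values)) {
    stop("id/label lengths do not match matrix dimensions", call. = FALSE)
  }
  n_neg <- sum(values < 0)
  if (n_neg > 0) {
    if (clamp_negative) {
      warning(n_neg, " negative raw score(s) clamped to 0 (alpha must be >= 0)",
        call. = FALSE
      )
      values[values < 0] <- 0
    } else {
      warning(n_neg, " negative raw score(s) kept (clamp_negative = FALSE)",
        call. = FALSE
      )
    }
  }
  dimnames(values) <- list(sequence_ids, labels)
  structure(
    list(values = values, sequence_ids = sequence_ids, labels = as.character(labels)),
    class = "score_matrix"
  )
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(
    "<score_matrix> ", nrow(x$values), " sequence(s) x ", ncol(x$values),
    " function(s): ", paste(x$labels, collapse = ", "), "\n",
    sep = ""
  )
  invisible(x)
}

as_score_values <- function(scores) {
  if (inherits(scores, "score_matrix")) scores$values else as.matrix(scores)
}

pop_strategies <- c("mean4", "sum4", "geomean4")

combine_pop <- function(a, b, c, d, strategy) {
  switch(strategy,
    mean4 = (a + b + c + d) / 4,
    sum4 = a + b + c + d,
    geomean4 = (a * b * c * d)^(1 / 4)
  )
}

#' Raw POP value for one sequence and one pair-of-pairs
#'
#' Collapses the four score slots of a POP (two pairs of two scores; a shared
#' column, if any, is counted each time it appears) into one number. The
#' default combiner is the arithmetic mean of the four slots; `"sum4"` and
#' `"geomean4"` are alternatives. The combiner in force is recorded in every
#' fitted feature object.
#'
#' @param alpha_row numeric vector of one sequence's raw scores (length >= 3).
#' @param pop a single-row slice of [enumerate_pops()] (fields `i1`, `j1`,
#'   `i2`, `j2`), or a numeric vector of those four indices.
#' @param strategy `"mean4"` (default), `"sum4"`, or `"geomean4"`.
#' @return scalar POP value.
#' @examples
#' pop_raw_score(c(1, 2, 3), enumerate_pops(3)[1, ]) # (1+2+1+3)/4 = 1.75
#' @export
pop_raw_score <- function(alpha_row, pop, strategy = "mean4") {
  if (!strategy %in% pop_strategies) {
    stop("unknown POP combiner strategy: ", strategy, call. = FALSE)
  }
  if (is.data.frame(pop)) {
    idx <- c(pop$i1[1], pop$j1[1], pop$i2[1], pop$j2[1])
  } else {
    idx <- as.numeric(pop)[seq_len(4)]
  }
  if (any(idx < 1) || any(idx > length(alpha_row))) {
    stop("POP indices out of range for this score row", call. = FALSE)
  }
  combine_pop(
    alpha_row[idx[1]], alpha_row[idx[2]], alpha_row[idx[3]], alpha_row[idx[4]],
    strategy
  )
}

#' Raw POP matrix for all sequences
#'
#' @param scores a [score_matrix()] or plain numeric matrix.
#' @inheritParams pop_raw_score
#' @return numeric matrix, sequences x `pop_count(n_functions)`.
#' @export
pop_raw_matrix <- function(scores, strategy = "mean4") {
  if (!strategy %in% pop_strategies) {
    stop("unknown POP combiner strategy: ", strategy, call. = FALSE)
  }
  v <- as_score_values(scores)
  pops <- enumerate_pops(ncol(v))
  out <- combine_pop(
    v[, pops$i1, drop = FALSE], v[, pops$j1, drop = FALSE],
    v[, pops$i2, drop = FALSE], v[, pops$j2, drop = FALSE],
    strategy
  )
  dimnames(out) <- list(rownames(v), paste0("pop_", pops$ordinal))
  out
}

#' Fit the POP standardizer on a training corpus
#'
#' Column-wise z-standardization of the raw POP matrix: each POP ordinal's
#' values across training sequences are centred and scaled to unit sample
#' standard deviation, so that a POP's computed value is its own z-score.
#' Zero-variance columns are set to 0 and flagged; their scale is stored as 1
#' so that applying the standardizer to new data maps them to a centred value
#' of 0 as well.
#'
#' @param raw_zeta numeric matrix of raw POP values (>= 2 rows), e.g. from
#'   [pop_raw_matrix()].
#' @param strategy combiner name recorded for provenance.
#' @return object of class `pop_features`: list with `zeta` (standardized
#'   matrix), `center`, `scale`, `constant` (logical flags), `strategy`.
#' @export
fit_standardizer <- function(raw_zeta, strategy = "mean4") {
  raw_zeta <- as.matrix(raw_zeta)
  if (nrow(raw_zeta) < 2) {
    stop("standardization needs >= 2 sequences (sd undefined for one row)",
      call. = FALSE
    )
  }
  center <- colMeans(raw_zeta)
  scale <- apply(raw_zeta, 2, stats::sd)
  constant <- scale < .Machine$double.eps^0.5
  scale[constant] <- 1
  zeta <- sweep(sweep(raw_zeta, 2, center, "-"), 2, scale, "/")
  zeta[, constant] <- 0
  structure(
    list(
      zeta = zeta, center = center, scale = scale,
      constant = constant, strategy = strategy
    ),
    class = "pop_features"
  )
}

#' @export
print.pop_features <- function(x, ...) {
  cat(
    "<pop_features> ", nrow(x$zeta), " sequence(s) x ", ncol(x$zeta),
    " POP column(s), strategy = ", x$strategy,
    if (any(x$constant)) paste0(" (", sum(x$constant), " constant column(s))"),
    "\n",
    sep = ""
  )
  invisible(x)
}

#' Apply a fitted standardizer to new raw POP values
#'
#' @param raw_zeta numeric matrix or single row of raw POP values with the
#'   same number of columns the standardizer was fitted on.
#' @param standardizer a `pop_features` object from [fit_standardizer()].
#' @return standardized matrix (or row) of POP z-scores.
#' @export
apply_standardizer <- function(raw_zeta, standardizer) {
  stopifnot(inherits(standardizer, "pop_features"))
  if (is.null(dim(raw_zeta))) raw_zeta <- matrix(raw_zeta, nrow = 1)
  if (ncol(raw_zeta) != length(standardizer$center)) {
    stop(
      "raw POP row length ", ncol(raw_zeta), " does not match the ",
      length(standardizer$center), " columns the standardizer was fitted on",
      call. = FALSE
    )
  }
  zeta <- sweep(sweep(raw_zeta, 2, standardizer$center, "-"),
    2, standardizer$scale, "/"
  )
  zeta[, standardizer$constant] <- 0
  zeta
}

#' Featurize a score matrix
#'
#' Convenience wrapper: raw POP values then standardizer fit in one call.
#'
#' @inheritParams pop_raw_matrix
#' @return a `pop_features` object.
#' @export
featurize <- function(scores, strategy = "mean4") {
  fit_standardizer(pop_raw_matrix(scores, strategy), strategy)
}

#' Beta-value of one sequence
#'
#' The beta-value is the sum of a sequence's standardized POP scores over all
#' `|D|` POP ordinals; it is the one-dimensional coordinate on which
#' clustering, intervals and the network target are defined.
#'
#' @param zeta_row numeric vector of standardized POP scores.
#' @return scalar beta.
#' @export
beta_value <- function(zeta_row) {
  zeta_row <- as.numeric(zeta_row)
  if (any(!is.finite(zeta_row))) {
    stop("non-finite POP scores; cannot compute beta", call. = FALSE)
  }
  sum(zeta_row)
}

#' Beta-values of all sequences
#'
#' @param features a `pop_features` object or standardized matrix.
#' @return named numeric vector of per-sequence beta-values.
#' @export
beta_values <- function(features) {
  zeta <- if (inherits(features, "pop_features")) features$zeta else as.matrix(features)
  if (any(!is.finite(zeta))) {
    stop("non-finite POP scores; cannot compute beta", call. = FALSE)
  }
  rowSums(zeta)
}
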