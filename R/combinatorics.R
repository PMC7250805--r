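# Combinatorics of the score sets.
#
# A sequence scored against n candidate functions yields the superset A of n
# raw HMM bit scores. B is the set of unordered pairs of those scores,
# |B| = C(n, 2); D is the set of unordered pairs of *distinct* pairs
# ("pairs of pairs", POPs), |D| = C(|B|, 2). |D| is the input dimensionality
# of the neural network, so these counts dictate the feasible architecture.

check_superset_size <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n != as.integer(n)) {
    stop("superset size `n` must be a single integer", call. = FALSE)
  }
  if (n < 3) {
    stop(
      "superset size n = ", n, " violates the axiomatic lower bound ",
      "min(n) = min|A| = min|B| = min|D| = 3",
      call. = FALSE
    )
  }
  as.integer(n)
}

#' Number of score pairs for a superset of n functions
#'
#' @param n superset size (number of candidate functions), `n >= 3`.
#' @return `choose(n, 2)` as an integer.
#' @examples
#' pair_count(3)  # 3
#' pair_count(18) # 153
#' @export
pair_count <- function(n) {
  n <- check_superset_size(n)
  as.integer(choose(n, 2))
}

#' Number of pairs-of-pairs (POPs) for a superset of n functions
#'
#' The POP set D contains every unordered pair of distinct score pairs, so
#' `|D| = choose(choose(n, 2), 2)`. This count is identically equal to the
#' quartic `0.125 n^4 - 0.25 n^3 - 0.125 n^2 + 0.25 n`.
#'
#' @inheritParams pair_count
#' @return `choose(choose(n, 2), 2)` as an integer.
#' @examples
#' pop_count(4)  # 15
#' pop_count(18) # 11628
#' @export
pop_count <- function(n) {
  n <- check_superset_size(n)
  as.integer(choose(choose(n, 2), 2))
}

#' Published fitted curves for |B| and |D| as functions of n
#'
#' Evaluates the reference regression fits of pair and POP cardinality against
#' superset size, verbatim with their printed coefficients. These are
#' provided for comparison only: the polynomial fit for `|B|` carries a
#' printed linear coefficient of -0.25 where the exact binomial expansion has
#' -0.5, so `B_poly` does *not* reproduce the exact count (e.g. it gives 3.75
#' at n = 3). All package computation uses the exact [pair_count()] and
#' [pop_count()].
#'
#' @inheritParams pair_count
#' @param which one of `"B_poly"`, `"B_power"`, `"D_poly"`, `"D_power"`.
#' @return the raw (unrounded) fitted value.
#' @examples
#' fitted_cardinality(4, "D_poly")  # 15 (the quartic is exact)
#' fitted_cardinality(3, "B_poly")  # 3.75 (the printed fit is not)
#' @export
fitted_cardinality <- function(n, which = c("B_poly", "B_power", "D_poly", "D_power")) {
  n <- check_superset_size(n)
  which <- match.arg(which)
  switch(which,
    B_poly  = 0.5 * n^2 - 0.25 * n + 2e-13,
    B_power = 0.298 * n^2.1704,
    D_poly  = 0.125 * n^4 - 0.25 * n^3 - 0.125 * n^2 + 0.25 * n - 2e-08,
    D_power = 0.0293 * n^4.4996
  )
}

#' Enumerate all score pairs
#'
#' @inheritParams pair_count
#' @return a data frame with integer columns `i`, `j` (1-based column
#'   indices, `i < j`), one row per unordered pair, in lexicographic order.
#' @examples
#' enumerate_pairs(3)
#' @export
enumerate_pairs <- function(n) {
  n <- check_superset_size(n)
  cmb <- utils::combn(n, 2L)
  data.frame(i = cmb[1L, ], j = cmb[2L, ])
}

#' Enumerate all pairs-of-pairs (POPs)
#'
#' A POP couples two distinct score pairs. The canonical enumeration is
#' lexicographic over ordered pairs of pair ordinals, giving a stable
#' bijection between `ordinal` and POP that serialized models rely on.
#'
#' The chained variant (`chained = TRUE`) restricts to POPs whose two pairs
#' share exactly one index, i.e. of the form ((a_i, a_j), (a_j, a_k)). It is
#' exposed for study only; its cardinality (12 at n = 4) is inconsistent with
#' the reference architecture table (15 at n = 4), so the pipeline always
#' uses the full enumeration.
#'
#' @inheritParams pair_count
#' @param chained if `TRUE`, keep only POPs whose pairs share one index.
#' @return a data frame with columns `ordinal` (1-based position in the
#'   canonical enumeration), `i1`, `j1`, `i2`, `j2` (the two pairs' 1-based
#'   column indices).
#' @examples
#' enumerate_pops(3)
#' nrow(enumerate_pops(4))                  # 15
#' nrow(enumerate_pops(4, chained = TRUE))  # 12
#' @export
enumerate_pops <- function(n, chained = FALSE) {
  n <- check_superset_size(n)
  pairs <- enumerate_pairs(n)
  idx <- utils::combn(nrow(pairs), 2L)
  pops <- data.frame(
    ordinal = seq_len(ncol(idx)),
    i1 = pairs$i[idx[1L, ]],
    j1 = pairs$j[idx[1L, ]],
    i2 = pairs$i[idx[2L, ]],
    j2 = pairs$j[idx[2L, ]]
  )
  if (chained) {
    shared <- mapply(
      function(a, b, c, d) length(intersect(c(a, b), c(c, d))),
      pops$i1, pops$j1, pops$i2, pops$j2
    )
    pops <- pops[shared == 1L, , drop = FALSE]
    rownames(pops) <- NULL
  }
  pops
}

#' Hidden-layer size heuristics
#'
#' Three rules mapping the network input dimensionality `d = |D|` to a hidden
#' node count for a 1:1:1 (one input layer, one hidden layer, one output
#' unit) feed-forward network:
#' \describe{
#'   \item{H1}{`0.5 (d + 1) + sqrt(d)`}
#'   \item{H2}{`2 sqrt(d + 1)`}
#'   \item{H3}{`2 (d + 1) / 3`}
#' }
#' each rounded half away from zero.
#'
#' @param d POP count `|D|`, `d >= 3`.
#' @return named integer vector `c(h1, h2, h3)`.
#' @examples
#' hidden_nodes(3)     # 4 4 3
#' hidden_nodes(11628) # 5922 216 7753
#' @export
hidden_nodes <- function(d) {
  if (!is.numeric(d) || length(d) != 1L || is.na(d) || d < 3) {
    stop("`d` must be a single number >= 3 (|D| has axiomatic minimum 3)", call. = FALSE)
  }
  c(
    h1 = as.integer(round_half_up(0.5 * (d + 1) + sqrt(d))),
    h2 = as.integer(round_half_up(2 * sqrt(d + 1))),
    h3 = as.integer(round_half_up(2 * (d + 1) / 3))
  )
}

#' Architecture table: superset size versus network dimensions
#'
#' Tabulates, for every superset size n from 3 to `n_max`, the exact pair and
#' POP cardinalities and the three hidden-node heuristics.
#'
#' @param n_max largest superset size, `>= 3`.
#' @return data frame with columns `n`, `b`, `d`, `h1`, `h2`, `h3`.
#' @examples
#' architecture_table(6)
#' @export
architecture_table <- function(n_max) {
  n_max <- check_superset_size(n_max)
  ns <- 3:n_max
  d <- vapply(ns, pop_count, integer(1))
  h <- t(vapply(d, hidden_nodes, integer(3)))
  data.frame(
    n = ns,
    b = vapply(ns, pair_count, integer(1)),
    d = d,
    h1 = h[, "h1"],
    h2 = h[, "h2"],
    h3 = h[, "h3"]
  )
}

#' Feasible superset sizes under a hidden-node budget
#'
#' Back-propagation networks of this 1:1:1 shape degrade beyond roughly 18
#' hidden nodes, which bounds the practical superset size. A size n is
#' feasible when its chosen hidden-node statistic does not exceed
#' `node_cap * (1 + slack)`. The default slack of 0.2 reflects that the cap
#' is an order-of-magnitude guide, not a hard wall: at the default rule the
#' feasible range is 3..6 (min heuristic at n = 6 is 21, within 20% of 18).
#'
#' @param node_cap hidden-node budget, `>= 3`.
#' @param rule which heuristic to compare: `"H1"`, `"H2"`, `"H3"`, or
#'   `"min"` (the smallest of the three; default).
#' @param slack multiplicative tolerance on the cap (default 0.2).
#' @return integer vector of feasible n (possibly empty).
#' @examples
#' feasible_superset_sizes(18)            # 3 4 5 6
#' feasible_superset_sizes(18, slack = 0) # 3 4 5
#' @export
feasible_superset_sizes <- function(node_cap, rule = c("min", "H1", "H2", "H3"),
                                    slack = 0.2) {
  if (!is.numeric(node_cap) || length(node_cap) != 1L || node_cap < 3) {
    stop("`node_cap` must be a single number >= 3", call. = FALSE)
  }
  rule <- match.arg(rule)
  limit <- node_cap * (1 + slack)
  feasible <- integer(0)
  n <- 3L
  repeat {
    h <- hidden_nodes(pop_count(n))
    stat <- switch(rule,
      min = min(h),
      H1 = h[["h1"]],
      H2 = h[["h2"]],
      H3 = h[["h3"]]
    )
    if (stat > limit) break # all three heuristics increase with n
    feasible <- c(feasible, n)
    n <- n + 1L
  }
  feasible
}
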