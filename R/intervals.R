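# Confidence intervals and the interval partition.
#
# Each function cluster gets a confidence interval for its centroid:
# centroid +/- t_{alpha/2} * sigma / sqrt(|G|) for small clusters (|G| < 30,
# Student t with |G| - 1 df), the normal quantile otherwise. The sorted
# intervals form the partition used to map a network output to exactly one
# function; the enclosing search-space bounds [a, b] are wider, using +/- one
# whole sigma around the extreme centroids, and the partition's outer measure
# is |b - a|. Intervals are treated as open: containment is strict, and a
# prediction exactly on a boundary is unassigned.

#' Confidence interval for one function cluster
#'
#' @param model one cluster: a single-row slice of a
#'   [fit_centroids()] result, or any list/row with fields `label`,
#'   `centroid`, `sigma`, `size`.
#' @param alpha significance level (default 0.05 for a 95% interval).
#' @return object of class `function_interval`: list with `label`, `low`,
#'   `high`, `centroid`, `sigma`, `size`, `coefficient`, `kind` (`"t"`,
#'   `"z"`, or `"degenerate"`).
#' @export
build_interval <- function(model, alpha = 0.05) {
  if (is.data.frame(model)) model <- as.list(model[1, ])
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must be a single value in (0, 1)", call. = FALSE)
  }
  size <- model$size
  sigma <- model$sigma
  if (size < 2 || sigma == 0) {
    if (size < 2) {
      warning("cluster '", model$label, "' has fewer than 2 members: ",
        "degenerate point interval",
        call. = FALSE
      )
    }
    coef <- 0
    kind <- "degenerate"
    half <- 0
  } else if (size < 30) {
    coef <- stats::qt(1 - alpha / 2, df = size - 1)
    kind <- "t"
    half <- abs(coef * sigma / sqrt(size))
  } else {
    coef <- stats::qnorm(1 - alpha / 2)
    kind <- "z"
    half <- abs(coef * sigma / sqrt(size))
  }
  structure(
    list(
      label = model$label, low = model$centroid - half,
      high = model$centroid + half, centroid = model$centroid,
      sigma = sigma, size = size, coefficient = coef, kind = kind
    ),
    class = "function_interval"
  )
}

#' @export
print.function_interval <- function(x, ...) {
  cat(
    sprintf(
      "<function_interval> %s: (%.6g, %.6g) [%s, |G| = %d]\n",
      x$label, x$low, x$high, x$kind, x$size
    )
  )
  invisible(x)
}

#' Assemble the interval partition
#'
#' Sorts the per-function intervals, checks pairwise disjointness (strict,
#' open intervals: adjacent intervals must satisfy `high_i < low_{i+1}`),
#' and computes the enclosing bounds `a = min(centroid) - sigma` and
#' `b = max(centroid) + sigma` (the sigma of the extreme clusters), the
#' outer measure `|b - a|`, and the mapping probability
#' `tau = 1 / n_intervals`. A non-disjoint set is returned with
#' `disjoint = FALSE` and a warning; prediction then degrades to ambiguous
#' status rather than failing.
#'
#' @param intervals list of `function_interval` objects (>= 3), or a
#'   `function_clusters` object (intervals are then built with `alpha`).
#' @param alpha significance level used when `intervals` is a
#'   `function_clusters` object.
#' @return object of class `interval_partition`: list with `intervals`
#'   (sorted by lower endpoint), `a`, `b`, `measure`, `tau`, `disjoint`,
#'   `alpha`.
#' @export
build_partition <- function(intervals, alpha = 0.05) {
  if (inherits(intervals, "function_clusters")) {
    intervals <- lapply(
      seq_len(nrow(intervals)),
      function(i) build_interval(intervals[i, ], alpha)
    )
  }
  if (length(intervals) < 3) {
    stop(
      "a partition needs >= 3 function intervals (axiom min|A| = 3)",
      call. = FALSE
    )
  }
  stopifnot(all(vapply(intervals, inherits, logical(1), "function_interval")))
  ord <- order(vapply(intervals, `[[`, numeric(1), "low"))
  intervals <- intervals[ord]
  lows <- vapply(intervals, `[[`, numeric(1), "low")
  highs <- vapply(intervals, `[[`, numeric(1), "high")
  cents <- vapply(intervals, `[[`, numeric(1), "centroid")
  sigmas <- vapply(intervals, `[[`, numeric(1), "sigma")
  disjoint <- all(highs[-length(highs)] < lows[-1])
  if (!disjoint) {
    warning(
      "function intervals overlap: partition is not disjoint, ",
      "predictions in overlaps will be ambiguous",
      call. = FALSE
    )
  }
  a <- cents[which.min(cents)] - sigmas[which.min(cents)]
  b <- cents[which.max(cents)] + sigmas[which.max(cents)]
  structure(
    list(
      intervals = intervals, a = a, b = b, measure = abs(b - a),
      tau = 1 / length(intervals), disjoint = disjoint, alpha = alpha
    ),
    class = "interval_partition"
  )
}

#' @export
print.interval_partition <- function(x, ...) {
  cat(
    "<interval_partition> ", length(x$intervals), " interval(s), ",
    if (x$disjoint) "disjoint" else "NOT disjoint",
    sprintf(
      "; [a, b] = [%.6g, %.6g], measure = %.6g, tau = %.4g\n",
      x$a, x$b, x$measure, x$tau
    ),
    sep = ""
  )
  for (iv in x$intervals) print(iv)
  invisible(x)
}

#' Probability of mapping a prediction to a distinct function
#'
#' `tau = 1 / n_intervals`: with a disjoint partition of the candidate
#' superset, an uninformed prediction lands in any one function's interval
#' with this probability. Under the practical superset bound 3 <= |A| <= 6,
#' tau spans 0.166 (6 functions) to 0.33 (3 functions), quoted truncated.
#'
#' @param partition an `interval_partition`.
#' @return scalar tau.
#' @examples
#' \dontrun{
#' truncate_decimal(mapping_probability(p3), 2) # 0.33 for 3 functions
#' }
#' @export
mapping_probability <- function(partition) {
  stopifnot(inherits(partition, "interval_partition"))
  1 / length(partition$intervals)
}

#' Map a network output to a function
#'
#' Assigns a scalar prediction `beta_dprime` to the unique function whose
#' (open) interval contains it, optionally after expanding every interval by
#' `epsilon` on both sides. Expanding by the cluster sigma
#' (`epsilon = "sigma"`) widens each interval to roughly the enclosing
#' one-sigma band around its centroid. Status is `"assigned"` (exactly one
#' interval), `"ambiguous"` (several; all candidates are listed together with
#' a nearest-centroid suggestion, which is never silently applied), or
#' `"unassigned"` (none; a value exactly on an interval boundary is
#' unassigned with a warning, since the intervals are open).
#'
#' @param beta_dprime scalar network output.
#' @param partition an `interval_partition`.
#' @param epsilon non-negative expansion applied to both ends of every
#'   interval (default 0), or the string `"sigma"` to expand each interval by
#'   its own cluster sigma.
#' @return list with `label` (NA unless assigned), `status`, `candidates`
#'   (labels of all containing intervals), `nearest` (nearest-centroid
#'   label), `beta_dprime`.
#' @export
map_prediction <- function(beta_dprime, partition, epsilon = 0) {
  stopifnot(inherits(partition, "interval_partition"))
  if (!is.finite(beta_dprime)) {
    stop("beta'' must be finite", call. = FALSE)
  }
  sigmas <- vapply(partition$intervals, `[[`, numeric(1), "sigma")
  eps <- if (identical(epsilon, "sigma")) {
    sigmas
  } else {
    if (!is.numeric(epsilon) || any(epsilon < 0)) {
      stop("`epsilon` must be non-negative or \"sigma\"", call. = FALSE)
    }
    rep_len(epsilon, length(partition$intervals))
  }
  lows <- vapply(partition$intervals, `[[`, numeric(1), "low") - eps
  highs <- vapply(partition$intervals, `[[`, numeric(1), "high") + eps
  labels <- vapply(partition$intervals, `[[`, character(1), "label")
  cents <- vapply(partition$intervals, `[[`, numeric(1), "centroid")
  inside <- beta_dprime > lows & beta_dprime < highs
  on_boundary <- any(beta_dprime == lows | beta_dprime == highs)
  nearest <- labels[which.min(abs(beta_dprime - cents))]
  if (sum(inside) == 1) {
    list(
      label = labels[inside], status = "assigned",
      candidates = labels[inside], nearest = nearest,
      beta_dprime = beta_dprime
    )
  } else if (sum(inside) > 1) {
    list(
      label = NA_character_, status = "ambiguous",
      candidates = labels[inside], nearest = nearest,
      beta_dprime = beta_dprime
    )
  } else {
    if (on_boundary) {
      warning(
        "beta'' = ", format(beta_dprime), " lies exactly on an open-interval ",
        "boundary: unassigned",
        call. = FALSE
      )
    }
    list(
      label = NA_character_, status = "unassigned",
      candidates = character(0), nearest = nearest,
      beta_dprime = beta_dprime
    )
  }
}

#' Serialize a partition to JSON
#'
#' @param partition an `interval_partition`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, path) {
  payload <- list(
    intervals = lapply(partition$intervals, function(iv) iv[c(
      "label", "low", "high", "centroid", "sigma", "size", "coefficient", "kind"
    )]),
    a = partition$a, b = partition$b, measure = partition$measure,
    tau = partition$tau, disjoint = partition$disjoint, alpha = partition$alpha
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
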