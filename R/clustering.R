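# Per-function clustering of beta-values.
#
# Each known function's training sequences form a cluster on the beta line;
# its centroid is the cluster mean (which minimizes the within-cluster sum of
# squared deviations), its dispersion the sample sd, and a chi-squared
# statistic measures how tightly members sit around the centroid. Outliers
# are members at least one sd from the centroid and are candidates for
# removal when refining the training set.

#' Chi-squared concordance of a beta cluster
#'
#' `sum((beta - centroid)^2 / centroid)`, the refinement statistic comparing
#' cluster members against their centroid; it is exactly 0 when the cluster
#' is constant. Standardized beta-values can be non-positive while the
#' statistic's denominator assumes a positive centroid, so when any value is
#' <= 0 a positivity shift `c = 1 + |min|` is added to both the members and
#' the centroid first (this preserves the zero point and the ordering of the
#' statistic across candidate refinements); the shift used is attached as
#' attribute `"shift"`.
#'
#' @param betas numeric vector of one cluster's beta-values.
#' @param centroid the cluster centroid (mean of `betas` in normal use).
#' @return scalar chi-squared with attribute `shift`.
#' @examples
#' chi_squared(c(1, 3), 2) # (1 + 1)/2 = 1
#' @export
chi_squared <- function(betas, centroid) {
  betas <- as.numeric(betas)
  if (any(!is.finite(betas)) || !is.finite(centroid)) {
    stop("non-finite beta or centroid", call. = FALSE)
  }
  lo <- min(c(betas, centroid))
  shift <- if (lo <= 0) 1 + abs(lo) else 0
  denom <- centroid + shift
  if (denom <= 0) {
    stop("internal error: shifted centroid not positive", call. = FALSE)
  }
  structure(sum((betas - centroid)^2) / denom, shift = shift)
}

#' Flag outlier members of a cluster
#'
#' Refinement rule: a well-chosen training sequence sits within one standard
#' deviation of its cluster centroid, so members with
#' `|beta - centroid| >= sigma` are flagged. A constant cluster (sigma 0)
#' flags nothing.
#'
#' @param betas numeric vector of member beta-values.
#' @param centroid cluster centroid.
#' @param sigma cluster sample standard deviation.
#' @param ids optional member identifiers (defaults to names of `betas`, then
#'   indices).
#' @return character vector of flagged ids (possibly empty).
#' @export
flag_outliers <- function(betas, centroid, sigma, ids = NULL) {
  ids <- ids %||% names(betas) %||% as.character(seq_along(betas))
  betas <- as.numeric(betas)
  dev <- abs(betas - centroid)
  flagged <- if (sigma > 0) dev >= sigma else dev > 0
  ids[flagged]
}

#' Fit per-function cluster models
#'
#' One model per function label: centroid (mean beta of members), sigma
#' (sample sd; 0 with a warning for singletons), size, chi-squared statistic,
#' and flagged outliers.
#'
#' @param betas named numeric vector of per-sequence beta-values.
#' @param labels character vector of per-sequence function labels, aligned
#'   with `betas`; at least 3 distinct labels.
#' @return object of class `function_clusters`: data frame with columns
#'   `label`, `size`, `centroid`, `sigma`, `chi2`, `chi2_shift`, plus
#'   attributes `members` and `outliers` (named lists).
#' @export
fit_centroids <- function(betas, labels) {
  betas <- stats::setNames(as.numeric(betas), names(betas))
  labels <- as.character(labels)
  if (length(betas) != length(labels)) {
    stop("`betas` and `labels` lengths differ", call. = FALSE)
  }
  ids <- names(betas) %||% as.character(seq_along(betas))
  ulab <- unique(labels)
  if (length(ulab) < 3) {
    stop(
      "only ", length(ulab), " distinct function label(s); the axiom ",
      "min|A| = 3 requires at least 3",
      call. = FALSE
    )
  }
  members <- outliers <- stats::setNames(vector("list", length(ulab)), ulab)
  rows <- lapply(ulab, function(lab) {
    sel <- labels == lab
    b <- betas[sel]
    if (length(b) == 0) stop("empty cluster for label ", lab, call. = FALSE)
    centroid <- mean(b)
    sigma <- if (length(b) < 2) {
      warning("singleton cluster for label '", lab, "': sigma set to 0",
        call. = FALSE
      )
      0
    } else {
      stats::sd(b)
    }
    chi2 <- chi_squared(b, centroid)
    members[[lab]] <<- stats::setNames(b, ids[sel])
    outliers[[lab]] <<- flag_outliers(b, centroid, sigma, ids[sel])
    data.frame(
      label = lab, size = length(b), centroid = centroid, sigma = sigma,
      chi2 = as.numeric(chi2), chi2_shift = attr(chi2, "shift")
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out,
    members = members, outliers = outliers,
    class = c("function_clusters", "data.frame")
  )
}

#' @export
print.function_clusters <- function(x, ...) {
  cat("<function_clusters> ", nrow(x), " function cluster(s)\n", sep = "")
  print.data.frame(x, ...)
  n_out <- sum(lengths(attr(x, "outliers")))
  if (n_out > 0) cat(n_out, "outlier sequence(s) flagged\n")
  invisible(x)
}

#' Unsupervised concordance check via k-means
#'
#' Clusters the beta-values with k-means (ignoring the labels) and reports
#' purity: the fraction of sequences whose cluster's majority label matches
#' their own. A purity near 1 confirms that the labelled structure is
#' recoverable from beta alone.
#'
#' @param betas numeric vector of beta-values.
#' @param labels per-sequence function labels.
#' @param k number of clusters (defaults to the number of distinct labels).
#' @param seed RNG seed for the k-means restarts (default 1234).
#' @param nstart k-means restarts, best inertia kept (default 10).
#' @return purity in \[0, 1\], with the k-means fit attached as attribute
#'   `"kmeans"`.
#' @export
unsupervised_check <- function(betas, labels, k = length(unique(labels)),
                               seed = 1234, nstart = 10) {
  betas <- as.numeric(betas)
  if (k > length(betas)) {
    stop("k = ", k, " exceeds the number of sequences", call. = FALSE)
  }
  n_distinct <- length(unique(betas))
  if (n_distinct <= k) {
    # as many clusters as distinct values (or fewer): k-means cannot place k
    # distinct centers, but the optimal partition is simply by value
    if (n_distinct < k) {
      warning("fewer distinct beta values than clusters; clustering by value",
        call. = FALSE
      )
    }
    assignment <- match(betas, sort(unique(betas)))
    km <- NULL
  } else {
    km <- with_local_seed(seed, {
      stats::kmeans(matrix(betas, ncol = 1), centers = k, nstart = nstart)
    })
    assignment <- km$cluster
  }
  correct <- 0L
  for (cl in unique(assignment)) {
    in_cl <- assignment == cl
    correct <- correct + max(table(labels[in_cl]))
  }
  structure(correct / length(betas), kmeans = km)
}

#' Write a cluster report as TSV
#'
#' @param clusters a `function_clusters` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cluster_report <- function(clusters, path) {
  df <- as.data.frame(clusters)
  out <- attr(clusters, "outliers")
  df$outliers <- vapply(
    df$label,
    function(l) paste(out[[l]], collapse = ","), character(1)
  )
  utils::write.table(df, path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
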