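# Pipeline orchestration: featurize -> cluster -> intervals -> network ->
# validate, with a serializable model bundle and seeded reproducibility.

#' Pipeline configuration
#'
#' Every tunable of the pipeline with its recorded default. The effective
#' config travels inside every fitted bundle and is serialized next to every
#' output, so any result can be reproduced from its files alone.
#'
#' @param strategy POP combiner (`"mean4"`, `"sum4"`, `"geomean4"`).
#' @param alpha significance level for the per-function intervals.
#' @param hidden_rule hidden-size heuristic (`"min"`, `"H1"`, `"H2"`, `"H3"`).
#' @param node_cap hidden-node budget (default 18).
#' @param epochs,lr,tol network training hyperparameters (see [train_ann()]).
#' @param epsilon interval expansion used at mapping time (default 0; may be
#'   `"sigma"`).
#' @param holdout_fraction validation split fraction (default 0.275, the
#'   midpoint of the conventional 25--30% band).
#' @param seed master seed: initializes network weights and derives the
#'   validation-split seed.
#' @param kmeans_seed seed for the unsupervised concordance check.
#' @param strict if `TRUE`, a non-disjoint partition is an error instead of
#'   a warning.
#' @param clamp_negative clamp negative raw scores to 0.
#' @return list of class `hmmann_config`.
#' @export
hmmann_config <- function(strategy = "mean4", alpha = 0.05,
                          hidden_rule = "min", node_cap = 18,
                          epochs = 5000, lr = 0.01, tol = 1e-6,
                          epsilon = 0, holdout_fraction = 0.275,
                          seed = 1, kmeans_seed = 1234,
                          strict = FALSE, clamp_negative = TRUE) {
  structure(
    list(
      strategy = strategy, alpha = alpha, hidden_rule = hidden_rule,
      node_cap = node_cap, epochs = epochs, lr = lr, tol = tol,
      epsilon = epsilon, holdout_fraction = holdout_fraction,
      seed = as.integer(seed), kmeans_seed = as.integer(kmeans_seed),
      strict = strict, clamp_negative = clamp_negative
    ),
    class = "hmmann_config"
  )
}

#' Read a flat key-value YAML config file
#'
#' Unknown keys are rejected; known keys override the defaults of
#' [hmmann_config()].
#'
#' @param path YAML file of scalar key: value pairs.
#' @return an `hmmann_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(hmmann_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  do.call(hmmann_config, vals)
}

#' Fit the full model
#'
#' Runs the training pipeline on a labeled score matrix: POP featurization
#' and standardization, per-sequence beta-values, per-function centroids and
#' chi-squared statistics, confidence intervals and their partition, and the
#' 1:1:1 network trained to regress each training sequence's POP features
#' onto its own function's centroid.
#'
#' @param scores a [score_matrix()] (or coercible matrix).
#' @param labels named character vector of function labels; names must cover
#'   the score matrix's sequence ids (order-free), or an unnamed vector
#'   aligned with the rows.
#' @param config an [hmmann_config()].
#' @return object of class `hmmann_model`: list with `features`
#'   (standardizer), `beta`, `clusters`, `partition`, `ann`, `config`,
#'   `labels`.
#' @export
hmmann_fit <- function(scores, labels, config = hmmann_config()) {
  stopifnot(inherits(config, "hmmann_config"))
  if (!inherits(scores, "score_matrix")) {
    scores <- score_matrix(scores, clamp_negative = config$clamp_negative)
  }
  labels <- align_labels(scores, labels)
  features <- featurize(scores, config$strategy)
  beta <- beta_values(features)
  names(beta) <- scores$sequence_ids
  clusters <- fit_centroids(beta, labels)
  partition <- build_partition(clusters, alpha = config$alpha)
  if (config$strict && !partition$disjoint) {
    stop("non-disjoint interval partition (strict mode)", call. = FALSE)
  }
  targets <- clusters$centroid[match(labels, clusters$label)]
  ann <- build_ann(
    n_inputs = ncol(features$zeta), hidden_rule = config$hidden_rule,
    node_cap = config$node_cap, seed = config$seed
  )
  ann <- train_ann(ann, features$zeta, targets,
    epochs = config$epochs, lr = config$lr, tol = config$tol
  )
  structure(
    list(
      features = features, beta = beta, clusters = clusters,
      partition = partition, ann = ann, config = config, labels = labels,
      function_labels = scores$labels
    ),
    class = "hmmann_model"
  )
}

align_labels <- function(scores, labels) {
  ids <- scores$sequence_ids
  if (!is.null(names(labels))) {
    missing <- setdiff(ids, names(labels))
    if (length(missing) > 0) {
      stop(
        "no label for sequence(s): ", paste(utils::head(missing, 5), collapse = ", "),
        call. = FALSE
      )
    }
    labels <- labels[ids]
  } else if (length(labels) != length(ids)) {
    stop("unnamed `labels` must align with the score matrix rows", call. = FALSE)
  }
  as.character(labels)
}

#' @export
print.hmmann_model <- function(x, ...) {
  cat(
    "<hmmann_model> ", length(x$function_labels), " function(s), ",
    length(x$beta), " training sequence(s); partition ",
    if (x$partition$disjoint) "disjoint" else "NOT disjoint", "\n",
    sep = ""
  )
  invisible(x)
}

#' Predict dominant function for new sequences
#'
#' @param object a fitted `hmmann_model`.
#' @param scores a [score_matrix()] (or matrix) with the same function
#'   columns the model was trained on.
#' @param epsilon interval expansion (defaults to the fitted config's value).
#' @param ... unused.
#' @return data frame with one row per sequence: `sequence_id`,
#'   `beta_dprime`, `label`, `status`, `nearest`, `dist_nearest`.
#' @export
predict.hmmann_model <- function(object, scores, epsilon = NULL, ...) {
  if (!inherits(scores, "score_matrix")) {
    scores <- score_matrix(scores, clamp_negative = object$config$clamp_negative)
  }
  if (!identical(scores$labels, object$function_labels)) {
    extra <- setdiff(scores$labels, object$function_labels)
    miss <- setdiff(object$function_labels, scores$labels)
    stop(
      "query function columns do not match the model's superset",
      if (length(miss)) paste0("; missing: ", paste(miss, collapse = ", ")),
      if (length(extra)) paste0("; unexpected: ", paste(extra, collapse = ", ")),
      call. = FALSE
    )
  }
  epsilon <- epsilon %||% object$config$epsilon
  raw <- pop_raw_matrix(scores, object$features$strategy)
  zeta <- apply_standardizer(raw, object$features)
  bpp <- predict(object$ann, zeta)
  cents <- vapply(object$partition$intervals, `[[`, numeric(1), "centroid")
  maps <- lapply(bpp, map_prediction, partition = object$partition, epsilon = epsilon)
  data.frame(
    sequence_id = scores$sequence_ids,
    beta_dprime = bpp,
    label = vapply(maps, `[[`, character(1), "label"),
    status = vapply(maps, `[[`, character(1), "status"),
    nearest = vapply(maps, `[[`, character(1), "nearest"),
    dist_nearest = vapply(bpp, function(b) min(abs(b - cents)), numeric(1)),
    row.names = NULL
  )
}

resolved_label <- function(pred) {
  ifelse(pred$status == "assigned", pred$label, pred$nearest)
}

prediction_metrics <- function(pred, truth, function_labels) {
  assigned <- pred$label
  resolved <- resolved_label(pred)
  per_fun <- do.call(rbind, lapply(function_labels, function(f) {
    tp <- sum(!is.na(assigned) & assigned == f & truth == f)
    fp <- sum(!is.na(assigned) & assigned == f & truth != f)
    fn <- sum(truth == f & (is.na(assigned) | assigned != f))
    data.frame(
      label = f, n = sum(truth == f),
      precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
      recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_
    )
  }))
  list(
    per_function = per_fun,
    accuracy_assigned = mean(!is.na(assigned) & assigned == truth),
    accuracy_resolved = mean(resolved == truth),
    status_counts = table(factor(pred$status,
      levels = c("assigned", "ambiguous", "unassigned")
    ))
  )
}

#' Validate the pipeline
#'
#' Three modes:
#' \describe{
#'   \item{holdout}{seeded stratified split; fit on the training part,
#'     evaluate on the held-out `fraction` (default 0.275). Intended for
#'     clusters with >= 30 members.}
#'   \item{loocv}{exhaustive leave-one-out: refit once per held-out
#'     sequence. Intended for clusters with < 30 members.}
#'   \item{empirical}{fit on everything, then check per sequence that the
#'     assigned function matches the argmax raw-score column.}
#' }
#' Per-function precision/recall count only strictly assigned labels;
#' `accuracy_resolved` additionally resolves ambiguous/unassigned sequences
#' to the nearest centroid (reported, never silently treated as assigned).
#'
#' @param scores a [score_matrix()] (or matrix).
#' @param labels per-sequence function labels (see [hmmann_fit()]).
#' @param mode `"holdout"`, `"loocv"`, or `"empirical"`.
#' @param fraction holdout fraction in (0, 0.5].
#' @param config an [hmmann_config()].
#' @return list of class `hmmann_validation`: mode, per-function
#'   precision/recall, accuracies, status counts, and for empirical mode the
#'   argmax concordance.
#' @export
hmmann_validate <- function(scores, labels, mode = c("holdout", "loocv", "empirical"),
                            fraction = NULL, config = hmmann_config()) {
  mode <- match.arg(mode)
  if (!inherits(scores, "score_matrix")) {
    scores <- score_matrix(scores, clamp_negative = config$clamp_negative)
  }
  labels <- align_labels(scores, labels)
  fraction <- fraction %||% config$holdout_fraction
  if (mode == "holdout" && (fraction <= 0 || fraction > 0.5)) {
    stop("holdout `fraction` must be in (0, 0.5]", call. = FALSE)
  }
  cl_sizes <- table(labels)
  if (mode == "holdout" && any(cl_sizes < 30)) {
    warning("holdout validation with cluster(s) smaller than 30; ",
      "leave-one-out is intended for small clusters",
      call. = FALSE
    )
  }
  if (mode == "loocv" && any(cl_sizes >= 30)) {
    warning("leave-one-out with cluster(s) of 30+ members; ",
      "a holdout split is intended for large clusters",
      call. = FALSE
    )
  }
  v <- as_score_values(scores)
  out <- switch(mode,
    holdout = {
      test_idx <- with_local_seed(config$seed + 1L, {
        unlist(lapply(split(seq_along(labels), labels), function(idx) {
          n_test <- max(1L, round(length(idx) * fraction))
          sample(idx, n_test)
        }), use.names = FALSE)
      })
      train_idx <- setdiff(seq_along(labels), test_idx)
      fit <- hmmann_fit(
        score_matrix(v[train_idx, , drop = FALSE]),
        labels[train_idx], config
      )
      pred <- predict(fit, score_matrix(v[test_idx, , drop = FALSE]))
      res <- prediction_metrics(pred, labels[test_idx], fit$clusters$label)
      c(list(mode = mode, n_test = length(test_idx), predictions = pred), res)
    },
    loocv = {
      preds <- lapply(seq_along(labels), function(i) {
        fit <- hmmann_fit(
          score_matrix(v[-i, , drop = FALSE]), labels[-i], config
        )
        predict(fit, score_matrix(v[i, , drop = FALSE]))
      })
      pred <- do.call(rbind, preds)
      res <- prediction_metrics(pred, labels, sort(unique(labels)))
      c(list(mode = mode, n_test = length(labels), predictions = pred), res)
    },
    empirical = {
      fit <- hmmann_fit(scores, labels, config)
      pred <- predict(fit, scores)
      argmax <- scores$labels[max.col(v, ties.method = "first")]
      concordant <- !is.na(pred$label) & pred$label == argmax
      res <- prediction_metrics(pred, labels, fit$clusters$label)
      c(
        list(
          mode = mode, n_test = length(labels), predictions = pred,
          argmax_label = argmax, concordance = mean(concordant)
        ),
        res
      )
    }
  )
  structure(out, class = "hmmann_validation")
}

#' @export
print.hmmann_validation <- function(x, ...) {
  cat(
    "<hmmann_validation> mode = ", x$mode, ", n = ", x$n_test,
    sprintf(
      "; accuracy (assigned) = %.3f, (resolved) = %.3f\n",
      x$accuracy_assigned, x$accuracy_resolved
    ),
    sep = ""
  )
  print(x$per_function)
  if (!is.null(x$concordance)) {
    cat(sprintf("argmax-score concordance = %.3f\n", x$concordance))
  }
  invisible(x)
}

#' Write a validation report as TSV
#'
#' @param report an `hmmann_validation`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(report, path) {
  df <- report$per_function
  df$mode <- report$mode
  df$accuracy_assigned <- report$accuracy_assigned
  df$accuracy_resolved <- report$accuracy_resolved
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# --- model bundle serialization ---------------------------------------------

#' Serialize a fitted model to JSON
#'
#' The payload carries everything needed to reproduce predictions:
#' standardizer (centers, scales, constant flags, combiner), cluster table,
#' partition, network weights and training record, and the effective config.
#' No timestamps are written, so refitting with the same config and data
#' yields byte-identical files.
#'
#' @param model an `hmmann_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hmmann <- function(model, path) {
  ann <- model$ann
  payload <- list(
    format = "hmmann-model-1",
    config = unclass(model$config),
    function_labels = model$function_labels,
    standardizer = list(
      center = unname(model$features$center),
      scale = unname(model$features$scale),
      constant = unname(model$features$constant),
      strategy = model$features$strategy
    ),
    beta = as.list(model$beta),
    clusters = as.data.frame(model$clusters),
    partition = list(
      intervals = lapply(model$partition$intervals, function(iv) iv[c(
        "label", "low", "high", "centroid", "sigma", "size", "coefficient", "kind"
      )]),
      a = model$partition$a, b = model$partition$b,
      measure = model$partition$measure, tau = model$partition$tau,
      disjoint = model$partition$disjoint, alpha = model$partition$alpha
    ),
    ann = list(
      n_inputs = ann$n_inputs, n_hidden = ann$n_hidden,
      superset_size = ann$superset_size, hidden_rule = ann$hidden_rule,
      node_cap = ann$node_cap, activation = ann$activation,
      output = ann$output,
      w1 = ann$w1, b1 = ann$b1, w2 = ann$w2, b2 = ann$b2,
      y_center = ann$y_center, y_scale = ann$y_scale,
      init_seed = ann$init_seed, training = ann$training
    ),
    labels = as.list(stats::setNames(model$labels, names(model$beta)))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a serialized model
#'
#' @param path a JSON file written by [write_hmmann()].
#' @return an `hmmann_model` (sufficient for prediction and inspection).
#' @export
read_hmmann <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "hmmann-model-1")) {
    stop("not an hmmann model file: ", path, call. = FALSE)
  }
  features <- structure(
    list(
      zeta = NULL,
      center = p$standardizer$center, scale = p$standardizer$scale,
      constant = p$standardizer$constant, strategy = p$standardizer$strategy
    ),
    class = "pop_features"
  )
  intervals <- lapply(seq_len(nrow(p$partition$intervals)), function(i) {
    structure(as.list(p$partition$intervals[i, ]), class = "function_interval")
  })
  partition <- structure(
    list(
      intervals = intervals, a = p$partition$a, b = p$partition$b,
      measure = p$partition$measure, tau = p$partition$tau,
      disjoint = p$partition$disjoint, alpha = p$partition$alpha
    ),
    class = "interval_partition"
  )
  ann <- structure(
    list(
      n_inputs = p$ann$n_inputs, n_hidden = p$ann$n_hidden,
      superset_size = p$ann$superset_size, hidden_rule = p$ann$hidden_rule,
      node_cap = p$ann$node_cap, activation = p$ann$activation,
      output = p$ann$output,
      w1 = matrix(unlist(p$ann$w1), nrow = p$ann$n_inputs),
      b1 = as.numeric(p$ann$b1),
      w2 = as.numeric(p$ann$w2), b2 = as.numeric(p$ann$b2),
      y_center = p$ann$y_center, y_scale = p$ann$y_scale,
      init_seed = p$ann$init_seed, trained = TRUE, training = p$ann$training
    ),
    class = "hmm_ann"
  )
  clusters <- structure(p$clusters, class = c("function_clusters", "data.frame"))
  structure(
    list(
      features = features, beta = unlist(p$beta), clusters = clusters,
      partition = partition, ann = ann,
      config = do.call(hmmann_config, p$config),
      labels = unlist(p$labels), function_labels = p$function_labels
    ),
    class = "hmmann_model"
  )
}
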