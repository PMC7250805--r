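# Single-output feed-forward network.
#
# Architecture is strictly 1:1:1 — one input layer (|D| POP features), one
# hidden layer, one linear output unit producing the scalar beta''. The
# hidden size comes from the H1/H2/H3 heuristics capped at a practical node
# budget (default 18). Training is full-batch back-propagation on the mean
# squared error with tanh hidden units and an identity output, using
# resilient propagation (iRprop-): per-weight step sizes grown 1.2x while a
# gradient keeps its sign and halved when it flips. Targets are
# standardized internally for conditioning and predictions are returned on
# the original scale. Everything is seeded and full-batch, so a fixed
# configuration and dataset reproduce identical weights.

infer_superset_size <- function(n_inputs) {
  n <- 3L
  repeat {
    d <- pop_count(n)
    if (d == n_inputs) return(n)
    if (d > n_inputs) {
      stop(
        "n_inputs = ", n_inputs, " is not pop_count(n) for any superset ",
        "size n >= 3",
        call. = FALSE
      )
    }
    n <- n + 1L
  }
}

#' Build an untrained 1:1:1 network
#'
#' @param n_inputs input dimensionality; must equal `pop_count(n)` for some
#'   superset size `n >= 3`.
#' @param hidden_rule heuristic choosing the hidden size from
#'   [hidden_nodes()]: `"H1"`, `"H2"`, `"H3"`, or `"min"` (smallest of the
#'   three; default).
#' @param node_cap upper bound on hidden nodes (default 18, the practical
#'   budget for this architecture).
#' @param seed RNG seed for weight initialization.
#' @return object of class `hmm_ann`: weight matrices `w1` (inputs x hidden),
#'   `b1`, `w2` (hidden), `b2`, plus architecture and training metadata.
#' @export
build_ann <- function(n_inputs, hidden_rule = c("min", "H1", "H2", "H3"),
                      node_cap = 18, seed = 1) {
  hidden_rule <- match.arg(hidden_rule)
  if (node_cap < 1) stop("`node_cap` must be >= 1", call. = FALSE)
  n <- infer_superset_size(n_inputs)
  h_all <- hidden_nodes(n_inputs)
  h_rule <- switch(hidden_rule,
    min = min(h_all),
    H1 = h_all[["h1"]], H2 = h_all[["h2"]], H3 = h_all[["h3"]]
  )
  n_hidden <- max(1L, min(h_rule, as.integer(node_cap)))
  # Small uniform init keeps tanh units in their near-linear regime at the
  # start, which matters for fitting nearly linear teachers.
  weights <- with_local_seed(seed, {
    list(
      w1 = matrix(
        stats::runif(n_inputs * n_hidden, -0.5, 0.5) / sqrt(n_inputs),
        nrow = n_inputs
      ),
      b1 = rep(0, n_hidden),
      w2 = stats::runif(n_hidden, -0.5, 0.5) / sqrt(n_hidden),
      b2 = 0
    )
  })
  structure(
    list(
      n_inputs = n_inputs, n_hidden = n_hidden, superset_size = n,
      hidden_rule = hidden_rule, node_cap = node_cap,
      activation = "tanh", output = "identity",
      w1 = weights$w1, b1 = weights$b1, w2 = weights$w2, b2 = weights$b2,
      y_center = 0, y_scale = 1,
      init_seed = seed, trained = FALSE, training = NULL
    ),
    class = "hmm_ann"
  )
}

#' @export
print.hmm_ann <- function(x, ...) {
  cat(
    "<hmm_ann> 1:1:1 network ", x$n_inputs, " -> ", x$n_hidden, " -> 1",
    " (rule ", x$hidden_rule, ", cap ", x$node_cap, "); ",
    if (x$trained) {
      paste0(
        "trained, final loss ", format(x$training$final_loss, digits = 4),
        " in ", x$training$epochs_run, " epoch(s)"
      )
    } else {
      "untrained"
    },
    "\n",
    sep = ""
  )
  invisible(x)
}

ann_forward <- function(model, zeta) {
  hidden <- tanh(sweep(zeta %*% model$w1, 2, model$b1, "+"))
  raw <- drop(hidden %*% model$w2 + model$b2)
  list(hidden = hidden, output = raw * model$y_scale + model$y_center)
}

#' Train the network by resilient back-propagation
#'
#' Full-batch training on the mean squared error between the network output
#' and the per-sequence target (in the pipeline, each training sequence's
#' target is its own function's centroid, so the net learns the map from POP
#' features to the cluster centroid line). The optimizer is iRprop-: each
#' weight keeps its own step size, grown by 1.2 while its gradient keeps
#' sign and halved when the sign flips (the flipped step is skipped). The
#' best weights seen are retained. Training stops early when the best loss
#' (standardized-target scale) has not improved by a relative `tol` for 25
#' consecutive epochs, or after `epochs` epochs. Deterministic: full batch,
#' no shuffling.
#'
#' @param model an `hmm_ann` from [build_ann()].
#' @param zeta numeric matrix of standardized POP features, rows aligned
#'   with `targets`.
#' @param targets numeric vector of per-sequence regression targets.
#' @param epochs maximum epochs (default 5000).
#' @param lr initial per-weight step size (default 0.01).
#' @param tol early-stopping relative tolerance on the loss (default 1e-6).
#' @return the trained `hmm_ann`, with `$training` holding the seed, epoch
#'   count and loss trace.
#' @export
train_ann <- function(model, zeta, targets, epochs = 5000, lr = 0.01,
                      tol = 1e-6) {
  stopifnot(inherits(model, "hmm_ann"))
  zeta <- as.matrix(zeta)
  targets <- as.numeric(targets)
  if (nrow(zeta) != length(targets)) {
    stop("rows of `zeta` do not align with `targets`", call. = FALSE)
  }
  if (ncol(zeta) != model$n_inputs) {
    stop(
      "feature width ", ncol(zeta), " does not match network input size ",
      model$n_inputs,
      call. = FALSE
    )
  }
  m <- nrow(zeta)
  y_center <- mean(targets)
  y_scale <- stats::sd(targets)
  if (!is.finite(y_scale) || y_scale == 0) y_scale <- 1
  y <- (targets - y_center) / y_scale

  d <- model$n_inputs
  h <- model$n_hidden
  n_w1 <- d * h
  # flat parameter vector: w1 (column-major), b1, w2, b2
  par <- c(model$w1, model$b1, model$w2, model$b2)
  i_w1 <- seq_len(n_w1)
  i_b1 <- n_w1 + seq_len(h)
  i_w2 <- n_w1 + h + seq_len(h)
  i_b2 <- n_w1 + 2L * h + 1L

  eval_net <- function(par) {
    w1 <- matrix(par[i_w1], nrow = d)
    b1 <- par[i_b1]
    w2 <- par[i_w2]
    b2 <- par[i_b2]
    hid <- tanh(sweep(zeta %*% w1, 2, b1, "+"))
    resid <- drop(hid %*% w2 + b2) - y
    g_out <- 2 * resid / m
    g_hid <- outer(g_out, w2) * (1 - hid^2)
    list(
      loss = mean(resid^2),
      grad = c(
        crossprod(zeta, g_hid), colSums(g_hid),
        drop(crossprod(hid, g_out)), sum(g_out)
      )
    )
  }

  step <- rep(lr, length(par))
  g_prev <- rep(0, length(par))
  cur <- eval_net(par)
  best_par <- par
  best_loss <- cur$loss
  trace <- numeric(0)
  patience <- 0L
  epochs_run <- 0L
  for (ep in seq_len(epochs)) {
    g <- cur$grad
    same <- sign(g) * sign(g_prev)
    step[same > 0] <- pmin(step[same > 0] * 1.2, 50)
    step[same < 0] <- pmax(step[same < 0] * 0.5, 1e-9)
    g[same < 0] <- 0 # iRprop-: skip the step whose gradient flipped
    par <- par - sign(g) * step
    g_prev <- g
    cur <- eval_net(par)
    epochs_run <- ep
    if (!is.finite(cur$loss)) {
      stop(
        "training diverged (non-finite loss); lower the initial step size ",
        "(current lr = ", lr, ")",
        call. = FALSE
      )
    }
    if (ep %% 25 == 0) trace <- c(trace, cur$loss)
    if (cur$loss < best_loss * (1 - tol)) {
      best_loss <- cur$loss
      best_par <- par
      patience <- 0L
    } else {
      if (cur$loss < best_loss) {
        best_loss <- cur$loss
        best_par <- par
      }
      patience <- patience + 1L
      if (patience >= 25L) break
    }
  }

  model$w1 <- matrix(best_par[i_w1], nrow = d)
  model$b1 <- best_par[i_b1]
  model$w2 <- best_par[i_w2]
  model$b2 <- best_par[i_b2]
  model$y_center <- y_center
  model$y_scale <- y_scale
  model$trained <- TRUE
  model$training <- list(
    seed = model$init_seed, epochs = epochs, epochs_run = epochs_run,
    lr = lr, tol = tol, optimizer = "irprop-",
    final_loss = best_loss, loss_trace = trace
  )
  model
}

#' Predict beta'' for new feature rows
#'
#' Deterministic forward pass: tanh hidden layer, identity output,
#' destandardized to the target scale.
#'
#' @param object a trained `hmm_ann`.
#' @param zeta numeric matrix (or single row) of standardized POP features.
#' @param ... unused.
#' @return numeric vector of beta'' values.
#' @export
predict.hmm_ann <- function(object, zeta, ...) {
  if (is.null(dim(zeta))) zeta <- matrix(zeta, nrow = 1)
  zeta <- as.matrix(zeta)
  if (ncol(zeta) != object$n_inputs) {
    stop(
      "feature width ", ncol(zeta), " does not match network input size ",
      object$n_inputs,
      call. = FALSE
    )
  }
  ann_forward(object, zeta)$output
}
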