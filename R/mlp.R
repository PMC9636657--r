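# Single-hidden-layer perceptron surrogate trained by full-batch error
# backpropagation with an L2 (Bayesian-style weight decay) penalty. The
# update is a resilient (sign-based, per-weight adaptive step) variant of
# backpropagation with an acceptance rule: a proposed epoch is kept only if
# the penalized loss does not increase, otherwise all steps shrink and the
# weights stay put. The recorded loss history is therefore monotone
# non-increasing by construction and runs are bit-reproducible given a seed.

#' MLP surrogate configuration
#'
#' @param hidden_units Neurons in the hidden layer (default 11).
#' @param activation Hidden-layer activation, `"tanh"` or `"logistic"`.
#' @param out_activation Output-unit activation. `"auto"` (default) uses a
#'   logistic output for the percentage target — an induction fraction is
#'   bounded, and the saturating output models its 0/1 plateaus smoothly
#'   instead of relying on hard clipping — and a linear output for speed.
#' @param max_epochs Maximum full-batch epochs.
#' @param l2_alpha L2 weight-decay coefficient (>= 0) applied to connection
#'   weights (not biases); the deterministic core of Bayesian-regularized
#'   backpropagation.
#' @param step_init Initial per-weight step size of the resilient update.
#' @param step_max Upper cap on per-weight step sizes.
#' @param seed Integer seed for the weight initialization.
#' @param train_fraction Fraction of rows used for training in a split
#'   (default 0.9).
#' @return A `callus_mlp_config` list.
#' @export
mlp_config <- function(hidden_units = 11L, activation = c("tanh", "logistic"),
                       out_activation = c("auto", "linear", "logistic"),
                       max_epochs = 4000L, l2_alpha = 3e-4,
                       step_init = 0.01, step_max = 1,
                       seed = 1L, train_fraction = 0.9) {
  activation <- match.arg(activation)
  out_activation <- match.arg(out_activation)
  if (hidden_units < 1) stop("hidden_units must be >= 1")
  if (l2_alpha < 0) stop("l2_alpha must be non-negative")
  if (step_init <= 0 || step_max < step_init) {
    stop("need 0 < step_init <= step_max")
  }
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must lie strictly between 0 and 1")
  }
  structure(
    list(hidden_units = as.integer(hidden_units), activation = activation,
         out_activation = out_activation,
         max_epochs = as.integer(max_epochs), l2_alpha = l2_alpha,
         step_init = step_init, step_max = step_max,
         seed = as.integer(seed), train_fraction = train_fraction),
    class = "callus_mlp_config"
  )
}

#' Seeded train/test split of condition summaries
#'
#' Disjoint, exhaustive partition with `round(n * fraction)` training rows,
#' drawn by a seeded shuffle.
#'
#' @param summaries Condition-summary data frame.
#' @param fraction Training fraction in (0, 1); default 0.9.
#' @param seed Integer seed.
#' @return List with elements `train` and `test`.
#' @export
split_train_test <- function(summaries, fraction = 0.9, seed = 1L) {
  if (fraction <= 0 || fraction >= 1) {
    stop("fraction must lie strictly between 0 and 1")
  }
  n <- nrow(summaries)
  n_train <- round(n * fraction)
  set.seed(seed)
  idx <- sample.int(n)
  list(train = summaries[sort(idx[seq_len(n_train)]), , drop = FALSE],
       test = summaries[sort(idx[-seq_len(n_train)]), , drop = FALSE])
}

# --- internal helpers shared with the RBF module ---------------------------

.target_column <- function(target = c("percentage", "speed")) {
  switch(match.arg(target), percentage = "induction_pct", speed = "speed")
}

.summaries_to_xy <- function(summaries, target, extra_features = NULL) {
  x <- encode_conditions(summaries)
  if (!is.null(extra_features)) {
    extra_features <- as.matrix(extra_features)
    if (nrow(extra_features) != nrow(x)) {
      stop("extra_features must have one row per summary")
    }
    if (is.null(colnames(extra_features))) {
      colnames(extra_features) <- paste0("extra_", seq_len(ncol(extra_features)))
    }
    x <- cbind(x, extra_features)
  }
  y <- summaries[[.target_column(target)]]
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("features and targets must be finite")
  }
  list(x = x, y = y)
}

.fit_scaler <- function(m) {
  lo <- apply(m, 2, min)
  hi <- apply(m, 2, max)
  span <- hi - lo
  span[span == 0] <- 1 # constant columns pass through unchanged
  list(lo = lo, span = span)
}

.apply_scaler <- function(m, sc) sweep(sweep(m, 2, sc$lo), 2, sc$span, "/")

.drop_features <- function(x, drop_features) {
  if (is.null(drop_features)) return(x)
  unknown <- setdiff(drop_features, colnames(x))
  if (length(unknown) > 0) {
    stop("unknown feature column(s): ", paste(unknown, collapse = ", "))
  }
  keep <- setdiff(colnames(x), drop_features)
  if (length(keep) == 0) stop("cannot drop every feature column")
  x[, keep, drop = FALSE]
}

# accept either the model's reduced layout or the full 10-column layout
.align_features <- function(x, feature_names) {
  if (ncol(x) == length(feature_names)) return(x)
  if (!is.null(colnames(x)) && all(feature_names %in% colnames(x))) {
    return(x[, feature_names, drop = FALSE])
  }
  stop("newdata must have ", length(feature_names),
       " feature columns (or named columns covering them)")
}

.activation_fns <- function(activation) {
  if (activation == "tanh") {
    list(f = tanh, df = function(a) 1 - a^2)
  } else {
    list(f = stats::plogis, df = function(a) a * (1 - a))
  }
}

#' Train an MLP surrogate
#'
#' Fits a 10-input, single-hidden-layer, linear-output perceptron to one
#' target (`"percentage"` or `"speed"`) of a condition-summary table. Inputs
#' and target are min-max scaled to \[0, 1\] internally and unscaled for
#' prediction; percentages are additionally clipped to \[0, 100\] at the
#' prediction interface. The penalized loss is
#' `mean((y - yhat)^2) + l2_alpha * sum(w^2)` over connection weights.
#'
#' @param train Condition-summary data frame (training rows).
#' @param target `"percentage"` or `"speed"`.
#' @param cfg An [mlp_config()].
#' @param drop_features Optional character vector of feature columns to
#'   withhold from the model (used by the leave-one-variable-out sensitivity
#'   analysis). Predictions on full 10-column inputs subset automatically.
#' @param extra_features Optional named matrix of additional feature columns,
#'   one row per training row, appended to the standard encoding.
#' @return A `callus_mlp` model with weights, scalers and the accepted-epoch
#'   loss history.
#' @export
train_mlp <- function(train, target = c("percentage", "speed"),
                      cfg = mlp_config(), drop_features = NULL,
                      extra_features = NULL) {
  target <- match.arg(target)
  if (!inherits(cfg, "callus_mlp_config")) cfg <- do.call(mlp_config, cfg)
  d <- .summaries_to_xy(train, target, extra_features)
  d$x <- .drop_features(d$x, drop_features)
  out_act <- cfg$out_activation
  if (out_act == "auto") {
    out_act <- if (target == "percentage") "logistic" else "linear"
  }
  xsc <- .fit_scaler(d$x)
  # percentages live on a fixed 0-100 scale; other targets are min-max scaled
  ysc <- if (target == "percentage") {
    list(lo = 0, span = 100)
  } else {
    .fit_scaler(matrix(d$y, ncol = 1))
  }
  x <- .apply_scaler(d$x, xsc)
  y <- (d$y - ysc$lo) / ysc$span

  n <- nrow(x); h <- cfg$hidden_units
  act <- .activation_fns(cfg$activation)
  out_f <- if (out_act == "logistic") stats::plogis else identity
  set.seed(cfg$seed)
  w1 <- matrix(stats::runif((ncol(x) + 1) * h, -0.7, 0.7), ncol(x) + 1, h)
  w2 <- matrix(stats::runif(h + 1, -0.7, 0.7), h + 1, 1)

  xb <- cbind(1, x)
  loss_fn <- function(w1, w2) {
    a <- act$f(xb %*% w1)
    yhat <- out_f(as.vector(cbind(1, a) %*% w2))
    mean((y - yhat)^2) +
      cfg$l2_alpha * (sum(w1[-1, ]^2) + sum(w2[-1, ]^2))
  }

  e1 <- w1 * 0 + cfg$step_init
  e2 <- w2 * 0 + cfg$step_init
  g1_prev <- w1 * 0; g2_prev <- w2 * 0
  history <- numeric(cfg$max_epochs)
  loss <- loss_fn(w1, w2)
  if (!is.finite(loss)) stop("training diverged (non-finite initial loss)")
  for (epoch in seq_len(cfg$max_epochs)) {
    a <- act$f(xb %*% w1)
    ab <- cbind(1, a)
    z <- as.vector(ab %*% w2)
    yhat <- out_f(z)
    dz <- 2 * (yhat - y) / n
    if (out_act == "logistic") dz <- dz * yhat * (1 - yhat)
    g2 <- crossprod(ab, dz)
    g2[-1, ] <- g2[-1, ] + 2 * cfg$l2_alpha * w2[-1, ]
    delta <- dz %o% as.vector(w2[-1, ]) * act$df(a)
    g1 <- crossprod(xb, delta)
    g1[-1, ] <- g1[-1, ] + 2 * cfg$l2_alpha * w1[-1, ]
    if (any(!is.finite(g1)) || any(!is.finite(g2))) {
      stop("training diverged (non-finite gradient at epoch ", epoch, ")")
    }

    c1 <- w1 - sign(g1) * e1
    c2 <- w2 - sign(g2) * e2
    cand <- loss_fn(c1, c2)
    if (!is.finite(cand)) {
      stop("training diverged (non-finite loss at epoch ", epoch, ")")
    }
    if (cand <= loss) {
      # grow steps where the gradient sign persisted, shrink where it flipped
      s1 <- sign(g1) * sign(g1_prev)
      s2 <- sign(g2) * sign(g2_prev)
      e1 <- pmin(pmax(e1 * ifelse(s1 > 0, 1.2, ifelse(s1 < 0, 0.5, 1)),
                      1e-10), cfg$step_max)
      e2 <- pmin(pmax(e2 * ifelse(s2 > 0, 1.2, ifelse(s2 < 0, 0.5, 1)),
                      1e-10), cfg$step_max)
      w1 <- c1; w2 <- c2
      loss <- cand
      g1_prev <- g1; g2_prev <- g2
    } else {
      e1 <- e1 * 0.5; e2 <- e2 * 0.5 # rejected: shrink all steps, stay put
      g1_prev <- g1_prev * 0; g2_prev <- g2_prev * 0
      if (max(e1, e2) < 1e-12) {
        history[epoch:cfg$max_epochs] <- loss
        break
      }
    }
    history[epoch] <- loss
  }

  structure(
    list(w1 = w1, w2 = w2, x_scaler = xsc, y_scaler = ysc,
         feature_names = colnames(d$x),
         activation = cfg$activation, out_activation = out_act,
         target = target, cfg = cfg,
         history = history, final_loss = loss),
    class = "callus_mlp"
  )
}

#' Predict from an MLP surrogate
#'
#' @param object A `callus_mlp` model.
#' @param newdata Feature matrix in the 10-column layout of
#'   [encode_conditions()], or a condition data frame.
#' @param ... Unused.
#' @return Numeric predictions on the original target scale; percentages are
#'   clipped to \[0, 100\].
#' @export
predict.callus_mlp <- function(object, newdata, ...) {
  x <- if (is.data.frame(newdata)) encode_conditions(newdata) else {
    if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
    newdata
  }
  x <- .align_features(x, object$feature_names)
  act <- .activation_fns(object$activation)
  xs <- .apply_scaler(x, object$x_scaler)
  a <- act$f(cbind(1, xs) %*% object$w1)
  ys <- as.vector(cbind(1, a) %*% object$w2)
  if (identical(object$out_activation, "logistic")) ys <- stats::plogis(ys)
  y <- ys * object$y_scaler$span + object$y_scaler$lo
  if (object$target == "percentage") y <- pmin(100, pmax(0, y))
  as.numeric(y)
}
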