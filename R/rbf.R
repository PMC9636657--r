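# Gaussian radial basis function network. Centers default to the training
# points; output weights solve a ridge-regularized linear least-squares
# problem on the kernel design matrix (bias unpenalized). The spread h is
# either given or chosen by leave-one-out error over a logarithmic grid.

#' Gaussian RBF transfer function
#'
#' `exp(-(||x_r - x_b|| * 0.8326 / h)^2)` with the Euclidean norm. The 0.8326
#' factor (numerically close to sqrt(ln 2)) makes `h` the half-response
#' distance: the kernel equals 1 exactly when the points coincide and about
#' 0.5 at distance `h`.
#'
#' @param x_r,x_b Numeric vectors of equal length.
#' @param h Spread, > 0 (same units as the scaled feature distance).
#' @return Kernel value in (0, 1].
#' @export
#' @examples
#' gaussian_kernel(c(0, 0), c(0, 0), h = 1) # 1
#' gaussian_kernel(0, 1, h = 1)             # ~0.5
gaussian_kernel <- function(x_r, x_b, h) {
  if (h <= 0) stop("spread h must be positive")
  if (length(x_r) != length(x_b)) stop("vectors must have equal length")
  d <- sqrt(sum((x_r - x_b)^2))
  exp(-(d * 0.8326 / h)^2)
}

# all-pairs kernel matrix between row sets (vectorized)
.kernel_matrix <- function(a, b, h) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  exp(-d2 * (0.8326 / h)^2)
}

#' RBF surrogate configuration
#'
#' @param h Spread; `NULL` selects it by leave-one-out error over
#'   `h_grid`.
#' @param h_grid Candidate spreads for the leave-one-out search (on min-max
#'   scaled features, so values are dimensionless).
#' @param metric_weights Per-block multipliers applied to the scaled feature
#'   columns before computing Euclidean distances, as a named vector with
#'   entries `pgr`, `ms`, `day`, `explant`. `NULL` (default) selects them
#'   jointly with `h` by leave-one-out error over a small factorial grid —
#'   the blocks of this mixed categorical/numeric space have no common
#'   natural length scale, so the metric is calibrated on the training data.
#' @param centers `"all_training_points"` (default; matches the model's
#'   indexing of observed inputs) or `"kmeans_subset"`.
#' @param n_centers Number of centers when `centers = "kmeans_subset"`.
#' @param ridge_lambda Ridge penalty on the kernel weights (>= 0; the bias is
#'   never penalized). `0` requests exact interpolation and fails with advice
#'   if the system is singular.
#' @param seed Seed (used only for k-means center selection).
#' @return A `callus_rbf_config` list.
#' @export
rbf_config <- function(h = NULL, h_grid = seq(0.3, 3, by = 0.3),
                       metric_weights = NULL,
                       centers = c("all_training_points", "kmeans_subset"),
                       n_centers = 24L, ridge_lambda = 1e-6, seed = 1L) {
  centers <- match.arg(centers)
  if (!is.null(h) && h <= 0) stop("spread h must be positive")
  if (ridge_lambda < 0) stop("ridge_lambda must be non-negative")
  if (!is.null(metric_weights)) {
    if (!all(c("pgr", "ms", "day", "explant") %in% names(metric_weights))) {
      stop("metric_weights needs entries pgr, ms, day, explant")
    }
    if (any(metric_weights <= 0)) stop("metric_weights must be positive")
  }
  structure(
    list(h = h, h_grid = h_grid, metric_weights = metric_weights,
         centers = centers,
         n_centers = as.integer(n_centers), ridge_lambda = ridge_lambda,
         seed = as.integer(seed)),
    class = "callus_rbf_config"
  )
}

# column multipliers implied by per-block metric weights, for the columns
# actually present (sensitivity retraining drops blocks)
.metric_multipliers <- function(feature_names, w) {
  block <- ifelse(grepl("^conc_", feature_names), "pgr",
           ifelse(feature_names == "ms_level", "ms",
           ifelse(feature_names == "sampling_day", "day",
           ifelse(grepl("^explant_", feature_names), "explant", "extra"))))
  out <- rep(1, length(feature_names))
  hit <- block %in% names(w)
  out[hit] <- as.numeric(w[block[hit]])
  out
}

.metric_weight_grid <- function() {
  expand.grid(pgr = c(1, 2, 4), ms = 1, day = c(0.5, 1),
              explant = c(0.35, 0.7, 1), KEEP.OUT.ATTRS = FALSE)
}

# ridge solve of [1 K] beta ~= y with unpenalized bias; lambda = 0 falls back
# to a pivoted QR least-squares solution
.rbf_solve <- function(K, y, lambda) {
  A <- cbind(1, K)
  if (lambda == 0) {
    qr_a <- qr(A)
    beta <- qr.coef(qr_a, y)
    beta[is.na(beta)] <- 0
    fitted <- as.vector(A %*% beta)
    if (max(abs(fitted - y)) > 1e-6 * max(1, max(abs(y)))) {
      stop("kernel system is singular with ridge_lambda = 0 and cannot ",
           "interpolate the targets; use ridge_lambda > 0")
    }
  } else {
    p <- ncol(A)
    pen <- diag(c(0, rep(lambda, p - 1)))
    beta <- solve(crossprod(A) + pen, crossprod(A, y))
  }
  as.vector(beta)
}

.rbf_loo_rmse <- function(x, y, h, lambda) {
  A <- cbind(1, .kernel_matrix(x, x, h))
  p <- ncol(A)
  M <- crossprod(A) + diag(c(0, rep(max(lambda, 1e-8), p - 1)))
  Minv <- tryCatch(solve(M), error = function(e) NULL)
  if (is.null(Minv)) return(Inf)
  H <- A %*% Minv %*% t(A)
  res <- y - as.vector(H %*% y)
  denom <- pmax(1 - diag(H), 1e-8)
  sqrt(mean((res / denom)^2))
}

#' Fit an RBF network surrogate
#'
#' Scales features to \[0, 1\] (so the spread is dimensionless and the explant
#' indicators do not dominate the Euclidean distance), places Gaussian kernels
#' on the centers, and solves the regularized least-squares problem
#' `y ~ w0 + sum_b w_b * f(x, x_b)` for the output weights.
#'
#' @param train Condition-summary data frame.
#' @param target `"percentage"` or `"speed"`.
#' @param cfg An [rbf_config()].
#' @param drop_features Optional feature columns to withhold (see
#'   [train_mlp()]).
#' @param extra_features Optional named matrix of additional feature columns
#'   appended to the standard encoding (see [train_mlp()]).
#' @return A `callus_rbf` model.
#' @export
fit_rbf <- function(train, target = c("percentage", "speed"),
                    cfg = rbf_config(), drop_features = NULL,
                    extra_features = NULL) {
  target <- match.arg(target)
  if (!inherits(cfg, "callus_rbf_config")) cfg <- do.call(rbf_config, cfg)
  d <- .summaries_to_xy(train, target, extra_features)
  d$x <- .drop_features(d$x, drop_features)
  xsc <- .fit_scaler(d$x)
  x <- .apply_scaler(d$x, xsc)
  y <- d$y

  # resolve metric weights and spread, by LOO error where unspecified
  h <- cfg$h
  mw <- cfg$metric_weights
  if (is.null(mw)) {
    if (!is.null(h)) {
      mw <- c(pgr = 1, ms = 1, day = 1, explant = 1)
    } else {
      wg <- .metric_weight_grid()
      best <- c(loo = Inf, row = 1L, h = cfg$h_grid[1])
      for (r in seq_len(nrow(wg))) {
        mult <- .metric_multipliers(colnames(d$x), unlist(wg[r, ]))
        xw <- sweep(x, 2, mult, "*")
        for (hh in cfg$h_grid) {
          loo <- .rbf_loo_rmse(xw, y, hh, cfg$ridge_lambda)
          if (loo < best["loo"]) best <- c(loo = loo, row = r, h = hh)
        }
      }
      mw <- unlist(wg[best[["row"]], ])
      h <- best[["h"]]
    }
  }
  mult <- .metric_multipliers(colnames(d$x), mw)
  x <- sweep(x, 2, mult, "*")
  if (is.null(h)) {
    loo <- vapply(cfg$h_grid, function(hh) {
      .rbf_loo_rmse(x, y, hh, cfg$ridge_lambda)
    }, numeric(1))
    h <- cfg$h_grid[which.min(loo)]
  }

  centers <- if (cfg$centers == "all_training_points") {
    x
  } else {
    if (cfg$n_centers > nrow(x)) stop("n_centers exceeds training size")
    set.seed(cfg$seed)
    km <- stats::kmeans(x, centers = cfg$n_centers, nstart = 5)
    km$centers
  }

  K <- .kernel_matrix(x, centers, h)
  beta <- .rbf_solve(K, y, cfg$ridge_lambda)

  structure(
    list(w0 = beta[1], w = beta[-1], centers = centers, h = h,
         metric_weights = mw, metric_multipliers = mult,
         x_scaler = xsc, feature_names = colnames(d$x),
         target = target, cfg = cfg),
    class = "callus_rbf"
  )
}

#' Predict from an RBF surrogate
#'
#' Evaluates `w0 + sum_b w_b * f(x, x_b)`; percentage predictions are clipped
#' to \[0, 100\].
#'
#' @param object A `callus_rbf` model.
#' @param newdata Feature matrix or condition data frame.
#' @param ... Unused.
#' @return Numeric predictions on the target scale.
#' @export
predict.callus_rbf <- function(object, newdata, ...) {
  x <- if (is.data.frame(newdata)) encode_conditions(newdata) else {
    if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
    newdata
  }
  x <- .align_features(x, object$feature_names)
  xs <- .apply_scaler(x, object$x_scaler)
  xs <- sweep(xs, 2, object$metric_multipliers, "*")
  K <- .kernel_matrix(xs, object$centers, object$h)
  y <- object$w0 + as.vector(K %*% object$w)
  if (object$target == "percentage") y <- pmin(100, pmax(0, y))
  as.numeric(y)
}
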