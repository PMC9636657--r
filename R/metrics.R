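# Fit metrics and leave-one-variable-out sensitivity ranking.

#' Root mean square error
#'
#' `sqrt(sum((y - yhat)^2) / n)`.
#'
#' @param y Observed values.
#' @param yhat Predicted values, same length.
#' @return Non-negative error in target units; 0 iff the vectors coincide.
#' @export
#' @examples
#' rmse(c(0, 0), c(3, 4)) # sqrt(25 / 2)
rmse <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("y and yhat must have equal length")
  if (length(y) < 1) stop("need at least one observation")
  sqrt(sum((y - yhat)^2) / length(y))
}

#' Coefficient of determination
#'
#' `1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`. May be negative for
#' predictors worse than the mean.
#'
#' @param y Observed values (not all identical).
#' @param yhat Predicted values, same length.
#' @return R-squared (<= 1).
#' @export
#' @examples
#' r_squared(c(1, 2, 3), c(1, 2, 2)) # 0.5
r_squared <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("y and yhat must have equal length")
  if (length(y) < 2) stop("need at least two observations")
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stop("constant observations: R-squared undefined")
  1 - sum((y - yhat)^2) / ss_tot
}

#' Train/test metric report for a surrogate
#'
#' @param model A `callus_mlp` or `callus_rbf` model.
#' @param train,test Condition-summary data frames (test may be `NULL`).
#' @return Data frame with one row per split: `split`, `n`, `rmse`, `r2`.
#' @export
metric_report <- function(model, train, test = NULL) {
  one <- function(summaries, split) {
    y <- summaries[[.target_column(model$target)]]
    yhat <- predict(model, summaries)
    data.frame(split = split, n = length(y),
               rmse = rmse(y, yhat), r2 = r_squared(y, yhat),
               stringsAsFactors = FALSE)
  }
  out <- one(train, "train")
  if (!is.null(test) && nrow(test) > 0) out <- rbind(out, one(test, "test"))
  out
}

# default semantic grouping of the 10 feature columns
.default_feature_groups <- function() {
  list(
    pgr_concentration = c("conc_24d", "conc_bap", "conc_kin", "conc_naa"),
    ms_concentration = "ms_level",
    sampling_time = "sampling_day",
    explant_type = paste0("explant_", .explants)
  )
}

#' Variable-sensitivity analysis (VSE / VSR)
#'
#' Ranks input-variable groups by how much the surrogate's error grows when a
#' group is withheld. A baseline model is trained on all features with a fixed
#' seed; for each group the model is retrained with the group's columns
#' removed (same configuration and seed) and its RMSE on the same data is the
#' variable sensitivity error (VSE). The variable sensitivity ratio
#' VSR = VSE / baseline RMSE ranks the groups: the most influential variable
#' has the highest VSR (rank 1). A permutation mode, which shuffles the
#' group's columns instead of retraining, is available as a cheaper
#' alternative.
#'
#' @param data Condition-summary data frame.
#' @param target `"percentage"` or `"speed"`.
#' @param model_family `"mlp"` or `"rbf"`.
#' @param cfg Surrogate configuration ([mlp_config()] or [rbf_config()]).
#' @param groups Named list mapping group labels to feature column names;
#'   default groups the four PGR concentrations, the MS multiplier, the
#'   sampling day and the explant one-hot block.
#' @param mode `"loco"` (leave-one-covariate-out retraining, default) or
#'   `"permutation"`.
#' @param extra_features Optional named matrix of additional feature columns
#'   (one row per summary) appended to the standard encoding; groups may
#'   reference these names, e.g. to probe a known pure-noise input.
#' @return Data frame with columns `group`, `vse`, `vsr`, `rank`, plus the
#'   baseline RMSE as attribute `"baseline_rmse"`.
#' @export
sensitivity_analysis <- function(data, target = c("percentage", "speed"),
                                 model_family = c("mlp", "rbf"),
                                 cfg = NULL,
                                 groups = .default_feature_groups(),
                                 mode = c("loco", "permutation"),
                                 extra_features = NULL) {
  target <- match.arg(target)
  model_family <- match.arg(model_family)
  mode <- match.arg(mode)
  if (length(groups) == 0) stop("groups must be a non-empty named list")
  trainer <- switch(model_family, mlp = train_mlp, rbf = fit_rbf)
  if (is.null(cfg)) {
    cfg <- switch(model_family, mlp = mlp_config(), rbf = rbf_config())
  }
  y <- data[[.target_column(target)]]

  baseline <- trainer(data, target = target, cfg = cfg,
                      extra_features = extra_features)
  full_x <- .summaries_to_xy(data, target, extra_features)$x
  base_rmse <- rmse(y, predict(baseline, full_x))

  vse <- vapply(names(groups), function(g) {
    cols <- groups[[g]]
    if (mode == "loco") {
      m <- trainer(data, target = target, cfg = cfg, drop_features = cols,
                   extra_features = extra_features)
      rmse(y, predict(m, full_x))
    } else {
      x <- full_x
      set.seed(cfg$seed)
      x[, cols] <- x[sample.int(nrow(x)), cols]
      rmse(y, predict(baseline, x))
    }
  }, numeric(1))

  out <- data.frame(group = names(groups), vse = as.numeric(vse),
                    vsr = as.numeric(vse) / base_rmse,
                    stringsAsFactors = FALSE)
  out$rank <- rank(-out$vsr, ties.method = "first")
  out <- out[order(out$rank), ]
  rownames(out) <- NULL
  attr(out, "baseline_rmse") <- base_rmse
  out
}
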