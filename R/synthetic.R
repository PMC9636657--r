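# Factorial replicate generator. Per-condition induction probabilities and
# diameter moments live in an effect table; replicates are Bernoulli draws
# (with optional logit-normal between-sub-set overdispersion) and callused
# diameters are zero-truncated normal.

#' Default per-condition effect table
#'
#' A complete 192-row table of induction probabilities and diameter moments
#' emulating the reported outcome structure of the factorial experiment:
#'
#' * all 8x MS conditions fail completely (p = 0);
#' * at 4x MS, treatments 5-7 induce callus in every replicate (p = 1) while
#'   treatments 1, 2, 4 and the hormone-free control (8) never do;
#' * at 1x MS, shoot explants respond strongly in treatments 1, 2, 5, 6, 7 and
#'   nodal explants in 2-6, with nodal explants weakest in treatments 1 and 7,
#'   and the hormone-free control inert everywhere;
#' * the overall best percentage is at (shoot, 1x MS, treatment 6, day 25) and
#'   the best growth-rate desirability (diameter/day) at (leaf, 1x MS,
#'   treatment 6, day 8).
#'
#' Cells for which only qualitative orderings are known carry interpolated
#' intermediate probabilities (0.15-0.9); these are a documented modeling
#' choice, not measured data. Diameters grow between day 8 and day 25 by a
#' factor of 1.6, so the diameter/day desirability always favors day 8.
#'
#' @return Data frame with 192 rows and columns `treatment_id`, `explant`,
#'   `ms_level`, `sampling_day`, `p_induction`, `mu_diameter_mm`,
#'   `sigma_diameter_mm`.
#' @export
default_effect_table <- function() {
  grid <- design_grid()

  # day-25 induction probabilities at 1x MS, rows = leaf/nodal/root/shoot,
  # cols = treatments 1..8
  p25_1x <- rbind(
    leaf  = c(0.55, 0.55, 0.55, 0.55, 0.55, 0.70, 0.55, 0),
    nodal = c(0.15, 0.80, 0.80, 0.80, 0.80, 0.80, 0.15, 0),
    root  = c(0.45, 0.45, 0.45, 0.45, 0.45, 0.60, 0.45, 0),
    shoot = c(0.90, 0.90, 0.65, 0.65, 0.90, 1.00, 0.90, 0)
  )
  # induction accrues over time: day-8 probabilities sit below day 25
  p8_1x <- ifelse(p25_1x == 1, 0.92,
                  ifelse(p25_1x == 0, 0, pmax(0.05, p25_1x - 0.15)))

  p_4x <- c(0, 0, NA, 0, 1, 1, 1, 0) # per treatment, all explants/days
  p25_4x_t3 <- 0.5
  p8_4x_t3 <- 0.4

  # day-8 diameter means (mm) at 1x MS: explant base x treatment multiplier
  d_base_1x <- c(leaf = 5.0, nodal = 3.2, root = 3.6, shoot = 4.6)
  d_mult <- c(0.95, 1.0, 1.0, 1.0, 1.05, 1.2, 0.95, 0)
  # at 4x MS the elevated salts depress growth; root copes best in treatment 5
  d_base_4x <- c(leaf = 2.8, nodal = 2.4, root = 3.2, shoot = 2.8)
  d_mult_4x <- c(0, 0, 0.7, 0, 1.1, 1.0, 0.95, 0)
  growth_25 <- 1.6

  p <- mu <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    tr <- grid$treatment_id[i]
    ex <- grid$explant[i]
    ms <- grid$ms_level[i]
    day <- grid$sampling_day[i]
    if (ms == 8) {
      p[i] <- 0; mu[i] <- 0
    } else if (ms == 4) {
      p[i] <- if (tr == 3) if (day == 8) p8_4x_t3 else p25_4x_t3 else p_4x[tr]
      mu[i] <- d_base_4x[ex] * d_mult_4x[tr] * if (day == 25) growth_25 else 1
    } else {
      p[i] <- if (day == 8) p8_1x[ex, tr] else p25_1x[ex, tr]
      mu[i] <- d_base_1x[ex] * d_mult[tr] * if (day == 25) growth_25 else 1
    }
    if (p[i] == 0) mu[i] <- 0
  }
  grid$p_induction <- p
  grid$mu_diameter_mm <- mu
  grid$sigma_diameter_mm <- ifelse(p > 0, 0.4, 0)
  grid
}

.check_effect_table <- function(tab) {
  need <- c("treatment_id", "explant", "ms_level", "sampling_day",
            "p_induction", "mu_diameter_mm", "sigma_diameter_mm")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) stop("effect table missing column(s): ",
                             paste(miss, collapse = ", "))
  .check_conditions(tab)
  if (nrow(tab) != 192) stop("effect table must cover all 192 conditions")
  if (any(tab$p_induction < 0 | tab$p_induction > 1)) {
    stop("p_induction must lie in [0, 1]")
  }
  if (any(tab$mu_diameter_mm < 0) || any(tab$sigma_diameter_mm < 0)) {
    stop("diameter moments must be non-negative")
  }
  if (any(tab$p_induction == 0 & tab$mu_diameter_mm != 0)) {
    stop("conditions with p = 0 must have mu_diameter_mm = 0")
  }
  invisible(tab)
}

#' Generator configuration
#'
#' @param seed Integer seed fixing the full simulated output bit-exactly.
#' @param n_replicates Replicates per condition (default 24), divisible by
#'   `n_subsets`.
#' @param n_subsets Number of sub-sets per condition (default 3, the
#'   completely-randomized-design sub-set structure of the experiment).
#' @param subset_effect_sd Logit-scale standard deviation of the between-
#'   sub-set random effect (default 0.3). Conditions with p exactly 0 or 1 are
#'   clamped and receive no sub-set effect.
#' @param effect_table Per-condition effect table; default
#'   [default_effect_table()].
#' @return A `callus_gen_config` list.
#' @export
generator_config <- function(seed = 1L, n_replicates = 24L, n_subsets = 3L,
                             subset_effect_sd = 0.3,
                             effect_table = default_effect_table()) {
  if (n_replicates < 1 || n_subsets < 1 || n_replicates %% n_subsets != 0) {
    stop("n_replicates must be a positive multiple of n_subsets")
  }
  if (subset_effect_sd < 0) stop("subset_effect_sd must be non-negative")
  .check_effect_table(effect_table)
  structure(
    list(seed = as.integer(seed), n_replicates = as.integer(n_replicates),
         n_subsets = as.integer(n_subsets),
         subset_effect_sd = subset_effect_sd, effect_table = effect_table),
    class = "callus_gen_config"
  )
}

# zero-truncated normal draws via inverse-CDF; sigma = 0 collapses to mu
.rtnorm0 <- function(n, mu, sigma) {
  if (n == 0) return(numeric(0))
  if (sigma == 0) return(rep(mu, n))
  lo <- stats::pnorm(0, mean = mu, sd = sigma)
  u <- stats::runif(n, lo, 1)
  stats::qnorm(u, mean = mu, sd = sigma)
}

#' Simulate a factorial callus-induction experiment
#'
#' For every condition in the effect table, draws per-sub-set induction
#' probabilities as `plogis(qlogis(p) + e)` with `e ~ N(0, subset_effect_sd)`
#' (p of exactly 0 or 1 is kept fixed, so impossible conditions never produce
#' callus and certain ones always do), then Bernoulli callus outcomes and
#' zero-truncated normal diameters for callused replicates. The same seed
#' reproduces the output bit-exactly.
#'
#' @param cfg A [generator_config()].
#' @return Replicate data frame with `192 * n_replicates` rows in the raw CSV
#'   schema (`treatment_id, explant, ms_level, sampling_day, subset_id,
#'   replicate_id, callus, diameter_mm`).
#' @export
#' @examples
#' rec <- simulate_experiment(generator_config(seed = 1))
#' nrow(rec) # 4608
simulate_experiment <- function(cfg) {
  if (!inherits(cfg, "callus_gen_config")) {
    stop("cfg must be created by generator_config()")
  }
  tab <- cfg$effect_table
  per_sub <- cfg$n_replicates %/% cfg$n_subsets
  set.seed(cfg$seed)
  out <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    p <- tab$p_induction[i]
    rows <- vector("list", cfg$n_subsets)
    for (s in seq_len(cfg$n_subsets)) {
      p_sub <- if (p <= 0 || p >= 1) p else {
        stats::plogis(stats::qlogis(p) + stats::rnorm(1, 0, cfg$subset_effect_sd))
      }
      callus <- stats::runif(per_sub) < p_sub
      diam <- numeric(per_sub)
      diam[callus] <- .rtnorm0(sum(callus), tab$mu_diameter_mm[i],
                               tab$sigma_diameter_mm[i])
      rows[[s]] <- data.frame(
        treatment_id = tab$treatment_id[i],
        explant = tab$explant[i],
        ms_level = tab$ms_level[i],
        sampling_day = tab$sampling_day[i],
        subset_id = s,
        replicate_id = (s - 1L) * per_sub + seq_len(per_sub),
        callus = callus,
        diameter_mm = diam,
        stringsAsFactors = FALSE
      )
    }
    out[[i]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Noise-free expected condition summaries
#'
#' The theoretical condition-level outcomes implied by an effect table:
#' induction percentage `100 * p`, mean diameter equal to the table's mean
#' (exact for `sigma = 0`; for `sigma > 0` the zero-truncation bias is
#' ignored, which is negligible at the default `mu/sigma` ratios), and speed
#' from [compute_speed()]. Useful as deterministic, noise-free training data
#' for surrogate-recovery checks.
#'
#' @param effect_table Effect table, default [default_effect_table()].
#' @param speed_mode Passed to [compute_speed()].
#' @return Condition-summary data frame in the layout of
#'   [condition_summaries()] (with `n = Inf` to mark expectations).
#' @export
expected_summaries <- function(effect_table = default_effect_table(),
                               speed_mode = c("as_written", "inverted")) {
  speed_mode <- match.arg(speed_mode)
  .check_effect_table(effect_table)
  out <- effect_table[, c("treatment_id", "explant", "ms_level", "sampling_day")]
  out$n <- Inf
  out$induction_pct <- 100 * effect_table$p_induction
  out$mean_diameter_mm <- ifelse(effect_table$p_induction > 0,
                                 effect_table$mu_diameter_mm, 0)
  out$speed <- compute_speed(out$sampling_day, out$mean_diameter_mm, speed_mode)
  out
}
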