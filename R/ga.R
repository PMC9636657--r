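# Discrete genetic algorithm over the 192-point design space. Chromosomes
# are 4 integer genes (treatment 1-8, explant 1-4, MS index 1-3, day index
# 1-2). Selection is binary tournament with elitism; recombination is the
# single-point operator on the gene string; mutation resamples genes
# uniformly. Multi-objective mode uses fast non-dominated sorting with
# crowding-distance tie-breaking, and the whole space is small enough that an
# exhaustive-enumeration oracle is provided for verification.

.gene_ranges <- c(treatment = 8L, explant = 4L, ms = 3L, day = 2L)

#' Decode chromosomes to culture conditions
#'
#' @param chrom Integer matrix with 4 columns (or a single 4-vector):
#'   treatment id 1-8, explant index 1-4 (leaf, nodal, root, shoot), MS index
#'   1-3 (1x, 4x, 8x), day index 1-2 (day 8, day 25).
#' @return Condition data frame.
#' @export
decode_chromosome <- function(chrom) {
  if (is.null(dim(chrom))) chrom <- matrix(chrom, nrow = 1)
  if (ncol(chrom) != 4) stop("chromosomes have 4 genes")
  for (j in 1:4) {
    if (any(chrom[, j] < 1 | chrom[, j] > .gene_ranges[j])) {
      stop("gene ", names(.gene_ranges)[j], " out of range")
    }
  }
  data.frame(
    treatment_id = chrom[, 1],
    explant = .explants[chrom[, 2]],
    ms_level = .ms_levels[chrom[, 3]],
    sampling_day = .sampling_days[chrom[, 4]],
    stringsAsFactors = FALSE
  )
}

#' Encode culture conditions as chromosomes
#'
#' @param conditions Condition data frame.
#' @return Integer matrix with 4 gene columns.
#' @export
encode_chromosome <- function(conditions) {
  .check_conditions(conditions)
  cbind(
    treatment = as.integer(conditions$treatment_id),
    explant = match(conditions$explant, .explants),
    ms = match(conditions$ms_level, .ms_levels),
    day = match(conditions$sampling_day, .sampling_days)
  )
}

#' Single-point crossover of two chromosomes
#'
#' Children swap the gene suffixes after the cut position, so the gene
#' multiset across the pair is conserved.
#'
#' @param a,b Integer chromosomes (4-vectors).
#' @param cut Cut position, 1-3 (genes after `cut` are exchanged).
#' @param apply If `FALSE`, the parents are returned unchanged.
#' @return List with children `a` and `b`.
#' @export
#' @examples
#' crossover_single_point(c(6, 4, 1, 1), c(1, 1, 3, 2), cut = 2)
crossover_single_point <- function(a, b, cut, apply = TRUE) {
  if (length(a) != 4 || length(b) != 4) stop("chromosomes have 4 genes")
  if (cut < 1 || cut > 3) stop("cut must lie in 1..3")
  if (!apply) return(list(a = a, b = b))
  tail_idx <- (cut + 1):4
  ca <- a; cb <- b
  ca[tail_idx] <- b[tail_idx]
  cb[tail_idx] <- a[tail_idx]
  list(a = ca, b = cb)
}

#' Uniform per-gene mutation
#'
#' Each gene is independently resampled uniformly from its full range with
#' probability `p` (the resample may repeat the current allele).
#'
#' @param chrom Integer chromosome (4-vector).
#' @param p Per-gene mutation probability in \[0, 1\].
#' @return Mutated chromosome, always within gene ranges.
#' @export
mutate_chromosome <- function(chrom, p) {
  if (p < 0 || p > 1) stop("p must lie in [0, 1]")
  hit <- stats::runif(4) < p
  if (any(hit)) {
    chrom[hit] <- vapply(which(hit), function(j) {
      sample.int(.gene_ranges[j], 1)
    }, integer(1))
  }
  chrom
}

#' Fast non-dominated sorting (both objectives maximized)
#'
#' @param points Numeric matrix with one row per point and 2+ objective
#'   columns, all maximized.
#' @return Integer vector of Pareto ranks: 0 for the non-dominated set, 1 for
#'   the set that becomes non-dominated once rank 0 is removed, and so on.
#'   Identical points share a rank.
#' @export
non_dominated_sort <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, nrow = 1)
  n <- nrow(points)
  ge <- matrix(TRUE, n, n)
  gt <- matrix(FALSE, n, n)
  for (m in seq_len(ncol(points))) {
    pm <- points[, m]
    ge <- ge & outer(pm, pm, ">=")
    gt <- gt | outer(pm, pm, ">")
  }
  dom <- ge & gt # dom[i, j]: i dominates j
  alive <- rep(TRUE, n)
  rank <- integer(n)
  level <- 0L
  while (any(alive)) {
    dcount <- colSums(dom[alive, , drop = FALSE])
    front <- alive & dcount == 0L
    rank[front] <- level
    alive[front] <- FALSE
    dom[front, ] <- FALSE
    level <- level + 1L
  }
  rank
}

#' Crowding distance within a front
#'
#' @param points Numeric objective matrix (rows = members of one front).
#' @return Non-negative crowding distances; boundary points get `Inf`.
#' @export
crowding_distance <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, nrow = 1)
  n <- nrow(points)
  if (n <= 2) return(rep(Inf, n))
  d <- numeric(n)
  for (m in seq_len(ncol(points))) {
    ord <- order(points[, m])
    span <- points[ord[n], m] - points[ord[1], m]
    d[ord[c(1, n)]] <- Inf
    if (span > 0) {
      mid <- 2:(n - 1)
      d[ord[mid]] <- d[ord[mid]] +
        (points[ord[mid + 1], m] - points[ord[mid - 1], m]) / span
    }
  }
  d
}

#' GA configuration
#'
#' Defaults follow the study's optimization setup: 100 initial population
#' members and 1000 generations.
#'
#' @param population_size Population size (>= 2; default 100).
#' @param generations Number of generations (default 1000).
#' @param crossover_prob Probability that a mated pair undergoes single-point
#'   crossover.
#' @param mutation_prob Per-gene mutation probability.
#' @param tournament_size Tournament size for selection (default 2).
#' @param elitism Number of elites copied unchanged each generation.
#' @param seed Integer seed; fixes the run bit-exactly.
#' @param objectives `"percentage"`, `"speed"` or `"both"`.
#' @return A `callus_ga_config` list.
#' @export
ga_config <- function(population_size = 100L, generations = 1000L,
                      crossover_prob = 0.9, mutation_prob = 0.05,
                      tournament_size = 2L, elitism = 1L, seed = 1L,
                      objectives = c("percentage", "speed", "both")) {
  objectives <- match.arg(objectives)
  if (population_size < 2) stop("population_size must be >= 2")
  if (elitism < 0 || elitism >= population_size) {
    stop("elitism must lie in [0, population_size)")
  }
  structure(
    list(population_size = as.integer(population_size),
         generations = as.integer(generations),
         crossover_prob = crossover_prob, mutation_prob = mutation_prob,
         tournament_size = as.integer(tournament_size),
         elitism = as.integer(elitism), seed = as.integer(seed),
         objectives = objectives),
    class = "callus_ga_config"
  )
}

# objective lookup over the full grid: percentage from the percentage
# surrogate; speed desirability (maximized) from the speed surrogate, negated
# when that surrogate was trained on the as-written day/diameter scale
.grid_objectives <- function(model_pct, model_speed,
                             speed_direction = c("desirability", "as_written")) {
  speed_direction <- match.arg(speed_direction)
  grid <- design_grid()
  x <- encode_conditions(grid)
  obj <- cbind(
    percentage = if (!is.null(model_pct)) predict(model_pct, x) else NA_real_,
    speed = if (!is.null(model_speed)) {
      s <- predict(model_speed, x)
      if (speed_direction == "as_written") -s else s
    } else NA_real_
  )
  list(grid = grid, objectives = obj)
}

.chrom_index <- function(chrom) {
  # row index into design_grid() (treatment fastest, then explant, ms, day)
  (chrom[, 4] - 1L) * 96L + (chrom[, 3] - 1L) * 32L +
    (chrom[, 2] - 1L) * 8L + chrom[, 1]
}

#' Run the discrete GA over the design space
#'
#' Single-objective mode maximizes one predicted output; multi-objective mode
#' (`objectives = "both"`) maximizes predicted percentage and speed
#' desirability jointly via non-dominated sorting with crowding-distance
#' tie-breaks (the parent and child populations are pooled and truncated each
#' generation). Surrogate predictions are precomputed over the 192-point grid
#' once, so fitness evaluation is exact and cheap.
#'
#' The reported compromise solution of a multi-objective run maximizes the
#' sum of min-max-normalized objectives over the final front (rule recorded
#' in the result as `selection_rule`).
#'
#' @param model_pct Percentage surrogate (`callus_mlp`/`callus_rbf`), or
#'   `NULL` when optimizing speed only.
#' @param model_speed Speed surrogate, or `NULL` when optimizing percentage
#'   only. Expected to predict the diameter/day desirability; set
#'   `speed_direction = "as_written"` if it predicts day/diameter, which is
#'   then minimized.
#' @param cfg A [ga_config()].
#' @param speed_direction How to orient the speed surrogate's output.
#' @return A `callus_ga_result` list: `best` (condition + objectives),
#'   `front` (non-dominated conditions, multi-objective mode), `selected`
#'   (compromise solution), `history` (per-generation best fitness, or front
#'   summary in multi-objective mode), and the decoded population.
#' @export
ga_optimize <- function(model_pct = NULL, model_speed = NULL,
                        cfg = ga_config(),
                        speed_direction = c("desirability", "as_written")) {
  if (!inherits(cfg, "callus_ga_config")) stop("cfg must come from ga_config()")
  multi <- cfg$objectives == "both"
  if (cfg$objectives %in% c("percentage", "both") && is.null(model_pct)) {
    stop("a trained percentage surrogate is required")
  }
  if (cfg$objectives %in% c("speed", "both") && is.null(model_speed)) {
    stop("a trained speed surrogate is required")
  }
  go <- .grid_objectives(model_pct, model_speed, speed_direction)
  obj_cols <- switch(cfg$objectives,
                     percentage = "percentage", speed = "speed",
                     both = c("percentage", "speed"))
  lookup <- go$objectives[, obj_cols, drop = FALSE]

  set.seed(cfg$seed)
  np <- cfg$population_size
  pop <- cbind(sample.int(8, np, TRUE), sample.int(4, np, TRUE),
               sample.int(3, np, TRUE), sample.int(2, np, TRUE))
  fitness <- function(p) lookup[.chrom_index(p), , drop = FALSE]

  history <- numeric(cfg$generations)
  f <- fitness(pop)

  rank_pop <- function(f) {
    if (!multi) {
      ord <- order(-f[, 1])
      list(order = ord, rank = rank(-f[, 1], ties.method = "min"))
    } else {
      r <- non_dominated_sort(f)
      cd <- numeric(nrow(f))
      for (lev in unique(r)) {
        sel <- r == lev
        cd[sel] <- crowding_distance(f[sel, , drop = FALSE])
      }
      ord <- order(r, -cd)
      list(order = ord, rank = r, crowding = cd)
    }
  }

  for (gen in seq_len(cfg$generations)) {
    rk <- rank_pop(f)
    # binary-style tournament selection on rank (crowding breaks ties)
    pick <- function() {
      cand <- sample.int(np, cfg$tournament_size)
      if (!multi) {
        cand[which.max(f[cand, 1])]
      } else {
        best <- cand[order(rk$rank[cand], -rk$crowding[cand])]
        best[1]
      }
    }
    n_child <- np
    children <- matrix(0L, n_child, 4)
    i <- 1L
    while (i <= n_child) {
      p1 <- pop[pick(), ]
      p2 <- pop[pick(), ]
      if (stats::runif(1) < cfg$crossover_prob) {
        cut <- sample.int(3, 1)
        cr <- crossover_single_point(p1, p2, cut)
        p1 <- cr$a; p2 <- cr$b
      }
      children[i, ] <- mutate_chromosome(p1, cfg$mutation_prob)
      if (i + 1L <= n_child) {
        children[i + 1L, ] <- mutate_chromosome(p2, cfg$mutation_prob)
      }
      i <- i + 2L
    }
    fc <- fitness(children)

    if (!multi) {
      # elitism: best parents survive, rest of the population is the children
      if (cfg$elitism > 0) {
        elite_idx <- rk$order[seq_len(cfg$elitism)]
        keep <- order(-fc[, 1])[seq_len(np - cfg$elitism)]
        pop <- rbind(pop[elite_idx, , drop = FALSE],
                     children[keep, , drop = FALSE])
      } else {
        pop <- children
      }
      f <- fitness(pop)
      history[gen] <- max(f[, 1])
    } else {
      # (mu + lambda) environmental selection on the pooled population
      all_pop <- rbind(pop, children)
      all_f <- rbind(f, fc)
      rk_all <- rank_pop(all_f)
      sel <- rk_all$order[seq_len(np)]
      pop <- all_pop[sel, , drop = FALSE]
      f <- all_f[sel, , drop = FALSE]
      front <- f[non_dominated_sort(f) == 0L, , drop = FALSE]
      history[gen] <- max(.normalized_sum(front))
    }
  }

  .ga_result(pop, f, lookup, go, cfg, history, multi)
}

# sum of min-max-normalized objectives (constant objectives count 1 for all)
.normalized_sum <- function(f) {
  if (is.null(dim(f))) f <- matrix(f, nrow = 1)
  z <- apply(f, 2, function(v) {
    span <- max(v) - min(v)
    if (span == 0) rep(1, length(v)) else (v - min(v)) / span
  })
  if (is.null(dim(z))) z <- matrix(z, nrow = nrow(f))
  rowSums(z)
}

.ga_result <- function(pop, f, lookup, go, cfg, history, multi) {
  dedup <- !duplicated(.chrom_index(pop))
  pop_u <- pop[dedup, , drop = FALSE]
  f_u <- f[dedup, , drop = FALSE]
  if (!multi) {
    best_i <- which.max(f_u[, 1])
    best <- cbind(decode_chromosome(pop_u[best_i, , drop = FALSE]),
                  stats::setNames(data.frame(f_u[best_i, 1]), colnames(f_u)))
    front <- best
    selected <- best
    rule <- "single_objective_max"
  } else {
    r <- non_dominated_sort(f_u)
    fr <- which(r == 0L)
    front <- cbind(decode_chromosome(pop_u[fr, , drop = FALSE]),
                   as.data.frame(f_u[fr, , drop = FALSE]))
    ns <- .normalized_sum(f_u[fr, , drop = FALSE])
    sel_i <- fr[which.max(ns)]
    selected <- cbind(decode_chromosome(pop_u[sel_i, , drop = FALSE]),
                      as.data.frame(f_u[sel_i, , drop = FALSE]))
    best <- selected
    rule <- "max_sum_of_minmax_normalized_objectives"
  }
  rownames(front) <- rownames(selected) <- rownames(best) <- NULL
  structure(
    list(best = best, front = front, selected = selected,
         selection_rule = rule, history = history, cfg = cfg),
    class = "callus_ga_result"
  )
}

#' Exhaustive-enumeration optimum (oracle)
#'
#' Evaluates the surrogate(s) on all 192 grid conditions and returns the
#' exact argmax (single objective) or the exact Pareto front plus the
#' compromise solution (both objectives). Ties are broken by the first row in
#' [design_grid()] order.
#'
#' @inheritParams ga_optimize
#' @param objectives `"percentage"`, `"speed"` or `"both"`.
#' @return List with `best`, `front`, `selected` in the same layout as
#'   [ga_optimize()] results.
#' @export
brute_force_optimum <- function(model_pct = NULL, model_speed = NULL,
                                objectives = c("percentage", "speed", "both"),
                                speed_direction = c("desirability", "as_written")) {
  objectives <- match.arg(objectives)
  go <- .grid_objectives(model_pct, model_speed, speed_direction)
  obj_cols <- switch(objectives,
                     percentage = "percentage", speed = "speed",
                     both = c("percentage", "speed"))
  f <- go$objectives[, obj_cols, drop = FALSE]
  if (objectives != "both") {
    best_i <- which.max(f[, 1]) # which.max takes the first maximum
    best <- cbind(go$grid[best_i, , drop = FALSE],
                  stats::setNames(data.frame(f[best_i, 1]), obj_cols))
    rownames(best) <- NULL
    return(list(best = best, front = best, selected = best))
  }
  r <- non_dominated_sort(f)
  fr <- which(r == 0L)
  front <- cbind(go$grid[fr, , drop = FALSE], as.data.frame(f[fr, , drop = FALSE]))
  ns <- .normalized_sum(f[fr, , drop = FALSE])
  sel <- front[which.max(ns), , drop = FALSE]
  rownames(front) <- rownames(sel) <- NULL
  list(best = sel, front = front, selected = sel)
}
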