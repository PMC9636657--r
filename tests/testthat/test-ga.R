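test_that("single-point crossover swaps suffixes and conserves genes", {
  cr <- crossover_single_point(c(6, 4, 1, 1), c(1, 1, 3, 2), cut = 2)
  expect_equal(cr$a, c(6, 4, 3, 2))
  expect_equal(cr$b, c(1, 1, 1, 1))
  # identical parents are unchanged by any cut
  for (cut in 1:3) {
    cr2 <- crossover_single_point(c(3, 2, 2, 1), c(3, 2, 2, 1), cut)
    expect_equal(cr2$a, c(3, 2, 2, 1))
    expect_equal(cr2$b, c(3, 2, 2, 1))
  }
  expect_equal(crossover_single_point(c(1, 2, 3, 2), c(8, 4, 1, 1), 2,
                                      apply = FALSE)$a, c(1, 2, 3, 2))
  expect_error(crossover_single_point(1:4, 1:4, cut = 4), "1..3")

  # per-position allele multisets are conserved across the pair
  set.seed(20)
  for (i in 1:200) {
    a <- c(sample(8, 1), sample(4, 1), sample(3, 1), sample(2, 1))
    b <- c(sample(8, 1), sample(4, 1), sample(3, 1), sample(2, 1))
    cr <- crossover_single_point(a, b, sample(3, 1))
    for (j in 1:4) {
      expect_equal(sort(c(cr$a[j], cr$b[j])), sort(c(a[j], b[j])))
    }
  }
})

test_that("mutation is uniform per gene with the requested rate", {
  set.seed(21)
  expect_equal(mutate_chromosome(c(5, 3, 2, 1), 0), c(5, 3, 2, 1))
  for (i in 1:50) {
    m <- mutate_chromosome(c(1, 1, 1, 1), 1)
    expect_true(all(m >= 1 & m <= c(8, 4, 3, 2)))
  }
  # empirical per-gene change rate ~ p * (1 - 1/range)
  p <- 0.3
  n <- 20000
  base <- c(4, 2, 2, 1)
  changed <- matrix(FALSE, n, 4)
  for (i in seq_len(n)) changed[i, ] <- mutate_chromosome(base, p) != base
  expected <- p * (1 - 1 / c(8, 4, 3, 2))
  se <- sqrt(expected * (1 - expected) / n)
  expect_true(all(abs(colMeans(changed) - expected) < 3 * se))
})

test_that("non-dominated sorting matches a pairwise-domination oracle", {
  expect_equal(non_dominated_sort(matrix(c(1, 1), 1)), 0L)
  expect_equal(non_dominated_sort(rbind(c(1, 1), c(2, 2))), c(1L, 0L))
  # equal points share a rank
  expect_equal(non_dominated_sort(rbind(c(1, 2), c(1, 2))), c(0L, 0L))

  oracle <- function(pts) {
    n <- nrow(pts)
    dominated <- function(i, alive) {
      any(vapply(alive, function(j) {
        i != j && all(pts[j, ] >= pts[i, ]) && any(pts[j, ] > pts[i, ])
      }, logical(1)))
    }
    rank <- rep(NA_integer_, n)
    level <- 0L
    while (anyNA(rank)) {
      alive <- which(is.na(rank))
      front <- alive[!vapply(alive, dominated, logical(1), alive = alive)]
      rank[front] <- level
      level <- level + 1L
    }
    rank
  }
  set.seed(22)
  for (i in 1:5) {
    pts <- matrix(sample(10, 100, replace = TRUE), 50, 2)
    expect_equal(non_dominated_sort(pts), oracle(pts))
  }
})

test_that("crowding distance marks boundary points as infinite", {
  pts <- cbind(c(0, 1, 2, 3), c(3, 2, 1, 0))
  d <- crowding_distance(pts)
  expect_equal(d[c(1, 4)], c(Inf, Inf))
  expect_true(all(is.finite(d[2:3])))
  expect_equal(crowding_distance(pts[1:2, ]), c(Inf, Inf))
})

test_that("a constant surrogate resolves ties to the first grid row", {
  s <- default_summaries()[1:40, ]
  s$speed <- 7
  m <- train_mlp(s, "speed", mlp_config(seed = 1, l2_alpha = 10,
                                        max_epochs = 200))
  b <- brute_force_optimum(NULL, m, "speed")$best
  g1 <- design_grid()[1, ]
  expect_equal(condition_key(b), condition_key(g1))
})

test_that("the GA always finds the exhaustive-enumeration optimum", {
  m <- default_mlp("percentage")
  oracle <- brute_force_optimum(m, NULL, "percentage")$best
  for (seed in 1:5) {
    r <- ga_optimize(m, NULL, ga_config(seed = seed, generations = 200,
                                        objectives = "percentage"))
    expect_equal(condition_key(r$best), condition_key(oracle))
    expect_equal(r$best$percentage, oracle$percentage)
  }
})

test_that("elitism makes the best fitness history non-decreasing", {
  m <- default_mlp("speed")
  r <- ga_optimize(NULL, m, ga_config(seed = 2, generations = 300,
                                      objectives = "speed"))
  expect_length(r$history, 300L)
  expect_true(all(diff(r$history) >= 0))
})

test_that("the evolved front is a subset of the exact Pareto front", {
  mp <- default_mlp("percentage")
  ms <- default_mlp("speed")
  r <- ga_optimize(mp, ms, ga_config(seed = 3, generations = 150,
                                     objectives = "both"))
  bf <- brute_force_optimum(mp, ms, "both")
  expect_true(all(condition_key(r$front) %in% condition_key(bf$front)))
  # no member of the returned front dominates another
  obj <- as.matrix(r$front[, c("percentage", "speed")])
  expect_true(all(non_dominated_sort(obj) == 0L))
})

test_that("seeded GA runs are exactly reproducible", {
  m <- default_mlp("percentage")
  cfg <- ga_config(seed = 9, generations = 100, objectives = "percentage")
  r1 <- ga_optimize(m, NULL, cfg)
  r2 <- ga_optimize(m, NULL, cfg)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$best, r2$best)
})

test_that("chromosome encoding round-trips over the whole grid", {
  g <- design_grid()
  ch <- encode_chromosome(g)
  expect_true(all(ch >= 1))
  back <- decode_chromosome(ch)
  expect_equal(condition_key(back), condition_key(g))
  expect_error(decode_chromosome(c(9, 1, 1, 1)), "out of range")
})
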