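test_that("default effect table encodes the reported outcome structure", {
  tab <- default_effect_table()
  expect_equal(nrow(tab), 192L)
  expect_true(all(tab$p_induction >= 0 & tab$p_induction <= 1))
  # elevated-salt failures: 8x MS never induces callus
  expect_true(all(tab$p_induction[tab$ms_level == 8] == 0))
  # 4x MS: treatments 5-7 always induce, 1, 2, 4 and the control never do
  expect_true(all(tab$p_induction[tab$ms_level == 4 &
                                    tab$treatment_id %in% 5:7] == 1))
  expect_true(all(tab$p_induction[tab$ms_level == 4 &
                                    tab$treatment_id %in% c(1, 2, 4, 8)] == 0))
  # hormone-free control is inert at every strength
  expect_true(all(tab$p_induction[tab$treatment_id == 8] == 0))
  # no diameter without induction
  expect_true(all(tab$mu_diameter_mm[tab$p_induction == 0] == 0))

  # the best percentage cell is (shoot, 1x, treatment 6, day 25)
  top <- tab[tab$p_induction == max(tab$p_induction) & tab$ms_level == 1, ]
  expect_true(any(top$explant == "shoot" & top$treatment_id == 6 &
                    top$sampling_day == 25))
  # the best growth-rate (diameter/day) cell is (leaf, 1x, treatment 6, day 8)
  des <- tab$mu_diameter_mm / tab$sampling_day
  best <- tab[which.max(des), ]
  expect_equal(best$explant, "leaf")
  expect_equal(best$ms_level, 1)
  expect_equal(best$treatment_id, 6)
  expect_equal(best$sampling_day, 8)
})

test_that("degenerate effect tables force degenerate outcomes", {
  tab <- default_effect_table()
  tab$p_induction <- 0
  tab$mu_diameter_mm <- 0
  tab$sigma_diameter_mm <- 0
  rec <- simulate_experiment(generator_config(seed = 3, effect_table = tab))
  expect_true(all(!rec$callus))
  expect_true(all(rec$diameter_mm == 0))

  tab$p_induction <- 1
  tab$mu_diameter_mm <- 4
  rec2 <- simulate_experiment(generator_config(seed = 3, effect_table = tab))
  expect_true(all(rec2$callus))
  expect_true(all(rec2$diameter_mm == 4))
})

test_that("certain and impossible conditions are never diluted by sub-set noise", {
  rec <- default_records()
  s <- condition_summaries(rec)
  tab <- default_effect_table()
  key <- condition_key(tab)
  p <- tab$p_induction[match(condition_key(s), key)]
  expect_true(all(s$induction_pct[p == 1] == 100))
  expect_true(all(s$induction_pct[p == 0] == 0))
})

test_that("the same seed regenerates the experiment bit-exactly", {
  a <- simulate_experiment(generator_config(seed = 7))
  b <- simulate_experiment(generator_config(seed = 7))
  expect_identical(a, b)
  c <- simulate_experiment(generator_config(seed = 8))
  expect_false(identical(a, c))
})

test_that("observed induction converges to the table probabilities", {
  # law-of-large-numbers check with sub-set overdispersion disabled
  cfg <- generator_config(seed = 5, n_replicates = 2400, n_subsets = 3,
                          subset_effect_sd = 0)
  s <- condition_summaries(simulate_experiment(cfg))
  tab <- cfg$effect_table
  p <- tab$p_induction[match(condition_key(s), condition_key(tab))]
  expect_true(all(abs(s$induction_pct - 100 * p) <= 3))
})

test_that("expected summaries are the noise-free limit of the generator", {
  es <- expected_summaries()
  tab <- default_effect_table()
  expect_equal(es$induction_pct, 100 * tab$p_induction)
  expect_equal(es$mean_diameter_mm[tab$p_induction > 0],
               tab$mu_diameter_mm[tab$p_induction > 0])
  expect_true(all(es$speed[es$mean_diameter_mm == 0] == 0))
  es_inv <- expected_summaries(speed_mode = "inverted")
  nz <- es_inv$mean_diameter_mm > 0
  expect_equal(es_inv$speed[nz],
               es_inv$mean_diameter_mm[nz] / es_inv$sampling_day[nz])
})

test_that("generator configuration is validated", {
  expect_error(generator_config(n_replicates = 25, n_subsets = 3), "multiple")
  expect_error(generator_config(subset_effect_sd = -1), "non-negative")
  tab <- default_effect_table()
  tab$p_induction[1] <- 2
  expect_error(generator_config(effect_table = tab), "0, 1")
  tab2 <- default_effect_table()[-1, ]
  expect_error(generator_config(effect_table = tab2), "192")
})
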