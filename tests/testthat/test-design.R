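test_that("treatment table holds the eight published PGR combinations", {
  tr <- pgr_treatments()
  expect_equal(nrow(tr), 8L)
  expect_equal(tr$treatment_id, 1:8)
  expect_true(all(tr[, -1] >= 0))
  # hormone-free control
  expect_equal(unlist(tr[tr$treatment_id == 8, -1]), c(conc_24d = 0,
    conc_bap = 0, conc_kin = 0, conc_naa = 0))
  # concentration multiset per regulator
  expect_equal(sort(tr$conc_24d), c(0, 0, 0.2, 0.2, 0.2, 0.5, 1, 1))
  expect_equal(sort(tr$conc_bap), c(0, 0, 0, 0, 0, 0.2, 0.3, 0.5))
  expect_equal(sort(tr$conc_kin), c(0, 0, 0, 0, 0, 0, 0.2, 1))
  expect_equal(sort(tr$conc_naa), c(0, 0, 0, 0, 0, 0, 0, 2))
})

test_that("design grid enumerates all 192 distinct conditions", {
  g <- design_grid()
  expect_equal(nrow(g), 192L)
  expect_equal(anyDuplicated(g), 0L)
  expect_setequal(unique(g$explant), c("leaf", "nodal", "root", "shoot"))
  expect_setequal(unique(g$ms_level), c(1, 4, 8))
  expect_setequal(unique(g$sampling_day), c(8, 25))
})

test_that("condition encoding matches the treatment compositions", {
  enc <- function(t, e, m, d) {
    as.vector(encode_conditions(data.frame(treatment_id = t, explant = e,
                                           ms_level = m, sampling_day = d)))
  }
  expect_equal(enc(6, "shoot", 1, 8), c(0.5, 0.5, 0, 0, 1, 8, 0, 0, 0, 1))
  expect_equal(enc(8, "leaf", 8, 25), c(0, 0, 0, 0, 8, 25, 1, 0, 0, 0))
  expect_equal(enc(1, "root", 4, 25), c(0, 0.3, 0, 2, 4, 25, 0, 0, 1, 0))
  expect_error(encode_conditions(data.frame(treatment_id = 9, explant = "leaf",
                                            ms_level = 1, sampling_day = 8)),
               "treatment_id")
  expect_error(encode_conditions(data.frame(treatment_id = 1, explant = "stem",
                                            ms_level = 1, sampling_day = 8)),
               "explant")
})

test_that("encoding and decoding are a bijection on the full grid", {
  g <- design_grid()
  x <- encode_conditions(g)
  expect_equal(dim(x), c(192L, 10L))
  expect_true(all(rowSums(x[, 7:10]) == 1))
  back <- decode_features(x)
  expect_equal(back$treatment_id, g$treatment_id)
  expect_equal(back$explant, g$explant)
  expect_equal(back$ms_level, g$ms_level)
  expect_equal(back$sampling_day, g$sampling_day)
})

test_that("induction speed follows the configured formula", {
  expect_equal(compute_speed(8, 4), 2)
  expect_equal(compute_speed(8, 4, mode = "inverted"), 0.5)
  expect_equal(compute_speed(25, 0), 0)
  expect_equal(compute_speed(25, 0, mode = "inverted"), 0)
  expect_equal(compute_speed(c(8, 25), c(2, 5)), c(4, 5))
  expect_error(compute_speed(0, 1), "positive")
  expect_error(compute_speed(8, -1), "non-negative")
})

test_that("condition summaries aggregate replicates correctly", {
  rec <- data.frame(
    treatment_id = 6, explant = "shoot", ms_level = 1, sampling_day = 8,
    subset_id = rep(1:3, each = 8), replicate_id = 1:24,
    callus = rep(c(TRUE, FALSE), times = c(6, 18)),
    diameter_mm = rep(c(4, 0), times = c(6, 18))
  )
  s <- condition_summaries(rec)
  expect_equal(s$n, 24L)
  expect_equal(s$induction_pct, 25)
  expect_equal(s$mean_diameter_mm, 4)
  expect_equal(s$speed, 2) # 8 days / 4 mm

  all_pos <- transform(rec, callus = TRUE, diameter_mm = 3)
  expect_equal(condition_summaries(all_pos)$induction_pct, 100)
  all_neg <- transform(rec, callus = FALSE, diameter_mm = 0)
  sn <- condition_summaries(all_neg)
  expect_equal(sn$induction_pct, 0)
  expect_equal(sn$speed, 0)
  expect_equal(nrow(condition_summaries(rec[0, ])), 0L)
})

test_that("summaries are permutation-invariant and additive over conditions", {
  rec <- default_records()
  s1 <- condition_summaries(rec)
  set.seed(42)
  s2 <- condition_summaries(rec[sample.int(nrow(rec)), ])
  ord <- function(d) d[order(d$treatment_id, d$explant, d$ms_level,
                             d$sampling_day), ]
  expect_equal(ord(s1), ord(s2), ignore_attr = TRUE)

  # summarizing two disjoint condition subsets = subsetting the full summary
  half <- rec$ms_level == 1
  s_halves <- rbind(condition_summaries(rec[half, ]),
                    condition_summaries(rec[!half, ]))
  expect_equal(ord(s_halves), ord(s1), ignore_attr = TRUE)
})

test_that("replicate CSV round-trips and rejects malformed rows", {
  rec <- default_records()
  path <- withr::local_tempfile(fileext = ".csv")
  write_replicates(rec, path)
  back <- read_replicates(path)
  expect_equal(back, rec, ignore_attr = TRUE)

  bad <- rec
  bad$explant[3] <- "stem"
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_replicates(bad, path2)
  expect_error(read_replicates(path2), "explant")

  bad2 <- rec[1:10, ]
  bad2$callus <- FALSE
  bad2$diameter_mm <- 2
  path3 <- withr::local_tempfile(fileext = ".csv")
  write_replicates(bad2, path3)
  expect_error(read_replicates(path3), "diameter_mm = 0")

  # user column mapping onto the canonical schema
  renamed <- utils::read.csv(path)
  names(renamed)[names(renamed) == "diameter_mm"] <- "diam"
  path4 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(renamed, path4, row.names = FALSE)
  remapped <- read_replicates(path4, columns = c(diameter_mm = "diam"))
  expect_equal(remapped$diameter_mm, rec$diameter_mm)
})
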