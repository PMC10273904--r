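test_that("generate_arc builds the closed-form prototypes", {
  a <- generate_arc("symmetric", 0.8, 400, 4, fs = 200)
  expect_equal(a$times[which.max(a$f0_hz)], 0.4)
  expect_equal(max(a$f0_hz) / min(a$f0_hz), 2^(4 / 12), tolerance = 1e-6)
  expect_equal(a$f0_hz[1], 400)

  left <- generate_arc("left_accentuated", 0.8, 400, 4, fs = 200)
  expect_equal(left$times[which.max(left$f0_hz)] / 0.8, 0.25)
  right <- generate_arc("right_accentuated", 0.8, 400, 4, fs = 200)
  expect_equal(right$times[which.max(right$f0_hz)] / 0.8, 0.75)

  pl <- generate_arc("plateau", 0.5, 400, 4, fs = 200)
  expect_lt(12 * log2(max(pl$f0_hz) / min(pl$f0_hz)), 0.5)
  expect_error(generate_arc("zigzag", 0.5, 400, 4), "invalid shape")
  expect_error(generate_arc("symmetric", -1, 400, 4), "duration")
})

test_that("vocalization generation is a pure function of its label seed", {
  lab <- make_label(category = "DA", n_arcs = 2L, seed = 123L)
  a <- generate_vocalization(lab)
  b <- generate_vocalization(lab)
  expect_identical(a$times, b$times)
  expect_identical(a$f0_hz, b$f0_hz)
  lab2 <- make_label(category = "DA", n_arcs = 2L, seed = 124L)
  expect_false(identical(generate_vocalization(lab2)$f0_hz, a$f0_hz))
  # generation restores the caller's RNG state
  set.seed(7); before <- .Random.seed
  invisible(generate_vocalization(lab))
  expect_identical(.Random.seed, before)
})

test_that("planted exclusions have their defining defect", {
  short <- generate_vocalization(make_label(excl = "too_short", seed = 5L))
  expect_lte(diff(range(short$times)), 0.3)
  jump <- generate_vocalization(make_label(excl = "no_pattern", n_arcs = 2L,
                                           seed = 6L))
  st <- 12 * log2(jump$f0_hz / 440)
  expect_gt(max(abs(diff(st))), 6)
  expect_true(all(jump$f0_hz >= 50 & jump$f0_hz <= 1200))
})

test_that("largest-remainder apportionment is exact, stable and seed-free", {
  mix <- c(SA = 0.39, DA = 0.21, TA = 0.07, MA = 0.03, SEG = 0.30)
  expect_identical(apportion_largest_remainder(100, mix),
                   c(SA = 39L, DA = 21L, TA = 7L, MA = 3L, SEG = 30L))
  set.seed(99)
  for (n in c(1L, 2L, 17L, 266L, 9237L)) {
    ap <- apportion_largest_remainder(n, mix)
    expect_identical(sum(ap), n)
    expect_true(all(abs(ap - n * mix) < 1))
  }
  # same result whatever the RNG state
  set.seed(1); a1 <- apportion_largest_remainder(123, mix)
  set.seed(2); a2 <- apportion_largest_remainder(123, mix)
  expect_identical(a1, a2)
})

test_that("corpus generation hits the configured counts exactly", {
  comp <- small_composition(seed = 3L, scale = 20L, n_excluded = 85L)
  corp <- generate_corpus(comp)
  lb <- corp$labels
  expect_identical(length(corp$contours), nrow(lb))
  expect_identical(sum(lb$planted_exclusion == "none"), sum(comp$counts))
  expect_identical(sum(lb$planted_exclusion != "none"), 85L)
  expect_false(anyDuplicated(lb$vocalization_id) > 0)

  # per-cell included counts match the composition
  inc <- lb[lb$planted_exclusion == "none", ]
  got <- table(inc$infant_id, inc$age_months)
  for (i in rownames(comp$counts)) {
    for (m in 1:12) {
      want <- comp$counts[i, m]
      have <- if (i %in% rownames(got) && as.character(m) %in% colnames(got)) {
        got[i, as.character(m)]
      } else 0L
      expect_identical(as.integer(have), as.integer(want))
    }
  }

  # age coding consistent with type stratification
  expect_true(all(lb$age_months[lb$voc_type %in% c("C", "NC")] <= 6))
  expect_true(all(lb$age_months[lb$voc_type %in% c("BM", "BC")] >= 7))
  # SEG labels always carry more arcs than pauses
  seg <- lb[!is.na(lb$true_category) & lb$true_category == "SEG", ]
  expect_true(all(seg$true_n_segmentations >= 1))
  expect_true(all(seg$true_n_arcs > seg$true_n_segmentations))
})

test_that("changing the seed changes contours but no count or share", {
  comp1 <- small_composition(seed = 5L, scale = 30L, n_excluded = 50L)
  comp2 <- small_composition(seed = 6L, scale = 30L, n_excluded = 50L)
  c1 <- generate_corpus(comp1)
  c2 <- generate_corpus(comp2)
  expect_identical(table(c1$labels$true_category),
                   table(c2$labels$true_category))
  expect_identical(table(c1$labels$voc_type), table(c2$labels$voc_type))
  expect_identical(table(c1$labels$planted_exclusion),
                   table(c2$labels$planted_exclusion))
  expect_false(identical(c1$contours[[1]]$f0_hz, c2$contours[[1]]$f0_hz))
})

test_that("ground-truth shares follow the mixture up to largest-remainder rounding", {
  comp <- small_composition(seed = 2L, scale = 8L)
  lb <- generate_corpus(comp)$labels
  inc <- lb[lb$planted_exclusion == "none", ]
  shares <- prop.table(table(inc$true_category))[names(comp$mixture)]
  expect_true(all(abs(shares - comp$mixture) < 0.01))
})

test_that("the packaged composition fixture equals the in-code default", {
  comp <- read_composition(default_composition_path())
  def <- corpus_composition()
  expect_identical(comp$counts, def$counts)
  expect_identical(comp$sex, def$sex)
  expect_equal(comp$mixture, def$mixture)
  expect_identical(comp$n_excluded, def$n_excluded)
  expect_equal(comp$type_ratio_early, def$type_ratio_early)
  expect_equal(comp$type_ratio_late, def$type_ratio_late)
  expect_identical(sum(comp$counts), 9237L)
  expect_identical(sum(comp$counts) + comp$n_excluded, 10988L)
})

test_that("simulated complexity outcomes follow the planted logit model", {
  s1 <- simulate_complexity_outcomes(5, 200, seed = 21)
  s2 <- simulate_complexity_outcomes(5, 200, seed = 21)
  expect_identical(s1, s2)
  # symmetric logit with no effects: outcome mean near 0.5
  s3 <- simulate_complexity_outcomes(10, 2000, beta0 = 0, seed = 22)
  expect_equal(mean(s3$complexity), 0.5, tolerance = 0.02)
  # strong positive age effect raises complexity with age
  s4 <- simulate_complexity_outcomes(10, 2000, beta_age = 0.5, beta0 = -1.5,
                                     seed = 23)
  m <- tapply(s4$complexity, s4$age_months, mean)
  expect_true(m[["6"]] > m[["1"]])
  expect_error(simulate_complexity_outcomes(0, 10), "n_infants")
})
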