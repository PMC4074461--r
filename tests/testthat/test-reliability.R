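test_that("ICC equals the brute-force ANOVA oracle on small matrices", {
  set.seed(21)
  for (rep in 1:15) {
    n <- sample(3:8, 1); k <- sample(2:4, 1)
    m <- matrix(sample(0:9, n * k, replace = TRUE), n, k)
    if (stats::var(as.vector(m)) == 0) next
    for (def in c("agreement", "consistency")) {
      expect_equal(icc_twoway(m, def)$icc, oracle_icc(m, def),
                   tolerance = 1e-10)
    }
    # average-measure unit is the Spearman-Brown step-up of the single form
    r1 <- oracle_icc(m, "consistency")
    expect_equal(icc_twoway(m, "consistency", "average")$icc,
                 k * r1 / (1 + (k - 1) * r1), tolerance = 1e-10)
  }
  # the fixed 6x2 integer fixture
  m <- cbind(c(9, 6, 8, 7, 10, 6), c(2, 1, 4, 1, 5, 2))
  expect_equal(icc_twoway(m, "agreement")$icc, oracle_icc(m, "agreement"),
               tolerance = 1e-10)
})

test_that("ICC hits its boundary cases", {
  col <- c(3, 7, 5, 9, 4, 8)
  perfect <- icc_twoway(cbind(col, col))
  expect_equal(perfect$icc, 1)
  expect_true(perfect$ci_low <= 1 && perfect$ci_high >= perfect$icc)
  # zero subject variance: independent noise columns, large n
  set.seed(22)
  noise <- cbind(rnorm(500), rnorm(500))
  expect_lt(abs(icc_twoway(noise)$icc), 0.1)
  expect_error(icc_twoway(matrix(5, 4, 2)), class = "swayboard_icc_error")
  expect_error(icc_twoway(matrix(1:4, 1, 4)), class = "swayboard_shape_error")
  expect_error(icc_twoway(cbind(c(1, 2, NA), c(2, 3, 4))),
               class = "swayboard_shape_error")
})

test_that("agreement penalizes a column offset, consistency forgives it", {
  set.seed(23)
  base <- rnorm(12, 50, 8)
  m <- cbind(base, base + rnorm(12, 0, 2))
  shifted <- m; shifted[, 2] <- shifted[, 2] + 10
  # adding a constant to ALL entries changes nothing
  all_shift <- icc_twoway(m + 100)
  expect_equal(all_shift$icc, icc_twoway(m)$icc, tolerance = 1e-10)
  # one-column offset: agreement falls, consistency identical
  expect_lt(icc_twoway(shifted, "agreement")$icc,
            icc_twoway(m, "agreement")$icc)
  expect_equal(icc_twoway(shifted, "consistency")$icc,
               icc_twoway(m, "consistency")$icc, tolerance = 1e-10)
})

test_that("ICC banding uses the 0.80 / 0.60 clinical thresholds", {
  expect_equal(classify_icc(0.918), "high")
  expect_equal(classify_icc(0.731), "moderate")
  expect_equal(classify_icc(0.80), "high")      # half-open band edges
  expect_equal(classify_icc(0.60), "moderate")
  expect_equal(classify_icc(0.599), "low")
  expect_equal(classify_icc(-0.2), "low")
  expect_error(classify_icc(NaN), class = "swayboard_parameter_error")
})

test_that("SEM follows SD * sqrt(1 - ICC) with repeated-measures scaling", {
  expect_equal(sem(10, 0.84), 4)
  expect_equal(sem(10, 0.84, n_repeats = 3), 4 * sqrt(3))
  expect_equal(sem(123, 1), 0)
  expect_equal(sem(7, 0), 7)          # SEM equals SD at ICC 0
  # monotone decreasing in ICC for fixed SD
  iccs <- seq(0, 1, by = 0.1)
  expect_true(all(diff(sem(10, iccs)) < 0))
  expect_warning(out <- sem(10, -0.1), "clamped")
  expect_equal(out, 10)
  expect_error(sem(-1, 0.5), class = "swayboard_parameter_error")
})

test_that("paired differences use the second-minus-first sign convention", {
  a <- c(36, 40, 44); b <- c(34, 41, 42)
  pd <- paired_difference(a, b)
  expect_equal(pd$diff_mean, mean(b - a))
  expect_equal(pd$diff_sd, stats::sd(b - a))
  same <- paired_difference(a, a)
  expect_equal(same$diff_mean, 0)
  expect_equal(same$diff_sd, 0)
  # closed-form t oracle on a seed-fixed normal sample
  set.seed(24)
  x <- rnorm(20); y <- x + rnorm(20, 0.3)
  pd <- paired_difference(x, y)
  d <- y - x
  expect_equal(pd$t, mean(d) / (stats::sd(d) / sqrt(20)), tolerance = 1e-10)
  expect_equal(pd$p_value, stats::t.test(y, x, paired = TRUE)$p.value,
               tolerance = 1e-12)
  expect_error(paired_difference(1:3, 1:4), class = "swayboard_pairing_error")
})

test_that("Bland-Altman limits behave as bias +/- 1.96 SD", {
  a <- c(10, 20, 30, 40)
  ba <- bland_altman(a, a + 2)
  expect_equal(ba$bias, 2)
  expect_equal(ba$sd_diff, 0)
  expect_equal(c(ba$loa_low, ba$loa_high), c(2, 2))
  ident <- bland_altman(a, a)
  expect_equal(c(ident$bias, ident$loa_low, ident$loa_high), c(0, 0, 0))
  expect_equal(ba$pairs$mean, a + 1)
  # normal coverage: ~95% of differences inside the LOAs
  set.seed(25)
  base <- rnorm(10000, 50, 5)
  diff <- rnorm(10000, 1, 2)
  ba <- bland_altman(base, base + diff)
  inside <- mean(diff >= ba$loa_low & diff <= ba$loa_high)
  expect_equal(inside, 0.95, tolerance = 0.0101)
})

test_that("a noiseless study yields a perfect report", {
  d <- study_design(n_subjects = 8, sigma_session = 0, sigma_error = 0,
                    device_scale = 1, device_bias = 0, seed = 26)
  rep <- reliability_report(summarize_trials(simulate_study(d)))
  expect_equal(nrow(rep), 8 * 3)      # 4 tasks x 2 metrics x 3 comparisons
  expect_equal(rep$icc, rep(1, 24))
  expect_equal(rep$sem, rep(0, 24))
  expect_equal(rep$diff_mean, rep(0, 24))
  expect_equal(unique(rep$band), "high")
})

test_that("report cells equal the composition of the individual operations", {
  d <- study_design(n_subjects = 12, seed = 27)
  summ <- summarize_trials(simulate_study(d))
  rep <- reliability_report(summ)
  row <- rep[rep$comparison == "validity" & rep$task == "SOCE" &
               rep$metric == "PL", ]
  m <- ratings_matrix(summ, "SOCE", "pl_cm", c("A1", "A3"))
  a <- m[, 1]; b <- m[, 2]
  icc <- icc_twoway(m, "agreement", "single")
  pd <- paired_difference(a, b)
  expect_equal(row$icc, icc$icc)
  expect_equal(row$ci_low, icc$ci_low)
  expect_equal(row$diff_mean, pd$diff_mean)
  expect_equal(row$p, pd$p_value)
  expect_equal(row$sem,
               sem(sqrt((sd(a)^2 + sd(b)^2) / 2), icc$icc))
  expect_equal(row$icc_consistency, icc_twoway(m, "consistency")$icc)
  expect_equal(row$band, classify_icc(icc$icc))
})

test_that("subjects with missing cells are dropped from the ratings matrix", {
  d <- study_design(n_subjects = 6, seed = 28)
  summ <- summarize_trials(simulate_study(d))
  summ <- summ[!(summ$subject == "S03" & summ$session == "B" &
                   summ$task == "STOE"), ]
  expect_message(m <- ratings_matrix(summ, "STOE", "pl_cm", c("A1", "B")),
                 "dropped 1 subject")
  expect_equal(nrow(m), 5)
  expect_false("S03" %in% rownames(m))
  expect_equal(attr(m, "n_dropped"), 1L)
  expect_error(ratings_matrix(summ, "STOE", "pl_cm", c("A1", "Z9")),
               class = "swayboard_design_error")
})
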