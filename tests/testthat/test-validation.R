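test_that("Dice matches direct counting and handles degenerate inputs", {
  a <- array(FALSE, c(4, 4, 4)); b <- a
  a[1:2, 1:2, 1:2] <- TRUE            # |A| = 8
  b[2:3, 1:2, 1:2] <- TRUE            # |B| = 8, |A n B| = 4
  expect_equal(dice(a, b), 0.5)
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, b), dice(b, a))
  disj <- array(FALSE, c(4, 4, 4)); disj[4, 4, 4] <- TRUE
  expect_equal(dice(a, disj), 0)
  empty <- array(FALSE, c(4, 4, 4))
  expect_equal(dice(empty, empty), 1)
  expect_error(dice(a, array(FALSE, c(3, 3, 3))), "shapes differ")
})

test_that("sensitivity counts recovered reference voxels", {
  ref <- array(FALSE, c(3, 3, 3)); ref[, 1, ] <- TRUE  # 9 voxels
  auto <- ref; auto[3, 1, 3] <- FALSE                  # 8 recovered
  expect_equal(sensitivity(auto, ref), 8 / 9)
  expect_equal(sensitivity(ref, ref), 1)
  none <- array(FALSE, c(3, 3, 3))
  expect_equal(sensitivity(none, ref), 0)
  expect_error(sensitivity(auto, none), "empty")
})

test_that("exact Mann-Whitney p-values match brute-force enumeration", {
  set.seed(91)
  for (rep in 1:20) {
    n1 <- sample(2:5, 1); n2 <- sample(2:7, 1)
    x <- sample(seq(1, 400), n1); y <- sample(seq(401, 800), n2) - sample(400, n2)
    while (any(duplicated(c(x, y)))) y <- y + stats::runif(n2, 0, 0.5)
    mw <- mann_whitney(x, y)
    expect_equal(mw$p_value, bf_mann_whitney_p(x, y), tolerance = 1e-10)
  }
  # full separation at n = 4 vs 6: exact two-sided p = 2/210
  mw <- mann_whitney(1:4, 11:16)
  expect_equal(mw$U, 0)
  expect_equal(mw$p_value, 2 / 210, tolerance = 1e-12)
  mw2 <- mann_whitney(11:16, 1:4)
  expect_equal(mw2$U, 24)
  expect_equal(mw2$p_value, mw$p_value)
})

test_that("degenerate and tied inputs are handled", {
  expect_equal(mann_whitney(5, 5)$p_value, 1)
  expect_error(mann_whitney(numeric(0), 1), "non-empty")
  tied <- mann_whitney(c(1, 2, 2, 3), c(2, 3, 3, 4))
  expect_equal(tied$method, "normal approximation")
  expect_true(tied$p_value > 0 && tied$p_value <= 1)
})

test_that("type-I error of the exact test at alpha 0.05 is near its discrete level", {
  set.seed(17)
  hits <- 0L
  n_rep <- 2000L
  for (i in seq_len(n_rep)) {
    p <- mann_whitney(rnorm(4), rnorm(6))$p_value
    if (p < 0.05) hits <- hits + 1L
  }
  rate <- hits / n_rep
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("group comparison produces the three contrasts with group summaries", {
  set.seed(5)
  reports <- tibble::tibble(
    case_id = sprintf("c%02d", 1:22),
    midnasal_cm3 = c(rnorm(12, 2.0, 0.3), rnorm(4, 1.45, 0.1), rnorm(6, 0.8, 0.2)),
    nares_cm3 = rnorm(22, 0.4, 0.05))
  groups <- tibble::tibble(case_id = reports$case_id,
                           group = rep(c("normal", "moderate", "severe"),
                                       c(12, 4, 6)))
  cmp <- compare_groups(reports, groups)
  expect_setequal(cmp$parameter, c("midnasal_cm3", "nares_cm3"))
  row <- cmp[cmp$parameter == "midnasal_cm3", ]
  expect_lt(row$p_c, 0.05)
  expect_equal(row$mean_normal, mean(reports$midnasal_cm3[1:12]))
  expect_equal(row$sd_severe, sd(reports$midnasal_cm3[17:22]))
  expect_error(compare_groups(reports,
                              tibble::tibble(case_id = "c01", group = "mild")),
               "unknown group label")
  expect_error(compare_groups(reports[-1, ], groups), "missing case")
  # identical groups: contrasts are non-significant by symmetry
  same <- reports; same$midnasal_cm3 <- 1
  cmp2 <- compare_groups(same, groups)
  expect_equal(cmp2$p_c[cmp2$parameter == "midnasal_cm3"], 1)
})
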