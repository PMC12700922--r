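test_that("Dice coefficient identities and symmetry", {
  x <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2)
  expect_equal(dice(x, x), 1)
  y <- matrix(c(FALSE, FALSE, TRUE, TRUE), 2)
  expect_equal(dice(x, y), 0)
  a <- array(FALSE, c(4, 4)); a[1, 1:4] <- TRUE
  b <- array(FALSE, c(4, 4)); b[1:4, 1] <- TRUE     # |a|=|b|=4, overlap 1...
  expect_equal(dice(a, b), 2 * 1 / 8)
  a2 <- array(FALSE, c(4, 4)); a2[1, 1:4] <- TRUE
  b2 <- array(FALSE, c(4, 4)); b2[1, 3:4] <- TRUE; b2[2, 1:2] <- TRUE
  expect_equal(dice(a2, b2), 0.5)                    # |x|=4, |y|=4, overlap 2
  set.seed(9)
  for (i in 1:10) {
    m1 <- matrix(runif(64) < 0.4, 8); m2 <- matrix(runif(64) < 0.4, 8)
    if (!any(m1) && !any(m2)) next
    expect_equal(dice(m1, m2), dice(m2, m1))
  }
  expect_error(dice(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2)),
               class = "ctpa_value_error")
  expect_error(dice(matrix(TRUE, 2, 2), matrix(TRUE, 3, 3)),
               class = "ctpa_value_error")
})

test_that("ICC(1,1) matches independent ANOVA and a frozen hand computation", {
  # hand-worked 3 subjects x 2 raters: MS_R = 8, MS_w = 0.5,
  # ICC = (8 - 0.5) / (8 + 0.5) = 7.5 / 8.5
  tab <- rbind(c(1, 2), c(3, 4), c(5, 6))
  r <- icc_oneway(tab)
  expect_equal(r$icc, 7.5 / 8.5, tolerance = 1e-12)
  expect_equal(r$icc, icc_oracle_anova(tab), tolerance = 1e-10)

  set.seed(31)
  for (i in 1:20) {
    n <- sample(3:6, 1); k <- sample(2:4, 1)
    tab <- matrix(stats::rnorm(n * k, 10, 3), n, k)
    expect_equal(icc_oneway(tab)$icc, icc_oracle_anova(tab), tolerance = 1e-10)
  }
})

test_that("ICC edge cases: perfect agreement, degenerate, negative", {
  ident <- cbind(c(1, 2, 3, 4), c(1, 2, 3, 4))
  r <- icc_oneway(ident)
  expect_equal(r$icc, 1)
  expect_equal(r$ci95, c(1, 1))
  expect_error(icc_oneway(matrix(2, 3, 2)), class = "ctpa_value_error")
  # within-variance only: ICC comes back negative, as computed
  anti <- rbind(c(0, 10), c(10, 0), c(0, 10), c(10, 0))
  expect_lt(icc_oneway(anti)$icc, 0)
})

test_that("ICC is invariant to location and positive scale", {
  set.seed(77)
  tab <- matrix(stats::rnorm(12, 5, 2), 4, 3)
  base <- icc_oneway(tab)
  expect_equal(icc_oneway(tab + 100)$icc, base$icc, tolerance = 1e-9)
  expect_equal(icc_oneway(tab * 3.7)$icc, base$icc, tolerance = 1e-9)
  expect_equal(icc_oneway(tab * 3.7 + 100)$ci95, base$ci95, tolerance = 1e-9)
})

test_that("simulated two-rater study recovers the variance-ratio ICC", {
  set.seed(123)
  n <- 2000
  subj <- stats::rnorm(n, sd = 1)
  ratings <- cbind(subj + stats::rnorm(n), subj + stats::rnorm(n))
  expect_lt(abs(icc_oneway(ratings)$icc - 0.5), 0.05)
})

test_that("accuracy counts relative agreement and is monotone in tolerance", {
  expect_equal(accuracy(c(1, 2, 3), c(1, 2, 3))$acc, 1)
  manual <- c(1, 1, 1, 1)
  auto <- manual * (1 + c(0.05, 0.08, 0.12, 0.30))
  expect_equal(accuracy(auto, manual, rel_tol = 0.10)$acc, 0.5)
  expect_equal(accuracy(auto, auto)$se, 0)       # constant outcome -> SE 0
  accs <- vapply(c(0.02, 0.06, 0.1, 0.2, 0.4),
                 function(tol) accuracy(auto, manual, rel_tol = tol)$acc,
                 numeric(1))
  expect_true(all(diff(accs) >= 0))
  expect_error(accuracy(1:3, 1:2), class = "ctpa_value_error")
  expect_error(accuracy(1:3, c(1, 0, 2)), class = "ctpa_value_error")
  # bootstrap SE is reproducible and sane for a mixed outcome
  s1 <- accuracy(auto, manual, rel_tol = 0.1)$se
  s2 <- accuracy(auto, manual, rel_tol = 0.1)$se
  expect_identical(s1, s2)
  expect_gt(s1, 0)
})

test_that("Bland-Altman bias, limits and coverage behave as specified", {
  manual <- c(1, 1.5, 2, 2.5)
  ba <- bland_altman(manual + 0.2, manual)
  expect_equal(ba$bias, 0.2)
  expect_equal(ba$loa_low, 0.2)
  expect_equal(ba$loa_high, 0.2)

  ba2 <- bland_altman(c(0, 2), c(1, 1))
  expect_equal(ba2$bias, 0)
  expect_equal(ba2$loa_high, 1.96 * sqrt(2))

  set.seed(42)
  diffs <- stats::rnorm(5000, 0.1, 0.05)
  ba3 <- bland_altman(1 + diffs, rep(1, 5000))
  expect_lt(abs(ba3$bias - 0.1), 0.005)
  covered <- mean(ba3$diffs >= ba3$loa_low & ba3$diffs <= ba3$loa_high)
  expect_gt(covered, 0.94); expect_lt(covered, 0.96)
  expect_error(bland_altman(1, 1), class = "ctpa_value_error")
})

test_that("per-index agreement pairs subjects and reports all statistics", {
  ids <- sprintf("s%02d", 1:12)
  set.seed(8)
  truth <- runif(12, 0.8, 1.6)
  rec <- rbind(
    measurement_records(ids, "RV_LV", truth * (1 + rnorm(12, 0, 0.03)), "auto"),
    measurement_records(ids, "RV_LV", truth * (1 + rnorm(12, 0, 0.03)), "manual"))
  ag <- evaluate_agreement(rec)
  expect_named(ag, "RV_LV")
  expect_equal(ag$RV_LV$n, 12)
  expect_true(ag$RV_LV$icc_ci95[1] <= ag$RV_LV$icc)
  expect_true(ag$RV_LV$icc <= ag$RV_LV$icc_ci95[2])

  # exact agreement: ICC 1, Acc 1, zero bias
  same <- rbind(measurement_records(ids, "SA", truth * 30, "auto"),
                measurement_records(ids, "SA", truth * 30, "manual"))
  ag2 <- evaluate_agreement(same)
  expect_equal(ag2$SA$icc, 1)
  expect_equal(ag2$SA$accuracy, 1)
  expect_equal(ag2$SA$bland_altman$bias, 0)

  # a subject missing its manual value is named in the error
  broken <- rec[-nrow(rec), ]
  expect_error(evaluate_agreement(broken), "s12", class = "ctpa_value_error")
})
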