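test_that("aggregation gives per-sphere means and sample SDs across scanners", {
  res <- lapply(c(0.8, 0.9, 1.0), fake_iq)
  summ <- aggregate_iq(res)
  r <- summ[summ$metric == "RC_mean" & summ$diameter == 37, ]
  expect_equal(r$mean, 0.9)
  expect_equal(r$sd, 0.1)
  expect_equal(r$n, 3)

  expect_error(aggregate_iq(res[1]), class = "nemaiq_insufficient_data")
  bad <- fake_iq(0.9, diameters = c(37, 28))
  expect_error(aggregate_iq(list(res[[1]], bad)), class = "nemaiq_incompatible_results")

  # identical results collapse to zero dispersion
  summ0 <- aggregate_iq(lapply(c(0.9, 0.9, 0.9), fake_iq))
  expect_true(all(summ0$sd == 0))
})

test_that("limits are mean +/- k SD with configurable k", {
  summ <- data.frame(diameter = 37, metric = "RC_mean", mean = 0.9, sd = 0.05, n = 6)
  lims <- derive_limits(summ, k = 2)
  expect_equal(lims$lower, 0.80)
  expect_equal(lims$upper, 1.00)
  expect_equal(lims$upper - lims$lower, 4 * 0.05)

  lims0 <- suppressWarnings(derive_limits(summ, k = 0))
  expect_equal(lims0$lower, lims0$upper)
  expect_warning(derive_limits(data.frame(diameter = 37, metric = "RC_mean",
                                          mean = 0.9, sd = 0, n = 6)),
                 "degenerate")
})

test_that("compliance uses closed intervals and reports percent deviations", {
  res <- lapply(c(0.85, 0.9, 0.95), fake_iq)
  lims <- derive_limits(aggregate_iq(res))
  rep_mid <- check_compliance(fake_iq(0.9), lims)
  expect_true(all(rep_mid$pass))

  # exactly on the lower bound still passes
  lo <- lims$lower[lims$metric == "RC_mean" & lims$diameter_mm == 37]
  at_bound <- fake_iq(0.9)
  at_bound$recovery$RC_mean[1] <- lo
  expect_true(check_compliance(at_bound, lims)$pass[
    check_compliance(at_bound, lims)$metric == "RC_mean" &
    check_compliance(at_bound, lims)$diameter == 37])

  # 5% below the lower bound fails with a -5% deviation
  below <- fake_iq(0.9)
  below$recovery$RC_mean <- lims$lower[lims$metric == "RC_mean"] * 0.95
  rep_b <- check_compliance(below, lims)
  bad <- rep_b[rep_b$metric == "RC_mean", ]
  expect_true(all(!bad$pass))
  expect_equal(bad$deviation_pct, rep(-5, 6), tolerance = 1e-9)

  expect_error(check_compliance(fake_iq(0.9, diameters = 37), lims),
               class = "nemaiq_incomplete_limits")
})

test_that("the shipped Ga-68 limits transcribe the published table", {
  lims <- ga68_limits()
  expect_equal(nrow(lims), 36)
  expect_setequal(unique(lims$family), c("conventional", "advanced"))
  pick <- function(fam, met, d) lims[lims$family == fam & lims$metric == met &
                                       lims$diameter_mm == d, c("lower", "upper")]
  expect_equal(unlist(pick("conventional", "RC_max", 37), use.names = FALSE),
               c(0.91, 1.14))
  expect_equal(unlist(pick("conventional", "RC_mean", 10), use.names = FALSE),
               c(0.20, 0.34))
  expect_equal(unlist(pick("advanced", "RC_max", 13), use.names = FALSE),
               c(0.65, 0.99))
  expect_equal(unlist(pick("advanced", "RC_peak", 17), use.names = FALSE),
               c(0.62, 0.84))
  expect_true(all(lims$lower < lims$upper))
  expect_true(all(lims$lower > 0))

  # midpoints of every band pass; 1% above every upper bound fails everywhere
  adv <- lims[lims$family == "advanced", ]
  mid <- fake_iq(0.5)
  for (m in c("RC_max", "RC_mean", "RC_peak")) {
    sub <- adv[adv$metric == m, ]
    mid$recovery[[m]] <- (sub$lower + sub$upper)[match(mid$recovery$diameter,
                                                       sub$diameter_mm)] / 2
  }
  expect_true(all(check_compliance(mid, lims, family = "advanced")$pass))
  over <- mid
  for (m in c("RC_max", "RC_mean", "RC_peak")) {
    sub <- adv[adv$metric == m, ]
    over$recovery[[m]] <- 1.01 * sub$upper[match(over$recovery$diameter,
                                                 sub$diameter_mm)]
  }
  expect_true(all(!check_compliance(over, lims, family = "advanced")$pass))
})

test_that("percentage difference is signed and reference-scaled", {
  expect_equal(pct_difference(1.08, 1.00), 8)
  expect_equal(pct_difference(0.92, 1.00), -8)
  expect_equal(pct_difference(0.73, 0.73), 0)
  expect_equal(pct_difference(2 * 1.08, 2 * 1.00), 8)  # common rescale
  expect_error(pct_difference(1, 0), class = "nemaiq_invalid_reference")
})

test_that("Welch's t test matches an independent naive implementation", {
  r <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)

  r2 <- welch_t_test(c(1, 2, 3), c(101, 102, 103.01))
  expect_lt(r2$p, 1e-6)

  a <- c(2.1, 1.9, 2.0, 2.2); b <- c(1.0, 1.1, 0.9, 1.2)
  r3 <- welch_t_test(a, b)
  # naive formula oracle
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t_naive <- (mean(a) - mean(b)) / sqrt(va + vb)
  df_naive <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p_naive <- 2 * pt(-abs(t_naive), df_naive)
  expect_equal(r3$t, t_naive, tolerance = 1e-6)
  expect_equal(r3$df, df_naive, tolerance = 1e-6)
  expect_equal(r3$p, p_naive, tolerance = 1e-9)

  # invariant to common positive rescaling
  r4 <- welch_t_test(10 * a, 10 * b)
  expect_equal(r4$t, r3$t, tolerance = 1e-9)
  expect_equal(r4$p, r3$p, tolerance = 1e-9)

  expect_error(welch_t_test(1, c(1, 2)), class = "nemaiq_insufficient_data")
})
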