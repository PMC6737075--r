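# Closed-form balanced 2x2 decomposition used as the ANOVA oracle.
balanced_ss <- function(tab) {
  grand <- mean(tab$value)
  ss_term <- function(f) {
    m <- tapply(tab$value, tab[[f]], mean)
    n <- tapply(tab$value, tab[[f]], length)
    sum(n * (m - grand)^2)
  }
  cellm <- tapply(tab$value, list(tab$genotype, tab$treatment), mean)
  gm <- tapply(tab$value, tab$genotype, mean)
  tm <- tapply(tab$value, tab$treatment, mean)
  ncell <- tapply(tab$value, list(tab$genotype, tab$treatment), length)
  ss_int <- sum(ncell * (sweep(sweep(cellm, 1, gm), 2, tm) + grand)^2)
  pred <- cellm[cbind(tab$genotype, tab$treatment)]
  list(genotype = ss_term("genotype"), treatment = ss_term("treatment"),
       interaction = ss_int, residual = sum((tab$value - pred)^2),
       total = sum((tab$value - grand)^2))
}

test_that("balanced toy data matches the hand-computed decomposition", {
  tab <- make_measurements(cv = c(10, 12), cg = c(20, 22),
                           kv = c(10, 12), kg = c(10, 12))
  res <- two_way_anova(tab)
  a <- res$anova
  get <- function(t, col) a[a$term == t, col]
  # hand-computed: SS = 50 for each effect, residual 8, F = 25, MSE = 2
  expect_equal(get("genotype", "sum_sq"), 50)
  expect_equal(get("treatment", "sum_sq"), 50)
  expect_equal(get("interaction", "sum_sq"), 50)
  expect_equal(get("residual", "sum_sq"), 8)
  expect_equal(get("genotype", "statistic"), 25)
  expect_equal(a$df, c(1, 1, 1, 4))
  # cross-check against the independent closed form
  oracle <- balanced_ss(tab)
  for (t in c("genotype", "treatment", "interaction", "residual"))
    expect_equal(get(t, "sum_sq"), oracle[[t]], tolerance = 1e-12)
})

test_that("the SS decomposition identity holds on random balanced data", {
  set.seed(44)
  for (i in 1:5) {
    tab <- make_measurements(cv = rnorm(4, 10), cg = rnorm(4, 12),
                             kv = rnorm(4, 9), kg = rnorm(4, 11))
    res <- two_way_anova(tab)
    ss <- res$anova$sum_sq
    oracle <- balanced_ss(tab)
    expect_equal(sum(ss), oracle$total, tolerance = 1e-10)
  }
})

test_that("F statistics are invariant to a constant shift of all cells", {
  tab <- make_measurements(cv = c(1, 2, 3), cg = c(4, 5, 7),
                           kv = c(2, 2, 3), kg = c(3, 5, 4))
  f1 <- two_way_anova(tab)$anova$statistic
  tab$value <- tab$value + 100
  f2 <- two_way_anova(tab)$anova$statistic
  expect_equal(f1, f2, tolerance = 1e-9)
})

test_that("degenerate designs are rejected", {
  tab <- make_measurements(cv = c(1, 2), cg = c(3, 4),
                           kv = c(5, 6), kg = c(7, 8))
  expect_error(two_way_anova(tab[tab$genotype != "ko" |
                                   tab$treatment != "glp2", ]),
               "empty design cell")
  one <- make_measurements(cv = c(1, 2), cg = c(3, 4), kv = c(5, 6), kg = 7)
  expect_error(two_way_anova(one), ">= 2")
  flat <- make_measurements(cv = c(1, 1), cg = c(2, 2),
                            kv = c(3, 3), kg = c(4, 4))
  expect_error(two_way_anova(flat), "degenerate")
})

test_that("treatment p-values are uniform under the null (type-I calibration)", {
  ps <- vapply(1:60, function(s) {
    tab <- simulate_morphometry(
      morph_config(means = c(control_vehicle = 1, control_glp2 = 1,
                             ko_vehicle = 1, ko_glp2 = 1),
                   sds = 0.1, n_mice = 4, seed = s))
    a <- two_way_anova(tab)
    a$anova$p_value[a$anova$term == "treatment"]
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("Sidak adjustment matches its closed form and bounds", {
  expect_equal(sidak_adjust(0, 10), 0)
  expect_equal(sidak_adjust(0.2, 1), 0.2)
  expect_equal(sidak_adjust(0.0127, 4), 1 - (1 - 0.0127)^4)
  # agrees with the 3-significant-figure reference value to its rounding
  expect_equal(sidak_adjust(0.0127, 4), 0.0499, tolerance = 2e-3)
  expect_equal(sidak_adjust(1, 3), 1)
  expect_error(sidak_adjust(0.5, 0), "m")
  expect_error(sidak_adjust(1.5, 2), "0, 1")
  set.seed(6)
  p <- runif(30)
  expect_true(all(sidak_adjust(p, 5) >= p))
  # agrees with Bonferroni to first order; the gap is the second-order
  # term, bounded by choose(m, 2) * p^2
  small <- c(1e-4, 1e-3, 0.01)
  for (m in 2:5)
    expect_true(all(abs(m * small - sidak_adjust(small, m)) <=
                      choose(m, 2) * small^2 * (1 + 1e-9) + 1e-15))
})

test_that("ddCt folds follow the definitional identities", {
  ct <- data.frame(sample_id = c("c1", "c2", "t1"),
                   group = c("ctl", "ctl", "trt"),
                   target_ct = c(24, 24, 23), reference_ct = c(18, 18, 18))
  res <- ddct_fold(ct, "ctl")
  expect_equal(res$per_group$fold[res$per_group$group == "ctl"], 1)
  expect_equal(res$per_group$fold[res$per_group$group == "trt"], 2)
  expect_equal(res$per_sample$fold, c(1, 1, 2))
  # generator round-trip, zero noise: exact recovery
  sim <- simulate_ct(4, c(control_vehicle = 1, control_glp2 = 2.5),
                     noise_sd = 0, seed = 1L)
  got <- ddct_fold(sim, "control_vehicle")$per_group
  expect_equal(got$fold[got$group == "control_glp2"], 2.5)
  # folds compose multiplicatively under composed ddCt shifts
  ct2 <- ct
  ct2$target_ct <- ct2$target_ct - c(0, 0, log2(3))
  res2 <- ddct_fold(ct2, "ctl")
  expect_equal(res2$per_group$fold[res2$per_group$group == "trt"], 2 * 3)
  # missing reference is an error naming the sample
  ct$reference_ct[3] <- NA
  expect_error(ddct_fold(ct, "ctl"), "t1")
  expect_error(ddct_fold(ct2, "absent"), "absent")
})

test_that("densitometry normalization anchors the vehicle-control mean at 1", {
  grp <- c("control_vehicle", "control_vehicle", "control_glp2",
           "control_glp2")
  res <- normalize_to_vehicle_control(c(2, 2, 2, 2), c(1, 1, 1, 1), grp)
  expect_equal(res$relative_expression, rep(1, 4))
  res2 <- normalize_to_vehicle_control(c(1, 1, 4, 4.3), c(1, 1, 1, 1), grp)
  treated <- res2$relative_expression[grp == "control_glp2"]
  expect_equal(mean(treated), 4.15)
  # scaling only the internal control must change the result
  res3 <- normalize_to_vehicle_control(c(1, 1, 4, 4.3), c(1, 1, 2, 2), grp)
  expect_false(isTRUE(all.equal(res3$relative_expression,
                                res2$relative_expression)))
  expect_error(normalize_to_vehicle_control(1, 0, "control_vehicle"),
               "positive")
})
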