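test_that("normalization divides by the maximum and floors at 0.01", {
  expect_equal(unname(normalize_profile(c(5, 5, 5, 5))), rep(1, 4))
  expect_equal(unname(normalize_profile(c(0, 50, 100, 25))),
               c(0.01, 0.5, 1.0, 0.25))
  expect_message(out <- normalize_profile(c(0, 0, 0, 0)), "excluded")
  expect_null(out)
  expect_error(normalize_profile(c(-1, 2, 3, 4)), "non-negative")
})

test_that("templates encode the printed baseline and change magnitude", {
  tp <- build_templates()
  expect_equal(unname(tp$cat1_up), c(0.5, 0.8, 0.5, 0.5))
  expect_equal(unname(tp$cat2_up), c(0.5, 0.5, 0.8, 0.8))
  expect_equal(unname(tp$cat1_down), c(0.5, 0.2, 0.5, 0.5))
  expect_equal(unname(tp$cat2_down), c(0.5, 0.5, 0.2, 0.2))
  expect_error(classifier_settings(change_threshold = 0), "positive")
  expect_error(classifier_settings(nochange_threshold = 0.4), "nochange")
  expect_error(classifier_settings(baseline = 0.8), "exceed 1")
})

test_that("template correlation matches hand-derived and oracle values", {
  tp <- build_templates()
  # self-correlation is perfect with a floored, not errored, p-value
  self <- correlate_template(tp$cat1_up, tp$cat1_up)
  expect_equal(self$r, 1)
  expect_equal(self$r_squared, 1)
  expect_gt(self$p_value, 0)
  # hand-computed cross-pattern value
  x <- correlate_template(c(0.5, 0.8, 0.5, 0.5), tp$cat2_up)
  expect_equal(x$r, -1 / sqrt(3))
  # zero-variance profile: correlation undefined, flagged
  flat <- correlate_template(c(0.3, 0.3, 0.3, 0.3), tp$cat1_up)
  expect_false(flat$defined)
  expect_error(correlate_template(c(0.5, 0.8, 0.5, 0.5), rep(0.5, 4)),
               "zero variance")
})

test_that("correlation p-values agree with the t closed form (cor.test oracle)", {
  tp <- build_templates()
  set.seed(201)
  for (i in 1:25) {
    prof <- runif(4)
    if (var(prof) == 0) next
    got <- correlate_template(prof, tp$cat1_up)
    ref <- cor.test(prof, tp$cat1_up)
    expect_equal(got$r, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("the df = 2 significance boundary sits at |r| ~ 0.950", {
  r_crit <- qt(0.975, 2) / sqrt(qt(0.975, 2)^2 + 2)
  expect_equal(r_crit, 0.950, tolerance = 5e-4)
  for (r in c(0.80, 0.90, 0.94, 0.951, 0.97, 0.999)) {
    p <- 2 * pt(-abs(r * sqrt(2 / (1 - r^2))), 2)
    # build a profile with exactly this correlation to cat1_up:
    # r * template + sqrt(1 - r^2) * an orthogonal contrast
    tpl <- build_templates()$cat1_up
    ortho <- c(1, 0, -1, 0)
    ortho <- ortho - mean(ortho)
    ortho <- ortho / sqrt(sum(ortho^2))
    tplc <- (tpl - mean(tpl)) / sqrt(sum((tpl - mean(tpl))^2))
    prof <- r * tplc + sqrt(1 - r^2) * ortho
    got <- correlate_template(prof, tpl)
    expect_equal(got$r, r, tolerance = 1e-10)
    expect_equal(got$p_value, p, tolerance = 1e-10)
    expect_identical(got$p_value < 0.05, r > r_crit)
  }
})

test_that("Pearson affine invariance: a + b * template gives identical r", {
  tp <- build_templates()
  set.seed(77)
  for (i in 1:10) {
    prof <- runif(4)
    a <- runif(1, -2, 2); b <- runif(1, 0.1, 5)
    expect_equal(correlate_template(prof, tp$cat1_up)$r,
                 correlate_template(prof, a + b * tp$cat1_up)$r,
                 tolerance = 1e-10)
  }
})

test_that("threshold arithmetic drives the category call", {
  st <- classifier_settings()
  tp <- build_templates(st)
  cls <- function(p) bbmpattern:::classify_profile(p, tp, st)
  # exact template match
  r1 <- cls(c(0.5, 0.8, 0.5, 0.5))
  expect_equal(r1$category, "cat1_up")
  expect_equal(r1$r_squared, 1)
  # all pairwise differences within the no-change band
  expect_equal(cls(c(0.50, 0.55, 0.50, 0.45))$category, "null")
  # deviation beyond no-change but short of the change threshold
  r3 <- cls(c(0.5, 0.65, 0.5, 0.5))
  expect_equal(r3$category, "unclassified")
  expect_false(r3$change_ok)
  # down-regulated pattern is called as its own category
  expect_equal(cls(c(1, 0.33, 1, 1))$category, "cat1_down")
  expect_equal(cls(c(0.33, 0.33, 1, 1))$category, "cat2_up")
})

test_that("equal template fit is flagged as a tie, never guessed", {
  st <- classifier_settings()
  t1 <- build_templates(st)$cat1_up
  res <- bbmpattern:::classify_profile(c(0.4, 0.9, 0.45, 0.41),
                                       list(cat1_up = t1, cat2_up = t1), st)
  expect_true(res$tie)
  expect_equal(res$category, "unclassified")
})

test_that("every category call satisfies the printed threshold definitions", {
  sim <- simulate_proteome(sim_config(n_proteins = 300, dispersion = 0.01,
                                      prob_down = 0.3, seed = 13L))
  res <- suppressMessages(classify_counts(sim$counts))
  called <- res[res$category %in% c("cat1_up", "cat1_down",
                                    "cat2_up", "cat2_down"), ]
  expect_gt(nrow(called), 0)
  expect_true(all(called$change_ok))
  expect_true(all(called$nochange_ok))
  expect_true(all(called$p_value < 0.05))
  expect_equal(called$r_squared, called$r^2)
})

test_that("classification is invariant to per-protein count scaling", {
  set.seed(31)
  base <- make_counts(list("P1", "G1", 100, 300, 100, 100),
                      list("P2", "G2", 50, 50, 150, 150),
                      list("P3", "G3", 80, 82, 79, 81))
  ref <- suppressMessages(classify_counts(base))
  for (c_mult in c(0.01, runif(3, 0.1, 50), 1000)) {
    scaled <- base
    for (g in bbm_groups()) scaled[[g]] <- scaled[[g]] * c_mult
    got <- suppressMessages(classify_counts(scaled))
    expect_equal(got$category, ref$category)
    expect_equal(got$r, ref$r, tolerance = 1e-10)
    expect_equal(got$fold_glp2_control, ref$fold_glp2_control,
                 tolerance = 1e-10)
  }
})

test_that("fold changes are plain ratios, identical on counts and profiles", {
  expect_equal(fold_change(c(100, 100, 100, 100), "control_glp2",
                           "control_vehicle"), 1)
  expect_equal(fold_change(c(100, 150, 100, 100), "control_glp2",
                           "control_vehicle"), 1.5)
  counts <- c(control_vehicle = 40, control_glp2 = 90,
              ko_vehicle = 10, ko_glp2 = 70)
  prof <- normalize_profile(counts)
  expect_equal(fold_change(counts, "ko_glp2", "control_vehicle"),
               fold_change(prof, "ko_glp2", "control_vehicle"))
  expect_warning(out <- fold_change(c(1, 2, 3, 0), "control_vehicle",
                                    "ko_glp2"), "zero denominator")
  expect_true(is.na(out))
  expect_error(fold_change(counts, "nope", "ko_glp2"), "unknown group")
})

test_that("all-zero proteins are excluded with accounting, not dropped silently", {
  tab <- make_counts(list("P1", "G1", 0, 0, 0, 0),
                     list("P2", "G2", 10, 30, 10, 10))
  expect_message(res <- classify_counts(tab), "excluded")
  expect_equal(nrow(res), 1L)
  expect_equal(attr(res, "excluded"), "P1")
})
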