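test_that("d equals the mean difference over the SD of the differences", {
  s <- paired_sample(c(0, 1, 2), c(1, 2, 4))
  est <- cohens_d_dif(s)
  # differences (1, 1, 2): mean 4/3, SD 1/sqrt(3)
  expect_equal(est$value, (4 / 3) / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(round(est$value, 4), 2.3094)
  expect_equal(unname(est$components["s_dif"]), 0.5774, tolerance = 1e-4)

  expect_error(cohens_d_dif(paired_sample(c(1, 2, 3), c(1, 2, 3))),
               "degenerate")
  expect_error(cohens_d_dif(paired_sample(c(0, 1), c(2, 3))), "degenerate")

  # differences symmetric about zero
  s <- paired_sample(c(0, 0, 0, 0), c(-2, -1, 1, 2))
  expect_equal(cohens_d_dif(s)$value, 0)
})

test_that("SID standardizes each case and averages back to d", {
  s <- paired_sample(c(0, 1, 2), c(1, 2, 4))
  expect_equal(round(sid_scores(s), 4), c(1.7321, 1.7321, 3.4641))
  expect_error(sid_scores(paired_sample(c(1, 2), c(2, 3))), "degenerate")

  set.seed(21)
  for (i in 1:10) {
    s <- random_paired_sample(n = sample(3:30, 1))
    expect_equal(mean(sid_scores(s)), cohens_d_dif(s)$value,
                 tolerance = 1e-12)
  }
})

test_that("RCI uses the error-of-difference denominator", {
  # S_pre = S_post = 1: with r = 0.5 the denominator is exactly 1, with
  # r = 0 it is sqrt(2)
  s0 <- paired_sample(c(-1, 0, 1), c(0, -1, 1))
  expect_equal(rci_scores(s0, reliability = 0.5), difference_scores(s0))
  expect_equal(rci_scores(s0, reliability = 0),
               difference_scores(s0) / sqrt(2))

  set.seed(22)
  s <- random_paired_sample(20)
  r <- cor(s$pre, s$post)
  denom <- sqrt(sd(s$pre)^2 * (1 - r) + sd(s$post)^2 * (1 - r))
  expect_equal(rci_scores(s), difference_scores(s) / denom)

  # supplied reliability overrides the sample correlation
  expect_equal(rci_scores(s, reliability = 0.5),
               difference_scores(s) /
                 sqrt((sd(s$pre)^2 + sd(s$post)^2) * 0.5))
  expect_error(rci_scores(s, reliability = 1), "reliability")
  expect_error(rci_scores(s, reliability = -0.1), "reliability")
  expect_error(rci_scores(paired_sample(c(1, 1, 1), c(1, 2, 3))),
               "degenerate")
})

test_that("reliable-change labels follow the strict cutoff rule", {
  lab <- classify_reliable_change(c(1.7, 1.645, 1.6, -2.1), 1.645, "one")
  expect_equal(as.character(lab),
               c("reliable_improvement", "no_reliable_change",
                 "no_reliable_change", "no_reliable_change"))
  lab <- classify_reliable_change(c(2.0, 1.96, -1.96, -2.1), 1.96, "two")
  expect_equal(as.character(lab),
               c("reliable_improvement", "no_reliable_change",
                 "no_reliable_change", "reliable_worsening"))
  expect_error(classify_reliable_change(1, cutoff = 0), "cutoff")
})

test_that("percentages aggregate labels exactly", {
  lab <- classify_reliable_change(rep(0, 5), 1.645)
  expect_equal(percent_reliable(lab)$value, 0)
  lab <- classify_reliable_change(c(2, rep(0, 24)), 1.645)
  expect_equal(percent_reliable(lab)$value, 4)
  expect_error(percent_reliable(factor(character())), "empty")
  expect_error(percent_reliable(c("yes", "no")), "labels")

  mk <- function(n_up, n_down, n) {
    classify_reliable_change(c(rep(3, n_up), rep(-3, n_down),
                               rep(0, n - n_up - n_down)), 1.96, "two")
  }
  # P+_exp = 40, P-_exp = 5, P+_ctrl = 10, P-_ctrl = 5 -> net 30
  est <- net_percent_reliable(mk(8, 1, 20), mk(2, 1, 20))
  expect_equal(est$value, 30)
  # identical groups cancel exactly
  expect_equal(net_percent_reliable(mk(5, 2, 20), mk(5, 2, 20))$value, 0)
  # the raw range extends to +/-200
  expect_equal(net_percent_reliable(mk(20, 0, 20), mk(0, 20, 20))$value, 200)
})

test_that("interaction F equals the brute-force mixed ANOVA and t^2", {
  set.seed(23)
  for (i in 1:10) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    tg <- two_group_sample(random_paired_sample(n1),
                           random_paired_sample(n2))
    est <- interaction_omega_squared(tg)
    f_pkg <- unname(est$components["f_ab"])
    # oracle 1: full mixed-design ANOVA decomposition via aov()
    expect_equal(f_pkg, aov_interaction_f(tg), tolerance = 1e-8)
    # oracle 2: squared independent-samples t on difference scores
    tt <- t.test(difference_scores(tg$experimental),
                 difference_scores(tg$control), var.equal = TRUE)
    expect_equal(f_pkg, unname(tt$statistic)^2, tolerance = 1e-10)
    # omega^2 formula with N counting every score in the design
    expect_equal(est$value,
                 (f_pkg - 1) / ((f_pkg - 1) + 2 * (n1 + n2)),
                 tolerance = 1e-12)
  }
})

test_that("omega^2 is zero at F = 1 and negative below, untruncated", {
  # n = 2 + 2 groups built so that F is exactly 1
  tg <- two_group_sample(paired_sample(c(0, 0), c(1 + sqrt(2), -1 + sqrt(2))),
                         paired_sample(c(0, 0), c(1, -1)))
  est <- interaction_omega_squared(tg)
  expect_equal(unname(est$components["f_ab"]), 1, tolerance = 1e-12)
  expect_equal(est$value, 0, tolerance = 1e-12)

  # identical group means -> F = 0 -> omega^2 < 0 is retained
  tg <- two_group_sample(paired_sample(c(0, 0), c(1, -1)),
                         paired_sample(c(0, 0), c(1, -1)))
  expect_lt(interaction_omega_squared(tg)$value, 0)

  # near-deterministic separation -> omega^2 approaches 1
  set.seed(24)
  tg <- two_group_sample(
    paired_sample(rep(0, 4), 2 + rnorm(4, sd = 1e-4)),
    paired_sample(rep(0, 4), rnorm(4, sd = 1e-4)))
  expect_gt(interaction_omega_squared(tg)$value, 0.99)

  expect_error(interaction_omega_squared(
    two_group_sample(paired_sample(c(0, 0), c(1, 1)),
                     paired_sample(c(0, 0), c(2, 2)))), "degenerate")
})

test_that("all change statistics are scale and shift invariant", {
  set.seed(25)
  tg <- two_group_sample(random_paired_sample(12), random_paired_sample(10))
  s <- tg$experimental
  transform <- function(ps, a, b) paired_sample(a * ps$pre + b,
                                                a * ps$post + b, ps$case_id)
  s2 <- transform(s, 3.7, 11.3)
  tg2 <- two_group_sample(transform(tg$experimental, 3.7, 11.3),
                          transform(tg$control, 3.7, 11.3))
  expect_equal(cohens_d_dif(s2)$value, cohens_d_dif(s)$value,
               tolerance = 1e-12)
  expect_equal(sid_scores(s2), sid_scores(s), tolerance = 1e-12)
  expect_equal(rci_scores(s2), rci_scores(s), tolerance = 1e-12)
  expect_equal(interaction_omega_squared(tg2)$value,
               interaction_omega_squared(tg)$value, tolerance = 1e-12)
  lab1 <- classify_reliable_change(sid_scores(s), 1.645)
  lab2 <- classify_reliable_change(sid_scores(s2), 1.645)
  expect_equal(percent_reliable(lab2)$value, percent_reliable(lab1)$value)
})

test_that("normal-tail percentages match the analytic oracle", {
  expect_equal(analytic_percent_normal(0, 1.645), 5.0, tolerance = 0.01)
  expect_equal(round(analytic_percent_normal(0.5, 1.645) / 100, 2), 0.13)
  expect_equal(analytic_percent_normal(1.645, 1.645), 50)

  # Monte-Carlo agreement with the population sigma_dif substituted
  set.seed(26)
  s <- simulate_paired_sample(design_condition(0.8, 2e5, 0.5))
  z <- difference_scores(s) / sigma_dif(0.5)
  p <- percent_reliable(classify_reliable_change(z, 1.645))$value
  expected <- analytic_percent_normal(0.8, 1.645)
  mc_se <- 100 * sqrt(expected / 100 * (1 - expected / 100) / 2e5)
  expect_lt(abs(p - expected), 3 * mc_se)
})

test_that("expected percentage of reliable changes rises with delta", {
  set.seed(27)
  deltas <- seq(0, 3.6, by = 0.6)
  mean_pct <- vapply(deltas, function(delta) {
    mean(replicate(200, {
      s <- simulate_paired_sample(design_condition(delta, 25, 0.7))
      percent_reliable(classify_reliable_change(sid_scores(s), 1.645))$value
    }))
  }, numeric(1))
  expect_true(all(diff(mean_pct) > 0))
})

test_that("case_changes assembles the per-case report", {
  set.seed(28)
  s <- random_paired_sample(10)
  cc <- case_changes(s, index = "sid", cutoff = 1.645, tails = "one")
  expect_equal(nrow(cc), 10)
  expect_equal(cc$difference, difference_scores(s))
  expect_equal(cc$sid, sid_scores(s))
  expect_equal(cc$rci, rci_scores(s))
  expect_equal(cc$label,
               classify_reliable_change(sid_scores(s), 1.645, "one"))
  cc2 <- case_changes(s, index = "rci", cutoff = 1.96, tails = "two")
  expect_equal(cc2$label,
               classify_reliable_change(rci_scores(s), 1.96, "two"))
})
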