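test_that("a reduced condition row produces well-formed pairs and fits", {
  res <- run_condition(moment_spec(), rho = 0.5, n = 25,
                       deltas = c(0, 1.8, 3.6), reps = 10, seed = 41)
  expect_s3_class(res, "condition_result")
  expect_equal(nrow(res$pairs), 30)
  expect_setequal(unique(res$pairs$delta), c(0, 1.8, 3.6))
  expect_named(res$fits, c("linear", "quadratic", "cubic", "logistic"))
  for (f in res$fits) expect_s3_class(f, "link_fit")
  expect_true(all(res$pairs$ibc >= 0 & res$pairs$ibc <= 100))
  expect_equal(res$redraws, 0L)
  # defaults: one-tailed 1.645 for the single-group design
  expect_equal(res$cutoff, 1.645)
  expect_equal(res$tails, "one")
})

test_that("control-group rows use omega-squared and the two-tailed rule", {
  # with only two widely separated deltas the saturated logistic family
  # can be unidentifiable; the runner records it and carries on
  suppressWarnings(
    res <- run_condition(moment_spec(), rho = 0.5, n = 10,
                         design = "control_group", deltas = c(0, 3.6),
                         reps = 10, seed = 42))
  expect_equal(res$cutoff, 1.96)
  expect_equal(res$tails, "two")
  expect_true(all(res$pairs$abc < 1))
  # omega^2 may legitimately fall below zero near delta = 0
  expect_true(all(res$pairs$ibc >= -200 & res$pairs$ibc <= 200))
  # large delta separates the groups
  expect_gt(mean(res$pairs$abc[res$pairs$delta == 3.6]),
            mean(res$pairs$abc[res$pairs$delta == 0]))
})

test_that("a single degenerate grid skips fitting with a warning", {
  expect_warning(
    res <- run_condition(moment_spec(), rho = 0.5, n = 25, deltas = 0,
                         reps = 1, seed = 43),
    "skipped")
  expect_equal(nrow(res$pairs), 1)
  expect_true(all(vapply(res$fits, is.null, logical(1))))
})

test_that("condition results are reproducible from the seed", {
  a <- run_condition(moment_spec(skewness = 1, excess_kurtosis = 2),
                     rho = 0.7, n = 15, deltas = c(0, 1), reps = 5,
                     seed = 44)
  b <- run_condition(moment_spec(skewness = 1, excess_kurtosis = 2),
                     rho = 0.7, n = 15, deltas = c(0, 1), reps = 5,
                     seed = 44)
  expect_identical(a$pairs, b$pairs)
})

test_that("the default configuration spans the full factorial grid", {
  cfg <- study_config()
  expect_equal(length(cfg$deltas), 13)
  expect_equal(cfg$deltas, seq(0, 3.6, by = 0.3))
  expect_equal(cfg$ns, c(25L, 50L, 100L))
  expect_equal(cfg$rhos, c(0.5, 0.7, 0.9))
  expect_length(cfg$shapes, 7)
  expect_equal(cfg$reps, 500L)
  expect_equal(length(cfg$deltas) * length(cfg$ns) * length(cfg$rhos) *
                 length(cfg$shapes), 819)
})

test_that("a smoke-scale study runs end to end and is seed-stable", {
  cfg <- study_config(deltas = c(0, 1.8, 3.6), ns = c(10, 20), rhos = 0.5,
                      shapes = study_shapes()["sk+0_kr0"], reps = 10,
                      seed = 45)
  res <- run_study(cfg)
  expect_s3_class(res, "study_result")
  expect_length(res$conditions, 2)
  expect_equal(nrow(res$r_squared), 2)
  expect_equal(nrow(res$coefficients), 2)
  expect_true(all(c("linear", "quadratic", "cubic", "logistic") %in%
                    names(res$r_squared)))
  res2 <- run_study(cfg)
  expect_identical(res$coefficients, res2$coefficients)
})

test_that("study tables and fits serialize to disk", {
  dir <- withr::local_tempdir()
  cfg <- study_config(deltas = c(0, 3.6), ns = 10, rhos = 0.5,
                      shapes = study_shapes()["sk+0_kr0"], reps = 8,
                      seed = 46)
  res <- run_study(cfg)
  paths <- summarize_tables(res, dir)
  expect_true(all(file.exists(paths)))
  coef <- read.csv(paths[["coefficients"]])
  expect_equal(nrow(coef), 1)
  expect_true(all(c("b0", "b0_se", "b1", "b1_se", "r_squared") %in%
                    names(coef)))
  fits <- jsonlite::read_json(paths[["fits"]])
  expect_length(fits, 1)
  expect_length(fits[[1]]$fits, 4)
  meta <- jsonlite::read_json(paths[["metadata"]])
  expect_equal(meta$seed, 46)
  expect_equal(meta$design, "single_group")

  # an empty result still writes tables with headers
  empty <- structure(list(config = cfg, conditions = list(),
                          r_squared = changelink:::empty_r2_table(),
                          coefficients = changelink:::coefficient_table(list())),
                     class = "study_result")
  paths <- summarize_tables(empty, file.path(dir, "empty"))
  expect_equal(nrow(read.csv(paths[["r_squared"]])), 0)
})

test_that("study configurations round-trip through a config file", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "deltas: [0, 0.9, 1.8]",
    "ns: [25]",
    "rhos: [0.7]",
    "shapes:",
    "  - {skewness: 0, excess_kurtosis: 0}",
    "  - {skewness: 2, excess_kurtosis: 9}",
    "reps: 12",
    "design: control_group",
    "index: rci",
    "seed: 99"), path)
  cfg <- read_study_config(path)
  expect_equal(cfg$deltas, c(0, 0.9, 1.8))
  expect_equal(cfg$ns, 25L)
  expect_equal(cfg$reps, 12L)
  expect_equal(cfg$design, "control_group")
  expect_equal(cfg$index, "rci")
  expect_equal(cfg$seed, 99L)
  expect_length(cfg$shapes, 2)
  expect_equal(cfg$shapes[[2]]$skewness, 2)
  expect_equal(cfg$cutoff, 1.96)      # design default applied
})

test_that("binned mean percentages are stable across sample sizes", {
  # the mean percentage at a given delta should not depend on n, only the
  # scatter around it should
  deltas <- c(0.6, 1.2, 1.8)
  r25 <- run_condition(moment_spec(), rho = 0.7, n = 25, deltas = deltas,
                       reps = 60, seed = 47)
  r100 <- run_condition(moment_spec(), rho = 0.7, n = 100, deltas = deltas,
                        reps = 60, seed = 48)
  m25 <- tapply(r25$pairs$ibc, r25$pairs$delta, mean)
  m100 <- tapply(r100$pairs$ibc, r100$pairs$delta, mean)
  expect_lt(max(abs(m25 - m100)), 6)      # Monte-Carlo error at reps = 60

  # while the residual scatter around the linear link shrinks with n
  sd_resid <- function(r) {
    f <- r$fits$linear
    sd(r$pairs$ibc - (f$coefficients[1] + f$coefficients[2] * r$pairs$abc))
  }
  expect_gt(sd_resid(r25), sd_resid(r100))
})

test_that("rci-indexed rows run and track the sid-indexed ones", {
  res <- run_condition(moment_spec(), rho = 0.5, n = 25,
                       deltas = c(0, 1.2, 2.4), reps = 30, index = "rci",
                       seed = 49)
  expect_gt(res$fits$linear$r_squared, 0.8)
  expect_equal(unname(res$fits$linear$coefficients[2]), 29, tolerance = 0.15)
})
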