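#' Configuration of a Monte-Carlo linking study
#'
#' Defaults reproduce the full factorial grid of the calibration study:
#' 13 effect sizes (0 to 3.6 in steps of 0.3) x 3 sample sizes (25, 50,
#' 100) x 3 pre-post correlations (0.5, 0.7, 0.9) x 7 distribution shapes
#' = 819 conditions, with 500 samples each.
#'
#' @param deltas Numeric vector of population effect sizes.
#' @param ns Integer vector of per-group sample sizes.
#' @param rhos Numeric vector of pre-post correlations.
#' @param shapes List of [moment_spec()] objects.
#' @param reps Replicates per (delta, n, rho, shape) cell.
#' @param design `"single_group"` or `"control_group"`.
#' @param index `"sid"` or `"rci"`: the individual change index.
#' @param cutoff,tails Reliable-change rule; `NULL` picks the design
#'   default (1.645 one-tailed for single group, 1.96 two-tailed for
#'   control group).
#' @param injection Effect-injection convention, see
#'   [simulate_paired_sample()].
#' @param seed Master seed; per-condition substreams are derived from it.
#' @return An object of class `"study_config"`.
#' @export
study_config <- function(deltas = seq(0, 3.6, by = 0.3),
                         ns = c(25L, 50L, 100L),
                         rhos = c(0.5, 0.7, 0.9),
                         shapes = study_shapes(),
                         reps = 500L,
                         design = c("single_group", "control_group"),
                         index = c("sid", "rci"),
                         cutoff = NULL, tails = NULL,
                         injection = c("sample_sdif", "population_sdif"),
                         seed = 1L) {
  design <- match.arg(design)
  index <- match.arg(index)
  injection <- match.arg(injection)
  stopifnot(is.numeric(deltas), length(deltas) >= 1L,
            is.numeric(ns), all(ns >= 2), all(ns == floor(ns)),
            is.numeric(rhos), all(abs(rhos) < 1),
            is.list(shapes), length(shapes) >= 1L,
            all(vapply(shapes, inherits, TRUE, "moment_spec")),
            is.numeric(reps), length(reps) == 1L, reps >= 1,
            is.numeric(seed), length(seed) == 1L)
  rule <- cutoff_rule(design, cutoff, tails)
  structure(list(deltas = deltas, ns = as.integer(ns), rhos = rhos,
                 shapes = shapes, reps = as.integer(reps), design = design,
                 index = index, cutoff = rule$cutoff, tails = rule$tails,
                 injection = injection, seed = as.integer(seed)),
            class = "study_config")
}

cutoff_rule <- function(design, cutoff, tails) {
  if (is.null(tails)) tails <- if (design == "single_group") "one" else "two"
  if (is.null(cutoff)) cutoff <- if (tails == "one") 1.645 else 1.96
  tails <- match.arg(tails, c("one", "two"))
  stopifnot(is.numeric(cutoff), length(cutoff) == 1L, cutoff > 0)
  list(cutoff = cutoff, tails = tails)
}

#' @export
print.study_config <- function(x, ...) {
  cat(sprintf(
    paste0("<study_config> %s, index = %s, cutoff = %g (%s-tailed)\n",
           "  %d deltas x %d n x %d rho x %d shapes = %d conditions, ",
           "%d reps each, seed %d\n"),
    x$design, x$index, x$cutoff, x$tails,
    length(x$deltas), length(x$ns), length(x$rhos), length(x$shapes),
    length(x$deltas) * length(x$ns) * length(x$rhos) * length(x$shapes),
    x$reps, x$seed))
  invisible(x)
}

#' Read a study configuration from a YAML or JSON file
#'
#' Recognized keys mirror the [study_config()] arguments; `shapes` is a
#' list of maps with `skewness` and `excess_kurtosis` entries. Missing
#' keys fall back to the defaults.
#'
#' @param path Path to the configuration file.
#' @return A [study_config()].
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- list()
  for (key in c("deltas", "ns", "rhos", "reps", "design", "index",
                "cutoff", "tails", "injection", "seed"))
    if (!is.null(raw[[key]])) args[[key]] <- unlist(raw[[key]])
  if (!is.null(raw$shapes))
    args$shapes <- lapply(raw$shapes, function(s)
      moment_spec(skewness = s$skewness %||% 0,
                  excess_kurtosis = s$excess_kurtosis %||% 0))
  do.call(study_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic per-condition substream seed below 2^31
condition_seed <- function(seed, idx) {
  as.integer((abs(seed) %% 2147483647) * 69069 + idx * 40503) %% 2147483629L
}

#' Run one condition row of the linking study
#'
#' A condition row fixes the marginal shape, pre-post correlation, sample
#' size and design, and sweeps the full vector of effect sizes. For each
#' (delta, replicate) cell one sample is simulated, its average-based
#' change (d or omega-squared) and individual-based change (percentage or
#' net percentage of reliable changes) are computed, and the pooled point
#' cloud (length(deltas) x reps pairs) is fit with all four link families.
#' Degenerate samples (zero variance of the differences, probability ~0
#' under continuous generation) are redrawn once and counted.
#'
#' @param shape A [moment_spec()].
#' @param rho Pre-post correlation.
#' @param n Per-group sample size.
#' @param design `"single_group"` or `"control_group"`.
#' @param deltas Effect sizes swept within the row.
#' @param reps Replicates per delta.
#' @param index `"sid"` or `"rci"`.
#' @param cutoff,tails Reliable-change rule; `NULL` picks the design
#'   default.
#' @param injection Effect-injection convention, see
#'   [simulate_paired_sample()].
#' @param seed Optional seed set before simulation.
#' @return An object of class `"condition_result"`: a list with the
#'   condition descriptors, `pairs` (data.frame `delta`, `rep`, `abc`,
#'   `ibc`), `fits` (one [link_fit()] per family, `NULL` when fitting was
#'   skipped), and `redraws`.
#' @examples
#' \donttest{
#' res <- run_condition(moment_spec(), rho = 0.5, n = 25, reps = 20,
#'                      seed = 1)
#' res$fits$linear
#' }
#' @export
run_condition <- function(shape = moment_spec(), rho = 0.5, n = 25L,
                          design = c("single_group", "control_group"),
                          deltas = seq(0, 3.6, by = 0.3), reps = 500L,
                          index = c("sid", "rci"),
                          cutoff = NULL, tails = NULL,
                          injection = c("sample_sdif", "population_sdif"),
                          seed = NULL) {
  design <- match.arg(design)
  index <- match.arg(index)
  injection <- match.arg(injection)
  stopifnot(reps >= 1, length(deltas) >= 1L)
  rule <- cutoff_rule(design, cutoff, tails)
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(rep = seq_len(reps), delta = deltas)
  abc <- numeric(nrow(grid))
  ibc <- numeric(nrow(grid))
  redraws <- 0L
  for (i in seq_len(nrow(grid))) {
    cond <- design_condition(grid$delta[i], n, rho, shape, design)
    pair <- simulate_measure(cond, index, rule, injection)
    if (is.null(pair)) {                  # degenerate draw: one redraw
      redraws <- redraws + 1L
      pair <- simulate_measure(cond, index, rule, injection)
      if (is.null(pair))
        stop("degenerate sample persisted after redraw in condition ",
             "delta = ", grid$delta[i], call. = FALSE)
    }
    abc[i] <- pair[1]
    ibc[i] <- pair[2]
  }
  pairs <- data.frame(delta = grid$delta, rep = grid$rep,
                      abc = abc, ibc = ibc)
  rng <- if (design == "single_group") c(0, 100) else c(-100, 100)
  families <- c("linear", "quadratic", "cubic", "logistic")
  fits <- stats::setNames(vector("list", 4L), families)
  if (nrow(pairs) >= 4L && diff(range(abc)) > 0 && stats::var(ibc) > 0) {
    for (fam in families) {
      fits[[fam]] <- tryCatch(
        fit_link(abc, ibc, fam, response_range = rng),
        error = function(e) {
          warning(fam, " link fit failed: ", conditionMessage(e),
                  call. = FALSE)
          NULL
        })
    }
  } else {
    warning("too few or degenerate points; link fitting skipped",
            call. = FALSE)
  }
  structure(list(shape = shape, rho = rho, n = as.integer(n),
                 design = design, index = index, cutoff = rule$cutoff,
                 tails = rule$tails, injection = injection, deltas = deltas,
                 reps = as.integer(reps), pairs = pairs, fits = fits,
                 redraws = redraws),
            class = "condition_result")
}

# one simulated sample -> c(abc, ibc), or NULL on a degenerate draw
simulate_measure <- function(cond, index, rule, injection) {
  if (cond$design == "single_group") {
    s <- simulate_paired_sample(cond, injection)
    if (stats::sd(difference_scores(s)) == 0) return(NULL)
    values <- if (index == "sid") sid_scores(s) else rci_scores(s)
    labels <- classify_reliable_change(values, rule$cutoff, rule$tails)
    c(cohens_d_dif(s)$value, percent_reliable(labels)$value)
  } else {
    s <- simulate_two_group_sample(cond, injection)
    de <- difference_scores(s$experimental)
    dc <- difference_scores(s$control)
    if (stats::sd(de) == 0 || stats::sd(dc) == 0 ||
        (stats::var(de) + stats::var(dc)) == 0) return(NULL)
    lab <- lapply(list(s$experimental, s$control), function(g) {
      values <- if (index == "sid") sid_scores(g) else rci_scores(g)
      classify_reliable_change(values, rule$cutoff, rule$tails)
    })
    c(interaction_omega_squared(s)$value,
      net_percent_reliable(lab[[1]], lab[[2]])$value)
  }
}

#' @export
print.condition_result <- function(x, ...) {
  cat(sprintf(
    "<condition_result> %s, g1 = %g, g2 = %g, rho = %g, n = %d; %d pairs\n",
    x$design, x$shape$skewness, x$shape$excess_kurtosis, x$rho, x$n,
    nrow(x$pairs)))
  if (!is.null(x$fits$linear))
    cat(sprintf("  linear link: b0 = %.2f, b1 = %.2f, R^2 = %.3f\n",
                x$fits$linear$coefficients[1], x$fits$linear$coefficients[2],
                x$fits$linear$r_squared))
  invisible(x)
}

#' Run the full linking study over a condition grid
#'
#' Iterates [run_condition()] over every (shape, rho, n) row of the
#' configured grid (each row sweeps all effect sizes), with a
#' deterministic per-row RNG substream derived from the master seed, so
#' results do not depend on execution order. Returns the per-condition
#' results plus aggregate tables: R-squared of the four link families and
#' the linear-link coefficients with standard errors.
#'
#' @param config A [study_config()].
#' @param verbose Print one progress line per condition row.
#' @return An object of class `"study_result"` with elements `config`,
#'   `conditions` (list of [run_condition()] results), `r_squared`
#'   (data.frame) and `coefficients` (data.frame).
#' @examples
#' \donttest{
#' cfg <- study_config(deltas = c(0, 1.8, 3.6), ns = 25,
#'                     rhos = 0.5, shapes = study_shapes()["sk+0_kr0"],
#'                     reps = 25, seed = 7)
#' run_study(cfg)$r_squared
#' }
#' @export
run_study <- function(config = study_config(), verbose = FALSE) {
  stopifnot(inherits(config, "study_config"))
  grid <- expand.grid(shape = seq_along(config$shapes),
                      rho = config$rhos, n = config$ns)
  conditions <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    shape <- config$shapes[[grid$shape[i]]]
    res <- tryCatch(
      run_condition(shape, grid$rho[i], grid$n[i], config$design,
                    config$deltas, config$reps, config$index,
                    config$cutoff, config$tails, config$injection,
                    seed = condition_seed(config$seed, i)),
      error = function(e) e)
    if (inherits(res, "error")) {
      warning("condition row ", i, " failed: ", conditionMessage(res),
              call. = FALSE)
      res <- NULL
    } else if (verbose) {
      message(sprintf("[%d/%d] g1 = %g, g2 = %g, rho = %g, n = %d done",
                      i, nrow(grid), shape$skewness, shape$excess_kurtosis,
                      grid$rho[i], grid$n[i]))
    }
    conditions[[i]] <- res
  }
  structure(list(config = config,
                 conditions = conditions[!vapply(conditions, is.null, TRUE)],
                 r_squared = r_squared_table(conditions),
                 coefficients = coefficient_table(conditions)),
            class = "study_result")
}

r_squared_table <- function(conditions) {
  rows <- lapply(conditions, function(cr) {
    if (is.null(cr)) return(NULL)
    r2 <- vapply(cr$fits, function(f)
      if (is.null(f)) NA_real_ else f$r_squared, numeric(1))
    data.frame(design = cr$design, skewness = cr$shape$skewness,
               excess_kurtosis = cr$shape$excess_kurtosis, rho = cr$rho,
               n = cr$n, linear = r2[["linear"]],
               quadratic = r2[["quadratic"]], cubic = r2[["cubic"]],
               logistic = r2[["logistic"]])
  })
  do.call(rbind, c(rows, list(empty_r2_table())))
}

empty_r2_table <- function() {
  data.frame(design = character(), skewness = numeric(),
             excess_kurtosis = numeric(), rho = numeric(), n = integer(),
             linear = numeric(), quadratic = numeric(), cubic = numeric(),
             logistic = numeric())
}

coefficient_table <- function(conditions) {
  rows <- lapply(conditions, function(cr) {
    if (is.null(cr) || is.null(cr$fits$linear)) return(NULL)
    f <- cr$fits$linear
    data.frame(design = cr$design, skewness = cr$shape$skewness,
               excess_kurtosis = cr$shape$excess_kurtosis, rho = cr$rho,
               n = cr$n, b0 = unname(f$coefficients[1]),
               b0_se = unname(f$standard_errors[1]),
               b1 = unname(f$coefficients[2]),
               b1_se = unname(f$standard_errors[2]),
               r_squared = f$r_squared)
  })
  do.call(rbind, c(rows, list(
    data.frame(design = character(), skewness = numeric(),
               excess_kurtosis = numeric(), rho = numeric(), n = integer(),
               b0 = numeric(), b0_se = numeric(), b1 = numeric(),
               b1_se = numeric(), r_squared = numeric()))))
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result> %s; %d condition rows\n",
              x$config$design, length(x$conditions)))
  if (nrow(x$r_squared) > 0) {
    cat("  R^2 (linear):", sprintf("%.3f", mean(x$r_squared$linear)),
        "on average\n")
  }
  invisible(x)
}

#' Write study tables and fits to disk
#'
#' Emits `r_squared.csv` (fit of the four families per condition row),
#' `linear_coefficients.csv` (intercept/slope with standard errors, the
#' machine-readable calibration table consumed by
#' [convert_effect_to_percentage()]), `fits.json` (all families, all
#' conditions) and `metadata.json` (configuration and seed).
#'
#' @param result A [run_study()] result.
#' @param dir Output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
summarize_tables <- function(result, dir) {
  stopifnot(inherits(result, "study_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(r_squared = file.path(dir, "r_squared.csv"),
             coefficients = file.path(dir, "linear_coefficients.csv"),
             fits = file.path(dir, "fits.json"),
             metadata = file.path(dir, "metadata.json"))
  utils::write.csv(result$r_squared, paths[["r_squared"]], row.names = FALSE)
  utils::write.csv(result$coefficients, paths[["coefficients"]],
                   row.names = FALSE)
  fits <- lapply(result$conditions, function(cr) {
    list(design = cr$design, skewness = cr$shape$skewness,
         excess_kurtosis = cr$shape$excess_kurtosis, rho = cr$rho,
         n = cr$n, index = cr$index, cutoff = cr$cutoff, tails = cr$tails,
         injection = cr$injection, redraws = cr$redraws,
         fits = lapply(Filter(Negate(is.null), cr$fits), function(f)
           list(family = f$family, coefficients = unname(f$coefficients),
                standard_errors = unname(f$standard_errors),
                r_squared = f$r_squared, n_points = f$n_points)))
  })
  jsonlite::write_json(fits, paths[["fits"]], auto_unbox = TRUE, digits = NA)
  cfg <- result$config
  jsonlite::write_json(
    list(design = cfg$design, index = cfg$index, cutoff = cfg$cutoff,
         tails = cfg$tails, injection = cfg$injection,
         deltas = cfg$deltas, ns = cfg$ns,
         rhos = cfg$rhos,
         shapes = lapply(cfg$shapes, function(s)
           list(skewness = s$skewness, excess_kurtosis = s$excess_kurtosis)),
         reps = cfg$reps, seed = cfg$seed,
         package_version = as.character(utils::packageVersion("changelink"))),
    paths[["metadata"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
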