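#' Standard deviation of pre-post differences under unit occasion variances
#'
#' For pre and post scores with unit variance and pre-post Pearson
#' correlation `rho`, the population standard deviation of the difference
#' scores is `sqrt(2 * (1 - rho))`: 1, 0.775 and 0.447 for rho = 0.5, 0.7
#' and 0.9.
#'
#' @param rho Pre-post correlation, in (-1, 1).
#' @return Numeric vector of the same length as `rho`.
#' @export
sigma_dif <- function(rho) {
  stopifnot(is.numeric(rho), all(is.finite(rho)))
  if (any(abs(rho) >= 1))
    stop("`rho` must lie strictly within (-1, 1)", call. = FALSE)
  sqrt(2 * (1 - rho))
}

#' One cell of the simulation design
#'
#' Bundles the parameters of a simulated pre-post condition: the population
#' effect size `delta` (standardized mean of pre-post differences, in units
#' of sigma_dif), the per-group sample size, the population pre-post
#' correlation, the marginal shape, and the design type. In the
#' control-group design the control arm always has a null effect.
#'
#' @param delta Population effect size (>= 0 in the default study grid).
#' @param n Cases per group (integer >= 2).
#' @param rho Population pre-post correlation, in (-1, 1).
#' @param shape A [moment_spec()]; the default study uses unit-variance,
#'   zero-mean shapes.
#' @param design `"single_group"` or `"control_group"`.
#' @param delta_ctrl Effect size of the control arm (fixed at 0).
#' @return An object of class `"design_condition"`.
#' @export
design_condition <- function(delta, n, rho, shape = moment_spec(),
                             design = c("single_group", "control_group"),
                             delta_ctrl = 0) {
  design <- match.arg(design)
  stopifnot(is.numeric(delta), length(delta) == 1L, is.finite(delta),
            is.numeric(n), length(n) == 1L, n == floor(n), n >= 2,
            is.numeric(rho), length(rho) == 1L, is.finite(rho))
  if (abs(rho) >= 1)
    stop("`rho` must lie strictly within (-1, 1)", call. = FALSE)
  if (!inherits(shape, "moment_spec"))
    stop("`shape` must be a moment_spec object", call. = FALSE)
  structure(list(delta = delta, n = as.integer(n), rho = rho, shape = shape,
                 design = design, delta_ctrl = delta_ctrl),
            class = "design_condition")
}

#' @export
print.design_condition <- function(x, ...) {
  cat(sprintf(
    "<design_condition> %s: delta = %g, n = %d, rho = %g, shape (g1 = %g, g2 = %g)\n",
    x$design, x$delta, x$n, x$rho, x$shape$skewness,
    x$shape$excess_kurtosis))
  invisible(x)
}

new_paired_sample <- function(pre, post, case_id = seq_along(pre)) {
  structure(list(case_id = case_id, pre = pre, post = post),
            class = "paired_sample")
}

#' Construct a paired pre/post sample
#'
#' @param pre,post Numeric vectors of equal length (n >= 2).
#' @param case_id Optional case labels; defaults to 1..n.
#' @return An object of class `"paired_sample"`; `as.data.frame()` turns it
#'   into a table with columns `case_id`, `pre`, `post`.
#' @export
paired_sample <- function(pre, post, case_id = seq_along(pre)) {
  stopifnot(is.numeric(pre), is.numeric(post))
  if (length(pre) != length(post))
    stop("`pre` and `post` must have the same length", call. = FALSE)
  if (length(pre) < 2L)
    stop("a paired sample needs at least 2 cases", call. = FALSE)
  if (anyNA(pre) || anyNA(post))
    stop("missing values are not allowed in a paired sample", call. = FALSE)
  if (length(case_id) != length(pre))
    stop("`case_id` must match the number of cases", call. = FALSE)
  new_paired_sample(pre, post, case_id)
}

#' @export
print.paired_sample <- function(x, ...) {
  d <- x$post - x$pre
  cat(sprintf(
    "<paired_sample> n = %d; mean pre = %.3f, mean post = %.3f, mean diff = %.3f\n",
    length(x$pre), mean(x$pre), mean(x$post), mean(d)))
  invisible(x)
}

#' @export
as.data.frame.paired_sample <- function(x, ...) {
  data.frame(case_id = x$case_id, pre = x$pre, post = x$post)
}

#' Difference scores of a paired sample
#'
#' @param sample A [paired_sample()].
#' @return Numeric vector `post - pre`.
#' @export
difference_scores <- function(sample) {
  stopifnot(inherits(sample, "paired_sample"))
  sample$post - sample$pre
}

#' Impose a target correlation on two independent score vectors
#'
#' Applies the Cholesky factor of the 2 x 2 correlation matrix: `x` is
#' returned unchanged and `y` becomes `rho * x + sqrt(1 - rho^2) * y`. The
#' population correlation of the pair is then exactly `rho`. For non-normal
#' marginals the mixing perturbs the skewness and kurtosis of the second
#' variable somewhat; this drift is accepted without correction.
#'
#' @param x,y Numeric vectors of equal length, independently generated.
#' @param rho Target correlation, in (-1, 1).
#' @return A list with components `x` (unchanged) and `y` (mixed).
#' @export
impose_correlation <- function(x, y, rho) {
  stopifnot(is.numeric(x), is.numeric(y), is.numeric(rho),
            length(rho) == 1L, is.finite(rho))
  if (length(x) != length(y))
    stop("`x` and `y` must have the same length", call. = FALSE)
  if (abs(rho) >= 1)
    stop("`rho` must lie strictly within (-1, 1)", call. = FALSE)
  list(x = x, y = rho * x + sqrt(1 - rho^2) * y)
}

#' Inject a standardized mean change into post scores
#'
#' Adds `delta * sigma_dif(rho)` to every post score, so that the
#' population mean of the difference scores becomes `delta` standard
#' deviations of the differences. The population value
#' `sigma_dif = sqrt(2 * (1 - rho))` is used, not a sample estimate,
#' because injection happens at generation time with known parameters.
#'
#' @param y Numeric vector of post scores.
#' @param delta Standardized effect size (finite).
#' @param rho Population pre-post correlation, in (-1, 1).
#' @return Shifted copy of `y`.
#' @export
inject_effect <- function(y, delta, rho) {
  stopifnot(is.numeric(y), is.numeric(delta), length(delta) == 1L,
            is.finite(delta))
  y + delta * sigma_dif(rho)
}

#' Simulate a single-group paired sample
#'
#' Three-step generation: (1) draw two independent score vectors from the
#' Pearson system with the condition's marginal shape; (2) impose the
#' pre-post correlation via the Cholesky mix; (3) shift every post score
#' by `delta` standard deviations of the difference scores. Every case
#' ends up with a different amount of change, centred on the designed
#' effect.
#'
#' With the default `injection = "sample_sdif"` the shift is `delta`
#' times the sample SD of the pre-injection differences, so the realized
#' effect is `delta` in the sample's own difference metric; this is the
#' convention under which the packaged calibration tables were produced.
#' `"population_sdif"` instead shifts by the population value
#' `delta * sqrt(2 * (1 - rho))` via [inject_effect()].
#'
#' @param cond A [design_condition()] with `design = "single_group"`.
#' @param injection `"sample_sdif"` or `"population_sdif"`.
#' @return A [paired_sample()].
#' @examples
#' set.seed(7)
#' s <- simulate_paired_sample(design_condition(1.2, 100, 0.7))
#' mean(difference_scores(s))
#' @export
simulate_paired_sample <- function(cond,
                                   injection = c("sample_sdif",
                                                 "population_sdif")) {
  stopifnot(inherits(cond, "design_condition"))
  injection <- match.arg(injection)
  if (cond$design != "single_group")
    stop("`cond` must be a single_group condition; use ",
         "simulate_two_group_sample() for control-group designs",
         call. = FALSE)
  simulate_arm(cond$n, cond$rho, cond$shape, cond$delta, injection)
}

simulate_arm <- function(n, rho, shape, delta, injection) {
  x_star <- rpearson(n, shape)
  y_star <- rpearson(n, shape)
  m <- impose_correlation(x_star, y_star, rho)
  post <- if (injection == "sample_sdif") {
    m$y + delta * stats::sd(m$y - m$x)
  } else {
    inject_effect(m$y, delta, rho)
  }
  new_paired_sample(m$x, post)
}

#' Simulate a two-group (experimental + control) paired sample
#'
#' Generates two independent paired samples under identical n, correlation
#' and shape; the mean shift is injected into the experimental group only
#' (the control group keeps a null effect).
#'
#' @param cond A [design_condition()] with `design = "control_group"`.
#' @param injection `"sample_sdif"` or `"population_sdif"`; see
#'   [simulate_paired_sample()].
#' @return An object of class `"two_group_sample"`: a list with
#'   `experimental` and `control` [paired_sample()] components.
#' @export
simulate_two_group_sample <- function(cond,
                                      injection = c("sample_sdif",
                                                    "population_sdif")) {
  stopifnot(inherits(cond, "design_condition"))
  injection <- match.arg(injection)
  if (cond$design != "control_group")
    stop("`cond` must be a control_group condition", call. = FALSE)
  structure(
    list(experimental = simulate_arm(cond$n, cond$rho, cond$shape,
                                     cond$delta, injection),
         control = simulate_arm(cond$n, cond$rho, cond$shape,
                                cond$delta_ctrl, injection)),
    class = "two_group_sample")
}

#' Construct a two-group sample from two paired samples
#'
#' @param experimental,control [paired_sample()] objects.
#' @return An object of class `"two_group_sample"`.
#' @export
two_group_sample <- function(experimental, control) {
  stopifnot(inherits(experimental, "paired_sample"),
            inherits(control, "paired_sample"))
  structure(list(experimental = experimental, control = control),
            class = "two_group_sample")
}

#' @export
print.two_group_sample <- function(x, ...) {
  cat("<two_group_sample>\n  experimental: ")
  print(x$experimental)
  cat("  control:      ")
  print(x$control)
  invisible(x)
}

#' @export
as.data.frame.two_group_sample <- function(x, ...) {
  rbind(cbind(as.data.frame(x$experimental), group = "experimental"),
        cbind(as.data.frame(x$control), group = "control"))
}
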