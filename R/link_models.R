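#' Construct a link-function fit from known coefficients
#'
#' Builds a `"link_fit"` object directly from coefficient values, e.g. to
#' apply published calibration coefficients without refitting.
#'
#' @param family `"linear"`, `"quadratic"`, `"cubic"` or `"logistic"`.
#' @param coefficients Numeric vector `(b0, b1, ...)`; its length must
#'   match the family (2, 3, 4, 2 respectively).
#' @param standard_errors Optional standard errors, same length.
#' @param r_squared Optional R-squared in `[0, 1]`.
#' @param n_points Optional number of points the fit is based on.
#' @param response_range Clipping range for predictions: `c(0, 100)` for a
#'   single-group percentage, `c(-100, 100)` for a net percentage.
#' @return An object of class `"link_fit"`.
#' @export
link_fit <- function(family = c("linear", "quadratic", "cubic", "logistic"),
                     coefficients, standard_errors = NULL,
                     r_squared = NA_real_, n_points = NA_integer_,
                     response_range = c(0, 100)) {
  family <- match.arg(family)
  p <- c(linear = 2L, quadratic = 3L, cubic = 4L, logistic = 2L)[[family]]
  stopifnot(is.numeric(coefficients))
  if (length(coefficients) != p)
    stop("a ", family, " link has ", p, " coefficients, got ",
         length(coefficients), call. = FALSE)
  if (!is.null(standard_errors) && length(standard_errors) != p)
    stop("`standard_errors` must match the coefficient count", call. = FALSE)
  if (!is.na(r_squared) && (r_squared < 0 || r_squared > 1))
    stop("`r_squared` must lie in [0, 1]", call. = FALSE)
  stopifnot(length(response_range) == 2L, response_range[1] < response_range[2])
  names(coefficients) <- paste0("b", seq_len(p) - 1L)
  if (!is.null(standard_errors)) names(standard_errors) <- names(coefficients)
  structure(list(family = family, coefficients = coefficients,
                 standard_errors = standard_errors, r_squared = r_squared,
                 n_points = n_points, response_range = response_range),
            class = "link_fit")
}

#' @export
print.link_fit <- function(x, ...) {
  cat(sprintf("<link_fit> %s; n = %s; R^2 = %s\n  coefficients: %s\n",
              x$family,
              ifelse(is.na(x$n_points), "?", x$n_points),
              ifelse(is.na(x$r_squared), "?", sprintf("%.4f", x$r_squared)),
              paste(sprintf("%s = %.4g", names(x$coefficients),
                            x$coefficients), collapse = ", ")))
  invisible(x)
}

#' Fit a link function of individual-based on average-based change
#'
#' Regresses the per-sample individual-based change value (a percentage)
#' on the per-sample average-based effect size. Polynomial families are
#' fit by ordinary least squares; the logistic family,
#' `ibc = 100 / (1 + exp(-(b0 + b1 * abc)))`, by nonlinear least squares
#' with multi-start initialization. R-squared is `1 - SSE/SST` on the raw
#' percentage scale for every family, so families are directly comparable.
#'
#' @param abc Numeric vector of average-based effect sizes (d or
#'   omega-squared), one per simulated or observed sample.
#' @param ibc Numeric vector of percentages (or net percentages), same
#'   length.
#' @param family `"linear"`, `"quadratic"`, `"cubic"` or `"logistic"`.
#' @param response_range Clipping range for later predictions.
#' @return A [link_fit()] with coefficients, standard errors and R-squared.
#' @examples
#' fit <- fit_link(c(0, 1, 2, 3), c(2, 32, 62, 92))
#' predict_percentage(fit, 0.9)
#' @export
fit_link <- function(abc, ibc,
                     family = c("linear", "quadratic", "cubic", "logistic"),
                     response_range = c(0, 100)) {
  family <- match.arg(family)
  stopifnot(is.numeric(abc), is.numeric(ibc))
  if (length(abc) != length(ibc))
    stop("`abc` and `ibc` must have the same length", call. = FALSE)
  if (anyNA(abc) || anyNA(ibc))
    stop("missing values in the points to fit", call. = FALSE)
  p <- c(linear = 2L, quadratic = 3L, cubic = 4L, logistic = 2L)[[family]]
  if (length(abc) < p)
    stop("need at least ", p, " points for a ", family, " fit",
         call. = FALSE)
  if (diff(range(abc)) == 0)
    stop("rank-deficient design: all `abc` values are equal", call. = FALSE)
  sst <- sum((ibc - mean(ibc))^2)
  if (sst == 0)
    stop("degenerate response: `ibc` is constant, R^2 is undefined",
         call. = FALSE)

  if (family == "logistic") {
    cf <- fit_logistic_link(abc, ibc)
    fitted <- 100 / (1 + exp(-(cf$coef[1] + cf$coef[2] * abc)))
    se <- cf$se
    coefs <- cf$coef
  } else {
    degree <- p - 1L
    X <- stats::model.matrix(~ stats::poly(abc, degree, raw = TRUE))
    fit <- stats::lm.fit(X, ibc)
    coefs <- unname(fit$coefficients)
    fitted <- X %*% coefs
    resid <- ibc - fitted
    sigma2 <- sum(resid^2) / (length(ibc) - p)
    se <- sqrt(diag(chol2inv(chol(crossprod(X)))) * sigma2)
  }
  sse <- sum((ibc - fitted)^2)
  link_fit(family, coefs, se, r_squared = 1 - sse / sst,
           n_points = length(abc), response_range = response_range)
}

# logistic least squares with multi-start; returns coef + asymptotic SEs
fit_logistic_link <- function(abc, ibc) {
  dat <- data.frame(abc = abc, ibc = ibc)
  # primary start: OLS on the logit of the clipped response
  z <- log(pmin(pmax(ibc / 100, 0.01), 0.99) /
             (1 - pmin(pmax(ibc / 100, 0.01), 0.99)))
  st0 <- unname(stats::coef(stats::lm(z ~ abc)))
  starts <- rbind(st0, as.matrix(expand.grid(b0 = c(-5, -3, -1, 0),
                                             b1 = c(0.5, 1, 2, 5, 10, 30))))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(ibc ~ 100 / (1 + exp(-(b0 + b1 * abc))),
                        data = dat,
                        start = list(b0 = starts[i, 1], b1 = starts[i, 2]),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      sse <- sum(stats::resid(fit)^2)
      if (is.null(best) || sse < best$sse)
        best <- list(fit = fit, sse = sse)
    }
  }
  if (is.null(best))
    stop("logistic link fit failed to converge from all starting values ",
         "(abc range ", signif(min(abc), 3), " to ", signif(max(abc), 3),
         ", ibc range ", signif(min(ibc), 3), " to ", signif(max(ibc), 3),
         ")", call. = FALSE)
  sm <- summary(best$fit)
  list(coef = unname(stats::coef(best$fit)),
       se = unname(sm$coefficients[, "Std. Error"]))
}

#' Predict a (net) percentage of reliable changes from a link fit
#'
#' Evaluates the fitted family at the given effect size and clips the
#' result to the fit's response range (percentages below 0 or above 100
#' are replaced by the limits; net percentages are clipped to
#' `[-100, 100]`).
#'
#' @param fit A [link_fit()].
#' @param abc Effect-size value(s) at which to predict.
#' @return Clipped percentage(s).
#' @export
predict_percentage <- function(fit, abc) {
  stopifnot(inherits(fit, "link_fit"), is.numeric(abc))
  b <- fit$coefficients
  raw <- switch(fit$family,
    linear = b[1] + b[2] * abc,
    quadratic = b[1] + b[2] * abc + b[3] * abc^2,
    cubic = b[1] + b[2] * abc + b[3] * abc^2 + b[4] * abc^3,
    logistic = 100 / (1 + exp(-(b[1] + b[2] * abc))))
  unname(pmin(pmax(raw, fit$response_range[1]), fit$response_range[2]))
}

#' Packaged linear-link calibration coefficients
#'
#' The linear-link coefficients (intercept, slope and their standard
#' errors) shipped with the package, keyed by design, marginal shape and
#' pre-post correlation. They come from the full calibration study at
#' n = 25 with 500 replicates per effect size, which [run_study()] can
#' regenerate.
#'
#' @return A data.frame with columns `design`, `skewness`,
#'   `excess_kurtosis`, `rho`, `b0`, `b0_se`, `b1`, `b1_se`, `n`, `reps`.
#' @export
link_coefficients <- function() {
  path <- system.file("extdata", "link_coefficients.csv",
                      package = "changelink", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Convert an average-based effect size into a percentage of changes
#'
#' Looks up the linear-link coefficients for the condition nearest to the
#' supplied shape and correlation and applies them, with clipping. This is
#' the "no raw data" conversion: a published d (single-group) or
#' omega-squared (control-group) is turned into an approximate (net)
#' percentage of reliable individual changes. Even when a neighbouring
#' condition is selected the estimate stays close, because the
#' coefficients vary little across conditions.
#'
#' @param value The effect-size estimate (d or omega-squared).
#' @param statistic `"d"` (single-group design) or `"omega_squared"`
#'   (control-group design).
#' @param shape A [moment_spec()] describing the score distribution;
#'   defaults to normal.
#' @param rho Pre-post correlation used to select the table column.
#' @param table Coefficient table, by default [link_coefficients()].
#' @return The clipped percentage, with the selected table row attached as
#'   attribute `"condition"`.
#' @examples
#' \donttest{
#' convert_effect_to_percentage(0.9, "d")                 # about 28%
#' convert_effect_to_percentage(0.4, "omega_squared", rho = 0.7)  # about 63%
#' }
#' @export
convert_effect_to_percentage <- function(value,
                                         statistic = c("d", "omega_squared"),
                                         shape = moment_spec(), rho = 0.5,
                                         table = link_coefficients()) {
  statistic <- match.arg(statistic)
  stopifnot(is.numeric(value), length(value) == 1L, is.finite(value),
            inherits(shape, "moment_spec"))
  design <- if (statistic == "d") "single_group" else "control_group"
  rows <- table[table$design == design, , drop = FALSE]
  if (nrow(rows) == 0L)
    stop("no coefficients for design ", design, call. = FALSE)
  dist2 <- (rows$skewness - shape$skewness)^2 +
    ((rows$excess_kurtosis - shape$excess_kurtosis) / 6)^2 +
    (rows$rho - rho)^2
  row <- rows[which.min(dist2), , drop = FALSE]
  rng <- if (design == "single_group") c(0, 100) else c(-100, 100)
  fit <- link_fit("linear", c(row$b0, row$b1), c(row$b0_se, row$b1_se),
                  response_range = rng)
  out <- predict_percentage(fit, value)
  attr(out, "condition") <- row
  out
}
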