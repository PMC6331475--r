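#' Target moments of a marginal score distribution
#'
#' Container for the first four moments of a score distribution: mean,
#' standard deviation, skewness (g1) and excess kurtosis (g2, normal = 0).
#' These are the population moments handed to the Pearson-system sampler
#' [rpearson()].
#'
#' The pair (g1, g2) must satisfy the moment bound
#' `excess_kurtosis >= skewness^2 - 2`; pairs below the bound correspond to
#' no distribution at all and are rejected.
#'
#' @param mean Population mean, in score units.
#' @param sd Population standard deviation, in score units; must be > 0.
#' @param skewness Population skewness g1 (dimensionless).
#' @param excess_kurtosis Population excess kurtosis g2 (dimensionless;
#'   0 for the normal distribution).
#' @return An object of class `"moment_spec"`.
#' @examples
#' moment_spec()                      # standard normal
#' moment_spec(skewness = 2, excess_kurtosis = 9)
#' @seealso [rpearson()], [pearson_type()], [study_shapes()]
#' @export
moment_spec <- function(mean = 0, sd = 1, skewness = 0, excess_kurtosis = 0) {
  stopifnot(is.numeric(mean), length(mean) == 1L, is.finite(mean),
            is.numeric(sd), length(sd) == 1L, is.finite(sd),
            is.numeric(skewness), length(skewness) == 1L, is.finite(skewness),
            is.numeric(excess_kurtosis), length(excess_kurtosis) == 1L,
            is.finite(excess_kurtosis))
  if (sd <= 0)
    stop("`sd` must be > 0, got ", sd, call. = FALSE)
  if (excess_kurtosis < skewness^2 - 2)
    stop("infeasible moment pair: excess kurtosis (", excess_kurtosis,
         ") is below the moment bound skewness^2 - 2 = ",
         skewness^2 - 2, call. = FALSE)
  structure(list(mean = mean, sd = sd, skewness = skewness,
                 excess_kurtosis = excess_kurtosis),
            class = "moment_spec")
}

#' @export
print.moment_spec <- function(x, ...) {
  cat(sprintf(
    "<moment_spec> mean = %g, sd = %g, skewness = %g, excess kurtosis = %g\n",
    x$mean, x$sd, x$skewness, x$excess_kurtosis))
  invisible(x)
}

#' The seven distribution shapes of the default study grid
#'
#' Unit-variance, zero-mean shapes ranging from extreme negative to extreme
#' positive skewness: (g1, g2) in {(-3, 18), (-2, 9), (-1, 2), (0, 0),
#' (1, 2), (2, 9), (3, 18)}.
#'
#' @return A named list of [moment_spec()] objects.
#' @export
study_shapes <- function() {
  g1 <- c(-3, -2, -1, 0, 1, 2, 3)
  g2 <- c(18, 9, 2, 0, 2, 9, 18)
  out <- Map(function(s, k) moment_spec(0, 1, s, k), g1, g2)
  names(out) <- sprintf("sk%+d_kr%d", g1, g2)
  out
}

# Standardized Pearson-system coefficients for mean 0, variance 1.
# The density solves  p'(x)/p(x) = -(c1 + x) / (c0 + c1 x + c2 x^2)  with
#   c0 = (4 b2 - 3 b1)/A,  c1 = g1 (b2 + 3)/A,  c2 = (2 b2 - 3 b1 - 6)/A,
#   A  = 10 b2 - 12 b1 - 18,   b1 = g1^2,  b2 = g2 + 3,
# which pins the first four moments at (0, 1, g1, g2 + 3).
pearson_coefs <- function(skewness, excess_kurtosis) {
  b1 <- skewness^2
  b2 <- excess_kurtosis + 3
  A <- 10 * b2 - 12 * b1 - 18
  if (abs(A) < 1e-10)
    stop("moment pair lies on a singular boundary of the Pearson plane ",
         "(10*b2 - 12*b1 - 18 = 0); not supported", call. = FALSE)
  list(c0 = (4 * b2 - 3 * b1) / A,
       c1 = skewness * (b2 + 3) / A,
       c2 = (2 * b2 - 3 * b1 - 6) / A)
}

#' Classify a moment pair within the Pearson distribution system
#'
#' Determines which Pearson type (0 = normal, I-VII) generates a
#' distribution with the requested skewness and excess kurtosis, via the
#' roots of the quadratic in the Pearson differential equation.
#'
#' @param spec A [moment_spec()], or a skewness value when
#'   `excess_kurtosis` is also given.
#' @param excess_kurtosis Excess kurtosis, when `spec` is a plain skewness.
#' @return A list of class `"pearson_type"` with elements `type` (integer
#'   0-7), `label`, and the standardized quadratic coefficients.
#' @examples
#' pearson_type(moment_spec())                 # type 0 (normal)
#' pearson_type(1, 2)                          # type IV
#' pearson_type(2, 9)                          # type VI
#' @export
pearson_type <- function(spec, excess_kurtosis = NULL) {
  if (inherits(spec, "moment_spec")) {
    g1 <- spec$skewness; g2 <- spec$excess_kurtosis
  } else {
    g1 <- spec; g2 <- excess_kurtosis
    if (is.null(g2)) stop("supply a moment_spec or both g1 and g2")
  }
  if (g2 < g1^2 - 2)
    stop("infeasible moment pair: excess kurtosis below skewness^2 - 2",
         call. = FALSE)
  if (g2 == g1^2 - 2)
    stop("moment pair lies on the two-point boundary of the Pearson ",
         "system; no continuous distribution exists there", call. = FALSE)
  tol <- 1e-10
  cf <- pearson_coefs(g1, g2)
  type <- if (abs(g1) < tol && abs(g2) < tol) {
    0L
  } else if (abs(cf$c2) < tol) {
    3L                                   # gamma line 2*b2 - 3*b1 - 6 = 0
  } else {
    disc <- cf$c1^2 - 4 * cf$c0 * cf$c2
    if (disc < -tol) {
      if (abs(cf$c1) < tol) 7L else 4L   # no real roots
    } else if (abs(disc) <= tol) {
      5L                                 # double root
    } else {
      r <- quad_roots(cf)
      if (r[1] < 0 && r[2] > 0) {
        if (abs(g1) < tol) 2L else 1L    # bounded support around the mean
      } else {
        6L                               # both roots on one side
      }
    }
  }
  labels <- c("0 (normal)", "I (beta)", "II (symmetric beta)",
              "III (gamma)", "IV", "V (inverse gamma)",
              "VI (beta prime)", "VII (scaled t)")
  structure(list(type = type, label = labels[type + 1L],
                 skewness = g1, excess_kurtosis = g2,
                 c0 = cf$c0, c1 = cf$c1, c2 = cf$c2),
            class = "pearson_type")
}

#' @export
print.pearson_type <- function(x, ...) {
  cat(sprintf("<pearson_type> type %s for g1 = %g, g2 = %g\n",
              x$label, x$skewness, x$excess_kurtosis))
  invisible(x)
}

# stable roots of c0 + c1 x + c2 x^2, sorted increasing
quad_roots <- function(cf) {
  disc <- cf$c1^2 - 4 * cf$c0 * cf$c2
  s <- sqrt(max(disc, 0))
  q <- -(cf$c1 + sign(cf$c1 + (cf$c1 == 0)) * s) / 2
  sort(c(q / cf$c2, cf$c0 / q))
}

# cache of type-IV quantile tables, keyed by "g1|g2"
.pearson_cache <- new.env(parent = emptyenv())

# Unnormalized log-density of the standardized Pearson family when the
# quadratic has no real roots (type IV; type VII is the c1 = 0 special case):
#   log p(x) = -log(Q)/(2 c2) - k * atan((2 c2 x + c1)/s),
#   Q = c0 + c1 x + c2 x^2,  s = sqrt(4 c0 c2 - c1^2),
#   k = c1 (2 c2 - 1) / (c2 s).
pearson_iv_logpdf <- function(x, cf) {
  s <- sqrt(4 * cf$c0 * cf$c2 - cf$c1^2)
  k <- cf$c1 * (2 * cf$c2 - 1) / (cf$c2 * s)
  q <- cf$c0 + cf$c1 * x + cf$c2 * x^2
  -log(q) / (2 * cf$c2) - k * atan((2 * cf$c2 * x + cf$c1) / s)
}

# Quantile table for type IV via trapezoid integration of the closed-form
# log-density on an adaptive grid (bounds grown until the density has
# dropped by 46 log units relative to the mode).
pearson_iv_qtable <- function(cf, n_grid = 20001L) {
  mode <- -cf$c1
  lp_mode <- pearson_iv_logpdf(mode, cf)
  grow <- function(dir) {
    w <- 5
    while (pearson_iv_logpdf(mode + dir * w, cf) - lp_mode > -46 &&
           w < 1e6) w <- w * 1.5
    mode + dir * w
  }
  x <- seq(grow(-1), grow(1), length.out = n_grid)
  p <- exp(pearson_iv_logpdf(x, cf) - lp_mode)
  h <- x[2] - x[1]
  cdf <- c(0, cumsum((p[-1] + p[-length(p)]) / 2)) * h
  cdf <- cdf / cdf[length(cdf)]
  keep <- !duplicated(cdf)
  list(cdf = cdf[keep], x = x[keep])
}

# n standardized draws (mean 0, sd 1) with skewness g1 >= 0, excess kurtosis g2
r_pearson_std <- function(n, g1, g2) {
  pt <- pearson_type(g1, g2)
  cf <- list(c0 = pt$c0, c1 = pt$c1, c2 = pt$c2)
  switch(as.character(pt$type),
    "0" = stats::rnorm(n),
    "1" = ,
    "2" = {                              # beta on (r1, r2)
      r <- quad_roots(cf)
      e1 <- -(cf$c1 + r[1]) / (cf$c2 * (r[1] - r[2]))
      e2 <- -(cf$c1 + r[2]) / (cf$c2 * (r[2] - r[1]))
      if (e1 <= -1 || e2 <= -1)
        stop("degenerate Pearson type I parameters", call. = FALSE)
      r[1] + (r[2] - r[1]) * stats::rbeta(n, e1 + 1, e2 + 1)
    },
    "3" = {                              # gamma: u = c0 + c1 x
      shape <- cf$c0 / cf$c1^2
      u <- stats::rgamma(n, shape = shape, scale = cf$c1^2)
      (u - cf$c0) / cf$c1
    },
    "4" = {
      key <- paste(g1, g2, sep = "|")
      qt <- .pearson_cache[[key]]
      if (is.null(qt)) {
        qt <- pearson_iv_qtable(cf)
        .pearson_cache[[key]] <- qt
      }
      stats::approx(qt$cdf, qt$x, xout = stats::runif(n), rule = 2)$y
    },
    "5" = {                              # inverse gamma above the double root
      r <- -cf$c1 / (2 * cf$c2)
      alpha <- 1 / cf$c2 - 1
      beta <- -(cf$c1 + r) / cf$c2
      if (alpha <= 0 || beta <= 0)
        stop("degenerate Pearson type V parameters", call. = FALSE)
      r + beta / stats::rgamma(n, shape = alpha)
    },
    "6" = {                              # beta prime above the upper root
      r <- quad_roots(cf)
      if (r[2] >= 0)
        stop("unexpected root configuration for Pearson type VI",
             call. = FALSE)
      e1 <- -(cf$c1 + r[1]) / (cf$c2 * (r[1] - r[2]))
      e2 <- -(cf$c1 + r[2]) / (cf$c2 * (r[2] - r[1]))
      a <- e2 + 1
      b <- -(e1 + e2) - 1
      if (a <= 0 || b <= 0)
        stop("degenerate Pearson type VI parameters", call. = FALSE)
      y <- stats::rbeta(n, a, b)
      (r[2] - r[1] * y) / (1 - y)
    },
    "7" = {                              # scaled Student t
      nu <- 1 / cf$c2 - 1
      if (nu <= 2)
        stop("degenerate Pearson type VII parameters", call. = FALSE)
      sqrt(cf$c0 / (1 - cf$c2)) * stats::rt(n, df = nu)
    })
}

#' Sample from the Pearson distribution system
#'
#' Draws independent scores whose population mean, standard deviation,
#' skewness and excess kurtosis equal those of `spec`. The Pearson type is
#' selected from the (skewness, kurtosis) pair; types 0, I, II, III, V, VI
#' and VII are sampled in closed form through beta, gamma and Student-t
#' draws, and type IV by numerical inversion of its closed-form density.
#'
#' @param n Number of draws.
#' @param spec A [moment_spec()] giving the target moments.
#' @return Numeric vector of length `n`.
#' @examples
#' set.seed(1)
#' x <- rpearson(1e4, moment_spec(skewness = 1, excess_kurtosis = 2))
#' mean(x); sd(x)
#' @export
rpearson <- function(n, spec = moment_spec()) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1, n == floor(n))
  if (!inherits(spec, "moment_spec"))
    stop("`spec` must be a moment_spec object", call. = FALSE)
  g1 <- spec$skewness
  z <- if (g1 < 0) -r_pearson_std(n, -g1, spec$excess_kurtosis)
       else r_pearson_std(n, g1, spec$excess_kurtosis)
  spec$mean + spec$sd * z
}

#' Sample moments of a numeric vector
#'
#' Mean, standard deviation (denominator n - 1), skewness
#' g1 = m3 / m2^(3/2) and excess kurtosis g2 = m4 / m2^2 - 3, where mk are
#' central sample moments with denominator n.
#'
#' @param x Numeric vector.
#' @return Named numeric vector with elements `mean`, `sd`, `skewness`,
#'   `excess_kurtosis`.
#' @export
sample_moments <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 2L)
  m <- mean(x)
  d <- x - m
  m2 <- mean(d^2)
  c(mean = m, sd = stats::sd(x),
    skewness = mean(d^3) / m2^1.5,
    excess_kurtosis = mean(d^4) / m2^2 - 3)
}
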