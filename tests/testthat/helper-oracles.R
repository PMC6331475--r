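# Independent oracles used across the suite.

# Independent construction of the Pearson density for a standardized
# (mean 0, variance 1) member with skewness g1 and excess kurtosis g2.
# Solves  p'(x)/p(x) = -(c1 + x)/(c0 + c1 x + c2 x^2)  by partial
# fractions and adaptive quadrature, never touching the package's
# type-specific beta/gamma/t transform samplers. Returns the unnormalized
# log-density, the support, the normalizing constant and the first four
# standardized moments.
ode_pearson_density <- function(g1, g2) {
  b1 <- g1^2; b2 <- g2 + 3
  A <- 10 * b2 - 12 * b1 - 18
  c0 <- (4 * b2 - 3 * b1) / A
  c1 <- g1 * (b2 + 3) / A
  c2 <- (2 * b2 - 3 * b1 - 6) / A

  if (abs(c2) < 1e-12 && abs(c1) < 1e-12) {           # normal
    logp <- function(x) -x^2 / 2
    lo <- -Inf; hi <- Inf
  } else if (abs(c2) < 1e-12) {                       # gamma line
    u <- c0 / c1
    logp <- function(x) -x / c1 + (u - c1) / c1 * log(abs(x + u))
    if (c1 > 0) { lo <- -u; hi <- Inf } else { lo <- -Inf; hi <- -u }
  } else {
    disc <- c1^2 - 4 * c0 * c2
    if (disc < 0) {                                   # no real roots
      s <- sqrt(4 * c0 * c2 - c1^2)
      logp <- function(x)
        -log(c0 + c1 * x + c2 * x^2) / (2 * c2) -
          c1 * (2 * c2 - 1) / (c2 * s) * atan((2 * c2 * x + c1) / s)
      lo <- -Inf; hi <- Inf
    } else {                                          # real roots: residues
      r <- sort(Re(polyroot(c(c0, c1, c2))))
      e1 <- -(c1 + r[1]) / (c2 * (r[1] - r[2]))
      e2 <- -(c1 + r[2]) / (c2 * (r[2] - r[1]))
      logp <- function(x) e1 * log(abs(x - r[1])) + e2 * log(abs(x - r[2]))
      if (r[1] < 0 && r[2] > 0) { lo <- r[1]; hi <- r[2] }
      else if (r[2] < 0) { lo <- r[2]; hi <- Inf }
      else { lo <- -Inf; hi <- r[1] }
    }
  }
  probe <- seq(max(lo, -30) + 1e-6, min(hi, 30) - 1e-6, length.out = 1e4)
  M <- max(logp(probe))
  pu <- function(x) exp(logp(x) - M)
  quad <- function(f) {
    for (tol in c(1e-10, 1e-8, 1e-6)) {
      out <- tryCatch(
        stats::integrate(f, lo, hi, rel.tol = tol,
                         subdivisions = 1000L)$value,
        error = function(e) NULL)
      if (!is.null(out)) return(out)
    }
    stop("quadrature failed")
  }
  Z <- quad(pu)
  mk <- vapply(1:4, function(k) quad(function(x) x^k * pu(x)) / Z,
               numeric(1))
  mu <- mk[1]; v <- mk[2] - mu^2
  list(pu = pu, lo = lo, hi = hi, Z = Z,
       mean = mu, sd = sqrt(v),
       skewness = (mk[3] - 3 * mu * v - mu^3) / v^1.5,
       excess_kurtosis = (mk[4] - 4 * mu * mk[3] + 6 * mu^2 * mk[2] -
                            3 * mu^4) / v^2 - 3)
}

ode_pearson_quantile <- function(dens, probs) {
  cdf <- function(x) stats::integrate(dens$pu, dens$lo, x,
                                      rel.tol = 1e-8,
                                      subdivisions = 1000L)$value / dens$Z
  lo <- if (is.finite(dens$lo)) dens$lo + 1e-9 else -30
  hi <- if (is.finite(dens$hi)) dens$hi - 1e-9 else 30
  vapply(probs, function(q)
    stats::uniroot(function(x) cdf(x) - q, c(lo, hi), tol = 1e-9)$root,
    numeric(1))
}

# Brute-force 2x2 mixed-design interaction F via aov() on long data
aov_interaction_f <- function(tg) {
  long <- rbind(
    data.frame(score = tg$experimental$pre, occasion = "pre",
               group = "e", id = paste0("e", seq_along(tg$experimental$pre))),
    data.frame(score = tg$experimental$post, occasion = "post",
               group = "e", id = paste0("e", seq_along(tg$experimental$pre))),
    data.frame(score = tg$control$pre, occasion = "pre",
               group = "c", id = paste0("c", seq_along(tg$control$pre))),
    data.frame(score = tg$control$post, occasion = "post",
               group = "c", id = paste0("c", seq_along(tg$control$pre))))
  long$occasion <- factor(long$occasion)
  long$group <- factor(long$group)
  long$id <- factor(long$id)
  fit <- stats::aov(score ~ group * occasion + Error(id / occasion),
                    data = long)
  tab <- summary(fit)[["Error: id:occasion"]][[1]]
  tab["group:occasion", "F value"]
}

# random small paired sample with non-degenerate differences
random_paired_sample <- function(n = 8) {
  pre <- stats::rnorm(n, sd = 2)
  paired_sample(pre, pre + stats::rnorm(n, mean = 0.5), seq_len(n))
}
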