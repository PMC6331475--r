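#' Standardized mean pre-post difference (d)
#'
#' The average-based change statistic for a single-group pre-post design:
#' `d = (M_post - M_pre) / S_dif`, where `S_dif` is the sample standard
#' deviation (denominator n - 1) of the difference scores.
#'
#' @param sample A [paired_sample()].
#' @return An object of class `"abc_estimate"` with the statistic value and
#'   its components (`m_pre`, `m_post`, `s_dif`).
#' @examples
#' cohens_d_dif(paired_sample(c(0, 1, 2), c(1, 2, 4)))
#' @export
cohens_d_dif <- function(sample) {
  stopifnot(inherits(sample, "paired_sample"))
  d <- difference_scores(sample)
  s_dif <- stats::sd(d)
  if (s_dif == 0)
    stop("degenerate sample: all difference scores are identical ",
         "(S_dif = 0)", call. = FALSE)
  structure(list(statistic = "d",
                 value = (mean(sample$post) - mean(sample$pre)) / s_dif,
                 components = c(m_pre = mean(sample$pre),
                                m_post = mean(sample$post),
                                s_dif = s_dif)),
            class = "abc_estimate")
}

#' Omega-squared for the group-by-occasion interaction
#'
#' The average-based change statistic for a two-group (experimental vs.
#' control) pre-post design: Hays' omega-squared for the interaction
#' between the between-subjects factor (group) and the within-subjects
#' factor (occasion), estimated as
#' `omega^2 = gl * (F - 1) / (gl * (F - 1) + N)`,
#' where `F` is the interaction F statistic, `gl = 1` its degrees of
#' freedom, and `N` the total number of scores in the design (both groups,
#' both occasions; `N = 4n` with equal groups). For the 2 x 2 mixed design
#' the interaction F equals the squared pooled-variance independent-samples
#' t statistic on the difference scores, which is how it is computed here.
#' Negative estimates (F < 1) are retained, not truncated at zero.
#'
#' @param sample A [two_group_sample()].
#' @return An object of class `"abc_estimate"` with the statistic value and
#'   components (`f_ab`, `gl_ab`, `n_scores`).
#' @export
interaction_omega_squared <- function(sample) {
  stopifnot(inherits(sample, "two_group_sample"))
  d1 <- difference_scores(sample$experimental)
  d2 <- difference_scores(sample$control)
  n1 <- length(d1); n2 <- length(d2)
  sp2 <- ((n1 - 1) * stats::var(d1) + (n2 - 1) * stats::var(d2)) /
    (n1 + n2 - 2)
  if (sp2 == 0)
    stop("degenerate sample: no within-group variance in the difference ",
         "scores", call. = FALSE)
  f_ab <- (mean(d1) - mean(d2))^2 / (sp2 * (1 / n1 + 1 / n2))
  n_scores <- 2L * (n1 + n2)
  structure(list(statistic = "omega_squared",
                 value = (f_ab - 1) / ((f_ab - 1) + n_scores),
                 components = c(f_ab = f_ab, gl_ab = 1, n_scores = n_scores)),
            class = "abc_estimate")
}

#' @export
print.abc_estimate <- function(x, ...) {
  cat(sprintf("<abc_estimate> %s = %.4f\n", x$statistic, x$value))
  invisible(x)
}

#' Standardized individual differences (SID)
#'
#' Each case's pre-post difference divided by the sample standard deviation
#' of the differences: `SID_i = D_i / S_dif`. The mean of the SID values
#' equals the sample `d` exactly.
#'
#' @param sample A [paired_sample()].
#' @return Numeric vector of SID values, one per case.
#' @export
sid_scores <- function(sample) {
  stopifnot(inherits(sample, "paired_sample"))
  d <- difference_scores(sample)
  s_dif <- stats::sd(d)
  if (s_dif == 0)
    stop("degenerate sample: all difference scores are identical ",
         "(S_dif = 0)", call. = FALSE)
  d / s_dif
}

#' Reliable change index (RCI)
#'
#' The variant that does not assume equal pre and post variances:
#' `RCI_i = D_i / sqrt(S_pre^2 * (1 - r) + S_post^2 * (1 - r))`,
#' where `r` is the reliability estimate. By default `r` is the sample
#' pre-post Pearson correlation of the analyzed sample, which yields the
#' lowest false-positive rate; an external reliability (e.g. test-retest
#' from a manual) can be supplied instead.
#'
#' @param sample A [paired_sample()].
#' @param reliability Optional reliability in `[0, 1)`; defaults to the
#'   sample pre-post correlation.
#' @return Numeric vector of RCI values, one per case.
#' @export
rci_scores <- function(sample, reliability = NULL) {
  stopifnot(inherits(sample, "paired_sample"))
  s_pre <- stats::sd(sample$pre)
  s_post <- stats::sd(sample$post)
  if (s_pre == 0 || s_post == 0)
    stop("degenerate sample: zero variance in pre or post scores",
         call. = FALSE)
  r <- if (is.null(reliability)) {
    stats::cor(sample$pre, sample$post)
  } else {
    stopifnot(is.numeric(reliability), length(reliability) == 1L)
    if (reliability < 0 || reliability >= 1)
      stop("`reliability` must lie in [0, 1)", call. = FALSE)
    reliability
  }
  if (r >= 1)
    stop("pre-post correlation is 1; the RCI denominator vanishes",
         call. = FALSE)
  denom <- sqrt(s_pre^2 * (1 - r) + s_post^2 * (1 - r))
  difference_scores(sample) / denom
}

#' Classify individual index values as reliable changes
#'
#' An index value counts as a reliable improvement only if it strictly
#' exceeds the cutoff (values exactly at the cutoff are not reliable
#' changes). With a two-tailed rule, values strictly below `-cutoff` are
#' reliable worsenings; a one-tailed rule never labels worsenings.
#'
#' @param values Numeric vector of SID or RCI values.
#' @param cutoff Positive cutoff (1.645 for one-tailed, 1.96 for two-tailed
#'   decisions at the usual levels).
#' @param tails `"one"` or `"two"`.
#' @return Factor with levels `reliable_improvement`, `no_reliable_change`,
#'   `reliable_worsening`.
#' @export
classify_reliable_change <- function(values, cutoff = 1.645,
                                     tails = c("one", "two")) {
  tails <- match.arg(tails)
  stopifnot(is.numeric(values), is.numeric(cutoff), length(cutoff) == 1L)
  if (cutoff <= 0)
    stop("`cutoff` must be > 0", call. = FALSE)
  lab <- rep("no_reliable_change", length(values))
  lab[values > cutoff] <- "reliable_improvement"
  if (tails == "two") lab[values < -cutoff] <- "reliable_worsening"
  factor(lab, levels = c("reliable_improvement", "no_reliable_change",
                         "reliable_worsening"))
}

check_labels <- function(labels) {
  if (length(labels) == 0L)
    stop("empty label vector", call. = FALSE)
  if (!all(labels %in% c("reliable_improvement", "no_reliable_change",
                         "reliable_worsening")))
    stop("`labels` must come from classify_reliable_change()",
         call. = FALSE)
}

#' Percentage of reliable improvements
#'
#' The individual-based change statistic for a single-group design:
#' `100 * #improvements / n`.
#'
#' @param labels Labels from [classify_reliable_change()].
#' @return An object of class `"ibc_estimate"` with `value` (per cent) and
#'   the improvement/worsening components `p_plus`, `p_minus`.
#' @export
percent_reliable <- function(labels) {
  check_labels(labels)
  p_plus <- 100 * mean(labels == "reliable_improvement")
  p_minus <- 100 * mean(labels == "reliable_worsening")
  structure(list(statistic = "percent", value = p_plus,
                 components = c(p_plus = p_plus, p_minus = p_minus)),
            class = "ibc_estimate")
}

#' Net percentage of reliable changes in a two-group design
#'
#' Improvements minus worsenings in the experimental group, minus the same
#' quantity in the control group:
#' `P_net = (P+_exp - P-_exp) - (P+_ctrl - P-_ctrl)`.
#' The raw value lives in `[-200, 200]`; it is reported unclipped.
#'
#' @param exp_labels,ctrl_labels Labels from [classify_reliable_change()]
#'   for the experimental and control groups.
#' @return An object of class `"ibc_estimate"` with `value` (per cent) and
#'   the four percentage components.
#' @export
net_percent_reliable <- function(exp_labels, ctrl_labels) {
  check_labels(exp_labels)
  check_labels(ctrl_labels)
  p <- c(pe_plus = 100 * mean(exp_labels == "reliable_improvement"),
         pe_minus = 100 * mean(exp_labels == "reliable_worsening"),
         pc_plus = 100 * mean(ctrl_labels == "reliable_improvement"),
         pc_minus = 100 * mean(ctrl_labels == "reliable_worsening"))
  structure(list(statistic = "net_percent",
                 value = unname((p["pe_plus"] - p["pe_minus"]) -
                                  (p["pc_plus"] - p["pc_minus"])),
                 components = p),
            class = "ibc_estimate")
}

#' @export
print.ibc_estimate <- function(x, ...) {
  cat(sprintf("<ibc_estimate> %s = %.2f%%\n", x$statistic, x$value))
  invisible(x)
}

#' Expected percentage of reliable changes under normality
#'
#' When the standardized difference scores are normal with known unit
#' standard deviation and mean `delta`, the expected percentage of values
#' above the cutoff is `100 * (1 - Phi(cutoff - delta))`: 5% at delta = 0
#' and about 13% at delta = 0.5 for the one-tailed cutoff 1.645. Serves as
#' the known-sigma oracle for [percent_reliable()].
#'
#' @param delta Standardized mean of the differences.
#' @param cutoff Cutoff on the standardized scale.
#' @return Percentage (vectorized over `delta`).
#' @export
analytic_percent_normal <- function(delta, cutoff = 1.645) {
  stopifnot(is.numeric(delta), is.numeric(cutoff))
  100 * stats::pnorm(cutoff - delta, lower.tail = FALSE)
}

#' Per-case change report for a paired sample
#'
#' Computes the difference, SID and RCI for every case and classifies each
#' case with the requested index, cutoff and tail rule.
#'
#' @param sample A [paired_sample()].
#' @param index `"sid"` or `"rci"`: which index drives the labels.
#' @param cutoff,tails Passed to [classify_reliable_change()].
#' @param reliability Optional reliability for [rci_scores()].
#' @return A data.frame with columns `case_id`, `pre`, `post`,
#'   `difference`, `sid`, `rci`, `label`.
#' @export
case_changes <- function(sample, index = c("sid", "rci"), cutoff = 1.645,
                         tails = c("one", "two"), reliability = NULL) {
  index <- match.arg(index)
  tails <- match.arg(tails)
  stopifnot(inherits(sample, "paired_sample"))
  sid <- sid_scores(sample)
  rci <- rci_scores(sample, reliability)
  values <- if (index == "sid") sid else rci
  data.frame(case_id = sample$case_id, pre = sample$pre, post = sample$post,
             difference = difference_scores(sample), sid = sid, rci = rci,
             label = classify_reliable_change(values, cutoff, tails))
}
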