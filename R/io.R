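#' Read a table of pre/post scores from CSV
#'
#' Expects a comma-separated, header-bearing file with numeric columns
#' `pre` and `post`, an optional `case_id` column (generated when absent;
#' duplicates are rejected) and an optional `group` column (exactly two
#' distinct labels). Rows with a missing pre or post score are dropped
#' with a warning reporting the count.
#'
#' @param path Path to the CSV file.
#' @return A data.frame with columns `case_id`, `pre`, `post` and, when
#'   present in the file, `group`.
#' @export
read_score_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("pre", "post")) {
    if (!col %in% names(tab))
      stop("column `", col, "` is missing from ", path, call. = FALSE)
    if (!is.numeric(tab[[col]]))
      tab[[col]] <- suppressWarnings(as.numeric(tab[[col]]))
  }
  if (nrow(tab) == 0L)
    stop("empty score table: ", path, call. = FALSE)
  if (!"case_id" %in% names(tab)) tab$case_id <- seq_len(nrow(tab))
  key <- if ("group" %in% names(tab))
    paste(tab$group, tab$case_id) else tab$case_id
  if (anyDuplicated(key))
    stop("duplicated case_id values in ", path, call. = FALSE)
  drop <- is.na(tab$pre) | is.na(tab$post)
  if (any(drop)) {
    warning(sum(drop), " row(s) with missing pre or post scores dropped",
            call. = FALSE)
    tab <- tab[!drop, , drop = FALSE]
  }
  if (nrow(tab) == 0L)
    stop("no complete rows left in ", path, call. = FALSE)
  keep <- intersect(c("case_id", "group", "pre", "post"), names(tab))
  if ("group" %in% keep && length(unique(tab$group)) != 2L &&
      length(unique(tab$group)) != 1L)
    stop("`group` must have exactly two distinct labels (or one for a ",
         "single-group table)", call. = FALSE)
  tab[, keep, drop = FALSE]
}

#' Write a table of pre/post scores to CSV
#'
#' Counterpart of [read_score_table()]; accepts a data.frame, a
#' [paired_sample()] or a [two_group_sample()]. Optionally writes a JSON
#' sidecar of metadata (e.g. the simulation condition and seed) next to
#' the CSV.
#'
#' @param x The scores to write.
#' @param path Output CSV path.
#' @param metadata Optional list serialized to `<path>.json`.
#' @return Invisibly, `path`.
#' @export
write_score_table <- function(x, path, metadata = NULL) {
  if (inherits(x, c("paired_sample", "two_group_sample")))
    x <- as.data.frame(x)
  stopifnot(is.data.frame(x), all(c("pre", "post") %in% names(x)))
  utils::write.csv(x, path, row.names = FALSE)
  if (!is.null(metadata))
    jsonlite::write_json(metadata, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Analyze observed pre/post scores at the group and individual level
#'
#' The recommended reporting sequence for applied data: (a) assess each
#' case's change with SID or RCI, (b) aggregate the individual decisions
#' into a percentage (or net percentage) of reliable changes, and (c)
#' report that individual-based statistic alongside the classical
#' average-based effect size (d for one group, omega-squared for an
#' experimental-vs-control comparison).
#'
#' A table without a `group` column (or with a single label) is treated
#' as a single-group design; with two labels, as a control-group design.
#' By default the lexicographically first label is the control group.
#'
#' @param table A data.frame from [read_score_table()], or anything
#'   coercible (a [paired_sample()] / [two_group_sample()]).
#' @param index `"sid"` or `"rci"`.
#' @param cutoff,tails Reliable-change rule; `NULL` picks the design
#'   default (1.645 one-tailed single group, 1.96 two-tailed two-group).
#' @param reliability Optional external reliability for the RCI.
#' @param experimental Label of the experimental group, when the default
#'   (lexicographically last) is wrong.
#' @param out Optional output directory: writes `cases.csv` (per-case
#'   table) and `summary.json`.
#' @return A list of class `"change_report"` with `design`, `cases`
#'   (per-case data.frame with difference, SID, RCI and label) and
#'   `summary` (named list with the effect size and percentage).
#' @examples
#' set.seed(42)
#' s <- simulate_paired_sample(design_condition(1, 25, 0.7))
#' analyze_change(as.data.frame(s))
#' @export
analyze_change <- function(table, index = c("sid", "rci"), cutoff = NULL,
                           tails = NULL, reliability = NULL,
                           experimental = NULL, out = NULL) {
  index <- match.arg(index)
  if (inherits(table, c("paired_sample", "two_group_sample")))
    table <- as.data.frame(table)
  stopifnot(is.data.frame(table), all(c("pre", "post") %in% names(table)))
  if (!"case_id" %in% names(table)) table$case_id <- seq_len(nrow(table))
  two_group <- "group" %in% names(table) &&
    length(unique(table$group)) == 2L

  if (!two_group) {
    rule <- cutoff_rule("single_group", cutoff, tails)
    if (nrow(table) < 2L)
      stop("need at least 2 cases", call. = FALSE)
    s <- paired_sample(table$pre, table$post, table$case_id)
    cases <- case_changes(s, index, rule$cutoff, rule$tails, reliability)
    abc <- cohens_d_dif(s)
    ibc <- percent_reliable(cases$label)
    summary <- list(design = "single_group", n = nrow(table),
                    index = index, cutoff = rule$cutoff, tails = rule$tails,
                    d = abc$value, percent_reliable = ibc$value,
                    percent_worsened = unname(ibc$components["p_minus"]))
  } else {
    rule <- cutoff_rule("control_group", cutoff, tails)
    labels <- sort(unique(table$group))
    exp_label <- experimental %||% labels[2]
    if (!exp_label %in% labels)
      stop("`experimental` label not present in the data", call. = FALSE)
    ctrl_label <- setdiff(labels, exp_label)
    arms <- lapply(c(exp_label, ctrl_label), function(g) {
      sub <- table[table$group == g, , drop = FALSE]
      if (nrow(sub) < 2L)
        stop("fewer than 2 cases in group ", g, call. = FALSE)
      paired_sample(sub$pre, sub$post, sub$case_id)
    })
    cases <- do.call(rbind, Map(function(s, g) {
      cbind(case_changes(s, index, rule$cutoff, rule$tails, reliability),
            group = g)
    }, arms, c(exp_label, ctrl_label)))
    tg <- two_group_sample(arms[[1]], arms[[2]])
    abc <- interaction_omega_squared(tg)
    ibc <- net_percent_reliable(
      cases$label[cases$group == exp_label],
      cases$label[cases$group == ctrl_label])
    summary <- list(design = "control_group",
                    n_experimental = length(arms[[1]]$pre),
                    n_control = length(arms[[2]]$pre),
                    experimental = exp_label, control = ctrl_label,
                    index = index, cutoff = rule$cutoff, tails = rule$tails,
                    omega_squared = abc$value,
                    f_interaction = unname(abc$components["f_ab"]),
                    net_percent = ibc$value,
                    components = as.list(ibc$components))
  }
  report <- structure(list(design = summary$design, cases = cases,
                           summary = summary),
                      class = "change_report")
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(cases, file.path(out, "cases.csv"), row.names = FALSE)
    jsonlite::write_json(summary, file.path(out, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.change_report <- function(x, ...) {
  s <- x$summary
  if (x$design == "single_group") {
    cat(sprintf(
      paste0("<change_report> single group, n = %d (%s, cutoff %g, ",
             "%s-tailed)\n  d = %.3f; reliable improvements = %.1f%%\n"),
      s$n, toupper(s$index), s$cutoff, s$tails, s$d, s$percent_reliable))
  } else {
    cat(sprintf(
      paste0("<change_report> control-group design, n = %d + %d (%s, ",
             "cutoff %g, %s-tailed)\n  omega^2 = %.3f; ",
             "net percent of changes = %.1f%%\n"),
      s$n_experimental, s$n_control, toupper(s$index), s$cutoff, s$tails,
      s$omega_squared, s$net_percent))
  }
  invisible(x)
}
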