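#' Tidy export of a set of test results
#'
#' Binds heterogeneous one-row statistic tibbles into one tidy table
#' (one row per test) and optionally writes it as CSV, with significance
#' markers at p < 0.01.
#'
#' @param ... Named one-row result tibbles (or lists with a `test`
#'   element, as returned by [group_feature_compare()]).
#' @param file Optional CSV path.
#' @return A tibble: `label`, `method`, `estimate`, `statistic`,
#'   `p_value`, `n`, `significant` (p < 0.01).
#' @export
stats_table <- function(..., file = NULL) {
  inputs <- list(...)
  rows <- purrr::imap(inputs, function(x, label) {
    if (is.list(x) && !is.data.frame(x) && !is.null(x$test)) x <- x$test
    tibble::tibble(
      label = label,
      method = x$method, estimate = x$estimate,
      statistic = x$statistic, p_value = x$p_value, n = x$n
    )
  })
  out <- dplyr::bind_rows(rows)
  out$significant <- !is.na(out$p_value) & out$p_value < 0.01
  if (!is.null(file)) readr::write_csv(out, file)
  out
}

#' Plain-text analysis report
#'
#' Assembles available analysis outputs into a deterministic text summary:
#' group medians with MAD per timing feature, a test table, the best
#' prediction windows per feature panel, and the turnover matrix with its
#' cluster orders. Sections whose inputs are not supplied are omitted.
#'
#' @param features Optional feature tibble from [compute_features()].
#' @param comparisons Optional named list of [group_feature_compare()]
#'   results.
#' @param panel_results Optional tibble from [evaluate_feature_panel()].
#' @param turnover Optional `turnover_matrix`.
#' @param clustering Optional `turnover_clustering`.
#' @param file Optional path to write the report to.
#' @param seed Seed to record in the provenance header.
#' @return Invisibly, the report lines.
#' @export
ck_report <- function(features = NULL, comparisons = NULL,
                      panel_results = NULL, turnover = NULL,
                      clustering = NULL, file = NULL, seed = NA) {
  if (is.null(features) && is.null(comparisons) && is.null(panel_results) &&
      is.null(turnover)) {
    abort("at least one analysis output is required",
          class = "embryokin_argument_error")
  }
  lines <- c(
    "# Cleavage-kinetics analysis report",
    paste0("# embryokin ", as.character(utils::packageVersion("embryokin")),
           " | seed: ", seed),
    ""
  )
  fmt <- function(x, d = 2) formatC(x, format = "f", digits = d)
  if (!is.null(features)) {
    lines <- c(lines, "## Stage durations (median [MAD], n) by group", "")
    feats <- c("cc1", "cc2", "cc3", "cc4", "diff2", "diff3", "diff4")
    for (g in unique(features$group)) {
      sub <- features[features$group == g, ]
      for (f in intersect(feats, names(sub))) {
        v <- sub[[f]]
        v <- v[!is.na(v)]
        if (length(v) == 0) next
        lines <- c(lines, sprintf(
          "%-6s %-6s %s [%s] h, n = %d", g, f, fmt(median(v)),
          fmt(median(abs(v - median(v)))), length(v)
        ))
      }
    }
    lines <- c(lines, "")
  }
  if (!is.null(comparisons)) {
    lines <- c(lines, "## Group comparisons (Wilcoxon rank sum; * p<0.01)", "")
    tab <- do.call(stats_table, comparisons)
    lines <- c(lines, sprintf(
      "%-12s estimate = %s h, p = %s %s", tab$label, fmt(tab$estimate),
      format(tab$p_value, digits = 3), ifelse(tab$significant, "*", "")
    ), "")
  }
  if (!is.null(panel_results)) {
    lines <- c(lines, "## Best prediction windows (by F-score)", "")
    lines <- c(lines, sprintf(
      "%-20s F = %s  accuracy = %s  (n = %d scored, %d excluded)",
      panel_results$features, fmt(panel_results$f_score, 3),
      fmt(panel_results$accuracy, 3), panel_results$n_scored,
      panel_results$n_excluded
    ), "")
  }
  if (!is.null(turnover)) {
    lines <- c(lines, "## Amino-acid turnover (pmol/embryo/h, + = depletion)", "")
    m <- as.matrix(turnover)
    lines <- c(lines,
               paste0(formatC("", width = 5),
                      paste(formatC(colnames(m), width = 11), collapse = "")))
    for (r in rownames(m)) {
      lines <- c(lines, paste0(
        formatC(r, width = 5),
        paste(formatC(fmt(m[r, ]), width = 11), collapse = "")
      ))
    }
    lines <- c(lines, "")
    if (!is.null(clustering)) {
      lines <- c(lines,
        "## Cluster orders",
        paste0("amino acids: ",
               paste(rownames(clustering$ordered), collapse = ", ")),
        paste0("groups: ",
               paste(colnames(clustering$ordered), collapse = ", ")),
        "")
    }
  }
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

#' Cleavage-stage duration plot
#'
#' Median stage lengths with MAD error bars per group and cleavage round —
#' the standard stage-duration summary figure.
#'
#' @param features Feature tibble from [compute_features()].
#' @return A ggplot.
#' @export
plot_stage_durations <- function(features) {
  long <- features |>
    dplyr::select("embryo_id", "group", dplyr::any_of(
      c("cc1", "cc2", "cc3", "cc4", "diff2", "diff3", "diff4")
    )) |>
    tidyr::pivot_longer(-c("embryo_id", "group"),
                        names_to = "feature", values_to = "hours") |>
    dplyr::filter(!is.na(.data$hours))
  summ <- long |>
    dplyr::group_by(.data$group, .data$feature) |>
    dplyr::summarise(
      median = median(.data$hours),
      mad = median(abs(.data$hours - median(.data$hours))),
      n = dplyr::n(), .groups = "drop"
    )
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$feature, y = .data$median,
                                     fill = .data$group)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$median - .data$mad,
                   ymax = .data$median + .data$mad),
      position = ggplot2::position_dodge(width = 0.8), width = 0.25
    ) +
    ggplot2::labs(x = NULL, y = "hours",
                  title = "Cleavage-stage durations (median ± MAD)") +
    ggplot2::theme_minimal()
}
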