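#' Extract cleavage-timing features
#'
#' Computes the per-embryo morphokinetic variable set used throughout the
#' package: division times to given cell counts, per-round mean cell-cycle
#' lengths, inter-stage durations, cleavage-stage lengths, and the duration
#' of the first cytokinesis.
#'
#' Definitions (all times in hours post activation, durations in hours):
#' \describe{
#'   \item{`div1`, `div2_1`, `div2_2`, `div3_1`, `div3_4`, `div4_1`,
#'     `div4_8`}{time the embryo reaches 2, 3, 4, 5, 8, 9 and 16 cells:
#'     the 1st, 2nd, 3rd, 4th, 7th, 8th and 15th order statistic of all
#'     observed division-completion times.}
#'   \item{`cc1`–`cc4`}{per-embryo mean cell-cycle length
#'     (`end_hpa - birth_hpa`) over the cells of cleavage round k; defined
#'     only when all 2^(k-1) cells of that round divided (partial averages
#'     would bias slow embryos — see `partial_cc`).}
#'   \item{`diff2`, `diff3`, `diff4`}{inter-stage durations, i.e. the time
#'     spent at 3 cells (`div2_2 - div2_1`), at 5–7 cells
#'     (`div3_4 - div3_1`), and at 9–15 cells (`div4_8 - div4_1`): a
#'     measure of sister-division synchrony.}
#'   \item{`stage2_len`–`stage4_len`}{entire cleavage-stage lengths,
#'     last-exit to last-exit: `div2_2 - div1`, `div3_4 - div2_2`,
#'     `div4_8 - div3_4`.}
#'   \item{`ck1`}{duration of the first cytokinesis,
#'     `div1 - cytokinesis_onset_hpa` of the root cell.}
#' }
#' Features whose defining events were not observed are `NA`, never
#' imputed. Extraction is invariant to the row order of the input.
#'
#' @param x A `division_table` cohort (any data frame with the division
#'   event columns) or a single [build_lineage()] tree.
#' @param partial_cc If `TRUE`, `cck` is averaged over whichever round-k
#'   cells divided, even when some did not (default `FALSE`).
#' @param ... Unused.
#' @return A tibble with one row per embryo: `embryo_id`, `group`,
#'   `treatment`, outcomes, and the feature columns above.
#' @export
compute_features <- function(x, ...) UseMethod("compute_features")

#' @rdname compute_features
#' @export
compute_features.division_table <- function(x, partial_cc = FALSE, ...) {
  compute_features.data.frame(x, partial_cc = partial_cc, ...)
}

#' @rdname compute_features
#' @export
compute_features.data.frame <- function(x, partial_cc = FALSE, ...) {
  df <- tibble::as_tibble(x)
  if (!"cytokinesis_onset_hpa" %in% names(df)) df$cytokinesis_onset_hpa <- NA_real_
  meta_cols <- intersect(c("group", "treatment", "blastocyst", "esc", "fetus"),
                         names(df))
  meta <- dplyr::distinct(df, dplyr::across(dplyr::all_of(c("embryo_id", meta_cols))))
  feats <- df |>
    dplyr::group_by(.data$embryo_id) |>
    dplyr::summarise(
      .feat = list(features_one(
        .data$cell_id, .data$birth_hpa, .data$end_hpa, .data$fate,
        .data$cytokinesis_onset_hpa, partial_cc = partial_cc
      )),
      .groups = "drop"
    ) |>
    tidyr::unnest_wider(".feat")
  out <- dplyr::left_join(meta, feats, by = "embryo_id")
  # preserve first-appearance embryo order of the input
  out[match(unique(df$embryo_id), out$embryo_id), ]
}

#' @rdname compute_features
#' @export
compute_features.lineage_tree <- function(x, partial_cc = FALSE, ...) {
  nd <- x$nodes
  f <- features_one(nd$cell_id, nd$birth_hpa, nd$end_hpa, nd$fate,
                    nd$cytokinesis_onset_hpa, partial_cc = partial_cc)
  tibble::tibble(
    embryo_id = x$embryo_id, group = x$group, treatment = x$treatment,
    blastocyst = x$blastocyst, esc = x$esc, fetus = x$fetus,
    !!!f
  )
}

# feature arithmetic for one embryo's cell vectors
features_one <- function(cell_id, birth, end, fate, cyt_onset,
                         partial_cc = FALSE) {
  divided <- fate == "divided"
  div_t <- sort(end[divided])
  nd <- length(div_t)
  ord <- function(k) if (nd >= k) div_t[[k]] else NA_real_
  div1 <- ord(1); div2_1 <- ord(2); div2_2 <- ord(3)
  div3_1 <- ord(4); div3_4 <- ord(7)
  div4_1 <- ord(8); div4_8 <- ord(15)

  rounds <- cell_round(cell_id)
  cc <- vapply(1:4, function(k) {
    sel <- rounds == k
    n_expected <- 2^(k - 1)
    if (!any(sel)) return(NA_real_)
    if (partial_cc) {
      if (!any(sel & divided)) return(NA_real_)
      return(mean(end[sel & divided] - birth[sel & divided]))
    }
    if (sum(sel) == n_expected && all(divided[sel])) {
      mean(end[sel] - birth[sel])
    } else {
      NA_real_
    }
  }, numeric(1))

  root_onset <- cyt_onset[rounds == 1]
  ck1 <- if (length(root_onset) == 1 && !is.na(root_onset) && !is.na(div1)) {
    div1 - root_onset
  } else {
    NA_real_
  }

  list(
    div1 = div1, div2_1 = div2_1, div2_2 = div2_2,
    div3_1 = div3_1, div3_4 = div3_4, div4_1 = div4_1, div4_8 = div4_8,
    cc1 = cc[1], cc2 = cc[2], cc3 = cc[3], cc4 = cc[4],
    diff2 = div2_2 - div2_1, diff3 = div3_4 - div3_1,
    diff4 = div4_8 - div4_1, ck1 = ck1,
    stage2_len = div2_2 - div1, stage3_len = div3_4 - div2_2,
    stage4_len = div4_8 - div3_4
  )
}

#' Classify embryo cleavage speed at the three-cell transition
#'
#' Labels embryos `fast`/`slow` (or `fast`/`intermediate`/`slow`) by their
#' time of division to the three-cell stage (`div2_1` by default) relative
#' to the 35–41 hpa window. In two-group mode the single cutoff is the
#' midpoint of `cutoffs` (default 38 hpa); embryos at or below it are
#' `fast`. In three-group mode, `div2_1 < cutoffs[1]` is `fast`,
#' `> cutoffs[2]` is `slow`, and the closed interval between is
#' `intermediate`.
#'
#' @param features A feature tibble from [compute_features()].
#' @param cutoffs Ordered pair of hpa values (default `c(35, 41)`).
#' @param mode `"two_group"` (default, as in blastocyst-rate contingency
#'   analyses) or `"three_group"`.
#' @param basis Feature used for classification (default `"div2_1"`).
#' @return `features` with an added `speed` factor column (`NA` where the
#'   basis feature is missing; such embryos are excluded from speed
#'   analyses).
#' @export
classify_speed <- function(features, cutoffs = c(35, 41),
                           mode = c("two_group", "three_group"),
                           basis = "div2_1") {
  mode <- match.arg(mode)
  if (length(cutoffs) != 2 || !is.numeric(cutoffs) || cutoffs[1] > cutoffs[2]) {
    abort("cutoffs must be an ordered pair of hpa values",
          class = "embryokin_argument_error")
  }
  if (!basis %in% names(features)) {
    abort(paste0("basis feature '", basis, "' not found in features"),
          class = "embryokin_argument_error")
  }
  v <- features[[basis]]
  if (mode == "two_group") {
    cut <- mean(cutoffs)
    lab <- dplyr::if_else(v <= cut, "fast", "slow")
    levels <- c("fast", "slow")
  } else {
    lab <- dplyr::case_when(
      v < cutoffs[1] ~ "fast",
      v > cutoffs[2] ~ "slow",
      !is.na(v) ~ "intermediate"
    )
    levels <- c("fast", "intermediate", "slow")
  }
  features$speed <- factor(lab, levels = levels)
  features
}
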