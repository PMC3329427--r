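#' Read a spent-media concentration table
#'
#' Long-format CSV of amino-acid concentrations measured in spent embryo
#' culture drops and matched embryo-free control drops. Required columns:
#' `sample_id`, `control_id` (empty/NA for control drops), `group`,
#' `stage_window` (one of `0-24`, `24-48`, `48-72`, `72-96` hpa),
#' `n_embryos` (0 for controls), `hours` (incubation duration),
#' `drop_volume_ul`, `amino_acid` (three-letter code), `conc_umol_l`.
#'
#' @param path CSV path.
#' @param dilution Dilution factor to apply when concentrations are raw
#'   assay readings rather than drop concentrations (e.g. 12.5 for a
#'   1:12.5 pre-assay dilution). Default 1 (already corrected).
#' @return A `media_table` tibble.
#' @export
read_media_table <- function(path, dilution = 1) {
  if (!file.exists(path)) {
    abort(paste0("media table not found: ", path), class = "embryokin_io_error")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  as_media_table(df, dilution = dilution)
}

#' @rdname read_media_table
#' @param df An in-memory data frame with the columns above.
#' @export
as_media_table <- function(df, dilution = 1) {
  required <- c("sample_id", "control_id", "group", "stage_window",
                "n_embryos", "hours", "drop_volume_ul", "amino_acid",
                "conc_umol_l")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("media table is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "embryokin_format_error")
  }
  df <- tibble::as_tibble(df)
  df$conc_umol_l <- df$conc_umol_l * dilution
  unknown <- setdiff(unique(df$amino_acid), .amino_acids)
  if (length(unknown) > 0) {
    warn(paste0("unrecognized amino acid name(s) passed through: ",
                paste(unknown, collapse = ", ")))
  }
  if (any(df$conc_umol_l < 0, na.rm = TRUE)) {
    abort("concentrations must be non-negative",
          class = "embryokin_validation_error")
  }
  ctrl <- is.na(df$control_id) | df$control_id == ""
  if (any(df$n_embryos[ctrl] != 0)) {
    abort("control drops (empty control_id) must have n_embryos = 0",
          class = "embryokin_validation_error")
  }
  if (any(df$n_embryos[!ctrl] < 1)) {
    abort("embryo drops must have n_embryos >= 1",
          class = "embryokin_validation_error")
  }
  if (any(df$hours <= 0) || any(df$drop_volume_ul <= 0)) {
    abort("hours and drop_volume_ul must be positive",
          class = "embryokin_validation_error")
  }
  structure(df, class = unique(c("media_table", class(df))))
}

#' Amino-acid turnover of one spent drop against its control
#'
#' Depletion/appearance rate per embryo per hour:
#' `rate = (C_control - C_sample) [umol/L] * drop_volume [uL] /
#' (n_embryos * hours)`, in pmol per embryo per hour. Positive rates are
#' depletion (consumption), negative rates appearance (release into the
#' medium). The matched embryo-free control corrects for non-specific
#' degradation or appearance.
#'
#' @param sample,control Data frames with `amino_acid` and `conc_umol_l`
#'   (one row per amino acid); `sample` must also carry `n_embryos`,
#'   `hours`, `drop_volume_ul`.
#' @return A tibble `amino_acid`, `rate_pmol_embryo_h`.
#' @export
compute_turnover <- function(sample, control) {
  n_embryos <- unique(sample$n_embryos)
  hours <- unique(sample$hours)
  vol <- unique(sample$drop_volume_ul)
  stopifnot(length(n_embryos) == 1, length(hours) == 1, length(vol) == 1)
  if (n_embryos == 0) {
    abort("sample has n_embryos = 0; cannot express turnover per embryo",
          class = "embryokin_argument_error")
  }
  missing_aa <- setdiff(sample$amino_acid, control$amino_acid)
  if (length(missing_aa) > 0) {
    abort(paste0("control is missing amino acid(s): ",
                 paste(missing_aa, collapse = ", ")),
          class = "embryokin_argument_error")
  }
  ctrl_conc <- control$conc_umol_l[match(sample$amino_acid, control$amino_acid)]
  tibble::tibble(
    amino_acid = sample$amino_acid,
    rate_pmol_embryo_h = (ctrl_conc - sample$conc_umol_l) * vol /
      (n_embryos * hours)
  )
}

#' Per-sample turnover rates for a whole media table
#'
#' Applies [compute_turnover()] to every embryo drop in a media table,
#' matched to its control drop by `control_id`.
#'
#' @param media A `media_table` (see [read_media_table()]).
#' @return A tibble: `sample_id`, `group`, `stage_window`, `amino_acid`,
#'   `rate_pmol_embryo_h`.
#' @export
turnover_rates <- function(media) {
  df <- tibble::as_tibble(media)
  is_ctrl <- is.na(df$control_id) | df$control_id == ""
  controls <- split(df[is_ctrl, ], df$sample_id[is_ctrl])
  samples <- split(df[!is_ctrl, ], df$sample_id[!is_ctrl])
  purrr::imap(samples, function(s, sid) {
    cid <- unique(s$control_id)
    ctrl <- controls[[cid]]
    if (is.null(ctrl)) {
      abort(paste0("sample '", sid, "' references missing control '",
                   cid, "'"),
            class = "embryokin_validation_error")
    }
    rates <- compute_turnover(s, ctrl)
    tibble::tibble(
      sample_id = sid, group = s$group[1], stage_window = s$stage_window[1],
      amino_acid = rates$amino_acid,
      rate_pmol_embryo_h = rates$rate_pmol_embryo_h
    )
  }) |> dplyr::bind_rows()
}

#' Total amino-acid turnover
#'
#' Sum of the absolute depletion and appearance rates — the overall
#' metabolic activity of a drop.
#'
#' @param rates Numeric vector of per-amino-acid rates, or a tibble from
#'   [compute_turnover()].
#' @return A single number (pmol per embryo per hour).
#' @export
total_turnover <- function(rates) {
  if (is.data.frame(rates)) rates <- rates$rate_pmol_embryo_h
  if (length(rates) == 0) {
    abort("rates must be non-empty", class = "embryokin_argument_error")
  }
  sum(abs(rates))
}

#' Build the turnover matrix (amino acids x group/stage)
#'
#' Summarises replicate drops into per-cell mean, SEM and n for each
#' (group, stage-window) combination — the heatmap table of the turnover
#' analysis. Combinations with no replicates are absent (with a warning
#' when an expected stage window is missing for a group).
#'
#' @param media A `media_table`, or a rates tibble from [turnover_rates()].
#' @return A `turnover_matrix`: a long tibble `amino_acid`, `group`,
#'   `stage_window`, `mean_rate`, `sem`, `n_replicates`, with the sign
#'   convention (positive = depletion) recorded in
#'   `attr(, "sign_convention")`.
#' @export
build_matrix <- function(media) {
  rates <- if ("rate_pmol_embryo_h" %in% names(media)) {
    tibble::as_tibble(media)
  } else {
    turnover_rates(media)
  }
  out <- rates |>
    dplyr::group_by(.data$amino_acid, .data$group, .data$stage_window) |>
    dplyr::summarise(
      mean_rate = mean(.data$rate_pmol_embryo_h),
      sem = if (dplyr::n() > 1) {
        sd(.data$rate_pmol_embryo_h) / sqrt(dplyr::n())
      } else {
        NA_real_
      },
      n_replicates = dplyr::n(),
      .groups = "drop"
    )
  expected <- tidyr::expand_grid(group = unique(out$group),
                                 stage_window = .stage_windows)
  have <- dplyr::distinct(out, .data$group, .data$stage_window)
  gone <- dplyr::anti_join(expected, have, by = c("group", "stage_window"))
  if (nrow(gone) > 0) {
    warn(paste0("no replicates for: ",
                paste(gone$group, gone$stage_window, collapse = "; ")))
  }
  structure(out, class = unique(c("turnover_matrix", class(out))),
            sign_convention = "positive = depletion (consumption); negative = appearance (release)")
}

#' Wide matrix view of a turnover matrix
#'
#' @param x A `turnover_matrix`.
#' @param ... Unused.
#' @return A numeric matrix, amino acids in rows, `group stage_window`
#'   columns.
#' @export
as.matrix.turnover_matrix <- function(x, ...) {
  wide <- tidyr::pivot_wider(
    tibble::as_tibble(x)[, c("amino_acid", "group", "stage_window", "mean_rate")],
    names_from = c("group", "stage_window"), values_from = "mean_rate",
    names_sep = " "
  )
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$amino_acid
  m
}

#' Hierarchical clustering of the turnover matrix
#'
#' Clusters amino acids by rank-correlation distance (1 - Spearman rho
#' across the group/stage columns) with complete linkage, and embryo
#' group/stage columns by Euclidean distance with Ward's minimum-variance
#' linkage (the squared-distance "ward.D2" criterion of the
#' Lance-Williams recurrence). An amino acid with a constant profile has
#' an undefined rank correlation; its distances are set to the maximum (2)
#' with a warning. Leaf order is made deterministic by ordering each
#' merge's subtrees by their smallest original index (the [stats::hclust()]
#' convention).
#'
#' @param matrix A `turnover_matrix` from [build_matrix()].
#' @param ward `"ward.D2"` (default) or `"ward.D"`: which Ward variant to
#'   apply to the column dendrogram.
#' @return A `turnover_clustering` list: `aa_hclust`, `group_hclust`
#'   (both `hclust` objects), and `ordered` (the wide matrix with rows and
#'   columns in dendrogram order).
#' @export
cluster_turnover <- function(matrix, ward = c("ward.D2", "ward.D")) {
  ward <- match.arg(ward)
  m <- as.matrix(matrix)
  if (nrow(m) < 2 || ncol(m) < 2) {
    abort("need at least 2 amino acids and 2 columns to cluster",
          class = "embryokin_argument_error")
  }
  constant <- apply(m, 1, function(r) sd(r) == 0 || all(is.na(r)))
  rho <- suppressWarnings(cor(t(m), method = "spearman"))
  d_aa <- 1 - rho
  if (any(constant)) {
    warn(paste0("constant turnover profile(s): ",
                paste(rownames(m)[constant], collapse = ", "),
                "; rank correlation undefined, distance set to 2"))
    d_aa[constant, ] <- 2
    d_aa[, constant] <- 2
  }
  diag(d_aa) <- 0
  aa_hclust <- hclust(stats::as.dist(d_aa), method = "complete")
  group_hclust <- hclust(dist(t(m)), method = ward)
  ordered <- m[aa_hclust$order, group_hclust$order, drop = FALSE]
  structure(
    list(aa_hclust = aa_hclust, group_hclust = group_hclust,
         ordered = ordered),
    class = "turnover_clustering"
  )
}

#' Export clustering dendrograms as Newick text
#'
#' @param clustering A `turnover_clustering`.
#' @param path Optional file path; when given, two trees (amino acids,
#'   then groups) are written one per line.
#' @return Invisibly, a character vector of two Newick strings (requires
#'   the \pkg{ape} package).
#' @export
turnover_newick <- function(clustering, path = NULL) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    abort("the 'ape' package is required for Newick export",
          class = "embryokin_argument_error")
  }
  nk <- c(
    ape::write.tree(ape::as.phylo(clustering$aa_hclust)),
    ape::write.tree(ape::as.phylo(clustering$group_hclust))
  )
  if (!is.null(path)) writeLines(nk, path)
  invisible(nk)
}

#' Correlation between two turnover profiles
#'
#' Squared Pearson correlation of the amino-acid rate vectors of two
#' (group, stage-window) columns — the stage-similarity comparison of the
#' metabolic-switch analysis. Signed r is reported alongside since r^2
#' alone is sign-blind.
#'
#' @param matrix A `turnover_matrix`.
#' @param column_a,column_b Column labels, `"GROUP stage"` (e.g.
#'   `"NT 24-48"`) as produced by [as.matrix.turnover_matrix()].
#' @return A [pearson_r2()] result tibble.
#' @export
profile_correlation <- function(matrix, column_a, column_b) {
  m <- as.matrix(matrix)
  miss <- setdiff(c(column_a, column_b), colnames(m))
  if (length(miss) > 0) {
    abort(paste0("column(s) not found: ", paste(miss, collapse = ", "),
                 "; available: ", paste(colnames(m), collapse = ", ")),
          class = "embryokin_argument_error")
  }
  shared <- complete.cases(m[, column_a], m[, column_b])
  if (sum(shared) < 3) {
    abort("columns share fewer than 3 amino acids",
          class = "embryokin_argument_error")
  }
  out <- pearson_r2(m[shared, column_a], m[shared, column_b])
  out$method <- paste0("profile_correlation (", column_a, " vs ",
                       column_b, ")")
  out
}

#' Heatmap of a turnover matrix
#'
#' @param object A `turnover_matrix`, or a `turnover_clustering` (rows and
#'   columns then follow the dendrogram order).
#' @param ... Unused.
#' @return A ggplot tile heatmap; consumption and release are mapped to a
#'   diverging fill centred at zero.
#' @method autoplot turnover_matrix
#' @export
autoplot.turnover_matrix <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$column <- paste(df$group, df$stage_window)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$column, y = .data$amino_acid,
                                   fill = .data$mean_rate)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(
      low = "darkgreen", mid = "black", high = "red", midpoint = 0,
      name = "pmol/embryo/h\n(+ = depletion)"
    ) +
    ggplot2::labs(x = NULL, y = NULL, title = "Amino-acid turnover") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname autoplot.turnover_matrix
#' @method autoplot turnover_clustering
#' @export
autoplot.turnover_clustering <- function(object, ...) {
  m <- object$ordered
  df <- tibble::as_tibble(as.data.frame(m), rownames = "amino_acid") |>
    tidyr::pivot_longer(-"amino_acid", names_to = "column",
                        values_to = "mean_rate")
  df$amino_acid <- factor(df$amino_acid, levels = rownames(m))
  df$column <- factor(df$column, levels = colnames(m))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$column, y = .data$amino_acid,
                                   fill = .data$mean_rate)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(
      low = "darkgreen", mid = "black", high = "red", midpoint = 0,
      name = "pmol/embryo/h\n(+ = depletion)"
    ) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Amino-acid turnover (clustered order)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
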