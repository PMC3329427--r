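#' Read an annotated division-event table
#'
#' Reads a CSV of time-lapse division annotations, one row per blastomere,
#' and validates it as a cohort of embryo lineage records. Times are in
#' decimal hours post activation (hpa); activation (nuclear-transfer
#' activation or sperm injection) defines t = 0.
#'
#' Required columns: `embryo_id`, `group`, `cell_id`, `parent_id`,
#' `birth_hpa`, `end_hpa`, `fate`, `aberrancy`. Optional: `treatment`,
#' `cytokinesis_onset_hpa`, `blastocyst`, `esc`, `fetus`. Lineage labels
#' follow the root "1", daughters "1.1"/"1.2" convention, so the number of
#' dot-separated components encodes the cleavage round. `aberrancy` is a
#' semicolon-separated subset of `multipolar_spindle`, `unipolar_spindle`,
#' `nondisjunction`, `cell_fusion`, `cytokinesis_failure`, or `"none"`.
#'
#' @param path Path to a CSV file (UTF-8, "." decimal separator, `NA` for
#'   missing values).
#' @return A validated `division_table` tibble, one row per cell.
#' @seealso [as_division_table()] to validate an in-memory data frame,
#'   [compute_features()] for timing-feature extraction.
#' @export
parse_division_table <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("division table not found: ", path), class = "embryokin_io_error")
  }
  df <- readr::read_csv(
    path,
    col_types = readr::cols(
      embryo_id = readr::col_character(),
      cell_id = readr::col_character(),
      parent_id = readr::col_character(),
      .default = readr::col_guess()
    ),
    progress = FALSE, show_col_types = FALSE
  )
  as_division_table(df)
}

#' Validate a division-event data frame
#'
#' Checks column presence, fate/aberrancy vocabulary, lineage-label
#' consistency (unique cell ids, exactly one root per embryo, every
#' non-root's parent present with `fate = "divided"` and
#' `end_hpa == birth_hpa` of the child), and time invariants
#' (`birth_hpa >= 0`, `end_hpa > birth_hpa` for divided cells, root born
#' at 0).
#'
#' @param df A data frame of division events (see [parse_division_table()]
#'   for the column contract).
#' @return `df` as a `division_table` tibble.
#' @export
as_division_table <- function(df) {
  required <- c("embryo_id", "group", "cell_id", "parent_id",
                "birth_hpa", "end_hpa", "fate", "aberrancy")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort(
      paste0("division table is missing required column(s): ",
             paste(missing_cols, collapse = ", ")),
      class = "embryokin_format_error"
    )
  }
  df <- tibble::as_tibble(df)
  if (!"treatment" %in% names(df)) df$treatment <- NA_character_
  if (!"cytokinesis_onset_hpa" %in% names(df)) df$cytokinesis_onset_hpa <- NA_real_
  for (col in c("blastocyst", "esc", "fetus")) {
    if (!col %in% names(df)) df[[col]] <- NA
    df[[col]] <- as.logical(df[[col]])
  }
  df$parent_id <- dplyr::if_else(
    is.na(df$parent_id) | df$parent_id == "", NA_character_, df$parent_id
  )

  if (nrow(df) == 0) {
    warn("division table is empty (header only); returning an empty cohort")
    return(structure(df, class = c("division_table", class(df))))
  }

  bad_fate <- setdiff(unique(df$fate), .fates)
  if (length(bad_fate) > 0) {
    abort(paste0("unknown fate value(s): ", paste(bad_fate, collapse = ", ")),
          class = "embryokin_format_error")
  }
  ab_tokens <- unique(unlist(strsplit(df$aberrancy[!is.na(df$aberrancy)], ";")))
  bad_ab <- setdiff(trimws(ab_tokens), .aberrancies)
  if (length(bad_ab) > 0) {
    abort(paste0("unknown aberrancy value(s): ", paste(bad_ab, collapse = ", ")),
          class = "embryokin_format_error")
  }
  if (any(df$birth_hpa < 0, na.rm = TRUE)) {
    abort("birth_hpa must be >= 0", class = "embryokin_validation_error")
  }

  by_embryo <- split(df, df$embryo_id)
  for (eid in names(by_embryo)) {
    e <- by_embryo[[eid]]
    if (anyDuplicated(e$cell_id)) {
      dup <- e$cell_id[duplicated(e$cell_id)][1]
      abort(paste0("embryo ", eid, ": duplicate cell_id '", dup, "'"),
            class = "embryokin_validation_error")
    }
    roots <- e$cell_id[is.na(e$parent_id)]
    if (length(roots) != 1) {
      abort(paste0("embryo ", eid, ": expected exactly one root cell, found ",
                   length(roots)),
            class = "embryokin_validation_error")
    }
    root <- e[is.na(e$parent_id), ]
    if (!isTRUE(all.equal(root$birth_hpa, 0))) {
      abort(paste0("embryo ", eid, ": root cell '", root$cell_id,
                   "' must have birth_hpa = 0 (activation)"),
            class = "embryokin_validation_error")
    }
    divided <- e$fate == "divided"
    if (any(divided & !(e$end_hpa > e$birth_hpa))) {
      bad <- e$cell_id[divided & !(e$end_hpa > e$birth_hpa)][1]
      abort(paste0("embryo ", eid, ": cell '", bad,
                   "' divided but end_hpa <= birth_hpa"),
            class = "embryokin_validation_error")
    }
    kids <- e[!is.na(e$parent_id), ]
    if (nrow(kids) > 0) {
      idx <- match(kids$parent_id, e$cell_id)
      if (anyNA(idx)) {
        bad <- kids$cell_id[is.na(idx)][1]
        abort(paste0("embryo ", eid, ": cell '", bad,
                     "' references missing parent '",
                     kids$parent_id[is.na(idx)][1], "'"),
              class = "embryokin_validation_error")
      }
      pfate <- e$fate[idx]
      if (any(pfate != "divided")) {
        bad <- kids$cell_id[pfate != "divided"][1]
        abort(paste0("embryo ", eid, ": parent of cell '", bad,
                     "' has fate != divided"),
              class = "embryokin_validation_error")
      }
      dt <- abs(kids$birth_hpa - e$end_hpa[idx])
      if (any(dt > 1e-8)) {
        bad <- kids$cell_id[dt > 1e-8][1]
        abort(paste0("embryo ", eid, ": cell '", bad,
                     "' birth_hpa does not match parent end_hpa"),
              class = "embryokin_validation_error")
      }
    }
  }
  structure(df, class = unique(c("division_table", class(df))))
}

# cleavage round of a lineage label: number of dot-separated components
cell_round <- function(cell_id) {
  stringr::str_count(cell_id, stringr::fixed(".")) + 1L
}
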