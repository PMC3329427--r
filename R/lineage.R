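#' Build a lineage tree for one embryo
#'
#' Converts the validated division records of a single embryo into a
#' `lineage_tree`: a binary cell-division tree with birth/division times on
#' the nodes. Cells still alive at the observation horizon are censored
#' (`end_hpa` set to the horizon). A divided cell must have either two
#' recorded daughters or none (annotation may stop after the division that
#' was timed); exactly one recorded daughter is a structural error.
#'
#' @param records A `division_table` (or compatible data frame). If it
#'   contains more than one embryo, `embryo_id` selects one.
#' @param horizon Observation horizon in hours post activation
#'   (default 96, the end of time-lapse recording).
#' @param embryo_id Which embryo to extract when `records` holds a cohort.
#' @return A `lineage_tree` object: a list with elements `embryo_id`,
#'   `group`, `nodes` (tibble with `cell_id`, `parent_id`, `round`,
#'   `birth_hpa`, `end_hpa`, `fate`, `aberrancy`, `cytokinesis_onset_hpa`),
#'   `horizon`, and the embryo-level outcomes.
#' @export
build_lineage <- function(records, horizon = 96, embryo_id = NULL) {
  df <- tibble::as_tibble(records)
  ids <- unique(df$embryo_id)
  if (is.null(embryo_id)) {
    if (length(ids) != 1) {
      abort("records contain multiple embryos; supply embryo_id",
            class = "embryokin_argument_error")
    }
    embryo_id <- ids
  }
  e <- df[df$embryo_id == embryo_id, ]
  if (nrow(e) == 0) {
    abort(paste0("no records for embryo '", embryo_id, "'"),
          class = "embryokin_argument_error")
  }

  n_children <- table(e$parent_id[!is.na(e$parent_id)])
  divided <- e$cell_id[e$fate == "divided"]
  kc <- as.integer(n_children[divided])
  kc[is.na(kc)] <- 0L
  if (any(!kc %in% c(0L, 2L))) {
    bad <- divided[!kc %in% c(0L, 2L)][1]
    abort(paste0("embryo ", embryo_id, ": divided cell '", bad,
                 "' has ", kc[!kc %in% c(0L, 2L)][1],
                 " recorded daughter(s); expected 0 or 2"),
          class = "embryokin_structure_error")
  }
  not_divided <- e$cell_id[e$fate != "divided"]
  if (any(not_divided %in% names(n_children))) {
    bad <- intersect(not_divided, names(n_children))[1]
    abort(paste0("embryo ", embryo_id, ": non-divided cell '", bad,
                 "' has recorded daughters"),
          class = "embryokin_structure_error")
  }

  nodes <- tibble::tibble(
    cell_id = e$cell_id,
    parent_id = e$parent_id,
    round = cell_round(e$cell_id),
    birth_hpa = e$birth_hpa,
    end_hpa = dplyr::if_else(e$fate == "censored", horizon, e$end_hpa),
    fate = e$fate,
    aberrancy = e$aberrancy,
    cytokinesis_onset_hpa = e$cytokinesis_onset_hpa
  )
  nodes <- dplyr::arrange(nodes, .data$round, .data$cell_id)
  structure(
    list(
      embryo_id = embryo_id,
      group = e$group[1],
      treatment = e$treatment[1] %||% NA_character_,
      nodes = nodes,
      horizon = horizon,
      blastocyst = e$blastocyst[1] %||% NA,
      esc = e$esc[1] %||% NA,
      fetus = e$fetus[1] %||% NA
    ),
    class = "lineage_tree"
  )
}

#' @export
print.lineage_tree <- function(x, ...) {
  cat("<lineage_tree> embryo", x$embryo_id, "(", x$group, ")\n")
  cat("  ", nrow(x$nodes), "cells, max round",
      max(x$nodes$round), ", horizon", x$horizon, "hpa\n")
  cat("  blastocyst:", x$blastocyst, "\n")
  invisible(x)
}
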