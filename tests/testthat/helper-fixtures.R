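# Hand-constructed embryo fixtures used across tests.

# T1: full lineage to the 8-cell stage. Root divides at 20.0; daughters at
# 38.0 / 39.0; the four 4-cell blastomeres divide at 50.0, 50.5 (children
# of "1.1") and 51.0, 53.0 (children of "1.2"). Terminal divided cells
# carry no child rows (annotation stops at their division).
toy_embryo_t1 <- function(blastocyst = TRUE) {
  tibble::tibble(
    embryo_id = "T1",
    group = "ICSI",
    treatment = NA_character_,
    cell_id  = c("1", "1.1", "1.2", "1.1.1", "1.1.2", "1.2.1", "1.2.2"),
    parent_id = c(NA, "1", "1", "1.1", "1.1", "1.2", "1.2"),
    birth_hpa = c(0, 20, 20, 38, 38, 39, 39),
    end_hpa   = c(20, 38, 39, 50, 50.5, 51, 53),
    fate = "divided",
    aberrancy = "none",
    cytokinesis_onset_hpa = c(19.4, rep(NA_real_, 6)),
    blastocyst = blastocyst, esc = NA, fetus = NA
  )
}

# T2: root divides at 22.0, both daughters still undivided at the horizon.
toy_embryo_t2 <- function(horizon = 96) {
  tibble::tibble(
    embryo_id = "T2",
    group = "NT",
    treatment = NA_character_,
    cell_id = c("1", "1.1", "1.2"),
    parent_id = c(NA, "1", "1"),
    birth_hpa = c(0, 22, 22),
    end_hpa = c(22, horizon, horizon),
    fate = c("divided", "censored", "censored"),
    aberrancy = "none",
    cytokinesis_onset_hpa = NA_real_,
    blastocyst = FALSE, esc = NA, fetus = NA
  )
}

write_cohort_csv <- function(df, path = tempfile(fileext = ".csv")) {
  readr::write_csv(df, path, na = "NA")
  path
}

# features tibble for window-search tests: one feature column x
window_toy <- function(x, outcome) {
  tibble::tibble(embryo_id = paste0("E", seq_along(x)), x = x,
                 blastocyst = outcome)
}

# brute-force best-F oracle over raw value endpoints (not midpoints)
oracle_best_1d <- function(x, y, objective = "f") {
  cand <- c(-Inf, sort(unique(x)), Inf)
  best <- -1
  for (lo in cand) for (hi in cand) {
    if (lo > hi) next
    inside <- x >= lo & x <= hi
    tp <- sum(inside & y); fp <- sum(inside & !y)
    fn <- sum(!inside & y); tn <- sum(!inside & !y)
    sn <- if (tp + fn > 0) tp / (tp + fn) else 0
    pr <- if (tp + fp > 0) tp / (tp + fp) else 0
    f <- if (pr + sn > 0) 2 * pr * sn / (pr + sn) else 0
    acc <- (tp + tn) / length(y)
    v <- if (objective == "f") f else acc
    if (v > best) best <- v
  }
  best
}
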