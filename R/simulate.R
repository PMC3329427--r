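#' Simulation presets for cleavage-lineage cohorts
#'
#' Returns a fully specified `sim_config` for the stochastic
#' branching-process generator of [simulate_cohort()]. Cell-cycle lengths
#' are log-normal around per-round group medians, with a shared embryo
#' effect, a heritable mother deviation (inducing mother-daughter and
#' sister correlations), a sister-shared mother effect, and an individual
#' cell term (controlling inter-stage asynchrony). Third-round M-phase
#' aberrancy follows a logistic model in the cell's cycle length;
#' blastocyst formation follows a logistic outcome model in a
#' standardized timing feature, overridden by the arrest rule.
#'
#' Presets:
#' \describe{
#'   \item{`ICSI-default`}{fertilized-control kinetics. Absolute medians
#'     (cc1 = 18, cc2 = 18, cc3 = 12.5, cc4 = 12 h) are declared baseline
#'     assumptions; dispersions are calibrated so the median three-cell
#'     inter-stage is about 1.0 h and the five-to-seven-cell inter-stage
#'     about 1.7 h. Tolerant arrest rule (an aberrant third-round mitosis
#'     does not preclude blastocyst formation). Outcome model on cc1,
#'     calibrated to an overall blastocyst rate near 41.4% and an
#'     in-sample cc1 best-window accuracy near 66.7%.}
#'   \item{`NT-default`}{cloned-embryo kinetics: baseline plus the
#'     group-median offsets (cc1 -0.4 h, cc2 +2.3 h, cc3 +3.4 h, cc4
#'     unchanged), wider sister asynchrony (inter-stage medians near
#'     1.7 h and 4.3 h), a negative round-3 inheritance coefficient
#'     (anticorrelated second and third cycles), the strict arrest rule
#'     (any third-round M-phase error prevents blastocyst formation), and
#'     an outcome model on the three-cell division time calibrated so the
#'     38-hpa fast/slow split yields blastocyst rates near 48.9% (fast)
#'     and 27.8% (slow).}
#'   \item{`null-independent`}{ICSI kinetics with the blastocyst outcome
#'     independent of every timing feature (slope 0), for null-control
#'     experiments.}
#' }
#'
#' @param name Preset name.
#' @return A `sim_config` list.
#' @export
sim_preset <- function(name = c("ICSI-default", "NT-default",
                                "null-independent")) {
  name <- match.arg(name)
  base <- list(
    preset = name,
    group = "ICSI",
    n_embryos = 500,
    # per-round cycle-length medians, hours
    cc_median = c(18, 18, 12.5, 12),
    # log-scale variance components
    embryo_effect_sd = 0.045,
    inherit = c(0, 0.35, 0.40, 0.60),
    mother_effect_sd = c(0, 0.020, 0.020, 0.020),
    sister_asynchrony_sd = c(0.050, 0.058, 0.026, 0.050),
    aberrancy_logit = c(-6.90, 0.25),
    arrest_rule = "tolerant",
    outcome_model = list(feature = "cc1", center = 18.1, scale = 1.25,
                         intercept = -0.50, slope = -1.15),
    esc_given_blastocyst = 0.38,
    fetus_given_blastocyst = 0.45,
    ck1_median = 0.75,
    ck1_sdlog = 0.18,
    horizon = 96,
    seed = 1
  )
  cfg <- switch(name,
    "ICSI-default" = base,
    "NT-default" = utils::modifyList(base, list(
      group = "NT",
      cc_median = c(17.6, 20.3, 15.9, 12),
      inherit = c(0, 0.35, -0.45, 0.55),
      sister_asynchrony_sd = c(0.050, 0.088, 0.123, 0.050),
      aberrancy_logit = c(-7.45, 0.25),
      arrest_rule = "nt_strict",
      outcome_model = list(feature = "div2_1", center = 37.6, scale = 2.1,
                           intercept = -0.20, slope = -0.52),
      esc_given_blastocyst = 0.30,
      fetus_given_blastocyst = 0.04
    )),
    "null-independent" = utils::modifyList(base, list(
      group = "NULL",
      outcome_model = list(feature = "cc1", center = 18.1, scale = 1.25,
                           intercept = -0.35, slope = 0)
    ))
  )
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$preset, "(group", x$group, ")\n")
  cat("  cc medians (h):", paste(x$cc_median, collapse = ", "), "\n")
  cat("  arrest rule:", x$arrest_rule, "| outcome on",
      x$outcome_model$feature, "\n")
  invisible(x)
}

validate_sim_config <- function(config) {
  stopifnot(
    inherits(config, "sim_config") || is.list(config),
    all(config$cc_median > 0),
    all(config$sister_asynchrony_sd >= 0),
    all(config$mother_effect_sd >= 0),
    config$embryo_effect_sd >= 0,
    config$horizon > 0,
    config$arrest_rule %in% c("nt_strict", "tolerant")
  )
  invisible(config)
}

# fixed 16-cell lineage layout: rows 1..15 are rounds 1-4
.sim_parent <- c(NA, 1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L, 5L, 5L, 6L, 6L, 7L, 7L)
.sim_round <- c(1L, 2L, 2L, 3L, 3L, 3L, 3L, rep(4L, 8))
.sim_label <- local({
  lab <- character(15)
  lab[1] <- "1"
  for (i in 2:15) {
    lab[i] <- paste0(lab[.sim_parent[i]], ".", 1 + i %% 2)
  }
  lab
})

#' Simulate a cohort of cleavage lineages
#'
#' Stochastic branching simulation of mouse pre-implantation cleavage up
#' to the 16-cell stage. Per embryo: an embryo effect is drawn; each
#' cell's cycle length is
#' `median_k * exp(embryo + inherited mother deviation + sister-shared +
#' individual)`; third-round cells acquire M-phase aberrancies with
#' logistic probability in their own cycle length; blastocyst formation
#' follows the outcome model unless the arrest rule fires; cells running
#' past the horizon are censored. Draws use deterministic per-embryo
#' substreams of `seed`, so a cohort is byte-reproducible and stable under
#' subsetting.
#'
#' @param config A [sim_preset()] configuration (fields may be overridden
#'   via [utils::modifyList()]).
#' @param n_embryos Number of embryos (default `config$n_embryos`).
#' @param seed Integer seed (default `config$seed`).
#' @return A validated `division_table` tibble (one row per cell).
#' @export
simulate_cohort <- function(config, n_embryos = NULL, seed = NULL) {
  validate_sim_config(config)
  n_embryos <- n_embryos %||% config$n_embryos
  seed <- seed %||% config$seed
  om <- config$outcome_model
  ab <- config$aberrancy_logit
  nh <- config$horizon

  blocks <- vector("list", n_embryos)
  for (i in seq_len(n_embryos)) {
    # deterministic per-embryo substream, kept inside 32-bit integer range
    set.seed((as.numeric(seed) * 69069 + i * 104729) %% 2147483399)
    e <- rnorm(1, 0, config$embryo_effect_sd)
    v <- numeric(15)
    v[1] <- rnorm(1, 0, config$sister_asynchrony_sd[1])
    for (m in 1:7) {
      k <- .sim_round[m] + 1L
      shared <- rnorm(1, 0, config$mother_effect_sd[k])
      kids <- which(.sim_parent == m)
      v[kids] <- config$inherit[k] * v[m] + shared +
        rnorm(2, 0, config$sister_asynchrony_sd[k])
    }
    len <- config$cc_median[.sim_round] * exp(e + v)
    birth <- numeric(15)
    end <- numeric(15)
    end[1] <- len[1]
    for (j in 2:15) {
      birth[j] <- end[.sim_parent[j]]
      end[j] <- birth[j] + len[j]
    }
    fate <- rep("divided", 15)
    keep <- rep(TRUE, 15)
    for (j in 1:15) {
      if (!keep[j]) next
      if (birth[j] >= nh) {
        keep[j] <- FALSE
        keep[.sim_parent %in% j] <- FALSE
      } else if (end[j] > nh) {
        fate[j] <- "censored"
        end[j] <- nh
        keep[.sim_parent %in% j] <- FALSE
      }
    }
    # descendants of removed cells
    for (j in 2:15) if (!keep[.sim_parent[j]]) keep[j] <- FALSE

    aberr <- rep("none", 15)
    r3 <- which(.sim_round == 3L)
    ab_draw <- runif(4)
    ab_type <- sample(c("multipolar_spindle", "unipolar_spindle",
                        "nondisjunction"), 4, replace = TRUE)
    for (jj in seq_along(r3)) {
      j <- r3[jj]
      if (keep[j] && fate[j] == "divided" &&
          ab_draw[jj] < plogis(ab[1] + ab[2] * len[j])) {
        aberr[j] <- ab_type[jj]
      }
    }
    arrested <- config$arrest_rule == "nt_strict" && any(aberr[r3] != "none")

    x <- switch(om$feature,
      cc1 = len[1],
      div2_1 = min(end[2], end[3]),
      cc2 = mean(len[2:3]),
      abort(paste0("unsupported outcome feature: ", om$feature),
            class = "embryokin_argument_error")
    )
    p_bl <- plogis(om$intercept + om$slope * (x - om$center) / om$scale)
    u <- runif(3)
    blast <- !arrested && u[1] < p_bl
    esc <- blast && u[2] < config$esc_given_blastocyst
    fetus <- blast && u[3] < config$fetus_given_blastocyst

    ck_dur <- config$ck1_median * exp(rnorm(1, 0, config$ck1_sdlog))
    cyt <- rep(NA_real_, 15)
    cyt[1] <- max(0, end[1] - ck_dur)

    blocks[[i]] <- list(
      embryo_id = sprintf("%s%05d", config$group, i),
      keep = keep, birth = birth, end = end, fate = fate,
      aberr = aberr, cyt = cyt, blast = blast, esc = esc, fetus = fetus
    )
  }

  rows <- purrr::map(blocks, function(b) {
    k <- b$keep
    tibble::tibble(
      embryo_id = b$embryo_id,
      group = config$group,
      treatment = NA_character_,
      cell_id = .sim_label[k],
      parent_id = c(NA_character_, .sim_label[.sim_parent[-1]])[k],
      birth_hpa = b$birth[k],
      end_hpa = b$end[k],
      fate = b$fate[k],
      aberrancy = b$aberr[k],
      cytokinesis_onset_hpa = b$cyt[k],
      blastocyst = b$blast,
      esc = b$esc,
      fetus = b$fetus
    )
  })
  as_division_table(dplyr::bind_rows(rows))
}

# baseline fertilized-embryo turnover profile, pmol/embryo/h
# (positive = depletion); stages 0-24, 24-48, 48-72, 72-96 hpa.
# Invented synthetic profile: total turnover rises with development,
# arginine depletion rises, alanine/glutamine/glycine are released.
media_baseline <- function() {
  m <- rbind(
    Ala = c(-0.30, -0.45, -0.80, -1.30),
    Arg = c(0.55, 1.05, 1.85, 2.60),
    Asn = c(0.15, 0.25, 0.45, 0.70),
    Asp = c(0.50, 0.65, 0.45, 0.30),
    Gln = c(-0.25, -0.50, -1.00, -1.60),
    Glu = c(0.35, 0.30, 0.20, 0.10),
    Gly = c(-0.20, -0.35, -0.60, -0.90),
    His = c(0.10, 0.15, 0.25, 0.35),
    Ile = c(0.12, 0.20, 0.35, 0.55),
    Leu = c(0.18, 0.30, 0.55, 0.85),
    Lys = c(0.14, 0.22, 0.40, 0.60),
    Met = c(0.06, 0.10, 0.16, 0.25),
    Phe = c(0.08, 0.14, 0.24, 0.38),
    Ser = c(0.25, 0.35, 0.20, 0.05),
    Thr = c(0.10, 0.18, 0.30, 0.45),
    Trp = c(0.05, 0.08, 0.13, 0.20),
    Tyr = c(0.09, 0.15, 0.26, 0.40),
    Val = c(0.15, 0.25, 0.45, 0.70)
  )
  colnames(m) <- .stage_windows
  m
}

#' Simulate spent-media concentration data
#'
#' Generates a long-format media table for NT and ICSI embryo groups over
#' the four 24-hour stage windows. The fertilized (ICSI) profile follows
#' an internal synthetic baseline whose total turnover rises with
#' development; the cloned (NT) profile implements the metabolic lag —
#' its 24-48 h column equals the ICSI 0-24 h column — and the arginine
#' inversion: NT arginine depletion is scaled below the ICSI value at
#' 48-72 h and above it at 72-96 h. Matched embryo-free control drops are
#' generated alongside. Gaussian measurement noise is added to every
#' concentration.
#'
#' @param n_replicates Drops per (group, stage window), default 6.
#' @param noise_sd Concentration noise SD in umol/L (default 1; 0 gives
#'   exact profiles).
#' @param seed Integer seed.
#' @param arginine_scale Length-2 multipliers for NT arginine at 48-72 and
#'   72-96 hpa (default `c(0.65, 1.3)`).
#' @return A validated `media_table` tibble.
#' @export
simulate_spent_media <- function(n_replicates = 6, noise_sd = 1, seed = 1,
                                 arginine_scale = c(0.65, 1.3)) {
  set.seed(seed)
  icsi <- media_baseline()
  nt <- icsi
  nt[, "24-48"] <- icsi[, "0-24"]
  nt["Arg", "48-72"] <- icsi["Arg", "48-72"] * arginine_scale[1]
  nt["Arg", "72-96"] <- icsi["Arg", "72-96"] * arginine_scale[2]
  profiles <- list(ICSI = icsi, NT = nt)

  aa <- rownames(icsi)
  conc0 <- setNames(200 + 15 * seq_along(aa), aa)  # medium baseline, umol/L
  n_emb_by_stage <- c(20, 15, 10, 5)
  hours <- 17
  vol <- 5

  out <- list()
  for (g in names(profiles)) {
    for (s in seq_along(.stage_windows)) {
      stage <- .stage_windows[s]
      for (r in seq_len(n_replicates)) {
        sid <- sprintf("%s_%s_r%02d", g, gsub("-", "_", stage), r)
        cid <- paste0(sid, "_ctrl")
        n_emb <- n_emb_by_stage[s]
        rate <- profiles[[g]][, s]
        delta <- rate * n_emb * hours / vol
        samp_conc <- pmax(0, conc0 - delta + rnorm(length(aa), 0, noise_sd))
        ctrl_conc <- pmax(0, conc0 + rnorm(length(aa), 0, noise_sd))
        out[[length(out) + 1]] <- tibble::tibble(
          sample_id = c(rep(sid, length(aa)), rep(cid, length(aa))),
          control_id = c(rep(cid, length(aa)), rep(NA_character_, length(aa))),
          group = g,
          stage_window = stage,
          n_embryos = c(rep(n_emb, length(aa)), rep(0, length(aa))),
          hours = hours,
          drop_volume_ul = vol,
          amino_acid = c(aa, aa),
          conc_umol_l = c(samp_conc, ctrl_conc)
        )
      }
    }
  }
  as_media_table(dplyr::bind_rows(out))
}
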