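#' @noRd
stat_result <- function(method, estimate, statistic, p_value, n, ...) {
  tibble::tibble(
    method = method, estimate = estimate, statistic = statistic,
    p_value = p_value, n = n, ...
  )
}

# exact null pmf of the Mann-Whitney U statistic for sample sizes (n, m),
# by subset-sum dynamic programming over ranks 1..n+m
u_statistic_pmf <- function(n, m) {
  N <- n + m
  maxs <- sum((m + 1):N)
  dp <- matrix(0, nrow = n + 1, ncol = maxs + 1)
  dp[1, 1] <- 1
  for (r in 1:N) {
    for (j in min(r, n):1) {
      dp[j + 1, (r + 1):(maxs + 1)] <-
        dp[j + 1, (r + 1):(maxs + 1)] + dp[j, 1:(maxs + 1 - r)]
    }
  }
  s <- 0:maxs
  u <- s - n * (n + 1) / 2
  keep <- u >= 0 & u <= n * m
  pmf <- dp[n + 1, keep]
  pmf / sum(pmf)
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Two-sided Wilcoxon (Mann-Whitney) rank-sum test, the comparison used for
#' all group-wise timing contrasts. In `"exact"` mode the null distribution
#' of the U statistic is computed by exact enumeration (dynamic programming
#' over rank subsets); `"auto"` uses the exact distribution when the
#' combined sample size is at most 20 and there are no ties, and otherwise
#' a normal approximation with tie and continuity corrections.
#'
#' @param x,y Numeric samples (non-empty; `NA` dropped).
#' @param mode `"auto"` (default), `"exact"`, or `"normal_approx"`.
#' @return A one-row tibble: `method`, `estimate` (median of `x` minus
#'   median of `y`), `statistic` (Mann-Whitney U for `x`), `p_value`, `n`.
#' @export
wilcoxon_rank_sum <- function(x, y, mode = c("auto", "exact", "normal_approx")) {
  mode <- match.arg(mode)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0) {
    abort("both samples must be non-empty", class = "embryokin_argument_error")
  }
  n <- length(x); m <- length(y); N <- n + m
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1) {
    warn("all values identical across both samples; p = 1")
    return(stat_result("wilcoxon_rank_sum", 0, n * m / 2, 1, N))
  }
  r <- rank(pooled)
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  ties <- anyDuplicated(pooled) > 0
  use_exact <- switch(mode,
    exact = TRUE,
    normal_approx = FALSE,
    auto = N <= 20 && !ties
  )
  if (use_exact && ties) {
    warn("ties present; falling back to the normal approximation")
    use_exact <- FALSE
  }
  if (use_exact) {
    pmf <- u_statistic_pmf(n, m)
    dev <- abs(seq_along(pmf) - 1 - n * m / 2)
    p <- sum(pmf[dev >= abs(U - n * m / 2) - 1e-9])
    method <- "wilcoxon_rank_sum (exact)"
  } else {
    tie_tab <- table(pooled)
    sigma2 <- (n * m / 12) *
      ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    z <- U - n * m / 2
    z <- z - sign(z) * 0.5  # continuity correction
    if (sigma2 <= 0) {
      warn("degenerate rank variance; p = 1")
      p <- 1
    } else {
      p <- min(1, 2 * pnorm(-abs(z) / sqrt(sigma2)))
    }
    method <- "wilcoxon_rank_sum (normal approx)"
  }
  stat_result(method, median(x) - median(y), U, p, N)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided Fisher's exact test: the p-value sums the hypergeometric
#' probabilities of all tables (with the observed margins) whose
#' probability does not exceed that of the observed table. Used for all
#' outcome-contingency analyses (fast/slow x blastocyst, aberrancy x
#' blastocyst, supplementation experiments, sister-division concordance).
#'
#' @param tab A 2x2 matrix (or coercible) of non-negative integer counts.
#' @return A one-row tibble: `estimate` is the sample odds ratio
#'   (`ad/bc`, `Inf`/0 allowed), `statistic` the hypergeometric probability
#'   of the observed table, plus `p_value` and `n`.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) {
    abort("tab must be 2x2", class = "embryokin_argument_error")
  }
  if (any(tab < 0) || any(abs(tab - round(tab)) > 1e-8)) {
    abort("tab entries must be non-negative integers",
          class = "embryokin_argument_error")
  }
  tab <- round(tab)
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  N <- sum(tab)
  or <- (a * d) / (b * c)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warn("a table margin is zero; the test is degenerate, p = 1")
    return(stat_result("fisher_exact", or, NA_real_, 1, N))
  }
  m1 <- a + b; n1 <- a + c
  klo <- max(0, n1 - (c + d)); khi <- min(n1, m1)
  k <- klo:khi
  logp <- lchoose(m1, k) + lchoose(c + d, n1 - k) - lchoose(N, n1)
  pk <- exp(logp - max(logp))
  pk <- pk / sum(pk)
  p_obs <- pk[k == a]
  p <- sum(pk[pk <= p_obs * (1 + 1e-7)])
  stat_result("fisher_exact", or, p_obs, min(1, p), N)
}

#' Squared Pearson correlation with a t-test
#'
#' The correlation summary used for mother-daughter and sister-sister
#' cycle-length consistency and for amino-acid profile similarity:
#' squared Pearson correlation coefficient r^2, with a two-sided p-value
#' from the t statistic on n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length (pairs with an `NA` are
#'   dropped), or `x` a two-column data frame/matrix of pairs.
#' @return A one-row tibble: `estimate` = r^2, `r` = signed r,
#'   `statistic` = t, `p_value`, `n` (number of complete pairs).
#' @export
pearson_r2 <- function(x, y = NULL) {
  if (is.null(y)) {
    x <- as.data.frame(x)
    stopifnot(ncol(x) >= 2)
    y <- x[[2]]; x <- x[[1]]
  }
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) {
    abort("pearson_r2 requires at least 3 complete pairs",
          class = "embryokin_argument_error")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    warn("zero variance in a coordinate; correlation undefined")
    return(stat_result("pearson_r2 (degenerate)", NA_real_, NA_real_,
                       NA_real_, n, r = NA_real_))
  }
  r <- cor(x, y)
  r2 <- r^2
  if (abs(r) >= 1 - 1e-12) {
    t <- Inf * sign(r); p <- 0
  } else {
    t <- r * sqrt((n - 2) / (1 - r2))
    p <- 2 * pt(-abs(t), df = n - 2)
  }
  stat_result("pearson_r2", r2, t, p, n, r = r)
}

#' Compare a timing feature between two embryo groups
#'
#' Robust group summaries (median, unscaled median absolute deviation, n)
#' of a feature per group plus a two-sided Wilcoxon rank-sum comparison.
#' The estimate is `median(first group) - median(second group)`.
#'
#' @param features Feature tibble from [compute_features()] (any data
#'   frame with a `group` column and the feature).
#' @param feature Name of the feature column to compare.
#' @param groups Character pair selecting and ordering the two groups
#'   (default: first two group levels in the data, so an NT/ICSI cohort
#'   yields NT minus ICSI when NT rows come first).
#' @return A list with `summary` (two-row tibble: `feature`, `group`,
#'   `median`, `mad`, `n`) and `test` (the Wilcoxon result).
#' @export
group_feature_compare <- function(features, feature, groups = NULL) {
  if (!feature %in% names(features)) {
    abort(paste0("feature '", feature, "' not found"),
          class = "embryokin_argument_error")
  }
  v <- features[[feature]]
  if (all(is.na(v))) {
    abort(paste0("feature '", feature, "' is missing for every embryo"),
          class = "embryokin_argument_error")
  }
  if (is.null(groups)) groups <- unique(as.character(features$group))
  if (length(groups) != 2) {
    abort("exactly two groups are required", class = "embryokin_argument_error")
  }
  vals <- lapply(groups, function(g) {
    w <- v[features$group == g]
    w[!is.na(w)]
  })
  if (any(lengths(vals) == 0)) {
    abort(paste0("no non-missing '", feature, "' values in group '",
                 groups[lengths(vals) == 0][1], "'"),
          class = "embryokin_argument_error")
  }
  summary <- tibble::tibble(
    feature = feature,
    group = groups,
    median = vapply(vals, median, numeric(1)),
    mad = vapply(vals, function(w) median(abs(w - median(w))), numeric(1)),
    n = lengths(vals)
  )
  test <- wilcoxon_rank_sum(vals[[1]], vals[[2]])
  test$estimate <- summary$median[1] - summary$median[2]
  test$feature <- feature
  list(summary = summary, test = test)
}

# per-cell cycle lengths of divided cells at a given cleavage round
round_lengths <- function(df, round_k) {
  df <- tibble::as_tibble(df)
  df$round <- cell_round(df$cell_id)
  dplyr::filter(df, .data$round == round_k, .data$fate == "divided") |>
    dplyr::mutate(length = .data$end_hpa - .data$birth_hpa)
}

#' Mother-daughter cell-cycle length correlation
#'
#' Pairs the cycle length of each divided round-k cell with the cycle
#' lengths of its divided round-(k+1) daughters and returns the squared
#' Pearson correlation — the measure of cleavage-pace consistency across
#' consecutive cell cycles.
#'
#' @param division_table A validated division-event cohort.
#' @param round_k Mother cleavage round (1 pairs the first with the second
#'   cell cycle).
#' @param method `"per_cell"` (default): both daughters contribute one
#'   pair each; `"daughter_mean"`: one pair per mother using the mean
#'   daughter cycle length.
#' @return A [pearson_r2()] result tibble.
#' @export
mother_daughter_correlation <- function(division_table, round_k,
                                        method = c("per_cell", "daughter_mean")) {
  method <- match.arg(method)
  mothers <- round_lengths(division_table, round_k)
  daughters <- round_lengths(division_table, round_k + 1)
  pairs <- dplyr::inner_join(
    dplyr::select(daughters, "embryo_id", "parent_id", d_len = "length"),
    dplyr::select(mothers, "embryo_id", cell_id_m = "cell_id", m_len = "length"),
    by = c("embryo_id", "parent_id" = "cell_id_m")
  )
  if (method == "daughter_mean") {
    pairs <- pairs |>
      dplyr::group_by(.data$embryo_id, .data$parent_id, .data$m_len) |>
      dplyr::summarise(d_len = mean(.data$d_len), .groups = "drop")
  }
  if (nrow(pairs) < 3) {
    abort("fewer than 3 mother-daughter pairs with both cycle lengths defined",
          class = "embryokin_argument_error")
  }
  out <- pearson_r2(pairs$m_len, pairs$d_len)
  out$method <- paste0("mother_daughter_correlation (", method, ")")
  out
}

#' Sister-cell cycle correlation and division concordance
#'
#' For the cells of cleavage round k, pairs each cell with its sister
#' (same mother). Returns (1) the squared Pearson correlation of sister
#' cycle lengths, ordering pairs by lineage label (the ".1" sister on x,
#' ".2" on y), and (2) a Fisher's exact test of the 2x2 concordance of
#' "divided within the observation horizon" between sisters, counted once
#' per unordered pair — the non-cell-autonomous cleavage analysis.
#'
#' @param division_table A validated division-event cohort.
#' @param round_k Cleavage round of the sister cells.
#' @return A list with `correlation` and `contingency` result tibbles (the
#'   latter also carries the concordance table as an attribute
#'   `"table"`).
#' @export
sister_stats <- function(division_table, round_k) {
  df <- tibble::as_tibble(division_table)
  df$round <- cell_round(df$cell_id)
  cells <- dplyr::filter(df, .data$round == round_k, !is.na(.data$parent_id))
  cells$suffix <- stringr::str_extract(cells$cell_id, "[12]$")
  cells$length <- dplyr::if_else(cells$fate == "divided",
                                 cells$end_hpa - cells$birth_hpa, NA_real_)
  wide <- cells |>
    dplyr::select("embryo_id", "parent_id", "suffix", "fate", "length") |>
    tidyr::pivot_wider(names_from = "suffix",
                       values_from = c("fate", "length")) |>
    dplyr::filter(!is.na(.data$fate_1), !is.na(.data$fate_2))
  both_len <- dplyr::filter(wide, !is.na(.data$length_1), !is.na(.data$length_2))
  if (nrow(both_len) < 3) {
    abort("fewer than 3 sister pairs with both cycle lengths defined",
          class = "embryokin_argument_error")
  }
  correlation <- pearson_r2(both_len$length_1, both_len$length_2)
  correlation$method <- "sister_correlation"
  d1 <- factor(wide$fate_1 == "divided", levels = c(TRUE, FALSE))
  d2 <- factor(wide$fate_2 == "divided", levels = c(TRUE, FALSE))
  tab <- table(d1, d2, dnn = c("cell_divided", "sister_divided"))
  contingency <- fisher_exact_2x2(tab)
  contingency$method <- "sister_division_concordance (fisher)"
  attr(contingency, "table") <- tab
  list(correlation = correlation, contingency = contingency)
}

#' Logistic association of M-phase aberrancy with cycle length
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares) of aberrancy on cell-cycle length:
#' logit P(aberrant) = b0 + b1 * length. Tests whether longer cell cycles
#' carry a higher risk of an aberrant M phase. Complete separation is
#' detected and flagged (with the sign of the diverging coefficient)
#' rather than reported as a finite estimate.
#'
#' @param events A data frame with numeric `cycle_length` (hours) and
#'   logical `aberrant`; or two vectors via `cycle_length`/`aberrant`.
#' @param cycle_length,aberrant Used when `events` is missing.
#' @return A one-row tibble: `estimate` = b1 (per hour), `statistic` =
#'   Wald z, `p_value`, `n`, `separation`, `converged`.
#' @export
aberrancy_logistic <- function(events = NULL, cycle_length = NULL,
                               aberrant = NULL) {
  if (!is.null(events)) {
    cycle_length <- events$cycle_length
    aberrant <- events$aberrant
  }
  ok <- complete.cases(cycle_length, aberrant)
  x <- cycle_length[ok]; y <- as.logical(aberrant[ok])
  if (sum(y) < 2 || sum(!y) < 2) {
    abort("need at least 2 events of each outcome class",
          class = "embryokin_argument_error")
  }
  # complete separation on a single predictor is a threshold on x
  sep_pos <- min(x[y]) > max(x[!y])
  sep_neg <- max(x[y]) < min(x[!y])
  if (sep_pos || sep_neg) {
    return(stat_result("aberrancy_logistic", Inf * (1 - 2 * sep_neg),
                       NA_real_, NA_real_, length(y),
                       separation = TRUE, converged = FALSE))
  }
  X <- cbind(1, x)
  beta <- c(0, 0)
  converged <- FALSE
  for (it in 1:100) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    XtWX <- crossprod(X, X * w)
    step <- solve(XtWX, crossprod(X, y - mu))
    beta <- beta + drop(step)
    if (max(abs(step)) < 1e-10) { converged <- TRUE; break }
  }
  mu <- plogis(drop(X %*% beta))
  w <- pmax(mu * (1 - mu), 1e-10)
  se <- unname(sqrt(diag(solve(crossprod(X, X * w)))))
  beta <- unname(beta)
  z <- beta[2] / se[2]
  stat_result("aberrancy_logistic", beta[2], z, 2 * pnorm(-abs(z)),
              length(y), separation = FALSE, converged = converged,
              intercept = beta[1])
}
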