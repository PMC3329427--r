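test_that("exact Wilcoxon p-values match full enumeration", {
  # spec'd worked example: complete separation of 3 vs 3
  res <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6), mode = "exact")
  expect_equal(res$p_value, 0.1)

  # enumeration oracle over all rank subsets, distinct values
  enum_p <- function(x, y) {
    n <- length(x); N <- n + length(y)
    r <- rank(c(x, y))
    U_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
    idx <- combn(N, n)
    U_all <- apply(idx, 2, function(s) sum(s) - n * (n + 1) / 2)
    nm2 <- n * length(y) / 2
    mean(abs(U_all - nm2) >= abs(U_obs - nm2) - 1e-9)
  }
  set.seed(42)
  for (n in 2:4) for (m in 2:4) {
    v <- sample(100, n + m)
    x <- v[seq_len(n)]; y <- v[-seq_len(n)]
    expect_equal(wilcoxon_rank_sum(x, y, mode = "exact")$p_value,
                 enum_p(x, y),
                 label = sprintf("exact p for n=%d m=%d", n, m))
  }
})

test_that("Wilcoxon agrees with the stats implementation in both modes", {
  set.seed(7)
  x <- rnorm(8); y <- rnorm(9, 0.5)
  expect_equal(wilcoxon_rank_sum(x, y, mode = "exact")$p_value,
               wilcox.test(x, y, exact = TRUE)$p.value)
  x2 <- c(rnorm(30), 1, 1); y2 <- c(rnorm(25, 0.4), 1)
  expect_equal(suppressWarnings(
    wilcoxon_rank_sum(x2, y2, mode = "normal_approx")$p_value),
    suppressWarnings(wilcox.test(x2, y2, exact = FALSE,
                                 correct = TRUE)$p.value))
})

test_that("degenerate Wilcoxon inputs give p = 1 with a warning", {
  expect_warning(res <- wilcoxon_rank_sum(1, 1), "identical")
  expect_equal(res$p_value, 1)
  same <- c(3, 1, 2)
  res2 <- suppressWarnings(wilcoxon_rank_sum(same, same))
  expect_equal(res2$p_value, 1)
})

test_that("Fisher's exact test reproduces hand and published tables", {
  # hypergeometric support enumerated by hand: [[2,0],[0,2]]
  expect_equal(fisher_exact_2x2(matrix(c(2, 0, 0, 2), 2))$p_value, 1 / 3)
  # fast/slow NT blastocyst counts reconstructed from the reported rates
  t1 <- matrix(c(129, 83, 135, 216), 2)
  expect_equal(fisher_exact_2x2(t1)$p_value, 2.6e-7, tolerance = 0.05)
  # arginine supplementation counts
  arg <- matrix(c(48, 70, 107, 85), 2)
  expect_equal(fisher_exact_2x2(arg)$p_value, 0.014, tolerance = 0.05)
  # NO-donor control experiment
  deta <- matrix(c(28, 33, 52, 48), 2)
  expect_equal(fisher_exact_2x2(deta)$p_value, 0.517, tolerance = 0.01)
  # cross-check every case against the reference implementation
  for (tab in list(t1, arg, deta, matrix(c(9, 3, 67, 30), 2))) {
    expect_equal(fisher_exact_2x2(tab)$p_value,
                 fisher.test(tab)$p.value, tolerance = 1e-10)
  }
})

test_that("Fisher's test is invariant under transposition and label swaps", {
  set.seed(3)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 8), 2)
    p <- fisher_exact_2x2(tab)$p_value
    expect_equal(fisher_exact_2x2(t(tab))$p_value, p)
    expect_equal(fisher_exact_2x2(tab[2:1, 2:1])$p_value, p)
  }
  expect_warning(res <- fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2)), "margin")
  expect_equal(res$p_value, 1)
  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2)),
               class = "embryokin_argument_error")
})

test_that("squared Pearson correlation matches hand computation", {
  x <- 0:5
  expect_equal(pearson_r2(x, 2 * x + 1)$estimate, 1)
  res <- pearson_r2(c(0, 1, 2, 3), c(0, 1, 0, 1))
  expect_equal(res$estimate, 0.2)
  expect_equal(res$p_value,
               cor.test(c(0, 1, 2, 3), c(0, 1, 0, 1))$p.value)
  expect_error(pearson_r2(c(1, 2), c(3, 4)),
               class = "embryokin_argument_error")
  expect_warning(out <- pearson_r2(c(1, 1, 1), c(1, 2, 3)), "variance")
  expect_true(is.na(out$estimate))
})

test_that("r^2 is invariant under positive affine transforms", {
  set.seed(5)
  x <- rnorm(20); y <- x + rnorm(20)
  base <- pearson_r2(x, y)$estimate
  expect_equal(pearson_r2(3 * x + 2, y)$estimate, base)
  expect_equal(pearson_r2(x, 0.5 * y - 7)$estimate, base)
})

test_that("group comparison reports medians, MADs and a Wilcoxon p", {
  f <- tibble::tibble(
    embryo_id = as.character(1:8),
    group = rep(c("NT", "ICSI"), each = 4),
    cc2 = c(20, 21, 22, 23, 17, 18, 19, 20)
  )
  res <- group_feature_compare(f, "cc2", groups = c("NT", "ICSI"))
  expect_equal(res$summary$median, c(21.5, 18.5))
  expect_equal(res$summary$mad, c(1, 1))
  expect_equal(res$test$estimate, 3)
  # identical groups: estimate 0, p 1
  f2 <- f; f2$cc2 <- rep(c(1, 2, 3, 4), 2)
  res2 <- group_feature_compare(f2, "cc2", groups = c("NT", "ICSI"))
  expect_equal(res2$test$estimate, 0)
  expect_equal(res2$test$p_value, 1)
  # permutation invariance of the cohort rows
  res3 <- group_feature_compare(f[sample(8), ], "cc2", groups = c("NT", "ICSI"))
  expect_equal(res3$summary, res$summary)
  expect_equal(res3$test, res$test)
  expect_error(group_feature_compare(f, "nope"),
               "nope", class = "embryokin_argument_error")
})

test_that("mother-daughter pairing uses both daughters and recovers r^2", {
  coh <- simulate_cohort(sim_preset("ICSI-default"), n_embryos = 40, seed = 2)
  res <- mother_daughter_correlation(coh, 2)
  expect_true(res$estimate >= 0 && res$estimate <= 1)
  # daughters inherit the mother's cycle length exactly -> r^2 = 1
  inherit <- dplyr::bind_rows(purrr::map(1:5, function(i) {
    l <- 16 + i
    tibble::tibble(
      embryo_id = paste0("m", i), group = "X",
      cell_id = c("1", "1.1", "1.2"), parent_id = c(NA, "1", "1"),
      birth_hpa = c(0, l, l), end_hpa = c(l, 2 * l, 2 * l),
      fate = "divided", aberrancy = "none"
    )
  }))
  expect_equal(mother_daughter_correlation(inherit, 1)$estimate, 1)
  # both daughters contribute: 5 mothers -> 10 pairs
  expect_equal(mother_daughter_correlation(inherit, 1)$n, 10)
  expect_equal(mother_daughter_correlation(inherit, 1,
                                           method = "daughter_mean")$n, 5)
})

test_that("independent cycle lengths give near-zero mother-daughter r^2", {
  set.seed(3)
  n <- 200
  rows <- purrr::map(seq_len(n), function(i) {
    l1 <- runif(1, 15, 25); l2 <- runif(2, 10, 20)
    tibble::tibble(
      embryo_id = paste0("e", i), group = "X",
      cell_id = c("1", "1.1", "1.2"), parent_id = c(NA, "1", "1"),
      birth_hpa = c(0, l1, l1), end_hpa = c(l1, l1 + l2),
      fate = "divided", aberrancy = "none"
    )
  })
  coh <- dplyr::bind_rows(rows)
  expect_lt(mother_daughter_correlation(coh, 1)$estimate, 0.05)
})

test_that("sister statistics: synchrony correlation and fate concordance", {
  coh <- simulate_cohort(sim_preset("ICSI-default"), n_embryos = 30, seed = 9)
  res <- suppressWarnings(sister_stats(coh, 2))
  expect_true(res$correlation$estimate >= 0 && res$correlation$estimate <= 1)
  expect_true(res$contingency$p_value >= 0 && res$contingency$p_value <= 1)

  # perfectly synchronous sisters -> r^2 = 1
  sync <- dplyr::bind_rows(purrr::map(1:6, function(i) {
    l1 <- 18 + i; l2 <- 12 + i
    tibble::tibble(
      embryo_id = paste0("s", i), group = "X",
      cell_id = c("1", "1.1", "1.2"), parent_id = c(NA, "1", "1"),
      birth_hpa = c(0, l1, l1), end_hpa = c(l1, l1 + l2, l1 + l2),
      fate = "divided", aberrancy = "none"
    )
  }))
  expect_equal(suppressWarnings(sister_stats(sync, 2))$correlation$estimate, 1)

  # concordant-only fates with both outcome types: significant association
  conc <- dplyr::bind_rows(purrr::map(1:12, function(i) {
    divides <- i <= 6
    tibble::tibble(
      embryo_id = paste0("c", i), group = "X",
      cell_id = c("1", "1.1", "1.2"), parent_id = c(NA, "1", "1"),
      birth_hpa = c(0, 20, 20),
      end_hpa = c(20, if (divides) c(38, 38.5) else c(96, 96)),
      fate = c("divided", if (divides) c("divided", "divided")
               else c("censored", "censored")),
      aberrancy = "none"
    )
  }))
  res2 <- suppressWarnings(sister_stats(conc, 2))
  expect_lt(res2$contingency$p_value, 0.05)
})

test_that("the aberrancy logistic fit matches a likelihood-grid oracle", {
  events <- tibble::tibble(
    cycle_length = c(10, 11, 12, 13, 14, 15, 16, 12.5),
    aberrant = c(FALSE, FALSE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE)
  )
  fit <- aberrancy_logistic(events)
  # brute-force likelihood maximization over a (b0, b1) grid
  loglik <- function(b0, b1) {
    eta <- b0 + b1 * events$cycle_length
    sum(ifelse(events$aberrant, plogis(eta, log.p = TRUE),
               plogis(-eta, log.p = TRUE)))
  }
  grid_b1 <- seq(fit$estimate - 0.5, fit$estimate + 0.5, by = 0.001)
  best <- -Inf; best_b1 <- NA
  for (b1 in grid_b1) {
    opt <- optimize(function(b0) -loglik(b0, b1), c(-50, 50))
    if (-opt$objective > best) { best <- -opt$objective; best_b1 <- b1 }
  }
  expect_equal(fit$estimate, best_b1, tolerance = 1e-3)
  # and against the reference IRLS fit
  ref <- glm(aberrant ~ cycle_length, binomial(), data = events)
  # glm stops on a looser deviance criterion; agreement to ~1e-3 suffices
  expect_equal(fit$estimate, unname(coef(ref)[2]), tolerance = 1e-4)
  expect_equal(fit$p_value,
               summary(ref)$coefficients[2, 4], tolerance = 1e-3)
})

test_that("logistic separation is flagged, not returned as a finite slope", {
  events <- tibble::tibble(cycle_length = c(10, 11, 12, 20, 21, 22),
                           aberrant = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  fit <- aberrancy_logistic(events)
  expect_true(fit$separation)
  expect_equal(fit$estimate, Inf)
  expect_error(aberrancy_logistic(
    tibble::tibble(cycle_length = 1:4, aberrant = c(TRUE, rep(FALSE, 3)))),
    class = "embryokin_argument_error")
})

test_that("a null cohort rarely shows a significant length-aberrancy link", {
  set.seed(9)
  reps <- 60
  sig <- 0
  for (r in seq_len(reps)) {
    ev <- tibble::tibble(cycle_length = rnorm(300, 13, 1.5),
                         aberrant = runif(300) < 0.15)
    if (sum(ev$aberrant) < 2 || sum(!ev$aberrant) < 2) next
    fit <- aberrancy_logistic(ev)
    if (!fit$separation && fit$p_value < 0.05) sig <- sig + 1
  }
  expect_lte(sig / reps, 0.10)
})
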