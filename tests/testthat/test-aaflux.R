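toy_sample <- function(conc, n_embryos = 10, hours = 17.5, vol = 5,
                       aa = names(conc)) {
  tibble::tibble(
    sample_id = "s1", control_id = "c1", group = "NT", stage_window = "0-24",
    n_embryos = n_embryos, hours = hours, drop_volume_ul = vol,
    amino_acid = aa, conc_umol_l = unname(conc)
  )
}
toy_control <- function(conc, aa = names(conc)) {
  tibble::tibble(
    sample_id = "c1", control_id = NA_character_, group = "NT",
    stage_window = "0-24", n_embryos = 0, hours = 17.5, drop_volume_ul = 5,
    amino_acid = aa, conc_umol_l = unname(conc)
  )
}

test_that("turnover rate follows the unit bookkeeping exactly", {
  s <- toy_sample(c(Arg = 90))
  ctrl <- toy_control(c(Arg = 100))
  r <- compute_turnover(s, ctrl)
  expect_equal(r$rate_pmol_embryo_h, 10 * 5 / (10 * 17.5))
  # sample == control -> all rates zero
  expect_equal(compute_turnover(toy_sample(c(Arg = 100)), ctrl)$rate_pmol_embryo_h, 0)
  # appearance gives a negative rate
  expect_lt(compute_turnover(toy_sample(c(Arg = 110)), ctrl)$rate_pmol_embryo_h, 0)
  # missing amino acid in the control is named
  expect_error(compute_turnover(toy_sample(c(Arg = 90, Gln = 500)), ctrl),
               "Gln", class = "embryokin_argument_error")
})

test_that("turnover is linear in the depletion and scales with volume", {
  ctrl <- toy_control(c(Arg = 100, Gln = 400))
  r1 <- compute_turnover(toy_sample(c(Arg = 95, Gln = 410)), ctrl)
  r2 <- compute_turnover(toy_sample(c(Arg = 90, Gln = 420)), ctrl)
  expect_equal(r2$rate_pmol_embryo_h, 2 * r1$rate_pmol_embryo_h)
  # doubling drop volume doubles every rate
  s2 <- toy_sample(c(Arg = 95, Gln = 410), vol = 10)
  expect_equal(compute_turnover(s2, ctrl)$rate_pmol_embryo_h,
               2 * r1$rate_pmol_embryo_h)
  # halving embryo-hours doubles the per-embryo rate
  s3 <- toy_sample(c(Arg = 95, Gln = 410), n_embryos = 5)
  expect_equal(compute_turnover(s3, ctrl)$rate_pmol_embryo_h,
               2 * r1$rate_pmol_embryo_h)
})

test_that("total turnover sums absolute depletion and appearance", {
  expect_equal(total_turnover(c(0.2, -0.3)), 0.5)
  expect_equal(total_turnover(c(0, 0, 0)), 0)
  expect_equal(total_turnover(-1.2), 1.2)
  expect_error(total_turnover(numeric(0)), class = "embryokin_argument_error")
})

test_that("the turnover matrix summarises replicates with mean and SEM", {
  rates <- tibble::tibble(
    sample_id = paste0("s", 1:3), group = "NT", stage_window = "0-24",
    amino_acid = "Arg", rate_pmol_embryo_h = c(0.2, 0.3, 0.4)
  )
  tm <- suppressWarnings(build_matrix(rates))
  expect_equal(tm$mean_rate, 0.3)
  expect_equal(tm$sem, sd(c(0.2, 0.3, 0.4)) / sqrt(3), tolerance = 1e-10)
  expect_equal(tm$n_replicates, 3)
  # identical replicates -> SEM 0
  rates0 <- rates; rates0$rate_pmol_embryo_h <- 0.2857
  expect_equal(suppressWarnings(build_matrix(rates0))$sem, 0)
  # a missing (group, stage) combination warns
  expect_warning(build_matrix(rates), "no replicates")
})

test_that("amino-acid clustering uses 1 - Spearman / complete linkage", {
  m <- tibble::tibble(
    amino_acid = rep(c("A", "B", "C", "D"), each = 4),
    group = "G",
    stage_window = rep(c("0-24", "24-48", "48-72", "72-96"), 4),
    mean_rate = c(1, 2, 3, 4,   1.1, 2.1, 3.1, 4.1,   4, 3, 2, 1,  2, 1, 4, 3),
    sem = 0, n_replicates = 3
  )
  class(m) <- c("turnover_matrix", class(m))
  cl <- cluster_turnover(m)
  # identical ranks (A, B) merge first at distance 0
  expect_equal(cl$aa_hclust$height[1], 0)
  expect_equal(unname(stats::cutree(cl$aa_hclust, 3)["A"]),
               unname(stats::cutree(cl$aa_hclust, 3)["B"]))
  # exactly reversed ranks sit at the maximal distance 2
  d <- 1 - cor(t(as.matrix(m)), method = "spearman")
  expect_equal(unname(d["A", "C"]), 2)
  # a constant profile has undefined rank correlation -> distance 2, warning
  m2 <- m
  m2$mean_rate[m2$amino_acid == "D"] <- 1
  expect_warning(cl2 <- cluster_turnover(m2), "constant")
  expect_equal(max(cl2$aa_hclust$height), 2)
})

test_that("group clustering reproduces a manual Lance-Williams Ward trace", {
  # independent naive agglomeration on squared Euclidean distances
  naive_ward <- function(m) {
    cl <- as.list(seq_len(ncol(m)))
    d <- as.matrix(dist(t(m)))^2
    sizes <- rep(1, ncol(m))
    merges <- list()
    act <- seq_len(ncol(m))
    while (length(act) > 1) {
      best <- c(NA, NA); bd <- Inf
      for (i in act) for (j in act) if (i < j) {
        dd <- d[i, j]
        if (dd < bd - 1e-12) { bd <- dd; best <- c(i, j) }
      }
      i <- best[1]; j <- best[2]
      merges[[length(merges) + 1]] <- list(pair = best, height = sqrt(bd))
      # Lance-Williams update for Ward's criterion
      for (k in setdiff(act, best)) {
        ai <- (sizes[i] + sizes[k]) / (sizes[i] + sizes[j] + sizes[k])
        aj <- (sizes[j] + sizes[k]) / (sizes[i] + sizes[j] + sizes[k])
        b <- -sizes[k] / (sizes[i] + sizes[j] + sizes[k])
        d[i, k] <- d[k, i] <- ai * d[i, k] + aj * d[j, k] + b * d[i, j]
      }
      sizes[i] <- sizes[i] + sizes[j]
      act <- setdiff(act, j)
    }
    merges
  }
  set.seed(6)
  mat <- matrix(rnorm(4 * 4), 4, 4,
                dimnames = list(c("A", "B", "C", "D"), paste0("g", 1:4)))
  m <- tibble::as_tibble(as.data.frame(mat), rownames = "amino_acid") |>
    tidyr::pivot_longer(-amino_acid, names_to = "col", values_to = "mean_rate")
  m$group <- m$col
  m$stage_window <- "0-24"
  m$sem <- 0; m$n_replicates <- 3
  class(m) <- c("turnover_matrix", class(m))
  cl <- suppressWarnings(cluster_turnover(m))
  trace <- naive_ward(mat)
  expect_equal(cl$group_hclust$height,
               vapply(trace, function(t) t$height, numeric(1)),
               tolerance = 1e-10)
})

test_that("profile correlations are symmetric in sign and self-identical", {
  tm <- suppressWarnings(build_matrix(turnover_rates(
    simulate_spent_media(n_replicates = 3, noise_sd = 0, seed = 2))))
  self <- profile_correlation(tm, "ICSI 0-24", "ICSI 0-24")
  expect_equal(self$estimate, 1)
  m <- as.matrix(tm)
  neg <- pearson_r2(m[, "ICSI 0-24"], -m[, "ICSI 0-24"])
  expect_equal(neg$estimate, 1)
  expect_equal(neg$r, -1)
  expect_error(profile_correlation(tm, "ICSI 0-24", "bogus"),
               "bogus", class = "embryokin_argument_error")
})
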