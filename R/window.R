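#' Candidate window boundaries for a feature axis
#'
#' Midpoints between consecutive sorted unique finite values, with -Inf
#' prepended and +Inf appended. These are the only boundary positions the
#' exhaustive window search needs to consider: moving a boundary between
#' two midpoints cannot change which embryos fall inside the window.
#'
#' @param values Numeric sample (`NA` ignored).
#' @return Ordered numeric vector of candidate boundaries.
#' @export
candidate_boundaries <- function(values) {
  v <- sort(unique(values[is.finite(values)]))
  if (length(v) == 0) {
    abort("all values are missing; no candidate boundaries",
          class = "embryokin_argument_error")
  }
  if (length(v) == 1) return(c(-Inf, Inf))
  mids <- (v[-1] + v[-length(v)]) / 2
  c(-Inf, mids, Inf)
}

#' Construct an axis-aligned window classifier
#'
#' The prediction rule of the timing-based blastocyst predictor: an embryo
#' whose value on every listed feature lies inside the closed interval
#' `[lower, upper]` for that feature is predicted to form a blastocyst.
#'
#' @param features Character vector of 1-3 feature names.
#' @param lower,upper Numeric vectors of interval endpoints (may be
#'   `-Inf`/`Inf`), one per feature, with `lower <= upper`.
#' @return A `window_classifier` object.
#' @export
window_classifier <- function(features, lower, upper) {
  if (length(features) < 1 || length(features) > 3) {
    abort("a window classifier uses 1 to 3 features",
          class = "embryokin_argument_error")
  }
  if (length(lower) != length(features) || length(upper) != length(features)) {
    abort("one interval per feature is required",
          class = "embryokin_argument_error")
  }
  if (any(lower > upper)) {
    abort("interval lower bounds must not exceed upper bounds",
          class = "embryokin_argument_error")
  }
  structure(
    list(features = features, lower = as.numeric(lower),
         upper = as.numeric(upper)),
    class = "window_classifier"
  )
}

#' @export
print.window_classifier <- function(x, ...) {
  cat("<window_classifier> predict blastocyst when\n")
  for (i in seq_along(x$features)) {
    cat(sprintf("  %s in [%.4g, %.4g]\n", x$features[i], x$lower[i], x$upper[i]))
  }
  if (!is.null(x$score)) {
    cat(sprintf("  F = %.3f, accuracy = %.3f (n = %d scored)\n",
                x$score$f_score, x$score$accuracy, x$score$n_scored))
  }
  invisible(x)
}

prediction_score <- function(tp, fp, tn, fn) {
  sn <- if (tp + fn > 0) tp / (tp + fn) else 0
  pr <- if (tp + fp > 0) tp / (tp + fp) else 0
  total <- tp + fp + tn + fn
  acc <- if (total > 0) (tp + tn) / total else 0
  f <- if (pr + sn > 0) 2 * pr * sn / (pr + sn) else 0
  tibble::tibble(tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = sn, precision = pr,
                 accuracy = acc, f_score = f)
}

# rows of `data` with no missing value on the classifier features,
# plus the outcome; returns list(values matrix, y, n_excluded)
window_data <- function(data, features, outcome) {
  miss <- setdiff(c(features, outcome), names(data))
  if (length(miss) > 0) {
    abort(paste0("column(s) not found: ", paste(miss, collapse = ", ")),
          class = "embryokin_argument_error")
  }
  vals <- as.matrix(data[, features, drop = FALSE])
  y <- as.logical(data[[outcome]])
  ok <- complete.cases(vals, y)
  list(values = vals[ok, , drop = FALSE], y = y[ok],
       n_excluded = sum(!ok))
}

#' Score a window classifier on a cohort
#'
#' Applies the inside-all-intervals rule (closed intervals) and reports
#' confusion counts together with sensitivity, precision, accuracy, and
#' F-score (harmonic mean of precision and sensitivity; 0 when both are
#' 0). Embryos missing any of the classifier's features or the outcome are
#' excluded and counted in `n_excluded`.
#'
#' @param classifier A [window_classifier()].
#' @param data Feature tibble (one row per embryo).
#' @param outcome Name of the logical outcome column
#'   (default `"blastocyst"`).
#' @return A one-row tibble of counts and scores plus `n_scored`,
#'   `n_excluded`.
#' @export
score_window <- function(classifier, data, outcome = "blastocyst") {
  wd <- window_data(data, classifier$features, outcome)
  if (length(wd$y) == 0) {
    abort("no embryos with complete features and outcome to score",
          class = "embryokin_argument_error")
  }
  inside <- rep(TRUE, length(wd$y))
  for (i in seq_along(classifier$features)) {
    v <- wd$values[, i]
    inside <- inside & v >= classifier$lower[i] & v <= classifier$upper[i]
  }
  sc <- prediction_score(
    tp = sum(inside & wd$y), fp = sum(inside & !wd$y),
    tn = sum(!inside & !wd$y), fn = sum(!inside & wd$y)
  )
  sc$n_scored <- length(wd$y)
  sc$n_excluded <- wd$n_excluded
  sc
}

# interval membership matrix: n x (#windows) logical, windows are all
# pairs lo < hi of the boundary vector b over values v
axis_windows <- function(v, b) {
  nb <- length(b)
  pairs <- which(upper.tri(matrix(TRUE, nb, nb)), arr.ind = TRUE)
  lo <- b[pairs[, 1]]
  hi <- b[pairs[, 2]]
  list(lo = lo, hi = hi)
}

#' Exhaustive best-window search
#'
#' Searches every axis-aligned window over the Cartesian product of
#' per-feature candidate boundaries (see [candidate_boundaries()]) and
#' returns the window maximizing the objective. The search is exact: no
#' pruning that could change the argmax. Ties are broken by (1) higher
#' accuracy, (2) smaller window volume (product of interval widths clipped
#' to the observed data range), (3) lexicographically smallest lower-bound
#' vector.
#'
#' @param data Feature tibble (one row per embryo).
#' @param features 1-3 feature names to search over.
#' @param outcome Logical outcome column name (default `"blastocyst"`).
#' @param objective `"f_score"` (default) or `"accuracy"`.
#' @return A `window_classifier` with the winning intervals; its `score`
#'   element holds the [score_window()] result.
#' @export
best_window <- function(data, features, outcome = "blastocyst",
                        objective = c("f_score", "accuracy")) {
  objective <- match.arg(objective)
  if (length(features) < 1 || length(features) > 3) {
    abort("best_window searches 1 to 3 features",
          class = "embryokin_argument_error")
  }
  wd <- window_data(data, features, outcome)
  y <- wd$y
  if (length(unique(y)) < 2) {
    abort("outcomes of both classes are required",
          class = "embryokin_argument_error")
  }
  d <- length(features)

  n_pos <- sum(y)
  n_tot <- length(y)
  score_counts <- function(tp, size) {
    fp <- size - tp
    fn <- n_pos - tp
    tn <- n_tot - size - fn
    sn <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
    pr <- ifelse(size > 0, tp / size, 0)
    acc <- (tp + tn) / n_tot
    f <- ifelse(pr + sn > 0, 2 * pr * sn / (pr + sn), 0)
    list(f = f, acc = acc)
  }

  best <- NULL
  consider <- function(obj, acc, vol, lo_vec, hi_vec) {
    if (is.null(best) ||
        obj > best$obj + 1e-12 ||
        (abs(obj - best$obj) <= 1e-12 &&
           (acc > best$acc + 1e-12 ||
              (abs(acc - best$acc) <= 1e-12 &&
                 (vol < best$vol - 1e-12 ||
                    (abs(vol - best$vol) <= 1e-12 &&
                       lex_less(lo_vec, best$lo))))))) {
      best <<- list(obj = obj, acc = acc, vol = vol, lo = lo_vec, hi = hi_vec)
    }
  }

  if (d == 1) {
    # a window covers a contiguous run of sorted unique values, so counts
    # come from cumulative sums over the boundaries: O(m^2) windows scored
    # without materializing membership matrices
    v <- wd$values[, 1]
    b <- candidate_boundaries(v)
    u <- sort(unique(v))
    pos_u <- vapply(u, function(z) sum(y[v == z]), numeric(1))
    tot_u <- vapply(u, function(z) sum(v == z), numeric(1))
    c0 <- c(0, cumsum(pos_u))
    t0 <- c(0, cumsum(tot_u))
    idx <- which(upper.tri(diag(length(b))), arr.ind = TRUE)
    tp <- c0[idx[, 2]] - c0[idx[, 1]]
    size <- t0[idx[, 2]] - t0[idx[, 1]]
    lo <- b[idx[, 1]]
    hi <- b[idx[, 2]]
    width <- pmin(hi, max(v)) - pmax(lo, min(v))
    sc <- score_counts(tp, size)
    obj <- if (objective == "f_score") sc$f else sc$acc
    top <- which(obj >= max(obj) - 1e-12)
    for (i in top) consider(obj[i], sc$acc[i], width[i], lo[i], hi[i])
  } else {
    axes <- lapply(seq_len(d), function(i) {
      v <- wd$values[, i]
      b <- candidate_boundaries(v)
      w <- axis_windows(v, b)
      # membership: n x #windows (combination search is meant for modest n)
      memb <- outer(v, w$lo, ">=") & outer(v, w$hi, "<=")
      rng <- range(v)
      width <- pmin(w$hi, rng[2]) - pmax(w$lo, rng[1])
      list(lo = w$lo, hi = w$hi, memb = memb, width = width)
    })
    # loop over windows of the later axes, vectorized over the first axis
    grid <- expand.grid(lapply(axes[-1], function(a) seq_along(a$lo)))
    A <- axes[[1]]
    for (g in seq_len(nrow(grid))) {
      inside_rest <- rep(TRUE, n_tot)
      vol_rest <- 1
      lo_rest <- numeric(d - 1); hi_rest <- numeric(d - 1)
      for (j in 2:d) {
        idx <- grid[g, j - 1]
        inside_rest <- inside_rest & axes[[j]]$memb[, idx]
        vol_rest <- vol_rest * axes[[j]]$width[idx]
        lo_rest[j - 1] <- axes[[j]]$lo[idx]
        hi_rest[j - 1] <- axes[[j]]$hi[idx]
      }
      tp <- as.numeric(crossprod(A$memb, y & inside_rest))
      size <- as.numeric(crossprod(A$memb, inside_rest))
      sc <- score_counts(tp, size)
      obj <- if (objective == "f_score") sc$f else sc$acc
      top <- which(obj >= max(obj) - 1e-12)
      for (i in top) {
        consider(obj[i], sc$acc[i], A$width[i] * vol_rest,
                 c(A$lo[i], lo_rest), c(A$hi[i], hi_rest))
      }
    }
  }

  cl <- window_classifier(features, best$lo, best$hi)
  cl$objective <- objective
  cl$score <- score_window(cl, data, outcome)
  cl
}

lex_less <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i] - 1e-12) return(TRUE)
    if (a[i] > b[i] + 1e-12) return(FALSE)
  }
  FALSE
}

#' Screen feature combinations for blastocyst predictivity
#'
#' Runs [best_window()] over every combination of `dims` features from the
#' panel and tabulates the winning window's scores, sorted by F-score
#' descending — the screen across div/cc/diff/ck1 timing variables.
#' Embryos with a missing feature are excluded per combination and counted.
#'
#' @param data Feature tibble.
#' @param panel Character vector of candidate feature names.
#' @param dims Combination size, 1-3 (default 1).
#' @param outcome Logical outcome column (default `"blastocyst"`).
#' @param objective Search objective, as in [best_window()].
#' @return A tibble with one row per combination: `features` (slash-joined
#'   name), per-feature intervals (list column `classifier`), `f_score`,
#'   `accuracy`, `sensitivity`, `precision`, `n_scored`, `n_excluded`.
#' @export
evaluate_feature_panel <- function(data, panel, dims = 1,
                                   outcome = "blastocyst",
                                   objective = c("f_score", "accuracy")) {
  objective <- match.arg(objective)
  if (length(panel) == 0) {
    abort("panel must be non-empty", class = "embryokin_argument_error")
  }
  if (dims < 1 || dims > 3 || dims > length(panel)) {
    abort("dims must be between 1 and min(3, length(panel))",
          class = "embryokin_argument_error")
  }
  combos <- combn(panel, dims, simplify = FALSE)
  rows <- purrr::map(combos, function(fs) {
    cl <- best_window(data, fs, outcome = outcome, objective = objective)
    sc <- cl$score
    tibble::tibble(
      features = paste(fs, collapse = "/"),
      classifier = list(cl),
      f_score = sc$f_score, accuracy = sc$accuracy,
      sensitivity = sc$sensitivity, precision = sc$precision,
      n_scored = sc$n_scored, n_excluded = sc$n_excluded
    )
  })
  dplyr::arrange(dplyr::bind_rows(rows), dplyr::desc(.data$f_score))
}

#' @method tidy window_classifier
#' @export
tidy.window_classifier <- function(x, ...) {
  tibble::tibble(feature = x$features, lower = x$lower, upper = x$upper)
}

#' @method glance window_classifier
#' @export
glance.window_classifier <- function(x, ...) {
  if (is.null(x$score)) {
    abort("classifier has not been scored", class = "embryokin_argument_error")
  }
  x$score
}

#' Plot a 1D or 2D window classifier over the cohort
#'
#' @param object A scored `window_classifier` from [best_window()].
#' @param data The feature tibble it was fitted on.
#' @param outcome Logical outcome column (default `"blastocyst"`).
#' @param ... Unused.
#' @return A ggplot: embryos as points (filled = blastocyst), the
#'   prediction window as a shaded band/rectangle.
#' @method autoplot window_classifier
#' @export
autoplot.window_classifier <- function(object, data, outcome = "blastocyst",
                                       ...) {
  d <- length(object$features)
  wd <- window_data(data, object$features, outcome)
  df <- tibble::as_tibble(as.data.frame(wd$values))
  names(df) <- object$features
  df$outcome <- wd$y
  clip <- function(v, i) {
    rng <- range(wd$values[, i])
    pad <- diff(rng) * 0.05 + 1e-9
    c(max(object$lower[i], rng[1] - pad), min(object$upper[i], rng[2] + pad))
  }
  if (d == 1) {
    xr <- clip(NULL, 1)
    ggplot2::ggplot(df, ggplot2::aes(x = .data[[object$features[1]]],
                                     y = 0)) +
      ggplot2::annotate("rect", xmin = xr[1], xmax = xr[2],
                        ymin = -0.5, ymax = 0.5, alpha = 0.2, fill = "steelblue") +
      ggplot2::geom_jitter(ggplot2::aes(shape = .data$outcome),
                           height = 0.3, width = 0) +
      ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                  name = "blastocyst") +
      ggplot2::labs(y = NULL, title = "Prediction window") +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.y = ggplot2::element_blank())
  } else {
    xr <- clip(NULL, 1); yr <- clip(NULL, 2)
    ggplot2::ggplot(df, ggplot2::aes(x = .data[[object$features[1]]],
                                     y = .data[[object$features[2]]])) +
      ggplot2::annotate("rect", xmin = xr[1], xmax = xr[2],
                        ymin = yr[1], ymax = yr[2],
                        alpha = 0.2, fill = "steelblue") +
      ggplot2::geom_point(ggplot2::aes(shape = .data$outcome)) +
      ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                  name = "blastocyst") +
      ggplot2::labs(title = "Prediction window") +
      ggplot2::theme_minimal()
  }
}
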