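#' Statistical test result container
#'
#' Uniform return shape for all comparisons: test name, statistic,
#' two-sided p-value, sample size, a `method` note (e.g. exact vs
#' approximation) and an effect summary (mean or median difference).
#'
#' @param test test name.
#' @param statistic test statistic.
#' @param p_value two-sided p-value in \[0, 1\] (or `NA`).
#' @param n sample size used.
#' @param method free-text method detail.
#' @param effect effect summary.
#' @return Object of class `stat_result`.
#' @export
stat_result <- function(test, statistic, p_value, n, method = "", effect = NA_real_) {
  if (!is.na(p_value) && (p_value < 0 || p_value > 1))
    stop("p_value must lie in [0, 1]")
  structure(list(test = test, statistic = as.numeric(statistic),
                 p_value = as.numeric(p_value), n = as.integer(n),
                 method = method, effect = as.numeric(effect)),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.3g (n = %d%s)\n",
              x$test, x$statistic, x$p_value, x$n,
              if (nzchar(x$method)) paste0("; ", x$method) else ""))
  invisible(x)
}

#' Paired t-test
#'
#' Two-sided t-test on the paired differences (df = n - 1), used for the
#' objective-noise and CNR comparisons between reconstruction arms.
#'
#' @param x,y paired numeric vectors of equal length (n >= 2).
#' @return A [stat_result()] with the mean difference as effect.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired (equal length)")
  if (length(x) < 2L) stop("need at least 2 pairs")
  d <- x - y
  if (stats::sd(d) == 0)
    stop("degenerate input: paired differences have zero variance")
  tt <- stats::t.test(x, y, paired = TRUE)
  stat_result("paired t-test", unname(tt$statistic), tt$p.value, length(x),
              sprintf("df = %d", length(x) - 1L), effect = mean(d))
}

#' Welch unpaired t-test
#'
#' Two-sided two-sample t-test without assuming equal variances, used for
#' the body-weight and BMI comparison between study and reference groups.
#'
#' @param a,b numeric vectors (each n >= 2).
#' @return A [stat_result()] with the mean difference as effect.
#' @export
unpaired_t <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) stop("each group needs at least 2 values")
  if (stats::sd(a) == 0 && stats::sd(b) == 0)
    stop("degenerate input: both groups are constant")
  tt <- stats::t.test(a, b, var.equal = FALSE)
  stat_result("Welch t-test", unname(tt$statistic), tt$p.value,
              length(a) + length(b),
              sprintf("df = %.2f", unname(tt$parameter)),
              effect = mean(a) - mean(b))
}

# exact null distribution of the positive-rank sum for rank values r:
# counts of achievable sums over all 2^n sign patterns, by polynomial
# convolution on a grid of 2 * rank (handles half-integer mid-ranks)
signrank_exact_p <- function(w, ranks) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  counts <- numeric(total + 1L)   # index s+1 holds #subsets with 2W = s
  counts[1] <- 1
  for (r in r2) {
    shifted <- c(numeric(r), counts[seq_len(total + 1L - r)])
    counts <- counts + shifted
  }
  probs <- counts / 2^length(r2)
  w2 <- as.integer(round(2 * w))
  p_le <- sum(probs[seq_len(w2 + 1L)])
  p_ge <- sum(probs[seq(w2 + 1L, total + 1L)])
  min(1, 2 * min(p_le, p_ge))
}

#' Wilcoxon signed-rank test
#'
#' Two-sided paired signed-rank test used for the subjective image-quality
#' comparisons. Zero differences are dropped by default (classic
#' convention; `zeros = "pratt"` keeps them in the ranking). Tied absolute
#' differences receive mid-ranks. The p-value is exact (full enumeration
#' of the 2^n sign patterns via rank convolution) when the number of
#' nonzero differences is at most 20 and there are no ties; otherwise a
#' normal approximation with tie and continuity corrections is used.
#' `mode` forces either branch.
#'
#' @param x,y paired numeric vectors.
#' @param mode `"auto"`, `"exact"` or `"approx"`.
#' @param zeros `"drop"` or `"pratt"`.
#' @return A [stat_result()]; statistic is the positive-rank sum V, the
#'   effect is the median of the nonzero differences.
#' @export
wilcoxon_signed_rank <- function(x, y, mode = c("auto", "exact", "approx"),
                                 zeros = c("drop", "pratt")) {
  mode <- match.arg(mode)
  zeros <- match.arg(zeros)
  if (length(x) != length(y)) stop("x and y must be paired (equal length)")
  d <- x - y
  nz <- d[d != 0]
  if (length(nz) == 0L)
    stop("degenerate input: all paired differences are zero")
  n_zero <- sum(d == 0)

  if (zeros == "drop") {
    r <- rank(abs(nz))
    w <- sum(r[nz > 0])
    ties <- any(duplicated(abs(nz)))
    n <- length(nz)
    use_exact <- switch(mode,
      auto = n <= 20L && !ties,
      exact = TRUE,
      approx = FALSE)
    if (use_exact && ties)
      stop("exact p-value is not defined with tied absolute differences")
    if (use_exact) {
      p <- signrank_exact_p(w, r)
      meth <- sprintf("exact enumeration, %d nonzero differences", n)
    } else {
      mu <- n * (n + 1) / 4
      tie_tab <- table(abs(nz))
      sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
        sum(tie_tab^3 - tie_tab) / 48
      z <- (w - mu - 0.5 * sign(w - mu)) / sqrt(sig2)
      p <- 2 * stats::pnorm(-abs(z))
      meth <- sprintf("normal approximation with tie and continuity correction, %d nonzero differences", n)
    }
  } else {
    # Pratt: zeros participate in the ranking, their ranks are discarded
    r_all <- rank(abs(d))
    w <- sum(r_all[d > 0])
    n <- length(d)
    mu <- (n * (n + 1) - n_zero * (n_zero + 1)) / 4
    tie_tab <- table(abs(d[d != 0]))
    sig2 <- (n * (n + 1) * (2 * n + 1) -
               n_zero * (n_zero + 1) * (2 * n_zero + 1)) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (w - mu - 0.5 * sign(w - mu)) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    meth <- sprintf("Pratt zero handling, normal approximation, %d zeros kept", n_zero)
  }
  stat_result("Wilcoxon signed-rank test", w, min(1, p),
              length(x), meth, effect = stats::median(nz))
}

#' Weighted Cohen's kappa
#'
#' Chance-corrected agreement for ordinal ratings with distance-dependent
#' weights: agreement weight `1 - (|i - j| / (k - 1))^q` with q = 1
#' (linear) or 2 (quadratic); expected agreement from the marginal
#' products. Returns the kappa coefficient as the statistic; no p-value
#' is attached (the coefficient is reported as a point estimate).
#'
#' @param r1,r2 equal-length integer rating vectors.
#' @param weights `"linear"` or `"quadratic"`.
#' @param categories vector of valid categories (default 1:5).
#' @return A [stat_result()] with kappa as statistic and `p_value = NA`.
#' @export
weighted_kappa <- function(r1, r2, weights = c("linear", "quadratic"),
                           categories = 1:5) {
  weights <- match.arg(weights)
  if (length(r1) != length(r2)) stop("rating vectors must have equal length")
  if (!all(r1 %in% categories) || !all(r2 %in% categories))
    stop("ratings outside the category range")
  k <- length(categories)
  f1 <- factor(r1, levels = categories)
  f2 <- factor(r2, levels = categories)
  O <- table(f1, f2) / length(r1)
  m1 <- rowSums(O); m2 <- colSums(O)
  E <- outer(m1, m2)
  dist <- abs(outer(seq_len(k), seq_len(k), `-`)) / (k - 1)
  W <- 1 - if (weights == "linear") dist else dist^2
  po <- sum(W * O)
  pe <- sum(W * E)
  kap <- if (abs(1 - pe) < .Machine$double.eps^0.5) 1 else (po - pe) / (1 - pe)
  stat_result("weighted kappa", kap, NA_real_, length(r1),
              sprintf("%s weights, %d categories", weights, k))
}

#' Compare two reconstruction arms across a cohort
#'
#' Builds the full comparison table for a paired cohort: one row per
#' quantity — objective noise in 5 anatomies and CNR at 2 sites by paired
#' t-test, 7 subjective items by Wilcoxon signed-rank test — with the
#' per-arm mean and SD and the raw two-sided p-value (no multiplicity
#' correction). Subjective scores are averaged over the two reviewers per
#' patient by default (`rating_mode = "reviewer_mean"`); with
#' `"per_reviewer"` each reviewer contributes a pair.
#'
#' @param cohort a `ct_cohort` from [generate_cohort()], or a list with
#'   `measurements` and `ratings` data.frames in the same schema.
#' @param arms length-2 character; defaults to the cohort's arms.
#' @param rating_mode `"reviewer_mean"` or `"per_reviewer"`.
#' @param kappa_weights weighting for the inter-reviewer agreement
#'   coefficient attached as attribute `"kappa"`.
#' @return data.frame of class `arm_comparison` with one row per
#'   quantity: `quantity`, `group`, `mean_a`, `sd_a`, `mean_b`, `sd_b`,
#'   `test`, `statistic`, `p_value`, `n`, `effect`. Attribute `"kappa"`
#'   holds the pooled inter-reviewer [weighted_kappa()].
#' @export
compare_arms <- function(cohort, arms = NULL,
                         rating_mode = c("reviewer_mean", "per_reviewer"),
                         kappa_weights = "linear") {
  rating_mode <- match.arg(rating_mode)
  meas <- cohort$measurements
  rat <- cohort$ratings
  if (is.null(arms))
    arms <- if (!is.null(cohort$spec)) cohort$spec$arms else unique(meas$arm)
  if (length(unique(meas$patient)) < 2L)
    stop("paired comparison needs at least 2 patients")

  rows <- list()
  add_row <- function(quantity, group, va, vb, res) {
    rows[[length(rows) + 1L]] <<- data.frame(
      quantity = quantity, group = group,
      mean_a = mean(va), sd_a = stats::sd(va),
      mean_b = mean(vb), sd_b = stats::sd(vb),
      test = res$test, statistic = res$statistic,
      p_value = res$p_value, n = res$n, effect = res$effect)
  }

  for (an in c("liver", "upper_fat", "psoas", "bladder", "lower_fat")) {
    va <- objective_noise(meas, an, arms[1])$values
    vb <- objective_noise(meas, an, arms[2])$values
    add_row(an, "objective_noise", va, vb, paired_t(va, vb))
  }
  for (site in c("liver", "pelvis")) {
    va <- cohort_cnr(meas, site, arms[1])
    vb <- cohort_cnr(meas, site, arms[2])
    add_row(site, "cnr", va, vb, paired_t(va, vb))
  }
  for (item in unique(rat$item)) {
    sub <- rat[rat$item == item, ]
    pick <- function(arm) {
      s <- sub[sub$arm == arm, ]
      if (rating_mode == "reviewer_mean") {
        v <- tapply(s$score, s$patient, mean)
        as.numeric(v[order(as.numeric(names(v)))])
      } else {
        s <- s[order(s$reviewer, s$patient), ]
        s$score
      }
    }
    va <- pick(arms[1]); vb <- pick(arms[2])
    add_row(item, "subjective", va, vb, wilcoxon_signed_rank(va, vb))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("arm_comparison", "data.frame")

  r_wide <- stats::reshape(
    rat[order(rat$arm, rat$item, rat$patient, rat$reviewer), ],
    idvar = c("patient", "arm", "item"), timevar = "reviewer",
    direction = "wide")
  attr(out, "kappa") <- weighted_kappa(r_wide$score.1, r_wide$score.2,
                                       weights = kappa_weights)
  attr(out, "arms") <- arms
  out
}

#' Write a report bundle
#'
#' Renders a comparison table (and optional TTF/NPS curves) to disk:
#' `table2.csv` with the per-row summaries, `stats.json` with the same
#' content plus the agreement coefficient, one CSV per curve under
#' `curves/`, a per-item score-distribution export (`score_distribution.csv`)
#' when ratings are supplied, and optional PNG figures under `figs/`.
#' Re-rendering identical inputs yields byte-identical CSV/JSON.
#'
#' @param results an `arm_comparison` from [compare_arms()].
#' @param curves named list of curve data.frames (`ttf_curve`,
#'   `nps_curve`, `esf_curve`, ...); may be empty.
#' @param dir output directory, created if missing.
#' @param ratings optional ratings data.frame for the score-distribution
#'   export.
#' @param plots logical; also draw PNG figures of the curves and score
#'   distributions.
#' @return Invisibly, the paths written.
#' @export
render_report <- function(results, curves = list(), dir, ratings = NULL,
                          plots = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  tab_path <- file.path(dir, "table2.csv")
  utils::write.csv(as.data.frame(results), tab_path, row.names = FALSE)
  paths <- c(paths, tab_path)

  kap <- attr(results, "kappa")
  js <- list(rows = as.data.frame(results),
             kappa = if (!is.null(kap))
               list(value = kap$statistic, method = kap$method) else NULL,
             arms = attr(results, "arms"))
  js_path <- file.path(dir, "stats.json")
  jsonlite::write_json(js, js_path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  paths <- c(paths, js_path)

  if (length(curves) > 0L) {
    cdir <- file.path(dir, "curves")
    if (!dir.exists(cdir)) dir.create(cdir)
    for (nm in names(curves)) {
      p <- file.path(cdir, paste0(nm, ".csv"))
      utils::write.csv(as.data.frame(curves[[nm]]), p, row.names = FALSE)
      paths <- c(paths, p)
    }
  }

  if (!is.null(ratings)) {
    dist <- as.data.frame(table(arm = ratings$arm, item = ratings$item,
                                score = ratings$score))
    names(dist)[names(dist) == "Freq"] <- "count"
    p <- file.path(dir, "score_distribution.csv")
    utils::write.csv(dist, p, row.names = FALSE)
    paths <- c(paths, p)
  }

  if (plots) {
    fdir <- file.path(dir, "figs")
    if (!dir.exists(fdir)) dir.create(fdir)
    for (nm in names(curves)) {
      cv <- curves[[nm]]
      p <- file.path(fdir, paste0(nm, ".png"))
      grDevices::png(p, width = 800, height = 600)
      graphics::plot(cv[[1]], cv[[2]], type = "l", xlab = names(cv)[1],
                     ylab = names(cv)[2], main = nm)
      grDevices::dev.off()
      paths <- c(paths, p)
    }
    if (!is.null(ratings)) {
      p <- file.path(fdir, "scores.png")
      grDevices::png(p, width = 900, height = 600)
      graphics::boxplot(score ~ interaction(arm, item), data = ratings,
                        las = 2, ylab = "score")
      grDevices::dev.off()
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
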