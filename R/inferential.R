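new_us_test <- function(test, statistic, p_value, n, posthoc = NULL,
                        extra = list()) {
  structure(c(list(test = test, statistic = statistic,
                   p_value = p_value, n = n, posthoc = posthoc), extra),
            class = "us_test")
}

#' @export
print.us_test <- function(x, ...) {
  cat(sprintf("<us_test> %s: statistic = %.4g, p = %.4g\n",
              x$test, x$statistic, x$p_value))
  if (!is.null(x$posthoc)) {
    cat("post-hoc:\n")
    print(x$posthoc)
  }
  invisible(x)
}

#' @export
tidy.us_test <- function(x, ...) {
  if (is.null(x$posthoc)) {
    tibble(test = x$test, statistic = x$statistic, p_value = x$p_value)
  } else {
    mutate(x$posthoc, test = x$test, .before = 1)
  }
}

#' @export
glance.us_test <- function(x, ...) {
  tibble(test = x$test, statistic = x$statistic, p_value = x$p_value,
         n = list(x$n))
}

#' Fisher's exact test on a 2 x 2 table
#'
#' Two-sided exact p-value from the hypergeometric distribution (tables whose
#' probability does not exceed the observed table's). Used for comparing
#' responder proportions between two groups. When a margin is zero the p-value
#' is 1 by convention, with a warning.
#'
#' @param a,b,c,d non-negative integer cells, row-wise: `matrix(c(a, b, c, d),
#'   2, byrow = TRUE)`.
#' @return a `us_test` (statistic is the odds ratio estimate).
#' @export
fisher_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    abort("cells must be non-negative integers")
  }
  tab <- matrix(cells, 2, 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warn("a margin of the table is zero; p = 1 by convention")
    return(new_us_test("fisher_exact", NA_real_, 1, sum(cells)))
  }
  ft <- fisher.test(tab)
  new_us_test("fisher_exact", unname(ft$estimate), ft$p.value, sum(cells))
}

#' Friedman test with Nemenyi post-hoc
#'
#' Friedman chi-square on within-subject ranks, followed (only when the omnibus
#' p-value is below `alpha`) by the Nemenyi test: the critical difference is
#' \eqn{CD = q_{\alpha} \sqrt{k(k+1)/(6n)}} with \eqn{q_\alpha} the
#' studentized-range quantile at infinite degrees of freedom divided by
#' \eqn{\sqrt{2}}; pairs of conditions whose mean-rank difference exceeds CD
#' differ significantly.
#'
#' @param mat subjects x conditions matrix (no missing cells).
#' @param alpha significance level.
#' @return a `us_test` with `posthoc` tibble (`cond_i`, `cond_j`, `rank_diff`,
#'   `critical_difference`, `significant`) when the omnibus test is
#'   significant; mean ranks are always returned in `mean_ranks`.
#' @export
friedman_nemenyi <- function(mat, alpha = 0.05) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) abort("missing cells are not allowed")
  n <- nrow(mat); k <- ncol(mat)
  if (n < 2L || k < 2L) abort("need at least 2 subjects and 2 conditions")
  ranks <- t(apply(mat, 1, rank))
  mean_ranks <- colMeans(ranks)
  ft <- suppressWarnings(friedman.test(mat))
  stat <- unname(ft$statistic)
  p <- ft$p.value
  if (is.nan(stat)) { stat <- 0; p <- 1 } # all columns identical
  cd <- qtukey(1 - alpha, k, Inf) / sqrt(2) * sqrt(k * (k + 1) / (6 * n))
  posthoc <- NULL
  if (p < alpha) {
    pairs <- which(upper.tri(diag(k)), arr.ind = TRUE)
    cn <- colnames(mat) %||% as.character(seq_len(k))
    posthoc <- tibble(
      cond_i = cn[pairs[, 1]], cond_j = cn[pairs[, 2]],
      rank_diff = abs(mean_ranks[pairs[, 1]] - mean_ranks[pairs[, 2]]),
      critical_difference = cd
    ) %>% mutate(significant = .data$rank_diff > cd)
  }
  new_us_test("friedman", stat, p, n, posthoc,
              extra = list(k = k, critical_difference = cd,
                           mean_ranks = mean_ranks, alpha = alpha))
}

#' Wilcoxon rank-sum test (two unmatched groups)
#'
#' Normal approximation with tie correction and continuity correction. All-tied
#' data gives p = 1 with a warning.
#'
#' @param x,y numeric samples.
#' @return a `us_test`.
#' @export
rank_sum_test <- function(x, y) {
  if (length(unique(c(x, y))) == 1L) {
    warn("all observations tied; p = 1")
    return(new_us_test("wilcoxon_rank_sum", NA_real_, 1,
                       c(length(x), length(y))))
  }
  wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
  new_us_test("wilcoxon_rank_sum", unname(wt$statistic), wt$p.value,
              c(length(x), length(y)))
}

#' Wilcoxon signed-rank test (matched pairs)
#'
#' @param x,y paired numeric samples of equal length.
#' @return a `us_test`; identical samples give p = 1 with a warning.
#' @export
signed_rank_test <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (all(x == y)) {
    warn("all paired differences are zero; p = 1")
    return(new_us_test("wilcoxon_signed_rank", NA_real_, 1, length(x)))
  }
  wt <- suppressWarnings(wilcox.test(x, y, paired = TRUE, exact = FALSE,
                                     correct = TRUE))
  new_us_test("wilcoxon_signed_rank", unname(wt$statistic), wt$p.value,
              length(x))
}

#' Kruskal–Wallis test with Dunn–Sidak post-hoc
#'
#' Kruskal–Wallis omnibus test across three or more groups; when significant at
#' `alpha`, Dunn's pairwise rank tests (normal approximation with tie
#' correction) with Sidak-adjusted p-values are reported.
#'
#' @param values numeric vector.
#' @param groups group labels (same length).
#' @param alpha significance level gating the post-hoc table.
#' @return a `us_test` with `posthoc` tibble (`group_i`, `group_j`, `z`,
#'   `p_raw`, `p_sidak`, `significant`) when the omnibus test is significant.
#' @export
kruskal_dunn_sidak <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  if (length(unique(values)) == 1L) {
    warn("all observations tied; p = 1")
    return(new_us_test("kruskal_wallis", NA_real_, 1, table(groups)))
  }
  kw <- kruskal.test(values, groups)
  posthoc <- NULL
  if (kw$p.value < alpha) {
    r <- rank(values)
    big_n <- length(values)
    ties <- table(values)
    tie_corr <- 1 - sum(ties^3 - ties) / (big_n^3 - big_n)
    lev <- levels(groups)
    mean_r <- tapply(r, groups, mean)
    n_g <- tapply(r, groups, length)
    pairs <- utils::combn(seq_along(lev), 2)
    m <- ncol(pairs)
    posthoc <- purrr::map_dfr(seq_len(m), function(pidx) {
      i <- pairs[1, pidx]; j <- pairs[2, pidx]
      se <- sqrt(big_n * (big_n + 1) / 12 * tie_corr * (1 / n_g[i] + 1 / n_g[j]))
      z <- (mean_r[i] - mean_r[j]) / se
      p_raw <- 2 * pnorm(-abs(z))
      tibble(group_i = lev[i], group_j = lev[j], z = unname(z),
             p_raw = unname(p_raw),
             p_sidak = unname(1 - (1 - p_raw)^m))
    }) %>% mutate(significant = .data$p_sidak < alpha)
  }
  new_us_test("kruskal_wallis", unname(kw$statistic), kw$p.value,
              as.integer(table(groups)), posthoc,
              extra = list(df = unname(kw$parameter), alpha = alpha))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
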