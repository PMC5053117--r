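#' Two-stage adaptive linear rank test
#'
#' The adaptive test first computes label-blind selector statistics for
#' skewness and tail weight on the pooled sample, picks the k-sample linear
#' rank test expected to be most powerful for that distributional shape,
#' and then applies it to the genotype groups. Because the selection stage
#' ignores the group labels, the two-stage procedure keeps its nominal
#' level under the null hypothesis.
#'
#' @name adaptive-rank-test
NULL

#' Selector statistics for skewness and tail weight
#'
#' Hogg-type selectors computed from means of blocks of order statistics.
#' With `Lbar(p)`, `Ubar(p)` the means of the `ceiling(p*N)` smallest and
#' largest order statistics and `Mbar(0.5)` the mean of the central half of
#' the sorted sample (the central block is widened by one when needed so it
#' is always symmetric around the centre),
#' \deqn{Q1 = (Ubar(.05) - Mbar(.5)) / (Mbar(.5) - Lbar(.05))}
#' \deqn{Q2 = (Ubar(.05) - Lbar(.05)) / (Ubar(.5) - Lbar(.5))}
#' `Q1` measures skewness (1 for an exactly symmetric sample, > 1 right
#' skew, < 1 left skew; mirroring the sample maps Q1 to 1/Q1) and `Q2`
#' measures tail weight (invariant to location and positive scaling;
#' about 1.9 for a uniform sample, larger for heavy tails).
#'
#' @param values numeric vector, pooled over groups; needs `n >= 8` and at
#'   least two distinct values.
#' @return object of class `selector_stats`: list with `q1_skewness`,
#'   `q2_tailweight`, `n`, and `degenerate` (TRUE when a selector
#'   denominator vanished, e.g. near-constant data).
#' @examples
#' selector_statistics(1:20)$q2_tailweight # 1.9
#' @export
selector_statistics <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 8L)
    stop("selector statistics need at least 8 observations", call. = FALSE)
  x <- sort(values)
  k05 <- ceiling(0.05 * n)
  k50 <- ceiling(0.50 * n)
  lbar05 <- mean(x[seq_len(k05)])
  ubar05 <- mean(x[seq.int(n - k05 + 1L, n)])
  lbar50 <- mean(x[seq_len(k50)])
  ubar50 <- mean(x[seq.int(n - k50 + 1L, n)])
  # symmetric central block: k50 order statistics, widened by one if n - k50
  # is odd so the block sits symmetrically around the centre
  lo <- (n - k50) %/% 2L + 1L
  hi <- n - (n - k50) %/% 2L
  mbar <- mean(x[lo:hi])
  d1 <- mbar - lbar05
  n1 <- ubar05 - mbar
  d2 <- ubar50 - lbar50
  degenerate <- d1 <= 0 || d2 <= 0
  out <- list(
    q1_skewness = if (degenerate) NA_real_ else n1 / d1,
    q2_tailweight = if (degenerate) NA_real_ else (ubar05 - lbar05) / d2,
    n = n,
    degenerate = degenerate
  )
  class(out) <- "selector_stats"
  out
}

#' Default selector decision table
#'
#' Ordered rules mapping the selector statistics to one of the six rank
#' tests. Each rule is a list with elements `test` and bounds
#' `q1_min`, `q1_max`, `q2_min`, `q2_max` (missing bound = unbounded); the
#' first matching rule wins and the final rule is a catch-all. The default
#' precedence is: short tails for light-tailed samples (Q2 <= 2), median
#' for very heavy tails (Q2 >= 7), long-tails for moderately heavy tails
#' (4.5 <= Q2 < 7), right/left skewness for Q1 >= 2 / Q1 <= 0.5, and
#' Kruskal-Wallis otherwise. The cutoffs are a configurable design choice
#' in the Hogg tradition, not a universal constant.
#'
#' @return list of rules consumable by [select_test()].
#' @export
default_selector_rules <- function() {
  list(
    list(test = "short_tails", q2_max = 2),
    list(test = "median", q2_min = 7),
    list(test = "long_tails", q2_min = 4.5, q2_max = 7),
    list(test = "right_skew", q1_min = 2),
    list(test = "left_skew", q1_max = 0.5),
    list(test = "kruskal_wallis")
  )
}

.RANK_TESTS <- c("kruskal_wallis", "median", "long_tails", "short_tails",
                 "right_skew", "left_skew")

#' Choose the rank test from selector statistics
#'
#' Applies the decision table in order; `q*_min` bounds are inclusive and
#' `q*_max` bounds are exclusive except when the rule has only a `q2_max`
#' (the light-tail rule), which is inclusive, so that every (Q1, Q2) pair
#' maps to exactly one test. Degenerate selectors fall back to
#' `kruskal_wallis`.
#'
#' @param s a `selector_stats` object.
#' @param rules decision table, see [default_selector_rules()].
#' @return one of `"kruskal_wallis"`, `"median"`, `"long_tails"`,
#'   `"short_tails"`, `"right_skew"`, `"left_skew"`.
#' @export
select_test <- function(s, rules = default_selector_rules()) {
  stopifnot(inherits(s, "selector_stats"))
  if (isTRUE(s$degenerate)) return("kruskal_wallis")
  q1 <- s$q1_skewness
  q2 <- s$q2_tailweight
  for (r in rules) {
    ok <- TRUE
    if (!is.null(r$q2_max) && is.null(r$q2_min)) ok <- ok && q2 <= r$q2_max
    if (!is.null(r$q2_min)) ok <- ok && q2 >= r$q2_min
    if (!is.null(r$q2_min) && !is.null(r$q2_max)) ok <- ok && q2 < r$q2_max
    if (!is.null(r$q1_min)) ok <- ok && q1 >= r$q1_min
    if (!is.null(r$q1_max)) ok <- ok && q1 <= r$q1_max
    if (ok) {
      if (!r$test %in% .RANK_TESTS)
        stop("unknown test in rules: ", r$test, call. = FALSE)
      return(r$test)
    }
  }
  "kruskal_wallis"
}

#' Rank score functions
#'
#' Returns the score `a(R)` for ranks `R = 1..n` of the six score families:
#' \describe{
#'   \item{kruskal_wallis}{Wilcoxon scores `a(R) = R`.}
#'   \item{median}{indicator of the upper half, `1{R > (n+1)/2}`, with 1/2
#'     at the central rank for odd n.}
#'   \item{long_tails}{winsorised Wilcoxon, `clamp(R - (n+1)/2, +-n/4)`.}
#'   \item{short_tails}{`R - (n+1)/2` on the outer quartiles
#'     (`|R - (n+1)/2| > n/4`), 0 on the middle half.}
#'   \item{right_skew}{`min(R, ceiling((n+1)/2))` — emphasises the lower
#'     ranks, powerful for right-skewed data.}
#'   \item{left_skew}{`max(R, floor((n+1)/2))`.}
#' }
#'
#' @param n sample size (>= 2).
#' @param score_type one of the six family names.
#' @return numeric vector of n scores, indexed by rank.
#' @export
score_values <- function(n, score_type) {
  stopifnot(n >= 2)
  r <- seq_len(n)
  c0 <- (n + 1) / 2
  switch(score_type,
    kruskal_wallis = as.numeric(r),
    median = ifelse(r > c0, 1, ifelse(r == c0, 0.5, 0)),
    long_tails = pmin(pmax(r - c0, -n / 4), n / 4),
    short_tails = ifelse(abs(r - c0) > n / 4, r - c0, 0),
    right_skew = pmin(r, ceiling(c0)),
    left_skew = pmax(r, floor(c0)),
    stop("unknown score_type: ", score_type, call. = FALSE)
  )
}

# Scores of observations: mid-rank ties handled by averaging the scores of
# the tied rank positions, which carries the tie correction into the
# realised-score variance automatically.
.observation_scores <- function(values, score_type) {
  n <- length(values)
  a <- score_values(n, score_type)
  o <- order(values)
  srt <- values[o]
  sc <- numeric(n)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && srt[j + 1L] == srt[i]) j <- j + 1L
    sc[i:j] <- mean(a[i:j])
    i <- j + 1L
  }
  out <- numeric(n)
  out[o] <- sc
  out
}

#' k-sample linear rank statistic
#'
#' With scores `a_i` assigned to the pooled ranks (mid-rank ties averaged),
#' group score sums `A_g`, score mean `abar` and realised score variance
#' `s2 = sum((a_i - abar)^2) / (N - 1)`, the statistic is
#' \deqn{T = (1/s2) \sum_g (A_g - n_g \bar a)^2 / n_g}
#' which is asymptotically chi-squared with g - 1 degrees of freedom under
#' the null of identical group distributions. With Wilcoxon scores and no
#' ties T is exactly the classical Kruskal-Wallis H.
#'
#' @param values numeric observations.
#' @param groups group labels (coerced to factor; empty levels dropped).
#' @param score_type score family, see [score_values()].
#' @param p_mode `"asymptotic"` for the chi-squared p-value, `"exact"` for a
#'   permutation p-value (full enumeration of group assignments when
#'   `choose(N, n_1, ...)` is small, otherwise Monte-Carlo).
#' @param n_perm Monte-Carlo permutations when enumeration is infeasible.
#' @return list with `statistic`, `df`, `p_value`, `group_sizes`.
#' @examples
#' linear_rank_statistic(1:9, rep(1:3, each = 3), "kruskal_wallis")$statistic # 7.2
#' @export
linear_rank_statistic <- function(values, groups,
                                  score_type = "kruskal_wallis",
                                  p_mode = c("asymptotic", "exact"),
                                  n_perm = 1e5) {
  p_mode <- match.arg(p_mode)
  g <- factor(groups)
  g <- droplevels(g)
  keep <- !is.na(values) & !is.na(g)
  values <- values[keep]
  g <- droplevels(g[keep])
  N <- length(values)
  k <- nlevels(g)
  if (k < 2L) stop("need at least 2 groups", call. = FALSE)
  if (N < 3L) stop("need at least 3 observations", call. = FALSE)
  a <- .observation_scores(values, score_type)
  stat <- .rank_stat_from_scores(a, g)
  df <- k - 1L
  if (p_mode == "asymptotic") {
    p <- if (is.na(stat)) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
    if (is.na(stat)) stat <- 0
  } else {
    p <- .perm_pvalue(a, g, stat, n_perm)
    if (is.na(stat)) { stat <- 0; p <- 1 }
  }
  list(statistic = stat, df = df, p_value = p,
       group_sizes = as.integer(table(g)))
}

# T given realised observation scores and a factor; NA when the scores are
# all equal (treated as T = 0, p = 1 by callers).
.rank_stat_from_scores <- function(a, g) {
  N <- length(a)
  abar <- mean(a)
  s2 <- sum((a - abar)^2) / (N - 1)
  if (s2 <= 0) return(NA_real_)
  Ag <- vapply(split(a, g), sum, numeric(1))
  ng <- vapply(split(a, g), length, numeric(1))
  sum((Ag - ng * abar)^2 / ng) / s2
}

.perm_pvalue <- function(a, g, stat, n_perm) {
  if (is.na(stat)) return(1)
  N <- length(a)
  n_arrangements <- exp(lgamma(N + 1) - sum(lgamma(table(g) + 1)))
  if (n_arrangements <= 2e5) {
    perms <- .all_group_assignments(as.integer(table(g)))
    stats <- apply(perms, 2L, function(lab)
      .rank_stat_from_scores(a, factor(lab)))
    mean(stats >= stat - 1e-12)
  } else {
    hits <- 0L
    for (b in seq_len(n_perm)) {
      s <- .rank_stat_from_scores(a, g[sample.int(N)])
      if (!is.na(s) && s >= stat - 1e-12) hits <- hits + 1L
    }
    (hits + 1) / (n_perm + 1)
  }
}

# All distinct assignments of N = sum(ng) positions to groups, as an
# integer matrix with one column per arrangement. Recursive multiset
# permutation; only used for small N.
.all_group_assignments <- function(ng) {
  N <- sum(ng)
  rec <- function(remaining) {
    if (sum(remaining) == 0L)
      return(matrix(integer(0), nrow = 0, ncol = 1))
    cols <- list()
    for (gi in seq_along(remaining)) {
      if (remaining[gi] == 0L) next
      rem <- remaining
      rem[gi] <- rem[gi] - 1L
      sub <- rec(rem)
      cols[[length(cols) + 1L]] <- rbind(rep.int(gi, ncol(sub)), sub)
    }
    do.call(cbind, cols)
  }
  rec(ng)
}

#' Adaptive linear rank test
#'
#' Runs the two-stage procedure: selector statistics on the pooled values
#' (label-blind), test selection via the decision table, then the chosen
#' k-sample linear rank test. A degenerate selector (near-constant data)
#' falls back to the Kruskal-Wallis branch and is flagged.
#'
#' @inheritParams linear_rank_statistic
#' @param rules selector decision table, see [default_selector_rules()].
#' @return object of class `adaptive_rank_test`: list with `chosen_test`,
#'   `statistic`, `df`, `p_value`, `selector`, `n_groups`, `group_sizes`,
#'   `fallback` (TRUE when the selector was degenerate).
#' @examples
#' set.seed(1)
#' x <- exp(rnorm(60))
#' g <- rep(0:2, each = 20)
#' adaptive_rank_test(x, g)
#' @export
adaptive_rank_test <- function(values, groups,
                               rules = default_selector_rules(),
                               p_mode = c("asymptotic", "exact"),
                               n_perm = 1e5) {
  p_mode <- match.arg(p_mode)
  g <- droplevels(factor(groups))
  keep <- !is.na(values) & !is.na(g)
  values <- values[keep]
  g <- droplevels(g[keep])
  if (nlevels(g) < 2L) stop("need at least 2 groups", call. = FALSE)
  fallback <- FALSE
  if (length(values) >= 8L && length(unique(values)) > 1L) {
    sel <- selector_statistics(values)
    if (isTRUE(sel$degenerate)) fallback <- TRUE
  } else {
    sel <- structure(list(q1_skewness = NA_real_, q2_tailweight = NA_real_,
                          n = length(values), degenerate = TRUE),
                     class = "selector_stats")
    fallback <- TRUE
  }
  chosen <- select_test(sel, rules)
  res <- linear_rank_statistic(values, g, chosen, p_mode, n_perm)
  out <- list(chosen_test = chosen, statistic = res$statistic, df = res$df,
              p_value = res$p_value, selector = sel,
              n_groups = nlevels(g), group_sizes = res$group_sizes,
              fallback = fallback)
  class(out) <- "adaptive_rank_test"
  out
}

#' @export
print.adaptive_rank_test <- function(x, ...) {
  cat("\n\tAdaptive linear rank test\n\n")
  cat(sprintf("chosen test: %s%s\n", x$chosen_test,
              if (x$fallback) " (selector degenerate, fallback)" else ""))
  if (!x$fallback)
    cat(sprintf("selector: Q1 (skewness) = %.3f, Q2 (tail weight) = %.3f\n",
                x$selector$q1_skewness, x$selector$q2_tailweight))
  cat(sprintf("T = %.4f, df = %d, p-value = %.4g\n",
              x$statistic, x$df, x$p_value))
  cat(sprintf("groups: %s\n\n", paste(x$group_sizes, collapse = "/")))
  invisible(x)
}

#' @export
print.selector_stats <- function(x, ...) {
  cat(sprintf("selector statistics (n = %d): Q1 = %.4f, Q2 = %.4f%s\n",
              x$n, x$q1_skewness, x$q2_tailweight,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Companion one-way ANOVA F test
#'
#' Classical one-way fixed-effects ANOVA p-value, reported alongside the
#' rank tests for comparison. Delegates to [stats::oneway.test()] with
#' equal variances; degenerate cases (zero within-group variance) are
#' resolved directly.
#'
#' @param values numeric observations.
#' @param groups group labels.
#' @return p-value.
#' @export
anova_f_test <- function(values, groups) {
  g <- droplevels(factor(groups))
  keep <- !is.na(values) & !is.na(g)
  values <- values[keep]
  g <- droplevels(g[keep])
  if (nlevels(g) < 2L) stop("need at least 2 groups", call. = FALSE)
  gm <- tapply(values, g, mean)
  ssw <- sum((values - gm[g])^2)
  ssb <- sum(tabulate(g) * (gm - mean(values))^2)
  if (ssw <= 0) return(if (ssb > 0) 0 else 1)
  stats::oneway.test(values ~ g, var.equal = TRUE)$p.value
}
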