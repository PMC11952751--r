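#' Lilliefors normality test with Monte-Carlo p value
#'
#' Kolmogorov-Smirnov statistic of the sample against a normal distribution
#' with estimated mean and SD. Because the parameters are estimated, the
#' statistic's null distribution is not the classical KS one; the p value is
#' obtained from a seeded Monte-Carlo null (the statistic is location/scale
#' free, so standard-normal samples of the same n suffice), exact at any n
#' up to simulation error and reproducible by seed.
#'
#' @param x Numeric sample (n >= 4).
#' @param nreps Monte-Carlo replicates (default 10000).
#' @param seed Integer seed for the null simulation.
#' @param null Optional pre-computed null statistic vector from
#'   [lilliefors_null()], reused across repeated calls at the same n.
#' @return One-row tibble: `statistic`, `p`, `n`, `degenerate` (TRUE for a
#'   constant sample, whose p is reported at the machine floor).
#' @export
lilliefors_test <- function(x, nreps = 10000, seed = 1L, null = NULL) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 4) stop("lilliefors_test needs n >= 4")
  if (stats::sd(x) == 0)
    return(tibble::tibble(statistic = 1, p = .Machine$double.xmin, n = n,
                          degenerate = TRUE))
  d <- lilliefors_statistic(x)
  if (is.null(null)) null <- lilliefors_null(n, nreps, seed)
  p <- (1 + sum(null >= d)) / (length(null) + 1)
  tibble::tibble(statistic = d, p = p, n = n, degenerate = FALSE)
}

lilliefors_statistic <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / stats::sd(x))
  f <- stats::pnorm(z)
  max(pmax(seq_len(n) / n - f, f - (seq_len(n) - 1) / n))
}

#' @rdname lilliefors_test
#' @param n Sample size of the null draws.
#' @return `lilliefors_null()`: numeric vector of `nreps` null statistics.
#' @export
lilliefors_null <- function(n, nreps = 10000, seed = 1L) {
  set.seed(seed)
  vapply(seq_len(nreps),
         function(i) lilliefors_statistic(stats::rnorm(n)), numeric(1))
}

#' Kruskal-Wallis omnibus test
#'
#' Rank-based H statistic with tie correction and chi-squared p value on
#' k - 1 degrees of freedom (delegates to [stats::kruskal.test()]).
#'
#' @param groups List of numeric samples (>= 2 groups, each non-empty,
#'   total n >= 3).
#' @return One-row tibble: `H`, `df`, `p`, `n`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) stop("kruskal_wallis needs >= 2 groups")
  groups <- lapply(groups, function(g) as.numeric(g[!is.na(g)]))
  sizes <- lengths(groups)
  if (any(sizes == 0)) stop("kruskal_wallis: a group is empty")
  if (sum(sizes) < 3) stop("kruskal_wallis needs total n >= 3")
  kt <- stats::kruskal.test(groups)
  tibble::tibble(H = unname(kt$statistic), df = unname(kt$parameter),
                 p = kt$p.value, n = sum(sizes))
}

#' Dunn post-hoc pairwise comparisons
#'
#' Pairwise z statistics from the pooled ranks with tie correction,
#' \deqn{z_{ij} = \frac{\bar R_i - \bar R_j}
#'   {\sqrt{\left(\frac{N(N+1)}{12} - \frac{\sum_t (t^3 - t)}{12 (N-1)}\right)
#'    \left(\frac{1}{n_i} + \frac{1}{n_j}\right)}}}
#' with two-sided p values adjusted over all pairs (Bonferroni by default;
#' `"holm"` and `"none"` available).
#'
#' @param groups Named list of numeric samples (names become group labels).
#' @param adjust Multiplicity adjustment: `"bonferroni"`, `"holm"` or
#'   `"none"`.
#' @return Tibble, one row per unordered pair: `group1`, `group2`, `z`, `p`
#'   (unadjusted), `p_adj`.
#' @export
dunn_posthoc <- function(groups, adjust = c("bonferroni", "holm", "none")) {
  adjust <- match.arg(adjust)
  if (length(groups) < 2) stop("dunn_posthoc needs >= 2 groups")
  groups <- lapply(groups, function(g) as.numeric(g[!is.na(g)]))
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), lengths(groups))
  N <- length(x)
  rk <- rank(x)
  rbar <- tapply(rk, g, mean)
  ns <- tapply(rk, g, length)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_term
  pairs <- utils::combn(names(groups), 2)
  out <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    se <- sqrt(s2 * (1 / ns[[i]] + 1 / ns[[j]]))
    z <- (rbar[[i]] - rbar[[j]]) / se
    tibble::tibble(group1 = i, group2 = j, z = z,
                   p = 2 * stats::pnorm(-abs(z)))
  })
  out$p_adj <- stats::p.adjust(out$p, method =
                                 if (adjust == "none") "none"
                                 else adjust)
  out
}

#' Two-sample pairwise test with normality-gated selection
#'
#' `policy = "auto"` runs Welch's two-sample t-test when both samples pass
#' the Lilliefors normality test at alpha = 0.05 and the Mann-Whitney test
#' otherwise (two-sided; exact when combined n <= 20 and tie-free, normal
#' approximation with tie/continuity correction otherwise). Policies `"t"`
#' and `"mann-whitney"` force the respective test.
#'
#' @param a,b Numeric samples (each n >= 2).
#' @param policy `"auto"`, `"t"` or `"mann-whitney"`.
#' @param nreps,seed Monte-Carlo settings for the normality gate.
#' @return One-row tibble: `statistic`, `p`, `test`.
#' @export
pairwise_test <- function(a, b, policy = c("auto", "t", "mann-whitney"),
                          nreps = 2000, seed = 1L) {
  policy <- match.arg(policy)
  a <- as.numeric(a[!is.na(a)]); b <- as.numeric(b[!is.na(b)])
  if (length(a) < 2 || length(b) < 2)
    stop("pairwise_test needs n >= 2 in both samples")
  use_t <- switch(policy, t = TRUE, `mann-whitney` = FALSE, auto = {
    null_a <- lilliefors_null(length(a), nreps, seed)
    null_b <- if (length(b) == length(a)) null_a
              else lilliefors_null(length(b), nreps, seed)
    lilliefors_test(a, null = null_a)$p > 0.05 &&
      lilliefors_test(b, null = null_b)$p > 0.05
  })
  if (use_t) {
    tt <- stats::t.test(a, b)
    return(tibble::tibble(statistic = unname(tt$statistic), p = tt$p.value,
                          test = "t"))
  }
  exact <- length(a) + length(b) <= 20 && !any(duplicated(c(a, b)))
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = !exact))
  tibble::tibble(statistic = unname(wt$statistic), p = wt$p.value,
                 test = "mann-whitney")
}

#' Group summary and omnibus/post-hoc comparison per feature
#'
#' Produces the cohort-table layout (n, mean, SD, median per group per
#' feature) plus, for every feature, the Kruskal-Wallis omnibus test and the
#' Dunn post-hoc pairwise table. Groups in which a feature is entirely
#' missing are reported with n = 0 and excluded from the tests. Differences
#' are flagged significant at `alpha` (default 0.05).
#'
#' @param features Feature tibble (one row per cell), e.g. from
#'   [extract_features()].
#' @param group Name of the grouping column (default `"age_group"`).
#' @param feature_cols Feature columns to analyse (default: the
#'   [ephys_feature_names()] present in the table).
#' @param adjust Post-hoc adjustment, see [dunn_posthoc()].
#' @param alpha Significance threshold.
#' @return An object of class `group_comparison`: list with tibbles
#'   `summary` (feature, group, n, mean, sd, median), `omnibus` (feature, H,
#'   df, p, significant) and `posthoc` (feature, group1, group2, z, p,
#'   p_adj, significant).
#' @export
group_summary <- function(features, group = "age_group",
                          feature_cols = NULL,
                          adjust = "bonferroni", alpha = 0.05) {
  stopifnot(is.data.frame(features), group %in% names(features))
  if (is.null(feature_cols))
    feature_cols <- intersect(ephys_feature_names(), names(features))
  if (!length(feature_cols)) stop("no feature columns to analyse")
  gvals <- features[[group]]
  glevels <- if (is.factor(gvals)) levels(gvals) else sort(unique(gvals))

  summaries <- list(); omni <- list(); post <- list()
  for (f in feature_cols) {
    x <- features[[f]]
    samples <- lapply(glevels, function(g)
      x[!is.na(x) & !is.na(gvals) & gvals == g])
    names(samples) <- glevels
    summaries[[f]] <- tibble::tibble(
      feature = f, group = glevels,
      n = unname(vapply(samples, length, integer(1))),
      mean = unname(vapply(samples, function(s)
        if (length(s)) mean(s) else NA_real_, numeric(1))),
      sd = unname(vapply(samples, function(s)
        if (length(s) > 1) stats::sd(s) else NA_real_, numeric(1))),
      median = unname(vapply(samples, function(s)
        if (length(s)) stats::median(s) else NA_real_, numeric(1))))
    nonempty <- samples[lengths(samples) > 0]
    if (length(nonempty) >= 2 && sum(lengths(nonempty)) >= 3) {
      kw <- kruskal_wallis(nonempty)
      omni[[f]] <- dplyr::mutate(kw, feature = f, .before = 1)
      dn <- dunn_posthoc(nonempty, adjust = adjust)
      post[[f]] <- dplyr::mutate(dn, feature = f, .before = 1)
    }
  }
  omnibus <- dplyr::bind_rows(omni)
  posthoc <- dplyr::bind_rows(post)
  if (nrow(omnibus)) omnibus$significant <- omnibus$p < alpha
  if (nrow(posthoc)) posthoc$significant <- posthoc$p_adj < alpha
  structure(list(summary = dplyr::bind_rows(summaries),
                 omnibus = omnibus, posthoc = posthoc,
                 group = group, alpha = alpha, adjust = adjust),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "<group_comparison> %d features x %d groups (alpha = %g, %s)\n",
    length(unique(x$summary$feature)), length(unique(x$summary$group)),
    x$alpha, x$adjust))
  if (nrow(x$omnibus)) {
    sig <- x$omnibus$feature[x$omnibus$significant]
    cat(sprintf("  omnibus significant: %d/%d\n",
                length(sig), nrow(x$omnibus)))
  }
  invisible(x)
}

#' Broom-style tidiers for group comparisons
#'
#' `tidy()` returns the omnibus table (or the post-hoc table with
#' `type = "posthoc"`, or the per-group summary with `type = "summary"`);
#' `glance()` returns a one-row overview.
#'
#' @param x A `group_comparison`.
#' @param type Which table to return.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.group_comparison <- function(x, type = c("omnibus", "posthoc",
                                              "summary"), ...) {
  type <- match.arg(type)
  switch(type, omnibus = x$omnibus, posthoc = x$posthoc,
         summary = x$summary)
}

#' @rdname tidy.group_comparison
#' @export
glance.group_comparison <- function(x, ...) {
  tibble::tibble(
    n_features = length(unique(x$summary$feature)),
    n_groups = length(unique(x$summary$group)),
    n_omnibus_significant = sum(x$omnibus$significant %||% logical()),
    alpha = x$alpha, adjust = x$adjust)
}

#' @importFrom rlang %||%
NULL

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance
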