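test_that("age groups follow the printed bounds and conventions", {
  expect_equal(as.character(assign_age_group(0.9)), "infant")
  expect_equal(as.character(assign_age_group(13)), "adolescence")
  expect_equal(as.character(assign_age_group(60)), "late_adulthood")
  # integer boundaries belong to the group whose range starts there
  expect_equal(as.character(assign_age_group(c(1, 7, 20, 40))),
               c("early_childhood", "late_childhood", "young_adulthood",
                 "middle_adulthood"))
  expect_equal(as.character(assign_age_group(85)), "late_adulthood")
  expect_error(assign_age_group(-0.1), "age")
  expect_equal(levels(assign_age_group(5)), age_group_levels())
})

test_that("Kruskal-Wallis matches the hand rank-formula value", {
  # untied data: H = 12/(N(N+1)) * sum n_i (Rbar_i - Rbar)^2 = 7.2
  kw <- kruskal_wallis(list(1:3, 4:6, 7:9))
  expect_equal(kw$H, 7.2, tolerance = 1e-12)
  expect_equal(kw$df, 2)
  expect_equal(kw$p, pchisq(7.2, 2, lower.tail = FALSE), tolerance = 1e-12)
  # identical multisets -> H = 0
  expect_equal(kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3)))$H, 0,
               tolerance = 1e-12)
  expect_error(kruskal_wallis(list(1:3)), ">= 2 groups")
  expect_error(kruskal_wallis(list(1:3, numeric())), "empty")
})

test_that("Kruskal-Wallis tie correction equals a from-scratch oracle", {
  set.seed(9)
  for (i in 1:10) {
    groups <- lapply(1:3, function(g) sample(1:6, 8, replace = TRUE))
    x <- unlist(groups)
    g <- rep(seq_along(groups), lengths(groups))
    rk <- rank(x)
    N <- length(x)
    rbar <- tapply(rk, g, mean)
    ns <- tapply(rk, g, length)
    h0 <- 12 / (N * (N + 1)) * sum(ns * (rbar - (N + 1) / 2)^2)
    ties <- table(x)
    h <- h0 / (1 - sum(ties^3 - ties) / (N^3 - N))
    expect_equal(kruskal_wallis(groups)$H, h, tolerance = 1e-10)
  }
})

test_that("Dunn post-hoc has the documented structure and properties", {
  groups <- list(a = c(1, 5, 9, 13), b = c(1, 5, 9, 13),
                 c = c(20, 25, 30, 35))
  d <- dunn_posthoc(groups)
  expect_equal(nrow(d), 3)   # C(3, 2) pairs
  ab <- d[d$group1 == "a" & d$group2 == "b", ]
  expect_equal(ab$z, 0, tolerance = 1e-12)
  expect_equal(ab$p, 1, tolerance = 1e-12)
  expect_true(all(d$p_adj >= d$p))
  expect_true(all(d$p_adj <= 1))
})

test_that("Dunn z equals a from-scratch pooled-rank oracle", {
  groups <- list(g1 = c(2.1, 3.4, 1.2, 5.5, 4.0),
                 g2 = c(6.1, 7.2, 5.9, 8.8),
                 g3 = c(1.1, 2.2, 2.2, 3.3, 2.2, 4.4))
  d <- dunn_posthoc(groups, adjust = "none")
  x <- unlist(groups)
  rk <- rank(x)
  N <- length(x)
  idx <- rep(1:3, lengths(groups))
  ties <- table(x)
  s2 <- N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1))
  for (k in seq_len(nrow(d))) {
    i <- match(d$group1[k], names(groups))
    j <- match(d$group2[k], names(groups))
    z <- (mean(rk[idx == i]) - mean(rk[idx == j])) /
      sqrt(s2 * (1 / sum(idx == i) + 1 / sum(idx == j)))
    expect_equal(d$z[k], z, tolerance = 1e-12)
    expect_equal(d$p_adj[k], d$p[k])  # "none" leaves p untouched
  }
})

test_that("Dunn and Mann-Whitney agree in direction on two groups", {
  set.seed(14)
  for (i in 1:10) {
    a <- rnorm(12)
    b <- rnorm(12, mean = runif(1, -2, 2))
    z <- dunn_posthoc(list(a = a, b = b))$z
    w <- unname(wilcox.test(a, b)$statistic)  # > n1 n2/2 when a tends larger
    expect_equal(sign(z), sign(w - length(a) * length(b) / 2))
  }
})

test_that("exact Mann-Whitney p values match enumeration", {
  # {1,2,3} vs {4,5,6}: U = 0; 2 of the 20 arrangements are as extreme
  res <- pairwise_test(c(1, 2, 3), c(4, 5, 6), policy = "mann-whitney")
  expect_equal(res$p, 0.1, tolerance = 1e-12)
  expect_equal(res$statistic, 0)
  # perfectly interleaved samples -> exact two-sided p = 1
  expect_equal(pairwise_test(c(1, 4, 5), c(2, 3, 6),
                             policy = "mann-whitney")$p, 1,
               tolerance = 1e-12)
  expect_error(pairwise_test(1, c(1, 2)), "n >= 2")
})

test_that("auto policy gates on normality and detects strong shifts", {
  set.seed(3)
  a <- rnorm(50)
  b <- rnorm(50, mean = 2)
  res_t <- pairwise_test(a, b, policy = "t")
  res_mw <- pairwise_test(a, b, policy = "mann-whitney")
  expect_lt(res_t$p, 1e-3)
  expect_lt(res_mw$p, 1e-3)
  auto <- pairwise_test(a, b, policy = "auto", seed = 5)
  expect_equal(auto$test, "t")   # both samples are Gaussian
  # a grossly non-normal sample flips the gate to Mann-Whitney
  c1 <- rexp(50)
  auto2 <- pairwise_test(c1, rexp(50) + 1, policy = "auto", seed = 5)
  expect_equal(auto2$test, "mann-whitney")
})

test_that("Lilliefors statistic agrees with the reference implementation", {
  skip_if_not_installed("nortest")
  set.seed(8)
  for (i in 1:5) {
    x <- rnorm(40, 3, 2)
    expect_equal(lilliefors_test(x, nreps = 200)$statistic,
                 unname(nortest::lillie.test(x)$statistic),
                 tolerance = 1e-10)
  }
})

test_that("Lilliefors p values are calibrated and seeded", {
  null100 <- lilliefors_null(100, nreps = 2000, seed = 2)
  set.seed(17)
  p_norm <- vapply(1:100, function(i)
    lilliefors_test(rnorm(100), null = null100)$p, numeric(1))
  expect_gte(mean(p_norm > 0.05), 0.90)
  set.seed(18)
  p_exp <- vapply(1:100, function(i)
    lilliefors_test(rexp(100), null = null100)$p, numeric(1))
  expect_gte(mean(p_exp < 0.05), 0.95)
  # an extreme outlier strictly increases the statistic
  x <- rnorm(30)
  expect_gt(lilliefors_test(c(x, 25), nreps = 100)$statistic,
            lilliefors_test(x, nreps = 100)$statistic)
  # determinism by seed
  expect_identical(lilliefors_test(x, nreps = 500, seed = 4),
                   lilliefors_test(x, nreps = 500, seed = 4))
  # constant sample is degenerate
  expect_true(lilliefors_test(rep(1, 10))$degenerate)
})

test_that("Kruskal-Wallis is invariant under monotone transforms", {
  set.seed(23)
  groups <- lapply(1:4, function(i) runif(10, 0, 5))
  h1 <- kruskal_wallis(groups)$H
  h2 <- kruskal_wallis(lapply(groups, function(g) exp(g)))$H
  h3 <- kruskal_wallis(lapply(groups, function(g) g^3 + 1))$H
  expect_equal(h1, h2, tolerance = 1e-12)
  expect_equal(h1, h3, tolerance = 1e-12)
})

test_that("group_summary reports empty groups and flags significance", {
  set.seed(2)
  tbl <- tibble::tibble(
    age_group = factor(rep(c("infant", "adolescence", "late_adulthood"),
                           each = 12), levels = age_group_levels()),
    input_resistance = c(rnorm(12, 250, 30), rnorm(12, 70, 15),
                         rnorm(12, 80, 15)),
    fi_slope = rnorm(36, 0.15, 0.03),
    tau = c(rnorm(24, 9, 2), rep(NA, 12)))
  gs <- group_summary(tbl, feature_cols = c("input_resistance", "fi_slope",
                                            "tau"))
  s <- tidy(gs, "summary")
  expect_equal(s$n[s$feature == "tau" & s$group == "late_adulthood"], 0)
  om <- tidy(gs)
  expect_true(om$significant[om$feature == "input_resistance"])
  expect_false(om$significant[om$feature == "fi_slope"])
  g <- glance(gs)
  expect_equal(g$n_features, 3)
  ph <- tidy(gs, "posthoc")
  expect_equal(sum(ph$feature == "input_resistance"), 3)
})

test_that("embedding standardizes, reproduces, and respects duplicates", {
  set.seed(6)
  n <- 30
  tbl <- tibble::tibble(
    cell_id = sprintf("c%02d", 1:n),
    group = rep(c("a", "b"), each = n / 2),
    resting_vm = c(rnorm(n / 2, -60, 1), rnorm(n / 2, -70, 1)),
    input_resistance = c(rnorm(n / 2, 250, 10), rnorm(n / 2, 70, 10)),
    tau = c(rnorm(n / 2, 20, 1), rnorm(n / 2, 9, 1)),
    sag_ratio = runif(n, 0.05, 0.12),
    rheobase = c(rnorm(n / 2, 80, 10), rnorm(n / 2, 250, 20)),
    ap_half_width = c(rnorm(n / 2, 0.5, 0.04), rnorm(n / 2, 0.22, 0.03)),
    ap_up_stroke = c(rnorm(n / 2, 28, 2), rnorm(n / 2, 70, 5)),
    ap_amplitude = rnorm(n, 29, 2))
  e1 <- embed_features(tbl, seed = 42)
  e2 <- embed_features(tbl, seed = 42)
  expect_equal(e1$embed_1, e2$embed_1, tolerance = 1e-12)
  # two programmed clusters separate cleanly
  skip_if_not_installed("cluster")
  sil <- cluster::silhouette(as.integer(factor(e1$group)),
                             dist(cbind(e1$embed_1, e1$embed_2)))
  expect_gt(mean(sil[, "sil_width"]), 0.3)
  # duplicated rows get identical coordinates
  tbl2 <- dplyr::bind_rows(tbl, tbl[3, ])
  e3 <- embed_features(tbl2, seed = 42)
  expect_equal(unname(unlist(e3[nrow(e3), c("embed_1", "embed_2")])),
               unname(unlist(e3[3, c("embed_1", "embed_2")])))
  # missing values drop the row with a log message
  tbl3 <- tbl
  tbl3$tau[5] <- NA
  expect_message(e4 <- embed_features(tbl3), "dropping 1")
  expect_equal(nrow(e4), n - 1)
})

test_that("series-resistance QC excludes high-Rs cells", {
  tbl <- tibble::tibble(cell_id = c("a", "b", "c", "d"),
                        series_resistance = c(12, 31, NA, 29))
  out <- qc_filter(tbl)
  expect_equal(out$cell_id, c("a", "c", "d"))
  expect_equal(attr(out, "n_excluded"), 1)
  out2 <- qc_filter(tbl, keep_missing = FALSE)
  expect_equal(out2$cell_id, c("a", "d"))
  recs <- lapply(1:2, function(i)
    make_rc_record(cell_id = sprintf("r%d", i),
                   series_resistance = c(20, 35)[i]))
  expect_length(qc_filter(recs), 1)
})
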