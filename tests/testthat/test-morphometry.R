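test_that("toy tree metrics match hand geometry", {
  m <- toy_morphology()
  a <- arbor_metrics(m)
  expect_equal(a$total_length_mm, 0.280, tolerance = 1e-12)
  expect_equal(a$apical_length_mm, 0.200, tolerance = 1e-12)
  expect_equal(a$basal_length_mm, 0.080, tolerance = 1e-12)
  expect_equal(a$n_nodes, 1)
  expect_equal(a$max_horizontal_um, 60)
  expect_equal(a$max_vertical_um, 220)
  expect_equal(a$apical_terminal_um, 50)
  expect_equal(a$basal_terminal_um, 80)
})

test_that("total dendritic length is apical plus basal exactly", {
  for (seed in 1:5) {
    a <- arbor_metrics(generate_morphology(seed))
    expect_equal(a$total_length_mm,
                 a$apical_length_mm + a$basal_length_mm,
                 tolerance = 1e-12)
  }
})

test_that("zero-length duplicate points do not change the metrics", {
  m <- toy_morphology()
  n <- m$nodes
  # duplicate the apical branch point in place: 2 -> 2b (same coords)
  dup <- n[n$id == 2, ]
  dup$id <- 6L
  dup$parent_id <- 2L
  n$parent_id[n$id %in% c(3, 4)] <- 6L
  m2 <- morphology(dplyr::bind_rows(n, dup)[c(1, 2, 6, 3, 4, 5), ])
  expect_equal(arbor_metrics(m2), arbor_metrics(toy_morphology()))
})

test_that("rigid rotation preserves lengths and node counts", {
  m <- generate_morphology(4)
  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  n <- m$nodes
  xyz <- as.matrix(n[, c("x", "y", "z")]) %*% t(rot)
  n$x <- xyz[, 1]; n$y <- xyz[, 2]; n$z <- xyz[, 3]
  m2 <- morphology(n, pia_direction = c(rot %*% c(0, 1, 0)))
  a1 <- arbor_metrics(m)
  a2 <- arbor_metrics(m2)
  for (col in c("total_length_mm", "apical_length_mm", "basal_length_mm",
                "n_nodes", "apical_terminal_um", "basal_terminal_um"))
    expect_equal(a2[[col]], a1[[col]], tolerance = 1e-9)
  # extents follow the annotated pia direction
  expect_equal(a2$max_vertical_um, a1$max_vertical_um, tolerance = 1e-9)
})

test_that("SWC round trip preserves the morphology", {
  m <- generate_morphology(12)
  path <- tempfile(fileext = ".swc")
  write_swc(m, path)
  m2 <- read_swc(path)
  expect_equal(m2$nodes$x, m$nodes$x, tolerance = 1e-7)
  expect_equal(m2$nodes$compartment, m$nodes$compartment)
  expect_equal(arbor_metrics(m2)[, 1:8], arbor_metrics(m)[, 1:8],
               tolerance = 1e-6)
  unlink(path)
})

test_that("SWC parse errors name the offending line", {
  path <- tempfile(fileext = ".swc")
  writeLines(c("# toy", "1 1 0 0 0 6 -1", "2 3 0 10 0 1 9"), path)
  expect_error(read_swc(path), "undefined parent")
  writeLines(c("1 1 0 0 0 6 -1", "2 3 0 10 0 1"), path)
  expect_error(read_swc(path), "line 2.*7 columns")
  writeLines(c("1 1 0 0 0 6 -1", "2 9 0 10 0 1 1"), path)
  expect_error(read_swc(path), "unknown SWC type code")
  writeLines(c("1 1 0 0 0 6 -1", "1 3 0 10 0 1 1"), path)
  expect_error(read_swc(path), "duplicate")
  # unknown codes can be remapped explicitly
  writeLines(c("1 1 0 0 0 6 -1", "2 9 0 10 0 1 1"), path)
  m <- read_swc(path, type_map = c(`9` = "basal"))
  expect_equal(m$nodes$compartment[2], "basal")
  unlink(path)
})

test_that("4-node toy SWC parses to one root and three dendritic nodes", {
  path <- tempfile(fileext = ".swc")
  writeLines(c("1 1 0 0 0 6 -1", "2 4 0 20 0 1 1", "3 4 0 40 0 1 2",
               "4 3 10 -20 0 1 1"), path)
  m <- read_swc(path)
  expect_equal(sum(m$nodes$parent_id == -1), 1)
  expect_equal(sum(m$nodes$compartment %in% c("apical", "basal")), 3)
  unlink(path)
})

test_that("generated trees match their manifests exactly", {
  for (seed in 1:10) {
    m <- generate_morphology(seed)
    man <- morphology_manifest(m)
    a <- arbor_metrics(m)
    for (col in setdiff(names(a), "soma_depth_um"))
      expect_equal(a[[col]], man$metrics[[col]], tolerance = 1e-9,
                   info = sprintf("seed %d, %s", seed, col))
    # per-branch spine counts recomputed from annotations equal the manifest
    sd <- spine_density(m)
    man_counts <- dplyr::summarise(
      dplyr::group_by(man$spines, .data$branch_id),
      n = sum(.data$n), .groups = "drop")
    got <- sd$per_branch[match(man_counts$branch_id,
                               sd$per_branch$branch_id), ]
    expect_equal(got$n_spines, man_counts$n)
  }
})

test_that("spine density follows the per-branch definition", {
  m <- toy_morphology()
  br <- branch_table(m)
  # 12 spines on the 80 um basal branch -> 0.15 /um; apical children empty
  basal_id <- br$branch_id[br$compartment == "basal"]
  spines <- tibble::tibble(
    branch_id = rep(basal_id, 12),
    arc_position_um = seq(5, 75, length.out = 12),
    protrusion_length_um = 1.5, head_diameter_um = 0.8,
    neck_diameter_um = 0.2, head_count = 1L)
  sd <- spine_density(m, spines)
  expect_equal(sd$per_branch$density[sd$per_branch$branch_id == basal_id],
               12 / 80)
  expect_equal(sd$per_branch$density[sd$per_branch$compartment == "apical"],
               rep(0, 3))
  expect_error(spine_density(m, dplyr::mutate(spines, branch_id = 999)),
               "unknown branch ids")
})

test_that("spine densities on generated trees recover the programmed rate", {
  dens <- vapply(1:20, function(seed) {
    m <- generate_morphology(seed, morphology_spec(
      spine_density = c(mushroom = 0.2)))
    sd <- spine_density(m, weighted = TRUE)
    total <- sum(sd$per_branch$n_spines) / sum(sd$per_branch$length_um)
    total
  }, numeric(1))
  expect_equal(mean(dens), 0.2, tolerance = 0.05)
})

test_that("classification rules fire in the documented order", {
  base <- tibble::tibble(arc_position_um = 1, branch_id = 1L)
  row <- function(len, head, neck, heads = 1L)
    dplyr::mutate(base, protrusion_length_um = len,
                  head_diameter_um = head, neck_diameter_um = neck,
                  head_count = heads)
  expect_equal(classify_spine(row(2, 0.8, 0.2, heads = 2L)), "branched")
  expect_equal(classify_spine(row(4, 0.15, 0.15)), "filopodium")
  expect_equal(classify_spine(row(0.5, 0.4, 0.4)), "stubby")
  expect_equal(classify_spine(row(2, 0.9, 0.2)), "mushroom")
  expect_equal(classify_spine(row(2, 0.35, 0.15)), "thin")
  # missing geometry -> unclassified
  expect_true(is.na(classify_spine(row(NA, NA, 0.2))))
})

test_that("generated spine geometry is recovered by the classifier", {
  m <- generate_morphology(33, morphology_spec(
    spine_density = c(mushroom = 0.3, thin = 0.3, filopodium = 0.15,
                      branched = 0.1, stubby = 0.2)))
  sp <- m$spines
  got <- classify_spine(sp)
  expect_gte(mean(got == sp$type), 0.95)
})

test_that("spine type fractions sum to 100 per branch", {
  m <- generate_morphology(14)
  fr <- spine_type_fractions(m)
  tot <- dplyr::summarise(dplyr::group_by(fr, .data$branch_id),
                          s = sum(.data$percent))
  expect_equal(tot$s, rep(100, nrow(tot)), tolerance = 1e-9)
  # partial spines are excluded before classification
  sp <- m$spines
  sp$partial[1] <- TRUE
  fr2 <- spine_type_fractions(m, sp)
  n1 <- sum(fr$n); n2 <- sum(fr2$n)
  expect_equal(n1 - n2, 1)
})

test_that("programmed spine-type contrast is detected by Mann-Whitney", {
  young <- generate_morphology(101, morphology_spec(
    spine_density = c(mushroom = 0.05, thin = 0.45, filopodium = 0.35,
                      branched = 0.1, stubby = 0.05)))
  old <- generate_morphology(202, morphology_spec(
    spine_density = c(mushroom = 0.45, thin = 0.2, filopodium = 0.03,
                      branched = 0.02, stubby = 0.3)))
  fy <- spine_type_fractions(young)
  fo <- spine_type_fractions(old)
  mushroom_y <- fy$percent[fy$type == "mushroom"]
  mushroom_o <- fo$percent[fo$type == "mushroom"]
  res <- pairwise_test(mushroom_y, mushroom_o, policy = "mann-whitney")
  expect_lt(res$p, 0.001)
  expect_lt(median(mushroom_y), median(mushroom_o))
  filo_y <- fy$percent[fy$type == "filopodium"]
  filo_o <- fo$percent[fo$type == "filopodium"]
  expect_lt(pairwise_test(filo_y, filo_o, policy = "mann-whitney")$p, 0.001)
  expect_gt(median(filo_y), median(filo_o))
})
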