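#' Branching specification for synthetic morphologies
#'
#' Parameters of the random dendritic-tree generator: branch (segment)
#' lengths are lognormal per compartment, bifurcation happens with
#' `branch_prob` at the end of every branch up to `max_order`, apical trees
#' grow toward +pia (+y) and basal trees away from it, and spines of each
#' type are placed as a Poisson process along every branch with the given
#' per-type densities (spines/um).
#'
#' @param apical_trunks,basal_stems Number of primary dendrites.
#' @param apical_length_um,basal_length_um Mean inter-bifurcation branch
#'   length per compartment (um).
#' @param length_cv Coefficient of variation of branch lengths.
#' @param branch_prob Bifurcation probability at each branch end.
#' @param max_order Maximum centrifugal branch order.
#' @param spine_density Named vector of per-type densities (spines/um) over
#'   `mushroom`, `thin`, `filopodium`, `branched`, `stubby`; 0 omits a type.
#' @return A list of class `morphology_spec`.
#' @export
morphology_spec <- function(apical_trunks = 1, basal_stems = 4,
                            apical_length_um = 90, basal_length_um = 70,
                            length_cv = 0.4, branch_prob = 0.7,
                            max_order = 5,
                            spine_density = c(mushroom = 0.4, thin = 0.5,
                                              filopodium = 0.1,
                                              branched = 0.05,
                                              stubby = 0.15)) {
  stopifnot(apical_trunks + basal_stems >= 1, branch_prob >= 0,
            branch_prob <= 1, max_order >= 1, all(spine_density >= 0))
  structure(list(apical_trunks = apical_trunks, basal_stems = basal_stems,
                 apical_length_um = apical_length_um,
                 basal_length_um = basal_length_um, length_cv = length_cv,
                 branch_prob = branch_prob, max_order = max_order,
                 spine_density = spine_density),
            class = "morphology_spec")
}

# unit vector jittered within `angle_sd` radians of `dir`
jitter_direction <- function(dir, angle_sd = 0.35) {
  v <- dir + stats::rnorm(3, 0, angle_sd)
  v / sqrt(sum(v^2))
}

# per-type spine geometry generators; matched to the classify_spine()
# default thresholds so generated labels are recoverable from geometry
spine_geometry <- function(type, n) {
  clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  switch(type,
    mushroom = tibble::tibble(
      protrusion_length_um = stats::runif(n, 1.2, 2.5),
      head_diameter_um = clip(stats::rnorm(n, 0.85, 0.08), 0.65, 1.2),
      neck_diameter_um = clip(stats::rnorm(n, 0.20, 0.03), 0.1, 0.3),
      head_count = rep(1L, n)),
    thin = tibble::tibble(
      protrusion_length_um = stats::runif(n, 1.2, 2.8),
      head_diameter_um = clip(stats::rnorm(n, 0.35, 0.05), 0.22, 0.5),
      neck_diameter_um = clip(stats::rnorm(n, 0.15, 0.02), 0.08, 0.18),
      head_count = rep(1L, n)),
    filopodium = tibble::tibble(
      protrusion_length_um = stats::runif(n, 3.2, 5),
      head_diameter_um = clip(stats::rnorm(n, 0.15, 0.015), 0.1, 0.17),
      neck_diameter_um = clip(stats::rnorm(n, 0.15, 0.015), 0.14, 0.2),
      head_count = rep(1L, n)),
    branched = tibble::tibble(
      protrusion_length_um = stats::runif(n, 1.5, 2.5),
      head_diameter_um = clip(stats::rnorm(n, 0.5, 0.08), 0.3, 0.8),
      neck_diameter_um = clip(stats::rnorm(n, 0.2, 0.03), 0.1, 0.3),
      head_count = rep(2L, n)),
    stubby = tibble::tibble(
      protrusion_length_um = stats::runif(n, 0.3, 0.9),
      head_diameter_um = clip(stats::rnorm(n, 0.40, 0.05), 0.25, 0.55),
      neck_diameter_um = clip(stats::rnorm(n, 0.42, 0.05), 0.35, 0.6),
      head_count = rep(1L, n)))
}

#' Generate a random morphology with ground truth
#'
#' Grows a rooted tree (soma at the origin) per [morphology_spec()] and
#' places spines along every dendritic branch. The returned object carries a
#' `manifest` attribute with the generative ground truth: total / apical /
#' basal length, bifurcation count, extents, per-compartment terminal
#' segment lengths, and per-branch spine counts per type — everything the
#' morphometry operations should recover exactly.
#'
#' @param seed Integer seed.
#' @param spec A [morphology_spec()].
#' @return A [morphology()] with attribute `manifest` (list with fields
#'   `metrics` (one-row tibble in [arbor_metrics()] layout), `terminal`
#'   (tibble of terminal branch lengths) and `spines` (per-branch per-type
#'   counts)).
#' @export
generate_morphology <- function(seed = 1L, spec = morphology_spec()) {
  stopifnot(inherits(spec, "morphology_spec"))
  if (spec$apical_trunks + spec$basal_stems < 1)
    stop("spec produces zero dendrites")
  set.seed(seed)
  sdlog <- sqrt(log(1 + spec$length_cv^2))
  draw_len <- function(mean_um)
    stats::rlnorm(1, log(mean_um) - sdlog^2 / 2, sdlog)

  nodes <- tibble::tibble(id = 1L, parent_id = -1L, compartment = "soma",
                          x = 0, y = 0, z = 0, radius = 6)
  next_id <- 2L
  branch_rows <- list()   # ground truth per branch
  # queue entries: anchor node id/xyz, direction, order, compartment
  queue <- list()
  for (i in seq_len(spec$apical_trunks))
    queue[[length(queue) + 1L]] <- list(
      anchor = 1L, at = c(0, 0, 0), dir = jitter_direction(c(0, 1, 0), 0.1),
      order = 1L, comp = "apical")
  for (i in seq_len(spec$basal_stems))
    queue[[length(queue) + 1L]] <- list(
      anchor = 1L, at = c(0, 0, 0),
      dir = jitter_direction(c(stats::rnorm(1, 0, 0.6), -1,
                               stats::rnorm(1, 0, 0.6)), 0.2),
      order = 1L, comp = "basal")

  while (length(queue)) {
    q <- queue[[1]]
    queue <- queue[-1]
    mean_len <- if (q$comp == "apical") spec$apical_length_um
                else spec$basal_length_um
    len <- draw_len(mean_len)
    # lay the branch down as 3 collinear-ish pieces (interior nodes have one
    # child, so they create no spurious bifurcations)
    n_pieces <- 3L
    at <- q$at
    dir <- q$dir
    parent <- q$anchor
    blen <- 0
    for (p in seq_len(n_pieces)) {
      dir <- jitter_direction(dir, 0.08)
      step <- len / n_pieces
      at2 <- at + dir * step
      nodes <- dplyr::bind_rows(nodes, tibble::tibble(
        id = next_id, parent_id = parent, compartment = q$comp,
        x = at2[1], y = at2[2], z = at2[3], radius = 0.8))
      blen <- blen + step
      parent <- next_id
      next_id <- next_id + 1L
      at <- at2
    }
    end_id <- parent
    will_branch <- q$order < spec$max_order &&
      stats::runif(1) < spec$branch_prob
    branch_rows[[length(branch_rows) + 1L]] <- tibble::tibble(
      branch_id = end_id, compartment = q$comp, length_um = blen,
      is_terminal = !will_branch)
    if (will_branch) {
      axis <- jitter_direction(c(dir[2], -dir[1], dir[3]), 0.2)
      for (sgn in c(1, -1)) {
        child_dir <- dir + sgn * 0.55 * axis
        queue[[length(queue) + 1L]] <- list(
          anchor = end_id, at = at,
          dir = child_dir / sqrt(sum(child_dir^2)),
          order = q$order + 1L, comp = q$comp)
      }
    }
  }

  branches <- dplyr::bind_rows(branch_rows)
  # spine placement: per branch x type, Poisson in the branch length
  types <- names(spec$spine_density)[spec$spine_density > 0]
  spine_rows <- list()
  count_rows <- list()
  for (bi in seq_len(nrow(branches))) {
    b <- branches[bi, ]
    for (ty in types) {
      n <- stats::rpois(1, spec$spine_density[[ty]] * b$length_um)
      count_rows[[length(count_rows) + 1L]] <- tibble::tibble(
        branch_id = b$branch_id, compartment = b$compartment,
        type = ty, n = n)
      if (n > 0)
        spine_rows[[length(spine_rows) + 1L]] <- dplyr::bind_cols(
          tibble::tibble(branch_id = rep(b$branch_id, n),
                         arc_position_um = stats::runif(n, 0, b$length_um)),
          spine_geometry(ty, n),
          tibble::tibble(type = rep(ty, n), partial = rep(FALSE, n)))
    }
  }
  spines <- if (length(spine_rows)) dplyr::bind_rows(spine_rows) else NULL

  m <- morphology(nodes, spines = spines)
  xyz <- as.matrix(nodes[, c("x", "y", "z")])
  term <- branches[branches$is_terminal, ]
  apical_len <- sum(branches$length_um[branches$compartment == "apical"])
  basal_len <- sum(branches$length_um[branches$compartment == "basal"])
  mean_or_na <- function(x) if (length(x)) mean(x) else NA_real_
  manifest <- list(
    metrics = tibble::tibble(
      total_length_mm = (apical_len + basal_len) / 1000,
      apical_length_mm = apical_len / 1000,
      basal_length_mm = basal_len / 1000,
      n_nodes = sum(!branches$is_terminal),
      max_horizontal_um = diff(range(xyz[, 1])),
      max_vertical_um = diff(range(xyz[, 2])),
      apical_terminal_um =
        mean_or_na(term$length_um[term$compartment == "apical"]),
      basal_terminal_um =
        mean_or_na(term$length_um[term$compartment == "basal"]),
      soma_depth_um = NA_real_),
    branches = branches,
    terminal = term,
    spines = dplyr::bind_rows(count_rows))
  attr(m, "manifest") <- manifest
  m
}

#' @rdname generate_morphology
#' @param m A generated [morphology()].
#' @export
morphology_manifest <- function(m) attr(m, "manifest")
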