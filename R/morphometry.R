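swc_type_names <- c(`1` = "soma", `2` = "axon", `3` = "basal",
                    `4` = "apical")

#' Neuron morphology container
#'
#' A rooted 3D tree of labelled points: one row per node with its parent,
#' compartment (`soma`, `axon`, `basal`, `apical`), coordinates in um, and
#' radius. Optional spine annotations (see [spine_density()]) and layer
#' annotation (L1/2 border depth, pia direction) ride along.
#'
#' @param nodes Data frame with columns `id`, `parent_id`, `compartment`,
#'   `x`, `y`, `z`, `radius`. Exactly one root (`parent_id` -1); every
#'   parent must precede its child.
#' @param spines Optional spine annotation tibble (columns `branch_id`,
#'   `arc_position_um`, `protrusion_length_um`, `head_diameter_um`,
#'   `neck_diameter_um`, `head_count`, optional `type`, optional `partial`).
#' @param pia_direction Unit-ish vector giving the pia-normal axis in the
#'   morphology's frame; default `c(0, 1, 0)` (+y toward the pia).
#' @param l12_depth_um Optional soma depth below the L1/2 border (um).
#' @return An object of class `morphology`.
#' @export
morphology <- function(nodes, spines = NULL, pia_direction = c(0, 1, 0),
                       l12_depth_um = NA_real_) {
  nodes <- tibble::as_tibble(nodes)
  need <- c("id", "parent_id", "compartment", "x", "y", "z", "radius")
  if (!all(need %in% names(nodes)))
    stop("morphology nodes need columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(nodes$id))
    stop("duplicate node ids: ",
         paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "))
  roots <- which(nodes$parent_id == -1)
  if (length(roots) != 1)
    stop(sprintf("morphology must have exactly one root, found %d",
                 length(roots)))
  pos <- match(nodes$parent_id, nodes$id)
  bad <- which(nodes$parent_id != -1 & is.na(pos))
  if (length(bad))
    stop(sprintf("node %s references undefined parent %s",
                 nodes$id[bad[1]], nodes$parent_id[bad[1]]))
  late <- which(nodes$parent_id != -1 & pos >= seq_len(nrow(nodes)))
  if (length(late))
    stop(sprintf("node %s appears before its parent %s",
                 nodes$id[late[1]], nodes$parent_id[late[1]]))
  if (any(!is.finite(as.matrix(nodes[, c("x", "y", "z")]))))
    stop("non-finite node coordinates")
  if (!all(nodes$compartment %in% swc_type_names))
    stop("unknown compartment label(s): ",
         paste(setdiff(unique(nodes$compartment), swc_type_names),
               collapse = ", "))
  structure(list(nodes = nodes, spines = spines,
                 pia_direction = pia_direction / sqrt(sum(pia_direction^2)),
                 l12_depth_um = l12_depth_um),
            class = "morphology")
}

#' @export
print.morphology <- function(x, ...) {
  n <- x$nodes
  cat(sprintf(
    "<morphology> %d nodes (%d apical, %d basal), %s spines\n",
    nrow(n), sum(n$compartment == "apical"), sum(n$compartment == "basal"),
    if (is.null(x$spines)) "no" else nrow(x$spines)))
  invisible(x)
}

#' Read / write SWC reconstructions
#'
#' Standard 7-column SWC (`id type x y z radius parent`), `#` comments
#' allowed. Type codes: 1 soma, 2 axon, 3 basal dendrite, 4 apical dendrite;
#' other codes are rejected unless remapped via `type_map`. Structural
#' errors (orphan nodes, duplicate ids, child before parent) are reported
#' with the offending line number.
#'
#' @param path SWC file path.
#' @param type_map Optional named vector remapping extra integer codes to
#'   compartment names, e.g. `c("5" = "basal")`.
#' @param ... Passed to [morphology()].
#' @return `read_swc()`: a [morphology()].
#' @export
read_swc <- function(path, type_map = NULL, ...) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (!length(keep)) stop(sprintf("'%s': no data lines", path))
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  bad <- which(lengths(fields) != 7)
  if (length(bad))
    stop(sprintf("'%s' line %d: expected 7 columns, found %d",
                 path, keep[bad[1]], lengths(fields)[bad[1]]))
  m <- matrix(as.numeric(unlist(fields)), ncol = 7, byrow = TRUE)
  if (any(is.na(m)))
    stop(sprintf("'%s' line %d: non-numeric field", path,
                 keep[which(rowSums(is.na(m)) > 0)[1]]))
  map <- c(swc_type_names, type_map)
  comp <- map[as.character(as.integer(m[, 2]))]
  if (any(is.na(comp)))
    stop(sprintf("'%s' line %d: unknown SWC type code %d", path,
                 keep[which(is.na(comp))[1]], m[which(is.na(comp))[1], 2]))
  nodes <- tibble::tibble(
    id = as.integer(m[, 1]), parent_id = as.integer(m[, 7]),
    compartment = unname(comp), x = m[, 3], y = m[, 4], z = m[, 5],
    radius = m[, 6])
  tryCatch(morphology(nodes, ...),
           error = function(e)
             stop(sprintf("'%s': %s", path, conditionMessage(e))))
}

#' @rdname read_swc
#' @param m A [morphology()].
#' @export
write_swc <- function(m, path) {
  stopifnot(inherits(m, "morphology"))
  code <- match(m$nodes$compartment, swc_type_names)
  lines <- sprintf("%d %d %.9g %.9g %.9g %.9g %d",
                   m$nodes$id, code, m$nodes$x, m$nodes$y, m$nodes$z,
                   m$nodes$radius, m$nodes$parent_id)
  writeLines(c("# SWC export", lines), path)
  invisible(path)
}

# drop nodes coincident with their parent (zero-length segments), splicing
# children through to the parent
prune_degenerate <- function(nodes) {
  repeat {
    pos <- match(nodes$parent_id, nodes$id)
    dup <- which(nodes$parent_id != -1 &
                   nodes$x == nodes$x[pos] & nodes$y == nodes$y[pos] &
                   nodes$z == nodes$z[pos])
    if (!length(dup)) return(nodes)
    d <- dup[1]
    nodes$parent_id[nodes$parent_id == nodes$id[d]] <- nodes$parent_id[d]
    nodes <- nodes[-d, ]
  }
}

# segment length from each node to its parent (0 for the root)
edge_lengths <- function(nodes) {
  pos <- match(nodes$parent_id, nodes$id)
  len <- sqrt((nodes$x - nodes$x[pos])^2 + (nodes$y - nodes$y[pos])^2 +
                (nodes$z - nodes$z[pos])^2)
  len[is.na(len)] <- 0
  len
}

# ids of dendritic branch points: dendritic nodes with >= 2 dendritic
# children
branch_point_ids <- function(nodes) {
  dend <- nodes$compartment %in% c("apical", "basal")
  kids <- table(nodes$parent_id[dend])
  ids <- as.numeric(names(kids)[kids >= 2])
  ids[ids %in% nodes$id[dend]]
}

#' Inter-bifurcation branch table
#'
#' Decomposes the dendritic arbor into branches: maximal paths running from
#' a branch point (or the soma) to the next branch point or terminal tip.
#' Each branch is identified by the id of its distal end node.
#'
#' @param m A [morphology()].
#' @return Tibble: `branch_id`, `compartment`, `length_um`, `is_terminal`.
#' @export
branch_table <- function(m) {
  nodes <- prune_degenerate(m$nodes)
  dend <- nodes$compartment %in% c("apical", "basal")
  bp <- branch_point_ids(nodes)
  elen <- edge_lengths(nodes)
  nkids <- table(nodes$parent_id)
  is_tip <- dend & !(nodes$id %in% as.numeric(names(nkids)))
  # branch ends: tips and branch points
  ends <- nodes$id[dend & (is_tip | nodes$id %in% bp)]
  pos <- match(nodes$parent_id, nodes$id)
  purrr::map_dfr(ends, function(e) {
    i <- match(e, nodes$id)
    len <- 0
    j <- i
    repeat {
      len <- len + elen[j]
      pj <- pos[j]
      if (is.na(pj)) break                       # reached the root
      if (nodes$id[pj] %in% bp) break            # proximal branch point
      if (nodes$compartment[pj] == "soma") break # soma anchors stems
      j <- pj
    }
    tibble::tibble(branch_id = e, compartment = nodes$compartment[i],
                   length_um = len, is_terminal = is_tip[i])
  })
}

#' Arbor metrics
#'
#' The morphometric summary of a reconstruction: total/apical/basal
#' dendritic length (mm; summed Euclidean inter-node distances, each edge
#' assigned to the child's compartment, axon excluded), bifurcation count
#' (dendritic nodes with >= 2 dendritic children), maximal horizontal and
#' vertical extension (um; vertical along the annotated pia direction,
#' horizontal along the orthogonal in-slice x axis with z collapsed, soma
#' included), and mean terminal segment length per compartment (path from
#' each terminal tip back to the last branch point before it; the soma
#' anchors unbranched stems). Zero-length duplicate points are pruned before
#' measurement.
#'
#' @param m A [morphology()].
#' @return One-row tibble: `total_length_mm`, `apical_length_mm`,
#'   `basal_length_mm`, `n_nodes`, `max_horizontal_um`, `max_vertical_um`,
#'   `apical_terminal_um`, `basal_terminal_um`, `soma_depth_um`.
#' @export
arbor_metrics <- function(m) {
  stopifnot(inherits(m, "morphology"))
  nodes <- prune_degenerate(m$nodes)
  if (!any(nodes$compartment %in% c("apical", "basal")))
    stop("morphology has no dendritic nodes")
  elen <- edge_lengths(nodes)
  apical <- sum(elen[nodes$compartment == "apical"])
  basal <- sum(elen[nodes$compartment == "basal"])
  keep <- nodes$compartment %in% c("soma", "apical", "basal")
  xyz <- as.matrix(nodes[keep, c("x", "y", "z")])
  vert <- xyz %*% m$pia_direction
  # horizontal: in-slice axis orthogonal to the pia normal (z collapsed)
  horiz_axis <- c(m$pia_direction[2], -m$pia_direction[1], 0)
  if (sum(horiz_axis^2) < 1e-12) horiz_axis <- c(1, 0, 0)
  horiz_axis <- horiz_axis / sqrt(sum(horiz_axis^2))
  horiz <- xyz %*% horiz_axis
  br <- branch_table(m)
  term <- br[br$is_terminal, ]
  mean_or_na <- function(x) if (length(x)) mean(x) else NA_real_
  tibble::tibble(
    total_length_mm = (apical + basal) / 1000,
    apical_length_mm = apical / 1000,
    basal_length_mm = basal / 1000,
    n_nodes = length(branch_point_ids(nodes)),
    max_horizontal_um = diff(range(horiz)),
    max_vertical_um = diff(range(vert)),
    apical_terminal_um =
      mean_or_na(term$length_um[term$compartment == "apical"]),
    basal_terminal_um =
      mean_or_na(term$length_um[term$compartment == "basal"]),
    soma_depth_um = m$l12_depth_um)
}

#' Spine density per branch and per compartment
#'
#' Per branch: spine count divided by the branch arc length (spines/um,
#' the between-bifurcations definition). Per compartment: the unweighted
#' mean of the branch densities (zero-spine branches included); the
#' length-weighted alternative (total spines / total length) is available
#' via `weighted = TRUE`.
#'
#' @param m A [morphology()].
#' @param spines Spine annotation tibble; defaults to the annotations
#'   stored in `m`.
#' @param weighted Use length-weighted compartment aggregation.
#' @return List with tibbles `per_branch` (`branch_id`, `compartment`,
#'   `length_um`, `n_spines`, `density`) and `per_compartment`
#'   (`compartment`, `n_branches`, `density`).
#' @export
spine_density <- function(m, spines = m$spines, weighted = FALSE) {
  stopifnot(inherits(m, "morphology"))
  if (is.null(spines) || !nrow(spines)) stop("no spine annotations")
  br <- branch_table(m)
  unknown <- setdiff(unique(spines$branch_id), br$branch_id)
  if (length(unknown))
    stop("spines reference unknown branch ids: ",
         paste(unknown, collapse = ", "))
  counts <- table(spines$branch_id)
  br$n_spines <- as.integer(counts[as.character(br$branch_id)])
  br$n_spines[is.na(br$n_spines)] <- 0L
  br$density <- br$n_spines / br$length_um
  per_comp <- dplyr::summarise(
    dplyr::group_by(br, .data$compartment),
    n_branches = dplyr::n(),
    density = if (weighted) sum(.data$n_spines) / sum(.data$length_um)
              else mean(.data$density),
    .groups = "drop")
  list(per_branch = dplyr::select(br, "branch_id", "compartment",
                                  "length_um", "n_spines", "density"),
       per_compartment = per_comp)
}

#' Geometric spine classification
#'
#' Rule-based typing of annotated spines, applied in fixed decision order:
#' two or more heads from one origin are `branched`; short protrusions
#' without a discernible neck (`length < l_stub` and head no wider than
#' `r_head` times the neck) are `stubby`; long protrusions without a
#' distinct head (`length > l_filo`, head within `r_head` of the neck) are
#' `filopodium`; a remaining spine with a large head (`>= d_mush`) is
#' `mushroom`; everything else is `thin`. The thresholds are explicit
#' configuration because published criteria are qualitative.
#'
#' @param spines Spine annotation tibble (see [morphology()]).
#' @param l_stub Max protrusion length of a stubby spine (um).
#' @param l_filo Min protrusion length of a filopodium (um).
#' @param d_mush Min head diameter of a mushroom spine (um).
#' @param r_head Head/neck ratio below which no distinct head is called.
#' @return Character vector of type labels (`NA` when geometry is missing).
#' @export
classify_spine <- function(spines, l_stub = 1.0, l_filo = 3.0,
                           d_mush = 0.6, r_head = 1.2) {
  n <- nrow(spines)
  len <- spines$protrusion_length_um
  head <- spines$head_diameter_um
  neck <- spines$neck_diameter_um
  heads <- spines$head_count
  out <- rep(NA_character_, n)
  no_head <- head <= neck * r_head
  out[heads >= 2] <- "branched"
  rest <- is.na(out)
  out[rest & len < l_stub & no_head] <- "stubby"
  rest <- is.na(out)
  out[rest & len > l_filo & no_head] <- "filopodium"
  rest <- is.na(out)
  out[rest & head >= d_mush] <- "mushroom"
  out[is.na(out) & !is.na(len) & !is.na(head)] <- "thin"
  out
}

#' Per-branch spine-type percentages
#'
#' Spines flagged `partial` (not fully visible) are excluded first; spines
#' lacking a prior `type` label are classified geometrically via
#' [classify_spine()]. Per branch the five type percentages sum to 100;
#' branches with no classified spine are excluded.
#'
#' @param m A [morphology()].
#' @param spines Spine annotations; default those stored in `m`.
#' @param ... Thresholds passed to [classify_spine()].
#' @return Tibble: `branch_id`, `compartment`, `type`, `n`, `percent`.
#' @export
spine_type_fractions <- function(m, spines = m$spines, ...) {
  stopifnot(inherits(m, "morphology"))
  if (is.null(spines) || !nrow(spines)) stop("no spine annotations")
  if ("partial" %in% names(spines))
    spines <- spines[!isTRUE_vec(spines$partial), , drop = FALSE]
  type <- if ("type" %in% names(spines) && !all(is.na(spines$type)))
    spines$type else classify_spine(spines, ...)
  spines$type <- type
  spines <- spines[!is.na(spines$type), , drop = FALSE]
  if (!nrow(spines)) stop("no classifiable spines")
  br <- branch_table(m)
  types <- c("mushroom", "thin", "filopodium", "branched", "stubby")
  tab <- dplyr::count(spines, .data$branch_id, .data$type)
  full <- tidyr::complete(tab, branch_id = unique(tab$branch_id),
                          type = types, fill = list(n = 0L))
  full <- dplyr::left_join(
    full, br[, c("branch_id", "compartment")], by = "branch_id")
  dplyr::mutate(
    dplyr::group_by(full, .data$branch_id),
    percent = 100 * .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::select("branch_id", "compartment", "type", "n", "percent")
}

isTRUE_vec <- function(x) !is.na(x) & x
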