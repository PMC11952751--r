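#' Run a complete synthetic lifespan study
#'
#' End-to-end pipeline on simulated data: draws the cohort manifest from the
#' spec, simulates each cell under the protocol, extracts the 32-feature
#' vector, applies the series-resistance quality gate, and runs the
#' age-group comparison (Kruskal-Wallis omnibus + Dunn post-hoc per
#' feature). Cells are simulated one at a time and their traces discarded
#' after extraction, so memory stays flat in cohort size.
#'
#' @param spec A [cohort_spec()]; default [lifespan_cohort_spec()].
#' @param protocol A [step_protocol()].
#' @param rs_max Series-resistance gate (MOhm) applied before the
#'   comparison; `Inf` disables it.
#' @param adjust,alpha Passed to [group_summary()].
#' @param ... Passed to [extract_cell_features()].
#' @return List with `features` (tibble, one row per cell), `comparison`
#'   (a `group_comparison`), and `manifest` (ground-truth parameters).
#' @export
run_lifespan_study <- function(spec = lifespan_cohort_spec(),
                               protocol = step_protocol(),
                               rs_max = 30, adjust = "bonferroni",
                               alpha = 0.05, ...) {
  manifest <- sample_cohort_params(spec)
  rows <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    rec <- simulate_membrane(manifest_params(row), protocol,
                             cell_id = row$cell_id, age = row$age,
                             sex = row$sex, region = row$region,
                             pathology = row$pathology,
                             soma_depth_um = row$soma_depth_um,
                             series_resistance = row$series_resistance)
    rows[[i]] <- extract_cell_features(rec, ...)
  }
  features <- dplyr::bind_rows(rows)
  features <- dplyr::mutate(features,
                            age_group = assign_age_group(.data$age),
                            .after = "age")
  kept <- qc_filter(features, rs_max = rs_max)
  list(features = features,
       comparison = group_summary(kept, group = "age_group",
                                  adjust = adjust, alpha = alpha),
       manifest = manifest)
}
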