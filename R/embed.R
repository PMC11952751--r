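#' The eight headline electrophysiological features
#'
#' Convenience subset used for the reduced embedding: resting Vm, input
#' resistance, tau, sag ratio, rheobase, AP half-width, AP up-stroke, AP
#' amplitude.
#'
#' @return Character vector of length 8.
#' @export
headline_feature_names <- function() {
  c("resting_vm", "input_resistance", "tau", "sag_ratio", "rheobase",
    "ap_half_width", "ap_up_stroke", "ap_amplitude")
}

#' Standardize features and embed them in 2D
#'
#' Complete-case rows of the chosen feature subset are z-scored
#' (standardization parameters are returned) and handed to an external
#' low-dimensional embedding routine; the embedding algorithm itself is a
#' pluggable backend, not part of this package's contribution. Backends:
#' `"nmds"` (Kruskal's nonmetric MDS on Euclidean distances, via
#' [MASS::isoMDS()] initialized from classical MDS) and `"pca"` (first two
#' principal components). Duplicate feature rows are collapsed before the
#' distance computation and re-expanded afterwards, so duplicates receive
#' identical coordinates. With a fixed seed the output is reproducible.
#'
#' @param features Feature tibble (one row per cell).
#' @param feature_cols Feature subset to embed; defaults to
#'   [headline_feature_names()]; use [ephys_feature_names()] for the full
#'   set.
#' @param method `"nmds"` or `"pca"`.
#' @param seed Integer seed.
#' @return The complete-case rows of `features` with `embed_1` / `embed_2`
#'   columns appended; attributes `center`, `scale` (standardization) and
#'   `dropped` (number of incomplete rows removed).
#' @export
embed_features <- function(features, feature_cols = headline_feature_names(),
                           method = c("nmds", "pca"), seed = 1L) {
  method <- match.arg(method)
  stopifnot(all(feature_cols %in% names(features)))
  x <- as.matrix(features[, feature_cols])
  complete <- stats::complete.cases(x)
  dropped <- sum(!complete)
  if (dropped)
    message(sprintf("embed_features: dropping %d incomplete row(s)",
                    dropped))
  out <- features[complete, , drop = FALSE]
  x <- x[complete, , drop = FALSE]
  if (nrow(x) < 3) stop("embed_features needs >= 3 complete rows")
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0] <- 1
  z <- scale(x, center = ctr, scale = scl)
  key <- apply(z, 1, paste, collapse = "\r")
  first <- !duplicated(key)
  zu <- z[first, , drop = FALSE]
  set.seed(seed)
  coords_u <- if (method == "pca" || nrow(zu) < 4) {
    stats::prcomp(zu, center = FALSE, scale. = FALSE)$x[, 1:2, drop = FALSE]
  } else {
    d <- stats::dist(zu)
    init <- stats::cmdscale(d, k = 2)
    utils::capture.output(
      fit <- MASS::isoMDS(d, y = init, k = 2, maxit = 50))
    fit$points
  }
  idx <- match(key, key[first])
  out$embed_1 <- coords_u[idx, 1]
  out$embed_2 <- coords_u[idx, 2]
  attr(out, "center") <- ctr
  attr(out, "scale") <- scl
  attr(out, "dropped") <- dropped
  out
}
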