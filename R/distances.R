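#' Pairwise nerve-artery inter-centroid distances
#'
#' Euclidean distances in the (x, z) slice plane between every nerve centroid
#' and every artery centroid, slice by slice. Slices lacking either class are
#' skipped (no imputation). Distances are inter-centroid only — they do not
#' account for the element perimeters (see
#' [perimeter_distance_bounds()] for the derived bound).
#'
#' @param profiles Profile table after [filter_capillaries()].
#' @return Data frame: `slice_index`, `nerve_label`, `artery_label`,
#'   `distance_um` — one row per nerve x artery pair per retained slice.
#' @export
pairwise_distances <- function(profiles) {
  out <- list()
  for (s in unique(profiles$slice_index)) {
    p <- profiles[profiles$slice_index == s, , drop = FALSE]
    nv <- p[p$element_class == "nerve", , drop = FALSE]
    ar <- p[p$element_class == "artery", , drop = FALSE]
    if (!nrow(nv) || !nrow(ar)) next
    g <- expand.grid(n = seq_len(nrow(nv)), a = seq_len(nrow(ar)))
    out[[length(out) + 1L]] <- data.frame(
      slice_index = s,
      nerve_label = nv$label[g$n],
      artery_label = ar$label[g$a],
      distance_um = sqrt(
        (nv$centroid_x_um[g$n] - ar$centroid_x_um[g$a])^2 +
        (nv$centroid_z_um[g$n] - ar$centroid_z_um[g$a])^2))
  }
  if (!length(out))
    return(data.frame(slice_index = integer(), nerve_label = integer(),
                      artery_label = integer(), distance_um = numeric()))
  do.call(rbind, out)
}

#' Summaries of nerve-artery distances
#'
#' Pools all pairwise distances across slices, and separately summarises the
#' per-slice minima (one minimum per slice).
#'
#' @param pairs Output of [pairwise_distances()].
#' @return List with `all_pairs` ([summary_stats()] over every distance),
#'   `per_slice_min` (stats over per-slice minima) and `minima` (data frame
#'   `slice_index`, `min_distance_um`).
#' @export
distance_summaries <- function(pairs) {
  if (!nrow(pairs)) stop("no nerve-artery distance records")
  mins <- vapply(split(pairs$distance_um, pairs$slice_index), min, numeric(1))
  minima <- data.frame(slice_index = as.integer(names(mins)),
                       min_distance_um = unname(mins))
  list(all_pairs = summary_stats(pairs$distance_um),
       per_slice_min = summary_stats(minima$min_distance_um),
       minima = minima)
}

#' Project all centroids into the first slice
#'
#' Collapses the slice coordinate, emitting every profile centroid with its
#' (x, z) unchanged. The projected pattern traces element trajectories on the
#' first-slice plane.
#'
#' @param profiles Profile table.
#' @return Data frame: `element_class`, `x_um`, `z_um`, `source_slice`.
#' @export
project_centroids <- function(profiles) {
  data.frame(element_class = profiles$element_class,
             x_um = profiles$centroid_x_um,
             z_um = profiles$centroid_z_um,
             source_slice = profiles$slice_index)
}

#' Perimeter-to-perimeter distance bound from centroid statistics
#'
#' Collapsed vessel walls make direct perimeter-to-perimeter measurement
#' unreliable, so the bound is derived arithmetically: subtracting the sum of
#' the largest (smallest) radii in the diameter interquartile ranges from the
#' inter-centroid distance gives the lower (upper) bound on the mean minimum
#' surface separation. Negative bounds are clamped at zero.
#'
#' @param min_centroid_distance Inter-centroid distance, um (e.g. the median
#'   minimum nerve-artery distance).
#' @param artery_diam_range,nerve_diam_range `c(lo, hi)` diameter IQRs, um.
#' @return Named numeric `c(lower, upper)`, um.
#' @examples
#' perimeter_distance_bounds(217, c(30, 71), c(20, 39))  # 162, 192
#' @export
perimeter_distance_bounds <- function(min_centroid_distance,
                                      artery_diam_range, nerve_diam_range) {
  stopifnot(min_centroid_distance > 0,
            length(artery_diam_range) == 2, length(nerve_diam_range) == 2,
            all(artery_diam_range >= 0), all(nerve_diam_range >= 0),
            artery_diam_range[2] >= artery_diam_range[1],
            nerve_diam_range[2] >= nerve_diam_range[1])
  lower <- min_centroid_distance -
    (artery_diam_range[2] + nerve_diam_range[2]) / 2
  upper <- min_centroid_distance -
    (artery_diam_range[1] + nerve_diam_range[1]) / 2
  c(lower = max(0, lower), upper = max(0, upper))
}
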