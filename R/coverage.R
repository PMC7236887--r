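#' Link per-slice profiles into element tracks
#'
#' Profiles in consecutive slices are joined into one track when their pixel
#' footprints overlap (the stack is relabelled with [label_components()], so
#' labels agree with [extract_profiles()]). A profile whose footprint overlaps
#' several successors — or several predecessors — marks a branch/merge event:
#' the parent track ends and each continuation starts a child track, so every
#' track covers a contiguous slice span with one profile per slice. Profiles
#' absent from `profiles` (e.g. removed by [filter_capillaries()]) are
#' treated as background. When no stack is supplied, linking falls back to
#' mutual-nearest centroids within `linking_radius`.
#'
#' @param profiles Profile table after [filter_capillaries()].
#' @param stack The [mask_stack()] the profiles came from; enables
#'   footprint-overlap linking.
#' @param linking_radius Centroid linking radius, um, for the fallback.
#' @param classes Classes to track; default artery and nerve.
#' @return Data frame: `track_id`, `element_class`, `slice_index`, `label`,
#'   `x_um`, `z_um` — one row per member profile.
#' @export
link_tracks <- function(profiles, stack = NULL, linking_radius = 30,
                        classes = c("artery", "nerve")) {
  key <- function(s, cls, lab) paste(s, cls, lab, sep = "/")
  assign_track <- integer(0)
  next_id <- 1L
  for (cls in classes) {
    pc <- profiles[profiles$element_class == cls, , drop = FALSE]
    if (!nrow(pc)) next
    n_slices <- attr(profiles, "n_slices")
    if (is.null(n_slices)) n_slices <- max(pc$slice_index)
    active <- integer(0)  # current track id per label of previous slice
    prev_lab <- NULL
    for (s in seq_len(n_slices)) {
      labs_here <- pc$label[pc$slice_index == s]
      if (!is.null(stack)) {
        m <- stack$masks[[cls]][[s]]
        cur_lab <- label_components(m)
        if (max(cur_lab) > 0L) {  # drop filtered-out components
          lut <- integer(max(cur_lab) + 1L)
          lut[labs_here + 1L] <- labs_here
          cur_lab <- matrix(lut[cur_lab + 1L], nrow = nrow(cur_lab))
        }
      } else cur_lab <- NULL
      new_active <- integer(0)
      if (length(labs_here)) {
        matched <- stats::setNames(rep(NA_integer_, length(labs_here)),
                                   labs_here)
        if (!is.null(stack) && !is.null(prev_lab)) {
          sel <- prev_lab > 0L & cur_lab > 0L
          if (any(sel)) {
            pairs <- unique(cbind(prev_lab[sel], cur_lab[sel]))
            # one-to-one overlaps continue the track; splits/merges start anew
            p_deg <- table(pairs[, 1]); c_deg <- table(pairs[, 2])
            for (r in seq_len(nrow(pairs))) {
              p <- pairs[r, 1]; cc <- pairs[r, 2]
              if (p_deg[[as.character(p)]] == 1L &&
                  c_deg[[as.character(cc)]] == 1L &&
                  !is.na(active[as.character(p)]))
                matched[as.character(cc)] <- active[[as.character(p)]]
            }
          }
        } else if (is.null(stack) && length(active)) {
          prev_rows <- pc[pc$slice_index == s - 1L &
                          pc$label %in% as.integer(names(active)), ,
                          drop = FALSE]
          cur_rows <- pc[pc$slice_index == s, , drop = FALSE]
          if (nrow(prev_rows) && nrow(cur_rows)) {
            d <- outer(cur_rows$centroid_x_um, prev_rows$centroid_x_um,
                       "-")^2 +
                 outer(cur_rows$centroid_z_um, prev_rows$centroid_z_um,
                       "-")^2
            d <- sqrt(d)
            for (i in seq_len(nrow(cur_rows))) {
              j <- which.min(d[i, ])
              if (d[i, j] <= linking_radius && which.min(d[, j]) == i)
                matched[as.character(cur_rows$label[i])] <-
                  active[[as.character(prev_rows$label[j])]]
            }
          }
        }
        for (lb in labs_here) {
          tid <- matched[[as.character(lb)]]
          if (is.na(tid)) { tid <- next_id; next_id <- next_id + 1L }
          new_active[[as.character(lb)]] <- tid
          assign_track[[key(s, cls, lb)]] <- tid
        }
      }
      active <- new_active
      prev_lab <- cur_lab
    }
  }
  sel <- profiles$element_class %in% classes
  p <- profiles[sel, , drop = FALSE]
  data.frame(
    track_id = unname(assign_track[key(p$slice_index, p$element_class,
                                       p$label)]),
    element_class = p$element_class, slice_index = p$slice_index,
    label = p$label, x_um = p$centroid_x_um, z_um = p$centroid_z_um)
}

#' Electrode placement grid in the X-Y plane
#'
#' Lattice of hypothetical needle positions over the sample: `x` spans the
#' slice width and `y` the stack (sectioning) direction. By default points
#' are inset half a spacing from the boundary, representing interior needle
#' placements; pass `offset = c(0, 0)` for a boundary-anchored lattice.
#' A spacing larger than the extent yields a single centred point in that
#' axis.
#'
#' @param extent `c(x, y)` extent, um.
#' @param dx,dy Grid spacings, um; defaults 1000 x 500.
#' @param offset `"half"` (default) or numeric `c(x, y)` offsets, um.
#' @return Data frame `x_um`, `y_um`, row-major (x varies fastest).
#' @export
build_grid <- function(extent, dx = 1000, dy = 500, offset = "half") {
  stopifnot(length(extent) == 2, all(extent > 0), dx > 0, dy > 0)
  if (identical(offset, "half")) offset <- c(dx / 2, dy / 2)
  stopifnot(is.numeric(offset), length(offset) == 2, all(offset >= 0))
  axis_points <- function(ext, step, off) {
    pts <- if (off > ext) numeric(0) else seq(off, ext + 1e-9, by = step)
    if (!length(pts)) ext / 2 else pts  # spacing exceeds extent: centre
  }
  expand.grid(x_um = axis_points(extent[1], dx, offset[1]),
              y_um = axis_points(extent[2], dy, offset[2]),
              KEEP.OUT.ATTRS = FALSE)
}

#' Cumulative radial coverage of element tracks
#'
#' Models a needle electrode inserted along Z at each grid point, generating
#' a cylindrical field of growing radius: a track is covered at radius `r`
#' when any of its per-slice centroids lies within `r` of the grid point in
#' the X-Y plane (`y = (slice_index - 1) * slice_spacing`; the depth
#' coordinate z is ignored, matching the needle model). The covered fraction
#' counts distinct tracks, not per-slice profiles.
#'
#' @param tracks Output of [link_tracks()].
#' @param grid Output of [build_grid()].
#' @param geometry A [voxel_geometry()] (for the slice spacing).
#' @param dr Radius step, um; default 100 (0.1 mm).
#' @param max_radius Largest tabulated radius, um; defaults to the smallest
#'   multiple of `dr` at which every curve reaches 1.
#' @return List with `curves` (grid_x_um, grid_y_um, element_class,
#'   radius_um, fraction, n_tracks; class `"all"` pools every track) and
#'   `mean_curve` (element_class, radius_um, fraction averaged over grid
#'   points).
#' @export
coverage_curves <- function(tracks, grid, geometry = voxel_geometry(),
                            dr = 100, max_radius = NULL) {
  if (!nrow(tracks)) stop("no tracks to cover")
  stopifnot(dr > 0)
  y <- (tracks$slice_index - 1) * geometry$slice_spacing
  ids <- unique(tracks$track_id)
  cls_of <- tracks$element_class[match(ids, tracks$track_id)]
  # min distance of each track to each grid point
  dmin <- matrix(Inf, length(ids), nrow(grid))
  for (gi in seq_len(nrow(grid))) {
    d <- sqrt((tracks$x_um - grid$x_um[gi])^2 + (y - grid$y_um[gi])^2)
    dmin[, gi] <- vapply(split(d, match(tracks$track_id, ids))[
      as.character(seq_along(ids))], min, numeric(1))
  }
  if (is.null(max_radius)) max_radius <- ceiling(max(dmin) / dr) * dr
  radii <- seq(dr, max_radius, by = dr)
  classes <- c(sort(unique(cls_of)), "all")
  out <- list()
  for (gi in seq_len(nrow(grid))) {
    for (cls in classes) {
      sel <- if (cls == "all") rep(TRUE, length(ids)) else cls_of == cls
      if (!any(sel)) next
      frac <- vapply(radii, function(r) mean(dmin[sel, gi] <= r), numeric(1))
      out[[length(out) + 1L]] <- data.frame(
        grid_x_um = grid$x_um[gi], grid_y_um = grid$y_um[gi],
        element_class = cls, radius_um = radii, fraction = frac,
        n_tracks = sum(sel))
    }
  }
  curves <- do.call(rbind, out)
  agg <- stats::aggregate(fraction ~ element_class + radius_um, curves, mean)
  agg <- agg[order(agg$element_class, agg$radius_um), ]
  rownames(agg) <- NULL
  list(curves = curves, mean_curve = agg)
}

#' Smallest radius reaching a target covered fraction
#'
#' Scans a tabulated coverage curve (normally the mean curve over grid
#' points) for the smallest radius whose fraction reaches `target`, per
#' class. An unreachable target is reported as `Inf` (unbounded within the
#' tabulated range).
#'
#' @param curve Data frame with `element_class`, `radius_um`, `fraction`.
#' @param target Target fraction in (0, 1]; default 0.5.
#' @return Named numeric vector of radii (um) per class.
#' @export
radius_at_fraction <- function(curve, target = 0.5) {
  stopifnot(target > 0, target <= 1)
  vapply(split(curve, curve$element_class), function(cc) {
    cc <- cc[order(cc$radius_um), ]
    hit <- which(cc$fraction >= target)
    if (length(hit)) cc$radius_um[hit[1]] else Inf
  }, numeric(1))
}
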