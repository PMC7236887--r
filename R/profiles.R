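#' Extract per-slice element profiles from a mask stack
#'
#' One profile is one 8-connected component of one class in one slice. The
#' centroid is the area centroid (first pixel moments) — for the second-moment
#' ellipse this coincides with the intersection of its major and minor axes.
#' Axes are the full axes of the ellipse with the same second central moments
#' as the pixel set (`4 * sqrt(eigenvalue)`, with the `pitch^2 / 12` pixel
#' extent correction so single-pixel profiles get pixel-sized axes). The
#' equivalent diameter is that of the circle with the profile's area,
#' `2 * sqrt(area / pi)`.
#'
#' @param stack A [mask_stack()].
#' @param classes Classes to profile; defaults to artery, nerve, vein (the
#'   elements treated as profiles; cartilage/dermis masks are contextual).
#' @return A data frame with one row per profile: `slice_index`,
#'   `element_class`, `label` (component label within its slice and class),
#'   `pixel_count`, `area_um2`, `centroid_x_um`, `centroid_z_um`,
#'   `major_axis_um`, `minor_axis_um`, `equivalent_diameter_um`,
#'   `touches_border`, plus a list column `hull` holding each profile's own
#'   convex-hull vertices (um, matrix with columns x, z). Attributes
#'   `n_slices` and `geometry` carry the stack context.
#' @export
extract_profiles <- function(stack, classes = c("artery", "nerve", "vein")) {
  stopifnot(is_mask_stack(stack))
  classes <- intersect(classes, names(stack$masks))
  g <- stack$geometry
  px <- g$pixel_pitch_x; pz <- g$pixel_pitch_z
  parea <- px * pz
  out <- list()
  for (s in seq_len(stack$n_slices)) {
    for (cls in classes) {
      m <- stack$masks[[cls]][[s]]
      if (!any(m)) next
      lab <- label_components(m)
      idx <- which(lab > 0L)
      labv <- lab[idx]
      nr <- nrow(lab); ncl <- ncol(lab)
      row <- ((idx - 1L) %% nr) + 1L
      col <- ((idx - 1L) %/% nr) + 1L
      x <- (col - 1) * px
      z <- (row - 1) * pz
      n <- tabulate(labv)
      cx <- rowsum(x, labv)[, 1] / n
      cz <- rowsum(z, labv)[, 1] / n
      # second central moments with pixel-extent correction
      vxx <- rowsum(x * x, labv)[, 1] / n - cx^2 + px^2 / 12
      vzz <- rowsum(z * z, labv)[, 1] / n - cz^2 + pz^2 / 12
      vxz <- rowsum(x * z, labv)[, 1] / n - cx * cz
      tr <- vxx + vzz
      det <- vxx * vzz - vxz^2
      disc <- sqrt(pmax(0, tr^2 / 4 - det))
      l1 <- tr / 2 + disc; l2 <- pmax(0, tr / 2 - disc)
      border <- rowsum(as.numeric(row == 1L | row == nr |
                                  col == 1L | col == ncl), labv)[, 1] > 0
      # profile hulls are built from pixel corners, not centres, so the ROI
      # (hull of these points) always contains the full counted pixel area
      hx <- px / 2; hz <- pz / 2
      hulls <- lapply(split(seq_along(labv), labv), function(ii) {
        pts <- cbind(x = c(x[ii] - hx, x[ii] + hx, x[ii] - hx, x[ii] + hx),
                     z = c(z[ii] - hz, z[ii] - hz, z[ii] + hz, z[ii] + hz))
        pts[grDevices::chull(pts), , drop = FALSE]
      })
      df <- data.frame(
        slice_index = s, element_class = cls, label = seq_along(n),
        pixel_count = n, area_um2 = n * parea,
        centroid_x_um = cx, centroid_z_um = cz,
        major_axis_um = 4 * sqrt(l1), minor_axis_um = 4 * sqrt(l2),
        equivalent_diameter_um = 2 * sqrt(n * parea / pi),
        touches_border = border, row.names = NULL)
      df$hull <- hulls
      out[[length(out) + 1L]] <- df
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(slice_index = integer(), element_class = character(),
               label = integer(), pixel_count = integer(),
               area_um2 = numeric(), centroid_x_um = numeric(),
               centroid_z_um = numeric(), major_axis_um = numeric(),
               minor_axis_um = numeric(),
               equivalent_diameter_um = numeric(),
               touches_border = logical(), hull = I(list()))
  attr(res, "n_slices") <- stack$n_slices
  attr(res, "geometry") <- g
  res
}

#' Remove capillary-scale structures from the artery profiles
#'
#' Artery profiles with equivalent diameter below `min_diameter` are dropped;
#' nerve and vein profiles are untouched (the exclusion is defined for the
#' artery masks only, separating arterioles from capillaries).
#'
#' @param profiles Profile table from [extract_profiles()].
#' @param min_diameter Exclusion threshold, um; default 10. Profiles at
#'   exactly the threshold are retained.
#' @return The filtered profile table (attributes preserved).
#' @export
filter_capillaries <- function(profiles, min_diameter = 10) {
  if (!is.numeric(min_diameter) || min_diameter < 0)
    stop("'min_diameter' must be non-negative")
  keep <- profiles$element_class != "artery" |
    profiles$equivalent_diameter_um >= min_diameter
  res <- profiles[keep, , drop = FALSE]
  attr(res, "n_slices") <- attr(profiles, "n_slices")
  attr(res, "geometry") <- attr(profiles, "geometry")
  res
}

#' Summary statistics: median, quartiles, IQR, mean, SD
#'
#' Quartiles use linear interpolation between closest ranks
#' (`stats::quantile()` type 7); SD is the sample standard deviation (n - 1
#' denominator, 0 for a single value).
#'
#' @param values Numeric vector with at least one finite value.
#' @return A one-row data frame: `n`, `median`, `q25`, `q75`, `iqr`, `mean`,
#'   `sd`.
#' @export
summary_stats <- function(values) {
  values <- values[is.finite(values)]
  if (!length(values)) stop("no finite values to summarise")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  data.frame(n = length(values), median = q[2], q25 = q[1], q75 = q[3],
             iqr = q[3] - q[1], mean = mean(values),
             sd = if (length(values) > 1) stats::sd(values) else 0)
}

#' Per-slice abundance of elements
#'
#' Counts retained profiles per slice per class (slices with no profile of a
#' class count 0), summarises the counts across slices, and tabulates the
#' normalised count histogram (probability of observing a given per-slice
#' count, pooled across all slices).
#'
#' @param profiles Profile table, normally after [filter_capillaries()].
#' @param n_slices Total slice count; taken from the table's attribute when
#'   omitted.
#' @return List with `counts` (slice_index x class long data frame),
#'   `summary` (one [summary_stats()] row per class) and `density` (class,
#'   count, probability; probabilities sum to 1 within each class).
#' @export
abundance <- function(profiles, n_slices = attr(profiles, "n_slices")) {
  if (is.null(n_slices)) stop("'n_slices' is required")
  classes <- sort(unique(profiles$element_class))
  if (!length(classes)) classes <- "artery"
  counts <- expand.grid(slice_index = seq_len(n_slices),
                        element_class = classes,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tab <- table(factor(profiles$slice_index, levels = seq_len(n_slices)),
               factor(profiles$element_class, levels = classes))
  counts$count <- as.vector(tab)
  summ <- do.call(rbind, lapply(classes, function(cls) {
    cbind(element_class = cls,
          summary_stats(counts$count[counts$element_class == cls]))
  }))
  dens <- do.call(rbind, lapply(classes, function(cls) {
    x <- counts$count[counts$element_class == cls]
    t <- table(x)
    data.frame(element_class = cls, count = as.integer(names(t)),
               probability = as.vector(t) / length(x))
  }))
  list(counts = counts, summary = summ, density = dens)
}

#' Convex hull area of a planar point set
#'
#' Utility behind the per-slice region of interest: the area of the convex
#' hull of the given points, zero for degenerate (collinear or < 3 point)
#' sets.
#'
#' @param points Two-column matrix of (x, z) coordinates, um.
#' @return List with `vertices` (hull vertices in order) and `area`.
#' @export
convex_hull_area <- function(points) {
  points <- unique(points[stats::complete.cases(points), , drop = FALSE])
  if (nrow(points) < 3L)
    return(list(vertices = points, area = 0))
  h <- grDevices::chull(points)
  v <- points[h, , drop = FALSE]
  area <- if (nrow(v) < 3L) 0 else abs(pracma::polyarea(v[, 1], v[, 2]))
  list(vertices = v, area = area)
}

#' Per-slice region of interest
#'
#' The ROI of a slice is the convex hull of the pixels of all retained artery
#' and nerve profiles of that slice, after first excluding profiles that touch
#' the raster border (elements at the field edge cannot be verified along the
#' stack and are dropped to reduce false detection). The hull is taken over
#' pixel corners, so every counted pixel lies fully inside the ROI and
#' occupied fractions can never exceed 100%. Fewer than three contributing
#' pixels give a degenerate ROI of zero area; such slices are excluded from
#' occupancy statistics.
#'
#' @param profiles Profile table rows of one slice (after
#'   [filter_capillaries()]).
#' @param classes Classes whose pixels define the hull; default artery and
#'   nerve.
#' @return List: `slice_index`, `vertices` (x, z um), `area_um2`.
#' @export
compute_roi <- function(profiles, classes = c("artery", "nerve")) {
  if (!nrow(profiles))
    return(list(slice_index = NA_integer_,
                vertices = matrix(numeric(), 0, 2), area_um2 = 0))
  stopifnot(length(unique(profiles$slice_index)) == 1L)
  sel <- profiles$element_class %in% classes & !profiles$touches_border
  if (sum(profiles$pixel_count[sel]) < 3L)  # degenerate: under 3 pixels
    return(list(slice_index = profiles$slice_index[1],
                vertices = matrix(numeric(), 0, 2), area_um2 = 0))
  pts <- do.call(rbind, profiles$hull[sel])
  if (is.null(pts))
    return(list(slice_index = profiles$slice_index[1],
                vertices = matrix(numeric(), 0, 2), area_um2 = 0))
  h <- convex_hull_area(pts)
  list(slice_index = profiles$slice_index[1], vertices = h$vertices,
       area_um2 = h$area)
}

#' ROIs for every slice of a profile table
#' @param profiles Profile table (after [filter_capillaries()]).
#' @param n_slices Total slice count; from the attribute when omitted.
#' @inheritParams compute_roi
#' @return List of [compute_roi()] results, one per slice index.
#' @export
compute_rois <- function(profiles, n_slices = attr(profiles, "n_slices"),
                         classes = c("artery", "nerve")) {
  if (is.null(n_slices)) n_slices <- max(profiles$slice_index, 0)
  lapply(seq_len(n_slices), function(s) {
    roi <- compute_roi(profiles[profiles$slice_index == s, , drop = FALSE],
                       classes)
    roi$slice_index <- s
    roi
  })
}

#' ROI-normalised area and volume occupancy
#'
#' Per slice, the occupied fraction of a class is the summed area of its
#' retained, non-border profiles divided by the ROI area (the counted pixels
#' all lie inside the ROI by construction, since the ROI is their convex
#' hull). Slices with a degenerate zero-area ROI are skipped with a message.
#' The volume fraction weights each slice by its spacing, so with the uniform
#' spacing of a stack it equals total class area over total ROI area.
#'
#' @param profiles Profile table after [filter_capillaries()].
#' @param rois Result of [compute_rois()].
#' @param geometry A [voxel_geometry()]; from the profile attribute when
#'   omitted.
#' @param classes Classes to quantify; default artery and nerve (veins are
#'   excluded from numerical occupancy because specimen processing collapses
#'   their thin walls unpredictably).
#' @return List with `slices` — a data frame per slice: `slice_index`,
#'   `roi_area_um2`, `excluded`, then per class `<class>_count`,
#'   `<class>_area_um2`, `<class>_pct` — and `volume_pct`, a named vector of
#'   per-class volume occupancy percentages over the retained slices.
#' @export
occupancy <- function(profiles, rois,
                      geometry = attr(profiles, "geometry"),
                      classes = c("artery", "nerve")) {
  n_slices <- length(rois)
  roi_area <- vapply(rois, function(r) r$area_um2, numeric(1))
  res <- data.frame(slice_index = seq_len(n_slices),
                    roi_area_um2 = roi_area,
                    excluded = roi_area <= 0)
  if (any(res$excluded))
    message(sum(res$excluded),
            " slice(s) with degenerate ROI excluded from occupancy")
  keep <- !profiles$touches_border
  for (cls in classes) {
    sel <- keep & profiles$element_class == cls
    cnt <- tabulate(profiles$slice_index[sel], nbins = n_slices)
    area <- rowsum(c(profiles$area_um2[sel], 0),
                   c(profiles$slice_index[sel], n_slices + 1L))
    area_v <- numeric(n_slices)
    ids <- as.integer(rownames(area))
    ok <- ids <= n_slices
    area_v[ids[ok]] <- area[ok, 1]
    res[[paste0(cls, "_count")]] <- cnt
    res[[paste0(cls, "_area_um2")]] <- area_v
    res[[paste0(cls, "_pct")]] <-
      ifelse(res$excluded, NA_real_, 100 * area_v / roi_area)
  }
  valid <- !res$excluded
  volume_pct <- vapply(classes, function(cls)
    100 * sum(res[[paste0(cls, "_area_um2")]][valid]) /
      sum(res$roi_area_um2[valid]), numeric(1))
  list(slices = res, volume_pct = volume_pct)
}
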