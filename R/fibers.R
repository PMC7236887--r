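#' Area of an ellipse from its full axes
#' @param major_axis,minor_axis Full axis lengths (> 0), any length unit.
#' @return Area, in the squared unit of the axes.
#' @examples
#' ellipse_area(20, 15)  # 235.62 (mm^2 for mm axes)
#' @export
ellipse_area <- function(major_axis, minor_axis) {
  if (!is.numeric(major_axis) || !is.numeric(minor_axis) ||
      any(major_axis <= 0) || any(minor_axis <= 0))
    stop("ellipse axes must be positive")
  pi * (major_axis / 2) * (minor_axis / 2)
}

#' Myelinated fiber model constants
#'
#' Constants for extrapolating vagal fiber counts from the sampled nerve
#' cross-sectional area. A-beta and A-delta fibers have mean diameters 8.5
#' and 3.5 um and make up 20% and 50% of the myelinated auricular vagus
#' axons, so the enforced count ratio is `N_Adelta / N_Abeta =
#' proportion_adelta / proportion_abeta = 2.5`. The cymba and cavity of
#' conchae together are modelled as an ellipse with full axes 20 x 15 mm.
#'
#' @param d_abeta,d_adelta Mean fiber diameters, um.
#' @param proportion_abeta,proportion_adelta Fractions of myelinated axons,
#'   in (0, 1).
#' @param concha_major_mm,concha_minor_mm Full axes of the concha ellipse,
#'   mm.
#' @return List of class `fiber_model`: the inputs plus derived per-fiber
#'   areas `a_abeta_um2`, `a_adelta_um2`, the `ratio`, and the concha area
#'   `a_cc_um2`.
#' @export
fiber_model <- function(d_abeta = 8.5, d_adelta = 3.5,
                        proportion_abeta = 0.20, proportion_adelta = 0.50,
                        concha_major_mm = 20, concha_minor_mm = 15) {
  stopifnot(d_abeta > 0, d_adelta > 0,
            proportion_abeta > 0, proportion_abeta < 1,
            proportion_adelta > 0, proportion_adelta < 1)
  structure(list(
    d_abeta = d_abeta, d_adelta = d_adelta,
    proportion_abeta = proportion_abeta,
    proportion_adelta = proportion_adelta,
    concha_major_mm = concha_major_mm, concha_minor_mm = concha_minor_mm,
    a_abeta_um2 = pi * (d_abeta / 2)^2,
    a_adelta_um2 = pi * (d_adelta / 2)^2,
    ratio = proportion_adelta / proportion_abeta,
    a_cc_um2 = ellipse_area(concha_major_mm, concha_minor_mm) * 1e6
  ), class = "fiber_model")
}

#' Extrapolate sampled nerve area to the whole concha
#'
#' Linear area scaling: the nerve area found in the sample is scaled by the
#' ratio of the concha area to the sample area,
#' `A_AN = (A_CC / A_S) * A_SN`.
#'
#' @param a_cc Concha area, um^2.
#' @param a_s Sample area, um^2 (> 0).
#' @param a_sn Nerve area within the sample, um^2 (`<= a_s`).
#' @return Extrapolated total nerve area `A_AN`, um^2.
#' @export
extrapolate_nerve_area <- function(a_cc, a_s, a_sn) {
  stopifnot(a_cc > 0, a_sn >= 0, a_sn <= a_s)
  if (a_s <= 0) stop("sample area must be positive")
  (a_cc / a_s) * a_sn
}

#' Solve the fiber counts from the total nerve area
#'
#' Solves the two-equation system: the count ratio
#' `N_Adelta = ratio * N_Abeta` and the area closure
#' `A_AN = N_Abeta * A_Abeta + N_Adelta * A_Adelta`, giving
#' `N_Abeta = A_AN / (A_Abeta + ratio * A_Adelta)`. Counts are returned as
#' reals; use [floor()] for integer display.
#'
#' @param a_an Total nerve cross-sectional area, um^2 (>= 0).
#' @param model A [fiber_model()].
#' @return Named numeric `c(n_abeta, n_adelta)`.
#' @export
solve_fiber_counts <- function(a_an, model = fiber_model()) {
  stopifnot(inherits(model, "fiber_model"), a_an >= 0)
  n_abeta <- a_an / (model$a_abeta_um2 + model$ratio * model$a_adelta_um2)
  c(n_abeta = n_abeta, n_adelta = model$ratio * n_abeta)
}

#' Occupancy of a reference fiber population in the nerve area
#'
#' Cross-check against independent axon counts: the percentage of the total
#' nerve cross-sectional area filled by `n_ref` fibers of mean diameter
#' `d_ref`.
#'
#' @param a_an Total nerve cross-sectional area, um^2 (> 0).
#' @param n_ref Reference fiber count; default 370 (reported myelinated
#'   A-beta axons of the auricular vagus).
#' @param d_ref Reference mean fiber diameter, um; default 8.5.
#' @return Occupancy percentage.
#' @export
occupancy_check <- function(a_an, n_ref = 370, d_ref = 8.5) {
  stopifnot(n_ref > 0, d_ref > 0)
  if (a_an <= 0) stop("total nerve area must be positive")
  100 * n_ref * pi * (d_ref / 2)^2 / a_an
}

#' Per-slice fiber estimates
#'
#' Applies the extrapolation and the count solution slice by slice. The
#' sample area `A_S` is per default the slice ROI area (consistent with the
#' nerve area being measured inside the ROI); pass `area_basis = "frame"`
#' with `frame_area_um2` to normalise by the full image frame instead.
#' Slices with zero nerve area yield zero estimates and are included; slices
#' with a degenerate ROI are excluded.
#'
#' @param slice_summary The `slices` data frame from [occupancy()] (needs
#'   `nerve_area_um2`, `roi_area_um2`, `excluded`).
#' @param model A [fiber_model()].
#' @param area_basis `"roi"` (default) or `"frame"`.
#' @param frame_area_um2 Full-frame area, um^2; required for
#'   `area_basis = "frame"`.
#' @return List with `estimates` (slice_index, a_s_um2, a_sn_um2, a_an_um2,
#'   n_abeta, n_adelta, occupancy_370_pct) and `summary` (one
#'   [summary_stats()] row per quantity).
#' @export
estimate_per_slice <- function(slice_summary, model = fiber_model(),
                               area_basis = c("roi", "frame"),
                               frame_area_um2 = NULL) {
  area_basis <- match.arg(area_basis)
  stopifnot(inherits(model, "fiber_model"))
  ss <- slice_summary[!slice_summary$excluded, , drop = FALSE]
  a_s <- if (area_basis == "roi") ss$roi_area_um2 else {
    if (is.null(frame_area_um2) || frame_area_um2 <= 0)
      stop("'frame_area_um2' is required for area_basis = \"frame\"")
    rep(frame_area_um2, nrow(ss))
  }
  a_sn <- ss$nerve_area_um2
  a_an <- ifelse(a_s > 0, (model$a_cc_um2 / a_s) * a_sn, NA_real_)
  denom <- model$a_abeta_um2 + model$ratio * model$a_adelta_um2
  n_abeta <- a_an / denom
  est <- data.frame(slice_index = ss$slice_index, a_s_um2 = a_s,
                    a_sn_um2 = a_sn, a_an_um2 = a_an,
                    n_abeta = n_abeta, n_adelta = model$ratio * n_abeta,
                    occupancy_370_pct = ifelse(a_an > 0,
                      100 * 370 * pi * (8.5 / 2)^2 / a_an, NA_real_))
  summ <- do.call(rbind, lapply(
    c("a_an_um2", "n_abeta", "n_adelta", "occupancy_370_pct"),
    function(v) cbind(quantity = v, summary_stats(est[[v]]))))
  list(estimates = est, summary = summ)
}
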