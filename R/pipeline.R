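#' Pipeline configuration
#'
#' Bundles every stage parameter for [run_pipeline()]. Exactly one input mode
#' is active: `"phantom"` (generate a synthetic stack from `phantom`) or
#' `"mask_dir"` (read a segmented stack from disk). All physical quantities
#' are micrometres (areas um^2).
#'
#' @param mode `"phantom"` or `"mask_dir"`.
#' @param phantom A [phantom_config()] (phantom mode).
#' @param mask_dir Directory for [read_mask_stack()] (mask_dir mode).
#' @param geometry A [voxel_geometry()].
#' @param capillary_min_diameter Artery exclusion threshold, um.
#' @param grid_dx,grid_dy Electrode grid spacings, um.
#' @param coverage_dr Coverage radius step, um.
#' @param coverage_target Coverage fraction whose radius is reported.
#' @param fiber A [fiber_model()].
#' @param area_basis `"roi"` or `"frame"` for the fiber sample area.
#' @param out_dir Output directory for tables and the report.
#' @param write_masks Also write the mask stack under `out_dir/masks`?
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("phantom", "mask_dir"),
                            phantom = phantom_config(),
                            mask_dir = NULL,
                            geometry = voxel_geometry(),
                            capillary_min_diameter = 10,
                            grid_dx = 1000, grid_dy = 500,
                            coverage_dr = 100, coverage_target = 0.5,
                            fiber = fiber_model(),
                            area_basis = c("roi", "frame"),
                            out_dir = NULL,
                            write_masks = FALSE) {
  mode <- match.arg(mode)
  area_basis <- match.arg(area_basis)
  if (mode == "mask_dir" && is.null(mask_dir))
    stop("mask_dir mode requires 'mask_dir'")
  structure(list(mode = mode, phantom = phantom, mask_dir = mask_dir,
                 geometry = geometry,
                 capillary_min_diameter = capillary_min_diameter,
                 grid_dx = grid_dx, grid_dy = grid_dy,
                 coverage_dr = coverage_dr,
                 coverage_target = coverage_target, fiber = fiber,
                 area_basis = area_basis, out_dir = out_dir,
                 write_masks = write_masks),
            class = "pipeline_config")
}

write_table <- function(df, out_dir, name) {
  if (is.null(out_dir)) return(invisible(NULL))
  df <- df[, !vapply(df, is.list, logical(1)), drop = FALSE]
  utils::write.csv(df, file.path(out_dir, paste0(name, ".csv")),
                   row.names = FALSE)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full morphometry pipeline
#'
#' Executes generate/read, profile extraction, capillary filtering,
#' ROI/occupancy, distance statistics, track linking and radial coverage,
#' and fiber estimation, writing one CSV per stage plus a JSON report under
#' `out_dir` when set. Identical configuration (including the phantom seed)
#' produces byte-identical outputs; each stage's CSV is sufficient to resume
#' downstream work. A stage failure aborts with the stage name and cause.
#'
#' @param config A [pipeline_config()].
#' @return (Invisibly) a list with every stage result: `stack`, `truth`,
#'   `profiles`, `filtered`, `abundance`, `rois`, `occupancy`, `distances`,
#'   `tracks`, `coverage`, `target_radius_um`, `fibers`, `report`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  if (!is.null(out) && !dir.exists(out))
    dir.create(out, recursive = TRUE)
  g <- config$geometry

  truth <- NULL
  stk <- stage("input", {
    if (config$mode == "phantom") {
      ph <- generate_phantom(config$phantom, g)
      truth <- ph$truth
      ph$stack
    } else read_mask_stack(config$mask_dir, g)
  })
  if (!is.null(out) && !is.null(truth)) write_table(truth, out, "ground_truth")
  if (!is.null(out) && config$write_masks)
    write_mask_stack(stk, file.path(out, "masks"))

  profiles <- stage("extract_profiles", extract_profiles(stk))
  filtered <- stage("filter_capillaries",
                    filter_capillaries(profiles,
                                       config$capillary_min_diameter))
  write_table(filtered, out, "profiles")

  ab <- stage("abundance", abundance(filtered))
  write_table(ab$counts, out, "abundance_counts")
  write_table(ab$summary, out, "abundance_summary")

  rois <- stage("roi", compute_rois(filtered))
  occ <- stage("occupancy", occupancy(filtered, rois))
  write_table(occ$slices, out, "slice_summary")

  pairs <- stage("distances", pairwise_distances(filtered))
  dists <- if (nrow(pairs)) stage("distances", distance_summaries(pairs))
           else NULL
  write_table(pairs, out, "distances")
  if (!is.null(dists)) write_table(dists$minima, out, "distance_minima")

  tracks <- stage("link_tracks", link_tracks(filtered, stack = stk))
  write_table(tracks, out, "tracks")
  extent <- c(stk$dim[2] * g$pixel_pitch_x,
              stk$n_slices * g$slice_spacing)
  grid <- stage("grid", build_grid(extent, config$grid_dx, config$grid_dy))
  cov <- stage("coverage",
               coverage_curves(tracks, grid, g, dr = config$coverage_dr))
  write_table(cov$curves, out, "coverage")
  write_table(cov$mean_curve, out, "coverage_mean")
  r_target <- radius_at_fraction(cov$mean_curve, config$coverage_target)

  fib <- stage("fiber_estimation",
               estimate_per_slice(occ$slices, config$fiber,
                                  area_basis = config$area_basis,
                                  frame_area_um2 =
                                    stk$dim[2] * g$pixel_pitch_x *
                                    stk$dim[1] * g$pixel_pitch_z))
  write_table(fib$estimates, out, "fiber_estimates")
  write_table(fib$summary, out, "fiber_summary")

  report <- list(
    mode = config$mode,
    seed = if (config$mode == "phantom") config$phantom$seed else NULL,
    geometry = unclass(g),
    n_slices = stk$n_slices,
    raster_dim = stk$dim,
    capillary_min_diameter_um = config$capillary_min_diameter,
    abundance = ab$summary,
    occupancy_volume_pct = as.list(occ$volume_pct),
    occupancy_area_pct = list(
      artery = summary_stats(stats::na.omit(occ$slices$artery_pct)),
      nerve = summary_stats(stats::na.omit(occ$slices$nerve_pct))),
    distances = if (!is.null(dists))
      list(all_pairs = dists$all_pairs,
           per_slice_min = dists$per_slice_min) else NULL,
    coverage_target = config$coverage_target,
    target_radius_um = as.list(r_target),
    fiber_summary = fib$summary)
  if (!is.null(out))
    jsonlite::write_json(report, file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")

  invisible(list(stack = stk, truth = truth, profiles = profiles,
                 filtered = filtered, abundance = ab, rois = rois,
                 occupancy = occ, distances = dists, pairs = pairs,
                 tracks = tracks, coverage = cov,
                 target_radius_um = r_target, fibers = fib,
                 report = report))
}
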