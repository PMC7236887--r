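test_that("straight tubes link into one track per element", {
  one <- generate_phantom(single_tube_config(d = 30, n_slices = 15))
  pr <- filter_capillaries(extract_profiles(one$stack))
  tr <- link_tracks(pr, stack = one$stack)
  expect_equal(length(unique(tr$track_id)), 1L)
  expect_equal(sort(tr$slice_index), 1:15)
  # centroid fallback agrees when footprints are unavailable
  tr2 <- link_tracks(pr)
  expect_equal(length(unique(tr2$track_id)), 1L)
})

test_that("well-separated tubes are never merged and match ground truth", {
  ph <- generate_phantom(small_config(seed = 26))
  pr <- filter_capillaries(extract_profiles(ph$stack))
  tr <- link_tracks(pr, stack = ph$stack)
  tt <- ph$truth
  n_true <- length(unique(tt$element_id[tt$class %in% c("artery", "nerve")]))
  expect_equal(length(unique(tr$track_id)), n_true)
  # bijection: every track spans all slices with one profile per slice
  for (id in unique(tr$track_id)) {
    s <- tr$slice_index[tr$track_id == id]
    expect_equal(sort(s), seq(min(s), max(s)))
  }
  # each track stays on one ground-truth centerline
  for (id in unique(tr$track_id)) {
    t1 <- tr[tr$track_id == id, ]
    dev <- sapply(unique(tt$element_id), function(e) {
      te <- tt[tt$element_id == e, ]
      if (!all(t1$slice_index %in% te$slice_index)) return(Inf)
      m <- match(t1$slice_index, te$slice_index)
      max(sqrt((t1$x_um - te$x_um[m])^2 + (t1$z_um - te$z_um[m])^2))
    })
    expect_lt(min(dev), 1.48)
  }
})

test_that("the electrode grid has the documented lattice structure", {
  g0 <- build_grid(c(3000, 2000), 1000, 500, offset = c(0, 0))
  expect_equal(nrow(g0), 20L)  # 4 x 5 boundary-anchored lattice
  g1 <- build_grid(c(300, 200), 1000, 500)
  expect_equal(nrow(g1), 1L)   # spacing exceeds extent: single centred point
  expect_equal(unlist(g1, use.names = FALSE), c(150, 100))
  set.seed(5)
  for (i in 1:6) {
    ext <- runif(2, 100, 5000)
    g <- build_grid(ext, 700, 400)
    expect_true(all(g$x_um >= 0 & g$x_um <= ext[1]))
    expect_true(all(g$y_um >= 0 & g$y_um <= ext[2]))
    # row-major: x varies fastest
    expect_true(all(diff(which(diff(g$y_um) != 0)) ==
                    length(unique(g$x_um)) |
                    length(unique(g$y_um)) == 1L))
  }
})

make_track <- function(id, cls, x, slices = 1:10) {
  data.frame(track_id = id, element_class = cls, slice_index = slices,
             label = 1L, x_um = x, z_um = 50)
}

test_that("coverage steps quantize distances up to the next radius", {
  g <- voxel_geometry()
  grid <- data.frame(x_um = 1000, y_um = 60)
  tracks <- rbind(make_track(1L, "artery", x = 1000),   # passes through g
                  make_track(2L, "nerve", x = 1550))    # 550 um away
  cv <- coverage_curves(tracks, grid, g, dr = 100)
  a <- cv$curves[cv$curves$element_class == "artery", ]
  expect_equal(a$fraction[a$radius_um == 100], 1)       # first step
  n <- cv$curves[cv$curves$element_class == "nerve", ]
  expect_equal(n$fraction[n$radius_um == 500], 0)
  expect_equal(n$fraction[n$radius_um == 600], 1)       # ceil to step
})

test_that("coverage equals the exhaustive oracle on a small phantom", {
  ph <- generate_phantom(small_config(seed = 37, n_arteries = 6L,
                                      n_nerves = 4L, n_veins = 0L))
  pr <- filter_capillaries(extract_profiles(ph$stack))
  tr <- link_tracks(pr, stack = ph$stack)
  expect_lte(length(unique(tr$track_id)), 20L)
  g <- voxel_geometry()
  grid <- build_grid(c(800, 20 * 15), 400, 150)
  cv <- coverage_curves(tr, grid, g, dr = 100, max_radius = 1200)
  oc <- oracle_coverage(tr, grid, g$slice_spacing, seq(100, 1200, 100))
  merged <- merge(cv$curves, oc,
                  by = c("grid_x_um", "grid_y_um", "element_class",
                         "radius_um"))
  expect_equal(nrow(merged), nrow(cv$curves))
  expect_equal(merged$fraction.x, merged$fraction.y, tolerance = 1e-12)
})

test_that("every coverage curve is monotone and bounded in [0, 1]", {
  ph <- generate_phantom(small_config(seed = 41))
  pr <- filter_capillaries(extract_profiles(ph$stack))
  tr <- link_tracks(pr, stack = ph$stack)
  cv <- coverage_curves(tr, build_grid(c(800, 300), 400, 150),
                        voxel_geometry())
  for (key in split(cv$curves,
                    cv$curves[c("grid_x_um", "grid_y_um",
                                "element_class")])) {
    if (!nrow(key)) next
    f <- key$fraction[order(key$radius_um)]
    expect_true(all(diff(f) >= 0))
    expect_true(all(f >= 0 & f <= 1))
    expect_equal(f[length(f)], 1)  # reaches 1 at the default max radius
  }
  # pooled fraction is the track-count-weighted mean of class fractions
  cl <- cv$curves
  for (r in unique(cl$radius_um)) {
    sub <- cl[cl$radius_um == r & cl$grid_x_um == cl$grid_x_um[1] &
              cl$grid_y_um == cl$grid_y_um[1], ]
    all_row <- sub[sub$element_class == "all", ]
    parts <- sub[sub$element_class != "all", ]
    expect_equal(all_row$fraction,
                 sum(parts$fraction * parts$n_tracks) / sum(parts$n_tracks))
  }
})

test_that("coverage is invariant when tracks and grid translate together", {
  tracks <- rbind(make_track(1L, "artery", x = 300),
                  make_track(2L, "artery", x = 700),
                  make_track(3L, "nerve", x = 500))
  grid <- data.frame(x_um = c(200, 600), y_um = c(40, 90))
  g <- voxel_geometry()
  cv0 <- coverage_curves(tracks, grid, g, dr = 100, max_radius = 900)
  tracks$x_um <- tracks$x_um + 250
  grid$x_um <- grid$x_um + 250
  cv1 <- coverage_curves(tracks, grid, g, dr = 100, max_radius = 900)
  expect_equal(cv1$curves$fraction, cv0$curves$fraction)
})

test_that("the target radius is the smallest tabulated radius at target", {
  curve <- data.frame(element_class = "artery",
                      radius_um = seq(100, 2000, 100),
                      fraction = pmin(1, seq(0.05, 1, 0.05) * 1.0))
  r <- radius_at_fraction(curve, 0.5)
  brute <- min(curve$radius_um[curve$fraction >= 0.5])
  expect_equal(unname(r["artery"]), brute)
  jump <- data.frame(element_class = "nerve", radius_um = c(100, 200),
                     fraction = c(1, 1))
  expect_equal(unname(radius_at_fraction(jump)["nerve"]), 100)
  short <- data.frame(element_class = "vein", radius_um = c(100, 200),
                      fraction = c(0.1, 0.2))
  expect_equal(unname(radius_at_fraction(short)["vein"]), Inf)
})

test_that("scattered straight tubes cover like the disk-area fraction", {
  # uniform axial tubes: expected covered fraction at radius r from a central
  # point approximates the r-disk / field area ratio (x-extent only matters)
  cfg <- phantom_config(n_arteries = 40L, n_nerves = 0L, n_veins = 0L,
                        artery_diameter = dist_spec("fixed", value = 20),
                        field_size = c(4000, 400), n_slices = 3L, seed = 51)
  ph <- generate_phantom(cfg)
  pr <- filter_capillaries(extract_profiles(ph$stack))
  tr <- link_tracks(pr, stack = ph$stack)
  grid <- data.frame(x_um = 2000, y_um = 15)
  cv <- coverage_curves(tr, grid, voxel_geometry(), dr = 500,
                        max_radius = 2000)
  f1000 <- cv$curves$fraction[cv$curves$radius_um == 1000 &
                              cv$curves$element_class == "artery"]
  expect_lt(abs(f1000 - 0.5), 0.2)  # 1000/2000 half-width, sampling error
})
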