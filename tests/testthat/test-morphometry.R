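test_that("an analytic disk yields one profile with the expected metrics", {
  g <- voxel_geometry()
  ctr <- c(60 * 1.48, 45 * 1.48)
  m <- rasterize_element(ctr, 14.8, g, c(100, 120))  # radius 10 px
  stk <- mask_stack(list(artery = list(m)), g)
  pr <- extract_profiles(stk)
  expect_equal(nrow(pr), 1L)
  expect_lt(abs(pr$equivalent_diameter_um - 29.6), 1.48)
  expect_lt(abs(pr$centroid_x_um - ctr[1]), 0.74)
  expect_lt(abs(pr$centroid_z_um - ctr[2]), 0.74)
  expect_lte(pr$minor_axis_um, pr$major_axis_um)
  # near-circular: moment axes close to the diameter
  expect_lt(abs(pr$major_axis_um - 29.6), 3)
  expect_false(pr$touches_border)
})

test_that("profile counts and pixel tallies match a flood-fill oracle", {
  g <- voxel_geometry()
  set.seed(21)
  for (i in 1:4) {
    m <- random_mask(48, 40, p = 0.3)
    stk <- mask_stack(list(nerve = list(m)), g)
    pr <- extract_profiles(stk)
    lab <- oracle_label8(m)
    expect_equal(nrow(pr), max(lab))
    expect_equal(sort(pr$pixel_count),
                 sort(as.integer(table(lab[lab > 0]))))
    expect_equal(sum(pr$area_um2), sum(m) * pixel_area(g))
  }
})

test_that("area and equivalent diameter invert each other exactly", {
  ph <- generate_phantom(small_config(seed = 4))
  pr <- extract_profiles(ph$stack)
  expect_equal(pi * (pr$equivalent_diameter_um / 2)^2, pr$area_um2,
               tolerance = 1e-12)
})

test_that("capillary exclusion is artery-only with a closed threshold", {
  pr <- fake_profiles(fake_profile(class = "artery", d = 9.9, label = 1),
                      fake_profile(class = "artery", d = 10.0, label = 2),
                      fake_profile(class = "nerve", d = 5, label = 3),
                      fake_profile(class = "vein", d = 4, label = 4))
  out <- filter_capillaries(pr)
  expect_false(any(out$element_class == "artery" &
                   out$equivalent_diameter_um < 10))
  expect_true(10.0 %in% out$equivalent_diameter_um[
    out$element_class == "artery"])
  expect_true(all(c("nerve", "vein") %in% out$element_class))
  expect_error(filter_capillaries(pr, -1), "non-negative")
  empty <- pr[0, ]
  expect_equal(nrow(filter_capillaries(empty)), 0L)
})

test_that("raising the exclusion threshold never raises artery counts", {
  ph <- generate_phantom(small_config(seed = 12))
  pr <- extract_profiles(ph$stack)
  prev <- Inf
  for (thr in c(0, 10, 20, 40, 80)) {
    n <- sum(filter_capillaries(pr, thr)$element_class == "artery")
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("summary stats match a sort-based percentile oracle", {
  expect_equal(summary_stats(c(5, 5, 5))[, c("median", "iqr", "sd")],
               data.frame(median = 5, iqr = 0, sd = 0))
  expect_equal(summary_stats(1:4)$median, 2.5)
  set.seed(33)
  for (i in 1:6) {
    x <- rnorm(sample(2:60, 1))
    s <- summary_stats(x)
    expect_equal(s$median, oracle_percentile(x, 0.5))
    expect_equal(s$q25, oracle_percentile(x, 0.25))
    expect_equal(s$q75, oracle_percentile(x, 0.75))
    expect_equal(s$iqr, s$q75 - s$q25)
    expect_equal(s$sd, sd(x))
  }
  expect_error(summary_stats(numeric(0)))
  expect_error(summary_stats(NA_real_))
})

test_that("abundance is constant on a straight-tube phantom and matches truth", {
  ph <- generate_phantom(small_config(seed = 6))
  fl <- filter_capillaries(extract_profiles(ph$stack))
  ab <- abundance(fl)
  sa <- ab$summary[ab$summary$element_class == "artery", ]
  sn <- ab$summary[ab$summary$element_class == "nerve", ]
  expect_equal(sa$median, 5); expect_equal(sa$sd, 0)
  expect_equal(sn$median, 3); expect_equal(sn$sd, 0)
  # per-slice counts equal ground-truth tallies
  tt <- ph$truth
  for (cls in c("artery", "nerve", "vein")) {
    truth_counts <- as.vector(table(tt$slice_index[tt$class == cls]))
    expect_equal(ab$counts$count[ab$counts$element_class == cls],
                 truth_counts)
  }
  # densities normalise to 1 within class
  agg <- tapply(ab$density$probability, ab$density$element_class, sum)
  expect_equal(as.numeric(agg), rep(1, length(agg)))
})

test_that("convex hull area agrees with a monotone-chain oracle", {
  set.seed(8)
  for (i in 1:8) {
    n <- sample(3:40, 1)
    pts <- cbind(runif(n, 0, 100), runif(n, 0, 100))
    expect_equal(convex_hull_area(pts)$area, oracle_hull_area(pts),
                 tolerance = 1e-9)
  }
  # degenerate: collinear points have zero hull area
  expect_equal(convex_hull_area(cbind(1:5, 2 * (1:5)))$area, 0)
})

test_that("the slice ROI contains its profiles and respects exclusions", {
  g <- voxel_geometry()
  m <- rasterize_element(c(40, 40), 10, g, c(80, 80)) |
       rasterize_element(c(90, 90), 8, g, c(80, 80))
  stk <- mask_stack(list(artery = list(m)), g)
  pr <- extract_profiles(stk)
  roi <- compute_roi(pr)
  expect_gte(roi$area_um2, sum(pr$area_um2[1]))       # hull superset
  expect_gte(roi$area_um2, max(pr$area_um2))
  # hull spans both centroids
  expect_true(min(roi$vertices[, 1]) <= min(pr$centroid_x_um) &&
              max(roi$vertices[, 1]) >= max(pr$centroid_x_um))
  # border-touching profiles are excluded before the hull is taken
  mb <- rasterize_element(c(0, 0), 6, g, c(80, 80))
  stk2 <- mask_stack(list(artery = list(m | mb)), g)
  pr2 <- extract_profiles(stk2)
  expect_true(any(pr2$touches_border))
  expect_equal(compute_roi(pr2)$area_um2, roi$area_um2)
})

test_that("occupancy fractions hit the analytic extremes", {
  g <- voxel_geometry()
  m <- matrix(FALSE, 40, 40); m[10:30, 8:28] <- TRUE  # filled rectangle
  stk <- mask_stack(list(artery = list(m), nerve = list(matrix(FALSE, 40, 40))), g)
  pr <- filter_capillaries(extract_profiles(stk))
  occ <- occupancy(pr, compute_rois(pr))
  expect_equal(occ$slices$artery_pct, 100)   # pixels exactly fill their hull
  expect_equal(occ$slices$nerve_pct, 0)
  expect_true(all(occ$slices$artery_pct + occ$slices$nerve_pct <= 100 + 1e-9))
})

test_that("volume fraction is the mean slice fraction under equal ROIs", {
  ph <- generate_phantom(small_config(seed = 13))
  fl <- filter_capillaries(extract_profiles(ph$stack))
  occ <- occupancy(fl, compute_rois(fl))
  sl <- occ$slices[!occ$slices$excluded, ]
  # straight tubes: identical slices, so ROI areas are equal across slices
  expect_true(diff(range(sl$roi_area_um2)) < 1e-6)
  expect_equal(unname(occ$volume_pct["artery"]), mean(sl$artery_pct))
  expect_equal(unname(occ$volume_pct["nerve"]), mean(sl$nerve_pct))
})

test_that("occupancy is invariant under translation of all masks", {
  g <- voxel_geometry()
  m <- rasterize_element(c(30, 30), 8, g, c(60, 60)) |
       rasterize_element(c(60, 45), 6, g, c(60, 60))
  shift <- function(mm, dr, dc) {
    out <- matrix(FALSE, nrow(mm), ncol(mm))
    out[(1 + dr):nrow(mm), (1 + dc):ncol(mm)] <-
      mm[1:(nrow(mm) - dr), 1:(ncol(mm) - dc)]
    out
  }
  pct_of <- function(mm) {
    pr <- filter_capillaries(extract_profiles(
      mask_stack(list(artery = list(mm)), g)))
    occupancy(pr, compute_rois(pr))$slices$artery_pct
  }
  expect_equal(pct_of(shift(m, 7, 5)), pct_of(m), tolerance = 1e-9)
})
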