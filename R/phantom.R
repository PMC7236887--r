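#' Distribution specification for phantom parameters
#'
#' Small helper constructing the distribution specs used by
#' [phantom_config()]. Three families are supported:
#' * `"lognormal"` — parameterised by the physical `median` (um) and `sdlog`
#'   (log-scale SD), optionally truncated below at `min` (resampled);
#' * `"uniform"` — on `[min, max]`;
#' * `"fixed"` — a degenerate point mass at `value`, for controlled phantoms.
#'
#' @param family One of `"lognormal"`, `"uniform"`, `"fixed"`.
#' @param median,sdlog,min,max,value Family parameters, um.
#' @return A list of class `dist_spec`.
#' @export
dist_spec <- function(family = c("lognormal", "uniform", "fixed"),
                      median = NULL, sdlog = NULL, min = 0, max = NULL,
                      value = NULL) {
  family <- match.arg(family)
  spec <- switch(family,
    lognormal = {
      stopifnot(is.numeric(median), median > 0, is.numeric(sdlog), sdlog >= 0)
      list(family = family, median = median, sdlog = sdlog, min = min)
    },
    uniform = {
      stopifnot(is.numeric(min), is.numeric(max), max >= min, min >= 0)
      list(family = family, min = min, max = max)
    },
    fixed = {
      stopifnot(is.numeric(value), value > 0)
      list(family = family, value = value)
    })
  structure(spec, class = "dist_spec")
}

dist_median <- function(spec) {
  switch(spec$family,
         lognormal = spec$median,
         uniform = (spec$min + spec$max) / 2,
         fixed = spec$value)
}

dist_support <- function(spec) {
  switch(spec$family,
         lognormal = c(spec$min, Inf),
         uniform = c(spec$min, spec$max),
         fixed = c(spec$value, spec$value))
}

sample_dist <- function(spec, n) {
  switch(spec$family,
    lognormal = {
      x <- stats::rlnorm(n, meanlog = log(spec$median), sdlog = spec$sdlog)
      while (any(bad <- x < spec$min))
        x[bad] <- stats::rlnorm(sum(bad), log(spec$median), spec$sdlog)
      x
    },
    uniform = stats::runif(n, spec$min, spec$max),
    fixed = rep(spec$value, n))
}

#' Phantom configuration
#'
#' Defaults emulate the analysed cymba conchae sample: 22 arteries and 15
#' nerves (plus a handful of collapsed veins) as straight axial tubes in a
#' 1024 x 768 px field (1515.52 x 1136.64 um at 1.48 um pitch) over 200
#' slices 15 um apart. Artery diameters are lognormal with median 41 um and
#' log-SD 0.64 (matching the reported 30-71 um interquartile range),
#' truncated at 12 um so the phantom contains no structures near the 10 um
#' capillary-exclusion threshold; nerve diameters are lognormal median 28 um,
#' log-SD 0.50 (20-39 um IQR), floor 5 um. Each of the first
#' `min(n_nerves, n_arteries)` nerves runs parallel to its companion artery at
#' a centre-to-centre offset drawn uniformly from 217-274 um, the reported
#' range of minimum nerve-artery inter-centroid distances.
#'
#' @param n_arteries,n_nerves,n_veins Element counts (>= 0).
#' @param artery_diameter,nerve_diameter,vein_diameter [dist_spec()]s for
#'   equivalent diameters, um. Veins are drawn as collapsed ellipses of the
#'   same cross-sectional area.
#' @param parallel_offset [dist_spec()] for the companion nerve-artery
#'   centreline offset, um. Its median must exceed the mean of the artery and
#'   nerve median radii so tubes do not systematically overlap.
#' @param branching_probability Per-artery probability of a single
#'   bifurcation at a uniform-random slice. Default 0 (straight tubes).
#' @param tortuosity Amplitude (um) of a low-frequency sinusoidal lateral
#'   wander of each centreline. Default 0.
#' @param field_size `c(x, z)` field extent in um.
#' @param n_slices Number of slices.
#' @param vein_axis_ratio Major:minor ratio of collapsed vein ellipses
#'   (>= 4 mimics thin-walled vein collapse).
#' @param seed Integer RNG seed; identical config + seed gives bit-identical
#'   output.
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(n_arteries = 22L, n_nerves = 15L, n_veins = 8L,
                           artery_diameter = dist_spec("lognormal",
                             median = 41, sdlog = 0.64, min = 12),
                           nerve_diameter = dist_spec("lognormal",
                             median = 28, sdlog = 0.50, min = 5),
                           vein_diameter = dist_spec("lognormal",
                             median = 40, sdlog = 0.50, min = 10),
                           parallel_offset = dist_spec("uniform",
                             min = 217, max = 274),
                           branching_probability = 0,
                           tortuosity = 0,
                           field_size = c(x = 1515.52, z = 1136.64),
                           n_slices = 200L,
                           vein_axis_ratio = 4,
                           seed = 1L) {
  stopifnot(n_arteries >= 0, n_nerves >= 0, n_veins >= 0,
            all(field_size > 0), length(field_size) == 2, n_slices >= 1,
            branching_probability >= 0, branching_probability <= 1,
            tortuosity >= 0, vein_axis_ratio >= 1)
  if (dist_median(parallel_offset) <=
      (dist_median(artery_diameter) + dist_median(nerve_diameter)) / 2)
    stop("parallel_offset median must exceed the mean artery/nerve radius ",
         "so companion tubes do not systematically overlap")
  structure(list(
    n_arteries = as.integer(n_arteries), n_nerves = as.integer(n_nerves),
    n_veins = as.integer(n_veins),
    artery_diameter = artery_diameter, nerve_diameter = nerve_diameter,
    vein_diameter = vein_diameter, parallel_offset = parallel_offset,
    branching_probability = branching_probability, tortuosity = tortuosity,
    field_size = unname(field_size), n_slices = as.integer(n_slices),
    vein_axis_ratio = vein_axis_ratio, seed = as.integer(seed)
  ), class = "phantom_config")
}

# linear pixel indices of a filled (rotated) ellipse; a >= b semi-axes (um),
# theta radians; pixels counted when their centres fall inside
ellipse_pixels <- function(cx, cz, a, b, theta, geometry, dim) {
  nr <- dim[1]; nc <- dim[2]
  px <- geometry$pixel_pitch_x; pz <- geometry$pixel_pitch_z
  # element centred outside the field does not rasterize
  if (cx < 0 || cz < 0 || cx > (nc - 1) * px || cz > (nr - 1) * pz)
    return(integer(0))
  r <- max(a, b)
  c0 <- max(1L, floor((cx - r) / px) + 1L)
  c1 <- min(nc, ceiling((cx + r) / px) + 1L)
  r0 <- max(1L, floor((cz - r) / pz) + 1L)
  r1 <- min(nr, ceiling((cz + r) / pz) + 1L)
  if (c0 > c1 || r0 > r1) return(integer(0))
  cols <- c0:c1; rows <- r0:r1
  dx <- (cols - 1) * px - cx
  dz <- (rows - 1) * pz - cz
  DX <- matrix(dx, length(rows), length(cols), byrow = TRUE)
  DZ <- matrix(dz, length(rows), length(cols))
  u <- DX * cos(theta) + DZ * sin(theta)
  v <- -DX * sin(theta) + DZ * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  if (!any(inside)) return(integer(0))
  sub <- which(inside, arr.ind = TRUE)
  (cols[sub[, 2]] - 1L) * nr + rows[sub[, 1]]
}

disk_pixels <- function(cx, cz, radius, geometry, dim) {
  px <- geometry$pixel_pitch_x; pz <- geometry$pixel_pitch_z
  if (radius < min(px, pz) / 2) {
    warning("radius ", signif(radius, 3),
            " um is below half a pixel pitch; marking a single pixel")
    nr <- dim[1]; nc <- dim[2]
    if (cx < 0 || cz < 0 || cx > (nc - 1) * px || cz > (nr - 1) * pz)
      return(integer(0))
    col <- round(cx / px) + 1L; row <- round(cz / pz) + 1L
    return((col - 1L) * nr + row)
  }
  ellipse_pixels(cx, cz, radius, radius, 0, geometry, dim)
}

#' Rasterize one circular element cross-section
#'
#' The pixel set is every pixel whose centre lies within `radius` of the
#' point. A radius below half a pixel pitch marks a single pixel with a
#' warning; a centre outside the field yields an empty mask.
#'
#' @param centre `c(x, z)` in um.
#' @param radius Radius in um (> 0).
#' @param geometry A [voxel_geometry()].
#' @param dim `c(rows, cols)` of the slice raster.
#' @return Logical matrix of dimension `dim`.
#' @export
rasterize_element <- function(centre, radius, geometry, dim) {
  stopifnot(length(centre) == 2, radius > 0, is_voxel_geometry(geometry))
  dim <- as.integer(dim)
  m <- matrix(FALSE, dim[1], dim[2])
  m[disk_pixels(centre[1], centre[2], radius, geometry, dim)] <- TRUE
  m
}

# per-element sinusoidal wander; returns n_slices x 2 matrix of (x, z)
wander_path <- function(x0, z0, amp, n_slices, cycles, phase_x, phase_z) {
  if (amp == 0 || n_slices == 1L)
    return(cbind(x = rep(x0, n_slices), z = rep(z0, n_slices)))
  t <- (seq_len(n_slices) - 1) / (n_slices - 1)
  cbind(x = x0 + amp * sin(2 * pi * cycles * t + phase_x),
        z = z0 + amp * sin(2 * pi * cycles * t + phase_z))
}

#' Generate a synthetic artery/nerve/vein phantom
#'
#' Places tubes by rejection sampling (100 retries per element, then an
#' explicit packing failure naming the class), rasterizes them into per-slice
#' binary masks, and emits exact per-slice ground truth. Arteries and
#' independent nerves are straight axial tubes (optionally with a shared
#' low-frequency lateral wander); companion nerves follow their artery's
#' centreline at a fixed offset vector (parallel wiring); veins are collapsed
#' high-eccentricity ellipses. With `branching_probability > 0` an artery may
#' bifurcate once at a uniform-random interior slice, the child taking
#' radius `2^(-1/3)` of the parent (Murray's law) and drifting away
#' laterally; a child is truncated before it would collide with another
#' element.
#'
#' @param config A [phantom_config()].
#' @param geometry A [voxel_geometry()].
#' @return A list with `stack` (a [mask_stack()] with artery/nerve/vein
#'   classes) and `truth`, a data frame with one row per element per slice:
#'   `element_id`, `class`, `slice_index` (1-based), `x_um`, `z_um`,
#'   `radius_um` (equivalent radius), `parent_id` (NA unless a branch child),
#'   and for veins the ellipse semi-axes `a_um`, `b_um` and angle
#'   `theta_rad`.
#' @export
generate_phantom <- function(config = phantom_config(),
                             geometry = voxel_geometry()) {
  stopifnot(inherits(config, "phantom_config"), is_voxel_geometry(geometry))
  set.seed(config$seed)
  px <- geometry$pixel_pitch_x; pz <- geometry$pixel_pitch_z
  nc <- max(1L, round(config$field_size[1] / px))
  nr <- max(1L, round(config$field_size[2] / pz))
  fx <- (nc - 1) * px; fz <- (nr - 1) * pz  # span of pixel centres
  ns <- config$n_slices
  margin <- 2  # um clearance between tube surfaces

  elements <- list()   # each: id, class, path (ns x 2), radius, a, b, theta,
                       #       bound (packing radius), parent, s0, s1
  add_ok <- function(cand) {
    for (e in elements) {
      s <- max(cand$s0, e$s0):min(cand$s1, e$s1)
      if (!length(s)) next
      d2 <- (cand$path[s, 1] - e$path[s, 1])^2 +
            (cand$path[s, 2] - e$path[s, 2])^2
      if (min(d2) < (cand$bound + e$bound + margin)^2) return(FALSE)
    }
    TRUE
  }
  place_tube <- function(class, diameter_spec, companion = NULL) {
    for (try in 1:100) {
      d <- sample_dist(diameter_spec, 1L)
      r <- d / 2
      amp <- config$tortuosity
      pad <- r + amp + 2 * max(px, pz)
      if (2 * pad >= min(fx, fz))
        stop("infeasible packing: class '", class,
             "' tube diameter exceeds the field")
      if (is.null(companion)) {
        x0 <- stats::runif(1, pad, fx - pad)
        z0 <- stats::runif(1, pad, fz - pad)
        cyc <- stats::runif(1, 0.5, 1.5)
        phx <- stats::runif(1, 0, 2 * pi); phz <- stats::runif(1, 0, 2 * pi)
        path <- wander_path(x0, z0, amp, ns, cyc, phx, phz)
      } else {
        off <- sample_dist(config$parallel_offset, 1L)
        ang <- stats::runif(1, 0, 2 * pi)
        path <- companion$path +
          matrix(c(off * cos(ang), off * sin(ang)), ns, 2, byrow = TRUE)
        if (any(path[, 1] < pad | path[, 1] > fx - pad |
                path[, 2] < pad | path[, 2] > fz - pad)) next
      }
      cand <- list(class = class, path = path, radius = r,
                   a = r, b = r, theta = 0, bound = r,
                   parent = NA_integer_, s0 = 1L, s1 = ns)
      if (add_ok(cand)) return(cand)
    }
    stop("infeasible packing: could not place a '", class,
         "' tube without overlap after 100 retries")
  }

  if (config$n_arteries > 0)
    for (i in seq_len(config$n_arteries))
      elements[[length(elements) + 1L]] <-
        place_tube("artery", config$artery_diameter)
  artery_idx <- which(vapply(elements, function(e) e$class, "") == "artery")
  if (config$n_nerves > 0)
    for (i in seq_len(config$n_nerves)) {
      comp <- if (i <= length(artery_idx)) elements[[artery_idx[i]]] else NULL
      elements[[length(elements) + 1L]] <-
        place_tube("nerve", config$nerve_diameter, companion = comp)
    }
  if (config$n_veins > 0)
    for (i in seq_len(config$n_veins)) {
      placed <- FALSE
      for (try in 1:100) {
        d <- sample_dist(config$vein_diameter, 1L)
        ratio <- config$vein_axis_ratio
        a <- d / 2 * sqrt(ratio); b <- d / 2 / sqrt(ratio)  # area-preserving
        theta <- stats::runif(1, 0, pi)
        amp <- config$tortuosity
        pad <- a + amp + 2 * max(px, pz)
        x0 <- stats::runif(1, pad, fx - pad)
        z0 <- stats::runif(1, pad, fz - pad)
        cyc <- stats::runif(1, 0.5, 1.5)
        phx <- stats::runif(1, 0, 2 * pi); phz <- stats::runif(1, 0, 2 * pi)
        cand <- list(class = "vein",
                     path = wander_path(x0, z0, amp, ns, cyc, phx, phz),
                     radius = d / 2, a = a, b = b, theta = theta, bound = a,
                     parent = NA_integer_, s0 = 1L, s1 = ns)
        if (add_ok(cand)) { elements[[length(elements) + 1L]] <- cand
                            placed <- TRUE; break }
      }
      if (!placed)
        stop("infeasible packing: could not place a 'vein' ellipse ",
             "without overlap after 100 retries")
    }

  # single bifurcation per artery with the configured probability
  if (config$branching_probability > 0 && ns >= 4L)
    for (i in artery_idx) {
      if (stats::runif(1) >= config$branching_probability) next
      parent <- elements[[i]]
      sb <- sample(seq(max(2L, round(ns * 0.25)), round(ns * 0.75)), 1L)
      ang <- stats::runif(1, 0, 2 * pi)
      drift <- 3  # um per slice of lateral divergence
      s <- sb:ns
      path <- matrix(NA_real_, ns, 2)
      path[s, 1] <- parent$path[s, 1] + drift * (s - sb) * cos(ang)
      path[s, 2] <- parent$path[s, 2] + drift * (s - sb) * sin(ang)
      r <- parent$radius * 2^(-1 / 3)
      # truncate before leaving the field or colliding with a non-parent
      s1 <- ns
      for (si in s) {
        hit <- path[si, 1] < r | path[si, 1] > fx - r |
               path[si, 2] < r | path[si, 2] > fz - r
        if (!hit) for (j in seq_along(elements)) {
          if (j == i) next
          e <- elements[[j]]
          if (si < e$s0 || si > e$s1) next
          if ((path[si, 1] - e$path[si, 1])^2 +
              (path[si, 2] - e$path[si, 2])^2 <
              (r + e$bound + margin)^2) { hit <- TRUE; break }
        }
        if (hit) { s1 <- si - 1L; break }
      }
      if (s1 > sb)
        elements[[length(elements) + 1L]] <-
          list(class = "artery", path = path, radius = r, a = r, b = r,
               theta = 0, bound = r, parent = i, s0 = sb, s1 = s1)
    }

  # rasterize
  dim <- c(nr, nc)
  classes <- c("artery", "nerve", "vein")
  masks <- stats::setNames(lapply(classes, function(cls)
    lapply(seq_len(ns), function(s) matrix(FALSE, nr, nc))), classes)
  for (idx in seq_along(elements)) {
    e <- elements[[idx]]
    for (s in e$s0:e$s1) {
      pix <- if (e$class == "vein")
        ellipse_pixels(e$path[s, 1], e$path[s, 2], e$a, e$b, e$theta,
                       geometry, dim)
      else
        disk_pixels(e$path[s, 1], e$path[s, 2], e$radius, geometry, dim)
      masks[[e$class]][[s]][pix] <- TRUE
    }
  }
  for (s in seq_len(ns)) {
    ov <- (masks$artery[[s]] & masks$nerve[[s]]) |
          (masks$artery[[s]] & masks$vein[[s]]) |
          (masks$nerve[[s]] & masks$vein[[s]])
    if (any(ov))
      stop("internal error: class masks overlap in slice ", s)
  }

  truth <- do.call(rbind, lapply(seq_along(elements), function(idx) {
    e <- elements[[idx]]
    s <- e$s0:e$s1
    data.frame(element_id = idx, class = e$class, slice_index = s,
               x_um = e$path[s, 1], z_um = e$path[s, 2],
               radius_um = e$radius, parent_id = e$parent,
               a_um = e$a, b_um = e$b, theta_rad = e$theta)
  }))
  list(stack = mask_stack(masks, geometry), truth = truth)
}
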