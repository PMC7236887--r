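# Small controlled phantoms shared across test files.

small_config <- function(seed = 3, ...) {
  args <- list(n_arteries = 5L, n_nerves = 3L, n_veins = 2L,
               field_size = c(800, 600), n_slices = 20L, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(phantom_config, args)
}

# one straight axial artery of exact diameter `d` um
single_tube_config <- function(d = 40, seed = 1, n_slices = 10L,
                               field = c(300, 300)) {
  phantom_config(n_arteries = 1L, n_nerves = 0L, n_veins = 0L,
                 artery_diameter = dist_spec("fixed", value = d),
                 field_size = field, n_slices = n_slices, seed = seed)
}

# synthetic profile table row without going through a mask
fake_profile <- function(slice = 1L, class = "artery", d = 20,
                         x = 100, z = 100, label = 1L, border = FALSE) {
  area <- pi * (d / 2)^2
  df <- data.frame(slice_index = slice, element_class = class,
                   label = label, pixel_count = max(1L, round(area / 2.19)),
                   area_um2 = area, centroid_x_um = x, centroid_z_um = z,
                   major_axis_um = d, minor_axis_um = d,
                   equivalent_diameter_um = d, touches_border = border)
  df$hull <- list(cbind(x = x + c(-d, d, d, -d) / 2,
                        z = z + c(-d, -d, d, d) / 2))
  df
}

fake_profiles <- function(...) {
  df <- do.call(rbind, list(...))
  attr(df, "n_slices") <- max(df$slice_index)
  attr(df, "geometry") <- voxel_geometry()
  df
}
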