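MASK_CLASSES <- c("artery", "nerve", "vein", "cartilage", "dermis")

#' Construct a multi-class mask stack
#'
#' A mask stack holds one ordered list of binary rasters per element class,
#' together with the physical [voxel_geometry()]. All rasters must share one
#' (rows, cols) shape and all classes one slice count; slice `i` lies at
#' `y = (i - 1) * slice_spacing` um.
#'
#' @param masks Named list; names from `artery`, `nerve`, `vein`, `cartilage`,
#'   `dermis`; each element a list of logical matrices (one per slice).
#' @param geometry A [voxel_geometry()].
#' @return Object of class `mask_stack` with fields `masks`, `geometry`,
#'   `n_slices`, `dim` (rows, cols).
#' @export
mask_stack <- function(masks, geometry = voxel_geometry()) {
  stopifnot(is.list(masks), length(masks) >= 1, is_voxel_geometry(geometry))
  cls <- names(masks)
  if (is.null(cls) || any(!nzchar(cls)))
    stop("'masks' must be a named list of classes")
  unknown <- setdiff(cls, MASK_CLASSES)
  if (length(unknown))
    stop("unknown mask class(es): ", paste(unknown, collapse = ", "),
         " (expected among: ", paste(MASK_CLASSES, collapse = ", "), ")")
  counts <- vapply(masks, length, integer(1))
  if (length(unique(counts)) != 1L)
    stop("mismatched slice counts across classes: ",
         paste(sprintf("%s=%d", cls, counts), collapse = ", "))
  n_slices <- counts[[1]]
  if (n_slices < 1L) stop("mask stack must contain at least one slice")
  dims <- unique(do.call(rbind, lapply(masks, function(s)
    t(vapply(s, dim, integer(2))))))
  if (nrow(dims) != 1L)
    stop("mismatched raster shapes within stack: ",
         paste(apply(dims, 1, paste, collapse = "x"), collapse = " vs "))
  masks <- lapply(masks, function(s) lapply(s, function(m) {
    stopifnot(is.matrix(m))
    m != 0
  }))
  structure(list(masks = masks, geometry = geometry,
                 n_slices = n_slices, dim = as.integer(dims[1, ])),
            class = "mask_stack")
}

is_mask_stack <- function(x) inherits(x, "mask_stack")

#' @export
print.mask_stack <- function(x, ...) {
  cat(sprintf("mask_stack: %d slices of %dx%d px, classes: %s\n",
              x$n_slices, x$dim[1], x$dim[2],
              paste(names(x$masks), collapse = ", ")))
  print(x$geometry)
  invisible(x)
}

#' Write a mask stack to disk
#'
#' Writes one lossless file set per class — a multi-page TIFF
#' (`<class>.tif`, 8-bit, one page per slice) or a numbered PNG series
#' (`<class>_<slice:04d>.png`) — plus a `geometry.yaml` sidecar holding the
#' [voxel_geometry()] fields. Empty rasters are written as zero pages, never
#' omitted, so slice counts always round-trip.
#'
#' @param stack A [mask_stack()].
#' @param path Output directory; created if missing.
#' @param format `"tiff"` (default) or `"png"`.
#' @return `path`, invisibly.
#' @seealso [read_mask_stack()]
#' @export
write_mask_stack <- function(stack, path, format = c("tiff", "png")) {
  stopifnot(is_mask_stack(stack))
  format <- match.arg(format)
  if (!dir.exists(path) && !dir.create(path, recursive = TRUE))
    stop("cannot create output directory: ", path)
  for (cls in names(stack$masks)) {
    pages <- lapply(stack$masks[[cls]], function(m) {
      storage.mode(m) <- "double"
      m
    })
    if (format == "tiff") {
      tiff::writeTIFF(pages, file.path(path, paste0(cls, ".tif")),
                      bits.per.sample = 8L, compression = "LZW")
    } else {
      for (i in seq_along(pages))
        png::writePNG(pages[[i]],
                      file.path(path, sprintf("%s_%04d.png", cls, i - 1L)))
    }
  }
  g <- stack$geometry
  yaml::write_yaml(list(
    pixel_pitch_x = g$pixel_pitch_x,
    pixel_pitch_z = g$pixel_pitch_z,
    section_thickness = g$section_thickness,
    subsampling_factor = g$subsampling_factor
  ), file.path(path, "geometry.yaml"))
  invisible(path)
}

#' Read a mask stack from disk
#'
#' Reads the per-class multi-page TIFFs or numbered PNG series written by
#' [write_mask_stack()] (or prepared externally under the same naming scheme).
#' Any nonzero pixel becomes `TRUE`; thresholding of grayscale masks is the
#' caller's concern. Class file sets with differing slice counts or raster
#' shapes are rejected.
#'
#' @param path Directory containing `<class>.tif` files and/or
#'   `<class>_<slice:04d>.png` series, optionally with a `geometry.yaml`
#'   sidecar.
#' @param geometry A [voxel_geometry()]; if `NULL`, read from the sidecar.
#' @return A [mask_stack()].
#' @export
read_mask_stack <- function(path, geometry = NULL) {
  if (!dir.exists(path)) stop("no such directory: ", path)
  if (is.null(geometry)) {
    side <- file.path(path, "geometry.yaml")
    if (!file.exists(side))
      stop("no 'geometry.yaml' sidecar in ", path,
           " and no geometry supplied")
    gy <- yaml::read_yaml(side)
    geometry <- voxel_geometry(gy$pixel_pitch_x, gy$pixel_pitch_z,
                               gy$section_thickness, gy$subsampling_factor)
  }
  tifs <- list.files(path, pattern = "\\.tif{1,2}$", full.names = TRUE)
  pngs <- list.files(path, pattern = "^[a-z]+_[0-9]{4}\\.png$",
                     full.names = TRUE)
  masks <- list()
  for (f in tifs) {
    cls <- sub("\\.tif{1,2}$", "", basename(f))
    if (!cls %in% MASK_CLASSES)
      stop("unknown class name in file: ", basename(f))
    pages <- tiff::readTIFF(f, all = TRUE)
    if (is.matrix(pages)) pages <- list(pages)
    masks[[cls]] <- lapply(pages, function(m) {
      if (length(dim(m)) == 3L) m <- m[, , 1L]  # tolerate RGB-encoded masks
      m != 0
    })
  }
  if (length(pngs)) {
    cls_of <- sub("_[0-9]{4}\\.png$", "", basename(pngs))
    for (cls in unique(cls_of)) {
      if (!cls %in% MASK_CLASSES)
        stop("unknown class name in PNG series: ", cls)
      files <- sort(pngs[cls_of == cls])
      masks[[cls]] <- lapply(files, function(f) {
        m <- png::readPNG(f)
        if (length(dim(m)) == 3L) m <- m[, , 1L]
        m != 0
      })
    }
  }
  if (!length(masks)) stop("no mask files found in ", path)
  mask_stack(masks, geometry)
}
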