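#' CT image container
#'
#' An `image_grid` holds a 2D matrix (or 3D array, slices along the third
#' dimension) of CT numbers in Hounsfield units together with the in-plane
#' pixel spacing and the slice thickness. The coordinate convention is
#' image origin at the grid centre, millimetre units, x to the right
#' (columns), y downward (rows).
#'
#' @param pixels numeric matrix or 3D array of CT numbers (HU).
#' @param pixel_spacing in-plane pixel pitch in mm (isotropic).
#' @param slice_thickness slice thickness in mm.
#' @param origin length-2 numeric, mm offset of the grid centre (x, y).
#' @return An object of class `image_grid`.
#' @examples
#' img <- image_grid(matrix(0, 64, 64), pixel_spacing = 0.5)
#' dim(img$pixels)
#' @export
image_grid <- function(pixels, pixel_spacing, slice_thickness = 0.5,
                       origin = c(0, 0)) {
  if (!is.numeric(pixels) || !(length(dim(pixels)) %in% c(2L, 3L)))
    stop("`pixels` must be a numeric matrix or 3D array")
  if (!all(is.finite(pixels)))
    stop("`pixels` must contain finite values only")
  if (!is.numeric(pixel_spacing) || length(pixel_spacing) != 1L ||
      pixel_spacing <= 0)
    stop("`pixel_spacing` must be a single positive number (mm)")
  if (slice_thickness <= 0)
    stop("`slice_thickness` must be positive (mm)")
  structure(
    list(pixels = pixels, pixel_spacing = pixel_spacing,
         slice_thickness = slice_thickness, origin = as.numeric(origin)),
    class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<image_grid> %s px @ %.4g mm, slice %.3g mm, HU range [%.1f, %.1f]\n",
              paste(d, collapse = " x "), x$pixel_spacing,
              x$slice_thickness, min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Grid geometry descriptor
#'
#' Describes the raster a phantom is rendered on: a square matrix of `n`
#' pixels per side. Spacing defaults to the reconstruction field of view
#' divided by the matrix size.
#'
#' @param n matrix size (pixels per side).
#' @param pixel_spacing pixel pitch in mm; if `NULL`, derived as `fov_mm / n`.
#' @param fov_mm reconstruction field of view in mm (used when
#'   `pixel_spacing` is `NULL`; default 350 mm).
#' @param slice_thickness slice thickness in mm.
#' @return A list of class `grid_geometry`.
#' @export
grid_geometry <- function(n, pixel_spacing = NULL, fov_mm = 350,
                          slice_thickness = 0.5) {
  n <- as.integer(n)
  if (n < 2L) stop("grid must have at least 2 pixels per side")
  if (is.null(pixel_spacing)) pixel_spacing <- fov_mm / n
  if (pixel_spacing <= 0) stop("pixel spacing must be positive")
  structure(list(n = n, pixel_spacing = pixel_spacing,
                 slice_thickness = slice_thickness),
            class = "grid_geometry")
}

# Pixel-centre coordinates (mm) along one axis of an n-pixel grid centred
# on the origin.
grid_axis <- function(n, spacing) (seq_len(n) - (n + 1) / 2) * spacing

#' Write / read an image grid as plain text
#'
#' Stores the pixel matrix as a TSV file with a small JSON sidecar
#' (`<path>.json`) holding the geometry, so grids survive round trips
#' through text-only pipelines.
#'
#' @param img an `image_grid` (2D only for `write_image_grid`).
#' @param path TSV file path.
#' @return `write_image_grid` returns `path` invisibly; `read_image_grid`
#'   returns an `image_grid`.
#' @export
write_image_grid <- function(img, path) {
  stopifnot(inherits(img, "image_grid"), length(dim(img$pixels)) == 2L)
  utils::write.table(img$pixels, path, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  meta <- list(pixel_spacing = img$pixel_spacing,
               slice_thickness = img$slice_thickness, origin = img$origin)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_image_grid
#' @export
read_image_grid <- function(path) {
  px <- as.matrix(utils::read.table(path, sep = "\t"))
  dimnames(px) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  image_grid(px, meta$pixel_spacing, meta$slice_thickness,
             as.numeric(meta$origin))
}
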