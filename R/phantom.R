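#' Cylindrical insert specification
#'
#' One cylindrical rod in a QA phantom: a circular cross-section of fixed
#' CT number at a given position.
#'
#' @param label material label, e.g. `"acrylic"`.
#' @param center_xy length-2 numeric, insert centre in mm (x right, y down,
#'   origin at phantom centre).
#' @param radius insert radius in mm, positive.
#' @param hu_value CT number of the material in HU, within \[-1024, 3071\].
#' @return An object of class `insert_spec`.
#' @export
insert_spec <- function(label, center_xy, radius, hu_value) {
  if (radius <= 0) stop("insert radius must be positive")
  if (hu_value < -1024 || hu_value > 3071)
    stop("hu_value must lie within [-1024, 3071]")
  structure(list(label = as.character(label),
                 center_xy = as.numeric(center_xy),
                 radius = as.numeric(radius),
                 hu_value = as.numeric(hu_value)),
            class = "insert_spec")
}

#' Phantom body specification
#'
#' A phantom cross-section: a disk or elliptical body of uniform background
#' CT number surrounded by air, optionally holding cylindrical inserts.
#' Every insert must lie fully inside the body outline.
#'
#' @param shape `"disk"` or `"ellipse"`.
#' @param semi_axes length-2 numeric, semi-axes in mm (equal for a disk).
#' @param background_hu CT number of the body material.
#' @param inserts list of [insert_spec()] objects.
#' @param outside_hu CT number outside the body (air, -1000).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c("disk", "ellipse"), semi_axes,
                         background_hu = 0, inserts = list(),
                         outside_hu = -1000) {
  shape <- match.arg(shape)
  semi_axes <- as.numeric(semi_axes)
  if (length(semi_axes) == 1L) semi_axes <- rep(semi_axes, 2L)
  if (any(semi_axes <= 0)) stop("semi_axes must be positive")
  if (shape == "disk" && abs(diff(semi_axes)) > 1e-9)
    stop("a disk phantom needs equal semi-axes")
  for (ins in inserts) {
    if (!inherits(ins, "insert_spec")) stop("inserts must be insert_spec objects")
    # farthest point of the insert circle must remain inside the ellipse;
    # checked on a dense ring of boundary points
    th <- seq(0, 2 * pi, length.out = 181L)
    bx <- ins$center_xy[1] + ins$radius * cos(th)
    by <- ins$center_xy[2] + ins$radius * sin(th)
    if (any((bx / semi_axes[1])^2 + (by / semi_axes[2])^2 > 1))
      stop(sprintf("insert '%s' extends outside the phantom body", ins$label))
  }
  structure(list(shape = shape, semi_axes = semi_axes,
                 background_hu = as.numeric(background_hu),
                 inserts = inserts, outside_hu = as.numeric(outside_hu)),
            class = "phantom_spec")
}

#' Reference CT numbers of the QA-phantom insert materials
#'
#' @return Named numeric vector of HU values for the standard insert set.
#' @export
insert_materials <- function() {
  c(air = -1000, polypropylene = -105, water = 0,
    acrylic = 120, delrin = 340, teflon = 940)
}

#' Built-in phantom specifications
#'
#' `qa_phantom()` is a water-equivalent disk holding cylindrical inserts of
#' the standard materials (air -1000 HU, polypropylene -105 HU, water 0 HU,
#' acrylic 120 HU, Delrin 340 HU, Teflon 940 HU) arranged on a ring; the
#' acrylic rod, whose +120 HU contrast is close to the soft-tissue-vs-fat
#' task, is the default TTF target. `abdomen_phantom()` is the uniform
#' elliptical body (330 mm by 220 mm diameters) used for noise analysis;
#' it has no inserts.
#'
#' @param body_radius QA body radius in mm.
#' @param insert_radius insert radius in mm.
#' @param ring_radius radius of the circle the insert centres sit on, mm.
#' @return A [phantom_spec()].
#' @export
qa_phantom <- function(body_radius = 80, insert_radius = 12.5,
                       ring_radius = 45) {
  mats <- insert_materials()
  th <- 2 * pi * (seq_along(mats) - 1) / length(mats)
  inserts <- Map(function(lab, hu, a) {
    insert_spec(lab, ring_radius * c(cos(a), sin(a)), insert_radius, hu)
  }, names(mats), mats, th)
  phantom_spec("disk", c(body_radius, body_radius),
               background_hu = 0, inserts = unname(inserts))
}

#' @rdname qa_phantom
#' @export
abdomen_phantom <- function() {
  # elliptical cylinder, 33 cm longest / 22 cm shortest diameter,
  # soft-tissue-equivalent resin body
  phantom_spec("ellipse", c(165, 110), background_hu = 50, inserts = list())
}

# Coverage fraction of each pixel by the region (x/a)^2 + (y/b)^2 <= 1
# centred at (cx, cy). Interior/exterior pixels are decided by their
# centre; pixels cut by the boundary get a 16x16 subpixel area fraction.
ellipse_coverage <- function(xs, ys, cx, cy, a, b, spacing, antialias = TRUE) {
  X <- matrix(xs, nrow = length(ys), ncol = length(xs), byrow = TRUE)
  Y <- matrix(ys, nrow = length(ys), ncol = length(xs))
  q <- ((X - cx) / a)^2 + ((Y - cy) / b)^2
  cov <- (q <= 1) * 1
  if (!antialias) return(cov)
  # a pixel can straddle the boundary only if its centre lies within half a
  # pixel diagonal of it; distance to the ellipse is >= |sqrt(q) - 1| * b
  # (b = min semi-axis), so this selects a superset of the cut pixels
  half_diag <- spacing * sqrt(2) / 2
  edge <- which(abs(sqrt(q) - 1) <= half_diag / min(a, b))
  if (length(edge) == 0L) return(cov)
  ns <- 16L
  off <- (seq_len(ns) - (ns + 1) / 2) / ns * spacing
  sub <- expand.grid(dx = off, dy = off)
  for (k in edge) {
    i <- (k - 1L) %% length(ys) + 1L
    j <- (k - 1L) %/% length(ys) + 1L
    px <- xs[j] + sub$dx
    py <- ys[i] + sub$dy
    cov[k] <- mean(((px - cx) / a)^2 + ((py - cy) / b)^2 <= 1)
  }
  cov
}

#' Render a phantom cross-section to an image grid
#'
#' Produces the noiseless, blur-free HU map of a phantom on a raster. With
#' `antialias = TRUE` (default) pixels cut by a region boundary receive an
#' area-fraction blend of the two materials, giving clean edges for
#' edge-spread work; with `antialias = FALSE` each pixel takes the HU of
#' the innermost region containing its centre (the brute-force oracle mode).
#'
#' @param spec a [phantom_spec()].
#' @param grid a [grid_geometry()].
#' @param antialias logical; area-fraction boundary blending.
#' @return An [image_grid()] in HU.
#' @examples
#' ph <- qa_phantom()
#' img <- render_phantom(ph, grid_geometry(128, fov_mm = 200))
#' @export
render_phantom <- function(spec, grid, antialias = TRUE) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(grid, "grid_geometry"))
  sp <- grid$pixel_spacing
  half <- grid$n * sp / 2
  if (half < max(spec$semi_axes))
    stop("grid does not cover the phantom outline")
  xs <- grid_axis(grid$n, sp)
  ys <- grid_axis(grid$n, sp)
  img <- matrix(spec$outside_hu, grid$n, grid$n)
  cov <- ellipse_coverage(xs, ys, 0, 0, spec$semi_axes[1], spec$semi_axes[2],
                          sp, antialias)
  img <- img * (1 - cov) + spec$background_hu * cov
  for (ins in spec$inserts) {
    ci <- ellipse_coverage(xs, ys, ins$center_xy[1], ins$center_xy[2],
                           ins$radius, ins$radius, sp, antialias)
    img <- img * (1 - ci) + ins$hu_value * ci
  }
  image_grid(img, sp, grid$slice_thickness)
}
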