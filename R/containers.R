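#' Pixel geometry of an acquisition
#'
#' Physical pixel sizes used to convert pixel-based measurements (vessel
#' diameters in particular) into micrometers. The defaults correspond to a
#' 5.25 mm x 5.25 mm lateral field of view sampled at 400 x 400 pixels
#' (13.125 um per lateral pixel) and resolution-matched axial sampling.
#'
#' @param lateral_pixel_um Micrometers per lateral (X/Y) pixel.
#' @param axial_pixel_um Micrometers per axial (Z) pixel.
#' @return An object of class `pixel_geometry`.
#' @export
pixel_geometry <- function(lateral_pixel_um = 13.125, axial_pixel_um = 7.5) {
  stopifnot(is.numeric(lateral_pixel_um), length(lateral_pixel_um) == 1L,
            is.finite(lateral_pixel_um), lateral_pixel_um > 0,
            is.numeric(axial_pixel_um), length(axial_pixel_um) == 1L,
            is.finite(axial_pixel_um), axial_pixel_um > 0)
  structure(list(lateral_pixel_um = lateral_pixel_um,
                 axial_pixel_um = axial_pixel_um),
            class = "pixel_geometry")
}

#' @export
print.pixel_geometry <- function(x, ...) {
  cat(sprintf("pixel geometry: %.4g um/px lateral, %.4g um/px axial\n",
              x$lateral_pixel_um, x$axial_pixel_um))
  invisible(x)
}

#' Angiography volume container
#'
#' Wraps a 3D (Z x X x Y) or 4D (Z x X x Y x N) intensity array in canonical
#' axis order together with its pixel geometry. Z is the axial (depth) axis,
#' X and Y the lateral axes and N the temporal (repeat-frame) axis.
#'
#' @param data Numeric 3D or 4D array, finite and non-negative.
#' @param geometry A [pixel_geometry()].
#' @return An `angio_volume` (subclass `angio_volume3d` or `angio_volume4d`).
#' @export
angio_volume <- function(data, geometry = pixel_geometry()) {
  stopifnot(is.array(data), is.numeric(data))
  nd <- length(dim(data))
  if (!nd %in% c(3L, 4L))
    stop("angiography volumes must be 3D (Z,X,Y) or 4D (Z,X,Y,N)")
  if (any(dim(data) < 1L)) stop("all extents must be >= 1")
  if (anyNA(data) || any(!is.finite(data)))
    stop("volume intensities must be finite")
  if (any(data < 0)) stop("volume intensities must be non-negative")
  stopifnot(inherits(geometry, "pixel_geometry"))
  cls <- if (nd == 4L) "angio_volume4d" else "angio_volume3d"
  structure(list(data = data, pixel_geometry = geometry),
            class = c(cls, "angio_volume"))
}

#' @export
print.angio_volume <- function(x, ...) {
  d <- dim(x$data)
  lab <- if (length(d) == 4L) "Z x X x Y x N" else "Z x X x Y"
  cat(sprintf("angio_volume: %s = %s, intensity range [%.4g, %.4g]\n",
              lab, paste(d, collapse = " x "), min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.angio_volume <- function(x) dim(x$data)

#' En face image container
#'
#' A 2D (X x Y) lateral image, typically a maximum intensity projection of
#' an angiography volume.
#'
#' @param data Numeric matrix (X x Y), finite.
#' @param geometry A [pixel_geometry()].
#' @return An object of class `enface_image`.
#' @export
enface_image <- function(data, geometry = pixel_geometry()) {
  stopifnot(is.matrix(data), is.numeric(data))
  if (anyNA(data) || any(!is.finite(data)))
    stop("en face intensities must be finite")
  stopifnot(inherits(geometry, "pixel_geometry"))
  structure(list(data = data, pixel_geometry = geometry),
            class = "enface_image")
}

#' @export
print.enface_image <- function(x, ...) {
  cat(sprintf("enface_image: %d x %d, intensity range [%.4g, %.4g]\n",
              nrow(x$data), ncol(x$data), min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.enface_image <- function(x) dim(x$data)

#' Binary angiography mask (BAM)
#'
#' Vessel pixels 1, background 0.
#'
#' @param mask Matrix containing only 0/1 (logical accepted).
#' @return Object of class `binary_angio_mask`.
#' @export
binary_angio_mask <- function(mask) {
  m <- as_binary_matrix(mask, "BAM")
  structure(list(mask = m), class = "binary_angio_mask")
}

#' Binary vessel skeleton (BVS)
#'
#' One-pixel-wide 8-connected medial lines of a binary angiography mask.
#'
#' @param skeleton Matrix containing only 0/1 (logical accepted).
#' @return Object of class `binary_vessel_skeleton`.
#' @export
binary_vessel_skeleton <- function(skeleton) {
  m <- as_binary_matrix(skeleton, "BVS")
  structure(list(skeleton = m), class = "binary_vessel_skeleton")
}

as_binary_matrix <- function(x, what) {
  if (inherits(x, "binary_angio_mask")) x <- x$mask
  if (inherits(x, "binary_vessel_skeleton")) x <- x$skeleton
  stopifnot(is.matrix(x))
  m <- x * 1
  if (anyNA(m) || !all(m %in% c(0, 1)))
    stop(what, " must contain only 0/1 values")
  storage.mode(m) <- "double"
  m
}

#' @export
print.binary_angio_mask <- function(x, ...) {
  cat(sprintf("binary_angio_mask: %d x %d, %d vessel px (%.2f%%)\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask),
              100 * mean(x$mask)))
  invisible(x)
}

#' @export
print.binary_vessel_skeleton <- function(x, ...) {
  cat(sprintf("binary_vessel_skeleton: %d x %d, %d skeleton px\n",
              nrow(x$skeleton), ncol(x$skeleton), sum(x$skeleton)))
  invisible(x)
}
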