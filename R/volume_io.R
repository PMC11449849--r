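#' Read an acquisition volume from disk
#'
#' Reads a 3D (Z,X,Y) or 4D (Z,X,Y,N) volume from a multi-page TIFF or a raw
#' binary payload. Axis order, extents, dtype and pixel sizes come from a
#' JSON sidecar (`<path>.json`, written by [write_volume()]) or from an
#' explicit `layout` list with the same fields; an explicit layout overrides
#' the sidecar. Whatever the on-disk axis order, the returned volume is
#' permuted to the canonical (Z, X, Y[, N]) order.
#'
#' @param path File path (`.tif`/`.tiff` or `.raw`/`.bin`).
#' @param layout Optional list with elements `axes` (string such as "ZXYN"),
#'   `extents` (integer vector in on-disk axis order), `dtype`
#'   ("float64"/"float32" — raw binary only), `lateral_pixel_um`,
#'   `axial_pixel_um`, and for rescaled TIFF `rescale_min`/`rescale_max`.
#' @return An [angio_volume()].
#' @export
read_volume <- function(path, layout = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  meta <- read_sidecar(path)
  if (!is.null(layout)) meta[names(layout)] <- layout
  if (is.null(meta$axes) || is.null(meta$extents))
    stop("no sidecar metadata and no layout given for ", path)
  axes <- strsplit(toupper(meta$axes), "")[[1]]
  extents <- as.integer(meta$extents)
  if (length(axes) != length(extents))
    stop("layout axes and extents disagree in length")
  if (!all(axes %in% c("Z", "X", "Y", "N")) || anyDuplicated(axes))
    stop("axes must be a permutation of Z, X, Y and optionally N")

  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
    if (!is.list(pages)) pages <- list(pages)
    # pages hold the first two on-disk axes as matrix rows/cols
    page_dim <- dim(pages[[1]])
    expect_pages <- prod(extents) / prod(extents[1:2])
    if (length(pages) != expect_pages || !all(page_dim == extents[1:2]))
      stop("TIFF payload inconsistent with declared extents")
    arr <- array(unlist(pages, use.names = FALSE), dim = c(page_dim, length(pages)))
    dim(arr) <- extents
    if (!is.null(meta$rescale_min)) {
      arr <- arr * (meta$rescale_max - meta$rescale_min) + meta$rescale_min
    }
  } else if (ext %in% c("raw", "bin")) {
    dtype <- if (is.null(meta$dtype)) "float64" else meta$dtype
    size <- switch(dtype, float64 = 8L, float32 = 4L,
                   stop("unsupported dtype: ", dtype))
    n_vals <- prod(extents)
    payload <- file.size(path)
    if (payload < n_vals * size)
      stop("payload shorter than declared extents (", payload, " bytes < ",
           n_vals * size, ")")
    con <- file(path, "rb"); on.exit(close(con))
    arr <- readBin(con, what = "double", n = n_vals, size = size)
    dim(arr) <- extents
  } else stop("unsupported volume format: .", ext)

  if (anyNA(arr) || any(!is.finite(arr))) stop("volume contains non-finite values")
  canon <- intersect(c("Z", "X", "Y", "N"), axes)
  arr <- aperm(arr, match(canon, axes))
  geom <- sidecar_geometry(meta)
  angio_volume(arr, geom)
}

#' Write an acquisition volume to disk
#'
#' Multi-page TIFF (`.tif`/`.tiff`; float32 with a linear rescale to [0,1]
#' recorded in the sidecar, pages = leading non-lateral axes) or raw binary
#' float64 (`.raw`/`.bin`; exact round trip). A JSON sidecar `<path>.json`
#' records axes, extents, dtype, pixel sizes and any rescale.
#'
#' @param vol An [angio_volume()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "angio_volume"))
  arr <- vol$data
  d <- dim(arr)
  axes <- if (length(d) == 4L) "ZXYN" else "ZXY"
  # on-disk order (X, Y, pages): pages iterate Z (fastest) then N
  perm <- if (length(d) == 4L) c(2, 3, 1, 4) else c(2, 3, 1)
  disk <- aperm(arr, perm)
  disk_axes <- if (length(d) == 4L) "XYZN" else "XYZ"
  meta <- list(axes = disk_axes, extents = dim(disk),
               lateral_pixel_um = vol$pixel_geometry$lateral_pixel_um,
               axial_pixel_um = vol$pixel_geometry$axial_pixel_um)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    mn <- min(disk); mx <- max(disk)
    scl <- if (mx > mn) (disk - mn) / (mx - mn) else disk * 0
    meta$rescale_min <- mn
    meta$rescale_max <- if (mx > mn) mx else mn + 1  # degenerate: slope 1
    n_pages <- prod(dim(disk)) / prod(dim(disk)[1:2])
    dim(scl) <- c(dim(disk)[1:2], n_pages)
    pages <- lapply(seq_len(n_pages), function(i) scl[, , i])
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
    meta$dtype <- "float32"
  } else if (ext %in% c("raw", "bin")) {
    con <- file(path, "wb")
    writeBin(as.vector(disk), con, size = 8L)
    close(con)
    meta$dtype <- "float64"
  } else stop("unsupported volume format: .", ext)
  write_sidecar(path, meta)
  invisible(path)
}

read_sidecar <- function(path) {
  sc <- paste0(path, ".json")
  if (file.exists(sc)) jsonlite::read_json(sc, simplifyVector = TRUE) else list()
}

write_sidecar <- function(path, meta) {
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
}

sidecar_geometry <- function(meta) {
  if (is.null(meta$lateral_pixel_um)) {
    warning("no lateral pixel size in metadata; defaulting to 13.125 um/px")
    meta$lateral_pixel_um <- 13.125
  }
  if (is.null(meta$axial_pixel_um)) meta$axial_pixel_um <- 7.5
  pixel_geometry(meta$lateral_pixel_um, meta$axial_pixel_um)
}

#' Write an en face image as 8- or 16-bit grayscale PNG/TIFF
#'
#' Intensities are linearly rescaled to the full bit range; the rescale
#' parameters are recorded in a JSON sidecar so [read_enface()] can restore
#' the original scale. A constant image has no defined rescale and is written
#' as all zeros with a warning.
#'
#' @param image An [enface_image()] or numeric matrix.
#' @param path Output path (`.png`, `.tif`, `.tiff`).
#' @param bit_depth 8 or 16.
#' @return `path`, invisibly.
#' @export
write_enface <- function(image, path, bit_depth = 16L) {
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
  geom <- pixel_geometry()
  if (inherits(image, "enface_image")) {
    geom <- image$pixel_geometry
    image <- image$data
  }
  stopifnot(is.matrix(image))
  if (anyNA(image) || any(!is.finite(image))) stop("image must be finite")
  mn <- min(image); mx <- max(image)
  if (mx > mn) {
    scl <- (image - mn) / (mx - mn)
  } else {
    warning("constant image: undefined rescale, writing all zeros")
    scl <- image * 0
    mx <- mn + 1
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (bit_depth != 8L)
      stop("PNG en face output is 8-bit; use .tif for 16-bit")
    png::writePNG(round(scl * 255) / 255, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(scl, path, bits.per.sample = as.integer(bit_depth))
  } else stop("unsupported en face format: .", ext)
  write_sidecar(path, list(rescale_min = mn, rescale_max = mx,
                           bit_depth = bit_depth,
                           lateral_pixel_um = geom$lateral_pixel_um,
                           axial_pixel_um = geom$axial_pixel_um))
  invisible(path)
}

#' Read an en face image written by [write_enface()]
#'
#' @param path Image path; intensities are restored from the sidecar rescale
#'   when present, otherwise returned in [0,1].
#' @return An [enface_image()].
#' @export
read_enface <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") png::readPNG(path) else tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  meta <- read_sidecar(path)
  if (!is.null(meta$rescale_min))
    img <- img * (meta$rescale_max - meta$rescale_min) + meta$rescale_min
  enface_image(img, sidecar_geometry(meta))
}

#' Write a binary mask or skeleton as a 0/255 8-bit PNG
#'
#' @param mask A [binary_angio_mask()], [binary_vessel_skeleton()] or 0/1
#'   matrix.
#' @param path Output `.png` path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  m <- as_binary_matrix(mask, "mask")
  png::writePNG(m, path)
  invisible(path)
}

#' Read a 0/255 binary mask PNG
#'
#' @param path Input path.
#' @return A 0/1 matrix.
#' @export
read_mask <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  (m > 0.5) * 1
}

#' Serialize a metrics, repeatability or cohort report
#'
#' Reports are written as CSV (long format: metric, value, unit) or JSON
#' (labeled values plus units), losslessly re-readable at full double
#' precision.
#'
#' @param report A `metrics_report` or a data frame.
#' @param path Output path.
#' @param format "csv" or "json"; default inferred from the extension.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path,
                         format = tolower(tools::file_ext(path))) {
  if (!format %in% c("csv", "json")) stop("format must be csv or json")
  df <- as.data.frame(report)
  if (format == "csv") {
    utils::write.csv(format_df_full(df), path, row.names = FALSE, quote = TRUE)
  } else {
    jsonlite::write_json(df, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", na = "null")
  }
  invisible(path)
}

format_df_full <- function(df) {
  df[] <- lapply(df, function(col) {
    if (is.numeric(col)) format(col, digits = 17, scientific = FALSE,
                                trim = TRUE) else col
  })
  df
}

#' Read a report written by [write_report()]
#'
#' @param path CSV or JSON report path.
#' @return A data frame.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    utils::read.csv(path, stringsAsFactors = FALSE)
  } else if (ext == "json") {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else stop("unsupported report format: .", ext)
}
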