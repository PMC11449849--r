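#' Vessel area density (VAD)
#'
#' Percentage of the field of view covered by the binary angiography mask:
#' `100 * sum(BAM) / (X * Y)`.
#'
#' @param bam A [binary_angio_mask()] or 0/1 matrix.
#' @return VAD in percent.
#' @export
vad <- function(bam) {
  m <- as_binary_matrix(bam, "BAM")
  100 * sum(m) / length(m)
}

#' Vessel skeleton density (VSD)
#'
#' Percentage of the field of view covered by skeleton pixels:
#' `100 * sum(BVS) / (X * Y)`.
#'
#' @param bvs A [binary_vessel_skeleton()] or 0/1 matrix.
#' @return VSD in percent.
#' @export
vsd <- function(bvs) {
  m <- as_binary_matrix(bvs, "BVS")
  100 * sum(m) / length(m)
}

#' Vessel diameter index (VDI)
#'
#' Mean vessel diameter over the skeleton: twice the Euclidean distance to
#' the vessel edge, averaged over all skeleton pixels, converted to
#' micrometers with the lateral pixel size.
#'
#' @param bam A [binary_angio_mask()] or 0/1 matrix.
#' @param bvs The matching [binary_vessel_skeleton()].
#' @param geometry A [pixel_geometry()].
#' @return VDI in micrometers.
#' @export
vdi <- function(bam, bvs, geometry = pixel_geometry()) {
  s <- as_binary_matrix(bvs, "BVS")
  if (sum(s) == 0) stop("no vessels: empty skeleton")
  df <- diameter_field(bam, bvs)
  sum(df$values) / sum(s) * geometry$lateral_pixel_um
}

#' Tortuosity index of one vessel segment
#'
#' `(segment length / endpoint Euclidean distance - 1) * 100`; zero for a
#' straight segment.
#'
#' @param seg A `vessel_segment` from [decompose_segments()].
#' @return The TI (unitless).
#' @export
segment_ti <- function(seg) {
  stopifnot(inherits(seg, "vessel_segment"))
  if (seg$chord_px <= 0) stop("zero chord: loop segments must be cut open")
  (seg$length_px / seg$chord_px - 1) * 100
}

#' Diameter-weighted tortuosity index (WTI)
#'
#' Averages the per-segment tortuosity with each segment's mean diameter as
#' the weight, so that the tortuosity of hemodynamically dominant vessels
#' counts proportionally to their caliber:
#' `100 * sum(d_n * (L_n / E_n - 1)) / sum(d_n)`.
#'
#' @param segments A `vessel_segments` list whose segments carry
#'   `mean_diameter_px` (decomposed with a diameter field).
#' @return The WTI (unitless).
#' @export
wti <- function(segments) {
  if (length(segments) == 0L) stop("no segments")
  d <- vapply(segments, `[[`, numeric(1), "mean_diameter_px")
  len <- vapply(segments, `[[`, numeric(1), "length_px")
  chord <- vapply(segments, `[[`, numeric(1), "chord_px")
  if (anyNA(d)) stop("segments carry no diameters; decompose with a diameter field")
  if (any(d <= 0)) stop("all segment diameters must be positive")
  100 * sum(d * (len / chord - 1)) / sum(d)
}

#' Coefficient of variation across repeated measurements
#'
#' Population standard deviation (divisor n) divided by the mean; the scan-
#' rescan repeatability statistic. Reported to 4 decimals in summaries.
#'
#' @param values Numeric vector of length >= 2 with non-zero mean.
#' @return The CV (unitless, full precision).
#' @export
coefficient_of_variation <- function(values) {
  stopifnot(is.numeric(values), length(values) >= 2)
  m <- mean(values)
  if (m == 0) stop("zero mean: CV undefined")
  sqrt(mean((values - m)^2)) / m
}

#' Cohort summary with Student-t confidence interval
#'
#' Mean, sample standard deviation (divisor n-1) and the symmetric
#' two-sided confidence interval `mean +/- t(1 - alpha/2, n - 1) * SD /
#' sqrt(n)`.
#'
#' @param values Numeric vector, n >= 2.
#' @param confidence Confidence level (default 0.95).
#' @return A one-row data frame: n, mean, sd, ci_lower, ci_upper.
#' @export
cohort_summary <- function(values, confidence = 0.95) {
  stopifnot(is.numeric(values))
  n <- length(values)
  if (n < 2) stop("cohort summary requires n >= 2")
  cohort_ci(mean(values), stats::sd(values), n, confidence)
}

#' Confidence interval from summary statistics
#'
#' Same t-interval as [cohort_summary()], computed from a published or
#' precomputed (mean, SD, n) triple.
#'
#' @param mean,sd,n Summary statistics (sample SD, divisor n-1).
#' @param confidence Confidence level.
#' @return A one-row data frame: n, mean, sd, ci_lower, ci_upper.
#' @export
cohort_ci <- function(mean, sd, n, confidence = 0.95) {
  stopifnot(n >= 2, sd >= 0, confidence > 0, confidence < 1)
  half <- stats::qt(1 - (1 - confidence) / 2, df = n - 1) * sd / sqrt(n)
  data.frame(n = n, mean = mean, sd = sd,
             ci_lower = mean - half, ci_upper = mean + half)
}

#' Moving-kernel heatmap of a local vessel statistic
#'
#' Slides an odd `kernel_px x kernel_px` window (edge-replicated) over the
#' field. For `mode = "density"` the value is the mean of the binary mask in
#' the window (local VAD / 100). For `"diameter"` and `"ti"` the value is
#' the mean of the non-zero skeleton-map values inside the window — zeros
#' off the skeleton would otherwise dilute the local statistic — and 0 where
#' the window holds no skeleton pixel.
#'
#' @param field A 0/1 mask (density) or a skeleton-supported value map
#'   (diameter field / TI map); containers or plain matrices.
#' @param kernel_px Odd kernel width >= 3.
#' @param mode One of "density", "diameter", "ti".
#' @return A numeric matrix of the same extents.
#' @export
local_heatmap <- function(field, kernel_px = 51L,
                          mode = c("density", "diameter", "ti")) {
  mode <- match.arg(mode)
  x <- field
  if (inherits(x, "binary_angio_mask")) x <- x$mask
  if (inherits(x, "diameter_field") || inherits(x, "ti_skeleton_map"))
    x <- x$values
  if (inherits(x, "binary_vessel_skeleton")) x <- x$skeleton
  stopifnot(is.matrix(x))
  kernel_px <- as.integer(kernel_px)
  if (kernel_px < 3L || kernel_px %% 2L == 0L)
    stop("kernel_px must be odd and >= 3")
  if (kernel_px > 2L * max(dim(x)) - 1L) stop("kernel larger than image")
  if (mode == "density") return(box_mean(x, kernel_px))
  support <- (x != 0) * 1
  num <- box_mean(x, kernel_px)
  den <- box_mean(support, kernel_px)
  # guard integral-image round-off: require at least half a support pixel
  ok <- den * kernel_px^2 >= 0.5
  out <- matrix(0, nrow(x), ncol(x))
  out[ok] <- num[ok] / den[ok]
  out
}

#' Full quantification of one en face projection
#'
#' Runs mask generation, skeletonization, segment decomposition and the four
#' metrics on a single en face angiogram, returning the metrics report and
#' all intermediate maps.
#'
#' @param img An [enface_image()] or numeric matrix.
#' @param params A [bam_params()].
#' @param geometry A [pixel_geometry()]; taken from `img` when it is an
#'   [enface_image()].
#' @param prune_px,min_len_px Skeleton spur pruning and minimum segment
#'   length, in pixels.
#' @param doi_label Label recorded in the report ("DOI 1", "DOI 2", ...).
#' @return A list with `report` (a `metrics_report`), `bam`, `bvs`,
#'   `segments`, `dfield`, `ti_map`.
#' @export
quantify_enface <- function(img, params = bam_params(),
                            geometry = NULL, prune_px = 5L, min_len_px = 5,
                            doi_label = "full") {
  if (inherits(img, "enface_image")) {
    if (is.null(geometry)) geometry <- img$pixel_geometry
    img <- img$data
  }
  if (is.null(geometry)) geometry <- pixel_geometry()
  bam <- make_bam(img, params)
  bvs <- skeletonize(bam, prune_px)
  dfield <- diameter_field(bam, bvs)
  segments <- decompose_segments(bvs, min_len_px, dfield)
  ti_map <- ti_skeleton_map(segments, dim(img))
  n_seg <- length(segments)
  tis <- vapply(segments, `[[`, numeric(1), "ti")
  report <- metrics_report(
    vad_percent = vad(bam),
    vsd_percent = vsd(bvs),
    vdi_um = if (sum(bvs$skeleton) > 0) vdi(bam, bvs, geometry) else NA_real_,
    wti = if (n_seg > 0) wti(segments) else NA_real_,
    mean_ti = if (n_seg > 0) mean(tis) else NA_real_,
    n_segments = n_seg, doi_label = doi_label)
  list(report = report, bam = bam, bvs = bvs, segments = segments,
       dfield = dfield, ti_map = ti_map)
}

#' Metrics report container
#'
#' @param vad_percent,vsd_percent Densities in percent.
#' @param vdi_um Vessel diameter index in micrometers.
#' @param wti Weighted tortuosity index (unitless).
#' @param mean_ti Unweighted mean segment TI.
#' @param n_segments Number of vessel segments.
#' @param doi_label Which depth layer the report describes.
#' @return An object of class `metrics_report`.
#' @export
metrics_report <- function(vad_percent, vsd_percent, vdi_um, wti,
                           mean_ti = NA_real_, n_segments = NA_integer_,
                           doi_label = "full") {
  stopifnot(vad_percent >= 0, vad_percent <= 100,
            vsd_percent >= 0, vsd_percent <= 100)
  structure(list(vad_percent = vad_percent, vsd_percent = vsd_percent,
                 vdi_um = vdi_um, wti = wti, mean_ti = mean_ti,
                 n_segments = n_segments, doi_label = doi_label),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "metrics_report [%s]: VAD %.2f%%, VSD %.2f%%, VDI %.2f um, WTI %.2f (%d segments)\n",
    x$doi_label, x$vad_percent, x$vsd_percent, x$vdi_um, x$wti,
    x$n_segments))
  invisible(x)
}

#' @export
as.data.frame.metrics_report <- function(x, ...) {
  data.frame(
    metric = c("VAD", "VSD", "VDI", "WTI", "mean_TI", "n_segments"),
    value = c(x$vad_percent, x$vsd_percent, x$vdi_um, x$wti, x$mean_ti,
              x$n_segments),
    unit = c("percent", "percent", "um", "unitless", "unitless", "count"),
    doi = x$doi_label)
}

#' Render a heatmap as a color PNG with a scale bar
#'
#' Maps the heatmap linearly onto a blue-green-yellow-red ramp and burns a
#' white scale bar of the given physical length into the lower-left corner.
#'
#' @param heatmap Numeric matrix from [local_heatmap()].
#' @param path Output `.png` path.
#' @param geometry A [pixel_geometry()] for the scale bar.
#' @param bar_um Scale bar length in micrometers.
#' @return `path`, invisibly; the value range is recorded in a JSON sidecar.
#' @export
render_heatmap <- function(heatmap, path, geometry = pixel_geometry(),
                           bar_um = 500) {
  stopifnot(is.matrix(heatmap))
  mn <- min(heatmap); mx <- max(heatmap)
  scl <- if (mx > mn) (heatmap - mn) / (mx - mn) else heatmap * 0
  ramp <- grDevices::colorRamp(c("#00204D", "#00A0A0", "#E8E800", "#C00000"))
  rgb <- ramp(as.vector(scl)) / 255
  arr <- array(rgb, c(nrow(heatmap), ncol(heatmap), 3))
  bar_px <- max(2L, round(bar_um / geometry$lateral_pixel_um))
  r0 <- nrow(heatmap) - 6L
  if (r0 > 2 && bar_px + 6 < ncol(heatmap))
    arr[r0:(r0 + 2), 5:(4 + bar_px), ] <- 1
  png::writePNG(arr, path)
  write_sidecar(path, list(value_min = mn, value_max = mx, bar_um = bar_um,
                           lateral_pixel_um = geometry$lateral_pixel_um))
  invisible(path)
}
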