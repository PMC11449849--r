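#' Depth intensity profile of an angiography volume
#'
#' Averages every depth slice over both lateral axes, giving the mean OCTA
#' signal intensity as a function of depth (length-Z vector), plus a
#' centered moving-average smoothed copy used for peak and crossing
#' detection. Raw per-slice means are speckle-noisy; the default 9-slice
#' window matches the scale of the depth structure without displacing the
#' intensity peak.
#'
#' @param vol An [angio_volume()] (3D) or numeric 3D array.
#' @param smooth_window Width of the centered moving average (odd; 1 = no
#'   smoothing). At the profile ends the window is truncated to the
#'   available slices.
#' @return An object of class `depth_profile` with fields `intensity`,
#'   `smoothed` and `mean_all`.
#' @export
depth_profile <- function(vol, smooth_window = 9L) {
  a <- if (inherits(vol, "angio_volume")) vol$data else vol
  stopifnot(length(dim(a)) == 3L, smooth_window >= 1)
  intensity <- apply(a, 1L, mean)
  structure(list(intensity = intensity,
                 smoothed = moving_average(intensity, smooth_window),
                 mean_all = mean(intensity)),
            class = "depth_profile")
}

# centered moving average with window truncation at the ends
moving_average <- function(x, w) {
  w <- as.integer(w)
  if (w <= 1L) return(x)
  h <- w %/% 2L
  n <- length(x)
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' @export
print.depth_profile <- function(x, ...) {
  cat(sprintf("depth_profile: %d depths, mean intensity %.4g\n",
              length(x$intensity), x$mean_all))
  invisible(x)
}

#' Export a depth profile as a data frame / CSV
#'
#' @param x A `depth_profile`.
#' @param ... Unused.
#' @return Data frame with columns `z` (0-based depth index), `raw`,
#'   `smoothed`.
#' @export
as.data.frame.depth_profile <- function(x, ...) {
  data.frame(z = seq_along(x$intensity) - 1L, raw = x$intensity,
             smoothed = x$smoothed)
}

#' Find the end depth of the signal-bearing region
#'
#' The end depth is the deepest location where the depth profile still holds
#' the mean intensity of all depths: below it the OCTA signal has attenuated
#' into noise. Because exact equality with the mean almost never occurs on
#' sampled data, the criterion is the deepest index whose (smoothed)
#' intensity is at or above `mean_all` — the last down-crossing of the mean
#' level.
#'
#' @param profile A [depth_profile()].
#' @return 0-based depth index of the last at-or-above-mean slice.
#' @export
find_end_depth <- function(profile) {
  stopifnot(inherits(profile, "depth_profile"))
  p <- profile$smoothed
  if (max(p) == min(p))
    stop("no attenuation structure: constant depth profile")
  max(which(p >= profile$mean_all)) - 1L
}

#' Find the layer separation depth
#'
#' The separation depth is the location of the maximum intensity peak of the
#' (smoothed) depth profile, searched between `z_min` and the end depth.
#' Ties (plateau maxima) break toward the smaller depth. By default `z_min`
#' skips the pre-tissue region: it is the first index where the smoothed
#' profile exceeds 10% of its maximum, so a bright surface-reflection
#' artifact in air cannot be selected as the peak.
#'
#' @param profile A [depth_profile()].
#' @param z_min 0-based lower search bound, or `NULL` for the default rule.
#' @return 0-based depth index of the intensity peak.
#' @export
find_separation_depth <- function(profile, z_min = NULL) {
  stopifnot(inherits(profile, "depth_profile"))
  p <- profile$smoothed
  end0 <- find_end_depth(profile)
  if (is.null(z_min)) z_min <- min(which(p > 0.1 * max(p))) - 1L
  if (z_min >= end0) stop("empty search range: z_min >= end depth")
  idx <- (z_min + 1L):(end0 + 1L)  # 1-based slice indices searched
  idx[which.max(p[idx])] - 1L
}

#' Depth-of-interest split of an angiography volume
#'
#' Splits the volume into a superficial layer (DOI 1: from the top down to
#' the layer separation depth) and a deep layer (DOI 2: from the separation
#' depth to the end depth), with the separation depth found at the maximum
#' intensity peak and the end depth at the last at-or-above-mean slice.
#' Boundaries are half-open 0-based depth indices: DOI 1 covers depths
#' `[0, separation)` and DOI 2 covers `[separation, end)`; slices at or
#' below the end depth bound belong to neither.
#'
#' @param vol An [angio_volume()] (3D).
#' @param smooth_window Passed to [depth_profile()].
#' @param z_min Passed to [find_separation_depth()].
#' @return List with `doi1` and `doi2` ([angio_volume()]s) and `split`, a
#'   `doi_split` with fields `separation_depth` and `end_depth`.
#' @export
split_doi <- function(vol, smooth_window = 9L, z_min = NULL) {
  stopifnot(inherits(vol, "angio_volume3d"))
  prof <- depth_profile(vol, smooth_window)
  sep <- find_separation_depth(prof, z_min)
  end_excl <- find_end_depth(prof) + 1L  # one past the last signal slice
  z_extent <- dim(vol$data)[1]
  if (sep < 3L || sep > end_excl - 3L)
    stop("degenerate split: separation depth within 2 slices of top or end")
  split <- structure(list(separation_depth = sep, end_depth = end_excl),
                     class = "doi_split")
  list(doi1 = angio_volume(vol$data[seq_len(sep), , , drop = FALSE],
                           vol$pixel_geometry),
       doi2 = angio_volume(vol$data[(sep + 1L):end_excl, , , drop = FALSE],
                           vol$pixel_geometry),
       split = split)
}

#' @export
print.doi_split <- function(x, ...) {
  cat(sprintf(
    "doi_split: DOI 1 depths [0, %d), DOI 2 depths [%d, %d)\n",
    x$separation_depth, x$separation_depth, x$end_depth))
  invisible(x)
}

#' Maximum intensity projection along depth
#'
#' Collapses a depth range of the volume to an en face image: each lateral
#' pixel takes the maximum intensity over the selected depths.
#'
#' @param vol An [angio_volume()] (3D).
#' @param z_range 1-based depth slice indices to project over (default: all).
#' @return An [enface_image()].
#' @export
mip <- function(vol, z_range = NULL) {
  stopifnot(inherits(vol, "angio_volume3d"))
  z_extent <- dim(vol$data)[1]
  if (is.null(z_range)) z_range <- seq_len(z_extent)
  z_range <- as.integer(z_range)
  if (length(z_range) == 0L) stop("empty depth range")
  if (any(z_range < 1L | z_range > z_extent))
    stop("depth range outside volume")
  sub <- vol$data[z_range, , , drop = FALSE]
  enface_image(apply(sub, c(2L, 3L), max), vol$pixel_geometry)
}
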