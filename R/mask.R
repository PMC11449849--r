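#' Parameters for binary angiography mask generation
#'
#' @param vessel_scales Hessian vesselness scales in pixels.
#' @param adaptive_window,adaptive_offset Local-mean threshold window (odd)
#'   and offset applied to the vesselness response.
#' @param otsu_scale The intensity gate keeps pixels brighter than
#'   `otsu_scale * global_otsu(img)`; it proposes the full-caliber candidate
#'   mask.
#' @param seed_frac Fraction of a candidate component's area that must carry
#'   tubularity seeds (adaptive-thresholded vesselness) for the component to
#'   be kept.
#' @param min_object_px Connected components (8-connected) smaller than this
#'   are removed.
#' @param max_hole_px Background holes up to this size are filled.
#' @return An object of class `bam_params`.
#' @export
bam_params <- function(vessel_scales = c(2, 4, 6, 8),
                       adaptive_window = 51L, adaptive_offset = 0.01,
                       otsu_scale = 0.6, seed_frac = 0.1,
                       min_object_px = 30L, max_hole_px = 20L) {
  structure(list(vessel_scales = vessel_scales,
                 adaptive_window = as.integer(adaptive_window),
                 adaptive_offset = adaptive_offset,
                 otsu_scale = otsu_scale, seed_frac = seed_frac,
                 min_object_px = as.integer(min_object_px),
                 max_hole_px = as.integer(max_hole_px)),
            class = "bam_params")
}

#' Binary angiography mask (BAM) from an en face projection
#'
#' Combines three classical vessel segmentation ingredients. A scaled global
#' Otsu threshold on the raw intensities proposes the full-caliber candidate
#' mask; the Hessian vesselness response, binarized by an adaptive
#' local-mean threshold, provides tubularity seeds; candidate connected
#' components insufficiently supported by seeds are discarded (a thresholded
#' vesselness map alone under-covers vessel caliber — the ridge response
#' decays toward vessel edges — while the intensity mask alone admits
#' non-tubular noise blobs; seeded reconstruction keeps the caliber of the
#' intensity mask and the specificity of the vesselness filter). Objects
#' smaller than `min_object_px` are removed and background holes up to
#' `max_hole_px` are filled.
#'
#' @param img An [enface_image()] or numeric matrix.
#' @param params A [bam_params()].
#' @return A [binary_angio_mask()].
#' @export
make_bam <- function(img, params = bam_params()) {
  x <- if (inherits(img, "enface_image")) img$data else img
  if (anyNA(x) || any(!is.finite(x))) stop("image must be finite")
  if (max(x) == min(x))  # constant image: nothing to segment
    return(binary_angio_mask(matrix(0, nrow(x), ncol(x))))
  v <- vesselness(x, params$vessel_scales)$data
  am <- adaptive_mask(v, params$adaptive_window, params$adaptive_offset)$mask
  gate <- (x > params$otsu_scale * global_otsu(x)) * 1
  seeds <- am * gate
  lab <- label8(gate)
  if (max(lab) > 0) {
    seed_px <- tabulate(lab[seeds > 0], nbins = max(lab))
    size_px <- tabulate(lab[lab > 0], nbins = max(lab))
    keep <- which(seed_px >= pmax(1, params$seed_frac * size_px))
    m <- (matrix(lab %in% keep, nrow(lab)) & gate > 0) * 1
  } else m <- gate
  m <- remove_small_objects(m, params$min_object_px)
  m <- fill_small_holes(m, params$max_hole_px)
  binary_angio_mask(m)
}

# 8-connected component labels of the set pixels of a binary matrix
label8 <- function(m) {
  idx <- which(m > 0)
  lab <- matrix(0L, nrow(m), ncol(m))
  if (length(idx) == 0L) return(lab)
  nr <- nrow(m); nc <- ncol(m)
  r <- ((idx - 1L) %% nr) + 1L
  c <- ((idx - 1L) %/% nr) + 1L
  vid <- match(idx, idx)
  edges <- NULL
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))) {
    r2 <- r + off[1]; c2 <- c + off[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- !is.na(match(nb, idx)) & m[cbind(r2[ok], c2[ok])] > 0
    from <- which(ok)[hit]
    to <- match(nb[hit], idx)
    if (length(from)) edges <- rbind(edges, cbind(from, to))
  }
  if (is.null(edges)) { lab[idx] <- seq_along(idx); return(lab) }
  g <- igraph::graph_from_edgelist(unique(edges), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  lab[idx] <- comp[seq_along(idx)]
  lab
}

remove_small_objects <- function(m, min_px) {
  if (min_px <= 1L || !any(m > 0)) return(m)
  lab <- label8(m)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_px)
  (lab %in% keep & m > 0) * 1
}

fill_small_holes <- function(m, max_px) {
  if (max_px < 1L) return(m)
  bg <- 1 - m
  lab <- EBImage::bwlabel(bg)  # 4-connected background components
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  sizes <- tabulate(lab[lab > 0])
  fill <- setdiff(which(sizes <= max_px), border)
  m[lab %in% fill] <- 1
  m
}

#' Skeletonize a binary angiography mask
#'
#' Topology-preserving Zhang-Suen thinning to a one-pixel-wide, 8-connected
#' medial skeleton, followed by removal of residual 2x2 blocks and pruning
#' of spurs (endpoint branches shorter than `prune_px` that terminate at a
#' junction). Sub-5-pixel spurs are thinning artifacts of boundary noise and
#' carry no usable chord geometry.
#'
#' @param bam A [binary_angio_mask()] or 0/1 matrix.
#' @param prune_px Spurs strictly shorter than this many pixels are removed.
#' @return A [binary_vessel_skeleton()].
#' @export
skeletonize <- function(bam, prune_px = 5L) {
  m <- as_binary_matrix(bam, "BAM")
  sk <- zhang_suen(m)
  sk <- remove_redundant_pixels(sk)
  sk <- prune_spurs(sk, prune_px)
  binary_vessel_skeleton(sk)
}

# zero-padded matrix shift: positive dr moves content down (neighbor lookup)
shift0 <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  rs <- seq_len(nr) - dr; cs <- seq_len(nc) - dc
  rok <- rs >= 1L & rs <= nr; cok <- cs >= 1L & cs <= nc
  out[rok, cok] <- m[rs[rok], cs[cok]]
  out
}

# neighbor stack in Zhang-Suen order P2..P9 = N, NE, E, SE, S, SW, W, NW
neighbor_stack <- function(m) {
  offs <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
               c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  lapply(offs, function(o) shift0(m, o[1], o[2]))
}

zhang_suen <- function(m) {
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      p <- neighbor_stack(m)
      b <- Reduce(`+`, p)
      a <- matrix(0, nrow(m), ncol(m))
      for (i in 1:8) {
        nxt <- if (i == 8) 1 else i + 1
        a <- a + (p[[i]] == 0 & p[[nxt]] == 1)
      }
      if (sub == 1) {
        cond <- m == 1 & b >= 2 & b <= 6 & a == 1 &
          p[[1]] * p[[3]] * p[[5]] == 0 & p[[3]] * p[[5]] * p[[7]] == 0
      } else {
        cond <- m == 1 & b >= 2 & b <= 6 & a == 1 &
          p[[1]] * p[[3]] * p[[7]] == 0 & p[[1]] * p[[5]] * p[[7]] == 0
      }
      if (any(cond)) { m[cond] <- 0; changed <- TRUE }
    }
    if (!changed) break
  }
  m
}

# Zhang-Suen leaves staircase corners and occasional 2x2 blocks: pixels with
# >= 2 neighbors whose removal keeps the neighborhood connected (8-simple).
# Removing them sequentially yields a strictly unit-width skeleton while
# preserving topology; a pure diagonal chain is untouched (its neighbors are
# not mutually adjacent, so its pixels are not simple).
remove_redundant_pixels <- function(m) {
  repeat {
    nb <- neighbor_count(m)
    cand <- which(m == 1 & nb >= 2)
    changed <- FALSE
    for (i in cand) {
      r <- ((i - 1L) %% nrow(m)) + 1L
      cc <- ((i - 1L) %/% nrow(m)) + 1L
      if (m[r, cc] == 1 && is_simple_pixel(m, r, cc)) {
        m[r, cc] <- 0
        changed <- TRUE
      }
    }
    if (!changed) return(m)
  }
}

# a pixel is 8-simple if its set neighbors form a single 8-connected
# component among themselves (true pixel adjacency, not ring adjacency), so
# removing it cannot disconnect the skeleton locally
is_simple_pixel <- function(m, r, c) {
  nr <- nrow(m); nc <- ncol(m)
  offs <- rbind(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
                c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  rr <- r + offs[, 1]; cc <- c + offs[, 2]
  ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
  set <- which(ok)[m[cbind(rr[ok], cc[ok])] == 1]
  k <- length(set)
  if (k < 2) return(FALSE)
  # union-find over the set neighbors via pairwise 8-adjacency
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (max(abs(offs[set[i], ] - offs[set[j], ])) <= 1) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  length(unique(vapply(seq_len(k), find, integer(1)))) == 1L
}

# count of set 8-neighbors per pixel
neighbor_count <- function(m) {
  Reduce(`+`, neighbor_stack(m))
}

prune_spurs <- function(m, prune_px) {
  if (prune_px <= 0L || !any(m > 0)) return(m)
  repeat {
    nb <- neighbor_count(m)
    ends <- which(m == 1 & nb == 1, arr.ind = TRUE)
    if (nrow(ends) == 0L) return(m)
    removed_any <- FALSE
    for (k in seq_len(nrow(ends))) {
      trace <- walk_from_endpoint(m, ends[k, 1], ends[k, 2], prune_px)
      if (trace$hit_branch && nrow(trace$pixels) < prune_px) {
        m[trace$pixels] <- 0
        removed_any <- TRUE
      }
    }
    if (!removed_any) return(m)
  }
}

# follow a chain from an endpoint until a junction (>= 3 neighbors), a dead
# end, or max_len pixels traced; returns traced pixels excluding the junction
walk_from_endpoint <- function(m, r, c, max_len) {
  nb <- neighbor_count(m)
  pixels <- matrix(integer(0), 0, 2)
  prev <- c(NA_integer_, NA_integer_)
  cur <- c(r, c)
  hit_branch <- FALSE
  while (nrow(pixels) < max_len) {
    if (nb[cur[1], cur[2]] >= 3) { hit_branch <- TRUE; break }
    pixels <- rbind(pixels, cur)
    nxt <- next_chain_pixel(m, cur, prev)
    if (is.null(nxt)) break
    prev <- cur
    cur <- nxt
  }
  list(pixels = pixels, hit_branch = hit_branch)
}

next_chain_pixel <- function(m, cur, prev) {
  nr <- nrow(m); nc <- ncol(m)
  for (o in list(c(-1, 0), c(0, 1), c(1, 0), c(0, -1),
                 c(-1, 1), c(1, 1), c(1, -1), c(-1, -1))) {
    rr <- cur[1] + o[1]; cc <- cur[2] + o[2]
    if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
    same_prev <- !is.na(prev[1]) && rr == prev[1] && cc == prev[2]
    if (m[rr, cc] == 1 && !same_prev) return(c(rr, cc))
  }
  NULL
}

#' Decompose a vessel skeleton into branch-free segments
#'
#' The skeleton is cut at branch points (pixels with three or more set
#' 8-neighbors, which belong to no segment); each remaining 8-connected
#' chain becomes one segment with its path length (orthogonal step 1,
#' diagonal step sqrt(2)), endpoint chord, and — when a diameter field is
#' supplied — mean diameter and per-segment tortuosity index. Closed loops
#' have zero chord, so a loop is cut at its topmost-leftmost pixel and
#' traversed as one open chain (reported via a message).
#'
#' @param bvs A [binary_vessel_skeleton()] or 0/1 matrix.
#' @param min_len_px Chains with path length below this are discarded.
#' @param dfield Optional [diameter_field()] used to attach per-segment mean
#'   diameters.
#' @return List of `vessel_segment` objects (class `vessel_segments`), with
#'   attributes `n_branch_px` and `n_dropped_px` accounting for skeleton
#'   pixels not assigned to any segment.
#' @export
decompose_segments <- function(bvs, min_len_px = 5, dfield = NULL) {
  m <- as_binary_matrix(bvs, "BVS")
  nb <- neighbor_count(m)
  branch <- m == 1 & nb >= 3
  chains_mat <- m
  chains_mat[branch] <- 0
  lab <- label8(chains_mat)
  n_comp <- max(lab)
  segs <- list()
  dropped <- 0L
  dvals <- if (!is.null(dfield)) dfield$values else NULL
  for (i in seq_len(n_comp)) {
    px <- which(lab == i, arr.ind = TRUE)
    ordered <- order_chain(chains_mat, px)
    seg <- build_segment(ordered, dvals)
    if (seg$length_px >= min_len_px) {
      segs[[length(segs) + 1L]] <- seg
    } else {
      dropped <- dropped + nrow(ordered)
    }
  }
  structure(segs, class = "vessel_segments",
            n_branch_px = sum(branch), n_dropped_px = dropped)
}

# order the pixels of a path-or-cycle component into a chain
order_chain <- function(m, px) {
  if (nrow(px) == 1L) return(px)
  sub <- m * 0
  sub[px] <- 1
  nb <- neighbor_count(sub)
  deg1 <- px[nb[px] == 1, , drop = FALSE]
  if (nrow(deg1) > 0L) {
    o <- order(deg1[, 2], deg1[, 1])
    start <- deg1[o[1], ]
  } else {
    # closed loop: cut at the topmost-leftmost pixel
    o <- order(px[, 2], px[, 1])
    start <- px[o[1], ]
    message("closed-loop segment cut at pixel (", start[1], ", ", start[2], ")")
  }
  out <- matrix(integer(0), 0, 2)
  prev <- c(NA_integer_, NA_integer_)
  cur <- start
  for (step in seq_len(nrow(px))) {
    out <- rbind(out, cur)
    sub[cur[1], cur[2]] <- 0  # visited
    nxt <- next_chain_pixel(sub, cur, prev)
    if (is.null(nxt)) break
    prev <- cur
    cur <- nxt
  }
  out
}

# Chain length: polyline length of the coordinate-smoothed chain (moving
# average, window 5, endpoints pinned). On axis-aligned and diagonal chains
# this equals the (1, sqrt(2)) step metric exactly; on digitally sampled
# curves it removes the ~5-8% zigzag overestimate of raw step sums, which
# would otherwise inflate every tortuosity index multiplicatively.
chain_length <- function(pixels, w = 5L) {
  n <- nrow(pixels)
  if (n < 2L) return(0)
  sm <- cbind(moving_average(pixels[, 1], w), moving_average(pixels[, 2], w))
  sm[1, ] <- pixels[1, ]
  sm[n, ] <- pixels[n, ]
  sum(sqrt(rowSums(diff(sm)^2)))
}

build_segment <- function(pixels, dvals = NULL) {
  n <- nrow(pixels)
  if (n < 2L) {
    len <- 0; chord <- 0
  } else {
    len <- chain_length(pixels)
    chord <- sqrt(sum((pixels[n, ] - pixels[1, ])^2))
  }
  mean_d <- if (!is.null(dvals)) mean(dvals[pixels]) else NA_real_
  ti <- if (chord > 0) (len / chord - 1) * 100 else NA_real_
  structure(list(pixels = pixels, length_px = len, chord_px = chord,
                 mean_diameter_px = mean_d, ti = ti),
            class = "vessel_segment")
}

#' @export
print.vessel_segments <- function(x, ...) {
  cat(sprintf("vessel_segments: %d segments (%d branch px, %d dropped px)\n",
              length(x), attr(x, "n_branch_px"), attr(x, "n_dropped_px")))
  invisible(x)
}

#' Tabulate vessel segments
#'
#' @param x A `vessel_segments` list.
#' @param ... Unused.
#' @return Data frame with one row per segment: id, n_pixels, length_px,
#'   chord_px, mean_diameter_px, ti.
#' @export
as.data.frame.vessel_segments <- function(x, ...) {
  data.frame(id = seq_along(x),
             n_pixels = vapply(x, function(s) nrow(s$pixels), integer(1)),
             length_px = vapply(x, `[[`, numeric(1), "length_px"),
             chord_px = vapply(x, `[[`, numeric(1), "chord_px"),
             mean_diameter_px = vapply(x, `[[`, numeric(1), "mean_diameter_px"),
             ti = vapply(x, `[[`, numeric(1), "ti"))
}

#' Vessel diameter field along the skeleton
#'
#' At each skeleton pixel, twice the Euclidean distance transform of the
#' vessel mask (shortest distance to the vessel edge), i.e. the local vessel
#' diameter in pixels; zero off the skeleton.
#'
#' @param bam A [binary_angio_mask()] or 0/1 matrix.
#' @param bvs A [binary_vessel_skeleton()] derived from `bam`.
#' @return An object of class `diameter_field` with a `values` matrix.
#' @export
diameter_field <- function(bam, bvs) {
  m <- as_binary_matrix(bam, "BAM")
  s <- as_binary_matrix(bvs, "BVS")
  if (any(s > m)) stop("skeleton pixel outside the vessel mask")
  if (all(m == 1)) {
    # no background at all: fall back to the distance to the image border
    warning("mask has no background; using image-border distances")
    d <- outer(pmin(seq_len(nrow(m)), rev(seq_len(nrow(m)))),
               pmin(seq_len(ncol(m)), rev(seq_len(ncol(m)))), pmin)
  } else {
    d <- EBImage::imageData(EBImage::distmap(m, metric = "euclidean"))
  }
  vals <- 2 * d * s
  vals[s == 0] <- 0
  structure(list(values = vals), class = "diameter_field")
}

#' Tortuosity-index skeleton map
#'
#' Each skeleton pixel carries the tortuosity index of its segment;
#' background and branch pixels are zero.
#'
#' @param segments A `vessel_segments` list from [decompose_segments()].
#' @param shape Integer vector (rows, cols) of the source skeleton.
#' @return An object of class `ti_skeleton_map` with a `values` matrix.
#' @export
ti_skeleton_map <- function(segments, shape) {
  out <- matrix(0, shape[1], shape[2])
  seen <- matrix(FALSE, shape[1], shape[2])
  for (seg in segments) {
    if (any(seen[seg$pixels])) stop("overlapping segments")
    seen[seg$pixels] <- TRUE
    out[seg$pixels] <- seg$ti
  }
  structure(list(values = out), class = "ti_skeleton_map")
}
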