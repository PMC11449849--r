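test_that("global Otsu matches the exhaustive 256-bin search oracle", {
  set.seed(51)
  bimodal <- matrix(c(rnorm(300, 30, 4), rnorm(200, 160, 12)), 25, 20)
  expect_equal(global_otsu(bimodal), oracle_otsu(bimodal), tolerance = 1e-9)
  skewed <- matrix(rexp(400, 1 / 20), 20, 20)
  expect_equal(global_otsu(skewed), oracle_otsu(skewed), tolerance = 1e-9)
  half <- matrix(rep(c(10, 200), each = 50), 10, 10)
  th <- global_otsu(half)
  expect_gt(th, 10); expect_lt(th, 200)
  expect_error(global_otsu(matrix(7, 5, 5)), "constant")
})

test_that("global Otsu classifies a bimodal image like EBImage's", {
  set.seed(52)
  img <- matrix(c(runif(200, 0, 0.3), runif(200, 0.6, 1)), 20, 20)
  ours <- global_otsu(img)
  ebi <- EBImage::otsu(EBImage::Image(img), range = c(0, 1), levels = 256)
  expect_identical(img > ours, img > ebi)
})

test_that("adaptive mask matches the brute-force local-mean oracle", {
  set.seed(53)
  img <- matrix(runif(15 * 17), 15, 17)
  img[7:9, ] <- img[7:9, ] + 1  # bright stripe
  got <- adaptive_mask(img, window = 5, offset = 0.1)$mask
  ref <- (img > oracle_local_mean(img, 5) + 0.1) * 1
  expect_identical(got, ref)
  expect_true(all(got[8, 3:15] == 1))
  # uniform image with positive offset: empty mask
  expect_true(all(adaptive_mask(matrix(2, 9, 9), 3, 0.5)$mask == 0))
  expect_error(adaptive_mask(img, window = 4), "odd")
  expect_error(adaptive_mask(img, window = 81), "twice")
})

test_that("vesselness responds to tubes, not blobs or flat regions", {
  expect_true(all(vesselness(matrix(3, 30, 30))$data == 0))
  img <- matrix(0, 60, 60)
  img[29:32, 6:54] <- 1  # tube of width 4
  v <- vesselness(img, scales = c(2, 4))$data
  axis_resp <- mean(v[30, 15:45])
  bg_resp <- mean(v[c(1:15, 46:60), ])
  expect_gt(axis_resp, 0.5)
  expect_lt(bg_resp, 0.05 * axis_resp)
  # blob of equal peak intensity scores below the tube
  blob <- matrix(0, 60, 60)
  xy <- expand.grid(1:60, 1:60)
  blob[] <- exp(-((xy[[1]] - 30)^2 + (xy[[2]] - 30)^2) / (2 * 4))
  tube <- matrix(0, 60, 60)
  tube[] <- exp(-(xy[[1]] - 30)^2 / (2 * 4))
  both <- rbind(cbind(blob, matrix(0, 60, 10) ), cbind(tube, matrix(0, 60, 10)))
  v2 <- vesselness(both, scales = c(2, 4))$data
  expect_gt(max(v2[61:120, 1:60]), max(v2[1:60, 1:60]))
})

test_that("make_bam recovers a noise-free tube and stays strictly binary", {
  tube <- make_tube_fixture(4)
  img <- tube * 0.8
  bam <- make_bam(img)
  expect_true(all(bam$mask %in% c(0, 1)))
  expect_gte(dice_overlap(bam$mask, tube), 0.90)
  empty <- make_bam(matrix(0, 40, 40))
  expect_true(all(empty$mask == 0))
})

test_that("skeletonization thins a bar to a single straight chain", {
  m <- matrix(0, 20, 120)
  m[8:12, 10:109] <- 1
  sk <- skeletonize(binary_angio_mask(m))
  segs <- decompose_segments(sk, 5)
  expect_length(segs, 1)
  expect_lt(abs(segs[[1]]$length_px - 100), 3 + 5)  # end effects + spur prune
  expect_equal(segs[[1]]$ti, 0, tolerance = 1e-9)
  # subset and unit-width invariants
  expect_true(all(sk$skeleton <= m))
  blk <- sk$skeleton
  expect_false(any(blk[-nrow(blk), -ncol(blk)] & blk[-1, -ncol(blk)] &
                     blk[-nrow(blk), -1] & blk[-1, -1] > 0))
  empty <- skeletonize(binary_angio_mask(matrix(0, 10, 10)))
  expect_true(all(empty$skeleton == 0))
})

test_that("segment decomposition cuts at branch points", {
  y <- matrix(0, 40, 40)
  y[cbind(20, 5:20)] <- 1
  y[cbind(20:8, 20:32)] <- 1
  y[cbind(20:32, 20:32)] <- 1
  segs <- decompose_segments(binary_vessel_skeleton(y), 3)
  expect_length(segs, 3)
  # single open curve: one segment
  arc <- make_centerline("arc", list(center = c(40, 40), radius = 25,
                                     theta0 = 0, theta1 = pi))
  chain <- rasterize_tube(arc, 0.5, c(80, 80))
  segs2 <- decompose_segments(skeletonize(binary_angio_mask(chain), 0), 3)
  expect_length(segs2, 1)
  # diagonal chain keeps the sqrt(2) step metric exactly
  d <- matrix(0, 10, 10); d[cbind(2:5, 2:5)] <- 1
  segs3 <- decompose_segments(binary_vessel_skeleton(d), 0)
  expect_equal(segs3[[1]]$length_px, 3 * sqrt(2), tolerance = 1e-12)
})

test_that("skeleton pixels partition into segments, branch and dropped px", {
  set.seed(54)
  ph <- make_structural_phantom(small_phantom_spec(seed = 55))
  q <- quantify_enface(mip(ph$volume, 1:40))
  segs <- q$segments
  seg_px <- sum(vapply(segs, function(s) nrow(s$pixels), integer(1)))
  total <- seg_px + attr(segs, "n_branch_px") + attr(segs, "n_dropped_px")
  expect_identical(total, as.integer(sum(q$bvs$skeleton)))
})

test_that("diameter field matches tube radii via the distance transform", {
  for (r in c(2, 3, 5, 8)) {
    tube <- make_tube_fixture(r)
    sk <- skeletonize(binary_angio_mask(tube))
    df <- diameter_field(tube, sk)
    on_skel <- df$values[sk$skeleton == 1]
    expect_gte(mean(on_skel), 2 * r - 1.5)
    expect_lte(mean(on_skel), 2 * r + 1.5)
    expect_identical((df$values > 0) * 1, sk$skeleton * 1)
  }
  # skeleton outside mask errors
  tube <- make_tube_fixture(3)
  stray <- matrix(0, nrow(tube), ncol(tube)); stray[1, 1] <- 1
  expect_error(diameter_field(tube, stray), "outside")
})

test_that("TI skeleton map carries per-segment values", {
  straight <- matrix(0, 20, 30); straight[10, 5:25] <- 1
  segs <- decompose_segments(binary_vessel_skeleton(straight), 3)
  tm <- ti_skeleton_map(segs, c(20, 30))
  expect_true(all(tm$values[straight == 1] == 0))
  # two segments: map takes exactly values {0, t1, t2}
  two <- matrix(0, 40, 40)
  two[10, 5:35] <- 1                      # straight segment, TI 0
  two[25:35, 25] <- 1; two[35, 26:32] <- 1  # L-shaped segment, TI > 0
  segs2 <- decompose_segments(binary_vessel_skeleton(two), 3)
  tm2 <- ti_skeleton_map(segs2, c(40, 40))
  vals <- sort(unique(as.vector(tm2$values)))
  tis <- sort(vapply(segs2, `[[`, numeric(1), "ti"))
  expect_equal(setdiff(vals, 0), setdiff(unique(tis), 0), tolerance = 1e-12)
})

test_that("rasterized semicircle TI is within 5% of the analytic value", {
  arc <- make_centerline("arc", list(center = c(60, 60), radius = 40,
                                     theta0 = 0, theta1 = pi))
  chain <- rasterize_tube(arc, 0.5, c(120, 120))
  segs <- decompose_segments(skeletonize(binary_angio_mask(chain), 0), 5)
  expect_length(segs, 1)
  expect_equal(segs[[1]]$ti, (pi / 2 - 1) * 100, tolerance = 0.05)
})

test_that("segment TI is stable under 90-degree rotation (< 2%)", {
  cl <- make_centerline("sinusoid", list(start = c(30, 6), span = 108,
                                         amplitude = 8, wavelength = 54))
  tube <- rasterize_tube(cl, 3, c(60, 120))
  rot <- t(tube)[ncol(tube):1, ]  # 90-degree rotation
  ti_of <- function(m) {
    segs <- decompose_segments(skeletonize(binary_angio_mask(m)), 5)
    stats::weighted.mean(vapply(segs, `[[`, numeric(1), "ti"),
                         vapply(segs, `[[`, numeric(1), "length_px"))
  }
  t1 <- ti_of(tube); t2 <- ti_of(rot)
  expect_lt(abs(t1 - t2) / max(t1, 1), 0.02)
})
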