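test_that("vessel area and skeleton densities match counting definitions", {
  expect_equal(vad(matrix(1, 20, 20)), 100)
  m <- matrix(0, 400, 400); m[seq_len(80000)] <- 1
  expect_equal(vad(m), 50)
  line <- matrix(0, 400, 400); line[200, ] <- 1
  expect_equal(vsd(line), 0.25)
  expect_equal(vsd(matrix(0, 10, 10)), 0)
  set.seed(61)
  rnd <- matrix(rbinom(900, 1, 0.3), 30, 30)
  cnt <- 0
  for (i in 1:30) for (j in 1:30) cnt <- cnt + rnd[i, j]
  expect_equal(vad(rnd), 100 * cnt / 900, tolerance = 1e-12)
})

test_that("VSD never exceeds VAD for a mask/skeleton pair", {
  for (s in 1:3) {
    set.seed(s)
    blob <- (matrix(runif(60 * 60), 60, 60) > 0.6) * 1
    blob <- octaq:::fill_small_holes(blob, 50)
    sk <- skeletonize(binary_angio_mask(blob), 2)
    expect_lte(vsd(sk), vad(blob))
    expect_true(all(sk$skeleton <= blob))
  }
})

test_that("VDI equals the diameter-field mean times the pixel size", {
  tube <- make_tube_fixture(3)
  sk <- skeletonize(binary_angio_mask(tube))
  geom <- pixel_geometry(13.125)
  v <- vdi(tube, sk, geom)
  expect_equal(v, 6 * 13.125, tolerance = 13.125)  # within 1 px equivalent
  # exact identity with the diameter field
  df <- diameter_field(tube, sk)
  expect_equal(v, mean(df$values[sk$skeleton == 1]) * 13.125,
               tolerance = 1e-12)
  # uniform diameter field: VDI = d * pixel size exactly
  expect_error(vdi(tube, matrix(0, nrow(tube), ncol(tube)), geom), "empty")
})

test_that("segment TI follows the arc-chord definition", {
  straight <- decompose_segments(binary_vessel_skeleton(
    { m <- matrix(0, 5, 30); m[3, 2:29] <- 1; m }), 3)[[1]]
  expect_equal(segment_ti(straight), 0)
  # ideal right angle: two legs of length L
  leg <- 12
  pts <- rbind(cbind(seq(leg + 1, 1), 1), cbind(1, seq(2, leg + 1)))
  seg <- structure(list(pixels = pts, length_px = 2 * leg,
                        chord_px = leg * sqrt(2), mean_diameter_px = 2,
                        ti = NA), class = "vessel_segment")
  expect_equal(segment_ti(seg), (sqrt(2) - 1) * 100, tolerance = 1e-12)
  # analytic semicircle centerline
  arc <- make_centerline("arc", list(center = c(0, 0), radius = 10,
                                     theta0 = 0, theta1 = pi))
  expect_equal((arc$length_px / arc$chord_px - 1) * 100, (pi / 2 - 1) * 100,
               tolerance = 1e-9)
})

test_that("WTI is the diameter-weighted mean of segment TIs", {
  mk_seg <- function(ti, d) structure(
    list(pixels = matrix(0, 2, 2), length_px = (1 + ti / 100) * 10,
         chord_px = 10, mean_diameter_px = d, ti = ti),
    class = "vessel_segment")
  segs <- list(mk_seg(10, 1), mk_seg(30, 3))
  expect_equal(wti(segs), 25)
  # equal diameters reduce WTI to the unweighted mean TI
  eq <- list(mk_seg(12, 2), mk_seg(40, 2), mk_seg(23, 2))
  expect_equal(wti(eq), mean(c(12, 40, 23)), tolerance = 1e-12)
  # bounded by min and max TI
  set.seed(62)
  rnd <- lapply(1:8, function(i) mk_seg(runif(1, 0, 60), runif(1, 1, 8)))
  tis <- vapply(rnd, `[[`, numeric(1), "ti")
  expect_gte(wti(rnd), min(tis))
  expect_lte(wti(rnd), max(tis))
  expect_error(wti(list()), "no segments")
})

test_that("coefficient of variation uses the population SD convention", {
  expect_equal(round(coefficient_of_variation(c(49.58, 50.05)), 4), 0.0047)
  expect_equal(round(coefficient_of_variation(c(7.12, 7.38)), 4), 0.0179)
  expect_equal(coefficient_of_variation(c(5, 5, 5)), 0)
  expect_error(coefficient_of_variation(c(-1, 1)), "zero mean")
  expect_error(coefficient_of_variation(3), "length")
})

test_that("cohort summaries use Student-t intervals", {
  ci <- cohort_ci(43.32, 8.12, 32)
  expect_equal(round(ci$ci_lower, 2), 40.39)
  expect_equal(round(ci$ci_upper, 2), 46.25)
  ci2 <- cohort_ci(23.39, 4.89, 8)
  expect_equal(round(ci2$ci_lower, 2), 19.30)
  expect_equal(round(ci2$ci_upper, 2), 27.48)
  # from raw values; degenerate n = 2 identical
  cs <- cohort_summary(c(4, 4))
  expect_equal(cs$sd, 0)
  expect_equal(cs$ci_lower, 4)
  expect_equal(cs$ci_upper, 4)
  set.seed(63)
  x <- rnorm(17, 50, 6)
  cs2 <- cohort_summary(x)
  expect_equal(cs2$mean, mean(x))
  expect_equal(cs2$ci_upper - cs2$mean, cs2$mean - cs2$ci_lower)
  expect_error(cohort_summary(5), "n >= 2")
})

test_that("local heatmaps match the brute-force sliding window", {
  set.seed(64)
  mask <- matrix(rbinom(15 * 17, 1, 0.4), 15, 17)
  got <- local_heatmap(mask, 5, "density")
  expect_equal(got, oracle_local_mean(mask, 5), tolerance = 1e-12)
  # uniform mask: constant heatmap equal to global density
  u <- matrix(1, 9, 9)
  expect_true(all(abs(local_heatmap(u, 3, "density") - 1) < 1e-12))
  # diameter mode averages only non-zero (skeleton) values
  dmap <- matrix(0, 11, 11); dmap[6, 3:9] <- 4
  hd <- local_heatmap(dmap, 5, "diameter")
  expect_equal(hd[6, 6], 4)
  expect_equal(hd[1, 1], 0)
  # brute-force oracle for the support-normalized mean
  ref <- matrix(0, 11, 11)
  num <- oracle_local_mean(dmap, 5); den <- oracle_local_mean((dmap != 0) * 1, 5)
  ref[den > 0] <- num[den > 0] / den[den > 0]
  expect_equal(hd, ref, tolerance = 1e-12)
  expect_error(local_heatmap(mask, 4), "odd")
  expect_error(local_heatmap(mask, 51), "larger")
})

test_that("VAD/VSD are rotation-invariant and VDI within 2%", {
  tube <- make_tube_fixture(4)
  rot <- t(tube)[ncol(tube):1, ]
  expect_equal(vad(tube), vad(rot))
  sk1 <- skeletonize(binary_angio_mask(tube))
  sk2 <- skeletonize(binary_angio_mask(rot))
  expect_equal(vsd(sk1) * length(tube), vsd(sk2) * length(rot))
  v1 <- vdi(tube, sk1); v2 <- vdi(rot, sk2)
  expect_lt(abs(v1 - v2) / v1, 0.02)
})

test_that("quantify_enface reports all four metrics on a phantom layer", {
  ph <- make_structural_phantom(small_phantom_spec(seed = 65))
  q <- quantify_enface(mip(ph$volume, 1:40))
  r <- q$report
  expect_gt(r$vad_percent, 0); expect_lte(r$vsd_percent, r$vad_percent)
  expect_gt(r$vdi_um, 0); expect_gte(r$wti, 0)
  expect_identical(r$n_segments, length(q$segments))
})

test_that("heatmaps render to color PNGs with a burned-in scale bar", {
  hm <- local_heatmap(make_tube_fixture(4), 11, "density")
  path <- file.path(tempdir(), "heat.png")
  render_heatmap(hm, path, pixel_geometry(13.125), bar_um = 200)
  img <- png::readPNG(path)
  expect_identical(dim(img)[1:2], dim(hm))
  expect_identical(dim(img)[3], 3L)
  bar <- img[nrow(hm) - 6, 5 + 0:14, ]
  expect_true(all(bar == 1))  # 200 um at 13.125 um/px ~ 15 white px
})
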