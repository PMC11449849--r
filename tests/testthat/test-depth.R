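test_that("depth profile equals per-slice means (loop oracle) and is linear", {
  set.seed(41)
  arr <- array(runif(20 * 6 * 5), c(20, 6, 5))
  prof <- depth_profile(arr, smooth_window = 1)
  ref <- vapply(1:20, function(z) mean(arr[z, , ]), numeric(1))
  expect_equal(prof$intensity, ref, tolerance = 1e-12)
  expect_equal(prof$mean_all, mean(ref))
  # slice z constant = z
  cz <- array(rep(0:9, 4 * 3), c(10, 4, 3))
  for (z in 1:10) cz[z, , ] <- z - 1
  expect_equal(depth_profile(cz, 1)$intensity, as.numeric(0:9))
  # linearity
  brr <- array(runif(20 * 6 * 5), c(20, 6, 5))
  lin <- depth_profile(2 * arr + 3 * brr, 1)$intensity
  expect_equal(lin, 2 * prof$intensity + 3 * depth_profile(brr, 1)$intensity,
               tolerance = 1e-12)
})

test_that("smoothing with window 1 is the identity", {
  set.seed(42)
  arr <- array(runif(15 * 3 * 3), c(15, 3, 3))
  prof <- depth_profile(arr, smooth_window = 1)
  expect_identical(prof$smoothed, prof$intensity)
})

test_that("end depth is the deepest at-or-above-mean index", {
  # linear profile 1 -> 0 over z = 0..99: mean 0.5, crossing at z = 49
  vals <- seq(1, 0, length.out = 100)
  arr <- array(rep(vals, 4), c(100, 2, 2))
  prof <- depth_profile(arr, 1)
  expect_identical(find_end_depth(prof), 49L)
  # scan-all-indices oracle
  expect_identical(max(which(vals >= mean(vals))) - 1L, 49L)
  prof2 <- depth_profile(array(rep(c(2, 2, 0, 0), 2), c(4, 1, 2)), 1)
  expect_identical(find_end_depth(prof2), 1L)
  flat <- depth_profile(array(1, c(10, 2, 2)), 1)
  expect_error(find_end_depth(flat), "constant")
})

test_that("separation depth finds the peak with low-z tie-breaking", {
  mk <- function(vals) depth_profile(array(rep(vals, 4), c(length(vals), 2, 2)), 1)
  single <- rep(0.2, 200); single[121] <- 5; single[150] <- 1
  expect_identical(find_separation_depth(mk(single), z_min = 0L), 120L)
  two <- rep(0.5, 250); two[81] <- 5; two[201] <- 3
  expect_identical(find_separation_depth(mk(two), z_min = 0L), 80L)
  plateau <- rep(0.5, 100); plateau[41:46] <- 4; plateau[60] <- 2
  expect_identical(find_separation_depth(mk(plateau), z_min = 0L), 40L)
  expect_error(find_separation_depth(mk(single), z_min = 199L), "search range")
})

test_that("split_doi partitions depths per the half-open convention", {
  vals <- rep(0.1, 400)
  vals[1:300] <- 0.1 + 0.9 * exp(-((1:300) - 101)^2 / 800)  # peak at z=100
  vals[200:300] <- vals[200:300] + 0.3
  set.seed(43)
  arr <- array(rep(vals, 6) * (1 + 0.01 * runif(2400)), c(400, 2, 3))
  sp <- split_doi(angio_volume(arr), smooth_window = 1)
  expect_identical(dim(sp$doi1$data)[1], sp$split$separation_depth)
  expect_identical(dim(sp$doi2$data)[1],
                   sp$split$end_depth - sp$split$separation_depth)
  expect_lt(abs(sp$split$separation_depth - 100), 3)
  # partition property: max of the two DOI projections = projection to end
  m1 <- mip(sp$doi1)$data
  m2 <- mip(sp$doi2)$data
  all_sig <- mip(angio_volume(arr), seq_len(sp$split$end_depth))$data
  expect_equal(pmax(m1, m2), all_sig, tolerance = 1e-12)
})

test_that("split_doi rejects degenerate splits near top or end", {
  vals <- c(5, 6, rep(1, 28), rep(0.01, 30))  # peak 1 slice below the top
  arr <- array(rep(vals, 4), c(60, 2, 2))
  expect_error(split_doi(angio_volume(arr), smooth_window = 1, z_min = 0L),
               "degenerate")
})

test_that("DOI separation recovers the phantom layer boundary", {
  errs <- vapply(1:6, function(s) {
    ph <- make_structural_phantom(small_phantom_spec(seed = 100 + s))
    prof <- depth_profile(ph$volume)
    find_separation_depth(prof) - ph$truth$boundary_z
  }, numeric(1))
  expect_lte(stats::median(abs(errs)), 3)
  expect_true(all(abs(errs) <= 5))
})

test_that("mip equals the brute-force per-pixel maximum and is monotone", {
  col <- array(0, c(3, 1, 1)); col[, 1, 1] <- c(1, 5, 3)
  expect_equal(mip(angio_volume(col))$data[1, 1], 5)
  set.seed(44)
  arr <- array(runif(12 * 5 * 6), c(12, 5, 6))
  vol <- angio_volume(arr)
  got <- mip(vol, 3:9)$data
  ref <- matrix(0, 5, 6)
  for (i in 1:5) for (j in 1:6) ref[i, j] <- max(arr[3:9, i, j])
  expect_equal(got, ref, tolerance = 0)
  expect_equal(mip(vol, 4)$data, arr[4, , ])
  bump <- array(runif(12 * 5 * 6), c(12, 5, 6))
  expect_true(all(mip(angio_volume(arr + bump))$data >= mip(vol)$data))
  expect_error(mip(vol, integer(0)), "empty")
  expect_error(mip(vol, 13), "outside")
})
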