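test_that("raw binary volumes round-trip exactly with sidecar metadata", {
  set.seed(11)
  vol <- angio_volume(array(runif(24 * 10 * 8 * 3), c(24, 10, 8, 3)),
                      pixel_geometry(10, 5))
  path <- file.path(tempdir(), "vol_rt.raw")
  write_volume(vol, path)
  back <- read_volume(path)
  expect_identical(dim(back$data), dim(vol$data))
  expect_equal(back$data, vol$data, tolerance = 0)
  expect_equal(back$pixel_geometry$lateral_pixel_um, 10)
  expect_equal(back$pixel_geometry$axial_pixel_um, 5)
})

test_that("multi-page TIFF volumes round-trip to float32 precision", {
  set.seed(12)
  vol <- angio_volume(array(runif(16 * 9 * 7) * 40, c(16, 9, 7)))
  path <- file.path(tempdir(), "vol_rt.tif")
  write_volume(vol, path)
  back <- read_volume(path)
  expect_identical(dim(back$data), dim(vol$data))
  expect_equal(back$data, vol$data, tolerance = 1e-6)
})

test_that("read_volume honors a declared axis layout and canonicalizes", {
  # file stored X, Y, Z; declared via explicit layout (no sidecar)
  arr <- array(seq_len(5 * 6 * 7), c(5, 6, 7))  # X=5, Y=6, Z=7 on disk
  path <- file.path(tempdir(), "layout.raw")
  con <- file(path, "wb"); writeBin(as.vector(arr) * 1.0, con); close(con)
  expect_warning(
    vol <- read_volume(path, layout = list(axes = "XYZ", extents = c(5, 6, 7),
                                           dtype = "float64")),
    "no lateral pixel size")
  expect_identical(dim(vol$data), c(7L, 5L, 6L))
  expect_equal(vol$data[3, 2, 4], arr[2, 4, 3])
})

test_that("truncated payloads and missing files are rejected", {
  path <- file.path(tempdir(), "short.raw")
  con <- file(path, "wb"); writeBin(rep(1.0, 10), con); close(con)
  expect_error(
    read_volume(path, layout = list(axes = "ZXY", extents = c(4, 4, 4))),
    "shorter than declared")
  expect_error(read_volume(file.path(tempdir(), "nope.raw")), "not found")
})

test_that("en face export rescales linearly to the full bit range", {
  img <- matrix(c(0, 2, 1, 3), 2, 2)  # values 0,1,2,3
  path <- file.path(tempdir(), "ef.png")
  write_enface(img, path, bit_depth = 8L)
  raw_px <- sort(unique(round(as.vector(png::readPNG(path)) * 255)))
  expect_identical(raw_px, c(0, 85, 170, 255))
  back <- read_enface(path)
  expect_equal(back$data, img, tolerance = 3 / 255)
})

test_that("16-bit en face round trip preserves intensity ordering", {
  set.seed(13)
  img <- matrix(runif(64) * 100, 8, 8)
  path <- file.path(tempdir(), "ef16.tif")
  write_enface(img, path, bit_depth = 16L)
  back <- read_enface(path)$data
  expect_identical(order(back), order(img))
  expect_equal(back, img, tolerance = 100 / 65535 * 2)
})

test_that("degenerate en face inputs are handled", {
  expect_error(write_enface(matrix(1, 3, 3),
                            file.path(tempdir(), "x.png"), bit_depth = 12),
               "8 or 16")
  expect_warning(write_enface(matrix(5, 3, 3),
                              file.path(tempdir(), "const.png"), 8L),
                 "constant")
  expect_true(all(png::readPNG(file.path(tempdir(), "const.png")) == 0))
})

test_that("mask PNG round trip is exact 0/255", {
  m <- matrix(rbinom(48, 1, 0.4), 6, 8)
  path <- file.path(tempdir(), "mask.png")
  write_mask(m, path)
  expect_identical(read_mask(path), m * 1)
})

test_that("metrics reports serialize with units and round-trip losslessly", {
  rep <- metrics_report(vad_percent = 53.26, vsd_percent = 7.00,
                        vdi_um = 91.04, wti = 20.30, mean_ti = 18.1,
                        n_segments = 120L, doi_label = "DOI 1")
  jpath <- file.path(tempdir(), "rep.json")
  cpath <- file.path(tempdir(), "rep.csv")
  write_report(rep, jpath)
  write_report(rep, cpath)
  jr <- read_report(jpath)
  expect_setequal(jr$metric, c("VAD", "VSD", "VDI", "WTI", "mean_TI",
                               "n_segments"))
  expect_equal(jr$value[jr$metric == "VAD"], 53.26)
  expect_equal(jr$value[jr$metric == "VDI"], 91.04)
  expect_equal(jr$unit[jr$metric == "VDI"], "um")
  expect_equal(jr$value[jr$metric == "WTI"], 20.30)
  cr <- read_report(cpath)
  expect_equal(cr$value, jr$value, tolerance = 1e-12)
})

test_that("an empty report still yields a valid header-only CSV", {
  path <- file.path(tempdir(), "empty.csv")
  write_report(data.frame(metric = character(0), value = numeric(0)), path)
  back <- read_report(path)
  expect_identical(nrow(back), 0L)
  expect_identical(names(back), c("metric", "value"))
})
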