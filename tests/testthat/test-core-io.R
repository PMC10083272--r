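test_that("ENVI write/read round-trips values, wavelengths and role exactly", {
  for (role in c("raw", "reflectance")) {
    cube <- tiny_cube(role = role)
    path <- file.path(withr::local_tempdir(), "cube.hdr")
    write_cube(cube, path)
    back <- read_cube(path)
    expect_identical(back$values, cube$values)
    expect_equal(back$wavelengths, cube$wavelengths)
    expect_identical(back$role, role)
  }
})

test_that("a 1x1x1 degenerate cube round-trips without error", {
  cube <- spectral_cube(array(0.5, c(1, 1, 1)), 700, role = "reflectance")
  path <- file.path(withr::local_tempdir(), "tiny.hdr")
  write_cube(cube, path)
  back <- read_cube(path)
  expect_equal(back$values, cube$values)
})

test_that("unsorted wavelengths are re-sorted with slices permuted consistently", {
  vals <- array(0, c(2, 2, 3))
  vals[, , 1] <- 7; vals[, , 2] <- 5; vals[, , 3] <- 6
  cube <- spectral_cube(vals, c(700, 500, 600), role = "raw")
  expect_equal(cube$wavelengths, c(500, 600, 700))
  expect_equal(unique(as.vector(cube$values[, , 1])), 5)
  expect_equal(unique(as.vector(cube$values[, , 2])), 6)
  expect_equal(unique(as.vector(cube$values[, , 3])), 7)
  # multiset of (wavelength, slice) pairs is unchanged: check via sums
  expect_equal(sum(cube$values), sum(vals))
})

test_that("reading rejects missing wavelength metadata and truncated data", {
  cube <- tiny_cube()
  dir <- withr::local_tempdir()
  path <- file.path(dir, "c.hdr")
  write_cube(cube, path)
  hdr <- readLines(path)
  writeLines(hdr[!grepl("^wavelength =", hdr)], path)
  expect_error(read_cube(path), "wavelength")
  # rectangularity: truncate the binary twin
  write_cube(cube, path)
  dat <- file.path(dir, "c.dat")
  bytes <- readBin(dat, "raw", file.size(dat))
  writeBin(bytes[seq_len(length(bytes) - 8)], dat)
  expect_error(read_cube(path), "rectangular")
})

test_that("spectral matrix CSV round-trips values, wavelengths and ids", {
  m <- spectral_matrix(matrix(c(0.1, 0.2, 0.3, 0.4), 2, 2),
                       c(500.5, 600.25), row_ids = c("a", "b"))
  path <- file.path(withr::local_tempdir(), "m.csv")
  write_spectra_csv(m, path)
  back <- read_spectra_csv(path)
  expect_equal(back$values, m$values)
  expect_equal(back$wavelengths, m$wavelengths)
  expect_equal(back$row_ids, m$row_ids)
})

test_that("cube invariants are enforced", {
  expect_error(spectral_cube(array(1, c(2, 2, 3)), c(1, 2), "raw"), "band")
  expect_error(spectral_cube(array(c(NA, rep(1, 11)), c(2, 2, 3)),
                             1:3, "reflectance"), "finite")
  expect_error(spectral_cube(array(-1, c(2, 2, 3)), 1:3, "dark"),
               "non-negative")
})

test_that("nearest-band lookup resolves ties toward the lower wavelength", {
  wl <- c(500, 600, 700)
  expect_equal(nearest_band(wl, 550), 1L)  # tie: 500 wins
  expect_equal(nearest_band(wl, 551), 2L)
  expect_equal(nearest_band(wl, 700), 3L)
  expect_error(nearest_band(wl, 800, tol = 10), "no band")
})
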