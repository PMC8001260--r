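test_that("peak lists are read sorted, with header and delimiter detection", {
  f <- tempfile(fileext = ".csv")
  writeLines("150.1,10\n200.2,5\n160.0,7", f)
  s <- read_peaklist(f)
  expect_s3_class(s, "spectrum")
  expect_equal(s$peaks$mz, c(150.1, 160.0, 200.2))
  expect_equal(s$peaks$intensity, c(10, 7, 5))

  writeLines("mz,intensity\n150.1,10\n160.0,7", f)
  expect_equal(n_peaks(read_peaklist(f)), 2)

  writeLines("intensity\tmz\tsnr\n10\t150.1\t3", f)
  s <- read_peaklist(f)
  expect_equal(s$peaks$mz, 150.1)
  expect_equal(s$peaks$snr, 3)
})

test_that("malformed peak lists fail loudly, naming the offending lines", {
  f <- tempfile(fileext = ".csv")
  expect_error(read_peaklist(f), "not found")
  writeLines("", f)
  expect_error(read_peaklist(f), "empty")
  writeLines("150.1,10\noops,5\n160.0,abc", f)
  expect_error(read_peaklist(f), "line\\(s\\): 2, 3")
  writeLines("150.1", f)
  expect_error(read_peaklist(f), "fewer than two")
})

test_that("write/read round trip preserves values to 1e-6", {
  s <- random_spectrum(200, seed = 42)
  s$peaks$snr <- runif(200, 0, 50)
  s$peaks$formula <- NA_character_
  s$peaks$formula[1] <- "C6H12O6"
  f <- tempfile(fileext = ".csv")
  write_peaklist(s, f)
  s2 <- read_peaklist(f, sample_id = s$sample_id)
  expect_equal(s2$peaks$mz, s$peaks$mz, tolerance = 1e-6)
  expect_equal(s2$peaks$intensity, s$peaks$intensity, tolerance = 1e-6)
  expect_equal(s2$peaks$snr, s$peaks$snr, tolerance = 1e-6)
  expect_equal(s2$peaks$formula[1], "C6H12O6")
})

test_that("Kendrick quantities follow the CH2 scaling", {
  k <- compute_kendrick(140.15650)  # 10 x CH2
  expect_equal(k$kendrick_mass, 140, tolerance = 1e-9)
  expect_equal(k$kmd_mDa, 0, tolerance = 1e-6)

  k <- compute_kendrick(255.23295)  # palmitate [M-H]-
  expect_equal(k$kendrick_mass, 255.23295 * 14.00000 / 14.01565,
               tolerance = 1e-12)
  expect_equal(k$nominal_mass, 255)
  expect_equal(k$kmd_mDa, 52.045, tolerance = 1e-3)

  expect_error(compute_kendrick(-1), "positive")
})

test_that("KMD is bounded and shared along CH2 homologous series", {
  set.seed(7)
  mz <- runif(500, 100, 900)
  k <- compute_kendrick(mz)
  expect_true(all(k$kmd_mDa > -500 & k$kmd_mDa <= 500))
  # homologues: adding CH2 leaves the KMD unchanged
  k2 <- compute_kendrick(mz + 14.01565)
  expect_true(all(abs(k2$kmd_mDa - k$kmd_mDa) < 1e-9))
})

test_that("window filter is inclusive, S/N filter strict, both idempotent", {
  s <- spectrum(c(149.9, 150.0, 750.0, 750.1), rep(1, 4))
  expect_equal(filter_peaks(s)$peaks$mz, c(150, 750))

  s <- spectrum(c(200, 300, 400), rep(1, 3), snr = c(1.9, 2.0, 2.1))
  expect_equal(filter_peaks(s, snr_min = 2)$peaks$mz, 400)

  s <- spectrum(c(200, 300), c(1, 1))  # no S/N column: all in-window kept
  expect_equal(n_peaks(filter_peaks(s)), 2)

  s <- random_spectrum(300, seed = 3)
  once <- filter_peaks(s)
  expect_identical(filter_peaks(once), once)
  expect_error(filter_peaks(s, 300, 200), "mz_min")
})

test_that("parity split partitions by nearest-integer mass", {
  s <- spectrum(c(150.02, 151.05, 152.9), rep(1, 3))
  pr <- split_parity(s)
  expect_equal(pr$even$peaks$mz, 150.02)
  expect_equal(pr$odd$peaks$mz, c(151.05, 152.9))  # 152.9 rounds to 153
  expect_equal(pr$even$parity, "even")
  expect_equal(pr$odd$parity, "odd")
  expect_error(split_parity(pr$even), "already split")

  s <- spectrum(c(150.1, 152.2, 154.0), rep(1, 3))
  expect_equal(n_peaks(split_parity(s)$odd), 0)

  for (seed in 1:5) {
    s <- random_spectrum(200, seed)
    pr <- split_parity(s)
    expect_equal(n_peaks(pr$even) + n_peaks(pr$odd), n_peaks(s))
    expect_length(intersect(pr$even$peaks$mz, pr$odd$peaks$mz), 0)
  }
})

test_that("manifest round trip and dataset loading work", {
  dir <- tempfile()
  gd <- generate_dataset(per_class = 1, master_seed = 5, out_dir = dir)
  spectra <- read_dataset(file.path(dir, "manifest.csv"))
  expect_length(spectra, 4)
  expect_setequal(vapply(spectra, `[[`, "", "label"),
                  c("Biological", "Meteorite", "Petroleum", "Synthetic"))
  expect_equal(spectra[[1]]$peaks$mz, gd$spectra[[1]]$peaks$mz,
               tolerance = 1e-6)
})
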