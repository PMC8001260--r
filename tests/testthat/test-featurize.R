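cfg <- histogram_config()

test_that("abundance coordinate places mean-log, midpoint and top peaks", {
  ml <- 10
  expect_equal(abundance_coordinate(exp(ml), ml, cfg), 0.5 / 9.2)
  expect_equal(abundance_coordinate(exp(ml + 4.1), ml, cfg), 0.5)
  expect_equal(abundance_coordinate(exp(ml + 8.7), ml, cfg), 1.0)
  expect_error(abundance_coordinate(0, ml, cfg), "positive")
})

test_that("histogram counts match geometry and conserve in-range peaks", {
  empty <- spectrum(numeric(0), numeric(0))
  counts <- bin_counts(empty, cfg)
  expect_equal(dim(counts), c(32L, 32L, 5L))
  expect_true(all(counts == 0))

  # single peak at the window edge lands in the first 18.75 Da mass bin
  s1 <- spectrum(150.0, 100)
  counts <- bin_counts(s1, cfg)
  expect_equal(which(apply(counts, 1, sum) > 0), 1L)
  expect_equal(sum(counts), 1)

  for (seed in 1:5) {
    s <- random_spectrum(500, seed)
    counts <- bin_counts(s, cfg)
    y <- abundance_coordinate(s$peaks$intensity,
                              mean(log(s$peaks$intensity)), cfg)
    expect_equal(sum(counts), sum(y >= 0 & y <= 1))
    expect_equal(sum(counts), attr(counts, "n_used"))
  }
})

test_that("mass-axis normalisation follows the stabilised column quotient", {
  counts <- array(0L, dim = c(32, 32, 5))
  counts[1:3, 1, 1] <- c(2L, 0L, 3L)
  n <- normalize_counts(counts, cfg)
  expect_equal(n[1:3, 1, 1], c(2, 0, 3) / (5 + 1e-8))
  expect_equal(sum(n[, 1, 1]), 5 / (5 + 1e-8))
  expect_true(all(n[, 2, ] == 0))  # empty columns stay zero
  # every nonzero column sums to T/(T+eps) < 1
  s <- random_spectrum(800, seed = 11)
  n <- normalize_counts(bin_counts(s, cfg), cfg)
  sums <- apply(n, c(2, 3), sum)
  expect_true(all(sums < 1))
})

test_that("truncated log transform has the printed bounds and is monotone", {
  expect_equal(log_transform(0, cfg), 0.5 * log(0.1) + 1.25)
  expect_equal(log_transform(0, cfg), 0.0987075, tolerance = 1e-6)
  expect_equal(log_transform(1, cfg), 1.2976551, tolerance = 1e-6)
  grid <- seq(0, 1, length.out = 201)
  x <- log_transform(grid, cfg)
  expect_true(all(diff(x) > 0))
  expect_error(log_transform(-0.01, cfg), "\\[0, 1\\]")
  expect_error(log_transform(1.01, cfg), "\\[0, 1\\]")
})

test_that("featurization is deterministic and floor-valued on empty input", {
  img <- featurize_spectrum(spectrum(numeric(0), numeric(0)), cfg)
  expect_true(all(abs(img$x - (0.5 * log(0.1) + 1.25)) < 1e-12))
  s <- random_spectrum(400, seed = 2)
  expect_identical(featurize_spectrum(s, cfg)$x, featurize_spectrum(s, cfg)$x)
})

test_that("featurization equals the brute-force oracle", {
  # a tiny hand-built spectrum plus random fixtures
  hand <- spectrum(c(150.0, 151.7, 400.03, 700.0, 749.99),
                   c(10, 1e4, 5e2, 3e3, 80))
  cases <- c(list(hand), lapply(1:8, function(i) random_spectrum(600, i)))
  for (s in cases) {
    img <- featurize_spectrum(s, cfg)
    oracle <- featurize_oracle(s, cfg)
    expect_equal(unname(as.vector(img$counts)), as.vector(oracle$counts))
    expect_equal(as.vector(img$x), as.vector(oracle$x), tolerance = 1e-12)
  }
})

test_that("feature images are invariant to intensity rescaling", {
  for (const in c(2, 1e3, 0.017)) {
    s <- random_spectrum(500, seed = 9)
    scaled <- s
    scaled$peaks$intensity <- scaled$peaks$intensity * const
    expect_identical(featurize_spectrum(s, cfg)$x,
                     featurize_spectrum(scaled, cfg)$x)
  }
})

test_that("flattening is mass-major and exactly invertible", {
  img <- featurize_spectrum(random_spectrum(300, 4), cfg)
  v <- flatten_image(img)
  expect_length(v, 5120)
  expect_identical(unflatten_image(v, cfg), img$x)

  toy <- histogram_config(n_mz_bins = 4, n_abund_bins = 4, n_kmd_bins = 2)
  x <- array(seq_len(32), dim = c(4, 4, 2))
  v <- flatten_image(x)
  expect_length(v, 32)
  # element ((i-1)*n_abund + (j-1))*n_kmd + k of v is x[i, j, k]
  for (i in 1:4) for (j in 1:4) for (k in 1:2)
    expect_equal(v[((i - 1) * 4 + (j - 1)) * 2 + k], x[i, j, k])
  expect_identical(unflatten_image(v, toy), x)
})

test_that("dataset assembly stacks two parity points per sample", {
  gd <- generate_dataset(per_class = 2, master_seed = 1)
  ds <- featurize_dataset(gd$spectra)
  expect_equal(dim(ds$features), c(16L, 5120L))
  expect_true(all(table(ds$groups) == 2))
  expect_equal(nlevels(ds$labels), 4)
  expect_error(labeled_dataset(ds$features, ds$labels[-1]), "match")
  expect_error(labeled_dataset(matrix(0, 3, 2), c("a", "a", "a"),
                               groups = c("s", "s", "s")), "at most twice")
})
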