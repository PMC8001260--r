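# Independent oracle: exhaustive pairwise comparison of residue-sum masses.
dkp_oracle <- function(tol = 1e-4) {
  res <- amino_acid_residues()
  idx <- cbind(utils::combn(20, 2), rbind(1:20, 1:20))
  sums <- res$mass[idx[1, ]] + res$mass[idx[2, ]]
  n_unique <- 0L
  multi <- 0L
  assigned <- rep(FALSE, length(sums))
  for (a in seq_along(sums)) {
    if (assigned[a]) next
    grp <- which(abs(sums - sums[a]) <= tol)
    assigned[grp] <- TRUE
    n_unique <- n_unique + 1L
    if (length(grp) > 1) multi <- multi + 1L
  }
  list(n_pairs = length(sums), n_unique = n_unique, n_multi = multi)
}

test_that("the residue table encodes standard monoisotopic chemistry", {
  tab <- amino_acid_residues()
  expect_equal(nrow(tab), 20)
  expect_true(all(tab$mass > 0))
  expect_equal(tab$mass[tab$code == "Gly"], 57.02146, tolerance = 1e-5)
  expect_identical(tab$mass[tab$code == "Leu"], tab$mass[tab$code == "Ile"])
})

test_that("DKP enumeration merges exact formula coincidences", {
  d <- enumerate_dkp_masses()
  expect_s3_class(d, "target_mass_list")
  expect_true(all(diff(d$mass) > 0))
  # cGlyGly: twice the Gly residue
  expect_equal(min(d$mass), 114.04293, tolerance = 1e-5)
  # Gly+Glu and Ala+Asp are the same elemental formula C7H10N2O4
  hit <- d[abs(d$mass - 186.06406) < 1e-4, ]
  expect_equal(nrow(hit), 1)
  expect_setequal(hit$compositions[[1]], c("cGlyGlu", "cAlaAsp"))
  # Leu/Ile sequence degeneracy is merged
  trio <- d[vapply(d$compositions, function(cc) "cLeuIle" %in% cc, TRUE), ]
  expect_setequal(trio$compositions[[1]], c("cLeuIle", "cLeuLeu", "cIleIle"))
  expect_error(enumerate_dkp_masses(merge_tol = -1), "non-negative")
})

test_that("DKP enumeration agrees with the exhaustive pairwise oracle", {
  oracle <- dkp_oracle()
  d <- enumerate_dkp_masses()
  expect_equal(oracle$n_pairs, 210)
  expect_equal(nrow(d), oracle$n_unique)
  expect_equal(sum(lengths(d$compositions) > 1), oracle$n_multi)
  expect_equal(sum(lengths(d$compositions)), 210)  # every pair accounted for
})

test_that("the SFA series is a CH2 ladder with correct endpoints", {
  sfa <- sfa_series(2, 20)
  expect_equal(sfa$mass[1], 60.02113, tolerance = 1e-5)   # acetic acid
  expect_equal(sfa$mass[15], 256.24023, tolerance = 1e-5) # palmitic acid
  ch2 <- 12 + 2 * 1.00782503207
  expect_true(all(abs(diff(sfa$mass) - ch2) < 1e-9))
  expect_error(sfa_series(1, 5), "c_min")
})

test_that("adduct m/z is the deprotonated mass and is monotone", {
  expect_equal(to_mz(114.04293), 113.03565, tolerance = 1e-5)
  expect_equal(to_mz(256.24023), 255.23295, tolerance = 1e-5)
  m <- sort(runif(50, 100, 700))
  expect_true(all(diff(to_mz(m)) > 0))
  expect_error(to_mz(100, adduct = "[M+H]+"), "unsupported")
})

test_that("peak matching finds planted targets within ppm tolerance", {
  d <- enumerate_dkp_masses()
  targets <- d[d$mass > 160 & d$mass < 400, ][1:5, ]
  class(targets) <- c("target_mass_list", "data.frame")
  planted <- to_mz(targets$mass)
  s <- spectrum(c(planted, 180.05, 300.123), rep(100, 7), sample_id = "hit")
  res <- match_peaks(s, targets, ppm_tol = 1)
  expect_true(all(res$matched))
  expect_true(all(abs(res$ppm_error) < 1e-6))
  expect_equal(attr(res, "summary")$n_matched, 5)

  # strict zero tolerance rejects 1 ppm offsets
  off <- spectrum(planted * (1 + 1e-6), rep(1, 5))
  res <- match_peaks(off, targets, ppm_tol = 0)
  expect_equal(sum(res$matched), 0)

  # widening the tolerance never removes a match (monotone)
  res1 <- match_peaks(off, targets, ppm_tol = 0.5)
  res2 <- match_peaks(off, targets, ppm_tol = 2)
  expect_true(all(res2$matched[res1$matched]))
})

test_that("targets below the detection cutoff are flagged and excluded", {
  d <- enumerate_dkp_masses()
  s <- spectrum(runif(100, 150, 750), rep(1, 100))
  res <- match_peaks(s, d, ppm_tol = 1, mz_min = 150)
  below <- res[res$below_cutoff, ]
  # direct computation places four DKPs below m/z 150
  expect_setequal(unlist(below$compositions),
                  c("cGlyGly", "cGlyAla", "cAlaAla", "cGlySer"))
  expect_false(any(below$matched))
  summ <- attr(res, "summary")
  expect_equal(summ$n_measurable, summ$n_targets - nrow(below))
})
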