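# Group sorted masses: new group wherever the gap to the previous mass
# exceeds tol. With exact formula coincidences the within-group spread is
# ~0, so chaining is not a concern at the default 1e-4 Da.
.merge_masses <- function(mass, comps, tol) {
  o <- order(mass)
  mass <- mass[o]; comps <- comps[o]
  grp <- cumsum(c(1, diff(mass) > tol))
  data.frame(mass = as.vector(tapply(mass, grp, mean)),
             compositions = I(unname(split(comps, grp))))
}

#' Enumerate diketopiperazine target masses
#'
#' Diketopiperazines (DKPs) are cyclic dipeptides: double condensation of
#' two amino acids, so the neutral monoisotopic mass is the sum of the two
#' residue masses (the two waters of cyclisation are accounted for by using
#' residue rather than free-amino-acid masses). All 210 unordered pairs of
#' the 20 coded amino acids are enumerated — cyclisation makes cAlaGly and
#' cGlyAla one structure — and masses within `merge_tol` are merged into a
#' single entry listing every contributing composition. At the default
#' tolerance all merges are exact elemental-formula coincidences: the 20
#' sequence degeneracies from Leu = Ile plus 13 cross-pair identities such
#' as Gly+Glu = Ala+Asp (C7H10N2O4), leaving 177 unique masses.
#'
#' @param residues residue-mass table, by default [amino_acid_residues()].
#' @param merge_tol masses closer than this (Da) merge into one entry;
#'   default 1e-4. Must be >= 0.
#' @return An object of class `"target_mass_list"`: data frame with
#'   strictly increasing `mass` (Da, neutral), `series` (`"DKP"`) and a
#'   `compositions` list column of contributing pair names.
#' @export
enumerate_dkp_masses <- function(residues = amino_acid_residues(),
                                 merge_tol = 1e-4) {
  if (merge_tol < 0) stop("merge_tol must be non-negative")
  n <- nrow(residues)
  idx <- cbind(utils::combn(n, 2), rbind(seq_len(n), seq_len(n)))
  mass <- residues$mass[idx[1, ]] + residues$mass[idx[2, ]]
  comps <- paste0("c", residues$code[idx[1, ]], residues$code[idx[2, ]])
  out <- .merge_masses(mass, comps, merge_tol)
  out$series <- "DKP"
  structure(out[c("mass", "series", "compositions")],
            class = c("target_mass_list", "data.frame"))
}

#' Saturated fatty acid (SFA) target masses
#'
#' Neutral monoisotopic masses of the straight-chain alkanoic acids
#' CnH2nO2 for carbon numbers `c_min:c_max`, computed from elemental
#' monoisotopic masses. Consecutive members differ by exactly one CH2.
#'
#' @param c_min,c_max carbon-number range, `2 <= c_min <= c_max`.
#' @return A `"target_mass_list"` (columns `mass`, `series`,
#'   `compositions`).
#' @examples
#' sfa_series(16, 16)$mass  # palmitic acid, 256.24023
#' @export
sfa_series <- function(c_min = 2, c_max = 40) {
  if (c_min < 2 || c_min > c_max) stop("need 2 <= c_min <= c_max")
  n <- seq(c_min, c_max)
  mass <- n * .elements[["C"]] + 2 * n * .elements[["H"]] + 2 * .elements[["O"]]
  out <- data.frame(mass = mass, series = "SFA",
                    compositions = I(as.list(sprintf("C%dH%dO2", n, 2 * n))))
  structure(out, class = c("target_mass_list", "data.frame"))
}

#' @export
print.target_mass_list <- function(x, n = 6, ...) {
  cat(sprintf("<target_mass_list> %d targets (%s)\n", nrow(x),
              paste(unique(x$series), collapse = ", ")))
  show <- utils::head(x, n)
  for (i in seq_len(nrow(show)))
    cat(sprintf("  %10.5f  %s\n", show$mass[i],
                paste(show$compositions[[i]], collapse = ", ")))
  if (nrow(x) > n) cat("  ...\n")
  invisible(x)
}

#' Expected m/z of a neutral mass under an ionisation adduct
#'
#' For negative electrospray the dominant species is the deprotonated
#' molecule: `[M-H]-` with m/z = M minus one proton mass (1.00727646 Da),
#' charge 1.
#'
#' @param neutral_mass numeric vector of neutral monoisotopic masses (Da).
#' @param adduct adduct identifier; only `"[M-H]-"` is supported.
#' @return Numeric m/z vector.
#' @export
to_mz <- function(neutral_mass, adduct = "[M-H]-") {
  if (!identical(adduct, "[M-H]-"))
    stop("unsupported adduct: ", adduct)
  neutral_mass - .proton_mass
}

#' Match target masses against a measured peak list
#'
#' Converts each target's neutral mass to the adduct m/z and looks for a
#' measured peak within `ppm_tol` parts per million. The nearest peak is
#' reported per target. Targets whose expected m/z falls below `mz_min`
#' (the instrument detection cutoff) are flagged `below_cutoff` and
#' excluded from the measurable denominator and from matching. Widening
#' `ppm_tol` never removes a match.
#'
#' @param s a [spectrum()].
#' @param targets a `"target_mass_list"` from [enumerate_dkp_masses()] or
#'   [sfa_series()].
#' @param adduct see [to_mz()].
#' @param ppm_tol match tolerance in ppm (> 0); default 1, appropriate for
#'   FT-ICR mass accuracy.
#' @param mz_min detection cutoff applied to the expected m/z (default
#'   150); `NULL` disables the cutoff flag.
#' @return An object of class `"match_result"`: data frame with one row per
#'   target (`mass`, `series`, `expected_mz`, `below_cutoff`, `obs_mz`,
#'   `ppm_error`, `matched`, `peak_index`) and a `summary` attribute of
#'   per-series counts (`n_targets`, `n_measurable`, `n_matched`).
#' @export
match_peaks <- function(s, targets, adduct = "[M-H]-", ppm_tol = 1,
                        mz_min = 150) {
  stopifnot(inherits(s, "spectrum"), inherits(targets, "target_mass_list"))
  if (ppm_tol < 0) stop("ppm_tol must be non-negative")
  expected <- to_mz(targets$mass, adduct)
  below <- if (is.null(mz_min)) rep(FALSE, length(expected)) else expected < mz_min
  mz <- s$peaks$mz
  res <- data.frame(mass = targets$mass,
                    series = targets$series,
                    expected_mz = expected,
                    below_cutoff = below,
                    obs_mz = NA_real_,
                    ppm_error = NA_real_,
                    matched = FALSE,
                    peak_index = NA_integer_)
  if (length(mz)) {
    # nearest measured peak per target (peaks are sorted ascending)
    pos <- findInterval(expected, mz)
    lo <- pmax(pos, 1L); hi <- pmin(pos + 1L, length(mz))
    d_lo <- abs(mz[lo] - expected); d_hi <- abs(mz[hi] - expected)
    nearest <- ifelse(d_lo <= d_hi, lo, hi)
    res$obs_mz <- mz[nearest]
    res$ppm_error <- (res$obs_mz - expected) / expected * 1e6
    res$peak_index <- nearest
    res$matched <- !below & abs(res$ppm_error) <= ppm_tol
    res$obs_mz[below] <- NA_real_
    res$ppm_error[below] <- NA_real_
    res$peak_index[below] <- NA_integer_
  }
  res$compositions <- targets$compositions
  summ <- do.call(rbind, lapply(split(res, res$series), function(d) {
    data.frame(series = d$series[1],
               n_targets = nrow(d),
               n_measurable = sum(!d$below_cutoff),
               n_matched = sum(d$matched))
  }))
  rownames(summ) <- NULL
  structure(res, summary = summ,
            class = c("match_result", "data.frame"))
}

#' @export
print.match_result <- function(x, ...) {
  s <- attr(x, "summary")
  cat("<match_result>\n")
  print(s, row.names = FALSE)
  hits <- x[x$matched, ]
  if (nrow(hits)) {
    cat("  matches:\n")
    for (i in seq_len(min(nrow(hits), 10)))
      cat(sprintf("  %10.5f -> obs %10.5f (%+.3f ppm)  %s\n",
                  hits$expected_mz[i], hits$obs_mz[i], hits$ppm_error[i],
                  paste(hits$compositions[[i]], collapse = ", ")))
    if (nrow(hits) > 10) cat("  ...\n")
  }
  invisible(x)
}
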