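# Monoisotopic masses (Da), CODATA/AME-derived values as tabulated in
# standard mass-spectrometry references.
.elements <- c(
  C = 12.0,
  H = 1.00782503207,
  N = 14.0030740048,
  O = 15.9949146196,
  S = 31.97207100
)

# Mass of a proton; [M-H]- m/z = M - .proton_mass for singly charged anions.
.proton_mass <- 1.007276466

# CH2 repeat unit, the Kendrick base.
.ch2_mass <- 14.01565

# Kendrick scaling factor: the paper's convention, exact nominal CH2 mass 14
# over its monoisotopic mass.
.kendrick_factor <- 14.00000 / 14.01565

#' Monoisotopic residue masses of the 20 coded amino acids
#'
#' Residue mass is the free amino acid minus one water: the incremental mass
#' an amino acid contributes inside a peptide. Masses are computed from
#' elemental monoisotopic masses, so exact elemental-formula coincidences
#' (e.g. Leu and Ile, both C6H11NO) are exactly equal.
#'
#' @return A data frame with one row per amino acid: three-letter `code`,
#'   elemental counts `C`, `H`, `N`, `O`, `S` of the residue, and
#'   monoisotopic residue `mass` in Da.
#' @examples
#' tab <- amino_acid_residues()
#' tab[tab$code == "Gly", "mass"]  # 57.02146
#' @export
amino_acid_residues <- function() {
  counts <- rbind(
    Gly = c(2, 3, 1, 1, 0),  Ala = c(3, 5, 1, 1, 0),
    Ser = c(3, 5, 1, 2, 0),  Pro = c(5, 7, 1, 1, 0),
    Val = c(5, 9, 1, 1, 0),  Thr = c(4, 7, 1, 2, 0),
    Cys = c(3, 5, 1, 1, 1),  Leu = c(6, 11, 1, 1, 0),
    Ile = c(6, 11, 1, 1, 0), Asn = c(4, 6, 2, 2, 0),
    Asp = c(4, 5, 1, 3, 0),  Gln = c(5, 8, 2, 2, 0),
    Lys = c(6, 12, 2, 1, 0), Glu = c(5, 7, 1, 3, 0),
    Met = c(5, 9, 1, 1, 1),  His = c(6, 7, 3, 1, 0),
    Phe = c(9, 9, 1, 1, 0),  Arg = c(6, 12, 4, 1, 0),
    Tyr = c(9, 9, 1, 2, 0),  Trp = c(11, 10, 2, 1, 0)
  )
  colnames(counts) <- c("C", "H", "N", "O", "S")
  mass <- drop(counts %*% .elements[colnames(counts)])
  data.frame(code = rownames(counts), counts, mass = mass,
             row.names = NULL, stringsAsFactors = FALSE)
}
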