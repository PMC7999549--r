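# Monoisotopic atomic masses (IUPAC/CODATA, Da). Hard-coded to >= 6 decimals;
# these are the single source of mass truth inside the package.
.atomic_mass <- c(
  C = 12.000000,
  H = 1.0078250319,
  N = 14.0030740052,
  O = 15.9949146221
)

#: proton mass used for positive-mode m/z (Da)
PROTON_MASS <- 1.007276

#: monoisotopic mass of water (Da), from the atomic masses above
WATER_MASS <- 2 * .atomic_mass[["H"]] + .atomic_mass[["O"]]

# Residue (condensed, i.e. minus one water) elemental formulas for the
# Gram-negative canonical muropeptide building blocks. D,D (4-3) crosslink
# chemotype only; no amidation/acetylation/glycine variants.
.residue_formulas <- list(
  GlcNAc    = c(C = 8,  H = 13, N = 1, O = 5),
  MurNAc    = c(C = 11, H = 17, N = 1, O = 7),
  anhMurNAc = c(C = 11, H = 15, N = 1, O = 6),  # MurNAc residue - H2O (1,6-anhydro ring)
  Ala       = c(C = 3,  H = 5,  N = 1, O = 1),  # L-Ala and D-Ala are isobaric
  iGlu      = c(C = 5,  H = 7,  N = 1, O = 3),  # D-isoglutamate
  mDAP      = c(C = 7,  H = 12, N = 2, O = 3)   # meso-diaminopimelate
)

.formula_mass <- function(formula) {
  stopifnot(all(names(formula) %in% names(.atomic_mass)))
  sum(formula * .atomic_mass[names(formula)])
}

#' Canonical muropeptide residues
#'
#' Returns the residue table used for all mass computations: the condensed
#' (minus one water) elemental formula and monoisotopic mass of each canonical
#' Gram-negative muropeptide building block. Stem peptides are assembled from
#' L-Ala, D-iGlu, meso-DAP and D-Ala; glycan units from GlcNAc and MurNAc
#' (or 1,6-anhydro-MurNAc at chain termini).
#'
#' @return A data.frame with columns `name`, `C`, `H`, `N`, `O` (element
#'   counts) and `residue_mass` (monoisotopic, Da).
#' @examples
#' muro_residues()
#' @export
muro_residues <- function() {
  out <- do.call(rbind, lapply(names(.residue_formulas), function(nm) {
    f <- .residue_formulas[[nm]]
    data.frame(name = nm, C = f[["C"]], H = f[["H"]], N = f[["N"]], O = f[["O"]],
               residue_mass = .formula_mass(f), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# Residue names making up a stem peptide of the given length (2-5).
.stem_residues <- function(stem_length) {
  stopifnot(stem_length %in% 2:5)
  c("Ala", "iGlu", "mDAP", "Ala", "Ala")[seq_len(stem_length)]
}
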