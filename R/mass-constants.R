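#' Monoisotopic atomic masses (Da)
#'
#' Masses of the elements occurring in unmodified polypeptides, used to
#' derive every residue and constant mass in the package from elemental
#' composition rather than from a transcribed table.
#'
#' @format Named numeric vector (H, C, N, O, S), Da.
#' @keywords internal
atomic_masses <- c(
  H = 1.0078250319,
  C = 12.0,
  N = 14.0030740052,
  O = 15.9949146221,
  S = 31.97207069
)

# Residue (i.e. amino acid minus water) elemental compositions.
residue_formulas <- list(
  G = c(C = 2, H = 3, N = 1, O = 1),
  A = c(C = 3, H = 5, N = 1, O = 1),
  S = c(C = 3, H = 5, N = 1, O = 2),
  P = c(C = 5, H = 7, N = 1, O = 1),
  V = c(C = 5, H = 9, N = 1, O = 1),
  T = c(C = 4, H = 7, N = 1, O = 2),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
  L = c(C = 6, H = 11, N = 1, O = 1),
  I = c(C = 6, H = 11, N = 1, O = 1),
  N = c(C = 4, H = 6, N = 2, O = 2),
  D = c(C = 4, H = 5, N = 1, O = 3),
  Q = c(C = 5, H = 8, N = 2, O = 2),
  K = c(C = 6, H = 12, N = 2, O = 1),
  E = c(C = 5, H = 7, N = 1, O = 3),
  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
  H = c(C = 6, H = 7, N = 3, O = 1),
  F = c(C = 9, H = 9, N = 1, O = 1),
  R = c(C = 6, H = 12, N = 4, O = 1),
  Y = c(C = 9, H = 9, N = 1, O = 2),
  W = c(C = 11, H = 10, N = 2, O = 1)
)

formula_mass <- function(formula) {
  sum(atomic_masses[names(formula)] * formula)
}

#' Monoisotopic mass table and physical constants
#'
#' Returns the residue masses and mass constants used throughout the
#' package: the 20 standard residue monoisotopic masses, the mass of
#' water (peptide termini), the proton mass (charging), and the mass of
#' isocyanic acid HNCO -- the neutral loss shed by the citrulline ureido
#' group during collision-induced dissociation, nominally "43 Da".
#'
#' All values are computed from [atomic_masses] at load time.
#'
#' @return A list with elements `residues` (named numeric vector, Da),
#'   `water`, `proton`, `hnco_loss` (each a single Da value).
#' @examples
#' mass_table()$hnco_loss  # 43.005814
#' @export
mass_table <- function() {
  list(
    residues = vapply(residue_formulas, formula_mass, numeric(1)),
    water = formula_mass(c(H = 2, O = 1)),
    # mass of H minus the electron mass
    proton = 1.00727646688,
    hnco_loss = formula_mass(c(H = 1, N = 1, C = 1, O = 1))
  )
}

# evaluated once; internal accessor avoids rebuilding the table per call
.mass <- mass_table()

#' Mass shift of deimination/deamidation
#'
#' The +0.984016 Da monoisotopic shift shared by citrullination of R
#' (guanidinium -> ureido: loss of NH, gain of O) and deamidation of
#' N/Q -- the isobaric confound this package exists to resolve.
#'
#' @return A single Da value.
#' @export
cit_delta <- function() {
  unname(atomic_masses["O"] - atomic_masses["N"] - atomic_masses["H"])
}
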