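# Element tables shared by geometry and surface code.
# Masses: IUPAC 2021 standard atomic weights (Da).
# Radii: Bondi van der Waals radii (Angstrom); heavy-atom models assumed,
# so no united-atom radii.

.element_masses <- c(
  H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, SE = 78.971, F = 18.998, CL = 35.45, BR = 79.904, I = 126.904,
  `NA` = 22.990, MG = 24.305, K = 39.098, CA = 40.078, MN = 54.938,
  FE = 55.845, CO = 58.933, NI = 58.693, CU = 63.546, ZN = 65.38
)

.element_radii <- c(
  H = 1.20, D = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
  `NA` = 2.27, MG = 1.73, K = 2.75, CA = 2.31, MN = 2.05,
  FE = 2.05, CO = 2.00, NI = 1.63, CU = 1.40, ZN = 1.39
)

# Electrons per amino-acid residue (heavy atoms only), used as coarse
# scattering weights at residue-level Debye evaluation.
.residue_electrons <- c(
  GLY = 30, ALA = 38, SER = 46, CYS = 54, THR = 54, PRO = 52, VAL = 54,
  ILE = 62, LEU = 62, ASN = 60, ASP = 59, GLN = 68, GLU = 67, MET = 70,
  HIS = 72, LYS = 71, ARG = 85, PHE = 78, TYR = 86, TRP = 98
)
.residue_electrons_default <- 62

element_mass <- function(element) {
  el <- toupper(element)
  m <- .element_masses[el]
  bad <- is.na(m)
  if (any(bad)) {
    abort_input(sprintf(
      "no atomic mass known for element(s): %s",
      paste(unique(el[bad]), collapse = ", ")
    ))
  }
  unname(m)
}

element_vdw_radius <- function(element) {
  el <- toupper(element)
  r <- .element_radii[el]
  bad <- is.na(r)
  if (any(bad)) {
    abort_input(sprintf(
      "no van der Waals radius known for element(s): %s",
      paste(unique(el[bad]), collapse = ", ")
    ))
  }
  unname(r)
}

residue_electron_count <- function(res_name) {
  e <- .residue_electrons[toupper(res_name)]
  e[is.na(e)] <- .residue_electrons_default
  unname(e)
}
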