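# Element tables shared across the package.

# Covalent radii (Cordero et al. single-bond values, Angstrom).
.COV_RADII <- c(
  H = 0.31, D = 0.31, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
  P = 1.07, S = 1.05, Cl = 1.02, Br = 1.20, I = 1.39, Se = 1.20,
  B = 0.84
)

# Standard (neutral) valences used for implicit-H counting and the
# valence-satisfaction heuristic.
.STD_VALENCE <- c(
  H = 1, D = 1, C = 4, N = 3, O = 2, F = 1,
  P = 5, S = 2, Cl = 1, Br = 1, I = 1, Se = 2, B = 3
)

# Gasteiger-Marsili PEOE electronegativity coefficients chi(q) = a + b q + c q^2
# (eV), per element/orbital class.  The H/C/N/O/halogen rows are the published
# coefficients of the original method; S and P are the extended values used by
# common cheminformatics toolkits.
.PEOE_COEF <- list(
  H      = c(7.17,  6.24, -0.56),
  C.sp3  = c(7.98,  9.18,  1.88),
  C.sp2  = c(8.79,  9.32,  1.51),
  C.sp   = c(10.39, 9.45,  0.73),
  N.sp3  = c(11.54, 10.82, 1.36),
  N.sp2  = c(12.87, 11.15, 0.85),
  N.sp   = c(15.68, 11.70, -0.27),
  O.sp3  = c(14.18, 12.92, 1.39),
  O.sp2  = c(17.07, 13.79, 0.47),
  F      = c(14.66, 13.85, 2.31),
  Cl     = c(11.00, 9.69,  1.35),
  Br     = c(10.08, 8.47,  1.16),
  I      = c(9.90,  7.96,  0.96),
  S.sp3  = c(10.14, 9.13,  1.38),
  P.sp3  = c(8.90,  8.24,  0.96)
)

# Cation electronegativity chi+ used as the normalizing denominator of the
# PEOE charge transfer; a + b + c except for hydrogen (fixed 20.02).
.peoe_chi_plus <- function(class) {
  if (class == "H") return(20.02)
  sum(.PEOE_COEF[[class]])
}

# Normalize an element symbol as found in PDB/mmCIF files ("CL", " C", "Zn")
# to canonical case.
normalize_element <- function(el) {
  el <- trimws(el)
  el <- paste0(toupper(substr(el, 1, 1)), tolower(substr(el, 2, 10)))
  el[el == ""] <- NA_character_
  el
}

is_known_element <- function(el) el %in% names(.COV_RADII)

# Element guess from a PDB atom name when the element column is absent.
element_from_name <- function(name) {
  nm <- trimws(name)
  two <- toupper(substr(nm, 1, 2))
  out <- character(length(nm))
  for (i in seq_along(nm)) {
    if (two[i] %in% c("CL", "BR", "SE", "FE", "ZN", "MG", "MN", "NA", "CA")) {
      out[i] <- paste0(substr(two[i], 1, 1), tolower(substr(two[i], 2, 2)))
    } else {
      # first alphabetic character
      ch <- regmatches(nm[i], regexpr("[A-Za-z]", nm[i]))
      out[i] <- toupper(ch)
    }
  }
  out
}

.WATER_CODES <- c("HOH", "WAT", "DOD", "H2O")

# Common monoatomic ion het codes (never ligand candidates, excluded from the
# protein environment together with water).
.ION_CODES <- c(
  "NA", "K", "CL", "CA", "MG", "ZN", "MN", "FE", "FE2", "CU", "CU1", "CO",
  "NI", "CD", "HG", "BR", "IOD", "F", "LI", "RB", "CS", "SR", "BA", "AL"
)

.STD_AA <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "MSE"
)
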