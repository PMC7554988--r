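# Physical constants and reference tables used across the package.

# Gas constant in kcal mol^-1 K^-1
.R_KCAL <- 1.9872e-3

# van der Waals radii (Angstrom), Bondi set plus common biological ions.
# Used by the Shrake-Rupley accessibility calculation.
.VDW_RADII <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
  FE = 2.00, ZN = 1.39, MG = 1.73, MN = 2.00, CU = 1.40, NI = 1.63,
  "NA" = 2.27, K = 2.75, CA = 2.31, CO = 2.00
)

# Theoretical maximum residue solvent accessibility (Angstrom^2) in an
# extended Gly-X-Gly tripeptide (Tien et al. 2013, theoretical values).
# Basis of relative (percent) accessibility.
.MAX_SASA_TIEN2013 <- c(
  ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
  GLU = 223, GLN = 225, GLY = 104, HIS = 224, ILE = 197,
  LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
  SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174
)

# Average (isotope-abundance-weighted) residue masses in Da, Expasy values;
# a free chain adds one water (18.01524 Da).
.RESIDUE_MASS_AVG <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)
.WATER_MASS_AVG <- 18.01524

# Molar extinction coefficients at 280 nm (M^-1 cm^-1) for the
# residue-contribution model (Pace/Gill-von Hippel):
#   eps280 = 5500 nTrp + 1490 nTyr + 125 nCystine
.EPS280_TRP <- 5500
.EPS280_TYR <- 1490
.EPS280_CYSTINE <- 125

# Side-chain and terminal pKa values (EMBOSS-style set) for the
# isoelectric-point bisection. Cysteines are treated as reduced thiols.
.PKA_SET <- list(
  nterm = 8.6, cterm = 3.6,
  positive = c(K = 10.8, R = 12.5, H = 6.5),
  negative = c(D = 3.9, E = 4.1, C = 8.5, Y = 10.1)
)

# 20 standard amino acids, one-letter, alphabetical
.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# three-letter <-> one-letter residue codes
.AA_3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLU = "E", GLN = "Q", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

.WATER_RESNAMES <- c("HOH", "WAT", "DOD", "H2O")

# BLOSUM62 comes with Biostrings; cached on first use
.pkg_cache <- new.env(parent = emptyenv())

.blosum62 <- function() {
  if (is.null(.pkg_cache$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pkg_cache$BLOSUM62 <- e$BLOSUM62
  }
  .pkg_cache$BLOSUM62
}

.substitution_matrix <- function(name) {
  if (!identical(name, "BLOSUM62")) {
    e <- new.env()
    ok <- tryCatch({
      utils::data(list = name, package = "Biostrings", envir = e)
      TRUE
    }, warning = function(w) FALSE, error = function(e) FALSE)
    if (!ok || is.null(e[[name]]))
      stop("unknown substitution matrix: ", name)
    return(e[[name]])
  }
  .blosum62()
}

# run code under a fixed RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer")
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}
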