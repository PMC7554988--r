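#' Sequence-derived physical properties of a protein
#'
#' Average isotopic mass (sum of residue masses plus one water), molar
#' extinction coefficient at 280 nm from the residue-contribution model
#' (`5500 nTrp + 1490 nTyr + 125 nCystine`, in 1/M/cm), and isoelectric
#' point by bisection of the Henderson-Hasselbalch net-charge equation
#' with an EMBOSS-style pKa set. Cysteines are treated as reduced unless
#' `nCystine` disulfide pairs are declared (each pair adds the cystine
#' absorbance term and removes two protonatable thiols).
#'
#' @param seq a protein sequence (character, `AAString` or length-1
#'   `AAStringSet`), standard residues only.
#' @param nCystine number of disulfide bonds. Default 0 (all thiols
#'   reduced).
#' @return A [SeqProperties-class].
#' @examples
#' sequenceProperties("GG")            # 132.12 Da dipeptide
#' sequenceProperties(strrep("WY", 3)) # eps280 = 3*5500 + 3*1490
#' @export
sequenceProperties <- function(seq, nCystine = 0L) {
  s <- .as_sequence(seq, "seq")
  chars <- strsplit(s, "")[[1]]
  if (any(chars == "X"))
    stop("sequence contains nonstandard letter 'X' at position ",
         which(chars == "X")[1])
  comp <- table(factor(chars, levels = .AA20))
  nCystine <- as.integer(nCystine)
  if (nCystine < 0 || 2L * nCystine > comp[["C"]])
    stop("nCystine inconsistent with ", comp[["C"]], " cysteine(s)")

  mass <- sum(.RESIDUE_MASS_AVG[chars]) + .WATER_MASS_AVG
  eps <- .EPS280_TRP * comp[["W"]] + .EPS280_TYR * comp[["Y"]] +
    .EPS280_CYSTINE * nCystine

  new("SeqProperties", averageMass = unname(mass),
      epsilon280 = unname(eps),
      pI = .isoelectric_point(comp, nCystine),
      composition = setNames(as.integer(comp), names(comp)),
      nResidues = length(chars), nCystine = nCystine)
}

# net charge at a given pH; disulfide-bonded cysteines do not titrate
.net_charge <- function(pH, comp, nCystine) {
  pk <- .PKA_SET
  pos <- 1 / (1 + 10^(pH - pk$nterm))
  for (aa in names(pk$positive))
    pos <- pos + comp[[aa]] / (1 + 10^(pH - pk$positive[[aa]]))
  neg <- 1 / (1 + 10^(pk$cterm - pH))
  for (aa in names(pk$negative)) {
    nAA <- comp[[aa]]
    if (aa == "C") nAA <- nAA - 2L * nCystine
    neg <- neg + nAA / (1 + 10^(pk$negative[[aa]] - pH))
  }
  pos - neg
}

.isoelectric_point <- function(comp, nCystine, tol = 1e-4) {
  lo <- 0; hi <- 14
  if (.net_charge(lo, comp, nCystine) < 0) return(lo)
  if (.net_charge(hi, comp, nCystine) > 0) return(hi)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (.net_charge(mid, comp, nCystine) > 0) lo <- mid else hi <- mid
  }
  round((lo + hi) / 2, 2)
}

#' Infer molecular mass from a size-exclusion calibration curve
#'
#' Linear fit of `log10(mass)` against elution volume for a set of
#' globular standards, then interpolation of the unknown's elution
#' volume; the standard error is propagated from the prediction SE on the
#' log scale.
#'
#' @param standards data.frame with columns `mass_kDa` and `ve` (elution
#'   volume, mL); at least 3 standards.
#' @param unknownVe elution volume of the unknown.
#' @return List: `mass_kDa`, `se_kDa`, `fit` (the `lm` object),
#'   `r_squared`, `extrapolated` (TRUE when `unknownVe` lies outside the
#'   standard range; flagged with a warning).
#' @examples
#' std <- data.frame(mass_kDa = c(158, 44, 17, 1.35),
#'                   ve = c(10.0, 12.0, 13.5, 17.5))
#' secInferMass(std, unknownVe = 13.6)
#' @export
secInferMass <- function(standards, unknownVe) {
  if (!all(c("mass_kDa", "ve") %in% names(standards)))
    stop("standards must have columns mass_kDa and ve")
  if (nrow(standards) < 3L) stop("need at least 3 standards")
  if (any(standards$mass_kDa <= 0)) stop("standard masses must be positive")
  o <- order(standards$ve)
  lm10 <- log10(standards$mass_kDa[o])
  if (any(diff(lm10) >= 0))
    warning("standards are not monotone (log mass should decrease with ",
            "elution volume); calibration may be unreliable")
  fit <- lm(lmass ~ ve, data = data.frame(lmass = log10(standards$mass_kDa),
                                          ve = standards$ve))
  extrap <- unknownVe < min(standards$ve) || unknownVe > max(standards$ve)
  if (extrap)
    warning("unknown elutes outside the standard range; extrapolating")
  pr <- predict(fit, newdata = data.frame(ve = unknownVe), se.fit = TRUE)
  mass <- 10^pr$fit
  # an exactly collinear calibration is legitimate; silence summary.lm's
  # perfect-fit note
  r2 <- suppressWarnings(summary(fit)$r.squared)
  list(mass_kDa = unname(mass),
       se_kDa = unname(mass * log(10) * pr$se.fit),
       fit = fit,
       r_squared = r2,
       extrapolated = extrap)
}
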