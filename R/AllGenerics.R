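#' Accessors for FeSConserv containers
#'
#' Small accessor generics so downstream code never reaches into slots:
#' `atoms()` and `chains()` for [ProteinStructure-class],
#' `interfaceResidues()` / `partnerResidues()` for [InterfaceSet-class],
#' `perResidueSasa()` / `perAtomSasa()` for [SasaResult-class],
#' `alignmentScore()` and `positionMap()` for [HomologAlignment-class].
#'
#' @param x an object of the documented class.
#' @return The underlying data.frame, character vector or numeric value.
#' @name accessors
#' @examples
#' toy <- makeToyComplex(4, 4, 2, seed = 1)
#' chains(toy$structure)
#' head(atoms(toy$structure))
NULL

#' @rdname accessors
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))
#' @rdname accessors
#' @export
setGeneric("chains", function(x) standardGeneric("chains"))
#' @rdname accessors
#' @export
setGeneric("interfaceResidues", function(x) standardGeneric("interfaceResidues"))
#' @rdname accessors
#' @export
setGeneric("partnerResidues", function(x) standardGeneric("partnerResidues"))
#' @rdname accessors
#' @export
setGeneric("perResidueSasa", function(x) standardGeneric("perResidueSasa"))
#' @rdname accessors
#' @export
setGeneric("perAtomSasa", function(x) standardGeneric("perAtomSasa"))
#' @rdname accessors
#' @export
setGeneric("alignmentScore", function(x) standardGeneric("alignmentScore"))
#' @rdname accessors
#' @export
setGeneric("positionMap", function(x) standardGeneric("positionMap"))

#' @rdname accessors
setMethod("atoms", "ProteinStructure", function(x) x@atoms)
#' @rdname accessors
setMethod("chains", "ProteinStructure", function(x) x@chains)
#' @rdname accessors
setMethod("interfaceResidues", "InterfaceSet", function(x) x@residuesA)
#' @rdname accessors
setMethod("partnerResidues", "InterfaceSet", function(x) x@residuesPartner)
#' @rdname accessors
setMethod("perResidueSasa", "SasaResult", function(x) x@perResidue)
#' @rdname accessors
setMethod("perAtomSasa", "SasaResult", function(x) x@atoms)
#' @rdname accessors
setMethod("alignmentScore", "HomologAlignment", function(x) x@score)
#' @rdname accessors
setMethod("positionMap", "HomologAlignment", function(x) x@map)

setMethod("show", "ProteinStructure", function(object) {
  a <- object@atoms
  cat("ProteinStructure (", object@format, "): ", nrow(a), " atoms, ",
      length(object@chains), " chain(s) [",
      paste(object@chains, collapse = ", "), "], ",
      sum(a$hetero), " hetero atom(s)\n", sep = "")
  cat("  source:", object@source, "\n")
})

setMethod("show", "InterfaceSet", function(object) {
  cat("InterfaceSet: ", object@chainA, " vs ", object@partner,
      " at < ", object@cutoff, " A\n", sep = "")
  cat("  ", nrow(object@residuesA), " residue(s) on ", object@chainA,
      ", ", nrow(object@residuesPartner), " on partner\n", sep = "")
})

setMethod("show", "SasaResult", function(object) {
  cat("SasaResult: ", nrow(object@atoms), " atoms, ",
      nrow(object@perResidue), " residues; probe ",
      object@probeRadius, " A, ", object@nSpherePoints, " points\n",
      sep = "")
  cat("  total SASA:", round(sum(object@atoms$sasa), 1), "A^2\n")
})

setMethod("show", "HomologAlignment", function(object) {
  cat("HomologAlignment (", object@mode, ", ", object@matrixName,
      ", gap ", object@gapOpen, "/", object@gapExtend, ")\n", sep = "")
  cat("  ", object@idA, " vs ", object@idB, ", score ",
      round(object@score, 1), "\n", sep = "")
  st <- identityStats(object)
  cat(sprintf("  identity %.1f%%, similarity %.1f%%, coverage %.1f%%\n",
              st["identity_pct"], st["similarity_pct"], st["coverage_pct"]))
})

setMethod("show", "RegionIdentityReport", function(object) {
  cat("RegionIdentityReport '", object@regionName, "': ",
      length(object@positions), " positions, ", sep = "")
  cat(sprintf("identity %.1f%%, similarity %.1f%% (%s)\n",
              object@identityPct, object@similarityPct, object@denominator))
})

setMethod("show", "TrimmedAlignment", function(object) {
  cat("TrimmedAlignment: ", length(object@aln), " records x ",
      Biostrings::width(object@aln)[1], " columns (",
      length(object@removedColumns), " of ", object@originalColumns,
      " columns trimmed)\n", sep = "")
  cat("  reference:", object@referenceId, "\n")
})

setMethod("show", "ConservationProfile", function(object) {
  cat("ConservationProfile: ", ncol(object@counts), " columns, ",
      object@nRecords, " records\n", sep = "")
  cat(sprintf("  modal frequency: median %.2f, %d absolutely conserved column(s)\n",
              median(object@modalFrequency, na.rm = TRUE),
              sum(object@modalFrequency == 1, na.rm = TRUE)))
})

setMethod("show", "ChemicalUnfoldingFit", function(object) {
  co <- object@coefficients
  cat("Two-state chemical unfolding fit (linear extrapolation)\n")
  cat(sprintf("  dG0 = %.2f +- %.2f kcal/mol,  m = %.2f +- %.2f kcal/mol/M\n",
              co["dG0"], object@se["dG0"], co["m"], object@se["m"]))
  cat(sprintf("  Cm = %.2f M at %.2f K;  RSS = %.3g\n",
              object@Cm, object@temperatureK, object@rss))
})

setMethod("show", "ThermalUnfoldingFit", function(object) {
  co <- object@coefficients
  cat("Two-state thermal unfolding fit (Gibbs-Helmholtz)\n")
  cat(sprintf("  Tm = %.2f +- %.2f K,  dHm = %.1f +- %.1f kcal/mol (dCp fixed at %.2f)\n",
              co["Tm"], object@se["Tm"], co["dHm"], object@se["dHm"],
              object@dCp))
  cat(sprintf("  dG(%.2f K) = %.2f kcal/mol;  RSS = %.3g\n",
              object@TrefK, object@dGTref, object@rss))
})

setMethod("show", "SeqProperties", function(object) {
  cat("SeqProperties:", object@nResidues, "residues\n")
  cat(sprintf("  average mass %.1f Da, eps280 %d /M/cm, pI %.2f\n",
              object@averageMass, as.integer(round(object@epsilon280)),
              object@pI))
})

setMethod("show", "Spectrum", function(object) {
  n <- length(object@wavelength)
  cat(sprintf("Spectrum: %d points, %.1f-%.1f nm, step %.4g nm\n",
              n, object@wavelength[1], object@wavelength[n],
              object@wavelength[2] - object@wavelength[1]))
})
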