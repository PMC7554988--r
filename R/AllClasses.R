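#' ProteinStructure: atomic coordinates of a (multi-chain) complex
#'
#' Holds one atom per row after alternate-location resolution. Columns of
#' `atoms`: `chain`, `resno` (author numbering), `insert` (insertion code,
#' `""` if none), `resid` (3-letter residue name), `elety` (atom name),
#' `elesy` (element symbol), `x`, `y`, `z` (Angstrom), `o` (occupancy) and
#' `hetero` (logical, HETATM record).
#'
#' @slot atoms data.frame of atoms, see description.
#' @slot chains character vector of chain identifiers present.
#' @slot source character, file or generator the structure came from.
#' @slot format character, input format ("pdb", "mmcif" or "synthetic").
#' @aliases ProteinStructure
#' @exportClass ProteinStructure
setClass("ProteinStructure",
  representation(atoms = "data.frame", chains = "character",
                 source = "character", format = "character"))

setValidity("ProteinStructure", function(object) {
  a <- object@atoms
  need <- c("chain", "resno", "insert", "resid", "elety", "elesy",
            "x", "y", "z", "o", "hetero")
  if (!all(need %in% names(a)))
    return(paste("atoms is missing columns:",
                 paste(setdiff(need, names(a)), collapse = ", ")))
  if (nrow(a) == 0L) return("structure has no atoms")
  if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
    return("non-finite coordinates")
  if (any(a$o < 0 | a$o > 1, na.rm = TRUE))
    return("occupancy outside [0, 1]")
  if (!all(a$chain %in% object@chains))
    return("atom chain identifier not listed in chains slot")
  key <- paste(a$chain, a$resno, a$insert, a$elety)
  if (anyDuplicated(key))
    return("duplicate (chain, resno, insert, atom name) after altloc resolution")
  TRUE
})

#' InterfaceSet: residues of two molecular partners in contact
#'
#' A contact is any (heavy-)atom pair at Euclidean distance strictly below
#' `cutoff`. Residue tables are ordered by (chain, residue number,
#' insertion code) and carry the minimal cross-partner atom distance plus
#' the identities of the contacting partner residues.
#'
#' @slot chainA character, first partner (chain identifier).
#' @slot partner character, second partner: a chain identifier or a ligand
#'   selector of the form `"resname:XXX"`.
#' @slot cutoff numeric, distance cutoff in Angstrom (strict `<`).
#' @slot residuesA data.frame: interface residues on `chainA`.
#' @slot residuesPartner data.frame: interface residues on the partner.
#' @aliases InterfaceSet
#' @exportClass InterfaceSet
setClass("InterfaceSet",
  representation(chainA = "character", partner = "character",
                 cutoff = "numeric", residuesA = "data.frame",
                 residuesPartner = "data.frame"))

#' SasaResult: Shrake-Rupley solvent accessibility
#'
#' @slot atoms data.frame of the atoms the calculation covered, with a
#'   `sasa` column in Angstrom^2.
#' @slot perResidue data.frame: `chain`, `resno`, `insert`, `resid`,
#'   `sasa` (sum over the residue's atoms).
#' @slot probeRadius numeric, solvent probe radius in Angstrom.
#' @slot nSpherePoints integer, quadrature points per atom.
#' @aliases SasaResult
#' @exportClass SasaResult
setClass("SasaResult",
  representation(atoms = "data.frame", perResidue = "data.frame",
                 probeRadius = "numeric", nSpherePoints = "integer"))

setValidity("SasaResult", function(object) {
  if (any(object@atoms$sasa < 0) || any(object@perResidue$sasa < 0))
    return("negative SASA value")
  TRUE
})

#' HomologAlignment: pairwise alignment of two protein sequences
#'
#' @slot idA,idB character sequence identifiers.
#' @slot seqA,seqB character, the full ungapped input sequences.
#' @slot alignedA,alignedB character, equal-length gapped strings covering
#'   the aligned span (the full sequences in global mode).
#' @slot startA,startB integer, 1-based position of the first aligned
#'   residue within each full sequence.
#' @slot mode character, `"global"` or `"local"`.
#' @slot matrixName character, substitution matrix used.
#' @slot gapOpen,gapExtend numeric, affine gap penalties (a gap of length L
#'   costs `gapOpen + gapExtend * L`).
#' @slot score numeric alignment score.
#' @slot map integer vector of length `nchar(seqA)`: for each position of
#'   sequence A the aligned 1-based position in sequence B, `NA` where
#'   unaligned. Strictly increasing over its non-`NA` entries.
#' @aliases HomologAlignment
#' @exportClass HomologAlignment
setClass("HomologAlignment",
  representation(idA = "character", idB = "character",
                 seqA = "character", seqB = "character",
                 alignedA = "character", alignedB = "character",
                 startA = "integer", startB = "integer",
                 mode = "character", matrixName = "character",
                 gapOpen = "numeric", gapExtend = "numeric",
                 score = "numeric", map = "integer"))

setValidity("HomologAlignment", function(object) {
  if (nchar(object@alignedA) != nchar(object@alignedB))
    return("aligned strings differ in length")
  if (gsub("-", "", object@alignedA, fixed = TRUE) !=
      substr(object@seqA, object@startA,
             object@startA + nchar(gsub("-", "", object@alignedA)) - 1L))
    return("alignedA does not recover the corresponding span of seqA")
  m <- object@map[!is.na(object@map)]
  if (length(m) > 1L && any(diff(m) <= 0))
    return("position map is not strictly increasing")
  TRUE
})

#' RegionIdentityReport: identity/similarity over a named residue region
#'
#' @slot regionName character label of the region.
#' @slot positions integer, 1-based positions in sequence A.
#' @slot detail data.frame with one row per region position: `pos_a`,
#'   `a_residue`, `pos_b`, `b_residue` (`NA` when the position aligns to a
#'   gap), `identical`, `similar`.
#' @slot nAligned,nIdentical,nSimilar integer counts.
#' @slot identityPct,similarityPct numeric percentages under the
#'   denominator policy used.
#' @slot denominator character, `"region_positions"` (unaligned positions
#'   count against identity) or `"aligned_only"`.
#' @aliases RegionIdentityReport
#' @exportClass RegionIdentityReport
setClass("RegionIdentityReport",
  representation(regionName = "character", positions = "integer",
                 detail = "data.frame", nAligned = "integer",
                 nIdentical = "integer", nSimilar = "integer",
                 identityPct = "numeric", similarityPct = "numeric",
                 denominator = "character"))

#' TrimmedAlignment: a curated multiple sequence alignment
#'
#' Stores the alignment after column trimming (mostly-gap columns removed,
#' columns beyond the last reference residue removed) together with the
#' trimming log.
#'
#' @slot aln `AAStringSet` of equal-width gapped sequences.
#' @slot referenceId character, identifier of the reference record.
#' @slot removedColumns integer, 1-based indices (in the original
#'   alignment) of columns removed by trimming.
#' @slot originalColumns integer, column count before trimming.
#' @aliases TrimmedAlignment
#' @exportClass TrimmedAlignment
setClass("TrimmedAlignment",
  representation(aln = "AAStringSet", referenceId = "character",
                 removedColumns = "integer", originalColumns = "integer"))

setValidity("TrimmedAlignment", function(object) {
  w <- Biostrings::width(object@aln)
  if (length(object@aln) < 2L) return("alignment needs at least 2 records")
  if (length(unique(w)) != 1L) return("ragged alignment")
  if (!object@referenceId %in% names(object@aln))
    return(paste("reference id not present:", object@referenceId))
  TRUE
})

#' ConservationProfile: per-column conservation statistics of an MSA
#'
#' @slot counts integer matrix, 20 standard amino-acid rows (alphabetical)
#'   by alignment columns.
#' @slot gapCounts integer, gaps per column.
#' @slot otherCounts integer, non-standard letters (X etc.) per column.
#' @slot modalResidue character, most frequent amino acid per column (ties
#'   broken alphabetically; gaps are never modal; `NA` for all-gap columns).
#' @slot modalFrequency numeric, modal count / number of records.
#' @slot informationBits numeric, `log2(20)` minus the Shannon entropy of
#'   the amino-acid distribution (gaps excluded).
#' @slot modalTie logical, TRUE where the modal residue was tied.
#' @slot nRecords integer, number of sequences.
#' @aliases ConservationProfile
#' @exportClass ConservationProfile
setClass("ConservationProfile",
  representation(counts = "matrix", gapCounts = "integer",
                 otherCounts = "integer", modalResidue = "character",
                 modalFrequency = "numeric", informationBits = "numeric",
                 modalTie = "logical", nRecords = "integer"))

setValidity("ConservationProfile", function(object) {
  tot <- colSums(object@counts) + object@gapCounts + object@otherCounts
  if (!all(tot == object@nRecords))
    return("column counts do not sum to the number of records")
  ok <- !is.na(object@modalFrequency)
  if (any(object@modalFrequency[ok] <= 0 | object@modalFrequency[ok] > 1))
    return("modal frequency outside (0, 1]")
  TRUE
})

#' ChemicalUnfoldingFit: two-state linear-extrapolation fit
#'
#' Result of fitting the six-parameter two-state model
#' `y(c) = (aN + bN c + (aU + bU c) K(c)) / (1 + K(c))` with
#' `K(c) = exp(-(dG0 - m c) / (R T))` to a chemical denaturation curve.
#'
#' @slot coefficients named numeric: `dG0` (kcal/mol), `m` (kcal/mol/M),
#'   `aN`, `bN`, `aU`, `bU`.
#' @slot se named numeric standard errors.
#' @slot cov numeric covariance matrix of the parameters.
#' @slot Cm numeric midpoint `dG0 / m` (M).
#' @slot temperatureK numeric, temperature of the fit.
#' @slot rss numeric residual sum of squares.
#' @slot data data.frame(x, y, fitted, residual).
#' @aliases ChemicalUnfoldingFit
#' @exportClass ChemicalUnfoldingFit
setClass("ChemicalUnfoldingFit",
  representation(coefficients = "numeric", se = "numeric", cov = "matrix",
                 Cm = "numeric", temperatureK = "numeric", rss = "numeric",
                 data = "data.frame"))

#' ThermalUnfoldingFit: two-state Gibbs-Helmholtz fit
#'
#' Thermal denaturation fit with
#' `dG(T) = dHm (1 - T/Tm) + dCp ((T - Tm) - T log(T/Tm))` and linear
#' native/unfolded baselines in temperature; `dCp` is fixed, not fitted.
#'
#' @slot coefficients named numeric: `Tm` (K), `dHm` (kcal/mol), `aN`,
#'   `bN`, `aU`, `bU`.
#' @slot se named numeric standard errors.
#' @slot cov numeric covariance matrix.
#' @slot dCp numeric, fixed heat-capacity change (kcal/mol/K).
#' @slot dGTref numeric, stability extrapolated to `TrefK`.
#' @slot TrefK numeric reference temperature (K).
#' @slot rss numeric residual sum of squares.
#' @slot data data.frame(x, y, fitted, residual).
#' @aliases ThermalUnfoldingFit
#' @exportClass ThermalUnfoldingFit
setClass("ThermalUnfoldingFit",
  representation(coefficients = "numeric", se = "numeric", cov = "matrix",
                 dCp = "numeric", dGTref = "numeric", TrefK = "numeric",
                 rss = "numeric", data = "data.frame"))

#' SeqProperties: sequence-derived physical constants
#'
#' @slot averageMass numeric, average isotopic mass in Da (residue masses
#'   plus one water).
#' @slot epsilon280 numeric, molar extinction coefficient at 280 nm.
#' @slot pI numeric, isoelectric point.
#' @slot composition named integer, residue counts.
#' @slot nResidues integer chain length.
#' @slot nCystine integer, disulfide-bonded cysteine pairs assumed.
#' @aliases SeqProperties
#' @exportClass SeqProperties
setClass("SeqProperties",
  representation(averageMass = "numeric", epsilon280 = "numeric",
                 pI = "numeric", composition = "integer",
                 nResidues = "integer", nCystine = "integer"))

#' Spectrum: a uniformly sampled absorbance or derivative spectrum
#'
#' @slot wavelength numeric, strictly increasing, uniform step (nm).
#' @slot value numeric, absorbance or derivative units; `NA` marks the
#'   invalid edge region of derivative spectra.
#' @slot metadata list (sampling step, filter parameters, ...).
#' @aliases Spectrum
#' @exportClass Spectrum
setClass("Spectrum",
  representation(wavelength = "numeric", value = "numeric",
                 metadata = "list"))

setValidity("Spectrum", function(object) {
  if (length(object@wavelength) != length(object@value))
    return("wavelength and value lengths differ")
  d <- diff(object@wavelength)
  if (any(d <= 0)) return("wavelengths must be strictly increasing")
  if (length(d) > 1L && max(abs(d - d[1])) > 1e-6)
    return("wavelength step is not uniform (tolerance 1e-6 nm)")
  TRUE
})
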