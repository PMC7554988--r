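#' Pairwise alignment of two homologous protein sequences
#'
#' Optimal affine-gap alignment (dynamic programming via Biostrings) in
#' two parameterisations: `"local"` with BLASTp-style penalties (BLOSUM62,
#' gap open 11, extend 1) for reproducing published identity tables, and
#' `"global"` (open 10, extend 0.5) for position-mapping tasks. A gap of
#' length L costs `gapOpen + gapExtend * L`.
#'
#' @param a,b sequences: plain character strings or length-1
#'   `AAStringSet`/`AAString`. Uppercase, 20 standard letters plus X.
#' @param idA,idB identifiers; default to names of `a`/`b` or "seqA"/"seqB".
#' @param mode `"local"` or `"global"`.
#' @param matrixName substitution matrix name (default `"BLOSUM62"`).
#' @param gapOpen,gapExtend affine penalties; defaults depend on `mode`
#'   (11/1 local, 10/0.5 global).
#' @return A [HomologAlignment-class].
#' @examples
#' aln <- alignPair("ACDEFGHIK", "ACDEFGHIK", mode = "global")
#' identityStats(aln)
#' @export
alignPair <- function(a, b, idA = NULL, idB = NULL,
                      mode = c("local", "global"),
                      matrixName = "BLOSUM62",
                      gapOpen = NULL, gapExtend = NULL) {
  mode <- match.arg(mode)
  sa <- .as_sequence(a, "a")
  sb <- .as_sequence(b, "b")
  if (is.null(idA)) idA <- if (!is.null(names(sa))) names(sa) else "seqA"
  if (is.null(idB)) idB <- if (!is.null(names(sb))) names(sb) else "seqB"
  if (is.null(gapOpen)) gapOpen <- if (mode == "local") 11 else 10
  if (is.null(gapExtend)) gapExtend <- if (mode == "local") 1 else 0.5
  mat <- .substitution_matrix(matrixName)

  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(unname(sa)), Biostrings::AAString(unname(sb)),
    type = mode, substitutionMatrix = mat,
    gapOpening = gapOpen, gapExtension = gapExtend)

  alnA <- as.character(Biostrings::alignedPattern(pa))
  alnB <- as.character(Biostrings::alignedSubject(pa))
  startA <- if (mode == "local") Biostrings::start(Biostrings::pattern(pa)) else 1L
  startB <- if (mode == "local") Biostrings::start(Biostrings::subject(pa)) else 1L

  map <- rep(NA_integer_, nchar(sa))
  ca <- strsplit(alnA, "")[[1]]
  cb <- strsplit(alnB, "")[[1]]
  ia <- startA - 1L
  ib <- startB - 1L
  for (k in seq_along(ca)) {
    if (ca[k] != "-") ia <- ia + 1L
    if (cb[k] != "-") ib <- ib + 1L
    if (ca[k] != "-" && cb[k] != "-") map[ia] <- ib
  }

  new("HomologAlignment", idA = idA, idB = idB,
      seqA = unname(sa), seqB = unname(sb),
      alignedA = alnA, alignedB = alnB,
      startA = as.integer(startA), startB = as.integer(startB),
      mode = mode, matrixName = matrixName,
      gapOpen = gapOpen, gapExtend = gapExtend,
      score = Biostrings::score(pa), map = map)
}

# coerce input to a validated single uppercase sequence string
.as_sequence <- function(s, argname) {
  if (is(s, "AAStringSet")) {
    if (length(s) != 1L) stop(argname, " must contain exactly one sequence")
    out <- setNames(as.character(s[[1]]), names(s))
  } else if (is(s, "AAString")) {
    out <- as.character(s)
  } else if (is.character(s) && length(s) == 1L) {
    out <- s
  } else stop(argname, " must be a single sequence")
  if (nchar(out) == 0L) stop(argname, ": empty sequence")
  if (out != toupper(out)) stop(argname, ": sequence must be uppercase")
  bad <- regmatches(out, gregexpr(sprintf("[^%sX]", paste(.AA20, collapse = "")),
                                  out))[[1]]
  if (length(bad))
    stop(argname, ": unknown residue letter '", bad[1], "' at position ",
         regexpr(sprintf("[^%sX]", paste(.AA20, collapse = "")), out))
  out
}

#' Identity, similarity and coverage of a pairwise alignment
#'
#' Identity is the percentage of columns with identical residues;
#' similarity the percentage of columns whose substitution score is
#' positive ("similar" per the BLOSUM62 convention); coverage the aligned
#' span of sequence A over its full length. With the default
#' `"aligned_columns"` denominator all columns of the (sub)alignment,
#' including gapped ones, enter the denominator (BLAST convention);
#' `"shorter_seq"` divides by the length of the shorter input instead.
#'
#' @param aln a [HomologAlignment-class].
#' @param denominator `"aligned_columns"` or `"shorter_seq"`.
#' @return Named numeric: `identity_pct`, `similarity_pct`,
#'   `coverage_pct`, `n_identical`, `n_similar`, `n_columns`.
#' @export
identityStats <- function(aln,
                          denominator = c("aligned_columns", "shorter_seq")) {
  stopifnot(is(aln, "HomologAlignment"))
  denominator <- match.arg(denominator)
  ca <- strsplit(aln@alignedA, "")[[1]]
  cb <- strsplit(aln@alignedB, "")[[1]]
  ncols <- length(ca)
  if (ncols == 0L) {
    warning("alignment has zero columns; all statistics are 0")
    return(c(identity_pct = 0, similarity_pct = 0, coverage_pct = 0,
             n_identical = 0, n_similar = 0, n_columns = 0))
  }
  both <- ca != "-" & cb != "-"
  ident <- both & ca == cb
  mat <- .substitution_matrix(aln@matrixName)
  simil <- both
  simil[both] <- mat[cbind(ca[both], cb[both])] > 0
  den <- switch(denominator,
                aligned_columns = ncols,
                shorter_seq = min(nchar(aln@seqA), nchar(aln@seqB)))
  spanA <- sum(ca != "-")
  c(identity_pct = 100 * sum(ident) / den,
    similarity_pct = 100 * sum(simil) / den,
    coverage_pct = 100 * spanA / nchar(aln@seqA),
    n_identical = sum(ident), n_similar = sum(simil), n_columns = ncols)
}

#' Region-restricted identity of a pairwise alignment
#'
#' Maps a named set of sequence-A positions (for instance, the interface
#' residues of a chain) through the alignment and reports identity and
#' similarity over the region. Under the default `"region_positions"`
#' policy every region position enters the denominator and positions that
#' align to a gap count as non-identical (a conservative convention,
#' echoed in the output); `"aligned_only"` divides by the number of
#' aligned region positions instead.
#'
#' @param aln a [HomologAlignment-class].
#' @param positions integer vector of 1-based positions in sequence A.
#' @param regionName label for the report.
#' @param denominator `"region_positions"` or `"aligned_only"`.
#' @return A [RegionIdentityReport-class].
#' @examples
#' pair <- makeOrthologPair(60, region = 10:19, regionIdentity = 0.6,
#'                          backgroundIdentity = 0.3, seed = 7)
#' aln <- alignPair(pair$seqA, pair$seqB, mode = "global")
#' regionIdentity(aln, 10:19)
#' @export
regionIdentity <- function(aln, positions, regionName = "region",
                           denominator = c("region_positions",
                                           "aligned_only")) {
  stopifnot(is(aln, "HomologAlignment"))
  denominator <- match.arg(denominator)
  positions <- as.integer(positions)
  if (length(positions) == 0L) stop("empty region")
  lenA <- nchar(aln@seqA)
  if (any(positions < 1L | positions > lenA))
    stop("region positions outside sequence A (length ", lenA, ")")
  positions <- sort(unique(positions))

  mat <- .substitution_matrix(aln@matrixName)
  aRes <- strsplit(aln@seqA, "")[[1]][positions]
  bPos <- aln@map[positions]
  bRes <- ifelse(is.na(bPos), NA_character_,
                 strsplit(aln@seqB, "")[[1]][ifelse(is.na(bPos), 1L, bPos)])
  identical_ <- !is.na(bRes) & aRes == bRes
  similar <- !is.na(bRes)
  similar[similar] <- mat[cbind(aRes[similar], bRes[similar])] > 0

  nAligned <- sum(!is.na(bPos))
  den <- if (denominator == "region_positions") length(positions) else
    max(nAligned, 1L)
  detail <- data.frame(pos_a = positions, a_residue = aRes,
                       pos_b = bPos, b_residue = bRes,
                       identical = identical_, similar = similar)
  new("RegionIdentityReport", regionName = regionName,
      positions = positions, detail = detail,
      nAligned = as.integer(nAligned),
      nIdentical = as.integer(sum(identical_)),
      nSimilar = as.integer(sum(similar)),
      identityPct = 100 * sum(identical_) / den,
      similarityPct = 100 * sum(similar) / den,
      denominator = denominator)
}

#' Conservation report for annotated (disease-linked) positions
#'
#' One row per annotated sequence-A position: its residue, the aligned
#' partner position and residue (or unaligned), and whether the residue
#' letter is conserved. Used for cross-referencing Friedreich's-Ataxia
#' positions of human frataxin against a homolog.
#'
#' @param aln a [HomologAlignment-class].
#' @param positions integer positions in sequence A.
#' @param labels optional character labels (same length as `positions`).
#' @return data.frame: pos_a, res_a, pos_b (`NA` when unaligned), res_b,
#'   conserved (logical), label.
#' @export
diseasePositionReport <- function(aln, positions, labels = NULL) {
  stopifnot(is(aln, "HomologAlignment"))
  positions <- as.integer(positions)
  lenA <- nchar(aln@seqA)
  if (any(positions < 1L | positions > lenA))
    stop("annotated position beyond sequence A (length ", lenA, ")")
  if (is.null(labels)) labels <- rep("", length(positions))
  if (length(labels) != length(positions))
    stop("labels must match positions in length")
  aChars <- strsplit(aln@seqA, "")[[1]]
  bChars <- strsplit(aln@seqB, "")[[1]]
  bPos <- aln@map[positions]
  resB <- ifelse(is.na(bPos), NA_character_,
                 bChars[ifelse(is.na(bPos), 1L, bPos)])
  data.frame(pos_a = positions, res_a = aChars[positions],
             pos_b = bPos, res_b = resB,
             conserved = !is.na(resB) & aChars[positions] == resB,
             label = labels)
}

#' Read protein sequences from a FASTA file
#'
#' Thin wrapper over [Biostrings::readAAStringSet()] kept so pipeline
#' configurations can name FASTA inputs uniformly.
#'
#' @param path FASTA file.
#' @return An `AAStringSet`.
#' @export
readSequences <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  Biostrings::readAAStringSet(path)
}
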