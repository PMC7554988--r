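#' Read and trim a curated multiple sequence alignment
#'
#' Loads a Clustal (`.aln`) or aligned-FASTA alignment and applies the two
#' curation rules used for the 54-genome frataxin alignment: columns where
#' most sequences have gaps (gap fraction strictly above
#' `maxGapFraction`) are removed, and columns after the last residue of
#' the reference sequence (the human frataxin record) are cut. The
#' trimming log (removed original column indices) is kept on the result.
#'
#' Trimming is idempotent: applying it to an already-trimmed alignment
#' removes nothing.
#'
#' @param path alignment file.
#' @param format `"clustal"` or `"fasta"`.
#' @param referenceId identifier of the reference record (must be present).
#' @param maxGapFraction columns with gap fraction strictly greater than
#'   this are removed. Default 0.5 ("most sequences").
#' @return A [TrimmedAlignment-class].
#' @export
readTrimAlignment <- function(path, format = c("clustal", "fasta"),
                              referenceId, maxGapFraction = 0.5) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("alignment file not found: ", path)
  msa <- tryCatch(
    Biostrings::readAAMultipleAlignment(path, format = format),
    error = function(e) stop("failed to read ", format, " alignment '",
                             path, "': ", conditionMessage(e),
                             call. = FALSE))
  aln <- methods::as(msa, "AAStringSet")
  trimAlignment(aln, referenceId = referenceId,
                maxGapFraction = maxGapFraction)
}

#' @rdname readTrimAlignment
#' @param aln an `AAStringSet` of equal-width gapped sequences (or a
#'   [TrimmedAlignment-class], whose alignment is re-trimmed).
#' @export
trimAlignment <- function(aln, referenceId, maxGapFraction = 0.5) {
  if (is(aln, "TrimmedAlignment")) aln <- aln@aln
  stopifnot(is(aln, "AAStringSet"))
  if (length(aln) < 2L) stop("alignment needs at least 2 records")
  w <- Biostrings::width(aln)
  if (length(unique(w)) != 1L)
    stop("ragged alignment: sequence widths ", paste(unique(w), collapse = ", "))
  if (!referenceId %in% names(aln))
    stop("reference id '", referenceId, "' not found in alignment")
  if (maxGapFraction <= 0 || maxGapFraction >= 1)
    stop("maxGapFraction must be in (0, 1)")

  m <- .aln_matrix(aln)
  isgap <- m == "-" | m == "."
  gapFrac <- colMeans(isgap)
  refRow <- which(names(aln) == referenceId)[1]
  refNonGap <- which(!isgap[refRow, ])
  if (!length(refNonGap))
    stop("reference record is all gaps")
  lastRef <- max(refNonGap)

  keep <- seq_len(ncol(m)) <= lastRef & gapFrac <= maxGapFraction
  removed <- which(!keep)
  kept <- m[, keep, drop = FALSE]
  out <- Biostrings::AAStringSet(apply(kept, 1, paste, collapse = ""))
  names(out) <- names(aln)
  new("TrimmedAlignment", aln = out, referenceId = referenceId,
      removedColumns = as.integer(removed),
      originalColumns = ncol(m))
}

# character matrix (records x columns) from a gapped AAStringSet
.aln_matrix <- function(aln) {
  do.call(rbind, strsplit(as.character(aln), ""))
}

.resolve_msa <- function(x) {
  if (is(x, "TrimmedAlignment")) x@aln
  else if (is(x, "AAStringSet")) x
  else stop("expected a TrimmedAlignment or AAStringSet")
}

#' Per-column conservation profile of an alignment
#'
#' Counts amino acids per column and derives the modal residue (gaps are
#' never modal; ties broken alphabetically and flagged), the modal
#' frequency with denominator equal to the number of records (so gaps
#' count against conservation), and the information content
#' `log2(20) - H`, with `H` the Shannon entropy of the amino-acid
#' frequency distribution excluding gaps.
#'
#' @param x a [TrimmedAlignment-class] or gapped `AAStringSet`.
#' @return A [ConservationProfile-class].
#' @examples
#' fx <- makeMsa(nSeqs = 10, nCols = 8, modalFreqs = rep(0.8, 8), seed = 3)
#' prof <- columnProfile(fx$msa)
#' prof
#' @export
columnProfile <- function(x) {
  aln <- .resolve_msa(x)
  m <- .aln_matrix(aln)
  n <- nrow(m)
  nc <- ncol(m)
  counts <- matrix(0L, nrow = length(.AA20), ncol = nc,
                   dimnames = list(.AA20, NULL))
  gaps <- integer(nc)
  other <- integer(nc)
  modal <- rep(NA_character_, nc)
  modalFreq <- rep(NA_real_, nc)
  bits <- rep(NA_real_, nc)
  tie <- rep(FALSE, nc)
  for (j in seq_len(nc)) {
    col <- m[, j]
    tab <- table(col)
    gaps[j] <- sum(tab[names(tab) %in% c("-", ".")])
    aa <- tab[names(tab) %in% .AA20]
    other[j] <- n - gaps[j] - sum(aa)
    if (length(aa)) {
      counts[names(aa), j] <- as.integer(aa)
      mx <- max(aa)
      cand <- sort(names(aa)[aa == mx])  # alphabetical tie-break
      modal[j] <- cand[1]
      tie[j] <- length(cand) > 1L
      modalFreq[j] <- mx / n
      p <- as.numeric(aa) / sum(aa)
      bits[j] <- log2(20) + sum(p * log2(p))
    }
  }
  new("ConservationProfile", counts = counts, gapCounts = gaps,
      otherCounts = other, modalResidue = modal,
      modalFrequency = modalFreq, informationBits = bits,
      modalTie = tie, nRecords = as.integer(n))
}

#' Conservation threshold statistics
#'
#' Counts alignment columns whose modal amino-acid frequency is strictly
#' greater than each threshold, and lists absolutely conserved columns
#' (modal count equal to the number of records). The default denominator
#' is the total number of records, so gap-containing columns are
#' penalised; `denominator = "nongap"` divides by the non-gap count
#' instead (provided as an explicit alternative, not the default).
#'
#' @param profile a [ConservationProfile-class].
#' @param thresholds fractions in (0, 1); default `c(0.5, 0.8, 0.9)`.
#' @param absolute also report absolutely conserved columns.
#' @param denominator `"records"` (default) or `"nongap"`.
#' @return List with `counts` (named integer per threshold), `fractions`
#'   (counts / number of columns) and, when `absolute`, a data.frame
#'   `absolute` of (column, residue).
#' @export
thresholdCounts <- function(profile, thresholds = c(0.5, 0.8, 0.9),
                            absolute = TRUE,
                            denominator = c("records", "nongap")) {
  stopifnot(is(profile, "ConservationProfile"))
  denominator <- match.arg(denominator)
  if (any(thresholds <= 0 | thresholds >= 1))
    stop("thresholds must be in (0, 1)")
  modalCount <- round(profile@modalFrequency * profile@nRecords)
  freq <- if (denominator == "records") profile@modalFrequency else {
    nong <- profile@nRecords - profile@gapCounts
    ifelse(nong > 0, modalCount / nong, NA_real_)
  }
  nc <- length(profile@modalFrequency)
  counts <- vapply(thresholds,
                   function(t) sum(freq > t, na.rm = TRUE), numeric(1))
  names(counts) <- paste0(">", thresholds)
  out <- list(counts = as.integer(counts),
              thresholds = thresholds,
              fractions = unname(counts) / nc,
              nColumns = nc, denominator = denominator)
  names(out$counts) <- names(counts)
  if (absolute) {
    absCols <- which(!is.na(profile@modalFrequency) &
                       modalCount == profile@nRecords)
    out$absolute <- data.frame(column = absCols,
                               residue = profile@modalResidue[absCols])
  }
  out
}

#' Map alignment columns to reference-sequence numbering
#'
#' Bidirectional map between alignment columns and 1-based positions of
#' the (gapped) reference record: columns where the reference has a gap
#' map to `NA`. Both directions are strictly increasing.
#'
#' @param x a [TrimmedAlignment-class] or gapped `AAStringSet`.
#' @param referenceId reference record identifier; defaults to the one
#'   stored in a [TrimmedAlignment-class].
#' @param offset integer added to reference positions, for converting
#'   domain-local numbering to full-protein numbering (e.g. an alignment
#'   whose reference position 1 is residue 91 of the mature protein uses
#'   `offset = 90`). Default 0.
#' @return List with `columnToReference` (integer per column, `NA` at
#'   reference gaps) and `referenceToColumn` (integer per reference
#'   residue).
#' @export
mapColumnToReference <- function(x, referenceId = NULL, offset = 0L) {
  aln <- .resolve_msa(x)
  if (is.null(referenceId)) {
    if (is(x, "TrimmedAlignment")) referenceId <- x@referenceId
    else stop("referenceId is required for a plain alignment")
  }
  if (!referenceId %in% names(aln))
    stop("reference id '", referenceId, "' not found in alignment")
  ref <- strsplit(as.character(aln[[which(names(aln) == referenceId)[1]]]),
                  "")[[1]]
  nong <- !(ref %in% c("-", "."))
  colToRef <- rep(NA_integer_, length(ref))
  colToRef[nong] <- seq_len(sum(nong)) + as.integer(offset)
  refToCol <- which(nong)
  names(refToCol) <- colToRef[nong]
  list(columnToReference = colToRef, referenceToColumn = refToCol)
}

#' Export a sequence-logo matrix
#'
#' One row per alignment column with amino-acid counts, frequencies and
#' information content, renderable by any logo tool.
#'
#' @param profile a [ConservationProfile-class].
#' @param file optional CSV output path.
#' @return data.frame (invisibly when written to a file).
#' @export
logoMatrix <- function(profile, file = NULL) {
  stopifnot(is(profile, "ConservationProfile"))
  cnt <- t(profile@counts)
  frq <- cnt / profile@nRecords
  colnames(frq) <- paste0("freq_", colnames(frq))
  colnames(cnt) <- paste0("count_", colnames(cnt))
  df <- data.frame(column = seq_len(nrow(cnt)), cnt, frq,
                   gap_count = profile@gapCounts,
                   modal_residue = profile@modalResidue,
                   modal_frequency = profile@modalFrequency,
                   information_bits = profile@informationBits)
  if (!is.null(file)) {
    write.csv(df, file, row.names = FALSE)
    return(invisible(df))
  }
  df
}
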