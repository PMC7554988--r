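mk_aln <- function(seqs, ids = NULL) {
  s <- Biostrings::AAStringSet(seqs)
  names(s) <- if (is.null(ids)) paste0("s", seq_along(seqs)) else ids
  s
}

test_that("trimming removes mostly-gap columns and columns past the reference end", {
  # column 2 is 60% gaps; reference ends 3 columns before the alignment end
  seqs <- c("AC-DEF--",
            "A-KDEFKL",
            "A-KDEFKL",
            "ACKDEFKL",
            "A-KDEFKL")
  ta <- trimAlignment(mk_aln(seqs, c("REF", paste0("g", 1:4))), "REF")
  expect_equal(ta@removedColumns, c(2L, 7L, 8L))
  expect_equal(Biostrings::width(ta@aln)[1], 5L)

  ta2 <- trimAlignment(mk_aln(seqs, c("REF", paste0("g", 1:4))), "REF",
                       maxGapFraction = 0.7)
  expect_equal(ta2@removedColumns, c(7L, 8L))
})

test_that("trimming is idempotent", {
  fx <- makeMsa(nSeqs = 12, nCols = 30, modalFreqs = rep(0.7, 30),
                gapCols = c(4L, 9L), seed = 5)
  t1 <- trimAlignment(fx$msa, "REF_HUMAN")
  t2 <- trimAlignment(t1, "REF_HUMAN")
  expect_identical(as.character(t1@aln), as.character(t2@aln))
  expect_length(t2@removedColumns, 0L)
})

test_that("ragged or reference-free alignments are rejected", {
  expect_error(trimAlignment(mk_aln(c("ACD", "AC")), "s1"), "ragged")
  expect_error(trimAlignment(mk_aln(c("ACD", "ACD")), "nope"),
               "not found")
})

test_that("column profile matches hand tallies, including ties and gaps", {
  seqs <- c(strrep("W", 4), strrep("W", 4), strrep("W", 4))
  prof <- columnProfile(mk_aln(seqs))
  expect_true(all(prof@modalResidue == "W"))
  expect_true(all(prof@modalFrequency == 1))

  # column with A:2, G:2, gap:1 -> alphabetical tie to A, flagged
  prof2 <- columnProfile(mk_aln(c("A", "A", "G", "G", "-")))
  expect_equal(prof2@modalResidue, "A")
  expect_true(prof2@modalTie)
  expect_equal(prof2@modalFrequency, 2 / 5)
  expect_equal(prof2@gapCounts, 1L)

  # uniform over the 20 residues carries zero information
  prof3 <- columnProfile(mk_aln(FeSConserv:::.AA20))
  expect_equal(prof3@informationBits, 0, tolerance = 1e-12)
})

test_that("profiles are invariant under row permutation", {
  fx <- makeMsa(nSeqs = 20, nCols = 15, modalFreqs = rep(0.6, 15), seed = 8)
  p1 <- columnProfile(fx$msa)
  set.seed(31)
  perm <- fx$msa[sample(seq_along(fx$msa))]
  p2 <- columnProfile(perm)
  expect_identical(p1@counts, p2@counts)
  expect_identical(p1@modalResidue, p2@modalResidue)
})

test_that("threshold counts equal planted construction truth across seeds", {
  set.seed(1234)
  for (seed in 1:50) {
    nSeqs <- sample(10:30, 1)
    nCols <- sample(10:25, 1)
    freqs <- sample(c(0.35, 0.55, 0.7, 0.85, 0.95, 1.0), nCols,
                    replace = TRUE)
    fx <- makeMsa(nSeqs = nSeqs, nCols = nCols, modalFreqs = freqs,
                  seed = seed)
    tc <- thresholdCounts(columnProfile(fx$msa))
    expect_equal(unname(tc$counts),
                 unname(as.integer(fx$truth$thresholdCounts)))
    expect_equal(tc$absolute$column, fx$truth$absoluteColumns)
  }
})

test_that("threshold counts are monotone and saturate for identical alignments", {
  fx <- makeMsa(nSeqs = 15, nCols = 12, modalFreqs = rep(1.0, 12), seed = 2)
  tc <- thresholdCounts(columnProfile(fx$msa))
  expect_equal(unname(tc$counts), rep(12L, 3))
  expect_equal(nrow(tc$absolute), 12L)

  fx2 <- makeMsa(seed = 77)  # study-scale default profile
  tc2 <- thresholdCounts(columnProfile(fx2$msa))
  expect_true(all(diff(tc2$counts) <= 0))
  expect_lte(nrow(tc2$absolute), min(tc2$counts))
})

test_that("the non-gap denominator switch changes gapped-column statistics only", {
  # 10 records: 4 W, 2 A, 4 gaps -> 0.4 by records, 4/6 by non-gap
  prof <- columnProfile(mk_aln(c(rep("W", 4), rep("A", 2), rep("-", 4))))
  byRec <- thresholdCounts(prof, thresholds = 0.5)
  byNong <- thresholdCounts(prof, thresholds = 0.5, denominator = "nongap")
  expect_equal(unname(byRec$counts), 0L)
  expect_equal(unname(byNong$counts), 1L)
})

test_that("column-to-reference maps respect gaps and offsets", {
  aln <- mk_aln(c("--ACD", "KKACD"), c("REF", "other"))
  mp <- mapColumnToReference(aln, "REF")
  expect_equal(mp$columnToReference, c(NA, NA, 1L, 2L, 3L))
  expect_equal(unname(mp$referenceToColumn), 3:5)
  expect_true(all(diff(mp$referenceToColumn) > 0))

  mpo <- mapColumnToReference(aln, "REF", offset = 90L)
  expect_equal(mpo$columnToReference[3], 91L)

  ungapped <- mk_aln(c("ACDEF", "ACDEF"), c("REF", "o"))
  expect_equal(mapColumnToReference(ungapped, "REF")$columnToReference, 1:5)
})

test_that("clustal round trip preserves the alignment and is deterministic", {
  fx <- makeMsa(nSeqs = 10, nCols = 24, modalFreqs = rep(0.8, 24),
                gapCols = 5L, seed = 3)
  f1 <- tempfile(fileext = ".aln")
  f2 <- tempfile(fileext = ".aln")
  writeClustal(fx$msa, f1)
  writeClustal(makeMsa(nSeqs = 10, nCols = 24, modalFreqs = rep(0.8, 24),
                       gapCols = 5L, seed = 3)$msa, f2)
  expect_identical(readLines(f1), readLines(f2))

  ta <- readTrimAlignment(f1, "clustal", referenceId = "REF_HUMAN")
  expect_equal(ta@removedColumns, 5L)
  raw <- FeSConserv:::.aln_matrix(fx$msa)
  expect_identical(FeSConserv:::.aln_matrix(ta@aln), raw[, -5])
})

test_that("logo matrix export carries counts, frequencies and information", {
  fx <- makeMsa(nSeqs = 12, nCols = 6, modalFreqs = rep(0.75, 6), seed = 4)
  lm <- logoMatrix(columnProfile(fx$msa))
  expect_equal(nrow(lm), 6L)
  expect_true(all(c("count_A", "freq_W", "modal_frequency",
                    "information_bits") %in% names(lm)))
  counts <- as.matrix(lm[, paste0("count_", FeSConserv:::.AA20)])
  expect_true(all(rowSums(counts) + lm$gap_count == 12))
})
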