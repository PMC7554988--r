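test_that("generators are byte-identical under a fixed seed", {
  t1 <- makeToyComplex(5, 5, 2, seed = 1)
  t2 <- makeToyComplex(5, 5, 2, seed = 1)
  expect_identical(t1$pdbText, t2$pdbText)
  expect_identical(t1$truth, t2$truth)
  t3 <- makeToyComplex(5, 5, 2, seed = 2)
  expect_false(identical(t1$pdbText, t3$pdbText))

  p1 <- makeOrthologPair(40, 5:14, 0.5, 0.2, seed = 4)
  p2 <- makeOrthologPair(40, 5:14, 0.5, 0.2, seed = 4)
  expect_identical(p1, p2)

  m1 <- makeMsa(nSeqs = 10, nCols = 12, modalFreqs = rep(0.7, 12), seed = 6)
  m2 <- makeMsa(nSeqs = 10, nCols = 12, modalFreqs = rep(0.7, 12), seed = 6)
  expect_identical(as.character(m1$msa), as.character(m2$msa))

  c1 <- simulateUnfolding("chemical", noiseSd = 0.02, seed = 8)
  c2 <- simulateUnfolding("chemical", noiseSd = 0.02, seed = 8)
  expect_identical(c1$curve, c2$curve)
  c3 <- simulateUnfolding("chemical", noiseSd = 0.02, seed = 9)
  expect_false(identical(c1$curve$y, c3$curve$y))

  s1 <- simulateSpectrum(list(c(center = 290, sigma = 2, amplitude = 1)),
                         noiseSd = 0.01, seed = 3)
  s2 <- simulateSpectrum(list(c(center = 290, sigma = 2, amplitude = 1)),
                         noiseSd = 0.01, seed = 3)
  expect_identical(s1$spectrum@value, s2$spectrum@value)
})

test_that("generators leave the caller's RNG state untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(makeToyComplex(4, 4, 1, seed = 55))
  invisible(makeMsa(nSeqs = 8, nCols = 5, modalFreqs = rep(0.9, 5),
                    seed = 55))
  expect_identical(.Random.seed, before)
})

test_that("toy complexes respect the planted contact geometry", {
  toy <- makeToyComplex(6, 6, 0, seed = 3)
  iface <- contactResidues(toy$structure, "A", "B")
  expect_equal(nrow(interfaceResidues(iface)), 0L)

  toy2 <- makeToyComplex(5, 7, 5, seed = 11)
  expect_equal(nrow(toy2$truth$pairs), 5L)
  # non-contact cross-chain residue pairs are farther than 6 A
  a <- atoms(toy2$structure)
  A <- a[a$chain == "A", ]; B <- a[a$chain == "B", ]
  pairs <- toy2$truth$pairs
  for (i in unique(A$resno)) for (j in unique(B$resno)) {
    d <- min(sqrt(outer(A$x[A$resno == i], B$x[B$resno == j], "-")^2 +
                    outer(A$y[A$resno == i], B$y[B$resno == j], "-")^2 +
                    outer(A$z[A$resno == i], B$z[B$resno == j], "-")^2))
    planted <- any(pairs$resno_a == i & pairs$resno_b == j)
    if (planted) expect_lt(d, 4) else expect_gt(d, 6)
  }
  expect_error(makeToyComplex(3, 3, 4, seed = 1), "exceed")
})

test_that("ortholog pairs plant exact identity counts", {
  pair <- makeOrthologPair(60, 10:19, 1.0, 0.0, seed = 5)
  aln <- alignPair(pair$seqA, pair$seqB, mode = "global")
  expect_equal(regionIdentity(aln, 10:19)@identityPct, 100)
  # with zero background identity the overall identity is region-only
  ident <- sum(strsplit(pair$seqA, "")[[1]] == strsplit(pair$seqB, "")[[1]])
  expect_equal(ident, length(pair$truth$identicalPositions))
  expect_equal(ident, 10L)
})

test_that("planted MSA gap columns carry the requested gap fraction", {
  fx <- makeMsa(nSeqs = 20, nCols = 10, modalFreqs = rep(0.7, 10),
                gapCols = c(3L, 8L), gapFraction = 0.6, seed = 9)
  m <- FeSConserv:::.aln_matrix(fx$msa)
  expect_equal(colSums(m == "-")[c(3, 8)], c(12, 12),
               ignore_attr = TRUE)
  expect_equal(sum(m[, -c(3, 8)] == "-"), 0)
  # the reference record is never gapped
  expect_false(any(m[1, ] == "-"))
})

test_that("simulated unfolding curves pass through the baseline midpoint", {
  sim <- simulateUnfolding("chemical", params = list(dG0 = 4.3, m = 1.55),
                           nPoints = 200, noiseSd = 0, seed = 1)
  p <- sim$truth
  cm <- p$dG0 / p$m
  yMid <- ((p$aN + p$bN * cm) + (p$aU + p$bU * cm)) / 2
  expect_equal(approx(sim$curve$x, sim$curve$y, xout = cm)$y, yMid,
               tolerance = 1e-3)

  simT <- simulateUnfolding("thermal", nPoints = 300, noiseSd = 0, seed = 1)
  pT <- simT$truth
  yMidT <- ((pT$aN + pT$bN * pT$Tm) + (pT$aU + pT$bU * pT$Tm)) / 2
  expect_equal(approx(simT$curve$x, simT$curve$y, xout = pT$Tm)$y, yMidT,
               tolerance = 1e-3)
  expect_error(simulateUnfolding("chemical", params = list(Tm = 5)),
               "unknown parameter")
})

test_that("simulated spectra validate their band definitions", {
  expect_error(simulateSpectrum(list(c(center = 500, sigma = 1,
                                       amplitude = 1)), seed = 1),
               "outside")
  expect_error(simulateSpectrum(list(c(sigma = 1, amplitude = 1)),
                                seed = 1), "center")
  flat <- simulateSpectrum(list(), seed = 1)
  expect_true(all(flat$spectrum@value == 0))
})
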