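test_that("readStructure parses minimal records, resolves altlocs and drops waters", {
  pdb <- c(
    "ATOM      1  N  AALA A   1      11.104   6.134  -6.504  0.60 10.00           N",
    "ATOM      2  N  BALA A   1      11.204   6.134  -6.504  0.40 10.00           N",
    "ATOM      3  CA  ALA A   1      11.639   6.071  -5.147  1.00 10.00           C",
    "HETATM    4  O   HOH A 101       5.000   5.000   5.000  1.00 10.00           O",
    "HETATM    5  P   LLP B 200       1.000   2.000   3.000  1.00 10.00           P",
    "END")
  f <- tempfile(fileext = ".pdb")
  writeLines(pdb, f)
  s <- readStructure(f)
  a <- atoms(s)
  expect_equal(nrow(a), 3L)            # water gone, one N kept
  expect_setequal(chains(s), c("A", "B"))
  n_kept <- a[a$elety == "N", ]
  expect_equal(n_kept$x, 11.104)       # altloc A (occupancy 0.6) wins
  expect_true(a$hetero[a$resid == "LLP"])
  expect_error(readStructure(tempfile()), "not found")
})

test_that("altloc occupancy ties resolve to the alphabetically first altloc", {
  pdb <- c(
    "ATOM      1  CA ATRP A   9       1.000   0.000   0.000  0.50 10.00           C",
    "ATOM      2  CA BTRP A   9       2.000   0.000   0.000  0.50 10.00           C",
    "END")
  f <- tempfile(fileext = ".pdb")
  writeLines(pdb, f)
  a <- atoms(readStructure(f))
  expect_equal(nrow(a), 1L)
  expect_equal(a$x, 1.0)
})

test_that("contact cutoff is strict and symmetric at the residue level", {
  # two single-residue chains, nearest heavy atoms exactly 4.0 A apart
  mk <- function(d) {
    at <- data.frame(
      type = "ATOM", chain = c("A", "B"), resno = 1L, insert = NA,
      resid = "GLY", elety = "CA", alt = NA, elesy = "C",
      x = c(0, d), y = 0, z = 0, o = 1)
    FeSConserv:::.structure_from_atom_table(at, "test", "synthetic")
  }
  at4 <- contactResidues(mk(4.0), "A", "B", cutoff = 4.0)
  expect_equal(nrow(interfaceResidues(at4)), 0L)
  near <- contactResidues(mk(3.5), "A", "B", cutoff = 4.0)
  expect_equal(interfaceResidues(near)$resno, 1L)
  expect_equal(partnerResidues(near)$resno, 1L)
  expect_equal(interfaceResidues(near)$min_distance, 3.5)
})

test_that("planted toy-complex contacts equal the brute-force oracle", {
  set.seed(99)
  for (seed in 1:25) {
    nA <- sample(3:8, 1)
    nB <- sample(3:8, 1)
    k <- sample(0:min(nA, nB), 1)
    toy <- makeToyComplex(nA, nB, k, seed = seed)
    iface <- contactResidues(toy$structure, "A", "B", cutoff = 4.0)
    oracle <- oracle_contact_residues(toy$structure, "A", "B", 4.0)
    expect_equal(interfaceResidues(iface)$resno, oracle$a)
    expect_equal(partnerResidues(iface)$resno, oracle$b)
    expect_equal(oracle$a, toy$truth$contactsA)
    expect_equal(oracle$b, toy$truth$contactsB)
  }
})

test_that("interfaces grow monotonically with the cutoff", {
  toy <- makeToyComplex(8, 8, 4, seed = 42)
  r <- lapply(c(3.5, 4.0, 5.0), function(ct)
    interfaceResidues(contactResidues(toy$structure, "A", "B", ct))$resno)
  expect_true(all(r[[1]] %in% r[[2]]))
  expect_true(all(r[[2]] %in% r[[3]]))
})

test_that("ligand selector extracts protein-cofactor contacts", {
  at <- data.frame(
    type = c("ATOM", "ATOM", "HETATM"),
    chain = c("A", "A", "A"), resno = c(1L, 2L, 300L), insert = NA,
    resid = c("GLY", "GLY", "LLP"), elety = c("CA", "CA", "P"),
    alt = NA, elesy = c("C", "C", "P"),
    x = c(0, 10, 3), y = 0, z = 0, o = 1)
  s <- FeSConserv:::.structure_from_atom_table(at, "test", "synthetic")
  iface <- contactResidues(s, "A", "resname:LLP", cutoff = 4.0)
  expect_equal(interfaceResidues(iface)$resno, 1L)
  expect_equal(partnerResidues(iface)$resid, "LLP")
  expect_error(contactResidues(s, "A", "resname:HEM"), "HEM")
})

test_that("isolated-atom SASA matches the analytic sphere to 1 percent", {
  at <- data.frame(type = "ATOM", chain = "A", resno = 1L, insert = NA,
                   resid = "UNK", elety = "C1", alt = NA, elesy = "C",
                   x = 0, y = 0, z = 0, o = 1)
  s <- FeSConserv:::.structure_from_atom_table(at, "test", "synthetic")
  got <- perAtomSasa(shrakeRupleySasa(s, nPoints = 960))$sasa
  expect_equal(got, 4 * pi * 3.1^2, tolerance = 0.01)
})

test_that("coincident atoms fully occlude each other", {
  at <- data.frame(type = "ATOM", chain = "A", resno = c(1L, 1L),
                   insert = NA, resid = "UNK", elety = c("C1", "C2"),
                   alt = NA, elesy = "C", x = 0, y = 0, z = 0, o = 1)
  s <- FeSConserv:::.structure_from_atom_table(at, "test", "synthetic")
  total <- sum(perAtomSasa(shrakeRupleySasa(s))$sasa)
  expect_equal(total, 4 * pi * 3.1^2, tolerance = 1e-6)
})

test_that("an atom enclosed by a constructed shell has zero SASA", {
  shell <- FeSConserv:::.sphere_points(30L) * 3.0
  at <- data.frame(type = "ATOM", chain = "A",
                   resno = c(1L, rep(2L, 30L)), insert = NA, resid = "UNK",
                   elety = paste0("C", 0:30), alt = NA, elesy = "C",
                   x = c(0, shell[, 1]), y = c(0, shell[, 2]),
                   z = c(0, shell[, 3]), o = 1)
  s <- FeSConserv:::.structure_from_atom_table(at, "test", "synthetic")
  res <- perResidueSasa(shrakeRupleySasa(s))
  expect_equal(res$sasa[res$resno == 1L], 0)
})

test_that("SASA quadrature converges and complexation only buries surface", {
  toy <- makeToyComplex(5, 5, 3, seed = 9)
  s960 <- sum(perAtomSasa(shrakeRupleySasa(toy$structure, nPoints = 960))$sasa)
  s1920 <- sum(perAtomSasa(shrakeRupleySasa(toy$structure, nPoints = 1920))$sasa)
  expect_lt(abs(s960 - s1920) / s1920, 0.005)

  together <- sum(perAtomSasa(shrakeRupleySasa(toy$structure))$sasa)
  apart <- sum(perAtomSasa(shrakeRupleySasa(toy$structure, chainSubset = "A"))$sasa) +
    sum(perAtomSasa(shrakeRupleySasa(toy$structure, chainSubset = "B"))$sasa)
  expect_lte(together, apart + 1e-9)
})

test_that("unknown elements are rejected with the offending atoms named", {
  at <- data.frame(type = "ATOM", chain = "A", resno = 1L, insert = NA,
                   resid = "UNK", elety = "XX1", alt = NA, elesy = "XX",
                   x = 0, y = 0, z = 0, o = 1)
  s <- FeSConserv:::.structure_from_atom_table(at, "test", "synthetic")
  expect_error(shrakeRupleySasa(s), "XX")
})

test_that("relative SASA: buried is 0, an extended Gly tripeptide centre is near its reference maximum", {
  shell <- FeSConserv:::.sphere_points(40L) * 3.0
  at <- data.frame(type = "ATOM", chain = "A",
                   resno = c(1L, rep(2L, 40L)), insert = NA,
                   resid = c("GLY", rep("UNK", 40L)),
                   elety = paste0("C", 0:40), alt = NA, elesy = "C",
                   x = c(0, shell[, 1]), y = c(0, shell[, 2]),
                   z = c(0, shell[, 3]), o = 1)
  s <- FeSConserv:::.structure_from_atom_table(at, "test", "synthetic")
  expect_equal(relativeSasa(shrakeRupleySasa(s), "A", 1L), 0)

  pep <- makeExtendedPeptide("GGG")
  rel <- relativeSasa(shrakeRupleySasa(pep), "A", 2L)
  # idealised planar backbone occludes slightly more than the reference
  # conformational maximum; accept a broad band around 100%
  expect_gt(rel, 70)
  expect_lt(rel, 130)
  expect_error(relativeSasa(shrakeRupleySasa(pep), "A", 99L), "not in")
})

test_that("delta-SASA on binding is zero far from the interface and positive at it", {
  toy <- makeToyComplex(6, 6, 2, seed = 5)
  d <- deltaSasaOnBinding(toy$structure, "A", "B")
  planted <- toy$truth$contactsA
  expect_true(all(d$delta_sasa[d$resno %in% planted] > 0))
  far <- setdiff(d$resno, planted)
  expect_true(all(abs(d$delta_sasa[d$resno %in% far]) < 1e-6))
  expect_true(all(d$sasa_complex <= d$sasa_free + 1e-9))
  expect_error(deltaSasaOnBinding(toy$structure, "A", character(0)),
               "empty")
})
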