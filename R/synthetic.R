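# Seeded synthetic-data generators. Every generator returns a list
# ("fixture bundle") with the payload, the planted ground truth, the seed
# and a generator version stamp; the same seed and parameters give a
# byte-identical payload. These fixtures exercise every analysis stage of
# the package without any external downloads.

.GENERATOR_VERSION <- "1.0"

#' Toy two-chain complex with planted contact residues
#'
#' Builds two pseudo-chains of alanine-like residues (CA + CB heavy
#' atoms) placed so that exactly `nContacts` residue pairs have a
#' heavy-atom distance below 4 A while all other cross-chain pairs are
#' farther than 6 A. The truth slot lists the planted contact pairs, so a
#' brute-force all-pairs scan can verify interface extraction exactly.
#'
#' @param nResA,nResB residues per chain.
#' @param nContacts number of planted contact pairs; at most
#'   `min(nResA, nResB)`.
#' @param seed RNG seed (the caller's RNG state is preserved).
#' @param contactDistance CA-CA distance of planted contacts (default
#'   3.4 A; must leave margin below 4 A after jitter).
#' @return List: `structure` ([ProteinStructure-class]), `pdbText`
#'   (character vector of PDB lines), `truth` (contact pairs and residue
#'   lists), `seed`, `generatorVersion`.
#' @examples
#' toy <- makeToyComplex(5, 5, 2, seed = 1)
#' toy$truth$pairs
#' @export
makeToyComplex <- function(nResA, nResB, nContacts, seed,
                           contactDistance = 3.4) {
  if (nContacts > min(nResA, nResB))
    stop("nContacts cannot exceed min(nResA, nResB)")
  if (contactDistance <= 2.5 || contactDistance > 3.6)
    stop("contactDistance must be in (2.5, 3.6] to keep planted margins")
  .with_seed(seed, {
    spacing <- 10
    farY <- 20
    contactA <- sort(sample.int(nResA, nContacts))
    contactB <- sample.int(nResB, nContacts)  # paired with contactA in order

    jit <- function(n) runif(n, -0.05, 0.05)
    resA <- data.frame(resno = seq_len(nResA))
    resA$ca <- cbind(resA$resno * spacing + jit(nResA), jit(nResA),
                     jit(nResA))
    resB <- data.frame(resno = seq_len(nResB))
    resB$ca <- cbind(resB$resno * spacing + jit(nResB),
                     farY + jit(nResB), jit(nResB))
    # relocate contact residues of B above their A partner
    for (k in seq_len(nContacts)) {
      ai <- contactA[k]; bi <- contactB[k]
      resB$ca[bi, ] <- c(resA$ca[ai, 1] + jit(1),
                         resA$ca[ai, 2] + contactDistance + jit(1),
                         resA$ca[ai, 3] + jit(1))
    }
    cbA <- resA$ca + cbind(jit(nResA), jit(nResA), 1.5 + jit(nResA) * 0)
    cbB <- resB$ca + cbind(jit(nResB), 1.5, jit(nResB) * 0)

    at <- function(chain, resno, elety, xyz) {
      data.frame(type = "ATOM", chain = chain, resno = resno, insert = NA,
                 resid = "ALA", elety = elety, alt = NA, elesy = "C",
                 x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], o = 1)
    }
    tab <- rbind(at("A", resA$resno, "CA", resA$ca),
                 at("A", resA$resno, "CB", cbA),
                 at("B", resB$resno, "CA", resB$ca),
                 at("B", resB$resno, "CB", cbB))
    tab <- tab[order(tab$chain, tab$resno, tab$elety), ]
    struct <- .structure_from_atom_table(tab, source = sprintf(
      "makeToyComplex(%d,%d,%d,seed=%d)", nResA, nResB, nContacts,
      as.integer(seed)), format = "synthetic")

    pdb <- c(sprintf(
      "ATOM  %5d  %-3s%4s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
      seq_len(nrow(tab)), tab$elety, tab$resid, tab$chain, tab$resno,
      tab$x, tab$y, tab$z, tab$o, 0), "END")

    list(structure = struct, pdbText = pdb,
         truth = list(pairs = data.frame(resno_a = contactA,
                                         resno_b = contactB),
                      contactsA = sort(unique(contactA)),
                      contactsB = sort(unique(contactB))),
         seed = seed, generatorVersion = .GENERATOR_VERSION)
  })
}

#' Ortholog sequence pair with controlled region identity
#'
#' Draws a random sequence A and derives B by keeping an exact number of
#' identical positions inside a named region (`round(regionIdentity *
#' length(region))`) and outside it (`round(backgroundIdentity * n)`),
#' substituting every other position with a different residue. The truth
#' slot records the exact identical-position sets.
#'
#' @param length sequence length.
#' @param region integer positions forming the region of interest.
#' @param regionIdentity,backgroundIdentity fractions in `[0, 1]`.
#' @param seed RNG seed.
#' @return List: `seqA`, `seqB` (character), `truth` (identical position
#'   sets and planted counts), `seed`, `generatorVersion`.
#' @export
makeOrthologPair <- function(length, region, regionIdentity,
                             backgroundIdentity, seed) {
  if (regionIdentity < 0 || regionIdentity > 1 ||
      backgroundIdentity < 0 || backgroundIdentity > 1)
    stop("identity fractions must be in [0, 1]")
  region <- sort(unique(as.integer(region)))
  if (any(region < 1L | region > length))
    stop("region positions outside 1..length")
  .with_seed(seed, {
    a <- sample(.AA20, length, replace = TRUE)
    keepRegion <- sort(sample(region, round(regionIdentity *
                                              base::length(region))))
    bg <- setdiff(seq_len(length), region)
    keepBg <- sort(sample(bg, round(backgroundIdentity * base::length(bg))))
    keep <- c(keepRegion, keepBg)
    b <- a
    subst <- setdiff(seq_len(length), keep)
    for (i in subst) b[i] <- sample(setdiff(.AA20, a[i]), 1)
    list(seqA = paste(a, collapse = ""), seqB = paste(b, collapse = ""),
         truth = list(identicalPositions = sort(keep),
                      regionIdentical = keepRegion,
                      nRegionIdentical = base::length(keepRegion),
                      backgroundIdentical = keepBg,
                      region = region),
         seed = seed, generatorVersion = .GENERATOR_VERSION)
  })
}

#' Synthetic multiple alignment with a planted conservation profile
#'
#' Per column, a modal residue is placed in `round(freq * nSeqs)` rows
#' and the remaining rows cycle through the other residues so that none
#' can tie the modal count. Optional gap columns receive a planted
#' fraction of gaps (never in the reference record, which is row 1 and
#' stays gap-free). Defaults mirror a 54-genome, 120-column functional
#' domain alignment with 3 absolutely conserved columns and 49/21/10
#' columns above 50/80/90 percent modal frequency.
#'
#' @param nSeqs number of records; default 54.
#' @param nCols alignment width; default 120.
#' @param modalFreqs numeric vector of length `nCols` in (0, 1]; default
#'   `c(1.0 x3, 0.95 x7, 0.85 x11, 0.6 x28, 0.45 x(nCols-49))`.
#' @param gapCols columns that receive planted gaps.
#' @param gapFraction fraction of records gapped in `gapCols` (default
#'   0.6, i.e. "most sequences").
#' @param referenceId name of the first (reference) record.
#' @param seed RNG seed.
#' @return List: `msa` (gapped `AAStringSet`), `truth` (modal residues,
#'   counts, expected threshold counts and absolute columns), `seed`,
#'   `generatorVersion`.
#' @export
makeMsa <- function(nSeqs = 54L, nCols = 120L, modalFreqs = NULL,
                    gapCols = integer(0), gapFraction = 0.6,
                    referenceId = "REF_HUMAN", seed) {
  if (is.null(modalFreqs)) {
    if (nCols < 49L) stop("default profile needs nCols >= 49")
    modalFreqs <- c(rep(1.0, 3), rep(0.95, 7), rep(0.85, 11),
                    rep(0.60, 28), rep(0.45, nCols - 49))
  }
  if (length(modalFreqs) != nCols)
    stop("modalFreqs must have length nCols")
  if (any(modalFreqs <= 0 | modalFreqs > 1))
    stop("modalFreqs must be in (0, 1]")
  gapCols <- as.integer(gapCols)
  if (any(gapCols < 1L | gapCols > nCols))
    stop("gapCols outside 1..nCols")
  .with_seed(seed, {
    m <- matrix("", nrow = nSeqs, ncol = nCols)
    modalRes <- character(nCols)
    modalCount <- integer(nCols)
    for (j in seq_len(nCols)) {
      isGapCol <- j %in% gapCols
      gapRows <- if (isGapCol)
        sample(2:nSeqs, round(gapFraction * nSeqs)) else integer(0)
      fill <- setdiff(seq_len(nSeqs), gapRows)
      modal <- sample(.AA20, 1)
      k <- round(modalFreqs[j] * nSeqs)
      k <- min(k, length(fill))
      if (k < 1L) stop("modal frequency too low for column ", j)
      modalRows <- c(1L, sample(setdiff(fill, 1L), k - 1L))
      others <- setdiff(fill, modalRows)
      if (length(others)) {
        pool <- sample(setdiff(.AA20, modal))
        reps <- ceiling(length(others) / length(pool))
        if (reps >= k)
          stop("cannot keep residue modal in column ", j,
               ": frequency too low")
        m[others, j] <- rep(pool, reps)[seq_along(others)]
      }
      m[modalRows, j] <- modal
      if (length(gapRows)) m[gapRows, j] <- "-"
      modalRes[j] <- modal
      modalCount[j] <- k
    }
    seqs <- apply(m, 1, paste, collapse = "")
    names(seqs) <- c(referenceId,
                     sprintf("GENOME_%02d", seq_len(nSeqs - 1L)))
    freq <- modalCount / nSeqs
    truth <- list(modalResidues = modalRes, modalCounts = modalCount,
                  modalFrequencies = freq,
                  thresholdCounts = c(">0.5" = sum(freq > 0.5),
                                      ">0.8" = sum(freq > 0.8),
                                      ">0.9" = sum(freq > 0.9)),
                  absoluteColumns = which(modalCount == nSeqs),
                  gapCols = gapCols)
    list(msa = Biostrings::AAStringSet(seqs), truth = truth, seed = seed,
         generatorVersion = .GENERATOR_VERSION)
  })
}

#' Write an alignment in Clustal format
#'
#' Minimal Clustal (.aln) writer for synthetic alignments, readable by
#' standard alignment parsers.
#'
#' @param aln gapped `AAStringSet` (equal widths).
#' @param file output path.
#' @return Invisibly, `file`.
#' @export
writeClustal <- function(aln, file) {
  stopifnot(is(aln, "AAStringSet"))
  w <- Biostrings::width(aln)
  if (length(unique(w)) != 1L) stop("ragged alignment")
  ids <- names(aln)
  pad <- max(nchar(ids)) + 3L
  lines <- c("CLUSTAL W (1.83) multiple sequence alignment", "", "")
  seqs <- as.character(aln)
  for (off in seq(1L, w[1], by = 60L)) {
    chunk <- substring(seqs, off, min(off + 59L, w[1]))
    lines <- c(lines,
               paste0(formatC(ids, width = -pad), chunk), "")
  }
  writeLines(lines, file)
  invisible(file)
}

#' Simulate a two-state unfolding curve
#'
#' Forward model plus optional Gaussian noise (expressed as a fraction of
#' the signal span). Chemical presets mirror a marginally stable
#' 116-residue protein (dG0 = 4.3 kcal/mol, m = 1.55 kcal/mol/M,
#' midpoint near 2.77 M); thermal presets use Tm = 330 K, dHm = 60
#' kcal/mol, dCp = 1.6 kcal/mol/K.
#'
#' @param mode `"chemical"` or `"thermal"`.
#' @param params named list overriding the preset parameters
#'   (`dG0, m, aN, bN, aU, bU, temperatureK, xmin, xmax` for chemical;
#'   `Tm, dHm, dCp, aN, bN, aU, bU, xmin, xmax` for thermal).
#' @param nPoints points on the x grid (default 37).
#' @param noiseSd Gaussian noise SD as a fraction of the baseline span
#'   (default 0).
#' @param seed RNG seed.
#' @return List: `curve` (data.frame x, y), `truth` (full parameter set),
#'   `mode`, `seed`, `generatorVersion`.
#' @export
simulateUnfolding <- function(mode = c("chemical", "thermal"),
                              params = list(), nPoints = 37L,
                              noiseSd = 0, seed) {
  mode <- match.arg(mode)
  defaults <- if (mode == "chemical") {
    list(dG0 = 4.3, m = 1.55, aN = 1.0, bN = -0.02, aU = 0.25, bU = 0.01,
         temperatureK = 293.15, xmin = 0, xmax = 7.2)
  } else {
    list(Tm = 330, dHm = 60, dCp = 1.6, aN = -10, bN = 0.01, aU = -2,
         bU = 0.005, xmin = 293.15, xmax = 363.15)
  }
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown))
    stop("unknown parameter(s) for mode '", mode, "': ",
         paste(unknown, collapse = ", "))
  p <- utils::modifyList(defaults, params)
  x <- seq(p$xmin, p$xmax, length.out = nPoints)
  y <- if (mode == "chemical")
    chemicalUnfoldingSignal(x, p$dG0, p$m, p$aN, p$bN, p$aU, p$bU,
                            p$temperatureK)
  else
    thermalUnfoldingSignal(x, p$Tm, p$dHm, p$dCp, p$aN, p$bN, p$aU, p$bU)
  .with_seed(seed, {
    if (noiseSd > 0) {
      span <- abs((p$aU + p$bU * mean(x)) - (p$aN + p$bN * mean(x)))
      y <- y + rnorm(length(y), sd = noiseSd * span)
    }
    list(curve = data.frame(x = x, y = y), truth = p, mode = mode,
         seed = seed, generatorVersion = .GENERATOR_VERSION)
  })
}

#' Simulate a Gaussian-band absorbance spectrum
#'
#' Sum of Gaussian bands on a uniform wavelength grid plus optional
#' Gaussian noise; the defaults mimic a protein near-UV absorbance band.
#'
#' @param bands list of named numeric vectors `c(center, sigma,
#'   amplitude)` in nm / nm / AU.
#' @param range wavelength window (nm), default `c(240, 340)`.
#' @param step sampling interval (nm), default 0.1.
#' @param noiseSd absolute Gaussian noise SD (AU), default 0.
#' @param seed RNG seed.
#' @return List: `spectrum` ([Spectrum-class]), `truth` (band table),
#'   `seed`, `generatorVersion`.
#' @export
simulateSpectrum <- function(bands, range = c(240, 340), step = 0.1,
                             noiseSd = 0, seed) {
  if (step <= 0) stop("step must be positive")
  wl <- seq(range[1], range[2], by = step)
  y <- numeric(length(wl))
  truth <- data.frame(center = numeric(0), sigma = numeric(0),
                      amplitude = numeric(0))
  for (b in bands) {
    if (!all(c("center", "sigma", "amplitude") %in% names(b)))
      stop("each band needs center, sigma and amplitude")
    if (b[["center"]] < range[1] || b[["center"]] > range[2])
      stop("band center outside the wavelength range")
    y <- y + b[["amplitude"]] *
      exp(-(wl - b[["center"]])^2 / (2 * b[["sigma"]]^2))
    truth <- rbind(truth, as.data.frame(as.list(b[c("center", "sigma",
                                                    "amplitude")])))
  }
  .with_seed(seed, {
    if (noiseSd > 0) y <- y + rnorm(length(y), sd = noiseSd)
    list(spectrum = Spectrum(wl, y), truth = truth, seed = seed,
         generatorVersion = .GENERATOR_VERSION)
  })
}

#' Extended peptide backbone (synthetic geometry)
#'
#' Builds an idealised fully extended backbone (N, CA, C, O per residue;
#' CB for non-glycine) as a planar zig-zag with standard bond lengths
#' and angles. Intended for accessibility reference checks (an extended
#' Gly-X-Gly tripeptide is the reference state of relative SASA).
#'
#' @param sequence one-letter sequence (e.g. "GGG").
#' @return A [ProteinStructure-class] with chain "A".
#' @export
makeExtendedPeptide <- function(sequence) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  if (!all(chars %in% .AA20)) stop("standard residues only")
  three <- names(.AA_3TO1)[match(chars, .AA_3TO1)]
  # planar zig-zag: bond lengths N-CA 1.458, CA-C 1.525, C-N 1.329;
  # supplementary turn angles from the canonical backbone bond angles
  blen <- c(NCA = 1.458, CAC = 1.525, CN = 1.329)
  turn <- c(NCA = pi - 111.0 * pi / 180,  # N-CA-C
            CAC = pi - 116.6 * pi / 180,  # CA-C-N
            CN = pi - 121.9 * pi / 180)   # C-N-CA
  pos <- matrix(0, nrow = 3 * length(chars), ncol = 2)
  dir <- 0
  sgn <- 1
  p <- c(0, 0)
  k <- 1L
  pos[1, ] <- p
  steps <- rep(c("NCA", "CAC", "CN"), length(chars))[-(3 * length(chars))]
  for (s in steps) {
    k <- k + 1L
    p <- p + blen[[s]] * c(cos(dir), sin(dir))
    pos[k, ] <- p
    dir <- dir + sgn * turn[[s]]
    sgn <- -sgn
  }
  rows <- list()
  for (i in seq_along(chars)) {
    base <- (i - 1L) * 3L
    n <- pos[base + 1L, ]; ca <- pos[base + 2L, ]; cc <- pos[base + 3L, ]
    rows[[length(rows) + 1L]] <- data.frame(
      type = "ATOM", chain = "A", resno = i, insert = NA,
      resid = three[i],
      elety = c("N", "CA", "C"), alt = NA, elesy = c("N", "C", "C"),
      x = c(n[1], ca[1], cc[1]), y = c(n[2], ca[2], cc[2]), z = 0, o = 1)
    # carbonyl O: 1.231 A off the carbonyl carbon, out of the chain line
    od <- cc - ca
    od <- od / sqrt(sum(od^2))
    operp <- c(-od[2], od[1])
    o <- cc + 1.231 * (0.45 * od + 0.89 * operp * ifelse(i %% 2 == 0, -1, 1))
    rows[[length(rows) + 1L]] <- data.frame(
      type = "ATOM", chain = "A", resno = i, insert = NA, resid = three[i],
      elety = "O", alt = NA, elesy = "O", x = o[1], y = o[2], z = 0, o = 1)
    if (chars[i] != "G") {
      cb <- ca + c(0, 0)  # placed off-plane below
      rows[[length(rows) + 1L]] <- data.frame(
        type = "ATOM", chain = "A", resno = i, insert = NA,
        resid = three[i], elety = "CB", alt = NA, elesy = "C",
        x = cb[1], y = cb[2], z = 1.53, o = 1)
    }
  }
  tab <- do.call(rbind, rows)
  .structure_from_atom_table(tab, source = paste0("makeExtendedPeptide(",
                                                  sequence, ")"),
                             format = "synthetic")
}
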