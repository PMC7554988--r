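#' Shrake-Rupley solvent-accessible surface area
#'
#' Per-atom SASA by sphere-point sampling: each atom is expanded by the
#' probe radius and covered with a deterministic golden-spiral quadrature;
#' a point counts as accessible when it lies outside every neighbouring
#' expanded sphere. Per-residue values are the sums over the residue's
#' atoms. Hydrogens, if present, are excluded (heavy-atom convention).
#'
#' `chainSubset` restricts both the atoms reported and the occluding
#' context, which is what distinguishes an isolated-chain calculation
#' from an in-complex one: compute a chain alone versus together with its
#' partners and compare (see [deltaSasaOnBinding()]).
#'
#' @param x a [ProteinStructure-class].
#' @param probeRadius solvent probe radius in Angstrom (default 1.4).
#' @param nPoints quadrature points per atom (default 960; at least 100).
#' @param chainSubset optional character vector of chain identifiers; the
#'   calculation is restricted to (and occluded by) these chains only.
#' @return A [SasaResult-class].
#' @references Shrake & Rupley (1973) J Mol Biol 79:351-371.
#' @examples
#' toy <- makeToyComplex(3, 3, 0, seed = 1)
#' sr <- shrakeRupleySasa(toy$structure, chainSubset = "A")
#' head(perResidueSasa(sr))
#' @export
shrakeRupleySasa <- function(x, probeRadius = 1.4, nPoints = 960L,
                             chainSubset = NULL) {
  stopifnot(is(x, "ProteinStructure"))
  if (nPoints < 100L) stop("nPoints must be at least 100")
  if (probeRadius < 0) stop("probeRadius must be non-negative")
  a <- x@atoms
  if (!is.null(chainSubset)) {
    missing_ch <- setdiff(chainSubset, x@chains)
    if (length(missing_ch))
      stop("chain(s) not in structure: ", paste(missing_ch, collapse = ", "))
    a <- a[a$chain %in% chainSubset, , drop = FALSE]
  }
  drop_h <- a$elesy == "H"
  if (any(drop_h)) a <- a[!drop_h, , drop = FALSE]
  resBefore <- .residue_table(x@atoms[if (is.null(chainSubset)) TRUE else
    x@atoms$chain %in% chainSubset, , drop = FALSE])
  if (nrow(a) == 0L) stop("no heavy atoms in the selected chains")

  unknown <- setdiff(unique(a$elesy), names(.VDW_RADII))
  if (length(unknown)) {
    bad <- a[a$elesy %in% unknown, ]
    stop("no van der Waals radius for element(s) ",
         paste(unknown, collapse = ", "), "; offending atoms: ",
         paste(head(paste0(bad$chain, "/", bad$resid, bad$resno, "/",
                           bad$elety), 5), collapse = ", "))
  }

  r <- unname(.VDW_RADII[a$elesy]) + probeRadius
  xyz <- as.matrix(a[, c("x", "y", "z")])
  pts <- .sphere_points(as.integer(nPoints))
  n <- nrow(a)
  sasa <- numeric(n)

  maxr <- max(r)
  for (i in seq_len(n)) {
    ci <- xyz[i, ]
    d2i <- (xyz[, 1] - ci[1])^2 + (xyz[, 2] - ci[2])^2 + (xyz[, 3] - ci[3])^2
    nb <- which(d2i < (r[i] + maxr)^2 & seq_len(n) != i)
    nb <- nb[d2i[nb] < (r[i] + r[nb])^2]
    if (!length(nb)) {
      sasa[i] <- 4 * pi * r[i]^2
      next
    }
    p <- sweep(pts * r[i], 2, ci, "+")
    acc <- rep(TRUE, nrow(p))
    for (j in nb) {
      if (!any(acc)) break
      cj <- xyz[j, ]
      dj2 <- (p[, 1] - cj[1])^2 + (p[, 2] - cj[2])^2 + (p[, 3] - cj[3])^2
      # a point exactly on the neighbour surface (degenerate, e.g.
      # duplicated atoms) is resolved deterministically: the
      # earlier-indexed atom keeps the surface
      tol <- 1e-9 * r[j]^2
      buried <- dj2 < r[j]^2 - tol
      if (j < i) buried <- buried | abs(dj2 - r[j]^2) <= tol
      acc <- acc & !buried
    }
    sasa[i] <- 4 * pi * r[i]^2 * sum(acc) / nrow(p)
  }

  a$sasa <- sasa
  key <- paste(a$chain, a$resno, a$insert, sep = "\r")
  per <- .residue_table(a)
  pkey <- paste(per$chain, per$resno, per$insert, sep = "\r")
  per$sasa <- as.numeric(tapply(a$sasa, key, sum)[pkey])

  droppedRes <- setdiff(paste(resBefore$chain, resBefore$resno,
                              resBefore$insert, sep = "\r"), pkey)
  if (length(droppedRes))
    warning(length(droppedRes),
            " residue(s) had no heavy atoms and were dropped")

  rownames(a) <- rownames(per) <- NULL
  new("SasaResult", atoms = a, perResidue = per,
      probeRadius = probeRadius, nSpherePoints = as.integer(nPoints))
}

# deterministic golden-spiral points on the unit sphere
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Relative (percent) solvent accessibility of a residue
#'
#' 100 x residue SASA / theoretical maximum for that residue type in an
#' extended Gly-X-Gly tripeptide (Tien et al. 2013 theoretical set).
#'
#' @param sasa a [SasaResult-class].
#' @param chain,resno,insert residue identity within the result.
#' @param referenceTable name of the max-SASA reference set; only
#'   `"tien2013"` is shipped.
#' @return Percent relative accessibility (can exceed 100 for an isolated
#'   residue without neighbours).
#' @export
relativeSasa <- function(sasa, chain, resno, insert = "",
                         referenceTable = "tien2013") {
  stopifnot(is(sasa, "SasaResult"))
  if (!identical(referenceTable, "tien2013"))
    stop("unknown reference table: ", referenceTable)
  per <- sasa@perResidue
  row <- per$chain == chain & per$resno == resno & per$insert == insert
  if (!any(row))
    stop("residue ", chain, "/", resno, insert, " not in SASA result")
  resname <- per$resid[row][1]
  if (!resname %in% names(.MAX_SASA_TIEN2013))
    stop("no reference maximum SASA for residue type '", resname, "'")
  100 * per$sasa[row][1] / .MAX_SASA_TIEN2013[[resname]]
}

#' Per-residue SASA change upon complex formation
#'
#' Computes the accessibility of every residue of `chain` twice: with the
#' chain isolated (`sasa_free`) and with the partner chains present as
#' occluders (`sasa_complex`), plus relative accessibilities for standard
#' residues. Because the same quadrature points are used, adding occluders
#' can only bury points, so `sasa_complex <= sasa_free` holds exactly.
#'
#' @param x a [ProteinStructure-class].
#' @param chain chain whose residues are reported.
#' @param partnerChains non-empty character vector of occluding chains.
#' @param probeRadius,nPoints passed to [shrakeRupleySasa()].
#' @return data.frame: chain, resno, insert, resid, sasa_free,
#'   sasa_complex, relative_free, relative_complex (percent; `NA` for
#'   nonstandard residues), delta_sasa.
#' @examples
#' toy <- makeToyComplex(5, 5, 2, seed = 1)
#' d <- deltaSasaOnBinding(toy$structure, "A", "B")
#' head(d)
#' @export
deltaSasaOnBinding <- function(x, chain, partnerChains,
                               probeRadius = 1.4, nPoints = 960L) {
  stopifnot(is(x, "ProteinStructure"))
  if (length(partnerChains) == 0L)
    stop("partnerChains must not be empty")
  free <- shrakeRupleySasa(x, probeRadius, nPoints, chainSubset = chain)
  bound <- shrakeRupleySasa(x, probeRadius, nPoints,
                            chainSubset = unique(c(chain, partnerChains)))
  pf <- free@perResidue
  pb <- bound@perResidue
  pb <- pb[pb$chain == chain, , drop = FALSE]
  keyf <- paste(pf$resno, pf$insert)
  keyb <- paste(pb$resno, pb$insert)
  m <- match(keyf, keyb)
  ref <- unname(.MAX_SASA_TIEN2013[pf$resid])
  out <- data.frame(chain = pf$chain, resno = pf$resno, insert = pf$insert,
                    resid = pf$resid,
                    sasa_free = pf$sasa, sasa_complex = pb$sasa[m],
                    relative_free = 100 * pf$sasa / ref,
                    relative_complex = 100 * pb$sasa[m] / ref)
  out$delta_sasa <- out$sasa_free - out$sasa_complex
  out
}
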