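#' Contact residues between two chains or a chain and a ligand
#'
#' Identifies the residues of `chainA` having any (heavy) atom at
#' Euclidean distance strictly below `cutoff` from any qualifying atom of
#' the partner, and vice versa. The partner is either a chain identifier
#' (polymer residues only) or a ligand selector of the form
#' `"resname:XXX"`, which selects hetero residues named `XXX` on any
#' chain (e.g. the PLP-derived cofactor of a cysteine desulfurase).
#'
#' The cutoff is strict (`< cutoff`): a nearest pair at exactly the cutoff
#' distance is excluded. Hydrogens are ignored when `heavyOnly = TRUE`
#' (the default; cryo-EM models carry no reliable hydrogens).
#'
#' @param x a [ProteinStructure-class].
#' @param chainA chain identifier of the first partner.
#' @param partner chain identifier or `"resname:XXX"` ligand selector.
#' @param cutoff distance cutoff in Angstrom, default 4.0.
#' @param heavyOnly ignore hydrogen atoms. Default `TRUE`.
#' @return An [InterfaceSet-class]; empty residue tables (not an error)
#'   when no contacts exist.
#' @examples
#' toy <- makeToyComplex(5, 5, 2, seed = 1)
#' iface <- contactResidues(toy$structure, "A", "B")
#' interfaceResidues(iface)
#' @export
contactResidues <- function(x, chainA, partner, cutoff = 4.0,
                            heavyOnly = TRUE) {
  stopifnot(is(x, "ProteinStructure"))
  if (!is.numeric(cutoff) || cutoff <= 0) stop("cutoff must be > 0")
  a <- x@atoms
  if (heavyOnly) a <- a[a$elesy != "H", , drop = FALSE]

  selA <- a$chain == chainA & !a$hetero
  if (!any(selA))
    stop("chain '", chainA, "' has no (polymer) atoms")

  if (grepl("^resname:", partner)) {
    lig <- sub("^resname:", "", partner)
    selB <- a$resid == lig
    if (!any(selB))
      stop("no atoms with residue name '", lig, "'")
  } else {
    selB <- a$chain == partner & !a$hetero
    if (!any(selB))
      stop("chain '", partner, "' has no (polymer) atoms")
  }

  A <- a[selA, , drop = FALSE]
  B <- a[selB, , drop = FALSE]
  d2 <- .pairwise_dist2(as.matrix(A[, c("x", "y", "z")]),
                        as.matrix(B[, c("x", "y", "z")]))
  hit <- d2 < cutoff^2

  keyA <- paste(A$chain, A$resno, A$insert, sep = "\r")
  keyB <- paste(B$chain, B$resno, B$insert, sep = "\r")
  labB <- paste0(B$resid, B$resno, ifelse(B$insert == "", "", B$insert))
  labA <- paste0(A$resid, A$resno, ifelse(A$insert == "", "", A$insert))

  resA <- .contact_side(A, keyA, hit, d2, labOther = labB, keyOther = keyB)
  resB <- .contact_side(B, keyB, t(hit), t(d2), labOther = labA,
                        keyOther = keyA)

  new("InterfaceSet", chainA = chainA, partner = partner, cutoff = cutoff,
      residuesA = resA, residuesPartner = resB)
}

# squared distances between two coordinate matrices
.pairwise_dist2 <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  d2[d2 < 0] <- 0  # numerical noise
  d2
}

# summarise contacts on one side: one row per residue with any hit
.contact_side <- function(A, keyA, hit, d2, labOther, keyOther) {
  anyHit <- tapply(rowSums(hit) > 0, keyA, any)
  resTab <- .residue_table(A)
  rkey <- paste(resTab$chain, resTab$resno, resTab$insert, sep = "\r")
  keep <- rkey[as.logical(anyHit[rkey])]
  resTab <- resTab[rkey %in% keep, , drop = FALSE]
  if (nrow(resTab) == 0L) {
    resTab$min_distance <- numeric(0)
    resTab$partner_residues <- character(0)
    return(resTab)
  }
  resTab$min_distance <- vapply(
    paste(resTab$chain, resTab$resno, resTab$insert, sep = "\r"),
    function(k) sqrt(min(d2[keyA == k, , drop = FALSE])), numeric(1),
    USE.NAMES = FALSE)
  resTab$partner_residues <- vapply(
    paste(resTab$chain, resTab$resno, resTab$insert, sep = "\r"),
    function(k) {
      h <- hit[keyA == k, , drop = FALSE]
      cols <- colSums(h) > 0
      ks <- keyOther[cols]
      lb <- labOther[cols]
      u <- !duplicated(ks)
      paste(lb[u][order(ks[u])], collapse = ";")
    }, character(1), USE.NAMES = FALSE)
  resTab <- resTab[order(resTab$chain, resTab$resno, resTab$insert), ,
                   drop = FALSE]
  rownames(resTab) <- NULL
  resTab
}

#' Export an interface as a CSV table
#'
#' One row per interface residue of the first partner: chain, residue
#' number, insertion code, residue name, minimal heavy-atom distance and
#' the contacting partner residues.
#'
#' @param iface an [InterfaceSet-class].
#' @param file output CSV path.
#' @return Invisibly, the written data.frame.
#' @export
writeInterfaceCsv <- function(iface, file) {
  stopifnot(is(iface, "InterfaceSet"))
  df <- interfaceResidues(iface)
  out <- data.frame(chain = df$chain, resnum = df$resno, icode = df$insert,
                    resname = df$resid,
                    min_distance_A = round(df$min_distance, 3),
                    partner_residues = df$partner_residues)
  write.csv(out, file, row.names = FALSE)
  invisible(out)
}
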