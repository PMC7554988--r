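#' Read a protein complex structure from PDB or mmCIF
#'
#' Parses a coordinate file into a [ProteinStructure-class]. Alternate
#' locations are resolved by keeping the highest-occupancy copy of each
#' atom (ties broken by the alphabetically first altloc identifier).
#' Water molecules are excluded by default; all other hetero groups (PLP
#' derivatives, metals, ...) are retained and flagged in the `hetero`
#' column so that ligand interfaces are first-class.
#'
#' Missing element symbols are inferred from the atom name, with a warning
#' naming the affected atoms.
#'
#' @param file path to a PDB or mmCIF file.
#' @param format `"auto"` (from the file extension), `"pdb"` or `"mmcif"`.
#' @param removeWaters drop water residues (HOH/WAT/DOD). Default `TRUE`.
#' @return A [ProteinStructure-class] object.
#' @seealso [contactResidues()], [shrakeRupleySasa()]
#' @examples
#' toy <- makeToyComplex(4, 4, 1, seed = 1)
#' pdb <- tempfile(fileext = ".pdb")
#' writeLines(toy$pdbText, pdb)
#' readStructure(pdb)
#' @export
readStructure <- function(file, format = c("auto", "pdb", "mmcif"),
                          removeWaters = TRUE) {
  format <- match.arg(format)
  if (!file.exists(file))
    stop("structure file not found: ", file)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(file))
    format <- switch(ext, cif = "mmcif", mmcif = "mmcif", pdb = "pdb",
                     ent = "pdb",
                     stop("cannot infer format from extension '", ext,
                          "'; pass format explicitly"))
  }
  parsed <- tryCatch(
    if (format == "pdb") {
      bio3d::read.pdb(file, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
    } else {
      bio3d::read.cif(file, verbose = FALSE)
    },
    error = function(e) {
      stop("failed to parse ", format, " file '", file, "': ",
           conditionMessage(e), call. = FALSE)
    })
  .structure_from_atom_table(parsed$atom, source = file, format = format,
                             removeWaters = removeWaters)
}

# Build a ProteinStructure from a bio3d-style atom table; shared between
# the file reader and the synthetic generator.
.structure_from_atom_table <- function(at, source, format,
                                       removeWaters = TRUE) {
  a <- data.frame(
    chain = ifelse(is.na(at$chain), " ", at$chain),
    resno = at$resno,
    insert = ifelse(is.na(at$insert), "", at$insert),
    resid = at$resid,
    elety = at$elety,
    alt = if ("alt" %in% names(at)) ifelse(is.na(at$alt), "", at$alt) else "",
    elesy = if ("elesy" %in% names(at)) at$elesy else NA_character_,
    x = at$x, y = at$y, z = at$z,
    o = if ("o" %in% names(at)) ifelse(is.na(at$o), 1, at$o) else 1,
    hetero = if ("type" %in% names(at)) at$type == "HETATM" else FALSE,
    stringsAsFactors = FALSE)

  if (removeWaters)
    a <- a[!(a$resid %in% .WATER_RESNAMES), , drop = FALSE]
  if (nrow(a) == 0L)
    stop("no atoms left after filtering in ", source)

  # altloc resolution: highest occupancy wins, ties to the alphabetically
  # first altloc identifier
  key <- paste(a$chain, a$resno, a$insert, a$elety, sep = "\r")
  ord <- order(key, -a$o, a$alt)
  a <- a[ord, , drop = FALSE]
  a <- a[!duplicated(key[ord]), , drop = FALSE]

  # element symbols: take from the file, infer from atom names otherwise
  miss <- is.na(a$elesy) | a$elesy == ""
  if (any(miss)) {
    inferred <- toupper(sub("^[0-9' ]*", "", a$elety[miss]))
    two <- substr(inferred, 1, 2)
    one <- substr(inferred, 1, 1)
    a$elesy[miss] <- ifelse(two %in% names(.VDW_RADII) &
                              !(one %in% c("C", "N", "O", "H", "P", "S")),
                            two, one)
    warning(sum(miss), " atom(s) lacked an element symbol; inferred from ",
            "atom names (e.g. ", paste(head(a$elety[miss], 3), collapse = ", "),
            ")")
  }
  a$elesy <- toupper(a$elesy)

  a <- a[order(a$chain, a$resno, a$insert, a$elety), , drop = FALSE]
  rownames(a) <- NULL
  a$alt <- NULL
  new("ProteinStructure", atoms = a, chains = sort(unique(a$chain)),
      source = source, format = format)
}

# residue-level table (one row per residue) from an atom table
.residue_table <- function(a) {
  key <- paste(a$chain, a$resno, a$insert, sep = "\r")
  first <- !duplicated(key)
  out <- a[first, c("chain", "resno", "insert", "resid", "hetero")]
  rownames(out) <- NULL
  out
}
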