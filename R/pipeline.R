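# End-to-end orchestration: structure -> interfaces -> ortholog
# alignment -> region identities -> conservation -> merged report.

#' Validate and normalise a pipeline configuration
#'
#' A configuration is a named list (or a YAML file holding one) with:
#' \describe{
#'   \item{structure}{path to a PDB/mmCIF file.}
#'   \item{hubRole}{role name of the hub protein (default "NFS1").}
#'   \item{roleChains}{named list role -> chain identifier; the hub role
#'     must be present. A ligand role maps to a `"resname:XXX"` selector.}
#'   \item{cutoff}{contact cutoff in Angstrom (default 4.0).}
#'   \item{pairs}{named list role -> list(a=, b=) of FASTA paths or raw
#'     sequences: the hub protein of the reference organism (`a`) and its
#'     ortholog (`b`).}
#'   \item{alignMode}{"local" (default) or "global".}
#'   \item{resnoOffset}{integer: sequence position = structure residue
#'     number - offset (default 0).}
#' }
#' Validation happens before any computation so a misconfigured run
#' fails fast.
#'
#' @param config named list or YAML path.
#' @return The normalised configuration list.
#' @export
readPipelineConfig <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  defaults <- list(hubRole = "NFS1", cutoff = 4.0, alignMode = "local",
                   resnoOffset = 0L)
  config <- utils::modifyList(defaults, config)
  for (field in c("structure", "roleChains", "pairs")) {
    if (is.null(config[[field]]))
      stop("config is missing required field '", field, "'")
  }
  if (is.character(config$structure) && !file.exists(config$structure) &&
      !is(config$structure, "ProteinStructure"))
    stop("structure file not found: ", config$structure)
  if (!config$hubRole %in% names(config$roleChains))
    stop("roleChains must include the hub role '", config$hubRole, "'")
  if (config$cutoff <= 0) stop("cutoff must be positive")
  config
}

#' Run the interface-conservation analysis end to end
#'
#' For each partner role: extracts the hub-chain residues within the
#' cutoff of the partner (chain or ligand), aligns the hub protein
#' against its ortholog, and reports the overall identity, the identity
#' restricted to the interface region, and their difference. The report
#' echoes every numeric convention used (strict cutoff, heavy atoms,
#' denominator policies) plus input checksums, so results are
#' self-describing.
#'
#' @param config a configuration list or YAML path, see
#'   [readPipelineConfig()].
#' @return A report list with elements `pairs` (one entry per partner
#'   role), `overall` (hub alignment statistics), `conventions`,
#'   `provenance` and `timestamp`.
#' @examples
#' toy <- makeToyComplex(6, 6, 3, seed = 2)
#' pair <- makeOrthologPair(6, region = 1:3, regionIdentity = 1,
#'                          backgroundIdentity = 0, seed = 2)
#' pdb <- tempfile(fileext = ".pdb"); writeLines(toy$pdbText, pdb)
#' cfg <- list(structure = pdb, roleChains = list(HUB = "A", P1 = "B"),
#'             hubRole = "HUB",
#'             pairs = list(HUB = list(a = pair$seqA, b = pair$seqB)),
#'             alignMode = "global")
#' rep <- runInterfaceConservation(cfg)
#' rep$pairs$P1$interface_identity_pct
#' @export
runInterfaceConservation <- function(config) {
  cfg <- readPipelineConfig(config)
  struct <- if (is(cfg$structure, "ProteinStructure")) cfg$structure else
    readStructure(cfg$structure)
  hubChain <- cfg$roleChains[[cfg$hubRole]]
  if (!grepl("^resname:", hubChain) && !hubChain %in% chains(struct))
    stop("hub chain '", hubChain, "' not present in the structure")
  partnerRoles <- setdiff(names(cfg$roleChains), cfg$hubRole)
  for (role in partnerRoles) {
    ch <- cfg$roleChains[[role]]
    if (!grepl("^resname:", ch) && !ch %in% chains(struct))
      stop("chain '", ch, "' for role '", role,
           "' not present in the structure")
  }
  hubPair <- cfg$pairs[[cfg$hubRole]]
  if (is.null(hubPair))
    stop("pairs must include the hub role '", cfg$hubRole, "'")

  seqA <- .pipeline_sequence(hubPair$a)
  seqB <- .pipeline_sequence(hubPair$b)
  aln <- alignPair(seqA, seqB, mode = cfg$alignMode)
  overall <- identityStats(aln)

  pairReports <- list()
  for (role in partnerRoles) {
    iface <- contactResidues(struct, hubChain, cfg$roleChains[[role]],
                             cutoff = cfg$cutoff)
    resA <- interfaceResidues(iface)
    positions <- resA$resno - cfg$resnoOffset
    positions <- positions[positions >= 1 & positions <= nchar(seqA)]
    entry <- list(role = role, chain = cfg$roleChains[[role]],
                  n_interface_residues = nrow(resA),
                  interface_residues = resA$resno)
    if (length(positions)) {
      reg <- regionIdentity(aln, positions,
                            regionName = paste0(cfg$hubRole, "-", role))
      entry$interface_identity_pct <- reg@identityPct
      entry$interface_similarity_pct <- reg@similarityPct
      entry$identity_delta <- reg@identityPct - overall[["identity_pct"]]
    } else {
      entry$interface_identity_pct <- NA_real_
      entry$interface_similarity_pct <- NA_real_
      entry$identity_delta <- NA_real_
    }
    pairReports[[role]] <- entry
  }

  provenance <- list(
    package_version = as.character(utils::packageVersion("FeSConserv")),
    structure_md5 = if (is.character(cfg$structure))
      unname(tools::md5sum(cfg$structure)) else "in-memory",
    config_hash = .hash_object(cfg[setdiff(names(cfg), "structure")]))

  list(schema_version = "1.0",
       hub = list(role = cfg$hubRole, chain = hubChain,
                  idA = aln@idA, idB = aln@idB),
       overall = as.list(overall),
       pairs = pairReports,
       conventions = list(
         cutoff_A = cfg$cutoff, cutoff_strict = TRUE, heavy_atoms_only = TRUE,
         align_mode = cfg$alignMode,
         overall_denominator = "aligned_columns",
         region_denominator = "region_positions"),
       provenance = provenance,
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

.pipeline_sequence <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    ss <- readSequences(x)
    if (length(ss) < 1L) stop("no sequences in ", x)
    return(setNames(as.character(ss[[1]]), names(ss)[1]))
  }
  x
}

# stable md5 of an R object via its serialised text representation
.hash_object <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  dput(x, file = tf)
  unname(tools::md5sum(tf))
}

#' Merge stage outputs into a single report
#'
#' Stage outputs are named lists (e.g. the result of
#' [runInterfaceConservation()], threshold statistics, fit summaries).
#' The merged summary is schema-versioned and serialisable to JSON; a
#' re-run on identical inputs is identical except for the timestamp.
#'
#' @param stages named list of stage outputs (may be empty).
#' @param file optional JSON output path.
#' @return The merged report list (invisibly when written to a file).
#' @export
runReport <- function(stages = list(), file = NULL) {
  if (!is.list(stages)) stop("stages must be a list")
  if (length(stages) && is.null(names(stages)))
    stop("stages must be named")
  report <- list(schema_version = "1.0",
                 n_stages = length(stages),
                 stages = stages,
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  if (!is.null(file)) {
    jsonlite::write_json(report, file, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
    return(invisible(report))
  }
  report
}

#' Plain-text summary table of an interface-conservation report
#'
#' @param report output of [runInterfaceConservation()].
#' @return Character vector of formatted lines (also printed).
#' @export
formatReportTable <- function(report) {
  lines <- c(sprintf("%-10s %10s %14s %14s %8s", "partner", "n_iface",
                     "iface_id_%", "overall_id_%", "delta"))
  for (p in report$pairs) {
    lines <- c(lines, sprintf("%-10s %10d %14.1f %14.1f %+8.1f",
                              p$role, p$n_interface_residues,
                              p$interface_identity_pct,
                              report$overall$identity_pct,
                              p$identity_delta))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
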