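#' @importFrom utils head tail
NULL

HARTREE_TO_KCAL <- 627.509

#' Read a multi-record SDF file as a conformer ensemble
#'
#' Each V2000 record becomes one conformer, in file order. The conformer
#' energy is taken from a named data field of the record; its name is
#' configurable because deposited ensembles use different dialects
#' (`energy`, `E_kcal`, ...).
#'
#' @param path Path to an SDF file.
#' @param catalyst_id,method_label Provenance attached to every conformer.
#' @param energy_property_name Name of the SDF data field holding the
#'   energy. Default `"energy"`.
#' @param constrained Logical; provenance flag.
#' @param energy_unit `"kcal/mol"` (default) or `"hartree"`; hartree values
#'   are converted with 627.509 kcal/mol per hartree.
#' @return An [ensemble()].
#' @export
read_sdf <- function(path, catalyst_id, method_label,
                     energy_property_name = "energy",
                     constrained = FALSE, energy_unit = c("kcal/mol", "hartree")) {
  energy_unit <- match.arg(energy_unit)
  if (!file.exists(path)) stop("file not found: ", path)
  if (!any(nzchar(readLines(path, warn = FALSE)))) stop("no records in ", path)
  sdfset <- withCallingHandlers(
    ChemmineR::read.SDFset(path),
    warning = function(w) {
      if (grepl("invalid SDFs", conditionMessage(w))) invokeRestart("muffleWarning")
    })
  n <- length(sdfset)
  if (n == 0L) stop("no records in ", path)
  datab <- ChemmineR::datablock(sdfset)
  confs <- vector("list", n)
  for (i in seq_len(n)) {
    sdf <- sdfset[[i]]
    ab <- ChemmineR::atomblock(sdf)
    coords <- unname(ab[, 1:3, drop = FALSE])
    symbols <- sub("_\\d+$", "", rownames(ab))
    fields <- datab[[i]]
    if (is.null(fields) || !(energy_property_name %in% names(fields)))
      stop(sprintf("record %d lacks energy property '%s'", i, energy_property_name))
    energy <- suppressWarnings(as.numeric(fields[[energy_property_name]]))
    if (is.na(energy))
      stop(sprintf("record %d has a non-numeric '%s' value", i, energy_property_name))
    if (energy_unit == "hartree") energy <- energy * HARTREE_TO_KCAL
    id <- ChemmineR::header(sdf)[["Molecule_Name"]]
    if (!nzchar(id)) id <- sprintf("%s_%s_%03d", catalyst_id, method_label, i)
    confs[[i]] <- conformer(id, catalyst_id, method_label, coords, energy,
                            atom_symbols = symbols, constrained = constrained)
  }
  # shared atom ordering across records is enforced by ensemble()
  ensemble(confs, provenance = path)
}

#' Write an ensemble to a multi-record V2000 SDF file
#'
#' Coordinates are written to 4 decimals; the energy goes into a data field
#' (default name `"energy"`, kcal/mol). Connectivity is not part of the
#' benchmark; by default a sequential chain bond block is written so records
#' are structurally valid, which is exact for the synthetic chain molecules
#' this package generates.
#'
#' @param e An [ensemble()].
#' @param path Output path.
#' @param energy_property_name Data field name for the energy.
#' @param bonds Optional m x 2 integer matrix of single bonds (1-based atom
#'   indices); default is the sequential chain.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(e, path, energy_property_name = "energy", bonds = NULL) {
  stopifnot(inherits(e, "ensemble"))
  na <- ensemble_n_atoms(e)
  if (is.null(bonds)) bonds <- cbind(seq_len(na - 1L), 2:na)
  lines <- character(0)
  for (cf in e$conformers) {
    atom_lines <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                          cf$coords[, 1], cf$coords[, 2], cf$coords[, 3],
                          cf$atom_symbols)
    bond_lines <- sprintf("%3d%3d  1  0  0  0  0", bonds[, 1], bonds[, 2])
    rec <- c(cf$conformer_id,
             "  confbench",
             "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nrow(bonds)),
             atom_lines, bond_lines,
             "M  END",
             sprintf(">  <%s>", energy_property_name),
             format(cf$energy, digits = 15, scientific = FALSE, trim = TRUE),
             "",
             "$$$$")
    lines <- c(lines, rec)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a multi-frame XYZ file as a conformer ensemble
#'
#' Every frame is `n_atoms`, a comment line, then `n_atoms` element/x/y/z
#' rows. The energy is parsed from the comment line: the first numeric token,
#' optionally prefixed by an `Energy=` key (case-insensitive, `=` glued or
#' followed by whitespace).
#'
#' @inheritParams read_sdf
#' @return An [ensemble()].
#' @export
read_xyz <- function(path, catalyst_id, method_label, constrained = FALSE,
                     energy_unit = c("kcal/mol", "hartree")) {
  energy_unit <- match.arg(energy_unit)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0L))]
  if (!length(lines)) stop("no records in ", path)
  confs <- list()
  pos <- 1L; frame <- 0L
  while (pos <= length(lines)) {
    frame <- frame + 1L
    na <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(na) || na < 1L)
      stop(sprintf("frame %d: bad atom-count line '%s'", frame, lines[pos]))
    if (pos + 1L + na > length(lines))
      stop(sprintf("frame %d: truncated (expected %d atom rows)", frame, na))
    energy <- parse_xyz_energy(lines[pos + 1L])
    if (is.na(energy))
      stop(sprintf("frame %d: no numeric energy in comment '%s'", frame, lines[pos + 1L]))
    if (energy_unit == "hartree") energy <- energy * HARTREE_TO_KCAL
    rows <- strsplit(trimws(lines[pos + 1L + seq_len(na)]), "\\s+")
    if (any(lengths(rows) < 4L))
      stop(sprintf("frame %d: malformed atom row", frame))
    symbols <- vapply(rows, `[`, character(1), 1L)
    coords <- matrix(as.numeric(vapply(rows, function(r) r[2:4], character(3))),
                     ncol = 3L, byrow = TRUE)
    if (anyNA(coords)) stop(sprintf("frame %d: non-numeric coordinates", frame))
    confs[[frame]] <- conformer(sprintf("%s_%s_%03d", catalyst_id, method_label, frame),
                                catalyst_id, method_label, coords, energy,
                                atom_symbols = symbols, constrained = constrained)
    pos <- pos + 2L + na
  }
  ensemble(confs, provenance = path)
}

parse_xyz_energy <- function(comment) {
  tokens <- strsplit(trimws(comment), "\\s+")[[1]]
  if (!length(tokens)) return(NA_real_)
  # strip an optional Energy= key, glued or free-standing
  tokens <- sub("^[Ee]nergy=?", "", tokens)
  tokens <- tokens[nzchar(tokens)]
  vals <- suppressWarnings(as.numeric(tokens))
  if (!any(!is.na(vals))) return(NA_real_)
  vals[which(!is.na(vals))[1]]
}

#' Write an ensemble to a multi-frame XYZ file
#'
#' The comment line is `Energy= <kcal/mol>`; coordinates are written to
#' 4 decimals.
#'
#' @param e An [ensemble()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(e, path) {
  stopifnot(inherits(e, "ensemble"))
  na <- ensemble_n_atoms(e)
  lines <- unlist(lapply(e$conformers, function(cf) {
    c(as.character(na),
      sprintf("Energy= %s", format(cf$energy, digits = 15, scientific = FALSE, trim = TRUE)),
      sprintf("%-3s %12.4f %12.4f %12.4f", cf$atom_symbols,
              cf$coords[, 1], cf$coords[, 2], cf$coords[, 3]))
  }))
  writeLines(lines, path)
  invisible(path)
}
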