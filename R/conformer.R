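#' Construct a single conformer
#'
#' A conformer is one geometry of a molecule together with its energy and
#' provenance: which catalyst it belongs to, which conformational-search
#' method produced it, and whether the search was run with a constrained
#' scaffold dihedral.
#'
#' All atom indices in this package are 1-based, matching R convention.
#' Energies are kcal/mol on the originating method's own scale; only
#' energies relative to an ensemble's minimum are ever compared across
#' methods.
#'
#' @param conformer_id Character scalar, unique within its ensemble.
#' @param catalyst_id Character scalar naming the molecule.
#' @param method_label Character scalar naming the search program.
#' @param coords Numeric n_atoms x 3 matrix of Cartesian coordinates (Angstrom).
#' @param energy Numeric scalar, kcal/mol.
#' @param atom_symbols Character vector of element symbols, length n_atoms.
#' @param constrained Logical scalar; `TRUE` for constrained-scaffold searches.
#' @return An object of class `conformer`.
#' @export
conformer <- function(conformer_id, catalyst_id, method_label, coords, energy,
                      atom_symbols = rep("C", nrow(coords)),
                      constrained = FALSE) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3L) stop("coords must be an n x 3 matrix")
  if (nrow(coords) < 4L) stop("a conformer needs at least 4 atoms")
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  if (length(energy) != 1L || !is.finite(energy)) stop("energy must be a finite scalar")
  if (length(atom_symbols) != nrow(coords)) stop("atom_symbols length != atom count")
  structure(
    list(conformer_id = as.character(conformer_id),
         catalyst_id = as.character(catalyst_id),
         method_label = as.character(method_label),
         constrained = isTRUE(constrained),
         atom_symbols = as.character(atom_symbols),
         coords = coords,
         energy = as.numeric(energy)),
    class = "conformer")
}

#' @export
print.conformer <- function(x, ...) {
  cat(sprintf("<conformer %s> %s / %s%s, %d atoms, E = %.4f kcal/mol\n",
              x$conformer_id, x$catalyst_id, x$method_label,
              if (x$constrained) " (constrained)" else "",
              nrow(x$coords), x$energy))
  invisible(x)
}

#' Construct a conformer ensemble
#'
#' An ensemble is the ordered set of conformers one search program produced
#' for one catalyst. All members must share the same atom count and element
#' ordering, and the same (catalyst, method, constrained) provenance.
#'
#' @param conformers List of [conformer()] objects, at least one.
#' @param provenance Optional free-text note (e.g. source file).
#' @return An object of class `ensemble`.
#' @export
ensemble <- function(conformers, provenance = "") {
  if (!length(conformers)) stop("ensemble must contain at least one conformer")
  if (!all(vapply(conformers, inherits, logical(1), "conformer")))
    stop("all elements must be conformer objects")
  ref <- conformers[[1L]]
  for (i in seq_along(conformers)) {
    ci <- conformers[[i]]
    if (nrow(ci$coords) != nrow(ref$coords) ||
        !identical(ci$atom_symbols, ref$atom_symbols))
      stop(sprintf("conformer %d breaks the shared atom ordering", i))
    if (ci$catalyst_id != ref$catalyst_id || ci$method_label != ref$method_label ||
        ci$constrained != ref$constrained)
      stop(sprintf("conformer %d has inconsistent provenance", i))
  }
  structure(
    list(catalyst_id = ref$catalyst_id,
         method_label = ref$method_label,
         constrained = ref$constrained,
         conformers = conformers,
         provenance = as.character(provenance)),
    class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  e <- ensemble_energies(x)
  cat(sprintf("<ensemble> %s / %s%s: %d conformers, dE span %.3f kcal/mol\n",
              x$catalyst_id, x$method_label,
              if (x$constrained) " (constrained)" else "",
              length(x$conformers), diff(range(e))))
  invisible(x)
}

#' @export
length.ensemble <- function(x) length(x$conformers)

#' Energies of an ensemble, in file order
#' @param e An [ensemble()].
#' @return Numeric vector, kcal/mol.
#' @export
ensemble_energies <- function(e) {
  vapply(e$conformers, function(c) c$energy, numeric(1))
}

#' Number of atoms per conformer in an ensemble
#' @param e An [ensemble()].
#' @return Integer scalar.
#' @export
ensemble_n_atoms <- function(e) nrow(e$conformers[[1L]]$coords)

#' Keep a subset of an ensemble's conformers
#' @param e An [ensemble()].
#' @param idx Integer indices (1-based), kept in the order given.
#' @return An [ensemble()].
#' @export
ensemble_subset <- function(e, idx) {
  if (!length(idx)) stop("cannot build an empty ensemble")
  out <- e
  out$conformers <- e$conformers[idx]
  out
}

#' Assemble a study registry
#'
#' The registry holds every (catalyst, method, constrained) ensemble of a
#' benchmarking study, the label of the reference method all others are
#' graded against, and the per-catalyst representative selection (atoms and
#' dihedral quadruples restricted to the catalyst scaffold and substituent
#' anchors) used for every subset-RMSD and torsion computation.
#'
#' @param ensembles List of [ensemble()] objects.
#' @param reference_method Character scalar; must be present for every
#'   catalyst that is graded.
#' @param selections Named list, `catalyst_id -> representative_selection`.
#' @return An object of class `study_registry`.
#' @export
study_registry <- function(ensembles, reference_method, selections) {
  keys <- vapply(ensembles, registry_key, character(1))
  if (anyDuplicated(keys)) stop("duplicate (catalyst, method, constrained) ensembles")
  names(ensembles) <- keys
  cats <- unique(vapply(ensembles, function(e) e$catalyst_id, character(1)))
  missing_sel <- setdiff(cats, names(selections))
  if (length(missing_sel))
    stop("no representative selection for catalyst(s): ",
         paste(missing_sel, collapse = ", "))
  structure(
    list(ensembles = ensembles,
         reference_method = as.character(reference_method),
         selections = selections),
    class = "study_registry")
}

registry_key <- function(e, catalyst_id = NULL, method_label = NULL,
                         constrained = NULL) {
  if (inherits(e, "ensemble"))
    sprintf("%s|%s|%d", e$catalyst_id, e$method_label, as.integer(e$constrained))
  else
    sprintf("%s|%s|%d", catalyst_id, method_label, as.integer(constrained))
}

#' Catalysts present in a registry
#' @param reg A [study_registry()].
#' @return Character vector of catalyst ids.
#' @export
registry_catalysts <- function(reg) {
  unique(vapply(reg$ensembles, function(e) e$catalyst_id, character(1)))
}

#' Non-reference method labels present in a registry
#' @param reg A [study_registry()].
#' @return Character vector of method labels, reference excluded.
#' @export
registry_methods <- function(reg) {
  m <- unique(vapply(reg$ensembles, function(e) e$method_label, character(1)))
  setdiff(m, reg$reference_method)
}

#' Fetch one ensemble from a registry
#' @param reg A [study_registry()].
#' @param catalyst_id,method_label,constrained Ensemble key.
#' @return An [ensemble()]; error if absent.
#' @export
registry_ensemble <- function(reg, catalyst_id, method_label, constrained = FALSE) {
  key <- registry_key(NULL, catalyst_id, method_label, constrained)
  e <- reg$ensembles[[key]]
  if (is.null(e)) stop("no ensemble for key ", key)
  e
}
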