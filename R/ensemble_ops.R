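#' Relative energies of an ensemble
#'
#' @param e An [ensemble()].
#' @return Numeric vector of energies shifted so the minimum is exactly 0
#'   (kcal/mol), in conformer order.
#' @export
relative_energies <- function(e) {
  en <- ensemble_energies(e)
  en - min(en)
}

#' Keep conformers within an energy window of the global minimum
#'
#' Standard post-optimization filtration: conformers with relative energy
#' above `cutoff` are discarded. The boundary is inclusive, so the typical
#' settings (10 kcal/mol unconstrained, 20 kcal/mol constrained, 6 kcal/mol
#' for metadynamics ensembles) keep a conformer sitting exactly at the
#' cutoff. The global minimum always survives.
#'
#' @param e An [ensemble()].
#' @param cutoff Window width in kcal/mol, > 0.
#' @return Filtered [ensemble()], original order preserved.
#' @export
energy_window_filter <- function(e, cutoff) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  ensemble_subset(e, which(relative_energies(e) <= cutoff))
}

#' Remove near-duplicate conformers by RMSD (optionally gated on energy)
#'
#' A single greedy pass in ascending energy order: each conformer is dropped
#' if it lies within `rmsd_threshold` (subset RMSD on the representative
#' atoms) of an already-kept conformer — and, when `energy_threshold` is
#' given, only if it is also within `energy_threshold` of that conformer
#' (the pair-merging rule used by metadynamics ensembles, where BOTH gates
#' must fire). The lowest-energy conformer is always kept, and every dropped
#' conformer is within `rmsd_threshold` of some kept one.
#'
#' @param e An [ensemble()].
#' @param rmsd_threshold Angstrom, > 0; boundary inclusive.
#' @param sel A [representative_selection()].
#' @param energy_threshold kcal/mol, > 0, or `NULL` (RMSD gate alone).
#' @return Deduplicated [ensemble()], survivors in original order.
#' @export
rmsd_dedupe <- function(e, rmsd_threshold, sel, energy_threshold = NULL) {
  if (rmsd_threshold <= 0) stop("rmsd_threshold must be > 0")
  if (!is.null(energy_threshold) && energy_threshold <= 0)
    stop("energy_threshold must be > 0")
  en <- ensemble_energies(e)
  ord <- order(en, seq_along(en))
  kept <- integer(0)
  for (i in ord) {
    drop <- FALSE
    for (k in kept) {
      close_geom <- subset_rmsd(e$conformers[[i]], e$conformers[[k]], sel) <= rmsd_threshold
      close_en <- is.null(energy_threshold) || abs(en[i] - en[k]) <= energy_threshold
      if (close_geom && close_en) { drop <- TRUE; break }
    }
    if (!drop) kept <- c(kept, i)
  }
  ensemble_subset(e, sort(kept))
}

#' Select a maximally diverse subset of conformers
#'
#' Greedy max-min selection on representative-atom RMSD: start from the
#' lowest-energy conformer, then repeatedly add the conformer whose minimum
#' distance to the already-selected set is largest (ties broken by lower
#' index). This is the programmatic stand-in for picking a set of
#' structures "as different as they can be from one another" ahead of
#' expensive re-optimization.
#'
#' @param e An [ensemble()].
#' @param k Number of conformers to keep, `1 <= k <= length(e)`.
#' @param sel A [representative_selection()].
#' @return [ensemble()] of exactly `k` conformers, in original order.
#' @export
diversity_subset <- function(e, k, sel) {
  ensemble_subset(e, diversity_indices(e, k, sel))
}

#' Indices of the maximally diverse subset
#'
#' The index form of [diversity_subset()], for callers that need to carry
#' companion per-conformer data (e.g. ground-truth labels) along.
#'
#' @inheritParams diversity_subset
#' @return Sorted integer vector of `k` conformer indices.
#' @export
diversity_indices <- function(e, k, sel) {
  n <- length(e)
  if (k < 1L || k > n) stop("k out of range 1..", n)
  en <- ensemble_energies(e)
  seed <- which.min(en)   # which.min takes the first = lowest index on ties
  selected <- seed
  if (k > 1L) {
    d <- pairwise_distance_matrix(e$conformers, sel, metric = "subset_rmsd")
    mind <- d[, seed]
    mind[seed] <- -Inf
    while (length(selected) < k) {
      nxt <- which.max(mind)
      selected <- c(selected, nxt)
      mind <- pmin(mind, d[, nxt])
      mind[nxt] <- -Inf
    }
  }
  sort(unname(selected))
}

#' Suggested conformer count from rotatable-bond count
#'
#' The common sizing heuristic for knowledge-based embedding: request the
#' cube of the number of rotatable bonds.
#'
#' @param n_rotatable Integer >= 1.
#' @return `n_rotatable^3`, as integer-valued numeric.
#' @export
suggested_conformer_count <- function(n_rotatable) {
  if (n_rotatable < 1L) stop("n_rotatable must be >= 1")
  if (n_rotatable %% 1 != 0) stop("n_rotatable must be an integer")
  n_rotatable^3
}
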