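#' Define the representative atoms and dihedrals of a catalyst
#'
#' Pairwise RMSD and torsion featurization never use the full molecule:
#' they are restricted to a hand-picked set of scaffold/substituent atoms
#' that keeps conformers distinguishable while avoiding local-symmetry
#' artifacts (e.g. ring flips of equivalent aryl atoms). Indices are
#' 1-based.
#'
#' @param atom_indices Integer vector of atom indices used for subset RMSD.
#' @param dihedral_quads List of length-4 integer vectors (bonded atom
#'   quadruples) used for torsion featurization.
#' @return An object of class `representative_selection`.
#' @export
representative_selection <- function(atom_indices, dihedral_quads = list()) {
  atom_indices <- as.integer(atom_indices)
  if (!length(atom_indices)) stop("atom_indices must be non-empty")
  if (any(atom_indices < 1L)) stop("atom indices are 1-based; got index < 1")
  dihedral_quads <- lapply(dihedral_quads, as.integer)
  for (q in dihedral_quads) {
    if (length(q) != 4L || anyDuplicated(q))
      stop("each dihedral quad must be 4 distinct atom indices")
  }
  structure(list(atom_indices = atom_indices, dihedral_quads = dihedral_quads),
            class = "representative_selection")
}

check_selection_bounds <- function(sel, n_atoms) {
  idx <- c(sel$atom_indices, unlist(sel$dihedral_quads))
  if (length(idx) && max(idx) > n_atoms)
    stop(sprintf("selection index %d exceeds atom count %d", max(idx), n_atoms))
  invisible(TRUE)
}

#' Minimum RMSD between two point sets under optimal superposition
#'
#' Both point sets are centered and the optimal proper rotation is found by
#' the Kabsch algorithm (SVD of the cross-covariance, with the determinant
#' sign correction that excludes reflections). Superposition is essential
#' here: conformers coming from different programs sit in arbitrary
#' coordinate frames, and without alignment the deviation would measure
#' frame placement rather than conformation.
#'
#' @param P,Q Numeric m x 3 matrices, m >= 2, with rows paired.
#' @return RMSD in the coordinate units (Angstrom), >= 0.
#' @export
kabsch_rmsd <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (!all(dim(P) == dim(Q))) stop("point sets differ in size")
  if (nrow(P) < 2L) stop("need at least 2 points")
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  s <- svd(crossprod(Pc, Qc))
  d <- sign(det(tcrossprod(s$v, s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  diffs <- Qc - Pc %*% t(R)
  sqrt(sum(diffs^2) / nrow(P))
}

#' Subset RMSD between two conformers on the representative atoms
#'
#' @param a,b [conformer()] objects sharing atom ordering.
#' @param sel A [representative_selection()].
#' @return Kabsch RMSD (Angstrom) over `sel$atom_indices` only.
#' @export
subset_rmsd <- function(a, b, sel) {
  if (nrow(a$coords) != nrow(b$coords)) stop("conformers differ in atom count")
  check_selection_bounds(sel, nrow(a$coords))
  kabsch_rmsd(a$coords[sel$atom_indices, , drop = FALSE],
              b$coords[sel$atom_indices, , drop = FALSE])
}

#' Signed dihedral angle of four points
#'
#' Standard IUPAC sign convention: looking down the p2->p3 bond, a clockwise
#' rotation of the far bond is positive. Result in (-180, 180].
#'
#' @param p1,p2,p3,p4 Numeric length-3 coordinate vectors (Angstrom).
#' @return Angle in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  if (sum(n1^2) < 1e-20 || sum(n2^2) < 1e-20)
    stop("degenerate geometry: collinear atoms in dihedral")
  b2u <- b2 / sqrt(sum(b2^2))
  ang <- atan2(sum(cross3(n1, n2) * b2u), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Torsion feature vector of a conformer
#'
#' One signed dihedral per quadruple of the representative selection, in
#' the selection's order.
#'
#' @param c A [conformer()].
#' @param sel A [representative_selection()] with non-empty `dihedral_quads`.
#' @return Numeric vector of degrees in (-180, 180].
#' @export
torsion_features <- function(c, sel) {
  if (!length(sel$dihedral_quads)) stop("selection has no dihedral quads")
  check_selection_bounds(sel, nrow(c$coords))
  vapply(sel$dihedral_quads, function(q) {
    dihedral_angle(c$coords[q[1], ], c$coords[q[2], ],
                   c$coords[q[3], ], c$coords[q[4], ])
  }, numeric(1))
}

wrap_angle <- function(theta) {
  # wrap to (-180, 180]
  w <- theta - 360 * floor((theta + 180) / 360)
  w[w <= -180] <- w[w <= -180] + 360
  w
}

circular_diff <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

#' Pairwise distance matrix over a conformer list
#'
#' Three metrics are available:
#' \describe{
#'   \item{`subset_rmsd`}{Kabsch RMSD on the representative atoms, for every
#'     pair (Angstrom).}
#'   \item{`torsion`}{Root-mean-square circular difference over the
#'     representative dihedrals, each difference wrapped to \[0, 180\]
#'     (degrees).}
#'   \item{`blended`}{`w *` torsion `+ (1 - w) *` subset RMSD after
#'     normalizing each matrix by its own maximum, so both data kinds
#'     contribute on a common \[0, 1\] scale.}
#' }
#'
#' @param conformers List of [conformer()] objects with shared atom ordering.
#' @param sel A [representative_selection()].
#' @param metric One of `"subset_rmsd"`, `"torsion"`, `"blended"`.
#' @param w Blend weight on the torsion part, default 0.5.
#' @return Symmetric matrix with zero diagonal; dimnames are conformer ids.
#' @export
pairwise_distance_matrix <- function(conformers, sel,
                                     metric = c("blended", "subset_rmsd", "torsion"),
                                     w = 0.5) {
  metric <- match.arg(metric)
  n <- length(conformers)
  if (n < 2L) stop("need at least 2 conformers")
  ids <- vapply(conformers, function(c) c$conformer_id, character(1))
  rmsd_mat <- function() {
    # center each selected-coordinate block once; per pair only the 3x3
    # cross-covariance SVD remains (rmsd^2 = (ssA + ssB - 2*sum sigma)/m)
    check_selection_bounds(sel, nrow(conformers[[1L]]$coords))
    cc <- lapply(conformers, function(c) {
      x <- c$coords[sel$atom_indices, , drop = FALSE]
      sweep(x, 2, colMeans(x))
    })
    ss <- vapply(cc, function(x) sum(x^2), numeric(1))
    npt <- length(sel$atom_indices)
    m <- matrix(0, n, n)
    for (i in seq_len(n - 1L)) {
      A <- cc[[i]]
      for (j in (i + 1L):n) {
        s <- svd(crossprod(A, cc[[j]]))
        sig <- s$d[1] + s$d[2] + s$d[3] * sign(det(s$u) * det(s$v))
        m[i, j] <- m[j, i] <- sqrt(max(0, ss[i] + ss[j] - 2 * sig) / npt)
      }
    }
    m
  }
  torsion_mat <- function() {
    q <- length(sel$dihedral_quads)
    feats <- t(matrix(vapply(conformers, torsion_features, numeric(q), sel = sel),
                      nrow = q))
    acc <- matrix(0, n, n)
    for (k in seq_len(ncol(feats))) {
      d <- abs(outer(feats[, k], feats[, k], "-")) %% 360
      d <- pmin(d, 360 - d)
      acc <- acc + d^2
    }
    sqrt(acc / ncol(feats))
  }
  m <- switch(metric,
    subset_rmsd = rmsd_mat(),
    torsion = torsion_mat(),
    blended = {
      tm <- torsion_mat(); rm <- rmsd_mat()
      tmax <- max(tm); rmax <- max(rm)
      if (tmax > 0) tm <- tm / tmax
      if (rmax > 0) rm <- rm / rmax
      w * tm + (1 - w) * rm
    })
  diag(m) <- 0
  dimnames(m) <- list(ids, ids)
  m
}

#' Export a distance matrix as TSV
#'
#' @param m Symmetric distance matrix with conformer-id dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(m, path) {
  df <- data.frame(conformer_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
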