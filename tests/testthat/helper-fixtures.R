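# Fixture builders shared across test files. Everything is generated in
# code; no data files.

# a bent 4-atom "molecule" with distinct interatomic distances
base_coords <- function() {
  matrix(c(0, 0, 0,
           1.5, 0, 0,
           2.0, 1.4, 0,
           1.6, 2.1, 1.2), ncol = 3, byrow = TRUE)
}

make_conformer <- function(id = "c1", coords = base_coords(), energy = 0,
                           catalyst = "catA", method = "m1",
                           symbols = c("C", "C", "C", "O"), constrained = FALSE) {
  conformer(id, catalyst, method, coords, energy,
            atom_symbols = symbols, constrained = constrained)
}

# ensemble of n copies of the base geometry with given energies; each copy
# optionally perturbed by adding `shift` to atom 4's z coordinate
make_toy_ensemble <- function(energies, catalyst = "catA", method = "m1",
                              shifts = rep(0, length(energies))) {
  confs <- lapply(seq_along(energies), function(i) {
    xyz <- base_coords()
    xyz[4, 3] <- xyz[4, 3] + shifts[i]
    make_conformer(sprintf("%s_%s_%02d", catalyst, method, i), xyz,
                   energies[i], catalyst, method)
  })
  ensemble(confs)
}

# chain conformer from torsions, with energy
chain_conformer <- function(torsions, energy = 0, id = "t1",
                            catalyst = "catA", method = "m1",
                            n_atoms = length(torsions) + 3L) {
  xyz <- build_chain_geometry(torsions, n_atoms)
  conformer(id, catalyst, method, xyz, energy)
}

chain_selection <- function(n_torsions, n_atoms = n_torsions + 3L) {
  representative_selection(seq_len(n_atoms),
                           lapply(seq_len(n_torsions), function(i) i:(i + 3L)))
}

# proper random rotation matrix (QR of a Gaussian matrix, det fixed to +1)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

rotation_from_euler <- function(a, b, g) {
  Rz <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0, 0, 0, 1), 3, byrow = TRUE)
  Ry <- function(t) matrix(c(cos(t), 0, sin(t), 0, 1, 0, -sin(t), 0, cos(t)), 3, byrow = TRUE)
  Rz(a) %*% Ry(b) %*% Rz(g)
}

# Independent oracle: minimum RMSD over rotations by coarse Euler grid plus
# Nelder-Mead refinement from the best grid points. Never calls kabsch_rmsd.
grid_search_rmsd <- function(P, Q, grid_step = 30, n_refine = 5) {
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  rmsd_at <- function(ang) {
    R <- rotation_from_euler(ang[1], ang[2], ang[3])
    sqrt(mean(rowSums((Qc - Pc %*% t(R))^2)))
  }
  step <- grid_step * pi / 180
  alphas <- seq(0, 2 * pi - step / 2, by = step)
  betas <- seq(0, pi, by = step)
  grid <- expand.grid(a = alphas, b = betas, g = alphas)
  vals <- apply(grid, 1, rmsd_at)
  best <- order(vals)[seq_len(n_refine)]
  refined <- vapply(best, function(i) {
    stats::optim(as.numeric(grid[i, ]), rmsd_at, method = "Nelder-Mead",
                 control = list(reltol = 1e-14, maxit = 2000))$value
  }, numeric(1))
  min(refined)
}

# Exhaustive max-min diversity oracle over all k-subsets that contain the
# lowest-energy conformer; returns the best achievable min pairwise distance
exhaustive_diversity <- function(e, k, sel) {
  d <- pairwise_distance_matrix(e$conformers, sel, metric = "subset_rmsd")
  n <- length(e)
  seed <- which.min(ensemble_energies(e))
  rest <- setdiff(seq_len(n), seed)
  combos <- utils::combn(rest, k - 1L)
  best_val <- -Inf; best_set <- NULL
  for (j in seq_len(ncol(combos))) {
    idx <- c(seed, combos[, j])
    val <- min(d[idx, idx][upper.tri(diag(k))])
    if (val > best_val) { best_val <- val; best_set <- sort(idx) }
  }
  list(value = best_val, set = best_set)
}

min_pairwise <- function(e, idx, sel) {
  d <- pairwise_distance_matrix(e$conformers, sel, metric = "subset_rmsd")
  min(d[idx, idx][upper.tri(diag(length(idx)))])
}
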