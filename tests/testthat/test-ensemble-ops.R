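test_that("relative energies are zero-anchored and idempotent", {
  e <- make_toy_ensemble(c(-5, -3, -1))
  expect_equal(relative_energies(e), c(0, 2, 4))
  e1 <- make_toy_ensemble(0)
  expect_equal(relative_energies(e1), 0)
  e2 <- make_toy_ensemble(c(0, 1.2))
  expect_equal(relative_energies(e2), c(0, 1.2))
})

test_that("energy window keeps the inclusive boundary and is idempotent and monotone", {
  e <- make_toy_ensemble(c(0, 2.9, 6.0, 7.4))
  kept <- energy_window_filter(e, 6.0)
  expect_equal(length(kept), 3L)
  expect_equal(relative_energies(kept), c(0, 2.9, 6.0))
  expect_equal(energy_window_filter(kept, 6.0), kept)   # idempotence
  expect_equal(energy_window_filter(e, 10), e)          # all below cutoff
  ids20 <- vapply(energy_window_filter(e, 20)$conformers,
                  function(c) c$conformer_id, character(1))
  ids10 <- vapply(energy_window_filter(e, 10)$conformers,
                  function(c) c$conformer_id, character(1))
  expect_true(all(ids10 %in% ids20))                    # superset relation
  expect_error(energy_window_filter(e, 0), "> 0")
})

test_that("rmsd_dedupe keeps one representative per duplicate group", {
  sel <- representative_selection(1:4)
  e <- make_toy_ensemble(c(3, 1, 2))   # identical geometries, lowest is #2
  out <- rmsd_dedupe(e, 0.5, sel)
  expect_equal(length(out), 1L)
  expect_equal(ensemble_energies(out), 1)
  expect_equal(rmsd_dedupe(out, 0.5, sel), out)   # idempotence
  # well-separated geometries are untouched
  e2 <- make_toy_ensemble(c(0, 1, 2), shifts = c(0, 4, 8))
  expect_equal(length(rmsd_dedupe(e2, 0.5, sel)), 3L)
})

test_that("pair-energy gate must fire together with the RMSD gate", {
  sel <- representative_selection(1:4)
  # identical geometry (RMSD 0 <= 0.125) but dE 0.2 > 0.05: both kept
  e <- make_toy_ensemble(c(0, 0.2))
  expect_equal(length(rmsd_dedupe(e, 0.125, sel, energy_threshold = 0.05)), 2L)
  # dE 0.03 <= 0.05: merged
  e2 <- make_toy_ensemble(c(0, 0.03))
  expect_equal(length(rmsd_dedupe(e2, 0.125, sel, energy_threshold = 0.05)), 1L)
  # without the energy gate the same pair merges regardless of dE
  expect_equal(length(rmsd_dedupe(e, 0.125, sel)), 1L)
})

test_that("every dropped conformer lies within the threshold of a kept one", {
  set.seed(71)
  sel <- chain_selection(3)
  confs <- lapply(1:12, function(i)
    chain_conformer(runif(3, -180, 180), id = paste0("d", i), energy = runif(1, 0, 5)))
  e <- ensemble(confs)
  thr <- 1.0
  out <- rmsd_dedupe(e, thr, sel)
  kept_ids <- vapply(out$conformers, function(c) c$conformer_id, character(1))
  expect_true(paste0("d", which.min(ensemble_energies(e))) %in% kept_ids)
  for (cf in e$conformers) {
    if (cf$conformer_id %in% kept_ids) next
    dmin <- min(vapply(out$conformers, subset_rmsd, numeric(1), a = cf, sel = sel))
    expect_lte(dmin, thr)
  }
  # kept set is pairwise separated when no energy gate is used
  if (length(out) > 1L) {
    d <- pairwise_distance_matrix(out$conformers, sel, metric = "subset_rmsd")
    expect_true(all(d[upper.tri(d)] >= thr))
  }
  expect_equal(rmsd_dedupe(out, thr, sel), out)
})

test_that("diversity_subset seeds at the lowest-energy conformer and covers k", {
  sel <- chain_selection(1)
  torsions <- c(0, 10, 120, -120)
  e <- ensemble(lapply(seq_along(torsions), function(i)
    chain_conformer(torsions[i], id = paste0("t", i), energy = i)))
  expect_equal(diversity_indices(e, 1, sel), 1L)        # k = 1: energy minimum
  expect_equal(diversity_indices(e, 4, sel), 1:4)       # k = n: identity
  # the 0/10/120/240 pattern: greedy must match the exhaustive optimum
  greedy <- diversity_indices(e, 3, sel)
  oracle <- exhaustive_diversity(e, 3, sel)
  expect_equal(greedy, oracle$set)
  expect_equal(min_pairwise(e, greedy, sel), oracle$value, tolerance = 1e-9)
  expect_error(diversity_subset(e, 0, sel), "out of range")
  expect_error(diversity_subset(e, 5, sel), "out of range")
})

test_that("greedy diversity matches the exhaustive oracle where greedy is optimal", {
  # k = 2 from the lowest-energy seed is the exhaustive optimum for any
  # geometry; monotone single-torsion ladders seeded at one end are optimal
  # for k = 3 (exchange argument on the extreme point)
  sel <- chain_selection(1)
  set.seed(29)
  for (rep in 1:8) {
    tor <- sort(runif(sample(5:8, 1), 0, 170))   # seed at torsion minimum end
    e <- ensemble(lapply(seq_along(tor), function(i)
      chain_conformer(tor[i], id = paste0("l", i), energy = i)))
    for (k in 2:3) {
      greedy <- diversity_indices(e, k, sel)
      oracle <- exhaustive_diversity(e, k, sel)
      expect_equal(min_pairwise(e, greedy, sel), oracle$value, tolerance = 1e-9,
                   label = sprintf("rep %d, k = %d objective", rep, k))
    }
  }
  # arbitrary geometry, k = 2: always exhaustively optimal
  set.seed(37)
  sel3 <- chain_selection(3)
  for (rep in 1:5) {
    e <- ensemble(lapply(1:7, function(i)
      chain_conformer(runif(3, -180, 180), id = paste0("g", i), energy = runif(1))))
    expect_equal(min_pairwise(e, diversity_indices(e, 2, sel3), sel3),
                 exhaustive_diversity(e, 2, sel3)$value, tolerance = 1e-9)
  }
})

test_that("diversity min-distance never increases with k (greedy dispersion property)", {
  set.seed(83)
  sel <- chain_selection(3)
  e <- ensemble(lapply(1:8, function(i)
    chain_conformer(runif(3, -180, 180), id = paste0("r", i), energy = runif(1))))
  vals <- vapply(2:6, function(k) min_pairwise(e, diversity_indices(e, k, sel), sel),
                 numeric(1))
  expect_true(all(diff(vals) <= 1e-9))
  # Gonzalez guarantee: greedy achieves at least half the unrestricted optimum
  for (k in 3:4) {
    d <- pairwise_distance_matrix(e$conformers, sel, metric = "subset_rmsd")
    combos <- utils::combn(8, k)
    best <- max(apply(combos, 2, function(idx) min(d[idx, idx][upper.tri(diag(k))])))
    expect_gte(min_pairwise(e, diversity_indices(e, k, sel), sel), best / 2 - 1e-9)
  }
})

test_that("suggested conformer count is the cube of the rotatable-bond count", {
  expect_equal(suggested_conformer_count(3), 27)
  expect_equal(suggested_conformer_count(1), 1)
  expect_equal(suggested_conformer_count(5), 125)
  expect_error(suggested_conformer_count(0), ">= 1")
})
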