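test_that("chain geometry reproduces requested torsions to below 1e-6 degrees", {
  x <- build_chain_geometry(c(180, 180))
  meas <- vapply(1:2, function(i)
    dihedral_angle(x[i, ], x[i + 1, ], x[i + 2, ], x[i + 3, ]), numeric(1))
  expect_equal(meas, c(180, 180), tolerance = 1e-9)
  x60 <- build_chain_geometry(60)
  expect_equal(dihedral_angle(x60[1, ], x60[2, ], x60[3, ], x60[4, ]), 60,
               tolerance = 1e-9)
  set.seed(99)
  worst <- 0
  for (rep in 1:100) {
    tor <- runif(sample(1:6, 1), -180, 180)
    x <- build_chain_geometry(tor)
    meas <- vapply(seq_along(tor), function(i)
      dihedral_angle(x[i, ], x[i + 1, ], x[i + 2, ], x[i + 3, ]), numeric(1))
    d <- abs(meas - tor); d <- pmin(d, 360 - d)
    worst <- max(worst, max(d))
  }
  expect_lt(worst, 1e-6)
  expect_error(build_chain_geometry(c(60, 60), n_chain_atoms = 4), ">=")
})

test_that("landscape and sampler specs enforce their invariants", {
  b2 <- list(list(center = c(0, 0), energy = 0), list(center = c(120, 120), energy = 1))
  l <- landscape_spec("c1", b2, torsion_jitter_sigma = 5)
  expect_equal(l$n_torsions, 2L)
  expect_equal(l$dihedral_quads[[2]], 2:5)
  # basins closer than 5 sigma are rejected
  near <- list(list(center = c(0, 0), energy = 0), list(center = c(10, 10), energy = 1))
  expect_error(landscape_spec("c1", near, torsion_jitter_sigma = 5), "5 x")
  expect_error(landscape_spec("c1", b2[1]), "at least 2")
  dup <- list(list(center = c(0, 0), energy = 0), list(center = c(120, 120), energy = 0))
  expect_error(landscape_spec("c1", dup), "unique")
  expect_error(sampler_spec("m", integer(0)), "non-empty")
})

test_that("sampling is deterministic per seed and honors coverage", {
  b3 <- list(list(center = c(-150, -150), energy = 0),
             list(center = c(0, 0), energy = 1),
             list(center = c(150, 150), energy = 2))
  l <- landscape_spec("c1", b3)
  sp <- sampler_spec("m", basin_coverage = c(1, 2), samples_per_basin = 5, seed = 77)
  out1 <- sample_method(l, sp)
  out2 <- sample_method(l, sp)
  expect_identical(out1$basin_labels, out2$basin_labels)
  expect_equal(out1$ensemble$conformers[[3]]$coords,
               out2$ensemble$conformers[[3]]$coords)
  expect_identical(ensemble_energies(out1$ensemble), ensemble_energies(out2$ensemble))
  expect_setequal(unique(out1$basin_labels), c(1L, 2L))
  expect_length(out1$ensemble$conformers, 10L)
  # zero jitter and zero error: basin mates identical, energies exact
  l0 <- landscape_spec("c1", b3, torsion_jitter_sigma = 0)
  sp0 <- sampler_spec("m", 1:3, samples_per_basin = 3,
                      geometric_jitter_sigma = 0, energy_error_sigma = 0)
  out0 <- sample_method(l0, sp0)
  expect_equal(out0$ensemble$conformers[[1]]$coords,
               out0$ensemble$conformers[[2]]$coords)
  expect_equal(ensemble_energies(out0$ensemble), rep(c(0, 1, 2), each = 3))
})

test_that("a frozen dihedral is constant across all sampled basins", {
  b2 <- list(list(center = c(0, 0, 0), energy = 0),
             list(center = c(120, 120, 120), energy = 1))
  l <- landscape_spec("c1", b2, frozen = list(index = 2L, value = 180))
  out <- sample_method(l, sampler_spec("m", 1:2, samples_per_basin = 4, seed = 3,
                                       geometric_jitter_sigma = 0))
  sel <- chain_selection(3)
  for (cf in out$ensemble$conformers) {
    expect_true(cf$constrained)
    expect_equal(torsion_features(cf, sel)[2], 180, tolerance = 1e-6)
  }
})

test_that("make_study assembles the registry, truth tables and guards the reference", {
  study <- default_study(seed = 2, n_catalysts = 3, samples_per_basin = 4)
  reg <- study$registry
  # 3 catalysts x (4 methods + 1 reference) ensembles
  expect_length(reg$ensembles, 15L)
  expect_length(registry_methods(reg), 4L)
  expect_equal(study$truth$catalysts$n_basins, rep(6L, 3))
  expect_equal(study$truth$catalysts$global_min_basin, rep(1L, 3))
  expect_equal(study$truth$coverage$systematic, 1:5)
  # truth labels partition every ensemble
  key <- registry_key(NULL, "cat_02", "genetic", FALSE)
  expect_length(study$truth$basin_labels[[key]], 4L * 3L)
  # a reference that misses the global basin, or carries bias, is rejected
  b2 <- list(list(center = c(0, 0), energy = 0), list(center = c(120, 120), energy = 1))
  l <- landscape_spec("c1", b2)
  expect_error(
    make_study(list(l), list(sampler_spec("reference", 2)), "reference"),
    "global-minimum")
  expect_error(
    make_study(list(l), list(sampler_spec("reference", 1:2, energy_bias = 1))),
    "bias")
  expect_error(make_study(list(l), list(sampler_spec("m", 1:2)), "reference"),
               "missing")
})

test_that("a perfect sampler reproduces the reference minima end to end", {
  landscapes <- lapply(1:3, function(ci) {
    basins <- lapply(1:3, function(b)
      list(center = rep(-120 + 120 * (b - 1), 4), energy = b - 1))
    landscape_spec(sprintf("c%d", ci), basins, torsion_jitter_sigma = 0)
  })
  samplers <- list(
    sampler_spec("reference", 1:3, 4, geometric_jitter_sigma = 0, energy_error_sigma = 0),
    sampler_spec("perfect", 1:3, 4, geometric_jitter_sigma = 0, energy_error_sigma = 0))
  study <- make_study(landscapes, samplers, seed = 5)
  reg <- study$registry
  n_hit <- 0L
  for (cat in registry_catalysts(reg)) {
    sel <- reg$selections[[cat]]
    if (most_stable_agrees(registry_ensemble(reg, cat, "perfect"),
                           registry_ensemble(reg, cat, "reference"), sel))
      n_hit <- n_hit + 1L
    pairs <- accuracy_pairs(study, cat, "perfect")
    expect_equal(energy_rmsd(relative_energies(pairs$method_ens),
                             relative_energies(pairs$ref_ens)), 0)
    rmsds <- vapply(seq_along(pairs$method_ens$conformers), function(i)
      subset_rmsd(pairs$method_ens$conformers[[i]], pairs$ref_ens$conformers[[i]], sel),
      numeric(1))
    expect_lt(max(rmsds), 1e-9)
  }
  expect_equal(grade_prediction_capacity(n_hit, 3), 10)
})

test_that("accuracy_pairs aligns the diversity subset with its basin truth", {
  study <- default_study(seed = 8, n_catalysts = 1, samples_per_basin = 5)
  pairs <- accuracy_pairs(study, "cat_01", "knowledge", k = 6)
  expect_length(pairs$method_ens$conformers, 6L)
  expect_length(pairs$ref_ens$conformers, 6L)
  sel <- study$registry$selections[["cat_01"]]
  # each method conformer sits close to its paired basin reference (5 degree
  # jitter, 0.02 A noise), far below the inter-basin scale
  rmsds <- vapply(seq_len(6), function(i)
    subset_rmsd(pairs$method_ens$conformers[[i]], pairs$ref_ens$conformers[[i]], sel),
    numeric(1))
  expect_lt(max(rmsds), 1.0)
  expect_error(accuracy_pairs(study, "nope", "knowledge"), "unknown catalyst")
})
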