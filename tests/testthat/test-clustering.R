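make_sized_registry <- function(sizes, catalyst = "cat_OH_ph") {
  ensembles <- lapply(names(sizes), function(m)
    make_toy_ensemble(seq_len(sizes[[m]]) * 0.1, catalyst = catalyst, method = m))
  sel <- representative_selection(1:4)
  study_registry(c(ensembles, list(make_toy_ensemble(c(0, 1), catalyst = catalyst,
                                                     method = "ref"))),
                 "ref", stats::setNames(list(sel), catalyst))
}

test_that("pooling concatenates methods and conserves provenance", {
  sizes <- list(balloon = 47L, rdkit = 20L, wsterimol = 25L, crest = 164L)
  reg <- make_sized_registry(sizes)
  pooled <- pool_conformers(reg, "cat_OH_ph")
  expect_length(pooled$conformers, 256L)
  tab <- table(pooled$provenance$method_label)
  expect_equal(as.integer(tab[names(sizes)]), unlist(sizes, use.names = FALSE))
  # provenance partitions exactly by method, preserving in-method order
  for (m in names(sizes)) {
    idx <- pooled$provenance$index_in_method[pooled$provenance$method_label == m]
    expect_equal(idx, seq_len(sizes[[m]]))
  }
  reg1 <- make_sized_registry(list(balloon = 5L))
  expect_error(pool_conformers(reg1, "cat_OH_ph"), "at least 2 methods")
  expect_error(pool_conformers(reg, "nope"), "no ensembles")
})

test_that("embedding is deterministic and two basins stay separated", {
  study <- default_study(seed = 9, n_catalysts = 1, samples_per_basin = 18)
  reg <- study$registry
  e <- registry_ensemble(reg, "cat_01", "metaMD")
  labels <- study$truth$basin_labels[[registry_key(e)]]
  keep <- labels %in% c(1, 4)
  confs <- e$conformers[keep]
  sel <- reg$selections[["cat_01"]]
  d <- pairwise_distance_matrix(confs, sel, metric = "blended")
  p <- embedding_params(n_neighbors = 10)
  xy1 <- embed_2d(d, p)
  xy2 <- embed_2d(d, p)
  expect_identical(xy1, xy2)
  expect_equal(ncol(xy1), 2L)
  lab <- labels[keep]
  emb_d <- as.matrix(stats::dist(xy1))
  same <- outer(lab, lab, "==") & upper.tri(emb_d)
  diff_b <- outer(lab, lab, "!=") & upper.tri(emb_d)
  expect_gt(min(emb_d[diff_b]), stats::median(emb_d[same]))
  expect_error(embed_2d(d[1:5, 1:5], embedding_params(n_neighbors = 10)),
               "n_neighbors")
})

test_that("density clustering finds blobs, handles degeneracy, flags sparse noise", {
  set.seed(42)
  blobs <- rbind(cbind(rnorm(50, 0, 0.01), rnorm(50, 0, 0.01)),
                 cbind(rnorm(50, 10, 0.01), rnorm(50, 10, 0.01)))
  r <- density_cluster(blobs, cluster_params())
  expect_equal(r$n_clusters, 2L)
  expect_equal(sum(r$labels == -1L), 0L)
  expect_equal(as.integer(table(r$labels)), c(50L, 50L))
  # all points identical: a single cluster
  r2 <- density_cluster(matrix(1, 30, 2), cluster_params())
  expect_equal(r2$n_clusters, 1L)
  expect_true(all(r2$labels == 0L))
  # sparse uniform noise with a large min_cluster_size: everything is an outlier
  set.seed(7)
  u <- cbind(runif(60) * 100, runif(60) * 100)
  r3 <- density_cluster(u, cluster_params(min_samples = 5, min_cluster_size = 50))
  expect_equal(r3$n_clusters, 0L)
  expect_true(all(r3$labels == -1L))
  # fewer points than min_cluster_size: warning + all outliers
  expect_warning(r4 <- density_cluster(matrix(rnorm(10), 5, 2),
                                       cluster_params(min_cluster_size = 8)),
                 "outlier")
  expect_true(all(r4$labels == -1L))
  # labels are contiguous 0..k-1
  expect_setequal(unique(r$labels), 0:1)
})

test_that("composition counts reconcile with cluster sizes and ensemble sizes", {
  prov <- data.frame(method_label = c("A", "B", "A", "B"))
  comp <- composition(c(0L, 0L, 1L, -1L), prov)
  expect_equal(comp$counts["cluster_0", ], c(A = 1L, B = 1L))
  expect_equal(comp$counts["cluster_1", ], c(A = 1L, B = 0L))
  expect_equal(comp$outliers, c(A = 0L, B = 1L))
  # conservation on a random labeling
  set.seed(13)
  lab <- sample(c(-1L, 0L, 1L, 2L), 60, replace = TRUE)
  prov2 <- data.frame(method_label = sample(c("A", "B", "C"), 60, replace = TRUE))
  comp2 <- composition(lab, prov2)
  expect_equal(unname(rowSums(comp2$counts)),
               as.integer(table(factor(lab[lab >= 0], levels = 0:2))))
  expect_equal(colSums(comp2$counts) + comp2$outliers[colnames(comp2$counts)],
               table(prov2$method_label)[colnames(comp2$counts)] |> as.integer() |>
                 stats::setNames(colnames(comp2$counts)))
  expect_error(composition(c(0L, 1L), prov), "lengths differ")
})

test_that("participation counts clusters reached, excluding outliers", {
  # 17 clusters: crest in all, balloon in 16 of them
  lab <- rep(0:16, each = 2)
  prov <- data.frame(method_label = rep(c("crest", "balloon"), 17))
  prov$method_label[34] <- "crest"   # balloon misses the last cluster
  comp <- composition(lab, prov)
  expect_equal(participation_fraction(comp, "crest"), 1.0)
  expect_equal(participation_fraction(comp, "balloon"), 16 / 17, tolerance = 1e-12)
  # absent method
  prov2 <- data.frame(method_label = rep("crest", 34))
  comp2 <- composition(lab, prov2)
  expect_error(participation_fraction(comp2, "ghost"), "unknown method")
  comp3 <- composition(rep(-1L, 4), data.frame(method_label = rep("A", 4)))
  expect_error(participation_fraction(comp3, "A"), "no clusters")
})

test_that("pipeline recovers the true basin partition of a pooled study", {
  skip_if_not_installed("mclust")
  study <- default_study(seed = 4, n_catalysts = 1, samples_per_basin = 20)
  reg <- study$registry
  res <- cluster_catalyst(reg, "cat_01")
  # ground-truth basin per pooled conformer, in pooling order
  truth <- unlist(lapply(registry_methods(reg), function(m) {
    key <- registry_key(NULL, "cat_01", m, FALSE)
    study$truth$basin_labels[[key]]
  }))
  expect_equal(res$composition$n_clusters, 6L)
  assigned <- res$labels$labels >= 0L
  ari <- mclust::adjustedRandIndex(res$labels$labels[assigned], truth[assigned])
  expect_gte(ari, 0.9)
  # conservation: cluster sizes + outliers = pooled size
  expect_equal(sum(res$composition$counts) + sum(res$composition$outliers),
               length(truth))
})
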