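#' Embedding parameters
#'
#' @param n_neighbors Neighborhood size of the k-NN graph, >= 2. Default 15.
#' @param min_distance Controls the guaranteed gap between disconnected
#'   neighborhood-graph components in the 2-D layout, in [0, 1). Default 0.1.
#' @param random_state Recorded for provenance; the embedding algorithm is
#'   fully deterministic, so the value never changes the output. Default 42.
#' @return An object of class `embedding_params`.
#' @export
embedding_params <- function(n_neighbors = 15L, min_distance = 0.1,
                             random_state = 42L) {
  if (n_neighbors < 2L) stop("n_neighbors must be >= 2")
  if (min_distance < 0 || min_distance >= 1) stop("min_distance must be in [0, 1)")
  structure(list(n_neighbors = as.integer(n_neighbors),
                 min_distance = min_distance,
                 n_components = 2L,
                 random_state = as.integer(random_state)),
            class = "embedding_params")
}

#' Density-clustering parameters
#'
#' @param min_samples Neighbor rank used for core distances, >= 2. Default 5.
#' @param min_cluster_size Smallest group accepted as a cluster, >= 2.
#'   Default 8.
#' @return An object of class `cluster_params`.
#' @export
cluster_params <- function(min_samples = 5L, min_cluster_size = 8L) {
  if (min_samples < 2L || min_cluster_size < 2L)
    stop("min_samples and min_cluster_size must both be >= 2")
  structure(list(min_samples = as.integer(min_samples),
                 min_cluster_size = as.integer(min_cluster_size)),
            class = "cluster_params")
}

#' Pool all methods' conformers of one catalyst
#'
#' Concatenates the ensembles of every non-reference method (>= 2 required)
#' for one catalyst, preserving per-conformer provenance.
#'
#' @param registry A [study_registry()].
#' @param catalyst_id Catalyst to pool.
#' @param constrained Logical ensemble flag.
#' @param methods Optional explicit method labels; default: all
#'   non-reference methods in the registry.
#' @return List with `conformers` (flat list) and `provenance` (data.frame
#'   with `method_label`, `index_in_method`, `conformer_id`).
#' @export
pool_conformers <- function(registry, catalyst_id, constrained = FALSE,
                            methods = NULL) {
  if (is.null(methods)) methods <- registry_methods(registry)
  keys <- vapply(methods, function(m)
    registry_key(NULL, catalyst_id, m, constrained), character(1))
  present <- keys %in% names(registry$ensembles)
  if (!any(present)) stop("no ensembles for catalyst ", catalyst_id)
  methods <- methods[present]
  if (length(methods) < 2L)
    stop("pooling requires at least 2 methods for catalyst ", catalyst_id)
  confs <- list(); prov <- list()
  for (m in methods) {
    e <- registry_ensemble(registry, catalyst_id, m, constrained)
    confs <- c(confs, e$conformers)
    prov[[m]] <- data.frame(
      method_label = m,
      index_in_method = seq_along(e$conformers),
      conformer_id = vapply(e$conformers, function(c) c$conformer_id, character(1)),
      stringsAsFactors = FALSE)
  }
  list(conformers = confs, provenance = do.call(rbind, c(prov, make.row.names = FALSE)))
}

#' Embed a distance matrix into 2-D
#'
#' Deterministic neighborhood-graph embedding of a precomputed distance
#' matrix: a symmetric k-nearest-neighbor graph is built (`n_neighbors`
#' neighbors per point), geodesic distances are computed within each
#' connected component, and each component is laid out by classical
#' multidimensional scaling of its geodesics. Disconnected components —
#' the signature of well-separated conformational basins — are placed on a
#' grid whose spacing exceeds every component's diameter, so between-basin
#' separation always survives the projection (the qualitative behavior
#' manifold learners show on disconnected data).
#'
#' @param dist Symmetric distance matrix (e.g. from
#'   [pairwise_distance_matrix()]).
#' @param p An [embedding_params()]. Requires `nrow(dist) >= n_neighbors`.
#' @return n x 2 coordinate matrix (rownames preserved).
#' @export
embed_2d <- function(dist, p = embedding_params()) {
  n <- nrow(dist)
  if (n < p$n_neighbors) stop("need at least n_neighbors points")
  k <- min(p$n_neighbors, n - 1L)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    nb <- order(dist[i, -i])  # indices into the vector without i
    nb <- seq_len(n)[-i][nb[seq_len(k)]]
    adj[i, nb] <- TRUE
  }
  adj <- adj | t(adj)
  g <- igraph::graph_from_adjacency_matrix(adj * dist, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  # zero-distance edges are legal; re-add them (graph_from_adjacency drops 0s)
  zero_edges <- which(adj & dist == 0 & upper.tri(dist), arr.ind = TRUE)
  if (nrow(zero_edges))
    g <- igraph::add_edges(g, t(zero_edges), weight = 0)
  comp <- igraph::components(g)$membership
  coords <- matrix(0, n, 2)
  comp_ids <- order(-tabulate(comp))  # largest component first: deterministic layout
  centered <- vector("list", length(comp_ids))
  radii <- numeric(length(comp_ids))
  for (ci in seq_along(comp_ids)) {
    idx <- which(comp == comp_ids[ci])
    if (length(idx) == 1L) {
      centered[[ci]] <- matrix(0, 1, 2)
    } else {
      geo <- igraph::distances(g, v = idx, to = idx)
      xy <- suppressWarnings(stats::cmdscale(geo, k = 2))
      if (ncol(xy) < 2L) xy <- cbind(xy, matrix(0, nrow(xy), 2L - ncol(xy)))
      centered[[ci]] <- sweep(xy, 2, colMeans(xy))
    }
    radii[ci] <- max(sqrt(rowSums(centered[[ci]]^2)), 0)
  }
  spacing <- (2 * max(radii) + 1) * (1 + p$min_distance)
  side <- ceiling(sqrt(length(comp_ids)))
  for (ci in seq_along(comp_ids)) {
    gx <- (ci - 1L) %% side
    gy <- (ci - 1L) %/% side
    idx <- which(comp == comp_ids[ci])
    coords[idx, ] <- sweep(centered[[ci]], 2, c(gx * spacing, gy * spacing), "+")
  }
  rownames(coords) <- rownames(dist)
  colnames(coords) <- c("x", "y")
  coords
}

#' Density-based clustering with outlier labeling
#'
#' Hierarchical density-based clustering of 2-D embedded points, following
#' the HDBSCAN construction: core distances at neighbor rank `min_samples`,
#' mutual-reachability distances, a minimum spanning tree, the single-linkage
#' hierarchy, condensation with `min_cluster_size`, and excess-of-mass
#' cluster selection. Points that never join a selected cluster are labeled
#' `-1` (outliers). The root is never selected, so data with no density
#' structure at the requested cluster size come back as all-noise; the fully
#' degenerate input (all points coincident) is shortcut to a single cluster.
#'
#' @param coords n x 2 coordinate matrix (or any point matrix).
#' @param p A [cluster_params()].
#' @return List of class `cluster_labels`: `labels` (integer, 0-based
#'   cluster ids, -1 = outlier) and `n_clusters`.
#' @export
density_cluster <- function(coords, p = cluster_params()) {
  n <- nrow(coords)
  if (n < p$min_cluster_size) {
    warning("fewer points than min_cluster_size: everything is an outlier")
    return(structure(list(labels = rep(-1L, n), n_clusters = 0L),
                     class = "cluster_labels"))
  }
  d <- as.matrix(stats::dist(coords))
  if (max(d) < 1e-12) {  # all points coincident
    return(structure(list(labels = rep(0L, n), n_clusters = 1L),
                     class = "cluster_labels"))
  }
  labels <- hdbscan_labels(d, p$min_samples, p$min_cluster_size)
  structure(list(labels = labels, n_clusters = max(labels + 1L, 0L)),
            class = "cluster_labels")
}

# HDBSCAN on a precomputed distance matrix. Returns 0-based labels, -1 noise.
hdbscan_labels <- function(d, min_samples, min_cluster_size) {
  n <- nrow(d)
  k <- min(min_samples, n - 1L)
  # each row includes self (0): the (k+1)-th smallest entry is the k-th
  # nearest other point
  core <- apply(d, 1, function(row) sort(row)[k + 1L])
  mreach <- pmax(outer(core, rep(1, n)), outer(rep(1, n), core))
  mreach <- pmax(mreach, d)
  diag(mreach) <- 0
  mst <- prim_mst(mreach)
  sl <- single_linkage_tree(mst, n)
  condensed <- condense_tree(sl, n, min_cluster_size)
  select_eom(condensed, n)
}

# Prim's algorithm on a dense matrix: returns data.frame(from, to, weight)
prim_mst <- function(w) {
  n <- nrow(w)
  in_tree <- rep(FALSE, n)
  in_tree[1] <- TRUE
  best_w <- w[1, ]; best_from <- rep(1L, n)
  edges <- matrix(0, n - 1L, 3)
  for (e in seq_len(n - 1L)) {
    cand <- which(!in_tree)
    j <- cand[which.min(best_w[cand])]
    edges[e, ] <- c(best_from[j], j, best_w[j])
    in_tree[j] <- TRUE
    upd <- !in_tree & w[j, ] < best_w
    best_w[upd] <- w[j, upd]
    best_from[upd] <- j
  }
  edges
}

# Single-linkage dendrogram from MST edges (union-find).
# Returns list(merges = matrix(node_a, node_b, height, new_id, size)),
# with leaf nodes 1..n and internal nodes n+1..2n-1.
single_linkage_tree <- function(mst, n) {
  ord <- order(mst[, 3], mst[, 1], mst[, 2])
  mst <- mst[ord, , drop = FALSE]
  parent <- seq_len(2L * n - 1L)
  node_of <- seq_len(n)        # current top node of each set root
  size_of <- c(rep(1L, n), rep(0L, n - 1L))
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  merges <- matrix(0, n - 1L, 5)
  colnames(merges) <- c("a", "b", "height", "id", "size")
  for (e in seq_len(n - 1L)) {
    ra <- find(mst[e, 1]); rb <- find(mst[e, 2])
    na_ <- node_of[ra]; nb_ <- node_of[rb]
    new_id <- n + e
    sz <- size_of[na_] + size_of[nb_]
    size_of[new_id] <- sz
    merges[e, ] <- c(na_, nb_, mst[e, 3], new_id, sz)
    parent[ra] <- rb
    node_of[rb] <- new_id
  }
  list(merges = merges, n = n, size_of = size_of)
}

# Condense the single-linkage tree: walk top-down; a split is true when both
# children reach min_cluster_size. Produces per condensed cluster: birth
# lambda, point fall-out lambdas, and child condensed clusters.
condense_tree <- function(sl, n, min_cluster_size) {
  merges <- sl$merges
  n_nodes <- 2L * n - 1L
  child_a <- child_b <- integer(n_nodes)
  height <- numeric(n_nodes)
  size_of <- sl$size_of
  size_of[seq_len(n)] <- 1L
  for (e in seq_len(nrow(merges))) {
    id <- merges[e, "id"]
    child_a[id] <- merges[e, "a"]; child_b[id] <- merges[e, "b"]
    height[id] <- merges[e, "height"]
  }
  lam <- function(h) 1 / max(h, 1e-12)
  # collect the leaf points under an SLT node
  leaves_under <- function(node) {
    out <- integer(0); stack <- node
    while (length(stack)) {
      v <- stack[[1]]; stack <- stack[-1]
      if (v <= n) out <- c(out, v) else stack <- c(stack, child_a[v], child_b[v])
    }
    out
  }
  clusters <- list()
  new_cluster <- function(birth_lambda, parent) {
    clusters[[length(clusters) + 1L]] <<- list(
      birth = birth_lambda, parent = parent,
      points = integer(0), point_lambda = numeric(0),
      split_lambda = NA_real_, children = integer(0))
    length(clusters)
  }
  root_cl <- new_cluster(0, 0L)
  # stack of (slt_node, condensed_cluster)
  stack <- list(c(n_nodes, root_cl))
  while (length(stack)) {
    top <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    node <- top[1]; cl <- top[2]
    if (node <= n) {
      clusters[[cl]]$points <- c(clusters[[cl]]$points, node)
      clusters[[cl]]$point_lambda <- c(clusters[[cl]]$point_lambda, Inf)
      next
    }
    a <- child_a[node]; b <- child_b[node]
    l <- lam(height[node])
    big_a <- size_of[a] >= min_cluster_size
    big_b <- size_of[b] >= min_cluster_size
    if (big_a && big_b) {
      ca <- new_cluster(l, cl); cb <- new_cluster(l, cl)
      clusters[[cl]]$children <- c(clusters[[cl]]$children, ca, cb)
      clusters[[cl]]$split_lambda <- l
      stack <- c(stack, list(c(a, ca), c(b, cb)))
    } else if (!big_a && !big_b) {
      pts <- c(leaves_under(a), leaves_under(b))
      clusters[[cl]]$points <- c(clusters[[cl]]$points, pts)
      clusters[[cl]]$point_lambda <- c(clusters[[cl]]$point_lambda, rep(l, length(pts)))
    } else {
      small <- if (big_a) b else a
      big <- if (big_a) a else b
      pts <- leaves_under(small)
      clusters[[cl]]$points <- c(clusters[[cl]]$points, pts)
      clusters[[cl]]$point_lambda <- c(clusters[[cl]]$point_lambda, rep(l, length(pts)))
      stack <- c(stack, list(c(big, cl)))
    }
  }
  clusters
}

# Excess-of-mass selection over the condensed tree; root (cluster 1) is
# never selectable. Returns 0-based labels with -1 noise.
select_eom <- function(clusters, n) {
  m <- length(clusters)
  if (m == 1L) return(rep(-1L, n))  # no true splits anywhere
  # stability: points contribute (min(lambda_p, split_lambda) - birth)
  stability <- numeric(m)
  for (i in seq_len(m)) {
    cl <- clusters[[i]]
    cap <- if (is.na(cl$split_lambda)) Inf else cl$split_lambda
    lp <- pmin(cl$point_lambda, cap)
    lp[!is.finite(lp)] <- cap
    if (any(!is.finite(lp))) {
      # leaf cluster whose points persist to zero distance: cap by the
      # largest finite point lambda (coincident-point guard)
      fin <- max(lp[is.finite(lp)], cl$birth)
      lp[!is.finite(lp)] <- max(fin, cl$birth)
    }
    stability[i] <- sum(lp - cl$birth)
    # descendants' spans below split are accounted in the children
    if (length(cl$children)) {
      # points that went to children contributed up to split via children's
      # birth; include their (split - birth) mass here
      kids_pts <- sum(vapply(cl$children, function(k) cluster_mass(clusters, k), numeric(1)))
      stability[i] <- stability[i] + kids_pts * (cl$split_lambda - cl$birth)
    }
  }
  selected <- rep(FALSE, m)
  subtree_stab <- numeric(m)
  # process bottom-up (children always have larger index than parent)
  for (i in rev(seq_len(m))) {
    cl <- clusters[[i]]
    if (!length(cl$children)) {
      selected[i] <- i != 1L
      subtree_stab[i] <- stability[i]
    } else {
      kid_sum <- sum(subtree_stab[cl$children])
      if (i != 1L && stability[i] >= kid_sum) {
        selected[i] <- TRUE
        subtree_stab[i] <- stability[i]
        deselect_below(selected, clusters, i) -> selected
      } else {
        subtree_stab[i] <- kid_sum
      }
    }
  }
  labels <- rep(-1L, n)
  sel_ids <- which(selected)
  for (s in sel_ids) {
    pts <- collect_points(clusters, s)
    labels[pts] <- s
  }
  # relabel contiguously by first point index
  firsts <- vapply(sel_ids, function(s) min(collect_points(clusters, s)), numeric(1))
  remap <- sel_ids[order(firsts)]
  out <- rep(-1L, n)
  for (j in seq_along(remap)) out[labels == remap[j]] <- j - 1L
  out
}

cluster_mass <- function(clusters, i) {
  total <- length(clusters[[i]]$points)
  for (k in clusters[[i]]$children) total <- total + cluster_mass(clusters, k)
  total
}

collect_points <- function(clusters, i) {
  pts <- clusters[[i]]$points
  for (k in clusters[[i]]$children) pts <- c(pts, collect_points(clusters, k))
  pts
}

deselect_below <- function(selected, clusters, i) {
  for (k in clusters[[i]]$children) {
    selected[k] <- FALSE
    selected <- deselect_below(selected, clusters, k)
  }
  selected
}

#' Cluster composition by method
#'
#' Counts, for every cluster, how many conformers each method contributed,
#' plus each method's outlier count. Row sums equal cluster sizes and each
#' method's column total plus its outliers equals its pooled ensemble size.
#'
#' @param labels A `cluster_labels` object (or integer vector with -1 noise).
#' @param provenance Data.frame with a `method_label` column, one row per
#'   pooled conformer, aligned with `labels`.
#' @return List of class `cluster_composition`: `counts` (cluster x method
#'   matrix), `outliers` (named vector per method), `n_clusters`.
#' @export
composition <- function(labels, provenance) {
  lab <- if (inherits(labels, "cluster_labels")) labels$labels else as.integer(labels)
  if (length(lab) != nrow(provenance)) stop("labels and provenance lengths differ")
  methods <- unique(provenance$method_label)
  n_clusters <- if (any(lab >= 0L)) max(lab) + 1L else 0L
  counts <- matrix(0L, n_clusters, length(methods),
                   dimnames = list(if (n_clusters) paste0("cluster_", seq_len(n_clusters) - 1L),
                                   methods))
  for (ci in seq_len(n_clusters)) {
    for (m in methods) {
      counts[ci, m] <- sum(lab == ci - 1L & provenance$method_label == m)
    }
  }
  outliers <- vapply(methods, function(m)
    sum(lab == -1L & provenance$method_label == m), integer(1))
  structure(list(counts = counts, outliers = outliers, n_clusters = n_clusters),
            class = "cluster_composition")
}

#' Fraction of clusters a method participates in
#'
#' The exploration statistic: the share of all clusters (outliers excluded
#' from both numerator and denominator) in which the method placed at least
#' one conformer.
#'
#' @param comp A [composition()] result.
#' @param method_label Method to score.
#' @return Fraction in [0, 1].
#' @export
participation_fraction <- function(comp, method_label) {
  if (comp$n_clusters == 0L) stop("no clusters: participation undefined")
  if (!method_label %in% colnames(comp$counts)) stop("unknown method ", method_label)
  sum(comp$counts[, method_label] > 0L) / comp$n_clusters
}

#' Cluster one catalyst's pooled ensembles end to end
#'
#' Pools the non-reference methods, computes the blended distance matrix on
#' the catalyst's representative selection, embeds to 2-D, density-clusters,
#' and tabulates composition and per-method participation.
#'
#' @param registry A [study_registry()].
#' @param catalyst_id Catalyst to process.
#' @param constrained Logical ensemble flag.
#' @param embedding An [embedding_params()].
#' @param clustering A [cluster_params()].
#' @param blend_w Torsion weight of the blended metric.
#' @return List with `coords`, `labels`, `composition`, `participation`
#'   (named vector), `provenance`.
#' @export
cluster_catalyst <- function(registry, catalyst_id, constrained = FALSE,
                             embedding = embedding_params(),
                             clustering = cluster_params(),
                             blend_w = 0.5) {
  pooled <- pool_conformers(registry, catalyst_id, constrained)
  sel <- registry$selections[[catalyst_id]]
  d <- pairwise_distance_matrix(pooled$conformers, sel, metric = "blended", w = blend_w)
  coords <- embed_2d(d, embedding)
  labels <- density_cluster(coords, clustering)
  comp <- composition(labels, pooled$provenance)
  part <- vapply(colnames(comp$counts), function(m)
    participation_fraction(comp, m), numeric(1))
  list(coords = coords, labels = labels, composition = comp,
       participation = part, provenance = pooled$provenance)
}
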