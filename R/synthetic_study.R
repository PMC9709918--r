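#' Specify a synthetic torsion landscape ("catalyst")
#'
#' A landscape is a chain molecule whose conformational space is a small set
#' of well-separated torsion basins, each with a declared well energy. It
#' plays the role of a catalyst in a synthetic benchmarking study: samplers
#' draw conformers from (subsets of) its basins, and every downstream
#' statistic can be checked against the known ground truth.
#'
#' @param catalyst_id Character scalar.
#' @param basins List of `list(center = <torsion vector, degrees>,
#'   energy = <well energy, kcal/mol>)`; at least 2, with a unique global
#'   minimum and centers whose pairwise circular distance is at least
#'   5 x `torsion_jitter_sigma` so basins are separable.
#' @param n_chain_atoms Number of chain atoms; must be at least
#'   `length(center) + 3`.
#' @param torsion_jitter_sigma Within-basin torsion spread (degrees),
#'   applied as wrapped Gaussian jitter.
#' @param frozen Optional `list(index, value)` freezing one dihedral to a
#'   fixed value across all basins — the "constrained search" emulation.
#' @return An object of class `landscape_spec`.
#' @export
landscape_spec <- function(catalyst_id, basins, n_chain_atoms = NULL,
                           torsion_jitter_sigma = 5, frozen = NULL) {
  if (length(basins) < 2L) stop("need at least 2 basins")
  q <- length(basins[[1]]$center)
  if (is.null(n_chain_atoms)) n_chain_atoms <- q + 3L
  if (n_chain_atoms < q + 3L) stop("n_chain_atoms must be >= n_torsions + 3")
  energies <- vapply(basins, function(b) b$energy, numeric(1))
  if (anyDuplicated(energies[energies == min(energies)]) || sum(energies == min(energies)) > 1L)
    stop("global-minimum well energy must be unique")
  for (b in basins) {
    if (length(b$center) != q) stop("all basin centers must have the same length")
  }
  cen <- t(vapply(basins, function(b) wrap_angle(b$center), numeric(q)))
  for (i in seq_len(nrow(cen) - 1L)) {
    for (j in (i + 1L):nrow(cen)) {
      sep <- max(circular_diff(cen[i, ], cen[j, ]))
      if (sep < 5 * torsion_jitter_sigma)
        stop(sprintf("basins %d and %d are closer than 5 x torsion_jitter_sigma", i, j))
    }
  }
  structure(
    list(catalyst_id = as.character(catalyst_id),
         basins = basins,
         n_chain_atoms = as.integer(n_chain_atoms),
         n_torsions = q,
         torsion_jitter_sigma = torsion_jitter_sigma,
         frozen = frozen,
         dihedral_quads = lapply(seq_len(q), function(i) i:(i + 3L))),
    class = "landscape_spec")
}

#' Specify a synthetic sampler ("method")
#'
#' A sampler emulates one conformational-search program: which basins it
#' finds (`basin_coverage`), how precisely it optimizes geometries
#' (`geometric_jitter_sigma`), and how accurate its energies are
#' (`energy_error_sigma`, plus an optional per-basin systematic
#' `energy_bias`).
#'
#' @param method_label Character scalar.
#' @param basin_coverage Integer vector of basin indices the sampler reaches.
#' @param samples_per_basin Conformers drawn per covered basin.
#' @param geometric_jitter_sigma Cartesian noise sigma, Angstrom, >= 0.
#' @param energy_error_sigma Random energy error sigma, kcal/mol, >= 0.
#' @param energy_bias Scalar or per-basin vector of systematic energy offsets,
#'   kcal/mol. Default 0.
#' @param seed Integer RNG seed for this sampler's stream.
#' @return An object of class `sampler_spec`.
#' @export
sampler_spec <- function(method_label, basin_coverage, samples_per_basin = 12L,
                         geometric_jitter_sigma = 0.02, energy_error_sigma = 0.3,
                         energy_bias = 0, seed = 1L) {
  if (!length(basin_coverage)) stop("basin_coverage must be non-empty")
  if (geometric_jitter_sigma < 0 || energy_error_sigma < 0) stop("sigmas must be >= 0")
  structure(
    list(method_label = as.character(method_label),
         basin_coverage = as.integer(basin_coverage),
         samples_per_basin = as.integer(samples_per_basin),
         geometric_jitter_sigma = geometric_jitter_sigma,
         energy_error_sigma = energy_error_sigma,
         energy_bias = energy_bias,
         seed = as.integer(seed)),
    class = "sampler_spec")
}

#' Build chain Cartesian coordinates from torsion angles
#'
#' Internal-coordinate chain with fixed bond length 1.5 Angstrom and bond
#' angle 109.5 degrees, converted to Cartesian by sequential natural
#' extension of the reference frame. Measuring the dihedral on quad
#' `(i, i+1, i+2, i+3)` of the result returns `torsions[i]` to well below
#' 1e-6 degrees.
#'
#' @param torsions Numeric vector of dihedrals, degrees.
#' @param n_chain_atoms Total chain atoms, >= `length(torsions) + 3`.
#'   Additional atoms beyond the controlled quads are appended trans (180).
#' @param bond_length,bond_angle Chain internals (Angstrom, degrees).
#' @return `n_chain_atoms` x 3 coordinate matrix.
#' @export
build_chain_geometry <- function(torsions, n_chain_atoms = length(torsions) + 3L,
                                 bond_length = 1.5, bond_angle = 109.5) {
  q <- length(torsions)
  if (n_chain_atoms < q + 3L) stop("n_chain_atoms must be >= length(torsions) + 3")
  if (n_chain_atoms > q + 3L) torsions <- c(torsions, rep(180, n_chain_atoms - q - 3L))
  r <- bond_length
  theta <- bond_angle * pi / 180
  x <- matrix(0, n_chain_atoms, 3)
  x[2, ] <- c(r, 0, 0)
  x[3, ] <- x[2, ] + r * c(-cos(theta), sin(theta), 0)
  for (i in 4:n_chain_atoms) {
    phi <- torsions[i - 3L] * pi / 180
    A <- x[i - 3L, ]; B <- x[i - 2L, ]; C <- x[i - 1L, ]
    bc <- C - B; bc <- bc / sqrt(sum(bc^2))
    n <- cross3(B - A, bc); n <- n / sqrt(sum(n^2))
    m <- cross3(n, bc)
    d <- c(-r * cos(theta), r * sin(theta) * cos(phi), r * sin(theta) * sin(phi))
    x[i, ] <- C + d[1] * bc + d[2] * m + d[3] * n
  }
  x
}

#' Sample one synthetic method ensemble from a landscape
#'
#' For each covered basin, `samples_per_basin` conformers are drawn: the
#' basin-center torsions receive wrapped Gaussian jitter (respecting a
#' frozen dihedral, if any), coordinates are built and perturbed with
#' Gaussian Cartesian noise, and the energy is the well energy plus the
#' sampler's bias and a Gaussian error. Fully deterministic given the
#' sampler's seed.
#'
#' @param landscape A [landscape_spec()].
#' @param sampler A [sampler_spec()].
#' @return List with `ensemble` (an [ensemble()]) and `basin_labels`
#'   (integer ground-truth basin index per conformer).
#' @export
sample_method <- function(landscape, sampler) {
  if (any(sampler$basin_coverage > length(landscape$basins)))
    stop("basin_coverage exceeds basin count")
  bias <- sampler$energy_bias
  if (length(bias) == 1L) bias <- rep(bias, length(landscape$basins))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(sampler$seed)
  confs <- list()
  labels <- integer(0)
  constrained <- !is.null(landscape$frozen)
  for (b in sampler$basin_coverage) {
    basin <- landscape$basins[[b]]
    for (s in seq_len(sampler$samples_per_basin)) {
      tor <- wrap_angle(basin$center +
                          stats::rnorm(landscape$n_torsions, 0, landscape$torsion_jitter_sigma))
      if (constrained) tor[landscape$frozen$index] <- landscape$frozen$value
      xyz <- build_chain_geometry(tor, landscape$n_chain_atoms)
      if (sampler$geometric_jitter_sigma > 0)
        xyz <- xyz + stats::rnorm(length(xyz), 0, sampler$geometric_jitter_sigma)
      en <- basin$energy + bias[b] + stats::rnorm(1, 0, sampler$energy_error_sigma)
      id <- sprintf("%s_%s_b%02d_%03d", landscape$catalyst_id, sampler$method_label, b, s)
      confs[[length(confs) + 1L]] <- conformer(
        id, landscape$catalyst_id, sampler$method_label, xyz, en,
        constrained = constrained)
      labels <- c(labels, b)
    }
  }
  list(ensemble = ensemble(confs, provenance = "synthetic"), basin_labels = labels)
}

#' Idealized reference geometry of a basin
#'
#' The noise-free chain built from the basin-center torsions with the well
#' energy — the synthetic analogue of the reference-method re-optimized
#' structure a sampled conformer relaxes to.
#'
#' @param landscape A [landscape_spec()].
#' @param basin Basin index.
#' @param method_label Provenance label for the returned conformer.
#' @return A [conformer()].
#' @export
basin_reference_conformer <- function(landscape, basin, method_label = "reference") {
  b <- landscape$basins[[basin]]
  tor <- wrap_angle(b$center)
  if (!is.null(landscape$frozen)) tor[landscape$frozen$index] <- landscape$frozen$value
  conformer(sprintf("%s_ref_b%02d", landscape$catalyst_id, basin),
            landscape$catalyst_id, method_label,
            build_chain_geometry(tor, landscape$n_chain_atoms), b$energy,
            constrained = !is.null(landscape$frozen))
}

#' Assemble a synthetic benchmarking study
#'
#' Samples every (catalyst, sampler) ensemble with a derived per-pair seed,
#' builds the study registry (representative selection = all chain atoms
#' plus the consecutive backbone quads), and records the ground truth:
#' basin count, global-minimum basin, per-method true coverage, and the
#' per-conformer basin labels.
#'
#' The reference sampler must cover the global-minimum basin of every
#' catalyst and carry no systematic energy bias; otherwise grading against
#' it would be meaningless and an error is raised.
#'
#' @param landscapes List of [landscape_spec()], one per catalyst.
#' @param samplers List of [sampler_spec()] templates (their `seed` fields
#'   are overwritten by the derived per-pair stream seeds).
#' @param reference_method Label of the reference sampler among `samplers`.
#' @param seed Integer master seed.
#' @return A list of class `synthetic_study`: `registry`, `landscapes`
#'   (named by catalyst), `truth`.
#' @export
make_study <- function(landscapes, samplers, reference_method = "reference",
                       seed = 1L) {
  labels <- vapply(samplers, function(s) s$method_label, character(1))
  if (!reference_method %in% labels) stop("reference sampler '", reference_method, "' missing")
  ref <- samplers[[match(reference_method, labels)]]
  if (any(ref$energy_bias != 0)) stop("reference sampler must have zero energy bias")
  for (l in landscapes) {
    gm <- which.min(vapply(l$basins, function(b) b$energy, numeric(1)))
    if (!gm %in% ref$basin_coverage)
      stop("reference sampler does not cover the global-minimum basin of ", l$catalyst_id)
  }
  ensembles <- list()
  basin_labels <- list()
  selections <- list()
  truth_rows <- list()
  coverage <- list()
  for (ci in seq_along(landscapes)) {
    l <- landscapes[[ci]]
    selections[[l$catalyst_id]] <- representative_selection(
      seq_len(l$n_chain_atoms), l$dihedral_quads)
    wells <- vapply(l$basins, function(b) b$energy, numeric(1))
    truth_rows[[ci]] <- data.frame(
      catalyst_id = l$catalyst_id,
      n_basins = length(l$basins),
      global_min_basin = which.min(wells),
      stringsAsFactors = FALSE)
    for (si in seq_along(samplers)) {
      sp <- samplers[[si]]
      sp$seed <- (abs(seed) %% 1000000L) * 1000L + ci * 211L + si * 17L
      out <- sample_method(l, sp)
      key <- registry_key(out$ensemble)
      ensembles[[length(ensembles) + 1L]] <- out$ensemble
      basin_labels[[key]] <- out$basin_labels
      coverage[[sp$method_label]] <- sp$basin_coverage
    }
  }
  registry <- study_registry(ensembles, reference_method, selections)
  structure(
    list(registry = registry,
         landscapes = stats::setNames(landscapes,
                                      vapply(landscapes, function(l) l$catalyst_id, character(1))),
         truth = list(catalysts = do.call(rbind, truth_rows),
                      coverage = coverage,
                      basin_labels = basin_labels)),
    class = "synthetic_study")
}

#' The package's default synthetic study
#'
#' Three torsion-landscape catalysts with 6 basins each (basin centers 60
#' degrees apart in every backbone torsion, well energies 0..5 kcal/mol in
#' 1 kcal/mol steps, within-basin torsion jitter 5 degrees) sampled by four
#' archetypal methods covering 6/5/4/3 basins with Cartesian noise 0.02
#' Angstrom and energy error 0.3 kcal/mol, plus a noise-free reference
#' covering everything. 20 samples per covered basin keep the smallest
#' single-method basin larger than the default embedding neighborhood.
#'
#' @param seed Integer master seed.
#' @param n_catalysts Number of catalysts, default 3.
#' @param samples_per_basin Conformers per covered basin per method,
#'   default 20.
#' @return A `synthetic_study` (see [make_study()]).
#' @export
default_study <- function(seed = 1L, n_catalysts = 3L, samples_per_basin = 20L) {
  landscapes <- lapply(seq_len(n_catalysts), function(ci) {
    n_tor <- 6L
    basins <- lapply(1:6, function(b) {
      list(center = rep(-150 + 60 * (b - 1L), n_tor), energy = (b - 1L) * 1.0)
    })
    landscape_spec(sprintf("cat_%02d", ci), basins, torsion_jitter_sigma = 5)
  })
  samplers <- list(
    sampler_spec("reference", 1:6, samples_per_basin,
                 geometric_jitter_sigma = 0, energy_error_sigma = 0),
    sampler_spec("metaMD", 1:6, samples_per_basin),
    sampler_spec("systematic", 1:5, samples_per_basin),
    sampler_spec("knowledge", 1:4, samples_per_basin),
    sampler_spec("genetic", 1:3, samples_per_basin))
  make_study(landscapes, samplers, reference_method = "reference", seed = seed)
}

#' Paired accuracy set for one (catalyst, method)
#'
#' Pairs every conformer of the method's ensemble with the idealized
#' reference structure of its ground-truth basin (see
#' [basin_reference_conformer()]): the structural pairs feed the subset-RMSD
#' accuracy criterion and the energy pairs feed the energy-RMSD criterion.
#'
#' @param study A `synthetic_study`.
#' @param catalyst_id,method_label Ensemble key (unconstrained).
#' @param k Optional diversity-subset size: when given, only the `k`
#'   maximally diverse conformers (see [diversity_indices()]) are paired,
#'   mirroring the practice of re-optimizing a small diverse set at the
#'   reference level.
#' @return List with `method_ens`, `ref_ens` (index-paired ensembles of
#'   equal length).
#' @export
accuracy_pairs <- function(study, catalyst_id, method_label, k = NULL) {
  l <- study$landscapes[[catalyst_id]]
  if (is.null(l)) stop("unknown catalyst ", catalyst_id)
  ens <- registry_ensemble(study$registry, catalyst_id, method_label,
                           constrained = !is.null(l$frozen))
  labels <- study$truth$basin_labels[[registry_key(ens)]]
  if (!is.null(k)) {
    sel <- study$registry$selections[[catalyst_id]]
    idx <- diversity_indices(ens, min(k, length(ens)), sel)
    ens <- ensemble_subset(ens, idx)
    labels <- labels[idx]
  }
  refs <- lapply(labels, function(b) {
    rc <- basin_reference_conformer(l, b)
    rc$method_label <- study$registry$reference_method
    rc
  })
  # make reference ids unique per pair
  for (i in seq_along(refs)) refs[[i]]$conformer_id <-
      sprintf("%s_p%03d", refs[[i]]$conformer_id, i)
  list(method_ens = ens, ref_ens = ensemble(refs, provenance = "idealized reference"))
}
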