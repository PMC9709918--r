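#' Calibration constants of the 0-10 grading scheme
#'
#' The structural and energy accuracy criteria are linear maps anchored at
#' two printed calibration points: a deviation of 0 maps to the perfect
#' grade 10 and the largest deviation observed in the benchmark maps to 0
#' (4.70 Angstrom across all 12063 structural comparisons; 17.31 kcal/mol
#' across all 120 energy comparisons). Tunability is scored against the
#' seven program features a user may want to modify.
#'
#' @param grade_scale Top grade. Default 10.
#' @param rmsd_max Structural calibration maximum, Angstrom. Default 4.70.
#' @param energy_rmsd_max Energy calibration maximum, kcal/mol.
#'   Default 17.31.
#' @param feature_list The tunability features. Default: the seven-item
#'   canonical list.
#' @return An object of class `grading_constants`.
#' @export
grading_constants <- function(grade_scale = 10,
                              rmsd_max = 4.70,
                              energy_rmsd_max = 17.31,
                              feature_list = c("conformer optimization method",
                                               "conformer generation method",
                                               "cutoff modifications",
                                               "molecule charge",
                                               "molecular constraints",
                                               "solvent selection",
                                               "temperature selection")) {
  if (grade_scale <= 0 || rmsd_max <= 0 || energy_rmsd_max <= 0)
    stop("calibration constants must be positive")
  structure(list(grade_scale = grade_scale,
                 rmsd_max = rmsd_max,
                 energy_rmsd_max = energy_rmsd_max,
                 n_feature_total = length(feature_list),
                 feature_list = feature_list),
            class = "grading_constants")
}

#' Prediction-capacity grade
#'
#' `grade_scale * n_correct / N`, where `n_correct` is the number of
#' catalysts for which the method's most stable conformer agrees with the
#' reference method's, out of `N` catalysts studied.
#'
#' @param n_correct Integer count, `0 <= n_correct <= N`.
#' @param N Number of catalysts, >= 1.
#' @param constants A [grading_constants()].
#' @return Grade in [0, grade_scale].
#' @export
grade_prediction_capacity <- function(n_correct, N, constants = grading_constants()) {
  if (N < 1L) stop("N must be >= 1")
  if (n_correct < 0L || n_correct > N) stop("n_correct out of 0..N")
  constants$grade_scale * n_correct / N
}

#' Tunability grade
#'
#' `grade_scale * n_features / n_feature_total`: the share of the evaluated
#' feature set (optimization method, generation method, cutoffs, charge,
#' constraints, solvent, temperature) the program lets the user modify.
#' Only whole features count.
#'
#' @param n_features Integer count of tunable features.
#' @param constants A [grading_constants()].
#' @return Grade in [0, grade_scale].
#' @export
grade_tunability <- function(n_features, constants = grading_constants()) {
  if (length(n_features) != 1L || n_features %% 1 != 0)
    stop("n_features must be a single integer")
  if (n_features < 0L || n_features > constants$n_feature_total)
    stop("n_features out of 0..", constants$n_feature_total)
  constants$grade_scale * n_features / constants$n_feature_total
}

#' Conformational-space exploration grade
#'
#' The mean over catalysts of the method's cluster participation fraction
#' (clusters the method reached over clusters found by all programs),
#' scaled to the grade range.
#'
#' @param participation Numeric vector of per-catalyst fractions in [0, 1].
#' @param constants A [grading_constants()].
#' @return Grade in [0, grade_scale].
#' @export
grade_exploration <- function(participation, constants = grading_constants()) {
  if (!length(participation)) stop("participation is empty")
  if (any(participation < 0 | participation > 1)) stop("fractions must be in [0, 1]")
  constants$grade_scale * mean(participation)
}

#' Structural-accuracy grade
#'
#' Linear between the calibration anchors: RMSD 0 -> grade 10,
#' RMSD `rmsd_max` (4.70 Angstrom) -> grade 0, clipped below at 0 for
#' deviations beyond the calibration maximum.
#'
#' @param rmsd Representative-atom RMSD to the reference structure,
#'   Angstrom, >= 0.
#' @param constants A [grading_constants()].
#' @return Grade in [0, grade_scale].
#' @export
structure_rmsd_grade <- function(rmsd, constants = grading_constants()) {
  if (any(rmsd < 0)) stop("rmsd must be >= 0")
  pmax(constants$grade_scale * (1 - rmsd / constants$rmsd_max), 0)
}

#' Energy RMSD between paired relative-energy vectors
#'
#' Root-mean-square difference between a method's relative conformer
#' energies and the reference method's, paired by conformer identity.
#' Both vectors are shifted to their own minimum first: absolute scales of
#' force-field, semiempirical and DFT energies are incommensurable, and the
#' benchmark compares relative energies throughout.
#'
#' @param rel_method,rel_ref Equal-length numeric vectors, kcal/mol.
#' @return RMSD in kcal/mol.
#' @export
energy_rmsd <- function(rel_method, rel_ref) {
  if (length(rel_method) != length(rel_ref)) stop("paired vectors differ in length")
  if (!length(rel_method)) stop("empty energy vectors")
  a <- rel_method - min(rel_method)
  b <- rel_ref - min(rel_ref)
  sqrt(mean((a - b)^2))
}

#' Energy-accuracy grade
#'
#' Linear between the calibration anchors: energy RMSD 0 -> grade 10,
#' `energy_rmsd_max` (17.31 kcal/mol) -> grade 0, clipped below at 0.
#'
#' @param e Energy RMSD, kcal/mol, >= 0.
#' @param constants A [grading_constants()].
#' @return Grade in [0, grade_scale].
#' @export
energy_rmsd_grade <- function(e, constants = grading_constants()) {
  if (any(e < 0)) stop("energy RMSD must be >= 0")
  pmax(constants$grade_scale * (1 - e / constants$energy_rmsd_max), 0)
}

#' Does a method's most stable conformer agree with the reference's?
#'
#' Both ensembles' minimum-energy conformers are compared by
#' representative-atom RMSD; agreement means the deviation is at most
#' `match_threshold` (default 0.5 Angstrom, the common deduplication
#' cutoff).
#'
#' @param ens Method [ensemble()].
#' @param ref Reference [ensemble()], shared atom ordering.
#' @param sel A [representative_selection()].
#' @param match_threshold Angstrom.
#' @return Logical scalar.
#' @export
most_stable_agrees <- function(ens, ref, sel, match_threshold = 0.5) {
  a <- ens$conformers[[which.min(ensemble_energies(ens))]]
  b <- ref$conformers[[which.min(ensemble_energies(ref))]]
  subset_rmsd(a, b, sel) <= match_threshold
}

#' Compile the five-criterion grade report
#'
#' One row per method with the prediction-capacity, tunability,
#' exploration, structural-accuracy and energy-accuracy grades, plus the
#' raw counts and deviations they were computed from.
#'
#' @param prediction Named list/vector, method -> n_correct.
#' @param N Number of catalysts graded for prediction.
#' @param tunability Named list/vector, method -> n_features.
#' @param participation Named list, method -> numeric vector of
#'   per-catalyst participation fractions.
#' @param structure_rmsd Named list/vector, method -> mean representative-atom
#'   RMSD to the reference over the accuracy pairs (Angstrom).
#' @param energy_rmsd_values Named list/vector, method -> energy RMSD versus
#'   the reference (kcal/mol).
#' @param constants A [grading_constants()].
#' @return A `data.frame` of class `grade_report`, one row per method.
#' @export
compile_report <- function(prediction, N, tunability, participation,
                           structure_rmsd, energy_rmsd_values,
                           constants = grading_constants()) {
  methods <- names(prediction)
  if (is.null(methods)) stop("prediction must be named by method")
  for (nm in c("tunability", "participation", "structure_rmsd", "energy_rmsd_values")) {
    part <- get(nm)
    missing <- setdiff(methods, names(part))
    if (length(missing))
      stop(sprintf("component '%s' missing for method(s): %s",
                   nm, paste(missing, collapse = ", ")))
  }
  rows <- lapply(methods, function(m) {
    data.frame(
      method = m,
      n_correct = as.integer(prediction[[m]]),
      n_catalysts = as.integer(N),
      n_features = as.integer(tunability[[m]]),
      mean_participation = mean(participation[[m]]),
      structure_rmsd = as.numeric(structure_rmsd[[m]]),
      energy_rmsd = as.numeric(energy_rmsd_values[[m]]),
      grade_prediction = grade_prediction_capacity(prediction[[m]], N, constants),
      grade_tunability = grade_tunability(tunability[[m]], constants),
      grade_exploration = grade_exploration(participation[[m]], constants),
      grade_structure = structure_rmsd_grade(structure_rmsd[[m]], constants),
      grade_energy = energy_rmsd_grade(energy_rmsd_values[[m]], constants),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("grade_report", "data.frame")
  out
}
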