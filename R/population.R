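#' Thermodynamic parameters for Boltzmann weighting
#'
#' @param temperature Kelvin, > 0. Default 298 K, the temperature used
#'   throughout the benchmark.
#' @param gas_constant kcal/(mol K). Default 1.987204e-3, matching the
#'   kcal/mol energy scale used everywhere in this package.
#' @return An object of class `thermo_params`.
#' @export
thermo_params <- function(temperature = 298, gas_constant = 1.987204e-3) {
  if (temperature <= 0) stop("temperature must be > 0")
  structure(list(temperature = temperature, gas_constant = gas_constant),
            class = "thermo_params")
}

#' Boltzmann weights of a set of relative conformer energies
#'
#' `w_i = exp(-dE_i / RT) / sum_j exp(-dE_j / RT)`. Energies are shifted by
#' their minimum before exponentiation, so the computation is stable for
#' arbitrarily large energy spans and the weights are invariant under any
#' additive shift of the absolute energies.
#'
#' @param rel_e Numeric vector of relative energies, kcal/mol.
#' @param thermo A [thermo_params()].
#' @return Numeric simplex vector (sums to 1).
#' @export
boltzmann_weights <- function(rel_e, thermo = thermo_params()) {
  if (!length(rel_e) || !all(is.finite(rel_e))) stop("rel_e must be finite and non-empty")
  rt <- thermo$gas_constant * thermo$temperature
  x <- exp(-(rel_e - min(rel_e)) / rt)
  x / sum(x)
}

#' Fraction of conformers needed to cover a cumulative population
#'
#' Conformers are ranked by descending weight (ties broken by original
#' index) and the smallest head count m whose cumulative weight reaches `q`
#' is found. The returned fraction m/n is the quantity behind statements
#' like "less than 10% of the generated conformers represent more than 99%
#' of the Boltzmann population".
#'
#' @param weights Simplex vector of Boltzmann weights.
#' @param q Target cumulative population, in (0, 1). Default 0.99.
#' @return m/n, in (0, 1].
#' @export
coverage_fraction <- function(weights, q = 0.99) {
  check_simplex(weights)
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)")
  cum <- cumsum(sort_desc_stable(weights))
  m <- which(cum >= q - 1e-12)[1]
  if (is.na(m)) m <- length(weights)   # guard against rounding at q ~ 1
  m / length(weights)
}

#' Population histogram over 5% conformer-rank intervals
#'
#' Conformers are sorted by descending weight; bin k collects the total
#' weight of conformers whose rank percentile lies in ((k-1)*width, k*width].
#' With the default 5% width there are 20 bins and they sum to 1. This is
#' the bar-chart summary of how front-loaded an ensemble's population is.
#'
#' @param weights Simplex vector of Boltzmann weights.
#' @param bin_width Percentile width of a bin, percent. Default 5.
#' @return Named numeric vector of bin totals, names like `"(0,5]"`.
#' @export
population_bins <- function(weights, bin_width = 5) {
  check_simplex(weights)
  n <- length(weights)
  sorted <- sort_desc_stable(weights)
  pct <- 100 * seq_len(n) / n
  k <- ceiling(pct / bin_width - 1e-9)
  n_bins <- ceiling(100 / bin_width)
  out <- numeric(n_bins)
  agg <- tapply(sorted, k, sum)
  out[as.integer(names(agg))] <- agg
  names(out) <- sprintf("(%g,%g]", bin_width * (seq_len(n_bins) - 1L),
                        bin_width * seq_len(n_bins))
  out
}

#' Full Boltzmann population summary of an ensemble
#'
#' @param e An [ensemble()].
#' @param thermo A [thermo_params()].
#' @param q Cumulative-population target for the coverage fraction.
#' @return A list of class `boltzmann_summary`: `weights` (conformer order),
#'   `cumulative` (descending-rank partial sums), `coverage_fraction_99`,
#'   `bins_5pct`.
#' @export
boltzmann_summary <- function(e, thermo = thermo_params(), q = 0.99) {
  w <- boltzmann_weights(relative_energies(e), thermo)
  structure(
    list(weights = w,
         cumulative = cumsum(sort_desc_stable(w)),
         coverage_fraction_99 = coverage_fraction(w, q),
         bins_5pct = population_bins(w)),
    class = "boltzmann_summary")
}

#' @export
print.boltzmann_summary <- function(x, ...) {
  cat(sprintf("<boltzmann_summary> %d conformers; %.1f%% of them cover %.0f%% of the population\n",
              length(x$weights), 100 * x$coverage_fraction_99, 99))
  invisible(x)
}

sort_desc_stable <- function(w) {
  w[order(-w, seq_along(w))]
}

check_simplex <- function(w) {
  if (!length(w) || any(w < -1e-12) || abs(sum(w) - 1) > 1e-8)
    stop("weights must be a simplex vector (non-negative, summing to 1)")
  invisible(TRUE)
}
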