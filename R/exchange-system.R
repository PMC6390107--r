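#' @useDynLib ttrstab, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Species bookkeeping for the H/D exchange network.
# Tetramers are indexed by their number of deuterated subunits (0..4); the two
# structurally distinct 2H2D assemblies are pooled because native MS cannot
# distinguish them.
TETRAMER_SPECIES <- c("4H", "3H1D", "2H2D", "1H3D", "4D")
DIMER_SPECIES    <- c("HH", "HD", "DD")
MONOMER_SPECIES  <- c("H", "D")

#' Rate constants for the subunit-exchange reaction network
#'
#' Bundles the four mass-action rate constants of the tetramer <-> dimer <->
#' monomer network together with a kinetic isotope factor. Association steps
#' are bimolecular and their constants are expressed per molecule per day
#' (the simulation works in copy numbers, not molar concentrations);
#' dissociation steps are unimolecular, per day.
#'
#' The isotope factor multiplies the rate of every reaction once per
#' deuterated subunit among the reacting molecules, the simplest scaling
#' consistent with the observed sensitivity of TTR subunit exchange to
#' deuteration. `isotope_factor = 1` makes H and D kinetically
#' indistinguishable.
#'
#' @param k_tet_diss Tetramer -> dimer + dimer rate (per day).
#' @param k_tet_assoc Dimer + dimer -> tetramer rate (per molecule per day).
#' @param k_dim_diss Dimer -> monomer + monomer rate (per day).
#' @param k_dim_assoc Monomer + monomer -> dimer rate (per molecule per day).
#' @param isotope_factor Dimensionless multiplier applied once per deuterated
#'   subunit taking part in a reaction. Must be positive.
#' @return An object of class `rate_set`.
#' @examples
#' rate_set(0.2, 1e-2, 0.5, 1e-2)
#' @export
rate_set <- function(k_tet_diss, k_tet_assoc, k_dim_diss, k_dim_assoc,
                     isotope_factor = 1) {
  r <- c(k_tet_diss = k_tet_diss, k_tet_assoc = k_tet_assoc,
         k_dim_diss = k_dim_diss, k_dim_assoc = k_dim_assoc)
  if (any(!is.finite(r)) || any(r < 0))
    stop("all rate constants must be finite and >= 0")
  if (!is.finite(isotope_factor) || isotope_factor <= 0)
    stop("isotope_factor must be finite and > 0")
  structure(as.list(c(r, isotope_factor = isotope_factor)), class = "rate_set")
}

#' @export
print.rate_set <- function(x, ...) {
  cat("Subunit-exchange rate set (per day; association per molecule per day)\n")
  cat(sprintf("  tetramer:  diss %.4g, assoc %.4g\n", x$k_tet_diss, x$k_tet_assoc))
  cat(sprintf("  dimer:     diss %.4g, assoc %.4g\n", x$k_dim_diss, x$k_dim_assoc))
  cat(sprintf("  isotope factor: %.4g\n", x$isotope_factor))
  invisible(x)
}

#' Define a subunit-exchange system state
#'
#' The state of the H/D exchange network: copy numbers of the five tetramer
#' species (`4H`, `3H1D`, `2H2D`, `1H3D`, `4D`), the three dimers (`HH`,
#' `HD`, `DD`) and the two monomers (`H`, `D`), together with a
#' [rate_set()]. Total monomer equivalents (4 per tetramer, 2 per dimer,
#' 1 per monomer) are conserved by every reaction of the network.
#'
#' @param tetramers Named numeric vector of tetramer copy numbers; names from
#'   `c("4H","3H1D","2H2D","1H3D","4D")`. Missing species default to 0.
#' @param dimers Named numeric vector over `c("HH","HD","DD")`; defaults 0.
#' @param monomers Named numeric vector over `c("H","D")`; defaults 0.
#' @param rates A [rate_set()].
#' @return An object of class `exchange_system`.
#' @seealso [equimolar_mix()] for the canonical 50:50 4H/4D starting state.
#' @export
exchange_system <- function(tetramers, dimers = NULL, monomers = NULL, rates) {
  fill <- function(x, species) {
    out <- stats::setNames(numeric(length(species)), species)
    if (!is.null(x)) {
      if (is.null(names(x)) || !all(names(x) %in% species))
        stop("species names must be among: ", paste(species, collapse = ", "))
      out[names(x)] <- x
    }
    out
  }
  tet <- fill(tetramers, TETRAMER_SPECIES)
  dim <- fill(dimers, DIMER_SPECIES)
  mon <- fill(monomers, MONOMER_SPECIES)
  counts <- c(tet, dim, mon)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("all copy numbers must be finite and >= 0")
  if (!inherits(rates, "rate_set")) stop("rates must be a rate_set object")
  structure(list(tetramers = tet, dimers = dim, monomers = mon, rates = rates),
            class = "exchange_system")
}

#' Equimolar 4H/4D starting mixture
#'
#' The canonical subunit-exchange starting state: hydrogenated and deuterated
#' tetramers mixed in equal parts, no free dimers or monomers.
#'
#' @param n_tetramers Total tetramer copy number (split 50:50). The default
#'   of 1e5 keeps relative stochastic fluctuations below about 1 percent,
#'   matching the smooth abundance curves seen in native MS.
#' @param rates A [rate_set()].
#' @return An `exchange_system`.
#' @export
equimolar_mix <- function(n_tetramers = 1e5, rates) {
  exchange_system(c("4H" = n_tetramers / 2, "4D" = n_tetramers / 2),
                  rates = rates)
}

#' Total monomer equivalents of a system state
#'
#' @param x An `exchange_system`, or a numeric vector of the 11 internal
#'   species counts (6 tetramer dimer-pair states, 3 dimers, 2 monomers) as
#'   stored in the `counts` attribute of a simulation result.
#' @return Total subunit count: `4 * tetramers + 2 * dimers + monomers`.
#' @export
monomer_equivalents <- function(x) {
  if (inherits(x, "exchange_system"))
    return(sum(x$tetramers) * 4 + sum(x$dimers) * 2 + sum(x$monomers))
  if (length(x) != 11L) stop("expected 11 internal species counts")
  sum(x[1:6]) * 4 + sum(x[7:9]) * 2 + sum(x[10:11])
}

#' @export
print.exchange_system <- function(x, ...) {
  cat("Subunit-exchange system state\n")
  cat("  tetramers:", paste(sprintf("%s=%.4g", names(x$tetramers), x$tetramers),
                            collapse = " "), "\n")
  cat("  dimers:   ", paste(sprintf("%s=%.4g", names(x$dimers), x$dimers),
                            collapse = " "), "\n")
  cat("  monomers: ", paste(sprintf("%s=%.4g", names(x$monomers), x$monomers),
                            collapse = " "), "\n")
  cat("  monomer equivalents:", monomer_equivalents(x), "\n")
  invisible(x)
}
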