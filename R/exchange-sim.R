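# Internal species layout. TTR tetramers are dimers of dimers, so each
# tetramer is tracked by its unordered pair of constituent dimers and
# dissociation returns exactly those two dimers; subunits scramble only at
# the dimer <-> monomer level. The two structurally distinct 2H2D
# assemblies (HH+DD and HD+HD) are pooled in the reported abundances only.
TET_PAIR_I <- c(0L, 0L, 0L, 1L, 1L, 2L)   # constituent dimer D-counts
TET_PAIR_J <- c(0L, 1L, 2L, 1L, 2L, 2L)
INTERNAL_SPECIES <- c("4H", "3H1D", "2H2D.HHDD", "2H2D.HDHD", "1H3D", "4D",
                      "HH", "HD", "DD", "H", "D")

# Mass-action ODE right-hand side, with the same combinatorial conventions
# as the stochastic simulator: unordered pairs react at rate k * n_i * n_j
# (k * n_i^2 / 2 for identical partners).
exchange_deriv <- function(t, x, p) {
  T6 <- x[1:6]; Dm <- x[7:9]; M <- x[10:11]
  iso <- p$isotope_factor
  nD <- TET_PAIR_I + TET_PAIR_J

  # tetramer dissociation into constituent dimers
  ftd <- p$k_tet_diss * iso^nD * T6
  # tetramer association from dimer pairs
  npair <- ifelse(TET_PAIR_I == TET_PAIR_J,
                  Dm[TET_PAIR_I + 1]^2 / 2,
                  Dm[TET_PAIR_I + 1] * Dm[TET_PAIR_J + 1])
  fta <- p$k_tet_assoc * iso^nD * npair

  dim_flux <- numeric(3)
  for (c in 1:6) {
    net <- ftd[c] - fta[c]
    dim_flux[TET_PAIR_I[c] + 1] <- dim_flux[TET_PAIR_I[c] + 1] + net
    dim_flux[TET_PAIR_J[c] + 1] <- dim_flux[TET_PAIR_J[c] + 1] + net
  }

  # dimer dissociation and association
  fdd <- p$k_dim_diss * iso^(0:2) * Dm
  fda <- c(p$k_dim_assoc * M[1]^2 / 2,
           p$k_dim_assoc * iso * M[1] * M[2],
           p$k_dim_assoc * iso^2 * M[2]^2 / 2)

  dT <- -ftd + fta
  dD <- dim_flux - fdd + fda
  dM <- c(2 * fdd[1] + fdd[2], fdd[2] + 2 * fdd[3]) -
    c(2 * fda[1] + fda[2], fda[2] + 2 * fda[3])
  list(c(dT, dD, dM))
}

#' Simulate H/D tetramer subunit exchange
#'
#' Propagates an [exchange_system()] through the reversible reaction network
#' tetramer <-> dimer + dimer <-> monomers, either deterministically
#' (mass-action ODEs integrated with `deSolve::lsoda`) or stochastically
#' (exact direct-method Gillespie simulation). Tetramer dissociation
#' repartitions the four subunits into two random unordered pairs, so a mixed
#' 2H2D tetramer yields HH + DD with probability 1/3 and HD + HD with
#' probability 2/3; association is composition-agnostic. Only the
#' dimer-mediated dissociation route is modelled.
#'
#' @param system An [exchange_system()] starting state.
#' @param t_grid Strictly increasing vector of times in days at which to
#'   report the state. A leading 0 is not required.
#' @param method `"ode"` (deterministic, default) or `"ssa"` (stochastic).
#' @param seed Integer seed for the stochastic method.
#' @return An object of class `abundance_ts`: a data frame with columns
#'   `time_days`, `species` and `abundance_pct` giving each tetramer species
#'   as a percentage of total tetramer signal, with the full 11-species
#'   internal count matrix (tetramers by constituent dimer pair, dimers,
#'   monomers) in `attr(, "counts")`.
#' @examples
#' rs <- rate_set(0.2, 1e-2, 0.5, 1e-2)
#' ts <- simulate_exchange(equimolar_mix(1e4, rs), t_grid = 0:11)
#' head(ts)
#' @export
simulate_exchange <- function(system, t_grid, method = c("ode", "ssa"),
                              seed = NULL) {
  method <- match.arg(method)
  if (!inherits(system, "exchange_system")) stop("system must be an exchange_system")
  if (length(t_grid) == 0 || any(!is.finite(t_grid)) || any(t_grid < 0))
    stop("t_grid must be non-empty, finite and non-negative")
  if (is.unsorted(t_grid, strictly = TRUE))
    stop("t_grid must be strictly increasing")

  # expand the MS-visible state to the internal dimer-pair bookkeeping: a
  # user-supplied pooled 2H2D count is split 1/3 HH+DD : 2/3 HD+HD, the
  # random-assembly proportions from a scrambled dimer pool
  tet <- system$tetramers
  x0 <- stats::setNames(
    c(tet[["4H"]], tet[["3H1D"]], tet[["2H2D"]] / 3, 2 * tet[["2H2D"]] / 3,
      tet[["1H3D"]], tet[["4D"]], system$dimers, system$monomers),
    INTERNAL_SPECIES)
  r <- system$rates

  if (method == "ode") {
    times <- unique(c(0, t_grid))
    sol <- deSolve::lsoda(y = x0, times = times, func = exchange_deriv,
                          parms = r, rtol = 1e-10, atol = 1e-8)
    counts <- sol[match(t_grid, sol[, 1]), -1, drop = FALSE]
  } else {
    if (!is.null(seed)) set.seed(seed)
    counts <- ssa_exchange_cpp(unname(x0), r$k_tet_diss, r$k_tet_assoc,
                               r$k_dim_diss, r$k_dim_assoc, r$isotope_factor,
                               t_grid)
  }
  colnames(counts) <- names(x0)
  abundance_ts_from_counts(t_grid, counts)
}

# Convert a grid x 11 internal-species count matrix to the percent-abundance
# format, pooling the two 2H2D assemblies.
abundance_ts_from_counts <- function(t_grid, counts) {
  tet <- cbind("4H" = counts[, "4H"], "3H1D" = counts[, "3H1D"],
               "2H2D" = counts[, "2H2D.HHDD"] + counts[, "2H2D.HDHD"],
               "1H3D" = counts[, "1H3D"], "4D" = counts[, "4D"])
  tot <- rowSums(tet)
  pct <- 100 * tet / ifelse(tot > 0, tot, NA_real_)
  out <- data.frame(
    time_days = rep(t_grid, times = length(TETRAMER_SPECIES)),
    species = factor(rep(TETRAMER_SPECIES, each = length(t_grid)),
                     levels = TETRAMER_SPECIES),
    abundance_pct = as.vector(pct)
  )
  structure(out, counts = counts, class = c("abundance_ts", "data.frame"))
}

#' Render native-MS style peak areas from an abundance time series
#'
#' Emulates the charge-state-resolved peak areas a Q-TOF instrument would
#' report for a tetramer abundance series: each species' signal is spread
#' over the given charge states with fixed intensity weights, then perturbed
#' with Gaussian noise truncated at zero. Before noise, the species-summed
#' proportions equal the input percent abundances exactly.
#'
#' @param ts An `abundance_ts` (see [simulate_exchange()]).
#' @param charge_states Integer vector of charge states, e.g. `13:15`.
#' @param weights Optional intensity weights, one per charge state; default
#'   is a Gaussian profile centred on the middle of the charge range, as in
#'   a typical charge-state envelope. Normalised internally.
#' @param noise_sd Noise standard deviation in percent of the per-charge
#'   total signal; must be >= 0.
#' @param total_area Total instrument signal per time point (arbitrary units).
#' @param seed Integer seed for the noise.
#' @return A data frame of class `peak_area_table` with columns `time_days`,
#'   `species`, `charge`, `area`.
#' @export
render_peak_areas <- function(ts, charge_states = 13:15, weights = NULL,
                              noise_sd = 0, total_area = 1e4, seed = NULL) {
  if (length(charge_states) == 0) stop("charge_states must be non-empty")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (is.null(weights)) {
    mid <- mean(range(charge_states))
    weights <- exp(-0.5 * ((charge_states - mid) / 1.5)^2)
  }
  if (length(weights) != length(charge_states))
    stop("weights must match charge_states in length")
  weights <- weights / sum(weights)
  if (!is.null(seed)) set.seed(seed)

  grid <- expand.grid(charge_idx = seq_along(charge_states),
                      row = seq_len(nrow(ts)))
  area0 <- ts$abundance_pct[grid$row] / 100 * total_area *
    weights[grid$charge_idx]
  noise <- if (noise_sd > 0)
    stats::rnorm(length(area0), 0, noise_sd / 100 * total_area *
                   weights[grid$charge_idx])
  else 0
  out <- data.frame(
    time_days = ts$time_days[grid$row],
    species = ts$species[grid$row],
    charge = charge_states[grid$charge_idx],
    area = pmax(area0 + noise, 0)
  )
  class(out) <- c("peak_area_table", "data.frame")
  out
}

#' Read and write abundance time-series CSV files
#'
#' Plain CSV interchange format with columns `time_days`, `species`,
#' `abundance_pct`.
#'
#' @param ts An `abundance_ts` data frame.
#' @param file Path to a CSV file.
#' @return `read_abundance_csv` returns an `abundance_ts`;
#'   `write_abundance_csv` returns `file` invisibly.
#' @export
write_abundance_csv <- function(ts, file) {
  utils::write.csv(as.data.frame(ts)[, c("time_days", "species", "abundance_pct")],
                   file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_abundance_csv
#' @export
read_abundance_csv <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("time_days", "species", "abundance_pct")
  if (!all(need %in% names(df)))
    stop("CSV must have columns: ", paste(need, collapse = ", "))
  df$species <- factor(df$species,
                       levels = union(TETRAMER_SPECIES, unique(df$species)))
  class(df) <- c("abundance_ts", "data.frame")
  df
}
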