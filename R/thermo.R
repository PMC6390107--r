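# Gas constant in kcal / (mol K).
R_KCAL <- 1.987e-3

#' Nonequilibrium work samples for free-energy estimation
#'
#' Container for forward and reverse alchemical work values (kcal/mol),
#' grouped by independent replicate. Reverse works are given in the forward
#' sign convention of the BAR self-consistency equation used by
#' [bar_free_energy()].
#'
#' @param forward,reverse Numeric work values in kcal/mol (>= 1 each).
#' @param temperature Temperature in kelvin (default 298).
#' @param forward_groups,reverse_groups Optional replicate labels (one per
#'   work value). The canonical design is 10 groups of 50.
#' @return An object of class `work_samples`.
#' @export
work_samples <- function(forward, reverse, temperature = 298,
                         forward_groups = NULL, reverse_groups = NULL) {
  if (length(forward) < 1 || length(reverse) < 1)
    stop("need at least one work value in each direction")
  if (!is.finite(temperature) || temperature <= 0)
    stop("temperature must be positive")
  chk <- function(g, n, what) {
    if (is.null(g)) return(rep(1L, n))
    if (length(g) != n) stop(what, " groups must match work values in length")
    if (any(table(g) == 0)) stop("empty replicate group")
    g
  }
  structure(list(forward = forward, reverse = reverse,
                 temperature = temperature,
                 forward_groups = chk(forward_groups, length(forward), "forward"),
                 reverse_groups = chk(reverse_groups, length(reverse), "reverse")),
            class = "work_samples")
}

#' Read a work-sample CSV
#'
#' Columns: `direction` (`forward`/`reverse`), `group`, `work_kcal_per_mol`.
#'
#' @param file CSV path.
#' @param temperature Temperature in kelvin.
#' @return A [work_samples()] object.
#' @export
read_work_csv <- function(file, temperature = 298) {
  df <- utils::read.csv(file)
  need <- c("direction", "group", "work_kcal_per_mol")
  if (!all(need %in% names(df)))
    stop("CSV must have columns: ", paste(need, collapse = ", "))
  f <- df$direction == "forward"
  work_samples(df$work_kcal_per_mol[f], df$work_kcal_per_mol[!f],
               temperature = temperature,
               forward_groups = df$group[f], reverse_groups = df$group[!f])
}

# Solve the BAR self-consistency equation for one set of works.
bar_solve <- function(wf, wr, beta, nf = length(wf), nr = length(wr)) {
  lr <- log(nf / nr)
  fermi <- function(dg) {
    c(sum(1 / (1 + exp(pmin(beta * (wf - dg) + lr, 700)))),
      sum(1 / (1 + exp(pmin(beta * (wr + dg) - lr, 700)))))
  }
  g <- function(dg) { s <- fermi(dg); s[1] - s[2] }
  lo <- min(c(wf, -wr)) - 50 / beta
  hi <- max(c(wf, -wr)) + 50 / beta
  root <- stats::uniroot(g, c(lo, hi), tol = 1e-10, extendInt = "yes")
  s <- fermi(root$root)
  list(dg = root$root, residual = abs(s[1] - s[2]),
       overlap = mean(s) / min(nf, nr))
}

#' Bennett acceptance ratio free-energy estimate
#'
#' Estimates the free-energy difference from forward and reverse
#' nonequilibrium work samples by solving the BAR self-consistency equation
#' \deqn{\sum_F [1 + (n_F/n_R) e^{\beta(W_F - \Delta G)}]^{-1} =
#'       \sum_R [1 + (n_R/n_F) e^{\beta(W_R + \Delta G)}]^{-1}}
#' by bracketed root finding (tolerance 1e-10 kcal/mol). The point estimate
#' pools all samples; the standard error is the standard error of the mean
#' of per-replicate-group BAR estimates.
#'
#' @param ws A [work_samples()] object, or forward works (with `reverse`
#'   supplied).
#' @param reverse Reverse works when `ws` is a numeric vector.
#' @param temperature Temperature in kelvin (used only for vector input).
#' @return An object of class `bar_estimate`: list with `dg`, `se`,
#'   `n_groups`, `overlap_warning` and the per-group estimates. Swapping the
#'   forward and reverse sets negates `dg` exactly.
#' @examples
#' bar_free_energy(work_samples(rnorm(50, 6, 1), rnorm(50, -4, 1)))
#' @export
bar_free_energy <- function(ws, reverse = NULL, temperature = 298) {
  if (!inherits(ws, "work_samples"))
    ws <- work_samples(ws, reverse, temperature)
  beta <- 1 / (R_KCAL * ws$temperature)
  main <- bar_solve(ws$forward, ws$reverse, beta)

  gl <- intersect(unique(ws$forward_groups), unique(ws$reverse_groups))
  per_group <- if (length(gl) >= 2) {
    vapply(gl, function(g) {
      bar_solve(ws$forward[ws$forward_groups == g],
                ws$reverse[ws$reverse_groups == g], beta)$dg
    }, 0)
  } else NA_real_
  se <- if (length(gl) >= 2)
    stats::sd(per_group) / sqrt(length(gl)) else NA_real_

  overlap_warning <- main$residual > 1e-6 || main$overlap < 1e-6 ||
    (length(gl) >= 2 && !is.finite(se))
  if (overlap_warning)
    warning("work distributions may not overlap; BAR estimate unreliable")
  structure(list(dg = main$dg, se = se, n_groups = length(gl),
                 per_group = per_group, residual = main$residual,
                 temperature = ws$temperature,
                 overlap_warning = overlap_warning),
            class = "bar_estimate")
}

#' @export
print.bar_estimate <- function(x, ...) {
  cat(sprintf("BAR free-energy estimate: %.3f ± %.3f kcal/mol (%d groups)\n",
              x$dg, x$se, x$n_groups))
  if (x$overlap_warning) cat("  warning: poor forward/reverse overlap\n")
  invisible(x)
}

#' Relative stability of a mutant in one oligomeric state
#'
#' One leg of the mutant thermodynamic cycle: the mutation free energy
#' computed in the folded state minus the same mutation computed in the
#' unfolded reference (capped tripeptide), giving the stability of the
#' mutant species relative to wild type. Positive values shift the
#' equilibrium toward the dissociated/unfolded side. Uncertainties combine
#' in quadrature.
#'
#' @param dg_state Mutation free energy in the oligomeric state (kcal/mol).
#' @param se_state Its standard error.
#' @param dg_reference Mutation free energy in the unfolded reference.
#' @param se_reference Its standard error.
#' @return List with `ddg` and `se` (class `ddg`).
#' @export
ddg_state <- function(dg_state, se_state = 0, dg_reference = 0,
                      se_reference = 0) {
  stopifnot(is.finite(dg_state), is.finite(dg_reference))
  structure(list(ddg = dg_state - dg_reference,
                 se = sqrt(se_state^2 + se_reference^2)),
            class = "ddg")
}

#' @export
print.ddg <- function(x, ...) {
  cat(sprintf("ddG = %+.2f ± %.2f kcal/mol (%s)\n", x$ddg, x$se,
              if (x$ddg > 0) "destabilising" else if (x$ddg < 0)
                "stabilising" else "neutral"))
  invisible(x)
}

#' Combined tetramer dissociation-and-unfolding ddG
#'
#' Stoichiometric combination of the per-state relative stabilities for the
#' overall process tetramer -> 2 dimers -> 4 monomers -> 4 unfolded chains,
#' per tetramer:
#' `ddG_unf = ddG_tetr + 2 ddG_dime + 4 ddG_mono`. Standard errors follow
#' the same coefficients in quadrature.
#'
#' @param ddg_tetr,ddg_dime,ddg_mono Per-state relative stabilities in
#'   kcal/mol (numeric, or `ddg` objects carrying their own errors).
#' @param se_tetr,se_dime,se_mono Standard errors (ignored for `ddg` input).
#' @return List with `ddg` and `se` (class `ddg`).
#' @export
ddg_unfold <- function(ddg_tetr, ddg_dime, ddg_mono,
                       se_tetr = 0, se_dime = 0, se_mono = 0) {
  grab <- function(x, se) {
    if (inherits(x, "ddg")) c(x$ddg, x$se) else c(x, se)
  }
  t <- grab(ddg_tetr, se_tetr); d <- grab(ddg_dime, se_dime)
  m <- grab(ddg_mono, se_mono)
  structure(list(ddg = t[1] + 2 * d[1] + 4 * m[1],
                 se = sqrt(t[2]^2 + 4 * d[2]^2 + 16 * m[2]^2)),
            class = "ddg")
}

#' Equilibrium-constant fold change of a ddG
#'
#' Converts a relative stability into the corresponding equilibrium-constant
#' ratio `exp(|ddG| / RT)`, with the direction (stabilising vs
#' destabilising) carried as a label from the sign.
#'
#' @param ddg Relative stability in kcal/mol (numeric or `ddg` object).
#' @param temperature Temperature in kelvin (default 298).
#' @return List with `factor` and `direction` (class `fold_change`).
#' @examples
#' fold_change(2.1)   # about 34-fold toward unfolded
#' @export
fold_change <- function(ddg, temperature = 298) {
  if (inherits(ddg, "ddg")) ddg <- ddg$ddg
  stopifnot(is.finite(ddg))
  structure(list(factor = exp(abs(ddg) / (R_KCAL * temperature)),
                 direction = if (ddg > 0) "destabilising" else if (ddg < 0)
                   "stabilising" else "neutral",
                 ddg = ddg, temperature = temperature),
            class = "fold_change")
}

#' @export
print.fold_change <- function(x, ...) {
  cat(sprintf("fold change: %.3g (%s)\n", x$factor, x$direction))
  invisible(x)
}

#' Binding free energy from a dissociation constant
#'
#' `dG = -RT ln(Kd / c0)` at standard state `c0` (1 M); the magnitude of the
#' binding free energy is returned.
#'
#' @param kd Dissociation constant in molar; must be > 0.
#' @param temperature Temperature in kelvin (default 298).
#' @param standard_state Standard-state concentration in molar (default 1).
#' @return Binding free-energy magnitude in kcal/mol.
#' @examples
#' kd_to_dg(2e-9)   # tafamidis Kd1: about 12 kcal/mol
#' @export
kd_to_dg <- function(kd, temperature = 298, standard_state = 1) {
  if (!is.finite(kd) || kd <= 0) stop("Kd must be positive")
  abs(-R_KCAL * temperature * log(kd / standard_state))
}

#' Additive combination of mutational ddG values
#'
#' For spatially separated mutations the energetic effects are assumed
#' additive: the combined ddG is the sum, with standard errors in
#' quadrature.
#'
#' @param ddg Numeric vector of ddG values (kcal/mol), or list of `ddg`
#'   objects; at least 2 entries.
#' @param se Standard errors matching `ddg` (ignored for `ddg` objects).
#' @return List with `ddg`, `se` and a net direction label (class `ddg`).
#' @examples
#' ddg_additivity(c(8.1, -12.4))   # S52P + T119M: net stabilising
#' @export
ddg_additivity <- function(ddg, se = NULL) {
  if (is.list(ddg) && all(vapply(ddg, inherits, TRUE, "ddg"))) {
    se <- vapply(ddg, function(x) x$se, 0)
    ddg <- vapply(ddg, function(x) x$ddg, 0)
  }
  if (length(ddg) < 1) stop("need at least 1 ddG entry")
  if (is.null(se)) se <- rep(0, length(ddg))
  structure(list(ddg = sum(ddg), se = sqrt(sum(se^2))), class = "ddg")
}
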