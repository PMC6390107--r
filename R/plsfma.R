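#' Partial-least-squares functional mode analysis
#'
#' Regresses a scalar functional property (typically the fraction of native
#' contacts Q) on main-chain atomic coordinates by PLS regression and
#' extracts the collective mode maximally correlated with the property. The
#' first `train_frac` of frames (time-ordered) are used for training and the
#' remainder for validation; model quality is reported as the Pearson
#' correlation between predicted and observed property on each set. The
#' PLS-FMA mode is the ensemble-weighted maximally correlated mode: the
#' covariance between the centred coordinates and the model prediction,
#' normalised to unit length -- the collective displacement pattern the
#' ensemble actually performs as the property changes. The raw
#' regression-coefficient direction is kept as `$coefficients`.
#'
#' Coordinates are centred per feature and the property is standardised
#' before the regression; frames should be superposed on a common reference
#' first ([align_frames()], done automatically for trajectory input unless
#' `align = FALSE`).
#'
#' @param traj A `coord_trajectory`, or a frames-by-features numeric matrix
#'   of (already aligned) coordinates.
#' @param property Numeric property value per frame.
#' @param n_components Number of PLS components (default 20).
#' @param train_frac Fraction of frames used for training (default 0.75).
#' @param split `"block"` (contiguous leading fraction, default) or
#'   `"random"` (seeded shuffle).
#' @param seed Seed for the random split.
#' @param selection Atom indices used as features for trajectory input;
#'   default all main-chain atoms.
#' @param align Superpose frames onto the trajectory reference before
#'   analysis (trajectory input only).
#' @return An object of class `fma_model`: the fitted PLS model, training
#'   and validation Pearson `r`, the unit-norm mode vector (one 3-vector per
#'   selected atom), the mean structure, and the feature atom table.
#' @examples
#' \donttest{
#' toy <- make_toy_oligomer(4)
#' traj <- make_unfolding_trajectory(toy, n_frames = 200, seed = 1)
#' cs <- build_contacts(toy, "fold", chain = "A")
#' q <- q_timeseries(traj, cs)$Q
#' fma <- fit_fma(traj, q, n_components = 20,
#'                selection = mainchain_indices(toy, "A"))
#' fma$r_val
#' }
#' @export
fit_fma <- function(traj, property, n_components = 20, train_frac = 0.75,
                    split = c("block", "random"), seed = 1,
                    selection = NULL, align = TRUE) {
  split <- match.arg(split)
  if (inherits(traj, "coord_trajectory")) {
    if (align) traj <- align_frames(traj)
    if (is.null(selection)) selection <- mainchain_indices(traj$ref)
    cols <- as.vector(t(cbind(3 * selection - 2, 3 * selection - 1,
                              3 * selection)))
    X <- traj$xyz[, cols, drop = FALSE]
    feat_atoms <- traj$ref$atoms[selection, c("elety", "resno", "chain"),
                                 drop = FALSE]
  } else {
    X <- as.matrix(traj)
    feat_atoms <- NULL
  }
  n <- nrow(X)
  if (length(property) != n)
    stop("property length must equal the number of frames")
  if (stats::sd(property) == 0)
    stop("property is constant; correlation with coordinates is undefined")
  if (!(train_frac > 0 && train_frac < 1))
    stop("train_frac must be in (0, 1)")
  if (n < 2 * n_components)
    stop("need at least 2 x n_components frames")
  n_train <- floor(train_frac * n)
  if (n_components >= n_train)
    stop("n_components must be smaller than the number of training frames")

  idx <- seq_len(n)
  if (split == "random") {
    set.seed(seed)
    idx <- sample(idx)
  }
  itr <- idx[seq_len(n_train)]
  ival <- idx[-seq_len(n_train)]

  colnames(X) <- paste0("x", seq_len(ncol(X)))
  y_mean <- mean(property[itr]); y_sd <- stats::sd(property[itr])
  y_std <- (property - y_mean) / y_sd
  fit <- mixOmics::pls(X[itr, , drop = FALSE],
                       matrix(y_std[itr], dimnames = list(NULL, "y")),
                       ncomp = n_components, mode = "regression",
                       scale = FALSE)
  pr_tr <- stats::predict(fit, X[itr, , drop = FALSE])
  pr_va <- stats::predict(fit, X[ival, , drop = FALSE])
  yhat_tr <- pr_tr$predict[, 1, n_components]
  yhat_va <- pr_va$predict[, 1, n_components]
  r_train <- stats::cor(yhat_tr, y_std[itr])
  r_val <- stats::cor(yhat_va, y_std[ival])

  beta <- pr_tr$B.hat[, 1, n_components]
  # ensemble-weighted maximally correlated mode: covariance of coordinates
  # with the prediction, i.e. the coefficient direction weighted by the
  # ensemble covariance. Sample covariances below the universal threshold
  # of their own sampling noise are shrunk to zero so that uninvolved atoms
  # do not accumulate spurious amplitude.
  cv <- as.vector(stats::cov(X[itr, , drop = FALSE], yhat_tr))
  noise_scale <- stats::mad(cv)
  if (noise_scale > 0) {
    thr <- noise_scale * sqrt(2 * log(length(cv)))
    shrunk <- sign(cv) * pmax(abs(cv) - thr, 0)
    if (any(shrunk != 0)) cv <- shrunk
  }
  mode <- cv / sqrt(sum(cv^2))

  structure(list(
    pls = fit,
    n_components = n_components,
    train_frac = train_frac,
    split = split,
    train_idx = itr,
    val_idx = ival,
    r_train = unname(r_train),
    r_val = unname(r_val),
    mode = unname(as.vector(mode)),
    coefficients = unname(beta / sqrt(sum(beta^2))),
    mean_structure = colMeans(X[itr, , drop = FALSE]),
    feature_atoms = feat_atoms,
    selection = if (inherits(traj, "coord_trajectory")) selection else NULL,
    y_center = y_mean, y_scale = y_sd
  ), class = "fma_model")
}

#' @export
print.fma_model <- function(x, ...) {
  cat("PLS functional mode analysis\n")
  cat(sprintf("  %d components, %.0f%%/%.0f%% %s split\n", x$n_components,
              100 * x$train_frac, 100 * (1 - x$train_frac), x$split))
  cat(sprintf("  Pearson r: training %.4f, validation %.4f\n",
              x$r_train, x$r_val))
  invisible(x)
}

#' @export
predict.fma_model <- function(object, newdata, ...) {
  if (inherits(newdata, "coord_trajectory")) {
    sel <- object$selection
    cols <- as.vector(t(cbind(3 * sel - 2, 3 * sel - 1, 3 * sel)))
    newdata <- newdata$xyz[, cols, drop = FALSE]
  }
  newdata <- as.matrix(newdata)
  colnames(newdata) <- paste0("x", seq_len(ncol(newdata)))
  pr <- stats::predict(object$pls, newdata)
  pr$predict[, 1, object$n_components] * object$y_scale + object$y_center
}

#' Per-residue amplitude of the PLS-FMA mode
#'
#' Aggregates the unit mode vector to residues: each residue's amplitude is
#' the Euclidean norm of its atoms' mode components, so the squared
#' amplitudes sum to one over all residues.
#'
#' @param model An `fma_model` fitted on trajectory input (or supply
#'   `atom_map`).
#' @param atom_map Optional data frame with one row per feature atom and
#'   columns `chain` and `resno`, overriding the model's stored atom table.
#' @return Data frame with columns `chain`, `resno`, `amplitude`, ordered by
#'   decreasing amplitude.
#' @export
mode_rmsf <- function(model, atom_map = NULL) {
  am <- if (is.null(atom_map)) model$feature_atoms else atom_map
  if (is.null(am))
    stop("no atom map available; supply atom_map")
  n_at <- length(model$mode) / 3
  if (nrow(am) != n_at)
    stop("atom map rows (", nrow(am), ") do not match mode atoms (", n_at, ")")
  comp2 <- matrix(model$mode^2, ncol = 3, byrow = TRUE)
  per_atom <- rowSums(comp2)
  key <- paste(am$chain, am$resno)
  agg <- tapply(per_atom, key, sum)
  parts <- do.call(rbind, strsplit(names(agg), " "))
  out <- data.frame(chain = parts[, 1], resno = as.integer(parts[, 2]),
                    amplitude = sqrt(as.numeric(agg)))
  out[order(-out$amplitude), , drop = FALSE]
}

#' Write a structure coloured by mode amplitude
#'
#' Writes a PDB file with each atom's B-factor set to the per-residue
#' PLS-FMA mode amplitude, for visualisation.
#'
#' @param model An `fma_model`.
#' @param structure The `protein_structure` the model was fitted on.
#' @param file Output PDB path.
#' @export
write_mode_pdb <- function(model, structure, file) {
  amp <- mode_rmsf(model)
  key <- paste(structure$atoms$chain, structure$atoms$resno)
  b <- amp$amplitude[match(key, paste(amp$chain, amp$resno))]
  b[is.na(b)] <- 0
  write_structure(structure, file, b = b)
}
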