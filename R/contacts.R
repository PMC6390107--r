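#' Build a native-contact list from a reference structure
#'
#' Enumerates all heavy-atom pairs within `cutoff` of each other in the
#' reference structure. In `"fold"` mode both atoms must be on the same
#' chain and on residues separated by more than `min_sep` other residues
#' (i.e. `|resno_i - resno_j| >= min_sep + 1`); in `"interface"` mode the
#' atoms must be on two different chains. Hydrogen and deuterium atoms are
#' excluded throughout.
#'
#' @param structure A `protein_structure` used as the native reference.
#' @param mode `"fold"` or `"interface"`.
#' @param cutoff Contact distance cutoff in Angstrom (default 4.5).
#' @param min_sep Minimum number of residues between the two contact
#'   residues in fold mode (default 3).
#' @param chain In fold mode, restrict to one chain (default: all chains,
#'   each within itself).
#' @param chain_pair In interface mode, a length-2 character vector limiting
#'   pairs to those between the two named chains (default: all inter-chain
#'   pairs).
#' @return An object of class `contact_set`: data frame with columns `i`,
#'   `j` (atom indices into the structure) and `r0` (reference distance),
#'   plus attributes `mode`, `cutoff` and `structure_atoms`. An empty result
#'   is returned (with a warning) when no pair qualifies.
#' @export
build_contacts <- function(structure, mode = c("fold", "interface"),
                           cutoff = 4.5, min_sep = 3, chain = NULL,
                           chain_pair = NULL) {
  mode <- match.arg(mode)
  at <- structure$atoms
  all_chains <- unique(at$chain)
  for (ch in c(chain, chain_pair))
    if (!is.null(ch) && !(ch %in% all_chains))
      stop("unknown chain id: ", ch)

  heavy <- which(is_heavy_atom(structure))
  if (mode == "fold" && !is.null(chain))
    heavy <- heavy[at$chain[heavy] == chain]
  if (mode == "interface" && !is.null(chain_pair))
    heavy <- heavy[at$chain[heavy] %in% chain_pair]

  xyz <- structure$xyz[heavy, , drop = FALSE]
  d <- as.matrix(stats::dist(xyz))
  idx <- which(d <= cutoff & upper.tri(d), arr.ind = TRUE)
  i <- heavy[idx[, 1]]; j <- heavy[idx[, 2]]

  same_chain <- at$chain[i] == at$chain[j]
  if (mode == "fold") {
    keep <- same_chain & abs(at$resno[i] - at$resno[j]) >= min_sep + 1
  } else {
    keep <- !same_chain
    if (!is.null(chain_pair))
      keep <- keep & ((at$chain[i] == chain_pair[1] & at$chain[j] == chain_pair[2]) |
                      (at$chain[i] == chain_pair[2] & at$chain[j] == chain_pair[1]))
  }
  out <- data.frame(i = i[keep], j = j[keep], r0 = d[idx][keep])
  out <- out[order(out$i, out$j), , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0)
    warning("no qualifying contact pairs found (", mode, " mode)")
  structure(out, mode = mode, cutoff = cutoff,
            structure_atoms = at[, c("elety", "resno", "chain")],
            class = c("contact_set", "data.frame"))
}

#' Fraction of native contacts Q of one frame
#'
#' Computes the smoothed fraction of native contacts
#' \deqn{Q(x) = \frac{1}{N} \sum_{(i,j)} \frac{1}{1 + \exp[\beta(r_{ij}(x) -
#' \lambda r^0_{ij})]}}{Q = mean(1 / (1 + exp(beta (r - lambda r0))))}
#' over the pairs of a [build_contacts()] set, where `r_ij(x)` is the pair
#' distance in the frame and `r0_ij` the reference distance.
#'
#' @param coords Frame coordinates: an `n_atoms x 3` matrix (full structure
#'   indexing) or a length-3N xyz vector.
#' @param contacts A `contact_set`.
#' @param beta Smoothing parameter in inverse Angstrom (default 5).
#' @param lambda Fluctuation tolerance factor (default 1.8, the value for
#'   atomistic simulations).
#' @return Q in (0, 1).
#' @export
q_value <- function(coords, contacts, beta = 5, lambda = 1.8) {
  if (nrow(contacts) == 0)
    stop("Q is undefined for an empty contact set")
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 3, byrow = TRUE)
  if (max(contacts$i, contacts$j) > nrow(coords))
    stop("frame does not supply coordinates for all contact atoms")
  dv <- coords[contacts$i, , drop = FALSE] - coords[contacts$j, , drop = FALSE]
  r <- sqrt(rowSums(dv * dv))
  mean(1 / (1 + exp(beta * (r - lambda * contacts$r0))))
}

#' Q time series over a trajectory
#'
#' Evaluates [q_value()] for each frame of a trajectory and each tracked
#' unit (e.g. one contact set per monomer fold and per interface).
#'
#' @param traj A `coord_trajectory`.
#' @param contacts_by_unit A single `contact_set` or a named list of them.
#' @param beta,lambda Passed to [q_value()].
#' @return A `q_series` data frame with columns `frame`, `unit`, `Q`.
#' @export
q_timeseries <- function(traj, contacts_by_unit, beta = 5, lambda = 1.8) {
  if (inherits(contacts_by_unit, "contact_set"))
    contacts_by_unit <- list(unit = contacts_by_unit)
  if (is.null(names(contacts_by_unit)))
    names(contacts_by_unit) <- paste0("unit", seq_along(contacts_by_unit))
  n_at <- nrow(traj$ref$atoms)
  n_fr <- nrow(traj$xyz)
  out <- vector("list", length(contacts_by_unit))
  for (u in seq_along(contacts_by_unit)) {
    cs <- contacts_by_unit[[u]]
    if (max(cs$i, cs$j) > n_at)
      stop("contact atoms exceed trajectory atom count")
    q <- numeric(n_fr)
    for (f in seq_len(n_fr)) {
      co <- frame_coords(traj, f)
      if (anyNA(co))
        stop("missing coordinates in frame ", f)
      q[f] <- q_value(co, cs, beta, lambda)
    }
    out[[u]] <- data.frame(frame = seq_len(n_fr),
                           unit = names(contacts_by_unit)[u], Q = q)
  }
  res <- do.call(rbind, out)
  class(res) <- c("q_series", "data.frame")
  res
}

#' Per-region Q time series
#'
#' Splits a contact set by structural region (e.g. beta-strand) and computes
#' Q over each region's contact subset for every frame. A pair belongs to a
#' region if either of its residues is in the region, so regions form
#' overlapping subsets rather than a partition unless requested.
#'
#' @param traj A `coord_trajectory`.
#' @param contacts A `contact_set` built on the trajectory's reference.
#' @param region_map Named list mapping region label to residue numbers, or
#'   a data frame with columns `resno` and `region` (optionally `chain`).
#' @param partition If `TRUE`, assign each pair to the region of its
#'   first-listed residue only, making the subsets a partition.
#' @param beta,lambda Passed to [q_value()].
#' @return A `q_series` data frame with columns `frame`, `region`, `Q`.
#'   Regions with no contacts are omitted with a warning.
#' @export
q_by_region <- function(traj, contacts, region_map, partition = FALSE,
                        beta = 5, lambda = 1.8) {
  at <- attr(contacts, "structure_atoms")
  if (is.data.frame(region_map)) {
    region_map <- split(region_map$resno, region_map$region)
  }
  res_i <- at$resno[contacts$i]
  res_j <- at$resno[contacts$j]
  assigned <- rep(FALSE, nrow(contacts))
  out <- list()
  for (rg in names(region_map)) {
    members <- region_map[[rg]]
    sel <- (res_i %in% members) | (res_j %in% members)
    if (partition) {
      sel <- sel & !assigned
      assigned <- assigned | sel
    }
    if (!any(sel)) {
      warning("region ", rg, " has no contacts; omitted")
      next
    }
    cs <- contacts[sel, , drop = FALSE]
    attributes(cs) <- c(attributes(cs),
                        attributes(contacts)[c("mode", "cutoff",
                                               "structure_atoms")])
    class(cs) <- class(contacts)
    qs <- q_timeseries(traj, list(cs), beta, lambda)
    out[[rg]] <- data.frame(frame = qs$frame, region = rg, Q = qs$Q)
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  class(res) <- c("q_series", "data.frame")
  res
}
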