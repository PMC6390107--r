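#' Resolve an atom selector to a single atom
#'
#' Selectors have the form `"chain/resno/atom"` (e.g. `"A/50/CA"`) or are
#' lists with elements `chain`, `resno`, `elety` and optionally `resid`.
#' When alternate locations are present the highest-occupancy one is taken,
#' ties broken alphabetically by altloc identifier.
#'
#' @param structure A `protein_structure`.
#' @param sel Selector string or list.
#' @return The index of the matching atom in the structure.
#' @export
atom_select <- function(structure, sel) {
  if (is.character(sel)) {
    parts <- strsplit(sel, "/", fixed = TRUE)[[1]]
    if (length(parts) != 3)
      stop("selector string must be chain/resno/atom: ", sel)
    sel <- list(chain = parts[1], resno = as.integer(parts[2]),
                elety = parts[3])
  }
  at <- structure$atoms
  cond <- at$chain == sel$chain & at$resno == sel$resno & at$elety == sel$elety
  if (!is.null(sel$resid)) cond <- cond & at$resid == sel$resid
  hits <- which(cond)
  label <- paste(sel$chain, sel$resno, sel$elety, sep = "/")
  if (length(hits) == 0)
    stop("selector does not resolve: ", label)
  if (length(hits) > 1) {
    alts <- at$alt[hits]
    if (all(alts == alts[1]))
      stop("ambiguous selector (", length(hits), " atoms): ", label)
    ord <- order(-at$o[hits], alts)
    hits <- hits[ord[1]]
  }
  hits
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Distance between two selected atoms
#'
#' @param structure A `protein_structure`.
#' @param a,b Atom selectors (see [atom_select()]).
#' @param digits Decimals to round to; distances are conventionally reported
#'   to 0.1 Angstrom. Use `NULL` for full precision.
#' @return Euclidean distance in Angstrom.
#' @examples
#' \donttest{
#' # CD-loop diagnostic: Ser50 CA to residue-52 amide N
#' # atom_distance(structure, "A/50/CA", "A/52/N")
#' }
#' @export
atom_distance <- function(structure, a, b, digits = 1) {
  i <- atom_select(structure, a)
  j <- atom_select(structure, b)
  d <- sqrt(sum((structure$xyz[i, ] - structure$xyz[j, ])^2))
  if (!is.null(digits)) d <- round(d, digits)
  d
}

#' Detect hydrogen bonds in a structure
#'
#' Finds donor-hydrogen-acceptor triplets satisfying a heavy-atom
#' donor-acceptor distance cutoff and a donor-H-acceptor angle cutoff.
#' Donors are N, O or S atoms with a covalently attached hydrogen or
#' deuterium (within 1.3 Angstrom); deuterium atoms are treated exactly as
#' hydrogens, consistent with neutron-structure conventions. Acceptors are N
#' or O atoms on a different residue. For structures without H/D atoms the
#' angle criterion is dropped and donor-acceptor distance alone is used.
#'
#' @param structure A `protein_structure`.
#' @param distance_cutoff Donor-acceptor heavy-atom distance cutoff in
#'   Angstrom (default 3.5).
#' @param angle_cutoff Minimum donor-H-acceptor angle in degrees (default
#'   120).
#' @param chains Optional chain subset.
#' @return Data frame with columns `donor`, `hydrogen`, `acceptor`
#'   (selector strings; `hydrogen` is `NA` in the heavy-atom fallback),
#'   `distance` (Angstrom) and `angle` (degrees, `NA` in the fallback).
#' @export
find_hbonds <- function(structure, distance_cutoff = 3.5, angle_cutoff = 120,
                        chains = NULL) {
  at <- structure$atoms
  xyz <- structure$xyz
  keep <- if (is.null(chains)) rep(TRUE, nrow(at)) else at$chain %in% chains
  hyd <- which(keep & at$elesy %in% c("H", "D"))
  don_heavy <- which(keep & at$elesy %in% c("N", "O", "S"))
  acc <- which(keep & at$elesy %in% c("N", "O"))
  sel_str <- function(i) paste(at$chain[i], at$resno[i], at$elety[i], sep = "/")
  res_key <- paste(at$chain, at$resno)

  out <- list()
  if (length(hyd) > 0) {
    for (h in hyd) {
      dv <- sweep(xyz[don_heavy, , drop = FALSE], 2, xyz[h, ])
      dh <- sqrt(rowSums(dv * dv))
      cand <- don_heavy[dh <= 1.3]
      if (length(cand) == 0) next
      d <- cand[which.min(dh[dh <= 1.3])]
      for (a in acc) {
        if (a == d || res_key[a] == res_key[d]) next
        dist_da <- sqrt(sum((xyz[d, ] - xyz[a, ])^2))
        if (dist_da > distance_cutoff) next
        v1 <- xyz[d, ] - xyz[h, ]
        v2 <- xyz[a, ] - xyz[h, ]
        ang <- acos(pmin(pmax(sum(v1 * v2) /
                                (sqrt(sum(v1^2)) * sqrt(sum(v2^2))), -1), 1)) *
          180 / pi
        if (ang < angle_cutoff) next
        out[[length(out) + 1]] <- data.frame(
          donor = sel_str(d), hydrogen = sel_str(h), acceptor = sel_str(a),
          distance = dist_da, angle = ang)
      }
    }
  } else {
    for (d in don_heavy) {
      for (a in acc) {
        if (a == d || res_key[a] == res_key[d]) next
        dist_da <- sqrt(sum((xyz[d, ] - xyz[a, ])^2))
        if (dist_da > distance_cutoff) next
        out[[length(out) + 1]] <- data.frame(
          donor = sel_str(d), hydrogen = NA_character_,
          acceptor = sel_str(a), distance = dist_da, angle = NA_real_)
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(donor = character(), hydrogen = character(),
                      acceptor = character(), distance = numeric(),
                      angle = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
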