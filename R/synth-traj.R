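# Lattice geometry of the toy protein: residues laid out on a serpentine
# grid (8 per row), 4.6 A between consecutive residues along a row, 4.2 A
# between rows, chains stacked 6 A apart in z. Each residue carries N, CA,
# C, O and CB pseudo-atoms spaced >= 1.5 A. The geometry is a compact
# lattice rather than a beta-sandwich: the contact statistics that Q and
# PLS-FMA consume depend only on contact topology, not on fold class.
TOY_ROW_LENGTH <- 8L
TOY_CA_SPACING <- 4.6
TOY_ROW_SPACING <- 4.2
TOY_CHAIN_SPACING <- 6.0

toy_chain_atoms <- function(n_res, chain, z0) {
  out <- vector("list", n_res)
  for (i in seq_len(n_res) - 1L) {
    r <- i %/% TOY_ROW_LENGTH
    cc <- i %% TOY_ROW_LENGTH
    if (r %% 2 == 1) cc <- TOY_ROW_LENGTH - 1L - cc     # serpentine fold-back
    ca <- c(cc * TOY_CA_SPACING, r * TOY_ROW_SPACING, z0)
    dirx <- if (r %% 2 == 0) 1 else -1
    pos <- rbind(N  = ca + c(-1.5 * dirx, 0, 0),
                 CA = ca,
                 C  = ca + c(1.5 * dirx, 0, 0),
                 O  = ca + c(1.5 * dirx, 0, 1.5),
                 CB = ca + c(0, 0, -1.6))
    out[[i + 1L]] <- data.frame(elety = rownames(pos), resid = "ALA",
                                chain = chain, resno = i + 1L,
                                x = pos[, 1], y = pos[, 2], z = pos[, 3],
                                stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Generate a compact toy oligomer
#'
#' Builds a synthetic multi-chain structure for validating the
#' native-contact, mode-analysis and geometry machinery without any
#' external structure download. Each chain is a compact serpentine lattice
#' of five-atom residues; chains are stacked so that every adjacent pair
#' shares an interface with contacts at the 4.5 Angstrom criterion. For
#' four chains, A-B is a monomer-monomer style interface and B-C a
#' dimer-dimer style one. Residues are labelled in eight sequential strand
#' analogues A-H per chain.
#'
#' The lattice is deterministic; `seed` is accepted for interface
#' consistency with the trajectory generators.
#'
#' @param n_chains Number of chains: 1 (monomer), 2 (dimer) or 4 (tetramer).
#' @param residues_per_chain Residues per chain (>= 8; default 24).
#' @param seed Unused by the deterministic lattice; kept for API symmetry.
#' @return An object of class `toy_protein` (a `protein_structure` with a
#'   `$regions` table mapping residues to strand labels).
#' @examples
#' toy <- make_toy_oligomer(4)
#' toy$regions[toy$regions$strand %in% c("C", "D"), ]
#' @export
make_toy_oligomer <- function(n_chains = 4, residues_per_chain = 24,
                              seed = 1) {
  if (!n_chains %in% c(1, 2, 4)) stop("n_chains must be 1, 2 or 4")
  if (residues_per_chain < 8) stop("residues_per_chain must be >= 8")
  atoms <- do.call(rbind, lapply(seq_len(n_chains), function(k)
    toy_chain_atoms(residues_per_chain, LETTERS[k],
                    (k - 1) * TOY_CHAIN_SPACING)))
  rownames(atoms) <- NULL
  ps <- protein_structure(atoms)
  n_str <- 8L
  per <- ceiling(residues_per_chain / n_str)
  strand <- LETTERS[pmin((seq_len(residues_per_chain) - 1L) %/% per + 1L,
                         n_str)]
  ps$regions <- data.frame(resno = seq_len(residues_per_chain),
                           strand = strand)
  class(ps) <- c("toy_protein", class(ps))
  ps
}

#' Default unfolding region: the CD-region analogue
#'
#' Residues of the strand-C/strand-D analogue plus the adjoining turn
#' (residues 7 to 14 of a 24-residue chain), mirroring the TTR region where
#' unfolding is proposed to initiate.
#'
#' @param toy A `toy_protein`.
#' @return Integer residue numbers.
#' @export
cd_region <- function(toy) {
  cd <- toy$regions$resno[toy$regions$strand %in% c("C", "D")]
  cd <- sort(unique(c(cd, max(cd) + 1L, max(cd) + 2L)))
  cd[cd <= max(toy$regions$resno)]
}

# Per-residue unfolding directions: dominated by the "escape" normal of the
# chain slab (z, signed away from the rest of the structure), with a small
# seeded random tilt so trajectories differ between seeds.
peel_directions <- function(structure, chain, region_res, tilt_sd) {
  at <- structure$atoms
  ch_sel <- at$chain == chain
  nu_sign <- if (mean(structure$xyz[ch_sel, 3]) <= mean(structure$xyz[, 3]))
    -1 else 1
  n <- length(region_res)
  tilt <- matrix(stats::rnorm(n * 2, sd = tilt_sd), n, 2)
  dirs <- t(vapply(seq_len(n), function(j) {
    v <- c(tilt[j, 1], tilt[j, 2], nu_sign)
    v / sqrt(sum(v^2))
  }, numeric(3)))
  dirs
}

smootherstep <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  x * x * (3 - 2 * x)
}

#' Generate a synthetic unfolding trajectory
#'
#' Produces a trajectory in which the residues of a chosen region peel away
#' from the structure while everything else only jitters thermally
#' (0.2 Angstrom). The region residues unfold sequentially: each residue
#' follows its own displacement window (50 percent overlap between
#' successive residues), moving along a randomised escape direction out of
#' the chain slab up to the schedule's maximum amplitude, so that
#' region-associated native contacts are lost progressively and the
#' region's block-averaged Q decreases monotonically.
#'
#' @param toy A `toy_protein` from [make_toy_oligomer()].
#' @param region Residue numbers to unfold; default [cd_region()], the
#'   C/D-strand analogue.
#' @param n_frames Number of frames (default 1000).
#' @param noise_schedule Non-decreasing displacement amplitudes in
#'   Angstrom, one per frame; default a linear ramp from 0 to 8.
#' @param seed Integer seed; identical seeds give identical trajectories.
#' @param chain Chain carrying the unfolding region (default `"A"`).
#' @param window_frac Fraction of the amplitude range over which each
#'   residue completes its displacement (default 0.5).
#' @param tilt_sd Spread of the random tilt applied to each residue's
#'   escape direction (default 0.12).
#' @param jitter Thermal jitter standard deviation in Angstrom applied to
#'   every atom in every frame (default 0.2, well below the
#'   contact-breaking scale set by the Q sigmoid midpoint).
#' @return A `coord_trajectory` with the toy structure as reference.
#' @export
make_unfolding_trajectory <- function(toy, region = NULL, n_frames = 1000,
                                      noise_schedule = NULL, seed = 1,
                                      chain = "A", window_frac = 0.5,
                                      tilt_sd = 0.12, jitter = 0.2) {
  if (is.null(region)) region <- cd_region(toy)
  at <- toy$atoms
  if (!chain %in% at$chain) stop("unknown chain id: ", chain)
  present <- unique(at$resno[at$chain == chain])
  if (!all(region %in% present))
    stop("region residues not in structure: ",
         paste(setdiff(region, present), collapse = ", "))
  if (is.null(noise_schedule))
    noise_schedule <- seq(0, 8, length.out = n_frames)
  if (length(noise_schedule) != n_frames)
    stop("noise_schedule must have one amplitude per frame")
  if (is.unsorted(noise_schedule))
    stop("noise_schedule amplitudes must be non-decreasing")

  set.seed(seed)
  region <- sort(region)
  dirs <- peel_directions(toy, chain, region, tilt_sd)
  smax <- max(noise_schedule)
  n_reg <- length(region)
  # staggered displacement windows in amplitude units
  if (smax > 0) {
    wid <- smax * window_frac
    theta <- (seq_len(n_reg) - 1) / max(1, n_reg - 1) * (smax - wid)
  }
  atom_rows <- lapply(region, function(rn)
    which(at$chain == chain & at$resno == rn))

  n_at <- nrow(at)
  xyz0 <- toy$xyz
  frames <- matrix(0, n_frames, 3 * n_at)
  for (f in seq_len(n_frames)) {
    fr <- xyz0 + matrix(stats::rnorm(n_at * 3, sd = jitter), ncol = 3)
    if (smax > 0) {
      for (j in seq_len(n_reg)) {
        dj <- smax * smootherstep((noise_schedule[f] - theta[j]) / wid)
        if (dj > 0) {
          rows <- atom_rows[[j]]
          fr[rows, ] <- fr[rows, ] +
            rep(dj * dirs[j, ], each = length(rows))
        }
      }
    }
    frames[f, ] <- as.vector(t(fr))
  }
  coord_trajectory(toy, frames)
}

#' Generate matched unfolding trajectories across oligomeric contexts
#'
#' Builds three trajectories of the same chain-A region unfolding in three
#' contexts -- monomer (chain A alone), dimer (chains A and B) and tetramer
#' (all four chains) -- with non-increasing displacement amplitudes from
#' monomer to tetramer. This emulates the observed ordering in which a
#' monomer in solution unfolds faster than a monomer inside a dimer, which
#' in turn unfolds faster than one inside a tetramer.
#'
#' @param toy A 4-chain `toy_protein`.
#' @param schedules Named list of per-context amplitude schedules
#'   (`monomer`, `dimer`, `tetramer`), each one value per frame; defaults
#'   are linear ramps to 8, 5.5 and 3.5 Angstrom.
#' @param n_frames Frames per trajectory (default 600).
#' @param seed Integer seed.
#' @param region Residues to unfold; default [cd_region()].
#' @return Named list of three `coord_trajectory` objects.
#' @export
make_hierarchy_series <- function(toy, schedules = NULL, n_frames = 600,
                                  seed = 1, region = NULL) {
  if (length(unique(toy$atoms$chain)) < 4)
    stop("toy must be a 4-chain oligomer")
  if (is.null(schedules))
    schedules <- list(monomer = seq(0, 8, length.out = n_frames),
                      dimer = seq(0, 5.5, length.out = n_frames),
                      tetramer = seq(0, 3.5, length.out = n_frames))
  need <- c("monomer", "dimer", "tetramer")
  if (!all(need %in% names(schedules)))
    stop("schedules must be named monomer, dimer, tetramer")
  amp <- vapply(schedules[need], max, 0)
  if (!(amp["monomer"] >= amp["dimer"] && amp["dimer"] >= amp["tetramer"]))
    stop("schedule amplitudes must be ordered monomer >= dimer >= tetramer")
  contexts <- list(monomer = "A", dimer = c("A", "B"),
                   tetramer = c("A", "B", "C", "D"))
  out <- lapply(need, function(ctx) {
    st <- subset_chains(toy, contexts[[ctx]])
    make_unfolding_trajectory(st, region = region,
                              n_frames = length(schedules[[ctx]]),
                              noise_schedule = schedules[[ctx]],
                              seed = seed, chain = "A")
  })
  names(out) <- need
  out
}
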