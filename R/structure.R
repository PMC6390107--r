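#' Protein structure and trajectory containers
#'
#' `protein_structure` holds an atom table (`eleno`, `elety`, `resid`,
#' `chain`, `resno`, `o`, `b`, `elesy`) and an `n x 3` coordinate matrix in
#' Angstrom. `coord_trajectory` pairs a reference `protein_structure` with a
#' frames-by-3N coordinate matrix (bio3d xyz layout: x1, y1, z1, x2, ...).
#'
#' @param atoms Data frame with at least `elety`, `resno`, `chain` and
#'   coordinates `x`, `y`, `z` (or supply `xyz`).
#' @param xyz Optional `n x 3` coordinate matrix overriding `x`,`y`,`z`.
#' @return An object of class `protein_structure`.
#' @export
protein_structure <- function(atoms, xyz = NULL) {
  if (is.null(xyz)) {
    if (!all(c("x", "y", "z") %in% names(atoms)))
      stop("atoms must have x, y, z columns (or pass xyz)")
    xyz <- as.matrix(atoms[, c("x", "y", "z")])
  }
  xyz <- unname(as.matrix(xyz))
  if (ncol(xyz) != 3 || nrow(xyz) != nrow(atoms))
    stop("xyz must be an n x 3 matrix matching atoms")
  need <- c("elety", "resno", "chain")
  if (!all(need %in% names(atoms)))
    stop("atoms must have columns: ", paste(need, collapse = ", "))
  atoms <- as.data.frame(atoms)
  if (is.null(atoms$eleno)) atoms$eleno <- seq_len(nrow(atoms))
  if (is.null(atoms$resid)) atoms$resid <- "ALA"
  if (is.null(atoms$o)) atoms$o <- 1
  if (is.null(atoms$b)) atoms$b <- 0
  if (is.null(atoms$alt)) atoms$alt <- ""
  if (is.null(atoms$elesy)) atoms$elesy <- guess_element(atoms$elety)
  atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  structure(list(atoms = atoms, xyz = xyz), class = "protein_structure")
}

#' @export
print.protein_structure <- function(x, ...) {
  cat("protein_structure:", nrow(x$atoms), "atoms,",
      length(unique(paste(x$atoms$chain, x$atoms$resno))), "residues,",
      "chains:", paste(unique(x$atoms$chain), collapse = " "), "\n")
  invisible(x)
}

# Infer the element from an atom name: strip digits/primes, deuterium names
# start with D (possibly after a leading digit), hydrogens with H.
guess_element <- function(elety) {
  s <- gsub("[0-9']", "", toupper(trimws(elety)))
  first <- substr(s, 1, 1)
  ifelse(first %in% c("H", "D"), first, first)
}

#' Is an atom a heavy (non-hydrogen, non-deuterium) atom?
#' @param structure A `protein_structure`.
#' @return Logical vector over atoms.
#' @export
is_heavy_atom <- function(structure) {
  !(structure$atoms$elesy %in% c("H", "D"))
}

#' Read a structure from PDB or mmCIF
#'
#' PDB files are parsed with `bio3d::read.pdb`; mmCIF files with a minimal
#' built-in `atom_site` reader. With `multi = TRUE` a multi-model PDB is
#' returned as a `coord_trajectory`.
#'
#' @param file Path to a `.pdb`/`.ent` or `.cif` file.
#' @param multi Read all MODELs of a PDB file as trajectory frames.
#' @return A `protein_structure`, or a `coord_trajectory` if `multi = TRUE`.
#' @export
read_structure <- function(file, multi = FALSE) {
  ext <- tolower(tools::file_ext(file))
  if (ext == "cif") {
    if (multi) stop("multi-model reading is supported for PDB input only")
    return(read_mmcif(file))
  }
  pdb <- bio3d::read.pdb(file, multi = multi, verbose = FALSE)
  at <- pdb$atom
  atoms <- data.frame(
    eleno = at$eleno, elety = at$elety, resid = at$resid, chain = at$chain,
    resno = at$resno, o = ifelse(is.na(at$o), 1, at$o),
    b = ifelse(is.na(at$b), 0, at$b),
    alt = ifelse(is.na(at$alt), "", at$alt),
    elesy = ifelse(is.na(at$elesy) | at$elesy == "", guess_element(at$elety),
                   trimws(at$elesy)),
    stringsAsFactors = FALSE
  )
  xyz1 <- matrix(pdb$xyz[1, ], ncol = 3, byrow = TRUE)
  ref <- protein_structure(atoms, xyz = xyz1)
  if (multi && nrow(pdb$xyz) > 1)
    return(coord_trajectory(ref, unclass(pdb$xyz)))
  ref
}

# Minimal mmCIF atom_site reader (no installed R package parses mmCIF).
# Handles the standard loop_ layout with whitespace-separated values.
read_mmcif <- function(file) {
  lines <- readLines(file)
  i <- grep("^\\s*loop_\\s*$", lines)
  start <- NA
  for (j in i) {
    if (j < length(lines) && grepl("^_atom_site\\.", trimws(lines[j + 1]))) {
      start <- j + 1; break
    }
  }
  if (is.na(start)) stop("no _atom_site loop found in ", file)
  cols <- character(0)
  k <- start
  while (k <= length(lines) && grepl("^_atom_site\\.", trimws(lines[k]))) {
    cols <- c(cols, sub("^_atom_site\\.", "", trimws(lines[k])))
    k <- k + 1
  }
  rows <- list()
  while (k <= length(lines)) {
    ln <- trimws(lines[k])
    if (ln == "" || grepl("^(#|loop_|_)", ln)) break
    rows[[length(rows) + 1]] <- scan(text = ln, what = character(),
                                     quiet = TRUE)
    k <- k + 1
  }
  m <- do.call(rbind, rows)
  colnames(m) <- cols[seq_len(ncol(m))]
  g <- function(nm, alt = NULL, default = NA) {
    if (nm %in% colnames(m)) m[, nm]
    else if (!is.null(alt) && alt %in% colnames(m)) m[, alt]
    else rep(default, nrow(m))
  }
  keep <- g("group_PDB", default = "ATOM") %in% c("ATOM", "HETATM")
  m <- m[keep, , drop = FALSE]
  num <- function(x) suppressWarnings(as.numeric(x))
  atoms <- data.frame(
    eleno = num(g("id", default = NA)),
    elety = g("auth_atom_id", "label_atom_id"),
    resid = g("auth_comp_id", "label_comp_id"),
    chain = g("auth_asym_id", "label_asym_id"),
    resno = num(g("auth_seq_id", "label_seq_id")),
    o = ifelse(is.na(num(g("occupancy"))), 1, num(g("occupancy"))),
    b = ifelse(is.na(num(g("B_iso_or_equiv"))), 0, num(g("B_iso_or_equiv"))),
    alt = ifelse(g("label_alt_id", default = ".") %in% c(".", "?"), "",
                 g("label_alt_id", default = ".")),
    elesy = g("type_symbol"),
    stringsAsFactors = FALSE
  )
  if (anyNA(atoms$eleno)) atoms$eleno <- seq_len(nrow(atoms))
  atoms$elesy <- ifelse(is.na(atoms$elesy) | atoms$elesy %in% c(".", "?"),
                        guess_element(atoms$elety), atoms$elesy)
  xyz <- cbind(num(g("Cartn_x")), num(g("Cartn_y")), num(g("Cartn_z")))
  protein_structure(atoms, xyz = xyz)
}

#' Write a structure or trajectory to PDB
#'
#' @param x A `protein_structure` or `coord_trajectory` (written as a
#'   multi-model PDB).
#' @param file Output path.
#' @param b Optional per-atom B-factor column to write.
#' @return `file`, invisibly.
#' @export
write_structure <- function(x, file, b = NULL) {
  if (inherits(x, "coord_trajectory")) {
    ref <- x$ref
    xyz <- x$xyz
  } else {
    ref <- x
    xyz <- matrix(as.vector(t(x$xyz)), nrow = 1)
  }
  at <- ref$atoms
  bio3d::write.pdb(file = file, xyz = xyz, resno = at$resno, resid = at$resid,
                   eleno = at$eleno, elety = at$elety, chain = at$chain,
                   o = at$o, b = if (is.null(b)) at$b else b)
  invisible(file)
}

#' @rdname protein_structure
#' @param ref Reference `protein_structure`.
#' @param frames Frames-by-3N coordinate matrix (or a single frame vector).
#' @export
coord_trajectory <- function(ref, frames) {
  if (!inherits(ref, "protein_structure")) stop("ref must be a protein_structure")
  if (is.null(dim(frames))) frames <- matrix(frames, nrow = 1)
  frames <- unname(as.matrix(frames))
  if (ncol(frames) != 3 * nrow(ref$atoms))
    stop("frame width ", ncol(frames), " does not match 3 x ",
         nrow(ref$atoms), " atoms")
  structure(list(ref = ref, xyz = frames), class = "coord_trajectory")
}

#' @export
print.coord_trajectory <- function(x, ...) {
  cat("coord_trajectory:", nrow(x$xyz), "frames x", nrow(x$ref$atoms),
      "atoms\n")
  invisible(x)
}

# Frame f of a trajectory as an n x 3 matrix.
frame_coords <- function(traj, f) {
  matrix(traj$xyz[f, ], ncol = 3, byrow = TRUE)
}

#' Read and write flat per-frame coordinate tables
#'
#' CSV interchange format for trajectories: columns `frame`, `atom`, `x`,
#' `y`, `z` with `atom` indexing the reference structure's atom order.
#'
#' @param traj A `coord_trajectory`.
#' @param file CSV path.
#' @param ref Reference `protein_structure` for `read_coord_table`.
#' @return `read_coord_table` returns a `coord_trajectory`.
#' @export
write_coord_table <- function(traj, file) {
  n_at <- nrow(traj$ref$atoms)
  n_fr <- nrow(traj$xyz)
  co <- matrix(t(traj$xyz), ncol = 3, byrow = TRUE)
  df <- data.frame(frame = rep(seq_len(n_fr), each = n_at),
                   atom = rep(seq_len(n_at), times = n_fr),
                   x = co[, 1], y = co[, 2], z = co[, 3])
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_coord_table
#' @export
read_coord_table <- function(file, ref) {
  df <- utils::read.csv(file)
  need <- c("frame", "atom", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("coordinate table must have columns: ", paste(need, collapse = ", "))
  frames <- sort(unique(df$frame))
  n_at <- nrow(ref$atoms)
  xyz <- matrix(NA_real_, length(frames), 3 * n_at)
  fi <- match(df$frame, frames)
  for (d in 1:3)
    xyz[cbind(fi, 3 * (df$atom - 1) + d)] <- df[[c("x", "y", "z")[d]]]
  if (anyNA(xyz)) stop("coordinate table does not cover all atoms per frame")
  coord_trajectory(ref, xyz)
}

#' Subset a structure by chain
#'
#' @param structure A `protein_structure` (or `toy_protein`).
#' @param chains Character vector of chain identifiers to keep.
#' @return A structure of the same class restricted to the chains.
#' @export
subset_chains <- function(structure, chains) {
  unknown <- setdiff(chains, unique(structure$atoms$chain))
  if (length(unknown) > 0)
    stop("unknown chain id(s): ", paste(unknown, collapse = ", "))
  sel <- structure$atoms$chain %in% chains
  out <- protein_structure(structure$atoms[sel, , drop = FALSE],
                           xyz = structure$xyz[sel, , drop = FALSE])
  if (inherits(structure, "toy_protein")) {
    out$regions <- structure$regions
    class(out) <- c("toy_protein", class(out))
  }
  out
}

#' Indices of main-chain atoms
#'
#' Main chain is defined as the N, CA, C and O atoms.
#'
#' @param structure A `protein_structure`.
#' @param chains Optional chain subset.
#' @return Integer atom indices.
#' @export
mainchain_indices <- function(structure, chains = NULL) {
  sel <- structure$atoms$elety %in% c("N", "CA", "C", "O")
  if (!is.null(chains)) sel <- sel & structure$atoms$chain %in% chains
  which(sel)
}
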