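# Synthetic structure fixtures built in code. The CD-loop models are
# synthetic stand-ins posed at the geometry reported for the deposited
# neutron structures (they are not the deposited coordinates).

# Synthetic CD-loop stand-in, wild-type-like: Ser52's amide deuteron and
# side-chain hydroxyl both donate to the Ser50 O-gamma, and the Ser50
# CA - Ser52 N distance is 4.2 A.
make_cdloop_wt <- function() {
  atoms <- rbind(
    data.frame(elety = c("N", "CA", "C", "O", "CB", "OG"),
               resid = "SER", chain = "A", resno = 50,
               x = c(-1.45, 0, 1.5, 2.6, -0.5, 0),
               y = c(0, 0, 0, 0.2, 1.2, 2.2),
               z = c(0, 0, 0, -1.0, 1.1, 0)),
    data.frame(elety = c("N", "D", "CA", "C", "O"),
               resid = "ALA", chain = "A", resno = 51,
               x = c(6.0, 6.2, 7.2, 8.6, 9.2),
               y = c(0.5, 1.4, 1.0, 0.6, 1.4),
               z = c(-2.5, -2.6, -3.0, -2.6, -2.0)),
    data.frame(elety = c("N", "D", "CA", "C", "O", "CB", "OG", "DG"),
               resid = "SER", chain = "A", resno = 52,
               x = c(2.872, 1.915, 3.6, 5.0, 5.6, 3.8, 2.4, 1.690),
               y = c(3.064, 2.776, 4.2, 4.0, 5.0, 5.0, 3.5, 3.115),
               z = c(0, 0, 0.5, 0.5, 0.6, 1.8, 2.0, 1.408))
  )
  protein_structure(atoms)
}

# Synthetic CD-loop stand-in, S52P-like: proline at 52 (no amide H, no
# hydroxyl) and the Ser50 CA - Pro52 N distance widened to 4.6 A.
make_cdloop_s52p <- function() {
  n52 <- c(2.872, 3.064, 0) * 4.6 / 4.2
  atoms <- rbind(
    data.frame(elety = c("N", "CA", "C", "O", "CB", "OG"),
               resid = "SER", chain = "A", resno = 50,
               x = c(-1.45, 0, 1.5, 2.6, -0.5, 0),
               y = c(0, 0, 0, 0.2, 1.2, 2.2),
               z = c(0, 0, 0, -1.0, 1.1, 0)),
    data.frame(elety = c("N", "D", "CA", "C", "O"),
               resid = "ALA", chain = "A", resno = 51,
               x = c(6.0, 6.2, 7.2, 8.6, 9.2),
               y = c(0.5, 1.4, 1.0, 0.6, 1.4),
               z = c(-2.5, -2.6, -3.0, -2.6, -2.0)),
    data.frame(elety = c("N", "CA", "C", "O", "CB", "CG", "CD"),
               resid = "PRO", chain = "A", resno = 52,
               x = c(n52[1], 4.0, 5.4, 6.0, 4.2, 3.9, 3.2),
               y = c(n52[2], 4.4, 4.2, 5.2, 5.4, 4.9, 3.7),
               z = c(n52[3], 0.5, 0.5, 0.6, 1.8, 3.2, 3.4))
  )
  protein_structure(atoms)
}

# Toy donor-hydrogen-acceptor triple with prescribed geometry: N-H along x,
# acceptor O at the given donor-acceptor distance and donor-H-acceptor angle.
make_hbond_toy <- function(d_da = 2.9, angle_dha = 175) {
  h <- c(1.0, 0, 0)
  # N at origin, H at (1,0,0); place A in the xy-plane at angle angle_dha
  # from H->N, with |HA| solved from the law of cosines so |NA| = d_da
  cosA <- cos(angle_dha * pi / 180)
  ha <- cosA + sqrt(cosA^2 - 1 + d_da^2)
  a <- h + ha * c(cos(pi - angle_dha * pi / 180),
                  sin(pi - angle_dha * pi / 180), 0)
  atoms <- rbind(
    data.frame(elety = c("N", "H", "CA"), resid = "GLY", chain = "A",
               resno = 1,
               x = c(0, h[1], -1.0), y = c(0, h[2], -1.1), z = c(0, h[3], 0)),
    data.frame(elety = c("O", "C"), resid = "GLY", chain = "A", resno = 5,
               x = c(a[1], a[1] + 1.3), y = c(a[2], a[2] + 0.4),
               z = c(a[3], a[3]))
  )
  protein_structure(atoms)
}

# Random compact 20-residue single-chain structure for brute-force oracles.
make_random_blob <- function(n_res = 20, seed = 7) {
  set.seed(seed)
  # random walk of CA positions with ~3.8 A steps, plus O and CB offsets
  ca <- matrix(0, n_res, 3)
  for (i in 2:n_res) {
    repeat {
      step <- stats::rnorm(3)
      step <- 3.8 * step / sqrt(sum(step^2))
      cand <- ca[i - 1, ] + step
      if (i < 3 || min(sqrt(rowSums(sweep(ca[1:(i - 2), , drop = FALSE], 2,
                                          cand)^2))) > 3.0) break
    }
    ca[i, ] <- cand
  }
  atoms <- do.call(rbind, lapply(seq_len(n_res), function(i) {
    data.frame(elety = c("CA", "O", "CB"), resid = "ALA", chain = "A",
               resno = i,
               x = ca[i, 1] + c(0, 0.9, -0.9),
               y = ca[i, 2] + c(0, 0.9, 0.4),
               z = ca[i, 3] + c(0, -0.7, 0.9))
  }))
  protein_structure(atoms)
}

# Independent brute-force contact enumeration (double loop).
brute_contacts <- function(structure, mode, cutoff = 4.5, min_sep = 3,
                           chain_pair = NULL) {
  at <- structure$atoms
  xyz <- structure$xyz
  heavy <- which(!(at$elesy %in% c("H", "D")))
  out <- NULL
  for (a in heavy) for (b in heavy) {
    if (a >= b) next
    d <- sqrt(sum((xyz[a, ] - xyz[b, ])^2))
    if (d > cutoff) next
    ok <- if (mode == "fold") {
      at$chain[a] == at$chain[b] && abs(at$resno[a] - at$resno[b]) >= min_sep + 1
    } else {
      diff <- at$chain[a] != at$chain[b]
      if (!is.null(chain_pair))
        diff && setequal(c(at$chain[a], at$chain[b]), chain_pair)
      else diff
    }
    if (ok) out <- rbind(out, data.frame(i = a, j = b, r0 = d))
  }
  out
}

# Independent brute-force Q (naive loop).
brute_q <- function(coords, contacts, beta = 5, lambda = 1.8) {
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 3, byrow = TRUE)
  s <- 0
  for (r in seq_len(nrow(contacts))) {
    d <- sqrt(sum((coords[contacts$i[r], ] - coords[contacts$j[r], ])^2))
    s <- s + 1 / (1 + exp(beta * (d - lambda * contacts$r0[r])))
  }
  s / nrow(contacts)
}

# Independent Kabsch superposition (SVD) of mobile onto fixed.
kabsch_fit <- function(fixed, mobile) {
  cf <- colMeans(fixed); cm <- colMeans(mobile)
  A <- sweep(mobile, 2, cm); B <- sweep(fixed, 2, cf)
  s <- svd(t(A) %*% B)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sweep(A %*% t(R), 2, cf, FUN = "+")
}

# RMSD between two xyz frames given as vectors or n x 3 matrices.
frame_rmsd_test <- function(a, b) {
  if (is.null(dim(a))) a <- matrix(a, ncol = 3, byrow = TRUE)
  if (is.null(dim(b))) b <- matrix(b, ncol = 3, byrow = TRUE)
  sqrt(mean(rowSums((a - b)^2)))
}

# Rigid rotation + translation applied to an n x 3 coordinate matrix.
rigid_transform <- function(coords, angles = c(0.4, -0.8, 1.1),
                            shift = c(5, -3, 8)) {
  rx <- function(a) matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)),
                           3, 3, byrow = TRUE)
  rz <- function(a) matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1),
                           3, 3, byrow = TRUE)
  R <- rz(angles[3]) %*% rx(angles[1]) %*% rz(angles[2])
  sweep(coords %*% t(R), 2, shift, FUN = "+")
}
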