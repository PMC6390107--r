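test_that("frame superposition removes rigid-body motion exactly", {
  toy <- make_toy_oligomer(1)
  ref_vec <- as.vector(t(toy$xyz))
  moved <- rigid_transform(toy$xyz)
  traj <- coord_trajectory(toy, rbind(ref_vec, as.vector(t(moved))))
  fitted <- align_frames(traj)
  expect_lt(frame_rmsd_test(fitted$xyz[2, ], ref_vec), 1e-6)
  # an already-aligned trajectory passes through unchanged
  again <- align_frames(fitted)
  expect_lt(max(abs(again$xyz - fitted$xyz)), 1e-8)
})

test_that("superposition is optimal against an independent Kabsch oracle", {
  set.seed(6)
  coil <- matrix(stats::rnorm(3 * 40, sd = 6), ncol = 3)
  atoms <- data.frame(elety = "CA", resid = "GLY", chain = "A",
                      resno = seq_len(40), x = coil[, 1], y = coil[, 2],
                      z = coil[, 3])
  ps <- protein_structure(atoms)
  frame <- rigid_transform(coil, angles = c(1.2, 0.3, -0.7),
                           shift = c(-4, 9, 2)) +
    matrix(stats::rnorm(120, sd = 0.5), ncol = 3)
  traj <- coord_trajectory(ps, as.vector(t(frame)))
  fitted <- align_frames(traj, selection = seq_len(40))
  oracle <- kabsch_fit(coil, frame)
  got <- matrix(fitted$xyz[1, ], ncol = 3, byrow = TRUE)
  expect_equal(got, oracle, tolerance = 1e-8)
  # degenerate (collinear) selections are rejected
  line <- protein_structure(data.frame(elety = "CA", resid = "GLY",
                                       chain = "A", resno = 1:5,
                                       x = 1:5, y = 0, z = 0))
  ltraj <- coord_trajectory(line, as.vector(t(line$xyz)))
  expect_error(align_frames(ltraj, selection = 1:5), "collinear")
})

test_that("a planted single-atom signal is recovered", {
  set.seed(1)
  n <- 500; n_at <- 40
  X <- matrix(stats::rnorm(n * 3 * n_at, sd = 0.5), n, 3 * n_at)
  y <- X[, 3 * 6 + 1] + stats::rnorm(n, sd = 0.02)  # x-coordinate of atom 7
  fma <- fit_fma(X, y, n_components = 20)
  expect_gte(fma$r_val, 0.99)
  amp <- mode_rmsf(fma, atom_map = data.frame(chain = "A",
                                              resno = seq_len(n_at)))
  expect_equal(amp$resno[1], 7)
  expect_gt(amp$amplitude[1]^2, 0.9)
})

test_that("a random property shows null validation correlation", {
  set.seed(2)
  X <- matrix(stats::rnorm(500 * 120, sd = 0.5), 500, 120)
  y <- stats::rnorm(500)
  fma <- fit_fma(X, y, n_components = 20)
  expect_lt(abs(fma$r_val), 0.3)
})

test_that("refitting with identical inputs is deterministic", {
  set.seed(3)
  X <- matrix(stats::rnorm(200 * 60), 200, 60)
  y <- X[, 5] + stats::rnorm(200, sd = 0.1)
  a <- fit_fma(X, y, n_components = 10, split = "random", seed = 17)
  b <- fit_fma(X, y, n_components = 10, split = "random", seed = 17)
  expect_identical(a$mode, b$mode)
  expect_identical(a$r_val, b$r_val)
})

test_that("training correlation never decreases with more components", {
  set.seed(4)
  X <- matrix(stats::rnorm(300 * 60), 300, 60)
  y <- X %*% stats::rnorm(60, sd = 0.3) + stats::rnorm(300, sd = 0.5)
  r <- vapply(c(2, 5, 10, 20), function(nc)
    fit_fma(X, as.vector(y), n_components = nc)$r_train, 0)
  expect_true(all(diff(r) >= -1e-10))
})

test_that("validation r is invariant under rigid-body motion of frames", {
  toy <- make_toy_oligomer(1)
  traj <- make_unfolding_trajectory(toy, n_frames = 200, seed = 5,
                                    noise_schedule = seq(0, 8,
                                                         length.out = 200))
  cs <- build_contacts(toy, "fold")
  q <- q_timeseries(traj, cs)$Q
  base <- fit_fma(traj, q, n_components = 10)
  wob <- traj
  set.seed(8)
  for (f in seq_len(nrow(wob$xyz))) {
    co <- matrix(wob$xyz[f, ], ncol = 3, byrow = TRUE)
    wob$xyz[f, ] <- as.vector(t(rigid_transform(
      co, angles = stats::rnorm(3, sd = 0.3), shift = stats::rnorm(3, sd = 4))))
  }
  moved <- fit_fma(wob, q, n_components = 10)
  expect_equal(moved$r_val, base$r_val, tolerance = 1e-6)
})

test_that("degenerate inputs are rejected", {
  X <- matrix(stats::rnorm(100 * 30), 100, 30)
  expect_error(fit_fma(X, rep(1, 100), n_components = 5), "constant")
  expect_error(fit_fma(X, stats::rnorm(100), n_components = 60), "2 x")
  expect_error(fit_fma(X, stats::rnorm(100), n_components = 5,
                       train_frac = 1.2), "train_frac")
})

test_that("mode amplitudes aggregate to residues with unit total", {
  # synthetic model: uniform mode over 12 atoms in 4 equal residues
  fm <- structure(list(mode = rep(1 / 6, 36),
                       feature_atoms = data.frame(
                         elety = "CA", resno = rep(1:4, each = 3),
                         chain = "A")),
                  class = "fma_model")
  amp <- mode_rmsf(fm)
  expect_equal(sum(amp$amplitude^2), 1, tolerance = 1e-12)
  expect_true(all(abs(amp$amplitude - amp$amplitude[1]) < 1e-12))
  # mode localised on one atom: only its residue is nonzero
  m <- rep(0, 36); m[14] <- 1
  fm2 <- structure(list(mode = m, feature_atoms = fm$feature_atoms),
                   class = "fma_model")
  amp2 <- mode_rmsf(fm2)
  expect_equal(amp2$resno[1], 2)
  expect_equal(amp2$amplitude[1], 1)
  expect_true(all(amp2$amplitude[-1] == 0))
  expect_error(mode_rmsf(structure(list(mode = m), class = "fma_model")),
               "atom map")
})

test_that("the mode localises on the perturbed region of an unfolding run", {
  toy <- make_toy_oligomer(4)
  traj <- make_unfolding_trajectory(toy, n_frames = 400, seed = 6,
                                    noise_schedule = seq(0, 8,
                                                         length.out = 400))
  cs <- build_contacts(toy, "fold", chain = "A")
  q <- q_timeseries(traj, cs)$Q
  fma <- fit_fma(traj, q, n_components = 20,
                 selection = mainchain_indices(toy, "A"))
  amp <- mode_rmsf(fma)
  region <- cd_region(toy)
  top <- amp[seq_len(length(region)), ]
  expect_true(all(top$resno %in% region))
  expect_gt(sum(amp$amplitude[amp$resno %in% region]^2), 0.8)
})
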