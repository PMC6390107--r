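# Closed-form equilibrium oracles used below:
# - full scrambling: tetramer composition is Binomial(4, 1/2) over D count
#   -> {6.25, 25, 37.5, 25, 6.25} percent for {4H, 3H1D, 2H2D, 1H3D, 4D}
# - frozen dimers (k_dim_diss = 0) from an equimolar 4H/4D start: random
#   pairing of intact HH/DD dimers -> {25, 0, 50, 0, 25} percent
binomial_equilibrium <- 100 * stats::dbinom(0:4, 4, 0.5)
dimer_pairing_equilibrium <- 100 * c(0.25, 0, 0.5, 0, 0.25)

abundance_matrix <- function(ts) {
  matrix(ts$abundance_pct, ncol = 5,
         dimnames = list(NULL, levels(ts$species)))
}

test_that("validation rejects negative rates and counts", {
  expect_error(rate_set(-0.1, 1, 1, 1), "rate")
  expect_error(rate_set(1, 1, 1, 1, isotope_factor = 0), "isotope_factor")
  expect_error(exchange_system(c("4H" = -5), rates = rate_set(1, 1, 1, 1)),
               "copy numbers")
  expect_error(exchange_system(c("5H" = 5), rates = rate_set(1, 1, 1, 1)),
               "species names")
})

test_that("with all rates zero the mixture stays exactly 50/50", {
  rs <- rate_set(0, 0, 0, 0)
  for (method in c("ode", "ssa")) {
    ts <- simulate_exchange(equimolar_mix(1e4, rs), t_grid = c(1, 5, 11),
                            method = method, seed = 3)
    ab <- abundance_matrix(ts)
    expect_equal(unname(ab[, "4H"]), rep(50, 3))
    expect_equal(unname(ab[, "4D"]), rep(50, 3))
    expect_equal(unname(ab[, "2H2D"]), rep(0, 3))
  }
})

test_that("monomer equivalents are conserved along both integrators", {
  rs <- rate_set(0.3, 5e-3, 0.8, 5e-3)
  sys <- equimolar_mix(2e4, rs)
  m0 <- monomer_equivalents(sys)
  ode <- simulate_exchange(sys, t_grid = c(0.5, 2, 7, 11))
  m_ode <- apply(attr(ode, "counts"), 1, monomer_equivalents)
  expect_equal(m_ode, rep(m0, 4), tolerance = 1e-8)
  ssa <- simulate_exchange(sys, t_grid = c(0.5, 2, 7, 11), method = "ssa",
                           seed = 11)
  m_ssa <- apply(attr(ssa, "counts"), 1, monomer_equivalents)
  expect_identical(m_ssa, rep(m0, 4))
})

test_that("long-time composition matches the binomial scrambling oracle", {
  rs <- rate_set(0.2, 1e-2, 0.5, 1e-2)
  ts <- simulate_exchange(equimolar_mix(1e5, rs), t_grid = 3000)
  expect_equal(ts$abundance_pct, binomial_equilibrium, tolerance = 1e-3)
  # any positive rate set reaches the same equilibrium
  rs2 <- rate_set(0.7, 4e-3, 1.5, 2e-2)
  ts2 <- simulate_exchange(equimolar_mix(1e5, rs2), t_grid = 3000)
  expect_equal(ts2$abundance_pct, binomial_equilibrium, tolerance = 1e-3)
})

test_that("frozen dimers reproduce the dimer-pairing oracle", {
  rs <- rate_set(0.5, 1e-2, 0, 1e-2)
  ts <- simulate_exchange(equimolar_mix(1e5, rs), t_grid = 2000)
  expect_equal(ts$abundance_pct, dimer_pairing_equilibrium, tolerance = 1e-3)
})

test_that("isotope_factor = 1 makes H and D relabelling a mirror symmetry", {
  rs <- rate_set(0.3, 1e-2, 0.6, 1e-2)
  a <- simulate_exchange(
    exchange_system(c("4H" = 7e4, "4D" = 3e4), rates = rs), t_grid = c(2, 8))
  b <- simulate_exchange(
    exchange_system(c("4H" = 3e4, "4D" = 7e4), rates = rs), t_grid = c(2, 8))
  ma <- abundance_matrix(a); mb <- abundance_matrix(b)
  mirror <- c("4H" = "4D", "3H1D" = "1H3D", "2H2D" = "2H2D",
              "1H3D" = "3H1D", "4D" = "4H")
  for (sp in names(mirror))
    expect_equal(unname(ma[, sp]), unname(mb[, mirror[[sp]]]),
                 tolerance = 1e-8)
})

test_that("stochastic runs are reproducible under a fixed seed", {
  rs <- rate_set(0.4, 1e-2, 0.8, 1e-2)
  sys <- equimolar_mix(5e3, rs)
  a <- simulate_exchange(sys, t_grid = 0:5, method = "ssa", seed = 99)
  b <- simulate_exchange(sys, t_grid = 0:5, method = "ssa", seed = 99)
  expect_identical(attr(a, "counts"), attr(b, "counts"))
  c <- simulate_exchange(sys, t_grid = 0:5, method = "ssa", seed = 100)
  expect_false(identical(attr(a, "counts"), attr(c, "counts")))
})

test_that("SSA replicate means agree with the ODE solution", {
  rs <- rate_set(0.25, 1e-2, 0.5, 1e-2)
  sys <- equimolar_mix(1e4, rs)
  grid <- c(1, 3, 6, 9, 11)
  ode <- abundance_matrix(simulate_exchange(sys, t_grid = grid))
  n_rep <- 200
  acc <- array(0, c(length(grid), 5, n_rep))
  for (r in seq_len(n_rep))
    acc[, , r] <- abundance_matrix(
      simulate_exchange(sys, t_grid = grid, method = "ssa", seed = 1e4 + r))
  mn <- apply(acc, c(1, 2), mean)
  mcse <- apply(acc, c(1, 2), stats::sd) / sqrt(n_rep)
  expect_true(all(abs(mn - ode) <= 3 * mcse + 1e-9))
})

test_that("peak-area rendering preserves proportions and is seeded", {
  rs <- rate_set(0.2, 1e-2, 0.5, 1e-2)
  ts <- simulate_exchange(equimolar_mix(1e5, rs), t_grid = c(1, 5, 11))
  expect_error(render_peak_areas(ts, charge_states = integer(0)), "non-empty")

  # noiseless, one charge state: proportions exactly equal the percentages
  p1 <- render_peak_areas(ts, charge_states = 14, noise_sd = 0)
  ra <- relative_abundance(p1, c(14, 14))
  expect_equal(ra$abundance_pct, ts$abundance_pct, tolerance = 1e-12)

  # noiseless, three charge states with uneven weights: species proportions
  # recovered after summing over charges
  p3 <- render_peak_areas(ts, charge_states = 13:15, weights = c(2, 5, 1),
                          noise_sd = 0)
  ra3 <- relative_abundance(p3, c(13, 15))
  expect_equal(ra3$abundance_pct, ts$abundance_pct, tolerance = 1e-12)

  # seeded noise is reproducible and truncated at zero
  n1 <- render_peak_areas(ts, noise_sd = 2, seed = 5)
  n2 <- render_peak_areas(ts, noise_sd = 2, seed = 5)
  expect_identical(n1, n2)
  expect_true(all(n1$area >= 0))
})

test_that("abundance CSV round trip preserves the series", {
  rs <- rate_set(0.2, 1e-2, 0.5, 1e-2)
  ts <- simulate_exchange(equimolar_mix(1e4, rs), t_grid = c(1, 5))
  f <- withr::local_tempfile(fileext = ".csv")
  write_abundance_csv(ts, f)
  back <- read_abundance_csv(f)
  expect_equal(back$abundance_pct, ts$abundance_pct, tolerance = 1e-9)
  expect_equal(as.character(back$species), as.character(ts$species))
})
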