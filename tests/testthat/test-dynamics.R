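test_that("a stretched harmonic dimer minimizes to the bond length", {
  s <- toy_dimer(1)
  for (method in c("cg_polak_ribiere", "steepest_descent")) {
    m <- minimize(s, bonded_potential(), method = method, tol = 1e-4,
                  max_iter = 2000)
    expect_equal(sqrt(sum((m$xyz[1, ] - m$xyz[2, ])^2)), 3.8, tolerance = 1e-3)
    info <- attr(m, "minimize_info")
    expect_identical(info$reason, "tol")
  }
})

test_that("an already-minimal structure is returned essentially unchanged", {
  s <- minimize(toy_dimer(1), bonded_potential(), tol = 1e-6, max_iter = 3000)
  m2 <- minimize(s, bonded_potential(), tol = 1e-4)
  expect_lte(attr(m2, "minimize_info")$iterations, 1)
  expect_equal(m2$xyz, s$xyz, tolerance = 1e-4)
})

test_that("minimization never increases the energy and reports its exit", {
  s <- toy_two_domain(seed = 12)
  s$xyz <- s$xyz + matrix(rnorm(nrow(s$xyz) * 3, sd = 0.3), ncol = 3)
  m <- minimize(s, potential_spec(), tol = 1e-3, max_iter = 400)
  info <- attr(m, "minimize_info")
  expect_true(all(diff(info$energies) <= 1e-9))     # monotone iterate audit
  expect_true(info$reason %in% c("tol", "max_iter"))
  expect_lte(info$energy, info$energies[1])
  # cross-check the reached minimum against an independent optimizer
  ctx <- cg_context(s, potential_spec())
  opt <- stats::optim(as.vector(s$xyz),
                      fn = function(x) demonmd:::.cg_energy_forces(
                        matrix(x, ncol = 3), ctx, FALSE)$total,
                      gr = function(x) -as.vector(demonmd:::.cg_energy_forces(
                        matrix(x, ncol = 3), ctx, TRUE)$forces),
                      method = "CG", control = list(type = 2, maxit = 400))
  expect_lt(info$energy, opt$value + 1.0)
})

test_that("Boltzmann draws satisfy equipartition with zero net momentum", {
  m <- rep(110, 1000)
  v <- boltzmann_velocities(m, 300, seed = 9)
  expect_lt(abs(demonmd:::.kinetic_T(v, m, ndf = 3000 - 3) - 300) / 300, 0.05)
  expect_lt(max(abs(colSums(v * m))), 1e-10)
  expect_identical(boltzmann_velocities(m, 300, seed = 9), v)
})

test_that("NVE integration conserves energy on the harmonic dimer", {
  s <- toy_dimer(1)
  v0 <- matrix(0, 2, 3)
  out <- integrate_md(s, v0, bonded_potential(),
                      cfg = md_config(dt = 5e-4, thermostat = "none",
                                      n_steps = 10000,
                                      com_removal_interval = 0,
                                      save_stride = 10))
  E <- out$diagnostics$pe + out$diagnostics$ke
  expect_lt((max(E) - min(E)) / abs(mean(E)), 1e-4)
})

test_that("the Berendsen thermostat holds the target temperature", {
  s <- minimize(toy_two_domain(seed = 3), potential_spec(), tol = 0.05,
                max_iter = 1500)
  set.seed(4)
  out <- integrate_md(s, boltzmann_velocities(s$atoms$mass, 10),
                      potential_spec(),
                      cfg = md_config(dt = 0.004, thermostat = "berendsen",
                                      tau = 0.5, T_target = 300,
                                      n_steps = 4000, save_stride = 10))
  Tl <- tail(out$diagnostics$temperature, 200)
  expect_lt(abs(mean(Tl) - 300) / 300, 0.05)
})

test_that("centre-of-mass motion removal zeroes the net momentum", {
  s <- toy_two_domain(seed = 3)
  v <- boltzmann_velocities(s$atoms$mass, 300, seed = 2)
  v <- v + 0.5                             # inject a drift
  out <- integrate_md(s, v, potential_spec(),
                      cfg = md_config(dt = 0.002, thermostat = "none",
                                      n_steps = 100,
                                      com_removal_interval = 100,
                                      save_stride = 0))
  p <- colSums(out$velocities * s$atoms$mass)
  expect_lt(max(abs(p)), 1e-8)
})

test_that("the staged equilibration ladder follows the published protocol", {
  s <- toy_two_domain(seed = 5)
  eq <- staged_equilibration(s, potential_spec(),
                             cfg = list(heat_steps = 100, min_iter = 60,
                                        ramp_steps = 120, seed = 1))
  led <- eq$ledger
  expect_equal(nrow(led), 6)
  expect_equal(led$kind, c("minimize", "heat_restrained", "minimize",
                           "heat_restrained", "minimize_restrained",
                           "ramp_unrestrained"))
  expect_equal(led$restraint_k[!is.na(led$restraint_k)], c(10, 5, 4))
  expect_equal(led$T_target[6], 310)       # ramp endpoint
})

test_that("the torsional/low-mode MC search honours its retention rules", {
  s <- minimize(toy_two_domain(seed = 8, n = 30, nflex = 12), potential_spec(),
                tol = 0.05, max_iter = 1000)
  cfg <- mc_search_config(n_steps = 30, seed = 42, min_iter = 50)
  out <- lowmode_mc_search(s, potential_spec(), cfg)
  e <- attr(out, "energies")
  expect_lte(length(out), cfg$n_saved)
  expect_true(all(e - min(e) <= 5.02 + 1e-9))
  expect_true(!is.unsorted(e))
  log <- attr(out, "log")
  lm <- log$magnitude[log$move == "lowmode"]
  expect_true(all(lm >= 3.0 & lm <= 7.5))
  # distinctness of retained conformers
  if (length(out) > 1) {
    for (a in 1:(length(out) - 1))
      for (b in (a + 1):length(out))
        expect_gt(demonmd:::.kabsch_rmsd(out[[a]]$xyz, out[[b]]$xyz), 0.5)
  }
  out2 <- lowmode_mc_search(s, potential_spec(), cfg)
  expect_identical(attr(out2, "energies"), e)
})
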