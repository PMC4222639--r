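test_that("bonded terms vanish at their reference geometry", {
  s <- toy_structure(rbind(c(0, 0, 0), c(3.8, 0, 0)))
  e <- energy(s, bonded_potential())
  expect_equal(unname(e$terms["bond"]), 0, tolerance = 1e-10)
  one <- toy_structure(matrix(c(1, 2, 3), 1, 3))
  expect_equal(energy(one, potential_spec())$total, 0)
})

test_that("a three-bead system matches an independently summed closed form", {
  xyz <- rbind(c(0, 0, 0), c(4.1, 0, 0), c(6.5, 3.0, 0.4))
  s <- toy_structure(xyz, charge = c(0.5, 0, -1))
  p <- potential_spec(bond_k = 80, bond_r0 = 3.8, angle_k = 12,
                      torsion = list(c(0, 1)), lj_epsilon = 0.3,
                      dielectric = "constant", diel_eps = 2,
                      debye_length = Inf)
  # hand-summed: two bonds + one angle (1-2 and 1-3 pairs excluded from
  # nonbonded, so no LJ/electrostatic contribution at all for a 3-bead chain)
  r12 <- sqrt(sum((xyz[2, ] - xyz[1, ])^2))
  r23 <- sqrt(sum((xyz[3, ] - xyz[2, ])^2))
  v1 <- xyz[1, ] - xyz[2, ]; v2 <- xyz[3, ] - xyz[2, ]
  th <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)))
  # angle reference captured from this same geometry, so the angle term is 0
  expected <- 0.5 * 80 * (r12 - 3.8)^2 + 0.5 * 80 * (r23 - 3.8)^2 +
    0.5 * 12 * (th - th)^2
  expect_equal(energy(s, p)$total, expected, tolerance = 1e-10)
})

test_that("nonbonded pairs follow the cutoff with constant and r-dependent dielectrics", {
  xyz <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(3.8, 3.8, 0), c(0, 3.8, 0))
  s <- toy_structure(xyz, charge = c(1, 0, 0, -1))
  # only the 1-4 pair is nonbonded (1-2/1-3 excluded); r14 = 3.8
  p1 <- potential_spec(bond_k = 0, angle_k = 0, torsion = list(c(0, 1)),
                       lj_epsilon = 0, dielectric = "constant", diel_eps = 1,
                       debye_length = Inf)
  expect_equal(energy(s, p1)$total, -332.0637 / 3.8, tolerance = 1e-6)
  p2 <- potential_spec(bond_k = 0, angle_k = 0, torsion = list(c(0, 1)),
                       lj_epsilon = 0, dielectric = "distance", diel_eps = 4,
                       debye_length = Inf)
  expect_equal(energy(s, p2)$total, -332.0637 / (4 * 3.8^2), tolerance = 1e-6)
  p3 <- potential_spec(bond_k = 0, angle_k = 0, torsion = list(c(0, 1)),
                       lj_epsilon = 0, dielectric = "constant", diel_eps = 1,
                       debye_length = 7.9)
  expect_equal(energy(s, p3)$total, -332.0637 / 3.8 * exp(-3.8 / 7.9),
               tolerance = 1e-6)
  # beyond the cutoff the interaction vanishes
  s2 <- s; s2$xyz[4, ] <- c(0, 50, 0)
  expect_equal(energy(s2, p1)$total, 0, tolerance = 1e-10)
})

test_that("forces are the exact negative gradient (finite-difference property)", {
  for (seed in 1:3) {
    s <- toy_two_domain(seed = seed)
    s$atoms$charge[c(2, 9)] <- c(-1, 1)
    s$contacts <- data.frame(i = 1L, j = 15L, r0 = 8, depth = 3, width = 1.2,
                             kind = "site")
    r <- restraint_set(
      positional = data.frame(i = 1:2, x = 0, y = 0, z = 0, k = 5),
      relative = data.frame(i = 3L, j = 12L, r0 = 6, k = 3),
      torsional = data.frame(i = 4L, j = 5L, k_ = 6L, l = 7L, t0 = 0.3, k = 2))
    ctx <- cg_context(s, potential_spec(wall_k = 1, wall_r = 30), r)
    expect_lt(fd_force_error(s, ctx, n_probe = 20, seed = seed), 1e-4)
  }
})

test_that("forces on an isolated interacting pair obey Newton's third law", {
  s <- toy_structure(rbind(c(0, 0, 0), c(0, 0, 5.1)), charge = c(1, -1))
  s$bonds <- matrix(integer(0), 0, 2)   # purely nonbonded pair
  F <- forces(s, potential_spec())
  expect_equal(colSums(F), c(0, 0, 0), tolerance = 1e-12)
  expect_gt(abs(F[1, 3]), 0)
})

test_that("a positional restraint exerts no force at its anchor", {
  s <- toy_dimer(0)
  r <- restraint_set(positional = data.frame(i = 1, x = 0, y = 0, z = 0, k = 10))
  e <- energy(s, bonded_potential(), r)
  expect_equal(unname(e$terms["restraint_pos"]), 0, tolerance = 1e-12)
  F <- forces(s, bonded_potential(), r)
  expect_equal(F[1, ], c(0, 0, 0), tolerance = 1e-10)
})

test_that("energy is invariant under global rotation and translation", {
  s <- toy_two_domain(seed = 6)
  s$atoms$charge[c(1, 20)] <- c(-1, 1)
  p <- potential_spec()
  e0 <- energy(s, p)$total
  th <- 0.83
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  s2 <- s; s2$xyz <- sweep(s$xyz %*% t(R), 2, c(5, -3, 11), `+`)
  ctx <- cg_context(s, p)     # reference geometry from the original frame
  e1 <- demonmd:::.cg_energy_forces(s2$xyz, ctx, FALSE)$total
  expect_equal(e1, e0, tolerance = 1e-8)
})

test_that("the elastic-network term vanishes on the reference geometry", {
  s <- toy_two_domain(seed = 2)
  e <- energy(s, potential_spec())
  expect_equal(unname(e$terms["elastic_network"]), 0, tolerance = 1e-12)
  s2 <- s; s2$xyz[15, ] <- s2$xyz[15, ] + 0.5
  e2 <- demonmd:::.cg_energy_forces(s2$xyz, cg_context(s, potential_spec()),
                                    FALSE)
  expect_gt(e2$terms[["elastic_network"]], 0)
})

test_that("overlapping beads are rejected before the LJ singularity", {
  # beads 1 and 4 are a nonbonded pair (1-2/1-3 are excluded) and coincide
  s <- toy_structure(rbind(c(0, 0, 0), c(0, 0, 4), c(0, 4, 4),
                           c(1e-8, 0, 0)))
  expect_error(energy(s, potential_spec()), "overlap")
})

test_that("site modifications follow the documented parameter table", {
  s <- make_parkin_like(toy_spec(n_residues = 200, seed = 7))
  expect_identical(apply_modification(s, site_modification(65, "identity")), s)
  q0 <- sum(s$atoms$charge)
  ps <- apply_modification(s, site_modification(65, "pSer"))
  expect_equal(sum(ps$atoms$charge), q0 - 2)
  expect_equal(ps$atoms$radius[65], s$atoms$radius[65] + 0.4)
  expect_equal(sum(ps$contacts$depth[ps$contacts$kind == "site"]), 0)
  # the fold network is untouched by a site modification
  expect_equal(ps$contacts$depth[ps$contacts$kind == "fold"],
               s$contacts$depth[s$contacts$kind == "fold"])
  sd_ <- apply_modification(s, site_modification(65, "StoD"))
  expect_equal(sum(sd_$atoms$charge), q0 - 1)
  sa <- apply_modification(s, site_modification(65, "StoA"))
  expect_equal(sum(sa$atoms$charge), q0)
  expect_equal(sa$atoms$radius[65], s$atoms$radius[65] - 0.2)
  cs <- apply_modification(s, site_modification(65, "CtoS"))
  expect_equal(sum(cs$atoms$charge), q0)
  expect_error(site_modification(65, "nonsense"), "unknown")
  # the original object is never mutated
  expect_equal(s$atoms$charge[65], 0)
})

test_that("zinc-cassette restraints are relative, not anchored in space", {
  s <- toy_two_domain(seed = 4)
  r <- zinc_restraints(s, list(c(10, 11, 12, 13)))
  expect_equal(nrow(r$relative), choose(4, 2))
  expect_true(all(r$relative$k == 50))
  p <- potential_spec(bond_k = 0, angle_k = 0, torsion = list(c(0, 1)),
                      lj_epsilon = 0)
  ctx <- cg_context(s, p, r)
  e0 <- demonmd:::.cg_energy_forces(s$xyz, ctx, FALSE)$terms[["restraint_rel"]]
  expect_equal(e0, 0, tolerance = 1e-12)
  # rigid translation of the whole group costs nothing
  s2 <- s; s2$xyz[10:13, ] <- s2$xyz[10:13, ] + rep(c(7, -2, 4), each = 4)
  e1 <- demonmd:::.cg_energy_forces(s2$xyz, ctx, FALSE)$terms[["restraint_rel"]]
  expect_equal(e1, 0, tolerance = 1e-9)
  expect_error(zinc_restraints(s, list(5)), "at least 2")
})

test_that("stretching one restrained pair by 1 A costs 25 kcal/mol", {
  s <- toy_structure(rbind(c(0, 0, 0), c(0, 0, 6)))
  s$bonds <- matrix(integer(0), 0, 2)
  r <- zinc_restraints(s, list(c(1, 2)))
  p <- potential_spec(bond_k = 0, angle_k = 0, torsion = list(c(0, 1)),
                      lj_epsilon = 0, nonbonded_cutoff = 0.1)
  ctx <- cg_context(s, p, r)
  s2 <- s; s2$xyz[2, 3] <- s2$xyz[2, 3] + 1
  e <- demonmd:::.cg_energy_forces(s2$xyz, ctx, FALSE)$terms[["restraint_rel"]]
  expect_equal(e, 0.5 * 50 * 1^2, tolerance = 1e-9)
})

test_that("elastic-network modes are physical: six rigid modes removed", {
  s <- toy_two_domain(seed = 8)
  m <- anm_modes(s, cutoff = 10, n_modes = 4)
  expect_true(all(m$values > 1e-8))        # no rigid-body contamination
  expect_equal(ncol(m$vectors), 4)
  expect_equal(length(m$idx) * 3, nrow(m$vectors))
  # modes are orthonormal
  expect_equal(crossprod(m$vectors), diag(4), tolerance = 1e-8)
})
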