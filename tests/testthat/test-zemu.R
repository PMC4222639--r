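test_that("flexibility zones follow the five-residue rule with terminal clipping", {
  s <- make_parkin_like(toy_spec(n_residues = 200, seed = 7))
  expect_equal(flexibility_zone(s, zone_spec(65))$res_ids, 63:67)
  expect_equal(flexibility_zone(s, zone_spec(1))$res_ids, 1:3)
  expect_equal(flexibility_zone(s, zone_spec(200))$res_ids, 198:200)
  expect_error(flexibility_zone(s, zone_spec(999)),
               class = "demonmd_invalid_residue")
})

test_that("the physics zone matches an all-pairs distance scan and is monotone", {
  s <- toy_two_domain(seed = 9, n = 30, nflex = 12)
  flex <- flexibility_zone(s, zone_spec(15))
  ph <- physics_zone(s, flex, 12)
  expect_true(all(flex$res_ids %in% ph$res_ids))
  # O(N^2) oracle
  fidx <- apply_selection(s, flex)
  D <- as.matrix(dist(s$xyz))
  bf <- sort(unique(c(s$atoms$res_id[apply(D[, fidx, drop = FALSE], 1, min) <= 12],
                      flex$res_ids)))
  expect_identical(ph$res_ids, bf)
  ph8 <- physics_zone(s, flex, 8)
  ph16 <- physics_zone(s, flex, 16)
  expect_true(all(ph8$res_ids %in% ph$res_ids))
  expect_true(all(ph$res_ids %in% ph16$res_ids))
  # an isolated short peptide is its own physics zone
  pep <- toy_structure(cbind(0, 0, seq(0, by = 3.8, length.out = 5)))
  fz <- flexibility_zone(pep, zone_spec(3))
  expect_equal(physics_zone(pep, fz, 12)$res_ids, 1:5)
  # a partner 50 A away is excluded
  far <- toy_structure(rbind(cbind(0, 0, seq(0, by = 3.8, length.out = 5)),
                             cbind(50, 0, seq(0, by = 3.8, length.out = 5))))
  fz2 <- cg_selection("flex", 2:4)
  expect_true(all(physics_zone(far, fz2, 12)$res_ids <= 5))
})

test_that("zone equilibration freezes everything outside the flexibility zone", {
  s <- make_parkin_like(toy_spec(n_residues = 200, seed = 7))
  flex <- flexibility_zone(s, zone_spec(65))
  phys <- physics_zone(s, flex, 12)
  eq <- equilibrate_zone(s, flex, phys, potential_spec(), maxit = 100)
  out_idx <- setdiff(seq_len(n_beads(s)), apply_selection(s, flex))
  expect_identical(eq$xyz[out_idx, ], s$xyz[out_idx, ])
  zi <- attr(eq, "zone_info")
  expect_lte(zi$energy_end, zi$energy_start)
  # an already-minimal zone stays put
  eq2 <- equilibrate_zone(eq, flex, phys, potential_spec(), maxit = 100)
  expect_equal(eq2$xyz, eq$xyz, tolerance = 0.05)
})

test_that("a perturbed zone torsion relaxes back to its minimum", {
  # 10-bead all-flexible peptide with a native reference captured at build
  pep <- minimize(make_parkin_like(toy_spec(
    n_residues = 10,
    domain_plan = list(list(range = c(1, 10), class = "flexible")),
    seed = 13)), potential_spec(), tol = 1e-3, max_iter = 3000)
  flex <- cg_selection("flex_zone", 4:8)
  phys <- cg_selection("physics_zone", 1:10)
  # 1-D oracle: scan the zone torsion about bond (5,6) (moving zone beads
  # 7-8 only, as the zone equilibrator does) for the energy minimum
  ctx <- demonmd:::.zone_context(pep, potential_spec(), phys)
  escan <- function(th) {
    x <- demonmd:::.rotate_about_bond(pep$xyz, 5, 6, 7:8, th)
    demonmd:::.cg_energy_forces(x, ctx, FALSE)$total
  }
  th_opt <- stats::optimize(escan, c(-0.5, 0.5), tol = 1e-9)$minimum
  pert <- pep
  pert$xyz <- demonmd:::.rotate_about_bond(pert$xyz, 5, 6, 7:8, 0.35)
  # relax under the native reference context, not one built on the perturbed
  # geometry (bonded terms take their reference from the context structure)
  eq <- equilibrate_zone(pert, flex, phys, potential_spec(), maxit = 600,
                         ctx = ctx)
  d_eq <- demonmd:::.dihedral(eq$xyz[4, ], eq$xyz[5, ], eq$xyz[6, ], eq$xyz[7, ])
  d_opt <- {
    x <- demonmd:::.rotate_about_bond(pep$xyz, 5, 6, 7:8, th_opt)
    demonmd:::.dihedral(x[4, ], x[5, ], x[6, ], x[7, ])
  }
  expect_lt(abs(d_eq - d_opt), 1e-2)
})

test_that("the identity modification scores a ddG of exactly zero", {
  s <- make_parkin_like(toy_spec(n_residues = 200, seed = 7))
  r <- ddg_mutation(s, site_modification(65, "identity"), p = potential_spec(),
                    maxit = 60)
  expect_equal(r$ddG, 0, tolerance = 1e-6)
  expect_equal(r$ddG, r$dG_wt - r$dG_mut)
})

test_that("ddG magnitude scales with the site charge in a fixed environment", {
  # a probe charge 5 A from the site isolates the electrostatic scaling
  xyz <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(7.6, 0, 0), c(11.4, 0, 0),
               c(15.2, 0, 0), c(7.6, 5, 0))
  s <- toy_structure(xyz, charge = c(0, 0, 0, 0, 0, -1))
  s$bonds <- cbind(1:4, 2:5)               # bead 6 is a detached probe
  p <- potential_spec(lj_epsilon = 0, debye_length = Inf)
  d1 <- ddg_mutation(s, site_modification(3, "StoD"), p = p,
                     equilibrate = FALSE)
  d2 <- ddg_mutation(s, site_modification(3, "pSer"), p = p,
                     equilibrate = FALSE)
  expect_gte(abs(d2$ddG), abs(d1$ddG))
  expect_equal(d2$ddG / d1$ddG, 2, tolerance = 1e-6)  # pure charge scaling
})

test_that("fixed-environment ddG is the plain energy difference, antisymmetric", {
  s <- make_parkin_like(toy_spec(n_residues = 200, seed = 7))
  m <- site_modification(65, "StoD")
  flex <- flexibility_zone(s, zone_spec(65))
  phys <- physics_zone(s, flex, 12)
  score <- function(x) demonmd:::.cg_energy_forces(
    x$xyz, demonmd:::.zone_context(x, potential_spec(), phys), FALSE)$total
  d <- ddg_mutation(s, m, p = potential_spec(), equilibrate = FALSE)
  expect_equal(d$ddG, score(s) - score(apply_modification(s, m)),
               tolerance = 1e-9)
  # swapping the roles of the two states negates the difference
  expect_equal(score(apply_modification(s, m)) - score(s), -d$ddG,
               tolerance = 1e-9)
})

test_that("ddG is invariant to a global rotation and translation of the input", {
  s <- make_parkin_like(toy_spec(n_residues = 200, seed = 7))
  m <- site_modification(65, "pSer")
  d0 <- ddg_mutation(s, m, p = potential_spec(), maxit = 50)
  th <- 0.62
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  s2 <- s; s2$xyz <- sweep(s$xyz %*% t(R), 2, c(10, -4, 2), `+`)
  d1 <- ddg_mutation(s2, m, p = potential_spec(), maxit = 50)
  expect_equal(d1$ddG, d0$ddG, tolerance = 1e-4)
})

test_that("the interaction decomposition follows the stated formula", {
  # two 5-bead chains far apart: no cross terms
  far <- toy_structure(rbind(cbind(0, 0, seq(0, by = 3.8, length.out = 5)),
                             cbind(60, 0, seq(0, by = 3.8, length.out = 5))))
  far$bonds <- rbind(cbind(1:4, 2:5), cbind(6:9, 7:10))
  a <- cg_selection("a", 1:5); b <- cg_selection("b", 6:10)
  expect_equal(as.numeric(ddg_interaction(far, a, b)), 0, tolerance = 1e-6)
  expect_equal(as.numeric(ddg_interaction(far, a, b, dG_kon = 1.5,
                                          dS_sc = 0.5)), 2.0, tolerance = 1e-6)
  # bound dimer: equals the hand-computed cross-pair nonbonded sum
  near <- far; near$xyz[6:10, 1] <- 5.5
  near$atoms$charge <- c(1, 0, 0, 0, 0, -1, 0, 0, 0, 0)
  p <- potential_spec(debye_length = Inf)
  v <- ddg_interaction(near, a, b, p = p)
  cross <- 0
  for (i in 1:5) for (j in 6:10) {
    rij <- sqrt(sum((near$xyz[i, ] - near$xyz[j, ])^2))
    if (rij <= p$nonbonded_cutoff) {
      sr6 <- (3.8 / rij)^6
      cross <- cross + 4 * p$lj_epsilon * (sr6^2 - sr6) +
        332.0637 * near$atoms$charge[i] * near$atoms$charge[j] / (4 * rij^2)
    }
  }
  expect_equal(as.numeric(v), cross, tolerance = 1e-6)
  expect_error(ddg_interaction(near, a, cg_selection("b", 6:9)), "partition")
})

test_that("batch ddG returns one scored row per mutation", {
  s <- make_parkin_like(toy_spec(n_residues = 200, seed = 7))
  tab <- ddg_batch(s, data.frame(res_id = c(65, 65), kind = c("StoA", "StoE")),
                   p = potential_spec(), maxit = 40)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$ddG, tab$dG_wt - tab$dG_mut)
})
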