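test_that("centre-of-mass distances reduce to hand arithmetic", {
  s <- toy_structure(rbind(c(0, 0, 0), c(3, 4, 0)))
  expect_equal(com_distance(s, cg_selection("a", 1), cg_selection("b", 2)), 5)
  # mirror symmetry about a plane at distance d gives separation 2d
  xyz <- rbind(c(2, 1, 0), c(2, -1, 0), c(-2, 1, 0), c(-2, -1, 0))
  s2 <- toy_structure(xyz)
  expect_equal(com_distance(s2, cg_selection("a", 1:2), cg_selection("b", 3:4)),
               4, tolerance = 1e-12)
  # unequal masses: weighted centroid arithmetic
  s3 <- toy_structure(rbind(c(0, 0, 0), c(2, 0, 0), c(4, 0, 0),
                            c(10, 0, 0), c(12, 0, 0), c(14, 0, 0),
                            c(16, 0, 0), c(18, 0, 0)),
                      mass = c(10, 20, 30, 1, 1, 1, 1, 6))
  ca <- sum(c(0, 2, 4) * c(10, 20, 30)) / 60
  cb <- sum(c(10, 12, 14, 16, 18) * c(1, 1, 1, 1, 6)) / 10
  expect_equal(com_distance(s3, cg_selection("a", 1:3), cg_selection("b", 4:8)),
               cb - ca, tolerance = 1e-12)
  expect_error(com_distance(s3, cg_selection("a", 1:3), cg_selection("b", 3:5)),
               "overlap")
})

test_that("Shrake-Rupley SASA matches closed forms and a grid oracle", {
  one <- toy_structure(matrix(0, 1, 3))
  a <- sasa(one, probe = 1.4, n_sphere_points = 960)
  expect_lt(abs(sum(a) - 4 * pi * 3.3^2) / (4 * pi * 3.3^2), 0.02)
  two_far <- toy_structure(rbind(c(0, 0, 0), c(100, 0, 0)))
  expect_equal(attr(sasa(two_far), "total"), 2 * 4 * pi * 3.3^2,
               tolerance = 1e-6)
  # contact pair vs a dense random-surface oracle
  two <- toy_structure(rbind(c(0, 0, 0), c(3.8, 0, 0)))
  mine <- attr(sasa(two, n_sphere_points = 960), "total")
  oracle <- {
    tot <- 0
    for (i in 1:2) {
      set.seed(10 + i)
      R <- 3.3
      pts <- matrix(rnorm(3 * 4000), ncol = 3)
      pts <- pts / sqrt(rowSums(pts^2)) * R
      pts <- sweep(pts, 2, two$xyz[i, ], `+`)
      j <- 3 - i
      ok <- colSums((t(pts) - two$xyz[j, ])^2) > R^2
      tot <- tot + 4 * pi * R^2 * mean(ok)
    }
    tot
  }
  expect_lt(abs(mine - oracle) / oracle, 0.03)
  expect_error(sasa(one, n_sphere_points = 8), "at least 16")
})

test_that("moving beads into contact never raises the total area", {
  xyz <- rbind(c(0, 0, 0), c(20, 0, 0), c(0, 20, 0))
  seps <- c(20, 10, 6, 4)
  areas <- vapply(seps, function(d) {
    s <- toy_structure(rbind(c(0, 0, 0), c(d, 0, 0), c(0, d, 0)))
    attr(sasa(s, n_sphere_points = 480), "total")
  }, 0)
  expect_true(all(diff(areas) <= 1e-6))
})

test_that("pocket water counts equal a brute-force scan and grow with cutoff", {
  set.seed(5)
  prot_xyz <- matrix(rnorm(30, sd = 4), 10, 3)
  wat_xyz <- matrix(rnorm(150, sd = 12), 50, 3)
  atoms <- data.frame(serial = 1:60, res_id = 1:60,
                      res_name = c(rep("ALA", 10), rep("HOH", 50)),
                      atom_label = c(rep("CA", 10), rep("W", 50)),
                      mass = c(rep(110, 10), rep(18, 50)),
                      charge = 0, radius = c(rep(1.9, 10), rep(1.4, 50)))
  s <- cg_structure(atoms, rbind(prot_xyz, wat_xyz))
  pocket <- cg_selection("p", 1:10)
  for (cut in c(3, 5, 8, 12)) {
    bf <- sum(apply(wat_xyz, 1, function(w)
      min(sqrt(colSums((t(prot_xyz) - w)^2))) <= cut))
    expect_equal(count_pocket_waters(s, pocket, cut), bf)
  }
  counts <- vapply(c(2, 4, 6, 10, 15), function(cut)
    count_pocket_waters(s, pocket, cut), 0L)
  expect_true(all(diff(counts) >= 0))
  expect_equal(count_pocket_waters(s, pocket, 0), 0L)
  dry <- toy_structure(prot_xyz)
  expect_message(n0 <- count_pocket_waters(dry, pocket, 5), "no water")
  expect_equal(n0, 0L)
})

test_that("pair distances resolve named probes exactly", {
  s <- toy_structure(rbind(c(0, 0, 0), c(1, 1, 1)))
  expect_equal(pair_distance(s, list(1), list(1)), 0)
  expect_equal(pair_distance(s, list(1), list(2)), sqrt(3))
  tr <- cg_trajectory(s, list(s$xyz, s$xyz * 2), c(1, 2))
  ser <- pair_distance_series(tr, list(1), list(2))
  expect_equal(ser$value, c(sqrt(3), 2 * sqrt(3)))
  # every series value equals independent recomputation from raw coordinates
  for (k in 1:2)
    expect_equal(ser$value[k],
                 sqrt(sum((tr$frames[[k]][1, ] - tr$frames[[k]][2, ])^2)))
  expect_error(pair_distance(s, list(9), list(1)), "resolves")
})

test_that("RMSD and RMSF vanish on static or rigidly tumbling trajectories", {
  s <- toy_two_domain(seed = 4)
  static <- cg_trajectory(s, list(s$xyz, s$xyz, s$xyz), 1:3)
  expect_lt(max(rmsd_series(static, s)$value), 1e-4)
  expect_lt(max(rmsf(static)$rmsf), 1e-10)
  th <- seq(0.3, 0.9, length.out = 3)
  tumbling <- cg_trajectory(s, lapply(th, function(a) {
    R <- rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))
    sweep(s$xyz %*% t(R), 2, c(a, 2 * a, 0), `+`)
  }), 1:3)
  expect_lt(max(rmsd_series(tumbling, s)$value), 1e-4)
  expect_lt(max(rmsf(tumbling)$rmsf), 1e-4)
})

test_that("two-frame RMSF equals the closed-form half displacement", {
  s <- toy_two_domain(seed = 4)
  f2 <- s$xyz; f2[3, ] <- f2[3, ] + c(0.8, 0, 0)
  # without superposition effects (displace one bead of many, others fixed),
  # each bead's RMSF is half its frame-to-frame displacement
  tr <- cg_trajectory(s, list(s$xyz, f2), 1:2)
  fl <- rmsf(tr)
  disp <- sqrt(rowSums((demonmd:::.kabsch_align(s$xyz, f2) - s$xyz)^2))
  # pairwise-aligned and mean-aligned superpositions differ at second order
  expect_lt(max(abs(fl$rmsf - disp / 2)), 0.02)
})

test_that("pseudo phi/psi dihedrals match planar references and an oracle", {
  cis <- toy_structure(rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)))
  expect_equal(phi_psi(cis)$phi[3], 0, tolerance = 1e-10)
  trans <- toy_structure(rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),
                               c(1, -1, 0)))
  expect_equal(abs(phi_psi(trans)$phi[3]), 180, tolerance = 1e-10)
  for (seed in 1:5) {
    set.seed(seed)
    q <- matrix(rnorm(12, sd = 2), 4, 3)
    s <- toy_structure(q)
    expect_equal(phi_psi(s)$phi[3],
                 oracle_dihedral(q[1, ], q[2, ], q[3, ], q[4, ]),
                 tolerance = 1e-6)
  }
})

test_that("all frame metrics are invariant under rigid motion of the frame", {
  s <- make_parkin_like(toy_spec(n_residues = 200, seed = 7))
  reg <- parkin_selections()
  th <- 0.7
  R <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
  x2 <- sweep(s$xyz %*% t(R), 2, c(-4, 8, 1), `+`)
  expect_equal(com_distance(s, reg$selections$CoM1, reg$selections$CoM2,
                            xyz = x2),
               com_distance(s, reg$selections$CoM1, reg$selections$CoM2),
               tolerance = 1e-9)
  expect_equal(pair_distance(s, list(65), list(115), xyz = x2),
               pair_distance(s, list(65), list(115)), tolerance = 1e-9)
  s2 <- s; s2$xyz <- x2
  # quadrature points live in the lab frame, so rotational invariance holds
  # only to within the quadrature error
  expect_equal(attr(sasa(s2, n_sphere_points = 480), "total"),
               attr(sasa(s, n_sphere_points = 480), "total"),
               tolerance = 0.02)
})

test_that("metric series export as annotated CSV and JSON", {
  ms <- metric_series(c(1, 2, 3), c(8.1, 8.4, 9.0), "cleft", "A")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_metric_series(ms, csv)
  lines <- readLines(csv)
  expect_match(lines[1], "units: A")
  back <- read.csv(csv, comment.char = "#")
  expect_equal(back$value, ms$value)
  js <- withr::local_tempfile(fileext = ".json")
  write_metric_series(ms, js)
  j <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(j$value, ms$value)
  expect_error(metric_series(c(1, 1), c(1, 2), "x", "A"), "increasing")
})
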