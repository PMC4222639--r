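test_that("the RMSD collective variable is a true superposition RMSD", {
  s <- toy_two_domain(seed = 2)
  expect_lt(rmsd_cv(s, s), 1e-4)
  # rigid motion leaves it at zero
  th <- 1.1
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  s2 <- s; s2$xyz <- sweep(s$xyz %*% t(R), 2, c(3, 4, 5), `+`)
  expect_lt(rmsd_cv(s2, s), 1e-4)
  expect_error(rmsd_cv(s, toy_dimer()), "bead counts")
})

test_that("Kabsch RMSD matches a rotation-grid brute force on 4-point systems", {
  for (seed in 1:4) {
    set.seed(seed)
    A <- matrix(rnorm(12, sd = 3), 4, 3)
    B <- matrix(rnorm(12, sd = 3), 4, 3)
    expect_equal(demonmd:::.kabsch_rmsd(A, B), oracle_rmsd(A, B),
                 tolerance = 1e-3)
  }
})

test_that("our RMSD agrees with an independent structural-biology implementation", {
  skip_if_not_installed("bio3d")
  set.seed(7)
  A <- matrix(rnorm(30, sd = 4), 10, 3)
  B <- A + matrix(rnorm(30, sd = 1), 10, 3)
  ref <- bio3d::rmsd(as.vector(t(A)), as.vector(t(B)), fit = TRUE)
  # bio3d rounds its RMSD to three decimals
  expect_equal(demonmd:::.kabsch_rmsd(A, B), ref, tolerance = 2e-3)
})

test_that("a guidepost equal to the start is reached with no sprints", {
  s <- minimize(toy_two_domain(seed = 5), potential_spec(), tol = 0.05,
                max_iter = 500)
  out <- demon_run(s, guidepost = s, cfg = demon_config(seed = 1))
  expect_true(out$stats$reached)
  expect_equal(nrow(out$stats$sprints), 0)
  expect_lt(out$stats$final_cv, 1e-6)
})

test_that("accepted-sprint CV sequences never rise beyond the tolerance", {
  s <- minimize(toy_two_domain(seed = 5), potential_spec(), tol = 0.05,
                max_iter = 500)
  gp <- s; gp$xyz[1:8, ] <- gp$xyz[1:8, ] + 2.5   # displaced flexible arm
  cfg <- demon_config(md = md_config(dt = 0.002, thermostat = "berendsen",
                                     tau = 0.3, save_stride = 0),
                      sprint_min = 20, sprint_max = 60, max_sprints = 60,
                      success_radius = 0.2, seed = 31)
  out <- demon_run(s, guidepost = gp, cfg = cfg)
  led <- out$stats$sprints
  acc <- led[led$accepted, ]
  if (nrow(acc) > 0)
    expect_true(all(acc$cv_after <= acc$cv_before + cfg$accept_tol + 1e-12))
  expect_gte(out$stats$discard_fraction, 0)
  expect_lte(out$stats$discard_fraction, 1)
  expect_identical(out$stats$reached, out$stats$final_cv <= 0.2)
  expect_equal(out$stats$n_accepted + out$stats$n_discarded, nrow(led))
})

test_that("with the demon off the run reduces exactly to plain integration", {
  s <- minimize(toy_two_domain(seed = 6), potential_spec(), tol = 0.05,
                max_iter = 500)
  v <- boltzmann_velocities(s$atoms$mass, 300, seed = 11)
  # COM removal off in both runs so the step schedules are identical
  cfg <- demon_config(md = md_config(dt = 0.002, thermostat = "berendsen",
                                     tau = 0.5, save_stride = 0,
                                     com_removal_interval = 0),
                      sprint_min = 15, sprint_max = 40, max_sprints = 8,
                      success_radius = 0, seed = 13)
  gp <- s; gp$xyz <- gp$xyz + 50           # unreachable target
  out <- demon_run(s, v, guidepost = gp, cfg = cfg, accept_all = TRUE)
  total_steps <- sum(out$stats$sprints$steps)
  ref <- integrate_md(s, v, potential_spec(),
                      cfg = md_config(dt = 0.002, thermostat = "berendsen",
                                      tau = 0.5, n_steps = total_steps,
                                      com_removal_interval = 0,
                                      save_stride = 0))
  expect_equal(out$final$xyz, ref$final$xyz, tolerance = 1e-12)
})

test_that("chained legs hand off state and keep complete ledgers", {
  s <- minimize(toy_two_domain(seed = 5), potential_spec(), tol = 0.05,
                max_iter = 500)
  posts <- structure(list(s, s), class = "guidepost_set")
  ch <- chain_guideposts(s, posts, demon_config(seed = 3), potential_spec())
  expect_true(all(ch$legs$reached))        # identical posts: trivially reached
  expect_equal(nrow(ch$legs), 2)
  gp2 <- s; gp2$xyz[1:8, ] <- gp2$xyz[1:8, ] + 1.5
  posts3 <- structure(list(s, gp2, s), class = "guidepost_set")
  ch3 <- chain_guideposts(s, posts3,
                          demon_config(sprint_min = 20, sprint_max = 50,
                                       max_sprints = 40, success_radius = 1,
                                       seed = 5),
                          potential_spec())
  expect_equal(nrow(ch3$legs), 3)
  expect_true(all(ch3$legs$discard_fraction >= 0 &
                  ch3$legs$discard_fraction <= 1))
  for (st in ch3$stats)
    expect_equal(st$n_accepted + st$n_discarded, nrow(st$sprints))
})

test_that("replicates derive distinct but reproducible trajectories", {
  s <- minimize(toy_two_domain(seed = 5), potential_spec(), tol = 0.05,
                max_iter = 500)
  gp <- s; gp$xyz[1:8, ] <- gp$xyz[1:8, ] + 3
  posts <- structure(list(s, gp), class = "guidepost_set")
  cfg <- demon_config(sprint_min = 20, sprint_max = 50, max_sprints = 30,
                      success_radius = 0.4, seed = 77)
  reps <- run_replicates(s, posts, cfg, n_reps = 3, p = potential_spec())
  expect_length(reps, 3)
  # sprint-length draws (and any accepted frames) differ between replicates
  ledg <- lapply(reps, function(r) r$stats[[2]]$sprints$steps)
  expect_false(identical(ledg[[1]], ledg[[2]]))
  expect_false(identical(ledg[[2]], ledg[[3]]))
  reps2 <- run_replicates(s, posts, cfg, n_reps = 3, p = potential_spec())
  expect_identical(reps[[2]]$final$xyz, reps2[[2]]$final$xyz)
  expect_identical(ledg[[3]], reps2[[3]]$stats[[2]]$sprints$steps)
})

test_that("sprint ledgers export as delimited text", {
  s <- minimize(toy_two_domain(seed = 5), potential_spec(), tol = 0.05,
                max_iter = 300)
  gp <- s; gp$xyz[1:8, ] <- gp$xyz[1:8, ] + 1
  out <- demon_run(s, guidepost = gp,
                   cfg = demon_config(sprint_min = 10, sprint_max = 20,
                                      max_sprints = 10, success_radius = 0.5,
                                      seed = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_demon_stats(out$stats, path)
  back <- read.csv(path)
  expect_equal(nrow(back), nrow(out$stats$sprints))
  expect_true(all(c("cv_before", "cv_after", "accepted") %in% names(back)))
})
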