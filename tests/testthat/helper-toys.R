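# small in-memory fixtures used across the suite

# bare bead structure from coordinates
toy_structure <- function(xyz, lab = "CA", radius = 1.9, mass = 110,
                          charge = 0, rigid = NULL) {
  n <- nrow(xyz)
  cg_structure(data.frame(serial = seq_len(n), res_id = seq_len(n),
                          res_name = ifelse(lab == "W", "HOH", "ALA"),
                          atom_label = lab, mass = mass, charge = charge,
                          radius = radius),
               xyz, rigid = rigid)
}

# 20-bead two-domain chain (8 flexible + 12 rigid)
toy_two_domain <- function(seed = 3, n = 20, nflex = 8) {
  make_parkin_like(toy_spec(
    n_residues = n,
    domain_plan = list(list(range = c(1, nflex), class = "flexible"),
                       list(range = c(nflex + 1, n), class = "rigid")),
    seed = seed))
}

# harmonic dimer stretched 1 A beyond the bond length
toy_dimer <- function(stretch = 1) {
  toy_structure(rbind(c(0, 0, 0), c(3.8 + stretch, 0, 0)))
}

# bonded-terms-only potential (no nonbonded), for clean integrator checks
bonded_potential <- function(...) {
  potential_spec(angle_k = 0, torsion = list(c(0, 1)), lj_epsilon = 0, ...)
}

# independent dihedral via an unrelated atan2 formulation (oracle)
oracle_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cx <- function(a, b) c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  n1 <- cx(b1, b2); n2 <- cx(b2, b3)
  m1 <- cx(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

# rotation-grid + refinement brute-force superposition RMSD oracle
oracle_rmsd <- function(A, B) {
  A <- sweep(A, 2, colMeans(A)); B <- sweep(B, 2, colMeans(B))
  rotmat <- function(ang) {
    ca <- cos(ang); sa <- sin(ang)
    Rx <- rbind(c(1, 0, 0), c(0, ca[1], -sa[1]), c(0, sa[1], ca[1]))
    Ry <- rbind(c(ca[2], 0, sa[2]), c(0, 1, 0), c(-sa[2], 0, ca[2]))
    Rz <- rbind(c(ca[3], -sa[3], 0), c(sa[3], ca[3], 0), c(0, 0, 1))
    Rz %*% Ry %*% Rx
  }
  f <- function(ang) sqrt(mean(rowSums((B %*% t(rotmat(ang)) - A)^2)))
  gr <- seq(0, 2 * pi, length.out = 9)[-9]
  best <- Inf; best_ang <- c(0, 0, 0)
  for (a1 in gr) for (a2 in gr) for (a3 in gr) {
    v <- f(c(a1, a2, a3))
    if (v < best) { best <- v; best_ang <- c(a1, a2, a3) }
  }
  opt <- stats::optim(best_ang, f, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 3000))
  opt$value
}

# max relative finite-difference error of forces over sampled coordinates
fd_force_error <- function(s, ctx, n_probe = 15, h = 1e-5, seed = 1) {
  set.seed(seed)
  F <- demonmd:::.cg_energy_forces(s$xyz, ctx, TRUE)$forces
  n <- nrow(s$xyz)
  err <- 0
  for (k in sample(3 * n, min(n_probe, 3 * n))) {
    i <- (k - 1) %% n + 1; c_ <- (k - 1) %/% n + 1
    xp <- s$xyz; xp[i, c_] <- xp[i, c_] + h
    xm <- s$xyz; xm[i, c_] <- xm[i, c_] - h
    fd <- -(demonmd:::.cg_energy_forces(xp, ctx, FALSE)$total -
            demonmd:::.cg_energy_forces(xm, ctx, FALSE)$total) / (2 * h)
    err <- max(err, abs(fd - F[i, c_]) / max(1, abs(fd)))
  }
  err
}
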