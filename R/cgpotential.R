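#' Coarse-grained potential specification
#'
#' Parameters of the bead-level energy model. Bonded terms (bond, angle,
#' torsion) take their reference geometry from the structure the evaluation
#' context is built on (a native-structure-based CG convention), except the
#' bond length which is the global `bond_r0`. Nonbonded terms are a 12-6
#' Lennard-Jones plus Coulomb electrostatics with either a constant dielectric
#' or the distance-dependent form eps(r) = `diel_eps` * r, truncated at
#' `nonbonded_cutoff` with 1-2 and 1-3 exclusions and no 1-4 scaling.
#' Rigid-tagged bead pairs within `en_cutoff` get elastic-network springs.
#'
#' @param bond_k bond force constant, kcal/(mol A^2); energy is
#'   `0.5 * k * (r - r0)^2`.
#' @param bond_r0 equilibrium pseudo-bond length, A (Calpha-Calpha 3.8).
#' @param angle_k angle force constant, kcal/(mol rad^2).
#' @param torsion list of torsion terms, each `c(amp, per)` with amplitude in
#'   kcal/mol and integer periodicity; the phase is set per quadruple so the
#'   reference geometry is a minimum.
#' @param lj_epsilon LJ well depth, kcal/mol.
#' @param lj_sigma reference LJ sigma, A, for a pair of default-radius (1.9 A)
#'   beads; actual pair sigma scales with the bead radii,
#'   `sigma_ij = lj_sigma * (r_i + r_j) / 3.8`.
#' @param dielectric `"distance"` for eps(r) = diel_eps * r, or `"constant"`.
#' @param diel_eps dielectric coefficient (dimensionless).
#' @param debye_length Debye screening length, A; the default 7.9 A is the
#'   150 mM physiological value, so bulk salt is carried by the screened
#'   Coulomb term rather than by explicit ion beads. `Inf` disables
#'   screening.
#' @param nonbonded_cutoff nonbonded cutoff, A.
#' @param en_cutoff elastic-network cutoff among rigid-tagged beads, A.
#' @param en_k elastic-network spring constant, kcal/(mol A^2).
#' @param wall_k containment-wall force constant, kcal/(mol A^2); 0 disables.
#' @param wall_r containment-wall radius, A (`NA`: auto, system extent + 5 A).
#' @return an object of class `potential_spec`.
#' @export
potential_spec <- function(bond_k = 100, bond_r0 = 3.8, angle_k = 10,
                           torsion = list(c(0.5, 1)), lj_epsilon = 0.2,
                           lj_sigma = 3.8, dielectric = c("distance", "constant"),
                           diel_eps = NULL, debye_length = 7.9,
                           nonbonded_cutoff = 9, en_cutoff = 10, en_k = 1,
                           wall_k = 0, wall_r = NA) {
  dielectric <- match.arg(dielectric)
  if (is.null(diel_eps)) diel_eps <- if (dielectric == "distance") 4 else 1
  stopifnot(bond_k >= 0, angle_k >= 0, lj_epsilon >= 0, nonbonded_cutoff > 0,
            en_cutoff > 0, en_k >= 0, bond_r0 > 0)
  structure(list(bond_k = bond_k, bond_r0 = bond_r0, angle_k = angle_k,
                 torsion = torsion, lj_epsilon = lj_epsilon, lj_sigma = lj_sigma,
                 dielectric = dielectric, diel_eps = diel_eps,
                 debye_length = debye_length, nonbonded_cutoff = nonbonded_cutoff,
                 en_cutoff = en_cutoff, en_k = en_k, wall_k = wall_k,
                 wall_r = wall_r),
            class = "potential_spec")
}

#' Restraint set
#'
#' Positional restraints anchor beads to fixed points; relative restraints are
#' harmonic in a pair distance; torsional restraints are harmonic in a
#' four-bead dihedral. All use the `0.5 * k * delta^2` convention.
#'
#' @param positional data.frame with columns `i`, `x`, `y`, `z`, `k`.
#' @param relative data.frame with columns `i`, `j`, `r0`, `k`.
#' @param torsional data.frame with columns `i`, `j`, `k_`, `l`, `t0`, `k`.
#' @return an object of class `restraint_set`.
#' @export
restraint_set <- function(positional = NULL, relative = NULL, torsional = NULL) {
  if (is.null(positional))
    positional <- data.frame(i = integer(0), x = numeric(0), y = numeric(0),
                             z = numeric(0), k = numeric(0))
  if (is.null(relative))
    relative <- data.frame(i = integer(0), j = integer(0), r0 = numeric(0),
                           k = numeric(0))
  if (is.null(torsional))
    torsional <- data.frame(i = integer(0), j = integer(0), k_ = integer(0),
                            l = integer(0), t0 = numeric(0), k = numeric(0))
  stopifnot(all(positional$k >= 0), all(relative$k >= 0), all(torsional$k >= 0))
  structure(list(positional = positional, relative = relative,
                 torsional = torsional), class = "restraint_set")
}

#' Positional restraints at current coordinates
#'
#' Convenience builder for the staged-equilibration protocol: anchors every
#' selected bead at its current position with force constant `k`.
#'
#' @param s a `cg_structure`.
#' @param k force constant, kcal/(mol A^2).
#' @param idx bead indices (default: all protein beads).
#' @return a `restraint_set`.
#' @export
positional_restraints <- function(s, k, idx = NULL) {
  if (is.null(idx)) idx <- which(s$atoms$atom_label == "CA")
  restraint_set(positional = data.frame(i = idx, x = s$xyz[idx, 1],
                                        y = s$xyz[idx, 2], z = s$xyz[idx, 3],
                                        k = k))
}

#' Semi-rigid zinc-finger restraints
#'
#' Builds the restraint scheme used to keep Zn-coordinating residue cassettes
#' moving as units: every within-group bead pair gets a relative harmonic
#' restraint at k = 50 kcal/(mol A^2) at its current distance (relative to each
#' other, not to coordinate space), and the backbone pseudo-torsion adjacent to
#' each group residue is softly restrained at k = 10 kcal/mol.
#'
#' @param s a `cg_structure`.
#' @param rigid_sites list of integer vectors of bead indices (each a group).
#' @return a `restraint_set`.
#' @export
zinc_restraints <- function(s, rigid_sites) {
  stopifnot(inherits(s, "cg_structure"))
  rel <- list(); tor <- list()
  chain <- which(s$atoms$atom_label == "CA")
  for (g in rigid_sites) {
    g <- as.integer(g)
    if (length(g) < 2) stop("zinc restraint group must contain at least 2 beads")
    pr <- utils::combn(sort(g), 2)
    d <- sqrt(rowSums((s$xyz[pr[1, ], , drop = FALSE] -
                       s$xyz[pr[2, ], , drop = FALSE])^2))
    rel[[length(rel) + 1]] <- data.frame(i = pr[1, ], j = pr[2, ], r0 = d, k = 50)
    for (i in g) {
      pos <- match(i, chain)
      if (is.na(pos) || pos < 2 || pos > length(chain) - 2) next
      q <- chain[(pos - 1):(pos + 2)]
      tor[[length(tor) + 1]] <- data.frame(
        i = q[1], j = q[2], k_ = q[3], l = q[4],
        t0 = .dihedral(s$xyz[q[1], ], s$xyz[q[2], ], s$xyz[q[3], ], s$xyz[q[4], ]),
        k = 10)
    }
  }
  tor <- if (length(tor)) unique(do.call(rbind, tor)) else NULL
  restraint_set(relative = if (length(rel)) do.call(rbind, rel),
                torsional = tor)
}

#' Site modification (phosphorylation / point mutation) as parameter edits
#'
#' The CG analog of modelling pSer65 and the S65A/D/E, C431S variants: a
#' modification changes the site bead's charge and radius by a documented table
#' and scales any native site contact the bead participates in. Phosphoserine
#' carries -2 at pH 7.4; phosphomimetics D/E carry -1; the phospho-dead A is
#' neutral and slightly smaller. Every non-identity modification removes the
#' site's native contact (the serine hydroxyl interaction is lost in all
#' variants).
#'
#' @param res_id residue to modify.
#' @param kind one of `"identity"`, `"pSer"`, `"StoA"`, `"StoD"`, `"StoE"`,
#'   `"CtoS"`.
#' @return an object of class `site_modification` with fields `charge_delta`,
#'   `radius_delta`, `contact_scale`, `res_name`.
#' @export
site_modification <- function(res_id, kind) {
  tab <- list(
    identity = list(charge_delta = 0,  radius_delta = 0,    contact_scale = 1, res_name = NA),
    pSer     = list(charge_delta = -2, radius_delta = 0.4,  contact_scale = 0, res_name = "SEP"),
    StoA     = list(charge_delta = 0,  radius_delta = -0.2, contact_scale = 0, res_name = "ALA"),
    StoD     = list(charge_delta = -1, radius_delta = 0,    contact_scale = 0, res_name = "ASP"),
    StoE     = list(charge_delta = -1, radius_delta = 0,    contact_scale = 0, res_name = "GLU"),
    CtoS     = list(charge_delta = 0,  radius_delta = 0,    contact_scale = 0, res_name = "SER"))
  if (!kind %in% names(tab)) stop("unknown modification kind: ", kind)
  structure(c(list(res_id = as.integer(res_id), kind = kind), tab[[kind]]),
            class = "site_modification")
}

#' Apply a site modification to a structure
#'
#' Returns a modified copy; the input structure is untouched. The site bead's
#' charge, radius and residue name are edited per the modification table, and
#' site contacts involving the bead have their depth scaled by
#' `contact_scale`.
#'
#' @param s a `cg_structure`.
#' @param m a [site_modification].
#' @return a new `cg_structure`.
#' @export
apply_modification <- function(s, m) {
  stopifnot(inherits(s, "cg_structure"), inherits(m, "site_modification"))
  idx <- which(s$atoms$res_id == m$res_id & s$atoms$atom_label == "CA")
  if (!length(idx))
    .dmd_stop(paste0("residue ", m$res_id, " not found"), "demonmd_invalid_residue")
  if (m$kind == "identity") return(s)
  s$atoms$charge[idx] <- s$atoms$charge[idx] + m$charge_delta
  s$atoms$radius[idx] <- s$atoms$radius[idx] + m$radius_delta
  if (!is.na(m$res_name)) s$atoms$res_name[idx] <- m$res_name
  if (nrow(s$contacts)) {
    hit <- (s$contacts$i %in% idx | s$contacts$j %in% idx) &
      s$contacts$kind == "site"
    s$contacts$depth[hit] <- s$contacts$depth[hit] * m$contact_scale
  }
  s
}

# signed dihedral (radians) for four points
.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
         n1[1] * b2[2] - n1[2] * b2[1])
  lb2 <- sqrt(sum(b2^2))
  if (lb2 < 1e-12) return(0)
  atan2(sum(m * n2) / lb2, sum(n1 * n2))
}

# chain angle triples and torsion quads from the bond list (assumes chain bonds)
.chain_tuples <- function(bonds, n) {
  if (!nrow(bonds)) return(list(angles = matrix(integer(0), 0, 3),
                                torsions = matrix(integer(0), 0, 4)))
  b <- bonds[order(bonds[, 1]), , drop = FALSE]
  nxt <- rep(NA_integer_, n)
  nxt[b[, 1]] <- b[, 2]
  i1 <- which(!is.na(nxt))
  i2 <- nxt[i1]; i3 <- ifelse(i2 <= n, nxt[i2], NA)
  ang <- cbind(i1, i2, i3)[!is.na(i3), , drop = FALSE]
  i4 <- ifelse(!is.na(i3), nxt[ifelse(is.na(i3), 1, i3)], NA)
  tor <- cbind(i1, i2, i3, i4)[!is.na(i3) & !is.na(i4), , drop = FALSE]
  list(angles = ang, torsions = tor)
}

#' Build an energy-evaluation context
#'
#' Precomputes the topology-dependent arrays consumed by the compiled energy
#' kernel: bonded tuples with reference geometry captured from `s`, the
#' nonbonded candidate pair list with 1-2/1-3 exclusions, elastic-network
#' springs among rigid-tagged beads, restraint arrays, site contacts and the
#' optional containment wall. Reusing a context across calls on the same
#' topology is what makes dynamics affordable; `energy()` and `forces()` build
#' one transparently.
#'
#' @param s a `cg_structure` (supplies the reference geometry).
#' @param p a [potential_spec].
#' @param r a [restraint_set] (or `NULL`).
#' @return an opaque context list for the compiled kernel.
#' @export
cg_context <- function(s, p, r = NULL) {
  stopifnot(inherits(s, "cg_structure"), inherits(p, "potential_spec"))
  if (is.null(r)) r <- restraint_set()
  n <- n_beads(s)
  xyz <- s$xyz
  bonds <- s$bonds
  tp <- .chain_tuples(bonds, n)

  ang <- tp$angles
  t0 <- if (nrow(ang)) vapply(seq_len(nrow(ang)), function(q) {
    v1 <- xyz[ang[q, 1], ] - xyz[ang[q, 2], ]
    v2 <- xyz[ang[q, 3], ] - xyz[ang[q, 2], ]
    acos(max(-1, min(1, sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)))))
  }, 0) else numeric(0)

  tor <- tp$torsions
  tor_i <- tor_j <- tor_k <- tor_l <- integer(0)
  tor_amp <- tor_per <- tor_phase <- numeric(0)
  if (nrow(tor)) {
    phi_ref <- vapply(seq_len(nrow(tor)), function(q)
      .dihedral(xyz[tor[q, 1], ], xyz[tor[q, 2], ], xyz[tor[q, 3], ],
                xyz[tor[q, 4], ]), 0)
    for (term in p$torsion) {
      tor_i <- c(tor_i, tor[, 1]); tor_j <- c(tor_j, tor[, 2])
      tor_k <- c(tor_k, tor[, 3]); tor_l <- c(tor_l, tor[, 4])
      tor_amp <- c(tor_amp, rep(term[1], nrow(tor)))
      tor_per <- c(tor_per, rep(term[2], nrow(tor)))
      # phase chosen so the reference dihedral is an energy minimum
      tor_phase <- c(tor_phase, term[2] * phi_ref - pi)
    }
  }

  # nonbonded candidate pairs: all pairs minus 1-2 and 1-3
  if (n >= 2) {
    ii <- rep.int(seq_len(n - 1L), (n - 1L):1L)
    jj <- sequence((n - 1L):1L) + ii
  } else ii <- jj <- integer(0)
  key <- function(a, b) (pmin(a, b) - 1) * n + pmax(a, b)
  excl <- key(bonds[, 1], bonds[, 2])
  if (nrow(ang)) excl <- c(excl, key(ang[, 1], ang[, 3]))
  keep <- !(key(ii, jj) %in% excl)
  ii <- ii[keep]; jj <- jj[keep]
  q <- s$atoms$charge; rad <- s$atoms$radius
  qq <- q[ii] * q[jj]
  sig <- p$lj_sigma * (rad[ii] + rad[jj]) / 3.8
  # drop pairs with neither LJ nor charge product (none by default; cheap guard)
  eps <- rep(p$lj_epsilon, length(ii))

  # elastic network on rigid-tagged beads
  en_i <- en_j <- integer(0); en_r0 <- numeric(0)
  rig <- which(s$rigid)
  if (length(rig) > 1) {
    d <- as.matrix(stats::dist(xyz[rig, , drop = FALSE]))
    w <- which(upper.tri(d) & d <= p$en_cutoff, arr.ind = TRUE)
    en_i <- rig[w[, 1]]; en_j <- rig[w[, 2]]; en_r0 <- d[w]
  }

  wall_r <- p$wall_r
  wall_center <- c(0, 0, 0)
  if (p$wall_k > 0 && is.na(wall_r)) {
    wall_center <- colMeans(xyz)
    wall_r <- max(sqrt(rowSums(sweep(xyz, 2, wall_center)^2))) + 5
  }

  list(n = n,
       bond_i = as.integer(bonds[, 1] - 1L), bond_j = as.integer(bonds[, 2] - 1L),
       bond_r0 = rep(p$bond_r0, nrow(bonds)), bond_k = rep(p$bond_k, nrow(bonds)),
       ang_i = as.integer(ang[, 1] - 1L), ang_j = as.integer(ang[, 2] - 1L),
       ang_k = as.integer(ang[, 3] - 1L), ang_t0 = t0,
       ang_ka = rep(p$angle_k, nrow(ang)),
       tor_i = as.integer(tor_i - 1L), tor_j = as.integer(tor_j - 1L),
       tor_k = as.integer(tor_k - 1L), tor_l = as.integer(tor_l - 1L),
       tor_amp = tor_amp, tor_per = tor_per, tor_phase = tor_phase,
       nb_i = as.integer(ii - 1L), nb_j = as.integer(jj - 1L),
       nb_qq = qq, nb_sig = sig, nb_eps = eps,
       cutoff = p$nonbonded_cutoff,
       diel_mode = if (p$dielectric == "distance") 1L else 0L,
       diel_eps = p$diel_eps,
       debye = if (is.finite(p$debye_length)) p$debye_length else -1,
       en_i = as.integer(en_i - 1L), en_j = as.integer(en_j - 1L),
       en_r0 = en_r0, en_k = rep(p$en_k, length(en_i)),
       rp_i = as.integer(r$positional$i - 1L),
       rp_xyz = cbind(r$positional$x, r$positional$y, r$positional$z),
       rp_k = r$positional$k,
       rr_i = as.integer(r$relative$i - 1L), rr_j = as.integer(r$relative$j - 1L),
       rr_r0 = r$relative$r0, rr_k = r$relative$k,
       rt_i = as.integer(r$torsional$i - 1L), rt_j = as.integer(r$torsional$j - 1L),
       rt_k = as.integer(r$torsional$k_ - 1L), rt_l = as.integer(r$torsional$l - 1L),
       rt_t0 = r$torsional$t0, rt_k_ = r$torsional$k,
       ct_i = as.integer(s$contacts$i - 1L), ct_j = as.integer(s$contacts$j - 1L),
       ct_r0 = s$contacts$r0, ct_depth = s$contacts$depth,
       ct_width = s$contacts$width,
       wall_k = p$wall_k, wall_r = if (is.na(wall_r)) 0 else wall_r,
       wall_center = wall_center,
       wall_sel = as.integer(seq_len(n) - 1L),
       mass = s$atoms$mass)
}

#' Potential energy of a structure
#'
#' Total CG energy and its per-term breakdown: bonded terms, nonbonded LJ and
#' electrostatics within the cutoff (1-2/1-3 excluded), elastic-network springs
#' among rigid-tagged pairs, restraints, site contacts and the containment
#' wall.
#'
#' @param s a `cg_structure`.
#' @param p a [potential_spec].
#' @param r a [restraint_set] (or `NULL`).
#' @param ctx optionally, a prebuilt [cg_context] (overrides `p`/`r`).
#' @return list with `total` (kcal/mol) and named `terms`.
#' @export
energy <- function(s, p = potential_spec(), r = NULL, ctx = NULL) {
  if (is.null(ctx)) ctx <- cg_context(s, p, r)
  out <- .cg_energy_forces(s$xyz, ctx, FALSE)
  list(total = out$total, terms = out$terms)
}

#' Forces on every bead
#'
#' Analytic negative gradient of [energy()], kcal/(mol A).
#'
#' @inheritParams energy
#' @return N x 3 matrix of forces.
#' @export
forces <- function(s, p = potential_spec(), r = NULL, ctx = NULL) {
  if (is.null(ctx)) ctx <- cg_context(s, p, r)
  .cg_energy_forces(s$xyz, ctx, TRUE)$forces
}

#' Elastic-network (ANM) normal modes
#'
#' Anisotropic-network-model Hessian on the Calpha beads with uniform springs
#' within `cutoff`, eigendecomposed; the six near-zero rigid-body modes are
#' dropped. Mode vectors are returned per bead (3N rows over the Calpha
#' subset).
#'
#' @param s a `cg_structure`.
#' @param cutoff spring cutoff, A.
#' @param n_modes number of non-trivial low-frequency modes to return.
#' @return list with `idx` (Calpha bead indices), `values` (eigenvalues,
#'   ascending) and `vectors` (3N x n_modes matrix).
#' @export
anm_modes <- function(s, cutoff = 10, n_modes = 6) {
  idx <- which(s$atoms$atom_label == "CA")
  nn <- length(idx)
  if (nn < 4) stop("too few Calpha beads for a mode calculation")
  xyz <- s$xyz[idx, , drop = FALSE]
  d <- as.matrix(stats::dist(xyz))
  H <- matrix(0, 3 * nn, 3 * nn)
  pr <- which(upper.tri(d) & d <= cutoff & d > 1e-6, arr.ind = TRUE)
  for (q in seq_len(nrow(pr))) {
    a <- pr[q, 1]; b <- pr[q, 2]
    dv <- xyz[a, ] - xyz[b, ]
    blk <- -tcrossprod(dv) / sum(dv^2)
    ia <- (3 * a - 2):(3 * a); ib <- (3 * b - 2):(3 * b)
    H[ia, ib] <- H[ia, ib] + blk
    H[ib, ia] <- H[ib, ia] + t(blk)
    H[ia, ia] <- H[ia, ia] - blk
    H[ib, ib] <- H[ib, ib] - blk
  }
  ev <- eigen(H, symmetric = TRUE)
  ord <- order(ev$values)
  vals <- ev$values[ord]; vecs <- ev$vectors[, ord, drop = FALSE]
  nz <- which(vals > max(1e-8, 1e-8 * max(abs(vals))))
  take <- nz[seq_len(min(n_modes, length(nz)))]
  list(idx = idx, values = vals[take], vectors = vecs[, take, drop = FALSE])
}
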