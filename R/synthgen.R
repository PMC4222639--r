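#' Synthetic system specification
#'
#' Defines a Parkin-like bead chain: total length, a domain plan assigning
#' contiguous residue ranges to a rigidity class, and the pseudo-bond length.
#' The default plan mirrors the Parkin domain map: a flexible N-terminal unit
#' plus linker (residues 1-140) and a rigid, restraint-stabilized core
#' (residues 141-465).
#'
#' @param n_residues chain length (>= 10).
#' @param domain_plan list of `list(range = c(first, last), class = "rigid" |
#'   "flexible")` tiling `1..n_residues`.
#' @param seed integer seed.
#' @param bond_length Calpha-Calpha pseudo-bond length, A.
#' @return an object of class `toy_spec`.
#' @export
toy_spec <- function(n_residues = 465, domain_plan = NULL, seed = 1,
                     bond_length = 3.8) {
  stopifnot(bond_length > 0)
  if (is.null(domain_plan)) {
    fl <- min(140, n_residues - 1)
    domain_plan <- list(list(range = c(1, fl), class = "flexible"),
                        list(range = c(fl + 1, n_residues), class = "rigid"))
  }
  covered <- sort(unlist(lapply(domain_plan, function(d)
    seq(d$range[1], d$range[2]))))
  if (!identical(covered, seq_len(n_residues)))
    stop("domain plan must tile 1..n_residues without gaps or overlaps")
  structure(list(n_residues = n_residues, domain_plan = domain_plan,
                 seed = seed, bond_length = bond_length), class = "toy_spec")
}

# solenoid helix: n beads, beads-per-turn ppt, pitch per turn, phase, center,
# direction dz (+1 up / -1 down); consecutive-bead chord == step
.solenoid <- function(n, ppt, pitch, step, center = c(0, 0, 0), z0 = 0,
                      dz = 1, phase = 0) {
  pb <- pitch / ppt                       # rise per bead
  chord_xy <- sqrt(max(step^2 - pb^2, 0.01))
  R <- chord_xy / (2 * sin(pi / ppt))
  i <- seq_len(n) - 1
  th <- phase + 2 * pi * i / ppt
  cbind(center[1] + R * cos(th), center[2] + R * sin(th),
        center[3] + z0 + dz * pb * i)
}

# planar circular arc from p0 to p1 with n steps of length `step`; bulges
# toward `lift` (unit-ish vector not parallel to the chord)
.arc_path <- function(p0, p1, n, step, lift) {
  ch <- p1 - p0
  c_len <- sqrt(sum(ch^2))
  if (c_len >= n * step) stop("arc anchors too far apart for the bead budget")
  u <- ch / c_len
  w <- lift - sum(lift * u) * u
  w <- w / sqrt(sum(w^2))
  f <- function(th) step * sin(th / 2) / sin(th / (2 * n)) - c_len
  th <- stats::uniroot(f, c(1e-4, 2 * pi - 1e-3), tol = 1e-10)$root
  R <- step / (2 * sin(th / (2 * n)))
  # circle centre: midpoint - w * sqrt(R^2 - (c/2)^2)
  mid <- (p0 + p1) / 2
  h <- sqrt(max(R^2 - (c_len / 2)^2, 0))
  ctr <- mid - w * h
  a0 <- atan2(sum((p0 - ctr) * w), sum((p0 - ctr) * u))
  pt <- function(a) ctr + R * (cos(a) * u + sin(a) * w)
  # sweep exactly th from a0, in whichever direction ends on p1
  a1 <- if (sum((pt(a0 + th) - p1)^2) < sum((pt(a0 - th) - p1)^2))
    a0 + th else a0 - th
  aa <- seq(a0, a1, length.out = n + 1)[-1]
  t(vapply(aa, pt, numeric(3)))
}

# serpentine wall in the plane x = x0: columns along z, spaced dy in y
.serpentine <- function(n, x0, y_start, dy, z_top, step, col_len) {
  out <- matrix(0, n, 3)
  for (k in seq_len(n)) {
    c_ <- (k - 1) %/% col_len
    p_ <- (k - 1) %% col_len
    zdir <- if (c_ %% 2 == 0) -1 else 1
    z <- if (zdir < 0) z_top - step * p_ else z_top - step * (col_len - 1) + step * p_
    out[k, ] <- c(x0, y_start + dy * c_, z)
  }
  out
}

#' Generate a synthetic Parkin-like structure
#'
#' Builds a self-avoiding Calpha bead chain realizing the domain plan. With
#' the default plan the geometry emulates the closed Parkin architecture at
#' coarse grain: a compact N-terminal (UBL-like) solenoid whose cleft face
#' (residues 1-4, 61-67) packs against a serpentine linker wall carrying
#' residues 95-128, a tethered rigid core solenoid below, a native
#' Ser65-to-linker-wall contact (Gaussian well) bridging the cleft, and unit
#' negative charges on the aspartate-like cleft residues 62 and 115 that bias
#' the walls apart once the bridge is lost. Rigid-plan beads are tagged for
#' elastic-network restraints. Reproducible for a fixed seed.
#'
#' @param spec a [toy_spec].
#' @return a `cg_structure` (protein beads only).
#' @export
make_parkin_like <- function(spec = toy_spec()) {
  stopifnot(inherits(spec, "toy_spec"))
  n <- spec$n_residues
  if (n < 10) stop("n_residues must be at least 10")
  set.seed(spec$seed)
  step <- spec$bond_length
  cls <- character(n)
  for (d in spec$domain_plan) cls[seq(d$range[1], d$range[2])] <- d$class
  parkin_mode <- n >= 141 && all(cls[1:140] == "flexible") &&
    all(cls[141:n] == "rigid")
  xyz <- if (parkin_mode) .parkin_geometry(n, step) else .generic_geometry(cls, step)
  xyz <- xyz + matrix(rnorm(3 * n, sd = 0.05), n, 3)   # break exact symmetries

  res_name <- rep("ALA", n)
  charge <- numeric(n)
  contacts <- NULL
  if (parkin_mode) {
    res_name[65] <- "SER"
    if (n >= 431) res_name[431] <- "CYS"
    res_name[c(62, 115)] <- "ASP"
    # acidic decoration of both cleft walls: with the Ser65 clamp intact the
    # closed state holds; once the clamp is lost the walls repel open
    res_name[c(18, 60, 108, 113)] <- "GLU"
    charge[c(62, 115, 18, 60, 108, 113)] <- -1
    # Native contacts of the closed state. (1) The Ser65 bridge clamps the
    # CoM1 wall segment (110-118) against the UBL cleft face and is lost in
    # every variant (the serine hydroxyl interaction survives none of them);
    # the cleft then opens by the linker wall bowing away, pushed by the
    # aspartate-like wall charges and, for pSer/D/E, by the site charge.
    # (2) Loose persistent tethers from the UBL underside to the core stand in
    # for the UBL-RING1 packing of the closed state, keeping the N-terminal
    # unit positioned over the cleft-metric timescale.
    nearest_of <- function(i, pool) {
      d <- sqrt(colSums((t(xyz[pool, , drop = FALSE]) - xyz[i, ])^2))
      c(j = pool[which.min(d)], r0 = max(min(d), 4.0))
    }
    # Ser65 pins the CoM1 wall triad (110, 111, 115); all three wells are
    # mediated by the serine site and lost together in every variant
    triad <- t(vapply(c(110, 111, 115), function(j) {
      c(j = j, r0 = max(sqrt(sum((xyz[65, ] - xyz[j, ])^2)), 4.0))
    }, numeric(2)))
    core_idx <- 141:n
    dcore <- vapply(1:76, function(i)
      min(colSums((t(xyz[core_idx, , drop = FALSE]) - xyz[i, ])^2)), 0)
    ubl_feet <- order(dcore)[1:3]
    feet <- t(vapply(ubl_feet, nearest_of, numeric(2), pool = core_idx))
    # Go-style fold network holding the UBL as a folded unit (the linker
    # stays an unstructured chain): all non-local intra-UBL pairs in contact
    # in the built fold
    du <- as.matrix(stats::dist(xyz[1:76, , drop = FALSE]))
    gp <- which(upper.tri(du) & du <= 8 & row(du) < col(du) - 2, arr.ind = TRUE)
    contacts <- rbind(
      data.frame(i = 65L, j = as.integer(triad[, "j"]), r0 = triad[, "r0"],
                 depth = 7.0, width = 1.5, kind = "site"),
      data.frame(i = as.integer(ubl_feet), j = as.integer(feet[, "j"]),
                 r0 = feet[, "r0"], depth = 3.0, width = 2.0, kind = "fold"),
      data.frame(i = as.integer(gp[, 1]), j = as.integer(gp[, 2]),
                 r0 = du[gp], depth = 2.0, width = 1.5, kind = "fold"))
  }
  atoms <- data.frame(serial = seq_len(n), res_id = seq_len(n),
                      res_name = res_name, atom_label = "CA", mass = 110,
                      charge = charge, radius = 1.9)
  cg_structure(atoms, xyz, rigid = cls == "rigid", contacts = contacts)
}

# closed-Parkin coarse geometry; n >= 141
.parkin_geometry <- function(n, step) {
  xyz <- matrix(0, n, 3)
  # UBL solenoid, cleft face at azimuth 0 (+x)
  xyz[1:76, ] <- .solenoid(76, ppt = 16, pitch = 6.0, step = step)
  # approach connector 77-94: arc from UBL top over +y to the serpentine start
  serp_xtop <- c(14.2, -13.5, 28.5)
  xyz[77:94, ] <- .arc_path(xyz[76, ], serp_xtop, 18, step, lift = c(0.3, 1, 0.6))
  # linker wall 95-128: serpentine at x = 14.2 facing the UBL cleft face
  xyz[95:128, ] <- .serpentine(34, x0 = 14.2, y_start = -13.5 + 4.5, dy = 4.5,
                               z_top = 28.5 - step, step = step, col_len = 8)
  xyz[95:128, 2] <- xyz[95:128, 2] - 4.5   # align first column under the start
  # tether 129-140 down to the core entry
  core_n <- n - 140
  core <- .solenoid(core_n, ppt = 18, pitch = 6.3, step = step,
                    center = c(7, 0, 0), z0 = -16, dz = -1,
                    phase = pi / 2)
  xyz[141:n, ] <- core
  # 13 steps whose final point is the core entry itself (bead 141)
  xyz[129:140, ] <- .arc_path(xyz[128, ], core[1, ], 13, step,
                              lift = c(1, 0.6, 0))[1:12, ]
  xyz
}

# generic plan: rigid ranges as compact solenoids, flexible ranges extended,
# laid out serially along +z with a lateral offset per segment
.generic_geometry <- function(cls, step) {
  n <- length(cls)
  xyz <- matrix(0, n, 3)
  segs <- rle(cls)
  ends <- cumsum(segs$lengths)
  starts <- c(1, head(ends, -1) + 1)
  cursor <- c(0, 0, 0)
  for (k in seq_along(segs$values)) {
    idx <- starts[k]:ends[k]
    m <- length(idx)
    if (segs$values[k] == "rigid" && m >= 8) {
      blk <- .solenoid(m, ppt = 10, pitch = 6.0, step = step)
    } else {
      # gentle extended sine to avoid exact collinearity
      i <- seq_len(m) - 1
      zig <- 0.6 * sin(i * 1.1)
      dzs <- sqrt(step^2 - (diff(c(zig, 0))[seq_len(m)])^2 * 0)  # keep simple
      blk <- cbind(zig, 0.6 * cos(i * 0.9), cumsum(c(0, rep(step, m - 1))))
    }
    blk <- sweep(blk, 2, blk[1, ])
    xyz[idx, ] <- sweep(blk, 2, cursor, `+`)
    cursor <- xyz[ends[k], ] + c(1.2, 1.2, step * 0.9) *
      c(1, -1, 1)^(k)                       # offset next segment
  }
  xyz
}

#' Solvation shell specification
#'
#' @param shell_depth shell depth from the protein surface, A; `NULL` draws
#'   once from 15-18 A (seeded).
#' @param water_density waters per 1000 A^3 of shell volume. The default is a
#'   desk-scale surrogate density: it provides water positions for hydration
#'   counting, not bulk-water physics.
#' @param ion_pairs count of +1/-1 ion pairs. The default is a token count:
#'   bulk 150 mM salt is represented by the screened Coulomb term of the
#'   potential, so explicit beads only sample local ion positions. `NULL`
#'   computes the full count a 150 mM concentration implies for the realized
#'   shell volume (only sensible with screening disabled).
#' @param seed integer seed.
#' @param r_excl protein-water clash distance, A.
#' @return an object of class `solvation_spec`.
#' @export
solvation_spec <- function(shell_depth = NULL, water_density = 1.0,
                           ion_pairs = 4, seed = 1, r_excl = 2.8) {
  if (!is.null(shell_depth) && shell_depth <= 0) stop("shell_depth must be > 0")
  if (water_density <= 0) stop("water_density must be > 0")
  structure(list(shell_depth = shell_depth, water_density = water_density,
                 ion_pairs = ion_pairs, seed = seed, r_excl = r_excl),
            class = "solvation_spec")
}

#' Add a solvation shell of point waters and ions
#'
#' Places water beads uniformly at random in the shell
#' `{x : r_excl < d(x, protein) <= shell_depth}` by rejection sampling against
#' overlap (with the protein and among solvent beads), then ion beads with
#' +1/-1 charges in equal counts, placed the same way. Reproducible per seed.
#'
#' @param s a `cg_structure`.
#' @param spec a [solvation_spec].
#' @return a new `cg_structure` with water and ion beads appended.
#' @export
solvate_shell <- function(s, spec = solvation_spec()) {
  stopifnot(inherits(s, "cg_structure"), inherits(spec, "solvation_spec"))
  set.seed(spec$seed)
  depth <- spec$shell_depth
  if (is.null(depth)) depth <- runif(1, 15, 18)
  pro <- s$xyz
  lo <- apply(pro, 2, min) - depth
  hi <- apply(pro, 2, max) + depth
  box_v <- prod(hi - lo)
  # shell volume by MC; then target water count from the density
  nmc <- 4000
  smp <- matrix(runif(3 * nmc), nmc, 3)
  smp <- sweep(sweep(smp, 2, hi - lo, `*`), 2, lo, `+`)
  mind <- .min_dist_to(smp, pro)
  in_shell <- mind > spec$r_excl & mind <= depth
  shell_v <- box_v * mean(in_shell)
  n_wat <- max(1, round(spec$water_density * shell_v / 1000))
  n_ion <- spec$ion_pairs
  # 150 mM => 9.03e-5 ions/A^3 over the realized shell volume, half are pairs
  if (is.null(n_ion)) n_ion <- max(1, round(0.5 * 9.03e-5 * shell_v))
  placed <- matrix(0, 0, 3)
  target <- n_wat + 2 * n_ion
  tries <- 0; max_tries <- min(200 * target, 60000)
  while (nrow(placed) < target && tries < max_tries) {
    batch <- min(512, max_tries - tries)
    tries <- tries + batch
    cand <- matrix(runif(3 * batch), batch, 3)
    cand <- sweep(sweep(cand, 2, hi - lo, `*`), 2, lo, `+`)
    md <- .min_dist_to(cand, pro)
    cand <- cand[md > spec$r_excl & md <= depth, , drop = FALSE]
    for (q in seq_len(nrow(cand))) {
      if (nrow(placed) >= target) break
      if (!nrow(placed) ||
          min(colSums((t(placed) - cand[q, ])^2)) > spec$r_excl^2)
        placed <- rbind(placed, cand[q, ])
    }
  }
  if (nrow(placed) < target)
    stop("solvent placement failed after bounded retries; lower water_density")
  n0 <- n_beads(s)
  r0 <- max(s$atoms$res_id)
  k <- nrow(placed)
  lab <- c(rep("W", n_wat), rep(c("NA", "CL"), n_ion))
  atoms <- data.frame(
    serial = n0 + seq_len(k), res_id = r0 + seq_len(k),
    res_name = c(rep("HOH", n_wat), rep(c("NA", "CL"), n_ion)),
    atom_label = lab,
    mass = c(rep(18.015, n_wat), rep(c(22.99, 35.45), n_ion)),
    charge = c(rep(0, n_wat), rep(c(1, -1), n_ion)),
    radius = c(rep(1.4, n_wat), rep(c(2.5, 2.4), n_ion)))
  out <- s
  out$atoms <- rbind(s$atoms, atoms)
  out$xyz <- rbind(s$xyz, placed)
  out$rigid <- c(s$rigid, rep(FALSE, k))
  attr(out, "solvation") <- list(shell_depth = depth, n_waters = n_wat,
                                 ion_pairs = n_ion, shell_volume = shell_v)
  out
}

# min distance from each row of A to any row of B
.min_dist_to <- function(A, B) {
  out <- numeric(nrow(A))
  bt <- t(B)
  for (i in seq_len(nrow(A))) out[i] <- sqrt(min(colSums((bt - A[i, ])^2)))
  out
}

#' Generate guidepost conformers along low-frequency modes
#'
#' Builds an elastic-network (ANM) mode basis on the Calpha network, forms a
#' fixed seeded mixture of the lowest non-trivial modes restricted to the
#' flexible region, and walks the structure outward in `n_posts - 1` evenly
#' spaced increments up to `amplitude` (RMS displacement over flexible beads),
#' energy-minimizing after each increment. The first guidepost is the
#' minimized input.
#'
#' @param s a `cg_structure` with at least one flexible (non-rigid) bead.
#' @param n_posts number of guideposts (>= 2).
#' @param amplitude total RMS displacement of the flexible region, A.
#' @param seed integer seed.
#' @param p a [potential_spec].
#' @param n_modes number of low modes mixed into the displacement direction.
#' @param min_iter per-post minimization iteration cap.
#' @return a `guidepost_set`: list of `cg_structure`s with attributes
#'   `rmsd_from_start` and `mode_weights`.
#' @export
generate_guideposts <- function(s, n_posts = 5, amplitude = 40, seed = 1,
                                p = potential_spec(), n_modes = 3,
                                min_iter = 150) {
  stopifnot(n_posts >= 2)
  if (amplitude <= 0) stop("amplitude must be positive")
  ca <- which(s$atoms$atom_label == "CA")
  flex <- ca[!s$rigid[ca]]
  if (!length(flex)) stop("structure has no flexible region to displace")
  set.seed(seed)
  modes <- anm_modes(s, cutoff = p$en_cutoff, n_modes = n_modes)
  w <- runif(ncol(modes$vectors), 0.3, 1) * sample(c(-1, 1), ncol(modes$vectors),
                                                   replace = TRUE)
  dir3 <- matrix(modes$vectors %*% w, ncol = 3, byrow = TRUE)  # per CA bead
  full <- matrix(0, n_beads(s), 3)
  full[modes$idx, ] <- dir3
  full[setdiff(seq_len(n_beads(s)), flex), ] <- 0
  rmsn <- sqrt(mean(rowSums(full[flex, , drop = FALSE]^2)))
  full <- full / rmsn
  ctx <- cg_context(s, p)
  posts <- vector("list", n_posts)
  cur <- minimize(s, p, tol = 0.2, max_iter = 2 * min_iter, ctx = ctx)
  posts[[1]] <- cur
  dstep <- amplitude / (n_posts - 1)
  # The linearized mode field is realized as a finite hinge rotation of the
  # flexible region (the motion the low mode linearizes): fit the rigid
  # rotation rate about the flexible/rigid boundary that best reproduces the
  # mode field, then walk that rotation in ~1 A sub-increments with light
  # relaxation. A pure linear displacement of this size would be retracted by
  # the minimizer through bond strain.
  rig <- which(s$rigid)
  if (length(rig)) {
    ft <- t(s$xyz[flex, , drop = FALSE])
    near <- rig[vapply(rig, function(i)
      min(colSums((ft - s$xyz[i, ])^2)) <= 100, TRUE)]
    hinge <- colMeans(s$xyz[if (length(near)) near else rig, , drop = FALSE])
  } else hinge <- colMeans(s$xyz)
  dmat <- sweep(s$xyz[flex, , drop = FALSE], 2, hinge)
  vfield <- full[flex, , drop = FALSE]
  M <- sum(rowSums(dmat^2)) * diag(3) - crossprod(dmat)
  rhs <- colSums(cbind(dmat[, 2] * vfield[, 3] - dmat[, 3] * vfield[, 2],
                       dmat[, 3] * vfield[, 1] - dmat[, 1] * vfield[, 3],
                       dmat[, 1] * vfield[, 2] - dmat[, 2] * vfield[, 1]))
  omega <- solve(M + 1e-8 * diag(3), rhs)
  axis <- omega / sqrt(sum(omega^2))
  rot_flex <- function(xyz, theta) {
    K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                  -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
    R <- diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
    xyz[flex, ] <- sweep(sweep(xyz[flex, , drop = FALSE], 2, hinge) %*% t(R),
                         2, hinge, `+`)
    xyz
  }
  rot_scale <- function(xyz) {             # RMS speed of flex beads, A per rad
    d <- sweep(xyz[flex, , drop = FALSE], 2, hinge)
    cr <- cbind(axis[2] * d[, 3] - axis[3] * d[, 2],
                axis[3] * d[, 1] - axis[1] * d[, 3],
                axis[1] * d[, 2] - axis[2] * d[, 1])
    sqrt(mean(rowSums(cr^2)))
  }
  sub <- 1.0                               # A RMS per sub-increment
  sgn <- {                                 # pick the rotation sense that
    e2 <- vapply(c(1, -1), function(sg) {  # relaxes to the lower energy
      tmp <- cur
      tmp$xyz <- rot_flex(tmp$xyz, sg * sub / rot_scale(tmp$xyz))
      attr(minimize(tmp, p, tol = 1, max_iter = 10, ctx = ctx),
           "minimize_info")$energy
    }, 0)
    c(1, -1)[which.min(e2)]
  }
  for (k in 2:n_posts) {
    nsub <- max(1, ceiling(dstep / sub))
    for (q in seq_len(nsub)) {
      cur$xyz <- rot_flex(cur$xyz, sgn * (dstep / nsub) / rot_scale(cur$xyz))
      cur <- minimize(cur, p, tol = 1.0, max_iter = 10, ctx = ctx)
    }
    cur <- minimize(cur, p, tol = 0.3, max_iter = min_iter, ctx = ctx)
    posts[[k]] <- cur
  }
  rmsd0 <- vapply(posts, function(x) rmsd_cv(x, posts[[1]]), 0)
  structure(posts, class = "guidepost_set", rmsd_from_start = rmsd0,
            mode_weights = w)
}

#' @export
print.guidepost_set <- function(x, ...) {
  cat(sprintf("guidepost_set: %d posts, Calpha RMSD from start: %s A\n",
              length(x), paste(sprintf("%.2f", attr(x, "rmsd_from_start")),
                               collapse = ", ")))
  invisible(x)
}
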