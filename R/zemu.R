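#' Zone specification for mutant equilibration
#'
#' A mutation site defines a small flexibility zone (the site plus
#' `flex_halfwidth` residues on each side, 5 residues by default) treated in
#' torsion space while the remainder of the protein stays rigid, and an
#' enclosing physics zone of all residues within `physics_cutoff` of the
#' flexible residues inside which nonbonded terms are evaluated.
#' `inertia_scale` is recorded for provenance: the torsion-space minimizer
#' used here has no dynamics, so the factor is intentionally inert.
#'
#' @param site mutation residue id.
#' @param flex_halfwidth residues on each side of the site (default 2).
#' @param physics_cutoff physics-zone cutoff, A (default 12).
#' @param inertia_scale recorded scaling factor for fast-spinning small groups
#'   (default 11.0; no effect in this implementation).
#' @return an object of class `zone_spec`.
#' @export
zone_spec <- function(site, flex_halfwidth = 2, physics_cutoff = 12,
                      inertia_scale = 11.0) {
  stopifnot(flex_halfwidth >= 0, physics_cutoff > 0)
  structure(list(site = as.integer(site), flex_halfwidth = flex_halfwidth,
                 physics_cutoff = physics_cutoff, inertia_scale = inertia_scale),
            class = "zone_spec")
}

#' Flexibility zone around a mutation site
#'
#' Residues `[site - flex_halfwidth, site + flex_halfwidth]` clipped to the
#' chain bounds; clipping keeps at least 3 residues at the termini.
#'
#' @param s a `cg_structure`.
#' @param spec a [zone_spec].
#' @return a `cg_selection` named `flex_zone`.
#' @export
flexibility_zone <- function(s, spec) {
  stopifnot(inherits(s, "cg_structure"), inherits(spec, "zone_spec"))
  res <- sort(unique(s$atoms$res_id[s$atoms$atom_label == "CA"]))
  if (!spec$site %in% res)
    .dmd_stop(paste0("mutation site ", spec$site, " not in the chain"),
              "demonmd_invalid_residue")
  zone <- seq(spec$site - spec$flex_halfwidth, spec$site + spec$flex_halfwidth)
  zone <- intersect(zone, res)
  if (length(zone) < 3) {                 # termini: keep the zone >= 3 residues
    pos <- match(spec$site, res)
    lo <- max(1, pos - spec$flex_halfwidth)
    hi <- min(length(res), pos + spec$flex_halfwidth)
    while (hi - lo + 1 < min(3, length(res))) {
      if (lo > 1) lo <- lo - 1 else hi <- min(length(res), hi + 1)
    }
    zone <- res[lo:hi]
  }
  cg_selection("flex_zone", zone)
}

#' Physics zone enclosing a flexibility zone
#'
#' All residues having any bead within `cutoff` of any flexibility-zone bead;
#' always a superset of the flexibility zone.
#'
#' @param s a `cg_structure`.
#' @param flex a `cg_selection` (the flexibility zone).
#' @param cutoff distance cutoff, A.
#' @return a `cg_selection` named `physics_zone`.
#' @export
physics_zone <- function(s, flex, cutoff = 12) {
  stopifnot(inherits(s, "cg_structure"), inherits(flex, "cg_selection"))
  fidx <- apply_selection(s, flex)
  ft <- t(s$xyz[fidx, , drop = FALSE])
  keep <- vapply(seq_len(n_beads(s)), function(i)
    min(colSums((ft - s$xyz[i, ])^2)) <= cutoff^2, TRUE)
  res <- sort(unique(c(s$atoms$res_id[keep], flex$res_ids)))
  cg_selection("physics_zone", res)
}

# context restricted to the physics zone: nonbonded pairs outside are dropped
.zone_context <- function(s, p, physics) {
  ctx <- cg_context(s, p)
  zidx <- apply_selection(s, physics) - 1L      # 0-based for the kernel
  keep <- ctx$nb_i %in% zidx & ctx$nb_j %in% zidx
  ctx$nb_i <- ctx$nb_i[keep]; ctx$nb_j <- ctx$nb_j[keep]
  ctx$nb_qq <- ctx$nb_qq[keep]; ctx$nb_sig <- ctx$nb_sig[keep]
  ctx$nb_eps <- ctx$nb_eps[keep]
  ctx
}

#' Torsion-space equilibration of a flexibility zone
#'
#' Minimizes the energy over the pseudo-torsions internal to the flexibility
#' zone only; every coordinate outside the zone is frozen, and nonbonded terms
#' are evaluated only within the physics zone. Torsion rotations move only
#' zone beads downstream of the rotated bond; the pseudo-bond linking the zone
#' to the rigid remainder acts as the closure restraint.
#'
#' @param s a `cg_structure`.
#' @param flex flexibility-zone `cg_selection`.
#' @param physics physics-zone `cg_selection`.
#' @param p a [potential_spec].
#' @param maxit optimizer iteration budget.
#' @param ctx optional physics-zone evaluation context carrying the bonded
#'   reference geometry (default: built from `s` itself; pass a context built
#'   on a reference structure to relax toward that reference).
#' @return the equilibrated `cg_structure`, with attribute `zone_info` (list:
#'   `energy_start`, `energy_end`, `iterations`).
#' @export
equilibrate_zone <- function(s, flex, physics, p = potential_spec(),
                             maxit = 200, ctx = NULL) {
  stopifnot(inherits(s, "cg_structure"))
  if (is.null(ctx)) ctx <- .zone_context(s, p, physics)
  chain <- which(s$atoms$atom_label == "CA")
  zidx <- intersect(apply_selection(s, flex), chain)
  pos <- match(zidx, chain)
  # rotatable bonds: (z[k], z[k+1]) pairs internal to the zone with movable tail
  axes <- list()
  for (q in seq_len(max(0, length(pos) - 1))) {
    if (pos[q + 1] != pos[q] + 1) next     # zone gap: no contiguous bond
    if (q + 2 > length(zidx)) next         # no zone beads downstream to move
    axes[[length(axes) + 1]] <- list(a = zidx[q], b = zidx[q + 1],
                                     moved = zidx[(q + 2):length(zidx)])
  }
  e0 <- .cg_energy_forces(s$xyz, ctx, FALSE)$total
  if (!length(axes)) {
    attr(s, "zone_info") <- list(energy_start = e0, energy_end = e0,
                                 iterations = 0L)
    return(s)
  }
  base_xyz <- s$xyz
  build <- function(theta) {
    xyz <- base_xyz
    for (q in seq_along(axes)) {
      ax <- axes[[q]]
      if (abs(theta[q]) > 1e-12)
        xyz <- .rotate_about_bond(xyz, ax$a, ax$b, ax$moved, theta[q])
    }
    xyz
  }
  fn <- function(theta) .cg_energy_forces(build(theta), ctx, FALSE)$total
  opt <- stats::optim(rep(0, length(axes)), fn, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-10))
  out <- s
  if (opt$value <= e0) {
    out$xyz <- build(opt$par)
    e1 <- opt$value
  } else e1 <- e0                          # keep the start if no improvement
  attr(out, "zone_info") <- list(energy_start = e0, energy_end = e1,
                                 iterations = opt$counts[["function"]])
  out
}

#' Zone-equilibrated mutation ddG
#'
#' Equilibrates the wild-type flexibility zone and scores `dG_wt` as the CG
#' energy of the physics zone; applies the modification, re-equilibrates, and
#' scores `dG_mut`; reports `ddG = dG_wt - dG_mut`. The CG physics-zone energy
#' stands in for a knowledge-based unfolding score: formula structure, zone
#' mechanics and sign behavior carry over, absolute magnitudes do not.
#'
#' @param s a `cg_structure`.
#' @param m a [site_modification].
#' @param spec a [zone_spec] (`NULL`: built from `m$res_id`).
#' @param p a [potential_spec].
#' @param maxit per-equilibration optimizer budget.
#' @param equilibrate set `FALSE` to score both states in the fixed input
#'   geometry (no zone rearrangement); isolates the parameter-edit energetics.
#' @return a `ddg_result`: list with `dG_wt`, `dG_mut`, `ddG` (kcal/mol), zone
#'   sizes and equilibration iteration counts.
#' @export
ddg_mutation <- function(s, m, spec = NULL, p = potential_spec(), maxit = 200,
                         equilibrate = TRUE) {
  stopifnot(inherits(m, "site_modification"))
  if (is.null(spec)) spec <- zone_spec(m$res_id)
  flex <- flexibility_zone(s, spec)
  phys <- physics_zone(s, flex, spec$physics_cutoff)
  score <- function(x) .cg_energy_forces(x$xyz, .zone_context(x, p, phys),
                                         FALSE)$total
  wt <- if (equilibrate) equilibrate_zone(s, flex, phys, p, maxit) else s
  dG_wt <- score(wt)
  it_wt <- if (equilibrate) attr(wt, "zone_info")$iterations else 0L
  mut <- apply_modification(s, m)
  if (equilibrate) mut <- equilibrate_zone(mut, flex, phys, p, maxit)
  dG_mut <- score(mut)
  it_mut <- if (equilibrate) attr(mut, "zone_info")$iterations else 0L
  structure(list(dG_wt = dG_wt, dG_mut = dG_mut, ddG = dG_wt - dG_mut,
                 site = m$res_id, kind = m$kind,
                 n_flex = length(flex$res_ids), n_physics = length(phys$res_ids),
                 iterations = c(wt = it_wt, mut = it_mut)),
            class = "ddg_result")
}

#' @export
print.ddg_result <- function(x, ...) {
  cat(sprintf("ddG(%s at %d) = %.4f kcal/mol (dG_wt %.4f, dG_mut %.4f; flex %d, physics %d residues)\n",
              x$kind, x$site, x$ddG, x$dG_wt, x$dG_mut, x$n_flex, x$n_physics))
  invisible(x)
}

#' FoldX-style interaction ddG decomposition
#'
#' Literal evaluation of
#' `ddG_ab = dG_ab - (dG_a + dG_b) + dG_kon + dS_sc`
#' with CG energies for the three `dG` terms; `dG_kon` (electrostatic
#' association contribution) and `dS_sc` (side-chain entropy loss) are
#' supplied by the caller and default to 0.
#'
#' @param ab_complex a `cg_structure` holding the complex.
#' @param a,b `cg_selection`s that partition the complex's residues.
#' @param dG_kon,dS_sc auxiliary terms, kcal/mol.
#' @param p a [potential_spec].
#' @return interaction ddG, kcal/mol, with attribute `terms`.
#' @export
ddg_interaction <- function(ab_complex, a, b, dG_kon = 0, dS_sc = 0,
                            p = potential_spec()) {
  ia <- apply_selection(ab_complex, a)
  ib <- apply_selection(ab_complex, b)
  if (length(intersect(ia, ib)) || length(union(ia, ib)) != n_beads(ab_complex))
    stop("selections a and b must partition the complex's beads")
  sub <- function(idx) {
    at <- ab_complex$atoms[idx, , drop = FALSE]
    keep_bonds <- ab_complex$bonds[, 1] %in% idx & ab_complex$bonds[, 2] %in% idx
    bonds <- matrix(match(ab_complex$bonds[keep_bonds, ], idx),
                    ncol = 2)
    ct <- ab_complex$contacts
    ctk <- ct$i %in% idx & ct$j %in% idx
    ct <- ct[ctk, , drop = FALSE]
    ct$i <- match(ct$i, idx); ct$j <- match(ct$j, idx)
    cg_structure(at, ab_complex$xyz[idx, , drop = FALSE],
                 chain_id = ab_complex$chain_id,
                 rigid = ab_complex$rigid[idx], bonds = bonds, contacts = ct)
  }
  dG_ab <- energy(ab_complex, p)$total
  dG_a <- energy(sub(ia), p)$total
  dG_b <- energy(sub(ib), p)$total
  out <- dG_ab - (dG_a + dG_b) + dG_kon + dS_sc
  attr(out, "terms") <- c(dG_ab = dG_ab, dG_a = dG_a, dG_b = dG_b,
                          dG_kon = dG_kon, dS_sc = dS_sc)
  out
}

#' Batch ddG over a mutation table
#'
#' @param s a `cg_structure`.
#' @param mutations data.frame with columns `res_id` and `kind`.
#' @param p a [potential_spec].
#' @param maxit per-equilibration optimizer budget.
#' @return tibble: one row per mutation with `dG_wt`, `dG_mut`, `ddG`.
#' @export
ddg_batch <- function(s, mutations, p = potential_spec(), maxit = 200) {
  rows <- lapply(seq_len(nrow(mutations)), function(k) {
    m <- site_modification(mutations$res_id[k], mutations$kind[k])
    r <- ddg_mutation(s, m, p = p, maxit = maxit)
    tibble::tibble(res_id = m$res_id, kind = m$kind, dG_wt = r$dG_wt,
                   dG_mut = r$dG_mut, ddG = r$ddG)
  })
  do.call(rbind, rows)
}
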