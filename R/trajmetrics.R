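#' Metric series container
#'
#' A `(time, value)` series for a trajectory metric, as a tibble with `name`
#' and `units` attributes. Times are in ps and must be strictly increasing.
#'
#' @param times numeric vector, ps.
#' @param values numeric vector, same length.
#' @param name metric name.
#' @param units one of `"A"`, `"A^2"`, `"count"`, `"degrees"`.
#' @return a tibble of class `metric_series`.
#' @export
metric_series <- function(times, values, name, units) {
  if (length(times) != length(values)) stop("times and values lengths differ")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  out <- tibble::tibble(time = as.numeric(times), value = as.numeric(values))
  attr(out, "name") <- name
  attr(out, "units") <- units
  class(out) <- c("metric_series", class(out))
  out
}

#' Write a metric series as CSV (with a unit-annotated header) or JSON
#' @param ms a [metric_series].
#' @param path output path; extension `.json` selects JSON, else CSV.
#' @return invisibly, `path`.
#' @export
write_metric_series <- function(ms, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(name = attr(ms, "name"), units = attr(ms, "units"),
                              time_ps = ms$time, value = ms$value),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    hdr <- sprintf("# metric: %s; units: %s; time in ps", attr(ms, "name"),
                   attr(ms, "units"))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    utils::write.csv(as.data.frame(ms[c("time", "value")]), con,
                     row.names = FALSE)
  }
  invisible(path)
}

# evaluate a per-frame scalar over a trajectory -> metric_series
.traj_series <- function(traj, fun, name, units) {
  vals <- vapply(traj$frames, fun, 0)
  metric_series(traj$times, vals, name, units)
}

#' Center-of-mass distance between two residue selections
#'
#' Euclidean distance between the (mass- or geometric-) weighted centroids of
#' two disjoint selections; the cleft-width metric when used with the CoM1 and
#' CoM2 probe sets.
#'
#' @param s a `cg_structure` (or a trajectory frame via `xyz`).
#' @param selA,selB disjoint `cg_selection`s.
#' @param weighting `"mass"` or `"geometric"`.
#' @param xyz optional coordinate override (N x 3).
#' @return distance in Angstrom.
#' @export
com_distance <- function(s, selA, selB, weighting = c("mass", "geometric"),
                         xyz = NULL) {
  weighting <- match.arg(weighting)
  if (length(intersect(selA$res_ids, selB$res_ids)))
    stop("selections overlap: centre-of-mass distance requires disjoint sets")
  ia <- apply_selection(s, selA)
  ib <- apply_selection(s, selB)
  if (is.null(xyz)) xyz <- s$xyz
  w <- if (weighting == "mass") s$atoms$mass else rep(1, n_beads(s))
  ca <- colSums(xyz[ia, , drop = FALSE] * w[ia]) / sum(w[ia])
  cb <- colSums(xyz[ib, , drop = FALSE] * w[ib]) / sum(w[ib])
  sqrt(sum((ca - cb)^2))
}

#' Center-of-mass distance series over a trajectory
#' @param traj a `cg_trajectory`.
#' @inheritParams com_distance
#' @return a [metric_series] in Angstrom.
#' @export
com_distance_series <- function(traj, selA, selB,
                                weighting = c("mass", "geometric")) {
  weighting <- match.arg(weighting)
  s <- traj$topology
  .traj_series(traj, function(fr) com_distance(s, selA, selB, weighting,
                                               xyz = fr),
               paste0("com_distance_", selA$name, "_", selB$name), "A")
}

# golden-spiral unit sphere points
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' For each bead, the fraction of `n_sphere_points` quadrature points on the
#' sphere of radius `r_i + probe` lying outside every neighbour's expanded
#' sphere, times `4 pi (r_i + probe)^2`.
#'
#' @param s a `cg_structure`.
#' @param probe probe radius, A (water, 1.4).
#' @param n_sphere_points quadrature points per bead (>= 16).
#' @param sel optional `cg_selection`: beads whose area is computed (neighbour
#'   occlusion always uses the full structure). Water/ion beads are excluded
#'   as occluders and targets unless selected explicitly.
#' @return numeric vector of per-bead areas (A^2) over the targeted beads,
#'   with names `res_id:atom_label` and attribute `total`.
#' @export
sasa <- function(s, probe = 1.4, n_sphere_points = 960, sel = NULL) {
  if (n_sphere_points < 16) stop("n_sphere_points must be at least 16")
  solute <- which(!s$atoms$atom_label %in% c("W", "NA", "CL"))
  targets <- if (is.null(sel)) solute else apply_selection(s, sel)
  occl <- union(solute, targets)
  pts <- .sphere_points(n_sphere_points)
  xyz <- s$xyz
  rad <- s$atoms$radius + probe
  out <- numeric(length(targets))
  ot <- xyz[occl, , drop = FALSE]
  orad <- rad[occl]
  for (q in seq_along(targets)) {
    i <- targets[q]
    ri <- rad[i]
    d2 <- colSums((t(ot) - xyz[i, ])^2)
    nb <- which(d2 < (ri + orad)^2 & d2 > 1e-12)
    if (!length(nb)) { out[q] <- 4 * pi * ri^2; next }
    sp <- sweep(pts * ri, 2, xyz[i, ], `+`)
    exposed <- rep(TRUE, n_sphere_points)
    for (j in nb) {
      if (!any(exposed)) break
      dj <- colSums((t(sp[exposed, , drop = FALSE]) - ot[j, ])^2)
      exposed[exposed] <- dj > orad[j]^2
    }
    out[q] <- 4 * pi * ri^2 * mean(exposed)
  }
  names(out) <- paste0(s$atoms$res_id[targets], ":", s$atoms$atom_label[targets])
  attr(out, "total") <- sum(out)
  out
}

#' SASA series for a selection over a trajectory
#' @param traj a `cg_trajectory`.
#' @param sel a `cg_selection`.
#' @inheritParams sasa
#' @return a [metric_series] in A^2 (summed over the selection).
#' @export
sasa_series <- function(traj, sel, probe = 1.4, n_sphere_points = 240) {
  s <- traj$topology
  .traj_series(traj, function(fr) {
    s$xyz <- fr
    attr(sasa(s, probe, n_sphere_points, sel), "total")
  }, paste0("sasa_", sel$name), "A^2")
}

#' Count waters within a pocket
#'
#' Number of water beads within `cutoff` of any pocket-residue bead, each
#' water counted once. A frame without waters yields 0 with a notice (not an
#' error).
#'
#' @param s a `cg_structure` (a trajectory frame via `xyz`).
#' @param pocket a `cg_selection` of pocket residues.
#' @param cutoff distance cutoff, A.
#' @param xyz optional coordinate override.
#' @return integer count.
#' @export
count_pocket_waters <- function(s, pocket, cutoff = 5.0, xyz = NULL) {
  if (is.null(xyz)) xyz <- s$xyz
  wat <- which(s$atoms$atom_label == "W")
  if (!length(wat)) {
    message("no water beads in frame; pocket water count is 0")
    return(0L)
  }
  if (cutoff <= 0) return(0L)
  pk <- apply_selection(s, pocket)
  pk <- setdiff(pk, wat)
  pt <- t(xyz[pk, , drop = FALSE])
  sum(vapply(wat, function(w) min(colSums((pt - xyz[w, ])^2)) <= cutoff^2, TRUE))
}

#' Pocket water count series over a trajectory
#' @param traj a `cg_trajectory`.
#' @inheritParams count_pocket_waters
#' @return a [metric_series] of counts.
#' @export
pocket_waters_series <- function(traj, pocket, cutoff = 5.0) {
  s <- traj$topology
  .traj_series(traj, function(fr)
    suppressMessages(count_pocket_waters(s, pocket, cutoff, xyz = fr)),
    paste0("pocket_waters_", pocket$name), "count")
}

# resolve a (res_id, label) probe to exactly one bead index
.resolve_probe <- function(s, probe) {
  res <- as.integer(probe[[1]])
  lab <- if (length(probe) > 1) probe[[2]] else "CA"
  idx <- which(s$atoms$res_id == res & s$atoms$atom_label == lab)
  if (length(idx) != 1)
    stop("probe (", res, ", ", lab, ") resolves to ", length(idx), " beads")
  idx
}

#' Distance between two named beads
#'
#' @param s a `cg_structure`.
#' @param probeA,probeB probes as `list(res_id, atom_label)` (label defaults
#'   to `"CA"`).
#' @param xyz optional coordinate override.
#' @return distance in Angstrom.
#' @export
pair_distance <- function(s, probeA, probeB, xyz = NULL) {
  ia <- .resolve_probe(s, probeA)
  ib <- .resolve_probe(s, probeB)
  if (is.null(xyz)) xyz <- s$xyz
  sqrt(sum((xyz[ia, ] - xyz[ib, ])^2))
}

#' Pair-distance series over a trajectory
#' @param traj a `cg_trajectory`.
#' @inheritParams pair_distance
#' @return a [metric_series] in Angstrom.
#' @export
pair_distance_series <- function(traj, probeA, probeB) {
  s <- traj$topology
  .traj_series(traj, function(fr) pair_distance(s, probeA, probeB, xyz = fr),
               paste0("dist_", probeA[[1]], "_", probeB[[1]]), "A")
}

#' RMSD series against a reference
#'
#' Per-frame Kabsch superposition RMSD over a selection (shares the collective
#' variable implementation).
#'
#' @param traj a `cg_trajectory`.
#' @param ref reference `cg_structure`.
#' @param sel a `cg_selection`, or `NULL` for all Calpha beads.
#' @return a [metric_series] in Angstrom.
#' @export
rmsd_series <- function(traj, ref, sel = NULL) {
  s <- traj$topology
  ib <- .cv_indices(ref, sel)
  ia <- .cv_indices(s, sel)
  B <- ref$xyz[ib, , drop = FALSE]
  .traj_series(traj, function(fr) .kabsch_rmsd(B, fr[ia, , drop = FALSE]),
               paste0("rmsd_", if (is.null(sel)) "calpha" else sel$name), "A")
}

#' Root-mean-square fluctuation per residue
#'
#' Frames are superposed (on the selection) onto the trajectory mean
#' structure, iterated twice; RMSF is each bead's root-mean-square deviation
#' from its time-mean position.
#'
#' @param traj a `cg_trajectory`.
#' @param sel a `cg_selection`, or `NULL` for all Calpha beads.
#' @return tibble: `res_id`, `rmsf` (A).
#' @export
rmsf <- function(traj, sel = NULL) {
  s <- traj$topology
  idx <- .cv_indices(s, sel)
  coords <- lapply(traj$frames, function(fr) fr[idx, , drop = FALSE])
  mean_x <- Reduce(`+`, coords) / length(coords)
  for (it in 1:2) {
    coords <- lapply(coords, function(x) .kabsch_align(mean_x, x))
    mean_x <- Reduce(`+`, coords) / length(coords)
  }
  dev2 <- Reduce(`+`, lapply(coords, function(x) rowSums((x - mean_x)^2))) /
    length(coords)
  tibble::tibble(res_id = s$atoms$res_id[idx], rmsf = sqrt(dev2))
}

#' Pseudo phi/psi backbone dihedrals
#'
#' Signed dihedrals over consecutive Calpha quadruples, in degrees within
#' (-180, 180]: for residue i, phi uses beads (i-2, i-1, i, i+1) and psi uses
#' (i-1, i, i+1, i+2).
#'
#' @param s a `cg_structure`.
#' @return tibble: `res_id`, `phi`, `psi` (degrees; `NA` where undefined).
#' @export
phi_psi <- function(s) {
  chain <- which(s$atoms$atom_label == "CA")
  nn <- length(chain)
  if (nn < 4) stop("need at least 4 backbone beads for dihedrals")
  dih <- function(a, b, c, d)
    .dihedral(s$xyz[a, ], s$xyz[b, ], s$xyz[c, ], s$xyz[d, ]) * 180 / pi
  phi <- psi <- rep(NA_real_, nn)
  for (q in seq_len(nn)) {
    if (q >= 3 && q + 1 <= nn)
      phi[q] <- dih(chain[q - 2], chain[q - 1], chain[q], chain[q + 1])
    if (q >= 2 && q + 2 <= nn)
      psi[q] <- dih(chain[q - 1], chain[q], chain[q + 1], chain[q + 2])
  }
  # map to (-180, 180]
  wrap <- function(x) ifelse(!is.na(x) & x <= -180, x + 360, x)
  tibble::tibble(res_id = s$atoms$res_id[chain], phi = wrap(phi), psi = wrap(psi))
}
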