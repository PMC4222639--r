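# Kabsch superposition RMSD between two n x 3 coordinate sets
.kabsch_rmsd <- function(A, B) {
  A <- sweep(A, 2, colMeans(A))
  B <- sweep(B, 2, colMeans(B))
  H <- crossprod(A, B)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  ssd <- sum(A^2) + sum(B^2) - 2 * sum(sv$d * c(1, 1, d))
  sqrt(max(0, ssd) / nrow(A))
}

# Kabsch rotation aligning B onto A (both centred); returns aligned B.
# With H = B0' A0 = U S V', the optimal rotation applied as B0 %*% R is
# R = U diag(1, 1, d) V' with d correcting improper rotations.
.kabsch_align <- function(A, B) {
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  H <- crossprod(B0, A0)
  sv <- svd(H)
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  sweep(B0 %*% R, 2, ca, `+`)
}

#' RMSD collective variable
#'
#' Optimal-superposition (Kabsch) root-mean-square deviation between a
#' structure and a reference over a residue selection (default: all Calpha
#' beads), superposing on the same selection.
#'
#' @param s a `cg_structure`.
#' @param ref reference `cg_structure`.
#' @param sel a `cg_selection`, or `NULL` for all Calpha beads.
#' @return RMSD in Angstrom.
#' @export
rmsd_cv <- function(s, ref, sel = NULL) {
  ia <- .cv_indices(s, sel); ib <- .cv_indices(ref, sel)
  if (length(ia) != length(ib))
    stop("selection resolves to different bead counts in structure and reference")
  .kabsch_rmsd(ref$xyz[ib, , drop = FALSE], s$xyz[ia, , drop = FALSE])
}

.cv_indices <- function(s, sel) {
  if (is.null(sel)) return(which(s$atoms$atom_label == "CA"))
  apply_selection(s, sel)
}

#' Maxwell's-demon run configuration
#'
#' The demon watches an RMSD collective variable (CV) to a guidepost: unbiased
#' MD sprints of randomized length are accepted only when the CV does not rise
#' by more than `accept_tol`; rejected sprints are discarded and thermal
#' velocities redrawn. Varying the sprint length guards against local wells.
#'
#' @param md an [md_config] providing the sprint integrator settings (its
#'   `n_steps` is ignored).
#' @param cv_selection `cg_selection` for the CV, `NULL` = all Calpha.
#' @param sprint_min,sprint_max sprint length bounds, steps (drawn uniformly).
#' @param accept_tol maximum tolerated CV rise per accepted sprint, A.
#' @param success_radius stop once CV falls to this value, A; 0 disables the
#'   stop so the run always uses `max_sprints` sprints.
#' @param max_sprints sprint cap per run.
#' @param burn_in steps of plain MD before the demon engages.
#' @param seed RNG seed.
#' @param directional reserved switch for directional velocity draws; only the
#'   isotropic Boltzmann redraw is implemented.
#' @return an object of class `demon_config`.
#' @export
demon_config <- function(md = md_config(dt = 0.004, thermostat = "berendsen",
                                        tau = 0.5, T_target = 300,
                                        save_stride = 0),
                         cv_selection = NULL, sprint_min = 80, sprint_max = 240,
                         accept_tol = 0, success_radius = 3.0,
                         max_sprints = 400, burn_in = 0, seed = NULL,
                         directional = FALSE) {
  stopifnot(success_radius >= 0, sprint_min > 0, sprint_max >= sprint_min)
  if (directional) stop("directional velocity draws are not implemented")
  structure(list(md = md, cv_selection = cv_selection, sprint_min = sprint_min,
                 sprint_max = sprint_max, accept_tol = accept_tol,
                 success_radius = success_radius, max_sprints = max_sprints,
                 burn_in = burn_in, seed = seed, directional = directional),
            class = "demon_config")
}

#' @export
print.demon_stats <- function(x, ...) {
  cat(sprintf(paste0("demon run: %d sprints (%d accepted, %d discarded, ",
                     "discard fraction %.2f)\n  final CV %.3f A; target %s\n"),
              nrow(x$sprints), x$n_accepted, x$n_discarded, x$discard_fraction,
              x$final_cv, if (x$reached) "reached" else "not reached"))
  invisible(x)
}

#' One Maxwell's-demon run toward a guidepost
#'
#' After `burn_in` unbiased steps the demon engages: each sprint snapshots the
#' state, integrates `sprint_min..sprint_max` steps, and accepts the sprint
#' only if the CV (RMSD to `guidepost`) did not rise by more than
#' `accept_tol`; otherwise coordinates are restored and velocities redrawn
#' from a fresh Boltzmann distribution. The run stops when the CV reaches
#' `success_radius` (if enabled) or after `max_sprints` sprints.
#'
#' @param s starting `cg_structure`.
#' @param v starting velocities (`NULL`: Boltzmann draw).
#' @param p a [potential_spec].
#' @param r a [restraint_set] or `NULL`.
#' @param guidepost target `cg_structure`.
#' @param cfg a [demon_config].
#' @param ctx optional prebuilt [cg_context].
#' @param accept_all disable the demon (accept every sprint); the run then
#'   reduces to plain integration with the same sprint partitioning.
#' @param t0 time origin, ps.
#' @return list with `trajectory` (accepted sprint-end frames; `NULL` when no
#'   sprint was accepted), `stats` (a `demon_stats` object: per-sprint ledger,
#'   discard fraction, reached flag, final CV), `final`, `velocities`.
#' @export
demon_run <- function(s, v = NULL, p = potential_spec(), r = NULL, guidepost,
                      cfg = demon_config(), ctx = NULL, accept_all = FALSE,
                      t0 = 0) {
  stopifnot(inherits(cfg, "demon_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  if (is.null(ctx)) ctx <- cg_context(s, p, r)
  if (is.null(v)) v <- boltzmann_velocities(s$atoms$mass, cfg$md$T_target)
  mass <- s$atoms$mass
  cvf <- function(x) {
    tmp <- s; tmp$xyz <- x
    rmsd_cv(tmp, guidepost, cfg$cv_selection)
  }
  mdc <- cfg$md
  run_chunk <- function(x, v, nsteps, tt) {
    tmp <- s; tmp$xyz <- x
    out <- integrate_md(tmp, v, cfg = md_config(
      dt = mdc$dt, thermostat = mdc$thermostat, tau = mdc$tau,
      T_target = mdc$T_target, n_steps = nsteps, seed = NULL,
      com_removal_interval = mdc$com_removal_interval, save_stride = 0,
      e_bound = mdc$e_bound), ctx = ctx, t0 = tt)
    list(x = out$final$xyz, v = out$velocities)
  }
  x <- s$xyz
  tnow <- t0
  if (cfg$burn_in > 0) {
    ch <- run_chunk(x, v, cfg$burn_in, tnow)
    x <- ch$x; v <- ch$v; tnow <- tnow + cfg$burn_in * mdc$dt
  }
  cv <- cvf(x)
  if (!is.finite(cv)) stop("collective variable undefined on the start structure")
  rows <- vector("list", cfg$max_sprints)
  frames <- list(); ftimes <- numeric(0)
  nspr <- 0
  while (nspr < cfg$max_sprints &&
         !(cfg$success_radius > 0 && cv <= cfg$success_radius)) {
    nspr <- nspr + 1
    L <- sample(cfg$sprint_min:cfg$sprint_max, 1)
    ch <- run_chunk(x, v, L, tnow)
    cv_new <- cvf(ch$x)
    accepted <- accept_all || cv_new <= cv + cfg$accept_tol
    rows[[nspr]] <- tibble::tibble(sprint = nspr, steps = L, cv_before = cv,
                                   cv_after = cv_new, accepted = accepted)
    if (accepted) {
      x <- ch$x; v <- ch$v; cv <- cv_new
      tnow <- tnow + L * mdc$dt
      frames[[length(frames) + 1]] <- x
      ftimes <- c(ftimes, tnow)
    } else {
      v <- boltzmann_velocities(mass, mdc$T_target)
    }
  }
  sprints <- if (nspr) do.call(rbind, rows[seq_len(nspr)]) else
    tibble::tibble(sprint = integer(0), steps = integer(0),
                   cv_before = numeric(0), cv_after = numeric(0),
                   accepted = logical(0))
  n_acc <- sum(sprints$accepted)
  stats <- structure(list(
    sprints = sprints, n_accepted = n_acc, n_discarded = nspr - n_acc,
    discard_fraction = if (nspr) (nspr - n_acc) / nspr else 0,
    final_cv = cv,
    reached = cv <= max(cfg$success_radius, 0) & cfg$success_radius > 0 |
      cfg$success_radius == 0 & FALSE), class = "demon_stats")
  stats$reached <- cfg$success_radius > 0 && cv <= cfg$success_radius
  final <- s; final$xyz <- x
  traj <- if (length(frames)) cg_trajectory(s, frames, ftimes) else NULL
  list(trajectory = traj, stats = stats, final = final, velocities = v,
       t_end = tnow)
}

#' Chain demon runs across an ordered guidepost set
#'
#' Runs [demon_run()] against guidepost k starting from the terminal structure
#' of leg k-1, concatenating accepted frames. A leg that fails to reach its
#' guidepost is flagged but does not abort the chain.
#'
#' @param s starting `cg_structure`.
#' @param posts a `guidepost_set` (or list of `cg_structure`), at least 2.
#' @param cfg a [demon_config].
#' @param p a [potential_spec].
#' @param r a [restraint_set] or `NULL`.
#' @param v starting velocities (`NULL`: Boltzmann draw).
#' @return list with `trajectory` (concatenated accepted frames), `stats`
#'   (list of per-leg `demon_stats`), `final`, `legs` (tibble summary).
#' @export
chain_guideposts <- function(s, posts, cfg = demon_config(),
                             p = potential_spec(), r = NULL, v = NULL) {
  posts <- unclass(posts)
  if (length(posts) < 2) stop("need at least 2 guideposts")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  cfg$seed <- NULL                       # single stream across legs
  ctx <- cg_context(s, p, r)
  cur <- s
  frames <- list(); ftimes <- numeric(0)
  stats <- vector("list", length(posts))
  tnow <- 0
  for (k in seq_along(posts)) {
    leg <- demon_run(cur, v, p, r, guidepost = posts[[k]], cfg = cfg, ctx = ctx,
                     t0 = tnow)
    stats[[k]] <- leg$stats
    if (!is.null(leg$trajectory)) {
      frames <- c(frames, leg$trajectory$frames)
      ftimes <- c(ftimes, leg$trajectory$times)
    }
    cur <- leg$final; v <- leg$velocities; tnow <- leg$t_end + 1e-9
  }
  legs <- tibble::tibble(
    leg = seq_along(posts),
    final_cv = vapply(stats, function(x) x$final_cv, 0),
    reached = vapply(stats, function(x) x$reached, TRUE),
    discard_fraction = vapply(stats, function(x) x$discard_fraction, 0),
    sprints = vapply(stats, function(x) nrow(x$sprints), 0L))
  traj <- if (length(frames)) cg_trajectory(s, frames, ftimes) else NULL
  list(trajectory = traj, stats = stats, final = cur, legs = legs)
}

#' Replicated demon-chained runs
#'
#' Repeats [chain_guideposts()] with replicate seeds derived deterministically
#' from the master seed, so replicates are reproducible yet draw distinct
#' sprint-length sequences.
#'
#' @param s starting `cg_structure`.
#' @param posts guidepost set.
#' @param cfg a [demon_config] whose `seed` acts as the master seed.
#' @param n_reps number of replicates.
#' @param p a [potential_spec].
#' @param r a [restraint_set] or `NULL`.
#' @return list of per-replicate results (as [chain_guideposts()]), with
#'   attribute `seeds`.
#' @export
run_replicates <- function(s, posts, cfg = demon_config(), n_reps = 4,
                           p = potential_spec(), r = NULL) {
  stopifnot(n_reps >= 1)
  master <- if (is.null(cfg$seed)) 1L else cfg$seed
  set.seed(master)
  seeds <- sample.int(.Machine$integer.max %/% 2, n_reps)
  out <- vector("list", n_reps)
  for (k in seq_len(n_reps)) {
    ck <- cfg; ck$seed <- seeds[k]
    out[[k]] <- chain_guideposts(s, posts, ck, p, r)
  }
  attr(out, "seeds") <- seeds
  out
}

#' Export a demon sprint ledger as delimited text
#' @param stats a `demon_stats` object.
#' @param path output path (CSV).
#' @return invisibly, `path`.
#' @export
write_demon_stats <- function(stats, path) {
  write.csv(stats$sprints, path, row.names = FALSE)
  invisible(path)
}
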