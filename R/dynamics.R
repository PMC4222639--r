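#' MD configuration
#'
#' @param dt timestep, ps (the 2-fs-spirit default; CG beads tolerate more).
#' @param thermostat `"none"`, `"berendsen"` (weak coupling) or `"langevin"`.
#' @param tau thermostat time constant, ps.
#' @param T_target target temperature, K.
#' @param n_steps number of steps.
#' @param seed RNG seed (used by `langevin` noise and velocity draws).
#' @param com_removal_interval steps between centre-of-mass translation and
#'   rotation removal (the flying ice-cube guard); 0 disables.
#' @param save_stride store a frame every this many steps; 0 stores none.
#' @param constraint `"none"` or `"bond-rigid"` (CG bonds are stiff harmonics;
#'   the flag is accepted for protocol compatibility and does not alter them).
#' @param e_bound abort when `|E|` exceeds this bound, kcal/mol.
#' @return an object of class `md_config`.
#' @export
md_config <- function(dt = 0.002, thermostat = c("berendsen", "none", "langevin"),
                      tau = 1.0, T_target = 300, n_steps = 1000, seed = NULL,
                      com_removal_interval = 50, save_stride = 10,
                      constraint = c("none", "bond-rigid"), e_bound = 1e8) {
  thermostat <- match.arg(thermostat)
  constraint <- match.arg(constraint)
  stopifnot(dt > 0, tau > 0, T_target > 0, n_steps >= 0)
  structure(list(dt = dt, thermostat = thermostat, tau = tau,
                 T_target = T_target, n_steps = n_steps, seed = seed,
                 com_removal_interval = com_removal_interval,
                 save_stride = save_stride, constraint = constraint,
                 e_bound = e_bound), class = "md_config")
}

#' Boltzmann velocity draw
#'
#' Each component is Normal(0, sqrt(kB T / m)); the centre-of-mass momentum is
#' removed after the draw.
#'
#' @param masses bead masses, Da.
#' @param T temperature, K.
#' @param seed optional RNG seed.
#' @return N x 3 velocity matrix, A/ps.
#' @export
boltzmann_velocities <- function(masses, T, seed = NULL) {
  stopifnot(T > 0, all(masses > 0))
  if (!is.null(seed)) set.seed(seed)
  n <- length(masses)
  sdv <- sqrt(.kB * T * .acc / masses)
  v <- matrix(rnorm(3 * n), n, 3) * sdv
  p <- colSums(v * masses) / sum(masses)
  sweep(v, 2, p)
}

# kinetic temperature of a velocity set
.kinetic_T <- function(v, masses, ndf = 3 * length(masses) - 6) {
  ke <- 0.5 * sum(masses * rowSums(v^2)) / .acc
  2 * ke / (ndf * .kB)
}

#' Energy minimization
#'
#' Steepest descent or Polak-Ribiere conjugate gradient with backtracking
#' (Armijo) line search. Accepted iterates never increase the energy;
#' termination is on the RMS gradient norm or the iteration cap, and the
#' result records which.
#'
#' @param s a `cg_structure`.
#' @param p a [potential_spec].
#' @param r a [restraint_set] or `NULL`.
#' @param method `"cg_polak_ribiere"` or `"steepest_descent"`.
#' @param tol RMS gradient tolerance, kcal/(mol A).
#' @param max_iter iteration cap.
#' @param ctx optional prebuilt [cg_context].
#' @return the minimized `cg_structure`, with attribute `minimize_info`: a list
#'   with `converged`, `reason` (`"tol"` or `"max_iter"`), `iterations`,
#'   `energies` (per accepted iterate) and final `gnorm`.
#' @export
minimize <- function(s, p = potential_spec(), r = NULL,
                     method = c("cg_polak_ribiere", "steepest_descent"),
                     tol = 1e-2, max_iter = 500, ctx = NULL) {
  method <- match.arg(method)
  if (is.null(ctx)) ctx <- cg_context(s, p, r)
  x <- s$xyz
  ef <- .cg_energy_forces(x, ctx, TRUE)
  e <- ef$total
  if (!is.finite(e)) stop("non-finite starting energy")
  g <- -ef$forces                      # gradient
  d <- -g
  energies <- e
  gn_rms <- function(g) sqrt(mean(g^2))
  reason <- "max_iter"
  iter <- 0
  alpha <- 0.1
  while (iter < max_iter) {
    if (gn_rms(g) < tol) { reason <- "tol"; break }
    iter <- iter + 1
    gd <- sum(g * d)
    if (gd >= 0) { d <- -g; gd <- sum(g * d) }   # reset on non-descent direction
    # backtracking line search
    a <- alpha
    ok <- FALSE
    for (ls in 1:40) {
      xn <- x + a * d
      en <- tryCatch(.cg_energy_forces(xn, ctx, FALSE)$total, error = function(e) NaN)
      if (is.finite(en) && en <= e + 1e-4 * a * gd) { ok <- TRUE; break }
      a <- a / 2
    }
    if (!ok) {
      if (!is.finite(en)) {
        cond <- structure(
          class = c("demonmd_linesearch_error", "demonmd_error", "error", "condition"),
          list(message = "non-finite energy during line search",
               call = sys.call(), structure = { s$xyz <- x; s }))
        stop(cond)
      }
      reason <- "tol"; break   # no downhill step available at machine scale
    }
    efn <- .cg_energy_forces(xn, ctx, TRUE)
    gn <- -efn$forces
    if (method == "cg_polak_ribiere") {
      beta <- max(0, sum(gn * (gn - g)) / max(sum(g * g), 1e-30))
      d <- -gn + beta * d
    } else d <- -gn
    x <- xn; e <- efn$total; g <- gn
    energies <- c(energies, e)
    alpha <- min(max(a * 2, 1e-6), 1)
  }
  if (iter >= max_iter && gn_rms(g) < tol) reason <- "tol"
  s$xyz <- x
  attr(s, "minimize_info") <- list(converged = reason == "tol", reason = reason,
                                   iterations = iter, energies = energies,
                                   gnorm = gn_rms(g), energy = e)
  s
}

#' Thermostatted velocity-Verlet integration
#'
#' Velocity-Verlet core with optional Berendsen weak-coupling or Langevin
#' thermostat, and periodic removal of centre-of-mass translation and rotation
#' (inertia-tensor angular-momentum subtraction) to guard against the flying
#' ice-cube artifact.
#'
#' @param s a `cg_structure` (starting coordinates).
#' @param v N x 3 starting velocities, A/ps (`NULL`: Boltzmann draw at
#'   `cfg$T_target`).
#' @param p a [potential_spec].
#' @param r a [restraint_set] or `NULL`.
#' @param cfg an [md_config].
#' @param ctx optional prebuilt [cg_context].
#' @param t0 trajectory time origin, ps.
#' @return list with `trajectory` (a `cg_trajectory`, `NULL` if no frames were
#'   stored), `final` (structure at the last step), `velocities`, and
#'   `diagnostics` (tibble: time, pe, ke, temperature).
#' @export
integrate_md <- function(s, v = NULL, p = potential_spec(), r = NULL,
                         cfg = md_config(), ctx = NULL, t0 = 0) {
  stopifnot(inherits(cfg, "md_config"))
  if (is.null(ctx)) ctx <- cg_context(s, p, r)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  if (is.null(v)) v <- boltzmann_velocities(s$atoms$mass, cfg$T_target)
  n <- n_beads(s)
  ndf <- max(1, 3 * n - if (cfg$com_removal_interval > 0) 6 else 0)
  th <- match(cfg$thermostat, c("none", "berendsen", "langevin")) - 1L
  out <- .cg_md_chunk(s$xyz, v, s$atoms$mass, ctx, as.integer(cfg$n_steps),
                      cfg$dt, th, cfg$tau, cfg$T_target,
                      as.integer(cfg$com_removal_interval), TRUE,
                      as.integer(cfg$save_stride), t0, as.integer(ndf),
                      cfg$e_bound)
  final <- s; final$xyz <- out$xyz
  traj <- NULL
  if (out$n_saved > 0) {
    frames <- lapply(seq_len(out$n_saved), function(k)
      matrix(out$frames[((k - 1) * 3 * n + 1):(k * 3 * n)], n, 3))
    traj <- cg_trajectory(s, frames, out$times)
  }
  diagnostics <- tibble::tibble(time = out$times, pe = out$pe, ke = out$ke,
                                temperature = out$temperature)
  list(trajectory = traj, final = final, velocities = out$vel,
       diagnostics = diagnostics)
}

#' Staged equilibration protocol
#'
#' The equilibration ladder run before production: minimize; heat with
#' positional restraints at k = 10 kcal/(mol A^2); minimize; heat with k = 5;
#' minimize with restraints reduced by 1 (k = 4); then an unrestrained
#' temperature ramp from 1 K to 310 K. Stage step counts are configurable and
#' default to desk-scale values.
#'
#' @param s a `cg_structure`.
#' @param p a [potential_spec].
#' @param cfg list of stage controls: `dt`, `tau`, `heat_steps`, `min_iter`,
#'   `min_tol`, `T_heat` (restrained-heating target, K), `ramp_from`,
#'   `ramp_to` (K), `ramp_steps`, `ramp_segments`, `seed`.
#' @return list with `structure`, `velocities` and `ledger` (tibble: one row
#'   per stage with kind, restraint k, temperatures and energies).
#' @export
staged_equilibration <- function(s, p = potential_spec(), cfg = list()) {
  cfg <- modifyList(list(dt = 0.002, tau = 0.2, heat_steps = 400, min_iter = 200,
                         min_tol = 0.05, T_heat = 300, ramp_from = 1,
                         ramp_to = 310, ramp_steps = 600, ramp_segments = 6,
                         seed = NULL), cfg)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  ledger <- list()
  log_stage <- function(kind, k, T_end, e_end)
    ledger[[length(ledger) + 1]] <<- tibble::tibble(
      stage = length(ledger) + 1, kind = kind, restraint_k = k,
      T_target = T_end, energy = e_end)
  mcfg <- function(n, T) md_config(dt = cfg$dt, thermostat = "berendsen",
                                   tau = cfg$tau, T_target = T, n_steps = n,
                                   save_stride = 0)
  heat <- function(s, k, v) {
    r <- positional_restraints(s, k)
    ctx <- cg_context(s, p, r)
    out <- integrate_md(s, v, cfg = mcfg(cfg$heat_steps, cfg$T_heat), ctx = ctx)
    list(s = out$final, v = out$velocities,
         e = energy(out$final, ctx = ctx)$total)
  }
  # 1: minimize
  s <- minimize(s, p, tol = cfg$min_tol, max_iter = cfg$min_iter)
  log_stage("minimize", NA, NA, attr(s, "minimize_info")$energy)
  # 2: restrained heating, k = 10
  v <- boltzmann_velocities(s$atoms$mass, cfg$ramp_from)
  h <- heat(s, 10, v)
  log_stage("heat_restrained", 10, cfg$T_heat, h$e)
  # 3: minimize
  s <- minimize(h$s, p, tol = cfg$min_tol, max_iter = cfg$min_iter)
  log_stage("minimize", NA, NA, attr(s, "minimize_info")$energy)
  # 4: restrained heating, k = 5
  h <- heat(s, 5, h$v)
  log_stage("heat_restrained", 5, cfg$T_heat, h$e)
  # 5: minimize with restraints reduced by 1 (k = 4)
  r4 <- positional_restraints(h$s, 4)
  s <- minimize(h$s, p, r4, tol = cfg$min_tol, max_iter = cfg$min_iter)
  log_stage("minimize_restrained", 4, NA, attr(s, "minimize_info")$energy)
  # 6: unrestrained ramp ramp_from -> ramp_to
  ctx <- cg_context(s, p)
  v <- boltzmann_velocities(s$atoms$mass, cfg$ramp_from)
  Ts <- seq(cfg$ramp_from, cfg$ramp_to, length.out = cfg$ramp_segments)
  nseg <- max(1, floor(cfg$ramp_steps / cfg$ramp_segments))
  for (T in Ts) {
    out <- integrate_md(s, v, cfg = mcfg(nseg, T), ctx = ctx)
    s <- out$final; v <- out$velocities
  }
  log_stage("ramp_unrestrained", NA, cfg$ramp_to, energy(s, ctx = ctx)$total)
  list(structure = s, velocities = v, ledger = do.call(rbind, ledger))
}

# rotate beads `moved` (indices) about the axis through xyz[a,] -> xyz[b,]
.rotate_about_bond <- function(xyz, a, b, moved, angle) {
  axis <- xyz[b, ] - xyz[a, ]
  axis <- axis / sqrt(sum(axis^2))
  ct <- cos(angle); st <- sin(angle)
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + st * K + (1 - ct) * (K %*% K)
  xyz[moved, ] <- sweep(sweep(xyz[moved, , drop = FALSE], 2, xyz[b, ]) %*% t(R),
                        2, xyz[b, ], `+`)
  xyz
}

#' Monte Carlo search configuration
#'
#' Defaults follow the mixed torsional / large-scale low-mode search settings:
#' at most 5000 steps per attempt with 100 steps per rotatable bond, saving 10
#' structures within a 5.02 kcal/mol window, torsion-move probability 0.5, and
#' low-mode move magnitudes between 3.0 and 7.5 A.
#'
#' @param max_steps_per_attempt cap on search steps.
#' @param steps_per_rotatable_bond budget multiplier on the rotatable-bond
#'   count.
#' @param n_saved maximum conformers returned.
#' @param energy_window retention window above the best energy, kcal/mol.
#' @param p_torsion probability of a torsion move (vs a low-mode move).
#' @param lowmode_min,lowmode_max low-mode move magnitude bounds, A (RMS
#'   displacement over the moved beads).
#' @param n_modes number of low-frequency modes sampled for low-mode moves.
#' @param n_steps explicit step count; `NULL` uses
#'   `min(max_steps_per_attempt, steps_per_rotatable_bond * n_rotatable)`.
#' @param min_iter,min_tol per-proposal minimization controls.
#' @param seed RNG seed.
#' @return an object of class `mc_search_config`.
#' @export
mc_search_config <- function(max_steps_per_attempt = 5000,
                             steps_per_rotatable_bond = 100, n_saved = 10,
                             energy_window = 5.02, p_torsion = 0.5,
                             lowmode_min = 3.0, lowmode_max = 7.5, n_modes = 3,
                             n_steps = NULL, min_iter = 60, min_tol = 0.2,
                             seed = NULL) {
  stopifnot(lowmode_min < lowmode_max, p_torsion >= 0, p_torsion <= 1)
  structure(list(max_steps_per_attempt = max_steps_per_attempt,
                 steps_per_rotatable_bond = steps_per_rotatable_bond,
                 n_saved = n_saved, energy_window = energy_window,
                 p_torsion = p_torsion, lowmode_min = lowmode_min,
                 lowmode_max = lowmode_max, n_modes = n_modes,
                 n_steps = n_steps, min_iter = min_iter, min_tol = min_tol,
                 seed = seed), class = "mc_search_config")
}

#' Mixed torsional / low-mode Monte Carlo conformer search
#'
#' Iterates: with probability `p_torsion` perturb a random backbone
#' pseudo-torsion, otherwise displace along a random low-frequency
#' elastic-network mode with RMS magnitude uniform in
#' `[lowmode_min, lowmode_max]`; minimize the proposal; retain it if its energy
#' lies within `energy_window` of the best found. Returns up to `n_saved`
#' lowest-energy conformers that are mutually distinct (pairwise Calpha RMSD
#' > 0.5 A), energies ascending.
#'
#' @param s a `cg_structure`.
#' @param p a [potential_spec].
#' @param cfg an [mc_search_config].
#' @param r a [restraint_set] or `NULL`.
#' @return list of `cg_structure` conformers, with attributes `energies` and
#'   `log` (tibble: step, move, magnitude, energy, retained).
#' @export
lowmode_mc_search <- function(s, p = potential_spec(), cfg = mc_search_config(),
                              r = NULL) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  ctx <- cg_context(s, p, r)
  chain <- which(s$atoms$atom_label == "CA")
  nrot <- max(0, length(chain) - 3)    # internal pseudo-torsions
  n_steps <- cfg$n_steps
  if (is.null(n_steps))
    n_steps <- min(cfg$max_steps_per_attempt, cfg$steps_per_rotatable_bond * nrot)
  modes <- anm_modes(s, cutoff = p$en_cutoff, n_modes = cfg$n_modes)
  cur <- minimize(s, p, r, tol = cfg$min_tol, max_iter = 4 * cfg$min_iter, ctx = ctx)
  e_cur <- attr(cur, "minimize_info")$energy
  saved <- list(cur); e_saved <- e_cur
  log <- vector("list", n_steps)
  n_accepted <- 0
  for (step in seq_len(n_steps)) {
    cand <- cur
    if (runif(1) < cfg$p_torsion && nrot > 0) {
      pos <- sample(2:(length(chain) - 2), 1)
      ang <- runif(1, -pi / 3, pi / 3)
      moved <- chain[(pos + 2):length(chain)]
      cand$xyz <- .rotate_about_bond(cand$xyz, chain[pos], chain[pos + 1],
                                     moved, ang)
      move <- "torsion"; mag <- ang
    } else {
      m <- sample(ncol(modes$vectors), 1)
      mag <- runif(1, cfg$lowmode_min, cfg$lowmode_max)
      dir <- sample(c(-1, 1), 1)
      vec <- matrix(modes$vectors[, m], ncol = 3, byrow = TRUE)
      vec <- vec / sqrt(mean(rowSums(vec^2)))       # unit RMS displacement
      cand$xyz[modes$idx, ] <- cand$xyz[modes$idx, ] + dir * mag * vec
      move <- "lowmode"
    }
    cand <- minimize(cand, p, r, tol = cfg$min_tol, max_iter = cfg$min_iter,
                     ctx = ctx)
    e_new <- attr(cand, "minimize_info")$energy
    retained <- is.finite(e_new) && e_new <= min(e_saved) + cfg$energy_window
    if (retained) {
      dup <- any(vapply(saved, function(x) .kabsch_rmsd(x$xyz, cand$xyz) <= 0.5,
                        TRUE))
      if (!dup) {
        saved <- c(saved, list(cand)); e_saved <- c(e_saved, e_new)
        n_accepted <- n_accepted + 1
      }
      if (e_new <= e_cur + cfg$energy_window) { cur <- cand; e_cur <- e_new }
    }
    log[[step]] <- tibble::tibble(step = step, move = move, magnitude = mag,
                                  energy = e_new, retained = retained)
  }
  if (n_accepted == 0)
    stop("low-mode MC search retained no new conformers; ",
         "consider a larger energy window")
  # prune to the window around the final best, dedup already done
  best <- min(e_saved)
  keep <- which(e_saved <= best + cfg$energy_window)
  ord <- keep[order(e_saved[keep])]
  ord <- head(ord, cfg$n_saved)
  out <- saved[ord]
  attr(out, "energies") <- e_saved[ord]
  attr(out, "log") <- do.call(rbind, log)
  out
}
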