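# known configuration schema: section -> allowed keys
.config_schema <- list(
  system = c("n_residues", "seed_offset", "bond_length"),
  solvation = c("shell_depth", "water_density", "ion_pairs", "r_excl"),
  potential = c("bond_k", "bond_r0", "angle_k", "lj_epsilon", "lj_sigma",
                "dielectric", "diel_eps", "debye_length", "nonbonded_cutoff",
                "en_cutoff", "en_k", "wall_k", "wall_r", "torsion_amp",
                "torsion_per"),
  equilibration = c("dt", "tau", "heat_steps", "min_iter", "min_tol", "T_heat",
                    "ramp_from", "ramp_to", "ramp_steps", "ramp_segments"),
  guideposts = c("n_posts", "amplitude", "n_modes", "min_iter"),
  demon = c("dt", "thermostat", "tau", "T_target", "com_removal_interval",
            "sprint_min", "sprint_max", "accept_tol", "success_radius",
            "max_sprints", "burn_in"),
  replicates = c("n_reps"),
  production = c("n_steps", "dt", "thermostat", "tau", "T_target",
                 "save_stride", "com_removal_interval", "solvated"),
  variants = NULL,                       # character vector
  metrics = c("pocket_cutoff", "sasa_points", "final_fraction"),
  ddg = c("maxit", "flex_halfwidth", "physics_cutoff"),
  output_dir = NULL,
  master_seed = NULL)

.default_config <- function() {
  list(system = list(n_residues = 465, bond_length = 3.8),
       solvation = list(water_density = 1.0),
       potential = list(),
       equilibration = list(heat_steps = 300, min_iter = 150, ramp_steps = 480,
                            dt = 0.004),
       guideposts = list(n_posts = 5, amplitude = 40, n_modes = 3,
                         min_iter = 150),
       demon = list(dt = 0.004, thermostat = "berendsen", tau = 0.5,
                    T_target = 300, com_removal_interval = 25, sprint_min = 80,
                    sprint_max = 240, accept_tol = 0, success_radius = 3.0,
                    max_sprints = 400, burn_in = 60),
       replicates = list(n_reps = 4),
       production = list(n_steps = 96000, dt = 0.004, thermostat = "berendsen",
                         tau = 1.0, T_target = 300, save_stride = 240,
                         com_removal_interval = 50, solvated = TRUE),
       variants = c("Ser65", "pSer65", "S65A", "S65D", "S65E"),
       metrics = list(pocket_cutoff = 5.0, sasa_points = 240,
                      final_fraction = 1 / 3),
       ddg = list(maxit = 150, flex_halfwidth = 2, physics_cutoff = 12),
       output_dir = "demonmd_out",
       master_seed = 20140901)
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration, validates it against the known schema
#' (unknown sections or keys are rejected), and fills unset values with the
#' bundled defaults. `path = NULL` returns the defaults.
#'
#' @param path YAML file path, or `NULL`.
#' @param overrides optional named list merged over the file values.
#' @return a validated configuration list of class `run_config`, carrying a
#'   `hash` attribute.
#' @export
run_config <- function(path = NULL, overrides = NULL) {
  cfg <- .default_config()
  user <- if (!is.null(path)) yaml::read_yaml(path) else list()
  if (!is.null(overrides)) user <- modifyList(user, overrides)
  bad <- setdiff(names(user), names(.config_schema))
  if (length(bad)) stop("unknown config section(s): ", paste(bad, collapse = ", "))
  for (sec in names(user)) {
    allowed <- .config_schema[[sec]]
    if (!is.null(allowed) && is.list(user[[sec]])) {
      badk <- setdiff(names(user[[sec]]), allowed)
      if (length(badk))
        stop("unknown key(s) in config section '", sec, "': ",
             paste(badk, collapse = ", "))
      cfg[[sec]] <- modifyList(cfg[[sec]], user[[sec]])
    } else {
      cfg[[sec]] <- user[[sec]]
    }
  }
  stopifnot(is.numeric(cfg$master_seed), length(cfg$master_seed) == 1)
  attr(cfg, "hash") <- rlang::hash(cfg)
  class(cfg) <- "run_config"
  cfg
}

#' Deterministic per-stage seed fan-out
#'
#' Derives one reproducible sub-seed per named stage from the master seed, so
#' stages are independent yet the whole pipeline replays bit-identically.
#'
#' @param master master seed (integer).
#' @return named integer vector of stage seeds.
#' @export
stage_seeds <- function(master) {
  set.seed(as.integer(master))
  stages <- c("system", "solvation", "guideposts", "equilibration", "demon",
              "replicates", "ddg", "Ser65", "pSer65", "S65A", "S65D", "S65E")
  setNames(sample.int(.Machine$integer.max %/% 4, length(stages)), stages)
}

.cfg_potential <- function(cfg, wall = FALSE) {
  pp <- cfg$potential
  tors <- if (!is.null(pp$torsion_amp))
    list(c(pp$torsion_amp, if (is.null(pp$torsion_per)) 1 else pp$torsion_per))
  else NULL
  args <- pp[setdiff(names(pp), c("torsion_amp", "torsion_per"))]
  if (!is.null(tors)) args$torsion <- tors
  p <- do.call(potential_spec, args)
  if (wall && p$wall_k == 0) p$wall_k <- 2.0
  p
}

.variant_modification <- function(name) {
  switch(name,
         Ser65 = site_modification(65, "identity"),
         pSer65 = site_modification(65, "pSer"),
         S65A = site_modification(65, "StoA"),
         S65D = site_modification(65, "StoD"),
         S65E = site_modification(65, "StoE"),
         stop("unknown variant: ", name))
}

.write_manifest <- function(outdir, cmd, cfg, inputs, outputs, seeds, t_start) {
  man <- list(command = cmd,
              config_hash = attr(cfg, "hash"),
              package_version = as.character(utils::packageVersion("demonmd")),
              master_seed = cfg$master_seed,
              stage_seeds = as.list(seeds),
              inputs = inputs, outputs = outputs,
              wall_time_s = round(as.numeric(Sys.time()) - t_start, 2))
  path <- file.path(outdir, paste0("manifest_", cmd, ".json"))
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA)
  path
}

.need_file <- function(path, producer) {
  if (!file.exists(path))
    stop("missing upstream file '", path, "'; run `", producer, "` first")
  path
}

#' Generate stage: system, solvation shell and guideposts
#'
#' Builds the synthetic Parkin-like system, a solvated copy, and the guidepost
#' conformer set (low-mode displacement of the pSer65-activated system, whose
#' cleft bridge is released), writing `system.pdb`, `solvated.pdb`,
#' `guidepost_<k>.pdb` and a manifest into the output directory.
#'
#' @param cfg a [run_config].
#' @return invisibly, named list of output paths.
#' @export
cmd_generate <- function(cfg = run_config()) {
  t0 <- as.numeric(Sys.time())
  seeds <- stage_seeds(cfg$master_seed)
  outdir <- cfg$output_dir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sys_spec <- toy_spec(n_residues = cfg$system$n_residues, seed = seeds["system"],
                       bond_length = cfg$system$bond_length)
  s <- make_parkin_like(sys_spec)
  p <- .cfg_potential(cfg)
  paths <- c(system = file.path(outdir, "system.pdb"))
  write_pdb(s, paths["system"])
  sol_args <- cfg$solvation
  sol_args$seed <- seeds["solvation"]
  sol <- solvate_shell(s, do.call(solvation_spec, sol_args))
  paths["solvated"] <- file.path(outdir, "solvated.pdb")
  write_pdb(sol, paths["solvated"])
  act <- apply_modification(s, site_modification(65, "pSer"))
  gp <- generate_guideposts(act, n_posts = cfg$guideposts$n_posts,
                            amplitude = cfg$guideposts$amplitude,
                            seed = seeds["guideposts"], p = p,
                            n_modes = cfg$guideposts$n_modes,
                            min_iter = cfg$guideposts$min_iter)
  for (k in seq_along(gp)) {
    nm <- sprintf("guidepost_%d", k)
    paths[nm] <- file.path(outdir, paste0(nm, ".pdb"))
    write_pdb(gp[[k]], paths[nm])
  }
  .write_manifest(outdir, "generate", cfg, inputs = list(),
                  outputs = as.list(paths), seeds = seeds, t0)
  invisible(as.list(paths))
}

.load_guideposts <- function(outdir) {
  k <- 1; posts <- list()
  while (file.exists(file.path(outdir, sprintf("guidepost_%d.pdb", k)))) {
    posts[[k]] <- read_pdb(file.path(outdir, sprintf("guidepost_%d.pdb", k)))
    k <- k + 1
  }
  if (length(posts) < 2)
    stop("missing guidepost files in '", outdir, "'; run `cmd_generate` first")
  structure(posts, class = "guidepost_set")
}

.demon_cfg <- function(cfg, seed = NULL) {
  d <- cfg$demon
  demon_config(md = md_config(dt = d$dt, thermostat = d$thermostat, tau = d$tau,
                              T_target = d$T_target,
                              com_removal_interval = d$com_removal_interval,
                              save_stride = 0),
               sprint_min = d$sprint_min, sprint_max = d$sprint_max,
               accept_tol = d$accept_tol, success_radius = d$success_radius,
               max_sprints = d$max_sprints, burn_in = d$burn_in, seed = seed)
}

#' Simulate stage: demon-chained runs, replicates and variant production MD
#'
#' Runs the staged equilibration on the pSer65-activated system, drives it
#' through the guidepost chain with the Maxwell's demon (plus replicate
#' chained runs with derived seeds), and runs unbiased production MD for each
#' Ser65 variant on the solvated system. Trajectories, sprint ledgers and a
#' JSON summary are written into the output directory.
#'
#' @param cfg a [run_config].
#' @return invisibly, a list with `chain`, `replicates`, `variants` summaries.
#' @export
cmd_simulate <- function(cfg = run_config()) {
  t0 <- as.numeric(Sys.time())
  seeds <- stage_seeds(cfg$master_seed)
  outdir <- cfg$output_dir
  .need_file(file.path(outdir, "system.pdb"), "cmd_generate")
  posts <- .load_guideposts(outdir)
  p <- .cfg_potential(cfg)
  outputs <- list()

  # --- demon chain from the equilibrated activated system
  start <- posts[[1]]
  eq_args <- cfg$equilibration
  eq_args$seed <- seeds["equilibration"]
  eq <- staged_equilibration(start, p, eq_args)
  eq_path <- file.path(outdir, "equilibrated.pdb")
  write_pdb(eq$structure, eq_path)
  outputs$equilibrated <- eq_path
  utils::write.csv(eq$ledger, file.path(outdir, "equilibration_ledger.csv"),
                   row.names = FALSE)
  chain <- chain_guideposts(eq$structure, posts, .demon_cfg(cfg, seeds["demon"]),
                            p)
  if (!is.null(chain$trajectory))
    write_trajectory(chain$trajectory, file.path(outdir, "chain_traj.pdb"))
  utils::write.csv(chain$legs, file.path(outdir, "chain_legs.csv"),
                   row.names = FALSE)
  for (k in seq_along(chain$stats))
    write_demon_stats(chain$stats[[k]],
                      file.path(outdir, sprintf("chain_leg%d_sprints.csv", k)))

  # --- replicates
  rcfg <- .demon_cfg(cfg, seeds["replicates"])
  reps <- run_replicates(eq$structure, posts, rcfg,
                         n_reps = cfg$replicates$n_reps, p = p)
  rep_final_cv <- vapply(reps, function(rr)
    rmsd_cv(rr$final, posts[[length(posts)]]), 0)
  for (k in seq_along(reps)) {
    if (!is.null(reps[[k]]$trajectory))
      write_trajectory(reps[[k]]$trajectory,
                       file.path(outdir, sprintf("replicate%d_traj.pdb", k)))
    utils::write.csv(reps[[k]]$legs,
                     file.path(outdir, sprintf("replicate%d_legs.csv", k)),
                     row.names = FALSE)
  }

  # --- variant production runs
  sol_path <- if (isTRUE(cfg$production$solvated))
    .need_file(file.path(outdir, "solvated.pdb"), "cmd_generate")
  else file.path(outdir, "system.pdb")
  base <- read_pdb(sol_path)
  pp <- .cfg_potential(cfg, wall = isTRUE(cfg$production$solvated))
  pr <- cfg$production
  var_summary <- list()
  for (vn in cfg$variants) {
    vs <- apply_modification(base, .variant_modification(vn))
    vmin <- minimize(vs, pp, tol = 0.3, max_iter = 200)
    out <- integrate_md(vmin, v = NULL, p = pp,
                        cfg = md_config(dt = pr$dt, thermostat = pr$thermostat,
                                        tau = pr$tau, T_target = pr$T_target,
                                        n_steps = pr$n_steps,
                                        seed = seeds[vn],
                                        com_removal_interval =
                                          pr$com_removal_interval,
                                        save_stride = pr$save_stride))
    write_trajectory(out$trajectory,
                     file.path(outdir, sprintf("variant_%s_traj.pdb", vn)))
    var_summary[[vn]] <- list(n_frames = n_frames(out$trajectory),
                              mean_T = mean(out$diagnostics$temperature))
  }

  summary <- list(
    chain = list(final_cv_per_leg = chain$legs$final_cv,
                 reached = chain$legs$reached,
                 discard_fraction = chain$legs$discard_fraction),
    replicates = list(final_cv = rep_final_cv),
    variants = var_summary)
  jsonlite::write_json(summary, file.path(outdir, "simulate_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  .write_manifest(outdir, "simulate", cfg,
                  inputs = list(system = file.path(outdir, "system.pdb")),
                  outputs = list(summary = file.path(outdir,
                                                     "simulate_summary.json")),
                  seeds = seeds, t0)
  invisible(summary)
}

#' Analyze stage: trajectory metrics and figure panels
#'
#' Computes the reported metric set from the simulate-stage trajectories:
#' cleft CoM1-CoM2 distance, Ser65-pocket SASA and pocket water counts per
#' variant; UBL-RING1 (Leu26-Cys238), UBL-IBR (Leu26-Phe364), REP-RING1
#' (Tyr391-Cys238) and RING0-active-site (Arg163-Cys431) distances, Cys431
#' SASA, and core/N-terminal RMSD-RMSF profiles for the demon chain. Writes
#' one CSV per series, a JSON summary and ggplot figure panels.
#'
#' @param cfg a [run_config].
#' @return invisibly, the summary list.
#' @export
cmd_analyze <- function(cfg = run_config()) {
  t0 <- as.numeric(Sys.time())
  seeds <- stage_seeds(cfg$master_seed)
  outdir <- cfg$output_dir
  reg <- parkin_selections()
  sel <- reg$selections
  mcfg <- cfg$metrics
  outputs <- list()
  summary <- list()

  pocket <- cg_selection("ser65_pocket",
                         sort(unique(c(sel$cleft_wall_1$res_ids,
                                       sel$cleft_wall_2$res_ids, 65))))
  variant_series <- list()
  for (vn in cfg$variants) {
    tp <- file.path(outdir, sprintf("variant_%s_traj.pdb", vn))
    .need_file(tp, "cmd_simulate")
    traj <- read_trajectory(tp)
    nmax <- max(traj$topology$atoms$res_id[traj$topology$atoms$atom_label == "CA"])
    ser <- list(
      cleft = com_distance_series(traj, sel$CoM1, sel$CoM2),
      pocket_sasa = sasa_series(traj, pocket, n_sphere_points = mcfg$sasa_points),
      pocket_waters = pocket_waters_series(traj, pocket,
                                           cutoff = mcfg$pocket_cutoff))
    if (nmax >= 465) {                  # probes in the C-terminal domains
      ser$ubl_ring1 <- pair_distance_series(traj, list(26), list(238))
      ser$ubl_ibr <- pair_distance_series(traj, list(26), list(364))
      ser$rep_ring1 <- pair_distance_series(traj, list(391), list(238))
      ser$ring0_active <- pair_distance_series(traj, list(163), list(431))
      ser$cys431_sasa <- sasa_series(traj, sel$Cys431,
                                     n_sphere_points = mcfg$sasa_points)
    }
    for (nm in names(ser)) {
      path <- file.path(outdir, sprintf("metric_%s_%s.csv", vn, nm))
      write_metric_series(ser[[nm]], path)
      outputs[[paste(vn, nm, sep = "_")]] <- path
    }
    variant_series[[vn]] <- ser
    ff <- mcfg$final_fraction
    lastk <- function(ms) mean(tail(ms$value, ceiling(nrow(ms) * ff)))
    summary$variants[[vn]] <- list(
      mean_cleft_final = lastk(ser$cleft),
      mean_pocket_waters_final = lastk(ser$pocket_waters),
      mean_pocket_sasa_final = lastk(ser$pocket_sasa))
    if (!is.null(ser$cys431_sasa))
      summary$variants[[vn]]$mean_cys431_sasa <- mean(ser$cys431_sasa$value)
  }

  # demon-chain profiles against the equilibrated start
  eqp <- file.path(outdir, "equilibrated.pdb")
  chp <- file.path(outdir, "chain_traj.pdb")
  if (file.exists(eqp) && file.exists(chp)) {
    eq <- read_pdb(eqp)
    chain_traj <- read_trajectory(chp)
    nmax <- max(eq$atoms$res_id[eq$atoms$atom_label == "CA"])
    core_sel <- cg_selection("core", 145:min(465, nmax))
    nter_sel <- cg_selection("nterm", 1:140)
    core_rmsd <- rmsd_series(chain_traj, eq, core_sel)
    nter_rmsd <- rmsd_series(chain_traj, eq, nter_sel)
    write_metric_series(core_rmsd, file.path(outdir, "metric_chain_core_rmsd.csv"))
    write_metric_series(nter_rmsd, file.path(outdir, "metric_chain_nterm_rmsd.csv"))
    fl <- rmsf(chain_traj)
    utils::write.csv(fl, file.path(outdir, "metric_chain_rmsf.csv"),
                     row.names = FALSE)
    summary$chain <- list(max_core_rmsd = max(core_rmsd$value),
                          max_nterm_rmsd = max(nter_rmsd$value),
                          mean_core_rmsf = mean(fl$rmsf[fl$res_id >= 145]),
                          mean_nterm_rmsf = mean(fl$rmsf[fl$res_id <= 140]))
  }

  .plot_panels(variant_series, outdir)
  jsonlite::write_json(summary, file.path(outdir, "analyze_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  .write_manifest(outdir, "analyze", cfg, inputs = list(),
                  outputs = outputs, seeds = seeds, t0)
  invisible(summary)
}

#' ddG stage: zone-equilibrated mutation scan
#'
#' Scores the Ser65 variant set (and C431S) on the unsolvated system with the
#' zone-equilibration protocol, writing a delimited table.
#'
#' @param cfg a [run_config].
#' @param mutations optional data.frame (`res_id`, `kind`); default is the
#'   pSer65/S65A/S65D/S65E/C431S panel.
#' @return invisibly, the ddG tibble.
#' @export
cmd_ddg <- function(cfg = run_config(), mutations = NULL) {
  t0 <- as.numeric(Sys.time())
  seeds <- stage_seeds(cfg$master_seed)
  outdir <- cfg$output_dir
  s <- read_pdb(.need_file(file.path(outdir, "system.pdb"), "cmd_generate"))
  p <- .cfg_potential(cfg)
  if (is.null(mutations))
    mutations <- data.frame(res_id = c(65, 65, 65, 65, 431),
                            kind = c("pSer", "StoA", "StoD", "StoE", "CtoS"))
  set.seed(seeds["ddg"])
  tab <- ddg_batch(s, mutations, p, maxit = cfg$ddg$maxit)
  path <- file.path(outdir, "ddg_table.csv")
  utils::write.csv(tab, path, row.names = FALSE)
  .write_manifest(outdir, "ddg", cfg,
                  inputs = list(system = file.path(outdir, "system.pdb")),
                  outputs = list(ddg_table = path), seeds = seeds, t0)
  invisible(tab)
}

#' Path to the bundled demo configuration
#' @return file path of the packaged demo YAML.
#' @export
demo_config_path <- function() {
  system.file("extdata", "demo_config.yaml", package = "demonmd", mustWork = TRUE)
}
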