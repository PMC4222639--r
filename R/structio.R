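#' Bead-level structure container
#'
#' A `cg_structure` is an ordered set of beads (one per residue for protein,
#' plus water/ion beads) with residue index, name, label, mass, charge, radius
#' and 3-D coordinates. Residue numbering is 1-based UniProt-style. Bonds are
#' stored as an index pair matrix; `rigid` tags beads that belong to the
#' restraint-stabilized core; `contacts` holds site-specific native contacts
#' (Gaussian wells) such as the Ser65 cleft bridge.
#'
#' @param atoms data.frame with columns `serial`, `res_id`, `res_name`,
#'   `atom_label`, `mass` (Da), `charge` (e), `radius` (Angstrom).
#' @param xyz numeric N x 3 matrix of coordinates (Angstrom).
#' @param chain_id single character chain identifier.
#' @param box optional length-3 box vector (Angstrom).
#' @param rigid logical vector tagging beads for elastic-network restraints.
#' @param bonds integer 2-column matrix of bonded bead indices (1-based).
#'   `NULL` derives a serial chain over protein (`CA`) beads.
#' @param contacts data.frame of site contacts with columns `i`, `j` (bead
#'   indices), `r0` (Angstrom), `depth` (kcal/mol), `width` (Angstrom).
#' @return an object of class `cg_structure`.
#' @export
cg_structure <- function(atoms, xyz, chain_id = "A", box = NULL,
                         rigid = NULL, bonds = NULL, contacts = NULL) {
  atoms <- as.data.frame(atoms)
  need <- c("serial", "res_id", "res_name", "atom_label", "mass", "charge", "radius")
  if (!all(need %in% names(atoms)))
    stop("atoms must have columns: ", paste(need, collapse = ", "))
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  dimnames(xyz) <- NULL
  n <- nrow(atoms)
  if (!is.matrix(xyz) || nrow(xyz) != n || ncol(xyz) != 3)
    stop("xyz must be an N x 3 matrix matching atoms")
  if (anyDuplicated(atoms$serial))
    .dmd_stop("duplicate bead serial numbers", "demonmd_invalid_structure")
  if (any(atoms$mass <= 0) || any(atoms$radius <= 0))
    .dmd_stop("bead mass and radius must be positive", "demonmd_invalid_structure")
  pro <- atoms$atom_label == "CA"
  if (is.unsorted(atoms$res_id[pro]))
    .dmd_stop("res_id must be non-decreasing along the chain",
              "demonmd_invalid_structure")
  if (is.null(rigid)) rigid <- rep(FALSE, n)
  if (is.null(bonds)) {
    idx <- which(pro)
    bonds <- if (length(idx) > 1) cbind(idx[-length(idx)], idx[-1]) else
      matrix(integer(0), 0, 2)
  }
  bonds <- matrix(as.integer(bonds), ncol = 2)
  if (nrow(bonds) && (min(bonds) < 1 || max(bonds) > n))
    .dmd_stop("bond topology references invalid bead indices",
              "demonmd_invalid_structure")
  if (is.null(contacts))
    contacts <- data.frame(i = integer(0), j = integer(0), r0 = numeric(0),
                           depth = numeric(0), width = numeric(0),
                           kind = character(0))
  if (is.null(contacts$kind)) contacts$kind <- "site"
  structure(list(atoms = atoms, xyz = xyz, chain_id = chain_id, box = box,
                 rigid = as.logical(rigid), bonds = bonds, contacts = contacts),
            class = "cg_structure")
}

#' @export
print.cg_structure <- function(x, ...) {
  n <- nrow(x$atoms)
  npro <- sum(x$atoms$atom_label == "CA")
  nw <- sum(x$atoms$atom_label == "W")
  cat(sprintf("cg_structure: %d beads (%d protein, %d water, %d other), chain %s\n",
              n, npro, nw, n - npro - nw, x$chain_id))
  cat(sprintf("  rigid-tagged: %d beads; bonds: %d; site contacts: %d\n",
              sum(x$rigid), nrow(x$bonds), nrow(x$contacts)))
  invisible(x)
}

#' Number of beads in a structure
#' @param s a `cg_structure`.
#' @return integer bead count.
#' @export
n_beads <- function(s) nrow(s$atoms)

# default CG bead parameters by atom label, used when a file carries no
# explicit mass/charge/radius (plain PDB input)
.bead_defaults <- function(label, res_name) {
  switch(label,
         CA = list(mass = 110, charge = 0, radius = 1.9),
         W  = list(mass = 18.015, charge = 0, radius = 1.4),
         "NA" = list(mass = 22.99, charge = 1, radius = 2.5),  # hydrated
         CL = list(mass = 35.45, charge = -1, radius = 2.4),  # hydrated
         P  = list(mass = 95, charge = -2, radius = 2.3),
         {
           warning("unknown bead label '", label,
                   "': using default bead (mass 110 Da, radius 1.9 A)")
           list(mass = 110, charge = 0, radius = 1.9)
         })
}

#' Read a structure from a PDB file
#'
#' Parses fixed-column `ATOM`/`HETATM` records (single model). Files written by
#' [write_pdb()] carry bead charge in the occupancy column, radius in the
#' B-factor column and rigidity/contact annotations in `REMARK 250` records;
#' plain PDB files fall back to a documented default bead table.
#'
#' @param path file path.
#' @return a `cg_structure`.
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty PDB file: ", path)
  res <- .parse_pdb_atoms(lines, path)
  if (!nrow(res$atoms)) stop("no ATOM/HETATM records in ", path)
  .structure_from_parsed(res, lines)
}

.parse_pdb_atoms <- function(lines, path, only = NULL) {
  sel <- grepl("^(ATOM  |HETATM)", lines)
  if (!is.null(only)) sel <- sel & only
  ln <- which(sel)
  rec <- lines[ln]
  parse_num <- function(txt, what, digits) {
    v <- suppressWarnings(as.numeric(txt))
    bad <- which(is.na(v))
    if (length(bad))
      stop(sprintf("malformed %s in %s at line %d", what, path, ln[bad[1]]))
    v
  }
  serial <- parse_num(substr(rec, 7, 11), "atom serial", NULL)
  label <- trimws(substr(rec, 13, 16))
  res_name <- trimws(substr(rec, 18, 20))
  chain <- substr(rec, 22, 22)
  res_id <- parse_num(substr(rec, 23, 26), "residue number", NULL)
  x <- parse_num(substr(rec, 31, 38), "x coordinate", NULL)
  y <- parse_num(substr(rec, 39, 46), "y coordinate", NULL)
  z <- parse_num(substr(rec, 47, 54), "z coordinate", NULL)
  occ <- suppressWarnings(as.numeric(substr(rec, 55, 60)))
  bfac <- suppressWarnings(as.numeric(substr(rec, 61, 66)))
  list(atoms = data.frame(serial = as.integer(serial), res_id = as.integer(res_id),
                          res_name = res_name, atom_label = label,
                          occ = occ, bfac = bfac),
       xyz = cbind(x, y, z), chain = chain, lineno = ln)
}

.structure_from_parsed <- function(res, lines) {
  at <- res$atoms
  n <- nrow(at)
  cg_dialect <- any(grepl("^REMARK 250 CGDIALECT", lines))
  mass <- charge <- radius <- numeric(n)
  for (i in seq_len(n)) {
    d <- .bead_defaults(at$atom_label[i], at$res_name[i])
    mass[i] <- d$mass; charge[i] <- d$charge; radius[i] <- d$radius
  }
  if (cg_dialect) {
    ok <- !is.na(at$occ); charge[ok] <- at$occ[ok]
    ok <- !is.na(at$bfac) & at$bfac > 0; radius[ok] <- at$bfac[ok]
  }
  atoms <- data.frame(serial = at$serial, res_id = at$res_id,
                      res_name = at$res_name, atom_label = at$atom_label,
                      mass = mass, charge = charge, radius = radius)
  rigid <- rep(FALSE, n)
  for (rm in grep("^REMARK 250 RIGID ", lines, value = TRUE)) {
    v <- as.integer(strsplit(trimws(sub("^REMARK 250 RIGID ", "", rm)), "\\s+")[[1]])
    rigid[atoms$res_id >= v[1] & atoms$res_id <= v[2] & atoms$atom_label == "CA"] <- TRUE
  }
  contacts <- NULL
  cl <- grep("^REMARK 250 CONTACT ", lines, value = TRUE)
  if (length(cl)) {
    toks <- lapply(cl, function(s)
      strsplit(trimws(sub("^REMARK 250 CONTACT ", "", s)), "\\s+")[[1]])
    vals <- do.call(rbind, lapply(toks, function(tk) as.numeric(tk[1:5])))
    kind <- vapply(toks, function(tk) if (length(tk) >= 6) tk[6] else "site", "")
    contacts <- data.frame(i = as.integer(vals[, 1]), j = as.integer(vals[, 2]),
                           r0 = vals[, 3], depth = vals[, 4], width = vals[, 5],
                           kind = kind)
  }
  cg_structure(atoms, res$xyz, chain_id = res$chain[1], rigid = rigid,
               contacts = contacts)
}

.pdb_atom_lines <- function(s) {
  at <- s$atoms
  hty <- ifelse(at$atom_label %in% c("W", "NA", "CL"), "HETATM", "ATOM  ")
  lab <- ifelse(nchar(at$atom_label) < 4, paste0(" ", at$atom_label), at$atom_label)
  # strict PDB columns: name 13-16, resName 18-20, chain 22, resSeq 23-26,
  # x/y/z 31-38/39-46/47-54, occupancy 55-60 (charge), B 61-66 (radius)
  sprintf("%s%5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          hty, at$serial, lab, at$res_name, s$chain_id, at$res_id,
          s$xyz[, 1], s$xyz[, 2], s$xyz[, 3], at$charge, at$radius)
}

.pdb_remarks <- function(s) {
  out <- "REMARK 250 CGDIALECT 1 (occupancy = charge e, B = radius A)"
  if (any(s$rigid)) {
    rid <- sort(unique(s$atoms$res_id[s$rigid]))
    brk <- c(0, which(diff(rid) > 1), length(rid))
    for (k in seq_len(length(brk) - 1)) {
      rr <- rid[(brk[k] + 1):brk[k + 1]]
      out <- c(out, sprintf("REMARK 250 RIGID %d %d", min(rr), max(rr)))
    }
  }
  if (nrow(s$contacts))
    out <- c(out, sprintf("REMARK 250 CONTACT %d %d %.4f %.4f %.4f %s",
                          s$contacts$i, s$contacts$j, s$contacts$r0,
                          s$contacts$depth, s$contacts$width, s$contacts$kind))
  out
}

#' Write a structure to a PDB file
#'
#' Fixed-column single-model PDB in the package's CG dialect: waters and ions
#' as `HETATM`, bead charge in the occupancy column, radius in the B column,
#' rigidity ranges and site contacts as `REMARK 250` annotations.
#'
#' @param s a `cg_structure`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_pdb <- function(s, path) {
  stopifnot(inherits(s, "cg_structure"))
  out <- c(.pdb_remarks(s), .pdb_atom_lines(s), "END")
  tryCatch(writeLines(out, path),
           error = function(e) stop("cannot write PDB to ", path, ": ",
                                    conditionMessage(e)))
  invisible(path)
}

#' Trajectory container
#'
#' Ordered frames sharing one topology. Frame times are in ps and must be
#' strictly increasing; every frame must carry one coordinate triple per bead.
#'
#' @param topology a `cg_structure`.
#' @param frames list of N x 3 coordinate matrices.
#' @param times numeric vector of frame times (ps).
#' @return an object of class `cg_trajectory`.
#' @export
cg_trajectory <- function(topology, frames, times) {
  stopifnot(inherits(topology, "cg_structure"))
  if (!length(frames)) stop("trajectory must contain at least one frame")
  n <- n_beads(topology)
  for (f in frames)
    if (!is.matrix(f) || nrow(f) != n || ncol(f) != 3)
      stop("every frame must be an N x 3 matrix matching the topology")
  if (length(times) != length(frames)) stop("times and frames lengths differ")
  if (any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  structure(list(topology = topology, frames = frames, times = as.numeric(times)),
            class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat(sprintf("cg_trajectory: %d frames x %d beads, t = %.4g .. %.4g ps\n",
              length(x$frames), n_beads(x$topology), min(x$times), max(x$times)))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param t a `cg_trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(t) length(t$frames)

#' Write a trajectory as multi-model PDB
#'
#' One `MODEL`/`ENDMDL` block per frame; frame time recorded in a
#' `REMARK 250 TIME` line inside each model.
#'
#' @param t a `cg_trajectory`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_trajectory <- function(t, path) {
  stopifnot(inherits(t, "cg_trajectory"))
  if (!length(t$frames)) stop("empty frame list")
  s <- t$topology
  out <- .pdb_remarks(s)
  for (k in seq_along(t$frames)) {
    s$xyz <- t$frames[[k]]
    out <- c(out, sprintf("MODEL     %4d", k),
             sprintf("REMARK 250 TIME %.6f", t$times[k]),
             .pdb_atom_lines(s), "ENDMDL")
  }
  out <- c(out, "END")
  tryCatch(writeLines(out, path),
           error = function(e) stop("cannot write trajectory to ", path, ": ",
                                    conditionMessage(e)))
  invisible(path)
}

#' Read a multi-model PDB trajectory
#'
#' Inverts [write_trajectory()]. A whitespace-delimited XYZ alternative is also
#' accepted: repeated blocks of `N`, a comment line (`t=<ps>` read if present),
#' then `label x y z` rows.
#'
#' @param path file path.
#' @return a `cg_trajectory`.
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!any(grepl("^(ATOM  |HETATM|MODEL)", lines))) return(.read_xyz_traj(lines, path))
  starts <- grep("^MODEL", lines)
  ends <- grep("^ENDMDL", lines)
  if (!length(starts)) stop("no MODEL records in ", path)
  if (length(starts) != length(ends)) stop("unbalanced MODEL/ENDMDL in ", path)
  frames <- vector("list", length(starts))
  times <- numeric(length(starts))
  topo <- NULL
  for (k in seq_along(starts)) {
    blk <- lines[starts[k]:ends[k]]
    res <- .parse_pdb_atoms(blk, path)
    if (is.null(topo)) topo <- .structure_from_parsed(res, lines)
    frames[[k]] <- unname(res$xyz)
    tl <- grep("^REMARK 250 TIME ", blk, value = TRUE)
    times[k] <- if (length(tl)) as.numeric(sub("^REMARK 250 TIME ", "", tl[1])) else k
  }
  cg_trajectory(topo, frames, times)
}

.read_xyz_traj <- function(lines, path) {
  lines <- lines[nzchar(trimws(lines))]
  frames <- list(); times <- numeric(0); pos <- 1; k <- 0
  topo <- NULL
  while (pos <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(n)) stop("malformed XYZ count at line ", pos, " of ", path)
    cm <- lines[pos + 1]
    tm <- regmatches(cm, regexpr("t=\\s*[-0-9.eE+]+", cm))
    k <- k + 1
    times[k] <- if (length(tm)) as.numeric(sub("t=\\s*", "", tm)) else k
    rows <- lines[(pos + 2):(pos + 1 + n)]
    toks <- do.call(rbind, strsplit(trimws(rows), "\\s+"))
    xyz <- apply(toks[, 2:4, drop = FALSE], 2, as.numeric)
    frames[[k]] <- matrix(xyz, ncol = 3)
    if (is.null(topo)) {
      lab <- toks[, 1]
      defs <- lapply(lab, .bead_defaults, res_name = "UNK")
      atoms <- data.frame(serial = seq_len(n), res_id = seq_len(n),
                          res_name = ifelse(lab == "W", "HOH", "ALA"),
                          atom_label = lab,
                          mass = vapply(defs, `[[`, 0, "mass"),
                          charge = vapply(defs, `[[`, 0, "charge"),
                          radius = vapply(defs, `[[`, 0, "radius"))
      topo <- cg_structure(atoms, frames[[1]])
    }
    pos <- pos + 2 + n
  }
  cg_trajectory(topo, frames, times)
}

#' Residue selection
#'
#' @param name selection name.
#' @param res_ids integer vector of residue ids (1-based).
#' @param atom_labels optional label filter (e.g. `"CA"`, `"W"`).
#' @return an object of class `cg_selection`.
#' @export
cg_selection <- function(name, res_ids, atom_labels = NULL) {
  res_ids <- sort(unique(as.integer(res_ids)))
  if (!length(res_ids)) stop("selection must be non-empty")
  structure(list(name = name, res_ids = res_ids, atom_labels = atom_labels),
            class = "cg_selection")
}

#' Named residue selections and domain map for Parkin
#'
#' The registry of residue sets used throughout the analysis, in UniProt-style
#' numbering of human Parkin: the domain map (UBL 1-76, linker 77-140, RING0
#' 141-216, RING1 217-328, IBR 329-378, REP 379-410, RING2 411-465), the two
#' cleft walls flanking Ser65, the center-of-mass probe sets CoM1/CoM2, the
#' E2-binding site in RING1, and single-residue probes (Ser65, Leu26, Cys238,
#' Phe364, Tyr391, Cys431, Arg163).
#'
#' @return a list with elements `domains` (named list of `c(first, last)`
#'   residue ranges) and `selections` (named list of [cg_selection] objects).
#' @export
parkin_selections <- function() {
  domains <- list(UBL = c(1, 76), linker = c(77, 140), RING0 = c(141, 216),
                  RING1 = c(217, 328), IBR = c(329, 378), REP = c(379, 410),
                  RING2 = c(411, 465))
  sel <- list(
    cleft_wall_1 = c(97, 110, 105, 111, 112, 115, 116, 117, 118),
    cleft_wall_2 = c(1, 2, 3, 4, 19, 61, 62, 63, 64, 66, 67),
    CoM1 = c(110, 111, 115),
    CoM2 = c(1, 2, 3, 4, 63),
    e2_site = c(236, 237, 238, 239, 240, 241, 242, 243, 244, 245,
                259, 260, 261, 262, 263, 264, 265, 266, 267),
    Ser65 = 65, Leu26 = 26, Cys238 = 238, Phe364 = 364, Tyr391 = 391,
    Cys431 = 431, Arg163 = 163)
  dm <- lapply(names(domains), function(d)
    cg_selection(d, seq(domains[[d]][1], domains[[d]][2])))
  names(dm) <- names(domains)
  selections <- c(lapply(names(sel), function(nm) cg_selection(nm, sel[[nm]])), dm)
  names(selections) <- c(names(sel), names(domains))
  list(domains = domains, selections = selections)
}

#' Export the selection registry as JSON
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_selection_registry <- function(path) {
  reg <- parkin_selections()
  out <- list(domains = reg$domains,
              selections = lapply(reg$selections, function(s) s$res_ids))
  jsonlite::write_json(out, path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' Resolve a selection to bead indices
#'
#' Returns the indices (in bead order) of beads whose residue id belongs to the
#' selection and whose label passes the optional filter. Requesting residues
#' absent from the structure is an error distinct from an empty label-filtered
#' result.
#'
#' @param s a `cg_structure`.
#' @param sel a `cg_selection`.
#' @return integer vector of bead indices.
#' @export
apply_selection <- function(s, sel) {
  stopifnot(inherits(s, "cg_structure"), inherits(sel, "cg_selection"))
  pres <- unique(s$atoms$res_id)
  missing <- setdiff(sel$res_ids, pres)
  if (length(missing))
    .dmd_stop(paste0("selection '", sel$name, "' requests residues absent from ",
                     "the structure: ", paste(head(missing, 5), collapse = ", ")),
              "demonmd_invalid_residue")
  idx <- which(s$atoms$res_id %in% sel$res_ids)
  if (!is.null(sel$atom_labels))
    idx <- idx[s$atoms$atom_label[idx] %in% sel$atom_labels]
  if (!length(idx))
    .dmd_stop(paste0("selection '", sel$name, "' matches no beads after label filter"),
              "demonmd_empty_selection")
  idx
}
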