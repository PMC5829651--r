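# Configuration files (YAML, one section per module), extended-XYZ
# trajectory output with per-bead role labels, TSV observables and
# plain-text contact maps.  Every run writes a manifest (config + seed +
# package version) sufficient to reproduce the trajectory bit-identically.

config_defaults <- function() {
  list(
    scenario = list(name = "fig1", overrides = list()),
    forcefield = list(l0 = 1, k_fene = 200, r_fene_max = 1.5, Lp_nm = 50,
                      Lt_nm = 75, eps_wca = 1, k_restraint = 60,
                      k_dihedral = 0.5, k_tether = 50, kT = 1),
    dynamics = list(dt = 5e-4, gamma_t = 1, gamma_r = 0.33, temperature = 1,
                    n_steps = 0, observe_every = 200, maintain_every = 20,
                    nlist_every = 20, skin = 1.5,
                    threaded_drag_multiplier = 10,
                    cohesin_drag_multiplier = 2,
                    threaded_rot_block = 1000, contact_dist = 3.5,
                    dwell = 5, aperture_r = 1.25, plane_tol = 1,
                    stop_R = NA, stop_on_dissociation = FALSE,
                    max_move = 0.05,
                    record_frames = TRUE,
                    record_profile = FALSE),
    units = list(sigma_nm = 10, bp_per_bead = 400),
    output = list(dir = ".", prefix = "run"),
    seed = 1)
}

config_ranges <- list(
  forcefield = list(l0 = c(0, Inf), k_fene = c(0, Inf),
                    r_fene_max = c(0, Inf), Lp_nm = c(0, Inf),
                    Lt_nm = c(0, Inf), eps_wca = c(0, Inf),
                    k_restraint = c(0, Inf), k_dihedral = c(0, Inf),
                    k_tether = c(0, Inf),
                    kT = c(0, Inf)),
  dynamics = list(dt = c(0, Inf), gamma_t = c(0, Inf), gamma_r = c(0, Inf),
                  temperature = c(-1e-12, Inf), n_steps = c(-1e-12, Inf),
                  observe_every = c(1, Inf), maintain_every = c(1, Inf),
                  nlist_every = c(1, Inf), skin = c(0, Inf),
                  threaded_drag_multiplier = c(1, Inf),
                  cohesin_drag_multiplier = c(1, Inf),
                  threaded_rot_block = c(1, Inf),
                  contact_dist = c(0, Inf), dwell = c(-1e-12, Inf),
                  aperture_r = c(0, Inf), plane_tol = c(0, Inf)),
  units = list(sigma_nm = c(0, Inf), bp_per_bead = c(0, Inf)))

#' Assemble a run configuration
#'
#' Fills defaults for every section (scenario, forcefield, dynamics, units,
#' output, seed), validating names and ranges; unknown keys are rejected
#' with the offending name.
#'
#' @param ... named sections (lists) or scalar fields (`seed`).
#' @return Object of class `sx_config`.
#' @export
run_config <- function(...) {
  user <- list(...)
  if (length(user) == 1 && is.null(names(user)) && is.list(user[[1]]))
    user <- user[[1]]
  defs <- config_defaults()
  bad <- setdiff(names(user), names(defs))
  if (length(bad))
    stop("unknown configuration section(s): ", paste(bad, collapse = ", "),
         "; expected ", paste(names(defs), collapse = ", "))
  for (sec in names(user)) {
    if (!is.list(defs[[sec]])) { defs[[sec]] <- user[[sec]]; next }
    unknown <- setdiff(names(user[[sec]]), names(defs[[sec]]))
    if (length(unknown))
      stop("unknown key(s) in section '", sec, "': ",
           paste(unknown, collapse = ", "))
    defs[[sec]] <- modifyList(defs[[sec]], user[[sec]])
  }
  for (sec in names(config_ranges)) {
    for (key in names(config_ranges[[sec]])) {
      v <- defs[[sec]][[key]]
      rng <- config_ranges[[sec]][[key]]
      if (is.numeric(v) && length(v) == 1 && !is.na(v) &&
          (v <= rng[1] || v > rng[2]))
        stop(sec, "$", key, " = ", v, " out of range (", rng[1], ", ",
             rng[2], "]")
    }
  }
  if (!is.null(defs$scenario$name) &&
      !defs$scenario$name %in% SCENARIO_NAMES)
    stop("scenario$name must be one of: ",
         paste(SCENARIO_NAMES, collapse = ", "))
  structure(defs, class = "sx_config")
}

#' Parse a configuration file
#'
#' Reads a YAML run configuration, fills defaults and validates keys and
#' ranges (an empty file yields the full default configuration).
#'
#' @param path file path.
#' @return An `sx_config`.
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  run_config(raw)
}

#' Write a configuration file
#' @param cfg an `sx_config`.
#' @param path output path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @export
print.sx_config <- function(x, ...) {
  cat("run configuration: scenario", x$scenario$name, "seed", x$seed, "\n")
  invisible(x)
}

config_objects <- function(cfg) {
  units <- unit_system(sigma_nm = cfg$units$sigma_nm,
                       bp_per_bead = cfg$units$bp_per_bead)
  ff <- do.call(forcefield_params, c(cfg$forcefield, list(units = units)))
  dyn <- do.call(dynamics_config, c(cfg$dynamics, list(seed = cfg$seed)))
  scn <- make_scenario(cfg$scenario$name,
                       c(cfg$scenario$overrides,
                         list(Lt_nm = cfg$forcefield$Lt_nm)))
  list(units = units, ff = ff, dyn = dyn, scn = scn)
}

bead_roles <- function(traj) {
  role <- c("fibre", "cohesin", "ctcf")[traj$species + 1]
  st <- traj$state
  role[seq_len(traj$n_fiber)][st$phantom[seq_len(traj$n_fiber)]] <- "phantom"
  role
}

#' Write a trajectory to disk
#'
#' Writes `<prefix>.xyz` (extended XYZ, one block per recorded frame, with
#' per-bead role labels fibre/phantom/cohesin/ctcf), `<prefix>.obs.tsv`
#' (one row of observables per frame), `<prefix>.events.tsv` and
#' `<prefix>.manifest.yaml` (system size, topology, seed, package version).
#' Coordinates are stored at 1e-6 sigma precision.
#'
#' @param traj an `sx_trajectory` with recorded frames.
#' @param prefix output path prefix.
#' @return The prefix, invisibly.
#' @export
write_trajectory <- function(traj, prefix) {
  stopifnot(inherits(traj, "sx_trajectory"))
  role <- bead_roles(traj)
  con <- file(paste0(prefix, ".xyz"), "w")
  on.exit(close(con))
  times <- traj$obs$time
  for (k in seq_along(traj$frames)) {
    fr <- traj$frames[[k]]
    writeLines(as.character(nrow(fr)), con)
    writeLines(sprintf("frame=%d time=%.6f", k, times[min(k, length(times))]),
               con)
    writeLines(sprintf("%s %.6f %.6f %.6f", role, fr[, 1], fr[, 2], fr[, 3]),
               con)
  }
  write.table(traj$obs, paste0(prefix, ".obs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(traj$events, paste0(prefix, ".events.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  manifest <- list(
    package = "supercoilex",
    version = as.character(packageVersion("supercoilex")),
    n_beads = nrow(traj$frames[[1]]),
    n_fiber = traj$n_fiber,
    circular = traj$circular,
    n_frames = length(traj$frames),
    seed = traj$config$seed,
    dt = traj$config$dt,
    scenario = if (!is.null(traj$scenario)) traj$scenario$name else NA)
  yaml::write_yaml(manifest, paste0(prefix, ".manifest.yaml"))
  invisible(prefix)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' Restores the frames, role labels, observables and manifest.  A truncated
#' XYZ file raises an explicit corruption error naming the frame index.
#'
#' @param prefix path prefix used when writing.
#' @return A list of class `sx_trajectory_view` with `frames`, `roles`,
#'   `obs`, `events`, `manifest`, `n_fiber`, `circular`.
#' @export
read_trajectory <- function(prefix) {
  xyz <- paste0(prefix, ".xyz")
  if (!file.exists(xyz)) stop("no trajectory at prefix: ", prefix)
  lines <- readLines(xyz)
  frames <- list()
  roles <- NULL
  pos <- 1
  k <- 0
  while (pos <= length(lines)) {
    if (!grepl("^[0-9]+$", lines[pos]))
      stop("corrupt trajectory file at frame ", k + 1,
           ": expected bead count, got '", lines[pos], "'")
    n <- as.integer(lines[pos])
    k <- k + 1
    if (pos + 1 + n > length(lines))
      stop("corrupt trajectory file: frame ", k, " truncated (expected ", n,
           " beads)")
    block <- lines[(pos + 2):(pos + 1 + n)]
    parts <- strsplit(block, " +")
    roles <- vapply(parts, `[`, "", 1)
    xyzm <- matrix(as.numeric(vapply(parts, function(p) p[2:4], character(3))),
                   ncol = 3, byrow = TRUE)
    frames[[k]] <- xyzm
    pos <- pos + 2 + n
  }
  obs_path <- paste0(prefix, ".obs.tsv")
  obs <- if (file.exists(obs_path))
    read.table(obs_path, header = TRUE, sep = "\t") else NULL
  ev_path <- paste0(prefix, ".events.tsv")
  events <- if (file.exists(ev_path))
    read.table(ev_path, header = TRUE, sep = "\t") else NULL
  man_path <- paste0(prefix, ".manifest.yaml")
  manifest <- if (file.exists(man_path)) yaml::read_yaml(man_path) else NULL
  structure(list(frames = frames, roles = roles, obs = obs, events = events,
                 manifest = manifest,
                 n_fiber = if (!is.null(manifest)) manifest$n_fiber else
                   sum(roles %in% c("fibre", "phantom")),
                 circular = isTRUE(manifest$circular)),
            class = "sx_trajectory_view")
}

#' Write / read a contact map as plain text
#'
#' Dense whitespace-separated matrix with a header comment carrying the
#' cutoff and frame count.
#'
#' @param m an `sx_contact_map` (or plain matrix).
#' @param path file path.
#' @export
write_contact_map <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# supercoilex contact map cutoff=%g frames=%d",
                     attr(m, "cutoff") %||% NA, attr(m, "n_frames") %||% NA),
             con)
  write.table(unclass(m), con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_contact_map
#' @export
read_contact_map <- function(path) {
  header <- readLines(path, n = 1)
  cutoff <- as.numeric(sub(".*cutoff=([0-9.eE+-]+).*", "\\1", header))
  nfr <- as.integer(sub(".*frames=([0-9]+).*", "\\1", header))
  m <- as.matrix(read.table(path, skip = 1))
  dimnames(m) <- NULL
  structure(m, cutoff = cutoff, n_frames = nfr,
            class = c("sx_contact_map", class(m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
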