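#' Assemble a simulation state
#'
#' Combines a fibre, cohesin handcuffs and the fibre's CTCF sites into the
#' flat particle system integrated by the engine: fibre beads first, then
#' handcuff beads, then one obstacle bead per CTCF site (tethered
#' concentrically to its attachment bead).  Per-bead drag multipliers follow
#' the threading rules: 10x for fibre beads currently threading a ring, 2x
#' for all cohesin beads, obstacle beads scale with their diameter.
#'
#' @param fiber an `sx_fiber` (optionally annotated with swivels, phantom
#'   regions and CTCF sites).
#' @param handcuffs list of `sx_handcuff` objects (or a single one), already
#'   placed with [thread_handcuff()] (or far from the fibre).
#' @param ff an [forcefield_params()].
#' @return Object of class `sx_state`.
#' @export
simulation_state <- function(fiber, handcuffs = list(),
                             ff = forcefield_params()) {
  if (inherits(handcuffs, "sx_handcuff")) handcuffs <- list(handcuffs)
  nf <- n_beads(fiber)
  nb <- n_bonds(fiber)
  x <- fiber$positions
  species <- rep(0L, nf)
  radius <- rep(fiber$bead_radius, nf)
  base_mult <- rep(1, nf)
  cuff_id <- rep(-1L, nf)
  phantom <- rep(FALSE, nf)
  phantom[fiber$phantom_beads] <- TRUE
  restraints <- NULL
  dihedrals <- NULL
  cuff_list <- list()

  for (ci in seq_along(handcuffs)) {
    h <- handcuffs[[ci]]
    off <- nrow(x)                       # 0-based offset for engine indices
    x <- rbind(x, h$beads)
    nh <- nrow(h$beads)
    species <- c(species, rep(1L, nh))
    radius <- c(radius, rep(h$cohesin_bead_radius, nh))
    base_mult <- c(base_mult, rep(2, nh))     # cohesin drag 2x
    cuff_id <- c(cuff_id, rep(ci - 1L, nh))
    phantom <- c(phantom, rep(FALSE, nh))
    rp <- h$restraint_pairs
    restraints <- rbind(restraints,
                        cbind(off + rp[, 1] - 1, off + rp[, 2] - 1, rp[, 3],
                              ff$k_restraint))
    dq <- h$dihedral_quads
    dihedrals <- rbind(dihedrals,
                       cbind(off + dq[, 1] - 1, off + dq[, 2] - 1,
                             off + dq[, 3] - 1, off + dq[, 4] - 1,
                             ff$k_dihedral, dq[, 5]))
    cuff_list[[ci]] <- list(
      ring_a = as.integer(off + h$ring_a - 1),
      ring_b = as.integer(off + h$ring_b - 1),
      shared = as.integer(off + h$shared - 1),
      alive = isTRUE(h$alive),
      state_a = if (identical(h$state_a, "anchored")) 1L else 0L,
      state_b = if (identical(h$state_b, "anchored")) 1L else 0L,
      threaded_a = if (is.na(h$threaded_a)) -1L else as.integer(h$threaded_a - 1),
      threaded_b = if (is.na(h$threaded_b)) -1L else as.integer(h$threaded_b - 1))
  }

  ctcf_list <- list()
  for (si in seq_along(fiber$ctcf_sites)) {
    s <- fiber$ctcf_sites[[si]]
    gi <- nrow(x)                        # 0-based index of the obstacle bead
    x <- rbind(x, fiber$positions[s$fibre_bead, , drop = FALSE])
    species <- c(species, 2L)
    radius <- c(radius, s$obstacle_diameter / 2)
    base_mult <- c(base_mult, s$obstacle_diameter)   # Stokes drag ~ diameter
    cuff_id <- c(cuff_id, -1L)
    phantom <- c(phantom, FALSE)
    restraints <- rbind(restraints,
                        cbind(gi, s$fibre_bead - 1, 0, ff$k_tether))
    ctcf_list[[si]] <- list(bead = as.integer(gi),
                            attach = as.integer(s$fibre_bead - 1),
                            orient = switch(s$orientation, convergent = 1L,
                                            divergent = -1L, obstacle = 0L))
  }
  if (is.null(restraints)) restraints <- matrix(0, 0, 4)
  if (is.null(dihedrals)) dihedrals <- matrix(0, 0, 6)

  # R joint j (1-based bead) maps to engine vertex j - 1 (0-based)
  vertex_passive <- logical(nb)
  vertex_passive[fiber$passive_swivels] <- TRUE
  actives <- lapply(fiber$active_swivels, function(s) list(
    vertex = as.integer(s$joint - 1L),
    rate = s$rate, sign = as.integer(s$sign), barrier = isTRUE(s$barrier),
    injected = s$injected_R))

  structure(list(
    fiber = fiber, handcuffs = handcuffs, ff = ff,
    n_fiber = nf, circular = fiber$circular,
    x = unname(as.matrix(x)), species = species, radius = radius,
    base_mult = base_mult, cuff_id = cuff_id, phantom = phantom,
    theta = fiber$joint_twist,
    phi0 = rep(0, nb),
    vertex_passive = vertex_passive,
    actives = actives, cuffs = cuff_list, ctcf = ctcf_list,
    restraints = unname(restraints),
    dihedrals = unname(dihedrals),
    dirs = NULL, m = NULL, Lk0 = NULL, time = 0
  ), class = "sx_state")
}

#' @export
print.sx_state <- function(x, ...) {
  cat(sprintf("simulation state: %d beads (%d fibre%s), %d handcuff(s), %d CTCF, t = %g tau\n",
              nrow(x$x), x$n_fiber, if (x$circular) ", circular" else "",
              length(x$cuffs), length(x$ctcf), x$time))
  invisible(x)
}

# engine-facing list
engine_system <- function(state) {
  list(x = state$x, n_fiber = state$n_fiber, circular = state$circular,
       species = state$species, radius = state$radius,
       base_mult = state$base_mult, phantom = state$phantom,
       cuff_id = state$cuff_id, theta = state$theta, phi0 = state$phi0,
       vertex_passive = state$vertex_passive, actives = state$actives,
       cuffs = state$cuffs, ctcf = state$ctcf,
       restraints = state$restraints,
       dihedrals = state$dihedrals,
       m0 = state$m,
       ff = list(l0 = state$ff$l0, k_fene = state$ff$k_fene,
                 r_fene_max = state$ff$r_fene_max, k_bend = state$ff$k_bend,
                 C = state$ff$C, eps_wca = state$ff$eps_wca,
                 kT = state$ff$kT),
       dirs = state$dirs, Lk0 = state$Lk0)
}

#' Forces, torques and energies of a state
#'
#' Single evaluation of the full force field on a simulation state: FENE
#' bonds, bending, twist elasticity (with swivel exceptions and the
#' twist-bend coupling through the parallel-transport framing), WCA excluded
#' volume with phantom masking, and all harmonic restraints.
#'
#' @param state an `sx_state`.
#' @param config a [dynamics_config()] (geometry/threading parameters).
#' @return List with per-bead force matrix `F` (kT/sigma), per-bond twist
#'   torques `tau` (kT), joint twists `phi`, energy components (kT), the
#'   per-bead drag multipliers and the minimal non-bonded distance.
#' @export
state_forces <- function(state, config = dynamics_config()) {
  cpp_forces(engine_system(state), engine_control(config))
}

#' Update threading detection and drag multipliers
#'
#' Recomputes, for every ring of every live handcuff, which fibre bead lies
#' nearest the ring centre within the inner aperture and within +-1 sigma of
#' the ring plane (ties broken towards the lowest index).  That bead's drag
#' multiplier is set to the threaded value (10x), restored when it exits;
#' cohesin beads always carry 2x.
#'
#' @param state an `sx_state`.
#' @param config a [dynamics_config()].
#' @return The state with updated `handcuffs[[i]]$threaded_*`, cuff records
#'   and a `per_bead_drag` field.
#' @export
update_threading_and_drag <- function(state, config = dynamics_config()) {
  drag <- state$base_mult
  for (ci in seq_along(state$cuffs)) {
    cf <- state$cuffs[[ci]]
    if (!cf$alive) next
    for (ring in c("a", "b")) {
      idx <- if (ring == "a") cf$ring_a else cf$ring_b
      det <- cpp_detect_threading(state$x, state$n_fiber, idx,
                                  config$aperture_r, config$plane_tol)
      bead <- det$bead
      fld <- paste0("threaded_", ring)
      state$cuffs[[ci]][[fld]] <- bead
      state$handcuffs[[ci]][[fld]] <-
        if (bead < 0) NA_integer_ else as.integer(bead + 1)
      if (bead >= 0) drag[bead + 1] <- config$threaded_drag_multiplier
    }
  }
  state$per_bead_drag <- drag
  state
}

#' Advance active swivels (bookkeeping operation)
#'
#' Advances the intrinsic twist offset of every active swivel by its rate
#' over `dt` and accumulates the injected-rotation counters
#' (`injected_R = rate * dt`, exactly).  The same operation runs inside the
#' integrator every step; this R-level version exposes the bookkeeping.
#'
#' @param state an `sx_state`.
#' @param dt time interval (tau).
#' @export
advance_active_swivels <- function(state, dt) {
  for (ai in seq_along(state$actives)) {
    a <- state$actives[[ai]]
    if (!a$barrier)
      state$phi0[a$vertex + 1] <- state$phi0[a$vertex + 1] -
        a$sign * 2 * pi * a$rate * dt
    state$actives[[ai]]$injected <- a$injected + a$rate * dt
  }
  state$fiber$active_swivels <- mapply(function(s, a) {
    s$injected_R <- a$injected; s
  }, state$fiber$active_swivels, state$actives, SIMPLIFY = FALSE)
  state
}
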