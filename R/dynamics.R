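#' Dynamics configuration
#'
#' Parameters of the overdamped Langevin (Euler--Maruyama) integrator.
#' Positions advance by `F/gamma * dt` plus Gaussian noise of variance
#' `2 kT dt / gamma` per coordinate, with `gamma = gamma_t` times the bead's
#' drag multiplier; per-bond material twist angles advance the same way
#' against the rotational drag `gamma_r`.  Fluctuation and dissipation are
#' therefore matched per effective drag, so a 10x threaded bead is both
#' slower and quieter.
#'
#' @param dt timestep (tau).  The default 5e-4 keeps FENE bonds far from
#'   their extensibility limit at default stiffnesses; over-extension aborts
#'   the run with a diagnostic.
#' @param gamma_t base translational friction (kT tau/sigma^2).
#' @param gamma_r base rotational friction per bond about the fibre axis
#'   (kT tau).  The default 0.33 is the no-slip cylinder estimate
#'   `4 pi eta r_fibre^2 l0` with `eta` implied by `gamma_t`.
#' @param temperature thermal energy (kT units; 0 switches noise off).
#' @param n_steps number of integration steps.
#' @param observe_every record observables every this many steps.
#' @param maintain_every threading/drag/CTCF bookkeeping cadence (steps).
#' @param nlist_every neighbour-list refresh cadence (steps).
#' @param skin neighbour-list skin (sigma).
#' @param threaded_drag_multiplier drag factor for fibre beads inside a ring.
#' @param cohesin_drag_multiplier drag factor for all cohesin beads.
#' @param threaded_rot_block rotational-drag factor applied to the two bonds
#'   touching a threaded bead.  A ring around a bent fibre sterically blocks
#'   the crankshaft (axial-spin) motion that carries twist; with twist as an
#'   internal coordinate that blocking must be imposed on the twist friction
#'   directly, and the default (1000) makes a threaded joint essentially
#'   non-conducting while leaving the translational drag at the 10x rule.
#' @param contact_dist ring-centre to CTCF-centre contact distance (sigma).
#' @param dwell divergent-orientation contact time before dissociation (tau).
#' @param aperture_r threading-detector aperture radius (sigma).
#' @param plane_tol threading-detector half-thickness of the ring-plane slab
#'   (sigma).
#' @param max_move cap on the per-step deterministic displacement (sigma);
#'   inactive at moderate forces, it keeps the explicit integrator stable
#'   inside the divergent FENE/WCA walls.
#' @param stop_R stop once the cumulative injected rotations of any active
#'   swivel reach this value (NA: run the full `n_steps`).
#' @param stop_on_dissociation stop once every handcuff has dissociated.
#' @param record_frames keep bead coordinates at every observation.
#' @param record_profile keep the per-segment writhe density profile.
#' @param seed RNG seed for the engine's own generator.
#' @return Object of class `sx_dynamics`.
#' @export
dynamics_config <- function(dt = 5e-4, gamma_t = 1, gamma_r = 0.33,
                            temperature = 1, n_steps = 0L,
                            observe_every = 200L, maintain_every = 20L,
                            nlist_every = 20L, skin = 1.5,
                            threaded_drag_multiplier = 10,
                            cohesin_drag_multiplier = 2,
                            threaded_rot_block = 1000,
                            contact_dist = 3.5, dwell = 5,
                            aperture_r = 1.25, plane_tol = 1,
                            stop_R = NA_real_, stop_on_dissociation = FALSE,
                            max_move = 0.05,
                            record_frames = TRUE,
                            record_profile = FALSE, seed = 1L) {
  stopifnot(dt > 0, gamma_t > 0, gamma_r > 0, temperature >= 0,
            n_steps >= 0, observe_every >= 1, maintain_every >= 1,
            threaded_drag_multiplier >= 1, cohesin_drag_multiplier >= 1,
            contact_dist > 0, dwell >= 0, aperture_r > 0, plane_tol > 0)
  structure(list(
    dt = dt, gamma_t = gamma_t, gamma_r = gamma_r,
    temperature = temperature, n_steps = as.integer(n_steps),
    observe_every = as.integer(observe_every),
    maintain_every = as.integer(maintain_every),
    nlist_every = as.integer(nlist_every), skin = skin,
    threaded_drag_multiplier = threaded_drag_multiplier,
    cohesin_drag_multiplier = cohesin_drag_multiplier,
    threaded_rot_block = threaded_rot_block,
    contact_dist = contact_dist, dwell = dwell,
    aperture_r = aperture_r, plane_tol = plane_tol,
    stop_R = stop_R,
    stop_on_dissociation = isTRUE(stop_on_dissociation),
    max_move = max_move,
    record_frames = isTRUE(record_frames),
    record_profile = isTRUE(record_profile), seed = as.integer(seed)
  ), class = "sx_dynamics")
}

#' @export
print.sx_dynamics <- function(x, ...) {
  cat(sprintf(paste0("dynamics: dt=%g tau, gamma_t=%g, gamma_r=%g, kT=%g, ",
                     "%d steps (observe every %d), seed %d\n"),
              x$dt, x$gamma_t, x$gamma_r, x$temperature, x$n_steps,
              x$observe_every, x$seed))
  invisible(x)
}

engine_control <- function(config) {
  list(dt = config$dt, gamma_t = config$gamma_t, gamma_r = config$gamma_r,
       temperature = config$temperature,
       thread_mult = config$threaded_drag_multiplier,
       cuff_mult = config$cohesin_drag_multiplier,
       contact_dist = config$contact_dist, dwell = config$dwell,
       aperture_r = config$aperture_r, plane_tol = config$plane_tol,
       maintain_every = config$maintain_every,
       observe_every = config$observe_every,
       nlist_every = config$nlist_every, skin = config$skin,
       max_move = config$max_move,
       rot_block = config$threaded_rot_block,
       n_steps = as.double(config$n_steps),
       stop_R = if (is.na(config$stop_R)) -1 else config$stop_R,
       stop_on_dissociation = config$stop_on_dissociation,
       record_frames = config$record_frames,
       record_profile = config$record_profile,
       time0 = 0)
}

#' Run the Brownian dynamics
#'
#' Integrates a simulation state for `config$n_steps` steps (or until the
#' injected-rotation stop condition), performing active-swivel driving,
#' threading-dependent drag modulation and the CTCF anchor/dissociate rule,
#' and recording topological observables at the configured cadence.  Fully
#' reproducible: the same state, configuration and seed give a bit-identical
#' trajectory.
#'
#' @param state an `sx_state` from [simulation_state()].
#' @param config a [dynamics_config()].
#' @return Object of class `sx_trajectory`: `obs` (one data.frame row per
#'   observation: time, Tw, Tw_free, Wr, lk_deficit, injected_R, threaded
#'   bead per ring, loop extent, enclosed writhe, minimal non-bonded
#'   distance), `frames` (bead coordinate matrices), `events`
#'   (threaded/unthreaded/anchored/dissociated transitions with timestamps),
#'   and the final `state` (reusable for analysis).
#' @examples
#' f <- build_fiber(n_beads = 40, circular = TRUE)
#' st <- simulation_state(f)
#' tr <- run_dynamics(st, dynamics_config(n_steps = 100, observe_every = 50))
#' tr$obs$Wr
#' @export
run_dynamics <- function(state, config = dynamics_config()) {
  stopifnot(inherits(state, "sx_state"), inherits(config, "sx_dynamics"))
  res <- cpp_run(engine_system(state), engine_control(config), config$seed)
  obs <- as.data.frame(res$obs)
  # engine indices are 0-based; report beads 1-based, NA when unthreaded
  obs$threaded_a <- ifelse(obs$threaded_a < 0, NA_integer_, obs$threaded_a + 1L)
  obs$threaded_b <- ifelse(obs$threaded_b < 0, NA_integer_, obs$threaded_b + 1L)

  fin <- res$final
  out_state <- state
  out_state$x <- fin$x
  out_state$theta <- fin$theta
  out_state$phi0 <- fin$phi0
  out_state$dirs <- fin$dirs
  out_state$m <- fin$m
  out_state$Lk0 <- fin$Lk0
  out_state$time <- fin$time
  out_state$per_bead_drag <- fin$mult
  nf <- state$n_fiber
  out_state$fiber$positions <- fin$x[seq_len(nf), , drop = FALSE]
  out_state$fiber$joint_twist <- fin$theta
  for (ai in seq_along(out_state$actives))
    out_state$actives[[ai]]$injected <- fin$injected[ai]
  for (ai in seq_along(out_state$fiber$active_swivels))
    out_state$fiber$active_swivels[[ai]]$injected_R <- fin$injected[ai]
  for (ci in seq_along(out_state$cuffs)) {
    fc <- fin$cuffs[[ci]]
    out_state$cuffs[[ci]]$alive <- fc$alive
    out_state$cuffs[[ci]]$state_a <- fc$state_a
    out_state$cuffs[[ci]]$state_b <- fc$state_b
    out_state$cuffs[[ci]]$threaded_a <- fc$threaded_a
    out_state$cuffs[[ci]]$threaded_b <- fc$threaded_b
    h <- out_state$handcuffs[[ci]]
    glob <- sort(unique(c(out_state$cuffs[[ci]]$ring_a,
                          out_state$cuffs[[ci]]$ring_b))) + 1
    h$beads <- fin$x[glob, , drop = FALSE]
    h$alive <- fc$alive
    h$state_a <- if (!fc$alive) "dissociated" else
      if (fc$state_a == 1) "anchored" else "active"
    h$state_b <- if (!fc$alive) "dissociated" else
      if (fc$state_b == 1) "anchored" else "active"
    h$threaded_a <- if (fc$threaded_a < 0) NA_integer_ else fc$threaded_a + 1L
    h$threaded_b <- if (fc$threaded_b < 0) NA_integer_ else fc$threaded_b + 1L
    out_state$handcuffs[[ci]] <- h
  }

  ev <- res$events
  ev$cuff <- ev$cuff + 1L
  ev$ring <- ifelse(ev$ring < 0, NA_integer_, ev$ring + 1L)
  ev$detail <- ifelse(ev$detail < 0, NA_integer_, ev$detail + 1L)

  structure(list(
    obs = obs, frames = res$frames, profiles = res$profiles, events = ev,
    state = out_state, config = config, n_fiber = nf,
    species = state$species, circular = state$circular,
    n_steps_done = res$n_steps_done
  ), class = "sx_trajectory")
}

#' Single integration step
#'
#' Convenience wrapper advancing a state by `n` steps (default one) and
#' returning the updated state.
#'
#' @param state an `sx_state`.
#' @param config a [dynamics_config()] (its `n_steps` is ignored).
#' @param n number of steps.
#' @export
step_dynamics <- function(state, config = dynamics_config(), n = 1L) {
  config$n_steps <- as.integer(n)
  config$record_frames <- FALSE
  run_dynamics(state, config)$state
}

#' @export
print.sx_trajectory <- function(x, ...) {
  o <- x$obs
  cat(sprintf(paste0("trajectory: %d observations over %g tau (%g steps), ",
                     "final Tw=%.2f Wr=%.2f lk_deficit=%.3f\n"),
              nrow(o), max(o$time), x$n_steps_done,
              o$Tw[nrow(o)], o$Wr[nrow(o)], o$lk_deficit[nrow(o)]))
  invisible(x)
}

#' @export
plot.sx_trajectory <- function(x, which = c("topology", "loop"), ...) {
  which <- match.arg(which)
  o <- x$obs
  if (which == "topology") {
    rng <- range(c(o$Tw, o$Wr, o$Tw + o$Wr), na.rm = TRUE)
    plot(o$time, o$Tw, type = "l", col = "steelblue", ylim = rng,
         xlab = "time (tau)", ylab = "turns", ...)
    lines(o$time, o$Wr, col = "firebrick")
    lines(o$time, o$Tw + o$Wr, col = "black", lty = 2)
    legend("bottomleft", c("Tw", "Wr", "Tw+Wr"), lty = c(1, 1, 2),
           col = c("steelblue", "firebrick", "black"), bty = "n")
  } else {
    plot(o$time, o$loop_extent, type = "s", xlab = "time (tau)",
         ylab = "loop extent (beads)", ...)
  }
  invisible(x)
}
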