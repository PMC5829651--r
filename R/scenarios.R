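# Programmatic builders for the in-silico experiments: a circular TAD-sized
# fibre (300 beads = 120 kb by default) with an active swivel injecting
# negative supercoiling; TAD borders carrying passive swivels flanked by
# 3-bead phantom regions (TOP2B emulation); optionally a cohesin handcuff
# threaded around the transcribed segment, and CTCF obstacle beads at the
# borders.  Placements scale with n_beads so the same scenarios run at
# reduced size.
#
# Geometry (1-based beads, defaults n = 300): borders at beads 1 and n/2+1
# (diametrically opposite); the TAD is the arc between them that contains
# the swivel.  fig1 has no borders and its swivel at n/2+1; bordered
# scenarios centre the swivel mid-TAD (bead n/4+1), except fig4/fig5 where
# the source sits a quarter TAD from the near border (bead n/8+1).

SCENARIO_NAMES <- c("fig1", "fig2_free", "fig2_handcuffed", "fig3",
                    "fig4_asymmetric", "fig5_convergent", "fig5_divergent",
                    "supp_low_twist", "supp_barrier")

#' Build a named scenario
#'
#' Returns the fully resolved configuration of one of the packaged
#' experiments:
#' \describe{
#'   \item{fig1}{closed 300-bead fibre, one active swivel, nothing else:
#'     negative supercoil accumulation and plectoneme formation.}
#'   \item{fig2_free}{fig1 geometry plus two border loci (passive swivel +
#'     3-bead phantom region each): supercoiling dissipates, no accumulation.}
#'   \item{fig2_handcuffed}{fig2_free plus a cohesin handcuff threaded
#'     symmetrically around the swivel: supercoiling localizes between the
#'     rings.}
#'   \item{fig3}{fig2_handcuffed run to border arrival: supercoiling-driven
#'     loop extrusion.}
#'   \item{fig4_asymmetric}{off-centre swivel, asymmetric threading, CTCF
#'     obstacle beads at both borders (convergent).}
#'   \item{fig5_convergent, fig5_divergent}{fig4 with both CTCF sites set to
#'     the given orientation: anchored stable loop vs dissociation.}
#'   \item{supp_low_twist}{fig3 with tenfold lower torsional stiffness.}
#'   \item{supp_barrier}{fig3 with the swivel acting as a topological
#'     barrier (continuous transcription, hemi-plectoneme regime).}
#' }
#'
#' @param name scenario name (see above).
#' @param overrides named list replacing any scenario field (e.g.
#'   `list(n_beads = 150)` scales every placement; or `rate`, `stop_R`,
#'   `Lt_nm`, `thread_offsets`, `seed`...).
#' @return Object of class `sx_scenario`.
#' @examples
#' make_scenario("fig1")
#' make_scenario("fig3", list(n_beads = 150))
#' @export
make_scenario <- function(name, overrides = list()) {
  if (!name %in% SCENARIO_NAMES)
    stop("unknown scenario '", name, "'; valid names: ",
         paste(SCENARIO_NAMES, collapse = ", "))
  scn <- list(name = name, n_beads = 300L, circular = TRUE,
              rate = 0.005, sign = -1L, barrier = FALSE,
              Lt_nm = 75, stop_R = 10,
              thread_offsets = NULL,     # c(left, right) beads from swivel
              asym_offsets = FALSE,
              swivel_frac = NA_real_,    # resolved below
              preload_turns = 2,
              with_borders = TRUE, with_handcuff = FALSE,
              ctcf_orientation = NULL,
              expected = "")
  scn <- switch(name,
    fig1 = modifyList(scn, list(with_borders = FALSE, swivel_frac = 0.5,
      expected = "negative plectonemes; |Delta(Tw+Wr)| = injected R")),
    fig2_free = modifyList(scn, list(swivel_frac = 0.25,
      expected = "no accumulation of supercoiling; low steady |Wr|")),
    fig2_handcuffed = modifyList(scn, list(swivel_frac = 0.25,
      with_handcuff = TRUE,
      expected = "supercoiling localized between the rings")),
    fig3 = modifyList(scn, list(swivel_frac = 0.25, with_handcuff = TRUE,
      stop_R = 40,
      expected = "loop grows to the whole TAD")),
    fig4_asymmetric = modifyList(scn, list(swivel_frac = 0.125,
      with_handcuff = TRUE, stop_R = 40, ctcf_orientation = "convergent",
      asym_offsets = TRUE,
      expected = "near ring anchors first, far ring keeps moving")),
    fig5_convergent = modifyList(scn, list(swivel_frac = 0.125,
      with_handcuff = TRUE, stop_R = 40, ctcf_orientation = "convergent",
      asym_offsets = TRUE,
      expected = "anchored handcuff, strong border-border contact")),
    fig5_divergent = modifyList(scn, list(swivel_frac = 0.125,
      with_handcuff = TRUE, stop_R = 40, ctcf_orientation = "divergent",
      asym_offsets = TRUE,
      expected = "handcuff dissociates, supercoiling relaxes")),
    supp_low_twist = modifyList(scn, list(swivel_frac = 0.25,
      with_handcuff = TRUE, stop_R = 40, Lt_nm = 7.5,
      expected = "pushing persists at tenfold lower torsional stiffness")),
    supp_barrier = modifyList(scn, list(swivel_frac = 0.25,
      with_handcuff = TRUE, stop_R = 40, barrier = TRUE,
      expected = "hemi-plectoneme: one flank supercoiled, one relaxed")))
  scn <- modifyList(scn, overrides)
  scn$n_beads <- as.integer(scn$n_beads)
  n <- scn$n_beads
  if (is.null(scn[["swivel"]]))
    scn$swivel <- 1L + as.integer(round(n * scn$swivel_frac))
  if (scn$with_borders) {
    if (is.null(scn[["borders"]])) scn$borders <- c(1L, 1L + n %/% 2L)
    if (is.null(scn[["phantoms"]]))
      scn$phantoms <- sort(unique(((rep(scn$borders, each = 3) +
                                      c(-1L, 0L, 1L)) - 1L) %% n + 1L))
  } else scn$borders <- scn$phantoms <- NULL
  if (scn$with_handcuff) {
    if (is.null(scn$thread_offsets)) {
      if (isTRUE(scn[["asym_offsets"]]))   # ring A much nearer the source
        scn$thread_offsets <- c(-max(4L, as.integer(round(n / 30))),
                                max(8L, as.integer(round(2 * n / 15))))
      else {
        off <- max(5L, as.integer(round(n / 15)))
        scn$thread_offsets <- c(-off, off)
      }
    }
    scn$thread_at <- ((scn[["swivel"]] + scn$thread_offsets) - 1L) %% n + 1L
  } else scn$thread_at <- NULL
  if (!is.null(scn$ctcf_orientation)) scn$ctcf_at <- scn$borders
  scn <- modifyList(scn, overrides)   # explicit overrides win over derived
  class(scn) <- "sx_scenario"
  scn
}

#' @export
print.sx_scenario <- function(x, ...) {
  cat(sprintf("scenario '%s': %d-bead %s fibre, swivel at %d (rate %g/tau, sign %+d%s)\n",
              x$name, x$n_beads, if (x$circular) "circular" else "linear",
              x$swivel, x$rate, x$sign, if (x$barrier) ", barrier" else ""))
  if (!is.null(x$borders))
    cat("  borders (passive swivel + phantom):", x$borders, "\n")
  if (!is.null(x$thread_at))
    cat("  handcuff threaded at beads:", x$thread_at, "\n")
  if (!is.null(x$ctcf_orientation))
    cat("  CTCF at beads", x$ctcf_at, "orientation", x$ctcf_orientation, "\n")
  cat(sprintf("  Lt = %g nm, stop at injected R = %g\n", x$Lt_nm, x$stop_R))
  cat("  expected:", x$expected, "\n")
  invisible(x)
}

#' Materialize a scenario into a simulation state
#'
#' Builds the fibre, annotations, handcuff threading and CTCF obstacles of a
#' scenario; deterministic (bit-identical geometry for identical inputs).
#'
#' @param scn an `sx_scenario` from [make_scenario()].
#' @param units an [unit_system()].
#' @param settle steps of athermal (zero-temperature) relaxation applied to
#'   the constructed geometry before use; removes the small excluded-volume
#'   overlaps of the pinched-loop threading construction.  Deterministic.
#' @return An `sx_state`.
#' @export
scenario_state <- function(scn, units = unit_system(), settle = 2000L) {
  ff <- forcefield_params(Lt_nm = scn$Lt_nm, units = units)
  f <- build_fiber(n_beads = scn$n_beads, circular = scn$circular,
                   units = units)
  f <- add_active_swivel(f, scn$swivel, rate = scn$rate, sign = scn$sign,
                         barrier = scn$barrier)
  for (b in scn$borders) f <- add_passive_swivel(f, b)
  if (!is.null(scn$phantoms)) f <- add_phantom_region(f, scn$phantoms)
  if (!is.null(scn$ctcf_orientation))
    for (b in scn$ctcf_at)
      f <- add_ctcf(f, b, orientation = scn$ctcf_orientation)
  cuffs <- list()
  if (scn$with_handcuff) {
    # the transcription machinery at the swivel is itself a bulky obstacle:
    # rings cannot slide past it, so the loop cannot lose its supercoil
    # source to an early fluctuation before the pushing sets in
    f <- add_obstacle(f, scn[["swivel"]])
    th <- thread_handcuff(f, build_handcuff(units = units),
                          scn$thread_at[1], scn$thread_at[2])
    f <- th$fiber
    cuffs <- list(th$handcuff)
    # handcuffs load at a crossing made by transcription-induced
    # supercoiling: the nascent loop starts with `preload_turns` of
    # sign-handed twist, compensated in the outer arc (Lk unchanged) --
    # without it the unpressurized loop collapses entropically before
    # injection can act
    if (scn$preload_turns > 0)
      f <- preload_loop_twist(f, scn$thread_at, scn[["swivel"]],
                              scn$sign * scn$preload_turns)
  }
  st <- simulation_state(f, cuffs, ff)
  if (settle > 0) {
    rates <- vapply(st$actives, function(a) a$rate, numeric(1))
    for (ai in seq_along(st$actives)) st$actives[[ai]]$rate <- 0
    st <- step_dynamics(st, dynamics_config(temperature = 0, seed = 1L),
                        n = settle)
    for (ai in seq_along(st$actives)) st$actives[[ai]]$rate <- rates[ai]
    st$time <- 0
  }
  st
}

# distribute `turns` of twist over the joints of the arc between the
# threading beads that contains the swivel, compensated uniformly over the
# complementary arc so the total material twist telescopes to zero
preload_loop_twist <- function(fiber, thread_at, swivel, turns) {
  n <- n_beads(fiber)
  a <- min(thread_at); b <- max(thread_at)
  inside <- if (swivel > a && swivel < b)
    seq(a + 1, b) else c(seq(b + 1, n), seq_len(a))
  outside <- setdiff(seq_len(n), inside)
  desired <- numeric(n)                       # per-vertex twist (rad)
  desired[inside] <- 2 * pi * turns / length(inside)
  desired[outside] <- -2 * pi * turns / length(outside)
  fiber$joint_twist <- cumsum(desired)        # theta_v = theta_{v-1} + phi_v
  fiber
}

#' Run a scenario
#'
#' Convenience wrapper: materializes the scenario and integrates it until
#' its stop condition (injected rotations) or `n_steps`.
#'
#' @param scn an `sx_scenario` or scenario name.
#' @param seed RNG seed.
#' @param config optional [dynamics_config()]; scenario stop condition and
#'   seed are filled in.
#' @param n_steps optional cap on steps (default: enough to reach `stop_R`).
#' @return An `sx_trajectory`.
#' @export
run_scenario <- function(scn, seed = 1L, config = NULL, n_steps = NULL) {
  if (is.character(scn)) scn <- make_scenario(scn)
  st <- scenario_state(scn)
  if (is.null(config)) config <- dynamics_config()
  config$seed <- as.integer(seed)
  config$stop_R <- scn$stop_R
  if (is.null(n_steps))
    n_steps <- ceiling(scn$stop_R / max(scn$rate, 1e-9) / config$dt * 1.05)
  config$n_steps <- as.integer(n_steps)
  tr <- run_dynamics(st, config)
  tr$scenario <- scn
  tr
}

#' Reference outcome of a scenario
#'
#' The assertable property bundle each scenario is expected to satisfy,
#' as used by the reduced-scale property suite (`check` subcommand of the
#' CLI and the package tests).
#'
#' @param name scenario name.
#' @return List of property descriptors (property id, description,
#'   comparator, threshold).
# the extruded loop is the arc between the threaded beads that contains the
# supercoil source; when both rings sit momentarily on the same side of the
# swivel the reported arc flips to the complement, so extents are folded back
# to at most half the fibre (the TAD size) for time-series measures
fold_loop <- function(le, n) pmin(le, n - le)

#' @export
reference_outcome <- function(name) {
  if (!name %in% SCENARIO_NAMES)
    stop("unknown scenario '", name, "'; valid names: ",
         paste(SCENARIO_NAMES, collapse = ", "))
  switch(name,
    fig1 = list(list(property = "lk_conservation",
      description = "|Tw+Wr drop| equals injected rotations within 0.05",
      comparator = "le", threshold = 0.05)),
    fig2_free = list(list(property = "steady_abs_wr",
      description = "time-averaged |Wr| < 2 at steady state",
      comparator = "lt", threshold = 2)),
    fig2_handcuffed = list(list(property = "enclosed_wr_fraction",
      description = "enclosed segment carries >= 80% of |Wr| during injection",
      comparator = "ge", threshold = 0.8)),
    fig3 = list(
      list(property = "loop_final_fraction",
        description = "final loop extent >= 80% of the TAD",
        comparator = "ge", threshold = 0.8),
      list(property = "loop_monotone",
        description = "smoothed loop extent non-decreasing until borders",
        comparator = "ge", threshold = 0)),
    fig4_asymmetric = list(list(property = "near_ring_anchors_first",
      description = "ring nearer the border anchors first; far ring keeps moving",
      comparator = "gt", threshold = 0)),
    fig5_convergent = list(list(property = "corner_contact",
      description = "border-border contact frequency (compare to divergent)",
      comparator = "gt", threshold = 0)),
    fig5_divergent = list(list(property = "corner_contact",
      description = "border-border contact frequency (compare to convergent)",
      comparator = "ge", threshold = 0)),
    supp_low_twist = list(list(property = "loop_final_fraction",
      description = "pushing persists: loop still grows past its start",
      comparator = "ge", threshold = 0.5)),
    supp_barrier = list(list(property = "flank_twist_asymmetry",
      description = "twist variance much larger on the injected flank",
      comparator = "ge", threshold = 4)))
}

#' Measured value of a scenario property
#'
#' Computes, from a finished trajectory, the quantity each
#' [reference_outcome()] property asserts on.
#'
#' @param property property id (see [reference_outcome()]).
#' @param traj an `sx_trajectory` from [run_scenario()].
#' @param ... extra inputs (e.g. `other = traj2` for the corner-contact
#'   comparison, `tail_frac` for steady-state averages).
#' @export
outcome_value <- function(property, traj, ...) {
  dots <- list(...)
  o <- traj$obs
  scn <- traj$scenario
  switch(property,
    lk_conservation = {
      drop <- abs(o$Tw + o$Wr - (o$Tw[1] + o$Wr[1]))
      abs(drop[nrow(o)] - o$injected_R[nrow(o)])
    },
    steady_abs_wr = {
      tf <- if (is.null(dots$tail_frac)) 0.5 else dots$tail_frac
      k <- o$time >= max(o$time) * (1 - tf)
      mean(abs(o$Wr[k]))
    },
    enclosed_wr_fraction = {
      # localization while injection is ongoing and the rings are still
      # inside the TAD (before border arrival, where border topoisomerase
      # activity relaxes whatever reaches it); writhe-weighted so frames
      # with negligible writhe do not contribute noise ratios
      tad <- scn$n_beads %/% 2L
      le <- fold_loop(o$loop_extent, scn$n_beads)
      k <- which(o$injected_R > 2 & !is.na(o$enclosed_Wr) & le < 0.8 * tad)
      if (!length(k)) return(NA_real_)
      min(sum(abs(o$enclosed_Wr[k])) / sum(abs(o$Wr[k])), 1)
    },
    loop_final_fraction = {
      # the loop grows until the rings arrive at the borders; in scenarios
      # without CTCF nothing holds them there afterwards, so arrival is the
      # maximum of the smoothed extent, not the last frame
      tad <- scn$n_beads %/% 2L
      le <- fold_loop(o$loop_extent, scn$n_beads)
      le <- le[!is.na(le)]
      if (length(le) < 10) return(NA_real_)
      sm <- stats::filter(le, rep(1 / 10, 10), sides = 1)
      max(sm, na.rm = TRUE) / tad
    },
    loop_monotone = {
      # smoothed loop extent must be non-decreasing through the growth
      # phase: from its minimum (the initial entropic collapse of the
      # nascent loop) until the rings reach the borders (80% of the TAD)
      le <- fold_loop(o$loop_extent, scn$n_beads)
      le <- le[!is.na(le)]
      sm <- stats::filter(le, rep(1 / 10, 10), sides = 1)
      sm <- sm[!is.na(sm)]
      tad <- scn$n_beads %/% 2L
      from <- which.min(sm)
      to <- if (any(sm >= 0.8 * tad)) min(which(sm >= 0.8 * tad)) else which.max(sm)
      if (to - from < 2) return(0)
      min(diff(sm[from:to]), 0)    # >= -tolerance when non-decreasing
    },
    near_ring_anchors_first = {
      ev <- traj$events
      anch <- ev[ev$type == "anchored", , drop = FALSE]
      if (nrow(anch) < 1) return(-1)
      first <- anch[which.min(anch$time), ]
      # ring "a" threads nearer the swivel-side border by construction
      near_first <- first$ring == 1
      moved_after <- {
        k <- o$time > first$time
        far <- if (near_first) o$threaded_b[k] else o$threaded_a[k]
        far <- far[!is.na(far)]
        length(far) > 1 && (max(far) - min(far)) > 2
      }
      as.numeric(near_first && moved_after)
    },
    corner_contact = {
      # border-border contact frequency over the late part of the run
      # (after the loop has had time to reach the borders)
      tf <- if (is.null(dots$tail_frac)) 0.25 else dots$tail_frac
      k0 <- max(1, floor(length(traj$frames) * (1 - tf)))
      cm <- contact_map(traj$frames[k0:length(traj$frames)],
                        cutoff = if (is.null(dots$cutoff)) 5 else dots$cutoff,
                        beads = seq_len(traj$n_fiber))
      b <- scn$borders
      w <- 3
      n <- scn$n_beads
      idx1 <- ((b[1] - 1 + (-w:w)) %% n) + 1
      idx2 <- ((b[2] - 1 + (-w:w)) %% n) + 1
      mean(cm[idx1, idx2])
    },
    flank_twist_asymmetry = {
      st <- traj$state
      phi <- joint_twists(st$fiber)
      joints <- fiber_joints(st$fiber)
      sw <- scn$swivel
      n <- scn$n_beads
      dist_sw <- pmin(abs(joints - sw), n - abs(joints - sw))
      lower <- ((joints - sw) %% n) > n / 2    # lower-index side of the swivel
      keep <- dist_sw > 2 & dist_sw < n / 2 - 2
      var(phi[keep & lower]) / max(var(phi[keep & !lower]), 1e-12)
    },
    stop("unknown property: ", property))
}
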