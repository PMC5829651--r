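#' Build a chromatin fibre
#'
#' Creates a bead-spring twistable worm-like chain, either as an equilateral
#' closed ring (circular) or a straight rod (linear), with bond length 1 sigma
#' and all material twist angles zero.  Bead indices are 1-based; genomic
#' coordinates are 0-based half-open intervals of `bp_per_bead` base pairs.
#'
#' Joints (the sites where the chain can twist and where swivels live) are
#' identified by bead index: joint `j` sits at bead `j`, between the bonds
#' `j-1 -> j` and `j -> j+1`.  Valid joints are `2..n-1` for a linear fibre
#' and `1..n` for a circular one.  The per-bond material twist angles are
#' stored in `joint_twist` (length `n-1` linear, `n` circular).
#'
#' @param length_bp fibre length in base pairs (converted with integer
#'   division by `bp_per_bead`); give exactly one of `length_bp`, `n_beads`.
#' @param n_beads number of beads.
#' @param circular logical; closed ring or linear rod.
#' @param units an [unit_system()].
#' @return An object of class `sx_fiber`.
#' @examples
#' f <- build_fiber(length_bp = 120000, circular = TRUE)  # 300 beads, 120 kb
#' n_beads(f)
#' @export
build_fiber <- function(length_bp = NULL, n_beads = NULL, circular = FALSE,
                        units = unit_system()) {
  if (is.null(length_bp) == is.null(n_beads))
    stop("give exactly one of `length_bp` or `n_beads`")
  n <- if (!is.null(length_bp)) {
    stopifnot(length_bp > 0)
    as.integer(length_bp %/% units$bp_per_bead)
  } else as.integer(n_beads)
  if (circular && n < 8)
    stop("a closed chain with bending at every joint needs at least 8 beads; ",
         "got ", n)
  if (!circular && n < 2) stop("a linear fibre needs at least 2 beads")

  if (circular) {
    rad <- 0.5 / sin(pi / n)
    ang <- 2 * pi * (seq_len(n) - 1) / n
    pos <- cbind(rad * cos(ang), rad * sin(ang), rep(0, n))
  } else {
    pos <- cbind(seq_len(n) - 1, rep(0, n), rep(0, n))
  }
  nb <- if (circular) n else n - 1L
  structure(list(
    positions = pos,
    circular = circular,
    joint_twist = rep(0, nb),
    bead_radius = 0.5,
    phantom_beads = integer(0),
    active_swivels = list(),
    passive_swivels = integer(0),
    ctcf_sites = list(),
    units = units
  ), class = "sx_fiber")
}

#' Sample a thermally equilibrated linear fibre
#'
#' Draws a linear fibre configuration directly from the discrete worm-like
#' chain Boltzmann distribution: bond angles from
#' `p(theta) ~ sin(theta) exp(-k_bend theta^2 / 2kT)`, azimuths uniform,
#' positions built along parallel-transported frames with all bonds at the
#' equilibrium length.  Used to start persistence-length measurements from
#' equilibrium instead of waiting out the slow relaxation of a straight rod.
#'
#' @param n_beads number of beads.
#' @param ff an [forcefield_params()] (bending stiffness and kT).
#' @param seed RNG seed (the global RNG state is restored on exit).
#' @param units an [unit_system()].
#' @return An `sx_fiber` (linear).
#' @export
sample_thermal_fiber <- function(n_beads, ff = forcefield_params(), seed = 1L,
                                 units = unit_system()) {
  stopifnot(n_beads >= 3)
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()))
  }
  k <- ff$k_bend / ff$kT
  # inverse-CDF sampling of the bend angle on a fine grid
  th_grid <- seq(1e-6, pi, length.out = 20000)
  w <- sin(th_grid) * exp(-0.5 * k * th_grid^2)
  cdf <- cumsum(w) / sum(w)
  nj <- n_beads - 2L
  for (attempt in 0:49) {
    set.seed((seed + 7919L * attempt) %% .Machine$integer.max)
    th <- th_grid[findInterval(runif(nj), cdf) + 1L]
    psi <- runif(nj, 0, 2 * pi)
    t_cur <- c(1, 0, 0)
    n1 <- c(0, 1, 0)
    pos <- matrix(0, n_beads, 3)
    pos[2, ] <- t_cur * ff$l0
    for (j in seq_len(nj)) {
      n2 <- pracma_cross(t_cur, n1)
      dirn <- cos(psi[j]) * n1 + sin(psi[j]) * n2
      t_new <- cos(th[j]) * t_cur + sin(th[j]) * dirn
      t_new <- t_new / sqrt(sum(t_new^2))
      # parallel-transport the frame vector to the new tangent
      n1 <- transport_vec(t_cur, t_new, n1)
      n1 <- n1 - sum(n1 * t_new) * t_new
      n1 <- n1 / sqrt(sum(n1^2))
      t_cur <- t_new
      pos[j + 2, ] <- pos[j + 1, ] + t_cur * ff$l0
    }
    # reject chains with deep self-overlaps (the chain model is
    # self-avoiding; a heavily overlapping start also destabilizes the
    # integrator) and redraw deterministically
    d <- as.matrix(dist(pos))
    sep <- abs(outer(seq_len(n_beads), seq_len(n_beads), "-"))
    if (min(d[sep > 1]) >= 0.8) break
  }
  f <- build_fiber(n_beads = n_beads, circular = FALSE, units = units)
  f$positions <- pos
  f
}

#' Number of beads of a fibre
#' @param fiber an `sx_fiber`.
#' @export
n_beads <- function(fiber) nrow(fiber$positions)

n_bonds <- function(fiber) if (fiber$circular) n_beads(fiber) else n_beads(fiber) - 1L

#' @export
print.sx_fiber <- function(x, ...) {
  n <- n_beads(x)
  cat(sprintf("chromatin fibre: %d beads (%s), %.0f kb, contour %.0f nm\n",
              n, if (x$circular) "circular" else "linear",
              n * x$units$bp_per_bead / 1000,
              n_bonds(x) * x$units$sigma_nm))
  if (length(x$active_swivels))
    cat("  active swivels at joint(s):",
        vapply(x$active_swivels, function(s) s$joint, 0), "\n")
  if (length(x$passive_swivels))
    cat("  passive swivels at joint(s):", x$passive_swivels, "\n")
  if (length(x$phantom_beads))
    cat("  phantom beads:", length(x$phantom_beads), "\n")
  if (length(x$ctcf_sites))
    cat("  CTCF sites at bead(s):",
        vapply(x$ctcf_sites, function(s) s$fibre_bead, 0), "\n")
  invisible(x)
}

#' Contour length of a fibre in nanometres
#' @param fiber an `sx_fiber`.
#' @export
contour_length_nm <- function(fiber)
  n_bonds(fiber) * fiber$units$sigma_nm

#' Genome to bead mapping
#'
#' `bead_of()` maps a 0-based genomic coordinate to its (1-based) bead index;
#' `bp_of()` returns the 0-based start coordinate of a bead's interval, so
#' `bead_of(fiber, bp_of(fiber, i)) == i` for every bead.
#'
#' @param fiber an `sx_fiber`.
#' @param bp 0-based genomic coordinate.
#' @param bead 1-based bead index.
#' @export
bead_of <- function(fiber, bp) {
  stopifnot(all(bp >= 0), all(bp < n_beads(fiber) * fiber$units$bp_per_bead))
  as.integer(bp %/% fiber$units$bp_per_bead) + 1L
}

#' @rdname bead_of
#' @export
bp_of <- function(fiber, bead) {
  stopifnot(all(bead >= 1), all(bead <= n_beads(fiber)))
  (as.integer(bead) - 1L) * fiber$units$bp_per_bead
}

valid_joint <- function(fiber, joint) {
  n <- n_beads(fiber)
  if (fiber$circular) joint >= 1 && joint <= n
  else joint >= 2 && joint <= n - 1
}

joint_is_annotated <- function(fiber, joint) {
  joint %in% fiber$passive_swivels ||
    joint %in% vapply(fiber$active_swivels, function(s) s$joint, 0)
}

#' Add an active swivel (transcription-induced supercoil injector)
#'
#' An active swivel forces the fibre segments flanking joint `joint` to
#' rotate axially with respect to each other, injecting `sign`-handed
#' supercoiling at `rate` turns per tau.  It emulates the topological effect
#' of RNA polymerase with TOP1 positioned ahead of it (net negative
#' supercoil injection, `sign = -1`).  With `barrier = TRUE` the joint also
#' acts as a topological barrier: twist does not transmit across it and all
#' injected twist accumulates on the lower-index side (a continuously
#' transcribing polymerase).
#'
#' @param fiber an `sx_fiber`.
#' @param joint joint (bead) index.
#' @param rate injected rotations per tau (turns/tau).
#' @param sign -1 for negative supercoiling, +1 for positive.
#' @param barrier logical; block twist transport through the joint.
#' @return The annotated fibre.
#' @export
add_active_swivel <- function(fiber, joint, rate = 0.005, sign = -1L,
                              barrier = FALSE) {
  stopifnot(valid_joint(fiber, joint), rate >= 0, sign %in% c(-1L, 1L))
  if (joint_is_annotated(fiber, joint))
    stop("joint ", joint, " already carries a swivel annotation")
  fiber$active_swivels <- c(fiber$active_swivels, list(list(
    joint = as.integer(joint), rate = rate, sign = as.integer(sign),
    barrier = isTRUE(barrier), injected_R = 0)))
  fiber
}

#' Add a passive swivel (local topoisomerase relaxation site)
#'
#' A passive swivel zeroes the twist elastic energy of one joint, so torsional
#' stress dissipates freely there; it emulates the local swivelling action of
#' type II topoisomerase at TAD borders.
#'
#' @inheritParams add_active_swivel
#' @export
add_passive_swivel <- function(fiber, joint) {
  stopifnot(valid_joint(fiber, joint))
  if (joint_is_annotated(fiber, joint))
    stop("joint ", joint, " already carries a swivel annotation")
  fiber$passive_swivels <- sort(c(fiber$passive_swivels, as.integer(joint)))
  fiber
}

#' Add a phantom (strand-passage) region
#'
#' Beads in a phantom region exert no fibre-fibre excluded-volume force, so
#' other fibre segments can pass through them: the intersegmental-passage
#' activity of type II topoisomerase.  Elastic properties are unchanged.
#'
#' @param fiber an `sx_fiber`.
#' @param beads bead indices (a contiguous interval is typical).
#' @export
add_phantom_region <- function(fiber, beads) {
  beads <- as.integer(beads)
  stopifnot(all(beads >= 1), all(beads <= n_beads(fiber)))
  fiber$phantom_beads <- sort(unique(c(fiber$phantom_beads, beads)))
  fiber
}

#' Add a CTCF obstacle
#'
#' CTCF bound at a TAD border is modelled as a large bead tethered to a fibre
#' bead; its diameter exceeds the cohesin ring aperture, so rings cannot pass.
#' `orientation` decides the fate of an arriving ring: "convergent" exposes
#' the cohesin-binding C-terminus (ring anchors), "divergent" hides it (the
#' handcuff dissociates after a dwell time in contact).
#'
#' @param fiber an `sx_fiber`.
#' @param bead attachment bead.
#' @param obstacle_diameter obstacle diameter in sigma (default 3.5 = 35 nm,
#'   larger than the 25 nm ring aperture).
#' @param orientation "convergent" or "divergent"; "obstacle" marks a
#'   neutral bulky obstacle (e.g. the transcription machinery itself) that
#'   blocks ring passage without anchoring or dissociating handcuffs.
#' @param bound_topo2 documentation flag (TOP2B rides the N-terminus).
#' @export
add_ctcf <- function(fiber, bead, obstacle_diameter = 3.5,
                     orientation = c("convergent", "divergent", "obstacle"),
                     bound_topo2 = TRUE) {
  orientation <- match.arg(orientation)
  bead <- as.integer(bead)
  stopifnot(bead >= 1, bead <= n_beads(fiber), obstacle_diameter > 0)
  if (bead %in% vapply(fiber$ctcf_sites, function(s) s$fibre_bead, 0L))
    stop("bead ", bead, " already carries a CTCF site")
  fiber$ctcf_sites <- c(fiber$ctcf_sites, list(list(
    fibre_bead = bead, obstacle_diameter = obstacle_diameter,
    orientation = orientation, bound_topo2 = isTRUE(bound_topo2))))
  fiber
}

#' Add a neutral bulky obstacle
#'
#' A bead larger than the cohesin ring aperture, tethered to a fibre bead:
#' rings cannot slide past it.  Used for the transcription machinery at the
#' active swivel (RNA polymerase with its transcript and associated factors
#' is far bulkier than the ~10 nm DNA-bound proteins that already block
#' cohesin diffusion), which guarantees a handcuff loaded around the
#' transcribed region cannot lose its supercoil source to a fluctuation.
#'
#' @param fiber an `sx_fiber`.
#' @param bead attachment bead.
#' @param diameter obstacle diameter in sigma (default 3 = 30 nm).
#' @export
add_obstacle <- function(fiber, bead, diameter = 3)
  add_ctcf(fiber, bead, obstacle_diameter = diameter,
           orientation = "obstacle")
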