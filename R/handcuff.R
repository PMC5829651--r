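# Cohesin handcuff: two tethered 15-bead rings sharing one bead, held in a
# planar figure-eight by a stiff harmonic distance-restraint network.  Ring
# centre-line diameter is 3.5 sigma (35 nm) and cohesin beads are 1 sigma
# (10 nm) across, giving the 45 nm external diameter and 25 nm mean inner
# aperture of catalytically active cohesin.

RING_BEADS <- 15L
RING_RADIUS <- 1.75       # sigma, centre-to-centre ring radius
COHESIN_BEAD_RADIUS <- 0.5

#' Build a cohesin handcuff
#'
#' Constructs the 29-bead figure-eight (two tangent 15-bead rings, one bead
#' common to both) in the plane perpendicular to `normal`, centred so the
#' shared bead is at `centre`.  The rigidity restraint network ties each ring
#' bead to its first and second neighbours, its diametric partner, the shared
#' bead and a small all-pairs frame spanning both rings, which keeps the
#' thermal shape RMSD below 0.2 sigma (tested contract) without freezing any
#' bead.
#'
#' @param centre position of the shared bead (sigma units).
#' @param normal normal of the handcuff plane.
#' @param units an [unit_system()].
#' @return An object of class `sx_handcuff` with 29 beads.
#' @examples
#' h <- build_handcuff()
#' handcuff_outer_diameter_nm(h)   # ~45 nm
#' handcuff_inner_aperture_nm(h)   # ~25 nm
#' @export
build_handcuff <- function(centre = c(0, 0, 0), normal = c(0, 0, 1),
                           units = unit_system()) {
  k <- seq_len(RING_BEADS) - 1
  angA <- 2 * pi * k / RING_BEADS          # bead 0 at angle 0 -> shared point
  cA <- c(-RING_RADIUS, 0, 0)
  cB <- c(RING_RADIUS, 0, 0)
  ringA <- cbind(cA[1] + RING_RADIUS * cos(angA),
                 cA[2] + RING_RADIUS * sin(angA), 0)
  ringB <- cbind(cB[1] + RING_RADIUS * cos(angA + pi),
                 cB[2] + RING_RADIUS * sin(angA + pi), 0)
  # bead 1 = shared bead (ringA[1] == ringB[1] == origin)
  beads <- rbind(ringA[1, , drop = FALSE], ringA[-1, ], ringB[-1, ])
  ring_a <- c(1L, 2L:15L)
  ring_b <- c(1L, 16L:29L)

  pairs <- handcuff_restraint_pairs(ring_a, ring_b)
  r0 <- sqrt(rowSums((beads[pairs[, 1], , drop = FALSE] -
                      beads[pairs[, 2], , drop = FALSE])^2))
  quads <- handcuff_dihedral_quads(ring_a, ring_b)
  phi0 <- apply(quads, 1, function(q) dihedral_angle(beads[q[1], ],
    beads[q[2], ], beads[q[3], ], beads[q[4], ]))

  # rotate plane normal z -> `normal`, translate shared bead -> `centre`
  beads <- rotate_to(beads, c(0, 0, 1), normal)
  beads <- sweep(beads, 2, centre, "+")

  structure(list(
    beads = beads,
    ring_a = ring_a, ring_b = ring_b, shared = 1L,
    restraint_pairs = cbind(pairs, r0),
    dihedral_quads = cbind(quads, phi0),
    state_a = "active", state_b = "active", alive = TRUE,
    threaded_a = NA_integer_, threaded_b = NA_integer_,
    cohesin_bead_radius = COHESIN_BEAD_RADIUS,
    units = units
  ), class = "sx_handcuff")
}

# restraint pair list (local bead indices); deduplicated, i < j
handcuff_restraint_pairs <- function(ring_a, ring_b) {
  pr <- list()
  add <- function(i, j) {
    ij <- cbind(pmin(i, j), pmax(i, j))
    pr[[length(pr) + 1]] <<- ij[ij[, 1] != ij[, 2], , drop = FALSE]
  }
  for (ring in list(ring_a, ring_b)) {
    n <- length(ring)
    k <- seq_len(n)
    add(ring[k], ring[ifelse(k %% n + 1 > n, 1, k %% n + 1)])      # neighbours
    add(ring[k], ring[(k + 1) %% n + 1])                           # 2nd neighbours
    add(ring[k], ring[(k + 6) %% n + 1])                           # diametric (k+7)
    add(ring[k], rep(ring[1], n))                                  # to shared bead
    frame <- ring[c(4, 8, 12)]                                     # local 3,7,11
    for (f in frame) add(ring[k], rep(f, n))
  }
  frame_all <- c(ring_a[1], ring_a[c(4, 8, 12)], ring_b[c(4, 8, 12)])
  cmb <- t(utils::combn(frame_all, 2))
  pr[[length(pr) + 1]] <- cbind(pmin(cmb[, 1], cmb[, 2]),
                                pmax(cmb[, 1], cmb[, 2]))
  out <- unique(do.call(rbind, pr))
  colnames(out) <- c("i", "j")
  out
}

# dihedral quadruples: every four consecutive beads around each ring
# (planarity and shape of the ring itself) plus four quadruples across the
# shared bead (the hinge between the rings).  A distance network alone is
# first-order insensitive to out-of-plane buckling of a planar object; the
# dihedral terms restore quadratic stiffness, the "strong and rigid bending
# potentials" holding the figure-eight flat.
handcuff_dihedral_quads <- function(ring_a, ring_b) {
  ring_quads <- function(r) {
    n <- length(r)
    t(vapply(seq_len(n), function(k)
      r[((k - 1 + 0:3) %% n) + 1], integer(4)))
  }
  A <- ring_a; B <- ring_b
  # rigid ring tilt about the shared axis is invisible to distances (rigid
  # in-ring motion, second order for cross distances): pin each ring's
  # out-of-plane orientation against the far bead of the other ring.
  # Positions 7..10 are skipped (b1 x b2 nearly vanishes there).
  ks <- c(2:6, 11:14)
  tiltA <- t(vapply(ks, function(k) c(B[9], A[1], A[k], A[k + 1]), integer(4)))
  tiltB <- t(vapply(ks, function(k) c(A[9], B[1], B[k], B[k + 1]), integer(4)))
  rbind(ring_quads(A), ring_quads(B), tiltA, tiltB,
        c(A[2], A[1], B[2], B[3]), c(A[15], A[1], B[15], B[14]),
        c(B[2], B[1], A[2], A[3]), c(B[15], B[1], A[15], A[14]))
}

dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- pracma_cross(b1, b2); n2 <- pracma_cross(b2, b3)
  atan2(sum(pracma_cross(n1, n2) * b2) / sqrt(sum(b2^2)), sum(n1 * n2))
}

rotate_to <- function(x, from, to) {
  from <- from / sqrt(sum(from^2))
  to <- to / sqrt(sum(to^2))
  v <- c(from[2] * to[3] - from[3] * to[2],
         from[3] * to[1] - from[1] * to[3],
         from[1] * to[2] - from[2] * to[1])
  s <- sqrt(sum(v^2))
  c_ <- sum(from * to)
  if (s < 1e-12) {
    if (c_ > 0) return(x)
    return(-x)  # antiparallel: rotate pi (mirror through origin is fine here:
                # the figure-eight is achiral in its own plane)
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
               byrow = TRUE)
  R <- diag(3) + vx + vx %*% vx * ((1 - c_) / s^2)
  x %*% t(R)
}

#' @export
print.sx_handcuff <- function(x, ...) {
  cat(sprintf(paste0("cohesin handcuff: %d beads (%d per ring, 1 shared), ",
                     "outer diameter %.1f nm, inner aperture %.1f nm [%s/%s]\n"),
              nrow(x$beads), length(x$ring_a),
              handcuff_outer_diameter_nm(x), handcuff_inner_aperture_nm(x),
              x$state_a, x$state_b))
  invisible(x)
}

ring_spans <- function(h, ring) {
  p <- h$beads[ring, , drop = FALSE]
  n <- nrow(p)
  opp <- (seq_len(n) + 6) %% n + 1          # diametric partner k+7
  sqrt(rowSums((p - p[opp, , drop = FALSE])^2))
}

#' Handcuff ring geometry
#'
#' `handcuff_outer_diameter_nm()` is the maximal centre-to-centre bead span
#' across one ring plus one cohesin bead diameter; the paper's cohesin rings
#' measure 45 nm.  `handcuff_inner_aperture_nm()` is the mean diametric span
#' minus one bead diameter: the ~25 nm opening a single 10-nm chromatin fibre
#' passes through but a bulky CTCF obstacle does not.
#'
#' @param h an `sx_handcuff`.
#' @param ring which ring ("a" or "b").
#' @export
handcuff_outer_diameter_nm <- function(h, ring = "a") {
  r <- if (ring == "a") h$ring_a else h$ring_b
  bead_d <- 2 * h$cohesin_bead_radius
  sigma_to_nm(max(ring_spans(h, r)) + bead_d, h$units)
}

#' @rdname handcuff_outer_diameter_nm
#' @export
handcuff_inner_aperture_nm <- function(h, ring = "a") {
  r <- if (ring == "a") h$ring_a else h$ring_b
  bead_d <- 2 * h$cohesin_bead_radius
  sigma_to_nm(mean(ring_spans(h, r)) - bead_d, h$units)
}

#' Shape RMSD of a handcuff from its reference figure-eight
#'
#' Optimal-superposition (Kabsch) RMSD between the current bead coordinates
#' and the reference planar build; the rigidity contract requires < 0.2 sigma
#' under thermal motion.
#'
#' @param h an `sx_handcuff` or a 29 x 3 coordinate matrix.
#' @param ref reference coordinates (default: a fresh [build_handcuff()]).
#' @export
handcuff_shape_rmsd <- function(h, ref = build_handcuff()) {
  x <- if (inherits(h, "sx_handcuff")) h$beads else h
  y <- ref$beads
  xc <- scale(x, scale = FALSE)
  yc <- scale(y, scale = FALSE)
  s <- svd(t(yc) %*% xc)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sqrt(mean(rowSums((xc %*% R - yc)^2)))
}

contour_sep <- function(fiber, a, b) {
  d <- abs(a - b)
  if (fiber$circular) min(d, n_beads(fiber) - d) else d
}

#' Thread a handcuff onto a fibre
#'
#' Places ring A around fibre bead `bead_a` and ring B around `bead_b`.
#' Because the two rings of a handcuff are only 3.5 sigma apart, the fibre is
#' deformed into the corresponding pinched-loop configuration: the arc
#' between the two beads (the nascent extruded loop, containing the supercoil
#' source) bulges out as one near-circular lobe, and the remaining contour
#' forms the second lobe, the two lobes slightly tilted out of plane so that
#' excluded volume is satisfied at the junction.  Ring planes are set
#' perpendicular to the local fibre tangent.
#'
#' @param fiber a circular `sx_fiber`.
#' @param handcuff an `sx_handcuff`.
#' @param bead_a,bead_b fibre beads to thread (contour separation >= 4).
#' @return A list with elements `fiber` (deformed) and `handcuff` (placed,
#'   with `threaded_a`/`threaded_b` set), ready for [simulation_state()].
#' @export
thread_handcuff <- function(fiber, handcuff, bead_a, bead_b) {
  if (bead_a == bead_b) stop("bead_a and bead_b must differ")
  if (contour_sep(fiber, bead_a, bead_b) < 4)
    stop("threading beads too close: contour separation must be >= 4 beads")
  if (!fiber$circular)
    stop("threading with fibre deformation is implemented for circular fibres")
  for (s in fiber$ctcf_sites) {
    if (contour_sep(fiber, s$fibre_bead, bead_a) < 3 ||
        contour_sep(fiber, s$fibre_bead, bead_b) < 3)
      stop("ring would overlap the CTCF obstacle at bead ", s$fibre_bead)
  }
  a <- min(bead_a, bead_b); b <- max(bead_a, bead_b)
  n <- n_beads(fiber)
  n_in <- b - a            # bonds in arc a -> b (ascending indices)
  n_out <- n - n_in        # bonds in arc b -> a (wrapping)
  gap <- 2 * RING_RADIUS   # chord between the two ring centres

  # beads a and b at the ring centres, x-axis through them
  pa <- c(-RING_RADIUS, 0, 0)
  pb <- c(RING_RADIUS, 0, 0)
  tilt <- 0.18             # rad, out-of-plane tilt separating the two lobes
  arc_in <- lobe_arc(pa, pb, n_in, c(0, 1, 0), tilt)     # beads a..b
  arc_out <- lobe_arc(pb, pa, n_out, c(0, -1, 0), tilt)  # beads b..a (wrapped)

  pos <- fiber$positions
  pos[a:(b - 1), ] <- arc_in[seq_len(n_in), ]                 # beads a..b-1
  pos[((b - 1):(b + n_out - 2)) %% n + 1, ] <- arc_out[seq_len(n_out), ]
  fiber$positions <- pos

  tang_at <- function(i) {
    ip <- i %% n + 1; im <- (i - 2) %% n + 1
    t <- pos[ip, ] - pos[im, ]
    t / sqrt(sum(t^2))
  }
  # one handcuff spanning both beads: shared bead midway, ring planes
  # perpendicular to the local tangents.  The fibre runs up through ring A
  # and back down through ring B, so the tangents are anti-parallel and the
  # common plane normal is their difference.
  nrm <- tang_at(a) - tang_at(b)
  nrm <- nrm / sqrt(sum(nrm^2))
  hc <- build_handcuff(centre = c(0, 0, 0), normal = nrm,
                       units = handcuff$units)
  # align ring axis a->b with the fibre chord: ring A centre must sit at pa
  ca <- colMeans(hc$beads[hc$ring_a, ])
  cb <- colMeans(hc$beads[hc$ring_b, ])
  axis_now <- (cb - ca) / sqrt(sum((cb - ca)^2))
  axis_want <- (pb - pa) / gap
  # rotate about `nrm` to bring axis_now to axis_want (project both on plane)
  hc$beads <- rotate_to(hc$beads, axis_now, axis_want)
  hc$beads <- sweep(hc$beads, 2, c(0, 0, 0) - colMeans(hc$beads[hc$ring_a, , drop = FALSE]) + pa, "+")
  hc$threaded_a <- a
  hc$threaded_b <- b
  list(fiber = fiber, handcuff = hc)
}

# circular-arc lobe between points p and q: `nb` bonds of ~1 sigma along the
# major arc (angle > pi), bulging towards `vdir`, then tilted about the chord
# axis to clear the opposite lobe.  Endpoints p and q lie on the axis and are
# preserved exactly.
lobe_arc <- function(p, q, nb, vdir, tilt) {
  chord <- sqrt(sum((q - p)^2))
  len <- nb                      # contour length in sigma
  f <- function(R) 2 * R * sin(len / (2 * R)) - chord
  # major arc: total angle len/R in (pi, 2*pi)
  R <- uniroot(f, c(len / (2 * pi) + 1e-9, len / pi), tol = 1e-12)$root
  th_tot <- len / R
  u <- (q - p) / chord
  v <- vdir - sum(vdir * u) * u
  v <- v / sqrt(sum(v^2))
  d <- sqrt(max(R^2 - chord^2 / 4, 0))
  cc <- (p + q) / 2 + v * d      # centre on the bulge side for a major arc
  phi_p <- atan2(-d, -chord / 2) # p = cc + R cos(phi) u + R sin(phi) v
  phi <- phi_p - (0:nb) * th_tot / nb   # decreasing phi traces the major arc
  arc <- t(vapply(phi, function(a) cc + R * cos(a) * u + R * sin(a) * v,
                  numeric(3)))
  M <- rot_about_axis(u, cos(tilt), sin(tilt))
  sweep(sweep(arc, 2, p, "-") %*% t(M), 2, p, "+")
}

rot_about_axis <- function(k, ct, st) {
  kx <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) * ct + kx * st + (k %o% k) * (1 - ct)
}
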