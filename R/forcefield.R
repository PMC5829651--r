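#' Force-field parameters
#'
#' All elastic and excluded-volume constants of the model, in reduced units
#' (length sigma, energy kT).  The bending stiffness is derived from the
#' bending persistence length as `k_bend = kT * Lp / l0` and the torsional
#' modulus from the torsional persistence length as `C = kT * Lt` (both
#' lengths first converted to sigma).  Defaults: Lp = 50 nm (chromatin
#' fibre), Lt = 75 nm (the value used for supercoiled DNA, configurable; a
#' tenfold lower value reproduces the low-torsional-stiffness sensitivity
#' runs), FENE extensibility `r_fene_max = 1.5 sigma` and `k_fene =
#' 200 kT/sigma^2` -- stiff enough that, with the bond potential centred at
#' `l0`, the extensibility walls sit five thermal standard deviations away
#' and bonds cannot cross.
#'
#' @param l0 equilibrium bond length (sigma).
#' @param k_fene FENE stiffness (kT/sigma^2).
#' @param r_fene_max maximal bond extension (sigma); the FENE energy diverges
#'   as the bond length approaches it.
#' @param Lp_nm bending persistence length (nm).
#' @param Lt_nm torsional persistence length (nm).
#' @param eps_wca excluded-volume energy scale (kT).
#' @param k_restraint handcuff rigidity restraint stiffness (kT/sigma^2).
#' @param k_dihedral handcuff planarity (dihedral) stiffness (kT/rad^2).
#' @param k_tether CTCF obstacle tether stiffness (kT/sigma^2).
#' @param kT thermal energy unit.
#' @param units an [unit_system()].
#' @return Object of class `sx_ff` with derived fields `k_bend` and `C`.
#' @export
forcefield_params <- function(l0 = 1, k_fene = 200, r_fene_max = 1.5,
                              Lp_nm = 50, Lt_nm = 75, eps_wca = 1,
                              k_restraint = 60, k_dihedral = 0.5, k_tether = 50, kT = 1,
                              units = unit_system()) {
  stopifnot(l0 > 0, k_fene > 0, r_fene_max > l0, Lp_nm > 0, Lt_nm > 0,
            eps_wca > 0, k_restraint > 0, k_dihedral > 0, k_tether > 0,
            kT > 0)
  Lp <- nm_to_sigma(Lp_nm, units)
  Lt <- nm_to_sigma(Lt_nm, units)
  structure(list(
    l0 = l0, k_fene = k_fene, r_fene_max = r_fene_max,
    Lp_nm = Lp_nm, Lt_nm = Lt_nm,
    k_bend = kT * Lp / l0,        # kT units
    C = kT * Lt,                  # kT * sigma
    eps_wca = eps_wca, sigma_wca = 1,
    k_restraint = k_restraint, k_dihedral = k_dihedral,
    k_tether = k_tether,
    kT = kT, units = units
  ), class = "sx_ff")
}

#' @export
print.sx_ff <- function(x, ...) {
  cat(sprintf(paste0("force field: l0=%g sigma, k_fene=%g, r_max=%g, ",
                     "Lp=%g nm (k_bend=%g kT), Lt=%g nm (C=%g kT sigma)\n"),
              x$l0, x$k_fene, x$r_fene_max, x$Lp_nm, x$k_bend, x$Lt_nm, x$C))
  invisible(x)
}

#' FENE bond energy and force
#'
#' Finitely extensible bond centred at the equilibrium length:
#' `E(r) = -1/2 k dmax^2 log(1 - ((r - l0)/dmax)^2)` with
#' `dmax = r_fene_max - l0`.  The energy is minimal at `r = l0` and diverges
#' as `r` approaches `r_fene_max` (or `2 l0 - r_fene_max`); a bond reaching
#' the limit during integration signals a too-large timestep.
#'
#' @param r bond length (sigma); vectorized.
#' @param ff an [forcefield_params()] object.
#' @return Energy in kT (`bond_energy`) or the scalar radial force
#'   `-dE/dr` in kT/sigma (`bond_force`).
#' @export
bond_energy <- function(r, ff = forcefield_params()) {
  dmax <- ff$r_fene_max - ff$l0
  u <- (r - ff$l0) / dmax
  out <- ifelse(abs(u) < 1, -0.5 * ff$k_fene * dmax^2 * log(1 - u^2), Inf)
  if (any(r <= 0)) stop("non-positive bond length")
  out
}

#' @rdname bond_energy
#' @export
bond_force <- function(r, ff = forcefield_params()) {
  dmax <- ff$r_fene_max - ff$l0
  u <- (r - ff$l0) / dmax
  ifelse(abs(u) < 1, -ff$k_fene * (r - ff$l0) / (1 - u^2), NaN)
}

fiber_bonds <- function(fiber) {
  n <- n_beads(fiber)
  i <- seq_len(n_bonds(fiber))
  cbind(i, ifelse(i %% n + 1 > n, 1L, i %% n + 1L))
}

#' Joint indices of a fibre
#'
#' Joints (twist/bend sites) are identified by bead index: all beads for a
#' circular fibre, beads `2..n-1` for a linear one.
#' @param fiber an `sx_fiber`.
#' @export
fiber_joints <- function(fiber) {
  n <- n_beads(fiber)
  if (fiber$circular) seq_len(n) else seq(2L, n - 1L)
}

joint_angles <- function(fiber) {
  pos <- fiber$positions
  n <- n_beads(fiber)
  vapply(fiber_joints(fiber), function(j) {
    im <- if (fiber$circular) (j - 2) %% n + 1 else j - 1
    ip <- if (fiber$circular) j %% n + 1 else j + 1
    e0 <- pos[j, ] - pos[im, ]
    e1 <- pos[ip, ] - pos[j, ]
    acos(max(-1, min(1, sum(e0 * e1) / sqrt(sum(e0^2) * sum(e1^2)))))
  }, numeric(1))
}

#' Bending energy of a fibre
#'
#' Harmonic in the deviation of each joint angle from straight:
#' `E_j = 1/2 k_bend theta_j^2`, zero for a straight rod.
#'
#' @param fiber an `sx_fiber`.
#' @param ff an [forcefield_params()].
#' @return Total bending energy (kT), with per-joint contributions in
#'   attribute `"per_joint"`.
#' @export
bend_energy <- function(fiber, ff = forcefield_params()) {
  th <- joint_angles(fiber)
  per <- 0.5 * ff$k_bend * th^2
  structure(sum(per), per_joint = per)
}

#' Twist energy of a fibre
#'
#' `E = sum_j C/(2 l0) (phi_j - phi0_j)^2` over transmitting joints; passive
#' swivel joints (and barrier joints of active swivels) have zero torsional
#' stiffness and contribute nothing at any angle.  The joint twist `phi_j`
#' combines the material angles of the two adjacent bonds with the reference
#' twist of the bent backbone (parallel-transport framing).
#'
#' @param fiber an `sx_fiber`.
#' @param ff an [forcefield_params()].
#' @param phi0 intrinsic twist offsets per joint (default all zero; the
#'   dynamics module advances the offset of active swivel joints).
#' @return Total twist energy (kT), per-joint contributions in attribute
#'   `"per_joint"` (named by joint index).
#' @export
twist_energy <- function(fiber, ff = forcefield_params(), phi0 = NULL) {
  phi <- joint_twists(fiber)
  joints <- fiber_joints(fiber)
  if (is.null(phi0)) phi0 <- rep(0, length(joints))
  passive <- joints %in% fiber$passive_swivels |
    joints %in% vapply(Filter(function(s) s$barrier, fiber$active_swivels),
                       function(s) s$joint, 0L)
  per <- ifelse(passive, 0, ff$C / (2 * ff$l0) * (phi - phi0)^2)
  names(per) <- joints
  structure(sum(per), per_joint = per)
}

#' Joint twist angles of a fibre
#'
#' Per-joint twist angles phi_j (radians) combining the per-bond material
#' angles with the reference twist of a freshly space-parallel-transported
#' framing of the current geometry.  One value per joint, ordered as
#' [fiber_joints()] orders them; `sum(joint_twists(f)) / (2*pi)` is the
#' total twist in turns.
#'
#' @param fiber an `sx_fiber`.
#' @return Numeric vector of joint twist angles (radians).
#' @export
joint_twists <- function(fiber) {
  pos <- fiber$positions
  n <- n_beads(fiber)
  nb <- n_bonds(fiber)
  bonds <- fiber_bonds(fiber)
  tang <- (pos[bonds[, 2], , drop = FALSE] - pos[bonds[, 1], , drop = FALSE])
  tang <- tang / sqrt(rowSums(tang^2))
  # transport a director along the chain; m = 0 except at the closure joint
  d <- matrix(0, nb, 3)
  ref <- if (abs(tang[1, 3]) > 0.9) c(1, 0, 0) else c(0, 0, 1)
  d0 <- pracma_cross(tang[1, ], ref)
  d[1, ] <- d0 / sqrt(sum(d0^2))
  for (b in seq_len(nb)[-1]) {
    v <- transport_vec(tang[b - 1, ], tang[b, ], d[b - 1, ])
    v <- v - sum(v * tang[b, ]) * tang[b, ]
    d[b, ] <- v / sqrt(sum(v^2))
  }
  joints <- fiber_joints(fiber)
  theta <- fiber$joint_twist
  vapply(joints, function(j) {
    bprev <- if (fiber$circular) (j - 2) %% nb + 1 else j - 1
    bnext <- if (fiber$circular) j else j    # bond with index = joint bead
    # for linear fibres joint j couples bonds j-1 and j
    bnext <- if (fiber$circular) j else j
    v <- transport_vec(tang[bprev, ], tang[bnext, ], d[bprev, ])
    m <- atan2(sum(pracma_cross(v, d[bnext, ]) * tang[bnext, ]),
               sum(v * d[bnext, ]))
    theta[bnext] - theta[bprev] + m
  }, numeric(1))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

transport_vec <- function(t0, t1, v) {
  k <- pracma_cross(t0, t1)
  s <- sqrt(sum(k^2))
  c_ <- sum(t0 * t1)
  if (s < 1e-12) { if (c_ > 0) return(v) else return(-v) }
  k <- k / s
  v * c_ + pracma_cross(k, v) * s + k * sum(k * v) * (1 - c_)
}
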