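test_that("FENE bond matches its closed form and diverges at the limit", {
  ff <- forcefield_params()
  expect_equal(bond_force(ff$l0, ff), 0)
  expect_equal(bond_energy(ff$l0, ff), 0)

  # independent evaluation of the centred-FENE expression at r = 1.1 l0
  r <- 1.1 * ff$l0
  dmax <- ff$r_fene_max - ff$l0
  u <- (r - ff$l0) / dmax
  expect_equal(bond_energy(r, ff),
               -0.5 * ff$k_fene * dmax^2 * log(1 - u^2))
  expect_equal(bond_force(r, ff), -ff$k_fene * (r - ff$l0) / (1 - u^2))
  # numerical derivative consistency: F = -dE/dr
  h <- 1e-7
  expect_equal(bond_force(r, ff),
               -(bond_energy(r + h, ff) - bond_energy(r - h, ff)) / (2 * h),
               tolerance = 1e-5)

  expect_gt(bond_energy(ff$r_fene_max - 1e-6, ff), 1e2)
  expect_identical(bond_energy(ff$r_fene_max, ff), Inf)
  expect_error(bond_energy(-1, ff), "non-positive")
})

test_that("bending energy is harmonic in the joint angle", {
  ff <- forcefield_params()
  expect_equal(ff$k_bend, 5)                 # kT * (50 nm / 10 nm) / 1 sigma
  rod <- build_fiber(n_beads = 20, circular = FALSE)
  expect_equal(as.numeric(bend_energy(rod, ff)), 0)

  # single joint bent by theta: E = 1/2 k theta^2, evaluated by hand
  theta <- 0.3
  f3 <- build_fiber(n_beads = 3, circular = FALSE)
  f3$positions[3, ] <- f3$positions[2, ] + c(cos(theta), sin(theta), 0)
  expect_equal(as.numeric(bend_energy(f3, ff)), 0.5 * 5 * theta^2,
               tolerance = 1e-10)
})

test_that("twist energy follows C/(2 l0) (phi - phi0)^2 over transmitting joints", {
  ff <- forcefield_params()
  f <- build_fiber(n_beads = 10, circular = FALSE)
  expect_equal(as.numeric(twist_energy(f, ff)), 0)

  # one joint twisted by 0.1 rad, Lt = 75 nm -> E = 0.5 * 7.5 * 0.01 kT
  f$joint_twist[9] <- 0.1        # last bond: only joint 9 is affected
  expect_equal(as.numeric(twist_energy(f, ff)), 0.5 * 7.5 * 0.1^2,
               tolerance = 1e-10)

  # the same angle at a passive swivel joint costs nothing
  g <- add_passive_swivel(build_fiber(n_beads = 10, circular = FALSE), 9)
  g$joint_twist[9] <- 0.1
  expect_equal(as.numeric(twist_energy(g, ff)), 0)
})

test_that("forces obey Newton's third law and match the energy gradient", {
  set.seed(42)
  f <- build_fiber(n_beads = 20, circular = TRUE)
  f$positions <- f$positions + matrix(rnorm(60, 0, 0.05), 20, 3)
  # near-zero torsional modulus isolates the position-dependent terms whose
  # energy is a pure function of coordinates (fene + bend + wca)
  ff <- forcefield_params(Lt_nm = 1e-6)
  st <- simulation_state(f, ff = ff)
  fr <- state_forces(st)
  expect_lt(max(abs(colSums(fr$F))), 1e-9)

  E_of <- function(x) { s <- st; s$x <- x; state_forces(s)$energy$total }
  h <- 1e-6
  num <- fr$F * 0
  for (i in 1:20) for (d in 1:3) {
    xp <- st$x; xp[i, d] <- xp[i, d] + h
    xm <- st$x; xm[i, d] <- xm[i, d] - h
    num[i, d] <- -(E_of(xp) - E_of(xm)) / (2 * h)
  }
  expect_lt(max(abs(fr$F - num)), 1e-4)
})

test_that("twist stress converts to writhe downhill in energy at T = 0", {
  # a uniformly overtwisted ring must relax by writhing: monotone energy
  # descent and Tw+Wr conservation; the sign of the resulting writhe matches
  # the sign of the imposed linking difference
  set.seed(11)
  n <- 50
  f <- build_fiber(n_beads = n, circular = TRUE)
  f$positions <- f$positions + matrix(rnorm(3 * n, 0, 0.03), n, 3)
  st <- simulation_state(f)
  st$phi0 <- rep(-2 * pi * 5 / n, n)     # relaxed state would have Tw = -5
  tr <- run_dynamics(st, dynamics_config(n_steps = 70000, observe_every = 3500,
                                         temperature = 0, seed = 7))
  e <- tr$obs$energy
  expect_true(all(diff(e) < 1e-6))
  expect_gt(tail(tr$obs$Wr, 1), 0.4)     # DLk = +5: writhe turns positive
  lk <- tr$obs$Tw + tr$obs$Wr
  expect_lt(max(abs(lk - lk[1])), 0.02)
})

test_that("excluded volume is WCA with phantom masking", {
  ff <- forcefield_params()
  f <- build_fiber(n_beads = 12, circular = FALSE)
  # fold the rod so beads 1 and 8 come close without being bonded
  f$positions[8:12, 1] <- f$positions[8:12, 1] - 2 * (f$positions[8:12, 1] - 7)
  f$positions[8:12, 2] <- 0.9
  st <- simulation_state(f, ff = ff)
  e_contact <- state_forces(st)$energy$wca
  expect_gt(e_contact, 0)

  # closed-form WCA at the observed minimum distance bounds from below
  dmin <- state_forces(st)$min_nonbonded
  expect_lt(dmin, 2^(1/6))
  wca <- function(r, s = 1) 4 * (s^12 / r^12 - s^6 / r^6) + 1
  expect_gte(e_contact, wca(dmin) - 1e-9)

  # marking one side phantom removes all fibre-fibre repulsion
  fp <- add_phantom_region(f, 8:12)
  stp <- simulation_state(fp, ff = ff)
  expect_equal(state_forces(stp)$energy$wca, 0)

  # empty phantom set is bit-identical to no phantom annotation
  f0 <- add_phantom_region(f, integer(0))
  expect_identical(state_forces(simulation_state(f0, ff = ff))$F,
                   state_forces(st)$F)

  # pair beyond the cutoff: no interaction
  g <- build_fiber(n_beads = 12, circular = FALSE)
  g$positions[8:12, 1] <- g$positions[8:12, 1] + 0   # straight rod
  expect_equal(state_forces(simulation_state(g, ff = ff))$energy$wca, 0)
})

test_that("restraint forces vanish at rest length and die with the handcuff", {
  far <- build_fiber(n_beads = 10, circular = FALSE)
  far$positions <- far$positions + 100
  h <- build_handcuff()
  st <- simulation_state(far, h)
  expect_equal(state_forces(st)$energy$restraint, 0, tolerance = 1e-20)

  h2 <- build_handcuff()
  h2$beads <- h2$beads * 1.05               # strained network
  st2 <- simulation_state(far, h2)
  expect_gt(state_forces(st2)$energy$restraint, 0)

  h2$alive <- FALSE                         # dissociated: all forces removed
  st3 <- simulation_state(far, h2)
  expect_equal(state_forces(st3)$energy$restraint, 0)
})
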