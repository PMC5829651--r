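test_that("zero forces and zero temperature leave the state unchanged", {
  rod <- build_fiber(n_beads = 12, circular = FALSE)   # exact force-free state
  st <- simulation_state(rod)
  tr <- run_dynamics(st, dynamics_config(n_steps = 200, temperature = 0,
                                         observe_every = 200, seed = 1))
  expect_identical(tr$state$x, st$x)
  expect_identical(tr$state$theta, st$theta)
})

test_that("trajectories are bit-identical for identical seeds", {
  f <- build_fiber(n_beads = 30, circular = TRUE)
  st <- simulation_state(f)
  cfg <- dynamics_config(n_steps = 2000, observe_every = 500, seed = 99)
  t1 <- run_dynamics(st, cfg)
  t2 <- run_dynamics(st, cfg)
  expect_identical(t1$obs, t2$obs)
  expect_identical(t1$state$x, t2$state$x)
  cfg$seed <- 100L
  t3 <- run_dynamics(st, cfg)
  expect_false(identical(t1$state$x, t3$state$x))
})

test_that("free diffusion satisfies the Einstein relation", {
  # a 2-bead fibre has no bending or twist energy; its centre of mass
  # diffuses with D = kT / (2 gamma), so MSD = 6 kT t / (2 gamma)
  dimer <- build_fiber(n_beads = 2, circular = FALSE)
  st <- simulation_state(dimer)
  cfg <- dynamics_config(n_steps = 400000, observe_every = 50, seed = 8)
  tr <- run_dynamics(st, cfg)
  com <- t(vapply(tr$frames, colMeans, numeric(3)))
  # average MSD over many origins at a short fixed lag (0.25 tau)
  lag <- 10
  d2 <- rowSums((com[-(1:lag), ] - com[1:(nrow(com) - lag), ])^2)
  msd <- mean(d2)
  expected <- 6 * 1 / (2 * 1) * (lag * 50 * cfg$dt)
  expect_equal(msd, expected, tolerance = 0.05)
})

test_that("threading sets 10x drag, cohesin 2x, restored on exit", {
  scn <- make_scenario("fig2_handcuffed", list(n_beads = 60))
  st <- scenario_state(scn, settle = 500)
  st <- update_threading_and_drag(st)
  thr <- c(st$handcuffs[[1]]$threaded_a, st$handcuffs[[1]]$threaded_b)
  expect_false(any(is.na(thr)))
  expect_equal(st$per_bead_drag[thr], c(10, 10))
  expect_true(all(st$per_bead_drag[st$species == 1] == 2))
  expect_true(all(st$per_bead_drag[setdiff(which(st$species == 0), thr)] == 1))

  # move the handcuff far away: threading lost, drag restored
  cuff_beads <- which(st$species == 1)
  st$x[cuff_beads, ] <- st$x[cuff_beads, ] + 500
  st <- update_threading_and_drag(st)
  expect_true(is.na(st$handcuffs[[1]]$threaded_a))
  expect_true(all(st$per_bead_drag[st$species == 0] == 1))
})

test_that("swivel bookkeeping is exact", {
  f <- add_active_swivel(build_fiber(n_beads = 20, circular = TRUE), 5,
                         rate = 0.07)
  st <- simulation_state(f)
  st2 <- advance_active_swivels(st, dt = 3)
  expect_equal(st2$actives[[1]]$injected, 0.21)
  expect_equal(st2$phi0[5], -(-1) * 2 * pi * 0.21)  # sign -1 advances phi0 up

  f0 <- add_active_swivel(build_fiber(n_beads = 20, circular = TRUE), 5,
                          rate = 0)
  st0 <- advance_active_swivels(simulation_state(f0), dt = 5)
  expect_equal(st0$actives[[1]]$injected, 0)

  # integrated: injected_R = rate * time exactly
  tr <- run_dynamics(st, dynamics_config(n_steps = 1000, observe_every = 1000,
                                         seed = 2))
  expect_equal(tail(tr$obs$injected_R, 1), 0.07 * 1000 * 5e-4,
               tolerance = 1e-12)
})

test_that("bond over-extension aborts with a diagnostic", {
  f <- build_fiber(n_beads = 10, circular = FALSE)
  f$positions[10, 1] <- f$positions[10, 1] + 0.52   # bond beyond the limit
  st <- simulation_state(f)
  expect_error(run_dynamics(st, dynamics_config(n_steps = 10, seed = 1)),
               "over-extension")
})

test_that("frozen-position injection moves Tw by the injected turns", {
  # gamma_t so large that beads cannot move: all injected rotation must
  # appear as (negative) transmitted twist
  n <- 100
  f <- add_active_swivel(build_fiber(n_beads = n, circular = TRUE), 50,
                         rate = 0.05)
  st <- simulation_state(f)
  cfg <- dynamics_config(n_steps = 140000, observe_every = 20000,
                         gamma_t = 1e12, temperature = 0, seed = 5,
                         stop_R = 3)
  tr <- run_dynamics(st, cfg)
  expect_equal(tail(tr$obs$injected_R, 1), 3, tolerance = 1e-4)
  expect_equal(tail(tr$obs$Tw, 1), -3, tolerance = 0.05)
})

test_that("Tw + Wr is conserved without swivels and tracks injection with one", {
  f <- build_fiber(n_beads = 60, circular = TRUE)
  st <- simulation_state(f)
  tr <- run_dynamics(st, dynamics_config(n_steps = 30000, observe_every = 3000,
                                         seed = 3))
  lk <- tr$obs$Tw + tr$obs$Wr
  expect_lt(max(abs(lk - lk[1])), 0.05)

  f2 <- add_active_swivel(build_fiber(n_beads = 60, circular = TRUE), 30,
                          rate = 0.005)         # quasi-static injection
  st2 <- simulation_state(f2)
  tr2 <- run_dynamics(st2, dynamics_config(n_steps = 900000, stop_R = 2,
                                           observe_every = 30000, seed = 3))
  o <- tr2$obs
  # time-averaged estimate: a single joint carries ~0.06 turns of thermal
  # twist noise, so the instantaneous Tw+Wr is de-trended through the
  # deficit and averaged over the last observations
  drop_est <- tail(o$injected_R, 1) - mean(tail(o$lk_deficit, 10))
  expect_equal(drop_est, 2, tolerance = 0.025)
  expect_lt(abs(mean(o$lk_deficit)), 0.05)
})

test_that("events log threading transitions with timestamps", {
  scn <- make_scenario("fig2_handcuffed", list(n_beads = 60))
  st <- scenario_state(scn, settle = 500)
  # teleport the handcuff away mid-construction so the run logs unthreading
  cuff_beads <- which(st$species == 1)
  st$x[cuff_beads, ] <- st$x[cuff_beads, ] + 500
  tr <- run_dynamics(st, dynamics_config(n_steps = 100, observe_every = 100,
                                         seed = 6))
  expect_true(all(c("step", "time", "type", "cuff", "ring") %in%
                    names(tr$events)))
  expect_true(any(tr$events$type == "unthreaded"))
})
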