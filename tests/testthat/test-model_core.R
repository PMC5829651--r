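test_that("fibre construction maps genome length to beads and is deterministic", {
  f <- build_fiber(length_bp = 120000, circular = TRUE)
  expect_equal(n_beads(f), 300L)                      # 400 bp per bead
  expect_equal(length(f$joint_twist), 300L)           # one per bead, circular

  g <- build_fiber(n_beads = 100, circular = FALSE)
  expect_equal(contour_length_nm(g), 990)             # 99 bonds x 1 sigma
  expect_equal(length(g$joint_twist), 99L)

  expect_error(build_fiber(n_beads = 4, circular = TRUE), "at least 8")
  expect_error(build_fiber(), "exactly one")
  expect_error(build_fiber(length_bp = 1000, n_beads = 10), "exactly one")

  f2 <- build_fiber(length_bp = 120000, circular = TRUE)
  expect_identical(f$positions, f2$positions)

  # bond lengths exactly 1 sigma on build
  pos <- f$positions
  bl <- sqrt(rowSums((pos[c(2:300, 1), ] - pos)^2))
  expect_equal(bl, rep(1, 300), tolerance = 1e-12)
})

test_that("genome<->bead mapping round-trips", {
  f <- build_fiber(n_beads = 37, circular = TRUE)
  for (i in seq_len(37))
    expect_identical(bead_of(f, bp_of(f, i)), i)
  expect_identical(bead_of(f, 0), 1L)
  expect_identical(bead_of(f, 399), 1L)
  expect_identical(bead_of(f, 400), 2L)
  expect_error(bead_of(f, 37 * 400))
})

test_that("swivel, phantom and CTCF annotations validate and take effect", {
  f <- build_fiber(n_beads = 40, circular = TRUE)
  f <- add_active_swivel(f, 10, rate = 0.01)
  expect_error(add_passive_swivel(f, 10), "already")
  expect_error(add_active_swivel(f, 10), "already")
  f <- add_passive_swivel(f, 20)
  expect_error(add_active_swivel(f, 20), "already")
  expect_error(add_active_swivel(f, 41), "valid_joint")

  # passive joint contributes zero twist energy at any angle
  g <- build_fiber(n_beads = 10, circular = FALSE)
  g <- add_passive_swivel(g, 9)
  g$joint_twist[9] <- pi          # only joint 9 sees this material angle
  e <- twist_energy(g)
  per <- attr(e, "per_joint")
  expect_equal(unname(per[names(per) == "9"]), 0)
  expect_equal(as.numeric(e), 0)

  # CTCF obstacle is bigger than the ring aperture by construction
  f <- add_ctcf(f, 1)
  s <- f$ctcf_sites[[1]]
  expect_gt(sigma_to_nm(s$obstacle_diameter),
            handcuff_inner_aperture_nm(build_handcuff()))
  expect_error(add_ctcf(f, 1), "already")

  f <- add_phantom_region(f, 2:4)
  expect_identical(f$phantom_beads, 2:4)
})

test_that("handcuff build satisfies the 29/15/1 and 45/25 nm contracts", {
  h <- build_handcuff()
  expect_identical(nrow(h$beads), 29L)
  expect_identical(length(h$ring_a), 15L)
  expect_identical(length(h$ring_b), 15L)
  expect_identical(intersect(h$ring_a, h$ring_b), h$shared)
  expect_length(intersect(h$ring_a, h$ring_b), 1)

  expect_equal(round(handcuff_outer_diameter_nm(h)), 45)
  expect_equal(round(handcuff_inner_aperture_nm(h)), 25)
  expect_lt(abs(handcuff_outer_diameter_nm(h) - 45), 45 * 0.05)
  expect_lt(abs(handcuff_inner_aperture_nm(h) - 25), 25 * 0.10)

  # planar figure-eight
  expect_lt(max(abs(h$beads[, 3])), 1e-12)
  # deterministic
  expect_identical(h$beads, build_handcuff()$beads)
  # rotated/translated build preserves the internal geometry
  h2 <- build_handcuff(centre = c(3, -2, 7), normal = c(1, 1, 0))
  expect_equal(handcuff_outer_diameter_nm(h2), handcuff_outer_diameter_nm(h))
  expect_equal(handcuff_shape_rmsd(h2), 0, tolerance = 1e-8)
})

test_that("handcuff geometry holds its tolerances under thermal motion", {
  far <- build_fiber(n_beads = 10, circular = FALSE)
  far$positions <- far$positions + 100        # fibre far from the cuff
  h <- build_handcuff()
  st <- simulation_state(far, h)
  tr <- run_dynamics(st, dynamics_config(n_steps = 100000,
                                         observe_every = 4000, seed = 4))
  # ring diameters stay within their stated tolerances while thermalized
  hh <- tr$state$handcuffs[[1]]
  for (ring in c("a", "b")) {
    expect_lt(abs(handcuff_outer_diameter_nm(hh, ring) - 45), 45 * 0.05)
    expect_lt(abs(handcuff_inner_aperture_nm(hh, ring) - 25), 25 * 0.10)
  }
  # overall shape deviation stays bounded; most of it is the deliberately
  # compliant hinge between the two rings (extrusion requires it), not
  # deformation of the rings themselves
  rmsd <- mean(vapply(tr$frames[13:26],
                      function(fr) handcuff_shape_rmsd(fr[11:39, ]),
                      numeric(1)))
  expect_lt(rmsd, 0.5)
})

test_that("threading builds the pinched loop and the detector confirms it", {
  f <- build_fiber(n_beads = 300, circular = TRUE)
  f <- add_active_swivel(f, 150)
  th <- thread_handcuff(f, build_handcuff(), 140, 160)
  st <- simulation_state(th$fiber, th$handcuff)
  st <- update_threading_and_drag(st)
  expect_identical(st$handcuffs[[1]]$threaded_a, 140L)
  expect_identical(st$handcuffs[[1]]$threaded_b, 160L)
  expect_identical(loop_extent(st), 20L)

  expect_error(thread_handcuff(f, build_handcuff(), 149, 151),
               "separation")
  expect_error(thread_handcuff(f, build_handcuff(), 150, 150), "differ")

  # asymmetric threading 10 and 40 beads from the swivel
  th2 <- thread_handcuff(f, build_handcuff(), 140, 190)
  st2 <- simulation_state(th2$fiber, th2$handcuff)
  expect_identical(loop_extent(st2), 50L)

  # ring may not be placed on top of a CTCF obstacle
  fc <- add_ctcf(f, 140)
  expect_error(thread_handcuff(fc, build_handcuff(), 140, 160), "CTCF")
})

test_that("one eRNA round injects the paper's supercoil count", {
  expect_equal(supercoils_per_transcript(350), 35)
  expect_gte(supercoils_per_transcript(350), 30)
  expect_equal(supercoils_per_transcript(100, 10), 10)
})

test_that("thermal fibre sampler reproduces the discrete WLC statistics", {
  ff <- forcefield_params()
  expect_identical(sample_thermal_fiber(50, ff, seed = 3)$positions,
                   sample_thermal_fiber(50, ff, seed = 3)$positions)
  cth <- 0
  nch <- 60
  for (s in seq_len(nch)) {
    f <- sample_thermal_fiber(60, ff, seed = s)
    tg <- diff(f$positions)
    bl <- sqrt(rowSums(tg^2))
    expect_equal(bl, rep(1, 59), tolerance = 1e-9)
    tg <- tg / bl
    cth <- cth + mean(rowSums(tg[-nrow(tg), ] * tg[-1, ]))
  }
  # exact expectation for p(theta) ~ sin(theta) exp(-k theta^2/2), k = 5
  th <- seq(1e-7, pi, length.out = 20001)
  w <- sin(th) * exp(-forcefield_params()$k_bend * th^2 / 2)
  expect_equal(cth / nch, sum(cos(th) * w) / sum(w), tolerance = 0.02)
})
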