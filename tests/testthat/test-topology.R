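test_that("writhe of a planar circle is zero and mirrors flip its sign", {
  f <- build_fiber(n_beads = 64, circular = TRUE)
  expect_lt(abs(writhe(f)), 1e-7)   # ~2k pair terms of float rounding

  set.seed(5)
  x <- apply(matrix(rnorm(40 * 3, 0, 0.7), 40, 3), 2, cumsum)
  w <- writhe(x, circular = FALSE)
  xm <- x
  xm[, 3] <- -xm[, 3]
  expect_equal(writhe(xm, circular = FALSE), -w, tolerance = 1e-12)

  expect_error(writhe(x[1:3, ]), "at least 4")
  xd <- x
  xd[2, ] <- xd[1, ]
  expect_error(writhe(xd), "degenerate")
})

test_that("vectorized writhe equals the brute-force pairwise oracle", {
  set.seed(7)
  for (k in 1:100) {
    n <- sample(8:60, 1)
    circ <- k %% 2 == 0
    if (circ) {
      f <- build_fiber(n_beads = n, circular = TRUE)
      x <- f$positions + matrix(rnorm(3 * n, 0, 0.35), n, 3)
    } else {
      x <- apply(matrix(rnorm(3 * n, 0, 0.8), n, 3), 2, cumsum)
    }
    expect_lt(abs(writhe(x, circ) - brute_writhe(x, circ)), 1e-9)
  }
})

test_that("writhe of a closed helical curve converges to the continuum", {
  x400 <- helix_curve(400)
  expect_lt(abs(writhe(x400, TRUE) - brute_writhe(x400, TRUE)), 1e-9)
  x4000 <- helix_curve(4000)
  expect_lt(abs(writhe(x400, TRUE) - writhe(x4000, TRUE)), 1e-3)
})

test_that("writhe density sums to the total and windows aggregate it", {
  x <- helix_curve(120)
  d <- writhe_density(x, circular = TRUE)
  expect_length(d, 120)
  expect_equal(sum(d), writhe(x, TRUE), tolerance = 1e-12)
  pr <- writhe_profile(x, circular = TRUE, window = 10)
  expect_equal(sum(pr$Wr), writhe(x, TRUE), tolerance = 1e-12)
  expect_equal(nrow(pr), 12)
})

test_that("twist sums transmitting joint angles in turns", {
  f <- build_fiber(n_beads = 20, circular = FALSE)
  expect_equal(twist(f), 0)
  f$joint_twist[19] <- 2 * pi          # one joint set to a full turn
  expect_equal(twist(f), 1, tolerance = 1e-12)

  g <- add_passive_swivel(build_fiber(n_beads = 20, circular = FALSE), 19)
  g$joint_twist[19] <- 2 * pi
  expect_equal(twist(g), 0)            # passive joints are reported apart
  expect_equal(twist(g, "free"), 1, tolerance = 1e-12)
  expect_equal(twist(g, "all"), 1, tolerance = 1e-12)
})

test_that("lk_deficit is zero at rest and flagged for open fibres", {
  f <- build_fiber(n_beads = 30, circular = TRUE)
  st <- simulation_state(f)
  expect_equal(lk_deficit(st), 0, tolerance = 1e-9)
  fo <- build_fiber(n_beads = 30, circular = FALSE)
  expect_warning(lk_deficit(simulation_state(fo)), "diagnostic")
})

test_that("loop extent limits: border-to-border spans the whole TAD", {
  scn <- make_scenario("fig2_handcuffed", list(n_beads = 300))
  st <- scenario_state(scn, settle = 0)
  # place the threaded-bead records at the two borders
  st$cuffs[[1]]$threaded_a <- 0L          # bead 1, 0-based
  st$cuffs[[1]]$threaded_b <- 150L        # bead 151
  expect_identical(loop_extent(st), 150L) # the full TAD, through the swivel
  st$cuffs[[1]]$threaded_a <- -1L
  expect_true(is.na(loop_extent(st)))
})

test_that("contact maps are symmetric probability matrices, monotone in cutoff", {
  f <- build_fiber(n_beads = 40, circular = TRUE)
  st <- simulation_state(f)
  tr <- run_dynamics(st, dynamics_config(n_steps = 4000, observe_every = 400,
                                         seed = 12))
  cm <- contact_map(tr, cutoff = 5)
  expect_equal(unclass(cm), t(unclass(cm)))
  expect_true(all(diag(cm) == 1))
  expect_true(all(cm >= 0 & cm <= 1))
  cm8 <- contact_map(tr, cutoff = 8)
  expect_true(all(unclass(cm8) - unclass(cm) >= -1e-12))

  # frozen straight rod: contacts only within the |i-j| <= cutoff band
  rod <- build_fiber(n_beads = 30, circular = FALSE)
  cmr <- contact_map(list(rod$positions), cutoff = 3.5)
  sep <- abs(outer(1:30, 1:30, "-"))
  expect_true(all(cmr[sep <= 3] == 1))
  expect_true(all(cmr[sep >= 4] == 0))
})

test_that("plectoneme detection finds synthetic hairpins and nothing in a circle", {
  f <- build_fiber(n_beads = 60, circular = TRUE)
  expect_identical(nrow(detect_plectonemes(f)), 0L)

  x <- two_hairpins(stem = 8, gap = 1.05)
  pl <- detect_plectonemes(x, cutoff = 1.6, min_stem = 3, min_loop = 4)
  expect_identical(nrow(pl), 2L)
  # apexes at the construction midpoints (hairpin tips)
  expect_lt(abs(pl$apex[1] - 9), 2)
  expect_lt(abs(pl$apex[2] - 26), 2)
  # disjoint and ordered
  expect_true(all(diff(pl$start) > 0))
  expect_true(all(pl$start[-1] > pl$end[-nrow(pl)]))
  expect_true(all(pl$apex >= pl$start & pl$apex <= pl$end))
  expect_true(all(pl$n_rungs >= 3))
  # bp coordinates follow the 400 bp/bead map
  expect_equal(pl$start_bp, (pl$start - 1) * 400)
})

test_that("persistence-length fit flags a frozen rod and rejects short input", {
  rod <- build_fiber(n_beads = 40, circular = FALSE)
  st <- simulation_state(rod)
  tr <- run_dynamics(st, dynamics_config(n_steps = 3000, observe_every = 200,
                                         temperature = 0, seed = 2))
  expect_warning(lp <- fit_persistence_length(tr), "frozen|decorrelation")
  expect_true(attr(lp, "flagged"))
  expect_identical(unclass(lp)[1], Inf)

  tr$frames <- tr$frames[1:3]
  expect_error(fit_persistence_length(tr), "too few frames")

  circ <- run_dynamics(simulation_state(build_fiber(n_beads = 20,
                                                    circular = TRUE)),
                       dynamics_config(n_steps = 100, observe_every = 10,
                                       seed = 1))
  expect_error(fit_persistence_length(circ), "linear")
})

test_that("strand passages are read from linking-number jumps", {
  traj <- structure(list(obs = data.frame(
    time = 1:6, lk_deficit = c(0, 0.02, -0.01, 1.98, 2.02, 2))),
    class = "sx_trajectory")
  ev <- detect_passages(traj)
  expect_identical(nrow(ev), 1L)
  expect_equal(ev$jump, 1.99, tolerance = 1e-9)
  expect_identical(ev$obs, 4L)
})
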