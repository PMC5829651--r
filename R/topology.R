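#' Writhe of a polygonal curve
#'
#' Discrete Gauss double integral (Klenin--Langowski exact segment-pair
#' solid angles) over all non-adjacent segment pairs.  For a closed curve
#' this is the writhe proper; for an open chain the same sum is reported as
#' the standard open-chain extension.  Writhe is antisymmetric under mirror
#' reflection and zero for any planar curve.
#'
#' @param x n x 3 matrix of bead positions (n >= 4), or an `sx_fiber`.
#' @param circular close the curve (taken from the fibre when `x` is one).
#' @return Writhe (dimensionless).
#' @examples
#' f <- build_fiber(n_beads = 50, circular = TRUE)
#' writhe(f)   # planar circle: 0
#' @export
writhe <- function(x, circular = FALSE) {
  if (inherits(x, "sx_fiber")) { circular <- x$circular; x <- x$positions }
  x <- as.matrix(x)
  if (nrow(x) < 4) stop("writhe needs at least 4 beads")
  seg <- diff(rbind(x, if (circular) x[1, ]))
  if (any(rowSums(seg^2) < 1e-20)) stop("degenerate (zero-length) segment")
  cpp_writhe(x, circular)
}

#' Per-segment writhe density and windowed profile
#'
#' Splits the Gauss double sum into per-segment contributions (half of each
#' pair term to each segment), so the density sums to the total writhe.
#' `writhe_profile()` aggregates the density in windows of `window` beads --
#' the supercoiling localization observable.
#'
#' @inheritParams writhe
#' @param window window size in beads (default 10 beads = 4 kb).
#' @export
writhe_density <- function(x, circular = FALSE) {
  if (inherits(x, "sx_fiber")) { circular <- x$circular; x <- x$positions }
  cpp_writhe_density(as.matrix(x), circular)
}

#' @rdname writhe_density
#' @export
writhe_profile <- function(x, circular = FALSE, window = 10) {
  d <- writhe_density(x, circular)
  n <- length(d)
  starts <- seq(1, n, by = window)
  data.frame(start = starts,
             end = pmin(starts + window - 1, n),
             Wr = vapply(starts, function(s)
               sum(d[s:min(s + window - 1, n)]), numeric(1)))
}

#' Twist of a fibre
#'
#' Sum of the joint twist angles over 2 pi.  `which = "transmitting"`
#' (default) sums joints that carry torsional stiffness -- the elastic twist
#' of the fibre; `"free"` sums passive-swivel, barrier and active-swivel
#' joints (their angle is reported but carries no elastic energy there);
#' `"all"` sums everything.
#'
#' @param fiber an `sx_fiber`.
#' @param which which joints to sum.
#' @return Twist in turns.
#' @export
twist <- function(fiber, which = c("transmitting", "free", "all")) {
  which <- match.arg(which)
  phi <- joint_twists(fiber)
  joints <- fiber_joints(fiber)
  act <- vapply(fiber$active_swivels, function(s) s$joint, 0L)
  free <- joints %in% fiber$passive_swivels | joints %in% act
  keep <- switch(which, transmitting = !free, free = free,
                 all = rep(TRUE, length(joints)))
  sum(phi[keep]) / (2 * pi)
}

#' Linking-number deficit
#'
#' White's-theorem bookkeeping `Tw + Wr - Lk0 - sign * injected_R`: zero
#' (within integration error) on a closed fibre without phantom passages,
#' jumping by ~+-2 when a strand passage occurs at a phantom region.  On an
#' open fibre the quantity is only a diagnostic and is flagged as such.
#'
#' @param x an `sx_trajectory` (returns the per-observation series) or an
#'   `sx_state`.
#' @return Numeric vector (trajectory) or scalar (state), in turns.
#' @export
lk_deficit <- function(x) {
  if (inherits(x, "sx_trajectory")) {
    if (!x$circular)
      warning("open fibre: lk_deficit is a diagnostic only")
    return(x$obs$lk_deficit)
  }
  stopifnot(inherits(x, "sx_state"))
  if (!x$circular) warning("open fibre: lk_deficit is a diagnostic only")
  f <- state_forces(x)
  wr <- writhe(x$x[seq_len(x$n_fiber), , drop = FALSE], x$circular)
  sgnR <- sum(vapply(x$actives, function(a) a$sign * a$injected, numeric(1)))
  lk0 <- if (is.null(x$Lk0)) f$Lk0 else x$Lk0
  f$tw_transmitting + wr - lk0 - sgnR
}

#' Detect strand-passage events
#'
#' Passages at phantom regions are detected post hoc as jumps of about +-2
#' turns in the linking-number deficit between consecutive observations.
#'
#' @param traj an `sx_trajectory`.
#' @param threshold minimal |jump| flagged (turns).
#' @return data.frame of events (observation index, time, jump).
#' @export
detect_passages <- function(traj, threshold = 1) {
  d <- diff(traj$obs$lk_deficit)
  i <- which(abs(d) > threshold)
  data.frame(obs = i + 1L, time = traj$obs$time[i + 1L], jump = d[i])
}

#' Loop extent spanned by a handcuff
#'
#' Contour distance (in beads) between the two threaded fibre beads,
#' measured through the fibre segment that contains the active swivel (the
#' transcribed, supercoiled segment).  `NA` with an event log entry when a
#' ring is unthreaded.
#'
#' @param x an `sx_state` or `sx_trajectory` (per-observation series).
#' @param handcuff handcuff index.
#' @return Beads (integer), or NA.
#' @export
loop_extent <- function(x, handcuff = 1) {
  if (inherits(x, "sx_trajectory")) return(x$obs$loop_extent)
  stopifnot(inherits(x, "sx_state"))
  cf <- x$cuffs[[handcuff]]
  a <- cf$threaded_a; b <- cf$threaded_b
  if (is.null(a) || a < 0 || b < 0 || !cf$alive) return(NA_integer_)
  a <- a + 1L; b <- b + 1L                      # 1-based beads
  lo <- min(a, b); hi <- max(a, b)
  if (!x$circular) return(hi - lo)
  sw <- if (length(x$actives)) x$actives[[1]]$vertex + 1L else 1L
  n <- x$n_fiber
  if (sw > lo && sw < hi) hi - lo else n - (hi - lo)
}

#' Time-averaged contact map
#'
#' Fraction of trajectory frames in which two fibre beads lie within
#' `cutoff` sigma of each other.  Symmetric with unit diagonal, values in
#' [0, 1] and monotone non-decreasing in the cutoff.
#'
#' @param traj an `sx_trajectory` with recorded frames (or a list of n x 3
#'   coordinate matrices).
#' @param cutoff contact distance (sigma; default 5 = 50 nm -- the paper
#'   never defines one, so it is a configurable artifact choice).
#' @param beads which beads to include (default: fibre beads only).
#' @return Object of class `sx_contact_map` (a matrix with attributes).
#' @export
contact_map <- function(traj, cutoff = 5, beads = NULL) {
  frames <- if (inherits(traj, "sx_trajectory")) traj$frames else traj
  if (length(frames) < 1) stop("contact_map needs at least one frame")
  if (inherits(traj, "sx_trajectory") && is.null(beads))
    beads <- seq_len(traj$n_fiber)
  if (!is.null(beads))
    frames <- lapply(frames, function(f) f[beads, , drop = FALSE])
  m <- cpp_contact_map(frames, cutoff)
  structure(m, cutoff = cutoff, n_frames = length(frames),
            class = c("sx_contact_map", class(m)))
}

#' @export
plot.sx_contact_map <- function(x, ...) {
  n <- nrow(x)
  image(seq_len(n), seq_len(n), unclass(x)[, n:1],
        col = hcl.colors(64, "YlOrRd", rev = TRUE),
        xlab = "bead", ylab = "bead", useRaster = TRUE, ...)
  invisible(x)
}

#' Detect plectonemes
#'
#' A plectoneme appears in a single frame as a ladder of contacts between
#' the two strands of its interwound stem: contact pairs (i, j) with contour
#' separation >= `min_loop` that form an anti-diagonal band of at least
#' `min_stem` rungs.  Rungs are clustered (pairs within 2 beads of each
#' other on both sides belong to one stem), merged into disjoint ordered
#' intervals; the apex is the midpoint of the innermost pair.  Stem
#' chirality is read from the sign of the crossing (pairwise writhe)
#' contributions: negative supercoiling gives right-handed (negative-sign)
#' interwinding.
#'
#' @param x n x 3 bead positions or an `sx_fiber`.
#' @param cutoff contact distance for stem rungs (sigma).
#' @param min_stem minimal number of rungs.
#' @param min_loop minimal contour separation of a rung (beads).
#' @param circular treat the chain as closed (stems straddling the origin
#'   are reported split).
#' @param units an [unit_system()] for the bp coordinates of the calls.
#' @return data.frame with one row per plectoneme: start, end, apex (beads),
#'   start_bp, end_bp, n_rungs, chirality ("right"/"left"), mean_crossing.
#' @export
detect_plectonemes <- function(x, cutoff = 3, min_stem = 3, min_loop = 4,
                               circular = FALSE, units = unit_system()) {
  if (inherits(x, "sx_fiber")) {
    circular <- x$circular; units <- x$units; x <- x$positions
  }
  x <- as.matrix(x)
  n <- nrow(x)
  dm <- as.matrix(dist(x))
  sep <- abs(outer(seq_len(n), seq_len(n), "-"))
  if (circular) sep <- pmin(sep, n - sep)
  hit <- which(dm < cutoff & sep >= min_loop & upper.tri(dm), arr.ind = TRUE)
  empty <- data.frame(start = integer(0), end = integer(0), apex = numeric(0),
                      start_bp = integer(0), end_bp = integer(0),
                      n_rungs = integer(0), chirality = character(0),
                      mean_crossing = numeric(0))
  if (nrow(hit) < min_stem) return(empty)

  # single-linkage clustering of contact pairs into stems
  np <- nrow(hit)
  comp <- seq_len(np)
  repeat {
    changed <- FALSE
    for (p in seq_len(np)) {
      nb <- which(abs(hit[, 1] - hit[p, 1]) <= 2 & abs(hit[, 2] - hit[p, 2]) <= 2)
      cmin <- min(comp[nb])
      if (any(comp[nb] != cmin)) { comp[nb] <- cmin; changed <- TRUE }
    }
    if (!changed) break
  }
  grp <- split(seq_len(np), comp)
  grp <- grp[vapply(grp, length, 0L) >= min_stem]
  if (!length(grp)) return(empty)

  calls <- do.call(rbind, lapply(grp, function(idx) {
    ii <- hit[idx, 1]; jj <- hit[idx, 2]
    inner <- idx[which.min(jj - ii)]
    cross <- vapply(idx, function(p) {
      i <- hit[p, 1]; j <- hit[p, 2]
      i2 <- min(i + 1, n); j2 <- min(j + 1, n)
      if (i2 == i || j2 == j) return(0)
      cpp_segment_pair_writhe(x[i, ], x[i2, ], x[j, ], x[j2, ])
    }, numeric(1))
    data.frame(start = min(ii), end = max(jj),
               apex = (hit[inner, 1] + hit[inner, 2]) / 2,
               n_rungs = length(idx), mean_crossing = mean(cross))
  }))
  calls <- calls[order(calls$start), , drop = FALSE]

  # merge overlapping intervals so the output is disjoint and ordered
  merged <- calls[1, , drop = FALSE]
  if (nrow(calls) > 1) for (r in 2:nrow(calls)) {
    last <- nrow(merged)
    if (calls$start[r] <= merged$end[last]) {
      w1 <- merged$n_rungs[last]; w2 <- calls$n_rungs[r]
      if (calls$end[r] - calls$start[r] < merged$end[last] - merged$start[last])
        merged$apex[last] <- calls$apex[r]
      merged$end[last] <- max(merged$end[last], calls$end[r])
      merged$mean_crossing[last] <-
        (merged$mean_crossing[last] * w1 + calls$mean_crossing[r] * w2) / (w1 + w2)
      merged$n_rungs[last] <- w1 + w2
    } else merged <- rbind(merged, calls[r, ])
  }
  merged$chirality <- ifelse(merged$mean_crossing < 0, "right", "left")
  merged$start_bp <- (merged$start - 1L) * units$bp_per_bead
  merged$end_bp <- merged$end * units$bp_per_bead
  rownames(merged) <- NULL
  merged[, c("start", "end", "apex", "start_bp", "end_bp", "n_rungs",
             "chirality", "mean_crossing")]
}

#' Fit the bending persistence length
#'
#' Exponential fit of the tangent-tangent correlation
#' `<t(s) . t(0)> = exp(-s l0 / Lp)` over an equilibrated linear-fibre
#' trajectory, averaged over all origins and frames, with a bootstrap CI
#' over frames.  A frozen straight rod has no decay; the fit is then flagged
#' and `Inf` returned.
#'
#' @param traj an `sx_trajectory` of a linear fibre with recorded frames.
#' @param max_lag maximal contour lag used (bonds); default half the chain.
#' @param min_frames minimal number of frames required.
#' @param n_boot bootstrap resamples for the CI.
#' @return Persistence length in nm, with attributes `ci` (95% bootstrap
#'   interval), `flagged` (logical) and `correlation` (the fitted curve).
#' @export
fit_persistence_length <- function(traj, max_lag = NULL, min_frames = 10,
                                   n_boot = 200) {
  stopifnot(inherits(traj, "sx_trajectory"))
  if (traj$circular) stop("persistence-length fit expects a linear fibre")
  frames <- traj$frames
  if (length(frames) < min_frames)
    stop("too few frames (", length(frames), "); need >= ", min_frames,
         " decorrelated observations")
  nf <- traj$n_fiber
  if (is.null(max_lag)) max_lag <- max(3L, (nf - 1L) %/% 2L)

  corr_one <- function(fr) {
    p <- fr[seq_len(nf), , drop = FALSE]
    tg <- diff(p)
    len <- sqrt(rowSums(tg^2))
    tg <- tg / len
    vapply(seq_len(max_lag), function(s) {
      k <- seq_len(nrow(tg) - s)
      mean(rowSums(tg[k, , drop = FALSE] * tg[k + s, , drop = FALSE]))
    }, numeric(1))
  }
  cs <- vapply(frames, corr_one, numeric(max_lag))
  mean_bond <- mean(vapply(frames, function(fr) {
    p <- fr[seq_len(nf), , drop = FALSE]
    mean(sqrt(rowSums(diff(p)^2)))
  }, numeric(1)))

  fit_lp <- function(cmat) {
    cm <- rowMeans(cmat)
    s <- seq_len(max_lag)
    # fit only the well-determined part of the decay: log of a small noisy
    # correlation has exploding variance, so weight by C^2 (delta method)
    use <- cm > 0.2
    if (sum(use) < 3) use <- cm > 0 & s <= 5
    sl <- coef(lm(log(cm[use]) ~ 0 + s[use], weights = cm[use]^2))[[1]]
    if (sl >= -1e-9) return(Inf)
    -1 / sl
  }
  lp_bonds <- fit_lp(cs)
  units <- traj$state$fiber$units
  flagged <- !is.finite(lp_bonds)
  if (flagged)
    warning("no measurable tangent decorrelation (frozen or too-stiff rod)")
  ci <- c(NA_real_, NA_real_)
  if (!flagged && length(frames) >= 5) {
    bt <- replicate(n_boot, {
      pick <- sample(ncol(cs), replace = TRUE)
      fit_lp(cs[, pick, drop = FALSE])
    })
    ci <- quantile(bt[is.finite(bt)], c(0.025, 0.975)) * mean_bond *
      units$sigma_nm
  }
  structure(lp_bonds * mean_bond * units$sigma_nm,
            ci = unname(ci), flagged = flagged,
            mean_bond_sigma = mean_bond,
            correlation = rowMeans(cs))
}
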