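# Independent oracles used across the suite.

# brute-force writhe: scalar R loops over all non-adjacent segment pairs,
# transcribing the exact Gauss pair integral independently of the vectorized
# engine path
brute_writhe <- function(x, circular = FALSE) {
  n <- nrow(x)
  nseg <- if (circular) n else n - 1
  seg_i <- function(i) list(p1 = x[i, ], p2 = x[i %% n + 1, ])
  wr <- 0
  for (i in seq_len(nseg)) {
    for (j in seq_len(nseg)) {
      if (j <= i + 1) next
      if (circular && i == 1 && j == nseg) next
      a <- seg_i(i); b <- seg_i(j)
      wr <- wr + pair_omega(a$p1, a$p2, b$p1, b$p2) / (2 * pi)
    }
  }
  wr
}

pair_omega <- function(p1, p2, p3, p4) {
  cr <- function(a, b) c(a[2]*b[3]-a[3]*b[2], a[3]*b[1]-a[1]*b[3],
                         a[1]*b[2]-a[2]*b[1])
  nrm <- function(v) sqrt(sum(v^2))
  r13 <- p3 - p1; r14 <- p4 - p1; r23 <- p3 - p2; r24 <- p4 - p2
  n1 <- cr(r13, r14); n2 <- cr(r14, r24); n3 <- cr(r24, r23); n4 <- cr(r23, r13)
  ls <- c(nrm(n1), nrm(n2), nrm(n3), nrm(n4))
  if (any(ls < 1e-14)) return(0)
  n1 <- n1/ls[1]; n2 <- n2/ls[2]; n3 <- n3/ls[3]; n4 <- n4/ls[4]
  cl <- function(z) max(-1, min(1, z))
  s <- asin(cl(sum(n1*n2))) + asin(cl(sum(n2*n3))) +
       asin(cl(sum(n3*n4))) + asin(cl(sum(n4*n1)))
  sgn <- if (sum(cr(p4 - p3, p2 - p1) * r13) >= 0) 1 else -1
  s * sgn
}

# closed helical test curve wound on a torus: smooth, non-planar, closed
helix_curve <- function(n, R = 5, r = 1.5, q = 4) {
  t <- 2 * pi * (seq_len(n) - 1) / n
  cbind((R + r * cos(q * t)) * cos(t),
        (R + r * cos(q * t)) * sin(t),
        r * sin(q * t))
}

# two synthetic hairpins glued end to end: plectoneme-detector oracle
two_hairpins <- function(stem = 8, gap = 1.1) {
  hp <- function(x0) {
    up <- cbind(x0, seq(0, stem - 1), 0)
    tip <- cbind(x0 + gap / 2, stem - 1 + gap / 2, 0)
    down <- cbind(x0 + gap, seq(stem - 1, 0), 0)
    rbind(up, tip, down)
  }
  rbind(hp(0), hp(12))
}

# small thermalized handcuffed scenario cached per session
fast_cfg <- function(...) dynamics_config(...)
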