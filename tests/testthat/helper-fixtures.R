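# Shared fixtures and small oracles, all built in code.

# Hand-computed 2D lateral-cephalogram fixture: FOP horizontal through
# (10,0)-(30,0), Ref the line y = 40 through Ar, PM meets Ref at (1.25, 40),
# ARa (vertical offset of PRa through LT) meets Ref at (-10, 40).
f2d_landmarks <- function(subject = "F2D") {
  landmarks2d(rbind(
    Poc = c(10, 0), Aoc = c(30, 0), Ar = c(-25, 40), SE = c(0, 50),
    PTM = c(5, 10), LT = c(0, 0), pra_fop_point = c(-15, 0), A = c(45, 25),
    B = c(42, -15), SPr = c(48, 15), IPr = c(46, -5), Me = c(40, -20),
    corpus_lowest = c(20, -22), ramus_posterior_most = c(-22, 20)),
    subject = subject)
}

f2d_expected <- c(maxillary_skeletal = 43.75, mandibular_skeletal = 52,
                  maxillary_dental = 46.75, mandibular_dental = 56,
                  mcf = 26.25, ramus = 15)

# Hand-computed 3D fixture in the canonical frame: PNS plane y = -10,
# lingual-tuberosity plane y = -15, clinoid plane y = 5.
f3d_landmarks <- function(subject = "F3D") {
  landmarks3d(rbind(
    PNS = c(0, -10, 0), rLT = c(20, -15, -10), lLT = c(-20, -15, -10),
    r_clinoid = c(12, 5, 20), l_clinoid = c(-12, 5, 20),
    A = c(0, 35, -5), B = c(0, 33, -25), SPr = c(0, 38, -8),
    IPr = c(0, 36, -22), Ba = c(0, -22, 12),
    rCo = c(45, -40, 5), lCo = c(-45, -40, 5)),
    subject = subject)
}

f3d_expected <- c(maxillary_skeletal = 45, mandibular_skeletal = 48,
                  maxillary_dental = 48, mandibular_dental = 51,
                  mcf = 27, ramus_right = 25, ramus_left = 25)

# random proper rotation (det +1) in 3D
rand_rotation3 <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# apply a rigid motion (R, t) to every row of a coordinate matrix
apply_rigid <- function(coords, R, tr) t(R %*% t(coords) + tr)

# triplets spanning the canonical axial (z=0), coronal (y=0) and sagittal
# (x=0) planes, ordered so each right-hand-rule normal points along the
# positive canonical axis
canonical_triplets <- function() {
  list(axial = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
       coronal = rbind(c(0, 0, 0), c(0, 0, 1), c(1, 0, 0)),
       sagittal = rbind(c(0, 0, 0), c(0, 1, 0), c(0, 0, 1)))
}

# brute-force one-sample KS statistic against a fitted normal: maximize
# both one-sided ECDF gaps at every sample point
ks_stat_oracle <- function(x) {
  n <- length(x)
  xs <- sort(x)
  f <- stats::pnorm(xs, mean = mean(x), sd = stats::sd(x))
  max(pmax(seq_len(n) / n - f, f - (seq_len(n) - 1L) / n))
}

# brute-force point-to-plane distance: iterative dense grid sampling of a
# bounded plane patch, independent of the projection formula
point_plane_distance_oracle <- function(p, plane, half = 80, levels = 8, k = 21) {
  n <- plane$normal
  e <- if (abs(n[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- c(n[2L] * e[3L] - n[3L] * e[2L],
         n[3L] * e[1L] - n[1L] * e[3L],
         n[1L] * e[2L] - n[2L] * e[1L])
  u <- u / sqrt(sum(u^2))
  v <- c(n[2L] * u[3L] - n[3L] * u[2L],
         n[3L] * u[1L] - n[1L] * u[3L],
         n[1L] * u[2L] - n[2L] * u[1L])
  ctr <- c(0, 0)
  best <- Inf
  for (lev in seq_len(levels)) {
    g <- seq(-half, half, length.out = k)
    ab <- cbind(rep(ctr[1L] + g, times = k), rep(ctr[2L] + g, each = k))
    pts <- outer(ab[, 1L], u) + outer(ab[, 2L], v)
    pts <- sweep(pts, 2L, plane$anchor, "+")
    d2 <- (pts[, 1L] - p[1L])^2 + (pts[, 2L] - p[2L])^2 + (pts[, 3L] - p[3L])^2
    i <- which.min(d2)
    best <- sqrt(d2[i])
    ctr <- ab[i, ]
    half <- 2 * half / (k - 1)  # next half-range = current grid spacing
  }
  best
}
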