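# Internal helpers: seeded substreams, small vector algebra.

# Derive a reproducible substream seed from a global seed and a stream id.
# Kept below 2^31 so it is always a valid R integer seed.
.substream <- function(seed, stream) {
  s <- (as.numeric(seed) * 48271 + as.numeric(stream) * 7919) %% 2147483647
  as.integer(s)
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG state.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

.vnorm <- function(v) sqrt(sum(v^2))

# Angle at p2 formed by p1 and p3, degrees in [0, 180]. NA if an arm collapses.
.angle_deg <- function(p1, p2, p3) {
  u <- p1 - p2
  v <- p3 - p2
  nu <- .vnorm(u)
  nv <- .vnorm(v)
  if (nu < 1e-12 || nv < 1e-12) return(NA_real_)
  cosang <- sum(u * v) / (nu * nv)
  cosang <- min(1, max(-1, cosang))
  acos(cosang) * 180 / pi
}

# Signed dihedral of p1-p2-p3-p4, IUPAC right-handed convention,
# degrees in (-180, 180]. NA for degenerate (collinear) configurations.
.dihedral_deg <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  nb2 <- .vnorm(b2)
  if (.vnorm(n1) < 1e-12 || .vnorm(n2) < 1e-12 || nb2 < 1e-12) return(NA_real_)
  cross12 <- c(n1[2] * n2[3] - n1[3] * n2[2],
               n1[3] * n2[1] - n1[1] * n2[3],
               n1[1] * n2[2] - n1[2] * n2[1])
  x <- sum(n1 * n2)
  y <- sum(cross12 * b2) / nb2
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

# Rotation matrix about unit axis by theta radians (Rodrigues).
.rotation_matrix <- function(axis, theta) {
  a <- axis / .vnorm(axis)
  K <- matrix(c(0, a[3], -a[2],
                -a[3], 0, a[1],
                a[2], -a[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# All pairwise Euclidean distances between rows of A and rows of B.
.pdist2 <- function(A, B) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
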