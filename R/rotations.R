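# Quaternion utilities, vectorized over columns. Quaternions are 4 x N
# matrices (w, x, y, z), unit norm; rotation matrices are stored as 9 x N
# (column-major 3x3 per column).

.quatIdentity <- function(n) rbind(rep(1, n), 0, 0, 0)

.quatNormalize <- function(q) {
  n <- sqrt(colSums(q * q))
  sweep(q, 2, n, "/")
}

# quaternion from rotation vector (3 x N)
.quatFromRotvec <- function(w) {
  th <- sqrt(colSums(w * w))
  half <- th / 2
  s <- ifelse(th < 1e-12, 0.5 - th^2 / 48, sin(half) / th)
  rbind(cos(half), w[1, ] * s, w[2, ] * s, w[3, ] * s)
}

# Hamilton product a x b, both 4 x N
.quatMul <- function(a, b) {
  rbind(a[1, ] * b[1, ] - a[2, ] * b[2, ] - a[3, ] * b[3, ] - a[4, ] * b[4, ],
        a[1, ] * b[2, ] + a[2, ] * b[1, ] + a[3, ] * b[4, ] - a[4, ] * b[3, ],
        a[1, ] * b[3, ] - a[2, ] * b[4, ] + a[3, ] * b[1, ] + a[4, ] * b[2, ],
        a[1, ] * b[4, ] + a[2, ] * b[3, ] - a[3, ] * b[2, ] + a[4, ] * b[1, ])
}

# rotation matrices (9 x N, column-major) from quaternions
.quatToMat <- function(q) {
  w <- q[1, ]; x <- q[2, ]; y <- q[3, ]; z <- q[4, ]
  rbind(1 - 2 * (y * y + z * z), 2 * (x * y + w * z), 2 * (x * z - w * y),
        2 * (x * y - w * z), 1 - 2 * (x * x + z * z), 2 * (y * z + w * x),
        2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x * x + y * y))
}

# single 3x3 matrix -> quaternion (Shepperd), for constant offsets
.matToQuat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(c(R[1, 1], R[2, 2], R[3, 3]))
    if (i == 1) {
      s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
      q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s,
             (R[1, 2] + R[2, 1]) / s, (R[1, 3] + R[3, 1]) / s)
    } else if (i == 2) {
      s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
      q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s,
             0.25 * s, (R[2, 3] + R[3, 2]) / s)
    } else {
      s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
      q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
             (R[2, 3] + R[3, 2]) / s, 0.25 * s)
    }
  }
  q / sqrt(sum(q * q))
}

# rotation vectors from 9 x N near-identity rotation matrices (|theta| < pi)
.rotvecFromMat <- function(L) {
  w1 <- 0.5 * (L[6, ] - L[8, ])   # L[3,2] - L[2,3]
  w2 <- 0.5 * (L[7, ] - L[3, ])   # L[1,3] - L[3,1]
  w3 <- 0.5 * (L[2, ] - L[4, ])   # L[2,1] - L[1,2]
  ct <- pmin(pmax((L[1, ] + L[5, ] + L[9, ] - 1) / 2, -1), 1)
  th <- acos(ct)
  f <- ifelse(th < 1e-8, 1 + th^2 / 6, th / sin(th))
  rbind(w1 * f, w2 * f, w3 * f)
}

.rotZ <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
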