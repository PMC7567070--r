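# Independent oracles used to cross-check the package's own numerics.
# Each takes a different algebraic route than the implementation it checks.

# Horn's quaternion method for the optimal proper rotation (weighted).
quaternion_fit_oracle <- function(mobile, reference, weights = NULL) {
  n <- nrow(mobile)
  if (is.null(weights)) weights <- rep(1, n)
  w <- weights / sum(weights)
  cm <- colSums(mobile * w); cr <- colSums(reference * w)
  x <- sweep(mobile, 2, cm); y <- sweep(reference, 2, cr)
  s <- t(x * w) %*% y
  nmat <- matrix(0, 4, 4)
  nmat[1, 1] <- s[1, 1] + s[2, 2] + s[3, 3]
  nmat[1, 2] <- nmat[2, 1] <- s[2, 3] - s[3, 2]
  nmat[1, 3] <- nmat[3, 1] <- s[3, 1] - s[1, 3]
  nmat[1, 4] <- nmat[4, 1] <- s[1, 2] - s[2, 1]
  nmat[2, 2] <- s[1, 1] - s[2, 2] - s[3, 3]
  nmat[2, 3] <- nmat[3, 2] <- s[1, 2] + s[2, 1]
  nmat[2, 4] <- nmat[4, 2] <- s[3, 1] + s[1, 3]
  nmat[3, 3] <- -s[1, 1] + s[2, 2] - s[3, 3]
  nmat[3, 4] <- nmat[4, 3] <- s[2, 3] + s[3, 2]
  nmat[4, 4] <- -s[1, 1] - s[2, 2] + s[3, 3]
  q <- eigen(nmat, symmetric = TRUE)$vectors[, 1]
  q0 <- q[1]; q1 <- q[2]; q2 <- q[3]; q3 <- q[4]
  r <- matrix(c(
    q0^2 + q1^2 - q2^2 - q3^2, 2 * (q1 * q2 - q0 * q3), 2 * (q1 * q3 + q0 * q2),
    2 * (q1 * q2 + q0 * q3), q0^2 - q1^2 + q2^2 - q3^2, 2 * (q2 * q3 - q0 * q1),
    2 * (q1 * q3 - q0 * q2), 2 * (q2 * q3 + q0 * q1), q0^2 - q1^2 - q2^2 + q3^2
  ), 3, 3, byrow = TRUE)
  # rotation maps mobile-frame -> reference-frame (same convention as kabsch_fit)
  fitted <- sweep(sweep(mobile, 2, cm) %*% t(r), 2, -cr)
  list(rotation = r,
       rmsd = sqrt(sum(w * rowSums((fitted - reference)^2))))
}

# Brute-force minimum RMSD over rotation space (Euler angles + optimal
# translation through centroids), multi-start Nelder-Mead.
numeric_min_rmsd_oracle <- function(mobile, reference, weights = NULL) {
  n <- nrow(mobile)
  if (is.null(weights)) weights <- rep(1, n)
  w <- weights / sum(weights)
  cm <- colSums(mobile * w); cr <- colSums(reference * w)
  x <- sweep(mobile, 2, cm); y <- sweep(reference, 2, cr)
  euler_rot <- function(a) {
    cz <- cos(a[1]); sz <- sin(a[1]); cy <- cos(a[2]); sy <- sin(a[2])
    cx <- cos(a[3]); sx <- sin(a[3])
    rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
    ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
    rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
    rz %*% ry %*% rx
  }
  obj <- function(a) sqrt(sum(w * rowSums((x %*% t(euler_rot(a)) - y)^2)))
  starts <- rbind(c(0, 0, 0), c(pi / 2, 0, 0), c(0, pi / 2, 0), c(0, 0, pi / 2),
                  c(pi, 0, 0), c(pi / 3, -pi / 4, pi / 5))
  best <- Inf
  for (i in seq_len(nrow(starts))) {
    o <- optim(starts[i, ], obj, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
    o <- optim(o$par, obj, method = "BFGS", control = list(reltol = 1e-14))
    best <- min(best, o$value)
  }
  best
}

# Torsion via perpendicular projections onto the plane normal to the central
# bond (different route than the plane-normal formula in the package).
torsion_projection_oracle <- function(p1, p2, p3, p4) {
  b2 <- p3 - p2
  b2u <- b2 / sqrt(sum(b2^2))
  perp <- function(v) v - sum(v * b2u) * b2u
  v1 <- perp(p1 - p2)
  v2 <- perp(p4 - p3)
  cr <- c(v1[2] * v2[3] - v1[3] * v2[2],
          v1[3] * v2[1] - v1[1] * v2[3],
          v1[1] * v2[2] - v1[2] * v2[1])
  atan2(sum(cr * b2u), sum(v1 * v2)) * 180 / pi
}

# Numeric root of the Gaussian log-density equality (bisection), used to
# check the closed-form CGI intersection.
cgi_bisection_oracle <- function(mu_f, sd_f, mu_r, sd_r) {
  f <- function(x) stats::dnorm(x, mu_f, sd_f, log = TRUE) -
    stats::dnorm(x, mu_r, sd_r, log = TRUE)
  uniroot(f, sort(c(mu_r, mu_f)), tol = 1e-12)$root
}

# Minimal multi-model PDB fixture written from code.
write_fixture_pdb <- function(path, frames) {
  lines <- character(0)
  for (k in seq_along(frames)) {
    xyz <- frames[[k]]
    lines <- c(lines, sprintf("MODEL     %4d", k))
    for (i in seq_len(nrow(xyz))) {
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        i, c("N", "CA", "C", "O")[(i - 1) %% 4 + 1], "GLY", "A",
        (i - 1) %/% 4 + 1, xyz[i, 1], xyz[i, 2], xyz[i, 3], 1.0, 0.0,
        c("N", "C", "C", "O")[(i - 1) %% 4 + 1]))
    }
    lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  path
}

random_rigid_transform <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  r <- matrix(c(
    q[1]^2 + q[2]^2 - q[3]^2 - q[4]^2, 2 * (q[2] * q[3] - q[1] * q[4]), 2 * (q[2] * q[4] + q[1] * q[3]),
    2 * (q[2] * q[3] + q[1] * q[4]), q[1]^2 - q[2]^2 + q[3]^2 - q[4]^2, 2 * (q[3] * q[4] - q[1] * q[2]),
    2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]), q[1]^2 - q[2]^2 - q[3]^2 + q[4]^2
  ), 3, 3, byrow = TRUE)
  trajmetrics:::new_rigid_transform(r, rnorm(3, sd = 5))
}
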