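#' Build an ideal alpha-helical Calpha trace
#'
#' Places one Calpha per residue on the parametric helix
#' (radius cos(k twist), radius sin(k twist), k rise). Defaults are textbook
#' alpha-helix values (rise 1.5 Angstrom/residue, twist 100 degrees/residue,
#' radius 2.3 Angstrom); this is fixture geometry, not a biological claim.
#'
#' @param n_residues number of residues (>= 4).
#' @param rise axial rise per residue, Angstrom.
#' @param twist rotation per residue, degrees.
#' @param radius helix radius, Angstrom.
#' @param start_resid first residue number (so specific residue numbers can
#'   be addressed in selections and quadruples).
#' @param chain chain identifier.
#' @return an [md_structure()] of `n_residues` Calpha atoms.
#' @export
build_ideal_helix <- function(n_residues, rise = 1.5, twist = 100,
                              radius = 2.3, start_resid = 1L, chain = "A") {
  if (n_residues < 4L) stopf("a helix fixture needs at least 4 residues")
  if (rise <= 0 || radius <= 0) stopf("rise and radius must be positive")
  k <- seq_len(n_residues) - 1
  coords <- cbind(radius * cos(deg2rad(k * twist)),
                  radius * sin(deg2rad(k * twist)),
                  k * rise)
  atoms <- new_atom_table(
    serial = seq_len(n_residues), name = "CA", element = "C",
    resname = "ALA", resid = start_resid + k, chain = chain
  )
  md_structure(atoms, coords, meta = list(source = "ideal_helix"))
}

#' Build a two-helix system with a prescribed quadruple torsion
#'
#' Joins two ideal helix segments -- residues 67-74 (alpha2-like) and 87-104
#' (alpha3-like) -- positioned so that the torsion of the canonical Calpha
#' quadruple 67 -> 74 -> 104 -> 87 equals `hinge_angle` exactly: the second
#' segment is rotated about the virtual bond between the two central quadruple
#' atoms until the target torsion is hit. The quadruple is attached to the
#' result's `meta$quadruple`.
#'
#' @param hinge_angle target torsion in degrees, in (-180, 180].
#' @param separation distance (Angstrom) between the two central quadruple
#'   atoms; default 5.
#' @return an [md_structure()] whose quadruple torsion is `hinge_angle`.
#' @export
build_two_helix_system <- function(hinge_angle, separation = 5) {
  if (hinge_angle <= -180 || hinge_angle > 180)
    stopf("hinge_angle must lie in (-180, 180]")
  ha <- build_ideal_helix(8, start_resid = 67L)           # quadruple atoms 67, 74
  hb <- build_ideal_helix(18, start_resid = 87L)          # quadruple atoms 104, 87
  ia <- c(which(ha$atoms$resid == 67L), which(ha$atoms$resid == 74L))
  ib <- c(which(hb$atoms$resid == 104L), which(hb$atoms$resid == 87L))

  ca <- sweep(ha$coords, 2, ha$coords[ia[2], ])           # CA74 at origin
  cb <- sweep(hb$coords, 2, hb$coords[ib[1], ])           # CA104 at origin ...
  cb <- sweep(cb, 2, c(0, 0, separation), `+`)            # ... then on +z

  p1 <- ca[ia[1], ]; p2 <- c(0, 0, 0); p3 <- c(0, 0, separation)
  phi0 <- torsion_angle(p1, p2, p3, cb[ib[2], ])
  placed <- FALSE
  for (delta in c(hinge_angle - phi0, phi0 - hinge_angle)) {
    cand <- cb %*% t(rot_z(delta))
    phi <- torsion_angle(p1, p2, p3, cand[ib[2], ])
    if (abs(circular_diff(phi, hinge_angle)) < 1e-9) {
      cb <- cand; placed <- TRUE; break
    }
  }
  if (!placed) stopf("internal error: could not realise hinge angle %g", hinge_angle)

  atoms <- dplyr::bind_rows(ha$atoms, hb$atoms)
  atoms$serial <- seq_len(nrow(atoms))
  md_structure(atoms, rbind(ca, cb),
               meta = list(source = "two_helix_system",
                           quadruple = dihedral_quadruple()))
}

rot_z <- function(deg) {
  th <- deg2rad(deg)
  matrix(c(cos(th), -sin(th), 0,
           sin(th),  cos(th), 0,
           0,        0,       1), 3, 3, byrow = TRUE)
}

#' Simulate a fluctuating trajectory around a base structure
#'
#' Frame k applies an optional rigid-body drift (rotation about z plus
#' translation, both linear in time) to the base coordinates perturbed by
#' independent Gaussian displacements of standard deviation `sigma` per atom
#' per axis. Seeded and bit-reproducible.
#'
#' @param base an [md_structure()].
#' @param sigma per-atom displacement standard deviation, Angstrom; scalar or
#'   one value per atom.
#' @param n_frames number of frames.
#' @param dt time step, ps.
#' @param rigid_drift optional list with `rotation_rate` (degrees/ps about the
#'   z axis) and/or `translation_rate` (Angstrom/ps, scalar along x or a
#'   3-vector).
#' @param seed integer seed.
#' @return an [md_trajectory()].
#' @export
simulate_fluctuations <- function(base, sigma = 0.5, n_frames = 100, dt = 1,
                                  rigid_drift = NULL, seed = 1) {
  stopifnot(inherits(base, "md_structure"))
  n <- nrow(base$coords)
  if (n_frames < 1L) stopf("n_frames must be >= 1")
  sigma <- rep_len(sigma, n)
  if (any(sigma < 0)) stopf("sigma must be nonnegative")
  rot_rate <- if (is.null(rigid_drift)) 0 else rigid_drift$rotation_rate %||% 0
  tr <- if (is.null(rigid_drift)) c(0, 0, 0) else {
    v <- rigid_drift$translation_rate %||% 0
    if (length(v) == 1L) c(v, 0, 0) else rep_len(v, 3L)
  }
  coords <- with_op_seed(seed, "simulate_fluctuations", {
    out <- array(NA_real_, c(n_frames, n, 3L))
    for (k in seq_len(n_frames)) {
      t_k <- (k - 1) * dt
      xk <- base$coords + matrix(rnorm(3L * n, sd = rep(sigma, 3L)), n, 3L)
      if (rot_rate != 0) xk <- xk %*% t(rot_z(rot_rate * t_k))
      out[k, , ] <- sweep(xk, 2, tr * t_k, `+`)
    }
    out
  })
  md_trajectory(base$atoms, coords, times = (seq_len(n_frames) - 1) * dt,
                meta = c(base$meta, list(sigma = sigma, seed = seed)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a von Mises pseudo-dihedral trajectory
#'
#' Draws i.i.d. angles from a von Mises distribution with circular mean `mu`
#' (degrees) and concentration `kappa`, mapped to (-180, 180]. Emulates the
#' stationary fluctuation of a helix-orientation torsion about its preferred
#' value; larger `kappa` means a narrower distribution.
#'
#' @param mu circular mean, degrees.
#' @param kappa concentration parameter (> 0).
#' @param n_frames number of frames.
#' @param dt frame spacing, ps.
#' @param seed integer seed.
#' @return a `dihedral_series` (see [compute_pseudo_dihedral()]).
#' @export
simulate_angle_trajectory <- function(mu, kappa, n_frames = 3000, dt = 10,
                                      seed = 1) {
  if (kappa <= 0) stopf("kappa must be positive")
  ang <- with_op_seed(seed, "simulate_angle_trajectory",
                      rvonmises(n_frames, deg2rad(mu), kappa))
  new_dihedral_series((seq_len(n_frames) - 1) * dt, wrap_angle(rad2deg(ang)),
                      dihedral_quadruple())
}

# Best & Fisher (1979) rejection sampler for the von Mises distribution.
rvonmises <- function(n, mu, kappa) {
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- max(16L, ceiling((n - got) * 1.5))
    u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    acc <- which(ok)
    if (length(acc)) {
      take <- acc[seq_len(min(length(acc), n - got))]
      out[got + seq_along(take)] <- sign(u3[take] - 0.5) * acos(f[take]) + mu
      got <- got + length(take)
    }
  }
  out
}

#' Simulate bidirectional nonequilibrium work samples
#'
#' Forward work ~ Normal(dg_true + dissipation, sigma^2); backward work
#' ~ Normal(-(dg_true - dissipation), sigma^2). With
#' `crooks_consistent = TRUE` (the default) sigma is set by the
#' fluctuation-dissipation link sigma^2 = 2 dissipation / beta, so the pair
#' satisfies the Crooks relation exactly in distribution and the Gaussian
#' intersection sits at `dg_true`. `dissipation = 0` gives the delta-function
#' limit (all works equal).
#'
#' @param dg_true planted free-energy difference, kJ/mol.
#' @param dissipation mean dissipated work per direction, kJ/mol (>= 0).
#' @param n_forward,n_backward sample sizes (>= 2).
#' @param temperature temperature, K.
#' @param sigma explicit work standard deviation (kJ/mol); overrides the
#'   Crooks-consistent choice when given.
#' @param crooks_consistent derive sigma from the dissipation? Default `TRUE`
#'   when `sigma` is `NULL`.
#' @param seed integer seed.
#' @return a [work_set()].
#' @export
simulate_work <- function(dg_true, dissipation, n_forward = 100,
                          n_backward = 100, temperature = 298.15,
                          sigma = NULL, crooks_consistent = is.null(sigma),
                          seed = 1) {
  if (dissipation < 0) stopf("dissipation must be nonnegative")
  if (!is.null(sigma) && crooks_consistent)
    stopf("give either sigma or crooks_consistent, not both")
  if (is.null(sigma)) {
    if (!crooks_consistent) stopf("sigma is required when crooks_consistent = FALSE")
    sigma <- sqrt(2 * dissipation * KB_KJ * temperature)
  }
  with_op_seed(seed, "simulate_work", {
    fw <- rnorm(n_forward, mean = dg_true + dissipation, sd = sigma)
    bw <- rnorm(n_backward, mean = -(dg_true - dissipation), sd = sigma)
    work_set(fw, bw, temperature = temperature)
  })
}
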