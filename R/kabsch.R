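#' Weighted least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation R and translation t minimising the weighted RMSD
#' between `mobile` (after the transform) and `reference`. Reflections are
#' excluded: when the optimal orthogonal matrix has determinant -1, the
#' singular direction with the smallest singular value is negated, so the
#' result is always a proper rotation.
#'
#' @param mobile numeric N x 3 matrix (Angstrom).
#' @param reference numeric N x 3 matrix, same N.
#' @param weights nonnegative per-atom weights (default uniform); typically
#'   atomic masses for a mass-weighted fit.
#' @return a `fit_result`: list with `transform` (a `rigid_transform` holding
#'   `rotation` and `translation`), `pre_rmsd`, `post_rmsd` (weighted, in
#'   Angstrom) and `weights`.
#' @export
kabsch_fit <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!identical(dim(mobile), dim(reference)))
    stopf("mobile is %dx%d but reference is %dx%d",
          nrow(mobile), ncol(mobile), nrow(reference), ncol(reference))
  n <- nrow(mobile)
  if (ncol(mobile) != 3L) stopf("coordinates must be N x 3")
  if (n < 3L) stopf("need at least 3 points to define a rigid fit")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0) || sum(weights) <= 0)
    stopf("weights must be nonnegative with positive sum")
  w <- weights / sum(weights)

  cm <- colSums(mobile * w)
  cr <- colSums(reference * w)
  xm <- sweep(mobile, 2, cm)
  xr <- sweep(reference, 2, cr)

  sv_m <- svd(xm * sqrt(w))$d
  if (sv_m[2] < 1e-8 * max(sv_m[1], 1e-12))
    stopf("degenerate geometry: weighted points are (nearly) collinear")

  h <- t(xm * w) %*% xr           # 3x3 weighted covariance
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)   # maps mobile-frame -> reference-frame
  trans <- as.numeric(cr - rot %*% cm)
  tf <- new_rigid_transform(rot, trans)

  pre <- sqrt(sum(w * rowSums((mobile - reference)^2)))
  fitted <- apply_transform(mobile, tf)
  post <- sqrt(sum(w * rowSums((fitted - reference)^2)))
  structure(list(transform = tf, pre_rmsd = pre, post_rmsd = post,
                 weights = weights),
            class = "fit_result")
}

new_rigid_transform <- function(rotation, translation) {
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8)
    stopf("rotation is not orthogonal")
  if (abs(det(rotation) - 1) > 1e-8)
    stopf("rotation is not proper (det != +1)")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Apply a rigid transform
#'
#' @param x an N x 3 matrix, `md_structure`, or `md_trajectory` (applied to
#'   every frame).
#' @param transform a `rigid_transform` from [kabsch_fit()].
#' @return same shape as `x`; lengths and internal angles are preserved.
#' @export
apply_transform <- function(x, transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  r <- transform$rotation; t0 <- transform$translation
  if (is.matrix(x)) {
    return(sweep(x %*% t(r), 2, -t0))
  }
  if (inherits(x, "md_structure")) {
    return(md_structure(x$atoms, apply_transform(x$coords, transform), x$meta))
  }
  if (inherits(x, "md_trajectory")) {
    coords <- x$coords
    for (k in seq_len(n_frames(x)))
      coords[k, , ] <- apply_transform(traj_frame(x, k), transform)
    return(md_trajectory(x$atoms, coords, x$times, x$meta))
  }
  stopf("cannot apply a transform to an object of class %s", class(x)[1])
}

#' Invert a rigid transform
#' @param transform a `rigid_transform`.
#' @return the inverse `rigid_transform`.
#' @export
invert_transform <- function(transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  rinv <- t(transform$rotation)
  new_rigid_transform(rinv, -as.numeric(rinv %*% transform$translation))
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> pre = %.4f A, post = %.4f A\n", x$pre_rmsd, x$post_rmsd))
  invisible(x)
}
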