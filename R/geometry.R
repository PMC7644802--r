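# Rigid-body transform algebra.
#
# A rigid transform pairs a proper rotation (3x3, det = +1) with a
# translation in Angstrom.  All placement math in the package reduces to
# composing these: a child module's world pose is parent_world %then%
# pair_transform.  Reflections are rejected outright -- a mirrored module
# is not a physically buildable protein placement.

#' Numerical tolerance for orthonormality / identity checks
#'
#' Fixed at 1e-9, a safe margin above double-precision rounding for the
#' handful of matrix products a deep design chain accumulates.
#' @keywords internal
RT_TOL <- 1e-9

#' Create a rigid transform
#'
#' @param rot 3x3 proper rotation matrix (orthonormal, det = +1).
#' @param tran numeric translation vector of length 3, in Angstrom.
#' @param check validate the rotation (default `TRUE`).  Internal callers
#'   that compose already-validated transforms may skip the check.
#' @return an object of class `rigid_transform` with fields `rot`, `tran`.
#' @examples
#' rt(diag(3), c(1, 0, 0))
#' @export
rt <- function(rot, tran = c(0, 0, 0), check = TRUE) {
  rot <- matrix(as.numeric(rot), 3L, 3L)
  tran <- as.numeric(tran)
  if (length(tran) != 3L || anyNA(tran) || any(!is.finite(tran))) {
    stop_modcad("translation must be a finite 3-vector", "invalid_transform")
  }
  if (check) assert_rotation(rot)
  structure(list(rot = rot, tran = tran), class = "rigid_transform")
}

#' @rdname rt
#' @export
rt_identity <- function() rt(diag(3), c(0, 0, 0), check = FALSE)

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\n")
  cat("rotation:\n")
  print(round(x$rot, 6))
  cat("translation (A):", paste(signif(x$tran, 6), collapse = ", "), "\n")
  invisible(x)
}

assert_rotation <- function(rot) {
  if (!is.matrix(rot) || any(dim(rot) != 3L) || anyNA(rot) ||
      any(!is.finite(rot))) {
    stop_modcad("rotation must be a finite 3x3 matrix", "invalid_transform")
  }
  if (max(abs(crossprod(rot) - diag(3))) > RT_TOL) {
    stop_modcad("rotation matrix is not orthonormal (within 1e-9)",
                "invalid_transform")
  }
  if (abs(det(rot) - 1) > RT_TOL) {
    stop_modcad(
      "rotation has det != +1; reflections are not valid placements",
      "invalid_transform")
  }
  invisible(rot)
}

is_rigid_transform <- function(x) inherits(x, "rigid_transform")

#' Compose two rigid transforms
#'
#' `rt_compose(outer, inner)` returns the transform whose action equals
#' applying `inner` first, then `outer` (matrix convention
#' `p -> R_o (R_i p + t_i) + t_o`).
#'
#' @param outer,inner `rigid_transform` objects.
#' @return a `rigid_transform`.
#' @export
rt_compose <- function(outer, inner) {
  if (!is_rigid_transform(outer) || !is_rigid_transform(inner)) {
    stop_modcad("rt_compose expects rigid_transform inputs",
                "invalid_transform")
  }
  assert_rotation(outer$rot)
  assert_rotation(inner$rot)
  rt(outer$rot %*% inner$rot,
     as.numeric(outer$rot %*% inner$tran) + outer$tran,
     check = FALSE)
}

#' Invert a rigid transform
#'
#' @param t a `rigid_transform`.
#' @return the inverse transform: `rt_compose(t, rt_invert(t))` is the
#'   identity to within 1e-9.
#' @export
rt_invert <- function(t) {
  if (!is_rigid_transform(t)) {
    stop_modcad("rt_invert expects a rigid_transform", "invalid_transform")
  }
  assert_rotation(t$rot)
  rinv <- t(t$rot)
  rt(rinv, as.numeric(-rinv %*% t$tran), check = FALSE)
}

#' Apply a rigid transform to a point set
#'
#' Points are rows of an n x 3 matrix; row names (labels), if present, are
#' preserved.  An empty point set maps to an empty point set.
#'
#' @param t a `rigid_transform`.
#' @param pts numeric matrix with 3 columns (Angstrom), or a length-3
#'   vector treated as a single point.
#' @return transformed coordinates, same shape and labels as the input.
#' @export
rt_apply <- function(t, pts) {
  if (!is_rigid_transform(t)) {
    stop_modcad("rt_apply expects a rigid_transform", "invalid_transform")
  }
  single <- is.null(dim(pts))
  if (single) pts <- matrix(as.numeric(pts), 1L, 3L)
  pts <- as.matrix(pts)
  if (ncol(pts) != 3L) stop_modcad("points must have 3 columns", "bad_points")
  if (nrow(pts) == 0L) return(pts)
  out <- pts %*% t(t$rot)
  out <- sweep(out, 2L, t$tran, "+")
  dimnames(out) <- dimnames(pts)
  if (single) as.numeric(out) else out
}

# Unvalidated Kabsch core: optimal proper rotation + translation mapping
# `mobile` onto `target` in the least-squares sense.  Works for any n >= 1
# (rotation is the identity-completed optimum for degenerate inputs); the
# public superpose() adds the strict preconditions.
kabsch <- function(mobile, target) {
  n <- nrow(mobile)
  mc <- colMeans(mobile)
  tc <- colMeans(target)
  if (n == 1L) {
    tr <- rt(diag(3), tc - mc, check = FALSE)
  } else {
    h <- crossprod(sweep(mobile, 2L, mc), sweep(target, 2L, tc))
    sv <- svd(h)
    d <- sign(det(sv$v %*% t(sv$u)))
    if (d == 0) d <- 1
    rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
    # re-orthonormalize to kill rounding drift before validation downstream
    svr <- svd(rot)
    rot <- svr$u %*% t(svr$v)
    tr <- rt(rot, tc - as.numeric(rot %*% mc), check = FALSE)
  }
  moved <- rt_apply(tr, mobile)
  rmsd <- sqrt(mean(rowSums((moved - target)^2)))
  list(transform = tr, rmsd = rmsd)
}

#' Least-squares superposition of two point sets (Kabsch)
#'
#' Finds the rigid transform minimizing the RMSD between `mobile` (after
#' transformation) and `target`, with point-to-point correspondence by row.
#'
#' @param mobile,target n x 3 numeric matrices, n >= 3, rows corresponding.
#' @return list with `transform` (a `rigid_transform`) and `rmsd` (Angstrom).
#' @export
superpose <- function(mobile, target) {
  mobile <- as.matrix(mobile)
  target <- as.matrix(target)
  if (ncol(mobile) != 3L || ncol(target) != 3L) {
    stop_modcad("point sets must have 3 columns", "bad_points")
  }
  if (nrow(mobile) != nrow(target)) {
    stop_modcad("point sets differ in length", "bad_points")
  }
  if (nrow(mobile) < 3L) {
    stop_modcad("superposition needs at least 3 points", "bad_points")
  }
  if (is_collinear(mobile) || is_collinear(target)) {
    stop_modcad("superposition of collinear points is degenerate",
                "degenerate_geometry")
  }
  kabsch(mobile, target)
}

is_collinear <- function(pts, tol = 1e-9) {
  c0 <- sweep(pts, 2L, colMeans(pts))
  s <- svd(c0, nu = 0, nv = 0)$d
  s[2] <= tol * max(s[1], 1)
}

#' Elementary rotations
#'
#' Right-handed rotations about the coordinate axes, angle in degrees.
#' @param deg angle in degrees.
#' @return a 3x3 rotation matrix.
#' @export
rot_x <- function(deg) {
  a <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3L, 3L)
}

#' @rdname rot_x
#' @export
rot_y <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3L, 3L)
}

#' @rdname rot_x
#' @export
rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3L, 3L)
}

# uniform random rotation (Arvo 1992), used by tests and random placements
random_rotation <- function() {
  x <- stats::runif(3)
  th <- 2 * pi * x[1]
  ph <- 2 * pi * x[2]
  z <- x[3]
  v <- c(cos(ph) * sqrt(z), sin(ph) * sqrt(z), sqrt(1 - z))
  rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  h <- diag(3) - 2 * tcrossprod(v)
  -h %*% rz
}

rt_equal <- function(a, b, tol = RT_TOL) {
  max(abs(a$rot - b$rot)) <= tol && max(abs(a$tran - b$tran)) <= tol
}
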