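#' Rotation matrix from Euler angles
#'
#' Builds a proper rotation matrix from three Euler angles using the
#' intrinsic Z-Y-Z convention, \eqn{R = R_z(\alpha) R_y(\beta) R_z(\gamma)}.
#' This convention is surjective onto SO(3) (any rotation is reached for
#' \eqn{\alpha,\gamma \in [0,2\pi)}, \eqn{\beta \in [0,\pi]}); since the
#' per-measurement orientations are nuisance parameters with an isotropic
#' prior, the choice of convention is immaterial as long as it is used
#' consistently, which it is throughout the package (sampler and simulator).
#'
#' @param angles numeric vector of three finite angles (radians).
#' @return a 3x3 orthonormal matrix with determinant +1.
#' @examples
#' euler_to_rotation(c(0, 0, 0))           # identity
#' R <- euler_to_rotation(c(0.3, 1.1, -2))
#' crossprod(R)                            # identity to rounding
#' @export
euler_to_rotation <- function(angles) {
  if (length(angles) != 3L || !is.numeric(angles) || any(!is.finite(angles)))
    stop("'angles' must be three finite numeric Euler angles (radians)")
  rz <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  ry <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
  rz(angles[1]) %*% ry(angles[2]) %*% rz(angles[3])
}

#' Euler angles of a rotation matrix
#'
#' Inverse of [euler_to_rotation()] (intrinsic Z-Y-Z). The angles are not
#' unique at the gimbal-lock boundary (beta = 0 or pi); the returned triple
#' always reproduces the matrix.
#'
#' @param R a 3x3 proper rotation matrix.
#' @return numeric vector of three angles (radians).
#' @export
rotation_to_euler <- function(R) {
  stopifnot(is.matrix(R), all(dim(R) == c(3L, 3L)))
  beta <- acos(max(-1, min(1, R[3, 3])))
  if (sin(beta) > 1e-10) {
    alpha <- atan2(R[2, 3], R[1, 3])
    gamma <- atan2(R[3, 2], -R[3, 1])
  } else {
    # gimbal lock: only alpha + gamma (beta ~ 0) or alpha - gamma matters
    alpha <- atan2(R[2, 1], R[1, 1])
    gamma <- 0
    if (R[3, 3] < 0) alpha <- -atan2(R[2, 1], R[1, 1])
  }
  c(alpha, beta, gamma)
}

## ---- quaternion helpers (internal) ----------------------------------------
## Rotations are stored row-wise as unit quaternions (w, x, y, z), one row per
## measurement, so that whole-population updates vectorize.

# n uniform (Haar) random rotations as unit quaternions: normalized 4D normals
runif_quat <- function(n) {
  q <- matrix(stats::rnorm(4 * n), n, 4)
  q / sqrt(rowSums(q^2))
}

# small random rotation quaternions: uniform axis, angle ~ N(0, step^2)
small_quat <- function(n, step) {
  ax <- matrix(stats::rnorm(3 * n), n, 3)
  ax <- ax / sqrt(rowSums(ax^2))
  ang <- stats::rnorm(n, 0, step)
  cbind(cos(ang / 2), sin(ang / 2) * ax)
}

# Hamilton product a*b, rows paired
quat_mult <- function(a, b) {
  cbind(a[, 1] * b[, 1] - a[, 2] * b[, 2] - a[, 3] * b[, 3] - a[, 4] * b[, 4],
        a[, 1] * b[, 2] + a[, 2] * b[, 1] + a[, 3] * b[, 4] - a[, 4] * b[, 3],
        a[, 1] * b[, 3] - a[, 2] * b[, 4] + a[, 3] * b[, 1] + a[, 4] * b[, 2],
        a[, 1] * b[, 4] + a[, 2] * b[, 3] - a[, 3] * b[, 2] + a[, 4] * b[, 1])
}

# rotate one fixed 3-vector v by every quaternion row: returns n x 3
quat_rotate_vec <- function(q, v) {
  # u = q_vec x v ; out = v + 2 (w u + q_vec x u)
  ux <- q[, 3] * v[3] - q[, 4] * v[2]
  uy <- q[, 4] * v[1] - q[, 2] * v[3]
  uz <- q[, 2] * v[2] - q[, 3] * v[1]
  cbind(v[1] + 2 * (q[, 1] * ux + q[, 3] * uz - q[, 4] * uy),
        v[2] + 2 * (q[, 1] * uy + q[, 4] * ux - q[, 2] * uz),
        v[3] + 2 * (q[, 1] * uz + q[, 2] * uy - q[, 3] * ux))
}

# rotate per-row vectors V (n x 3) by per-row quaternions q (n x 4)
quat_rotate_rows <- function(q, V) {
  ux <- q[, 3] * V[, 3] - q[, 4] * V[, 2]
  uy <- q[, 4] * V[, 1] - q[, 2] * V[, 3]
  uz <- q[, 2] * V[, 2] - q[, 3] * V[, 1]
  cbind(V[, 1] + 2 * (q[, 1] * ux + q[, 3] * uz - q[, 4] * uy),
        V[, 2] + 2 * (q[, 1] * uy + q[, 4] * ux - q[, 2] * uz),
        V[, 3] + 2 * (q[, 1] * uz + q[, 2] * uy - q[, 3] * ux))
}

quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

matrix_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] >= R[2, 2] && R[1, 1] >= R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] >= R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  q / sqrt(sum(q^2))
}

# Kabsch: proper rotation R minimizing ||R A - B||_F over rows of centered
# A, B (k x 3). Returns 3x3 matrix with det +1.
kabsch_rotation <- function(A, B) {
  H <- crossprod(A, B)                 # 3x3
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  sv$v %*% D %*% t(sv$u)
}

#' Apply a rigid-body perspective to a polygon template
#'
#' Maps canonical template node positions to true positions for one
#' measurement: node j goes to \eqn{R (X_j - X_1) + X_1 + T}, i.e. the
#' rotation is centred on node 1 and the translation positions node 1.
#'
#' @param template a `polygon_template` (or a J x 3 matrix of canonical
#'   positions).
#' @param translation 3-vector (nm).
#' @param angles three Euler angles (radians), ignored when `rotation` given.
#' @param rotation optional 3x3 rotation matrix, overrides `angles`.
#' @return J x 3 matrix of true positions (nm).
#' @export
apply_perspective <- function(template, translation = c(0, 0, 0),
                              angles = c(0, 0, 0), rotation = NULL) {
  X <- if (inherits(template, "polygon_template")) template$positions else as.matrix(template)
  if (is.null(rotation)) rotation <- euler_to_rotation(angles)
  if (length(translation) != 3L || any(!is.finite(translation)))
    stop("'translation' must be a finite 3-vector")
  X1 <- X[1, ]
  Xc <- sweep(X, 2, X1)
  sweep(Xc %*% t(rotation), 2, X1 + translation, "+")
}

#' Reduce arbitrary node positions to canonical template plus perspective
#'
#' Inverse of [apply_perspective()]: factors a J x 3 configuration into a
#' canonical-frame template (node 1 at the origin, node 2 on the
#' non-negative x-axis, node 3 in the x-y plane with non-negative y) and the
#' rigid motion mapping the template back onto the input. Degenerate inputs
#' are handled by convention rather than error: coincident nodes 1 and 2
#' leave the frame orientation free (identity continuation is used), and
#' collinear nodes 1-2-3 give y3 = 0.
#'
#' @param positions J x 3 matrix of node positions (nm), J >= 2.
#' @return list with `template` (a [polygon_template()]), `translation` and
#'   `angles` such that `apply_perspective(template, translation, angles)`
#'   reproduces `positions`.
#' @export
standardize_polygon <- function(positions) {
  P <- as.matrix(positions)
  if (ncol(P) != 3L || nrow(P) < 2L) stop("'positions' must be a J x 3 matrix with J >= 2")
  if (any(!is.finite(P))) stop("'positions' must be finite")
  J <- nrow(P)
  t0 <- P[1, ]
  Pc <- sweep(P, 2, t0)
  v1 <- Pc[2, ]
  n1 <- sqrt(sum(v1^2))
  e1 <- if (n1 > 1e-12) v1 / n1 else c(1, 0, 0)
  # second basis vector from node 3 (or any later non-collinear node)
  e2 <- NULL
  j <- 3L
  while (is.null(e2) && j <= J) {
    w <- Pc[j, ] - sum(Pc[j, ] * e1) * e1
    nw <- sqrt(sum(w^2))
    if (nw > 1e-10) e2 <- w / nw
    j <- j + 1L
  }
  if (is.null(e2)) {              # collinear (or J == 2): pick any perpendicular
    a <- if (abs(e1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    w <- a - sum(a * e1) * e1
    e2 <- w / sqrt(sum(w^2))
  }
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  R <- cbind(e1, e2, e3)          # maps template coords -> original frame
  X <- Pc %*% R                   # coordinates in the canonical basis
  X[1, ] <- 0
  X[abs(X) < 1e-12] <- 0
  tpl <- polygon_template(X)
  list(template = tpl, translation = t0, angles = rotation_to_euler(R),
       rotation = R)
}

#' Internal angles of a triangle template
#'
#' Internal angle at each node of a triangle, computed from the side
#' lengths by the law of cosines. Angles are reported in degrees and sum to
#' 180 for any non-degenerate triangle. A node whose two adjacent sides
#' include a zero length has an undefined angle and is returned as `NA`
#' (with a warning).
#'
#' @param x a `polygon_template` with J = 3, a 3 x 3 position matrix, or a
#'   numeric vector of the three side lengths `c(l12, l13, l23)`.
#' @return numeric vector of three angles in degrees (at nodes 1, 2, 3).
#' @export
internal_angles <- function(x) {
  l <- if (is.numeric(x) && is.null(dim(x)) && length(x) == 3L) x
       else edge_lengths(x)[c("l12", "l13", "l23")]
  l <- unname(l)
  if (any(l < 0) || any(!is.finite(l))) stop("side lengths must be finite and non-negative")
  ang <- function(a, b, c) {        # angle between sides a, b (opposite c)
    if (a == 0 || b == 0) return(NA_real_)
    acos(max(-1, min(1, (a^2 + b^2 - c^2) / (2 * a * b)))) * 180 / pi
  }
  out <- c(ang(l[1], l[2], l[3]),   # at node 1 between 1-2 and 1-3
           ang(l[1], l[3], l[2]),   # at node 2 between 2-1 and 2-3
           ang(l[2], l[3], l[1]))   # at node 3 between 3-1 and 3-2
  if (anyNA(out)) warning("zero-length adjacent side: angle undefined at some node")
  names(out) <- c("angle1", "angle2", "angle3")
  out
}

#' Does a triple of lengths satisfy the triangle inequality?
#'
#' TRUE iff each length is no greater than the sum of the other two;
#' equality (a degenerate, collinear triangle) counts as satisfied. The
#' complementary event, used as the violation statistic for
#' independence-resampled pair-wise posteriors, is the strict violation.
#'
#' @param lengths numeric vector of three non-negative lengths, or a matrix
#'   with three columns (one triple per row).
#' @return logical (vector).
#' @export
triangle_inequality_holds <- function(lengths) {
  L <- if (is.null(dim(lengths))) matrix(lengths, ncol = 3) else as.matrix(lengths)
  if (ncol(L) != 3L || any(L < 0)) stop("'lengths' must be three non-negative values per triple")
  s <- rowSums(L)
  (L[, 1] <= s - L[, 1]) & (L[, 2] <= s - L[, 2]) & (L[, 3] <= s - L[, 3])
}
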