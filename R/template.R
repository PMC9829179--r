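#' Canonical polygon template
#'
#' The template is the shared architecture being inferred: J fluorophore
#' node positions in a canonical frame with node 1 at the origin, node 2 on
#' the non-negative x-axis, and node 3 (if present) in the x-y plane with
#' non-negative y. All coordinates are nanometres.
#'
#' @param positions J x 3 numeric matrix of canonical node positions.
#' @return an object of class `polygon_template` with elements `positions`
#'   (J x 3) and `J`.
#' @seealso [triangle_template()] to build a triangle from its side lengths,
#'   [standardize_polygon()] to canonicalize arbitrary positions.
#' @export
polygon_template <- function(positions) {
  X <- as.matrix(positions)
  if (ncol(X) != 3L) stop("'positions' must have 3 columns (x, y, z in nm)")
  J <- nrow(X)
  if (J < 2L) stop("a polygon template needs J >= 2 nodes")
  if (any(!is.finite(X))) stop("template positions must be finite")
  if (any(abs(X[1, ]) > 1e-9)) stop("canonical frame requires X1 = (0,0,0)")
  if (abs(X[2, 2]) > 1e-9 || abs(X[2, 3]) > 1e-9 || X[2, 1] < -1e-9)
    stop("canonical frame requires X2 on the non-negative x-axis")
  if (J >= 3L && (abs(X[3, 3]) > 1e-9 || X[3, 2] < -1e-9))
    stop("canonical frame requires X3 in the x-y plane with y >= 0")
  X[1, ] <- 0
  X[2, 2:3] <- 0
  X[2, 1] <- max(X[2, 1], 0)
  if (J >= 3L) { X[3, 3] <- 0; X[3, 2] <- max(X[3, 2], 0) }
  dimnames(X) <- list(paste0("node", seq_len(J)), c("x", "y", "z"))
  structure(list(positions = X, J = J), class = "polygon_template")
}

#' Triangle template from side lengths
#'
#' Builds the canonical triangle with `|X2-X1| = l12`, `|X3-X1| = l13`,
#' `|X3-X2| = l23`. The lengths must satisfy the triangle inequality
#' (boundary allowed, giving a collinear template).
#'
#' @param l12,l13,l23 non-negative side lengths (nm).
#' @return a `polygon_template` with J = 3.
#' @examples
#' tri <- triangle_template(50, 60, 15)
#' edge_lengths(tri)
#' internal_angles(tri)
#' @export
triangle_template <- function(l12, l13, l23) {
  l <- c(l12, l13, l23)
  if (any(l < 0) || any(!is.finite(l))) stop("side lengths must be finite and non-negative")
  if (!triangle_inequality_holds(l)) stop("side lengths violate the triangle inequality")
  x2 <- l12
  if (l12 > 0) {
    x3 <- (l12^2 + l13^2 - l23^2) / (2 * l12)
    y3sq <- l13^2 - x3^2
    y3 <- sqrt(max(y3sq, 0))
  } else {
    x3 <- l13
    y3 <- 0
  }
  polygon_template(rbind(c(0, 0, 0), c(x2, 0, 0), c(x3, y3, 0)))
}

#' Pairwise edge lengths of a polygon
#'
#' @param x a `polygon_template` or a J x 3 position matrix.
#' @return named numeric vector of lengths `l_ij` for all i < j (nm).
#' @export
edge_lengths <- function(x) {
  X <- if (inherits(x, "polygon_template")) x$positions else as.matrix(x)
  J <- nrow(X)
  idx <- utils::combn(J, 2)
  out <- apply(idx, 2, function(ij) sqrt(sum((X[ij[2], ] - X[ij[1], ])^2)))
  names(out) <- apply(idx, 2, function(ij) paste0("l", ij[1], ij[2]))
  out
}

#' @export
print.polygon_template <- function(x, ...) {
  cat("Polygon template (canonical frame), J =", x$J, "nodes\n")
  print(round(x$positions, 3))
  cat("Edge lengths (nm):\n")
  print(round(edge_lengths(x), 2))
  invisible(x)
}

# free canonical coordinates of a template as a flat vector (used by the
# template random-walk sampler): x2 | x3,y3 | full rows for j >= 4
template_free_coords <- function(tpl) {
  X <- tpl$positions
  J <- tpl$J
  co <- X[2, 1]
  if (J >= 3) co <- c(co, X[3, 1:2])
  if (J >= 4) co <- c(co, t(X[4:J, , drop = FALSE]))
  co
}

template_from_free_coords <- function(co, J) {
  X <- matrix(0, J, 3)
  X[2, 1] <- co[1]
  k <- 1L
  if (J >= 3) { X[3, 1:2] <- co[2:3]; k <- 3L }
  if (J >= 4) X[4:J, ] <- matrix(co[(k + 1):length(co)], J - 3, 3, byrow = TRUE)
  polygon_template(X)
}

# TRUE when free coords lie in the canonical chart support
free_coords_valid <- function(co, J) {
  if (co[1] < 0) return(FALSE)
  if (J >= 3 && co[3] < 0) return(FALSE)
  TRUE
}
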