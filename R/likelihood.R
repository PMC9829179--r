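## Internal representation: a measurement set is held as a list of J
## matrices Y[[j]] (N x 3), plus measurement ids and subset ids, so that
## per-fluorophore operations vectorize over measurements.

as_measurement_arrays <- function(data) {
  if (!all(c("measurement_id", "fluorophore", "x_nm", "y_nm", "z_nm") %in% names(data)))
    stop("data must have columns measurement_id, fluorophore, x_nm, y_nm, z_nm")
  if (any(!is.finite(data$x_nm)) || any(!is.finite(data$y_nm)) || any(!is.finite(data$z_nm)))
    stop("non-finite coordinates in data")
  J <- max(data$fluorophore)
  ids <- sort(unique(data$measurement_id))
  N <- length(ids)
  if (nrow(data) != N * J)
    stop("every measurement must have exactly one row per fluorophore 1..J")
  data <- data[order(data$measurement_id, data$fluorophore), ]
  if (!identical(as.integer(data$fluorophore), rep(seq_len(J), N)))
    stop("every measurement must have exactly one row per fluorophore 1..J")
  Y <- vector("list", J)
  for (j in seq_len(J)) {
    dj <- data[data$fluorophore == j, ]
    Y[[j]] <- cbind(dj$x_nm, dj$y_nm, dj$z_nm)
  }
  subset_id <- if ("subset_id" %in% names(data))
    data$subset_id[data$fluorophore == 1] else rep("all", N)
  list(Y = Y, ids = ids, subset_id = subset_id, N = N, J = J)
}

# per-measurement log-likelihood contributions for one state's template and
# errors; q is N x 4 quaternions, Tn is N x 3.
# sig: list(xy = length-J, z = length-J). Returns length-N vector.
loglik_per_measurement <- function(Y, X, q, Tn, sig, rows = NULL) {
  J <- nrow(X)
  if (is.null(rows)) rows <- seq_len(nrow(q))
  qs <- q[rows, , drop = FALSE]
  Ts <- Tn[rows, , drop = FALSE]
  out <- numeric(length(rows))
  for (j in seq_len(J)) {
    pred <- quat_rotate_vec(qs, X[j, ]) + Ts
    r <- Y[[j]][rows, , drop = FALSE] - pred
    pxy <- 1 / sig$xy[j]^2; pz <- 1 / sig$z[j]^2
    out <- out +
      (-2 * log(sig$xy[j]) - log(sig$z[j]) - 1.5 * log(2 * pi)) -
      0.5 * ((r[, 1]^2 + r[, 2]^2) * pxy + r[, 3]^2 * pz)
  }
  out
}

#' Log-likelihood of the single-state polygon model
#'
#' Sum over fluorophores j and measurements n of the anisotropic Gaussian
#' log-density of the measured position about the perspective-mapped
#' template position \eqn{R^n (X_j - X_1) + X_1 + T^n}:
#' \deqn{\sum_{j,n} \tfrac12 \log\det\tau_j - \tfrac32\log 2\pi
#'       - \tfrac12 \|X_j^n - \tilde X_j^n\|^2_{\tau_j},}
#' with \eqn{\tau_j = \mathrm{diag}(\sigma_{j;xy}^{-2}, \sigma_{j;xy}^{-2},
#' \sigma_{j;z}^{-2})}.
#'
#' @param data a `polygon_data` data frame.
#' @param template a `polygon_template`.
#' @param rotations list of 3x3 rotation matrices (or N x 4 quaternion
#'   matrix), one per measurement.
#' @param translations N x 3 matrix.
#' @param sigma_xy,sigma_z length-J vectors of positive errors (nm).
#' @return scalar log-likelihood.
#' @export
polygon_loglik <- function(data, template, rotations, translations,
                           sigma_xy, sigma_z) {
  ms <- as_measurement_arrays(data)
  if (any(sigma_xy <= 0) || any(sigma_z <= 0)) stop("sigma values must be positive")
  if (length(sigma_xy) != ms$J || length(sigma_z) != ms$J)
    stop("need one sigma_xy and sigma_z per fluorophore")
  q <- if (is.matrix(rotations) && ncol(rotations) == 4) rotations
       else do.call(rbind, lapply(rotations, matrix_to_quat))
  Tn <- as.matrix(translations)
  if (nrow(q) != ms$N || nrow(Tn) != ms$N) stop("one rotation and translation per measurement required")
  X <- if (inherits(template, "polygon_template")) template$positions else as.matrix(template)
  sum(loglik_per_measurement(ms$Y, X, q, Tn, list(xy = sigma_xy, z = sigma_z)))
}

#' Log prior density of the template under the flat-length construction
#'
#' The reference prior on the template is chosen so that the marginal of
#' each edge length is (approximately) flat. For a triangle this is exact:
#' the change of variables from the canonical coordinates (x2, x3, y3) to
#' the lengths (l12, l13, l23) has Jacobian l12 * y3 / (l13 * l23), so the
#' density proportional to that factor makes the joint length distribution
#' uniform on the triangle-inequality simplex. A cut-off `l_max` on every
#' length makes the prior proper. For J = 2 the single canonical
#' coordinate is the length itself and the prior is flat. For J > 3 the
#' pairwise correction factor prod(1/l_ij) is applied; this reproduces the
#' flat-length property only approximately and is flagged as such.
#'
#' @param template a `polygon_template`.
#' @param l_max length cut-off (nm), default 1000.
#' @return log density up to a constant; `-Inf` on degenerate or
#'   out-of-support templates.
#' @export
template_log_prior <- function(template, l_max = 1000) {
  X <- template$positions
  J <- template$J
  l <- edge_lengths(template)
  if (any(l > l_max)) return(-Inf)
  if (J == 2L) return(0)
  if (J == 3L) {
    l12 <- l[["l12"]]; l13 <- l[["l13"]]; l23 <- l[["l23"]]
    y3 <- X[3, 2]
    if (l12 <= 0 || l13 <= 0 || l23 <= 0 || y3 <= 0) return(-Inf)
    return(log(l12) + log(y3) - log(l13) - log(l23))
  }
  if (any(l <= 0)) return(-Inf)
  -sum(log(l))
}

# direct sampler from the J=3 flat-length template prior (used by tests and
# for initialization sanity checks): draw lengths uniform on the
# triangle-inequality simplex within [0, l_max], rejecting invalid triples.
sample_template_prior <- function(n, l_max = 1000) {
  out <- vector("list", n)
  k <- 0L
  while (k < n) {
    m <- (n - k) * 2L
    L <- matrix(stats::runif(3L * m, 0, l_max), m, 3)
    ok <- triangle_inequality_holds(L)
    L <- L[ok, , drop = FALSE]
    take <- min(nrow(L), n - k)
    for (i in seq_len(take))
      out[[k + i]] <- triangle_template(L[i, 1], L[i, 2], L[i, 3])
    k <- k + take
  }
  out
}
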