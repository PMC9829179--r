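#' Simulation design for multi-fluorophore polygon data
#'
#' Describes the generative model the inference assumes: Z polygon
#' templates (conformational states), per-state per-fluorophore anisotropic
#' localization errors, and one or more measurement subsets each with its
#' own state-proportion vector (or a pure-state flag). Each simulated
#' measurement draws a state from its subset's proportions, a uniform
#' (Haar) random rotation, a translation uniform in a cube, and adds
#' independent Gaussian noise per fluorophore with covariance
#' diag(sigma_xy^2, sigma_xy^2, sigma_z^2).
#'
#' @param templates a `polygon_template` or list of Z of them (one per
#'   state). All states must share the same J.
#' @param sigma_xy,sigma_z per-fluorophore lateral / axial localization
#'   error (nm): a length-J vector (shared across states) or a Z x J matrix.
#' @param subsets list of subset descriptions, each a list with elements
#'   `name`, `N` (measurements), and either `proportions` (length-Z simplex
#'   weights) or `state` (integer: pure, state-informing subset). A single
#'   `list(name=, N=)` with Z = 1 needs neither.
#' @return an object of class `polygon_design`.
#' @seealso [design_preset()] for the named simulation regimes,
#'   [simulate_polygons()] to draw data.
#' @export
polygon_design <- function(templates, sigma_xy, sigma_z, subsets) {
  if (inherits(templates, "polygon_template")) templates <- list(templates)
  Z <- length(templates)
  J <- templates[[1]]$J
  for (t in templates) if (t$J != J) stop("all state templates must share J")
  sxy <- if (is.matrix(sigma_xy)) sigma_xy else matrix(sigma_xy, Z, J, byrow = TRUE)
  sz  <- if (is.matrix(sigma_z))  sigma_z  else matrix(sigma_z,  Z, J, byrow = TRUE)
  if (!all(dim(sxy) == c(Z, J)) || !all(dim(sz) == c(Z, J)))
    stop("sigma_xy / sigma_z must be length J or Z x J")
  if (any(sxy <= 0) || any(sz <= 0)) stop("all sigma values must be strictly positive")
  if (missing(subsets)) stop("'subsets' is required")
  if (!is.null(subsets$N)) subsets <- list(subsets)   # single subset shorthand
  subsets <- lapply(subsets, function(s) {
    if (is.null(s$name)) stop("each subset needs a 'name'")
    if (is.null(s$N) || s$N < 1) stop("each subset needs N >= 1")
    if (!is.null(s$state)) {
      if (!(s$state %in% seq_len(Z))) stop("pure-state flag outside 1..Z")
      s$proportions <- as.numeric(seq_len(Z) == s$state)
    } else if (is.null(s$proportions)) {
      if (Z == 1) s$proportions <- 1
      else stop("mixed subsets need 'proportions'")
    }
    p <- s$proportions
    if (length(p) != Z || any(p < 0) || abs(sum(p) - 1) > 1e-8)
      stop("subset proportions must be a length-Z simplex vector")
    s
  })
  structure(list(templates = templates, sigma_xy = sxy, sigma_z = sz,
                 subsets = subsets, Z = Z, J = J),
            class = "polygon_design")
}

#' @export
print.polygon_design <- function(x, ...) {
  cat("Polygon simulation design: Z =", x$Z, "state(s), J =", x$J, "fluorophores\n")
  for (z in seq_len(x$Z)) {
    cat(sprintf("state %d lengths (nm): %s; sigma_xy: %s; sigma_z: %s\n", z,
                paste(round(edge_lengths(x$templates[[z]]), 1), collapse = ", "),
                paste(x$sigma_xy[z, ], collapse = ", "),
                paste(x$sigma_z[z, ], collapse = ", ")))
  }
  for (s in x$subsets)
    cat(sprintf("subset '%s': N = %d, proportions = (%s)%s\n", s$name, s$N,
                paste(round(s$proportions, 3), collapse = ", "),
                if (!is.null(s$state)) paste0(" [pure state ", s$state, "]") else ""))
  invisible(x)
}

#' Named simulation regimes
#'
#' Preset designs for the single-state regimes `"example_1_1"` ...
#' `"example_1_6"` (N = 400 triangles; 1.1 has isotropic per-fluorophore
#' errors 15, 15, 25 nm, 1.2-1.6 anisotropic errors (10,20), (10,20),
#' (15,30) nm with side lengths (50,60,15), (45,60,15), (60,60,15),
#' (15,15,15) and (60,60,0) respectively) and the two-state regimes
#' `"example_2_1"` ... `"example_2_6"` (state 1 sides (45,85,45), state 2
#' sides (50,60,15), minority proportion p2 = 0, 0.1, ..., 0.5; a mixed
#' subset of N = 600 plus a pure state-2 informing subset of
#' (1 - p2) * 600 measurements).
#'
#' @param name preset name, e.g. `"example_1_2"`.
#' @return a `polygon_design`.
#' @export
design_preset <- function(name) {
  aniso_xy <- c(10, 10, 15); aniso_z <- c(20, 20, 30)
  single <- function(l, sxy, sz)
    polygon_design(triangle_template(l[1], l[2], l[3]), sxy, sz,
                   subsets = list(name = "sim", N = 400))
  two_state <- function(p2) {
    n_inf <- round((1 - p2) * 600)
    polygon_design(list(triangle_template(45, 85, 45), triangle_template(50, 60, 15)),
                   rbind(aniso_xy, aniso_xy), rbind(aniso_z, aniso_z),
                   subsets = list(
                     list(name = "mixed", N = 600, proportions = c(1 - p2, p2)),
                     list(name = "informing", N = n_inf, state = 2L)))
  }
  switch(name,
    example_1_1 = single(c(50, 60, 15), c(15, 15, 25), c(15, 15, 25)),
    example_1_2 = single(c(50, 60, 15), aniso_xy, aniso_z),
    example_1_3 = single(c(45, 60, 15), aniso_xy, aniso_z),
    example_1_4 = single(c(60, 60, 15), aniso_xy, aniso_z),
    example_1_5 = single(c(15, 15, 15), aniso_xy, aniso_z),
    example_1_6 = single(c(60, 60, 0),  aniso_xy, aniso_z),
    example_2_1 = two_state(0.0),
    example_2_2 = two_state(0.1),
    example_2_3 = two_state(0.2),
    example_2_4 = two_state(0.3),
    example_2_5 = two_state(0.4),
    example_2_6 = two_state(0.5),
    stop("unknown preset '", name, "'")
  )
}

#' Simulate spot-centre measurements from a design
#'
#' Draws a full synthetic measurement set: per measurement a state
#' affiliation from the subset's proportions, a Haar-uniform rotation
#' (via uniform unit quaternions), a translation uniform in a cube of side
#' ten times the largest template length, and per-fluorophore anisotropic
#' Gaussian noise. Deterministic given `seed`.
#'
#' The returned data frame has one row per (measurement, fluorophore) with
#' columns `measurement_id`, `subset_id`, `fluorophore`, `x_nm`, `y_nm`,
#' `z_nm`. Ground truth used by recovery tests (state affiliations, noise-
#' free positions and perspectives) is attached as `attr(x, "truth")`; the
#' inference entry points never look at it.
#'
#' @param design a [polygon_design()].
#' @param seed integer seed.
#' @return data frame of class `polygon_data`.
#' @export
simulate_polygons <- function(design, seed = 1L) {
  stopifnot(inherits(design, "polygon_design"))
  set.seed(as.integer(seed))
  J <- design$J; Z <- design$Z
  lmax <- max(vapply(design$templates, function(t) max(edge_lengths(t)), 0))
  side <- 10 * max(lmax, 1)
  rows <- list(); truths <- list()
  m0 <- 0L
  for (s in design$subsets) {
    N <- as.integer(s$N)
    zeta <- if (Z == 1) rep(1L, N)
            else sample.int(Z, N, replace = TRUE, prob = s$proportions)
    q <- runif_quat(N)
    Tn <- matrix(stats::runif(3 * N, -side / 2, side / 2), N, 3)
    ids <- m0 + seq_len(N)
    for (z in seq_len(Z)) {
      n_z <- which(zeta == z)
      if (!length(n_z)) next
      X <- design$templates[[z]]$positions
      for (j in seq_len(J)) {
        true_j <- quat_rotate_vec(q[n_z, , drop = FALSE], X[j, ]) + Tn[n_z, , drop = FALSE]
        sxy <- design$sigma_xy[z, j]; sz <- design$sigma_z[z, j]
        noise <- cbind(stats::rnorm(length(n_z), 0, sxy),
                       stats::rnorm(length(n_z), 0, sxy),
                       stats::rnorm(length(n_z), 0, sz))
        meas <- true_j + noise
        rows[[length(rows) + 1L]] <- data.frame(
          measurement_id = ids[n_z], subset_id = s$name, fluorophore = j,
          x_nm = meas[, 1], y_nm = meas[, 2], z_nm = meas[, 3])
        truths[[length(truths) + 1L]] <- data.frame(
          measurement_id = ids[n_z], fluorophore = j, state = z,
          true_x = true_j[, 1], true_y = true_j[, 2], true_z = true_j[, 3])
      }
    }
    m0 <- m0 + N
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$measurement_id, out$fluorophore), ]
  rownames(out) <- NULL
  truth <- do.call(rbind, truths)
  truth <- truth[order(truth$measurement_id, truth$fluorophore), ]
  rownames(truth) <- NULL
  attr(out, "truth") <- truth
  class(out) <- c("polygon_data", "data.frame")
  out
}

#' Uncorrected Euclidean distance summary for one fluorophore pair
#'
#' The naive (biased) estimator the correction methods improve on: the
#' sample mean of the measured Euclidean distances |X~_j - X~_i| over
#' measurements, with its standard error.
#'
#' @param data a `polygon_data` data frame (long format, see
#'   [simulate_polygons()]).
#' @param pair integer pair `c(i, j)` of fluorophore labels.
#' @return named vector: `mean`, `se`, `sd`, `n`.
#' @export
euclidean_distance_summary <- function(data, pair = c(2, 3)) {
  d <- pair_distances(data, pair)
  c(mean = mean(d), se = stats::sd(d) / sqrt(length(d)),
    sd = stats::sd(d), n = length(d))
}

# measured displacement vectors for a fluorophore pair: one row per
# measurement (i -> j)
pair_displacements <- function(data, pair) {
  di <- data[data$fluorophore == pair[1], ]
  dj <- data[data$fluorophore == pair[2], ]
  di <- di[order(di$measurement_id), ]
  dj <- dj[order(dj$measurement_id), ]
  if (!identical(di$measurement_id, dj$measurement_id))
    stop("pair ", pair[1], "-", pair[2], " not complete across measurements")
  cbind(dj$x_nm - di$x_nm, dj$y_nm - di$y_nm, dj$z_nm - di$z_nm)
}

# measured Euclidean distances for a fluorophore pair
pair_distances <- function(data, pair) {
  V <- pair_displacements(data, pair)
  sqrt(rowSums(V^2))
}
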