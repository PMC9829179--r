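## Single-state polygon sampler internals. All updates operate on the plain
## chain-state pieces (Y, X, q, Tn, sig) so each block can be unit-tested
## against brute-force oracles in isolation.

# 0.5 * weighted squared residual per measurement (quadratic part of the
# log-likelihood, the only part the perspective updates need)
quad_per_measurement <- function(Y, X, q, Tn, sig) {
  J <- nrow(X)
  out <- numeric(nrow(q))
  for (j in seq_len(J)) {
    pred <- quat_rotate_vec(q, X[j, ]) + Tn
    r <- Y[[j]] - pred
    out <- out + 0.5 * ((r[, 1]^2 + r[, 2]^2) / sig$xy[j]^2 + r[, 3]^2 / sig$z[j]^2)
  }
  out
}

# quadratic part restricted to fluorophore j (template node updates)
quad_for_node <- function(Y, Xj, j, q, Tn, sig) {
  pred <- quat_rotate_vec(q, Xj) + Tn
  r <- Y[[j]] - pred
  sum(0.5 * ((r[, 1]^2 + r[, 2]^2) / sig$xy[j]^2 + r[, 3]^2 / sig$z[j]^2))
}

# Exact Gibbs draw of all translations: the full conditional of T^n is a
# 3D Gaussian with (diagonal) precision sum_j tau_j and mean the tau-weighted
# average of (Y_j^n - R^n X_j) over fluorophores (template node 1 at origin).
gibbs_translation <- function(Y, X, q, sig) {
  J <- nrow(X); N <- nrow(q)
  pxy <- 1 / sig$xy^2; pz <- 1 / sig$z^2
  Pxy <- sum(pxy); Pz <- sum(pz)
  ax <- ay <- az <- numeric(N)
  for (j in seq_len(J)) {
    d <- Y[[j]] - quat_rotate_vec(q, X[j, ])
    ax <- ax + pxy[j] * d[, 1]
    ay <- ay + pxy[j] * d[, 2]
    az <- az + pz[j] * d[, 3]
  }
  cbind(ax / Pxy + stats::rnorm(N) / sqrt(Pxy),
        ay / Pxy + stats::rnorm(N) / sqrt(Pxy),
        az / Pz + stats::rnorm(N) / sqrt(Pz))
}

# Conjugate draw of (sigma_xy, sigma_z) for one fluorophore under the flat
# prior on sigma. With u = sigma^-2 the flat-sigma prior contributes
# u^(-3/2) du, so u_xy | rest ~ Gamma(N - 1/2, S_xy / 2) (x and y pooled,
# 2N residual components) and u_z | rest ~ Gamma(N/2 - 1/2, S_z / 2).
# Degenerate shapes (too few measurements) fall back to a random-walk MH
# step on sigma itself.
gibbs_sigma <- function(S_xy, S_z, N, current = NULL) {
  if (S_xy <= 0 || S_z <= 0) stop("residuals are degenerate (all zero): sigma update undefined")
  draw1 <- function(shape, S, ncomp, cur) {
    if (shape > 0) return(1 / sqrt(stats::rgamma(1L, shape = shape, rate = S / 2)))
    # MH fallback on sigma with flat prior (only reachable for N < 2)
    prop <- cur * exp(stats::rnorm(1L, 0, 0.3))
    logpost <- function(s) -ncomp * log(s) - S / (2 * s^2)
    if (log(stats::runif(1L)) < logpost(prop) - logpost(cur) + log(prop / cur)) prop else cur
  }
  c(xy = draw1(N - 0.5, S_xy, 2 * N, current[1]),
    z = draw1(N / 2 - 0.5, S_z, N, current[2]))
}

# residual sums of squares per fluorophore: list(S_xy = J-vector, S_z = J-vector)
residual_sums <- function(Y, X, q, Tn) {
  J <- nrow(X)
  S_xy <- S_z <- numeric(J)
  for (j in seq_len(J)) {
    r <- Y[[j]] - (quat_rotate_vec(q, X[j, ]) + Tn)
    S_xy[j] <- sum(r[, 1]^2 + r[, 2]^2)
    S_z[j] <- sum(r[, 3]^2)
  }
  list(S_xy = S_xy, S_z = S_z)
}

# Metropolis update of all rotations (one small-rotation composition
# proposal per measurement, symmetric). Returns updated q and acceptance count.
mh_rotations <- function(Y, X, q, Tn, sig, step) {
  N <- nrow(q)
  dq <- small_quat(N, step)
  qn <- quat_mult(dq, q)
  quad_old <- quad_per_measurement(Y, X, q, Tn, sig)
  quad_new <- quad_per_measurement(Y, X, qn, Tn, sig)
  acc <- log(stats::runif(N)) < (quad_old - quad_new)
  q[acc, ] <- qn[acc, , drop = FALSE]
  list(q = q, n_accept = sum(acc))
}

# Metropolis update of the template's free canonical coordinates, one node
# block at a time; proposals outside the canonical chart (x2 < 0, y3 < 0)
# or the length cut-off are rejected through the prior support.
mh_template <- function(Y, tpl, q, Tn, sig, steps, l_max) {
  J <- tpl$J
  co <- template_free_coords(tpl)
  lp <- template_log_prior(tpl, l_max)
  blocks <- template_blocks(J)
  n_acc <- integer(length(blocks))
  for (b in seq_along(blocks)) {
    idx <- blocks[[b]]$idx
    node <- blocks[[b]]$node
    co_new <- co
    co_new[idx] <- co[idx] + stats::rnorm(length(idx), 0, steps[b])
    if (!free_coords_valid(co_new, J)) next
    tpl_new <- template_from_free_coords(co_new, J)
    lp_new <- template_log_prior(tpl_new, l_max)
    if (!is.finite(lp_new)) next
    dquad <- quad_for_node(Y, tpl$positions[node, ], node, q, Tn, sig) -
             quad_for_node(Y, tpl_new$positions[node, ], node, q, Tn, sig)
    if (log(stats::runif(1L)) < dquad + lp_new - lp) {
      co <- co_new; tpl <- tpl_new; lp <- lp_new
      n_acc[b] <- n_acc[b] + 1L
    }
  }
  list(template = tpl, n_accept = n_acc)
}

# free-coordinate blocks: node 2 (x2), node 3 (x3, y3), nodes >= 4 (x,y,z)
template_blocks <- function(J) {
  blocks <- list(list(node = 2L, idx = 1L))
  if (J >= 3) blocks <- c(blocks, list(list(node = 3L, idx = 2:3)))
  if (J >= 4) for (j in 4:J)
    blocks <- c(blocks, list(list(node = j, idx = 3L * (j - 3L) + 1:3)))
  blocks
}

# per-measurement Kabsch alignment of a template to the data: returns the
# rotation (quaternion) and translation placing X closest to each measured
# polygon (unweighted least squares)
align_to_template <- function(ms, X, rows = NULL) {
  if (is.null(rows)) rows <- seq_len(ms$N)
  J <- nrow(X)
  Xbar <- colMeans(X)
  Xc <- sweep(X, 2, Xbar)
  q <- matrix(0, ms$N, 4); q[, 1] <- 1
  Tn <- matrix(0, ms$N, 3)
  for (n in rows) {
    Pn <- t(vapply(seq_len(J), function(j) ms$Y[[j]][n, ], numeric(3)))
    Pbar <- colMeans(Pn)
    R <- kabsch_rotation(Xc, sweep(Pn, 2, Pbar))
    q[n, ] <- matrix_to_quat(R)
    Tn[n, ] <- Pbar - as.numeric(R %*% Xbar)
  }
  list(q = q, Tn = Tn)
}

# restrict the internal measurement arrays to a subset of rows
slice_ms <- function(ms, rows) {
  list(Y = lapply(ms$Y, function(m) m[rows, , drop = FALSE]),
       N = length(rows), J = ms$J,
       subset_id = ms$subset_id[rows])
}

# data-driven starting point: template from the mean pairwise-distance
# matrix (classical MDS embedding), perspectives by per-measurement Kabsch
# alignment, sigma from residual moments.
initialize_chain <- function(ms, jitter = 0) {
  J <- ms$J; N <- ms$N
  D <- matrix(0, J, J)
  for (i in seq_len(J - 1)) for (j in (i + 1):J) {
    V <- ms$Y[[j]] - ms$Y[[i]]
    D[i, j] <- D[j, i] <- mean(sqrt(rowSums(V^2)))
  }
  k <- min(3L, J - 1L)
  XY <- suppressWarnings(stats::cmdscale(D, k = k))
  if (is.null(dim(XY))) XY <- matrix(XY, ncol = 1)
  X0 <- cbind(XY, matrix(0, J, 3 - ncol(XY)))
  if (jitter > 0) X0 <- X0 + matrix(stats::rnorm(3 * J, 0, jitter), J, 3)
  tpl <- standardize_polygon(X0)$template
  X <- tpl$positions
  al <- align_to_template(ms, X)
  q <- al$q; Tn <- al$Tn
  rs <- residual_sums(ms$Y, X, q, Tn)
  sig <- list(xy = pmax(sqrt(rs$S_xy / (2 * N)), 0.5),
              z = pmax(sqrt(rs$S_z / N), 0.5))
  list(template = tpl, q = q, Tn = Tn, sig = sig)
}

run_single_chain <- function(ms, cfg, chain_seed, init_jitter = 0) {
  set.seed(chain_seed)
  J <- ms$J; N <- ms$N
  st <- initialize_chain(ms, jitter = init_jitter)
  tpl <- st$template; q <- st$q; Tn <- st$Tn; sig <- st$sig
  blocks <- template_blocks(J)
  step_rot <- cfg$step_rotation
  step_tpl <- rep(cfg$step_template, length(blocks))
  n_iter <- cfg$iterations
  n_burn <- floor(cfg$burnin * n_iter)
  thin <- cfg$thin
  keep_at <- seq(n_burn + thin, n_iter, by = thin)
  idx2 <- utils::combn(J, 2)
  n_len <- ncol(idx2)
  n_free <- length(template_free_coords(tpl))
  draws <- matrix(NA_real_, length(keep_at),
                  n_len + (if (J == 3) 3 else 0) + 2 * J + 1 + n_free)
  acc_rot <- acc_rot_n <- 0
  acc_tpl <- rep(0, length(blocks)); acc_tpl_n <- 0
  win_rot <- 0; win_tpl <- rep(0, length(blocks)); win_n <- 0
  krow <- 0L
  for (it in seq_len(n_iter)) {
    Tn <- gibbs_translation(ms$Y, tpl$positions, q, sig)
    rot <- mh_rotations(ms$Y, tpl$positions, q, Tn, sig, step_rot)
    q <- rot$q
    tu <- mh_template(ms$Y, tpl, q, Tn, sig, step_tpl, cfg$l_max)
    tpl <- tu$template
    rs <- residual_sums(ms$Y, tpl$positions, q, Tn)
    for (j in seq_len(J)) {
      s <- gibbs_sigma(rs$S_xy[j], rs$S_z[j], N, c(sig$xy[j], sig$z[j]))
      sig$xy[j] <- s[["xy"]]; sig$z[j] <- s[["z"]]
    }
    win_rot <- win_rot + rot$n_accept / N
    win_tpl <- win_tpl + tu$n_accept
    win_n <- win_n + 1
    if (it <= n_burn && cfg$adapt && it %% 50 == 0) {
      step_rot <- min(max(step_rot * exp(0.6 * (win_rot / win_n - 0.3)), 1e-4), pi)
      step_tpl <- pmin(pmax(step_tpl * exp(0.6 * (win_tpl / win_n - 0.3)), 1e-4), 200)
      win_rot <- 0; win_tpl[] <- 0; win_n <- 0
    }
    if (it > n_burn) {
      acc_rot <- acc_rot + rot$n_accept / N
      acc_tpl <- acc_tpl + tu$n_accept
      acc_rot_n <- acc_rot_n + 1
    }
    if (krow < length(keep_at) && it == keep_at[krow + 1L]) {
      krow <- krow + 1L
      lens <- edge_lengths(tpl)
      ll <- sum(loglik_per_measurement(ms$Y, tpl$positions, q, Tn, sig))
      lp <- ll + template_log_prior(tpl, cfg$l_max)
      row <- c(lens,
               if (J == 3) internal_angles(lens) else NULL,
               sig$xy, sig$z, lp, template_free_coords(tpl))
      draws[krow, ] <- row
    }
  }
  len_names <- apply(idx2, 2, function(ij) paste0("l", ij[1], ij[2]))
  cn <- c(len_names,
          if (J == 3) c("angle1", "angle2", "angle3") else NULL,
          paste0("sigma", seq_len(J), "_xy"), paste0("sigma", seq_len(J), "_z"),
          "log_posterior", paste0("tpl", seq_len(n_free)))
  colnames(draws) <- cn
  list(draws = as.data.frame(draws),
       acceptance = c(rotation = acc_rot / max(acc_rot_n, 1),
                      stats::setNames(acc_tpl / max(acc_rot_n, 1),
                                      paste0("template_node", vapply(blocks, `[[`, 0L, "node")))),
       steps = list(rotation = step_rot, template = step_tpl))
}

#' Fit the Bayesian polygon model to spot-centre measurements
#'
#' Runs the Markov chain Monte Carlo sampler for the polygon-template
#' model: per sweep, exact Gibbs draws of all per-measurement translations,
#' Metropolis small-rotation updates of all per-measurement rotations,
#' Metropolis random-walk updates of the template's free canonical
#' coordinates, and conjugate Gibbs draws of the per-fluorophore
#' localization errors under the flat-sigma prior. With `states > 1` the
#' mixture sampler additionally updates per-measurement state affiliations
#' (Metropolis, with a minimum-occupancy-3 constraint) and per-subset state
#' proportions (Dirichlet Gibbs); see also [state_affiliations()].
#'
#' The first `burnin` fraction of each chain is discarded (and used to
#' adapt proposal step sizes to a 20-40% acceptance rate; steps are frozen
#' afterwards so the post-burn-in kernel satisfies detailed balance).
#'
#' @param data a `polygon_data` data frame (long format; see
#'   [simulate_polygons()] / [read_spot_data()]).
#' @param states number of polygon states Z (1 = homogeneous population).
#' @param iterations MCMC sweeps per chain.
#' @param chains number of independent chains.
#' @param burnin fraction of iterations discarded as burn-in.
#' @param thin keep every `thin`-th post-burn-in sweep (default targets
#'   about 1000 stored draws per chain).
#' @param seed master seed; per-chain streams are derived from it.
#' @param l_max template length cut-off making the flat-length prior
#'   proper (nm).
#' @param step_rotation,step_template initial proposal scales (radians /
#'   nm); adapted during burn-in when `adapt = TRUE`.
#' @param adapt adapt proposal steps during burn-in.
#' @param informing for `states > 1`: named list mapping subset id to the
#'   state it purely contains, e.g. `list(informing = 2)`. Measurements in
#'   informing subsets have fixed affiliations and contribute the
#'   single-state likelihood of their state.
#' @param state_prior optional [informative_state_prior()] applied to
#'   state 1 (mixture only).
#' @param init optional explicit starting point for mixture chains
#'   (diagnostics/expert use): a list with any of `templates` (list of Z
#'   `polygon_template`s), `sig` (list of Z `list(xy=, z=)` error vectors),
#'   `zeta` (integer affiliations). Default: data-driven initialization.
#' @return an object of class `polygon_fit` (or `c("polygon_mixfit",
#'   "polygon_fit")`) with components `draws` (posterior samples of edge
#'   lengths, internal angles, sigmas, log-posterior, and for mixtures
#'   per-subset proportions), `acceptance`, `rhat`, `config`. Methods:
#'   `print`, `summary`, `coef`, `plot`.
#' @examples
#' \donttest{
#' d <- simulate_polygons(design_preset("example_1_2"), seed = 1)
#' fit <- polygon_fit(d, iterations = 2000, chains = 2, seed = 1)
#' summary(fit)
#' }
#' @export
polygon_fit <- function(data, states = 1L, iterations = 20000L, chains = 2L,
                        burnin = 0.4, thin = NULL, seed = 1L, l_max = 1000,
                        step_rotation = 0.3, step_template = 2,
                        adapt = TRUE, informing = NULL, state_prior = NULL,
                        init = NULL) {
  if (burnin <= 0 || burnin >= 1) stop("'burnin' must be in (0, 1)")
  if (iterations < 10) stop("'iterations' too small")
  if (states < 1) stop("'states' must be >= 1")
  if (states > 1L)
    return(mixture_fit_impl(data, Z = as.integer(states), iterations = iterations,
                            chains = chains, burnin = burnin, thin = thin,
                            seed = seed, l_max = l_max,
                            step_rotation = step_rotation,
                            step_template = step_template, adapt = adapt,
                            informing = informing, state_prior = state_prior,
                            init = init))
  ms <- as_measurement_arrays(data)
  if (ms$N < 2) stop("need at least 2 measurements")
  if (is.null(thin))
    thin <- max(1L, floor((1 - burnin) * iterations / 1000))
  cfg <- list(iterations = as.integer(iterations), burnin = burnin,
              thin = as.integer(thin), l_max = l_max,
              step_rotation = step_rotation, step_template = step_template,
              adapt = adapt, chains = as.integer(chains), seed = as.integer(seed))
  res <- vector("list", chains)
  for (ch in seq_len(chains)) {
    res[[ch]] <- run_single_chain(ms, cfg, chain_seed = chain_stream_seed(seed, ch),
                                  init_jitter = if (ch == 1) 0 else 2)
    res[[ch]]$draws$chain <- ch
  }
  draws <- do.call(rbind, lapply(res, `[[`, "draws"))
  keep <- setdiff(colnames(draws), c("chain", grep("^tpl", colnames(draws), value = TRUE)))
  fit <- structure(list(
    draws = draws,
    acceptance = lapply(res, `[[`, "acceptance"),
    rhat = split_rhat(draws, setdiff(keep, "log_posterior")),
    config = cfg, J = ms$J, N = ms$N, states = 1L,
    measurement_ids = ms$ids), class = "polygon_fit")
  warn_rhat(fit$rhat)
  fit
}

# deterministic per-chain / per-purpose seed streams below 2^31
chain_stream_seed <- function(seed, k) {
  (as.integer(seed) %% 1000003L) * 1009L + 37L * as.integer(k)
}

split_rhat <- function(draws, cols) {
  chains <- split(draws, draws$chain)
  halves <- list()
  for (d in chains) {
    m <- nrow(d) %/% 2
    if (m < 2) next
    halves <- c(halves, list(d[seq_len(m), , drop = FALSE], d[(m + 1):(2 * m), , drop = FALSE]))
  }
  if (length(halves) < 2) return(stats::setNames(rep(NA_real_, length(cols)), cols))
  out <- vapply(cols, function(cl) {
    x <- vapply(halves, function(h) mean(h[[cl]]), 0)
    s2 <- vapply(halves, function(h) stats::var(h[[cl]]), 0)
    n <- nrow(halves[[1]])
    W <- mean(s2)
    B <- n * stats::var(x)
    if (W <= 0) return(1)
    sqrt(((n - 1) / n * W + B / n) / W)
  }, 0)
  out
}

warn_rhat <- function(rhat, tol = 1.05) {
  bad <- names(rhat)[is.finite(rhat) & rhat > tol]
  if (length(bad))
    warning("potential-scale-reduction above ", tol, " for: ",
            paste(bad, collapse = ", "), " - consider more iterations")
  invisible(NULL)
}
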