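#' Density of a measured 3D distance under isotropic Gaussian error
#'
#' The classic closed-form likelihood for the Euclidean distance l between
#' two spot centres whose true separation is mu, with isotropic Gaussian
#' displacement error sigma (a scaled noncentral-chi distribution with 3
#' degrees of freedom):
#' \deqn{p(l) = \sqrt{2/\pi}\,\frac{l}{\mu\sigma}
#'   e^{-(l^2+\mu^2)/(2\sigma^2)} \sinh(l\mu/\sigma^2),}
#' with continuous limit at mu = 0 equal to the Maxwell density
#' \eqn{\sqrt{2/\pi}\, l^2 \sigma^{-3} e^{-l^2/(2\sigma^2)}}. Evaluated in
#' log space for numerical stability at large \eqn{l\mu/\sigma^2}.
#'
#' @param l measured distance(s), >= 0 (nm).
#' @param mu true separation, >= 0 (nm).
#' @param sigma isotropic displacement error, > 0 (nm).
#' @param log return the log density.
#' @return density (or log density) values, vectorized over `l`.
#' @export
churchman_pdf <- function(l, mu, sigma, log = FALSE) {
  if (sigma <= 0) stop("'sigma' must be positive")
  if (mu < 0) stop("'mu' must be non-negative")
  if (any(l < 0)) stop("'l' must be non-negative")
  out <- rep(-Inf, length(l))
  pos <- l > 0
  lp <- l[pos]
  if (mu == 0) {
    out[pos] <- 0.5 * log(2 / pi) + 2 * log(lp) - 3 * log(sigma) -
      lp^2 / (2 * sigma^2)
  } else {
    x <- lp * mu / sigma^2
    # log sinh(x) = x + log1p(-exp(-2x)) - log 2, series for tiny x
    logsinh <- ifelse(x > 1e-4, x + log1p(-exp(-2 * x)) - log(2),
                      log(x) + log1p(x^2 / 6))
    out[pos] <- 0.5 * log(2 / pi) + log(lp) - log(mu) - log(sigma) -
      (lp^2 + mu^2) / (2 * sigma^2) + logsinh
  }
  if (log) out else exp(out)
}

#' Maximum likelihood pair-wise distance correction
#'
#' Maximizes the closed-form isotropic distance likelihood
#' ([churchman_pdf()]) over (mu, sigma) for a sample of measured distances.
#' Standard errors come from the observed information (numerical Hessian);
#' boundary solutions mu = 0 are reported as such with `NA` standard error
#' for mu. For short true separations this estimator is known to be
#' error-prone with overconfident uncertainty.
#'
#' @param distances measured Euclidean distances (nm), length >= 2.
#' @return list with `mu`, `sigma`, `se_mu`, `se_sigma`, `boundary`
#'   (logical, mu pinned at 0), `logLik`, `convergence`.
#' @export
churchman_mle <- function(distances) {
  d <- as.numeric(distances)
  if (length(d) < 2) stop("need at least 2 distances")
  if (any(d < 0) || any(!is.finite(d))) stop("distances must be finite and non-negative")
  if (stats::sd(d) == 0)
    return(list(mu = d[1], sigma = 0, se_mu = NA_real_, se_sigma = NA_real_,
                boundary = TRUE, logLik = Inf,
                convergence = "degenerate: repeated identical distance"))
  negll <- function(par) {
    mu <- par[1]; sigma <- exp(par[2])
    -sum(churchman_pdf(d, mu, sigma, log = TRUE))
  }
  m <- mean(d); s0 <- stats::sd(d)
  starts <- list(c(m, log(s0)), c(m / 2, log(s0)), c(0, log(sqrt(mean(d^2) / 3))))
  best <- NULL
  for (st in starts) {
    o <- try(stats::optim(st, negll, method = "L-BFGS-B",
                          lower = c(0, log(1e-6)), upper = c(10 * m, log(10 * m + 10))),
             silent = TRUE)
    if (inherits(o, "try-error")) next
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best)) stop("MLE optimization failed from all starts")
  mu <- best$par[1]; sigma <- exp(best$par[2])
  boundary <- mu < 1e-8
  se <- c(NA_real_, NA_real_)
  H <- try(stats::optimHess(best$par, negll), silent = TRUE)
  if (!inherits(H, "try-error") && !boundary) {
    V <- try(solve(H), silent = TRUE)
    if (!inherits(V, "try-error") && all(diag(V) > 0)) {
      se[1] <- sqrt(V[1, 1])
      se[2] <- sqrt(V[2, 2]) * sigma      # delta method for log parametrization
    }
  } else if (!inherits(H, "try-error") && boundary && H[2, 2] > 0) {
    se[2] <- sqrt(1 / H[2, 2]) * sigma
  }
  list(mu = mu, sigma = sigma, se_mu = se[1], se_sigma = se[2],
       boundary = boundary, logLik = -best$value,
       convergence = if (best$convergence == 0) "converged" else paste("optim code", best$convergence))
}

#' Flat-prior posterior for the pair-wise distance correction
#'
#' Posterior over (mu, sigma) proportional to the product of
#' [churchman_pdf()] terms with a flat prior d mu d sigma on the positive
#' quadrant, evaluated on a deterministic adaptive 2D grid (coarse pass to
#' locate the high-posterior region, refined pass over it; the mu axis
#' always extends to 0 to capture the thick tail of short separations).
#'
#' @param distances measured Euclidean distances (nm), length >= 3 (the
#'   posterior is improper for fewer).
#' @param n_grid refined grid resolution per axis.
#' @return object of class `churchman_post` with posterior `mean_mu`,
#'   `sd_mu`, `mean_sigma`, `sd_sigma`, marginal grids, and the joint grid
#'   (for resampling). Methods: `print`, `coef`; draws via
#'   [posterior_draws()].
#' @export
churchman_posterior <- function(distances, n_grid = 160L) {
  d <- as.numeric(distances)
  if (length(d) < 3) stop("posterior is improper for fewer than 3 distances")
  if (any(d < 0) || any(!is.finite(d))) stop("distances must be finite and non-negative")
  m <- mean(d); s0 <- stats::sd(d)
  logpost <- function(mu, sigma) sum(churchman_pdf(d, mu, sigma, log = TRUE))
  grid_eval <- function(mus, sigmas) {
    lp <- matrix(-Inf, length(mus), length(sigmas))
    for (i in seq_along(mus)) for (k in seq_along(sigmas))
      lp[i, k] <- logpost(mus[i], sigmas[k])
    lp
  }
  # coarse pass
  mus0 <- seq(0, m + 6 * s0, length.out = 48)
  sig0 <- seq(max(s0 / 6, 1e-3), 3 * s0 + 1e-3, length.out = 40)
  lp0 <- grid_eval(mus0, sig0)
  top <- max(lp0)
  keep <- which(lp0 > top - 18, arr.ind = TRUE)
  mu_hi <- min(max(mus0[keep[, 1]]) * 1.3 + 2, max(mus0))
  sig_lo <- max(min(sig0[keep[, 2]]) * 0.7, 1e-3)
  sig_hi <- max(sig0[keep[, 2]]) * 1.3
  # refined pass (mu from 0: thick tails to zero matter)
  mus <- seq(0, mu_hi, length.out = n_grid)
  sigmas <- seq(sig_lo, sig_hi, length.out = n_grid)
  lp <- grid_eval(mus, sigmas)
  w <- exp(lp - max(lp))
  w <- w / sum(w)
  wmu <- rowSums(w); wsig <- colSums(w)
  mean_mu <- sum(wmu * mus); sd_mu <- sqrt(max(sum(wmu * mus^2) - mean_mu^2, 0))
  mean_sig <- sum(wsig * sigmas); sd_sig <- sqrt(max(sum(wsig * sigmas^2) - mean_sig^2, 0))
  structure(list(mean_mu = mean_mu, sd_mu = sd_mu,
                 mean_sigma = mean_sig, sd_sigma = sd_sig,
                 mu_grid = mus, sigma_grid = sigmas, weight = w,
                 n = length(d)), class = "churchman_post")
}

#' @export
print.churchman_post <- function(x, ...) {
  cat(sprintf("Pair-wise flat-prior posterior (n = %d distances)\n", x$n))
  cat(sprintf("  mu    : %.2f +- %.2f nm\n", x$mean_mu, x$sd_mu))
  cat(sprintf("  sigma : %.2f +- %.2f nm\n", x$mean_sigma, x$sd_sigma))
  invisible(x)
}

#' @export
coef.churchman_post <- function(object, ...)
  c(mu = object$mean_mu, sigma = object$mean_sigma)

#' Draws from a fitted posterior
#'
#' Generic accessor returning Monte Carlo draws of the quantity a fitted
#' object infers. For `churchman_post`, draws of (mu, sigma) are sampled
#' from the posterior grid (cells by weight, jittered uniformly within a
#' cell); for `pairwise_fit` and `polygon_fit`, stored MCMC samples are
#' returned.
#'
#' @param object a fitted object.
#' @param n number of draws (grid-based posteriors only).
#' @param ... passed to methods.
#' @return data frame of draws.
#' @export
posterior_draws <- function(object, ...) UseMethod("posterior_draws")

#' @rdname posterior_draws
#' @export
posterior_draws.churchman_post <- function(object, n = 10000L, ...) {
  idx <- sample.int(length(object$weight), n, replace = TRUE,
                    prob = as.numeric(object$weight))
  ij <- arrayInd(idx, dim(object$weight))
  dmu <- if (length(object$mu_grid) > 1) diff(object$mu_grid[1:2]) else 0
  dsig <- if (length(object$sigma_grid) > 1) diff(object$sigma_grid[1:2]) else 0
  data.frame(mu = pmax(object$mu_grid[ij[, 1]] + stats::runif(n, -dmu / 2, dmu / 2), 0),
             sigma = pmax(object$sigma_grid[ij[, 2]] + stats::runif(n, -dsig / 2, dsig / 2), 1e-6))
}

#' @rdname posterior_draws
#' @export
posterior_draws.polygon_fit <- function(object, ...) object$draws

#' Anisotropic pair-wise distance correction by MCMC
#'
#' Bayesian sampler for a single inter-fluorophore distance: each measured
#' displacement is modelled as l times a direction on the unit sphere plus
#' anisotropic Gaussian error with pair-level sigma_xy (lateral) and
#' sigma_z (axial). Priors are flat on l and on the sigmas, directions
#' isotropic, matching the priors of the polygon method. With
#' `isotropic = TRUE` a single sigma is used and the marginal (mu, sigma)
#' posterior coincides with [churchman_posterior()] (same assumptions).
#'
#' @param data either a `polygon_data` data frame (with `pair`) or an
#'   N x 3 matrix of displacement vectors.
#' @param pair fluorophore pair `c(i, j)` when `data` is a data frame.
#' @param isotropic constrain the error to be isotropic (one sigma).
#' @param iterations,chains,burnin,thin,seed,adapt as in [polygon_fit()].
#' @param l_max flat-prior cut-off on the length (nm).
#' @return object of class `pairwise_fit` with `draws` (columns `l`,
#'   `sigma_xy`, `sigma_z`, `log_posterior`, `chain`), `acceptance`,
#'   `rhat`, `config`.
#' @export
pairwise_fit <- function(data, pair = c(1, 2), isotropic = FALSE,
                         iterations = 20000L, chains = 2L, burnin = 0.4,
                         thin = NULL, seed = 1L, l_max = 1000, adapt = TRUE) {
  V <- if (is.matrix(data)) data else pair_displacements(data, pair)
  if (ncol(V) != 3) stop("displacements must be N x 3")
  N <- nrow(V)
  if (N < 3) stop("need at least 3 measurements")
  if (burnin <= 0 || burnin >= 1) stop("'burnin' must be in (0, 1)")
  if (is.null(thin)) thin <- max(1L, floor((1 - burnin) * iterations / 1000))
  cfg <- list(iterations = as.integer(iterations), burnin = burnin,
              thin = as.integer(thin), l_max = l_max, isotropic = isotropic,
              chains = as.integer(chains), seed = as.integer(seed), adapt = adapt)
  res <- vector("list", chains)
  for (ch in seq_len(chains)) {
    res[[ch]] <- run_pairwise_chain(V, cfg, chain_stream_seed(seed, ch))
    res[[ch]]$draws$chain <- ch
  }
  draws <- do.call(rbind, lapply(res, `[[`, "draws"))
  fit <- structure(list(draws = draws,
                        acceptance = lapply(res, `[[`, "acceptance"),
                        rhat = split_rhat(draws, c("l", "sigma_xy", "sigma_z")),
                        config = cfg, N = N), class = "pairwise_fit")
  warn_rhat(fit$rhat)
  fit
}

run_pairwise_chain <- function(V, cfg, chain_seed) {
  set.seed(chain_seed)
  N <- nrow(V)
  dn <- sqrt(rowSums(V^2))
  ## init: directions along the measured displacements, moment-based scales
  u <- V / pmax(dn, 1e-9)
  s0 <- max(stats::sd(V[, 1]), 1e-2)
  sig_xy <- s0; sig_z <- max(stats::sd(V[, 3]), 1e-2)
  if (cfg$isotropic) sig_z <- sig_xy <- max(sqrt(mean(V^2)), 1e-2)
  l <- sqrt(max(mean(dn^2) - (2 * sig_xy^2 + sig_z^2), (mean(dn) / 4)^2))
  step_u <- 0.4; step_l <- max(s0 / sqrt(N), 0.05)
  n_iter <- cfg$iterations
  n_burn <- floor(cfg$burnin * n_iter)
  keep_at <- seq(n_burn + cfg$thin, n_iter, by = cfg$thin)
  draws <- matrix(NA_real_, length(keep_at), 4)
  colnames(draws) <- c("l", "sigma_xy", "sigma_z", "log_posterior")
  quad <- function(u, l, sxy, sz) {
    r1 <- V[, 1] - l * u[, 1]; r2 <- V[, 2] - l * u[, 2]; r3 <- V[, 3] - l * u[, 3]
    0.5 * ((r1^2 + r2^2) / sxy^2 + r3^2 / sz^2)
  }
  acc_u <- acc_l <- 0; acc_n <- 0
  win_u <- win_l <- 0; win_n <- 0
  krow <- 0L
  for (it in seq_len(n_iter)) {
    ## directions: symmetric small-rotation proposals on the sphere
    dq <- small_quat(N, step_u)
    un <- quat_rotate_rows(dq, u)
    qo <- quad(u, l, sig_xy, sig_z)
    qn <- quad(un, l, sig_xy, sig_z)
    acc <- log(stats::runif(N)) < (qo - qn)
    u[acc, ] <- un[acc, , drop = FALSE]
    ## length: random walk with flat prior on [0, l_max]
    lp <- l + stats::rnorm(1, 0, step_l)
    l_acc <- FALSE
    if (lp >= 0 && lp <= cfg$l_max) {
      dl <- sum(quad(u, l, sig_xy, sig_z)) - sum(quad(u, lp, sig_xy, sig_z))
      if (log(stats::runif(1)) < dl) { l <- lp; l_acc <- TRUE }
    }
    ## sigmas: conjugate draws under the flat-sigma prior
    r1 <- V[, 1] - l * u[, 1]; r2 <- V[, 2] - l * u[, 2]; r3 <- V[, 3] - l * u[, 3]
    if (cfg$isotropic) {
      S <- sum(r1^2 + r2^2 + r3^2)
      uu <- stats::rgamma(1, shape = 1.5 * N - 0.5, rate = S / 2)
      sig_xy <- sig_z <- 1 / sqrt(uu)
    } else {
      S_xy <- sum(r1^2 + r2^2); S_z <- sum(r3^2)
      s <- gibbs_sigma(S_xy, S_z, N, c(sig_xy, sig_z))
      sig_xy <- s[["xy"]]; sig_z <- s[["z"]]
    }
    win_u <- win_u + mean(acc); win_l <- win_l + l_acc; win_n <- win_n + 1
    if (it <= n_burn && cfg$adapt && it %% 50 == 0) {
      step_u <- min(max(step_u * exp(0.6 * (win_u / win_n - 0.3)), 1e-4), pi)
      step_l <- min(max(step_l * exp(0.6 * (win_l / win_n - 0.3)), 1e-4), 100)
      win_u <- win_l <- 0; win_n <- 0
    }
    if (it > n_burn) { acc_u <- acc_u + mean(acc); acc_l <- acc_l + l_acc; acc_n <- acc_n + 1 }
    if (krow < length(keep_at) && it == keep_at[krow + 1L]) {
      krow <- krow + 1L
      ll <- sum(-2 * log(sig_xy) - log(sig_z) - 1.5 * log(2 * pi) -
                  quad(u, l, sig_xy, sig_z))
      draws[krow, ] <- c(l, sig_xy, sig_z, ll)
    }
  }
  list(draws = as.data.frame(draws),
       acceptance = c(direction = acc_u / max(acc_n, 1), length = acc_l / max(acc_n, 1)))
}

#' @export
print.pairwise_fit <- function(x, ...) {
  cat(sprintf("Pair-wise %s MCMC fit (N = %d, %d chains x %d iterations)\n",
              if (x$config$isotropic) "isotropic" else "anisotropic",
              x$N, x$config$chains, x$config$iterations))
  s <- summary(x)
  print(round(s, 2))
  invisible(x)
}

#' @export
summary.pairwise_fit <- function(object, ...) {
  cols <- c("l", "sigma_xy", "sigma_z")
  t(vapply(cols, function(cl) {
    x <- object$draws[[cl]]
    c(mean = mean(x), sd = stats::sd(x),
      `2.5%` = unname(stats::quantile(x, 0.025)),
      `97.5%` = unname(stats::quantile(x, 0.975)))
  }, numeric(4)))
}

#' @export
coef.pairwise_fit <- function(object, ...) {
  c(l = mean(object$draws$l), sigma_xy = mean(object$draws$sigma_xy),
    sigma_z = mean(object$draws$sigma_z))
}
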