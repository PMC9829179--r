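test_that("distance density has the Maxwell limit and integrates to one", {
  l <- seq(0.01, 120, by = 0.25)
  # continuous limit at mu = 0
  expect_equal(churchman_pdf(l, 0, 20), churchman_pdf(l, 1e-8, 20),
               tolerance = 1e-6)
  maxwell <- sqrt(2 / pi) * l^2 / 20^3 * exp(-l^2 / (2 * 20^2))
  expect_equal(churchman_pdf(l, 0, 20), maxwell, tolerance = 1e-10)
  # normalization over a (mu, sigma) grid
  for (mu in c(0, 5, 15, 50)) for (sigma in c(5, 21.2, 29.2)) {
    Z <- integrate(function(x) churchman_pdf(x, mu, sigma), 0, Inf,
                   rel.tol = 1e-10)$value
    expect_equal(Z, 1, tolerance = 1e-8)
  }
  expect_error(churchman_pdf(10, 5, -1), "positive")
})

test_that("density mean matches simulated pair distances (inflation regime)", {
  # true separation 15 nm, isotropic pair error 29.2 nm: analytic mean of
  # the distance distribution vs Monte Carlo from the simulator
  m_th <- integrate(function(x) x * churchman_pdf(x, 15, 29.2), 0, Inf)$value
  des <- design_preset("example_1_1")
  means <- vapply(1:6, function(k) {
    d <- simulate_polygons(des, seed = 500 + k)
    unname(euclidean_distance_summary(d, c(2, 3))["mean"])
  }, 0)
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - m_th), 3 * se + 0.05)
  # and the analytic mean exhibits the inflation: well above 15
  expect_gt(m_th, 45)
})

test_that("MLE recovers (mu, sigma) for a well-separated pair", {
  set.seed(50)
  sim_dist <- function(n, mu, sigma)
    sqrt((mu + rnorm(n, 0, sigma))^2 + rnorm(n, 0, sigma)^2 + rnorm(n, 0, sigma)^2)
  d <- sim_dist(400, 50, 21.2)
  est <- churchman_mle(d)
  expect_lt(abs(est$mu - 50), 3 * 1.5 + 1)
  expect_lt(abs(est$sigma - 21.2), 4)
  expect_false(est$boundary)
  expect_true(is.finite(est$se_mu))
  # repeated identical distance: degenerate diagnostic, no crash
  deg <- churchman_mle(rep(10, 5))
  expect_true(deg$boundary || grepl("degenerate", deg$convergence))
  # mu = 0 truth: large samples pile the MLE onto (or near) the boundary,
  # far below the error scale - the regime where the estimator is known to
  # be misleading
  hits <- vapply(1:6, function(k) {
    set.seed(70 + k)
    churchman_mle(sim_dist(1e4, 0, 10))$mu
  }, 0)
  expect_lt(median(hits), 3)
  expect_lt(max(hits), 10)
  expect_gt(sum(hits < 1e-6), 1)
})

test_that("flat-prior posterior agrees with the MLE when mu >> sigma", {
  set.seed(51)
  d <- sqrt((80 + rnorm(300, 0, 8))^2 + rnorm(300, 0, 8)^2 + rnorm(300, 0, 8)^2)
  post <- churchman_posterior(d)
  est <- churchman_mle(d)
  expect_lt(abs(post$mean_mu - est$mu), 0.3 * est$se_mu + 0.2)
  expect_error(churchman_posterior(c(1, 2)), "improper")
  # grid draws reproduce the grid moments
  dr <- posterior_draws(post, n = 20000)
  expect_equal(mean(dr$mu), post$mean_mu, tolerance = 0.05 * post$mean_mu + 0.3)
  expect_equal(sd(dr$mu), post$sd_mu, tolerance = 0.2 * post$sd_mu + 0.3)
})

test_that("anisotropic pair-wise MCMC concentrates on noise-free data", {
  set.seed(52)
  u <- matrix(rnorm(60), 20, 3); u <- u / sqrt(rowSums(u^2))
  V <- 25 * u + matrix(rnorm(60, 0, 0.05), 20, 3)
  fit <- suppressWarnings(pairwise_fit(V, iterations = 2000, chains = 1, seed = 9))
  s <- summary(fit)
  expect_equal(unname(s["l", "mean"]), 25, tolerance = 0.2)
  expect_lt(s["l", "sd"], 0.5)
})

test_that("isotropic pair-wise MCMC matches the closed-form posterior", {
  des <- design_preset("example_1_1")
  d <- simulate_polygons(des, seed = 53)
  dist23 <- polycorr:::pair_distances(d, c(2, 3))
  post <- churchman_posterior(dist23)
  fit <- suppressWarnings(
    pairwise_fit(d, pair = c(2, 3), isotropic = TRUE,
                 iterations = 6000, chains = 2, seed = 10))
  s <- summary(fit)
  # shared assumptions: means agree within joint Monte Carlo error
  expect_lt(abs(s["l", "mean"] - post$mean_mu),
            0.35 * sqrt(s["l", "sd"]^2 + post$sd_mu^2))
  expect_lt(abs(s["sigma_xy", "mean"] - post$mean_sigma),
            3 * post$sd_sigma)
})

test_that("pair-wise error composition holds between polygon and pair fits", {
  # sigma_ij;d = sqrt(sigma_j;d^2 + sigma_i;d^2): the displacement noise of
  # the simulator composes the per-fluorophore errors
  des <- design_preset("example_1_2")
  d <- simulate_polygons(des, seed = 54)
  truth <- attr(d, "truth")
  for (pair in list(c(1, 2), c(2, 3))) {
    V <- polycorr:::pair_displacements(d, pair)
    ti <- truth[truth$fluorophore == pair[1], ]
    tj <- truth[truth$fluorophore == pair[2], ]
    R <- V - cbind(tj$true_x - ti$true_x, tj$true_y - ti$true_y,
                   tj$true_z - ti$true_z)
    sxy_pair <- sqrt(sum(des$sigma_xy[1, pair]^2))
    sz_pair <- sqrt(sum(des$sigma_z[1, pair]^2))
    expect_equal(sd(c(R[, 1], R[, 2])), sxy_pair, tolerance = 0.08 * sxy_pair)
    expect_equal(sd(R[, 3]), sz_pair, tolerance = 0.12 * sz_pair)
  }
})

test_that("uncorrected mean always exceeds the corrected posterior mean (inflation ordering)", {
  des <- design_preset("example_1_1")
  d <- simulate_polygons(des, seed = 55)
  for (pair in list(c(1, 3), c(2, 3))) {
    raw <- unname(euclidean_distance_summary(d, pair)["mean"])
    post <- churchman_posterior(polycorr:::pair_distances(d, pair))
    expect_gt(raw, post$mean_mu)
  }
})
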