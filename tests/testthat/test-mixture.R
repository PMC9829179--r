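test_that("affiliation flips with identical states reduce to the proportion ratio", {
  # likelihood cancels: acceptance should be governed by min(1, p'/p)
  set.seed(40)
  Nf <- 2000
  zeta <- rep(1L, Nf)
  logL <- matrix(0, Nf, 2)            # identical templates and errors
  counts <- c(Nf, 5L)
  logp <- list(all = log(c(0.8, 0.2)))
  au <- polycorr:::mh_affiliations(zeta, logL, rep("all", Nf), logp, counts)
  # expected acceptance for 1 -> 2 is p2/p1 = 0.25
  expect_equal(au$n_accept / Nf, 0.25, tolerance = 0.05)
})

test_that("occupancy floor makes a 3-member state immovable", {
  zeta <- c(1L, 1L, 1L, 2L, 2L, 2L)
  logL <- matrix(c(rep(0, 6), rep(50, 6)), 6, 2)  # state 2 hugely preferred
  counts <- c(3L, 3L)
  logp <- list(all = log(c(0.5, 0.5)))
  au <- polycorr:::mh_affiliations(zeta, logL, rep("all", 6), logp, counts)
  expect_identical(au$zeta, zeta)      # every move would break the floor
  expect_identical(au$n_accept, 0L)
})

test_that("informative state prior is centred, bounded and validated", {
  pr <- informative_state_prior(c(45, 85, 45), c(10, 10, 15), c(20, 20, 30))
  at_ref <- state_prior_logdensity(c(45, 85, 45), c(10, 10, 15), c(20, 20, 30), pr)
  expect_equal(at_ref, 0)              # maximum (up to the constant)
  off <- state_prior_logdensity(c(50, 80, 40), c(10, 10, 15), c(20, 20, 30), pr)
  expect_lt(off, at_ref)
  # outside the support
  expect_identical(
    state_prior_logdensity(c(45 + 31, 85, 45), c(10, 10, 15), c(20, 20, 30), pr),
    -Inf)
  expect_identical(
    state_prior_logdensity(c(45, 85, 45), c(10 + 7, 10, 15), c(20, 20, 30), pr),
    -Inf)
  expect_error(informative_state_prior(c(10, 10, 30), c(1, 1, 1), c(1, 1, 1)),
               "triangle inequality")
  expect_error(informative_state_prior(c(45, 85, 45), c(-1, 1, 1), c(1, 1, 1)),
               "positive")
})

test_that("mean state affiliations classify by the evidence thresholds", {
  fake <- structure(list(
    zbar = cbind(1 - c(0.1, 0.5, 0.9, 0, 1), c(0.1, 0.5, 0.9, 0, 1)),
    states = 2L,
    measurement_ids = 1:5,
    subset_id = rep("a", 5)), class = c("polygon_mixfit", "polygon_fit"))
  za <- state_affiliations(fake)
  expect_equal(za$label, c("state1", "undecided", "state2", "state1", "state2"))
  expect_equal(za$zbar, c(0.1, 0.5, 0.9, 0, 1))
})

test_that("two well-separated states are recovered with correct proportions", {
  des <- polygon_design(list(triangle_template(45, 85, 45),
                             triangle_template(50, 60, 15)),
                        c(2, 2, 3), c(4, 4, 6),
                        subsets = list(
                          list(name = "mixed", N = 150, proportions = c(0.7, 0.3)),
                          list(name = "informing", N = 105, state = 2L)))
  d <- simulate_polygons(des, seed = 41)
  fit <- suppressWarnings(
    polygon_fit(d, states = 2, iterations = 1500, chains = 1, seed = 6,
                informing = list(informing = 2)))
  s <- summarize_draws(fit$draws)$pooled
  truth <- attr(d, "truth")
  st <- truth$state[truth$fluorophore == 1]
  realized <- mean(st[1:150] == 2)
  expect_lt(abs(s["p2_mixed", "mean"] - realized), 3 * s["p2_mixed", "sd"] + 0.02)
  expect_equal(unname(s[c("l12_s1", "l13_s1", "l23_s1"), "mean"]),
               c(45, 85, 45), tolerance = 0.05)
  expect_equal(unname(s[c("l12_s2", "l13_s2", "l23_s2"), "mean"]),
               c(50, 60, 15), tolerance = 0.05)
  # informing measurements have affiliation fixed at state 2
  za <- state_affiliations(fit)
  expect_true(all(za$zbar[za$subset_id == "informing"] == 1))
  # nearly all measurements classified to their true state
  lab <- ifelse(za$zbar >= 0.5, 2, 1)
  expect_gt(mean(lab == st), 0.95)
  # per-draw proportions live on the simplex
  expect_equal(fit$draws$p1_mixed + fit$draws$p2_mixed, rep(1, nrow(fit$draws)),
               tolerance = 1e-12)
})

test_that("the anchor prior with wide support has negligible posterior impact", {
  des <- polygon_design(list(triangle_template(45, 85, 45),
                             triangle_template(50, 60, 15)),
                        c(3, 3, 4), c(6, 6, 8),
                        subsets = list(
                          list(name = "mixed", N = 120, proportions = c(0.7, 0.3)),
                          list(name = "informing", N = 84, state = 2L)))
  d <- simulate_polygons(des, seed = 42)
  pr <- informative_state_prior(c(45, 85, 45), c(3, 3, 4), c(6, 6, 8),
                                sd_length = 50, halfwidth_length = 150,
                                sd_sigma = 20, halfwidth_sigma = 60)
  fit0 <- suppressWarnings(
    polygon_fit(d, states = 2, iterations = 1500, chains = 1, seed = 7,
                informing = list(informing = 2)))
  fit1 <- suppressWarnings(
    polygon_fit(d, states = 2, iterations = 1500, chains = 1, seed = 7,
                informing = list(informing = 2), state_prior = pr))
  s0 <- summarize_draws(fit0$draws)$pooled
  s1 <- summarize_draws(fit1$draws)$pooled
  for (v in c("l12_s1", "l13_s1", "l23_s1", "p2_mixed"))
    expect_lt(abs(s0[v, "mean"] - s1[v, "mean"]), s0[v, "sd"] + 0.02)
})

test_that("Z = 1 through the mixture path matches the single-state sampler", {
  d <- tiny_triangle_data(N = 50, sides = c(40, 50, 20),
                          sigma_xy = c(4, 4, 6), sigma_z = c(8, 8, 12),
                          seed = 43)
  fit1 <- suppressWarnings(polygon_fit(d, iterations = 1500, chains = 1, seed = 8))
  fitm <- suppressWarnings(
    polycorr:::mixture_fit_impl(d, Z = 1L, iterations = 1500, chains = 1,
                                burnin = 0.4, thin = NULL, seed = 8,
                                l_max = 1000, step_rotation = 0.3,
                                step_template = 2, adapt = TRUE,
                                informing = NULL, state_prior = NULL))
  s1 <- summarize_draws(fit1$draws, c("l12", "l13", "l23"))$pooled
  sm <- summarize_draws(fitm$draws, c("l12_s1", "l13_s1", "l23_s1"))$pooled
  for (i in 1:3)
    expect_lt(abs(s1[i, "mean"] - sm[i, "mean"]),
              3 * sqrt(s1[i, "sd"]^2 + sm[i, "sd"]^2) / sqrt(10) + 0.3)
})

test_that("infeasible occupancy and unknown informing subsets are rejected", {
  d <- tiny_triangle_data(N = 4, seed = 44)
  expect_error(
    polygon_fit(d, states = 2, iterations = 100, informing = list(nope = 2)),
    "not present")
  expect_error(
    polygon_fit(d, states = 2, iterations = 100),
    "occupancy")
})
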