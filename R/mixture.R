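#' Informative prior for the anchor state of a mixture fit
#'
#' Bounded-support prior applied to state 1 in multi-state runs to limit
#' exploration during burn-in: independent truncated Gaussians on the
#' state-1 edge lengths and per-fluorophore errors, centred on reference
#' values. The length part is wide relative to typical length posteriors,
#' so its impact on the inferred geometry is negligible (the package's
#' mixture tests check this directly); the error part is deliberately not
#' weak - it pins the anchor state's localization errors near their
#' references, which prevents the anchor state from inflating its errors to
#' absorb measurements of other states, a degeneracy that otherwise
#' produces long-lived contaminated sampler states.
#'
#' @param lengths reference edge lengths for state 1 (nm), in the order of
#'   [edge_lengths()]; must satisfy polygon constraints.
#' @param sigma_xy,sigma_z reference per-fluorophore errors (nm).
#' @param sd_length,sd_sigma Gaussian scale of the length / error terms (nm).
#' @param halfwidth_length,halfwidth_sigma half-width of the truncation
#'   window around each reference value (nm).
#' @return object of class `state_prior`.
#' @export
informative_state_prior <- function(lengths, sigma_xy, sigma_z,
                                    sd_length = 10, halfwidth_length = 30,
                                    sd_sigma = 2, halfwidth_sigma = 6) {
  if (length(lengths) == 3L && !triangle_inequality_holds(lengths))
    stop("reference lengths violate the triangle inequality")
  if (any(lengths < 0) || any(sigma_xy <= 0) || any(sigma_z <= 0))
    stop("reference values must be non-negative lengths and positive sigmas")
  if (sd_length <= 0 || sd_sigma <= 0 || halfwidth_length <= 0 || halfwidth_sigma <= 0)
    stop("prior widths must be positive")
  structure(list(lengths = lengths, sigma_xy = sigma_xy, sigma_z = sigma_z,
                 sd_length = sd_length, halfwidth_length = halfwidth_length,
                 sd_sigma = sd_sigma, halfwidth_sigma = halfwidth_sigma),
            class = "state_prior")
}

# log density (up to a constant) of the informative state prior; -Inf
# outside the truncation window. Pieces are separable so the sigma part can
# be used alone in the error updates.
state_prior_length_logdensity <- function(lengths, prior) {
  d <- lengths - prior$lengths
  if (any(abs(d) > prior$halfwidth_length)) return(-Inf)
  -sum(d^2) / (2 * prior$sd_length^2)
}

state_prior_sigma_logdensity <- function(sigma_xy, sigma_z, prior) {
  dx <- sigma_xy - prior$sigma_xy
  dz <- sigma_z - prior$sigma_z
  if (any(abs(dx) > prior$halfwidth_sigma) || any(abs(dz) > prior$halfwidth_sigma))
    return(-Inf)
  -(sum(dx^2) + sum(dz^2)) / (2 * prior$sd_sigma^2)
}

#' Log density of the informative state prior
#'
#' @param lengths state-1 edge lengths (nm).
#' @param sigma_xy,sigma_z state-1 per-fluorophore errors (nm).
#' @param prior an [informative_state_prior()].
#' @return log density up to a constant; `-Inf` outside the support.
#' @export
state_prior_logdensity <- function(lengths, sigma_xy, sigma_z, prior) {
  stopifnot(inherits(prior, "state_prior"))
  state_prior_length_logdensity(lengths, prior) +
    state_prior_sigma_logdensity(sigma_xy, sigma_z, prior)
}

#' Log-likelihood of the multi-state mixture model
#'
#' Each measurement contributes the single-state Gaussian likelihood of its
#' own state's template and errors; with Z = 1 this is identical to
#' [polygon_loglik()].
#'
#' @param data a `polygon_data` data frame.
#' @param templates list of Z `polygon_template`s.
#' @param rotations N x 4 quaternion matrix or list of rotation matrices.
#' @param translations N x 3 matrix.
#' @param sigma_xy,sigma_z Z x J matrices of positive errors.
#' @param affiliations integer vector of per-measurement states (1..Z).
#' @return scalar log-likelihood.
#' @export
mixture_loglik <- function(data, templates, rotations, translations,
                           sigma_xy, sigma_z, affiliations) {
  if (inherits(templates, "polygon_template")) templates <- list(templates)
  Z <- length(templates)
  ms <- as_measurement_arrays(data)
  sigma_xy <- matrix(sigma_xy, nrow = Z)
  sigma_z <- matrix(sigma_z, nrow = Z)
  if (any(sigma_xy <= 0) || any(sigma_z <= 0)) stop("sigma values must be positive")
  q <- if (is.matrix(rotations) && ncol(rotations) == 4) rotations
       else do.call(rbind, lapply(rotations, matrix_to_quat))
  Tn <- as.matrix(translations)
  zeta <- as.integer(affiliations)
  if (length(zeta) != ms$N || any(zeta < 1) || any(zeta > Z))
    stop("'affiliations' must assign every measurement to a state in 1..Z")
  tot <- 0
  for (z in seq_len(Z)) {
    rows <- which(zeta == z)
    if (!length(rows)) next
    tot <- tot + sum(loglik_per_measurement(
      ms$Y, templates[[z]]$positions, q, Tn,
      list(xy = sigma_xy[z, ], z = sigma_z[z, ]), rows = rows))
  }
  tot
}

# Gibbs draw of one subset's state proportions: Dirichlet(1 + counts)
gibbs_proportions <- function(counts) {
  g <- stats::rgamma(length(counts), shape = 1 + counts, rate = 1)
  g / sum(g)
}

# Metropolis sweep over the free state affiliations. logL is the
# N_free x Z matrix of per-measurement log-likelihoods under each state;
# logp maps each free measurement to its subset's log proportions (vector
# list). counts is the global occupancy over free (non-informing)
# measurements; moves that would push a state below min_occ are rejected.
# Sequential scan, vectorized pre-computation.
mh_affiliations <- function(zeta, logL, subset_of, logp_by_subset, counts,
                            min_occ = 3L) {
  Nf <- length(zeta)
  Z <- ncol(logL)
  if (Z == 1) return(list(zeta = zeta, counts = counts, n_accept = 0L))
  prop <- zeta + sample.int(Z - 1L, Nf, replace = TRUE)
  prop <- ((prop - 1L) %% Z) + 1L            # uniform over the other states
  lu <- log(stats::runif(Nf))
  idx <- cbind(seq_len(Nf), zeta)
  idxp <- cbind(seq_len(Nf), prop)
  dL <- logL[idxp] - logL[idx]
  n_acc <- 0L
  for (n in seq_len(Nf)) {
    zc <- zeta[n]; zp <- prop[n]
    if (counts[zc] <= min_occ) next          # would drop below occupancy floor
    dlp <- logp_by_subset[[subset_of[n]]][zp] - logp_by_subset[[subset_of[n]]][zc]
    if (lu[n] < dL[n] + dlp) {
      zeta[n] <- zp
      counts[zc] <- counts[zc] - 1L
      counts[zp] <- counts[zp] + 1L
      n_acc <- n_acc + 1L
    }
  }
  list(zeta = zeta, counts = counts, n_accept = n_acc)
}

# marginal-over-translation log-likelihood of single measurements: with the
# flat translation prior, integrating T out of the Gaussian likelihood gives
# log m(state, R) = sum_j (1/2 log det tau_j) - 3/2 (J-1) log 2pi
#                   - 1/2 log det(sum_j tau_j) - 1/2 Q_min,
# Q_min the translation-minimized quadratic. Also returns the conditional
# mean/precision of T needed to redraw it after an accepted joint move.
marginal_T_loglik <- function(ms, templates, sig, zs, qs, rows) {
  n <- length(rows)
  J <- ms$J
  logm <- mx <- my <- mz <- pxy_out <- pz_out <- numeric(n)
  for (z in unique(zs)) {
    sel <- which(zs == z)
    r <- rows[sel]
    X <- templates[[z]]$positions
    pxy <- 1 / sig[[z]]$xy^2; pz <- 1 / sig[[z]]$z^2
    Pxy <- sum(pxy); Pz <- sum(pz)
    ax <- ay <- az <- Q <- numeric(length(sel))
    for (j in seq_len(J)) {
      d <- ms$Y[[j]][r, , drop = FALSE] -
        quat_rotate_vec(qs[sel, , drop = FALSE], X[j, ])
      ax <- ax + pxy[j] * d[, 1]
      ay <- ay + pxy[j] * d[, 2]
      az <- az + pz[j] * d[, 3]
      Q <- Q + pxy[j] * (d[, 1]^2 + d[, 2]^2) + pz[j] * d[, 3]^2
    }
    Qmin <- Q - (ax^2 + ay^2) / Pxy - az^2 / Pz
    logc <- sum(-2 * log(sig[[z]]$xy) - log(sig[[z]]$z)) -
      1.5 * (J - 1) * log(2 * pi) - 0.5 * (2 * log(Pxy) + log(Pz))
    logm[sel] <- logc - 0.5 * Qmin
    mx[sel] <- ax / Pxy; my[sel] <- ay / Pxy; mz[sel] <- az / Pz
    pxy_out[sel] <- Pxy; pz_out[sel] <- Pz
  }
  list(logm = logm, mx = mx, my = my, mz = mz, Pxy = pxy_out, Pz = pz_out)
}

# Joint (state, rotation, translation) Metropolis move for the free
# measurements: proposes the other state together with a fresh Haar-uniform
# rotation, accepts on the translation-marginalized likelihood ratio, and
# redraws the translation from its exact Gaussian conditional on acceptance.
# This mode-jumping move breaks the metastable coupling between affiliations
# and perspectives (a flip usually requires a different orientation); the
# plain per-measurement affiliation flip is kept alongside it.
joint_state_perspective_move <- function(ms, templates, sig, q, Tn, zeta, free,
                                         subset_of_free, logp_by_subset, counts,
                                         min_occ = 3L) {
  Nf <- length(free)
  Z <- length(templates)
  if (Z == 1 || !Nf)
    return(list(q = q, Tn = Tn, zeta = zeta, counts = counts, n_accept = 0L))
  zf <- zeta[free]
  prop_z <- zf + sample.int(Z - 1L, Nf, replace = TRUE)
  prop_z <- ((prop_z - 1L) %% Z) + 1L
  qprop <- runif_quat(Nf)
  cur <- marginal_T_loglik(ms, templates, sig, zf, q[free, , drop = FALSE], free)
  prop <- marginal_T_loglik(ms, templates, sig, prop_z, qprop, free)
  lu <- log(stats::runif(Nf))
  n_acc <- 0L
  Tdraw <- cbind(prop$mx + stats::rnorm(Nf) / sqrt(prop$Pxy),
                 prop$my + stats::rnorm(Nf) / sqrt(prop$Pxy),
                 prop$mz + stats::rnorm(Nf) / sqrt(prop$Pz))
  for (i in seq_len(Nf)) {
    zc <- zeta[free[i]]; zp <- prop_z[i]
    if (counts[zc] <= min_occ) next
    dlp <- logp_by_subset[[subset_of_free[i]]][zp] -
           logp_by_subset[[subset_of_free[i]]][zc]
    if (lu[i] < prop$logm[i] - cur$logm[i] + dlp) {
      n <- free[i]
      zeta[n] <- zp
      q[n, ] <- qprop[i, ]
      Tn[n, ] <- Tdraw[i, ]
      counts[zc] <- counts[zc] - 1L
      counts[zp] <- counts[zp] + 1L
      n_acc <- n_acc + 1L
    }
  }
  list(q = q, Tn = Tn, zeta = zeta, counts = counts, n_accept = n_acc)
}

# sigma update for one state/fluorophore under the informative prior:
# flat-prior Gamma conditional as independence proposal, MH-corrected by
# the truncated-Gaussian prior ratio (exact; reduces to plain Gibbs with a
# flat prior).
gibbs_sigma_with_prior <- function(S_xy, S_z, N, current, j, prior) {
  cand <- gibbs_sigma(S_xy, S_z, N, current)
  cur_lp <- state_prior_sigma_logdensity(current[1], current[2],
              list(sigma_xy = prior$sigma_xy[j], sigma_z = prior$sigma_z[j],
                   sd_sigma = prior$sd_sigma, halfwidth_sigma = prior$halfwidth_sigma))
  cand_lp <- state_prior_sigma_logdensity(cand[["xy"]], cand[["z"]],
              list(sigma_xy = prior$sigma_xy[j], sigma_z = prior$sigma_z[j],
                   sd_sigma = prior$sd_sigma, halfwidth_sigma = prior$halfwidth_sigma))
  if (cand_lp == -Inf) return(c(xy = current[1], z = current[2]))
  if (log(stats::runif(1L)) < cand_lp - cur_lp) cand
  else c(xy = current[1], z = current[2])
}

run_mixture_chain <- function(ms, Z, cfg, chain_seed, informing, prior) {
  set.seed(chain_seed)
  J <- ms$J; N <- ms$N
  subset_names <- unique(ms$subset_id)
  informing_state <- stats::setNames(rep(NA_integer_, length(subset_names)), subset_names)
  for (nm in names(informing)) {
    if (!nm %in% subset_names) stop("informing subset '", nm, "' not present in data")
    informing_state[nm] <- as.integer(informing[[nm]])
  }
  mixed_subsets <- subset_names[is.na(informing_state)]
  free <- which(is.na(informing_state[ms$subset_id]))
  fixed <- setdiff(seq_len(N), free)
  if (length(free) < 3L * Z)
    stop("need at least 3 Z non-informing measurements for the occupancy constraint")

  ## --- initialization -----------------------------------------------------
  ## templates: informing states from their pure subsets; remaining states
  ## from the free measurements that informing states explain worst (a
  ## residual-based split), so a minority state is not initialized on top of
  ## the anchored one
  informing_states <- sort(unique(informing_state[!is.na(informing_state)]))
  templates <- vector("list", Z)
  sig <- vector("list", Z)
  for (z in informing_states) {
    inf_sub <- names(informing_state)[which(informing_state == z)]
    st <- initialize_chain(slice_ms(ms, which(ms$subset_id %in% inf_sub)))
    templates[[z]] <- st$template
    sig[[z]] <- st$sig
  }
  noninf_states <- setdiff(seq_len(Z), informing_states)
  if (length(noninf_states)) {
    pool <- free
    if (length(informing_states)) {
      best <- rep(-Inf, length(free))
      for (z in informing_states) {
        al <- align_to_template(ms, templates[[z]]$positions, rows = free)
        best <- pmax(best, loglik_per_measurement(
          ms$Y, templates[[z]]$positions, al$q, al$Tn, sig[[z]], rows = free))
      }
      ntake <- max(3L, ceiling(length(free) / 2))
      pool <- free[order(best)][seq_len(ntake)]     # worst-explained half
    }
    for (k in seq_along(noninf_states)) {
      z <- noninf_states[k]
      st <- initialize_chain(slice_ms(ms, pool), jitter = 2 * (k - 1))
      templates[[z]] <- st$template
      sig[[z]] <- st$sig
    }
  }
  ## the informative state-1 prior has bounded support: start inside it
  if (!is.null(prior)) {
    hw <- 0.9 * prior$halfwidth_sigma
    sig[[1]]$xy <- pmin(pmax(sig[[1]]$xy, prior$sigma_xy - hw), prior$sigma_xy + hw)
    sig[[1]]$z <- pmin(pmax(sig[[1]]$z, prior$sigma_z - hw), prior$sigma_z + hw)
    sig[[1]]$xy <- pmax(sig[[1]]$xy, 0.5); sig[[1]]$z <- pmax(sig[[1]]$z, 0.5)
    l1 <- edge_lengths(templates[[1]])
    if (any(abs(l1 - prior$lengths) > prior$halfwidth_length) && J == 3)
      templates[[1]] <- triangle_template(prior$lengths[1], prior$lengths[2],
                                          prior$lengths[3])
  }

  ## affiliations: per-state Kabsch alignment, assign by aligned likelihood
  als <- lapply(seq_len(Z), function(z) align_to_template(ms, templates[[z]]$positions))
  logL <- vapply(seq_len(Z), function(z)
    loglik_per_measurement(ms$Y, templates[[z]]$positions,
                           als[[z]]$q, als[[z]]$Tn, sig[[z]]),
    numeric(N))
  zeta <- max.col(logL)
  zeta[fixed] <- informing_state[ms$subset_id[fixed]]
  counts <- tabulate(zeta[free], nbins = Z)
  for (z in seq_len(Z)) {                    # enforce occupancy floor at start
    need <- 3L - counts[z]
    if (need > 0) {
      cand <- free[order(logL[free, z], decreasing = TRUE)]
      cand <- cand[zeta[cand] != z]
      for (i in seq_len(need)) {
        counts[zeta[cand[i]]] <- counts[zeta[cand[i]]] - 1L
        zeta[cand[i]] <- z
        counts[z] <- counts[z] + 1L
      }
    }
  }
  q <- als[[1]]$q; Tn <- als[[1]]$Tn
  for (z in seq_len(Z)) {
    rows <- which(zeta == z)
    q[rows, ] <- als[[z]]$q[rows, , drop = FALSE]
    Tn[rows, ] <- als[[z]]$Tn[rows, , drop = FALSE]
  }
  if (!is.null(cfg$init)) {      # explicit starting point (diagnostics)
    ini <- cfg$init
    if (!is.null(ini$templates)) templates <- ini$templates
    if (!is.null(ini$sig)) sig <- ini$sig
    if (!is.null(ini$zeta)) {
      zeta <- ini$zeta
      zeta[fixed] <- informing_state[ms$subset_id[fixed]]
      counts <- tabulate(zeta[free], nbins = Z)
      als2 <- lapply(seq_len(Z), function(z)
        align_to_template(ms, templates[[z]]$positions, rows = which(zeta == z)))
      for (z in seq_len(Z)) {
        rows <- which(zeta == z)
        q[rows, ] <- als2[[z]]$q[rows, , drop = FALSE]
        Tn[rows, ] <- als2[[z]]$Tn[rows, , drop = FALSE]
      }
    }
  }
  p <- stats::setNames(vector("list", length(mixed_subsets)), mixed_subsets)
  for (s in mixed_subsets) {
    cs <- tabulate(zeta[ms$subset_id == s & seq_len(N) %in% free], nbins = Z)
    p[[s]] <- (cs + 1) / sum(cs + 1)
  }
  subset_of_free <- ms$subset_id[free]

  ## --- sweep loop ----------------------------------------------------------
  blocks <- template_blocks(J)
  step_rot <- cfg$step_rotation
  step_tpl <- matrix(cfg$step_template, Z, length(blocks))
  n_iter <- cfg$iterations
  n_burn <- floor(cfg$burnin * n_iter)
  thin <- cfg$thin
  keep_at <- seq(n_burn + thin, n_iter, by = thin)
  idx2 <- utils::combn(J, 2)
  len_names <- apply(idx2, 2, function(ij) paste0("l", ij[1], ij[2]))
  per_state_cols <- function(z) c(paste0(len_names, "_s", z),
                                  if (J == 3) paste0("angle", 1:3, "_s", z),
                                  paste0("sigma", seq_len(J), "_xy_s", z),
                                  paste0("sigma", seq_len(J), "_z_s", z))
  prop_cols <- unlist(lapply(mixed_subsets, function(s) paste0("p", seq_len(Z), "_", s)))
  cn <- c(unlist(lapply(seq_len(Z), per_state_cols)), prop_cols, "log_posterior")
  draws <- matrix(NA_real_, length(keep_at), length(cn))
  colnames(draws) <- cn
  zeta_accum <- matrix(0, N, Z)
  n_accum <- 0L
  acc_rot <- acc_aff <- 0; acc_n <- 0
  win_rot <- 0; win_tpl <- matrix(0, Z, length(blocks)); win_n <- 0
  krow <- 0L

  for (it in seq_len(n_iter)) {
    ## translations and rotations, per state (exact Gibbs / Metropolis)
    rot_acc_it <- 0
    for (z in seq_len(Z)) {
      rows <- which(zeta == z)
      if (!length(rows)) next
      Yz <- lapply(ms$Y, function(m) m[rows, , drop = FALSE])
      Tn[rows, ] <- gibbs_translation(Yz, templates[[z]]$positions,
                                      q[rows, , drop = FALSE], sig[[z]])
      ru <- mh_rotations(Yz, templates[[z]]$positions, q[rows, , drop = FALSE],
                         Tn[rows, , drop = FALSE], sig[[z]], step_rot)
      q[rows, ] <- ru$q
      rot_acc_it <- rot_acc_it + ru$n_accept
    }
    ## templates, per state (with the informative prior on state 1)
    for (z in if (isTRUE(cfg$init$fix_params)) integer(0) else seq_len(Z)) {
      rows <- which(zeta == z)
      if (!length(rows)) next
      Yz <- lapply(ms$Y, function(m) m[rows, , drop = FALSE])
      tu <- mh_template_state(Yz, templates[[z]], q[rows, , drop = FALSE],
                              Tn[rows, , drop = FALSE], sig[[z]], step_tpl[z, ],
                              cfg$l_max, if (z == 1L) prior else NULL)
      templates[[z]] <- tu$template
      win_tpl[z, ] <- win_tpl[z, ] + tu$n_accept
    }
    ## measurement errors, per state and fluorophore
    for (z in if (isTRUE(cfg$init$fix_params)) integer(0) else seq_len(Z)) {
      rows <- which(zeta == z)
      if (length(rows) < 1) next
      Yz <- lapply(ms$Y, function(m) m[rows, , drop = FALSE])
      rs <- residual_sums(Yz, templates[[z]]$positions, q[rows, , drop = FALSE],
                          Tn[rows, , drop = FALSE])
      for (j in seq_len(J)) {
        cur <- c(sig[[z]]$xy[j], sig[[z]]$z[j])
        s <- if (z == 1L && !is.null(prior))
          gibbs_sigma_with_prior(rs$S_xy[j], rs$S_z[j], length(rows), cur, j, prior)
        else gibbs_sigma(rs$S_xy[j], rs$S_z[j], length(rows), cur)
        sig[[z]]$xy[j] <- s[["xy"]]; sig[[z]]$z[j] <- s[["z"]]
      }
    }
    ## state affiliations (free measurements only) and proportions: the
    ## plain flip plus the collapsed (state, rotation, translation) move
    if (Z > 1 && length(free)) {
      logp <- lapply(p, log)
      logL_free <- per_state_loglik(ms, templates, sig, q, Tn, rows = free)
      au <- mh_affiliations(zeta[free], logL_free, subset_of_free, logp, counts)
      zeta[free] <- au$zeta
      counts <- au$counts
      jacc <- 0L
      n_joint <- if (isTRUE(cfg$init$no_joint)) 0L else 3L
      for (rep in seq_len(n_joint)) {
        jm <- joint_state_perspective_move(ms, templates, sig, q, Tn, zeta, free,
                                           subset_of_free, logp, counts)
        q <- jm$q; Tn <- jm$Tn; zeta <- jm$zeta; counts <- jm$counts
        jacc <- jacc + jm$n_accept
      }
      acc_aff_it <- (au$n_accept + jacc / max(n_joint, 1)) / (2 * length(free))
    } else acc_aff_it <- 0
    for (s in mixed_subsets) {
      cs <- tabulate(zeta[intersect(which(ms$subset_id == s), free)], nbins = Z)
      p[[s]] <- gibbs_proportions(cs)
    }
    ## adaptation / bookkeeping
    win_rot <- win_rot + rot_acc_it / N
    win_n <- win_n + 1
    if (it <= n_burn && cfg$adapt && it %% 50 == 0) {
      step_rot <- min(max(step_rot * exp(0.6 * (win_rot / win_n - 0.3)), 1e-4), pi)
      step_tpl <- pmin(pmax(step_tpl * exp(0.6 * (win_tpl / win_n - 0.3)), 1e-4), 200)
      win_rot <- 0; win_tpl[] <- 0; win_n <- 0
    }
    if (it > n_burn) {
      acc_rot <- acc_rot + rot_acc_it / N
      acc_aff <- acc_aff + acc_aff_it
      acc_n <- acc_n + 1
      zeta_accum[cbind(seq_len(N), zeta)] <- zeta_accum[cbind(seq_len(N), zeta)] + 1
      n_accum <- n_accum + 1L
      stopifnot(all(tabulate(zeta[free], nbins = Z) >= 3L))
    }
    if (krow < length(keep_at) && it == keep_at[krow + 1L]) {
      krow <- krow + 1L
      row <- numeric(0)
      lp <- 0
      for (z in seq_len(Z)) {
        lens <- edge_lengths(templates[[z]])
        row <- c(row, lens, if (J == 3) internal_angles(lens) else NULL,
                 sig[[z]]$xy, sig[[z]]$z)
        lp <- lp + template_log_prior(templates[[z]], cfg$l_max)
      }
      for (s in mixed_subsets) row <- c(row, p[[s]])
      ll <- mixture_loglik_arrays(ms, templates, sig, q, Tn, zeta)
      for (s in mixed_subsets) {
        rows_s <- intersect(which(ms$subset_id == s), free)
        lp <- lp + sum(log(p[[s]][zeta[rows_s]]))
      }
      if (!is.null(prior))
        lp <- lp + state_prior_logdensity(edge_lengths(templates[[1]]),
                                          sig[[1]]$xy, sig[[1]]$z, prior)
      draws[krow, ] <- c(row, ll + lp)
    }
  }
  list(draws = as.data.frame(draws),
       zbar = zeta_accum / max(n_accum, 1L),
       acceptance = c(rotation = acc_rot / max(acc_n, 1),
                      affiliation = acc_aff / max(acc_n, 1)),
       mixed_subsets = mixed_subsets)
}

# template Metropolis update with an optional informative prior on the
# state's lengths
mh_template_state <- function(Y, tpl, q, Tn, sig, steps, l_max, prior) {
  if (is.null(prior)) return(mh_template(Y, tpl, q, Tn, sig, steps, l_max))
  J <- tpl$J
  co <- template_free_coords(tpl)
  lp <- template_log_prior(tpl, l_max) +
    state_prior_length_logdensity(edge_lengths(tpl), prior)
  blocks <- template_blocks(J)
  n_acc <- integer(length(blocks))
  for (b in seq_along(blocks)) {
    idx <- blocks[[b]]$idx; node <- blocks[[b]]$node
    co_new <- co
    co_new[idx] <- co[idx] + stats::rnorm(length(idx), 0, steps[b])
    if (!free_coords_valid(co_new, J)) next
    tpl_new <- template_from_free_coords(co_new, J)
    lp_new <- template_log_prior(tpl_new, l_max) +
      state_prior_length_logdensity(edge_lengths(tpl_new), prior)
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

# N x Z matrix of full per-measurement log-likelihoods under each state
per_state_loglik <- function(ms, templates, sig, q, Tn, rows = NULL) {
  if (is.null(rows)) rows <- seq_len(ms$N)
  Z <- length(templates)
  out <- matrix(0, length(rows), Z)
  for (z in seq_len(Z))
    out[, z] <- loglik_per_measurement(ms$Y, templates[[z]]$positions, q, Tn,
                                       sig[[z]], rows = rows)
  out
}

mixture_loglik_arrays <- function(ms, templates, sig, q, Tn, zeta) {
  tot <- 0
  for (z in seq_along(templates)) {
    rows <- which(zeta == z)
    if (!length(rows)) next
    tot <- tot + sum(loglik_per_measurement(ms$Y, templates[[z]]$positions,
                                            q, Tn, sig[[z]], rows = rows))
  }
  tot
}

mixture_fit_impl <- function(data, Z, iterations, chains, burnin, thin, seed,
                             l_max, step_rotation, step_template, adapt,
                             informing, state_prior, init = NULL) {
  ms <- as_measurement_arrays(data)
  if (!is.null(state_prior)) stopifnot(inherits(state_prior, "state_prior"))
  if (is.null(thin)) thin <- max(1L, floor((1 - burnin) * iterations / 1000))
  cfg <- list(iterations = as.integer(iterations), burnin = burnin,
              thin = as.integer(thin), l_max = l_max,
              step_rotation = step_rotation, step_template = step_template,
              adapt = adapt, chains = as.integer(chains), seed = as.integer(seed),
              init = init)
  res <- vector("list", chains)
  for (ch in seq_len(chains)) {
    res[[ch]] <- run_mixture_chain(ms, Z, cfg, chain_stream_seed(seed, ch),
                                   informing, state_prior)
    res[[ch]]$draws$chain <- ch
  }
  res <- align_mixture_chains(res, Z, ms$J)
  draws <- do.call(rbind, lapply(res, `[[`, "draws"))
  zbar <- Reduce(`+`, lapply(res, `[[`, "zbar")) / chains
  keep <- setdiff(colnames(draws), c("chain", "log_posterior"))
  fit <- structure(list(
    draws = draws,
    zbar = zbar,
    acceptance = lapply(res, `[[`, "acceptance"),
    rhat = split_rhat(draws, keep),
    config = cfg, J = ms$J, N = ms$N, states = Z,
    mixed_subsets = res[[1]]$mixed_subsets,
    informing = informing,
    measurement_ids = ms$ids,
    subset_id = ms$subset_id), class = c("polygon_mixfit", "polygon_fit"))
  warn_rhat(fit$rhat)
  fit
}

# post-hoc label alignment across chains: permute states of chains > 1 to
# match chain 1's posterior-mean length vectors (label switching is not
# penalized during sampling)
align_mixture_chains <- function(res, Z, J) {
  if (length(res) < 2 || Z < 2) return(res)
  len_cols <- function(z) grep(paste0("^l[0-9]+_s", z, "$"),
                               colnames(res[[1]]$draws), value = TRUE)
  ref <- vapply(seq_len(Z), function(z) colMeans(res[[1]]$draws[len_cols(z)]),
                numeric(length(len_cols(1))))
  perms <- all_permutations(Z)
  for (ch in seq_along(res)[-1]) {
    cur <- vapply(seq_len(Z), function(z) colMeans(res[[ch]]$draws[len_cols(z)]),
                  numeric(nrow(ref)))
    cost <- vapply(perms, function(pm) sum((cur[, pm, drop = FALSE] - ref)^2), 0)
    pm <- perms[[which.min(cost)]]
    if (identical(pm, seq_len(Z))) next
    d <- res[[ch]]$draws
    new <- d
    for (z in seq_len(Z)) {
      from <- grep(paste0("_s", pm[z], "$"), colnames(d), value = TRUE)
      to <- sub(paste0("_s", pm[z], "$"), paste0("_s", z), from)
      new[to] <- d[from]
      pcols_from <- grep(paste0("^p", pm[z], "_"), colnames(d), value = TRUE)
      pcols_to <- sub(paste0("^p", pm[z]), paste0("p", z), pcols_from)
      new[pcols_to] <- d[pcols_from]
    }
    res[[ch]]$draws <- new
    res[[ch]]$zbar <- res[[ch]]$zbar[, pm, drop = FALSE]
  }
  res
}

all_permutations <- function(Z) {
  if (Z == 1) return(list(1L))
  out <- list()
  rec <- function(head, rest) {
    if (!length(rest)) { out[[length(out) + 1L]] <<- head; return(invisible()) }
    for (i in seq_along(rest)) rec(c(head, rest[i]), rest[-i])
  }
  rec(integer(0), seq_len(Z))
  out
}

#' Mean state affiliations and evidence-based classification
#'
#' For a two-state fit, the mean state affiliation of measurement n is the
#' posterior fraction of MCMC samples in which it belongs to state 2.
#' Measurements are labelled `"state1"` when this fraction is at most 0.24,
#' `"state2"` when at least 0.76 (substantial-evidence thresholds, i.e.
#' Bayes factor >= 3.2 against even odds), and `"undecided"` otherwise.
#' Members of state-informing subsets have fixed affiliations, hence mean
#' affiliation exactly 0 or 1.
#'
#' @param fit a `polygon_mixfit` from [polygon_fit()] with `states = 2`.
#' @param lower,upper classification thresholds.
#' @return data frame with columns `measurement_id`, `subset_id`, `zbar`,
#'   `label`.
#' @export
state_affiliations <- function(fit, lower = 0.24, upper = 0.76) {
  stopifnot(inherits(fit, "polygon_mixfit"))
  if (fit$states != 2L)
    stop("thresholded classification is defined for two-state fits")
  zbar <- fit$zbar[, 2]
  label <- ifelse(zbar <= lower, "state1",
                  ifelse(zbar >= upper, "state2", "undecided"))
  data.frame(measurement_id = fit$measurement_ids,
             subset_id = fit$subset_id, zbar = zbar, label = label)
}
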