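#' Triangle-inequality violation rate of resampled length triples
#'
#' Given three marginal posterior sample vectors for the lengths of a
#' triangle (typically from three independent pair-wise fits), resamples
#' triples independently with replacement and returns the fraction that
#' strictly violate the triangle inequality, with its binomial standard
#' error. With `joint = TRUE` the three vectors are treated as aligned
#' draws from a joint posterior and checked row by row (for any joint
#' polygon posterior this rate is exactly zero, since each draw is a
#' realized triangle).
#'
#' @param l12,l13,l23 numeric sample vectors of the three lengths (nm).
#' @param n_resamples number of independently resampled triples.
#' @param joint treat the vectors as index-aligned joint draws.
#' @param seed optional seed for the resampling.
#' @return list with `rate`, `se`, `n`.
#' @export
violation_rate <- function(l12, l13, l23, n_resamples = 1e5, joint = FALSE,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (joint) {
    if (length(l12) != length(l13) || length(l12) != length(l23))
      stop("joint draws must be index-aligned (equal lengths)")
    L <- cbind(l12, l13, l23)
  } else {
    n <- as.integer(n_resamples)
    resamp <- function(x) x[sample.int(length(x), n, replace = TRUE)]
    L <- cbind(resamp(l12), resamp(l13), resamp(l23))
  }
  viol <- !triangle_inequality_holds(L)
  rate <- mean(viol)
  list(rate = rate, se = sqrt(rate * (1 - rate) / nrow(L)), n = nrow(L))
}

#' Consensus ("average") polygon of template samples
#'
#' Computes the polygon minimizing the summed squared Euclidean distance to
#' a set of sampled templates, each allowed its own rigid motion:
#' alternating minimization between (i) optimal proper-rotation alignment
#' of every sample to the current consensus (closed-form orthogonal
#' alignment; reflections excluded since templates live in a
#' chirality-fixed canonical chart) and (ii) the node-wise mean as the new
#' consensus. The objective is non-increasing and iteration stops when its
#' decrease falls below `tol`.
#'
#' @param templates list of `polygon_template`s, or an S x J x 3 array, or
#'   a `polygon_fit` (its stored template draws are used).
#' @param tol convergence tolerance on the objective decrease.
#' @param max_iter iteration cap.
#' @return list with `consensus` (a `polygon_template`), `aligned`
#'   (S x J x 3 array of aligned node clouds), `objective`, `iterations`.
#' @export
average_polygon <- function(templates, tol = 1e-10, max_iter = 200L) {
  A <- template_array(templates)
  S <- dim(A)[1]; J <- dim(A)[2]
  cons <- A[1, , ]
  if (J == 1) stop("need J >= 2 nodes")
  aligned <- A
  obj_old <- Inf
  iters <- 0L
  repeat {
    iters <- iters + 1L
    cc <- colMeans(cons)
    Cc <- sweep(cons, 2, cc)
    for (s in seq_len(S)) {
      P <- A[s, , ]
      pc <- colMeans(P)
      Pc <- sweep(P, 2, pc)
      R <- kabsch_rotation(Pc, Cc)
      aligned[s, , ] <- sweep(Pc %*% t(R), 2, cc, "+")
    }
    cons_new <- apply(aligned, c(2, 3), mean)
    obj <- sum(sweep(aligned, c(2, 3), cons_new)^2)
    if (obj_old - obj < tol * max(1, obj) || iters >= max_iter) {
      cons <- cons_new
      break
    }
    cons <- cons_new
    obj_old <- obj
  }
  list(consensus = standardize_polygon(cons)$template,
       aligned = aligned, objective = obj, iterations = iters)
}

template_array <- function(templates) {
  if (inherits(templates, "polygon_fit")) {
    tplcols <- grep("^tpl", colnames(templates$draws), value = TRUE)
    if (!length(tplcols)) {
      lens <- templates$draws[, c("l12", "l13", "l23")]
      A <- array(0, c(nrow(lens), 3, 3))
      for (s in seq_len(nrow(lens)))
        A[s, , ] <- triangle_template(lens[s, 1], lens[s, 2], lens[s, 3])$positions
      return(A)
    }
    J <- templates$J
    A <- array(0, c(nrow(templates$draws), J, 3))
    for (s in seq_len(nrow(templates$draws)))
      A[s, , ] <- template_from_free_coords(
        as.numeric(templates$draws[s, tplcols]), J)$positions
    return(A)
  }
  if (is.array(templates) && length(dim(templates)) == 3) return(templates)
  if (inherits(templates, "polygon_template")) templates <- list(templates)
  S <- length(templates); J <- templates[[1]]$J
  A <- array(0, c(S, J, 3))
  for (s in seq_len(S)) A[s, , ] <- templates[[s]]$positions
  A
}

#' Number of inferred parameters of each correction method
#'
#' Counts the free parameters the posterior explores. Pair-wise: one length
#' plus the error scale(s) plus five perspective parameters per measurement
#' (three translation components and a direction on the sphere). Polygon
#' (single state): the template's free canonical coordinates (1 for J = 2,
#' 3J - 6 for J >= 3) plus 2J error scales plus six perspective parameters
#' per measurement. Multi-state: Z copies of the template and error
#' parameters, Z - 1 proportions per mixed subset, six perspective
#' parameters for every measurement, and one affiliation per non-informing
#' measurement.
#'
#' @param J number of fluorophores.
#' @param N measurements: a single count, or for `method = "mixture"` a
#'   vector of subset sizes.
#' @param Z number of states (mixture only).
#' @param method `"pairwise"`, `"polygon"`, or `"mixture"`.
#' @param isotropic for `"pairwise"`: isotropic (one sigma) vs anisotropic
#'   (two).
#' @param n_informing for `"mixture"`: number of measurements in
#'   state-informing (pure) subsets, which have fixed affiliations.
#' @param n_mixed_subsets for `"mixture"`: number of subsets with free
#'   proportions (default: all subsets not fully informing).
#' @return integer parameter count.
#' @examples
#' parameter_count(J = 3, N = 400, method = "pairwise", isotropic = TRUE)  # 2002
#' parameter_count(J = 3, N = 400, method = "polygon")                     # 2409
#' parameter_count(J = 3, N = c(600, 600), Z = 2, method = "mixture",
#'                 n_informing = 600)                                      # 7819
#' @export
parameter_count <- function(J, N, Z = 1L, method = c("polygon", "pairwise", "mixture"),
                            isotropic = TRUE, n_informing = 0L,
                            n_mixed_subsets = NULL) {
  method <- match.arg(method)
  if (J < 2 || any(N < 1)) stop("need J >= 2 and N >= 1")
  template_dof <- if (J == 2) 1L else 3L * J - 6L
  error_dof <- 2L * J
  switch(method,
    pairwise = {
      if (length(N) != 1) stop("pairwise expects a single N")
      as.integer((if (isotropic) 2L else 3L) + 5L * N)
    },
    polygon = {
      if (length(N) != 1) stop("polygon expects a single N")
      as.integer(template_dof + error_dof + 6L * N)
    },
    mixture = {
      Ntot <- sum(N)
      if (is.null(n_mixed_subsets)) {
        n_inf_subsets <- if (n_informing > 0) 1L else 0L
        n_mixed_subsets <- length(N) - n_inf_subsets
      }
      as.integer(Z * (template_dof + error_dof) +
                 (Z - 1L) * n_mixed_subsets + 6L * Ntot + (Ntot - n_informing))
    })
}

#' Posterior summary of a sample table
#'
#' Per-column mean, standard deviation and central 95% credible interval,
#' pooled and (when a `chain` column is present) per chain.
#'
#' @param draws data frame of posterior draws (e.g. `fit$draws`).
#' @param columns which columns to summarize (default: all numeric except
#'   bookkeeping columns).
#' @return list with `pooled` (matrix) and `per_chain` (list of matrices).
#' @export
summarize_draws <- function(draws, columns = NULL) {
  if (nrow(draws) == 0) stop("empty sample set")
  if (is.null(columns))
    columns <- setdiff(names(draws)[vapply(draws, is.numeric, TRUE)],
                       c("chain", "iteration"))
  smy <- function(d) t(vapply(columns, function(cl) {
    x <- d[[cl]]
    c(mean = mean(x), sd = stats::sd(x),
      `2.5%` = unname(stats::quantile(x, 0.025)),
      `97.5%` = unname(stats::quantile(x, 0.975)))
  }, numeric(4)))
  per_chain <- if ("chain" %in% names(draws))
    lapply(split(draws, draws$chain), smy) else NULL
  list(pooled = smy(draws), per_chain = per_chain)
}
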