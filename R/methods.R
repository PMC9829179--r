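#' @export
print.polygon_fit <- function(x, ...) {
  cat(sprintf("Bayesian polygon fit: J = %d fluorophores, N = %d measurements\n",
              x$J, x$N))
  cat(sprintf("%d chain(s) x %d iterations (%.0f%% burn-in), %d stored draws\n",
              x$config$chains, x$config$iterations, 100 * x$config$burnin,
              nrow(x$draws)))
  if (inherits(x, "polygon_mixfit"))
    cat(sprintf("mixture of %d states; mixed subsets: %s\n", x$states,
                paste(x$mixed_subsets, collapse = ", ")))
  lens <- grep("^l[0-9]+", names(x$draws), value = TRUE)
  s <- summarize_draws(x$draws, lens)$pooled
  cat("Posterior edge lengths (nm):\n")
  print(round(s, 2))
  if (any(is.finite(x$rhat) & x$rhat > 1.05))
    cat("note: some split-Rhat > 1.05; consider longer chains\n")
  invisible(x)
}

#' @export
summary.polygon_fit <- function(object, ...) {
  cols <- setdiff(names(object$draws)[vapply(object$draws, is.numeric, TRUE)],
                  c("chain", grep("^tpl", names(object$draws), value = TRUE)))
  out <- list(summary = summarize_draws(object$draws, cols)$pooled,
              rhat = object$rhat,
              acceptance = object$acceptance,
              N = object$N, J = object$J, states = object$states)
  class(out) <- "summary.polygon_fit"
  out
}

#' @export
print.summary.polygon_fit <- function(x, ...) {
  cat(sprintf("Posterior summary (J = %d, N = %d, Z = %d)\n", x$J, x$N, x$states))
  print(round(x$summary, 3))
  cat("split-Rhat:\n")
  print(round(x$rhat, 3))
  invisible(x)
}

#' @export
coef.polygon_fit <- function(object, ...) {
  cols <- grep("^(l[0-9]+|sigma|p[0-9]+_)", names(object$draws), value = TRUE)
  vapply(object$draws[cols], mean, 0)
}

#' Trace and density plots for a polygon fit
#'
#' Base-graphics diagnostics: for each selected quantity, the per-chain
#' trace of the stored draws and the pooled histogram.
#'
#' @param x a `polygon_fit`.
#' @param pars which columns to plot (default: the edge lengths).
#' @param ... unused.
#' @export
plot.polygon_fit <- function(x, pars = NULL, ...) {
  if (is.null(pars)) pars <- grep("^l[0-9]+", names(x$draws), value = TRUE)
  pars <- intersect(pars, names(x$draws))
  old <- graphics::par(mfrow = c(length(pars), 2), mar = c(3, 3, 2, 1))
  on.exit(graphics::par(old))
  for (p in pars) {
    chains <- split(x$draws[[p]], x$draws$chain)
    graphics::plot(chains[[1]], type = "l", col = 1, main = paste("trace:", p),
                   xlab = "", ylab = p,
                   ylim = range(x$draws[[p]]))
    if (length(chains) > 1)
      for (ch in 2:length(chains)) graphics::lines(chains[[ch]], col = ch)
    graphics::hist(x$draws[[p]], breaks = 40, main = paste("posterior:", p),
                   xlab = p)
  }
  invisible(x)
}
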