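#' Bound-constrained derivative-free compass search
#'
#' Minimizes `fn` over a box by coordinate (compass) search: each sweep
#' probes `x +/- step_i * e_i` for every coordinate, accepts the best
#' improving probe, and halves every step size when no probe improves.
#' Iterates are always feasible (probes are clamped to the box) and the
#' sequence of accepted objective values is non-increasing by construction,
#' which makes the method suitable for the monotone-acceptance contract of
#' the estimation routines.
#'
#' @param fn objective function of a numeric vector; must return a finite
#'   scalar (use a large penalty value for infeasible points).
#' @param x0 feasible starting point.
#' @param lower,upper bounds (recycled); `upper` may be `Inf`.
#' @param step0 initial step sizes (recycled); default `0.25 * pmax(|x0|, 1)`.
#' @param step_tol terminate when all steps fall below `step_tol *
#'   pmax(|x|, 1)` (default 1e-9).
#' @param max_eval maximum number of objective evaluations (default 2e4).
#' @param f_tol stop as soon as the objective falls to or below this value
#'   (default `-Inf`, i.e. never).
#' @return list with elements `par`, `value`, `trace` (accepted objective
#'   values, non-increasing), `evals`, and `converged`.
#' @export
compass_search <- function(fn, x0, lower = -Inf, upper = Inf, step0 = NULL,
                           step_tol = 1e-9, max_eval = 2e4, f_tol = -Inf) {
  n <- length(x0)
  lower <- rep_len(lower, n); upper <- rep_len(upper, n)
  x <- pmin(pmax(x0, lower), upper)
  if (is.null(step0)) step0 <- 0.25 * pmax(abs(x), 1)
  step <- rep_len(step0, n)
  f <- fn(x)
  evals <- 1L
  trace <- f
  repeat {
    if (f <= f_tol)
      return(list(par = x, value = f, trace = trace, evals = evals,
                  converged = TRUE))
    improved <- FALSE
    best_x <- x; best_f <- f
    for (i in seq_len(n)) {
      for (s in c(1, -1)) {
        xi <- x
        xi[i] <- min(max(x[i] + s * step[i], lower[i]), upper[i])
        if (xi[i] == x[i]) next
        fi <- fn(xi)
        evals <- evals + 1L
        if (fi < best_f) { best_f <- fi; best_x <- xi; improved <- TRUE }
        if (evals >= max_eval) break
      }
      if (evals >= max_eval) break
    }
    if (improved) {
      x <- best_x; f <- best_f
      trace <- c(trace, f)
    } else {
      step <- step / 2
    }
    if (all(step < step_tol * pmax(abs(x), 1)))
      return(list(par = x, value = f, trace = trace, evals = evals,
                  converged = TRUE))
    if (evals >= max_eval)
      return(list(par = x, value = f, trace = trace, evals = evals,
                  converged = FALSE))
  }
}

#' Multi-start wrapper around [compass_search()]
#'
#' Runs the compass search from `n_starts` starting points: the supplied
#' `x0` plus starts perturbed multiplicatively by factors drawn uniformly in
#' `[0.5, 2]` per coordinate, and returns the best run.
#'
#' @inheritParams compass_search
#' @param n_starts number of starts (default 1 = only `x0`).
#' @param seed integer seed controlling the perturbations.
#' @return as [compass_search()], plus `start_values` (best value per start).
#' @export
multistart_search <- function(fn, x0, lower = -Inf, upper = Inf,
                              n_starts = 1, seed = 1, ...) {
  n <- length(x0)
  lower <- rep_len(lower, n); upper <- rep_len(upper, n)
  set.seed(seed)
  starts <- list(x0)
  if (n_starts > 1) {
    for (k in seq_len(n_starts - 1)) {
      fac <- exp(stats::runif(n, log(0.5), log(2)))
      starts[[k + 1]] <- pmin(pmax(x0 * fac, lower), upper)
    }
  }
  best <- NULL
  vals <- numeric(n_starts)
  for (k in seq_len(n_starts)) {
    fit <- compass_search(fn, starts[[k]], lower, upper, ...)
    vals[k] <- fit$value
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  best$start_values <- vals
  best
}
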