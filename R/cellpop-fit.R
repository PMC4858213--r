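# Least-squares estimation of the population model from flow-cytometry
# style observations (phase fractions, dead fraction, optionally labeling
# index) per drug dose.

pop_predict_row <- function(theta, alpha = NULL, mu_deg, Delta, with_LI) {
  if (is.null(mu_deg)) mu_deg <- theta[["mu_pp"]]
  p <- tryCatch({
    if (is.null(alpha)) {
      pop_params(lambda1 = theta[["lambda1"]], T2 = theta[["T2"]],
                 T3 = theta[["T3"]], mu_p = theta[["mu_p"]],
                 mu_pp = theta[["mu_pp"]], mu_deg = mu_deg, Delta = Delta)
    } else {
      # balanced-growth relation eliminates lambda1 when alpha is known
      beta <- alpha + theta[["mu_p"]]
      den <- 2 * exp(-beta * (theta[["T2"]] + theta[["T3"]])) - 1
      if (den <= 0) stop("infeasible: alpha too large for these transit times")
      pop_params(lambda1 = beta / den, T2 = theta[["T2"]],
                 T3 = theta[["T3"]], mu_p = theta[["mu_p"]],
                 mu_pp = theta[["mu_pp"]], mu_deg = mu_deg, Delta = Delta,
                 alpha = alpha)
    }
  }, error = function(e) NULL)
  if (is.null(p)) return(NULL)
  obs <- tryCatch(phase_fractions(p), error = function(e) NULL)
  if (is.null(obs)) return(NULL)
  if (with_LI) obs$LI <- labeling_index(p)
  list(params = p, obs = obs)
}

fit_one_dose <- function(row, alpha = NULL, mu_deg, Delta, start,
                         step_tol = 1e-9, max_eval = 12000, n_starts = 3,
                         seed = 1) {
  with_LI <- "LI" %in% names(row) && is.finite(row[["LI"]])
  fields <- intersect(c("fG1", "fS", "fG2M", "fA", "fDead",
                        if (with_LI) "LI"), names(row))
  fields <- fields[vapply(fields, function(f) is.finite(row[[f]]), logical(1))]
  target <- unlist(row[fields])
  free <- if (is.null(alpha)) c("lambda1", "T2", "T3", "mu_p", "mu_pp")
          else c("T2", "T3", "mu_p", "mu_pp")
  th0 <- unlist(start[free])
  lo <- c(lambda1 = 1e-4, T2 = 0.02, T3 = 0.02, mu_p = 0, mu_pp = 1e-4)[free]
  hi <- c(lambda1 = 30, T2 = 5, T3 = 5, mu_p = 20, mu_pp = 30)[free]
  loss <- function(th) {
    names(th) <- free
    pr <- pop_predict_row(th, alpha, mu_deg, Delta, with_LI)
    if (is.null(pr)) return(1e8)
    sum((unlist(pr$obs[fields]) - target)^2)
  }
  opt <- multistart_search(loss, th0, lower = lo, upper = hi,
                           n_starts = n_starts, seed = seed,
                           step_tol = step_tol, max_eval = max_eval,
                           f_tol = 1e-18)
  # simplex polish (still derivative-free; bounds enforced by clamping);
  # accepted only if it improves, so the loss trace stays non-increasing
  if (opt$value > 1e-18) {
    clamp_loss <- function(th) loss(pmin(pmax(th, lo), hi))
    pol <- stats::optim(opt$par, clamp_loss, method = "Nelder-Mead",
                        control = list(maxit = 4000, reltol = 1e-15,
                                       parscale = pmax(abs(opt$par), 0.05)))
    for (rep in 1:2) {
      if (pol$value >= opt$value) break
      pol2 <- stats::optim(pmin(pmax(pol$par, lo), hi), clamp_loss,
                           method = "Nelder-Mead",
                           control = list(maxit = 4000, reltol = 1e-15,
                                          parscale = pmax(abs(pol$par), 0.05)))
      if (pol2$value < pol$value) pol <- pol2 else break
    }
    if (pol$value < opt$value) {
      opt$par <- pmin(pmax(pol$par, lo), hi)
      opt$value <- clamp_loss(pol$par)
      opt$trace <- c(opt$trace, opt$value)
    }
  }
  th <- opt$par; names(th) <- free
  pr <- pop_predict_row(th, alpha, mu_deg, Delta, with_LI = TRUE)
  list(params = pr$params, obs = pr$obs, loss = opt$value,
       trace = opt$trace, converged = opt$converged, fields = fields)
}

#' Fit the cell-population model to per-dose observations
#'
#' Bound-constrained least squares for the six-parameter population model,
#' dose by dose, with the balanced-growth relation imposed exactly.  For the
#' control (dose 0) row the externally measured growth rate `alpha_control`
#' is fixed and eliminates `lambda1` through the balanced-growth relation;
#' for treated rows the growth rate is derived from the fitted parameters.
#' The fragment clearance rate is not identifiable from composition data
#' and is fixed to the fitted control fragmentation rate for all doses.
#'
#' @param data data frame with columns `dose`, `fG1`, `fS`, `fG2M`,
#'   `fDead`, and optionally `fA` and `LI` (absolute labeled fraction) or
#'   `LI_ratio` (treated/control ratio, converted using the fitted control
#'   labeling index).  Control is the `dose == 0` row.
#' @param alpha_control growth rate (1/day) of the untreated population,
#'   measured independently (e.g. from a growth curve).
#' @param Delta labeling period (day), default 0.25.
#' @param start named list of starting values for `lambda1`, `T2`, `T3`,
#'   `mu_p`, `mu_pp`.
#' @param n_starts multistart runs per dose (default 3).
#' @param seed integer seed for multistart perturbations.
#' @param step_tol,max_eval compass-search controls.
#' @return an object of class `cellpop_fit`: list with `estimates` (data
#'   frame of fitted parameters, derived `alpha` and doubling/halving time
#'   per dose), `fits` (per-dose detail including monotone loss traces),
#'   `data`, `alpha_control`, `mu_deg`.
#' @export
cellpop_fit <- function(data, alpha_control, Delta = 0.25,
                        start = list(lambda1 = 0.5, T2 = 0.4, T3 = 0.3,
                                     mu_p = 0.1, mu_pp = 0.5),
                        n_starts = 3, seed = 1,
                        step_tol = 1e-9, max_eval = 12000) {
  if (!"dose" %in% names(data)) stop("data must have a dose column")
  need <- c("fG1", "fS", "fG2M", "fDead")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("data lacks columns: ", paste(miss, collapse = ", "))
  if (!any(data$dose == 0)) stop("data must contain a control (dose 0) row")
  data <- data[order(data$dose), , drop = FALSE]

  ctrl_row <- as.list(data[data$dose == 0, , drop = FALSE][1, ])
  ctrl <- fit_one_dose(ctrl_row, alpha = alpha_control, mu_deg = NULL,
                       Delta = Delta, start = start, step_tol = step_tol,
                       max_eval = max_eval, n_starts = n_starts, seed = seed)
  mu_deg <- ctrl$params$mu_pp

  # refit control with mu_deg fixed at its own mu_pp (self-consistency)
  ctrl <- fit_one_dose(ctrl_row, alpha = alpha_control, mu_deg = mu_deg,
                       Delta = Delta, start = start, step_tol = step_tol,
                       max_eval = max_eval, n_starts = n_starts, seed = seed)
  mu_deg <- ctrl$params$mu_pp

  fits <- list(`0` = ctrl)
  doses <- setdiff(unique(data$dose), 0)
  for (ds in doses) {
    row <- as.list(data[data$dose == ds, , drop = FALSE][1, ])
    if (!is.null(row$LI_ratio) && is.finite(row$LI_ratio) &&
        !("LI" %in% names(row) && is.finite(row$LI)))
      row$LI <- row$LI_ratio * ctrl$obs$LI
    st <- start
    st[names(ctrl$params)[1:5]] <- ctrl$params[1:5]
    fits[[as.character(ds)]] <-
      fit_one_dose(row, alpha = NULL, mu_deg = mu_deg, Delta = Delta,
                   start = st, step_tol = step_tol, max_eval = max_eval,
                   n_starts = n_starts, seed = seed)
  }
  est <- do.call(rbind, lapply(names(fits), function(nm) {
    p <- fits[[nm]]$params
    data.frame(dose = as.numeric(nm), lambda1 = p$lambda1, T2 = p$T2,
               T3 = p$T3, mu_p = p$mu_p, mu_pp = p$mu_pp,
               mu_deg = p$mu_deg, alpha = p$alpha,
               time_x2 = log(2) / abs(p$alpha),
               LI = fits[[nm]]$obs$LI, loss = fits[[nm]]$loss)
  }))
  est <- est[order(est$dose), ]
  rownames(est) <- NULL
  structure(list(estimates = est, fits = fits, data = data,
                 alpha_control = alpha_control, mu_deg = mu_deg,
                 Delta = Delta),
            class = "cellpop_fit")
}

#' @export
print.cellpop_fit <- function(x, ...) {
  cat("Cell-population model fit\n")
  cat(sprintf("  control growth rate fixed at alpha = %.4g /d; mu_deg fixed at control mu'' = %.4g /d\n",
              x$alpha_control, x$mu_deg))
  print(cbind(x$estimates[1:8], signif(x$estimates[9:11], 4)), digits = 4)
  invisible(x)
}

#' @export
coef.cellpop_fit <- function(object, ...) object$estimates

#' Predicted observables of a fitted population model
#'
#' @param object a `cellpop_fit`.
#' @param ... unused.
#' @return data frame of closed-form observables per dose.
#' @export
predict.cellpop_fit <- function(object, ...) {
  do.call(rbind, lapply(names(object$fits), function(nm) {
    o <- object$fits[[nm]]$obs
    data.frame(dose = as.numeric(nm), fG1 = o$fG1, fS = o$fS,
               fG2M = o$fG2M, fA = o$fA, fDead = o$fDead, LI = o$LI)
  }))
}

#' @export
residuals.cellpop_fit <- function(object, ...) {
  pred <- predict(object)
  obs <- object$data
  common <- intersect(names(pred), names(obs))
  common <- setdiff(common, "dose")
  m <- merge(obs, pred, by = "dose", suffixes = c(".obs", ".pred"))
  out <- sapply(common, function(f) m[[paste0(f, ".obs")]] - m[[paste0(f, ".pred")]])
  rownames(out) <- m$dose
  out
}

#' @export
summary.cellpop_fit <- function(object, ...) {
  r <- residuals(object)
  cat("Cell-population fit summary\n")
  print(object)
  cat(sprintf("  max |residual| = %.4g\n", max(abs(r), na.rm = TRUE)))
  invisible(list(residuals = r, estimates = object$estimates))
}

#' @export
plot.cellpop_fit <- function(x, ...) {
  pred <- predict(x)
  obs <- x$data
  fields <- c("fG1", "fS", "fG2M", "fDead")
  op <- graphics::par(mfrow = c(1, 4), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (f in fields) {
    graphics::plot(obs$dose + 1, obs[[f]], log = "x", pch = 16,
                   xlab = "dose + 1 (nM)", ylab = f, main = f,
                   ylim = range(0, obs[[f]], pred[[f]]), ...)
    graphics::lines(pred$dose + 1, pred[[f]], col = 2)
  }
  invisible(x)
}

#' Simulate noisy observation sets from a fitted population model
#'
#' @param object a `cellpop_fit`.
#' @param nsim number of replicate data sets.
#' @param seed integer seed.
#' @param sd noise level passed to [synth_population()].
#' @param ... unused.
#' @return list of data frames shaped like the fitted data.
#' @export
simulate.cellpop_fit <- function(object, nsim = 1, seed = 1, sd = 0.02, ...) {
  plist <- lapply(object$fits, function(f) f$params)
  names(plist) <- names(object$fits)
  out <- vector("list", nsim)
  for (k in seq_len(nsim))
    out[[k]] <- synth_population(plist, sd = sd, seed = seed + k - 1)$data
  out
}
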