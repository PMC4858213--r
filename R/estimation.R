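# Least-squares estimation of ISN parameters from dose-response tables.

# Map a measured analyte onto the model state.  Antibody read-outs for the
# two Akt phospho-sites bind the doubly phosphorylated form as well, so they
# are fit by sums of Akt states.  2-deoxyglucose uptake is taken proportional
# to surface GLUT4; the proportionality constant cancels once curves are
# renormalized to the control value at maximal insulin.
isn_analytes <- c(pIR = "IRnY",
                  pAktS473 = "AktnS+AktnTS",
                  pAktT308 = "AktnT+AktnTS",
                  pGSK3B = "GSK3Bn",
                  pS6K1 = "S6K1n",
                  GLUT4pm = "GLUT4n",
                  PIP3 = "PIP3n",
                  pAS160 = "pAS160n",
                  uptake2DG = "GLUT4n")

analyte_value <- function(state, analyte) {
  switch(analyte,
         pIR = state$IRnY,
         pAktS473 = state$AktnS + state$AktnTS,
         pAktT308 = state$AktnT + state$AktnTS,
         pGSK3B = state$GSK3Bn,
         pS6K1 = state$S6K1n,
         GLUT4pm = state$GLUT4n,
         PIP3 = state$PIP3n,
         pAS160 = state$pAS160n,
         uptake2DG = state$GLUT4n,
         stop("unknown analyte: ", analyte))
}

check_measurement_table <- function(data) {
  need <- c("condition", "analyte", "insulin_nM", "value")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("measurement table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (!"error" %in% names(data)) data$error <- NA_real_
  if (!"used_in_fit" %in% names(data)) data$used_in_fit <- TRUE
  bad <- setdiff(unique(data$analyte), names(isn_analytes))
  if (length(bad)) stop("unknown analyte(s): ", paste(bad, collapse = ", "))
  if (any(data$insulin_nM < 0)) stop("insulin_nM must be nonnegative")
  if (any(!is.na(data$error) & data$error <= 0)) stop("errors must be positive")
  data
}

# Predictions for every row of a measurement table under a shared parameter
# set, per-condition presets, and optional per-condition environment
# overrides.  Renormalization divides each analyte's curve by the reference
# condition's value at the maximal insulin level in the table.
isn_predict_table <- function(params, env, data, conditions, ref_condition,
                              env_overrides = NULL, renormalize = TRUE,
                              mtorc1_model = NULL,
                              dbdb_glut4_scale = 0.5) {
  conds <- names(conditions)
  Ie_ref <- max(data$insulin_nM)
  states <- list()
  for (cn in conds) {
    ce <- apply_condition(params, env, conditions[[cn]],
                          dbdb_glut4_scale = dbdb_glut4_scale)
    ov <- env_overrides[[cn]]
    if (!is.null(ov)) {
      e <- ce$env
      for (nm in names(ov)) e[[nm]] <- ov[[nm]]
      ce$env <- isn_environment(e$Ie, e$J, e$PTEN_n, e$W)
    }
    grid <- sort(unique(c(data$insulin_nM[data$condition == cn], Ie_ref)))
    states[[cn]] <- list(grid = grid,
                         state = isn_steady_state(ce$params, ce$env, Ie = grid,
                                                  mtorc1_model = mtorc1_model))
  }
  pred <- numeric(nrow(data))
  for (i in seq_len(nrow(data))) {
    s <- states[[data$condition[i]]]
    j <- match(data$insulin_nM[i], s$grid)
    pred[i] <- analyte_value(s$state, data$analyte[i])[j]
  }
  if (renormalize) {
    sref <- states[[ref_condition]]
    jref <- match(Ie_ref, sref$grid)
    for (a in unique(data$analyte)) {
      ref_val <- analyte_value(sref$state, a)[jref]
      if (ref_val <= 0) stop("zero reference value for analyte ", a)
      idx <- data$analyte == a
      pred[idx] <- pred[idx] / ref_val
    }
  }
  pred
}

#' Fit the ISN model to dose-response measurements
#'
#' Bound-constrained least-squares estimation of a shared ISN parameter set
#' from a measurement table spanning one or more experimental conditions.
#' Conditions are linked to the shared parameters through the named presets
#' of [apply_condition()] (e.g. control and PTEN-silenced data are fit
#' jointly with a single parameter vector, PTEN differing only through the
#' preset).  Optimization uses a derivative-free projected compass search
#' with optional multistart; the sequence of accepted loss values is
#' non-increasing.
#'
#' Measured analytes are matched to the model as follows: `pAktS473` to
#' `AktnS + AktnTS`, `pAktT308` to `AktnT + AktnTS`, `pIR` to `IRnY`,
#' `pGSK3B`, `pS6K1`, `GLUT4pm`, `PIP3`, `pAS160` to the corresponding
#' normalized states, and `uptake2DG` to `GLUT4n` (proportionality constant
#' cancelling under renormalization).  When `renormalize = TRUE` (the
#' convention for relative densitometry data) every predicted curve is
#' divided by the reference condition's value at the maximal insulin
#' concentration in the table.
#'
#' @param data measurement table: a data frame with columns `condition`,
#'   `analyte`, `insulin_nM`, `value`, and optionally `error` (positive) and
#'   `used_in_fit` (logical; excluded rows are predicted but not fit).
#' @param start an [isn_params()] object used as starting point and as the
#'   source of all fixed parameters.
#' @param free character vector of free parameters: names of entries of
#'   `start` (including `Ie_half`, `S_half`, `rho`) and/or per-condition
#'   environment entries written `"J@condition"` (also `PTEN_n@`, `W@`).
#' @param conditions named list mapping each condition label in `data` to a
#'   preset accepted by [apply_condition()]; by default each label is used
#'   as its own preset name.
#' @param ref_condition condition used for renormalization (default
#'   `"control"` if present, otherwise the first condition).
#' @param env baseline [isn_environment()] shared by all conditions before
#'   presets and overrides.
#' @param ties named character vector tying parameters together after each
#'   update, e.g. `c(a10 = "a9")` (the default) keeps `a10` equal to `a9`.
#' @param weighting `"none"` (unweighted sum of squares, default) or
#'   `"inverse_error2"`.
#' @param renormalize logical; see Details.
#' @param lower,upper named numeric vectors of bounds for free parameters
#'   (defaults: 0 and `Inf`, with `rho` in (0, 0.5) and `mu_ratio <= 0.01`).
#' @param n_starts number of multistart runs (start point plus random
#'   multiplicative perturbations in `[0.5, 2]` per free parameter).
#' @param seed integer seed for the multistart perturbations.
#' @param step_tol,max_eval compass-search controls (see [compass_search()]).
#' @param mtorc1_model optional mTORC1 submodel closure (see
#'   [isn_steady_state()]).
#' @return An object of class `isn_fit` with components `params` (fitted
#'   shared parameter set), `env_overrides`, `coefficients`, `loss`,
#'   `trace` (monotone accepted losses), `data` (with `fitted` and
#'   `residual` columns), `conditions`, and optimizer diagnostics.
#' @seealso [predict.isn_fit()], [synth_dose_response()]
#' @export
isn_fit <- function(data, start, free,
                    conditions = NULL, ref_condition = NULL,
                    env = isn_environment(),
                    ties = c(a10 = "a9"),
                    weighting = c("none", "inverse_error2"),
                    renormalize = TRUE,
                    lower = NULL, upper = NULL,
                    n_starts = 1, seed = 1,
                    step_tol = 1e-7, max_eval = 4000,
                    mtorc1_model = NULL) {
  weighting <- match.arg(weighting)
  data <- check_measurement_table(data)
  if (nrow(data) == 0) stop("empty measurement table")
  conds <- unique(data$condition)
  if (is.null(conditions)) conditions <- stats::setNames(as.list(conds), conds)
  miss <- setdiff(conds, names(conditions))
  if (length(miss)) stop("no preset mapping for condition(s): ",
                         paste(miss, collapse = ", "))
  if (is.null(ref_condition))
    ref_condition <- if ("control" %in% conds) "control" else conds[[1]]

  is_env_free <- grepl("@", free, fixed = TRUE)
  par_free <- free[!is_env_free]
  env_free <- free[is_env_free]
  bad <- setdiff(par_free, names(start))
  if (length(bad)) stop("unknown free parameter(s): ", paste(bad, collapse = ", "))

  # starting vector
  th0 <- numeric(0)
  for (nm in par_free) th0[nm] <- start[[nm]]
  base_overrides <- list()
  for (ef in env_free) {
    parts <- strsplit(ef, "@", fixed = TRUE)[[1]]
    if (length(parts) != 2 || !parts[1] %in% c("Ie", "J", "PTEN_n", "W"))
      stop("malformed environment free parameter: ", ef)
    if (!parts[2] %in% conds) stop("unknown condition in ", ef)
    ce <- apply_condition(start, env, conditions[[parts[2]]])
    th0[ef] <- max(ce$env[[parts[1]]], 1e-4)
  }

  lo <- stats::setNames(rep(0, length(th0)), names(th0))
  hi <- stats::setNames(rep(Inf, length(th0)), names(th0))
  if ("rho" %in% names(th0)) { lo["rho"] <- 1e-6; hi["rho"] <- 0.499 }
  if ("mu_ratio" %in% names(th0)) hi["mu_ratio"] <- 0.01
  for (nm in grep("PTEN_n@|^W@", names(th0), value = TRUE)) hi[nm] <- 1
  if (!is.null(lower)) lo[names(lower)] <- lower
  if (!is.null(upper)) hi[names(upper)] <- upper

  w <- rep(1, nrow(data))
  if (weighting == "inverse_error2") {
    if (any(is.na(data$error))) stop("inverse_error2 weighting requires errors")
    w <- 1 / data$error^2
  }
  used <- as.logical(data$used_in_fit)

  build <- function(th) {
    p <- start
    if (length(par_free))
      p <- do.call(update_isn_params, c(list(p), as.list(th[par_free])))
    for (tgt in names(ties))
      p <- do.call(update_isn_params,
                   c(list(p), stats::setNames(list(p[[ties[[tgt]]]]), tgt)))
    ov <- base_overrides
    for (ef in env_free) {
      parts <- strsplit(ef, "@", fixed = TRUE)[[1]]
      ov[[parts[2]]] <- c(ov[[parts[2]]],
                          stats::setNames(th[[ef]], parts[1]))
    }
    list(params = p, overrides = ov)
  }

  loss_fn <- function(th) {
    b <- tryCatch(build(th), error = function(e) NULL)
    if (is.null(b)) return(1e10)
    pred <- tryCatch(
      isn_predict_table(b$params, env, data, conditions, ref_condition,
                        env_overrides = b$overrides,
                        renormalize = renormalize,
                        mtorc1_model = mtorc1_model),
      error = function(e) NULL)
    if (is.null(pred) || any(!is.finite(pred))) return(1e10)
    sum(w[used] * (pred[used] - data$value[used])^2)
  }

  opt <- multistart_search(loss_fn, th0, lower = lo, upper = hi,
                           n_starts = n_starts, seed = seed,
                           step_tol = step_tol, max_eval = max_eval,
                           f_tol = 1e-15)
  b <- build(opt$par)
  pred <- isn_predict_table(b$params, env, data, conditions, ref_condition,
                            env_overrides = b$overrides,
                            renormalize = renormalize,
                            mtorc1_model = mtorc1_model)
  data$fitted <- pred
  data$residual <- data$value - pred
  structure(list(params = b$params, env = env,
                 env_overrides = b$overrides,
                 coefficients = opt$par, loss = opt$value,
                 trace = opt$trace, evals = opt$evals,
                 converged = opt$converged,
                 start_values = opt$start_values,
                 data = data, conditions = conditions,
                 ref_condition = ref_condition, free = free, ties = ties,
                 weighting = weighting, renormalize = renormalize,
                 mtorc1_model = mtorc1_model),
            class = "isn_fit")
}

#' @export
print.isn_fit <- function(x, ...) {
  cat("ISN dose-response fit\n")
  cat(sprintf("  conditions: %s (reference: %s)\n",
              paste(names(x$conditions), collapse = ", "), x$ref_condition))
  cat(sprintf("  %d observations (%d fit), loss = %.6g, %d evaluations\n",
              nrow(x$data), sum(x$data$used_in_fit), x$loss, x$evals))
  cat("  estimates:\n")
  print(signif(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.isn_fit <- function(object, ...) object$coefficients

#' @export
summary.isn_fit <- function(object, ...) {
  r <- object$data$residual[object$data$used_in_fit]
  structure(list(fit = object,
                 rmse = sqrt(mean(r^2)),
                 loss = object$loss,
                 n = length(r),
                 by_analyte = tapply(abs(object$data$residual),
                                     object$data$analyte, max)),
            class = "summary.isn_fit")
}

#' @export
print.summary.isn_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  RMSE = %.4g over %d fitted points\n", x$rmse, x$n))
  cat("  max |residual| by analyte:\n")
  print(signif(x$by_analyte, 3))
  invisible(x)
}

#' Predict dose-response curves from a fitted ISN model
#'
#' @param object an `isn_fit` object.
#' @param insulin insulin grid (nM); defaults to the fitted grid.
#' @param conditions condition labels to predict (default: all fitted).
#' @param analytes analytes to predict (default: all fitted).
#' @param renormalize logical; default as fitted.
#' @param ... unused.
#' @return data frame with columns `condition`, `analyte`, `insulin_nM`,
#'   `value`.
#' @export
predict.isn_fit <- function(object, insulin = NULL, conditions = NULL,
                            analytes = NULL, renormalize = NULL, ...) {
  if (is.null(insulin)) insulin <- sort(unique(object$data$insulin_nM))
  if (is.null(conditions)) conditions <- names(object$conditions)
  if (is.null(analytes)) analytes <- unique(object$data$analyte)
  if (is.null(renormalize)) renormalize <- object$renormalize
  grid <- expand.grid(condition = conditions, analyte = analytes,
                      insulin_nM = insulin, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid$value <- isn_predict_table(object$params, object$env, grid,
                                  object$conditions[conditions],
                                  object$ref_condition,
                                  env_overrides = object$env_overrides,
                                  renormalize = renormalize,
                                  mtorc1_model = object$mtorc1_model)
  grid[order(grid$condition, grid$analyte, grid$insulin_nM), ]
}

#' @export
residuals.isn_fit <- function(object, ...) object$data$residual

#' @export
fitted.isn_fit <- function(object, ...) object$data$fitted

#' @export
plot.isn_fit <- function(x, analytes = NULL, ...) {
  d <- x$data
  if (is.null(analytes)) analytes <- unique(d$analyte)
  conds <- names(x$conditions)
  op <- graphics::par(mfrow = c(1, length(analytes)), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  grid <- exp(seq(log(0.05), log(max(d$insulin_nM)), length.out = 25))
  grid <- sort(unique(c(0, grid)))
  curves <- predict(x, insulin = grid, analytes = analytes)
  for (a in analytes) {
    da <- d[d$analyte == a, ]
    ca <- curves[curves$analyte == a, ]
    graphics::plot(NA, xlim = range(d$insulin_nM),
                   ylim = range(0, da$value, ca$value),
                   xlab = "insulin (nM)", ylab = a, main = a, ...)
    for (i in seq_along(conds)) {
      ci <- ca[ca$condition == conds[i], ]
      di <- da[da$condition == conds[i], ]
      graphics::lines(ci$insulin_nM, ci$value, col = i)
      graphics::points(di$insulin_nM, di$value, col = i, pch = 16)
    }
    graphics::legend("bottomright", legend = conds, col = seq_along(conds),
                     lty = 1, bty = "n", cex = 0.8)
  }
  invisible(x)
}

#' Simulate replicate measurement tables from a fitted ISN model
#'
#' @param object an `isn_fit` object.
#' @param nsim number of replicate tables.
#' @param seed integer seed.
#' @param sd Gaussian noise standard deviation on renormalized values.
#' @param ... unused.
#' @return a list of measurement tables (data frames).
#' @export
simulate.isn_fit <- function(object, nsim = 1, seed = 1, sd = 0.05, ...) {
  set.seed(seed)
  out <- vector("list", nsim)
  clean <- predict(object)
  for (k in seq_len(nsim)) {
    t_k <- clean
    t_k$value <- pmax(0, t_k$value + stats::rnorm(nrow(t_k), 0, sd))
    t_k$error <- sd
    out[[k]] <- t_k
  }
  out
}

#' Renormalize dose-response curves to a reference condition
#'
#' Divides each analyte's values by the reference curve's value at the
#' maximal insulin concentration present in the reference, mirroring the
#' convention of plotting relative data with the control response equal to
#' one at maximal insulin.  The operation is linear, so applying it twice
#' gives the same result as applying it once.
#'
#' @param dr an [isn_dose_response()] data frame (any set of conditions).
#' @param reference an [isn_dose_response()] data frame holding the
#'   reference (control) condition.
#' @param analytes analytes to renormalize (default: all in `dr`).
#' @return `dr` with rescaled `value` column.
#' @export
renormalize_dose_response <- function(dr, reference, analytes = NULL) {
  if (is.null(analytes)) analytes <- unique(dr$analyte)
  Ie_max <- max(reference$Ie_nM)
  for (a in analytes) {
    ref <- reference$value[reference$analyte == a & reference$Ie_nM == Ie_max]
    if (length(ref) != 1) stop("reference lacks a unique maximal-insulin point for ", a)
    if (ref == 0) stop("zero reference value for analyte ", a)
    dr$value[dr$analyte == a] <- dr$value[dr$analyte == a] / ref
  }
  dr
}
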