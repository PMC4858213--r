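# Synthetic-data generators with known ground truth, emulating the
# structure of replotted densitometry / flow-cytometry data sets: noisy
# normalized dose-response tables across experimental conditions, and
# per-dose cell-population observations.  All randomness is controlled by
# an integer seed; the same seed reproduces the table exactly.

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) return(alpha / sum(alpha))
  g / sum(g)
}

#' Generate a synthetic dose-response measurement table
#'
#' Computes the exact model curves for each condition, renormalizes each
#' analyte to a unity control value at maximal insulin (the convention of
#' relative densitometry data), and adds independent Gaussian noise of
#' standard deviation `sd` to every normalized value (truncated at zero).
#' The noiseless truth is attached so that recovery can be scored.
#'
#' @param params true (ground-truth) [isn_params()] set.
#' @param env baseline [isn_environment()].
#' @param conditions named list mapping condition labels to presets of
#'   [apply_condition()]; default control plus PTEN-silenced.
#' @param insulin insulin grid (nM); default `c(0, 0.1, 1, 10, 100)`.
#' @param analytes analytes to tabulate (see [isn_fit()] for the set).
#' @param sd Gaussian noise standard deviation on normalized values
#'   (default 0.05); scalar or named per-analyte vector.
#' @param replicates replicate measurements per design point (default 1).
#' @param seed integer seed fixing all randomness.
#' @param ref_condition renormalization reference (default `"control"`).
#' @return a measurement table (data frame with columns `condition`,
#'   `analyte`, `insulin_nM`, `value`, `error`, `used_in_fit`) with
#'   attributes `truth` (noiseless table) and `params`.
#' @export
synth_dose_response <- function(params, env = isn_environment(),
                                conditions = list(control = "control",
                                                  pten_silenced = "pten_silenced"),
                                insulin = c(0, 0.1, 1, 10, 100),
                                analytes = c("pIR", "pAktS473", "pAktT308",
                                             "pGSK3B", "pS6K1"),
                                sd = 0.05, replicates = 1, seed = 1,
                                ref_condition = names(conditions)[1]) {
  grid <- expand.grid(condition = names(conditions), analyte = analytes,
                      insulin_nM = insulin, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid$value <- isn_predict_table(params, env, grid, conditions,
                                  ref_condition, renormalize = TRUE)
  truth <- grid[order(grid$condition, grid$analyte, grid$insulin_nM), ]
  rownames(truth) <- NULL
  sdv <- if (length(sd) == 1) rep(sd, nrow(truth))
         else unname(sd[truth$analyte])
  set.seed(seed)
  out <- truth[rep(seq_len(nrow(truth)), each = replicates), ]
  sdv <- rep(sdv, each = replicates)
  out$value <- pmax(0, out$value + stats::rnorm(nrow(out), 0, sdv))
  out$error <- ifelse(sdv > 0, sdv, NA_real_)
  out$used_in_fit <- TRUE
  rownames(out) <- NULL
  attr(out, "truth") <- truth
  attr(out, "params") <- params
  out
}

#' Generate a synthetic per-dose cell-population observation set
#'
#' Perturbs the closed-form composition on the simplex by Dirichlet
#' resampling around `(fG1, fS, fG2M, fA)` (preserving the sum-to-one
#' invariant) and adds truncated Gaussian noise to the dead fraction and
#' labeling index.  The Dirichlet concentration is chosen so that a
#' component with mean one half has standard deviation `sd`.
#'
#' @param params_by_dose named list of true [pop_params()] sets, names =
#'   dose.
#' @param sd noise level (default 0.02); `sd = 0` returns exact closed
#'   forms.
#' @param seed integer seed.
#' @return list with `data` (data frame: `dose`, `fG1`, `fS`, `fG2M`,
#'   `fA`, `fDead`, `LI`, `LI_ratio`) and `truth` (noiseless equivalent).
#' @export
synth_population <- function(params_by_dose, sd = 0.02, seed = 1) {
  doses <- as.numeric(names(params_by_dose))
  if (any(is.na(doses))) stop("params_by_dose must be named by dose")
  truth <- do.call(rbind, lapply(seq_along(doses), function(i) {
    o <- pop_observables(params_by_dose[[i]])
    data.frame(dose = doses[i], fG1 = o$fG1, fS = o$fS, fG2M = o$fG2M,
               fA = o$fA, fDead = o$fDead, LI = o$LI)
  }))
  li_ctrl <- truth$LI[truth$dose == min(truth$dose)][1]
  truth$LI_ratio <- truth$LI / li_ctrl
  set.seed(seed)
  data <- truth
  if (sd > 0) {
    conc <- 0.25 / sd^2 - 1
    for (i in seq_len(nrow(data))) {
      f <- as.numeric(truth[i, c("fG1", "fS", "fG2M", "fA")])
      f <- pmax(f, 1e-6)
      data[i, c("fG1", "fS", "fG2M", "fA")] <- rdirichlet1(f * conc)
    }
    data$fDead <- pmin(1, pmax(0, data$fDead + stats::rnorm(nrow(data), 0, sd)))
    data$LI <- pmin(1, pmax(0, data$LI + stats::rnorm(nrow(data), 0, sd)))
    data$LI_ratio <- data$LI / data$LI[data$dose == min(data$dose)][1]
  }
  list(data = data, truth = truth)
}

#' Random valid ISN parameter set (for property testing and simulation)
#'
#' Draws a parameter set satisfying every structural constraint: the
#' receptor slope inside its feasible bracket, positive Akt-block
#' combinations, `a29 < a30`, `a28 < 1`, and `mu_ratio <= 0.01`.
#'
#' @param seed optional integer seed.
#' @return an [isn_params()] object.
#' @export
random_isn_params <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rho <- stats::runif(1, 0.01, 0.3)
  Ie_half <- stats::runif(1, 2, 100)
  s_lo <- (1 - 2 * rho) / (4 * Ie_half * (1 - rho))
  s_hi <- (1 - 2 * rho) / (2 * Ie_half)
  S_half <- stats::runif(1, s_lo + 0.05 * (s_hi - s_lo),
                         s_hi - 0.05 * (s_hi - s_lo))
  a17g <- stats::runif(1, 0.05, 2); a19g <- stats::runif(1, 0.05, 2)
  ate <- stats::runif(1, 0.05, 1.5); aed <- stats::runif(1, 0.05, 1.5)
  a30 <- stats::runif(1, 1, 10)
  isn_params(rho = rho, Ie_half = Ie_half, S_half = S_half,
             a3 = stats::runif(1, 0.2, 3), a4 = stats::runif(1, 0, 2),
             aP = stats::runif(1, 0, 1),
             a6 = stats::runif(1, 0.5, 10), a6p = stats::runif(1, 0, 1),
             a8 = stats::runif(1, 0.3, 3),
             a9 = stats::runif(1, 0.3, 5), a11 = stats::runif(1, 0, 20),
             a12 = stats::runif(1, 0, 1),
             a13d = stats::runif(1, 0.05, 2), a15e = stats::runif(1, 0.05, 2),
             a17g = a17g, a17d = a17g * aed + stats::runif(1, 0.05, 2),
             a19g = a19g, a19e = a19g * ate + stats::runif(1, 0.05, 2),
             a_theta_e = ate, a_eta_d = aed,
             mu_ratio = stats::runif(1, 0, 0.01),
             a21 = stats::runif(1, 0.5, 5), a23 = stats::runif(1, 0.5, 5),
             a23p = stats::runif(1, 0, 1), a24 = stats::runif(1, 0.5, 5),
             a26 = stats::runif(1, 0.5, 5), a26mu = stats::runif(1, 0, 0.1),
             a27 = stats::runif(1, 0.5, 5),
             a28 = stats::runif(1, 0.05, 0.6),
             a29 = stats::runif(1, 0.1, 0.95) * a30, a30 = a30)
}

#' Random valid cell-population parameter set
#'
#' Draws transit times, transition and loss rates in realistic ranges for a
#' cultured tumour line (transit times 0.1-0.8 day, rates up to about 2/day)
#' and re-draws until the balanced-composition constraints hold.
#'
#' @param seed optional integer seed.
#' @param declining if `TRUE`, bias draws toward treated-like (negative
#'   growth) parameter sets.
#' @return a [pop_params()] object.
#' @export
random_pop_params <- function(seed = NULL, declining = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  repeat {
    lambda1 <- stats::runif(1, 0.1, 2) * if (declining) 0.3 else 1
    T2 <- stats::runif(1, 0.15, 0.8)
    T3 <- stats::runif(1, 0.1, 0.6)
    mu_p <- stats::runif(1, 0, 1.2) * if (declining) 1.5 else 1
    mu_pp <- stats::runif(1, 0.2, 2)
    p <- tryCatch(pop_params(lambda1, T2, T3, mu_p, mu_pp),
                  error = function(e) NULL)
    if (!is.null(p) && p$alpha + p$mu_pp > 0.05 && p$alpha + p$mu_p > 0.02)
      return(p)
  }
}
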