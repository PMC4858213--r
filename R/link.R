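# Link analysis: saturating relations between signalling-network outputs
# and cell-population kinetic parameters under mTOR inhibition, and the
# equivalent-insulin representation of constitutive PI3K/Akt activation.

#' Fit a saturating link function between two quantities
#'
#' Fits one of three monotone link forms by nonlinear least squares
#' (Levenberg-Marquardt with positivity bounds):
#' \describe{
#'   \item{`michaelis`}{`y = A x / (B + x)` (increasing).}
#'   \item{`inhibition`}{`y = A / (B + x)` (decreasing).}
#'   \item{`inhibition_power`}{`y = A / (B + x^n)` with the exponent free.}
#' }
#' Fits are scale-equivariant: rescaling `y` rescales `A` only.
#'
#' @param x,y positive numeric vectors (at least 3 points; `x = 0` allowed
#'   for the Michaelis form, where it forces `y = 0`).
#' @param form one of `"michaelis"`, `"inhibition"`, `"inhibition_power"`.
#' @param x_name,y_name labels stored in the result.
#' @return An object of class `link_fit` with elements `A`, `B`, `n`,
#'   `residual` (root-mean-square), `form`, `fitted`.
#' @export
fit_link <- function(x, y, form = c("michaelis", "inhibition",
                                    "inhibition_power"),
                     x_name = deparse(substitute(x)),
                     y_name = deparse(substitute(y))) {
  form <- match.arg(form)
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3) stop("need at least 3 points")
  if (any(y < 0) || any(x < 0)) stop("x and y must be nonnegative")
  if (diff(range(x)) <= 0) stop("degenerate x range")
  df <- data.frame(x = x, y = y)
  fit <- tryCatch(switch(form,
    michaelis = minpack.lm::nlsLM(
      y ~ A * x / (B + x), data = df,
      start = list(A = max(y), B = max(stats::median(x), 1e-6)),
      lower = c(1e-12, 1e-12), control = minpack.lm::nls.lm.control(maxiter = 200)),
    inhibition = minpack.lm::nlsLM(
      y ~ A / (B + x), data = df,
      start = list(A = max(y) * max(stats::median(x), 1), B = max(stats::median(x), 1e-6)),
      lower = c(1e-12, 1e-12), control = minpack.lm::nls.lm.control(maxiter = 200)),
    inhibition_power = minpack.lm::nlsLM(
      y ~ A / (B + x^n), data = df,
      start = list(A = max(y), B = 1, n = 1),
      lower = c(1e-12, 1e-12, 0.05), upper = c(Inf, Inf, 10),
      control = minpack.lm::nls.lm.control(maxiter = 400))),
    error = function(e) NULL)
  if (is.null(fit)) {
    # near-degenerate data (e.g. an almost flat response): derivative-free
    # least squares on log-parameters
    predf <- function(cf, x) switch(form,
      michaelis = cf[1] * x / (cf[2] + x),
      inhibition = cf[1] / (cf[2] + x),
      inhibition_power = cf[1] / (cf[2] + x^cf[3]))
    np <- if (form == "inhibition_power") 3 else 2
    obj <- function(lth) sum((predf(exp(lth), x) - y)^2)
    o <- stats::optim(log(c(max(y), stats::median(x[x > 0]), 1)[seq_len(np)]),
                      obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
    cf <- exp(o$par)
    names(cf) <- c("A", "B", "n")[seq_len(np)]
    return(structure(list(A = cf[["A"]], B = cf[["B"]],
                          n = if (np == 3) cf[["n"]] else 1,
                          residual = sqrt(o$value / length(x)),
                          form = form, x = x, y = y,
                          fitted = predf(cf, x),
                          x_name = x_name, y_name = y_name),
                     class = "link_fit"))
  }
  cf <- stats::coef(fit)
  structure(list(A = cf[["A"]], B = cf[["B"]],
                 n = if ("n" %in% names(cf)) cf[["n"]] else 1,
                 residual = sqrt(mean(stats::resid(fit)^2)),
                 form = form, x = x, y = y,
                 fitted = stats::fitted(fit),
                 x_name = x_name, y_name = y_name),
            class = "link_fit")
}

#' @export
print.link_fit <- function(x, ...) {
  eqn <- switch(x$form,
    michaelis = sprintf("y = %.4g x / (%.4g + x)", x$A, x$B),
    inhibition = sprintf("y = %.4g / (%.4g + x)", x$A, x$B),
    inhibition_power = sprintf("y = %.4g / (%.4g + x^%.3g)", x$A, x$B, x$n))
  cat(sprintf("Link fit [%s ~ %s]: %s (RMS residual %.3g)\n",
              x$y_name, x$x_name, eqn, x$residual))
  invisible(x)
}

#' @export
coef.link_fit <- function(object, ...)
  c(A = object$A, B = object$B, n = object$n)

#' @export
predict.link_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$x else newdata
  switch(object$form,
         michaelis = object$A * x / (object$B + x),
         inhibition = object$A / (object$B + x),
         inhibition_power = object$A / (object$B + x^object$n))
}

#' @export
residuals.link_fit <- function(object, ...) object$y - object$fitted

#' @export
plot.link_fit <- function(x, ...) {
  graphics::plot(x$x, x$y, pch = 16, xlab = x$x_name, ylab = x$y_name, ...)
  xs <- seq(min(x$x), max(x$x), length.out = 100)
  graphics::lines(xs, predict(x, xs), col = 2)
  invisible(x)
}

#' Represent constitutive activation and fit per-dose mTOR inhibition
#'
#' Constitutively active PI3K/Akt signalling (as in AML blasts) is
#' represented by a constant "equivalent" insulin input `Ie_equiv`.  Given
#' a normalized (control = 1) phospho-S6K1 inhibition profile over drug
#' doses, this routine fits one inhibition multiplier per dose, applied
#' jointly to the mTORC2 activation constants (`a10`, `a11`) and the mTORC1
#' constant (`a24`), such that the model reproduces the profile; all other
#' parameters stay at their reference (myotube-derived) values.  When a
#' normalized phospho-Akt(Ser473) profile is also supplied, `Ie_equiv` is
#' fit jointly by least squares over both profiles; otherwise it is fixed.
#'
#' @param params reference [isn_params()] set.
#' @param env reference [isn_environment()].
#' @param doses drug concentrations (first entry must be 0 = control).
#' @param s6k1_ratio normalized pS6K1 per dose (control = 1).
#' @param akt_ratio optional normalized pAkt(Ser473) per dose.
#' @param Ie_equiv equivalent insulin (nM); fixed unless `akt_ratio` is
#'   supplied, in which case this is the starting value.
#' @return list with `Ie_equiv`, `multipliers` (per dose, control = 1),
#'   `fitted` (per-dose predicted ratios), `loss`.
#' @export
equivalent_insulin_refit <- function(params, env, doses, s6k1_ratio,
                                     akt_ratio = NULL, Ie_equiv = 10) {
  if (doses[1] != 0) stop("first dose must be 0 (control)")
  if (abs(s6k1_ratio[1] - 1) > 1e-8)
    stop("control pS6K1 ratio must be 1 (normalization anchor)")
  if (any(diff(s6k1_ratio) > 0))
    warning("pS6K1 profile is not monotone decreasing; fitting anyway")
  nd <- length(doses)
  ratios_at <- function(Ie, mults) {
    ctrl <- isn_steady_state(params, env, Ie = Ie)
    s6_c <- ctrl$S6K1n
    akt_c <- ctrl$AktnS + ctrl$AktnTS
    s6 <- akt <- numeric(nd)
    s6[1] <- akt[1] <- 1
    for (i in seq_len(nd)[-1]) {
      pi <- update_isn_params(params, a10 = params$a10 * mults[i],
                              a11 = params$a11 * mults[i],
                              a24 = params$a24 * mults[i])
      st <- isn_steady_state(pi, env, Ie = Ie)
      s6[i] <- st$S6K1n / s6_c
      akt[i] <- (st$AktnS + st$AktnTS) / akt_c
    }
    list(s6 = s6, akt = akt)
  }
  fit_mults <- function(Ie) {
    mults <- rep(1, nd)
    for (i in seq_len(nd)[-1]) {
      f <- function(m) {
        pi <- update_isn_params(params, a10 = params$a10 * m,
                                a11 = params$a11 * m, a24 = params$a24 * m)
        st <- isn_steady_state(pi, env, Ie = Ie)
        ctrl <- isn_steady_state(params, env, Ie = Ie)
        st$S6K1n / ctrl$S6K1n - s6k1_ratio[i]
      }
      # pS6K1 ratio is monotone increasing in the multiplier
      mults[i] <- stats::uniroot(f, c(1e-6, 1), extendInt = "upX",
                                 tol = 1e-12)$root
    }
    mults
  }
  if (is.null(akt_ratio)) {
    mults <- fit_mults(Ie_equiv)
    r <- ratios_at(Ie_equiv, mults)
    loss <- sum((r$s6 - s6k1_ratio)^2)
  } else {
    obj <- function(logIe) {
      Ie <- exp(logIe)
      mults <- fit_mults(Ie)
      r <- ratios_at(Ie, mults)
      sum((r$s6 - s6k1_ratio)^2) + sum((r$akt - akt_ratio)^2)
    }
    opt <- stats::optimize(obj, log(c(0.05, 1000)))
    Ie_equiv <- exp(opt$minimum)
    mults <- fit_mults(Ie_equiv)
    r <- ratios_at(Ie_equiv, mults)
    loss <- opt$objective
  }
  list(Ie_equiv = Ie_equiv, multipliers = stats::setNames(mults, doses),
       fitted = data.frame(dose = doses, s6k1_ratio = r$s6,
                           akt_ratio = r$akt),
       loss = loss)
}

#' End-to-end drug-response link analysis
#'
#' Runs the joint signalling/population analysis of an mTOR-inhibitor dose
#' escalation: applies per-dose inhibition multipliers to the network at the
#' equivalent insulin level, extracts the signalling read-outs, pairs them
#' with per-dose population parameters, and fits the saturating link
#' functions (phospho-Akt(Ser473) and phospho-GSK3beta against the G1-to-S
#' rate constant; phospho-S6K1 against the mean cycle time
#' `Tc = 1/lambda1 + T2 + T3` and against the loss rate).
#'
#' @param params,env reference network and environment.
#' @param Ie_equiv equivalent insulin level (nM).
#' @param multipliers per-dose inhibition multipliers (control = 1).
#' @param pop_estimates data frame with columns `dose`, `lambda1`, `T2`,
#'   `T3`, `mu_p` (e.g. `coef()` of a [cellpop_fit()]).
#' @return list with `table` (per-dose merged read-outs, control-normalized)
#'   and `links` (list of `link_fit` objects `akt_lambda1`, `gsk3b_lambda1`,
#'   `s6k1_Tc`, `s6k1_mu_p`).
#' @export
link_analysis <- function(params, env, Ie_equiv, multipliers,
                          pop_estimates) {
  doses <- as.numeric(names(multipliers))
  if (is.null(doses) || any(is.na(doses)))
    doses <- pop_estimates$dose[seq_along(multipliers)]
  read <- data.frame(dose = doses, pAktS473 = NA_real_, pGSK3B = NA_real_,
                     pS6K1 = NA_real_, FoxO1_cyt = NA_real_)
  for (i in seq_along(doses)) {
    m <- multipliers[[i]]
    pi <- update_isn_params(params, a10 = params$a10 * m,
                            a11 = params$a11 * m, a24 = params$a24 * m)
    st <- isn_steady_state(pi, env, Ie = Ie_equiv)
    read$pAktS473[i] <- st$AktnS + st$AktnTS
    read$pGSK3B[i] <- st$GSK3Bn
    read$pS6K1[i] <- st$S6K1n
    read$FoxO1_cyt[i] <- st$FoxO1n_cyt
  }
  for (f in c("pAktS473", "pGSK3B", "pS6K1", "FoxO1_cyt"))
    read[[f]] <- read[[f]] / read[[f]][1]
  tab <- merge(read, pop_estimates, by = "dose")
  tab$Tc <- 1 / tab$lambda1 + tab$T2 + tab$T3
  links <- list(
    akt_lambda1 = fit_link(tab$lambda1, tab$pAktS473, "michaelis",
                           "lambda1", "pAktS473"),
    gsk3b_lambda1 = fit_link(tab$lambda1, tab$pGSK3B, "michaelis",
                             "lambda1", "pGSK3B"),
    s6k1_Tc = fit_link(tab$Tc, tab$pS6K1, "inhibition", "Tc", "pS6K1"),
    s6k1_mu_p = fit_link(tab$mu_p, tab$pS6K1, "inhibition_power",
                         "mu_p", "pS6K1"))
  list(table = tab, links = links)
}
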