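#' Log-log sensitivity matrix of the steady state
#'
#' Computes, at a given insulin level, the relative sensitivity
#' \deqn{S_{cp} = \frac{\partial \log c}{\partial \log p}
#'   \approx \frac{\log c(p(1+\delta)) - \log c(p(1-\delta))}
#'                {\log(1+\delta) - \log(1-\delta)}}
#' of every normalized steady-state concentration `c` to every parameter
#' `p`, by central differences on a symmetric plus/minus perturbation
#' (default 10 percent).  Entries are dimensionless: positive values mean
#' positive regulation, negative values inhibition.  Concentrations that are
#' zero at the evaluation point yield undefined entries, reported as `NA`
#' and flagged in the `"undefined"` attribute rather than propagated.
#'
#' Perturbing `Ie_half` or `S_half` re-derives the internal receptor
#' constants, and the special name `"J"` perturbs the environment factor J.
#'
#' @param params an [isn_params()] object.
#' @param env an [isn_environment()] object.
#' @param Ie insulin level (nM) at which sensitivities are evaluated.
#' @param delta perturbation fraction (default 0.10).
#' @param parameters character vector of parameter names (default: every
#'   strictly positive numeric parameter except the derived `a0`, `a1`,
#'   `ab`, plus `"J"` when `env$J > 0`).
#' @param mtorc1_model optional mTORC1 submodel closure.
#' @return an `isn_sensitivity` matrix (rows = state components, columns =
#'   parameters) with attributes `Ie`, `delta`, `undefined`.
#' @export
isn_sensitivity <- function(params, env, Ie, delta = 0.10, parameters = NULL,
                            mtorc1_model = NULL) {
  stopifnot(length(Ie) == 1, Ie >= 0, delta > 0, delta < 1)
  if (is.null(parameters)) {
    num <- names(params)[vapply(params, is.numeric, logical(1))]
    num <- setdiff(num, c("a0", "a1", "ab"))
    parameters <- num[vapply(num, function(nm) params[[nm]] > 0, logical(1))]
    if (env$J > 0) parameters <- c(parameters, "J")
  }
  states <- c("IRnY", "IRS1nY", "IRS1nS", "PTP1Bn", "PI3Kn", "PIP3n",
              "PDK1n", "mTORC2n", "AktnT", "AktnS", "AktnTS",
              "FoxO1n_cyt", "GSK3Bn", "mTORC1n", "S6K1n", "GLUT4n",
              "pAS160n")
  solve_at <- function(p, e) {
    st <- isn_steady_state(p, e, Ie = Ie, mtorc1_model = mtorc1_model)
    vapply(states, function(nm) st[[nm]], numeric(1))
  }
  perturbed <- function(nm, fac) {
    if (nm == "J") {
      list(p = params, e = isn_environment(env$Ie, env$J * fac,
                                           env$PTEN_n, env$W))
    } else {
      list(p = do.call(update_isn_params,
                       c(list(params),
                         stats::setNames(list(params[[nm]] * fac), nm))),
           e = env)
    }
  }
  denom <- log(1 + delta) - log(1 - delta)
  S <- matrix(NA_real_, length(states), length(parameters),
              dimnames = list(states, parameters))
  undef <- matrix(FALSE, length(states), length(parameters),
                  dimnames = list(states, parameters))
  for (j in seq_along(parameters)) {
    nm <- parameters[j]
    up <- perturbed(nm, 1 + delta)
    dn <- perturbed(nm, 1 - delta)
    cu <- solve_at(up$p, up$e)
    cd <- solve_at(dn$p, dn$e)
    ok <- cu > 0 & cd > 0
    S[ok, j] <- (log(cu[ok]) - log(cd[ok])) / denom
    undef[!ok, j] <- TRUE
  }
  structure(S, class = c("isn_sensitivity", "matrix"),
            Ie = Ie, delta = delta, undefined = undef)
}

#' @export
print.isn_sensitivity <- function(x, ...) {
  cat(sprintf("Log-log sensitivities at Ie = %.4g nM (delta = %.2g)\n",
              attr(x, "Ie"), attr(x, "delta")))
  m <- x; attributes(m) <- list(dim = dim(x), dimnames = dimnames(x))
  print(round(m, 3), ...)
  if (any(attr(x, "undefined")))
    cat("NA entries: concentration zero at the evaluation point\n")
  invisible(x)
}

#' @export
plot.isn_sensitivity <- function(x, ...) {
  m <- unclass(x)
  attr(m, "Ie") <- attr(m, "delta") <- attr(m, "undefined") <- NULL
  m[is.na(m)] <- 0
  lim <- max(abs(m), 1e-9)
  cols <- grDevices::colorRampPalette(c("blue", "white", "red"))(64)
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), t(m[nrow(m):1, ]),
                  zlim = c(-lim, lim), col = cols, axes = FALSE,
                  xlab = "", ylab = "", ...)
  graphics::axis(1, seq_len(ncol(m)), colnames(m), las = 2, cex.axis = 0.7)
  graphics::axis(2, seq_len(nrow(m)), rev(rownames(m)), las = 2,
                 cex.axis = 0.7)
  graphics::box()
  invisible(x)
}

#' Write a sensitivity matrix to CSV
#'
#' @param x an `isn_sensitivity` matrix.
#' @param path output file.
#' @export
write_sensitivity_csv <- function(x, path) {
  m <- unclass(x)
  attr(m, "Ie") <- attr(m, "delta") <- attr(m, "undefined") <- NULL
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}
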