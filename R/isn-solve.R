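# Fixed-point machinery for the steady-state network.
#
# The full network collapses to two unknowns (PDK1n, mTORC2n): given a trial
# pair, the Akt block and all substrates follow algebraically, the upstream
# layer closes the feedback loops, and the PDK1/mTORC2 layer returns an
# updated pair.  A steady state is a fixed point of that map.

# One sweep of the reduced map.  P, M, IRnY are equal-length vectors (one
# entry per insulin level); returns the updated pair plus the full state.
isn_map <- function(params, env, IRnY, P, M, mtorc1_model = NULL) {
  akt <- akt_block(params, P, M)
  m1 <- if (is.null(mtorc1_model)) NULL else
    mtorc1_model(akt$AktnT + akt$AktnTS)
  down <- downstream_layer(params, env, akt$AktnT, akt$AktnS, akt$AktnTS,
                           P, mTORC1n = m1)
  up <- upstream_layer(params, env, IRnY, down$S6K1n, akt$AktnTS)
  new <- pdk1_mtorc2_layer(params, env, up$PIP3n, down$S6K1n)
  c(new, akt, down, up)
}

assemble_state <- function(I, IRnY, sweep, P, M) {
  structure(list(
    I = I, IRnY = IRnY,
    IRS1nY = sweep$IRS1nY, IRS1nS = sweep$IRS1nS, PTP1Bn = sweep$PTP1Bn,
    PI3Kn = sweep$PI3Kn, PIP3n = sweep$PIP3n,
    PDK1n = P, mTORC2n = M,
    AktnT = sweep$AktnT, AktnS = sweep$AktnS, AktnTS = sweep$AktnTS,
    FoxO1n_cyt = sweep$FoxO1n_cyt, GSK3Bn = sweep$GSK3Bn,
    mTORC1n = sweep$mTORC1n, S6K1n = sweep$S6K1n,
    GLUT4n = sweep$GLUT4n, pAS160n = sweep$pAS160n),
    class = "isn_state")
}

#' Solve the ISN steady state
#'
#' Finds the self-consistent steady state of the full network at the insulin
#' level(s) in `env$Ie` (or `Ie` if supplied) by damped fixed-point iteration
#' on the reduced pair (PDK1n, mTORC2n).  If the iteration fails to converge,
#' the slower grid-search solver ([isn_grid_solve()]) is used as a fallback
#' for the offending insulin levels.
#'
#' @param params an [isn_params()] object.
#' @param env an [isn_environment()] object.
#' @param Ie optional insulin level(s) (nM) overriding `env$Ie`; vectorized.
#' @param mtorc1_model optional function of the mTORC1-activating Akt drive
#'   (`AktnT + AktnTS`) returning normalized mTORC1, replacing the lumped
#'   saturating form (used to wire in the TSC2/Rheb/PRAS40 submodel).
#' @param damping damping factor of the fixed-point iteration (default 0.5).
#' @param tol convergence tolerance on the residual (infinity norm) of the
#'   two reduced equations (default 1e-12).
#' @param max_iter maximum number of iterations (default 1e4).
#' @return An object of class `isn_state`: a list of normalized
#'   concentrations (each a vector along `Ie`) with attributes `Ie` and
#'   `residual`.  All concentrations lie in `[0, 1]`; free insulin `I`
#'   satisfies `0 <= I <= Ie`.
#' @examples
#' st <- isn_steady_state(isn_params(), isn_environment(Ie = 10))
#' st$AktnTS
#' @export
isn_steady_state <- function(params, env, Ie = NULL, mtorc1_model = NULL,
                             damping = 0.5, tol = 1e-12, max_iter = 1e4) {
  validate_isn_params(params)
  if (is.null(Ie)) Ie <- env$Ie
  if (any(Ie < 0)) stop("Ie must be nonnegative")
  m <- length(Ie)
  if (m == 0) {
    st <- assemble_state(numeric(0), numeric(0),
                         isn_map(params, env, numeric(0), numeric(0),
                                 numeric(0), mtorc1_model),
                         numeric(0), numeric(0))
    attr(st, "Ie") <- numeric(0); attr(st, "residual") <- numeric(0)
    return(st)
  }
  ir <- ir_layer(params, Ie)
  P <- rep(0.5, m); M <- rep(0.5, m)
  res <- rep(Inf, m)
  for (it in seq_len(max_iter)) {
    sweep <- isn_map(params, env, ir$IRnY, P, M, mtorc1_model)
    rP <- sweep$PDK1n - P
    rM <- sweep$mTORC2n - M
    res <- pmax(abs(rP), abs(rM))
    if (all(res < tol)) break
    P <- P + damping * rP
    M <- M + damping * rM
  }
  bad <- which(res >= tol)
  if (length(bad)) {
    for (i in bad) {
      g <- isn_grid_solve(params, env, Ie[i], mtorc1_model = mtorc1_model)
      P[i] <- g$PDK1n; M[i] <- g$mTORC2n; res[i] <- attr(g, "residual")
    }
    if (any(res >= 1e-8))
      stop(sprintf("steady-state solver failed at Ie = %s (best residual %.3g)",
                   paste(Ie[res >= 1e-8], collapse = ", "), max(res)))
  }
  sweep <- isn_map(params, env, ir$IRnY, P, M, mtorc1_model)
  st <- assemble_state(ir$I, ir$IRnY, sweep, P, M)
  attr(st, "Ie") <- Ie
  attr(st, "residual") <- res
  st
}

#' @export
print.isn_state <- function(x, ...) {
  Ie <- attr(x, "Ie")
  cat(sprintf("ISN steady state at %d insulin level(s); max residual %.2e\n",
              length(Ie), max(attr(x, "residual"), 0)))
  df <- as.data.frame(x)
  print(cbind(Ie_nM = Ie, round(df, 4)), ...)
  invisible(x)
}

#' @export
as.data.frame.isn_state <- function(x, ...) {
  as.data.frame(unclass(x), ...)
}

#' Brute-force grid solver for the reduced steady-state equations
#'
#' Independent of the damped iteration: minimizes the squared residual of
#' the two reduced equations over a dense grid on the unit square in
#' (PDK1n, mTORC2n), then refines around the best point by repeated local
#' grid zoom.  Used as a reference oracle and as the fallback solver.
#'
#' @inheritParams isn_steady_state
#' @param Ie a single insulin level (nM).
#' @param n_grid points per axis of the coarse grid (default 401).
#' @param refine number of zoom rounds (default 8), each re-gridding a
#'   shrinking square (41 x 41) around the current best point.
#' @return an `isn_state` (single insulin level) with attribute `residual`.
#' @export
isn_grid_solve <- function(params, env, Ie, mtorc1_model = NULL,
                           n_grid = 401, refine = 8) {
  stopifnot(length(Ie) == 1, Ie >= 0)
  ir <- ir_layer(params, Ie)
  obj <- function(P, M) {
    sweep <- isn_map(params, env, rep(ir$IRnY, length(P)), P, M, mtorc1_model)
    (sweep$PDK1n - P)^2 + (sweep$mTORC2n - M)^2
  }
  g <- seq(0, 1, length.out = n_grid)
  gr <- expand.grid(P = g, M = g)
  r2 <- obj(gr$P, gr$M)
  best <- which.min(r2)
  p0 <- gr$P[best]; m0 <- gr$M[best]
  h <- 1 / (n_grid - 1)
  for (k in seq_len(refine)) {
    gp <- seq(max(0, p0 - h), min(1, p0 + h), length.out = 41)
    gm <- seq(max(0, m0 - h), min(1, m0 + h), length.out = 41)
    gr <- expand.grid(P = gp, M = gm)
    r2 <- obj(gr$P, gr$M)
    best <- which.min(r2)
    p0 <- gr$P[best]; m0 <- gr$M[best]
    h <- h / 10
  }
  sweep <- isn_map(params, env, ir$IRnY, p0, m0, mtorc1_model)
  st <- assemble_state(ir$I, ir$IRnY, sweep, p0, m0)
  attr(st, "Ie") <- Ie
  attr(st, "residual") <- max(abs(sweep$PDK1n - p0), abs(sweep$mTORC2n - m0))
  st
}

#' Dose-response curves of all network components
#'
#' Solves the steady state along an insulin grid and returns the normalized
#' concentration of every component at every grid point in long format.
#'
#' @inheritParams isn_steady_state
#' @param insulin nonnegative, sorted insulin grid (nM); the conventional
#'   experimental designs use `c(0, 1, 10, 100)` or `c(0, 0.1, 1, 10, 100)`.
#' @param condition label stored alongside the curves (default "control").
#' @return an object of class `isn_dose_response`: a data frame with columns
#'   `condition`, `Ie_nM`, `analyte`, `value`.
#' @export
isn_dose_response <- function(params, env, insulin = c(0, 0.1, 1, 10, 100),
                              condition = "control", mtorc1_model = NULL) {
  if (any(insulin < 0)) stop("insulin grid must be nonnegative")
  if (is.unsorted(insulin)) stop("insulin grid must be sorted")
  if (length(insulin) == 0) {
    out <- data.frame(condition = character(0), Ie_nM = numeric(0),
                      analyte = character(0), value = numeric(0))
    class(out) <- c("isn_dose_response", "data.frame")
    return(out)
  }
  st <- isn_steady_state(params, env, Ie = insulin,
                         mtorc1_model = mtorc1_model)
  df <- as.data.frame(st)
  out <- data.frame(
    condition = condition,
    Ie_nM = rep(insulin, times = ncol(df)),
    analyte = rep(names(df), each = length(insulin)),
    value = unlist(df, use.names = FALSE))
  rownames(out) <- NULL
  class(out) <- c("isn_dose_response", "data.frame")
  out
}

#' @export
print.isn_dose_response <- function(x, ...) {
  cat(sprintf("ISN dose-response: %d condition(s), %d insulin level(s), %d analytes\n",
              length(unique(x$condition)), length(unique(x$Ie_nM)),
              length(unique(x$analyte))))
  NextMethod()
}

#' @export
plot.isn_dose_response <- function(x, analytes = c("AktnS", "AktnT", "AktnTS",
                                                   "S6K1n", "GLUT4n"), ...) {
  x <- x[x$analyte %in% analytes, , drop = FALSE]
  conds <- unique(x$condition)
  op <- graphics::par(mfrow = c(1, length(analytes)), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (a in analytes) {
    xa <- x[x$analyte == a, , drop = FALSE]
    graphics::plot(NA, xlim = range(xa$Ie_nM), ylim = c(0, max(xa$value, 1e-6)),
                   xlab = "insulin (nM)", ylab = a, main = a, ...)
    for (i in seq_along(conds)) {
      xc <- xa[xa$condition == conds[i], , drop = FALSE]
      graphics::lines(xc$Ie_nM, xc$value, col = i, type = "b", pch = 16)
    }
  }
  invisible(x)
}
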