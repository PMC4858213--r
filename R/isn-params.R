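#' Construct a validated ISN parameter set
#'
#' Builds the full parameter set of the normalized steady-state insulin
#' signalling network (ISN) model.  All parameters are nondimensional rate
#' ratios except `Ie_half` (nM) and `S_half` (1/nM), which parameterize the
#' insulin-receptor layer and from which the internal receptor constants
#' `a0`, `a1` and `ab` are derived (see [ir_reparameterization()]).
#'
#' The Akt block is parameterized by the composite constants `a13d`, `a15e`,
#' `a17g`, `a17d`, `a19g`, `a19e`, `a_theta_e`, `a_eta_d` and the small ratio
#' `mu_ratio` (phosphorylated-Akt degradation over dephosphorylation, kept
#' well below one).  Validity requires `a17d > a17g * a_eta_d` and
#' `a19e > a19g * a_theta_e`; both guarantee nonnegative Akt concentrations.
#'
#' @param rho basal IR tyrosine autophosphorylation fraction at zero
#'   insulin, in (0, 0.5).
#' @param Ie_half total insulin concentration (nM) at which normalized
#'   receptor phosphorylation reaches one half.
#' @param S_half slope (1/nM) of the receptor dose-response at `Ie_half`.
#' @param a2,a3 IRS1 tyrosine-phosphorylation constants (`a2` is the
#'   PTP1B-independent part, zero by default).
#' @param a4 strength of the S6K1 negative feedback on IRS1.
#' @param aP strength of the Akt positive feedback on PTP1B (zero disables).
#' @param a6,a6p PI3K activation constants (quadratic and linear in
#'   tyrosine-phosphorylated IRS1).
#' @param a7,a8 PIP3 layer constants; `a8` multiplies normalized PTEN.
#' @param a9 PDK1 activation constant; `a10` mTORC2 activation by PIP3
#'   (conventionally tied to `a9`); `a10mu` basal mTORC2 term; `a11` mTORC2
#'   activation per unit of the insulin-independent factor J (1/conc.);
#'   `a12` S6K1 negative feedback on mTORC2.
#' @param a10,a10mu,a11,a12 see `a9`.
#' @param a13d,a15e,a17g,a17d,a19g,a19e,a_theta_e,a_eta_d,mu_ratio Akt-block
#'   composite constants (see Details).
#' @param a21 FoxO1 phosphorylation constant (driven by Ser473-containing
#'   Akt forms).
#' @param a23,a23p GSK3beta constants; `a23p` multiplies the sequestration
#'   factor W.
#' @param a24 mTORC1 activation constant (driven by Thr308-containing Akt).
#' @param a26,a26mu,a27 S6K1 constants (mTORC1-driven Thr389 and PDK1-driven
#'   Thr229 steps).
#' @param a28,a29,a30 GLUT4 translocation constants; `a28 < 1` is the basal
#'   surface fraction and `a29 < a30` bounds the response below one.
#' @param a_as160 coefficient of the AS160 (Thr642) saturating response.
#' @param gsk3b_substrate which Akt forms drive GSK3beta phosphorylation:
#'   `"aktT"` (Thr308 + doubly phosphorylated, the default) or `"aktS"`
#'   (Ser473 + doubly phosphorylated, used for insulin-resistant myotubes).
#' @return An object of class `isn_params` (a named list).
#' @seealso [isn_environment()], [isn_steady_state()], [apply_condition()]
#' @examples
#' p <- isn_params()
#' p$a0   # derived from Ie_half, S_half, rho
#' @export
isn_params <- function(rho = 0.03, Ie_half = 44.68, S_half = 0.008,
                       a2 = 0, a3 = 1, a4 = 0.5, aP = 0,
                       a6 = 4, a6p = 0.1, a7 = 0, a8 = 1,
                       a9 = 2, a10 = a9, a10mu = 0, a11 = 0, a12 = 1e-4,
                       a13d = 0.3, a15e = 0.3, a17g = 0.5, a17d = 1,
                       a19g = 0.5, a19e = 1, a_theta_e = 0.5, a_eta_d = 0.5,
                       mu_ratio = 0.005,
                       a21 = 2, a23 = 2, a23p = 0, a24 = 2,
                       a26 = 2, a26mu = 0.01, a27 = 2,
                       a28 = 0.2, a29 = 4, a30 = 6,
                       a_as160 = 0.5, gsk3b_substrate = c("aktT", "aktS")) {
  gsk3b_substrate <- match.arg(gsk3b_substrate)
  ir <- ir_reparameterization(Ie_half, S_half, rho)
  p <- list(rho = rho, Ie_half = Ie_half, S_half = S_half,
            a0 = ir[["a0"]], a1 = ir[["a1"]], ab = ir[["ab"]],
            a2 = a2, a3 = a3, a4 = a4, aP = aP,
            a6 = a6, a6p = a6p, a7 = a7, a8 = a8,
            a9 = a9, a10 = a10, a10mu = a10mu, a11 = a11, a12 = a12,
            a13d = a13d, a15e = a15e, a17g = a17g, a17d = a17d,
            a19g = a19g, a19e = a19e,
            a_theta_e = a_theta_e, a_eta_d = a_eta_d, mu_ratio = mu_ratio,
            a21 = a21, a23 = a23, a23p = a23p, a24 = a24,
            a26 = a26, a26mu = a26mu, a27 = a27,
            a28 = a28, a29 = a29, a30 = a30,
            a_as160 = a_as160, gsk3b_substrate = gsk3b_substrate)
  class(p) <- "isn_params"
  validate_isn_params(p)
  p
}

#' @export
print.isn_params <- function(x, ...) {
  cat("ISN parameter set\n")
  cat(sprintf("  IR layer: rho = %.4g, Ie_half = %.4g nM, S_half = %.4g /nM\n",
              x$rho, x$Ie_half, x$S_half))
  num <- vapply(x, is.numeric, logical(1))
  v <- unlist(x[num])
  cat("  ", paste(sprintf("%s=%.4g", names(v)[-(1:3)], v[-(1:3)]),
                  collapse = ", "), "\n", sep = "")
  cat(sprintf("  GSK3beta driven by: %s\n", x$gsk3b_substrate))
  invisible(x)
}

#' Validate an ISN parameter set
#'
#' Checks nonnegativity, the receptor-layer consistency `ab = a0*rho/(1-rho)`,
#' the GLUT4 bounds `a28 < 1`, `a29 < a30`, and the Akt-block positivity
#' constraints `a17d - a17g*a_eta_d > 0`, `a19e - a19g*a_theta_e > 0`.
#'
#' @param p an `isn_params` object.
#' @return `p`, invisibly; signals an error naming the violated constraint.
#' @export
validate_isn_params <- function(p) {
  num <- vapply(p, is.numeric, logical(1))
  v <- unlist(p[num])
  if (any(!is.finite(v))) stop("non-finite parameter: ",
                               paste(names(v)[!is.finite(v)], collapse = ", "))
  if (any(v < 0)) stop("negative parameter: ",
                       paste(names(v)[v < 0], collapse = ", "))
  if (p$rho <= 0 || p$rho >= 0.5) stop("constraint violated: 0 < rho < 0.5")
  if (p$a28 >= 1) stop("constraint violated: a28 < 1")
  if (p$a29 >= p$a30) stop("constraint violated: a29 < a30")
  if (p$a17d - p$a17g * p$a_eta_d <= 0)
    stop("constraint violated: a17d - a17g*a_eta_d > 0")
  if (p$a19e - p$a19g * p$a_theta_e <= 0)
    stop("constraint violated: a19e - a19g*a_theta_e > 0")
  if (abs(p$ab - p$a0 * p$rho / (1 - p$rho)) > 1e-8 * max(1, p$ab))
    stop("constraint violated: ab = a0*rho/(1-rho)")
  if (p$mu_ratio > 0.01) stop("constraint violated: mu_ratio <= 0.01")
  if (!p$gsk3b_substrate %in% c("aktT", "aktS"))
    stop("gsk3b_substrate must be 'aktT' or 'aktS'")
  invisible(p)
}

#' Modify an ISN parameter set
#'
#' Returns a copy of `p` with the named entries replaced and re-validated.
#' Changing any of `rho`, `Ie_half`, `S_half` re-derives `a0`, `a1`, `ab`;
#' these derived constants cannot be set directly.
#'
#' @param p an `isn_params` object.
#' @param ... name = value replacements.
#' @return a new `isn_params` object.
#' @export
update_isn_params <- function(p, ...) {
  repl <- list(...)
  if (length(repl) == 0) return(p)
  nm <- names(repl)
  if (is.null(nm) || any(nm == "")) stop("all replacements must be named")
  bad <- setdiff(nm, names(p))
  if (length(bad)) stop("unknown parameter: ", paste(bad, collapse = ", "))
  if (any(nm %in% c("a0", "a1", "ab")))
    stop("a0, a1, ab are derived from Ie_half, S_half, rho; set those instead")
  p[nm] <- repl
  if (any(nm %in% c("rho", "Ie_half", "S_half"))) {
    ir <- ir_reparameterization(p$Ie_half, p$S_half, p$rho)
    p[c("a0", "a1", "ab")] <- ir[c("a0", "a1", "ab")]
  }
  validate_isn_params(p)
  p
}

#' Construct the extracellular environment of the ISN
#'
#' @param Ie total extracellular insulin (nM).
#' @param J concentration (arbitrary units) of the insulin-independent
#'   mTORC2-activating factor implicated in insulin resistance.
#' @param PTEN_n normalized PTEN level in `[0, 1]` (1 = control, 0.1 = PTEN
#'   silenced to 10 percent).
#' @param W GSK3beta sequestration factor (0 = inactive).
#' @return an object of class `isn_environment`.
#' @export
isn_environment <- function(Ie = 0, J = 0.001, PTEN_n = 1, W = 0) {
  if (any(c(Ie, J, PTEN_n, W) < 0)) stop("environment values must be nonnegative")
  if (PTEN_n > 1) stop("PTEN_n must lie in [0, 1]")
  structure(list(Ie = Ie, J = J, PTEN_n = PTEN_n, W = W),
            class = "isn_environment")
}

#' @export
print.isn_environment <- function(x, ...) {
  cat(sprintf("ISN environment: Ie = %.4g nM, J = %.4g, PTEN_n = %.3g, W = %.3g\n",
              x$Ie, x$J, x$PTEN_n, x$W))
  invisible(x)
}

#' Convert the receptor half-response parameterization to internal constants
#'
#' The insulin-receptor layer is parameterized by the half-response insulin
#' concentration `Ie_half`, the slope `S_half` of the receptor curve at that
#' point, and the basal phosphorylation fraction `rho`.  The internal
#' constants are recovered as
#' \deqn{a_0 = \left(\frac{1}{2 S_{0.5}} - \frac{I_{e,0.5}}{1-2\rho}\right)
#'        \frac{1-\rho}{1-2\rho}, \quad
#'       a_1 = \left(\frac{4 I_{e,0.5}(1-\rho)}{1-2\rho} -
#'        \frac{1}{S_{0.5}}\right)\frac{1-\rho}{1-2\rho},}
#' with \eqn{a_b = a_0 \rho/(1-\rho)}.  Both bracketed terms must be positive;
#' this bounds `S_half` inside
#' \eqn{\big((1-2\rho)/(4 I_{e,0.5} (1-\rho)),\; (1-2\rho)/(2 I_{e,0.5})\big)}.
#' The forward map is the exact algebraic inverse:
#' \eqn{I_{e,0.5} = (a_0 + a_1/2)(1-2\rho)/(1-\rho)} and
#' \eqn{S_{0.5} = (1-\rho)/(a_1 + 4 a_0 (1-\rho))}.
#'
#' @param Ie_half half-response insulin concentration (nM), positive.
#' @param S_half receptor-curve slope at `Ie_half` (1/nM), positive.
#' @param rho basal phosphorylation fraction, in (0, 0.5).
#' @return named numeric vector with elements `a0`, `a1`, `ab`.
#' @seealso [ir_forward_map()] for the inverse direction.
#' @export
ir_reparameterization <- function(Ie_half, S_half, rho) {
  if (!(rho > 0 && rho < 0.5)) stop("rho must lie in (0, 0.5)")
  if (Ie_half <= 0 || S_half <= 0) stop("Ie_half and S_half must be positive")
  u <- (1 - rho) / (1 - 2 * rho)
  b0 <- 1 / (2 * S_half) - Ie_half / (1 - 2 * rho)
  b1 <- 4 * Ie_half * (1 - rho) / (1 - 2 * rho) - 1 / S_half
  if (b0 <= 0)
    stop("constraint violated: 1/(2*S_half) - Ie_half/(1-2*rho) must be positive")
  if (b1 <= 0)
    stop("constraint violated: 4*Ie_half*(1-rho)/(1-2*rho) - 1/S_half must be positive")
  a0 <- b0 * u
  a1 <- b1 * u
  c(a0 = a0, a1 = a1, ab = a0 * rho / (1 - rho))
}

#' Recover (Ie_half, S_half) from the internal receptor constants
#'
#' Algebraic inverse of [ir_reparameterization()].
#'
#' @param a0,a1 internal receptor constants (nM), positive.
#' @param rho basal phosphorylation fraction, in (0, 0.5).
#' @return named numeric vector with elements `Ie_half`, `S_half`.
#' @export
ir_forward_map <- function(a0, a1, rho) {
  if (!(rho > 0 && rho < 0.5)) stop("rho must lie in (0, 0.5)")
  c(Ie_half = (a0 + a1 / 2) * (1 - 2 * rho) / (1 - rho),
    S_half = (1 - rho) / (a1 + 4 * a0 * (1 - rho)))
}

#' Named experimental condition presets
#'
#' Returns the modified `(params, environment)` pair describing a named
#' experimental condition:
#' \describe{
#'   \item{control}{identity.}
#'   \item{pten_silenced}{normalized PTEN reduced to 0.1.}
#'   \item{dbdb}{insulin-resistant conditioned medium: the
#'     mTORC2-activating factor raised to `J = 0.07`, GSK3beta sequestration
#'     active (`W = 1`, GSK3beta driven by Ser473-containing Akt), a twofold
#'     increase of the IRS1 degradation rate (implemented as `a6 / 4`,
#'     `a6p / 2` because PI3K activation is quadratic in phospho-IRS1), and
#'     GLUT4 translocation capacity reduced (`a28`, `a29` scaled by
#'     `glut4_scale`).}
#'   \item{rapamycin}{mTORC1 activation constant `a24` scaled by 0.1.}
#'   \item{pp242}{dual mTOR inhibition: `a10`, `a11`, `a24` scaled by 0.15.}
#'   \item{ucn01}{PDK1 inhibition: `a9` scaled by 0.1.}
#'   \item{custom}{user-specified `multipliers` on parameters and
#'     environment overrides.}
#' }
#'
#' @param params an `isn_params` object.
#' @param env an `isn_environment` object.
#' @param preset preset name (see Details) or a list with elements
#'   `name = "custom"`, `multipliers` (named numeric, strictly positive) and
#'   optionally `environment` (named list of overrides among Ie, J, PTEN_n, W).
#' @param dbdb_mu_scale assumed fold-increase of the IRS1 degradation rate
#'   in the db/db condition (default 2).
#' @param dbdb_glut4_scale scale applied to `a28` and `a29` in the db/db
#'   condition (default 0.5).
#' @return list with elements `params` and `env`.
#' @export
apply_condition <- function(params, env, preset,
                            dbdb_mu_scale = 2, dbdb_glut4_scale = 0.5) {
  if (is.list(preset)) {
    if (is.null(preset$name) || !identical(preset$name, "custom"))
      stop("list presets must have name = 'custom'")
    mult <- preset$multipliers
    if (!is.null(mult)) {
      if (any(mult <= 0)) stop("condition multipliers must be strictly positive")
      bad <- setdiff(names(mult), names(params))
      if (length(bad)) stop("unknown parameter in multipliers: ",
                            paste(bad, collapse = ", "))
      for (nm in names(mult))
        params <- do.call(update_isn_params,
                          c(list(params),
                            stats::setNames(list(params[[nm]] * mult[[nm]]), nm)))
    }
    ov <- preset$environment
    if (!is.null(ov)) {
      bad <- setdiff(names(ov), c("Ie", "J", "PTEN_n", "W"))
      if (length(bad)) stop("unknown environment override: ",
                            paste(bad, collapse = ", "))
      for (nm in names(ov)) env[[nm]] <- ov[[nm]]
      env <- isn_environment(env$Ie, env$J, env$PTEN_n, env$W)
    }
    return(list(params = params, env = env))
  }
  preset <- match.arg(preset, c("control", "pten_silenced", "dbdb",
                                "rapamycin", "pp242", "ucn01"))
  switch(preset,
    control = NULL,
    pten_silenced = {
      env <- isn_environment(env$Ie, env$J, 0.1, env$W)
    },
    dbdb = {
      env <- isn_environment(env$Ie, 0.07, env$PTEN_n, 1)
      params <- update_isn_params(params,
        a6 = params$a6 / dbdb_mu_scale^2,
        a6p = params$a6p / dbdb_mu_scale,
        a28 = params$a28 * dbdb_glut4_scale,
        a29 = params$a29 * dbdb_glut4_scale,
        gsk3b_substrate = "aktS")
    },
    rapamycin = {
      params <- update_isn_params(params, a24 = params$a24 * 0.1)
    },
    pp242 = {
      params <- update_isn_params(params, a10 = params$a10 * 0.15,
                                  a11 = params$a11 * 0.15,
                                  a24 = params$a24 * 0.15)
    },
    ucn01 = {
      params <- update_isn_params(params, a9 = params$a9 * 0.1)
    })
  list(params = params, env = env)
}
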