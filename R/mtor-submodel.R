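# TSC2/Rheb/PRAS40 activation submodel of mTORC1, and the Akt-localization
# adequacy checks.
#
# The submodel refines the lumped one-constant mTORC1 activation law:
# phosphorylated Akt (Thr308-containing forms) inactivates TSC2; active TSC2
# keeps Rheb GDP-loaded, so TSC2 inactivation raises Rheb/GTP, which
# activates mTORC1; PRAS40 binds and inhibits mTORC1 and is itself relieved
# by Akt phosphorylation.  Synthesis rates enter only through ratios: phi
# encodes the PRAS40/mTORC1 synthesis ratio via 1 + phi = b_mTORC1/b_PRAS,
# and the catalytic constants K_mTOR, K_mTOR_mu scale inversely with the
# PRAS40 synthesis rate.

#' Parameters of the mTORC1 activation submodel
#'
#' @param K_TSC strength of TSC2 inactivation by phosphorylated Akt.
#' @param K_Rheb strength of Rheb/GTP suppression by active TSC2
#'   (proportional to the TSC2 synthesis rate; zero reproduces TSC2-null).
#' @param K_mTORC1 mTORC1 saturation constant.
#' @param K_PRAS strength of PRAS40 phosphorylation (inhibition relief) by
#'   Akt.
#' @param phi PRAS40/mTORC1 synthesis-ratio parameter, in (-1, Inf);
#'   `1 + phi` equals the mTORC1-to-PRAS40 synthesis-rate ratio (the default
#'   -2/3 corresponds to PRAS40 synthesized three times faster).
#' @param K_mTOR catalytic constant of Rheb/GTP-driven mTORC1 activation
#'   (per unit PRAS40 synthesis); the default is calibrated so that, driven
#'   by the reference myotube Akt profile, the submodel reproduces the
#'   lumped single-constant mTORC1 law.
#' @param K_mTOR_mu basal (Rheb-independent) activation constant.
#' @return an object of class `mtorc1_params`.
#' @export
mtorc1_params <- function(K_TSC = 65.95, K_Rheb = 6.48, K_mTORC1 = 7.2e-3,
                          K_PRAS = 16.72, phi = -0.67,
                          K_mTOR = 0.0405, K_mTOR_mu = 1e-4) {
  if (phi <= -1) stop("phi must exceed -1")
  vals <- c(K_TSC, K_Rheb, K_mTORC1, K_PRAS, K_mTOR, K_mTOR_mu)
  if (any(vals < 0)) stop("submodel constants must be nonnegative")
  structure(list(K_TSC = K_TSC, K_Rheb = K_Rheb, K_mTORC1 = K_mTORC1,
                 K_PRAS = K_PRAS, phi = phi, K_mTOR = K_mTOR,
                 K_mTOR_mu = K_mTOR_mu),
            class = "mtorc1_params")
}

#' @export
print.mtorc1_params <- function(x, ...) {
  cat("mTORC1 activation submodel parameters\n")
  v <- unlist(x)
  cat("  ", paste(sprintf("%s=%.4g", names(v), v), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Steady state of the mTORC1 activation submodel
#'
#' Given the activating Akt drive (normalized `AktnT + AktnTS`), evaluates
#' the self-consistent normalized levels of active TSC2, Rheb/GTP, the
#' inhibitory (unphosphorylated) PRAS40 fraction, and active mTORC1:
#' \deqn{TSC2_n = \frac{1}{1 + K_{TSC} A}, \quad
#'       Rheb/GTP_n = \frac{1}{1 + b_{TSC} K_{Rheb}\, TSC2_n}, \quad
#'       PRAS40_n = \frac{1}{1 + K_{PRAS} A},}
#' \deqn{mTORC1_n = \frac{x}{1 + x}, \qquad
#'       x = \frac{(K_{mTOR}/b_{PRAS})\, b_{Rheb}\, Rheb/GTP_n +
#'                 K_{mTOR\mu}/b_{PRAS}}
#'                {K_{mTORC1}\,\big(1 + \tfrac{b_{PRAS}}{1+\varphi}
#'                 PRAS40_n\big)}.}
#' Setting `b_TSC = 0` (TSC2 loss) forces `Rheb/GTPn = 1` exactly; the
#' submodel output is monotone increasing in the Akt drive.
#'
#' @param sub an [mtorc1_params()] object.
#' @param akt_drive normalized activating Akt (`AktnT + AktnTS`), in
#'   `[0, 1]`; vectorized.
#' @param b_PRAS,b_Rheb,b_TSC synthesis-rate multipliers relative to control
#'   (default 1); knockdown/overexpression perturbations scale these.
#' @param K_mTOR_scale multiplier on the catalytic constant `K_mTOR`
#'   (rapamycin acts here).
#' @return list with elements `TSC2n`, `RhebGTPn`, `PRAS40n`, `mTORC1n`,
#'   each in `[0, 1]`.
#' @export
mtorc1_submodel_steady <- function(sub, akt_drive, b_PRAS = 1, b_Rheb = 1,
                                   b_TSC = 1, K_mTOR_scale = 1) {
  if (any(akt_drive < 0 | akt_drive > 1))
    stop("akt_drive must lie in [0, 1]")
  A <- akt_drive
  TSC2n <- 1 / (1 + sub$K_TSC * A)
  RhebGTPn <- 1 / (1 + b_TSC * sub$K_Rheb * TSC2n)
  PRAS40n <- 1 / (1 + sub$K_PRAS * A)
  r <- b_PRAS / (1 + sub$phi)  # PRAS40-to-mTORC1 abundance ratio
  x <- (sub$K_mTOR * K_mTOR_scale / b_PRAS * b_Rheb * RhebGTPn +
          sub$K_mTOR_mu / b_PRAS) /
    (sub$K_mTORC1 * (1 + r * PRAS40n))
  list(TSC2n = TSC2n, RhebGTPn = RhebGTPn, PRAS40n = PRAS40n,
       mTORC1n = x / (1 + x))
}

#' Build a closure wiring the submodel into the full network
#'
#' @inheritParams mtorc1_submodel_steady
#' @return a function of `akt_drive` returning `mTORC1n`, usable as the
#'   `mtorc1_model` argument of [isn_steady_state()].
#' @export
mtorc1_model_fn <- function(sub, b_PRAS = 1, b_Rheb = 1, b_TSC = 1,
                            K_mTOR_scale = 1) {
  force(sub)
  function(akt_drive)
    mtorc1_submodel_steady(sub, akt_drive, b_PRAS = b_PRAS, b_Rheb = b_Rheb,
                           b_TSC = b_TSC,
                           K_mTOR_scale = K_mTOR_scale)$mTORC1n
}

#' Calibrate the submodel catalytic constant against the lumped mTORC1 law
#'
#' Chooses `K_mTOR` so that, driven by the Akt profile of the full network
#' under `params` along an insulin grid, the submodel reproduces the lumped
#' one-constant mTORC1 activation curve in the least-squares sense.
#'
#' @param sub an [mtorc1_params()] object (all constants but `K_mTOR` used
#'   as given).
#' @param params,env the reference network and environment.
#' @param insulin insulin grid (nM) spanning the calibration range.
#' @return `sub` with calibrated `K_mTOR`; attribute `"rmse"` holds the
#'   residual curve mismatch.
#' @export
calibrate_mtorc1_submodel <- function(sub, params, env,
                                      insulin = c(0, 10^seq(-2, 2, by = 0.25))) {
  st <- isn_steady_state(params, env, Ie = insulin)
  drive <- st$AktnT + st$AktnTS
  target <- st$mTORC1n
  obj <- function(logK) {
    s <- sub; s$K_mTOR <- exp(logK)
    m <- mtorc1_submodel_steady(s, drive)$mTORC1n
    sum((m - target)^2)
  }
  opt <- stats::optimize(obj, c(-15, 5))
  sub$K_mTOR <- exp(opt$minimum)
  attr(sub, "rmse") <- sqrt(opt$objective / length(drive))
  sub
}

# Perturbation presets of the extended model: multipliers on synthesis
# rates / catalytic constants, the Akt-block scale applied for long-term
# rapamycin, and the insulin level conventionally used to display each.
mtor_perturbations <- list(
  pras_kd      = list(b_PRAS = 0.1, Ie = 1),
  pras_oe      = list(b_PRAS = 2, Ie = 1),
  pras_rheb_oe = list(b_PRAS = 2, b_Rheb = 5, Ie = 1),
  tsc2_null    = list(b_TSC = 0, Ie = 1),
  rapa_short   = list(K_mTOR_scale = 0.1, Ie = 10),
  rapa_long    = list(K_mTOR_scale = 0.1, mtorc2_scale = 0.1, Ie = 10))

#' Simulate a named perturbation of the extended (submodel-based) network
#'
#' Solves the full network with the lumped mTORC1 law replaced by the
#' TSC2/Rheb/PRAS40 submodel and the named perturbation applied:
#' \describe{
#'   \item{pras_kd / pras_oe}{PRAS40 synthesis scaled by 0.1 / 2.}
#'   \item{pras_rheb_oe}{PRAS40 synthesis doubled and Rheb synthesis
#'     increased fivefold.}
#'   \item{tsc2_null}{TSC2 synthesis set to zero (Rheb/GTP pinned at one).}
#'   \item{rapa_short}{catalytic mTORC1 activation reduced tenfold.}
#'   \item{rapa_long}{as `rapa_short`, plus the mTORC2 synthesis rate
#'     reduced tenfold, which scales the Akt-block constants `a15e`, `a19e`
#'     and `a19g`.}
#' }
#' Multipliers are taken from the preset table and can be overridden via
#' `...` (e.g. `b_PRAS = 0.2`).
#'
#' @param params an [isn_params()] object (reference network).
#' @param env an [isn_environment()] object.
#' @param sub an [mtorc1_params()] object.
#' @param name perturbation name (see Details), or `"control"`.
#' @param Ie insulin level (nM); default from the preset table.
#' @param ... overrides of the preset multipliers.
#' @return an `isn_state` with attribute `"submodel"` holding the submodel
#'   state at the solution.
#' @export
simulate_perturbation <- function(params, env, sub, name, Ie = NULL, ...) {
  if (!name %in% c("control", names(mtor_perturbations)))
    stop("unknown perturbation: ", name)
  pre <- if (name == "control") list(Ie = 1) else mtor_perturbations[[name]]
  ov <- list(...)
  pre[names(ov)] <- ov
  if (is.null(Ie)) Ie <- pre$Ie
  mult <- function(nm, def = 1) if (is.null(pre[[nm]])) def else pre[[nm]]
  if (!is.null(pre$mtorc2_scale)) {
    s <- pre$mtorc2_scale
    params <- update_isn_params(params, a15e = params$a15e * s,
                                a19e = params$a19e * s,
                                a19g = params$a19g * s)
  }
  fn <- mtorc1_model_fn(sub, b_PRAS = mult("b_PRAS"),
                        b_Rheb = mult("b_Rheb"), b_TSC = mult("b_TSC"),
                        K_mTOR_scale = mult("K_mTOR_scale"))
  st <- isn_steady_state(params, env, Ie = Ie, mtorc1_model = fn)
  attr(st, "submodel") <-
    mtorc1_submodel_steady(sub, st$AktnT + st$AktnTS,
                           b_PRAS = mult("b_PRAS"), b_Rheb = mult("b_Rheb"),
                           b_TSC = mult("b_TSC"),
                           K_mTOR_scale = mult("K_mTOR_scale"))
  st
}

#' Parameters of the compartmental Akt localization model
#'
#' Rate and saturation constants of the membrane/cytosol/nucleus Akt
#' transport scheme: `k13`/`k_minus13` govern PIP3-mediated recruitment of
#' unphosphorylated Akt to the plasma membrane and its return, `K13` the
#' recruitment saturation, `k_mc` transport of phosphorylated Akt from
#' membrane to cytosol, `k_cn`/`k_nc` nuclear import/export, and `K14`,
#' `K15` the PP2A dephosphorylation constants at membrane and cytosol.
#'
#' @param k13,k_minus13,K13,k_mc,k_cn,k_nc,K14,K15,PP2A nonnegative
#'   constants.
#' @return an object of class `akt_localization_params`.
#' @export
akt_localization_params <- function(k13 = 1, k_minus13 = 0.01, K13 = 1,
                                    k_mc = 10, k_cn = 1, k_nc = 1,
                                    K14 = 0.1, K15 = 10, PP2A = 1) {
  v <- c(k13, k_minus13, K13, k_mc, k_cn, k_nc, K14, K15, PP2A)
  if (any(v < 0)) stop("localization constants must be nonnegative")
  structure(list(k13 = k13, k_minus13 = k_minus13, K13 = K13, k_mc = k_mc,
                 k_cn = k_cn, k_nc = k_nc, K14 = K14, K15 = K15,
                 PP2A = PP2A),
            class = "akt_localization_params")
}

#' Check the conditions under which compartmental Akt reduces to lumped Akt
#'
#' At steady state the membrane, cytosolic and nuclear phosphorylated-Akt
#' concentrations tend to a common value, so the lumped (well-mixed) Akt
#' block is adequate, provided (i) nuclear import and export balance
#' (`k_nc` close to `k_cn`), (ii) membrane-to-cytosol transport matches
#' cytosolic dephosphorylation (`k_mc` close to `K15 * PP2A`), (iii) the
#' recruitment drives `K13 * PIP3` and `K13 * PDK1` are comparable, (iv) the
#' back-transport `k_minus13` is much smaller than both, and (v) transport
#' `k_mc` is much larger than membrane dephosphorylation `K14 * PP2A`.
#'
#' @param loc an [akt_localization_params()] object.
#' @param PIP3 normalized PIP3 level.
#' @param PDK1 normalized PDK1 level.
#' @param rel_tol relative tolerance for the equality conditions
#'   (default 0.25).
#' @param factor fold-difference required by the "much smaller/larger"
#'   conditions (default 10).
#' @return data frame with one row per condition: `condition`, `satisfied`,
#'   `margin` (ratio tested), deterministic in its inputs.
#' @export
akt_localization_equalization <- function(loc, PIP3, PDK1, rel_tol = 0.25,
                                          factor = 10) {
  rel <- function(a, b) abs(a - b) / pmax((a + b) / 2, .Machine$double.eps)
  drive_p <- loc$K13 * PIP3
  drive_k <- loc$K13 * PDK1
  out <- data.frame(
    condition = c("nuclear_balance", "transport_matches_dephosphorylation",
                  "comparable_recruitment_drives",
                  "back_transport_negligible",
                  "transport_dominates_membrane_dephosphorylation"),
    satisfied = c(rel(loc$k_nc, loc$k_cn) <= rel_tol,
                  rel(loc$k_mc, loc$K15 * loc$PP2A) <= rel_tol,
                  rel(drive_p, drive_k) <= rel_tol,
                  loc$k_minus13 * factor <= min(drive_p, drive_k),
                  loc$k_mc >= factor * loc$K14 * loc$PP2A),
    margin = c(rel(loc$k_nc, loc$k_cn),
               rel(loc$k_mc, loc$K15 * loc$PP2A),
               rel(drive_p, drive_k),
               loc$k_minus13 / pmax(min(drive_p, drive_k),
                                    .Machine$double.eps),
               loc$k_mc / pmax(loc$K14 * loc$PP2A, .Machine$double.eps)))
  out
}
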