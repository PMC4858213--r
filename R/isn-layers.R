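#' Insulin-receptor layer
#'
#' Computes the free insulin concentration and the normalized tyrosine
#' phosphorylated insulin receptor at a total extracellular insulin level.
#' Free insulin is the nonnegative root of the receptor-binding quadratic,
#' \deqn{I = \tfrac12\left(-(a_b+a_0+a_1-I_e) +
#'   \sqrt{(a_b+a_0+a_1-I_e)^2 + 4 (a_b+a_0) I_e}\right),}
#' and the receptor response is \eqn{IR^Y_n = (a_b + I)/(a_b + a_0 + I)},
#' equal to `rho` at zero insulin and strictly increasing in `Ie`.
#'
#' @param params an [isn_params()] object.
#' @param Ie total extracellular insulin (nM); may be a vector.
#' @return list with numeric elements `I` (free insulin, nM) and `IRnY`.
#' @export
ir_layer <- function(params, Ie) {
  if (any(Ie < 0)) stop("Ie must be nonnegative")
  ab <- params$ab; a0 <- params$a0; a1 <- params$a1
  b <- ab + a0 + a1 - Ie
  disc <- b^2 + 4 * (ab + a0) * Ie
  I <- 0.5 * (-b + sqrt(disc))
  I <- pmax(I, 0)  # guard roundoff at Ie = 0
  list(I = I, IRnY = (ab + I) / (ab + a0 + I))
}

#' Upstream signalling layer: PTP1B, IRS1, PI3K, PIP3
#'
#' Evaluates the saturating steady-state forms for the phosphatase PTP1B
#' (under Akt positive feedback), tyrosine- and serine-phosphorylated IRS1
#' (under S6K1 negative feedback), PI3K (quadratic in phospho-IRS1) and PIP3
#' (shaped by normalized PTEN).
#'
#' @param params an [isn_params()] object.
#' @param env an [isn_environment()] object (supplies `PTEN_n`).
#' @param IRnY normalized phospho-IR, in `[0, 1]` (vectorized).
#' @param S6K1n normalized active S6K1, in `[0, 1]`.
#' @param AktnTS normalized doubly phosphorylated Akt, in `[0, 1]`.
#' @return list with elements `PTP1Bn`, `IRS1nY`, `IRS1nS`, `PI3Kn`, `PIP3n`.
#' @export
upstream_layer <- function(params, env, IRnY, S6K1n, AktnTS) {
  p <- params
  PTP1Bn <- 1 / (1 + p$aP * AktnTS)
  g <- (p$a2 + p$a3 * PTP1Bn) * (1 + p$a4 * S6K1n) + IRnY
  IRS1nY <- IRnY / g
  IRS1nS <- (p$a2 + p$a3 * PTP1Bn) * p$a4 * S6K1n / g
  PI3Kn <- p$a6 * IRS1nY^2 / (1 + p$a6p * IRS1nY + p$a6 * IRS1nY^2)
  den <- p$a7 + p$a8 * env$PTEN_n + PI3Kn
  PIP3n <- ifelse(den > 0, PI3Kn / den, 0)
  list(PTP1Bn = PTP1Bn, IRS1nY = IRS1nY, IRS1nS = IRS1nS,
       PI3Kn = PI3Kn, PIP3n = PIP3n)
}

#' PDK1 and mTORC2 layer
#'
#' PDK1 follows a saturating response to PIP3; mTORC2 is activated by PIP3
#' and by the insulin-independent factor J, attenuated by the S6K1 negative
#' feedback on Rictor:
#' \deqn{mTORC2_n = \frac{a_{10} PIP3_n + a_{11} J}
#'   {1 + (1 + a_{12} S6K1_n)(a_{10\mu} + a_{10} PIP3_n + a_{11} J)}.}
#'
#' @inheritParams upstream_layer
#' @param PIP3n normalized PIP3, in `[0, 1]` (vectorized).
#' @return list with elements `PDK1n`, `mTORC2n`.
#' @export
pdk1_mtorc2_layer <- function(params, env, PIP3n, S6K1n) {
  p <- params
  PDK1n <- p$a9 * PIP3n / (1 + p$a9 * PIP3n)
  drive <- p$a10mu + p$a10 * PIP3n + p$a11 * env$J
  mTORC2n <- (p$a10 * PIP3n + p$a11 * env$J) /
    (1 + (1 + p$a12 * S6K1n) * drive)
  list(PDK1n = PDK1n, mTORC2n = mTORC2n)
}

#' Three-state Akt phosphorylation block
#'
#' Rational steady-state forms for Akt phosphorylated at Thr308 only
#' (`AktnT`, by PDK1), Ser473 only (`AktnS`, by mTORC2) and both residues
#' (`AktnTS`), sharing a common denominator.  The two phosphorylation sites
#' are independent, so either order of events leads to full activation; the
#' small composite `mu_ratio` replaces a near-cancelling combination of
#' constants in the denominator.  All three forms lie in `[0, 1]` and their
#' sum never exceeds one.
#'
#' @param params an [isn_params()] object.
#' @param PDK1n,mTORC2n normalized kinase levels in `[0, 1]` (vectorized).
#' @return list with elements `AktnT`, `AktnS`, `AktnTS`.
#' @export
akt_block <- function(params, PDK1n, mTORC2n) {
  p <- params
  if (p$a17d - p$a17g * p$a_eta_d <= 0)
    stop("constraint violated: a17d - a17g*a_eta_d > 0")
  if (p$a19e - p$a19g * p$a_theta_e <= 0)
    stop("constraint violated: a19e - a19g*a_theta_e > 0")
  P <- PDK1n; M <- mTORC2n
  ate <- p$a_theta_e; aed <- p$a_eta_d
  cross <- p$a13d * (p$a19e - p$a19g * ate) +
    p$a15e * (p$a17d - p$a17g * aed) +
    p$a17g * p$a15e + p$a19g * p$a13d +
    p$a17d * p$a19e * p$mu_ratio
  D1p <- p$a13d * p$a17g * P^2 * (p$a19e * M + ate) +
    p$a15e * p$a19g * M^2 * (p$a17d * P + aed) +
    P * M * cross +
    P * (p$a13d + p$a17g * ate) +
    M * (p$a15e + p$a19g * aed) + 1
  AktnT <- P * (p$a13d * p$a17g * ate * P +
                  p$a15e * (p$a17d - p$a17g * aed) * M + p$a13d) / D1p
  AktnS <- M * (p$a15e * p$a19g * aed * M +
                  p$a13d * (p$a19e - p$a19g * ate) * P + p$a15e) / D1p
  AktnTS <- P * M * (p$a15e * p$a17d * p$a19g * M +
                       p$a13d * p$a19e * p$a17g * P +
                       p$a15e * p$a17g + p$a13d * p$a19g) / D1p
  list(AktnT = AktnT, AktnS = AktnS, AktnTS = AktnTS)
}

#' Downstream substrate layer: FoxO1, GSK3beta, mTORC1, S6K1, GLUT4, AS160
#'
#' Saturating responses of the direct and indirect Akt substrates.
#' Cytoplasmic FoxO1 is driven by the Ser473-containing Akt forms; GSK3beta
#' by the Thr308-containing forms (or the Ser473-containing forms when
#' `gsk3b_substrate = "aktS"`), with sequestration term `a23p * W`; mTORC1
#' and GLUT4 by the Thr308-containing forms; S6K1 requires both mTORC1
#' (Thr389) and PDK1 (Thr229):
#' \deqn{S6K1_n = \frac{a_{26} mTORC1_n \, a_{27} PDK1_n}
#'   {1 + a_{26} mTORC1_n + (a_{26\mu} + a_{26} mTORC1_n) a_{27} PDK1_n}.}
#'
#' @inheritParams upstream_layer
#' @param AktnT,AktnS,AktnTS normalized Akt forms in `[0, 1]` (vectorized).
#' @param PDK1n normalized PDK1.
#' @param mTORC1n optional externally supplied mTORC1 level; when `NULL`
#'   (default) the lumped saturating form in `a24` is used.  Supplying a
#'   value lets the TSC2/Rheb/PRAS40 submodel replace the lumped form.
#' @return list with elements `FoxO1n_cyt`, `GSK3Bn`, `mTORC1n`, `S6K1n`,
#'   `GLUT4n`, `pAS160n`.
#' @export
downstream_layer <- function(params, env, AktnT, AktnS, AktnTS, PDK1n,
                             mTORC1n = NULL) {
  p <- params
  xS <- AktnS + AktnTS
  xT <- AktnT + AktnTS
  FoxO1n_cyt <- p$a21 * xS / (1 + p$a21 * xS)
  xG <- if (p$gsk3b_substrate == "aktS") xS else xT
  GSK3Bn <- p$a23 * xG / (1 + p$a23p * env$W + p$a23 * xG)
  if (is.null(mTORC1n)) mTORC1n <- p$a24 * xT / (1 + p$a24 * xT)
  S6K1n <- p$a26 * mTORC1n * p$a27 * PDK1n /
    (1 + p$a26 * mTORC1n + (p$a26mu + p$a26 * mTORC1n) * p$a27 * PDK1n)
  GLUT4n <- (p$a28 + p$a29 * xT) / (1 + p$a30 * xT)
  pAS160n <- p$a_as160 * xT / (1 + p$a_as160 * xT)
  list(FoxO1n_cyt = FoxO1n_cyt, GSK3Bn = GSK3Bn, mTORC1n = mTORC1n,
       S6K1n = S6K1n, GLUT4n = GLUT4n, pAS160n = pAS160n)
}
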