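test_that("receptor layer reproduces basal fraction and half response", {
  p <- isn_params(rho = 0.03)
  r0 <- ir_layer(p, 0)
  expect_equal(r0$I, 0)
  expect_equal(r0$IRnY, 0.03, tolerance = 1e-12)
  rh <- ir_layer(p, p$Ie_half)
  expect_equal(rh$IRnY, 0.5, tolerance = 1e-10)
  expect_error(ir_layer(p, -1), "nonnegative")
})

test_that("free insulin equals total insulin when receptor binding is off", {
  set.seed(11)
  for (k in 1:100) {
    p <- random_isn_params()
    p$a1 <- 0  # remove the binding term directly (derived constants bypass)
    Ie <- stats::runif(1, 0, 200)
    expect_equal(ir_layer(p, Ie)$I, Ie, tolerance = 1e-9)
  }
})

test_that("free insulin is conserved and receptor response is monotone", {
  set.seed(12)
  for (k in 1:20) {
    p <- random_isn_params()
    Ie <- sort(stats::runif(8, 0, 500))
    r <- ir_layer(p, Ie)
    expect_true(all(r$I >= 0 & r$I <= Ie + 1e-10))
    expect_true(all(diff(r$IRnY) > 0))
  }
})

test_that("receptor reparameterization round-trips and matches a root-finding oracle", {
  set.seed(13)
  for (k in 1:50) {
    rho <- stats::runif(1, 0.01, 0.45)
    Ie_half <- stats::runif(1, 1, 200)
    s_lo <- (1 - 2 * rho) / (4 * Ie_half * (1 - rho))
    s_hi <- (1 - 2 * rho) / (2 * Ie_half)
    S_half <- stats::runif(1, s_lo * 1.02, s_hi * 0.98)
    a <- ir_reparameterization(Ie_half, S_half, rho)
    fwd <- ir_forward_map(a[["a0"]], a[["a1"]], rho)
    expect_equal(fwd[["Ie_half"]], Ie_half, tolerance = 1e-10)
    expect_equal(fwd[["S_half"]], S_half, tolerance = 1e-10)
    # independent oracle: solve IRnY(Ie) = 1/2 numerically
    p <- isn_params(rho = rho, Ie_half = Ie_half, S_half = S_half)
    root <- stats::uniroot(function(Ie) ir_layer(p, Ie)$IRnY - 0.5,
                           c(1e-9, 1e5), tol = 1e-12)$root
    expect_equal(root, Ie_half, tolerance = 1e-6)
    # and the slope at the half point by central difference
    h <- 1e-5 * Ie_half
    slope <- (ir_layer(p, Ie_half + h)$IRnY -
                ir_layer(p, Ie_half - h)$IRnY) / (2 * h)
    expect_equal(slope, S_half, tolerance = 1e-5)
  }
  expect_error(ir_reparameterization(50, 1e-6, 0.03), "must be positive")
})

test_that("upstream layer limits: no feedback, zero receptor signal", {
  p <- update_isn_params(ref_c2c12, aP = 0)
  u <- upstream_layer(p, env0, IRnY = 0.4, S6K1n = 0.2, AktnTS = 0.3)
  expect_equal(u$PTP1Bn, 1)
  u0 <- upstream_layer(p, env0, IRnY = 0, S6K1n = 0.5, AktnTS = 0)
  expect_equal(u0$IRS1nY, 0)
  expect_equal(u0$PI3Kn, 0)
  expect_equal(u0$PIP3n, 0)
  p4 <- update_isn_params(ref_c2c12, a4 = 0)
  u4 <- upstream_layer(p4, env0, IRnY = 0.4, S6K1n = 0.9, AktnTS = 0)
  expect_equal(u4$IRS1nS, 0)
  pP <- update_isn_params(ref_c2c12, aP = 2)
  uP <- upstream_layer(pP, env0, IRnY = 0.4, S6K1n = 0.2, AktnTS = 0.5)
  expect_equal(uP$PTP1Bn, 1 / 2)
})

test_that("PDK1/mTORC2 layer limits and the half-activation identity", {
  p <- ref_l6
  z <- pdk1_mtorc2_layer(p, env0, PIP3n = 0, S6K1n = 0.3)
  expect_equal(z$PDK1n, 0)
  eJ0 <- isn_environment(J = 0)
  z0 <- pdk1_mtorc2_layer(update_isn_params(p, a10mu = 0), eJ0, 0, 0.3)
  expect_equal(z0$mTORC2n, 0)
  # with no feedback and no basal term, drive = 1 gives exactly one half
  ph <- update_isn_params(ref_l6, a12 = 0, a10mu = 0)
  PIP3 <- 0.5 / ph$a10   # so that a10*PIP3 + a11*J = 1 with J below
  eh <- isn_environment(J = 0.5 / ph$a11)
  zh <- pdk1_mtorc2_layer(ph, eh, PIP3, S6K1n = 0.7)
  expect_equal(zh$mTORC2n, 0.5, tolerance = 1e-12)
  # monotone in J at fixed PIP3, S6K1
  Js <- seq(0, 2, by = 0.25)
  m <- vapply(Js, function(J)
    pdk1_mtorc2_layer(p, isn_environment(J = J), 0.3, 0.4)$mTORC2n,
    numeric(1))
  expect_true(all(diff(m) > 0))
})

test_that("Akt block zero-input structure and boundedness over random draws", {
  a <- akt_block(ref_l6, PDK1n = 0, mTORC2n = 0.6)
  expect_equal(a$AktnT, 0)
  expect_equal(a$AktnTS, 0)
  expect_gt(a$AktnS, 0)
  a2 <- akt_block(ref_l6, PDK1n = 0.6, mTORC2n = 0)
  expect_equal(a2$AktnS, 0)
  expect_equal(a2$AktnTS, 0)
  set.seed(21)
  for (k in 1:200) {
    p <- random_isn_params()
    P <- stats::runif(50); M <- stats::runif(50)
    a <- akt_block(p, P, M)
    v <- c(a$AktnT, a$AktnS, a$AktnTS)
    expect_true(all(v >= -1e-14 & v <= 1))
    expect_true(all(a$AktnT + a$AktnS + a$AktnTS <= 1 + 1e-12))
  }
  bad <- ref_l6; bad$a17d <- bad$a17g * bad$a_eta_d * 0.5
  expect_error(akt_block(bad, 0.5, 0.5), "a17d")
})

test_that("downstream layer limits", {
  d0 <- downstream_layer(ref_l6, env0, 0, 0, 0, PDK1n = 0.5)
  expect_equal(d0$FoxO1n_cyt, 0)
  expect_equal(d0$GSK3Bn, 0)
  expect_equal(d0$mTORC1n, 0)
  expect_equal(d0$S6K1n, 0)
  expect_equal(d0$GLUT4n, ref_l6$a28)
  expect_equal(d0$pAS160n, 0)
  dm <- downstream_layer(ref_l6, env0, 0.2, 0.2, 0.1, PDK1n = 0.9,
                         mTORC1n = 0)
  expect_equal(dm$S6K1n, 0)
  # GLUT4 stays below one at the maximal drive because a29 < a30, a28 < 1
  d1 <- downstream_layer(ref_l6, env0, 0.5, 0, 0.5, PDK1n = 1)
  expect_lt(d1$GLUT4n, 1)
  expect_equal(d1$GLUT4n, (ref_l6$a28 + ref_l6$a29) / (1 + ref_l6$a30))
})

test_that("with all feedback off the fixed point is a single forward pass", {
  set.seed(31)
  for (k in 1:10) {
    p <- random_isn_params()
    p0 <- update_isn_params(p, a4 = 0, aP = 0, a12 = 0)
    Ie <- stats::runif(1, 0, 100)
    st <- isn_steady_state(p0, env0, Ie = Ie, tol = 1e-14)
    ir <- ir_layer(p0, Ie)
    up <- upstream_layer(p0, env0, ir$IRnY, S6K1n = 0, AktnTS = 0)
    pm <- pdk1_mtorc2_layer(p0, env0, up$PIP3n, S6K1n = 0)
    expect_lt(abs(st$PDK1n - pm$PDK1n), 1e-12)
    expect_lt(abs(st$mTORC2n - pm$mTORC2n), 1e-12)
  }
})

test_that("the converged residual honours the solver contract", {
  set.seed(32)
  for (k in 1:10) {
    p <- random_isn_params()
    st <- isn_steady_state(p, env0, Ie = c(0, 1, 10, 100))
    expect_true(all(attr(st, "residual") < 1e-10))
    expect_state_bounded(st)
  }
})

test_that("steady states stay bounded at extreme insulin", {
  set.seed(33)
  for (k in 1:10) {
    p <- random_isn_params()
    st <- isn_steady_state(p, env0, Ie = c(0, 1e4))
    expect_state_bounded(st)
    expect_true(all(st$I <= c(0, 1e4) + 1e-8))
  }
})

test_that("dose-response output is tidy, monotone in the receptor, and empty-safe", {
  dr <- isn_dose_response(ref_c2c12, env0, insulin = c(0, 1, 10, 100))
  expect_s3_class(dr, "isn_dose_response")
  expect_setequal(names(dr), c("condition", "Ie_nM", "analyte", "value"))
  ir <- dr$value[dr$analyte == "IRnY"]
  expect_true(all(diff(ir) > 0))
  empty <- isn_dose_response(ref_c2c12, env0, insulin = numeric(0))
  expect_equal(nrow(empty), 0)
  expect_error(isn_dose_response(ref_c2c12, env0, insulin = c(5, 1)), "sorted")
})

test_that("insulin-resistant medium raises basal Ser473 phosphorylation", {
  ctrl <- isn_steady_state(ref_l6, env0, Ie = 0)
  ce <- apply_condition(ref_l6, env0, "dbdb")
  db <- isn_steady_state(ce$params, ce$env, Ie = 0)
  expect_gt(db$AktnS, ctrl$AktnS)
})
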