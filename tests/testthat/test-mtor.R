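test_that("TSC2 loss pins Rheb/GTP at its maximal value exactly", {
  out <- mtorc1_submodel_steady(ref_sub, akt_drive = c(0, 0.3, 0.9),
                                b_TSC = 0)
  expect_equal(out$RhebGTPn, rep(1, 3))
})

test_that("the submodel state is bounded and minimal at zero Akt drive", {
  drive <- seq(0, 1, by = 0.01)
  out <- mtorc1_submodel_steady(ref_sub, drive)
  v <- unlist(out)
  expect_true(all(v >= 0 & v <= 1))
  expect_equal(which.min(out$mTORC1n), 1)
  expect_true(all(diff(out$mTORC1n) > 0))   # monotone in the drive
  expect_true(all(diff(out$TSC2n) < 0))
  expect_true(all(diff(out$RhebGTPn) > 0))
  expect_error(mtorc1_submodel_steady(ref_sub, 1.5), "akt_drive")
})

test_that("mTORC1 increases with Rheb/GTP and decreases with PRAS40 load", {
  base <- mtorc1_submodel_steady(ref_sub, 0.3)
  more_rheb <- mtorc1_submodel_steady(ref_sub, 0.3, b_Rheb = 2)
  more_pras <- mtorc1_submodel_steady(ref_sub, 0.3, b_PRAS = 2)
  expect_gt(more_rheb$mTORC1n, base$mTORC1n)
  expect_lt(more_pras$mTORC1n, base$mTORC1n)
})

test_that("substituting the submodel reproduces the lumped mTORC1 law within calibration tolerance", {
  grid <- c(0, 0.1, 1, 10, 100)
  lumped <- isn_steady_state(ref_l6, env0, Ie = grid)
  sub <- isn_steady_state(ref_l6, env0, Ie = grid,
                          mtorc1_model = mtorc1_model_fn(ref_sub))
  rmse <- sqrt(mean((lumped$mTORC1n - sub$mTORC1n)^2))
  expect_lt(rmse, 0.1)
  expect_lt(max(abs(lumped$S6K1n - sub$S6K1n)), 0.05)
})

test_that("PRAS40 knockdown and overexpression move mTORC1 in opposite directions", {
  ctrl <- simulate_perturbation(ref_l6, env0, ref_sub, "control")
  kd <- simulate_perturbation(ref_l6, env0, ref_sub, "pras_kd")
  oe <- simulate_perturbation(ref_l6, env0, ref_sub, "pras_oe")
  expect_gt(kd$mTORC1n, ctrl$mTORC1n)
  expect_lt(oe$mTORC1n, ctrl$mTORC1n)
  expect_gt(kd$S6K1n, ctrl$S6K1n)
  expect_lt(oe$S6K1n, ctrl$S6K1n)
})

test_that("joint PRAS40/Rheb overexpression rescues S6K1 toward control", {
  ctrl <- simulate_perturbation(ref_l6, env0, ref_sub, "control")
  oe <- simulate_perturbation(ref_l6, env0, ref_sub, "pras_oe")
  both <- simulate_perturbation(ref_l6, env0, ref_sub, "pras_rheb_oe")
  expect_lt(abs(both$S6K1n - ctrl$S6K1n), abs(oe$S6K1n - ctrl$S6K1n))
})

test_that("TSC2-null raises mTORC1 and depresses PI3K/mTORC2 through the feedback", {
  ctrl <- simulate_perturbation(ref_l6, env0, ref_sub, "control")
  null <- simulate_perturbation(ref_l6, env0, ref_sub, "tsc2_null")
  expect_equal(attr(null, "submodel")$RhebGTPn, 1)
  expect_gt(null$mTORC1n, ctrl$mTORC1n)
  expect_lt(null$PI3Kn, ctrl$PI3Kn)
  expect_lt(null$mTORC2n, ctrl$mTORC2n)
})

test_that("short rapamycin spares mTORC2 while long rapamycin suppresses Ser473 Akt", {
  ctrl <- simulate_perturbation(ref_l6, env0, ref_sub, "control", Ie = 10)
  short <- simulate_perturbation(ref_l6, env0, ref_sub, "rapa_short")
  long <- simulate_perturbation(ref_l6, env0, ref_sub, "rapa_long")
  expect_lt(short$mTORC1n, ctrl$mTORC1n)
  expect_gt(short$mTORC2n, ctrl$mTORC2n)
  expect_lt(long$AktnS, ctrl$AktnS)
  expect_lt(long$AktnS, short$AktnS)
  expect_error(simulate_perturbation(ref_l6, env0, ref_sub, "bogus"),
               "unknown perturbation")
})

test_that("Akt localization adequacy checks report the equality and dominance conditions", {
  loc <- akt_localization_params(k_cn = 1, k_nc = 1, k_mc = 10, K15 = 10,
                                 PP2A = 1, k_minus13 = 0.001, K13 = 1,
                                 K14 = 0.1)
  rep1 <- akt_localization_equalization(loc, PIP3 = 0.3, PDK1 = 0.3)
  expect_true(all(rep1$satisfied))
  loc2 <- akt_localization_params(k_minus13 = 10 * 0.3, K13 = 1)
  rep2 <- akt_localization_equalization(loc2, PIP3 = 0.3, PDK1 = 0.3)
  expect_false(rep2$satisfied[rep2$condition == "back_transport_negligible"])
  # deterministic: identical output on repeated calls
  expect_identical(rep1, akt_localization_equalization(loc, 0.3, 0.3))
})

test_that("submodel calibration recovers the catalytic constant scale", {
  sub0 <- mtorc1_params(K_mTOR = 1)
  cal <- calibrate_mtorc1_submodel(sub0, ref_l6, env0)
  expect_equal(cal$K_mTOR, ref_sub$K_mTOR, tolerance = 1e-3)
  expect_lt(attr(cal, "rmse"), 0.1)
})
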