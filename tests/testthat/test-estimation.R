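test_that("zero-noise table with truth initialization gives essentially zero loss", {
  tab <- synth_dose_response(ref_c2c12, sd = 0, seed = 1)
  fit <- isn_fit(tab, ref_c2c12, free = c("a3", "a6", "a9", "a24"),
                 conditions = list(control = "control",
                                   pten_silenced = "pten_silenced"),
                 n_starts = 1, max_eval = 300)
  expect_lt(fit$loss, 1e-12)
  pred <- predict(fit)
  truth <- attr(tab, "truth")
  m <- merge(truth, pred, by = c("condition", "analyte", "insulin_nM"))
  expect_lt(max(abs(m$value.x - m$value.y)), 1e-6)
})

test_that("the accepted loss sequence is non-increasing and constraints hold at the optimum", {
  tab <- synth_dose_response(ref_c2c12, sd = 0.05, seed = 3)
  fit <- isn_fit(tab, ref_c2c12, free = c("a3", "a9", "a24"),
                 conditions = list(control = "control",
                                   pten_silenced = "pten_silenced"),
                 n_starts = 2, seed = 4, max_eval = 400)
  expect_true(all(diff(fit$trace) <= 0))
  expect_true(all(coef(fit) >= 0))
  expect_s3_class(validate_isn_params(fit$params), "isn_params")
})

test_that("rows flagged as excluded do not influence the fit", {
  tab <- synth_dose_response(ref_c2c12, sd = 0, seed = 1)
  spoiled <- tab
  bad <- which(spoiled$analyte == "pS6K1" & spoiled$insulin_nM == 0)
  spoiled$value[bad] <- 25
  spoiled$used_in_fit[bad] <- FALSE
  fit <- isn_fit(spoiled, ref_c2c12, free = c("a3", "a24"),
                 conditions = list(control = "control",
                                   pten_silenced = "pten_silenced"),
                 n_starts = 1, max_eval = 200)
  expect_lt(fit$loss, 1e-12)  # the corrupted, excluded rows cost nothing
  expect_gt(max(abs(fit$data$residual[bad])), 1)  # but are still predicted
})

test_that("inverse-variance weighting changes the objective as documented", {
  tab <- synth_dose_response(ref_c2c12, sd = 0.05, seed = 5)
  tab$error <- ifelse(tab$analyte == "pIR", 0.01, 0.5)
  f1 <- isn_fit(tab, ref_c2c12, free = "a3", n_starts = 1, max_eval = 60,
                conditions = list(control = "control",
                                  pten_silenced = "pten_silenced"))
  f2 <- isn_fit(tab, ref_c2c12, free = "a3", n_starts = 1, max_eval = 60,
                conditions = list(control = "control",
                                  pten_silenced = "pten_silenced"),
                weighting = "inverse_error2")
  w <- 1 / tab$error^2
  expect_equal(f2$loss, sum(w * (f2$data$fitted - tab$value)^2),
               tolerance = 1e-8)
  expect_false(isTRUE(all.equal(f1$loss, f2$loss)))
})

test_that("a shared parameter vector fits control and PTEN-silenced jointly", {
  tab <- synth_dose_response(ref_c2c12, sd = 0.02, seed = 6,
                             analytes = c("pIR", "pAktS473", "pS6K1"))
  fit <- isn_fit(tab, ref_c2c12, free = c("a9", "a24"),
                 conditions = list(control = "control",
                                   pten_silenced = "pten_silenced"),
                 n_starts = 1, max_eval = 200)
  # one parameter set; the conditions differ only through the preset
  expect_length(coef(fit), 2)
  both <- predict(fit, insulin = c(0, 100))
  expect_setequal(unique(both$condition), c("control", "pten_silenced"))
})

test_that("per-condition environment entries can be freed (J in the resistant medium)", {
  conds <- list(control = "control", dbdb = "dbdb")
  tab <- synth_dose_response(ref_l6, conditions = conds, sd = 0,
                             seed = 7, analytes = c("pAktS473", "pAktT308"))
  fit <- isn_fit(tab, ref_l6, free = c("J@dbdb"), conditions = conds,
                 n_starts = 1, max_eval = 150)
  expect_named(coef(fit), "J@dbdb")
  expect_equal(unname(coef(fit)["J@dbdb"]), 0.07, tolerance = 0.02)
})

test_that("renormalization is anchored at control, linear and idempotent", {
  dr_ctrl <- isn_dose_response(ref_c2c12, env0, insulin = c(0, 1, 10, 100))
  ce <- apply_condition(ref_c2c12, env0, "pten_silenced")
  dr_sil <- isn_dose_response(ce$params, ce$env, insulin = c(0, 1, 10, 100),
                              condition = "pten_silenced")
  r_ctrl <- renormalize_dose_response(dr_ctrl, dr_ctrl)
  expect_equal(r_ctrl$value[r_ctrl$analyte == "AktnS" & r_ctrl$Ie_nM == 100], 1)
  # renormalizing an already renormalized set against its own (unit) control
  # leaves it unchanged
  r2 <- renormalize_dose_response(r_ctrl, r_ctrl)
  expect_equal(r2$value, r_ctrl$value, tolerance = 1e-12)
  # silenced PTEN responses sit above control pointwise after renormalization
  for (a in c("AktnS", "AktnTS", "PIP3n")) {
    s <- renormalize_dose_response(dr_sil, dr_ctrl)
    expect_true(all(s$value[s$analyte == a] >=
                      r_ctrl$value[r_ctrl$analyte == a] - 1e-10))
  }
  expect_error(renormalize_dose_response(dr_sil, transform(dr_ctrl, value = 0)),
               "zero reference")
})
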