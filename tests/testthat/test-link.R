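test_that("link fits recover exact generating constants", {
  x <- c(0.02, 0.05, 0.1, 0.3, 0.8, 2)
  lf <- fit_link(x, 2 * x / (0.5 + x), "michaelis")
  expect_equal(lf$A, 2, tolerance = 1e-8)
  expect_equal(lf$B, 0.5, tolerance = 1e-8)
  expect_lt(lf$residual, 1e-10)
  lf2 <- fit_link(x, 3 / (0.4 + x), "inhibition")
  expect_equal(unname(coef(lf2)[c("A", "B")]), c(3, 0.4), tolerance = 1e-7)
  lf3 <- fit_link(x, 1.5 / (0.2 + x^1.8), "inhibition_power")
  expect_equal(lf3$n, 1.8, tolerance = 1e-5)
  # the saturating form passes through the origin
  expect_equal(predict(lf, 0), 0)
  expect_error(fit_link(c(1, 1, 1), c(1, 2, 3), "michaelis"), "degenerate")
  expect_error(fit_link(1:2, 1:2, "michaelis"), "3 points")
})

test_that("link fits are scale-equivariant in y", {
  x <- c(0.05, 0.1, 0.4, 1, 3)
  y <- 1.2 * x / (0.3 + x) + c(0.01, -0.02, 0.015, 0, -0.01)
  f1 <- fit_link(x, y, "michaelis")
  f2 <- fit_link(x, 5 * y, "michaelis")
  expect_equal(f2$A, 5 * f1$A, tolerance = 1e-6)
  expect_equal(f2$B, f1$B, tolerance = 1e-6)
})

test_that("near-flat responses still produce a usable link fit", {
  x <- c(0.05, 0.1, 0.4, 1)
  y <- c(0.99, 0.995, 1.0, 1.0)
  lf <- fit_link(x, y, "michaelis")
  expect_lt(lf$residual, 0.02)
})

test_that("inhibition multipliers are recovered exactly from a noiseless profile", {
  doses <- c(0, 10, 100, 1000)
  true_m <- c(1, 0.5, 0.2, 0.05)
  ctrl <- isn_steady_state(ref_l6, env0, Ie = 10)
  prof <- vapply(true_m, function(m) {
    pm <- update_isn_params(ref_l6, a10 = ref_l6$a10 * m,
                            a11 = ref_l6$a11 * m, a24 = ref_l6$a24 * m)
    isn_steady_state(pm, env0, Ie = 10)$S6K1n / ctrl$S6K1n
  }, numeric(1))
  eq <- equivalent_insulin_refit(ref_l6, env0, doses, prof, Ie_equiv = 10)
  expect_equal(unname(eq$multipliers), true_m, tolerance = 1e-6)
  expect_equal(unname(eq$fitted$s6k1_ratio[1]), 1)
  expect_error(equivalent_insulin_refit(ref_l6, env0, c(5, 10), c(1, 0.5)),
               "control")
  expect_warning(equivalent_insulin_refit(ref_l6, env0, doses,
                                          c(1, 0.4, 0.9, 0.2)),
                 "monotone")
})

test_that("the fitted dose profile follows a saturating-decay law", {
  doses <- c(0, 10, 100, 1000)
  true_m <- c(1, 0.45, 0.18, 0.06)
  ctrl <- isn_steady_state(ref_l6, env0, Ie = 10)
  prof <- vapply(true_m, function(m) {
    pm <- update_isn_params(ref_l6, a10 = ref_l6$a10 * m,
                            a11 = ref_l6$a11 * m, a24 = ref_l6$a24 * m)
    isn_steady_state(pm, env0, Ie = 10)$S6K1n / ctrl$S6K1n
  }, numeric(1))
  lf <- fit_link(pmax(doses, 1e-6), prof, "inhibition_power")
  expect_lt(lf$residual, 0.05)
})

test_that("end-to-end drug escalation gives concordant signalling and kinetics", {
  est <- coef(cellpop_fit(synth_population(ref_pop, sd = 0, seed = 3)$data,
                          alpha_control = ref_pop[["0"]]$alpha,
                          n_starts = 1))
  mults <- stats::setNames(c(1, 0.5, 0.2, 0.05), est$dose)
  la <- link_analysis(ref_l6, env0, Ie_equiv = 10, multipliers = mults,
                      pop_estimates = est)
  tab <- la$table
  expect_true(all(diff(tab$pAktS473) < 0))
  expect_true(all(diff(tab$pS6K1) < 0))
  expect_true(all(diff(tab$lambda1) < 0))
  expect_true(all(diff(tab$mu_p) > 0))
  # Michaelis-type association between Ser473 Akt and the G1 exit rate:
  # small residual, amplitude near one after control normalization
  lf <- la$links$akt_lambda1
  expect_lt(lf$residual, 0.1)
  expect_lt(abs(lf$A / (1 + lf$B / tab$lambda1[1]) - 1), 0.3)
})
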