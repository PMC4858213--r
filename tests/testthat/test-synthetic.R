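test_that("zero-noise tables equal the model curves exactly", {
  tab <- synth_dose_response(ref_c2c12, sd = 0, seed = 9)
  truth <- attr(tab, "truth")
  expect_equal(tab$value, truth$value)
  # control at maximal insulin is the renormalization anchor
  for (a in unique(tab$analyte))
    expect_equal(tab$value[tab$condition == "control" & tab$analyte == a &
                             tab$insulin_nM == 100], 1, tolerance = 1e-12)
})

test_that("the same seed reproduces the table exactly and seeds differ", {
  t1 <- synth_dose_response(ref_c2c12, sd = 0.05, seed = 5)
  t2 <- synth_dose_response(ref_c2c12, sd = 0.05, seed = 5)
  t3 <- synth_dose_response(ref_c2c12, sd = 0.05, seed = 6)
  expect_identical(t1$value, t2$value)
  expect_false(identical(t1$value, t3$value))
})

test_that("replicate means concentrate on the model curve (CLT check)", {
  n <- 10000
  tab <- synth_dose_response(ref_c2c12, sd = 0.05, seed = 7,
                             insulin = c(10, 100),
                             analytes = "pAktS473", replicates = n)
  truth <- attr(tab, "truth")
  for (i in seq_len(nrow(truth))) {
    sel <- tab$condition == truth$condition[i] &
      tab$insulin_nM == truth$insulin_nM[i]
    # truncation at zero is negligible at these signal levels
    expect_gt(truth$value[i], 4 * 0.05)
    expect_lt(abs(mean(tab$value[sel]) - truth$value[i]),
              3 * 0.05 / sqrt(n))
  }
})

test_that("population observations stay on the simplex and are seed-stable", {
  s1 <- synth_population(ref_pop, sd = 0.02, seed = 11)
  s2 <- synth_population(ref_pop, sd = 0.02, seed = 11)
  expect_identical(s1$data, s2$data)
  sums <- rowSums(s1$data[, c("fG1", "fS", "fG2M", "fA")])
  expect_equal(sums, rep(1, nrow(s1$data)), tolerance = 1e-12)
  s0 <- synth_population(ref_pop, sd = 0, seed = 11)
  expect_equal(s0$data[, 1:7], s0$truth[, 1:7])
})

test_that("random parameter generators always satisfy the structural constraints", {
  set.seed(12)
  for (k in 1:50) expect_s3_class(validate_isn_params(random_isn_params()),
                                  "isn_params")
  for (k in 1:25) {
    p <- random_pop_params()
    expect_lt(abs(isnet:::balanced_growth_residual(p)), 1e-8)
  }
})

test_that("generate -> fit -> predict recovers truth curves within the noise envelope", {
  sd <- 0.03
  tab <- synth_dose_response(ref_c2c12, sd = sd, seed = 13,
                             analytes = c("pIR", "pAktS473", "pS6K1"))
  fit <- isn_fit(tab, ref_c2c12, free = c("a9", "a24"),
                 conditions = list(control = "control",
                                   pten_silenced = "pten_silenced"),
                 n_starts = 2, seed = 13, max_eval = 400)
  truth <- attr(tab, "truth")
  pred <- predict(fit)
  m <- merge(truth, pred, by = c("condition", "analyte", "insulin_nM"))
  rmse <- sqrt(mean((m$value.x - m$value.y)^2))
  expect_lt(rmse, 2 * sd)
})
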