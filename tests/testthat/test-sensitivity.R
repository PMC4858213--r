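test_that("parameters off every path to a read-out have exactly zero sensitivity", {
  S <- isn_sensitivity(ref_l6, env0, Ie = 10,
                       parameters = c("a21", "a23", "a28"))
  # FoxO1, GSK3beta and GLUT4 are terminal branches: their constants cannot
  # reach any other node
  reach <- c("FoxO1n_cyt", "GSK3Bn", "GLUT4n")
  for (p in colnames(S)) {
    off <- setdiff(rownames(S), reach)
    expect_true(all(S[off, p] == 0 | is.na(S[off, p])))
  }
  expect_gt(S["FoxO1n_cyt", "a21"], 0)
  expect_gt(S["GSK3Bn", "a23"], 0)
})

test_that("PTEN constant inhibits downstream nodes but promotes IRS1/PI3K via feedback", {
  S <- isn_sensitivity(ref_l6, env0, Ie = ref_l6$Ie_half,
                       parameters = "a8")
  for (dn in c("PIP3n", "PDK1n", "AktnT", "AktnS", "AktnTS", "S6K1n"))
    expect_lt(S[dn, "a8"], 0)
  expect_gt(S["IRS1nY", "a8"], 0)
  expect_gt(S["PI3Kn", "a8"], 0)
})

test_that("sensitivities are deterministic and converge at O(delta^2)", {
  S1 <- isn_sensitivity(ref_l6, env0, Ie = 10, parameters = c("a9", "a24"))
  S2 <- isn_sensitivity(ref_l6, env0, Ie = 10, parameters = c("a9", "a24"))
  expect_identical(unclass(S1), unclass(S2))
  Sh <- isn_sensitivity(ref_l6, env0, Ie = 10, delta = 0.05,
                        parameters = c("a9", "a24"))
  Sq <- isn_sensitivity(ref_l6, env0, Ie = 10, delta = 0.025,
                        parameters = c("a9", "a24"))
  # halving delta should change entries by roughly a quarter of the
  # delta = 0.05 -> 0.1 change
  d1 <- max(abs(S1 - Sh), na.rm = TRUE)
  d2 <- max(abs(Sh - Sq), na.rm = TRUE)
  expect_lt(d2, d1)
})

test_that("zero concentrations are flagged undefined rather than propagated", {
  pJ <- update_isn_params(ref_l6, a11 = 0, a6 = 0)
  # with PI3K activation and the insulin-independent input both absent the
  # cascade downstream of IRS1 is dark
  S <- isn_sensitivity(pJ, isn_environment(J = 0), Ie = 0,
                       parameters = "a9")
  expect_true(any(attr(S, "undefined")))
  expect_true(all(is.na(S[attr(S, "undefined")])))
})

test_that("the resistance factor J matters more in the conditioned medium", {
  S_ctrl <- isn_sensitivity(ref_l6, isn_environment(J = 0.001),
                            Ie = ref_l6$Ie_half, parameters = "J")
  S_db <- isn_sensitivity(ref_l6, isn_environment(J = 0.07),
                          Ie = ref_l6$Ie_half, parameters = "J")
  expect_gt(S_db["AktnS", "J"], S_ctrl["AktnS", "J"])
})

test_that("sensitivity CSV export round-trips", {
  S <- isn_sensitivity(ref_l6, env0, Ie = 10, parameters = c("a9", "a24"))
  path <- tempfile(fileext = ".csv")
  write_sensitivity_csv(S, path)
  back <- utils::read.csv(path, row.names = 1)
  expect_equal(as.matrix(back), unclass(S)[, , drop = FALSE],
               ignore_attr = TRUE, tolerance = 1e-12)
})
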