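# Shared fixtures: packaged synthetic reference sets and small helpers.

ref_c2c12 <- isn_reference_params("c2c12")
ref_l6 <- isn_reference_params("l6")
ref_sub <- mtorc1_reference_params()
ref_pop <- pop_reference_params()
env0 <- isn_environment()

state_fields <- c("IRnY", "IRS1nY", "IRS1nS", "PTP1Bn", "PI3Kn", "PIP3n",
                  "PDK1n", "mTORC2n", "AktnT", "AktnS", "AktnTS",
                  "FoxO1n_cyt", "GSK3Bn", "mTORC1n", "S6K1n", "GLUT4n",
                  "pAS160n")

state_vector <- function(st) {
  unlist(lapply(state_fields, function(f) st[[f]]))
}

expect_state_bounded <- function(st) {
  v <- state_vector(st)
  expect_true(all(v >= -1e-12 & v <= 1 + 1e-12))
  expect_true(all(st$AktnT + st$AktnS + st$AktnTS <= 1 + 1e-10))
}
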