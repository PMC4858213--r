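test_that("balanced-growth root matches limits and a bisection oracle", {
  # degenerate transit times: the relation collapses to alpha = lambda1 - mu'
  expect_equal(solve_balanced_growth(1, 0, 0, 0), 1)
  expect_equal(solve_balanced_growth(0.7, 0, 0, 0.2), 0.5)
  # bisection oracle, written independently of uniroot
  bisect <- function(f, lo, hi, tol = 1e-13) {
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) hi <- mid else lo <- mid
      if (hi - lo < tol) break
    }
    (lo + hi) / 2
  }
  a <- solve_balanced_growth(1, 0.25, 0.25, 0)
  a_oracle <- bisect(function(x) x + 1 - 2 * exp(-0.5 * x), 0, 1)
  expect_equal(a, a_oracle, tolerance = 1e-12)
  set.seed(41)
  for (k in 1:20) {
    l1 <- stats::runif(1, 0.05, 3); T23 <- stats::runif(2, 0.05, 1)
    mu <- stats::runif(1, 0, 1)
    a <- solve_balanced_growth(l1, T23[1], T23[2], mu)
    resid <- a + mu + l1 - 2 * l1 * exp(-(a + mu) * sum(T23))
    expect_lt(abs(resid), 1e-10)
    expect_gt(a + mu, 0)
  }
  expect_error(solve_balanced_growth(0, 1, 1, 0), "positive")
})

test_that("phase fractions sum to one and vanish appropriately without cell loss", {
  p <- pop_params(0.5, 0.4, 0.3, mu_p = 0, mu_pp = 0.5)
  f <- phase_fractions(p)
  expect_equal(f$fDead, 0)
  expect_equal(f$fA, 0)
  expect_equal(f$fG1 + f$fS + f$fG2M + f$fA, 1, tolerance = 1e-12)
  set.seed(42)
  for (k in 1:25) {
    f <- phase_fractions(random_pop_params())
    expect_equal(f$fG1 + f$fS + f$fG2M + f$fA, 1, tolerance = 1e-12)
    expect_true(all(unlist(f) >= 0 & unlist(f) <= 1))
  }
})

test_that("the dead fraction grows with the loss rate", {
  base <- random_pop_params(seed = 43)
  f0 <- phase_fractions(base)$fDead
  up <- pop_params(base$lambda1, base$T2, base$T3, base$mu_p + 0.05,
                   base$mu_pp, base$mu_deg)
  expect_gt(phase_fractions(up)$fDead, f0)
})

test_that("labeling index limits: no G1 exit, no labeling period", {
  p <- pop_params(0.5, 0.4, 0.3, 0.1, 0.5)
  # at Delta = 0 only the cells residing in S are labeled
  beta <- p$alpha + p$mu_p; q <- p$lambda1 / beta
  N2 <- q * (1 - exp(-beta * p$T2))
  N3 <- q * exp(-beta * p$T2) * (1 - exp(-beta * p$T3))
  D <- p$mu_p * c(1, N2, N3) / (p$alpha + p$mu_pp)
  A <- p$mu_pp * sum(D) / (p$alpha + p$mu_deg)
  expect_equal(labeling_index(p, Delta = 0),
               N2 / (1 + N2 + N3 + sum(D) + A), tolerance = 1e-12)
  # lambda1 -> 0 kills the index
  expect_equal(labeling_index(pop_params(1e-12, 0.4, 0.3, 0.1, 0.5,
                                         alpha = NULL)), 0,
               tolerance = 1e-9)
})

test_that("exponential growth without loss matches the trajectory slope", {
  p <- pop_params(0.8, 0.4, 0.3, mu_p = 0, mu_pp = 0.5)
  tr <- simulate_population(p, t_end = 30)
  expect_equal(attr(tr, "growth_rate"), p$alpha, tolerance = 1e-3)
  # no deaths: dead compartments stay empty
  expect_true(all(tr$D1 == 0 & tr$D2 == 0 & tr$D3 == 0 & tr$A == 0))
})

test_that("an empty initial population stays identically zero", {
  p <- pop_params(0.8, 0.4, 0.3, 0.1, 0.5)
  tr <- simulate_population(p, t_end = 2, init = list(N1 = 0))
  expect_true(all(tr$Ntot == 0))
})

test_that("closed-form composition and labeling index agree with the age-structured simulator", {
  set.seed(44)
  worst_f <- 0; worst_li <- 0
  for (k in 1:12) {
    p <- random_pop_params()
    f <- phase_fractions(p)
    tr <- simulate_population(p, t_end = 150)
    last <- tr[nrow(tr), ]
    worst_f <- max(worst_f,
                   abs(c(last$fG1 - f$fG1, last$fS - f$fS,
                         last$fG2M - f$fG2M, last$fA - f$fA,
                         last$fDead - f$fDead)))
    worst_li <- max(worst_li,
                    abs(labeling_index(p) - isnet:::simulate_labeling_index(p)))
  }
  expect_lt(worst_f, 1e-3)
  expect_lt(worst_li, 1e-3)
})

test_that("population fit recovers exact parameters to well under one percent", {
  truth <- ref_pop[c("0", "100")]
  synth <- synth_population(truth, sd = 0, seed = 1)
  fit <- cellpop_fit(synth$data, alpha_control = truth[["0"]]$alpha,
                     n_starts = 2)
  est <- coef(fit)
  for (i in seq_len(nrow(est))) {
    tp <- truth[[as.character(est$dose[i])]]
    for (f in c("lambda1", "T2", "T3", "mu_p", "mu_pp"))
      expect_equal(est[[f]][i], tp[[f]], tolerance = 1e-4)
  }
  # the control labeling index is predicted even though never measured
  ctrl_data <- synth$data[, setdiff(names(synth$data), c("LI", "LI_ratio"))]
  fit2 <- cellpop_fit(ctrl_data[ctrl_data$dose == 0, , drop = FALSE],
                      alpha_control = truth[["0"]]$alpha, n_starts = 2)
  expect_true(is.finite(coef(fit2)$LI[1]))
  # monotone loss trace per dose
  for (f in fit$fits) expect_true(all(diff(f$trace) <= 0))
})

test_that("a dose escalation with decreasing G1 exit is recovered monotone", {
  truth <- ref_pop
  synth <- synth_population(truth, sd = 0, seed = 2)
  fit <- cellpop_fit(synth$data, alpha_control = truth[["0"]]$alpha,
                     n_starts = 2)
  est <- coef(fit)
  expect_true(all(diff(est$lambda1) < 0))
  expect_true(all(diff(est$mu_p) > 0))
})
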