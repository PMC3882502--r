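test_that("single-stage boundaries degenerate to the fixed-sample design", {
  b <- triangular_boundaries(confirmatory_spec(J = 1))
  expect_equal(b$efficacy, qnorm(0.975), tolerance = 1e-10)
  expect_equal(b$futility, b$efficacy)
  expect_equal(b$n_per_stage, single_stage_n2(0.25, 0.025, 0.1), tolerance = 1e-8)
})

test_that("two-stage triangular calibration attains its defining error rates", {
  conf <- confirmatory_spec(J = 2)
  b <- triangular_boundaries(conf)
  # boundary shape: l2 = u2 = 2C, l1 < u1
  expect_equal(b$efficacy[2], 2 * b$C, tolerance = 1e-10)
  expect_equal(b$futility[2], b$efficacy[2], tolerance = 1e-10)
  expect_lt(b$futility[1], b$efficacy[1])
  # calibration targets: efficacy-crossing probability (futility
  # non-binding) equals alpha at mu = 0 and 1 - beta at mu = delta
  cross0 <- mamscreen:::.gs_crossing(b$efficacy, b$futility, 0, binding = FALSE)
  expect_equal(sum(cross0$efficacy), 0.025, tolerance = 1e-8)
  crossd <- mamscreen:::.gs_crossing(b$efficacy, b$futility,
                                     0.25 * sqrt(b$n_per_stage / 2),
                                     binding = FALSE)
  expect_equal(sum(crossd$efficacy), 0.9, tolerance = 1e-7)
  # operational (futility-binding) rates are slightly conservative
  expect_lt(b$alpha_attained, 0.025)
  expect_lt(b$power_attained, 0.9)
  expect_gt(b$power_attained, 0.85)
})

test_that("stage probabilities agree with the bivariate-normal oracle", {
  skip_if_not_installed("mvtnorm")
  b <- triangular_boundaries(confirmatory_spec(J = 2))
  rho <- sqrt(0.5)
  S <- matrix(c(1, rho, rho, 1), 2)
  for (mu in c(0, 0.1, 0.25)) {
    th <- mu * sqrt(b$n_per_stage / 2)
    sp <- stopping_probabilities(b, mu)
    e2 <- mvtnorm::pmvnorm(lower = c(b$futility[1], b$efficacy[2]),
                           upper = c(b$efficacy[1], 40),
                           mean = c(th, th * sqrt(2)), sigma = S,
                           algorithm = mvtnorm::Miwa(steps = 512))
    expect_equal(sp$efficacy[1], 1 - pnorm(b$efficacy[1] - th), tolerance = 1e-9)
    expect_equal(sp$efficacy[2], as.numeric(e2), tolerance = 1e-6)
  }
})

test_that("stopping probabilities are a distribution and match trial simulation", {
  for (J in c(2, 3)) {
    b <- triangular_boundaries(confirmatory_spec(J = J))
    for (mu in c(-0.1, 0, 0.12, 0.3)) {
      sp <- stopping_probabilities(b, mu)
      expect_equal(sum(sp$efficacy) + sum(sp$futility), 1, tolerance = 1e-8)
    }
  }
  b <- triangular_boundaries(confirmatory_spec(J = 2))
  mc <- mc_gs_trial(b, 0.1, n_reps = 4e5, seed = 31)
  sp <- stopping_probabilities(b, 0.1)
  for (j in 1:2) {
    expect_lt(abs(sp$efficacy[j] - mc$efficacy[j]), 3 * mc$se)
    expect_lt(abs(sp$futility[j] - mc$futility[j]), 3 * mc$se)
  }
})

test_that("expected confirmatory sample size behaves at its limits", {
  b <- triangular_boundaries(confirmatory_spec(J = 2))
  # strong effects stop at the first analysis
  expect_equal(expected_confirmatory_ss(b, 5), b$stage_ss[1], tolerance = 1e-6)
  # decomposition by outcome is exhaustive
  for (mu in c(0, 0.15))
    expect_equal(expected_confirmatory_ss(b, mu),
                 expected_confirmatory_ss(b, mu, "success") +
                   expected_confirmatory_ss(b, mu, "failure"),
                 tolerance = 1e-10)
  # early stopping saves patients relative to the single-stage trial at delta
  expect_lt(expected_confirmatory_ss(b, 0.25),
            2 * single_stage_n2(0.25, 0.025, 0.1))
  b1 <- triangular_boundaries(confirmatory_spec(J = 1))
  expect_equal(expected_confirmatory_ss(b1, 0.1), b1$stage_ss[1], tolerance = 1e-10)
})

test_that("group-sequential program ESS reduces to the single-stage ESS at J = 1", {
  prior <- tI_prior()
  for (des in list(c(9, 22, -0.429), c(1, 16, 0.814), c(4, 12, 0.1))) {
    d <- screening_design(des[1], des[2], des[3])
    expect_equal(ess_top_groupseq(d, prior, confirmatory_spec(J = 1))$ess,
                 ess_top_single(d, prior, confirmatory_spec(J = 1))$ess,
                 tolerance = 1e-8)
  }
})

test_that("group-sequential program ESS matches full-program simulation", {
  prior <- tI_prior()
  conf <- confirmatory_spec(J = 2)
  d <- screening_design(8, 14, -0.334)
  res <- ess_top_groupseq(d, prior, conf)
  sim <- simulate_ss_quantile(d, prior, conf, n_reps = 2e4, seed = 41)
  expect_lt(abs(sim$mean_ss - res$ess) / res$ess, 0.03)
  # sequential stopping beats the single-stage program at the same design
  res1 <- ess_top_single(d, prior, confirmatory_spec(J = 1))
  expect_lt(res$ess, res1$ess)
})
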