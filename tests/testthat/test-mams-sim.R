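test_that("the dataset bank is reproducible and honours a degenerate prior", {
  p <- tI_prior()
  b1 <- build_bank(3, p, n_reps = 5000, seed = 42)
  b2 <- build_bank(3, p, n_reps = 5000, seed = 42)
  expect_identical(b1$effects, b2$effects)
  expect_identical(b1$screening_noise, b2$screening_noise)
  expect_identical(b1$confirmatory_noise, b2$confirmatory_noise)
  b3 <- build_bank(3, p, n_reps = 5000, seed = 43)
  expect_false(identical(b1$effects, b3$effects))
  # column means within the law-of-large-numbers band
  expect_true(all(abs(colMeans(b1$effects) - 0) < 4 * 0.1 / sqrt(5000)))
  b0 <- build_bank(2, prior_spec(0.07, 0), n_reps = 100, seed = 1)
  expect_true(all(b0$effects == 0.07))
})

test_that("common random numbers give identical evaluations and smooth comparisons", {
  p <- tI_prior(); conf <- confirmatory_spec(rule = "all-interesting")
  bank <- build_bank(2, p, n_reps = 20000, seed = 7)
  d <- screening_design(2, 20, 0.96)
  e1 <- ess_mams(d, p, conf, bank)
  e2 <- ess_mams(d, p, conf, bank)
  expect_identical(e1$ess, e2$ess)
  # p_conduct decreases as the threshold is raised, on the same draws
  pcs <- vapply(c(-0.5, 0, 0.5, 1, 1.5), function(cc)
    estimate_phase3_quantities(screening_design(2, 20, cc), conf, bank)$p_conduct,
    numeric(1))
  expect_true(all(diff(pcs) < 0))
  # an impossible threshold conducts no trial
  est <- suppressWarnings(
    estimate_phase3_quantities(screening_design(2, 20, Inf), conf, bank))
  expect_equal(est$p_conduct, 0)
})

test_that("single-stage simulation estimates match the analytic module within 3 SE", {
  p <- tI_prior(); conf <- confirmatory_spec(rule = "all-interesting")
  bank <- build_bank(2, p, n_reps = 4e5, seed = 99)
  d <- screening_design(2, 20, 0.96)
  est <- estimate_phase3_quantities(d, conf, bank)
  ana <- ess_all_interesting(d, p, conf)
  expect_lt(abs(est$p_conduct - ana$p_conduct), 3 * est$se$p_conduct)
  p_s_ana <- ana$p_success / ana$p_conduct
  expect_lt(abs(est$p_success_given_conduct - p_s_ana),
            3 * est$se$p_success_given_conduct)
  sim <- ess_mams(d, p, conf, bank)
  expect_lt(abs(sim$ess - ana$ess), 3 * sim$diagnostics$se_ess)
})

test_that("simulated two-stage top-treatment programs match the analytic ESS", {
  p <- tI_prior(); conf <- confirmatory_spec(J = 2)
  bank <- build_bank(1, p, n_reps = 4e5, seed = 57)
  d <- screening_design(1, 8, 0.766)
  sim <- ess_mams(d, p, conf, bank)
  ana <- ess_top_groupseq(d, p, conf)
  expect_lt(abs(sim$ess - ana$ess), 3 * sim$diagnostics$se_ess)
})

test_that("multi-arm two-stage boundaries generalize the two-arm calibration", {
  conf <- confirmatory_spec(J = 2, rule = "all-interesting")
  b1 <- mams_boundaries(1, conf)
  b2 <- mams_boundaries(2, conf)
  b3 <- mams_boundaries(3, conf)
  # one arm reduces to the plain triangular design
  expect_equal(b1$C, triangular_boundaries(conf)$C, tolerance = 1e-8)
  # more arms need wider boundaries (Dunnett-type penalty) and more patients
  expect_true(b1$C < b2$C && b2$C < b3$C)
  expect_true(b1$n_per_stage < b2$n_per_stage)
  # FWER defining equation holds at the solution
  expect_lt(abs(mamscreen:::.mams_fwer2(b2$C, 2) - 0.025), 1e-7)
  # simulation check of the non-binding FWER for two arms under the null
  set.seed(77)
  M <- 4e5
  w <- matrix(rnorm(M * 2), M, 2)   # control increments
  cross <- rep(FALSE, M)
  for (arm in 1:2) {
    a <- matrix(rnorm(M * 2), M, 2)
    z1 <- (a[, 1] - w[, 1]) / sqrt(2)
    z2 <- (a[, 1] + a[, 2] - w[, 1] - w[, 2]) / 2
    cross <- cross | z1 >= b2$efficacy[1] | z2 >= b2$efficacy[2]
  }
  expect_lt(abs(mean(cross) - 0.025), 3 * sqrt(0.025 * 0.975 / M))
})

test_that("MAMS programs are cheaper than their single-stage counterparts", {
  p <- tI_prior()
  bank <- build_bank(2, p, n_reps = 2e5, seed = 3)
  d <- screening_design(2, 20, 0.96)
  mams <- ess_mams(d, p, confirmatory_spec(J = 2, rule = "all-interesting"), bank)
  single <- ess_all_interesting(d, p, confirmatory_spec(rule = "all-interesting"))
  expect_lt(mams$ess, single$ess)
})

test_that("program-level simulation reproduces quantile and mean structure", {
  p <- tI_prior(); conf <- tI_conf()
  d <- screening_design(9, 22, -0.429)
  q1 <- simulate_ss_quantile(d, p, conf, n_reps = 2e4, seed = 11)
  q2 <- simulate_ss_quantile(d, p, conf, n_reps = 2e4, seed = 11)
  expect_identical(q1$quantile, q2$quantile)  # seed contract
  # every program pays at least one screening round plus one confirmatory trial
  n2 <- single_stage_n2(0.25, 0.025, 0.1)
  qmin <- simulate_ss_quantile(d, p, conf, q = 1e-4, n_reps = 5000, seed = 2)
  expect_gte(qmin$quantile, 10 * 22 + 2 * n2 - 1e-6)
  # doubling replicates shrinks the bootstrap SE by about sqrt(2)
  q4 <- simulate_ss_quantile(d, p, conf, n_reps = 8e4, seed = 12, n_boot = 100)
  expect_lt(q4$se, q1$se)
})
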