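test_that("recommendation probability matches closed forms in reducible cases", {
  # K = 1: Z is marginally N(0, 1 + n1 v0^2 / 2), so p = 1 - Phi(c1 / sd)
  d <- screening_design(1, 16, 0.814)
  p <- prob_recommend_one(d, prior_spec(0, 0.1))
  expect_equal(p, 1 - pnorm(0.814 / sqrt(1.08)), tolerance = 1e-8)
  expect_equal(p, 0.2168, tolerance = 1e-3)
  # c1 = -Inf: some treatment is always top, so p = 1/K by exchangeability
  for (K in c(1, 3, 7)) {
    p <- prob_recommend_one(screening_design(K, 20, -Inf), prior_spec(0.05, 0.2))
    expect_equal(p, 1 / K, tolerance = 1e-8)
  }
})

test_that("recommendation and success probabilities match the Monte-Carlo oracle", {
  prior <- tI_prior(); conf <- tI_conf()
  d <- screening_design(9, 22, -0.429)
  mc <- mc_top_program(9, 22, -0.429, 0, 0.1, n_reps = 1e6, seed = 71)
  p1 <- 9 * prob_recommend_one(d, prior)
  p2 <- 9 * prob_success_one(d, prior, conf)
  expect_lt(abs(p1 - mc$p_conduct), 3 * mc$se_p_conduct)
  expect_lt(abs(p2 - mc$p_success), 3 * mc$se_p_success)
})

test_that("degenerate prior collapses success probability to alpha times recommendation", {
  # with v0 = 0 and m0 = 0 every effect is exactly null, so the confirmatory
  # trial rejects with probability alpha independently of selection
  d <- screening_design(5, 30, 0.3)
  prior0 <- prior_spec(0, 0)
  conf <- tI_conf()
  expect_equal(prob_success_one(d, prior0, conf),
               0.025 * prob_recommend_one(d, prior0), tolerance = 1e-9)
})

test_that("success probability is monotone in the prior mean and in c1", {
  d <- screening_design(4, 20, 0.5)
  conf <- tI_conf()
  ps <- vapply(c(-0.05, 0, 0.05, 0.1),
               function(m) prob_success_one(d, prior_spec(m, 0.1), conf),
               numeric(1))
  expect_true(all(diff(ps) > 0))
  prior <- tI_prior()
  pr <- vapply(c(-0.5, 0, 0.5, 1),
               function(cc) prob_recommend_one(screening_design(4, 20, cc), prior),
               numeric(1))
  pc <- vapply(c(-0.5, 0, 0.5, 1),
               function(cc) prob_success_one(screening_design(4, 20, cc), prior, conf),
               numeric(1))
  expect_true(all(diff(pr) < 0))
  expect_true(all(diff(pc) < 0))
  # success never exceeds recommendation
  expect_true(all(pc <= pr))
})

test_that("screening error rate and power match closed forms and the oracle", {
  # K = 1 closed forms
  expect_equal(screening_fwer(screening_design(1, 16, 0.814)),
               1 - pnorm(0.814), tolerance = 1e-8)
  expect_equal(screening_power(screening_design(1, 16, 0.814), 0.25),
               1 - pnorm(0.814 - 0.25 * sqrt(8)), tolerance = 1e-8)
  # delta = 0 makes power equal the error rate at K = 1
  expect_equal(screening_power(screening_design(1, 12, 0.4), 0),
               screening_fwer(screening_design(1, 12, 0.4)), tolerance = 1e-8)
  # c1 = -Inf triggers a confirmatory trial with certainty
  expect_equal(screening_fwer(screening_design(6, 15, -Inf)), 1, tolerance = 1e-10)
  # K = 9 against the fixed-effects simulation oracle
  mc <- mc_screening_fixed(9, 22, -0.429, c(0.25, rep(0, 8)),
                           n_reps = 4e5, seed = 13)
  expect_lt(abs(screening_fwer(screening_design(9, 22, -0.429)) -
                  mc_screening_fixed(9, 22, -0.429, 0, n_reps = 4e5, seed = 17)$fwer),
            3 * mc$se_fwer)
  expect_lt(abs(screening_power(screening_design(9, 22, -0.429), 0.25) - mc$power),
            3 * mc$se_power)
})

test_that("program ESS follows the renewal identity and is label-invariant", {
  prior <- tI_prior(); conf <- tI_conf()
  res <- ess_top_single(screening_design(9, 22, -0.429), prior, conf)
  # renewal identity recombines from the reported probabilities
  n2 <- res$diagnostics$n2
  expect_equal(res$ess,
               (10 * 22 + 2 * n2 * res$p_conduct) / res$p_success,
               tolerance = 1e-12)
  expect_true(res$p_success <= res$p_conduct)
  expect_gte(res$ess, 10 * 22)
  # renewal-process simulation of full programs reproduces the ESS
  sim <- simulate_ss_quantile(screening_design(9, 22, -0.429), prior, conf,
                              n_reps = 3e4, seed = 5)
  expect_lt(abs(sim$mean_ss - res$ess) / res$ess, 0.02)
})

test_that("zero success probability signals an infinite ESS", {
  # an absurdly high threshold: no treatment ever progresses
  res <- ess_top_single(screening_design(2, 5, 50), tI_prior(), tI_conf())
  expect_true(res$ess == Inf || res$ess > 1e8)
})
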