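# Brute-force Monte-Carlo oracles, independent of the analytic paths they
# check: each simulates the model directly from its definition (patient-
# level sample means, shared control groups, prior draws) and returns
# estimates with standard errors.  Chunked so large replicate counts stay
# within memory.

# screening + (optional) two-arm confirmatory cycle under the prior
mc_top_program <- function(K, n1, c1, m0, v0, delta = 0.25, alpha = 0.025,
                           beta = 0.1, n_reps = 2e5, seed = 1,
                           chunk = 1e6) {
  set.seed(seed)
  n2 <- single_stage_n2(delta, alpha, beta)
  n_rec <- n_succ <- 0
  done <- 0
  while (done < n_reps) {
    M <- min(chunk, n_reps - done)
    mu <- matrix(rnorm(M * K, m0, v0), M, K)
    xbar <- mu + matrix(rnorm(M * K, 0, 1 / sqrt(n1)), M, K)
    x0 <- rnorm(M, 0, 1 / sqrt(n1))
    Z <- (xbar - x0) * sqrt(n1 / 2)
    top <- max.col(Z, ties.method = "first")
    sel <- Z[cbind(seq_len(M), top)] > c1
    n_rec <- n_rec + sum(sel)
    zc <- rnorm(M, mu[cbind(seq_len(M), top)] * sqrt(n2 / 2), 1)
    n_succ <- n_succ + sum(sel & zc > qnorm(1 - alpha))
    done <- done + M
  }
  p1 <- n_rec / n_reps; p2 <- n_succ / n_reps
  list(p_conduct = p1, p_success = p2,
       se_p_conduct = sqrt(p1 * (1 - p1) / n_reps),
       se_p_success = sqrt(p2 * (1 - p2) / n_reps))
}

# screening rule under fixed effects (mu vector), for FWER/power oracles
mc_screening_fixed <- function(K, n1, c1, mu, n_reps = 2e5, seed = 1) {
  set.seed(seed)
  mu <- rep_len(mu, K)
  muM <- matrix(mu, n_reps, K, byrow = TRUE)
  xbar <- muM + matrix(rnorm(n_reps * K, 0, 1 / sqrt(n1)), n_reps, K)
  x0 <- rnorm(n_reps, 0, 1 / sqrt(n1))
  Z <- (xbar - x0) * sqrt(n1 / 2)
  top <- max.col(Z, ties.method = "first")
  any_pass <- Z[cbind(seq_len(n_reps), top)] > c1
  first_sel <- any_pass & top == 1L
  list(fwer = mean(any_pass), power = mean(first_sel),
       se_fwer = sd(any_pass) / sqrt(n_reps),
       se_power = sd(first_sel) / sqrt(n_reps))
}

# all-interesting cycle: subset pass counts and cycle success
mc_all_program <- function(K, n1, c1, m0, v0, conf, n_reps = 2e5, seed = 1) {
  set.seed(seed)
  cd <- confirmatory_design(K, conf)
  mu <- matrix(rnorm(n_reps * K, m0, v0), n_reps, K)
  xbar <- mu + matrix(rnorm(n_reps * K, 0, 1 / sqrt(n1)), n_reps, K)
  x0 <- rnorm(n_reps, 0, 1 / sqrt(n1))
  Z <- (xbar - x0) * sqrt(n1 / 2)
  pass <- Z > c1
  icount <- rowSums(pass)
  n_i <- c(0, cd$n2_by_arms)[icount + 1L]
  c_i <- c(Inf, cd$c2_by_arms)[icount + 1L]
  y0 <- rnorm(n_reps) / sqrt(pmax(n_i, 1))
  ybar <- mu + matrix(rnorm(n_reps * K), n_reps, K) / sqrt(pmax(n_i, 1))
  Zc <- (ybar - y0) * sqrt(n_i / 2)
  win <- pass & Zc > c_i
  success <- icount > 0 & rowSums(win) > 0
  counts <- tabulate(icount + 1L, nbins = K + 1L)
  list(p_by_count = counts / n_reps,
       se_by_count = sqrt(counts / n_reps * (1 - counts / n_reps) / n_reps),
       p_success = mean(success),
       se_success = sd(success) / sqrt(n_reps))
}

# two-arm group-sequential trial at fixed effect mu
mc_gs_trial <- function(b, mu, n_reps = 2e5, seed = 1) {
  set.seed(seed)
  J <- b$J; n <- b$n_per_stage
  eff <- fut <- matrix(FALSE, n_reps, J)
  open <- rep(TRUE, n_reps)
  cum <- numeric(n_reps)
  for (j in seq_len(J)) {
    cum <- cum + rnorm(n_reps)      # (zeta_arm - zeta_ctl)/sqrt(2)
    Zj <- mu * sqrt(j * n / 2) + cum / sqrt(j)
    e <- open & Zj >= b$efficacy[j]
    f <- open & !e & Zj <= b$futility[j]
    eff[, j] <- e; fut[, j] <- f
    open <- open & !(e | f)
  }
  list(efficacy = colMeans(eff), futility = colMeans(fut),
       se = sqrt(0.25 / n_reps))
}

# default scenario objects shared across test files
tI_prior <- function() prior_spec(0, 0.1)
tI_conf <- function() confirmatory_spec(0.25, 0.025, 0.1, 1L, "top-treatment")
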