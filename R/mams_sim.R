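# Simulation engine with a reusable dataset bank.
#
# The bank stores design-independent standard-normal increments: a sample
# mean for any candidate (n1, n2) is formed by scaling, which is exact for
# the normal model and lets every candidate design reuse the same draws
# (common random numbers), keeping the simulated ESS surface smooth enough
# for Nelder-Mead.

#' Build a reusable bank of simulated program draws
#'
#' Draws `n_reps` replicates of: true standardized effects for up to
#' `K_max` treatments from the prior; one standard-normal screening noise
#' term per arm (control + `K_max` treatments); and one standard-normal
#' confirmatory noise increment per arm and stage.  Sample means for any
#' per-arm size `n` are formed as `mu + noise/sqrt(n)`, so one bank serves
#' every candidate design.
#'
#' @param K_max Largest number of screening arms the bank must support.
#' @param prior A [prior_spec()].
#' @param n_reps Number of replicates.
#' @param seed Integer seed; identical `(seed, n_reps, K_max, J_max)`
#'   reproduce the bank bit for bit.
#' @param J_max Largest number of confirmatory stages supported.
#' @return An object of class `dataset_bank`.
#' @examples
#' bank <- build_bank(3, prior_spec(0, 0.1), n_reps = 1000, seed = 1)
#' @export
build_bank <- function(K_max, prior, n_reps, seed, J_max = 2L) {
  stopifnot(inherits(prior, "prior_spec"), K_max >= 1, n_reps >= 1, J_max >= 1)
  set.seed(seed)
  effects <- matrix(stats::rnorm(n_reps * K_max, prior$m0, prior$v0),
                    n_reps, K_max)
  screening_noise <- matrix(stats::rnorm(n_reps * (K_max + 1)),
                            n_reps, K_max + 1)  # col 1 = control
  confirmatory_noise <- array(stats::rnorm(n_reps * (K_max + 1) * J_max),
                              dim = c(n_reps, K_max + 1, J_max))
  structure(list(effects = effects, screening_noise = screening_noise,
                 confirmatory_noise = confirmatory_noise,
                 prior = prior, K_max = as.integer(K_max),
                 J_max = as.integer(J_max), n_reps = as.integer(n_reps),
                 seed = as.integer(seed)),
            class = "dataset_bank")
}

#' @export
print.dataset_bank <- function(x, ...) {
  cat(sprintf("Dataset bank: %d replicates, up to %d arms, %d stage(s), seed %d\n",
              x$n_reps, x$K_max, x$J_max, x$seed))
  invisible(x)
}

# ---- MAMS boundary calibration -------------------------------------------

# Non-binding FWER of an i-arm, two-stage trial with triangular bounds
# scaled by C: probability any arm's statistic ever crosses an efficacy
# bound under the global null, accounting for the shared control group.
# Conditioning on the control's two stage increments makes arms
# independent; the per-arm crossing probability needs one more
# one-dimensional integral over the arm's first-stage increment.
.mams_fwer2 <- function(C, i, quad_points = 32L, inner_points = 48L) {
  b <- .tri_shape(C, 2L)
  u1 <- b$u[1]; u2 <- b$u[2]
  gw <- .gh(quad_points)
  fw <- 0
  for (k in seq_len(quad_points)) {
    w1 <- gw$nodes[k]
    hi <- sqrt(2) * u1 + w1                       # a1 below hi: no stage-1 stop
    g <- .gl(inner_points, -8.5, hi)
    # P(stage-2 cross | a1, w1 + w2): a2 > 2 u2 - a1 + w1 + w2
    tail2 <- outer(g$nodes, gw$nodes + w1,
                   function(a, w12) 1 - stats::pnorm(2 * u2 - a + w12))
    q <- (1 - stats::pnorm(hi)) +
      as.vector(crossprod(g$weights * stats::dnorm(g$nodes), tail2))
    fw <- fw + gw$weights[k] * sum(gw$weights * (1 - (1 - q)^i))
  }
  fw
}

#' Triangular boundaries for a multi-arm multi-stage confirmatory trial
#'
#' Generalizes [triangular_boundaries()] to `i` experimental arms sharing
#' one control.  The boundary shape is unchanged; the scale constant is
#' re-calibrated so that the family-wise error rate — the probability that
#' any arm ever crosses an efficacy bound under the global null, with
#' futility bounds non-binding — equals `alpha`, and the per-stage,
#' per-arm size so that the marginal efficacy-crossing probability of a
#' specific treatment with effect `delta` equals `1 - beta`.  For
#' `i = 1` this is exactly [triangular_boundaries()]; two-stage trials
#' (`J = 2`) are supported for `i > 1`.
#'
#' @param i Number of experimental arms.
#' @param conf A [confirmatory_spec()].
#' @param grid_points Gauss-Legendre node count for power calibration.
#' @return A `gs_boundaries` object (with an `arms` field).
#' @export
mams_boundaries <- function(i, conf, grid_points = 160L) {
  stopifnot(is.numeric(i), length(i) == 1L, i >= 1, i == round(i))
  if (i == 1 || conf$J == 1) {
    b <- triangular_boundaries(conf, grid_points)
    b$arms <- as.integer(i)
    if (conf$J == 1 && i > 1) {
      # single-stage multi-arm: Dunnett critical value and matching n2
      c2 <- dunnett_c2(i, conf$alpha)
      n2 <- multiarm_n2(i, conf$delta, conf$alpha, conf$beta)
      b$efficacy <- c2; b$futility <- c2
      b$C <- c2 / 2; b$n_per_stage <- n2
      b$stage_ss <- (i + 1) * n2
    }
    return(b)
  }
  if (conf$J != 2)
    stop("multi-arm boundaries are implemented for J = 1 and J = 2", call. = FALSE)
  C <- stats::uniroot(function(C) .mams_fwer2(C, i) - conf$alpha,
                      lower = 0.5, upper = 2.5, tol = 1e-9)$root
  sh <- .tri_shape(C, 2L)
  pw <- function(n) sum(.gs_crossing(sh$u, sh$l, conf$delta * sqrt(n / 2),
                                     binding = FALSE, grid_points)$efficacy)
  n_single <- single_stage_n2(conf$delta, conf$alpha, conf$beta)
  n <- stats::uniroot(function(n) pw(n) - (1 - conf$beta),
                      lower = 1e-2, upper = 4 * n_single, tol = 1e-8)$root
  structure(list(J = 2L, C = C, efficacy = sh$u, futility = sh$l,
                 n_per_stage = n, stage_ss = (i + 1) * seq_len(2L) * n,
                 alpha_attained = NA_real_, power_attained = NA_real_,
                 arms = as.integer(i), spec = conf),
            class = "gs_boundaries")
}

# ---- per-replicate program cycle on the bank ------------------------------

# Runs the screening rule and (where triggered) the confirmatory trial on
# every bank replicate.  Returns per-replicate logical/numeric vectors:
# conducted, success, conf_ss (patients in the confirmatory trial, all
# arms; 0 when no trial runs).
.simulate_cycle_bank <- function(design, conf, bank) {
  K <- design$K; n1 <- design$n1; c1 <- design$c1
  if (K > bank$K_max) stop("bank was built for fewer arms than 'design$K'",
                           call. = FALSE)
  if (conf$J > bank$J_max) stop("bank was built for fewer stages than 'conf$J'",
                                call. = FALSE)
  mu <- bank$effects[, seq_len(K), drop = FALSE]
  x0 <- bank$screening_noise[, 1] / sqrt(n1)
  xbar <- mu + bank$screening_noise[, 1 + seq_len(K), drop = FALSE] / sqrt(n1)
  Z <- (xbar - x0) * sqrt(n1 / 2)
  M <- nrow(Z)
  zeta0 <- bank$confirmatory_noise[, 1, , drop = FALSE]  # control increments
  dim(zeta0) <- c(M, bank$J_max)

  if (conf$rule == "top-treatment") {
    top <- max.col(Z, ties.method = "first")
    conducted <- Z[cbind(seq_len(M), top)] > c1
    mu_sel <- mu[cbind(seq_len(M), top)]
    zeta_sel <- matrix(bank$confirmatory_noise[cbind(
      rep(seq_len(M), conf$J), rep(1L + top, conf$J),
      rep(seq_len(conf$J), each = M))], M, conf$J)
    b <- triangular_boundaries(conf)
    n <- b$n_per_stage
    success <- rep(FALSE, M)
    conf_ss <- numeric(M)
    open <- conducted
    cum_t <- cum_c <- numeric(M)
    for (j in seq_len(conf$J)) {
      cum_t <- cum_t + zeta_sel[, j]
      cum_c <- cum_c + zeta0[, j]
      Zj <- mu_sel * sqrt(j * n / 2) + (cum_t - cum_c) / sqrt(2 * j)
      eff <- open & Zj >= b$efficacy[j]
      fut <- open & !eff & (Zj <= b$futility[j])
      stop_now <- eff | fut
      success[eff] <- TRUE
      conf_ss[stop_now] <- 2 * j * n
      open <- open & !stop_now
    }
    # l_J = u_J forces a decision, so nothing remains open
    return(list(conducted = conducted, success = success, conf_ss = conf_ss))
  }

  # all-interesting rule
  pass <- Z > c1
  icount <- rowSums(pass)
  conducted <- icount > 0
  success <- rep(FALSE, M)
  conf_ss <- numeric(M)
  designs <- lapply(seq_len(K), mams_boundaries, conf = conf)
  n_by_i <- vapply(designs, `[[`, numeric(1), "n_per_stage")
  n_rep <- ifelse(conducted, n_by_i[pmax(icount, 1L)], 0)
  u1_rep <- vapply(designs, function(d) d$efficacy[1], numeric(1))[pmax(icount, 1L)]
  zeta1 <- matrix(bank$confirmatory_noise[, 1 + seq_len(K), 1], M, K)
  # stage-1 confirmatory statistics: theta + (zeta_arm - zeta_ctl)/sqrt(2)
  Zc1 <- mu * sqrt(n_rep / 2) + (zeta1 - zeta0[, 1]) / sqrt(2)
  if (conf$J == 1) {
    c2_rep <- u1_rep
    hit <- pass & (Zc1 > c2_rep)
    success <- conducted & rowSums(hit) > 0
    conf_ss <- ifelse(conducted, (icount + 1) * n_rep, 0)
    return(list(conducted = conducted, success = success, conf_ss = conf_ss))
  }
  if (conf$J != 2)
    stop("the all-interesting simulation supports J = 1 or J = 2", call. = FALSE)
  l1_rep <- vapply(designs, function(d) d$futility[1], numeric(1))[pmax(icount, 1L)]
  u2_rep <- vapply(designs, function(d) d$efficacy[2], numeric(1))[pmax(icount, 1L)]
  succ1 <- conducted & rowSums(pass & (Zc1 >= u1_rep)) > 0
  active2 <- pass & (Zc1 > l1_rep) & !succ1
  n_active2 <- rowSums(active2)
  go2 <- conducted & !succ1 & n_active2 > 0
  zeta2 <- matrix(bank$confirmatory_noise[, 1 + seq_len(K), 2], M, K)
  Zc2 <- mu * sqrt(2 * n_rep / 2) +
    (zeta1 + zeta2 - zeta0[, 1] - zeta0[, 2]) / sqrt(4)
  succ2 <- go2 & rowSums(active2 & (Zc2 >= u2_rep)) > 0
  success <- succ1 | succ2
  conf_ss <- ifelse(conducted, (icount + 1) * n_rep, 0) +
    ifelse(go2, (n_active2 + 1) * n_rep, 0)
  list(conducted = conducted, success = success, conf_ss = conf_ss)
}

#' Simulation estimates of the confirmatory-phase quantities
#'
#' Applies the screening rule and, where triggered, simulates the
#' confirmatory trial on every bank replicate, and returns the four
#' quantities the renewal ESS formula needs: the probability a
#' confirmatory trial takes place, the probability it succeeds given that
#' it takes place, and its expected sample size when it fails and when it
#' succeeds.  Standard errors accompany each estimate.
#'
#' @param design A [screening_design()].
#' @param conf A [confirmatory_spec()].
#' @param bank A [build_bank()] object with `K_max >= design$K`.
#' @return A list with `p_conduct`, `p_success_given_conduct`,
#'   `e_ss_fail`, `e_ss_success`, their `se`, and `n_reps`.
#' @export
estimate_phase3_quantities <- function(design, conf, bank) {
  stopifnot(inherits(bank, "dataset_bank"))
  sim <- .simulate_cycle_bank(design, conf, bank)
  M <- length(sim$conducted)
  nc <- sum(sim$conducted)
  if (nc == 0)
    warning("no replicate triggered a confirmatory trial; estimates are degenerate")
  p_c <- nc / M
  succ_c <- sim$success[sim$conducted]
  p_s <- if (nc > 0) mean(succ_c) else NA_real_
  ss_f <- sim$conf_ss[sim$conducted & !sim$success]
  ss_s <- sim$conf_ss[sim$conducted & sim$success]
  se_mean <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
  list(p_conduct = p_c,
       p_success_given_conduct = p_s,
       e_ss_fail = if (length(ss_f)) mean(ss_f) else 0,
       e_ss_success = if (length(ss_s)) mean(ss_s) else 0,
       se = list(p_conduct = sqrt(p_c * (1 - p_c) / M),
                 p_success_given_conduct = if (nc > 0) sqrt(p_s * (1 - p_s) / nc) else NA_real_,
                 e_ss_fail = se_mean(ss_f),
                 e_ss_success = se_mean(ss_s)),
       n_reps = M)
}

#' Simulation-based program ESS on a dataset bank
#'
#' Plugs the [estimate_phase3_quantities()] estimates into the renewal
#' identity: expected per-cycle patients divided by the per-cycle success
#' probability.  A Monte-Carlo standard error is attached by splitting the
#' bank into batches.
#'
#' @inheritParams estimate_phase3_quantities
#' @param prior The [prior_spec()] the bank was built from (checked for
#'   consistency).
#' @param n_batches Batch count for the ESS standard error.
#' @return A `program_result`; `diagnostics` carries `se_ess` and the four
#'   plug-in estimates.
#' @export
ess_mams <- function(design, prior, conf, bank, n_batches = 20L) {
  stopifnot(inherits(bank, "dataset_bank"))
  if (!isTRUE(all.equal(unclass(bank$prior), unclass(prior))))
    warning("'prior' differs from the prior the bank was built with; using the bank's draws")
  sim <- .simulate_cycle_bank(design, conf, bank)
  M <- length(sim$conducted)
  cycle_ss <- (design$K + 1) * design$n1 + sim$conf_ss
  p <- mean(sim$success)
  ess <- if (p > 0) mean(cycle_ss) / p else Inf
  # batch-means standard error
  idx <- rep(seq_len(n_batches), length.out = M)
  bs <- vapply(seq_len(n_batches), function(b) {
    sel <- idx == b
    pb <- mean(sim$success[sel])
    if (pb > 0) mean(cycle_ss[sel]) / pb else NA_real_
  }, numeric(1))
  se <- stats::sd(bs, na.rm = TRUE) / sqrt(sum(!is.na(bs)))
  est <- estimate_phase3_quantities(design, conf, bank)
  program_result(
    ess = ess,
    p_conduct = mean(sim$conducted),
    p_success = p,
    diagnostics = list(se_ess = se, estimates = est, n_reps = M))
}

# ---- fresh-draw program simulation (sample-size quantiles) ----------------

# One batch of M iid program cycles drawn fresh from the prior (not the
# bank); returns total patients in the cycle and the success indicator.
.simulate_cycles_fresh <- function(M, design, prior, conf, pre) {
  K <- design$K; n1 <- design$n1; c1 <- design$c1
  mu <- matrix(stats::rnorm(M * K, prior$m0, prior$v0), M, K)
  x0 <- stats::rnorm(M, 0, 1 / sqrt(n1))
  xbar <- mu + matrix(stats::rnorm(M * K, 0, 1 / sqrt(n1)), M, K)
  Z <- (xbar - x0) * sqrt(n1 / 2)
  ss <- rep((K + 1) * n1, M)
  if (conf$rule == "top-treatment") {
    top <- max.col(Z, ties.method = "first")
    conducted <- Z[cbind(seq_len(M), top)] > c1
    mu_sel <- mu[cbind(seq_len(M), top)]
    success <- rep(FALSE, M)
    b <- pre$boundaries
    n <- b$n_per_stage
    open <- conducted
    cum <- numeric(M)
    for (j in seq_len(conf$J)) {
      cum <- cum + stats::rnorm(M)  # (zeta_arm - zeta_ctl)/sqrt(2) per stage
      Zj <- mu_sel * sqrt(j * n / 2) + cum / sqrt(j)
      eff <- open & Zj >= b$efficacy[j]
      fut <- open & !eff & (Zj <= b$futility[j])
      success[eff] <- TRUE
      ss[eff | fut] <- ss[eff | fut] + 2 * j * n
      open <- open & !(eff | fut)
    }
    return(list(ss = ss, success = success))
  }
  # all-interesting rule
  pass <- Z > c1
  icount <- rowSums(pass)
  conducted <- icount > 0
  n_by_i <- vapply(pre$designs, `[[`, numeric(1), "n_per_stage")
  n_rep <- ifelse(conducted, n_by_i[pmax(icount, 1L)], 0)
  pick <- function(field, stage)
    vapply(pre$designs, function(d) d[[field]][stage], numeric(1))[pmax(icount, 1L)]
  zeta0 <- matrix(stats::rnorm(M * conf$J), M, conf$J)
  zeta1 <- matrix(stats::rnorm(M * K), M, K)
  Zc1 <- mu * sqrt(n_rep / 2) + (zeta1 - zeta0[, 1]) / sqrt(2)
  if (conf$J == 1) {
    success <- conducted & rowSums(pass & (Zc1 > pick("efficacy", 1))) > 0
    ss <- ss + ifelse(conducted, (icount + 1) * n_rep, 0)
    return(list(ss = ss, success = success))
  }
  u1 <- pick("efficacy", 1); l1 <- pick("futility", 1); u2 <- pick("efficacy", 2)
  succ1 <- conducted & rowSums(pass & (Zc1 >= u1)) > 0
  active2 <- pass & (Zc1 > l1) & !succ1
  n_active2 <- rowSums(active2)
  go2 <- conducted & !succ1 & n_active2 > 0
  zeta2 <- matrix(stats::rnorm(M * K), M, K)
  Zc2 <- mu * sqrt(n_rep) + (zeta1 + zeta2 - zeta0[, 1] - zeta0[, 2]) / 2
  succ2 <- go2 & rowSums(active2 & (Zc2 >= u2)) > 0
  ss <- ss + ifelse(conducted, (icount + 1) * n_rep, 0) +
    ifelse(go2, (n_active2 + 1) * n_rep, 0)
  list(ss = ss, success = succ1 | succ2)
}

# precomputed confirmatory machinery shared by all cycles of a simulation
.precompute_confirmatory <- function(design, conf) {
  if (conf$rule == "top-treatment")
    list(boundaries = triangular_boundaries(conf))
  else
    list(designs = lapply(seq_len(design$K), mams_boundaries, conf = conf))
}

#' Simulated quantile of the total sample size until phase III success
#'
#' Simulates full programs — independent screening + confirmatory cycles
#' repeated until the first confirmatory success — and returns the
#' empirical `q`-quantile of the total number of patients, with a
#' bootstrap standard error.  The mean of the simulated totals estimates
#' the analytic ESS and is returned as a cross-check.
#'
#' @inheritParams ess_top_single
#' @param q Quantile level in (0, 1).
#' @param n_reps Number of simulated programs.
#' @param seed Integer seed.
#' @param n_boot Bootstrap resamples for the quantile standard error.
#' @return A list with `quantile`, `se`, `mean_ss`, `q`, `n_reps`.
#' @examples
#' simulate_ss_quantile(screening_design(9, 22, -0.429), prior_spec(0, 0.1),
#'                      confirmatory_spec(), n_reps = 2000, seed = 1)
#' @export
simulate_ss_quantile <- function(design, prior, conf = confirmatory_spec(),
                                 q = 0.95, n_reps = 100000L, seed = 1L,
                                 n_boot = 50L) {
  stopifnot(q > 0, q < 1, n_reps >= 1)
  set.seed(seed)
  pre <- .precompute_confirmatory(design, conf)
  totals <- numeric(n_reps)
  alive <- seq_len(n_reps)
  rounds <- 0L
  while (length(alive) > 0L) {
    rounds <- rounds + 1L
    if (rounds > 10000L)
      stop("program simulation did not terminate; success probability may be ~0",
           call. = FALSE)
    res <- .simulate_cycles_fresh(length(alive), design, prior, conf, pre)
    totals[alive] <- totals[alive] + res$ss
    alive <- alive[!res$success]
  }
  qhat <- unname(stats::quantile(totals, q))
  bq <- vapply(seq_len(n_boot), function(b)
    unname(stats::quantile(sample(totals, replace = TRUE), q)), numeric(1))
  list(quantile = qhat, se = stats::sd(bq), mean_ss = mean(totals),
       q = q, n_reps = n_reps)
}
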