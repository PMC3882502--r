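# Top-treatment screening with a single-stage confirmatory trial.
#
# All quantities are prior-predictive: the true standardized effects of the
# K screened treatments are integrated over the exchangeable N(m0, v0^2)
# prior.  The shared screening control group couples the K z-statistics,
# but conditioning on a treatment's own sample mean (and integrating the
# control mean analytically) reduces every quantity to one- or
# two-dimensional smooth integrals evaluated by Gauss-Hermite quadrature.

# selection kernel: given treatment i's sample mean x, the probability that
# it beats the other K-1 arms (each marginally N(m0, v0^2 + 1/n1)) and that
# its z-statistic clears c1 once the control mean (N(0, 1/n1)) is
# integrated out.
.selection_kernel <- function(x, K, n1, c1, m0, v0) {
  sd_m <- sqrt(v0^2 + 1 / n1)
  beat <- if (K > 1) stats::pnorm(x, m0, sd_m)^(K - 1) else 1
  beat * stats::pnorm(sqrt(n1) * (x - c1 * sqrt(2 / n1)))
}

#' Prior-predictive probability that a specific treatment is recommended
#'
#' Probability that a given treatment's screening z-statistic exceeds `c1`
#' *and* is the largest of the `K` statistics, averaged over the
#' treatment-effect prior.  By exchangeability the expected probability
#' that *any* confirmatory trial is conducted is `K` times this value.
#'
#' @param design A [screening_design()].
#' @param prior A [prior_spec()].
#' @param quad_points Gauss-Hermite node count.
#' @return A probability in \[0, 1/K\].
#' @examples
#' prob_recommend_one(screening_design(9, 22, -0.429), prior_spec(0, 0.1))
#' @export
prob_recommend_one <- function(design, prior, quad_points = .QUAD_POINTS) {
  stopifnot(inherits(design, "screening_design"), inherits(prior, "prior_spec"))
  g <- .gh(quad_points)
  sd_m <- sqrt(prior$v0^2 + 1 / design$n1)
  x <- prior$m0 + sd_m * g$nodes  # marginal draw of the treatment's sample mean
  sum(g$weights * .selection_kernel(x, design$K, design$n1, design$c1,
                                    prior$m0, prior$v0))
}

#' Prior-predictive probability of recommendation plus phase III success
#'
#' Probability that a specific treatment is recommended by the screening
#' trial *and* subsequently wins its two-arm confirmatory trial.  The
#' selection kernel of [prob_recommend_one()] is weighted by the
#' confirmatory power function at the treatment's true effect and
#' integrated jointly over (sample mean, true effect) — a two-dimensional
#' quadrature.  `K` times this value is the expected per-cycle probability
#' of a phase III success.
#'
#' @inheritParams prob_recommend_one
#' @param conf A [confirmatory_spec()] with `J = 1`.
#' @param n2 Optional per-arm confirmatory sample size; defaults to
#'   [single_stage_n2()] for `conf`.
#' @return A probability, bounded above by [prob_recommend_one()].
#' @export
prob_success_one <- function(design, prior, conf = confirmatory_spec(),
                             n2 = NULL, quad_points = .QUAD_POINTS) {
  stopifnot(inherits(design, "screening_design"), inherits(prior, "prior_spec"),
            inherits(conf, "confirmatory_spec"))
  if (conf$J != 1)
    stop("prob_success_one() is the single-stage path; use ess_top_groupseq() for J > 1",
         call. = FALSE)
  if (is.null(n2)) n2 <- single_stage_n2(conf$delta, conf$alpha, conf$beta)
  g <- .gh(quad_points)
  if (prior$v0 > 0) {
    mu <- prior$m0 + prior$v0 * g$nodes
    wm <- g$weights
  } else {
    mu <- prior$m0
    wm <- 1
  }
  # x | mu ~ N(mu, 1/n1); tensor-product quadrature over (mu, x)
  X <- outer(mu, sqrt(1 / design$n1) * g$nodes, "+")
  S <- .selection_kernel(X, design$K, design$n1, design$c1, prior$m0, prior$v0)
  inner <- as.vector(S %*% g$weights)
  sum(wm * phase3_power_function(mu, n2, conf$alpha) * inner)
}

#' Screening family-wise error rate
#'
#' Probability that any confirmatory trial is triggered when all `K` true
#' effects are zero, i.e. `P(max(Z_1, ..., Z_K) > c1)` for equicorrelated
#' (rho = 1/2) standard normal statistics.  Evaluated by integrating over
#' the shared control mean; the result does not depend on `n1`.
#'
#' @inheritParams prob_recommend_one
#' @return A probability.
#' @examples
#' screening_fwer(screening_design(1, 16, 0.814))  # 1 - pnorm(0.814)
#' @export
screening_fwer <- function(design, quad_points = .QUAD_POINTS) {
  stopifnot(inherits(design, "screening_design"))
  g <- .gh(quad_points)
  1 - sum(g$weights * stats::pnorm(g$nodes + design$c1 * sqrt(2))^design$K)
}

#' Screening power for a single effective treatment
#'
#' Probability that treatment 1 progresses to the confirmatory trial when
#' its true standardized effect is `delta` and the other `K - 1` effects
#' are zero: `P(Z_1 > c1 and Z_1 > Z_j for all j)`.
#'
#' @inheritParams prob_recommend_one
#' @param delta True standardized effect of the one effective treatment.
#' @return A probability.
#' @examples
#' screening_power(screening_design(1, 16, 0.814), 0.25)
#' @export
screening_power <- function(design, delta, quad_points = .QUAD_POINTS) {
  stopifnot(inherits(design, "screening_design"), is.numeric(delta))
  g <- .gh(quad_points)
  n1 <- design$n1
  x <- delta + sqrt(1 / n1) * g$nodes  # treatment 1's sample mean
  beat <- if (design$K > 1) stats::pnorm(sqrt(n1) * x)^(design$K - 1) else 1
  sum(g$weights * beat * stats::pnorm(sqrt(n1) * (x - design$c1 * sqrt(2 / n1))))
}

#' ESS until phase III success: top-treatment rule, single-stage phase III
#'
#' Expected number of patients recruited, across repeated independent
#' screening + confirmatory cycles, up to and including the first
#' confirmatory success.  Because cycles draw fresh treatments from the
#' same prior, the renewal identity gives
#' \deqn{ESS = \frac{(K+1) n_1 + 2 n_2 E(P_1)}{E(P_2)},}
#' where \eqn{E(P_1)} and \eqn{E(P_2)} are the per-cycle probabilities of
#' conducting, and of winning, a confirmatory trial.
#'
#' @inheritParams prob_success_one
#' @param integer_n2 Round the confirmatory per-arm size up to a whole
#'   patient.
#' @return A `program_result` with fields `ess`, `p_conduct`, `p_success`,
#'   `fwer`, `power`.
#' @examples
#' ess_top_single(screening_design(9, 22, -0.429), prior_spec(0, 0.1),
#'                confirmatory_spec())
#' @export
ess_top_single <- function(design, prior, conf = confirmatory_spec(),
                           integer_n2 = FALSE, quad_points = .QUAD_POINTS) {
  stopifnot(inherits(conf, "confirmatory_spec"))
  if (conf$rule != "top-treatment")
    stop("'conf$rule' must be \"top-treatment\"", call. = FALSE)
  if (conf$J != 1)
    stop("use ess_top_groupseq() for multi-stage confirmatory trials",
         call. = FALSE)
  n2 <- single_stage_n2(conf$delta, conf$alpha, conf$beta, integer = integer_n2)
  p1 <- design$K * prob_recommend_one(design, prior, quad_points)
  p2 <- design$K * prob_success_one(design, prior, conf, n2 = n2,
                                    quad_points = quad_points)
  ess <- if (p2 > 0) ((design$K + 1) * design$n1 + 2 * n2 * p1) / p2 else Inf
  program_result(
    ess = ess, p_conduct = p1, p_success = p2,
    fwer = screening_fwer(design, quad_points),
    power = screening_power(design, conf$delta, quad_points),
    diagnostics = list(n2 = n2, cycle_ss = (design$K + 1) * design$n1 + 2 * n2 * p1))
}
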