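# All-interesting-treatments screening with a single-stage multi-arm
# confirmatory trial.
#
# Every screening arm whose z-statistic clears c1 enters one confirmatory
# trial whose Dunnett critical value c2(i) and per-arm size n2(i) depend on
# the number i of arms that passed.  Conditioning on the screening control
# mean makes the K pass events independent with a common probability, so
# the 2^K subsets collapse to K + 1 pass counts with binomial
# multiplicities; conditioning additionally on the confirmatory control
# mean factorizes the joint (pass, fail-to-confirm) event across
# treatments.

# probability a treatment passes screening given the standardized control
# mean u = sqrt(n1) * xbar_0, with its effect integrated over the prior
.pass_prob_given_control <- function(u, n1, c1, m0, v0) {
  1 - stats::pnorm((u + c1 * sqrt(2) - sqrt(n1) * m0) / sqrt(1 + n1 * v0^2))
}

#' Distribution of the number of treatments passing screening
#'
#' Prior-predictive probabilities `P(|I| = i)`, `i = 0, ..., K`, where `I`
#' is the set of treatments whose screening z-statistics exceed `c1`.
#'
#' @inheritParams prob_recommend_one
#' @return An object of class `subset_distribution`: a list with
#'   `p_by_count` (named numeric vector over counts `0..K`).
#' @examples
#' subset_pass_distribution(screening_design(2, 20, 0.96), prior_spec(0, 0.1))
#' @export
subset_pass_distribution <- function(design, prior, quad_points = .QUAD_POINTS) {
  stopifnot(inherits(design, "screening_design"), inherits(prior, "prior_spec"))
  g <- .gh(quad_points)
  K <- design$K
  a <- .pass_prob_given_control(g$nodes, design$n1, design$c1,
                                prior$m0, prior$v0)
  p <- vapply(0:K, function(i)
    choose(K, i) * sum(g$weights * a^i * (1 - a)^(K - i)), numeric(1))
  structure(list(p_by_count = stats::setNames(p, 0:K)),
            class = "subset_distribution")
}

#' @export
print.subset_distribution <- function(x, ...) {
  cat("P(number of treatments passing screening)\n")
  print(round(x$p_by_count, 4))
  invisible(x)
}

#' Prior-predictive probability that a cycle confirms no treatment
#'
#' Probability that one screening + confirmatory cycle ends without any
#' treatment exceeding its Dunnett critical value — either because no arm
#' passes screening or because every arm that passes fails the multi-arm
#' confirmatory trial.  Computed by conditioning on the screening and
#' confirmatory control means (two-dimensional outer quadrature); given
#' both, each treatment independently contributes a bivariate-normal
#' rectangle probability (pass screening, miss confirmation) that is
#' itself integrated over the effect prior.
#'
#' @inheritParams prob_success_one
#' @param cdesign Optional [confirmatory_design()] for `design$K` arms;
#'   computed from `conf` if missing.
#' @return A probability.
#' @export
prob_cycle_no_success <- function(design, prior, conf = confirmatory_spec(rule = "all-interesting"),
                                  cdesign = NULL, quad_points = .QUAD_POINTS) {
  stopifnot(inherits(design, "screening_design"), inherits(prior, "prior_spec"),
            inherits(conf, "confirmatory_spec"))
  if (conf$rule != "all-interesting")
    stop("'conf$rule' must be \"all-interesting\"", call. = FALSE)
  if (conf$J != 1)
    stop("the analytic path covers single-stage confirmatory trials; use the simulation engine for J > 1",
         call. = FALSE)
  if (is.null(cdesign)) cdesign <- confirmatory_design(design$K, conf,
                                                       quad_points = quad_points)
  g <- .gh(quad_points)
  K <- design$K; n1 <- design$n1; c1 <- design$c1
  u <- g$nodes; wu <- g$weights          # standardized screening control mean
  w <- g$nodes; ww <- g$weights          # standardized confirmatory control mean
  if (prior$v0 > 0) {
    mu <- prior$m0 + prior$v0 * g$nodes; wm <- g$weights
  } else {
    mu <- prior$m0; wm <- 1
  }
  a <- .pass_prob_given_control(u, n1, c1, prior$m0, prior$v0)
  pno <- sum(wu * (1 - a)^K)             # no arm passes
  for (i in seq_len(K)) {
    c2i <- cdesign$c2_by_arms[i]; n2i <- cdesign$n2_by_arms[i]
    # per-treatment P(pass & not confirmed | u, w), separable over the
    # prior nodes: pass depends on (mu, u), miss depends on (mu, w)
    G <- outer(mu, u, function(m, uu) 1 - stats::pnorm(uu + c1 * sqrt(2) - m * sqrt(n1)))
    H <- outer(mu, w, function(m, vv) stats::pnorm(vv + c2i * sqrt(2) - m * sqrt(n2i)))
    B <- crossprod(G * wm, H)            # (u x w) grid of rectangle probs
    pno <- pno + choose(K, i) * sum((wu * (1 - a)^(K - i)) * (B^i %*% ww))
  }
  min(max(pno, 0), 1)
}

#' ESS until phase III success: all-interesting rule, single-stage phase III
#'
#' Renewal-identity ESS for the all-interesting-treatments program: the
#' expected per-cycle cost is \eqn{\sum_i P(|I|=i)\,[(K+1)n_1 + (i+1)n_2(i)]}
#' and the per-cycle success probability is one minus
#' [prob_cycle_no_success()].
#'
#' @inheritParams prob_cycle_no_success
#' @param integer_n2 Round each `n2(i)` up to a whole patient.
#' @return A `program_result`; `diagnostics` carries the subset
#'   distribution and the confirmatory design table.
#' @examples
#' ess_all_interesting(screening_design(2, 20, 0.96), prior_spec(0, 0.1),
#'                     confirmatory_spec(rule = "all-interesting"))
#' @export
ess_all_interesting <- function(design, prior,
                                conf = confirmatory_spec(rule = "all-interesting"),
                                integer_n2 = FALSE, quad_points = .QUAD_POINTS) {
  cdesign <- confirmatory_design(design$K, conf, integer_n2 = integer_n2,
                                 quad_points = quad_points)
  sub <- subset_pass_distribution(design, prior, quad_points)
  pno <- prob_cycle_no_success(design, prior, conf, cdesign, quad_points)
  K <- design$K
  ss_by_count <- (K + 1) * design$n1 +
    (0:K + 1) * c(0, cdesign$n2_by_arms)  # n2(0) = 0: no confirmatory trial
  e_cycle_ss <- sum(sub$p_by_count * ss_by_count)
  p_success <- 1 - pno
  ess <- if (p_success > 0) e_cycle_ss / p_success else Inf
  program_result(
    ess = ess,
    p_conduct = 1 - sub$p_by_count[["0"]],
    p_success = p_success,
    fwer = screening_fwer(design, quad_points),
    power = screening_power(design, conf$delta, quad_points),
    diagnostics = list(subset = sub, cdesign = cdesign,
                       cycle_ss = e_cycle_ss))
}
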