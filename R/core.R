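#' Power function of a two-arm fixed-sample confirmatory trial
#'
#' Probability that a two-arm trial with `n2` patients per arm rejects the
#' one-sided null at level `alpha` when the true standardized effect is
#' `mu`:
#' \deqn{R(\mu) = \Phi\left(\mu\sqrt{n_2/2} - z_{1-\alpha}\right).}
#' At `mu = 0` this equals `alpha`; it is strictly increasing in both `mu`
#' and `n2`.
#'
#' @param mu Standardized treatment effect (vectorized).
#' @param n2 Patients per arm in the confirmatory trial (> 0).
#' @param alpha One-sided type-I error rate.
#' @return Rejection probability, same length as `mu`.
#' @examples
#' phase3_power_function(0, 336.24, 0.025)     # = alpha
#' phase3_power_function(0.25, 336.24, 0.025)  # ~ 0.90
#' @export
phase3_power_function <- function(mu, n2, alpha = 0.025) {
  if (!is.numeric(n2) || length(n2) != 1L || !is.finite(n2) || n2 <= 0)
    stop("'n2' must be a single positive number", call. = FALSE)
  stats::pnorm(mu * sqrt(n2 / 2) - stats::qnorm(1 - alpha))
}

#' Per-arm sample size of a two-arm confirmatory trial
#'
#' Closed-form per-arm sample size giving power `1 - beta` at standardized
#' difference `delta` with one-sided level `alpha`:
#' \deqn{n_2 = 2 (z_{1-\alpha} + z_{1-\beta})^2 / \delta^2.}
#'
#' @param delta Standardized clinically relevant difference (> 0).
#' @param alpha One-sided type-I error rate.
#' @param beta One minus power.
#' @param integer If `TRUE`, round up to the next whole patient.
#' @return Per-arm sample size (continuous unless `integer = TRUE`).
#' @examples
#' single_stage_n2(0.25, 0.025, 0.1)  # 336.24
#' @export
single_stage_n2 <- function(delta, alpha = 0.025, beta = 0.1, integer = FALSE) {
  if (!is.numeric(delta) || length(delta) != 1L || !is.finite(delta) || delta <= 0)
    stop("'delta' must be > 0 (delta = 0 needs an infinite sample size)",
         call. = FALSE)
  n2 <- 2 * (stats::qnorm(1 - alpha) + stats::qnorm(1 - beta))^2 / delta^2
  if (integer) ceiling(n2) else n2
}

# FWER of i shared-control z-statistics at critical value c:
# (Z_1 .. Z_i) are equicorrelated (rho = 1/2) standard normals, so
# conditioning on the shared control draw reduces P(max Z <= c) to a
# one-dimensional integral.
.dunnett_fwer <- function(cc, i, quad_points = .QUAD_POINTS) {
  g <- .gh(quad_points)
  1 - sum(g$weights * stats::pnorm(cc * sqrt(2) + g$nodes)^i)
}

#' Dunnett-type critical value for a shared-control multi-arm comparison
#'
#' Critical value `c` such that `P(max(Z_1, ..., Z_i) > c) = alpha` when
#' the `i` z-statistics compare `i` experimental arms to one shared
#' control with equal allocation (multivariate normal, zero mean, unit
#' variances, pairwise correlation 1/2).  Solved by root-finding on the
#' one-dimensional control-conditioning integral.
#'
#' @param i Number of experimental arms (integer >= 1).
#' @param alpha Family-wise one-sided type-I error rate.
#' @param quad_points Gauss-Hermite node count for the conditioning
#'   integral.
#' @return The critical value on the z scale; for `i = 1` this is
#'   `qnorm(1 - alpha)`.
#' @examples
#' dunnett_c2(1, 0.025)  # 1.95996
#' dunnett_c2(2, 0.025)  # 2.2121
#' @export
dunnett_c2 <- function(i, alpha = 0.025, quad_points = .QUAD_POINTS) {
  stopifnot(is.numeric(i), length(i) == 1L, i >= 1, i == round(i),
            is.numeric(alpha), alpha > 0, alpha < 1)
  if (i == 1) return(stats::qnorm(1 - alpha))
  z1 <- stats::qnorm(1 - alpha)
  stats::uniroot(function(cc) .dunnett_fwer(cc, i, quad_points) - alpha,
                 lower = z1 - 1e-9, upper = z1 + 3 + log(i),
                 tol = 1e-10)$root
}

#' Per-arm sample size of a multi-arm confirmatory trial
#'
#' Smallest per-arm `n2` such that the marginal power of a specific
#' treatment — the probability its own z-statistic exceeds the Dunnett
#' critical value [dunnett_c2()] when its true effect is `delta` and all
#' other experimental effects are zero — equals `1 - beta`.  Because the
#' marginal event involves only that treatment's statistic, the continuous
#' solution is closed-form:
#' \deqn{n_2(i) = 2 (c_2(i) + z_{1-\beta})^2 / \delta^2.}
#' For `i = 1` this reduces to [single_stage_n2()].
#'
#' @inheritParams dunnett_c2
#' @inheritParams single_stage_n2
#' @return Per-arm sample size.
#' @examples
#' multiarm_n2(1, 0.25)  # = single_stage_n2(0.25)
#' multiarm_n2(3, 0.25)
#' @export
multiarm_n2 <- function(i, delta, alpha = 0.025, beta = 0.1,
                        integer = FALSE, quad_points = .QUAD_POINTS) {
  if (!is.numeric(delta) || delta <= 0)
    stop("'delta' must be > 0 (delta = 0 needs an infinite sample size)",
         call. = FALSE)
  c2 <- dunnett_c2(i, alpha, quad_points)
  n2 <- 2 * (c2 + stats::qnorm(1 - beta))^2 / delta^2
  if (integer) ceiling(n2) else n2
}

#' Single-stage multi-arm confirmatory designs for every possible arm count
#'
#' For the all-interesting-treatments rule, the confirmatory trial tests
#' however many arms passed screening; its critical value and per-arm size
#' therefore depend on that count.  This helper tabulates
#' `(c2(i), n2(i))` for `i = 1, ..., K`.
#'
#' @param K Maximum number of arms that could pass screening.
#' @param conf A [confirmatory_spec()].
#' @param integer_n2 Round each `n2(i)` up to a whole patient.
#' @param quad_points Gauss-Hermite node count.
#' @return An object of class `confirmatory_design` with fields
#'   `c2_by_arms` and `n2_by_arms` (vectors indexed by arm count).
#' @examples
#' confirmatory_design(3, confirmatory_spec(rule = "all-interesting"))
#' @export
confirmatory_design <- function(K, conf, integer_n2 = FALSE,
                                quad_points = .QUAD_POINTS) {
  stopifnot(inherits(conf, "confirmatory_spec"), K >= 1)
  c2 <- vapply(seq_len(K), dunnett_c2, numeric(1),
               alpha = conf$alpha, quad_points = quad_points)
  n2 <- 2 * (c2 + stats::qnorm(1 - conf$beta))^2 / conf$delta^2
  if (integer_n2) n2 <- ceiling(n2)
  structure(list(c2_by_arms = c2, n2_by_arms = n2,
                 n2_integer = integer_n2, spec = conf),
            class = "confirmatory_design")
}

#' @export
print.confirmatory_design <- function(x, ...) {
  cat("Single-stage multi-arm confirmatory designs (Dunnett-type FWER control)\n")
  tab <- data.frame(arms = seq_along(x$c2_by_arms),
                    c2 = round(x$c2_by_arms, 4),
                    n2_per_arm = round(x$n2_by_arms, 2))
  print(tab, row.names = FALSE)
  invisible(x)
}
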