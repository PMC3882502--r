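# Group-sequential (triangular-boundary) confirmatory trials and the
# analytic program ESS for top-treatment screening feeding into them.
#
# Stage statistics are handled on the score scale S_j = Z_j * sqrt(j)
# (equal information increments), where the per-stage increments are
# independent N(theta, 1) with drift theta = mu * sqrt(n/2) for per-arm,
# per-stage size n.  Stage-wise stopping probabilities follow from the
# classical density recursion over the continuation regions, evaluated
# with Gauss-Legendre panels.

# z-scale triangular boundaries at information fractions t_j = j/J,
# scaled by the constant C:
#   u_j = C (1 + t_j) / sqrt(t_j),   l_j = -C (1 - 3 t_j) / sqrt(t_j)
# so that l_J = u_J = 2C at the final analysis.
.tri_shape <- function(C, J) {
  t <- seq_len(J) / J
  list(u = C * (1 + t) / sqrt(t), l = -C * (1 - 3 * t) / sqrt(t))
}

# stage-wise efficacy (and, when binding, futility) crossing probabilities.
# u, l: z-scale bounds; theta: per-stage score drift; binding = FALSE drops
# the futility bounds (continuation extends to -Inf, truncated far in the
# lower tail), which is the calibration convention for type-I error and
# power (futility bounds are operational only).
.gs_crossing <- function(u, l, theta, binding = TRUE, grid_points = 160L) {
  J <- length(u)
  U <- u * sqrt(seq_len(J))
  L <- if (binding) l * sqrt(seq_len(J))
       else pmin(seq_len(J) * theta - 8.5 * sqrt(seq_len(J)), U)
  eff <- fut <- numeric(J)
  eff[1] <- 1 - stats::pnorm(U[1] - theta)
  fut[1] <- stats::pnorm(L[1] - theta)
  if (J == 1) return(list(efficacy = eff, futility = fut))
  g <- .gl(grid_points, L[1], U[1])
  s <- g$nodes
  f <- g$weights * stats::dnorm(s - theta)   # weighted continuation subdensity
  for (j in 2:J) {
    eff[j] <- sum(f * (1 - stats::pnorm(U[j] - s - theta)))
    fut[j] <- sum(f * stats::pnorm(L[j] - s - theta))
    if (j < J) {
      g2 <- .gl(grid_points, L[j], U[j])
      f <- g2$weights * as.vector(crossprod(f, outer(s, g2$nodes,
             function(a, b) stats::dnorm(b - a - theta))))
      s <- g2$nodes
    }
  }
  list(efficacy = eff, futility = fut)
}

#' Triangular group-sequential confirmatory design
#'
#' Constructs a `J`-stage confirmatory design with triangular stopping
#' boundaries at equal information increments: on the z scale, with
#' `t_j = j/J`,
#' \deqn{u_j = C(1 + t_j)/\sqrt{t_j}, \qquad l_j = -C(1 - 3 t_j)/\sqrt{t_j},}
#' so the bounds converge to a forced decision (`l_J = u_J`) at the final
#' analysis.  The constant `C` is calibrated by numerical integration so
#' that the probability of ever crossing an efficacy bound under `mu = 0`
#' equals `alpha`, and the per-stage, per-arm sample size so that the same
#' crossing probability at `mu = delta` equals `1 - beta`.  Both
#' calibrations treat the futility bounds as non-binding (crossing
#' probabilities are computed without futility truncation); the futility
#' bounds are then applied operationally when the trial is run, so the
#' attained error rates under futility-stopping — reported in the returned
#' object — are slightly below their nominal targets.
#'
#' @param conf A [confirmatory_spec()]; `J = 1` returns the degenerate
#'   single-stage design with `u_1 = qnorm(1 - alpha)` and
#'   [single_stage_n2()] patients per arm.
#' @param grid_points Gauss-Legendre node count per continuation region.
#' @return An object of class `gs_boundaries`: stages `J`, scale constant
#'   `C`, z-scale `efficacy` and `futility` bounds, `n_per_stage` (per
#'   arm, continuous), `stage_ss` (total patients over both arms if the
#'   trial stops at each stage), and attained operating characteristics.
#' @examples
#' triangular_boundaries(confirmatory_spec(J = 2))
#' @export
triangular_boundaries <- function(conf, grid_points = 160L) {
  stopifnot(inherits(conf, "confirmatory_spec"))
  J <- conf$J
  if (J == 1) {
    u <- stats::qnorm(1 - conf$alpha)
    n <- single_stage_n2(conf$delta, conf$alpha, conf$beta)
    return(structure(list(J = 1L, C = u / 2, efficacy = u, futility = u,
                          n_per_stage = n, stage_ss = 2 * n,
                          alpha_attained = conf$alpha,
                          power_attained = 1 - conf$beta,
                          spec = conf),
                     class = "gs_boundaries"))
  }
  type1 <- function(C) {
    b <- .tri_shape(C, J)
    sum(.gs_crossing(b$u, b$l, 0, binding = FALSE, grid_points)$efficacy)
  }
  C <- stats::uniroot(function(C) type1(C) - conf$alpha,
                      lower = 0.3, upper = 3, tol = 1e-10)$root
  b <- .tri_shape(C, J)
  pw <- function(n) sum(.gs_crossing(b$u, b$l, conf$delta * sqrt(n / 2),
                                     binding = FALSE, grid_points)$efficacy)
  n_single <- single_stage_n2(conf$delta, conf$alpha, conf$beta)
  n <- stats::uniroot(function(n) pw(n) - (1 - conf$beta),
                      lower = 1e-2, upper = 4 * n_single, tol = 1e-8)$root
  bind0 <- .gs_crossing(b$u, b$l, 0, binding = TRUE, grid_points)
  bindd <- .gs_crossing(b$u, b$l, conf$delta * sqrt(n / 2),
                        binding = TRUE, grid_points)
  structure(list(J = J, C = C, efficacy = b$u, futility = b$l,
                 n_per_stage = n, stage_ss = 2 * seq_len(J) * n,
                 alpha_attained = sum(bind0$efficacy),
                 power_attained = sum(bindd$efficacy),
                 spec = conf),
            class = "gs_boundaries")
}

#' @export
print.gs_boundaries <- function(x, ...) {
  cat(sprintf("Triangular group-sequential design, J = %d stage(s)\n", x$J))
  tab <- data.frame(stage = seq_len(x$J),
                    futility = round(x$futility, 4),
                    efficacy = round(x$efficacy, 4),
                    total_ss = round(x$stage_ss, 1))
  print(tab, row.names = FALSE)
  cat(sprintf("per-arm patients per stage: %.2f\n", x$n_per_stage))
  cat(sprintf("attained (with futility stopping): type-I %.5f, power %.5f\n",
              x$alpha_attained, x$power_attained))
  invisible(x)
}

#' Stage-wise stopping probabilities of a group-sequential trial
#'
#' Probabilities of stopping for efficacy and for futility at each
#' analysis, for a true standardized effect `mu`, with the futility bounds
#' applied (the trial as actually run).  The probabilities sum to one.
#'
#' @param b A [triangular_boundaries()] design.
#' @param mu Standardized treatment effect.
#' @param grid_points Gauss-Legendre node count.
#' @return A list with per-stage vectors `efficacy` and `futility`.
#' @export
stopping_probabilities <- function(b, mu, grid_points = 160L) {
  stopifnot(inherits(b, "gs_boundaries"))
  theta <- mu * sqrt(b$n_per_stage / 2)
  .gs_crossing(b$efficacy, b$futility, theta, binding = TRUE, grid_points)
}

#' Expected confirmatory-trial sample size at a given effect
#'
#' \eqn{\sum_j N^*(j) P(\text{stop at } j \mid \mu)}, where `N*(j)` counts
#' patients on both arms if the trial stops at analysis `j`.  Restricting
#' `outcome` gives the joint expectation over stopping with that outcome
#' (not conditional on it).
#'
#' @inheritParams stopping_probabilities
#' @param outcome `"any"`, `"success"` (efficacy stops only) or
#'   `"failure"` (futility stops only).
#' @return Expected patients (both arms).
#' @export
expected_confirmatory_ss <- function(b, mu, outcome = c("any", "success", "failure"),
                                     grid_points = 160L) {
  outcome <- match.arg(outcome)
  sp <- stopping_probabilities(b, mu, grid_points)
  w <- switch(outcome,
              any     = sp$efficacy + sp$futility,
              success = sp$efficacy,
              failure = sp$futility)
  sum(b$stage_ss * w)
}

#' ESS until phase III success: top-treatment rule, group-sequential phase III
#'
#' Program-level expected sample size when the selected treatment enters a
#' `J`-stage triangular group-sequential confirmatory trial.  Writing
#' \eqn{\psi} for the selected treatment (0 = none) and \eqn{\chi} for the
#' confirmatory outcome, the renewal identity gives
#' \deqn{ESS = \frac{(K+1) n_1 + E(N; \psi \ne 0, \chi = 0) + E(N; \psi \ne 0, \chi = 1)}
#'                  {P(\psi \ne 0, \chi = 1)},}
#' where `N` is the realized confirmatory sample size.  Exchangeability
#' reduces each term to a two-dimensional integral over the selected
#' treatment's screening sample mean and its true effect, weighting the
#' selection kernel by the stage-wise stopping probabilities.
#'
#' @inheritParams prob_success_one
#' @param boundaries Optional precomputed [triangular_boundaries()] for
#'   `conf`.
#' @param grid_points Gauss-Legendre node count for the stage recursion.
#' @return A `program_result`; `diagnostics` carries the boundary object
#'   and the numerator decomposition.
#' @examples
#' ess_top_groupseq(screening_design(8, 14, -0.334), prior_spec(0, 0.1),
#'                  confirmatory_spec(J = 2))
#' @export
ess_top_groupseq <- function(design, prior, conf = confirmatory_spec(J = 2),
                             boundaries = NULL, quad_points = .QUAD_POINTS,
                             grid_points = 160L) {
  stopifnot(inherits(design, "screening_design"), inherits(prior, "prior_spec"),
            inherits(conf, "confirmatory_spec"))
  if (conf$rule != "top-treatment")
    stop("'conf$rule' must be \"top-treatment\"", call. = FALSE)
  if (is.null(boundaries)) boundaries <- triangular_boundaries(conf, grid_points)
  g <- .gh(quad_points)
  if (prior$v0 > 0) {
    mu <- prior$m0 + prior$v0 * g$nodes; wm <- g$weights
  } else {
    mu <- prior$m0; wm <- 1
  }
  # effect-dependent confirmatory quantities (independent of n1, c1)
  en_succ <- en_fail <- p_eff <- numeric(length(mu))
  for (i in seq_along(mu)) {
    sp <- stopping_probabilities(boundaries, mu[i], grid_points)
    p_eff[i] <- sum(sp$efficacy)
    en_succ[i] <- sum(boundaries$stage_ss * sp$efficacy)
    en_fail[i] <- sum(boundaries$stage_ss * sp$futility)
  }
  # selection kernel integrated over the treatment's sample mean given mu
  X <- outer(mu, sqrt(1 / design$n1) * g$nodes, "+")
  S <- .selection_kernel(X, design$K, design$n1, design$c1, prior$m0, prior$v0)
  sel <- as.vector(S %*% g$weights)
  K <- design$K
  p1 <- K * sum(wm * sel)                    # P(psi != 0)
  p2 <- K * sum(wm * sel * p_eff)            # P(psi != 0, chi = 1)
  n_succ <- K * sum(wm * sel * en_succ)      # E(N; psi != 0, chi = 1)
  n_fail <- K * sum(wm * sel * en_fail)      # E(N; psi != 0, chi = 0)
  ess <- if (p2 > 0) ((K + 1) * design$n1 + n_fail + n_succ) / p2 else Inf
  program_result(
    ess = ess, p_conduct = p1, p_success = p2,
    fwer = screening_fwer(design, quad_points),
    power = screening_power(design, conf$delta, quad_points),
    diagnostics = list(boundaries = boundaries,
                       e_n_success = n_succ, e_n_failure = n_fail))
}
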