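#' Exchangeable normal prior on standardized treatment effects
#'
#' Candidate treatments are assumed to carry independent, identically
#' distributed true standardized effects \eqn{\mu_i \sim N(m_0, v_0^2)},
#' with the control effect fixed at zero.  All responses are standardized
#' to unit within-arm standard deviation, so `m0` and `v0` are in
#' effect-size units.
#'
#' @param m0 Prior mean of a treatment's standardized effect.
#' @param v0 Prior standard deviation (>= 0; `v0 = 0` gives the degenerate
#'   prior in which every treatment has effect exactly `m0`).
#' @return An object of class `prior_spec`.
#' @examples
#' prior_spec(0, 0.1)
#' @export
prior_spec <- function(m0, v0) {
  stopifnot(is.numeric(m0), length(m0) == 1L, is.finite(m0),
            is.numeric(v0), length(v0) == 1L, is.finite(v0))
  if (v0 < 0) stop("'v0' must be >= 0", call. = FALSE)
  structure(list(m0 = m0, v0 = v0), class = "prior_spec")
}

#' Screening-trial design point
#'
#' A screening trial allocates `n1` patients to each of `K` experimental
#' arms and to a shared control arm.  For each arm the variance-standardized
#' statistic \eqn{Z_i = (\bar X_i - \bar X_0)\sqrt{n_1/2}} is compared with
#' the progression threshold `c1`.
#'
#' @param K Number of experimental arms (integer >= 1).
#' @param n1 Patients per arm (>= 1; may be non-integer during
#'   optimization).
#' @param c1 Progression threshold on the z scale (may be negative;
#'   `-Inf`/`Inf` are allowed for limiting cases).
#' @return An object of class `screening_design`.
#' @examples
#' screening_design(K = 9, n1 = 22, c1 = -0.429)
#' @export
screening_design <- function(K, n1, c1) {
  stopifnot(is.numeric(K), length(K) == 1L, is.finite(K),
            is.numeric(n1), length(n1) == 1L, is.finite(n1),
            is.numeric(c1), length(c1) == 1L, !is.na(c1))
  if (K < 1 || K != round(K)) stop("'K' must be an integer >= 1", call. = FALSE)
  if (n1 < 1) stop("'n1' must be >= 1", call. = FALSE)
  structure(list(K = as.integer(K), n1 = n1, c1 = c1),
            class = "screening_design")
}

#' Confirmatory-trial requirements
#'
#' The confirmatory (phase III) trial is sized before the program starts:
#' one-sided type-I error `alpha` (family-wise when several arms are
#' tested), power `1 - beta` at the standardized clinically relevant
#' difference `delta`, with `J` analysis stages and a progression `rule`
#' linking it to the screening trial.
#'
#' @param delta Standardized clinically relevant difference (> 0).
#' @param alpha One-sided (family-wise) type-I error rate, in (0, 0.5).
#' @param beta One minus power, in (0, 0.5).
#' @param J Number of stages (1 = fixed-sample trial).
#' @param rule Progression rule: `"top-treatment"` (only the best screening
#'   arm may proceed) or `"all-interesting"` (every arm above the threshold
#'   proceeds to one multi-arm confirmatory trial).
#' @return An object of class `confirmatory_spec`.
#' @examples
#' confirmatory_spec()  # delta 0.25, alpha 0.025, power 0.9, single stage
#' @export
confirmatory_spec <- function(delta = 0.25, alpha = 0.025, beta = 0.1,
                              J = 1L, rule = c("top-treatment", "all-interesting")) {
  rule <- match.arg(rule)
  stopifnot(is.numeric(delta), length(delta) == 1L,
            is.numeric(alpha), length(alpha) == 1L,
            is.numeric(beta), length(beta) == 1L,
            is.numeric(J), length(J) == 1L)
  if (!(alpha > 0 && alpha < 0.5)) stop("'alpha' must be in (0, 0.5)", call. = FALSE)
  if (!(beta > 0 && beta < 0.5)) stop("'beta' must be in (0, 0.5)", call. = FALSE)
  if (!(delta > 0)) stop("'delta' must be > 0", call. = FALSE)
  if (J < 1 || J != round(J)) stop("'J' must be an integer >= 1", call. = FALSE)
  structure(list(delta = delta, alpha = alpha, beta = beta,
                 J = as.integer(J), rule = rule),
            class = "confirmatory_spec")
}

# internal constructor for the per-design-point summary returned by the
# ess_* functions
program_result <- function(ess, p_conduct, p_success, fwer = NA_real_,
                           power = NA_real_, diagnostics = list()) {
  structure(list(ess = ess, p_conduct = p_conduct, p_success = p_success,
                 fwer = fwer, power = power, diagnostics = diagnostics),
            class = "program_result")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat(sprintf("Treatment-effect prior: N(m0 = %g, v0^2 = %g^2)\n", x$m0, x$v0))
  invisible(x)
}

#' @export
print.screening_design <- function(x, ...) {
  cat(sprintf("Screening design: K = %d arms, n1 = %g per arm, c1 = %g\n",
              x$K, x$n1, x$c1))
  invisible(x)
}

#' @export
print.confirmatory_spec <- function(x, ...) {
  cat(sprintf(
    "Confirmatory spec: delta = %g, one-sided alpha = %g, power = %g, J = %d, rule = %s\n",
    x$delta, x$alpha, 1 - x$beta, x$J, x$rule))
  invisible(x)
}

#' @export
print.program_result <- function(x, ...) {
  cat("Program operating characteristics\n")
  cat(sprintf("  ESS until phase III success : %.1f patients\n", x$ess))
  cat(sprintf("  P(confirmatory trial/cycle) : %.4f\n", x$p_conduct))
  cat(sprintf("  P(phase III success/cycle)  : %.4f\n", x$p_success))
  if (!is.na(x$fwer))
    cat(sprintf("  Screening family-wise error : %.4f\n", x$fwer))
  if (!is.na(x$power))
    cat(sprintf("  Screening power             : %.4f\n", x$power))
  invisible(x)
}
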