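# Screening-design optimization: Nelder-Mead over (n1, c1) for each K,
# integer refinement of n1, and a scan over K.
#
# The search works in transformed coordinates (n1 = 1 + exp(a), c1 free)
# so the n1 >= 1 bound needs no penalty and the objective stays smooth.

.design_family <- function(conf) {
  if (conf$rule == "top-treatment") {
    if (conf$J == 1) "top-single" else "top-gs"
  } else {
    if (conf$J == 1) "all-single" else "all-mams"
  }
}

# fast ESS-only evaluators, with everything that does not depend on
# (n1, c1) precomputed once per (K, prior, conf)
.make_objective <- function(K, prior, conf, opts = list()) {
  qp <- opts$quad_points %||% .QUAD_POINTS
  family <- .design_family(conf)
  g <- .gh(qp)
  m0 <- prior$m0; v0 <- prior$v0
  if (family == "top-single") {
    n2 <- single_stage_n2(conf$delta, conf$alpha, conf$beta)
    za <- stats::qnorm(1 - conf$alpha)
    if (v0 > 0) { mu <- m0 + v0 * g$nodes; wm <- g$weights } else { mu <- m0; wm <- 1 }
    pow <- stats::pnorm(mu * sqrt(n2 / 2) - za)
    fn <- function(n1, c1) {
      sd_m <- sqrt(v0^2 + 1 / n1)
      x <- m0 + sd_m * g$nodes
      p1 <- K * sum(g$weights * .selection_kernel(x, K, n1, c1, m0, v0))
      X <- outer(mu, sqrt(1 / n1) * g$nodes, "+")
      sel <- as.vector(.selection_kernel(X, K, n1, c1, m0, v0) %*% g$weights)
      p2 <- K * sum(wm * pow * sel)
      if (p2 <= 0) return(Inf)
      ((K + 1) * n1 + 2 * n2 * p1) / p2
    }
    post <- function(n1, c1)
      ess_top_single(screening_design(K, n1, c1), prior, conf, quad_points = qp)
  } else if (family == "all-single") {
    cdesign <- confirmatory_design(K, conf, quad_points = qp)
    fn <- function(n1, c1) {
      d <- screening_design(K, n1, c1)
      sub <- subset_pass_distribution(d, prior, qp)$p_by_count
      pno <- prob_cycle_no_success(d, prior, conf, cdesign, qp)
      if (pno >= 1) return(Inf)
      ss <- (K + 1) * n1 + (0:K + 1) * c(0, cdesign$n2_by_arms)
      sum(sub * ss) / (1 - pno)
    }
    post <- function(n1, c1)
      ess_all_interesting(screening_design(K, n1, c1), prior, conf,
                          quad_points = qp)
  } else if (family == "top-gs") {
    boundaries <- opts$boundaries %||% triangular_boundaries(conf)
    if (v0 > 0) { mu <- m0 + v0 * g$nodes; wm <- g$weights } else { mu <- m0; wm <- 1 }
    p_eff <- en_tot <- numeric(length(mu))
    for (i in seq_along(mu)) {
      sp <- stopping_probabilities(boundaries, mu[i])
      p_eff[i] <- sum(sp$efficacy)
      en_tot[i] <- sum(boundaries$stage_ss * (sp$efficacy + sp$futility))
    }
    fn <- function(n1, c1) {
      X <- outer(mu, sqrt(1 / n1) * g$nodes, "+")
      sel <- as.vector(.selection_kernel(X, K, n1, c1, m0, v0) %*% g$weights)
      p2 <- K * sum(wm * sel * p_eff)
      if (p2 <= 0) return(Inf)
      ((K + 1) * n1 + K * sum(wm * sel * en_tot)) / p2
    }
    post <- function(n1, c1)
      ess_top_groupseq(screening_design(K, n1, c1), prior, conf,
                       boundaries = boundaries, quad_points = qp)
  } else { # all-mams: simulation-backed objective on a shared bank (CRN)
    bank <- opts$bank
    if (is.null(bank))
      bank <- build_bank(K, prior, n_reps = opts$n_reps %||% 100000L,
                         seed = opts$seed %||% 1L, J_max = conf$J)
    fn <- function(n1, c1)
      ess_mams(screening_design(K, n1, c1), prior, conf, bank)$ess
    post <- function(n1, c1)
      ess_mams(screening_design(K, n1, c1), prior, conf, bank)
  }
  list(fn = fn, post = post, family = family)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Optimize a screening design for fixed K
#'
#' Minimizes the program ESS over the per-arm screening size `n1` and the
#' progression threshold `c1` for a fixed number of arms `K`: Nelder-Mead
#' search in transformed coordinates (continuous `n1`), followed by
#' one-dimensional re-optimization of `c1` at the floor and ceiling
#' integers of the continuous optimum, returning the better integer
#' design.
#'
#' @param K Number of screening arms.
#' @param prior A [prior_spec()].
#' @param conf A [confirmatory_spec()]; the design family follows from its
#'   `rule` and `J`.
#' @param opts List of options: `start` (c(n1, c1), default c(20, 0.5)),
#'   `restarts` (extra perturbed starts, default 2), `maxit`, `reltol`,
#'   `quad_points`, and for the simulation-backed family `bank` /
#'   `n_reps` / `seed`.
#' @return An object of class `design_optimum`: `K`, integer `n1`,
#'   re-optimized `c1`, `ess`, the continuous-stage solution, the full
#'   `program_result`, and the evaluation trace.
#' @examples
#' \donttest{
#' optimize_design(9, prior_spec(0, 0.1), confirmatory_spec())
#' }
#' @export
optimize_design <- function(K, prior, conf = confirmatory_spec(), opts = list()) {
  obj <- .make_objective(K, prior, conf, opts)
  trace_env <- new.env(parent = emptyenv())
  trace_env$rows <- list()
  fn_t <- function(par) {
    n1 <- 1 + exp(par[1]); c1 <- par[2]
    v <- obj$fn(n1, c1)
    trace_env$rows[[length(trace_env$rows) + 1L]] <- c(n1, c1, v)
    v
  }
  start <- opts$start %||% c(20, 0.5)
  starts <- list(start,
                 c(max(start[1] / 2, 2), start[2] - 1),
                 c(start[1] * 1.5, start[2] + 0.75))
  starts <- starts[seq_len(1 + (opts$restarts %||% 2L))]
  best <- NULL
  for (s in starts) {
    fit <- stats::optim(c(log(s[1] - 1), s[2]), fn_t, method = "Nelder-Mead",
                        control = list(maxit = opts$maxit %||% 500L,
                                       reltol = opts$reltol %||% 1e-10))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  n1_cont <- 1 + exp(best$par[1]); c1_cont <- best$par[2]
  # integer refinement: re-optimize c1 at the neighboring integers of n1
  cand <- unique(pmax(c(floor(n1_cont), ceiling(n1_cont)), 1))
  ref <- lapply(cand, function(n1i) {
    o <- stats::optimize(function(c1) obj$fn(n1i, c1),
                         interval = c1_cont + c(-1, 1), tol = 1e-7)
    list(n1 = n1i, c1 = o$minimum, ess = o$objective)
  })
  pick <- ref[[which.min(vapply(ref, `[[`, numeric(1), "ess"))]]
  res <- obj$post(pick$n1, pick$c1)
  trace <- do.call(rbind, trace_env$rows)
  colnames(trace) <- c("n1", "c1", "ess")
  structure(list(K = K, n1 = pick$n1, c1 = pick$c1, ess = pick$ess,
                 n1_continuous = n1_cont, c1_continuous = c1_cont,
                 ess_continuous = best$value, result = res,
                 family = obj$family, trace = trace),
            class = "design_optimum")
}

#' @export
print.design_optimum <- function(x, ...) {
  cat(sprintf("Optimal %s screening design at K = %d:\n", x$family, x$K))
  cat(sprintf("  n1 = %d, c1 = %.3f, ESS = %.1f\n", x$n1, x$c1, x$ess))
  invisible(x)
}

#' Scan the number of screening arms
#'
#' Runs [optimize_design()] for each `K` in `K_range` and tabulates the
#' optimal designs; the row minimizing ESS is marked as the overall
#' optimum.
#'
#' @param K_range Integer vector of arm counts to scan.
#' @inheritParams optimize_design
#' @return An object of class `scan_result`: a data frame `per_K` with
#'   columns `K`, `n1`, `c1`, `ess`, `fwer`, `power`, the `best` row, and
#'   the per-K `design_optimum` objects in `fits`.
#' @examples
#' \donttest{
#' scan_K(8:10, prior_spec(0, 0.1), confirmatory_spec())
#' }
#' @export
scan_K <- function(K_range, prior, conf = confirmatory_spec(), opts = list()) {
  stopifnot(length(K_range) >= 1, all(K_range >= 1))
  fits <- lapply(K_range, function(K) optimize_design(K, prior, conf, opts))
  per_K <- data.frame(
    K = K_range,
    n1 = vapply(fits, `[[`, numeric(1), "n1"),
    c1 = vapply(fits, `[[`, numeric(1), "c1"),
    ess = vapply(fits, `[[`, numeric(1), "ess"),
    fwer = vapply(fits, function(f) f$result$fwer %||% NA_real_, numeric(1)),
    power = vapply(fits, function(f) f$result$power %||% NA_real_, numeric(1)))
  structure(list(per_K = per_K, best = per_K[which.min(per_K$ess), ],
                 fits = fits, family = fits[[1]]$family),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("Optimal %s screening designs by number of arms\n", x$family))
  tab <- x$per_K
  tab$c1 <- round(tab$c1, 3); tab$ess <- round(tab$ess, 1)
  tab$fwer <- round(tab$fwer, 3); tab$power <- round(tab$power, 3)
  print(tab, row.names = FALSE)
  cat(sprintf("Overall optimum: K = %d (ESS = %.1f)\n", x$best$K, x$best$ess))
  invisible(x)
}

#' ESS cost of pinning a design parameter
#'
#' Evaluates the percentage ESS increase when `c1` (and/or `n1`) is pinned
#' to a chosen value while the remaining parameters stay at their optimal
#' values — e.g. the cost of insisting on `c1 = 0` (never progress a
#' treatment that looks worse than control).
#'
#' @inheritParams optimize_design
#' @param c1,n1 Values to pin; `NULL` leaves the parameter at its optimum.
#' @param optimum Optional precomputed [optimize_design()] result.
#' @return A list: `pct_increase`, `ess_pinned`, `ess_optimal`, and the
#'   pinned design point.
#' @examples
#' \donttest{
#' sensitivity_at(9, prior_spec(0, 0.1), confirmatory_spec(), c1 = 0)
#' }
#' @export
sensitivity_at <- function(K, prior, conf = confirmatory_spec(),
                           c1 = NULL, n1 = NULL, optimum = NULL, opts = list()) {
  if (is.null(optimum)) optimum <- optimize_design(K, prior, conf, opts)
  obj <- .make_objective(K, prior, conf, opts)
  n1_use <- n1 %||% optimum$n1
  c1_use <- c1 %||% optimum$c1
  ess_pinned <- obj$fn(n1_use, c1_use)
  list(pct_increase = 100 * (ess_pinned / optimum$ess - 1),
       ess_pinned = ess_pinned, ess_optimal = optimum$ess,
       n1 = n1_use, c1 = c1_use, optimum = optimum)
}
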