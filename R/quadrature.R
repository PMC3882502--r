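# Quadrature helpers shared by the analytic modules.
#
# All prior-predictive quantities in this package are expectations of smooth
# functions against normal densities, so Gauss-Hermite rules (in the
# probabilists' normalization returned by statmod) converge essentially to
# machine precision at <= 100 nodes.  Rules are cached per node count.

.quad_cache <- new.env(parent = emptyenv())

# standard-normal Gauss-Hermite nodes/weights
.gh <- function(n) {
  key <- paste0("gh", n)
  if (is.null(.quad_cache[[key]]))
    .quad_cache[[key]] <- statmod::gauss.quad.prob(n, dist = "normal")
  .quad_cache[[key]]
}

# Gauss-Legendre rule rescaled to [a, b]
.gl <- function(n, a, b) {
  key <- paste0("gl", n)
  if (is.null(.quad_cache[[key]]))
    .quad_cache[[key]] <- statmod::gauss.quad(n, kind = "legendre")
  g <- .quad_cache[[key]]
  list(nodes   = (a + b) / 2 + (b - a) / 2 * g$nodes,
       weights = (b - a) / 2 * g$weights)
}

# default node count; enough for the 3-4 significant figures the design
# tables are quoted to, with a wide safety margin (checked against
# Monte-Carlo oracles in the test suite)
.QUAD_POINTS <- 96L
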