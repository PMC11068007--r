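# Fixture builders used across the suite; everything is generated in code.

# Erdos-Renyi signed graph as a raw edge table (may be disconnected;
# as_signed_graph() keeps the largest component)
rand_signed_edges <- function(n, p, neg_prob = 0.4) {
  pairs <- t(utils::combn(n, 2)) - 1L
  keep <- stats::runif(nrow(pairs)) < p
  data.frame(
    from = pairs[keep, 1],
    to = pairs[keep, 2],
    sign = ifelse(stats::runif(sum(keep)) < neg_prob, -1L, 1L)
  )
}

rand_signed_graph <- function(n, p, neg_prob = 0.4) {
  as_signed_graph(rand_signed_edges(n, p, neg_prob))
}

# a single triangle with the given signs on edges (01, 02, 12)
triangle_graph <- function(signs) {
  as_signed_graph(data.frame(from = c(0, 0, 1), to = c(1, 2, 2),
                             sign = as.integer(signs)))
}

# complete graph on n nodes, all positive unless signs given
complete_graph <- function(n, signs = 1L) {
  pairs <- t(utils::combn(n, 2)) - 1L
  as_signed_graph(data.frame(from = pairs[, 1], to = pairs[, 2],
                             sign = as.integer(signs)))
}

unsigned_degrees <- function(g) {
  sort(tabulate(c(g$edges$from, g$edges$to) + 1L, nbins = g$n_nodes))
}
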