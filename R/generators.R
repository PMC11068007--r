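#' Power-law degree sequence
#'
#' Draws `n` i.i.d. integer degrees with `P(k) ~ k^-gamma` on
#' `[k_min, k_max]` by inverse-CDF sampling of the continuous truncated
#' power law, floored to integers. The default upper cutoff is the natural
#' cutoff `n^(1/(gamma-1))`. If the sum is odd one entry is incremented so
#' the sequence can be wired by stub matching.
#'
#' @param n Sequence length.
#' @param gamma Exponent (> 1).
#' @param k_min,k_max Support bounds, `1 <= k_min <= k_max`.
#' @return An integer vector of length `n` with an even sum.
#' @export
power_law_degree_sequence <- function(n, gamma, k_min = 1L, k_max = NULL) {
  stopifnot(gamma > 1, k_min >= 1)
  if (is.null(k_max)) k_max <- max(k_min, floor(n^(1 / (gamma - 1))))
  if (k_max < k_min) stop("k_max must be >= k_min")
  a <- gamma - 1
  u <- runif(n)
  lo <- k_min^(-a)
  hi <- (k_max + 1)^(-a)
  k <- pmin(as.integer(floor((lo - u * (lo - hi))^(-1 / a))), as.integer(k_max))
  if (sum(k) %% 2 == 1) {
    i <- sample.int(n, 1)
    k[i] <- k[i] + 1L
  }
  k
}

#' Co-sort two degree sequences with partial exchange
#'
#' Arranges both sequences in ascending order, then walks the first
#' sequence and, independently with probability `exchange_prob` per
#' position, swaps that entry with a uniformly random position of the same
#' sequence. The multisets of both sequences are preserved; the exchange
#' dials the rank correlation down from its co-sorted maximum.
#'
#' @param a,b Numeric vectors of equal length (positive and negative target
#'   degrees).
#' @param exchange_prob Per-position exchange probability.
#' @return A tibble with columns `k_pos` (exchanged `a`) and `k_neg`
#'   (sorted `b`).
#' @export
correlate_sorted_sequences <- function(a, b, exchange_prob = 0.2) {
  stopifnot(length(a) == length(b), exchange_prob >= 0, exchange_prob <= 1)
  n <- length(a)
  a <- sort(a)
  b <- sort(b)
  do_swap <- runif(n) < exchange_prob
  partner <- sample.int(n, n, replace = TRUE)
  for (i in which(do_swap)) {
    j <- partner[i]
    tmp <- a[i]; a[i] <- a[j]; a[j] <- tmp
  }
  tibble::tibble(k_pos = a, k_neg = b)
}

#' Strongly balanced reference network
#'
#' Builds a two-group signed configuration model that is strongly balanced
#' by construction (Harary bipartition): nodes are split into two equal
#' groups; positive target degrees follow a power law with exponent
#' `gamma_pos`, negative target degrees one with exponent `gamma_neg`; the
#' two sequences are co-sorted and partially exchanged (see
#' [correlate_sorted_sequences()]) to induce a moderate positive-negative
#' degree correlation, then assigned to nodes in a random order. Positive
#' stubs are matched uniformly *within* each group and negative stubs
#' *across* the two groups; self-loops and duplicate pairings are discarded
#' (erased configuration model) and the result is preprocessed (largest
#' component, compacted ids). Every cycle therefore has an even number of
#' negative edges.
#'
#' Per-group positive stub counts are made even by dropping one random
#' stub, and the two cross-group negative stub lists are truncated to the
#' shorter one; with heavy-tailed sequences the realized degrees fall
#' slightly below the targets, as with any erased configuration model.
#'
#' @param n_nodes Total number of nodes (even).
#' @param gamma_pos,gamma_neg Power-law exponents of the positive/negative
#'   target degree sequences.
#' @param exchange_prob Per-position exchange probability of the co-sort.
#' @param k_min,k_max_pos,k_max_neg Degree-sequence support (defaults: 1 and
#'   the natural cutoffs).
#' @return A preprocessed `signed_graph`; the target degree tibble is
#'   attached as attribute `"target_degrees"`.
#' @examples
#' set.seed(1)
#' g <- generate_sb_reference(400)
#' all(census_graphlets(g)$count[!pattern_catalog()$balanced] == 0)
#' @export
generate_sb_reference <- function(n_nodes = 120000L, gamma_pos = 2,
                                  gamma_neg = 3, exchange_prob = 0.2,
                                  k_min = 1L, k_max_pos = NULL,
                                  k_max_neg = NULL) {
  stopifnot(n_nodes >= 4L, n_nodes %% 2 == 0)
  kp <- power_law_degree_sequence(n_nodes, gamma_pos, k_min, k_max_pos)
  kn <- power_law_degree_sequence(n_nodes, gamma_neg, k_min, k_max_neg)
  seqs <- correlate_sorted_sequences(kp, kn, exchange_prob)
  perm <- sample.int(n_nodes)
  k_pos <- seqs$k_pos[perm]
  k_neg <- seqs$k_neg[perm]
  group <- rep(c(1L, 2L), each = n_nodes / 2)

  pos_edges <- lapply(1:2, function(gr) {
    idx <- which(group == gr)
    stubs <- rep(idx, k_pos[idx])
    if (length(stubs) %% 2 == 1) stubs <- stubs[-sample.int(length(stubs), 1)]
    if (length(stubs) < 2) return(NULL)
    matrix(sample(stubs), ncol = 2)
  })
  pos <- do.call(rbind, pos_edges)

  s1 <- rep(which(group == 1L), k_neg[group == 1L])
  s2 <- rep(which(group == 2L), k_neg[group == 2L])
  m <- min(length(s1), length(s2))
  if (m == 0L) stop("no negative stubs on one side; increase n_nodes")
  neg <- cbind(sample(s1)[seq_len(m)], sample(s2)[seq_len(m)])

  records <- rbind(
    if (!is.null(pos)) cbind(pos, 1L),
    cbind(neg, -1L)
  )
  g <- as_signed_graph(data.frame(from = records[, 1] - 1L,
                                  to = records[, 2] - 1L,
                                  sign = records[, 3]))
  attr(g, "target_degrees") <- seqs
  g
}

#' Edge-copying reference network
#'
#' Grows a signed network by edge copying from an all-positive triangle:
#' each new node picks an existing node uniformly at random, attaches to it
#' with a positive sign with probability `q` (negative otherwise), and
#' independently copies each edge of the chosen node with probability
#' `p_copy`, keeping the copied sign when the attachment is positive and
#' reversing it when negative. This local rule preserves a two-camp
#' structure exactly, so the grown network contains no unbalanced cycle of
#' any length.
#'
#' @param n_nodes Final number of nodes (>= 3); `n_nodes = 3` returns the
#'   seed triangle.
#' @param q Probability that the attachment edge is positive.
#' @param p_copy Per-neighbour copy probability.
#' @return A preprocessed `signed_graph` (connected by construction).
#' @examples
#' set.seed(1)
#' g <- generate_ec_reference(500)
#' is_balanced(g)
#' @export
generate_ec_reference <- function(n_nodes = 120000L, q = 0.9, p_copy = 0.45) {
  stopifnot(n_nodes >= 3L, q >= 0, q <= 1, p_copy >= 0, p_copy <= 1)
  res <- cpp_ec_generate(as.integer(n_nodes), q, p_copy)
  edges <- tibble::tibble(from = res$edges[, 1], to = res$edges[, 2],
                          sign = res$signs)
  new_signed_graph(dplyr::arrange(edges, .data$from, .data$to),
                   n_nodes)
}

#' Degrade balance by random rewiring
#'
#' Applies degree-preserving edge swaps ([rewire()]) with
#' `swap_fraction * E` attempts, leaving signs on the edges. On a balanced
#' network this progressively destroys the camp structure, so unbalanced
#' pattern counts grow (in expectation) with `swap_fraction`; the degree
#' sequence is conserved for any fraction.
#'
#' @param g A `signed_graph` (or coercible edge table).
#' @param swap_fraction Swap attempts as a fraction of the edge count
#'   (0 leaves the graph untouched).
#' @return A `signed_graph`.
#' @export
degrade_balance <- function(g, swap_fraction) {
  stopifnot(swap_fraction >= 0)
  rewire(g, attempts_per_edge = swap_fraction)
}
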