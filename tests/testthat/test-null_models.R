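test_that("rewire conserves degrees and sign totals; no valid swap leaves a triangle fixed", {
  set.seed(301)
  g <- rand_signed_graph(30, 0.2)
  r <- rewire(g)
  expect_equal(unsigned_degrees(r), unsigned_degrees(g))
  expect_equal(sum(r$edges$sign < 0), sum(g$edges$sign < 0))
  # all proposed swaps on a triangle abort (only 3 nodes)
  tri <- triangle_graph(c(1, 1, -1))
  r2 <- rewire(tri, attempts_per_edge = 100)
  expect_equal(r2$edges, tri$edges)
  expect_equal(attr(r2, "swaps_performed"), 0)
})

test_that("signed rewire conserves the signed degree vector exactly", {
  set.seed(302)
  for (rep in 1:5) {
    g <- rand_signed_graph(30, 0.2)
    r <- signed_rewire(g)
    expect_equal(signed_degrees(r)$k_pos, signed_degrees(g)$k_pos)
    expect_equal(signed_degrees(r)$k_neg, signed_degrees(g)$k_neg)
    # simple graph: no duplicated pairs (hence no contradictory signs)
    expect_false(any(duplicated(r$edges[, c("from", "to")])))
  }
  # lone negative edge has no swap partner: negative subgraph unchanged
  g <- as_signed_graph(data.frame(from = c(0, 1, 2, 3), to = c(1, 2, 3, 0),
                                  sign = c(-1, 1, 1, 1)))
  r <- signed_rewire(g, attempts_per_edge = 100)
  neg0 <- g$edges[g$edges$sign < 0, c("from", "to")]
  neg1 <- r$edges[r$edges$sign < 0, c("from", "to")]
  expect_equal(neg1, neg0)
})

test_that("sign shuffle permutes signs on a fixed topology", {
  set.seed(303)
  g <- rand_signed_graph(25, 0.25)
  s <- sign_shuffle(g)
  expect_equal(s$edges[, c("from", "to")], g$edges[, c("from", "to")])
  expect_equal(sum(s$edges$sign < 0), sum(g$edges$sign < 0))
  allpos <- complete_graph(5)
  expect_equal(sign_shuffle(allpos)$edges, allpos$edges)
})

test_that("STP fit handles degenerate structures by clamping", {
  # all-positive graph: every p_neg is 0
  f <- fit_stp(complete_graph(4))
  expect_equal(f$p_neg, rep(0, 6))
  # a single negative edge: constraint forces p_neg = 1
  f2 <- fit_stp(as_signed_graph(data.frame(from = 0, to = 1, sign = -1)))
  expect_equal(f2$p_neg, 1)
  # triangle AB-, BC+, AC+: C forces its edges to 0, then A and B force AB to 1
  f3 <- fit_stp(as_signed_graph(data.frame(from = c(0, 1, 0), to = c(1, 2, 2),
                                           sign = c(-1, 1, 1))))
  expect_equal(f3$p_neg, c(1, 0, 0))  # edges (01, 02, 12)
  expect_equal(unname(f3$residual), rep(0, 3))
})

test_that("STP fixed point matches a scalar bisection solve on a symmetric graph", {
  # K5 with a negative Hamiltonian cycle: every node has degree 4, k_neg 2;
  # by symmetry alpha is constant and solves c*(alpha^2+1) = k
  pairs <- t(utils::combn(5, 2)) - 1L
  cyc <- rbind(c(0, 1), c(1, 2), c(2, 3), c(3, 4), c(0, 4))
  iscyc <- apply(pairs, 1, function(r) any(cyc[, 1] == r[1] & cyc[, 2] == r[2]))
  g <- as_signed_graph(data.frame(from = pairs[, 1], to = pairs[, 2],
                                  sign = ifelse(iscyc, -1L, 1L)))
  f <- fit_stp(g, tol = 1e-8)
  # independent scalar root: g(a) = k*a/(c*(a^2+1)) - a, solved by bisection
  k <- 4; cneg <- 2
  h <- function(a) k * a / (cneg * (a^2 + 1)) - a
  lo <- 1e-6; hi <- 1e6
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    if (h(mid) > 0) lo <- mid else hi <- mid
  }
  a_star <- (lo + hi) / 2
  expect_equal(unique(round(f$alpha, 6)), round(a_star, 6))
  expect_equal(unique(round(f$p_neg, 8)), cneg / k)  # = 1/(1+alpha^2)
})

test_that("STP fit satisfies the signed-degree constraints and ignores labelling", {
  set.seed(304)
  df <- rand_signed_edges(40, 0.15, neg_prob = 0.35)
  g <- as_signed_graph(df)
  f <- fit_stp(g)
  free <- f$status == "free" & f$k_neg > 0
  expect_lte(max(abs(f$residual[free]) / f$k_neg[free]), 1e-2)
  expect_true(f$converged)
  # relabel nodes: per-edge p_neg must be identical
  perm <- sample(0:39)
  g2 <- as_signed_graph(data.frame(from = perm[df$from + 1],
                                   to = perm[df$to + 1], sign = df$sign))
  f2 <- fit_stp(g2)
  # map g2's permuted labels back to the original ids before comparing
  key <- function(gg, p, unmap = identity) {
    u <- unmap(as.integer(gg$labels))[gg$edges$from + 1]
    v <- unmap(as.integer(gg$labels))[gg$edges$to + 1]
    stats::setNames(p, paste(pmin(u, v), pmax(u, v)))
  }
  k1 <- key(g, f$p_neg)
  k2 <- key(g2, f2$p_neg, unmap = function(lab) match(lab, perm) - 1L)
  expect_equal(k1[sort(names(k1))], k2[sort(names(k1))], tolerance = 1e-6)
})

test_that("STP samples concentrate on the target signed degrees", {
  set.seed(305)
  g <- rand_signed_graph(60, 0.12, neg_prob = 0.4)
  f <- fit_stp(g)
  n_rep <- 400
  kneg_sum <- numeric(g$n_nodes)
  for (i in seq_len(n_rep)) {
    s <- sample_stp(g, f)
    d <- signed_degrees(s)
    kneg_sum <- kneg_sum + d$k_neg
  }
  kneg_bar <- kneg_sum / n_rep
  # per-node binomial standard error bound
  p <- f$p_neg
  varn <- vapply(seq_len(g$n_nodes) - 1L, function(v) {
    onv <- g$edges$from == v | g$edges$to == v
    sum(p[onv] * (1 - p[onv]))
  }, numeric(1))
  se <- sqrt(pmax(varn, 1e-12) / n_rep)
  dev <- abs(kneg_bar - f$k_neg)
  expect_true(all(dev <= pmax(3 * se, 1e-9) + abs(f$residual) + 1e-8))
  # sampling keeps the exact edge set
  s <- sample_stp(g, f)
  expect_equal(s$edges[, c("from", "to")], g$edges[, c("from", "to")])
  # all-zero p_neg reproduces the all-positive graph
  ap <- complete_graph(5)
  expect_equal(sample_stp(ap, fit_stp(ap))$edges$sign, rep(1L, 10))
  # topology mismatch is an error
  expect_error(sample_stp(complete_graph(4), f), "different topology")
})

test_that("sampled censuses match the analytic independent-edge expectation", {
  set.seed(306)
  g <- rand_signed_graph(14, 0.35, neg_prob = 0.4)
  f <- fit_stp(g)
  occ <- graphlet_occurrences(g)
  # analytic expectation per pattern: sum over occurrences of the product of
  # per-edge pattern-sign probabilities, via full enumeration per family
  pc <- pattern_catalog()
  expected <- numeric(35)
  for (fam in c("triangle", "squareX", "squareZ", "square")) {
    m <- occ[[fam]]
    if (nrow(m) == 0) next
    k <- ncol(m)
    for (r in seq_len(nrow(m))) {
      pe <- f$p_neg[m[r, ] + 1L]
      for (mask in 0:(2^k - 1)) {
        bits <- bitwAnd(bitwShiftR(mask, 0:(k - 1)), 1L)
        pr <- prod(ifelse(bits == 1, pe, 1 - pe))
        sig <- paste(ifelse(bits == 1, "-", "+"), collapse = "")
        id <- canonical_pattern(fam, sig)$id
        expected[id] <- expected[id] + pr
      }
    }
  }
  n_rep <- 300
  acc <- numeric(35)
  for (i in seq_len(n_rep)) {
    s <- sample_stp(g, f)
    acc <- acc + census_graphlets(s)$count
  }
  avg <- acc / n_rep
  # agreement within Monte-Carlo scatter (loose 5-sigma-ish band)
  tolerance <- 5 * sqrt(pmax(expected, 1) / n_rep) + 0.5
  expect_true(all(abs(avg - expected) <= tolerance))
})
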