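test_that("edge lists parse with sign tokens, ratings and comments", {
  f <- withr::local_tempfile(lines = c("# a comment", "0 1 -1", "1 2 1"))
  rec <- read_signed_edgelist(f)
  expect_equal(rec$from, c("0", "1"))
  expect_equal(rec$to, c("1", "2"))
  expect_equal(rec$sign, c(-1L, 1L))

  f2 <- withr::local_tempfile(lines = c("7 9 -10", "7,8,3.5"))
  rec2 <- read_signed_edgelist(f2, sign_mode = "rating")
  expect_equal(rec2$sign, c(-1L, 1L))

  f3 <- withr::local_tempfile(lines = c("a b"))
  expect_error(read_signed_edgelist(f3), "line 1")
  f4 <- withr::local_tempfile(lines = c("0 1 1", "1 2 0"))
  expect_error(read_signed_edgelist(f4, sign_mode = "rating"), "line 2")
  f5 <- withr::local_tempfile(lines = c("0 1 bogus"))
  expect_error(read_signed_edgelist(f5), "bogus")
})

test_that("preprocessing collapses direction, drops contradictions and keeps the LCC", {
  # direction collapse: reciprocal records merge into one edge
  g <- as_signed_graph(data.frame(from = c(0, 1), to = c(1, 0), sign = c(1, 1)))
  expect_equal(nrow(g$edges), 1L)
  expect_equal(attr(g, "preprocessing")$duplicates, 1L)

  # contradictory pair dropped entirely, then LCC keeps {1,2}
  g2 <- as_signed_graph(data.frame(from = c(0, 1, 1), to = c(1, 0, 2),
                                   sign = c(1, -1, 1)))
  expect_equal(g2$n_nodes, 2L)
  expect_equal(g2$labels, c("1", "2"))
  expect_equal(g2$edges$sign, 1L)
  expect_equal(attr(g2, "preprocessing")$contradictory_pairs, 1L)

  # self-loop removal
  g3 <- as_signed_graph(data.frame(from = c(0, 0), to = c(0, 1), sign = c(1, -1)))
  expect_equal(nrow(g3$edges), 1L)
  expect_equal(g3$edges$sign, -1L)
  expect_equal(attr(g3, "preprocessing")$self_loops, 1L)

  # everything filtered away -> error
  expect_error(as_signed_graph(data.frame(from = 0, to = 0, sign = 1)),
               "no edges remain")
  # component tie broken toward the smallest label
  g4 <- as_signed_graph(data.frame(from = c(5, 0), to = c(6, 1), sign = 1))
  expect_equal(g4$labels, c("0", "1"))
})

test_that("preprocessing is idempotent through a write/read round trip", {
  set.seed(101)
  g <- rand_signed_graph(20, 0.15)
  f <- withr::local_tempfile()
  write_signed_edgelist(g, f)
  g2 <- as_signed_graph(read_signed_edgelist(f))
  expect_equal(g2$edges, g$edges)
  expect_equal(g2$n_nodes, g$n_nodes)
  # empty graph writes a warning and no edge lines
  f2 <- withr::local_tempfile()
  ge <- g
  ge$edges <- ge$edges[0, ]
  expect_warning(write_signed_edgelist(ge, f2), "empty")
})

test_that("signed degrees and their conservation laws", {
  g <- triangle_graph(c(1, 1, -1))  # edges 01+, 02+, 12-
  d <- signed_degrees(g)
  expect_equal(d$k_pos, c(2L, 1L, 1L))
  expect_equal(d$k_neg, c(0L, 1L, 1L))

  hub <- as_signed_graph(data.frame(from = 0, to = 1:3, sign = 1))
  expect_equal(signed_degrees(hub)$k_pos[1], 3L)

  neg <- as_signed_graph(data.frame(from = 0, to = 1, sign = -1))
  expect_equal(signed_degrees(neg)$k_neg, c(1L, 1L))

  set.seed(7)
  for (rep in 1:5) {
    g <- rand_signed_graph(25, 0.15)
    d <- signed_degrees(g)
    expect_equal(sum(d$k_pos), 2L * sum(g$edges$sign > 0))
    expect_equal(sum(d$k_neg), 2L * sum(g$edges$sign < 0))
    expect_equal(d$k_pos + d$k_neg,
                 tabulate(c(g$edges$from, g$edges$to) + 1L, nbins = g$n_nodes))
  }
})

test_that("degree correlation hits the textbook extremes", {
  # k_pos identical to k_neg: a path of +- pairs... build explicitly:
  # two triangles sharing nothing, each node one + and one - edge
  g <- as_signed_graph(data.frame(from = c(0, 0, 1), to = c(1, 2, 2),
                                  sign = c(1, -1, 1)))
  # k_pos = (1,2,1), k_neg = (1,0,1): perfect anti-alignment with constant total
  expect_equal(degree_correlation(g), -1)
  expect_warning(dc <- degree_correlation(triangle_graph(c(1, 1, 1))),
                 "constant")
  expect_true(is.na(dc))
})

test_that("network summary matches hand counts", {
  s <- network_summary(triangle_graph(c(1, 1, -1)))
  expect_equal(s$nodes, 3L)
  expect_equal(s$edges, 3L)
  expect_equal(s$density, 1)
  expect_equal(s$positive_ratio, 2 / 3)
  s2 <- glance(as_signed_graph(data.frame(from = 0, to = 1, sign = 1)))
  expect_equal(s2$density, 1)
  expect_equal(s2$positive_ratio, 1)
})

test_that("reverse_signs is an involution that flips the positive ratio", {
  set.seed(9)
  g <- rand_signed_graph(15, 0.3)
  r <- reverse_signs(g)
  expect_equal(network_summary(r)$positive_ratio,
               1 - network_summary(g)$positive_ratio)
  expect_equal(reverse_signs(r)$edges, g$edges)
  expect_false(is_balanced(reverse_signs(triangle_graph(c(1, 1, 1)))))
})
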