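test_that("catalog has the right family sizes and stable ids", {
  pc <- pattern_catalog()
  expect_equal(nrow(pc), 35L)
  expect_equal(sum(pc$family == "triangle"), 4L)
  expect_equal(sum(pc$family == "squareX"), 11L)
  expect_equal(sum(pc$family == "squareZ"), 14L)
  expect_equal(sum(pc$family == "square"), 6L)
  expect_equal(pc$id, 1:35)
  # family blocks in order, balanced listed before unbalanced within each
  expect_equal(unique(pc$family), c("triangle", "squareX", "squareZ", "square"))
  for (fam in unique(pc$family)) {
    b <- pc$balanced[pc$family == fam]
    expect_false(is.unsorted(rev(b)))  # TRUEs first
  }
  # the six square signatures up to symmetry
  expect_setequal(pc$signature[pc$family == "square"],
                  c("++++", "+++-", "++--", "+-+-", "+---", "----"))
})

test_that("canonicalization identifies symmetric sign assignments", {
  expect_equal(canonical_pattern("triangle", c("-", "+", "+"))$id,
               canonical_pattern("triangle", c("+", "+", "-"))$id)
  expect_equal(canonical_pattern("square", c("+", "-", "+", "-"))$id,
               canonical_pattern("square", c("-", "+", "-", "+"))$id)
  # the diamond diagonal is fixed by every automorphism: moving the one
  # negative sign between cycle and diagonal changes the pattern
  expect_false(canonical_pattern("squareZ", c("+", "+", "+", "+", "-"))$id ==
                 canonical_pattern("squareZ", c("+", "+", "+", "-", "+"))$id)
  expect_error(canonical_pattern("triangle", c("+", "+")), "3 edges")
  # numeric signs accepted
  expect_equal(canonical_pattern("triangle", c(-1, 1, 1))$id,
               canonical_pattern("triangle", "-++")$id)
})

test_that("balance flags equal exhaustive cycle-parity checking on all 35 patterns", {
  # independent oracle: enumerate every simple cycle of the family graph by
  # walking all node permutations, and require an even number of negative
  # edges on each
  fams <- list(
    triangle = rbind(c(0, 1), c(0, 2), c(1, 2)),
    squareX = rbind(c(0, 1), c(0, 2), c(0, 3), c(1, 2), c(1, 3), c(2, 3)),
    squareZ = rbind(c(0, 1), c(1, 2), c(2, 3), c(3, 0), c(0, 2)),
    square = rbind(c(0, 1), c(1, 2), c(2, 3), c(3, 0))
  )
  all_cycles <- function(ed, n) {
    ed <- cbind(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
    has <- function(a, b) any((ed[, 1] == pmin(a, b)) & (ed[, 2] == pmax(a, b)))
    eidx <- function(a, b) which((ed[, 1] == pmin(a, b)) & (ed[, 2] == pmax(a, b)))
    cycles <- list()
    seen <- character()
    for (len in 3:n) {
      for (sub in utils::combn(n, len, simplify = FALSE)) {
        nodes <- sub - 1L
        perms <- if (len == 3) list(nodes) else
          lapply(seq_len(6), function(i) {
            rest <- nodes[-1]
            o <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                       c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))[i, ]
            c(nodes[1], rest[o])
          })
        for (p in perms) {
          ring <- cbind(p, c(p[-1], p[1]))
          if (all(apply(ring, 1, function(r) has(r[1], r[2])))) {
            key <- paste(sort(apply(ring, 1, function(r) eidx(r[1], r[2]))),
                         collapse = "-")
            if (!key %in% seen) {
              seen <- c(seen, key)
              cycles[[length(cycles) + 1L]] <-
                apply(ring, 1, function(r) eidx(r[1], r[2]))
            }
          }
        }
      }
    }
    cycles
  }
  pc <- pattern_catalog()
  for (fam in names(fams)) {
    ed <- fams[[fam]]
    n <- max(ed) + 1L
    cyc <- all_cycles(ed, n)
    sub <- pc[pc$family == fam, ]
    for (r in seq_len(nrow(sub))) {
      neg <- strsplit(sub$signature[r], "")[[1]] == "-"
      parity_balanced <- all(vapply(cyc, function(ix) sum(neg[ix]) %% 2 == 0,
                                    logical(1)))
      expect_identical(sub$balanced[r], parity_balanced,
                       label = paste(fam, sub$signature[r]))
    }
  }
})

test_that("is_balanced matches the two-colouring criterion", {
  expect_true(is_balanced(triangle_graph(c(1, 1, 1))))
  expect_true(is_balanced(triangle_graph(c(1, -1, -1))))
  expect_false(is_balanced(triangle_graph(c(1, 1, -1))))
  expect_false(is_balanced(triangle_graph(c(-1, -1, -1))))
  # all-negative 4-cycle is balanced
  c4 <- as_signed_graph(data.frame(from = c(0, 1, 2, 0), to = c(1, 2, 3, 3),
                                   sign = -1L))
  expect_true(is_balanced(c4))
  # agreement with a zero-unbalanced-pattern census on random graphs
  set.seed(31)
  for (rep in 1:10) {
    g <- rand_signed_graph(12, 0.3)
    cc <- census_graphlets(g)
    if (is_balanced(g)) {
      expect_equal(sum(cc$count[!cc$balanced]), 0)
    }
  }
})
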