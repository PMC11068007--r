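#' Exact signed graphlet census
#'
#' Counts every occurrence of the 35 signed three- and four-node patterns in
#' a signed graph. In `"graphlet"` (induced) mode each node subset is
#' counted once under its induced topology, so only subsets whose induced
#' subgraph is a triangle, square, squareZ or squareX enter the counts. In
#' `"motif"` (non-induced) mode each family counts all sign-classified
#' occurrences of its edge set regardless of additional edges among the
#' four nodes; the fully connected families (triangle, squareX) coincide
#' across modes.
#'
#' The enumeration is exact: an edge-iterator with sorted-adjacency
#' intersection for triangles, per-edge common-neighbourhood combination
#' for squareX/squareZ, and wedge pairing for chordless squares, implemented
#' in C++.
#'
#' @param g A `signed_graph` (or coercible edge table).
#' @param families Which pattern families to report. Defaults to all four.
#' @param mode `"graphlet"` (induced) or `"motif"` (non-induced).
#' @return A tibble with one row per catalog pattern in `families`:
#'   `id`, `family`, `signature`, `balanced`, `count`; the census `mode` and
#'   the network size are attached as attributes.
#' @seealso [brute_force_census()] for the exhaustive oracle,
#'   [pattern_catalog()] for the taxonomy.
#' @examples
#' g <- as_signed_graph(data.frame(from = c(0, 1, 2), to = c(1, 2, 0),
#'                                 sign = c(1, 1, -1)))
#' census_graphlets(g)
#' @export
census_graphlets <- function(g, families = c("triangle", "square", "squareZ",
                                             "squareX"),
                             mode = c("graphlet", "motif")) {
  mode <- match.arg(mode)
  families <- match.arg(families, several.ok = TRUE)
  g <- as_signed_graph(g)
  luts <- .pattern_luts0()
  res <- cpp_census(g$n_nodes, .edge_matrix(g), g$edges$sign,
                    luts$triangle, luts$squareX, luts$squareZ, luts$square,
                    mode == "motif", "triangle" %in% families,
                    any(c("square", "squareZ", "squareX") %in% families))
  counts <- if (mode == "motif") res$motif else res$graphlet
  out <- pattern_catalog()
  out$count <- counts
  out <- out[out$family %in% families, c("id", "family", "signature",
                                         "balanced", "count")]
  attr(out, "mode") <- mode
  attr(out, "n_nodes") <- g$n_nodes
  attr(out, "n_edges") <- nrow(g$edges)
  out
}

#' @rdname census_graphlets
#' @export
census_triangles <- function(g) {
  census_graphlets(g, families = "triangle")
}

#' @rdname census_graphlets
#' @export
census_four_node <- function(g, mode = c("graphlet", "motif")) {
  census_graphlets(g, families = c("square", "squareZ", "squareX"),
                   mode = mode)
}

#' Brute-force census oracle
#'
#' Exhaustive enumeration of all 3- and 4-node subsets in pure R, classified
#' by induced topology (graphlet mode) or by enumerating every subset of the
#' present edges that forms a family's topology (motif mode). Identical
#' contract to [census_graphlets()]; intended as an independent correctness
#' oracle at desk scale, hence the hard size guard.
#'
#' @inheritParams census_graphlets
#' @param max_nodes Size guard; enumeration is \eqn{O(n^4)}.
#' @return As [census_graphlets()].
#' @export
brute_force_census <- function(g, families = c("triangle", "square", "squareZ",
                                               "squareX"),
                               mode = c("graphlet", "motif"), max_nodes = 32L) {
  mode <- match.arg(mode)
  families <- match.arg(families, several.ok = TRUE)
  g <- as_signed_graph(g)
  n <- g$n_nodes
  if (n > max_nodes) stop("brute_force_census is limited to ", max_nodes, " nodes")
  counts <- numeric(35)
  sgn <- new.env(hash = TRUE)
  for (i in seq_len(nrow(g$edges))) {
    assign(paste(g$edges$from[i], g$edges$to[i]), g$edges$sign[i], envir = sgn)
  }
  edge_sign <- function(a, b) {
    key <- if (a < b) paste(a, b) else paste(b, a)
    if (exists(key, envir = sgn, inherits = FALSE)) get(key, envir = sgn) else 0L
  }
  add <- function(fam, signs) {
    id <- canonical_pattern(fam, signs)$id
    counts[id] <<- counts[id] + 1
  }
  classify4 <- function(nodes, signs6, present) {
    # pairs in order (01,02,03,12,13,23) of the sorted 4-subset
    pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
    ne <- sum(present)
    if (ne == 6) {
      add("squareX", signs6)
    } else if (ne == 5) {
      miss <- pairs[!present, ]
      pq <- c(miss)                      # degree-2 nodes
      rs <- setdiff(1:4, pq)             # degree-3 nodes
      role <- c(rs[1], pq[1], rs[2], pq[2])  # a, b, c, d
      es <- function(i, j) signs6[which(pairs[, 1] == min(role[i], role[j]) &
                                        pairs[, 2] == max(role[i], role[j]))]
      add("squareZ", c(es(1, 2), es(2, 3), es(3, 4), es(4, 1), es(1, 3)))
    } else if (ne == 4) {
      deg <- tabulate(c(pairs[present, ]), nbins = 4)
      if (all(deg == 2)) {               # chordless 4-cycle
        nb1 <- pairs[present & (pairs[, 1] == 1 | pairs[, 2] == 1), ]
        nbrs <- setdiff(c(nb1), 1)
        v <- nbrs[1]; x <- nbrs[2]
        w <- setdiff(1:4, c(1, v, x))
        es <- function(i, j) signs6[which(pairs[, 1] == min(i, j) &
                                          pairs[, 2] == max(i, j))]
        add("square", c(es(1, v), es(v, w), es(w, x), es(x, 1)))
      }
    }
  }
  # triangles
  if (n >= 3) {
    for (trip in utils::combn(n, 3, simplify = FALSE)) {
      a <- trip[1] - 1L; b <- trip[2] - 1L; c_ <- trip[3] - 1L
      s1 <- edge_sign(a, b); s2 <- edge_sign(a, c_); s3 <- edge_sign(b, c_)
      if (s1 != 0 && s2 != 0 && s3 != 0) add("triangle", c(s1, s2, s3))
    }
  }
  # four-node subsets
  if (n >= 4) {
    pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
    for (quad in utils::combn(n, 4, simplify = FALSE)) {
      ids <- quad - 1L
      signs6 <- vapply(seq_len(6), function(k)
        edge_sign(ids[pairs[k, 1]], ids[pairs[k, 2]]), numeric(1))
      present <- signs6 != 0
      if (sum(present) < 3) next
      if (mode == "graphlet") {
        classify4(quad, signs6, present)
      } else {
        # every subset of the present edges isomorphic to a family topology
        pe <- which(present)
        if (length(pe) < 4L) next
        for (k in 4:length(pe)) {
          for (sub in utils::combn(pe, k, simplify = FALSE)) {
            sel <- logical(6); sel[sub] <- TRUE
            classify4(quad, signs6, sel)
          }
        }
      }
    }
  }
  out <- pattern_catalog()
  out$count <- counts
  out <- out[out$family %in% families, c("id", "family", "signature",
                                         "balanced", "count")]
  attr(out, "mode") <- mode
  attr(out, "n_nodes") <- n
  attr(out, "n_edges") <- nrow(g$edges)
  out
}

#' Cache unsigned graphlet occurrences
#'
#' For topology-preserving randomizations (sign shuffle, the maximum-entropy
#' signed-degree model) the unsigned occurrences never change, so the census
#' of each null sample reduces to re-reading edge signs along cached
#' edge-index tuples. This enumerates each family's occurrences once and
#' returns them for repeated scoring with [score_occurrences()].
#'
#' @inheritParams census_graphlets
#' @return An opaque list of edge-index matrices (one per family).
#' @export
graphlet_occurrences <- function(g) {
  g <- as_signed_graph(g)
  luts <- .pattern_luts0()
  occ <- cpp_occurrences(g$n_nodes, .edge_matrix(g), g$edges$sign,
                         luts$triangle, luts$squareX, luts$squareZ, luts$square)
  structure(occ, class = "graphlet_occurrences", n_edges = nrow(g$edges))
}

#' @rdname graphlet_occurrences
#' @param occ A `graphlet_occurrences` object.
#' @param signs Integer vector of +1/-1, one per edge of the graph the
#'   occurrences were extracted from.
#' @return `score_occurrences()`: a list with `graphlet` and `motif` count
#'   vectors (length 35, catalog order).
#' @export
score_occurrences <- function(occ, signs, motifs = FALSE) {
  stopifnot(inherits(occ, "graphlet_occurrences"),
            length(signs) == attr(occ, "n_edges"))
  luts <- .pattern_luts0()
  cpp_score_occurrences(occ, as.integer(signs),
                        luts$triangle, luts$squareX, luts$squareZ, luts$square,
                        motifs)
}

#' @rdname graphlet_occurrences
#' @param motifs Also accumulate non-induced (motif) counts.
#' @export
n_occurrences <- function(occ) {
  sum(vapply(unclass(occ), nrow, integer(1)))
}
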