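#' Signed graphs
#'
#' A `signed_graph` is a simple undirected graph in which every edge carries
#' a sign in \{+1, -1\}. Nodes are stored as contiguous integer ids
#' `0..n_nodes-1`; the original input labels are kept alongside so results
#' can be mapped back. The object is guaranteed to be *preprocessed*: no
#' self-loops, at most one edge per unordered pair, no pair connected with
#' both signs, and only the largest connected component retained.
#'
#' `as_signed_graph()` turns a raw edge table (as produced by
#' [read_signed_edgelist()], or any data frame whose first three columns are
#' source, target and sign) into a `signed_graph`, applying the full
#' preprocessing pipeline:
#'
#' 1. self-loops are removed;
#' 2. edge direction is collapsed (records `u->v` and `v->u` are the same
#'    undirected edge) and duplicate records with identical sign are merged;
#' 3. pairs that appear with *both* signs are contradictory and removed
#'    entirely;
#' 4. only the largest connected component is kept (ties broken in favour of
#'    the component containing the smallest original label);
#' 5. node ids are compacted to `0..n-1` in ascending original-label order.
#'
#' Counts of records dropped at each stage are attached as the
#' `"preprocessing"` attribute and reported by `print()`.
#'
#' @param x A data frame of raw edge records (columns: source, target, sign
#'   with sign coercible to +1/-1), or an existing `signed_graph`.
#' @param edges,n_nodes,labels Low-level constructor pieces: an integer edge
#'   matrix/tibble with 0-based endpoints and a sign column, the node count,
#'   and optional original labels.
#' @return A `signed_graph` object.
#' @examples
#' g <- as_signed_graph(data.frame(from = c(0, 1, 2), to = c(1, 2, 0),
#'                                 sign = c(1, 1, -1)))
#' g
#' signed_degrees(g)
#' @export
as_signed_graph <- function(x) {
  UseMethod("as_signed_graph")
}

#' @export
as_signed_graph.signed_graph <- function(x) x

#' @export
as_signed_graph.data.frame <- function(x) {
  stopifnot(ncol(x) >= 3)
  from <- as.character(x[[1]])
  to <- as.character(x[[2]])
  sgn <- x[[3]]
  if (!is.numeric(sgn)) sgn <- .parse_sign_tokens(as.character(sgn))
  sgn <- as.integer(sign(sgn))
  if (any(sgn == 0L | is.na(sgn))) {
    stop("every edge record needs a nonzero sign", call. = FALSE)
  }
  n_records <- length(from)

  self <- from == to
  n_self <- sum(self)
  from <- from[!self]; to <- to[!self]; sgn <- sgn[!self]
  if (length(from) == 0L) {
    stop("no edges remain after preprocessing", call. = FALSE)
  }

  # collapse direction: order each pair by label
  swap <- .label_order(from) > .label_order(to)
  u <- ifelse(swap, to, from)
  v <- ifelse(swap, from, to)
  key <- paste0(u, "\r", v)
  dup <- duplicated(paste0(key, "\r", sgn))
  n_dup <- sum(dup)
  u <- u[!dup]; v <- v[!dup]; sgn <- sgn[!dup]; key <- key[!dup]

  # contradictory pairs: same unordered pair with both signs
  contra_keys <- unique(key[duplicated(key)])
  contra <- key %in% contra_keys
  n_contra <- length(contra_keys)
  u <- u[!contra]; v <- v[!contra]; sgn <- sgn[!contra]

  if (length(u) == 0L) {
    stop("no edges remain after preprocessing", call. = FALSE)
  }

  # largest connected component; ties -> component with the smallest label
  labs <- unique(c(u, v))
  labs <- labs[order(.label_order(labs))]
  ig <- igraph::graph_from_edgelist(
    cbind(match(u, labs), match(v, labs)), directed = FALSE)
  comp <- igraph::components(ig)
  biggest <- which(comp$csize == max(comp$csize))
  keep_comp <- biggest[1L]  # labs is sorted, membership of labs[1]... pick by smallest member
  if (length(biggest) > 1L) {
    first_member <- vapply(biggest, function(cc) min(which(comp$membership == cc)),
                           integer(1))
    keep_comp <- biggest[which.min(first_member)]
  }
  keep_nodes <- labs[comp$membership == keep_comp]
  keep_edge <- u %in% keep_nodes  # v is in the same component as u by construction
  n_outside <- sum(!keep_edge)
  u <- u[keep_edge]; v <- v[keep_edge]; sgn <- sgn[keep_edge]

  labels <- keep_nodes  # already in ascending label order
  edges <- tibble::tibble(
    from = match(u, labels) - 1L,
    to = match(v, labels) - 1L,
    sign = sgn
  )
  # store with from < to on compacted ids, sorted for reproducibility
  flip <- edges$from > edges$to
  tmp <- edges$from[flip]; edges$from[flip] <- edges$to[flip]; edges$to[flip] <- tmp
  edges <- dplyr::arrange(edges, .data$from, .data$to)

  g <- new_signed_graph(edges, length(labels), labels)
  attr(g, "preprocessing") <- list(
    n_records = n_records, self_loops = n_self, duplicates = n_dup,
    contradictory_pairs = n_contra, edges_outside_lcc = n_outside,
    n_components = comp$no
  )
  g
}

#' @rdname as_signed_graph
#' @export
new_signed_graph <- function(edges, n_nodes, labels = NULL) {
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("from", "to", "sign") %in% names(edges)))
  if (is.null(labels)) labels <- as.character(seq_len(n_nodes) - 1L)
  structure(
    list(edges = edges, n_nodes = as.integer(n_nodes), labels = labels),
    class = "signed_graph"
  )
}

# order labels numerically when they all parse as numbers, else lexicographically
.label_order <- function(x) {
  num <- suppressWarnings(as.numeric(x))
  if (!anyNA(num)) num else xtfrm(x)
}

.parse_sign_tokens <- function(tok) {
  out <- rep(NA_real_, length(tok))
  out[tok %in% c("+1", "1", "+")] <- 1
  out[tok %in% c("-1", "-")] <- -1
  if (anyNA(out)) {
    bad <- which(is.na(out))[1]
    stop(sprintf("unrecognized sign token '%s'", tok[bad]), call. = FALSE)
  }
  out
}

#' @export
print.signed_graph <- function(x, ...) {
  s <- glance(x)
  cat(sprintf("# A signed graph: %d nodes, %d edges (density %.3g, positive ratio %.3g)\n",
              s$nodes, s$edges, s$density, s$positive_ratio))
  pp <- attr(x, "preprocessing")
  if (!is.null(pp)) {
    cat(sprintf("# preprocessing: %d records; dropped %d self-loops, %d duplicates, %d contradictory pairs, %d edges outside the largest of %d components\n",
                pp$n_records, pp$self_loops, pp$duplicates,
                pp$contradictory_pairs, pp$edges_outside_lcc, pp$n_components))
  }
  print(x$edges, ...)
  invisible(x)
}

#' Read a signed edge list
#'
#' Parses a plain-text signed edge list in the SNAP `soc-sign` dialect: one
#' edge per line, fields separated by whitespace or commas, lines starting
#' with `#` are comments. The third field is either a sign
#' (`+1`/`1`/`-1`/`+`/`-`) or, with `sign_mode = "rating"`, an arbitrary
#' nonzero number whose arithmetic sign becomes the edge sign.
#'
#' Records are returned raw - direction, duplicates and contradictions are
#' preserved - so that [as_signed_graph()] can report exactly what the
#' preprocessing removed.
#'
#' @param file Path or connection.
#' @param sign_mode `"sign"` (third field is a sign token) or `"rating"`
#'   (third field is a nonzero rating; its sign is used).
#' @return A tibble with columns `from`, `to` (character) and `sign` (+1/-1).
#' @export
read_signed_edgelist <- function(file, sign_mode = c("sign", "rating")) {
  sign_mode <- match.arg(sign_mode)
  lines <- readLines(file)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(tibble::tibble(from = character(), to = character(), sign = integer()))
  }
  parts <- strsplit(trimws(lines), "[,[:space:]]+")
  nf <- lengths(parts)
  if (any(nf < 3L)) {
    bad <- which(nf < 3L)[1]
    stop(sprintf("line %d: expected at least 3 fields, got %d",
                 lineno[bad], nf[bad]), call. = FALSE)
  }
  from <- vapply(parts, `[[`, character(1), 1L)
  to <- vapply(parts, `[[`, character(1), 2L)
  third <- vapply(parts, `[[`, character(1), 3L)
  if (sign_mode == "rating") {
    val <- suppressWarnings(as.numeric(third))
    if (anyNA(val)) {
      bad <- which(is.na(val))[1]
      stop(sprintf("line %d: rating '%s' is not numeric", lineno[bad], third[bad]),
           call. = FALSE)
    }
    if (any(val == 0)) {
      bad <- which(val == 0)[1]
      stop(sprintf("line %d: zero rating cannot be converted to a sign",
                   lineno[bad]), call. = FALSE)
    }
    sgn <- as.integer(sign(val))
  } else {
    ok <- third %in% c("+1", "1", "+", "-1", "-")
    if (!all(ok)) {
      bad <- which(!ok)[1]
      stop(sprintf("line %d: unrecognized sign token '%s'", lineno[bad], third[bad]),
           call. = FALSE)
    }
    sgn <- ifelse(third %in% c("+1", "1", "+"), 1L, -1L)
  }
  tibble::tibble(from = from, to = to, sign = sgn)
}

#' Write a signed edge list
#'
#' Writes one `u v s` line per edge with compacted node ids and `s` in
#' \{1, -1\}; the output round-trips through [read_signed_edgelist()] and
#' [as_signed_graph()] to an identical graph.
#'
#' @param g A `signed_graph` (or coercible edge table).
#' @param file Path or connection.
#' @param header Optional character vector of metadata lines, written as
#'   `#`-prefixed comments before the edges.
#' @return `g`, invisibly.
#' @export
write_signed_edgelist <- function(g, file, header = NULL) {
  g <- as_signed_graph(g)
  lines <- character()
  if (!is.null(header)) lines <- paste0("# ", header)
  if (nrow(g$edges) == 0L) {
    warning("writing an empty signed graph")
  } else {
    lines <- c(lines, sprintf("%d %d %d", g$edges$from, g$edges$to, g$edges$sign))
  }
  writeLines(lines, file)
  invisible(g)
}

#' Signed degrees
#'
#' Per-node positive (`k_pos`) and negative (`k_neg`) degrees. For every
#' node `k_pos + k_neg` equals its total degree, and the column sums equal
#' twice the positive/negative edge counts.
#'
#' @param g A `signed_graph` (or coercible edge table).
#' @return A tibble with columns `node` (0-based id), `label`, `k_pos`, `k_neg`.
#' @export
signed_degrees <- function(g) {
  g <- as_signed_graph(g)
  n <- g$n_nodes
  pos <- g$edges$sign > 0
  k_pos <- tabulate(c(g$edges$from[pos], g$edges$to[pos]) + 1L, nbins = n)
  k_neg <- tabulate(c(g$edges$from[!pos], g$edges$to[!pos]) + 1L, nbins = n)
  tibble::tibble(node = seq_len(n) - 1L, label = g$labels,
                 k_pos = k_pos, k_neg = k_neg)
}

#' Pearson correlation between positive and negative degrees
#'
#' @param g A `signed_graph` (or coercible edge table).
#' @return The sample Pearson correlation between `k_pos` and `k_neg` over
#'   nodes, or `NA` (with a warning) when either degree sequence is constant.
#' @export
degree_correlation <- function(g) {
  d <- signed_degrees(g)
  if (nrow(d) < 2L || sd(d$k_pos) == 0 || sd(d$k_neg) == 0) {
    warning("degree correlation undefined: constant degree sequence")
    return(NA_real_)
  }
  cor(d$k_pos, d$k_neg)
}

#' Network summary
#'
#' One-row overview of a signed graph: node and edge counts, density
#' `E / (N(N-1)/2)` and positive ratio (positive edges / all edges).
#' `glance()` on a `signed_graph` returns the same row.
#'
#' @param g A `signed_graph` (or coercible edge table).
#' @return A one-row tibble with columns `nodes`, `edges`, `density`,
#'   `positive_ratio`.
#' @export
network_summary <- function(g) {
  g <- as_signed_graph(g)
  n <- g$n_nodes
  e <- nrow(g$edges)
  tibble::tibble(
    nodes = n,
    edges = e,
    density = if (n > 1) e / (n * (n - 1) / 2) else NA_real_,
    positive_ratio = if (e > 0) mean(g$edges$sign > 0) else NA_real_
  )
}

#' @rdname network_summary
#' @param x A `signed_graph`.
#' @param ... Unused.
#' @method glance signed_graph
#' @export
glance.signed_graph <- function(x, ...) network_summary(x)

#' Flip every edge sign
#'
#' Topology is unchanged; the positive ratio maps to one minus itself.
#' Applying it twice returns the original graph.
#'
#' @param g A `signed_graph` (or coercible edge table).
#' @return A `signed_graph` with all signs reversed.
#' @export
reverse_signs <- function(g) {
  g <- as_signed_graph(g)
  g$edges$sign <- -g$edges$sign
  attr(g, "preprocessing") <- NULL
  g
}

# internal: replace signs (same topology), dropping stale preprocessing info
.with_signs <- function(g, signs) {
  g$edges$sign <- as.integer(signs)
  attr(g, "preprocessing") <- NULL
  g
}

# internal: 0-based edge matrix for C++
.edge_matrix <- function(g) {
  cbind(g$edges$from, g$edges$to)
}
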