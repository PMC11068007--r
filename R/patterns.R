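#' Signed graphlet taxonomy
#'
#' The census distinguishes four connected pattern families: `triangle`
#' (3-cycle), `square` (chordless 4-cycle), `squareZ` (4-cycle plus one
#' diagonal, the "diamond") and `squareX` (complete graph K4). Assigning a
#' sign to every edge and identifying assignments related by a symmetry of
#' the underlying unsigned graph yields 4 triangle, 6 square, 14 squareZ and
#' 11 squareX patterns - 35 in total.
#'
#' A pattern is *balanced* when every cycle inside it has a positive product
#' of edge signs; equivalently, when its nodes can be split into two camps
#' with positive edges within camps and negative edges across.
#'
#' Signatures are written over a fixed canonical edge order per family:
#' triangle `(01, 02, 12)`; square cycle `(01, 12, 23, 30)`; squareZ cycle
#' `(01, 12, 23, 30)` plus diagonal `(02)` (nodes 0 and 2 are the two
#' degree-3 nodes); squareX `(01, 02, 03, 12, 13, 23)`. The stored signature
#' is the lexicographically smallest (`'+' < '-'`) over all symmetries.
#' Ids 1-35 run triangle, squareX, squareZ, square, balanced patterns before
#' unbalanced ones, lexicographic within each block.
#'
#' @return `pattern_catalog()`: a 35-row tibble with columns `id`, `family`,
#'   `signature`, `n_edges`, `balanced`.
#' @examples
#' pattern_catalog()
#' canonical_pattern("triangle", c("-", "+", "+"))
#' @export
pattern_catalog <- function() {
  .pattern_cache()$catalog
}

.family_defs <- list(
  triangle = list(n_nodes = 3L, edges = rbind(c(0L, 1L), c(0L, 2L), c(1L, 2L))),
  squareX  = list(n_nodes = 4L, edges = rbind(c(0L, 1L), c(0L, 2L), c(0L, 3L),
                                              c(1L, 2L), c(1L, 3L), c(2L, 3L))),
  squareZ  = list(n_nodes = 4L, edges = rbind(c(0L, 1L), c(1L, 2L), c(2L, 3L),
                                              c(3L, 0L), c(0L, 2L))),
  square   = list(n_nodes = 4L, edges = rbind(c(0L, 1L), c(1L, 2L), c(2L, 3L),
                                              c(3L, 0L)))
)

# all node permutations of 0..k-1
.perms <- function(k) {
  if (k == 1L) return(matrix(0L, 1, 1))
  sub <- .perms(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(pos) {
    cbind(sub[, seq_len(pos - 1L), drop = FALSE], k - 1L,
          sub[, seq(pos, k - 1L)[seq_len(k - pos)], drop = FALSE])
  }))
}

# edge permutations induced by the automorphisms of a family's unsigned graph
.automorphism_edge_perms <- function(fam) {
  ed <- .family_defs[[fam]]$edges
  k <- .family_defs[[fam]]$n_nodes
  m <- nrow(ed)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  canon <- key(ed[, 1], ed[, 2])
  perms <- .perms(k)
  out <- list()
  for (r in seq_len(nrow(perms))) {
    p <- perms[r, ]
    mapped <- key(p[ed[, 1] + 1L], p[ed[, 2] + 1L])
    idx <- match(mapped, canon)
    if (!anyNA(idx)) out[[length(out) + 1L]] <- idx  # edge i -> position idx[i]
  }
  out
}

# does a sign assignment admit a Harary two-colouring?
.mask_balanced <- function(fam, bits) {
  ed <- .family_defs[[fam]]$edges
  k <- .family_defs[[fam]]$n_nodes
  for (col in 0:(2^k - 1)) {
    colour <- bitwAnd(bitwShiftR(col, 0:(k - 1)), 1L)
    same <- colour[ed[, 1] + 1L] == colour[ed[, 2] + 1L]
    if (all(same == (bits == 0L))) return(TRUE)  # + within, - across
  }
  FALSE
}

.mask_bits <- function(mask, m) bitwAnd(bitwShiftR(mask, 0:(m - 1)), 1L)
.bits_mask <- function(bits) sum(bits * 2L^(seq_along(bits) - 1L))
.bits_sig <- function(bits) paste(ifelse(bits == 1L, "-", "+"), collapse = "")

# catalog + per-family mask -> id lookup tables, computed once per session
.pattern_cache <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    fams <- c("triangle", "squareX", "squareZ", "square")
    luts <- list()
    rows <- list()
    for (fam in fams) {
      m <- nrow(.family_defs[[fam]]$edges)
      perms <- .automorphism_edge_perms(fam)
      # lexicographic order on signatures ('+' < '-') = numeric order when the
      # first edge is the most significant bit; locale-independent
      msb_val <- function(bits) sum(bits * 2L^(m - seq_len(m)))
      canon_mask <- integer(2^m)
      for (mask in 0:(2^m - 1)) {
        bits <- .mask_bits(mask, m)
        best <- NULL
        for (ep in perms) {
          b2 <- integer(m); b2[ep] <- bits
          v <- msb_val(b2)
          if (is.null(best) || v < best$v) best <- list(v = v, bits = b2)
        }
        canon_mask[mask + 1L] <- .bits_mask(best$bits)
      }
      reps <- sort(unique(canon_mask))
      sig <- vapply(reps, function(ms) .bits_sig(.mask_bits(ms, m)), character(1))
      bal <- vapply(reps, function(ms) .mask_balanced(fam, .mask_bits(ms, m)), logical(1))
      lexv <- vapply(reps, function(ms) msb_val(.mask_bits(ms, m)), numeric(1))
      ord <- order(!bal, lexv)
      rows[[fam]] <- tibble::tibble(family = fam, signature = sig[ord],
                                    n_edges = m, balanced = bal[ord],
                                    rep_mask = reps[ord])
      luts[[fam]] <- canon_mask
    }
    catalog <- dplyr::bind_rows(rows)
    catalog$id <- seq_len(nrow(catalog))
    # lut: mask -> id (1..35)
    for (fam in fams) {
      sub <- catalog[catalog$family == fam, ]
      id_of_rep <- setNames(sub$id, as.character(sub$rep_mask))
      luts[[fam]] <- unname(id_of_rep[as.character(luts[[fam]])])
    }
    catalog <- catalog[, c("id", "family", "signature", "n_edges", "balanced")]
    cache <<- list(catalog = catalog, luts = luts)
    cache
  }
})

# internal: integer LUTs (0-based pattern index for C++)
.pattern_luts0 <- function() {
  lapply(.pattern_cache()$luts, function(v) as.integer(v - 1L))
}

#' @rdname pattern_catalog
#' @param family One of `"triangle"`, `"square"`, `"squareZ"`, `"squareX"`.
#' @param signs Edge signs over the family's canonical edge order: a
#'   character vector of `"+"`/`"-"`, a single string like `"++-"`, or a
#'   numeric vector of +1/-1.
#' @return `canonical_pattern()`: the matching one-row slice of the catalog.
#' @export
canonical_pattern <- function(family, signs) {
  family <- match.arg(family, names(.family_defs))
  m <- nrow(.family_defs[[family]]$edges)
  if (is.character(signs) && length(signs) == 1L && nchar(signs) > 1L) {
    signs <- strsplit(signs, "")[[1]]
  }
  if (is.character(signs)) {
    bits <- as.integer(signs == "-")
    if (!all(signs %in% c("+", "-"))) stop("signs must be '+' or '-'")
  } else {
    bits <- as.integer(signs < 0)
  }
  if (length(bits) != m) {
    stop(sprintf("family '%s' has %d edges, got %d signs", family, m, length(bits)))
  }
  cache <- .pattern_cache()
  id <- cache$luts[[family]][.bits_mask(bits) + 1L]
  cache$catalog[cache$catalog$id == id, ]
}

#' Test strong balance
#'
#' A signed graph is strongly balanced when every cycle has an even number
#' of negative edges - equivalently, when the nodes admit a two-colouring
#' with positive edges inside colours and negative edges across (Harary's
#' criterion). Checked by breadth-first switching in O(N + E).
#'
#' @param g A `signed_graph` (or coercible edge table). Disconnected input
#'   is allowed; each component is checked.
#' @return `TRUE` or `FALSE`.
#' @export
is_balanced <- function(g) {
  g <- as_signed_graph(g)
  n <- g$n_nodes
  if (nrow(g$edges) == 0L) return(TRUE)
  # adjacency in flat form
  from <- c(g$edges$from, g$edges$to) + 1L
  to <- c(g$edges$to, g$edges$from) + 1L
  sgn <- rep(g$edges$sign, 2L)
  ord <- order(from)
  from <- from[ord]; to <- to[ord]; sgn <- sgn[ord]
  ptr <- c(0L, cumsum(tabulate(from, nbins = n)))
  colour <- rep(NA_integer_, n)
  for (start in seq_len(n)) {
    if (!is.na(colour[start])) next
    colour[start] <- 0L
    queue <- start
    while (length(queue) > 0L) {
      v <- queue[[1L]]; queue <- queue[-1L]
      idx <- seq.int(ptr[v] + 1L, length.out = ptr[v + 1L] - ptr[v])
      for (i in idx) {
        w <- to[i]
        want <- if (sgn[i] > 0) colour[v] else 1L - colour[v]
        if (is.na(colour[w])) {
          colour[w] <- want
          queue <- c(queue, w)
        } else if (colour[w] != want) {
          return(FALSE)
        }
      }
    }
  }
  TRUE
}
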