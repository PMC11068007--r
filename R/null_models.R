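#' Randomization schemes for signed networks
#'
#' Four null models with different conservation laws:
#'
#' * `rewire()` - degree-preserving double edge swaps. Two random edges
#'   `A-B`, `C-D` are swapped with equal probability to `A-D, C-B` or
#'   `A-C, B-D`; a swap is aborted when the four endpoints are not distinct
#'   or a proposed edge already exists. Signs ride on the edges, so the
#'   total sign counts are conserved but signed degrees generally are not.
#' * `signed_rewire()` - as `rewire()` but the two candidate edges always
#'   carry the same sign and a swap is aborted if a proposed edge already
#'   exists with either sign, so the per-node `(k_pos, k_neg)` vector is
#'   conserved exactly while the topology is randomized.
#' * `sign_shuffle()` - the topology is kept and the multiset of signs is
#'   uniformly permuted over the edges.
#' * [fit_stp()] / [sample_stp()] - the maximum-entropy model that keeps the
#'   topology exactly and matches every node's expected signed degree.
#'
#' Aborted swap attempts count toward the attempt budget, so
#' `attempts_per_edge = 40` performs `40 * E` attempts in total.
#' Randomness is drawn from R's global RNG; use `set.seed()` for
#' reproducibility.
#'
#' @param g A `signed_graph` (or coercible edge table).
#' @param attempts_per_edge Swap attempts per edge (including aborted ones).
#' @return A `signed_graph` with the same nodes; the number of performed
#'   (non-aborted) swaps is attached as attribute `"swaps_performed"`.
#' @examples
#' set.seed(1)
#' g <- generate_ec_reference(50)
#' table(sign_shuffle(g)$edges$sign) == table(g$edges$sign)
#' @export
rewire <- function(g, attempts_per_edge = 40) {
  .rewire_impl(g, attempts_per_edge, signed_mode = FALSE)
}

#' @rdname rewire
#' @export
signed_rewire <- function(g, attempts_per_edge = 40) {
  .rewire_impl(g, attempts_per_edge, signed_mode = TRUE)
}

.rewire_impl <- function(g, attempts_per_edge, signed_mode) {
  g <- as_signed_graph(g)
  E <- nrow(g$edges)
  if (E < 2L) return(g)
  res <- cpp_rewire(g$n_nodes, .edge_matrix(g), g$edges$sign,
                    attempts_per_edge * E, signed_mode)
  edges <- tibble::tibble(from = res$edges[, 1], to = res$edges[, 2],
                          sign = g$edges$sign)
  out <- new_signed_graph(edges, g$n_nodes, g$labels)
  attr(out, "swaps_performed") <- res$performed
  out
}

#' @rdname rewire
#' @export
sign_shuffle <- function(g) {
  g <- as_signed_graph(g)
  .with_signs(g, sample(g$edges$sign))
}

#' Fit the signed-degree and topology preserving null model
#'
#' Fits the maximum-entropy distribution over sign assignments on a fixed
#' topology whose expected negative degree matches every node's observed
#' negative degree. The probability that edge `(i,j)` is negative is
#' `p_neg = 1 / (1 + alpha_i * alpha_j)` with one positive multiplier
#' `alpha_i` per node (`theta_i = log(alpha_i)` is the Lagrange multiplier
#' of node `i`'s constraint). The multipliers solve the fixed point
#' \deqn{\alpha_i' = \frac{1}{k^-_i} \sum_{j : (i,j) \in G}
#'       \frac{1}{\alpha_j + 1/\alpha_i}}
#' iterated synchronously from `alpha = 1` until the maximum relative
#' change of `alpha` drops below `tol` or `max_iter` is reached.
#'
#' Degenerate nodes - those with no negative edges or with only negative
#' edges - are the limits `alpha -> Inf` / `alpha -> 0` of the fixed point;
#' they are excluded from the iteration and their incident edges clamped to
#' `p_neg = 0` / `p_neg = 1`, with neighbours' residual constraints adjusted
#' accordingly (the clamping cascades until no degenerate node remains).
#' Because the clamped values always equal the observed edge signs, the
#' residual problem stays feasible.
#'
#' @param g A `signed_graph` (or coercible edge table).
#' @param tol Stop when the maximum relative change of `alpha` between two
#'   consecutive iterations falls below this.
#' @param max_iter Iteration cap; non-convergence is reported in the fitted
#'   object, not silently ignored.
#' @return An object of class `stp_model`: per-node multipliers `alpha`,
#'   per-edge negative-sign probabilities `p_neg`, degeneracy flags and
#'   convergence metadata. Use [tidy()] for a per-node table, [glance()]
#'   for a one-row fit summary and [sample_stp()] to draw sign assignments.
#' @examples
#' set.seed(1)
#' g <- generate_ec_reference(200)
#' fit <- fit_stp(g)
#' glance(fit)
#' @export
fit_stp <- function(g, tol = 1e-3, max_iter = 10000L) {
  g <- as_signed_graph(g)
  n <- g$n_nodes
  E <- nrow(g$edges)
  ef <- g$edges$from + 1L
  et <- g$edges$to + 1L
  deg <- tabulate(c(ef, et), nbins = n)
  k_neg <- tabulate(c(ef, et)[rep(g$edges$sign < 0, 2L)], nbins = n)

  p_neg <- rep(NA_real_, E)
  k_eff <- k_neg
  deg_eff <- deg
  edge_active <- rep(TRUE, E)
  status <- rep("free", n)

  # peel degenerate nodes; clamped values equal the observed signs
  repeat {
    all_pos <- which(k_eff == 0L & deg_eff > 0L & status == "free")
    all_neg <- which(k_eff == deg_eff & deg_eff > 0L & status == "free")
    if (length(all_pos) == 0L && length(all_neg) == 0L) break
    status[all_pos] <- "all_positive"
    status[all_neg] <- "all_negative"
    fixed <- status != "free"
    clamp <- edge_active & (fixed[ef] | fixed[et])
    val <- as.numeric(g$edges$sign[clamp] < 0)
    p_neg[clamp] <- val
    edge_active[clamp] <- FALSE
    dd <- tabulate(c(ef[clamp], et[clamp]), nbins = n)
    dn <- tabulate(c(ef[clamp], et[clamp])[rep(val == 1, 2L)], nbins = n)
    deg_eff <- deg_eff - dd
    k_eff <- k_eff - dn
  }
  free_node <- status == "free" & deg_eff > 0L

  alpha <- rep(1, n)
  iter <- 0L
  delta <- NA_real_
  converged <- !any(free_node)
  if (any(free_node)) {
    af <- ef[edge_active]
    at <- et[edge_active]
    idx <- c(af, at)          # constraint owner
    oth <- c(at, af)          # the other endpoint
    for (iter in seq_len(max_iter)) {
      contrib <- 1 / (alpha[oth] + 1 / alpha[idx])
      s <- rowsum(contrib, idx, reorder = FALSE)
      new_alpha <- alpha
      who <- as.integer(rownames(s))
      upd <- s[, 1] / k_eff[who]
      new_alpha[who] <- pmin(pmax(upd, 1e-12), 1e12)
      delta <- max(abs(new_alpha[free_node] - alpha[free_node]) /
                     alpha[free_node])
      alpha <- new_alpha
      if (delta < tol) { converged <- TRUE; break }
    }
    p_neg[edge_active] <- 1 / (1 + alpha[af] * alpha[at])
  }
  alpha[status == "all_positive"] <- Inf
  alpha[status == "all_negative"] <- 0

  # residual of the original constraints (clamped edges contribute exactly)
  sum_p <- rowsum(c(p_neg, p_neg), c(ef, et), reorder = FALSE)
  residual <- rep(0, n)
  residual[as.integer(rownames(sum_p))] <- sum_p[, 1]
  residual <- residual - k_neg

  structure(list(
    alpha = alpha, p_neg = p_neg, k_neg = k_neg, degree = deg,
    status = status, iterations = iter, converged = converged,
    max_rel_change = delta, residual = residual, tol = tol,
    n_nodes = n, n_edges = E, edges = g$edges[, c("from", "to")]
  ), class = "stp_model")
}

#' @export
print.stp_model <- function(x, ...) {
  cat(sprintf("# STP null model fit: %d nodes, %d edges\n", x$n_nodes, x$n_edges))
  cat(sprintf("#   %d free nodes, %d all-positive, %d all-negative\n",
              sum(x$status == "free"), sum(x$status == "all_positive"),
              sum(x$status == "all_negative")))
  cat(sprintf("#   %s after %d iterations (max relative change %.2g, max |residual| %.2g)\n",
              if (x$converged) "converged" else "NOT converged",
              x$iterations, x$max_rel_change, max(abs(x$residual))))
  invisible(x)
}

#' @rdname fit_stp
#' @param x An `stp_model`.
#' @param ... Unused.
#' @method tidy stp_model
#' @export
tidy.stp_model <- function(x, ...) {
  tibble::tibble(
    node = seq_len(x$n_nodes) - 1L,
    alpha = x$alpha,
    theta = log(x$alpha),
    degree = x$degree,
    k_neg = x$k_neg,
    status = x$status,
    residual = x$residual
  )
}

#' @rdname fit_stp
#' @method glance stp_model
#' @export
glance.stp_model <- function(x, ...) {
  free <- x$status == "free"
  tibble::tibble(
    nodes = x$n_nodes, edges = x$n_edges,
    free_nodes = sum(free),
    iterations = x$iterations, converged = x$converged,
    max_rel_change = x$max_rel_change,
    max_rel_residual = if (any(free & x$k_neg > 0)) {
      max(abs(x$residual[free & x$k_neg > 0]) / x$k_neg[free & x$k_neg > 0])
    } else 0
  )
}

#' @rdname fit_stp
#' @param model A fitted `stp_model` for the same topology as `g`.
#' @return `sample_stp()`: a `signed_graph` with `g`'s exact edge set and
#'   each edge independently negative with its fitted probability.
#' @export
sample_stp <- function(g, model) {
  g <- as_signed_graph(g)
  stopifnot(inherits(model, "stp_model"))
  if (nrow(g$edges) != model$n_edges || g$n_nodes != model$n_nodes ||
      !identical(g$edges$from, model$edges$from) ||
      !identical(g$edges$to, model$edges$to)) {
    stop("model was fitted on a different topology")
  }
  neg <- runif(model$n_edges) < model$p_neg
  .with_signs(g, ifelse(neg, -1L, 1L))
}
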