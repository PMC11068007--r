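#' Ensemble z-score
#'
#' `z = (n_obs - mean(samples)) / sd(samples)` with the sample
#' (n-1-denominator) standard deviation. Undefined (returns `NA`) when the
#' null counts do not vary, since a zero denominator carries no information.
#'
#' @param n_obs Observed count.
#' @param samples Numeric vector of null-ensemble counts (length >= 2).
#' @return A number, or `NA` if `sd(samples) == 0`.
#' @export
zscore <- function(n_obs, samples) {
  if (length(samples) < 2L) stop("need at least 2 null samples for a z-score")
  s <- sd(samples)
  if (s == 0) return(NA_real_)
  (n_obs - mean(samples)) / s
}

#' One-sided empirical P value
#'
#' `P = (r + 1) / (n + 1)` where `n` is the ensemble size and `r` the number
#' of samples at least as extreme as the observation, in the direction of
#' the observed deviation: the upper tail (samples `>= n_obs`) when `n_obs`
#' is at or above the ensemble mean, the lower tail (samples `<= n_obs`)
#' otherwise. Ties count toward `r`, so `1/(n+1) <= P <= 1`.
#'
#' @inheritParams zscore
#' @return A probability in `[1/(n+1), 1]`.
#' @export
empirical_pvalue <- function(n_obs, samples) {
  n <- length(samples)
  if (n < 1L) stop("need at least 1 null sample")
  r <- if (n_obs >= mean(samples)) sum(samples >= n_obs) else sum(samples <= n_obs)
  (r + 1) / (n + 1)
}

#' Graphlet enrichment against a null ensemble
#'
#' Runs the full enrichment pipeline: census the observed network once, draw
#' `n_samples` randomized replicas under the chosen null model, census each
#' under identical settings, and summarise per pattern with the ensemble
#' mean and SD, z-score, fold change `n_obs / mean`, one-sided empirical
#' P value and a significance flag (`|z| > 2` and `P < 0.01`).
#'
#' For the topology-preserving nulls (`"sign_shuffle"`, `"stp"`) the
#' unsigned occurrences are enumerated once and each replica only re-reads
#' edge signs along the cached tuples; when the occurrence set would exceed
#' `cache_max` tuples the replicas are re-censused from scratch instead
#' (identical results, bounded memory). The rewiring nulls change the
#' topology and are always re-censused.
#'
#' @param g A `signed_graph` (or coercible edge table).
#' @param null One of `"stp"`, `"sign_shuffle"`, `"rewire"`,
#'   `"signed_rewire"`.
#' @param n_samples Ensemble size.
#' @param seed Master seed; each replica uses a stream derived from it by
#'   sample index, so ensembles are reproducible.
#' @param families,mode Passed to the census (see [census_graphlets()]).
#' @param attempts_per_edge Swap attempts per edge for the rewiring nulls.
#' @param tol,max_iter Passed to [fit_stp()] for `null = "stp"`.
#' @param cache_max Occurrence-cache cap (tuples); see Details.
#' @return A tibble of class `signed_enrichment` with one row per catalog
#'   pattern in `families`: `id`, `family`, `signature`, `balanced`,
#'   `n_obs`, `mean_rand`, `sd_rand`, `z`, `fold_change`, `p_value`,
#'   `n_samples`, `significant`. Run metadata is attached as attributes.
#' @examples
#' set.seed(7)
#' g <- generate_ec_reference(80)
#' enrichment_table(g, null = "sign_shuffle", n_samples = 50, seed = 1,
#'                  families = "triangle")
#' @export
enrichment_table <- function(g,
                             null = c("stp", "sign_shuffle", "rewire",
                                      "signed_rewire"),
                             n_samples = 1000L, seed = 1L,
                             families = c("triangle", "square", "squareZ",
                                          "squareX"),
                             mode = c("graphlet", "motif"),
                             attempts_per_edge = 40, tol = 1e-3,
                             max_iter = 10000L, cache_max = 5e7) {
  null <- match.arg(null)
  mode <- match.arg(mode)
  families <- match.arg(families, several.ok = TRUE)
  stopifnot(n_samples >= 1L)
  g <- as_signed_graph(g)
  E <- nrow(g$edges)

  observed <- census_graphlets(g, families = families, mode = mode)

  topology_fixed <- null %in% c("stp", "sign_shuffle")
  model <- NULL
  if (null == "stp") model <- fit_stp(g, tol = tol, max_iter = max_iter)

  occ <- NULL
  if (topology_fixed) {
    occ <- graphlet_occurrences(g)
    if (n_occurrences(occ) > cache_max) occ <- NULL
  }

  n_neg <- sum(g$edges$sign < 0)
  counts_of <- function(gg) {
    census_graphlets(gg, families = families, mode = mode)$count
  }
  want_motifs <- mode == "motif"
  keep_ids <- observed$id

  samples <- matrix(0, nrow = n_samples, ncol = nrow(observed))
  for (i in seq_len(n_samples)) {
    set.seed((as.integer(seed) + 104729L * i) %% 2147483647L)
    if (topology_fixed) {
      signs <- if (null == "stp") {
        ifelse(runif(E) < model$p_neg, -1L, 1L)
      } else {
        sample(g$edges$sign)
      }
      if (!is.null(occ)) {
        sc <- score_occurrences(occ, signs, motifs = want_motifs)
        counts <- if (want_motifs) sc$motif else sc$graphlet
        samples[i, ] <- counts[keep_ids]
      } else {
        samples[i, ] <- counts_of(.with_signs(g, signs))
      }
    } else {
      gg <- .rewire_impl(g, attempts_per_edge, null == "signed_rewire")
      samples[i, ] <- counts_of(gg)
    }
  }

  mean_rand <- colMeans(samples)
  sd_rand <- apply(samples, 2, sd)
  n_obs <- observed$count
  z <- ifelse(sd_rand > 0, (n_obs - mean_rand) / sd_rand, NA_real_)
  fold <- ifelse(mean_rand > 0, n_obs / mean_rand, NA_real_)
  pv <- vapply(seq_along(n_obs), function(j)
    empirical_pvalue(n_obs[j], samples[, j]), numeric(1))
  out <- tibble::tibble(
    id = observed$id, family = observed$family,
    signature = observed$signature, balanced = observed$balanced,
    n_obs = n_obs, mean_rand = mean_rand, sd_rand = sd_rand,
    z = z, fold_change = fold, p_value = pv,
    n_samples = n_samples,
    significant = !is.na(z) & abs(z) > 2 & pv < 0.01
  )
  class(out) <- c("signed_enrichment", class(out))
  attr(out, "null") <- null
  attr(out, "seed") <- seed
  attr(out, "mode") <- mode
  if (!is.null(model)) attr(out, "stp_converged") <- model$converged
  out
}

#' @rdname enrichment_table
#' @param x A `signed_enrichment` table.
#' @param ... Unused.
#' @method glance signed_enrichment
#' @export
glance.signed_enrichment <- function(x, ...) {
  tibble::tibble(
    null = attr(x, "null"), mode = attr(x, "mode"),
    n_samples = x$n_samples[1], patterns = nrow(x),
    n_significant = sum(x$significant, na.rm = TRUE),
    n_undefined_z = sum(is.na(x$z))
  )
}

#' Plot enrichment z-scores
#'
#' One bar per pattern, coloured by sign of z, faceted by family, balanced
#' patterns listed first and separated from unbalanced ones; significant
#' patterns (`|z| > 2`, `P < 0.01`) are starred. Patterns with an undefined
#' z (zero null SD) are omitted.
#'
#' @param object A `signed_enrichment` table.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot signed_enrichment
#' @export
autoplot.signed_enrichment <- function(object, ...) {
  df <- as.data.frame(object[!is.na(object$z), ])
  df$signature <- factor(df$signature,
                         levels = df$signature[order(df$family, !df$balanced, df$id)])
  df$direction <- ifelse(df$z >= 0, "over", "under")
  df$label <- ifelse(df$significant, "*", "")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$signature, y = .data$z,
                                   fill = .data$direction)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = c(-2, 2), linetype = "dashed",
                        linewidth = 0.3) +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), vjust = 0.2) +
    ggplot2::facet_grid(. ~ family, scales = "free_x", space = "free_x") +
    ggplot2::scale_fill_manual(values = c(over = "#3366bb", under = "#bb3333")) +
    ggplot2::labs(x = NULL, y = "z-score",
                  title = paste0("Signed graphlet enrichment vs ",
                                 attr(object, "null"), " null")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
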