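# broom-style tidiers and ggplot2 autoplot methods

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy a censcape PCA fit
#'
#' @param x A `censcape_pca` object.
#' @param matrix One of `"scores"` (default; one row per observation),
#'   `"loadings"` (one row per feature) or `"eigenvalues"`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.censcape_pca <- function(x, matrix = c("scores", "loadings",
                                            "eigenvalues"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "eigenvalues") {
    ev <- x$explained_variance
    return(tibble(component = seq_along(ev), variance = ev,
                  percent = 100 * ev / sum(ev),
                  cumulative = cumsum(100 * ev / sum(ev))))
  }
  m <- if (matrix == "scores") x$scores else x$loadings
  id_col <- if (matrix == "scores") "row" else "feature"
  out <- as_tibble(m, rownames = id_col)
  out
}

#' @rdname tidy.censcape_pca
#' @export
glance.censcape_pca <- function(x, ...) {
  ev <- x$explained_variance
  tibble(
    n = nrow(x$scores), n_features = nrow(x$loadings),
    n_components = x$n_components,
    total_variance = sum(ev),
    pc1_percent = 100 * ev[1] / sum(ev),
    pc2_percent = if (length(ev) > 1) 100 * ev[2] / sum(ev) else NA_real_
  )
}

#' Tidy a logistic group model
#'
#' @param x A `censcape_logit` object.
#' @param ... Unused.
#' @return Coefficient tibble (term, estimate, std.error, statistic,
#'   p.value).
#' @export
tidy.censcape_logit <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble(
    term = rownames(sm), estimate = sm[, 1], std.error = sm[, 2],
    statistic = sm[, 3], p.value = sm[, 4]
  )
}

#' @rdname tidy.censcape_logit
#' @export
glance.censcape_logit <- function(x, ...) {
  tibble(
    n = x$n, deviance = x$deviance, null_deviance = x$null_deviance,
    lrt_statistic = x$lrt_statistic, lrt_df = x$lrt_df, lrt_p = x$lrt_p,
    separation = x$separation
  )
}

#' PCA score plot with group ellipses
#'
#' Scatter of the first two principal-component scores, coloured by
#' group, with the normal-theory data ellipse (default 95%) drawn for
#' every group with at least 3 points.
#'
#' @param object A `censcape_pca` object.
#' @param groups Optional factor/character vector of group labels, one
#'   per observation.
#' @param level Ellipse coverage level (default 0.95).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.censcape_pca <- function(object, groups = NULL, level = 0.95,
                                  ...) {
  sc <- as_tibble(object$scores, rownames = "row")
  names(sc)[2:3] <- c("PC1", "PC2")
  ev <- object$explained_variance
  pct <- 100 * ev / sum(ev)
  sc$group <- if (is.null(groups)) "all" else as.character(groups)
  p <- ggplot2::ggplot(sc, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                        colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", pct[1]),
                  y = sprintf("PC2 (%.1f%%)", pct[2]),
                  colour = "group") +
    ggplot2::theme_minimal()
  ell <- sc |>
    group_by(.data$group) |>
    dplyr::filter(n() >= 3) |>
    dplyr::group_modify(function(d, key) {
      ellipse_outline(data_ellipse(d[, c("PC1", "PC2")], level = level))
    }) |>
    ungroup()
  if (nrow(ell) > 0) {
    p <- p + ggplot2::geom_path(
      data = ell, ggplot2::aes(x = .data$x, y = .data$y,
                               colour = .data$group),
      inherit.aes = FALSE, linewidth = 0.5
    )
  }
  p
}

#' Group comparison boxplot of PC1 scores
#'
#' @param scores Numeric vector of PC1 scores.
#' @param groups Group labels, same length.
#' @return A ggplot object.
#' @export
plot_group_scores <- function(scores, groups) {
  d <- tibble(score = scores, group = as.factor(groups))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$score,
                                  fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.5, show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "PC1 score") +
    ggplot2::theme_minimal()
}

#' Null-distribution plot for cluster permutation results
#'
#' Histogram of permutation occurrence counts per signature with the
#' observed count marked.
#'
#' @param results Tibble from [cluster_permutation_test()].
#' @param max_signatures Show at most this many signatures (smallest p
#'   first).
#' @return A ggplot object.
#' @export
plot_cluster_null <- function(results, max_signatures = 6) {
  top <- utils::head(results, max_signatures)
  d <- top |>
    select("signature", "null_counts") |>
    tidyr::unnest_longer("null_counts", values_to = "count")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$count)) +
    ggplot2::geom_bar() +
    ggplot2::geom_vline(
      data = select(top, "signature", "observed_count"),
      ggplot2::aes(xintercept = .data$observed_count),
      colour = "red", linetype = 2
    ) +
    ggplot2::facet_wrap(~signature, scales = "free_y") +
    ggplot2::labs(x = "occurrences per permutation", y = "permutations") +
    ggplot2::theme_minimal()
}
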