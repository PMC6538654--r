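# PCA of enrichment profiles, 95% data ellipses, between-group rank
# comparisons with star notation, and logistic-regression group models.

#' Principal component analysis of an enrichment-profile matrix
#'
#' Columns are centred but not rescaled (entries are already z-scores
#' on a common scale); components come from the singular value
#' decomposition, with the sign of each component fixed so that its
#' largest-magnitude loading is positive (for determinism).
#'
#' @param x Numeric matrix, windows x features (no non-finite
#'   entries, at least 2 rows).
#' @param n_components Number of components to retain in scores and
#'   loadings (default 2). Explained variances are kept for all
#'   components.
#' @return An object of class `censcape_pca`: list with `scores`
#'   (n x n_components), `loadings` (p x n_components),
#'   `explained_variance` (all components), `center`, `total_variance`,
#'   `n_components`.
#' @export
fit_pca <- function(x, n_components = 2) {
  x <- as.matrix(x)
  if (nrow(x) < 2) abort("need at least 2 rows")
  if (any(!is.finite(x))) abort("non-finite entries in input matrix")
  n_components <- min(n_components, nrow(x) - 1L, ncol(x))
  fit <- prcomp(x, center = TRUE, scale. = FALSE)
  ev <- fit$sdev^2
  load <- fit$rotation[, seq_len(n_components), drop = FALSE]
  scores <- fit$x[, seq_len(n_components), drop = FALSE]
  for (j in seq_len(n_components)) {
    top <- which.max(abs(load[, j]))
    if (load[top, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(
    list(scores = scores, loadings = load, explained_variance = ev,
         center = fit$center,
         total_variance = sum(apply(x, 2, stats::var)),
         n_components = n_components),
    class = "censcape_pca"
  )
}

#' @export
print.censcape_pca <- function(x, ...) {
  pct <- 100 * x$explained_variance / sum(x$explained_variance)
  cat(sprintf("<censcape_pca> %d observations, %d components retained\n",
              nrow(x$scores), x$n_components))
  cat(sprintf("  variance explained: %s\n",
              paste(sprintf("PC%d %.1f%%", seq_len(min(5, length(pct))),
                            pct[seq_len(min(5, length(pct)))]),
                    collapse = ", ")))
  invisible(x)
}

#' Normal-theory data ellipse for bivariate points
#'
#' The ellipse that encloses `level` of the data under a bivariate
#' normal model: centre at the mean, axes and angle from the
#' eigendecomposition of the sample covariance, scaled by
#' `sqrt(qchisq(level, 2))`.
#'
#' @param points Two-column matrix or data frame of (PC1, PC2)
#'   coordinates; at least 3 points.
#' @param level Coverage fraction (default 0.95).
#' @return An object of class `censcape_ellipse`: list with `center`,
#'   `semi_axes` (major, minor), `angle` (radians), `level`, `cov`,
#'   `n`.
#' @export
data_ellipse <- function(points, level = 0.95) {
  m <- as.matrix(points)
  if (ncol(m) != 2) abort("points must have exactly 2 columns")
  if (nrow(m) < 3) abort("need at least 3 points")
  ctr <- colMeans(m)
  S <- cov(m)
  eig <- eigen(S, symmetric = TRUE)
  q <- qchisq(level, df = 2)
  structure(
    list(center = ctr, semi_axes = sqrt(pmax(eig$values, 0) * q),
         angle = atan2(eig$vectors[2, 1], eig$vectors[1, 1]),
         level = level, cov = S, n = nrow(m)),
    class = "censcape_ellipse"
  )
}

#' Is each point inside a data ellipse?
#'
#' @param ellipse A [data_ellipse()] object.
#' @param points Two-column matrix of coordinates.
#' @return Logical vector (Mahalanobis distance within the ellipse's
#'   chi-square radius).
#' @export
in_ellipse <- function(ellipse, points) {
  d2 <- mahalanobis(as.matrix(points), ellipse$center, ellipse$cov)
  d2 <= qchisq(ellipse$level, df = 2)
}

#' Polygon approximation of an ellipse outline (for plotting)
#'
#' @param ellipse A [data_ellipse()] object.
#' @param n Number of points on the outline.
#' @return Tibble with columns `x`, `y`.
#' @export
ellipse_outline <- function(ellipse, n = 180) {
  t <- seq(0, 2 * pi, length.out = n)
  a <- ellipse$semi_axes[1]
  b <- ellipse$semi_axes[2]
  th <- ellipse$angle
  x <- a * cos(t)
  y <- b * sin(t)
  tibble(
    x = ellipse$center[1] + x * cos(th) - y * sin(th),
    y = ellipse$center[2] + x * sin(th) + y * cos(th)
  )
}

#' Star notation for a p-value
#'
#' `p > 0.05` = ns; `0.01 < p <= 0.05` = `*`; `0.001 < p <= 0.01` =
#' `**`; `0.0001 < p <= 0.001` = `***`; `p <= 0.0001` = `****`.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Character vector of star labels.
#' @export
star_label <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must be in [0, 1]")
  dplyr::case_when(
    p <= 1e-4 ~ "****",
    p <= 1e-3 ~ "***",
    p <= 1e-2 ~ "**",
    p <= 0.05 ~ "*",
    TRUE ~ "ns"
  )
}

#' Rank-based mean comparison between two groups of scores
#'
#' Two-sided Wilcoxon rank-sum test on the given scores (typically PC1
#' values of two window groups): exact when both groups have at most
#' 25 observations and there are no ties, otherwise the normal
#' approximation with continuity correction.
#'
#' @param scores_a,scores_b Numeric vectors, both non-empty.
#' @param label_a,label_b Group labels for the output.
#' @return One-row tibble with columns `group_a`, `group_b`,
#'   `statistic` (rank-sum W), `p`, `stars`.
#' @export
compare_group_means <- function(scores_a, scores_b,
                                label_a = "A", label_b = "B") {
  if (length(scores_a) == 0 || length(scores_b) == 0) {
    abort("both groups must be non-empty")
  }
  exact <- length(scores_a) <= 25 && length(scores_b) <= 25
  wt <- suppressWarnings(
    wilcox.test(scores_a, scores_b, alternative = "two.sided",
                exact = exact, correct = TRUE)
  )
  tibble(
    group_a = label_a, group_b = label_b,
    statistic = unname(wt$statistic), p = wt$p.value,
    stars = star_label(wt$p.value)
  )
}

#' All pairwise group mean comparisons of PC1 scores
#'
#' @param scores Numeric vector of scores (e.g. PC1).
#' @param groups Factor or character vector of group labels, same
#'   length as `scores`.
#' @return Tibble with one row per unordered group pair.
#' @export
compare_all_groups <- function(scores, groups) {
  groups <- as.factor(groups)
  lev <- levels(droplevels(groups))
  if (length(lev) < 2) abort("need at least two groups")
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  bind_rows(lapply(pairs, function(pr) {
    compare_group_means(scores[groups == pr[1]], scores[groups == pr[2]],
                        label_a = pr[1], label_b = pr[2])
  }))
}

#' Logistic regression of group membership on PC scores
#'
#' Maximum-likelihood logistic fit of membership on the given
#' principal-component scores, with a likelihood-ratio test against
#' the intercept-only model. Complete or quasi-complete separation is
#' detected (fitted probabilities collapsing to 0/1) and flagged
#' rather than returning divergent coefficients as meaningful.
#'
#' @param scores Numeric matrix or data frame of PC scores
#'   (observations x components).
#' @param is_member Logical (or 0/1) membership indicator; both
#'   classes must be present.
#' @return An object of class `censcape_logit`: list with
#'   `coefficients` (including intercept), `lrt_statistic`, `lrt_df`,
#'   `lrt_p`, `separation`, `deviance`, `null_deviance`, `n`.
#' @export
logistic_group_model <- function(scores, is_member) {
  y <- as.integer(as.logical(is_member))
  if (length(unique(y)) < 2) abort("both classes must be present")
  x <- as.matrix(scores)
  if (is.null(colnames(x))) colnames(x) <- paste0("PC", seq_len(ncol(x)))
  df <- as.data.frame(x)
  df$.y <- y
  sep <- FALSE
  fit <- withCallingHandlers(
    glm(.y ~ ., data = df, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
          grepl("algorithm did not converge", conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  lrt <- fit$null.deviance - fit$deviance
  df_lrt <- fit$df.null - fit$df.residual
  structure(
    list(coefficients = stats::coef(fit),
         lrt_statistic = lrt, lrt_df = df_lrt,
         lrt_p = pchisq(lrt, df = df_lrt, lower.tail = FALSE),
         separation = sep,
         deviance = fit$deviance, null_deviance = fit$null.deviance,
         n = length(y), fit = fit),
    class = "censcape_logit"
  )
}

#' @export
print.censcape_logit <- function(x, ...) {
  cat(sprintf("<censcape_logit> n = %d, LRT p = %.3g%s\n", x$n, x$lrt_p,
              if (x$separation) " (separation detected)" else ""))
  print(x$coefficients)
  invisible(x)
}
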