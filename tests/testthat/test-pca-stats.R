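test_that("PCA recovers the closed-form eigenstructure of toy data", {
  x <- cbind(a = c(-2, -2, 2, 2), b = c(-1, 1, -1, 1))
  f <- fit_pca(x, 2)
  # sample covariance is diag(16/3, 4/3); PCs align with the axes
  expect_equal(unname(f$loadings), diag(2), tolerance = 1e-12)
  expect_equal(f$explained_variance, c(16 / 3, 4 / 3), tolerance = 1e-12)
  # independent oracle: eigenvalues of the 2x2 covariance
  expect_equal(f$explained_variance,
               sort(eigen(stats::cov(x))$values, decreasing = TRUE),
               tolerance = 1e-12)
})

test_that("degenerate and invalid PCA inputs are handled", {
  same <- matrix(3, nrow = 5, ncol = 4)
  f <- fit_pca(same, 2)
  expect_true(all(abs(f$scores) < 1e-12))
  expect_true(all(f$explained_variance < 1e-24))
  expect_error(fit_pca(matrix(1, 1, 3)), "at least 2 rows")
  expect_error(fit_pca(matrix(c(1, NA, 2, 3), 2)), "non-finite")
})

test_that("explained variances sum to the total column variance", {
  set.seed(42)
  x <- matrix(rnorm(60 * 10), 60, 10)
  f <- fit_pca(x, 3)
  expect_equal(sum(f$explained_variance), f$total_variance,
               tolerance = 1e-8)
})

test_that("PCA scores are row-order invariant under the sign convention", {
  set.seed(7)
  x <- matrix(rnorm(40 * 6), 40, 6)
  f1 <- fit_pca(x, 2)
  perm <- sample(40)
  f2 <- fit_pca(x[perm, ], 2)
  expect_equal(unname(f2$scores), unname(f1$scores[perm, ]),
               tolerance = 1e-9)
})

test_that("the 95% data ellipse has the chi-square radius", {
  # four points with exact identity sample covariance
  a <- sqrt(1.5)
  pts <- rbind(c(a, 0), c(-a, 0), c(0, a), c(0, -a))
  e <- data_ellipse(pts, level = 0.95)
  expect_equal(unname(e$center), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(e$semi_axes), rep(sqrt(qchisq(0.95, 2)), 2),
               tolerance = 1e-9)
  expect_equal(unname(e$semi_axes[1]), 2.4477, tolerance = 1e-4)
  # level -> 0 degenerates to the centroid
  e0 <- data_ellipse(pts, level = 1e-12)
  expect_true(all(e0$semi_axes < 1e-4))
  expect_error(data_ellipse(pts[1:2, ]), "at least 3")
})

test_that("ellipse containment converges to the nominal level", {
  set.seed(123)
  pts <- cbind(rnorm(10000), rnorm(10000))
  e <- data_ellipse(pts, level = 0.95)
  expect_equal(mean(in_ellipse(e, pts)), 0.95, tolerance = 0.01)
})

test_that("rank-sum comparison matches exact enumeration and stars", {
  # enumeration oracle: all C(6,3) rank splits of {1..6}
  splits <- utils::combn(6, 3)
  w_obs <- sum(rank(c(1, 2, 3, 10, 11, 12))[1:3]) - 6
  w_all <- apply(splits, 2, function(idx) sum(idx) - 6)
  p_enum <- mean(abs(w_all - 4.5) >= abs(w_obs - 4.5))
  expect_equal(p_enum, 0.1)
  cmp <- compare_group_means(c(1, 2, 3), c(10, 11, 12))
  expect_equal(cmp$p, 0.1)
  expect_identical(cmp$stars, "ns")

  same <- compare_group_means(c(1, 2, 3), c(1, 2, 3))
  expect_identical(same$stars, "ns")
  expect_error(compare_group_means(numeric(0), 1:3), "non-empty")

  expect_identical(star_label(c(0.03, 5e-5)), c("*", "****"))
})

test_that("pairwise group comparisons cover all group pairs", {
  set.seed(9)
  sc <- c(rnorm(10), rnorm(10, 5), rnorm(10, 10))
  gr <- rep(c("a", "b", "c"), each = 10)
  cmp <- compare_all_groups(sc, gr)
  expect_identical(nrow(cmp), 3L)
  expect_true(all(cmp$p >= 0 & cmp$p <= 1))
})

test_that("logistic group model recovers a planted slope", {
  set.seed(31)
  x <- rnorm(2000)
  y <- rbinom(2000, 1, stats::plogis(2.0 * x))
  m <- logistic_group_model(cbind(PC1 = x), y)
  expect_false(m$separation)
  expect_equal(unname(m$coefficients["PC1"]), 2.0, tolerance = 0.3)
  expect_lt(m$lrt_p, 1e-10)
})

test_that("separation is flagged and label permutation kills the signal", {
  x <- c(rnorm(30, -5), rnorm(30, 5))
  y <- rep(c(0, 1), each = 30)
  m <- logistic_group_model(cbind(PC1 = x), y)
  expect_true(m$separation)
  expect_lt(m$lrt_p, 1e-6)

  set.seed(77)
  yp <- sample(y)
  mp <- logistic_group_model(cbind(PC1 = x), yp)
  expect_gt(mp$lrt_p, 1e-4)
  expect_error(logistic_group_model(cbind(PC1 = x), rep(1, 60)),
               "both classes")
})

test_that("tidiers return well-formed tibbles", {
  set.seed(5)
  x <- matrix(rnorm(30 * 5), 30, 5)
  f <- fit_pca(x, 2)
  expect_identical(nrow(tidy(f, "scores")), 30L)
  expect_identical(nrow(tidy(f, "loadings")), 5L)
  ev <- tidy(f, "eigenvalues")
  expect_equal(max(ev$cumulative), 100, tolerance = 1e-9)
  g <- glance(f)
  expect_identical(g$n, 30L)

  m <- logistic_group_model(cbind(PC1 = rnorm(40)),
                            rep(c(0, 1), 20))
  td <- tidy(m)
  expect_true(all(c("term", "estimate", "p.value") %in% names(td)))
})
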