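# Native community statistics against hand arithmetic and independent
# implementations (vegan / stats) as oracles.

test_that("Bray-Curtis matches hand arithmetic and its bounds", {
  expect_equal(bray_curtis(c(1, 2), c(1, 2)), 0)
  expect_equal(bray_curtis(c(1, 0), c(0, 2)), 1) # disjoint supports
  expect_equal(bray_curtis(c(1, 2), c(3, 0)), 4 / 6)
  expect_error(bray_curtis(c(0, 0), c(0, 0)),
               class = "reefpress_validation_error")
})

test_that("Bray-Curtis and Euclidean matrices match vegan", {
  skip_if_not_installed("vegan")
  set.seed(7)
  m <- matrix(rpois(60, 8), 10, 6)
  rownames(m) <- paste0("s", 1:10)
  d <- dissimilarity_matrix(m, "bray_curtis")
  expect_equal(unclass(as.matrix(d)),
               as.matrix(vegan::vegdist(m, "bray")),
               tolerance = 1e-12, ignore_attr = TRUE)
  de <- dissimilarity_matrix(m, "euclidean")
  expect_equal(unclass(as.matrix(de)),
               as.matrix(vegan::vegdist(m, "euclidean")),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("ANOSIM R is 1 under maximal separation and matches vegan", {
  # two tight clusters far apart
  x <- rbind(matrix(rnorm(10, 0, 0.01), 5), matrix(rnorm(10, 50, 0.01), 5))
  d <- dissimilarity_matrix(x, "euclidean")
  g <- rep(c("A", "B"), each = 5)
  res <- anosim(d, g, n_perm = 99, seed = 1)
  expect_equal(res$statistic, 1)
  skip_if_not_installed("vegan")
  set.seed(42)
  y <- matrix(rpois(48, 6), 8, 6) + rep(c(0, 4), each = 4)
  dy <- dissimilarity_matrix(y, "bray_curtis")
  gy <- rep(c("A", "B"), each = 4)
  mine <- anosim(dy, gy, n_perm = 999, seed = 2)
  ref <- vegan::anosim(vegan::vegdist(y, "bray"), gy, permutations = 999)
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
})

test_that("exhaustive ANOSIM p equals full-enumeration brute force", {
  set.seed(5)
  x <- matrix(rnorm(8), 4, 2)
  d <- dissimilarity_matrix(x, "euclidean")
  g <- c("A", "A", "B", "B")
  res <- anosim(d, g, exhaustive = TRUE)
  # independent oracle: enumerate the 6 choose(4,2) labelings directly
  m <- as.matrix(d)
  ut <- upper.tri(m)
  rk <- rank(m[ut]); ii <- row(m)[ut]; jj <- col(m)[ut]
  r_of <- function(lab) {
    w <- lab[ii] == lab[jj]
    (mean(rk[!w]) - mean(rk[w])) / (4 * 3 / 4)
  }
  labs <- utils::combn(4, 2, function(id) {
    l <- rep("B", 4); l[id] <- "A"; l
  })
  r_all <- apply(labs, 2, r_of)
  p_oracle <- mean(r_all >= r_of(g))
  expect_equal(res$p_value, p_oracle)
  expect_equal(res$n_perm, 6L)
})

test_that("random labels on homogeneous data give R near zero on average", {
  set.seed(31)
  x <- matrix(rnorm(60), 12, 5)
  d <- dissimilarity_matrix(x, "euclidean")
  rs <- vapply(1:60, function(i) {
    g <- sample(rep(c("A", "B"), each = 6))
    anosim(d, g, n_perm = 9, seed = i)$statistic
  }, 0)
  expect_lt(abs(mean(rs)), 0.05)
  expect_true(all(rs >= -1 & rs <= 1))
})

test_that("ANOSIM rejects invalid groupings", {
  d <- dissimilarity_matrix(matrix(rnorm(10), 5, 2), "euclidean")
  expect_error(anosim(d, c("A", "A", "A", "A", "B")),
               class = "reefpress_validation_error")
})

test_that("PCoA on Euclidean distances reproduces PCA scores", {
  set.seed(13)
  x <- matrix(rnorm(42), 7, 6)
  d <- dissimilarity_matrix(x, "euclidean")
  pc <- pcoa(d, k = 3)
  ref <- stats::prcomp(x, center = TRUE)$x[, 1:3]
  # equality up to per-axis sign
  for (j in 1:3) {
    expect_true(max(abs(pc$points[, j] - ref[, j])) < 1e-8 ||
                  max(abs(pc$points[, j] + ref[, j])) < 1e-8)
  }
})

test_that("PCoA handles collinear and duplicated configurations", {
  x <- cbind(c(0, 1, 2), 0)
  d <- dissimilarity_matrix(x, "euclidean")
  expect_warning(pc <- pcoa(d, k = 2), "truncating")
  pos <- pc$eigenvalues[pc$eigenvalues > 1e-9]
  expect_equal(length(pos), 1L)
  expect_equal(pc$explained[1], 1)
  y <- rbind(c(1, 2), c(1, 2), c(4, 6), c(0, 9))
  dy <- dissimilarity_matrix(y, "euclidean")
  py <- pcoa(dy, k = 2)
  expect_equal(py$points[1, ], py$points[2, ], tolerance = 1e-10)
})

test_that("PCA matches an SVD oracle and normalizes explained variance", {
  set.seed(17)
  x <- matrix(rnorm(24), 6, 4)
  res <- pca(x)
  expect_equal(sum(res$explained), 1, tolerance = 1e-12)
  xc <- scale(x, center = TRUE, scale = FALSE)
  sv <- svd(xc)
  oracle <- sv$u %*% diag(sv$d)
  for (j in seq_len(ncol(res$scores))) {
    expect_true(max(abs(res$scores[, j] - oracle[, j])) < 1e-8 ||
                  max(abs(res$scores[, j] + oracle[, j])) < 1e-8)
  }
  # rank-1 data: one component carries everything
  r1 <- outer(1:5, c(2, -1, 3))
  res1 <- pca(r1)
  expect_equal(res1$explained[1], 1, tolerance = 1e-12)
  expect_equal(pca(matrix(1, 4, 3))$flag, "degenerate")
})

test_that("Friedman statistic matches direct formula cases", {
  y <- matrix(c(1, 2, 3,
                1, 2, 3,
                1, 2, 3), 3, 3, byrow = TRUE)
  # perfectly consistent ordering: rank sums 3, 6, 9 -> chi2 = 6
  expect_equal(friedman_test(y)$statistic, 6)
  expect_equal(friedman_test(matrix(5, 3, 3))$statistic, 0)
})

test_that("Friedman is invariant to within-block monotone transforms", {
  set.seed(23)
  y <- matrix(runif(12, 1, 9), 4, 3)
  a <- friedman_test(y)$statistic
  b <- friedman_test(exp(y))$statistic
  expect_equal(a, b)
})

test_that("Friedman matches stats::friedman.test on tie-free tables", {
  set.seed(29)
  for (i in 1:10) {
    y <- matrix(sample(1:100, 15), 5, 3) # distinct values: no ties
    mine <- friedman_test(y)
    ref <- stats::friedman.test(y)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p_value, unname(ref$p.value), tolerance = 1e-12)
  }
})

test_that("Friedman post hoc flags only clearly separated treatments", {
  # strong, consistent separation across many blocks
  y <- matrix(rep(c(1, 10, 20), 12), 12, 3, byrow = TRUE)
  fr <- friedman_test(y)
  expect_true(all(fr$posthoc$significant))
  y0 <- matrix(runif(9), 3, 3)
  expect_equal(sum(friedman_test(matrix(5, 3, 3))$posthoc$significant), 0)
})

test_that("basic univariate tests behave algebraically", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(t_test_sqrt(x, x, sqrt_transform = FALSE)$statistic, 0)
  # ANOVA with two groups equals the squared pooled t
  set.seed(3)
  a <- rnorm(12, 5); b <- rnorm(12, 6)
  tt <- t_test_sqrt(a, b, sqrt_transform = FALSE, var_equal = TRUE)
  an <- anova_sqrt(c(a, b), rep(c("a", "b"), each = 12),
                   sqrt_transform = FALSE)
  expect_equal(an$statistic, tt$statistic^2, tolerance = 1e-10)
  # ten-SD separation is decisive
  big <- t_test_sqrt(rnorm(20, 0, 1), rnorm(20, 10, 1),
                     sqrt_transform = FALSE)
  expect_lt(big$p_value, 1e-6)
  reg <- ols_slope_test(1:10, 2 * (1:10) + rnorm(10, 0, 1e-8))
  expect_equal(reg$slope, 2, tolerance = 1e-6)
})
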