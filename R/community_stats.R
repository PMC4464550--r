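# Natively implemented community statistics: Bray-Curtis dissimilarity,
# ANOSIM with permutation (or exhaustive) p-values, principal coordinates
# and principal components analysis, and Friedman rank tests with a
# Siegel-Castellan post hoc. Ordinary univariate fits delegate to stats.

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' sum(|x - y|) / sum(x + y), in [0, 1] for non-negative data.
#'
#' @param x,y equal-length non-negative numeric vectors.
#' @return dissimilarity in [0, 1].
#' @examples
#' bray_curtis(c(1, 2), c(3, 0)) # 4/6
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) validation_error("vectors must align")
  if (any(x < 0) || any(y < 0)) validation_error("abundances must be >= 0")
  s <- sum(x + y)
  if (s == 0) validation_error("Bray-Curtis undefined for two all-zero vectors")
  sum(abs(x - y)) / s
}

#' Pairwise dissimilarity matrix
#'
#' @param mat samples x taxa non-negative matrix.
#' @param method `"bray_curtis"` or `"euclidean"`.
#' @return object of class `dissimilarity`: the full symmetric matrix with
#'   zero diagonal, attribute `method`.
#' @export
dissimilarity_matrix <- function(mat, method = c("bray_curtis", "euclidean")) {
  method <- match.arg(method)
  mat <- as.matrix(mat)
  n <- nrow(mat)
  if (n < 2L) validation_error("need >= 2 samples")
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- if (method == "bray_curtis")
        bray_curtis(mat[i, ], mat[j, ])
      else sqrt(sum((mat[i, ] - mat[j, ])^2))
    }
  }
  structure(d, method = method, class = c("dissimilarity", "matrix"))
}

as_dist_matrix <- function(d) {
  m <- unclass(as.matrix(d))
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-12 ||
      any(abs(diag(m)) > 1e-12))
    validation_error("not a symmetric zero-diagonal dissimilarity matrix")
  m
}

# All distinct assignments of group labels to positions (multiset
# permutations); feasible only for small n, used for exact ANOSIM p-values.
multiset_permutations <- function(labels) {
  labels <- as.character(labels)
  rec <- function(pool) {
    if (length(pool) == 0L) return(list(character(0)))
    out <- list()
    for (u in unique(pool)) {
      rest <- pool[-match(u, pool)]
      for (tail in rec(rest)) out[[length(out) + 1L]] <- c(u, tail)
    }
    out
  }
  rec(sort(labels))
}

#' Analysis of similarities (ANOSIM)
#'
#' Ranks all between-sample dissimilarities (average ranks for ties) and
#' contrasts mean between-group and within-group ranks:
#' R = (rB - rW) / (n (n - 1) / 4), in [-1, 1]. The p-value is estimated
#' over random relabelings as (1 + exceedances) / (n_perm + 1), or computed
#' exactly over every distinct labeling with `exhaustive = TRUE`.
#'
#' @param d a [dissimilarity_matrix()] (or any symmetric matrix).
#' @param grouping group label per sample; >= 2 groups of >= 2 samples.
#' @param n_perm number of random permutations.
#' @param seed integer seed for the permutations.
#' @param exhaustive enumerate all distinct labelings instead (small n).
#' @return list of class `anosim_result`: `statistic`, `p_value`,
#'   `n_perm`, `group_sizes`, `mean_rank_between`, `mean_rank_within`,
#'   `exhaustive`.
#' @export
anosim <- function(d, grouping, n_perm = 999L, seed = 1L,
                   exhaustive = FALSE) {
  m <- as_dist_matrix(d)
  n <- nrow(m)
  g <- as.character(grouping)
  if (length(g) != n) validation_error("grouping must match sample count")
  sizes <- table(g)
  if (length(sizes) < 2L || any(sizes < 2L))
    validation_error("ANOSIM needs >= 2 groups with >= 2 samples each")
  ut <- upper.tri(m)
  ii <- row(m)[ut]; jj <- col(m)[ut]
  rk <- rank(m[ut]) # average ranks on ties
  denom <- n * (n - 1) / 4
  r_of <- function(within) {
    (mean(rk[!within]) - mean(rk[within])) / denom
  }
  w_obs <- g[ii] == g[jj]
  r_obs <- r_of(w_obs)
  if (exhaustive) {
    perms <- multiset_permutations(g)
    r_all <- vapply(perms, function(p) r_of(p[ii] == p[jj]), 0)
    p <- mean(r_all >= r_obs)
    n_used <- length(perms)
  } else {
    gi <- as.integer(factor(g))
    w_mat <- with_stream(seed, "anosim", {
      G <- vapply(seq_len(n_perm), function(i) sample(gi), integer(n))
      G[ii, , drop = FALSE] == G[jj, , drop = FALSE]
    })
    nw <- colSums(w_mat)
    sw <- colSums(rk * w_mat)
    M <- length(rk)
    r_perm <- (((sum(rk) - sw) / (M - nw)) - sw / nw) / denom
    p <- (1 + sum(r_perm >= r_obs)) / (n_perm + 1)
    n_used <- n_perm
  }
  structure(list(statistic = r_obs, p_value = p, n_perm = n_used,
                 group_sizes = as.integer(sizes),
                 mean_rank_between = mean(rk[!w_obs]),
                 mean_rank_within = mean(rk[w_obs]),
                 exhaustive = exhaustive),
            class = "anosim_result")
}

#' @export
print.anosim_result <- function(x, ...) {
  cat(sprintf("ANOSIM R = %.4f, p = %.4g (%s, %d %s)\n",
              x$statistic, x$p_value,
              if (x$exhaustive) "exhaustive" else "permutation",
              x$n_perm,
              if (x$exhaustive) "labelings" else "permutations"))
  invisible(x)
}

#' Principal coordinates analysis (metric MDS)
#'
#' Gower double-centering of -d^2/2 followed by an eigendecomposition;
#' coordinates are eigenvectors scaled by the square root of their
#' (positive) eigenvalues. Negative eigenvalues, which arise for
#' semi-metric coefficients such as Bray-Curtis, are reported rather than
#' silently dropped.
#'
#' @param d a [dissimilarity_matrix()] (or symmetric matrix).
#' @param k number of coordinate axes to return.
#' @return list of class `pcoa_result`: `points` (n x k), `eigenvalues`
#'   (all n), `explained` (fractions of the positive eigenvalue sum).
#' @export
pcoa <- function(d, k = 2L) {
  m <- as_dist_matrix(d)
  n <- nrow(m)
  a <- -0.5 * m^2
  ctr <- diag(n) - matrix(1 / n, n, n)
  b <- ctr %*% a %*% ctr
  e <- eigen((b + t(b)) / 2, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9
  pos <- which(e$values > tol)
  if (k > length(pos)) {
    warning(sprintf("only %d positive eigenvalue(s); truncating k from %d",
                    length(pos), k))
    k <- length(pos)
  }
  pts <- e$vectors[, pos[seq_len(k)], drop = FALSE] %*%
    diag(sqrt(e$values[pos[seq_len(k)]]), k)
  rownames(pts) <- rownames(m)
  colnames(pts) <- paste0("PCo", seq_len(k))
  structure(list(points = pts, eigenvalues = e$values,
                 explained = e$values[pos] / sum(e$values[pos])),
            class = "pcoa_result")
}

#' Principal components analysis
#'
#' Column-centered covariance eigendecomposition (any transform, e.g.
#' arcsine square root, is applied upstream by the caller).
#'
#' @param mat samples x variables numeric matrix (>= 2 of each).
#' @param k components to keep (default all with positive variance).
#' @return list of class `pca_result`: `scores`, `loadings`,
#'   `explained` (fractions summing to 1 over retained variance),
#'   `eigenvalues`, `flag` (`"ok"` or `"degenerate"` for a constant
#'   matrix).
#' @export
pca <- function(mat, k = NULL) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2L || ncol(mat) < 2L)
    validation_error("PCA needs >= 2 samples and >= 2 variables")
  x <- scale(mat, center = TRUE, scale = FALSE)
  cv <- crossprod(x) / (nrow(x) - 1)
  e <- eigen((cv + t(cv)) / 2, symmetric = TRUE)
  tol <- max(1e-300, max(abs(e$values)) * 1e-12)
  if (all(e$values <= tol)) {
    return(structure(list(scores = NULL, loadings = NULL,
                          explained = NULL, eigenvalues = e$values,
                          flag = "degenerate"), class = "pca_result"))
  }
  pos <- which(e$values > tol)
  if (is.null(k)) k <- length(pos)
  k <- min(k, length(pos))
  keep <- pos[seq_len(k)]
  scores <- x %*% e$vectors[, keep, drop = FALSE]
  rownames(scores) <- rownames(mat)
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(scores = scores,
                 loadings = e$vectors[, keep, drop = FALSE],
                 explained = e$values[pos] / sum(e$values[pos]),
                 eigenvalues = e$values, flag = "ok"),
            class = "pca_result")
}

#' Friedman rank test with Siegel-Castellan post hoc
#'
#' Within-block average ranks (ties averaged); the statistic is
#' chi2 = 12 / (n k (k + 1)) * sum_j R_j^2 - 3 n (k + 1) on k - 1 degrees
#' of freedom, with R_j the treatment rank sums over n blocks. The post hoc
#' compares |R_j - R_l| against z_(1 - alpha / (k (k - 1))) *
#' sqrt(n k (k + 1) / 6), a Bonferroni-style family control.
#'
#' @param y blocks x treatments numeric matrix (no missing cells).
#' @param alpha family error rate for the post hoc.
#' @return list of class `friedman_result`: `statistic`, `df`, `p_value`,
#'   `rank_sums`, `n_blocks`, `k_treatments`, `posthoc` (data.frame of
#'   pairwise comparisons).
#' @export
friedman_test <- function(y, alpha = 0.05) {
  y <- as.matrix(y)
  if (anyNA(y)) validation_error("Friedman test requires complete blocks")
  n <- nrow(y); k <- ncol(y)
  if (n < 2L || k < 2L)
    validation_error("need >= 2 blocks and >= 2 treatments")
  rk <- t(apply(y, 1L, rank)) # average ranks within each block
  rj <- colSums(rk)
  stat <- 12 / (n * k * (k + 1)) * sum(rj^2) - 3 * n * (k + 1)
  p <- stats::pchisq(stat, df = k - 1, lower.tail = FALSE)
  crit <- stats::qnorm(1 - alpha / (k * (k - 1))) * sqrt(n * k * (k + 1) / 6)
  pairs <- utils::combn(k, 2L)
  trt <- colnames(y)
  if (is.null(trt)) trt <- paste0("T", seq_len(k))
  posthoc <- data.frame(
    treatment_1 = trt[pairs[1L, ]], treatment_2 = trt[pairs[2L, ]],
    rank_sum_diff = abs(rj[pairs[1L, ]] - rj[pairs[2L, ]]),
    critical = crit, stringsAsFactors = FALSE)
  posthoc$significant <- posthoc$rank_sum_diff > crit
  rownames(posthoc) <- NULL
  structure(list(statistic = stat, df = k - 1, p_value = p,
                 rank_sums = stats::setNames(rj, trt), n_blocks = n,
                 k_treatments = k, posthoc = posthoc),
            class = "friedman_result")
}

#' @export
print.friedman_result <- function(x, ...) {
  cat(sprintf("Friedman chi2 = %.4g, df = %d, p = %.4g (%d blocks, %d treatments)\n",
              x$statistic, x$df, x$p_value, x$n_blocks, x$k_treatments))
  if (any(x$posthoc$significant))
    cat("  post hoc significant pairs:",
        sum(x$posthoc$significant), "of", nrow(x$posthoc), "\n")
  invisible(x)
}

test_row <- function(method, statistic, df, p, transform) {
  data.frame(method = method, statistic = statistic, df = df,
             p_value = p, transform = transform, stringsAsFactors = FALSE)
}

#' Two-sample or paired t-test, optionally on square roots
#'
#' @param x,y numeric samples.
#' @param sqrt_transform apply the square-root transform first (the
#'   convention for count- and pressure-like responses here).
#' @param var_equal pooled-variance test instead of Welch.
#' @param paired paired test.
#' @return one-row data.frame: `method`, `statistic`, `df`, `p_value`,
#'   `transform`.
#' @export
t_test_sqrt <- function(x, y, sqrt_transform = TRUE, var_equal = FALSE,
                        paired = FALSE) {
  if (length(x) < 2L || length(y) < 2L)
    validation_error("need >= 2 observations per sample")
  if (sqrt_transform) {
    if (any(x < 0) || any(y < 0))
      validation_error("square-root transform needs non-negative data")
    x <- sqrt(x); y <- sqrt(y)
  }
  tt <- stats::t.test(x, y, var.equal = var_equal, paired = paired)
  test_row(if (paired) "paired_t" else "t", unname(tt$statistic),
           unname(tt$parameter), tt$p.value,
           if (sqrt_transform) "sqrt" else "none")
}

#' One-way ANOVA, optionally on square roots
#'
#' @param values response vector.
#' @param groups factor-like group labels.
#' @inheritParams t_test_sqrt
#' @return one-row data.frame as in [t_test_sqrt()] (statistic is F,
#'   `df` the between-group degrees of freedom, `df_resid` added).
#' @export
anova_sqrt <- function(values, groups, sqrt_transform = TRUE) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L || any(table(groups) < 2L))
    validation_error("need >= 2 groups with >= 2 observations")
  if (sqrt_transform) {
    if (any(values < 0))
      validation_error("square-root transform needs non-negative data")
    values <- sqrt(values)
  }
  fit <- stats::aov(values ~ groups)
  sm <- summary(fit)[[1L]]
  out <- test_row("anova", sm[["F value"]][1L], sm[["Df"]][1L],
                  sm[["Pr(>F)"]][1L],
                  if (sqrt_transform) "sqrt" else "none")
  out$df_resid <- sm[["Df"]][2L]
  out
}

#' OLS slope test
#'
#' @param x predictor, @param y response.
#' @return one-row data.frame: t statistic for the slope, its df and p,
#'   plus `slope` and `r_squared` columns.
#' @export
ols_slope_test <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    validation_error("need >= 3 aligned observations")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  out <- test_row("ols_slope", sm$coefficients[2L, 3L],
                  fit$df.residual, sm$coefficients[2L, 4L], "none")
  out$slope <- unname(stats::coef(fit)[2L])
  out$r_squared <- sm$r.squared
  out
}
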