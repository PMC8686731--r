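# Whole-diet comparisons: presence/absence Bray-Curtis, permutation MANOVA,
# multivariate dispersion homogeneity, sample-based rarefaction,
# accumulation-curve ensembles and the assemblage randomization test.

#' Presence/absence Bray-Curtis (Sorensen) dissimilarity
#'
#' `d = (A + B - 2J) / (A + B)` where `A` and `B` are the richnesses of the
#' two diets and `J` the number of shared taxa. Identical diets give 0,
#' disjoint diets 1; undefined (error) when both diets are empty.
#'
#' @param a,b Binary vectors of equal length.
#' @return Dissimilarity in \[0, 1\].
#' @export
bray_curtis_presence <- function(a, b) {
  if (length(a) != length(b)) pd_validation_error("vectors differ in length")
  a <- as.numeric(a > 0); b <- as.numeric(b > 0)
  A <- sum(a); B <- sum(b)
  if (A + B == 0)
    pd_validation_error("dissimilarity undefined: both diets are empty")
  J <- sum(a * b)
  (A + B - 2 * J) / (A + B)
}

#' Pairwise presence/absence Bray-Curtis distances among specimens
#'
#' @param pm A [presence_matrix()] (taxa x specimens; empty specimens are
#'   excluded at construction).
#' @return A `"prey_dist"` object: symmetric matrix with zero diagonal and a
#'   `groups` attribute carrying specimen sex.
#' @export
pairwise_distances <- function(pm) {
  m <- unwrap(pm)
  A <- colSums(m)
  Jm <- crossprod(m)               # shared-taxon counts
  S <- outer(A, A, "+")
  d <- (S - 2 * Jm) / S
  diag(d) <- 0
  structure(d, class = c("prey_dist", "matrix"),
            groups = attr(pm, "sex"))
}

upper_tri_mean <- function(d) mean(d[upper.tri(d)])

#' Mean pairwise dissimilarity with a BCa bootstrap interval
#'
#' The resampling unit is the specimen: each bootstrap replicate resamples
#' specimen columns with replacement and recomputes the mean of the
#' resampled pairwise distances (duplicated specimens contribute zero
#' distances, as they should).
#'
#' @param d A `"prey_dist"` matrix (or any symmetric distance matrix).
#' @param B Bootstrap resamples.
#' @param alpha Two-sided error level.
#' @param seed Optional seed.
#' @return List with `mean` and `ci` (`c(lo, hi)`).
#' @export
mean_dissimilarity <- function(d, B = 2000, alpha = 0.05, seed = NULL) {
  n <- ncol(d)
  stat <- function(idx) upper_tri_mean(d[idx, idx, drop = FALSE])
  t0 <- upper_tri_mean(d)
  t_boot <- with_seed(seed, vapply(seq_len(B), function(i)
    stat(sample.int(n, n, replace = TRUE)), 0))
  t_jack <- vapply(seq_len(n), function(i) stat(seq_len(n)[-i]), 0)
  list(mean = t0, ci = bca_interval(t0, t_boot, t_jack, alpha))
}

permanova_f <- function(d2, groups, dfb, dfw) {
  n <- length(groups)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    sub <- d2[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
  }
  ss_between <- ss_total - ss_within
  f <- (ss_between / dfb) / (ss_within / dfw)
  c(f = f, r2 = ss_between / ss_total)
}

#' One-way PERMANOVA on a distance matrix
#'
#' Pseudo-F from the squared-distance decomposition of a one-way design
#' (equivalent to the Gower-centered trace form): `F = (SS_between/(g-1)) /
#' (SS_within/(n-g))`, with `R^2 = SS_between/SS_total`. The p-value
#' permutes group labels freely and uses the add-one estimator
#' `p = (#{F* >= F} + 1)/(n_perm + 1)`, so `p` is never 0.
#'
#' @param d Distance matrix (e.g. [pairwise_distances()]).
#' @param groups Group label per specimen; `NULL` uses the matrix's `groups`
#'   attribute.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Optional seed.
#' @return A `"prey_perm_test"` list: `statistic` (pseudo-F), `R2`, `df`,
#'   `p`, `n_permutations`, `seed`.
#' @export
permanova <- function(d, groups = NULL, n_perm = 10000, seed = NULL) {
  groups <- groups %||% attr(d, "groups")
  groups <- as.character(groups)
  n <- length(groups)
  if (n != ncol(d)) pd_validation_error("groups must match matrix size")
  sizes <- table(groups)
  if (any(sizes < 2))
    pd_validation_error("every group needs at least 2 specimens")
  g <- length(sizes)
  dfb <- g - 1; dfw <- n - g
  d2 <- unclass(d)^2
  obs <- permanova_f(d2, groups, dfb, dfw)
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i)
      permanova_f(d2, sample(groups), dfb, dfw)[1], 0) >= obs[1] - 1e-12)
  })
  structure(list(statistic = unname(obs[1]), R2 = unname(obs[2]),
                 df = c(dfb, dfw), p = (exceed + 1) / (n_perm + 1),
                 n_permutations = n_perm, seed = seed,
                 method = "PERMANOVA"),
            class = "prey_perm_test")
}

#' @export
print.prey_perm_test <- function(x, ...) {
  cat(sprintf("%s: statistic(%s) = %.4g%s, p = %.4g (%d permutations)\n",
              x$method,
              paste(x$df, collapse = ","), x$statistic,
              if (!is.null(x$R2)) sprintf(", R2 = %.3g", x$R2) else "",
              x$p, x$n_permutations))
  invisible(x)
}

# Principal-coordinate embedding of a distance matrix, keeping negative-
# eigenvalue axes separated (presence/absence Bray-Curtis is non-Euclidean).
pcoa_embed <- function(d) {
  n <- ncol(d)
  a <- -0.5 * unclass(d)^2
  a <- sweep(a, 1, rowMeans(a))
  a <- sweep(a, 2, colMeans(a))  # Gower centering: A - row - col + grand
  e <- eigen(a, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-8
  pos <- e$values > tol
  neg <- e$values < -tol
  list(pos = e$vectors[, pos, drop = FALSE] %*%
         diag(sqrt(e$values[pos]), sum(pos)),
       neg = e$vectors[, neg, drop = FALSE] %*%
         diag(sqrt(-e$values[neg]), sum(neg)))
}

# Distances to group centroids with the standard real/imaginary correction:
# squared contributions of negative axes are subtracted and the squared
# distance floored at 0.
centroid_distances <- function(emb, groups) {
  z <- numeric(length(groups))
  for (g in unique(groups)) {
    idx <- which(groups == g)
    cp <- colMeans(emb$pos[idx, , drop = FALSE])
    dp <- rowSums(sweep(emb$pos[idx, , drop = FALSE], 2, cp)^2)
    dn <- 0
    if (ncol(emb$neg)) {
      cn <- colMeans(emb$neg[idx, , drop = FALSE])
      dn <- rowSums(sweep(emb$neg[idx, , drop = FALSE], 2, cn)^2)
    }
    z[idx] <- sqrt(pmax(dp - dn, 0))
  }
  z
}

anova_f <- function(z, groups) {
  gm <- mean(z)
  ssb <- ssw <- 0
  for (g in unique(groups)) {
    zi <- z[groups == g]
    ssb <- ssb + length(zi) * (mean(zi) - gm)^2
    ssw <- ssw + sum((zi - mean(zi))^2)
  }
  g <- length(unique(groups)); n <- length(z)
  if (ssw == 0) return(if (ssb == 0) 0 else Inf)
  (ssb / (g - 1)) / (ssw / (n - g))
}

#' Multivariate homogeneity of group dispersions
#'
#' Embeds the distance matrix by principal coordinates (keeping
#' negative-eigenvalue axes), computes each specimen's distance to its group
#' centroid with the standard correction, and compares group mean distances
#' with a one-way F test. The p-value is reported both from the F reference
#' distribution and from permutation of group labels.
#'
#' @inheritParams permanova
#' @return A `"prey_perm_test"` list with `statistic` (F), `df`, `p`
#'   (permutation), `p_f` (parametric), and the per-specimen `distances`.
#' @export
dispersion_homogeneity <- function(d, groups = NULL, n_perm = 999,
                                   seed = NULL) {
  groups <- as.character(groups %||% attr(d, "groups"))
  n <- length(groups)
  if (n != ncol(d)) pd_validation_error("groups must match matrix size")
  if (any(table(groups) < 2))
    pd_validation_error("every group needs at least 2 specimens")
  g <- length(unique(groups))
  emb <- pcoa_embed(d)
  z <- centroid_distances(emb, groups)
  f_obs <- anova_f(z, groups)
  exceed <- with_seed(seed, sum(vapply(seq_len(n_perm), function(i) {
    gi <- sample(groups)
    anova_f(centroid_distances(emb, gi), gi)
  }, 0) >= f_obs - 1e-12))
  structure(list(statistic = f_obs, R2 = NULL, df = c(g - 1, n - g),
                 p = (exceed + 1) / (n_perm + 1),
                 p_f = stats::pf(f_obs, g - 1, n - g, lower.tail = FALSE),
                 distances = z, n_permutations = n_perm, seed = seed,
                 method = "dispersion homogeneity (PERMDISP)"),
            class = "prey_perm_test")
}

#' Expected sample-based rarefaction curve (exact)
#'
#' `E[S(m)] = sum_i (1 - choose(n - n_i, m)/choose(n, m))` over taxa with
#' incidence `n_i` among `n` samples — the hypergeometric closed form for
#' the mean cumulative richness over random sample orderings.
#'
#' @param pm A [presence_matrix()] or binary matrix (taxa x samples).
#' @param m Integer vector of sample counts (1..n).
#' @return Numeric vector `E[S(m)]`.
#' @export
rarefaction_expected <- function(pm, m) {
  mat <- unwrap(pm) > 0
  n <- ncol(mat)
  if (any(m < 0 | m > n)) pd_validation_error("m must lie in 0..n")
  ni <- rowSums(mat)
  vapply(m, function(mm) {
    sum(1 - exp(lchoose(n - ni, mm) - lchoose(n, mm)))
  }, 0)
}

#' Random-ordering accumulation-curve ensemble
#'
#' For each of `R` randomizations, samples are taken in a uniformly random
#' order and the cumulative number of distinct taxa recorded. The endpoint
#' of every curve equals the total observed richness.
#'
#' @param pm A [presence_matrix()] or binary matrix.
#' @param R Number of randomizations (default 1000).
#' @param seed Optional seed.
#' @return A `"prey_accumulation"` list: `curves` (R x n matrix), `mean`
#'   curve, and `n_samples`.
#' @export
accumulation_ensemble <- function(pm, R = 1000, seed = NULL) {
  mat <- (unwrap(pm) > 0) + 0L
  mat <- mat[rowSums(mat) > 0, , drop = FALSE]
  n <- ncol(mat)
  curves <- with_seed(seed, {
    raw <- vapply(seq_len(R), function(r) {
      ord <- sample.int(n)
      first <- max.col(mat[, ord, drop = FALSE], ties.method = "first")
      cumsum(tabulate(first, n))
    }, numeric(n))
    # vapply drops to a vector when n = 1
    if (is.null(dim(raw))) matrix(raw, ncol = 1) else t(raw)
  })
  structure(list(curves = curves, mean = colMeans(curves), n_samples = n),
            class = "prey_accumulation")
}

# Area statistic: sum over groups of the absolute gap between the group's
# expected accumulation curve and the pooled curve, evaluated at integer
# sample counts 1..n_g.
ecotest_stat <- function(mat, groups) {
  pooled <- function(m) rarefaction_expected(mat, m)
  total <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    mg <- seq_along(idx)
    eg <- rarefaction_expected(mat[, idx, drop = FALSE], mg)
    total <- total + sum(abs(eg - pooled(mg)))
  }
  total
}

#' Assemblage randomization test on accumulation curves
#'
#' Tests whether the groups' diets are drawn from one shared prey
#' assemblage: the observed statistic is the summed absolute area between
#' each group's expected accumulation curve and the pooled curve (both by
#' exact rarefaction, evaluated at 1..n_g samples); the null distribution
#' reassigns specimens to groups of the same sizes at random.
#'
#' @param pm A [presence_matrix()].
#' @param groups Group label per specimen; `NULL` uses the sex attribute.
#' @param iterations Number of reshufflings (default 200).
#' @param seed Optional seed.
#' @return A `"prey_perm_test"` list (`statistic` = observed area).
#' @export
assemblage_ecotest <- function(pm, groups = NULL, iterations = 200,
                               seed = NULL) {
  groups <- as.character(groups %||% attr(pm, "sex"))
  mat <- unwrap(pm) > 0
  if (length(groups) != ncol(mat))
    pd_validation_error("groups must match specimen count")
  if (any(table(groups) < 2))
    pd_validation_error("every group needs at least 2 specimens")
  obs <- ecotest_stat(mat, groups)
  exceed <- with_seed(seed, sum(vapply(seq_len(iterations), function(i)
    ecotest_stat(mat, sample(groups)), 0) >= obs - 1e-9))
  structure(list(statistic = obs, R2 = NULL,
                 df = c(length(unique(groups)) - 1, ncol(mat)),
                 p = (exceed + 1) / (iterations + 1),
                 n_permutations = iterations, seed = seed,
                 method = "assemblage randomization (accumulation curves)"),
            class = "prey_perm_test")
}
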