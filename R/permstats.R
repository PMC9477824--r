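# Distance-based multivariate statistics: PCoA, PERMANOVA, PERMDISP,
# NMDS, Mantel. All permutation schedules run under an explicit seed.

check_dist <- function(D, tol = 1e-8) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) {
    stop("distance input must be a square matrix")
  }
  if (max(abs(D - t(D))) > tol) stop("distance matrix is not symmetric")
  if (max(abs(diag(D))) > tol) stop("distance matrix diagonal is not zero")
  invisible(D)
}

#' Principal coordinates analysis (classical scaling)
#'
#' Eigen-decomposes the Gower-centered matrix `-1/2 J D^2 J`. Axes with
#' positive eigenvalues carry real coordinates; axes with negative
#' eigenvalues (semi-metric dissimilarities such as Bray-Curtis) are kept
#' as imaginary coordinates so that corrected squared distances can be
#' formed as (real part) - (imaginary part).
#'
#' @param D Symmetric dissimilarity matrix with zero diagonal.
#' @param tol Eigenvalues within `tol * max(|eig|)` of zero are dropped.
#' @return Object of class `pcoa`: list with `points` (n x p real axes),
#'   `neg_points` (n x q imaginary axes), `eig` (all eigenvalues), `ids`.
#' @export
pcoa <- function(D, tol = 1e-8) {
  check_dist(D)
  n <- nrow(D)
  A <- -0.5 * D^2
  G <- sweep(A, 1, rowMeans(A))
  G <- sweep(G, 2, colMeans(G))
  G <- (G + t(G)) / 2
  e <- eigen(G, symmetric = TRUE)
  cut <- tol * max(abs(e$values), 1e-300)
  pos <- e$values > cut
  neg <- e$values < -cut
  ids <- rownames(D) %||% as.character(seq_len(n))
  pts <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), sum(pos))
  npts <- e$vectors[, neg, drop = FALSE] %*%
    diag(sqrt(-e$values[neg]), sum(neg))
  rownames(pts) <- rownames(npts) <- ids
  structure(list(points = pts, neg_points = npts, eig = e$values,
                 ids = ids, trace = sum(diag(G))),
            class = "pcoa")
}

# Sum over groups of within-group squared distances / group size.
ss_within <- function(d2, group_idx) {
  s <- 0
  for (idx in group_idx) s <- s + sum(d2[idx, idx]) / (2 * length(idx))
  s
}

permanova_f <- function(d2, groups) {
  n <- nrow(d2)
  gi <- split(seq_len(n), groups)
  sst <- sum(d2) / (2 * n)
  ssw <- ss_within(d2, gi)
  g <- length(gi)
  list(F = ((sst - ssw) / (g - 1)) / (ssw / (n - g)),
       R2 = (sst - ssw) / sst, df = c(g - 1, n - g))
}

# All permutations of 1..n as rows (guarded small n).
all_permutations <- function(n) {
  if (n > 9) stop("exhaustive enumeration limited to n <= 9")
  rec <- function(v) {
    if (length(v) == 1) return(matrix(v, 1, 1))
    do.call(rbind, lapply(seq_along(v), function(i) {
      cbind(v[i], rec(v[-i]))
    }))
  }
  rec(seq_len(n))
}

draw_permutations <- function(n, n_perm, strata = NULL) {
  if (is.null(strata)) {
    return(t(replicate(n_perm, sample.int(n))))
  }
  strata <- as.factor(strata)
  idx <- split(seq_len(n), strata)
  t(replicate(n_perm, {
    p <- seq_len(n)
    for (s in idx) p[s] <- s[sample.int(length(s))]
    p
  }))
}

#' Permutational multivariate analysis of variance (one-way)
#'
#' Partitions the total sum of squared dissimilarities by a grouping
#' factor: `SS_total = sum_{i<j} d_ij^2 / n`, `SS_within` analogously per
#' group, giving the pseudo-F `((SS_b/(g-1)) / (SS_w/(n-g)))` and
#' `R^2 = SS_b / SS_total`. Significance is assessed by permuting sample
#' labels, freely or within `strata` (experimental blocks); the estimator
#' includes the observed statistic, `p = (1 + b)/(1 + n_perm)`, so p is
#' never 0. With `n_perm = "exact"` all label permutations are enumerated
#' and p is the exact proportion with `F >= F_obs`.
#'
#' @param D Symmetric dissimilarity matrix with zero diagonal.
#' @param groups Grouping vector/factor, one label per sample.
#' @param n_perm Number of permutations, or `"exact"`.
#' @param seed RNG seed for the permutation schedule.
#' @param strata Optional blocking factor restricting permutations.
#' @return Object of class `permanova_result` with `F`, `R2`, `p`,
#'   `n_perm`, `df`, `exact`.
#' @export
permanova <- function(D, groups, n_perm = 999, seed = NULL, strata = NULL) {
  check_dist(D)
  groups <- as.factor(groups)
  n <- nrow(D)
  if (length(groups) != n) stop("one group label per sample required")
  if (nlevels(droplevels(groups)) < 2) stop("need >= 2 groups")
  if (n - nlevels(droplevels(groups)) < 1) {
    stop("all groups are singletons; within-group SS undefined")
  }
  d2 <- D^2
  obs <- permanova_f(d2, groups)
  eps <- 1e-12
  if (identical(n_perm, "exact")) {
    P <- all_permutations(n)
    Fs <- apply(P, 1, function(p) permanova_f(d2, groups[p])$F)
    pval <- mean(Fs >= obs$F - eps)
    n_used <- nrow(P)
    exact <- TRUE
  } else {
    P <- with_seed(seed, draw_permutations(n, n_perm, strata))
    Fs <- apply(P, 1, function(p) permanova_f(d2, groups[p])$F)
    pval <- (1 + sum(Fs >= obs$F - eps)) / (1 + n_perm)
    n_used <- n_perm
    exact <- FALSE
  }
  structure(list(F = obs$F, R2 = obs$R2, p = pval, n_perm = n_used,
                 df = obs$df, exact = exact, seed = seed),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4f (df %d, %d), R2 = %.4f, p = %.4g%s\n",
              x$F, x$df[1], x$df[2], x$R2, x$p,
              if (x$exact) " (exact)" else sprintf(" (%d permutations)",
                                                   x$n_perm)))
  invisible(x)
}

#' Pairwise post-hoc PERMANOVA between all group pairs
#'
#' @inheritParams permanova
#' @param correction Multiple-testing correction over the pairs: `"none"`
#'   (raw p, the default) or `"BH"` (Benjamini-Hochberg).
#' @return Data frame with one row per pair: `a`, `b`, `F`, `R2`, `p`,
#'   `p_adj`.
#' @export
pairwise_permanova <- function(D, groups, n_perm = 999, seed = NULL,
                               strata = NULL,
                               correction = c("none", "BH")) {
  correction <- match.arg(correction)
  groups <- as.factor(groups)
  levs <- levels(droplevels(groups))
  pairs <- utils::combn(levs, 2)
  seeds <- derive_seeds(seed, ncol(pairs))
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    keep <- groups %in% pairs[, k]
    res <- permanova(D[keep, keep, drop = FALSE], droplevels(groups[keep]),
                     n_perm = n_perm, seed = seeds[[k]],
                     strata = if (is.null(strata)) NULL else strata[keep])
    data.frame(a = pairs[1, k], b = pairs[2, k],
               F = res$F, R2 = res$R2, p = res$p)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- if (correction == "BH") stats::p.adjust(out$p, "BH") else out$p
  out
}

# Fast one-way ANOVA F on a numeric vector (internal permutation engine).
f_oneway <- function(values, groups) {
  gi <- split(values, groups)
  n <- length(values); g <- length(gi)
  ssb <- sum(vapply(gi, function(v) length(v) * (mean(v) - mean(values))^2,
                    numeric(1)))
  ssw <- sum(vapply(gi, function(v) sum((v - mean(v))^2), numeric(1)))
  # all values (near-)identical: no dispersion signal at all
  if (ssb + ssw <= 1e-12 * max(mean(values)^2, 1) * n) return(0)
  ((ssb / (g - 1)) / (ssw / (n - g)))
}

#' Homogeneity of multivariate dispersions (PERMDISP)
#'
#' Embeds the dissimilarity matrix by PCoA and measures each sample's
#' distance to its group centroid, with imaginary axes contributing
#' negatively to the squared distance (clamped at zero). Group differences
#' in these dispersions are tested with a one-way ANOVA F whose null
#' distribution comes from relabelling the samples and recomputing the
#' centroid distances for every permutation, which keeps the test exact
#' under exchangeability even for small groups.
#'
#' @inheritParams permanova
#' @return List with `F`, `p`, `dispersion` (per-group means),
#'   `distances` (per-sample centroid distances), `n_perm`.
#' @export
permdisp <- function(D, groups, n_perm = 999, seed = NULL) {
  check_dist(D)
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2) stop("need >= 2 groups")
  if (any(table(droplevels(groups)) < 2)) {
    stop("every group needs >= 2 samples")
  }
  ord <- pcoa(D)
  z <- centroid_distances_to_own_group(ord, groups)
  obs <- f_oneway(z, groups)
  # relabel samples and recompute the centroid distances per permutation:
  # permuting precomputed dispersions ignores their dependence on the
  # group centroids and is anticonservative for small groups
  perms <- with_seed(seed, draw_permutations(length(z), n_perm))
  Fs <- apply(perms, 1, function(p) {
    gp <- groups[p]
    f_oneway(centroid_distances_to_own_group(ord, gp), gp)
  })
  p <- (1 + sum(Fs >= obs - 1e-12)) / (1 + n_perm)
  list(F = obs, p = p,
       dispersion = tapply(z, groups, mean),
       distances = z, n_perm = n_perm)
}

centroid_distances_to_own_group <- function(ord, groups) {
  gi <- as.integer(as.factor(groups))
  sq_part <- function(X) {
    if (ncol(X) == 0) return(numeric(nrow(X)))
    C <- rowsum(X, gi, reorder = TRUE) / tabulate(gi)
    rowSums(X^2) - 2 * rowSums(X * C[gi, , drop = FALSE]) +
      rowSums(C^2)[gi]
  }
  z2 <- sq_part(ord$points) - sq_part(ord$neg_points)
  sqrt(pmax(z2, 0))
}

#' Distance between two group centroids in corrected PCoA space
#'
#' Squared centroid separation is the difference of squared real-axis and
#' imaginary-axis separations (clamped at zero).
#'
#' @param D Symmetric dissimilarity matrix with sample ids as dimnames.
#' @param group_a,group_b Sample id (or index) vectors of the two groups.
#' @return Centroid distance (scalar).
#' @export
centroid_distance <- function(D, group_a, group_b) {
  check_dist(D)
  if (!length(group_a) || !length(group_b)) stop("empty group")
  ord <- pcoa(D)
  idx <- function(g) {
    if (is.character(g)) match(g, ord$ids) else as.integer(g)
  }
  ia <- idx(group_a); ib <- idx(group_b)
  if (anyNA(ia) || anyNA(ib)) stop("unknown sample id in group")
  dp <- colMeans(ord$points[ia, , drop = FALSE]) -
    colMeans(ord$points[ib, , drop = FALSE])
  dn <- colMeans(ord$neg_points[ia, , drop = FALSE]) -
    colMeans(ord$neg_points[ib, , drop = FALSE])
  sqrt(max(sum(dp^2) - sum(dn^2), 0))
}

lower_tri <- function(D) D[lower.tri(D)]

#' Mantel test of matrix correlation
#'
#' Pearson correlation of the off-diagonal entries of two distance
#' matrices; significance (one-sided, positive association) by jointly
#' permuting rows and columns of the second matrix.
#'
#' @param D1,D2 Symmetric dissimilarity matrices over the same samples
#'   (matching dimnames when present).
#' @param n_perm Number of permutations.
#' @param seed RNG seed.
#' @return List with `r`, `p`, `n_perm`.
#' @export
mantel <- function(D1, D2, n_perm = 999, seed = NULL) {
  check_dist(D1); check_dist(D2)
  if (nrow(D1) != nrow(D2)) stop("matrices differ in size")
  if (!is.null(rownames(D1)) && !is.null(rownames(D2))) {
    if (!setequal(rownames(D1), rownames(D2))) {
      stop("sample ids of the two matrices do not match")
    }
    D2 <- D2[rownames(D1), rownames(D1)]
  }
  v1 <- lower_tri(D1)
  r <- stats::cor(v1, lower_tri(D2))
  n <- nrow(D1)
  perms <- with_seed(seed, draw_permutations(n, n_perm))
  rp <- apply(perms, 1, function(p) stats::cor(v1, lower_tri(D2[p, p])))
  list(r = r, p = (1 + sum(rp >= r - 1e-12)) / (1 + n_perm),
       n_perm = n_perm)
}

#' Non-metric multidimensional scaling by stress majorization
#'
#' Minimizes Kruskal stress-1 with SMACOF iterations: disparities are fit
#' by monotone (isotonic) regression on the dissimilarity order and
#' renormalized, then the configuration is updated by the Guttman
#' transform, which cannot increase the stress. The best of `n_restarts`
#' starts (classical-scaling start plus seeded random starts) is returned.
#'
#' @param D Symmetric dissimilarity matrix.
#' @param k Embedding dimension (default 2), `k < n`.
#' @param seed RNG seed for the random restarts.
#' @param n_restarts Number of starts.
#' @param max_iter,tol Iteration cap and stress-change tolerance.
#' @return Object of class `nmds_result`: `points` (n x k), `stress`
#'   (Kruskal stress-1), `trace` (stress per iteration, non-increasing),
#'   `converged`, `seed`.
#' @export
nmds <- function(D, k = 2, seed = NULL, n_restarts = 4,
                 max_iter = 300, tol = 1e-7) {
  check_dist(D)
  n <- nrow(D)
  if (k >= n) stop("k must be smaller than the number of samples")
  delta <- lower_tri(D)
  ord <- order(delta)
  starts <- vector("list", n_restarts)
  starts[[1]] <- suppressWarnings(
    stats::cmdscale(stats::as.dist(D), k = k))
  if (ncol(starts[[1]]) < k) {  # degenerate classical start: pad with noise
    starts[[1]] <- cbind(starts[[1]],
                         matrix(0, n, k - ncol(starts[[1]])))
  }
  if (n_restarts > 1) {
    rnd <- with_seed(seed, lapply(seq_len(n_restarts - 1), function(i) {
      matrix(stats::runif(n * k, -1, 1), n, k)
    }))
    starts[(2:n_restarts)] <- rnd
  }
  best <- NULL
  for (X0 in starts) {
    fit <- nmds_engine(X0, delta, ord, n, max_iter, tol)
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  rownames(best$points) <- rownames(D) %||% as.character(seq_len(n))
  structure(c(best, list(seed = seed, k = k)), class = "nmds_result")
}

nmds_engine <- function(X, delta, ord, n, max_iter, tol) {
  m <- length(delta)
  li <- lower.tri(matrix(0, n, n))
  dist_vec <- function(X) lower_tri(as.matrix(stats::dist(X)))
  trace <- numeric(0)
  last <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    dis <- dist_vec(X)
    iso <- stats::isoreg(seq_len(m), dis[ord])
    dhat <- numeric(m)
    dhat[ord] <- iso$yf
    dhat <- dhat * sqrt(m / sum(dhat^2))
    stress <- sqrt(sum((dis - dhat)^2) / sum(dis^2))
    trace <- c(trace, stress)
    if (is.finite(last) && last - stress < tol) {
      # Terminate on non-improvement; a (numerical) uptick is discarded so
      # the reported trace is the monotone majorization sequence.
      converged <- TRUE
      if (stress > last) trace <- trace[-length(trace)]
      break
    }
    last <- stress
    # Guttman transform
    ratio <- ifelse(dis > 0, dhat / dis, 0)
    B <- matrix(0, n, n)
    B[li] <- -ratio
    B <- B + t(B)
    diag(B) <- -rowSums(B)
    X <- B %*% X / n
  }
  list(points = X, stress = min(trace), trace = trace,
       converged = converged, iterations = length(trace))
}

#' @export
print.nmds_result <- function(x, ...) {
  cat(sprintf("NMDS (k = %d): stress-1 = %.5f after %d iteration(s)%s\n",
              x$k, x$stress, x$iterations,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}
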