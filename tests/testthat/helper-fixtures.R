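# Shared fixtures, built in code.

# Euclidean distance matrix from a coordinate matrix, with sample ids.
coord_dist <- function(X, ids = NULL) {
  D <- as.matrix(stats::dist(X))
  ids <- ids %||% sprintf("s%02d", seq_len(nrow(X)))
  dimnames(D) <- list(ids, ids)
  D
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small random community table under a fixed seed.
random_community <- function(n_taxa = 15, n_samples = 6, depth = 500,
                             seed = 1) {
  soildispersal:::with_seed(seed, {
    mat <- vapply(seq_len(n_samples), function(i) {
      p <- stats::rgamma(n_taxa, shape = 0.7)
      as.integer(stats::rmultinom(1, depth, p / sum(p))[, 1])
    }, integer(n_taxa))
  })
  dimnames(mat) <- list(sprintf("t%02d", seq_len(n_taxa)),
                        sprintf("s%02d", seq_len(n_samples)))
  mat
}

# A small, fast experiment configuration for end-to-end tests.
small_config <- function(...) {
  experiment_config(n_blocks = 4, n_taxa = 48, seq_depth = 300, ...)
}

# Independent McArdle-Anderson route to the PERMANOVA F: Gower-center the
# squared distances and project onto the group design (hat matrix).
permanova_f_hat <- function(D, groups) {
  n <- nrow(D)
  groups <- as.factor(groups)
  A <- -0.5 * D^2
  J <- diag(n) - matrix(1 / n, n, n)
  G <- J %*% A %*% J
  Xd <- stats::model.matrix(~ groups)
  H <- Xd %*% solve(crossprod(Xd)) %*% t(Xd)
  ssb <- sum(diag(H %*% G %*% H))
  sst <- sum(diag(G))
  g <- nlevels(groups)
  ((ssb / (g - 1)) / ((sst - ssb) / (n - g)))
}
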