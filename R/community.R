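#' Rarefy a community table to a fixed depth with resampling
#'
#' Draws `depth` reads per sample without replacement (multivariate
#' hypergeometric), repeated `n_resamplings` times, and averages. Samples
#' whose total is below `depth` are dropped and reported in the `"dropped"`
#' attribute. Under this scheme the expected rarefied count of taxon i in a
#' sample with counts x and total N is `depth * x_i / N`.
#'
#' @param table Taxa x sample integer matrix.
#' @param depth Target depth (reads per sample), >= 1.
#' @param n_resamplings Number of independent resamplings to average over.
#' @param seed RNG seed for the resampling stream.
#' @param keep If `TRUE`, also return the individual resampled tables.
#' @return Object of class `rarefied_table`: list with `mean` (taxa x sample
#'   numeric matrix), `depth`, `n_resamplings`, and (if `keep`) `draws`.
#'   Attribute `"dropped"` lists excluded sample ids.
#' @export
rarefy <- function(table, depth, n_resamplings = 1, seed = NULL,
                   keep = FALSE) {
  if (depth < 1) stop("depth must be >= 1")
  check_community(table)
  totals <- colSums(table)
  dropped <- colnames(table)[totals < depth]
  table <- table[, totals >= depth, drop = FALSE]
  if (ncol(table) == 0) stop("no sample reaches the rarefaction depth")
  draws <- if (keep) vector("list", n_resamplings) else NULL
  acc <- matrix(0, nrow(table), ncol(table), dimnames = dimnames(table))
  with_seed(seed, {
    for (b in seq_len(n_resamplings)) {
      tab <- apply(table, 2, rarefy_once, depth = depth)
      acc <- acc + tab
      if (keep) {
        dimnames(tab) <- dimnames(table)
        draws[[b]] <- tab
      }
    }
  })
  out <- list(mean = acc / n_resamplings, depth = depth,
              n_resamplings = n_resamplings, draws = draws)
  attr(out, "dropped") <- dropped
  class(out) <- "rarefied_table"
  out
}

# One without-replacement draw of `depth` reads from count vector x.
rarefy_once <- function(x, depth) {
  reads <- sample.int(sum(x), depth)
  breaks <- c(0, cumsum(x))
  tabulate(findInterval(reads, breaks, left.open = TRUE),
           nbins = length(x))
}

check_community <- function(table) {
  if (!is.matrix(table)) stop("community table must be a matrix")
  if (any(table < 0)) stop("community table has negative entries")
  if (anyDuplicated(colnames(table))) stop("duplicate sample ids")
  invisible(table)
}

#' Bray-Curtis dissimilarity between two count vectors
#'
#' `BC(x, y) = sum |x_i - y_i| / sum (x_i + y_i)`, in `[0, 1]`: 0 for
#' identical vectors, 1 for disjoint supports.
#'
#' @param x,y Non-negative numeric vectors of equal length, not both zero.
#' @return The dissimilarity.
#' @export
#' @examples
#' bray_curtis(c(6, 2, 0), c(2, 2, 4))  # 0.5
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) stop("vectors differ in length")
  if (any(x < 0) || any(y < 0)) stop("counts must be non-negative")
  tot <- sum(x) + sum(y)
  if (tot == 0) stop("both vectors are all-zero")
  sum(abs(x - y)) / tot
}

#' Pairwise Bray-Curtis distance matrix over the samples of a table
#'
#' @param table Taxa x sample matrix (counts or averaged rarefied counts).
#' @return Symmetric `dist_matrix` (plain matrix with sample dimnames,
#'   zero diagonal).
#' @export
bray_curtis_matrix <- function(table) {
  n <- ncol(table)
  D <- matrix(0, n, n, dimnames = list(colnames(table), colnames(table)))
  for (i in seq_len(n - 1)) {
    xi <- table[, i]
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- bray_curtis(xi, table[, j])
    }
  }
  D
}

#' Mean Bray-Curtis distances across rarefaction resamplings
#'
#' Computes the distance matrix within each rarefaction resampling and
#' averages the matrices, so sampling-depth noise is integrated out at the
#' distance level rather than the count level.
#'
#' @inheritParams rarefy
#' @param n_resamplings Number of resamplings to average over.
#' @return Symmetric matrix of averaged dissimilarities.
#' @export
rarefied_bray_curtis <- function(table, depth, n_resamplings = 100,
                                 seed = NULL) {
  check_community(table)
  totals <- colSums(table)
  table <- table[, totals >= depth, drop = FALSE]
  if (ncol(table) < 2) stop("need >= 2 samples at depth")
  acc <- 0
  with_seed(seed, {
    for (b in seq_len(n_resamplings)) {
      tab <- apply(table, 2, rarefy_once, depth = depth)
      acc <- acc + bray_curtis_matrix(tab)
    }
  })
  D <- acc / n_resamplings
  dimnames(D) <- list(colnames(table), colnames(table))
  D
}

#' Shannon diversity (natural-log units)
#'
#' `H = -sum p_i ln p_i` over the positive relative abundances of a count
#' vector.
#'
#' @param x Non-negative counts with positive sum.
#' @return Shannon index in nats.
#' @export
#' @examples
#' shannon(rep(5, 4))  # log(4)
shannon <- function(x) {
  if (any(x < 0)) stop("counts must be non-negative")
  if (sum(x) == 0) stop("all-zero sample")
  p <- x[x > 0] / sum(x)
  -sum(p * log(p))
}
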