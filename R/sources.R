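#' Attribute a sink community to fixed source profiles by multinomial EM
#'
#' Models the sink count vector as a multinomial draw from a convex
#' mixture of known source relative-abundance profiles plus, optionally,
#' an "unknown" component whose profile is re-estimated from the EM
#' responsibilities. Source profiles are smoothed with a pseudocount
#' (default `1/n_taxa` per taxon) before normalization, so sink taxa
#' absent from a source retain small nonzero probability. Initialisation
#' is deterministic (uniform mixing weights; unknown starts at 0.1 with a
#' uniform profile over observed taxa), so the estimate is seed-free.
#'
#' By default the unknown profile stays fixed at that uniform shape
#' (`unknown_profile = "fixed"`): a freely re-estimated unknown profile
#' makes the model unidentifiable, because the maximum-likelihood solution
#' is always "unknown = 1 with the sink's own empirical profile". With
#' `unknown_profile = "em"` the profile is re-estimated each M-step
#' anyway, which is only useful with few iterations or strong sources.
#'
#' @param sink Non-negative count vector over taxa (named or aligned with
#'   the rows of `sources`).
#' @param sources Taxa x source matrix of counts or relative abundances.
#' @param unknown Include an unknown component (default `TRUE`).
#' @param tol Stop when the log-likelihood improves by less than this.
#' @param max_iter Iteration cap.
#' @param pseudocount Smoothing mass added to each source profile entry
#'   before normalization; default `1/n_taxa`.
#' @param unknown_profile `"fixed"` (default) keeps the unknown component
#'   uniform over the sink's observed taxa; `"em"` re-estimates it from
#'   the responsibilities each M-step (see Details).
#' @return Object of class `mixture_estimate`: `proportions` (named,
#'   summing to 1, including `unknown` if requested), `loglik` (trace,
#'   non-decreasing), `iterations`, `converged`, `unknown_profile`.
#' @export
#' @examples
#' src <- cbind(A = c(9, 1, 0, 0), B = c(0, 0, 1, 9))
#' sink <- c(45, 5, 5, 45)
#' estimate_mixture(sink, src, unknown = FALSE)$proportions
estimate_mixture <- function(sink, sources, unknown = TRUE, tol = 1e-8,
                             max_iter = 1000, pseudocount = NULL,
                             unknown_profile = c("fixed", "em")) {
  unknown_profile <- match.arg(unknown_profile)
  if (is.null(dim(sources)) || ncol(sources) < 1) {
    stop("at least one source profile is required")
  }
  if (length(sink) != nrow(sources)) {
    stop("sink and sources must share a taxon index")
  }
  if (any(sources < 0)) stop("source profiles must be non-negative")
  if (any(sink < 0)) stop("sink counts must be non-negative")
  if (sum(sink) == 0) stop("sink is all-zero")
  n_taxa <- nrow(sources)
  pseudocount <- pseudocount %||% (1 / n_taxa)
  P <- apply(sources, 2, function(s) {
    s <- s + pseudocount  # smooth on the observed count scale
    s / sum(s)
  })
  labels <- colnames(sources) %||% paste0("source", seq_len(ncol(sources)))
  K <- ncol(P)
  if (unknown) {
    q <- as.numeric(sink > 0)
    q <- q / sum(q)
    P <- cbind(P, q)
    labels <- c(labels, "unknown")
    pi <- c(rep(0.9 / K, K), 0.1)
  } else {
    pi <- rep(1 / K, K)
  }
  y <- as.numeric(sink)
  # the EM only involves observed sink taxa: unobserved taxa contribute
  # nothing to the likelihood or the weight updates
  obs <- y > 0
  yo <- y[obs]
  Po <- P[obs, , drop = FALSE]
  if (any(rowSums(Po) == 0)) {
    stop("observed sink taxa have zero support under every component; ",
         "use a positive pseudocount or enable the unknown component")
  }
  ll_trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    mix <- as.numeric(Po %*% pi)
    if (any(mix == 0)) {
      stop("observed sink taxa have zero support under every component; ",
           "use a positive pseudocount or enable the unknown component")
    }
    ll <- sum(yo * log(mix))
    if (length(ll_trace) && ll < ll_trace[length(ll_trace)] - 1e-9) {
      stop("EM log-likelihood decreased; numerical failure")
    }
    ll_trace <- c(ll_trace, ll)
    if (length(ll_trace) > 1 &&
        ll - ll_trace[length(ll_trace) - 1] < tol) {
      converged <- TRUE
      break
    }
    # E-step: responsibilities per observed taxon x component
    R <- sweep(Po, 2, pi, `*`) / mix
    wk <- as.numeric(crossprod(R, yo))  # expected reads per component
    pi <- wk / sum(wk)
    if (unknown && unknown_profile == "em") {  # M-step for the unknown profile
      ru <- R[, ncol(R)] * yo
      if (sum(ru) > 0) {
        Po[, ncol(Po)] <- ru / sum(ru)
        P[, ncol(P)] <- 0
        P[obs, ncol(P)] <- Po[, ncol(Po)]
      }
    }
  }
  structure(list(proportions = stats::setNames(pi, labels),
                 loglik = ll_trace,
                 iterations = length(ll_trace),
                 converged = converged,
                 unknown_profile = if (unknown) P[, ncol(P)] else NULL),
            class = "mixture_estimate")
}

#' @export
print.mixture_estimate <- function(x, ...) {
  cat("Source attribution (multinomial-mixture EM)\n")
  print(round(x$proportions, 4))
  cat(sprintf("  log-likelihood %.3f after %d iteration(s)%s\n",
              x$loglik[length(x$loglik)], x$iterations,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Attribute many sink samples to labelled source communities
#'
#' Pools the source samples by label into per-source profiles, runs
#' [estimate_mixture()] on every sink column, and (when a grouping is
#' supplied) averages the proportions per group.
#'
#' @param sinks Taxa x sink-sample count matrix.
#' @param sources Taxa x source-sample count matrix.
#' @param source_labels Source name per column of `sources`; columns with
#'   the same label are pooled.
#' @param groups Optional grouping (e.g. treatment) per sink column.
#' @param ... Passed to [estimate_mixture()].
#' @return List with `proportions` (sink x component data frame) and, when
#'   grouped, `group_means`.
#' @export
attribute_samples <- function(sinks, sources, source_labels,
                              groups = NULL, ...) {
  if (length(source_labels) != ncol(sources)) {
    stop("one source label per source column required")
  }
  pooled <- vapply(split(seq_len(ncol(sources)), source_labels),
                   function(idx) rowSums(sources[, idx, drop = FALSE]),
                   numeric(nrow(sources)))
  ests <- lapply(seq_len(ncol(sinks)), function(i) {
    estimate_mixture(sinks[, i], pooled, ...)$proportions
  })
  props <- as.data.frame(do.call(rbind, ests))
  props <- cbind(sample_id = colnames(sinks) %||%
                   as.character(seq_len(ncol(sinks))), props)
  rownames(props) <- NULL
  out <- list(proportions = props)
  if (!is.null(groups)) {
    comp <- setdiff(names(props), "sample_id")
    out$group_means <- stats::aggregate(props[comp],
                                        by = list(group = groups), mean)
  }
  out
}
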