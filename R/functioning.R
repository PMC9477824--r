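#' Percent litter mass loss from wet weights and dry:wet ratios
#'
#' Dry mass before and after deployment is wet mass times the dry:wet
#' ratio measured on a subsample; decomposition is the percent decrease,
#' `100 * (dry0 - dry1) / dry0`. Losses outside `[-20, 100]` percent are
#' flagged suspect (a gain beyond measurement tolerance) with a warning.
#'
#' @param wet_initial_g,wet_final_g Wet masses (g), `wet_initial_g > 0`.
#' @param dry_ratio_initial,dry_ratio_final Dry:wet ratios in `(0, 1]`.
#'   A data frame with these four columns may be passed as the first
#'   argument instead.
#' @return Percent mass loss, vectorised.
#' @export
#' @examples
#' mass_loss_percent(10, 0.4, 5, 0.56)  # 30
mass_loss_percent <- function(wet_initial_g, dry_ratio_initial,
                              wet_final_g, dry_ratio_final) {
  if (is.data.frame(wet_initial_g)) {
    rec <- wet_initial_g
    return(mass_loss_percent(rec$wet_initial_g, rec$dry_ratio_initial,
                             rec$wet_final_g, rec$dry_ratio_final))
  }
  if (any(wet_initial_g <= 0) || any(wet_final_g < 0)) {
    stop("wet masses must be positive (final may be zero)")
  }
  ratios <- c(dry_ratio_initial, dry_ratio_final)
  if (any(ratios <= 0) || any(ratios > 1)) {
    stop("dry:wet ratios must lie in (0, 1]")
  }
  dry0 <- wet_initial_g * dry_ratio_initial
  dry1 <- wet_final_g * dry_ratio_final
  loss <- 100 * (dry0 - dry1) / dry0
  suspect <- loss < -20 | loss > 100
  if (any(suspect)) {
    warning(sprintf("%d mass-loss value(s) outside [-20, 100]%% flagged suspect",
                    sum(suspect)))
  }
  loss
}

#' Mass-loss contrasts by dispersal route
#'
#' Within each block, exposure to the above/near routes is isolated as
#' Overhead - Closed and the below route as Open - Overhead; each contrast
#' gets a mean, 95% t-interval and one-sample t-test against zero. The
#' Elevated treatment is excluded by default because its bags sit on
#' raised tables where abiotic photodegradation, not dispersal, dominates
#' its mass loss; set `include_elevated = TRUE` to add the
#' Elevated - Closed contrast. Blocks missing a required treatment are
#' dropped with a message.
#'
#' @param loss Data frame with columns `block`, `treatment`, `loss`
#'   (percent mass loss), one row per block x treatment (one interval).
#' @param include_elevated Also report the Elevated - Closed contrast.
#' @param alternative Sidedness of the t-tests.
#' @return Data frame with one row per contrast (`mean`, `ci_lo`, `ci_hi`,
#'   `t`, `df`, `p`, `n_blocks`); per-block differences in attribute
#'   `"blocks"`.
#' @export
route_mass_loss <- function(loss, include_elevated = FALSE,
                            alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  need <- c("block", "treatment", "loss")
  if (!all(need %in% names(loss))) {
    stop("`loss` needs columns block, treatment, loss")
  }
  wide <- stats::reshape(loss[need], idvar = "block",
                         timevar = "treatment", direction = "wide")
  names(wide) <- sub("^loss\\.", "", names(wide))
  trts <- c("Closed", "Overhead", "Open",
            if (include_elevated) "Elevated")
  if (!all(trts %in% names(wide))) {
    stop("missing treatment(s): ",
         paste(setdiff(trts, names(wide)), collapse = ", "))
  }
  complete <- stats::complete.cases(wide[trts])
  if (any(!complete)) {
    message(sprintf("dropping %d incomplete block(s)", sum(!complete)))
  }
  wide <- wide[complete, , drop = FALSE]
  if (nrow(wide) < 2) stop("fewer than 2 complete blocks")
  diffs <- cbind(above_near = wide$Overhead - wide$Closed,
                 below = wide$Open - wide$Overhead)
  if (include_elevated) {
    diffs <- cbind(diffs, above = wide$Elevated - wide$Closed)
  }
  rownames(diffs) <- wide$block
  rows <- lapply(colnames(diffs), function(r) {
    tt <- one_sample_t(diffs[, r], mu0 = 0, alternative = alternative)
    data.frame(contrast = r, mean = tt$mean,
               ci_lo = tt$ci[1], ci_hi = tt$ci[2],
               t = tt$t, df = tt$df, p = tt$p, n_blocks = nrow(diffs))
  })
  out <- do.call(rbind, rows)
  attr(out, "blocks") <- diffs
  out
}

#' One-way analysis of variance
#'
#' Standard fixed-effects one-way ANOVA via `lm`, reporting F, p and
#' `R^2 = SS_between / SS_total`. Zero within-group variance is flagged
#' degenerate (p = 0 when means differ, p = 1 otherwise).
#'
#' @param values Numeric response.
#' @param groups Grouping vector/factor (>= 2 groups, n > number of groups).
#' @return Object of class `anova_result`: `F`, `df`, `p`, `r_squared`,
#'   `means`, `degenerate`.
#' @export
#' @examples
#' one_way_anova(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))$F  # 13.5
one_way_anova <- function(values, groups) {
  groups <- factor(groups)
  g <- nlevels(droplevels(groups))
  if (g < 2) stop("need >= 2 groups")
  if (length(values) <= g) stop("need more observations than groups")
  means <- tapply(values, groups, mean)
  fit <- stats::lm(values ~ groups)
  tab <- quiet_perfect_fit(stats::anova(fit))
  ssb <- tab$`Sum Sq`[1]; ssw <- tab$`Sum Sq`[2]
  degenerate <- ssw <= 1e-12 * max(ssb, 1)
  if (degenerate) {
    distinct <- stats::var(means) > 0
    out <- list(F = if (distinct) Inf else 0, df = tab$Df,
                p = if (distinct) 0 else 1,
                r_squared = if (distinct) 1 else 0,
                means = means, degenerate = TRUE)
  } else {
    out <- list(F = tab$`F value`[1], df = tab$Df, p = tab$`Pr(>F)`[1],
                r_squared = ssb / (ssb + ssw), means = means,
                degenerate = FALSE)
  }
  class(out) <- "anova_result"
  out
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F = %.4f (df %d, %d), p = %.4g, R2 = %.4f%s\n",
              x$F, x$df[1], x$df[2], x$p, x$r_squared,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Tukey's HSD with compact letter display
#'
#' Pairwise comparisons with the studentized range statistic using the
#' pooled within-group variance (Tukey-Kramer under unequal n):
#' `q = |m_i - m_j| / sqrt(MSE/2 * (1/n_i + 1/n_j))`, with p-values from
#' `ptukey`. Letters are assigned by insert-and-absorb so that two groups
#' share a letter if and only if their difference is not significant at
#' `alpha`.
#'
#' @inheritParams one_way_anova
#' @param alpha Significance level for the letter display.
#' @return List with `pairs` (data frame: `a`, `b`, `diff`, `q`, `p_adj`,
#'   `significant`), `letters` (named character per group), `alpha`, `mse`.
#' @export
tukey_hsd <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  av <- one_way_anova(values, groups)
  sizes <- table(droplevels(groups))
  levs <- names(sizes)
  g <- length(levs)
  dfw <- av$df[2]
  gi <- split(values, droplevels(groups))
  mse <- sum(vapply(gi, function(v) sum((v - mean(v))^2), numeric(1))) / dfw
  pairs <- utils::combn(levs, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    d <- av$means[a] - av$means[b]
    se <- sqrt(mse / 2 * (1 / sizes[a] + 1 / sizes[b]))
    q <- abs(d) / se
    p <- if (mse == 0) as.numeric(abs(d) == 0) else
      stats::ptukey(q, nmeans = g, df = dfw, lower.tail = FALSE)
    data.frame(a = a, b = b, diff = unname(d), q = unname(q),
               p_adj = unname(p))
  })
  tab <- do.call(rbind, rows)
  tab$significant <- tab$p_adj < alpha
  letters_out <- compact_letters(levs, tab[tab$significant, c("a", "b")],
                                 order(-av$means[levs]))
  list(pairs = tab, letters = letters_out, alpha = alpha, mse = mse,
       means = av$means)
}

# Insert-and-absorb compact letter display. `sig` is a two-column frame of
# significantly different pairs; groups sharing a letter are exactly the
# pairs not listed there.
compact_letters <- function(levs, sig, display_order = seq_along(levs)) {
  sets <- list(levs)
  for (k in seq_len(nrow(sig))) {
    i <- sig$a[k]; j <- sig$b[k]
    new_sets <- list()
    for (s in sets) {
      if (i %in% s && j %in% s) {
        new_sets <- c(new_sets, list(setdiff(s, i)), list(setdiff(s, j)))
      } else {
        new_sets <- c(new_sets, list(s))
      }
    }
    # absorb: drop sets contained in another set
    keep <- rep(TRUE, length(new_sets))
    for (x in seq_along(new_sets)) {
      for (y in seq_along(new_sets)) {
        if (x != y && keep[y] &&
            all(new_sets[[x]] %in% new_sets[[y]]) &&
            (length(new_sets[[x]]) < length(new_sets[[y]]) || x > y)) {
          keep[x] <- FALSE
          break
        }
      }
    }
    sets <- new_sets[keep]
  }
  sets <- sets[lengths(sets) > 0]
  # order letters by the best-ranked member so "a" marks the top group
  first_rank <- vapply(sets, function(s) min(match(s, levs[display_order])),
                       numeric(1))
  sets <- sets[order(first_rank)]
  out <- stats::setNames(character(length(levs)), levs)
  for (k in seq_along(sets)) {
    for (gname in sets[[k]]) out[gname] <- paste0(out[gname], letters[k])
  }
  out
}

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks. For `n <= 9` the p-value is exact
#' by enumerating all rank permutations (two-sided); otherwise the
#' t-approximation `t = rho * sqrt((n-2)/(1-rho^2))` is used. Constant
#' input leaves the correlation undefined and is flagged.
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`.
#' @param exact Force exact enumeration on or off; default `n <= 9`.
#' @return List with `rho`, `p`, `n`, `method`, `degenerate`.
#' @export
spearman <- function(x, y, exact = NULL) {
  n <- length(x)
  if (length(y) != n) stop("x and y differ in length")
  if (n < 3) stop("need n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input: Spearman correlation undefined")
    return(list(rho = NA_real_, p = NA_real_, n = n,
                method = "undefined", degenerate = TRUE))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  exact <- exact %||% (n <= 9)
  if (exact) {
    P <- all_permutations(n)
    rxc <- rx - mean(rx)
    ryc <- ry - mean(ry)
    denom <- sqrt(sum(rxc^2) * sum(ryc^2))
    rhos <- as.numeric(matrix(ryc[t(P)], ncol = n, byrow = TRUE) %*% rxc) /
      denom
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact"
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
    method <- "t-approximation"
  }
  list(rho = rho, p = p, n = n, method = method, degenerate = FALSE)
}
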