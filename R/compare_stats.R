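#' Fold change of per-cell -KTS units between two groups
#'
#' Estimates `mean(n_minus in B) / mean(n_minus in A)` - the readout behind
#' the transcriptional-compensation claim that -KTS transcripts double when
#' the +KTS donor is lost. The mean of per-cell informative units (rather
#' than pooled totals) makes the estimate robust to unequal cell numbers.
#' Uncertainty comes from a percentile bootstrap resampling cells within
#' each group; a two-sided permutation test of the per-cell mean difference
#' provides a p-value. The result is deterministic given `seed`.
#'
#' @param countsA,countsB [count_cells()] tables (or any data.frames with an
#'   `n_minus` column) for the reference (A) and comparison (B) group
#' @param n_boot bootstrap replicates
#' @param n_perm label permutations for the p-value (0 to skip)
#' @param seed integer seed or NULL
#' @param conf confidence level
#' @return list (class `group_comparison`) with `fold_change`, `ci_low`,
#'   `ci_high`, `p_value`, per-group means and sizes, `defined` (FALSE when
#'   `mean(A) == 0` leaves the fold undefined), and the `n_boot`, `n_perm`
#'   and `seed` used
#' @examples
#' a <- data.frame(n_minus = rpois(50, 10))
#' b <- data.frame(n_minus = rpois(50, 20))
#' fold_change(a, b, seed = 1)$fold_change
#' @export
fold_change <- function(countsA, countsB, n_boot = 2000L, n_perm = 999L,
                        seed = NULL, conf = 0.95) {
  stopifnot("n_minus" %in% names(countsA), "n_minus" %in% names(countsB),
            nrow(countsA) >= 1L, nrow(countsB) >= 1L)
  set_seed_if(seed)
  a <- countsA$n_minus
  b <- countsB$n_minus
  res <- list(mean_a = mean(a), mean_b = mean(b),
              n_a = length(a), n_b = length(b),
              n_boot = n_boot, n_perm = n_perm, seed = seed, conf = conf)
  if (mean(a) == 0) {
    res <- c(res, list(fold_change = NA_real_, ci_low = NA_real_,
                       ci_high = NA_real_, p_value = NA_real_,
                       defined = FALSE))
    return(structure(res, class = "group_comparison"))
  }
  fold <- mean(b) / mean(a)
  bm_a <- colMeans(matrix(sample(a, length(a) * n_boot, replace = TRUE),
                          nrow = length(a)))
  bm_b <- colMeans(matrix(sample(b, length(b) * n_boot, replace = TRUE),
                          nrow = length(b)))
  folds <- bm_b / bm_a
  ci <- quantile(folds, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                 na.rm = TRUE, names = FALSE)
  p <- if (n_perm > 0)
    permutation_test(c(a, b),
                     rep(c("A", "B"), c(length(a), length(b))),
                     n_perm = n_perm, seed = NULL)$p_value
  else NA_real_
  res <- c(res, list(fold_change = fold, ci_low = ci[1L], ci_high = ci[2L],
                     p_value = p, defined = TRUE))
  structure(res, class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  if (!x$defined) {
    cat("fold change undefined (reference group mean is 0)\n")
    return(invisible(x))
  }
  cat(sprintf(
    "fold change (B/A) = %.3f  [%.0f%% CI %.3f, %.3f]  p = %.4g\n",
    x$fold_change, 100 * x$conf, x$ci_low, x$ci_high, x$p_value))
  cat(sprintf("  A: mean %.3f (n=%d)   B: mean %.3f (n=%d)\n",
              x$mean_a, x$n_a, x$mean_b, x$n_b))
  invisible(x)
}

#' Two-group permutation test on per-cell values
#'
#' Tests the difference of group means by permuting group labels. The
#' two-sided p-value uses the add-one correction
#' `p = (#\{|T*| >= |T|\} + 1) / (n_perm + 1)`, so it is never 0. With
#' `exact = TRUE` all `choose(n, nA)` distinct relabellings are enumerated
#' instead and `p = #\{|T*| >= |T|\} / N` (the identity relabelling
#' guarantees p > 0).
#'
#' @param values numeric vector of per-cell values
#' @param labels group labels (exactly two distinct, each n >= 1); the
#'   statistic is `mean(group2) - mean(group1)` in label sort order
#' @param n_perm number of random permutations
#' @param seed integer seed or NULL
#' @param exact enumerate all relabellings (feasible for small groups)
#' @return list with `statistic`, `p_value`, `n_perm`, `seed`
#' @export
permutation_test <- function(values, labels, n_perm = 999L, seed = NULL,
                             exact = FALSE) {
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  if (length(lev) != 2L)
    stop("'labels' must contain exactly two distinct groups")
  g2 <- labels == lev[2L]
  if (sum(g2) == 0L || sum(!g2) == 0L) stop("both groups must be non-empty")
  set_seed_if(seed)
  n <- length(values)
  n2 <- sum(g2)
  tot <- sum(values)
  stat_from_sum2 <- function(s2) s2 / n2 - (tot - s2) / (n - n2)
  obs <- stat_from_sum2(sum(values[g2]))
  if (exact) {
    combs <- utils::combn(n, n2)
    s2 <- colSums(matrix(values[combs], nrow = n2))
    perm <- stat_from_sum2(s2)
    p <- mean(abs(perm) >= abs(obs) - 1e-12)
    return(list(statistic = obs, p_value = p, n_perm = ncol(combs),
                seed = seed))
  }
  s2 <- vapply(seq_len(n_perm),
               function(i) sum(values[sample.int(n, n2)]), numeric(1))
  perm <- stat_from_sum2(s2)
  p <- (sum(abs(perm) >= abs(obs) - 1e-12) + 1) / (n_perm + 1)
  list(statistic = obs, p_value = p, n_perm = n_perm, seed = seed)
}

#' Dose-ordered trend test across an allelic series
#'
#' Tests whether per-cell values increase with an ordered dose (e.g. the
#' number of -KTS-encoding alleles: 1 in FRASIER/NULL, 2 in
#' FRASIER/FRASIER). The statistic is the Jonckheere-type pairwise
#' concordance sum: over all pairs of observations in dose-ordered group
#' pairs, the number of concordant pairs (higher dose, higher value) minus
#' discordant ones; ties count 0. Reversing the dose order negates the
#' statistic. Significance comes from permuting values across all cells,
#' two-sided with the add-one correction.
#'
#' @param values numeric vector of per-cell values
#' @param doses dose labels; order taken from factor levels (or sorted
#'   unique values), lowest first
#' @param n_perm number of permutations
#' @param seed integer seed or NULL
#' @return list (class `trend_result`) with `statistic`, `p_value`,
#'   `levels`, `n_per_level`, `n_perm`, `seed`
#' @export
dose_trend <- function(values, doses, n_perm = 999L, seed = NULL) {
  f <- if (is.factor(doses)) doses else factor(doses)
  f <- droplevels(f)
  if (nlevels(f) < 2L) stop("need at least two dose levels")
  if (any(table(f) == 0L)) stop("every dose level must be non-empty")
  set_seed_if(seed)
  lev <- levels(f)
  trend_stat <- function(v) {
    s <- 0
    for (i in seq_len(length(lev) - 1L)) {
      vi <- v[f == lev[i]]
      for (j in seq.int(i + 1L, length(lev))) {
        vj <- v[f == lev[j]]
        s <- s + sum(sign(outer(vj, vi, "-")))
      }
    }
    s
  }
  obs <- trend_stat(values)
  perm <- vapply(seq_len(n_perm),
                 function(i) trend_stat(sample(values)), numeric(1))
  p <- (sum(abs(perm) >= abs(obs) - 1e-12) + 1) / (n_perm + 1)
  structure(list(statistic = obs, p_value = p, levels = lev,
                 n_per_level = as.integer(table(f)), n_perm = n_perm,
                 seed = seed),
            class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("dose trend over %s: statistic = %g, p = %.4g (%d perms)\n",
              paste(x$levels, collapse = " < "), x$statistic, x$p_value,
              x$n_perm))
  invisible(x)
}
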