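# Exact enumerated permutation tests with "ordered p" values: the count of
# permuted statistics strictly greater than the observed statistic, divided
# by the total number of permutations (sign flips for paired change tests,
# group relabelings for between-group tests), plus Benjamini-Hochberg FDR
# filtering and baseline-difference screening.

perm_count_p <- function(t1, perm_stats, alternative, estimator) {
  n <- length(perm_stats)
  k <- switch(alternative,
              two.sided = sum(abs(perm_stats) > abs(t1) + 1e-12),
              observed = if (t1 >= 0) sum(perm_stats > t1 + 1e-12)
                         else sum(perm_stats < t1 - 1e-12))
  p <- switch(estimator,
              ordered = k / n,
              plus_one = (k + 1) / (n + 1))
  list(n_greater = k, p = p)
}

#' Exact sign-flip permutation test for paired differences
#'
#' Enumerates all `2^n` sign assignments of the paired differences and
#' counts permuted statistics strictly greater than the observed statistic
#' t1 (on the observed direction by default, the worked convention for
#' within-group change tests). The ordered p is that count over `2^n`; it
#' can be zero, faithfully to the counting rule; use
#' `estimator = "plus_one"` for the conventional `(k+1)/(N+1)` estimator.
#'
#' @param paired_differences Numeric vector (e.g. EP - BL change per
#'   subject); n at most 20 for exact enumeration.
#' @param statistic Function of a difference vector (default `mean`).
#' @param alternative `"observed"` (one-sided on the direction of t1) or
#'   `"two.sided"`.
#' @param estimator `"ordered"` (strict-greater count over N) or
#'   `"plus_one"`.
#' @return Object of class `permutation_result`: `t1`, `n_perms`,
#'   `n_greater`, `ordered_p`, plus the enumeration.
#' @export
#' @examples
#' signflip_perm_test(c(1, 2, -3, 4))$ordered_p  # 3/16 = 0.1875
signflip_perm_test <- function(paired_differences, statistic = mean,
                               alternative = c("observed", "two.sided"),
                               estimator = c("ordered", "plus_one")) {
  alternative <- match.arg(alternative)
  estimator <- match.arg(estimator)
  d <- paired_differences
  n <- length(d)
  if (n > 20) {
    stop("n > 20: exact sign-flip enumeration infeasible; ",
         "use a Monte-Carlo approximation (flagged non-exact) instead")
  }
  t1 <- statistic(d)
  signs <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
  perm_stats <- apply(signs * rep(abs(d), each = nrow(signs)), 1, statistic)
  # sign-flipping acts on magnitudes; the observed assignment is included
  cnt <- perm_count_p(t1, perm_stats, alternative, estimator)
  structure(list(statistic_label = "sign-flip", t1 = t1,
                 n_perms = length(perm_stats), n_greater = cnt$n_greater,
                 ordered_p = cnt$p, perm_stats = perm_stats,
                 alternative = alternative, estimator = estimator),
            class = "permutation_result")
}

#' Exact group-exchange permutation test
#'
#' Enumerates all `choose(nA + nB, nA)` relabelings of the combined sample
#' and counts permuted statistics strictly greater than the observed one;
#' used for between-group comparisons of BL, EP or change values.
#'
#' @param values_a,values_b Numeric vectors for the two groups.
#' @param statistic Function of two vectors (default mean difference
#'   `mean(a) - mean(b)`).
#' @inheritParams signflip_perm_test
#' @return A `permutation_result`.
#' @export
#' @examples
#' group_perm_test(1:4, 5:8)$n_perms  # choose(8, 4) = 70
group_perm_test <- function(values_a, values_b,
                            statistic = function(a, b) mean(a) - mean(b),
                            alternative = c("observed", "two.sided"),
                            estimator = c("ordered", "plus_one")) {
  alternative <- match.arg(alternative)
  estimator <- match.arg(estimator)
  pooled <- c(values_a, values_b)
  na <- length(values_a)
  nb <- length(values_b)
  if (na + nb > 16) {
    stop("combined n > 16: exact relabeling enumeration infeasible; ",
         "use a Monte-Carlo approximation (flagged non-exact) instead")
  }
  t1 <- statistic(values_a, values_b)
  idx <- combn(na + nb, na)
  perm_stats <- apply(idx, 2, function(ii)
    statistic(pooled[ii], pooled[-ii]))
  cnt <- perm_count_p(t1, perm_stats, alternative, estimator)
  structure(list(statistic_label = "group-exchange", t1 = t1,
                 n_perms = ncol(idx), n_greater = cnt$n_greater,
                 ordered_p = cnt$p, perm_stats = perm_stats,
                 alternative = alternative, estimator = estimator),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("%s permutation test: t1 = %.4g, %d/%d permuted > t1, ordered p = %.4g\n",
              x$statistic_label, x$t1, x$n_greater, x$n_perms, x$ordered_p))
  invisible(x)
}

#' Benjamini-Hochberg FDR significance flags
#'
#' Standard step-up rule at level `q`: reject all `p_(i)` with
#' `i <= max{k : p_(k) <= k q / m}`.
#'
#' @param p_values Numeric p values in `[0, 1]` (one family).
#' @param q FDR level (default 0.20).
#' @return Logical vector of rejection flags (empty input gives empty
#'   output); `NA` p values are never rejected.
#' @export
#' @examples
#' bh_fdr(seq(0.01, 0.10, by = 0.01), q = 0.20)  # all TRUE
bh_fdr <- function(p_values, q = 0.20) {
  if (!length(p_values)) return(logical(0))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p values must lie in [0, 1]")
  }
  adj <- p.adjust(p_values, method = "BH")
  out <- !is.na(adj) & adj <= q
  out
}

#' Screen features for baseline group differences
#'
#' Runs the exact group-exchange permutation test on baseline values of
#' every feature and flags features whose BL difference is significant
#' (FDR-filtered within the family by default, or by raw ordered p);
#' flagged features are excluded from correlation discovery, with reasons
#' recorded.
#'
#' @param bl_table Data frame with columns `measure`, `group`, `bl` (one
#'   row per subject per measure).
#' @param features Features to screen (default: all in the table).
#' @param q FDR level for the family of screened features.
#' @param use_fdr Logical; `FALSE` excludes on raw ordered p < `alpha`.
#' @param alpha Raw-p exclusion level when `use_fdr = FALSE`.
#' @return Data frame: `measure`, `t1`, `ordered_p`, `excluded`, `reason`.
#' @export
baseline_screen <- function(bl_table, features = unique(bl_table$measure),
                            q = 0.20, use_fdr = TRUE, alpha = 0.05) {
  res <- lapply(features, function(f) {
    sub <- bl_table[bl_table$measure == f, ]
    groups <- sort(unique(as.character(sub$group)))
    if (length(groups) != 2) stop("baseline screen requires both groups")
    a <- sub$bl[sub$group == groups[1]]
    b <- sub$bl[sub$group == groups[2]]
    pt <- group_perm_test(a, b, alternative = "two.sided")
    data.frame(measure = f, t1 = pt$t1, ordered_p = pt$ordered_p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$excluded <- if (use_fdr) bh_fdr(out$ordered_p, q) else out$ordered_p < alpha
  out$reason <- ifelse(out$excluded, "significant BL group difference", "")
  out
}
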