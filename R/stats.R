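# Statistical layer: Welch unpaired t-test, Wilcoxon rank sum with exact
# small-sample enumeration, Spearman rank correlation with exact permutation
# p for small n, the significance-star convention, and the adhesion-vs-
# aggregation correlation report.

adhesion_test <- function(test_name, statistic, p_value, n1, n2 = NA_integer_,
                          estimate = NA_real_) {
  structure(list(test_name = test_name,
                 statistic = unname(statistic),
                 p_value = min(max(p_value, 0), 1),
                 n1 = as.integer(n1), n2 = as.integer(n2),
                 estimate = unname(estimate),
                 stars = significance_stars(min(max(p_value, 0), 1))),
            class = "adhesion_test")
}

#' @export
print.adhesion_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (%s), n = %s\n",
              x$test_name, x$statistic, x$p_value, x$stars,
              if (is.na(x$n2)) x$n1 else paste(x$n1, x$n2, sep = " + ")))
  if (!is.na(x$estimate))
    cat(sprintf("  estimate: %.4g\n", x$estimate))
  invisible(x)
}

#' Unpaired two-sample t-test (Welch)
#'
#' Two-sided unequal-variance t-test; the Welch form is used because group
#' spreads of adhesion forces typically differ between variants. Samples
#' that are both constant yield statistic 0 and p 1 when their means agree
#' (and p 0 otherwise) rather than an error.
#'
#' @param a,b numeric samples, each of length >= 2.
#' @return An object of class `adhesion_test` with fields `statistic`,
#'   `p_value`, `n1`, `n2`, `stars`.
#' @export
t_test_unpaired <- function(a, b) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (isTRUE(all.equal(mean(a), mean(b))))
      return(adhesion_test("t_unpaired", 0, 1, length(a), length(b),
                           estimate = 0))
    return(adhesion_test("t_unpaired", sign(mean(a) - mean(b)) * Inf, 0,
                         length(a), length(b), estimate = mean(a) - mean(b)))
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  adhesion_test("t_unpaired", ht$statistic, ht$p.value,
                length(a), length(b), estimate = mean(a) - mean(b))
}

# Two-sided p from a discrete null distribution of a statistic, using the
# symmetric doubling convention: 2 * min(P(T <= t), P(T >= t)), capped at 1.
two_sided_discrete <- function(values, t_obs, tol = 1e-9) {
  lo <- mean(values <= t_obs + tol)
  hi <- mean(values >= t_obs - tol)
  min(1, 2 * min(lo, hi))
}

#' Wilcoxon rank sum test
#'
#' Rank-sum (Mann-Whitney) test of two independent samples, reporting the
#' Mann-Whitney U of the first sample. For pooled sizes n1 + n2 <= 12 the
#' two-sided p-value is exact, computed by enumerating all
#' choose(n1+n2, n1) assignments of the pooled midranks (ties enter the
#' enumeration through the midranks); larger samples use the normal
#' approximation with tie-corrected variance and continuity correction.
#'
#' @param a,b numeric samples, each of length >= 3.
#' @param exact force (`TRUE`) or suppress (`FALSE`) enumeration; default
#'   enumerates iff n1 + n2 <= 12.
#' @return An `adhesion_test` (statistic = Mann-Whitney U of `a`).
#' @export
wilcoxon_rank_sum <- function(a, b, exact = NULL) {
  n1 <- length(a); n2 <- length(b)
  stopifnot(n1 >= 3L, n2 >= 3L)
  N <- n1 + n2
  if (is.null(exact)) exact <- N <= 12L
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (stats::var(c(a, b)) == 0)
    return(adhesion_test("wilcoxon_rank_sum", u_obs, 1, n1, n2))
  if (exact) {
    combs <- utils::combn(N, n1)
    w <- colSums(matrix(r[combs], nrow = n1))
    u_all <- w - n1 * (n1 + 1) / 2
    p <- two_sided_discrete(u_all, u_obs)
  } else {
    ties <- table(r)
    mu <- n1 * n2 / 2
    sigma2 <- (n1 * n2 / 12) * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    z <- u_obs - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)  # continuity correction
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  adhesion_test("wilcoxon_rank_sum", u_obs, p, n1, n2)
}

# All permutations of 1..n as a matrix with n rows (columns = permutations).
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, n, n * ncol(sub))
  k <- 0L
  for (i in seq_len(n)) {
    block <- rbind(rep(i, ncol(sub)), sub + (sub >= i))
    out[, k + seq_len(ncol(sub))] <- block
    k <- k + ncol(sub)
  }
  out
}

#' Spearman rank correlation test
#'
#' Rank correlation with midrank handling of ties. For n <= 7 the two-sided
#' p-value is exact: the permutation distribution of rho over all n!
#' orderings of one variable is enumerated and p is the fraction with
#' |rho| >= |rho_obs|. Larger n use the t approximation
#' t = rho * sqrt((n - 2) / (1 - rho^2)).
#'
#' @param x,y paired numeric samples, n >= 3.
#' @param exact force or suppress enumeration; default enumerates iff
#'   n <= 7.
#' @return An `adhesion_test` with `estimate` = rho.
#' @export
spearman_test <- function(x, y, exact = NULL) {
  n <- length(x)
  stopifnot(n >= 3L, length(y) == n)
  rx <- rank(x); ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0)
    stop("undefined correlation: zero rank variance in one variable")
  rho <- stats::cor(rx, ry)
  if (is.null(exact)) exact <- n <= 7L
  if (exact) {
    perms <- all_perms(n)
    rho_all <- apply(perms, 2L, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(rho_all) >= abs(rho) - 1e-9)
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- min(1, 2 * stats::pt(-abs(tt), df = n - 2))
  }
  adhesion_test("spearman", rho, p, n, NA_integer_, estimate = rho)
}

#' Significance stars
#'
#' Maps a p-value to the reporting convention
#' p > 0.05 (n.s.), 0.05 >= p > 0.01 (*), 0.01 >= p > 0.001 (**),
#' p <= 0.001 (***); boundaries are inclusive toward the more significant
#' label exactly as written.
#'
#' @param p p-value in \[0, 1\].
#' @return One of `"n.s."`, `"*"`, `"**"`, `"***"`.
#' @export
significance_stars <- function(p) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop("p must be a single value in [0, 1]")
  if (p > 0.05) "n.s."
  else if (p > 0.01) "*"
  else if (p > 0.001) "**"
  else "***"
}

#' Correlate single-cell adhesion forces with population aggregation
#'
#' Spearman rank correlation between per-variant mean maximum adhesion force
#' (single-cell force spectroscopy) and total aggregate area (aggregation
#' microscopy), the cross-assay consistency check of the two read-outs.
#'
#' @param points data frame with columns `variant`, `mean_fmax_nN`,
#'   `total_aggregate_area`; at least 3 variants.
#' @return Object of class `variant_correlation`: list with `test` (the
#'   Spearman `adhesion_test`) and `table` (the input points, ranked).
#' @export
correlate_variants <- function(points) {
  need <- c("variant", "mean_fmax_nN", "total_aggregate_area")
  if (!is.data.frame(points) || !all(need %in% names(points)))
    stop("`points` needs columns ", paste(need, collapse = ", "))
  if (nrow(points) < 3L)
    stop("need at least 3 variants to correlate")
  if (any(!is.finite(points$mean_fmax_nN)) ||
      any(!is.finite(points$total_aggregate_area)))
    stop("non-finite variant point values")
  test <- spearman_test(points$mean_fmax_nN, points$total_aggregate_area)
  tab <- points[need]
  tab$rank_fmax <- rank(points$mean_fmax_nN)
  tab$rank_area <- rank(points$total_aggregate_area)
  structure(list(test = test, table = tab), class = "variant_correlation")
}

#' @export
print.variant_correlation <- function(x, ...) {
  cat(sprintf(
    "Adhesion force vs aggregation area: Spearman rho = %.3f, p = %.4g (%s), n = %d\n",
    x$test$estimate, x$test$p_value, x$test$stars, x$test$n1))
  print.data.frame(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}
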