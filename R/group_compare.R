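# Group comparison of per-fly slopes: a Kruskal-Wallis rank test plus a
# seeded percentile bootstrap of pairwise mean differences (estimation-
# statistics style effect sizes with confidence intervals).

# Kruskal-Wallis H with tie correction, from ranks. Used for the permutation
# p-value; cross-checked against stats::kruskal.test in the test suite.
kw_h <- function(values, groups) {
  n <- length(values)
  r <- rank(values)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, groups, function(x) length(x) * mean(x)^2)) - 3 * (n + 1)
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

#' Compare slope distributions between groups
#'
#' Rank-based omnibus test (Kruskal-Wallis, tie-corrected) across named groups
#' of per-fly slopes, together with a seeded percentile bootstrap of every
#' pairwise mean difference with its confidence interval, in the spirit of
#' estimation statistics.
#'
#' @param groups named list of numeric vectors (per-fly slopes), each with at
#'   least 2 values.
#' @param n_boot bootstrap resamples per pair (default 5000).
#' @param conf confidence level of the bootstrap interval (default 0.95).
#' @param seed optional integer; when given, the bootstrap (and permutation
#'   test, if requested) are reproducible and the caller's RNG state is left
#'   untouched.
#' @param p_method `"chisq"` for the chi-squared approximation of the
#'   Kruskal-Wallis p-value (default), `"permutation"` for a Monte-Carlo
#'   permutation p-value (`n_perm` label shuffles), preferable at small group
#'   sizes.
#' @param n_perm permutation count for `p_method = "permutation"`.
#' @return List with `kruskal` (`H`, `df`, `p`, `method`) and `bootstrap`
#'   (data frame: `group1`, `group2`, `mean_diff`, `ci_lo`, `ci_hi`).
#' @export
group_compare <- function(groups, n_boot = 5000, conf = 0.95, seed = NULL,
                          p_method = c("chisq", "permutation"),
                          n_perm = 10000) {
  p_method <- match.arg(p_method)
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    stop("`groups` must be a named list")
  }
  small <- names(groups)[vapply(groups, length, 1L) < 2]
  if (length(small) > 0) {
    stop("each group needs at least 2 values; too small: ",
         paste(small, collapse = ", "))
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  values <- unlist(groups, use.names = FALSE)
  labels <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  kt <- stats::kruskal.test(values, labels)
  h <- unname(kt$statistic)
  if (p_method == "chisq") {
    p <- kt$p.value
  } else {
    h_perm <- replicate(n_perm, kw_h(values, sample(labels)))
    p <- (1 + sum(h_perm >= h - 1e-12)) / (n_perm + 1)
  }
  nm <- names(groups)
  pairs <- utils::combn(nm, 2)
  alpha <- (1 - conf) / 2
  boot <- apply(pairs, 2, function(pr) {
    x <- groups[[pr[1]]]; y <- groups[[pr[2]]]
    d <- replicate(n_boot, {
      mean(sample(y, replace = TRUE)) - mean(sample(x, replace = TRUE))
    })
    ci <- unname(stats::quantile(d, c(alpha, 1 - alpha), type = 7))
    c(mean_diff = mean(y) - mean(x), ci_lo = ci[1], ci_hi = ci[2])
  })
  bootstrap <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                          t(boot), row.names = NULL)
  list(kruskal = list(H = h, df = unname(kt$parameter), p = p,
                      method = p_method),
       bootstrap = bootstrap)
}
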