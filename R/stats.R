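#' Mann-Whitney U test with exact tie-aware enumeration for small samples
#'
#' For combined sample sizes up to `exact_max`, the two-sided p-value is
#' computed by full enumeration of all group-label arrangements, with ties
#' handled through the midrank U statistic (each tied cross-pair contributes
#' 1/2): `p = P(|U - n1*n2/2| >= |U_obs - n1*n2/2|)` over arrangements.  For
#' larger samples the tie-corrected normal approximation of
#' [stats::wilcox.test()] (with continuity correction) is used.
#'
#' @param a,b numeric vectors (both non-empty).
#' @param exact_max largest `length(a) + length(b)` for exact enumeration
#'   (default 12).
#' @return list: `p`, `u`, `method` (`"exact"` or `"normal"`).
#' @export
mw_test <- function(a, b, exact_max = 12L) {
  if (!length(a) || !length(b)) stop_ctx("both groups must be non-empty")
  n1 <- length(a); n2 <- length(b)
  u_obs <- u_statistic(a, b)
  if (n1 + n2 <= exact_max) {
    pool <- c(a, b)
    mu <- n1 * n2 / 2
    idx <- utils::combn(n1 + n2, n1)
    dev_obs <- abs(u_obs - mu)
    hits <- 0L
    for (j in seq_len(ncol(idx))) {
      ga <- pool[idx[, j]]
      gb <- pool[-idx[, j]]
      if (abs(u_statistic(ga, gb) - mu) >= dev_obs - 1e-9) hits <- hits + 1L
    }
    return(list(p = hits / ncol(idx), u = u_obs, method = "exact"))
  }
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                            correct = TRUE))
  list(p = wt$p.value, u = u_obs, method = "normal")
}

# midrank U statistic: pairs with a > b count 1, ties count 1/2
u_statistic <- function(a, b) {
  r <- rank(c(a, b))
  sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
}

#' Permutation test on the difference of group medians
#'
#' Group labels are shuffled `n_perm` times under the given seed;
#' `p = (1 + #{|perm stat| >= |observed|}) / (1 + n_perm)` where the
#' statistic is `median(a) - median(b)`.
#'
#' @param a,b numeric vectors.
#' @param n_perm number of permutations (default 10000).
#' @param seed RNG seed (required for reproducibility).
#' @return list: `p`, `observed`.
#' @export
permutation_test <- function(a, b, n_perm = 10000L, seed = 1L) {
  if (!length(a) || !length(b)) stop_ctx("both groups must be non-empty")
  obs <- stats::median(a) - stats::median(b)
  pool <- c(a, b)
  n1 <- length(a)
  n <- length(pool)
  hits <- 0L
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  for (i in seq_len(n_perm)) {
    take <- sample.int(n, n1)
    stat <- stats::median(pool[take]) - stats::median(pool[-take])
    if (abs(stat) >= abs(obs) - 1e-12) hits <- hits + 1L
  }
  list(p = (1 + hits) / (1 + n_perm), observed = obs)
}

#' Compare two groups of per-site values
#'
#' Runs the tie-aware Mann-Whitney test ([mw_test()]) and the
#' median-difference permutation test ([permutation_test()]), and reports
#' group medians and quartiles.
#'
#' @inheritParams permutation_test
#' @param exact_max passed to [mw_test()].
#' @return object of class `group_comparison`: group sizes, medians,
#'   quartiles, `mw_p`, `perm_p`, `seed`.
#' @export
group_compare <- function(a, b, n_perm = 10000L, seed = 1L,
                          exact_max = 12L) {
  mw <- mw_test(a, b, exact_max = exact_max)
  pm <- permutation_test(a, b, n_perm = n_perm, seed = seed)
  qa <- stats::quantile(a, c(0.25, 0.5, 0.75), names = FALSE)
  qb <- stats::quantile(b, c(0.25, 0.5, 0.75), names = FALSE)
  structure(list(n_a = length(a), n_b = length(b),
                 median_a = qa[2], median_b = qb[2],
                 q1_a = qa[1], q3_a = qa[3], q1_b = qb[1], q3_b = qb[3],
                 mw_p = mw$p, mw_method = mw$method, u = mw$u,
                 perm_p = pm$p, perm_stat = pm$observed,
                 n_perm = n_perm, seed = seed),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("group comparison: n = %d vs %d\n", x$n_a, x$n_b))
  cat(sprintf("  medians: %.4g vs %.4g (diff %.4g)\n", x$median_a,
              x$median_b, x$perm_stat))
  cat(sprintf("  Mann-Whitney p = %.4g (%s), permutation p = %.4g (%d perms)\n",
              x$mw_p, x$mw_method, x$perm_p, x$n_perm))
  invisible(x)
}
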