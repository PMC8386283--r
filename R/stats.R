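# Exact statistics for the burden comparisons, implemented from first
# principles: a two-sided Fisher exact test by the point-probability
# method, and a Mann-Whitney U test with an exact-permutation mode.

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Computes the exact two-sided p value by the point-probability
#' ("min-likelihood") method: with the table margins fixed, the p value is
#' the sum of hypergeometric probabilities of all tables whose probability
#' does not exceed that of the observed table (within relative tolerance
#' 1e-7). Probabilities are evaluated in log space via `lchoose`, so the
#' computation is exact to floating point for any table size; no normal or
#' chi-square approximation is involved.
#'
#' @param tab a 2x2 matrix (or something coercible) of non-negative counts;
#'   rows are groups, columns are outcome classes.
#' @return the two-sided p value in `(0, 1]`.
#' @examples
#' fisher_exact_2x2(matrix(c(8, 4, 5, 15), nrow = 2))  # 0.030
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- matrix(as.numeric(tab), nrow = 2)
  stopifnot(all(tab >= 0), all(tab == round(tab)))
  if (sum(tab) == 0) stop("all-zero table")
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); n <- sum(tab)
  a_obs <- tab[1, 1]

  support <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, support) + lchoose(r2, c1 - support) - lchoose(n, c1)
  logp_obs <- lchoose(r1, a_obs) + lchoose(r2, c1 - a_obs) - lchoose(n, c1)
  p <- sum(exp(logp)[exp(logp) <= exp(logp_obs) * (1 + 1e-7)])
  min(p, 1)
}

#' @keywords internal
u_from_ranks <- function(rank_sum, n_a) rank_sum - n_a * (n_a + 1) / 2

#' Mann-Whitney U test with exact-permutation p value
#'
#' The U statistic is computed from midranks of the pooled sample (so ties
#' are handled), with `U = R_a - n_a(n_a+1)/2` where `R_a` is the rank sum
#' of the first group. The two-sided p value is the permutation tail
#' probability of `|U - E[U]|` with `E[U] = n_a n_b / 2`:
#'
#' * `exact_permutation` — all `C(n_a+n_b, n_a)` label assignments are
#'   enumerated when that count is at most `max_enumeration` (default
#'   2e6); otherwise a seeded Monte-Carlo sample of `n_resamples` label
#'   assignments (default 1e5) is used, with the add-one tail estimator
#'   `(1 + #extreme) / (1 + B)`.
#' * `normal_tie_corrected` — large-sample normal approximation with the
#'   tie-corrected variance and no continuity correction.
#'
#' @param a,b numeric vectors (both non-empty).
#' @param method `"exact_permutation"` or `"normal_tie_corrected"`.
#' @param seed integer seed for the Monte-Carlo fallback.
#' @param max_enumeration largest assignment count enumerated exhaustively.
#' @param n_resamples Monte-Carlo sample size.
#' @return a list with `u`, `p`, and `method_used` (`"enumeration"`,
#'   `"monte_carlo"` or `"normal"`).
#' @examples
#' mann_whitney_u(c(1, 1), c(0, 0))  # p = 2/6
#' @export
mann_whitney_u <- function(a, b,
                           method = c("exact_permutation",
                                      "normal_tie_corrected"),
                           seed = 1L, max_enumeration = 2e6,
                           n_resamples = 1e5) {
  method <- match.arg(method)
  stopifnot(length(a) > 0, length(b) > 0)
  pooled <- c(a, b)
  n_a <- length(a); n_b <- length(b); n <- n_a + n_b
  r <- rank(pooled)
  u_obs <- u_from_ranks(sum(r[seq_len(n_a)]), n_a)
  eu <- n_a * n_b / 2
  dev_obs <- abs(u_obs - eu)
  eps <- 1e-9

  if (method == "normal_tie_corrected") {
    ties <- table(pooled)
    var_u <- n_a * n_b / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    p <- if (var_u <= 0) 1 else min(1, 2 * stats::pnorm(-dev_obs / sqrt(var_u)))
    return(list(u = u_obs, p = p, method_used = "normal"))
  }

  n_comb <- choose(n, n_a)
  if (n_comb <= max_enumeration) {
    idx <- utils::combn(n, n_a)
    rank_sums <- colSums(matrix(r[idx], nrow = n_a))
    dev <- abs(u_from_ranks(rank_sums, n_a) - eu)
    p <- mean(dev >= dev_obs - eps)
    list(u = u_obs, p = p, method_used = "enumeration")
  } else {
    old <- local_seed(seed)
    on.exit(restore_seed(old))
    dev <- vapply(seq_len(n_resamples), function(i) {
      abs(u_from_ranks(sum(r[sample.int(n, n_a)]), n_a) - eu)
    }, numeric(1))
    p <- (1 + sum(dev >= dev_obs - eps)) / (1 + n_resamples)
    list(u = u_obs, p = p, method_used = "monte_carlo")
  }
}

# Seed the RNG locally, returning the previous state for restoration.
#' @keywords internal
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  set.seed(seed)
  old
}

#' @keywords internal
restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible()
}
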