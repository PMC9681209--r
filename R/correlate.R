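# Correlation of signature enrichment with cell-type composition, and
# gene-list overlap testing.

#' Spearman correlation with exact small-sample p-value
#'
#' Rho is computed from average-ranked data (ties handled by mid-ranks).
#' For `n <= exact_max_n` the p-value comes from full enumeration of all
#' `n!` permutations of one variable's ranks; for larger n the usual
#' t-approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2`
#' degrees of freedom is used.
#'
#' @param x,y Numeric vectors of equal length >= 3 with finite values.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @param exact_max_n Largest n for which the permutation null is fully
#'   enumerated (default 9).
#' @return A list with `rho`, `p`, `n` and `method`; `rho` and `p` are
#'   `NA` when either vector is constant.
#' @export
spearman_cor <- function(x, y,
                         alternative = c("two.sided", "greater", "less"),
                         exact_max_n = 9L) {
  alternative <- match.arg(alternative)
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3L) stop("need at least 3 observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("x and y must be finite")
  }
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n, method = "undefined"))
  }
  rho <- cor(rx, ry)
  if (n <= exact_max_n) {
    perms <- all_permutations(n)
    rxc <- rx - mean(rx)
    ryc <- ry - mean(ry)
    denom <- sqrt(sum(rxc^2) * sum(ryc^2))
    rho_all <- as.vector(matrix(ryc[perms], nrow(perms)) %*% rxc) / denom
    tol <- 1e-12
    p <- switch(alternative,
      two.sided = mean(abs(rho_all) >= abs(rho) - tol),
      greater = mean(rho_all >= rho - tol),
      less = mean(rho_all <= rho + tol)
    )
    method <- "exact permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- switch(alternative,
      two.sided = 2 * pt(-abs(tstat), n - 2),
      greater = pt(tstat, n - 2, lower.tail = FALSE),
      less = pt(tstat, n - 2)
    )
    p <- min(p, 1)
    method <- "t approximation"
  }
  list(rho = rho, p = p, n = n, method = method)
}

# All permutations of 1..n as an (n!) x n integer matrix.
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- all_permutations(n - 1L)
  m <- nrow(sub)
  out <- matrix(0L, n * m, n)
  for (i in seq_len(n)) {
    out[(i - 1L) * m + seq_len(m), ] <- cbind(i, sub + (sub >= i))
  }
  out
}

#' Over-representation test for a gene-list overlap
#'
#' Probability of observing an overlap at least as large as `k` between
#' two lists of sizes `n1` and `n2` drawn from a universe of `N` genes:
#' the upper hypergeometric tail `P(X >= k)`. The universe size must be
#' supplied explicitly. A two-sided alternative uses Fisher's exact test
#' on the corresponding 2x2 table.
#'
#' @param k Observed overlap count.
#' @param n1,n2 Sizes of the two gene lists.
#' @param N Universe size (e.g. number of expressed genes).
#' @param alternative `"greater"` (over-representation, default) or
#'   `"two.sided"`.
#' @return The p-value.
#' @export
overlap_test <- function(k, n1, n2, N,
                         alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (missing(N)) stop("the universe size N must be supplied explicitly")
  if (k < 0 || n1 < 0 || n2 < 0) stop("counts must be non-negative")
  if (k > min(n1, n2) || max(n1, n2) > N) {
    stop("need k <= min(n1, n2) and n1, n2 <= N")
  }
  if (n1 + n2 - k > N) stop("lists of these sizes cannot fit in the universe")
  if (alternative == "greater") {
    phyper(k - 1, n1, N - n1, n2, lower.tail = FALSE)
  } else {
    tab <- matrix(c(k, n1 - k, n2 - k, N - n1 - n2 + k), 2L)
    fisher.test(tab)$p.value
  }
}
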