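#' Exact two-sided Fisher test for a 2x2 table
#'
#' Computes the exact two-sided p-value under the hypergeometric null
#' with all margins fixed, using the minimum-likelihood convention: the
#' p-value is the sum of the point probabilities of every table (with the
#' same margins) whose probability does not exceed that of the observed
#' table, the comparison made with a relative tolerance of 1e-7 to absorb
#' floating-point noise among tied probabilities. With a degenerate
#' carrier margin (`a + c = 0`) only one table is consistent with the
#' margins and the p-value is 1.
#'
#' The cell layout follows the carrier test: `a` = case units with
#' qualifying carriage, `b` = case units without, `c` = control units
#' with, `d` = control units without (units are individuals under the
#' dominant model, alleles under the additive model).
#'
#' @param a,b,c,d Non-negative integer cell counts; vectors are recycled
#'   to a common length and the computation is grouped by shared margins.
#' @return Numeric vector of p-values in `(0, 1]`.
#' @examples
#' fisher_exact_two_sided(17, 2084, 3, 1350)  # ~0.036
#' @export
fisher_exact_two_sided <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), n); b <- rep_len(as.numeric(b), n)
  c <- rep_len(as.numeric(c), n); d <- rep_len(as.numeric(d), n)
  cells <- cbind(a, b, c, d)
  if (anyNA(cells) || any(cells < 0)) {
    stop("all cells of the 2x2 table must be non-negative", call. = FALSE)
  }
  if (any(cells != floor(cells))) {
    stop("all cells of the 2x2 table must be integers", call. = FALSE)
  }
  N <- a + b + c + d
  if (any(N == 0)) stop("table has no observations", call. = FALSE)
  K <- a + c   # carrier margin
  k <- a + b   # case margin
  p <- numeric(n)
  for (g in split(seq_len(n), paste(N, K, k))) {
    lut <- fisher_margin_pvals(N[g[1]], K[g[1]], k[g[1]])
    p[g] <- lut$p[a[g] - lut$lo + 1L]
  }
  p
}

# p-values for every admissible a given margins (N total, K carriers,
# k cases); returns list(lo, p) with p[a - lo + 1] the p-value at a.
fisher_margin_pvals <- function(N, K, k) {
  lo <- max(0, k - (N - K))
  hi <- min(k, K)
  x <- lo:hi
  if (length(x) == 1L) return(list(lo = lo, p = 1))
  pr <- stats::dhyper(x, K, N - K, k)
  rel <- 1 + 1e-7
  # inc[j, i] = does table j enter the p-value of observed table i
  inc <- outer(pr, pr * rel, "<=")
  list(lo = lo, p = pmin(as.vector(crossprod(inc, pr)), 1))
}
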