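#' Per-individual binomial Z-score for parental count asymmetry
#'
#' For one individual and one gene with \code{m} maternally and \code{p}
#' paternally assigned transcripts, the Z-score is the normal approximation
#' to Binomial(m + p, 1/2):
#' \deqn{Z = (m - n/2) / \sqrt{n/4}, \quad n = m + p.}
#' Only its sign is used downstream: individuals with \eqn{Z = 0}
#' (exact ties, \code{m == p}) are excluded before the across-individual
#' sign test, so no overdispersion model is needed.
#'
#' @param m Integer vector of maternal transcript counts.
#' @param p Integer vector of paternal transcript counts (recycled against
#'   \code{m}).
#' @return Numeric vector of Z-scores; \code{sign(z) == sign(m - p)}.
#' @examples
#' individual_z(5, 5)   # 0: perfectly balanced
#' individual_z(10, 0)  # sqrt(10): all-maternal
#' @export
individual_z <- function(m, p) {
  if (length(m) == 0L) return(numeric(0))
  stopifnot(is.numeric(m), is.numeric(p))
  n <- m + p
  if (any(!is.finite(n)) || any(m < 0) || any(p < 0)) {
    stop("'m' and 'p' must be non-negative finite counts")
  }
  if (any(n == 0)) {
    stop("individual_z() is undefined for m + p = 0")
  }
  (m - n / 2) / sqrt(n / 4)
}

#' Exact two-sided binomial sign test at success probability 1/2
#'
#' Computes the two-sided p-value for observing \code{k} individuals in the
#' minority direction out of \code{n} non-tied individuals, under the null
#' that each individual independently favours either parent with
#' probability 1/2:
#' \deqn{p = \min\left(1,\; 2 \sum_{i=0}^{\min(k, n-k)} \binom{n}{i} 2^{-n}\right).}
#' Because Binomial(n, 1/2) is symmetric, doubling the smaller tail equals
#' the usual exact two-sided test. The tail sum is accumulated in log space
#' (log-binomial coefficients combined with a log-sum-exp), so p-values far
#' below double underflow of individual operations (e.g. 1e-41 at n = 150)
#' retain full relative precision.
#'
#' @param k Integer vector: count of individuals in one direction (either
#'   direction may be passed; the smaller tail is used).
#' @param n Integer vector: number of non-tied individuals, recycled
#'   against \code{k}.
#' @return Numeric vector of two-sided p-values in (0, 1].
#' @examples
#' sign_test_pvalue(2, 150)  # ~1.59e-41
#' sign_test_pvalue(0, 43)   # ~2.27e-13
#' sign_test_pvalue(5, 10)   # 1: perfectly balanced
#' @export
sign_test_pvalue <- function(k, n) {
  if (length(k) == 0L) return(numeric(0))
  stopifnot(is.numeric(k), is.numeric(n))
  kn <- cbind(k = k, n = n)  # recycles
  k <- kn[, "k"]; n <- kn[, "n"]
  if (any(!is.finite(k)) || any(!is.finite(n))) {
    stop("'k' and 'n' must be finite")
  }
  if (any(k != round(k)) || any(n != round(n))) {
    stop("'k' and 'n' must be integer-valued")
  }
  if (any(n < 1)) stop("'n' must be >= 1")
  if (any(k < 0) || any(k > n)) stop("'k' must satisfy 0 <= k <= n")
  kk <- pmin(k, n - k)
  log_tail <- vapply(seq_along(kk), function(i) {
    lt <- lchoose(n[i], 0:kk[i]) - n[i] * log(2)
    mx <- max(lt)
    mx + log(sum(exp(lt - mx)))
  }, numeric(1))
  pmin(1, exp(log(2) + log_tail))
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up BH adjusted p-values (q-values), order-preserving on the input
#' index. Validates that inputs are proper p-values and then delegates to
#' \code{stats::p.adjust(method = "BH")}. \code{NA} entries (untestable
#' genes) stay \code{NA} and do not count toward the number of tests.
#'
#' @param p Numeric vector of p-values in (0, 1]; \code{NA} allowed.
#' @return Numeric vector of BH-adjusted values, same length and order.
#' @examples
#' bh_fdr(c(0.001, 1))  # 0.002, 1
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  stopifnot(is.numeric(p))
  ok <- !is.na(p)
  if (any(p[ok] <= 0 | p[ok] > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  q <- rep(NA_real_, length(p))
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}
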