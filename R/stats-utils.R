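#' Vectorized two-sample t test from summary statistics
#'
#' Closed-form Welch (default) or pooled two-sample t test, vectorized over
#' events. Used by the screening module so that panels with hundreds of
#' events and a dozen tissue groups are screened in milliseconds.
#'
#' Degenerate inputs follow limit behaviour: if both groups have zero
#' variance the p-value is 1 when the means are equal and 0 otherwise.
#' Comparisons with fewer than 2 observations in either group are untestable
#' and return NA.
#'
#' @param mean1,var1,n1 summary statistics of group 1 (e.g. tumor).
#' @param mean2,var2,n2 summary statistics of group 2 (e.g. a normal tissue).
#' @param equal_variance use the pooled-variance t test instead of Welch.
#' @param alternative "two.sided" or "greater" (group 1 mean larger).
#' @return numeric vector of p-values (NA where untestable).
#' @export
t_test_summary <- function(mean1, var1, n1, mean2, var2, n2,
                           equal_variance = FALSE,
                           alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  k <- max(length(mean1), length(mean2))
  mean1 <- rep_len(mean1, k); var1 <- rep_len(var1, k); n1 <- rep_len(n1, k)
  mean2 <- rep_len(mean2, k); var2 <- rep_len(var2, k); n2 <- rep_len(n2, k)

  p <- rep(NA_real_, k)
  testable <- !is.na(mean1) & !is.na(mean2) & n1 >= 2 & n2 >= 2
  zero <- testable & (var1 == 0) & (var2 == 0)
  if (any(zero)) {
    eq <- mean1[zero] == mean2[zero]
    if (alternative == "two.sided") {
      p[zero] <- ifelse(eq, 1, 0)
    } else {
      p[zero] <- ifelse(eq, 1, ifelse(mean1[zero] > mean2[zero], 0, 1))
    }
  }
  ok <- testable & !zero
  if (any(ok)) {
    if (equal_variance) {
      df <- n1[ok] + n2[ok] - 2
      sp2 <- ((n1[ok] - 1) * var1[ok] + (n2[ok] - 1) * var2[ok]) / df
      se <- sqrt(sp2 * (1 / n1[ok] + 1 / n2[ok]))
    } else {
      a <- var1[ok] / n1[ok]
      b <- var2[ok] / n2[ok]
      se <- sqrt(a + b)
      df <- (a + b)^2 / (a^2 / (n1[ok] - 1) + b^2 / (n2[ok] - 1))
    }
    tt <- (mean1[ok] - mean2[ok]) / se
    p[ok] <- if (alternative == "two.sided") 2 * pt(abs(tt), df, lower.tail = FALSE)
             else pt(tt, df, lower.tail = FALSE)
  }
  p
}

#' One-sided Fisher exact p-value for tumor enrichment of a junction
#'
#' Probability, under the hypergeometric null with fixed margins, of
#' observing at least `k_tumor` expressing samples among the tumor group.
#' This is the one-sided (greater) Fisher exact test p-value for the 2x2
#' table (expressing / not expressing) x (tumor / normal), vectorized.
#'
#' @param k_tumor number of tumor samples expressing the junction.
#' @param n_tumor tumor group size.
#' @param k_normal number of normal samples expressing the junction.
#' @param n_normal normal group size.
#' @return numeric vector of one-sided p-values (NA for empty groups).
#' @export
fisher_onesided <- function(k_tumor, n_tumor, k_normal, n_normal) {
  k <- max(length(k_tumor), length(k_normal))
  k_tumor <- rep_len(k_tumor, k); n_tumor <- rep_len(n_tumor, k)
  k_normal <- rep_len(k_normal, k); n_normal <- rep_len(n_normal, k)
  p <- rep(NA_real_, k)
  ok <- n_tumor > 0 & n_normal > 0
  # P(X >= k_tumor), X ~ Hypergeom(total = n_t + n_n, white = k_t + k_n, drawn = n_t)
  p[ok] <- phyper(k_tumor[ok] - 1, k_tumor[ok] + k_normal[ok],
                  n_tumor[ok] + n_normal[ok] - k_tumor[ok] - k_normal[ok],
                  n_tumor[ok], lower.tail = FALSE)
  p
}

# Row-wise mean/var/n over a column subset, NA-aware.
row_group_stats <- function(mat, cols) {
  x <- mat[, cols, drop = FALSE]
  n <- rowSums(!is.na(x))
  m <- rowMeans(x, na.rm = TRUE)
  m[n == 0] <- NA_real_
  v <- matrixStats::rowVars(x, na.rm = TRUE)
  v[n < 2] <- NA_real_
  list(n = n, mean = m, var = v)
}

#' Stable hash of a configuration object
#'
#' Recursively sorts list names before hashing so that semantically
#' identical configurations (differing only in key order) hash identically.
#'
#' @param config a (possibly nested) list.
#' @return character scalar, sha256 hex digest.
#' @export
config_hash <- function(config) {
  canon <- function(x) {
    if (is.list(x)) {
      if (!is.null(names(x))) x <- x[order(names(x))]
      lapply(x, canon)
    } else x
  }
  digest::digest(canon(config), algo = "sha256")
}
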