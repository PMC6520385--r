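# Exact permutation null of Spearman's rank correlation for small n.
#
# For tie-free ranks, r_s = 1 - 6 * S / (n^3 - n) with S = sum of squared
# rank differences, so the null distribution follows from the frequency
# table of S over all n! permutations (enumerated in C++).

.null_cache <- new.env(parent = emptyenv())

#' Exact permutation null distribution of Spearman's rank correlation
#'
#' Enumerates all `n!` permutations of tie-free ranks and tabulates the exact
#' distribution of \eqn{r_s} under the uniform-permutation null. Results are
#' cached per session, keyed by `n`.
#'
#' @param n Number of paired observations (3 to 10 for full enumeration).
#' @return An object of class `spearman_exact_null`: a list with `n`, a
#'   data frame `table` (attainable `r`, point probability `prob`), and
#'   `abs_r`/`tail` giving the two-sided tail \eqn{P(|R| \ge v)} at each
#'   attainable \eqn{|r|}.
#' @examples
#' null5 <- exact_null(5)
#' sum(null5$table$prob)  # 1
#' @export
exact_null <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 3L)
    stop("exact null requires n >= 3, got ", n)
  if (n > 10L)
    stop("full enumeration supported only for n <= 10; use spearman_exact_p() ",
         "which falls back to a t approximation for larger n")
  key <- as.character(n)
  if (!is.null(.null_cache[[key]]))
    return(.null_cache[[key]])
  counts <- .null_sumdsq_counts(n)
  s_vals <- seq_along(counts) - 1
  keep <- counts > 0
  r <- 1 - 6 * s_vals[keep] / (n^3 - n)
  prob <- counts[keep] / sum(counts)
  ord <- order(r)
  tab <- data.frame(r = r[ord], prob = prob[ord])
  abs_r <- sort(unique(abs(tab$r)))
  tail <- vapply(abs_r,
                 function(v) sum(tab$prob[abs(tab$r) >= v - 1e-12]),
                 numeric(1))
  out <- structure(list(n = n, table = tab, abs_r = abs_r, tail = tail),
                   class = "spearman_exact_null")
  assign(key, out, envir = .null_cache)
  out
}

#' Exact two-sided critical value for the Spearman screen
#'
#' The critical value is the smallest attainable \eqn{|r_s|} whose exact
#' two-sided tail probability under the permutation null does not exceed
#' `alpha`. At `n = 10`, `alpha = 0.05` this is 0.64848..., the tabulated
#' 0.648 threshold used to call a probe's correlation significant.
#'
#' @param n Number of paired observations (>= 3; above 10 a t-distribution
#'   approximation is used, with a warning).
#' @param alpha Two-sided significance level.
#' @return A list of class `spearman_critical` with `n`, `alpha`, `critical`
#'   (NA if no attainable value reaches significance), `tail_at_critical`,
#'   `attainable` (logical: is any critical value attainable), and `exact`
#'   (FALSE when the large-n approximation was used).
#' @examples
#' exact_critical_value(10, 0.05)$critical  # 0.6484848...
#' @export
exact_critical_value <- function(n, alpha = 0.05) {
  n <- as.integer(n)
  if (is.na(n) || n < 3L)
    stop("critical value requires n >= 3, got ", n)
  stopifnot(alpha > 0, alpha < 1)
  if (n > 10L) {
    warning("n > 10: using t approximation, not full enumeration")
    # invert the t approximation t = r sqrt((n-2)/(1-r^2))
    tcrit <- stats::qt(1 - alpha / 2, df = n - 2)
    crit <- tcrit / sqrt(n - 2 + tcrit^2)
    return(structure(list(n = n, alpha = alpha, critical = crit,
                          tail_at_critical = alpha, attainable = TRUE,
                          exact = FALSE),
                     class = "spearman_critical"))
  }
  null <- exact_null(n)
  ok <- null$tail <= alpha + 1e-15
  if (!any(ok)) {
    return(structure(list(n = n, alpha = alpha, critical = NA_real_,
                          tail_at_critical = NA_real_, attainable = FALSE,
                          exact = TRUE),
                     class = "spearman_critical"))
  }
  idx <- which(ok)[1]
  structure(list(n = n, alpha = alpha, critical = null$abs_r[idx],
                 tail_at_critical = null$tail[idx], attainable = TRUE,
                 exact = TRUE),
            class = "spearman_critical")
}

#' @export
print.spearman_critical <- function(x, ...) {
  cat("Spearman exact critical value (two-sided)\n")
  cat(sprintf("  n = %d, alpha = %g\n", x$n, x$alpha))
  if (x$attainable) {
    cat(sprintf("  |r_s| >= %.6f (tail mass %.6f)%s\n", x$critical,
                x$tail_at_critical, if (x$exact) "" else " [approximate]"))
  } else {
    cat("  none attainable: even |r_s| = 1 is not significant\n")
  }
  invisible(x)
}

#' Exact two-sided P value for an observed Spearman correlation
#'
#' For tie-free ranks the P value is read off the enumerated permutation
#' null; for `n > 10` a t approximation is used with a warning.
#'
#' @param r_s Observed correlation(s) in `[-1, 1]`.
#' @param n Number of paired observations.
#' @return Two-sided \eqn{P(|R| \ge |r_s|)}, vectorised over `r_s`.
#' @export
spearman_exact_p <- function(r_s, n) {
  n <- as.integer(n)
  if (is.na(n) || n < 3L) stop("n >= 3 required")
  if (n > 10L) {
    warning("n > 10: t approximation used for Spearman P values")
    tstat <- abs(r_s) * sqrt((n - 2) / pmax(1 - r_s^2, 1e-300))
    return(2 * pt(tstat, df = n - 2, lower.tail = FALSE))
  }
  null <- exact_null(n)
  vapply(r_s, function(r) {
    if (is.na(r)) return(NA_real_)
    idx <- findInterval(abs(r) - 1e-12, null$abs_r)
    # tail at the smallest attainable |r| >= |r_s|
    if (idx >= length(null$abs_r)) {
      if (abs(r) > null$abs_r[length(null$abs_r)] + 1e-9) return(0)
      return(null$tail[length(null$abs_r)])
    }
    null$tail[idx + 1L]
  }, numeric(1))
}

#' Exact two-sided P value in the presence of tied ranks
#'
#' Enumerates every distinct arrangement of the observed (possibly tied)
#' rank multiset `xr` against the fixed ranks `yr` and returns the fraction
#' with `|r| >= |r_obs|`, where `r` is the Pearson correlation of ranks.
#'
#' @param xr Average-ranked values (ties allowed), length 3..10.
#' @param yr Fixed comparison ranks, same length.
#' @return Two-sided exact P value.
#' @export
spearman_exact_p_tied <- function(xr, yr) {
  r_obs <- cor(xr, yr)
  res <- .tied_null_tail(as.numeric(xr), as.numeric(yr), r_obs)
  res[1] / res[2]
}

#' Spearman's rank correlation coefficient
#'
#' Pearson correlation of average ranks. Degenerate inputs (zero variance in
#' either rank vector) return `NA` with a warning, which downstream screening
#' treats as not significant.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return \eqn{r_s} in `[-1, 1]`, or `NA` for degenerate input.
#' @examples
#' spearman_rho(c(10, 30, 20), 1:3)  # 0.5
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("at least 3 observations required")
  rx <- rank(x)
  ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) {
    warning("zero variance in a rank vector; r_s undefined")
    return(NA_real_)
  }
  cor(rx, ry)
}
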