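# Array normalisation and the three-step probe filter:
# present-call -> one-way ANOVA across lines -> fold-range of line means.

#' Global scaling to a trimmed average intensity
#'
#' Each array (sample column) is multiplied by a single factor so that its
#' trimmed mean — excluding the `trim` fraction of probes with the highest
#' and the `trim` fraction with the lowest values (counts rounded down) —
#' equals `target`. The operation is idempotent.
#'
#' @param data An [expression_dataset()].
#' @param target Target trimmed average intensity (default 500).
#' @param trim Fraction trimmed from each tail (default 0.02).
#' @return The rescaled `expression_dataset`, with `normalized = TRUE`.
#' @export
global_scale <- function(data, target = 500, trim = 0.02) {
  stopifnot(inherits(data, "expression_dataset"))
  if (trim < 0 || trim >= 0.5) stop("trim must be in [0, 0.5)")
  if (target <= 0) stop("target must be positive")
  x <- data$intensity
  k <- floor(trim * nrow(x))
  idx <- if (k > 0) seq.int(k + 1L, nrow(x) - k) else seq_len(nrow(x))
  tmeans <- apply(x, 2, function(col) mean(sort(col)[idx]))
  if (any(tmeans <= 0))
    stop("array with non-positive trimmed mean: scale undefined (",
         colnames(x)[which(tmeans <= 0)[1]], ")")
  data$intensity <- sweep(x, 2, target / tmeans, "*")
  data$normalized <- TRUE
  data
}

#' Present-call probe filter
#'
#' Retains probes flagged `"P"` in at least `min_present` replicates of at
#' least one cell line. Marginal (`"M"`) calls do not count as present.
#' The decision depends only on the call matrix, never on intensities.
#'
#' @param data An [expression_dataset()] with calls.
#' @param min_present Minimum number of present calls within one line.
#' @return Character vector of retained probe ids.
#' @export
present_filter <- function(data, min_present = 4) {
  stopifnot(inherits(data, "expression_dataset"))
  p <- data$calls == "P"
  lines <- unique(data$lines)
  ind <- vapply(lines, function(l) data$lines == l, logical(length(data$lines)))
  counts <- p %*% ind
  rownames(data$intensity)[apply(counts, 1, max) >= min_present]
}

# vectorised one-way fixed-effects ANOVA across lines, one F/P per probe
.anova_p <- function(data, probes = NULL, log2_input = FALSE) {
  x <- data$intensity
  if (!is.null(probes)) x <- x[probes, , drop = FALSE]
  if (log2_input) x <- log2(pmax(x, .Machine$double.eps))
  lines <- unique(data$lines)
  L <- length(lines)
  N <- ncol(x)
  if (L < 2L) stop("ANOVA requires >= 2 lines")
  if (N <= L) stop("ANOVA requires >= 2 replicates per line")
  ind <- vapply(lines, function(l) data$lines == l, logical(N))
  nl <- colSums(ind)
  gm <- sweep(x %*% ind, 2, nl, "/")            # group means
  grand <- rowMeans(x)
  ssb <- rowSums(sweep(gm - grand, 2, nl, "*") * (gm - grand))
  sst <- rowSums((x - grand)^2)
  ssw <- pmax(sst - ssb, 0)
  f <- (ssb / (L - 1)) / (ssw / (N - L))
  p <- pf(f, L - 1, N - L, lower.tail = FALSE)
  # all-equal degenerate probes (0/0): undefined, treated as not significant
  degenerate <- ssw < 1e-300 & ssb < 1e-300
  p[degenerate] <- 1
  attr(p, "degenerate") <- sum(degenerate)
  names(p) <- rownames(x)
  p
}

#' One-way ANOVA probe filter
#'
#' Retains probes whose expression differs among cell lines by a one-way
#' fixed-effects ANOVA (replicates as observations) at `P < alpha`. By
#' default the test runs on linear normalised intensities; set
#' `log2_input = TRUE` to test log2 signals instead.
#'
#' @param data An [expression_dataset()].
#' @param probes Probe ids to test (default: all).
#' @param alpha Significance threshold.
#' @param log2_input Test on log2-transformed intensities?
#' @return Character vector of retained probe ids, with the per-probe P
#'   values as attribute `"p"`.
#' @export
anova_filter <- function(data, probes = NULL, alpha = 0.05,
                         log2_input = FALSE) {
  p <- .anova_p(data, probes, log2_input)
  if (attr(p, "degenerate") > 0)
    message(attr(p, "degenerate"),
            " probe(s) with undefined ANOVA treated as not significant")
  keep <- names(p)[p < alpha]
  attr(keep, "p") <- p
  keep
}

#' Fold-range probe filter
#'
#' Retains probes whose line-mean intensities span at least `min_ratio`
#' between the highest- and lowest-expressing lines (boundary inclusive).
#' A non-positive minimum with positive maximum is treated as an infinite
#' ratio (retained, logged).
#'
#' @param data An [expression_dataset()].
#' @param probes Probe ids to test (default: all).
#' @param min_ratio Minimum max/min ratio of line means (default 5).
#' @return Character vector of retained probe ids, with the per-probe
#'   ratios as attribute `"ratio"`.
#' @export
fold_filter <- function(data, probes = NULL, min_ratio = 5) {
  m <- .line_means(data, probes)
  mn <- apply(m, 1, min)
  mx <- apply(m, 1, max)
  ratio <- ifelse(mn > 0, mx / mn, ifelse(mx > 0, Inf, NaN))
  n_inf <- sum(is.infinite(ratio))
  if (n_inf > 0)
    message(n_inf, " probe(s) with non-positive minimum line mean ",
            "treated as infinite fold range")
  keep <- rownames(m)[!is.nan(ratio) & ratio >= min_ratio]
  attr(keep, "ratio") <- setNames(ratio, rownames(m))
  keep
}

#' Three-step probe filter
#'
#' Applies, in order: the present-call filter, the one-way ANOVA filter, and
#' the fold-range filter. Survivor sets are nested by construction.
#'
#' @param data A normalised [expression_dataset()] with calls.
#' @param alpha ANOVA significance threshold.
#' @param min_present Present-call threshold (per line).
#' @param min_ratio Fold-range threshold.
#' @param log2_input Run the ANOVA on log2 intensities?
#' @return A `filter_report`: list with `steps` (survivor id vectors
#'   `present`, `anova`, `fold`), `counts`, `anova_p` and `fold_range`.
#' @export
filter_probes <- function(data, alpha = 0.05, min_present = 4,
                          min_ratio = 5, log2_input = FALSE) {
  stopifnot(inherits(data, "expression_dataset"))
  s1 <- present_filter(data, min_present)
  if (length(s1)) {
    a <- anova_filter(data, s1, alpha, log2_input)
    s2 <- as.character(a)
    p <- attr(a, "p")
  } else {
    s2 <- character(0)
    p <- numeric(0)
  }
  if (length(s2)) {
    f <- fold_filter(data, s2, min_ratio)
    s3 <- as.character(f)
    ratio <- attr(f, "ratio")
  } else {
    s3 <- character(0)
    ratio <- numeric(0)
  }
  structure(list(
    steps = list(present = s1, anova = s2, fold = s3),
    counts = c(input = nrow(data$intensity), present = length(s1),
               anova = length(s2), fold = length(s3)),
    anova_p = p,
    fold_range = ratio,
    parameters = list(alpha = alpha, min_present = min_present,
                      min_ratio = min_ratio, log2_input = log2_input)),
    class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Three-step probe filter\n")
  cat(sprintf("  input:          %6d probes\n", x$counts["input"]))
  cat(sprintf("  present-call:   %6d\n", x$counts["present"]))
  cat(sprintf("  ANOVA P < %g: %6d\n", x$parameters$alpha, x$counts["anova"]))
  cat(sprintf("  fold >= %g:      %6d\n", x$parameters$min_ratio,
              x$counts["fold"]))
  invisible(x)
}
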