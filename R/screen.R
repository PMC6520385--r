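# Probe-by-probe Spearman screen against lineage propensity ranks, with the
# exact small-n permutation null, signed candidate sets, and the
# inverse-correlation (switch-marker) intersection.

#' Screen probes for rank correlation with lineage propensities
#'
#' For every probe, the replicate-summarised intensity per line (mean by
#' default) is rank-correlated against each lineage's propensity order
#' (equivalently the PC1 scores: both orientations rank the highest
#' propensity first, so a positive \eqn{r_s} means higher expression in
#' lines with stronger propensity). Significance is decided against the
#' exact two-sided permutation null at `n = n_lines`: tie-free probes by the
#' unrounded critical value, tied probes by exact enumeration over the tied
#' rank multiset. No multiple-testing correction is applied to the selection
#' (the screen uses raw exact P < alpha); BH q-values are reported for
#' transparency.
#'
#' @param data An [expression_dataset()].
#' @param probes Probe ids to screen (e.g. the filter survivors).
#' @param ranking A `propensity_ranking` covering the same cell lines.
#' @param alpha Two-sided significance level (default 0.05).
#' @param annotation Optional probe-to-gene map: data frame with columns
#'   `probe_id`, `gene`.
#' @param summary Replicate summary statistic, `"mean"` or `"median"`.
#' @return An object of class `marker_screen_result`: list with `table`
#'   (probe, gene, lineage, r_s, exact_p, q, significant, sign),
#'   `candidates` (per lineage, `positive`/`negative` probe-id sets),
#'   `critical`, `n_lines`, `alpha`, `annotation`.
#' @export
screen_markers <- function(data, probes, ranking, alpha = 0.05,
                           annotation = NULL,
                           summary = c("mean", "median")) {
  stopifnot(inherits(data, "expression_dataset"),
            inherits(ranking, "propensity_ranking"))
  summary <- match.arg(summary)
  lines <- unique(data$lines)
  if (!setequal(lines, rownames(ranking$pc1)))
    stop("cell lines in expression data and ranking do not match")
  n <- length(lines)
  crit <- exact_critical_value(n, alpha)
  if (!crit$attainable)
    warning("no attainable critical value at n = ", n,
            ": nothing can be significant")

  if (length(probes) == 0) {
    tab <- data.frame(probe = character(0), gene = character(0),
                      lineage = character(0), r_s = numeric(0),
                      exact_p = numeric(0), q = numeric(0),
                      significant = logical(0), sign = character(0))
    lineages <- colnames(ranking$pc1)
    candidates <- lapply(setNames(lineages, lineages), function(lg)
      list(positive = character(0), negative = character(0)))
    return(structure(list(table = tab, candidates = candidates,
                          critical = crit, n_lines = n, alpha = alpha,
                          annotation = annotation),
                     class = "marker_screen_result"))
  }
  if (summary == "mean") {
    lm <- .line_means(data, probes)
  } else {
    x <- data$intensity[probes, , drop = FALSE]
    lm <- vapply(lines, function(l) {
      apply(x[, data$lines == l, drop = FALSE], 1, stats::median)
    }, numeric(length(probes)))
    if (length(probes) == 1L) lm <- matrix(lm, nrow = 1,
                                           dimnames = list(probes, lines))
  }
  lm <- lm[, rownames(ranking$pc1), drop = FALSE]  # align line order

  # rank probe intensities within each row; propensity order from PC1
  xr <- t(apply(lm, 1, rank))
  if (length(probes) == 1L) xr <- matrix(xr, nrow = 1,
                                         dimnames = list(probes, NULL))
  lineages <- colnames(ranking$pc1)
  rows <- vector("list", length(lineages))
  degenerate <- apply(xr, 1, function(v) sd(v) == 0)
  if (any(degenerate))
    warning(sum(degenerate), " probe(s) constant across lines: ",
            "r_s undefined, treated as not significant")
  tied <- apply(xr, 1, anyDuplicated) > 0 & !degenerate

  xs <- (xr - rowMeans(xr)) / sqrt(pmax(rowSums((xr - rowMeans(xr))^2), 1e-300))
  for (k in seq_along(lineages)) {
    yr <- rank(ranking$pc1[, k])   # ascending: high PC1 = high rank value
    ys <- (yr - mean(yr)) / sqrt(sum((yr - mean(yr))^2))
    r <- as.numeric(xs %*% ys)
    r[degenerate] <- NA_real_
    p <- rep(NA_real_, length(r))
    idx_free <- which(!degenerate & !tied)
    if (length(idx_free))
      p[idx_free] <- spearman_exact_p(r[idx_free], n)
    for (i in which(tied))
      p[i] <- spearman_exact_p_tied(xr[i, ], yr)
    sig <- !is.na(p) & ifelse(tied, p < alpha,
                              !is.na(r) & crit$attainable &
                                abs(r) >= crit$critical - 1e-12)
    rows[[k]] <- data.frame(
      probe = rownames(xr), lineage = lineages[k], r_s = r, exact_p = p,
      q = p.adjust(p, method = "BH"),
      significant = sig,
      sign = ifelse(sig, ifelse(r > 0, "positive", "negative"), NA_character_),
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  if (!is.null(annotation)) {
    if (!all(c("probe_id", "gene") %in% names(annotation)))
      stop("annotation must have columns probe_id, gene")
    tab$gene <- annotation$gene[match(tab$probe, annotation$probe_id)]
  } else {
    tab$gene <- NA_character_
  }
  tab <- tab[, c("probe", "gene", "lineage", "r_s", "exact_p", "q",
                 "significant", "sign")]
  candidates <- lapply(setNames(lineages, lineages), function(lg) {
    sub <- tab[tab$lineage == lg & tab$significant, ]
    list(positive = sub$probe[sub$sign == "positive"],
         negative = sub$probe[sub$sign == "negative"])
  })
  structure(list(table = tab, candidates = candidates,
                 critical = crit, n_lines = n, alpha = alpha,
                 annotation = annotation),
            class = "marker_screen_result")
}

#' @export
print.marker_screen_result <- function(x, ...) {
  cat(sprintf("marker_screen_result: %d probes x %d lineages, n = %d lines\n",
              length(unique(x$table$probe)), length(x$candidates), x$n_lines))
  for (lg in names(x$candidates))
    cat(sprintf("  %s: %d positive, %d negative\n", lg,
                length(x$candidates[[lg]]$positive),
                length(x$candidates[[lg]]$negative)))
  invisible(x)
}

# map a probe set to gene symbols through the screen's annotation
.genes_of <- function(result, probes) {
  ann <- result$annotation
  g <- ann$gene[match(probes, ann$probe_id)]
  list(genes = unique(g[!is.na(g) & g != ""]),
       unannotated = sum(is.na(g) | g == ""))
}

#' Inverse-correlation (switch-marker) intersection
#'
#' Candidate probes are mapped to genes, then intersected across lineages in
#' two orientations: orientation A = positively correlated with ectoderm and
#' negatively with both mesoderm and endoderm; orientation B is the mirror
#' image. A gene in either set behaves as a differentiation switch between
#' the ectoderm and mesoderm/endoderm fates.
#'
#' @param result A `marker_screen_result` built with a probe-to-gene
#'   annotation.
#' @param lineages Character vector naming the (ectoderm, mesoderm,
#'   endoderm) columns, in that order. Defaults to the screen's lineages.
#' @return List with `ecto_positive` and `ecto_negative` gene sets and
#'   `unannotated` (count of candidate probes without gene annotation).
#' @export
inverse_correlation_intersection <- function(result, lineages = NULL) {
  stopifnot(inherits(result, "marker_screen_result"))
  if (is.null(result$annotation))
    stop("an annotation (probe -> gene) is required for gene-level sets")
  if (is.null(lineages)) lineages <- names(result$candidates)
  if (length(lineages) != 3)
    stop("exactly three lineages required, got ", length(lineages))
  cand <- result$candidates[lineages]
  unann <- 0L
  gene_set <- function(lg, sgn) {
    gs <- .genes_of(result, cand[[lg]][[sgn]])
    unann <<- unann + gs$unannotated
    gs$genes
  }
  a <- Reduce(intersect, list(gene_set(lineages[1], "positive"),
                              gene_set(lineages[2], "negative"),
                              gene_set(lineages[3], "negative")))
  b <- Reduce(intersect, list(gene_set(lineages[1], "negative"),
                              gene_set(lineages[2], "positive"),
                              gene_set(lineages[3], "positive")))
  list(ecto_positive = sort(a), ecto_negative = sort(b), unannotated = unann)
}

#' Top-k propensity marker candidates
#'
#' Per lineage and sign, the `k` significant genes with the largest
#' \eqn{|r_s|}. Ties in \eqn{|r_s|} break lexicographically by gene id (then
#' probe id), so the table is deterministic across runs.
#'
#' @param result A `marker_screen_result`.
#' @param k Number of genes per (lineage, sign); fewer are returned when
#'   fewer candidates exist.
#' @return Data frame (`lineage`, `sign`, `rank`, `gene`, `probe`, `r_s`).
#' @export
top_k_table <- function(result, k = 5) {
  stopifnot(inherits(result, "marker_screen_result"))
  if (k == 0) {
    return(data.frame(lineage = character(0), sign = character(0),
                      rank = integer(0), gene = character(0),
                      probe = character(0), r_s = numeric(0)))
  }
  tab <- result$table[result$table$significant, ]
  out <- list()
  for (lg in names(result$candidates)) {
    for (sgn in c("positive", "negative")) {
      sub <- tab[tab$lineage == lg & tab$sign == sgn, ]
      if (nrow(sub) == 0) next
      key_gene <- ifelse(is.na(sub$gene), sub$probe, sub$gene)
      ord <- order(-abs(sub$r_s), key_gene, sub$probe)
      sub <- sub[utils::head(ord, k), ]
      out[[paste(lg, sgn)]] <- data.frame(
        lineage = lg, sign = sgn, rank = seq_len(nrow(sub)),
        gene = sub$gene, probe = sub$probe, r_s = sub$r_s,
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(lineage = character(0), sign = character(0),
               rank = integer(0), gene = character(0),
               probe = character(0), r_s = numeric(0))
  rownames(res) <- NULL
  res
}
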