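# Trilineage propensity ranking: comparative-Ct quantification of the qPCR
# marker panel, per-gene z-scoring, PCA per germ layer, PC1-based line ranks.

#' Comparative-Ct relative quantification
#'
#' Duplicate wells are averaged on the Ct scale, then
#' \eqn{\Delta Ct = Ct_{gene} - Ct_{housekeeping}} per (line, replicate) and
#' \eqn{\Delta\Delta Ct = \Delta Ct - \overline{\Delta Ct}_{reference}}
#' (mean over all reference-line replicates). Fold change is
#' \eqn{2^{-\Delta\Delta Ct}}; the reference line's mean fold change is 1
#' for every gene.
#'
#' @param ct Long-format data frame with columns `line`, `replicate`,
#'   `gene`, `well`, `ct` (Ct > 0).
#' @param housekeeping Housekeeping gene id (default `"GAPDH"`).
#' @param reference_line Reference cell line (default `"201B7"`).
#' @return Data frame (`line`, `replicate`, `gene`, `fold`) of relative
#'   expression, housekeeping gene excluded.
#' @export
comparative_ct <- function(ct, housekeeping = "GAPDH",
                           reference_line = "201B7") {
  req <- c("line", "replicate", "gene", "ct")
  if (!all(req %in% names(ct)))
    stop("ct table must have columns: ", paste(req, collapse = ", "))
  if (any(ct$ct <= 0)) stop("Ct values must be positive")
  if (!housekeeping %in% ct$gene)
    stop("housekeeping gene not found: ", housekeeping)
  if (!reference_line %in% ct$line)
    stop("reference line not found: ", reference_line)
  # mean over duplicate wells
  agg <- stats::aggregate(ct ~ line + replicate + gene, data = ct, FUN = mean)
  hk <- agg[agg$gene == housekeeping, c("line", "replicate", "ct")]
  names(hk)[3] <- "hk_ct"
  gn <- agg[agg$gene != housekeeping, ]
  merged <- merge(gn, hk, by = c("line", "replicate"), all.x = TRUE)
  dropped <- is.na(merged$hk_ct)
  if (any(dropped)) {
    bad <- unique(merged[dropped, c("line", "replicate")])
    message(nrow(bad), " (line, replicate) pair(s) without housekeeping Ct ",
            "excluded")
    merged <- merged[!dropped, ]
  }
  merged$dct <- merged$ct - merged$hk_ct
  ref <- merged[merged$line == reference_line, ]
  ref_mean <- tapply(ref$dct, ref$gene, mean)
  merged$ddct <- merged$dct - ref_mean[as.character(merged$gene)]
  merged$fold <- 2^(-merged$ddct)
  out <- merged[order(merged$gene, merged$line, merged$replicate),
                c("line", "replicate", "gene", "fold")]
  rownames(out) <- NULL
  out
}

#' Line-mean fold-change matrix
#'
#' @param fold Output of [comparative_ct()].
#' @return Numeric matrix, lines x genes, of mean fold change per line.
#' @export
line_mean_fold <- function(fold) {
  tab <- tapply(fold$fold, list(fold$line, fold$gene), mean)
  m <- matrix(tab, nrow = nrow(tab), dimnames = dimnames(tab))
  if (anyNA(m)) stop("incomplete (line, gene) coverage in fold table")
  m
}

#' Per-gene standardisation (z-scoring)
#'
#' Standardises each gene (column) across lines to mean 0, SD 1. The
#' population SD (divide by n) is the default; ranks downstream are
#' invariant to the convention. Zero-variance genes are dropped with a
#' warning because their z-score is undefined.
#'
#' @param mat Numeric matrix, lines x genes.
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return Standardised matrix, possibly with fewer columns.
#' @export
zscore_per_gene <- function(mat, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (nrow(mat) < 2) stop("z-scoring requires >= 2 lines")
  mu <- colMeans(mat)
  sdv <- apply(mat, 2, sd)
  if (sd_type == "population")
    sdv <- sdv * sqrt((nrow(mat) - 1) / nrow(mat))
  drop_cols <- sdv == 0 | is.na(sdv)
  if (any(drop_cols)) {
    warning(sum(drop_cols), " zero-variance gene(s) excluded from z-scoring: ",
            paste(utils::head(colnames(mat)[drop_cols], 5), collapse = ", "))
    mat <- mat[, !drop_cols, drop = FALSE]
    mu <- mu[!drop_cols]
    sdv <- sdv[!drop_cols]
  }
  if (ncol(mat) == 0) stop("no non-constant genes left to standardise")
  sweep(sweep(mat, 2, mu, "-"), 2, sdv, "/")
}

#' First principal component of a marker panel
#'
#' PC1 is the projection of the (column-centred) panel matrix onto its first
#' right-singular vector. The sign of a principal component is arbitrary, so
#' the score is oriented deterministically: PC1 must correlate non-negatively
#' with the per-line mean of the panel, making high PC1 mean high overall
#' marker expression.
#'
#' @param z Standardised panel matrix, lines x genes.
#' @return List with `scores` (named PC1 per line), `explained` (fraction of
#'   variance on PC1) and `loadings`.
#' @export
pca_pc1 <- function(z) {
  if (nrow(z) < 2) stop("PCA requires >= 2 lines")
  zc <- sweep(z, 2, colMeans(z), "-")
  sv <- svd(zc)
  if (sv$d[1] <= 1e-12) stop("degenerate panel matrix (rank 0)")
  scores <- sv$u[, 1] * sv$d[1]
  loadings <- sv$v[, 1]
  panel_mean <- rowMeans(z)
  orient <- cor(scores, panel_mean)
  s <- if (is.na(orient) || abs(orient) < 1e-12) {
    nz <- which(abs(loadings) > 1e-12)[1]
    sign(loadings[nz])
  } else {
    sign(orient)
  }
  scores <- scores * s
  loadings <- loadings * s
  names(scores) <- rownames(z)
  names(loadings) <- colnames(z)
  list(scores = scores, explained = sv$d[1]^2 / sum(sv$d^2),
       loadings = loadings)
}

#' Rank cell lines by descending PC1
#'
#' Rank 1 is the line with the highest PC1 (strongest propensity); exact
#' ties receive average ranks.
#'
#' @param pc1 Numeric matrix, lines x lineages, of PC1 scores (or a list of
#'   named score vectors).
#' @param explained Optional named vector of explained-variance fractions.
#' @param panels Optional list of panel gene ids per lineage.
#' @return An object of class `propensity_ranking`: list with `pc1`, `rank`
#'   (1 = highest PC1, average ranks on ties), `explained`, `panels`.
#' @export
rank_lines <- function(pc1, explained = NULL, panels = NULL) {
  if (is.list(pc1) && !is.matrix(pc1))
    pc1 <- do.call(cbind, pc1)
  if (!is.matrix(pc1)) pc1 <- matrix(pc1, ncol = 1)
  rk <- apply(pc1, 2, function(v) rank(-v))
  structure(list(pc1 = pc1, rank = rk, explained = explained,
                 panels = panels),
            class = "propensity_ranking")
}

#' @export
print.propensity_ranking <- function(x, ...) {
  cat(sprintf("propensity_ranking: %d lines x %d lineage(s)\n",
              nrow(x$pc1), ncol(x$pc1)))
  print(x$rank)
  invisible(x)
}

#' Full propensity ranking from a Ct table
#'
#' Convenience wrapper: comparative-Ct quantification, line-mean fold
#' changes, per-gene z-scoring within each lineage panel, PCA, and PC1-based
#' ranking. Genes listed in several panels contribute to each of them.
#'
#' @param ct Long-format Ct table (see [comparative_ct()]).
#' @param panel Data frame with columns `gene`, `lineage` (panel membership;
#'   one row per gene-lineage pair).
#' @param housekeeping,reference_line Passed to [comparative_ct()].
#' @param sd_type Passed to [zscore_per_gene()].
#' @param level `"line"` (default; PCA on the 10 line means) or
#'   `"replicate"` (PCA on all line x replicate samples, PC1 averaged
#'   within line).
#' @return A `propensity_ranking`.
#' @export
propensity_ranking <- function(ct, panel, housekeeping = "GAPDH",
                               reference_line = "201B7",
                               sd_type = "population",
                               level = c("line", "replicate")) {
  level <- match.arg(level)
  if (!all(c("gene", "lineage") %in% names(panel)))
    stop("panel must have columns gene, lineage")
  fold <- comparative_ct(ct, housekeeping, reference_line)
  if (level == "line") {
    m <- line_mean_fold(fold)
  } else {
    tab <- tapply(fold$fold, list(paste(fold$line, fold$replicate, sep = "\r"),
                                  fold$gene), mean)
    m <- matrix(tab, nrow = nrow(tab), dimnames = dimnames(tab))
  }
  lineages <- unique(as.character(panel$lineage))
  pc1 <- list(); expl <- c(); panels <- list()
  for (lg in lineages) {
    genes <- intersect(panel$gene[panel$lineage == lg], colnames(m))
    if (length(genes) == 0) stop("no panel genes found for lineage ", lg)
    z <- zscore_per_gene(m[, genes, drop = FALSE], sd_type)
    p <- pca_pc1(z)
    sc <- p$scores
    if (level == "replicate") {
      ln <- sub("\r.*$", "", names(sc))
      sc <- tapply(sc, ln, mean)
      sc <- setNames(as.numeric(sc), names(sc))
    }
    pc1[[lg]] <- sc
    expl[lg] <- p$explained
    panels[[lg]] <- genes
  }
  rank_lines(do.call(cbind, pc1), explained = expl, panels = panels)
}

#' Rank correlation between lineage propensity ranks
#'
#' Spearman correlation of the differentiation ranks for each pair of
#' lineages, with exact two-sided permutation P values (tied ranks fall back
#' to enumeration over the tied multiset).
#'
#' @param ranking A `propensity_ranking`.
#' @return Data frame (`lineage1`, `lineage2`, `r_s`, `p`).
#' @export
interlineage_rank_correlation <- function(ranking) {
  stopifnot(inherits(ranking, "propensity_ranking"))
  rk <- ranking$rank
  if (ncol(rk) < 2) stop("at least two lineages required")
  prs <- utils::combn(colnames(rk), 2)
  out <- data.frame(lineage1 = prs[1, ], lineage2 = prs[2, ],
                    r_s = NA_real_, p = NA_real_)
  for (i in seq_len(ncol(prs))) {
    x <- rk[, prs[1, i]]
    y <- rk[, prs[2, i]]
    r <- spearman_rho(x, y)
    out$r_s[i] <- r
    if (is.na(r)) next
    tied <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
    out$p[i] <- if (tied && nrow(rk) <= 10) {
      spearman_exact_p_tied(rank(x), rank(y))
    } else {
      spearman_exact_p(r, nrow(rk))
    }
  }
  out
}
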