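# HM450-style differential methylation: detection/annotation filtering,
# per-probe t tests with BH correction, hyper/hypo classification, genomic
# region categorisation and per-gene island/shore tracks.

.REGION_PRIORITY <- c("TSS200", "TSS1500", "5'UTR", "1stExon", "Body", "3'UTR")
.REGION_LABELS <- c("TSS1500", "TSS200", "5'UTR", "1st exon", "Gene body",
                    "3'UTR", "Intergenic")
.REGION_MAP <- c(TSS1500 = "TSS1500", TSS200 = "TSS200", "5'UTR" = "5'UTR",
                 "1stExon" = "1st exon", Body = "Gene body", "3'UTR" = "3'UTR")

#' Methylation dataset container
#'
#' Beta values (0 = unmethylated, 1 = methylated) over two groups of
#' replicate arrays, with per-sample detection P values and an HM450-style
#' probe manifest.
#'
#' @param beta Numeric matrix in `[0, 1]`, probes x samples, probe ids as
#'   rownames, sample columns named `<group>_<replicate>`.
#' @param detection_p Numeric matrix of detection P values, same shape.
#' @param manifest Data frame with columns `IlmnID`, `CHR`, `MAPINFO`,
#'   `UCSC_RefGene_Name`, `UCSC_RefGene_Group`,
#'   `Relation_to_UCSC_CpG_Island` (empty strings mark missing annotation).
#' @param groups Character/factor of group labels, one per sample column
#'   (exactly two distinct groups).
#' @return An object of class `methylation_dataset`.
#' @export
methylation_dataset <- function(beta, detection_p, manifest, groups) {
  if (!is.matrix(beta) || is.null(rownames(beta)))
    stop("beta must be a matrix with probe-id rownames")
  if (anyDuplicated(rownames(beta)))
    stop("duplicate probe id: ", rownames(beta)[duplicated(rownames(beta))][1])
  if (any(beta < 0 | beta > 1)) stop("beta values must lie in [0, 1]")
  if (!identical(dim(beta), dim(detection_p)))
    stop("beta and detection_p must share dimensions")
  groups <- as.character(groups)
  if (length(groups) != ncol(beta)) stop("one group label per column required")
  if (length(unique(groups)) != 2L) stop("exactly two groups required")
  req <- c("IlmnID", "CHR", "MAPINFO", "UCSC_RefGene_Name",
           "UCSC_RefGene_Group", "Relation_to_UCSC_CpG_Island")
  if (!all(req %in% names(manifest)))
    stop("manifest missing column(s): ",
         paste(setdiff(req, names(manifest)), collapse = ", "))
  structure(list(beta = beta, detection_p = detection_p, manifest = manifest,
                 groups = groups),
            class = "methylation_dataset")
}

#' @export
print.methylation_dataset <- function(x, ...) {
  cat(sprintf("methylation_dataset: %d probes, groups %s (%s replicates)\n",
              nrow(x$beta), paste(unique(x$groups), collapse = " vs "),
              paste(table(x$groups)[unique(x$groups)], collapse = "/")))
  invisible(x)
}

#' Detection P-value filter
#'
#' A probe is retained only if its detection P value is below `threshold` in
#' every sample; a single sample at `P >= threshold` removes the probe.
#'
#' @param data A [methylation_dataset()].
#' @param threshold Detection P threshold (default 0.01, exclusive).
#' @return Character vector of retained probe ids.
#' @export
detection_filter <- function(data, threshold = 0.01) {
  stopifnot(inherits(data, "methylation_dataset"))
  keep <- apply(data$detection_p < threshold, 1, all)
  rownames(data$beta)[keep]
}

#' Annotation filter
#'
#' Retains probes whose manifest row carries both a chromosome and a
#' position. Probes absent from the manifest are removed and counted
#' separately (attribute `"missing_from_manifest"`).
#'
#' @param probes Character vector of probe ids.
#' @param manifest HM450-style manifest data frame.
#' @return Retained probe ids.
#' @export
annotation_filter <- function(probes, manifest) {
  idx <- match(probes, manifest$IlmnID)
  missing <- is.na(idx)
  chr <- as.character(manifest$CHR[idx])
  pos <- manifest$MAPINFO[idx]
  annotated <- !missing & !is.na(chr) & chr != "" &
    !is.na(pos) & as.character(pos) != ""
  out <- probes[annotated]
  attr(out, "missing_from_manifest") <- sum(missing)
  out
}

#' Classify probes from q-value and log2 fold-change
#'
#' Both thresholds are strict: `hyper` requires `q < q_threshold` AND
#' `lfc > lfc_threshold`; `hypo` mirrors with `lfc < -lfc_threshold`.
#' Boundary values (`q == q_threshold`, `|lfc| == lfc_threshold`) are
#' `unchanged`.
#'
#' @param q BH-adjusted P values.
#' @param lfc log2 fold-changes (group 2 over group 1).
#' @param q_threshold,lfc_threshold Classification thresholds.
#' @return Character vector in `{hyper, hypo, unchanged}`.
#' @export
classify_methylation <- function(q, lfc, q_threshold = 0.05,
                                 lfc_threshold = 0.6) {
  ifelse(q < q_threshold & lfc > lfc_threshold, "hyper",
         ifelse(q < q_threshold & lfc < -lfc_threshold, "hypo", "unchanged"))
}

#' Differential methylation between two groups
#'
#' Per-probe two-sided two-sample t test on beta values (pooled-variance
#' Student's t by default; Welch optional), Benjamini-Hochberg correction
#' over all retained probes, and log2 fold-change of group mean betas with
#' an epsilon floor. Probes not in `probes` are carried with class
#' `"excluded"` so that hyper + hypo + unchanged + excluded equals the probe
#' total.
#'
#' @param data A [methylation_dataset()].
#' @param probes Retained probe ids (after detection and annotation
#'   filters); defaults to all probes.
#' @param q_threshold,lfc_threshold Classification thresholds (strict).
#' @param var_equal Pooled-variance t test (default) or Welch.
#' @param epsilon Floor applied to group means before the log ratio.
#' @param use_m_values Compute the fold change on M-values
#'   (logit2-transformed betas) instead of betas.
#' @return An object of class `diff_methylation`: list with `table` (probe,
#'   mean_g1, mean_g2, lfc, t, p, q, class), `groups`, `thresholds`.
#' @export
differential_methylation <- function(data, probes = NULL,
                                     q_threshold = 0.05, lfc_threshold = 0.6,
                                     var_equal = TRUE, epsilon = 1e-6,
                                     use_m_values = FALSE) {
  stopifnot(inherits(data, "methylation_dataset"))
  all_probes <- rownames(data$beta)
  if (is.null(probes)) probes <- all_probes
  b <- data$beta[probes, , drop = FALSE]
  gl <- unique(data$groups)
  g1 <- data$groups == gl[1]
  g2 <- data$groups == gl[2]
  n1 <- sum(g1); n2 <- sum(g2)
  if (n1 < 2 || n2 < 2) stop("at least 2 replicates per group required")
  x1 <- b[, g1, drop = FALSE]; x2 <- b[, g2, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(se))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tt <- (m2 - m1) / se
  p <- 2 * pt(abs(tt), df, lower.tail = FALSE)
  degenerate <- se == 0 & m1 == m2
  if (any(degenerate)) {
    p[degenerate] <- 1
    tt[degenerate] <- 0
    message(sum(degenerate), " probe(s) with zero variance and equal means: ",
            "p set to 1")
  }
  q <- p.adjust(p, method = "BH")
  if (use_m_values) {
    mv1 <- log2(pmax(m1, epsilon) / pmax(1 - m1, epsilon))
    mv2 <- log2(pmax(m2, epsilon) / pmax(1 - m2, epsilon))
    lfc <- mv2 - mv1
  } else {
    lfc <- log2(pmax(m2, epsilon) / pmax(m1, epsilon))
  }
  cls <- classify_methylation(q, lfc, q_threshold, lfc_threshold)
  tab <- data.frame(probe = probes, mean_g1 = m1, mean_g2 = m2, lfc = lfc,
                    t = tt, p = p, q = q, class = cls,
                    stringsAsFactors = FALSE)
  excl <- setdiff(all_probes, probes)
  if (length(excl)) {
    tab <- rbind(tab, data.frame(probe = excl, mean_g1 = NA_real_,
                                 mean_g2 = NA_real_, lfc = NA_real_,
                                 t = NA_real_, p = NA_real_, q = NA_real_,
                                 class = "excluded",
                                 stringsAsFactors = FALSE))
  }
  rownames(tab) <- NULL
  structure(list(table = tab, groups = gl,
                 thresholds = list(q = q_threshold, lfc = lfc_threshold,
                                   var_equal = var_equal, epsilon = epsilon,
                                   use_m_values = use_m_values)),
            class = "diff_methylation")
}

#' @export
print.diff_methylation <- function(x, ...) {
  cnt <- table(factor(x$table$class,
                      levels = c("hyper", "hypo", "unchanged", "excluded")))
  cat(sprintf("diff_methylation: %s vs %s\n", x$groups[1], x$groups[2]))
  print(cnt)
  invisible(x)
}

#' Summary fractions of differential methylation
#'
#' Reports (as percentages) the fraction of assessed probes that changed
#' methylation status, and the fraction of those differential probes that
#' are hypermethylated. Denominators: `assessed` = probes not excluded by
#' filters; `differential` = hyper + hypo.
#'
#' @param result A `diff_methylation`.
#' @return List with `pct_differential`, `pct_hyper_among_differential`
#'   (NA when no probe is differential), and the counts used.
#' @export
summarize_fractions <- function(result) {
  stopifnot(inherits(result, "diff_methylation"))
  cls <- result$table$class
  assessed <- sum(cls != "excluded")
  hyper <- sum(cls == "hyper")
  hypo <- sum(cls == "hypo")
  diffn <- hyper + hypo
  list(pct_differential = if (assessed > 0) 100 * diffn / assessed else NA,
       pct_hyper_among_differential = if (diffn > 0) 100 * hyper / diffn
                                      else NA,
       counts = c(assessed = assessed, differential = diffn, hyper = hyper,
                  hypo = hypo))
}

# single region category per probe by fixed promoter-first priority
.region_category <- function(groups) {
  vapply(strsplit(ifelse(is.na(groups), "", groups), ";", fixed = TRUE),
         function(toks) {
           toks <- toks[toks != ""]
           if (length(toks) == 0) return("Intergenic")
           hit <- .REGION_PRIORITY[.REGION_PRIORITY %in% toks][1]
           if (is.na(hit)) return("Intergenic")
           unname(.REGION_MAP[hit])
         }, character(1))
}

#' Seven-category genomic region distribution
#'
#' Assigns each probe of the requested class exactly one of TSS1500,
#' TSS200, 5'UTR, 1st exon, gene body, 3'UTR or intergenic, using a fixed
#' promoter-first priority (TSS200 > TSS1500 > 5'UTR > 1st exon > gene body
#' > 3'UTR; probes without any gene association are intergenic), then
#' reports the percentage distribution (summing to 100).
#'
#' @param result A `diff_methylation`.
#' @param manifest HM450-style manifest.
#' @param class Probe class to summarise (default `"hyper"`).
#' @return Named numeric vector of percentages over the seven categories,
#'   with probe counts as attribute `"counts"`.
#' @export
region_distribution <- function(result, manifest, class = "hyper") {
  stopifnot(inherits(result, "diff_methylation"))
  probes <- result$table$probe[result$table$class == class]
  if (length(probes) == 0)
    stop("no probes of class '", class, "'")
  grp <- manifest$UCSC_RefGene_Group[match(probes, manifest$IlmnID)]
  cat7 <- factor(.region_category(grp), levels = .REGION_LABELS)
  counts <- table(cat7)
  pct <- 100 * as.numeric(counts) / length(probes)
  names(pct) <- .REGION_LABELS
  attr(pct, "counts") <- setNames(as.integer(counts), .REGION_LABELS)
  pct
}

#' Per-gene methylation track
#'
#' All probes annotated to a gene, ordered by genomic position, with the
#' CpG-island relation, group mean betas and a per-probe significance flag.
#' Significance here is the raw t-test `P < 0.05` (track-level criterion),
#' deliberately distinct from the genome-wide hyper/hypo classification
#' which additionally requires the BH q-value and fold-change thresholds.
#'
#' @param gene Gene symbol.
#' @param data A [methylation_dataset()].
#' @param result A `diff_methylation` computed from `data`.
#' @param manifest HM450-style manifest (defaults to the dataset's).
#' @param p_threshold Raw P threshold for the track flag.
#' @return Data frame (`probe`, `chr`, `position`, `relation`, `mean_g1`,
#'   `mean_g2`, `p`, `significant`) ordered by position.
#' @export
gene_track <- function(gene, data, result, manifest = NULL,
                       p_threshold = 0.05) {
  stopifnot(inherits(data, "methylation_dataset"),
            inherits(result, "diff_methylation"))
  if (is.null(manifest)) manifest <- data$manifest
  gene_lists <- strsplit(ifelse(is.na(manifest$UCSC_RefGene_Name), "",
                                manifest$UCSC_RefGene_Name), ";", fixed = TRUE)
  hit <- vapply(gene_lists, function(g) gene %in% g, logical(1))
  if (!any(hit)) stop("gene not present in manifest: ", gene)
  man <- manifest[hit, ]
  idx <- match(man$IlmnID, result$table$probe)
  out <- data.frame(probe = man$IlmnID,
                    chr = as.character(man$CHR),
                    position = as.numeric(man$MAPINFO),
                    relation = as.character(man$Relation_to_UCSC_CpG_Island),
                    mean_g1 = result$table$mean_g1[idx],
                    mean_g2 = result$table$mean_g2[idx],
                    p = result$table$p[idx],
                    stringsAsFactors = FALSE)
  out$significant <- !is.na(out$p) & out$p < p_threshold
  out <- out[order(out$position), ]
  rownames(out) <- NULL
  out
}
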