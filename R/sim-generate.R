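# Generators: lineage propensities, expression arrays with planted markers,
# panel qPCR Ct tables, and two-group methylation arrays.

# symmetric PSD square root; errors on genuinely indefinite input
.psd_factor <- function(C, what = "coupling") {
  e <- eigen(C, symmetric = TRUE)
  if (min(e$values) < -1e-8)
    stop("infeasible ", what,
         " (rank-correlation structure not positive semidefinite)")
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(C))
}

# pseudo-inverse square root for whitening (tolerates rank deficiency)
.pinv_sqrt <- function(W, tol = 1e-10) {
  e <- eigen(W, symmetric = TRUE)
  d <- ifelse(e$values > tol * max(e$values), 1 / sqrt(e$values), 0)
  e$vectors %*% diag(d, nrow(W)) %*% t(e$vectors)
}

.coupling_matrix <- function(coupling) {
  C <- diag(3)
  C[1, 2] <- C[2, 1] <- coupling[["ecto_meso"]]
  C[1, 3] <- C[3, 1] <- coupling[["ecto_endo"]]
  C[2, 3] <- C[3, 2] <- coupling[["meso_endo"]]
  dimnames(C) <- list(.LINEAGES, .LINEAGES)
  C
}

# greedy pairwise-swap refinement of rank columns toward a target Spearman
# coupling matrix (rank-coupled construction: the realized cohort coupling,
# not just its expectation, approximates the target)
.refine_rank_coupling <- function(R, Cs, passes = 8) {
  n <- nrow(R)
  ut <- upper.tri(Cs)
  obj <- function(R) sum((cor(R) - Cs)[ut]^2)
  cur <- obj(R)
  if (cur < 1e-12) return(R)
  for (p in seq_len(passes)) {
    improved <- FALSE
    for (k in 2:ncol(R)) {
      for (i in 1:(n - 1)) {
        for (j in (i + 1):n) {
          R2 <- R
          R2[c(i, j), k] <- R2[c(j, i), k]
          o <- obj(R2)
          if (o < cur - 1e-12) {
            R <- R2
            cur <- o
            improved <- TRUE
          }
        }
      }
    }
    if (!improved) break
  }
  R
}

#' Simulate coupled lineage propensities
#'
#' Draws one latent differentiation-propensity value per (lineage, line)
#' such that the realized pairwise Spearman correlations of the cohort
#' approximate the configured coupling targets. Construction: an
#' Iman-Conover step imposes the target correlation on Gaussian scores,
#' the scores are ranked, and a pairwise-swap refinement tightens the
#' realized rank coupling (the study analyses one fixed cohort of lines, so
#' the generator controls the realized coupling, not merely its
#' expectation). An indefinite target matrix is rejected.
#'
#' @param config A [sim_config()].
#' @return An object of class `propensity_set`: list with `values` (lines x
#'   lineages, Gaussian scores), `ranks` (1 = strongest propensity, the
#'   descending-PC1 convention), `coupling_target` and `coupling_realized`.
#' @export
simulate_propensities <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_lines
  Cs <- .coupling_matrix(config$coupling)
  L <- .psd_factor(Cs, "coupling triple")
  R <- .with_seed(config$seed, {
    M <- matrix(rnorm(n * 3), n, 3)
    Mc <- scale(M)
    Z <- Mc %*% .pinv_sqrt(stats::cor(Mc)) %*% t(L)
    .refine_rank_coupling(apply(Z, 2, rank), Cs)
  })
  values <- apply(R, 2, function(r) qnorm(r / (n + 1)))
  lines <- .line_labels(config)
  dimnames(values) <- list(lines, .LINEAGES)
  ranks <- n + 1 - R  # 1 = strongest propensity
  dimnames(ranks) <- dimnames(values)
  structure(list(values = values, ranks = ranks,
                 coupling_target = Cs,
                 coupling_realized = stats::cor(R)),
            class = "propensity_set")
}

#' @export
print.propensity_set <- function(x, ...) {
  cat(sprintf("propensity_set: %d lines x %d lineages\n",
              nrow(x$values), ncol(x$values)))
  cat("realized coupling (Spearman):\n")
  print(round(x$coupling_realized, 3))
  invisible(x)
}

# planted line-score vector: a permutation of 1..n whose rank correlations
# with the targeted lineages' propensity ranks best match the targets
.plant_scores <- function(prop, targets) {
  n <- nrow(prop$values)
  lineages <- names(targets)
  Rasc <- apply(prop$values[, lineages, drop = FALSE], 2, rank)
  if (n <= 10) {
    v <- .best_rank_plant(Rasc, as.numeric(targets))
  } else {
    # continuous least-squares fallback, then rank
    Chat <- stats::cor(Rasc)
    e <- eigen(Chat, symmetric = TRUE)
    pos <- e$values > 1e-10 * max(e$values)
    a <- e$vectors[, pos, drop = FALSE] %*%
      ((t(e$vectors[, pos, drop = FALSE]) %*% as.numeric(targets)) /
         e$values[pos])
    q <- drop(as.numeric(targets) %*% a)
    if (q > 1) a <- a / sqrt(q)
    v <- rank(drop(scale(Rasc) %*% a))
  }
  v
}

#' Simulate an expression dataset with planted markers
#'
#' Planted probes receive line-mean log2 intensities that are monotone in a
#' rank vector chosen (by exhaustive search over permutations for
#' `n_lines <= 10`) to match the specified rank correlations with the
#' realized propensity ranks; at `noise_sd = 0` the screen therefore
#' recovers the nearest attainable correlation exactly. Null expressed
#' probes have a common mean across lines; absent probes get low intensity
#' and `"A"` calls, expressed probes `"P"` calls.
#'
#' @param config A [sim_config()].
#' @param prop The [simulate_propensities()] output for the same config.
#' @return An [expression_dataset()] with two extra elements: `annotation`
#'   (data frame `probe_id`, `gene`) and `planted` (per planted marker, the
#'   realized noiseless rank correlations).
#' @export
simulate_expression <- function(config, prop) {
  stopifnot(inherits(config, "sim_config"),
            inherits(prop, "propensity_set"))
  n <- config$n_lines
  reps <- config$n_replicates
  ids <- sprintf("P%05d", seq_len(config$n_probes))
  lines <- rownames(prop$values)
  planted_ids <- vapply(config$planted_markers, `[[`, character(1), "probe")

  out <- .with_seed(config$seed + 1L, {
    free <- setdiff(ids, planted_ids)
    n_absent <- round(config$absent_fraction * config$n_probes)
    absent <- sample(free, min(n_absent, length(free)))
    log2_mean <- matrix(0, config$n_probes, n, dimnames = list(ids, lines))
    expressed <- setdiff(free, absent)
    log2_mean[expressed, ] <- config$expr_base_log2 +
      rnorm(length(expressed), 0, 1)   # probe offset, constant across lines
    log2_mean[absent, ] <- config$absent_base_log2 +
      rnorm(length(absent), 0, 0.5)
    planted_info <- list()
    for (m in config$planted_markers) {
      v <- .plant_scores(prop, m$targets)
      vz <- (v - mean(v)) / sd(v)
      log2_mean[m$probe, ] <- config$expr_base_log2 + config$expr_gain * vz
      Rasc <- apply(prop$values[, names(m$targets), drop = FALSE], 2, rank)
      planted_info[[m$probe]] <- list(
        probe = m$probe, gene = m$gene, targets = m$targets,
        realized = setNames(as.numeric(cor(v, Rasc)), names(m$targets)))
    }
    noise <- matrix(rnorm(config$n_probes * n * reps, 0, config$noise_sd),
                    config$n_probes, n * reps)
    rep_mean <- log2_mean[, rep(seq_len(n), each = reps), drop = FALSE]
    intensity <- 2^(rep_mean + noise)
    list(intensity = intensity, absent = absent, planted_info = planted_info)
  })

  sample_lines <- rep(lines, each = reps)
  colnames(out$intensity) <- paste(sample_lines, rep(seq_len(reps), n),
                                   sep = "_")
  rownames(out$intensity) <- ids
  calls <- matrix("P", config$n_probes, n * reps,
                  dimnames = dimnames(out$intensity))
  calls[out$absent, ] <- "A"
  data <- expression_dataset(out$intensity, calls, sample_lines,
                             normalized = FALSE)
  gene <- paste0("G", sub("^P", "", ids))
  for (m in config$planted_markers) gene[ids == m$probe] <- m$gene
  data$annotation <- data.frame(probe_id = ids, gene = gene,
                                stringsAsFactors = FALSE)
  data$planted <- out$planted_info
  data
}

#' Simulate a trilineage panel qPCR Ct table
#'
#' Panel-gene Ct decreases linearly with the (mean, for shared markers)
#' propensity of the gene's lineage(s); the housekeeping gene is constant
#' up to noise; each gene is run in duplicate wells that differ only by
#' noise.
#'
#' @param config A [sim_config()].
#' @param prop The matching [simulate_propensities()] output.
#' @return Long-format data frame (`line`, `replicate`, `gene`, `well`,
#'   `ct`) with the panel membership table as attribute `"panel"`.
#' @export
simulate_panel_cts <- function(config, prop) {
  stopifnot(inherits(config, "sim_config"),
            inherits(prop, "propensity_set"))
  panel <- panel_layout(config)
  genes <- unique(panel$gene)
  lines <- rownames(prop$values)
  n <- length(lines)
  reps <- config$n_replicates
  grid <- expand.grid(well = 1:2, replicate = seq_len(reps), line = lines,
                      gene = c(genes, config$housekeeping),
                      stringsAsFactors = FALSE)
  signal <- vapply(genes, function(g) {
    lgs <- panel$lineage[panel$gene == g]
    rowMeans(prop$values[, lgs, drop = FALSE])
  }, numeric(n))
  mean_ct <- config$ct_base - config$ct_gain * signal  # lines x genes
  ct0 <- numeric(nrow(grid))
  is_hk <- grid$gene == config$housekeeping
  ct0[is_hk] <- config$hk_ct
  li <- match(grid$line, lines)
  gi <- match(grid$gene, genes)
  ct0[!is_hk] <- mean_ct[cbind(li[!is_hk], gi[!is_hk])]
  ct <- .with_seed(config$seed + 2L,
                   ct0 + rnorm(nrow(grid), 0, config$ct_noise_sd))
  out <- data.frame(line = grid$line, replicate = grid$replicate,
                    gene = grid$gene, well = grid$well, ct = ct,
                    stringsAsFactors = FALSE)
  attr(out, "panel") <- panel
  out
}

#' Simulate a two-group methylation dataset
#'
#' Beta values for two groups (control vs knockdown, 3 replicates each by
#' default) with an HM450-style manifest: genes of `probes_per_gene` probes
#' spanning TSS1500/TSS200/5'UTR/1st exon/gene body/3'UTR positions plus
#' intergenic probes; gene-body probes of the first `meth_hyper_genes`
#' genes (synthetic "WNTL" genes) are hypermethylated in group 2 by
#' `meth_effect`, and of the next `meth_hypo_genes` genes hypomethylated.
#' A configured fraction of (never planted) probes lacks chromosome/locus
#' annotation, and another fraction fails detection P < 0.01 in one sample.
#' Out-of-range beta draws are clipped strictly inside (0, 1); the clip
#' count is reported via `attr(, "planted")$clip_count` with a warning.
#'
#' @param config A [sim_config()].
#' @return A [methylation_dataset()] with attribute `"planted"`: list with
#'   `hyper`/`hypo` probe-id sets, `unannotated`, `detection_fail` and
#'   `clip_count`.
#' @export
simulate_methylation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  np <- config$n_meth_probes
  ppg <- config$probes_per_gene
  reps <- config$meth_replicates
  ids <- sprintf("cg%06d", seq_len(np))
  n_genic <- floor(np * 0.9)
  n_genes <- ceiling(n_genic / ppg)
  gene_names <- c(
    if (config$meth_hyper_genes > 0)
      sprintf("WNTL%d", seq_len(config$meth_hyper_genes)),
    if (config$meth_hypo_genes > 0)
      sprintf("HYPOL%d", seq_len(config$meth_hypo_genes)),
    sprintf("MG%04d",
            seq_len(max(0, n_genes - config$meth_hyper_genes -
                          config$meth_hypo_genes))))[seq_len(n_genes)]
  group_tpl <- c("TSS1500", "TSS200", "5'UTR", "1stExon",
                 rep("Body", max(1, ppg - 5)), "3'UTR")
  rel_tpl <- c("N_Shore", "Island", "Island", "Island", "S_Shore",
               rep(c("Island", "OpenSea"), length.out = max(1, ppg - 6)),
               "OpenSea")
  gi <- rep(seq_len(n_genes), each = ppg)[seq_len(n_genic)]
  within <- unlist(lapply(rle(gi)$lengths, seq_len))
  manifest <- data.frame(
    IlmnID = ids,
    CHR = paste0("chr", (c(gi, rep(0, np - n_genic)) %% 22) + 1),
    MAPINFO = c(gi * 100000 + within * 500,
                10000000 + seq_len(np - n_genic) * 137),
    UCSC_RefGene_Name = c(gene_names[gi], rep("", np - n_genic)),
    UCSC_RefGene_Group = c(group_tpl[pmin(within, length(group_tpl))],
                           rep("", np - n_genic)),
    Relation_to_UCSC_CpG_Island = c(rel_tpl[pmin(within, length(rel_tpl))],
                                    rep("OpenSea", np - n_genic)),
    stringsAsFactors = FALSE)
  is_body <- manifest$UCSC_RefGene_Group == "Body"
  hyper_genes <- gene_names[seq_len(config$meth_hyper_genes)]
  hypo_genes <- if (config$meth_hypo_genes > 0)
    gene_names[config$meth_hyper_genes + seq_len(config$meth_hypo_genes)]
  else character(0)
  hyper <- ids[is_body & manifest$UCSC_RefGene_Name %in% hyper_genes]
  hypo <- ids[is_body & manifest$UCSC_RefGene_Name %in% hypo_genes]
  planted_any <- c(hyper, hypo)

  res <- .with_seed(config$seed + 3L, {
    base <- runif(np, 0.2, 0.8)
    # planted baselines are kept in a range where the planted effect both
    # stays inside (0, 1) and crosses the |log2 FC| > 0.6 threshold, so the
    # constructed classes are recoverable by design
    ih <- match(hyper, ids)
    il <- match(hypo, ids)
    hyper_hi <- max(0.21, min(0.45, 0.95 - config$meth_effect))
    hypo_lo <- min(0.74, max(0.45, config$meth_effect + 0.05))
    base[ih] <- runif(length(ih), 0.2, hyper_hi)
    base[il] <- runif(length(il), hypo_lo, 0.75)
    m2 <- base
    m2[match(hyper, ids)] <- base[match(hyper, ids)] + config$meth_effect
    m2[match(hypo, ids)] <- base[match(hypo, ids)] - config$meth_effect
    mu <- cbind(matrix(base, np, reps), matrix(m2, np, reps))
    eps <- 1e-4
    raw <- mu + matrix(rnorm(np * 2 * reps, 0, config$meth_noise_sd),
                       np, 2 * reps)
    clip_count <- sum(raw <= eps | raw >= 1 - eps)
    beta <- pmin(pmax(raw, eps), 1 - eps)
    detp <- matrix(runif(np * 2 * reps, 0, 0.005), np, 2 * reps)
    free <- setdiff(ids, planted_any)
    n_unann <- round(config$meth_unannotated_fraction * np)
    unann <- sample(free, min(n_unann, length(free)))
    free2 <- setdiff(free, unann)
    n_fail <- round(config$meth_detection_fail_fraction * np)
    fail <- sample(free2, min(n_fail, length(free2)))
    fail_col <- sample(2 * reps, length(fail), replace = TRUE)
    detp[cbind(match(fail, ids), fail_col)] <- runif(length(fail), 0.01, 0.5)
    list(beta = beta, detp = detp, unann = unann, fail = fail,
         clip_count = clip_count)
  })
  manifest$CHR[match(res$unann, ids)] <- ""
  manifest$MAPINFO[match(res$unann, ids)] <- NA
  groups <- rep(c("control", "kd"), each = reps)
  cn <- paste(groups, rep(seq_len(reps), 2), sep = "_")
  dimnames(res$beta) <- list(ids, cn)
  dimnames(res$detp) <- list(ids, cn)
  if (res$clip_count > 0)
    warning(res$clip_count, " beta draw(s) clipped into (0, 1)")
  data <- methylation_dataset(res$beta, res$detp, manifest, groups)
  attr(data, "planted") <- list(hyper = hyper, hypo = hypo,
                                unannotated = res$unann,
                                detection_fail = res$fail,
                                clip_count = res$clip_count)
  data
}
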