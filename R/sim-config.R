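# Configuration for the synthetic-data generator. Defaults mirror the study
# design the analysis assumes: 10 hiPSC lines x 6 expression replicates,
# trilineage marker panels of 45/56/27 genes overlapping to 97 distinct
# genes, negative ectoderm-mesoderm and positive mesoderm-endoderm
# propensity coupling, and two methylation groups of 3 replicates.

.LINEAGES <- c("ectoderm", "mesoderm", "endoderm")

#' Planted marker specification
#'
#' Declares a probe whose line-mean expression rank should correlate with
#' one or more lineage propensity ranks at the given signed targets.
#'
#' @param probe Probe id (must exist in the simulated probe set).
#' @param targets Named numeric vector of target Spearman correlations in
#'   `[-1, 1]`; names among `ectoderm`, `mesoderm`, `endoderm`.
#' @param gene Gene symbol for the probe (default `GENE_<probe>`).
#' @return A `planted_marker` list.
#' @examples
#' planted_marker("P00001",
#'                c(ectoderm = 0.9, mesoderm = -0.9, endoderm = -0.9),
#'                gene = "SWITCH1")
#' @export
planted_marker <- function(probe, targets, gene = NULL) {
  stopifnot(is.character(probe), length(probe) == 1)
  if (is.null(names(targets)) || !all(names(targets) %in% .LINEAGES))
    stop("targets must be named with lineages: ",
         paste(.LINEAGES, collapse = ", "))
  if (any(abs(targets) > 1)) stop("|target correlation| must be <= 1")
  if (is.null(gene)) gene <- paste0("GENE_", probe)
  structure(list(probe = probe, targets = targets, gene = gene),
            class = "planted_marker")
}

#' Simulation configuration
#'
#' Collects every tunable of the synthetic-data generator. A fixed `seed`
#' makes all outputs byte-identical across runs; the generator derives
#' independent sub-seeds per stage so stages can be re-simulated
#' individually.
#'
#' @param n_lines Number of cell lines (default 10).
#' @param n_replicates Expression replicates per line (default 6).
#' @param n_probes Number of expression probes (default 5000; desk scale,
#'   not full array scale).
#' @param panel_sizes Named sizes of the ectoderm/mesoderm/endoderm marker
#'   panels (default 45/56/27).
#' @param panel_overlap Named overlap counts `ecto_meso`, `ecto_endo`,
#'   `meso_endo` (pairwise, excluding the triple) and `all_three`; the
#'   default yields 97 distinct genes.
#' @param planted_markers List of [planted_marker()] specs.
#' @param coupling Named target Spearman correlations between lineage
#'   propensities (`ecto_meso`, `ecto_endo`, `meso_endo`). The
#'   ectoderm-endoderm default -0.52 is the value implied by conditional
#'   independence given mesoderm (-0.66 * 0.79).
#' @param noise_sd Replicate-level log2 intensity noise SD (default 0.25).
#' @param absent_fraction Fraction of probes simulated as not expressed
#'   (default 0.3).
#' @param expr_base_log2,expr_gain,absent_base_log2 Expression scale
#'   parameters: baseline log2 intensity of expressed probes, log2 gain per
#'   propensity SD for planted probes, baseline of absent probes.
#' @param ct_base,ct_gain,ct_noise_sd,hk_ct qPCR parameters: baseline Ct of
#'   panel genes, Ct decrease per propensity SD, well-level Ct noise SD,
#'   housekeeping Ct.
#' @param housekeeping,reference_line Housekeeping gene and reference line
#'   labels.
#' @param n_meth_probes,meth_replicates Methylation array size and
#'   replicates per group (default 5000 probes, 3 + 3 samples).
#' @param meth_effect Planted gene-body beta increase in group 2
#'   (default 0.3).
#' @param meth_noise_sd Replicate-level beta noise SD (default 0.02).
#' @param meth_hyper_genes,meth_hypo_genes Number of genes whose gene-body
#'   probes are planted hyper-/hypomethylated. The defaults (31 and 5 genes,
#'   5 gene-body probes each, of 5000 probes) reproduce the study's observed
#'   differential fraction (~3.7% of assessed probes) and hyper share
#'   (~86% of differential probes).
#' @param meth_unannotated_fraction Fraction of probes lacking
#'   chromosome/locus annotation (default 48/485577, the HM450 manifest
#'   rate).
#' @param meth_detection_fail_fraction Fraction of probes failing detection
#'   P < 0.01 in at least one sample (default 0.001).
#' @param probes_per_gene Methylation probes per simulated gene.
#' @param seed Integer RNG seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_lines = 10, n_replicates = 6, n_probes = 5000,
                       panel_sizes = c(ectoderm = 45, mesoderm = 56,
                                       endoderm = 27),
                       panel_overlap = c(ecto_meso = 11, ecto_endo = 2,
                                         meso_endo = 12, all_three = 3),
                       planted_markers = list(),
                       coupling = c(ecto_meso = -0.66, ecto_endo = -0.52,
                                    meso_endo = 0.79),
                       noise_sd = 0.25, absent_fraction = 0.3,
                       expr_base_log2 = 7, expr_gain = 1.5,
                       absent_base_log2 = 4,
                       ct_base = 26, ct_gain = 1.5, ct_noise_sd = 0.15,
                       hk_ct = 20, housekeeping = "GAPDH",
                       reference_line = "201B7",
                       n_meth_probes = 5000, meth_replicates = 3,
                       meth_effect = 0.3, meth_noise_sd = 0.02,
                       meth_hyper_genes = 31, meth_hypo_genes = 5,
                       meth_unannotated_fraction = 48 / 485577,
                       meth_detection_fail_fraction = 0.001,
                       probes_per_gene = 10,
                       seed = 1) {
  counts <- c(n_lines = n_lines, n_replicates = n_replicates,
              n_probes = n_probes, n_meth_probes = n_meth_probes,
              meth_replicates = meth_replicates,
              probes_per_gene = probes_per_gene)
  if (any(counts < 1)) stop("all counts must be positive")
  if (n_lines < 3) stop("n_lines must be >= 3 for rank correlation")
  stopifnot(all(names(panel_sizes) == .LINEAGES))
  req_ov <- c("ecto_meso", "ecto_endo", "meso_endo", "all_three")
  if (!all(req_ov %in% names(panel_overlap)))
    stop("panel_overlap must name: ", paste(req_ov, collapse = ", "))
  only <- c(panel_sizes["ectoderm"] - panel_overlap["ecto_meso"] -
              panel_overlap["ecto_endo"] - panel_overlap["all_three"],
            panel_sizes["mesoderm"] - panel_overlap["ecto_meso"] -
              panel_overlap["meso_endo"] - panel_overlap["all_three"],
            panel_sizes["endoderm"] - panel_overlap["ecto_endo"] -
              panel_overlap["meso_endo"] - panel_overlap["all_three"])
  if (any(only < 0))
    stop("panel overlaps exceed panel sizes")
  if (!all(names(coupling)[1:3] == c("ecto_meso", "ecto_endo", "meso_endo")))
    stop("coupling must be named ecto_meso, ecto_endo, meso_endo")
  if (any(abs(coupling) > 1)) stop("coupling targets must lie in [-1, 1]")
  if (noise_sd < 0 || ct_noise_sd < 0 || meth_noise_sd < 0)
    stop("noise SDs must be non-negative")
  if (absent_fraction < 0 || absent_fraction >= 1)
    stop("absent_fraction must be in [0, 1)")
  for (frac in c(meth_unannotated_fraction, meth_detection_fail_fraction))
    if (frac < 0 || frac >= 1) stop("fractions must be in [0, 1)")
  probe_ids <- sprintf("P%05d", seq_len(n_probes))
  for (m in planted_markers) {
    if (!inherits(m, "planted_marker"))
      stop("planted_markers must be built with planted_marker()")
    if (!m$probe %in% probe_ids)
      stop("planted probe id out of range: ", m$probe)
  }
  pl <- vapply(planted_markers, function(m) m$probe, character(1))
  if (anyDuplicated(pl))
    stop("duplicate planted probe id: ", pl[duplicated(pl)][1])
  structure(list(
    n_lines = n_lines, n_replicates = n_replicates, n_probes = n_probes,
    panel_sizes = panel_sizes, panel_overlap = panel_overlap,
    planted_markers = planted_markers, coupling = coupling,
    noise_sd = noise_sd, absent_fraction = absent_fraction,
    expr_base_log2 = expr_base_log2, expr_gain = expr_gain,
    absent_base_log2 = absent_base_log2,
    ct_base = ct_base, ct_gain = ct_gain, ct_noise_sd = ct_noise_sd,
    hk_ct = hk_ct, housekeeping = housekeeping,
    reference_line = reference_line,
    n_meth_probes = n_meth_probes, meth_replicates = meth_replicates,
    meth_effect = meth_effect, meth_noise_sd = meth_noise_sd,
    meth_hyper_genes = meth_hyper_genes, meth_hypo_genes = meth_hypo_genes,
    meth_unannotated_fraction = meth_unannotated_fraction,
    meth_detection_fail_fraction = meth_detection_fail_fraction,
    probes_per_gene = probes_per_gene,
    seed = as.integer(seed)),
    class = "sim_config")
}

# line labels: the reference line first, then synthetic names
.line_labels <- function(config) {
  c(config$reference_line,
    sprintf("iPSC%02d", seq_len(config$n_lines - 1) + 1))
}

# evaluate expr under a fixed seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Trilineage panel membership
#'
#' Generates the gene-lineage membership table implied by the configured
#' panel sizes and overlaps: genes belonging to one, two or all three germ
#' layer panels, named by their membership (`ECT`/`MES`/`END` for a single
#' panel, `EM`/`EE`/`ME` for pairs, `EME` for the triple).
#'
#' @param config A [sim_config()].
#' @return Data frame (`gene`, `lineage`), one row per membership.
#' @export
panel_layout <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ov <- config$panel_overlap
  sz <- config$panel_sizes
  only <- c(ecto = unname(sz["ectoderm"] - ov["ecto_meso"] - ov["ecto_endo"] -
                            ov["all_three"]),
            meso = unname(sz["mesoderm"] - ov["ecto_meso"] - ov["meso_endo"] -
                            ov["all_three"]),
            endo = unname(sz["endoderm"] - ov["ecto_endo"] - ov["meso_endo"] -
                            ov["all_three"]))
  mk <- function(prefix, k) if (k > 0) sprintf("%s%02d", prefix, seq_len(k))
                            else character(0)
  groups <- list(
    list(genes = mk("ECT", only["ecto"]), lineages = "ectoderm"),
    list(genes = mk("MES", only["meso"]), lineages = "mesoderm"),
    list(genes = mk("END", only["endo"]), lineages = "endoderm"),
    list(genes = mk("EM", ov["ecto_meso"]),
         lineages = c("ectoderm", "mesoderm")),
    list(genes = mk("EE", ov["ecto_endo"]),
         lineages = c("ectoderm", "endoderm")),
    list(genes = mk("ME", ov["meso_endo"]),
         lineages = c("mesoderm", "endoderm")),
    list(genes = mk("EME", ov["all_three"]), lineages = .LINEAGES))
  rows <- do.call(rbind, lapply(groups, function(g) {
    if (length(g$genes) == 0) return(NULL)
    expand.grid(gene = g$genes, lineage = g$lineages,
                stringsAsFactors = FALSE)
  }))
  data.frame(gene = rows$gene, lineage = rows$lineage,
             stringsAsFactors = FALSE)
}
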