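# End-to-end pipeline: simulate -> normalise/filter -> rank -> screen ->
# intersect -> methylation, with a machine-readable run report.

#' Pipeline configuration
#'
#' @param sim A [sim_config()] describing the synthetic inputs (used when
#'   `simulate = TRUE`).
#' @param simulate Generate inputs with the synthetic-data module? (When
#'   `FALSE`, the `paths` entries must point to existing input files.)
#' @param paths Named list of input paths (used when `simulate = FALSE`):
#'   `intensity`, `calls`, `ct`, `panel`, `beta`, `detection_p`, `manifest`,
#'   `annotation`.
#' @param stages Named logical toggles: `filter`, `rank`, `screen`,
#'   `methylation`.
#' @param alpha Screen / ANOVA significance level.
#' @param min_present,min_ratio Filter thresholds.
#' @param q_threshold,lfc_threshold Methylation thresholds.
#' @param normalize Apply global scaling before filtering?
#' @param scale_target,scale_trim Global-scaling parameters.
#' @param top_k Rows per (lineage, sign) in the candidate table.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), simulate = TRUE,
                            paths = list(),
                            stages = c(filter = TRUE, rank = TRUE,
                                       screen = TRUE, methylation = TRUE),
                            alpha = 0.05, min_present = 4, min_ratio = 5,
                            q_threshold = 0.05, lfc_threshold = 0.6,
                            normalize = TRUE, scale_target = 500,
                            scale_trim = 0.02, top_k = 5) {
  structure(list(sim = sim, simulate = simulate, paths = paths,
                 stages = stages, alpha = alpha, min_present = min_present,
                 min_ratio = min_ratio, q_threshold = q_threshold,
                 lfc_threshold = lfc_threshold, normalize = normalize,
                 scale_target = scale_target, scale_trim = scale_trim,
                 top_k = top_k),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' Understands the same fields as [pipeline_config()]; the `sim` entry holds
#' [sim_config()] arguments (planted markers as a list of
#' `{probe, targets, gene}` objects).
#'
#' @param path JSON file path.
#' @param seed Optional seed overriding the file's value.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, seed = NULL) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  sim_args <- raw$sim %||% list()
  if (!is.null(sim_args$planted_markers)) {
    pm <- sim_args$planted_markers
    if (is.data.frame(pm)) pm <- split(pm, seq_len(nrow(pm)))
    sim_args$planted_markers <- lapply(pm, function(m) {
      planted_marker(as.character(m$probe), unlist(m$targets),
                     gene = if (!is.null(m$gene)) as.character(m$gene))
    })
  }
  for (nm in c("panel_sizes", "panel_overlap", "coupling"))
    if (!is.null(sim_args[[nm]])) sim_args[[nm]] <- unlist(sim_args[[nm]])
  if (!is.null(seed)) sim_args$seed <- seed
  cfg_args <- raw[setdiff(names(raw), "sim")]
  if (!is.null(cfg_args$stages)) cfg_args$stages <- unlist(cfg_args$stages)
  cfg_args$sim <- do.call(sim_config, sim_args)
  do.call(pipeline_config, cfg_args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full marker-discovery pipeline
#'
#' Executes (optionally) simulation, normalisation and the three-step
#' filter, propensity ranking, the Spearman screen with the
#' inverse-correlation intersection, and the differential-methylation
#' analysis. Per-stage artifacts are written under `out_dir` together with
#' a machine-readable `run_report.json` carrying the seed, all thresholds
#' and per-stage counts; results never go to stderr.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed); `NULL` skips
#'   artifact writing and returns results in memory only.
#' @param quiet Suppress progress messages (written via `message()`)?
#' @return Invisibly, a list with the stage results and the run report.
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(...)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  art <- function(name) if (is.null(out_dir)) NULL else file.path(out_dir, name)
  report <- list(seed = config$sim$seed,
                 package_version = as.character(packageVersion("propscreen")),
                 parameters = list(alpha = config$alpha,
                                   min_present = config$min_present,
                                   min_ratio = config$min_ratio,
                                   q_threshold = config$q_threshold,
                                   lfc_threshold = config$lfc_threshold,
                                   normalize = config$normalize,
                                   scale_target = config$scale_target,
                                   scale_trim = config$scale_trim))
  results <- list()
  stage <- "simulate"
  res <- tryCatch({
    if (config$simulate) {
      say("simulating inputs (seed ", config$sim$seed, ")")
      prop <- simulate_propensities(config$sim)
      expr <- simulate_expression(config$sim, prop)
      ct <- simulate_panel_cts(config$sim, prop)
      panel <- attr(ct, "panel")
      meth <- if (isTRUE(config$stages["methylation"]))
        simulate_methylation(config$sim) else NULL
      annotation <- expr$annotation
      if (!is.null(out_dir)) {
        write_expression_tsv(expr, art("intensity.tsv"), art("calls.tsv"))
        write_ct_tsv(ct, art("ct.tsv"))
        write_panel_csv(panel, art("panel.csv"))
        if (!is.null(meth))
          write_methylation_tsv(meth, art("beta.tsv"), art("detection_p.tsv"),
                                art("manifest.csv"))
      }
      results$propensities <- prop
      report$simulate <- list(n_probes = config$sim$n_probes,
                              n_lines = config$sim$n_lines,
                              planted = length(config$sim$planted_markers))
    } else {
      p <- config$paths
      expr <- read_expression_tsv(p$intensity, p$calls)
      ct <- read_ct_tsv(p$ct)
      panel <- read_panel_csv(p$panel)
      annotation <- if (!is.null(p$annotation))
        .read_table_checked(p$annotation, "\t",
                            required = c("probe_id", "gene")) else NULL
      meth <- if (isTRUE(config$stages["methylation"]))
        read_methylation_tsv(p$beta, p$detection_p, p$manifest) else NULL
    }

    if (config$normalize && !expr$normalized) {
      say("global scaling to trimmed mean ", config$scale_target)
      expr <- global_scale(expr, config$scale_target, config$scale_trim)
    }
    results$expression <- expr

    if (isTRUE(config$stages["filter"])) {
      stage <- "filter"
      say("three-step probe filter")
      flt <- filter_probes(expr, alpha = config$alpha,
                           min_present = config$min_present,
                           min_ratio = config$min_ratio)
      results$filter <- flt
      report$filter <- as.list(flt$counts)
      if (!is.null(out_dir))
        write_filter_report(flt, art("filter_report.json"),
                            art("filtered_probes.tsv"))
      survivors <- flt$steps$fold
    } else {
      survivors <- probe_ids(expr)
    }

    if (isTRUE(config$stages["rank"])) {
      stage <- "rank"
      say("propensity ranking (PC1 per lineage)")
      ranking <- propensity_ranking(
        ct, panel, housekeeping = config$sim$housekeeping,
        reference_line = config$sim$reference_line)
      results$ranking <- ranking
      report$rank <- list(
        explained = as.list(ranking$explained),
        interlineage = lapply(
          seq_len(nrow(interlineage_rank_correlation(ranking))),
          function(i) as.list(interlineage_rank_correlation(ranking)[i, ])))
      if (!is.null(out_dir)) {
        df <- data.frame(line = rownames(ranking$pc1), ranking$pc1,
                         rank = ranking$rank, check.names = FALSE)
        utils::write.table(df, art("ranking.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
      }
    }

    if (isTRUE(config$stages["screen"])) {
      if (!isTRUE(config$stages["rank"]))
        stop("the screen stage requires the rank stage")
      stage <- "screen"
      say("Spearman screen over ", length(survivors), " probes")
      scr <- screen_markers(expr, survivors, results$ranking,
                            alpha = config$alpha, annotation = annotation)
      results$screen <- scr
      inter <- inverse_correlation_intersection(scr)
      results$intersection <- inter
      results$top_candidates <- top_k_table(scr, config$top_k)
      report$screen <- list(
        screened = length(survivors),
        candidates = lapply(scr$candidates, function(cc)
          list(positive = length(cc$positive),
               negative = length(cc$negative))),
        intersection = list(ecto_positive = inter$ecto_positive,
                            ecto_negative = inter$ecto_negative))
      if (!is.null(out_dir)) {
        write_screen_tsv(scr, art("screen.tsv"))
        jsonlite::write_json(inter, art("intersection.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
      }
    }

    if (isTRUE(config$stages["methylation"]) && !is.null(meth)) {
      stage <- "methylation"
      say("differential methylation")
      retained <- annotation_filter(detection_filter(meth), meth$manifest)
      dm <- differential_methylation(meth, retained,
                                     q_threshold = config$q_threshold,
                                     lfc_threshold = config$lfc_threshold)
      results$methylation <- dm
      fr <- summarize_fractions(dm)
      rd <- tryCatch(region_distribution(dm, meth$manifest, "hyper"),
                     error = function(e) NULL)
      report$methylation <- list(
        retained = length(retained),
        counts = as.list(table(dm$table$class)),
        pct_differential = fr$pct_differential,
        pct_hyper_among_differential = fr$pct_hyper_among_differential,
        hyper_region_pct = if (!is.null(rd)) as.list(rd))
      if (!is.null(out_dir)) {
        utils::write.table(dm$table, art("methylation.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        jsonlite::write_json(report$methylation, art("methylation_summary.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
      }
    }
    NULL
  }, error = function(e) e)
  if (inherits(res, "error"))
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(res))
  if (!is.null(out_dir))
    jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(results = results, report = report))
}
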