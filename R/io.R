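# Readers and writers for the package's tabular formats. All files are
# header-bearing UTF-8 text, tab-separated unless named *.csv; genomic
# coordinates are 1-based inclusive (HM450 MAPINFO convention).

.read_table_checked <- function(path, sep, numeric_cols = NULL,
                                required = NULL) {
  df <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (!is.null(required) && !all(required %in% names(df)))
    stop(basename(path), ": missing required column(s): ",
         paste(setdiff(required, names(df)), collapse = ", "))
  for (cc in intersect(numeric_cols, names(df))) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(v) & !is.na(df[[cc]]) & df[[cc]] != "" &
                   df[[cc]] != "NA")
    if (length(bad))
      stop(basename(path), ": non-numeric value in column '", cc,
           "' at data line ", bad[1])
    df[[cc]] <- v
  }
  df
}

.read_matrix_tsv <- function(path, id_col = "probe_id") {
  df <- .read_table_checked(path, "\t", required = id_col)
  ids <- df[[id_col]]
  if (anyDuplicated(ids))
    stop(basename(path), ": duplicate probe id: ", ids[duplicated(ids)][1])
  m <- as.matrix(df[, setdiff(names(df), id_col), drop = FALSE])
  rownames(m) <- ids
  m
}

#' Write / read an expression dataset as a TSV pair
#'
#' Intensities and calls are written as two TSVs with a `probe_id` column
#' followed by one `<line>_<replicate>` column per sample.
#'
#' @param data An [expression_dataset()].
#' @param intensity_path,calls_path File paths.
#' @return `write_expression_tsv` returns the paths invisibly;
#'   `read_expression_tsv` returns an `expression_dataset`.
#' @export
write_expression_tsv <- function(data, intensity_path, calls_path) {
  stopifnot(inherits(data, "expression_dataset"))
  wr <- function(m, path) {
    df <- data.frame(probe_id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wr(data$intensity, intensity_path)
  wr(data$calls, calls_path)
  invisible(c(intensity_path, calls_path))
}

#' @rdname write_expression_tsv
#' @param normalized Normalisation state to record on reading.
#' @export
read_expression_tsv <- function(intensity_path, calls_path,
                                normalized = FALSE) {
  intensity <- .read_matrix_tsv(intensity_path)
  suppressWarnings(storage.mode(intensity) <- "double")
  if (anyNA(intensity))
    stop(basename(intensity_path), ": non-numeric intensity cell")
  calls <- .read_matrix_tsv(calls_path)
  if (!identical(colnames(intensity), colnames(calls)))
    stop("intensity and calls files disagree on sample columns")
  lines <- sub("_[^_]*$", "", colnames(intensity))
  expression_dataset(intensity, calls, lines, normalized = normalized)
}

#' Write / read a long-format Ct table
#'
#' Columns: `line`, `replicate`, `gene`, `well`, `ct`.
#'
#' @param ct Ct data frame.
#' @param path File path.
#' @export
write_ct_tsv <- function(ct, path) {
  utils::write.table(ct[, c("line", "replicate", "gene", "well", "ct")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ct_tsv
#' @export
read_ct_tsv <- function(path) {
  .read_table_checked(path, "\t", numeric_cols = c("replicate", "well", "ct"),
                      required = c("line", "replicate", "gene", "well", "ct"))
}

#' Write / read panel membership (gene, lineage) as CSV
#' @param panel Data frame with columns `gene`, `lineage`.
#' @param path File path.
#' @export
write_panel_csv <- function(panel, path) {
  utils::write.csv(panel[, c("gene", "lineage")], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_panel_csv
#' @export
read_panel_csv <- function(path) {
  .read_table_checked(path, ",", required = c("gene", "lineage"))
}

#' Write / read a methylation dataset (beta TSV, detection-P TSV, manifest CSV)
#'
#' Beta and detection-P files carry a `probe_id` column and
#' `<group>_<replicate>` sample columns; the manifest CSV uses HM450-style
#' columns (`IlmnID`, `CHR`, `MAPINFO`, `UCSC_RefGene_Name`,
#' `UCSC_RefGene_Group`, `Relation_to_UCSC_CpG_Island`). Empty `CHR` or
#' `MAPINFO` fields mark missing annotation.
#'
#' @param data A [methylation_dataset()].
#' @param beta_path,detp_path,manifest_path File paths.
#' @export
write_methylation_tsv <- function(data, beta_path, detp_path, manifest_path) {
  stopifnot(inherits(data, "methylation_dataset"))
  wr <- function(m, path) {
    df <- data.frame(probe_id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wr(data$beta, beta_path)
  wr(data$detection_p, detp_path)
  utils::write.csv(data$manifest, manifest_path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(c(beta_path, detp_path, manifest_path))
}

#' @rdname write_methylation_tsv
#' @export
read_methylation_tsv <- function(beta_path, detp_path, manifest_path) {
  beta <- .read_matrix_tsv(beta_path)
  suppressWarnings(storage.mode(beta) <- "double")
  detp <- .read_matrix_tsv(detp_path)
  suppressWarnings(storage.mode(detp) <- "double")
  if (anyNA(beta) || anyNA(detp))
    stop("non-numeric cell in beta or detection-P file")
  manifest <- .read_table_checked(
    manifest_path, ",",
    required = c("IlmnID", "CHR", "MAPINFO", "UCSC_RefGene_Name",
                 "UCSC_RefGene_Group", "Relation_to_UCSC_CpG_Island"))
  manifest$CHR[is.na(manifest$CHR)] <- ""
  groups <- sub("_[^_]*$", "", colnames(beta))
  methylation_dataset(beta, detp, manifest, groups)
}

#' Write screen results as TSV
#' @param result A `marker_screen_result`.
#' @param path File path.
#' @export
write_screen_tsv <- function(result, path) {
  stopifnot(inherits(result, "marker_screen_result"))
  utils::write.table(result$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a filter report as JSON plus surviving-probe TSV
#' @param report A `filter_report`.
#' @param json_path,probes_path File paths.
#' @export
write_filter_report <- function(report, json_path, probes_path) {
  stopifnot(inherits(report, "filter_report"))
  jsonlite::write_json(
    list(counts = as.list(report$counts),
         parameters = report$parameters),
    json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.table(data.frame(probe_id = report$steps$fold),
                     probes_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(json_path, probes_path))
}
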