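#' Expression dataset container
#'
#' Probe-level expression intensities with Affymetrix-style detection calls
#' over (cell line, replicate, probe). Columns are samples named
#' `<line>_<replicate>`; rows are probes.
#'
#' @param intensity Non-negative numeric matrix, probes x samples, with
#'   probe ids as rownames.
#' @param calls Character matrix of detection calls (`"P"`, `"A"`, `"M"`),
#'   same dimensions and dimnames as `intensity`.
#' @param lines Character/factor of cell-line labels, one per sample column.
#' @param normalized Logical: has global scaling been applied?
#' @return An object of class `expression_dataset`.
#' @export
expression_dataset <- function(intensity, calls, lines, normalized = FALSE) {
  if (!is.matrix(intensity) || !is.numeric(intensity))
    stop("intensity must be a numeric matrix")
  if (is.null(rownames(intensity)))
    stop("intensity must carry probe ids as rownames")
  if (anyDuplicated(rownames(intensity)))
    stop("duplicate probe id: ",
         rownames(intensity)[duplicated(rownames(intensity))][1])
  if (any(intensity < 0)) stop("intensities must be non-negative")
  if (!identical(dim(intensity), dim(calls)))
    stop("intensity and calls must share dimensions")
  if (!all(calls %in% c("P", "A", "M")))
    stop("calls must be one of P, A, M")
  if (is.null(dimnames(calls))) dimnames(calls) <- dimnames(intensity)
  lines <- as.character(lines)
  if (length(lines) != ncol(intensity))
    stop("one line label per sample column required")
  reps <- table(lines)
  if (length(unique(reps)) != 1L)
    stop("replicate count must be uniform across lines")
  structure(list(intensity = intensity, calls = calls, lines = lines,
                 normalized = normalized),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf(
    "expression_dataset: %d probes x %d samples (%d lines x %d replicates), %s\n",
    nrow(x$intensity), ncol(x$intensity), length(unique(x$lines)),
    ncol(x$intensity) / length(unique(x$lines)),
    if (x$normalized) "normalized" else "raw"))
  invisible(x)
}

#' Probe ids of an expression dataset
#' @param data An `expression_dataset`.
#' @return Character vector of probe ids.
#' @export
probe_ids <- function(data) rownames(data$intensity)

# per-line mean intensity matrix (probes x lines) for a subset of probes
.line_means <- function(data, probes = NULL) {
  x <- data$intensity
  if (!is.null(probes)) {
    missing <- setdiff(probes, rownames(x))
    if (length(missing))
      stop("unknown probe id: ", missing[1])
    x <- x[probes, , drop = FALSE]
  }
  lines <- unique(data$lines)
  ind <- vapply(lines, function(l) data$lines == l, logical(length(data$lines)))
  m <- x %*% ind
  sweep(m, 2, colSums(ind), "/")
}
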