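#' Construct a case/control expression study
#'
#' Holds a gene-by-sample matrix of log-scale expression values together
#' with a case/control label per sample. Values are stored as given; the
#' dysregulation caller assumes they are on the log2 scale.
#'
#' @param values numeric matrix, genes in rows, samples in columns; both
#'   dimensions must be named.
#' @param labels character vector of `"case"`/`"control"` labels, either
#'   named by sample or in column order.
#' @param probe_level logical; set `TRUE` when rows are probes that will
#'   later be collapsed to genes, which permits duplicate row names.
#' @return An object of class `expression_study` with elements `genes`,
#'   `samples`, `values` and `labels`.
#' @export
expression_study <- function(values, labels, probe_level = FALSE) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have row (gene) and column (sample) names")
  }
  if (!probe_level && anyDuplicated(rownames(values))) {
    stop("duplicate gene rows; use probe_level = TRUE and a probe map")
  }
  samples <- colnames(values)
  if (!is.null(names(labels))) {
    miss <- setdiff(samples, names(labels))
    if (length(miss)) {
      stop("samples missing from labels: ", paste(utils::head(miss, 5L), collapse = ", "))
    }
    labels <- labels[samples]
  } else if (length(labels) != length(samples)) {
    stop("labels length does not match sample count")
  }
  labels <- as.character(labels)
  if (!all(labels %in% c("case", "control"))) {
    stop("labels must be 'case' or 'control'")
  }
  if (sum(labels == "control") < 2L) stop("need at least 2 control samples")
  if (sum(labels == "case") < 1L) stop("need at least 1 case sample")
  structure(list(genes = rownames(values), samples = samples,
                 values = values, labels = stats::setNames(labels, samples),
                 probe_level = probe_level),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("expression_study: %d %s x %d samples (%d case, %d control)\n",
              length(x$genes), if (isTRUE(x$probe_level)) "probes" else "genes",
              length(x$samples), sum(x$labels == "case"),
              sum(x$labels == "control")))
  invisible(x)
}

#' Read an expression matrix and sample labels
#'
#' The matrix is a TSV with a header row of sample identifiers and gene
#' identifiers in the first column. The labels file is a two-column TSV
#' (sample, label) without a header; labels are `case` or `control`.
#' Values are used as given (no transformation); set
#' `log2_transform = TRUE` to apply `log2(x + 1)` to raw intensities.
#'
#' @param matrix_path path to the expression TSV.
#' @param labels_path path to the labels TSV.
#' @param probe_level logical, passed to [expression_study()]; required to
#'   accept duplicate gene rows prior to probe collapsing.
#' @param log2_transform logical; apply `log2(x + 1)` on read.
#' @return An [expression_study].
#' @export
read_expression <- function(matrix_path, labels_path, probe_level = FALSE,
                            log2_transform = FALSE) {
  if (!file.exists(matrix_path)) stop("expression file not found: ", matrix_path)
  if (!file.exists(labels_path)) stop("labels file not found: ", labels_path)
  tab <- utils::read.delim(matrix_path, header = TRUE, check.names = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 2L) stop("expression matrix needs a gene column plus samples")
  genes <- tab[[1L]]
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals),
                                dimnames = dimnames(vals)))
  if (anyNA(num) ) {
    bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
    if (nrow(bad)) {
      stop(sprintf("non-numeric expression value at gene '%s', sample '%s'",
                   genes[bad[1L, 1L]], colnames(vals)[bad[1L, 2L]]))
    }
    stop("missing values in expression matrix")
  }
  rownames(num) <- genes
  if (log2_transform) num <- log2(num + 1)
  lab <- utils::read.delim(labels_path, header = FALSE, check.names = FALSE,
                           colClasses = "character")
  if (ncol(lab) < 2L) stop("labels file needs two columns: sample, label")
  labels <- stats::setNames(trimws(lab[[2L]]), trimws(lab[[1L]]))
  expression_study(num, labels, probe_level = probe_level)
}

#' Write an expression study to TSV files
#'
#' @param study an [expression_study].
#' @param matrix_path output path for the gene-by-sample TSV.
#' @param labels_path output path for the two-column labels TSV.
#' @return Invisibly, `matrix_path`.
#' @export
write_expression <- function(study, matrix_path, labels_path) {
  tab <- data.frame(gene = study$genes, study$values, check.names = FALSE)
  utils::write.table(tab, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(study$samples, unname(study$labels)),
                     labels_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(matrix_path)
}

#' Collapse probe-level rows to gene-level rows
#'
#' Probes mapping to the same gene are averaged (arithmetic mean per
#' sample, on the log scale at which the values are stored). Probes
#' absent from the map are dropped with a warning.
#'
#' @param study an [expression_study], typically with `probe_level = TRUE`.
#' @param probe_map data frame with columns `probe` and `gene` (the first
#'   two columns are used).
#' @return A gene-level [expression_study].
#' @export
collapse_probes <- function(study, probe_map) {
  if (is.matrix(probe_map)) probe_map <- as.data.frame(probe_map)
  probe <- as.character(probe_map[[1L]])
  gene <- as.character(probe_map[[2L]])
  map <- stats::setNames(gene, probe)
  hit <- study$genes %in% probe
  if (!all(hit)) {
    warning(sprintf("dropped %d probe row(s) absent from the probe map",
                    sum(!hit)))
  }
  vals <- study$values[hit, , drop = FALSE]
  g <- map[study$genes[hit]]
  if (!nrow(vals)) stop("no probes left after applying the probe map")
  collapsed <- rowsum(vals, group = g, reorder = TRUE) /
    as.vector(table(g)[sort(unique(g))])
  expression_study(collapsed, study$labels, probe_level = FALSE)
}
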