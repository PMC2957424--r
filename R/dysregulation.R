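#' Fit the per-gene control model
#'
#' For each gene, the mean and sample standard deviation (denominator
#' n - 1) of its expression over the control samples are computed and
#' used as the parameters of a normal null model for that gene. Genes
#' with zero control variance are flagged; they can never be called
#' dysregulated because the normal model is degenerate there.
#'
#' @param study an [expression_study].
#' @return An object of class `control_model`: list with `mean`, `sd`
#'   (named numeric vectors), `n_controls` and `zero_sd` (logical flags).
#' @export
fit_control_model <- function(study) {
  ctl <- study$values[, study$labels == "control", drop = FALSE]
  if (ncol(ctl) < 2L) stop("need at least 2 control samples")
  mu <- rowMeans(ctl)
  sdev <- apply(ctl, 1L, stats::sd)
  structure(list(mean = mu, sd = sdev, n_controls = ncol(ctl),
                 zero_sd = sdev == 0),
            class = "control_model")
}

#' @export
print.control_model <- function(x, ...) {
  cat(sprintf("control_model: %d genes, %d controls, %d with zero sd\n",
              length(x$mean), x$n_controls, sum(x$zero_sd)))
  invisible(x)
}

#' Normal-model p-value of a case expression value
#'
#' Probability, under the fitted control normal of `gene`, of observing
#' an expression value at least as extreme as `case_value` in the chosen
#' direction: upper tail for `UP`, lower tail for `DOWN`, and the
#' two-sided probability `min(1, 2 * min(tails))` for `DIFF`.
#'
#' @param model a [control_model][fit_control_model].
#' @param gene gene identifier (must be present in the model).
#' @param case_value numeric expression value(s) for that gene in case
#'   sample(s).
#' @param direction `"UP"`, `"DOWN"` or `"DIFF"`.
#' @return Numeric vector of p-values.
#' @export
case_pvalue <- function(model, gene, case_value, direction = c("UP", "DOWN", "DIFF")) {
  direction <- match.arg(direction)
  if (!gene %in% names(model$mean)) stop("gene not in control model: ", gene)
  mu <- model$mean[[gene]]
  s <- model$sd[[gene]]
  if (s == 0) stop("gene has zero control sd; it is never called dysregulated")
  up <- stats::pnorm(case_value, mu, s, lower.tail = FALSE)
  lo <- stats::pnorm(case_value, mu, s, lower.tail = TRUE)
  switch(direction,
         UP = up,
         DOWN = lo,
         DIFF = pmin(1, 2 * pmin(up, lo)))
}

#' Call per-case gene dysregulation
#'
#' Converts an expression study into a binary gene-by-case incidence
#' matrix. A gene is called dysregulated in a case when both gates pass:
#' the normal-model tail probability is below `p_threshold`, and the
#' anti-logged fold change `2^(case_value - control_mean)` deviates by at
#' least `fold_threshold` in the tested direction. For `DIFF`, a call is
#' the union of the `UP` and `DOWN` calls at the same thresholds (a gene
#' is dysregulated in a case if it is so in either direction). Genes with
#' zero control variance are never called.
#'
#' @param study an [expression_study] with log2-scale values.
#' @param direction `"UP"`, `"DOWN"` or `"DIFF"`.
#' @param p_threshold per-entry p-value gate (default 0.05).
#' @param fold_threshold minimal fold change on the raw scale
#'   (default 1.4).
#' @return An object of class `dysregulation_matrix`: list with `genes`,
#'   `cases`, binary integer matrix `incidence` and `direction`.
#' @examples
#' vals <- rbind(g1 = c(-1, 0, 1, 3))
#' colnames(vals) <- c("c1", "c2", "c3", "s1")
#' st <- expression_study(vals, c("control", "control", "control", "case"))
#' call_dysregulation(st, "UP")$incidence
#' @export
call_dysregulation <- function(study, direction = c("UP", "DOWN", "DIFF"),
                               p_threshold = 0.05, fold_threshold = 1.4) {
  direction <- match.arg(direction)
  stopifnot(p_threshold > 0, p_threshold < 1, fold_threshold > 1)
  model <- fit_control_model(study)
  cases <- study$samples[study$labels == "case"]
  vals <- study$values[, cases, drop = FALSE]
  mu <- model$mean
  s <- model$sd
  dlog <- vals - mu                      # log2 fold change per entry
  lf <- log2(fold_threshold)
  call_one <- function(dir) {
    if (dir == "UP") {
      p <- stats::pnorm(vals, mu, s, lower.tail = FALSE)
      p < p_threshold & dlog >= lf
    } else {
      p <- stats::pnorm(vals, mu, s, lower.tail = TRUE)
      p < p_threshold & dlog <= -lf
    }
  }
  inc <- switch(direction,
                UP = call_one("UP"),
                DOWN = call_one("DOWN"),
                DIFF = call_one("UP") | call_one("DOWN"))
  inc[model$zero_sd, ] <- FALSE
  storage.mode(inc) <- "integer"
  dimnames(inc) <- list(study$genes, cases)
  structure(list(genes = study$genes, cases = cases, incidence = inc,
                 direction = direction),
            class = "dysregulation_matrix")
}

#' @export
print.dysregulation_matrix <- function(x, ...) {
  cat(sprintf("dysregulation_matrix (%s): %d genes x %d cases, %d calls\n",
              x$direction, length(x$genes), length(x$cases),
              sum(x$incidence)))
  invisible(x)
}

#' Summarize a dysregulation matrix
#'
#' @param m a [dysregulation_matrix][call_dysregulation].
#' @return List with `per_gene` (row sums, i.e. the cover-set sizes
#'   `|S_v|`), `per_case` (column sums) and `total` calls.
#' @export
matrix_summary <- function(m) {
  list(per_gene = rowSums(m$incidence),
       per_case = colSums(m$incidence),
       total = sum(m$incidence))
}

#' Write a dysregulation matrix as TSV
#'
#' @param m a [dysregulation_matrix][call_dysregulation].
#' @param path output path; genes in rows, case identifiers as header.
#' @return Invisibly, `path`.
#' @export
write_dysregulation <- function(m, path) {
  tab <- data.frame(gene = m$genes, m$incidence, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
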