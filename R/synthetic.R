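#' Generate a random gene network
#'
#' Network generator for benchmarking: preferential attachment
#' (scale-free, emulating the heavy-tailed degree sequence of protein
#' interaction networks) or Erdos-Renyi. The result is always connected:
#' for the Erdos-Renyi model, the largest component is kept and re-grown
#' to `n_nodes` by attaching fresh nodes to uniformly chosen existing
#' ones.
#'
#' @param n_nodes number of nodes (>= 3).
#' @param model `"pa"` (preferential attachment, default) or `"er"`.
#' @param m edges added per node for `"pa"` (default 2).
#' @param p edge probability for `"er"` (default 0.05).
#' @param seed optional integer seed (`set.seed` is called when given).
#' @return A connected [gene_network] with nodes named `g0001`, ...
#' @export
generate_network <- function(n_nodes, model = c("pa", "er"), m = 2,
                             p = 0.05, seed = NULL) {
  model <- match.arg(model)
  if (n_nodes < 3L) stop("n_nodes must be >= 3")
  if (!is.null(seed)) set.seed(seed)
  if (model == "pa") {
    g <- igraph::sample_pa(n_nodes, m = m, directed = FALSE)
  } else {
    if (p <= 0 || p > 1) stop("invalid edge probability")
    g <- igraph::sample_gnp(n_nodes, p)
    comp <- igraph::components(g)
    keep <- which(comp$membership == which.max(comp$csize))
    g <- igraph::induced_subgraph(g, keep)
    while (igraph::vcount(g) < n_nodes) {
      g <- igraph::add_vertices(g, 1L)
      g <- igraph::add_edges(g, c(igraph::vcount(g),
                                  sample.int(igraph::vcount(g) - 1L, 1L)))
    }
  }
  g <- igraph::set_vertex_attr(g, "name",
                               value = sprintf("g%04d", seq_len(n_nodes)))
  from_igraph(g)
}

#' Plant a dysregulated pathway in synthetic expression data
#'
#' Builds a case/control expression study over the nodes of `network`
#' with a known connected pathway planted in it. Controls are standard
#' normal per gene (log2 scale, unit control sd). The planted node set
#' of size `planted_size` is grown by randomized breadth-first search
#' from a random root, so it is connected and of small radius. In each
#' non-outlier case, a per-case random subset of `per_case_active`
#' planted genes is shifted by `+delta` control sds (`-delta` for the
#' `DOWN` model); outlier cases receive no shift. Background gene/case
#' entries are shifted at rate `fp_rate` to mimic the null leakage of
#' the dysregulation-calling threshold.
#'
#' @param network a connected [gene_network].
#' @param n_cases,n_controls cohort sizes (defaults 20 and 20).
#' @param k planted per-case dysregulation threshold (default 10).
#' @param planted_size number of planted pathway genes (default 15).
#' @param n_outliers number of planted outlier cases (default 2).
#' @param delta effect size in control-sd units (default 4).
#' @param per_case_active planted genes shifted per non-outlier case
#'   (default `k`; must be `>= k`).
#' @param fp_rate background false-positive shift rate (default 0.05).
#' @param direction `"UP"` or `"DOWN"` planting.
#' @param seed optional integer seed.
#' @return List of class `planted_instance` with `network`, `study`
#'   (an [expression_study]) and `truth` (planted nodes, outlier cases,
#'   k, and the generation parameters).
#' @export
plant_dp <- function(network, n_cases = 20, n_controls = 20, k = 10,
                     planted_size = 15, n_outliers = 2, delta = 4,
                     per_case_active = k, fp_rate = 0.05,
                     direction = c("UP", "DOWN"), seed = NULL) {
  direction <- match.arg(direction)
  if (!is.null(seed)) set.seed(seed)
  n <- length(network$nodes)
  if (planted_size > n) stop("planted size exceeds network size")
  if (per_case_active < k) stop("per_case_active must be >= k")
  if (per_case_active > planted_size) stop("per_case_active exceeds planted size")
  if (n_outliers >= n_cases) stop("n_outliers must be < n_cases")
  planted_idx <- grow_connected(network, planted_size)
  planted <- network$nodes[planted_idx]
  samples <- c(sprintf("case%02d", seq_len(n_cases)),
               sprintf("ctrl%02d", seq_len(n_controls)))
  labels <- stats::setNames(rep(c("case", "control"), c(n_cases, n_controls)),
                            samples)
  vals <- matrix(stats::rnorm(n * length(samples)), nrow = n,
                 dimnames = list(network$nodes, samples))
  sgn <- if (direction == "UP") 1 else -1
  outliers <- sort(sample(samples[seq_len(n_cases)], n_outliers))
  active_cases <- setdiff(samples[seq_len(n_cases)], outliers)
  for (cs in active_cases) {
    hit <- sample(planted, per_case_active)
    vals[hit, cs] <- vals[hit, cs] + sgn * delta
  }
  if (fp_rate > 0) {
    bg <- setdiff(network$nodes, planted)
    if (length(bg)) {
      flips <- matrix(stats::runif(length(bg) * n_cases) < fp_rate,
                      nrow = length(bg))
      vals[bg, seq_len(n_cases)] <- vals[bg, seq_len(n_cases)] +
        sgn * delta * flips
    }
  }
  structure(list(network = network,
                 study = expression_study(vals, labels),
                 truth = list(nodes = planted, outliers = outliers, k = k,
                              params = list(delta = delta,
                                            per_case_active = per_case_active,
                                            fp_rate = fp_rate,
                                            planted_size = planted_size,
                                            direction = direction))),
            class = "planted_instance")
}

# connected node set of the requested size, grown by randomized BFS from
# a random root (keeps the planted module's radius small)
grow_connected <- function(network, size) {
  n <- length(network$nodes)
  root <- sample.int(n, 1L)
  chosen <- root
  frontier <- setdiff(network$adj[[root]], chosen)
  while (length(chosen) < size) {
    if (!length(frontier)) {
      stop("network component too small for the requested planted size")
    }
    frontier <- frontier[sample.int(length(frontier))]  # randomized order
    take <- frontier[seq_len(min(length(frontier), size - length(chosen)))]
    chosen <- c(chosen, take)
    frontier <- setdiff(unique(c(frontier[-seq_along(take)],
                                 unlist(network$adj[take]))), chosen)
  }
  chosen
}

#' @export
print.planted_instance <- function(x, ...) {
  cat(sprintf("planted_instance: %d-node network, planted pathway of %d genes (k = %d)\n",
              length(x$network$nodes), length(x$truth$nodes), x$truth$k))
  cat(sprintf("  %d cases (%d planted outliers), %d controls, delta = %g\n",
              sum(x$study$labels == "case"), length(x$truth$outliers),
              sum(x$study$labels == "control"), x$truth$params$delta))
  invisible(x)
}

#' Recovery metrics against a planted truth
#'
#' @param result a [dp_result] or a character vector of recovered node
#'   identifiers.
#' @param truth the `truth` element of a [plant_dp()] instance, or a
#'   character vector of planted node identifiers.
#' @return List with `precision`, `recall` and `jaccard`.
#' @export
recovery_metrics <- function(result, truth) {
  found <- if (inherits(result, "dp_result")) result$nodes else as.character(result)
  planted <- if (is.list(truth)) truth$nodes else as.character(truth)
  ov <- length(intersect(found, planted))
  un <- length(union(found, planted))
  list(precision = if (length(found)) ov / length(found) else 0,
       recall = if (length(planted)) ov / length(planted) else 0,
       jaccard = if (un) ov / un else 0)
}

#' Write a planted instance as analysis-ready fixture files
#'
#' Emits the exact input formats the readers consume: an edge-list
#' network, a gene-by-sample expression TSV, a two-column labels TSV and
#' a JSON file with the planted truth.
#'
#' @param pi a [plant_dp()] instance.
#' @param dir output directory (created if needed).
#' @return Invisibly, a named list of the written paths.
#' @export
write_planted <- function(pi, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(network = file.path(dir, "network.tsv"),
                expression = file.path(dir, "expression.tsv"),
                labels = file.path(dir, "labels.tsv"),
                truth = file.path(dir, "truth.json"))
  write_network(pi$network, paths$network)
  write_expression(pi$study, paths$expression, paths$labels)
  jsonlite::write_json(pi$truth, paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
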