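#' Detect dysregulated pathways in a protein interaction network
#'
#' End-to-end driver. Expression values are compared, gene by gene,
#' against a normal model fitted to the control samples, giving a binary
#' genes-by-cases dysregulation matrix; the method then searches the
#' interaction network for a minimum-size connected subnetwork in which
#' at least `k` genes are dysregulated in every case except up to `l`
#' outliers, restricted to the smallest achievable search radius.
#' With a grid of `k` values, the returned pathway is the one whose size
#' is most significant against gene-label-shuffled networks.
#'
#' @param network a [gene_network] or path to a network file
#'   (see [read_network()]).
#' @param expression an [expression_study], or path to an expression TSV
#'   (then `labels` must be the labels path).
#' @param labels labels file path when `expression` is a path.
#' @param probe_map optional probe-to-gene table (or path to a
#'   two-column TSV) applied with [collapse_probes()].
#' @param direction `"UP"`, `"DOWN"` or `"DIFF"`.
#' @param k single k, or an integer grid to select over (default
#'   `c(5, 10, 15, 20, 25, 30)`).
#' @param outlier_fraction fraction of cases allowed as outliers
#'   (default 0.2); `l = floor(outlier_fraction * n_cases)`.
#' @param p_threshold,fold_threshold dysregulation-calling gates
#'   (defaults 0.05 and 1.4); see [call_dysregulation()].
#' @param n_permutations shuffled networks per k for significance
#'   (default 200); 0 skips significance (single k only).
#' @param hub_hide,hub_degree,hub_quantile hub-hiding controls; see
#'   [hide_hubs()].
#' @param two_phase use the two-phase greedy (default `TRUE`).
#' @param log2_transform apply `log2(x + 1)` when reading raw
#'   intensities from file.
#' @param seed optional integer seed for the permutation stream.
#' @return Object of class `dyspath`: list with `dp` (list of minimum
#'   size [dp_result]s), `k`, `l`, `selection` (per-k table or `NULL`),
#'   `r_min`, `direction`, `matrix_summary`, `instance` and `config`.
#' @examples
#' net <- generate_network(60, "pa", seed = 1)
#' pl <- plant_dp(net, n_cases = 10, n_controls = 10, k = 3,
#'                planted_size = 6, n_outliers = 1, per_case_active = 3,
#'                seed = 2)
#' fit <- dyspath(net, pl$study, direction = "UP", k = 3,
#'                n_permutations = 0)
#' fit
#' @export
dyspath <- function(network, expression, labels = NULL, probe_map = NULL,
                    direction = c("UP", "DOWN", "DIFF"),
                    k = c(5L, 10L, 15L, 20L, 25L, 30L),
                    outlier_fraction = 0.2, p_threshold = 0.05,
                    fold_threshold = 1.4, n_permutations = 200,
                    hub_hide = TRUE, hub_degree = 100, hub_quantile = 0.75,
                    two_phase = TRUE, log2_transform = FALSE, seed = NULL) {
  direction <- match.arg(direction)
  t0 <- proc.time()[["elapsed"]]
  if (is.character(network)) network <- read_network(network)
  if (is.character(expression)) {
    if (is.null(labels)) stop("labels path required with an expression path")
    expression <- read_expression(expression, labels,
                                  probe_level = !is.null(probe_map),
                                  log2_transform = log2_transform)
  }
  if (!is.null(probe_map)) {
    if (is.character(probe_map)) {
      probe_map <- utils::read.delim(probe_map, header = FALSE,
                                     colClasses = "character")
    }
    expression <- collapse_probes(expression, probe_map)
  }
  if (!is.null(seed)) set.seed(seed)
  dmat <- call_dysregulation(expression, direction,
                             p_threshold = p_threshold,
                             fold_threshold = fold_threshold)
  n_cases <- length(dmat$cases)
  l <- outlier_count(n_cases, outlier_fraction)
  k <- sort(unique(as.integer(k)))
  selection <- NULL
  if (length(k) > 1L && n_permutations < 1) {
    stop("a k grid requires n_permutations >= 1 to select over")
  }
  if (length(k) > 1L || n_permutations > 0) {
    selection <- select_k(network, dmat, k_grid = k, l = l,
                          n_permutations = n_permutations,
                          hub_hide = hub_hide, hub_degree = hub_degree,
                          hub_quantile = hub_quantile,
                          two_phase = two_phase)
    chosen_k <- selection$chosen_k
    dp <- selection$dp
  } else {
    chosen_k <- k
    inst <- build_instance(network, dmat, k = chosen_k, l = l)
    if (hub_hide) inst <- hide_hubs_instance(inst, hub_degree, hub_quantile)
    dp <- solve_mrmcc(inst, two_phase = two_phase)
  }
  inst <- build_instance(network, dmat, k = chosen_k, l = l)
  if (hub_hide) inst <- hide_hubs_instance(inst, hub_degree, hub_quantile)
  structure(list(dp = dp, k = chosen_k, l = l,
                 selection = if (is.null(selection)) NULL else selection$table,
                 r_min = dp[[1L]]$radius, direction = direction,
                 matrix_summary = matrix_summary(dmat),
                 dysregulation = dmat, instance = inst,
                 config = list(direction = direction, k_grid = k,
                               outlier_fraction = outlier_fraction,
                               p_threshold = p_threshold,
                               fold_threshold = fold_threshold,
                               n_permutations = n_permutations,
                               hub_hide = hub_hide, hub_degree = hub_degree,
                               hub_quantile = hub_quantile,
                               two_phase = two_phase, seed = seed),
                 elapsed = proc.time()[["elapsed"]] - t0),
            class = "dyspath")
}

#' @export
print.dyspath <- function(x, ...) {
  best <- x$dp[[1L]]
  cat(sprintf("dyspath (%s): pathway of %d nodes at k = %d, l = %d\n",
              x$direction, best$size, x$k, x$l))
  cat(sprintf("  root %s, radius %d, %d outlier case(s)\n",
              best$root, best$radius, length(best$outliers)))
  if (!is.na(best$p_value)) {
    cat(sprintf("  empirical p = %.4g (%d permutations)\n",
                best$p_value, x$config$n_permutations))
  }
  if (length(x$dp) > 1L) {
    cat(sprintf("  %d equal-size pathways found\n", length(x$dp)))
  }
  invisible(x)
}

#' @export
summary.dyspath <- function(object, ...) {
  x <- object
  print(x)
  ms <- x$matrix_summary
  cat(sprintf("dysregulation calls: %d total; per-case median %g; %d genes ever called\n",
              ms$total, stats::median(ms$per_case), sum(ms$per_gene > 0)))
  if (!is.null(x$selection)) {
    cat("k grid:\n")
    print(x$selection, row.names = FALSE)
  }
  invisible(x)
}

#' Plot a detected pathway
#'
#' Draws the induced subgraph of the best pathway with igraph; the root
#' is highlighted and node size scales with the number of cases each
#' gene covers.
#'
#' @param x a `dyspath` object.
#' @param which index of the pathway to draw when several tie (default
#'   1).
#' @param ... passed to [igraph::plot.igraph()].
#' @return Invisibly, the igraph object drawn.
#' @export
plot.dyspath <- function(x, which = 1L, ...) {
  dp <- x$dp[[which]]
  sub <- network_induced(x$instance$network, dp$nodes)
  g <- as_igraph(sub)
  cov <- x$instance$set_sizes[match(igraph::V(g)$name, x$instance$network$nodes)]
  igraph::plot.igraph(
    g,
    vertex.size = 6 + 10 * cov / max(1, max(cov)),
    vertex.color = ifelse(igraph::V(g)$name == dp$root, "tomato", "skyblue"),
    vertex.label.cex = 0.7, ...)
  invisible(g)
}
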