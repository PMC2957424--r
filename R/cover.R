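#' Build a connected-cover problem instance
#'
#' Reconciles a network with a dysregulation matrix into a set-multicover
#' instance: the universe is the set of case samples, and each network
#' node carries the set of cases in which it is dysregulated. Expression
#' genes absent from the network are dropped; network nodes without
#' expression evidence keep empty cover sets (they remain available as
#' connector "back" nodes).
#'
#' @param network a [gene_network].
#' @param m a [dysregulation_matrix][call_dysregulation] (or a binary
#'   incidence matrix with gene row names and case column names).
#' @param k minimal number of dysregulated genes required per case.
#' @param l number of outlier cases allowed to fall below `k`;
#'   `0 <= l < n cases`.
#' @return An object of class `cover_instance`.
#' @export
build_instance <- function(network, m, k, l) {
  inc_in <- if (inherits(m, "dysregulation_matrix")) m$incidence else m
  if (is.null(rownames(inc_in)) || is.null(colnames(inc_in))) {
    stop("incidence matrix must have gene and case names")
  }
  k <- as.integer(k)
  l <- as.integer(l)
  if (k < 1L) stop("k must be >= 1")
  n_cases <- ncol(inc_in)
  if (l < 0L || l >= n_cases) stop("l must satisfy 0 <= l < number of cases")
  nodes <- network$nodes
  if (!any(rownames(inc_in) %in% nodes)) {
    stop("no expression gene appears in the network")
  }
  inc <- matrix(0L, nrow = length(nodes), ncol = n_cases,
                dimnames = list(nodes, colnames(inc_in)))
  shared <- intersect(rownames(inc_in), nodes)
  inc[shared, ] <- inc_in[shared, , drop = FALSE]
  new_cover_instance(network, inc, k, l)
}

new_cover_instance <- function(network, inc, k, l) {
  set_sizes <- rowSums(inc)
  nbr_tot <- vapply(network$adj, function(ix) sum(set_sizes[ix]), numeric(1))
  structure(list(network = network, inc = inc,
                 cases = colnames(inc), k = as.integer(k), l = as.integer(l),
                 set_sizes = set_sizes, nbr_tot = nbr_tot,
                 name_rank = rank(network$nodes, ties.method = "first")),
            class = "cover_instance")
}

#' @export
print.cover_instance <- function(x, ...) {
  cat(sprintf("cover_instance: %d nodes, %d edges, %d cases, k = %d, l = %d\n",
              length(x$network$nodes), network_edge_count(x$network),
              length(x$cases), x$k, x$l))
  invisible(x)
}

#' Outlier budget from an outlier fraction
#'
#' `l = floor(fraction * n_cases)`, the conservative rounding of the
#' "fraction of the cases" rule used throughout the package (default
#' fraction 0.20).
#'
#' @param n_cases number of case samples.
#' @param fraction fraction of cases allowed as outliers.
#' @return Integer outlier budget `l`.
#' @export
outlier_count <- function(n_cases, fraction = 0.2) {
  stopifnot(fraction >= 0, fraction < 1)
  as.integer(floor(fraction * n_cases))
}

#' Validate a connected (k,l)-cover
#'
#' A node set is a connected (k,l)-cover when it induces a connected
#' subgraph and at most `l` cases have fewer than `k` dysregulated genes
#' inside the set.
#'
#' @param C character vector of node identifiers (or integer node
#'   indices).
#' @param inst a [cover_instance][build_instance].
#' @return List with `valid` (logical) and `outliers`: all under-covered
#'   cases, ordered from worst covered upward (ties by case identifier).
#' @export
is_connected_cover <- function(C, inst) {
  idx <- resolve_nodes(C, inst)
  if (!length(idx)) return(list(valid = FALSE, outliers = character()))
  counts <- colSums(inst$inc[idx, , drop = FALSE])
  under <- which(counts < inst$k)
  ord <- order(counts[under], names(counts)[under])
  outliers <- names(counts)[under][ord]
  connected <- cpp_is_connected(inst$network$adj, as.integer(idx))
  list(valid = connected && length(under) <= inst$l, outliers = outliers)
}

resolve_nodes <- function(C, inst) {
  if (is.character(C)) {
    idx <- match(C, inst$network$nodes)
    if (anyNA(idx)) stop("unknown node(s): ",
                         paste(utils::head(C[is.na(idx)], 5L), collapse = ", "))
    idx
  } else {
    as.integer(C)
  }
}

#' Hide uninformative hubs
#'
#' Removes high-degree nodes whose direct neighborhoods show little
#' dysregulation, to counter the degree bias of curated interaction
#' networks. For each node the neighborhood score is the mean cover-set
#' size over its direct neighbors; a node is removed iff its degree
#' strictly exceeds `hub_degree` and its score falls below the
#' `hub_quantile` nearest-rank quantile of all nodes' scores. Removal is
#' simultaneous (one pass on the original graph) and may disconnect the
#' network.
#'
#' @param network a [gene_network].
#' @param set_sizes named numeric vector of per-gene cover-set sizes
#'   `|S_v|` (e.g. `matrix_summary(m)$per_gene`); nodes without an entry
#'   count as 0.
#' @param hub_degree degree above which a node is a hub candidate
#'   (default 100, strict inequality).
#' @param hub_quantile quantile of neighborhood scores below which hub
#'   candidates are removed (default 0.75).
#' @return A `gene_network` without the hidden hubs; the removed node
#'   identifiers are attached as attribute `"hidden"`.
#' @export
hide_hubs <- function(network, set_sizes, hub_degree = 100,
                      hub_quantile = 0.75) {
  sz <- stats::setNames(numeric(length(network$nodes)), network$nodes)
  shared <- intersect(names(set_sizes), network$nodes)
  sz[shared] <- set_sizes[shared]
  deg <- lengths(network$adj)
  score <- vapply(seq_along(network$adj), function(i) {
    nb <- network$adj[[i]]
    if (!length(nb)) 0 else mean(sz[nb])
  }, numeric(1))
  thr <- nearest_rank_quantile(score, hub_quantile)
  drop <- deg > hub_degree & score < thr
  if (!any(drop)) {
    attr(network, "hidden") <- character()
    return(network)
  }
  keep <- network$nodes[!drop]
  out <- network_induced(network, keep)
  attr(out, "hidden") <- network$nodes[drop]
  out
}

nearest_rank_quantile <- function(x, q) {
  xs <- sort(x)
  xs[max(1L, ceiling(q * length(xs)))]
}

#' Apply hub hiding to a cover instance
#'
#' Re-derives the instance on the hub-hidden network; coverage sets of
#' surviving nodes are unchanged.
#'
#' @param inst a [cover_instance][build_instance].
#' @param hub_degree,hub_quantile see [hide_hubs()].
#' @return A `cover_instance` on the reduced network.
#' @export
hide_hubs_instance <- function(inst, hub_degree = 100, hub_quantile = 0.75) {
  if (max(lengths(inst$network$adj)) <= hub_degree) return(inst)
  net2 <- hide_hubs(inst$network, inst$set_sizes, hub_degree, hub_quantile)
  if (!length(attr(net2, "hidden"))) return(inst)
  inc2 <- inst$inc[net2$nodes, , drop = FALSE]
  out <- new_cover_instance(net2, inc2, inst$k, inst$l)
  attr(out, "hidden") <- attr(net2, "hidden")
  out
}

#' A solved dysregulated pathway
#'
#' Container for one connected (k,l)-cover found by the solver.
#'
#' @param nodes character vector of module node identifiers.
#' @param root root node of the rooted search that produced the module.
#' @param radius search radius around the root.
#' @param k,l cover parameters.
#' @param outliers case identifiers left under-covered (at most `l`).
#' @param p_value,z_score optional empirical significance annotations.
#' @return An object of class `dp_result`.
#' @export
dp_result <- function(nodes, root, radius, k, l, outliers = character(),
                      p_value = NA_real_, z_score = NA_real_) {
  structure(list(nodes = as.character(nodes), root = as.character(root),
                 radius = as.integer(radius), k = as.integer(k),
                 l = as.integer(l), outliers = as.character(outliers),
                 size = length(nodes), p_value = as.numeric(p_value),
                 z_score = as.numeric(z_score)),
            class = "dp_result")
}

#' @export
print.dp_result <- function(x, ...) {
  cat(sprintf("dysregulated pathway: %d nodes (k = %d, l = %d)\n",
              x$size, x$k, x$l))
  cat(sprintf("  root %s, radius %d, %d outlier case(s)\n",
              x$root, x$radius, length(x$outliers)))
  if (!is.na(x$p_value)) {
    cat(sprintf("  empirical p = %.4g", x$p_value))
    if (!is.na(x$z_score)) cat(sprintf(", z = %.2f", x$z_score))
    cat("\n")
  }
  invisible(x)
}

#' Greedy expansion of a rooted connected cover
#'
#' Starting from `root`, iteratively adds the adjacent allowed node that
#' contributes the most new progress toward k-coverage (a node's
#' contribution to a case counts only while that case is still below
#' `k`). Ties are broken by the total number of cases covered by a
#' node's neighbors, then lexicographically by node identifier. The
#' search stops once at most `l` cases remain under-covered; it fails if
#' the frontier is exhausted first.
#'
#' @param inst a [cover_instance][build_instance].
#' @param root root node identifier.
#' @param allowed optional node identifiers delimiting the search region
#'   (defaults to all nodes); must contain `root`.
#' @return A [dp_result] or `NULL` on failure.
#' @export
expanding_greedy <- function(inst, root, allowed = NULL) {
  ridx <- resolve_nodes(root, inst)
  aidx <- if (is.null(allowed)) seq_along(inst$network$nodes)
          else resolve_nodes(allowed, inst)
  if (!ridx %in% aidx) stop("root is not in the allowed region")
  res <- cpp_greedy(inst$network$adj, inst$inc, inst$k, inst$l,
                    as.integer(ridx), as.integer(aidx),
                    inst$nbr_tot, as.integer(inst$name_rank))
  if (!isTRUE(res$ok)) return(NULL)
  nodes <- inst$network$nodes[res$nodes]
  cc <- is_connected_cover(nodes, inst)
  dp_result(nodes, inst$network$nodes[ridx],
            radius_of(inst, ridx, res$nodes), inst$k, inst$l,
            outliers = cc$outliers)
}

radius_of <- function(inst, root_idx, node_idx) {
  # eccentricity of the root within the full instance network, over the
  # module nodes
  d <- bfs_distances(inst$network$adj, root_idx)
  max(d[node_idx])
}

bfs_distances <- function(adj, root_idx) {
  n <- length(adj)
  d <- rep.int(NA_integer_, n)
  d[root_idx] <- 0L
  frontier <- root_idx
  lev <- 0L
  while (length(frontier)) {
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- nxt[is.na(d[nxt])]
    lev <- lev + 1L
    d[nxt] <- lev
    frontier <- nxt
  }
  d
}

#' Two-phase greedy with up-front outlier selection
#'
#' The greedy search selects its outliers only implicitly, when it
#' halts, and may spend nodes covering cases that end up discarded. The
#' two-phase heuristic first runs [expanding_greedy()], takes the `l`
#' least-covered cases of that cover as the outlier set, and reruns the
#' search with those cases removed from the universe and `l = 0`. Both
#' results are cleaned up and the smaller one is returned.
#'
#' @inheritParams expanding_greedy
#' @return A [dp_result] or `NULL` if both phases fail.
#' @export
expanding_greedy_2phase <- function(inst, root, allowed = NULL) {
  dp1 <- expanding_greedy(inst, root, allowed)
  if (is.null(dp1)) return(NULL)
  # outliers: the l cases with the lowest coverage under the raw run-1
  # cover (before clean-up), ties by case identifier
  counts <- colSums(inst$inc[resolve_nodes(dp1$nodes, inst), , drop = FALSE])
  dp1 <- cleanup(dp1, inst)
  if (inst$l == 0L) return(dp1)
  ord <- order(counts, names(counts))
  O <- names(counts)[ord][seq_len(inst$l)]
  keep <- setdiff(inst$cases, O)
  inst2 <- new_cover_instance(inst$network,
                              inst$inc[, keep, drop = FALSE], inst$k, 0L)
  dp2 <- expanding_greedy(inst2, root, allowed)
  if (is.null(dp2)) return(dp1)
  dp2 <- cleanup(dp2, inst2)
  if (dp2$size <= dp1$size) {
    cc <- is_connected_cover(dp2$nodes, inst)
    dp_result(dp2$nodes, dp2$root, radius_of(inst, resolve_nodes(dp2$root, inst),
                                             resolve_nodes(dp2$nodes, inst)),
              inst$k, inst$l, outliers = cc$outliers)
  } else {
    dp1
  }
}

#' Remove superfluous nodes from a cover
#'
#' Iteratively removes any node whose removal keeps the induced subgraph
#' connected and the (k,l)-cover condition satisfied, sweeping in
#' lexicographic node order until no further reduction is possible. The
#' result is a valid cover no larger than the input, and the operation
#' is idempotent.
#'
#' @param dp a [dp_result] holding a valid cover.
#' @param inst the [cover_instance][build_instance] it was solved on.
#' @return A reduced [dp_result].
#' @export
cleanup <- function(dp, inst) {
  cc <- is_connected_cover(dp$nodes, inst)
  if (!cc$valid) stop("cleanup requires a valid connected (k,l)-cover")
  idx <- resolve_nodes(dp$nodes, inst)
  kept <- cpp_cleanup(inst$network$adj, inst$inc, inst$k, inst$l,
                      as.integer(idx), as.integer(inst$name_rank))
  nodes <- inst$network$nodes[kept]
  cc2 <- is_connected_cover(nodes, inst)
  root_idx <- match(dp$root, inst$network$nodes)
  rad <- if (!is.na(root_idx)) radius_of(inst, root_idx, kept) else dp$radius
  dp_result(nodes, dp$root, rad, dp$k, dp$l, outliers = cc2$outliers,
            p_value = dp$p_value, z_score = dp$z_score)
}
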