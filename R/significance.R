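#' Shuffle gene labels on the network
#'
#' The permutation null used throughout: a uniformly random permutation
#' of node identifiers is applied to the network, so the topology is
#' untouched while the attachment of cover sets to topological positions
#' is permuted. Degree sequence, node and edge counts, and the multiset
#' of cover sets are all preserved. Edges are never rewired.
#'
#' @param inst a [cover_instance][build_instance].
#' @param perm optional integer permutation of node positions (position
#'   `j` receives the identity of node `perm[j]`); drawn from the current
#'   RNG when omitted.
#' @return A `cover_instance` with permuted gene labels.
#' @export
shuffle_gene_labels <- function(inst, perm = NULL) {
  n <- length(inst$network$nodes)
  if (is.null(perm)) perm <- sample.int(n)
  stopifnot(length(perm) == n, !anyDuplicated(perm))
  net <- inst$network
  net$nodes <- inst$network$nodes[perm]
  inc <- inst$inc[perm, , drop = FALSE]
  rownames(inc) <- net$nodes
  new_cover_instance(net, inc, inst$k, inst$l)
}

#' Permutation null of smallest pathway sizes
#'
#' Solves the instance on `n_permutations` gene-label-shuffled copies of
#' the network, recording the smallest pathway size in each (infeasible
#' permutations count as `Inf`). Hub hiding is re-applied to every
#' permuted instance so the null traverses the same pipeline as the
#' real data.
#'
#' @param inst a [cover_instance][build_instance] (pre hub hiding).
#' @param n_permutations number of shuffled networks (default 200).
#' @param perms optional list of permutations to reuse (e.g. a shared
#'   stream across several values of k); overrides `n_permutations`.
#' @param hub_hide re-apply hub hiding per permutation (default `TRUE`).
#' @param hub_degree,hub_quantile see [hide_hubs()].
#' @param two_phase passed to [smallest_dp_size()].
#' @return Object of class `permutation_null`: list with `sizes`
#'   (numeric, `Inf` allowed), `k` and `n_permutations`.
#' @export
permutation_null <- function(inst, n_permutations = 200, perms = NULL,
                             hub_hide = TRUE, hub_degree = 100,
                             hub_quantile = 0.75, two_phase = TRUE) {
  if (is.null(perms)) {
    n <- length(inst$network$nodes)
    perms <- lapply(seq_len(n_permutations), function(i) sample.int(n))
  }
  sizes <- vapply(perms, function(p) {
    pi <- shuffle_gene_labels(inst, perm = p)
    if (hub_hide) pi <- hide_hubs_instance(pi, hub_degree, hub_quantile)
    smallest_dp_size(pi, two_phase = two_phase)
  }, numeric(1))
  structure(list(sizes = sizes, k = inst$k,
                 n_permutations = length(perms)),
            class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  fin <- x$sizes[is.finite(x$sizes)]
  cat(sprintf("permutation_null (k = %d): %d permutations, %d feasible\n",
              x$k, x$n_permutations, length(fin)))
  if (length(fin)) {
    cat(sprintf("  null sizes: mean %.1f, sd %.2f\n", mean(fin), stats::sd(fin)))
  }
  invisible(x)
}

#' Empirical p-value of a pathway size
#'
#' Fraction of shuffled networks yielding an equal-sized or smaller
#' smallest pathway, with an add-one pseudo-count so the p-value is
#' never zero: `p = (#\{null <= real\} + 1) / (n + 1)`. Infeasible
#' permutations (size `Inf`) never count as smaller.
#'
#' @param real_size smallest pathway size on the real network.
#' @param null a [permutation_null] or a numeric vector of null sizes.
#' @return Numeric p-value in `(0, 1]`.
#' @export
empirical_pvalue <- function(real_size, null) {
  sizes <- if (inherits(null, "permutation_null")) null$sizes else null
  if (!length(sizes)) stop("empty permutation null")
  (sum(sizes <= real_size) + 1) / (length(sizes) + 1)
}

#' Select k by permutation significance over a grid
#'
#' For each candidate `k`, the real instance is solved and an empirical
#' p-value for its smallest pathway size is computed against a
#' permutation null; the same seed-derived permutation stream is reused
#' across the grid for variance reduction. The chosen `k` attains the
#' smallest p-value; ties are resolved by the most significant z-score
#' `(real - null mean) / null sd` over feasible null sizes (undefined
#' z-scores rank last), then by the smaller `k`.
#'
#' @param network a [gene_network].
#' @param m a [dysregulation_matrix][call_dysregulation].
#' @param k_grid integer vector of candidate k values.
#' @param l outlier budget; when `NULL`, derived as
#'   `outlier_count(n_cases, outlier_fraction)`.
#' @param outlier_fraction used when `l` is `NULL` (default 0.2).
#' @param n_permutations shuffled networks per k (default 200).
#' @param hub_hide,hub_degree,hub_quantile hub-hiding controls, applied
#'   to the real and every permuted instance.
#' @param two_phase passed to the solver.
#' @return Object of class `k_selection`: a per-k data frame (`k`,
#'   `size`, `null_mean`, `null_sd`, `p_value`, `z_score`), the
#'   `chosen_k`, and `dp`, the solved pathways at the chosen k.
#' @export
select_k <- function(network, m, k_grid, l = NULL, outlier_fraction = 0.2,
                     n_permutations = 200, hub_hide = TRUE,
                     hub_degree = 100, hub_quantile = 0.75,
                     two_phase = TRUE) {
  k_grid <- sort(unique(as.integer(k_grid)))
  stopifnot(length(k_grid) >= 1L, all(k_grid >= 1L))
  n_cases <- length(if (inherits(m, "dysregulation_matrix")) m$cases
                    else colnames(m))
  if (is.null(l)) l <- outlier_count(n_cases, outlier_fraction)
  base <- build_instance(network, m, k = k_grid[1L], l = l)
  n <- length(base$network$nodes)
  perms <- lapply(seq_len(n_permutations), function(i) sample.int(n))
  rows <- vector("list", length(k_grid))
  dps_by_k <- vector("list", length(k_grid))
  for (i in seq_along(k_grid)) {
    inst <- base
    inst$k <- k_grid[i]
    real_inst <- if (hub_hide) hide_hubs_instance(inst, hub_degree, hub_quantile)
                 else inst
    real_size <- smallest_dp_size(real_inst, two_phase = two_phase)
    if (is.infinite(real_size)) {
      rows[[i]] <- data.frame(k = k_grid[i], size = Inf, null_mean = NA_real_,
                              null_sd = NA_real_, p_value = NA_real_,
                              z_score = NA_real_)
      next
    }
    nul <- permutation_null(inst, perms = perms, hub_hide = hub_hide,
                            hub_degree = hub_degree,
                            hub_quantile = hub_quantile,
                            two_phase = two_phase)
    fin <- nul$sizes[is.finite(nul$sizes)]
    z <- if (length(fin) >= 2L && stats::sd(fin) > 0) {
      (real_size - mean(fin)) / stats::sd(fin)
    } else NA_real_
    rows[[i]] <- data.frame(k = k_grid[i], size = real_size,
                            null_mean = if (length(fin)) mean(fin) else NA_real_,
                            null_sd = if (length(fin) >= 2L) stats::sd(fin) else NA_real_,
                            p_value = empirical_pvalue(real_size, nul),
                            z_score = z)
    dps_by_k[[i]] <- real_inst
  }
  tab <- do.call(rbind, rows)
  feas <- which(!is.na(tab$p_value))
  if (!length(feas)) stop("no k in the grid is feasible on the real network")
  # argmin p, tie-break by most significant (smallest) z with undefined
  # z ranked last, then by smaller k
  z_key <- ifelse(is.na(tab$z_score[feas]), Inf, tab$z_score[feas])
  best <- feas[order(tab$p_value[feas], z_key, tab$k[feas])][1L]
  dp <- solve_mrmcc(dps_by_k[[best]], two_phase = two_phase)
  for (j in seq_along(dp)) {
    dp[[j]]$p_value <- tab$p_value[best]
    dp[[j]]$z_score <- tab$z_score[best]
  }
  structure(list(table = tab, chosen_k = tab$k[best], dp = dp),
            class = "k_selection")
}

#' @export
print.k_selection <- function(x, ...) {
  cat("k selection by permutation significance\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("chosen k = %d (pathway of %d nodes)\n",
              x$chosen_k, x$dp[[1L]]$size))
  invisible(x)
}

#' Hypergeometric overlap of a module with a reference gene set
#'
#' Upper-tail hypergeometric probability of observing at least the seen
#' overlap between a module and a reference gene set drawn from a
#' background of `background_size` genes.
#'
#' @param module_genes character vector of module gene identifiers.
#' @param reference_set character vector of reference gene identifiers.
#' @param background_size size of the gene background (must be at least
#'   the size of either set).
#' @return List with `overlap`, `p_value` and `fraction` (share of the
#'   module inside the reference set).
#' @export
overlap_pvalue <- function(module_genes, reference_set, background_size) {
  module_genes <- unique(module_genes)
  reference_set <- unique(reference_set)
  if (background_size < max(length(module_genes), length(reference_set))) {
    stop("background smaller than the gene sets")
  }
  ov <- length(intersect(module_genes, reference_set))
  p <- stats::phyper(ov - 1L, length(reference_set),
                     background_size - length(reference_set),
                     length(module_genes), lower.tail = FALSE)
  list(overlap = ov, p_value = p,
       fraction = if (length(module_genes)) ov / length(module_genes) else 0)
}
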