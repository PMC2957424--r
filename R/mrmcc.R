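#' Minimal feasible search radius for one root
#'
#' Runs a breadth-first search from `v`, incrementing a per-case
#' counting array as each node is reached, and after each completed
#' level checks whether at least `n - l` cases are covered at least `k`
#' times by the nodes seen so far (the root's own level 0 counts). The
#' smallest such level is the minimal radius at which the root's
#' neighborhood contains a connected (k,l)-cover. The search halts once
#' the level exceeds `cap`.
#'
#' @param inst a [cover_instance][build_instance].
#' @param v root node identifier.
#' @param cap radius cap (default `Inf`); levels beyond it are not
#'   explored.
#' @return Integer radius, or `Inf` when no radius `<= cap` is feasible.
#' @export
min_radius_for_root <- function(inst, v, cap = Inf) {
  idx <- resolve_nodes(v, inst)
  capi <- if (is.finite(cap)) as.integer(cap) else -1L
  r <- cpp_min_radius(inst$network$adj, inst$inc, inst$k, inst$l,
                      as.integer(idx), capi)
  if (r < 0) Inf else r
}

#' Scan all roots for the minimal feasible radius
#'
#' Every node is tested as a potential root with [min_radius_for_root()];
#' the running minimum radius caps the BFS of subsequent roots. A cheap
#' global feasibility bound (total attainable coverage over all nodes)
#' short-circuits hopeless instances.
#'
#' @param inst a [cover_instance][build_instance].
#' @return List of class `radius_scan` with `r_min` (integer or `Inf`)
#'   and `v_min` (character vector of roots attaining it, possibly
#'   empty).
#' @export
radius_scan <- function(inst) {
  total <- colSums(inst$inc)
  if (sum(total >= inst$k) < length(inst$cases) - inst$l) {
    return(structure(list(r_min = Inf, v_min = character()),
                     class = "radius_scan"))
  }
  sc <- cpp_radius_scan(inst$network$adj, inst$inc, inst$k, inst$l)
  if (sc$r_min < 0) {
    return(structure(list(r_min = Inf, v_min = character()),
                     class = "radius_scan"))
  }
  structure(list(r_min = sc$r_min, v_min = inst$network$nodes[sc$v_min]),
            class = "radius_scan")
}

#' @export
print.radius_scan <- function(x, ...) {
  cat(sprintf("radius scan: r_min = %s, %d candidate root(s)\n",
              format(x$r_min), length(x$v_min)))
  invisible(x)
}

#' Nodes within distance r of a root
#'
#' @param inst a [cover_instance][build_instance].
#' @param v root node identifier.
#' @param r radius.
#' @return Character vector of node identifiers (includes the root).
#' @export
neighborhood <- function(inst, v, r) {
  idx <- resolve_nodes(v, inst)
  inst$network$nodes[cpp_neighborhood(inst$network$adj, as.integer(idx),
                                      as.integer(r))]
}

#' Solve the minimal-radius minimal connected cover problem
#'
#' The driver of the method: find the minimal radius `r_min` and the
#' candidate root set via [radius_scan()], then run a rooted greedy
#' search (optionally the two-phase variant) restricted to each root's
#' `r_min`-neighborhood, clean up each result, and return every solution
#' tying the minimum size.
#'
#' @param inst a [cover_instance][build_instance].
#' @param two_phase use [expanding_greedy_2phase()] instead of the
#'   single-phase search (default `TRUE`).
#' @return List of [dp_result]s, all of minimum size, each recording its
#'   root and radius.
#' @export
solve_mrmcc <- function(inst, two_phase = TRUE) {
  sc <- radius_scan(inst)
  if (is.infinite(sc$r_min)) {
    stop(sprintf("no connected (%d,%d)-cover exists in this instance",
                 inst$k, inst$l))
  }
  dps <- list()
  for (root in sc$v_min) {
    allowed <- neighborhood(inst, root, sc$r_min)
    dp <- if (two_phase) expanding_greedy_2phase(inst, root, allowed)
          else expanding_greedy(inst, root, allowed)
    if (is.null(dp)) next
    if (!two_phase) dp <- cleanup(dp, inst)
    stopifnot(is_connected_cover(dp$nodes, inst)$valid)
    dps[[length(dps) + 1L]] <- dp
  }
  if (!length(dps)) stop("all rooted searches failed")
  sizes <- vapply(dps, function(d) d$size, numeric(1))
  dps[sizes == min(sizes)]
}

#' Size of the smallest pathway in an instance
#'
#' Convenience wrapper around [solve_mrmcc()] returning only the minimum
#' cover size, or `Inf` when the instance is infeasible. Used for
#' permutation nulls, where only the size distribution matters.
#'
#' @inheritParams solve_mrmcc
#' @return Numeric scalar: minimum size or `Inf`.
#' @export
smallest_dp_size <- function(inst, two_phase = TRUE) {
  total <- colSums(inst$inc)
  if (sum(total >= inst$k) < length(inst$cases) - inst$l) return(Inf)
  adj <- inst$network$adj
  inc <- inst$inc
  k <- inst$k
  l <- inst$l
  rank <- as.integer(inst$name_rank)
  sc <- cpp_radius_scan(adj, inc, k, l)
  if (sc$r_min < 0) return(Inf)
  best <- Inf
  for (ridx in sc$v_min) {
    allowed <- cpp_neighborhood(adj, ridx, sc$r_min)
    g1 <- cpp_greedy(adj, inc, k, l, ridx, allowed, inst$nbr_tot, rank)
    if (!isTRUE(g1$ok)) next
    c1 <- cpp_cleanup(adj, inc, k, l, g1$nodes, rank)
    size <- length(c1)
    if (two_phase && l > 0L) {
      # drop the l least-covered cases of the raw first-phase cover and
      # rerun with no outlier budget
      counts <- colSums(inc[g1$nodes, , drop = FALSE])
      drop_cases <- order(counts, colnames(inc))[seq_len(l)]
      inc2 <- inc[, -drop_cases, drop = FALSE]
      g2 <- cpp_greedy(adj, inc2, k, 0L, ridx, allowed,
                       inst$nbr_tot, rank)
      if (isTRUE(g2$ok)) {
        c2 <- cpp_cleanup(adj, inc2, k, 0L, g2$nodes, rank)
        size <- min(size, length(c2))
      }
    }
    best <- min(best, size)
  }
  best
}

#' Exact minimum connected cover by exhaustive search
#'
#' Independent brute-force oracle for small instances: enumerates node
#' subsets in increasing size and returns the first connected
#' (k,l)-cover found, which is a global optimum. Written in plain R,
#' deliberately sharing no machinery with the greedy solver.
#'
#' @param inst a [cover_instance][build_instance].
#' @param max_nodes refuse instances larger than this (default 14).
#' @return List with `size` (integer or `Inf`) and `nodes` (a witness,
#'   or `NULL` when infeasible).
#' @export
brute_force_mcc <- function(inst, max_nodes = 14L) {
  n <- length(inst$network$nodes)
  if (n > max_nodes) stop("instance too large for exhaustive search")
  inc <- inst$inc
  k <- inst$k
  need <- length(inst$cases) - inst$l
  adjm <- matrix(FALSE, n, n)
  for (i in seq_len(n)) adjm[i, inst$network$adj[[i]]] <- TRUE
  connected_r <- function(sub) {
    if (length(sub) <= 1L) return(TRUE)
    reached <- sub[1L]
    repeat {
      grow <- sub[colSums(adjm[reached, sub, drop = FALSE]) > 0]
      grow <- union(reached, grow)
      if (length(grow) == length(reached)) break
      reached <- grow
    }
    length(reached) == length(sub)
  }
  for (s in seq_len(n)) {
    subsets <- utils::combn(n, s)
    for (j in seq_len(ncol(subsets))) {
      sub <- subsets[, j]
      counts <- colSums(inc[sub, , drop = FALSE])
      if (sum(counts >= k) < need) next
      if (connected_r(sub)) {
        return(list(size = s, nodes = inst$network$nodes[sub]))
      }
    }
  }
  list(size = Inf, nodes = NULL)
}
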