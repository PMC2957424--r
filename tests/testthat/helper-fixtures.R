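# Shared fixtures and independent oracles. The oracles here are written
# in plain R against the problem definitions and share no machinery with
# the package's solver path.

# tiny named path graph a-b-c with configurable cover sets
path_instance <- function(sets, k = 1, l = 0,
                          cases = sort(unique(unlist(sets)))) {
  net <- gene_network(cbind(c("a", "b"), c("b", "c")))
  inc <- matrix(0L, 3, length(cases), dimnames = list(c("a", "b", "c"), cases))
  for (g in names(sets)) inc[g, sets[[g]]] <- 1L
  build_instance(net, inc, k = k, l = l)
}

# random connected instance for fuzzing
random_instance <- function(n_nodes, n_cases, p_edge = 0.3, p_inc = 0.3,
                            k = 1, l = 0) {
  net <- generate_network(n_nodes, "er", p = p_edge)
  inc <- matrix(as.integer(stats::runif(n_nodes * n_cases) < p_inc),
                n_nodes, n_cases,
                dimnames = list(net$nodes, sprintf("u%02d", seq_len(n_cases))))
  build_instance(net, inc, k = k, l = l)
}

# independent all-pairs BFS distances (plain R, queue per root)
oracle_distances <- function(net) {
  n <- length(net$nodes)
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    D[s, s] <- 0
    frontier <- s
    d <- 0
    while (length(frontier)) {
      nxt <- unique(unlist(net$adj[frontier]))
      nxt <- nxt[is.infinite(D[s, nxt])]
      d <- d + 1
      D[s, nxt] <- d
      frontier <- nxt
    }
  }
  D
}

# independent per-root minimal feasible radius: grow the neighborhood
# radius by radius and test the coverage condition directly
oracle_min_radius <- function(inst, D = oracle_distances(inst$network)) {
  n <- length(inst$network$nodes)
  need <- length(inst$cases) - inst$l
  vapply(seq_len(n), function(v) {
    dmax <- max(D[v, is.finite(D[v, ])])
    for (r in 0:dmax) {
      nb <- which(D[v, ] <= r)
      counts <- colSums(inst$inc[nb, , drop = FALSE])
      if (sum(counts >= inst$k) >= need) return(r)
    }
    Inf
  }, numeric(1))
}

# independent greedy set cover (Johnson's rule) over a plain list of
# sets; tie-breaks mirror the package's: largest gain, then the largest
# total coverage of the other sets (= smallest own set on a tie), then
# lexicographic set name
oracle_greedy_set_cover <- function(sets, universe) {
  total <- sum(lengths(sets))
  uncovered <- universe
  chosen <- character()
  while (length(uncovered)) {
    gains <- vapply(sets, function(s) length(intersect(s, uncovered)),
                    numeric(1))
    if (max(gains) == 0) return(NULL)
    others <- total - lengths(sets)        # coverage total of the other sets
    ord <- order(-gains, -others, names(sets))
    pick <- names(sets)[ord[1L]]
    chosen <- c(chosen, pick)
    uncovered <- setdiff(uncovered, sets[[pick]])
    sets[[pick]] <- character()
  }
  chosen
}

# a valid cover fuzzed by growing it with random adjacent nodes
fuzz_cover <- function(inst, n_extra = 3) {
  dp <- tryCatch(solve_mrmcc(inst)[[1L]], error = function(e) NULL)
  if (is.null(dp)) return(NULL)
  nodes <- match(dp$nodes, inst$network$nodes)
  for (i in seq_len(n_extra)) {
    frontier <- setdiff(unique(unlist(inst$network$adj[nodes])), nodes)
    if (!length(frontier)) break
    nodes <- c(nodes, frontier[sample.int(length(frontier), 1L)])
  }
  inst$network$nodes[nodes]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
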