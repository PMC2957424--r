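#' Construct a gene interaction network
#'
#' Builds a simple undirected graph over gene identifiers from a two-column
#' edge table. Duplicate edges (in either orientation) are collapsed and
#' self-loops are dropped with a warning, so the result is always a simple
#' graph.
#'
#' @param edges two-column character matrix or data frame of edge endpoints.
#' @param nodes optional character vector of node identifiers; defaults to
#'   the union of the edge endpoints. Extra identifiers become isolated
#'   nodes.
#' @return An object of class `gene_network`: a list with `nodes` (sorted
#'   character vector) and `adj` (adjacency list of integer node indices).
#' @examples
#' net <- gene_network(cbind(c("A", "B"), c("B", "C")))
#' net
#' @export
gene_network <- function(edges, nodes = NULL) {
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (length(edges) == 0L) {
    edges <- matrix(character(), ncol = 2L)
  }
  if (ncol(edges) != 2L) stop("`edges` must have exactly two columns")
  storage.mode(edges) <- "character"
  loops <- edges[, 1L] == edges[, 2L]
  if (any(loops)) {
    warning(sprintf("dropped %d self-loop(s)", sum(loops)))
    edges <- edges[!loops, , drop = FALSE]
  }
  nodes <- sort(unique(c(nodes, as.vector(edges))))
  a <- match(edges[, 1L], nodes)
  b <- match(edges[, 2L], nodes)
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  keep <- !duplicated(cbind(lo, hi))
  lo <- lo[keep]
  hi <- hi[keep]
  adj <- vector("list", length(nodes))
  for (i in seq_along(adj)) adj[[i]] <- integer()
  if (length(lo)) {
    ends <- split(c(hi, lo), c(lo, hi))
    for (nm in names(ends)) {
      i <- as.integer(nm)
      adj[[i]] <- sort(unique(as.integer(ends[[nm]])))
    }
  }
  structure(list(nodes = nodes, adj = adj), class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("gene_network: %d nodes, %d edges\n",
              length(x$nodes), network_edge_count(x)))
  invisible(x)
}

network_edge_count <- function(network) {
  sum(lengths(network$adj)) %/% 2L
}

#' Node degrees of a gene network
#'
#' @param network a `gene_network`.
#' @return Named integer vector of node degrees.
#' @export
network_degree <- function(network) {
  stats::setNames(lengths(network$adj), network$nodes)
}

#' Edge list of a gene network
#'
#' @param network a `gene_network`.
#' @return Two-column character matrix, one row per undirected edge.
#' @export
network_edges <- function(network) {
  n <- length(network$nodes)
  from <- integer()
  to <- integer()
  for (i in seq_len(n)) {
    nb <- network$adj[[i]]
    nb <- nb[nb > i]
    from <- c(from, rep.int(i, length(nb)))
    to <- c(to, nb)
  }
  cbind(network$nodes[from], network$nodes[to])
}

#' Induced subgraph of a gene network
#'
#' @param network a `gene_network`.
#' @param nodes character vector of node identifiers to keep.
#' @return A `gene_network` over the requested nodes.
#' @export
network_induced <- function(network, nodes) {
  keep <- network$nodes %in% nodes
  missing <- setdiff(nodes, network$nodes)
  if (length(missing)) {
    stop("nodes not in network: ", paste(utils::head(missing, 5L), collapse = ", "))
  }
  idx <- which(keep)
  em <- network_edges(network)
  in_keep <- em[, 1L] %in% network$nodes[idx] & em[, 2L] %in% network$nodes[idx]
  gene_network(em[in_keep, , drop = FALSE], nodes = network$nodes[idx])
}

#' Convert a gene network to an igraph object
#'
#' @param network a `gene_network`.
#' @return An undirected [igraph::graph] with vertex name attributes.
#' @export
as_igraph <- function(network) {
  g <- igraph::make_empty_graph(n = length(network$nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = network$nodes)
  em <- network_edges(network)
  if (nrow(em)) g <- igraph::add_edges(g, t(em))
  g
}

#' Convert an igraph object to a gene network
#'
#' Drops multi-edges and self-loops so the result is a simple graph.
#'
#' @param g an [igraph::graph]; vertices must be named.
#' @return A `gene_network`.
#' @export
from_igraph <- function(g) {
  nm <- igraph::V(g)$name
  if (is.null(nm)) nm <- as.character(seq_len(igraph::vcount(g)))
  em <- igraph::as_edgelist(g, names = FALSE)
  edges <- cbind(nm[em[, 1L]], nm[em[, 2L]])
  suppressWarnings(gene_network(edges, nodes = nm))
}

#' Read a protein interaction network
#'
#' Reads a tab- or whitespace-delimited edge list (two columns, `#`
#' comments allowed) or a SIF file (`node relation node [node ...]`).
#' The result is a deduplicated simple undirected graph; self-loops are
#' dropped with a warning.
#'
#' @param path path to the network file.
#' @param format `"edgelist"` or `"sif"`; defaults to `"sif"` when the
#'   file extension is `.sif`, otherwise `"edgelist"`.
#' @return A [gene_network].
#' @export
read_network <- function(path, format = NULL) {
  if (!file.exists(path)) stop("network file not found: ", path)
  if (is.null(format)) {
    format <- if (grepl("\\.sif$", path, ignore.case = TRUE)) "sif" else "edgelist"
  }
  format <- match.arg(format, c("edgelist", "sif"))
  lines <- readLines(path, warn = FALSE)
  raw_n <- seq_along(lines)
  blank <- !nzchar(trimws(lines)) | grepl("^\\s*#", lines)
  lines <- lines[!blank]
  raw_n <- raw_n[!blank]
  if (!length(lines)) stop("network file is empty: ", path)
  toks <- strsplit(trimws(lines), "[\t ]+")
  edges <- vector("list", length(toks))
  lonely <- character()
  for (i in seq_along(toks)) {
    tk <- toks[[i]]
    if (format == "edgelist") {
      if (length(tk) != 2L) {
        stop(sprintf("malformed edge-list line %d in %s: expected 2 fields, got %d",
                     raw_n[i], path, length(tk)))
      }
      edges[[i]] <- matrix(tk, ncol = 2L)
    } else {
      if (length(tk) == 1L) {
        lonely <- c(lonely, tk)        # SIF allows isolated nodes
        edges[[i]] <- matrix(character(), ncol = 2L)
      } else if (length(tk) >= 3L) {
        edges[[i]] <- cbind(tk[1L], tk[-(1:2)])
      } else {
        stop(sprintf("malformed SIF line %d in %s: expected >=3 fields, got %d",
                     raw_n[i], path, length(tk)))
      }
    }
  }
  em <- do.call(rbind, edges)
  net <- gene_network(em, nodes = lonely)
  message(sprintf("read network: %d nodes, %d edges",
                  length(net$nodes), network_edge_count(net)))
  net
}

#' Write a network as a tab-delimited edge list
#'
#' @param network a `gene_network`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_network <- function(network, path) {
  em <- network_edges(network)
  utils::write.table(em, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a newline-delimited gene set
#'
#' @param path path to a file with one gene identifier per line; blank
#'   lines and `#` comments are skipped.
#' @return Character vector of unique gene identifiers.
#' @export
read_gene_set <- function(path) {
  if (!file.exists(path)) stop("gene set file not found: ", path)
  x <- trimws(readLines(path, warn = FALSE))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  unique(x)
}
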