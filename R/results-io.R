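#' Write a dysregulated pathway to disk
#'
#' `TSV` lists one module node per row with its per-case coverage count;
#' `JSON` round-trips every field of the result; `GML` preserves the
#' induced subgraph topology with a `root` vertex attribute (written via
#' igraph).
#'
#' @param dp a [dp_result].
#' @param path output path.
#' @param format `"tsv"`, `"json"` or `"gml"`; inferred from the file
#'   extension when omitted.
#' @param inst the [cover_instance][build_instance] the result was
#'   solved on; required for `"tsv"` (coverage counts) and `"gml"`
#'   (topology).
#' @return Invisibly, `path`.
#' @export
write_dp <- function(dp, path, format = NULL, inst = NULL) {
  if (is.null(format)) {
    format <- tolower(tools::file_ext(path))
    if (!format %in% c("tsv", "json", "gml")) {
      stop("cannot infer format from extension: ", path)
    }
  }
  format <- match.arg(format, c("tsv", "json", "gml"))
  if (format == "json") {
    jsonlite::write_json(unclass(dp), path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  } else if (format == "tsv") {
    if (is.null(inst)) stop("TSV output needs the cover instance")
    idx <- resolve_nodes(dp$nodes, inst)
    cov <- vapply(idx, function(i) sum(inst$inc[i, ]), numeric(1))
    tab <- data.frame(node = dp$nodes, n_cases_covered = cov,
                      is_root = dp$nodes == dp$root)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    if (is.null(inst)) stop("GML output needs the cover instance")
    sub <- network_induced(inst$network, dp$nodes)
    g <- as_igraph(sub)
    g <- igraph::set_vertex_attr(g, "root",
                                 value = as.integer(igraph::V(g)$name == dp$root))
    igraph::write_graph(g, path, format = "gml")
  }
  invisible(path)
}

#' Read a dysregulated pathway from JSON
#'
#' Inverse of `write_dp(..., format = "json")`.
#'
#' @param path path to the JSON file.
#' @return A [dp_result].
#' @export
read_dp <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  dp_result(nodes = x$nodes, root = x$root, radius = x$radius, k = x$k,
            l = x$l, outliers = if (is.null(x$outliers)) character() else x$outliers,
            p_value = if (is.null(x$p_value)) NA_real_ else x$p_value,
            z_score = if (is.null(x$z_score)) NA_real_ else x$z_score)
}
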