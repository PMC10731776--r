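#' Construct a rooted disease ontology DAG
#'
#' A disease's semantic context is its ancestor graph in a disease ontology:
#' the disease itself (the root, i.e. the most specific term), every broader
#' term reachable from it, and the child-to-parent edges connecting them.
#'
#' @param root Disease identifier; the most specific node.
#' @param edges Data frame with character columns `child` and `parent`. May
#'   be empty for a single-node graph.
#' @param nodes Optional explicit node set; defaults to the root plus every
#'   endpoint of `edges`.
#' @return A list of class `disease_dag` with elements `root`, `nodes`,
#'   `edges`.
#' @export
disease_dag <- function(root, edges = data.frame(child = character(),
                                                 parent = character()),
                        nodes = NULL) {
  root <- as.character(root)
  edges <- data.frame(child = as.character(edges$child),
                      parent = as.character(edges$parent),
                      stringsAsFactors = FALSE)
  if (is.null(nodes)) nodes <- unique(c(root, edges$child, edges$parent))
  nodes <- as.character(nodes)
  if (!root %in% nodes) abort(paste0("root ", root, " absent from DAG nodes"))
  if (nrow(edges)) {
    g <- igraph::graph_from_data_frame(edges, vertices = data.frame(name = nodes))
    if (!igraph::is_dag(g)) {
      abort(paste0("cycle detected in ontology graph of disease ", root))
    }
  }
  structure(list(root = root, nodes = nodes, edges = edges),
            class = "disease_dag")
}

#' @export
print.disease_dag <- function(x, ...) {
  cat(sprintf("<disease_dag> root=%s nodes=%d edges=%d\n",
              x$root, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

# parent -> children adjacency (list keyed by node)
dag_children <- function(dag) {
  ch <- split(dag$edges$child, dag$edges$parent)
  ch[intersect(names(ch), dag$nodes)]
}
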