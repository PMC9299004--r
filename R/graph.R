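#' Bipartite graph constructor (internal)
#'
#' Simple (no duplicate edges), strictly bipartite graph connecting
#' documents (left side) to terms or metadata values (right side).  Edges
#' are stored as a two-column integer matrix of (left index, right index).
#'
#' @param left Character vector of left node identifiers (documents).
#' @param right Character vector of right node labels (terms or values).
#' @param edges Two-column integer matrix; each row one edge.
#' @param right_type Node type tag of the right side, e.g. `"term"`,
#'   `"year"`, `"country"`.
#' @return An object of class `"bipartite_graph"`.
#' @keywords internal
bipartite_graph <- function(left, right, edges, right_type = "term") {
  stopifnot(is.character(left), is.character(right))
  edges <- matrix(as.integer(edges), ncol = 2L,
                  dimnames = list(NULL, c("left", "right")))
  if (nrow(edges)) {
    stopifnot(min(edges) >= 1L,
              max(edges[, 1L]) <= length(left),
              max(edges[, 2L]) <= length(right))
    if (anyDuplicated(paste(edges[, 1L], edges[, 2L])))
      stop("duplicate edges: the graph must be simple")
  }
  structure(list(left = left, right = right, edges = edges,
                 left_type = "document", right_type = right_type),
            class = "bipartite_graph")
}

#' @export
print.bipartite_graph <- function(x, ...) {
  cat("Bipartite graph:", length(x$left), paste0(x$left_type, "s"), "x",
      length(x$right), paste0(x$right_type, "s,"), nrow(x$edges), "edges\n")
  invisible(x)
}

#' Number of edges of a bipartite graph
#' @param graph A `bipartite_graph`.
#' @return Integer edge count.
#' @export
n_edges <- function(graph) nrow(graph$edges)

#' Build the document-term incidence graph
#'
#' Connects each document to its distinct terms: local term frequency is
#' discarded, so each (document, term) pair contributes at most one edge
#' and the model sees binary incidence.  Documents with no tokens cannot be
#' placed by the model and are dropped with a warning.
#'
#' @param corpus A preprocessed [corpus()].
#' @param min_tokens Minimum number of distinct terms for a document to be
#'   kept (default 1).
#' @return A `bipartite_graph` with `right_type = "term"`.
#' @export
build_doc_term_graph <- function(corpus, min_tokens = 1L) {
  stopifnot(inherits(corpus, "corpus"), min_tokens >= 1L)
  term_sets <- lapply(corpus$documents, function(d) unique(d$tokens))
  keep <- vapply(term_sets, length, 0L) >= min_tokens
  if (!all(keep)) {
    dropped <- vapply(corpus$documents[!keep], `[[`, "", "doc_id")
    warning("dropping ", length(dropped),
            " document(s) with fewer than ", min_tokens,
            " distinct term(s): ", paste(utils::head(dropped, 5L),
                                         collapse = ", "),
            if (length(dropped) > 5L) ", ..." else "")
  }
  docs <- corpus$documents[keep]
  term_sets <- term_sets[keep]
  left <- vapply(docs, `[[`, "", "doc_id")
  right <- sort(unique(unlist(term_sets, use.names = FALSE)))
  if (is.null(right)) right <- character()
  li <- rep.int(seq_along(docs), vapply(term_sets, length, 0L))
  ri <- match(unlist(term_sets, use.names = FALSE), right)
  bipartite_graph(left, right, cbind(li, ri), right_type = "term")
}

#' Build a document-metadata incidence graph
#'
#' Connects each document to each value it carries for one metadata field
#' (multi-valued fields yield one edge per value).  Documents lacking the
#' field are omitted from this graph.
#'
#' @param corpus A [corpus()].
#' @param field Metadata field name, e.g. `"year"`.
#' @return A `bipartite_graph` whose `right_type` is the field name.
#' @export
build_doc_metadata_graph <- function(corpus, field) {
  stopifnot(inherits(corpus, "corpus"), is.character(field),
            length(field) == 1L)
  vals <- lapply(corpus$documents, function(d) unique(d$metadata[[field]]))
  keep <- vapply(vals, length, 0L) > 0L
  if (!any(keep))
    stop("metadata field '", field, "' present in no document")
  docs <- corpus$documents[keep]
  vals <- vals[keep]
  left <- vapply(docs, `[[`, "", "doc_id")
  right <- sort(unique(unlist(vals, use.names = FALSE)))
  li <- rep.int(seq_along(docs), vapply(vals, length, 0L))
  ri <- match(unlist(vals, use.names = FALSE), right)
  bipartite_graph(left, right, cbind(li, ri), right_type = field)
}

#' Restrict a document-metadata graph to a document subset
#'
#' Used for sub-corpus re-chaining: keeps only the given documents and any
#' metadata values still connected to at least one of them.
#'
#' @param graph A `bipartite_graph`.
#' @param doc_ids Character vector of document identifiers to keep.
#' @return A restricted `bipartite_graph`.
#' @export
subset_graph <- function(graph, doc_ids) {
  stopifnot(inherits(graph, "bipartite_graph"))
  keep_l <- which(graph$left %in% doc_ids)
  if (!length(keep_l)) stop("no documents left after restriction")
  e <- graph$edges[graph$edges[, 1L] %in% keep_l, , drop = FALSE]
  keep_r <- sort(unique(e[, 2L]))
  bipartite_graph(graph$left[keep_l], graph$right[keep_r],
                  cbind(match(e[, 1L], keep_l), match(e[, 2L], keep_r)),
                  right_type = graph$right_type)
}

#' Write a graph as a portable edge list plus node table
#'
#' Produces `<prefix>_nodes.tsv` (node id, type, label) and
#' `<prefix>_edges.tsv` (source id, target id).
#'
#' @param graph A `bipartite_graph`.
#' @param prefix Output path prefix.
#' @return Invisibly, the two file paths.
#' @export
write_graph_edgelist <- function(graph, prefix) {
  nodes <- data.frame(
    id = c(paste0("d", seq_along(graph$left)),
           paste0("r", seq_along(graph$right))),
    type = c(rep(graph$left_type, length(graph$left)),
             rep(graph$right_type, length(graph$right))),
    label = c(graph$left, graph$right),
    stringsAsFactors = FALSE)
  edges <- data.frame(source = paste0("d", graph$edges[, 1L]),
                      target = paste0("r", graph$edges[, 2L]),
                      stringsAsFactors = FALSE)
  fn <- paste0(prefix, c("_nodes.tsv", "_edges.tsv"))
  utils::write.table(nodes, fn[1L], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(edges, fn[2L], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(fn)
}

#' Export a graph to GraphML
#'
#' Requires the igraph package.
#'
#' @param graph A `bipartite_graph`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_graphml <- function(graph, path) {
  if (!requireNamespace("igraph", quietly = TRUE))
    stop("GraphML export requires the igraph package")
  nl <- length(graph$left)
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, nl), rep(TRUE, length(graph$right))),
    edges = as.vector(t(cbind(graph$edges[, 1L],
                              graph$edges[, 2L] + nl))),
    directed = FALSE)
  igraph::V(g)$name <- c(graph$left, graph$right)
  igraph::V(g)$nodetype <- c(rep(graph$left_type, nl),
                             rep(graph$right_type, length(graph$right)))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
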