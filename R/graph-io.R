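#' Read an undirected network from a plain-text edge list
#'
#' Parses the common edge-list dialects used by public network repositories:
#' one edge per line as two node labels separated by whitespace or a comma,
#' lines beginning with `#` or `%` treated as comments, blank lines ignored.
#' A line with a single token declares an isolated (degree-0) node. The
#' resulting graph is undirected and simple: self-loops and duplicate edges
#' are dropped with a warning that reports how many of each were discarded.
#'
#' Node labels are kept as opaque strings; vertices are indexed internally in
#' first-seen order.
#'
#' @param source path to a file, or a connection, or a character vector of
#'   lines (useful for tests and small literals).
#' @param delimiter optional regular expression used to split each line. The
#'   default splits on any run of whitespace and/or commas.
#' @param comment_prefix character vector of line prefixes to skip.
#' @return an [igraph::igraph] object, undirected and simple, with vertex
#'   attribute `name` carrying the labels.
#' @seealso [write_edge_list()], [degree_map()]
#' @examples
#' g <- read_edge_list(c("a b", "b c", "# a comment", "d"))
#' igraph::vcount(g)  # 4 nodes, one isolated
#' @export
read_edge_list <- function(source, delimiter = NULL,
                           comment_prefix = c("#", "%")) {
  lines <- if (is.character(source) && length(source) > 1L) {
    source
  } else if (is.character(source) && !file.exists(source) &&
             grepl("[ \t,]", source)) {
    # a single literal line such as "a b"
    source
  } else {
    tryCatch(suppressWarnings(readLines(source, warn = FALSE)),
             error = function(e) stop("cannot read edge list: ",
                                      conditionMessage(e), call. = FALSE))
  }
  split_re <- if (is.null(delimiter)) "[\\s,]+" else delimiter

  nodes <- character(0)
  seen <- new.env(parent = emptyenv())
  from <- character(0)
  to <- character(0)
  n_loops <- 0L

  note <- function(lab) {
    if (is.null(seen[[lab]])) {
      seen[[lab]] <- TRUE
      nodes[[length(nodes) + 1L]] <<- lab
    }
  }

  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    ln <- sub("\\s+$", "", sub("^\\s+", "", ln))
    if (!nzchar(ln)) next
    if (any(startsWith(ln, comment_prefix))) next
    toks <- strsplit(ln, split_re, perl = TRUE)[[1]]
    toks <- toks[nzchar(toks)]
    if (length(toks) == 0L) {
      stop("malformed edge-list line ", i, ": no node labels found",
           call. = FALSE)
    }
    if (length(toks) == 1L) {       # isolated-node declaration
      note(toks[[1]])
      next
    }
    a <- toks[[1]]; b <- toks[[2]]
    note(a); note(b)
    if (a == b) {
      n_loops <- n_loops + 1L
      next
    }
    from[[length(from) + 1L]] <- a
    to[[length(to) + 1L]] <- b
  }

  # canonicalize each edge and count duplicates
  lo <- ifelse(from < to, from, to)
  hi <- ifelse(from < to, to, from)
  key <- paste(lo, hi, sep = "\r")
  dup <- duplicated(key)
  n_dups <- sum(dup)
  if (n_loops > 0L || n_dups > 0L) {
    warning(sprintf("dropped %d self-loop(s) and %d duplicate edge(s)",
                    n_loops, n_dups), call. = FALSE)
  }
  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = nodes)
  if (any(!dup)) {
    g <- igraph::add_edges(g, rbind(lo[!dup], hi[!dup]))
  }
  g
}

#' Write a graph as a plain-text edge list
#'
#' Emits each edge exactly once with endpoints in canonical (label-sorted)
#' order, tab-separated, and each isolated node as a single-token line, so
#' that `read_edge_list(write_edge_list(g))` reproduces the node and edge
#' sets.
#'
#' @param graph an undirected [igraph::igraph] with named vertices.
#' @param sink path or connection to write to.
#' @param header optional character vector of comment lines (written with a
#'   leading `"# "`).
#' @return `sink`, invisibly.
#' @export
write_edge_list <- function(graph, sink, header = NULL) {
  graph <- as_glinet_graph(graph)
  el <- igraph::as_edgelist(graph, names = TRUE)
  out <- character(0)
  if (!is.null(header)) out <- paste0("# ", header)
  if (nrow(el) > 0L) {
    lo <- pmin(el[, 1], el[, 2])
    hi <- pmax(el[, 1], el[, 2])
    out <- c(out, paste(lo, hi, sep = "\t"))
  }
  iso <- igraph::V(graph)$name[igraph::degree(graph) == 0L]
  out <- c(out, iso)
  writeLines(out, sink)
  invisible(sink)
}

#' Degree of every node and the network maximum degree
#'
#' @param graph an undirected [igraph::igraph] with named vertices.
#' @return a list with components `degree` (named integer vector, one entry
#'   per node) and `max_degree` (0 for an edgeless graph).
#' @examples
#' g <- worked_example_graph()
#' degree_map(g)$max_degree  # 6
#' @export
degree_map <- function(graph) {
  graph <- as_glinet_graph(graph)
  d <- igraph::degree(graph)
  storage.mode(d) <- "integer"
  list(degree = d, max_degree = if (length(d)) max(d) else 0L)
}

# Validate/coerce a graph argument: must be an undirected simple igraph.
# Unnamed vertices receive labels "v1", "v2", ... in vertex order.
as_glinet_graph <- function(graph) {
  if (!igraph::is_igraph(graph)) {
    stop("`graph` must be an igraph object (see read_edge_list())",
         call. = FALSE)
  }
  if (igraph::is_directed(graph)) {
    stop("directed graphs are not supported", call. = FALSE)
  }
  if (!igraph::is_simple(graph)) {
    graph <- igraph::simplify(graph)
  }
  if (is.null(igraph::V(graph)$name)) {
    graph <- igraph::set_vertex_attr(graph, "name",
                                     value = paste0("v", seq_len(igraph::vcount(graph))))
  }
  graph
}

# Adjacency as a list of integer vectors (1-based vertex indices).
adjacency_index <- function(graph) {
  lapply(igraph::adjacent_vertices(graph, igraph::V(graph)), as.integer)
}

# Resolve node labels to vertex indices, with a helpful error.
node_index <- function(graph, v) {
  labels <- igraph::V(graph)$name
  idx <- match(as.character(v), labels)
  if (anyNA(idx)) {
    stop("unknown node(s): ", paste(v[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  idx
}
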