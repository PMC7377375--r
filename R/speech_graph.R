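#' Build a directed word graph from a token sequence
#'
#' Each distinct word becomes a node; each observed transition between
#' consecutive tokens becomes a directed edge.  Repeated transitions
#' collapse to a single edge, self-loops (immediate word repetition) are
#' retained, and no edge is created across a paragraph break.
#'
#' @param tokens character vector of word tokens, or a [tokenized_report()].
#' @param break_positions integer positions `i` meaning "no transition
#'   between token `i` and `i + 1`"; ignored when `tokens` is a report.
#' @return An object of class `word_graph` with elements `nodes` (character)
#'   and `edges` (two-column character matrix `from`/`to`).
#' @examples
#' g <- build_graph(c("a", "b", "a", "b"))
#' graph_measures(g)
#' @export
build_graph <- function(tokens, break_positions = integer(0)) {
  if (inherits(tokens, "tokenized_report")) {
    break_positions <- tokens$break_positions
    tokens <- tokens$tokens
  }
  tokens <- as.character(tokens)
  if (length(tokens) == 0) stop("cannot build a graph from zero tokens", call. = FALSE)
  n <- length(tokens)
  if (n > 1) {
    from_idx <- setdiff(seq_len(n - 1L), as.integer(break_positions))
    edges <- unique(cbind(from = tokens[from_idx], to = tokens[from_idx + 1L]))
  } else {
    edges <- matrix(character(0), ncol = 2, dimnames = list(NULL, c("from", "to")))
  }
  structure(list(nodes = unique(tokens), edges = edges), class = "word_graph")
}

#' @export
print.word_graph <- function(x, ...) {
  cat(sprintf("<word_graph: %d nodes, %d edges>\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Connectedness measures of a word graph
#'
#' Computes the three connectedness attributes used in speech-graph
#' analysis: `edges`, the number of distinct directed edges; `lcc`, the node
#' count of the largest connected component when edge direction is ignored;
#' and `lsc`, the node count of the largest strongly connected component
#' (mutual directed reachability; an isolated node counts as size 1).
#'
#' @param g a `word_graph` from [build_graph()].
#' @return A list with `n_nodes`, `edges`, `lcc` and `lsc`.
#' @export
graph_measures <- function(g) {
  stopifnot(inherits(g, "word_graph"))
  ig <- igraph::graph_from_data_frame(
    as.data.frame(g$edges, stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = g$nodes, stringsAsFactors = FALSE)
  )
  list(
    n_nodes = length(g$nodes),
    edges = nrow(g$edges),
    lcc = max(igraph::components(ig, mode = "weak")$csize),
    lsc = max(igraph::components(ig, mode = "strong")$csize)
  )
}

#' Write a word graph as an edge list
#'
#' One `source TAB target` line per distinct directed edge.
#'
#' @param g a `word_graph`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path) {
  stopifnot(inherits(g, "word_graph"))
  writeLines(paste(g$edges[, "from"], g$edges[, "to"], sep = "\t"), path)
  invisible(path)
}
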