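# Partially directed graphs: the data model shared by every module.
#
# A "pdg" is a list with
#   $nodes : sorted character vector of node labels
#   $dir   : k x 2 character matrix of directed edges (from, to)
#   $und   : k x 2 character matrix of undirected edges, rows stored with
#            the lexicographically smaller label first
# A "dag" is a pdg with no undirected edges and no directed cycle; it
# carries class c("dag", "pdg").

.label_re <- "^[A-Za-z0-9_]+$"

.as_edge_matrix <- function(x, what) {
  if (is.null(x) || (is.matrix(x) && nrow(x) == 0) || length(x) == 0) {
    return(matrix(character(0), ncol = 2L))
  }
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.character(x) && !is.matrix(x)) {
    if (length(x) %% 2L != 0L) {
      stop(sprintf("%s edges must come in pairs of labels", what), call. = FALSE)
    }
    x <- matrix(x, ncol = 2L, byrow = TRUE)
  }
  if (!is.matrix(x) || ncol(x) != 2L) {
    stop(sprintf("%s edges must be a 2-column matrix", what), call. = FALSE)
  }
  storage.mode(x) <- "character"
  dimnames(x) <- NULL
  x
}

.sort_rows <- function(m) {
  if (nrow(m) == 0L) return(m)
  m[order(m[, 1L], m[, 2L]), , drop = FALSE]
}

.pair_keys <- function(m) {
  if (nrow(m) == 0L) return(character(0))
  paste(pmin(m[, 1L], m[, 2L]), pmax(m[, 1L], m[, 2L]), sep = "\r")
}

err_parse <- function(msg) {
  stop(errorCondition(msg, class = c("edgeodds_parse_error", "edgeodds_error")))
}

err_limit <- function(msg) {
  stop(errorCondition(msg, class = c("edgeodds_limit_error", "edgeodds_error")))
}

#' Construct a partially directed graph
#'
#' A partially directed graph (PDG) has a node set and at most one edge per
#' unordered node pair; each edge is either directed or undirected. This is
#' the syntax of essential graphs: a directed edge is compelled, an
#' undirected edge marks an orientation that differs across the members of
#' the equivalence class the graph summarises.
#'
#' @param nodes Character vector of node labels (letters, digits,
#'   underscore). Nodes that appear only in `nodes` are isolated.
#' @param directed Directed edges, as a 2-column matrix/data frame
#'   (from, to) or a flat character vector `c("A","B", "B","C")` read
#'   pairwise.
#' @param undirected Undirected edges in the same formats; endpoint order is
#'   irrelevant and is canonicalised internally.
#' @return An object of class `pdg`.
#' @examples
#' hub <- pdg(undirected = c("A", "H", "B", "H", "C", "H"))
#' pdg(nodes = "D", directed = c("A", "B"))
#' @seealso [dag()], [parse_graph()], [skeleton()]
#' @export
pdg <- function(nodes = character(0), directed = NULL, undirected = NULL) {
  dir <- .as_edge_matrix(directed, "directed")
  und <- .as_edge_matrix(undirected, "undirected")
  nodes <- as.character(nodes)
  all_labels <- c(nodes, as.vector(dir), as.vector(und))
  bad <- all_labels[!grepl(.label_re, all_labels)]
  if (length(bad)) {
    err_parse(sprintf("invalid node label(s): %s", paste(unique(bad), collapse = ", ")))
  }
  if (nrow(dir) && any(dir[, 1L] == dir[, 2L])) err_parse("self-loops are not allowed")
  if (nrow(und) && any(und[, 1L] == und[, 2L])) err_parse("self-loops are not allowed")
  # canonical endpoint order for undirected edges
  if (nrow(und)) {
    und <- cbind(pmin(und[, 1L], und[, 2L]), pmax(und[, 1L], und[, 2L]))
  }
  keys <- c(.pair_keys(dir), .pair_keys(und))
  if (anyDuplicated(keys)) {
    err_parse("at most one edge is allowed per node pair")
  }
  g <- structure(
    list(
      nodes = sort(unique(all_labels)),
      dir = .sort_rows(dir),
      und = .sort_rows(und)
    ),
    class = "pdg"
  )
  g
}

#' Construct a directed acyclic graph
#'
#' A DAG is a fully directed [pdg()] with no directed cycle. Construction
#' fails if a cycle is present.
#'
#' @inheritParams pdg
#' @param edges Directed edges (from, to), same formats as in [pdg()].
#' @return An object of class `c("dag", "pdg")`.
#' @examples
#' dag(edges = c("A", "B", "C", "B"))   # the collider A -> B <- C
#' @export
dag <- function(nodes = character(0), edges = NULL) {
  as_dag(pdg(nodes = nodes, directed = edges))
}

#' Coerce a fully directed graph to a DAG
#'
#' @param g A [pdg()] whose edges are all directed.
#' @return The same graph with class `c("dag", "pdg")`.
#' @export
as_dag <- function(g) {
  stopifnot(inherits(g, "pdg"))
  if (nrow(g$und)) stop("graph has undirected edges; orient them first", call. = FALSE)
  if (!.acyclic_dir(g$nodes, g$dir)) stop("directed graph contains a cycle", call. = FALSE)
  class(g) <- c("dag", "pdg")
  g
}

#' @export
print.pdg <- function(x, ...) {
  kind <- if (inherits(x, "dag")) "dag" else "pdg"
  cat(sprintf("<%s> %d nodes, %d directed + %d undirected edges\n",
              kind, length(x$nodes), nrow(x$dir), nrow(x$und)))
  cat(" nodes:", paste(x$nodes, collapse = " "), "\n")
  if (nrow(x$dir)) cat(" ", paste(x$dir[, 1L], "->", x$dir[, 2L], collapse = "  "), "\n")
  if (nrow(x$und)) cat(" ", paste(x$und[, 1L], "--", x$und[, 2L], collapse = "  "), "\n")
  invisible(x)
}

# canonical single-string encoding; equal graphs <=> equal keys
graph_key <- function(g) {
  paste(
    paste(g$nodes, collapse = ","),
    paste(paste0(g$dir[, 1L], ">", g$dir[, 2L]), collapse = ";"),
    paste(paste0(g$und[, 1L], "-", g$und[, 2L]), collapse = ";"),
    sep = "|"
  )
}

#' Test two graphs for equality
#'
#' Graphs compare by node labels and edge sets, not by object identity.
#'
#' @param g1,g2 [pdg()] objects.
#' @return Logical.
#' @export
pdg_equal <- function(g1, g2) {
  stopifnot(inherits(g1, "pdg"), inherits(g2, "pdg"))
  graph_key(g1) == graph_key(g2)
}

# parent / child lookup tables for a directed edge matrix
.parents_of <- function(nodes, dir) {
  out <- rep(list(character(0)), length(nodes))
  names(out) <- nodes
  if (nrow(dir)) {
    sp <- split(dir[, 1L], dir[, 2L])
    out[names(sp)] <- sp
  }
  out
}

.children_of <- function(nodes, dir) {
  out <- rep(list(character(0)), length(nodes))
  names(out) <- nodes
  if (nrow(dir)) {
    sp <- split(dir[, 2L], dir[, 1L])
    out[names(sp)] <- sp
  }
  out
}

# Kahn's algorithm on a directed edge matrix; TRUE iff acyclic
.acyclic_dir <- function(nodes, dir) {
  if (nrow(dir) == 0L) return(TRUE)
  indeg <- table(factor(dir[, 2L], levels = nodes))
  indeg <- stats::setNames(as.integer(indeg), nodes)
  children <- .children_of(nodes, dir)
  queue <- nodes[indeg == 0L]
  removed <- 0L
  while (length(queue)) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    removed <- removed + 1L
    for (ch in children[[v]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  removed == length(nodes)
}
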