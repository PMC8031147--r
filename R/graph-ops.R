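# Graph-theoretic operators: skeleton, acyclicity, colliders, descendants,
# active paths, d-separation, Markov equivalence.

#' Skeleton of a graph
#'
#' The skeleton erases all orientation information: it is the set of
#' directly connected node pairs.
#'
#' @param g A [pdg()].
#' @return A 2-column character matrix of unordered pairs, each row with the
#'   smaller label first, rows in lexicographic order.
#' @examples
#' skeleton(dag(edges = c("A", "B", "C", "B")))  # same as skeleton of A--B--C
#' @export
skeleton <- function(g) {
  stopifnot(inherits(g, "pdg"))
  m <- rbind(g$dir, g$und)
  if (nrow(m)) m <- cbind(pmin(m[, 1L], m[, 2L]), pmax(m[, 1L], m[, 2L]))
  .sort_rows(m)
}

#' Acyclicity of a fully directed graph
#'
#' @param g A [pdg()] whose edges are all directed (an error is raised
#'   otherwise: undirected edges must be oriented before the question makes
#'   sense).
#' @return Logical: `TRUE` iff no directed cycle exists.
#' @export
is_acyclic <- function(g) {
  stopifnot(inherits(g, "pdg"))
  if (nrow(g$und)) stop("graph has undirected edges; orient them first", call. = FALSE)
  .acyclic_dir(g$nodes, g$dir)
}

# uncovered colliders of an arbitrary arrow set, with "covered" judged
# against an arbitrary adjacency key set (needed by consistent_extensions,
# where arrows come from the directed part but adjacency from the full
# skeleton)
.uncovered_colliders_raw <- function(nodes, dir, adj_keys) {
  pa <- .parents_of(nodes, dir)
  out <- matrix(character(0), ncol = 3L)
  for (m in nodes) {
    p <- pa[[m]]
    if (length(p) < 2L) next
    p <- sort(p)
    for (i in seq_len(length(p) - 1L)) {
      for (j in seq((i + 1L), length(p))) {
        key <- paste(p[[i]], p[[j]], sep = "\r")
        if (!(key %in% adj_keys)) out <- rbind(out, c(p[[i]], m, p[[j]]))
      }
    }
  }
  .sort_rows_3(out)
}

.sort_rows_3 <- function(m) {
  if (nrow(m) == 0L) return(m)
  m[order(m[, 1L], m[, 2L], m[, 3L]), , drop = FALSE]
}

#' Uncovered colliders (v-structures) of a DAG
#'
#' A collider is a triple X -> M <- Y; it is uncovered when X and Y are not
#' directly connected. Uncovered colliders, together with the skeleton,
#' characterise Markov equivalence.
#'
#' @param d A [dag()].
#' @return A 3-column character matrix (left, mid, right), each row with
#'   `left < right` lexicographically, rows sorted.
#' @examples
#' uncovered_colliders(dag(edges = c("A", "B", "C", "B")))
#' @export
uncovered_colliders <- function(d) {
  stopifnot(inherits(d, "dag"))
  .uncovered_colliders_raw(d$nodes, d$dir, .pair_keys(skeleton(d)))
}

#' Descendants of a node
#'
#' All nodes reachable from `x` along directed paths, excluding `x` itself.
#'
#' @param d A [dag()].
#' @param x A node label in `d`.
#' @return Character vector (possibly empty), sorted.
#' @export
descendants <- function(d, x) {
  stopifnot(inherits(d, "dag"))
  if (!(x %in% d$nodes)) stop(sprintf("unknown node '%s'", x), call. = FALSE)
  ch <- .children_of(d$nodes, d$dir)
  seen <- character(0)
  frontier <- ch[[x]]
  while (length(frontier)) {
    new <- setdiff(frontier, seen)
    seen <- c(seen, new)
    frontier <- unique(unlist(ch[new], use.names = FALSE))
  }
  sort(seen)
}

# ancestors of a node set, including the set itself
.ancestors_incl <- function(d, xs) {
  pa <- .parents_of(d$nodes, d$dir)
  seen <- xs
  frontier <- unique(unlist(pa[xs], use.names = FALSE))
  while (length(frontier)) {
    new <- setdiff(frontier, seen)
    seen <- c(seen, new)
    frontier <- unique(unlist(pa[new], use.names = FALSE))
  }
  seen
}

#' Is a path active (open) given a conditioning set?
#'
#' A path is active conditional on a set C when no noncollider on the path
#' is in C and every collider on the path is in C or has a descendant in C.
#' Path endpoints count as noncolliders.
#'
#' @param d A [dag()].
#' @param path Character vector of node labels; consecutive labels must be
#'   directly connected in `d` (the edge between them is implied, since a
#'   graph holds at most one edge per pair).
#' @param cond Character vector of conditioning nodes (possibly empty).
#' @return Logical.
#' @examples
#' d <- dag(edges = c("A", "B", "C", "B"))
#' is_active_path(d, c("A", "B", "C"), character(0))  # blocked collider
#' is_active_path(d, c("A", "B", "C"), "B")           # opened by conditioning
#' @export
is_active_path <- function(d, path, cond = character(0)) {
  stopifnot(inherits(d, "dag"), is.character(path), length(path) >= 1L)
  if (!all(path %in% d$nodes)) stop("path contains unknown nodes", call. = FALSE)
  dir_keys <- paste(d$dir[, 1L], d$dir[, 2L], sep = "\r")
  n <- length(path)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      fwd <- paste(path[[i]], path[[i + 1L]], sep = "\r")
      bwd <- paste(path[[i + 1L]], path[[i]], sep = "\r")
      if (!(fwd %in% dir_keys || bwd %in% dir_keys)) {
        stop(sprintf("'%s' and '%s' are not adjacent: not a path of the graph",
                     path[[i]], path[[i + 1L]]), call. = FALSE)
      }
    }
  }
  into <- function(i, j) paste(path[[i]], path[[j]], sep = "\r") %in% dir_keys
  for (i in seq_len(n)) {
    is_collider <- i > 1L && i < n && into(i - 1L, i) && into(i + 1L, i)
    v <- path[[i]]
    if (is_collider) {
      if (!(v %in% cond || length(intersect(descendants(d, v), cond)))) return(FALSE)
    } else {
      if (v %in% cond) return(FALSE)
    }
  }
  TRUE
}

#' d-separation in a DAG
#'
#' Nodes `x` and `y` are d-separated by `cond` when no path between them is
#' active given `cond`. The default implementation restricts the graph to
#' the ancestors of `{x, y}` and `cond`, moralises (marries co-parents),
#' drops the conditioning nodes, and tests undirected connectivity — the
#' standard ancestral-moral-graph criterion. `method = "paths"` instead
#' enumerates every simple path between `x` and `y` and applies
#' [is_active_path()] to each; it is exponential and intended as an
#' independent cross-check on small graphs.
#'
#' @param d A [dag()].
#' @param x,y Distinct node labels, neither in `cond`.
#' @param cond Character vector of conditioning nodes.
#' @param method `"reachability"` (default) or `"paths"`.
#' @return Logical: `TRUE` iff `x` and `y` are d-separated given `cond`.
#' @examples
#' chain <- dag(edges = c("A", "B", "B", "C"))
#' d_separated(chain, "A", "C", "B")            # TRUE
#' coll <- dag(edges = c("A", "B", "C", "B"))
#' d_separated(coll, "A", "C")                  # TRUE
#' d_separated(coll, "A", "C", "B")             # FALSE
#' @export
d_separated <- function(d, x, y, cond = character(0),
                        method = c("reachability", "paths")) {
  method <- match.arg(method)
  stopifnot(inherits(d, "dag"))
  if (!all(c(x, y, cond) %in% d$nodes)) stop("unknown node", call. = FALSE)
  if (x == y) stop("x and y must be distinct", call. = FALSE)
  if (x %in% cond || y %in% cond) {
    stop("conditioning set may not contain x or y", call. = FALSE)
  }
  if (method == "paths") return(.d_sep_paths(d, x, y, cond))
  anc <- .ancestors_incl(d, unique(c(x, y, cond)))
  keep <- d$dir[d$dir[, 1L] %in% anc & d$dir[, 2L] %in% anc, , drop = FALSE]
  # moral graph: every directed edge undirected, co-parents married
  und <- keep
  pa <- .parents_of(anc, keep)
  for (m in anc) {
    p <- pa[[m]]
    if (length(p) >= 2L) {
      und <- rbind(und, t(utils::combn(sort(p), 2L)))
    }
  }
  # drop conditioning nodes, test connectivity x ~ y
  live <- setdiff(anc, cond)
  if (nrow(und)) {
    und <- und[und[, 1L] %in% live & und[, 2L] %in% live, , drop = FALSE]
  }
  nb <- rep(list(character(0)), length(live))
  names(nb) <- live
  if (nrow(und)) {
    for (i in seq_len(nrow(und))) {
      a <- und[i, 1L]; b <- und[i, 2L]
      nb[[a]] <- c(nb[[a]], b)
      nb[[b]] <- c(nb[[b]], a)
    }
  }
  seen <- x
  frontier <- nb[[x]]
  while (length(frontier)) {
    if (y %in% frontier) return(FALSE)
    new <- setdiff(frontier, seen)
    seen <- c(seen, new)
    frontier <- unique(unlist(nb[new], use.names = FALSE))
  }
  TRUE
}

# exponential oracle: enumerate all simple paths in the skeleton, test each
.d_sep_paths <- function(d, x, y, cond) {
  sk <- skeleton(d)
  nb <- rep(list(character(0)), length(d$nodes))
  names(nb) <- d$nodes
  if (nrow(sk)) {
    for (i in seq_len(nrow(sk))) {
      a <- sk[i, 1L]; b <- sk[i, 2L]
      nb[[a]] <- c(nb[[a]], b)
      nb[[b]] <- c(nb[[b]], a)
    }
  }
  found_active <- FALSE
  recurse <- function(path) {
    if (found_active) return()
    v <- path[[length(path)]]
    if (v == y) {
      if (is_active_path(d, path, cond)) found_active <<- TRUE
      return()
    }
    for (w in nb[[v]]) {
      if (!(w %in% path)) recurse(c(path, w))
    }
  }
  recurse(x)
  !found_active
}

#' Markov equivalence of two DAGs
#'
#' Two DAGs entail exactly the same d-separation statements iff they share
#' skeleton and uncovered colliders; that characterisation is what is
#' tested here.
#'
#' @param d1,d2 [dag()] objects on the same node set.
#' @return Logical.
#' @export
markov_equivalent <- function(d1, d2) {
  stopifnot(inherits(d1, "dag"), inherits(d2, "dag"))
  if (!identical(d1$nodes, d2$nodes)) {
    stop("DAGs must share one node set", call. = FALSE)
  }
  mec_signature(d1) == mec_signature(d2)
}

# one string per (skeleton, uncovered colliders); equal <=> Markov equivalent
mec_signature <- function(d) {
  sk <- skeleton(d)
  uc <- uncovered_colliders(d)
  paste(
    paste(paste0(sk[, 1L], "-", sk[, 2L]), collapse = ";"),
    paste(paste0(uc[, 1L], ">", uc[, 2L], "<", uc[, 3L]), collapse = ";"),
    sep = "|"
  )
}
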