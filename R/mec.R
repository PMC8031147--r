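# Equivalence classes: consistent extensions of an essential graph, the
# pattern of a DAG, and explicit (possibly restricted) member sets.
#
# Enumeration is deliberately brute force over the 2^u orientations of the
# u undirected edges: at the scale this package targets (census graphs,
# worked examples) that is exact, fast enough, and doubles as its own
# correctness oracle. A hard limit guards against accidental blow-up.

#' Enumerate the consistent extensions of a partially directed graph
#'
#' A consistent extension orients every undirected edge, keeps the directed
#' edges as they are, creates no directed cycle, and neither creates nor
#' destroys an uncovered collider: the extension's v-structures are exactly
#' those already present among the input's directed edges.
#'
#' @param g A [pdg()].
#' @param max_undirected Refuse inputs with more undirected edges than this
#'   (the search is exponential in that number).
#' @return A list of [dag()] objects in a deterministic (canonical) order;
#'   empty when `g` admits no consistent extension (then `g` is not a valid
#'   essential graph).
#' @examples
#' hub <- pdg(undirected = c("A", "H", "B", "H", "C", "H"))
#' length(consistent_extensions(hub))   # 4
#' @export
consistent_extensions <- function(g, max_undirected = 20L) {
  stopifnot(inherits(g, "pdg"))
  u <- nrow(g$und)
  if (u > max_undirected) {
    err_limit(sprintf("%d undirected edges exceeds the limit of %d", u, max_undirected))
  }
  if (!.acyclic_dir(g$nodes, g$dir)) {
    stop("directed edges of the input already contain a cycle", call. = FALSE)
  }
  adj <- .pair_keys(skeleton(g))
  base_sig <- .collider_sig(.uncovered_colliders_raw(g$nodes, g$dir, adj))
  out <- list()
  for (bits in 0:(2L^u - 1L)) {
    dirm <- g$dir
    if (u) {
      o <- as.integer(intToBits(bits))[seq_len(u)]
      or <- cbind(ifelse(o == 1L, g$und[, 2L], g$und[, 1L]),
                  ifelse(o == 1L, g$und[, 1L], g$und[, 2L]))
      dirm <- rbind(dirm, or)
    }
    if (!.acyclic_dir(g$nodes, dirm)) next
    if (.collider_sig(.uncovered_colliders_raw(g$nodes, dirm, adj)) != base_sig) next
    cand <- structure(list(nodes = g$nodes, dir = .sort_rows(dirm),
                           und = matrix(character(0), ncol = 2L)),
                      class = c("dag", "pdg"))
    out[[length(out) + 1L]] <- cand
  }
  out[order(vapply(out, graph_key, character(1)))]
}

.collider_sig <- function(uc) {
  paste(paste0(uc[, 1L], ">", uc[, 2L], "<", uc[, 3L]), collapse = ";")
}

#' The pattern (complete Markov equivalence class summary) of a DAG
#'
#' Enumerates every orientation of the DAG's skeleton, keeps the acyclic
#' ones Markov equivalent to the input, and summarises: an edge is directed
#' in the pattern iff it is oriented the same way in every equivalent DAG,
#' otherwise undirected.
#'
#' @param d A [dag()].
#' @param max_edges Refuse skeletons with more edges than this.
#' @return A [pdg()]: the pattern (CPDAG) of `d`'s equivalence class.
#' @examples
#' pattern_of(dag(edges = c("H", "A", "H", "B", "H", "C")))  # the undirected hub
#' @export
pattern_of <- function(d, max_edges = 20L) {
  mec_members(d, max_edges)$summary
}

#' The full Markov equivalence class of a DAG
#'
#' @inheritParams pattern_of
#' @return An `mec_class` object: all same-skeleton DAGs Markov equivalent
#'   to `d`, plus the derived summary pattern.
#' @examples
#' mec_members(dag(edges = c("H", "A", "H", "B", "H", "C")))  # 4 members
#' @export
mec_members <- function(d, max_edges = 20L) {
  stopifnot(inherits(d, "dag"))
  sk <- skeleton(d)
  if (nrow(sk) > max_edges) {
    err_limit(sprintf("%d skeleton edges exceeds the limit of %d", nrow(sk), max_edges))
  }
  sig <- mec_signature(d)
  m <- nrow(sk)
  members <- list()
  for (bits in 0:(2L^m - 1L)) {
    if (m) {
      o <- as.integer(intToBits(bits))[seq_len(m)]
      dirm <- cbind(ifelse(o == 1L, sk[, 2L], sk[, 1L]),
                    ifelse(o == 1L, sk[, 1L], sk[, 2L]))
    } else {
      dirm <- matrix(character(0), ncol = 2L)
    }
    if (!.acyclic_dir(d$nodes, dirm)) next
    cand <- structure(list(nodes = d$nodes, dir = .sort_rows(dirm),
                           und = matrix(character(0), ncol = 2L)),
                      class = c("dag", "pdg"))
    if (mec_signature(cand) == sig) members[[length(members) + 1L]] <- cand
  }
  make_class(members)
}

#' Wrap an explicit set of Markov equivalent DAGs as an equivalence class
#'
#' An essential graph need not contain every DAG Markov equivalent to its
#' members — background knowledge may restrict the set. The member list is
#' therefore the source of truth here; the summary graph is always derived
#' from it: an edge is rendered directed iff it has one constant
#' orientation across the members given.
#'
#' @param members Non-empty list of [dag()] objects on one node set, all
#'   pairwise Markov equivalent.
#' @return An `mec_class` object with fields `nodes`, `members` (canonical
#'   order), `summary` (a [pdg()]), and `member_keys`.
#' @examples
#' cl <- mec_members(dag(edges = c("A", "B", "B", "C")))
#' make_class(cl$members[1:2])
#' @export
make_class <- function(members) {
  if (!is.list(members) || length(members) == 0L) {
    stop("members must be a non-empty list of DAGs", call. = FALSE)
  }
  lapply(members, function(d) stopifnot(inherits(d, "dag")))
  sig <- mec_signature(members[[1L]])
  for (i in seq_along(members)) {
    if (!identical(members[[i]]$nodes, members[[1L]]$nodes)) {
      stop("members must share one node set", call. = FALSE)
    }
    if (mec_signature(members[[i]]) != sig) {
      stop(sprintf("members 1 and %d are not Markov equivalent", i), call. = FALSE)
    }
  }
  keys <- vapply(members, graph_key, character(1))
  if (anyDuplicated(keys)) {
    members <- members[!duplicated(keys)]
    keys <- keys[!duplicated(keys)]
  }
  ord <- order(keys)
  members <- members[ord]
  keys <- keys[ord]
  nodes <- members[[1L]]$nodes
  sk <- skeleton(members[[1L]])
  dirm <- matrix(character(0), ncol = 2L)
  undm <- matrix(character(0), ncol = 2L)
  if (nrow(sk)) {
    for (i in seq_len(nrow(sk))) {
      a <- sk[i, 1L]; b <- sk[i, 2L]
      fwd <- vapply(members, function(d) .has_arrow(d, a, b), logical(1))
      if (all(fwd)) {
        dirm <- rbind(dirm, c(a, b))
      } else if (!any(fwd)) {
        dirm <- rbind(dirm, c(b, a))
      } else {
        undm <- rbind(undm, c(a, b))
      }
    }
  }
  summary <- pdg(nodes = nodes, directed = dirm, undirected = undm)
  structure(
    list(nodes = nodes, members = members, summary = summary,
         member_keys = keys,
         key = paste(keys, collapse = "\n")),
    class = "mec_class"
  )
}

.has_arrow <- function(d, a, b) {
  any(d$dir[, 1L] == a & d$dir[, 2L] == b)
}

#' @export
print.mec_class <- function(x, ...) {
  cat(sprintf("<equivalence class> %d member DAG(s) on {%s}\n",
              length(x$members), paste(x$nodes, collapse = ", ")))
  cat("summary ")
  print(x$summary)
  invisible(x)
}

#' Number of member DAGs in an equivalence class
#'
#' @param c An `mec_class`.
#' @return Integer.
#' @export
class_size <- function(c) {
  stopifnot(inherits(c, "mec_class"))
  length(c$members)
}

#' Validate a partially directed graph as an essential graph
#'
#' A PDG is a usable essential graph iff it has at least one consistent
#' extension. The diagnostic also reports whether the input equals the
#' summary of its own extension set, i.e. is maximally informative (no
#' undirected edge that is in fact compelled).
#'
#' @inheritParams consistent_extensions
#' @return A list with `valid`, `n_extensions`, `maximally_informative`,
#'   and `class` (the `mec_class` of the extensions when valid).
#' @export
validate_essential_graph <- function(g, max_undirected = 20L) {
  ext <- consistent_extensions(g, max_undirected)
  if (length(ext) == 0L) {
    return(list(valid = FALSE, n_extensions = 0L,
                maximally_informative = FALSE, class = NULL))
  }
  cl <- make_class(ext)
  list(valid = TRUE, n_extensions = length(ext),
       maximally_informative = pdg_equal(cl$summary, g), class = cl)
}

#' Undirected edges of a class summary
#'
#' @param c An `mec_class`.
#' @return 2-column character matrix (a, b) with `a < b`, rows sorted.
#' @export
undirected_summary_edges <- function(c) {
  stopifnot(inherits(c, "mec_class"))
  c$summary$und
}

# k x u 0/1 matrix: entry [i, e] = 1 iff member i orients summary edge e as
# a -> b (canonical order a < b)
orientation_matrix <- function(c) {
  und <- undirected_summary_edges(c)
  k <- length(c$members)
  u <- nrow(und)
  m <- matrix(0, nrow = k, ncol = u)
  if (u) {
    for (e in seq_len(u)) {
      m[, e] <- vapply(c$members, function(d) as.numeric(.has_arrow(d, und[e, 1L], und[e, 2L])),
                       numeric(1))
    }
    colnames(m) <- paste0(und[, 1L], "->", und[, 2L])
  }
  m
}
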