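# Exhaustive census of small directed graphs / DAGs: Markov-equivalence
# partition, node-permutation pattern types, and the tally of
# orientation-imbalanced undirected edges under a uniform distribution over
# each class.

.check_census_limits <- function(n, m, max_nodes = 7L) {
  n <- as.integer(n); m <- as.integer(m)
  if (n < 1L || n > max_nodes) {
    err_limit(sprintf("node count %d outside the supported range 1..%d", n, max_nodes))
  }
  np <- (n * (n - 1L)) %/% 2L
  if (m < 0L || m > np) {
    err_limit(sprintf("edge count %d infeasible for %d nodes", m, n))
  }
  list(n = n, m = m)
}

#' Enumerate all directed graphs with given node and edge counts
#'
#' Every way to choose `m` unordered pairs from `n` labelled nodes
#' (`A`, `B`, ...) and orient each chosen pair either way — cyclic graphs
#' included. The count is `choose(n*(n-1)/2, m) * 2^m`.
#'
#' @param n Number of nodes (at most `max_nodes`).
#' @param m Number of edges.
#' @param max_nodes Enumeration guard (default 7).
#' @return List of fully directed [pdg()] objects (not necessarily
#'   acyclic).
#' @export
enumerate_directed_graphs <- function(n, m, max_nodes = 7L) {
  lim <- .check_census_limits(n, m, max_nodes)
  n <- lim$n; m <- lim$m
  nodes <- LETTERS[seq_len(n)]
  if (m == 0L) return(list(pdg(nodes = nodes)))
  pairs <- t(utils::combn(nodes, 2L))
  skels <- utils::combn(nrow(pairs), m)
  out <- vector("list", ncol(skels) * 2L^m)
  idx <- 0L
  for (s in seq_len(ncol(skels))) {
    chosen <- pairs[skels[, s], , drop = FALSE]
    for (bits in 0:(2L^m - 1L)) {
      o <- as.integer(intToBits(bits))[seq_len(m)]
      dirm <- cbind(ifelse(o == 1L, chosen[, 2L], chosen[, 1L]),
                    ifelse(o == 1L, chosen[, 1L], chosen[, 2L]))
      idx <- idx + 1L
      out[[idx]] <- pdg(nodes = nodes, directed = dirm)
    }
  }
  out
}

#' Enumerate all DAGs with given node and edge counts
#'
#' The acyclic subset of [enumerate_directed_graphs()].
#'
#' @inheritParams enumerate_directed_graphs
#' @return List of [dag()] objects.
#' @examples
#' length(enumerate_dags(4, 3))   # 152
#' @export
enumerate_dags <- function(n, m, max_nodes = 7L) {
  gs <- enumerate_directed_graphs(n, m, max_nodes)
  lapply(Filter(is_acyclic, gs), as_dag)
}

#' Partition DAGs into Markov equivalence classes
#'
#' @param dags List of [dag()] objects on one node set.
#' @return List of `mec_class` objects; disjoint, covering the input,
#'   within-class pairs Markov equivalent.
#' @export
partition_by_equivalence <- function(dags) {
  if (!length(dags)) return(list())
  lapply(dags, function(d) stopifnot(inherits(d, "dag")))
  nodes <- dags[[1L]]$nodes
  for (d in dags) {
    if (!identical(d$nodes, nodes)) stop("DAGs must share one node set", call. = FALSE)
  }
  sigs <- vapply(dags, mec_signature, character(1))
  groups <- split(dags, sigs)
  out <- lapply(groups, make_class)
  names(out) <- NULL
  out[order(vapply(out, function(cl) graph_key(cl$summary), character(1)))]
}

# canonical encoding of a pdg under node relabeling: minimum over all
# permutations of the node set of the graph's key with labels replaced by
# positional codes
.canonical_type_key <- function(g, max_nodes = 7L) {
  n <- length(g$nodes)
  if (n > max_nodes) err_limit(sprintf("%d nodes exceeds the permutation limit %d", n, max_nodes))
  perms <- .permutations(n)
  codes <- sprintf("n%02d", seq_len(n))
  best <- NULL
  for (r in seq_len(nrow(perms))) {
    map <- stats::setNames(codes[perms[r, ]], g$nodes)
    dirm <- g$dir; undm <- g$und
    if (nrow(dirm)) dirm <- cbind(unname(map[dirm[, 1L]]), unname(map[dirm[, 2L]]))
    if (nrow(undm)) {
      undm <- cbind(unname(map[undm[, 1L]]), unname(map[undm[, 2L]]))
      undm <- cbind(pmin(undm[, 1L], undm[, 2L]), pmax(undm[, 1L], undm[, 2L]))
    }
    key <- paste(
      paste(sort(paste0(dirm[, 1L], ">", dirm[, 2L])), collapse = ";"),
      paste(sort(paste0(undm[, 1L], "-", undm[, 2L])), collapse = ";"),
      sep = "|"
    )
    if (is.null(best) || key < best) best <- key
  }
  best
}

.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  r <- 0L
  for (i in seq_len(n)) {
    for (s in seq_len(nrow(sub))) {
      r <- r + 1L
      rest <- seq_len(n)[-i]
      out[r, ] <- c(i, rest[sub[s, ]])
    }
  }
  out
}

#' Group equivalence classes into node-permutation types
#'
#' Two classes have the same type when their summary graphs are identical
#' up to a relabeling of the nodes. Canonicalisation is by brute-force
#' minimisation over all `n!` relabelings — exact, and cheap at the node
#' counts this package enumerates.
#'
#' @param classes List of `mec_class` objects from one enumeration.
#' @param max_nodes Permutation guard (default 7).
#' @return List of types, each a list with `representative` (a summary
#'   [pdg()]), `dag_count` (total member DAGs of that type), `n_classes`,
#'   and `classes`.
#' @export
type_classes <- function(classes, max_nodes = 7L) {
  if (!length(classes)) return(list())
  keys <- vapply(classes, function(cl) .canonical_type_key(cl$summary, max_nodes),
                 character(1))
  groups <- split(classes, keys)
  out <- lapply(groups, function(cls) {
    list(representative = cls[[1L]]$summary,
         dag_count = sum(vapply(cls, class_size, integer(1))),
         n_classes = length(cls),
         classes = cls)
  })
  names(out) <- NULL
  out[order(vapply(out, function(t) -t$dag_count, numeric(1)),
            vapply(out, function(t) graph_key(t$representative), character(1)))]
}

#' Census of orientation-imbalanced undirected edges
#'
#' Enumerates every DAG with `n` nodes and `m` edges, partitions them into
#' Markov equivalence classes, and — under a uniform distribution over each
#' class — tallies, once per DAG per undirected edge of its pattern, the
#' larger of the two orientation probabilities of that edge. An edge
#' instance is "imbalanced" when that maximum exceeds one half. Counting
#' instances per DAG (class size times number of undirected summary edges)
#' rather than per pattern is what makes the tally reproduce the printed
#' headline arithmetic for 4 nodes and 3 edges.
#'
#' @inheritParams enumerate_directed_graphs
#' @return A `census_result`: counts of directed graphs, skeletons, cyclic
#'   graphs and DAGs; the equivalence classes and their permutation types;
#'   `edge_tally` (named numeric: maximum orientation probability, rounded
#'   to 6 decimals, to instance count); `n_instances`;
#'   `imbalanced_fraction`; and `imbalanced_percent` (rounded to the
#'   nearest integer).
#' @examples
#' cr <- imbalance_census(4, 3)
#' cr$imbalanced_percent   # 46
#' @export
imbalance_census <- function(n, m, max_nodes = 7L) {
  lim <- .check_census_limits(n, m, max_nodes)
  n <- lim$n; m <- lim$m
  digraphs <- enumerate_directed_graphs(n, m, max_nodes)
  acyclic <- vapply(digraphs, is_acyclic, logical(1))
  dags <- lapply(digraphs[acyclic], as_dag)
  classes <- partition_by_equivalence(dags)
  types <- if (length(classes)) type_classes(classes, max_nodes) else list()
  tally <- numeric(0)
  n_instances <- 0L
  n_imbalanced <- 0L
  for (cl in classes) {
    und <- undirected_summary_edges(cl)
    if (nrow(und) == 0L) next
    p <- uniform_distribution(cl)
    for (e in seq_len(nrow(und))) {
      pf <- orientation_probability(p, und[e, 1L], und[e, 2L])
      pmaxv <- max(pf, 1 - pf)
      bucket <- sprintf("%.6f", round(pmaxv, 6L))
      inst <- class_size(cl)               # one instance per member DAG
      tally[bucket] <- (if (bucket %in% names(tally)) tally[[bucket]] else 0L) + inst
      n_instances <- n_instances + inst
      if (pmaxv > 0.5 + 1e-9) n_imbalanced <- n_imbalanced + inst
    }
  }
  frac <- if (n_instances > 0L) n_imbalanced / n_instances else 0
  structure(
    list(n_nodes = n, n_edges = m,
         n_digraphs = length(digraphs),
         n_skeletons = choose(n * (n - 1L) / 2L, m),
         n_dags = length(dags),
         n_cyclic = length(digraphs) - length(dags),
         classes = classes,
         types = types,
         edge_tally = tally[order(names(tally))],
         n_instances = n_instances,
         imbalanced_fraction = frac,
         imbalanced_percent = round(100 * frac)),
    class = "census_result"
  )
}

#' @export
print.census_result <- function(x, ...) {
  cat(sprintf("census of %d-node, %d-edge graphs\n", x$n_nodes, x$n_edges))
  cat(sprintf("  %d directed graphs over %d skeletons: %d DAGs, %d cyclic\n",
              x$n_digraphs, x$n_skeletons, x$n_dags, x$n_cyclic))
  cat(sprintf("  %d equivalence classes in %d permutation types\n",
              length(x$classes), length(x$types)))
  if (length(x$edge_tally)) {
    cat("  undirected-edge instances by max orientation probability:\n")
    for (b in names(x$edge_tally)) {
      cat(sprintf("    %s : %d\n", b, as.integer(x$edge_tally[[b]])))
    }
    cat(sprintf("  imbalanced fraction: %.4f (%d%%)\n",
                x$imbalanced_fraction, x$imbalanced_percent))
  } else {
    cat("  no undirected-edge instances\n")
  }
  invisible(x)
}

#' Write a census report as CSV
#'
#' One row per permutation type (canonical representative edge list, DAG
#' count, instance counts per probability bucket) plus a `TOTAL` summary
#' row.
#'
#' @param x A `census_result`.
#' @param file Path or connection.
#' @return The data frame written, invisibly.
#' @export
write_census_csv <- function(x, file) {
  stopifnot(inherits(x, "census_result"))
  buckets <- names(x$edge_tally)
  rows <- lapply(x$types, function(t) {
    tt <- numeric(length(buckets))
    names(tt) <- buckets
    for (cl in t$classes) {
      und <- undirected_summary_edges(cl)
      if (nrow(und) == 0L) next
      p <- uniform_distribution(cl)
      for (e in seq_len(nrow(und))) {
        pf <- orientation_probability(p, und[e, 1L], und[e, 2L])
        b <- sprintf("%.6f", round(max(pf, 1 - pf), 6L))
        tt[[b]] <- tt[[b]] + class_size(cl)
      }
    }
    c(list(pattern = .edge_list_string(t$representative),
           dag_count = t$dag_count, n_classes = t$n_classes),
      as.list(tt))
  })
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, check.names = FALSE)))
  total <- as.data.frame(c(list(pattern = "TOTAL", dag_count = x$n_dags,
                                n_classes = length(x$classes)),
                           as.list(x$edge_tally)), check.names = FALSE)
  if (length(buckets)) names(total)[-(1:3)] <- buckets
  df <- rbind(df, total)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(df)
}

.edge_list_string <- function(g) {
  paste(c(paste(g$dir[, 1L], "->", g$dir[, 2L]),
          paste(g$und[, 1L], "--", g$und[, 2L])),
        collapse = "; ")
}
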