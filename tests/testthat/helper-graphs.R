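# Shared fixtures and independent oracles used across test files.

# the four members of the hub class, written out by hand from the worked
# example: H never has more than one incoming arrow
hub_member_dags <- function() {
  list(
    dag(edges = c("H", "A", "H", "B", "H", "C")),
    dag(edges = c("A", "H", "H", "B", "H", "C")),
    dag(edges = c("B", "H", "H", "A", "H", "C")),
    dag(edges = c("C", "H", "H", "A", "H", "B"))
  )
}

# every DAG on n labelled nodes, all edge counts pooled
all_dags_on <- function(n) {
  unlist(lapply(0:choose(n, 2), function(m) enumerate_dags(n, m)), recursive = FALSE)
}

# full d-separation profile of a DAG as one string: every unordered node
# pair, every conditioning subset of the remaining nodes
dsep_profile <- function(d, method = "reachability") {
  nodes <- d$nodes
  ans <- character(0)
  for (i in seq_len(length(nodes) - 1L)) {
    for (j in seq((i + 1L), length(nodes))) {
      rest <- setdiff(nodes, c(nodes[[i]], nodes[[j]]))
      subsets <- c(list(character(0)),
                   unlist(lapply(seq_along(rest), function(k) {
                     asplit(utils::combn(rest, k), 2)
                   }), recursive = FALSE))
      for (cond in subsets) {
        ans <- c(ans, sprintf("%s,%s|%s=%d", nodes[[i]], nodes[[j]],
                              paste(sort(as.character(cond)), collapse = ","),
                              d_separated(d, nodes[[i]], nodes[[j]],
                                          as.character(cond), method = method)))
      }
    }
  }
  paste(ans, collapse = ";")
}

# random partially directed graph: take a random DAG and forget the
# orientation of a random subset of its edges
random_pdg <- function(n, m, seed) {
  d <- random_dag(n, m, seed)
  k <- nrow(d$dir)
  set.seed(seed + 1L)
  undirect <- sample(c(TRUE, FALSE), k, replace = TRUE)
  pdg(nodes = d$nodes,
      directed = d$dir[!undirect, , drop = FALSE],
      undirected = d$dir[undirect, , drop = FALSE])
}

# Dirichlet-ish strictly positive distribution over class members
random_distribution <- function(cl) {
  w <- stats::rexp(class_size(cl)) + 1e-6
  dag_distribution(cl, w / sum(w))
}
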