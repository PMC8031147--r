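# Plain-text I/O, worked-example fixtures, and random DAG generation.
#
# Graph dialect, one edge per line:
#   A -> B     directed
#   A -- B     undirected
#   node X     isolated node
#   # comment  (also allowed after an edge); blank lines ignored

#' Parse a graph from the plain edge-list dialect
#'
#' @param text Either a character vector of lines, a single string with
#'   embedded newlines, or (when `is_file = TRUE`) a path.
#' @param is_file Read `text` as a file path.
#' @return A [pdg()].
#' @examples
#' parse_graph("A -- H\nB -- H\nC -- H")
#' @export
parse_graph <- function(text, is_file = FALSE) {
  lines <- if (is_file) readLines(text, warn = FALSE) else unlist(strsplit(text, "\n", fixed = TRUE))
  if (length(text) > 1L && !is_file) lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  nodes <- character(0)
  dirm <- matrix(character(0), ncol = 2L)
  undm <- matrix(character(0), ncol = 2L)
  for (i in seq_along(lines)) {
    line <- sub("#.*$", "", lines[[i]])
    line <- trimws(line)
    if (line == "") next
    if (grepl("^node\\s+\\S+$", line)) {
      nodes <- c(nodes, sub("^node\\s+", "", line))
      next
    }
    m <- regmatches(line, regexec("^(\\S+)\\s*(->|--)\\s*(\\S+)$", line))[[1L]]
    if (length(m) != 4L) {
      err_parse(sprintf("line %d: cannot parse '%s'", i, lines[[i]]))
    }
    if (!grepl(.label_re, m[[2L]]) || !grepl(.label_re, m[[4L]])) {
      err_parse(sprintf("line %d: invalid node label", i))
    }
    if (m[[2L]] == m[[4L]]) err_parse(sprintf("line %d: self-loop", i))
    key_new <- paste(min(m[[2L]], m[[4L]]), max(m[[2L]], m[[4L]]), sep = "\r")
    if (key_new %in% c(.pair_keys(dirm), .pair_keys(undm))) {
      err_parse(sprintf("line %d: duplicate edge for pair %s, %s", i, m[[2L]], m[[4L]]))
    }
    if (m[[3L]] == "->") dirm <- rbind(dirm, c(m[[2L]], m[[4L]]))
    else undm <- rbind(undm, c(m[[2L]], m[[4L]]))
  }
  tryCatch(
    pdg(nodes = nodes, directed = dirm, undirected = undm),
    error = function(e) err_parse(conditionMessage(e))
  )
}

#' Write a graph in the plain edge-list dialect
#'
#' Deterministic: isolated nodes first, then directed edges, then
#' undirected edges, each block lexicographically sorted, so
#' `parse_graph(write_graph(g))` reproduces `g` exactly.
#'
#' @param g A [pdg()].
#' @param file Optional path; when given the text is also written there.
#' @return The text, as a single string, invisibly when `file` is given.
#' @export
write_graph <- function(g, file = NULL) {
  stopifnot(inherits(g, "pdg"))
  connected <- unique(c(as.vector(g$dir), as.vector(g$und)))
  isolated <- setdiff(g$nodes, connected)
  lines <- c(
    if (length(isolated)) paste("node", sort(isolated)),
    if (nrow(g$dir)) paste(g$dir[, 1L], "->", g$dir[, 2L]),
    if (nrow(g$und)) paste(g$und[, 1L], "--", g$und[, 2L])
  )
  txt <- paste0(paste(lines, collapse = "\n"), if (length(lines)) "\n" else "")
  if (!is.null(file)) {
    writeLines(sub("\n$", "", txt), file)
    return(invisible(txt))
  }
  txt
}

#' Export a graph as DOT
#'
#' Directed edges become arrows; undirected edges are emitted as
#' `a -> b [dir=none]` so any DOT renderer draws them without arrowheads.
#'
#' @param g A [pdg()].
#' @return A single DOT string.
#' @export
export_dot <- function(g) {
  stopifnot(inherits(g, "pdg"))
  body <- c(
    paste0("  ", g$nodes, ";"),
    if (nrow(g$dir)) paste0("  ", g$dir[, 1L], " -> ", g$dir[, 2L], ";"),
    if (nrow(g$und)) paste0("  ", g$und[, 1L], " -> ", g$und[, 2L], " [dir=none];")
  )
  paste0("digraph {\n", paste(body, collapse = "\n"), "\n}\n")
}

#' Read edge beliefs from CSV
#'
#' Columns `from,to,prob`; either ordering of an edge may be omitted and is
#' filled with the complement.
#'
#' @param c An `mec_class` the beliefs refer to.
#' @param file Path or connection.
#' @return An [edge_beliefs()] object.
#' @export
read_beliefs_csv <- function(c, file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("from", "to", "prob")
  if (!all(need %in% names(df))) err_parse("beliefs CSV needs columns from,to,prob")
  edge_beliefs(c, df$from, df$to, df$prob)
}

#' Write edge beliefs as CSV
#'
#' @param beliefs An [edge_beliefs()] object.
#' @param file Path or connection.
#' @export
write_beliefs_csv <- function(beliefs, file) {
  stopifnot(inherits(beliefs, "edge_beliefs"))
  utils::write.csv(beliefs$table, file, row.names = FALSE)
  invisible(beliefs$table)
}

#' Read a bet package from CSV
#'
#' Columns `from,to,win,lose`; one row per bet.
#'
#' @param c An `mec_class` the bets refer to.
#' @param file Path or connection.
#' @return A [ceob()].
#' @export
read_bets_csv <- function(c, file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("from", "to", "win", "lose")
  if (!all(need %in% names(df))) err_parse("bets CSV needs columns from,to,win,lose")
  if (nrow(df) == 0L) err_parse("bets CSV is empty")
  ceob(lapply(seq_len(nrow(df)), function(i) {
    eob(c, df$from[[i]], df$to[[i]], df$win[[i]], df$lose[[i]])
  }))
}

#' Worked-example fixtures
#'
#' Small named objects used throughout the documentation and tests:
#' \describe{
#'   \item{`hub_graph`}{the essential graph with undirected edges A--H,
#'     B--H, C--H (H an undirected hub).}
#'   \item{`hub_class`}{its equivalence class (4 member DAGs).}
#'   \item{`hub_members`}{the member list of `hub_class`.}
#'   \item{`steve_package`}{the three-bet package on the hub: each bet wins
#'     $6 on an into-H guess being right (A->H, B->H, C->H) and loses $4
#'     otherwise.}
#'   \item{`chain4`}{the undirected 4-node chain A--B--C--D.}
#'   \item{`triangle4`}{the undirected triangle A--B--C plus isolated D.}
#'   \item{`two_node`}{the single undirected edge A--B.}
#' }
#'
#' @param name One of the names above.
#' @return The corresponding object.
#' @export
fixture <- function(name) {
  hub <- pdg(undirected = c("A", "H", "B", "H", "C", "H"))
  switch(name,
    hub_graph = hub,
    hub_class = make_class(consistent_extensions(hub)),
    hub_members = consistent_extensions(hub),
    steve_package = {
      cl <- make_class(consistent_extensions(hub))
      ceob(eob(cl, "A", "H", 6, -4),
           eob(cl, "B", "H", 6, -4),
           eob(cl, "C", "H", 6, -4))
    },
    chain4 = pdg(undirected = c("A", "B", "B", "C", "C", "D")),
    triangle4 = pdg(nodes = "D", undirected = c("A", "B", "A", "C", "B", "C")),
    two_node = pdg(undirected = c("A", "B")),
    stop(sprintf("unknown fixture '%s'", name), call. = FALSE)
  )
}

# run code under a local, seeded RNG stream without disturbing the caller's
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Draw a uniformly random DAG with given node and edge counts
#'
#' Rejection sampling: a skeleton of `m` pairs and an orientation are drawn
#' uniformly and redrawn until acyclic, which is uniform over the DAGs the
#' census enumerates. Deterministic for a fixed seed; the caller's RNG
#' state is left untouched.
#'
#' @param n,m Node and edge counts, `m <= n*(n-1)/2`.
#' @param seed Integer seed.
#' @return A [dag()] on nodes `A`, `B`, ...
#' @export
random_dag <- function(n, m, seed) {
  n <- as.integer(n); m <- as.integer(m)
  np <- (n * (n - 1L)) %/% 2L
  if (n < 1L || n > 26L || m < 0L || m > np) {
    stop("infeasible node/edge counts", call. = FALSE)
  }
  nodes <- LETTERS[seq_len(n)]
  pairs <- if (np) t(utils::combn(nodes, 2L)) else matrix(character(0), ncol = 2L)
  .with_seed(seed, {
    repeat {
      chosen <- pairs[sample.int(nrow(pairs), m), , drop = FALSE]
      flip <- stats::runif(m) < 0.5
      dirm <- cbind(ifelse(flip, chosen[, 2L], chosen[, 1L]),
                    ifelse(flip, chosen[, 1L], chosen[, 2L]))
      g <- pdg(nodes = nodes, directed = dirm)
      if (is_acyclic(g)) return(as_dag(g))
    }
  })
}
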