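# Credences: distributions over class members, induced edge-orientation
# probabilities, and linear-programming coherence checks of per-edge
# orientation beliefs.

# boot::simplex can hit a degenerate-pivot NaN on problems with many
# zero right-hand sides; retry with a tiny, purely relaxing jitter of the
# inequality bounds (<= rows up, >= rows down), which perturbs the optimum
# by at most the jitter itself
.safe_simplex <- function(a, A1 = NULL, b1 = NULL, A2 = NULL, b2 = NULL,
                          A3 = NULL, b3 = NULL, maxi = FALSE) {
  for (jit in c(0, 1e-9, 1e-7)) {
    sol <- tryCatch(
      boot::simplex(a = a,
                    A1 = A1, b1 = if (!is.null(b1)) b1 + jit else NULL,
                    A2 = A2, b2 = if (!is.null(b2)) b2 - jit else NULL,
                    A3 = A3, b3 = b3, maxi = maxi),
      error = function(e) NULL
    )
    if (!is.null(sol) && sol$solved == 1) return(sol)
  }
  sol
}

#' Orientation indicator
#'
#' 1 iff the directed edge a -> b is present in the DAG, else 0 — including
#' when no edge joins a and b at all.
#'
#' @param a,b Node labels in `d`.
#' @param d A [dag()].
#' @return 0 or 1.
#' @export
orientation_indicator <- function(a, b, d) {
  stopifnot(inherits(d, "dag"))
  if (!all(c(a, b) %in% d$nodes)) stop("unknown node", call. = FALSE)
  as.numeric(.has_arrow(d, a, b))
}

#' Probability distribution over the members of an equivalence class
#'
#' @param c An `mec_class`.
#' @param prob Numeric vector, one probability per member in the class's
#'   canonical member order; must be nonnegative and sum to 1 (tolerance
#'   1e-9). Members with probability exactly 0 are allowed but make the
#'   distribution non-strict; the Dutch-book immunity guarantee of the
#'   expected-value accept rule is stated for strictly positive
#'   distributions, so strictness is tracked and surfaced.
#' @return A `dag_distribution` object.
#' @seealso [uniform_distribution()], [orientation_table()]
#' @export
dag_distribution <- function(c, prob) {
  stopifnot(inherits(c, "mec_class"))
  prob <- as.numeric(prob)
  k <- length(c$members)
  if (length(prob) != k) {
    stop(sprintf("need %d probabilities, got %d", k, length(prob)), call. = FALSE)
  }
  if (any(prob < 0)) stop("probabilities must be nonnegative", call. = FALSE)
  if (abs(sum(prob) - 1) > 1e-9) stop("probabilities must sum to 1", call. = FALSE)
  structure(list(class = c, prob = prob, strictly_positive = all(prob > 0)),
            class = "dag_distribution")
}

#' Uniform distribution over class members
#'
#' @param c An `mec_class`.
#' @return A `dag_distribution` giving each member probability
#'   `1/class_size(c)`.
#' @export
uniform_distribution <- function(c) {
  stopifnot(inherits(c, "mec_class"))
  k <- length(c$members)
  dag_distribution(c, rep(1 / k, k))
}

#' @export
print.dag_distribution <- function(x, ...) {
  cat(sprintf("<distribution over %d member DAG(s)>%s\n", length(x$prob),
              if (x$strictly_positive) "" else " (not strictly positive)"))
  print(stats::setNames(x$prob, paste0("D", seq_along(x$prob))))
  invisible(x)
}

#' Orientation probability induced by a distribution over members
#'
#' The probability that the revealed DAG contains a -> b: the sum over
#' members of the member's probability times the orientation indicator.
#'
#' @param p A [dag_distribution()].
#' @param a,b Node labels, adjacent in the class skeleton.
#' @return A number in `[0, 1]`.
#' @examples
#' hub <- make_class(consistent_extensions(
#'   pdg(undirected = c("A", "H", "B", "H", "C", "H"))))
#' orientation_probability(uniform_distribution(hub), "A", "H")  # 0.25
#' @export
orientation_probability <- function(p, a, b) {
  stopifnot(inherits(p, "dag_distribution"))
  sk <- .pair_keys(skeleton(p$class$summary))
  if (!(paste(min(a, b), max(a, b), sep = "\r") %in% sk)) {
    stop(sprintf("'%s' and '%s' are not adjacent in the class skeleton", a, b),
         call. = FALSE)
  }
  ind <- vapply(p$class$members, function(d) .has_arrow(d, a, b), logical(1))
  sum(p$prob[ind])
}

#' Per-edge orientation beliefs
#'
#' A belief table assigns a probability to each ordered version of every
#' undirected edge of a class summary; the two orderings of one edge must
#' sum to 1. Beliefs about edges directed in the summary are rejected: bets
#' (and hence coherence questions) concern undirected edges only.
#'
#' @param c An `mec_class`.
#' @param from,to Character vectors (recycled together) naming ordered
#'   pairs.
#' @param prob Probability that `from -> to` is in the revealed DAG. Any
#'   ordering missing from the input is filled with the complement of its
#'   reverse.
#' @return An `edge_beliefs` object whose `$table` covers both orderings of
#'   every undirected summary edge.
#' @export
edge_beliefs <- function(c, from, to, prob) {
  stopifnot(inherits(c, "mec_class"))
  from <- as.character(from); to <- as.character(to); prob <- as.numeric(prob)
  stopifnot(length(from) == length(to), length(to) == length(prob))
  und <- undirected_summary_edges(c)
  und_keys <- .pair_keys(und)
  got_keys <- paste(pmin(from, to), pmax(from, to), sep = "\r")
  bad <- !(got_keys %in% und_keys)
  if (any(bad)) {
    stop(sprintf("pair (%s, %s) is not an undirected edge of the class summary",
                 from[bad][1L], to[bad][1L]), call. = FALSE)
  }
  if (any(prob < -1e-12 | prob > 1 + 1e-12)) {
    stop("beliefs must lie in [0, 1]", call. = FALSE)
  }
  lookup <- stats::setNames(prob, paste(from, to, sep = "\r"))
  if (anyDuplicated(names(lookup))) stop("duplicate belief rows", call. = FALSE)
  tab_from <- character(0); tab_to <- character(0); tab_p <- numeric(0)
  for (e in seq_len(nrow(und))) {
    a <- und[e, 1L]; b <- und[e, 2L]
    kf <- paste(a, b, sep = "\r"); kb <- paste(b, a, sep = "\r")
    has_f <- kf %in% names(lookup); has_b <- kb %in% names(lookup)
    if (!has_f && !has_b) {
      stop(sprintf("no belief given for undirected edge %s -- %s", a, b), call. = FALSE)
    }
    pf <- if (has_f) lookup[[kf]] else 1 - lookup[[kb]]
    pb <- if (has_b) lookup[[kb]] else 1 - pf
    if (abs(pf + pb - 1) > 1e-9) {
      stop(sprintf("beliefs for %s/%s must sum to 1", a, b), call. = FALSE)
    }
    tab_from <- c(tab_from, a, b); tab_to <- c(tab_to, b, a)
    tab_p <- c(tab_p, pf, pb)
  }
  structure(list(class = c,
                 table = data.frame(from = tab_from, to = tab_to, prob = tab_p,
                                    stringsAsFactors = FALSE)),
            class = "edge_beliefs")
}

#' @export
print.edge_beliefs <- function(x, ...) {
  cat(sprintf("<edge beliefs> %d ordered pair(s)\n", nrow(x$table)))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Look up one belief
#'
#' @param beliefs An [edge_beliefs()] object.
#' @param a,b Ordered node pair.
#' @return The believed probability of a -> b.
#' @export
belief_of <- function(beliefs, a, b) {
  stopifnot(inherits(beliefs, "edge_beliefs"))
  hit <- beliefs$table$from == a & beliefs$table$to == b
  if (!any(hit)) stop(sprintf("no belief recorded for %s -> %s", a, b), call. = FALSE)
  beliefs$table$prob[hit][1L]
}

#' Induced belief table of a distribution
#'
#' Batch version of [orientation_probability()] over both orderings of
#' every undirected summary edge. By construction the result is coherent.
#'
#' @param p A [dag_distribution()].
#' @return An [edge_beliefs()] object (empty table when the summary has no
#'   undirected edges).
#' @export
orientation_table <- function(p) {
  stopifnot(inherits(p, "dag_distribution"))
  c <- p$class
  und <- undirected_summary_edges(c)
  if (nrow(und) == 0L) {
    return(structure(list(class = c,
                          table = data.frame(from = character(0), to = character(0),
                                             prob = numeric(0), stringsAsFactors = FALSE)),
                     class = "edge_beliefs"))
  }
  pf <- vapply(seq_len(nrow(und)),
               function(e) orientation_probability(p, und[e, 1L], und[e, 2L]),
               numeric(1))
  edge_beliefs(c, und[, 1L], und[, 2L], pf)
}

#' Coherence of edge beliefs with some distribution over members
#'
#' Beliefs are coherent when some probability distribution over the class
#' members induces them, i.e. when the belief vector lies in the convex
#' hull of the members' orientation-indicator vectors. The test is a linear
#' program: minimise the largest absolute mismatch `t` over distributions
#' `p >= 0, sum(p) = 1`; the beliefs are feasible iff the optimum satisfies
#' `t <= tol`. Exact equality is deliberately relaxed to `tol` because
#' user-supplied floating-point beliefs rarely satisfy rational equalities
#' exactly.
#'
#' @param c An `mec_class`.
#' @param beliefs An [edge_beliefs()] object on `c`'s undirected summary
#'   edges.
#' @param tol Positive feasibility tolerance (default `1e-8`).
#' @return A `coherence_result`: list with `feasible` (logical), `witness`
#'   (a [dag_distribution()] reproducing the beliefs within `tol`, or
#'   `NULL`), and `max_violation` (the LP optimum; 0 means exactly
#'   representable).
#' @examples
#' hub <- make_class(consistent_extensions(
#'   pdg(undirected = c("A", "H", "B", "H", "C", "H"))))
#' und <- undirected_summary_edges(hub)
#' even <- edge_beliefs(hub, und[, 1], und[, 2], rep(0.5, 3))
#' coherence_check(hub, even)$feasible   # FALSE: no distribution gives 50/50/50
#' @export
coherence_check <- function(c, beliefs, tol = 1e-8) {
  stopifnot(inherits(c, "mec_class"), inherits(beliefs, "edge_beliefs"))
  if (!is.numeric(tol) || tol <= 0) stop("tolerance must be positive", call. = FALSE)
  if (!identical(beliefs$class$key, c$key)) {
    stop("beliefs refer to a different equivalence class", call. = FALSE)
  }
  und <- undirected_summary_edges(c)
  k <- length(c$members)
  u <- nrow(und)
  if (u == 0L) {
    wit <- uniform_distribution(c)
    return(structure(list(feasible = TRUE, witness = wit, max_violation = 0),
                     class = "coherence_result"))
  }
  ind <- orientation_matrix(c)                  # k x u
  q <- vapply(seq_len(u), function(e) belief_of(beliefs, und[e, 1L], und[e, 2L]),
              numeric(1))
  # vars x = (p_1..p_k, t); min t  s.t.  sum p = 1,  |ind' p - q| <= t
  a <- c(rep(0, k), 1)
  A1 <- cbind(t(ind), -1)                       # ind' p - t <= q
  A2 <- cbind(t(ind), 1)                        # ind' p + t >= q
  A3 <- matrix(c(rep(1, k), 0), nrow = 1L)
  sol <- .safe_simplex(a = a, A1 = A1, b1 = q, A2 = A2, b2 = q,
                       A3 = A3, b3 = 1, maxi = FALSE)
  if (is.null(sol)) stop("coherence LP failed to solve", call. = FALSE)
  viol <- unname(sol$value)
  feasible <- sol$solved == 1 && viol <= tol
  witness <- NULL
  if (feasible) {
    p <- pmax(sol$soln[seq_len(k)], 0)
    p <- p / sum(p)
    witness <- dag_distribution(c, p)
  }
  structure(list(feasible = feasible, witness = witness,
                 max_violation = max(viol, 0)),
            class = "coherence_result")
}

#' @export
print.coherence_result <- function(x, ...) {
  if (x$feasible) {
    cat(sprintf("coherent (max violation %.3g)\n", x$max_violation))
  } else {
    cat(sprintf("INCOHERENT: best achievable max violation %.3g\n", x$max_violation))
  }
  invisible(x)
}
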