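# Edge-orientation bets: payoff calculus, expected values under naive
# per-edge beliefs and under distributions over members, Dutch-book
# detection, the nonnegative-expected-value accept rule, and LP
# construction of Dutch books against incoherent beliefs.

.money_eps <- 1e-9

#' An edge orientation bet (EOB)
#'
#' A wager on the orientation of one undirected edge of an essential graph:
#' when the member DAG is revealed, the bettor's wealth changes by `win` if
#' it contains `from -> to` and by `lose` if it contains `to -> from`.
#' Either amount may have either sign.
#'
#' @param c An `mec_class`.
#' @param from,to Endpoints of an undirected edge of the class summary.
#' @param win,lose Finite money amounts.
#' @return An `eob` object.
#' @export
eob <- function(c, from, to, win, lose) {
  stopifnot(inherits(c, "mec_class"))
  und_keys <- .pair_keys(undirected_summary_edges(c))
  if (!(paste(min(from, to), max(from, to), sep = "\r") %in% und_keys)) {
    stop(sprintf("(%s, %s) is not an undirected edge of the class summary", from, to),
         call. = FALSE)
  }
  if (!is.finite(win) || !is.finite(lose)) stop("stakes must be finite", call. = FALSE)
  structure(list(class = c, from = from, to = to,
                 win = as.numeric(win), lose = as.numeric(lose)),
            class = "eob")
}

#' @export
print.eob <- function(x, ...) {
  cat(sprintf("<bet> %+g if %s -> %s, %+g if %s -> %s\n",
              x$win, x$from, x$to, x$lose, x$to, x$from))
  invisible(x)
}

#' A collection of edge orientation bets (CEOB)
#'
#' A non-empty set of [eob()]s on one and the same essential graph, settled
#' together by a single revealed member DAG. Several bets on the same edge
#' are allowed.
#'
#' @param ... [eob()] objects, or a single list of them.
#' @return A `ceob` object.
#' @export
ceob <- function(...) {
  bets <- list(...)
  if (length(bets) == 1L && is.list(bets[[1L]]) && !inherits(bets[[1L]], "eob")) {
    bets <- bets[[1L]]
  }
  if (length(bets) == 0L) stop("a CEOB must contain at least one bet", call. = FALSE)
  lapply(bets, function(b) stopifnot(inherits(b, "eob")))
  key <- bets[[1L]]$class$key
  for (b in bets) {
    if (!identical(b$class$key, key)) {
      stop("all bets in a CEOB must refer to one equivalence class", call. = FALSE)
    }
  }
  structure(list(bets = bets, class_ref = bets[[1L]]$class), class = "ceob")
}

#' @export
print.ceob <- function(x, ...) {
  cat(sprintf("<bet package> %d bet(s)\n", length(x$bets)))
  for (b in x$bets) print(b)
  invisible(x)
}

#' Payoff of one bet under one revealed DAG
#'
#' @param bet An [eob()].
#' @param d A [dag()] that is a member of the bet's equivalence class.
#' @return `win` if the bet's edge is oriented `from -> to` in `d`, else
#'   `lose`.
#' @export
payoff <- function(bet, d) {
  stopifnot(inherits(bet, "eob"), inherits(d, "dag"))
  if (!(graph_key(d) %in% bet$class$member_keys)) {
    stop("the revealed DAG is not a member of the bet's class", call. = FALSE)
  }
  if (.has_arrow(d, bet$from, bet$to)) bet$win else bet$lose
}

# total package payoff per member: numeric vector of length class_size
.member_totals <- function(e) {
  cl <- e$class_ref
  totals <- numeric(length(cl$members))
  for (b in e$bets) {
    ind <- vapply(cl$members, function(d) .has_arrow(d, b$from, b$to), logical(1))
    totals <- totals + ifelse(ind, b$win, b$lose)
  }
  totals
}

#' Expected value of a bet package under per-edge beliefs
#'
#' The "naive" expected value: each bet is valued with the bettor's
#' marginal orientation beliefs alone, ignoring any dependence between
#' edges. This is the quantity an agent who prices edges one at a time
#' computes — and the quantity a Dutch book exploits.
#'
#' @param e A [ceob()].
#' @param beliefs An [edge_beliefs()] covering every bet's edge.
#' @return Money amount: sum over bets of
#'   `belief(from, to) * win + belief(to, from) * lose`.
#' @export
naive_expected_value <- function(e, beliefs) {
  stopifnot(inherits(e, "ceob"), inherits(beliefs, "edge_beliefs"))
  sum(vapply(e$bets, function(b) {
    belief_of(beliefs, b$from, b$to) * b$win +
      belief_of(beliefs, b$to, b$from) * b$lose
  }, numeric(1)))
}

#' Expected value of a bet package under a distribution over members
#'
#' @param e A [ceob()].
#' @param p A [dag_distribution()] over the same class.
#' @return Money amount: the double sum over bets and members of the
#'   member's probability times the bet's payoff.
#' @export
class_expected_value <- function(e, p) {
  stopifnot(inherits(e, "ceob"), inherits(p, "dag_distribution"))
  if (!identical(p$class$key, e$class_ref$key)) {
    stop("distribution refers to a different equivalence class", call. = FALSE)
  }
  sum(p$prob * .member_totals(e))
}

#' Is a bet package a Dutch book?
#'
#' A package is a Dutch book when its total payoff is strictly negative for
#' every member DAG: acceptance guarantees a loss whichever member is
#' revealed.
#'
#' @param e A [ceob()].
#' @return List with `dutch_book` (logical), `worst_payoff` (the maximum —
#'   i.e. least bad — total payoff over members), and `totals` (per-member
#'   totals in canonical member order).
#' @export
is_dutch_book <- function(e) {
  stopifnot(inherits(e, "ceob"))
  totals <- .member_totals(e)
  list(dutch_book = all(totals < -.money_eps),
       worst_payoff = max(totals),
       totals = totals)
}

#' The nonnegative-expected-value accept rule
#'
#' An agent whose credences are a probability distribution over the class
#' members, and who accepts a bet package only when its expected value
#' under that distribution is nonnegative, can never accept a Dutch book —
#' provided the distribution is strictly positive. With zero-probability
#' members the rule is still computed, but a warning is attached because
#' the immunity guarantee does not cover that case.
#'
#' @param e A [ceob()].
#' @param p A [dag_distribution()] over the same class.
#' @return Logical: accept (`TRUE`) iff [class_expected_value()] is `>= 0`
#'   (to within 1e-9).
#' @export
ev_accept <- function(e, p) {
  stopifnot(inherits(p, "dag_distribution"))
  if (!p$strictly_positive) {
    warning("distribution has zero-probability members; ",
            "Dutch-book immunity of the accept rule is only guaranteed for ",
            "strictly positive distributions", call. = FALSE)
  }
  class_expected_value(e, p) >= -.money_eps
}

#' Construct a Dutch book against incoherent edge beliefs
#'
#' Searches for stakes — one (win, lose) pair per undirected summary edge —
#' such that the package has nonnegative naive expected value under the
#' given beliefs yet pays strictly negative in every member DAG. The search
#' is a linear program over belief-fair bets: a bet on edge `e` with
#' directional stake `y_e` pays `y_e * (1 - q_e)` on `from -> to` and
#' `-y_e * q_e` otherwise, where `q_e` is the agent's belief, so each bet —
#' and hence the package — has naive expected value exactly 0, and the
#' package total under member `D` is the inner product of `y` with the
#' member's indicator vector minus the belief vector. Restricting to fair
#' bets loses nothing: subtracting its naive expected value from each bet
#' of an arbitrary book with nonnegative total EV gives a fair book whose
#' member totals are at least as negative. The LP maximises the
#' guaranteed-loss margin `m` subject to every member total `<= -m` and
#' `|win|, |lose| <= stake_bound`; a book is reported when the optimal
#' margin reaches `margin`. By the separating-hyperplane theorem such
#' stakes exist exactly when the beliefs lie outside the convex hull of the
#' members' indicator vectors, i.e. when [coherence_check()] is infeasible;
#' coherent beliefs yield `found = FALSE`. One bet per edge suffices (two
#' bets on one edge add up to one), so the search space is restricted
#' accordingly.
#'
#' Any returned package is re-verified outside the LP with
#' [is_dutch_book()] and [naive_expected_value()].
#'
#' @param c An `mec_class`.
#' @param beliefs An [edge_beliefs()] on `c`.
#' @param margin Required guaranteed loss per member, in money units
#'   (default 1e-3). Strict inequality ("guaranteed loss") cannot be
#'   expressed in raw LP feasibility, hence the explicit margin.
#' @param stake_bound Bound on `|win|` and `|lose|` per bet (default 100).
#' @return A `dutch_book_report`: list with `found`, `ceob` (or `NULL`),
#'   `worst_payoff`, `naive_ev`, `margin_achieved`.
#' @examples
#' hub <- make_class(consistent_extensions(
#'   pdg(undirected = c("A", "H", "B", "H", "C", "H"))))
#' und <- undirected_summary_edges(hub)
#' even <- edge_beliefs(hub, und[, 1], und[, 2], rep(0.5, 3))
#' find_dutch_book(hub, even)$found   # TRUE
#' @export
find_dutch_book <- function(c, beliefs, margin = 1e-3, stake_bound = 100) {
  stopifnot(inherits(c, "mec_class"), inherits(beliefs, "edge_beliefs"))
  if (!is.numeric(margin) || margin <= 0) stop("margin must be positive", call. = FALSE)
  if (!is.numeric(stake_bound) || stake_bound <= 0) {
    stop("stake bound must be positive", call. = FALSE)
  }
  if (!identical(beliefs$class$key, c$key)) {
    stop("beliefs refer to a different equivalence class", call. = FALSE)
  }
  und <- undirected_summary_edges(c)
  u <- nrow(und)
  empty <- structure(list(found = FALSE, ceob = NULL, worst_payoff = NA_real_,
                          naive_ev = NA_real_, margin_achieved = 0),
                     class = "dutch_book_report")
  if (u == 0L) return(empty)
  ind <- orientation_matrix(c)                        # k x u
  k <- nrow(ind)
  q <- vapply(seq_len(u), function(e) belief_of(beliefs, und[e, 1L], und[e, 2L]),
              numeric(1))
  # vars x >= 0: (yp_e, yn_e) per edge, then m; y = yp - yn is the
  # directional stake of the fair bet on edge e
  nv <- 2L * u + 1L
  obj <- c(rep(0, 2L * u), 1)
  # member constraints: sum_e y_e (ind_e(D) - q_e) + m <= 0
  A1 <- matrix(0, nrow = k, ncol = nv)
  for (e in seq_len(u)) {
    A1[, 2L * e - 1L] <- ind[, e] - q[[e]]
    A1[, 2L * e] <- -(ind[, e] - q[[e]])
  }
  A1[, nv] <- 1
  b1 <- rep(0, k)
  # |y_e| <= stake_bound / max(q_e, 1 - q_e) keeps |win|, |lose| within the
  # stake bound; bound each sign part separately
  ybound <- stake_bound / pmax(q, 1 - q, 0.5)
  bnd <- matrix(0, nrow = 2L * u, ncol = nv)
  for (j in seq_len(2L * u)) bnd[j, j] <- 1
  A1 <- rbind(A1, bnd)
  b1 <- c(b1, rep(ybound, each = 2L))
  sol <- .safe_simplex(a = obj, A1 = A1, b1 = b1, maxi = TRUE)
  if (is.null(sol) || sol$solved != 1) return(empty)
  m_star <- unname(sol$value)
  if (m_star < margin) {
    empty$margin_achieved <- max(m_star, 0)
    return(empty)
  }
  x <- sol$soln
  bets <- vector("list", u)
  for (e in seq_len(u)) {
    y <- x[[2L * e - 1L]] - x[[2L * e]]
    bets[[e]] <- eob(c, und[e, 1L], und[e, 2L], y * (1 - q[[e]]), -y * q[[e]])
  }
  book <- ceob(bets)
  # independent re-verification of the LP's claim
  check <- is_dutch_book(book)
  nev <- naive_expected_value(book, beliefs)
  if (!check$dutch_book || nev < -.money_eps) {
    warning("LP solution failed independent verification; reporting no book",
            call. = FALSE)
    empty$margin_achieved <- m_star
    return(empty)
  }
  structure(list(found = TRUE, ceob = book, worst_payoff = check$worst_payoff,
                 naive_ev = nev, margin_achieved = m_star),
            class = "dutch_book_report")
}

#' @export
print.dutch_book_report <- function(x, ...) {
  if (!x$found) {
    cat("no Dutch book found (beliefs appear coherent)\n")
  } else {
    cat(sprintf("Dutch book found: naive EV %+g, worst-case payoff %+g\n",
                x$naive_ev, x$worst_payoff))
    print(x$ceob)
  }
  invisible(x)
}
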