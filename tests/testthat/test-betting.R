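test_that("bet payoffs follow the stake/indicator rule exactly", {
  hub <- fixture("hub_class")
  bet1 <- eob(hub, "A", "H", 6, -4)
  into_A <- Filter(function(d) orientation_indicator("A", "H", d) == 1, hub$members)[[1]]
  out_A <- Filter(function(d) orientation_indicator("H", "A", d) == 1, hub$members)[[1]]
  expect_identical(payoff(bet1, into_A), 6)
  expect_identical(payoff(bet1, out_A), -4)

  flat <- eob(hub, "A", "H", 2.5, 2.5)
  for (d in hub$members) expect_identical(payoff(flat, d), 2.5)

  # antisymmetry: a bet and its negation cancel on every member
  neg <- eob(hub, "A", "H", -6, 4)
  for (d in hub$members) expect_identical(payoff(bet1, d) + payoff(neg, d), 0)

  stranger <- dag(nodes = c("B", "C", "H"), edges = c("A", "B"))
  expect_error(payoff(bet1, stranger), "not a member")
  expect_error(eob(hub, "A", "B", 1, -1), "not an undirected edge")
})

test_that("the worked three-bet package prices at $1 per bet and $3 total under even odds", {
  hub <- fixture("hub_class")
  st <- fixture("steve_package")
  und <- undirected_summary_edges(hub)
  even <- edge_beliefs(hub, und[, 1], und[, 2], rep(0.5, 3))

  expect_identical(naive_expected_value(ceob(st$bets[[1]]), even), 1)
  expect_identical(naive_expected_value(st, even), 3)

  zero <- ceob(eob(hub, "A", "H", 0, 0), eob(hub, "B", "H", 0, 0))
  expect_identical(naive_expected_value(zero, even), 0)

  # a belief table from a different class cannot price the bets
  other <- make_class(consistent_extensions(fixture("chain4")))
  ob <- orientation_table(uniform_distribution(other))
  expect_error(naive_expected_value(st, ob), "no belief recorded")
})

test_that("expected value under the class distribution exposes the trap", {
  hub <- fixture("hub_class")
  st <- fixture("steve_package")
  u <- uniform_distribution(hub)
  # each bet: 0.25 * 6 + 0.75 * (-4) = -1.5
  expect_equal(class_expected_value(ceob(st$bets[[1]]), u), -1.5)
  expect_equal(class_expected_value(st, u), -4.5)

  zero <- ceob(eob(hub, "A", "H", 0, 0))
  expect_identical(class_expected_value(zero, u), 0)

  other <- make_class(consistent_extensions(fixture("chain4")))
  expect_error(class_expected_value(st, uniform_distribution(other)),
               "different equivalence class")
})

test_that("class expected value equals naive value under the induced beliefs", {
  set.seed(61)
  classes <- list(fixture("hub_class"),
                  make_class(consistent_extensions(fixture("chain4"))),
                  make_class(consistent_extensions(fixture("triangle4"))))
  for (cl in classes) {
    und <- undirected_summary_edges(cl)
    for (i in 1:20) {
      p <- random_distribution(cl)
      bets <- lapply(sample(nrow(und), sample(1:4, 1), replace = TRUE), function(e) {
        eob(cl, und[e, 1], und[e, 2], runif(1, -10, 10), runif(1, -10, 10))
      })
      e <- ceob(bets)
      expect_equal(class_expected_value(e, p),
                   naive_expected_value(e, orientation_table(p)),
                   tolerance = 1e-9)
    }
  }
})

test_that("the worked package is a Dutch book with best case -$2", {
  st <- fixture("steve_package")
  res <- is_dutch_book(st)
  expect_true(res$dutch_book)
  expect_identical(res$worst_payoff, -2)
  expect_identical(sort(res$totals), c(-12, -2, -2, -2))

  two <- make_class(consistent_extensions(fixture("two_node")))
  expect_false(is_dutch_book(ceob(eob(two, "A", "B", 6, -4)))$dutch_book)

  hub <- fixture("hub_class")
  nonneg <- ceob(eob(hub, "A", "H", 3, 0), eob(hub, "B", "H", 0, 1))
  expect_false(is_dutch_book(nonneg)$dutch_book)
})

test_that("the expected-value accept rule rejects the trap and flags non-strict distributions", {
  hub <- fixture("hub_class")
  st <- fixture("steve_package")
  u <- uniform_distribution(hub)
  expect_false(ev_accept(st, u))
  expect_true(ev_accept(ceob(eob(hub, "A", "H", 0, 0)), u))

  lopsided <- dag_distribution(hub, c(1, 0, 0, 0))
  expect_warning(ev_accept(st, lopsided), "strictly positive")
})

test_that("accepted packages are never Dutch books under strictly positive credences", {
  set.seed(71)
  cl <- fixture("hub_class")
  und <- undirected_summary_edges(cl)
  p <- random_distribution(cl)
  n_accept <- 0
  for (i in 1:200) {
    bets <- lapply(seq_len(nrow(und)), function(e) {
      eob(cl, und[e, 1], und[e, 2], runif(1, -10, 10), runif(1, -10, 10))
    })
    e <- ceob(bets)
    if (ev_accept(e, p)) {
      n_accept <- n_accept + 1
      expect_false(is_dutch_book(e)$dutch_book)
    }
  }
  expect_gt(n_accept, 0)  # the property was actually exercised
})

test_that("Dutch books are constructed against incoherent beliefs and verified", {
  hub <- fixture("hub_class")
  und <- undirected_summary_edges(hub)
  even <- edge_beliefs(hub, und[, 1], und[, 2], rep(0.5, 3))
  rep <- find_dutch_book(hub, even)
  expect_true(rep$found)
  expect_true(is_dutch_book(rep$ceob)$dutch_book)
  expect_gte(naive_expected_value(rep$ceob, even), -1e-9)
  expect_lt(rep$worst_payoff, 0)

  # coherent beliefs admit no book
  set.seed(81)
  for (cl in list(hub, make_class(consistent_extensions(fixture("chain4"))))) {
    induced <- orientation_table(uniform_distribution(cl))
    expect_false(find_dutch_book(cl, induced)$found)
  }

  two <- make_class(consistent_extensions(fixture("two_node")))
  for (p in c(0.05, 0.5, 0.95)) {
    expect_false(find_dutch_book(two, edge_beliefs(two, "A", "B", p))$found)
  }

  expect_error(find_dutch_book(hub, even, margin = 0), "positive")
  expect_error(find_dutch_book(hub, even, stake_bound = -1), "positive")
})
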