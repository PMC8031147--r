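test_that("the orientation indicator reads arrows, absent edges give 0", {
  d <- dag(nodes = c("B", "C"), edges = c("A", "H"))
  expect_equal(orientation_indicator("A", "H", d), 1)
  expect_equal(orientation_indicator("H", "A", d), 0)
  expect_equal(orientation_indicator("A", "B", d), 0)
  expect_error(orientation_indicator("A", "Z", d), "unknown")
})

test_that("distributions over members validate and the uniform one is uniform", {
  hub <- fixture("hub_class")
  u <- uniform_distribution(hub)
  expect_equal(u$prob, rep(0.25, 4))
  expect_true(u$strictly_positive)

  single <- mec_members(dag(edges = c("A", "B", "C", "B")))
  expect_equal(uniform_distribution(single)$prob, 1)

  expect_error(dag_distribution(hub, c(0.5, 0.5)), "need 4")
  expect_error(dag_distribution(hub, c(0.7, 0.2, 0.2, -0.1)), "nonnegative")
  expect_error(dag_distribution(hub, c(0.4, 0.4, 0.1, 0.2)), "sum to 1")
  expect_false(dag_distribution(hub, c(0.5, 0.5, 0, 0))$strictly_positive)
})

test_that("induced orientation probabilities on the worked classes", {
  hub <- fixture("hub_class")
  u <- uniform_distribution(hub)
  for (x in c("A", "B", "C")) {
    expect_equal(orientation_probability(u, x, "H"), 0.25)
    expect_equal(orientation_probability(u, "H", x), 0.75)
  }

  chain <- make_class(consistent_extensions(fixture("chain4")))
  uc <- uniform_distribution(chain)
  expect_equal(orientation_probability(uc, "B", "C"), 0.5)
  expect_equal(orientation_probability(uc, "A", "B"), 0.25)
  expect_equal(orientation_probability(uc, "C", "D"), 0.75)

  expect_error(orientation_probability(u, "A", "B"), "not adjacent")
})

test_that("orientation tables cover both orderings and always sum to 1", {
  hub <- fixture("hub_class")
  tab <- orientation_table(uniform_distribution(hub))
  expect_equal(nrow(tab$table), 6)
  for (x in c("A", "B", "C")) {
    expect_equal(belief_of(tab, x, "H"), 0.25)
    expect_equal(belief_of(tab, "H", x), 0.75)
  }

  single <- mec_members(dag(edges = c("A", "B", "C", "B")))
  expect_equal(nrow(orientation_table(uniform_distribution(single))$table), 0)

  set.seed(5)
  for (i in 1:10) {
    tab <- orientation_table(random_distribution(hub))
    sums <- tapply(tab$table$prob,
                   paste(pmin(tab$table$from, tab$table$to),
                         pmax(tab$table$from, tab$table$to)),
                   sum)
    expect_equal(as.numeric(sums), rep(1, 3))
  }
})

test_that("belief tables validate their edges and complements", {
  hub <- fixture("hub_class")
  # complement filled from one ordering
  b <- edge_beliefs(hub, c("A", "B", "C"), c("H", "H", "H"), c(0.3, 0.5, 0.9))
  expect_equal(belief_of(b, "H", "A"), 0.7)
  expect_error(edge_beliefs(hub, "A", "B", 0.5), "not an undirected edge")
  expect_error(edge_beliefs(hub, c("A", "H", "B", "C"), c("H", "A", "H", "H"),
                            c(0.3, 0.5, 0.5, 0.5)), "sum to 1")
  expect_error(edge_beliefs(hub, c("A", "B"), c("H", "H"), c(0.3, 0.5)),
               "no belief given")
})

test_that("equal odds on the hub are incoherent; induced beliefs are coherent", {
  hub <- fixture("hub_class")
  und <- undirected_summary_edges(hub)
  even <- edge_beliefs(hub, und[, 1], und[, 2], rep(0.5, 3))
  res <- coherence_check(hub, even)
  expect_false(res$feasible)
  expect_null(res$witness)
  # best achievable max mismatch is 1/6: P(into-H) probabilities sum to 1
  # across the three edges, so they cannot all reach 1/2
  expect_equal(res$max_violation, 1 / 6, tolerance = 1e-7)

  set.seed(31)
  classes <- list(hub,
                  make_class(consistent_extensions(fixture("chain4"))),
                  make_class(consistent_extensions(fixture("triangle4"))))
  for (cl in classes) {
    for (i in 1:5) {
      p <- random_distribution(cl)
      res <- coherence_check(cl, orientation_table(p))
      expect_true(res$feasible)
      expect_lte(res$max_violation, 1e-8)
      # witness reproduces the beliefs
      wtab <- orientation_table(res$witness)
      ptab <- orientation_table(p)
      expect_equal(wtab$table$prob, ptab$table$prob, tolerance = 1e-6)
    }
  }
})

test_that("a lone undirected edge is coherent for every belief", {
  two <- make_class(consistent_extensions(fixture("two_node")))
  for (p in c(0, 0.1, 0.5, 0.77, 1)) {
    b <- edge_beliefs(two, "A", "B", p)
    expect_true(coherence_check(two, b)$feasible)
  }
})

test_that("orientation probabilities are linear in the distribution", {
  hub <- fixture("hub_class")
  set.seed(41)
  for (i in 1:5) {
    p1 <- random_distribution(hub)
    p2 <- random_distribution(hub)
    w <- runif(1)
    mix <- dag_distribution(hub, w * p1$prob + (1 - w) * p2$prob)
    und <- undirected_summary_edges(hub)
    for (e in seq_len(nrow(und))) {
      expect_equal(orientation_probability(mix, und[e, 1], und[e, 2]),
                   w * orientation_probability(p1, und[e, 1], und[e, 2]) +
                     (1 - w) * orientation_probability(p2, und[e, 1], und[e, 2]),
                   tolerance = 1e-12)
    }
  }
})

test_that("coherence is invariant under node relabeling", {
  hub <- fixture("hub_class")
  und <- undirected_summary_edges(hub)
  beliefs <- c(0.2, 0.4, 0.9)
  res1 <- coherence_check(hub, edge_beliefs(hub, und[, 1], und[, 2], beliefs))

  # relabel A<->C, H->Z (spokes X, Y, and keep structure)
  relabeled <- pdg(undirected = c("C", "Z", "B", "Z", "A", "Z"))
  cl2 <- make_class(consistent_extensions(relabeled))
  und2 <- undirected_summary_edges(cl2)
  # map beliefs through the relabeling A->C, B->B, C->A, H->Z
  map <- c(A = "C", B = "B", C = "A", H = "Z")
  b2 <- edge_beliefs(cl2, unname(map[und[, 1]]), unname(map[und[, 2]]), beliefs)
  res2 <- coherence_check(cl2, b2)
  expect_identical(res1$feasible, res2$feasible)
  expect_equal(res1$max_violation, res2$max_violation, tolerance = 1e-9)
})

test_that("coherence rejects nonpositive tolerances and foreign beliefs", {
  hub <- fixture("hub_class")
  und <- undirected_summary_edges(hub)
  b <- edge_beliefs(hub, und[, 1], und[, 2], c(0.25, 0.25, 0.25))
  expect_error(coherence_check(hub, b, tol = 0), "positive")
  other <- make_class(consistent_extensions(fixture("chain4")))
  expect_error(coherence_check(other, b), "different equivalence class")
})
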