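---
title: "Interpreting undirected edges in essential graphs: orientation odds, coherence, and Dutch books"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpreting undirected edges in essential graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edgeodds)
```

## The problem

Causal discovery algorithms rarely return a single DAG. Their usual output
is an *essential graph* (CPDAG): a partially directed graph summarising a
Markov equivalence class, with compelled edges drawn as arrows and
reversible edges left undirected. Users then face a quantitative question
the picture does not answer: *how likely is an undirected edge to point one
way rather than the other?*

A tempting shortcut — treat every undirected edge as a 50/50 coin — is not
merely imprecise; it is incoherent for many graphs, in the betting sense:
an adversary can sell such a user a package of bets that looks profitable
edge-by-edge yet loses money for every DAG in the class. This package makes
the sound alternative computable: form a probability distribution over the
*member DAGs* first, and derive per-edge orientation probabilities from it.

## Model and notation

A partially directed graph (`pdg`) has nodes and at most one edge —
directed or undirected — per node pair. A DAG is a fully directed acyclic
`pdg`. Two DAGs are Markov equivalent iff they share skeleton and
uncovered colliders (v-structures `X -> M <- Y` with `X`, `Y`
non-adjacent); equivalently, iff they entail identical d-separation
statements. An equivalence class object (`mec_class`) stores an explicit
member list plus a derived summary graph: an edge is drawn directed iff
its orientation is constant across members.

Given a distribution \(P\) over the members of a class \(G\), the
orientation probability of an ordered pair \((A,B)\) is
\[
P(A \to B) \;=\; \sum_{D \in G} P(D)\, \mathbb{1}[A \to B \in D],
\]
computed by `orientation_probability()`. A user-supplied table of per-edge
beliefs \(q_{AB}\) (with \(q_{AB} + q_{BA} = 1\)) is *coherent* when some
\(P\) over the members induces it — i.e. when the belief vector lies in
the convex hull of the members' orientation-indicator vectors.

## Worked example

The hub graph (`A -- H`, `B -- H`, `C -- H`) has exactly four members:
orienting two or more spokes into `H` would create a new v-structure, so
`H` has at most one parent in any member. Under the uniform distribution
each spoke points *into* the hub with probability 1/4 and *out* with
probability 3/4 — far from 50/50:

```{r hub}
hub <- make_class(consistent_extensions(fixture("hub_graph")))
orientation_table(uniform_distribution(hub))
```

Equal odds on all three spokes are incoherent (the three into-hub
probabilities must sum to at most 1 across members, so they cannot all be
1/2), and the classic three-bet package — win \$6 per correct into-hub
guess, lose \$4 otherwise — exploits exactly that:

```{r steve}
package <- fixture("steve_package")
und <- undirected_summary_edges(hub)
even <- edge_beliefs(hub, und[, 1], und[, 2], rep(0.5, 3))
naive_expected_value(package, even)   # looks like +$3 ...
is_dutch_book(package)[c("dutch_book", "worst_payoff")]  # ... guarantees -$2
```

## Coherence as a linear program

`coherence_check()` minimises, over distributions \(p \ge 0,\ \sum p = 1\),
the largest absolute mismatch \(t\) between induced and stated orientation
probabilities, and declares the beliefs coherent when the optimum
satisfies \(t \le \mathrm{tol}\). Equalities are relaxed to a tolerance
(default `1e-8`) because floating-point beliefs essentially never satisfy
exact rational constraints. The witness distribution is returned so the
caller can verify it reproduces the beliefs.

## Constructing Dutch books

`find_dutch_book()` searches for one bet per undirected edge. It
parametrises each bet as *belief-fair*: directional stake \(y_e\) pays
\(y_e (1 - q_e)\) on one orientation and \(-y_e q_e\) on the other, so
every bet has naive expected value exactly zero and the package total
under member \(D\) is \(y \cdot (\mathbb{1}_D - q)\). This restriction
loses nothing — subtracting its own naive value from each bet of any book
with nonnegative total EV yields a fair book at least as bad for the
bettor — and it reduces the search to a separating-hyperplane problem: a
guaranteed-loss stake vector exists iff \(q\) lies outside the hull of the
member indicator vectors, i.e. iff the beliefs are incoherent. The LP
maximises the guaranteed loss margin subject to a stake bound; both
defaults are surfaced (`margin = 1e-3` money units, `stake_bound = 100`).
A margin is needed because "guaranteed loss" is a strict inequality that
raw LP feasibility cannot express. Every returned package is re-verified
outside the LP with `is_dutch_book()` and `naive_expected_value()`.

The complementary strategy is `ev_accept()`: accept a package only when
its expected value under your distribution over members is nonnegative.
Accepted packages are then never Dutch books. The guarantee is proved for
strictly positive distributions; with zero-probability members the rule
still computes but attaches a warning, since a zero-probability member
could mask a uniform loss on the support's complement.

## The census

`imbalance_census(n, m)` enumerates all \(\binom{\binom{n}{2}}{m} 2^m\)
directed graphs on \(n\) labelled nodes with \(m\) edges, keeps the acyclic
ones, partitions them by (skeleton, v-structures), groups class summaries
that coincide up to node relabeling, and tallies — *once per DAG per
undirected edge of its pattern*, under a uniform distribution over each
class — the larger of the two orientation probabilities. At \(n = 4, m =
3\): 160 directed graphs over 20 skeletons, 8 cyclic, 152 DAGs, 60 classes
in 6 permutation types, and 144 of 312 undirected-edge instances (46%)
imbalanced, all at probability 3/4.

Two conventions matter and are deliberate:

* **Instances are counted per DAG**, i.e. class size × number of
  undirected summary edges — this is the convention under which the
  headline ratio \((96+48)/(96+48+48+48+72) \approx 46\%\) comes out of
  the per-type tallies, and it weights each possible ground truth equally.
* **Probability buckets** are keyed by the maximum orientation probability
  rounded to 6 decimals; the headline fraction is additionally rounded to
  an integer percent.

Uniformity over members is the census's modelling assumption, not a
theorem: it quantifies how often *equal odds are impossible*, not what the
odds of any real edge are.

## Numerical and design choices

* **Enumeration is brute force** over the \(2^u\) orientations of \(u\)
  undirected edges (and \(2^m\) skeleton orientations for patterns), with
  a hard limit (`max_undirected = 20`). At the graph sizes for which
  exhaustive interpretation is meaningful this is exact and fast, and it
  doubles as its own oracle; orientation-propagation rule systems are
  deliberately out of scope.
* **d-separation** is decided by the ancestral-moral-graph reduction
  (restrict to ancestors, marry co-parents, drop the conditioning set,
  test connectivity). An independent exponential checker — enumerate all
  simple skeleton paths, apply the collider/noncollider activation rule to
  each — ships as `d_separated(..., method = "paths")`. The two are
  compared exhaustively on every DAG with up to 4 nodes (all edge counts,
  all queries) and on a seeded sample of 5-node DAGs; full exhaustion at 5
  nodes (29,281 DAGs × 80 queries) adds runtime without adding much
  evidence, so the suite samples there.
* **Path semantics**: the activation rule is defined for arbitrary node
  sequences, but d-separation is decided over simple paths; the
  reachability reduction is equivalent to both readings, which confines
  the ambiguity to documentation.
* **The LP solver** is the two-phase simplex from the recommended `boot`
  package; the problems here are at most a few dozen variables. Its
  textbook pivoting can stall on the degenerate all-zero right-hand sides
  the Dutch-book LP produces, so LP calls go through a wrapper that
  retries with a purely relaxing jitter (`1e-9`, then `1e-7`) of the
  inequality bounds — perturbing the optimum by no more than the jitter.
* **Money comparisons** use an absolute epsilon of `1e-9`; the worked
  integer example is asserted exactly in the tests.
* **Restricted classes**: `make_class()` accepts any mutually equivalent
  member subset (background knowledge may rule members out). The member
  list is authoritative; the summary is always re-derived, so an edge
  whose orientation happens to be constant across a restricted subset is
  rendered directed. That is intended: the summary answers "what varies
  across the members I am actually entertaining".
* **Degenerate inputs**: isolated nodes are legal everywhere (the census
  triangle type needs one); the empty graph is trivially acyclic; classes
  whose summary has no undirected edge admit no bets, an empty belief
  table, and are vacuously coherent.

## Randomised inputs and what the tests show

`random_dag(n, m, seed)` draws uniformly over the enumerable DAG set by
rejection from uniform directed graphs, with a local RNG stream so the
caller's state is untouched. Property tests use it, plus random strictly
positive member distributions and random per-edge beliefs, to exercise:
the exchange identity (class-EV equals naive EV under induced beliefs, to
`1e-9`); accept-rule immunity over 1,000 random packages per bettable
4-node/3-edge class; and the empirical biconditional *book found ⟺
beliefs incoherent* on randomised beliefs over all 4-node/3-edge classes.
The biconditional is checked per instance, with every constructed book
re-verified; the package certifies instances, it does not prove the
general necessity claim. These synthetic inputs probe the betting
calculus, not statistical practice: real edge-belief tables come from
resampling or posterior summaries with their own estimation error, which
nothing here models.

## Limitations

* No latent confounders: essential graphs cannot express an unmeasured
  common cause; ancestral-graph classes (MAGs/PAGs) are out of scope.
* Exponential enumeration: classes with many undirected edges exceed the
  limit by design; no clique-tree or counting shortcuts are provided.
* The necessity direction of the coherence–bookability equivalence is
  checked empirically per instance, never assumed.
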