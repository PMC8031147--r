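# edgeodds

Quantitative interpretation of undirected edges in **essential graphs**
(CPDAGs), the standard output of causal discovery algorithms.

An essential graph summarises a Markov equivalence class of causal DAGs:
compelled edges are drawn as arrows, reversible ones are left undirected.
Practitioners routinely read an undirected edge as "points either way,
50/50" — but the orientations of different undirected edges are coupled
through the class, and for many graphs *no* distribution over the member
DAGs gives every undirected edge equal odds. An agent who prices bets
edge-by-edge at 50/50 can then be **Dutch booked**: sold a package of bets
that looks profitable bet-by-bet yet loses money whichever member DAG is
true.

`edgeodds` is for anyone who needs to attach numbers to undirected edges —
methodologists studying causal-discovery output, and analysts
post-processing CPDAGs or bootstrap edge-frequency tables. It provides:

* the graph calculus: skeletons, v-structures, d-separation
  (`d_separated()`, with an independent path-enumeration cross-check),
  Markov equivalence;
* class enumeration: `consistent_extensions()` (the member DAGs of an
  essential graph), `pattern_of()`, `mec_members()`, `make_class()` for
  background-knowledge-restricted member sets;
* orientation probabilities induced by a distribution over members
  (`orientation_probability()`, `orientation_table()`), where for a
  distribution \(P\) over class \(G\):
  \(P(A \to B) = \sum_{D \in G} P(D)\,\mathbb{1}[A \to B \in D]\);
* **coherence checking** of arbitrary per-edge beliefs by linear
  programming (`coherence_check()`: is the belief vector in the convex
  hull of the members' indicator vectors?);
* the **betting calculus**: edge-orientation bets and packages (`eob()`,
  `ceob()`), payoffs, naive vs class expected value, `is_dutch_book()`,
  the immune accept rule `ev_accept()`, and `find_dutch_book()`, which
  constructs a verified Dutch book against any incoherent belief table via
  a separating-hyperplane LP;
* an exhaustive **census** (`imbalance_census()`) of how common
  orientation-imbalanced undirected edges are among all small DAGs;
* plain-text graph and CSV belief/bet I/O plus a CLI
  (`inst/cli/edgeodds`).

## Worked example: the undirected hub

```r
library(edgeodds)

hub <- make_class(consistent_extensions(parse_graph("A -- H\nB -- H\nC -- H")))
hub
#> <equivalence class> 4 member DAG(s) on {A, B, C, H}
```

Only four DAGs are in this class: a second arrow into `H` would create a
new v-structure. Under a uniform distribution over them, the odds are far
from even:

```r
orientation_table(uniform_distribution(hub))
#> <edge beliefs> 6 ordered pair(s)
#>  from to prob
#>     A  H 0.25
#>     H  A 0.75
#>     B  H 0.25
#>     H  B 0.75
#>     C  H 0.25
#>     H  C 0.75
```

Each spoke points *out* of the hub with probability 3/4. Believing 50/50
on all three spokes is incoherent, and a Dutch book against that belief is
constructed automatically:

```r
und  <- undirected_summary_edges(hub)
even <- edge_beliefs(hub, und[, 1], und[, 2], rep(0.5, 3))
coherence_check(hub, even)
#> INCOHERENT: best achievable max violation 0.167

find_dutch_book(hub, even, stake_bound = 10)
#> Dutch book found: naive EV +0, worst-case payoff -10
#> <bet package> 3 bet(s)
#> <bet> +10 if A -> H, -10 if H -> A
#> <bet> +10 if B -> H, -10 if H -> B
#> <bet> +10 if C -> H, -10 if H -> C
```

At 50/50 each bet looks fair (naive expected value 0), yet at most one
into-hub guess can win, so the package loses at least $10 in every member.
The defence is to price packages against a distribution over members:
`ev_accept()` accepts only packages with nonnegative expected value under
your distribution, and such an agent (with strictly positive credences)
can never accept a Dutch book.

How common is this? The census over all DAGs with 4 nodes and 3 edges:

```r
imbalance_census(4, 3)
#> census of 4-node, 3-edge graphs
#>   160 directed graphs over 20 skeletons: 152 DAGs, 8 cyclic
#>   60 equivalence classes in 6 permutation types
#>   undirected-edge instances by max orientation probability:
#>     0.500000 : 168
#>     0.750000 : 144
#>   imbalanced fraction: 0.4615 (46%)
```

46% of undirected-edge instances are 75/25 rather than 50/50.

## Command line

```sh
inst/cli/edgeodds extensions graph.txt
inst/cli/edgeodds orient-probs graph.txt --beliefs out.csv
inst/cli/edgeodds coherence graph.txt beliefs.csv
inst/cli/edgeodds dutchbook graph.txt beliefs.csv --stake-bound 10
inst/cli/edgeodds census --nodes 4 --edges 3 --out report.csv
```

Graphs are plain edge lists (`A -> B` directed, `A -- B` undirected,
`node X` for isolated nodes, `#` comments). Exit codes: 0 success, 2 parse
error, 3 infeasible input or enumeration limit.

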