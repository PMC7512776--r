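---
title: "Entropy-based centrality for weighted networks: model, conventions and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropy-based centrality for weighted networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(entrank)
```

## The problem

Identifying *vital nodes* — the airports, users or proteins whose activation
or removal disproportionately affects dynamics on a network — is a classic
network-science task. Most centralities use either shortest paths
(betweenness, closeness) or raw neighbourhood counts (degree, k-core), and
both families discard the information carried by edge *weights*: in an
airline network the number of flights per connection, in a social network
the message frequency between users. entrank implements an entropy-based
centrality for weighted, directed (or undirected) networks that uses that
information explicitly, together with the standard baselines and a
spreading simulator to compare them.

## The model

For a node $i$ in a weighted digraph $G(V, E, W)$, let $G_i$ be its **ego
subgraph**: the induced subgraph on $i$ and all of its in- and
out-neighbours (all $M$ of them). Each member $v$ of $G_i$ has a *subgraph
degree centrality* $SDC_v$, its in-degree plus out-degree counted within
$G_i$; for undirected networks this is simply the number of members adjacent
to $v$. Two Shannon entropies are computed:

* **structural entropy**
  $I_i^s = -\sum_{v \in G_i} p_v \log_b p_v$, with
  $p_v = SDC_v / \sum_u SDC_u$ — high when activity in $i$'s neighbourhood
  is spread over many well-connected members, a proxy for activity and
  popularity;
* **frequency entropy**
  $I_i^f = -\sum_{j} q_j \log_b q_j$, with
  $q_j = C_{ij} / \sum_k C_{ik}$ over $i$'s out-edge weights (incident
  weights when undirected) — high when $i$ maintains many ties of comparable
  strength, a proxy for accessibility.

The **local influence** is the convex combination
$LI_i = \omega_1 I_i^s + \omega_2 I_i^f$. Influence also propagates, but
empirical work on social contagion finds it hard to detect beyond two or
three steps, so propagation is modelled on **two-hop** neighbourhoods only:
for each two-hop neighbour $p$ (reachable as $i \to j \to p$ but not a
one-hop out-neighbour), the per-target influence averages
$LI_i \cdot LI_j$ over the $N_{ip}$ common intermediates $j$, and the
**indirect influence** $II_i$ is the mean of those terms over the $M_i$
two-hop neighbours. The ranking score is the **total influence**
$I_i = \theta_1 LI_i + \theta_2 II_i$.

### Parameters

| parameter | meaning | default | notes |
|---|---|---|---|
| $\omega_1, \omega_2$ | weight of structural vs frequency entropy in $LI$ | 0.4, 0.6 | must be nonnegative and sum to 1 |
| $\theta_1, \theta_2$ | weight of local vs indirect influence in $I$ | 0.6, 0.4 | must be nonnegative and sum to 1 |
| $b$ (`log_base`) | base of both entropy logarithms | 10 | entropies are in $\log_{10}$ units; any base $>0$, $\neq 1$ rescales all scores monotonically |

The defaults follow the convention established for this family of entropy
centralities: frequency information is weighted slightly above structure,
and direct influence above propagated influence. With $\theta_2 = 0$ the
ranking reduces exactly to the local-influence ranking (a tested property).
Scores depend only on degree structure and weight *proportions*, so a global
rescaling of all weights leaves every score unchanged.

## Conventions the formulas do not pin down

Several choices are required to make the definitions operational; entrank's
choices are recorded in the `conventions` attribute of every result and are
exercised against a brute-force oracle in the test suite:

* **Ego-subgraph edge set** — the *induced* edge set, including
  neighbour–neighbour edges. This is the only reading consistent with the
  worked example below (nodes D and E reach $SDC = 6$ in B's subgraph only
  through their mutual edges).
* **Membership** — the union of in- and out-neighbours. The fully
  reciprocal example cannot discriminate this from out-neighbours only;
  non-reciprocal synthetic graphs in the tests pin the behaviour against the
  oracle.
* **Frequency entropy** — out-edge weights only in directed networks (the
  weight of an edge in its direction); all incident weights in undirected
  networks.
* **Two-hop traversal** — follows edge direction at both hops and excludes
  the focal node and its one-hop *out*-neighbours.
* **Indirect-influence divisor** — $M_i$ is the number of *distinct*
  two-hop neighbours, applied uniformly to every node.
* **Degenerate distributions** — $0 \log 0 := 0$; a node with no edges, or
  a single out-edge, contributes zero to the corresponding entropy; a node
  with no two-hop neighbours has $II_i = 0$.
* **Ties** — ranks are assigned by descending total influence with ties
  broken by ascending node identifier, and tied scores are flagged in the
  `tied` column rather than hidden.

## The worked example

`toy_network()` ships the 8-airport, 26-connection example used throughout
the documentation; each weight counts flights on a connection in the given
direction. The full pipeline reproduces its published reference values: the
subgraph degree centralities in B's ego subgraph (B 8, A 4, C 4, D 6, E 6),
B's entropies $I_B^s = 0.6836$ and $I_B^f = 0.5898$, its local influence
$LI_B = 0.6273$, and the final ranking E, B, D, C, G, F, A, H.

```{r}
entropy_centrality(toy_network())
```

Two caveats, documented rather than matched, apply to the original published
tabulation of this example. First, it prints $LI_C = 0.4955$ where the
definitions above give $0.4995$ (a digit transposition), and the downstream
values computed *with* the transposed digit inherit the error: the printed
indirect influence of B (0.3713) and E (0.3619) and the corresponding totals
differ from the consistent values (0.3721, 0.3626) in the third decimal.
Second, node H's printed indirect influence divides by 2 where H has three
two-hop neighbours; entrank applies the uniform $M_i$ divisor to every node.
Neither discrepancy affects the ranking, which reproduces exactly.

## Baseline centralities

The comparison baselines make their weighted/directed conventions explicit
(and configurable), since published comparisons rarely state them: degree is
the unweighted total degree; betweenness and closeness treat strong ties as
short by using distances $1/w$; closeness defaults to the harmonic variant,
which is well defined on weakly connected digraphs (unreachable pairs
contribute zero rather than poisoning the mean); eigenvector centrality is
the principal eigenvector of the weighted adjacency, power-iterated to an
L2 tolerance of $10^{-8}$ (at most 1000 iterations, with an explicit error
on non-convergence). The iteration applies a diagonal shift equal to the
maximum weight: this leaves the eigenvector unchanged while making the
dominant eigenvalue unique, so bipartite-like spectra (stars, rings) —
whose unshifted power iteration oscillates — converge too. Directed scores
are fed by in-edges.

## The SI spreading evaluation

Ranking quality is scored by seeding a susceptible–infectious process with
each method's top-$k$ nodes and comparing the mean number of infected nodes
over time (the *influence spread*). Choices that matter:

* **Weighted infection probability** — per step, a susceptible node is
  infected across an edge of weight $w$ with probability
  $1 - (1-\beta)^w$ (the weight acts as $w$ independent contacts); the
  alternative form $(w/w_{\max})^\alpha$ is also provided.
* **Synchronous discrete time** — all challenges in a step use the
  infection state at the start of the step; infections take effect at step
  end. Curves depend on this choice, so it is fixed and stated.
* **Transmission direction** — along edge direction only ($j \to i$ lets an
  infected $j$ challenge $i$); undirected edges transmit both ways with the
  single weight.
* **Horizon and spread rate** — no canonical $\beta$ exists for this
  evaluation; experiments should sweep it. `t_max` defaults to 30, chosen so
  curves plateau on the test networks.
* **Reproducibility** — replicate $r$ draws its randomness from
  `seed + r`, so identical configurations are bit-identical and every
  method/seed-set faces the same noise in `compare_methods()`.

```{r, fig.width = 6, fig.height = 3}
net <- random_network(100, mean_out_degree = 6, reciprocity = 0.3, seed = 7)
cmp <- compare_methods(net, k = c(5, 10),
                       config = si_config(beta = 0.05, t_max = 15,
                                          replicates = 100, seed = 7))
autoplot(cmp)
```

## What the synthetic generator does and does not emulate

`random_network()` produces $G(n,p)$-style arc sampling with a reciprocity
parameter (the worked example is fully reciprocal; most real directed
networks are not, and only non-reciprocal graphs exercise the in/out
distinctions of the algorithm) and i.i.d. weights (uniform integers,
geometric, or continuous log-normal, covering count-like and fractional
weights). It deliberately does **not** reproduce heavy-tailed degree
distributions, degree–weight correlations, clustering or community
structure of real networks. Passing tests on these graphs therefore
establish *correctness of the computation* (against brute-force
enumeration, exact to $10^{-12}$) and the qualitative behaviour of the
evaluation protocol, not performance claims on any real network.

The shipped evaluation uses a 300-node network with mean out-degree 8 and
reciprocity 0.3, seed-set sizes $k \in \{5, 10, 20\}$, 200 replicates and a
$\beta$ sweep over $\{0.02, 0.1\}$ — sizes at which the monotonicity
properties (spread non-decreasing in $t$, $\beta$ and $k$) are clearly
resolved; time monotonicity is exact (infected sets are nested within a
replicate), while the $k$ and $\beta$ comparisons are Monte-Carlo estimates
judged within three standard errors.

## Known limitations

* Total influence is **not** bounded by 1 in general: a node with $M$
  neighbours can reach structural entropy $\log_{10}(M+1)$, which exceeds 1
  for $M > 9$. The unit range often quoted for this family of scores holds
  only for small examples.
* Nodes in sparse, locally similar neighbourhoods can receive nearly
  indistinguishable scores; the `tied` flag surfaces exact ties but not
  near-ties.
* Negative or zero weights are rejected by construction — the entropy
  logarithms require positive arguments — so signed networks are out of
  scope.
* Propagation is fixed at two hops by design; there is no configurable
  depth.
* Exact betweenness on large dense networks is the usual $O(nm)$ cost of
  the Brandes algorithm; the entropy centrality itself only touches
  two-hop neighbourhoods and scales accordingly.
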