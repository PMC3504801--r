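---
title: "Assembling multimeric complexes with a spanning-tree genetic algorithm"
author: "TreeDock authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembling multimeric complexes with a spanning-tree genetic algorithm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TreeDock)
```

## The problem and the model

Multiple protein docking asks for the three-dimensional structure of a
complex of $n$ rigid subunits when only the subunit structures and a library
of *pairwise* docking predictions are available. TreeDock represents one
candidate complex as a **spanning tree** over the subunit set: nodes are
subunits, and each edge $(i, j)$ selects one rigid-body transform (a
"decoy") from the pairwise library for that subunit pair. Because a spanning
tree touches every subunit and contains no cycles, composing the edge
transforms along tree paths from a root places every subunit uniquely: a
genome of $n - 1$ (edge, decoy) choices fully determines an all-atom model.
Not every subunit pair needs a direct interface — only the tree edges carry
transforms.

The search space is enormous even at desk scale (Cayley's formula gives
$n^{n-2}$ labeled trees, times the decoy choices per edge), so the package
explores it with a **genetic algorithm**:

* **Mutation** deletes one tree edge, which splits the tree into two
  components, then reconnects them with an edge drawn uniformly over all
  component-crossing pairs (re-drawing the deleted pair is allowed) and a
  decoy drawn uniformly from that pair's pool.
* **Crossover** builds a child from the multiset union of two parents'
  edges, drawing candidates uniformly without replacement and accepting an
  edge iff its pair is unused and it closes no cycle. The union of two
  spanning trees is connected, so the child always completes; every child
  edge carries a parent's decoy index.
* **Within-generation clustering + truncation selection.** The expanded
  pool is de-duplicated by greedy RMSD clustering (below) and the surviving
  representatives are ranked by fitness; the best $M$ continue.

With the default growth settings and $M = 200$, a generation's pool sizes
trace $200 \to 300$ (crossover adds 50%) $\to 600$ (mutation doubles:
one mutant per pool member) $\to \le 200$ survivors. Without crossover,
$200 \to 400 \to \le 200$. These are the package's reference operating
points; both stages are fractions (`crossoverGrowth`, `mutationGrowth`) so
other regimes can be configured.

## Greedy RMSD clustering

Pairwise decoy pools and GA generations are both de-duplicated by the same
greedy scheme. Two members are *neighbors* when their distance is strictly
below the cutoff. Repeatedly: the member with the most unclustered neighbors
becomes a cluster center (ties: better quality, then lower index); the
cluster is the center plus its unclustered neighbors; the member with the
best quality in the cluster (ties: lower index) is emitted as its
representative and the cluster is removed.

Two metrics/qualities instantiate this scheme:

* **Pairwise decoy pools** (`clusterDecoys`, cutoffs typically 5 or 10
  Angstrom): distance is the *ligand* C-alpha RMSD — the RMSD between the
  two placements of the mobile subunit with the receptor frame shared and
  **no** re-superposition (re-superposing would collapse genuinely
  different placements). Quality is the decoy's shape score.
* **GA generations** (`selectPopulation`, default cutoff 10 Angstrom):
  distance is the superposed global C-alpha RMSD between assembled models;
  quality is (negated) fitness.

The tie-break rules and the strict `<` neighbor relation are fixed so that
the output is fully deterministic; a brute-force re-implementation of the
same rules is kept in the test suite as an independent oracle.

Cost accounting: a clustering pass over $k$ members counts $k^2$ distance
evaluations (each member's neighbor row scans the whole pool). This makes
the cost of the clustering step — the only quadratic step in a generation —
hardware-independent and testable: pools of 600 vs 400 cost exactly
$(600/400)^2 = 2.25$ as much.

## Fitness

The fitness of an assembled model is a weighted linear combination of three
inter-subunit interaction terms (lower is better), evaluated over all
subunit pairs with intra-subunit terms excluded (rigid subunits make them
constant):

* a 12-6 Lennard-Jones **van der Waals** term (8 Angstrom cutoff) with
  per-element radii and well depths; below $0.6\,\sigma$ the potential
  continues linearly so a single deep clash cannot dominate the total;
* a Coulomb **electrostatic** term $q_i q_j / (4 r^2)$ with
  distance-dependent dielectric $\varepsilon = 4r$ (12 Angstrom cutoff) and
  unit charges on standard charged groups (carboxylate oxygens $-0.5$ each,
  Lys NZ $+1$, Arg NH1/NH2 $+0.5$ each, His neutral);
* a **knowledge-based contact** term: a symmetric $5 \times 5$ potential
  over the atom classes {nonpolar C, polar-adjacent C, N, O, S} summed over
  heavy-atom pairs within 4.5 Angstrom.

All parameters — radii, well depths, charges, the contact matrix, cutoffs
and weights (default 1/1/1) — live in a plain-text parameter file shipped
with the package (`system.file("extdata", "score_params.txt", package =
"TreeDock")`), so published parameter sets can be substituted without
touching code. The functional forms and cutoffs are this package's own
concrete choices for a desk-scale three-term potential; no claim of
energetic accuracy against any published force field is made, and the
default weights are deliberately unnormalized — users calibrating against a
reference scoring function should adjust them. The terms are verified to be
invariant under global rigid motion and subunit relabeling, and exactly
linear in the weights.

For validation of the *search engine* independent of this physics stand-in,
`runGA(fitness = "oracle")` scores a model by its superposed C-alpha RMSD
to a supplied native structure.

## Evaluation metrics

`superposedCaRmsd` computes the global C-alpha RMSD after one closed-form
least-squares superposition (Kabsch/SVD) of the whole complex; no per-chain
fitting and no chain-permutation search (correspondence is positional, the
i-th C-alpha of the i-th subunit). A model within 2.5 Angstrom of the
native is classed **near-native**. `fnat` is the CAPRI fraction of native
contacts: native contacts are inter-subunit residue pairs with any
heavy-atom pair within 5 Angstrom, and fnat is the fraction of them the
model reproduces. For homomeric complexes a chain-swapped model scores
poorly under positional correspondence; permutation-aware matching is
deliberately out of scope.

## The synthetic fixture generator

Real benchmark complexes would require an external pairwise docking stage,
so the package generates its own test problems end to end:

* **Subunits** are compact random point clouds ("blobs"): each residue
  contributes a C-alpha and one side-chain heavy atom, with a sprinkling of
  charged Asp/Lys residues (70/15/15 Ala/Asp/Lys). Points are uniform in a
  ball whose radius is set so the blob's radius of gyration matches the
  empirical scaling for globular domains, $R_g \approx 2.2\,N^{0.38}$
  Angstrom for $N$ residues — this keeps whole-model RMSDs, and hence the
  behaviour of the 5/10 Angstrom clustering cutoffs, on a realistic scale.
* **The native complex** places the subunits in a chain with randomized
  orientations, adjusting each interface distance until the pair shares at
  least 5 residue contacts at 5 Angstrom while the closest heavy-atom
  approach stays at or above 3 Angstrom (a physical contact distance;
  tighter packing would turn the native into a steric clash that the van
  der Waals term rightly penalizes). Subunits are returned in their own
  local frames, as individually solved structures would be.
* **Decoy pools**: for each pair in contact in the native, decoy 1 is the
  exact native relative transform, optionally perturbed by a configurable
  rotation (degrees, about a random axis through the placed ligand
  centroid) and translation (Angstrom, random direction); the remaining
  decoys are uniformly random orientations placed on the receptor's
  surface, resampled a bounded number of times to avoid deep overlap.
  Non-contacting pairs get all-random pools. Shape scores mix a
  standardized negative ligand-RMSD-to-native with Gaussian noise in
  proportion `scoreSignal`: at 1 the planted decoy always scores best, at 0
  the score is pure noise.

The **standard fixture** (`standardFixture`) is 4 subunits of 60 residues,
200 decoys per pair, the exact native planted (noise 0) and `scoreSignal`
0.5 — matching a four-chain complex at a pool size small enough for
desk-scale runs. Everything is deterministic per seed.

What passing tests on this generator do and do not show: the blobs exercise
the full search, clustering, scoring and evaluation machinery under
realistic geometry, but they are not folded proteins — there are no
backbone connectivity constraints, no realistic side-chain chemistry, and
the planted decoy makes the global optimum known by construction. Results
on the fixture validate the algorithmics, not docking accuracy on real
complexes.

## Numerical choices

* Rotations are validated orthonormal (det $+1$) to $10^{-6}$; composition
  chains re-project to the nearest rotation (SVD) when drift exceeds that.
* The single-pair superposed RMSD uses the explicit-rotation residual
  rather than the trace identity, so identical structures give 0 to
  machine precision. The all-pairs RMSD matrix inside the
  within-generation clustering — the quadratic hot path — uses a
  closed-form 3x3 eigenvalue solution of the same Kabsch problem, which
  agrees with the SVD route to about $10^{-15}$ and avoids a LAPACK call
  per pair.
* Energy neighbor search is a vectorized all-pairs computation under the
  term cutoffs; at the subunit sizes this package targets (tens to a few
  hundred atoms) this is faster in practice than maintaining a cell grid,
  and it *is* the reference semantics a spatial index would have to
  reproduce.
* The transform-file writer prints `%.10g`, so write-read round trips are
  faithful to well below $10^{-6}$.
* Degenerate inputs: a clustering pool of one returns itself; fnat of a
  native with no inter-subunit contacts is defined as 1 with a warning;
  2-subunit mutation always redraws the single pair's decoy.
* All stochastic operations draw from R's global RNG; `runGA` seeds it once
  from its config, so a seed fully determines a run (the trace test asserts
  bitwise-identical reruns).

## Design choices on genuinely open points

* **Root convention.** Assembly roots at the lowest subunit index, which
  keeps its input coordinates. Any fixed convention works because all
  downstream metrics superpose; tests assert re-rooting changes nothing
  beyond a rigid motion ($< 10^{-6}$ Angstrom after superposition).
* **Edge directionality.** Decoys are stored once per ordered pair
  $(i, j)$, $i < j$; traversing an edge against storage order applies the
  exact inverse transform. Storing one direction halves the library.
* **Mutation's reconnection distribution** is uniform over
  component-crossing pairs, constructed directly (no rejection loop); this
  includes re-selecting the deleted pair.
* **Mutation count.** "Doubling" the pool is realized as exactly one
  mutant per member of the expanded pool, which makes the count
  deterministic; for non-unit `mutationGrowth` the mutants' sources are
  drawn uniformly.
* **Crossover pairing** draws uniformly random distinct parent pairs;
  children number `round(crossoverGrowth * pool)`.
* **Selection** is strict truncation (cluster representatives ranked by
  fitness, top $M$); no roulette or tournament variants. When clustering
  leaves fewer than $M$ representatives the population shrinks for that
  generation and the next expansion starts from the survivors.
* **Within-generation metric** is the superposed global C-alpha RMSD — the
  same metric used for evaluation — with one shared greedy clustering
  implementation behind both metrics.
* **Termination** is a fixed generation budget, plus an optional
  RMSD-to-native early stop used in validation mode only.
* **Pairwise clustering atoms.** Ligand-only C-alpha RMSD (the receptor
  frame is shared, so receptor atoms contribute nothing); the ligand
  C-alpha set is an explicit argument, so sensitivity checks with other
  atom subsets are possible.

## Problem sizes used by the shipped checks

The test suite and the acceptance script run entirely on generated
fixtures: pool-arithmetic and cost-ratio checks use 12-residue subunits
(the arithmetic is size-independent); operator-distribution checks use
10,000-20,000 draws against enumeration oracles; the planted-native
recovery experiment runs the standard 4 x 60-residue fixture for up to 200
generations over ten (suite) or five (acceptance script) seeds with the
RMSD early stop. On one CPU the full suite completes in roughly a quarter
hour, dominated by the recovery experiment.

## Known limitations

* Subunits are strictly rigid; no backbone or side-chain flexibility, no
  refinement of the final population.
* The scoring stand-in is configurable but not calibrated; rankings on real
  complexes should use an externally validated parameter set.
* No chain-permutation-aware RMSD for homomers.
* The pairwise decoy libraries are inputs (or synthetic); the package does
  not perform pairwise docking itself.
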