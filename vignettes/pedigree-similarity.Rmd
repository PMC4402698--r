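---
title: "Comparing two-generation pedigrees: model, solvers and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing two-generation pedigrees: model, solvers and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedcmp)
```

## The data model and its axioms

A pedigree here is a directed graph of individuals with a sex function,
edges running parent → child, under four axioms: the graph is acyclic;
every individual has in-degree 0 (a founder) or 2; the two parents of any
child have opposite sexes; and no individual is isolated. Violations are
reported as data by `validate_pedigree()` rather than thrown, because
malformed files are an expected input, not a programming error. Isolated
individuals found in a PED file are dropped with a warning — they carry
no relational information.

A pedigree is *generational* when a function g exists with g = 1 on every
founder and g(child) = g(parent) + 1 along every edge; inter-generational
matings make the constraints inconsistent, and `assign_generations()`
then returns `NULL`. Everything downstream is restricted to
two-generation pedigrees (max g = 2). One modeling consequence worth
noting: a generation-1 individual without a mate cannot occur in this
model, because it would be isolated — every edge points at a child with
two parents.

Identifiers are opaque strings used only for file round-tripping; all
comparisons treat pedigrees as unlabeled. Serialization sorts individuals
lexicographically so outputs are byte-stable.

## Families and the two comparison regimes

`families_of()` groups the second generation by (unordered) parent
couple: a couple with i daughters and j sons is an ⟨i, j⟩-family.
Families may share a parent but never a child, so Σ(i + j) over families
equals the number of generation-2 individuals, sex-wise. The family
multiset is kept in lexicographic (i, j) order; the whole pedigree is
decomposed at once, components are not treated specially.

For monogamous pedigrees (every generation-1 individual in exactly one
couple) the pedigree is a disjoint union of families and isomorphism
reduces to multiset equality of the ⟨i, j⟩ pairs, decided by a two-pass
sort (`monogamous_isomorphic()`). Sexes are never interchangeable: ⟨2,1⟩
and ⟨1,2⟩ families differ. For general two-generation pedigrees exact
isomorphism is as hard as bipartite graph isomorphism —
`pedigree_from_bipartite()` realizes the embedding (males on one side,
females on the other, one all-female single-child family per edge) and
the test suite checks both transfer directions against the brute-force
oracle — so the package deliberately offers no general fast isomorphism
test, only the similarity relaxation below and a capped exhaustive
oracle.

## The similarity model: minimum common pair partitions

Two family multisets S and T with equal projection sums are compared by
the smallest multiset H of ⟨g, h⟩ pairs that refines both: every tuple of
S, and independently every tuple of T, must be the componentwise sum of
the pieces of H assigned to it. The size |H| is the similarity score
(|H| = |S| iff the multisets coincide); the assignment exhibits the
matching sub-families, and a generation-1 couple may appear in several
sub-families. Pedigrees whose generation-2 sex totals differ admit no
common partition and are reported *incomparable* rather than silently
scored. Pairs are non-negative; ⟨0, b⟩ and ⟨a, 0⟩ pieces are meaningful
(a sub-family with children of one sex), ⟨0, 0⟩ is never allowed.

### Heuristic

Two local moves drive the heuristic (`heuristic_mcipp()`):

* *dominating step*: if s ≥ t componentwise, emit t and keep the
  residual s − t (both removed when equal);
* *non-dominating split*: for incomparable s, t with s₁ > t₁, s₂ < t₂,
  emit ⟨t₁, s₂⟩ and keep the zero-padded residuals ⟨s₁ − t₁, 0⟩ and
  ⟨0, t₂ − s₂⟩.

Both moves conserve the projection sums on both sides (a property test
asserts this across random runs). The heuristic applies dominating steps
while any exist; when none does and both sides still hold ≥ 2 tuples it
brute-forces a non-dominating starting pair from which the remainder can
be finished by dominating steps alone, and applies one split. When one
side is down to a single tuple the other side is emitted verbatim. The
result is always a valid common partition of size at most |S| + |T|, and
since no partition can be smaller than max(|S|, |T|), the heuristic is a
factor-2 approximation; both bounds are attached to every result as a
certificate.

Three details the terse statement of the moves leaves open, resolved
here:

* **Tie-break.** "Select a dominating pair" is nondeterministic; the
  package always takes the lexicographically smallest (s, t). Determinism
  beats cleverness for reproducibility, and correctness does not depend
  on the choice.
* **Degenerate splits.** A non-dominating pair of the shape (x, 0) vs
  (0, y) would emit the forbidden ⟨0, 0⟩ piece and leave the instance
  unchanged, looping forever. Such pairs are ineligible; whenever no
  dominating pair exists an eligible split can be shown to exist, so
  this costs no generality.
* **"Leads to successive dominating pairs".** Operationalized in two
  layers: a cheap probe that replays the deterministic dominating-step
  rule, then, if no start passes the probe, an exhaustive memoized
  search over dominating-step choices (`dom_only_completable()`). On the
  bundled 3-vs-3 instance exactly 4 of the 9 starts are completable in
  this sense and the remaining 5 peak at a size-7 partition
  (`mcipp_start_analysis()` recomputes this classification).

### Exact search

`exact_mcipp_fpt()` answers the decision question "is there a common
partition of size ≤ k" by depth-bounded branching, and
`mcipp_optimize()` wraps it in iterative deepening from max(|S|, |T|) to
|S| + |T|. Each node pivots on the tuple attaining the minimum first
component over both sides (tie-break: minimum second component) and
branches over every piece that tuple can contribute, jointly subtracted
from every candidate opposite-side source. Completeness needs no
structural lemma: any common partition must assign the pivot at least
one piece, and all of them are enumerated. Budgets below the
max(|S|, |T|) lower bound are refused outright, failed states are
memoized per budget, and candidate pieces are ordered greedy-first (the
whole pivot tuple, then the piece anchored at the global componentwise
minima, then decreasing size), so the cheap greedy descent is the fast
path.

A design note on why the branching is this wide. For *integer*
multisets, the classical minimum-element property holds: some optimal
common partition contains the smallest element of A ∪ B unsplit, which
is what `exact_mcip_fpt()` branches on (only the choice of opposite-side
element to subtract from). One might hope the pair case admits the
analogous narrow rules — commit a whole minimum-attaining input tuple,
commit the piece joining the two componentwise minima, or at least keep
the minimum component in a single piece. All of these fail, and the test
suite pins concrete refutations computed with the exhaustive oracle: on
the 3-vs-3 instance S = {⟨9,4⟩, ⟨1,11⟩, ⟨6,3⟩},
T = {⟨2,8⟩, ⟨12,1⟩, ⟨2,9⟩} (optimum 6) no optimal solution contains
⟨1,11⟩ or ⟨12,1⟩ (no opposite tuple dominates them) nor the minima piece
⟨1,1⟩ (forcing it costs 7); and on S = {⟨4,3⟩, ⟨7,5⟩},
T = {⟨2,6⟩, ⟨3,0⟩, ⟨3,1⟩, ⟨3,1⟩} (optimum 5) every optimal solution
splits the first component of the minimum tuple ⟨2,6⟩ as ⟨1,3⟩ + ⟨1,3⟩.
Correctness therefore comes from full pivot enumeration, and the narrow
rules survive only as the preferred ordering. The search is still
effectively parameterized by k through the depth bound, the lower-bound
prune and the per-budget failure memo.

Two further conventions: tuples common to S and T are moved into the
solution up front (they belong to some optimal solution as-is, by the
merging argument), and returned optimal partitions are post-merged so
that no two pieces share the same (s, t) source pair — two such pieces
would merge into a strictly smaller partition — then re-validated.

The integer solver `exact_mcip_fpt()` keeps the narrow minimum-element
branching, which *is* sound for positive integers; the suite checks both
the oracle equivalence and that an optimal solution containing the
global minimum is always reachable.

### Oracles

The reference implementations share no search code with the fast paths,
so agreement is a meaningful certificate. `brute_force_mcipp()` pivots
on the first tuple of the canonical S and enumerates every piece and
every opposite source, iteratively deepened so the first succeeding
budget is the optimum; `brute_force_mcip()` does the analogous
enumeration for integers; `pedigree_isomorphic_bruteforce()` backtracks
over sex-preserving bijections pruned by (sex, in-degree, out-degree)
classes and returns a checkable witness. All three refuse inputs above
documented caps (projection sums 25 and 4 tuples per side; instance sum
40; 12 individuals) — they exist as ground truth, not for performance,
and the caps keep the exhaustive grids cheap. Memoization is toggleable
and tested to leave answers unchanged.

A related size bound is stated strictly in some presentations
(optimum > max(|S|, |T|)); equality is clearly attainable (S = T), so
the package implements and certifies the non-strict form.

## The synthetic generators

The generators exist so every solver is testable without external data;
all take an explicit seed and are byte-reproducible.

* `gen_planted_mcipp()` draws `n_pieces` tuples componentwise uniform on
  0..`max_value` (rejecting ⟨0,0⟩) and groups them randomly into the two
  sides, so feasibility holds by construction and the pieces certify
  optimum ≤ `n_pieces`. Defaults (`max_value` 6, small sides) keep
  oracle certification fast; the acceptance grid uses sides up to 4 and
  per-projection sums up to 25, about 600 seeded instances.
* `gen_random_pedigree()` builds mating couples; with probability
  `polygamy_rate` a parent slot reuses an existing generation-1
  individual of the right sex. Child counts default to 1 + geometric
  (mean 2, minimum 1) — small families that keep brute-force
  cross-checks within the 12-individual oracle cap — and child sexes are
  uniform. The generated family counts are recorded as ground truth and
  compared against `families_of()`.
* `gen_bipartite_pair()` yields graph pairs that are relabeled copies or
  perturbed and *certified* non-isomorphic by exhaustive side-preserving
  search (sides ≤ 5).

What the generators deliberately do not emulate: realistic demography
(age structure, mate choice, family-size correlations), genotypes, or
missing-parent noise. Passing tests certify the combinatorial machinery
— decomposition, solvers, bounds — on structurally valid pedigrees; they
say nothing about robustness to data errors upstream of the PED file.

## Numerical and interface choices

* Multisets are integer matrices in canonical lexicographic row order;
  all equality tests are on canonical forms, so results are independent
  of input order.
* Problem sizes in the test suite (pedigrees ≤ 12 individuals for the
  isomorphism oracle, instance sides ≤ 4 and sums ≤ 25 for the partition
  oracles, ~600-instance grids) were chosen so the exhaustive
  ground-truth runs stay in the tens of seconds while still exercising
  every branch shape; the solvers themselves accept larger inputs.
* The CLI distinguishes informative negatives ("false", "no solution"),
  which exit 0, from usage and validation errors (unreadable file,
  invalid pedigree, infeasible instance), which exit 2 — scripts can
  pipe answers without parsing error text.
* PED dialect: 4 mandatory tab-separated columns (id, father, mother,
  sex as 1/2), `0` for missing parents, both parents present or both
  absent, `#` comments. This is the minimal unambiguous subset of the
  ubiquitous PED convention; family and phenotype columns are out of
  scope.

## Known limitations

* Pedigrees with three or more generations are accepted by the data
  model but rejected by every comparison operation.
* The exact solvers are exponential in the solution size; family
  multisets from cohorts with hundreds of large families need the
  heuristic (factor-2 certified) rather than the exact search. Known
  sharper approximations for the integer problem are not implemented.
* `similarity_mcipp()` requires equal sex-wise child totals; there is no
  partial-credit score for incomparable pedigrees.
* The brute-force isomorphism oracle is exponential and hard-capped; it
  is a certification device, not an end-user isomorphism test.
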