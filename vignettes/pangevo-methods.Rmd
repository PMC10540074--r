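---
title: "Models and methods behind pangevo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pangevo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

pangevo implements the comparative layer of a genus-scale evolutionary
genomics study: genomic-species delineation from average nucleotide
identity (ANI), pangenome partitioning and openness, ancestral gene-content
reconstruction, and per-orthogroup selection metrics. This vignette
documents the models, the tunable parameters and their defaults, the
numerical choices, and what the built-in simulators do and do not emulate.

## Genomic species: thresholded ANI graph + Markov clustering

Pairwise ANI values are percentages in [0, 100]; 95% is the conventional
intra-species boundary for bacterial genomes and is the default threshold.
ANI estimates are mildly asymmetric (A→B need not equal B→A), so
`build_ani_graph()` keeps an undirected edge when **either** direction
reaches the threshold and weights it with the mean of the available
directions — the most inclusive deterministic rule, stamped into the run
manifest. Self-comparisons are dropped; genomes mentioned only below
threshold remain as isolated nodes.

`mcl()` is a from-scratch Markov Cluster implementation: a
column-stochastic matrix over the (sorted) genomes, alternating expansion
(matrix power, default e = 2) and inflation (elementwise power, default
r = 2.0, renormalized), pruning entries below 1e-6, until the maximum
column change falls below 1e-6 or 200 iterations. These are the classic
MCL defaults; the clustering program the workflow descends from does not
publish the parameters it was run with, so the defaults are recorded in
every output. Each node's self-loop weight is its maximum incident edge
weight (1 for isolated nodes), which guarantees aperiodicity. Clusters are
read off the attractor structure; overlaps are resolved by largest
membership weight, then lexicographically, so the partition is unique and
reproducible. Because expansion cannot create probability mass between
disconnected blocks, MCL here can only ever refine the connected
components of the thresholded graph — the test suite asserts this against
a union-find oracle. Weighted edges are the default; `binary_edges = TRUE`
clusters the pass/fail graph instead, since it is genuinely unknowable
from the published description which variant the original analysis used.

## Pangenome partitioning and openness

With k the number of genomes carrying an orthogroup and f = k/N, classes
are assigned by the first matching rule:

1. k = 1 → unique
2. f = 1 → core
3. f ≥ 0.90 → soft-core
4. f ≥ 0.15 → shell
5. k ≥ 2 → cloud

The published class boundaries are phrased in percentage bands
("between 99.999 and 90%", "between 89 and 15%", "14% down to two
strains"); we interpret them as half-open fraction intervals
[0.90, 1), [0.15, 0.90) plus the count rules. Putting the count rules
(unique, cloud) at the precedence positions shown keeps the classes
exhaustive and mutually exclusive for every N — including small N, where
a single genome already exceeds 15% — which the tests verify by exhaustive
(N, k) enumeration up to N = 30 against an independently coded rule set.

`accumulation_curve()` draws `n_permutations` (default 1000) random genome
orders and records the cumulative pangenome size; the fit target of
`fit_power_law()` is the **mean** cumulative curve, not per-permutation
fits and not the new-genes-per-genome curve. Columns are put in a
canonical (sorted-name) order before permuting so the curve depends on the
genome set, not on incidental column order. The Heaps model y = a·x^γ is
fitted by Levenberg–Marquardt least squares (start a = y₁, γ = 0.3,
tolerances 1e-10); γ < 0.05 on clonal matrices and γ ∈ [0.98, 1.02] on
fully disjoint matrices are verified as limiting cases, and noiseless
power-law data is recovered to at least four significant figures. An
exponent in (0, 1) is reported as an open pangenome.

COG enrichment compares the core against the pooled accessory fraction
(soft-core + shell + cloud + unique). An orthogroup's category set is the
union of its member genes' root-level COG letters, so a multi-letter
orthogroup counts once in each category; orthogroups with no annotation
carry the `@` pseudo-category and stay in the denominators. Whether such
percentages should count families or genes is not specified in the kind of
study this package reproduces; both are available (`unit = "family"`
default, `"gene"` alternative). Calls: core-enriched at log2 ≥ 1,
core-depleted at ≤ −1, undefined when either percentage is zero.

## Ancestral gene content by Wagner parsimony

`wagner_reconstruct()` runs per-family Sankoff dynamic programming over
the binary states {absent, present} with penalties gain = loss = 1 by
default (both configurable). The bottom-up pass computes
cost(v, s) = Σ_children min_t [cost(child, t) + penalty(s→t)];
multifurcations are handled natively by the sum. Tie policy: at the root,
ties prefer absence (default), which avoids inflating ancestral genome
sizes; in the traceback, ties prefer the parent's state, which minimizes
spurious gain/loss pairs on sibling edges. Both choices are deterministic
and recorded. Branch lengths are ignored — this is the parsimony stage
only; probabilistic birth–death rate optimization is out of scope.

Correctness is established by brute force: for every rooted binary labeled
topology with 3–6 leaves (1068 trees, enumerated with phangorn) plus a
fixed set of multifurcating 6-leaf trees, and every binary leaf pattern,
the reconstructed cost equals the exhaustive minimum over all internal
labelings. The full enumeration of multifurcating topologies at six leaves
(2752 trees) is omitted to keep the check under a minute; the binary
enumeration plus the fixed multifurcating set already exercises every code
path, including the multifurcation sum.

`simulate_recovery_check()` compares reconstructed per-edge event counts
to a simulation's true log. True counts are restricted to families present
in at least one leaf: a family that went extinct everywhere leaves no
trace in the observable matrix and is unreconstructable in principle, so
including it would measure the simulator's burial rate, not the
reconstruction.

## Tajima's D and group comparisons

`tajimas_d()` computes D = (π − S/a₁)/√(e₁S + e₂S(S−1)) with the standard
constants for sample size n. Gap and ambiguity handling is
complete-column deletion: any column containing a character outside
A/C/G/T is excluded from both S and π identically — the conservative
convention, recorded in output metadata. D is undefined (flagged, never
silently dropped) when S = 0 or n < 4, so denominator choices in
downstream comparisons stay explicit. The implementation is checked to
1e-10 against a second, independently written evaluation of the same
formulas on 50 coalescent samples, and calibrated on 1000 neutral
replicates (n = 20, θ = 5), where the mean defined D must lie in
[−0.2, 0.1]. D is computed per orthogroup on within-cluster sequences
only; pooling across clusters would conflate divergence with diversity.

`compare_groups()` scores U = Σ pairs [1 if a > b, 0.5 if tie] and reports
CLES = U/(n₁n₂). The two-sided p-value uses the exact tie-free U null
distribution when there are no ties and n₁n₂ ≤ 400, otherwise the
tie-corrected normal approximation with continuity correction; both paths
agree within 0.01 near the switch point. Exact enumeration under ties is
combinatorially infeasible at the switch point and is not attempted.

## dN/dS, Tajima–Nei distances, and the selection screen

The pairwise dN/dS engine is the Nei–Gojobori (1986) counting method with
Jukes–Cantor correction, chosen because it is fully specifiable and has an
exact brute-force oracle (pathway enumeration), and it supports the
downstream two-fold screen unchanged; the engine name is stamped into all
outputs. Site opportunities are fractional (each of the three changes per
position carries weight 1/3) and averaged over the two sequences. Changes
to stop codons contribute no site opportunity — consistent with the codon
chain used for validation, in which stop states are excluded. For codons
differing at 2–3 positions, difference counts are averaged over all
single-step pathways, excluding pathways through stop codons (falling back
to all pathways only if every one is blocked). Codons containing gaps, N,
or a stop in either sequence are skipped pairwise. Saturation
(p ≥ 3/4) flags the pair unusable rather than producing a complex
logarithm. NG86 is known to be biased under transition/transversion
asymmetry; recovery tests therefore use κ = 1, where the median ω̂ over
200 simulated pairs (300 codons, divergence 0.2) must fall in [0.85, 1.15]
for true ω = 1 and [0.14, 0.30] for true ω = 0.2.

`tajima_nei_pair()` implements the 1984 distance
d = −b·log(1 − p/b), with b computed from the pooled base frequencies and
the pair-frequency term h; it reduces to Jukes–Cantor in the
equal-frequency limit (verified within 1e-3) and flags excess divergence
(p ≥ b) as unusable.

The filter policy drops, in any order and idempotently: unusable pairs,
pairs at zero distance, ω > 5, dS > 10, and (by default) same-cluster
pairs. "Zero distance" is applied to the Tajima–Nei distance — the
quantity introduced in the same breath as the rule — not to dS. Removal
reasons are tallied per rule in the run report.

`selection_screen()` compares two clusters' ω multisets, each member
measured against the **same** designated outgroup sequence (when the
outgroup carries paralogs, the one with the smallest median Tajima–Nei
distance to the ingroup is chosen, ties by ID). An orthogroup is flagged
only when |log2(median ratio)| > 1 **and** Mann–Whitney p < 0.05. The
default comparison mode is ingroup-versus-outgroup per cluster; whether
ingroup-versus-ingroup cross-cluster pairs should also enter is ambiguous
in the workflow this reproduces, and the per-cluster-versus-outgroup mode
is the one that keeps the two ω multisets on a common yardstick.

## What the simulators emulate — and what they do not

All generators are seed-deterministic (identical configuration + seed ⇒
byte-identical output) and never perturb the caller's RNG stream.

* `simulate_gene_content()`: root families ~ Poisson(λ₀); along each edge
  of length t families survive with probability exp(−μt) and
  Poisson(σt) new families are born, each once globally
  (infinitely-many-genes). This keeps ground truth unambiguous for
  recovery tests but departs from biology: no re-gain after loss, no
  horizontal transfer, no duplication states.
* `simulate_coalescent()`: the standard n-coalescent with infinite-sites
  mutations mapped onto L finite sites (warning when E[S] > 0.1·L). It is
  calibrated against E[S] = θa₁ and E[π] = θ within 5% at n = 10, θ = 5,
  2000 replicates. No recombination, no demography.
* `simulate_codon_pair()` / `simulate_codon_orthogroup()`: exact
  event-by-event stochastic simulation of a GY94-style chain
  (single-nucleotide codon moves, ×κ transitions, ×ω nonsynonymous, stops
  excluded), normalized to one expected substitution per codon per unit
  time at stationarity, so divergence parameters are in
  substitutions/codon. Realized substitution counts by type are returned
  as ground truth. In the orthogroup generator all members of a cluster
  share the founder branch, so their ω estimates against the outgroup are
  correlated — exactly as real within-species sequences are
  phylogenetically correlated. A single founder draw can therefore shift a
  whole cluster's ω multiset; the planted five-fold contrast used for
  validation (ω 1.0 vs 0.2, 19 members, 200 codons) carries that variance
  with margin, and under the null (equal ω) the joint two-fold + p < 0.05
  rule flags at most 7% of 200 replicates.
* `simulate_ani_table()`: truncated-normal within/between distributions
  (defaults 97.5 ± 0.8 truncated at ≥ 95.5, and 82 ± 3 truncated at
  ≤ 92) with independent per-direction jitter clamped back into the class
  bounds — so thresholding at 95 provably leaves zero between-cluster
  edges and recovery must equal the planted partition. Real ANI noise is
  not truncation-bounded; this generator validates the clustering
  machinery, not FastANI.
* `make_fixture()`: a complete miniature study (default 4 clusters × 5
  genomes, ~300 root families, 120-codon genes) whose files feed every
  pipeline stage; dimensions were chosen so the full test suite runs in a
  few minutes on one CPU.

Passing tests on these generators demonstrate correctness of the
algorithms under the stated models; they do not demonstrate robustness to
assembly artifacts, annotation error, recombination, or orthology
misassignment in real data.

## Verification problem sizes

The test suite and the acceptance script use: 1068 + 8 enumerated trees ×
all leaf patterns for parsimony; 50 dual-implementation alignments and
1000 neutral replicates for Tajima's D; the exhaustive ≤ 2-position codon
pair sweep plus 2 × 200 recovery replicates for NG86; 1 planted + 200
null screen replicates; 100 planted ANI trials; exhaustive (N ≤ 30)
partition enumeration; 2000 coalescent calibration replicates; and a
byte-identity rerun of the fixture study. These sizes are the package's
reference conditions and are reproduced verbatim by
`scripts/acceptance.R`.

## Known limitations

* ANI computation itself, genome QC, annotation, and orthology inference
  are upstream inputs, not reproduced here.
* The dN/dS engine is counting-based; it will underestimate ω under
  strong transition bias and does not model codon-frequency or site-class
  variation.
* Wagner parsimony reports one optimal labeling under deterministic tie
  policies; co-optimal histories are not enumerated.
* The MWU exact path requires tie-free data; heavily tied small samples
  fall back to the normal approximation.
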