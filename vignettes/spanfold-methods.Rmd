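---
title: "Span-constrained RNA structure ensembles: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Span-constrained RNA structure ensembles: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spanfold)
```

## The ensemble

spanfold computes expected values over the Boltzmann ensemble of RNA
secondary structures in which every base pair `(k, l)` is canonical
(`AU, UA, CG, GC, GU, UG`), hairpin loops contain at least three unpaired
bases (`5 <= l - k + 1`), and the pair span is bounded: `l - k + 1 <= W`.
The span constraint restricts the ensemble to locally folded structures
and is what makes genome-length inputs tractable: the inside tables only
ever cover subsequences of length `O(W)`, so the total work is
`O(N W^2)` rather than `O(N^3)`.

Every structure decomposes uniquely into *outermost pairs* — pairs not
enclosed by any other pair — and exterior unpaired stretches between
them. Writing positions as gap coordinates (`(i, j)` pairs residues
`(i+1, j)`), the set of potential outermost pairs is
`P = {(i, j) : (x[i+1], x[j]) canonical, 5 <= j - i <= W}`.

Structures are scored by a nearest-neighbour loop model: stacking
energies per adjacent pair, length-dependent hairpin/bulge/internal-loop
penalties (log-extrapolated beyond the tables, capped at a total
internal-loop size of 30), and affine multiloops
`a + b * branches + c * unpaired`. Every Boltzmann factor is
`exp(-dG / RT)` at `T = 310.15` K. Two deliberate simplifications, both
configurable, keep the model minimal: no dangling-end or mismatch terms
(`dangle_mode = "none"`; a simplified terminal non-CG penalty on exterior
and multiloop branches can be switched on), and no prohibition of lonely
pairs. The bundled parameter file carries Turner-style stack values
satisfying thermodynamic symmetry; since all validation compares the
engine to an exhaustive-enumeration oracle *under the same model*,
algorithmic correctness is decoupled from parameter richness.

## Grammar and inside–outside

The engine uses a six-state unambiguous grammar: `Outer` (exterior),
`Stem` (region under an outermost or nested pair), `StemEnd` (the loop
closed by a pair: hairpin, internal/bulge with at least one unpaired
base — stacking is handled by `Stem` directly — or multiloop), and three
multiloop states: `Multi` (full interior, two or more branches, split
before the last branch), `Multi1` (one or more branches, decomposed by
the last branch), `Multi2` (exactly one branch plus trailing unpaired
bases). Unambiguity matters because probabilities are sums over
derivations; it is enforced empirically by requiring the grammar's
partition function to equal the oracle's structure-by-structure sum on
every fixture.

All sums of Boltzmann terms are log-sum-exp; no linear-scale partition
value is ever stored.

## Ratio dynamic programming

For long sequences the exterior quantities `alpha_Outer(j)` (partition
function of the prefix) and `beta_Outer(j)` (suffix) grow exponentially
with `N`, while every probability is a ratio of such quantities. spanfold
therefore stores only the per-position fold changes

* `Dalpha(h) = alpha_Outer(h+1) / alpha_Outer(h)`
* `Dbeta(h) = beta_Outer(h) / beta_Outer(h+1)`

as logs (the `ratio_db`). Both are computed by a direct-ratio recursion:
dividing the `Outer` recursion by `alpha_Outer(j-1)` expresses
`Dalpha(j-1)` through the previous `W` fold changes and the banded
`Stem` values only, so every stored quantity is bounded in magnitude
independent of `N` (empirically `max |log Dalpha| ~ 5.5` at `W = 50`
for random sequences of any length).

All probabilities are recovered through the locally reconstructible
ratio `r(i, j) = Z / (alpha_Outer(i) beta_Outer(j))`, a sum over the
anchor set `S(i)` of exterior block weights
`u(p, q) = t(Outer->Outer.Stem) exp(alpha_Stem(p, q))` (or the unpaired
step weight) times products of at most `W` fold changes. The outside
variables are rebuilt directly on the probability scale,
`beta_sigma(k,l)/Z`, by seeding the banded outside recursion with
`t(Outer->Outer.Stem) / r(i, j)` at every potential outermost pair; the
engine evaluates `r(j, j)` for every `j` in `O(W^2)` each and shifts by
local `Dalpha` products. Base-pairing probabilities, stem probabilities
(`p_stem(i) = sum_j p(i, j)`; accessibility is `1 - p_stem`) and the
six-way structural profile (stem / bulge / exterior / hairpin /
interior / multi, attributed strictly by paired-versus-unpaired status
and the branch count of the enclosing loop) all come out of this single
outside pass, accumulated with range-update arrays so the pass stays
`O(N W (W + c^2))` where `c` is the internal-loop cap.

## Divide and Connect

The construction of the fold-change database parallelises over `K`
contiguous segments `(s, e]` (equal tiles of `ceiling(N/K)`; each job
reads at most `W` residues of context either side). A job computes the
partial inside variables `alpha^h_k`: the weight of `x[s-h+1 .. k]`
whose first outermost pair starts at `s - h` (with `alpha^0_k` the
span-respecting partition function of `x[s+1 .. k]`), persisted as the
scale-free ratios `d-alpha^h_k = alpha^h_k / alpha^0_k` together with
the segment-local fold change `R_k = alpha^0_k / alpha^0_{k-1}`. The
`h = 0` row is identically 1 and is not stored. Connect then recovers

`alpha_Outer(k) = sum_h alpha_Outer(s - h) * alpha^h_k`

carried as `C_k = alpha_Outer(k) / (alpha_Outer(s) alpha^0_k)`, giving
`Dalpha(k-1) = (C_k / C_{k-1}) R_k` left to right across segments; the
beta side is the exact mirror, processed right to left. The merged
database agrees with the monolithic recursion to ~1e-13 for every `K`.

The low-disk variant persists only the two boundary windows of `W + 1`
positions per segment (disk `O(N + K W^2)` instead of `O(N W)`); at
merge time each segment's full table is recomputed in memory by the
identical routine Divide uses — the second DP round, costing a second
pass of construction time — so the result is byte-identical to the
standard merge, and the persisted boundary rows double as an integrity
check on the recomputation.

## Downstream analyses

**Gamma-centroid (`gamma <= 1`).** The gain-maximising structure is the
set of pairs with `p(i, j) > 1/(gamma + 1) >= 1/2`. Ties at exactly the
threshold are excluded (strict inequality), which guarantees
well-nestedness without any assembly DP: two conflicting pairs cannot
both exceed 1/2. `gamma > 1` would require a different decoder and is
deliberately unsupported.

**Windowed averages and composition regression.** Raw stem
probabilities are bimodal; means over 32-nt windows are approximately
normal, which is why 32 is the default window. For each non-overlapping
window the design row is `(1/32, #AAAA/32, ..., #UUUU/32)` (257
features; a 32-mer contains 29 overlapping 4-mers, so the count features
of a row sum to `29/32`; windows containing `N` are dropped), and the
ridge criterion `(1/2)||y - Xw||^2 + (lambda/2)||w||^2` is solved in
closed form; `lambda = 0` with the rank-deficient design falls back to
the minimum-norm SVD solution. The residual `Dp_stem = y - Xw` is the
structure propensity beyond sequence composition; subtracting the
compositional part also removes most of the correlation between
neighbouring windows, which is what justifies treating windows as
independent degrees of freedom in rank tests. `k = 4` and `L = 32` are
defaults, not constants. The default penalty is `lambda = 1` on this
feature scale; because the features are counts divided by 32, smaller
designs may need a smaller penalty to avoid over-shrinking (the
command-line `normalize` exposes `--lambda`).

**Splicing comparison.** Exon tables (1-based inclusive, on the
pre-mRNA) map every mRNA position to its pre-mRNA position;
`Dq_stem(i) = p_stem,mRNA(i) - p_stem,pre-mRNA(i)` is summarised per
splice junction by the median and the (unscaled) median absolute
deviation within a 200-nt window, with optional 32-nt sliding averages
computed separately upstream and downstream so windows never straddle
the junction.

**Statistics.** MCC uses the standard `(TP*TN - FP*FN)` numerator;
ROC-AUC is the rank-based pairwise probability with ties counted half;
both Wilcoxon statistics use mid-ranks, tie-corrected variances, no
continuity correction, and are reported on the Z scale (for the sample
sizes these tools target, p-values underflow; Z does not). The rank-sum
test accepts pre-binned input whose result is algebraically identical to
the raw-sample path, so tens of millions of values need memory
proportional to the number of distinct bins. One-sided Bonferroni
control is provided as a threshold transform on Z.

## The synthetic-data generator and the oracle

All tests run on synthetic inputs generated in code: uniform-composition
random sequences with a chosen GC fraction, designed perfect hairpins
(random 5' arm, reverse-complement 3' arm, non-pairing loop), and a toy
two-exon gene whose intron opens with the reverse complement of the
upstream exon tail, so splicing frees that tail and shifts `Dq_stem`
negative near the junction. These fixtures emulate composition, local
helices and junction-coupled refolding; they do not emulate real
transcriptome features such as modified bases, protein binding,
repeat-driven composition bias, or experimentally measured structure, so
passing tests demonstrate algorithmic correctness of the ensemble
computation, not predictive accuracy on cellular RNA.

Ground truth on short sequences (`N <= 25`) is exhaustive enumeration:
every admissible structure is generated by backtracking, scored by an
independent geometric loop decomposition, and summed directly. The
oracle classifies loop types from each structure's geometry with the
same rules the engine's profile uses, giving an
implementation-independent check of the grammar's state semantics.
Internal loops above the size cap are excluded by both codings, so with
all energies zero the partition function equals the admissible-structure
count.

## Numerical choices

* Log-sum-exp everywhere; banded arrays hold `-Inf` for zero weight,
  never `NaN` or `+Inf`.
* Cross-checks between the ratio path and raw log-domain accumulation
  are asserted at 1e-10 in the log domain; engine-versus-oracle
  probability agreement at 1e-9.
* Cumulative sums of `log Dalpha` used to shift `r(j, j)` to `r(i, j)`
  are carried in extended precision so the `O(N)`-magnitude prefix sums
  do not erode the bounded differences.
* Probabilities are reported unclipped; validity (`[0, 1]` within 1e-9,
  profile rows summing to 1) is a test, not a post-hoc correction.
* Degenerate inputs: pairless sequences give unit fold changes, an empty
  pair table and an all-exterior profile; `W` below the minimal pair
  span gives the same; `W >= N` reproduces the unconstrained ensemble.

## Problem sizes used by the test suite

Unit tests run on sequences of 5–600 nt. The end-to-end validation uses
200 random sequences of 8–22 nt at every span for the enumeration
comparison, a 3,000-nt sequence at `W = 100` for K-invariance over
`K in {1, 2, 3, 5, 8}`, a 100,000-nt sequence at `W = 50` for numerical
stability and locality, and a 10,000-nt synthetic mini-genome for the
command-line round trip at `K = 4`. These sizes exercise every code path
(including segment context truncation at both sequence ends) while
keeping the suite's total runtime in minutes; all scale claims are
complexity-driven, so larger inputs change runtime, not behaviour.

## Known limitations

* **Locality is approximate.** Stem probabilities deep inside a long
  sequence are reproduced from a padded subsequence with identical
  flanks, but the agreement at five spans (`5W`) of padding is only
  approximate: for `W = 50`, the maximum absolute difference over a
  200-nt motif is typically around 5e-3, and occasionally a few
  hundredths when a chain of competing helices couples the motif to
  context 250–500 nt away. Ten spans of padding pin the ensemble to
  ~1e-5 or better on the same fixtures. Users extracting windows from
  genome-scale runs should pad accordingly.
* **Composition weights are only partly identifiable.** Overlapping
  4-mer counts obey near-exact linear constraints (counts of k-mers
  sharing a 3-mer prefix/suffix differ only by window-boundary effects),
  so the ridge solution's individual weights carry noise amplified along
  those directions even when predictions, residuals and the identifiable
  component of the weights are accurate. Interpret `Dp_stem` (the
  residual), not single k-mer weights.
* The energy model omits dangles, mismatches, coaxial stacking and
  special hairpin tables; absolute probabilities will differ from
  full-parameter folding engines even though all ensemble algebra is
  exact for the model used.
* `gamma > 1` centroids, suboptimal-structure enumeration and pseudoknots
  are out of scope.
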