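---
title: "Methods: banded profile-HMM alignment and SEP phylogenetic placement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: banded profile-HMM alignment and SEP phylogenetic placement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models implemented in **hmmplace**, the
parameters that matter and their defaults, the numerical choices, and
what the synthetic benchmarks do and do not demonstrate.

## The alignment model

### Consensus sequence and CSFM-index

The reference multiple sequence alignment (MSA) defines, per column, a
gap fraction and a consensus symbol (the modal non-gap base, ties
broken alphabetically; a gap when more than half the column is gapped).
Columns with gap fraction ≤ 0.5 are *match columns*; the gap-free
concatenation of their consensus bases is the consensus sequence (CS),
and CS position `k` corresponds one-to-one to profile match state `k`
and to tree site `k`.

The CSFM-index is a Burrows-Wheeler transform of the CS with cumulative
symbol counts, per-position occurrence counts (rank support), and a
sampled suffix array (stride 8) so that any suffix-array row can be
mapped back to a 1-based CS position by LF-stepping. Seed finding looks
for a maximal exact match of at least `min_seed_len = 20` bases
anchored in the first/last `window = 40` bases of the read; matches
occurring at more than `max_seed_hits = 10` CS loci are discarded as
ambiguous. None of these three values is dictated by the method itself;
they are chosen so that fixed-primer amplicons essentially always seed
while random 20-mers (expected once per 4^20 bases) essentially never
do, and all three are exposed as arguments.

### plan7 architecture

The profile has match states M_1..M_K, internal inserts I_1..I_{K−1},
deletes D_1..D_K, flanking states N (5′) and C (3′), and silent B/E.
Two conventions matter:

* **Wing retraction.** B enters any M_k directly with uniform
  probability 1/K, and E is reachable only from match states (each M_k
  exits with probability ε = 1/(K+1), M_K with probability 1). No path
  can therefore have an empty match segment, and the alignment is
  local in the profile while consuming the whole read.
* **5′/3′ overhang states.** The overhang insert states I_0 and I_K
  are realized as the emission distributions of N and C: the flanks
  emit with the trained I_0/I_K insert emissions and self-loop with
  probability 0.8. This is an equivalent parameterization of dedicated
  overhang states that keeps the DP three-matrix.

Training uses Henikoff position-based sequence weights (normalized to
mean 1) over the match columns. Emissions and transitions are posterior
means under Dirichlet priors: match emissions under a Dirichlet mixture
(default: a single symmetric Dirichlet(1,1,1,1) component), insert
emissions under Dirichlet(1,1,1,1), and transitions under mildly sparse
densities (M→{M,I,D}: (6,1,1); I→{M,I} and D→{M,D}: (2,2)). The
Dirichlet trainers maximize the Dirichlet-multinomial marginal
likelihood (L-BFGS on log-concentrations; EM over responsibilities for
mixtures) and recover simulated concentrations within 20 % at n = 5000
observations. `'N'` bases emit with probability 1 in every state, so
they are score-neutral.

### Banded Viterbi

Scores are natural-log probabilities; the Viterbi recurrence maximizes
log P(read, path | profile). The delete chain within a row is resolved
with a cumulative-maximum scan, so each row costs O(K) vector work.
Banding restricts row `i` to match states within `band_width = 100`
diagonals of any seed diagonal; bands are contiguous per row, so no
delete chain can tunnel through a forbidden cell. The banded score
therefore never exceeds the full score and equals it whenever the
optimal path stays in the band; `band_width = Inf` reproduces the full
DP cell for cell. The default 100 is generous for indel drift at 16S
scale and is configurable. Reads with no usable seed fall back to the
full DP; unpaired reads additionally retry reverse-complemented. For
mate pairs, each mate is aligned independently and the alignments are
merged over the union CS interval; columns observed by neither mate are
recorded as unobserved and excluded from all downstream likelihoods,
and where overlapping mates disagree the forward mate wins.

## The placement model

### Substitution models and tree evaluation

GTR, TN93 and HKY85 are parameterized by stationary frequencies π and
exchangeabilities R, with Q = R·diag(π) scaled to mean rate 1 and
exponentiated through the π-symmetrized eigendecomposition (real
spectrum for every reversible model; rows renormalized after clipping
round-off negatives). Training estimates π from observed base
frequencies and R by moment matching on the symmetrized
ancestor–offspring substitution counts — from leaf triplets with
outgroup-resolved ancestral states (Gojobori three-sequence method;
triplet enumeration capped at 50,000 random triplets) or from plain
pairs (Goldman two-sequence method). This count-based estimator is
accurate for modest divergence (≤ 15 % relative error on
exchangeabilities at 100 kb, divergence 0.05) which matches its use
here: reference databases of closely related marker genes.

Tree evaluation is Felsenstein pruning in log space. The only
non-standard element is the *double cache*: for every node `v` we store
both `lik_sub[v]` (data below `v`, conditional on `v`'s state) and
`lik_out[v]` (data outside `v`'s subtree, conditional on the state of
`v`'s parent, exclusive of the branch). Under a reversible model any
branch can then act as a local root: convolving the two messages toward
any point on the branch and dotting with π reproduces the total
likelihood exactly (the Pulley Principle), which the tests verify to
1e-9. Memory is 2 × 4 × S doubles per branch per rate category.

Gap and `N` leaf states are fully ambiguous (likelihood 1 for all
bases) — the standard pruning convention. Ancestral sequences maximize
the per-site marginal posterior (sub × out messages × π), except that a
site whose descendant leaves are majority-gap is assigned a gap; this
gap rule is a design choice, made so that inferred ancestors carry the
same gap structure that their clades show.

Discrete-Gamma rate variation uses k = 4 equal-probability categories
with mean-preserving category rates (conditional means between
α-quantiles; exactly unit mean). The shape α is estimated by
negative-binomial moment matching on per-site substitution counts,
α = m²/(v − m), where counts compare the (observed or ML-ancestral)
states across every branch; when v ≤ m the data show no
over-dispersion and a rate-homogeneous sentinel is returned. Rate
variation is **off by default**: reference trees whose branch lengths
were inferred under a fixed-rate model are internally consistent only
under that assumption, and k = 1 reproduces fixed-rate likelihoods
bit-for-bit.

### Seed–Estimate–Place

*Seed.* Candidate nodes are ranked by p-distance between the aligned
read and each node's observed or inferred sequence over the read's
observed CS sites (ties by node id); the default keeps `max_seeds = 5`
nodes, and the candidate branch set is every branch incident to a seed
node.

*Estimate.* With `d_u`, `d_v` the read's p-distances to the branch
endpoints and `w_0` the branch length: the branching fraction is
`w_ur/w_0 = d_u/(d_u + d_v)` (0.5 when both vanish) and the pendant
estimate is `w_nr = max(min(d_u, d_v) − min(w_ur, w_rv), min_branch)`,
the simplest triangle-consistent estimate from observed distances. The
estimate's likelihood uses only the two cached messages and the read's
leaf log-likelihoods; the global tree is never touched. Because
unobserved sites are split-invariant, their contribution equals the
cached tree site log-likelihoods and only the read's observed sites are
recomputed.

*Place.* The `top_n = 5` estimates by likelihood are refined by
alternating Brent line searches over `w_ur ∈ [0, w_0]` (the constraint
`w_ur + w_rv = w_0` keeps the reference branch length, hence the whole
reference tree, unchanged) and `w_nr ∈ [min_branch, 2]`, with explicit
boundary checks because the optimum frequently sits at a branch end.
The sweep stops when the log-likelihood improves by < `tol = 1e-6`
(cap `max_iter = 100`; in practice 2–3 sweeps). Direct numerical
maximization was chosen over an EM update for the branch lengths: it
optimizes the same objective, needs no expected sufficient statistics,
and is easy to validate against a grid-search oracle (agreement within
1e-3). The best candidate is chosen by likelihood (a uniform placement
prior); an optional node-height prior subtracts `height/τ` (height =
longest branch path to a descendant leaf, τ = 1 by default) to prefer
near-leaf assignments.

The reported node is the parent `u` when `w_ur ≤ min_branch`, otherwise
the child `v` — taxonomy lives on nodes, and an interior attachment is
summarized by the branch's child. The Q-score is
`min(250, −10·log10(1 − w))` with `w` the chosen placement's softmax
weight among optimized candidates: a phred-style scale whose cap at 250
marks placements with a single surviving candidate; two tied candidates
give Q ≈ 3.01.

### Chimera detection

The aligned read is split at the median observed CS site into 5′ and 3′
halves (two segments; reads with fewer than 20 observed sites per half
are returned unevaluated). Both halves are placed with the *common*
seed set of the whole read; each half's best branch, and its
re-placement on the other half's best branch, give
`LOD = (loglik5_best − loglik5_alt) + (loglik3_best − loglik3_alt)`.
A read is chimeric when the two best branches differ **and**
LOD ≥ cutoff (default 50; the LOD is non-negative by construction when
the branches differ). On toy chimeras spliced from parents at
p-distance ≥ 0.10 with central breakpoints, sensitivity exceeds 90 %
at cutoff 0 with < 10 % false flags on unspliced controls.

## OTUs and representative sequences

Placements that survive the chimera and Q-score filters are grouped by
assigned node; every node with at least `otu_min_reads` (default 1)
placed reads becomes an OTU, and sub-threshold reads are returned in a
rejects table so read counts are conserved exactly. The representative
sequence is a per-site Dirichlet posterior: observed base counts from
the members' aligned strings plus a prior of concentration 2 (two
pseudo-reads) distributed as the softmax of the node's marginal
log-likelihoods — "proportional to the node likelihood" realized with
softmax normalization, the one normalization that makes the prior a
probability vector. The consensus base maximizes the posterior mean
unless gap observations outnumber base observations, in which case a
gap is emitted; the prior can be disabled. The OTU tree keeps OTU nodes
plus minimal connectors and collapses pass-through nodes with branch
lengths summed, preserving pairwise path lengths between OTU nodes to
1e-9.

## The synthetic-data generator

`make_toy_reference` draws a random bifurcating topology, branch
lengths uniform on 0.25–1.75 × a scale of 0.08 substitutions/site
(pairwise leaf divergences of roughly 5–30 %, the range spanned by
16S hypervariable regions at genus-to-family depth), evolves gap-free
sequences from a stationary root draw, and assigns 7-rank taxonomy
strings from the topology (rank j names the ancestor at fraction
(j−1)/6 of the root-to-leaf path; internal nodes take the longest
common rank prefix of their leaves). `simulate_reads` follows the
library-construction scheme the placement model assumes: uniform
branch, uniform branching point, fixed or uniform locus, fixed or
truncated-Gaussian amplicon length (defaults μ = 150, σ = 30, bounds
75–300), and bases sampled from the conditional posterior of the four
bases at the branching point; the recorded truth taxonomy is the
nearer branch endpoint's. The default experiment shape is 20 samples ×
5000 reads. `simulate_chimeras` splices sequence pairs whose p-distance
falls in the requested bins at a uniform aligned breakpoint, labelling
a read chimeric exactly when the breakpoint fraction lies in
[0.25, 0.75), and strips alignment gaps from the output.

What the simulators deliberately omit: sequencing error models
(substitution/indel error profiles and quality-dependent errors), PCR
amplification bias, alignment gaps in reads, and taxonomy annotation
noise. Passing benchmarks on these fixtures therefore demonstrates
correctness of the algorithms under their own generative assumptions —
not robustness to platform-specific artefacts, which on real data is
mitigated upstream by quality trimming.

## Numerical choices and degenerate inputs

* All likelihood arithmetic is log-space; convolutions use column-wise
  log-sum-exp and are exact for entries down to −1e4.
* `min_branch = 1e-6` substitutions/site is the smallest representable
  branch length; zero-length placements clamp to it.
* Tie-breaks are deterministic everywhere (first maximum in argmax,
  alphabetic consensus ties, node-id ties in seed ranking), so
  identical seeds give byte-identical outputs and serial equals
  parallel.
* Multifurcating input trees are resolved with zero-length branches;
  single-leaf Newick degenerates parse to a one-tip tree.
* Empty read, empty pattern, all-gap MSA columns, unplaceable reads
  (no observed CS overlap) and too-short chimera segments each have a
  defined error or sentinel path, exercised by the tests.

## Benchmark problem sizes

The test-suite and acceptance-script sizes are chosen as the smallest
fixtures that make the statistical assertions meaningful: toy
references of 10–20 leaves × 100–200 sites; 100 reads for banded/full
and exhaustive-placement comparisons; 200 near-leaf reads for
alignment/taxonomy recovery; 40 chimera/control pairs; 50,000 sites
for shape-parameter recovery and 100 kb triplets for
substitution-model recovery; brute-force oracles (path enumeration,
ancestral-state enumeration) run at K ≤ 4 / 5 leaves where exhaustive
computation is exact.

## Known limitations

* The FM-index stores plain rank tables rather than a wavelet tree;
  the contract (exact counts and positions) is identical, but memory
  is linear in the alphabet size. At reference scales beyond ~10^6
  consensus bases a compressed rank structure would be preferable.
* Placement evaluates one read against one reference package; there is
  no multi-profile or multi-domain ("J"-state) alignment.
* The OTU threshold counts a mate pair as a single placement.
* jplace output reports the single best placement per read rather than
  the full candidate distribution.
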