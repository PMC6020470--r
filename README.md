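# hmmplace

Taxonomic assignment and OTU picking for 16S rRNA-style amplicon reads,
built around two core algorithms:

1. **CSFM-index banded profile-HMM alignment.** Reads are aligned to a
   reference multiple sequence alignment with a plan7 profile HMM
   (match/insert/delete states M/I/D plus flanking N, C and begin/end
   B, E states; wing-retracted uniform entry B→M_k and exit M_k→E make
   the alignment local in the profile and global in the read). Exact
   substrings at the 5′ and 3′ ends of each read ("seeds") are located
   on the gap-free alignment consensus with an FM-index — a
   Burrows-Wheeler transform with rank support and consensus-position
   lookup (CSFM-index) — and the Viterbi dynamic program is restricted
   to a diagonal band around the seed paths, falling back to the full
   DP when no seed is found.

2. **Seed-Estimate-Place (SEP) phylogenetic placement.** The reference
   phylogeny is evaluated once under a reversible substitution model
   (GTR, TN93 or HKY85; optional discrete-Gamma rate variation) with
   Felsenstein pruning, caching both directional conditional
   log-likelihood matrices on every branch and ML ancestral sequences
   on every internal node. A read is then placed by: ranking candidate
   nodes by observed p-distance (*seed*), estimating the attachment
   point and pendant length on each adjacent branch from p-distances
   with a cached-message likelihood (*estimate*), and jointly
   optimizing the branching point `w_ur` (with `w_ur + w_rv = w_0`
   fixed, so the reference topology never changes) and pendant length
   `w_nr` for the top candidates (*place*). By the Pulley Principle the
   resulting local likelihood equals the whole-tree likelihood with the
   read grafted. Each placement carries a Q-score
   `min(250, -10·log10(1 − w))` with `w` the placement's softmax weight
   among the optimized candidates.

On top of these the package provides chimera detection (the aligned
read is split into 5′/3′ halves, each half placed independently, and
the joint log-odds
`LOD = (loglik5_best − loglik5_alt) + (loglik3_best − loglik3_alt)`
flags reads whose halves prefer different branches; default cutoff 50),
phylogeny-based OTUs (each reference node with placed reads becomes an
OTU) with Dirichlet-consensus representative sequences and a pruned OTU
tree, readers/writers for FASTA/FASTQ/Newick/TSV/jplace, model training
(Dirichlet densities and mixtures for profile priors, Gojobori
three-sequence and Goldman two-sequence substitution-model training,
moment-matching discrete-Gamma shape estimation), and simulators plus
evaluation metrics for all of the above.

## Worked example

```r
library(hmmplace)

# 1. build a toy reference package (20 taxa, 200 consensus sites)
toy <- make_toy_reference(n_leaves = 20, S = 200, seed = 42)
pkg <- toy$package
pkg
#> ref_package: 20 tips, 200 sites, GTR model, dGamma off

# 2. simulate 50 reads from random branch points and assign them
sim <- simulate_reads(pkg, n_samples = 1, reads_per_sample = 50, seed = 42,
                      amplicon = list(type = "gaussian", mu = 120, sd = 20,
                                      min = 80, max = 160))
asn <- assign_reads(pkg, sim[, c("id", "seq", "sample")], chimera = TRUE)
head(asn[, c("id", "cs_start", "cs_end", "branch_id", "q_score", "taxonomy")], 3)
#>           id cs_start cs_end branch_id   q_score                                         taxonomy
#> 1 read000001       36    174        38  4.342451                             k__n21;p__n21;c__n38
#> 2 read000002       42    148        16 80.132390 k__n21;p__n22;c__n27;o__n33;f__n34;g__n35;s__n16
#> 3 read000003        2    111         1  9.636909  k__n21;p__n21;c__n22;o__n23;f__n23;g__n23;s__n1

# 3. how well did we do?
eval_alignment(asn, sim)$accuracy
#> [1] 1
eval_taxonomy(asn$taxonomy, sim$taxonomy)[, c("level", "TPR", "PPV", "ACC")]
#>   level       TPR       PPV ACC
#> 1     k 100.00000 100.00000 100
#> 2     p  96.96970  78.04878  80
#> ...
#> 6     g  96.42857  75.00000  80
#> 7     s  94.73684  58.06452  72

# 4. summarize into phylogeny-based OTUs
res <- summarize_otus(pkg, asn, "otu_out")
length(res$otus)
#> [1] 28
```

Reading the output: every aligned consensus locus here covers its true
locus (accuracy 1 under the ≥90 %-overlap rule). Reads were drawn from
*random* branch points — many genuinely originate from internal
(ancestral) branches, so correct assignments often stop at higher ranks
and the per-level precision reflects reads whose placement resolves one
rank deeper or shallower than the truth. The first read's Q-score of
4.3 says its best placement holds about 63 % of the softmax posterior
weight; read 2's Q of 80 is essentially certain. `summarize_otus`
writes the OTU count table (`otu_table.tsv`), Dirichlet-consensus
representative sequences (`rep_seqs.fasta`), and the pruned OTU tree
(`otu_tree.nwk`).

The same pipeline is scriptable from a shell via `inst/bin/hmmplace`
with subcommands `build`, `assign`, `sum`, `train-dm`, `train-sm`,
`train-hmm`, `sim`, `jplace`.

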