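test_that("toy reference generation is seed-deterministic and distance-coherent", {
  a <- make_toy_reference(8, 60, seed = 5)
  b <- make_toy_reference(8, 60, seed = 5)
  expect_identical(serialize(a$package, NULL), serialize(b$package, NULL))
  c_ <- make_toy_reference(8, 60, seed = 6)
  expect_false(identical(a$package$msa$seqs, c_$package$msa$seqs))
  # p-distance grows with path length on the tree (Spearman rho > 0.5)
  toy <- fixture("toy_rho", make_toy_reference(20, 150, seed = 7))
  tree <- toy$package$tree
  d <- ape::dist.nodes(tree$phy)
  pdv <- c(); plv <- c()
  for (i in 1:19) for (j in (i + 1):20) {
    pdv <- c(pdv, oracle_pdist(tree$seq[i, ], tree$seq[j, ]))
    plv <- c(plv, d[i, j])
  }
  expect_gt(cor(pdv, plv, method = "spearman"), 0.5)
  expect_error(make_toy_reference(3, 60), "n_leaves")
  expect_error(make_toy_reference(8, 20), "S")
})

test_that("read simulation follows the branch-point posterior", {
  toy <- toy_small()
  tree <- toy$package$tree
  # fraction forced to the leaf end: bases converge to the leaf sequence
  leaf_branches <- which(tree$tip)
  sim <- simulate_reads(toy$package, 1, 60, seed = 8,
                        branch_set = leaf_branches[1],
                        frac_range = c(0.999999, 1),
                        locus_mode = "fixed", locus = c(1, tree$S))
  leaf_str <- hmmplace:::int_to_seq(tree$seq[leaf_branches[1], ])
  mism <- vapply(sim$seq, function(s)
    mean(strsplit(s, "")[[1]] != strsplit(leaf_str, "")[[1]]), numeric(1))
  expect_lt(mean(mism), 0.01)
  # same seed, same reads; fixed locus respected
  sim2 <- simulate_reads(toy$package, 1, 60, seed = 8,
                         branch_set = leaf_branches[1],
                         frac_range = c(0.999999, 1),
                         locus_mode = "fixed", locus = c(1, tree$S))
  expect_identical(sim, sim2)
  expect_true(all(sim$cs_start == 1 & sim$cs_end == tree$S))
  # truncated-Gaussian amplicons respect their bounds
  sim3 <- simulate_reads(toy$package, 1, 50, seed = 9,
                         amplicon = list(type = "gaussian", mu = 60, sd = 15,
                                         min = 40, max = 90))
  lens <- sim3$cs_end - sim3$cs_start + 1
  expect_true(all(lens >= 40 & lens <= 90))
  expect_error(simulate_reads(toy$package, 1, 1, locus_mode = "fixed",
                              locus = c(1, tree$S + 10)),
               "longer")
})

test_that("chimera simulation applies the breakpoint rule exactly", {
  toy <- toy_mid()
  msa <- toy$package$msa
  ch <- simulate_chimeras(msa, bins = list(c(0.05, 0.30)), n_per_bin = 60,
                          seed = 10)
  expect_equal(nrow(ch), 60)
  # label follows the [0.25, 0.75) rule
  expect_equal(ch$label == "chimera",
               ch$breakpoint >= 0.25 & ch$breakpoint < 0.75)
  # non-chimeras equal their gap-stripped first parent
  for (i in which(ch$label == "non-chimera")[1:5]) {
    p1 <- gsub("-", "", msa$seqs[match(ch$parent1[i], msa$ids)], fixed = TRUE)
    expect_identical(ch$seq[i], p1)
  }
  # chimera halves equal the two parents over consensus columns
  i <- which(ch$label == "chimera")[1]
  bp <- max(1L, min(msa$L - 1L, round(ch$breakpoint[i] * msa$L)))
  s1 <- msa$seqs[match(ch$parent1[i], msa$ids)]
  s2 <- msa$seqs[match(ch$parent2[i], msa$ids)]
  manual <- gsub("-", "", paste0(substr(s1, 1, bp), substr(s2, bp + 1, msa$L)),
                 fixed = TRUE)
  expect_identical(ch$seq[i], manual)
  # emitted pairs honour the requested p-distance bin
  for (i in seq_len(10)) {
    a <- hmmplace:::seq_to_int(msa$seqs[match(ch$parent1[i], msa$ids)])
    b <- hmmplace:::seq_to_int(msa$seqs[match(ch$parent2[i], msa$ids)])
    pd <- oracle_pdist(a, b)
    expect_gte(pd, 0.05); expect_lt(pd, 0.30)
  }
  expect_error(simulate_chimeras(msa, bins = list(c(0.9, 0.99))), "p-distance")
})

test_that("alignment evaluation implements the 90%-overlap rule", {
  truths <- data.frame(id = c("a", "b", "c"), cs_start = c(1L, 101L, 50L),
                       cs_end = c(100L, 200L, 149L))
  alns <- data.frame(id = c("a", "b", "c"),
                     cs_start = c(1L, 112L, 40L),     # b covers 89/100
                     cs_end = c(100L, 200L, 160L))
  ev <- eval_alignment(alns, truths)
  expect_equal(ev$correct, c(TRUE, FALSE, TRUE))
  expect_equal(ev$accuracy, 2 / 3)
  # interval-arithmetic oracle on random perturbations
  set.seed(12)
  tr <- data.frame(id = sprintf("r%d", 1:50),
                   cs_start = sample(1:100, 50, TRUE))
  tr$cs_end <- tr$cs_start + sample(30:80, 50, TRUE)
  al <- tr
  al$cs_start <- al$cs_start + sample(-20:20, 50, TRUE)
  al$cs_end <- al$cs_end + sample(-20:20, 50, TRUE)
  ev2 <- eval_alignment(al, tr)
  oracle <- vapply(1:50, function(i) {
    ov <- length(intersect(seq(al$cs_start[i], al$cs_end[i]),
                           seq(tr$cs_start[i], tr$cs_end[i])))
    ov / (tr$cs_end[i] - tr$cs_start[i] + 1) >= 0.9
  }, logical(1))
  expect_equal(ev2$correct, oracle)
})

test_that("taxonomy metrics match direct 2x2 confusion arithmetic", {
  truth <- c("k__K;p__P;g__G1", "k__K;p__P;g__G2", "k__K;p__P", "k__K")
  asgn <- c("k__K;p__P;g__G1", "k__K;p__P;g__G3", "k__K;p__P;g__G9", "k__K")
  ev <- eval_taxonomy(asgn, truth)
  g <- ev[ev$level == "g", ]
  expect_equal(g$TP, 1)   # G1
  expect_equal(g$TN, 1)   # the bare-kingdom pair lacks genus on both sides
  expect_equal(g$FP, 2)   # G3 mismatch + G9 spurious
  expect_equal(g$FN, 1)   # G2 missed (mismatch)
  expect_equal(g$TPR, 100 * 1 / 2)
  expect_equal(g$PPV, 100 * 1 / 3)
  expect_equal(g$ACC, 100 * 2 / 5)
  perfect <- eval_taxonomy(truth, truth)
  expect_true(all(perfect$TPR[perfect$TP > 0] == 100))
  expect_true(all(perfect$ACC == 100))
})

test_that("placement EMD is a tree Earth-Mover distance", {
  toy <- toy_small()
  tree <- toy$package$tree
  p1 <- data.frame(node = c(1L, 2L))
  expect_equal(placement_emd(p1, p1, tree), 0)
  # unit mass on two nodes at path distance d costs exactly d
  d <- ape::dist.nodes(tree$phy)
  for (pair in list(c(1L, 2L), c(3L, 8L))) {
    e <- placement_emd(data.frame(node = pair[1]),
                       data.frame(node = pair[2]), tree)
    expect_equal(e, d[pair[1], pair[2]], tolerance = 1e-9)
  }
  # small-case transport oracle: moving fraction f over distance d
  pa <- data.frame(node = c(1L, 2L), mass = c(0.75, 0.25))
  pb <- data.frame(node = c(1L, 2L), mass = c(0.25, 0.75))
  expect_equal(placement_emd(pa, pb, tree), 0.5 * d[1, 2], tolerance = 1e-9)
  expect_error(placement_emd(data.frame(node = 1L, mass = 0), p1, tree),
               "mass")
})
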