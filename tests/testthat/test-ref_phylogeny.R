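gtr_test_model <- function() subst_model("GTR", pi = c(.3, .2, .27, .23),
                                         rates = c(1.2, 3.5, .9, 1.1, 4, 1))

test_that("convolute is a log-space matrix convolution", {
  set.seed(41)
  L <- matrix(log(runif(4 * 12)), 4, 12)
  expect_equal(convolute(L, diag(4)), L, tolerance = 1e-12)
  P <- transition_matrix(gtr_test_model(), 0.1)
  onehot <- matrix(-Inf, 4, 3); onehot[1, ] <- 0
  expect_equal(convolute(onehot, P), matrix(log(P[, 1]), 4, 3),
               tolerance = 1e-12)
  # linear-space oracle at moderate magnitudes
  expect_equal(convolute(L, P), log(P %*% exp(L)), tolerance = 1e-10)
  # no underflow for entries down to -1e4
  Ldeep <- matrix(-1e4, 4, 2); Ldeep[2, ] <- -9990
  out <- convolute(Ldeep, P)
  expect_true(all(is.finite(out)))
  expect_equal(out[1, 1], log(sum(P[1, ] * exp(Ldeep[, 1] + 1e4))) - 1e4,
               tolerance = 1e-9)
  expect_error(convolute(L, matrix(1, 4, 4)), "stochastic")
})

test_that("two identical leaves at zero distance give log(pi) per site", {
  phy <- parse_newick("(A:0,B:0);")
  m <- gtr_test_model()
  rt <- evaluate_tree(build_ref_tree(phy, c(A = "AAAA", B = "AAAA"), m))
  expect_equal(rt$site_loglik, rep(log(m$pi[1]), 4), tolerance = 1e-12)
})

test_that("pruning equals brute-force enumeration for all three models", {
  set.seed(42)
  phy <- ape::rtree(5)
  phy$edge.length <- runif(nrow(phy$edge), 0.05, 0.3)
  seqs <- vapply(1:5, function(i)
    paste(sample(c("A", "C", "G", "T"), 10, TRUE), collapse = ""), "")
  names(seqs) <- phy$tip.label
  for (m in list(gtr_test_model(),
                 subst_model("TN93", c(.28, .22, .24, .26), c(3, 5)),
                 subst_model("HKY85", c(.25, .25, .3, .2), 4))) {
    rt <- evaluate_tree(build_ref_tree(phy, seqs, m))
    expect_equal(rt$loglik, oracle_tree_loglik(rt), tolerance = 1e-8,
                 info = m$name)
  }
  # ambiguous leaf states (gaps, N) handled as likelihood 1
  seqs2 <- seqs
  substr(seqs2[1], 3, 4) <- "-N"
  rt2 <- evaluate_tree(build_ref_tree(phy, seqs2, gtr_test_model()))
  expect_equal(rt2$loglik, oracle_tree_loglik(rt2), tolerance = 1e-8)
})

test_that("likelihood is invariant under rerooting (Pulley Principle)", {
  toy <- toy_small()
  tree <- toy$package$tree
  ls <- setNames(vapply(seq_len(tree$n_tip),
                        function(i) hmmplace:::int_to_seq(tree$seq[i, ]), ""),
                 tree$phy$tip.label)
  for (m in list(tree$model,
                 subst_model("TN93", c(.28, .22, .24, .26), c(3, 5)),
                 subst_model("HKY85", c(.25, .25, .3, .2), 4))) {
    base <- evaluate_tree(build_ref_tree(tree$phy, ls, m))$loglik
    for (out_tip in c(1L, 4L, 9L)) {
      re <- ape::root(tree$phy, outgroup = out_tip, resolve.root = TRUE)
      ll <- evaluate_tree(build_ref_tree(re, ls, m))$loglik
      expect_equal(ll, base, tolerance = 1e-6,
                   info = sprintf("%s outgroup %d", m$name, out_tip))
    }
  }
})

test_that("directional caches make any branch a local root", {
  toy <- toy_small()
  tree <- toy$package$tree
  lpi <- log(tree$model$pi)
  for (v in c(2L, 7L, 12L, 14L)) {
    w0 <- tree$blen[v]
    for (f in c(0, 0.5, 1)) {
      A <- convolute(tree$lik_out[[v]][, , 1],
                     transition_matrix(tree$model, f * w0))
      B <- convolute(tree$lik_sub[[v]][, , 1],
                     transition_matrix(tree$model, (1 - f) * w0))
      ll <- sum(hmmplace:::col_log_sum_exp(A + B + lpi))
      expect_equal(ll, tree$loglik, tolerance = 1e-9)
    }
  }
})

test_that("ancestral inference maximizes the marginal posterior", {
  m <- subst_model("GTR", rep(.25, 4), rep(1, 6))
  phy <- parse_newick("((A:0.1,B:0.1):0.1,C:0.1);")
  rt <- build_ref_tree(phy, c(A = "A", B = "A", C = "C"), m)
  rt <- infer_ancestral_sequences(evaluate_tree(rt))
  anc_of_pair <- setdiff(which(!rt$tip), rt$root)
  expect_equal(rt$seq[anc_of_pair, 1], 1L)   # 'A'
  # identical leaves: every ancestor matches
  rt2 <- build_ref_tree(phy, c(A = "ACGT", B = "ACGT", C = "ACGT"), m)
  rt2 <- infer_ancestral_sequences(evaluate_tree(rt2))
  for (v in which(!rt2$tip)) expect_equal(rt2$seq[v, ], c(1L, 2L, 3L, 4L))
  # all-gap site propagates gaps to ancestors
  rt3 <- build_ref_tree(phy, c(A = "A-", B = "A-", C = "A-"), m)
  rt3 <- infer_ancestral_sequences(evaluate_tree(rt3))
  for (v in which(!rt3$tip)) expect_equal(rt3$seq[v, 2], 0L)
  expect_error(infer_ancestral_sequences(build_ref_tree(phy, c(A = "A", B = "A", C = "C"), m)),
               "evaluated")
})

test_that("taxonomy propagates from the nearest annotated ancestor", {
  phy <- parse_newick("(((A:1,B:1)n1:1,C:1)n2:1,D:1)n3;")
  m <- gtr_test_model()
  tax <- data.frame(id = c("n3", "n2", "A"),
                    taxonomy = c("k__K", "k__K;o__Y", "k__K;o__Y;g__A"))
  rt <- build_ref_tree(phy, setNames(rep("ACGT", 4), c("A", "B", "C", "D")),
                       m, taxonomy = tax)
  rt <- propagate_taxonomy(rt)
  lab <- function(x) rt$taxonomy[match(x, rt$label)]
  expect_equal(lab("A"), "k__K;o__Y;g__A")       # keeps its own
  expect_equal(lab("B"), "k__K;o__Y")            # nearest annotated ancestor
  expect_equal(lab("C"), "k__K;o__Y")
  expect_equal(lab("n1"), "k__K;o__Y")           # chain of unnamed nodes
  expect_equal(lab("D"), "k__K")
  rt$taxonomy[rt$root] <- ""
  expect_error(propagate_taxonomy(rt), "root")
})

test_that("reference package assembly is consistent and deterministic", {
  toy <- toy_small()
  pkg <- toy$package
  expect_equal(pkg$profile$K, pkg$tree$S)
  expect_equal(nchar(pkg$profile$consensus_cs), pkg$tree$S)
  expect_identical(pkg$meta$magic, "hmmplace-refpkg")
  # tip name mismatch errors with the orphan names
  bad <- pkg$msa
  bad$ids[1] <- "zzz"
  expect_error(build_reference_package(bad, pkg$tree$phy, NULL,
                                       model = pkg$tree$model),
               pkg$tree$phy$tip.label[1])
  # rebuilding from the same inputs is bit-identical
  again <- make_toy_reference(10, 100, seed = 101)
  expect_identical(serialize(again$package, NULL),
                   serialize(toy$package, NULL))
  # archive round-trip
  f <- withr::local_tempfile(fileext = ".rds")
  save_reference_package(pkg, f)
  expect_equal(load_reference_package(f)$tree$loglik, pkg$tree$loglik)
})

test_that("discrete-Gamma evaluation changes site likelihoods, not topology", {
  toy <- toy_small()
  msa <- toy$package$msa
  phy <- toy$truth$phy
  m <- toy$truth$model
  base <- build_reference_package(msa, phy, NULL, model = m, dgamma = FALSE)
  dg <- build_reference_package(msa, phy, NULL, model = m, dgamma = TRUE)
  expect_identical(dg$tree$parent, base$tree$parent)
  if (!is.na(dg$meta$dgamma_alpha)) {
    expect_false(isTRUE(all.equal(dg$tree$site_loglik, base$tree$site_loglik)))
    expect_equal(dg$tree$dgamma$k, 4L)
  }
  # k = 1 discretization reproduces fixed-rate likelihoods
  rt1 <- base$tree
  rt1$dgamma <- discretize_gamma(0.5, 1)
  rt1 <- evaluate_tree(rt1)
  expect_equal(rt1$loglik, base$tree$loglik, tolerance = 1e-12)
})
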