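test_that("seed-node ranking matches the naive p-distance oracle", {
  toy <- toy_small()
  tree <- toy$package$tree
  # a read identical to a leaf over its interval ranks that leaf first
  sites <- integer(tree$S)
  sites[21:80] <- tree$seq[3, 21:80]
  sn <- find_seed_nodes(tree, sites, max_seeds = 5)
  expect_equal(sn$node[1], 3)
  expect_equal(sn$p_dist[1], 0)
  expect_true(all(diff(sn$p_dist) >= 0))
  # oracle agreement on every node
  pd_all <- vapply(seq_len(tree$n_node), function(v)
    oracle_pdist(sites, tree$seq[v, ]), numeric(1))
  sn_all <- find_seed_nodes(tree, sites, max_seeds = tree$n_node)
  expect_equal(sn_all$p_dist, pd_all[sn_all$node], tolerance = 1e-12)
  expect_equal(nrow(find_seed_nodes(tree, sites, max_seeds = 1)), 1)
  expect_error(find_seed_nodes(tree, integer(tree$S)), "overlap")
})

test_that("estimate_place reproduces the zero-distance closed case", {
  toy <- toy_small()
  tree <- toy$package$tree
  leaf <- 5L
  sites <- tree$seq[leaf, ]
  est <- estimate_place(tree, sites, leaf)
  # read identical to the leaf: pendant at the floor, branch point at the
  # leaf end of the branch
  expect_lte(est$w_nr, 1e-6 + 1e-12)
  expect_gte(est$w_ur / est$w0, 0.99)
  expect_equal(est$w_ur + est$w_rv, est$w0, tolerance = 1e-12)
  # optimization never worsens the estimate
  opt <- joint_opt_place(tree, sites, est)
  expect_gte(opt$loglik, est$loglik - 1e-6)
  expect_lte(opt$w_nr, 1e-6 + 1e-6)
})

test_that("joint optimization matches a grid-search oracle", {
  toy <- toy_small()
  tree <- toy$package$tree
  set.seed(51)
  sim <- simulate_reads(toy$package, 1, 3, seed = 51,
                        amplicon = list(type = "fixed_len", len = 70))
  for (i in 1:3) {
    aln <- align_read(toy$package$profile, toy$package$index, sim$seq[i],
                      read_id = sim$id[i])
    sites <- hmmplace:::alignment_sites(aln, tree$S)
    v <- sim$branch[i]
    est <- estimate_place(tree, sites, v)
    opt <- joint_opt_place(tree, sites, est)
    ctx <- hmmplace:::placement_context(tree, v, sites)
    grid_a <- seq(0, est$w0, length.out = 41)
    grid_b <- exp(seq(log(1e-6), log(0.5), length.out = 41))
    grid_best <- max(vapply(grid_a, function(a)
      max(vapply(grid_b, function(b)
        hmmplace:::placement_loglik(ctx, a, b), numeric(1))), numeric(1)))
    expect_gte(opt$loglik, grid_best - 1e-3)
  }
})

test_that("placement log-likelihood equals whole-tree re-evaluation with the read grafted", {
  toy <- toy_small()
  tree <- toy$package$tree
  sim <- simulate_reads(toy$package, 1, 5, seed = 52,
                        amplicon = list(type = "fixed_len", len = 70))
  for (i in 1:5) {
    aln <- align_read(toy$package$profile, toy$package$index, sim$seq[i],
                      read_id = sim$id[i])
    pl <- place_read(tree, aln)
    expect_equal(pl$loglik, oracle_grafted_loglik(tree, aln, pl),
                 tolerance = 1e-6)
  }
})

test_that("placement is symmetric in the branch orientation", {
  # attaching at distal a from u must equal attaching at w0 - a from v's
  # perspective: the likelihood profile over the branch is well defined
  toy <- toy_small()
  tree <- toy$package$tree
  sites <- tree$seq[2, ]
  v <- 2L
  ctx <- hmmplace:::placement_context(tree, v, sites)
  for (a in c(0, 0.3, 0.7, 1)) {
    ll1 <- hmmplace:::placement_loglik(ctx, a * ctx$w0, 0.01)
    # recompute with the two cached messages swapped and the distal
    # length measured from the other end
    ctx2 <- ctx
    ctx2$Mout <- ctx$Msub; ctx2$Msub <- ctx$Mout
    ll2 <- hmmplace:::placement_loglik(ctx2, (1 - a) * ctx$w0, 0.01)
    expect_equal(ll1, ll2, tolerance = 1e-8)
  }
})

test_that("Q-scores follow the softmax posterior definition", {
  toy <- toy_small()
  tree <- toy$package$tree
  sim <- simulate_reads(toy$package, 1, 6, seed = 53,
                        amplicon = list(type = "fixed_len", len = 80))
  for (i in 1:6) {
    aln <- align_read(toy$package$profile, toy$package$index, sim$seq[i],
                      read_id = sim$id[i])
    pl <- place_read(tree, aln)
    w <- pl$candidates$weight
    expect_equal(sum(w), 1, tolerance = 1e-9)
    wbest <- max(w)
    q_exp <- if (wbest >= 1 - 1e-25) 250 else min(250, -10 * log10(1 - wbest))
    expect_equal(pl$q_score, q_exp, tolerance = 1e-9)
  }
  # analytic two-candidate case: equal logliks give q = -10*log10(0.5)
  w <- exp(c(-5, -5) - hmmplace:::log_sum_exp(c(-5, -5)))
  expect_equal(-10 * log10(1 - w[1]), 3.0103, tolerance = 1e-4)
})

test_that("reads from leaf-adjacent branch points recover the leaf taxonomy", {
  toy <- toy_small()
  pkg <- toy$package
  tree <- pkg$tree
  sim <- simulate_reads(pkg, 1, 40, seed = 54,
                        branch_set = which(tree$tip), frac_range = c(0.9, 1),
                        amplicon = list(type = "fixed_len", len = 80))
  got <- vapply(seq_len(nrow(sim)), function(i) {
    aln <- align_read(pkg$profile, pkg$index, sim$seq[i], read_id = sim$id[i])
    place_read(tree, aln)$taxonomy
  }, character(1))
  genus <- function(x) regmatches(x, regexpr("g__[^;]*", x))
  hit <- mapply(function(g, t_) length(genus(g)) == 1 &&
                  identical(genus(g), genus(t_)), got, sim$taxonomy)
  expect_gte(mean(hit), 0.95)
})

test_that("chimera LOD follows the best-vs-alternative definition", {
  toy <- toy_mid()
  pkg <- toy$package
  tree <- pkg$tree
  # a clean leaf read: both halves place on the same branch, never flagged
  sites <- tree$seq[4, ]
  ch <- detect_chimera(tree, sites, lod_cutoff = 0)
  expect_equal(ch$best5, ch$best3)
  expect_false(ch$is_chimera)
  expect_equal(ch$lod, 0)           # alt == best when branches agree
  # spliced halves of two distant leaves are flagged with positive LOD
  pd <- outer(seq_len(tree$n_tip), seq_len(tree$n_tip),
              Vectorize(function(i, j) oracle_pdist(tree$seq[i, ], tree$seq[j, ])))
  far <- which(pd == max(pd), arr.ind = TRUE)[1, ]
  half <- floor(tree$S / 2)
  sites2 <- c(tree$seq[far[1], 1:half], tree$seq[far[2], (half + 1):tree$S])
  ch2 <- detect_chimera(tree, sites2, lod_cutoff = 0)
  expect_false(ch2$best5 == ch2$best3)
  expect_true(ch2$is_chimera)
  expect_gte(ch2$lod, 0)
  # the same read passes at a high cutoff only if the LOD clears it
  ch3 <- detect_chimera(tree, sites2, lod_cutoff = ch2$lod + 1)
  expect_false(ch3$is_chimera)
  # too-short reads are returned unevaluated
  short <- integer(tree$S); short[1:25] <- tree$seq[1, 1:25]
  expect_equal(detect_chimera(tree, short)$flag, "unknown")
})

test_that("SEP finds the globally best branch among exhaustive placements", {
  toy <- toy_small()
  pkg <- toy$package
  tree <- pkg$tree
  sim <- simulate_reads(pkg, 1, 10, seed = 55,
                        amplicon = list(type = "fixed_len", len = 80))
  n_ok <- 0
  for (i in 1:10) {
    aln <- align_read(pkg$profile, pkg$index, sim$seq[i], read_id = sim$id[i])
    sites <- hmmplace:::alignment_sites(aln, tree$S)
    pl <- place_read(tree, aln)
    exhaustive <- max(vapply(which(tree$parent != 0L), function(v)
      joint_opt_place(tree, sites, estimate_place(tree, sites, v))$loglik,
      numeric(1)))
    if (pl$loglik >= exhaustive - 1e-3) n_ok <- n_ok + 1
  }
  expect_gte(n_ok, 9)
})
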