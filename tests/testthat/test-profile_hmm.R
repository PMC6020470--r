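test_that("Dirichlet density fitting behaves like its marginal-likelihood oracle", {
  # symmetric counts -> near-symmetric alpha
  set.seed(21)
  counts <- matrix(rpois(400, 10), 100, 4)
  fit <- train_dirichlet(counts, "density")
  expect_lt(max(fit$alpha) / min(fit$alpha), 1.2)
  # the fit is a local optimum of the marginal likelihood: perturbations lose
  base <- dirichlet_logmarg(fit, counts)
  for (j in 1:4) {
    up <- fit$alpha; up[j] <- up[j] * 1.15
    dn <- fit$alpha; dn[j] <- dn[j] * 0.85
    expect_lte(dirichlet_logmarg(structure(list(alpha = up),
                                           class = "dirichlet_density"), counts), base)
    expect_lte(dirichlet_logmarg(structure(list(alpha = dn),
                                           class = "dirichlet_density"), counts), base)
  }
  expect_error(train_dirichlet(matrix(0, 5, 4), "density"), "zero")
})

test_that("Dirichlet parameters are recovered from simulated counts", {
  set.seed(22)
  n <- 5000
  alpha_true <- c(10, 1, 1, 1)
  p <- matrix(rgamma(n * 4, rep(alpha_true, each = n)), n, 4)
  p <- p / rowSums(p)
  counts <- t(apply(p, 1, function(pp) rmultinom(1, 50, pp)))
  fit <- train_dirichlet(counts, "density")
  expect_true(all(abs(fit$alpha - alpha_true) / alpha_true < 0.2))
})

test_that("one-component mixture reduces to the density fit", {
  set.seed(23)
  counts <- matrix(rpois(200, 6), 50, 4)
  fm <- train_dirichlet(counts, "mixture", ncomp = 1)
  fd <- train_dirichlet(counts, "density")
  expect_equal(dirichlet_logmarg(fm, counts), dirichlet_logmarg(fd, counts),
               tolerance = 1e-6)
})

test_that("match emissions are Dirichlet posterior means; distributions normalize", {
  # 3 x 'A' with symmetric Dir(1,1,1,1) and unit weights: P(A) = 4/7
  m <- msa_from_records(rep("A", 3))
  p <- build_profile(m)
  expect_equal(exp(p$match_emis[1, 1]), 4 / 7, tolerance = 1e-12)
  # an all-gap column is not a match state
  m2 <- msa_from_records(c("A-G", "A-G", "A-G"))
  expect_equal(build_profile(m2)$K, 2)
  expect_error(build_profile(msa_from_records(c("--", "--", "--"))), "match")
  # every distribution normalizes on a random toy MSA
  set.seed(24)
  seqs <- vapply(1:10, function(i)
    paste(sample(c("A", "C", "G", "T", "-"), 60, TRUE,
                 prob = c(.23, .23, .23, .23, .08)), collapse = ""), "")
  prof <- build_profile(msa_from_records(seqs))
  K <- prof$K
  expect_true(all(abs(rowSums(exp(prof$match_emis)) - 1) < 1e-9))
  expect_true(all(abs(rowSums(exp(prof$ins_emis)) - 1) < 1e-9))
  expect_true(all(abs(rowSums(exp(prof$tM)) - 1) < 1e-9))
  expect_true(all(abs(rowSums(exp(prof$tI)) - 1) < 1e-9))
  expect_true(all(abs(rowSums(exp(prof$tD)) - 1) < 1e-9))
  # effective M-state outgoing (exit + scaled core) also sums to 1
  eff <- prof$exit_prob + (1 - prof$exit_prob) * rowSums(exp(prof$tM[-K, , drop = FALSE]))
  expect_true(all(abs(eff - 1) < 1e-9))
})

test_that("full Viterbi equals exhaustive path enumeration (K<=4, len<=5)", {
  set.seed(25)
  for (rep in 1:6) {
    nseq <- sample(3:6, 1)
    Kcols <- sample(2:4, 1)
    seqs <- vapply(seq_len(nseq), function(i)
      paste(sample(c("A", "C", "G", "T"), Kcols, TRUE), collapse = ""), "")
    prof <- build_profile(msa_from_records(seqs))
    for (len in 1:5) {
      read <- paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = "")
      got <- full_viterbi(prof, read)$score
      expect_equal(got, oracle_viterbi(prof, read), tolerance = 1e-10,
                   info = sprintf("K=%d read=%s", prof$K, read))
    }
  }
})

test_that("clean read through a clean profile takes the expected path", {
  prof <- build_profile(msa_from_records(rep("ACG", 5)))
  a <- full_viterbi(prof, "ACG")
  expect_equal(a$vpath, c("N", "B", "M1", "M2", "M3", "E", "C"))
  expect_equal(c(a$cs_start, a$cs_end), c(1, 3))
  expect_equal(a$aligned, "ACG")
  expect_lte(full_viterbi(prof, "TTTT")$score, a$score)
  expect_error(full_viterbi(prof, ""), "empty")
  expect_error(full_viterbi(prof, "AC-G"), "gap")
})

test_that("banded Viterbi never beats the full DP and matches it in-band", {
  toy <- toy_small()
  prof <- toy$package$profile
  idx <- toy$package$index
  cons <- prof$consensus_cs
  set.seed(26)
  n_eq <- 0
  for (i in 1:30) {
    st <- sample(nchar(cons) - 60, 1)
    read <- mutate_seq(substr(cons, st, st + 59), 0.10)
    seeds <- rbind(find_seeds(idx, read, "five_prime"),
                   find_seeds(idx, read, "three_prime"))
    full <- full_viterbi(prof, read)
    if (nrow(seeds) == 0) next
    band <- banded_viterbi(prof, read, seeds, band_width = 100)
    expect_lte(band$score, full$score + 1e-9)
    if (abs(band$score - full$score) < 1e-9) n_eq <- n_eq + 1
    # infinite band reproduces the full DP exactly
    inf <- banded_viterbi(prof, read, seeds, band_width = Inf)
    expect_equal(inf$score, full$score, tolerance = 1e-12)
  }
  expect_gte(n_eq, 1)
})

test_that("inconsistent 5'/3' seeds signal fallback", {
  toy <- toy_small()
  prof <- toy$package$profile
  seeds <- data.frame(read_from = c(0L, 40L), read_to = c(20L, 60L),
                      cs_from = c(70L, 5L), cs_to = c(90L, 25L),
                      end = c("five_prime", "three_prime"))
  expect_null(banded_viterbi(prof, strrep("ACGT", 20), seeds))
})

test_that("align_read orchestrates seeding, fallback, and strand retry", {
  toy <- toy_small()
  pkg <- toy$package
  cons <- pkg$profile$consensus_cs
  read <- substr(cons, 11, 90)
  a <- align_read(pkg$profile, pkg$index, read)
  expect_true(a$banded)
  expect_equal(a$strand, "+")
  expect_equal(c(a$cs_start, a$cs_end), c(11, 90))
  # reverse-complemented input is recovered on the minus strand
  arc <- align_read(pkg$profile, pkg$index, revcomp(read))
  expect_equal(arc$strand, "-")
  expect_equal(c(arc$cs_start, arc$cs_end), c(11, 90))
  # heavily mutated read: no seeds, full Viterbi fallback
  set.seed(27)
  noisy <- mutate_seq(read, 0.35)
  an <- align_read(pkg$profile, pkg$index, noisy)
  expect_false(an$banded)
})

test_that("mate pairs merge over the union interval with unobserved middle", {
  toy <- toy_small()
  pkg <- toy$package
  cons <- pkg$profile$consensus_cs
  m1 <- substr(cons, 5, 40)
  m2 <- revcomp(substr(cons, 61, 95))   # reverse mate as sequenced
  a <- align_read(pkg$profile, pkg$index, m1, mate = m2)
  expect_equal(c(a$cs_start, a$cs_end), c(5, 95))
  mid <- substr(a$aligned, 41 - 5 + 1, 60 - 5 + 1)
  expect_true(all(strsplit(mid, "")[[1]] == "-"))
  # overlapping agreeing mates behave like the assembled read
  m1o <- substr(cons, 5, 60)
  m2o <- revcomp(substr(cons, 41, 95))
  ao <- align_read(pkg$profile, pkg$index, m1o, mate = m2o)
  asm <- align_read(pkg$profile, pkg$index, substr(cons, 5, 95))
  expect_equal(c(ao$cs_start, ao$cs_end), c(asm$cs_start, asm$cs_end))
  expect_equal(ao$aligned, asm$aligned)
})

test_that("HMMER-style text export round-trips", {
  toy <- toy_small()
  prof <- toy$package$profile
  txt <- export_hmmer_text(prof)
  expect_equal(sum(grepl("^  i ", txt)), prof$K)
  back <- import_hmmer_text(txt)
  expect_equal(back$K, prof$K)
  expect_equal(back$match_emis, prof$match_emis, tolerance = 1e-4)
  expect_equal(back$tM, prof$tM, tolerance = 1e-4)
  # fixpoint: export(import(export(x))) == export(x)
  expect_identical(export_hmmer_text(back), txt)
  # emissions are written as negative natural-log probabilities
  row1 <- as.numeric(strsplit(trimws(txt[grep("^  1 ", txt)[1]]), "\\s+")[[1]][-1])
  expect_true(all(row1 >= 0))
})
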