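# Shared fixtures (lazily built, cached for the whole test run) and
# independent oracles used across the suite.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

toy_small <- function() fixture("toy_small", make_toy_reference(10, 100, seed = 101))
toy_mid <- function() fixture("toy_mid", make_toy_reference(16, 160, seed = 202,
                                                            branch_scale = 0.12))

# --- independent oracles -------------------------------------------------

# exhaustive plan7 path enumeration: maximum log-likelihood over every
# legal state path emitting the read (feasible for K <= 4, reads <= 5)
oracle_viterbi <- function(prof, read) {
  rint <- hmmplace:::seq_to_int(read)
  K <- prof$K
  L <- length(rint)
  eM <- cbind(prof$match_emis, 0)
  eI <- cbind(prof$ins_emis[2:(K + 1), , drop = FALSE], 0)
  eN <- c(prof$ins_emis[1, ], 0)
  eC <- c(prof$ins_emis[K + 1, ], 0)
  lloop <- log(prof$nc_loop); lleave <- log(1 - prof$nc_loop)
  eps <- prof$exit_prob; lcont <- log(1 - eps)
  exitl <- function(k) if (k < K) log(eps) else 0
  tMM <- prof$tM[, 1] + lcont; tMI <- prof$tM[, 2] + lcont; tMD <- prof$tM[, 3] + lcont
  tIM <- prof$tI[, 1]; tII <- prof$tI[, 2]
  tDM <- prof$tD[, 1]; tDD <- prof$tD[, 2]
  best <- -Inf
  # recursive enumeration; pos = read bases consumed so far (absolute)
  recur <- function(state, k, pos, sc) {
    if (state == "M") {
      # option: exit here; C emits the rest
      tot <- sc + exitl(k)
      if (pos < L) tot <- tot + sum(lloop + eC[rint[(pos + 1):L]])
      tot <- tot + lleave
      if (tot > best) best <<- tot
    }
    if (state == "M") {
      if (k < K) {
        if (pos < L) {
          recur("M", k + 1, pos + 1, sc + tMM[k] + eM[k + 1, rint[pos + 1]])
          recur("I", k, pos + 1, sc + tMI[k] + eI[k, rint[pos + 1]])
        }
        recur("D", k + 1, pos, sc + tMD[k])
      }
    } else if (state == "I") {
      if (pos < L) {
        recur("I", k, pos + 1, sc + tII[k] + eI[k, rint[pos + 1]])
        if (k < K) recur("M", k + 1, pos + 1, sc + tIM[k] + eM[k + 1, rint[pos + 1]])
      }
    } else if (state == "D") {
      if (k < K) {
        recur("D", k + 1, pos, sc + tDD[k])
        if (pos < L) recur("M", k + 1, pos + 1, sc + tDM[k] + eM[k + 1, rint[pos + 1]])
      }
    }
  }
  for (n5 in 0:(L - 1)) {
    sc5 <- if (n5 > 0) sum(lloop + eN[rint[1:n5]]) else 0
    sc5 <- sc5 + lleave - log(K)
    for (k0 in 1:K) {
      recur("M", k0, n5 + 1, sc5 + eM[k0, rint[n5 + 1]])
    }
  }
  best
}

# naive p-distance between two site vectors over shared observed sites
oracle_pdist <- function(a, b) {
  ok <- a >= 1 & a <= 4 & b >= 1 & b <= 4
  if (!any(ok)) return(NA_real_)
  mean(a[ok] != b[ok])
}

# brute-force tree likelihood: sum over all ancestral-state assignments
oracle_tree_loglik <- function(tree, sites = seq_len(tree$S)) {
  ints <- which(!tree$tip)
  Ps <- lapply(seq_len(tree$n_node), function(v) {
    if (tree$parent[v] == 0L) NULL else transition_matrix(tree$model, tree$blen[v])
  })
  total <- 0
  grid <- as.matrix(expand.grid(rep(list(1:4), length(ints))))
  for (s in sites) {
    acc <- 0
    for (g in seq_len(nrow(grid))) {
      st <- integer(tree$n_node)
      st[ints] <- grid[g, ]
      st[tree$tip] <- tree$seq[tree$tip, s]
      p <- tree$model$pi[st[tree$root]]
      for (v in seq_len(tree$n_node)) {
        u <- tree$parent[v]
        if (u == 0L) next
        sv <- st[v]; su <- st[u]
        if (sv >= 1 && sv <= 4) p <- p * Ps[[v]][su, sv]
        # ambiguous leaf (gap/N): sum over its states = row sum = 1
      }
      acc <- acc + p
    }
    total <- total + log(acc)
  }
  total
}

# whole-tree re-evaluation with a read grafted onto branch (u, v)
oracle_grafted_loglik <- function(tree, aln, pl) {
  v <- pl$v
  w0 <- tree$blen[v]
  pos <- min(max(pl$w_rv, 1e-9), max(w0 - 1e-9, 0))
  qt <- structure(list(edge = matrix(c(2L, 1L), 1, 2), tip.label = "QUERY__",
                       edge.length = max(pl$w_nr, 1e-9), Nnode = 1L),
                  class = "phylo")
  newphy <- ape::bind.tree(tree$phy, qt, where = v, position = pos)
  ls <- stats::setNames(
    vapply(seq_len(tree$n_tip),
           function(j) hmmplace:::int_to_seq(tree$seq[j, ]), character(1)),
    tree$phy$tip.label)
  sites <- hmmplace:::alignment_sites(aln, tree$S)
  ls[["QUERY__"]] <- hmmplace:::int_to_seq(ifelse(sites == 5L, 0L, sites))
  evaluate_tree(build_ref_tree(newphy, ls, tree$model))$loglik
}

# mutate a sequence with iid substitutions at the given rate
mutate_seq <- function(seq, rate) {
  v <- hmmplace:::seq_to_int(seq)
  hit <- which(stats::runif(length(v)) < rate & v >= 1 & v <= 4)
  for (i in hit) v[i] <- sample(setdiff(1:4, v[i]), 1)
  hmmplace:::int_to_seq(v)
}
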