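# Simulators and evaluation metrics: toy reference packages, the read
# simulator (reads emitted from the conditional base posterior at a
# random branching point), the chimera splicer, and the benchmark
# metrics (locus-overlap alignment accuracy, per-level taxonomy
# TPR/TNR/PPV/ACC, and the weighted-UniFrac / Earth-Mover placement
# distance).

TAX_PREFIXES <- c("k", "p", "c", "o", "f", "g", "s")

# leaf taxonomy strings from the tree topology: for rank j (1..7) take
# the ancestor at fraction (j-1)/6 of the root-to-leaf path, so kingdom
# is always the root and species the leaf itself; internal nodes get the
# longest common rank prefix of their descendant leaves
toy_taxonomy <- function(phy) {
  ntip <- length(phy$tip.label)
  n_node <- ntip + phy$Nnode
  parent <- integer(n_node)
  for (e in seq_len(nrow(phy$edge))) parent[phy$edge[e, 2]] <- phy$edge[e, 1]
  leaf_ranks <- matrix("", ntip, 7)
  for (i in seq_len(ntip)) {
    path <- i
    v <- i
    while (parent[v] != 0L) { v <- parent[v]; path <- c(v, path) }
    m <- length(path)
    for (j in 1:7) {
      anc <- path[1 + round((j - 1) / 6 * (m - 1))]
      leaf_ranks[i, j] <- sprintf("%s__n%d", TAX_PREFIXES[j], anc)
    }
  }
  tax_string <- function(ranks) paste(ranks[nzchar(ranks)], collapse = ";")
  leaf_tax <- apply(leaf_ranks, 1L, tax_string)
  # internal nodes: longest common rank prefix of descendant leaves
  desc <- vector("list", n_node)
  for (i in seq_len(ntip)) desc[[i]] <- i
  ord <- rev(seq_len(nrow(phy$edge)))  # cladewise edges reversed: children first
  for (e in ord) {
    u <- phy$edge[e, 1]; v <- phy$edge[e, 2]
    desc[[u]] <- c(desc[[u]], desc[[v]])
  }
  node_tax <- character(phy$Nnode)
  for (v in (ntip + 1):n_node) {
    leaves <- leaf_ranks[desc[[v]], , drop = FALSE]
    shared <- character(0)
    for (j in 1:7) {
      if (length(unique(leaves[, j])) == 1) shared <- c(shared, leaves[1, j])
      else break
    }
    node_tax[v - ntip] <- paste(shared, collapse = ";")
  }
  list(leaf = leaf_tax, node = node_tax)
}

#' Generate a toy reference package with known truth
#'
#' Draws a random bifurcating tree, evolves gap-free sequences along it
#' under the given substitution model, assigns hierarchical 7-rank
#' taxonomy strings from clade structure, and assembles the full
#' reference package (index, profile, evaluated phylogeny). Everything
#' is a deterministic function of `seed`.
#'
#' @param n_leaves number of tips (>= 4)
#' @param S number of sites (>= 50)
#' @param model a `subst_model` (default a mildly asymmetric GTR)
#' @param seed RNG seed
#' @param branch_scale mean branch length in substitutions/site
#' @return list with `package` (a `ref_package`) and `truth`
#'   (`phy`, `leaf_taxonomy`, `model`)
#' @export
make_toy_reference <- function(n_leaves = 20L, S = 200L, model = NULL,
                               seed = 1L, branch_scale = 0.08) {
  if (n_leaves < 4) stop_hp("n_leaves must be >= 4")
  if (S < 50) stop_hp("S must be >= 50")
  model <- model %||% subst_model("GTR", pi = c(0.30, 0.20, 0.27, 0.23),
                                  rates = c(1.2, 3.5, 0.9, 1.1, 4.0, 1.0))
  set.seed(seed)
  phy <- ape::rtree(n_leaves, br = NULL)
  phy$edge.length <- stats::runif(nrow(phy$edge), 0.25, 1.75) * branch_scale
  ntip <- n_leaves
  n_node <- ntip + phy$Nnode
  phy$node.label <- paste0("n", (ntip + 1):n_node)
  # evolve sequences root -> tips
  parent <- integer(n_node)
  blen <- numeric(n_node)
  for (e in seq_len(nrow(phy$edge))) {
    parent[phy$edge[e, 2]] <- phy$edge[e, 1]
    blen[phy$edge[e, 2]] <- phy$edge.length[e]
  }
  root <- ntip + 1L
  seqs <- matrix(0L, n_node, S)
  seqs[root, ] <- sample.int(4L, S, replace = TRUE, prob = model$pi)
  # preorder
  kids <- vector("list", n_node)
  for (v in seq_len(n_node)) if (parent[v] > 0) kids[[parent[v]]] <- c(kids[[parent[v]]], v)
  stack <- root
  while (length(stack) > 0) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    for (c_ in kids[[v]]) {
      P <- transition_matrix(model, blen[c_])
      seqs[c_, ] <- vapply(seqs[v, ], function(b)
        sample.int(4L, 1L, prob = P[b, ]), integer(1))
      stack <- c(stack, c_)
    }
  }
  leaf_seqs <- vapply(seq_len(ntip), function(i) int_to_seq(seqs[i, ]), character(1))
  msa <- msa_from_records(leaf_seqs, phy$tip.label)
  tax <- toy_taxonomy(phy)
  taxonomy <- data.frame(
    id = c(phy$tip.label, phy$node.label),
    taxonomy = c(tax$leaf, tax$node),
    stringsAsFactors = FALSE)
  pkg <- build_reference_package(msa, phy, taxonomy, model = model)
  list(package = pkg,
       truth = list(phy = phy, leaf_taxonomy = stats::setNames(tax$leaf, phy$tip.label),
                    model = model, seed = seed))
}

#' Simulate amplicon reads from a reference package
#'
#' Mimics construction of a 16S library: per read, (1) a branch is drawn
#' uniformly from the reference tree, (2) a branching point uniformly
#' along it, (3) a consensus locus (fixed or uniform start), (4) an
#' amplicon size (fixed, or truncated-Gaussian for random loci), and
#' (5) bases sampled from the conditional posterior of the four bases at
#' the branching point; gap sites are skipped so reads are gap-free.
#' The true branch, branching fraction, locus, and taxonomy (of the
#' nearer branch endpoint) are recorded for every read.
#'
#' @param pkg a `ref_package`
#' @param n_samples,reads_per_sample experiment shape (defaults 20 x 5000)
#' @param locus_mode "random" or "fixed"
#' @param locus c(start, end) when `locus_mode = "fixed"`
#' @param amplicon list: `type` "gaussian" (fields mu, sd, min, max) or
#'   "fixed_len" (field len); defaults mu=150, sd=30, min=75, max=300
#' @param seed RNG seed
#' @param branch_set optional child-node ids restricting the branch draw
#'   (e.g. leaf branches only)
#' @param frac_range branching-fraction range, measured from the parent
#'   (default c(0, 1))
#' @return data.frame: `id`, `sample`, `seq`, `branch` (child node id),
#'   `fraction`, `cs_start`, `cs_end`, `taxonomy`
#' @export
simulate_reads <- function(pkg, n_samples = 20L, reads_per_sample = 5000L,
                           locus_mode = c("random", "fixed"), locus = NULL,
                           amplicon = list(type = "gaussian", mu = 150,
                                           sd = 30, min = 75, max = 300),
                           seed = 1L, branch_set = NULL,
                           frac_range = c(0, 1)) {
  locus_mode <- match.arg(locus_mode)
  tree <- pkg$tree
  S <- tree$S
  if (locus_mode == "fixed") {
    if (is.null(locus)) stop_hp("fixed locus_mode needs `locus = c(start, end)`")
    if (locus[2] - locus[1] + 1 > S) stop_hp("amplicon longer than the consensus")
  }
  if (identical(amplicon$type, "fixed_len") && amplicon$len > S)
    stop_hp("amplicon longer than the consensus")
  branches <- branch_set %||% which(tree$parent != 0L)
  set.seed(seed)
  n_total <- n_samples * reads_per_sample
  rates <- tree_rates(tree)
  ncat <- length(rates)
  lpi <- log(tree$model$pi)
  out <- vector("list", n_total)
  for (r in seq_len(n_total)) {
    v <- branches[sample.int(length(branches), 1L)]
    f <- stats::runif(1, frac_range[1], frac_range[2])
    w0 <- tree$blen[v]
    w_ur <- f * w0
    if (locus_mode == "fixed") {
      st <- locus[1]; en <- locus[2]
    } else {
      len <- if (identical(amplicon$type, "fixed_len")) amplicon$len else {
        repeat {
          len <- round(stats::rnorm(1, amplicon$mu, amplicon$sd))
          if (len >= amplicon$min && len <= amplicon$max) break
        }
        len
      }
      len <- min(len, S)
      st <- sample.int(S - len + 1L, 1L)
      en <- st + len - 1L
    }
    sitesel <- st:en
    # conditional posterior over bases at the branch point, per site
    probs <- matrix(0, 4, length(sitesel))
    for (g in seq_len(ncat)) {
      A <- convolute(matrix(tree$lik_out[[v]][, sitesel, g], nrow = 4),
                     transition_matrix(tree$model, w_ur, rates[g]))
      B <- convolute(matrix(tree$lik_sub[[v]][, sitesel, g], nrow = 4),
                     transition_matrix(tree$model, w0 - w_ur, rates[g]))
      lp <- A + B + lpi
      probs <- probs + exp(sweep(lp, 2L, col_log_sum_exp(lp), "-"))
    }
    probs <- probs / ncat
    near <- if (f < 0.5) tree$parent[v] else v
    gap <- tree$seq[near, sitesel] == 0L
    bases <- vapply(which(!gap), function(j)
      sample.int(4L, 1L, prob = probs[, j]), integer(1))
    out[[r]] <- data.frame(
      id = sprintf("read%06d", r),
      sample = sprintf("S%02d", (r - 1L) %/% reads_per_sample + 1L),
      seq = paste(DNA_BASES[bases], collapse = ""),
      branch = v, fraction = f, cs_start = st, cs_end = en,
      taxonomy = tree$taxonomy[near],
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Simulate chimeric and non-chimeric reads from an MSA
#'
#' For each p-distance bin, pairs of aligned reference sequences whose
#' p-distance falls in the bin are drawn; a breaking point is uniform on
#' the aligned positions. If its fraction lies in [0.25, 0.75) the two
#' sequences are spliced into a chimera, otherwise the first sequence is
#' kept unchanged (a non-chimeric control). Alignment gaps are removed
#' from the emitted sequences.
#'
#' @param msa an `hp_msa`
#' @param bins list of c(lo, hi) p-distance ranges (default the four
#'   ranges [0.01,0.03), [0.03,0.05), [0.05,0.10), [0.10,0.15))
#' @param n_per_bin records per bin
#' @param seed RNG seed
#' @return data.frame: `id`, `seq`, `parent1`, `parent2`, `bin`,
#'   `breakpoint`, `label` ("chimera"/"non-chimera")
#' @export
simulate_chimeras <- function(msa,
                              bins = list(c(0.01, 0.03), c(0.03, 0.05),
                                          c(0.05, 0.10), c(0.10, 0.15)),
                              n_per_bin = 100L, seed = 1L) {
  n <- msa$n
  pd <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- msa$mat[i, ]; b <- msa$mat[j, ]
    ok <- a >= 1 & a <= 4 & b >= 1 & b <= 4
    pd[i, j] <- pd[j, i] <- mean(a[ok] != b[ok])
  }
  set.seed(seed)
  out <- list()
  rid <- 0L
  for (bi in seq_along(bins)) {
    rng <- bins[[bi]]
    cand <- which(upper.tri(pd) & pd >= rng[1] & pd < rng[2], arr.ind = TRUE)
    if (nrow(cand) == 0)
      stop_hp("no sequence pair with p-distance in [%g,%g)", rng[1], rng[2])
    for (k in seq_len(n_per_bin)) {
      rid <- rid + 1L
      pick <- cand[sample.int(nrow(cand), 1L), ]
      bp_frac <- stats::runif(1)
      bp <- max(1L, min(msa$L - 1L, round(bp_frac * msa$L)))
      is_chim <- bp_frac >= 0.25 && bp_frac < 0.75
      s1 <- msa$seqs[pick[1]]; s2 <- msa$seqs[pick[2]]
      seq_aln <- if (is_chim)
        paste0(substr(s1, 1, bp), substr(s2, bp + 1, msa$L)) else s1
      out[[rid]] <- data.frame(
        id = sprintf("chim%05d", rid),
        seq = gsub("-", "", seq_aln, fixed = TRUE),
        parent1 = msa$ids[pick[1]], parent2 = msa$ids[pick[2]],
        bin = sprintf("[%g,%g)", rng[1], rng[2]),
        breakpoint = bp_frac,
        label = if (is_chim) "chimera" else "non-chimera",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Alignment accuracy by the 90%-overlap rule
#'
#' A read's alignment is correct when the aligned consensus locus covers
#' at least 90% of the true locus.
#'
#' @param alignments data.frame with `id`, `cs_start`, `cs_end`
#' @param truths data.frame with `id`, `cs_start`, `cs_end`
#' @param min_overlap fraction of the true locus (default 0.9)
#' @return list with `accuracy` and per-read logical `correct`
#' @export
eval_alignment <- function(alignments, truths, min_overlap = 0.9) {
  m <- match(alignments$id, truths$id)
  ts <- truths$cs_start[m]; te <- truths$cs_end[m]
  inter <- pmax(0, pmin(alignments$cs_end, te) - pmax(alignments$cs_start, ts) + 1)
  correct <- inter / (te - ts + 1) >= min_overlap
  list(accuracy = mean(correct), correct = correct)
}

parse_ranks <- function(tax) {
  out <- matrix("", length(tax), 7)
  for (i in seq_along(tax)) {
    parts <- strsplit(tax[i], ";", fixed = TRUE)[[1]]
    parts <- trimws(parts)
    for (p in parts) {
      j <- match(substr(p, 1, 1), TAX_PREFIXES)
      if (!is.na(j) && nchar(p) > 3) out[i, j] <- p
    }
  }
  out
}

#' Per-level taxonomy assignment metrics
#'
#' True positive: both the known and the assigned taxonomy carry the
#' level and agree; true negative: both lack it; a disagreement counts
#' as both a false positive and a false negative; an annotation present
#' on only one side is a false positive (assigned only) or false
#' negative (known only).
#'
#' @param assigned,truth character vectors of taxonomy strings
#'   ("k__..;p__..;...")
#' @return data.frame with one row per rank: `level`, `TP`, `TN`, `FP`,
#'   `FN`, `TPR`, `TNR`, `PPV`, `ACC` (ratios in percent; NaN when
#'   undefined)
#' @export
eval_taxonomy <- function(assigned, truth) {
  A <- parse_ranks(assigned)
  Tr <- parse_ranks(truth)
  out <- lapply(1:7, function(j) {
    a <- A[, j]; t_ <- Tr[, j]
    ha <- nzchar(a); ht <- nzchar(t_)
    tp <- sum(ha & ht & a == t_)
    tn <- sum(!ha & !ht)
    fp <- sum(ha & (!ht | (ht & a != t_)))
    fn <- sum(ht & (!ha | (ha & a != t_)))
    data.frame(level = TAX_PREFIXES[j], TP = tp, TN = tn, FP = fp, FN = fn,
               TPR = 100 * tp / (tp + fn), TNR = 100 * tn / (tn + fp),
               PPV = 100 * tp / (tp + fp),
               ACC = 100 * (tp + tn) / (tp + tn + fp + fn))
  })
  do.call(rbind, out)
}

#' Weighted-UniFrac (Earth-Mover) distance between two placement sets
#'
#' Both sets are normalized to unit mass on the nodes of the same
#' reference tree; the distance is the minimal mass-transport cost along
#' branches, computed as `sum_branches blen * |subtree mass difference|`.
#'
#' @param placements_a,placements_b data.frames with `node` (and
#'   optionally `mass`; default equal mass per row)
#' @param tree a `ref_tree`
#' @return scalar distance
#' @export
placement_emd <- function(placements_a, placements_b, tree) {
  mass_on <- function(pl) {
    m <- numeric(tree$n_node)
    w <- pl$mass %||% rep(1, nrow(pl))
    if (sum(w) <= 0) stop_hp("placement set has zero total mass")
    for (i in seq_len(nrow(pl))) m[pl$node[i]] <- m[pl$node[i]] + w[i]
    m / sum(w)
  }
  ma <- mass_on(placements_a)
  mb <- mass_on(placements_b)
  # subtree-cumulative masses, bottom-up (postorder: children first, so
  # each node's subtree total is complete before it is added to its parent)
  ca <- ma; cb <- mb
  for (v in tree$postorder) {
    u <- tree$parent[v]
    if (u > 0L) { ca[u] <- ca[u] + ca[v]; cb[u] <- cb[u] + cb[v] }
  }
  sum(vapply(which(tree$parent != 0L), function(v)
    tree$blen[v] * abs(ca[v] - cb[v]), numeric(1)))
}
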