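# Reference tree engine: Felsenstein pruning with cached directional
# conditional log-likelihoods on every branch, ML ancestral sequence
# inference, taxonomy propagation, and reference-package assembly.
#
# Caches (all 4 x S x ncat log-likelihood arrays):
#   lik_sub[[v]]  - data in the subtree below v, conditional on v's state
#   lik_out[[v]]  - data outside v's subtree, conditional on the state of
#                   v's *parent* (exclusive of the branch parent-v)
# With a reversible model these two messages let any branch act as a
# local root (Pulley Principle), which is what the SEP placement step
# exploits: attaching a read to branch (u,v) only needs lik_out[[v]],
# lik_sub[[v]] and the read's own leaf log-likelihoods.

#' Log-space convolution of a conditional-likelihood matrix with P
#'
#' `out[i, s] = log sum_j P[i, j] * exp(L[j, s])`, computed by
#' log-sum-exp so entries as low as -1e4 neither overflow nor underflow.
#'
#' @param L 4 x S log-likelihood matrix
#' @param P 4 x 4 row-stochastic transition matrix
#' @return 4 x S log matrix
#' @export
convolute <- function(L, P) {
  if (any(abs(rowSums(P) - 1) > 1e-6)) stop_hp("P is not row-stochastic")
  mx <- if (nrow(L) == 4L) pmax(L[1L, ], L[2L, ], L[3L, ], L[4L, ])
        else apply(L, 2L, max)
  if (all(is.finite(mx))) {
    return(log(P %*% exp(L - rep(mx, each = nrow(L)))) +
             rep(mx, each = nrow(L)))
  }
  fin <- is.finite(mx)
  out <- matrix(-Inf, nrow(L), ncol(L))
  if (any(fin)) {
    E <- exp(sweep(L[, fin, drop = FALSE], 2L, mx[fin], "-"))
    out[, fin] <- log(P %*% E) + rep(mx[fin], each = 4L)
  }
  out
}

# leaf conditional log-likelihoods from an integer site vector
# (1..4 observed base; 0 gap or 5 N -> fully ambiguous, likelihood 1)
leaf_loglik <- function(sites) {
  S <- length(sites)
  L <- matrix(-Inf, 4, S)
  amb <- sites == 0L | sites == 5L
  L[, amb] <- 0
  obs <- which(!amb)
  if (length(obs) > 0) L[cbind(sites[obs], obs)] <- 0
  L
}

#' Build the internal reference-tree structure
#'
#' @param phy rooted [ape::phylo]; multifurcations are resolved by
#'   inserting zero-length branches
#' @param leaf_seqs named character vector of aligned leaf sequences
#'   (match columns only, names = tip labels)
#' @param model a `subst_model`
#' @param taxonomy optional data.frame (id, taxonomy) annotating tips
#'   and/or internal node labels
#' @param dgamma optional `discrete_gamma`
#' @return an object of class `ref_tree` (not yet evaluated)
#' @export
build_ref_tree <- function(phy, leaf_seqs, model, taxonomy = NULL,
                           dgamma = NULL) {
  if (!ape::is.rooted(phy)) stop_hp("reference tree must be rooted")
  if (!ape::is.binary(phy)) phy <- ape::multi2di(phy)
  ntip <- length(phy$tip.label)
  n_node <- ntip + phy$Nnode
  parent <- integer(n_node)
  blen <- numeric(n_node)
  for (e in seq_len(nrow(phy$edge))) {
    child <- phy$edge[e, 2]
    parent[child] <- phy$edge[e, 1]
    blen[child] <- if (!is.null(phy$edge.length)) max(phy$edge.length[e], 0) else 0.1
  }
  root <- ntip + 1L
  parent[root] <- 0L
  children <- vector("list", n_node)
  for (v in seq_len(n_node)) if (parent[v] > 0) {
    children[[parent[v]]] <- c(children[[parent[v]]], v)
  }
  miss <- setdiff(phy$tip.label, names(leaf_seqs))
  if (length(miss) > 0)
    stop_hp("tree tips missing from the alignment: %s",
            paste(miss, collapse = ", "))
  S <- nchar(leaf_seqs[[phy$tip.label[1]]])
  seqm <- matrix(NA_integer_, n_node, S)
  for (i in seq_len(ntip)) seqm[i, ] <- seq_to_int(leaf_seqs[[phy$tip.label[i]]])
  label <- c(phy$tip.label,
             if (!is.null(phy$node.label)) phy$node.label else rep("", phy$Nnode))
  label[!nzchar(label)] <- ""
  taxo <- rep("", n_node)
  if (!is.null(taxonomy)) {
    hit <- match(label, taxonomy$id)
    taxo[!is.na(hit)] <- taxonomy$taxonomy[hit[!is.na(hit)]]
  }
  # iterative DFS preorder; its reverse is a valid postorder
  pre <- integer(0)
  stack <- root
  while (length(stack) > 0) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    pre <- c(pre, v)
    stack <- c(stack, children[[v]])
  }
  structure(list(phy = phy, n_tip = ntip, n_node = n_node, root = root,
                 parent = parent, children = children, blen = blen,
                 label = label, taxonomy = taxo,
                 tip = seq_len(n_node) <= ntip,
                 seq = seqm, S = S, model = model, dgamma = dgamma,
                 preorder = pre, postorder = rev(pre),
                 lik_sub = NULL, lik_out = NULL, loglik = NA_real_),
            class = "ref_tree")
}

#' @export
print.ref_tree <- function(x, ...) {
  cat(sprintf("ref_tree: %d tips, %d nodes, %d sites, %s model%s%s\n",
              x$n_tip, x$n_node, x$S, x$model$name,
              if (!is.null(x$dgamma)) sprintf(", dGamma(alpha=%.3g, k=%d)",
                                              x$dgamma$alpha, x$dgamma$k) else "",
              if (is.finite(x$loglik)) sprintf(", logL = %.3f", x$loglik) else ""))
  invisible(x)
}

tree_rates <- function(tree) {
  if (is.null(tree$dgamma)) 1 else tree$dgamma$category_rates
}

# transition matrices for one branch, one per rate category
branch_P <- function(tree, v) {
  lapply(tree_rates(tree), function(r) transition_matrix(tree$model, tree$blen[v], r))
}

#' Evaluate a reference tree (Felsenstein pruning, both directions)
#'
#' Fills `lik_sub` by a postorder sweep and `lik_out` by a preorder
#' sweep, then computes the total log-likelihood
#' `sum_s log sum_b pi_b exp(lik_sub[root][b, s])`, averaged over
#' discrete-Gamma category rates when present. After evaluation any
#' branch can serve as a local root.
#'
#' @param tree a `ref_tree`
#' @return the evaluated tree (fields `lik_sub`, `lik_out`, `loglik`,
#'   `site_loglik` filled)
#' @export
evaluate_tree <- function(tree) {
  if (is.null(tree$model)) stop_hp("tree has no substitution model")
  rates <- tree_rates(tree)
  ncat <- length(rates)
  S <- tree$S
  Pcache <- lapply(seq_len(tree$n_node), function(v) {
    if (tree$parent[v] == 0L) NULL else branch_P(tree, v)
  })
  lik_sub <- vector("list", tree$n_node)
  for (v in tree$postorder) {
    if (tree$tip[v]) {
      base <- leaf_loglik(tree$seq[v, ])
      lik_sub[[v]] <- array(base, dim = c(4, S, ncat))
    } else {
      acc <- array(0, dim = c(4, S, ncat))
      for (c_ in tree$children[[v]]) {
        for (g in seq_len(ncat)) {
          acc[, , g] <- acc[, , g] +
            convolute(matrix(lik_sub[[c_]][, , g], nrow = 4), Pcache[[c_]][[g]])
        }
      }
      lik_sub[[v]] <- acc
    }
  }
  lik_out <- vector("list", tree$n_node)
  for (v in tree$preorder) {
    u <- tree$parent[v]
    if (u == 0L) next
    acc <- array(0, dim = c(4, S, ncat))
    if (tree$parent[u] != 0L) {
      for (g in seq_len(ncat)) {
        acc[, , g] <- convolute(matrix(lik_out[[u]][, , g], nrow = 4),
                                Pcache[[u]][[g]])
      }
    }
    for (s_ in tree$children[[u]]) {
      if (s_ == v) next
      for (g in seq_len(ncat)) {
        acc[, , g] <- acc[, , g] +
          convolute(matrix(lik_sub[[s_]][, , g], nrow = 4), Pcache[[s_]][[g]])
      }
    }
    lik_out[[v]] <- acc
  }
  lpi <- log(tree$model$pi)
  percat <- vapply(seq_len(ncat), function(g) {
    col_log_sum_exp(matrix(lik_sub[[tree$root]][, , g], nrow = 4) + lpi)
  }, numeric(S))
  dim(percat) <- c(S, ncat)
  site_ll <- apply(percat, 1L, log_sum_exp) - log(ncat)
  tree$lik_sub <- lik_sub
  tree$lik_out <- lik_out
  tree$site_loglik <- site_ll
  tree$loglik <- sum(site_ll)
  tree
}

# marginal posterior (unnormalized log) over states at node v, per site,
# summed over rate categories
node_marginal_log <- function(tree, v) {
  rates <- tree_rates(tree)
  ncat <- length(rates)
  lpi <- log(tree$model$pi)
  per <- lapply(seq_len(ncat), function(g) {
    up <- if (tree$parent[v] == 0L) 0 else
      convolute(matrix(tree$lik_out[[v]][, , g], nrow = 4),
                transition_matrix(tree$model, tree$blen[v], rates[g]))
    matrix(tree$lik_sub[[v]][, , g], nrow = 4) + up + lpi
  })
  if (ncat == 1) return(per[[1]])
  arr <- array(unlist(per), dim = c(4, tree$S, ncat))
  apply(arr, c(1, 2), log_sum_exp) - log(ncat)
}

#' Infer ML ancestral sequences at all internal nodes
#'
#' Per node and site, the state maximizing the marginal posterior
#' (product of the sub-tree and rest-of-tree messages and the
#' stationary frequencies). Sites where more than half of a node's
#' descendant leaves are gapped are assigned a gap.
#'
#' @param tree an evaluated `ref_tree`
#' @return the tree with `seq` filled for internal nodes
#' @export
infer_ancestral_sequences <- function(tree) {
  if (is.null(tree$lik_sub)) stop_hp("tree must be evaluated first")
  # descendant-leaf gap fractions, bottom-up
  gapcount <- matrix(0, tree$n_node, tree$S)
  nleaf <- numeric(tree$n_node)
  for (v in tree$postorder) {
    if (tree$tip[v]) {
      gapcount[v, ] <- as.numeric(tree$seq[v, ] == 0L)
      nleaf[v] <- 1
    } else {
      for (c_ in tree$children[[v]]) {
        gapcount[v, ] <- gapcount[v, ] + gapcount[c_, ]
        nleaf[v] <- nleaf[v] + nleaf[c_]
      }
    }
  }
  for (v in which(!tree$tip)) {
    post <- node_marginal_log(tree, v)
    st <- apply(post, 2L, which.max)
    st[gapcount[v, ] / nleaf[v] > 0.5] <- 0L
    tree$seq[v, ] <- st
  }
  tree
}

#' Propagate taxonomy labels down the tree
#'
#' Every node without its own annotation inherits the taxonomy string of
#' its nearest annotated ancestor.
#'
#' @param tree a `ref_tree` (root must be annotated, at least to kingdom)
#' @return the tree with `taxonomy` filled on every node
#' @export
propagate_taxonomy <- function(tree) {
  if (!nzchar(tree$taxonomy[tree$root]))
    stop_hp("root node has no taxonomy annotation")
  for (v in tree$preorder) {
    if (v == tree$root) next
    if (!nzchar(tree$taxonomy[v]))
      tree$taxonomy[v] <- tree$taxonomy[tree$parent[v]]
  }
  tree
}

#' Assemble a complete reference package
#'
#' Builds, from an aligned reference MSA, a rooted tree and a taxonomy
#' table: the match-column alignment statistics, the CSFM-index over the
#' gap-free consensus, the trained plan7 profile, and the evaluated
#' phylogeny with ancestral sequences and propagated taxonomy. With
#' `dgamma = TRUE` the discrete-Gamma shape is estimated from per-site
#' mutation counts (moment matching) and the tree re-evaluated under the
#' discretized rates.
#'
#' @param msa an `hp_msa` or path to an aligned FASTA
#' @param tree an [ape::phylo], or Newick text/path
#' @param taxonomy data.frame (id, taxonomy) or path to a taxonomy TSV;
#'   NULL assigns a bare "k__Root" to the root
#' @param model a `subst_model`, or a model name ("GTR", "TN93",
#'   "HKY85") to be trained from the MSA by the Gojobori triplet method
#' @param dgamma enable discrete-Gamma among-site rate variation
#' @param dgamma_k category count (default 4)
#' @return an object of class `ref_package` with fields `msa`, `index`,
#'   `profile`, `tree`, `taxonomy`, `meta`
#' @export
build_reference_package <- function(msa, tree, taxonomy = NULL,
                                    model = "GTR", dgamma = FALSE,
                                    dgamma_k = 4L) {
  if (is.character(msa)) msa <- read_msa(msa)
  if (is.character(tree)) {
    tree_txt <- if (file.exists(tree[1]) && length(tree) == 1)
      paste(readLines(tree), collapse = "") else paste(tree, collapse = "")
    phy <- parse_newick(tree_txt)
  } else phy <- tree
  if (is.character(taxonomy) && length(taxonomy) == 1 && file.exists(taxonomy))
    taxonomy <- read_taxonomy_tsv(taxonomy)
  if (is.character(model)) {
    model <- train_subst_model(msa, method = "gojobori3", model_name = model)
  }
  match_cols <- which(msa$col_gap_frac <= 0.5)
  if (length(match_cols) == 0) stop_hp("no match columns in the MSA")
  miss <- setdiff(phy$tip.label, msa$ids)
  if (length(miss) > 0)
    stop_hp("tree tips absent from MSA: %s", paste(miss, collapse = ", "))
  leaf_seqs <- vapply(phy$tip.label, function(id) {
    row <- msa$mat[match(id, msa$ids), match_cols]
    int_to_seq(row)
  }, character(1))
  rt <- build_ref_tree(phy, leaf_seqs, model, taxonomy)
  if (!nzchar(rt$taxonomy[rt$root])) rt$taxonomy[rt$root] <- "k__Root"
  rt <- evaluate_tree(rt)
  rt <- infer_ancestral_sequences(rt)
  rt <- propagate_taxonomy(rt)
  alpha <- NA_real_
  if (isTRUE(dgamma)) {
    alpha <- estimate_gamma_shape(count_site_mutations(rt))
    if (!is.na(alpha)) {
      rt$dgamma <- discretize_gamma(alpha, dgamma_k)
      rt <- evaluate_tree(rt)
    }
  }
  consensus_cs <- gsub("-", "", msa$consensus, fixed = TRUE)
  index <- build_index(consensus_cs)
  profile <- build_profile(msa)
  stopifnot(profile$K == rt$S)
  structure(list(msa = msa, index = index, profile = profile, tree = rt,
                 taxonomy = data.frame(id = rt$label, taxonomy = rt$taxonomy,
                                       stringsAsFactors = FALSE),
                 meta = list(magic = "hmmplace-refpkg", version = 1L,
                             model = model$name, dgamma = isTRUE(dgamma),
                             dgamma_alpha = alpha, S = rt$S)),
            class = "ref_package")
}

#' @export
print.ref_package <- function(x, ...) {
  cat(sprintf("ref_package: %d tips, %d sites, %s model, dGamma %s\n",
              x$tree$n_tip, x$tree$S, x$meta$model,
              if (x$meta$dgamma) "on" else "off"))
  invisible(x)
}

#' Save / load a reference package
#'
#' The on-disk archive is a serialized R object carrying a magic string
#' and format version for self-description.
#'
#' @param pkg a `ref_package`
#' @param path archive path
#' @export
save_reference_package <- function(pkg, path) {
  saveRDS(pkg, path, version = 2)
  invisible(path)
}

#' @rdname save_reference_package
#' @export
load_reference_package <- function(path) {
  pkg <- readRDS(path)
  if (!identical(pkg$meta$magic, "hmmplace-refpkg"))
    stop_hp("'%s' is not a reference-package archive", path)
  pkg
}
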