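# Phylogeny-based OTU summarization: cluster placements around reference
# nodes, infer Dirichlet-consensus representative sequences, prune the
# reference tree to an OTU tree, and write the OTU artifacts.

#' Cluster placements into phylogeny-based OTUs
#'
#' Every reference node carrying at least `otu_min_reads` placed reads
#' (after excluding chimera-flagged and sub-Q reads upstream) becomes an
#' OTU; reads on sub-threshold nodes are returned in the rejects table
#' so read counts are conserved.
#'
#' @param placements data.frame with at least columns `id`, `node`,
#'   `sample`
#' @param otu_min_reads minimum total reads for a node to form an OTU
#'   (default 1: every placed node is its own OTU)
#' @return list with `otus` (list of per-node records: `node`, `counts`
#'   per sample, `members`) and `rejects` (data.frame of dropped reads)
#' @export
cluster_placements <- function(placements, otu_min_reads = 1L) {
  if (nrow(placements) == 0)
    return(list(otus = list(), rejects = placements))
  samples <- sort(unique(placements$sample))
  byn <- split(placements, placements$node)
  keep <- vapply(byn, nrow, integer(1)) >= otu_min_reads
  otus <- lapply(byn[keep], function(df) {
    cnt <- table(factor(df$sample, levels = samples))
    list(node = df$node[1], counts = as.integer(cnt),
         samples = samples, members = df$id)
  })
  rejects <- do.call(rbind, byn[!keep])
  if (is.null(rejects)) rejects <- placements[0, ]
  list(otus = unname(otus), rejects = rejects)
}

#' Dirichlet-consensus representative sequence of an OTU
#'
#' Per consensus site, observed base counts from the member reads'
#' aligned strings are combined with a Dirichlet density prior whose
#' parameters are the `concentration` times the node's likelihood-
#' normalized base posterior (softmax over the node's marginal
#' log-likelihoods, from the pre-evaluated caches). The consensus base
#' maximizes the posterior mean, unless gap observations outnumber base
#' observations, in which case a gap is emitted. `use_prior = FALSE`
#' sets the prior parameters to zero.
#'
#' @param otu one OTU record from [cluster_placements()]
#' @param tree the evaluated `ref_tree`
#' @param alignments named list (by read id) of `hp_alignment`s of the
#'   member reads
#' @param concentration total prior strength (default 2 pseudo-reads)
#' @param use_prior disable to use raw observed counts
#' @return list with `seq` (gap-free rep-seq), `aligned` (over the OTU's
#'   observed consensus span), `span` (c(start, end))
#' @export
consensus_repseq <- function(otu, tree, alignments, concentration = 2,
                             use_prior = TRUE) {
  members <- alignments[otu$members]
  members <- members[!vapply(members, is.null, logical(1))]
  if (length(members) == 0) stop_hp("OTU at node %s has no member alignments",
                                    otu$node)
  S <- tree$S
  counts <- matrix(0, 5, S)    # rows: A,C,G,T, gap-within-span
  lo <- S + 1L; hi <- 0L
  for (a in members) {
    sites <- alignment_sites(a, S)
    lo <- min(lo, a$cs_start); hi <- max(hi, a$cs_end)
    idx <- a$cs_start:a$cs_end
    for (s in idx) {
      b <- sites[s]
      if (b >= 1 && b <= 4) counts[b, s] <- counts[b, s] + 1
      else if (b == 0) counts[5, s] <- counts[5, s] + 1
    }
  }
  post <- node_marginal_log(tree, otu$node)   # 4 x S unnormalized log
  span <- lo:hi
  out <- vapply(span, function(s) {
    prior <- if (use_prior) {
      p <- exp(post[, s] - log_sum_exp(post[, s]))
      concentration * p
    } else rep(0, 4)
    pm <- counts[1:4, s] + prior
    if (counts[5, s] > sum(counts[1:4, s])) return("-")
    if (sum(pm) == 0) return("-")
    DNA_BASES[which.max(pm)]
  }, character(1))
  aligned <- paste(out, collapse = "")
  list(seq = gsub("-", "", aligned, fixed = TRUE), aligned = aligned,
       span = c(lo, hi))
}

#' Prune the reference tree to an OTU tree
#'
#' Keeps the OTU nodes plus the minimal set of connecting nodes, then
#' collapses pass-through (degree-2) nodes summing their branch lengths,
#' so pairwise path lengths between OTU nodes are preserved.
#'
#' @param tree a `ref_tree`
#' @param otu_nodes integer node ids of the OTUs
#' @return an [ape::phylo] tree whose tips/nodes are the OTU nodes
#'   (labels `otu_<node>` for OTU nodes)
#' @export
prune_otu_tree <- function(tree, otu_nodes) {
  otu_nodes <- sort(unique(otu_nodes))
  if (length(otu_nodes) == 0) stop_hp("no OTU nodes to keep")
  is_otu <- rep(FALSE, tree$n_node)
  is_otu[otu_nodes] <- TRUE
  # a node is retained while it is an OTU or has >= 1 retained child;
  # compute bottom-up, then drop chains by collapsing degree-2 nodes
  retained <- is_otu
  for (v in tree$postorder) {
    if (retained[v] && tree$parent[v] != 0L) retained[tree$parent[v]] <- TRUE
  }
  # recursive emit: returns NULL (pruned), or list(label, length, newick)
  node_label <- function(v) {
    if (is_otu[v]) paste0("otu_", v)
    else ""
  }
  emit <- function(v, acc_len) {
    kids <- tree$children[[v]]
    kids <- kids[retained[kids]]
    if (length(kids) == 0) {
      if (!is_otu[v]) return(NULL)
      return(sprintf("%s:%s", node_label(v), format(acc_len, digits = 12)))
    }
    sub <- lapply(kids, function(k) emit(k, tree$blen[k]))
    sub <- sub[!vapply(sub, is.null, logical(1))]
    if (length(sub) == 0) {
      if (!is_otu[v]) return(NULL)
      return(sprintf("%s:%s", node_label(v), format(acc_len, digits = 12)))
    }
    if (length(sub) == 1 && !is_otu[v]) {
      # pass-through: splice the child upward, adding this branch length
      child <- sub[[1]]
      # child is "...:len"; add acc_len to its top length
      m <- regmatches(child, regexpr(":[-0-9.eE+]+$", child))
      len <- as.numeric(substring(m, 2))
      return(sprintf("%s:%s", sub(":[-0-9.eE+]+$", "", child),
                     format(len + acc_len, digits = 12)))
    }
    sprintf("(%s)%s:%s", paste(unlist(sub), collapse = ","), node_label(v),
            format(acc_len, digits = 12))
  }
  nwk <- emit(tree$root, 0)
  if (is.null(nwk)) stop_hp("pruning removed every node")
  # root: strip the trailing :0 length
  nwk <- sub(":[-0-9.eE+]+$", "", nwk)
  parse_newick(paste0(nwk, ";"))
}

#' Write the OTU table, representative sequences, and OTU tree
#'
#' @param otus list from [cluster_placements()]
#' @param tree the `ref_tree`
#' @param alignments named list of member `hp_alignment`s
#' @param outdir output directory (created if needed)
#' @param use_prior passed to [consensus_repseq()]
#' @return invisible named vector of the three file paths
#'   (`otu_table.tsv`, `rep_seqs.fasta`, `otu_tree.nwk`)
#' @export
write_otu_artifacts <- function(otus, tree, alignments, outdir,
                                use_prior = TRUE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tab_path <- file.path(outdir, "otu_table.tsv")
  fas_path <- file.path(outdir, "rep_seqs.fasta")
  nwk_path <- file.path(outdir, "otu_tree.nwk")
  if (length(otus) == 0) {
    writeLines("#OTU_ID\ttaxonomy", tab_path)
    file.create(fas_path)
    writeLines(";", nwk_path)
    return(invisible(c(otu_table = tab_path, rep_seqs = fas_path,
                       otu_tree = nwk_path)))
  }
  samples <- otus[[1]]$samples
  con <- file(tab_path, "w")
  writeLines(paste(c("#OTU_ID", samples, "taxonomy"), collapse = "\t"), con)
  for (o in otus) {
    writeLines(paste(c(paste0("otu_", o$node), o$counts,
                       tree$taxonomy[o$node]), collapse = "\t"), con)
  }
  close(con)
  reps <- lapply(otus, function(o) consensus_repseq(o, tree, alignments,
                                                    use_prior = use_prior))
  recs <- data.frame(
    id = vapply(otus, function(o) paste0("otu_", o$node), character(1)),
    desc = vapply(otus, function(o) tree$taxonomy[o$node], character(1)),
    seq = vapply(reps, `[[`, character(1), "seq"),
    qual = NA_character_, stringsAsFactors = FALSE)
  write_sequences(recs, fas_path, "fasta")
  nodes <- vapply(otus, `[[`, integer(1), "node")
  if (length(nodes) >= 2 || (length(nodes) == 1 && nodes[1] != tree$root)) {
    phy <- prune_otu_tree(tree, nodes)
    writeLines(write_newick(phy), nwk_path)
  } else writeLines(";", nwk_path)
  invisible(c(otu_table = tab_path, rep_seqs = fas_path, otu_tree = nwk_path))
}
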