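# Per-read orchestration: align + place (+ optional chimera check) for a
# batch of reads, with a deterministic serial/parallel map.

#' Apply a per-read worker with deterministic merge
#'
#' Results are returned in input order regardless of the worker count, so
#' serial and parallel runs are identical. A worker error marks that
#' element as failed (field `error`) without aborting the rest.
#'
#' @param xs list/vector of inputs
#' @param worker pure function of one element
#' @param threads worker processes (fork-based; 1 = serial)
#' @return list of worker results; failed elements are
#'   `list(error = <message>)`
#' @export
parallel_map <- function(xs, worker, threads = 1L) {
  safe <- function(x) tryCatch(worker(x),
                               error = function(e) list(error = conditionMessage(e)))
  if (threads > 1L && .Platform$OS.type == "unix" &&
      requireNamespace("parallel", quietly = TRUE)) {
    parallel::mclapply(xs, safe, mc.cores = threads, mc.preschedule = TRUE)
  } else {
    lapply(xs, safe)
  }
}

#' Align and place a batch of reads against a reference package
#'
#' For each read: CSFM-index seeding + banded Viterbi alignment (full
#' Viterbi fallback), SEP placement with Q-score and taxonomy, and the
#' optional segment-placement chimera check. Reads below `min_q` are
#' flagged "low_q"; chimeric reads "chimera"; both are kept in the
#' output (downstream OTU clustering excludes flagged reads).
#'
#' @param pkg a `ref_package`
#' @param reads data.frame with `id`, `seq` (and optionally `sample`,
#'   `mate` for paired input)
#' @param sample default sample id for reads without one
#' @param chimera run chimera detection
#' @param lod_cutoff chimera LOD cutoff (default 50)
#' @param min_q minimum Q-score (default 0 = keep all)
#' @param prior placement prior ("uniform" or "height")
#' @param band_width banded Viterbi half-width
#' @param threads parallel workers
#' @param max_seeds,top_n SEP controls
#' @return data.frame, one row per read, with assignment columns (see
#'   [write_assignment_tsv()]) plus `node`, `sample`; the per-read
#'   `hp_alignment`s are attached as attribute "alignments" (named list)
#' @export
assign_reads <- function(pkg, reads, sample = "S1", chimera = FALSE,
                         lod_cutoff = 50, min_q = 0, prior = "uniform",
                         band_width = 100L, threads = 1L,
                         max_seeds = 5L, top_n = 5L) {
  tree <- pkg$tree
  if (is.null(reads$sample)) reads$sample <- sample
  worker <- function(i) {
    rid <- reads$id[i]
    mate <- if (!is.null(reads$mate)) reads$mate[i] else NULL
    aln <- align_read(pkg$profile, pkg$index, reads$seq[i], mate = mate,
                      read_id = rid, band_width = band_width)
    if (is.null(aln)) return(list(error = "unalignable mate pair"))
    pl <- place_read(tree, aln, max_seeds = max_seeds, top_n = top_n,
                     prior = prior)
    flags <- pl$flags
    if (!nzchar(flags) && pl$q_score < min_q) flags <- "low_q"
    if (!nzchar(flags) && chimera) {
      ch <- detect_chimera(tree, aln, lod_cutoff = lod_cutoff,
                           max_seeds = max_seeds, top_n = top_n)
      if (isTRUE(ch$is_chimera)) flags <- "chimera"
    }
    list(aln = aln, pl = pl, flags = flags)
  }
  res <- parallel_map(seq_len(nrow(reads)), worker, threads)
  rows <- lapply(seq_along(res), function(i) {
    r <- res[[i]]
    if (!is.null(r$error)) {
      return(data.frame(id = reads$id[i], cs_start = NA_integer_,
                        cs_end = NA_integer_, alignment = "",
                        branch_id = NA_integer_, taxonomy = "",
                        loglik = NA_real_, q_score = 0,
                        flags = paste0("failed:", r$error),
                        node = NA_integer_, sample = reads$sample[i],
                        distal = NA_real_, pendant = NA_real_,
                        stringsAsFactors = FALSE))
    }
    data.frame(id = reads$id[i], cs_start = r$aln$cs_start,
               cs_end = r$aln$cs_end, alignment = r$aln$aligned,
               branch_id = r$pl$v, taxonomy = r$pl$taxonomy,
               loglik = r$pl$loglik, q_score = r$pl$q_score,
               flags = if (nzchar(r$flags)) r$flags else "-",
               node = r$pl$node, sample = reads$sample[i],
               distal = r$pl$w_ur, pendant = r$pl$w_nr,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  alns <- lapply(res, function(r) r$aln)
  names(alns) <- reads$id
  attr(out, "alignments") <- alns
  out
}

# rebuild hp_alignment objects from assignment-TSV rows (enough for the
# OTU consensus step, which only needs the projected string + interval)
alignments_from_assignments <- function(assignments) {
  alns <- lapply(seq_len(nrow(assignments)), function(i) {
    a <- assignments[i, ]
    if (is.na(a$cs_start) || !nzchar(a$alignment)) return(NULL)
    structure(list(read_id = a$id, cs_start = a$cs_start, cs_end = a$cs_end,
                   aligned = a$alignment, score = NA_real_, banded = NA,
                   strand = "+"), class = "hp_alignment")
  })
  names(alns) <- assignments$id
  alns
}

#' Summarize assignments into OTU artifacts
#'
#' Filters flagged reads (chimera / low-Q / failed / unplaced), clusters
#' the rest by assigned node, and writes the OTU table, Dirichlet-
#' consensus rep-seqs, and pruned OTU tree.
#'
#' @param pkg a `ref_package`
#' @param assignments data.frame from [assign_reads()] (or read back
#'   from an assignment TSV with a `node`/`sample` column added)
#' @param outdir output directory
#' @param otu_min_reads OTU threshold (default 1)
#' @param use_prior Dirichlet node prior for rep-seqs
#' @return list with `otus`, `rejects`, and the written `paths`
#' @export
summarize_otus <- function(pkg, assignments, outdir, otu_min_reads = 1L,
                           use_prior = TRUE) {
  keep <- assignments$flags %in% c("-", "")
  placed <- assignments[keep & !is.na(assignments$node), , drop = FALSE]
  cl <- cluster_placements(placed, otu_min_reads)
  alns <- attr(assignments, "alignments") %||%
    alignments_from_assignments(assignments)
  paths <- write_otu_artifacts(cl$otus, pkg$tree, alns, outdir,
                               use_prior = use_prior)
  c(cl, list(paths = paths))
}

#' Export assignments to jplace
#'
#' @param pkg a `ref_package`
#' @param assignments data.frame from [assign_reads()]
#' @param path output jplace file
#' @export
assignments_to_jplace <- function(pkg, assignments, path) {
  phy <- pkg$tree$phy
  ok <- !is.na(assignments$branch_id)
  df <- assignments[ok, , drop = FALSE]
  # edge number: row of phy$edge whose child is branch_id, minus 1
  edge_of <- match(df$branch_id, phy$edge[, 2]) - 1L
  placements <- data.frame(
    id = df$id, edge_num = edge_of, likelihood = df$loglik,
    like_weight_ratio = pmin(1, 1 - 10^(-df$q_score / 10)),
    distal_length = df$distal %||% 0,
    pendant_length = df$pendant %||% 0,
    stringsAsFactors = FALSE)
  write_jplace(placements, phy, path)
}
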