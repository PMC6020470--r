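# Readers/writers for the standard formats the tool touches:
# FASTA/FASTQ, aligned FASTA (MSA), Newick, taxonomy TSV, assignment TSV,
# and jplace JSON. Sequence parsing is delegated to Biostrings and tree
# parsing to ape; this file only adds the package's conventions on top
# (uppercasing, '.'->'-' normalization, consensus/gap statistics,
# edge-numbered jplace trees).

#' Read sequences from FASTA or FASTQ
#'
#' Returns one row per record, in file order. Sequences are uppercased and
#' '.' gap characters are normalized to '-'. For FASTQ input the
#' Phred-scaled base qualities are kept as an ASCII (offset 33) string.
#'
#' @param path file path
#' @param format "fasta" or "fastq"
#' @return a data.frame with columns `id`, `desc`, `seq`, `qual`
#'   (`qual` is `NA` for FASTA input)
#' @export
read_sequences <- function(path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_hp("file does not exist: %s", path)
  if (file.size(path) == 0) {
    return(data.frame(id = character(), desc = character(),
                      seq = character(), qual = character(),
                      stringsAsFactors = FALSE))
  }
  if (format == "fasta") {
    set <- tryCatch(
      Biostrings::readBStringSet(path, format = "fasta"),
      error = function(e) stop_hp("malformed FASTA in %s: %s", path, conditionMessage(e)))
    qual <- rep(NA_character_, length(set))
  } else {
    qset <- tryCatch(
      suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path)),
      error = function(e) stop_hp("malformed FASTQ in %s: %s", path, conditionMessage(e)))
    set <- as(qset, "DNAStringSet")
    qual <- tryCatch(as.character(Biostrings::quality(qset)),
                     error = function(e)
                       stop_hp("malformed FASTQ in %s: quality line length does not match its sequence", path))
    bad <- which(nchar(qual) != nchar(as.character(set)))
    if (length(bad) > 0)
      stop_hp("FASTQ record %d ('%s'): quality length != sequence length",
              bad[1], names(set)[bad[1]])
  }
  hdr <- names(set) %||% rep("", length(set))
  id <- sub("\\s.*$", "", hdr)
  desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  seq <- chartr(".", "-", toupper(as.character(set)))
  if (any(nchar(seq) == 0)) {
    bad <- which(nchar(seq) == 0)[1]
    stop_hp("record %d ('%s') has an empty sequence", bad, id[bad])
  }
  data.frame(id = id, desc = desc, seq = unname(seq), qual = unname(qual),
             stringsAsFactors = FALSE)
}

#' Write sequences to FASTA or FASTQ
#'
#' @param records data.frame as returned by [read_sequences()]
#' @param path output file
#' @param format "fasta" or "fastq"; FASTQ requires a `qual` column
#'   (records missing qualities get uniform 'I', Phred 40)
#' @export
write_sequences <- function(records, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  hdr <- ifelse(nzchar(records$desc %||% ""), paste(records$id, records$desc),
                records$id)
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "fasta") {
    writeLines(paste0(">", hdr, "\n", records$seq), con, sep = "\n")
  } else {
    qual <- records$qual
    if (is.null(qual)) qual <- rep(NA_character_, nrow(records))
    qual <- ifelse(is.na(qual),
                   vapply(nchar(records$seq),
                          function(n) strrep("I", n), character(1)),
                   qual)
    writeLines(paste0("@", hdr, "\n", records$seq, "\n+\n", qual), con, sep = "\n")
  }
  invisible(path)
}

#' Read an aligned FASTA file as an MSA
#'
#' All records must have identical aligned length. The consensus at each
#' column is the modal non-gap symbol (alphabetic tie-break), or '-' when
#' the column's gap fraction exceeds 0.5.
#'
#' @param path aligned FASTA file
#' @return an object of class `hp_msa`: list with `ids`, `seqs`, `n`, `L`,
#'   `mat` (integer matrix n x L, 0 = gap), `consensus` (length-L string),
#'   `col_gap_frac` (numeric length L)
#' @export
read_msa <- function(path) {
  recs <- read_sequences(path, "fasta")
  msa_from_records(recs$seq, recs$id)
}

#' Build an `hp_msa` from aligned sequence strings
#' @param seqs character vector of equal-length aligned sequences
#' @param ids record ids (default seq1..seqn)
#' @return an `hp_msa` (see [read_msa()])
#' @export
msa_from_records <- function(seqs, ids = NULL) {
  n <- length(seqs)
  if (n == 0) stop_hp("empty MSA")
  ids <- ids %||% paste0("seq", seq_len(n))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1) {
    bad <- which(lens != lens[1])[1]
    stop_hp("ragged MSA: record '%s' has length %d, expected %d",
            ids[bad], lens[bad], lens[1])
  }
  L <- lens[1]
  mat <- t(vapply(seqs, seq_to_int, integer(L), USE.NAMES = FALSE))
  dim(mat) <- c(n, L)
  gap_frac <- colMeans(mat == 0L)
  cons <- vapply(seq_len(L), function(j) {
    if (gap_frac[j] > 0.5) return("-")
    col <- mat[, j]
    col <- col[col >= 1L & col <= 4L]
    if (length(col) == 0) return("-")
    tab <- tabulate(col, nbins = 4L)
    DNA_BASES[which.max(tab)]  # which.max takes the first (alphabetic) tie
  }, character(1))
  structure(list(ids = ids, seqs = unname(seqs), n = n, L = L, mat = mat,
                 consensus = paste(cons, collapse = ""),
                 col_gap_frac = unname(gap_frac)),
            class = "hp_msa")
}

#' @export
print.hp_msa <- function(x, ...) {
  cat(sprintf("hp_msa: %d sequences x %d columns (%d match columns)\n",
              x$n, x$L, sum(x$col_gap_frac <= 0.5)))
  invisible(x)
}

#' Parse a Newick string into a rooted tree
#'
#' Thin wrapper around [ape::read.tree()] that adds a balanced-parenthesis
#' check with position reporting and records whether the input was rooted.
#'
#' @param text Newick text
#' @return an [ape::phylo] object
#' @export
parse_newick <- function(text) {
  depth <- 0L
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L) stop_hp("Newick parse error: unbalanced ')' at position %d", i)
  }
  if (depth != 0L) stop_hp("Newick parse error: %d unclosed '(' at end of input", depth)
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy)) {
    # single-leaf degenerate "A:1.0;" is not representable by ape; synthesize
    m <- regmatches(text, regexec("^\\s*([^():;,]+?)(:([0-9eE.+-]+))?;\\s*$", text))[[1]]
    if (length(m) > 0 && nzchar(m[2])) {
      phy <- structure(list(edge = matrix(c(2L, 1L), 1, 2),
                            tip.label = m[2], Nnode = 1L,
                            edge.length = if (nzchar(m[4])) as.numeric(m[4]) else NULL),
                       class = "phylo", order = "cladewise")
      return(phy)
    }
    stop_hp("Newick parse error near position 1: could not parse '%s'",
            substr(text, 1, 40))
  }
  phy
}

#' Serialize a tree to Newick text
#' @param phy an [ape::phylo] object
#' @return Newick string (with trailing ';')
#' @export
write_newick <- function(phy) {
  ape::write.tree(phy)
}

#' Read a taxonomy table (id <tab> taxonomy string)
#' @param path TSV file; '#' comment lines are skipped; a header row with
#'   first field "id" is tolerated
#' @return data.frame with columns `id`, `taxonomy`
#' @export
read_taxonomy_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(lines)]
  if (length(lines) > 0 && grepl("^id\t", lines[1])) lines <- lines[-1]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(id = vapply(parts, `[`, "", 1),
             taxonomy = vapply(parts, function(p) p[2] %||% "", ""),
             stringsAsFactors = FALSE)
}

ASSIGN_COLS <- c("id", "cs_start", "cs_end", "alignment", "branch_id",
                 "taxonomy", "loglik", "q_score", "flags")

#' Write per-read assignments as TSV
#'
#' One row per read: id, 1-based consensus interval, the profile-projected
#' alignment, assigned branch (child-node id), taxonomy, placement
#' log-likelihood, Q-score, and flags (e.g. "chimera", "unplaced").
#'
#' @param placements data.frame with the columns listed above
#' @param path output file
#' @export
write_assignment_tsv <- function(placements, path) {
  df <- placements[, ASSIGN_COLS, drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(ASSIGN_COLS, collapse = "\t"), con)
  if (nrow(df) > 0) {
    df$loglik <- sprintf("%.6f", df$loglik)
    df$q_score <- sprintf("%.4f", df$q_score)
    writeLines(do.call(paste, c(lapply(df, as.character), sep = "\t")), con)
  }
  invisible(path)
}

#' Read an assignment TSV back
#' @param path file written by [write_assignment_tsv()]
#' @return data.frame with the assignment columns
#' @export
read_assignment_tsv <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = c(id = "character", taxonomy = "character",
                                         alignment = "character", flags = "character"))
  df
}

# Edge-numbered Newick for jplace: every branch gets a {n} tag, numbered
# 0..(nedge-1) in the order of phy$edge rows.
jplace_tree_string <- function(phy) {
  ntip <- length(phy$tip.label)
  root <- ntip + 1L
  children <- split(seq_len(nrow(phy$edge)), phy$edge[, 1])
  rec <- function(node) {
    kid_edges <- children[[as.character(node)]]
    lab <- if (node <= ntip) phy$tip.label[node]
           else (phy$node.label[node - ntip] %||% "")
    if (is.null(kid_edges)) return(lab)
    inner <- vapply(kid_edges, function(e) {
      child <- phy$edge[e, 2]
      bl <- if (!is.null(phy$edge.length)) phy$edge.length[e] else 0
      sprintf("%s:%s{%d}", rec(child), format(bl, digits = 10), e - 1L)
    }, character(1))
    paste0("(", paste(inner, collapse = ","), ")", lab)
  }
  paste0(rec(root), ";")
}

#' Write placements in jplace (version 3) format
#'
#' @param placements data.frame with columns `id`, `edge_num`, `likelihood`,
#'   `like_weight_ratio`, `distal_length`, `pendant_length`; `edge_num`
#'   refers to a row of `phy$edge` minus 1
#' @param phy the reference [ape::phylo] tree
#' @param path output file (NULL returns the JSON text)
#' @return the JSON text, invisibly when written to a file
#' @export
write_jplace <- function(placements, phy, path = NULL) {
  nedge <- nrow(phy$edge)
  if (nrow(placements) > 0 &&
      any(placements$edge_num < 0 | placements$edge_num >= nedge))
    stop_hp("placement references unknown edge number")
  plist <- lapply(seq_len(nrow(placements)), function(i) {
    p <- placements[i, ]
    list(p = list(list(p$edge_num, p$likelihood, p$like_weight_ratio,
                       p$distal_length, p$pendant_length)),
         n = list(p$id))
  })
  obj <- list(
    version = 3L,
    tree = jplace_tree_string(phy),
    placements = plist,
    fields = list("edge_num", "likelihood", "like_weight_ratio",
                  "distal_length", "pendant_length"),
    metadata = list(invocation = "hmmplace"))
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
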