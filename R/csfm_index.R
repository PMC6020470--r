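# Consensus-sequence FM-index (CSFM-index): a Burrows-Wheeler transform
# with rank support over the gap-free MSA consensus, used to map exact read
# substrings ("seeds") to 1-based consensus positions. This is the seed
# finder for the banded Viterbi aligner, so positions (not just counts)
# must be recoverable; a sampled suffix array plus LF-stepping provides
# locate() without storing the full SA.

CSFM_ALPHABET <- c("$", "A", "C", "G", "T")

#' Build a CSFM-index over a consensus sequence
#'
#' The input must be gap-free (gap-majority columns are dropped before
#' indexing) and contain only A/C/G/T. The suffix array is built by
#' sorting all suffixes; the index stores the BWT, cumulative symbol
#' counts (the C array), per-position occurrence counts (rank support),
#' and suffix-array samples at a fixed stride.
#'
#' @param consensus gap-free consensus string over {A,C,G,T}
#' @param sa_stride suffix-array sampling stride (default 8)
#' @return an object of class `csfm_index`
#' @export
build_index <- function(consensus, sa_stride = 8L) {
  if (nchar(consensus) == 0) stop_hp("empty consensus")
  if (grepl("$", consensus, fixed = TRUE)) stop_hp("'$' not allowed in consensus")
  if (grepl("[^ACGT]", consensus)) stop_hp("consensus must be gap-free over A/C/G/T")
  text <- paste0(consensus, "$")
  n <- nchar(text)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  # suffix array: '$' sorts before A<C<G<T; use a sentinel that the C
  # locale orders first
  key <- chartr("$ACGT", "\001ACGT", text)
  suffixes <- substring(key, seq_len(n), n)
  old <- Sys.getlocale("LC_COLLATE"); Sys.setlocale("LC_COLLATE", "C")
  sa <- order(suffixes)                     # 1-based suffix start offsets
  Sys.setlocale("LC_COLLATE", old)
  bwt_idx <- ifelse(sa == 1L, n, sa - 1L)
  bwt <- chars[bwt_idx]
  code <- match(bwt, CSFM_ALPHABET)         # 1..5
  # occ[i, a] = number of symbol a among bwt[1..i]
  occ <- apply(vapply(1:5, function(a) as.integer(code == a), integer(n)),
               2L, cumsum)
  dim(occ) <- c(n, 5L)
  tot <- occ[n, ]
  Carr <- c(0L, cumsum(tot))[1:5]           # symbols < a
  keep <- ((sa - 1L) %% sa_stride) == 0L
  structure(list(n = n, bwt = paste(bwt, collapse = ""), code = code,
                 occ = occ, C = Carr, sa_stride = as.integer(sa_stride),
                 sa_sample_rows = which(keep), sa_sample_vals = sa[keep],
                 text_len = n - 1L),
            class = "csfm_index")
}

#' @export
print.csfm_index <- function(x, ...) {
  cat(sprintf("csfm_index over %d bp consensus (SA stride %d)\n",
              x$text_len, x$sa_stride))
  invisible(x)
}

# rank(symbol code a, prefix length i) over the BWT
csfm_rank <- function(index, a, i) {
  if (i == 0L) return(0L)
  index$occ[i, a]
}

# LF mapping for BWT row i (1-based)
csfm_lf <- function(index, i) {
  a <- index$code[i]
  index$C[a] + csfm_rank(index, a, i)
}

#' Recover a text position from a suffix-array row
#'
#' Walks the LF mapping from the given row until a sampled suffix-array
#' entry is hit; equals a full suffix-array lookup. The row holding the
#' '$' suffix maps, by convention, to position `text_len + 1`.
#'
#' @param index a `csfm_index`
#' @param sa_index 1-based BWT/suffix-array row
#' @return 1-based consensus position of the suffix's first character
#' @export
locate_cs <- function(index, sa_index) {
  if (sa_index < 1L || sa_index > index$n)
    stop_hp("suffix-array row %d out of range [1,%d]", sa_index, index$n)
  steps <- 0L
  i <- sa_index
  repeat {
    hit <- match(i, index$sa_sample_rows)
    if (!is.na(hit)) return(index$sa_sample_vals[hit] + steps)
    i <- csfm_lf(index, i)
    steps <- steps + 1L
  }
}

#' Exact backward search over the indexed consensus
#'
#' @param index a `csfm_index`
#' @param pattern non-empty pattern over {A,C,G,T}
#' @param locate if FALSE only the count is computed
#' @return list with `count` and sorted 0-based `positions` of every exact
#'   match start (empty integer vector when `locate = FALSE` found none
#'   or locating was skipped)
#' @export
backward_search <- function(index, pattern, locate = TRUE) {
  if (nchar(pattern) == 0) stop_hp("empty pattern")
  pat <- match(strsplit(pattern, "", fixed = TRUE)[[1]], CSFM_ALPHABET)
  if (anyNA(pat) || any(pat == 1L))
    return(list(count = 0L, positions = integer()))
  lo <- 1L; hi <- index$n                 # inclusive SA row range
  for (a in rev(pat)) {
    lo2 <- index$C[a] + csfm_rank(index, a, lo - 1L) + 1L
    hi2 <- index$C[a] + csfm_rank(index, a, hi)
    if (lo2 > hi2) return(list(count = 0L, positions = integer()))
    lo <- lo2; hi <- hi2
  }
  cnt <- hi - lo + 1L
  pos <- integer()
  if (locate) {
    pos <- sort(vapply(lo:hi, function(r) locate_cs(index, r), integer(1))) - 1L
  }
  list(count = cnt, positions = pos)
}

#' Find seed paths anchoring a read end on the consensus
#'
#' Looks for a maximal exact match of at least `min_seed_len` bases
#' anchored inside the first (`five_prime`) or last (`three_prime`)
#' `window` bases of the read. Matches occurring at more than
#' `max_seed_hits` consensus loci are rejected as ambiguous; every
#' accepted locus yields one `SeedPath`-style row.
#'
#' @param index a `csfm_index`
#' @param read read sequence (A/C/G/T/N; N never matches)
#' @param which_end "five_prime" or "three_prime"
#' @param min_seed_len minimum exact-match length (default 20)
#' @param window anchor window at the read end (default 40)
#' @param max_seed_hits ambiguity cutoff (default 10)
#' @return data.frame with columns `read_from`, `read_to` (0-based
#'   half-open), `cs_from`, `cs_to` (1-based inclusive), `end`;
#'   zero rows when no seed qualifies
#' @export
find_seeds <- function(index, read, which_end = c("five_prime", "three_prime"),
                       min_seed_len = 20L, window = 40L, max_seed_hits = 10L) {
  which_end <- match.arg(which_end)
  L <- nchar(read)
  empty <- data.frame(read_from = integer(), read_to = integer(),
                      cs_from = integer(), cs_to = integer(),
                      end = character(), stringsAsFactors = FALSE)
  if (L < min_seed_len) return(empty)
  starts <- if (which_end == "five_prime") {
    seq.int(0L, min(window - min_seed_len, L - min_seed_len))
  } else {
    # anchor so the match *ends* within the final `window` bases
    seq.int(max(0L, L - window), L - min_seed_len)
  }
  if (which_end == "three_prime") starts <- rev(starts)
  for (s in starts) {
    kmer <- substr(read, s + 1L, s + min_seed_len)
    if (grepl("[^ACGT]", kmer)) next
    hit <- backward_search(index, kmer, locate = FALSE)
    if (hit$count == 0L || hit$count > max_seed_hits) next
    # extend to the maximal match length still present in the consensus
    len <- min_seed_len
    while (s + len < L) {
      cand <- substr(read, s + 1L, s + len + 1L)
      if (grepl("[^ACGT]", substr(cand, len + 1L, len + 1L))) break
      h2 <- backward_search(index, cand, locate = FALSE)
      if (h2$count == 0L) break
      len <- len + 1L
      hit <- h2
    }
    final <- backward_search(index, substr(read, s + 1L, s + len))
    return(data.frame(read_from = s, read_to = s + len,
                      cs_from = final$positions + 1L,
                      cs_to = final$positions + len,
                      end = which_end, stringsAsFactors = FALSE))
  }
  empty
}

# Inverse BWT (LF-walk); reconstructs the original text without '$'.
# Row 1 always holds the '$' suffix, and its BWT symbol is the last text
# character; following LF yields the text right-to-left.
invert_bwt <- function(index) {
  res <- integer(index$text_len)
  i <- 1L
  for (k in seq_len(index$text_len)) {
    res[k] <- index$code[i]
    i <- csfm_lf(index, i)
  }
  paste(rev(CSFM_ALPHABET[res]), collapse = "")
}
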