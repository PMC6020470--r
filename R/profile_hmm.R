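# plan7 profile HMM: training from a reference MSA under Dirichlet
# priors, and banded/full Viterbi alignment of reads to the profile.
#
# Architecture: M/I/D core states 1..K plus flanking N (5') and C (3')
# states, B (begin) and E (end). Wing retraction: B enters directly into
# any match state M_k (uniform entry) and E is reachable only from match
# states, so no alignment path is match-empty. The 5'/3' overhang insert
# states (I_0, I_K) are realized as the emission distributions of N and C
# respectively. There is no J state: a read aligns to the profile once.
#
# All parameters are kept as natural-log probabilities; the Viterbi
# recurrences therefore maximize the log-likelihood of (read, path).

#' Build a plan7 profile from an MSA
#'
#' Match states are the MSA columns with gap fraction <= 0.5. Emissions
#' and core transitions are posterior-mean estimates from
#' position-specifically weighted counts (Henikoff position-based
#' weights) under Dirichlet priors: a Dirichlet mixture for match
#' emissions, Dirichlet densities for insert emissions and transitions.
#'
#' @param msa an `hp_msa` (see [read_msa()])
#' @param dd_priors list of Dirichlet densities with elements `ins`
#'   (insert emissions, 4 dims), `m` (M transitions: MM, MI, MD),
#'   `i` (IM, II), `d` (DM, DD); defaults are mild sparse priors
#' @param dm_prior Dirichlet mixture (or density) prior for match
#'   emissions; default symmetric Dirichlet(1,1,1,1)
#' @param exit_prob per-match-state end probability epsilon
#'   (default 1/(K+1)); with uniform entry this makes the alignment
#'   local in the profile and global in the read
#' @param nc_loop self-loop probability of the N and C flanking states
#' @return an object of class `p7_profile`
#' @export
build_profile <- function(msa, dd_priors = NULL, dm_prior = NULL,
                          exit_prob = NULL, nc_loop = 0.8) {
  stopifnot(inherits(msa, "hp_msa"))
  match_cols <- which(msa$col_gap_frac <= 0.5)
  K <- length(match_cols)
  if (K == 0) stop_hp("MSA has no match columns (all gap fractions > 0.5)")
  dd_priors <- dd_priors %||% list()
  dd_ins <- dd_priors$ins %||% structure(list(alpha = rep(1, 4)), class = "dirichlet_density")
  dd_m <- dd_priors$m %||% structure(list(alpha = c(6, 1, 1)), class = "dirichlet_density")
  dd_i <- dd_priors$i %||% structure(list(alpha = c(2, 2)), class = "dirichlet_density")
  dd_d <- dd_priors$d %||% structure(list(alpha = c(2, 2)), class = "dirichlet_density")
  dm_prior <- dm_prior %||% structure(list(alpha = rep(1, 4)), class = "dirichlet_density")
  eps <- exit_prob %||% (1 / (K + 1))

  w <- henikoff_weights(msa$mat[, match_cols, drop = FALSE])

  is_match <- msa$col_gap_frac <= 0.5
  # region index for each column: insert residues between match k and k+1
  # pool into insert state k (columns before the first match -> I_0,
  # after the last -> I_K)
  region <- cumsum(is_match)            # per column, the preceding match index

  memis <- matrix(0, K, 4)
  for (k in seq_len(K)) {
    col <- msa$mat[, match_cols[k]]
    obs <- vapply(1:4, function(b) sum(w[col == b]), numeric(1))
    memis[k, ] <- dirichlet_postmean(dm_prior, obs)
  }

  iemis <- matrix(0, K + 1, 4)          # rows = I_0 .. I_K
  for (k in 0:K) {
    cols <- which(!is_match & region == k)
    if (length(cols) > 0) {
      sub <- msa$mat[, cols, drop = FALSE]
      obs <- vapply(1:4, function(b) sum(w * rowSums(sub == b)), numeric(1))
    } else obs <- rep(0, 4)
    iemis[k + 1, ] <- dirichlet_postmean(dd_ins, obs)
  }

  # core transition counts between consecutive match positions
  cm <- matrix(0, K, 3, dimnames = list(NULL, c("MM", "MI", "MD")))
  ci <- matrix(0, K, 2, dimnames = list(NULL, c("IM", "II")))
  cd <- matrix(0, K, 2, dimnames = list(NULL, c("DM", "DD")))
  for (i in seq_len(msa$n)) {
    row <- msa$mat[i, ]
    st <- ifelse(row[match_cols] != 0L, 1L, 3L)   # 1 = M, 3 = D per match col
    nins <- vapply(seq_len(K - 1), function(k) {
      cols <- which(!is_match & region == k)
      if (length(cols) == 0) 0L else sum(row[cols] != 0L)
    }, integer(1))
    for (k in seq_len(K - 1)) {
      from <- st[k]; to <- st[k + 1]; ni <- nins[k]
      if (ni > 0) {
        if (from == 1L) cm[k, "MI"] <- cm[k, "MI"] + w[i]
        # D -> I transitions are not part of plan7; fold them into D->M
        ci[k, "II"] <- ci[k, "II"] + w[i] * (ni - 1L)
        ci[k, "IM"] <- ci[k, "IM"] + w[i]
        if (from == 3L) cd[k, "DM"] <- cd[k, "DM"] + w[i]
      } else {
        if (from == 1L) {
          if (to == 1L) cm[k, "MM"] <- cm[k, "MM"] + w[i]
          else cm[k, "MD"] <- cm[k, "MD"] + w[i]
        } else {
          if (to == 1L) cd[k, "DM"] <- cd[k, "DM"] + w[i]
          else cd[k, "DD"] <- cd[k, "DD"] + w[i]
        }
      }
    }
  }
  tM <- unname(t(vapply(seq_len(K), function(k) dirichlet_postmean(dd_m, cm[k, ]), numeric(3))))
  tI <- unname(t(vapply(seq_len(K), function(k) dirichlet_postmean(dd_i, ci[k, ]), numeric(2))))
  tD <- unname(t(vapply(seq_len(K), function(k) dirichlet_postmean(dd_d, cd[k, ]), numeric(2))))

  structure(list(
    K = K, cs_map = match_cols,
    match_emis = log(memis), ins_emis = log(iemis),
    tM = log(tM), tI = log(tI), tD = log(tD),
    exit_prob = eps, nc_loop = nc_loop,
    consensus_cs = gsub("-", "", msa$consensus, fixed = TRUE)),
    class = "p7_profile")
}

#' @export
print.p7_profile <- function(x, ...) {
  cat(sprintf("p7_profile with K = %d match states\n", x$K))
  invisible(x)
}

# Henikoff position-based sequence weights over match columns,
# normalized to mean 1. Gap cells contribute nothing.
henikoff_weights <- function(mat) {
  n <- nrow(mat); L <- ncol(mat)
  w <- numeric(n)
  for (j in seq_len(L)) {
    col <- mat[, j]
    obs <- col >= 1L & col <= 4L
    if (!any(obs)) next
    tab <- tabulate(col[obs], nbins = 4L)
    r <- sum(tab > 0)
    w[obs] <- w[obs] + 1 / (r * tab[col[obs]])
  }
  if (all(w == 0)) w <- rep(1, n)
  w / mean(w[w > 0])
}

# Emission score lookup: 4 base columns as trained, gap column never
# queried, N column = 0 (emits with probability 1, score-neutral).
emis_lookup <- function(log_emis) {
  cbind(log_emis, 0)      # column 5 = N
}

check_read_symbols <- function(rint, read) {
  if (length(rint) == 0) stop_hp("empty read")
  # seq_to_int maps unknown symbols and N to 5; gaps (0) are not sequence
  if (any(rint == 0L)) stop_hp("gap characters are not allowed in reads")
  invisible(TRUE)
}

# Core Viterbi DP over rows i = 1..L (read positions) and match states
# k = 1..K, restricted per row to k in [lo[i], hi[i]]. Returns the score
# and a traceback. The same routine serves full (lo=1, hi=K) and banded
# alignment; scores of banded runs can never exceed the full run.
viterbi_dp <- function(prof, rint, lo, hi) {
  K <- prof$K; L <- length(rint)
  eM <- emis_lookup(prof$match_emis)
  eI <- emis_lookup(prof$ins_emis[2:(K + 1), , drop = FALSE])  # I_1..I_K (I_K unused)
  eN <- c(prof$ins_emis[1, ], 0)
  eC <- c(prof$ins_emis[K + 1, ], 0)
  lloop <- log(prof$nc_loop); lleave <- log(1 - prof$nc_loop)
  eps <- prof$exit_prob
  lcont <- log(1 - eps)
  entry <- -log(K)
  exitl <- c(rep(log(eps), K - 1), 0)     # M_K must exit
  ltMM <- prof$tM[, 1] + lcont; ltMI <- prof$tM[, 2] + lcont; ltMD <- prof$tM[, 3] + lcont
  ltIM <- prof$tI[, 1]; ltII <- prof$tI[, 2]
  ltDM <- prof$tD[, 1]; ltDD <- prof$tD[, 2]
  ltMI[K] <- -Inf                          # no internal insert after M_K

  NEG <- -Inf
  VM <- matrix(NEG, L + 1, K); VI <- matrix(NEG, L + 1, K); VD <- matrix(NEG, L + 1, K)
  VN <- c(0, cumsum(lloop + eN[rint]))
  VB <- VN + lleave
  VE <- rep(NEG, L + 1); VC <- rep(NEG, L + 1)

  # cumDD[k] = sum of ltDD[1..k-1]; used to solve the same-row delete
  # chain VD[k] = max_{j<k} VM[j] + ltMD[j] + sum(ltDD[(j+1)..(k-1)])
  # with a single cummax scan. Bands are contiguous per row, so a chain
  # between two in-band cells never crosses an out-of-band cell.
  cumDD <- c(0, cumsum(ltDD[-K]))
  cumDD <- c(cumDD, cumDD[K])              # length K+1; last entry unused
  for (i in seq_len(L)) {
    ks <- lo[i]:hi[i]
    b <- rint[i]
    prevM <- VM[i, ]; prevI <- VI[i, ]; prevD <- VD[i, ]
    # shifted (k-1) predecessors
    pM <- c(NEG, prevM[-K] + ltMM[-K])
    pI <- c(NEG, prevI[-K] + ltIM[-K])
    pD <- c(NEG, prevD[-K] + ltDM[-K])
    m <- pmax(VB[i] + entry, pM, pI, pD) + eM[, b]
    m[-ks] <- NEG
    VM[i + 1, ] <- m
    ii <- pmax(prevM + ltMI, prevI + ltII) + eI[, b]
    ii[-ks] <- NEG
    VI[i + 1, ] <- ii
    base <- VM[i + 1, ] + ltMD - cumDD[2:(K + 1)]
    d <- cummax(c(NEG, base[-K])) + cumDD[1:K]
    d[-ks] <- NEG
    VD[i + 1, ] <- d
    VE[i + 1] <- max(VM[i + 1, ] + exitl)
    VC[i + 1] <- max(VE[i + 1], VC[i] + lloop + eC[b])
  }
  score <- VC[L + 1] + lleave
  list(score = score, VM = VM, VI = VI, VD = VD, VN = VN, VB = VB,
       VE = VE, VC = VC, exitl = exitl, entry = entry,
       ltMM = ltMM, ltMI = ltMI, ltMD = ltMD, ltIM = ltIM, ltII = ltII,
       ltDM = ltDM, ltDD = ltDD, eM = eM, eI = eI, eC = eC, lloop = lloop)
}

# Traceback of a finished DP; returns the state path and the profile-column
# projection of the read (inserts excluded, deletions as '-').
viterbi_traceback <- function(dp, prof, rint) {
  K <- prof$K; L <- length(rint)
  if (!is.finite(dp$score)) return(NULL)
  # find the row where E fired (prefer the latest row whose VC came from E)
  j <- L
  while (j >= 1 && dp$VC[j + 1] > dp$VE[j + 1]) j <- j - 1
  if (j < 1) return(NULL)
  k <- which.max(dp$VM[j + 1, ] + dp$exitl)
  cs_end <- k
  i <- j                       # read bases consumed by the time we are at M_k
  cols <- character(0)
  path <- character(0)
  state <- "M"
  cs_start <- k
  repeat {
    if (state == "M") {
      path <- c(sprintf("M%d", k), path)
      cols <- c(c("A", "C", "G", "T", "N")[rint[i]], cols)
      if (k > 1) {
        cand <- c(dp$VB[i] + dp$entry,
                  dp$VM[i, k - 1] + dp$ltMM[k - 1],
                  dp$VI[i, k - 1] + dp$ltIM[k - 1],
                  dp$VD[i, k - 1] + dp$ltDM[k - 1])
      } else cand <- c(dp$VB[i] + dp$entry, -Inf, -Inf, -Inf)
      pick <- which.max(cand)
      i <- i - 1
      if (pick == 1L) { cs_start <- k; break }
      k <- k - 1
      state <- c("B", "M", "I", "D")[pick]
    } else if (state == "I") {
      path <- c(sprintf("I%d", k), path)
      cand <- c(dp$VM[i, k] + dp$ltMI[k], dp$VI[i, k] + dp$ltII[k])
      pick <- which.max(cand)
      i <- i - 1
      state <- c("M", "I")[pick]
    } else { # D: consumes a profile column but no read base
      path <- c(sprintf("D%d", k), path)
      cols <- c("-", cols)
      cand <- c(dp$VM[i + 1, k - 1] + dp$ltMD[k - 1],
                dp$VD[i + 1, k - 1] + dp$ltDD[k - 1])
      pick <- which.max(cand)
      k <- k - 1
      state <- c("M", "D")[pick]
    }
  }
  list(cs_start = cs_start, cs_end = cs_end,
       aligned = paste(cols, collapse = ""),
       vpath = c("N", "B", path, "E", "C"), n5 = i)
}

#' Full (non-banded) Viterbi alignment of a read to the profile
#'
#' @param profile a `p7_profile`
#' @param read read sequence over A/C/G/T/N
#' @param read_id id recorded in the result
#' @return an `hp_alignment`: list with `read_id`, `cs_start`, `cs_end`
#'   (1-based match-state interval), `aligned` (profile-column projection,
#'   '-' for deletions, inserts excluded), `vpath`, `score`, `banded`,
#'   `strand`
#' @export
full_viterbi <- function(profile, read, read_id = "read") {
  rint <- seq_to_int(read)
  check_read_symbols(rint, read)
  dp <- viterbi_dp(profile, rint, rep(1L, length(rint)), rep(profile$K, length(rint)))
  tb <- viterbi_traceback(dp, profile, rint)
  structure(list(read_id = read_id, cs_start = tb$cs_start, cs_end = tb$cs_end,
                 aligned = tb$aligned, vpath = tb$vpath, score = dp$score,
                 banded = FALSE, strand = "+"),
            class = "hp_alignment")
}

#' Banded Viterbi alignment restricted around seed diagonals
#'
#' Identical recurrences to [full_viterbi()] but only DP cells within
#' `band_width` diagonals of a seed path are searched, so the banded
#' score never exceeds the full score and equals it whenever the optimal
#' path stays inside the band.
#'
#' @param profile a `p7_profile`
#' @param read read sequence
#' @param seeds data.frame of seed paths from [find_seeds()] (5' and/or 3')
#' @param band_width diagonals allowed each side of a seed diagonal
#'   (default 100; `Inf` reproduces the full DP)
#' @param read_id id recorded in the result
#' @return an `hp_alignment` (field `banded = TRUE`), or NULL when the
#'   seeds are mutually inconsistent (3' locus before 5' locus)
#' @export
banded_viterbi <- function(profile, read, seeds, band_width = 100L,
                           read_id = "read") {
  rint <- seq_to_int(read)
  check_read_symbols(rint, read)
  if (nrow(seeds) == 0) stop_hp("banded_viterbi requires at least one seed")
  s5 <- seeds[seeds$end == "five_prime", , drop = FALSE]
  s3 <- seeds[seeds$end == "three_prime", , drop = FALSE]
  if (nrow(s5) > 0 && nrow(s3) > 0 && max(s3$cs_from) < min(s5$cs_from))
    return(NULL)                     # inconsistent seeds: caller falls back
  L <- length(rint); K <- profile$K
  diags <- seeds$cs_from - seeds$read_from   # k - i offsets (i 1-based)
  i <- seq_len(L)
  if (is.finite(band_width)) {
    lo <- pmax(1L, pmin(i + min(diags) - band_width, K))
    hi <- pmin(K, pmax(i + max(diags) + band_width, 1L))
    lo <- pmin(lo, hi)
  } else {
    lo <- rep(1L, L); hi <- rep(K, L)
  }
  dp <- viterbi_dp(profile, rint, as.integer(lo), as.integer(hi))
  if (!is.finite(dp$score)) return(NULL)
  tb <- viterbi_traceback(dp, profile, rint)
  structure(list(read_id = read_id, cs_start = tb$cs_start, cs_end = tb$cs_end,
                 aligned = tb$aligned, vpath = tb$vpath, score = dp$score,
                 banded = TRUE, strand = "+"),
            class = "hp_alignment")
}

#' Reverse-complement a DNA string
#' @param x sequence string
#' @return reverse complement (N and '-' preserved)
#' @export
revcomp <- function(x) {
  chartr("ACGTacgt", "TGCAtgca",
         vapply(x, function(s) paste(rev(strsplit(s, "")[[1]]), collapse = ""),
                character(1), USE.NAMES = FALSE))
}

#' Seed-then-align orchestration for one read or a mate pair
#'
#' Finds 5'/3' seeds in the CSFM-index, runs the banded Viterbi and
#' falls back to the full DP when no usable seed exists. Unpaired reads
#' without forward seeds are retried reverse-complemented (on by
#' default); if neither strand seeds, both strands are aligned with the
#' full DP and the better-scoring one is kept. For pairs, the reverse
#' mate is reverse-complemented, both mates aligned independently, and
#' the alignments merged over the union consensus interval; columns
#' between non-overlapping mates are unobserved ('-' in the projection).
#'
#' @param profile a `p7_profile`
#' @param index the matching `csfm_index`
#' @param read forward read sequence
#' @param mate optional reverse mate (as sequenced; will be
#'   reverse-complemented)
#' @param read_id id recorded in the result
#' @param band_width band half-width for the banded DP
#' @param min_seed_len,window,max_seed_hits seed-finding controls
#'   (see [find_seeds()])
#' @param try_revcomp retry unpaired reads on the reverse strand when no
#'   forward seed is found
#' @return an `hp_alignment`; `NULL` when a mate pair has inverted
#'   merged intervals (unalignable)
#' @export
align_read <- function(profile, index, read, mate = NULL, read_id = "read",
                       band_width = 100L, min_seed_len = 20L, window = 40L,
                       max_seed_hits = 10L, try_revcomp = TRUE) {
  if (!is.null(mate)) {
    a1 <- align_read(profile, index, read, NULL, paste0(read_id, "/1"),
                     band_width, min_seed_len, window, max_seed_hits,
                     try_revcomp = FALSE)
    a2 <- align_read(profile, index, revcomp(mate), NULL, paste0(read_id, "/2"),
                     band_width, min_seed_len, window, max_seed_hits,
                     try_revcomp = FALSE)
    return(merge_mate_alignments(a1, a2, read_id))
  }
  get_seeds <- function(sq) {
    rbind(find_seeds(index, sq, "five_prime", min_seed_len, window, max_seed_hits),
          find_seeds(index, sq, "three_prime", min_seed_len, window, max_seed_hits))
  }
  seeds <- get_seeds(read)
  strand <- "+"
  sq <- read
  if (nrow(seeds) == 0 && try_revcomp) {
    rc <- revcomp(read)
    seeds_rc <- get_seeds(rc)
    if (nrow(seeds_rc) > 0) {
      seeds <- seeds_rc; sq <- rc; strand <- "-"
    }
  }
  if (nrow(seeds) > 0) {
    aln <- banded_viterbi(profile, sq, seeds, band_width, read_id)
    if (!is.null(aln)) {
      aln$strand <- strand
      return(aln)
    }
  }
  aln <- full_viterbi(profile, sq, read_id)
  if (try_revcomp && strand == "+") {
    aln_rc <- full_viterbi(profile, revcomp(read), read_id)
    if (aln_rc$score > aln$score) {
      aln <- aln_rc; aln$strand <- "-"
    }
  }
  aln
}

# Merge two mate alignments over the union consensus interval. Where both
# mates observe a column and disagree, the forward mate wins; columns
# observed by neither are '-' (unobserved, excluded from likelihoods).
merge_mate_alignments <- function(a1, a2, read_id) {
  if (is.null(a1) || is.null(a2)) return(a1 %||% a2)
  cs_start <- min(a1$cs_start, a2$cs_start)
  cs_end <- max(a1$cs_end, a2$cs_end)
  if (cs_end < cs_start) return(NULL)
  width <- cs_end - cs_start + 1L
  cols <- rep("-", width)
  put <- function(cols, a) {
    idx <- (a$cs_start:a$cs_end) - cs_start + 1L
    ch <- strsplit(a$aligned, "")[[1]]
    keep <- ch != "-"
    cols[idx[keep]] <- ch[keep]
    cols
  }
  cols <- put(cols, a2)
  cols <- put(cols, a1)       # forward mate applied last -> wins overlaps
  structure(list(read_id = read_id, cs_start = cs_start, cs_end = cs_end,
                 aligned = paste(cols, collapse = ""),
                 vpath = NULL, score = a1$score + a2$score,
                 banded = isTRUE(a1$banded) && isTRUE(a2$banded),
                 strand = "+", paired = TRUE),
            class = "hp_alignment")
}

#' Export a profile in HMMER3-style text
#'
#' Emissions and transitions are written as negative natural-log
#' probabilities, one match-state row per line, mirroring the HMMER3
#' text layout closely enough for lossless re-import with
#' [import_hmmer_text()].
#'
#' @param profile a `p7_profile`
#' @return character vector of text lines
#' @export
export_hmmer_text <- function(profile) {
  fmt <- function(x) sprintf("%.5f", -x)   # negative log probabilities
  K <- profile$K
  lines <- c("HMMER3/f [hmmplace profile]",
             sprintf("LENG  %d", K),
             "ALPH  DNA",
             sprintf("STATS exit %.8f ncloop %.8f", profile$exit_prob, profile$nc_loop),
             sprintf("CSMAP %s", paste(profile$cs_map, collapse = ",")),
             "HMM          A        C        G        T",
             sprintf("  INS0   %s", paste(fmt(profile$ins_emis[1, ]), collapse = " ")))
  for (k in seq_len(K)) {
    lines <- c(lines,
               sprintf("  %-6d %s", k, paste(fmt(profile$match_emis[k, ]), collapse = " ")),
               sprintf("  i      %s", paste(fmt(profile$ins_emis[k + 1, ]), collapse = " ")),
               sprintf("  t      %s", paste(fmt(c(profile$tM[k, ], profile$tI[k, ],
                                                  profile$tD[k, ])), collapse = " ")))
  }
  c(lines, "//")
}

#' Re-import a profile written by [export_hmmer_text()]
#' @param lines character vector of text lines
#' @return a `p7_profile`
#' @export
import_hmmer_text <- function(lines) {
  gv <- function(prefix) {
    ln <- grep(prefix, lines, value = TRUE)[1]
    trimws(sub(prefix, "", ln))
  }
  K <- as.integer(gv("^LENG"))
  stats <- as.numeric(strsplit(gv("^STATS"), "\\s+")[[1]][c(2, 4)])
  cs_map <- as.integer(strsplit(gv("^CSMAP"), ",")[[1]])
  nums <- function(ln) -as.numeric(strsplit(trimws(ln), "\\s+")[[1]][-1])
  ins0 <- nums(grep("^  INS0", lines, value = TRUE))
  body <- lines[(grep("^HMM ", lines) + 2):(length(lines) - 1)]
  memis <- matrix(0, K, 4); iemis <- matrix(0, K + 1, 4)
  iemis[1, ] <- ins0
  tM <- matrix(0, K, 3); tI <- matrix(0, K, 2); tD <- matrix(0, K, 2)
  for (k in seq_len(K)) {
    memis[k, ] <- nums(body[3 * (k - 1) + 1])
    iemis[k + 1, ] <- nums(body[3 * (k - 1) + 2])
    tr <- nums(body[3 * (k - 1) + 3])
    tM[k, ] <- tr[1:3]; tI[k, ] <- tr[4:5]; tD[k, ] <- tr[6:7]
  }
  structure(list(K = K, cs_map = cs_map, match_emis = memis, ins_emis = iemis,
                 tM = tM, tI = tI, tD = tD,
                 exit_prob = stats[1], nc_loop = stats[2],
                 consensus_cs = NULL),
            class = "p7_profile")
}
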