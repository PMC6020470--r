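# Time-reversible DNA substitution models (GTR, TN93, HKY85), their
# training from alignments, and discrete-Gamma among-site rate variation.
#
# A model is parameterized by equilibrium base frequencies pi and
# symmetric exchangeabilities R (6 free for GTR; TN93 constrains the four
# transversion exchangeabilities to be equal; HKY85 additionally equates
# the two transition exchangeabilities). The rate matrix is
# Q[i,j] = R[i,j] * pi[j] (i != j), rows summing to zero, scaled so the
# mean substitution rate -sum(pi_i Q_ii) equals 1. Matrix exponentials
# use the eigendecomposition of the pi-symmetrized similarity transform,
# which is real for every reversible model.

# base order everywhere: A, C, G, T
# exchangeability order: AC, AG, AT, CG, CT, GT (AG and CT are transitions)
R_PAIRS <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
TRANSITIONS <- c(2, 5)   # indices of AG, CT within the 6-vector

#' Construct a reversible DNA substitution model
#'
#' @param name "GTR", "TN93" or "HKY85"
#' @param pi equilibrium base frequencies (A,C,G,T), summing to 1
#' @param rates exchangeabilities in order AC, AG, AT, CG, CT, GT (GTR);
#'   for TN93, a vector c(kappa1, kappa2) of the AG and CT
#'   exchangeabilities relative to a transversion rate of 1; for HKY85 a
#'   single kappa
#' @return an object of class `subst_model` with fields `name`, `pi`,
#'   `R` (6 exchangeabilities), `Q` (4x4, mean rate 1), plus the cached
#'   eigendecomposition used by [transition_matrix()]
#' @export
subst_model <- function(name = c("GTR", "TN93", "HKY85"),
                        pi = rep(0.25, 4), rates = rep(1, 6)) {
  name <- match.arg(name)
  if (length(pi) != 4 || any(pi <= 0)) stop_hp("pi must be 4 positive values")
  pi <- pi / sum(pi)
  R6 <- switch(name,
    GTR = {
      if (length(rates) != 6) stop_hp("GTR needs 6 exchangeabilities")
      rates
    },
    TN93 = {
      if (length(rates) != 2) stop_hp("TN93 needs c(kappa1, kappa2)")
      c(1, rates[1], 1, 1, rates[2], 1)
    },
    HKY85 = {
      if (length(rates) != 1) stop_hp("HKY85 needs a single kappa")
      c(1, rates[1], 1, 1, rates[1], 1)
    })
  if (any(R6 <= 0)) stop_hp("exchangeabilities must be positive")
  Rm <- matrix(0, 4, 4)
  for (p in seq_len(6)) {
    i <- R_PAIRS[p, 1]; j <- R_PAIRS[p, 2]
    Rm[i, j] <- R6[p]; Rm[j, i] <- R6[p]
  }
  Q <- Rm %*% diag(pi)
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q <- Q / mu
  # symmetrized B = D^{1/2} Q D^{-1/2} has a real spectrum
  s <- sqrt(pi)
  B <- diag(s) %*% Q %*% diag(1 / s)
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  structure(list(name = name, pi = pi, R = R6 / mean(R6), Q = Q,
                 evec = diag(1 / s) %*% eig$vectors,
                 ivec = t(eig$vectors) %*% diag(s),
                 evals = eig$values),
            class = "subst_model")
}

#' @export
print.subst_model <- function(x, ...) {
  cat(sprintf("%s model; pi = (%s)\n", x$name,
              paste(sprintf("%.3f", x$pi), collapse = ", ")))
  invisible(x)
}

#' Transition probability matrix P(t) = exp(Q * rate * t)
#'
#' @param model a `subst_model`
#' @param t branch length (expected substitutions per site), >= 0
#' @param rate site-rate multiplier (discrete-Gamma category rate)
#' @return 4x4 row-stochastic matrix
#' @export
transition_matrix <- function(model, t, rate = 1) {
  if (t < 0) stop_hp("negative branch length")
  P <- model$evec %*% (exp(model$evals * t * rate) * model$ivec)
  # clip tiny negative round-off and renormalize rows
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Estimate a substitution model from aligned sequences
#'
#' Accumulates a matrix of observed "ancestral-offspring" substitution
#' counts, then fits the requested model by moment matching: pi from
#' observed base frequencies, exchangeabilities proportional to the
#' symmetrized count of each unordered base pair divided by the product
#' of its frequencies (pooled within the constraint classes of TN93 /
#' HKY85).
#'
#' With `method = "gojobori3"`, every sampled leaf triplet contributes:
#' at each site where the outgroup member agrees with one of the other
#' two, that shared state is taken as ancestral and a substitution to the
#' differing state is counted. With `method = "goldman2"`, sequence pairs
#' contribute their mismatched sites symmetrically.
#'
#' @param msa an `hp_msa` (or character vector of aligned sequences)
#' @param method "gojobori3" or "goldman2"
#' @param model_name "GTR", "TN93" or "HKY85"
#' @param max_triplets cap on enumerated triplets (random subsample,
#'   seeded by the current RNG state)
#' @return a `subst_model`
#' @export
train_subst_model <- function(msa, method = c("gojobori3", "goldman2"),
                              model_name = "GTR", max_triplets = 50000L) {
  method <- match.arg(method)
  if (is.character(msa)) msa <- msa_from_records(msa)
  mat <- msa$mat
  n <- nrow(mat)
  if (method == "gojobori3" && n < 3) stop_hp("gojobori3 needs >= 3 sequences")
  if (n < 2) stop_hp("need >= 2 sequences")
  counts <- matrix(0, 4, 4)
  if (method == "gojobori3") {
    trips <- utils::combn(n, 3)
    if (ncol(trips) > max_triplets)
      trips <- trips[, sample.int(ncol(trips), max_triplets), drop = FALSE]
    for (ci in seq_len(ncol(trips))) {
      idx <- trips[, ci]
      for (rot in 1:3) {
        out <- mat[idx[rot], ]
        a <- mat[idx[rot %% 3 + 1], ]
        b <- mat[idx[(rot + 1) %% 3 + 1], ]
        ok <- out >= 1 & out <= 4 & a >= 1 & a <= 4 & b >= 1 & b <= 4 & a != b
        anc_a <- ok & out == a      # ancestral state a, offspring state b
        anc_b <- ok & out == b
        if (any(anc_a)) {
          tab <- table(factor(a[anc_a], 1:4), factor(b[anc_a], 1:4))
          counts <- counts + unclass(tab)
        }
        if (any(anc_b)) {
          tab <- table(factor(b[anc_b], 1:4), factor(a[anc_b], 1:4))
          counts <- counts + unclass(tab)
        }
      }
    }
  } else {
    pairs <- utils::combn(n, 2)
    for (ci in seq_len(ncol(pairs))) {
      a <- mat[pairs[1, ci], ]; b <- mat[pairs[2, ci], ]
      ok <- a >= 1 & a <= 4 & b >= 1 & b <= 4 & a != b
      if (any(ok)) {
        tab <- unclass(table(factor(a[ok], 1:4), factor(b[ok], 1:4)))
        counts <- counts + tab + t(tab)   # direction unknown: symmetrize
      }
    }
  }
  if (sum(counts) == 0) stop_hp("no informative sites: sequences are identical")
  base_tab <- tabulate(mat[mat >= 1 & mat <= 4], nbins = 4)
  pi <- base_tab / sum(base_tab)
  sym <- counts + t(counts)
  r6 <- vapply(seq_len(6), function(p) {
    i <- R_PAIRS[p, 1]; j <- R_PAIRS[p, 2]
    sym[i, j] / (2 * pi[i] * pi[j])
  }, numeric(1))
  if (any(r6 <= 0)) r6[r6 <= 0] <- min(r6[r6 > 0]) * 1e-3
  rates <- switch(model_name,
    GTR = r6 / r6[6],
    TN93 = {
      tv <- mean(r6[-TRANSITIONS])
      c(r6[TRANSITIONS[1]] / tv, r6[TRANSITIONS[2]] / tv)
    },
    HKY85 = mean(r6[TRANSITIONS]) / mean(r6[-TRANSITIONS]),
    stop_hp("unknown model '%s'", model_name))
  subst_model(model_name, pi, rates)
}

#' Write / read a substitution model as labeled plain text
#'
#' Format: `MODEL` name line, `PI` line (4 frequencies), `RATE` line
#' (6 exchangeabilities, AC AG AT CG CT GT order), and four `Q` rows.
#' The Q rows are informational; re-reading reconstructs the model from
#' name, pi and rates.
#'
#' @param model a `subst_model`
#' @param path output file
#' @export
write_subst_model <- function(model, path) {
  r6 <- model$R
  rates <- switch(model$name,
    GTR = r6 / r6[6],
    TN93 = c(r6[TRANSITIONS[1]], r6[TRANSITIONS[2]]) / mean(r6[-TRANSITIONS]),
    HKY85 = mean(r6[TRANSITIONS]) / mean(r6[-TRANSITIONS]))
  lines <- c(sprintf("MODEL\t%s", model$name),
             sprintf("PI\t%s", paste(sprintf("%.8g", model$pi), collapse = "\t")),
             sprintf("RATE\t%s", paste(sprintf("%.8g", rates), collapse = "\t")),
             vapply(1:4, function(i)
               sprintf("Q.%s\t%s", DNA_BASES[i],
                       paste(sprintf("%.8g", model$Q[i, ]), collapse = "\t")),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_subst_model
#' @export
read_subst_model <- function(path) {
  lines <- readLines(path)
  fld <- function(tag) {
    ln <- grep(paste0("^", tag, "\t"), lines, value = TRUE)[1]
    strsplit(ln, "\t", fixed = TRUE)[[1]][-1]
  }
  subst_model(fld("MODEL"), as.numeric(fld("PI")), as.numeric(fld("RATE")))
}

#' Moment-matching estimate of the discrete-Gamma shape parameter
#'
#' Per-site substitution counts are modelled as negative-binomially
#' distributed; matching the first two moments gives
#' alpha = m^2 / (v - m) with m, v the mean and variance of the counts.
#' When v <= m there is no over-dispersion signal and the sentinel
#' `NA` ("rate-homogeneous") is returned.
#'
#' @param site_mutation_counts non-negative integer vector, one count per
#'   consensus site (see [count_site_mutations()])
#' @return shape alpha, or `NA_real_` when the counts show no rate
#'   variation
#' @export
estimate_gamma_shape <- function(site_mutation_counts) {
  x <- site_mutation_counts
  if (any(x < 0)) stop_hp("negative mutation counts")
  m <- mean(x); v <- stats::var(x)
  if (!is.finite(v) || v <= m) return(NA_real_)
  m^2 / (v - m)
}

#' Discretize a Gamma rate distribution into equal-probability categories
#'
#' Category rates are the conditional means of Gamma(alpha, alpha)
#' between consecutive alpha-quantiles (the mean-preserving
#' discretization), so the rates are non-decreasing and average exactly 1.
#'
#' @param alpha shape parameter > 0
#' @param k number of categories >= 1
#' @return object of class `discrete_gamma` with `alpha`, `k`,
#'   `category_rates`
#' @export
discretize_gamma <- function(alpha, k = 4L) {
  if (!is.finite(alpha) || alpha <= 0) stop_hp("alpha must be positive")
  if (k < 1) stop_hp("k must be >= 1")
  if (k == 1) {
    return(structure(list(alpha = alpha, k = 1L, category_rates = 1),
                     class = "discrete_gamma"))
  }
  q <- stats::qgamma(seq_len(k - 1) / k, shape = alpha, rate = alpha)
  bounds <- c(0, q, Inf)
  # E[X | a < X < b] for X ~ Gamma(alpha, alpha) via the incomplete-gamma
  # identity: integral of x f(x) over (a,b) = F_{alpha+1}(b) - F_{alpha+1}(a)
  upper <- stats::pgamma(bounds[-1], shape = alpha + 1, rate = alpha)
  lower <- stats::pgamma(bounds[-(k + 1)], shape = alpha + 1, rate = alpha)
  r <- k * (upper - lower)
  r <- r / mean(r)          # exact unit mean despite quantile round-off
  structure(list(alpha = alpha, k = as.integer(k), category_rates = r),
            class = "discrete_gamma")
}

#' Count observed substitutions per consensus site on a reference tree
#'
#' For every branch, compares the (observed or ML-inferred ancestral)
#' states of parent and child at each site; the per-site count is the
#' number of branches whose two endpoint states are defined (non-gap)
#' and differ.
#'
#' @param tree an evaluated `ref_tree` with ancestral sequences inferred
#' @return integer vector of length S
#' @export
count_site_mutations <- function(tree) {
  if (is.null(tree$seq) || anyNA(tree$seq[!tree$tip, , drop = FALSE]))
    stop_hp("tree must be evaluated with ancestral sequences inferred")
  S <- tree$S
  counts <- integer(S)
  for (v in seq_len(tree$n_node)) {
    u <- tree$parent[v]
    if (u == 0L) next
    pa <- tree$seq[u, ]; ch <- tree$seq[v, ]
    ok <- pa >= 1 & pa <= 4 & ch >= 1 & ch <= 4
    counts <- counts + as.integer(ok & pa != ch)
  }
  counts
}
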