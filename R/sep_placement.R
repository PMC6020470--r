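# Seed-Estimate-Place (SEP) local phylogenetic placement, taxonomy
# assignment with Q-scores, and segment-placement chimera detection.
#
# A placement attaches a read n to a reference branch (u, v) by a new
# junction node r, with w_ur + w_rv = w0 (the original branch length is
# conserved, so the reference topology and all other branches are
# untouched) and a pendant length w_nr. Because the model is reversible,
# the likelihood of the whole tree with the read attached factorizes at
# the junction into three pre-computed messages (Pulley Principle):
# lik_out[[v]] from the rest of the tree, lik_sub[[v]] from below v, and
# the read's own leaf log-likelihoods — no global re-evaluation needed.

# sites vector (length S) of an aligned read: 1..4 observed base,
# 5 = N, 0 = gap/unobserved
alignment_sites <- function(alignment, S) {
  sites <- integer(S)
  idx <- alignment$cs_start:alignment$cs_end
  sites[idx] <- seq_to_int(alignment$aligned)
  sites
}

# p-distance between a read-sites vector and one node sequence,
# over sites where both carry an observed base
p_dist <- function(sites, nodeseq) {
  ok <- sites >= 1L & sites <= 4L & nodeseq >= 1L & nodeseq <= 4L
  if (!any(ok)) return(NA_real_)
  mean(sites[ok] != nodeseq[ok])
}

#' Rank reference nodes by observed distance to an aligned read
#'
#' Computes the p-distance between the read and every node's observed or
#' ML-inferred sequence over the read's consensus interval, and returns
#' the closest `max_seeds` nodes (ascending p-distance, ties broken by
#' node id).
#'
#' @param tree an evaluated `ref_tree` with ancestral sequences
#' @param sites integer sites vector (see details) or an `hp_alignment`
#' @param max_seeds number of seed candidates (default 5)
#' @return data.frame with columns `node`, `p_dist`
#' @export
find_seed_nodes <- function(tree, sites, max_seeds = 5L) {
  if (inherits(sites, "hp_alignment")) sites <- alignment_sites(sites, tree$S)
  if (!any(sites >= 1L & sites <= 4L))
    stop_hp("read has no observed overlap with the consensus sites")
  pd <- vapply(seq_len(tree$n_node), function(v) p_dist(sites, tree$seq[v, ]),
               numeric(1))
  ord <- order(pd, seq_along(pd), na.last = TRUE)
  ord <- ord[!is.na(pd[ord])]
  head_n <- utils::head(ord, max_seeds)
  data.frame(node = head_n, p_dist = pd[head_n])
}

# Pre-sliced evaluation context for placements of one read on one
# branch: the two directional messages and the read leaf log-likelihoods
# restricted to the read's observed sites, plus the cached contribution
# of all other sites (which is split-invariant by the Pulley Principle
# and therefore equals the plain tree site log-likelihoods).
placement_context <- function(tree, v, sites) {
  obs <- which(sites >= 1L & sites <= 4L)
  rates <- tree_rates(tree)
  list(v = v, w0 = tree$blen[v], rates = rates,
       model = tree$model, lpi = log(tree$model$pi),
       Mout = lapply(seq_along(rates), function(g)
         matrix(tree$lik_out[[v]][, obs, g], nrow = 4)),
       Msub = lapply(seq_along(rates), function(g)
         matrix(tree$lik_sub[[v]][, obs, g], nrow = 4)),
       readL = leaf_loglik(sites[obs]),
       const_rest = tree$loglik - sum(tree$site_loglik[obs]),
       nobs = length(obs))
}

# log-likelihood of the full tree with the read attached at distal
# length w_ur (from the parent end) and pendant length w_nr
placement_loglik <- function(ctx, w_ur, w_nr) {
  w_rv <- max(ctx$w0 - w_ur, 0)
  ncat <- length(ctx$rates)
  percat <- vapply(seq_len(ncat), function(g) {
    A <- convolute(ctx$Mout[[g]], transition_matrix(ctx$model, w_ur, ctx$rates[g]))
    B <- convolute(ctx$Msub[[g]], transition_matrix(ctx$model, w_rv, ctx$rates[g]))
    N <- convolute(ctx$readL, transition_matrix(ctx$model, w_nr, ctx$rates[g]))
    col_log_sum_exp(A + B + N + ctx$lpi)
  }, numeric(ctx$nobs))
  ll_obs <- if (ncat == 1) sum(percat) else {
    dim(percat) <- c(ctx$nobs, ncat)
    sum(apply(percat, 1L, log_sum_exp) - log(ncat))
  }
  ctx$const_rest + ll_obs
}

#' Fast placement estimate on one branch (Procedure Estimate-Place)
#'
#' The branching point and pendant length are set from observed
#' p-distances (d_u to the parent's sequence, d_v to the child's):
#' `w_ur/w0 = d_u/(d_u + d_v)` (0.5 when both are zero) and
#' `w_nr = max(min(d_u, d_v) - min(w_ur, w_rv), min_branch)`. The
#' estimate's log-likelihood uses the cached directional messages only;
#' the global tree is never modified.
#'
#' @param tree an evaluated `ref_tree`
#' @param sites read sites vector or `hp_alignment`
#' @param v child node of the candidate branch (parent(v), v)
#' @param min_branch smallest representable branch length
#' @return list with `v`, `w0`, `w_ur`, `w_rv`, `w_nr`, `loglik`
#' @export
estimate_place <- function(tree, sites, v, min_branch = 1e-6, ctx = NULL) {
  if (inherits(sites, "hp_alignment")) sites <- alignment_sites(sites, tree$S)
  u <- tree$parent[v]
  if (u == 0L) stop_hp("cannot place on the root's virtual branch")
  w0 <- tree$blen[v]
  d_u <- p_dist(sites, tree$seq[u, ])
  d_v <- p_dist(sites, tree$seq[v, ])
  ratio <- if (isTRUE(d_u + d_v > 0)) d_u / (d_u + d_v) else 0.5
  ratio <- min(max(ratio, 0), 1)
  w_ur <- ratio * w0
  w_rv <- w0 - w_ur
  w_nr <- max(min(d_u, d_v) - min(w_ur, w_rv), min_branch)
  ctx <- ctx %||% placement_context(tree, v, sites)
  ll <- placement_loglik(ctx, w_ur, w_nr)
  list(v = v, u = u, w0 = w0, w_ur = w_ur, w_rv = w_rv, w_nr = w_nr,
       loglik = ll, ctx = ctx)
}

#' Jointly optimize a placement estimate (Procedure Joint-Opt-Place)
#'
#' Alternates Brent line searches over the branching point
#' (w_ur in [0, w0], with w_rv = w0 - w_ur) and the pendant length w_nr
#' until the log-likelihood improves by less than `tol` or `max_iter`
#' sweeps are reached. The returned log-likelihood equals the whole-tree
#' log-likelihood with the read grafted (reversible model required).
#'
#' @param tree an evaluated `ref_tree`
#' @param sites read sites vector or `hp_alignment`
#' @param estimate output of [estimate_place()]
#' @param tol convergence tolerance on the log-likelihood
#' @param max_iter maximum alternation sweeps
#' @param min_branch smallest branch length
#' @param max_pendant upper bound of the pendant length search
#' @return the estimate list with optimized lengths, final `loglik`, and
#'   a `converged` flag
#' @export
joint_opt_place <- function(tree, sites, estimate, tol = 1e-6,
                            max_iter = 100L, min_branch = 1e-6,
                            max_pendant = 2) {
  if (!is.null(tree$model$evals) && is.null(tree$model$pi))
    stop_hp("placement requires a reversible substitution model")
  if (inherits(sites, "hp_alignment")) sites <- alignment_sites(sites, tree$S)
  v <- estimate$v
  w0 <- estimate$w0
  ctx <- estimate$ctx %||% placement_context(tree, v, sites)
  f <- function(w_ur, w_nr) placement_loglik(ctx, w_ur, w_nr)
  w_ur <- min(max(estimate$w_ur, 0), w0)
  w_nr <- max(estimate$w_nr, min_branch)
  ll <- f(w_ur, w_nr)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    if (w0 > 0) {
      o1 <- stats::optimize(function(a) f(a, w_nr), c(0, w0), maximum = TRUE,
                            tol = max(w0 * 1e-4, 1e-9))
      # Brent can miss boundary optima; check the ends explicitly
      cand_a <- c(o1$maximum, 0, w0)
      lls <- c(o1$objective, f(0, w_nr), f(w0, w_nr))
      w_ur <- cand_a[which.max(lls)]
    }
    o2 <- stats::optimize(function(b) f(w_ur, b), c(min_branch, max_pendant),
                          maximum = TRUE, tol = 1e-7)
    cand_b <- c(o2$maximum, min_branch)
    llb <- c(o2$objective, f(w_ur, min_branch))
    w_nr <- cand_b[which.max(llb)]
    ll_new <- max(llb)
    if (abs(ll_new - ll) < tol) { ll <- ll_new; converged <- TRUE; break }
    ll <- ll_new
  }
  out <- estimate
  out$ctx <- NULL
  out$w_ur <- w_ur
  out$w_rv <- w0 - w_ur
  out$w_nr <- w_nr
  out$loglik <- ll
  out$converged <- converged
  out
}

# maximal branch-length path from each node down to a descendant leaf
node_heights <- function(tree) {
  h <- numeric(tree$n_node)
  for (v in tree$postorder) {
    if (tree$tip[v]) next
    h[v] <- max(vapply(tree$children[[v]],
                       function(c_) h[c_] + tree$blen[c_], numeric(1)))
  }
  h
}

# candidate branches (child-node ids) adjacent to the seed nodes
seed_branches <- function(tree, seed_nodes) {
  vs <- integer(0)
  for (x in seed_nodes) {
    if (tree$parent[x] != 0L) vs <- c(vs, x)
    vs <- c(vs, tree$children[[x]])
  }
  sort(unique(vs))
}

#' Place one aligned read on the reference tree
#'
#' Runs the full SEP pipeline: seed nodes by p-distance, fast estimates
#' on every seed-adjacent branch, joint optimization of the `top_n`
#' estimates, and selection of the best candidate by log-likelihood
#' (uniform placement prior) or log-likelihood plus a node-height log
#' prior (-height/tau, favouring near-leaf assignments). The Q-score is
#' `min(250, -10 log10(1 - w))` with w the chosen candidate's softmax
#' weight among all optimized candidates.
#'
#' @param tree an evaluated `ref_tree` with ancestral sequences and
#'   taxonomy
#' @param alignment an `hp_alignment` (or sites vector)
#' @param max_seeds seed candidates by p-distance (default 5)
#' @param top_n estimates to optimize (default 5)
#' @param prior "uniform" or "height"
#' @param tau height-prior scale (default 1)
#' @param tol,max_iter,min_branch optimization controls
#' @return an object of class `hp_placement`: fields `read_id`, `u`,
#'   `v`, `w_ur`, `w_rv`, `w_nr`, `loglik`, `q_score`, `node`,
#'   `taxonomy`, `flags`, `candidates`
#' @export
place_read <- function(tree, alignment, max_seeds = 5L, top_n = 5L,
                       prior = c("uniform", "height"), tau = 1,
                       tol = 1e-6, max_iter = 100L, min_branch = 1e-6) {
  prior <- match.arg(prior)
  read_id <- if (inherits(alignment, "hp_alignment")) alignment$read_id else "read"
  sites <- if (inherits(alignment, "hp_alignment"))
    alignment_sites(alignment, tree$S) else alignment
  res_unplaced <- structure(
    list(read_id = read_id, u = NA_integer_, v = NA_integer_,
         w_ur = NA_real_, w_rv = NA_real_, w_nr = NA_real_,
         loglik = NA_real_, q_score = 0, node = NA_integer_,
         taxonomy = "", flags = "unplaced", candidates = NULL),
    class = "hp_placement")
  seeds <- tryCatch(find_seed_nodes(tree, sites, max_seeds),
                    error = function(e) NULL)
  if (is.null(seeds) || nrow(seeds) == 0) return(res_unplaced)
  branches <- seed_branches(tree, seeds$node)
  if (length(branches) == 0) return(res_unplaced)
  ests <- lapply(branches, function(v) estimate_place(tree, sites, v, min_branch))
  ord <- order(vapply(ests, `[[`, numeric(1), "loglik"), decreasing = TRUE)
  ests <- ests[utils::head(ord, top_n)]
  opts <- lapply(ests, function(e) joint_opt_place(tree, sites, e, tol,
                                                   max_iter, min_branch))
  lls <- vapply(opts, `[[`, numeric(1), "loglik")
  assigned_node <- vapply(opts, function(o) {
    if (o$w_ur <= min_branch) o$u
    else o$v                      # taxonomy lives on nodes; branch -> child
  }, integer(1))
  score <- lls
  if (prior == "height") {
    h <- node_heights(tree)
    score <- lls - h[assigned_node] / tau
  }
  best <- which.max(score)
  w <- exp(lls - log_sum_exp(lls))       # softmax over optimized candidates
  wbest <- w[best]
  q <- if (wbest >= 1 - 1e-25) 250 else min(250, -10 * log10(1 - wbest))
  o <- opts[[best]]
  node <- assigned_node[best]
  structure(list(read_id = read_id, u = o$u, v = o$v,
                 w_ur = o$w_ur, w_rv = o$w_rv, w_nr = o$w_nr,
                 loglik = o$loglik, q_score = q, node = node,
                 taxonomy = tree$taxonomy[node], flags = "",
                 candidates = data.frame(v = vapply(opts, `[[`, integer(1), "v"),
                                         loglik = lls, weight = w)),
            class = "hp_placement")
}

#' @export
print.hp_placement <- function(x, ...) {
  cat(sprintf("placement of '%s': branch (%s,%s), logL = %.3f, Q = %.1f, %s\n",
              x$read_id, x$u, x$v, x$loglik, x$q_score, x$taxonomy))
  invisible(x)
}

#' Segment-placement chimera detection
#'
#' Splits the aligned read into equal 5'/3' consensus segments, places
#' both with the common seed set of the whole read, then computes the
#' joint log-odds of best versus alternative placements:
#' `LOD = (loglik5_best - loglik5_alt) + (loglik3_best - loglik3_alt)`,
#' where the alternative re-places each segment on the other segment's
#' best branch. A read is flagged chimeric when the two best branches
#' differ and LOD >= `lod_cutoff`.
#'
#' @param tree an evaluated `ref_tree`
#' @param alignment an `hp_alignment` (or sites vector)
#' @param lod_cutoff default 50
#' @param min_segment minimum observed sites per segment; shorter reads
#'   are returned unevaluated with flag "unknown"
#' @param max_seeds,top_n,tol,max_iter,min_branch SEP controls
#' @return list of class `hp_chimera`: `is_chimera`, `lod`, `best5`,
#'   `best3` (branch child ids), the four segment log-likelihoods, and
#'   `flag` ("ok" or "unknown")
#' @export
detect_chimera <- function(tree, alignment, lod_cutoff = 50,
                           min_segment = 20L, max_seeds = 5L, top_n = 5L,
                           tol = 1e-6, max_iter = 100L, min_branch = 1e-6) {
  sites <- if (inherits(alignment, "hp_alignment"))
    alignment_sites(alignment, tree$S) else alignment
  obs <- which(sites >= 1L & sites <= 4L)
  if (length(obs) < 2 * min_segment) {
    return(structure(list(is_chimera = NA, lod = NA_real_,
                          best5 = NA_integer_, best3 = NA_integer_,
                          loglik5_best = NA_real_, loglik5_alt = NA_real_,
                          loglik3_best = NA_real_, loglik3_alt = NA_real_,
                          flag = "unknown"), class = "hp_chimera"))
  }
  mid <- obs[ceiling(length(obs) / 2)]
  s5 <- sites; s5[seq_along(sites) > mid] <- 0L
  s3 <- sites; s3[seq_along(sites) <= mid] <- 0L
  seeds <- find_seed_nodes(tree, sites, max_seeds)   # common seed set
  branches <- seed_branches(tree, seeds$node)
  place_segment <- function(sseg) {
    ests <- lapply(branches, function(v) estimate_place(tree, sseg, v, min_branch))
    ord <- order(vapply(ests, `[[`, numeric(1), "loglik"), decreasing = TRUE)
    opts <- lapply(ests[utils::head(ord, top_n)],
                   function(e) joint_opt_place(tree, sseg, e, tol, max_iter,
                                               min_branch))
    lls <- vapply(opts, `[[`, numeric(1), "loglik")
    opts[[which.max(lls)]]
  }
  b5 <- place_segment(s5)
  b3 <- place_segment(s3)
  opt_on <- function(sseg, v) {
    joint_opt_place(tree, sseg, estimate_place(tree, sseg, v, min_branch),
                    tol, max_iter, min_branch)$loglik
  }
  ll5_alt <- if (b3$v == b5$v) b5$loglik else opt_on(s5, b3$v)
  ll3_alt <- if (b3$v == b5$v) b3$loglik else opt_on(s3, b5$v)
  lod <- (b5$loglik - ll5_alt) + (b3$loglik - ll3_alt)
  structure(list(is_chimera = (b5$v != b3$v) && lod >= lod_cutoff,
                 lod = lod, best5 = b5$v, best3 = b3$v,
                 loglik5_best = b5$loglik, loglik5_alt = ll5_alt,
                 loglik3_best = b3$loglik, loglik3_alt = ll3_alt,
                 flag = "ok"),
            class = "hp_chimera")
}
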