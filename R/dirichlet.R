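# Dirichlet-density (DD) and Dirichlet-mixture (DM) models over count
# data, fit by maximizing the Dirichlet-multinomial marginal likelihood.
# DDs serve as priors for profile-HMM transitions and insert emissions,
# DMs for match emissions; both give closed-form posterior-mean estimates.

#' Log marginal likelihood of count rows under a Dirichlet-multinomial
#'
#' @param counts matrix (rows = observations, cols = alphabet)
#' @param alpha positive concentration vector
#' @return numeric vector, one log marginal likelihood per row
#' @keywords internal
dirmult_logmarg <- function(counts, alpha) {
  A <- sum(alpha)
  n <- rowSums(counts)
  lgamma(A) - lgamma(A + n) +
    rowSums(lgamma(sweep(counts, 2L, alpha, "+"))) - sum(lgamma(alpha))
}

fit_dd_weighted <- function(counts, w, alpha0 = NULL) {
  d <- ncol(counts)
  alpha0 <- alpha0 %||% rep(1, d)
  obj <- function(la) -sum(w * dirmult_logmarg(counts, exp(la)))
  grad <- function(la) {
    a <- exp(la)
    A <- sum(a)
    n <- rowSums(counts)
    g <- vapply(seq_len(d), function(j) {
      sum(w * (digamma(A) - digamma(A + n) +
                 digamma(counts[, j] + a[j]) - digamma(a[j])))
    }, numeric(1))
    -g * a  # chain rule for log-parameterization
  }
  fit <- stats::optim(log(alpha0), obj, grad, method = "L-BFGS-B",
                      lower = log(1e-4), upper = log(1e4),
                      control = list(maxit = 500, factr = 1e5))
  exp(fit$par)
}

#' Fit a Dirichlet density or mixture to observed count vectors
#'
#' Maximizes the (weighted) Dirichlet-multinomial marginal likelihood of
#' the observation rows. Mixtures are fit by EM over component
#' responsibilities with an L-BFGS M-step per component.
#'
#' @param observations non-negative count matrix (rows = observations)
#' @param model_kind "density" or "mixture"
#' @param ncomp number of mixture components (mixture only)
#' @param max_iter,tol EM controls
#' @return an object of class `dirichlet_density` (field `alpha`) or
#'   `dirichlet_mixture` (fields `weights`, `components`)
#' @export
train_dirichlet <- function(observations, model_kind = c("density", "mixture"),
                            ncomp = 2L, max_iter = 100L, tol = 1e-6) {
  model_kind <- match.arg(model_kind)
  counts <- as.matrix(observations)
  if (any(counts < 0)) stop_hp("negative counts")
  keep <- rowSums(counts) > 0
  if (!any(keep)) stop_hp("all observation rows are zero")
  counts <- counts[keep, , drop = FALSE]
  if (model_kind == "density") {
    alpha <- fit_dd_weighted(counts, rep(1, nrow(counts)))
    return(structure(list(alpha = alpha), class = "dirichlet_density"))
  }
  d <- ncol(counts)
  # init: moment-flavoured split around the pooled mean
  pooled <- colSums(counts) / sum(counts)
  set_alpha <- lapply(seq_len(ncomp), function(c) {
    pmax(pooled * d * (0.5 + c), 1e-3)
  })
  wts <- rep(1 / ncomp, ncomp)
  prev <- -Inf
  for (it in seq_len(max_iter)) {
    lm <- vapply(seq_len(ncomp),
                 function(c) dirmult_logmarg(counts, set_alpha[[c]]) + log(wts[c]),
                 numeric(nrow(counts)))
    dim(lm) <- c(nrow(counts), ncomp)
    mx <- apply(lm, 1L, max)
    resp <- exp(lm - mx)
    ll <- sum(mx + log(rowSums(resp)))
    resp <- resp / rowSums(resp)
    wts <- pmax(colMeans(resp), 1e-8)
    wts <- wts / sum(wts)
    set_alpha <- lapply(seq_len(ncomp), function(c) {
      fit_dd_weighted(counts, resp[, c], alpha0 = set_alpha[[c]])
    })
    if (is.finite(prev) && abs(ll - prev) < tol) break
    prev <- ll
  }
  structure(list(weights = wts,
                 components = lapply(set_alpha,
                                     function(a) structure(list(alpha = a),
                                                           class = "dirichlet_density"))),
            class = "dirichlet_mixture")
}

#' Total log marginal likelihood of counts under a fitted model
#' @param model `dirichlet_density` or `dirichlet_mixture`
#' @param counts count matrix
#' @return scalar log marginal likelihood (sum over rows)
#' @export
dirichlet_logmarg <- function(model, counts) {
  counts <- as.matrix(counts)
  if (inherits(model, "dirichlet_density"))
    return(sum(dirmult_logmarg(counts, model$alpha)))
  lm <- vapply(seq_along(model$weights),
               function(c) dirmult_logmarg(counts, model$components[[c]]$alpha) +
                 log(model$weights[c]),
               numeric(nrow(counts)))
  dim(lm) <- c(nrow(counts), length(model$weights))
  sum(apply(lm, 1L, log_sum_exp))
}

#' Posterior-mean multinomial parameters for one count vector
#'
#' Under a density prior this is `(n + alpha) / sum(n + alpha)`; under a
#' mixture, the responsibility-weighted average of per-component
#' posterior means.
#'
#' @param model `dirichlet_density` or `dirichlet_mixture`
#' @param n a single count vector
#' @return probability vector summing to 1
#' @export
dirichlet_postmean <- function(model, n) {
  if (inherits(model, "dirichlet_density")) {
    p <- n + model$alpha
    return(p / sum(p))
  }
  lm <- vapply(seq_along(model$weights),
               function(c) dirmult_logmarg(matrix(n, 1), model$components[[c]]$alpha) +
                 log(model$weights[c]), numeric(1))
  r <- exp(lm - log_sum_exp(lm))
  means <- vapply(model$components,
                  function(cm) (n + cm$alpha) / sum(n + cm$alpha),
                  numeric(length(n)))
  as.numeric(means %*% r)
}
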