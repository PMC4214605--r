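#' Fix non-centrality parameters from observed Z-scores
#'
#' The model treats the NCP (expected Z-score of a causal SNP) as fixed
#' rather than estimated, since estimating both causal status and effect
#' size from one Z-score per SNP would over-specify the model. Under the
#' default `"clamped"` strategy the NCP equals the observed Z when
#' |Z| > threshold and sign(Z) * threshold otherwise (sign(0) taken as +1);
#' `"observed"` uses the Z-score as is; `"locus_max"` uses sign(Z) times
#' the largest |Z| at the locus.
#'
#' @param z numeric vector of Z-scores.
#' @param strategy one of `"clamped"`, `"observed"`, `"locus_max"`.
#' @param threshold clamping threshold (default 3.7, roughly the Wald
#'   statistic at p = 1e-4).
#' @return Numeric vector of NCPs, same length as `z`.
#' @export
ncp_from_z <- function(z, strategy = c("clamped", "observed", "locus_max"),
                       threshold = 3.7) {
  strategy <- match.arg(strategy)
  stopifnot(threshold > 0)
  sgn <- ifelse(z >= 0, 1, -1)
  switch(strategy,
         clamped = ifelse(abs(z) > threshold, z, sgn * threshold),
         observed = z,
         locus_max = sgn * max(abs(z)))
}

#' Logistic prior probability of causality
#'
#' Per-SNP prior `p_j = 1 / (1 + exp(gamma' a_j))` where `a_j` is the
#' SNP's annotation row (baseline first). Under this sign convention a
#' large positive baseline coefficient gives a small prior, and a negative
#' annotation coefficient means enrichment of causal variants in the
#' annotation.
#'
#' @param gamma numeric coefficient vector, length = number of annotation
#'   columns (baseline included).
#' @param annotations m x (K+1) binary matrix with leading baseline column.
#' @return Numeric vector of prior probabilities in (0, 1).
#' @export
prior_prob <- function(gamma, annotations) {
  annotations <- as.matrix(annotations)
  if (ncol(annotations) != length(gamma))
    stop("gamma has length ", length(gamma), " but annotations have ",
         ncol(annotations), " columns")
  plogis(-drop(annotations %*% gamma))
}

#' Log prior of a causal configuration
#'
#' Independent-Bernoulli log prior: sum of `log p_j` over causal SNPs plus
#' `log(1 - p_j)` over the rest.
#'
#' @param config integer vector of causal SNP indices (possibly empty).
#' @param priors per-SNP prior probabilities in (0, 1).
#' @return Log prior probability.
#' @export
config_log_prior <- function(config, priors) {
  stopifnot(all(priors > 0 & priors < 1))
  base <- sum(log1p(-priors))
  if (!length(config)) return(base)
  config <- as.integer(config)
  stopifnot(all(config >= 1L), all(config <= length(priors)),
            !anyDuplicated(config))
  base + sum(log(priors[config]) - log1p(-priors[config]))
}

#' Log Bayes factor of a causal configuration
#'
#' Under the model `Z | c ~ MVN(Sigma (lambda o c), Sigma)` the log ratio
#' of the configuration's MVN density to the null (zero-mean) density has
#' the closed form `lambda_c' z - 0.5 * lambda_c' Sigma lambda_c`,
#' touching only the causal rows/columns of the LD matrix. The empty
#' configuration returns exactly 0.
#'
#' @param config integer vector of causal indices (1-based, possibly
#'   empty).
#' @param z Z-score vector.
#' @param ld positive-definite LD matrix (regularize first if needed).
#' @param ncp NCP vector from [ncp_from_z()].
#' @return Log Bayes factor against the null configuration.
#' @export
config_log_bf <- function(config, z, ld, ncp) {
  if (!length(config)) return(0)
  config <- as.integer(config)
  lam <- ncp[config]
  sum(lam * z[config]) -
    0.5 * drop(crossprod(lam, ld[config, config, drop = FALSE] %*% lam))
}

## Enumerate all causal configurations of size <= kmax as a list of
## k x n_k index matrices (k = 0 entry is NULL; the empty config is
## implicit). Errors if the enumeration exceeds `cap` configurations.
config_index_sets <- function(m, kmax, cap = 5e6) {
  kmax <- min(kmax, m)
  total <- sum(choose(m, 0:kmax))
  if (total > cap)
    stop("configuration space has ", format(total, big.mark = ","),
         " elements (m = ", m, ", max_causals = ", kmax,
         "), above the cap of ", format(cap, big.mark = ","),
         "; reduce max_causals")
  lapply(seq_len(kmax), function(k) {
    if (k == 1L) matrix(seq_len(m), nrow = 1L) else combn(m, k)
  })
}

## Per-configuration log Bayes factors for all enumerated configurations,
## grouped by configuration size; element [[k]] aligns with
## config_index_sets()[[k]] columns. Computed once per locus: they do not
## depend on gamma.
config_logbf_sets <- function(idx_sets, z, ld, ncp) {
  lz <- ncp * z
  lapply(idx_sets, function(idx) {
    k <- nrow(idx)
    if (k == 1L) {
      drop(lz - 0.5 * ncp^2 * diag(ld))
    } else if (k == 2L) {
      i <- idx[1L, ]; j <- idx[2L, ]
      lz[i] + lz[j] -
        0.5 * (ncp[i]^2 + ncp[j]^2 + 2 * ncp[i] * ncp[j] * ld[cbind(i, j)])
    } else {
      apply(idx, 2L, function(cfg) config_log_bf(cfg, z, ld, ncp))
    }
  })
}

## Internal per-locus workspace reused across EM iterations: regularized
## LD, NCPs, enumerated configurations and their (gamma-free) log BFs.
locus_prep <- function(x, control) {
  z <- x$snps$zscore
  ld <- regularize_ld(x$ld, control$ld_ridge)
  ncp <- ncp_from_z(z, control$ncp_strategy, control$ncp_threshold)
  idx <- config_index_sets(length(z), control$max_causals, control$enum_cap)
  list(locus_id = x$locus_id, z = z, ld = ld, ncp = ncp,
       A = x$annotations, idx = idx,
       logbf = config_logbf_sets(idx, z, ld, ncp))
}

## Core E-step on a prepared locus for a given gamma. Returns the
## normalized configuration posteriors (grouped by size), the per-SNP
## marginal posteriors, and the locus log-likelihood (relative to the
## null-density constant, which cancels in all ratios).
e_step_prep <- function(prep, gamma) {
  p <- prior_prob(gamma, prep$A)
  base <- sum(log1p(-p))
  q <- log(p) - log1p(-p)
  lw <- vector("list", length(prep$idx) + 1L)
  lw[[1L]] <- base                         # empty configuration
  for (k in seq_along(prep$idx)) {
    idx <- prep$idx[[k]]
    qsum <- if (nrow(idx) == 1L) q else
      colSums(matrix(q[idx], nrow = nrow(idx)))
    lw[[k + 1L]] <- prep$logbf[[k]] + base + qsum
  }
  all_lw <- unlist(lw, use.names = FALSE)
  mx <- max(all_lw)
  loglik <- mx + log(sum(exp(all_lw - mx)))
  m <- length(prep$z)
  snp_post <- numeric(m)
  w <- vector("list", length(lw))
  w[[1L]] <- exp(lw[[1L]] - loglik)
  for (k in seq_along(prep$idx)) {
    wk <- exp(lw[[k + 1L]] - loglik)
    w[[k + 1L]] <- wk
    idx <- prep$idx[[k]]
    rs <- rowsum(rep(wk, each = nrow(idx)), as.vector(idx))
    g <- as.integer(rownames(rs))
    snp_post[g] <- snp_post[g] + rs[, 1L]
  }
  list(config_w = w, snp_post = pmin(snp_post, 1), loglik = loglik)
}

#' Per-locus marginal log-likelihood
#'
#' Log of the sum, over all causal configurations with at most
#' `max_causals` members, of `exp(log BF + log prior)`, computed with a
#' stable log-sum-exp. The value is relative to the null MVN density of
#' the Z-scores; that constant cancels in posterior ratios, EM updates and
#' likelihood-ratio tests.
#'
#' @param x a [locus()] object.
#' @param gamma annotation coefficient vector aligned to
#'   `x$annotations`.
#' @param control a [finemap_control()].
#' @return Log-likelihood (relative scale).
#' @export
locus_log_likelihood <- function(x, gamma, control = finemap_control()) {
  e_step_prep(locus_prep(x, control), gamma)$loglik
}
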