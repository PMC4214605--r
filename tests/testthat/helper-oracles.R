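# Independent oracles and small fixture builders used across tests.

# Dense multivariate normal log density via Cholesky; deliberately
# independent of the package's reduced-form Bayes factor path.
dmvn_log <- function(x, mu, S) {
  U <- chol(S)
  d <- backsolve(U, x - mu, transpose = TRUE)
  -0.5 * length(x) * log(2 * pi) - sum(log(diag(U))) - 0.5 * sum(d^2)
}

# Exhaustive Bayesian model averaging over all causal configurations of
# size <= kmax, using dense MVN densities and explicit Bernoulli priors.
brute_posterior <- function(z, ld, priors, ncp, kmax = length(z)) {
  m <- length(z)
  configs <- list(integer(0))
  for (k in seq_len(min(kmax, m)))
    configs <- c(configs, lapply(seq_len(ncol(combn(m, k))),
                                 function(j) combn(m, k)[, j]))
  logw <- vapply(configs, function(cfg) {
    lam <- numeric(m); lam[cfg] <- ncp[cfg]
    inc <- seq_len(m) %in% cfg
    lp <- sum(log(ifelse(inc, priors, 1 - priors)))
    lp + dmvn_log(z, drop(ld %*% lam), ld) - dmvn_log(z, rep(0, m), ld)
  }, 0)
  w <- exp(logw - max(logw))
  w <- w / sum(w)
  snp_post <- vapply(seq_len(m), function(j)
    sum(w[vapply(configs, function(cfg) j %in% cfg, TRUE)]), 0)
  list(configs = configs, w = w, snp_post = snp_post,
       loglik = max(logw) + log(sum(exp(logw - max(logw)))))
}

# random positive-definite correlation matrix
random_corr <- function(m) {
  X <- matrix(rnorm(m * (m + 5)), m + 5, m)
  regularize_ld(cor(X), 1e-4)
}

# quick locus fixture with given z, optional annotation column
make_locus <- function(z, ld = NULL, ann = NULL, id = "L1") {
  m <- length(z)
  if (is.null(ld)) ld <- diag(m)
  snps <- data.frame(snp_id = sprintf("%s_s%02d", id, seq_len(m)),
                     chrom = "1", pos = seq_len(m) * 100L, zscore = z)
  locus(id, snps, ld, ann)
}
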