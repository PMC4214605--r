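test_that("E-step posteriors match exhaustive enumeration", {
  # two independent SNPs, z = (4, 0), one causal max, flat priors 1/2
  l <- make_locus(c(4, 0))
  ctl <- finemap_control(max_causals = 1, ld_ridge = 0)
  ep <- e_step(l, gamma = 0, control = ctl)
  expect_equal(sum(ep$config_post), 1, tolerance = 1e-12)
  ncp <- ncp_from_z(c(4, 0))
  w <- c(1, exp(config_log_bf(1L, c(4, 0), diag(2), ncp)),
         exp(config_log_bf(2L, c(4, 0), diag(2), ncp)))
  expect_equal(ep$snp_post[1], w[2] / sum(w), tolerance = 1e-10)
  expect_equal(ep$snp_post[1], 0.99966, tolerance = 1e-4)

  # marginal posteriors are sums of configuration posteriors
  has1 <- vapply(ep$configs, function(cfg) 1L %in% cfg, TRUE)
  expect_equal(ep$snp_post[1], sum(ep$config_post[has1]))
})

test_that("E-step equals exhaustive model averaging for kmax = m", {
  set.seed(12)
  for (rep in 1:5) {
    m <- sample(4:8, 1)
    ld <- random_corr(m)
    z <- rnorm(m, sd = 2.5)
    ann <- cbind(a1 = rbinom(m, 1, .4))
    l <- make_locus(z, ld = ld, ann = ann)
    gamma <- c(runif(1, 0.5, 3), runif(1, -2, 1))
    ctl <- finemap_control(max_causals = m, ld_ridge = 0)
    ep <- e_step(l, gamma, ctl)
    oracle <- brute_posterior(z, ld, prior_prob(gamma, l$annotations),
                              ncp_from_z(z))
    expect_equal(ep$snp_post, oracle$snp_post, tolerance = 1e-8)
    expect_equal(ep$loglik, oracle$loglik, tolerance = 1e-8)
    expect_equal(sum(ep$config_post), 1, tolerance = 1e-10)
  }
})

test_that("flat signal yields symmetric posteriors", {
  l <- make_locus(rep(0, 6))
  ep <- e_step(l, gamma = 3, finemap_control(ld_ridge = 0))
  expect_equal(ep$snp_post, rep(ep$snp_post[1], 6), tolerance = 1e-12)
})

test_that("M-step solves soft-label logistic regression", {
  set.seed(4)
  A <- cbind(baseline = 1, a1 = rbinom(200, 1, .3))
  # fixed point: labels generated exactly at gamma0
  g0 <- c(2.5, -1)
  E <- prior_prob(g0, A)
  expect_equal(unname(m_step(E, A, g0)), g0, tolerance = 1e-5)

  # closed forms for the baseline-only model
  A0 <- cbind(baseline = rep(1, 50))
  expect_equal(unname(m_step(rep(0.5, 50), A0, 0, l2_penalty = 0)), 0,
               tolerance = 1e-6)
  expect_equal(unname(m_step(rep(0.0325, 50), A0, 0, l2_penalty = 0)),
               log((1 - 0.0325) / 0.0325), tolerance = 1e-4)

  # analytic gradient agrees with central finite differences
  E2 <- runif(200)
  obj <- function(g) {
    p <- prior_prob(g, A)
    sum(E2 * log(p) + (1 - E2) * log(1 - p))
  }
  g <- c(1.2, -0.7)
  an_grad <- unname(drop(crossprod(A, E2 - prior_prob(g, A)))) # of -obj
  h <- 1e-6
  for (j in 1:2) {
    e <- numeric(2); e[j] <- h
    fd <- -(obj(g + e) - obj(g - e)) / (2 * h)
    expect_equal(an_grad[j], fd, tolerance = 1e-6)
  }
})

test_that("single-locus single-causal fit matches the analytic posterior", {
  set.seed(21)
  m <- 15
  z <- rnorm(m); z[4] <- 5.2
  l <- make_locus(z)
  ctl <- finemap_control(max_causals = 1, ld_ridge = 0,
                         max_em_iters = 1) # one E-step at gamma_init
  fit <- finemap(l, ctl, gamma_init = log(m - 1))
  p <- rep(1 / m, m)
  ncp <- ncp_from_z(z)
  w <- c(prod(1 - p),
         vapply(seq_len(m), function(j)
           p[j] * prod(1 - p[-j]) * exp(config_log_bf(j, z, diag(m), ncp)),
           0))
  expect_equal(fit$snp_table$posterior, (w[-1] / sum(w)), tolerance = 1e-8)
})

test_that("EM is monotone, deterministic, and order-invariant", {
  set.seed(33)
  sim <- simulate_finemap(sim_config(n_loci = 15, snps_per_locus = c(8, 15),
                                     z_mode = "mvn_direct",
                                     target_causals = 15), seed = 3)
  fit <- finemap(sim$loci)
  expect_true(fit$converged)
  # shuffling locus order changes nothing material
  fit2 <- finemap(rev(sim$loci))
  expect_equal(coef(fit2), coef(fit), tolerance = 1e-6)
  expect_equal(fit2$loglik, fit$loglik, tolerance = 1e-6)

  # loci with no annotation columns fit identically to a stripped run
  stripped <- lapply(sim$loci, function(l) {
    l$annotations <- l$annotations[, 1, drop = FALSE]
    l
  })
  f_a <- finemap(stripped)
  f_b <- finemap(lapply(sim$loci, annofine:::subset_annotations))
  expect_equal(coef(f_a), coef(f_b))
  expect_equal(f_a$loglik, f_b$loglik)
})

test_that("strengthening an annotation never hurts its top SNP", {
  set.seed(14)
  m <- 20
  ld <- random_corr(m)
  z <- rnorm(m); z[7] <- 6
  ann <- cbind(a1 = rbinom(m, 1, .3)); ann[7, 1] <- 1
  l <- make_locus(z, ld = ld, ann = ann)
  post_at <- function(g1)
    e_step(l, c(3, g1), finemap_control())$snp_post[7]
  posts <- vapply(seq(0, -3, by = -0.5), post_at, 0)
  expect_true(all(diff(posts) >= -1e-12))
})

test_that("credible sets take the minimal posterior-ranked prefix", {
  tab <- data.frame(locus_id = "L1", snp_id = paste0("s", 1:4),
                    zscore = c(5, 4, 3, 2),
                    posterior = c(0.9, 0.5, 0.4, 0.2))
  cs <- credible_set(tab, rho = 0.9)
  expect_equal(nrow(cs$members), 3)
  expect_equal(cs$mass_captured, 1.8)
  # rho -> 1 keeps every SNP with posterior mass
  cs1 <- credible_set(tab, rho = 1 - 1e-9)
  expect_equal(nrow(cs1$members), 4)

  # greedy prefix is minimal against exhaustive subset search
  set.seed(6)
  for (rep in 1:5) {
    n <- sample(6:12, 1)
    post <- runif(n)
    tab <- data.frame(locus_id = "L1", snp_id = sprintf("s%02d", 1:n),
                      zscore = rnorm(n), posterior = post)
    rho <- runif(1, .5, .95)
    cs <- credible_set(tab, rho)
    target <- rho * sum(post)
    # smallest subset cardinality achieving the target, by enumeration
    sizes <- vapply(seq_len(2^n) - 1L, function(b) {
      sel <- bitwAnd(b, 2^(seq_len(n) - 1L)) > 0
      if (sum(post[sel]) >= target - 1e-12) sum(sel) else NA_integer_
    }, 0L)
    expect_equal(nrow(cs$members), min(sizes, na.rm = TRUE))
    expect_gte(cs$mass_captured, target - 1e-12)
  }
})

test_that("per-locus credible sets normalize within each locus", {
  tab <- data.frame(locus_id = rep(c("L1", "L2"), each = 2),
                    snp_id = paste0("s", 1:4),
                    zscore = c(4, 1, 2, 1.5),
                    posterior = c(0.96, 0.04, 0.30, 0.28))
  cs <- credible_set(tab, rho = 0.9, mode = "per_locus")
  # L1 needs only its top SNP (0.96 of 1.0); L2 needs both (0.30 < 0.9 * 0.58)
  expect_setequal(cs$members$snp_id, c("s1", "s3", "s4"))
  csg <- credible_set(tab, rho = 0.9, mode = "global")
  expect_equal(nrow(csg$members), 3) # 0.96+0.30+0.28 = 1.54 >= 0.9*1.58
})
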