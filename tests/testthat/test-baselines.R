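test_that("single-causal posteriors follow the approximate Bayes factor", {
  # symmetric signal: uniform posteriors
  expect_equal(single_causal_posterior(rep(2.2, 5)), rep(0.2, 5))
  # direct formula evaluation at z = (4, 0), W = 100
  p <- single_causal_posterior(c(4, 0), W = 100)
  labf <- 16 * 100 / (2 * 101)
  expect_equal(p[1], exp(labf) / (exp(labf) + 1), tolerance = 1e-12)
  set.seed(3)
  z <- rnorm(20, sd = 2)
  expect_equal(sum(single_causal_posterior(z)), 1, tolerance = 1e-12)
  # at a single locus the ranking coincides with p-value ranking for any W
  for (W in c(1, 10, 500))
    expect_identical(order(-single_causal_posterior(z, W)),
                     order(-abs(z)))
})

test_that("p-value ranking orders by |z| with deterministic ties", {
  expect_equal(pvalue_ranking(c(1, -3, 2)), c(2L, 3L, 1L))
  expect_equal(pvalue_ranking(c(2, -2), snp_id = c("b", "a")), c(2L, 1L))
  # agrees with two-sided p-value ascending
  set.seed(1)
  z <- rnorm(30)
  expect_equal(pvalue_ranking(z), order(2 * pnorm(-abs(z))))
})

test_that("iterative conditioning ranks by order of model entry", {
  set.seed(42)
  N <- 800
  G <- matrix(rnorm(N * 6), N, 6)
  G <- qr.Q(qr(G)) * sqrt(N) # exactly orthogonal columns
  y <- 0.3 * G[, 2] + 0.2 * G[, 5] + rnorm(N)
  # orthogonal SNPs: same order as marginal ranking
  expect_equal(conditional_ranking(G, y),
               pvalue_ranking(abs(drop(cor(G, y)))))

  # a perfect duplicate never adds signal and enters at exhaustion
  G2 <- cbind(G[, 1:3], G[, 2])
  y2 <- 0.5 * G2[, 2] + rnorm(N, sd = 0.5)
  r <- conditional_ranking(G2, y2)
  expect_equal(r[1], 2L)
  expect_equal(r[4], 4L) # the clone comes last

  # LD-confounded pair: conditioning recovers both planted causals early
  L <- chol(matrix(c(1, .9, .9, 1), 2))
  X <- matrix(rnorm(N * 2), N, 2) %*% L
  G3 <- cbind(X[, 1], X[, 2], matrix(rnorm(N * 3), N, 3))
  y3 <- 0.5 * G3[, 1] - 0.45 * G3[, 2] + rnorm(N, sd = 0.3)
  expect_setequal(conditional_ranking(G3, y3)[1:2], c(1L, 2L))
})

test_that("ranking curves measure recall per SNPs selected per locus", {
  truth <- data.frame(
    locus_id = rep(c("L1", "L2", "L3"), each = 4),
    snp_id = paste0("s", 1:12),
    causal = c(1, 0, 0, 0, 1, 1, 0, 0, 0, 0, 0, 0))
  # oracle scores: the truth itself
  scores <- transform(truth, score = causal + (12:1) * 1e-4)
  cur <- ranking_curve(scores[, c("locus_id", "snp_id", "score")], truth)
  # only the 2 causal loci retained; 3 causals found within 3 picks
  expect_equal(cur$n_loci, 2)
  expect_equal(cur$points$recall[3], 1)
  expect_equal(unname(threshold_at(cur, 1.0)), 3 / 2)
  # recall never decreases and PPV is a fraction
  expect_true(all(diff(cur$points$recall) >= 0))
  expect_true(all(cur$points$ppv <= 1 & cur$points$ppv >= 0))

  # when a zero-causal locus harbours high-scoring distractors,
  # restricting to causal loci improves recall at fixed SNPs/locus
  scores2 <- scores
  scores2$score <- c(1, .1, .1, .1, .9, .88, .1, .1, .95, .94, .93, .92)
  cur_res <- ranking_curve(scores2[, c("locus_id", "snp_id", "score")], truth)
  cur_all <- ranking_curve(scores2[, c("locus_id", "snp_id", "score")],
                           truth, restrict_to_causal_loci = FALSE)
  for (x in c(1, 2)) {
    r_res <- max(cur_res$points$recall[cur_res$points$snps_per_locus <= x], 0)
    r_all <- max(cur_all$points$recall[cur_all$points$snps_per_locus <= x], 0)
    expect_gte(r_res, r_all)
  }

  # random scores track the diagonal in expectation
  set.seed(8)
  n <- 40
  truth2 <- data.frame(locus_id = "L1", snp_id = sprintf("s%02d", 1:n),
                       causal = rep(c(1, 0), c(8, n - 8)))
  rec_half <- replicate(300, {
    sc <- transform(truth2, score = runif(n))
    cur <- ranking_curve(sc[, c("locus_id", "snp_id", "score")], truth2)
    cur$points$recall[n / 2]
  })
  expect_equal(mean(rec_half), 0.5, tolerance = 0.03)
})

test_that("per-locus interleaving takes each locus's best SNPs first", {
  truth <- data.frame(locus_id = rep(c("L1", "L2"), each = 3),
                      snp_id = paste0("s", 1:6),
                      causal = c(0, 0, 1, 1, 0, 0))
  scores <- data.frame(locus_id = truth$locus_id, snp_id = truth$snp_id,
                       score = c(.9, .8, .7, .3, .2, .1))
  cur <- ranking_curve(scores, truth, mode = "per_locus")
  # ranks 1 of both loci precede rank 2 of any locus: s4 (causal, rank 1
  # of L2) is found within the first two selections even though its score
  # is below every L1 score
  expect_equal(cur$points$recall[2], 0.5)
  cur_across <- ranking_curve(scores, truth, mode = "across_loci")
  expect_equal(cur_across$points$recall[2], 0)
})

test_that("utility curves are maximized at the posterior threshold C/B", {
  uc <- utility_curve(c(0.9, 0.2), B = 1, C = 0.5)
  expect_equal(uc$argmax$n_selected, 1)
  expect_equal(uc$argmax$utility, 0.4)

  # expectation mode: argmax set equals {posterior > C/B}, verified by
  # exhaustive subset search
  set.seed(17)
  for (rep in 1:5) {
    n <- sample(8:15, 1)
    post <- round(runif(n), 3)
    B <- runif(1, 1, 5); C <- runif(1, 0.05, 0.9)
    uc <- utility_curve(post, B, C)
    expect_setequal(uc$selected, which(post > C / B))
    # exhaustive: no subset beats the threshold set
    best <- max(vapply(seq_len(2^n) - 1L, function(b) {
      sel <- bitwAnd(b, 2^(seq_len(n) - 1L)) > 0
      B * sum(post[sel]) - C * sum(sel)
    }, 0))
    expect_equal(uc$argmax$utility, best, tolerance = 1e-10)
  }

  # vanishing cost selects everything with posterior mass
  uc0 <- utility_curve(c(.5, .01, 0), B = 1, C = 1e-9)
  expect_equal(sort(uc0$selected), 1:2)

  # simulation mode counts true causals
  uc_t <- utility_curve(c(.9, .8, .1), B = 2, C = 0.5, truth = c(1, 0, 1))
  expect_equal(uc_t$points$utility, c(0, 1.5, 1, 2.5))
})

test_that("localization distances are measured to the nearest causal", {
  scores <- data.frame(locus_id = "L1", snp_id = paste0("s", 1:5),
                       pos = c(100L, 500L, 900L, 1500L, 2000L),
                       score = c(.1, .9, .8, .2, .05))
  truth <- data.frame(locus_id = "L1", snp_id = paste0("s", 1:5),
                      causal = c(0, 1, 0, 0, 0))
  # the causal itself is ranked first: distance 0; N = 1 median == min
  d1 <- localization_distance(scores, truth, top_n = 1)
  expect_equal(d1$min_bp, 0)
  expect_equal(d1$median_bp, d1$min_bp)

  d2 <- localization_distance(scores, truth, top_n = 2)
  expect_equal(d2$min_bp, 0)
  expect_equal(d2$median_bp, 200) # distances 0 and 400

  # masked causals: the causal SNP cannot be selected but remains the target
  dm <- localization_distance(scores, truth, top_n = 1, mask_causals = TRUE)
  expect_equal(dm$min_bp, 400) # top non-causal is s3 at 900
})
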