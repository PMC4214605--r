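#' Simulation configuration
#'
#' Describes a synthetic fine-mapping study. Defaults emulate the standard
#' regime of the simulation framework: 100 loci, ~10 Kb scale with a few
#' dozen common SNPs each, one synthetic functional annotation covering
#' 1/3 of SNPs, logistic prior coefficients (4.62, -2.15) (8-fold causal
#' enrichment, about one expected causal per locus at ~31 SNPs/locus),
#' N = 10,000 individuals and total variance explained 0.25 split equally
#' among causal SNPs.
#'
#' @param n_loci number of loci.
#' @param snps_per_locus integer scalar, or length-2 range sampled
#'   uniformly per locus.
#' @param ld_source `"ar1"` (correlation `ar1_rho^|j-k|`), `"block"`
#'   (blocks of size `block_size` with within-block correlation
#'   `block_r`), or `"haplotype_file"` (Pearson LD of supplied
#'   haplotypes).
#' @param ar1_rho,block_size,block_r LD shape parameters.
#' @param haplotypes optional 2N x m 0/1 matrix for
#'   `ld_source = "haplotype_file"`.
#' @param annotation_spec data.frame with columns `name`, `fraction`, and
#'   logical `contiguous` (contiguous block vs random assignment).
#' @param gamma_true generating logistic coefficients (baseline first),
#'   aligned to `c("baseline", annotation_spec$name)`.
#' @param target_causals if non-`NULL`, the baseline coefficient is
#'   recalibrated per replicate (annotation coefficients fixed) so the
#'   expected total number of causal SNPs equals this value.
#' @param n_individuals sample size for genotype-based Z-scores.
#' @param h2 total phenotypic variance explained by the causal SNPs of
#'   all loci jointly.
#' @param effect_model `"equal_split"` (variance divided equally among
#'   causals) or `"gamma_distributed"` (heterogeneous effects drawn from a
#'   unit-shape gamma, rescaled to `h2`).
#' @param z_mode `"genotype_ols"` (simulate genotypes and phenotype, Wald
#'   Z by marginal OLS) or `"mvn_direct"` (draw Z from
#'   MVN(LD %*% lambda_c, LD) with causal NCPs ~ N(`mvn_ncp_mean`,
#'   `mvn_ncp_sd`), the route used for large loci).
#' @param mvn_ncp_mean,mvn_ncp_sd NCP distribution for `"mvn_direct"`.
#' @param maf_min minimum minor-allele frequency of simulated SNPs.
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(n_loci = 100L, snps_per_locus = c(25L, 60L),
                       ld_source = c("ar1", "block", "haplotype_file"),
                       ar1_rho = 0.9, block_size = 10L, block_r = 0.8,
                       haplotypes = NULL,
                       annotation_spec = data.frame(
                         name = "functional", fraction = 1 / 3,
                         contiguous = FALSE, stringsAsFactors = FALSE),
                       gamma_true = c(4.62, -2.15),
                       target_causals = NULL,
                       n_individuals = 10000L, h2 = 0.25,
                       effect_model = c("equal_split", "gamma_distributed"),
                       z_mode = c("genotype_ols", "mvn_direct"),
                       mvn_ncp_mean = 5, mvn_ncp_sd = 0.2,
                       maf_min = 0.01) {
  ld_source <- match.arg(ld_source)
  effect_model <- match.arg(effect_model)
  z_mode <- match.arg(z_mode)
  if (is.null(annotation_spec)) {
    annotation_spec <- data.frame(name = character(0), fraction = numeric(0),
                                  contiguous = logical(0))
  }
  annotation_spec <- as.data.frame(annotation_spec)
  if (nrow(annotation_spec)) {
    stopifnot(all(annotation_spec$fraction > 0),
              all(annotation_spec$fraction < 1))
    if (is.null(annotation_spec$contiguous))
      annotation_spec$contiguous <- FALSE
  }
  stopifnot(h2 >= 0, h2 < 1, n_loci >= 1,
            length(gamma_true) == nrow(annotation_spec) + 1L,
            maf_min > 0, maf_min < 0.5)
  structure(list(n_loci = as.integer(n_loci),
                 snps_per_locus = as.integer(snps_per_locus),
                 ld_source = ld_source, ar1_rho = ar1_rho,
                 block_size = as.integer(block_size), block_r = block_r,
                 haplotypes = haplotypes,
                 annotation_spec = annotation_spec,
                 gamma_true = as.numeric(gamma_true),
                 target_causals = target_causals,
                 n_individuals = as.integer(n_individuals), h2 = h2,
                 effect_model = effect_model, z_mode = z_mode,
                 mvn_ncp_mean = mvn_ncp_mean, mvn_ncp_sd = mvn_ncp_sd,
                 maf_min = maf_min),
            class = "sim_config")
}

#' Calibrate the baseline coefficient for a target causal count
#'
#' Solves, by monotone bisection, for the baseline coefficient `gamma0`
#' such that the expected total number of causal SNPs
#' `sum_ij 1 / (1 + exp(gamma0 + gamma_annot' a_ij))` equals
#' `target`, with the annotation coefficients held fixed.
#'
#' @param target desired expected number of causal SNPs (> 0, < total
#'   SNPs).
#' @param annotation_list list of per-locus annotation matrices (baseline
#'   column first), or a single stacked matrix.
#' @param gamma_annot annotation coefficients (without the baseline).
#' @param tol bisection tolerance on the expected count.
#' @return The calibrated `gamma0`.
#' @export
calibrate_gamma0 <- function(target, annotation_list, gamma_annot = numeric(0),
                             tol = 1e-6) {
  A <- if (is.list(annotation_list)) do.call(rbind, annotation_list)
       else as.matrix(annotation_list)
  offs <- if (length(gamma_annot))
    drop(A[, -1L, drop = FALSE] %*% gamma_annot) else rep(0, nrow(A))
  if (target <= 0 || target >= nrow(A))
    stop("target expected causal count must lie in (0, ", nrow(A), ")")
  f <- function(g0) sum(plogis(-(g0 + offs))) - target
  lo <- -50; hi <- 50
  if (f(lo) < 0 || f(hi) > 0) stop("no root in bounds [-50, 50]")
  while (hi - lo > 1e-12 && abs(f((lo + hi) / 2)) > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Generating coefficients for a given log2 enrichment
#'
#' For a single annotation covering a known fraction of SNPs, returns the
#' logistic coefficients `(gamma0, gamma1)` such that the prior causal
#' probability is exactly `2^log2_enrichment`-fold higher inside the
#' annotation than outside, while the expected total causal count equals
#' `target` over `n_snps` SNPs.
#'
#' @param log2_enrichment desired log2 ratio of prior probabilities.
#' @param fraction fraction of SNPs annotated.
#' @param n_snps total SNP count.
#' @param target expected total causal count.
#' @return Numeric `c(gamma0, gamma1)`.
#' @export
enrichment_gamma <- function(log2_enrichment, fraction = 1 / 3,
                             n_snps = 3100, target = 100) {
  r <- 2^log2_enrichment
  p_mean <- target / n_snps
  p_out <- p_mean / ((1 - fraction) + fraction * r)
  p_in <- r * p_out
  stopifnot(p_in < 1, p_out < 1)
  g0 <- log((1 - p_out) / p_out)
  c(g0, log((1 - p_in) / p_in) - g0)
}

#' Simulate an LD matrix
#'
#' `"ar1"`: `Sigma[j,k] = ar1_rho^|j-k|`; `"block"`: constant `block_r`
#' within consecutive blocks of `block_size` SNPs, 0 between;
#' `"haplotype_file"`: Pearson correlation of supplied 0/1 haplotypes
#' after filtering SNPs below `maf_min` (at least 2 haplotypes required).
#' Diagonals are always 1.
#'
#' @param m number of SNPs (ignored for `"haplotype_file"`).
#' @param config a [sim_config()] (its LD fields are used).
#' @return Correlation matrix; for `"haplotype_file"`, a matrix with
#'   attribute `"kept"` giving the retained SNP columns.
#' @export
simulate_ld <- function(m, config = sim_config()) {
  switch(config$ld_source,
    ar1 = config$ar1_rho^abs(outer(seq_len(m), seq_len(m), "-")),
    block = {
      blk <- rep(seq_len(ceiling(m / config$block_size)),
                 each = config$block_size)[seq_len(m)]
      out <- outer(blk, blk, "==") * config$block_r
      diag(out) <- 1
      out
    },
    haplotype_file = {
      H <- config$haplotypes
      if (is.null(H) || nrow(H) < 2L)
        stop("haplotype_file LD requires a haplotype matrix with >= 2 rows")
      maf <- pmin(colMeans(H), 1 - colMeans(H))
      kept <- which(maf >= config$maf_min)
      if (length(kept) < 2L) stop("fewer than 2 SNPs pass the MAF filter")
      structure(compute_ld(H[, kept, drop = FALSE]), kept = kept)
    })
}

## Correlated 0/1 haplotypes via a Gaussian copula: latent AR1/block
## Gaussians thresholded at the MAF quantile per SNP. Realized LD is the
## genotype correlation, not the latent one.
simulate_haplotypes <- function(n_hap, m, config, maf) {
  sigma <- simulate_ld(m, config)
  U <- chol(regularize_ld(sigma, 1e-8))
  X <- matrix(rnorm(n_hap * m), n_hap, m) %*% U
  H <- sweep(X, 2L, qnorm(maf), "<") * 1
  ## guard against monomorphic columns (negligible at large n_hap)
  mono <- which(colSums(H) == 0 | colSums(H) == n_hap)
  for (j in mono) H[sample.int(n_hap, 2L), j] <- c(0, 1)
  H
}

#' Draw causal indicators from the logistic prior
#'
#' Independent Bernoulli draws with per-SNP probabilities
#' `prior_prob(gamma_true, annotations)`.
#'
#' @param annotations m x (K+1) binary matrix (baseline first).
#' @param gamma_true generating coefficients.
#' @return Integer 0/1 vector of causal indicators.
#' @export
draw_causals <- function(annotations, gamma_true) {
  p <- prior_prob(gamma_true, annotations)
  rbinom(nrow(annotations), 1L, p)
}

#' Simulate a phenotype and marginal Wald Z-scores
#'
#' Standardizes the genotype columns, assigns each causal SNP an effect on
#' the standardized scale — `+/- sqrt(h2_locus / n_causal)` under
#' `"equal_split"`, or gamma-distributed magnitudes rescaled so the
#' aggregate variance equals `h2_locus` under `"gamma_distributed"` —
#' draws the phenotype with residual variance `1 - h2_total`, and returns
#' the per-SNP marginal OLS Wald statistics.
#'
#' @param genotypes N x m dosage matrix.
#' @param causals integer indices of causal SNPs (possibly empty).
#' @param h2_locus variance explained by this locus's causals.
#' @param h2_total total variance explained across all loci (sets the
#'   residual variance; defaults to `h2_locus`).
#' @param effect_model `"equal_split"` or `"gamma_distributed"`.
#' @return List: `z` (Wald statistics), `beta` (standardized effects, 0
#'   for non-causal SNPs), `phenotype`.
#' @export
simulate_phenotype_z <- function(genotypes, causals, h2_locus,
                                 h2_total = h2_locus,
                                 effect_model = "equal_split") {
  if (h2_total >= 1) stop("h2 must be < 1")
  G <- scale(as.matrix(genotypes))
  N <- nrow(G); m <- ncol(G)
  beta <- numeric(m)
  if (length(causals) && h2_locus > 0) {
    nc <- length(causals)
    mag <- if (effect_model == "equal_split") rep(sqrt(h2_locus / nc), nc)
           else {
             raw <- stats::rgamma(nc, shape = 1)
             raw * sqrt(h2_locus / sum(raw^2))
           }
    beta[causals] <- mag * sample(c(-1, 1), nc, replace = TRUE)
  }
  y <- drop(G %*% beta) + rnorm(N, sd = sqrt(1 - h2_total))
  r <- drop(cor(G, y))
  z <- r * sqrt((N - 2) / pmax(1 - r^2, .Machine$double.eps))
  list(z = z, beta = beta, phenotype = y)
}

#' Draw Z-scores directly from the multivariate normal model
#'
#' `z ~ MVN(Sigma lambda_c, Sigma)` where `lambda_c` holds NCPs drawn
#' from N(`ncp_mean`, `ncp_sd`) at causal sites and 0 elsewhere — the
#' summary-level route used when simulating genotypes is impractical.
#'
#' @param ld positive-definite LD matrix.
#' @param causals integer causal indices (possibly empty).
#' @param ncp_mean,ncp_sd NCP distribution at causal sites.
#' @return List: `z`, `lambda` (the drawn NCP vector).
#' @export
simulate_z_direct <- function(ld, causals, ncp_mean = 5, ncp_sd = 0.2) {
  m <- nrow(ld)
  lam <- numeric(m)
  if (length(causals))
    lam[causals] <- rnorm(length(causals), ncp_mean, ncp_sd)
  U <- chol(ld)
  z <- drop(ld %*% lam) + drop(crossprod(U, rnorm(m)))
  list(z = z, lambda = lam)
}

## build one locus's annotation matrix from the spec
build_annotations <- function(m, spec) {
  A <- matrix(1, m, 1L, dimnames = list(NULL, "baseline"))
  if (!nrow(spec)) return(A)
  cols <- vapply(seq_len(nrow(spec)), function(i) {
    n_in <- max(1L, round(spec$fraction[i] * m))
    v <- numeric(m)
    if (spec$contiguous[i]) {
      s <- sample.int(m - n_in + 1L, 1L)
      v[s:(s + n_in - 1L)] <- 1
    } else v[sample.int(m, n_in)] <- 1
    v
  }, numeric(m))
  cbind(A, matrix(cols, m, dimnames = list(NULL, spec$name)))
}

#' Simulate a complete fine-mapping data set
#'
#' Generates `n_loci` loci with LD, annotations, causal indicators drawn
#' from the logistic prior, and Z-scores (via genotypes and a phenotype,
#' or directly from the MVN model), plus the ground truth. All randomness
#' derives from `seed` through per-stage substreams (layout/LD,
#' annotations, causal draws, effects/noise).
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return List of class `"sim_data"`: `loci` (list of [locus()]),
#'   `truth` (data.frame `locus_id`, `snp_id`, `causal`, `beta`),
#'   `gamma_used`, `config`, `seed`.
#' @export
simulate_finemap <- function(config = sim_config(), seed = 1L) {
  set.seed(seed)
  stage_seed <- sample.int(.Machine$integer.max - 1L, 4L)
  spec <- config$annotation_spec
  L <- config$n_loci

  ## stage 1: locus sizes, LD / genotypes
  set.seed(stage_seed[1L])
  spl <- config$snps_per_locus
  m_l <- if (length(spl) == 1L) rep(spl, L) else
    sample(seq(spl[1L], spl[2L]), L, replace = TRUE)
  genotypes <- vector("list", L)
  lds <- vector("list", L)
  for (i in seq_len(L)) {
    if (config$z_mode == "genotype_ols") {
      maf <- runif(m_l[i], config$maf_min, 0.5)
      H <- simulate_haplotypes(2L * config$n_individuals, m_l[i], config, maf)
      G <- H[seq_len(config$n_individuals), ] +
        H[config$n_individuals + seq_len(config$n_individuals), ]
      genotypes[[i]] <- G
      lds[[i]] <- compute_ld(G)
    } else {
      lds[[i]] <- regularize_ld(simulate_ld(m_l[i], config), 1e-8)
    }
  }

  ## stage 2: annotations
  set.seed(stage_seed[2L])
  anns <- lapply(m_l, build_annotations, spec = spec)

  ## stage 3: causal status (with optional baseline recalibration)
  set.seed(stage_seed[3L])
  gamma_used <- config$gamma_true
  if (!is.null(config$target_causals))
    gamma_used[1L] <- calibrate_gamma0(config$target_causals, anns,
                                       gamma_used[-1L])
  causal <- lapply(anns, draw_causals, gamma_true = gamma_used)

  ## stage 4: effects, phenotype / Z draws
  set.seed(stage_seed[4L])
  n_causal_tot <- sum(unlist(causal))
  loci <- vector("list", L)
  truth <- vector("list", L)
  for (i in seq_len(L)) {
    cs <- which(causal[[i]] == 1L)
    beta <- numeric(m_l[i])
    if (config$z_mode == "genotype_ols") {
      ## variance is split equally across all causal SNPs of the study,
      ## so this locus explains h2 * (its causal share); the remaining
      ## loci's contribution is independent of local genotypes and is
      ## absorbed into the residual
      h2_locus <- if (n_causal_tot > 0)
        config$h2 * length(cs) / n_causal_tot else 0
      sim <- simulate_phenotype_z(genotypes[[i]], cs, h2_locus,
                                  h2_total = h2_locus,
                                  effect_model = config$effect_model)
      z <- sim$z
      beta <- sim$beta
    } else {
      sim <- simulate_z_direct(lds[[i]], cs, config$mvn_ncp_mean,
                               config$mvn_ncp_sd)
      z <- sim$z
      beta <- sim$lambda
    }
    id <- sprintf("locus%03d", i)
    snp_id <- sprintf("%s_snp%03d", id, seq_len(m_l[i]))
    snps <- data.frame(snp_id = snp_id, chrom = as.character(i),
                       pos = seq_len(m_l[i]) * 250L, zscore = z,
                       stringsAsFactors = FALSE)
    loci[[i]] <- locus(id, snps, lds[[i]], anns[[i]])
    truth[[i]] <- data.frame(locus_id = id, snp_id = snp_id,
                             causal = causal[[i]], beta = beta,
                             stringsAsFactors = FALSE)
  }
  structure(list(loci = loci, truth = do.call(rbind, truth),
                 gamma_used = gamma_used, config = config, seed = seed),
            class = "sim_data")
}

#' @export
print.sim_data <- function(x, ...) {
  cat("<sim_data> ", length(x$loci), " loci, ", nrow(x$truth), " SNPs, ",
      sum(x$truth$causal), " causal (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Write a simulated data set to disk
#'
#' One file triplet per locus in the [read_locus()] dialect, a truth
#' table, and a list file enumerating the triplets (consumed by the
#' command-line `fit`).
#'
#' @param sim a `"sim_data"` object.
#' @param dir output directory (created if needed).
#' @return Invisibly, the list-file path.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- vapply(sim$loci, function(l) {
    zf <- file.path(dir, paste0(l$locus_id, ".snps"))
    lf <- file.path(dir, paste0(l$locus_id, ".ld"))
    af <- file.path(dir, paste0(l$locus_id, ".annot"))
    write_locus(l, zf, lf, af)
    paste(zf, lf, if (ncol(l$annotations) > 1L) af else "-", sep = "\t")
  }, "")
  listfile <- file.path(dir, "loci.list")
  writeLines(rows, listfile)
  write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(listfile)
}
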