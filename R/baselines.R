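#' Single-causal posterior probabilities from Z-scores
#'
#' Approximate per-SNP Bayes factor on the Z scale under a normal prior
#' with variance `W` on the (squared) non-centrality:
#' `ABF_j = sqrt(1 / (1 + W)) * exp(z_j^2 W / (2 (1 + W)))`, converted to
#' posteriors by normalizing within the locus under the assumption of
#' exactly one causal variant with a uniform prior. At a single locus this
#' ranking coincides with p-value ranking for any `W`.
#'
#' @param z Z-score vector for one locus.
#' @param W prior variance (default 10).
#' @return Posterior probabilities summing to 1.
#' @export
single_causal_posterior <- function(z, W = 10) {
  stopifnot(W > 0)
  labf <- 0.5 * log(1 / (1 + W)) + z^2 * W / (2 * (1 + W))
  mx <- max(labf)
  exp(labf - mx) / sum(exp(labf - mx))
}

#' Rank SNPs by marginal association
#'
#' Order of decreasing |Z| (equivalently increasing two-sided p-value);
#' ties broken by SNP id.
#'
#' @param z Z-score vector.
#' @param snp_id optional ids for tie-breaking (default positional).
#' @return Integer permutation: `ranking[1]` is the top SNP's index.
#' @export
pvalue_ranking <- function(z, snp_id = NULL) {
  if (is.null(snp_id)) snp_id <- sprintf("s%06d", seq_along(z))
  order(-abs(z), snp_id, method = "radix")
}

#' Iterative-conditioning ranking from individual-level data
#'
#' Forward stepwise marginal regression: at each step the SNP most
#' strongly associated with the phenotype given the previously selected
#' SNPs (as covariates) enters the model; the order of entry is the
#' ranking. SNPs that become collinear with the selected set are appended
#' at the end by marginal |Z|.
#'
#' @param genotypes N x m dosage matrix.
#' @param phenotype length-N response.
#' @param tol residual-variance threshold below which a SNP is treated as
#'   collinear with the selected set.
#' @return Integer permutation (order of entry).
#' @export
conditional_ranking <- function(genotypes, phenotype, tol = 1e-8) {
  G <- scale(as.matrix(genotypes))
  y <- as.numeric(scale(phenotype))
  N <- nrow(G); m <- ncol(G)
  z_marg <- abs(drop(cor(G, y))) # for the exhaustion stage
  Rg <- G; ry <- y
  active <- rep(TRUE, m)
  entered <- integer(0)
  while (any(active)) {
    v <- colSums(Rg^2)
    collinear <- active & v < tol * N
    active[collinear] <- FALSE
    if (!any(active)) break
    sc <- rep(-Inf, m)
    idx <- which(active)
    r <- abs(colSums(Rg[, idx, drop = FALSE] * ry)) /
      sqrt(v[idx] * sum(ry^2))
    sc[idx] <- r
    j <- which.max(sc)
    entered <- c(entered, j)
    active[j] <- FALSE
    ## orthogonalize the remainder and the response against SNP j
    u <- Rg[, j] / sqrt(v[j])
    ry <- ry - u * sum(u * ry)
    rest <- which(active)
    if (length(rest))
      Rg[, rest] <- Rg[, rest, drop = FALSE] -
        u %*% crossprod(u, Rg[, rest, drop = FALSE])
  }
  leftover <- setdiff(seq_len(m), entered)
  c(entered, leftover[order(-z_marg[leftover], leftover)])
}

#' Recall curve of a SNP prioritization
#'
#' Proportion of true causal SNPs identified as a function of the average
#' number of SNPs selected per locus, optionally restricted to loci
#' containing at least one causal variant. `"across_loci"` ranks all SNPs
#' by score globally; `"per_locus"` first ranks within each locus and then
#' interleaves loci by within-locus rank (score as secondary key).
#'
#' @param scores data.frame with columns `locus_id`, `snp_id`, `score`,
#'   and optionally `zscore` for tie-breaking.
#' @param truth data.frame with columns `locus_id`, `snp_id`, `causal`.
#' @param mode `"across_loci"` or `"per_locus"`.
#' @param restrict_to_causal_loci drop loci without causal variants before
#'   ranking (the default, matching how accuracy is usually assessed).
#' @return Object of class `"ranking_curve"`: `points` (data.frame
#'   `n_selected`, `snps_per_locus`, `recall`, `ppv`), `n_loci`,
#'   `n_causals`, plus `snps_per_locus_at()` via [threshold_at()].
#' @export
ranking_curve <- function(scores, truth,
                          mode = c("across_loci", "per_locus"),
                          restrict_to_causal_loci = TRUE) {
  mode <- match.arg(mode)
  d <- merge(as.data.frame(scores), as.data.frame(truth),
             by = c("locus_id", "snp_id"))
  if (nrow(d) != nrow(scores))
    stop("scores and truth tables do not align")
  if (restrict_to_causal_loci) {
    keep <- names(which(vapply(split(d$causal, d$locus_id), sum, 0) > 0))
    d <- d[d$locus_id %in% keep, , drop = FALSE]
  }
  if (!nrow(d)) stop("no loci left to evaluate")
  if (is.null(d$zscore)) d$zscore <- d$score
  L <- length(unique(d$locus_id))
  if (mode == "across_loci") {
    o <- order(-d$score, -abs(d$zscore), d$snp_id, method = "radix")
  } else {
    within_rank <- integer(nrow(d))
    for (ix in split(seq_len(nrow(d)), d$locus_id)) {
      o_l <- order(-d$score[ix], -abs(d$zscore[ix]), d$snp_id[ix],
                   method = "radix")
      within_rank[ix[o_l]] <- seq_along(ix)
    }
    o <- order(within_rank, -d$score, d$snp_id, method = "radix")
  }
  hit <- cumsum(d$causal[o])
  n_sel <- seq_len(nrow(d))
  points <- data.frame(n_selected = n_sel, snps_per_locus = n_sel / L,
                       recall = hit / sum(d$causal), ppv = hit / n_sel)
  structure(list(points = points, mode = mode, n_loci = L,
                 n_causals = sum(d$causal),
                 restricted = restrict_to_causal_loci),
            class = "ranking_curve")
}

#' SNPs per locus needed to reach a recall level
#'
#' @param curve a [ranking_curve()].
#' @param recall target recall level(s), e.g. `c(0.5, 0.9)`.
#' @return Named numeric vector of `snps_per_locus` at the first point
#'   reaching each level (`NA` if never reached).
#' @export
threshold_at <- function(curve, recall = c(0.5, 0.9)) {
  stopifnot(inherits(curve, "ranking_curve"))
  vapply(setNames(recall, paste0("recall_", recall)), function(r) {
    i <- which(curve$points$recall >= r - 1e-12)[1L]
    if (is.na(i)) NA_real_ else curve$points$snps_per_locus[i]
  }, 0)
}

#' @export
print.ranking_curve <- function(x, ...) {
  th <- threshold_at(x)
  cat("<ranking_curve> ", x$mode, ", ", x$n_loci, " loci, ", x$n_causals,
      " causals; SNPs/locus at 50%/90% recall: ",
      paste(format(th, digits = 4), collapse = " / "), "\n", sep = "")
  invisible(x)
}

#' @export
plot.ranking_curve <- function(x, ...) {
  graphics::plot(x$points$snps_per_locus, x$points$recall, type = "l",
                 xlab = "SNPs selected per locus",
                 ylab = "proportion of causals identified",
                 ylim = c(0, 1), ...)
  invisible(x)
}

#' Benefit-to-cost utility of follow-up selection
#'
#' Utility `U = B * Nc - C * Nt` of validating the top `Nt` SNPs by score,
#' where `Nc` is the number of true causals among them (simulation mode,
#' when `truth` is given) or the expected number, i.e. the sum of their
#' posteriors (expectation mode). In expectation mode the maximizing set
#' is exactly the SNPs with posterior above `C / B = 1 / R`.
#'
#' @param posterior per-SNP scores (posterior probabilities).
#' @param B,C benefit per causal found and cost per SNP tested (both
#'   > 0).
#' @param truth optional 0/1 causal indicators aligned with `posterior`.
#' @param snp_id,z optional tie-breaking keys.
#' @return Object of class `"utility_curve"`: `points` (`n_selected`,
#'   `utility`, `causals`), `argmax` (row at maximum utility, first
#'   maximum on ties), `selected` (indices selected at the argmax),
#'   `ratio_R`, `mode`.
#' @export
utility_curve <- function(posterior, B, C, truth = NULL, snp_id = NULL,
                          z = NULL) {
  stopifnot(B > 0, C > 0)
  n <- length(posterior)
  if (is.null(snp_id)) snp_id <- sprintf("s%06d", seq_len(n))
  if (is.null(z)) z <- posterior
  o <- rank_order(posterior, z, snp_id)
  nc <- if (is.null(truth)) cumsum(posterior[o]) else cumsum(truth[o])
  u <- B * nc - C * seq_len(n)
  points <- data.frame(n_selected = 0:n, utility = c(0, u),
                       causals = c(0, nc))
  i_max <- which.max(points$utility)
  structure(list(points = points, argmax = points[i_max, ],
                 selected = if (i_max > 1L) o[seq_len(i_max - 1L)]
                            else integer(0),
                 ratio_R = B / C,
                 mode = if (is.null(truth)) "expectation" else "simulation"),
            class = "utility_curve")
}

#' @export
print.utility_curve <- function(x, ...) {
  cat(sprintf("<utility_curve> R = %.3g (%s mode): max utility %.3f at %d SNPs (%.2f causals)\n",
              x$ratio_R, x$mode, x$argmax$utility, x$argmax$n_selected,
              x$argmax$causals))
  invisible(x)
}

#' Distance from prioritized SNPs to the nearest causal variant
#'
#' For each locus, takes the `top_n` highest-scoring SNPs and reports the
#' median and minimum base-pair distance to the closest true causal
#' variant. With `mask_causals = TRUE` the causal SNPs themselves are
#' removed from the ranking before selection (the causal positions remain
#' the distance targets), emulating panels from which the causal variant
#' is absent.
#'
#' @param scores data.frame with `locus_id`, `snp_id`, `pos`, `score`.
#' @param truth data.frame with `locus_id`, `snp_id`, `causal` (and
#'   positions via `scores`).
#' @param top_n number of SNPs per locus to consider.
#' @param mask_causals drop causal SNPs from the candidate ranking.
#' @return data.frame per causal locus: `locus_id`, `median_bp`, `min_bp`.
#' @export
localization_distance <- function(scores, truth, top_n = 1L,
                                  mask_causals = FALSE) {
  d <- merge(as.data.frame(scores), as.data.frame(truth),
             by = c("locus_id", "snp_id"))
  out <- lapply(split(d, d$locus_id), function(dd) {
    cpos <- dd$pos[dd$causal == 1]
    if (!length(cpos)) return(NULL)
    cand <- if (mask_causals) dd[dd$causal == 0, , drop = FALSE] else dd
    if (!nrow(cand)) return(NULL)
    o <- order(-cand$score, cand$snp_id, method = "radix")
    top <- cand$pos[o][seq_len(min(top_n, nrow(cand)))]
    dist <- vapply(top, function(p) min(abs(p - cpos)), 0)
    data.frame(locus_id = dd$locus_id[1L], median_bp = median(dist),
               min_bp = min(dist), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  rownames(out) <- NULL
  out
}
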