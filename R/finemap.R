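#' E-step: posterior over causal configurations at one locus
#'
#' Applies Bayes' theorem over the enumerated configuration space:
#' `P(c | z)` is proportional to `exp(log BF(c) + log prior(c))`,
#' normalized over all configurations with at most `max_causals` causal
#' SNPs. Per-SNP marginal posteriors sum the configuration posteriors over
#' configurations containing each SNP.
#'
#' @param x a [locus()] object.
#' @param gamma annotation coefficient vector (baseline first).
#' @param control a [finemap_control()].
#' @return List of class `"locus_posterior"`: `configs` (list of integer
#'   index vectors), `config_post` (matching probabilities summing to 1),
#'   `snp_post`, `loglik`, `locus_id`.
#' @export
e_step <- function(x, gamma, control = finemap_control()) {
  prep <- locus_prep(x, control)
  res <- e_step_prep(prep, gamma)
  configs <- c(list(integer(0)),
               unlist(lapply(prep$idx, function(idx)
                 lapply(seq_len(ncol(idx)), function(j) idx[, j])),
                 recursive = FALSE))
  structure(list(locus_id = x$locus_id, configs = configs,
                 config_post = unlist(res$config_w, use.names = FALSE),
                 snp_post = res$snp_post, loglik = res$loglik),
            class = "locus_posterior")
}

#' M-step: refit annotation coefficients from soft labels
#'
#' Maximizes the expected complete-data log-likelihood
#' `sum_ij E_ij log p_ij(gamma) + (1 - E_ij) log(1 - p_ij(gamma))` where
#' `E_ij` are the current per-SNP posteriors — a logistic regression with
#' soft labels, concave in `gamma`, optimized by L-BFGS-B with an analytic
#' gradient. A small L2 penalty (see [finemap_control()]) stabilizes
#' separable cases.
#'
#' @param snp_post numeric vector of per-SNP posteriors, stacked across
#'   loci in the same order as the rows of `annotations`.
#' @param annotations stacked annotation matrix (baseline first).
#' @param gamma_init starting coefficient vector.
#' @param l2_penalty ridge penalty coefficient.
#' @return Named numeric vector of fitted coefficients.
#' @export
m_step <- function(snp_post, annotations, gamma_init,
                   l2_penalty = 1e-6) {
  A <- as.matrix(annotations)
  E <- snp_post
  stopifnot(length(E) == nrow(A), length(gamma_init) == ncol(A),
            all(E >= 0 & E <= 1))
  nll <- function(g) {
    eta <- drop(A %*% g)
    -sum(E * plogis(-eta, log.p = TRUE) + (1 - E) * plogis(eta, log.p = TRUE)) +
      l2_penalty * sum(g^2)
  }
  gr <- function(g) {
    p <- plogis(-drop(A %*% g))
    drop(crossprod(A, E - p)) + 2 * l2_penalty * g
  }
  fit <- optim(gamma_init, nll, gr, method = "L-BFGS-B",
               control = list(maxit = 500))
  if (fit$convergence != 0 && fit$convergence != 52) {
    stop("M-step optimizer failed (code ", fit$convergence, ", |grad| = ",
         format(sqrt(sum(gr(fit$par)^2))), ") at gamma = ",
         paste(format(fit$par, digits = 4), collapse = ", "))
  }
  setNames(fit$par, colnames(A))
}

#' Fit the annotation-aware fine-mapping model
#'
#' Estimates the annotation coefficient vector by maximum likelihood
#' across loci with an EM algorithm: the E-step computes, independently at
#' each locus, posterior probabilities over causal configurations under
#' the current logistic prior; the M-step refits the prior coefficients to
#' the per-SNP posteriors by soft-label logistic regression. Non-centrality
#' parameters are fixed from the observed Z-scores ([ncp_from_z()]) and
#' not optimized. Convergence requires both the change in total
#' log-likelihood and the max-norm change in `gamma` to fall below their
#' tolerances.
#'
#' @param loci a [locus()] or list of them; annotation columns must agree
#'   across loci.
#' @param control a [finemap_control()].
#' @param gamma_init optional starting coefficients. The default sets the
#'   baseline to `log(mbar - 1)` (one expected causal per locus of mean
#'   size `mbar`) and annotation coefficients to 0.
#' @return Object of class `"finemap"`: fitted `gamma`, per-locus
#'   posteriors, a per-SNP results table, total log-likelihood, iteration
#'   count and convergence flag.
#' @export
finemap <- function(loci, control = finemap_control(), gamma_init = NULL) {
  loci <- as_locus_list(loci)
  ann_names <- colnames(loci[[1L]]$annotations)
  for (l in loci)
    if (!identical(colnames(l$annotations), ann_names))
      stop("annotation columns differ across loci (locus '", l$locus_id, "')")
  preps <- lapply(loci, locus_prep, control = control)
  K1 <- length(ann_names)
  if (is.null(gamma_init)) {
    mbar <- mean(vapply(loci, n_snps, 0L))
    gamma_init <- c(log(max(mbar - 1, 1.5)), rep(0, K1 - 1L))
  }
  stopifnot(length(gamma_init) == K1)
  gamma <- setNames(as.numeric(gamma_init), ann_names)
  A_all <- do.call(rbind, lapply(preps, `[[`, "A"))

  total_ll <- -Inf
  n_iter <- 0L
  converged <- FALSE
  estep_out <- NULL
  repeat {
    n_iter <- n_iter + 1L
    estep_out <- lapply(preps, e_step_prep, gamma = gamma)
    ll <- sum(vapply(estep_out, `[[`, 0, "loglik"))
    if (ll < total_ll - 1e-6 * (1 + abs(total_ll)))
      stop("EM log-likelihood decreased (", format(total_ll), " -> ",
           format(ll), ") beyond numerical tolerance")
    delta_ll <- ll - total_ll
    total_ll <- ll
    E_all <- unlist(lapply(estep_out, `[[`, "snp_post"), use.names = FALSE)
    gamma_new <- m_step(E_all, A_all, gamma, control$l2_penalty)
    delta_g <- max(abs(gamma_new - gamma))
    gamma <- gamma_new
    if (is.finite(delta_ll) && delta_ll < control$em_tol &&
        delta_g < control$gamma_tol) {
      converged <- TRUE
      break
    }
    if (n_iter >= control$max_em_iters) break
  }

  snp_table <- do.call(rbind, lapply(seq_along(loci), function(i) {
    l <- loci[[i]]
    cbind(data.frame(locus_id = l$locus_id, l$snps,
                     posterior = estep_out[[i]]$snp_post,
                     stringsAsFactors = FALSE),
          as.data.frame(l$annotations[, -1L, drop = FALSE]))
  }))
  rownames(snp_table) <- NULL
  structure(list(gamma = gamma,
                 locus_posteriors = lapply(seq_along(loci), function(i) {
                   e <- estep_out[[i]]
                   list(locus_id = loci[[i]]$locus_id,
                        snp_post = e$snp_post, config_w = e$config_w,
                        config_idx = preps[[i]]$idx, loglik = e$loglik)
                 }),
                 snp_table = snp_table, loglik = total_ll,
                 n_iter = n_iter, converged = converged,
                 control = control, n_loci = length(loci)),
            class = "finemap")
}

#' @export
print.finemap <- function(x, ...) {
  cat("Annotation-aware fine-mapping fit\n")
  cat("  loci: ", x$n_loci, "  SNPs: ", nrow(x$snp_table),
      "  max causals/locus: ", x$control$max_causals, "\n", sep = "")
  cat("  log-likelihood (relative): ", format(x$loglik), "  EM iterations: ",
      x$n_iter, if (!x$converged) "  [NOT CONVERGED]", "\n", sep = "")
  cat("  coefficients (logistic scale; negative = enriched):\n")
  print(round(x$gamma, 4))
  invisible(x)
}

#' @export
coef.finemap <- function(object, ...) object$gamma

#' @export
logLik.finemap <- function(object, ...) {
  structure(object$loglik, df = length(object$gamma), class = "logLik")
}

#' @export
fitted.finemap <- function(object, ...) object$snp_table$posterior

#' Summarize a fine-mapping fit
#'
#' Reports, per annotation, the fitted coefficient, the prior probability
#' of causality inside and outside the annotation (others at baseline),
#' and the log2 relative probability of causality.
#'
#' @param object a `"finemap"` fit.
#' @param ... unused.
#' @export
summary.finemap <- function(object, ...) {
  g <- object$gamma
  ann <- names(g)[-1L]
  p0 <- plogis(-g[[1L]])
  tab <- data.frame(
    annotation = ann,
    gamma_hat = unname(g[-1L]),
    prior_in = plogis(-(g[[1L]] + unname(g[-1L]))),
    prior_out = p0,
    log2_relprob = log2(plogis(-(g[[1L]] + unname(g[-1L]))) / p0),
    frequency = if (length(ann))
      vapply(ann, function(a) mean(object$snp_table[[a]]), 0) else numeric(0),
    stringsAsFactors = FALSE)
  out <- list(coefficients = g, baseline_prior = p0, annotations = tab,
              loglik = object$loglik, n_iter = object$n_iter,
              converged = object$converged, n_loci = object$n_loci)
  class(out) <- "summary.finemap"
  out
}

#' @export
print.summary.finemap <- function(x, ...) {
  cat("Baseline prior probability of causality:",
      format(x$baseline_prior, digits = 4), "\n")
  if (nrow(x$annotations)) {
    cat("Annotation effects:\n")
    print(x$annotations, row.names = FALSE, digits = 4)
  } else cat("(no annotations beyond baseline)\n")
  cat("Total relative log-likelihood:", format(x$loglik),
      "| EM iterations:", x$n_iter,
      if (!x$converged) "[NOT CONVERGED]", "\n")
  invisible(x)
}

#' @export
plot.finemap <- function(x, locus_id = NULL, ...) {
  tab <- x$snp_table
  if (!is.null(locus_id)) tab <- tab[tab$locus_id == locus_id, ]
  if (!nrow(tab)) stop("no SNPs to plot")
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(op))
  graphics::plot(tab$pos, abs(tab$zscore), xlab = "position (bp)",
                 ylab = "|Z|", pch = 16, cex = 0.6,
                 main = if (is.null(locus_id)) "all loci" else locus_id, ...)
  graphics::plot(tab$pos, tab$posterior, xlab = "position (bp)",
                 ylab = "posterior P(causal)", ylim = c(0, 1),
                 pch = 16, cex = 0.6, ...)
  invisible(x)
}

## deterministic ranking order used everywhere: posterior desc, |z| desc,
## snp_id lexicographic
rank_order <- function(posterior, z, snp_id) {
  order(-posterior, -abs(z), snp_id, method = "radix")
}

#' Credible (confidence) set of likely causal SNPs
#'
#' The minimal set of posterior-ranked SNPs whose summed posterior reaches
#' a fraction `rho` of the total posterior mass. In `"global"` mode SNPs
#' are ranked across all loci against the grand total; in `"per_locus"`
#' mode the rule is applied within each locus against that locus's mass
#' and the sets are unioned. Ties are broken by |Z| then SNP id.
#'
#' @param fit a `"finemap"` fit, or a data.frame with columns `locus_id`,
#'   `snp_id`, `zscore`, `posterior`.
#' @param rho credible level in (0, 1).
#' @param mode `"global"` or `"per_locus"`.
#' @return Object of class `"credible_set"`: `members` (data.frame sorted
#'   by posterior), `mass_captured`, `total_mass`, `rho`, `mode`.
#' @export
credible_set <- function(fit, rho = 0.9, mode = c("global", "per_locus")) {
  stopifnot(rho > 0, rho < 1)
  mode <- match.arg(mode)
  tab <- if (inherits(fit, "finemap")) fit$snp_table else as.data.frame(fit)
  stopifnot(all(c("locus_id", "snp_id", "zscore", "posterior") %in% names(tab)))
  take_prefix <- function(d, target) {
    o <- rank_order(d$posterior, d$zscore, d$snp_id)
    d <- d[o, , drop = FALSE]
    cum <- cumsum(d$posterior)
    n_take <- if (target <= 0) 0L else
      which(cum >= target - 1e-12)[1L]
    if (is.na(n_take)) n_take <- nrow(d)
    d[seq_len(n_take), , drop = FALSE]
  }
  total <- sum(tab$posterior)
  if (mode == "global") {
    members <- take_prefix(tab, rho * total)
  } else {
    members <- do.call(rbind, lapply(split(tab, tab$locus_id), function(d)
      take_prefix(d, rho * sum(d$posterior))))
    o <- rank_order(members$posterior, members$zscore, members$snp_id)
    members <- members[o, , drop = FALSE]
  }
  rownames(members) <- NULL
  structure(list(members = members[, c("locus_id", "snp_id", "posterior")],
                 mass_captured = sum(members$posterior),
                 total_mass = total, rho = rho, mode = mode),
            class = "credible_set")
}

#' @export
print.credible_set <- function(x, ...) {
  cat(sprintf("%.0f%% credible set (%s): %d SNPs capturing %.3f of %.3f total posterior mass\n",
              100 * x$rho, x$mode, nrow(x$members), x$mass_captured,
              x$total_mass))
  invisible(x)
}

#' Write the per-SNP results table
#'
#' Tab-delimited table with columns `locus_id`, `snp_id`, `chrom`, `pos`,
#' `zscore`, `posterior`, plus one column per annotation.
#'
#' @param fit a `"finemap"` fit.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_results <- function(fit, path) {
  stopifnot(inherits(fit, "finemap"))
  write.table(fit$snp_table, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
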