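## restrict a locus to a subset of annotation columns (baseline always kept)
subset_annotations <- function(x, keep = character(0)) {
  cols <- c("baseline", setdiff(keep, "baseline"))
  missing <- setdiff(cols, colnames(x$annotations))
  if (length(missing))
    stop("annotation(s) not present: ", paste(missing, collapse = ", "))
  x$annotations <- x$annotations[, cols, drop = FALSE]
  x
}

#' Likelihood-ratio test for one annotation
#'
#' Compares a fitted baseline-only (null) model to a model containing the
#' annotation: `stat = 2 * (LL_alt - LL_null)`, referred to the upper tail
#' of a chi-square with one degree of freedom. Both fits share the same
#' initialization protocol (the alternative is warm-started from the null
#' fit's baseline coefficient); small negative statistics arising from EM
#' tolerances are clipped to zero and flagged.
#'
#' @param loci list of [locus()] objects carrying the annotation.
#' @param annotation annotation column name to test.
#' @param control a [finemap_control()].
#' @param null_fit optional pre-computed baseline-only `"finemap"` fit on
#'   the same loci (reused across a scan).
#' @return List: `stat`, `p_value`, `gamma_hat` (annotation coefficient in
#'   the alternative), `fit_alt`, `fit_null`, `clipped`.
#' @export
annotation_lrt <- function(loci, annotation, control = finemap_control(),
                           null_fit = NULL) {
  loci <- as_locus_list(loci)
  if (is.null(null_fit))
    null_fit <- finemap(lapply(loci, subset_annotations), control)
  if (!null_fit$converged) stop("null model did not converge")
  alt_init <- c(null_fit$gamma[[1L]], 0)
  fit_alt <- finemap(lapply(loci, subset_annotations, keep = annotation),
                     control, gamma_init = alt_init)
  if (!fit_alt$converged) stop("alternative model did not converge for '",
                               annotation, "'")
  stat <- 2 * (fit_alt$loglik - null_fit$loglik)
  clipped <- stat < 0
  stat <- max(stat, 0)
  list(stat = stat, p_value = pchisq(stat, df = 1, lower.tail = FALSE),
       gamma_hat = unname(fit_alt$gamma[annotation]),
       fit_alt = fit_alt, fit_null = null_fit, clipped = clipped)
}

#' Marginal enrichment scan over annotations
#'
#' Fits the model once per annotation (baseline plus that single
#' annotation) and reports, per annotation: the fitted coefficient, the
#' log2 relative probability of causality inside versus outside the
#' annotation, the fraction of SNPs annotated, and the likelihood-ratio
#' statistic and p-value. Annotations whose fit fails are recorded with
#' `NA` statistics and the scan continues.
#'
#' @param loci list of [locus()] objects.
#' @param annotations annotation names to scan; default all non-baseline
#'   columns of the first locus.
#' @param control a [finemap_control()].
#' @return data.frame of class `"enrichment_scan"`, one row per
#'   annotation, sorted by p-value ascending (failures last).
#' @export
marginal_scan <- function(loci, annotations = NULL,
                          control = finemap_control()) {
  loci <- as_locus_list(loci)
  if (is.null(annotations))
    annotations <- setdiff(colnames(loci[[1L]]$annotations), "baseline")
  if (!length(annotations)) {
    out <- data.frame(annotation = character(0), gamma_hat = numeric(0),
                      log2_relprob = numeric(0), frequency = numeric(0),
                      lrt_stat = numeric(0), p_value = numeric(0),
                      error = character(0), stringsAsFactors = FALSE)
    class(out) <- c("enrichment_scan", "data.frame")
    return(out)
  }
  null_fit <- finemap(lapply(loci, subset_annotations), control)
  rows <- lapply(annotations, function(a) {
    freq <- mean(unlist(lapply(loci, function(l) l$annotations[, a])))
    res <- tryCatch(annotation_lrt(loci, a, control, null_fit = null_fit),
                    error = function(e) e)
    if (inherits(res, "error"))
      return(data.frame(annotation = a, gamma_hat = NA_real_,
                        log2_relprob = NA_real_, frequency = freq,
                        lrt_stat = NA_real_, p_value = NA_real_,
                        error = conditionMessage(res),
                        stringsAsFactors = FALSE))
    g0 <- res$fit_alt$gamma[[1L]]
    data.frame(annotation = a, gamma_hat = res$gamma_hat,
               log2_relprob = log2(plogis(-(g0 + res$gamma_hat)) /
                                     plogis(-g0)),
               frequency = freq, lrt_stat = res$stat, p_value = res$p_value,
               error = NA_character_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p_value, method = "radix", na.last = TRUE), ]
  rownames(out) <- NULL
  class(out) <- c("enrichment_scan", "data.frame")
  out
}

#' Select top annotations from a scan
#'
#' Keeps the most significant record within each duplicate group (e.g.
#' experimental replicates of the same tissue and mark), then returns the
#' `k` annotations with the smallest p-values.
#'
#' @param scan an [marginal_scan()] result (or compatible data.frame).
#' @param k number of annotations to keep.
#' @param dedupe_key optional function mapping an annotation name to a
#'   group label; only the best record per group is eligible.
#' @return Character vector of at most `k` annotation names.
#' @export
select_annotations <- function(scan, k, dedupe_key = NULL) {
  stopifnot(k >= 1)
  scan <- as.data.frame(scan)
  scan <- scan[!is.na(scan$p_value), , drop = FALSE]
  scan <- scan[order(scan$p_value, scan$annotation, method = "radix"), ]
  if (!is.null(dedupe_key)) {
    grp <- vapply(scan$annotation, dedupe_key, "")
    scan <- scan[!duplicated(grp), , drop = FALSE]
  }
  head(scan$annotation, k)
}

#' Bootstrap standard errors for annotation coefficients
#'
#' Loci are treated as independent, so uncertainty in the fitted
#' coefficients is assessed by resampling entire loci with replacement,
#' refitting the model on each replicate, and taking the per-coefficient
#' standard deviation across replicates.
#'
#' @param loci list of [locus()] objects.
#' @param annotations annotation names in the model.
#' @param B number of bootstrap replicates (default 1000).
#' @param seed RNG seed for the resampling.
#' @param control a [finemap_control()].
#' @return Named numeric vector of bootstrap SDs (baseline first), with
#'   attributes `n_failed` and `B`.
#' @export
bootstrap_se <- function(loci, annotations = NULL, B = 1000L, seed = 1L,
                         control = finemap_control()) {
  stopifnot(B >= 2L)
  loci <- as_locus_list(loci)
  if (is.null(annotations))
    annotations <- setdiff(colnames(loci[[1L]]$annotations), "baseline")
  loci <- lapply(loci, subset_annotations, keep = annotations)
  set.seed(seed)
  draws <- matrix(sample.int(length(loci), length(loci) * B, replace = TRUE),
                  nrow = B)
  reps <- vector("list", B)
  n_failed <- 0L
  for (b in seq_len(B)) {
    fit <- tryCatch(finemap(loci[draws[b, ]], control),
                    error = function(e) NULL)
    if (is.null(fit)) n_failed <- n_failed + 1L else reps[[b]] <- fit$gamma
  }
  if (n_failed > 0.1 * B)
    stop(n_failed, " of ", B, " bootstrap refits failed (> 10%)")
  G <- do.call(rbind, reps[!vapply(reps, is.null, TRUE)])
  structure(apply(G, 2L, sd), n_failed = n_failed, B = B)
}
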