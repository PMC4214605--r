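#' Construct a fine-mapping locus
#'
#' A locus bundles everything the model needs for one region: per-SNP
#' metadata with association Z-scores, the LD (pairwise Pearson
#' correlation) matrix, and a binary annotation matrix whose first column
#' is the all-ones baseline.
#'
#' @param locus_id character scalar identifying the region.
#' @param snps data.frame with columns `snp_id`, `chrom`, `pos` (1-based
#'   base pairs), `zscore` (marginal Wald statistic). Row order is the SNP
#'   order used by `ld` and `annotations`.
#' @param ld numeric m x m matrix of pairwise Pearson correlations between
#'   SNP dosages, in the same order as `snps`.
#' @param annotations optional numeric/integer m x K binary matrix (one
#'   column per annotation, named). A baseline column of ones is prepended
#'   if not already present as the first column named `"baseline"`.
#' @return An object of class `"locus"`.
#' @export
locus <- function(locus_id, snps, ld, annotations = NULL) {
  stopifnot(is.character(locus_id), length(locus_id) == 1L)
  snps <- as.data.frame(snps)
  req <- c("snp_id", "chrom", "pos", "zscore")
  miss <- setdiff(req, names(snps))
  if (length(miss))
    stop("locus '", locus_id, "': snp table lacks column(s) ",
         paste(miss, collapse = ", "))
  m <- nrow(snps)
  snps$snp_id <- as.character(snps$snp_id)
  snps$chrom <- as.character(snps$chrom)
  snps$pos <- as.integer(snps$pos)
  snps$zscore <- as.numeric(snps$zscore)
  if (any(snps$pos <= 0L)) stop("locus '", locus_id, "': positions must be > 0")
  if (any(!is.finite(snps$zscore))) {
    bad <- which(!is.finite(snps$zscore))
    stop("locus '", locus_id, "': non-finite zscore at row(s) ",
         paste(bad, collapse = ", "))
  }
  ld <- as.matrix(ld)
  if (!all(dim(ld) == c(m, m)))
    stop("locus '", locus_id, "': LD is ", nrow(ld), "x", ncol(ld),
         " but there are ", m, " SNPs")
  if (max(abs(ld - t(ld))) > 1e-8)
    stop("locus '", locus_id, "': LD matrix is not symmetric")
  if (any(abs(ld) > 1 + 1e-8))
    stop("locus '", locus_id, "': LD entries must lie in [-1, 1]")
  ld <- (ld + t(ld)) / 2
  dimnames(ld) <- NULL

  if (is.null(annotations)) {
    annotations <- matrix(1, m, 1, dimnames = list(NULL, "baseline"))
  } else {
    annotations <- as.matrix(annotations)
    if (nrow(annotations) != m)
      stop("locus '", locus_id, "': annotation matrix has ", nrow(annotations),
           " rows for ", m, " SNPs")
    if (is.null(colnames(annotations)))
      colnames(annotations) <- paste0("A", seq_len(ncol(annotations)))
    if (!(colnames(annotations)[1] == "baseline" &&
          all(annotations[, 1] == 1))) {
      annotations <- cbind(baseline = rep(1, m), annotations)
    }
    if (anyDuplicated(colnames(annotations)))
      stop("locus '", locus_id, "': duplicate annotation names")
    if (!all(annotations %in% c(0, 1)))
      stop("locus '", locus_id, "': annotations must be binary 0/1")
  }
  structure(list(locus_id = locus_id, snps = snps, ld = ld,
                 annotations = annotations),
            class = "locus")
}

#' @export
print.locus <- function(x, ...) {
  cat("<locus> ", x$locus_id, ": ", nrow(x$snps), " SNPs, annotations: ",
      paste(colnames(x$annotations), collapse = ", "), "\n", sep = "")
  invisible(x)
}

n_snps <- function(x) nrow(x$snps)

## coerce a single locus to a one-element list, pass lists through
as_locus_list <- function(loci) {
  if (inherits(loci, "locus")) loci <- list(loci)
  if (!length(loci) || !all(vapply(loci, inherits, TRUE, "locus")))
    stop("expected a locus or a non-empty list of locus objects")
  loci
}

#' Fitting options
#'
#' Collects the tuning constants of the likelihood and the EM fit.
#'
#' @param max_causals maximum number of causal SNPs per configuration
#'   (default 2; 3 is tractable for moderate loci).
#' @param em_tol EM convergence tolerance on the change in total
#'   log-likelihood.
#' @param gamma_tol additional convergence requirement: max-norm of the
#'   change in the annotation coefficient vector.
#' @param max_em_iters maximum EM iterations.
#' @param ld_ridge ridge added to the LD matrix (then rescaled to unit
#'   diagonal) before any likelihood evaluation; guards against
#'   rank-deficient reference-panel LD.
#' @param ncp_strategy how non-centrality parameters are fixed from the
#'   observed Z-scores: `"clamped"` (observed Z if |Z| exceeds
#'   `ncp_threshold`, else sign(Z) times the threshold), `"observed"`, or
#'   `"locus_max"` (sign(Z) times the locus-maximum |Z|).
#' @param ncp_threshold clamping threshold for `"clamped"` (default 3.7).
#' @param enum_cap maximum number of causal configurations enumerated per
#'   locus before erroring.
#' @param l2_penalty L2 regularization on the annotation coefficients in
#'   the M-step, stabilizing separable cases.
#' @return A list of class `"finemap_control"`.
#' @export
finemap_control <- function(max_causals = 2L, em_tol = 1e-4, gamma_tol = 1e-3,
                            max_em_iters = 100L, ld_ridge = 1e-3,
                            ncp_strategy = c("clamped", "observed", "locus_max"),
                            ncp_threshold = 3.7, enum_cap = 5e6,
                            l2_penalty = 1e-6) {
  ncp_strategy <- match.arg(ncp_strategy)
  stopifnot(max_causals >= 1L, em_tol > 0, gamma_tol > 0, max_em_iters >= 1L,
            ld_ridge >= 0, ncp_threshold > 0, enum_cap > 0, l2_penalty >= 0)
  structure(list(max_causals = as.integer(max_causals), em_tol = em_tol,
                 gamma_tol = gamma_tol, max_em_iters = as.integer(max_em_iters),
                 ld_ridge = ld_ridge, ncp_strategy = ncp_strategy,
                 ncp_threshold = ncp_threshold, enum_cap = enum_cap,
                 l2_penalty = l2_penalty),
            class = "finemap_control")
}

#' Read a locus from its on-disk files
#'
#' File dialect: a whitespace-delimited locus table with a header row and
#' columns `snp_id`, `chrom`, `pos`, `zscore`; a dense whitespace-delimited
#' square LD matrix with no header; and an optional dense binary annotation
#' matrix with a header of track names (absence of a header assigns
#' `A1..AK`).
#'
#' @param zfile path to the locus table.
#' @param ldfile path to the LD matrix.
#' @param annotfile optional path to the annotation matrix; if `NULL` the
#'   locus carries only the baseline annotation.
#' @param locus_id identifier; defaults to the basename of `zfile` without
#'   extension.
#' @return A [locus()] object.
#' @export
read_locus <- function(zfile, ldfile, annotfile = NULL, locus_id = NULL) {
  for (f in c(zfile, ldfile, annotfile))
    if (!file.exists(f)) stop("file not found: ", f)
  if (is.null(locus_id))
    locus_id <- sub("\\.[^.]*$", "", basename(zfile))
  snps <- read.table(zfile, header = TRUE, stringsAsFactors = FALSE)
  zn <- suppressWarnings(as.numeric(snps$zscore))
  if (any(is.na(zn))) {
    bad <- which(is.na(zn))
    stop("non-numeric zscore in ", zfile, " at data line(s) ",
         paste(bad, collapse = ", "))
  }
  snps$zscore <- zn
  ld <- as.matrix(read.table(ldfile, header = FALSE))
  if (nrow(ld) != nrow(snps))
    stop("dimension mismatch: ", zfile, " has ", nrow(snps), " SNPs but ",
         ldfile, " has ", nrow(ld), " rows")
  ann <- NULL
  if (!is.null(annotfile)) {
    first <- strsplit(trimws(readLines(annotfile, n = 1L)), "\\s+")[[1]]
    has_header <- any(is.na(suppressWarnings(as.numeric(first))))
    ann <- as.matrix(read.table(annotfile, header = has_header))
    if (!has_header) colnames(ann) <- paste0("A", seq_len(ncol(ann)))
    if (nrow(ann) != nrow(snps))
      stop("dimension mismatch: ", zfile, " has ", nrow(snps), " SNPs but ",
           annotfile, " has ", nrow(ann), " rows")
  }
  locus(locus_id, snps, ld, ann)
}

#' Write a locus to disk
#'
#' Inverse of [read_locus()]; the baseline annotation column is not
#' written (it is implicit).
#'
#' @param x a [locus()] object.
#' @param zfile,ldfile,annotfile output paths; `annotfile = NULL` skips the
#'   annotation matrix.
#' @return Invisibly, the paths written.
#' @export
write_locus <- function(x, zfile, ldfile, annotfile = NULL) {
  stopifnot(inherits(x, "locus"))
  snps <- x$snps
  snps$zscore <- format(snps$zscore, digits = 17) # lossless round-trip
  write.table(snps, zfile, quote = FALSE, row.names = FALSE)
  write.table(format(x$ld, digits = 17), ldfile, quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  paths <- c(zfile, ldfile)
  if (!is.null(annotfile) && ncol(x$annotations) > 1L) {
    ann <- x$annotations[, -1L, drop = FALSE]
    write.table(ann, annotfile, quote = FALSE, row.names = FALSE)
    paths <- c(paths, annotfile)
  }
  invisible(paths)
}

#' Read BED interval tracks
#'
#' Reads a BED3+ file into an annotation track: a named set of 0-based
#' half-open `(chrom, start, end)` intervals with union semantics.
#' `track` and `browser` lines and `#` comments are skipped.
#'
#' @param path BED file path.
#' @param name track name; defaults to the file basename without extension.
#' @return A list of class `"annotation_track"` with elements `name` and
#'   `intervals` (data.frame `chrom`, `start`, `end`).
#' @export
read_bed_track <- function(path, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  if (!any(keep)) stop("BED file ", path, " contains no intervals")
  df <- read.table(text = lines[keep], header = FALSE, fill = TRUE,
                   stringsAsFactors = FALSE)
  annotation_track(name, data.frame(chrom = as.character(df[[1]]),
                                    start = as.numeric(df[[2]]),
                                    end = as.numeric(df[[3]])))
}

#' @rdname read_bed_track
#' @param intervals data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open).
#' @export
annotation_track <- function(name, intervals) {
  stopifnot(is.character(name), length(name) == 1L)
  intervals <- as.data.frame(intervals)
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  if (any(intervals$start >= intervals$end))
    stop("track '", name, "': intervals must satisfy start < end")
  structure(list(name = name, intervals = intervals),
            class = "annotation_track")
}

#' Intersect locus SNPs with annotation tracks
#'
#' Appends one binary annotation column per track: a SNP at 1-based
#' position p is inside a 0-based half-open interval `[start, end)` iff
#' `start <= p - 1 < end`. Overlapping intervals within a track are
#' treated as their union.
#'
#' @param x a [locus()] object.
#' @param tracks a single `annotation_track` or list of them.
#' @return The locus with the extra annotation columns (baseline stays
#'   first).
#' @export
intersect_annotations <- function(x, tracks) {
  stopifnot(inherits(x, "locus"))
  if (inherits(tracks, "annotation_track")) tracks <- list(tracks)
  nms <- vapply(tracks, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("duplicate track names: ",
                               paste(unique(nms[duplicated(nms)]), collapse = ", "))
  if (any(nms %in% colnames(x$annotations)))
    stop("track name already present in locus annotations")
  snp_gr <- GenomicRanges::GRanges(
    x$snps$chrom, IRanges::IRanges(start = x$snps$pos, width = 1L))
  cols <- vapply(tracks, function(tr) {
    iv <- tr$intervals
    tr_gr <- GenomicRanges::GRanges(
      iv$chrom, IRanges::IRanges(start = iv$start + 1L, end = iv$end))
    as.numeric(IRanges::overlapsAny(snp_gr, tr_gr))
  }, numeric(n_snps(x)))
  cols <- matrix(cols, nrow = n_snps(x), dimnames = list(NULL, nms))
  x$annotations <- cbind(x$annotations, cols)
  x
}

#' Compute an LD matrix from genotype dosages
#'
#' Pairwise Pearson correlation of per-individual dosages; use either
#' in-sample genotypes or a reference panel, the module is agnostic.
#'
#' @param genotypes numeric N x m matrix (individuals by SNPs).
#' @param snp_ids optional SNP identifiers used in error messages.
#' @return m x m correlation matrix with unit diagonal.
#' @export
compute_ld <- function(genotypes, snp_ids = NULL) {
  genotypes <- as.matrix(genotypes)
  v <- apply(genotypes, 2L, stats::var)
  if (any(v == 0)) {
    bad <- which(v == 0)
    ids <- if (is.null(snp_ids)) paste0("column ", bad) else snp_ids[bad]
    stop("zero-variance genotype column(s): ", paste(ids, collapse = ", "))
  }
  ld <- cor(genotypes)
  ld <- (ld + t(ld)) / 2
  diag(ld) <- 1
  dimnames(ld) <- NULL
  ld
}

#' Ridge-regularize an LD matrix
#'
#' Returns `(ld + ridge * I)` rescaled so the diagonal is exactly 1, i.e.
#' off-diagonals are divided by `1 + ridge`. With `ridge = 0` the input is
#' returned unchanged. The result is checked for positive definiteness.
#'
#' @param ld symmetric correlation matrix.
#' @param ridge nonnegative ridge; the default mirrors
#'   [finemap_control()].
#' @return Regularized correlation matrix.
#' @export
regularize_ld <- function(ld, ridge = 1e-3) {
  stopifnot(ridge >= 0)
  ld <- as.matrix(ld)
  if (max(abs(ld - t(ld))) > 1e-8) stop("LD matrix is not symmetric")
  out <- if (ridge == 0) ld else {
    o <- ld / (1 + ridge)
    diag(o) <- 1
    o
  }
  ok <- tryCatch({ chol(out); TRUE }, error = function(e) FALSE)
  if (!ok)
    stop("LD matrix is not positive definite after ridge ", ridge,
         "; increase ld_ridge")
  out
}

#' Read genotype dosages from a VCF
#'
#' Extracts the ALT-allele dosage (0/1/2) from the GT field of a
#' biallelic VCF, individuals in rows. Multi-allelic records are rejected.
#'
#' @param path VCF path (plain text or bgzipped).
#' @return list with `genotypes` (N x m dosage matrix) and `snps`
#'   (data.frame `snp_id`, `chrom`, `pos`).
#' @export
read_vcf_genotypes <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_vcf_genotypes requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (any(grepl(",", fix[, "ALT"], fixed = TRUE)))
    stop("multi-allelic records present; split or filter them upstream")
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- apply(gt, c(1, 2), function(g) {
    if (is.na(g)) return(NA_real_)
    sum(as.integer(strsplit(g, "[/|]")[[1]]) > 0)
  })
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <-
    paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(ids) | ids == "."]
  list(genotypes = t(dos),
       snps = data.frame(snp_id = ids, chrom = fix[, "CHROM"],
                         pos = as.integer(fix[, "POS"]),
                         stringsAsFactors = FALSE))
}
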