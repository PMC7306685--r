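# Library-size normalization: CPM/FPKM, the expression filter, and
# trimmed-mean-of-M-values (TMM) composition factors.

#' Counts per million
#'
#' @param x a [count_matrix()] or a plain counts matrix.
#' @param effective_lib_sizes per-sample effective library sizes; defaults
#'   to the stored library sizes (use `library_sizes * norm_factors` for
#'   TMM-normalized CPM).
#' @return genes x samples matrix of CPM values.
#' @export
cpm <- function(x, effective_lib_sizes = NULL) {
  counts <- if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
  if (is.null(effective_lib_sizes)) {
    if (!inherits(x, "count_matrix")) {
      stop("effective_lib_sizes required for a plain matrix")
    }
    effective_lib_sizes <- x$library_sizes
  }
  if (length(effective_lib_sizes) != ncol(counts)) {
    stop("effective_lib_sizes length must equal the number of samples")
  }
  if (any(effective_lib_sizes <= 0)) stop("library sizes must be positive")
  sweep(counts, 2, effective_lib_sizes, "/") * 1e6
}

#' Fragments per kilobase per million
#'
#' `count / (length/1e3) / (effective_size/1e6)`.
#'
#' @inheritParams cpm
#' @param gene_lengths named vector of gene lengths in bp; every gene in the
#'   matrix must be present.
#' @return genes x samples matrix of FPKM values.
#' @export
fpkm <- function(x, gene_lengths, effective_lib_sizes = NULL) {
  counts <- if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
  missing <- setdiff(rownames(counts), names(gene_lengths))
  if (length(missing)) {
    stop("gene length missing for: ", paste(head(missing, 5), collapse = ", "))
  }
  len <- gene_lengths[rownames(counts)]
  if (any(len <= 0)) stop("gene lengths must be positive")
  cpm(x, effective_lib_sizes) / (len / 1e3)
}

#' Gene lengths from an annotation
#' @param annotation a [gene_annotation()].
#' @return named vector of `end - start + 1` lengths.
#' @export
gene_lengths <- function(annotation) {
  setNames(annotation$end - annotation$start + 1L, annotation$gene_id)
}

#' Filter to expressed genes
#'
#' A gene is retained when its CPM exceeds `cpm_threshold` in at least
#' `min_samples` samples (the study rule: CPM > 1 in three or more of the
#' 24 libraries), evaluated on raw library sizes before any normalization.
#'
#' @param x a [count_matrix()].
#' @param cpm_threshold CPM cutoff, exceeded strictly (default 1).
#' @param min_samples minimum number of qualifying samples (default 3).
#' @return Character vector of retained gene ids, with attribute
#'   `n_removed` giving the number of genes filtered out.
#' @export
filter_expressed <- function(x, cpm_threshold = 1, min_samples = 3) {
  v <- cpm(x)
  keep <- rowSums(v > cpm_threshold) >= min_samples
  out <- rownames(x$counts)[keep]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Trimmed mean of M-values normalization factors
#'
#' Estimates per-sample RNA-composition scaling factors. For each sample
#' versus the reference column, genes zero in either column are excluded;
#' the per-gene log2 ratios of library-size-scaled counts (M-values) are
#' doubly trimmed — `logratio_trim` of each M tail and `abs_trim` of each
#' A (average abundance) tail — and averaged with precision weights (the
#' inverse asymptotic variance of M under binomial sampling). Factors are
#' rescaled so their geometric mean is 1.
#'
#' @param x a [count_matrix()]; every column must contain a nonzero count.
#' @param logratio_trim fraction trimmed from each tail of the M-values
#'   (default 0.30).
#' @param abs_trim fraction trimmed from each tail of the A-values
#'   (default 0.05).
#' @param reference reference sample id or column index; by default the
#'   column whose upper quartile of scaled counts is closest to the mean
#'   upper quartile.
#' @return Named vector of normalization factors, geometric mean 1.
#' @export
tmm_norm_factors <- function(x, logratio_trim = 0.30, abs_trim = 0.05,
                             reference = NULL) {
  counts <- x$counts
  lib <- x$library_sizes
  if (any(colSums(counts) == 0)) {
    stop("column(s) with all-zero counts: ",
         paste(colnames(counts)[colSums(counts) == 0], collapse = ", "))
  }
  if (is.null(reference)) {
    uq <- apply(sweep(counts, 2, lib, "/"), 2, quantile, probs = 0.75)
    reference <- which.min(abs(uq - mean(uq)))
  }
  if (is.character(reference)) reference <- match(reference, colnames(counts))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    .tmm_pair(counts[, j], counts[, reference], lib[j], lib[reference],
              logratio_trim, abs_trim)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

# One sample against the reference: doubly-trimmed precision-weighted mean
# of M-values, following the published TMM estimator.
.tmm_pair <- function(obs, ref, n_obs, n_ref, logratio_trim, abs_trim) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  if (length(obs) == 0) return(1)
  p_obs <- obs / n_obs
  p_ref <- ref / n_ref
  M <- log2(p_obs / p_ref)
  A <- (log2(p_obs) + log2(p_ref)) / 2
  w <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  fin <- is.finite(M) & is.finite(A) & is.finite(w)
  M <- M[fin]; A <- A[fin]; w <- w[fin]
  if (length(M) == 0 || max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  loM <- floor(n * logratio_trim) + 1
  hiM <- n + 1 - loM
  loA <- floor(n * abs_trim) + 1
  hiA <- n + 1 - loA
  keep2 <- rank(M, ties.method = "first") >= loM &
    rank(M, ties.method = "first") <= hiM &
    rank(A, ties.method = "first") >= loA &
    rank(A, ties.method = "first") <= hiA
  if (!any(keep2)) return(1)
  2^(sum(M[keep2] / w[keep2]) / sum(1 / w[keep2]))
}
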