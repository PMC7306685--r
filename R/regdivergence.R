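# Partition parental expression divergence into cis and trans components:
# pFC (parental log2 fold-change, total counts), aFC (allelic log2
# fold-change inside the hybrid's heterozygous introgressions), the
# Student's t trans test comparing the two, the seven-way category rules,
# and the misexpression association tests.

REG_CATEGORIES <- c("CIS_ONLY", "TRANS_ONLY", "CIS_TRANS_REINFORCING",
                    "CIS_TRANS_OPPOSING", "CIS_X_TRANS", "COMPENSATORY",
                    "CONSERVED", "AMBIGUOUS")

#' Parental fold-change (pFC): total cis + trans divergence
#'
#' Contrast of the two parental lines within one tissue on total counts,
#' without the fold-change threshold (the threshold is dropped here so
#' compensatory changes are not overestimated). Sign convention
#' log2(SF5/IM62).
#'
#' @param x a [count_matrix()] (any superset of the parental samples).
#' @param design the matching [sample_design()].
#' @param tissue `"stamen"` or `"carpel"`.
#' @param dispersions dispersion estimates (see [test_contrast()]).
#' @param alpha FDR level (default 0.05).
#' @param norm_factors optional TMM factors (full-design factors are
#'   subset to the parental samples).
#' @return data.frame with `gene_id`, `pFC`, `p`, `fdr`, `pFC_sig`.
#' @export
compute_pfc <- function(x, design, tissue, dispersions, alpha = 0.05,
                        norm_factors = NULL) {
  keep <- design$line %in% PARENT_LINES & design$tissue == tissue
  if (sum(keep) < 4) stop("need at least two replicates per parent")
  sub_design <- design[keep, , drop = FALSE]
  class(sub_design) <- class(design)
  sub <- subset_samples(x, sub_design$sample_id)
  nf <- if (is.null(norm_factors)) NULL else
    norm_factors[sub_design$sample_id] /
      exp(mean(log(norm_factors[sub_design$sample_id])))
  de <- test_contrast(sub, sub_design, dispersions,
                      contrast = paste0("SF5_", tissue, " - IM62_", tissue),
                      lfc_threshold = 0, alpha = alpha, norm_factors = nf)
  data.frame(gene_id = de$gene_id, pFC = de$log2fc, p = de$p, fdr = de$fdr,
             pFC_sig = de$significant, stringsAsFactors = FALSE)
}

#' Allelic fold-change (aFC): cis divergence within the hybrid
#'
#' For heterozygous introgression genes of one hybrid line and tissue, fits
#' a per-gene negative-binomial GLM on the six allelic counts (3 replicates
#' x 2 alleles) with an allele factor, a replicate blocking factor, and
#' per-(sample, allele) effective library sizes as offsets; the allele
#' effect is tested by likelihood ratio. Sign convention
#' log2(SF5 allele / IM62 allele). Genes below `min_allelic_cpm` mean
#' allelic CPM in the group are dropped before testing.
#'
#' @param allele_counts an [allele_count_matrix()].
#' @param design the matching [sample_design()].
#' @param line hybrid line (`"FER"` or `"STE"`).
#' @param tissue `"stamen"` or `"carpel"`.
#' @param block_genes genes inside the line's heterozygous blocks (see
#'   [genes_in_blocks()]); genes outside are excluded with a warning.
#' @param genes genes to evaluate (default: `block_genes`).
#' @param dispersion NB dispersion for the allelic model: a scalar, a named
#'   per-gene vector, or a [estimate_dispersions()] result.
#' @param min_allelic_cpm mean allelic-CPM floor (default 1).
#' @param alpha FDR level (default 0.05).
#' @param allele_lib_sizes optional samples x 2 matrix of per-(sample,
#'   allele) effective sizes. The default splits each sample's total
#'   allelic depth equally between the alleles: both alleles of a
#'   heterozygous gene are sequenced from the same library, so per-allele
#'   genome-wide totals (dominated by the homozygous recurrent-parent
#'   background) or per-allele block totals (tilted by whichever cis
#'   effects the block happens to carry) would both shift every aFC away
#'   from the allele-balance null.
#' @return data.frame with `gene_id`, `aFC`, `p`, `fdr`, `aFC_sig`.
#' @export
compute_afc <- function(allele_counts, design, line, tissue, block_genes,
                        genes = NULL, dispersion = 0.05,
                        min_allelic_cpm = 1, alpha = 0.05,
                        allele_lib_sizes = NULL) {
  stopifnot(line %in% HYBRID_LINES, tissue %in% TISSUES)
  if (is.null(genes)) genes <- block_genes
  outside <- setdiff(genes, block_genes)
  if (length(outside)) {
    warning(length(outside),
            " gene(s) outside the heterozygous blocks excluded")
    genes <- intersect(genes, block_genes)
  }
  samples <- design$sample_id[design$line == line & design$tissue == tissue]
  if (length(samples) < 2) stop("need at least two replicates")
  arr <- allele_counts$counts[, samples, , drop = FALSE]
  genes <- intersect(genes, dimnames(arr)[[1]])
  lib <- if (is.null(allele_lib_sizes)) {
    tot <- rowSums(allele_counts$library_sizes[samples, , drop = FALSE])
    cbind(IM62 = tot / 2, SF5 = tot / 2)
  } else {
    allele_lib_sizes[samples, , drop = FALSE]
  }
  if (any(lib <= 0)) stop("zero allelic library size")

  # flatten to gene x (sample, allele) with matching offsets
  nrep <- length(samples)
  slice <- function(al) {
    m <- arr[genes, , al]
    if (is.null(dim(m))) m <- matrix(m, nrow = length(genes),
                                     dimnames = list(genes, samples))
    m
  }
  y <- cbind(slice("IM62"), slice("SF5"))
  offs <- log(c(lib[, "IM62"], lib[, "SF5"]))
  allele <- factor(rep(ALLELES, each = nrep), levels = ALLELES)
  replicate <- factor(rep(seq_len(nrep), times = 2))

  # the expression floor uses genome-wide allelic library sizes (CPM in
  # its usual sense); only the GLM offsets are block-centered
  global_lib <- allele_counts$library_sizes[samples, , drop = FALSE]
  global_offs <- c(global_lib[, "IM62"], global_lib[, "SF5"])
  mean_cpm <- rowMeans(sweep(y, 2, pmax(global_offs, 1), "/") * 1e6)
  keep <- mean_cpm >= min_allelic_cpm
  y <- y[keep, , drop = FALSE]
  genes <- genes[keep]
  if (!length(genes)) {
    return(data.frame(gene_id = character(), aFC = numeric(), p = numeric(),
                      fdr = numeric(), aFC_sig = logical()))
  }
  phi <- .dispersion_vector(dispersion, genes)

  X_full <- model.matrix(~ replicate + allele)
  X_null <- model.matrix(~ replicate)
  res <- t(vapply(seq_along(genes), function(g) {
    .nb_lrt_glm(y[g, ], X_full, X_null, offs, phi[g],
                coef_name = "alleleSF5")
  }, numeric(2)))
  aFC <- res[, 1] / log(2)
  p <- res[, 2]
  fdr <- bh_fdr(p)
  data.frame(gene_id = genes, aFC = aFC, p = p, fdr = fdr,
             aFC_sig = fdr <= alpha, stringsAsFactors = FALSE)
}

#' Allelic library sizes over the heterozygous-block genes
#'
#' Per-(sample, allele) totals restricted to the heterozygous gene set; an
#' alternative offset choice for [compute_afc()] that centers aFC on the
#' block-average allelic balance instead of strict within-sample symmetry.
#'
#' @param allele_counts an [allele_count_matrix()].
#' @param block_genes heterozygous-block gene ids.
#' @return samples x 2 matrix of totals.
#' @export
block_allele_lib_sizes <- function(allele_counts, block_genes) {
  genes <- intersect(block_genes, dimnames(allele_counts$counts)[[1]])
  if (!length(genes)) stop("no block genes present in the allele matrix")
  apply(allele_counts$counts[genes, , , drop = FALSE], c(2, 3), sum)
}

# Likelihood-ratio test of one coefficient in a general NB GLM with fixed
# dispersion, via stats::glm with the MASS negative-binomial family.
.nb_lrt_glm <- function(y, X_full, X_null, offsets, phi, coef_name) {
  fam <- MASS::negative.binomial(theta = 1 / max(phi, DISPERSION_FLOOR))
  fit_full <- tryCatch(
    suppressWarnings(glm.fit(X_full, y, family = fam, offset = offsets)),
    error = function(e) NULL)
  fit_null <- tryCatch(
    suppressWarnings(glm.fit(X_null, y, family = fam, offset = offsets)),
    error = function(e) NULL)
  if (is.null(fit_full) || is.null(fit_null)) return(c(NA_real_, 1))
  lr <- max(fit_null$deviance - fit_full$deviance, 0)
  est <- fit_full$coefficients[coef_name]
  c(est, pchisq(lr, df = 1, lower.tail = FALSE))
}

#' Student's t-test for trans divergence
#'
#' Compares replicate-level parental log ratios with hybrid allelic log
#' ratios for each tested gene: x_i = log2((CPM_SF5,i + eps)/(CPM_IM62,i +
#' eps)) pairing parental replicates by index, y_i likewise from the
#' hybrid's allelic CPM, then a two-sample equal-variance Student's t.
#' A significant difference (BH FDR over the tested set) between total
#' parental divergence and allelic (cis) divergence is evidence of trans
#' divergence.
#'
#' @param parent_cpm_sf5,parent_cpm_im62 genes x replicates CPM matrices of
#'   the two parents in the analyzed tissue, replicate columns aligned.
#' @param hybrid_allele_cpm_sf5,hybrid_allele_cpm_im62 genes x replicates
#'   allelic CPM matrices of the hybrid.
#' @param tested_genes genes with significant pFC or aFC (the only genes
#'   the trans test is run on).
#' @param eps CPM prior guarding zeros (default 0.5).
#' @param alpha FDR level (default 0.05).
#' @return data.frame with `gene_id`, `trans_stat`, `trans_p`, `trans_fdr`,
#'   `trans_sig`; genes with fewer than two usable replicates in either
#'   group are reported untestable (`NA` statistics, `trans_sig = NA`).
#' @export
trans_test <- function(parent_cpm_sf5, parent_cpm_im62,
                       hybrid_allele_cpm_sf5, hybrid_allele_cpm_im62,
                       tested_genes, eps = 0.5, alpha = 0.05) {
  if (ncol(parent_cpm_sf5) != ncol(parent_cpm_im62)) {
    stop("parental replicate counts differ; cannot pair by index")
  }
  res <- t(vapply(tested_genes, function(g) {
    x <- log2((parent_cpm_sf5[g, ] + eps) / (parent_cpm_im62[g, ] + eps))
    yv <- log2((hybrid_allele_cpm_sf5[g, ] + eps) /
                 (hybrid_allele_cpm_im62[g, ] + eps))
    x <- x[is.finite(x)]; yv <- yv[is.finite(yv)]
    if (length(x) < 2 || length(yv) < 2) return(c(NA_real_, NA_real_))
    student_t2(x, yv)
  }, numeric(2)))
  trans_stat <- res[, 1]
  trans_p <- res[, 2]
  ok <- !is.na(trans_p)
  trans_fdr <- rep(NA_real_, length(tested_genes))
  trans_fdr[ok] <- bh_fdr(trans_p[ok])
  data.frame(gene_id = tested_genes, trans_stat = trans_stat,
             trans_p = trans_p, trans_fdr = trans_fdr,
             trans_sig = trans_fdr <= alpha, stringsAsFactors = FALSE)
}

#' Two-sample equal-variance Student's t
#'
#' Pooled-variance t statistic and two-sided p on `n1 + n2 - 2` degrees of
#' freedom. Degenerate zero-variance, zero-difference inputs give t = 0,
#' p = 1.
#'
#' @param x,y numeric vectors (each length >= 2).
#' @return c(statistic, p).
#' @export
student_t2 <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  d <- mean(x) - mean(y)
  if (sp2 <= 0) {
    if (abs(d) < .Machine$double.eps^0.5) return(c(0, 1))
    return(c(sign(d) * Inf, 0))
  }
  tt <- d / sqrt(sp2 * (1 / n1 + 1 / n2))
  c(tt, 2 * pt(-abs(tt), df = n1 + n2 - 2))
}

#' Assign regulatory-divergence categories
#'
#' Rule table over the pFC/aFC/trans significance calls and the fold-change
#' signs:
#' cis only (pFC and aFC significant, trans not), trans only (pFC
#' significant, aFC not), cis + trans (all three significant, matching
#' signs; reinforcing when |pFC| > |aFC|, otherwise opposing), cis x trans
#' (all three significant, opposite signs), compensatory (pFC not
#' significant, aFC and trans significant), conserved (neither pFC nor aFC
#' significant), and ambiguous for every other combination. Ties
#' |pFC| = |aFC| fall to reinforcing (a measure-zero event).
#'
#' @param pFC,aFC numeric log2 fold-changes (signs and magnitudes used for
#'   the cis + trans split).
#' @param pFC_sig,aFC_sig logical significance calls.
#' @param trans_sig logical; may be `NA` where the trans test was not run
#'   (genes with neither pFC nor aFC significant).
#' @return factor over the eight category levels.
#' @export
classify_regulatory <- function(pFC, pFC_sig, aFC, aFC_sig, trans_sig) {
  n <- length(pFC)
  out <- rep("AMBIGUOUS", n)
  t_sig <- !is.na(trans_sig) & trans_sig
  t_not <- !is.na(trans_sig) & !trans_sig
  same_sign <- sign(pFC) == sign(aFC)
  out[!pFC_sig & !aFC_sig] <- "CONSERVED"
  out[pFC_sig & !aFC_sig] <- "TRANS_ONLY"
  out[pFC_sig & aFC_sig & t_not] <- "CIS_ONLY"
  out[pFC_sig & aFC_sig & t_sig & same_sign & abs(pFC) >= abs(aFC)] <-
    "CIS_TRANS_REINFORCING"
  out[pFC_sig & aFC_sig & t_sig & same_sign & abs(pFC) < abs(aFC)] <-
    "CIS_TRANS_OPPOSING"
  out[pFC_sig & aFC_sig & t_sig & !same_sign] <- "CIS_X_TRANS"
  out[!pFC_sig & aFC_sig & t_sig] <- "COMPENSATORY"
  # remaining reachable cells (e.g. aFC significant alone without trans
  # support, or untested trans where it was required) stay AMBIGUOUS
  factor(out, levels = REG_CATEGORIES)
}

#' Full regulatory-divergence analysis for one hybrid line and tissue
#'
#' Chains [compute_pfc()], [compute_afc()], [trans_test()] (on genes with
#' significant pFC or aFC) and [classify_regulatory()] over the
#' heterozygous-block genes, and flags the tissue when its misexpressed
#' fraction exceeds `caution_threshold` (inference from strongly disrupted
#' tissues should be read with caution).
#'
#' @param x total [count_matrix()].
#' @param allele_counts the [allele_count_matrix()].
#' @param design the [sample_design()].
#' @param line,tissue hybrid line and tissue analyzed.
#' @param block_genes heterozygous-block genes for `line`.
#' @param dispersions dispersions for the total-count model.
#' @param allele_dispersion dispersion for the allelic model (default: the
#'   common value of `dispersions` when available, else 0.05).
#' @param norm_factors optional TMM factors for the total model.
#' @param alpha FDR level (default 0.05).
#' @param misexpressed optional logical per block gene (or a gene-id
#'   character vector) marking misexpression, used only for the caution
#'   flag.
#' @param caution_threshold misexpressed-fraction threshold for the
#'   caution flag (default 0.10).
#' @return data.frame of class `"regdiv_result"`: per evaluated gene
#'   `gene_id`, `pFC`, `pFC_sig`, `aFC`, `aFC_sig`, `trans_stat`,
#'   `trans_p`, `trans_fdr`, `trans_sig`, `category`; attribute `caution`.
#' @export
regulatory_divergence <- function(x, allele_counts, design, line, tissue,
                                  block_genes, dispersions,
                                  allele_dispersion = NULL,
                                  norm_factors = NULL, alpha = 0.05,
                                  misexpressed = NULL,
                                  caution_threshold = 0.10) {
  if (is.null(allele_dispersion)) {
    allele_dispersion <- if (inherits(dispersions, "dispersion_estimates"))
      dispersions$common else 0.05
  }
  pfc <- compute_pfc(x, design, tissue, dispersions, alpha, norm_factors)
  afc <- compute_afc(allele_counts, design, line, tissue, block_genes,
                     dispersion = allele_dispersion, alpha = alpha)
  genes <- intersect(afc$gene_id, pfc$gene_id)
  pfc <- pfc[match(genes, pfc$gene_id), ]
  afc <- afc[match(genes, afc$gene_id), ]

  tested <- genes[pfc$pFC_sig | afc$aFC_sig]
  tt <- if (length(tested)) {
    samples_p <- function(ln) design$sample_id[design$line == ln &
                                                 design$tissue == tissue]
    cpm_tot <- cpm(x)
    hyb <- samples_p(line)
    # symmetric per-sample allelic depth, as in compute_afc
    tot <- rowSums(allele_counts$library_sizes[hyb, , drop = FALSE]) / 2
    acpm <- function(al) {
      m <- allele_counts$counts[genes, hyb, al, drop = TRUE]
      if (is.null(dim(m))) m <- matrix(m, nrow = length(genes),
                                       dimnames = list(genes, hyb))
      sweep(m, 2, pmax(tot, 1), "/") * 1e6
    }
    trans_test(cpm_tot[genes, samples_p("SF5"), drop = FALSE],
               cpm_tot[genes, samples_p("IM62"), drop = FALSE],
               acpm("SF5"), acpm("IM62"), tested, alpha = alpha)
  } else {
    data.frame(gene_id = character(), trans_stat = numeric(),
               trans_p = numeric(), trans_fdr = numeric(),
               trans_sig = logical())
  }
  m <- match(genes, tt$gene_id)
  out <- data.frame(
    gene_id = genes,
    pFC = pfc$pFC, pFC_sig = pfc$pFC_sig,
    aFC = afc$aFC, aFC_sig = afc$aFC_sig,
    trans_stat = tt$trans_stat[m], trans_p = tt$trans_p[m],
    trans_fdr = tt$trans_fdr[m], trans_sig = tt$trans_sig[m],
    stringsAsFactors = FALSE
  )
  out$category <- classify_regulatory(out$pFC, out$pFC_sig, out$aFC,
                                      out$aFC_sig, out$trans_sig)
  caution <- FALSE
  if (!is.null(misexpressed)) {
    if (is.character(misexpressed)) {
      misexpressed <- genes %in% misexpressed
    }
    frac <- mean(misexpressed)
    caution <- is.finite(frac) && frac > caution_threshold
  }
  attr(out, "caution") <- caution
  class(out) <- c("regdiv_result", "data.frame")
  out
}

#' Pearson chi-square test on a 2x2 table
#'
#' Without continuity correction: `chi2 = n (ad - bc)^2 / (r1 r2 c1 c2)`,
#' p from the chi-square distribution with 1 degree of freedom. All
#' marginals must be positive.
#'
#' @param table 2x2 non-negative integer matrix.
#' @return list with `chi2`, `p`, `df = 1`.
#' @export
chisq_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("table must be 2x2")
  if (any(table < 0)) stop("counts must be non-negative")
  r <- rowSums(table); cs <- colSums(table)
  if (any(r == 0) || any(cs == 0)) stop("zero marginal in 2x2 table")
  n <- sum(table)
  chi2 <- n * (table[1, 1] * table[2, 2] - table[1, 2] * table[2, 1])^2 /
    (r[1] * r[2] * cs[1] * cs[2])
  chi2 <- unname(chi2)
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE), df = 1)
}

#' Association between compensating regulation and misexpression
#'
#' Tests whether genes with compensating cis and trans changes (cis + trans
#' opposing, cis x trans, compensatory) are more often misexpressed than
#' (a) genes with conserved regulation and (b) genes with other forms of
#' regulatory divergence (cis only, trans only, cis + trans reinforcing).
#'
#' @param regdiv a [regulatory_divergence()] result (or data.frame with
#'   `gene_id` and `category`).
#' @param misexpressed character vector of misexpressed gene ids, or a
#'   logical aligned to `regdiv$gene_id`.
#' @return list with per-comparison elements (`vs_conserved`, `vs_other`),
#'   each holding the 2x2 `table`, `chi2`, `p`, and misexpressed
#'   percentages per group; comparisons with an empty group are reported
#'   as skipped.
#' @export
misexpression_association <- function(regdiv, misexpressed) {
  cat_chr <- as.character(regdiv$category)
  if (is.character(misexpressed)) {
    mis <- regdiv$gene_id %in% misexpressed
  } else {
    stopifnot(length(misexpressed) == nrow(regdiv))
    mis <- as.logical(misexpressed)
  }
  compensating <- cat_chr %in% c("CIS_TRANS_OPPOSING", "CIS_X_TRANS",
                                 "COMPENSATORY")
  conserved <- cat_chr == "CONSERVED"
  other <- cat_chr %in% c("CIS_ONLY", "TRANS_ONLY", "CIS_TRANS_REINFORCING")
  one <- function(g1, g2, n1, n2) {
    if (!any(g1) || !any(g2)) {
      return(list(skipped = TRUE, reason = "empty group"))
    }
    tab <- rbind(c(sum(mis[g1]), sum(!mis[g1])),
                 c(sum(mis[g2]), sum(!mis[g2])))
    dimnames(tab) <- list(c(n1, n2), c("misexpressed", "not"))
    test <- if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
      chisq_2x2(tab)
    } else list(chi2 = NA_real_, p = NA_real_, df = 1)
    list(skipped = FALSE, table = tab, chi2 = test$chi2, p = test$p,
         pct = setNames(100 * c(mean(mis[g1]), mean(mis[g2])), c(n1, n2)))
  }
  list(vs_conserved = one(compensating, conserved, "compensating", "conserved"),
       vs_other = one(compensating, other, "compensating", "other_divergent"))
}
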