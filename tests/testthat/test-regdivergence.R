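# Independent oracle for the seven-way rule table plus ambiguous.
oracle_regulatory <- function(p_sig, a_sig, t_sig, pFC, aFC) {
  if (!p_sig && !a_sig) return("CONSERVED")
  if (p_sig && !a_sig) return("TRANS_ONLY")
  if (p_sig && a_sig && !is.na(t_sig) && !t_sig) return("CIS_ONLY")
  if (p_sig && a_sig && !is.na(t_sig) && t_sig) {
    if (sign(pFC) == sign(aFC)) {
      return(if (abs(pFC) >= abs(aFC)) "CIS_TRANS_REINFORCING"
             else "CIS_TRANS_OPPOSING")
    }
    return("CIS_X_TRANS")
  }
  if (!p_sig && a_sig && !is.na(t_sig) && t_sig) return("COMPENSATORY")
  "AMBIGUOUS"
}

test_that("regulatory classifier equals the exhaustive enumeration oracle", {
  grid <- expand.grid(p_sig = c(TRUE, FALSE), a_sig = c(TRUE, FALSE),
                      t_sig = c(TRUE, FALSE, NA),
                      s_p = c(-1, 1), s_a = c(-1, 1),
                      mag = c("p_gt_a", "a_gt_p"),
                      stringsAsFactors = FALSE)
  pFC <- grid$s_p * ifelse(grid$mag == "p_gt_a", 3, 1)
  aFC <- grid$s_a * ifelse(grid$mag == "p_gt_a", 1, 3)
  got <- classify_regulatory(pFC, grid$p_sig, aFC, grid$a_sig, grid$t_sig)
  expected <- mapply(oracle_regulatory, grid$p_sig, grid$a_sig, grid$t_sig,
                     pFC, aFC)
  expect_equal(as.character(got), unname(expected))

  # the quoted rule-by-rule examples
  expect_equal(as.character(classify_regulatory(2, TRUE, 2, TRUE, FALSE)),
               "CIS_ONLY")
  expect_equal(as.character(classify_regulatory(0.1, FALSE, 0.2, FALSE, NA)),
               "CONSERVED")
  expect_equal(as.character(classify_regulatory(0.1, FALSE, 2, TRUE, TRUE)),
               "COMPENSATORY")
  expect_equal(as.character(classify_regulatory(2, TRUE, 0.3, FALSE, TRUE)),
               "TRANS_ONLY")
  # tie |pFC| = |aFC| falls to reinforcing
  expect_equal(as.character(classify_regulatory(2, TRUE, 2, TRUE, TRUE)),
               "CIS_TRANS_REINFORCING")

  # allele-label swap: negating both fold-changes fixes every category
  got_swapped <- classify_regulatory(-pFC, grid$p_sig, -aFC, grid$a_sig,
                                     grid$t_sig)
  expect_equal(as.character(got_swapped), as.character(got))
})

test_that("Student's t matches the closed form and stats::t.test", {
  x <- c(1.0, 1.1, 0.9); y <- c(3.0, 3.1, 2.9)
  res <- student_t2(x, y)
  # hand computation: pooled sd with 4 df
  sp2 <- (2 * var(x) + 2 * var(y)) / 4
  t_hand <- (mean(x) - mean(y)) / sqrt(sp2 * (2 / 3))
  expect_equal(res[1], t_hand)
  expect_equal(res[2], 2 * pt(-abs(t_hand), 4))
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(res[1], unname(ref$statistic))
  expect_equal(res[2], ref$p.value)
  # identical samples: t = 0, p = 1
  expect_equal(student_t2(c(1, 1, 1), c(1, 1, 1)), c(0, 1))
})

test_that("trans test flags pFC/aFC discrepancies and respects pairing", {
  genes <- c("gA", "gB")
  mk <- function(vals) matrix(rep(vals, each = 2), 2, 3, byrow = FALSE,
                              dimnames = list(genes, paste0("r", 1:3)))
  p_sf5 <- matrix(c(8, 8, 8, 8, 8, 8), 2, 3, dimnames = list(genes, NULL))
  p_im62 <- p_sf5
  h_sf5 <- p_sf5
  h_im62 <- p_sf5
  # gA: parents equal, alleles 4-fold apart -> strong trans signal
  h_im62["gA", ] <- c(32, 33, 31)
  res <- trans_test(p_sf5, p_im62, h_sf5, h_im62, genes)
  expect_lt(res$trans_p[res$gene_id == "gA"], 0.01)
  expect_gt(res$trans_p[res$gene_id == "gB"], 0.9)
  expect_equal(res$trans_fdr, bh_fdr(res$trans_p))

  # untestable gene: fewer than two finite replicates reported as NA
  h_bad <- h_sf5; h_bad["gB", 2:3] <- NA
  res2 <- trans_test(p_sf5, p_im62, h_bad, h_im62, genes)
  expect_true(is.na(res2$trans_p[res2$gene_id == "gB"]))
  expect_true(is.na(res2$trans_sig[res2$gene_id == "gB"]))
})

test_that("pFC and aFC recover the generative effects with correct signs", {
  fx <- recovery_fixture(seed = 11)
  tr <- fx$truth
  pfc <- compute_pfc(fx$counts, fx$design, "carpel", fx$dispersions,
                     norm_factors = fx$norm_factors)
  m <- match(pfc$gene_id, tr$gene_id)
  cis <- tr$true_regulatory_category[m] == "cis_only"
  # sign convention log2(SF5/IM62): a positive cis effect (IM62 up) gives
  # negative pFC
  expect_equal(pfc$pFC[cis], -(tr$cis_log2 + tr$trans_log2)[m][cis],
               tolerance = 0.25)
  # null pFC significance rate near alpha
  consv <- tr$true_regulatory_category[m] == "conserved" &
    tr$baseline_log2[m] > 2
  expect_lt(mean(pfc$pFC_sig[consv]), 0.12)

  block_genes <- intersect(tr$gene_id[tr$het_STE], pfc$gene_id)
  afc <- compute_afc(fx$allele_counts, fx$design, "STE", "carpel",
                     block_genes, dispersion = fx$dispersions$common)
  m2 <- match(afc$gene_id, tr$gene_id)
  # every heterozygous gene's allelic imbalance is its cis effect,
  # whatever the category: aFC = -c under the log2(SF5/IM62) convention
  has_cis <- tr$cis_log2[m2] != 0
  expect_true(sum(has_cis) >= 3)
  dev <- afc$aFC[has_cis] + tr$cis_log2[m2][has_cis]
  expect_true(all(sign(afc$aFC[has_cis]) == sign(-tr$cis_log2[m2][has_cis])))
  expect_lt(median(abs(dev)), 0.4)  # per-gene noise at 3 replicates
  consv2 <- tr$true_regulatory_category[m2] == "conserved"
  expect_lt(mean(afc$aFC_sig[consv2]), 0.12)

  # genes outside the blocks are excluded with a warning
  outside <- setdiff(pfc$gene_id, block_genes)[1]
  expect_warning(
    compute_afc(fx$allele_counts, fx$design, "STE", "carpel", block_genes,
                genes = c(block_genes[1:3], outside),
                dispersion = fx$dispersions$common),
    "outside")
})

test_that("chi-square 2x2 matches the closed form and reference values", {
  expect_equal(chisq_2x2(matrix(c(10, 10, 10, 10), 2))$chi2, 0)
  expect_equal(chisq_2x2(matrix(c(10, 10, 10, 10), 2))$p, 1)
  res <- chisq_2x2(matrix(c(20, 30, 30, 20), 2))
  expect_equal(res$chi2, 4)
  ref <- chisq.test(matrix(c(20, 30, 30, 20), 2), correct = FALSE)
  expect_equal(res$chi2, unname(ref$statistic))
  expect_equal(res$p, ref$p.value)
  expect_error(chisq_2x2(matrix(c(0, 0, 5, 5), 2)), "marginal")
  # the worked reference example: chi2 = 3.77 on 1 df prints as p = 0.052
  expect_equal(round(pchisq(3.77, 1, lower.tail = FALSE), 3), 0.052)
})

test_that("misexpression association finds a constructed enrichment", {
  n <- 300
  cats <- rep(c("COMPENSATORY", "CONSERVED", "CIS_ONLY"), each = 100)
  genes <- sprintf("g%03d", 1:n)
  rd <- data.frame(gene_id = genes,
                   category = factor(cats, levels = asepartition:::REG_CATEGORIES))
  # force compensatory genes to be misexpressed
  mis <- c(rep(TRUE, 80), rep(FALSE, 20), rep(TRUE, 20), rep(FALSE, 80),
           rep(TRUE, 20), rep(FALSE, 80))
  res <- misexpression_association(rd, mis)
  expect_false(res$vs_conserved$skipped)
  expect_lt(res$vs_conserved$p, 1e-6)
  expect_gt(res$vs_conserved$pct[["compensating"]],
            res$vs_conserved$pct[["conserved"]])
  # marginals conserved
  expect_equal(sum(res$vs_conserved$table), 200)
  expect_equal(unname(rowSums(res$vs_conserved$table)), c(100, 100))

  # identical fractions give chi2 ~ 0
  mis_eq <- rep(c(TRUE, FALSE), 150)
  res_eq <- misexpression_association(rd, mis_eq)
  expect_lt(res_eq$vs_conserved$chi2, 1e-9)

  # empty group comparisons are skipped, not errored
  rd2 <- rd; rd2$category[rd2$category == "CONSERVED"] <- "CIS_ONLY"
  res2 <- misexpression_association(rd2, mis)
  expect_true(res2$vs_conserved$skipped)
})

test_that("full regulatory partition recovers large-effect categories", {
  fx <- recovery_fixture(seed = 11)
  gt <- genotype_line(fx$allele_counts, fx$design, "FER", fx$annotation)
  bg <- intersect(genes_in_blocks(gt$blocks, fx$annotation),
                  rownames(fx$counts$counts))
  rd <- regulatory_divergence(fx$counts, fx$allele_counts, fx$design,
                              "FER", "carpel", bg, fx$dispersions,
                              norm_factors = fx$norm_factors)
  tr <- fx$truth[match(rd$gene_id, fx$truth$gene_id), ]
  map <- c(cis_only = "CIS_ONLY", trans_only = "TRANS_ONLY",
           compensatory = "COMPENSATORY", conserved = "CONSERVED")
  i <- tr$true_regulatory_category %in% names(map)
  acc <- mean(as.character(rd$category[i]) ==
                map[tr$true_regulatory_category[i]])
  expect_gt(acc, 0.8)
  # categories partition the evaluated genes
  expect_equal(sum(table(rd$category)), nrow(rd))
  # trans tested iff pFC or aFC significant
  expect_true(all(is.na(rd$trans_sig) == !(rd$pFC_sig | rd$aFC_sig)))
})

test_that("for cis-only genes aFC tracks pFC with unit slope", {
  # dedicated fixture: many cis-only genes inside a whole-chromosome block
  cfg <- sim_config(n_genes = 504, seed = 29,
                    fractions = c(cis_only = 0.5),
                    misexpressed_fraction = 0,
                    blocks = list(list(lines = c("FER", "STE"),
                                       chromosome = "chr11",
                                       from = 1, to = 36)))
  st <- simulate_truth(cfg)
  sim <- simulate_counts(st$truth, st$design, cfg)
  xf <- subset_genes(sim$counts,
                     intersect(st$annotation$gene_id,
                               filter_expressed(sim$counts)))
  nf <- tmm_norm_factors(xf)
  disp <- estimate_dispersions(xf, st$design, norm_factors = nf)
  bg <- intersect(st$truth$gene_id[st$truth$het_FER], rownames(xf$counts))
  rd <- regulatory_divergence(xf, sim$allele_counts, st$design, "FER",
                              "carpel", bg, disp, norm_factors = nf)
  tr <- st$truth[match(rd$gene_id, st$truth$gene_id), ]
  ci <- tr$true_regulatory_category == "cis_only"
  expect_gte(sum(ci), 10)
  slope <- coef(lm(rd$aFC[ci] ~ 0 + rd$pFC[ci]))[[1]]
  expect_gt(slope, 0.9)
  expect_lt(slope, 1.1)
  # trans-only genes keep aFC near zero
  to <- tr$true_regulatory_category == "trans_only"
  if (any(to)) expect_lt(max(abs(rd$aFC[to])), 0.75)
})
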