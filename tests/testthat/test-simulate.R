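test_that("truth generation is deterministic with exact category counts", {
  cfg <- sim_config(n_genes = 1000, seed = 9,
                    fractions = c(compensatory = 0.10, cis_only = 0.05))
  t1 <- simulate_truth(cfg)
  t2 <- simulate_truth(cfg)
  expect_identical(t1$truth, t2$truth)
  # deterministic allocation by count, not coin flips
  expect_equal(sum(t1$truth$true_regulatory_category == "compensatory"), 100)
  expect_equal(sum(t1$truth$true_regulatory_category == "cis_only"), 50)
  # compensatory effects cancel exactly
  comp <- t1$truth[t1$truth$true_regulatory_category == "compensatory", ]
  expect_equal(comp$cis_log2, -comp$trans_log2)

  # all fractions zero: every gene conserved with c = r = 0
  cfg0 <- sim_config(n_genes = 200, seed = 1,
                     fractions = c(cis_only = 0), misexpressed_fraction = 0)
  t0 <- simulate_truth(cfg0)$truth
  expect_true(all(t0$true_regulatory_category == "conserved"))
  expect_true(all(t0$cis_log2 == 0 & t0$trans_log2 == 0))

  expect_error(sim_config(n_genes = 100,
                          fractions = c(cis_only = 0.7, trans_only = 0.5)),
               "sum to at most 1")
})

test_that("simulated counts reproduce the generative means at low dispersion", {
  design <- default_design()
  cfg <- sim_config(n_genes = 40, seed = 2, library_size_mean = 1e7,
                    library_size_sdlog = 0, dispersion = 1e-8)

  # target library sizes are identical (sdlog = 0), so raw counts compare
  # directly; actual column sums differ by construction when all genes
  # share a cis effect
  group_mean <- function(counts, lib, design, line, tissue) {
    s <- design$sample_id[design$line == line & design$tissue == tissue]
    rowMeans(counts[, s, drop = FALSE])
  }

  # cis-only gene with c = 2: parental and hybrid allelic log2 ratios -> 2
  # (per-gene deviations are Poisson sampling noise at 3 replicates; the
  # 0.05 check applies to the gene-averaged estimate)
  truth <- manual_truth(40, baseline = 9, c_eff = 2, phi = 1e-8)
  sim <- simulate_counts(truth, design, cfg)
  lib <- sim$counts$library_sizes
  par_ratio <- log2(group_mean(sim$counts$counts, lib, design, "IM62", "stamen") /
                    group_mean(sim$counts$counts, lib, design, "SF5", "stamen"))
  expect_true(all(abs(par_ratio - 2) < 0.2))
  expect_lt(abs(mean(par_ratio) - 2), 0.05)
  hyb <- design$sample_id[design$line == "STE" & design$tissue == "carpel"]
  allelic <- log2(rowMeans(sim$allele_counts$counts[, hyb, "IM62"]) /
                  rowMeans(sim$allele_counts$counts[, hyb, "SF5"]))
  expect_true(all(abs(allelic - 2) < 0.2))
  expect_lt(abs(mean(allelic) - 2), 0.05)

  # compensatory gene (c = 2, r = -2, m = 1): parents equal, alleles differ
  truth <- manual_truth(40, baseline = 9, c_eff = 2, r_eff = -2, m = 1,
                        phi = 1e-8)
  sim <- simulate_counts(truth, design, cfg)
  lib <- sim$counts$library_sizes
  par_ratio <- log2(group_mean(sim$counts$counts, lib, design, "IM62", "stamen") /
                    group_mean(sim$counts$counts, lib, design, "SF5", "stamen"))
  expect_true(all(abs(par_ratio) < 0.2))
  expect_lt(abs(mean(par_ratio)), 0.05)
  allelic <- log2(rowMeans(sim$allele_counts$counts[, hyb, "IM62"]) /
                  rowMeans(sim$allele_counts$counts[, hyb, "SF5"]))
  expect_true(all(abs(allelic - 2) < 0.2))
  expect_lt(abs(mean(allelic) - 2), 0.05)
})

test_that("count simulation is deterministic and conserves allelic totals", {
  cfg <- sim_config(n_genes = 150, seed = 4)
  st <- simulate_truth(cfg)
  s1 <- simulate_counts(st$truth, st$design, cfg)
  s2 <- simulate_counts(st$truth, st$design, cfg)
  expect_identical(s1$counts$counts, s2$counts$counts)
  expect_identical(s1$allele_counts$counts, s2$allele_counts$counts)
  # allelic counts never exceed totals
  allelic_sum <- s1$allele_counts$counts[, , 1] + s1$allele_counts$counts[, , 2]
  expect_true(all(allelic_sum <= s1$counts$counts))

  # with no unassignable reads, allelic counts sum exactly to totals
  cfg0 <- sim_config(n_genes = 100, seed = 4, nonallelic_fraction = 0)
  st0 <- simulate_truth(cfg0)
  s0 <- simulate_counts(st0$truth, st0$design, cfg0)
  asum <- s0$allele_counts$counts[, , 1] + s0$allele_counts$counts[, , 2]
  expect_identical(unname(asum), unname(s0$counts$counts))
})

test_that("misexpression is confined to STE stamens", {
  cfg <- sim_config(n_genes = 400, seed = 6, misexpressed_fraction = 0.25,
                    fractions = c(cis_only = 0))
  st <- simulate_truth(cfg)
  mm_ste_st <- expected_log2_means(st$truth, "STE", "stamen")
  mm_ste_cp <- expected_log2_means(st$truth, "STE", "carpel")
  mm_fer_st <- expected_log2_means(st$truth, "FER", "stamen")
  mis <- st$truth$misexpression_log2 != 0
  expect_equal(sum(mis), 100)
  d <- st$truth$misexpression_log2[mis]
  expect_equal(mm_ste_st$hybrid_total[mis] - mm_fer_st$hybrid_total[mis],
               d, tolerance = 1e-12)
  expect_equal(mm_ste_cp$hybrid_total[mis],
               expected_log2_means(st$truth, "FER", "carpel")$hybrid_total[mis])
})

test_that("RSB crossing simulator matches the scheme's expectations", {
  r <- simulate_rsb_cross(10000, seed = 3)
  expect_equal(mean(!r$fertile), 0.5, tolerance = 0.015)
  # sterility is exactly the hms1-het x hms2-SF5/SF5 combination
  expect_true(all(r$fertile == (r$hms1 == "SF5/SF5")))
  expect_true(all(r$hms2 == "SF5/SF5"))
  # drive transmission ~98%
  expect_equal(mean(r$chr11 == "IM62/SF5"), 0.98, tolerance = 0.01)
  # background heterozygosity: 0.5 / 2^8, printing as 0.2%
  expect_equal(expected_het_fraction(8), 0.5 / 2^8)
  expect_equal(round(100 * expected_het_fraction(8), 1), 0.2)
  expect_lt(abs(mean(r$het_fraction) - expected_het_fraction(8)), 2e-4)

  expect_true(all(simulate_rsb_cross(200, drive_transmission = 1,
                                     seed = 1)$chr11 == "IM62/SF5"))
  expect_error(simulate_rsb_cross(0), "positive")
})
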