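make_acm <- function(im62, sf5, design) {
  genes <- rownames(im62)
  arr <- array(0, dim = c(nrow(im62), nrow(design), 2),
               dimnames = list(genes, design$sample_id, c("IM62", "SF5")))
  arr[, , "IM62"] <- im62
  arr[, , "SF5"] <- sf5
  allele_count_matrix(arr)
}

test_that("binarization applies the depth floor at the documented boundary", {
  design <- default_design(n_reps = 1)
  genes <- c("g1", "g2", "g3")
  im62 <- matrix(0, 3, 8, dimnames = list(genes, design$sample_id))
  sf5 <- im62
  ste <- design$sample_id[design$line == "STE"]
  im62["g1", ste] <- c(5, 4)   # pooled 9 -> absent
  im62["g2", ste] <- c(5, 5)   # pooled 10 -> present
  sf5["g2", ste] <- c(20, 20)
  acm <- make_acm(im62, sf5, design)
  b <- binarize_allele_counts(acm, design, "STE")
  expect_equal(unname(b["g1", ]), c(0, 0))
  expect_equal(unname(b["g2", ]), c(1, 1))
  expect_equal(unname(b["g3", ]), c(0, 0))

  # threshold-first: two sub-threshold libraries never sum to presence
  b2 <- binarize_allele_counts(acm, design, "STE", order = "threshold-first")
  expect_equal(unname(b2["g2", "IM62"]), 0)  # 5 and 5 both below 10
  expect_equal(unname(b2["g2", "SF5"]), 1)   # 20 passes alone
})

test_that("genotype calls follow the binary table and flag hybrid IM62 calls", {
  b <- matrix(c(1, 1, 0, 0,
                0, 1, 1, 0), ncol = 2,
              dimnames = list(paste0("g", 1:4), c("IM62", "SF5")))
  calls <- call_genotypes(b, "FER")
  expect_equal(as.character(calls$call),
               c("IM62", "HET", "SF5", "NONEXPRESSED"))
  expect_equal(calls$flagged_erroneous, c(TRUE, FALSE, FALSE, FALSE))
  # parents are never flagged
  expect_false(any(call_genotypes(b, "IM62")$flagged_erroneous))
})

test_that("block detection applies the run rule from the worked example", {
  ann <- gene_annotation(paste0("g", 1:6), "chr6",
                         start = (0:5) * 1000 + 1, end = (0:5) * 1000 + 500)
  calls <- data.frame(
    gene_id = paste0("g", 1:6), line = "STE",
    call = factor(c("SF5", "HET", "HET", "NONEXPRESSED", "HET", "SF5"),
                  levels = c("IM62", "HET", "SF5", "NONEXPRESSED")),
    flagged_erroneous = FALSE, stringsAsFactors = FALSE)
  blocks <- find_introgression_blocks(calls, ann)
  expect_equal(nrow(blocks), 1)
  expect_equal(blocks$first_gene, "g2")
  expect_equal(blocks$last_gene, "g5")
  expect_equal(blocks$n_genes, 4)
  expect_equal(blocks$n_expressed, 3)
  expect_equal(blocks$start_bp, 1001)
  expect_equal(blocks$end_bp, 4500)
  # outer bounds run to just inside the flanking SF5 genes
  expect_equal(blocks$outer_start_bp, 501)
  expect_equal(blocks$outer_end_bp, 5000)

  # all-SF5 chromosome yields no blocks
  calls$call[] <- "SF5"
  expect_equal(nrow(find_introgression_blocks(calls, ann)), 0)

  # flagged erroneous calls behave like NONEXPRESSED
  calls$call <- factor(c("SF5", "HET", "IM62", "HET", "HET", "SF5"),
                       levels = levels(calls$call))
  calls$flagged_erroneous <- calls$call == "IM62"
  b2 <- find_introgression_blocks(calls, ann)
  expect_equal(nrow(b2), 1)
  expect_equal(b2$n_genes, 4)

  # unordered input is refused
  expect_error(find_introgression_blocks(calls[c(2, 1, 3:6), ], ann),
               "ordered")
})

test_that("planted introgression blocks are recovered exactly when expressed", {
  cfg <- sim_config(n_genes = 560, seed = 8, baseline_mean = 7,
                    baseline_sd = 0.5, misexpressed_fraction = 0)
  st <- simulate_truth(cfg)
  sim <- simulate_counts(st$truth, st$design, cfg)
  for (line in c("STE", "FER")) {
    gt <- genotype_line(sim$allele_counts, st$design, line, st$annotation)
    truth_genes <- st$truth$gene_id[st$truth[[paste0("het_", line)]]]
    found <- genes_in_blocks(gt$blocks, st$annotation)
    expect_setequal(found, truth_genes)
    chroms <- unique(st$truth$chromosome[st$truth[[paste0("het_", line)]]])
    expect_setequal(unique(gt$blocks$chromosome), chroms)
  }
  # STE carries chr6 + chr11, FER only chr11
  gt_ste <- genotype_line(sim$allele_counts, st$design, "STE", st$annotation)
  gt_fer <- genotype_line(sim$allele_counts, st$design, "FER", st$annotation)
  expect_setequal(gt_ste$blocks$chromosome, c("chr6", "chr11"))
  expect_setequal(gt_fer$blocks$chromosome, "chr11")
})

test_that("pure-parent lines give no false HET calls; errors scale with misassignment", {
  base_cfg <- function(eps) {
    sim_config(n_genes = 300, seed = 15, baseline_mean = 7, baseline_sd = 0.5,
               allele_misassignment = eps)
  }
  het_rate <- function(eps) {
    cfg <- base_cfg(eps)
    st <- simulate_truth(cfg)
    sim <- simulate_counts(st$truth, st$design, cfg)
    b <- binarize_allele_counts(sim$allele_counts, st$design, "SF5")
    calls <- call_genotypes(b[sort_annotation(st$annotation)$gene_id, ], "SF5")
    mean(calls$call == "HET")
  }
  r0 <- het_rate(0)
  expect_equal(r0, 0)
  r1 <- het_rate(0.002)
  r2 <- het_rate(0.05)
  expect_true(r0 <= r1 && r1 <= r2)
  expect_gt(r2, 0)
})

test_that("blocks export as 0-based half-open BED", {
  blocks <- data.frame(line = "STE", chromosome = "chr6",
                       first_gene = "g1", last_gene = "g2",
                       start_bp = 1001L, end_bp = 4501L,
                       outer_start_bp = 502L, outer_end_bp = 5000L,
                       n_genes = 4L, n_expressed = 3L)
  path <- withr::local_tempfile(fileext = ".bed")
  write_blocks_bed(blocks, path)
  bed <- read.delim(path, header = FALSE)
  expect_equal(bed$V2, 1000)
  expect_equal(bed$V3, 4501)
})
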