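# Independent hand-coded oracle for the eight-category decision table,
# written cell by cell rather than by the package's masking logic.
oracle_inheritance <- function(A, B, P, fc_A, fc_B) {
  between <- sign(fc_A) * sign(fc_B) <= 0
  if (!A && !B && !P) return("SIMILAR")
  if (!A && B && !P) return("SF5_LIKE_SIMILAR")
  if (!A && B && P) return("SF5_LIKE_DIVERGENT")
  if (A && !B && !P) return("IM62_LIKE_SIMILAR")
  if (A && !B && P) return("IM62_LIKE_DIVERGENT")
  if (!A && !B && P) return("INTERMEDIATE_DIVERGENT")
  if (A && B && P) {
    return(if (between) "INTERMEDIATE_DIVERGENT" else "MISEXPRESSED_DIVERGENT")
  }
  # A && B && !P
  if (between) "UNCLASSIFIABLE" else "MISEXPRESSED_SIMILAR"
}

test_that("inheritance classifier equals the exhaustive enumeration oracle", {
  grid <- expand.grid(A = c(TRUE, FALSE), B = c(TRUE, FALSE),
                      P = c(TRUE, FALSE), sA = c(-1, 1), sB = c(-1, 1))
  genes <- sprintf("g%02d", seq_len(nrow(grid)))
  fc_A <- grid$sA * 2
  fc_B <- grid$sB * 1.5
  res <- classify_inheritance(
    fake_de(genes, fc_A, grid$A),
    fake_de(genes, fc_B, grid$B),
    fake_de(genes, fc_A - fc_B, grid$P)
  )
  expected <- mapply(oracle_inheritance, grid$A, grid$B, grid$P, fc_A, fc_B)
  expect_equal(as.character(res$category), unname(expected))

  # worked examples from the category definitions
  expect_equal(as.character(res$category[!grid$A & !grid$B & !grid$P][1]),
               "SIMILAR")
  # misexpression direction: above both parents = over
  over <- res$category == "MISEXPRESSED_SIMILAR" & fc_A > 0
  expect_true(all(res$direction[over] == "over"))
  under <- res$category %in% c("MISEXPRESSED_SIMILAR",
                               "MISEXPRESSED_DIVERGENT") & fc_A < 0
  expect_true(all(res$direction[under] == "under"))
  # ambiguous cells carry their flags
  expect_true(all(res$flag[res$category == "UNCLASSIFIABLE"] ==
                    "unclassifiable"))
  noP <- !grid$A & !grid$B & grid$P
  expect_true(all(res$flag[noP] == "intermediate (no test significant)"))

  # categories partition the gene set
  expect_equal(sum(table(res$category)), length(genes))

  expect_error(classify_inheritance(fake_de(genes, fc_A, grid$A),
                                    fake_de(genes[-1], fc_B[-1], grid$B[-1]),
                                    fake_de(genes, fc_A, grid$P)),
               "different gene sets|missing")
})

test_that("swapping parent labels mirrors the SF5/IM62 categories", {
  set.seed(61)
  n <- 200
  genes <- sprintf("g%03d", 1:n)
  A <- runif(n) < 0.4; B <- runif(n) < 0.4; P <- runif(n) < 0.5
  fc_A <- rnorm(n); fc_B <- rnorm(n)
  orig <- classify_inheritance(fake_de(genes, fc_A, A),
                               fake_de(genes, fc_B, B),
                               fake_de(genes, fc_A - fc_B, P))
  # swap: hybrid-vs-SF5 becomes hybrid-vs-IM62 and the parent contrast flips
  swap <- classify_inheritance(fake_de(genes, fc_B, B),
                               fake_de(genes, fc_A, A),
                               fake_de(genes, fc_B - fc_A, P))
  map <- c(SIMILAR = "SIMILAR",
           SF5_LIKE_SIMILAR = "IM62_LIKE_SIMILAR",
           SF5_LIKE_DIVERGENT = "IM62_LIKE_DIVERGENT",
           IM62_LIKE_SIMILAR = "SF5_LIKE_SIMILAR",
           IM62_LIKE_DIVERGENT = "SF5_LIKE_DIVERGENT",
           INTERMEDIATE_DIVERGENT = "INTERMEDIATE_DIVERGENT",
           MISEXPRESSED_SIMILAR = "MISEXPRESSED_SIMILAR",
           MISEXPRESSED_DIVERGENT = "MISEXPRESSED_DIVERGENT",
           UNCLASSIFIABLE = "UNCLASSIFIABLE")
  expect_equal(as.character(swap$category),
               unname(map[as.character(orig$category)]))
})

test_that("misexpression recall and false positives on simulated data", {
  # large |delta| misexpression with all other effects zero
  cfg <- sim_config(n_genes = 600, seed = 71, fractions = c(cis_only = 0),
                    misexpressed_fraction = 0.2,
                    misexpression_range = c(2.5, 4))
  st <- simulate_truth(cfg)
  sim <- simulate_counts(st$truth, st$design, cfg)
  xf <- subset_genes(sim$counts,
                     intersect(st$annotation$gene_id,
                               filter_expressed(sim$counts)))
  nf <- tmm_norm_factors(xf)
  disp <- estimate_dispersions(xf, st$design, norm_factors = nf)
  de <- function(a, b, ts) {
    test_contrast(xf, st$design, disp,
                  paste0(a, "_", ts, " - ", b, "_", ts),
                  norm_factors = nf)
  }
  tr <- st$truth[match(rownames(xf$counts), st$truth$gene_id), ]
  mis_true <- tr$misexpression_log2 != 0

  inh_ste <- classify_inheritance(de("STE", "SF5", "stamen"),
                                  de("STE", "IM62", "stamen"),
                                  de("SF5", "IM62", "stamen"))
  called <- grepl("^MISEXPRESSED", inh_ste$category)
  expect_gt(sum(called & mis_true) / sum(mis_true), 0.9)   # recall
  # FER stamens carry no misexpression: false-positive rate <= 5%
  inh_fer <- classify_inheritance(de("FER", "SF5", "stamen"),
                                  de("FER", "IM62", "stamen"),
                                  de("SF5", "IM62", "stamen"))
  expect_lt(mean(grepl("^MISEXPRESSED", inh_fer$category)), 0.05)
  # direction matches the sign of the planted effect
  dir_true <- ifelse(tr$misexpression_log2 > 0, "over", "under")
  hit <- called & mis_true
  expect_gt(mean(inh_ste$direction[hit] == dir_true[hit]), 0.95)
})

test_that("tissue-bias grid collapses to the nine joint categories", {
  grid <- expand.grid(s = c("stamen", "carpel", "none"),
                      g = c("stamen", "carpel", "none"),
                      stringsAsFactors = FALSE)
  genes <- sprintf("g%02d", seq_len(nrow(grid)))
  fc_of <- function(b) ifelse(b == "stamen", 2, ifelse(b == "carpel", -2, 0.3))
  res <- classify_tissue_bias(
    fake_de(genes, fc_of(grid$s), grid$s != "none"),
    fake_de(genes, fc_of(grid$g), grid$g != "none"))
  expected <- c("BOTH_STAMEN", "OPPOSING_SF5CARPEL_IM62STAMEN",
                "IM62_ONLY_STAMEN", "OPPOSING_SF5STAMEN_IM62CARPEL",
                "BOTH_CARPEL", "IM62_ONLY_CARPEL", "SF5_ONLY_STAMEN",
                "SF5_ONLY_CARPEL", "UNBIASED")
  expect_equal(as.character(res$category), expected)
  expect_equal(sum(table(res$category)), nrow(grid))
})

test_that("bias cross-tabulation counts and percentages match direct counting", {
  genes <- sprintf("g%02d", 1:20)
  cats <- rep(c("BOTH_STAMEN", "SF5_ONLY_STAMEN", "BOTH_CARPEL", "UNBIASED"),
              each = 5)
  bias <- data.frame(gene_id = genes,
                     category = factor(cats,
                                       levels = asepartition:::TISSUE_BIAS_CATEGORIES))
  tab <- crosstab_bias_by_deset(bias, list(all = genes,
                                           first = genes[1:10],
                                           none = character(0)))
  expect_equal(tab$stamen_any, c(10, 10, 0))
  expect_equal(tab$carpel_any, c(5, 0, 0))
  expect_equal(tab$pct_stamen_any, c(50, 100, 0))
  expect_equal(tab$n, c(20, 10, 0))
  expect_error(crosstab_bias_by_deset(bias, list(bad = "gX")), "unknown gene")

  # the printed-style percentage helper reproduces reported roundings
  expect_equal(pct_of(1715, 2062), 83)
  expect_equal(pct_of(3953, 5344), 74)
})
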