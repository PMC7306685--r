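# Ground-truth generator. Emulates the 24-library crossing design at the
# count level: per-gene cis (c), trans (r), dominance-modifier (m) and
# misexpression (delta) effects on a log2-CPM scale, negative-binomial
# sampling, heterozygous introgression blocks on two chromosomes, and a
# forward simulator of the recurrent-selection backcross (RSB) scheme.
#
# Expression model (log2 scale, relative to baseline b + tissue effect t):
#   SF5 parent total:          b + t
#   IM62 parent total:         b + t + c + r
#   hybrid, heterozygous gene: SF5 allele  b + t - 1 + m*r
#                              IM62 allele b + t - 1 + c + m*r
#   hybrid, background gene:   total b + t + m*r (both alleles SF5)
# The -1 halves each allele in heterozygotes so that total hybrid expression
# is conserved when c = 0 (additive inheritance is the null). Misexpression
# delta is added to every allelic mean of affected genes in STE stamens
# only. m is the fraction of the IM62 trans effect expressed in the hybrid
# background (0 when the unmodeled trans factor lies in the SF5 background,
# 0.5 when it is flagged as inside a heterozygous introgression).

GEN_REG_CATEGORIES <- c("conserved", "cis_only", "trans_only",
                        "cis_trans_reinforcing", "cis_trans_opposing",
                        "cis_x_trans", "compensatory")

#' Configuration for the synthetic-data generator
#'
#' Defaults mirror the motivating study design: 14 chromosomes, a
#' heterozygous donor block on chromosome 6 present in STE only (the
#' sterility-associated introgression) and a block on chromosome 11 present
#' in both FER and STE (the drive-associated introgression), three
#' replicates, and a 22% misexpressed fraction in STE stamens.
#'
#' @param n_genes number of genes (default 2000, a desk-scale stand-in for
#'   the genome-wide gene set).
#' @param n_chromosomes number of chromosomes (default 14).
#' @param blocks list of heterozygous introgression blocks, each a list with
#'   `lines` (character), `chromosome` (e.g. `"chr6"`), and `from`/`to`
#'   (1-based gene indices within that chromosome, inclusive). Blocks must
#'   not overlap.
#' @param library_size_mean,library_size_sdlog lognormal library-size model
#'   (defaults 5e6 and 0.1).
#' @param fractions named fractions of genes per generated regulatory
#'   category (`cis_only`, `trans_only`, `cis_trans_reinforcing`,
#'   `cis_trans_opposing`, `cis_x_trans`, `compensatory`); the remainder is
#'   `conserved`. Must sum to at most 1. Allocation is deterministic by
#'   count (`round(fraction * n_genes)`), placement is random.
#' @param misexpressed_fraction fraction of genes given a misexpression
#'   effect in STE stamens (default 0.22).
#' @param effect_range range of |c| and |r| magnitudes, log2 units
#'   (default `c(2, 3)`).
#' @param misexpression_range range of |delta|, log2 units (default `c(2, 4)`).
#' @param baseline_mean,baseline_sd normal model for baseline log2 CPM
#'   (defaults 4 and 2).
#' @param tissue_effect_sd sd of the per-gene stamen-vs-carpel log2 effect
#'   (default 1.5; carpel is the reference tissue).
#' @param dispersion negative-binomial dispersion phi (default 0.05).
#' @param nonallelic_fraction fraction of reads that carry no diagnostic SNP
#'   and are counted in the total matrix only (default 0.43, the
#'   study-reported share of primary non-allele-specific alignments).
#' @param allele_misassignment probability that an allele-specific read is
#'   assigned to the wrong allele (default 0).
#' @param trans_in_introgression_fraction fraction of trans-affected genes
#'   whose (unmodeled) trans factor is flagged as lying inside a
#'   heterozygous introgression, giving hybrid trans modifier m = 0.5
#'   instead of 0 (default 0.15).
#' @param seed integer seed; all draws flow from it in documented order.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_genes = 2000,
                       n_chromosomes = 14,
                       blocks = NULL,
                       library_size_mean = 5e6,
                       library_size_sdlog = 0.1,
                       fractions = c(cis_only = 0.05, trans_only = 0.05,
                                     cis_trans_reinforcing = 0.02,
                                     cis_trans_opposing = 0.01,
                                     cis_x_trans = 0.01, compensatory = 0.02),
                       misexpressed_fraction = 0.22,
                       effect_range = c(2, 3),
                       misexpression_range = c(2, 4),
                       baseline_mean = 4, baseline_sd = 2,
                       tissue_effect_sd = 1.5,
                       dispersion = 0.05,
                       nonallelic_fraction = 0.43,
                       allele_misassignment = 0,
                       trans_in_introgression_fraction = 0.15,
                       seed = 1) {
  if (n_genes < 1) stop("n_genes must be positive")
  per_chrom <- .genes_per_chromosome(n_genes, n_chromosomes)
  if (is.null(blocks)) {
    # donor blocks cover ~35% of chr6 and ~53% of chr11 genes, the
    # chromosome shares of the study's 699- and 1066-gene introgressions
    mk <- function(chrom_i, lines, frac) {
      per <- per_chrom[chrom_i]
      from <- max(1, round(0.2 * per))
      to <- min(per, from + max(3, round(frac * per)) - 1)
      list(lines = lines, chromosome = paste0("chr", chrom_i),
           from = from, to = to)
    }
    blocks <- list(mk(6, "STE", 0.35), mk(11, c("FER", "STE"), 0.53))
  }
  for (b in blocks) {
    stopifnot(all(c("lines", "chromosome", "from", "to") %in% names(b)))
    idx <- match(b$chromosome, paste0("chr", seq_len(n_chromosomes)))
    if (is.na(idx)) stop("block on unknown chromosome: ", b$chromosome)
    if (b$from < 1 || b$to > per_chrom[idx] || b$from > b$to) {
      stop("block gene range out of bounds on ", b$chromosome)
    }
  }
  ov <- .blocks_overlap(blocks)
  if (!is.null(ov)) stop("overlapping blocks on ", ov)
  bad <- setdiff(names(fractions), GEN_REG_CATEGORIES)
  if (length(bad)) stop("unknown category fraction(s): ",
                        paste(bad, collapse = ", "))
  if (any(fractions < 0) || sum(fractions) > 1) {
    stop("category fractions must be non-negative and sum to at most 1")
  }
  if (misexpressed_fraction < 0 || misexpressed_fraction > 1) {
    stop("misexpressed_fraction must be in [0, 1]")
  }
  if (nonallelic_fraction < 0 || nonallelic_fraction >= 1) {
    stop("nonallelic_fraction must be in [0, 1)")
  }
  if (dispersion <= 0) stop("dispersion must be positive")
  structure(list(
    n_genes = as.integer(n_genes), n_chromosomes = as.integer(n_chromosomes),
    blocks = blocks, library_size_mean = library_size_mean,
    library_size_sdlog = library_size_sdlog, fractions = fractions,
    misexpressed_fraction = misexpressed_fraction,
    effect_range = effect_range, misexpression_range = misexpression_range,
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    tissue_effect_sd = tissue_effect_sd, dispersion = dispersion,
    nonallelic_fraction = nonallelic_fraction,
    allele_misassignment = allele_misassignment,
    trans_in_introgression_fraction = trans_in_introgression_fraction,
    seed = as.integer(seed)
  ), class = "sim_config")
}

.genes_per_chromosome <- function(n_genes, n_chromosomes) {
  base <- n_genes %/% n_chromosomes
  extra <- n_genes %% n_chromosomes
  base + c(rep(1, extra), rep(0, n_chromosomes - extra))
}

.blocks_overlap <- function(blocks) {
  if (length(blocks) < 2) return(NULL)
  for (i in seq_len(length(blocks) - 1)) {
    for (j in (i + 1):length(blocks)) {
      a <- blocks[[i]]; b <- blocks[[j]]
      if (a$chromosome == b$chromosome &&
          a$from <= b$to && b$from <= a$to) {
        return(a$chromosome)
      }
    }
  }
  NULL
}

#' Draw the per-gene ground truth
#'
#' Assigns every gene a chromosome, position, baseline and tissue effect,
#' a regulatory category with matching cis/trans effects, a hybrid trans
#' modifier, a misexpression effect (STE stamens), and a dispersion.
#' Category allocation is deterministic by count; placement of category
#' members across the gene list is random under the configured seed.
#'
#' @param config a [sim_config()].
#' @return A list with `truth` (data.frame, one row per gene), `annotation`
#'   (a [gene_annotation()]) and `design` (the canonical [default_design()]).
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  per_chrom <- .genes_per_chromosome(n, config$n_chromosomes)
  chromosome <- rep(paste0("chr", seq_len(config$n_chromosomes)), per_chrom)
  idx_in_chrom <- unlist(lapply(per_chrom, seq_len))
  gene_id <- sprintf("g%05d", seq_len(n))
  start <- (idx_in_chrom - 1L) * 10000L + 1L
  annotation <- gene_annotation(gene_id, chromosome, start, start + 1999L,
                                strand = "+")

  # heterozygous-block membership per hybrid line
  het <- matrix(FALSE, n, length(HYBRID_LINES),
                dimnames = list(gene_id, HYBRID_LINES))
  for (b in config$blocks) {
    in_block <- chromosome == b$chromosome &
      idx_in_chrom >= b$from & idx_in_chrom <= b$to
    for (ln in intersect(b$lines, HYBRID_LINES)) het[in_block, ln] <- TRUE
  }

  # deterministic category counts, random placement
  counts <- round(config$fractions * n)
  if (sum(counts) > n) stop("category counts exceed n_genes")
  category <- rep("conserved", n)
  pool <- sample.int(n)
  at <- 0
  for (cat in names(counts)) {
    k <- counts[[cat]]
    if (k > 0) category[pool[(at + 1):(at + k)]] <- cat
    at <- at + k
  }

  rmag <- function(k, range) runif(k, range[1], range[2])
  rsign <- function(k) sample(c(-1, 1), k, replace = TRUE)
  c_eff <- numeric(n); r_eff <- numeric(n)
  for (cat in setdiff(GEN_REG_CATEGORIES, "conserved")) {
    i <- which(category == cat)
    if (!length(i)) next
    k <- length(i)
    s <- rsign(k)
    if (cat == "cis_only") {
      c_eff[i] <- s * rmag(k, config$effect_range)
    } else if (cat == "trans_only") {
      r_eff[i] <- s * rmag(k, config$effect_range)
    } else if (cat == "cis_trans_reinforcing") {
      # same-sign cis and trans: |pFC| = |c + r| > |aFC| = |c|
      c_eff[i] <- s * rmag(k, config$effect_range)
      r_eff[i] <- s * rmag(k, config$effect_range)
    } else if (cat == "cis_trans_opposing") {
      # opposite-sign trans smaller than cis: same pFC sign, |pFC| < |aFC|
      c_eff[i] <- s * rmag(k, config$effect_range)
      r_eff[i] <- -s * runif(k, 0.75, 1.25)
    } else if (cat == "cis_x_trans") {
      # opposite-sign trans larger than cis: pFC and aFC signs differ
      c_eff[i] <- s * rmag(k, config$effect_range)
      r_eff[i] <- -s * (abs(c_eff[i]) + rmag(k, c(1, 2)))
    } else if (cat == "compensatory") {
      c_eff[i] <- s * rmag(k, config$effect_range)
      r_eff[i] <- -c_eff[i]
    }
  }

  m <- numeric(n)
  trans_genes <- which(r_eff != 0)
  if (length(trans_genes)) {
    flagged <- runif(length(trans_genes)) < config$trans_in_introgression_fraction
    m[trans_genes[flagged]] <- 0.5
  }

  n_mis <- round(config$misexpressed_fraction * n)
  delta <- numeric(n)
  mis_idx <- sample.int(n, n_mis)
  delta[mis_idx] <- rsign(n_mis) * rmag(n_mis, config$misexpression_range)

  truth <- data.frame(
    gene_id = gene_id,
    chromosome = chromosome,
    baseline_log2 = rnorm(n, config$baseline_mean, config$baseline_sd),
    tissue_effect_stamen = rnorm(n, 0, config$tissue_effect_sd),
    cis_log2 = c_eff,
    trans_log2 = r_eff,
    hybrid_trans_fraction = m,
    misexpression_log2 = delta,
    dispersion = rep(config$dispersion, n),
    het_FER = het[, "FER"],
    het_STE = het[, "STE"],
    true_regulatory_category = category,
    stringsAsFactors = FALSE
  )
  truth$true_inheritance_category <-
    true_inheritance_categories(truth, line = "STE", tissue = "stamen")
  list(truth = truth, annotation = annotation, design = default_design())
}

#' Expected log2 means under the generative model
#'
#' Per-gene expected log2 expression (relative scale, log2 CPM) of the two
#' parents and of one hybrid line in one tissue, plus the hybrid's two
#' allelic means where the gene is heterozygous.
#'
#' @param truth truth table from [simulate_truth()].
#' @param line hybrid line, `"FER"` or `"STE"`.
#' @param tissue `"stamen"` or `"carpel"`.
#' @return data.frame with `sf5`, `im62`, `hybrid_total`,
#'   `hybrid_allele_sf5`, `hybrid_allele_im62` (allelic columns `NA` for
#'   homozygous-background genes).
#' @export
expected_log2_means <- function(truth, line, tissue) {
  stopifnot(line %in% HYBRID_LINES, tissue %in% TISSUES)
  base <- truth$baseline_log2 +
    if (tissue == "stamen") truth$tissue_effect_stamen else 0
  cc <- truth$cis_log2; rr <- truth$trans_log2; m <- truth$hybrid_trans_fraction
  het <- truth[[paste0("het_", line)]]
  d <- if (line == "STE" && tissue == "stamen") truth$misexpression_log2 else 0
  a_sf5 <- ifelse(het, base - 1 + m * rr + d, NA_real_)
  a_im62 <- ifelse(het, base - 1 + cc + m * rr + d, NA_real_)
  h_tot <- ifelse(het, log2(2^a_sf5 + 2^a_im62), base + m * rr + d)
  data.frame(
    gene_id = truth$gene_id,
    sf5 = base,
    im62 = base + cc + rr,
    hybrid_total = h_tot,
    hybrid_allele_sf5 = a_sf5,
    hybrid_allele_im62 = a_im62
  )
}

#' Ground-truth inheritance categories implied by the effect sizes
#'
#' Applies the eight-category decision table to the noise-free expected
#' means, calling a difference "significant" when it exceeds the log2
#' fold-change threshold, so recovery tests have an exact reference.
#'
#' @inheritParams expected_log2_means
#' @param lfc_threshold log2 threshold standing in for the significance
#'   call (default 1.25).
#' @return character vector of category labels (see
#'   [classify_inheritance()] for the level set).
#' @export
true_inheritance_categories <- function(truth, line, tissue,
                                        lfc_threshold = 1.25) {
  mm <- expected_log2_means(truth, line, tissue)
  fc_vs_sf5 <- mm$hybrid_total - mm$sf5
  fc_vs_im62 <- mm$hybrid_total - mm$im62
  fc_parents <- mm$sf5 - mm$im62
  .inheritance_table(
    A = abs(fc_vs_sf5) > lfc_threshold,
    B = abs(fc_vs_im62) > lfc_threshold,
    P = abs(fc_parents) > lfc_threshold,
    fc_A = fc_vs_sf5, fc_B = fc_vs_im62
  )$category
}

#' Simulate total and allele-specific count matrices
#'
#' Draws negative-binomial counts under the generative expression model for
#' every sample of the design. Draw order under the seeded stream:
#' library sizes, the shared per-(gene, sample) gamma noise matrix, then
#' the IM62-allele, SF5-allele and non-allele-specific Poisson component
#' matrices (each genes x samples, column-major).
#' Total counts are the sum of the two allelic matrices plus the
#' non-allele-specific reads, so allelic counts never exceed totals and
#' equal them when `nonallelic_fraction` is 0.
#'
#' @param truth truth table from [simulate_truth()].
#' @param design a [sample_design()] (lines restricted to the four canonical
#'   lines).
#' @param config the [sim_config()] used for `truth`.
#' @return list with `counts` (a [count_matrix()]) and `allele_counts`
#'   (an [allele_count_matrix()]).
#' @export
simulate_counts <- function(truth, design, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n <- nrow(truth)
  ns <- nrow(design)
  lib <- round(rlnorm(ns, log(config$library_size_mean),
                      config$library_size_sdlog))
  names(lib) <- design$sample_id

  mu_im62 <- matrix(0, n, ns)  # allelic mean counts
  mu_sf5 <- matrix(0, n, ns)
  mu_tot <- matrix(0, n, ns)   # total mean counts (CPM x scale)
  f_na <- config$nonallelic_fraction
  for (j in seq_len(ns)) {
    line <- design$line[j]; tissue <- design$tissue[j]
    base <- truth$baseline_log2 +
      if (tissue == "stamen") truth$tissue_effect_stamen else 0
    cc <- truth$cis_log2; rr <- truth$trans_log2
    m <- truth$hybrid_trans_fraction
    scale <- lib[j] / 1e6
    if (line == "IM62") {
      tot <- 2^(base + cc + rr)
      im62 <- tot; sf5 <- 0 * tot
    } else if (line == "SF5") {
      tot <- 2^base
      sf5 <- tot; im62 <- 0 * tot
    } else {
      het <- truth[[paste0("het_", line)]]
      d <- if (line == "STE" && tissue == "stamen")
        truth$misexpression_log2 else 0
      a_sf5 <- ifelse(het, 2^(base - 1 + m * rr + d), 2^(base + m * rr + d))
      a_im62 <- ifelse(het, 2^(base - 1 + cc + m * rr + d), 0)
      sf5 <- a_sf5; im62 <- a_im62
      tot <- a_sf5 + a_im62
    }
    mu_tot[, j] <- tot * scale
    mu_im62[, j] <- im62 * scale * (1 - f_na)
    mu_sf5[, j] <- sf5 * scale * (1 - f_na)
  }

  # gamma-Poisson with the biological-noise multiplier shared across a
  # gene-sample's read components: each component is marginally NB with
  # dispersion phi, components are positively correlated, and the total is
  # exactly NB(mu_total, phi)
  size <- 1 / truth$dispersion
  noise <- matrix(stats::rgamma(n * ns, shape = rep(size, ns),
                                rate = rep(size, ns)), n, ns)
  draw <- function(mu) {
    y <- matrix(0, n, ns)
    pos <- mu > 0
    y[pos] <- stats::rpois(sum(pos), (mu * noise)[pos])
    y
  }
  y_im62 <- draw(mu_im62)
  y_sf5 <- draw(mu_sf5)
  y_na <- draw(mu_tot * f_na)

  eps <- config$allele_misassignment
  if (eps > 0) {
    flip_to_sf5 <- matrix(rbinom(n * ns, as.vector(y_im62), eps), n, ns)
    flip_to_im62 <- matrix(rbinom(n * ns, as.vector(y_sf5), eps), n, ns)
    y_im62 <- y_im62 - flip_to_sf5 + flip_to_im62
    y_sf5 <- y_sf5 - flip_to_im62 + flip_to_sf5
  }

  total <- y_im62 + y_sf5 + y_na
  dimnames(total) <- list(truth$gene_id, design$sample_id)
  arr <- array(0, dim = c(n, ns, 2),
               dimnames = list(truth$gene_id, design$sample_id, ALLELES))
  arr[, , "IM62"] <- y_im62
  arr[, , "SF5"] <- y_sf5
  list(counts = count_matrix(total),
       allele_counts = allele_count_matrix(arr))
}

#' Expected heterozygous genome fraction after backcrossing
#'
#' Expected fraction of the genome still heterozygous in an RSB introgression
#' line (outside the selected blocks) after `n_backcrosses` rounds of
#' backcrossing to the recurrent parent, `0.5 / 2^n_backcrosses`. The
#' RSB7 design of the emulated study corresponds to `n_backcrosses = 8`.
#'
#' @param n_backcrosses number of backcross rounds (default 8).
#' @return Expected heterozygous fraction.
#' @examples
#' round(100 * expected_het_fraction(8), 1)  # ~0.2%
#' @export
expected_het_fraction <- function(n_backcrosses = 8) {
  0.5 / 2^n_backcrosses
}

#' Forward-simulate the recurrent-selection backcross scheme
#'
#' Each generation a pollen-sterile individual (always heterozygous at the
#' hms1 locus) is selected and backcrossed to the SF5 recurrent parent, so
#' final-generation progeny inherit the heterozygous hms1 introgression
#' with probability 1/2. The chromosome-11 drive-locus introgression is
#' transmitted with probability `drive_transmission`. The background is
#' fixed for SF5 at hms2, and a progeny is sterile exactly when it combines
#' a heterozygous IM62 hms1 allele with the SF5/SF5 hms2 genotype.
#' Genome-wide background heterozygosity is simulated as `n_loci` unlinked
#' markers each heterozygous with probability
#' [expected_het_fraction()]`(n_backcrosses)`.
#'
#' @param n_progeny number of final-generation progeny to draw.
#' @param n_backcrosses backcross rounds (default 8, the RSB7 design).
#' @param drive_transmission transmission probability of the chromosome-11
#'   drive introgression (default 0.98).
#' @param seed integer seed.
#' @param n_loci unlinked background markers per progeny (default 400).
#' @return data.frame with one row per progeny: `hms1`, `hms2`, `chr11`
#'   genotypes, `fertile`, and `het_fraction`.
#' @export
simulate_rsb_cross <- function(n_progeny, n_backcrosses = 8,
                               drive_transmission = 0.98, seed = 1,
                               n_loci = 400) {
  if (length(n_progeny) != 1 || is.na(n_progeny) || n_progeny <= 0) {
    stop("n_progeny must be a positive integer")
  }
  set.seed(seed)
  n <- as.integer(n_progeny)
  hms1_het <- rbinom(n, 1, 0.5) == 1
  chr11_het <- rbinom(n, 1, drive_transmission) == 1
  p_bg <- expected_het_fraction(n_backcrosses)
  het_fraction <- rbinom(n, n_loci, p_bg) / n_loci
  data.frame(
    progeny = seq_len(n),
    hms1 = ifelse(hms1_het, "IM62/SF5", "SF5/SF5"),
    hms2 = "SF5/SF5",
    chr11 = ifelse(chr11_het, "IM62/SF5", "SF5/SF5"),
    fertile = !hms1_het,  # sterile = het hms1 on the fixed SF5/SF5 hms2
    het_fraction = het_fraction,
    stringsAsFactors = FALSE
  )
}
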