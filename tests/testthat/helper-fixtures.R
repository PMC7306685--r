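# Shared in-code fixtures: tiny designs, hand-built truth tables, and a
# two-group NB sampler used across the statistical tests.

two_group_design <- function(n_reps = 3, lines = c("SF5", "IM62"),
                             tissue = "stamen") {
  grid <- expand.grid(replicate = seq_len(n_reps), line = lines,
                      stringsAsFactors = FALSE)
  sample_design(paste(grid$line, tissue, grid$replicate, sep = "_"),
                grid$line, tissue, grid$replicate)
}

nb_two_group_counts <- function(n_genes, mu_a, mu_b, phi, n_reps = 3,
                                lib = 5e6) {
  design <- two_group_design(n_reps)
  mu <- cbind(matrix(mu_a, n_genes, n_reps), matrix(mu_b, n_genes, n_reps))
  y <- matrix(rnbinom(length(mu), mu = mu, size = 1 / phi),
              n_genes, 2 * n_reps,
              dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                              design$sample_id))
  list(x = count_matrix(y, rep(lib, 2 * n_reps)), design = design)
}

# hand-built truth table rows for direct simulate_counts() checks
manual_truth <- function(n, baseline = 6, tissue_eff = 0, c_eff = 0,
                         r_eff = 0, m = 0, delta = 0, phi = 0.05,
                         het = TRUE) {
  data.frame(
    gene_id = sprintf("g%04d", seq_len(n)),
    chromosome = "chr1",
    baseline_log2 = baseline,
    tissue_effect_stamen = tissue_eff,
    cis_log2 = c_eff,
    trans_log2 = r_eff,
    hybrid_trans_fraction = m,
    misexpression_log2 = delta,
    dispersion = phi,
    het_FER = het,
    het_STE = het,
    true_regulatory_category = "conserved",
    stringsAsFactors = FALSE
  )
}

# fake DE result with given significance calls and fold-changes
fake_de <- function(gene_id, log2fc, significant, contrast = "A - B") {
  out <- data.frame(gene_id = gene_id, log2fc = log2fc,
                    p = ifelse(significant, 0.001, 0.5),
                    fdr = ifelse(significant, 0.01, 0.6),
                    significant = significant,
                    direction = ifelse(!significant, "none",
                                       ifelse(log2fc > 0, "up", "down")),
                    stringsAsFactors = FALSE)
  attr(out, "contrast") <- contrast
  class(out) <- c("de_result", "data.frame")
  out
}

# the standard synthetic study fixture used by recovery tests: one large
# chromosome-11 block shared by FER and STE so enough heterozygous genes
# are available for allele-specific inference
recovery_fixture <- function(seed = 11, n_genes = 1008) {
  cfg <- sim_config(
    n_genes = n_genes, seed = seed,
    blocks = list(list(lines = c("FER", "STE"), chromosome = "chr11",
                       from = 1, to = 72))
  )
  st <- simulate_truth(cfg)
  sim <- simulate_counts(st$truth, st$design, cfg)
  expressed <- filter_expressed(sim$counts)
  xf <- subset_genes(sim$counts, intersect(st$annotation$gene_id, expressed))
  nf <- tmm_norm_factors(xf)
  disp <- estimate_dispersions(xf, st$design, norm_factors = nf)
  list(config = cfg, truth = st$truth, annotation = st$annotation,
       design = st$design, counts = xf, allele_counts = sim$allele_counts,
       norm_factors = nf, dispersions = disp)
}
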