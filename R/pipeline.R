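# End-to-end orchestration: simulate or ingest counts, filter and
# normalize, run the DE contrasts, genotype the hybrid lines, classify
# inheritance and tissue bias, partition regulatory divergence, and emit
# summary tables. Deterministic given the config and seed.

#' Pipeline configuration
#'
#' Either a simulation config (`sim`) or a set of input paths must be
#' given. All stage thresholds live here; no stage uses a hidden constant.
#'
#' @param sim a [sim_config()] to generate the inputs, or `NULL`.
#' @param counts,allele_counts,design,annotation input file paths (TSV,
#'   TSV, TSV, GFF3), used when `sim` is `NULL`.
#' @param cpm_threshold,min_samples expression filter (defaults 1 and 3).
#' @param lfc_threshold,alpha DE significance rule (defaults 1.25 and 0.05).
#' @param genotype_min_count pooled-count depth floor for genotyping
#'   (default 10).
#' @param min_allelic_cpm allelic expression floor for aFC (default 1).
#' @param caution_misexpression_threshold misexpressed fraction above which
#'   a tissue's regulatory inference is flagged (default 0.10).
#' @param out_dir output directory, or `NULL` to skip writing.
#' @param seed integer seed recorded with every run.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(sim = NULL, counts = NULL, allele_counts = NULL,
                            design = NULL, annotation = NULL,
                            cpm_threshold = 1, min_samples = 3,
                            lfc_threshold = 1.25, alpha = 0.05,
                            genotype_min_count = 10, min_allelic_cpm = 1,
                            caution_misexpression_threshold = 0.10,
                            out_dir = NULL, seed = 1) {
  if (is.null(sim)) {
    paths <- c(counts = counts, allele_counts = allele_counts,
               design = design, annotation = annotation)
    if (length(paths) < 4) {
      stop("either a sim config or all four input paths are required")
    }
    missing <- paths[!file.exists(paths)]
    if (length(missing)) {
      stop("input file(s) not found: ", paste(missing, collapse = ", "))
    }
  }
  stopifnot(cpm_threshold > 0, min_samples > 0, lfc_threshold >= 0,
            alpha > 0, alpha < 1, genotype_min_count > 0)
  structure(list(sim = sim, counts = counts, allele_counts = allele_counts,
                 design = design, annotation = annotation,
                 cpm_threshold = cpm_threshold, min_samples = min_samples,
                 lfc_threshold = lfc_threshold, alpha = alpha,
                 genotype_min_count = genotype_min_count,
                 min_allelic_cpm = min_allelic_cpm,
                 caution_misexpression_threshold =
                   caution_misexpression_threshold,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; a `sim:` mapping is
#' passed to [sim_config()].
#'
#' @param path YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim)) y$sim <- do.call(sim_config, y$sim)
  do.call(pipeline_config, y)
}

# Deterministic hash of the configuration for run provenance.
.config_hash <- function(config) {
  txt <- paste(deparse(config[setdiff(names(config), "out_dir")]),
               collapse = "")
  v <- utf8ToInt(txt)
  h <- 0
  for (chunk in split(v, ceiling(seq_along(v) / 4096))) {
    h <- (h * 31 + sum(chunk * (seq_along(chunk) %% 97 + 1))) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Run the full analysis pipeline
#'
#' Stages, in dependency order: input (simulate or read), expression
#' filter, TMM normalization, dispersion estimation, DE contrasts (hybrid
#' vs each parent, hybrid vs hybrid, parents, and stamen-vs-carpel within
#' each parent), per-hybrid genotyping with introgression blocks,
#' inheritance classification per hybrid line and tissue, tissue-bias
#' classification, regulatory-divergence partitioning over
#' heterozygous-block genes, the misexpression association tests, and
#' summary tables. When the design contains no hybrid line the
#' inheritance and regulatory stages are skipped with a logged reason.
#'
#' @param config a [pipeline_config()].
#' @return A results bundle (list) with the stage outputs, a `log`
#'   character vector, and `run_info` (config hash, seed); written to
#'   `config$out_dir` as TSV/BED/plain-text when set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- character(0)
  note <- function(...) {
    log <<- c(log, paste0(...))
    invisible(NULL)
  }

  # ---- input ----
  if (!is.null(config$sim)) {
    sim <- simulate_truth(config$sim)
    cnts <- simulate_counts(sim$truth, sim$design, config$sim)
    x <- cnts$counts; acm <- cnts$allele_counts
    design <- sim$design; annotation <- sim$annotation
    truth <- sim$truth
    note("input: simulated ", nrow(truth), " genes x ", nrow(design),
         " samples (seed ", config$sim$seed, ")")
  } else {
    design <- read_design(config$design)
    x <- read_count_matrix(config$counts, design)
    acm <- read_allele_counts(config$allele_counts, design)
    annotation <- read_annotation(config$annotation)
    truth <- NULL
    note("input: read ", nrow(x$counts), " genes x ", nrow(design),
         " samples")
  }
  shared <- intersect(rownames(x$counts), dimnames(acm$counts)[[1]])
  dropped <- nrow(x$counts) - length(shared)
  if (dropped > 0) {
    note("gene sets of total and allele matrices intersected; dropped ",
         dropped, " gene(s)")
    x <- subset_genes(x, shared)
  }
  annotation <- sort_annotation(
    annotation[annotation$gene_id %in% rownames(x$counts), , drop = FALSE])

  # ---- filter + normalize ----
  expressed <- filter_expressed(x, config$cpm_threshold, config$min_samples)
  note("expression filter (CPM > ", config$cpm_threshold, " in >= ",
       config$min_samples, " samples): removed ",
       attr(expressed, "n_removed"), " genes, kept ", length(expressed))
  ann_expr <- annotation[annotation$gene_id %in% expressed, , drop = FALSE]
  genes_ordered <- ann_expr$gene_id
  xf <- subset_genes(x, genes_ordered)
  nf <- tmm_norm_factors(xf)
  note("TMM factors: ", paste(signif(nf, 3), collapse = " "))
  cpm_norm <- cpm(xf, xf$library_sizes * nf)

  disp <- estimate_dispersions(xf, design, norm_factors = nf)
  note("dispersion: common ", signif(disp$common, 3))

  lines_present <- unique(design$line)
  tissues_present <- unique(design$tissue)
  hybrids <- intersect(HYBRID_LINES, lines_present)
  parents_ok <- all(PARENT_LINES %in% lines_present)

  # ---- DE contrasts ----
  de <- list()
  run_de <- function(a, b) {
    key <- paste0(a, "_vs_", b)
    de[[key]] <<- test_contrast(xf, design, disp, c(a, b),
                                lfc_threshold = config$lfc_threshold,
                                alpha = config$alpha, norm_factors = nf)
    note("DE ", key, ": ", sum(de[[key]]$significant), " significant")
    invisible(NULL)
  }
  for (ts in tissues_present) {
    grp <- function(ln) paste(ln, ts, sep = "_")
    if (parents_ok) run_de(grp("SF5"), grp("IM62"))
    for (h in hybrids) {
      if ("SF5" %in% lines_present) run_de(grp(h), grp("SF5"))
      if ("IM62" %in% lines_present) run_de(grp(h), grp("IM62"))
    }
    if (all(c("STE", "FER") %in% hybrids)) run_de(grp("STE"), grp("FER"))
  }
  if (length(tissues_present) == 2) {
    for (ln in lines_present) {
      run_de(paste(ln, "stamen", sep = "_"), paste(ln, "carpel", sep = "_"))
    }
  }

  # ---- tissue bias ----
  tissue_bias <- NULL
  if (parents_ok && length(tissues_present) == 2) {
    tissue_bias <- classify_tissue_bias(de[["SF5_stamen_vs_SF5_carpel"]],
                                        de[["IM62_stamen_vs_IM62_carpel"]])
    note("tissue bias: ",
         sum(tissue_bias$category != "UNBIASED"), " biased genes")
  } else {
    note("tissue bias skipped: needs both parents and both tissues")
  }

  # ---- genotyping ----
  genotypes <- list()
  for (h in hybrids) {
    genotypes[[h]] <- genotype_line(acm, design, h, ann_expr,
                                    min_count = config$genotype_min_count,
                                    genes = genes_ordered)
    note("genotyping ", h, ": ", nrow(genotypes[[h]]$blocks), " block(s), ",
         genotypes[[h]]$n_flagged, " erroneous IM62 call(s) dropped")
  }

  # ---- inheritance ----
  inheritance <- list()
  if (length(hybrids) && parents_ok) {
    for (h in hybrids) {
      for (ts in tissues_present) {
        key <- paste(h, ts, sep = "_")
        inheritance[[key]] <- classify_inheritance(
          de[[paste0(h, "_", ts, "_vs_SF5_", ts)]],
          de[[paste0(h, "_", ts, "_vs_IM62_", ts)]],
          de[[paste0("SF5_", ts, "_vs_IM62_", ts)]]
        )
        note("inheritance ", key, ": ",
             sum(grepl("^MISEXPRESSED", inheritance[[key]]$category)),
             " misexpressed")
      }
    }
  } else {
    note("inheritance skipped: requires hybrid lines and both parents")
  }

  # ---- regulatory divergence ----
  regdiv <- list()
  association <- list()
  if (length(hybrids) && parents_ok) {
    for (h in hybrids) {
      blocks <- genotypes[[h]]$blocks
      block_genes <- genes_in_blocks(blocks, ann_expr)
      if (!length(block_genes)) {
        note("regulatory divergence ", h,
             " skipped: no heterozygous block genes")
        next
      }
      for (ts in tissues_present) {
        key <- paste(h, ts, sep = "_")
        mis_genes <- if (!is.null(inheritance[[key]])) {
          inh <- inheritance[[key]]
          inh$gene_id[grepl("^MISEXPRESSED", inh$category)]
        } else character(0)
        regdiv[[key]] <- regulatory_divergence(
          xf, acm, design, h, ts, block_genes, disp,
          norm_factors = nf, alpha = config$alpha,
          misexpressed = mis_genes,
          caution_threshold = config$caution_misexpression_threshold)
        note("regdiv ", key, ": ", nrow(regdiv[[key]]), " genes evaluated",
             if (attr(regdiv[[key]], "caution"))
               " [caution: high misexpression]" else "")
        if (!is.null(inheritance[[key]])) {
          association[[key]] <- misexpression_association(
            regdiv[[key]],
            misexpressed = regdiv[[key]]$gene_id %in% mis_genes)
        }
      }
    }
  } else {
    note("regulatory divergence skipped: requires hybrid lines and parents")
  }

  # ---- summaries ----
  summaries <- summarize_categories(
    inheritance = inheritance, tissue_bias = tissue_bias,
    regdiv = regdiv, de = de, tissues = tissues_present
  )

  bundle <- list(
    design = design, annotation = ann_expr, counts = xf,
    allele_counts = acm, norm_factors = nf, cpm = cpm_norm,
    dispersions = disp, de = de, tissue_bias = tissue_bias,
    genotypes = genotypes, inheritance = inheritance, regdiv = regdiv,
    association = association, summaries = summaries, truth = truth,
    log = log,
    run_info = list(config_hash = .config_hash(config), seed = config$seed)
  )
  if (!is.null(config$out_dir)) .write_bundle(bundle, config)
  bundle
}

#' Summary tables across pipeline stages
#'
#' Per-category counts and percentages for the inheritance, tissue-bias and
#' regulatory stages, and Venn-style overlap counts of the significant gene
#' sets from the three hybrid/parent DE comparisons per tissue.
#'
#' @param inheritance named list of [classify_inheritance()] results.
#' @param tissue_bias a [classify_tissue_bias()] result or `NULL`.
#' @param regdiv named list of [regulatory_divergence()] results.
#' @param de named list of [test_contrast()] results.
#' @param tissues tissues analyzed.
#' @return list with `inheritance`, `tissue_bias`, `regdiv` count tables
#'   and `venn` overlap tables.
#' @export
summarize_categories <- function(inheritance = list(), tissue_bias = NULL,
                                 regdiv = list(), de = list(),
                                 tissues = TISSUES) {
  cat_table <- function(f) {
    tab <- table(f)
    data.frame(category = names(tab), n = as.integer(tab),
               pct = round(100 * as.integer(tab) / max(sum(tab), 1), 1),
               stringsAsFactors = FALSE)
  }
  inh <- lapply(inheritance, function(d) cat_table(d$category))
  tb <- if (is.null(tissue_bias)) NULL else cat_table(tissue_bias$category)
  rd <- lapply(regdiv, function(d) cat_table(d$category))
  venn <- list()
  for (ts in tissues) {
    keys <- paste0(c("STE_", "STE_", "FER_"), ts,
                   c("_vs_FER_", "_vs_SF5_", "_vs_SF5_"), ts)
    if (all(keys %in% names(de))) {
      sets <- lapply(de[keys], function(d) d$gene_id[d$significant])
      names(sets) <- c("STE_vs_FER", "STE_vs_SF5", "FER_vs_SF5")
      venn[[ts]] <- venn_counts(sets)
    }
  }
  list(inheritance = inh, tissue_bias = tb, regdiv = rd, venn = venn)
}

#' Venn region counts for two or three sets
#'
#' @param sets named list of 2 or 3 character vectors.
#' @return named integer vector of exclusive region counts (e.g. `A`,
#'   `B`, `A:B` for two sets; all seven regions for three).
#' @export
venn_counts <- function(sets) {
  k <- length(sets)
  if (!k %in% c(2, 3)) stop("venn_counts supports 2 or 3 sets")
  nm <- names(sets)
  all_items <- unique(unlist(sets))
  member <- vapply(sets, function(s) all_items %in% s, logical(length(all_items)))
  if (length(all_items) == 0) {
    member <- matrix(logical(0), 0, k)
  }
  if (is.null(dim(member))) member <- matrix(member, ncol = k)
  pattern <- apply(member, 1, function(r) paste(nm[r], collapse = ":"))
  regions <- unlist(lapply(seq_len(k), function(m) {
    combn(nm, m, paste, collapse = ":")
  }))
  out <- setNames(integer(length(regions)), regions)
  tab <- table(pattern)
  out[names(tab)] <- as.integer(tab)
  out
}

.write_bundle <- function(bundle, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(config$out_dir, paste0(...))
  write_design(bundle$design, p("design.tsv"))
  write_annotation(bundle$annotation, p("annotation.gff3"))
  write_count_matrix(bundle$counts, p("counts_filtered.tsv"))
  for (key in names(bundle$de)) {
    write_results_table(bundle$de[[key]], p("de_", key, ".tsv"))
  }
  if (!is.null(bundle$tissue_bias)) {
    write_results_table(bundle$tissue_bias, p("tissue_bias.tsv"))
  }
  for (h in names(bundle$genotypes)) {
    write_results_table(bundle$genotypes[[h]]$calls, p("genotypes_", h, ".tsv"))
    blocks <- bundle$genotypes[[h]]$blocks
    write_results_table(blocks, p("blocks_", h, ".tsv"))
    write_blocks_bed(blocks, p("blocks_", h, ".bed"))
  }
  for (key in names(bundle$inheritance)) {
    write_results_table(bundle$inheritance[[key]],
                        p("inheritance_", key, ".tsv"))
  }
  for (key in names(bundle$regdiv)) {
    write_results_table(bundle$regdiv[[key]], p("regdiv_", key, ".tsv"))
  }
  info <- data.frame(config_hash = bundle$run_info$config_hash,
                     seed = bundle$run_info$seed)
  write_results_table(info, p("run_info.tsv"))
  writeLines(c(paste0("# run ", bundle$run_info$config_hash, " seed ",
                      bundle$run_info$seed), bundle$log),
             p("report.txt"))
  invisible(NULL)
}
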