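# Per-gene genotype calls from allele-specific read counts (binary
# presence/absence after pooling a line's replicates) and delimitation of
# heterozygous introgression blocks along the annotation order.

GENOTYPE_CALLS <- c("IM62", "HET", "SF5", "NONEXPRESSED")

#' Binarize pooled allele-specific counts
#'
#' Pools a line's replicate libraries (both tissues) and converts each
#' allele's pooled count to a presence flag. Two pooling orders are
#' supported: `"pool-first"` (default) sums replicates and then applies the
#' depth floor, treating `min_count` as a pooled-depth requirement;
#' `"threshold-first"` zeroes per-sample counts below `min_count` before
#' pooling, so presence requires at least one individually convincing
#' library.
#'
#' @param allele_counts an [allele_count_matrix()].
#' @param design the matching [sample_design()].
#' @param line line whose samples are pooled.
#' @param min_count depth floor: counts below it are treated as absent
#'   (default 10, i.e. presence requires a count of at least 10).
#' @param order `"pool-first"` or `"threshold-first"`.
#' @return genes x 2 binary (0/1) matrix with columns `IM62`, `SF5`.
#' @export
binarize_allele_counts <- function(allele_counts, design, line,
                                   min_count = 10,
                                   order = c("pool-first", "threshold-first")) {
  order <- match.arg(order)
  samples <- design$sample_id[design$line == line]
  if (!length(samples)) stop("no samples for line ", line)
  arr <- allele_counts$counts[, samples, , drop = FALSE]
  if (order == "threshold-first") {
    arr[arr < min_count] <- 0
    pooled <- apply(arr, c(1, 3), sum)
    out <- (pooled > 0) * 1L
  } else {
    pooled <- apply(arr, c(1, 3), sum)
    out <- (pooled >= min_count) * 1L
  }
  out[, ALLELES, drop = FALSE]
}

#' Call per-gene genotypes from binary allele presence
#'
#' Four-way call: IM62 (1, 0), HET (1, 1), SF5 (0, 1), NONEXPRESSED (0, 0).
#' In the hybrid lines (FER, STE), IM62 calls are biologically impossible
#' under the crossing scheme (any IM62 allele is accompanied by an SF5
#' copy); they are flagged erroneous and treated as no-calls downstream.
#'
#' @param binary genes x 2 binary matrix from [binarize_allele_counts()].
#' @param line the line the calls belong to.
#' @return data.frame with `gene_id`, `line`, `call`, `flagged_erroneous`.
#' @export
call_genotypes <- function(binary, line) {
  im <- binary[, "IM62"] > 0
  sf <- binary[, "SF5"] > 0
  call <- ifelse(im & sf, "HET",
                 ifelse(im, "IM62", ifelse(sf, "SF5", "NONEXPRESSED")))
  flagged <- line %in% HYBRID_LINES & call == "IM62"
  data.frame(gene_id = rownames(binary), line = line,
             call = factor(call, levels = GENOTYPE_CALLS),
             flagged_erroneous = flagged,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Delimit heterozygous introgression blocks
#'
#' A block is a maximal run of HET-called genes along one chromosome.
#' NONEXPRESSED genes (and flagged erroneous calls) never break a run; any
#' SF5- or unflagged IM62-called gene terminates it. The reported inner
#' span uses the HET gene extremes; the outer span extends to just inside
#' the nearest terminating genes (or the chromosome's annotated extremes).
#'
#' @param calls genotype calls from [call_genotypes()].
#' @param annotation a [gene_annotation()] covering the called genes.
#' @return data.frame with one row per block: `line`, `chromosome`,
#'   `first_gene`, `last_gene`, `start_bp`, `end_bp` (inner HET extremes),
#'   `outer_start_bp`, `outer_end_bp`, `n_genes` (genes spanned, including
#'   interior no-calls), `n_expressed` (HET genes).
#' @export
find_introgression_blocks <- function(calls, annotation) {
  ann <- annotation[match(calls$gene_id, annotation$gene_id), , drop = FALSE]
  if (anyNA(ann$gene_id)) {
    stop("calls contain gene(s) missing from the annotation")
  }
  ord <- order(ann$chromosome, ann$start)
  if (any(ord != seq_len(nrow(ann)))) {
    stop("genotype calls must be ordered by (chromosome, start)")
  }
  line <- unique(calls$line)
  if (length(line) != 1) stop("calls must come from a single line")

  state <- as.character(calls$call)
  state[calls$flagged_erroneous] <- "NONEXPRESSED"

  blocks <- list()
  for (chrom in unique(ann$chromosome)) {
    idx <- which(ann$chromosome == chrom)
    run <- integer(0)        # indices of HET genes in the current run
    last_break <- NA_integer_  # annotation row of the last terminating gene
    flush <- function(next_break) {
      if (!length(run)) return(invisible(NULL))
      first <- run[1]; last <- run[length(run)]
      outer_start <- if (is.na(last_break)) min(ann$start[idx]) else
        ann$end[last_break] + 1L
      outer_end <- if (is.na(next_break)) max(ann$end[idx]) else
        ann$start[next_break] - 1L
      blocks[[length(blocks) + 1]] <<- data.frame(
        line = line, chromosome = chrom,
        first_gene = calls$gene_id[first], last_gene = calls$gene_id[last],
        start_bp = ann$start[first], end_bp = ann$end[last],
        outer_start_bp = outer_start, outer_end_bp = outer_end,
        n_genes = sum(idx >= first & idx <= last),
        n_expressed = length(run),
        stringsAsFactors = FALSE
      )
      invisible(NULL)
    }
    for (i in idx) {
      if (state[i] == "HET") {
        run <- c(run, i)
      } else if (state[i] %in% c("SF5", "IM62")) {
        flush(i)
        run <- integer(0)
        last_break <- i
      }
      # NONEXPRESSED: neither extends nor breaks
    }
    flush(NA_integer_)
  }
  if (!length(blocks)) {
    return(data.frame(line = character(), chromosome = character(),
                      first_gene = character(), last_gene = character(),
                      start_bp = integer(), end_bp = integer(),
                      outer_start_bp = integer(), outer_end_bp = integer(),
                      n_genes = integer(), n_expressed = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, blocks)
}

#' Genotype a line end to end
#'
#' Convenience wrapper: binarize, call, and delimit blocks for one line.
#'
#' @inheritParams binarize_allele_counts
#' @param annotation a [gene_annotation()].
#' @param genes optional gene subset (defaults to all genes in the allele
#'   matrix), kept in annotation order.
#' @return list with `calls` (data.frame) and `blocks` (data.frame), plus
#'   `n_flagged` erroneous IM62 calls dropped.
#' @export
genotype_line <- function(allele_counts, design, line, annotation,
                          min_count = 10,
                          order = c("pool-first", "threshold-first"),
                          genes = NULL) {
  if (is.null(genes)) genes <- dimnames(allele_counts$counts)[[1]]
  ann <- sort_annotation(annotation[annotation$gene_id %in% genes, ,
                                    drop = FALSE])
  binary <- binarize_allele_counts(allele_counts, design, line, min_count,
                                   order)
  binary <- binary[ann$gene_id, , drop = FALSE]
  calls <- call_genotypes(binary, line)
  blocks <- find_introgression_blocks(calls, ann)
  list(calls = calls, blocks = blocks,
       n_flagged = sum(calls$flagged_erroneous))
}

#' Gene ids inside heterozygous blocks
#'
#' @param blocks block table from [find_introgression_blocks()].
#' @param annotation the matching [gene_annotation()].
#' @return character vector of genes whose span falls inside a block's
#'   inner bounds.
#' @export
genes_in_blocks <- function(blocks, annotation) {
  out <- character(0)
  for (i in seq_len(nrow(blocks))) {
    hit <- annotation$chromosome == blocks$chromosome[i] &
      annotation$start >= blocks$start_bp[i] &
      annotation$end <= blocks$end_bp[i]
    out <- c(out, annotation$gene_id[hit])
  }
  unique(out)
}

#' Write introgression blocks as BED
#'
#' BED is 0-based half-open, so `start_bp - 1` to `end_bp`.
#' @param blocks block table from [find_introgression_blocks()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_blocks_bed <- function(blocks, path) {
  bed <- data.frame(chrom = blocks$chromosome,
                    start = blocks$start_bp - 1L,
                    end = blocks$end_bp,
                    name = paste0(blocks$line, "_block_",
                                  seq_len(max(nrow(blocks), 0))),
                    stringsAsFactors = FALSE)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
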