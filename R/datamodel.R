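# Domain types shared by every stage: the sample design, gene annotation,
# total and allele-specific count matrices, and tabular readers/writers.
# All matrices keep genes as rows and samples as columns; sample order always
# follows the design, never the file.

#' Construct a sample design table
#'
#' Describes the crossing-design samples: which inbred line or hybrid class
#' each library comes from, which tissue it was dissected from, and its
#' biological replicate number. The canonical design of the motivating study
#' is 4 lines (IM62, SF5, FER, STE) x 2 tissues (stamen, carpel) x 3
#' replicates = 24 libraries.
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param line character, one of `"IM62"`, `"SF5"`, `"FER"`, `"STE"`.
#' @param tissue character, `"stamen"` or `"carpel"`.
#' @param replicate positive integer replicate index within (line, tissue).
#' @return A `data.frame` of class `"sample_design"` with one row per sample
#'   and a `group` column (`line_tissue`) used to build model matrices.
#' @examples
#' design <- default_design()
#' table(design$line, design$tissue)
#' @export
sample_design <- function(sample_id, line, tissue, replicate) {
  line <- as.character(line)
  tissue <- as.character(tissue)
  if (anyDuplicated(sample_id)) {
    stop("duplicated sample_id: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  }
  bad <- setdiff(unique(line), LINES)
  if (length(bad)) stop("unknown line(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(tissue), TISSUES)
  if (length(bad)) stop("unknown tissue(s): ", paste(bad, collapse = ", "))
  replicate <- as.integer(replicate)
  if (any(is.na(replicate)) || any(replicate < 1)) {
    stop("replicate must be a positive integer")
  }
  out <- data.frame(
    sample_id = as.character(sample_id),
    line = line,
    tissue = tissue,
    replicate = replicate,
    stringsAsFactors = FALSE
  )
  out$group <- paste(out$line, out$tissue, sep = "_")
  class(out) <- c("sample_design", "data.frame")
  out
}

#' The canonical 24-sample design
#'
#' Four genotype lines by two tissues by three biological replicates, the
#' layout of the study design this package emulates.
#'
#' @param n_reps replicates per (line, tissue) group (default 3).
#' @return A [sample_design()] table with `4 * 2 * n_reps` rows.
#' @export
default_design <- function(n_reps = 3) {
  grid <- expand.grid(replicate = seq_len(n_reps), tissue = TISSUES,
                      line = LINES, stringsAsFactors = FALSE)
  sample_design(
    sample_id = paste(grid$line, grid$tissue, grid$replicate, sep = "_"),
    line = grid$line, tissue = grid$tissue, replicate = grid$replicate
  )
}

#' Construct a gene-by-sample count matrix
#'
#' @param counts integer matrix, genes x samples, with gene ids as rownames
#'   and sample ids as colnames; no negative entries.
#' @param library_sizes optional per-sample positive totals; defaults to the
#'   column sums of `counts`.
#' @return A list of class `"count_matrix"` with elements `counts` and
#'   `library_sizes`.
#' @export
count_matrix <- function(counts, library_sizes = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have gene ids as rownames")
  if (is.null(colnames(counts))) stop("counts must have sample ids as colnames")
  if (any(counts < 0)) stop("negative counts are not allowed")
  if (is.null(library_sizes)) library_sizes <- colSums(counts)
  library_sizes <- as.numeric(library_sizes)
  if (length(library_sizes) != ncol(counts)) {
    stop("library_sizes length must equal the number of samples")
  }
  if (any(library_sizes <= 0)) stop("library_sizes must be positive")
  names(library_sizes) <- colnames(counts)
  structure(list(counts = counts, library_sizes = library_sizes),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "genes x", ncol(x$counts), "samples\n")
  invisible(x)
}

#' Construct an allele-resolved count matrix
#'
#' Allele-specific read counts indexed by (gene, sample, allele). The allele
#' axis is exactly the two parental alleles, IM62 and SF5.
#'
#' @param counts 3-d array genes x samples x 2 with
#'   `dimnames[[3]] == c("IM62", "SF5")`.
#' @param library_sizes optional samples x 2 matrix of per-(sample, allele)
#'   totals; defaults to the per-slice column sums.
#' @return A list of class `"allele_count_matrix"` with elements `counts`
#'   (the array) and `library_sizes`.
#' @export
allele_count_matrix <- function(counts, library_sizes = NULL) {
  if (length(dim(counts)) != 3 || dim(counts)[3] != 2) {
    stop("counts must be a genes x samples x 2 array")
  }
  if (!identical(dimnames(counts)[[3]], ALLELES)) {
    stop("third dimension must be the alleles c(\"IM62\", \"SF5\")")
  }
  if (any(counts < 0)) stop("negative counts are not allowed")
  if (is.null(library_sizes)) {
    library_sizes <- apply(counts, c(2, 3), sum)
  }
  library_sizes <- as.matrix(library_sizes)
  if (!all(dim(library_sizes) == dim(counts)[2:3])) {
    stop("library_sizes must be a samples x 2 matrix")
  }
  if (any(library_sizes < 0)) stop("library_sizes must be non-negative")
  dimnames(library_sizes) <- dimnames(counts)[2:3]
  structure(list(counts = counts, library_sizes = library_sizes),
            class = "allele_count_matrix")
}

#' @export
print.allele_count_matrix <- function(x, ...) {
  cat("allele_count_matrix:", dim(x$counts)[1], "genes x",
      dim(x$counts)[2], "samples x 2 alleles\n")
  invisible(x)
}

#' Construct a gene annotation table
#'
#' 1-based inclusive coordinates, GFF convention. Genes are sortable by
#' (chromosome, start); block-boundary arithmetic converts to other
#' conventions only at the output edge.
#'
#' @param gene_id,chromosome character vectors.
#' @param start,end 1-based inclusive positions, `start <= end`.
#' @param strand `"+"`, `"-"` or `"."`.
#' @return A `data.frame` of class `"gene_annotation"`.
#' @export
gene_annotation <- function(gene_id, chromosome, start, end, strand = ".") {
  if (anyDuplicated(gene_id)) {
    stop("duplicated gene id: ",
         paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "))
  }
  start <- as.integer(start); end <- as.integer(end)
  if (any(end < start)) {
    stop("end < start for gene(s): ",
         paste(gene_id[end < start], collapse = ", "))
  }
  strand <- rep_len(as.character(strand), length(gene_id))
  if (!all(strand %in% c("+", "-", "."))) stop("strand must be +, - or .")
  out <- data.frame(gene_id = as.character(gene_id),
                    chromosome = as.character(chromosome),
                    start = start, end = end, strand = strand,
                    stringsAsFactors = FALSE)
  class(out) <- c("gene_annotation", "data.frame")
  out
}

#' Sort an annotation by genomic position
#' @param annotation a [gene_annotation()] table.
#' @return The same table ordered by (chromosome, start, end).
#' @export
sort_annotation <- function(annotation) {
  annotation[order(annotation$chromosome, annotation$start, annotation$end), ,
             drop = FALSE]
}

# ---- readers / writers ------------------------------------------------------

#' Read a gene-by-sample count matrix from TSV
#'
#' The file carries a header of sample ids and one row per gene; the first
#' column holds gene ids. Columns are reordered to match the design order
#' regardless of file order, and library sizes are set to the column sums.
#'
#' @param path TSV file.
#' @param design a [sample_design()]; every design sample must be present in
#'   the header.
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(path, design) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  gene_id <- as.character(tab[[1]])
  mat <- tab[, -1, drop = FALSE]
  missing <- setdiff(design$sample_id, colnames(mat))
  if (length(missing)) {
    stop("sample(s) missing from count file header: ",
         paste(missing, collapse = ", "))
  }
  mat <- mat[, design$sample_id, drop = FALSE]
  .check_integer_cells(mat, gene_id, path)
  m <- as.matrix(mat)
  storage.mode(m) <- "double"
  rownames(m) <- gene_id
  count_matrix(m)
}

.check_integer_cells <- function(mat, gene_id, path) {
  for (j in seq_along(mat)) {
    v <- mat[[j]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) | num != floor(num) | num < 0)
    if (length(bad)) {
      stop(sprintf(
        "non-integer or negative count in %s: gene '%s', sample '%s' (value '%s')",
        path, gene_id[bad[1]], colnames(mat)[j], v[bad[1]]))
    }
  }
  invisible(TRUE)
}

#' Write a count matrix to TSV
#' @param x a [count_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(x, path) {
  df <- data.frame(gene_id = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an allele-resolved count matrix from TSV
#'
#' On disk the allele axis is flattened to a pair of columns per sample,
#' `<sample>__IM62` and `<sample>__SF5`.
#'
#' @inheritParams read_count_matrix
#' @return An [allele_count_matrix()] with samples in design order.
#' @export
read_allele_counts <- function(path, design) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  gene_id <- as.character(tab[[1]])
  mat <- tab[, -1, drop = FALSE]
  wanted <- as.vector(outer(design$sample_id, ALLELES, paste, sep = "__"))
  missing <- setdiff(wanted, colnames(mat))
  if (length(missing)) {
    stop("allele column(s) missing from header: ",
         paste(missing, collapse = ", "))
  }
  .check_integer_cells(mat[wanted], gene_id, path)
  arr <- array(0, dim = c(length(gene_id), nrow(design), 2),
               dimnames = list(gene_id, design$sample_id, ALLELES))
  for (al in ALLELES) {
    cols <- paste(design$sample_id, al, sep = "__")
    arr[, , al] <- as.matrix(mat[cols])
  }
  allele_count_matrix(arr)
}

#' Write an allele-resolved count matrix to TSV
#' @param x an [allele_count_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_allele_counts <- function(x, path) {
  samples <- dimnames(x$counts)[[2]]
  out <- data.frame(gene_id = dimnames(x$counts)[[1]],
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (s in samples) {
    for (al in ALLELES) {
      out[[paste(s, al, sep = "__")]] <- x$counts[, s, al]
    }
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample design table from TSV
#'
#' Expects columns `sample_id`, `line`, `tissue`, `replicate`.
#' @param path TSV file.
#' @return A [sample_design()].
#' @export
read_design <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "line", "tissue", "replicate")
  missing <- setdiff(need, colnames(tab))
  if (length(missing)) {
    stop("design file missing column(s): ", paste(missing, collapse = ", "))
  }
  sample_design(tab$sample_id, tab$line, tab$tissue, tab$replicate)
}

#' Write a sample design table to TSV
#' @param design a [sample_design()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  write.table(as.data.frame(design)[c("sample_id", "line", "tissue",
                                      "replicate")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene annotations from a GFF3 file
#'
#' Only `gene` features are consumed; each must carry an `ID` attribute.
#' Coordinates stay 1-based inclusive.
#'
#' @param path GFF3 file.
#' @return A [gene_annotation()] table (possibly with zero rows).
#' @export
read_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
  if (length(gr) == 0) {
    return(gene_annotation(character(), character(), integer(), integer(),
                           character()))
  }
  ids <- as.character(gr$ID)
  if (any(is.na(ids) | ids == "")) {
    stop("gene feature without an ID attribute in ", path)
  }
  if (anyDuplicated(ids)) {
    stop("duplicated gene ID in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  gene_annotation(
    gene_id = ids,
    chromosome = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = sub("\\*", ".", as.character(GenomicRanges::strand(gr)))
  )
}

#' Write gene annotations to a GFF3 file
#' @param annotation a [gene_annotation()] table.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(annotation)) {
    lines <- sprintf("%s\tasepartition\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     annotation$chromosome, annotation$start, annotation$end,
                     annotation$strand, annotation$gene_id)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Write a per-gene results table
#'
#' Deterministic column order (as given), tab-separated, one row per record,
#' record order preserved. Factor columns are written as their labels.
#'
#' @param records a `data.frame` of per-gene records.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(records, path) {
  records <- as.data.frame(records)
  for (j in seq_along(records)) {
    if (is.factor(records[[j]])) records[[j]] <- as.character(records[[j]])
  }
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a results table written by [write_results_table()]
#' @param path TSV file.
#' @return A `data.frame`.
#' @export
read_results_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Restrict a count matrix to a gene set
#' @param x a [count_matrix()] or [allele_count_matrix()].
#' @param genes character vector of gene ids to keep (order respected).
#' @param recompute_lib_sizes recompute library sizes from the retained
#'   genes (default `FALSE`: keep the full-library totals, so filtering does
#'   not change normalization denominators).
#' @return Object of the same class restricted to `genes`.
#' @export
subset_genes <- function(x, genes, recompute_lib_sizes = FALSE) {
  if (inherits(x, "count_matrix")) {
    missing <- setdiff(genes, rownames(x$counts))
    if (length(missing)) {
      stop("gene(s) not in matrix: ", paste(head(missing, 5), collapse = ", "))
    }
    counts <- x$counts[genes, , drop = FALSE]
    ls <- if (recompute_lib_sizes) colSums(counts) else x$library_sizes
    count_matrix(counts, ls)
  } else if (inherits(x, "allele_count_matrix")) {
    missing <- setdiff(genes, dimnames(x$counts)[[1]])
    if (length(missing)) {
      stop("gene(s) not in matrix: ", paste(head(missing, 5), collapse = ", "))
    }
    counts <- x$counts[genes, , , drop = FALSE]
    ls <- if (recompute_lib_sizes) apply(counts, c(2, 3), sum) else
      x$library_sizes
    allele_count_matrix(counts, ls)
  } else {
    stop("unsupported class: ", paste(class(x), collapse = "/"))
  }
}

#' Restrict a count matrix to a sample subset
#' @param x a [count_matrix()].
#' @param samples sample ids to keep, in the desired order.
#' @return A [count_matrix()] with those columns.
#' @export
subset_samples <- function(x, samples) {
  missing <- setdiff(samples, colnames(x$counts))
  if (length(missing)) {
    stop("sample(s) not in matrix: ", paste(missing, collapse = ", "))
  }
  count_matrix(x$counts[, samples, drop = FALSE], x$library_sizes[samples])
}
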