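# Diploid pseudoreference construction: substitute filtered biallelic SNPs
# into a reference FASTA to obtain the alternate haplotype, then emit both
# haplotypes side by side with allele-suffixed chromosome and feature names.
# SNP-only by construction, so coordinates are shared between haplotypes.

#' Read variant records from a VCF file
#'
#' Consumes only CHROM/POS/REF/ALT and the INFO fields MQ (mapping quality)
#' and QD (quality by depth). A record is flagged biallelic when REF and ALT
#' are single bases and ALT carries exactly one allele.
#'
#' @param path VCF file (v4.x, plain text).
#' @return A `data.frame` with columns `chromosome`, `pos`, `ref`, `alt`,
#'   `mq`, `qd`, `biallelic`.
#' @export
read_variants <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  mq <- suppressWarnings(as.numeric(vcfR::extract.info(v, "MQ")))
  qd <- suppressWarnings(as.numeric(vcfR::extract.info(v, "QD")))
  ref <- as.character(fix[, "REF"])
  alt <- as.character(fix[, "ALT"])
  data.frame(
    chromosome = as.character(fix[, "CHROM"]),
    pos = as.integer(fix[, "POS"]),
    ref = ref,
    alt = alt,
    mq = mq,
    qd = qd,
    biallelic = nchar(ref) == 1 & nchar(alt) == 1 & !grepl(",", alt),
    stringsAsFactors = FALSE
  )
}

#' Filter variants for pseudoreference construction
#'
#' Keeps biallelic SNPs with mapping quality at least `min_mq` and quality
#' by depth at least `min_qd`; multi-allelic records and indels are dropped,
#' not split. Input order is preserved.
#'
#' @param records variant table as returned by [read_variants()].
#' @param min_mq minimum mapping quality (default 40).
#' @param min_qd minimum quality by depth (default 2).
#' @return The surviving rows of `records`.
#' @export
filter_variants <- function(records, min_mq = 40, min_qd = 2) {
  if (nrow(records) == 0) return(records)
  keep <- records$biallelic &
    !is.na(records$mq) & records$mq >= min_mq &
    !is.na(records$qd) & records$qd >= min_qd
  records[keep, , drop = FALSE]
}

#' Substitute SNP alleles into reference sequences
#'
#' Produces the alternate haplotype: identical to the reference except that
#' each SNP position carries the ALT base. Sequence lengths are unchanged.
#' Every SNP's REF base must match the reference.
#'
#' @param reference a [Biostrings::DNAStringSet] (or named character vector)
#'   of reference sequences.
#' @param snps filtered variant table (see [filter_variants()]).
#' @return A `DNAStringSet` with the substitutions applied.
#' @export
apply_snps <- function(reference, snps) {
  if (!methods::is(reference, "DNAStringSet")) {
    reference <- Biostrings::DNAStringSet(reference)
  }
  out <- reference
  if (nrow(snps) == 0) return(out)
  unknown <- setdiff(unique(snps$chromosome), names(out))
  if (length(unknown)) {
    stop("SNP(s) on unknown chromosome(s): ", paste(unknown, collapse = ", "))
  }
  for (chrom in unique(snps$chromosome)) {
    s <- snps[snps$chromosome == chrom, , drop = FALSE]
    seq_len_chrom <- Biostrings::width(out[chrom])
    if (any(s$pos < 1 | s$pos > seq_len_chrom)) {
      bad <- s$pos[s$pos < 1 | s$pos > seq_len_chrom][1]
      stop("SNP position outside sequence: ", chrom, ":", bad)
    }
    chrom_seq <- as.character(out[[chrom]])
    have <- substring(chrom_seq, s$pos, s$pos)
    mismatch <- which(toupper(have) != toupper(s$ref))
    if (length(mismatch)) {
      stop("reference mismatch at ", chrom, ":", s$pos[mismatch[1]],
           " (expected ", s$ref[mismatch[1]], ", found ", have[mismatch[1]], ")")
    }
    out[[chrom]] <- Biostrings::replaceLetterAt(
      out[[chrom]], s$pos, toupper(s$alt))
  }
  out
}

#' Build a diploid pseudoreference genome and annotation
#'
#' Merges two same-coordinate haplotypes into one FASTA whose chromosome
#' names carry allele suffixes (`chr1_IM62`, `chr1_SF5`), and duplicates the
#' annotation with suffixed chromosome and gene ids, so reads can be mapped
#' competitively against both alleles.
#'
#' @param ref reference haplotype (`DNAStringSet` or named character).
#' @param alt alternate haplotype; must share chromosome names and lengths
#'   with `ref`.
#' @param annotation a [gene_annotation()] table on the shared coordinates.
#' @param labels length-2 character, suffix for `ref` and `alt` haplotypes
#'   (default `c("IM62", "SF5")`).
#' @return A list with `fasta` (`DNAStringSet`, every chromosome twice) and
#'   `annotation` (a [gene_annotation()] with `2 *` the input gene count).
#' @export
make_diploid <- function(ref, alt, annotation, labels = c("IM62", "SF5")) {
  if (!methods::is(ref, "DNAStringSet")) ref <- Biostrings::DNAStringSet(ref)
  if (!methods::is(alt, "DNAStringSet")) alt <- Biostrings::DNAStringSet(alt)
  if (!setequal(names(ref), names(alt))) {
    stop("chromosome sets differ: only in ref: ",
         paste(setdiff(names(ref), names(alt)), collapse = ", "),
         "; only in alt: ",
         paste(setdiff(names(alt), names(ref)), collapse = ", "))
  }
  alt <- alt[names(ref)]
  if (!all(Biostrings::width(ref) == Biostrings::width(alt))) {
    bad <- names(ref)[Biostrings::width(ref) != Biostrings::width(alt)]
    stop("chromosome length mismatch: ", paste(bad, collapse = ", "))
  }
  stopifnot(length(labels) == 2)
  ref_out <- ref
  names(ref_out) <- paste(names(ref), labels[1], sep = "_")
  alt_out <- alt
  names(alt_out) <- paste(names(alt), labels[2], sep = "_")
  fasta <- c(ref_out, alt_out)

  suffix_ann <- function(lab) {
    if (nrow(annotation) == 0) return(annotation)
    gene_annotation(
      gene_id = paste(annotation$gene_id, lab, sep = "_"),
      chromosome = paste(annotation$chromosome, lab, sep = "_"),
      start = annotation$start, end = annotation$end,
      strand = annotation$strand
    )
  }
  ann2 <- rbind(as.data.frame(suffix_ann(labels[1])),
                as.data.frame(suffix_ann(labels[2])))
  class(ann2) <- c("gene_annotation", "data.frame")
  list(fasta = fasta, annotation = ann2)
}

#' Write sequences to FASTA
#'
#' Line width fixed at 60 characters for determinism.
#' @param seqs a `DNAStringSet` or named character vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (!methods::is(seqs, "DNAStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path, width = 60)
  invisible(path)
}

#' Read sequences from FASTA
#' @param path FASTA file.
#' @return A `DNAStringSet`.
#' @export
read_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}
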