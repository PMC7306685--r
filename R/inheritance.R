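# Expression-inheritance categories (hybrid vs both parents) and the joint
# parental tissue-bias classification.

INHERITANCE_CATEGORIES <- c(
  "SIMILAR",
  "SF5_LIKE_SIMILAR", "SF5_LIKE_DIVERGENT",
  "IM62_LIKE_SIMILAR", "IM62_LIKE_DIVERGENT",
  "INTERMEDIATE_DIVERGENT",
  "MISEXPRESSED_SIMILAR", "MISEXPRESSED_DIVERGENT",
  "UNCLASSIFIABLE"
)

TISSUE_BIAS_CATEGORIES <- c(
  "BOTH_STAMEN", "BOTH_CARPEL",
  "SF5_ONLY_STAMEN", "SF5_ONLY_CARPEL",
  "IM62_ONLY_STAMEN", "IM62_ONLY_CARPEL",
  "OPPOSING_SF5STAMEN_IM62CARPEL", "OPPOSING_SF5CARPEL_IM62STAMEN",
  "UNBIASED"
)

# Decision table over the three significance bits and the fold-change
# signs. A = hybrid differs from SF5, B = hybrid differs from IM62,
# P = parents differ; fc_A = log2(hybrid/SF5), fc_B = log2(hybrid/IM62).
# Opposite fc signs place the hybrid between the parents; matching signs
# place it outside both (misexpression).
.inheritance_table <- function(A, B, P, fc_A, fc_B) {
  n <- length(A)
  category <- character(n)
  flag <- character(n)
  between <- sign(fc_A) * sign(fc_B) <= 0  # opposite signs (or a zero)
  category[!A & !B & !P] <- "SIMILAR"
  category[!A & B & !P] <- "SF5_LIKE_SIMILAR"
  category[!A & B & P] <- "SF5_LIKE_DIVERGENT"
  category[A & !B & !P] <- "IM62_LIKE_SIMILAR"
  category[A & !B & P] <- "IM62_LIKE_DIVERGENT"
  category[A & B & P & between] <- "INTERMEDIATE_DIVERGENT"
  category[A & B & P & !between] <- "MISEXPRESSED_DIVERGENT"
  category[A & B & !P & !between] <- "MISEXPRESSED_SIMILAR"
  # hybrid distinguishable from both parents, yet between two parents that
  # do not differ: no category of the scheme names this cell
  sel <- A & B & !P & between
  category[sel] <- "UNCLASSIFIABLE"
  flag[sel] <- "unclassifiable"
  # parents differ but the hybrid is distinguishable from neither: the
  # hybrid necessarily sits within the parental range (low-power cell)
  sel <- !A & !B & P
  category[sel] <- "INTERMEDIATE_DIVERGENT"
  flag[sel] <- "intermediate (no test significant)"
  outside <- !between
  direction <- ifelse(category %in% c("MISEXPRESSED_SIMILAR",
                                      "MISEXPRESSED_DIVERGENT") & outside,
                      ifelse(fc_A > 0, "over", "under"), "none")
  data.frame(category = category, direction = direction, flag = flag,
             stringsAsFactors = FALSE)
}

#' Classify expression inheritance per gene
#'
#' Assigns each gene one of eight inheritance categories from three
#' threshold DE results: hybrid vs SF5, hybrid vs IM62, and SF5 vs IM62
#' (all on the same gene set, typically at `lfc_threshold = 1.25`,
#' `alpha = 0.05`). Misexpression means the hybrid sits significantly
#' outside both parents in the same direction; the `direction` column
#' records over- vs under-expression.
#'
#' @param de_h_vs_sf5,de_h_vs_im62 [test_contrast()] results of the hybrid
#'   against each parent (positive log2fc = higher in the hybrid).
#' @param de_parents [test_contrast()] result between the parents.
#' @return data.frame with `gene_id`, `category` (factor over the eight
#'   categories plus `UNCLASSIFIABLE`), `direction` (`over`/`under`/`none`)
#'   and `flag` for the two ambiguous cells.
#' @export
classify_inheritance <- function(de_h_vs_sf5, de_h_vs_im62, de_parents) {
  genes <- de_h_vs_sf5$gene_id
  .check_same_genes(list(de_h_vs_sf5, de_h_vs_im62, de_parents))
  b <- de_h_vs_im62[match(genes, de_h_vs_im62$gene_id), ]
  p <- de_parents[match(genes, de_parents$gene_id), ]
  out <- .inheritance_table(
    A = de_h_vs_sf5$significant,
    B = b$significant,
    P = p$significant,
    fc_A = de_h_vs_sf5$log2fc,
    fc_B = b$log2fc
  )
  data.frame(gene_id = genes,
             category = factor(out$category, levels = INHERITANCE_CATEGORIES),
             direction = out$direction, flag = out$flag,
             stringsAsFactors = FALSE)
}

.check_same_genes <- function(de_list) {
  genes <- de_list[[1]]$gene_id
  for (d in de_list[-1]) {
    extra <- setdiff(genes, d$gene_id)
    if (length(extra)) {
      stop("gene(s) missing from a DE input: ",
           paste(head(extra, 5), collapse = ", "))
    }
    if (length(d$gene_id) != length(genes)) {
      stop("DE inputs cover different gene sets")
    }
  }
  invisible(TRUE)
}

#' Classify joint parental tissue bias
#'
#' Crosses each parent's stamen-vs-carpel DE call (stamen-biased,
#' carpel-biased, or unbiased; sign convention log2(stamen/carpel)) into
#' the nine joint categories: biased the same way in both parents, biased
#' in one parent only, opposing biases, or unbiased.
#'
#' @param de_sf5,de_im62 [test_contrast()] results of stamen vs carpel
#'   within SF5 and within IM62 on a shared gene set.
#' @return data.frame with `gene_id` and `category` (factor over the nine
#'   categories).
#' @export
classify_tissue_bias <- function(de_sf5, de_im62) {
  genes <- de_sf5$gene_id
  .check_same_genes(list(de_sf5, de_im62))
  i <- de_im62[match(genes, de_im62$gene_id), ]
  bias <- function(d) ifelse(!d$significant, "none",
                             ifelse(d$log2fc > 0, "stamen", "carpel"))
  s <- bias(de_sf5); g <- bias(i)
  category <- rep("UNBIASED", length(genes))
  category[s == "stamen" & g == "stamen"] <- "BOTH_STAMEN"
  category[s == "carpel" & g == "carpel"] <- "BOTH_CARPEL"
  category[s == "stamen" & g == "none"] <- "SF5_ONLY_STAMEN"
  category[s == "carpel" & g == "none"] <- "SF5_ONLY_CARPEL"
  category[s == "none" & g == "stamen"] <- "IM62_ONLY_STAMEN"
  category[s == "none" & g == "carpel"] <- "IM62_ONLY_CARPEL"
  category[s == "stamen" & g == "carpel"] <- "OPPOSING_SF5STAMEN_IM62CARPEL"
  category[s == "carpel" & g == "stamen"] <- "OPPOSING_SF5CARPEL_IM62STAMEN"
  data.frame(gene_id = genes,
             category = factor(category, levels = TISSUE_BIAS_CATEGORIES),
             stringsAsFactors = FALSE)
}

#' Cross-tabulate tissue bias within gene sets
#'
#' For each named gene set, counts and percentages of genes stamen-biased
#' in at least one parent, carpel-biased in at least one parent, and
#' unbiased. Genes with opposing biases count toward both biased groups,
#' so the two biased percentages can overlap.
#'
#' @param bias result of [classify_tissue_bias()].
#' @param gene_sets named list of character vectors, each a subset of the
#'   classified genes.
#' @return data.frame with one row per set: `set`, `n`, `stamen_any`,
#'   `carpel_any`, `unbiased`, and integer percentage columns `pct_*`.
#' @export
crosstab_bias_by_deset <- function(bias, gene_sets) {
  stamen_any <- c("BOTH_STAMEN", "SF5_ONLY_STAMEN", "IM62_ONLY_STAMEN",
                  "OPPOSING_SF5STAMEN_IM62CARPEL",
                  "OPPOSING_SF5CARPEL_IM62STAMEN")
  carpel_any <- c("BOTH_CARPEL", "SF5_ONLY_CARPEL", "IM62_ONLY_CARPEL",
                  "OPPOSING_SF5STAMEN_IM62CARPEL",
                  "OPPOSING_SF5CARPEL_IM62STAMEN")
  rows <- lapply(names(gene_sets), function(nm) {
    genes <- gene_sets[[nm]]
    unknown <- setdiff(genes, bias$gene_id)
    if (length(unknown)) {
      stop("unknown gene(s) in set '", nm, "': ",
           paste(head(unknown, 5), collapse = ", "))
    }
    cat_here <- as.character(bias$category[match(genes, bias$gene_id)])
    n <- length(genes)
    st <- sum(cat_here %in% stamen_any)
    cp <- sum(cat_here %in% carpel_any)
    un <- sum(cat_here == "UNBIASED")
    pct <- function(k) if (n == 0) 0L else as.integer(round(100 * k / n))
    data.frame(set = nm, n = n, stamen_any = st, carpel_any = cp,
               unbiased = un, pct_stamen_any = pct(st),
               pct_carpel_any = pct(cp), pct_unbiased = pct(un),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
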