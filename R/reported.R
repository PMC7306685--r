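# Genome-wide reference tallies reported for the IM62 x SF5 introgression
# RNA-seq design this package models, shipped for internal-consistency
# checking of the classification bookkeeping (categories must partition
# the expressed gene set, up + down counts must sum to totals, fractions
# must reproduce the printed percentages).

#' Reference tallies from the motivating introgression study
#'
#' Genome-wide bookkeeping numbers of the IM62/SF5 introgression-hybrid
#' RNA-seq analysis that this package's classifiers reproduce at synthetic
#' scale: the expressed-gene total, the nine joint tissue-bias category
#' counts, the STE-stamen differential-expression counts, the misexpression
#' tally, and the stamen/carpel bias composition of the up- and
#' down-regulated STE-stamen gene sets. These feed consistency checks
#' (partitions summing to totals, printed percentages reproduced), not any
#' inference.
#'
#' @return A list:
#' \describe{
#'   \item{expressed_genes}{20431, genes expressed across the 14 chromosomes.}
#'   \item{tissue_bias}{named vector of the nine joint tissue-bias counts.}
#'   \item{ste_stamen_de}{c(up = 3207, down = 1639).}
#'   \item{misexpressed_ste_stamen}{4533 of the expressed genes.}
#'   \item{conserved_tissue_bias}{7512 genes biased the same way in both
#'     parents.}
#'   \item{single_parent_bias}{c(sf5_stamen = 546, sf5_carpel = 1339,
#'     im62_stamen = 615, im62_carpel = 2228).}
#'   \item{down_set}{c(n = 2062, stamen_any = 1715, carpel_any = 108):
#'     bias composition of the down-regulated STE-stamen set.}
#'   \item{up_set}{c(n = 5344, stamen_any = 344, carpel_any = 3953).}
#' }
#' @export
reference_tallies <- function() {
  list(
    expressed_genes = 20431L,
    tissue_bias = c(
      BOTH_STAMEN = 1812L, BOTH_CARPEL = 5700L,
      SF5_ONLY_STAMEN = 546L, SF5_ONLY_CARPEL = 1339L,
      IM62_ONLY_STAMEN = 615L, IM62_ONLY_CARPEL = 2228L,
      OPPOSING_SF5STAMEN_IM62CARPEL = 28L,
      OPPOSING_SF5CARPEL_IM62STAMEN = 50L,
      UNBIASED = 8113L
    ),
    ste_stamen_de = c(up = 3207L, down = 1639L),
    misexpressed_ste_stamen = 4533L,
    conserved_tissue_bias = 7512L,
    single_parent_bias = c(sf5_stamen = 546L, sf5_carpel = 1339L,
                           im62_stamen = 615L, im62_carpel = 2228L),
    down_set = c(n = 2062L, stamen_any = 1715L, carpel_any = 108L),
    up_set = c(n = 5344L, stamen_any = 344L, carpel_any = 3953L)
  )
}

#' Percentage of a count within a total, printed style
#'
#' `round(100 * count / total)` to the given number of digits — the
#' convention used when reporting category fractions (e.g. 4533 of 20431
#' is printed as 22).
#'
#' @param count,total non-negative numbers, `total > 0`.
#' @param digits decimal places (default 0).
#' @return The rounded percentage.
#' @export
pct_of <- function(count, total, digits = 0) {
  if (total <= 0) stop("total must be positive")
  round(100 * count / total, digits)
}
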