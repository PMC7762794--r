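#' Curate per-culture ASV counts
#'
#' Applies the per-culture low-count filter used when screening culture
#' amplicon libraries: within each sample independently, any ASV represented
#' by fewer than `min_reads` reads is discarded (set to zero) to guard
#' against sequencing error and index cross-talk. A count of exactly
#' `min_reads` is kept. The input table is not modified.
#'
#' @param counts wide ASV count tibble (`sample_id` first column).
#' @param min_reads minimum reads for an ASV to be retained in a sample
#'   (default 20; must be >= 1).
#' @param drop_empty drop ASV columns that are zero in every sample after
#'   filtering (default `FALSE`: column layout is preserved in memory).
#' @return the curated count tibble; any attached metadata is carried over.
#' @export
#' @examples
#' tbl <- tibble::tibble(sample_id = "c1", ASV_A = 19L, ASV_B = 21L)
#' curate_culture_counts(tbl)
curate_culture_counts <- function(counts, min_reads = 20, drop_empty = FALSE) {
  if (!is.finite(min_reads) || min_reads < 1) abort("min_reads must be >= 1")
  m <- as.matrix(counts[-1])
  m[m < min_reads] <- 0L
  out <- dplyr::bind_cols(counts[1], as_tibble(m))
  if (drop_empty && ncol(out) > 1) {
    out <- out[, c(TRUE, colSums(as.matrix(out[-1])) > 0), drop = FALSE]
  }
  attr(out, "metadata") <- attr(counts, "metadata")
  out
}

#' Curate the environmental sample
#'
#' Environmental curation for a bacterial-primer seawater survey: ASVs
#' classified as chloroplast at the bacterial-order level are removed first,
#' then ASVs with fewer than `min_reads` reads are removed. Doing the
#' chloroplast removal first means post-curation totals (the denominators of
#' environmental relative abundances) exclude chloroplast reads.
#'
#' @param counts wide count tibble holding the environmental sample(s).
#' @param taxonomy taxonomy tibble from [read_taxonomy()] (needs `asv_id`
#'   and `is_chloroplast`). ASVs absent from the taxonomy trigger a warning
#'   and are treated as non-chloroplast.
#' @param min_reads minimum reads for retention (default 20).
#' @param drop_empty drop removed ASV columns (default `TRUE`).
#' @return the curated count tibble.
#' @export
curate_environment <- function(counts, taxonomy, min_reads = 20,
                               drop_empty = TRUE) {
  if (!is.finite(min_reads) || min_reads < 1) abort("min_reads must be >= 1")
  asvs <- names(counts)[-1]
  missing <- setdiff(asvs, taxonomy$asv_id)
  if (length(missing) > 0) {
    warn(paste0("ASV(s) without taxonomy entry treated as non-chloroplast: ",
                paste(missing, collapse = ", ")))
  }
  chloro <- taxonomy$asv_id[taxonomy$is_chloroplast]
  keep <- !(asvs %in% chloro)
  out <- counts[, c(TRUE, keep), drop = FALSE]
  m <- as.matrix(out[-1])
  m[m < min_reads] <- 0L
  out <- dplyr::bind_cols(out[1], as_tibble(m))
  if (drop_empty && ncol(out) > 1) {
    out <- out[, c(TRUE, colSums(as.matrix(out[-1])) > 0), drop = FALSE]
  }
  attr(out, "metadata") <- attr(counts, "metadata")
  out
}

#' Convert curated counts to within-sample relative abundances
#'
#' Each ASV's proportion is its read count divided by the sample's total
#' post-curation reads. Samples with zero post-curation reads (cultures that
#' yielded no amplification product) are not divided: their rows stay at
#' zero and their ids are recorded in the `"zero_samples"` attribute.
#'
#' @param counts curated wide count tibble.
#' @return a tibble of the same shape holding proportions; rows with reads
#'   sum to 1.
#' @export
relative_abundance <- function(counts) {
  m <- as.matrix(counts[-1])
  totals <- rowSums(m)
  prop <- m / ifelse(totals > 0, totals, 1)
  out <- dplyr::bind_cols(counts[1], as_tibble(prop))
  attr(out, "zero_samples") <- counts$sample_id[totals == 0]
  attr(out, "metadata") <- attr(counts, "metadata")
  out
}
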