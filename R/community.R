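#' Define a source-community profile
#'
#' A community profile is the simulation ground truth for a dilution-to-
#' extinction experiment: the taxa present in the inoculum water sample, their
#' relative abundances, and the per-cell probability that a cell of each taxon
#' grows to detection under the culturing conditions (its viability, the
#' quantity the downstream culturability statistic estimates).
#'
#' @param taxa a data frame with columns `taxon_id` (unique strings),
#'   `abundance` (non-negative fractions summing to 1) and `viability`
#'   (probabilities in `[0, 1]`). Optional columns: `lineage`
#'   (semicolon-delimited ranked taxonomy), `group_label` (analysis grouping,
#'   e.g. `"SAR11 subclade Ia"`), `is_chloroplast` (logical; defaults to
#'   whether `lineage` contains the order-level label `"Chloroplast"`).
#' @return a tibble of class `community_profile` with all six columns.
#' @export
#' @examples
#' community_profile(data.frame(
#'   taxon_id = c("ASV001", "ASV002"),
#'   abundance = c(0.7, 0.3),
#'   viability = c(0.05, 0.01)
#' ))
community_profile <- function(taxa) {
  taxa <- as_tibble(taxa)
  required <- c("taxon_id", "abundance", "viability")
  missing <- setdiff(required, names(taxa))
  if (length(missing) > 0) {
    abort(paste0("community profile is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (nrow(taxa) == 0) abort("community profile must contain at least one taxon")
  if (anyDuplicated(taxa$taxon_id)) abort("taxon_id values must be unique")
  if (any(!is.finite(taxa$abundance)) || any(taxa$abundance < 0)) {
    abort("abundances must be finite and non-negative")
  }
  if (abs(sum(taxa$abundance) - 1) > 1e-9) {
    abort("abundances must sum to 1 (within 1e-9)")
  }
  if (any(!is.finite(taxa$viability)) ||
      any(taxa$viability < 0 | taxa$viability > 1)) {
    abort("viabilities must lie in [0, 1]")
  }
  if (!"lineage" %in% names(taxa)) taxa$lineage <- ""
  if (!"group_label" %in% names(taxa)) taxa$group_label <- ""
  if (!"is_chloroplast" %in% names(taxa)) {
    taxa$is_chloroplast <- lineage_is_chloroplast(taxa$lineage)
  }
  taxa <- taxa[, c("taxon_id", "abundance", "viability", "lineage",
                   "group_label", "is_chloroplast")]
  class(taxa) <- c("community_profile", class(taxa))
  taxa
}

# Order-level chloroplast call from a semicolon-delimited lineage string.
lineage_is_chloroplast <- function(lineage) {
  grepl("(^|;)\\s*Chloroplast\\s*(;|$)", lineage %||% "")
}

`%||%` <- function(x, y) if (is.null(x)) y else x
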