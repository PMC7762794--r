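#' Read a wide ASV count table with its sample metadata
#'
#' The count table is a UTF-8 tab-separated file whose header row holds ASV
#' identifiers and whose first column holds sample identifiers; all remaining
#' cells must be non-negative integers. The metadata file is a TSV with
#' columns `sample_id`, `role` (`culture`, `environment` or `control`),
#' `experiment`, and `cells_per_well` (the inoculum size `X`; required for
#' every culture sample).
#'
#' @param path path to the count TSV.
#' @param metadata_path path to the sample-metadata TSV.
#' @return the count tibble, with the metadata tibble attached as the
#'   `"metadata"` attribute (see [sample_metadata()]).
#' @export
read_count_table <- function(path, metadata_path) {
  counts <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE)
  names(counts)[1] <- "sample_id"
  counts[-1] <- suppressWarnings(lapply(counts[-1], as.numeric))
  check_count_values(counts)
  counts[-1] <- lapply(counts[-1], as.integer)
  if (anyDuplicated(counts$sample_id)) abort("duplicate sample ids in count table")
  if (anyDuplicated(names(counts)[-1])) abort("duplicate ASV ids in count table")

  metadata <- readr::read_tsv(metadata_path, progress = FALSE,
                              show_col_types = FALSE)
  required <- c("sample_id", "role")
  if (!all(required %in% names(metadata))) {
    abort("metadata must contain columns sample_id and role")
  }
  bad_roles <- setdiff(unique(metadata$role), c("culture", "environment", "control"))
  if (length(bad_roles) > 0) {
    abort(paste0("unknown sample role(s): ", paste(bad_roles, collapse = ", ")))
  }
  orphan <- setdiff(counts$sample_id, metadata$sample_id)
  if (length(orphan) > 0) {
    abort(paste0("sample(s) in counts but absent from metadata: ",
                 paste(orphan, collapse = ", ")))
  }
  if (!"cells_per_well" %in% names(metadata)) metadata$cells_per_well <- NA_real_
  cult <- metadata[metadata$role == "culture", ]
  if (any(!is.finite(cult$cells_per_well))) {
    abort(paste0("culture sample(s) missing cells_per_well (X): ",
                 paste(cult$sample_id[!is.finite(cult$cells_per_well)],
                       collapse = ", ")))
  }
  attr(counts, "metadata") <- as_tibble(metadata)
  counts
}

check_count_values <- function(counts) {
  m <- as.matrix(counts[-1])
  bad <- which(!is.finite(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "count table cell is not a non-negative integer: sample '%s', ASV '%s'",
      counts$sample_id[bad[1, 1]], colnames(m)[bad[1, 2]]))
  }
  invisible(counts)
}

#' Sample metadata attached to a count table
#'
#' @param counts a count tibble from [read_count_table()] or a metadata
#'   tibble passed through the pipeline.
#' @return the metadata tibble, or `NULL` if none is attached.
#' @export
sample_metadata <- function(counts) attr(counts, "metadata")

#' Write a wide ASV count table
#'
#' ASV columns that are zero in every sample are dropped on write by default
#' to keep files compact; set `drop_empty = FALSE` to preserve them.
#'
#' @param counts wide count tibble (`sample_id` first).
#' @param path output TSV path.
#' @param drop_empty drop all-zero ASV columns before writing.
#' @return `counts`, invisibly.
#' @export
write_count_table <- function(counts, path, drop_empty = TRUE) {
  out <- counts
  if (drop_empty && ncol(out) > 1) {
    keep <- c(TRUE, colSums(as.matrix(out[-1])) > 0)
    out <- out[, keep, drop = FALSE]
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(counts)
}

#' Read an ASV taxonomy table
#'
#' TSV with columns `asv_id`, `lineage` (semicolon-delimited ranked string)
#' and `group_label`. An `is_chloroplast` column is honoured if present and
#' checked against the lineage; otherwise the flag is derived from an
#' order-level `"Chloroplast"` entry in the lineage.
#'
#' @param path taxonomy TSV path.
#' @return a tibble with columns `asv_id`, `lineage`, `group_label`,
#'   `is_chloroplast`.
#' @export
read_taxonomy <- function(path) {
  tax <- readr::read_tsv(path, progress = FALSE, show_col_types = FALSE)
  if (!all(c("asv_id", "lineage") %in% names(tax))) {
    abort("taxonomy table must contain columns asv_id and lineage")
  }
  if (anyDuplicated(tax$asv_id)) abort("duplicate asv_id in taxonomy table")
  if (!"group_label" %in% names(tax)) tax$group_label <- ""
  from_lineage <- lineage_is_chloroplast(tax$lineage)
  if (!"is_chloroplast" %in% names(tax)) {
    tax$is_chloroplast <- from_lineage
  } else if (!identical(as.logical(tax$is_chloroplast), from_lineage)) {
    warn("is_chloroplast column disagrees with lineage-derived chloroplast flag")
  }
  as_tibble(tax[, c("asv_id", "lineage", "group_label", "is_chloroplast")])
}
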