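#' Partition ASV sets into Venn-diagram membership regions
#'
#' Given two or three named ASV sets (e.g. the environment-detected ASVs and
#' the ASVs isolated in each cultivation experiment), returns the exact
#' partition of their union into all `2^k - 1` membership regions.
#'
#' @param named_sets named list of 2 or 3 character vectors.
#' @return a tibble with one row per membership pattern: `region` (labels
#'   joined with `"&"`), `sets` (list of member labels), `asv_ids`
#'   (list-column) and `n`. Regions are disjoint and their union is the
#'   union of the input sets.
#' @export
#' @examples
#' venn_membership(list(env = c("a", "b", "c"), cultured = c("b", "c")))
venn_membership <- function(named_sets) {
  if (!is.list(named_sets) || length(named_sets) < 2 || length(named_sets) > 3) {
    abort("named_sets must be a named list of 2 or 3 ASV sets")
  }
  labels <- names(named_sets)
  if (is.null(labels) || any(labels == "") || anyDuplicated(labels)) {
    abort("all sets must have unique, non-empty names")
  }
  named_sets <- lapply(named_sets, function(s) unique(as.character(s)))
  universe <- sort(unique(unlist(named_sets, use.names = FALSE)))
  member <- vapply(named_sets, function(s) universe %in% s,
                   logical(length(universe)))
  member <- matrix(member, nrow = length(universe),
                   dimnames = list(universe, labels))
  patterns <- expand.grid(rep(list(c(TRUE, FALSE)), length(labels)))
  names(patterns) <- labels
  patterns <- patterns[rowSums(patterns) > 0, , drop = FALSE]
  rows <- purrr::map(seq_len(nrow(patterns)), function(i) {
    mask <- unlist(patterns[i, ])
    in_region <- rowSums(member == matrix(mask, nrow = nrow(member),
                                          ncol = length(mask),
                                          byrow = TRUE)) == length(mask)
    tibble(region = paste(labels[mask], collapse = "&"),
           sets = list(labels[mask]),
           asv_ids = list(universe[in_region]),
           n = sum(in_region))
  })
  out <- dplyr::bind_rows(rows)
  out[order(-lengths(out$sets), out$region), ]
}

#' Summarise isolates by taxonomic group against the environment
#'
#' Builds the collection-summary table: for every taxonomic group and
#' cultivation experiment, the number of distinct ASVs isolated and the
#' number of strains (isolate records; the same ASV isolated twice counts as
#' two strains), alongside the group's relative abundance in the curated
#' environmental sample. Groups isolated but not detected in the environment
#' get abundance 0 and `env_detected = FALSE`.
#'
#' @param isolates isolate registry from [assign_isolate_ids()].
#' @param taxonomy taxonomy tibble (`asv_id`, `group_label`); every isolate
#'   ASV must be present.
#' @param env_proportions environmental relative abundances: either the wide
#'   one-sample tibble from [relative_abundance()] or a long tibble with
#'   columns `asv_id`, `proportion`. `NULL` for no environmental data.
#' @return a tibble: `group_label`, `experiment`, `n_asvs`, `n_strains`,
#'   `env_n_asvs`, `env_abundance_pct`, `env_detected`.
#' @export
group_summary <- function(isolates, taxonomy, env_proportions = NULL) {
  env <- normalise_env_proportions(env_proportions)
  missing <- setdiff(unique(isolates$asv_id), taxonomy$asv_id)
  if (length(missing) > 0) {
    abort(paste0("isolate ASV(s) missing from taxonomy: ",
                 paste(missing, collapse = ", ")))
  }
  tax <- taxonomy[, c("asv_id", "group_label")]
  env_groups <- env %>%
    left_join(tax, by = "asv_id") %>%
    mutate(group_label = ifelse(is.na(.data$group_label), "(ungrouped)",
                                .data$group_label)) %>%
    group_by(.data$group_label) %>%
    summarise(env_n_asvs = n_distinct(.data$asv_id),
              env_abundance_pct = 100 * sum(.data$proportion),
              .groups = "drop")
  iso <- isolates %>%
    left_join(tax, by = "asv_id") %>%
    group_by(.data$group_label, .data$experiment) %>%
    summarise(n_asvs = n_distinct(.data$asv_id), n_strains = n(),
              .groups = "drop")
  experiments <- unique(iso$experiment)
  if (length(experiments) == 0) experiments <- NA_character_
  grid <- tidyr::expand_grid(
    group_label = sort(unique(c(env_groups$group_label, iso$group_label))),
    experiment = experiments
  )
  grid %>%
    left_join(iso, by = c("group_label", "experiment")) %>%
    left_join(env_groups, by = "group_label") %>%
    mutate(
      n_asvs = ifelse(is.na(.data$n_asvs), 0L, .data$n_asvs),
      n_strains = ifelse(is.na(.data$n_strains), 0L, .data$n_strains),
      env_detected = !is.na(.data$env_n_asvs),
      env_n_asvs = ifelse(is.na(.data$env_n_asvs), 0L, .data$env_n_asvs),
      env_abundance_pct = ifelse(is.na(.data$env_abundance_pct), 0,
                                 .data$env_abundance_pct)
    )
}

normalise_env_proportions <- function(env_proportions) {
  if (is.null(env_proportions)) {
    return(tibble(asv_id = character(0), proportion = numeric(0)))
  }
  if (all(c("asv_id", "proportion") %in% names(env_proportions))) {
    return(as_tibble(env_proportions[, c("asv_id", "proportion")]))
  }
  if (names(env_proportions)[1] == "sample_id") {
    if (nrow(env_proportions) != 1) {
      abort("wide environmental proportions must contain exactly one sample")
    }
    return(tidyr::pivot_longer(env_proportions, -"sample_id",
                               names_to = "asv_id",
                               values_to = "proportion")[, c("asv_id", "proportion")])
  }
  abort("env_proportions must be a wide one-sample table or have columns asv_id, proportion")
}

#' Co-occurrence of ASVs across mixed cultures
#'
#' Counts, for every pair of member ASVs, the number of mixed cultures in
#' which both grew; the diagonal counts the mixed cultures containing each
#' ASV. Answers queries such as "of the mixed cultures containing ASV018,
#' how many also contained ASV002?".
#'
#' @param mixed_calls tibble of `mixed`-category calls from
#'   [classify_cultures()]; any other category is an error.
#' @return a long tibble `asv_1`, `asv_2`, `n_cultures` covering all ordered
#'   pairs with `asv_1 <= asv_2` over the observed member ASVs (zeros
#'   included). The member proportions behind the counts are attached as the
#'   `"proportions"` attribute (`sample_id`, `asv_id`, `proportion`).
#' @export
cooccurrence <- function(mixed_calls) {
  if (nrow(mixed_calls) == 0) {
    return(tibble(asv_1 = character(0), asv_2 = character(0),
                  n_cultures = integer(0)))
  }
  if (any(mixed_calls$category != "mixed")) {
    abort("cooccurrence expects mixed-category calls only")
  }
  long <- tidyr::unnest(mixed_calls[, c("sample_id", "members")], "members")
  asvs <- sort(unique(long$asv_id))
  mat <- matrix(0L, length(asvs), length(asvs), dimnames = list(asvs, asvs))
  for (sid in unique(long$sample_id)) {
    mem <- sort(unique(long$asv_id[long$sample_id == sid]))
    mat[cbind(mem, mem)] <- mat[cbind(mem, mem)] + 1L
    if (length(mem) >= 2) {
      pairs <- utils::combn(mem, 2)
      mat[t(pairs)] <- mat[t(pairs)] + 1L
    }
  }
  idx <- which(upper.tri(mat, diag = TRUE), arr.ind = TRUE)
  out <- tibble(asv_1 = asvs[idx[, 1]], asv_2 = asvs[idx[, 2]],
                n_cultures = mat[idx])
  out <- out[order(out$asv_1, out$asv_2), ]
  attr(out, "proportions") <- long[, c("sample_id", "asv_id", "proportion")]
  out
}
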