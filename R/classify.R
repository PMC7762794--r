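#' Classify one culture from its post-curation ASV proportions
#'
#' Applies the standard screening rules for dilution cultures, in order:
#' \enumerate{
#'   \item zero post-curation reads: `no_amplification`;
#'   \item a single ASV at >= 90\% of reads with no other ASV at >= 5\%:
#'     `monoculture`;
#'   \item a single ASV at >= 90\% with at least one other ASV at >= 5\%:
#'     `mixed` (dominant plus every ASV at >= 5\% become members);
#'   \item a dominant ASV at >= 50\% but < 90\%: `mixed` (members as above);
#'   \item no ASV at >= 50\%: `no_dominant` (not considered further).
#' }
#' Member ASVs of monocultures and mixed cultures are the ones that receive
#' isolate identifiers.
#'
#' @param proportions named numeric vector of post-curation proportions for
#'   one culture (an all-zero vector marks a culture with no reads).
#' @param dominant,majority,minor classification thresholds (defaults 0.90,
#'   0.50, 0.05).
#' @param minor_inclusive treat exactly 5\% as a member (`>=`, the default)
#'   rather than requiring strictly more.
#' @param counts optional named raw counts for deterministic tie-breaking of
#'   two ASVs at exactly the majority threshold (higher count wins, then
#'   lexicographic ASV id). Proportion ties from a shared denominator are
#'   count ties, so this matters only for proportions computed elsewhere.
#' @return a one-row tibble: `category`, `dominant_asv`, `dominant_prop`,
#'   `n_members`, and `members` (list-column of tibbles `asv_id`,
#'   `proportion`).
#' @export
#' @examples
#' classify_culture(c(ASV_A = 0.95, ASV_B = 0.03, ASV_C = 0.02))
#' classify_culture(c(ASV_A = 0.60, ASV_B = 0.36, ASV_C = 0.04))
classify_culture <- function(proportions, dominant = 0.90, majority = 0.50,
                             minor = 0.05, minor_inclusive = TRUE,
                             counts = NULL) {
  check_thresholds(minor, majority, dominant)
  p <- proportions
  if (is.null(names(p)) || any(names(p) == "")) {
    abort("proportions must be a fully named vector")
  }
  total <- sum(p)
  if (total == 0) {
    return(culture_call_row("no_amplification", NA_character_, NA_real_,
                            empty_members()))
  }
  if (abs(total - 1) > 1e-6) {
    abort("proportions of a culture with reads must sum to 1 (within 1e-6)")
  }
  tie_counts <- if (is.null(counts)) rep(0, length(p)) else counts[names(p)]
  ord <- order(-p, -tie_counts, names(p))
  dom_id <- names(p)[ord[1]]
  dom_p <- p[[ord[1]]]
  meets_minor <- if (minor_inclusive) p >= minor else p > minor
  minors <- p[meets_minor & names(p) != dom_id]

  if (dom_p >= dominant && length(minors) == 0) {
    members <- tibble(asv_id = dom_id, proportion = dom_p)
    return(culture_call_row("monoculture", dom_id, dom_p, members))
  }
  if (dom_p >= majority) {
    minors <- minors[order(-minors, names(minors))]
    members <- tibble(asv_id = c(dom_id, names(minors)),
                      proportion = c(dom_p, unname(minors)))
    return(culture_call_row("mixed", dom_id, dom_p, members))
  }
  culture_call_row("no_dominant", NA_character_, dom_p, empty_members())
}

culture_call_row <- function(category, dom_id, dom_p, members) {
  tibble(category = category, dominant_asv = dom_id, dominant_prop = dom_p,
         n_members = nrow(members), members = list(members))
}

empty_members <- function() tibble(asv_id = character(0), proportion = numeric(0))

check_thresholds <- function(minor, majority, dominant) {
  if (!(0 < minor && minor < majority && majority <= dominant && dominant <= 1)) {
    abort("thresholds must satisfy 0 < minor < majority <= dominant <= 1")
  }
}

#' Classify every culture in an experiment
#'
#' Vectorised classification of a curated count table: computes within-sample
#' proportions, excludes non-culture samples when metadata is supplied, and
#' applies [classify_culture()]'s rules to every culture. A control sample
#' with nonzero post-curation reads triggers a contamination warning.
#'
#' @param counts curated wide ASV count tibble.
#' @param metadata optional sample metadata (`sample_id`, `role`,
#'   `experiment`); defaults to the table's attached metadata. Without any
#'   metadata all samples are treated as cultures.
#' @inheritParams classify_culture
#' @return a tibble with one row per culture: `sample_id`, `experiment`,
#'   `category`, `dominant_asv`, `dominant_prop`, `n_members`, `members`.
#' @export
classify_cultures <- function(counts, metadata = NULL, dominant = 0.90,
                              majority = 0.50, minor = 0.05,
                              minor_inclusive = TRUE) {
  check_thresholds(minor, majority, dominant)
  if (is.null(metadata)) metadata <- attr(counts, "metadata")
  experiment <- NA_character_
  if (!is.null(metadata)) {
    ctl <- metadata$sample_id[metadata$role == "control"]
    if (length(ctl) > 0) {
      ctl_tot <- rowSums(as.matrix(counts[counts$sample_id %in% ctl, -1]))
      if (any(ctl_tot > 0)) {
        warn(paste0("control sample(s) with post-curation reads (possible ",
                    "contamination): ",
                    paste(ctl[ctl_tot > 0], collapse = ", ")))
      }
    }
    keep <- metadata$sample_id[metadata$role == "culture"]
    counts <- counts[counts$sample_id %in% keep, , drop = FALSE]
    exps <- unique(metadata$experiment[metadata$role == "culture"])
    if (length(exps) == 1) experiment <- as.character(exps)
  }
  if (nrow(counts) == 0) abort("no culture samples to classify")

  # column order fixes lexicographic tie-breaking; proportions share a
  # denominator within a sample, so count ties and proportion ties coincide
  asv_order <- order(names(counts)[-1])
  m <- as.matrix(counts[-1])[, asv_order, drop = FALSE]
  totals <- rowSums(m)
  prop <- m / ifelse(totals > 0, totals, 1)
  dom_col <- max.col(prop, ties.method = "first")
  dom_p <- prop[cbind(seq_len(nrow(prop)), dom_col)]
  meets <- if (minor_inclusive) prop >= minor else prop > minor
  n_meet <- rowSums(meets)
  dom_meets <- if (minor_inclusive) dom_p >= minor else dom_p > minor
  has_other_minor <- (n_meet - as.integer(dom_meets)) > 0

  category <- dplyr::case_when(
    totals == 0 ~ "no_amplification",
    dom_p >= dominant & !has_other_minor ~ "monoculture",
    dom_p >= majority ~ "mixed",
    TRUE ~ "no_dominant"
  )
  dom_id <- colnames(prop)[dom_col]
  dom_id[category %in% c("no_amplification", "no_dominant")] <- NA_character_
  dom_p[category == "no_amplification"] <- NA_real_

  members <- vector("list", nrow(prop))
  for (i in seq_len(nrow(prop))) {
    members[[i]] <- switch(
      category[i],
      monoculture = tibble(asv_id = dom_id[i], proportion = dom_p[i]),
      mixed = {
        sel <- which(meets[i, ] & colnames(prop) != dom_id[i])
        sel <- sel[order(-prop[i, sel], colnames(prop)[sel])]
        tibble(asv_id = c(dom_id[i], colnames(prop)[sel]),
               proportion = c(dom_p[i], unname(prop[i, sel])))
      },
      empty_members()
    )
  }
  tibble(
    sample_id = counts$sample_id,
    experiment = experiment,
    category = category,
    dominant_asv = dom_id,
    dominant_prop = dom_p,
    n_members = vapply(members, nrow, integer(1)),
    members = members
  )
}

#' Tally culture calls by category
#'
#' @param calls tibble from [classify_cultures()].
#' @return a tibble `category`, `n` covering all four categories (zero-filled),
#'   in the fixed order monoculture, mixed, no_dominant, no_amplification.
#' @export
category_tally <- function(calls) {
  levels <- c("monoculture", "mixed", "no_dominant", "no_amplification")
  tal <- table(factor(calls$category, levels = levels))
  tibble(category = levels, n = as.integer(tal))
}

#' Assign isolate identifiers to member ASVs
#'
#' Every member ASV of a monoculture or mixed culture becomes one isolate
#' (strain) in the culture-collection registry, numbered sequentially with a
#' collection prefix (e.g. `"HIMB"`). Numbering order is deterministic:
#' sample order in `calls`, then member proportion descending, ties broken by
#' ASV id ascending.
#'
#' @param calls tibble from [classify_cultures()].
#' @param prefix culture-collection prefix for isolate ids.
#' @param start first number to assign.
#' @return a tibble: `isolate_id`, `asv_id`, `sample_id`, `experiment`,
#'   `category`, `proportion`.
#' @export
assign_isolate_ids <- function(calls, prefix = "HIMB", start = 1) {
  keep <- calls[calls$category %in% c("monoculture", "mixed"), , drop = FALSE]
  if (nrow(keep) == 0) {
    return(tibble(isolate_id = character(0), asv_id = character(0),
                  sample_id = character(0), experiment = character(0),
                  category = character(0), proportion = numeric(0)))
  }
  keep$.sample_order <- seq_len(nrow(keep))
  reg <- tidyr::unnest(
    keep[, c(".sample_order", "sample_id", "experiment", "category", "members")],
    "members")
  reg <- reg[order(reg$.sample_order, -reg$proportion, reg$asv_id), ]
  if (anyDuplicated(reg[, c("sample_id", "asv_id")])) {
    abort("duplicate isolate assignment: same ASV listed twice for one culture")
  }
  width <- max(4L, nchar(as.character(start + nrow(reg) - 1)))
  tibble(
    isolate_id = sprintf("%s%0*d", prefix, width, start + seq_len(nrow(reg)) - 1),
    asv_id = reg$asv_id,
    sample_id = reg$sample_id,
    experiment = reg$experiment,
    category = reg$category,
    proportion = reg$proportion
  )
}
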