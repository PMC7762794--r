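#' Simulate viable founder cells for each well
#'
#' Realises the Poisson extinction model that underlies limiting-dilution
#' viability estimation. Each well receives a Poisson number of cells with
#' mean `X = cells_per_well`, taxa are drawn by abundance, and each cell is
#' independently viable with its taxon's per-cell viability. By Poisson
#' thinning the viable founders of taxon `t` are therefore
#' `Poisson(X * abundance_t * viability_t)`, independently across taxa and
#' wells; a well is positive for growth iff it contains at least one viable
#' founder. This is exactly the regime in which `V = -ln(1 - p)/X` inverts
#' the fraction of positive wells into per-cell viability.
#'
#' @param community a [community_profile()].
#' @param design an [htc_design()].
#' @param seed integer seed; identical seed and inputs give byte-identical
#'   output.
#' @return a tibble with one row per well: `well_id`, one integer founder
#'   column per taxon, and `positive` (any viable founder present).
#' @seealso [expected_positive_fraction()] for the closed-form oracle.
#' @export
simulate_wells <- function(community, design, seed = NULL) {
  stopifnot(inherits(community, "community_profile"),
            inherits(design, "htc_design"))
  lambda <- design$cells_per_well * community$abundance * community$viability
  if (any(!is.finite(lambda))) abort("non-finite founder rate lambda")
  n <- design$n_wells
  k <- nrow(community)
  founders <- with_seed(substream(seed, 1L), {
    matrix(rpois(n * k, rep(lambda, each = n)), nrow = n, ncol = k)
  })
  colnames(founders) <- community$taxon_id
  width <- max(4L, nchar(as.character(n)))
  out <- tibble(well_id = sprintf("W%0*d", width, seq_len(n)))
  out <- dplyr::bind_cols(out, as_tibble(founders))
  out$positive <- rowSums(founders) > 0
  out
}

# Truncated lognormal depth draws, moment-matched to depth_mean/depth_sd and
# kept in [depth_min, depth_max] by rejection. depth_sd = 0 degenerates to a
# constant depth (rejection on a point mass would not terminate).
draw_depths <- function(n, design) {
  if (n == 0) return(integer(0))
  if (design$depth_sd == 0) return(rep(as.integer(round(design$depth_mean)), n))
  cv2 <- (design$depth_sd / design$depth_mean)^2
  sdlog <- sqrt(log1p(cv2))
  meanlog <- log(design$depth_mean) - sdlog^2 / 2
  out <- numeric(0)
  while (length(out) < n) {
    draw <- rlnorm(2L * (n - length(out)) + 16L, meanlog, sdlog)
    draw <- draw[draw >= design$depth_min & draw <= design$depth_max]
    out <- c(out, draw)
  }
  as.integer(round(out[seq_len(n)]))
}

#' Simulate per-culture ASV read counts from well ground truth
#'
#' Emulates the amplicon sequencing screen of grown cultures. Each positive
#' well receives a total read depth drawn from the design's truncated
#' lognormal model, distributed over taxa by a multinomial whose probabilities
#' are proportional to viable founder counts (equal per-taxon growth, with
#' optional per-taxon growth weights), after reassigning a `contamination`
#' fraction of probability mass to community taxa drawn by abundance.
#' Negative wells yield all-zero rows, the analogue of cultures that produced
#' no amplification product.
#'
#' @param wells output of [simulate_wells()].
#' @param community the [community_profile()] used to simulate `wells`.
#' @param design the [htc_design()]; supplies the depth model and the
#'   `contamination` fraction.
#' @param seed integer seed.
#' @param growth_weights optional positive per-taxon multipliers on founder
#'   counts (default: equal growth).
#' @return a wide ASV count tibble: `sample_id` followed by one integer
#'   column per taxon.
#' @export
simulate_reads <- function(wells, community, design, seed = NULL,
                           growth_weights = NULL) {
  stopifnot(inherits(community, "community_profile"),
            inherits(design, "htc_design"))
  eps <- design$contamination
  if (eps >= 1) abort("contamination must be < 1")
  taxa <- community$taxon_id
  if (!all(taxa %in% names(wells))) {
    abort("wells table lacks founder columns for some community taxa")
  }
  if (is.null(growth_weights)) growth_weights <- rep(1, length(taxa))
  if (any(growth_weights <= 0)) abort("growth_weights must be positive")
  founders <- as.matrix(wells[, taxa, drop = FALSE])
  n <- nrow(founders)
  counts <- matrix(0L, nrow = n, ncol = length(taxa),
                   dimnames = list(NULL, taxa))
  pos <- which(wells$positive)
  if (length(pos) > 0) {
    abund <- community$abundance / sum(community$abundance)
    with_seed(substream(seed, 2L), {
      depths <- draw_depths(length(pos), design)
      for (j in seq_along(pos)) {
        f <- founders[pos[j], ] * growth_weights
        base <- f / sum(f)
        probs <- (1 - eps) * base + eps * abund
        counts[pos[j], ] <- rmultinom(1, depths[j], probs)[, 1]
      }
    })
  }
  dplyr::bind_cols(tibble(sample_id = wells$well_id), as_tibble(counts))
}

#' Simulate the environmental (inoculum) sample
#'
#' One multinomial draw of `env_depth` reads over all community taxa,
#' proportional to abundance. Chloroplast-flagged taxa are included, as they
#' are in real bacterial-primer surveys of seawater; downstream environmental
#' curation removes them.
#'
#' @param community a [community_profile()].
#' @param env_depth total read depth (>= 1); default matches a deeply
#'   sequenced inoculum sample (65,924 reads).
#' @param seed integer seed.
#' @param sample_id name for the single sample row.
#' @return a one-row wide ASV count tibble.
#' @export
simulate_environment <- function(community, env_depth = 65924, seed = NULL,
                                 sample_id = "ENV1") {
  stopifnot(inherits(community, "community_profile"))
  if (length(env_depth) != 1 || !is.finite(env_depth) || env_depth < 1) {
    abort("env_depth must be a positive integer")
  }
  probs <- community$abundance / sum(community$abundance)
  counts <- with_seed(substream(seed, 3L), {
    rmultinom(1, as.integer(env_depth), probs)[, 1]
  })
  m <- matrix(as.integer(counts), nrow = 1,
              dimnames = list(NULL, community$taxon_id))
  dplyr::bind_cols(tibble(sample_id = sample_id), as_tibble(m))
}

#' Simulate a complete HTC experiment
#'
#' Convenience wrapper running [simulate_wells()], [simulate_reads()] and
#' [simulate_environment()] with substreams of one seed, and assembling the
#' sample metadata table the curation and classification steps expect.
#'
#' @inheritParams simulate_wells
#' @param experiment experiment label recorded in the metadata.
#' @param n_controls number of uninoculated control wells appended (all-zero
#'   rows with role `"control"`).
#' @return a list with elements `wells`, `counts`, `env`, `metadata` and
#'   `taxonomy` (taxonomy table derived from the community profile).
#' @export
simulate_experiment <- function(community, design, seed = NULL,
                                experiment = "sim1", n_controls = 0) {
  wells <- simulate_wells(community, design, seed)
  counts <- simulate_reads(wells, community, design, seed)
  env <- simulate_environment(community, design$env_depth, seed)
  if (n_controls > 0) {
    zero <- matrix(0L, nrow = n_controls, ncol = ncol(counts) - 1,
                   dimnames = list(NULL, names(counts)[-1]))
    ctl <- dplyr::bind_cols(
      tibble(sample_id = sprintf("CTRL%02d", seq_len(n_controls))),
      as_tibble(zero))
    counts <- dplyr::bind_rows(counts, ctl)
  }
  metadata <- tibble(
    sample_id = c(counts$sample_id, env$sample_id),
    role = c(rep("culture", design$n_wells),
             rep("control", n_controls),
             "environment"),
    experiment = experiment,
    cells_per_well = c(rep(design$cells_per_well, design$n_wells),
                       rep(NA_real_, n_controls), NA_real_)
  )
  taxonomy <- tibble(
    asv_id = community$taxon_id,
    lineage = community$lineage,
    group_label = community$group_label,
    is_chloroplast = community$is_chloroplast
  )
  list(wells = wells, counts = counts, env = env, metadata = metadata,
       taxonomy = taxonomy)
}

#' Closed-form probability that a well is positive for growth
#'
#' Under Poisson inoculation with mean `X` cells per well, the number of
#' viable founders is Poisson with mean `X * sum(abundance * viability)`, so
#' the probability of at least one is `1 - exp(-X * sum(a * v))`. Inverting
#' this relation for observed positive fractions is what the culturability
#' statistic `V = -ln(1 - p)/X` does.
#'
#' @param community a [community_profile()].
#' @param X mean cells per well (>= 0).
#' @return the expected fraction of positive wells.
#' @export
expected_positive_fraction <- function(community, X) {
  stopifnot(inherits(community, "community_profile"))
  if (!is.finite(X) || X < 0) abort("X must be non-negative")
  1 - exp(-X * sum(community$abundance * community$viability))
}

#' Closed-form probability that a well is positive and taxonomically pure
#'
#' The probability that exactly one taxon contributes viable founders:
#' `sum_t (1 - exp(-lambda_t)) * prod_{s != t} exp(-lambda_s)` with
#' `lambda_t = X * a_t * v_t`. Serves as the analytic oracle for the fraction
#' of wells expected to yield monocultures in the absence of sequencing noise
#' and contamination.
#'
#' @inheritParams expected_positive_fraction
#' @return the expected fraction of pure positive wells.
#' @export
expected_pure_well_fraction <- function(community, X) {
  stopifnot(inherits(community, "community_profile"))
  if (!is.finite(X) || X < 0) abort("X must be non-negative")
  lambda <- X * community$abundance * community$viability
  total <- sum(lambda)
  sum((1 - exp(-lambda)) * exp(-(total - lambda)))
}
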