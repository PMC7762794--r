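# Fixture builders shared across test files. All fixtures are generated in
# code; nothing is read from disk except where a test writes its own temp
# files first.

toy_community <- function(abundance = c(0.4, 0.3, 0.15, 0.1, 0.05),
                          viability = c(0.02, 0.05, 0.1, 0, 0.3),
                          ids = sprintf("ASV%03d", seq_along(abundance)),
                          ...) {
  community_profile(tibble::tibble(taxon_id = ids, abundance = abundance,
                                   viability = viability, ...))
}

uniform_community <- function(k, v, ids = sprintf("ASV%03d", seq_len(k))) {
  community_profile(tibble::tibble(taxon_id = ids, abundance = rep(1 / k, k),
                                   viability = rep(v, k)))
}

# Wide count tibble from named per-sample count lists, zero-filled.
make_counts <- function(...) {
  samples <- list(...)
  asvs <- sort(unique(unlist(lapply(samples, names))))
  rows <- lapply(names(samples), function(sid) {
    x <- stats::setNames(rep(0L, length(asvs)), asvs)
    x[names(samples[[sid]])] <- as.integer(samples[[sid]])
    dplyr::bind_cols(tibble::tibble(sample_id = sid),
                     tibble::as_tibble(as.list(x)))
  })
  dplyr::bind_rows(rows)
}

make_taxonomy <- function(asv_id, lineage = "", group_label = "") {
  tibble::tibble(asv_id = asv_id, lineage = lineage,
                 group_label = group_label,
                 is_chloroplast = grepl("(^|;)\\s*Chloroplast\\s*(;|$)", lineage))
}

# Independent literal restatement of the screening category sentences,
# used as the classification oracle. Deliberately written over the sorted
# proportion vector, with no shared code with classify_culture().
oracle_classify <- function(p) {
  if (sum(p) == 0) return("no_amplification")
  sorted <- sort(p, decreasing = TRUE)
  top <- sorted[1]
  rest <- sorted[-1]
  if (top >= 0.90 && !any(rest >= 0.05)) return("monoculture")
  if (top >= 0.90 && any(rest >= 0.05)) return("mixed")
  if (top >= 0.50) return("mixed")
  "no_dominant"
}

# All length-3 proportion vectors on a 0.05 grid summing to 1 (231 vectors).
proportion_grid <- function(step = 0.05) {
  n <- round(1 / step)
  grid <- expand.grid(i = 0:n, j = 0:n)
  grid <- grid[grid$i + grid$j <= n, ]
  t(apply(grid, 1, function(r) c(r[["i"]], r[["j"]], n - r[["i"]] - r[["j"]]) * step))
}

# Bisection oracle for exact binomial confidence limits: solves the tail
# equations P(X >= x | p_low) = alpha/2 and P(X <= x | p_high) = alpha/2
# directly, independent of the beta-quantile route.
cp_bisect <- function(x, n, alpha = 0.05, tol = 1e-12) {
  half <- alpha / 2
  lower <- if (x == 0) 0 else {
    f <- function(p) 1 - pbinom(x - 1, n, p) - half  # increasing in p
    uniroot(f, c(0, 1), tol = tol)$root
  }
  upper <- if (x == n) 1 else {
    f <- function(p) pbinom(x, n, p) - half          # decreasing in p
    uniroot(f, c(0, 1), tol = tol)$root
  }
  c(lower = lower, upper = upper)
}
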