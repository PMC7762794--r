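#' Describe a dilution-to-extinction experiment design
#'
#' Captures the plate layout and sequencing-depth model of one high-throughput
#' culturing (HTC) experiment: how many wells are inoculated, the mean number
#' of cells per well, and the lognormal read-depth distribution used when
#' simulating per-culture amplicon libraries. Depth defaults reproduce the
#' per-culture depths typical of HTC amplicon screens (mean 14,047, SD 8,014,
#' range 679 to 57,557 reads; environmental sample 65,924 reads).
#'
#' @param n_wells number of inoculated wells (>= 1).
#' @param cells_per_well mean number of cells per inoculation, `X` (> 0).
#'   In a dilute suspension the realised cell number per well is
#'   Poisson-distributed around this mean.
#' @param depth_mean,depth_sd mean and SD of per-culture read depth. Setting
#'   `depth_sd = 0` gives every positive well exactly `depth_mean` reads.
#' @param depth_min,depth_max truncation range for read depth.
#' @param env_depth read depth of the environmental (inoculum) sample.
#' @param contamination fraction of read probability mass reassigned to
#'   community taxa drawn by abundance, emulating low-level cross-talk and
#'   reagent contamination; must be `< 1`.
#' @param growth_threshold informational flow-cytometry positivity threshold
#'   (cells per ml); growth dynamics are not modelled.
#' @return a one-row tibble of class `htc_design`.
#' @export
#' @examples
#' htc_design(n_wells = 576, cells_per_well = 5)
htc_design <- function(n_wells,
                       cells_per_well,
                       depth_mean = 14047,
                       depth_sd = 8014,
                       depth_min = 679,
                       depth_max = 57557,
                       env_depth = 65924,
                       contamination = 0.005,
                       growth_threshold = 1e4) {
  if (length(n_wells) != 1 || !is.finite(n_wells) || n_wells < 1 ||
      n_wells != as.integer(n_wells)) {
    abort("n_wells must be a positive integer")
  }
  if (!is.finite(cells_per_well) || cells_per_well <= 0) {
    abort("cells_per_well must be a positive number")
  }
  if (!(depth_min <= depth_mean && depth_mean <= depth_max)) {
    abort("require depth_min <= depth_mean <= depth_max")
  }
  if (depth_sd < 0) abort("depth_sd must be non-negative")
  if (contamination < 0 || contamination >= 1) {
    abort("contamination must lie in [0, 1)")
  }
  if (env_depth < 1) abort("env_depth must be at least 1")
  out <- tibble(
    n_wells = as.integer(n_wells),
    cells_per_well = as.numeric(cells_per_well),
    depth_mean = depth_mean,
    depth_sd = depth_sd,
    depth_min = depth_min,
    depth_max = depth_max,
    env_depth = env_depth,
    contamination = contamination,
    growth_threshold = growth_threshold
  )
  class(out) <- c("htc_design", class(out))
  out
}
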