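#' Configuration of a synthetic genetic-interaction screen
#'
#' Bundles every tunable of the synthetic eSGA-style screen generator:
#' screen geometry (queries, recipients, plate density, colony duplicates,
#' replicate screens), the noise model, planted-epistasis fractions, and the
#' linkage-suppression window. The defaults emulate a genome-scale bacterial
#' screen: 163 query donors crossed to a 4,117-strain recipient array
#' (including a small fraction of hypomorphic essential-gene alleles) on
#' 384-colony plates arrayed in duplicate, with two replicate screens so that
#' every pair is measured eight times.
#'
#' @param n_queries Number of query (donor) genes.
#' @param n_recipients Number of recipient (array) genes; queries are drawn
#'   from this gene universe.
#' @param frac_hypomorph Fraction of recipients carried as hypomorphic
#'   alleles of essential genes rather than outright deletions.
#' @param plate_density Colonies per plate (rows x columns; 384 = 16 x 24).
#' @param n_colony_duplicates Number of positions each recipient occupies on
#'   a plate.
#' @param n_replicate_screens Number of independent replicate screens; each
#'   replicate is pinned as two plate copies, so measurements per pair equal
#'   `n_colony_duplicates * n_replicate_screens * 2`.
#' @param plate_scale Nominal colony size (area units) of a healthy colony.
#' @param noise_sd Lognormal sigma of per-colony multiplicative size noise.
#' @param replicate_effect_sd Lognormal sigma of the per-plate-copy,
#'   per-strain effect shared by duplicate colonies pinned from the same
#'   source position: biological variation between replicate platings
#'   (conjugation efficiency, outgrowth timing), the component that limits
#'   replicate-screen reproducibility.
#' @param spatial_row_amp,spatial_col_amp Amplitudes of smooth sinusoidal
#'   row/column growth gradients (fraction of plate scale).
#' @param edge_boost Additive growth boost on edge rows/columns (nutrient
#'   edge effect), as a fraction of the nominal effect factor.
#' @param batch_effect_sd Lognormal sigma of per-plate batch scale wobble.
#' @param frac_aggravating,frac_alleviating Expected fractions of tested
#'   pairs carrying planted aggravating (negative) / alleviating (positive)
#'   epistasis. Their sum must be <= 1.
#' @param coupled_density Planting probability for gene pairs falling inside
#'   a designated coupled module pair (the within/between-module signal that
#'   downstream enrichment stages must recover).
#' @param eps_aggravating,eps_alleviating Ranges (length-2) of planted
#'   epistasis deviations on the multiplicative scale (the deviation e in
#'   the double-mutant factor `1 + e`).
#' @param linkage_window_bp Chromosomal window inside which double mutants
#'   suffer linkage suppression and are masked from scoring.
#' @param linkage_factor Multiplicative colony-size suppression applied to
#'   pairs within the linkage window.
#' @param chromosome_length_bp Length of the single circular chromosome.
#' @param module_size Genes per planted functional module.
#' @param n_modules Number of planted modules (default ~40% gene coverage).
#' @param n_processes Number of bioprocess categories modules are annotated
#'   with.
#' @param frac_sick_deletion Fraction of deletion strains with a fitness
#'   defect; the remainder sit at fitness 1 (no defect on rich medium).
#' @param sick_fitness_range Fitness range (uniform) of sick deletions.
#' @param hypomorph_fitness_range Fitness range (uniform) of hypomorphs;
#'   narrower and higher than sick deletions because hypomorphs are viable
#'   partial-function alleles of essential genes.
#' @param rng_seed Integer seed; the same seed yields bit-identical screens.
#'
#' @return An object of class `screen_config` (a validated list).
#' @export
screen_config <- function(n_queries = 163L,
                          n_recipients = 4117L,
                          frac_hypomorph = 149 / 4117,
                          plate_density = 384L,
                          n_colony_duplicates = 2L,
                          n_replicate_screens = 2L,
                          plate_scale = 100,
                          noise_sd = 0.15,
                          replicate_effect_sd = 0.12,
                          spatial_row_amp = 0.08,
                          spatial_col_amp = 0.08,
                          edge_boost = 0.15,
                          batch_effect_sd = 0.10,
                          frac_aggravating = 0.02,
                          frac_alleviating = 0.015,
                          coupled_density = 0.4,
                          eps_aggravating = c(-0.9, -0.3),
                          eps_alleviating = c(0.3, 0.9),
                          linkage_window_bp = 30000,
                          linkage_factor = 0.05,
                          chromosome_length_bp = 4641652,
                          module_size = 6L,
                          n_modules = NULL,
                          n_processes = 8L,
                          frac_sick_deletion = 0.4,
                          sick_fitness_range = c(0.2, 1.0),
                          hypomorph_fitness_range = c(0.5, 0.9),
                          rng_seed = 1L) {
  cfg <- list(
    n_queries = as.integer(n_queries),
    n_recipients = as.integer(n_recipients),
    frac_hypomorph = frac_hypomorph,
    plate_density = as.integer(plate_density),
    n_colony_duplicates = as.integer(n_colony_duplicates),
    n_replicate_screens = as.integer(n_replicate_screens),
    plate_scale = plate_scale,
    noise_sd = noise_sd,
    replicate_effect_sd = replicate_effect_sd,
    spatial_row_amp = spatial_row_amp,
    spatial_col_amp = spatial_col_amp,
    edge_boost = edge_boost,
    batch_effect_sd = batch_effect_sd,
    frac_aggravating = frac_aggravating,
    frac_alleviating = frac_alleviating,
    coupled_density = coupled_density,
    eps_aggravating = eps_aggravating,
    eps_alleviating = eps_alleviating,
    linkage_window_bp = linkage_window_bp,
    linkage_factor = linkage_factor,
    chromosome_length_bp = chromosome_length_bp,
    module_size = as.integer(module_size),
    n_modules = if (is.null(n_modules)) NULL else as.integer(n_modules),
    n_processes = as.integer(n_processes),
    frac_sick_deletion = frac_sick_deletion,
    sick_fitness_range = sick_fitness_range,
    hypomorph_fitness_range = hypomorph_fitness_range,
    rng_seed = as.integer(rng_seed)
  )
  if (is.null(cfg$n_modules)) {
    cfg$n_modules <- max(4L, as.integer(floor(cfg$n_recipients * 0.4 / cfg$module_size)))
  }
  class(cfg) <- "screen_config"
  validate_screen_config(cfg)
  cfg
}

validate_screen_config <- function(cfg) {
  stop_cfg <- function(field, why) {
    stop(sprintf("invalid screen_config field '%s': %s", field, why),
         call. = FALSE)
  }
  counts <- c("n_queries", "n_recipients", "plate_density",
              "n_colony_duplicates", "n_replicate_screens", "module_size",
              "n_modules", "n_processes")
  for (f in counts) {
    v <- cfg[[f]]
    if (length(v) != 1L || is.na(v) || v < 1L) stop_cfg(f, "must be a positive count")
  }
  if (cfg$n_queries > cfg$n_recipients)
    stop_cfg("n_queries", "queries are drawn from the recipient gene universe")
  if (cfg$plate_density %% cfg$n_colony_duplicates != 0L)
    stop_cfg("n_colony_duplicates", "must divide plate_density")
  for (f in c("frac_hypomorph", "frac_aggravating", "frac_alleviating",
              "coupled_density", "frac_sick_deletion", "linkage_factor")) {
    v <- cfg[[f]]
    if (length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop_cfg(f, "must lie in [0, 1]")
  }
  if (cfg$frac_aggravating + cfg$frac_alleviating > 1)
    stop_cfg("frac_aggravating", "planted fractions must sum to <= 1")
  for (f in c("plate_scale", "chromosome_length_bp", "linkage_window_bp")) {
    if (cfg[[f]] <= 0) stop_cfg(f, "must be positive")
  }
  for (f in c("noise_sd", "replicate_effect_sd", "spatial_row_amp",
              "spatial_col_amp", "edge_boost", "batch_effect_sd")) {
    if (cfg[[f]] < 0) stop_cfg(f, "must be non-negative")
  }
  for (f in c("eps_aggravating", "eps_alleviating", "sick_fitness_range",
              "hypomorph_fitness_range")) {
    v <- cfg[[f]]
    if (length(v) != 2L || any(is.na(v)) || v[1] > v[2])
      stop_cfg(f, "must be an ordered length-2 range")
  }
  if (cfg$eps_aggravating[1] < -1)
    stop_cfg("eps_aggravating", "deviation below -1 implies negative colony size")
  if (any(cfg$sick_fitness_range <= 0) || any(cfg$hypomorph_fitness_range <= 0))
    stop_cfg("sick_fitness_range", "arrayed single mutants must be viable (fitness > 0)")
  invisible(cfg)
}

#' @export
print.screen_config <- function(x, ...) {
  cat(sprintf(
    "screen_config: %d queries x %d recipients, %d-colony plates, %dx duplicates, %d replicate screens\n",
    x$n_queries, x$n_recipients, x$plate_density, x$n_colony_duplicates,
    x$n_replicate_screens))
  cat(sprintf("  measurements per pair: %d; noise_sd %.3g; planted frac (agg, all) = (%.3g, %.3g)\n",
              x$n_colony_duplicates * x$n_replicate_screens * 2L,
              x$noise_sd, x$frac_aggravating, x$frac_alleviating))
  invisible(x)
}

# Plate geometry: rows x cols closest to 2:3 (384 -> 16 x 24).
plate_dims <- function(plate_density) {
  r <- floor(sqrt(plate_density * 2 / 3))
  while (r > 1L && plate_density %% r != 0L) r <- r - 1L
  c(rows = as.integer(r), cols = as.integer(plate_density / r))
}
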