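# Scenario presets: the three species designs at small and large scale, and
# their documented desk-scale reductions (population sizes / 10, historical
# generations / 4, SNP panel / 10; the fish nucleus of 20 sires x 20 dams is
# kept intact because it defines that design's effective population size).

#' Scenario parameters for the preset populations
#'
#' Returns the genome, historical-phase, trait and recent-design parameters
#' for a preset.  With \code{scaled_down = TRUE} (the default everywhere in
#' the package) the documented divisors are applied: population sizes and
#' the SNP panel by 10, historical generations by 4.
#'
#' @param preset \code{"fish"}, \code{"beef"} or \code{"dairy"}.
#' @param scale \code{"small"} or \code{"large"} population series.
#' @param scaled_down apply the desk-scale divisors.
#' @return List with \code{genome} (a \code{\link{genome_spec}}),
#'   \code{trait} (a \code{\link{trait_spec}}), \code{hist_sizes},
#'   \code{prop_male}, and \code{recent} (design parameter list).
#' @export
scenario_params <- function(preset = c("fish", "beef", "dairy"),
                            scale = c("small", "large"),
                            scaled_down = TRUE) {
  preset <- match.arg(preset)
  scale <- match.arg(scale)
  if (preset == "fish") {
    # the large-series reduction keeps enough terminal animals (32% male)
    # to seed the intact 200 x 200 nucleus, hence sizes / 4 there
    hist_div <- if (scale == "large") 4 else 10
    hist_sizes <- if (scaled_down)
      round(seq(5000, 3100, length.out = 51) / hist_div)
    else
      round(seq(5000, 3100, length.out = 201))
    prop_male <- 0.32
    n_snps <- if (scaled_down) 3500 else 35000
    trait <- trait_spec(heritability = 0.25, sex_limited = FALSE)
    # the nucleus (sires x dams) defines each fish design -- its effective
    # population size and family structure -- so desk-scale reductions
    # divide the litter, never the nucleus
    recent <- list(n_sires = 20, n_dams = 20, n_gen_random = 5,
                   off_per_dam = 2, litter = 100, geno_frac = 0.5)
    if (scale == "large") {
      recent$n_sires <- 200; recent$n_dams <- 200
    }
    if (scaled_down) recent$litter <- 10
  } else {
    hist_sizes <- if (scaled_down)
      c(round(seq(100, 5000, length.out = 251)),
        round(seq(5000, 2300, length.out = 251))[-1])
    else
      c(round(seq(1000, 50000, length.out = 1001)),
        round(seq(50000, 23000, length.out = 1001))[-1])
    prop_male <- 3000 / 23000
    n_snps <- if (scaled_down) 6500 else 65000
    if (preset == "beef") {
      trait <- trait_spec(heritability = 0.30, sex_limited = TRUE)
      mult <- if (scale == "large") 5 else 1
      div <- if (scaled_down) 10 else 1
      recent <- list(n_sires = max(2, round(200 * mult / div)),
                     n_dams = round(10000 * mult / div),
                     n_gen_random = 5, off_per_dam = 2,
                     n_lines = 5, line_sires = 10,
                     line_dams = round(500 * mult / div),
                     line_gens = 2, line_off_per_dam = 2,
                     pool_gens = 5, pool_off_per_dam = 2)
    } else {
      trait <- trait_spec(heritability = 0.35, sex_limited = TRUE)
      # sires scaled by 10 in the large series (ten times more genotyped
      # bulls); the desk-scale preset keeps ~10 phenotyped daughters per
      # genotyped sire
      if (scaled_down) {
        recent <- list(n_sires = if (scale == "large") 1000 else 200,
                       n_dams = if (scale == "large") 7000 else 2000,
                       n_gens = 10, off_per_dam = 2, geno_gen = 7)
      } else {
        recent <- list(n_sires = if (scale == "large") 10000 else 1000,
                       n_dams = if (scale == "large") 70000 else 20000,
                       n_gens = 10, off_per_dam = 2, geno_gen = 7)
      }
    }
  }
  list(genome = genome_spec(n_snps = n_snps),
       trait = trait, hist_sizes = hist_sizes, prop_male = prop_male,
       recent = recent, preset = preset, scale = scale,
       scaled_down = scaled_down)
}

#' Simulate a complete preset scenario
#'
#' Runs the historical phase and the recent-population design for one preset
#' and returns the full \code{gwas_sim} (pedigree, genotype panel,
#' phenotypes, QTN registry, true variance components).
#'
#' @inheritParams scenario_params
#' @param seed scenario seed; expanded into independent sub-stream seeds for
#'   the historical and recent stages.
#' @param overrides optional named list patched over the preset parameters
#'   (\code{genome}, \code{hist_sizes}, \code{prop_male}, \code{trait},
#'   \code{recent}); \code{recent} entries are merged element-wise.
#' @return A \code{gwas_sim}.
#' @export
sim_scenario <- function(preset = c("fish", "beef", "dairy"),
                         scale = c("small", "large"), scaled_down = TRUE,
                         seed = 1L, overrides = NULL) {
  pars <- scenario_params(preset, scale, scaled_down)
  if (!is.null(overrides)) {
    if (!is.null(overrides$recent)) {
      pars$recent[names(overrides$recent)] <- overrides$recent
      overrides$recent <- NULL
    }
    pars[names(overrides)] <- overrides
  }
  seeds <- derive_seeds(seed, 2)
  pool <- simulate_historical(pars$genome, pars$hist_sizes, pars$prop_male,
                              seed = seeds[1])
  sim <- simulate_recent(pars$preset, pool, pars$trait, pars$recent,
                         seed = seeds[2])
  sim$meta$preset <- pars$preset
  sim$meta$scale <- pars$scale
  sim$meta$scaled_down <- pars$scaled_down
  sim$meta$seed <- seed
  sim
}
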