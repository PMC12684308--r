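#' Configuration of the three-tier rescue experiment
#'
#' Describes the demographic design simulated by [simulate_experiment()]:
#' a large base population (BP) kept as bottles under circular mixing, a set
#' of moderate-size populations (N50) founded from the BP, and three sets of
#' small lines (N8) founded from each surviving N50 — a non-rescued control,
#' lines rescued with males from another N50, and lines rescued with BP
#' males. Rescue introduces one extra male at each of `rescue_generations`;
#' surviving lines are duplicated at `duplication_generation`.
#'
#' The full design (defaults) is 32 bottles of 80 flies, 30 N50 populations
#' of 25 males + 25 females run for 31 generations after founding at BP
#' generation 10, and lines of 4 males + 4 females run for 33 generations.
#'
#' @param n_bottles,bottle_size Bottles of the base population and flies per
#'   bottle (half of each sex).
#' @param founding_generation_of_n50 BP generation at which N50 populations
#'   are founded by sampling across bottles.
#' @param n50_count,n50_size,n50_generations Number, census size (half each
#'   sex) and duration of the N50 populations.
#' @param n8_size,n8_generations Census size (half each sex) and duration of
#'   the small lines.
#' @param lines_per_n50 Lines founded per treatment from each surviving N50.
#' @param rescue_generations Line generations at which a single migrant male
#'   is introduced into rescued lines.
#' @param duplication_generation Line generation at which surviving lines are
#'   duplicated into two independent lines (`NA` disables duplication).
#' @param sequencing_generation Line generation at which 12 males of one
#'   non-rescued and one rescued-BP line are sampled for genotyping.
#' @param p_max Expected juveniles per mating pair at relative fitness 1.
#' @param rearing_capacity Vial/bottle crowding cap: at most
#'   `rearing_capacity` times the census size of juveniles are reared per
#'   population per generation.
#' @param n_assay_vials_outbred,n_assay_vials_inbred Vials per scheme in the
#'   productivity assays.
#' @param vial_noise_sd SD of the multiplicative lognormal vial noise on
#'   productivity counts.
#' @param n_neutral_loci,n_deleterious_loci,n_lethal_loci Loci of each class
#'   laid out on the simulated genome.
#' @param genome_length_bp Total autosomal length represented (default 110 Mb
#'   over arms 2L, 2R, 3L and 3R).
#' @param mean_recomb_cM_per_Mb Genome-average recombination rate of the
#'   100-kb-bin map.
#' @return An object of class `experiment_config`.
#' @seealso [reduced_experiment_config()] for a desk-scale validation design.
#' @export
experiment_config <- function(n_bottles = 32,
                              bottle_size = 80,
                              founding_generation_of_n50 = 10,
                              n50_count = 30,
                              n50_size = 50,
                              n50_generations = 31,
                              n8_size = 8,
                              n8_generations = 33,
                              lines_per_n50 = 2,
                              rescue_generations = c(2, 3),
                              duplication_generation = 7,
                              sequencing_generation = 11,
                              p_max = 90,
                              rearing_capacity = 5,
                              n_assay_vials_outbred = 81,
                              n_assay_vials_inbred = 56,
                              vial_noise_sd = 0.3,
                              n_neutral_loci = 3000,
                              n_deleterious_loci = 1500,
                              n_lethal_loci = 300,
                              genome_length_bp = 110e6,
                              mean_recomb_cM_per_Mb = 2) {
  counts <- c(n_bottles, bottle_size, n50_count, n50_size, n50_generations,
              n8_size, n8_generations, lines_per_n50, founding_generation_of_n50)
  if (any(counts <= 0) || any(counts != round(counts))) {
    abort("Design counts must be positive integers.")
  }
  if (bottle_size %% 2 != 0 || n50_size %% 2 != 0 || n8_size %% 2 != 0) {
    abort("Census sizes must be even (half of each sex).")
  }
  if (length(rescue_generations) &&
      (any(rescue_generations < 1) || any(rescue_generations > n8_generations))) {
    abort("`rescue_generations` must lie within [1, n8_generations].")
  }
  if (p_max <= 0) abort("`p_max` must be positive.")
  structure(
    list(
      n_bottles = n_bottles,
      bottle_size = bottle_size,
      founding_generation_of_n50 = founding_generation_of_n50,
      n50_count = n50_count,
      n50_size = n50_size,
      n50_generations = n50_generations,
      n8_size = n8_size,
      n8_generations = n8_generations,
      lines_per_n50 = lines_per_n50,
      rescue_generations = sort(unique(rescue_generations)),
      duplication_generation = duplication_generation,
      sequencing_generation = sequencing_generation,
      p_max = p_max,
      rearing_capacity = rearing_capacity,
      n_assay_vials_outbred = n_assay_vials_outbred,
      n_assay_vials_inbred = n_assay_vials_inbred,
      vial_noise_sd = vial_noise_sd,
      n_neutral_loci = n_neutral_loci,
      n_deleterious_loci = n_deleterious_loci,
      n_lethal_loci = n_lethal_loci,
      genome_length_bp = genome_length_bp,
      mean_recomb_cM_per_Mb = mean_recomb_cM_per_Mb
    ),
    class = "experiment_config"
  )
}

#' Reduced validation design
#'
#' A scaled-down version of the experiment used for stochastic validation of
#' the simulator (replicated runs are affordable at this size): 8 bottles of
#' 20 flies, 5 N50 populations of 20 individuals run for 15 generations
#' after founding at BP generation 2, 10 lines per treatment run for 15
#' generations, and a reduced genome. Rescue generations and all model rules
#' are those of the full design; duplication is disabled.
#'
#' @param ... Overrides passed on to [experiment_config()].
#' @return An `experiment_config`.
#' @export
reduced_experiment_config <- function(...) {
  defaults <- list(
    n_bottles = 8,
    bottle_size = 20,
    founding_generation_of_n50 = 2,
    n50_count = 5,
    n50_size = 20,
    n50_generations = 15,
    n8_size = 8,
    n8_generations = 15,
    lines_per_n50 = 2,
    rescue_generations = c(2, 3),
    duplication_generation = NA,
    sequencing_generation = 11,
    n_assay_vials_outbred = 81,
    n_assay_vials_inbred = 56,
    n_neutral_loci = 600,
    n_deleterious_loci = 400,
    n_lethal_loci = 100
  )
  overrides <- list(...)
  defaults[names(overrides)] <- overrides
  do.call(experiment_config, defaults)
}

# Total BP generations needed to run the whole design in parallel.
bp_total_generations <- function(config) {
  config$founding_generation_of_n50 + config$n50_generations +
    config$n8_generations
}

#' @export
print.experiment_config <- function(x, ...) {
  cat("<experiment_config>\n")
  cat(sprintf("  BP: %d bottles x %d flies, circular mixing, %d generations total\n",
              x$n_bottles, x$bottle_size, bp_total_generations(x)))
  cat(sprintf("  N50: %d populations of %d, founded at BP gen %d, run %d generations\n",
              x$n50_count, x$n50_size, x$founding_generation_of_n50,
              x$n50_generations))
  cat(sprintf("  Lines: 3 treatments x %d per N50, census %d, %d generations\n",
              x$lines_per_n50, x$n8_size, x$n8_generations))
  cat(sprintf("  rescue at line generations %s; duplication at %s\n",
              paste(x$rescue_generations, collapse = ", "),
              ifelse(is.na(x$duplication_generation), "none",
                     x$duplication_generation)))
  invisible(x)
}

#' Read an experiment configuration from YAML
#'
#' The YAML file may contain any subset of [experiment_config()] and
#' [mutation_model()] fields under top-level keys `design` and `mutation`.
#'
#' @param path Path to a YAML file.
#' @return A list with elements `config` and `model`.
#' @export
read_experiment_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- do.call(experiment_config, y$design %||% list())
  model_args <- y$mutation %||% list()
  model <- do.call(mutation_model, model_args)
  list(config = cfg, model = model)
}
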