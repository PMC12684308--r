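#' Run a configured analysis pipeline
#'
#' Executes the requested stages in order — `simulate`, `delta`, `popgen`,
#' `roh`, `load`, `survival` — and writes a machine-readable JSON report
#' plus a log of seeds and the package version. Re-running with an
#' identical configuration reproduces an identical report.
#'
#' The configuration is a YAML file (or an equivalent list) with a
#' top-level `stages` vector, a `seed`, optional `design`/`mutation`
#' sections for the simulator, and per-stage input paths:
#' \describe{
#'   \item{delta}{`productivity`: CSV of vial records (`population_id`,
#'     `scheme`, `vial_id`, `pupae_count`) or of scheme summaries
#'     (`population_id`, `scheme`, `mean_pupae`); `F` (default 0.25);
#'     `n_boot` (records only).}
#'   \item{popgen, roh, load}{`vcf` (and `vcf_ref` for load), optional
#'     `annotation` TSV and `recomb_map` BED.}
#'   \item{survival}{`records`: CSV of line fates; `horizon`.}
#' }
#'
#' @param config Path to a YAML file or a list.
#' @param out_dir Directory for `report.json` (created if needed);
#'   `NULL` skips writing.
#' @return The report, invisibly, as a nested list.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  stages <- cfg$stages %||% character()
  seed <- cfg$seed %||% 1L
  report <- list(seed = seed,
                 package_version = as.character(utils::packageVersion("rescuelab")),
                 stages = as.list(setNames(nm = stages)))
  sim <- NULL

  for (stage in stages) {
    report$stages[[stage]] <- switch(
      stage,
      simulate = {
        design <- do.call(experiment_config, cfg$design %||% list())
        model <- do.call(mutation_model, cfg$mutation %||% list())
        sim <- simulate_experiment(design, model, seed = seed)
        list(
          n_lines = nrow(sim$survival),
          n_extinct = sum(!is.na(sim$survival$extinction_generation)),
          final_survival_pct = as.list(
            survival_curve(sim$survival, horizon = design$n8_generations) |>
              filter(.data$generation == design$n8_generations) |>
              select("treatment", "surviving_pct") |>
              tidyr::pivot_wider(names_from = "treatment",
                                 values_from = "surviving_pct")
          )
        )
      },
      delta = {
        prod <- read_productivity_csv(cfg$delta$productivity)
        Fval <- cfg$delta$F %||% 0.25
        if ("pupae_count" %in% names(prod)) {
          n_boot <- cfg$delta$n_boot %||% 1000
          ests <- prod |>
            group_by(.data$population_id) |>
            dplyr::group_map(function(d, key) {
              e <- estimate_delta(d$pupae_count[d$scheme == "outbred"],
                                  d$pupae_count[d$scheme == "inbred"],
                                  F = Fval, n_boot = n_boot, seed = seed)
              c(list(population = key$population_id[[1]]),
                glance(e) |> as.list())
            })
          ests
        } else {
          prod |>
            tidyr::pivot_wider(names_from = "scheme",
                               values_from = "mean_pupae") |>
            mutate(delta = delta_from_means(.data$outbred, .data$inbred,
                                            Fval)) |>
            purrr::transpose()
        }
      },
      popgen = {
        gm <- load_genotypes(cfg$popgen$vcf,
                             annotation = cfg$popgen$annotation)$genotypes
        as.list(diversity_summary(gm))
      },
      roh = {
        loaded <- load_genotypes(
          cfg$roh$vcf,
          policy = site_filter_policy(drop_monomorphic = FALSE)
        )
        segs <- call_roh(loaded$genotypes, params = roh_params())
        fr <- f_roh(segs, cfg$roh$genome_length_bp %||% 110e6)
        list(n_segments = nrow(segs),
             mean_f_roh = if (nrow(fr)) mean(fr$f_roh) else 0)
      },
      load = {
        pol <- site_filter_policy(drop_monomorphic = FALSE)
        focal <- load_genotypes(cfg$load$vcf_focal, pol,
                                annotation = cfg$load$annotation,
                                line = "focal")$genotypes
        ref <- load_genotypes(cfg$load$vcf_ref, pol,
                              annotation = cfg$load$annotation,
                              line = "reference")$genotypes
        std <- standardize_load(derived_count_profile(focal),
                                derived_count_profile(ref))
        purrr::transpose(load_summary(std))
      },
      survival = {
        rec <- read_survival_csv(cfg$survival$records)
        horizon <- cfg$survival$horizon %||% 33
        list(
          final = purrr::transpose(
            survival_curve(rec, horizon) |>
              filter(.data$generation == horizon)),
          interval_rates = purrr::transpose(
            interval_extinction_rate(rec, horizon = horizon))
        )
      },
      abort(sprintf("Unknown pipeline stage: %s", stage))
    )
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(report)
}
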