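# Driver for the full three-tier experiment.

deal_roundrobin <- function(members_by_group, need) {
  # interleave shuffled group member lists so early picks spread evenly
  # across groups (1-2 per group when groups are plentiful)
  groups <- lapply(members_by_group, function(g) g[sample.int(length(g))])
  groups <- groups[sample.int(length(groups))]
  out <- integer(0)
  r <- 1L
  while (length(out) < need) {
    added <- FALSE
    for (g in groups) {
      if (r <= length(g)) {
        out <- c(out, g[r])
        added <- TRUE
        if (length(out) >= need) break
      }
    }
    if (!added) break
    r <- r + 1L
  }
  out
}

found_n50_sets <- function(bp, config, ctx) {
  per_sex <- config$n50_size / 2
  sel <- lapply(c(1L, 2L), function(s) {
    members <- split(which(bp$sex == s), bp$bottle[bp$sex == s])
    deal_roundrobin(members, per_sex * config$n50_count)
  })
  pops <- vector("list", config$n50_count)
  for (k in seq_len(config$n50_count)) {
    take <- c(sel[[1]][seq.int((k - 1) * per_sex + 1, k * per_sex)],
              sel[[2]][seq.int((k - 1) * per_sex + 1, k * per_sex)])
    take <- take[!is.na(take)]
    p <- subset_population(bp, take)
    p$bottle <- NULL
    p$F <- numeric(pop_size(p))
    p$kin <- diag(0.5, pop_size(p))
    pops[[k]] <- p
    ctx$ped[[length(ctx$ped) + 1L]] <- tibble(
      id = p$id, sire = NA_integer_, dam = NA_integer_, sex = p$sex,
      population = sprintf("n50_%02d", k), generation = 0L
    )
  }
  pops
}

found_lines_from_n50 <- function(n50, origin, config, genome, ctx) {
  treatments <- c("non_rescued", "rescued_n50", "rescued_bp")
  n_vials <- length(treatments) * config$lines_per_n50
  per_sex <- config$n8_size / 2
  need <- n_vials * per_sex

  enough <- sum(n50$sex == 1L) >= need && sum(n50$sex == 2L) >= need
  if (enough) {
    src <- n50
    males <- which(src$sex == 1L); males <- males[sample.int(length(males), need)]
    females <- which(src$sex == 2L); females <- females[sample.int(length(females), need)]
  } else {
    # not enough adults: found the vials from a progeny pool of the N50
    pool <- breed_pool(n50, which(n50$sex == 2L), which(n50$sex == 1L),
                       p_max = config$p_max,
                       cap = max(6L * need, 4L * config$rearing_capacity * config$n8_size),
                       genome = genome)
    if (is.null(pool)) return(NULL)
    G <- length(pool$sex)
    F_off <- n50$kin[cbind(pool$dam, pool$sire)]
    M <- matrix(0, G, pop_size(n50))
    M[cbind(seq_len(G), pool$dam)] <- M[cbind(seq_len(G), pool$dam)] + 0.5
    M[cbind(seq_len(G), pool$sire)] <- M[cbind(seq_len(G), pool$sire)] + 0.5
    kin <- M %*% n50$kin %*% t(M)
    diag(kin) <- 0.5 * (1 + F_off)
    ids <- seq.int(ctx$next_id, length.out = G)
    ctx$next_id <- ctx$next_id + G
    src <- new_population(pool$h1, pool$h2, pool$a1, pool$a2, pool$sex,
                          ids, F_off, kin = kin)
    males <- which(src$sex == 1L)
    females <- which(src$sex == 2L)
    if (length(males) < need || length(females) < need) return(NULL)
    males <- males[sample.int(length(males), need)]
    females <- females[sample.int(length(females), need)]
  }

  lines <- list()
  v <- 0L
  for (tr in treatments) {
    for (j in seq_len(config$lines_per_n50)) {
      v <- v + 1L
      take <- c(males[seq.int((v - 1) * per_sex + 1, v * per_sex)],
                females[seq.int((v - 1) * per_sex + 1, v * per_sex)])
      p <- subset_population(src, take)
      p$bottle <- NULL
      line_id <- sprintf("%s_%s_%d", origin, tr, j)
      lines[[line_id]] <- list(pop = p, id = line_id, treatment = tr,
                               origin = origin, alive = TRUE,
                               extinction_generation = NA_integer_)
      ctx$ped[[length(ctx$ped) + 1L]] <- tibble(
        id = p$id, sire = NA_integer_, dam = NA_integer_, sex = p$sex,
        population = line_id, generation = 0L
      )
    }
  }
  lines
}

record_traj <- function(ctx, population, type, treatment, generation, pop,
                        mean_w = NULL) {
  ctx$traj[[length(ctx$traj) + 1L]] <- tibble(
    population = population, type = type, treatment = treatment,
    generation = as.integer(generation), census = pop_size(pop),
    mean_fitness = mean_w %||% NA_real_,
    mean_pedigree_F = if (!is.null(pop$F)) mean(pop$F) else NA_real_
  )
}

run_assays <- function(ctx, bp, n50s, config, genome, seed, tag,
                       schemes, bp_gen, n50_gen) {
  for (sch in schemes) {
    n_vials <- if (sch == "outbred") config$n_assay_vials_outbred else config$n_assay_vials_inbred
    rec <- with_seed(child_seed(seed, 70L, match(sch, c("outbred", "inbred")), tag), {
      assay_pairs(bp, sch, n_vials, genome, p_max = config$p_max,
                  noise_sd = config$vial_noise_sd, population_id = "BP")
    })
    rec$generation <- bp_gen
    ctx$prod[[length(ctx$prod) + 1L]] <- rec
    alive <- which(!vapply(n50s, is.null, logical(1)))
    if (length(alive)) {
      share <- diff(round(seq(0, n_vials, length.out = length(alive) + 1L)))
      for (ii in seq_along(alive)) {
        if (share[ii] == 0) next
        rec <- with_seed(child_seed(seed, 71L, match(sch, c("outbred", "inbred")),
                                    tag, alive[ii]), {
          assay_pairs(n50s[[alive[ii]]], sch, share[ii], genome,
                      p_max = config$p_max, noise_sd = config$vial_noise_sd,
                      population_id = "N50")
        })
        rec$generation <- n50_gen
        ctx$prod[[length(ctx$prod) + 1L]] <- rec
      }
    }
  }
}

#' Simulate the full genetic-rescue experiment
#'
#' Runs the three-tier design forward in time: the base population (BP)
#' under circular bottle mixing for the whole span of the experiment; N50
#' populations founded from the BP at the configured generation and run for
#' `n50_generations`; and, from each surviving N50, three treatment sets of
#' small lines (non-rescued, rescued with a male from another N50, rescued
#' with a BP male at the configured rescue generations), run for
#' `n8_generations` with extinction recorded whenever a line produces no
#' progeny or progeny of a single sex. Productivity assays are performed on
#' the BP and the pooled N50 populations at a mid-point and at the
#' line-founding generation (outbred-only at the mid-point, both schemes at
#' founding), and twelve males of one non-rescued and one rescued-BP line
#' are genotyped at the sequencing generation.
#'
#' The run is deterministic given `(config, model, seed)`: every
#' population/line/generation derives its own child seed from the master
#' seed, so adding replicates or reordering evaluation never perturbs
#' existing streams.
#'
#' @param config An [experiment_config()].
#' @param model A [mutation_model()].
#' @param seed Master seed.
#' @return An object of class `rescue_sim` with elements `survival`,
#'   `productivity`, `trajectory`, `pedigree` (tibbles), `snapshots`
#'   (genotype matrices of the two sequenced lines, or NULL), `final_lines`,
#'   `genome`, `config`, `seed`.
#' @export
simulate_experiment <- function(config = experiment_config(),
                                model = mutation_model(), seed = 1L) {
  genome <- build_genome(config, model, seed = child_seed(seed, 1L))
  ctx <- new.env(parent = emptyenv())
  ctx$ped <- list(); ctx$traj <- list(); ctx$prod <- list()

  n_bp <- config$n_bottles * config$bottle_size
  bp <- with_seed(child_seed(seed, 2L), {
    p <- found_population(genome, n_bp)
    p$bottle <- rep(seq_len(config$n_bottles), each = config$bottle_size)[sample.int(n_bp)]
    p
  })
  ctx$next_id <- n_bp + 1L
  record_traj(ctx, "BP", "bp", NA_character_, 0L, bp,
              mean(population_fitness(bp, genome)))

  g_found_n50 <- config$founding_generation_of_n50
  g_found_lines <- g_found_n50 + config$n50_generations
  g_total <- g_found_lines + config$n8_generations
  mid_assay <- max(1L, round(config$n50_generations * 13 / 31))

  n50s <- NULL
  lines <- NULL
  snapshots <- NULL
  final_lines <- list()

  for (g in seq_len(g_total)) {
    bp_next <- with_seed(child_seed(seed, 10L, g), {
      advance_bp(bp, genome, config, ctx)
    })
    if (is_extinct(bp_next)) abort("Base population collapsed; check the model.")
    bp <- bp_next
    record_traj(ctx, "BP", "bp", NA_character_, g, bp, attr(bp, "mean_w"))

    if (g == g_found_n50) {
      n50s <- with_seed(child_seed(seed, 20L), found_n50_sets(bp, config, ctx))
      for (k in seq_along(n50s)) {
        record_traj(ctx, sprintf("n50_%02d", k), "n50", NA_character_, 0L,
                    n50s[[k]], mean(population_fitness(n50s[[k]], genome)))
      }
    }

    if (!is.null(n50s) && g > g_found_n50 && g <= g_found_lines) {
      tg <- g - g_found_n50
      for (k in seq_along(n50s)) {
        if (is.null(n50s[[k]])) next
        nxt <- with_seed(child_seed(seed, 30L, k, tg), {
          advance_small(n50s[[k]], config$n50_size / 2, config$n50_size / 2,
                        genome, config$p_max, config$rearing_capacity,
                        ctx = ctx)
        })
        if (is_extinct(nxt)) {
          n50s[k] <- list(NULL)
          next
        }
        par <- attr(nxt, "parents")
        par$population <- sprintf("n50_%02d", k)
        par$generation <- tg
        ctx$ped[[length(ctx$ped) + 1L]] <- par
        n50s[[k]] <- nxt
        record_traj(ctx, sprintf("n50_%02d", k), "n50", NA_character_, tg,
                    nxt, attr(nxt, "mean_w"))
      }
      if (tg == mid_assay && tg < config$n50_generations) {
        run_assays(ctx, bp, n50s, config, genome, seed, 1L,
                   "outbred", bp_gen = g, n50_gen = tg)
      }
      if (tg == config$n50_generations) {
        run_assays(ctx, bp, n50s, config, genome, seed, 2L,
                   c("outbred", "inbred"), bp_gen = g, n50_gen = tg)
      }
    }

    if (g == g_found_lines) {
      lines <- list()
      alive_n50 <- which(!vapply(n50s, is.null, logical(1)))
      for (k in alive_n50) {
        ls <- with_seed(child_seed(seed, 40L, k), {
          found_lines_from_n50(n50s[[k]], sprintf("n50_%02d", k), config,
                               genome, ctx)
        })
        lines <- c(lines, ls)
      }
    }

    if (!is.null(lines) && g > g_found_lines) {
      lg <- g - g_found_lines
      alive_n50 <- which(!vapply(n50s, is.null, logical(1)))
      for (li in seq_along(lines)) {
        ln <- lines[[li]]
        if (!ln$alive) next
        rescue_male <- NULL
        if (lg %in% config$rescue_generations && ln$treatment != "non_rescued") {
          rescue_male <- with_seed(child_seed(seed, 50L, li, lg), {
            if (ln$treatment == "rescued_bp") {
              ms <- which(bp$sex == 1L)
              take_individual(bp, ms[sample.int(length(ms), 1L)])
            } else {
              donors <- setdiff(alive_n50,
                                which(sprintf("n50_%02d", seq_along(n50s)) == ln$origin))
              if (!length(donors)) donors <- alive_n50
              if (!length(donors)) {
                NULL
              } else {
                d <- n50s[[donors[sample.int(length(donors), 1L)]]]
                ms <- which(d$sex == 1L)
                take_individual(d, ms[sample.int(length(ms), 1L)])
              }
            }
          })
        }
        nxt <- with_seed(child_seed(seed, 60L, li, lg), {
          advance_small(ln$pop, config$n8_size / 2, config$n8_size / 2,
                        genome, config$p_max, config$rearing_capacity,
                        rescue_male = rescue_male, ctx = ctx)
        })
        if (is_extinct(nxt)) {
          lines[[li]]$alive <- FALSE
          lines[[li]]$extinction_generation <- lg
          next
        }
        par <- attr(nxt, "parents")
        par$population <- ln$id
        par$generation <- lg
        ctx$ped[[length(ctx$ped) + 1L]] <- par
        lines[[li]]$pop <- nxt
        record_traj(ctx, ln$id, "line", ln$treatment, lg, nxt,
                    attr(nxt, "mean_w"))
      }

      if (!is.na(config$duplication_generation) &&
          lg == config$duplication_generation) {
        for (li in seq_along(lines)) {
          ln <- lines[[li]]
          if (!ln$alive) next
          dup <- with_seed(child_seed(seed, 65L, li), {
            advance_small(ln$pop, config$n8_size / 2, config$n8_size / 2,
                          genome, config$p_max, config$rearing_capacity,
                          ctx = ctx)
          })
          if (is_extinct(dup)) next
          id2 <- paste0(ln$id, "_dup")
          lines[[id2]] <- list(pop = dup, id = id2, treatment = ln$treatment,
                               origin = ln$origin, alive = TRUE,
                               extinction_generation = NA_integer_)
        }
      }

      if (lg == config$sequencing_generation) {
        snapshots <- with_seed(child_seed(seed, 80L), {
          seq_lines <- purrr::map(c(non_rescued = "non_rescued",
                                    rescued_bp = "rescued_bp"), function(tr) {
            cand <- purrr::keep(lines, ~ .x$alive && .x$treatment == tr)
            if (!length(cand)) return(NULL)
            ln <- cand[[sample.int(length(cand), 1L)]]
            prog <- line_progeny(ln$pop, 150L, genome, p_max = config$p_max)
            if (is.null(prog) || sum(prog$sex == 1L) < 12L) return(NULL)
            gm <- export_genotypes(prog, 12L, genome, line = tr)
            gm
          })
          if (any(vapply(seq_lines, is.null, logical(1)))) NULL else seq_lines
        })
      }
    }
  }

  if (!is.null(lines)) {
    for (ln in lines) {
      if (ln$alive) final_lines[[ln$id]] <- ln$pop
    }
  }

  survival <- if (is.null(lines)) {
    tibble(line_id = character(), treatment = character(),
           origin_n50 = character(), founded_generation = integer(),
           extinction_generation = integer())
  } else {
    purrr::map_dfr(lines, function(ln) {
      tibble(line_id = ln$id, treatment = ln$treatment, origin_n50 = ln$origin,
             founded_generation = 0L,
             extinction_generation = ln$extinction_generation)
    })
  }

  structure(
    list(
      survival = survival,
      productivity = bind_rows(ctx$prod),
      trajectory = bind_rows(ctx$traj),
      pedigree = bind_rows(ctx$ped),
      snapshots = snapshots,
      final_lines = final_lines,
      genome = genome,
      config = config,
      seed = seed
    ),
    class = "rescue_sim"
  )
}

#' @export
print.rescue_sim <- function(x, ...) {
  cat("<rescue_sim>\n")
  cat(sprintf("  seed %d; %d lines simulated, %d extinct; %d productivity vials\n",
              x$seed, nrow(x$survival),
              sum(!is.na(x$survival$extinction_generation)),
              nrow(x$productivity)))
  if (!is.null(x$snapshots)) {
    cat("  sequenced snapshots: ", paste(names(x$snapshots), collapse = ", "), "\n")
  }
  invisible(x)
}

#' First-generation heterosis between lines
#'
#' Compares the mean fitness of within-line offspring against offspring of
#' crosses between independent lines at the end of a simulated experiment.
#' Masking of deleterious recessives drifted to high frequency within lines
#' predicts hybrid offspring to be at least as fit on average.
#'
#' @param sim A `rescue_sim`.
#' @param treatment Treatment whose surviving lines are crossed.
#' @param n_offspring Offspring genotypes sampled per cross.
#' @param seed Seed for the crossing draws.
#' @return A tibble with mean within-line and between-line offspring fitness.
#' @export
heterosis_check <- function(sim, treatment = "non_rescued", n_offspring = 60,
                            seed = 1L) {
  pops <- sim$final_lines[
    names(sim$final_lines) %in%
      sim$survival$line_id[sim$survival$treatment == treatment]
  ]
  if (length(pops) < 2) {
    abort("Need at least two surviving lines of the requested treatment.")
  }
  genome <- sim$genome
  with_seed(seed, {
    within_w <- purrr::map_dbl(pops, function(p) {
      f <- which(p$sex == 2L); m <- which(p$sex == 1L)
      off <- make_offspring(p, sample(f, n_offspring, replace = TRUE),
                            sample(m, n_offspring, replace = TRUE), genome)
      mean(offspring_fitness(off, genome))
    })
    combos <- utils::combn(length(pops), 2)
    between_w <- apply(combos, 2, function(pr) {
      p1 <- pops[[pr[1]]]; p2 <- pops[[pr[2]]]
      f <- which(p1$sex == 2L); m <- which(p2$sex == 1L)
      merged <- new_population(rbind(p1$h1, p2$h1), rbind(p1$h2, p2$h2),
                               rbind(p1$a1, p2$a1), rbind(p1$a2, p2$a2),
                               c(p1$sex, p2$sex),
                               seq_len(pop_size(p1) + pop_size(p2)))
      f2 <- f
      m2 <- pop_size(p1) + m
      off <- make_offspring(merged, sample(f2, n_offspring, replace = TRUE),
                            sample(m2, n_offspring, replace = TRUE), genome)
      mean(offspring_fitness(off, genome))
    })
    tibble(
      mean_within = mean(within_w),
      mean_between = mean(between_w),
      n_lines = length(pops)
    )
  })
}
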