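# Forward-time individual-based engine for the three-tier rescue design.
#
# Demography per generation, all regimes: each female is mated to a male of
# her group drawn uniformly at random; juveniles per female are
# Poisson(p_max); the reared juvenile pool is capped at rearing_capacity x
# census (vial/bottle crowding); each juvenile survives to adulthood with
# probability equal to its multiplicative fitness; the configured numbers of
# male and female breeders are then drawn uniformly from survivors. A group
# whose progeny pool is empty, or contains a single sex only, is extinct.

extinction_marker <- function(reason) {
  structure(list(extinct = TRUE, reason = reason), class = "extinction_marker")
}

#' Test for an extinction marker
#' @param x Object returned by [advance_generation()].
#' @return Logical scalar.
#' @export
is_extinct <- function(x) inherits(x, "extinction_marker")

append_individual <- function(pop, ind) {
  kin <- pop$kin
  if (!is.null(kin)) {
    n <- nrow(kin)
    kin <- rbind(cbind(kin, 0), 0)
    kin[n + 1, n + 1] <- 0.5 * (1 + (ind$F %||% 0))
  }
  new_population(rbind(pop$h1, ind$h1), rbind(pop$h2, ind$h2),
                 rbind(pop$a1, ind$a1), rbind(pop$a2, ind$a2),
                 c(pop$sex, ind$sex), c(pop$id, ind$id),
                 c(pop$F, ind$F %||% 0), kin = kin)
}

#' Extract one individual as a transferable unit
#'
#' Used e.g. to pass a migrant male into [advance_generation()].
#'
#' @param pop A `sim_population`.
#' @param idx Row index of the individual.
#' @return A list with the individual's haplotypes, sex, id and pedigree F.
#' @export
take_individual <- function(pop, idx) {
  list(h1 = pop$h1[idx, , drop = FALSE], h2 = pop$h2[idx, , drop = FALSE],
       a1 = pop$a1[idx, , drop = FALSE], a2 = pop$a2[idx, , drop = FALSE],
       sex = pop$sex[idx], id = pop$id[idx], F = pop$F[idx])
}

offspring_fitness <- function(off, genome) {
  lw <- log_fitness_cpp(off$h1, off$h2, genome$log_het, genome$log_hom)
  if (genome$adaptive$n > 0) {
    da <- off$a1 + off$a2
    lw <- lw +
      rowSums(da == 1L) * log1p(genome$adaptive$h * genome$adaptive$s) +
      rowSums(da == 2L) * log1p(genome$adaptive$s)
  }
  exp(lw)
}

# Rear a capped juvenile pool from given parents. Returns NULL when no
# juvenile survives, else offspring matrices + parent indices + sexes.
breed_pool <- function(pop, females, males, p_max, cap, genome,
                       mate_of = NULL) {
  if (!length(females) || !length(males)) return(NULL)
  if (is.null(mate_of)) {
    mate_of <- males[sample.int(length(males), length(females), replace = TRUE)]
  }
  n_juv <- rpois(length(females), p_max)
  tot <- sum(n_juv)
  if (tot == 0) return(NULL)
  n_pool <- min(tot, cap)
  fi <- sample.int(length(females), n_pool, replace = TRUE, prob = n_juv)
  dams <- females[fi]
  sires <- mate_of[fi]
  off <- make_offspring(pop, dams, sires, genome)
  w <- offspring_fitness(off, genome)
  alive <- which(runif(n_pool) < w)
  if (!length(alive)) return(NULL)
  list(
    h1 = off$h1[alive, , drop = FALSE], h2 = off$h2[alive, , drop = FALSE],
    a1 = off$a1[alive, , drop = FALSE], a2 = off$a2[alive, , drop = FALSE],
    dam = dams[alive], sire = sires[alive],
    sex = sample(c(1L, 2L), length(alive), replace = TRUE),
    w = w[alive],
    n_juveniles = tot
  )
}

# Advance a single bottle/vial population one generation.
advance_small <- function(pop, n_m, n_f, genome, p_max, cap_mult,
                          rescue_male = NULL, ctx = NULL) {
  pop2 <- if (!is.null(rescue_male)) append_individual(pop, rescue_male) else pop
  females <- which(pop2$sex == 2L)
  males <- which(pop2$sex == 1L)
  if (!length(females) || !length(males)) {
    return(extinction_marker("single_sex"))
  }
  # rear in batches up to the vial capacity until both sexes are filled;
  # extinction decisions use the accumulated progeny
  pool <- NULL
  for (batch in 1:4) {
    b <- breed_pool(pop2, females, males, p_max,
                    cap = cap_mult * (n_m + n_f), genome = genome)
    if (is.null(b)) next
    pool <- if (is.null(pool)) b else list(
      h1 = rbind(pool$h1, b$h1), h2 = rbind(pool$h2, b$h2),
      a1 = rbind(pool$a1, b$a1), a2 = rbind(pool$a2, b$a2),
      dam = c(pool$dam, b$dam), sire = c(pool$sire, b$sire),
      sex = c(pool$sex, b$sex), w = c(pool$w, b$w),
      n_juveniles = pool$n_juveniles + b$n_juveniles
    )
    if (sum(pool$sex == 1L) >= n_m && sum(pool$sex == 2L) >= n_f) break
  }
  if (is.null(pool)) return(extinction_marker("no_progeny"))
  sm <- which(pool$sex == 1L)
  sf <- which(pool$sex == 2L)
  if (!length(sm) || !length(sf)) return(extinction_marker("single_sex"))
  bm <- sm[sample.int(length(sm), min(n_m, length(sm)))]
  bf <- sf[sample.int(length(sf), min(n_f, length(sf)))]
  sel <- c(bm, bf)

  F_new <- if (!is.null(pop2$kin)) {
    pop2$kin[cbind(pool$dam[sel], pool$sire[sel])]
  } else {
    numeric(length(sel))
  }
  kin_new <- NULL
  if (!is.null(pop2$kin)) {
    G <- length(sel)
    M <- matrix(0, G, pop_size(pop2))
    M[cbind(seq_len(G), pool$dam[sel])] <- M[cbind(seq_len(G), pool$dam[sel])] + 0.5
    M[cbind(seq_len(G), pool$sire[sel])] <- M[cbind(seq_len(G), pool$sire[sel])] + 0.5
    kin_new <- M %*% pop2$kin %*% t(M)
    diag(kin_new) <- 0.5 * (1 + F_new)
  }
  ids <- if (!is.null(ctx)) {
    out <- seq.int(ctx$next_id, length.out = length(sel))
    ctx$next_id <- ctx$next_id + length(sel)
    out
  } else {
    seq.int(max(pop2$id) + 1L, length.out = length(sel))
  }
  out <- new_population(pool$h1[sel, , drop = FALSE],
                        pool$h2[sel, , drop = FALSE],
                        pool$a1[sel, , drop = FALSE],
                        pool$a2[sel, , drop = FALSE],
                        pool$sex[sel], ids, F_new, kin = kin_new)
  attr(out, "parents") <- tibble(
    id = ids, sire = pop2$id[pool$sire[sel]], dam = pop2$id[pool$dam[sel]],
    sex = pool$sex[sel]
  )
  attr(out, "mean_w") <- mean(pool$w[sel])
  out
}

# Advance the base population one generation under circular bottle mixing:
# new bottle i is assembled from the progeny pools of bottles i and i + 1
# (wrapping), a quarter of the bottle per source and sex.
advance_bp <- function(pop, genome, config, ctx = NULL) {
  B <- config$n_bottles
  quarter <- config$bottle_size / 4
  pools <- vector("list", B)
  for (b in seq_len(B)) {
    idx <- which(pop$bottle == b)
    females <- idx[pop$sex[idx] == 2L]
    males <- idx[pop$sex[idx] == 1L]
    pools[[b]] <- breed_pool(pop, females, males, config$p_max,
                             cap = config$rearing_capacity * config$bottle_size,
                             genome = genome)
  }
  pick <- function(pool, sex, k) {
    if (is.null(pool)) return(integer(0))
    cand <- which(pool$sex == sex)
    cand[sample.int(length(cand), min(k, length(cand)))]
  }
  rows <- list(); src_bottle <- integer(0); dest_bottle <- integer(0)
  for (i in seq_len(B)) {
    j <- if (i == B) 1L else i + 1L
    for (src in c(i, j)) {
      for (sex in c(1L, 2L)) {
        r <- pick(pools[[src]], sex, quarter)
        if (length(r)) {
          rows[[length(rows) + 1L]] <- list(src = src, rows = r)
          src_bottle <- c(src_bottle, rep.int(src, length(r)))
          dest_bottle <- c(dest_bottle, rep.int(i, length(r)))
        }
      }
    }
  }
  if (!length(rows)) return(extinction_marker("no_progeny"))
  h1 <- do.call(rbind, lapply(rows, function(r) pools[[r$src]]$h1[r$rows, , drop = FALSE]))
  h2 <- do.call(rbind, lapply(rows, function(r) pools[[r$src]]$h2[r$rows, , drop = FALSE]))
  a1 <- do.call(rbind, lapply(rows, function(r) pools[[r$src]]$a1[r$rows, , drop = FALSE]))
  a2 <- do.call(rbind, lapply(rows, function(r) pools[[r$src]]$a2[r$rows, , drop = FALSE]))
  sex <- unlist(lapply(rows, function(r) pools[[r$src]]$sex[r$rows]))
  w <- unlist(lapply(rows, function(r) pools[[r$src]]$w[r$rows]))
  n <- length(sex)
  ids <- if (!is.null(ctx)) {
    out <- seq.int(ctx$next_id, length.out = n)
    ctx$next_id <- ctx$next_id + n
    out
  } else {
    seq.int(max(pop$id) + 1L, length.out = n)
  }
  out <- new_population(h1, h2, a1, a2, sex, ids, numeric(n),
                        bottle = dest_bottle)
  attr(out, "source_bottles") <- src_bottle
  attr(out, "mean_w") <- mean(w)
  out
}

#' Advance a population one generation
#'
#' One generation of the rearing model under one of the three maintenance
#' regimes: `bp_circular` (bottles under circular mixing — requires a
#' `bottle` assignment on the population), `n50_bottle` (half/half census
#' from the pooled progeny) or `n8_vial` (4 males + 4 females, optional
#' rescue male competing on equal terms for matings). Uses the current RNG
#' state; seed with [set.seed()] for reproducibility.
#'
#' @param pop A `sim_population`.
#' @param regime One of "bp_circular", "n50_bottle", "n8_vial".
#' @param genome A [build_genome()] object.
#' @param config An [experiment_config()].
#' @param rescue_male Optional migrant male (see [take_individual()]);
#'   only meaningful for the `n8_vial` regime.
#' @return The next-generation `sim_population`, or an extinction marker
#'   (test with [is_extinct()]) when the progeny pool is empty or single-sex.
#'   The `parents` attribute records sire/dam ids of the new breeders.
#' @export
advance_generation <- function(pop, regime = c("n8_vial", "n50_bottle", "bp_circular"),
                               genome, config, rescue_male = NULL) {
  regime <- match.arg(regime)
  if (!is.null(rescue_male) && regime != "n8_vial") {
    abort("`rescue_male` is only supported in the n8_vial regime.")
  }
  switch(regime,
    bp_circular = {
      if (is.null(pop$bottle)) abort("bp_circular regime needs a `bottle` assignment.")
      advance_bp(pop, genome, config)
    },
    n50_bottle = advance_small(pop, config$n50_size / 2, config$n50_size / 2,
                               genome, config$p_max, config$rearing_capacity),
    n8_vial = advance_small(pop, config$n8_size / 2, config$n8_size / 2,
                            genome, config$p_max, config$rearing_capacity,
                            rescue_male = rescue_male)
  )
}

#' Productivity assay on a population
#'
#' Emulates the paired-vial productivity design: in the outbred scheme the
#' evaluated offspring descend from crosses of unrelated pairs (design F =
#' 0); in the inbred scheme a full-sib couple is mated so the evaluated
#' offspring carry a design inbreeding coefficient of 0.25 relative to the
#' population. Each vial's pupae count is Poisson with mean `p_max` times
#' the mean offspring viability, under multiplicative lognormal vial noise.
#'
#' @param pop A `sim_population`.
#' @param scheme "outbred" or "inbred".
#' @param n_pairs Number of assay vials.
#' @param genome A [build_genome()] object.
#' @param p_max Expected pupae per pair at fitness 1.
#' @param noise_sd SD of the lognormal vial noise (log scale); the noise is
#'   mean-centred so it adds skew without changing the expectation.
#' @param n_eval Offspring genotypes drawn per vial to estimate mean
#'   viability.
#' @param population_id Label stored on the records.
#' @return A tibble of productivity records: `population_id`, `scheme`,
#'   `vial_id`, `pupae_count`, `design_F`.
#' @export
assay_pairs <- function(pop, scheme = c("outbred", "inbred"), n_pairs,
                        genome, p_max = 90, noise_sd = 0.3, n_eval = 30,
                        population_id = "pop") {
  scheme <- match.arg(scheme)
  if (n_pairs <= 0) {
    return(tibble(population_id = character(), scheme = character(),
                  vial_id = integer(), pupae_count = integer(),
                  design_F = numeric()))
  }
  males <- which(pop$sex == 1L)
  females <- which(pop$sex == 2L)
  need <- if (scheme == "outbred") 2L else 1L
  if (length(males) < need || length(females) < need) {
    abort("Not enough individuals of each sex for the assay.")
  }
  counts <- integer(n_pairs)
  for (v in seq_len(n_pairs)) {
    if (scheme == "outbred") {
      m <- males[sample.int(length(males), 2L)]
      f <- females[sample.int(length(females), 2L)]
      # t = 1: two unrelated pairs; t = 2: cross their offspring
      kid1 <- make_offspring(pop, f[1], m[1], genome)
      kid2 <- make_offspring(pop, f[2], m[2], genome)
      par_h1 <- rbind(kid1$h1, kid2$h1); par_h2 <- rbind(kid1$h2, kid2$h2)
      par_a1 <- rbind(kid1$a1, kid2$a1); par_a2 <- rbind(kid1$a2, kid2$a2)
    } else {
      m <- males[sample.int(length(males), 1L)]
      f <- females[sample.int(length(females), 1L)]
      # full sibs mated: evaluated offspring have design F = 0.25
      kid1 <- make_offspring(pop, f, m, genome)
      kid2 <- make_offspring(pop, f, m, genome)
      par_h1 <- rbind(kid1$h1, kid2$h1); par_h2 <- rbind(kid1$h2, kid2$h2)
      par_a1 <- rbind(kid1$a1, kid2$a1); par_a2 <- rbind(kid1$a2, kid2$a2)
    }
    tmp <- new_population(par_h1, par_h2, par_a1, par_a2,
                          sex = c(2L, 1L), id = c(1L, 2L))
    eggs <- make_offspring(tmp, rep(1L, n_eval), rep(2L, n_eval), genome)
    w_bar <- mean(offspring_fitness(eggs, genome))
    lambda <- p_max * w_bar * rlnorm(1, -noise_sd^2 / 2, noise_sd)
    counts[v] <- rpois(1, lambda)
  }
  dF <- if (scheme == "outbred") 0 else 0.25
  tibble(
    population_id = population_id,
    scheme = scheme,
    vial_id = seq_len(n_pairs),
    pupae_count = counts,
    design_F = dF
  )
}

#' Random-mating progeny of a population
#'
#' Generates a pool of surviving offspring of the current breeders, used
#' e.g. to sample males for sequencing.
#'
#' @inheritParams assay_pairs
#' @param n_pool Juvenile pool size to rear.
#' @return A `sim_population` of surviving progeny (census may be smaller
#'   than `n_pool` because of viability selection), or `NULL` if none
#'   survive.
#' @export
line_progeny <- function(pop, n_pool, genome, p_max = 90) {
  females <- which(pop$sex == 2L)
  males <- which(pop$sex == 1L)
  pool <- breed_pool(pop, females, males, p_max = p_max, cap = n_pool,
                     genome = genome)
  if (is.null(pool)) return(NULL)
  new_population(pool$h1, pool$h2, pool$a1, pool$a2, pool$sex,
                 id = seq_len(length(pool$sex)))
}
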