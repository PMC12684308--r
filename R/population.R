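# Population container: a list with integer haplotype matrices h1/h2
# (individuals x loci, derived-allele codes), adaptive-locus haplotypes
# a1/a2, sex (1 male, 2 female), global ids, pedigree inbreeding F, and an
# optional kinship matrix for populations whose pedigree F is tracked.

new_population <- function(h1, h2, a1, a2, sex, id, F = NULL, kin = NULL,
                           bottle = NULL) {
  structure(
    list(h1 = h1, h2 = h2, a1 = a1, a2 = a2, sex = as.integer(sex),
         id = id, F = F %||% numeric(nrow(h1)), kin = kin, bottle = bottle),
    class = "sim_population"
  )
}

pop_size <- function(pop) nrow(pop$h1)

#' @export
print.sim_population <- function(x, ...) {
  cat(sprintf("<sim_population> %d individuals (%d males, %d females), %d loci\n",
              pop_size(x), sum(x$sex == 1), sum(x$sex == 2), ncol(x$h1)))
  invisible(x)
}

#' Found a population at linkage equilibrium
#'
#' Draws `n` diploid founders whose alleles are independent Bernoulli draws
#' at the genome's initial frequencies (standing variation at
#' mutation-selection balance for selected loci, equilibrium spectrum for
#' neutral loci). Founders are unrelated and non-inbred; sexes are balanced.
#'
#' @param genome A [build_genome()] object.
#' @param n Number of individuals.
#' @param first_id First global id to assign.
#' @return A `sim_population`.
#' @export
found_population <- function(genome, n, first_id = 1L) {
  L <- genome$L
  draw <- function() {
    matrix(rbinom(n * L, 1L, rep(genome$q0, each = n)), nrow = n, ncol = L)
  }
  A <- genome$adaptive$n
  draw_a <- function() {
    if (A == 0) return(matrix(0L, n, 0))
    matrix(rbinom(n * A, 1L, genome$adaptive$p0), nrow = n, ncol = A)
  }
  sex <- rep(c(1L, 2L), length.out = n)[sample.int(n)]
  new_population(draw(), draw(), draw_a(), draw_a(), sex,
                 id = seq.int(first_id, length.out = n),
                 F = numeric(n))
}

subset_population <- function(pop, idx) {
  new_population(pop$h1[idx, , drop = FALSE], pop$h2[idx, , drop = FALSE],
                 pop$a1[idx, , drop = FALSE], pop$a2[idx, , drop = FALSE],
                 pop$sex[idx], pop$id[idx], pop$F[idx],
                 kin = if (!is.null(pop$kin)) pop$kin[idx, idx, drop = FALSE],
                 bottle = pop$bottle[idx])
}

# Draw one gamete per entry of `parents` (row indices into pop), with
# recombination along the genome and new recurrent deleterious/lethal
# mutations, plus free-assorting adaptive loci.
draw_gametes <- function(pop, parents, genome) {
  g <- make_gametes_cpp(pop$h1, pop$h2, as.integer(parents),
                        genome$gpos, genome$arm_idx, genome$arm_len_M)
  G <- length(parents)
  if (genome$mu_del > 0 && length(genome$del_idx)) {
    nm <- rpois(G, genome$mu_del)
    tot <- sum(nm)
    if (tot > 0) {
      g[cbind(rep.int(seq_len(G), nm),
              sample(genome$del_idx, tot, replace = TRUE))] <- 1L
    }
  }
  if (genome$mu_let > 0 && length(genome$let_idx)) {
    nm <- rpois(G, genome$mu_let)
    tot <- sum(nm)
    if (tot > 0) {
      g[cbind(rep.int(seq_len(G), nm),
              sample(genome$let_idx, tot, replace = TRUE))] <- 1L
    }
  }
  g
}

draw_adaptive_gametes <- function(pop, parents, genome) {
  A <- genome$adaptive$n
  if (A == 0) return(matrix(0L, length(parents), 0))
  da <- pop$a1[parents, , drop = FALSE] + pop$a2[parents, , drop = FALSE]
  out <- (da == 2L) * 1L
  het <- da == 1L
  nhet <- sum(het)
  if (nhet > 0) out[het] <- rbinom(nhet, 1L, 0.5)
  out
}

# Multiplicative relative fitness of every individual.
population_fitness <- function(pop, genome) {
  lw <- log_fitness_cpp(pop$h1, pop$h2, genome$log_het, genome$log_hom)
  A <- genome$adaptive$n
  if (A > 0) {
    da <- pop$a1 + pop$a2
    lw <- lw +
      rowSums(da == 1L) * log1p(genome$adaptive$h * genome$adaptive$s) +
      rowSums(da == 2L) * log1p(genome$adaptive$s)
  }
  exp(lw)
}

# Generate offspring genotypes for given mother/father row indices.
make_offspring <- function(pop, mothers, fathers, genome) {
  list(
    h1 = draw_gametes(pop, mothers, genome),
    h2 = draw_gametes(pop, fathers, genome),
    a1 = draw_adaptive_gametes(pop, mothers, genome),
    a2 = draw_adaptive_gametes(pop, fathers, genome)
  )
}
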