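#' Pedigree kinship and inbreeding coefficients
#'
#' `pedigree_inbreeding()` returns Wright's coefficient of inbreeding of an
#' individual — the kinship of its parents — computed by the standard
#' recursion f(a, b) = (f(a, sire_b) + f(a, dam_b)) / 2 with
#' f(a, a) = (1 + F_a) / 2, memoised over the pedigree. Founders (missing
#' parents) are taken as unrelated and non-inbred.
#'
#' @param pedigree A data frame with columns `id`, `sire`, `dam` (parent ids,
#'   `NA` for founders).
#' @param id Individual id(s).
#' @return Numeric vector of inbreeding coefficients in \[0, 1].
#' @examples
#' ped <- tibble::tibble(
#'   id = c(1, 2, 3, 4, 5),
#'   sire = c(NA, NA, 1, 1, 3),
#'   dam = c(NA, NA, 2, 2, 4)
#' )
#' pedigree_inbreeding(ped, 5) # offspring of full sibs: 0.25
#' @export
pedigree_inbreeding <- function(pedigree, id) {
  ped <- prepare_pedigree(pedigree)
  vapply(id, function(i) {
    row <- ped$index[[as.character(i)]]
    if (is.null(row)) abort(sprintf("Unknown individual id: %s", i))
    s <- ped$sire[row]; d <- ped$dam[row]
    if (is.na(s) || is.na(d)) return(0)
    kinship_pair(ped, s, d, depth = 0L)
  }, numeric(1))
}

#' @rdname pedigree_inbreeding
#' @param id1,id2 Ids of the two individuals whose kinship (coancestry) is
#'   required.
#' @export
pedigree_kinship <- function(pedigree, id1, id2) {
  ped <- prepare_pedigree(pedigree)
  for (i in c(id1, id2)) {
    if (is.null(ped$index[[as.character(i)]])) {
      abort(sprintf("Unknown individual id: %s", i))
    }
  }
  kinship_pair(ped, id1, id2, depth = 0L)
}

prepare_pedigree <- function(pedigree) {
  stopifnot(all(c("id", "sire", "dam") %in% names(pedigree)))
  ids <- as.character(pedigree$id)
  if (anyDuplicated(ids)) abort("Duplicate ids in pedigree.")
  env <- new.env(parent = emptyenv())
  list(
    index = setNames(as.list(seq_along(ids)), ids),
    id = pedigree$id,
    sire = pedigree$sire,
    dam = pedigree$dam,
    memo = env,
    n = length(ids)
  )
}

kinship_pair <- function(ped, a, b, depth) {
  if (depth > 4L * ped$n + 8L) abort("Pedigree appears to contain a cycle.")
  if (is.na(a) || is.na(b)) return(0)
  key <- if (a <= b) paste0(a, ":", b) else paste0(b, ":", a)
  hit <- ped$memo[[key]]
  if (!is.null(hit)) return(hit)
  ra <- ped$index[[as.character(a)]]
  rb <- ped$index[[as.character(b)]]
  # ids absent from the table are founders
  val <- if (a == b) {
    if (is.null(ra)) {
      0.5
    } else {
      s <- ped$sire[ra]; d <- ped$dam[ra]
      0.5 * (1 + kinship_pair(ped, s, d, depth + 1L))
    }
  } else if (is.null(ra) && is.null(rb)) {
    0
  } else {
    # recurse through the younger individual (appears later in the table);
    # founders and ids absent from the table terminate the recursion
    use_a <- !is.null(ra) && (is.null(rb) || ra >= rb)
    row <- if (use_a) ra else rb
    other <- if (use_a) b else a
    s <- ped$sire[row]; d <- ped$dam[row]
    if (is.na(s) && is.na(d)) {
      0
    } else {
      0.5 * (kinship_pair(ped, s, other, depth + 1L) +
               kinship_pair(ped, d, other, depth + 1L))
    }
  }
  ped$memo[[key]] <- val
  val
}

#' Effective size from realized offspring numbers
#'
#' Estimates the inbreeding effective size of a simulated dioecious
#' population from the realized distribution of breeding offspring per
#' parent. For every generation transition the probability that a random
#' male and a random female breeder share a mother (`P_M`) or a father
#' (`P_F`) is computed from the per-parent counts of breeding sons and
#' daughters: `P = sum_i s_i d_i / (K_m K_f)`. With `q = (P_M + P_F) / 4`
#' the mean-kinship recursion of a random-mating population with separate
#' sexes is `u_{t+1} = (1 - q) u_t + (q/2) u_{t-1}` (u = 1 - kinship), whose
#' asymptotic decay rate `r` gives the per-generation inbreeding rate
#' `1 - r` and hence `Ne = 1 / (2 (1 - r))`. Generations are combined
#' harmonically. Because mates of the founder generation cannot be related,
#' expected trajectories use exponent `t - 1`:
#' `F_t = 1 - (1 - 1/(2 Ne))^(t-1)`.
#'
#' @param pedigree Pedigree tibble with columns `id`, `sire`, `dam`, `sex`,
#'   `population`, `generation` (as produced by [simulate_experiment()]).
#' @param population Population label to analyse.
#' @return A tibble with `population`, `Ne` and the number of transitions
#'   used.
#' @export
estimate_ne <- function(pedigree, population) {
  ped <- pedigree[pedigree$population == population, ]
  if (!nrow(ped)) abort(sprintf("No pedigree rows for population %s", population))
  gens <- sort(unique(ped$generation))
  per_gen <- purrr::map_dbl(head(gens, -1), function(g) {
    parents <- ped[ped$generation == g, ]
    kids <- ped[ped$generation == g + 1L, ]
    if (!nrow(kids) || nrow(parents) < 4) return(NA_real_)
    km <- sum(kids$sex == 1L)
    kf <- sum(kids$sex == 2L)
    if (km == 0 || kf == 0) return(NA_real_)
    share_prob <- function(parent_col) {
      counts <- kids |>
        group_by(parent = .data[[parent_col]]) |>
        summarise(s = sum(.data$sex == 1L), d = sum(.data$sex == 2L),
                  .groups = "drop")
      sum(counts$s * counts$d) / (km * kf)
    }
    q <- (share_prob("dam") + share_prob("sire")) / 4
    if (q <= 0) return(NA_real_)
    r <- ((1 - q) + sqrt((1 - q)^2 + 2 * q)) / 2
    1 / (2 * (1 - r))
  })
  per_gen <- per_gen[!is.na(per_gen)]
  if (!length(per_gen)) abort("Not enough pedigree information to estimate Ne.")
  tibble(
    population = population,
    Ne = length(per_gen) / sum(1 / per_gen),
    n_generations = length(per_gen)
  )
}
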