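# Derived-allele load profiles. The derived count of an individual in a
# category is the total number of derived copies it carries over that
# category's sites (1 per heterozygote, 2 per homozygote), including sites
# fixed for the derived allele in the sample; missing calls are skipped.
# Counts are normalised by the putatively neutral fourfold-synonymous count
# and standardised by the reference (non-rescued) line so its mean is one.

load_categories <- c("intergenic", "intronic", "synonymous_other",
                     "synonymous_fourfold", "missense",
                     "missense_deleterious", "lof")

#' Raw derived-allele counts per individual and category
#'
#' @param gm A polarized [genotype_matrix()] whose sites carry annotation
#'   categories.
#' @param categories Categories to profile (default: all present).
#' @return A tibble: `id`, `line`, `category`, `count`.
#' @export
derived_count_profile <- function(gm, categories = NULL) {
  if (all(is.na(gm$sites$category))) {
    abort("Sites carry no annotation categories; cannot profile load.")
  }
  categories <- categories %||% intersect(load_categories,
                                          unique(gm$sites$category))
  purrr::map_dfr(categories, function(cc) {
    idx <- which(gm$sites$category == cc)
    tibble(
      id = gm$individuals$id,
      line = gm$individuals$line,
      category = cc,
      count = if (length(idx)) {
        unname(rowSums(gm$dosage[, idx, drop = FALSE], na.rm = TRUE))
      } else {
        rep(0, nrow(gm$dosage))
      }
    )
  })
}

#' Normalise and standardise load profiles against a reference line
#'
#' Each individual's category count is divided by its fourfold-synonymous
#' count (technical-noise normalisation); the normalised ratios are then
#' divided by the reference line's mean ratio per category, so the
#' reference line's standardized mean is exactly one in every category.
#'
#' @param focal,reference Profiles from [derived_count_profile()].
#' @param fourfold Name of the neutral normalising category.
#' @return A tibble of per-individual standardized ratios for both lines:
#'   `line`, `id`, `category`, `ratio`, `standardized`.
#' @seealso [load_summary()] for per-line means and standard errors.
#' @export
standardize_load <- function(focal, reference,
                             fourfold = "synonymous_fourfold") {
  norm_one <- function(profile) {
    ff <- profile |>
      filter(.data$category == fourfold) |>
      select("id", ff_count = "count")
    if (!nrow(ff)) abort("Profile lacks the fourfold-synonymous category.")
    out <- profile |>
      left_join(ff, by = "id")
    if (any(out$ff_count == 0)) {
      abort("Zero fourfold-synonymous count: normalisation undefined.")
    }
    out |>
      mutate(ratio = .data$count / .data$ff_count) |>
      select(-"ff_count")
  }
  f <- norm_one(focal)
  r <- norm_one(reference)
  ref_means <- r |>
    group_by(.data$category) |>
    summarise(ref_mean = mean(.data$ratio), .groups = "drop")
  bind_rows(f, r) |>
    left_join(ref_means, by = "category") |>
    mutate(standardized = .data$ratio / .data$ref_mean) |>
    select("line", "id", "category", "ratio", "standardized")
}

#' Per-line load means and standard errors
#'
#' @param standardized Output of [standardize_load()].
#' @return A tibble per line x category with the mean standardized ratio
#'   and its standard error (SD over individuals / sqrt(n)).
#' @export
load_summary <- function(standardized) {
  standardized |>
    group_by(.data$line, .data$category) |>
    summarise(mean = mean(.data$standardized),
              se = sd(.data$standardized) / sqrt(n()),
              n = n(), .groups = "drop")
}

#' Stratify sites by local recombination rate quartiles
#'
#' Sites are assigned the rate of their 100-kb map bin (BED convention:
#' 0-based half-open), ranked, and the top and bottom quartiles labelled
#' `high` and `low` (`middle` otherwise). Ties are broken by genomic
#' position; rate ties straddling a quartile boundary are resolved to the
#' lower-ranked stratum by that ordering and reported with a message. A
#' fully tied rate vector yields empty high/low strata with a warning.
#'
#' @param sites Tibble with `chrom`, `pos` (and optionally `cM_per_Mb`,
#'   ignored in favour of the map).
#' @param recomb_map BED-like tibble: `chrom`, `start`, `end`, `cM_per_Mb`.
#' @return `sites` with added columns `rate` and `stratum`.
#' @export
recombination_strata <- function(sites, recomb_map) {
  sites <- as_tibble(sites)
  rate <- rep(NA_real_, nrow(sites))
  for (cc in unique(sites$chrom)) {
    m <- recomb_map[recomb_map$chrom == cc, ]
    i <- which(sites$chrom == cc)
    if (!nrow(m)) next
    bin <- findInterval(sites$pos[i] - 1L, m$start)
    ok <- bin >= 1 & sites$pos[i] - 1L < m$end[pmax(bin, 1)]
    rate[i[ok]] <- m$cM_per_Mb[bin[ok]]
  }
  if (anyNA(rate)) abort("Some sites fall outside the recombination map.")
  n <- length(rate)
  if (min(rate) == max(rate)) {
    warn("All sites share one recombination rate; high/low strata are empty.")
    return(mutate(sites, rate = rate, stratum = "middle"))
  }
  ord <- order(rate, sites$chrom, sites$pos)
  n_q <- floor(n / 4)
  stratum <- rep("middle", n)
  stratum[ord[seq_len(n_q)]] <- "low"
  stratum[ord[seq.int(n - n_q + 1L, n)]] <- "high"
  lo_cut <- rate[ord[n_q]]
  hi_cut <- rate[ord[n - n_q + 1L]]
  if (sum(rate == lo_cut) > 1 || sum(rate == hi_cut) > 1) {
    inform("Rate ties straddle a quartile boundary; resolved by genomic position.")
  }
  mutate(sites, rate = rate, stratum = stratum)
}

#' Compare standardized load between two lines in one category
#'
#' Two-sided test on the per-individual standardized ratios of the focal
#' versus the reference line: Welch's t by default, or a permutation test
#' (individuals shuffled between lines) when requested.
#'
#' @param standardized Output of [standardize_load()] containing both lines.
#' @param category Category to test.
#' @param focal,reference Line labels; defaults to the two lines present
#'   (focal = the non-reference one as ordered in the data).
#' @param method "welch" or "permutation".
#' @param n_perm Permutations for the permutation test.
#' @param seed Seed for the permutation test.
#' @return A one-row tibble: `category`, `estimate` (focal - reference mean
#'   standardized ratio), `se`, `p`, `method`.
#' @export
compare_load <- function(standardized, category, focal = NULL,
                         reference = NULL, method = c("welch", "permutation"),
                         n_perm = 10000, seed = 1L) {
  method <- match.arg(method)
  lines <- unique(standardized$line)
  if (length(lines) != 2 && (is.null(focal) || is.null(reference))) {
    abort("Supply `focal` and `reference` when more than two lines are present.")
  }
  reference <- reference %||% lines[2]
  focal <- focal %||% setdiff(lines, reference)[1]
  x <- standardized$standardized[standardized$line == focal &
                                   standardized$category == category]
  y <- standardized$standardized[standardized$line == reference &
                                   standardized$category == category]
  if (length(x) < 2 || length(y) < 2) {
    abort("Need at least two individuals per line.")
  }
  est <- mean(x) - mean(y)
  se <- sqrt(var(x) / length(x) + var(y) / length(y))
  p <- if (identical(x, y) || (var(x) == 0 && var(y) == 0 && est == 0)) {
    1
  } else if (method == "welch") {
    t.test(x, y)$p.value
  } else {
    with_seed(seed, {
      pool <- c(x, y)
      nx <- length(x)
      obs <- abs(est)
      hits <- 0L
      for (b in seq_len(n_perm)) {
        idx <- sample.int(length(pool), nx)
        if (abs(mean(pool[idx]) - mean(pool[-idx])) >= obs - 1e-12) {
          hits <- hits + 1L
        }
      }
      (hits + 1) / (n_perm + 1)
    })
  }
  tibble(category = category, estimate = est, se = se, p = p,
         method = method)
}
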