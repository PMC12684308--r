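# Diversity statistics over polarized biallelic genotype matrices. The
# haploid sample size is twice the number of sequenced individuals (males
# sequenced on autosomes); missing genotypes reduce the per-site allele
# count.

site_allele_counts <- function(gm) {
  dos <- gm$dosage
  n_obs <- 2L * colSums(!is.na(dos))
  d <- colSums(dos, na.rm = TRUE)
  list(n = n_obs, derived = d)
}

#' Nucleotide diversity of a genotype matrix
#'
#' Unbiased mean pairwise difference per site, averaged over analysed
#' sites: at each site with at least two observed alleles the contribution
#' is `2 d (n - d) / (n (n - 1))` for derived count `d` among `n` observed
#' alleles; sites with fewer than two observed alleles are skipped.
#'
#' @param gm A [genotype_matrix()].
#' @return Mean per-site diversity (a single number).
#' @export
nucleotide_diversity <- function(gm) {
  if (!ncol(gm$dosage)) abort("Empty genotype matrix.")
  ac <- site_allele_counts(gm)
  ok <- ac$n >= 2
  if (!any(ok)) abort("No site has two or more observed alleles.")
  n <- ac$n[ok]; d <- ac$derived[ok]
  mean(2 * d * (n - d) / (n * (n - 1)))
}

#' Watterson's theta from the number of segregating sites
#'
#' `theta_W = S / a1` with `a1 = sum_{i=1}^{n-1} 1/i`: the segregating-site
#' count corrected by the number of sequences. Supply either the count and
#' haploid sample size directly, or a genotype matrix via
#' [diversity_summary()].
#'
#' @param S Number of segregating sites (or total mutations Eta for
#'   biallelic data).
#' @param n Haploid sample size (>= 2).
#' @return Watterson's theta on the count scale.
#' @examples
#' watterson_theta(62520.50, 24)
#' @export
watterson_theta <- function(S, n) {
  if (n < 2) abort("`n` must be at least 2.")
  if (any(S < 0)) abort("`S` must be non-negative.")
  S / sum(1 / seq_len(n - 1))
}

#' Heterozygous positions per individual
#'
#' Number of sites with dosage 1 for one individual (or all), missing calls
#' excluded.
#'
#' @param gm A [genotype_matrix()].
#' @param individual Optional individual id; when omitted all individuals
#'   are returned.
#' @return A tibble with `id` and `n_het`.
#' @export
heterozygous_positions <- function(gm, individual = NULL) {
  ids <- gm$individuals$id
  if (!is.null(individual)) {
    if (!individual %in% ids) {
      abort(sprintf("Unknown individual: %s", individual))
    }
    ids <- individual
  }
  rows <- match(ids, gm$individuals$id)
  tibble(
    id = ids,
    n_het = vapply(rows, function(r) {
      sum(gm$dosage[r, ] == 1L, na.rm = TRUE)
    }, numeric(1))
  )
}

tajima_constants <- function(n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D of a genotype matrix
#'
#' Standard normalized difference between the total pairwise diversity and
#' Watterson's theta, `D = (k - S/a1) / sqrt(e1 S + e2 S (S - 1))`, with the
#' canonical constants evaluated at the modal haploid sample size. Positive
#' values indicate an excess of intermediate-frequency variants. Returns
#' `NA` (undefined) when there are no segregating sites.
#'
#' @param gm A [genotype_matrix()].
#' @return Tajima's D, or `NA_real_` when undefined.
#' @export
tajimas_d <- function(gm) {
  ac <- site_allele_counts(gm)
  ok <- ac$n >= 2
  n_site <- ac$n[ok]; d <- ac$derived[ok]
  seg <- d > 0 & d < n_site
  S <- sum(seg)
  if (S == 0) return(NA_real_)
  n <- as.integer(names(sort(table(n_site), decreasing = TRUE))[1])
  if (n < 2) return(NA_real_)
  k <- sum(2 * d[seg] * (n_site[seg] - d[seg]) /
             (n_site[seg] * (n_site[seg] - 1)))
  cst <- tajima_constants(n)
  (k - S / cst$a1) / sqrt(cst$e1 * S + cst$e2 * S * (S - 1))
}

#' Diversity summary of a genotype matrix
#'
#' One-row tibble with the statistics reported for each sequenced line:
#' segregating sites S (equal to the total mutation count Eta for biallelic
#' data), nucleotide diversity per site, Watterson's theta, the mean number
#' of heterozygous positions per individual, Tajima's D and the haploid
#' sample size.
#'
#' @param gm A [genotype_matrix()].
#' @return A tibble.
#' @export
diversity_summary <- function(gm) {
  ac <- site_allele_counts(gm)
  ok <- ac$n >= 2
  seg <- ac$derived[ok] > 0 & ac$derived[ok] < ac$n[ok]
  S <- sum(seg)
  n_seq <- 2L * nrow(gm$dosage)
  het <- heterozygous_positions(gm)
  tibble(
    line = gm$individuals$line[1],
    n_sequences = n_seq,
    S = S,
    eta = S,
    pi = nucleotide_diversity(gm),
    theta_w = watterson_theta(S, n_seq),
    mean_het_positions = mean(het$n_het),
    tajimas_d = tajimas_d(gm)
  )
}
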