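# Shared fixtures and independent oracles used across the suite.

`%||%` <- function(a, b) if (is.null(a)) b else a

# quick genotype matrix: dosage rows = individuals; positions default evenly
# spaced on one chromosome
make_gm <- function(dosage, pos = NULL, chrom = NULL, category = NULL,
                    line = NA_character_) {
  dosage <- as.matrix(dosage)
  n_sites <- ncol(dosage)
  pos <- pos %||% seq(1000, by = 1000, length.out = n_sites)
  chrom <- chrom %||% rep("2L", n_sites)
  sites <- tibble::tibble(chrom = chrom, pos = as.integer(pos))
  if (!is.null(category)) sites$category <- category
  genotype_matrix(dosage, sites,
                  tibble::tibble(id = paste0("i", seq_len(nrow(dosage))),
                                 line = line))
}

random_gm <- function(n_ind, n_snps, p_missing = 0, het_bias = 0.5,
                      max_pos = NULL) {
  max_pos <- max_pos %||% (n_snps * 20000)
  pos <- sort(sample.int(max_pos, n_snps))
  dos <- matrix(sample(0:2, n_ind * n_snps, replace = TRUE,
                       prob = c((1 - het_bias) / 2, het_bias,
                                (1 - het_bias) / 2)),
                n_ind, n_snps)
  if (p_missing > 0) {
    dos[runif(length(dos)) < p_missing] <- NA_integer_
  }
  make_gm(dos, pos = pos)
}

# Naive reimplementation of the sliding-window ROH pipeline with explicit
# loops: windows tested one by one, hit rates accumulated per SNP, runs
# scanned linearly, every candidate piece tested directly against every
# filter.
roh_oracle <- function(gm, individual, params, min_snps) {
  r <- match(individual, gm$individuals$id)
  out <- list()
  for (cc in unique(gm$sites$chrom)) {
    sel <- which(gm$sites$chrom == cc)
    pos <- gm$sites$pos[sel]
    geno <- gm$dosage[r, sel]
    m <- length(geno)
    W <- params$window_snps
    eligible <- rep(FALSE, m)
    if (m >= W) {
      n_win <- m - W + 1
      hom <- logical(n_win)
      for (j in seq_len(n_win)) {
        win <- geno[j:(j + W - 1)]
        hom[j] <- sum(win == 1L, na.rm = TRUE) <= params$window_het_allowance &&
          sum(is.na(win)) <= params$window_missing_allowance
      }
      for (i in seq_len(m)) {
        hits <- 0L; covers <- 0L
        for (j in max(1, i - W + 1):min(i, n_win)) {
          covers <- covers + 1L
          if (hom[j]) hits <- hits + 1L
        }
        eligible[i] <- covers > 0 && hits / covers >= params$window_threshold
      }
    }
    i <- 1
    while (i <= m) {
      if (!eligible[i]) { i <- i + 1; next }
      j <- i
      while (j < m && eligible[j + 1]) j <- j + 1
      # split run at large gaps
      piece_start <- i
      for (kk in i:j) {
        end_piece <- kk == j || (pos[kk + 1] - pos[kk]) > params$max_gap_bp
        if (end_piece) {
          n_snps <- kk - piece_start + 1
          len <- pos[kk] - pos[piece_start] + 1
          if (n_snps >= min_snps && len >= params$min_length_bp &&
              n_snps * params$min_density_bp >= len) {
            out[[length(out) + 1]] <- tibble::tibble(
              individual = individual, chrom = cc,
              start = pos[piece_start], end = pos[kk],
              n_snps = n_snps, length_bp = len)
          }
          piece_start <- kk + 1
        }
      }
      i <- j + 1
    }
  }
  if (!length(out)) {
    tibble::tibble(individual = character(), chrom = character(),
                   start = integer(), end = integer(), n_snps = integer(),
                   length_bp = integer())
  } else {
    dplyr::bind_rows(out)
  }
}

# Tajima's D from first principles: allele-pair enumeration for the mean
# pairwise difference and the canonical constants written out directly.
tajima_oracle <- function(dosage) {
  n_ind <- nrow(dosage)
  n <- 2 * n_ind
  S <- 0
  k_total <- 0
  for (s in seq_len(ncol(dosage))) {
    d <- sum(dosage[, s])
    if (d > 0 && d < n) {
      S <- S + 1
      alleles <- c(rep(1, d), rep(0, n - d))
      diffs <- 0
      pairs <- 0
      for (a in 1:(n - 1)) {
        for (b in (a + 1):n) {
          pairs <- pairs + 1
          if (alleles[a] != alleles[b]) diffs <- diffs + 1
        }
      }
      k_total <- k_total + diffs / pairs
    }
  }
  if (S == 0) return(NA_real_)
  a1 <- 0; a2 <- 0
  for (i in 1:(n - 1)) { a1 <- a1 + 1 / i; a2 <- a2 + 1 / i^2 }
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (k_total - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Exact two-sided Mann-Whitney p by enumerating every group assignment.
mw_oracle <- function(x, y) {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  combos <- utils::combn(n + m, n)
  u_of <- function(xs, ys) {
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u_obs <- u_of(x, y)
  us <- apply(combos, 2, function(idx) u_of(pooled[idx], pooled[-idx]))
  p <- min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
  list(U = u_obs, p = p)
}

tiny_config <- function(...) {
  reduced_experiment_config(
    n_bottles = 4, bottle_size = 8, founding_generation_of_n50 = 1,
    n50_count = 2, n50_size = 8, n50_generations = 3,
    n8_size = 8, n8_generations = 4, lines_per_n50 = 1,
    rescue_generations = c(2, 3), sequencing_generation = 2,
    n_assay_vials_outbred = 5, n_assay_vials_inbred = 5,
    n_neutral_loci = 150, n_deleterious_loci = 80, n_lethal_loci = 20,
    ...
  )
}
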