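test_that("nucleotide diversity matches hand-computed pair counts", {
  # 2 diploids = 4 sequences, one site with derived count 2: 4 of 6 pairs differ
  gm <- make_gm(matrix(c(1, 1), ncol = 1))
  expect_equal(nucleotide_diversity(gm), 2 / 3, tolerance = 1e-12)
  # one diploid (2 sequences) differing at 3 of 10 sites
  gm2 <- make_gm(matrix(c(rep(1, 3), rep(0, 7)), nrow = 1))
  expect_equal(nucleotide_diversity(gm2), 0.3, tolerance = 1e-12)
  gm3 <- make_gm(matrix(0L, 4, 6))
  expect_equal(nucleotide_diversity(gm3), 0)
  expect_error(nucleotide_diversity(make_gm(matrix(0L, 2, 0))), "Empty")
})

test_that("pi matches the closed form on fixed allele frequencies", {
  set.seed(21)
  n_ind <- 10; n <- 2 * n_ind; L <- 400
  dos <- matrix(rbinom(n_ind * L, 2, rep(runif(L, 0.05, 0.95), each = n_ind)),
                n_ind, L)
  gm <- make_gm(dos)
  p_hat <- colSums(dos) / n
  closed <- mean(2 * p_hat * (1 - p_hat) * n / (n - 1))
  expect_equal(nucleotide_diversity(gm), closed, tolerance = 1e-12)
})

test_that("Watterson's theta is S corrected by the number of sequences", {
  expect_equal(watterson_theta(62520.50, 24), 16742.27, tolerance = 0.005)
  expect_equal(watterson_theta(41092.00, 24), 11003.96, tolerance = 0.005)
  expect_equal(watterson_theta(0, 24), 0)
  expect_equal(watterson_theta(5, 2), 5)
  expect_error(watterson_theta(5, 1), "at least 2")
})

test_that("heterozygous positions count dosage-1 sites, skipping missing", {
  gm <- make_gm(rbind(c(0, 1, 2, 1), c(0, 0, 2, 2)))
  expect_equal(heterozygous_positions(gm, "i1")$n_het, 2)
  expect_equal(heterozygous_positions(gm, "i2")$n_het, 0)
  gm2 <- make_gm(matrix(c(1, NA, 1), nrow = 1))
  expect_equal(heterozygous_positions(gm2, "i1")$n_het, 2)
  expect_error(heterozygous_positions(gm, "nobody"), "Unknown")
})

test_that("Tajima's D agrees with the constant-by-constant oracle", {
  gm0 <- make_gm(matrix(0L, 4, 5))
  expect_true(is.na(tajimas_d(gm0)))
  # single singleton site among 4 sequences (2 diploids)
  gm1 <- make_gm(rbind(c(1, 0), c(0, 0)))
  expect_equal(tajimas_d(gm1), tajima_oracle(rbind(c(1, 0), c(0, 0))),
               tolerance = 1e-10)
  set.seed(31)
  for (i in 1:20) {
    n_ind <- sample(3:8, 1)
    dos <- matrix(sample(0:2, n_ind * 30, replace = TRUE), n_ind, 30)
    gm <- make_gm(dos)
    d_pkg <- tajimas_d(gm)
    d_orc <- tajima_oracle(dos)
    if (is.na(d_orc)) {
      expect_true(is.na(d_pkg))
    } else {
      expect_equal(d_pkg, d_orc, tolerance = 1e-10)
    }
  }
})

test_that("intermediate-frequency variants give larger D than singletons", {
  n_ind <- 6
  inter <- matrix(rep(c(rep(1, n_ind)), 15), n_ind, 15) # all heterozygous
  singl <- matrix(0L, n_ind, 15)
  singl[1, ] <- 1L
  expect_gt(tajimas_d(make_gm(inter)), tajimas_d(make_gm(singl)))
})

test_that("pi and theta are invariant to individual order and polarity swap", {
  set.seed(41)
  gm <- random_gm(8, 60)
  perm <- sample.int(8)
  gmp <- genotype_matrix(gm$dosage[perm, ], gm$sites,
                         gm$individuals[perm, ])
  expect_equal(nucleotide_diversity(gmp), nucleotide_diversity(gm))
  flip <- sample(c(TRUE, FALSE), 60, replace = TRUE)
  dos2 <- gm$dosage
  dos2[, flip] <- 2L - dos2[, flip]
  gmf <- genotype_matrix(dos2, gm$sites, gm$individuals)
  expect_equal(nucleotide_diversity(gmf), nucleotide_diversity(gm))
  s1 <- diversity_summary(gm); s2 <- diversity_summary(gmf)
  expect_equal(s1$theta_w, s2$theta_w)
  expect_equal(s1$S, s2$S)
})

test_that("diversity summary ties eta to S and theta to eta / a1", {
  set.seed(51)
  gm <- random_gm(12, 80)
  s <- diversity_summary(gm)
  expect_equal(s$eta, s$S)
  a1 <- sum(1 / seq_len(s$n_sequences - 1))
  expect_equal(s$theta_w * a1, s$eta, tolerance = 1e-9)
  expect_equal(s$n_sequences, 24)
})
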