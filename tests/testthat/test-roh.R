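test_that("minimum SNP rule follows the false-positive formula", {
  expect_equal(min_roh_snps(1000, 1, 0.5, 0.05), 15L)
  expect_equal(min_roh_snps(1000, 10, 0.5, 0.05), 18L)
  expect_equal(min_roh_snps(1000, 1, 0.99, 0.05), 3L)
  expect_error(min_roh_snps(1000, 1, 0, 0.05), "strictly between")
  expect_error(min_roh_snps(1000, 1, 1, 0.05), "strictly between")
})

test_that("a clean homozygous tract is called as one exact segment", {
  # 200 homozygous SNPs evenly spanning 1,000..201,000, individual otherwise
  # heterozygous at flanking SNPs far away
  pos <- c(round(seq(1000, 201000, length.out = 200)),
           seq(500000, by = 60000, length.out = 40))
  geno <- c(rep(0, 200), rep(1, 40))
  gm <- make_gm(matrix(geno, nrow = 1), pos = pos)
  segs <- call_roh(gm, params = roh_params(min_snps = 30))
  expect_equal(nrow(segs), 1)
  expect_equal(segs$start, 1000)
  expect_equal(segs$end, 201000)
  expect_equal(segs$n_snps, 200)
  expect_equal(segs$length_bp, 200001)
})

test_that("tracts shorter than the minimum length are rejected", {
  pos <- round(seq(1000, 90999, length.out = 150))
  gm <- make_gm(matrix(rep(0, 150), nrow = 1), pos = pos)
  segs <- call_roh(gm, params = roh_params(min_snps = 30))
  expect_equal(nrow(segs), 0)
})

test_that("a fully heterozygous individual yields no segments", {
  gm <- make_gm(matrix(rep(1, 300), nrow = 1),
                pos = seq(1000, by = 900, length.out = 300))
  expect_equal(nrow(call_roh(gm, params = roh_params(min_snps = 10))), 0)
})

test_that("caller equals the brute-force window enumerator on random data", {
  set.seed(61)
  n_match <- 0
  for (trial in 1:40) {
    n_snps <- sample(40:500, 1)
    gm <- random_gm(1, n_snps, p_missing = runif(1, 0, 0.1),
                    het_bias = runif(1, 0.02, 0.3),
                    max_pos = n_snps * sample(c(2000, 20000, 60000), 1))
    params <- roh_params(
      window_snps = sample(c(10, 20, 30), 1),
      window_threshold = sample(c(0.01, 0.05), 1),
      min_length_bp = sample(c(50000, 100000), 1),
      max_gap_bp = sample(c(50000, 200000), 1),
      min_snps = sample(c(10, 25), 1)
    )
    got <- call_roh(gm, params = params)
    want <- roh_oracle(gm, "i1", params, params$min_snps)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got)) {
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$n_snps, want$n_snps)
    }
    n_match <- n_match + 1
  }
  expect_equal(n_match, 40)
})

test_that("raising thresholds never adds segments and filters always hold", {
  set.seed(71)
  for (trial in 1:20) {
    gm <- random_gm(1, 300, het_bias = 0.1)
    base <- roh_params(min_snps = 15, window_snps = 15)
    strict <- roh_params(min_snps = 30, window_snps = 15,
                         min_length_bp = 2 * base$min_length_bp)
    s_base <- call_roh(gm, params = base)
    s_strict <- call_roh(gm, params = strict)
    expect_lte(nrow(s_strict), nrow(s_base))
    if (nrow(s_base)) {
      expect_true(all(s_base$n_snps >= 15))
      expect_true(all(s_base$length_bp >= base$min_length_bp))
      expect_true(all(s_base$length_bp <= s_base$n_snps * base$min_density_bp))
      expect_true(all(s_base$end >= s_base$start))
    }
  }
})

test_that("F_ROH sums segment lengths over the analysed genome", {
  expect_equal(nrow(f_roh(call_roh(make_gm(matrix(1, 1, 50)),
                                   params = roh_params(min_snps = 5)))), 0)
  segs <- tibble::tibble(individual = "a", chrom = "2L", start = 1,
                         end = 11e6, n_snps = 500, length_bp = 11e6)
  expect_equal(f_roh(segs)$f_roh, 0.1)
  segs2 <- tibble::tibble(
    individual = "a", chrom = c("2L", "3R"), start = c(1, 1),
    end = c(5e6, 6e6), n_snps = c(100, 100), length_bp = c(5e6, 6e6))
  expect_equal(f_roh(segs2)$f_roh, 0.1)
  expect_true(all(f_roh(segs2)$f_roh >= 0 & f_roh(segs2)$f_roh <= 1))
  overlap <- tibble::tibble(
    individual = "a", chrom = "2L", start = c(1, 4e6),
    end = c(5e6, 8e6), n_snps = c(10, 10), length_bp = c(5e6, 4e6 + 1))
  expect_error(f_roh(overlap), "Overlap")
})

test_that("length classes split at the 1.5 Mb boundary", {
  segs <- tibble::tibble(individual = "a", chrom = "2L",
                         start = c(1, 1e7), end = c(4e5, 1.2e7),
                         n_snps = c(50, 60),
                         length_bp = c(4e5, 2e6))
  lc <- roh_length_classes(segs)
  expect_equal(lc$counts$n_short, 1)
  expect_equal(lc$counts$n_long, 1)
  empty <- roh_length_classes(segs[0, ])
  expect_equal(empty$counts$n_short, 0)
  expect_equal(empty$counts$n_long, 0)
})

test_that("presets override single scan parameters", {
  expect_equal(roh_preset("density200")$min_density_bp, 200000)
  expect_equal(roh_preset("gap200")$max_gap_bp, 200000)
  expect_equal(roh_preset("window60")$window_snps, 60)
  expect_equal(roh_preset("threshold001")$window_threshold, 0.01)
})
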