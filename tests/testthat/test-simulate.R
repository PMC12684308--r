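test_that("a mutation-free model keeps mean fitness at one everywhere", {
  cfg <- tiny_config()
  sim <- simulate_experiment(cfg, neutral_model(), seed = 7)
  expect_true(all(abs(sim$trajectory$mean_fitness - 1) < 1e-12))
})

test_that("census sizes are conserved in non-extinct populations", {
  cfg <- tiny_config()
  sim <- simulate_experiment(cfg, mutation_model(), seed = 8)
  tr <- sim$trajectory
  expect_true(all(tr$census[tr$type == "bp"] ==
                    cfg$n_bottles * cfg$bottle_size))
  expect_true(all(tr$census[tr$type == "n50"] == cfg$n50_size))
  expect_true(all(tr$census[tr$type == "line"] == cfg$n8_size))
})

test_that("circular mixing rebuilds each bottle from its two source bottles", {
  cfg <- tiny_config()
  g <- build_genome(cfg, mutation_model(), seed = 2)
  set.seed(3)
  bp <- found_population(g, cfg$n_bottles * cfg$bottle_size)
  bp$bottle <- rep(seq_len(cfg$n_bottles), each = cfg$bottle_size)
  nxt <- advance_generation(bp, "bp_circular", g, cfg)
  expect_equal(sort(unique(nxt$bottle)), seq_len(cfg$n_bottles))
  src <- attr(nxt, "source_bottles")
  for (i in seq_len(cfg$n_bottles)) {
    j <- if (i == cfg$n_bottles) 1L else i + 1L
    expect_true(all(src[nxt$bottle == i] %in% c(i, j)))
  }
  expect_equal(nrow(nxt$h1), cfg$n_bottles * cfg$bottle_size)
})

test_that("single-sex progeny produces an extinction marker, not an error", {
  cfg <- tiny_config()
  g <- build_genome(cfg, neutral_model(), seed = 2)
  set.seed(4)
  p <- found_population(g, 8)
  p$sex <- rep(1L, 8) # all male: no mating possible
  out <- advance_generation(p, "n8_vial", g, cfg)
  expect_true(is_extinct(out))
  expect_equal(out$reason, "single_sex")
})

test_that("a rescue male competes on equal terms for matings", {
  cfg <- tiny_config(n8_size = 300, rearing_capacity = 3, p_max = 250)
  g <- build_genome(cfg, neutral_model(), seed = 2)
  set.seed(5)
  p <- found_population(g, 8)
  donor <- found_population(g, 2)
  migrant <- take_individual(donor, which(donor$sex == 1L)[1])
  migrant$id <- 999L
  out <- advance_generation(p, "n8_vial", g, cfg, rescue_male = migrant)
  expect_false(is_extinct(out))
  par <- attr(out, "parents")
  frac <- mean(par$sire == 999L)
  n <- nrow(par)
  expect_lt(abs(frac - 0.2), 3 * sqrt(0.2 * 0.8 / n))
})

test_that("assay schemes carry their design inbreeding coefficients", {
  cfg <- tiny_config()
  g <- build_genome(cfg, mutation_model(), seed = 2)
  set.seed(6)
  p <- found_population(g, 30)
  out <- assay_pairs(p, "outbred", 12, g)
  expect_true(all(out$design_F == 0))
  expect_equal(nrow(out), 12)
  inb <- assay_pairs(p, "inbred", 10, g)
  expect_true(all(inb$design_F == 0.25))
  expect_equal(nrow(assay_pairs(p, "outbred", 0, g)), 0)
  expect_true(all(out$pupae_count >= 0))
})

test_that("inbred assay vials are less productive under a deleterious model", {
  cfg <- tiny_config()
  g <- build_genome(tiny_config(n_deleterious_loci = 600,
                                n_lethal_loci = 200), mutation_model(),
                    seed = 11)
  set.seed(12)
  p <- found_population(g, 60)
  out <- assay_pairs(p, "outbred", 120, g)
  inb <- assay_pairs(p, "inbred", 120, g)
  expect_gt(mean(out$pupae_count), mean(inb$pupae_count))
})

test_that("exported genotypes encode dosages and sample twelve males", {
  cfg <- tiny_config()
  g <- build_genome(cfg, mutation_model(), seed = 2)
  set.seed(7)
  p <- found_population(g, 40)
  gm <- export_genotypes(p, 12, g, line = "test")
  expect_equal(nrow(gm$dosage), 12)
  expect_true(all(colSums(gm$dosage) > 0))
  expect_error(export_genotypes(p, 35, g), "males")
  # VCF encoding of the three dosage values
  gm3 <- make_gm(matrix(c(0L, 1L, 2L), 1, 3))
  f <- withr::local_tempfile(fileext = ".vcf")
  write_genotypes_vcf(gm3, f)
  body <- readLines(f)
  gtcols <- vapply(strsplit(grep("^2L", body, value = TRUE), "\t"),
                   function(x) x[10], character(1))
  expect_equal(gtcols, c("0/0", "0/1", "1/1"))
  # round trip through the loader
  vcf2 <- withr::local_tempfile(fileext = ".vcf")
  write_genotypes_vcf(gm, vcf2)
  back <- load_genotypes(vcf2, site_filter_policy(drop_monomorphic = FALSE))
  expect_equal(unname(back$genotypes$dosage), unname(gm$dosage))
})

test_that("identical configuration and seed give identical results", {
  cfg <- tiny_config()
  s1 <- simulate_experiment(cfg, mutation_model(), seed = 9)
  s2 <- simulate_experiment(cfg, mutation_model(), seed = 9)
  expect_identical(s1$trajectory, s2$trajectory)
  expect_identical(s1$survival, s2$survival)
  expect_identical(s1$productivity, s2$productivity)
  expect_identical(s1$snapshots$non_rescued$dosage,
                   s2$snapshots$non_rescued$dosage)
  s3 <- simulate_experiment(cfg, mutation_model(), seed = 10)
  expect_false(identical(s1$trajectory, s3$trajectory))
})

test_that("sequenced snapshots carry twelve males per line with annotations", {
  cfg <- tiny_config()
  sim <- simulate_experiment(cfg, mutation_model(), seed = 8)
  if (!is.null(sim$snapshots)) {
    for (gm in sim$snapshots) {
      expect_equal(nrow(gm$dosage), 12)
      expect_true(all(!is.na(gm$sites$category)))
      expect_true(all(gm$sites$cM_per_Mb >= 0))
    }
  }
  expect_true(all(c("non_rescued", "rescued_n50", "rescued_bp") %in%
                    sim$survival$treatment))
})

test_that("line crosses mask drifted recessives at least as well as within-line matings", {
  cfg <- tiny_config(n8_generations = 8, n50_generations = 2)
  sim <- simulate_experiment(cfg, mutation_model(), seed = 21)
  n_alive <- sum(sim$survival$treatment == "non_rescued" &
                   is.na(sim$survival$extinction_generation))
  expect_gte(n_alive, 2)
  h <- heterosis_check(sim, seed = 3)
  expect_gte(h$mean_between, h$mean_within - 1e-9)
})

test_that("lines are founded directly from N50 adults when enough exist", {
  cfg <- tiny_config(n50_size = 16, n8_size = 4, n50_generations = 2,
                     n8_generations = 3, sequencing_generation = 1)
  sim <- simulate_experiment(cfg, neutral_model(), seed = 31)
  per_n50 <- dplyr::count(sim$survival, origin_n50)
  expect_true(all(per_n50$n == 3 * cfg$lines_per_n50))
  tr <- sim$trajectory
  expect_true(all(tr$census[tr$type == "line"] == 4))
})
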