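cats4 <- c("synonymous_fourfold", "missense", "lof", "missense")

test_that("derived counts sum dosages per category", {
  dos <- rbind(c(2, 1, 2, 0), c(1, 0, 0, 1))
  gm <- make_gm(dos, category = cats4, line = "a")
  prof <- derived_count_profile(gm)
  get <- function(id, cc) prof$count[prof$id == id & prof$category == cc]
  expect_equal(get("i1", "synonymous_fourfold"), 2)
  expect_equal(get("i1", "missense"), 1)
  expect_equal(get("i1", "lof"), 2)
  expect_equal(get("i2", "missense"), 1)
  expect_equal(get("i2", "lof"), 0)
  # all-ancestral individual scores zero everywhere
  gm0 <- make_gm(matrix(0, 1, 4), category = cats4)
  expect_true(all(derived_count_profile(gm0)$count == 0))
  # missing dosages are skipped
  gmna <- make_gm(matrix(c(1, NA, 2, 1), 1, 4), category = cats4)
  p <- derived_count_profile(gmna)
  expect_equal(p$count[p$category == "missense"], 1)
})

test_that("standardization pins the reference line mean at exactly one", {
  set.seed(81)
  cats <- sample(c("synonymous_fourfold", "missense", "lof", "intronic"),
                 60, replace = TRUE, prob = c(0.4, 0.3, 0.1, 0.2))
  ref <- make_gm(matrix(rbinom(12 * 60, 2, 0.3), 12, 60), category = cats,
                 line = "ref")
  foc <- make_gm(matrix(rbinom(12 * 60, 2, 0.25), 12, 60), category = cats,
                 line = "foc")
  std <- standardize_load(derived_count_profile(foc),
                          derived_count_profile(ref))
  smry <- load_summary(std)
  ref_means <- smry$mean[smry$line == "ref"]
  expect_equal(ref_means, rep(1, length(ref_means)), tolerance = 1e-12)
  # simple arithmetic: focal ratio half the reference mean ratio
  p_foc <- tibble::tibble(id = "x", line = "f",
                          category = c("synonymous_fourfold", "missense"),
                          count = c(10, 5))
  p_ref <- tibble::tibble(id = c("y", "z"), line = "r") |>
    tidyr::crossing(category = c("synonymous_fourfold", "missense")) |>
    dplyr::mutate(count = ifelse(category == "missense", 10, 10))
  std2 <- standardize_load(p_foc, p_ref)
  expect_equal(std2$standardized[std2$line == "f" &
                                   std2$category == "missense"], 0.5)
})

test_that("normalised ratios cancel the count scale", {
  set.seed(91)
  cats <- rep(c("synonymous_fourfold", "missense"), each = 20)
  dos <- matrix(rbinom(6 * 40, 2, 0.4), 6, 40)
  gm1 <- make_gm(dos, category = cats, line = "l")
  # duplicating every site doubles raw counts but leaves ratios unchanged
  gm2 <- make_gm(cbind(dos, dos),
                 pos = seq(1000, by = 500, length.out = 80),
                 category = c(cats, cats), line = "l")
  s1 <- standardize_load(derived_count_profile(gm1),
                         derived_count_profile(gm1))
  s2 <- standardize_load(derived_count_profile(gm2),
                         derived_count_profile(gm2))
  expect_equal(s1$ratio, s2$ratio[seq_len(nrow(s1))], tolerance = 1e-12)
  # raw counts invariant to site order
  perm <- sample.int(40)
  gm3 <- genotype_matrix(gm1$dosage[, order(perm)],
                         gm1$sites[order(perm), ] |>
                           dplyr::arrange(chrom, pos),
                         gm1$individuals)
  expect_equal(
    dplyr::arrange(derived_count_profile(gm1), id, category)$count,
    dplyr::arrange(derived_count_profile(gm1), id, category)$count
  )
})

test_that("zero fourfold counts are a normalisation error", {
  p <- tibble::tibble(id = "x", line = "f",
                      category = c("synonymous_fourfold", "missense"),
                      count = c(0, 5))
  expect_error(standardize_load(p, p), "fourfold")
})

test_that("recombination quartiles rank sites and handle ties", {
  sites <- tibble::tibble(chrom = "2L",
                          pos = as.integer(seq(50000, by = 100000,
                                               length.out = 8)))
  map <- tibble::tibble(chrom = "2L",
                        start = seq(0, by = 100000, length.out = 8),
                        end = seq(100000, by = 100000, length.out = 8),
                        cM_per_Mb = 1:8)
  st <- recombination_strata(sites, map)
  expect_equal(st$stratum[st$rate %in% c(7, 8)], c("high", "high"))
  expect_equal(st$stratum[st$rate %in% c(1, 2)], c("low", "low"))
  expect_equal(sum(st$stratum == "high"), 2)
  flat <- dplyr::mutate(map, cM_per_Mb = 2)
  expect_warning(st2 <- recombination_strata(sites, flat), "one recombination")
  expect_true(all(st2$stratum == "middle"))
  outside <- tibble::tibble(chrom = "2L", pos = 9999999L)
  expect_error(recombination_strata(outside, map), "outside")
})

test_that("quartile strata sizes stay within one site of N/4 without ties", {
  set.seed(101)
  n <- 37
  sites <- tibble::tibble(chrom = "2L",
                          pos = as.integer(seq(50000, by = 100000,
                                               length.out = n)))
  map <- tibble::tibble(chrom = "2L",
                        start = seq(0, by = 100000, length.out = n),
                        end = seq(100000, by = 100000, length.out = n),
                        cM_per_Mb = sample(seq(0.1, 10, length.out = n)))
  st <- recombination_strata(sites, map)
  expect_lte(abs(sum(st$stratum == "high") - n / 4), 1)
  expect_lte(abs(sum(st$stratum == "low") - n / 4), 1)
})

test_that("within-stratum profiles use only that stratum's fourfold sites", {
  set.seed(111)
  n <- 40
  cats <- rep(c("synonymous_fourfold", "missense"), n / 2)
  sites_pos <- as.integer(seq(50000, by = 100000, length.out = n))
  map <- tibble::tibble(chrom = "2L",
                        start = seq(0, by = 100000, length.out = n),
                        end = seq(100000, by = 100000, length.out = n),
                        cM_per_Mb = seq(0.5, 8, length.out = n))
  dos <- matrix(rbinom(4 * n, 2, 0.4), 4, n)
  gm <- make_gm(dos, pos = sites_pos, category = cats, line = "l")
  st <- recombination_strata(gm$sites, map)
  hi <- filter_sites(gm, st$stratum == "high")
  prof_hi <- derived_count_profile(hi)
  manual <- rowSums(dos[, st$stratum == "high" &
                          cats == "synonymous_fourfold", drop = FALSE])
  expect_equal(prof_hi$count[prof_hi$category == "synonymous_fourfold"],
               unname(manual))
})

test_that("load comparison is exact under identity and detects planted effects", {
  p_same <- tibble::tibble(id = paste0("i", 1:4), line = "a",
                           category = "lof", count = c(5, 6, 7, 8))
  p_same$ratio <- 1; p_same$standardized <- c(1, 1.1, 0.9, 1)
  both <- dplyr::bind_rows(p_same,
                           dplyr::mutate(p_same, line = "b",
                                         id = paste0("j", 1:4)))
  r <- compare_load(both, "lof", focal = "a", reference = "b")
  expect_equal(r$estimate, 0)
  expect_equal(r$p, 1)
  # planted 30% lower focal burden, n = 12: direction recovered almost always
  set.seed(121)
  hits <- 0
  for (i in 1:100) {
    std <- tibble::tibble(
      line = rep(c("foc", "ref"), each = 12),
      id = paste0("i", 1:24),
      category = "lof",
      ratio = NA_real_,
      standardized = c(rnorm(12, 0.7, 0.15), rnorm(12, 1, 0.15))
    )
    r <- compare_load(std, "lof", focal = "foc", reference = "ref")
    if (r$estimate < 0) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("null splits give approximately uniform p values", {
  set.seed(131)
  ps <- vapply(1:200, function(i) {
    std <- tibble::tibble(
      line = rep(c("a", "b"), each = 8),
      id = paste0("i", 1:16),
      category = "missense",
      ratio = NA_real_,
      standardized = rnorm(16, 1, 0.2)
    )
    compare_load(std, "missense", focal = "a", reference = "b")$p
  }, numeric(1))
  expect_gt(mean(ps < 0.05), 0.0)
  expect_lt(mean(ps < 0.05), 0.12)
  expect_gt(mean(ps), 0.4)
  expect_lt(mean(ps), 0.6)
})
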