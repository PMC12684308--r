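test_that("pedigree inbreeding recovers classic identities", {
  ped <- tibble::tibble(
    id = 1:5,
    sire = c(NA, NA, 1, 1, 3),
    dam = c(NA, NA, 2, 2, 4)
  )
  expect_equal(pedigree_inbreeding(ped, 1), 0)
  expect_equal(pedigree_inbreeding(ped, 3), 0)
  # offspring of full sibs
  expect_equal(pedigree_inbreeding(ped, 5), 0.25)
  expect_equal(pedigree_kinship(ped, 3, 4), 0.25)
  expect_error(pedigree_inbreeding(ped, 99), "Unknown")
})

test_that("the inbred assay pedigree yields F = 0.25 at the egg generation", {
  # founders M (1), F (2); two full-sib pairs (3,4) and (5,6) from them;
  # within-pair matings give 7 and 8 (F = 0.25, the laying females);
  # the cousin mating 7 x 8 gives the eggs (9)
  ped <- tibble::tibble(
    id = 1:9,
    sire = c(NA, NA, 1, 1, 1, 1, 3, 5, 7),
    dam = c(NA, NA, 2, 2, 2, 2, 4, 6, 8)
  )
  expect_equal(pedigree_inbreeding(ped, 7), 0.25)
  expect_equal(pedigree_inbreeding(ped, 8), 0.25)
  expect_equal(pedigree_inbreeding(ped, 9), 0.25)
})

test_that("cyclic pedigrees are rejected", {
  ped <- tibble::tibble(id = c(1, 2), sire = c(2, 1), dam = c(4, 4))
  expect_error(pedigree_inbreeding(ped, 1), "cycle")
})

test_that("kinship matrix bookkeeping in the simulator matches the recursion", {
  cfg <- tiny_config()
  g <- build_genome(cfg, neutral_model(), seed = 3)
  set.seed(5)
  p <- found_population(g, 8)
  p$kin <- diag(0.5, 8)
  ped <- tibble::tibble(id = p$id, sire = NA_real_, dam = NA_real_)
  for (t in 1:5) {
    p2 <- advance_generation(p, "n8_vial", g, cfg)
    if (is_extinct(p2)) break
    par <- attr(p2, "parents")
    ped <- dplyr::bind_rows(ped, tibble::tibble(
      id = par$id, sire = as.numeric(par$sire), dam = as.numeric(par$dam)))
    expect_equal(p2$F, unname(pedigree_inbreeding(ped, par$id)),
                 tolerance = 1e-12)
    p <- p2
  }
})

test_that("Ne from offspring numbers predicts realized neutral inbreeding", {
  cfg <- tiny_config()
  g <- build_genome(cfg, neutral_model(), seed = 13)
  set.seed(99)
  TG <- 10
  f_obs <- c(); ne_est <- c()
  for (r in 1:25) {
    p <- found_population(g, 8)
    p$kin <- diag(0.5, 8)
    ped <- list(tibble::tibble(id = p$id, sire = NA_integer_,
                               dam = NA_integer_, sex = p$sex,
                               population = "x", generation = 0L))
    ok <- TRUE
    for (t in 1:TG) {
      p2 <- advance_generation(p, "n8_vial", g, cfg)
      if (is_extinct(p2)) { ok <- FALSE; break }
      par <- attr(p2, "parents")
      par$population <- "x"; par$generation <- t
      ped[[t + 1]] <- par
      p <- p2
    }
    if (!ok) next
    f_obs <- c(f_obs, mean(p$F))
    ne_est <- c(ne_est, estimate_ne(dplyr::bind_rows(ped), "x")$Ne)
  }
  ne <- 1 / mean(1 / ne_est)
  expected <- 1 - (1 - 1 / (2 * ne))^TG
  se <- sd(f_obs) / sqrt(length(f_obs))
  expect_lt(abs(mean(f_obs) - expected), 3 * se)
})
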