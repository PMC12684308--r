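#' Lay out the simulated genome
#'
#' Builds the genomic substrate used by [simulate_experiment()]: four
#' autosomal arms (2L, 2R, 3L, 3R) spanning `genome_length_bp` in total, a
#' 100-kb-bin recombination map, and a set of biallelic loci with positions,
#' annotation categories, selection and dominance coefficients, and initial
#' derived-allele frequencies.
#'
#' Neutral loci carry the annotation categories used by the load module
#' (intergenic, intronic, fourfold and other synonymous); deleterious loci
#' are labelled missense or missense_deleterious by effect size and the
#' lethal class is labelled lof. Initial frequencies of selected loci follow
#' the deterministic mutation-selection balance approximation (q = u/(hs), or
#' sqrt(u/s) when dominance is weak); neutral loci draw frequencies from the
#' 1/q equilibrium spectrum. The recombination map follows a smooth
#' arm-level profile (suppressed near arm ends, elevated mid-arm) with the
#' requested genome-wide mean, giving the rate variation needed for
#' recombination-quartile analyses.
#'
#' @param config An [experiment_config()].
#' @param model A [mutation_model()].
#' @param seed Integer seed for the layout draws.
#' @return An object of class `sim_genome` with fields `sites` (tibble:
#'   chrom, pos, category, s, h, cM_per_Mb), `map` (BED-like tibble), and
#'   internal selection/recombination vectors.
#' @export
build_genome <- function(config, model, seed = 1L) {
  with_seed(seed, {
    arm_frac <- c("2L" = 23, "2R" = 26, "3L" = 28, "3R" = 33) / 110
    arm_len_bp <- round(arm_frac * config$genome_length_bp)
    arms <- tibble(
      chrom = names(arm_frac),
      length_bp = as.numeric(arm_len_bp)
    )

    # 100-kb recombination map; mid-arm elevated, ends suppressed.
    map <- purrr::map_dfr(seq_len(nrow(arms)), function(a) {
      len <- arms$length_bp[a]
      starts <- seq(0, len - 1, by = 1e5)
      ends <- pmin(starts + 1e5, len)
      mid <- (starts + ends) / 2 / len
      rate <- config$mean_recomb_cM_per_Mb * 1.5 * 4 * mid * (1 - mid)
      tibble(chrom = arms$chrom[a], start = starts, end = ends,
             cM_per_Mb = rate)
    })

    n_neu <- config$n_neutral_loci
    n_del <- config$n_deleterious_loci
    n_let <- config$n_lethal_loci
    L <- n_neu + n_del + n_let

    chrom <- sample(arms$chrom, L, replace = TRUE, prob = arms$length_bp)
    pos <- vapply(chrom, function(cc) {
      sample.int(arms$length_bp[arms$chrom == cc], 1L)
    }, numeric(1))

    class_lab <- c(rep("neutral", n_neu), rep("deleterious", n_del),
                   rep("lethal", n_let))

    cat_neu <- sample(c("intergenic", "intronic", "synonymous_fourfold",
                        "synonymous_other"),
                      n_neu, replace = TRUE,
                      prob = c(0.40, 0.30, 0.15, 0.15))
    s <- numeric(L)
    h <- numeric(L)
    category <- character(L)
    category[class_lab == "neutral"] <- cat_neu
    if (n_del > 0) {
      s_del <- rgamma(n_del, shape = model$s_shape,
                      scale = model$s_mean / model$s_shape)
      s_del <- pmin(pmax(s_del, 1e-6), 1)
      s[class_lab == "deleterious"] <- s_del
      h[class_lab == "deleterious"] <- model$h_of_s(s_del)
      category[class_lab == "deleterious"] <-
        ifelse(s_del < 0.03, "missense", "missense_deleterious")
    }
    if (n_let > 0) {
      s[class_lab == "lethal"] <- 1
      h[class_lab == "lethal"] <- model$lethal_h
      category[class_lab == "lethal"] <- "lof"
    }

    # Initial derived-allele frequencies.
    q0 <- numeric(L)
    if (n_neu > 0) {
      qmin <- 0.005
      u <- runif(n_neu)
      q0[class_lab == "neutral"] <- pmin(qmin * (1 / qmin)^u, 0.95)
    }
    msb <- function(u_loc, s_loc, h_loc) {
      strong <- h_loc * s_loc > sqrt(u_loc * s_loc)
      q <- ifelse(strong, u_loc / (h_loc * s_loc), sqrt(u_loc / s_loc))
      pmin(q, 0.25)
    }
    if (n_del > 0) {
      u_del <- model$deleterious_rate / max(n_del, 1)
      idx <- class_lab == "deleterious"
      q0[idx] <- msb(u_del, s[idx], pmax(h[idx], 1e-4))
    }
    if (n_let > 0) {
      u_let <- model$lethal_rate / max(n_let, 1)
      idx <- class_lab == "lethal"
      q0[idx] <- msb(u_let, s[idx], pmax(h[idx], 1e-4))
    }

    ord <- order(match(chrom, arms$chrom), pos)
    chrom <- chrom[ord]; pos <- pos[ord]; s <- s[ord]; h <- h[ord]
    category <- category[ord]; q0 <- q0[ord]; class_lab <- class_lab[ord]

    arm_idx <- match(chrom, arms$chrom)
    # genetic position within arm (Morgans), integrating the bin map
    gpos <- numeric(L)
    rate_site <- numeric(L)
    for (a in seq_len(nrow(arms))) {
      m <- map[map$chrom == arms$chrom[a], ]
      cum_cM <- cumsum(m$cM_per_Mb * (m$end - m$start) / 1e6)
      cum0 <- c(0, head(cum_cM, -1))
      here <- which(arm_idx == a)
      if (!length(here)) next
      bin <- findInterval(pos[here] - 1, m$start)
      rate_site[here] <- m$cM_per_Mb[bin]
      gpos[here] <- (cum0[bin] +
                       (pos[here] - m$start[bin]) / 1e6 * m$cM_per_Mb[bin]) / 100
    }
    arm_len_M <- vapply(seq_len(nrow(arms)), function(a) {
      m <- map[map$chrom == arms$chrom[a], ]
      sum(m$cM_per_Mb * (m$end - m$start) / 1e6) / 100
    }, numeric(1))

    sites <- tibble(
      chrom = chrom, pos = as.integer(pos), category = category,
      s = s, h = h, cM_per_Mb = rate_site
    )

    structure(
      list(
        arms = arms,
        map = map,
        sites = sites,
        class_lab = class_lab,
        q0 = q0,
        arm_idx = as.integer(arm_idx),
        gpos = gpos,
        arm_len_M = arm_len_M,
        log_het = log1p(-pmin(h * s, 1 - 1e-12)),
        log_hom = log1p(-pmin(s, 1 - 1e-12)),
        del_idx = which(class_lab == "deleterious"),
        let_idx = which(class_lab == "lethal"),
        mu_del = model$deleterious_rate,
        mu_let = model$lethal_rate,
        adaptive = list(n = model$adaptive_loci, p0 = model$adaptive_p0,
                        s = model$adaptive_s, h = model$adaptive_h),
        L = L,
        genome_length_bp = config$genome_length_bp
      ),
      class = "sim_genome"
    )
  })
}

#' @export
print.sim_genome <- function(x, ...) {
  cat("<sim_genome>\n")
  cat(sprintf("  %d loci on %d arms (%.0f Mb); %d neutral, %d deleterious, %d lethal\n",
              x$L, nrow(x$arms), x$genome_length_bp / 1e6,
              sum(x$class_lab == "neutral"), sum(x$class_lab == "deleterious"),
              sum(x$class_lab == "lethal")))
  cat(sprintf("  map length %.2f Morgans; %d adaptive loci\n",
              sum(x$arm_len_M), x$adaptive$n))
  invisible(x)
}
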