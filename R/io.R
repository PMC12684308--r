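#' Genotype matrix container
#'
#' Holds polarized biallelic genotypes as derived-allele dosages (0, 1, 2,
#' `NA` for missing) for a set of individuals, together with per-site
#' metadata (chromosome, 1-based position, ancestral/derived alleles,
#' annotation category, local recombination rate) and per-individual
#' metadata.
#'
#' @param dosage Integer matrix, individuals x sites, values 0/1/2/NA.
#' @param sites Tibble with columns `chrom`, `pos` and optionally `anc`,
#'   `der`, `category`, `cM_per_Mb`. Positions must be strictly increasing
#'   within each chromosome.
#' @param individuals Tibble with columns `id` and optionally `line`; one
#'   row per dosage row.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, sites, individuals = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  sites <- as_tibble(sites)
  stopifnot(ncol(dosage) == nrow(sites))
  if (is.null(individuals)) {
    individuals <- tibble(id = rownames(dosage) %||%
                            paste0("ind_", seq_len(nrow(dosage))),
                          line = NA_character_)
  }
  individuals <- as_tibble(individuals)
  stopifnot(nrow(individuals) == nrow(dosage))
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L)) {
    abort("Dosages must be 0, 1, 2 or NA.")
  }
  for (cc in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == cc]
    if (is.unsorted(p, strictly = TRUE)) {
      abort(sprintf("Positions must be strictly increasing within %s.", cc))
    }
  }
  if (!"category" %in% names(sites)) sites$category <- NA_character_
  if (!"anc" %in% names(sites)) sites$anc <- "A"
  if (!"der" %in% names(sites)) sites$der <- "T"
  if (!"cM_per_Mb" %in% names(sites)) sites$cM_per_Mb <- NA_real_
  rownames(dosage) <- individuals$id
  structure(list(dosage = dosage, sites = sites, individuals = individuals),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d individuals x %d sites (%s)\n",
              nrow(x$dosage), ncol(x$dosage),
              paste(unique(x$sites$chrom), collapse = ", ")))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Tidy a genotype matrix into long form
#'
#' @param x A [genotype_matrix()].
#' @param ... Unused.
#' @return A tibble with one row per individual x site: `id`, `line`,
#'   `chrom`, `pos`, `category`, `dosage`.
#' @export
tidy.genotype_matrix <- function(x, ...) {
  tibble(
    id = rep(x$individuals$id, times = ncol(x$dosage)),
    line = rep(x$individuals$line, times = ncol(x$dosage)),
    chrom = rep(x$sites$chrom, each = nrow(x$dosage)),
    pos = rep(x$sites$pos, each = nrow(x$dosage)),
    category = rep(x$sites$category, each = nrow(x$dosage)),
    dosage = as.vector(x$dosage)
  )
}

#' Subset a genotype matrix by sites
#'
#' @param gm A [genotype_matrix()].
#' @param idx Logical or integer site index.
#' @return A `genotype_matrix` restricted to the selected sites.
#' @export
filter_sites <- function(gm, idx) {
  genotype_matrix(gm$dosage[, idx, drop = FALSE], gm$sites[idx, ],
                  gm$individuals)
}

#' Export genotypes of sampled males from a simulated population
#'
#' Samples `n_individuals` males and assembles their derived-allele dosages
#' over the simulated loci, mirroring the whole-genome-sequencing step of
#' the experiment. By default only sites carrying at least one derived
#' allele in the sample are emitted (a variant caller does not report
#' invariant reference sites).
#'
#' @param pop A `sim_population`.
#' @param n_individuals Number of males to sample.
#' @param genome The [build_genome()] layout the population evolved on.
#' @param line Line label stored with the individuals.
#' @param sites `"present"` (derived allele observed) or `"all"`.
#' @return A [genotype_matrix()].
#' @export
export_genotypes <- function(pop, n_individuals, genome, line = NA_character_,
                             sites = c("present", "all")) {
  sites <- match.arg(sites)
  males <- which(pop$sex == 1L)
  if (length(males) < n_individuals) {
    abort(sprintf("Population has %d males; %d requested.",
                  length(males), n_individuals))
  }
  take <- males[sample.int(length(males), n_individuals)]
  dos <- pop$h1[take, , drop = FALSE] + pop$h2[take, , drop = FALSE]
  keep <- if (sites == "present") colSums(dos) > 0L else rep(TRUE, ncol(dos))
  st <- genome$sites[keep, ]
  st$anc <- "A"
  st$der <- "T"
  genotype_matrix(
    dos[, keep, drop = FALSE],
    st[, c("chrom", "pos", "anc", "der", "category", "cM_per_Mb")],
    tibble(id = sprintf("%s_ind%02d", ifelse(is.na(line), "ind", line),
                        seq_len(n_individuals)),
           line = line)
  )
}

#' Write a genotype matrix as a polarized VCF
#'
#' Emits VCF v4.2 with GT-only genotype columns, REF = ancestral and ALT =
#' derived allele (the `AA` INFO tag is set to REF accordingly). Dosage 0 is
#' written `0/0`, 1 `0/1`, 2 `1/1`, missing `./.`.
#'
#' @param gm A [genotype_matrix()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(gm, path) {
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  n <- nrow(gm$dosage)
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$individuals$id), collapse = "\t")
  )
  gt <- matrix("./.", nrow = ncol(gm$dosage), ncol = n)
  for (d in 0:2) {
    gt[t(gm$dosage) == d] <- gt_code[[as.character(d)]]
  }
  body <- paste(
    gm$sites$chrom, gm$sites$pos, ".", gm$sites$anc, gm$sites$der, ".",
    "PASS", paste0("AA=", gm$sites$anc), "GT",
    apply(gt, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write the site annotation table
#'
#' Companion TSV to the VCF: chrom, 1-based pos, annotation category and
#' local recombination rate.
#'
#' @param gm A [genotype_matrix()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_site_annotation <- function(gm, path) {
  readr::write_tsv(
    gm$sites[, c("chrom", "pos", "category", "cM_per_Mb")],
    path
  )
  invisible(path)
}

#' Read a site annotation table
#' @param path TSV with columns chrom, pos, category, cM_per_Mb.
#' @return A tibble.
#' @export
read_site_annotation <- function(path) {
  readr::read_tsv(
    path, show_col_types = FALSE,
    col_types = readr::cols(chrom = readr::col_character(),
                            pos = readr::col_integer(),
                            category = readr::col_character(),
                            cM_per_Mb = readr::col_double())
  )
}

#' Write / read a BED-like recombination map
#'
#' BED convention: 0-based half-open 100-kb bins with a cM/Mb rate column.
#'
#' @param map Tibble with chrom, start, end, cM_per_Mb.
#' @param path File path.
#' @return `path` (write) or a tibble (read).
#' @export
write_recomb_map <- function(map, path) {
  readr::write_tsv(map, path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_recomb_map
#' @export
read_recomb_map <- function(path) {
  readr::read_tsv(
    path, col_names = c("chrom", "start", "end", "cM_per_Mb"),
    show_col_types = FALSE,
    col_types = readr::cols(chrom = readr::col_character(),
                            start = readr::col_double(),
                            end = readr::col_double(),
                            cM_per_Mb = readr::col_double())
  )
}

#' Site filter policy
#'
#' The SNP-level filters applied when loading genotypes: maximum missingness
#' per site, exclusion of monomorphic and multiallelic records (and of
#' non-SNP records). Depth and indel-proximity rules are optional and only
#' applied when the VCF carries the required fields.
#'
#' @param max_missing_fraction Sites with a larger fraction of missing
#'   genotypes are discarded (strictly greater than).
#' @param drop_monomorphic,drop_multiallelic Logical switches.
#' @param depth_sd_bound Optional: drop sites whose mean depth deviates from
#'   the average by more than this many SDs (needs a DP FORMAT field).
#' @return A `site_filter_policy` list.
#' @export
site_filter_policy <- function(max_missing_fraction = 0.15,
                               drop_monomorphic = TRUE,
                               drop_multiallelic = TRUE,
                               depth_sd_bound = NULL) {
  stopifnot(max_missing_fraction >= 0, max_missing_fraction <= 1)
  structure(list(max_missing_fraction = max_missing_fraction,
                 drop_monomorphic = drop_monomorphic,
                 drop_multiallelic = drop_multiallelic,
                 depth_sd_bound = depth_sd_bound),
            class = "site_filter_policy")
}

#' Load polarized genotypes from a VCF
#'
#' Reads a VCF (GT field required), applies the [site_filter_policy()] and
#' returns the genotype matrix plus a per-rule exclusion report. Genotypes
#' are converted to derived-allele dosages; polarization uses the `AA` INFO
#' tag when present, otherwise REF is taken as ancestral (the convention of
#' generator-written files). When `annotation` is supplied, categories and
#' recombination rates are joined onto the retained sites.
#'
#' @param path VCF file.
#' @param policy A [site_filter_policy()].
#' @param annotation Optional site annotation tibble or TSV path.
#' @param line Optional line label for the samples.
#' @return A list with `genotypes` (a [genotype_matrix()]) and `report`
#'   (tibble of rule, n_removed).
#' @export
load_genotypes <- function(path, policy = site_filter_policy(),
                           annotation = NULL, line = NA_character_) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (is.null(dim(v@gt)) || ncol(v@gt) < 2) {
    abort("VCF has no genotype columns.")
  }
  fmt <- v@gt[, 1]
  if (!all(grepl("GT", fmt))) abort("VCF records lack a GT field.")
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)

  n_in <- nrow(fix)
  keep <- rep(TRUE, n_in)
  report <- list()
  note <- function(rule, removed) {
    report[[length(report) + 1L]] <<- tibble(rule = rule,
                                             n_removed = sum(removed))
  }

  is_snp <- nchar(fix$REF) == 1 & nchar(gsub(",.*", "", fix$ALT %||% "")) == 1 &
    !is.na(fix$ALT) & fix$ALT != "."
  multi <- grepl(",", fix$ALT %||% "")
  if (policy$drop_multiallelic) {
    rm1 <- keep & (multi | !is_snp)
    note("multiallelic_or_not_snp", rm1)
    keep <- keep & !rm1
  }

  gt_clean <- gsub("\\|", "/", gt)
  dos_code <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  dos <- matrix(dos_code[gt_clean], nrow = nrow(gt), ncol = ncol(gt))
  miss_frac <- rowMeans(is.na(dos))
  rm2 <- keep & miss_frac > policy$max_missing_fraction
  note("missingness", rm2)
  keep <- keep & !rm2

  if (policy$drop_monomorphic) {
    # monomorphic = only one allele observed (all hom-ref or all hom-alt)
    mono <- apply(dos, 1, function(r) {
      r <- r[!is.na(r)]
      length(r) == 0L || all(r == 0L) || all(r == 2L)
    })
    rm3 <- keep & mono
    note("monomorphic", rm3)
    keep <- keep & !rm3
  }

  if (!is.null(policy$depth_sd_bound) && "DP" %in%
      unlist(strsplit(fmt[1], ":"))) {
    dp <- suppressWarnings(
      apply(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE), 1,
            mean, na.rm = TRUE))
    mu <- mean(dp[keep], na.rm = TRUE); sdv <- sd(dp[keep], na.rm = TRUE)
    rm4 <- keep & abs(dp - mu) > policy$depth_sd_bound * sdv & !is.na(dp)
    note("depth", rm4)
    keep <- keep & !rm4
  }

  fixk <- fix[keep, , drop = FALSE]
  dosk <- dos[keep, , drop = FALSE]

  aa <- stringr::str_match(fixk$INFO %||% "", "AA=([^;]+)")[, 2]
  anc <- ifelse(is.na(aa), fixk$REF, aa)
  flip <- anc == fixk$ALT
  if (any(flip, na.rm = TRUE)) {
    dosk[which(flip), ] <- 2L - dosk[which(flip), ]
  }
  der <- ifelse(flip, fixk$REF, fixk$ALT)

  sites <- tibble(
    chrom = fixk$CHROM, pos = as.integer(fixk$POS),
    anc = ifelse(flip, fixk$ALT, fixk$REF), der = der
  )
  if (!is.null(annotation)) {
    ann <- if (is.character(annotation)) read_site_annotation(annotation) else annotation
    sites <- left_join(sites, ann, by = c("chrom", "pos"))
  }
  gm <- genotype_matrix(t(dosk), sites,
                        tibble(id = samples, line = line))
  list(genotypes = gm, report = bind_rows(report))
}

#' Write productivity or survival tables
#'
#' Thin CSV writers/readers with the column conventions used throughout the
#' package.
#'
#' @param x A tibble.
#' @param path File path.
#' @return `path` (write) or a tibble (read).
#' @export
write_productivity_csv <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname write_productivity_csv
#' @export
read_productivity_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname write_productivity_csv
#' @export
write_survival_csv <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname write_productivity_csv
#' @export
read_survival_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
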