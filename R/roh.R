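#' Parameters for runs-of-homozygosity calling
#'
#' Sliding-window ROH detection parameters. The defaults mirror the
#' analysis settings used on the sequenced lines: a 30-SNP scanning window
#' with threshold 0.05, 100-kb minimum length, at least 1 SNP per 50 kb,
#' maximum internal gap 50 kb, and one heterozygote / five missing calls
#' tolerated per window. `min_snps` is the false-positive-controlled
#' minimum SNP count from [min_roh_snps()]; leave `NULL` to compute it from
#' the data at call time.
#'
#' Named presets expose the alternative settings used for sensitivity
#' analysis: `"density200"` (1 SNP per 200 kb), `"gap200"` (200-kb gap),
#' `"window60"` (60-SNP window) and `"threshold001"` (threshold 0.01).
#'
#' @param alpha False-positive proportion for the minimum-SNP rule.
#' @param window_snps Scanning window size in SNPs.
#' @param window_threshold Minimum fraction of homozygous windows covering
#'   a SNP for it to be run-eligible.
#' @param min_length_bp Minimum segment length.
#' @param min_density_bp Minimum density: one SNP per this many bp.
#' @param max_gap_bp Maximum gap between consecutive SNPs inside a run.
#' @param window_het_allowance,window_missing_allowance Heterozygous and
#'   missing calls tolerated in a homozygous window.
#' @param min_snps Minimum SNPs per segment, or `NULL` to derive it.
#' @return A `roh_params` list.
#' @export
roh_params <- function(alpha = 0.05,
                       window_snps = 30,
                       window_threshold = 0.05,
                       min_length_bp = 100000,
                       min_density_bp = 50000,
                       max_gap_bp = 50000,
                       window_het_allowance = 1,
                       window_missing_allowance = 5,
                       min_snps = NULL) {
  stopifnot(alpha > 0, alpha < 1, window_snps >= 2, min_length_bp > 0,
            min_density_bp > 0, max_gap_bp > 0)
  structure(
    list(alpha = alpha, window_snps = window_snps,
         window_threshold = window_threshold, min_length_bp = min_length_bp,
         min_density_bp = min_density_bp, max_gap_bp = max_gap_bp,
         window_het_allowance = window_het_allowance,
         window_missing_allowance = window_missing_allowance,
         min_snps = min_snps),
    class = "roh_params"
  )
}

#' @rdname roh_params
#' @param preset One of "default", "density200", "gap200", "window60",
#'   "threshold001".
#' @param ... Further overrides passed to [roh_params()].
#' @export
roh_preset <- function(preset = c("default", "density200", "gap200",
                                  "window60", "threshold001"), ...) {
  preset <- match.arg(preset)
  args <- switch(preset,
    default = list(),
    density200 = list(min_density_bp = 200000),
    gap200 = list(max_gap_bp = 200000),
    window60 = list(window_snps = 60),
    threshold001 = list(window_threshold = 0.01)
  )
  do.call(roh_params, utils::modifyList(args, list(...)))
}

#' Minimum SNP count for a ROH at a controlled false-positive rate
#'
#' The minimum number of consecutive homozygous SNPs required so that the
#' expected number of chance runs across the dataset stays below `alpha`:
#' `l = ceil( ln(alpha / (n_snps * n_individuals)) / ln(1 - mean_het) )`,
#' where `mean_het` is the mean per-SNP heterozygosity.
#'
#' @param n_snps_total SNPs in the dataset.
#' @param n_individuals Individuals scanned.
#' @param mean_het Mean heterozygosity per SNP, strictly inside (0, 1).
#' @param alpha Tolerated false-positive proportion.
#' @return Integer minimum SNP count.
#' @examples
#' min_roh_snps(1000, 1, 0.5, 0.05) # 15
#' @export
min_roh_snps <- function(n_snps_total, n_individuals, mean_het,
                         alpha = 0.05) {
  if (mean_het <= 0 || mean_het >= 1) {
    abort("`mean_het` must lie strictly between 0 and 1.")
  }
  stopifnot(n_snps_total >= 1, n_individuals >= 1, alpha > 0, alpha < 1)
  as.integer(ceiling(log(alpha / (n_snps_total * n_individuals)) /
                       log(1 - mean_het)))
}

# window homozygosity + per-SNP hit rates for one chromosome
roh_eligible_snps <- function(geno, params) {
  m <- length(geno)
  W <- params$window_snps
  if (m < W) return(rep(FALSE, m))
  het <- as.integer(!is.na(geno) & geno == 1L)
  mis <- as.integer(is.na(geno))
  csum <- function(x, W) {
    cs <- cumsum(x)
    cs[W:length(x)] - c(0, cs)[seq_len(length(x) - W + 1)]
  }
  hom_win <- csum(het, W) <= params$window_het_allowance &
    csum(mis, W) <= params$window_missing_allowance
  n_win <- m - W + 1L
  cw <- c(0, cumsum(hom_win))
  i <- seq_len(m)
  lo <- pmax(1L, i - W + 1L)
  hi <- pmin(i, n_win)
  hits <- cw[hi + 1L] - cw[lo]
  denom <- hi - lo + 1L
  hits / denom >= params$window_threshold
}

#' Call runs of homozygosity
#'
#' Sliding-window ROH detection: windows of `window_snps` consecutive SNPs
#' are classified homozygous when they contain at most the allowed numbers
#' of heterozygous and missing calls; each SNP's hit rate is the fraction
#' of windows covering it that are homozygous, and SNPs at or above
#' `window_threshold` are run-eligible. Maximal runs of eligible SNPs are
#' split at gaps larger than `max_gap_bp` and then filtered by `min_snps`,
#' `min_length_bp` and the SNP density rule; surviving runs are bounded by
#' their first and last SNP (1-based inclusive).
#'
#' When `params$min_snps` is `NULL` it is computed with [min_roh_snps()]
#' from the dataset size and the observed mean heterozygosity.
#'
#' @param gm A [genotype_matrix()] with sites sorted by chromosome and
#'   position.
#' @param individual Optional id (default: all individuals).
#' @param params A [roh_params()].
#' @return A tibble of segments: `individual`, `chrom`, `start`, `end`,
#'   `n_snps`, `length_bp`.
#' @export
call_roh <- function(gm, individual = NULL, params = roh_params()) {
  ids <- if (is.null(individual)) gm$individuals$id else individual
  if (!all(ids %in% gm$individuals$id)) abort("Unknown individual id.")
  min_snps <- params$min_snps
  if (is.null(min_snps)) {
    dos <- gm$dosage
    mh <- mean(dos == 1L, na.rm = TRUE)
    mh <- min(max(mh, 1e-6), 1 - 1e-6)
    min_snps <- min_roh_snps(ncol(dos), nrow(dos), mh, params$alpha)
  }
  out <- list()
  for (id in ids) {
    r <- match(id, gm$individuals$id)
    for (cc in unique(gm$sites$chrom)) {
      sel <- which(gm$sites$chrom == cc)
      pos <- gm$sites$pos[sel]
      geno <- gm$dosage[r, sel]
      elig <- roh_eligible_snps(geno, params)
      if (!any(elig)) next
      runs <- rle(elig)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      for (k in which(runs$values)) {
        idx <- seq.int(starts[k], ends[k])
        gaps <- which(diff(pos[idx]) > params$max_gap_bp)
        piece_start <- c(1L, gaps + 1L)
        piece_end <- c(gaps, length(idx))
        for (p in seq_along(piece_start)) {
          pi_idx <- idx[seq.int(piece_start[p], piece_end[p])]
          n_snps <- length(pi_idx)
          len <- pos[pi_idx[n_snps]] - pos[pi_idx[1]] + 1L
          if (n_snps < min_snps) next
          if (len < params$min_length_bp) next
          if (n_snps * params$min_density_bp < len) next
          out[[length(out) + 1L]] <- tibble(
            individual = id, chrom = cc,
            start = pos[pi_idx[1]], end = pos[pi_idx[n_snps]],
            n_snps = n_snps, length_bp = len
          )
        }
      }
    }
  }
  if (!length(out)) {
    return(tibble(individual = character(), chrom = character(),
                  start = integer(), end = integer(), n_snps = integer(),
                  length_bp = integer()))
  }
  bind_rows(out)
}

#' Genomic inbreeding coefficient from ROH
#'
#' `F_ROH` is the summed ROH length of an individual divided by the
#' analysed autosomal genome length (110 Mb by default). Overlapping
#' segments within an individual are an error.
#'
#' @param segments ROH tibble from [call_roh()].
#' @param genome_length_bp Analysed genome length.
#' @return A tibble with `individual` and `f_roh` (empty input gives an
#'   empty tibble; individuals with no segments that appear in `segments`
#'   are not invented).
#' @export
f_roh <- function(segments, genome_length_bp = 110e6) {
  if (!nrow(segments)) {
    return(tibble(individual = character(), f_roh = numeric()))
  }
  overlaps <- segments |>
    group_by(.data$individual, .data$chrom) |>
    arrange(.data$start, .by_group = TRUE) |>
    summarise(ov = if (n() < 2) FALSE else any(.data$start[-1] <= head(.data$end, -1)),
              .groups = "drop")
  if (any(overlaps$ov)) abort("Overlapping ROH segments within an individual.")
  segments |>
    group_by(.data$individual) |>
    summarise(f_roh = sum(.data$length_bp) / genome_length_bp,
              .groups = "drop")
}

#' ROH length classes and histogram
#'
#' Counts of short (< `boundary_bp`) and long (>= `boundary_bp`) segments
#' plus a binned length histogram.
#'
#' @param segments ROH tibble from [call_roh()].
#' @param boundary_bp Short/long boundary (default 1.5 Mb).
#' @param bin_width_bp Histogram bin width.
#' @return A list with `counts` (tibble: n_short, n_long) and `histogram`
#'   (tibble: bin_start, bin_end, n).
#' @export
roh_length_classes <- function(segments, boundary_bp = 1.5e6,
                               bin_width_bp = 250000) {
  if (!nrow(segments)) {
    return(list(
      counts = tibble(n_short = 0L, n_long = 0L),
      histogram = tibble(bin_start = numeric(), bin_end = numeric(),
                         n = integer())
    ))
  }
  counts <- tibble(
    n_short = sum(segments$length_bp < boundary_bp),
    n_long = sum(segments$length_bp >= boundary_bp)
  )
  bin <- floor(segments$length_bp / bin_width_bp)
  hist <- tibble(bin = bin) |>
    count(.data$bin) |>
    mutate(bin_start = .data$bin * bin_width_bp,
           bin_end = (.data$bin + 1) * bin_width_bp) |>
    select("bin_start", "bin_end", "n")
  list(counts = counts, histogram = hist)
}
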