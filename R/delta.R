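#' Inbreeding depression rate from productivity records
#'
#' Estimates the inbreeding depression rate `delta = ln(P_O / P_I) / F`,
#' where `P_O` and `P_I` are the mean pupae productivities of the outbred
#' and inbred assay schemes and `F` is the design inbreeding coefficient of
#' the inbred scheme (0.25 for full-sib derived eggs). `delta` expresses the
#' proportional decline of the trait mean per unit inbreeding; multiplied by
#' 100 it is the percent reduction per 0.01 of F. When `n_boot` is given, a
#' bootstrap standard error is attached (see [bootstrap_delta_se()]).
#'
#' @param outbred,inbred Productivity records: tibbles with a `pupae_count`
#'   column (as produced by [assay_pairs()]) or bare numeric vectors.
#' @param F Design inbreeding coefficient contrast between the schemes.
#' @param n_boot Optional number of bootstrap replicates for the SE.
#' @param seed Seed for the bootstrap.
#' @return A `delta_estimate` object; see [tidy.delta_estimate()].
#' @examples
#' estimate_delta(rep(90.60, 4), rep(55.09, 4), F = 0.25)
#' @export
estimate_delta <- function(outbred, inbred, F = 0.25, n_boot = NULL,
                           seed = 1L) {
  xo <- pupae_values(outbred)
  xi <- pupae_values(inbred)
  if (!length(xo) || !length(xi)) abort("Both record sets must be non-empty.")
  if (F <= 0) abort("`F` must be positive.")
  P_O <- mean(xo)
  P_I <- mean(xi)
  if (P_O <= 0 || P_I <= 0) {
    abort("delta is undefined when a scheme mean is not positive.")
  }
  est <- structure(
    list(P_O = P_O, P_I = P_I, F = F,
         delta = delta_from_means(P_O, P_I, F),
         se = NA_real_, n_outbred = length(xo), n_inbred = length(xi),
         n_boot = NA_integer_, n_redraws = 0L),
    class = "delta_estimate"
  )
  if (!is.null(n_boot)) {
    bs <- bootstrap_delta_se(xo, xi, F, n_boot = n_boot, seed = seed)
    est$se <- bs
    est$n_boot <- as.integer(n_boot)
    est$n_redraws <- attr(bs, "n_redraws")
  }
  est
}

#' @rdname estimate_delta
#' @param P_O,P_I Scheme means (e.g. published summary values).
#' @export
delta_from_means <- function(P_O, P_I, F = 0.25) {
  if (any(P_O <= 0) || any(P_I <= 0)) {
    abort("delta is undefined for non-positive means.")
  }
  if (any(F <= 0)) abort("`F` must be positive.")
  log(P_O / P_I) / F
}

pupae_values <- function(x) {
  if (is.data.frame(x)) {
    stopifnot("pupae_count" %in% names(x))
    as.numeric(x$pupae_count)
  } else {
    as.numeric(x)
  }
}

#' Bootstrap standard error of the depression rate
#'
#' Resamples the outbred and inbred vials independently, with replacement
#' and at their original sizes, recomputes delta for each of `n_boot`
#' replicates and returns the standard deviation of the replicate values.
#' Replicates in which a resampled scheme mean is not positive (possible
#' when records contain zeros) are redrawn; the number of redraws is
#' attached as an attribute.
#'
#' @inheritParams estimate_delta
#' @param n_boot Number of bootstrap replicates.
#' @return The bootstrap SE with attribute `n_redraws`.
#' @export
bootstrap_delta_se <- function(outbred, inbred, F = 0.25, n_boot = 1000,
                               seed = 1L) {
  if (n_boot < 2) abort("`n_boot` must be at least 2.")
  xo <- pupae_values(outbred)
  xi <- pupae_values(inbred)
  if (!length(xo) || !length(xi)) abort("Both record sets must be non-empty.")
  with_seed(seed, {
    reps <- numeric(n_boot)
    redraws <- 0L
    for (b in seq_len(n_boot)) {
      repeat {
        mo <- mean(sample(xo, length(xo), replace = TRUE))
        mi <- mean(sample(xi, length(xi), replace = TRUE))
        if (mo > 0 && mi > 0) break
        redraws <- redraws + 1L
        if (redraws > 100L * n_boot) {
          abort("Bootstrap cannot find resamples with positive means.")
        }
      }
      reps[b] <- log(mo / mi) / F
    }
    if (redraws > 0) {
      inform(sprintf("bootstrap_delta_se: %d resamples redrawn (non-positive mean).",
                     redraws))
    }
    structure(sd(reps), n_redraws = redraws)
  })
}

#' @export
print.delta_estimate <- function(x, ...) {
  cat(sprintf("delta = %.3f%s  (P_O = %.2f, n = %d; P_I = %.2f, n = %d; F = %.2f)\n",
              x$delta,
              if (is.na(x$se)) "" else sprintf(" +/- %.3f", x$se),
              x$P_O, x$n_outbred, x$P_I, x$n_inbred, x$F))
  invisible(x)
}

#' Tidy methods for depression-rate estimates
#'
#' @param x A `delta_estimate`.
#' @param ... Unused.
#' @return `tidy()` returns a one-row tibble with `estimate` and
#'   `std.error`; `glance()` adds the scheme means and sizes.
#' @export
tidy.delta_estimate <- function(x, ...) {
  tibble(term = "delta", estimate = x$delta, std.error = x$se)
}

#' @rdname tidy.delta_estimate
#' @export
glance.delta_estimate <- function(x, ...) {
  tibble(delta = x$delta, se = x$se, P_O = x$P_O, P_I = x$P_I, F = x$F,
         n_outbred = x$n_outbred, n_inbred = x$n_inbred, n_boot = x$n_boot)
}

#' Expected inbreeding under drift
#'
#' Closed-form expected inbreeding coefficient after `t` generations at
#' effective size `Ne`: `F_t = 1 - (1 - 1/(2 Ne))^t`, and the corresponding
#' expected relative fitness `exp(-delta * F_t)` when a depression rate is
#' supplied.
#'
#' @param Ne Effective population size (>= 1).
#' @param t Generations (vectorised).
#' @param delta Optional depression rate for the fitness column.
#' @return A tibble with `Ne`, `t`, `F_t` and (optionally) `w_rel`.
#' @examples
#' expected_inbreeding(25, c(1, 13))
#' @export
expected_inbreeding <- function(Ne, t, delta = NULL) {
  if (any(Ne < 1)) abort("`Ne` must be at least 1.")
  if (any(t < 0)) abort("`t` must be non-negative.")
  out <- tibble(Ne = Ne, t = t, F_t = 1 - (1 - 1 / (2 * Ne))^t)
  if (!is.null(delta)) out$w_rel <- exp(-delta * out$F_t)
  out
}

#' Relative productivity decline between two evaluation periods
#'
#' Arithmetic of the focal-versus-reference productivity comparison: the
#' early decline `1 - P_focal_early / P_ref_early`, the additional (net)
#' decline between the early and late evaluations
#' `P_focal_early / P_ref_early - P_focal_late / P_ref_late`, their ratio
#' (also as a percentage), the late relative productivity of the focal
#' populations, and the growth of the reference mean between the periods.
#'
#' @param P_focal_early,P_ref_early,P_focal_late,P_ref_late Scheme means.
#' @return A one-row tibble with `decline_early`, `decline_late_net`,
#'   `ratio`, `ratio_pct`, `rel_late` (focal/reference at the late point),
#'   `rel_late_pct`, `ref_increase` and `ref_increase_pct`.
#' @examples
#' relative_decline(67.18, 69.18, 65.58, 90.60)
#' @export
relative_decline <- function(P_focal_early, P_ref_early, P_focal_late,
                             P_ref_late) {
  if (P_ref_early <= 0 || P_ref_late <= 0) {
    abort("Reference means must be positive.")
  }
  early <- 1 - P_focal_early / P_ref_early
  late_net <- P_focal_early / P_ref_early - P_focal_late / P_ref_late
  ratio <- if (early == 0) {
    if (late_net == 0) NA_real_ else abort("Ratio undefined: early decline is zero.")
  } else {
    late_net / early
  }
  rel_late <- P_focal_late / P_ref_late
  ref_incr <- P_ref_late / P_ref_early - 1
  tibble(
    decline_early = early,
    decline_late_net = late_net,
    ratio = ratio,
    ratio_pct = 100 * ratio,
    rel_late = rel_late,
    rel_late_pct = 100 * rel_late,
    ref_increase = ref_incr,
    ref_increase_pct = 100 * ref_incr
  )
}

#' Two-sided Mann-Whitney test
#'
#' Nonparametric comparison of two samples of line or vial means. The exact
#' null distribution is enumerated when both samples are small
#' (`min(n, m) <= 8`) and tie-free; otherwise the normal approximation with
#' tie and continuity corrections is used.
#'
#' @param x,y Numeric samples.
#' @return A one-row tibble with the `U` statistic (for `x`), the two-sided
#'   `p` value and the method used.
#' @export
mann_whitney_two_sided <- function(x, y) {
  if (!length(x) || !length(y)) abort("Samples must be non-empty.")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- min(length(x), length(y)) <= 8 && !ties
  res <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = TRUE)
  )
  tibble(U = unname(res$statistic), p = res$p.value,
         method = if (exact) "exact" else "normal_approx")
}

#' Generate synthetic productivity assay records
#'
#' Draws vial records from the productivity model used by the simulator:
#' each vial's expected count is the scheme mean times mean-centred
#' lognormal vial noise, and the observed pupae count is Poisson. The
#' inbred-scheme mean is `mean_outbred * exp(-delta * F)`.
#'
#' @param n_outbred,n_inbred Vials per scheme.
#' @param mean_outbred Outbred-scheme expected mean.
#' @param delta True inbreeding depression rate.
#' @param F Design inbreeding coefficient.
#' @param noise_sd Lognormal vial noise SD (log scale).
#' @param seed Seed.
#' @return A tibble of productivity records for both schemes.
#' @export
simulate_productivity <- function(n_outbred, n_inbred, mean_outbred = 90,
                                  delta = 1.99, F = 0.25, noise_sd = 0.3,
                                  seed = 1L) {
  with_seed(seed, {
    draw <- function(n, mu, scheme, dF) {
      lambda <- mu * rlnorm(n, -noise_sd^2 / 2, noise_sd)
      tibble(population_id = "synthetic", scheme = scheme,
             vial_id = seq_len(n), pupae_count = rpois(n, lambda),
             design_F = dF)
    }
    bind_rows(
      draw(n_outbred, mean_outbred, "outbred", 0),
      draw(n_inbred, mean_outbred * exp(-delta * F), "inbred", F)
    )
  })
}
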