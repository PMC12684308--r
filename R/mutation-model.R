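#' Mutation model for the forward simulator
#'
#' Defines the deleterious, lethal and lab-adaptation mutation classes used by
#' [simulate_experiment()]. Selection coefficients of segregating deleterious
#' mutations follow a gamma distribution truncated to (0, 1]; dominance
#' declines with severity via `h_of_s`, so mild mutations are nearly additive
#' while severe ones are close to fully recessive — the regime under which an
#' inbreeding load accumulates in heterozygotes and purging under slow
#' inbreeding is possible. A separate lethal class (s = 1, small h) carries
#' most of the load expressed under fast inbreeding. Lab-adaptation loci are
#' beneficial alleles, rare at capture, that respond to selection in the
#' laboratory environment throughout the experiment.
#'
#' Defaults follow standard Drosophila mutation-parameter magnitudes: a
#' genomic deleterious rate of 0.2 per gamete per generation with mean s =
#' 0.05 and gamma shape 0.33, `h(s) = 0.5 exp(-13 s)`, and a lethal rate of
#' 0.015 per gamete.
#'
#' @param deleterious_rate Mean new deleterious mutations per gamete per
#'   generation.
#' @param s_shape,s_mean Gamma shape and mean of the selection coefficient of
#'   deleterious mutations; draws are truncated to (0, 1].
#' @param h_of_s Function mapping s to the dominance coefficient in \[0, 0.5].
#' @param lethal_rate Per-gamete rate of recessive lethals (s = 1).
#' @param lethal_h Dominance of the lethal class.
#' @param adaptive_loci Number of unlinked lab-adaptation loci.
#' @param adaptive_p0 Initial frequency of each beneficial allele.
#' @param adaptive_s,adaptive_h Selective advantage and dominance of the
#'   beneficial alleles.
#' @return An object of class `mutation_model`.
#' @examples
#' m <- mutation_model()
#' m$h_of_s(0.05)
#' @export
mutation_model <- function(deleterious_rate = 0.2,
                           s_shape = 0.33,
                           s_mean = 0.05,
                           h_of_s = function(s) 0.5 * exp(-13 * s),
                           lethal_rate = 0.015,
                           lethal_h = 0.02,
                           adaptive_loci = 50,
                           adaptive_p0 = 0.02,
                           adaptive_s = 0.1,
                           adaptive_h = 0.5) {
  stopifnot(deleterious_rate >= 0, lethal_rate >= 0, s_shape > 0, s_mean > 0,
            adaptive_loci >= 0)
  if (adaptive_loci > 0 && (adaptive_p0 <= 0 || adaptive_p0 >= 1)) {
    abort("`adaptive_p0` must lie in (0, 1).")
  }
  h_test <- h_of_s(c(0.001, 0.05, 1))
  if (any(h_test < 0 | h_test > 0.5)) {
    abort("`h_of_s` must return dominance values in [0, 0.5].")
  }
  structure(
    list(
      deleterious_rate = deleterious_rate,
      s_shape = s_shape,
      s_mean = s_mean,
      h_of_s = h_of_s,
      lethal_rate = lethal_rate,
      lethal_h = lethal_h,
      adaptive_loci = adaptive_loci,
      adaptive_p0 = adaptive_p0,
      adaptive_s = adaptive_s,
      adaptive_h = adaptive_h
    ),
    class = "mutation_model"
  )
}

#' Neutral mutation model
#'
#' All selected classes switched off; useful for checking the simulator's
#' drift behaviour against closed-form expectations.
#'
#' @return A `mutation_model` with zero mutation rates and no adaptive loci.
#' @export
neutral_model <- function() {
  mutation_model(deleterious_rate = 0, lethal_rate = 0, adaptive_loci = 0)
}

#' @export
print.mutation_model <- function(x, ...) {
  cat("<mutation_model>\n")
  cat(sprintf("  deleterious: rate %.3g/gamete, s ~ Gamma(shape %.3g, mean %.3g)\n",
              x$deleterious_rate, x$s_shape, x$s_mean))
  cat(sprintf("  lethal:      rate %.3g/gamete (s = 1, h = %.3g)\n",
              x$lethal_rate, x$lethal_h))
  cat(sprintf("  adaptive:    %d loci, p0 = %.3g, s = %.3g, h = %.3g\n",
              x$adaptive_loci, x$adaptive_p0, x$adaptive_s, x$adaptive_h))
  invisible(x)
}
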