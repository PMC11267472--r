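#' Define a liability-scale trait model over a founder panel
#'
#' Mating propensity is modelled as a standard liability: a polygenic score
#' over `n_causal` causal variants plus Gaussian environmental noise, with
#' additive effects rescaled so the expected genetic variance (under
#' Hardy-Weinberg at the founder allele frequencies) is `h2` and the
#' environmental variance is `1 - h2`, giving unit total variance.
#' The liability maps to a per-minute per-pair mating hazard through a
#' bounded logistic link (see [liability_hazard()]).
#'
#' @param panel A `founder_panel`.
#' @param n_causal Number of causal variants.
#' @param h2 Target genetic variance fraction on the liability scale.
#' @param hazard_max Upper bound of the per-minute per-pair mating hazard.
#' @param hazard_intercept,hazard_slope Logistic link coefficients from
#'   liability to the fraction of `hazard_max` realised.  The defaults are
#'   calibrated so an outbred cohort assayed in vials of 10 males and 5
#'   tester females mates about a third of the females within an hour,
#'   while latency ranks carry a usable share of the liability signal.
#' @param freq_range Founder-frequency window causal variants are drawn
#'   from (keeps causal variants segregating in the intercross).
#' @param effects "normal" draws effects from a Gaussian (a polygenic
#'   spectrum with many near-zero effects); "equal" gives every causal
#'   variant the same |effect| with random sign (a few-loci architecture
#'   of uniformly large effects).
#' @param seed Optional RNG seed.
#' @return A `trait_model`: causal variant indices, effects, variances and
#'   hazard-link parameters.
#' @export
trait_model <- function(panel, n_causal = 20, h2 = 0.27,
                        hazard_max = 0.004, hazard_intercept = -2,
                        hazard_slope = 3, freq_range = c(0.15, 0.85),
                        effects = c("normal", "equal"), seed = NULL) {
  effects <- match.arg(effects)
  if (h2 < 0 || h2 >= 1) stop("h2 must lie in [0, 1)")
  p <- colMeans(panel$genotypes) / 2
  eligible <- which(p >= freq_range[1] & p <= freq_range[2])
  if (length(eligible) < n_causal)
    stop("not enough segregating variants in freq_range for n_causal")
  with_seed(seed, {
    causal <- sort(sample(eligible, n_causal))
    beta <- if (effects == "equal")
      sample(c(-1, 1), n_causal, replace = TRUE)
    else rnorm(n_causal)
    vg_raw <- sum(beta^2 * 2 * p[causal] * (1 - p[causal]))
    if (h2 > 0 && vg_raw > 0) beta <- beta * sqrt(h2 / vg_raw)
    if (h2 == 0) beta <- beta * 0
    structure(list(causal = causal, beta = beta, p_founder = p[causal],
                   var_g = h2, var_e = 1 - h2,
                   hazard_max = hazard_max,
                   hazard_intercept = hazard_intercept,
                   hazard_slope = hazard_slope),
              class = "trait_model")
  })
}

#' Mating liabilities of a simulated cohort
#'
#' Genetic value (centred polygenic score) plus independent Gaussian
#' environmental noise with variance `model$var_e`.
#'
#' @param pop A `population`.
#' @param panel The originating `founder_panel`.
#' @param model A `trait_model`.
#' @param seed Optional RNG seed (environmental draw).
#' @return Numeric vector with attribute `"genetic"` holding the genetic
#'   values.
#' @export
mating_liability <- function(pop, panel, model, seed = NULL) {
  D <- population_dosage(pop, panel, model$causal)
  g <- drop(sweep(D, 2, 2 * model$p_founder) %*% model$beta)
  with_seed(seed, {
    lia <- g + rnorm(length(g), 0, sqrt(model$var_e))
    attr(lia, "genetic") <- g
    lia
  })
}

#' Map liabilities to per-minute mating hazards
#'
#' `hazard_max * plogis(intercept + slope * liability)`: monotone in the
#' liability and bounded in (0, hazard_max).
#'
#' @param liability Numeric vector.
#' @param model A `trait_model` (only the hazard-link fields are used).
#' @return Per-minute per-pair hazard rates.
#' @export
liability_hazard <- function(liability, model) {
  model$hazard_max *
    stats::plogis(model$hazard_intercept + model$hazard_slope * liability)
}
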