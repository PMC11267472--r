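#' Simulate replicate-level line mating phenotypes
#'
#' Generates a one-way random-effects phenotype table on the proportion
#' scale: line effects are Normal(0, h2 * sd_total^2), replicate residuals
#' Normal(0, (1 - h2) * sd_total^2), so the intraclass correlation on the
#' modelled (un-truncated) scale equals `h2_target`.  Replicate proportions
#' are clamped to [0, 1] and discretised to `n_mated` out of `n_females`
#' females, mirroring how assay data arrive.  With the default grand mean
#' (0.05, a strongly discriminating tester at 2 h) the clamp at zero is
#' active, so realised heritability on the recorded scale sits below the
#' target; parameter-recovery work should place the grand mean mid-scale
#' and use a fine assay (large `n_females`) so the Gaussian model holds.
#'
#' @param n_lines Number of lines.
#' @param replicates Replicate vials per line.
#' @param n_females Females per replicate (the denominator of the
#'   proportion).
#' @param h2_target Intraclass correlation of the generating model, in
#'   [0, 1).
#' @param grand_mean Grand mean proportion, in (0, 1).
#' @param sd_total Total phenotypic standard deviation on the proportion
#'   scale.
#' @param window Observation window recorded in the table (minutes).
#' @param seed Optional RNG seed.
#' @return A `phenotypes` data.frame: line, replicate, n_females, n_mated,
#'   window_min, proportion.
#' @export
#' @examples
#' ph <- simulate_line_phenotypes(20, 5, h2_target = 0.3, seed = 1)
#' head(ph)
simulate_line_phenotypes <- function(n_lines = 205, replicates = 10,
                                     n_females = 5, h2_target = 0.27,
                                     grand_mean = 0.05, sd_total = 0.1,
                                     window = 120, seed = NULL) {
  if (h2_target < 0 || h2_target >= 1) stop("h2_target must lie in [0, 1)")
  if (grand_mean <= 0 || grand_mean >= 1) stop("grand_mean must lie in (0, 1)")
  if (n_females < 1) stop("n_females must be positive")
  with_seed(seed, {
    lines <- sprintf("line_%03d", seq_len(n_lines))
    g <- rnorm(n_lines, 0, sd_total * sqrt(h2_target))
    e <- rnorm(n_lines * replicates, 0, sd_total * sqrt(1 - h2_target))
    p <- clamp(grand_mean + rep(g, each = replicates) + e)
    n_mated <- as.integer(round(p * n_females))
    structure(data.frame(
      line = rep(lines, each = replicates),
      replicate = rep(seq_len(replicates), n_lines),
      n_females = as.integer(n_females),
      n_mated = n_mated,
      window_min = window,
      proportion = n_mated / n_females,
      stringsAsFactors = FALSE
    ), class = c("phenotypes", "data.frame"))
  })
}
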