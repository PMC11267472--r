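#' Pooled sequencing of a simulated pool of flies
#'
#' The true pool frequency at each site is the alt-chromosome fraction over
#' the 2n chromosomes actually in the pool; the alt read count is then
#' Binomial(depth, true frequency), i.e. reads sample the pooled
#' chromosomes with replacement.
#'
#' @param pool A `population` holding the pooled individuals.
#' @param panel The originating `founder_panel`.
#' @param coverage Mean (Poisson) or exact (fixed) per-site depth.
#' @param depth "poisson" or "fixed".
#' @param pool_id Pool label written into the output.
#' @param variants Optional variant indices (default: all).
#' @param seed Optional RNG seed.
#' @return A `pool_counts` data.frame: chrom, pos, ref, alt, pool_id,
#'   ref_count, alt_count, n_flies.
#' @export
simulate_pool_seq <- function(pool, panel, coverage = 60,
                              depth = c("poisson", "fixed"),
                              pool_id = "pool", variants = NULL,
                              seed = NULL) {
  depth <- match.arg(depth)
  if (nrow(pool$hap1) == 0) stop("pool is empty")
  if (coverage < 0) stop("coverage must be non-negative")
  if (is.null(variants)) variants <- seq_len(nrow(panel$variants))
  freq <- population_freq(pool, panel, variants)
  with_seed(seed, {
    m <- length(variants)
    dp <- if (depth == "poisson") rpois(m, coverage) else rep(as.integer(coverage), m)
    alt <- rbinom(m, dp, freq)
    structure(data.frame(
      chrom = panel$variants$chrom[variants],
      pos = panel$variants$pos[variants],
      ref = panel$variants$ref[variants],
      alt = panel$variants$alt[variants],
      pool_id = pool_id,
      ref_count = dp - alt,
      alt_count = alt,
      n_flies = nrow(pool$hap1),
      stringsAsFactors = FALSE
    ), class = c("pool_counts", "data.frame"))
  })
}

#' Pooled sequencing counts from population allele frequencies
#'
#' Drift-free binomial pool: at each site the pool's 2n chromosomes are an
#' independent Binomial(2n, p) draw from the source frequency p, and reads
#' are Binomial(depth, pooled frequency) on top.  This is the sampling
#' model the pooled Z test assumes, so it is the reference null generator
#' for calibration work.
#'
#' @param freq Source alt-allele frequencies (one per site).
#' @param n_flies Flies in the pool.
#' @param coverage Mean (Poisson) or exact (fixed) depth per site.
#' @param depth "poisson" or "fixed".
#' @param pool_id Pool label.
#' @param chrom,pos Optional site coordinates (defaults: "sim", 1..m).
#' @param seed Optional RNG seed.
#' @return A `pool_counts` data.frame as [simulate_pool_seq()].
#' @export
simulate_pool_from_freq <- function(freq, n_flies, coverage = 60,
                                    depth = c("poisson", "fixed"),
                                    pool_id = "pool", chrom = NULL,
                                    pos = NULL, seed = NULL) {
  depth <- match.arg(depth)
  if (n_flies <= 0) stop("pool is empty")
  if (any(freq < 0 | freq > 1)) stop("frequencies must lie in [0, 1]")
  m <- length(freq)
  if (is.null(chrom)) chrom <- rep("sim", m)
  if (is.null(pos)) pos <- seq_len(m)
  with_seed(seed, {
    pooled <- rbinom(m, 2L * n_flies, freq) / (2 * n_flies)
    dp <- if (depth == "poisson") rpois(m, coverage) else rep(as.integer(coverage), m)
    alt <- rbinom(m, dp, pooled)
    structure(data.frame(chrom = chrom, pos = pos, ref = "N", alt = "N",
                         pool_id = pool_id, ref_count = dp - alt,
                         alt_count = alt, n_flies = n_flies,
                         stringsAsFactors = FALSE),
              class = c("pool_counts", "data.frame"))
  })
}
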