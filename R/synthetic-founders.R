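#' Default genome layout for the simulator
#'
#' Chromosome arm lengths (bp) approximating the D. melanogaster major
#' autosome arms.  The X is omitted by default; the simulator treats every
#' chromosome as an autosome unless a pool is declared male-haploid in the
#' pool-seq variance (see [z_statistic()]).
#'
#' @return Named numeric vector of arm lengths in bp.
#' @export
default_genome <- function() {
  c("2L" = 23.0e6, "2R" = 21.1e6, "3L" = 24.5e6, "3R" = 28.0e6)
}

#' Default polymorphic inversion blocks
#'
#' The five common cosmopolitan inversions used as GWA covariates, with
#' breakpoints on the arms of [default_genome()] and founder arrangement
#' frequencies typical of a North American population sample.  In(3R)K,
#' In(3R)Mo and In(2L)t use published breakpoint coordinates; the other two
#' use approximate literature spans.
#'
#' @return data.frame with columns name, chrom, start, end, freq.
#' @export
default_inversions <- function() {
  data.frame(
    name  = c("In(2L)t", "In(2R)NS", "In(3R)P", "In(3R)K", "In(3R)Mo"),
    chrom = c("2L", "2R", "3R", "3R", "3R"),
    start = c(2225744, 11278659, 12257931, 7576289, 17232639),
    end   = c(13154180, 16163839, 20569732, 21966092, 24857019),
    freq  = c(0.15, 0.15, 0.10, 0.05, 0.10),
    stringsAsFactors = FALSE
  )
}

#' Simulate a panel of fully inbred, sequenced founder lines
#'
#' Emulates an inbred reference panel (a DGRP-like design): each line is
#' fully homozygous, so dosages are coded 0/2 per variant.  Variants inside a
#' polymorphic inversion are generated in strong linkage disequilibrium with
#' the line's arrangement, reproducing the "island of differentiation"
#' structure that motivates inversion adjustment in association analysis.
#' Lines may be heterokaryotypic for an inversion (residual segregating
#' inversions are common in real inbred panels); the two arrangement alleles
#' are drawn independently at the inversion's frequency.
#'
#' @param n_lines Number of inbred lines (>= 2).
#' @param n_variants Number of biallelic variants.
#' @param maf_range Range of the uniform law for the alt-allele (minor)
#'   frequency; must lie in (0, 0.5].
#' @param inversions data.frame as [default_inversions()], or NULL for none.
#' @param wolbachia_rate Probability a line is Wolbachia-infected.
#' @param genome Named vector of chromosome lengths (bp).
#' @param ld_strength Probability a block variant is an arrangement tag
#'   (alt-allele probability 0.05 + 0.9 * arrangement dose / 2).
#' @param seed Optional RNG seed.
#' @return A `founder_panel`: list with `genotypes` (n_lines x n_variants
#'   dosage matrix in \{0, 2\}), `variants` (chrom, pos, ref, alt, af),
#'   `karyotypes` (per-line class ST/ST, ST/INV or INV/INV per inversion),
#'   `inv_dose` (arrangement allele count per line per inversion),
#'   `wolbachia` (logical per line), `genome`, `inversions`.
#' @export
#' @examples
#' p <- simulate_founders(8, 100, seed = 1)
#' all(p$genotypes %in% c(0, 2))
simulate_founders <- function(n_lines, n_variants,
                              maf_range = c(0.05, 0.5),
                              inversions = default_inversions(),
                              wolbachia_rate = 0.5,
                              genome = default_genome(),
                              ld_strength = 0.8,
                              seed = NULL) {
  if (n_lines < 2) stop("need at least 2 founder lines")
  if (n_variants < 1) stop("n_variants must be positive")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stop("maf_range must lie in (0, 0.5]")
  if (wolbachia_rate < 0 || wolbachia_rate > 1)
    stop("wolbachia_rate must be a probability")
  with_seed(seed, {
    lines <- sprintf("line_%03d", seq_len(n_lines))
    chrom <- sample(names(genome), n_variants, replace = TRUE,
                    prob = genome / sum(genome))
    pos <- floor(runif(n_variants, 1, genome[chrom])) + 0
    o <- order(match(chrom, names(genome)), pos)
    chrom <- chrom[o]; pos <- pos[o]
    af <- runif(n_variants, maf_range[1], maf_range[2])
    variants <- data.frame(
      id = sprintf("%s_%d", chrom, pos), chrom = chrom, pos = pos,
      ref = sample(c("A", "C", "G", "T"), n_variants, replace = TRUE),
      alt = sample(c("A", "C", "G", "T"), n_variants, replace = TRUE),
      af = af, stringsAsFactors = FALSE
    )

    n_inv <- if (is.null(inversions)) 0L else nrow(inversions)
    inv_dose <- matrix(0L, n_lines, max(n_inv, 1),
                       dimnames = list(lines, if (n_inv) inversions$name))
    geno <- matrix(2L * rbinom(n_lines * n_variants, 1L, rep(af, each = n_lines)),
                   n_lines, n_variants, dimnames = list(lines, variants$id))

    if (n_inv > 0) {
      for (i in seq_len(n_inv)) {
        inv_dose[, i] <- rbinom(n_lines, 2L, inversions$freq[i])
        in_block <- which(chrom == inversions$chrom[i] &
                            pos >= inversions$start[i] &
                            pos <= inversions$end[i])
        if (!length(in_block)) next
        tagged <- in_block[runif(length(in_block)) < ld_strength]
        for (v in tagged) {
          p_alt <- 0.05 + 0.9 * inv_dose[, i] / 2
          geno[, v] <- 2L * rbinom(n_lines, 1L, p_alt)
        }
      }
      kar <- as.data.frame(
        lapply(seq_len(n_inv), function(i)
          factor(c("ST/ST", "ST/INV", "INV/INV")[inv_dose[, i] + 1L],
                 levels = c("ST/ST", "ST/INV", "INV/INV"))),
        col.names = inversions$name, check.names = FALSE)
      kar <- cbind(data.frame(line = lines, stringsAsFactors = FALSE), kar)
    } else {
      kar <- data.frame(line = lines, stringsAsFactors = FALSE)
    }

    structure(list(
      genotypes = geno,
      variants = variants,
      karyotypes = kar,
      inv_dose = if (n_inv) inv_dose else inv_dose[, 0, drop = FALSE],
      wolbachia = setNames(runif(n_lines) < wolbachia_rate, lines),
      genome = genome,
      inversions = if (n_inv) inversions else NULL
    ), class = "founder_panel")
  })
}

#' @export
print.founder_panel <- function(x, ...) {
  cat(sprintf("founder_panel: %d inbred lines x %d variants on %s\n",
              nrow(x$genotypes), ncol(x$genotypes),
              paste(names(x$genome), collapse = ",")))
  if (!is.null(x$inversions))
    cat(sprintf("  inversions: %s\n", paste(x$inversions$name, collapse = ", ")))
  cat(sprintf("  Wolbachia+ lines: %d\n", sum(x$wolbachia)))
  invisible(x)
}

# per-haplotype arrangement (0 = standard, 1 = inverted) used for
# recombination suppression; a line carrying any inverted allele contributes
# an inverted-arrangement haplotype for that block
founder_inv_haplotype <- function(panel) {
  (panel$inv_dose >= 1) * 1L
}
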