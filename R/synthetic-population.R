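# Forward simulation of the advanced intercross population (AIP).
#
# Individuals are diploid; each haplotype is stored as a founder-origin
# vector over the variant grid (every segment of a haplotype traces back to
# exactly one fully inbred founder line, so the founder index at a variant
# determines the allele carried there).  Crossovers fall as a Poisson
# process along each chromosome; male meiosis is achiasmatic (no crossing
# over), matching Drosophila, unless switched on.  Inversions act as
# recombination-suppressed blocks in heterokaryotypic parents.

new_population <- function(hap1, hap2, sex, generation, bottle = NULL) {
  stopifnot(identical(dim(hap1), dim(hap2)), nrow(hap1) == length(sex))
  structure(list(hap1 = hap1, hap2 = hap2,
                 sex = factor(sex, levels = c("F", "M")),
                 generation = as.integer(generation),
                 bottle = bottle),
            class = "population")
}

#' @export
print.population <- function(x, ...) {
  cat(sprintf("population: %d individuals (%d F, %d M), generation %d\n",
              nrow(x$hap1), sum(x$sex == "F"), sum(x$sex == "M"),
              x$generation))
  if (!is.null(x$bottle))
    cat(sprintf("  bottles: %d\n", length(unique(x$bottle))))
  invisible(x)
}

# variant indices and positions per chromosome, plus inversion anchors
# (the first variant inside each block, used to read off a haplotype's
# arrangement from its founder of origin there)
panel_geography <- function(panel) {
  chroms <- names(panel$genome)
  idx <- lapply(chroms, function(ch) which(panel$variants$chrom == ch))
  names(idx) <- chroms
  inv <- panel$inversions
  if (!is.null(inv)) {
    inv$anchor <- vapply(seq_len(nrow(inv)), function(i) {
      j <- which(panel$variants$chrom == inv$chrom[i] &
                   panel$variants$pos >= inv$start[i] &
                   panel$variants$pos <= inv$end[i])
      if (length(j)) j[1] else NA_integer_
    }, integer(1))
    inv <- inv[!is.na(inv$anchor), , drop = FALSE]
  }
  list(idx = idx, pos = lapply(idx, function(j) panel$variants$pos[j]),
       inv = inv, inv_hap = founder_inv_haplotype(panel))
}

# one recombinant gamete from haplotype-origin vectors h1/h2
.gamete <- function(h1, h2, geo, genome, rate) {
  out <- h1
  for (ci in seq_along(genome)) {
    idx <- geo$idx[[ci]]
    start <- sample.int(2L, 1L)
    k <- if (rate > 0) rpois(1L, genome[ci] * rate) else 0L
    if (k == 0L) {
      if (start == 2L && length(idx)) out[idx] <- h2[idx]
      next
    }
    xo <- runif(k, 0, genome[ci])
    inv <- geo$inv
    if (!is.null(inv) && nrow(inv)) {
      here <- which(inv$chrom == names(genome)[ci])
      for (bi in here) {
        a1 <- geo$inv_hap[h1[inv$anchor[bi]], inv$name[bi]]
        a2 <- geo$inv_hap[h2[inv$anchor[bi]], inv$name[bi]]
        if (a1 != a2)  # heterokaryotypic: block inherited as a unit
          xo <- xo[xo < inv$start[bi] | xo > inv$end[bi]]
      }
      if (!length(xo)) {
        if (start == 2L && length(idx)) out[idx] <- h2[idx]
        next
      }
    }
    if (!length(idx)) next
    seg <- findInterval(geo$pos[[ci]], sort(xo))
    use2 <- (start - 1L + seg) %% 2L == 1L
    out[idx] <- ifelse(use2, h2[idx], h1[idx])
  }
  out
}

# one gamete without crossing over: independent assortment of whole
# chromosomes (Drosophila male meiosis)
.gamete_achiasmatic <- function(h1, h2, geo) {
  out <- h1
  for (idx in geo$idx)
    if (length(idx) && sample.int(2L, 1L) == 2L) out[idx] <- h2[idx]
  out
}

# gametes from the given parents (rows of pop); one gamete per entry of idx
make_gametes <- function(pop, idx, geo, genome, rate, recombining = TRUE) {
  out <- matrix(0L, length(idx), ncol(pop$hap1))
  for (g in seq_along(idx)) {
    i <- idx[g]
    out[g, ] <- if (recombining)
      .gamete(pop$hap1[i, ], pop$hap2[i, ], geo, genome, rate)
    else
      .gamete_achiasmatic(pop$hap1[i, ], pop$hap2[i, ], geo)
  }
  out
}

# offspring from sampled mother/father indices (into moms/dads populations)
make_offspring <- function(moms, dads, mom_idx, dad_idx, sex, geo, genome,
                           rate, male_recomb = FALSE, generation = NA,
                           bottle = NULL) {
  hap_m <- make_gametes(moms, mom_idx, geo, genome, rate, recombining = TRUE)
  hap_p <- make_gametes(dads, dad_idx, geo, genome, rate,
                        recombining = male_recomb)
  new_population(hap_m, hap_p, sex, generation, bottle)
}

subset_population <- function(pop, i) {
  new_population(pop$hap1[i, , drop = FALSE], pop$hap2[i, , drop = FALSE],
                 pop$sex[i], pop$generation,
                 if (!is.null(pop$bottle)) pop$bottle[i])
}

bind_populations <- function(...) {
  ps <- list(...)
  new_population(do.call(rbind, lapply(ps, `[[`, "hap1")),
                 do.call(rbind, lapply(ps, `[[`, "hap2")),
                 unlist(lapply(ps, function(p) as.character(p$sex))),
                 ps[[1]]$generation,
                 {
                   b <- lapply(ps, `[[`, "bottle")
                   if (all(vapply(b, is.null, logical(1)))) NULL
                   else unlist(lapply(seq_along(ps), function(i)
                     if (is.null(b[[i]])) rep(NA, nrow(ps[[i]]$hap1)) else b[[i]]))
                 })
}

#' Dosage matrix of a simulated population
#'
#' Looks up each haplotype's founder of origin per variant in the founder
#' genotype table, giving alt-allele dosages in \{0, 1, 2\}.
#'
#' @param pop A `population`.
#' @param panel The `founder_panel` the population descends from.
#' @param variants Optional variant indices (default: all).
#' @return Numeric matrix, individuals x variants.
#' @export
population_dosage <- function(pop, panel, variants = NULL) {
  if (is.null(variants)) variants <- seq_len(ncol(pop$hap1))
  A <- panel$genotypes / 2  # founder haplotype allele (0/1)
  n <- nrow(pop$hap1)
  out <- matrix(0, n, length(variants))
  for (j in seq_along(variants)) {
    v <- variants[j]
    out[, j] <- A[pop$hap1[, v], v] + A[pop$hap2[, v], v]
  }
  colnames(out) <- panel$variants$id[variants]
  out
}

#' Alt-allele frequencies in a simulated population
#'
#' @inheritParams population_dosage
#' @return Numeric vector of frequencies over 2n chromosomes.
#' @export
population_freq <- function(pop, panel, variants = NULL) {
  colMeans(population_dosage(pop, panel, variants)) / 2
}

#' Count distinct F1 genotypes in a generation-1 population
#'
#' A generation-1 individual carries two intact founder haplotypes, so its
#' genotype is the ordered founder pair (dam line, sire line).
#'
#' @param pop A generation-1 `population`.
#' @return Number of distinct founder pairs.
#' @export
count_f1_genotypes <- function(pop) {
  nrow(unique(cbind(pop$hap1[, 1], pop$hap2[, 1])))
}

#' Build an advanced intercross population from inbred founders
#'
#' Reproduces a round-robin advanced-intercross breeding design: generation
#' 1 crosses line i females to line i+1 males (cyclically) giving exactly
#' `n_lines` F1 genotypes; generation 2 round-robin-crosses the F1
#' genotypes (F1 i females x F1 i+2 males) and distributes one female and
#' one male from each cross into each of `n_bottles` replicate bottles;
#' from then on each bottle of the next generation receives
#' `per_bottle_f` females and `per_bottle_m` males bred from each bottle of
#' the previous generation.  With the defaults (10 bottles, 4 + 4) the
#' maintained census is 10 x 10 x 8 = 800.
#'
#' @param panel A `founder_panel` with at least 3 lines.
#' @param generations Last generation to simulate (1 = F1 only).
#' @param recomb_rate Crossover rate per bp per female meiosis
#'   (default 2e-8, about 2 crossovers per 100 Mb arm pair).
#' @param n_bottles Number of replicate bottles from generation 2 on.
#' @param per_bottle_f,per_bottle_m Migrants per source bottle per new
#'   bottle during maintenance.
#' @param male_recomb Allow crossing over in males (off: Drosophila males
#'   are achiasmatic).
#' @param seed Optional RNG seed.
#' @return A `population` for the requested generation.
#' @export
#' @examples
#' p <- simulate_founders(6, 50, inversions = NULL, seed = 1)
#' f1 <- build_aip(p, generations = 1, seed = 2)
#' count_f1_genotypes(f1)
build_aip <- function(panel, generations, recomb_rate = 2e-8,
                      n_bottles = 10, per_bottle_f = 4, per_bottle_m = 4,
                      male_recomb = FALSE, seed = NULL) {
  n_lines <- nrow(panel$genotypes)
  if (n_lines < 3) stop("round-robin intercross needs at least 3 founder lines")
  if (generations < 1) stop("generations must be >= 1")
  V <- ncol(panel$genotypes)
  geo <- panel_geography(panel)
  genome <- panel$genome
  with_seed(seed, {
    # generation 1: F1 genotypes, one female and one male of each
    dam <- seq_len(n_lines)
    sire <- c(seq_len(n_lines)[-1], 1L)
    h1 <- matrix(rep(dam, each = 2), ncol = 1)[, rep(1, V), drop = FALSE]
    h2 <- matrix(rep(sire, each = 2), ncol = 1)[, rep(1, V), drop = FALSE]
    pop <- new_population(h1, h2, rep(c("F", "M"), n_lines), 1L)
    if (generations == 1) return(pop)

    # generation 2: round-robin of F1 genotypes; each cross contributes one
    # female and one male to each bottle
    f1_f <- which(pop$sex == "F")          # female of F1 genotype i
    f1_m <- which(pop$sex == "M")          # male of F1 genotype i
    cross_dam <- seq_len(n_lines)
    cross_sire <- (seq_len(n_lines) + 1L) %% n_lines + 1L  # i + 2 cyclic
    per_cross <- 2L * n_bottles
    mom_idx <- rep(f1_f[cross_dam], each = per_cross)
    dad_idx <- rep(f1_m[cross_sire], each = per_cross)
    sexes <- rep(rep(c("F", "M"), n_bottles), n_lines)
    bottle <- rep(rep(seq_len(n_bottles), each = 2), n_lines)
    pop <- make_offspring(pop, pop, mom_idx, dad_idx, sexes, geo, genome,
                          recomb_rate, male_recomb, generation = 2L,
                          bottle = bottle)
    # maintenance: each new bottle draws per_bottle_f + per_bottle_m
    # offspring from every old bottle
    for (g in seq_len(generations - 2L) + 2L) {
      haps1 <- vector("list", n_bottles); haps2 <- haps1
      sex_all <- bottle_all <- vector("list", n_bottles)
      per_new <- per_bottle_f + per_bottle_m
      for (b in seq_len(n_bottles)) {
        in_b <- which(pop$bottle == b)
        fem <- in_b[pop$sex[in_b] == "F"]; mal <- in_b[pop$sex[in_b] == "M"]
        n_off <- per_new * n_bottles       # this bottle's contribution
        mom <- sample(fem, n_off, replace = TRUE)
        dad <- sample(mal, n_off, replace = TRUE)
        sx <- rep(c(rep("F", per_bottle_f), rep("M", per_bottle_m)), n_bottles)
        dest <- rep(seq_len(n_bottles), each = per_new)
        off <- make_offspring(pop, pop, mom, dad, sx, geo, genome,
                              recomb_rate, male_recomb, generation = g,
                              bottle = dest)
        haps1[[b]] <- off$hap1; haps2[[b]] <- off$hap2
        sex_all[[b]] <- as.character(off$sex); bottle_all[[b]] <- off$bottle
      }
      pop <- new_population(do.call(rbind, haps1), do.call(rbind, haps2),
                            unlist(sex_all), g, unlist(bottle_all))
    }
    pop
  })
}

#' Breed a cohort from chosen parents
#'
#' Produces `n_female` + `n_male` offspring by sampling a dam and a sire
#' uniformly (with replacement) per offspring from the supplied parents.
#' Used by the selection-experiment simulator to raise each generation's
#' assay cohort.
#'
#' @param parents A `population` containing the breeding adults.
#' @param panel The originating `founder_panel`.
#' @param n_female,n_male Offspring of each sex.
#' @param recomb_rate Crossover rate per bp (female meiosis).
#' @param male_recomb Allow crossing over in males.
#' @param seed Optional RNG seed.
#' @return A `population`.
#' @export
breed_cohort <- function(parents, panel, n_female, n_male,
                         recomb_rate = 2e-8, male_recomb = FALSE,
                         seed = NULL) {
  fem <- which(parents$sex == "F"); mal <- which(parents$sex == "M")
  if (!length(fem) || !length(mal)) stop("need parents of both sexes")
  geo <- panel_geography(panel)
  with_seed(seed, {
    n <- n_female + n_male
    make_offspring(parents, parents,
                   sample(fem, n, replace = TRUE),
                   sample(mal, n, replace = TRUE),
                   c(rep("F", n_female), rep("M", n_male)),
                   geo, panel$genome, recomb_rate, male_recomb,
                   generation = parents$generation + 1L)
  })
}
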