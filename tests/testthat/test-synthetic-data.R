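# The simulator underlying every downstream analysis: founder panels,
# intercross breeding, mating assays, truncation selection, pool
# sequencing and the one-way phenotype generator.

test_that("founder panels are fully inbred with the requested structure", {
  p <- simulate_founders(40, 1000, seed = 1)
  expect_true(all(p$genotypes %in% c(0, 2)))
  expect_equal(dim(p$genotypes), c(40, 1000))
  expect_true(all(p$variants$af >= 0 & p$variants$af <= 1))
  for (inv in p$inversions$name)
    expect_true(all(p$karyotypes[[inv]] %in% c("ST/ST", "ST/INV", "INV/INV")))
  # wolbachia_rate 0 means no infected lines
  p0 <- simulate_founders(10, 50, wolbachia_rate = 0, seed = 2)
  expect_false(any(p0$wolbachia))
  expect_error(simulate_founders(1, 10), "at least 2")
  expect_error(simulate_founders(10, 10, maf_range = c(0, 0.6)), "maf_range")
})

test_that("empirical mean MAF matches the sampling law", {
  # uniform(0.05, 0.5) law: mean folded MAF should sit at 0.275 within
  # Monte-Carlo error of the realised line frequencies
  p <- simulate_founders(200, 5000, maf_range = c(0.05, 0.5),
                         inversions = NULL, seed = 3)
  maf <- pmin(colMeans(p$genotypes) / 2, 1 - colMeans(p$genotypes) / 2)
  se <- sd(maf) / sqrt(length(maf))
  expect_lt(abs(mean(maf) - 0.275), 3 * se + 0.01)
})

test_that("variants inside an inversion track the karyotype", {
  p <- simulate_founders(120, 2000, seed = 4)
  inv <- "In(2L)t"
  blk <- with(p$variants, which(chrom == "2L" &
                                  pos >= 2225744 & pos <= 13154180))
  dose <- p$inv_dose[, inv]
  r_blk <- apply(p$genotypes[, blk, drop = FALSE], 2,
                 function(g) suppressWarnings(cor(g, dose)))
  out <- with(p$variants, which(chrom %in% c("3L", "3R")))
  r_out <- apply(p$genotypes[, sample(out, 200), drop = FALSE], 2,
                 function(g) suppressWarnings(cor(g, dose)))
  expect_gt(mean(r_blk, na.rm = TRUE), 0.3)
  expect_gt(mean(r_blk, na.rm = TRUE), mean(r_out, na.rm = TRUE) + 0.25)
  expect_lt(abs(mean(r_out, na.rm = TRUE)), 0.1)
})

test_that("round-robin intercross bookkeeping is exact", {
  p <- tiny_panel(40, 200, seed = 5)
  f1 <- build_aip(p, generations = 1, seed = 6)
  expect_equal(count_f1_genotypes(f1), 40)
  aip <- build_aip(p, generations = 4, seed = 7)
  expect_equal(nrow(aip$hap1), 800)
  expect_equal(sort(unique(aip$bottle)), 1:10)
  # founder-origin labels partition the genome: every entry is a line index
  expect_true(all(aip$hap1 %in% seq_len(40)))
  expect_true(all(aip$hap2 %in% seq_len(40)))
  expect_error(build_aip(tiny_panel(2, 10), 1), "at least 3")
})

test_that("zero recombination transmits intact parental haplotypes", {
  p <- tiny_panel(6, 150, seed = 8)
  aip <- build_aip(p, generations = 3, recomb_rate = 0, seed = 9)
  # every haplotype is a single founder along its full length
  expect_true(all(apply(aip$hap1, 1, function(h) length(unique(h))) <=
                    length(p$genome)))
  # per chromosome, exactly one founder of origin
  for (ch in names(p$genome)) {
    idx <- which(p$variants$chrom == ch)
    if (length(idx) < 2) next
    expect_true(all(apply(aip$hap1[, idx, drop = FALSE], 1,
                          function(h) length(unique(h))) == 1))
  }
})

test_that("identical seeds reproduce the simulation exactly", {
  p1 <- simulate_founders(15, 200, seed = 11)
  p2 <- simulate_founders(15, 200, seed = 11)
  expect_identical(p1, p2)
  a1 <- build_aip(p1, 3, seed = 12)
  a2 <- build_aip(p2, 3, seed = 12)
  expect_identical(a1, a2)
  ph1 <- simulate_line_phenotypes(30, 5, seed = 13)
  ph2 <- simulate_line_phenotypes(30, 5, seed = 13)
  expect_identical(ph1, ph2)
})

test_that("mating assay honours degenerate hazards and conserves females", {
  z <- simulate_mating_assay(rep(0, 30), window = 60, seed = 14)
  expect_equal(sum(z$mated), 0)
  hi <- simulate_mating_assay(rep(1e9, 30), window = 60, seed = 15)
  s <- assay_summary(hi)
  expect_true(all(s$proportion == 1))
  # conservation: mated + unmated females = 5 per vial, no male twice
  m <- simulate_mating_assay(rep(0.002, 40), window = 120, seed = 16)
  s <- assay_summary(m)
  expect_true(all(s$n_mated <= s$n_females))
  expect_true(all(table(m$male_id) == 1))
  expect_true(all(m$latency[m$mated] <= 120))
  expect_error(simulate_mating_assay(0.1, window = 0), "window")
})

test_that("constant-hazard assay matches the competing-risk closed form", {
  h <- 0.0012; t <- 60; n_vials <- 400
  a <- simulate_mating_assay(rep(h, 10 * n_vials), window = t, seed = 17)
  s <- assay_summary(a)
  exp_mated <- expected_matings_oracle(5, 10, h, t)
  se <- sd(s$n_mated) / sqrt(n_vials)
  expect_lt(abs(mean(s$n_mated) - exp_mated), 3 * se)
})

test_that("truncation selection implements first-k, fastest and random", {
  set.seed(18)
  a <- simulate_mating_assay(rep(0.003, 300), window = 120, seed = 18)
  sel <- truncation_select(a, "first_k", 40, seed = 19)
  expect_length(sel, 40)
  lat_sel <- a$latency[a$male_id %in% sel]
  lat_un <- a$latency[!is.na(a$latency) & !(a$male_id %in% sel)]
  expect_lte(max(lat_sel), min(lat_un))
  expect_identical(truncation_select(a, "k_fastest", 40, seed = 20),
                   truncation_select(a, "first_k", 40, seed = 20))
  expect_identical(truncation_select(a, "k_random", 50, seed = 21),
                   truncation_select(a, "k_random", 50, seed = 21))
  expect_error(truncation_select(a, "first_k", 10000),
               "cannot select")
})

test_that("pool sequencing is exact at fixed sites and unbiased overall", {
  p <- tiny_panel(8, 100, seed = 22)
  aip <- build_aip(p, 3, seed = 23)
  pool <- matescan:::subset_population(aip, 1:50)
  freq <- population_freq(pool, p)
  pc <- simulate_pool_seq(pool, p, coverage = 80, depth = "fixed", seed = 24)
  expect_equal(pc$ref_count + pc$alt_count, rep(80L, 100))
  expect_true(all(pc$alt_count[freq == 0] == 0))
  expect_true(all(pc$ref_count[freq == 1] == 0))
  # unbiasedness against the binomial-mean oracle at freq 0.3
  pc2 <- simulate_pool_from_freq(rep(0.3, 10000), n_flies = 50,
                                 coverage = 100, depth = "fixed", seed = 25)
  est <- pc2$alt_count / (pc2$alt_count + pc2$ref_count)
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 0.3), 3 * se)
  expect_error(simulate_pool_from_freq(0.5, 0), "empty")
})

test_that("phenotype generator hits its intraclass correlation target", {
  # h2 = 0: REML should sit at the boundary
  ph0 <- simulate_line_phenotypes(80, 8, n_females = 100, h2_target = 0,
                                  grand_mean = 0.5, seed = 26)
  expect_lt(estimate_h2(ph0)$H2, 0.05)
  # h2 = 0.4 at scale: recovery within a few MC standard errors
  est <- vapply(1:30, function(i)
    estimate_h2(simulate_line_phenotypes(100, 8, n_females = 100,
                                         h2_target = 0.4, grand_mean = 0.5,
                                         seed = 300 + i))$H2, numeric(1))
  expect_lt(abs(mean(est) - 0.4), 3 * sd(est) / sqrt(30) + 0.01)
  expect_error(simulate_line_phenotypes(10, 2, h2_target = 1.2), "h2_target")
})

test_that("trait model realises its liability variance split", {
  p <- simulate_founders(40, 600, seed = 27)
  aip <- build_aip(p, 4, seed = 28)
  m <- trait_model(p, 20, h2 = 0.27, seed = 29)
  lia <- mating_liability(aip, p, m, seed = 30)
  g <- attr(lia, "genetic")
  expect_lt(abs(var(g) / var(lia) - 0.27), 0.08)
  expect_lt(abs(var(lia) - 1), 0.2)
  # h2 = 0 gives a flat genetic value
  m0 <- trait_model(p, 5, h2 = 0, seed = 31)
  expect_equal(var(attr(mating_liability(aip, p, m0, seed = 32), "genetic")), 0)
})
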