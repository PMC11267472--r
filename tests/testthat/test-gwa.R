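# MAF filtering, covariate adjustment, relationship matrix and the
# spectral mixed-model association scan.

make_gmat <- function(n, m, p = 0.3, seed = 1, inbred = TRUE) {
  set.seed(seed)
  d <- if (inbred) matrix(2 * rbinom(n * m, 1, p), n, m)
  else matrix(rbinom(n * m, 2, p), n, m)
  v <- data.frame(id = paste0("v", seq_len(m)), chrom = "2L",
                  pos = seq_len(m) * 100, ref = "A", alt = "T",
                  stringsAsFactors = FALSE)
  genotype_matrix(d * 1, v)
}

test_that("MAF filtering folds, uses strict inequality and is idempotent", {
  # 10 inbred lines; column alt frequencies 0.1, 0.3, 0.9, 0.5 fold to
  # 0.1, 0.3, 0.1, 0.5
  col <- function(k) c(rep(2, k), rep(0, 10 - k))
  d <- cbind(col(1), col(3), col(9), col(5))
  g <- genotype_matrix(d * 1,
                       data.frame(id = paste0("v", 1:4), chrom = "2L",
                                  pos = 1:4, ref = "A", alt = "T"))
  expect_equal(unname(folded_maf(g)), c(0.1, 0.3, 0.1, 0.5))
  kept <- maf_filter(g, 0.1)
  expect_equal(kept$variants$id, c("v2", "v4"))  # strictly greater
  expect_identical(maf_filter(kept, 0.1)$variants, kept$variants)
  # alt frequency 0.98 folds to 0.02 and is removed at threshold 0.02
  g2 <- genotype_matrix(matrix(c(rep(2, 49), 0), 50, 1),
                        data.frame(id = "w", chrom = "2L", pos = 1,
                                   ref = "A", alt = "T"))
  expect_equal(ncol(maf_filter(g2, 0.02)$dosage), 0)
  # brute-force recount on a random matrix
  g3 <- make_gmat(50, 300, seed = 2)
  f <- colMeans(g3$dosage) / 2
  expect_equal(ncol(maf_filter(g3, 0.1)$dosage),
               sum(pmin(f, 1 - f) > 0.1))
})

test_that("phenotype adjustment regresses out covariate classes", {
  set.seed(3)
  n <- 60
  lines <- sprintf("l%02d", 1:n)
  karyo <- rep(c("ST/ST", "ST/INV", "INV/INV"), each = n / 3)
  base <- rnorm(n, 0.1, 0.02)
  shifted <- base + 0.2 * (karyo == "ST/INV")
  means <- data.frame(line = lines, mean = shifted)
  cov <- data.frame(line = lines, wolbachia = "n", inv = karyo,
                    stringsAsFactors = FALSE)
  adj <- adjust_phenotype(means, cov)
  fit <- attr(adj, "fit")
  expect_lt(abs(unname(coef(fit)["invST/INV"]) - 0.2), 0.02)
  # class re-centred: adjusted values should not differ by class
  expect_lt(abs(mean(adj[karyo == "ST/INV"]) - mean(adj[karyo == "ST/ST"])),
            0.02)
  # mean preserved, variance never increased
  expect_equal(mean(adj), mean(shifted))
  expect_lte(var(adj), var(shifted))
  # constant covariates leave the phenotype untouched
  strip <- function(x) { attributes(x) <- NULL; x }
  cov0 <- data.frame(line = lines, wolbachia = "n", inv = "ST/ST",
                     stringsAsFactors = FALSE)
  expect_equal(strip(adjust_phenotype(means, cov0)), shifted)
  # skipping inversions with constant wolbachia is also a no-op
  expect_equal(strip(adjust_phenotype(means, cov,
                                      adjust_inversions = FALSE)), shifted)
  expect_error(adjust_phenotype(means, cov[-1, ]), "missing")
})

test_that("the relationship matrix has the canonical structure", {
  g <- make_gmat(30, 2000, seed = 4)
  # duplicate a line: its off-diagonal entry equals the diagonal entries
  g$dosage[2, ] <- g$dosage[1, ]
  K <- compute_grm(g)
  expect_equal(K[1, 2], K[1, 1])
  expect_equal(K, t(K))
  expect_gt(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
            -1e-8)
  # independent HWE dosages: mean diagonal near 1; fully inbred 0/2
  # dosages double every squared deviation, so their diagonal sits at 2
  g2 <- make_gmat(40, 4000, seed = 5, inbred = FALSE)
  K2 <- compute_grm(g2)
  dse <- sd(diag(K2)) / sqrt(nrow(K2))
  expect_lt(abs(mean(diag(K2)) - 1), 3 * dse + 0.02)
  g2i <- make_gmat(40, 4000, seed = 5, inbred = TRUE)
  expect_lt(abs(mean(diag(compute_grm(g2i))) - 2), 0.05)
  # missing dosages are mean-imputed, not fatal
  g3 <- make_gmat(20, 100, seed = 6)
  g3$dosage[1, 1] <- NA
  expect_silent(compute_grm(g3))
})

test_that("with an identity relationship the scan is exactly OLS", {
  g <- make_gmat(60, 120, seed = 7)
  set.seed(8)
  y <- setNames(rnorm(60), g$lines)
  sc <- lmm_association(y, g, K = diag(60))
  X <- g$dosage
  ols <- t(vapply(seq_len(ncol(X)), function(j) {
    s <- summary(lm(y ~ X[, j]))$coefficients
    c(beta = s[2, 1], se = s[2, 2], p = s[2, 4])
  }, numeric(3)))
  expect_equal(sc$beta, unname(ols[, "beta"]), tolerance = 1e-10)
  expect_equal(sc$se, unname(ols[, "se"]), tolerance = 1e-10)
  expect_equal(sc$p, unname(ols[, "p"]), tolerance = 1e-10)
})

test_that("the scan is invariant to line reordering", {
  g <- make_gmat(40, 80, seed = 9)
  K <- compute_grm(g) + diag(1e-4, 40)
  set.seed(10)
  y <- setNames(rnorm(40), g$lines)
  sc1 <- lmm_association(y, g, K)
  perm <- sample(40)
  g2 <- genotype_matrix(g$dosage[perm, ], g$variants)
  sc2 <- lmm_association(y[perm], g2, K[perm, perm])
  expect_equal(sc1$p, sc2$p, tolerance = 1e-8)
})

test_that("missing dosages drop lines from that variant's test only", {
  g <- make_gmat(50, 40, seed = 11)
  K <- compute_grm(g) + diag(1e-4, 50)
  set.seed(12)
  y <- setNames(rnorm(50), g$lines)
  g$dosage[1:5, 3] <- NA
  sc <- lmm_association(y, g, K)
  expect_equal(sc$n[3], 45)
  expect_equal(sc$n[-3], rep(50L, 39))
  expect_true(is.finite(sc$p[3]))
})

test_that("a strong causal variant is found and the scan stays calibrated", {
  p <- tiny_panel(60, 400, seed = 13)
  g <- maf_filter(genotype_matrix(p$genotypes * 1, p$variants), 0.05)
  K <- compute_grm(g)
  set.seed(14)
  j <- which.min(abs(folded_maf(g) - 0.4))[1]
  y <- setNames(0.25 * g$dosage[, j] + rnorm(60, 0, 0.5), g$lines)
  sc <- lmm_association(y, g, K + diag(1e-4, 60))
  expect_lte(rank(sc$p)[j], 10)
})

test_that("Bonferroni threshold is alpha over m", {
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.1, 10), 0.01)
  expect_error(bonferroni_threshold(0.05, 0), "at least 1")
})

test_that("gene assignment matches a brute-force interval scan", {
  genes <- data.frame(gene = c("g1", "g2", "g3"),
                      chrom = c("2L", "2L", "3R"),
                      start = c(1000, 5000, 2000),
                      end = c(2000, 6000, 2500), stringsAsFactors = FALSE)
  rec <- data.frame(id = c("a", "b", "c", "d"), chrom = c("2L", "2L", "2L", "3R"),
                    pos = c(1500, 900, 899, 3000), stringsAsFactors = FALSE)
  ann <- annotate_variants(rec, genes, window = 100)
  expect_equal(ann$gene[ann$id == "a"], "g1")      # inside the body
  expect_equal(ann$gene[ann$id == "b"], "g1")      # exactly window bp away
  expect_true(ann$intergenic[ann$id == "c"])       # window + 1 bp away
  expect_true(ann$intergenic[ann$id == "d"])
  # randomized all-pairs oracle
  set.seed(15)
  rec2 <- data.frame(id = sprintf("v%03d", 1:150),
                     chrom = sample(c("2L", "3R"), 150, TRUE),
                     pos = sample(1e5, 150), stringsAsFactors = FALSE)
  st <- sample(1e5, 30)
  genes2 <- data.frame(gene = sprintf("g%02d", 1:30),
                       chrom = sample(c("2L", "3R"), 30, TRUE),
                       start = st, end = st + sample(5000, 30),
                       stringsAsFactors = FALSE)
  ann2 <- annotate_variants(rec2, genes2, window = 500)
  got <- ann2[!ann2$intergenic, c("id", "gene")]
  got <- got[order(got$id, got$gene), ]
  rownames(got) <- NULL
  want <- annotate_brute_oracle(rec2, genes2, 500)
  rownames(want) <- NULL
  expect_equal(got, want)
})

test_that("gene list overlaps partition correctly", {
  expect_equal(unname(gene_overlap(list(A = c("a", "b", "c"),
                                        B = c("b", "c", "d")))),
               c(2L, 1L, 1L))
  ov <- gene_overlap(list(A = letters[1:3], B = letters[1:3]))
  expect_equal(unname(ov), c(3L, 0L, 0L))
  ov3 <- gene_overlap(list(X = c("a", "b", "d", "g"),
                           Y = c("b", "c", "g"),
                           Z = c("d", "e", "g")))
  expect_equal(ov3[["X&Y&Z"]], 1L)
  expect_equal(ov3[["X&Y"]], 1L)   # b
  expect_equal(ov3[["X&Z"]], 1L)   # d
  expect_equal(ov3[["X"]], 1L)     # a
  expect_equal(sum(ov3), length(unique(c("a","b","d","g","b","c","g","d","e","g"))))
})

test_that("inversion adjustment deflates a confounded scan", {
  # phenotype driven by karyotype alone: the unadjusted scan inherits the
  # long-range inversion LD, the adjusted one does not
  p <- simulate_founders(100, 800, seed = 16)
  set.seed(17)
  y_raw <- 0.05 + 0.1 * (p$inv_dose[, "In(2L)t"] / 2) + rnorm(100, 0, 0.03)
  means <- data.frame(line = p$karyotypes$line, mean = y_raw)
  cov <- cbind(data.frame(line = p$karyotypes$line,
                          wolbachia = ifelse(p$wolbachia, "y", "n")),
               p$karyotypes[-1])
  g <- maf_filter(genotype_matrix(p$genotypes * 1, p$variants), 0.05)
  adj <- adjust_phenotype(means, cov)
  una <- adjust_phenotype(means, cov, adjust_inversions = FALSE)
  # marker-regression scans (identity relationship) expose the inversion
  # confounding directly
  I <- diag(100)
  l_adj <- genomic_lambda(lmm_association(adj, g, I)$p)
  l_una <- genomic_lambda(lmm_association(una, g, I)$p)
  expect_gt(l_una, 1.1)
  expect_lt(l_adj, l_una)
  expect_lt(abs(l_adj - 1), abs(l_una - 1))
})
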