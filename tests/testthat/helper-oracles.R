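# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: closed forms, brute-force enumeration and
# textbook estimators only.

# two-sided Fisher exact p by full hypergeometric enumeration over all
# tables with the observed margins
fisher_enum_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  x <- max(0, k - n):min(k, m)
  pr <- dhyper(x, m, n, k)
  p0 <- dhyper(a, m, n, k)
  sum(pr[pr <= p0 * (1 + 1e-7)])
}

# balanced one-way ANOVA estimator of the intraclass correlation
anova_h2_oracle <- function(y, line, r) {
  fit <- anova(lm(y ~ factor(line)))
  msb <- fit$"Mean Sq"[1]; msw <- fit$"Mean Sq"[2]
  vg <- max(0, (msb - msw) / r)
  c(vg = vg, ve = msw, H2 = vg / (vg + msw))
}

# expected number of matings by time t in a vial of f females and m males
# under a constant per-pair hazard h: a pure-death chain with rates
# (f - j)(m - j) h, j = 0, 1, ...; E[N(t)] = sum_k P(T_k <= t) with T_k
# hypoexponential (distinct rates), via the standard partial-fraction form
expected_matings_oracle <- function(f, m, h, t) {
  kmax <- min(f, m)
  lam <- (f - 0:(kmax - 1)) * (m - 0:(kmax - 1)) * h
  sum(vapply(seq_len(kmax), function(k) {
    l <- lam[seq_len(k)]
    1 - sum(vapply(seq_len(k), function(j) {
      exp(-l[j] * t) * prod(l[-j] / (l[-j] - l[j]))
    }, numeric(1)))
  }, numeric(1)))
}

# brute-force variant-to-gene assignment by scanning all pairs
annotate_brute_oracle <- function(records, genes, window) {
  out <- list()
  for (i in seq_len(nrow(records))) for (j in seq_len(nrow(genes))) {
    if (records$chrom[i] == genes$chrom[j] &&
          records$pos[i] >= genes$start[j] - window &&
          records$pos[i] <= genes$end[j] + window)
      out[[length(out) + 1]] <- c(records$id[i], genes$gene[j])
  }
  if (!length(out)) return(data.frame(id = character(), gene = character()))
  df <- as.data.frame(do.call(rbind, out), stringsAsFactors = FALSE)
  names(df) <- c("id", "gene")
  df[order(df$id, df$gene), ]
}

# small founder panel + intercross reused by several files
tiny_panel <- function(n_lines = 12, n_variants = 120, seed = 42, ...) {
  simulate_founders(n_lines, n_variants, seed = seed, ...)
}

# pool-counts row constructor for hand-built Z-test cases
pool_row <- function(alt, cov, n_flies, pool_id = "p", chrom = "2L",
                     pos = 1000) {
  data.frame(chrom = chrom, pos = pos, ref = "A", alt = "T",
             pool_id = pool_id, ref_count = cov - alt, alt_count = alt,
             n_flies = n_flies, stringsAsFactors = FALSE)
}
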