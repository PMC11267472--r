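# Mixed-model genome-wide association for an inbred line panel:
# covariate adjustment (Wolbachia + inversion karyotypes), folded-MAF
# filtering, a centred-scaled genomic relationship matrix, and per-variant
# generalized least squares after a single spectral decomposition of the
# relationship matrix (the two-step approximation used by spectral LMM
# association software).

#' Construct a genotype matrix object
#'
#' @param dosage Numeric matrix, lines x variants, dosages in
#'   \{0, 1, 2, NA\} (inbred panels: 0/2/NA).
#' @param variants data.frame with at least id, chrom, pos (1-based), ref,
#'   alt; row order matches the dosage columns.
#' @return A `genotype_matrix` list: dosage, variants, lines.
#' @export
genotype_matrix <- function(dosage, variants) {
  stopifnot(is.matrix(dosage), nrow(variants) == ncol(dosage))
  ok <- dosage %in% c(0, 1, 2) | is.na(dosage)
  if (!all(ok)) stop("dosages must be 0, 1, 2 or missing")
  if (is.null(rownames(dosage)))
    rownames(dosage) <- sprintf("line_%03d", seq_len(nrow(dosage)))
  colnames(dosage) <- variants$id
  structure(list(dosage = dosage, variants = variants,
                 lines = rownames(dosage)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d lines x %d variants\n",
              nrow(x$dosage), ncol(x$dosage)))
  invisible(x)
}

#' Folded minor allele frequencies
#'
#' Computed from non-missing lines only and folded into [0, 0.5].
#'
#' @param g A `genotype_matrix`.
#' @return Numeric vector, one per variant.
#' @export
folded_maf <- function(g) {
  f <- colMeans(g$dosage, na.rm = TRUE) / 2
  pmin(f, 1 - f)
}

#' Filter variants by minor allele frequency
#'
#' Retains variants whose folded MAF is strictly greater than `threshold`
#' (so "MAF > 0.02" keeps 0.021 but drops 0.02 exactly).
#'
#' @param g A `genotype_matrix`.
#' @param threshold MAF threshold in [0, 0.5).
#' @return The filtered `genotype_matrix`.
#' @export
maf_filter <- function(g, threshold = 0.02) {
  if (threshold < 0 || threshold >= 0.5) stop("threshold must lie in [0, 0.5)")
  # strict inequality up to floating-point dust in the folding
  keep <- which(folded_maf(g) - threshold > 1e-12)
  genotype_matrix(g$dosage[, keep, drop = FALSE],
                  g$variants[keep, , drop = FALSE])
}

#' Adjust line means for Wolbachia and inversion karyotypes
#'
#' Ordinary least squares of line means on Wolbachia infection status (two
#' levels) and, optionally, each polymorphic inversion's karyotype class
#' (up to three levels, class-coded).  The adjusted phenotype is the OLS
#' residual re-centred at the grand mean, which leaves the mean unchanged
#' and never increases the variance.
#'
#' @param means Line-mean table ([line_means()]).
#' @param covariates data.frame with `line`, `wolbachia` (logical or
#'   y/n) and one column per inversion.
#' @param inversions Character vector of inversion columns to adjust for;
#'   NULL uses every non-line, non-wolbachia column.
#' @param adjust_inversions Set FALSE to adjust for Wolbachia only (the
#'   companion scan that deliberately leaves inversion effects in).
#' @return Named numeric vector of adjusted phenotypes (one per line),
#'   with the fitted model as attribute `"fit"`.
#' @export
adjust_phenotype <- function(means, covariates, inversions = NULL,
                             adjust_inversions = TRUE) {
  i <- match(means$line, covariates$line)
  if (anyNA(i)) stop("covariates missing for lines: ",
                     paste(means$line[is.na(i)], collapse = ", "))
  cov <- covariates[i, , drop = FALSE]
  if (is.null(inversions))
    inversions <- setdiff(names(cov), c("line", "wolbachia"))
  wb <- cov$wolbachia
  if (is.character(wb)) wb <- wb %in% c("y", "yes", "TRUE", "1")
  df <- data.frame(y = means$mean, wolbachia = factor(wb))
  terms <- "1"
  if (nlevels(df$wolbachia) > 1) terms <- c(terms, "wolbachia")
  if (adjust_inversions) {
    for (inv in inversions) {
      cl <- droplevels(factor(as.character(cov[[inv]])))
      if (nlevels(cl) > 1) {
        nm <- make.names(inv)
        df[[nm]] <- cl
        terms <- c(terms, nm)
      }
    }
  }
  fit <- lm(stats::reformulate(terms, response = "y"), data = df)
  out <- setNames(residuals(fit) + mean(means$mean), means$line)
  attr(out, "fit") <- fit
  out
}

#' Genomic relationship matrix
#'
#' `K = W W' / L`, where W holds dosages centred by twice the allele
#' frequency and scaled by `sqrt(2 p (1 - p))`, and L is the number of
#' variants used.  Missing dosages are mean-imputed per variant;
#' monomorphic variants are dropped.  K is symmetric positive
#' semi-definite by construction.
#'
#' @param g A `genotype_matrix` (normally after [maf_filter()]).
#' @return Line x line relationship matrix.
#' @export
compute_grm <- function(g) {
  X <- g$dosage
  if (ncol(X) == 0) stop("no variants to build a relationship matrix from")
  cm <- colMeans(X, na.rm = TRUE)
  na <- which(is.na(X), arr.ind = TRUE)
  if (nrow(na)) X[na] <- cm[na[, 2]]
  p <- cm / 2
  keep <- p > 0 & p < 1
  if (!any(keep)) stop("all variants monomorphic")
  X <- X[, keep, drop = FALSE]; p <- p[keep]
  W <- sweep(X, 2, 2 * p)
  W <- sweep(W, 2, sqrt(2 * p * (1 - p)), "/")
  K <- tcrossprod(W) / ncol(W)
  dimnames(K) <- list(g$lines, g$lines)
  K
}

#' Mixed-model association scan
#'
#' Fits `y = X b + Z u + e` per variant, with `u ~ N(0, var_u K)` the
#' polygenic effect.  K is eigendecomposed once; the variance ratio
#' `delta = var_e / var_u` is estimated by REML under the no-variant model
#' and reused for every variant (two-step spectral approximation), each
#' variant then being tested by generalized least squares in the rotated
#' space with a two-sided Wald t test.  With `K = I` this reduces exactly
#' to per-variant ordinary least squares.
#'
#' Lines with a missing dosage at a variant are excluded from that
#' variant's test (exact GLS on the remaining lines, at the null variance
#' components).
#'
#' @param y Named numeric vector of (adjusted) line phenotypes.
#' @param g A `genotype_matrix` over the same lines.
#' @param K Relationship matrix from [compute_grm()]; NULL computes it
#'   from `g`.
#' @return An `assoc_scan` data.frame: id, chrom, pos, maf, n, beta, se,
#'   t, p; attributes `delta`, `var_u`, `var_e`.
#' @export
lmm_association <- function(y, g, K = NULL) {
  if (is.null(K)) K <- compute_grm(g)
  if (!is.null(names(y))) {
    stopifnot(all(names(y) %in% g$lines))
    g <- genotype_matrix(g$dosage[names(y), , drop = FALSE], g$variants)
    if (!is.null(dimnames(K))) K <- K[names(y), names(y)]
  }
  n <- length(y)
  if (n != nrow(g$dosage) || n != nrow(K)) stop("y, g and K must align")
  if (sd(y) == 0) stop("phenotype is constant")
  eg <- eigen((K + t(K)) / 2, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  if (min(eg$values) < -1e-6) stop("K is not positive semi-definite")
  U <- eg$vectors
  ys <- drop(crossprod(U, y))
  os <- drop(crossprod(U, rep(1, n)))

  m2rll <- function(log_delta) {
    d <- lam + exp(log_delta)
    w <- 1 / d
    mu <- sum(w * os * ys) / sum(w * os^2)
    q <- sum(w * (ys - mu * os)^2)
    vu <- q / (n - 1)
    (n - 1) * log(vu) + sum(log(d)) + log(sum(w * os^2) / vu) + q / vu
  }
  opt <- optimize(m2rll, c(-12, 12), tol = 1e-9)
  delta <- exp(opt$minimum)
  d <- lam + delta
  w <- 1 / d
  mu <- sum(w * os * ys) / sum(w * os^2)
  vu <- sum(w * (ys - mu * os)^2) / (n - 1)

  X <- g$dosage
  miss <- colSums(is.na(X)) > 0
  Xs <- crossprod(U, ifelse(is.na(X), 0, X))   # rotated dosages (complete cols)
  s11 <- sum(w * os^2)
  s1y <- sum(w * os * ys)
  syy <- sum(w * ys^2)
  sx1 <- colSums(w * Xs * os)
  sxy <- colSums(w * Xs * ys)
  sxx <- colSums(w * Xs^2)
  det2 <- s11 * sxx - sx1^2
  beta <- (s11 * sxy - sx1 * s1y) / det2
  alpha <- (sxx * s1y - sx1 * sxy) / det2
  rss <- syy - alpha * s1y - beta * sxy
  sigma2 <- rss / (n - 2)
  se <- sqrt(sigma2 * s11 / det2)
  n_used <- rep(n, ncol(X))

  # exact per-variant GLS for variants with missing lines
  if (any(miss)) {
    V <- K * 1 + diag(delta, n)   # covariance up to var_u
    for (j in which(miss)) {
      keep <- which(!is.na(X[, j]))
      n_used[j] <- length(keep)
      if (length(keep) < 3 || sd(X[keep, j]) == 0) {
        beta[j] <- NA; se[j] <- NA
        next
      }
      Vi <- solve(V[keep, keep])
      Xd <- cbind(1, X[keep, j])
      xtvx <- crossprod(Xd, Vi %*% Xd)
      xtvy <- crossprod(Xd, Vi %*% y[keep])
      bh <- solve(xtvx, xtvy)
      r <- y[keep] - Xd %*% bh
      s2 <- drop(crossprod(r, Vi %*% r)) / (length(keep) - 2)
      beta[j] <- bh[2]
      se[j] <- sqrt(s2 * solve(xtvx)[2, 2])
    }
  }
  tstat <- beta / se
  p <- 2 * pt(-abs(tstat), n_used - 2)
  # monomorphic columns give det2 == 0; report NA
  bad <- !is.finite(tstat)
  p[bad] <- NA

  out <- data.frame(id = g$variants$id, chrom = g$variants$chrom,
                    pos = g$variants$pos, maf = folded_maf(g), n = n_used,
                    beta = beta, se = se, t = tstat, p = p,
                    stringsAsFactors = FALSE)
  attr(out, "delta") <- delta
  attr(out, "var_u") <- vu
  attr(out, "var_e") <- vu * delta
  class(out) <- c("assoc_scan", "data.frame")
  out
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise error rate.
#' @param m Number of tests (>= 1).
#' @return `alpha / m`.
#' @export
#' @examples
#' bonferroni_threshold(0.05, 2525695)
bonferroni_threshold <- function(alpha = 0.05, m) {
  if (m < 1) stop("m must be at least 1")
  alpha / m
}

#' Genomic inflation factor
#'
#' `lambda = median(chisq(p)) / qchisq(0.5, 1)` from two-sided p-values; 1
#' indicates a calibrated scan, > 1 inflation (e.g. unmodelled inversion
#' structure).
#'
#' @param p Vector of p-values.
#' @return Genomic lambda.
#' @export
genomic_lambda <- function(p) {
  p <- p[is.finite(p)]
  median(qchisq(p, df = 1, lower.tail = FALSE)) / qchisq(0.5, df = 1)
}

#' Assign variants to genes within a window
#'
#' A variant is assigned to every gene whose span, extended by `window` bp
#' on both sides, contains its position (1-based, inclusive; a variant
#' exactly `window` bp upstream of the start is assigned, `window + 1` is
#' not).  Variants with no assignment are labelled intergenic.
#'
#' @param records data.frame with id, chrom, pos (e.g. an `assoc_scan`).
#' @param genes data.frame with gene, chrom, start, end (1-based,
#'   inclusive).
#' @param window Assignment window in bp.
#' @return data.frame: id, chrom, pos, gene (NA and `intergenic = TRUE`
#'   for unassigned variants; one row per variant-gene pair otherwise).
#' @export
annotate_variants <- function(records, genes, window = 1000) {
  if (any(genes$start > genes$end)) stop("malformed gene intervals")
  if (window < 0) stop("window must be non-negative")
  gr_v <- GenomicRanges::GRanges(records$chrom,
                                 IRanges::IRanges(records$pos, records$pos))
  gr_g <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(pmax(1, genes$start - window),
                                                  genes$end + window))
  hits <- GenomicRanges::findOverlaps(gr_v, gr_g)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  assigned <- data.frame(id = records$id[qi], chrom = records$chrom[qi],
                         pos = records$pos[qi], gene = genes$gene[si],
                         intergenic = FALSE, stringsAsFactors = FALSE)
  rest <- setdiff(seq_len(nrow(records)), unique(qi))
  if (length(rest)) {
    assigned <- rbind(assigned, data.frame(
      id = records$id[rest], chrom = records$chrom[rest],
      pos = records$pos[rest], gene = NA_character_, intergenic = TRUE,
      stringsAsFactors = FALSE))
  }
  assigned[order(match(assigned$chrom, unique(records$chrom)), assigned$pos), ,
           drop = FALSE]
}

#' Overlap partition of two or three gene lists
#'
#' Exact set-intersection cardinalities: for two lists the shared count and
#' the count unique to each; for three lists all seven Venn cells.
#'
#' @param lists Named list of 2 or 3 character vectors of gene ids.
#' @return Named integer vector of cell counts.
#' @export
#' @examples
#' gene_overlap(list(A = c("a", "b", "c"), B = c("b", "c", "d")))
gene_overlap <- function(lists) {
  lists <- lapply(lists, unique)
  k <- length(lists)
  if (!k %in% c(2L, 3L)) stop("gene_overlap takes 2 or 3 lists")
  nm <- names(lists)
  if (is.null(nm)) nm <- LETTERS[seq_len(k)]
  if (k == 2L) {
    sh <- intersect(lists[[1]], lists[[2]])
    out <- c(length(sh), length(setdiff(lists[[1]], lists[[2]])),
             length(setdiff(lists[[2]], lists[[1]])))
    names(out) <- c("shared", paste0("unique_", nm))
    return(out)
  }
  all_ids <- unique(unlist(lists))
  member <- sapply(lists, function(s) all_ids %in% s)
  cell <- apply(member, 1, function(z) paste(nm[z], collapse = "&"))
  cells <- c(nm, paste(nm[1], nm[2], sep = "&"), paste(nm[1], nm[3], sep = "&"),
             paste(nm[2], nm[3], sep = "&"), paste(nm, collapse = "&"))
  out <- vapply(cells, function(cl) sum(cell == cl), integer(1))
  names(out) <- cells
  out
}
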