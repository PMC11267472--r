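# Line-level quantitative genetics of mating success.

#' Line means of replicate-level mating proportions
#'
#' Each replicate contributes `n_mated / n_females`; the line mean is the
#' unweighted average over replicates (the "line mean" that downstream
#' correlations, karyotype fits and association scans consume).
#'
#' @param pheno A phenotype table (line, replicate, n_females, n_mated,
#'   window_min), e.g. from [simulate_line_phenotypes()] or
#'   [read_phenotypes()].
#' @param window Optional observation window (minutes) to subset on; by
#'   default all records are used.
#' @return data.frame: line, n_replicates, mean (plus the per-replicate
#'   proportions as attribute `"replicates"`).
#' @export
line_means <- function(pheno, window = NULL) {
  if (!is.null(window)) {
    pheno <- pheno[pheno$window_min == window, , drop = FALSE]
    if (!nrow(pheno)) stop(sprintf("no records at window %s min", window))
  }
  if (any(pheno$n_females <= 0)) stop("every record needs n_females > 0")
  p <- pheno$n_mated / pheno$n_females
  sp <- split(p, pheno$line)
  out <- data.frame(line = names(sp),
                    n_replicates = lengths(sp),
                    mean = vapply(sp, mean, numeric(1)),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "replicates") <- sp
  out
}

# -2 * restricted log-likelihood (up to an additive constant shared between
# the full and the null model) of the one-way random-effects model, given
# the variance ratio lambda = var_g / var_e.  Works from per-line
# sufficient statistics; the error variance is profiled out in closed form.
.one_way_m2rll <- function(lambda, n_i, ybar_i, ssw, N) {
  u <- n_i / (1 + n_i * lambda)           # GLS weights up to 1/var_e
  mu <- sum(u * ybar_i) / sum(u)
  q <- ssw + sum(u * (ybar_i - mu)^2)     # quadratic form * var_e
  ve <- q / (N - 1)                        # REML profile estimate
  # log|V| = (N - L) log ve + sum log(ve (1 + n_i lambda));
  # log|X' V^-1 X| = log(sum u / ve)
  (N - length(n_i)) * log(ve) + sum(log(ve * (1 + n_i * lambda))) +
    log(sum(u) / ve) + q / ve
}

#' REML variance components and broad-sense heritability
#'
#' Fits the one-way random-effects model `y_ij = mu + g_i + e_ij` to
#' replicate-level mating proportions by REML, profiling the likelihood
#' over the single variance ratio (a bounded 1-D search, with the boundary
#' `var_g = 0` handled by clamping).  Broad-sense heritability is
#' `H2 = var_g / (var_g + var_e)`.  Significance of the genetic variance is
#' a restricted likelihood-ratio test against `var_g = 0` with the
#' boundary-corrected null, an equal mixture of a point mass at zero and
#' chi-square(1).
#'
#' @param pheno A phenotype table as in [line_means()].
#' @param window Optional window subset (minutes).
#' @param transform "none" (fit proportions directly) or "logit"
#'   (empirical logits with a 0.5-count continuity correction).
#' @return A `variance_components` list: var_g, var_e, H2, loglik_full,
#'   loglik_null (both as -2 * restricted LL up to a shared constant),
#'   lrt, p_value, n_lines, n_obs.
#' @export
#' @examples
#' ph <- simulate_line_phenotypes(50, 10, n_females = 50,
#'                                h2_target = 0.4, grand_mean = 0.5,
#'                                seed = 1)
#' estimate_h2(ph)$H2
estimate_h2 <- function(pheno, window = NULL,
                        transform = c("none", "logit")) {
  transform <- match.arg(transform)
  if (!is.null(window)) pheno <- pheno[pheno$window_min == window, , drop = FALSE]
  if (any(pheno$n_females <= 0)) stop("every record needs n_females > 0")
  y <- pheno$n_mated / pheno$n_females
  if (transform == "logit")
    y <- log((pheno$n_mated + 0.5) / (pheno$n_females - pheno$n_mated + 0.5))
  f <- factor(pheno$line)
  if (nlevels(f) < 2) stop("need at least 2 lines to partition variance")
  n_i <- as.numeric(table(f))
  if (all(n_i < 2)) stop("need replicate measurements within lines")
  ybar_i <- vapply(split(y, f), mean, numeric(1))
  ssw <- sum((y - ybar_i[as.integer(f)])^2)
  N <- length(y)

  obj <- function(log_lambda) .one_way_m2rll(exp(log_lambda), n_i, ybar_i, ssw, N)
  opt <- optimize(obj, c(-18, 12), tol = 1e-10)
  m2_0 <- .one_way_m2rll(0, n_i, ybar_i, ssw, N)
  if (m2_0 <= opt$objective) {   # boundary solution
    lambda <- 0; m2_full <- m2_0
  } else {
    lambda <- exp(opt$minimum); m2_full <- opt$objective
  }
  u <- n_i / (1 + n_i * lambda)
  mu <- sum(u * ybar_i) / sum(u)
  ve <- (ssw + sum(u * (ybar_i - mu)^2)) / (N - 1)
  vg <- lambda * ve
  lrt <- max(0, m2_0 - m2_full)
  p <- if (lrt <= 0) 1 else 0.5 * pchisq(lrt, df = 1, lower.tail = FALSE)
  structure(list(var_g = vg, var_e = ve, H2 = vg / (vg + ve), mean = mu,
                 loglik_full = -m2_full / 2, loglik_null = -m2_0 / 2,
                 lrt = lrt, p_value = p,
                 n_lines = nlevels(f), n_obs = N, transform = transform),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("One-way REML: var_g = %.4g, var_e = %.4g, H2 = %.3f\n",
              x$var_g, x$var_e, x$H2))
  cat(sprintf("  LRT(var_g = 0) = %.3f, p = %.3g (0.5 chisq(0) + 0.5 chisq(1))\n",
              x$lrt, x$p_value))
  cat(sprintf("  %d lines, %d observations\n", x$n_lines, x$n_obs))
  invisible(x)
}

#' Pearson correlation of line means between two traits
#'
#' Lines are inner-joined on their identifier; significance is the usual
#' two-sided t test, `t = r * sqrt((n - 2) / (1 - r^2))`.
#'
#' @param a,b Line-mean tables as returned by [line_means()] (columns
#'   `line` and `mean`), or named numeric vectors.
#' @return A `correlation_result` list: r, n, t, p_value.
#' @export
trait_correlation <- function(a, b) {
  as_lm <- function(x) {
    if (is.data.frame(x)) setNames(x$mean, x$line) else x
  }
  a <- as_lm(a); b <- as_lm(b)
  shared <- intersect(names(a), names(b))
  if (length(shared) < 3) stop("need at least 3 lines shared between traits")
  x <- a[shared]; y <- b[shared]
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance in one trait")
  ct <- stats::cor.test(x, y, method = "pearson")
  structure(list(r = unname(ct$estimate), n = length(shared),
                 t = unname(ct$statistic), p_value = ct$p.value),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f (n = %d lines, t = %.3f, p = %.3g)\n",
              x$r, x$n, x$t, x$p_value))
  invisible(x)
}

#' Effect of an inversion karyotype on line means
#'
#' One-way fixed-effect linear model of line means on karyotype class
#' (ST/ST, ST/INV, INV/INV).  Reports the overall F-test, per-class
#' least-squares means with t-based 95% confidence intervals, and pairwise
#' contrasts of each non-standard class against ST/ST.
#'
#' @param means Line-mean table ([line_means()]).
#' @param karyo Covariate table with a `line` column and one column per
#'   inversion holding karyotype classes.
#' @param inversion Name of the inversion column to test.
#' @param conf_level Confidence level for the class means.
#' @return A `karyotype_effect` list: p_overall, class table (class, n,
#'   lsmean, lower, upper), contrasts vs ST/ST (estimate, p_value), fit.
#' @export
karyotype_effect <- function(means, karyo, inversion, conf_level = 0.95) {
  if (!inversion %in% names(karyo))
    stop(sprintf("inversion '%s' not found in covariate table", inversion))
  kk <- karyo[match(means$line, karyo$line), inversion]
  if (anyNA(kk)) stop("karyotypes missing for some lines")
  cls <- factor(as.character(kk), levels = c("ST/ST", "ST/INV", "INV/INV"))
  cls <- droplevels(cls)
  if (nlevels(cls) < 2) stop("only one karyotype class present")
  fit <- lm(means$mean ~ cls)
  p_overall <- anova(fit)[["Pr(>F)"]][1]
  mse <- sum(residuals(fit)^2) / fit$df.residual
  tab <- data.frame(class = levels(cls),
                    n = as.integer(table(cls)),
                    lsmean = vapply(split(means$mean, cls), mean, numeric(1)))
  half <- stats::qt(1 - (1 - conf_level) / 2, fit$df.residual) *
    sqrt(mse / tab$n)
  tab$lower <- tab$lsmean - half
  tab$upper <- tab$lsmean + half
  cf <- summary(fit)$coefficients
  contrasts <- data.frame(
    class = levels(cls)[-1],
    estimate = cf[-1, "Estimate"],
    p_value = cf[-1, "Pr(>|t|)"],
    row.names = NULL
  )
  structure(list(inversion = inversion, p_overall = p_overall,
                 classes = tab, contrasts = contrasts, fit = fit),
            class = "karyotype_effect")
}

#' @export
print.karyotype_effect <- function(x, ...) {
  cat(sprintf("Karyotype effect of %s: overall F-test p = %.3g\n",
              x$inversion, x$p_overall))
  print(x$classes, row.names = FALSE)
  cat("contrasts vs ST/ST:\n")
  print(x$contrasts, row.names = FALSE)
  invisible(x)
}

#' Fisher exact test for a mating contrast
#'
#' Two-sided Fisher exact test of mated/unmated counts between a treatment
#' (e.g. an RNAi knockdown) and its control, summing hypergeometric
#' probabilities no larger than the observed table's.
#'
#' @param mated_a,unmated_a Counts for group A.
#' @param mated_b,unmated_b Counts for group B.
#' @return Two-sided p-value.
#' @export
#' @examples
#' fisher_mating_test(10, 40, 2, 48)
fisher_mating_test <- function(mated_a, unmated_a, mated_b, unmated_b) {
  counts <- c(mated_a, unmated_a, mated_b, unmated_b)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  tab <- matrix(counts, 2, 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || all(colSums(tab) == 0))
    stop("each group needs at least one fly and some outcome observed")
  fisher.test(tab)$p.value
}
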