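# Pooled-sequencing allele-frequency divergence tests.
#
# Each pool contributes a frequency estimate p = alt / (alt + ref) whose
# sampling variance has two parts: drawing 2n chromosomes into the pool
# (1 / 2n) and drawing c reads from the pool (1 / c), giving
# v = p (1 - p) (1 / 2n + 1 / c).  Replicates within a group are averaged;
# their variances are combined with weights proportional to sequencing
# depth, and the standardized difference of group means is referred to the
# standard normal.

# stack a list of pool_counts tables, tagging group and replicate
combine_pools <- function(pools, group) {
  stopifnot(length(pools) >= 1)
  out <- do.call(rbind, lapply(seq_along(pools), function(i) {
    p <- pools[[i]]
    p$group <- group
    p$replicate <- i
    p
  }))
  rownames(out) <- NULL
  out
}

# per-replicate frequency/variance/weight matrices for one group, rows =
# variants (keyed by chrom:pos), cols = replicates
.group_arrays <- function(pools, x_male = FALSE) {
  key <- paste(pools[[1]]$chrom, pools[[1]]$pos)
  n_rep <- length(pools)
  p <- v <- cc <- matrix(NA_real_, length(key), n_rep)
  for (r in seq_len(n_rep)) {
    pr <- pools[[r]]
    if (!identical(paste(pr$chrom, pr$pos), key))
      stop("pools must share an identical variant grid")
    cov <- pr$ref_count + pr$alt_count
    pf <- ifelse(cov > 0, pr$alt_count / cov, NA_real_)
    chrom_n <- if (x_male) pr$n_flies else 2 * pr$n_flies
    p[, r] <- pf
    v[, r] <- pf * (1 - pf) * (1 / chrom_n + 1 / cov)
    cc[, r] <- ifelse(cov > 0, cov, NA_real_)
  }
  list(key = key, p = p, v = v, cov = cc,
       chrom = pools[[1]]$chrom, pos = pools[[1]]$pos)
}

# core of the Z statistic, vectorized over variants; a and b are
# .group_arrays() for control (group 1) and high/selected (group 2)
.z_core <- function(a, b, mode = c("literal", "delta"), z_max = 50) {
  mode <- match.arg(mode)
  wsum <- function(x, w) rowSums(x * w, na.rm = TRUE)
  norm_w <- function(cc) {
    tot <- rowSums(cc, na.rm = TRUE)
    sweep(cc, 1, tot, "/")
  }
  wa <- norm_w(a$cov); wb <- norm_w(b$cov)
  if (mode == "literal") {
    p1 <- rowMeans(a$p, na.rm = TRUE)
    p2 <- rowMeans(b$p, na.rm = TRUE)
    var_z <- wsum(a$v, wa) + wsum(b$v, wb)
  } else {
    p1 <- wsum(a$p, wa)
    p2 <- wsum(b$p, wb)
    var_z <- wsum(a$v, wa^2) + wsum(b$v, wb^2)
  }
  used1 <- rowSums(!is.na(a$p)); used2 <- rowSums(!is.na(b$p))
  z <- rep(NA_real_, length(p1))
  ok <- used1 > 0 & used2 > 0
  dz <- p2 - p1
  pos_var <- ok & var_z > 0
  z[pos_var] <- dz[pos_var] / sqrt(var_z[pos_var])
  degen <- ok & var_z <= 0
  z[degen] <- ifelse(dz[degen] == 0, 0, sign(dz[degen]) * z_max)
  if (any(degen & dz != 0, na.rm = TRUE))
    warning("variants with zero sampling variance but nonzero difference; ",
            "|Z| clamped to ", z_max)
  z <- clamp(z, -z_max, z_max)
  list(p1 = p1, p2 = p2, z = z, p = 2 * pnorm(-abs(z)),
       used1 = used1, used2 = used2, skipped = !ok)
}

#' Pooled allele-frequency Z statistic for one variant
#'
#' Standardizes the difference of mean allele frequency between a
#' high/selected group and a control group of sequencing pools:
#' `Z = (p2bar - p1bar) / sqrt(sum w2 v2 + sum w1 v1)` with per-replicate
#' variance `v = p (1 - p) (1 / 2n + 1 / c)` and depth-proportional
#' weights `w = c / sum(c)` within each group.  In `mode = "literal"` the
#' group means are unweighted replicate means and the variance combines
#' single-power weights (the printed form of the test); `mode = "delta"`
#' uses depth-weighted means with squared-weight (delta-method) variance.
#' The two modes coincide when replicate depths within a group are equal.
#' P-values are two-sided from the standard normal.
#'
#' @param high List of `pool_counts` replicates for the high/selected
#'   group.
#' @param control List of `pool_counts` replicates for the control group.
#' @param variant Variant selector: index into the shared grid, or
#'   "chrom:pos" string; NULL returns all variants (see [xqtl_scan()]).
#' @param mode "literal" or "delta".
#' @param x_male Treat pools as male X chromosomes (n rather than 2n
#'   chromosomes per pool).
#' @param z_max Clamp for degenerate zero-variance variants.
#' @return One-row data.frame: chrom, pos, p1_bar, p2_bar, z, p,
#'   n_rep_high, n_rep_control.
#' @export
#' @examples
#' h <- data.frame(chrom = "2L", pos = 1, ref = "A", alt = "T",
#'                 pool_id = "h1", ref_count = 60, alt_count = 40,
#'                 n_flies = 50)
#' c0 <- transform(h, pool_id = "c1", ref_count = 80, alt_count = 20)
#' z_statistic(list(h), list(c0), 1)$z  # 2.236
z_statistic <- function(high, control, variant = 1, mode = "literal",
                        x_male = FALSE, z_max = 50) {
  if (inherits(high, "data.frame")) high <- list(high)
  if (inherits(control, "data.frame")) control <- list(control)
  a <- .group_arrays(control, x_male)
  b <- .group_arrays(high, x_male)
  i <- if (is.character(variant)) match(variant, gsub(" ", ":", a$key)) else variant
  if (is.na(i) || i < 1 || i > length(a$key)) stop("variant not found")
  sub <- function(g) list(p = g$p[i, , drop = FALSE], v = g$v[i, , drop = FALSE],
                          cov = g$cov[i, , drop = FALSE])
  zz <- .z_core(sub(a), sub(b), mode, z_max)
  if (zz$skipped) stop("no replicate with positive coverage in one group")
  data.frame(chrom = a$chrom[i], pos = a$pos[i],
             p1_bar = zz$p1, p2_bar = zz$p2, z = zz$z, p = zz$p,
             n_rep_high = zz$used2, n_rep_control = zz$used1,
             stringsAsFactors = FALSE)
}

#' Genome-wide pooled divergence scan (xQTL)
#'
#' Applies [z_statistic()] to every variant on the shared grid of the
#' replicate pools.  Replicates with zero coverage at a variant are
#' dropped for that variant; variants with no covered replicate in either
#' group are skipped and reported with reason "no coverage".
#'
#' @inheritParams z_statistic
#' @param report_threshold P-value below which a variant is flagged in
#'   the `hit` column (the scan's candidate-reporting cut-off, 1e-5).
#' @return An `xqtl_scan` data.frame: chrom, pos, p1_bar, p2_bar, z, p,
#'   hit; skipped variants carried with NA statistics and attribute
#'   `skipped`.
#' @export
xqtl_scan <- function(high, control, mode = "literal",
                      report_threshold = 1e-5, x_male = FALSE, z_max = 50) {
  if (inherits(high, "data.frame")) high <- list(high)
  if (inherits(control, "data.frame")) control <- list(control)
  if (!length(high) || !length(control)) stop("each group needs >= 1 pool")
  a <- .group_arrays(control, x_male)
  b <- .group_arrays(high, x_male)
  zz <- .z_core(a, b, mode, z_max)
  out <- data.frame(chrom = a$chrom, pos = a$pos,
                    p1_bar = zz$p1, p2_bar = zz$p2, z = zz$z, p = zz$p,
                    hit = !is.na(zz$p) & zz$p < report_threshold,
                    stringsAsFactors = FALSE)
  out$p1_bar[zz$skipped] <- NA; out$p2_bar[zz$skipped] <- NA
  out$z[zz$skipped] <- NA; out$p[zz$skipped] <- NA
  attr(out, "skipped") <- data.frame(
    chrom = a$chrom[zz$skipped], pos = a$pos[zz$skipped],
    reason = rep("no coverage", sum(zz$skipped)), stringsAsFactors = FALSE)
  attr(out, "mode") <- mode
  class(out) <- c("xqtl_scan", "data.frame")
  out
}

#' All-pairs divergence rule for unpaired selection pools
#'
#' When selected and control pools are not paired replicates (the
#' multi-generation selection design), every selected x control pair is
#' tested separately with the single-pair Z statistic, and a variant
#' passes only if its weakest pair — the largest p-value, i.e. the
#' smallest |Z| — is still beyond the threshold.
#'
#' @param selected,control Lists of `pool_counts` (one per population).
#' @param threshold P-value the weakest pair must beat.
#' @param mode,x_male,z_max As in [z_statistic()].
#' @return data.frame: chrom, pos, n_pairs, min_abs_z, max_p, pass; all
#'   per-pair statistics in attribute `pairs`.
#' @export
allpairs_divergence <- function(selected, control, threshold = 1e-5,
                                mode = "literal", x_male = FALSE,
                                z_max = 50) {
  if (inherits(selected, "data.frame")) selected <- list(selected)
  if (inherits(control, "data.frame")) control <- list(control)
  if (!length(selected) || !length(control)) stop("each group needs >= 1 pool")
  grid <- NULL
  pair_stats <- list()
  for (i in seq_along(selected)) for (j in seq_along(control)) {
    sc <- xqtl_scan(selected[i], control[j], mode = mode,
                    report_threshold = threshold, x_male = x_male,
                    z_max = z_max)
    sc$pair <- sprintf("sel%d_vs_ctl%d", i, j)
    pair_stats[[length(pair_stats) + 1L]] <- sc
    if (is.null(grid)) grid <- sc[, c("chrom", "pos")]
  }
  pm <- sapply(pair_stats, `[[`, "p")
  zm <- sapply(pair_stats, `[[`, "z")
  if (is.null(dim(pm))) { pm <- matrix(pm, nrow = 1); zm <- matrix(zm, nrow = 1) }
  max_p <- apply(pm, 1, function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE))
  min_z <- apply(abs(zm), 1, function(x) if (all(is.na(x))) NA_real_ else min(x, na.rm = TRUE))
  any_na <- apply(pm, 1, anyNA)
  out <- data.frame(chrom = grid$chrom, pos = grid$pos,
                    n_pairs = length(pair_stats),
                    min_abs_z = min_z, max_p = max_p,
                    pass = !any_na & !is.na(max_p) & max_p < threshold,
                    stringsAsFactors = FALSE)
  attr(out, "pairs") <- do.call(rbind, pair_stats)
  out
}
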