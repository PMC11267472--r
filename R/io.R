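# Readers and writers for the on-disk formats: genotypes (VCF or dosage
# TSV), replicate-level phenotypes, line covariates, sync-style pooled
# counts and selection trajectories.  All writers emit a deterministic
# column order, rows sorted by (chrom, pos) where applicable, and a header
# comment carrying the tool version and a config hash.

.write_tsv <- function(df, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# matescan %s%s", packageVersion("matescan"),
                     if (is.null(comment)) "" else paste0(" ", comment)),
             con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read genotypes from VCF or dosage TSV
#'
#' VCF: GT fields are converted to dosages (inbred convention: 0/0 -> 0,
#' 1/1 -> 2, ./. -> missing); heterozygous calls in an inbred panel are
#' set missing by default, or kept as 1.  Dosage TSV: columns chrom, pos,
#' id, ref, alt, then one dosage column per line.
#'
#' @param path File path (.vcf / .vcf.gz or .tsv).
#' @param het One of "missing" or "dosage" — treatment of heterozygous
#'   VCF calls.
#' @return A `genotype_matrix`.
#' @export
read_genotypes <- function(path, het = c("missing", "dosage")) {
  het <- match.arg(het)
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")
    gt <- gsub("\\|", "/", gt)
    d <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
    d[gt == "0/0"] <- 0
    d[gt == "1/1"] <- 2
    d[gt %in% c("0/1", "1/0")] <- if (het == "dosage") 1 else NA_real_
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    variants <- data.frame(
      id = ifelse(is.na(fix$ID) | fix$ID == ".",
                  sprintf("%s_%s", fix$CHROM, fix$POS), fix$ID),
      chrom = fix$CHROM, pos = as.integer(fix$POS),
      ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
    genotype_matrix(t(d), variants)
  } else {
    df <- .read_tsv(path)
    meta <- c("chrom", "pos", "id", "ref", "alt")
    if (!all(meta %in% names(df)))
      stop("dosage TSV needs columns: ", paste(meta, collapse = ", "))
    lines <- setdiff(names(df), meta)
    d <- t(as.matrix(df[, lines, drop = FALSE]))
    rownames(d) <- lines
    genotype_matrix(d, df[, meta[c(3, 1, 2, 4, 5)]][
      , c("id", "chrom", "pos", "ref", "alt")])
  }
}

#' Write genotypes as dosage TSV or minimal VCF
#'
#' The VCF writer emits diploid GT calls (0 -> 0/0, 1 -> 0/1, 2 -> 1/1,
#' NA -> ./.), which round-trips through [read_genotypes()].
#'
#' @param g A `genotype_matrix`.
#' @param path Output path; format chosen by extension (.vcf vs .tsv).
#' @param comment Extra text for the TSV header comment.
#' @return The path, invisibly.
#' @export
write_genotypes <- function(g, path, comment = NULL) {
  o <- order(match(g$variants$chrom, unique(g$variants$chrom)),
             g$variants$pos)
  v <- g$variants[o, , drop = FALSE]
  d <- g$dosage[, o, drop = FALSE]
  if (grepl("\\.vcf$", path)) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("##fileformat=VCFv4.2",
                 sprintf("##source=matescan_%s", packageVersion("matescan")),
                 '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
                 paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                         "FILTER", "INFO", "FORMAT", rownames(d)),
                       collapse = "\t")), con)
    gt_code <- c("0/0", "0/1", "1/1")
    for (j in seq_len(nrow(v))) {
      gt <- ifelse(is.na(d[, j]), "./.", gt_code[d[, j] + 1])
      writeLines(paste(c(v$chrom[j], v$pos[j], v$id[j], v$ref[j], v$alt[j],
                         ".", "PASS", ".", "GT", gt), collapse = "\t"), con)
    }
  } else {
    df <- cbind(v[, c("chrom", "pos", "id", "ref", "alt")],
                as.data.frame(t(d)))
    .write_tsv(df, path, comment)
  }
  invisible(path)
}

#' Read/write replicate-level phenotype tables
#'
#' TSV columns: line, replicate, n_females, n_mated, window_min.
#'
#' @param path File path.
#' @return A `phenotypes` data.frame.
#' @export
read_phenotypes <- function(path) {
  df <- .read_tsv(path)
  need <- c("line", "replicate", "n_females", "n_mated", "window_min")
  if (!all(need %in% names(df)))
    stop("phenotype TSV needs columns: ", paste(need, collapse = ", "))
  if (any(df$n_mated < 0 | df$n_mated > df$n_females))
    stop("n_mated must lie in [0, n_females]")
  df$proportion <- df$n_mated / df$n_females
  structure(df, class = c("phenotypes", "data.frame"))
}

#' @rdname read_phenotypes
#' @param pheno A phenotype table.
#' @param comment Extra header text.
#' @export
write_phenotypes <- function(pheno, path, comment = NULL) {
  .write_tsv(pheno[, c("line", "replicate", "n_females", "n_mated",
                       "window_min")], path, comment)
}

#' Read/write line covariate tables
#'
#' TSV columns: line, wolbachia (y/n), then one column per inversion with
#' karyotype classes ST/ST, ST/INV, INV/INV.
#'
#' @param path File path.
#' @return data.frame with logical `wolbachia`.
#' @export
read_covariates <- function(path) {
  df <- .read_tsv(path)
  if (!all(c("line", "wolbachia") %in% names(df)))
    stop("covariate TSV needs 'line' and 'wolbachia' columns")
  df$wolbachia <- df$wolbachia %in% c("y", "yes", "TRUE", "1")
  bad <- lapply(setdiff(names(df), c("line", "wolbachia")), function(cl)
    setdiff(unique(df[[cl]]), c("ST/ST", "ST/INV", "INV/INV")))
  if (length(unlist(bad)))
    stop("unknown karyotype classes: ", paste(unlist(bad), collapse = ", "))
  df
}

#' @rdname read_covariates
#' @param panel A `founder_panel` whose karyotype/Wolbachia data to write,
#'   or a ready covariate data.frame.
#' @param comment Extra header text.
#' @export
write_covariates <- function(panel, path, comment = NULL) {
  df <- if (inherits(panel, "founder_panel")) {
    cbind(data.frame(line = panel$karyotypes$line,
                     wolbachia = ifelse(panel$wolbachia, "y", "n"),
                     stringsAsFactors = FALSE),
          panel$karyotypes[, -1, drop = FALSE])
  } else panel
  .write_tsv(df, path, comment)
}

#' Read/write sync-style pooled allele counts
#'
#' TSV columns: chrom, pos, ref, alt, pool_id, ref_count, alt_count,
#' n_flies (one row per pool per variant).  An optional `coverage` column
#' is checked against ref_count + alt_count.
#'
#' @param path File path.
#' @return Named list of `pool_counts` data.frames, one per pool_id.
#' @export
read_pool_counts <- function(path) {
  df <- .read_tsv(path)
  need <- c("chrom", "pos", "ref", "alt", "pool_id", "ref_count",
            "alt_count", "n_flies")
  if (!all(need %in% names(df)))
    stop("pool count TSV needs columns: ", paste(need, collapse = ", "))
  if (any(df$ref_count < 0 | df$alt_count < 0 | df$n_flies <= 0))
    stop("negative counts or empty pools in ", path)
  if (any(df$ref_count != round(df$ref_count) |
            df$alt_count != round(df$alt_count)))
    stop("counts must be integral")
  if ("coverage" %in% names(df) &&
        any(df$coverage != df$ref_count + df$alt_count))
    stop("coverage column disagrees with ref_count + alt_count")
  lapply(split(df[, need], df$pool_id), function(p) {
    rownames(p) <- NULL
    structure(p, class = c("pool_counts", "data.frame"))
  })
}

#' @rdname read_pool_counts
#' @param pools A `pool_counts` data.frame or list of them.
#' @param comment Extra header text.
#' @export
write_pool_counts <- function(pools, path, comment = NULL) {
  if (inherits(pools, "data.frame")) pools <- list(pools)
  df <- do.call(rbind, lapply(pools, function(p)
    p[, c("chrom", "pos", "ref", "alt", "pool_id", "ref_count",
          "alt_count", "n_flies")]))
  df <- df[order(df$pool_id, match(df$chrom, unique(df$chrom)), df$pos), ]
  rownames(df) <- NULL
  .write_tsv(df, path, comment)
}

#' Read a selection trajectory table
#'
#' TSV columns: generation, population_id, role (selected/control),
#' n_assayed, n_mated; proportions are n_mated / n_assayed.
#'
#' @param path File path.
#' @return List of data.frames `selected` and `control` in the layout
#'   [deviation_trajectory()] expects.
#' @export
read_trajectories <- function(path) {
  df <- .read_tsv(path)
  need <- c("generation", "population_id", "role", "n_assayed", "n_mated")
  if (!all(need %in% names(df)))
    stop("trajectory TSV needs columns: ", paste(need, collapse = ", "))
  df$proportion <- df$n_mated / df$n_assayed
  df$replicate <- df$population_id
  list(selected = df[df$role == "selected",
                     c("generation", "replicate", "proportion")],
       control = df[df$role == "control",
                    c("generation", "replicate", "proportion")])
}
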