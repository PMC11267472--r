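# Configuration-driven pipeline driver chaining the package's stages into
# the three screens (inbred-panel GWA, single-generation xQTL, selection
# divergence) plus a simulator stage, with per-stage seeds derived from a
# master seed and a plain-text provenance log.

#' Load a run configuration
#'
#' YAML or JSON file, or a list passed through.  Must contain a `seed` and
#' an `out_dir`; stage parameters are optional and fall back to the
#' package defaults.
#'
#' @param config Path or list.
#' @return Validated config list.
#' @export
load_config <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  if (is.null(config$seed)) stop("config needs an explicit seed")
  if (is.null(config$out_dir)) stop("config needs an out_dir")
  config
}

.log_line <- function(con, ...) {
  kv <- c(...)
  writeLines(paste(names(kv), unname(kv), sep = "=", collapse = " "), con)
}

#' Run a pipeline screen from a configuration
#'
#' Screens:
#' \describe{
#'   \item{simulate}{Founder panel + replicate phenotypes; writes
#'     genotypes.tsv, genotypes.vcf, phenotypes.tsv, covariates.tsv.}
#'   \item{dgrp-gwa}{Line means, covariate adjustment, MAF filter, GRM,
#'     mixed-model scan, optional gene annotation; writes gwa.tsv.}
#'   \item{xqtl}{Replicated pooled Z scan; writes xqtl.tsv.}
#'   \item{divergence}{Unpaired all-pairs rule; writes divergence.tsv.}
#'   \item{response}{Deviation trajectories and response regression;
#'     writes response.tsv.}
#' }
#' Every stochastic stage receives a seed derived from the master seed via
#' [derive_seed()], so identical configs give identical outputs; a
#' provenance log (run.log, key=value lines) records versions, seeds and
#' parameters.
#'
#' @param config Config list or file (see [load_config()]).
#' @param screen One of "simulate", "dgrp-gwa", "xqtl", "divergence",
#'   "response".
#' @return Named list of output paths, invisibly.
#' @export
run_pipeline <- function(config, screen = c("simulate", "dgrp-gwa", "xqtl",
                                            "divergence", "response")) {
  screen <- match.arg(screen)
  cfg <- load_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  # hash the scientific parameters only; the output location is not part
  # of the run's identity
  hashed <- cfg[setdiff(sort(names(cfg)), "out_dir")]
  cfg_hash <- fnv1a32(paste(deparse(hashed), collapse = ""))
  note <- sprintf("config=%s seed=%s screen=%s", cfg_hash, cfg$seed, screen)
  log_path <- file.path(cfg$out_dir, "run.log")
  con <- file(log_path, "a")
  on.exit(close(con))
  .log_line(con, screen = screen, version = as.character(packageVersion("matescan")),
            seed = cfg$seed, config_hash = cfg_hash)
  get_par <- function(name, default) {
    if (is.null(cfg[[name]])) default else cfg[[name]]
  }
  out <- switch(screen,
    "simulate" = {
      panel <- simulate_founders(
        n_lines = get_par("n_lines", 40),
        n_variants = get_par("n_variants", 1000),
        wolbachia_rate = get_par("wolbachia_rate", 0.5),
        seed = derive_seed(cfg$seed, "founders"))
      ph <- simulate_line_phenotypes(
        n_lines = nrow(panel$genotypes),
        replicates = get_par("replicates", 10),
        n_females = get_par("n_females", 5),
        h2_target = get_par("h2_target", 0.27),
        grand_mean = get_par("grand_mean", 0.05),
        window = get_par("assay_window", 120),
        seed = derive_seed(cfg$seed, "phenotypes"))
      ph$line <- rep(panel$karyotypes$line,
                     each = get_par("replicates", 10))
      paths <- list(
        genotypes_tsv = file.path(cfg$out_dir, "genotypes.tsv"),
        genotypes_vcf = file.path(cfg$out_dir, "genotypes.vcf"),
        phenotypes = file.path(cfg$out_dir, "phenotypes.tsv"),
        covariates = file.path(cfg$out_dir, "covariates.tsv"))
      g <- genotype_matrix(panel$genotypes, panel$variants)
      write_genotypes(g, paths$genotypes_tsv, note)
      write_genotypes(g, paths$genotypes_vcf)
      write_phenotypes(ph, paths$phenotypes, note)
      write_covariates(panel, paths$covariates, note)
      paths
    },
    "dgrp-gwa" = {
      ph <- read_phenotypes(cfg$pheno)
      g <- read_genotypes(cfg$geno)
      cov <- read_covariates(cfg$covar)
      lm_tab <- line_means(ph, window = get_par("assay_window", NULL))
      adj <- adjust_phenotype(lm_tab, cov,
                              adjust_inversions = get_par("adjust_inversions",
                                                          TRUE))
      g <- maf_filter(g, get_par("maf_threshold", 0.02))
      scan <- lmm_association(adj, g)
      scan$bonferroni <- bonferroni_threshold(get_par("alpha", 0.05),
                                              nrow(scan))
      scan$candidate <- scan$p < get_par("report_threshold", 1e-5)
      if (!is.null(cfg$genes)) {
        genes <- .read_tsv(cfg$genes)
        ann <- annotate_variants(scan, genes, get_par("gene_window", 1000))
        gcol <- vapply(scan$id, function(i) {
          gg <- ann$gene[ann$id == i & !ann$intergenic]
          if (length(gg)) paste(gg, collapse = ",") else "intergenic"
        }, character(1))
        scan$genes <- gcol
      }
      path <- file.path(cfg$out_dir, "gwa.tsv")
      .write_tsv(scan[order(match(scan$chrom, unique(scan$chrom)),
                            scan$pos), ], path, note)
      .log_line(con, n_variants = nrow(scan),
                delta = signif(attr(scan, "delta"), 6))
      list(gwa = path)
    },
    "xqtl" = {
      high <- unlist(lapply(cfg$high, read_pool_counts), recursive = FALSE)
      control <- unlist(lapply(cfg$control, read_pool_counts),
                        recursive = FALSE)
      scan <- xqtl_scan(high, control, mode = get_par("z_mode", "literal"),
                        report_threshold = get_par("report_threshold", 1e-5))
      path <- file.path(cfg$out_dir, "xqtl.tsv")
      .write_tsv(scan, path, note)
      list(xqtl = path)
    },
    "divergence" = {
      sel <- unlist(lapply(cfg$selected, read_pool_counts),
                    recursive = FALSE)
      ctl <- unlist(lapply(cfg$control, read_pool_counts),
                    recursive = FALSE)
      div <- allpairs_divergence(sel, ctl,
                                 threshold = get_par("report_threshold",
                                                     1e-5),
                                 mode = get_par("z_mode", "literal"))
      path <- file.path(cfg$out_dir, "divergence.tsv")
      .write_tsv(div, path, note)
      list(divergence = path)
    },
    "response" = {
      tr <- read_trajectories(cfg$trajectories)
      traj <- deviation_trajectory(tr$selected, tr$control)
      reg <- response_regression(traj)
      path <- file.path(cfg$out_dir, "response.tsv")
      .write_tsv(reg, path, note)
      list(response = path)
    })
  .log_line(con, status = "ok", outputs = paste(unlist(out), collapse = ","))
  invisible(out)
}
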