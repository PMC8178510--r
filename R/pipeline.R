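#' Assemble and validate a pipeline configuration
#'
#' The configuration is a flat, serializable source of truth for one run:
#' input paths, every stage threshold, the seed and the output directory.
#' It can be built in code or loaded from a YAML file; [run_pipeline()]
#' snapshots it next to the results so a run is reproducible from its own
#' output directory.
#'
#' @param inputs named list of paths: `genotypes` (VCF), `mirna`, `mrna`
#'   (RPM TSVs, samples x features), `features` (GFF3/BED),
#'   `covariates`, `cnv`, `cpg`, `survival`, `groups` (TSVs), and
#'   optionally `candidates` (TSV `gene_id`, `integrated_score`).
#' @param out_dir output directory for stage reports.
#' @param qc a [qc_thresholds()].
#' @param funnel a [funnel_thresholds()].
#' @param cis_window cis window half-width in bp.
#' @param cis_fdr FDR threshold for calling significant cis associations.
#' @param prep_max_absent,prep_sd_limit expression preparation settings.
#' @param de_fc,de_q,de_group_max_absent miRNA differential-expression
#'   settings.
#' @param seed integer seed recorded in the manifest (the stages
#'   themselves are deterministic).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(inputs, out_dir,
                            qc = qc_thresholds(),
                            funnel = funnel_thresholds(),
                            cis_window = 1e6, cis_fdr = 0.1,
                            prep_max_absent = 20, prep_sd_limit = 3,
                            de_fc = 2, de_q = 0.01,
                            de_group_max_absent = 10, seed = 1L) {
  structure(list(inputs = inputs, out_dir = out_dir, qc = qc,
                 funnel = funnel, cis_window = cis_window,
                 cis_fdr = cis_fdr, prep_max_absent = prep_max_absent,
                 prep_sd_limit = prep_sd_limit, de_fc = de_fc,
                 de_q = de_q, de_group_max_absent = de_group_max_absent,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path a YAML file with keys `inputs`, `out_dir` and (optionally)
#'   any threshold accepted by [pipeline_config()], with `qc` and
#'   `funnel` given as nested key-value maps.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  qc <- do.call(qc_thresholds, y$qc %||% list())
  funnel <- do.call(funnel_thresholds, y$funnel %||% list())
  args <- y[setdiff(names(y), c("qc", "funnel"))]
  args$qc <- qc
  args$funnel <- funnel
  do.call(pipeline_config, args)
}

validate_pipeline_config <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  required <- c("genotypes", "mirna", "mrna", "features", "covariates",
                "cnv", "cpg", "survival", "groups")
  miss <- setdiff(required, names(config$inputs))
  if (length(miss) > 0L) {
    stop("pipeline validation: missing input path(s): ",
         paste(miss, collapse = ", "))
  }
  for (nm in intersect(c(required, "candidates"), names(config$inputs))) {
    path <- config$inputs[[nm]]
    if (!file.exists(path)) {
      stop("pipeline validation: input '", nm, "' does not exist: ", path)
    }
  }
  invisible(TRUE)
}

#' Run the screening pipeline end to end
#'
#' Executes, in fixed order: genotype QC, expression preparation, the
#' covariate-adjusted cis-eQTL scan, miRNA differential expression,
#' instrumental-variable target regression (instruments = significant cis
#' associations at the configured FDR), mRNA differential expression and
#' the median-split survival screen, and the five-criterion candidate
#' funnel. Each stage writes its TSV report into `out_dir`; a manifest
#' with per-file checksums and stage counts is written last. With the
#' same configuration and inputs, all result files are bit-identical
#' across runs (the manifest carries the only timestamp).
#'
#' @param config a [pipeline_config()] or path to a YAML file.
#' @return The manifest data.frame, invisibly; stage results are attached
#'   as attribute `"results"`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  validate_pipeline_config(config)
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  p <- function(f) file.path(out, f)
  counts <- list()
  emitted <- character(0)
  emit <- function(df, file) {
    write_tsv(df, p(file))
    emitted <<- c(emitted, file)
  }

  # --- genotype QC ---
  genotypes <- read_vcf(config$inputs$genotypes)
  qc_geno <- filter_variants(genotypes, config$qc)
  emit(attr(qc_geno, "qc_report"), "qc_report.tsv")
  write_vcf(qc_geno, p("qc_genotypes.vcf"))
  emitted <- c(emitted, "qc_genotypes.vcf")
  counts$qc_variants_in <- nrow(genotypes$variants)
  counts$qc_variants_out <- nrow(qc_geno$variants)

  # --- expression preparation ---
  coords <- read_feature_coords(config$inputs$features)
  mirna_rpm <- read_expression_tsv(config$inputs$mirna)
  mrna_rpm <- read_expression_tsv(config$inputs$mrna)
  mirna <- prepare_expression(mirna_rpm, config$prep_max_absent,
                              config$prep_sd_limit, coords)
  mrna <- prepare_expression(mrna_rpm, max_absent = nrow(mrna_rpm),
                             sd_limit = config$prep_sd_limit, coords)
  prov <- attr(mirna, "provenance")
  emit(prov$masked, "prep_masked.tsv")
  emit(prov$dropped, "prep_dropped.tsv")
  counts$mirna_features <- length(mirna$feature_ids)
  counts$mrna_features <- length(mrna$feature_ids)

  covs <- read_tsv(config$inputs$covariates)
  cnv <- read_expression_tsv(config$inputs$cnv)
  cpg <- read_expression_tsv(config$inputs$cpg)
  covariates <- covariate_table(covs$sample_id, covs$age, covs$sex,
                                cnv, cpg)
  groups <- read_tsv(config$inputs$groups)
  group_labels <- groups$group[match(mirna$sample_ids, groups$sample_id)]

  # --- cis-eQTL scan ---
  cis <- scan_cis(qc_geno, mirna, covariates, config$cis_window)
  emit(as.data.frame(cis), "cis_associations.tsv")
  sig_cis <- cis[!is.na(cis$q_value) & cis$q_value <= config$cis_fdr, ,
                 drop = FALSE]
  counts$cis_pairs_tested <- nrow(cis)
  counts$cis_significant <- nrow(sig_cis)
  counts$cis_esnps <- length(unique(sig_cis$snp_id))
  counts$cis_emirs <- length(unique(sig_cis$mirna_id))

  # --- miRNA differential expression ---
  de_mirna <- differential_test(mirna, group_labels, config$de_fc,
                                config$de_q, config$de_group_max_absent)
  emit(as.data.frame(de_mirna), "de_mirna.tsv")
  counts$de_mirna_called <- sum(de_mirna$called)

  # --- instrumental-variable target regression ---
  iv <- iv_scan(sig_cis, qc_geno, mirna, mrna)
  emit(iv, "iv_results.tsv")
  counts$iv_axes <- nrow(iv)

  # --- mRNA differential expression and survival screen ---
  de_mrna <- differential_test(mrna, group_labels,
                               fc_threshold = 2^config$funnel$de_lfc,
                               q_threshold = config$funnel$de_q,
                               group_max_absent = nrow(mrna$values))
  emit(as.data.frame(de_mrna), "de_mrna.tsv")
  survival_tab <- read_tsv(config$inputs$survival)
  surv <- survival_screen(mrna, survival_tab)
  emit(surv, "survival_screen.tsv")

  # --- candidate funnel ---
  candidates <- if (!is.null(config$inputs$candidates)) {
    read_tsv(config$inputs$candidates)
  } else {
    data.frame(gene_id = mrna$feature_ids, integrated_score = 1,
               stringsAsFactors = FALSE)
  }
  candidates$present_calls <- colSums(mrna$present)[
    match(candidates$gene_id, mrna$feature_ids)]
  funnel <- run_funnel(candidates, iv, de_mrna, surv, config$funnel)
  emit(funnel$stages, "funnel_stages.tsv")
  emit(funnel$genes, "funnel_genes.tsv")
  counts$funnel_survivors <- length(funnel$survivors)

  # --- manifest ---
  snapshot <- p("config_snapshot.yaml")
  yaml::write_yaml(list(
    inputs = config$inputs, out_dir = config$out_dir,
    qc = unclass(config$qc), funnel = unclass(config$funnel),
    cis_window = config$cis_window, cis_fdr = config$cis_fdr,
    prep_max_absent = config$prep_max_absent,
    prep_sd_limit = config$prep_sd_limit, de_fc = config$de_fc,
    de_q = config$de_q,
    de_group_max_absent = config$de_group_max_absent,
    seed = config$seed), snapshot)
  manifest <- data.frame(
    file = emitted,
    md5 = unname(tools::md5sum(vapply(emitted, p, character(1)))),
    stringsAsFactors = FALSE
  )
  manifest_meta <- data.frame(
    key = c("version", "seed", "timestamp",
            paste0("count_", names(counts))),
    value = c(as.character(utils::packageVersion("eqtlmr")),
              as.character(config$seed),
              format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
              vapply(counts, as.character, character(1))),
    stringsAsFactors = FALSE
  )
  write_tsv(manifest, p("manifest.tsv"))
  write_tsv(manifest_meta, p("manifest_meta.tsv"))
  attr(manifest, "results") <- list(
    qc = qc_geno, mirna = mirna, mrna = mrna, cis = cis,
    de_mirna = de_mirna, iv = iv, de_mrna = de_mrna, survival = surv,
    funnel = funnel, counts = counts)
  invisible(manifest)
}
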