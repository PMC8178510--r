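#' Write a genotype matrix as VCF
#'
#' Emits a minimal VCFv4.2 file with per-sample `GT:DS:GP` fields (DS =
#' expected alt-allele dosage, GP = genotype probabilities) and the
#' imputation quality as `INFO=<score>` in the INFO column. Missing calls
#' are written as `./.:.:.`.
#'
#' @param g a [genotype_matrix()].
#' @param path output file path (plain text `.vcf`).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=eqtlmr",
    "##INFO=<ID=INFO,Number=1,Type=Float,Description=\"Imputation info score\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Best-guess genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Expected alt allele dosage\">",
    "##FORMAT=<ID=GP,Number=3,Type=Float,Description=\"Genotype probabilities\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", g$sample_ids), collapse = "\t")
  ), con)
  gt_codes <- c("0/0", "0/1", "1/1")
  for (j in seq_len(nrow(g$variants))) {
    v <- g$variants[j, ]
    d <- g$dosages[, j]
    mp <- g$max_posterior[, j]
    cells <- vapply(seq_along(d), function(i) {
      if (is.na(d[i])) return("./.:.:.")
      bg <- max(0L, min(2L, as.integer(round(d[i]))))
      post <- if (is.na(mp[i])) 1 else mp[i]
      gp <- rep((1 - post) / 2, 3)
      gp[bg + 1L] <- post
      sprintf("%s:%.6f:%s", gt_codes[bg + 1L], d[i],
              paste(sprintf("%.6f", gp), collapse = ","))
    }, character(1))
    writeLines(paste(c(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS",
                       sprintf("INFO=%.4f", v$info_score), "GT:DS:GP",
                       cells), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a genotype matrix from VCF
#'
#' Parses a VCF carrying `DS` (dosage) and optionally `GP` (genotype
#' probability) FORMAT fields; the per-call maximum genotype probability
#' is taken as the maximum of the GP triple. Falls back to hard `GT`
#' calls when no DS field is present.
#'
#' @param path a `.vcf` or `.vcf.gz` file.
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fixed <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  info <- vcfR::extract.info(vcf, element = "INFO", as.numeric = TRUE)
  if (all(is.na(info))) info <- rep(1, nrow(fixed))
  fmt <- unique(vcf@gt[, "FORMAT"])
  has_ds <- any(grepl("DS", fmt))
  if (has_ds) {
    ds <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    ds <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
    ds[gt %in% c("0/0", "0|0")] <- 0
    ds[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1
    ds[gt %in% c("1/1", "1|1")] <- 2
  }
  gp <- tryCatch(vcfR::extract.gt(vcf, element = "GP"),
                 error = function(e) NULL)
  mp <- if (!is.null(gp) && !all(is.na(gp))) {
    apply(gp, c(1, 2), function(s) {
      if (is.na(s) || s == ".") return(NA_real_)
      max(as.numeric(strsplit(s, ",")[[1]]))
    })
  } else {
    NULL
  }
  variants <- data.frame(
    id = fixed$ID, chrom = fixed$CHROM, pos = as.integer(fixed$POS),
    ref = fixed$REF, alt = fixed$ALT, info_score = as.numeric(info),
    stringsAsFactors = FALSE
  )
  dos <- t(ds)
  mp_t <- if (is.null(mp)) NULL else t(mp)
  if (!is.null(mp_t)) mp_t[is.na(mp_t) & !is.na(dos)] <- 1
  genotype_matrix(dos, variants, rownames(dos), mp_t)
}

#' Write a genotype matrix as Oxford GEN + SAMPLE files
#'
#' The GEN file carries one variant per line (`chrom id pos ref alt`
#' followed by per-sample genotype-probability triples); the SAMPLE file
#' follows the two-header-row convention of imputation software.
#'
#' @param g a [genotype_matrix()].
#' @param gen_path,sample_path output paths.
#' @return `gen_path`, invisibly.
#' @export
write_gen <- function(g, gen_path, sample_path) {
  stopifnot(inherits(g, "genotype_matrix"))
  writeLines(c("ID_1 ID_2 missing", "0 0 0",
               paste(g$sample_ids, g$sample_ids, "0")), sample_path)
  con <- file(gen_path, "w")
  on.exit(close(con))
  for (j in seq_len(nrow(g$variants))) {
    v <- g$variants[j, ]
    d <- g$dosages[, j]
    mp <- g$max_posterior[, j]
    trips <- vapply(seq_along(d), function(i) {
      if (is.na(d[i])) return("0 0 0")
      bg <- max(0L, min(2L, as.integer(round(d[i]))))
      post <- if (is.na(mp[i])) 1 else mp[i]
      gp <- rep((1 - post) / 2, 3)
      gp[bg + 1L] <- post
      paste(sprintf("%.6f", gp), collapse = " ")
    }, character(1))
    writeLines(paste(c(v$chrom, v$id, v$pos, v$ref, v$alt, trips),
                     collapse = " "), con)
  }
  invisible(gen_path)
}

#' Read Oxford GEN + SAMPLE genotypes
#'
#' Dosage is computed from each probability triple as `p_het + 2 p_alt`;
#' an all-zero triple is a missing call. The per-call maximum probability
#' populates `max_posterior`.
#'
#' @param gen_path,sample_path input paths.
#' @param info_score optional per-variant info scores (defaults to 1).
#' @return A [genotype_matrix()].
#' @export
read_gen <- function(gen_path, sample_path, info_score = NULL) {
  smp <- utils::read.table(sample_path, header = TRUE,
                           stringsAsFactors = FALSE)
  smp <- smp[-1L, , drop = FALSE]  # drop the type row
  sample_ids <- smp[[1L]]
  gen <- utils::read.table(gen_path, header = FALSE,
                           stringsAsFactors = FALSE)
  n <- length(sample_ids)
  stopifnot(ncol(gen) == 5L + 3L * n)
  m <- nrow(gen)
  dos <- matrix(NA_real_, n, m)
  mp <- matrix(NA_real_, n, m)
  probs <- as.matrix(gen[, -(1:5), drop = FALSE])
  for (i in seq_len(n)) {
    tri <- probs[, 3L * (i - 1L) + 1:3, drop = FALSE]
    tot <- rowSums(tri)
    ok <- tot > 0
    dos[i, ok] <- tri[ok, 2L] + 2 * tri[ok, 3L]
    mp[i, ok] <- apply(tri[ok, , drop = FALSE], 1L, max)
  }
  variants <- data.frame(
    id = gen[[2L]], chrom = as.character(gen[[1L]]),
    pos = as.integer(gen[[3L]]), ref = gen[[4L]], alt = gen[[5L]],
    info_score = info_score %||% rep(1, m), stringsAsFactors = FALSE
  )
  genotype_matrix(dos, variants, sample_ids, mp)
}

#' Write feature coordinates as GFF3
#'
#' @param coords data.frame `feature_id`, `chrom`, `start`, `end`,
#'   `strand` (1-based inclusive).
#' @param path output `.gff3` path.
#' @return `path`, invisibly.
#' @export
write_feature_gff3 <- function(coords, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = coords$chrom,
    ranges = IRanges::IRanges(start = coords$start, end = coords$end),
    strand = coords$strand
  )
  gr$ID <- coords$feature_id
  gr$type <- "gene"
  gr$source <- "eqtlmr"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read feature coordinates from GFF3 or BED
#'
#' @param path a `.gff3`/`.gff` or `.bed` file.
#' @return data.frame `feature_id`, `chrom`, `start`, `end`, `strand`
#'   (1-based inclusive).
#' @export
read_feature_coords <- function(path) {
  gr <- rtracklayer::import(path)
  ids <- gr$ID %||% gr$Name %||% gr$name %||%
    as.character(seq_along(gr))
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "+"
  data.frame(
    feature_id = as.character(ids),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    strand = strand, stringsAsFactors = FALSE
  )
}

# Expression helpers: samples in rows, features in columns, first column
# sample_id.
write_expression_tsv <- function(mat, path, sample_ids = rownames(mat)) {
  if (is.null(sample_ids)) stop("matrix has no sample identifiers")
  df <- data.frame(sample_id = sample_ids, mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

read_expression_tsv <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}

#' Serialize a synthetic cohort to standard file formats
#'
#' Writes the cohort as VCF genotypes, RPM-scale expression TSVs (samples
#' x features; values are back-transformed from the log2 scale), a GFF3
#' of feature coordinates, covariate / CNV / CpG / survival / group TSVs,
#' and a ground-truth manifest of the planted effects. A run manifest
#' listing every emitted file with its MD5 checksum is written last and
#' returned.
#'
#' @param cohort a [generate_cohort()] result.
#' @param directory output directory (created if needed).
#' @return data.frame `file`, `md5`, `bytes` (also written as
#'   `manifest.tsv`).
#' @export
write_fixture <- function(cohort, directory) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory ", directory)
  }
  if (file.access(directory, 2L) != 0L) {
    stop("directory is not writable: ", directory)
  }
  p <- function(f) file.path(directory, f)

  write_vcf(cohort$genotypes, p("genotypes.vcf"))
  rpm <- function(m) round(pmax(2^m - 1, 0), 6)
  write_expression_tsv(rpm(cohort$mirna$values), p("mirna_rpm.tsv"))
  write_expression_tsv(rpm(cohort$mrna$values), p("mrna_rpm.tsv"))
  write_feature_gff3(rbind(cohort$mirna$feature_coords,
                           cohort$mrna$feature_coords),
                     p("features.gff3"))
  cov <- cohort$covariates
  write_tsv(data.frame(sample_id = cov$sample_ids, age = cov$age,
                       sex = cov$sex), p("covariates.tsv"))
  write_expression_tsv(cov$cnv, p("cnv_categories.tsv"),
                       sample_ids = cov$sample_ids)
  write_expression_tsv(cov$cpg, p("cpg_categories.tsv"),
                       sample_ids = cov$sample_ids)
  write_tsv(cohort$survival, p("survival.tsv"))
  write_tsv(data.frame(sample_id = cov$sample_ids,
                       group = cohort$group_labels), p("groups.tsv"))

  tr <- cohort$truth
  truth <- rbind(
    if (nrow(tr$cis_effects) > 0) data.frame(
      kind = "cis", source = cohort$genotypes$variants$id[tr$cis_effects$variant],
      target = cohort$mirna$feature_ids[tr$cis_effects$mirna],
      beta = tr$cis_effects$beta, stringsAsFactors = FALSE),
    if (nrow(tr$trans_effects) > 0) data.frame(
      kind = "trans", source = cohort$mirna$feature_ids[tr$trans_effects$mirna],
      target = cohort$mrna$feature_ids[tr$trans_effects$mrna],
      beta = tr$trans_effects$beta, stringsAsFactors = FALSE),
    data.frame(kind = "survival", source = "expression",
               target = cohort$mrna$feature_ids,
               beta = tr$survival_loghr, stringsAsFactors = FALSE)
  )
  write_tsv(truth, p("truth.tsv"))

  files <- c("genotypes.vcf", "mirna_rpm.tsv", "mrna_rpm.tsv",
             "features.gff3", "covariates.tsv", "cnv_categories.tsv",
             "cpg_categories.tsv", "survival.tsv", "groups.tsv",
             "truth.tsv")
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(vapply(files, p, character(1)))),
    bytes = unname(file.size(vapply(files, p, character(1)))),
    stringsAsFactors = FALSE
  )
  write_tsv(manifest, p("manifest.tsv"))
  manifest
}

#' Read a serialized cohort back from disk
#'
#' Inverse of [write_fixture()]: expression is re-transformed to
#' `log2(RPM + 1)` so a written-and-reread cohort is directly comparable
#' to the in-memory one.
#'
#' @param directory the fixture directory.
#' @return list with `genotypes`, `mirna`, `mrna`, `covariates`,
#'   `survival`, `group_labels`, `truth` (the truth manifest data.frame).
#' @export
read_cohort_fixture <- function(directory) {
  p <- function(f) file.path(directory, f)
  genotypes <- read_vcf(p("genotypes.vcf"))
  coords <- read_feature_coords(p("features.gff3"))
  mirna_rpm <- read_expression_tsv(p("mirna_rpm.tsv"))
  mrna_rpm <- read_expression_tsv(p("mrna_rpm.tsv"))
  mk_expr <- function(rpm) {
    expression_matrix(log2(rpm + 1), rownames(rpm), colnames(rpm),
                      coords[coords$feature_id %in% colnames(rpm), ,
                             drop = FALSE],
                      present = rpm > 0)
  }
  covs <- read_tsv(p("covariates.tsv"))
  cnv <- read_expression_tsv(p("cnv_categories.tsv"))
  cpg <- read_expression_tsv(p("cpg_categories.tsv"))
  groups <- read_tsv(p("groups.tsv"))
  list(
    genotypes = genotypes,
    mirna = mk_expr(mirna_rpm), mrna = mk_expr(mrna_rpm),
    covariates = covariate_table(covs$sample_id, covs$age, covs$sex,
                                 cnv, cpg),
    survival = read_tsv(p("survival.tsv")),
    group_labels = groups$group,
    truth = read_tsv(p("truth.tsv"))
  )
}
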