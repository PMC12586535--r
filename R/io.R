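# Canonical interchange formats (tab-separated, UTF-8, header row, '.' for
# missing), VCF genotype ingestion/emission, the TPM-to-count bridge, and the
# end-to-end pipeline driver with per-stage audit logging.

write_twinase_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".", fileEncoding = "UTF-8")
  invisible(path)
}

read_twinase_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", na.strings = ".",
                    stringsAsFactors = FALSE)
}

#' Read an allelic counts table
#'
#' Schema: `snp_id`, `transcript_id`, `pair_id`, `member` (`affected` /
#' `unaffected`), `alt_count`, `ref_count`.
#'
#' @param path TSV path.
#' @return Data frame of count records.
#' @export
read_counts_tsv <- function(path) {
  df <- read_twinase_tsv(path)
  need <- c("snp_id", "transcript_id", "pair_id", "member",
            "alt_count", "ref_count")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("counts TSV ", path, " missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  for (col in c("alt_count", "ref_count")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad))
      stop("corrupt counts TSV ", path, ": non-numeric ", col,
           " at data line ", bad[1], " (value '", df[[col]][bad[1]], "')",
           call. = FALSE)
    if (any(is.na(v)))
      stop("corrupt counts TSV ", path, ": missing ", col, " at data line ",
           which(is.na(v))[1], call. = FALSE)
    if (any(v < 0))
      stop("corrupt counts TSV ", path, ": negative ", col, " at data line ",
           which(v < 0)[1], call. = FALSE)
    df[[col]] <- v
  }
  df
}

#' Read a genotype table
#'
#' Schema: `snp_id`, `pair_id`, `genotype` in `{hom_ref, het, hom_alt}`,
#' missing as `.` (monozygotic co-twins share genotypes, so there is one
#' genotype per twin pair).
#'
#' @param path TSV path.
#' @return Data frame genotype table.
#' @export
read_genotypes_tsv <- function(path) {
  df <- read_twinase_tsv(path)
  need <- c("snp_id", "pair_id", "genotype")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("genotype TSV ", path, " missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  ok <- is.na(df$genotype) | df$genotype %in% c("hom_ref", "het", "hom_alt")
  if (!all(ok))
    stop("genotype TSV ", path, ": invalid genotype at data line ",
         which(!ok)[1], call. = FALSE)
  df
}

#' Read genotypes from a VCF (GT field, one sample per twin pair)
#'
#' `0/0` (or `0|0`) maps to `hom_ref`, `0/1`/`1/0` to `het`, `1/1` to
#' `hom_alt`, `./.` to missing. Multi-allelic records are skipped with a
#' warning.
#'
#' @param path VCF 4.2 path.
#' @return Genotype table data frame (`snp_id`, `pair_id`, `genotype`).
#' @export
read_genotypes_vcf <- function(path) {
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e)
                  stop("malformed VCF ", path, ": ", conditionMessage(e),
                       call. = FALSE))
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  multi <- grepl(",", fix$ALT)
  if (any(multi)) {
    warning("skipping ", sum(multi), " multi-allelic VCF record(s)")
    fix <- fix[!multi, , drop = FALSE]
    gt <- gt[!multi, , drop = FALSE]
  }
  snp_id <- ifelse(is.na(fix$ID) | fix$ID == ".",
                   paste0(fix$CHROM, ":", fix$POS), fix$ID)
  map_gt <- function(x) {
    x <- gsub("\\|", "/", x)
    out <- rep(NA_character_, length(x))
    out[x %in% "0/0"] <- "hom_ref"
    out[x %in% c("0/1", "1/0")] <- "het"
    out[x %in% "1/1"] <- "hom_alt"
    out
  }
  pairs <- colnames(gt)
  data.frame(
    snp_id = rep(snp_id, times = length(pairs)),
    pair_id = rep(pairs, each = nrow(gt)),
    genotype = map_gt(as.vector(gt)),
    stringsAsFactors = FALSE
  )
}

#' Write per-pair genotypes as a minimal VCF 4.2 (GT only)
#'
#' @param cohort An `ase_cohort` (uses `snps` and `genotypes`).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_genotypes_vcf <- function(cohort, path) {
  snps <- cohort$snps
  gt_map <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1")
  pairs <- sort(unique(cohort$genotypes$pair_id))
  wide <- matrix("./.", nrow(snps), length(pairs),
                 dimnames = list(snps$snp_id, pairs))
  idx <- cbind(match(cohort$genotypes$snp_id, snps$snp_id),
               match(cohort$genotypes$pair_id, pairs))
  gtv <- gt_map[cohort$genotypes$genotype]
  gtv[is.na(gtv)] <- "./."
  wide[idx] <- gtv
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", pairs), collapse = "\t")
  ), con)
  body <- paste(snps$chrom, snps$pos, snps$snp_id, snps$ref_allele,
                snps$alt_allele, ".", "PASS", ".", "GT",
                apply(wide, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Convert haplotype TPM values to effective allelic counts
#'
#' Transcript-level haplotype quantifications arrive as TPM pairs; the
#' count likelihood needs integers, so TPMs are scaled by a library factor
#' and rounded half-to-even.
#'
#' @param tpm_ref,tpm_alt Non-negative haplotype TPM values (vectorized).
#' @param library_scale Positive reads-per-TPM scale factor.
#' @return List with integer `ref_count` and `alt_count`.
#' @export
tpm_to_effective_counts <- function(tpm_ref, tpm_alt, library_scale = 1) {
  if (any(tpm_ref < 0) || any(tpm_alt < 0))
    stop("negative TPM input", call. = FALSE)
  if (any(tpm_ref + tpm_alt <= 0))
    stop("tpm_ref + tpm_alt must be > 0", call. = FALSE)
  if (library_scale <= 0) stop("library_scale must be > 0", call. = FALSE)
  rc <- as.integer(round(tpm_ref * library_scale))
  ac <- as.integer(round(tpm_alt * library_scale))
  if (any(rc + ac == 0))
    stop("zero effective depth after rounding; increase library_scale",
         call. = FALSE)
  list(ref_count = rc, alt_count = ac)
}

#' Write the cohort tables to a directory
#'
#' Emits `genotypes.tsv`, `counts.tsv`, `truth.tsv`, `snps.tsv`,
#' `annotation.tsv` and `genotypes.vcf`.
#'
#' @param cohort An `ase_cohort`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_twinase_tsv(cohort$genotypes, file.path(dir, "genotypes.tsv"))
  write_twinase_tsv(cohort$counts, file.path(dir, "counts.tsv"))
  write_twinase_tsv(cohort$truth, file.path(dir, "truth.tsv"))
  write_twinase_tsv(cohort$snps, file.path(dir, "snps.tsv"))
  write_twinase_tsv(cohort$annotation, file.path(dir, "annotation.tsv"))
  write_genotypes_vcf(cohort, file.path(dir, "genotypes.vcf"))
  invisible(dir)
}

stage_log <- function(stage, n_in, n_out) {
  message(sprintf("[%s] in=%d out=%d", stage, n_in, n_out))
}

#' Run the full screening pipeline: simulate, ASE screen, co-expression screen
#'
#' Simulates (or, via `config$counts_tsv` etc., ingests) a twin cohort, runs
#' the ASE screening cascade and the genotype-dependent co-expression screen,
#' and writes all artifacts plus the fully resolved configuration snapshot
#' next to them. Every stochastic step is driven by the seeds in the config;
#' reruns with the same config are identical.
#'
#' @param config A list (or path to a YAML file) with optional elements
#'   `cohort` (arguments to [cohort_config()]), `panel` (arguments to
#'   [coexpr_panel_config()]), `priors` (arguments to [prior_spec()]),
#'   `thresholds` (arguments to [screen_thresholds()]), `bf_threshold`, and
#'   `method`.
#' @param out_dir Output directory.
#' @return Invisibly, a list with the cohort, screen result, co-expression
#'   results and summary.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg_cohort <- do.call(cohort_config, config$cohort %||% list())
  cfg_panel <- do.call(coexpr_panel_config, config$panel %||% list())
  priors <- do.call(prior_spec, config$priors %||% list())
  thresholds <- do.call(screen_thresholds, config$thresholds %||% list())
  bf_threshold <- config$bf_threshold %||% 5
  method <- config$method %||% "laplace_aghq"

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  resolved <- list(cohort = unclass(cfg_cohort), panel = unclass(cfg_panel),
                   priors = unclass(priors), thresholds = unclass(thresholds),
                   bf_threshold = bf_threshold, method = method,
                   twinase_version =
                     as.character(utils::packageVersion("twinase")))
  yaml::write_yaml(resolved, file.path(out_dir, "resolved_config.yaml"))

  cohort <- simulate_cohort(cfg_cohort)
  stage_log("simulate", cfg_cohort$n_snps, nrow(cohort$counts))
  write_cohort(cohort, file.path(out_dir, "cohort"))

  screen <- run_ase_screen(cohort, priors = priors,
                           bf_threshold = bf_threshold, method = method)
  stage_log("ase_screen", screen$summary$n_pairs_annotated,
            screen$summary$n_hits)
  write_twinase_tsv(screen$bf_records, file.path(out_dir, "bf_table.tsv"))
  write_twinase_tsv(screen$hits, file.path(out_dir, "hits.tsv"))
  write_twinase_tsv(screen$aaf_table, file.path(out_dir, "aaf.tsv"))
  hit_summary <- summarize_hits(screen)
  jsonlite::write_json(
    list(stage_counts = screen$summary,
         hits = hit_summary[c("n_hit_snps", "n_hit_transcripts",
                              "n_hit_genes")]),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)

  panel <- simulate_expression_panel(cfg_panel)
  coexpr <- genotype_dependent_screen(panel, thresholds)
  stage_log("coexpr_screen", nrow(coexpr), sum(coexpr$passed))
  write_twinase_tsv(coexpr, file.path(out_dir, "coexpr_results.tsv"))
  passed <- coexpr$gene_id[coexpr$passed]
  writeLines(passed, file.path(out_dir, "passed_genes.txt"))

  pos <- positive_correlation_screen(panel, thresholds$pos_r_min,
                                     thresholds$pos_p_max)
  enr <- overlap_enrichment(passed, pos, ncol(panel$gene_expr))
  jsonlite::write_json(
    list(n_passed = length(passed), n_positive_correlated = length(pos),
         overlap = enr$overlap, odds_ratio = enr$odds_ratio, p = enr$p),
    file.path(out_dir, "enrichment.json"), auto_unbox = TRUE, digits = NA)

  invisible(list(cohort = cohort, screen = screen, coexpr = coexpr,
                 enrichment = enr, hit_summary = hit_summary,
                 out_dir = out_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
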