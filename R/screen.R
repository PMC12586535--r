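# The end-to-end ASE screening cascade: SNP-to-transcript pairing via exon
# overlap, the heterozygosity and discordant-homozygote genotype filters,
# per-individual allelic-imbalance (AAF) summaries, Bayes-factor calling and
# hit summarization.

#' Pair SNPs to lncRNA transcripts by exon overlap
#'
#' Emits one SNP-transcript pair per (SNP, transcript) whose exon contains
#' the SNP position; a SNP may map to several transcripts. Input coordinates
#' are 1-based inclusive (GTF-like) and converted internally to 0-based
#' half-open intervals for the overlap arithmetic.
#'
#' @param variants Data frame with `snp_id`, `chrom`, `pos` (1-based),
#'   `ref_allele`, `alt_allele`.
#' @param annotation Data frame of exons: `transcript_id`, `gene_id`,
#'   `chrom`, `start`, `end` (1-based inclusive; one row per exon).
#' @return Data frame of SNP-transcript pairs (`snp_id`, `chrom`, `pos`,
#'   `ref_allele`, `alt_allele`, `transcript_id`, `gene_id`).
#' @export
pair_snps_to_transcripts <- function(variants, annotation) {
  bad <- annotation$start > annotation$end
  if (any(bad))
    stop("malformed exon interval (start > end) for transcript ",
         annotation$transcript_id[which(bad)[1]], " [",
         annotation$start[which(bad)[1]], ", ",
         annotation$end[which(bad)[1]], "]", call. = FALSE)
  if (any(variants$pos < 1)) stop("SNP pos must be >= 1", call. = FALSE)
  snp_gr <- GenomicRanges::GRanges(
    variants$chrom, IRanges::IRanges(variants$pos, width = 1L))
  exon_gr <- GenomicRanges::GRanges(
    annotation$chrom, IRanges::IRanges(annotation$start, annotation$end))
  ov <- GenomicRanges::findOverlaps(snp_gr, exon_gr)
  qi <- S4Vectors::queryHits(ov)
  si <- S4Vectors::subjectHits(ov)
  out <- data.frame(
    snp_id = variants$snp_id[qi], chrom = variants$chrom[qi],
    pos = variants$pos[qi],
    ref_allele = variants$ref_allele[qi], alt_allele = variants$alt_allele[qi],
    transcript_id = annotation$transcript_id[si],
    gene_id = annotation$gene_id[si], stringsAsFactors = FALSE
  )
  # one pair per (snp, transcript) even when a transcript has several exons
  out <- out[!duplicated(out[c("snp_id", "transcript_id")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Retain SNP-transcript pairs heterozygous in at least one twin pair
#'
#' A SNP is ASE-informative only where some twin pair carries it
#' heterozygously; missing genotypes count as non-het.
#'
#' @param pairs Data frame of SNP-transcript pairs (needs `snp_id`).
#' @param genotypes Data frame `snp_id`, `pair_id`, `genotype` in
#'   `{hom_ref, het, hom_alt}` or `NA` for missing.
#' @return The retained subset of `pairs`.
#' @export
filter_informative <- function(pairs, genotypes) {
  het <- genotypes$genotype %in% "het"
  keep_snps <- unique(genotypes$snp_id[het])
  out <- pairs[pairs$snp_id %in% keep_snps, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Exclude SNPs with discordant homozygous genotypes across twin pairs
#'
#' A SNP is excluded iff one twin pair is homozygous reference and another is
#' homozygous alternate: such sites reflect genotype, not allele-specific
#' expression, differences.
#'
#' @inheritParams filter_informative
#' @return The retained subset of `pairs`.
#' @export
filter_discordant_homozygous <- function(pairs, genotypes) {
  hr <- unique(genotypes$snp_id[genotypes$genotype %in% "hom_ref"])
  ha <- unique(genotypes$snp_id[genotypes$genotype %in% "hom_alt"])
  drop_snps <- intersect(hr, ha)
  out <- pairs[!(pairs$snp_id %in% drop_snps), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Signed per-individual allelic imbalance (AAF)
#'
#' `AAF = (alt - ref) / (alt + ref)` in `[-1, 1]`; positive values mean
#' alternative-haplotype dominance, negative reference-haplotype dominance.
#'
#' @param alt_count,ref_count Non-negative counts (vectorized).
#' @return Numeric vector of AAF values.
#' @export
compute_aaf <- function(alt_count, ref_count) {
  if (any(alt_count < 0) || any(ref_count < 0))
    stop("negative counts", call. = FALSE)
  tot <- alt_count + ref_count
  if (any(tot == 0)) stop("zero total depth", call. = FALSE)
  (alt_count - ref_count) / tot
}

#' Run the full ASE screening cascade on a cohort
#'
#' Pairs SNPs to transcripts, applies the heterozygous-informative and
#' discordant-homozygote filters, computes a Bayes factor per surviving
#' SNP-transcript pair and a per-individual AAF table, and tallies the
#' retention at every stage. Deterministic given inputs, priors and threshold.
#'
#' @param cohort An `ase_cohort` (or a list with `snps`, `genotypes`,
#'   `counts`, and optionally `annotation`).
#' @param annotation Exon annotation; defaults to `cohort$annotation`.
#' @param priors A [prior_spec()].
#' @param bf_threshold Bayes-factor calling threshold.
#' @param method Marginalization method, see [log_marginal()].
#' @return An `ase_screen_result`: `retained_pairs`, `bf_records`, `hits`,
#'   `aaf_table`, `summary` (stage counts).
#' @export
run_ase_screen <- function(cohort, annotation = NULL,
                           priors = prior_spec(), bf_threshold = 5,
                           method = c("laplace_aghq", "laplace")) {
  method <- match.arg(method)
  if (is.null(annotation)) annotation <- cohort$annotation
  if (is.null(cohort$counts) || nrow(cohort$counts) == 0L)
    stop("uninformative cohort: no allelic count records", call. = FALSE)

  pairs0 <- pair_snps_to_transcripts(cohort$snps, annotation)
  pairs1 <- filter_informative(pairs0, cohort$genotypes)
  pairs2 <- filter_discordant_homozygous(pairs1, cohort$genotypes)
  if (nrow(pairs2) == 0L)
    stop("uninformative cohort: no SNP-transcript pair survives the filters",
         call. = FALSE)

  key <- paste(cohort$counts$snp_id, cohort$counts$transcript_id)
  test_keys <- paste(pairs2$snp_id, pairs2$transcript_id)
  recs <- vector("list", nrow(pairs2))
  n_no_counts <- 0L
  for (u in seq_len(nrow(pairs2))) {
    sub <- cohort$counts[key == test_keys[u], , drop = FALSE]
    if (nrow(sub) == 0L) { n_no_counts <- n_no_counts + 1L; next }
    recs[[u]] <- bayes_factor(sub, priors, bf_threshold, method)
  }
  bf_records <- do.call(rbind, recs[!vapply(recs, is.null, TRUE)])
  if (is.null(bf_records))
    stop("uninformative cohort: no tested pair has count records",
         call. = FALSE)
  rownames(bf_records) <- NULL
  hits <- bf_records[bf_records$call, , drop = FALSE]

  tested <- cohort$counts[key %in% test_keys, , drop = FALSE]
  agg <- stats::aggregate(
    cbind(alt_count, ref_count) ~ snp_id + transcript_id + pair_id + member,
    data = tested, FUN = sum)
  agg$aaf <- compute_aaf(agg$alt_count, agg$ref_count)
  aaf_table <- agg[order(agg$snp_id, agg$transcript_id, agg$pair_id,
                         agg$member), , drop = FALSE]
  rownames(aaf_table) <- NULL

  summary <- list(
    n_snps_input = length(unique(cohort$snps$snp_id)),
    n_pairs_annotated = nrow(pairs0),
    n_pairs_het_informative = nrow(pairs1),
    n_pairs_after_hom_filter = nrow(pairs2),
    n_pairs_tested = nrow(bf_records),
    n_pairs_without_counts = n_no_counts,
    n_nonconverged = sum(!bf_records$converged),
    n_missing_genotypes = sum(is.na(cohort$genotypes$genotype)),
    n_hits = nrow(hits),
    bf_threshold = bf_threshold
  )
  structure(list(retained_pairs = pairs2, bf_records = bf_records,
                 hits = hits, aaf_table = aaf_table, summary = summary),
            class = "ase_screen_result")
}

#' @export
print.ase_screen_result <- function(x, ...) {
  s <- x$summary
  cat("ASE screen:", s$n_pairs_annotated, "SNP-transcript pairs ->",
      s$n_pairs_het_informative, "het-informative ->",
      s$n_pairs_after_hom_filter, "after hom filter ->",
      s$n_pairs_tested, "tested ->", s$n_hits, "hits (BF >",
      s$bf_threshold, ")\n")
  invisible(x)
}

#' Three-level hit summary (SNPs, transcripts, genes)
#'
#' Distinct-SNP, distinct-transcript and distinct-gene counts among the
#' Bayes-factor hits, plus the per-stage retention counts of the screen.
#'
#' @param result An `ase_screen_result` from [run_ase_screen()].
#' @return A list with `n_hit_snps`, `n_hit_transcripts`, `n_hit_genes`, and
#'   `stages` (a data frame of per-stage counts).
#' @export
summarize_hits <- function(result) {
  hits <- result$hits
  gene_of <- result$retained_pairs$gene_id[
    match(paste(hits$snp_id, hits$transcript_id),
          paste(result$retained_pairs$snp_id,
                result$retained_pairs$transcript_id))]
  s <- result$summary
  list(
    n_hit_snps = length(unique(hits$snp_id)),
    n_hit_transcripts = length(unique(hits$transcript_id)),
    n_hit_genes = length(unique(gene_of[!is.na(gene_of)])),
    stages = data.frame(
      stage = c("annotated", "het_informative", "after_hom_filter",
                "tested", "hits"),
      n = c(s$n_pairs_annotated, s$n_pairs_het_informative,
            s$n_pairs_after_hom_filter, s$n_pairs_tested, s$n_hits)
    )
  )
}
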