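# Genotype-dependent co-expression screen: per-group Pearson correlation and
# OLS slope of each gene on a focal lncRNA, BH-FDR over the heterozygote
# group, the slope-ratio and WT-exclusion rules, the pooled
# positive-correlation screen, and set-overlap enrichment.

#' Pearson correlation with a two-sided p-value
#'
#' Product-moment correlation; p from the t transform with n - 2 degrees of
#' freedom (via [stats::cor.test()]).
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return List with `r` and `p`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Ordinary least-squares line
#'
#' @param x,y Numeric vectors, length >= 2, `x` non-constant.
#' @return List with `intercept` and `slope` (`cov(x, y) / var(x)`).
#' @export
simple_linear_fit <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (length(x) < 2) stop("need at least 2 observations", call. = FALSE)
  if (stats::sd(x) == 0) stop("constant x", call. = FALSE)
  slope <- stats::cov(x, y) / stats::var(x)
  list(intercept = mean(y) - slope * mean(x), slope = slope)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values in input order.
#' @export
bh_fdr <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0) || any(pvals > 1))
    stop("p-values must be in [0, 1]", call. = FALSE)
  stats::p.adjust(pvals, method = "BH")
}

#' Thresholds of the genotype-dependent co-expression screen
#'
#' A gene passes iff `|r_het| > r_het_min`, its BH-adjusted heterozygote
#' p-value is below `fdr_max`, `|beta_het| >= beta_ratio_min * |beta_wt|`,
#' and `|r_wt| <= r_wt_max`. `pos_r_min` / `pos_p_max` govern the separate
#' pooled positive-correlation screen.
#'
#' @param r_het_min,fdr_max,beta_ratio_min,r_wt_max,pos_r_min,pos_p_max
#'   Numeric thresholds.
#' @return A `screen_thresholds` list.
#' @export
screen_thresholds <- function(r_het_min = 0.5, fdr_max = 0.05,
                              beta_ratio_min = 2, r_wt_max = 0.5,
                              pos_r_min = 0.3, pos_p_max = 1e-5) {
  structure(list(r_het_min = r_het_min, fdr_max = fdr_max,
                 beta_ratio_min = beta_ratio_min, r_wt_max = r_wt_max,
                 pos_r_min = pos_r_min, pos_p_max = pos_p_max),
            class = "screen_thresholds")
}

#' Genotype-dependent co-expression screen
#'
#' Splits samples into WT (homozygous reference) and Heter (heterozygous)
#' groups at the focal SNP and, per gene, computes Pearson correlation and
#' OLS slope against the focal lncRNA in each group. FDR is controlled by BH
#' over the Heter-group p-values. A gene passes when the Heter correlation is
#' strong and significant, the Heter slope is at least `beta_ratio_min` times
#' the WT slope in absolute value, and the WT correlation is weak;
#' `fail_reason` records the first violated rule. Genes constant in either
#' group are excluded with `fail_reason = "constant"`.
#'
#' @param panel An `expression_panel` (see [simulate_expression_panel()]) or a
#'   list with `genotype`, `lnc_expr`, `gene_expr`.
#' @param thresholds A [screen_thresholds()].
#' @return Data frame with one row per gene: `gene_id`, `r_wt`, `r_het`,
#'   `p_het`, `q_het`, `beta_wt`, `beta_het`, `passed`, `fail_reason`.
#' @export
genotype_dependent_screen <- function(panel,
                                      thresholds = screen_thresholds()) {
  th <- thresholds
  wt <- panel$genotype == "WT"
  het <- panel$genotype == "Heter"
  if (sum(wt) < 3 || sum(het) < 3)
    stop("each genotype group needs at least 3 samples", call. = FALSE)
  x_wt <- panel$lnc_expr[wt]
  x_het <- panel$lnc_expr[het]
  genes <- colnames(panel$gene_expr)

  n <- length(genes)
  r_wt <- r_het <- p_het <- b_wt <- b_het <- rep(NA_real_, n)
  constant <- logical(n)
  for (g in seq_len(n)) {
    y_wt <- panel$gene_expr[wt, g]
    y_het <- panel$gene_expr[het, g]
    if (stats::sd(y_wt) == 0 || stats::sd(y_het) == 0) {
      constant[g] <- TRUE
      next
    }
    cw <- pearson_r(x_wt, y_wt)
    ch <- pearson_r(x_het, y_het)
    r_wt[g] <- cw$r; r_het[g] <- ch$r; p_het[g] <- ch$p
    b_wt[g] <- simple_linear_fit(x_wt, y_wt)$slope
    b_het[g] <- simple_linear_fit(x_het, y_het)$slope
  }
  q_het <- rep(NA_real_, n)
  q_het[!constant] <- bh_fdr(p_het[!constant])

  fail <- rep(NA_character_, n)
  passed <- logical(n)
  for (g in seq_len(n)) {
    if (constant[g]) { fail[g] <- "constant"; next }
    if (abs(r_het[g]) <= th$r_het_min) { fail[g] <- "r_het"; next }
    if (q_het[g] >= th$fdr_max) { fail[g] <- "fdr"; next }
    if (abs(b_het[g]) < th$beta_ratio_min * abs(b_wt[g])) {
      fail[g] <- "beta_ratio"; next
    }
    if (abs(r_wt[g]) > th$r_wt_max) { fail[g] <- "r_wt"; next }
    passed[g] <- TRUE
  }
  data.frame(gene_id = genes, r_wt = r_wt, r_het = r_het, p_het = p_het,
             q_het = q_het, beta_wt = b_wt, beta_het = b_het,
             passed = passed, fail_reason = fail, stringsAsFactors = FALSE)
}

#' Pooled positive-correlation screen
#'
#' Genes whose signed Pearson correlation with the focal lncRNA across all
#' samples exceeds `r_min` at `p < p_max` (negative correlations never pass).
#'
#' @inheritParams genotype_dependent_screen
#' @param r_min,p_max Thresholds on the signed correlation and p-value.
#' @return Character vector of gene ids.
#' @export
positive_correlation_screen <- function(panel, r_min = 0.3, p_max = 1e-5) {
  genes <- colnames(panel$gene_expr)
  keep <- vapply(seq_along(genes), function(g) {
    y <- panel$gene_expr[, g]
    if (stats::sd(y) == 0) return(FALSE)
    ct <- pearson_r(panel$lnc_expr, y)
    ct$r > r_min && ct$p < p_max
  }, logical(1))
  genes[keep]
}

#' Overlap enrichment of two gene sets against a background
#'
#' 2x2 table `(k, |A| - k, |B| - k, N - |A| - |B| + k)`; odds ratio
#' `ad / (bc)` with a Haldane 0.5 correction iff any cell is zero; p-value is
#' the upper-tail hypergeometric probability `P(X >= k)` (one-sided Fisher).
#'
#' @param set_a,set_b Character vectors of ids drawn from the background.
#' @param background_size Size `N` of the background universe.
#' @return List with `overlap`, `odds_ratio`, `p`.
#' @export
overlap_enrichment <- function(set_a, set_b, background_size) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  N <- background_size
  if (length(set_a) > N || length(set_b) > N ||
      length(union(set_a, set_b)) > N)
    stop("sets exceed the background universe", call. = FALSE)
  k <- length(intersect(set_a, set_b))
  a <- k
  b <- length(set_a) - k
  c_ <- length(set_b) - k
  d <- N - length(set_a) - length(set_b) + k
  cells <- c(a, b, c_, d)
  if (any(cells == 0)) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  p <- stats::phyper(k - 1, length(set_a), N - length(set_a), length(set_b),
                     lower.tail = FALSE)
  list(overlap = k, odds_ratio = or, p = p)
}
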