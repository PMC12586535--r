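# Shared fixture builders. All fixtures are generated in code; nothing is
# read from disk except files the tests themselves write.

# allelic counts for k twin pairs under the logit mixed model
make_counts <- function(k, depth = 50, betas = 1, b0 = 0, sigma_gamma = 0.4,
                        seed = NULL, depth_range = NULL) {
  if (!is.null(seed)) set.seed(seed)
  do.call(rbind, lapply(seq_len(k), function(i) {
    g <- rnorm(1, 0, sigma_gamma)
    n <- if (is.null(depth_range)) c(depth, depth)
         else sample(depth_range[1]:depth_range[2], 2, replace = TRUE)
    a <- c(rbinom(1, n[1], plogis(b0 + betas + g)),
           rbinom(1, n[2], plogis(b0 + g)))
    data.frame(pair_id = sprintf("p%02d", i),
               member = c("affected", "unaffected"),
               alt_count = a, ref_count = n - a,
               stringsAsFactors = FALSE)
  }))
}

# long genotype table from a snp x pair matrix of genotype strings
geno_table <- function(m) {
  data.frame(
    snp_id = rep(rownames(m), each = ncol(m)),
    pair_id = rep(colnames(m), times = nrow(m)),
    genotype = as.vector(t(m)),
    stringsAsFactors = FALSE
  )
}

# independent BH step-up recursion (oracle for bh_fdr)
bh_manual <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}
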