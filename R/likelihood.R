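# Likelihood layer for the binomial / beta-binomial logit mixed models.
#
# M1: logit(p_is) = beta0 + betas * s + gamma_i   (s = 1 affected co-twin)
# M0: logit(p_is) = beta0 + gamma_i
# p_is is the proportion of reads supporting the alternative allele in pair i
# at disease status s; gamma_i is a random intercept shared by the co-twins.

#' Prior specification for the ASE model comparison
#'
#' Bayes factors depend on the priors, so they are explicit and documented:
#' independent Normal(0, beta_sd^2) priors on the fixed effects and a
#' half-Normal(sigma_gamma_scale) prior on the random-intercept SD.
#'
#' @param beta_sd SD of the Normal prior on each fixed effect (logit scale).
#' @param sigma_gamma_scale Scale of the half-Normal prior on `sigma_gamma`.
#' @param rho_mode `"fixed_zero"` (binomial likelihood), `"fixed_value"`
#'   (beta-binomial at `rho_value`), or `"profile"` (beta-binomial with rho
#'   chosen on a small grid by marginal likelihood).
#' @param rho_value Overdispersion used when `rho_mode = "fixed_value"`.
#' @return A `prior_spec` object.
#' @export
prior_spec <- function(beta_sd = 3, sigma_gamma_scale = 1,
                       rho_mode = c("fixed_zero", "fixed_value", "profile"),
                       rho_value = 0) {
  rho_mode <- match.arg(rho_mode)
  if (beta_sd <= 0) stop("beta_sd must be > 0", call. = FALSE)
  if (sigma_gamma_scale <= 0)
    stop("sigma_gamma_scale must be > 0", call. = FALSE)
  if (rho_mode == "fixed_value" && (rho_value < 0 || rho_value >= 1))
    stop("rho_value must be in [0, 1)", call. = FALSE)
  if (rho_mode == "fixed_zero") rho_value <- 0
  structure(list(beta_sd = beta_sd, sigma_gamma_scale = sigma_gamma_scale,
                 rho_mode = rho_mode, rho_value = rho_value),
            class = "prior_spec")
}

# Internal: validate a counts data.frame for one SNP-transcript pair and
# compress it into parallel vectors. Zero-depth records are dropped with a
# warning when other records remain (errored otherwise).
ase_records <- function(counts) {
  if (is.null(counts) || nrow(counts) == 0L)
    stop("empty record list", call. = FALSE)
  need <- c("pair_id", "member", "alt_count", "ref_count")
  miss <- setdiff(need, names(counts))
  if (length(miss))
    stop("counts table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(counts$alt_count < 0) || any(counts$ref_count < 0))
    stop("negative allelic counts", call. = FALSE)
  tot <- counts$alt_count + counts$ref_count
  if (all(tot == 0)) stop("all records have zero total depth", call. = FALSE)
  if (any(tot == 0)) {
    warning("dropping ", sum(tot == 0), " record(s) with zero total depth")
    counts <- counts[tot > 0, , drop = FALSE]
  }
  if (!all(counts$member %in% c("affected", "unaffected")))
    stop("member must be 'affected' or 'unaffected'", call. = FALSE)
  pair_ids <- sort(unique(counts$pair_id))
  pair <- match(counts$pair_id, pair_ids)
  k <- length(pair_ids)
  # pair-aggregation indicator (k x records): pair sums as one matrix product
  P <- matrix(0, k, length(pair))
  P[cbind(pair, seq_along(pair))] <- 1
  list(
    a = as.numeric(counts$alt_count),
    n = as.numeric(counts$alt_count + counts$ref_count),
    s = as.numeric(counts$member == "affected"),
    pair = pair,
    pair_ids = pair_ids,
    k = k,
    P = P
  )
}

# Beta-binomial log-pmf with mean p and intra-class correlation rho.
bbinom_lpmf <- function(a, n, p, rho) {
  al <- p * (1 - rho) / rho
  be <- (1 - p) * (1 - rho) / rho
  lchoose(n, a) + lbeta(a + al, n - a + be) - lbeta(al, be)
}

rec_loglik <- function(rec, beta0, betas, gamma, rho) {
  if (length(gamma) != rec$k)
    stop("gamma length (", length(gamma), ") does not match number of pairs (",
         rec$k, ")", call. = FALSE)
  eta <- beta0 + betas * rec$s + gamma[rec$pair]
  p <- stats::plogis(eta)
  if (rho <= 0) {
    sum(stats::dbinom(rec$a, rec$n, p, log = TRUE))
  } else {
    sum(bbinom_lpmf(rec$a, rec$n, p, rho))
  }
}

#' Log-likelihood of one SNP-transcript pair under M1 or M0
#'
#' Sums binomial (or beta-binomial when `rho > 0`) log-pmfs of the
#' alternative-allele count out of total depth, with success probability
#' `plogis(beta0 + betas * s + gamma_i)`; `s = 1` for the affected co-twin.
#' Under M0 the `betas` term is fixed at zero.
#'
#' @param counts Data frame of allelic count records for one SNP-transcript
#'   pair (columns `pair_id`, `member`, `alt_count`, `ref_count`).
#' @param params List with `beta0`, `betas`, `gamma` (one per pair present in
#'   `counts`, matched to sorted pair ids), and `rho`.
#' @param model `"M1"` or `"M0"`.
#' @return Log-likelihood in nats.
#' @export
ase_loglik <- function(counts, params, model = c("M1", "M0")) {
  model <- match.arg(model)
  rec <- ase_records(counts)
  rho <- if (is.null(params$rho)) 0 else params$rho
  betas <- if (model == "M1") params$betas else 0
  rec_loglik(rec, params$beta0, betas, params$gamma, rho)
}
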