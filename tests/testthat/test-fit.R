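test_that("perfectly balanced counts put the fixed-effect mode at zero", {
  cts <- data.frame(pair_id = rep(c("p1", "p2"), each = 2),
                    member = rep(c("affected", "unaffected"), 2),
                    alt_count = c(25, 25, 40, 40),
                    ref_count = c(25, 25, 40, 40))
  fit <- fit_mode(cts, "M1")
  expect_true(fit$converged)
  expect_lt(abs(fit$mode[["beta0"]]), 1e-3)
  expect_lt(abs(fit$mode[["betas"]]), 1e-3)
})

test_that("the posterior mode recovers a strong phenotype effect", {
  set.seed(31)
  cts <- make_counts(9, depth = 1000, betas = 2, sigma_gamma = 0)
  fit <- fit_mode(cts, "M1")
  expect_true(fit$converged)
  expect_lt(abs(fit$mode[["betas"]] - 2), 0.3)
})

test_that("empty or degenerate inputs error", {
  expect_error(fit_mode(data.frame()), "empty record list")
  expect_error(log_marginal(NULL, "M1"), "empty record list")
})

test_that("laplace and laplace_aghq agree on a minimal one-pair instance", {
  tiny <- data.frame(pair_id = "p1", member = c("affected", "unaffected"),
                     alt_count = c(1, 3), ref_count = c(1, 1))
  for (m in c("M1", "M0")) {
    la <- log_marginal(tiny, m, method = "laplace")
    ag <- log_marginal(tiny, m, method = "laplace_aghq")
    expect_true(la$converged && ag$converged)
    expect_lt(abs(la$log_marginal - ag$log_marginal), 0.05)
  }
})

test_that("collapsing the random-effect prior recovers the fixed model", {
  # as the half-Normal scale -> 0 the random intercepts pin to zero and the
  # marginal likelihood reduces to a 1D (or 2D) integral over fixed effects
  cts <- make_counts(2, depth = 30, betas = 0.8, sigma_gamma = 0, seed = 32L)
  pr <- prior_spec(beta_sd = 3, sigma_gamma_scale = 1e-4)
  rec_a <- cts[cts$member == "affected", ]
  rec_u <- cts[cts$member == "unaffected", ]
  f <- function(b0) {
    vapply(b0, function(b) {
      exp(sum(dbinom(rec_a$alt_count, rec_a$alt_count + rec_a$ref_count,
                     plogis(b), log = TRUE)) +
          sum(dbinom(rec_u$alt_count, rec_u$alt_count + rec_u$ref_count,
                     plogis(b), log = TRUE)) +
          dnorm(b, 0, 3, log = TRUE))
    }, numeric(1))
  }
  oracle <- log(integrate(f, -15, 15, rel.tol = 1e-10)$value)
  got <- log_marginal(cts, "M0", pr, method = "laplace_aghq")$log_marginal
  expect_lt(abs(got - oracle), 0.05)
})

test_that("brute-force quadrature reduces to the likelihood under point-mass priors", {
  cts <- make_counts(2, depth = 25, betas = 0.5, seed = 33L)
  pr <- prior_spec(beta_sd = 1e-3, sigma_gamma_scale = 1e-3)
  gs <- brute_grid_spec(b_center = 0, bs_center = 0, b_half = 0.01, b_n = 41,
                        s_min = 1e-6, s_max = 5e-3, s_n = 25,
                        z_switch = Inf)
  got <- brute_force_log_marginal(cts, "M1", pr, gs)
  at_zero <- ase_loglik(cts, list(beta0 = 0, betas = 0, gamma = c(0, 0),
                                  rho = 0), "M1")
  expect_lt(abs(got - at_zero), 0.05)
})

test_that("brute-force quadrature is converged in its grid resolution", {
  cts <- make_counts(2, depth = 40, betas = 1, seed = 34L)
  v1 <- brute_force_log_marginal(cts, "M1", grid_spec = brute_grid_spec())
  v2 <- brute_force_log_marginal(
    cts, "M1",
    grid_spec = brute_grid_spec(b_n = 81, g_n = 121, s_n = 64, z_n = 321))
  expect_lt(abs(v1 - v2), 0.02)
})

test_that("brute force refuses more than six integration dimensions", {
  cts <- make_counts(4, depth = 20, seed = 35L)
  expect_error(brute_force_log_marginal(cts, "M1"), "dimension")
  expect_silent(invisible(brute_force_log_marginal(cts, "M0")))
})

test_that("importance sampling agrees with brute-force quadrature", {
  cts <- make_counts(2, depth = 40, betas = 1, seed = 36L)
  br <- brute_force_log_marginal(cts, "M1")
  set.seed(361)
  is1 <- is_log_marginal(cts, "M1", n_draws = 2e5)
  expect_lt(abs(is1 - br), 0.1)
})

test_that("laplace_aghq tracks the brute-force oracle on small instances", {
  set.seed(37)
  for (k in 1:3) {
    cts <- make_counts(k, betas = runif(1, -1.5, 1.5), depth_range = c(10, 50))
    for (m in c("M1", "M0")) {
      ag <- log_marginal(cts, m, method = "laplace_aghq")$log_marginal
      br <- brute_force_log_marginal(cts, m)
      expect_lt(abs(ag - br), 0.1)
    }
  }
})

test_that("beta-binomial marginal likelihoods are finite and well-behaved", {
  cts <- make_counts(3, depth = 60, betas = 1, seed = 38L)
  pr <- prior_spec(rho_mode = "fixed_value", rho_value = 0.05)
  f1 <- log_marginal(cts, "M1", pr, method = "laplace_aghq")
  expect_true(f1$converged)
  expect_true(is.finite(f1$log_marginal))
  # overdispersion absorbs signal: evidence under rho > 0 is weaker than
  # under the binomial for the same counts
  f1_bin <- log_marginal(cts, "M1", method = "laplace_aghq")
  expect_false(isTRUE(all.equal(f1$log_marginal, f1_bin$log_marginal)))
})
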