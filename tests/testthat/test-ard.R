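test_that("ARD prunes to the planted number of signatures", {
  sc <- planted_scenario(k = 2L, n_samples = 60L, seed = 24L,
                         burden_range = c(1e3, 1e4))
  sim <- simulate_catalogue(sc)
  fit <- ard_nmf(sim$catalogue, k_max = 10L, seed = 25L, n_restarts = 3L,
                 tol = 1e-7, max_iter = 3000L)
  expect_equal(fit$effective_k, 2L)
  rec <- recovery_cosines(sc$signatures$W, fit$signatures$W)
  expect_true(all(rec >= 0.95))
})

test_that("the returned restart maximizes the posterior", {
  sc <- planted_scenario(k = 2L, n_samples = 20L, seed = 26L)
  sim <- simulate_catalogue(sc)
  fit <- ard_nmf(sim$catalogue, k_max = 5L, seed = 27L, n_restarts = 4L,
                 tol = 1e-6, max_iter = 1000L)
  expect_equal(fit$log_posterior, -min(fit$restarts$neg_log_posterior))
  expect_equal(nrow(fit$restarts), 4L)
})

test_that("pruning negligible components barely changes the reconstruction", {
  sc <- planted_scenario(k = 2L, n_samples = 40L, seed = 28L)
  sim <- simulate_catalogue(sc)
  M <- sim$catalogue$counts
  fit <- ard_nmf(M, k_max = 8L, seed = 29L, n_restarts = 2L, tol = 1e-7,
                 max_iter = 3000L)
  R_pruned <- fit$signatures$W %*% fit$exposures
  err_pruned <- kl_divergence(M, R_pruned)
  # reconstruction with the pruned model stays close to the data
  expect_gt(mean(vapply(seq_len(ncol(M)), function(j)
    cosine(M[, j], R_pruned[, j]), numeric(1))), 0.95)
  expect_lt(err_pruned / sum(M), 1)  # bounded per-mutation divergence
})

test_that("both component priors are accepted", {
  sc <- planted_scenario(k = 2L, n_samples = 25L, seed = 30L)
  sim <- simulate_catalogue(sc)
  for (prior in c("exponential", "halfnormal")) {
    fit <- ard_nmf(sim$catalogue, k_max = 6L, prior = prior, seed = 31L,
                   n_restarts = 2L, tol = 1e-6, max_iter = 1500L)
    expect_gte(fit$effective_k, 1L)
    expect_lte(fit$effective_k, 6L)
  }
  expect_error(ard_nmf(sim$catalogue, k_max = 0L), "k_max")
})

test_that("two-step extraction: hypermutator catalogue from step-1 signatures adds nothing", {
  sigs <- synthetic_signatures("SBS96", k = 2L, seed = 32L)
  sc_low <- simulation_scenario(sigs, 50L, burden_range = c(1e3, 5e3),
                                noise = "poisson", seed = 33L, name = "low")
  sc_hyp <- simulation_scenario(sigs, 8L, burden_range = c(1e5, 2e5),
                                noise = "poisson", seed = 34L, name = "hyp")
  V_low <- simulate_catalogue(sc_low)$catalogue
  V_hyp <- simulate_catalogue(sc_hyp)$catalogue
  ts <- two_step_extract(V_low, V_hyp, k_max = 6L, seed = 35L,
                         n_restarts = 2L, tol = 1e-7, max_iter = 20000L)
  expect_length(ts$hyper_only, 0L)
})

test_that("two-step extraction isolates a signature unique to hypermutators", {
  sigs3 <- synthetic_signatures("SBS96", k = 3L, seed = 36L,
                                max_pairwise = 0.2)
  low_sigs <- signature_set(sigs3$W[, 1:2], "SBS96")
  hyper_sig <- sigs3$W[, 3]
  sc_low <- simulation_scenario(low_sigs, 50L, burden_range = c(1e3, 5e3),
                                noise = "poisson", seed = 37L, name = "low")
  V_low <- simulate_catalogue(sc_low)$catalogue
  set.seed(38)
  V_hyp <- vapply(1:8, function(j) stats::rpois(96, hyper_sig * 3e5),
                  numeric(96))
  rownames(V_hyp) <- rownames(sigs3$W)
  colnames(V_hyp) <- paste0("hyp", 1:8)
  ts <- two_step_extract(V_low, V_hyp, k_max = 6L, seed = 39L,
                         n_restarts = 2L, tol = 1e-7, max_iter = 20000L)
  expect_length(ts$hyper_only, 1L)
  hyper_W <- ts$signatures$W[, ts$hyper_only, drop = FALSE]
  expect_gt(cosine(hyper_W[, 1], hyper_sig), 0.95)
  # fixed-column contract: step-1 signatures pass through unchanged
  k1 <- n_signatures(ts$step1$signatures)
  expect_identical(ts$signatures$W[, seq_len(k1)], ts$step1$signatures$W)
})

test_that("empty hypermutator set returns the step-1 result", {
  sigs <- synthetic_signatures("SBS96", k = 2L, seed = 40L)
  sc <- simulation_scenario(sigs, 30L, noise = "poisson", seed = 41L)
  V <- simulate_catalogue(sc)$catalogue
  ts <- two_step_extract(V, NULL, k_max = 5L, seed = 42L, n_restarts = 2L,
                         tol = 1e-6, max_iter = 1500L)
  expect_length(ts$hyper_only, 0L)
  expect_identical(ts$signatures$W, ts$step1$signatures$W)
})

test_that("the burden-quantile splitter is labelled heuristic and splits correctly", {
  V <- matrix(10, 96, 20)
  colnames(V) <- paste0("s", 1:20)
  V[, 20] <- 1000
  sp <- split_by_burden(V, 0.9)
  expect_true("s20" %in% sp$hyper)
  expect_length(intersect(sp$low, sp$hyper), 0L)
})
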