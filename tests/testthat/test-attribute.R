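two_sig_set <- function(seed = 50L) {
  synthetic_signatures("SBS96", k = 2L, seed = seed, max_pairwise = 0.4)
}

test_that("pure and exact-mixture spectra are attributed exactly", {
  sigs <- two_sig_set()
  s1 <- sigs$W[, 1]; s2 <- sigs$W[, 2]
  a <- attribute_sample(100 * s1, sigs)
  expect_equal(unname(a$exposures), c(100, 0), tolerance = 1e-6)
  b <- attribute_sample(60 * s1 + 40 * s2, sigs)
  expect_equal(unname(b$exposures), c(60, 40), tolerance = 1e-6)
  expect_equal(b$cosine, 1.0, tolerance = 1e-9)
})

test_that("an all-zero spectrum warns and returns zero exposures", {
  sigs <- two_sig_set()
  expect_warning(res <- attribute_sample(rep(0, 96), sigs), "zero")
  expect_true(all(res$exposures == 0))
})

test_that("disallowed signatures receive exactly zero exposure", {
  sigs <- synthetic_signatures("SBS96", k = 4L, seed = 51L)
  spectrum <- 200 * sigs$W[, 2] + 100 * sigs$W[, 3]
  res <- attribute_sample(spectrum, sigs, allowed = c("SynSig2", "SynSig3"))
  expect_identical(unname(res$exposures[c(1, 4)]), c(0, 0))
  expect_equal(unname(res$exposures[2:3]), c(200, 100), tolerance = 1e-6)
})

test_that("attribution equals the exhaustive-support least-squares oracle", {
  set.seed(52)
  for (rep in 1:40) {
    k <- sample(2:6, 1)
    sigs <- synthetic_signatures("SBS96", k = k, seed = 52L + rep,
                                 max_pairwise = 0.6)
    y <- as.numeric(sigs$W %*% stats::rgamma(k, 1, 1 / 50) +
                      stats::runif(96, 0, 2))
    fit <- attribute_sample(y, sigs)
    oracle <- nnls_oracle(sigs$W, y)
    expect_lte(fit$residual_frob^2, oracle$obj + 1e-6)
  }
})

test_that("sparse attribution keeps exactly the generating signatures", {
  sigs <- synthetic_signatures("SBS96", k = 5L, seed = 53L)
  # single generating signature among five available
  res <- sparse_attribute(500 * sigs$W[, 1], sigs, drop_tol = 0.01)
  expect_equal(res$support, "SynSig1")
  # exact two-signature mixture: removal of either costs more than the tol
  res2 <- sparse_attribute(300 * sigs$W[, 1] + 200 * sigs$W[, 2],
                           signature_set(sigs$W[, 1:2], "SBS96"),
                           drop_tol = 0.01)
  expect_setequal(res2$support, c("SynSig1", "SynSig2"))
})

test_that("drop_tol = 0 reproduces the dense support", {
  sigs <- two_sig_set(54L)
  y <- 100 * sigs$W[, 1] + 50 * sigs$W[, 2]
  dense <- attribute_sample(y, sigs)
  sparse <- sparse_attribute(y, sigs, drop_tol = 0)
  expect_setequal(sparse$support,
                  names(dense$exposures)[dense$exposures > 1e-9])
})

test_that("sparse support shrinks monotonically along the elimination trace", {
  set.seed(55)
  sigs <- synthetic_signatures("SBS96", k = 6L, seed = 55L,
                               max_pairwise = 0.6)
  y <- as.numeric(sigs$W %*% c(200, 150, 100, 0, 0, 0)) +
    stats::rpois(96, 1)
  res <- sparse_attribute(y, sigs, drop_tol = 0.02)
  # each elimination step removed one signature; support + steps = start
  start <- sum(attribute_sample(y, sigs)$exposures > 1e-9)
  expect_equal(length(res$support), start - length(res$trace))
})

test_that("ARD attribution respects the indicator mask exactly", {
  sigs <- synthetic_signatures("SBS96", k = 3L, seed = 56L)
  sc <- simulation_scenario(sigs, 12L, burden_range = c(1e3, 1e4),
                            noise = "poisson", seed = 57L)
  sim <- simulate_catalogue(sc)
  # mask identity: all-ones Z equals the unconstrained fixed-W fit
  full <- attribute_ard(sim$catalogue, sigs, seed = 58L, max_iter = 3000L)
  Z <- matrix(1, 3, 12)
  masked <- attribute_ard(sim$catalogue, sigs, Z = Z, seed = 58L,
                          max_iter = 3000L)
  expect_equal(masked$exposures, full$exposures, tolerance = 1e-6)
  # mask annihilation: a zeroed row gives identically zero exposure
  Z2 <- Z; Z2[2, ] <- 0
  res <- attribute_ard(sim$catalogue, sigs, Z = Z2, seed = 58L,
                       max_iter = 3000L)
  expect_true(all(res$exposures[2, ] == 0))
})

test_that("ARD attribution recovers planted exposures across heterogeneous burdens", {
  sigs <- synthetic_signatures("SBS96", k = 3L, seed = 59L,
                               max_pairwise = 0.2)
  sc <- simulation_scenario(sigs, 60L, burden_range = c(1e2, 1e5),
                            noise = "poisson", seed = 60L)
  sim <- simulate_catalogue(sc)
  res <- attribute_ard(sim$catalogue, sigs, seed = 61L, max_iter = 3000L)
  for (k in 1:3) {
    rho <- stats::cor(sim$exposures[k, ], res$exposures[k, ],
                      method = "spearman")
    expect_gte(rho, 0.9)
  }
})

test_that("per-class signature probabilities normalize and degenerate correctly", {
  sigs <- two_sig_set(62L)
  # single active signature: every defined row is 1 for it
  P1 <- mutation_probabilities(sigs, c(10, 0))
  defined <- !attr(P1, "undefined")
  expect_true(all(P1[defined, 1] == 1))
  # direct arithmetic
  W <- matrix(c(0.2, 0.8, 0.1, 0.9), 2, 2)
  P <- mutation_probabilities(signature_set(W), c(10, 40))
  expect_equal(P[1, ], c(2 / 6, 4 / 6), tolerance = 1e-12,
               ignore_attr = TRUE)
  # rows sum to one
  set.seed(63)
  W3 <- matrix(stats::runif(96 * 3), 96, 3)
  P3 <- mutation_probabilities(signature_set(W3), c(5, 1, 8))
  expect_true(all(abs(rowSums(P3) - 1) < 1e-12))
  expect_error(mutation_probabilities(sigs, c(0, 0)), "zero")
})

test_that("allow-list rules become a binary indicator mask", {
  sigs <- synthetic_signatures("SBS96", k = 4L, seed = 64L)
  meta <- tibble::tibble(
    sample_id = c("s1", "s2", "s3"),
    cancer_type = c("Lung-AdenoCA", "Liver-HCC", "Head-SCC"))
  rules <- list(SynSig2 = list(cancer_types = list("Lung-AdenoCA",
                                                   "Head-SCC")),
                SynSig4 = list(samples = list("s2")))
  Z <- allow_mask_from_rules(rules, sigs, meta)
  expect_equal(Z["SynSig2", ], c(s1 = 1, s2 = 0, s3 = 1))
  expect_equal(Z["SynSig4", ], c(s1 = 0, s2 = 1, s3 = 0))
  expect_true(all(Z[c("SynSig1", "SynSig3"), ] == 1))
  expect_error(allow_mask_from_rules(list(Nope = list(samples = "s1")),
                                     sigs, meta), "unknown signature")
  # the shipped example config parses
  path <- system.file("extdata", "example_attribution_rules.yaml",
                      package = "sigtool")
  expect_true(file.exists(path))
  expect_type(yaml::read_yaml(path), "list")
})
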