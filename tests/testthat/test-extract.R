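test_that("a single planted signature gives a maximally stable rank-1 solution", {
  sc <- planted_scenario(k = 1L, n_samples = 25L, seed = 8L)
  sim <- simulate_catalogue(sc)
  ex <- extract_signatures(sim$catalogue, k_range = 1:3, n_iterations = 12L,
                           seed = 9L, max_iter = 2000L)
  expect_equal(ex$selected_k, 1L)
  expect_gt(ex$stability[["1"]], 0.98)
  rec <- recovery_cosines(sc$signatures$W, solution_at(ex, 1L)$signatures$W)
  expect_gt(rec[1], 0.99)
})

test_that("three planted signatures are recovered at the correct rank", {
  sc <- planted_scenario(k = 3L, n_samples = 100L, seed = 10L)
  sim <- simulate_catalogue(sc)
  ex <- extract_signatures(sim$catalogue, k_range = 2:4, n_iterations = 16L,
                           seed = 11L, tol = 1e-6, max_iter = 2000L)
  expect_equal(ex$selected_k, 3L)
  rec <- recovery_cosines(sc$signatures$W, solution_at(ex, 3L)$signatures$W)
  expect_true(all(rec >= 0.95))
})

test_that("extraction is bitwise reproducible under a fixed seed", {
  sc <- planted_scenario(k = 2L, n_samples = 20L, seed = 12L)
  sim <- simulate_catalogue(sc)
  ex1 <- extract_signatures(sim$catalogue, k_range = 2L, n_iterations = 8L,
                            seed = 13L, max_iter = 500L)
  ex2 <- extract_signatures(sim$catalogue, k_range = 2L, n_iterations = 8L,
                            seed = 13L, max_iter = 500L)
  expect_identical(solution_at(ex1, 2L)$signatures$W,
                   solution_at(ex2, 2L)$signatures$W)
})

test_that("too few iterations for a stability estimate is an error", {
  sc <- planted_scenario(k = 1L, n_samples = 10L, seed = 14L)
  sim <- simulate_catalogue(sc)
  expect_error(extract_signatures(sim$catalogue, 1L, n_iterations = 1L),
               "n_iterations")
})

test_that("glance exposes the full stability/accuracy table for human rank review", {
  sc <- planted_scenario(k = 2L, n_samples = 20L, seed = 15L)
  sim <- simulate_catalogue(sc)
  ex <- extract_signatures(sim$catalogue, k_range = 1:3, n_iterations = 8L,
                           seed = 16L, max_iter = 500L)
  g <- glance(ex)
  expect_named(g, c("k", "stability", "kl_error", "frob_error",
                    "relative_gain", "selected"))
  expect_equal(g$k, 1:3)
  expect_true(all(g$stability >= -1 & g$stability <= 1))
  expect_true(all(g$kl_error >= 0))
  expect_equal(sum(g$selected), 1L)
})

test_that("hierarchical extraction stops at one level when everything reconstructs", {
  sc <- planted_scenario(k = 2L, n_samples = 30L, seed = 17L)
  sim <- simulate_catalogue(sc)
  hx <- hierarchical_extract(sim$catalogue, k_range = 2L,
                             n_iterations = 8L, seed = 18L,
                             recon_threshold = 0.8, max_iter = 500L)
  expect_equal(nrow(hx$report), 1L)
  expect_equal(n_signatures(hx$signatures), 2L)
})

test_that("hierarchical extraction rescues a rare signature at level 2", {
  sigs <- synthetic_signatures("SBS96", k = 2L, seed = 19L,
                               max_pairwise = 0.12)
  W <- sigs$W
  set.seed(20)
  n_common <- 95L; n_rare <- 5L
  burdens <- round(10^stats::runif(n_common + n_rare, 3, 3.5))
  V <- cbind(
    vapply(1:n_common, function(j)
      stats::rpois(96, W[, 1] * burdens[j]), numeric(96)),
    vapply(1:n_rare, function(j)
      stats::rpois(96, W[, 2] * burdens[n_common + j]), numeric(96)))
  rownames(V) <- rownames(W)
  colnames(V) <- sprintf("s%03d", seq_len(ncol(V)))
  hx <- hierarchical_extract(V, k_range = 1L, n_iterations = 8L,
                             seed = 21L, recon_threshold = 0.9,
                             max_levels = 2L, tol = 1e-6, max_iter = 2000L)
  expect_gte(nrow(hx$report), 2L)
  # level 2 ran on exactly the rare samples
  expect_equal(hx$report$n_samples[2], n_rare)
  rec <- recovery_cosines(W, hx$signatures$W)
  expect_true(all(rec >= 0.95))
})

test_that("max_levels = 1 reduces to plain extraction", {
  sc <- planted_scenario(k = 2L, n_samples = 20L, seed = 22L)
  sim <- simulate_catalogue(sc)
  hx <- hierarchical_extract(sim$catalogue, k_range = 2L, n_iterations = 8L,
                             seed = 30L, max_levels = 1L, max_iter = 500L)
  ex <- extract_signatures(sim$catalogue, k_range = 2L, n_iterations = 8L,
                           seed = 31L, max_iter = 500L)
  # same consensus profiles up to column order and seed-independent noise
  rec <- recovery_cosines(solution_at(ex, 2L)$signatures$W, hx$signatures$W)
  expect_true(all(rec >= 0.98))
  expect_equal(nrow(hx$report), 1L)
})

test_that("the Hungarian assignment equals exhaustive search on small instances", {
  set.seed(23)
  for (n in 2:6) {
    C <- matrix(stats::runif(n * n), n, n)
    a <- hungarian_assign(C)
    perms <- all_permutations(n)
    costs <- apply(perms, 1, function(p) sum(C[cbind(1:n, p)]))
    expect_equal(sum(C[cbind(1:n, a)]), min(costs), tolerance = 1e-12)
  }
  # rectangular: 3 rows into 5 columns
  C <- matrix(stats::runif(15), 3, 5)
  a <- hungarian_assign(C)
  expect_equal(length(unique(a)), 3L)
})
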