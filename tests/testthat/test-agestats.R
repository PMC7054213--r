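test_that("three-standard-deviation outlier removal is single-pass with a kept boundary", {
  expect_equal(remove_outliers(rep(5, 10)), 1:10)          # sd = 0
  x <- c(rep(0, 9), 100)                                   # mean 10, sd ~31.6
  expect_equal(remove_outliers(x), 1:10)                   # 100 < 10 + 3 sd
  # a value exactly at the 3-sd boundary is kept (non-strict <=)
  y <- c(-1, 1, rep(0, 48))
  m <- mean(y); s <- stats::sd(y)
  z <- c(y, m + 3 * s)
  keep <- remove_outliers(z)
  expect_true(length(z) %in% keep)
  # a clear outlier is removed
  w <- c(stats::rnorm(50), 1e6)
  expect_false(51 %in% remove_outliers(w))
  expect_error(remove_outliers(c(1, 2)), "at least 3")
})

test_that("robust regression recovers a noiseless line", {
  x <- seq(20, 80, length.out = 30)
  fit <- robust_fit(x, 2 * x + 1)
  expect_equal(fit$slope, 2.0, tolerance = 1e-8)
  expect_equal(fit$intercept, 1.0, tolerance = 1e-6)
  expect_lt(fit$p_value, 1e-6)
  expect_error(robust_fit(rep(50, 10), stats::rnorm(10)), "degenerate")
  expect_error(robust_fit(1:3, 1:3), "at least 4")
})

test_that("slope F-test holds its nominal size under the null", {
  set.seed(90)
  n <- 200L
  hits <- 0L
  reps <- 500L
  for (r in seq_len(reps)) {
    x <- stats::runif(n, 30, 80)
    y <- stats::rnorm(n)
    if (robust_fit(x, y)$p_value < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.03)
  expect_lte(hits / reps, 0.07)
})

test_that("bisquare weighting resists gross outliers where plain least squares fails", {
  set.seed(91)
  n <- 100L
  x <- stats::runif(n, 20, 80)
  y <- 3 * x + stats::rnorm(n, sd = 2)
  out <- sample.int(n, 10L)
  y[out] <- y[out] + stats::runif(10L, 300, 600)
  fit <- robust_fit(x, y)
  ols <- stats::coef(stats::lm(y ~ x))[2]
  expect_lt(abs(fit$slope - 3), 0.2)
  expect_gt(abs(ols - 3), abs(fit$slope - 3))
})

test_that("robust fit agrees with rlm-style M-estimation on clean data", {
  set.seed(92)
  x <- stats::runif(60, 20, 80)
  y <- 1.5 * x + stats::rnorm(60, sd = 3)
  fit <- robust_fit(x, y)
  rlm_fit <- MASS::rlm(y ~ x, psi = MASS::psi.bisquare, c = 4.685,
                       maxit = 100)
  expect_equal(fit$slope, unname(stats::coef(rlm_fit)[2]), tolerance = 0.05)
})

test_that("Benjamini-Hochberg adjustment matches the step-up definition", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(93)
  for (rep in 1:1000) {
    m <- sample(1:12, 1)
    p <- stats::runif(m)
    q <- bh_adjust(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
  }
  # monotone in the sorted-p order
  p <- stats::runif(20)
  q <- bh_adjust(p)
  expect_true(all(diff(q[order(p)]) >= -1e-15))
})

test_that("the age scan finds the one signature with a real clock-like slope", {
  set.seed(94)
  n <- 80L
  ages <- stats::runif(n, 30, 80)
  H <- rbind(
    SigA = 10 * ages + stats::rnorm(n, sd = 40),   # true slope 10 / year
    SigB = stats::rnorm(n, 500, 80),
    SigC = stats::rnorm(n, 200, 50))
  H <- pmax(H, 0)
  colnames(H) <- sprintf("s%02d", 1:n)
  meta <- tibble::tibble(sample_id = colnames(H), age = ages,
                         cancer_type = "Liver-HCC")
  scan <- age_scan(H, meta)
  res <- tidy(scan)
  expect_lt(res$q_value[res$signature == "SigA"], 0.05)
  expect_equal(res$slope[res$signature == "SigA"], 10, tolerance = 1.5)
  expect_true(all(res$q_value[res$signature != "SigA"] > 0.05))
})

test_that("tiny strata are skipped with a reason, and sample order is irrelevant", {
  set.seed(95)
  n <- 40L
  ages <- stats::runif(n, 30, 80)
  H <- rbind(SigA = 5 * ages + stats::rnorm(n, sd = 20))
  colnames(H) <- sprintf("s%02d", 1:n)
  meta <- tibble::tibble(
    sample_id = colnames(H), age = ages,
    cancer_type = c(rep("TypeBig", n - 3L), rep("TypeTiny", 3L)))
  scan <- age_scan(H, meta)
  expect_equal(nrow(tidy(scan)), 1L)
  expect_equal(scan$skipped$cancer_type, "TypeTiny")
  # shuffled sample order gives identical results
  perm <- sample.int(n)
  scan2 <- age_scan(H[, perm, drop = FALSE], meta[perm, ])
  expect_equal(tidy(scan2), tidy(scan))
})

test_that("p-values are corrected jointly across signatures and cancer types", {
  set.seed(96)
  n <- 60L
  ages <- stats::runif(n, 30, 80)
  types <- rep(c("A", "B"), each = n / 2)
  H <- rbind(Sig1 = stats::rnorm(n, 100, 10),
             Sig2 = stats::rnorm(n, 100, 10))
  colnames(H) <- sprintf("s%02d", 1:n)
  meta <- tibble::tibble(sample_id = colnames(H), age = ages,
                         cancer_type = types)
  res <- tidy(age_scan(H, meta))
  expect_equal(nrow(res), 4L)  # 2 signatures x 2 types, one family
  expect_equal(res$q_value, bh_adjust(res$p_value))
})
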