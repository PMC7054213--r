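# Shared fixtures and independent oracles, built in code at test time.

# deterministic toy reference: one contig with known composition
toy_reference <- function(length = 5000L, seed = 99L) {
  set.seed(seed)
  stats::setNames(paste(sample(c("A", "C", "G", "T"), length,
                               replace = TRUE), collapse = ""), "chr1")
}

# enumerate all permutations of 1..n (for brute-force assignment search)
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, ifelse(sub >= i, sub + 1L, sub))
  }))
}

# independent NNLS oracle: exhaustive search over all support subsets,
# solving unconstrained least squares on each and keeping the best
# feasible (all-nonnegative) solution. Exact for small signature counts.
nnls_oracle <- function(W, y) {
  k <- ncol(W)
  best <- list(obj = sum(y^2), x = rep(0, k))
  for (size in seq_len(k)) {
    for (sub in utils::combn(k, size, simplify = FALSE)) {
      fit <- tryCatch(stats::lm.fit(W[, sub, drop = FALSE], y),
                      error = function(e) NULL)
      if (is.null(fit)) next
      coefs <- fit$coefficients
      if (anyNA(coefs) || any(coefs < -1e-10)) next
      x <- rep(0, k); x[sub] <- pmax(coefs, 0)
      obj <- sum((y - W %*% x)^2)
      if (obj < best$obj) best <- list(obj = obj, x = x)
    }
  }
  best
}

# brute-force step-up Benjamini-Hochberg from the definition:
# q_i = min_{k: p_(k) >= p_(i)} m * p_(k) / k, in input order
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(vapply(i:m, function(k) m * p[ord[k]] / k,
                              numeric(1)), 1)
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# O(n^2) all-pairs clustered-mutation oracle
clustered_oracle <- function(mutations, max_dist = 1000L) {
  out <- logical(nrow(mutations))
  for (i in seq_len(nrow(mutations))) {
    same <- mutations$sample_id == mutations$sample_id[i] &
      mutations$chrom == mutations$chrom[i]
    same[i] <- FALSE
    out[i] <- any(abs(mutations$pos[same] - mutations$pos[i]) < max_dist)
  }
  out
}

# planted-signature scenario used across extraction tests
planted_scenario <- function(k = 3L, n_samples = 200L, seed = 1L,
                             max_pairwise = 0.25, noise = "poisson",
                             burden_range = c(1e3, 1e4)) {
  sigs <- synthetic_signatures("SBS96", k = k, seed = seed,
                               max_pairwise = max_pairwise)
  simulation_scenario(sigs, n_samples, burden_range = burden_range,
                      dirichlet_alpha = 1, noise = noise, seed = seed)
}

# greatest cosine match of each true signature among recovered columns
recovery_cosines <- function(W_true, W_hat) {
  sims <- t(W_true) %*% W_hat /
    outer(sqrt(colSums(W_true^2)), sqrt(colSums(W_hat^2)))
  if (ncol(W_hat) >= ncol(W_true)) {
    assign <- hungarian_assign(-sims)
    sims[cbind(seq_len(nrow(sims)), assign)]
  } else {
    apply(sims, 1, max)
  }
}
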