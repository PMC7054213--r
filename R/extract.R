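# ---- assignment and similarity helpers --------------------------------

#' Optimal one-to-one assignment (Hungarian algorithm)
#'
#' Minimum-cost assignment of rows to columns of a rectangular cost
#' matrix (shortest-augmenting-path formulation, O(n^2 m)). With more rows
#' than columns the transpose is solved.
#'
#' @param cost numeric matrix.
#' @return integer vector: for each row, the assigned column (0 = row
#'   unassigned, possible only when `nrow > ncol`).
#' @export
hungarian_assign <- function(cost) {
  if (nrow(cost) > ncol(cost)) {
    colmatch <- hungarian_assign(t(cost))
    out <- integer(nrow(cost))
    out[colmatch] <- seq_along(colmatch)
    return(out)
  }
  n <- nrow(cost); m <- ncol(cost)
  u <- numeric(n); v <- numeric(m + 1L)
  p <- integer(m + 1L); way <- integer(m + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i; j0 <- 0L
    minv <- rep(Inf, m); used <- rep(FALSE, m + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      free <- which(!used[-1L])
      cur <- cost[i0, free] - u[i0] - v[free + 1L]
      upd <- cur < minv[free]
      minv[free[upd]] <- cur[upd]
      way[free[upd] + 1L] <- j0
      j1 <- free[which.min(minv[free])]
      delta <- minv[j1]
      usedj <- which(used) # 1-based positions = col index + 1
      u[p[usedj]] <- u[p[usedj]] + delta
      v[usedj] <- v[usedj] - delta
      minv[free] <- minv[free] - delta
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  out <- integer(n)
  for (j in seq_len(m)) if (p[j + 1L] > 0L) out[p[j + 1L]] <- j
  out
}

# columns-of-A vs columns-of-B cosine similarity matrix
cosine_columns <- function(A, B) {
  na <- sqrt(colSums(A^2)); nb <- sqrt(colSums(B^2))
  crossprod(A, B) / outer(pmax(na, 1e-300), pmax(nb, 1e-300))
}

# ---- consensus clustering of bootstrap signatures ---------------------

# Ws: list of classes x k matrices (one per NMF iteration, columns
# normalized). Returns centroids, mean silhouette and per-point silhouettes.
consensus_cluster <- function(Ws, k, seed, max_rounds = 100L,
                              silhouette_cap = 3000L) {
  n_iter <- length(Ws)
  set.seed(seed)
  centroids <- Ws[[sample.int(n_iter, 1L)]]
  assign_prev <- NULL
  for (round in seq_len(max_rounds)) {
    assignments <- matrix(0L, n_iter, k)
    sums <- matrix(0, nrow(centroids), k)
    for (i in seq_len(n_iter)) {
      cost <- 1 - cosine_columns(Ws[[i]], centroids)  # k x k
      a <- hungarian_assign(cost)                     # signature -> cluster
      assignments[i, ] <- a
      for (s in seq_len(k)) sums[, a[s]] <- sums[, a[s]] + Ws[[i]][, s]
    }
    centroids <- sweep(sums, 2, pmax(colSums(sums), 1e-300), "/")
    if (!is.null(assign_prev) && identical(assignments, assign_prev)) break
    assign_prev <- assignments
  }
  pooled <- do.call(cbind, Ws)
  labels <- as.integer(t(assign_prev))  # iteration-major, signature within
  if (k == 1L) {
    sil <- as.numeric(cosine_columns(pooled, centroids))
    return(list(centroids = centroids, silhouettes = sil,
                stability = mean(sil)))
  }
  idx <- seq_len(ncol(pooled))
  if (length(idx) > silhouette_cap) idx <- sort(sample(idx, silhouette_cap))
  D <- 1 - cosine_columns(pooled[, idx, drop = FALSE],
                          pooled[, idx, drop = FALSE])
  lab <- labels[idx]
  sil <- vapply(seq_along(idx), function(p) {
    own <- lab == lab[p]
    a <- if (sum(own) > 1L) sum(D[p, own]) / (sum(own) - 1L) else 0
    b <- min(vapply(setdiff(unique(lab), lab[p]), function(cl)
      mean(D[p, lab == cl]), numeric(1)))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
  list(centroids = centroids, silhouettes = sil, stability = mean(sil))
}

# ---- de novo extraction ----------------------------------------------

#' De novo signature extraction by bootstrapped KL-NMF with consensus
#' clustering
#'
#' For each candidate rank `k`, runs [nmf_kl()] on `n_iterations`
#' bootstrap resamples of the catalogue, pools the resulting signature
#' vectors, and clusters them into `k` consensus signatures under cosine
#' distance with the constraint that each iteration contributes exactly
#' one signature per cluster (optimal per-iteration matching). Solution
#' stability is the mean silhouette of the clustered vectors; consensus
#' exposures re-attribute the original catalogue by nonnegative least
#' squares. Automatic rank selection (largest stable rank whose
#' reconstruction still improves) is advisory: inspect the full
#' stability/accuracy table via [glance()].
#'
#' @inheritParams nmf_kl
#' @param k_range integer vector of candidate ranks.
#' @param n_iterations bootstrap NMF iterations per rank (default 1024).
#' @param stability_min minimum mean silhouette for a rank to be eligible.
#' @param gain_min minimum relative KL improvement over the previous rank.
#' @param scheme bootstrap resampling scheme, see [bootstrap_catalogue()].
#' @return object of class `signature_extraction`: per-rank solutions
#'   (`signatures`, `exposures`, `stability`, `kl_error`, `frob_error`,
#'   per-sample reconstruction cosines) plus `selected_k`.
#' @export
extract_signatures <- function(V, k_range, n_iterations = 1024L, seed = 1L,
                               tol = 1e-8, max_iter = 10000L,
                               stability_min = 0.8, gain_min = 0.02,
                               scheme = "multinomial") {
  M <- catalogue_matrix(V)
  schema <- if (inherits(V, "mutation_catalogue")) V$schema else NA_character_
  if (n_iterations < 2L)
    stop("n_iterations must be at least 2 for a stability estimate",
         call. = FALSE)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 1L) || any(k_range > min(dim(M))))
    stop("k_range outside valid rank bounds", call. = FALSE)

  by_rank <- list()
  for (k in k_range) {
    Ws <- vector("list", n_iterations)
    for (it in seq_len(n_iterations)) {
      iter_seed <- seed + 1000L * match(k, k_range) + it
      Vb <- bootstrap_catalogue(M, seed = iter_seed, scheme = scheme)
      fit <- nmf_kl(Vb, k, seed = iter_seed, tol = tol, max_iter = max_iter)
      Ws[[it]] <- fit$W
    }
    cc <- consensus_cluster(Ws, k, seed = seed + match(k, k_range))
    W <- cc$centroids
    dimnames(W) <- list(rownames(M), paste0("Sig", seq_len(k)))
    sig <- signature_set(W, schema)
    att <- attribute_catalogue(M, sig)
    R <- sig$W %*% att$exposures
    by_rank[[as.character(k)]] <- list(
      k = k, signatures = sig, exposures = att$exposures,
      stability = cc$stability, silhouettes = cc$silhouettes,
      kl_error = kl_divergence(M, R),
      frob_error = sqrt(sum((M - R)^2)),
      sample_cosines = att$diagnostics$cosine)
  }

  kl <- vapply(by_rank, `[[`, numeric(1), "kl_error")
  stab <- vapply(by_rank, `[[`, numeric(1), "stability")
  gain <- c(Inf, -diff(kl) / utils::head(kl, -1))
  eligible <- stab >= stability_min & gain >= gain_min
  selected_k <- if (any(eligible)) max(k_range[eligible]) else k_range[1]

  structure(list(by_rank = by_rank, k_range = k_range,
                 selected_k = selected_k, stability = stab, kl_error = kl,
                 relative_gain = gain,
                 params = list(n_iterations = n_iterations, seed = seed,
                               stability_min = stability_min,
                               gain_min = gain_min, scheme = scheme)),
            class = "signature_extraction")
}

#' @export
print.signature_extraction <- function(x, ...) {
  cat("<signature_extraction> ranks", paste(x$k_range, collapse = ","),
      "- selected k =", x$selected_k, "(advisory)\n")
  print(glance(x))
  invisible(x)
}

#' Extract the solution at one rank
#' @param x a `signature_extraction`.
#' @param k rank; defaults to the selected rank.
#' @return list with `signatures`, `exposures` and diagnostics.
#' @export
solution_at <- function(x, k = x$selected_k) {
  sol <- x$by_rank[[as.character(k)]]
  if (is.null(sol)) stop("rank ", k, " was not examined", call. = FALSE)
  sol
}

#' Hierarchical signature extraction
#'
#' Runs [extract_signatures()] on all samples, then re-runs it on the
#' subset of samples whose spectra are poorly reconstructed
#' (reconstruction cosine below `recon_threshold`), appending any novel
#' signatures (cosine below `novelty_max` to every signature already
#' found). Iterates until no sample fails the threshold or `max_levels`
#' is reached. This recovers signatures that generate few mutations or
#' occur in few samples.
#'
#' @inheritParams extract_signatures
#' @param recon_threshold per-sample reconstruction-cosine threshold.
#' @param max_levels maximum number of extraction levels.
#' @param novelty_max a candidate signature is novel when its maximum
#'   cosine to the existing set is below this value.
#' @return list with `signatures` (combined `signature_set`), `report`
#'   (per-level tibble) and `levels` (per-level extraction objects).
#' @export
hierarchical_extract <- function(V, k_range, n_iterations = 64L, seed = 1L,
                                 recon_threshold = 0.95, max_levels = 3L,
                                 novelty_max = 0.9, ...) {
  M <- catalogue_matrix(V)
  schema <- if (inherits(V, "mutation_catalogue")) V$schema else NA_character_
  levels <- list()
  report <- list()
  combined <- NULL
  active <- colnames(M) %||% as.character(seq_len(ncol(M)))
  colnames(M) <- active

  for (level in seq_len(max_levels)) {
    sub <- M[, active, drop = FALSE]
    k_here <- k_range[k_range <= min(dim(sub))]
    if (!length(k_here)) break
    ex <- extract_signatures(sub, k_here, n_iterations = n_iterations,
                             seed = seed + level, ...)
    sol <- solution_at(ex)
    levels[[level]] <- ex
    new_W <- sol$signatures$W
    novel <- if (is.null(combined)) seq_len(ncol(new_W)) else {
      sims <- cosine_columns(new_W, combined)
      which(apply(sims, 1L, max) < novelty_max)
    }
    if (is.null(combined)) {
      combined <- new_W
      colnames(combined) <- paste0("L1.", colnames(new_W))
    } else if (length(novel)) {
      add <- new_W[, novel, drop = FALSE]
      colnames(add) <- paste0("L", level, ".", colnames(new_W)[novel])
      combined <- cbind(combined, add)
    }
    sigset <- signature_set(combined, schema)
    att <- attribute_catalogue(M, sigset)
    failing <- colnames(M)[att$diagnostics$cosine < recon_threshold]
    report[[level]] <- tibble::tibble(
      level = level, n_samples = length(active),
      n_novel = if (level == 1L) ncol(new_W) else length(novel),
      n_failing_after = length(failing))
    if (!length(failing)) break
    if (identical(sort(failing), sort(active)) && level > 1L) break
    active <- failing
  }

  list(signatures = signature_set(combined, schema),
       report = dplyr::bind_rows(report), levels = levels)
}
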