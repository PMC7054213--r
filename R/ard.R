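#' Bayesian NMF with automatic relevance determination
#'
#' Factorizes the catalogue under a Poisson (generalized-KL) likelihood
#' with per-component scale hyperparameters; components whose relevance
#' collapses are pruned, so the effective number of signatures is inferred
#' rather than fixed. Component priors are exponential (`"exponential"`,
#' L1-type, the default) or half-normal (`"halfnormal"`, L2-type). The
#' procedure performs a stochastic search: `n_restarts` runs from random
#' initializations are performed and the solution with the highest
#' posterior probability (lowest negative log-posterior) is returned.
#'
#' @inheritParams nmf_kl
#' @param k_max maximum number of components.
#' @param prior `"exponential"` or `"halfnormal"`.
#' @param n_restarts number of random restarts (default 10).
#' @param a hyperprior shape; larger values sharpen relevance selection.
#' @param b hyperprior scale; `NULL` uses a data-scaled default.
#' @param prune_rel component pruned when its relevance (share of
#'   reconstructed mass) falls below `prune_rel` times the maximum.
#' @return list with `signatures` (pruned `signature_set`), `exposures`,
#'   `relevance` (per surviving component), `effective_k`,
#'   `log_posterior` (of the best restart, up to a constant), and
#'   `restarts` (per-restart table).
#' @export
ard_nmf <- function(V, k_max, prior = c("exponential", "halfnormal"),
                    seed = 1L, n_restarts = 10L, a = 10, b = NULL,
                    prune_rel = 1e-2, tol = 1e-8, max_iter = 10000L) {
  prior <- match.arg(prior)
  M <- catalogue_matrix(V)
  schema <- if (inherits(V, "mutation_catalogue")) V$schema else NA_character_
  if (k_max < 1L) stop("k_max must be at least 1", call. = FALSE)
  if (k_max > min(dim(M)))
    stop("k_max exceeds min(classes, samples)", call. = FALSE)
  prior_code <- if (prior == "exponential") 1L else 2L
  if (is.null(b)) {
    b <- if (prior == "exponential")
      sqrt((a - 1) * (a - 2) * mean(M) / k_max)
    else (a - 1) * mean(M) / k_max
  }
  runs <- vector("list", n_restarts)
  for (r in seq_len(n_restarts)) {
    set.seed(seed + r - 1L)
    W0 <- matrix(stats::runif(nrow(M) * k_max, 0.1, 1), nrow(M), k_max)
    H0 <- matrix(stats::runif(k_max * ncol(M), 0.1, 1) * mean(M), k_max,
                 ncol(M))
    runs[[r]] <- cpp_ard_nmf(M, W0, H0, a, b, prior_code, tol,
                             as.integer(max_iter), 10L, 0L, TRUE,
                             matrix(1, 1, 1), FALSE)
  }
  nlp <- vapply(runs, `[[`, numeric(1), "neg_log_posterior")
  best <- runs[[which.min(nlp)]]
  pruned <- prune_components(best$W, best$H, prune_rel)
  W <- pruned$W
  dimnames(W) <- list(rownames(M), paste0("Sig", seq_len(ncol(W))))
  H <- pruned$H
  dimnames(H) <- list(colnames(W),
                      colnames(M) %||% paste0("S", seq_len(ncol(M))))
  list(signatures = signature_set(sweep(W, 2, colSums(W), "/"), schema),
       exposures = sweep(H, 1, colSums(W), "*"),
       relevance = pruned$relevance, effective_k = ncol(W),
       log_posterior = -min(nlp),
       restarts = tibble::tibble(restart = seq_len(n_restarts),
                                 neg_log_posterior = nlp,
                                 kl = vapply(runs, `[[`, numeric(1), "kl")))
}

# relevance = share of reconstructed mass carried by each component
prune_components <- function(W, H, prune_rel) {
  energy <- colSums(W) * rowSums(H)
  keep <- energy >= prune_rel * max(energy)
  list(W = W[, keep, drop = FALSE], H = H[keep, , drop = FALSE],
       relevance = energy[keep] / sum(energy))
}

#' Two-step extraction for cohorts with hypermutated samples
#'
#' Step 1 extracts signatures by [ard_nmf()] from the samples with a low
#' mutation burden only. Step 2 re-runs the ARD updates on the
#' hypermutated samples with the step-1 signature columns held fixed and
#' `k_extra` additional free columns, so signatures found in low-burden
#' samples may explain hypermutated spectra while novel processes unique
#' to hypermutators surface as new columns. Free columns surviving
#' relevance pruning are labelled hyper-only when they are novel (maximum
#' cosine to every step-1 signature below `novelty_max`); at extreme
#' burdens a free column can instead re-learn an existing profile, and
#' such duplicates have their activity folded back into the matching
#' fixed signature. Hyper-only signatures must never be offered when
#' attributing low-burden samples. Which samples count as
#' hypermutated is a biological decision supplied by the caller (see
#' [split_by_burden()] for a labelled heuristic).
#'
#' @param V_low,V_hyper catalogues (or matrices) over disjoint sample
#'   sets; `V_low` must be nonempty, `V_hyper` may be `NULL`/empty.
#' @param k_max maximum components for step 1.
#' @param k_extra free columns offered in step 2 (default `k_max`).
#' @param novelty_max cosine threshold below which a surviving free
#'   column counts as a novel, hyper-only signature.
#' @inheritParams ard_nmf
#' @return list with `signatures` (combined set), `hyper_only` (names of
#'   hyper-only signatures), `step1`, and exposures for both steps.
#' @export
two_step_extract <- function(V_low, V_hyper, k_max, seed = 1L,
                             k_extra = k_max, prior = "exponential",
                             n_restarts = 10L, a = 10, b = NULL,
                             prune_rel = 1e-2, novelty_max = 0.9,
                             tol = 1e-8, max_iter = 10000L) {
  M_low <- catalogue_matrix(V_low)
  if (!ncol(M_low)) stop("V_low must be nonempty", call. = FALSE)
  step1 <- ard_nmf(V_low, k_max, prior = prior, seed = seed,
                   n_restarts = n_restarts, a = a, b = b,
                   prune_rel = prune_rel, tol = tol, max_iter = max_iter)
  W1 <- step1$signatures$W
  if (is.null(V_hyper) || ncol(catalogue_matrix(V_hyper)) == 0L) {
    return(list(signatures = step1$signatures, hyper_only = character(0),
                step1 = step1, exposures_low = step1$exposures,
                exposures_hyper = NULL))
  }
  M_hyper <- catalogue_matrix(V_hyper)
  if (length(intersect(colnames(M_low), colnames(M_hyper))))
    stop("low-burden and hypermutated sample sets must be disjoint",
         call. = FALSE)
  prior_code <- if (prior == "exponential") 1L else 2L
  if (is.null(b)) {
    b <- if (prior == "exponential")
      sqrt((a - 1) * (a - 2) * mean(M_hyper) / max(k_extra, 1L))
    else (a - 1) * mean(M_hyper) / max(k_extra, 1L)
  }
  n_fixed <- ncol(W1)
  runs <- vector("list", n_restarts)
  for (r in seq_len(n_restarts)) {
    set.seed(seed + 100L + r)
    W0 <- cbind(W1, matrix(stats::runif(nrow(M_hyper) * k_extra, 0.1, 1),
                           nrow(M_hyper), k_extra))
    H0 <- matrix(stats::runif((n_fixed + k_extra) * ncol(M_hyper), 0.1, 1) *
                   mean(M_hyper), n_fixed + k_extra, ncol(M_hyper))
    runs[[r]] <- cpp_ard_nmf(M_hyper, W0, H0, a, b, prior_code, tol,
                             as.integer(max_iter), 10L, n_fixed, TRUE,
                             matrix(1, 1, 1), FALSE)
  }
  nlp <- vapply(runs, `[[`, numeric(1), "neg_log_posterior")
  best <- runs[[which.min(nlp)]]
  free_idx <- seq_len(k_extra) + n_fixed
  energy <- colSums(best$W) * rowSums(best$H)
  keep_free <- free_idx[energy[free_idx] >= prune_rel * max(energy)]
  # a surviving free column is hyper-only when it is genuinely novel;
  # free columns that merely re-learn a step-1 profile (a well-known
  # failure mode at extreme burdens, where even a minute profile misfit
  # outweighs the relevance penalty) have their activity folded back into
  # the matching fixed signature
  H_free <- best$H[keep_free, , drop = FALSE] *
    colSums(best$W[, keep_free, drop = FALSE])
  W_free <- sweep(best$W[, keep_free, drop = FALSE], 2,
                  colSums(best$W[, keep_free, drop = FALSE]), "/")
  H_fixed <- best$H[seq_len(n_fixed), , drop = FALSE]
  novel_W <- matrix(numeric(0), nrow(W1), 0)
  novel_H <- matrix(numeric(0), 0, ncol(M_hyper))
  if (length(keep_free)) {
    sims <- cosine_columns(W_free, W1)
    for (i in order(rowSums(H_free), decreasing = TRUE)) {
      if (max(sims[i, ]) >= novelty_max) {
        j <- which.max(sims[i, ])
        H_fixed[j, ] <- H_fixed[j, ] + H_free[i, ]
      } else if (ncol(novel_W) &&
                 max(cosine_columns(W_free[, i, drop = FALSE],
                                    novel_W)) >= novelty_max) {
        # near-duplicate of an already-accepted novel column
        j <- which.max(cosine_columns(W_free[, i, drop = FALSE], novel_W))
        novel_H[j, ] <- novel_H[j, ] + H_free[i, ]
      } else {
        novel_W <- cbind(novel_W, W_free[, i])
        novel_H <- rbind(novel_H, H_free[i, ])
      }
    }
  }
  hyper_names <- if (ncol(novel_W)) paste0("Hyper", seq_len(ncol(novel_W)))
                 else character(0)
  colnames(novel_W) <- hyper_names
  W_comb <- cbind(W1, if (ncol(novel_W)) novel_W)
  H_hyper <- rbind(H_fixed, novel_H)
  rownames(H_hyper) <- colnames(W_comb)
  colnames(H_hyper) <- colnames(M_hyper)
  list(signatures = signature_set(W_comb, step1$signatures$schema),
       hyper_only = hyper_names, step1 = step1,
       exposures_low = step1$exposures, exposures_hyper = H_hyper)
}

#' Split samples into low-burden and hypermutated sets by burden quantile
#'
#' A heuristic convenience only: the published strategy defines
#' hypermutators by tumour biology (mismatch-repair deficiency, POLE
#' mutation, UV exposure, temozolomide treatment), not by a numeric rule.
#'
#' @param V `mutation_catalogue` or counts matrix.
#' @param quantile burden quantile above which a sample is called
#'   hypermutated.
#' @return list with character vectors `low` and `hyper`.
#' @export
split_by_burden <- function(V, quantile = 0.95) {
  M <- catalogue_matrix(V)
  burdens <- colSums(M)
  cut <- stats::quantile(burdens, quantile)
  list(low = colnames(M)[burdens <= cut], hyper = colnames(M)[burdens > cut])
}
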