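#' Attribute a mutational spectrum to fixed signatures
#'
#' Finds the nonnegative exposure vector `a` minimizing
#' `||spectrum - W a||` (Frobenius/Euclidean norm) over the allowed
#' signatures, by active-set nonnegative least squares. The optimum of
#' this convex problem is solver-independent. Exposures are on the
#' mutation-count scale; disallowed signatures receive exactly zero.
#'
#' @param spectrum numeric class-count vector (length = schema classes).
#' @param signatures a `signature_set` (or classes x signatures matrix).
#' @param allowed character or integer subset of signatures permitted for
#'   this sample; default all.
#' @param renormalize if `TRUE`, scale nonzero exposures so they sum to
#'   the observed mutation total.
#' @return list with `exposures` (named vector over all signatures),
#'   `cosine` (reconstruction cosine), `residual_frob`, `residual_kl`.
#' @export
attribute_sample <- function(spectrum, signatures, allowed = NULL,
                             renormalize = FALSE) {
  W <- if (inherits(signatures, "signature_set")) signatures$W
       else as.matrix(signatures)
  if (length(spectrum) != nrow(W))
    stop("spectrum length does not match signature classes", call. = FALSE)
  sig_names <- colnames(W) %||% paste0("Sig", seq_len(ncol(W)))
  colnames(W) <- sig_names
  exposures <- stats::setNames(numeric(ncol(W)), sig_names)
  if (all(spectrum == 0)) {
    warning("all-zero spectrum: returning zero exposures", call. = FALSE)
    return(list(exposures = exposures, cosine = NA_real_,
                residual_frob = 0, residual_kl = 0))
  }
  idx <- if (is.null(allowed)) seq_len(ncol(W)) else {
    if (is.character(allowed)) match(allowed, sig_names) else as.integer(allowed)
  }
  if (anyNA(idx)) stop("unknown signature in `allowed`", call. = FALSE)
  if (length(idx)) {
    fit <- pracma::lsqnonneg(W[, idx, drop = FALSE], as.numeric(spectrum))
    exposures[idx] <- fit$x
  }
  if (renormalize && sum(exposures) > 0)
    exposures <- exposures * sum(spectrum) / sum(exposures)
  rec <- as.numeric(W %*% exposures)
  list(exposures = exposures,
       cosine = cosine(spectrum, pmax(rec, 1e-300)),
       residual_frob = sqrt(sum((spectrum - rec)^2)),
       residual_kl = kl_divergence(matrix(spectrum), matrix(rec)))
}

#' Sparse attribution by backward elimination
#'
#' Starts from the full [attribute_sample()] solution and iteratively
#' removes the active signature whose removal costs the least
#' reconstruction cosine, refitting after each removal, while the drop
#' from the original cosine stays within `drop_tol`. Returns the sparsest
#' subset reached.
#'
#' @inheritParams attribute_sample
#' @param drop_tol allowed total reduction in reconstruction cosine.
#' @return as [attribute_sample()], plus `support` (retained signature
#'   names) and `trace` (cosine after each elimination).
#' @export
sparse_attribute <- function(spectrum, signatures, allowed = NULL,
                             drop_tol = 0.01) {
  full <- attribute_sample(spectrum, signatures, allowed)
  if (all(full$exposures == 0))
    return(c(full, list(support = character(0), trace = numeric(0))))
  support <- names(full$exposures)[full$exposures > 1e-9]
  best <- full
  trace <- numeric(0)
  while (length(support) > 1L) {
    fits <- lapply(seq_along(support), function(d)
      attribute_sample(spectrum, signatures, setdiff(support, support[d])))
    cosines <- vapply(fits, `[[`, numeric(1), "cosine")
    d <- which.max(cosines)
    if (full$cosine - cosines[d] > drop_tol) break
    support <- setdiff(support, support[d])
    best <- fits[[d]]
    trace <- c(trace, cosines[d])
  }
  c(best, list(support = support, trace = trace))
}

#' Attribute every sample of a catalogue
#'
#' @param V `mutation_catalogue` or counts matrix.
#' @param signatures a `signature_set`.
#' @param allowed optional `IndicatorMask`-style binary matrix
#'   (signatures x samples; 1 allowed) or a list of per-sample allowed
#'   signature names.
#' @param sparse_tol if non-`NULL`, apply [sparse_attribute()] per sample
#'   with this cosine drop tolerance.
#' @inheritParams attribute_sample
#' @return object of class `signature_attribution`: `exposures`
#'   (signatures x samples matrix) and `diagnostics` (per-sample tibble).
#' @export
attribute_catalogue <- function(V, signatures, allowed = NULL,
                                sparse_tol = NULL, renormalize = FALSE) {
  M <- catalogue_matrix(V)
  sig_names <- signatures$names %||% colnames(signatures$W)
  samples <- colnames(M) %||% paste0("S", seq_len(ncol(M)))
  H <- matrix(0, length(sig_names), ncol(M),
              dimnames = list(sig_names, samples))
  diag_rows <- vector("list", ncol(M))
  for (j in seq_len(ncol(M))) {
    allow_j <- allowed_for_sample(allowed, sig_names, samples[j])
    res <- if (is.null(sparse_tol))
      suppressWarnings(attribute_sample(M[, j], signatures, allow_j,
                                        renormalize))
    else suppressWarnings(sparse_attribute(M[, j], signatures, allow_j,
                                           sparse_tol))
    H[, j] <- res$exposures
    diag_rows[[j]] <- tibble::tibble(
      sample_id = samples[j], total = sum(M[, j]),
      attributed = sum(res$exposures), cosine = res$cosine,
      residual_frob = res$residual_frob, residual_kl = res$residual_kl)
  }
  structure(list(exposures = H, diagnostics = dplyr::bind_rows(diag_rows),
                 signatures = signatures),
            class = "signature_attribution")
}

allowed_for_sample <- function(allowed, sig_names, sample) {
  if (is.null(allowed)) return(NULL)
  if (is.matrix(allowed)) {
    col <- allowed[, sample]
    return(sig_names[col > 0])
  }
  if (is.list(allowed)) return(allowed[[sample]])
  stop("unsupported `allowed` specification", call. = FALSE)
}

#' @export
print.signature_attribution <- function(x, ...) {
  cat("<signature_attribution>", nrow(x$exposures), "signatures x",
      ncol(x$exposures), "samples; median reconstruction cosine",
      round(stats::median(x$diagnostics$cosine, na.rm = TRUE), 4), "\n")
  invisible(x)
}

#' ARD attribution with fixed signatures and an indicator mask
#'
#' Runs the Bayesian ARD-NMF updates on the activity matrix `H` only,
#' holding the signature matrix `W` fixed. The binary indicator matrix
#' `Z` (1 = signature allowed in that sample) multiplies `H` elementwise
#' after every update, so disallowed entries are exactly zero. Relevance
#' pruning acts on rows of `H` only: signatures whose total attributed
#' mass is negligible are zeroed.
#'
#' @param V `mutation_catalogue` or counts matrix.
#' @param signatures fixed `signature_set` (the W matrix).
#' @param Z binary matrix signatures x samples; default all-ones.
#' @param seed integer seed for the H initialization.
#' @param a,b ARD hyperparameters (inverse-gamma prior on the component
#'   scales); `b = NULL` uses a data-scaled default.
#' @param prune_rel relative relevance threshold for pruning H rows.
#' @param tol,max_iter convergence controls.
#' @return a `signature_attribution` whose exposures satisfy the mask.
#' @export
attribute_ard <- function(V, signatures, Z = NULL, seed = 1L,
                          a = 10, b = NULL, prune_rel = 1e-2,
                          tol = 1e-8, max_iter = 10000L) {
  M <- catalogue_matrix(V)
  W <- signatures$W
  K <- ncol(W); N <- ncol(M)
  samples <- colnames(M) %||% paste0("S", seq_len(ncol(M)))
  colnames(M) <- samples
  if (is.null(Z)) Z <- matrix(1, K, N)
  if (!all(dim(Z) == c(K, N)))
    stop("Z must be signatures x samples", call. = FALSE)
  if (is.null(colnames(Z))) colnames(Z) <- samples
  dead <- colSums(Z[, samples, drop = FALSE]) == 0 & colSums(M) > 0
  if (any(dead))
    warning("sample(s) with nonzero spectrum but all-zero Z column: ",
            paste(samples[dead], collapse = ", "), call. = FALSE)
  set.seed(seed)
  if (is.null(b)) b <- sqrt((a - 1) * (a - 2) * mean(M) / K)
  H0 <- matrix(stats::runif(K * N, 0.5, 1.5) * mean(M) * nrow(M) / K, K, N)
  H0 <- H0 * Z[, samples, drop = FALSE]
  fit <- cpp_ard_nmf(M, W, H0, a, b, 1L, tol, as.integer(max_iter), 10L,
                     0L, FALSE, Z[, samples, drop = FALSE], TRUE)
  H <- fit$H
  rel <- rowSums(H)
  H[rel < prune_rel * max(rel), ] <- 0
  dimnames(H) <- list(colnames(W), samples)
  R <- W %*% H
  diagnostics <- tibble::tibble(
    sample_id = samples, total = colSums(M), attributed = colSums(H),
    cosine = vapply(seq_len(N), function(j)
      if (sum(M[, j]) == 0) NA_real_
      else cosine(M[, j], pmax(R[, j], 1e-300)), numeric(1)),
    residual_frob = sqrt(colSums((M - R)^2)),
    residual_kl = vapply(seq_len(N), function(j)
      kl_divergence(M[, j, drop = FALSE], R[, j, drop = FALSE]), numeric(1)))
  structure(list(exposures = H, diagnostics = diagnostics,
                 signatures = signatures),
            class = "signature_attribution")
}

#' Per-class signature probabilities for one sample
#'
#' For each mutation class `i`, the probability that an attributed
#' signature `k` generated a mutation of that class:
#' `P[i, k] = W[i, k] h[k] / sum_k' W[i, k'] h[k']`. Rows with zero
#' reconstructed mass are returned as `NA` and flagged.
#'
#' @param signatures a `signature_set`.
#' @param h exposure vector (one entry per signature, some entry > 0).
#' @return matrix classes x signatures; defined rows sum to 1. Attribute
#'   `undefined` marks classes with zero reconstructed mass.
#' @export
mutation_probabilities <- function(signatures, h) {
  W <- if (inherits(signatures, "signature_set")) signatures$W
       else as.matrix(signatures)
  if (length(h) != ncol(W))
    stop("exposure vector length must equal the number of signatures",
         call. = FALSE)
  if (any(h < 0)) stop("exposures must be nonnegative", call. = FALSE)
  if (all(h == 0)) stop("all-zero exposure vector", call. = FALSE)
  num <- sweep(W, 2, h, "*")
  den <- rowSums(num)
  P <- num / ifelse(den > 0, den, NA_real_)
  attr(P, "undefined") <- den == 0
  P
}

#' Build an indicator mask from biological allow-list rules
#'
#' Rules restrict specific signatures to specific cancer types (for
#' example, allowing a tobacco-smoking signature only in lung and
#' head-and-neck tumours, or a treatment signature only in named
#' samples). Signatures without a rule are allowed everywhere. Rules are
#' supplied as configuration, never hard-coded:
#'
#' ```yaml
#' SynSig2:
#'   cancer_types: [Lung-AdenoCA, Head-SCC]
#' SynSig4:
#'   samples: [SP12345]
#' ```
#'
#' @param rules named list (or path to a YAML file): per signature,
#'   `cancer_types` and/or `samples` entries listing where it is allowed.
#' @param signatures a `signature_set` (row space of the mask).
#' @param metadata tibble with `sample_id` and (when type rules are used)
#'   `cancer_type` for every sample.
#' @return binary matrix signatures x samples (1 = allowed), usable as
#'   the `Z` of [attribute_ard()] or `allowed` of
#'   [attribute_catalogue()].
#' @export
allow_mask_from_rules <- function(rules, signatures, metadata) {
  if (is.character(rules)) rules <- yaml::read_yaml(rules)
  sig_names <- signatures$names
  samples <- metadata$sample_id
  Z <- matrix(1, length(sig_names), length(samples),
              dimnames = list(sig_names, samples))
  for (sig in names(rules)) {
    if (!sig %in% sig_names)
      stop("rule references unknown signature: ", sig, call. = FALSE)
    rule <- rules[[sig]]
    ok <- rep(FALSE, length(samples))
    if (!is.null(rule$cancer_types)) {
      if (is.null(metadata$cancer_type))
        stop("cancer-type rules need a cancer_type metadata column",
             call. = FALSE)
      ok <- ok | metadata$cancer_type %in% unlist(rule$cancer_types)
    }
    if (!is.null(rule$samples))
      ok <- ok | samples %in% unlist(rule$samples)
    Z[sig, !ok] <- 0
  }
  Z
}
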