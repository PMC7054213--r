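#' Cosine similarity between two nonnegative vectors
#'
#' @param u,v numeric vectors of equal length, each with at least one
#'   nonzero entry.
#' @return cosine similarity in `[0, 1]` for nonnegative inputs.
#' @export
cosine <- function(u, v) {
  if (length(u) != length(v)) stop("length mismatch", call. = FALSE)
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine undefined for a zero vector",
                               call. = FALSE)
  sum(u * v) / (nu * nv)
}

#' Optimally match two signature sets
#'
#' One-to-one assignment between the signatures of `A` and `B` maximizing
#' the total cosine similarity (Hungarian algorithm on negated cosines).
#' Rectangular sets are allowed; surplus signatures stay unmatched. Ties
#' break deterministically by index order.
#'
#' @param A,B `signature_set` objects over the same schema.
#' @return tibble with columns `signature_a`, `signature_b`, `cosine`,
#'   ordered by the signatures of the smaller set.
#' @export
match_signatures <- function(A, B) {
  if (!identical(A$schema, B$schema) || nrow(A$W) != nrow(B$W))
    stop("signature sets have different schemas", call. = FALSE)
  swap <- ncol(A$W) > ncol(B$W)
  X <- if (swap) B else A
  Y <- if (swap) A else B
  sims <- cosine_columns(X$W, Y$W)
  assign <- hungarian_assign(-sims)
  out <- tibble::tibble(
    signature_a = colnames(X$W),
    signature_b = colnames(Y$W)[assign],
    cosine = sims[cbind(seq_len(nrow(sims)), assign)])
  if (swap) {
    out <- dplyr::rename(out, signature_a = "signature_b",
                         signature_b = "signature_a")
    out <- dplyr::select(out, "signature_a", "signature_b", "cosine")
  }
  out
}

#' Pairwise separation of a signature set
#'
#' All pairwise cosine similarities between the signatures of a set and
#' their median: lower values mean better-separated (more distinguishable)
#' signatures.
#'
#' @param S a `signature_set` with at least two signatures.
#' @return list with `pairs` (tibble `signature_a`, `signature_b`,
#'   `cosine` over the `C(n, 2)` unordered pairs) and `median`.
#' @export
set_separation <- function(S) {
  W <- if (inherits(S, "signature_set")) S$W else as.matrix(S)
  n <- ncol(W)
  if (n < 2L) stop("need at least two signatures", call. = FALSE)
  sims <- cosine_columns(W, W)
  idx <- which(upper.tri(sims), arr.ind = TRUE)
  pairs <- tibble::tibble(
    signature_a = colnames(W)[idx[, 1]],
    signature_b = colnames(W)[idx[, 2]],
    cosine = sims[idx])
  list(pairs = pairs, median = stats::median(pairs$cosine))
}

#' Test for a shift between two similarity distributions
#'
#' Two-sided rank-based two-sample test (Mann-Whitney U with normal
#' approximation and tie correction by default, or a permutation test on
#' the difference of medians) comparing, e.g., the pairwise-cosine
#' distributions of two signature sets.
#'
#' @param sims_a,sims_b numeric vectors of similarities.
#' @param method `"wilcoxon"` or `"permutation"`.
#' @param n_perm permutations for `method = "permutation"`.
#' @param seed seed for the permutation test.
#' @return two-sided p-value.
#' @export
separation_shift_test <- function(sims_a, sims_b,
                                  method = c("wilcoxon", "permutation"),
                                  n_perm = 10000L, seed = 1L) {
  method <- match.arg(method)
  if (!length(sims_a) || !length(sims_b))
    stop("empty similarity list", call. = FALSE)
  if (method == "wilcoxon") {
    return(stats::wilcox.test(sims_a, sims_b, exact = FALSE,
                              correct = TRUE)$p.value)
  }
  set.seed(seed)
  obs <- abs(stats::median(sims_a) - stats::median(sims_b))
  pooled <- c(sims_a, sims_b)
  na <- length(sims_a)
  hits <- 0L
  for (p in seq_len(n_perm)) {
    idx <- sample.int(length(pooled), na)
    stat <- abs(stats::median(pooled[idx]) - stats::median(pooled[-idx]))
    if (stat >= obs - 1e-15) hits <- hits + 1L
  }
  (hits + 1) / (n_perm + 1)
}
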