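catalogue_matrix <- function(V) {
  if (inherits(V, "mutation_catalogue")) V$counts else as.matrix(V)
}

#' KL-divergence nonnegative matrix factorization
#'
#' Factorizes a nonnegative catalogue `V` (classes x samples) as `W %*% H`
#' by multiplicative updates minimizing the generalized Kullback-Leibler
#' divergence. The objective trace is non-increasing up to numerical
#' epsilon; iteration stops when the relative objective change falls below
#' `tol` or at `max_iter`. Columns of `W` are renormalized to sum to 1,
#' with the scale folded into `H`, so `H` is on the mutation-count scale.
#'
#' @param V `mutation_catalogue` or nonnegative matrix with no all-zero
#'   sample column.
#' @param k factorization rank, `1 <= k <= min(dim(V))`.
#' @param seed integer seed for the random initialization.
#' @param tol relative-change convergence tolerance.
#' @param max_iter iteration cap.
#' @return list with `W` (classes x k, columns sum to 1), `H` (k x
#'   samples), `objective` (final generalized KL), `trace`, `iterations`.
#' @export
nmf_kl <- function(V, k, seed = 1L, tol = 1e-8, max_iter = 10000L) {
  V <- catalogue_matrix(V)
  if (any(V < 0)) stop("V must be nonnegative", call. = FALSE)
  zero <- colSums(V) == 0
  if (any(zero))
    stop("all-zero sample column(s): ",
         paste(colnames(V)[zero] %||% which(zero), collapse = ", "),
         "; remove them before factorization", call. = FALSE)
  if (k < 1L || k > min(dim(V)))
    stop("rank k out of range [1, ", min(dim(V)), "]", call. = FALSE)
  set.seed(seed)
  scale <- mean(V)
  W0 <- matrix(stats::runif(nrow(V) * k, 0.1, 1), nrow(V), k)
  H0 <- matrix(stats::runif(k * ncol(V), 0.1, 1) * scale, k, ncol(V))
  fit <- cpp_nmf_kl(V, W0, H0, tol, as.integer(max_iter), 10L)
  cs <- colSums(fit$W)
  W <- sweep(fit$W, 2, cs, "/")
  H <- fit$H * cs
  dimnames(W) <- list(rownames(V), paste0("Sig", seq_len(k)))
  dimnames(H) <- list(colnames(W), colnames(V))
  list(W = W, H = H, objective = fit$objective, trace = fit$trace,
       iterations = fit$iterations)
}

#' Bootstrap-resample a mutation catalogue
#'
#' Each sample column is resampled multinomially with its own total count
#' and empirical class proportions, preserving column totals exactly.
#' With `scheme = "poisson"` each cell is resampled independently Poisson
#' with its observed mean (column totals then vary).
#'
#' @param V `mutation_catalogue` or counts matrix.
#' @param seed integer seed.
#' @param scheme `"multinomial"` (default) or `"poisson"`.
#' @return matrix of the same shape and dimnames.
#' @export
bootstrap_catalogue <- function(V, seed = 1L, scheme = c("multinomial",
                                                         "poisson")) {
  scheme <- match.arg(scheme)
  M <- catalogue_matrix(V)
  set.seed(seed)
  out <- if (scheme == "multinomial") {
    apply(M, 2, function(col) {
      n <- sum(col)
      if (n == 0) col else as.numeric(stats::rmultinom(1, n, col / n))
    })
  } else {
    matrix(stats::rpois(length(M), M), nrow(M), ncol(M))
  }
  dimnames(out) <- dimnames(M)
  out
}

#' Generalized KL divergence between a matrix and its reconstruction
#' @param V observed nonnegative matrix.
#' @param R reconstruction of the same shape.
#' @return nonnegative scalar.
#' @export
kl_divergence <- function(V, R) {
  R <- pmax(R, 1e-16)
  pos <- V > 0
  sum(V[pos] * log(V[pos] / R[pos]) - V[pos]) + sum(R)
}
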