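#' Construct a signature set
#'
#' A signature set holds the W matrix of an NMF factorization: one column
#' per signature, each a probability profile over mutation classes
#' (nonnegative, summing to 1). Columns are renormalized on construction;
#' an all-zero column is an error.
#'
#' @param W nonnegative matrix, classes x signatures.
#' @param schema schema name, or `NA` for schema-agnostic sets (e.g.
#'   concatenated COMPOSITE features).
#' @param names signature identifiers; defaults to existing column names
#'   or `Sig1..SigK`.
#' @return an object of class `signature_set`.
#' @export
signature_set <- function(W, schema = NA_character_, names = NULL) {
  W <- as.matrix(W)
  if (any(W < 0)) stop("signature profiles must be nonnegative", call. = FALSE)
  cs <- colSums(W)
  if (any(cs == 0)) stop("all-zero signature column", call. = FALSE)
  W <- sweep(W, 2, cs, "/")
  colnames(W) <- names %||% colnames(W) %||% paste0("Sig", seq_len(ncol(W)))
  if (!is.na(schema) && is.null(rownames(W)))
    rownames(W) <- enumerate_classes(schema)
  structure(list(schema = schema, names = colnames(W), W = W),
            class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat("<signature_set>", ncol(x$W), "signatures x", nrow(x$W),
      "classes (schema ", x$schema, ")\n", sep = " ")
  invisible(x)
}

#' Number of signatures in a set
#' @param set a `signature_set`.
#' @return integer.
#' @export
n_signatures <- function(set) ncol(set$W)

#' Concatenate catalogues of different schemas into a COMPOSITE matrix
#'
#' Stacks the class rows of several catalogues over the same samples
#' (e.g. SBS1536 + DBS78 + ID83 = 1,697 features). No per-block weighting
#' is applied.
#'
#' @param ... `mutation_catalogue` objects sharing the same samples.
#' @return numeric matrix, stacked classes x samples.
#' @export
composite_matrix <- function(...) {
  cats <- list(...)
  samples <- cats[[1]]$samples
  for (ct in cats)
    if (!identical(ct$samples, samples))
      stop("catalogues must share an identical sample set", call. = FALSE)
  do.call(rbind, lapply(cats, function(ct) {
    m <- ct$counts
    rownames(m) <- paste0(ct$schema, ":", rownames(m))
    m
  }))
}
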