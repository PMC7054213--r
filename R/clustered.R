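#' Partition substitutions into clustered and unclustered sets
#'
#' A single-base substitution is clustered when its distance to the
#' nearest other substitution of the same sample on the same chromosome
#' is strictly below `max_dist` (default 1,000 bp, the kataegis-style
#' intermutational-distance rule). Distances are never computed across
#' chromosomes or samples. Non-SBS records (doublets, indels) are dropped
#' from the clustering input.
#'
#' @param mutations tibble with `sample_id`, `chrom`, `pos`, `ref`, `alt`
#'   (any sort order; sorted internally). Duplicated coordinates count as
#'   distance 0.
#' @param max_dist clustering threshold in bp (strict `<`).
#' @return the SBS rows of `mutations` with a logical `clustered` column;
#'   the partition is exhaustive and disjoint.
#' @export
find_clustered <- function(mutations, max_dist = 1000L) {
  sbs <- mutations[nchar(mutations$ref) == 1L & nchar(mutations$alt) == 1L &
                     mutations$ref != mutations$alt, , drop = FALSE]
  sbs |>
    dplyr::group_by(.data$sample_id, .data$chrom) |>
    dplyr::arrange(.data$pos, .by_group = TRUE) |>
    dplyr::mutate(
      gap_prev = .data$pos - dplyr::lag(.data$pos),
      gap_next = dplyr::lead(.data$pos) - .data$pos,
      clustered = pmin(.data$gap_prev, .data$gap_next, na.rm = TRUE) <
        max_dist,
      clustered = dplyr::coalesce(.data$clustered, FALSE)) |>
    dplyr::ungroup() |>
    dplyr::select(-"gap_prev", -"gap_next")
}

#' Catalogue of clustered substitutions only
#'
#' Builds an SBS96 catalogue restricted to the clustered partition of
#' [find_clustered()]; feeding the result to [extract_signatures()]
#' yields clustered mutational signatures. Samples with no clustered
#' mutation keep an all-zero column (flagged in the `empty` attribute).
#'
#' @inheritParams build_catalogue
#' @inheritParams find_clustered
#' @return a `mutation_catalogue` (SBS96) of clustered mutations.
#' @export
clustered_catalogue <- function(mutations, reference, max_dist = 1000L,
                                samples = NULL) {
  part <- find_clustered(mutations, max_dist)
  samples <- samples %||% unique(mutations$sample_id)
  ct <- build_catalogue(part[part$clustered, , drop = FALSE], reference,
                        "SBS96", samples = samples)
  attr(ct, "empty") <- colSums(ct$counts) == 0
  ct
}

#' Expected number of immediately adjacent substitution pairs under
#' random placement
#'
#' If `n` substitution positions are placed independently and uniformly
#' on a linear sequence of length `L`, the expected number of pairs at
#' adjacent positions is `C(n, 2) * 2 (L - 1) / L^2`, approximately
#' `n (n - 1) / L`. Comparing the observed count of adjacent substitution
#' pairs with this baseline indicates whether doublets arise more often
#' than random adjacency of independent substitutions would produce. The
#' formula is a null model of this package (a heuristic baseline, not a
#' published estimator).
#'
#' @param n_sbs number of substitutions (`>= 0`).
#' @param genome_length sequence length in bp (`>= 2`).
#' @return expected count of adjacent pairs.
#' @export
expected_adjacent_pairs <- function(n_sbs, genome_length) {
  if (genome_length < 2) stop("genome_length must be at least 2",
                              call. = FALSE)
  if (n_sbs < 0) stop("n_sbs must be nonnegative", call. = FALSE)
  choose(n_sbs, 2) * 2 * (genome_length - 1) / genome_length^2
}
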