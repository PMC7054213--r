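#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a mutation catalogue into long format
#'
#' @param x a `mutation_catalogue`.
#' @param ... unused.
#' @return tibble with `class`, `sample_id`, `count`.
#' @method tidy mutation_catalogue
#' @export
tidy.mutation_catalogue <- function(x, ...) {
  tibble::as_tibble(as.table(x$counts), .name_repair = "minimal") |>
    stats::setNames(c("class", "sample_id", "count")) |>
    dplyr::mutate(count = as.integer(.data$count))
}

#' One-row summary of a mutation catalogue
#' @inheritParams tidy.mutation_catalogue
#' @return tibble with schema, dimensions, totals and skip count.
#' @method glance mutation_catalogue
#' @export
glance.mutation_catalogue <- function(x, ...) {
  tibble::tibble(schema = x$schema, n_classes = length(x$classes),
                 n_samples = length(x$samples),
                 n_mutations = sum(x$counts), n_skipped = nrow(x$skipped))
}

#' Tidy a signature set into long format
#' @param x a `signature_set`.
#' @param ... unused.
#' @return tibble with `class`, `signature`, `weight`.
#' @method tidy signature_set
#' @export
tidy.signature_set <- function(x, ...) {
  tibble::as_tibble(as.table(x$W), .name_repair = "minimal") |>
    stats::setNames(c("class", "signature", "weight"))
}

#' Tidy a de novo extraction: consensus profiles at one rank
#' @param x a `signature_extraction`.
#' @param k rank to tidy; defaults to the selected rank.
#' @param ... unused.
#' @return tibble with `k`, `class`, `signature`, `weight`.
#' @method tidy signature_extraction
#' @export
tidy.signature_extraction <- function(x, k = x$selected_k, ...) {
  dplyr::mutate(tidy(solution_at(x, k)$signatures), k = k, .before = 1)
}

#' Per-rank model-selection table of a de novo extraction
#' @param x a `signature_extraction`.
#' @param ... unused.
#' @return tibble with `k`, `stability`, `kl_error`, `frob_error`,
#'   `relative_gain`, `selected`.
#' @method glance signature_extraction
#' @export
glance.signature_extraction <- function(x, ...) {
  tibble::tibble(
    k = x$k_range,
    stability = unname(x$stability),
    kl_error = unname(x$kl_error),
    frob_error = vapply(x$by_rank, `[[`, numeric(1), "frob_error"),
    relative_gain = unname(x$relative_gain),
    selected = x$k_range == x$selected_k)
}

#' Tidy an attribution into long exposures
#' @param x a `signature_attribution`.
#' @param ... unused.
#' @return tibble with `signature`, `sample_id`, `exposure`.
#' @method tidy signature_attribution
#' @export
tidy.signature_attribution <- function(x, ...) {
  tibble::as_tibble(as.table(x$exposures), .name_repair = "minimal") |>
    stats::setNames(c("signature", "sample_id", "exposure"))
}

#' One-row reconstruction summary of an attribution
#' @param x a `signature_attribution`.
#' @param ... unused.
#' @return tibble with sample count and reconstruction-quality summaries.
#' @method glance signature_attribution
#' @export
glance.signature_attribution <- function(x, ...) {
  d <- x$diagnostics
  tibble::tibble(n_samples = nrow(d),
                 median_cosine = stats::median(d$cosine, na.rm = TRUE),
                 min_cosine = min(d$cosine, na.rm = TRUE),
                 total_mutations = sum(d$total),
                 total_attributed = sum(d$attributed))
}

#' Tidy an age scan
#' @param x an `age_scan`.
#' @param ... unused.
#' @return the per-stratum results tibble.
#' @method tidy age_scan
#' @export
tidy.age_scan <- function(x, ...) x$results

#' One-row summary of an age scan
#' @param x an `age_scan`.
#' @param ... unused.
#' @return tibble with counts of tested, significant and skipped strata.
#' @method glance age_scan
#' @export
glance.age_scan <- function(x, ...) {
  tibble::tibble(n_tested = nrow(x$results),
                 n_significant = sum(x$results$q_value < 0.05),
                 n_skipped = nrow(x$skipped))
}
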