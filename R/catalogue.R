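#' Construct a mutation catalogue from a counts matrix
#'
#' @param counts nonnegative integer matrix, classes x samples. Row names
#'   must be (a permutation of) the schema's canonical labels; rows are
#'   reordered into canonical order.
#' @param schema schema name as in [enumerate_classes()].
#' @param skipped optional tibble of skipped records.
#' @return an object of class `mutation_catalogue`.
#' @export
as_catalogue <- function(counts, schema, skipped = NULL) {
  classes <- enumerate_classes(schema)
  if (is.null(rownames(counts)))
    stop("counts matrix must carry class row names", call. = FALSE)
  if (!setequal(rownames(counts), classes) ||
      nrow(counts) != length(classes))
    stop("row names do not match the ", schema, " class set", call. = FALSE)
  counts <- counts[classes, , drop = FALSE]
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("S", seq_len(ncol(counts)))
  structure(list(schema = schema, classes = classes,
                 samples = colnames(counts), counts = counts,
                 skipped = skipped %||% empty_skip_log()),
            class = "mutation_catalogue")
}

empty_skip_log <- function() {
  tibble::tibble(sample_id = character(), chrom = character(),
                 pos = integer(), ref = character(), alt = character(),
                 reason = character())
}

#' @export
print.mutation_catalogue <- function(x, ...) {
  cat("<mutation_catalogue> schema", x$schema, "-",
      length(x$classes), "classes x", length(x$samples), "samples;",
      sum(x$counts), "mutations,", nrow(x$skipped), "skipped\n")
  invisible(x)
}

schema_kind <- function(schema) {
  switch(schema,
         SBS96 = "SBS", SBS192 = "SBS", SBS1536 = "SBS",
         DBS78 = "DBS", ID83 = c("INS", "DEL"))
}

#' Build a mutation catalogue from variant calls and a reference sequence
#'
#' Classifies every mutation under the requested schema and tallies counts
#' per class and sample. Mutations of the wrong kind for the schema,
#' mutations with `N` in their alleles or context, mutations too close to a
#' contig edge, and (for the stranded schema) mutations without an
#' unambiguous transcript strand are excluded and reported in the skip log
#' with a reason, so that per sample `colSums(counts) + skips = inputs`.
#'
#' @param mutations tibble with `sample_id`, `chrom`, `pos`, `ref`, `alt`
#'   (VCF-style alleles accepted).
#' @param reference named character vector, `DNAStringSet`, or path to a
#'   FASTA file.
#' @param schema one of `"SBS96"`, `"SBS192"`, `"SBS1536"`, `"DBS78"`,
#'   `"ID83"`.
#' @param annotation stranded transcript annotation (required for
#'   `"SBS192"`), as from [read_strand_bed()].
#' @param samples declared sample set; defaults to the samples present.
#'   A mutation naming a sample outside this set is an error.
#' @return a `mutation_catalogue`.
#' @export
build_catalogue <- function(mutations, reference, schema,
                            annotation = NULL, samples = NULL) {
  schema <- match.arg(schema, c("SBS96", "SBS192", "SBS1536", "DBS78", "ID83"))
  if (schema == "SBS192" && is.null(annotation))
    stop("schema SBS192 requires a transcript annotation", call. = FALSE)
  if (is.character(reference) && length(reference) == 1L &&
      is.null(names(reference)) && file.exists(reference))
    reference <- read_reference_fasta(reference)
  ref_chr <- reference_as_character(reference)

  if (is.null(samples)) samples <- unique(mutations$sample_id)
  unknown <- setdiff(unique(mutations$sample_id), samples)
  if (length(unknown))
    stop("mutation references undeclared sample(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)

  norm <- normalize_mutations(mutations, ref_chr)
  classes <- enumerate_classes(schema)
  counts <- matrix(0L, length(classes), length(samples),
                   dimnames = list(classes, samples))
  wanted <- schema_kind(schema)
  flank <- if (schema == "SBS1536") 2L else 1L
  skips <- list()

  for (i in seq_len(nrow(norm))) {
    row <- norm[i, ]
    skip <- function(reason) {
      skips[[length(skips) + 1L]] <<- tibble::tibble(
        sample_id = row$sample_id, chrom = row$chrom, pos = row$pos,
        ref = row$ref, alt = row$alt, reason = reason)
    }
    if (!is.na(row$skip_reason)) { skip(row$skip_reason); next }
    if (!row$kind %in% wanted) { skip("wrong mutation kind"); next }
    if (!row$chrom %in% names(ref_chr))
      stop("chromosome ", row$chrom, " not in reference", call. = FALSE)
    chrom_seq <- ref_chr[[row$chrom]]
    L <- nchar(chrom_seq)

    label <- NULL
    if (row$kind == "SBS") {
      if (row$pos - flank < 1L || row$pos + flank > L) {
        skip("context out of range"); next
      }
      ctx <- substr(chrom_seq, row$pos - flank, row$pos + flank)
      centre <- substr(ctx, flank + 1L, flank + 1L)
      if (centre != row$ref)
        stop(sprintf("reference mismatch at %s:%d (reference %s, call %s)",
                     row$chrom, row$pos, centre, row$ref), call. = FALSE)
      if (grepl("N", ctx, fixed = TRUE)) { skip("context contains N"); next }
      if (schema == "SBS192") {
        label <- classify_sbs_stranded(row$ref, row$alt, ctx, row$chrom,
                                       row$pos, annotation)
        if (is.na(label)) { skip("no unambiguous transcript strand"); next }
      } else {
        label <- classify_sbs(row$ref, row$alt, ctx, flank)
      }
    } else if (row$kind == "DBS") {
      if (row$pos + 1L > L) { skip("context out of range"); next }
      obs <- substr(chrom_seq, row$pos, row$pos + 1L)
      if (obs != row$ref)
        stop(sprintf("reference mismatch at %s:%d (reference %s, call %s)",
                     row$chrom, row$pos, obs, row$ref), call. = FALSE)
      label <- classify_dbs(row$ref, row$alt)
    } else {
      motif <- if (row$kind == "DEL") row$ref else row$alt
      need <- 6L * nchar(motif)
      up_start <- row$pos - need
      dn_end <- if (row$kind == "DEL") row$pos + nchar(motif) - 1L + need
                else row$pos - 1L + need
      if (up_start < 1L || dn_end > L) { skip("flank out of range"); next }
      if (row$kind == "DEL") {
        obs <- substr(chrom_seq, row$pos, row$pos + nchar(motif) - 1L)
        if (obs != motif)
          stop(sprintf("reference mismatch at %s:%d (reference %s, call %s)",
                       row$chrom, row$pos, obs, motif), call. = FALSE)
      }
      upstream <- substr(chrom_seq, up_start, row$pos - 1L)
      downstream <- if (row$kind == "DEL")
        substr(chrom_seq, row$pos + nchar(motif), dn_end)
      else substr(chrom_seq, row$pos, dn_end)
      if (grepl("N", paste0(upstream, downstream), fixed = TRUE)) {
        skip("context contains N"); next
      }
      label <- classify_indel(row$kind, motif, upstream, downstream)
    }
    counts[label, row$sample_id] <- counts[label, row$sample_id] + 1L
  }

  as_catalogue(counts, schema,
               skipped = if (length(skips)) dplyr::bind_rows(skips)
                         else empty_skip_log())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
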