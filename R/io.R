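#' Read a reference genome FASTA
#'
#' @param path FASTA file.
#' @return named character vector of chromosome sequences (names truncated
#'   at the first whitespace, as in BAM/VCF conventions).
#' @export
read_reference_fasta <- function(path) {
  reference_as_character(Biostrings::readDNAStringSet(path))
}

#' Write a reference FASTA
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @export
write_reference_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Read somatic mutation calls from a VCF file
#'
#' Parses the fixed columns of a VCF v4.x file. Multi-allelic records are
#' split into one row per alternate allele. The sample identifier is taken
#' from the `sample_id` argument, or a `##sample=` header line, or the file
#' basename, in that order.
#'
#' @param path VCF file (uncompressed).
#' @param sample_id optional sample identifier applied to all records.
#' @return tibble with `sample_id`, `chrom`, `pos`, `ref`, `alt`.
#' @export
read_vcf_mutations <- function(path, sample_id = NULL) {
  lines <- readLines(path)
  header <- lines[startsWith(lines, "##")]
  body <- lines[!startsWith(lines, "#")]
  if (is.null(sample_id)) {
    sl <- header[startsWith(header, "##sample=")]
    sample_id <- if (length(sl)) sub("^##sample=", "", sl[1]) else
      sub("\\.vcf$", "", basename(path))
  }
  if (!length(body)) {
    return(tibble::tibble(sample_id = character(), chrom = character(),
                          pos = integer(), ref = character(),
                          alt = character()))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  tab <- tibble::tibble(
    sample_id = sample_id,
    chrom = vapply(fields, `[[`, "", 1L),
    pos = as.integer(vapply(fields, `[[`, "", 2L)),
    ref = toupper(vapply(fields, `[[`, "", 4L)),
    alt = toupper(vapply(fields, `[[`, "", 5L)))
  tidyr::separate_longer_delim(tab, "alt", delim = ",")
}

#' Write mutation calls as a minimal VCF v4.2 file
#'
#' @param mutations tibble with `chrom`, `pos`, `ref`, `alt` (VCF-style
#'   alleles: indels anchored on the preceding base).
#' @param path output file.
#' @param sample_id written as a `##sample=` header line.
#' @param contigs optional named vector of contig lengths for the header.
#' @export
write_vcf_mutations <- function(mutations, path, sample_id = NULL,
                                contigs = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           if (!is.null(sample_id)) paste0("##sample=", sample_id),
           if (!is.null(contigs))
             sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                     as.integer(contigs)),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  ord <- order(mutations$chrom, mutations$pos)
  m <- mutations[ord, , drop = FALSE]
  rows <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.",
                  m$chrom, m$pos, m$ref, m$alt)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read mutation calls from a MAF-like tab-delimited file
#'
#' @param path TSV file with one row per mutation.
#' @param col_map named character vector mapping the canonical fields
#'   `sample_id`, `chrom`, `pos`, `ref`, `alt` to column names in the file.
#' @return tibble with the canonical columns.
#' @export
read_maf_mutations <- function(path,
                               col_map = c(sample_id = "Tumor_Sample_Barcode",
                                           chrom = "Chromosome",
                                           pos = "Start_Position",
                                           ref = "Reference_Allele",
                                           alt = "Tumor_Seq_Allele2")) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  missing <- setdiff(unname(col_map), names(tab))
  if (length(missing))
    stop("MAF file lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  tibble::tibble(
    sample_id = as.character(tab[[col_map[["sample_id"]]]]),
    chrom = as.character(tab[[col_map[["chrom"]]]]),
    pos = as.integer(tab[[col_map[["pos"]]]]),
    ref = toupper(ifelse(tab[[col_map[["ref"]]]] %in% c("-", ""), "",
                         tab[[col_map[["ref"]]]])),
    alt = toupper(ifelse(tab[[col_map[["alt"]]]] %in% c("-", ""), "",
                         tab[[col_map[["alt"]]]])))
}

#' Read a stranded transcript annotation from a BED file
#'
#' Intervals are 0-based half-open (BED convention). Overlapping intervals
#' on the same strand are merged.
#'
#' @param path BED file with at least 6 columns (strand in column 6).
#' @return tibble with `chrom`, `start`, `end`, `strand`.
#' @export
read_strand_bed <- function(path) {
  tab <- readr::read_tsv(path,
                         col_names = c("chrom", "start", "end", "name",
                                       "score", "strand"),
                         col_types = "ciiccc", comment = "#")
  merge_strand_intervals(
    tibble::tibble(chrom = tab$chrom, start = tab$start, end = tab$end,
                   strand = tab$strand))
}

#' Merge overlapping same-strand intervals
#' @param intervals tibble with `chrom`, `start`, `end`, `strand`.
#' @return tibble with non-overlapping intervals per (chrom, strand).
#' @export
merge_strand_intervals <- function(intervals) {
  intervals |>
    dplyr::group_by(.data$chrom, .data$strand) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::mutate(grp = cumsum(.data$start > dplyr::lag(cummax(.data$end),
                                                        default = -1L))) |>
    dplyr::group_by(.data$chrom, .data$strand, .data$grp) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end),
                     .groups = "drop") |>
    dplyr::select("chrom", "start", "end", "strand") |>
    dplyr::arrange(.data$chrom, .data$start)
}

# ---- matrix CSV conventions -------------------------------------------
# All matrix files: UTF-8 comma-separated, '.' decimal, first column the
# row labels (mutation classes or signature names), header row of column
# names. Lines starting with '#' are provenance comments.

write_matrix_csv <- function(mat, path, row_label, provenance = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(provenance)) writeLines(paste0("# ", provenance), con)
  df <- data.frame(lab = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- row_label
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, comment.char = "#",
                        stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- df[[1]]
  mat
}

#' Write a mutation catalogue as CSV
#'
#' Rows are class labels in canonical schema order, columns are samples.
#'
#' @param catalogue a `mutation_catalogue`.
#' @param path output file.
#' @param provenance optional comment line written at the top.
#' @export
write_catalogue_csv <- function(catalogue, path, provenance = NULL) {
  write_matrix_csv(catalogue$counts, path, "MutationType", provenance)
}

#' Read a mutation catalogue CSV
#' @param path CSV written by [write_catalogue_csv()] (or any classes x
#'   samples matrix with labels in the first column).
#' @param schema schema name; inferred from the row count when `NULL`.
#' @return a `mutation_catalogue`.
#' @export
read_catalogue_csv <- function(path, schema = NULL) {
  mat <- read_matrix_csv(path)
  if (is.null(schema)) schema <- infer_schema(rownames(mat))
  as_catalogue(mat, schema)
}

infer_schema <- function(labels) {
  n <- length(labels)
  schema <- switch(as.character(n), "96" = "SBS96", "192" = "SBS192",
                   "1536" = "SBS1536", "78" = "DBS78", "83" = "ID83", NULL)
  if (is.null(schema))
    stop("cannot infer schema from ", n, " row labels", call. = FALSE)
  schema
}

#' Write a signature set as CSV (classes x signatures)
#' @param signatures a `signature_set`.
#' @inheritParams write_catalogue_csv
#' @export
write_signatures_csv <- function(signatures, path, provenance = NULL) {
  write_matrix_csv(signatures$W, path, "MutationType", provenance)
}

#' Read a signature set CSV (classes x signatures)
#' @inheritParams read_catalogue_csv
#' @return a `signature_set`.
#' @export
read_signatures_csv <- function(path, schema = NULL) {
  mat <- read_matrix_csv(path)
  if (is.null(schema))
    schema <- tryCatch(infer_schema(rownames(mat)), error = function(e) NA)
  signature_set(mat, schema)
}

#' Write an exposure matrix as CSV (signatures x samples)
#' @param exposures matrix with signature rownames and sample colnames.
#' @inheritParams write_catalogue_csv
#' @export
write_exposures_csv <- function(exposures, path, provenance = NULL) {
  write_matrix_csv(exposures, path, "Signature", provenance)
}

#' Read an exposure matrix CSV
#' @param path CSV written by [write_exposures_csv()].
#' @return matrix signatures x samples.
#' @export
read_exposures_csv <- function(path) read_matrix_csv(path)
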