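is_pyrimidine <- function(base) base %in% c("C", "T")

check_dna <- function(x, what) {
  bad <- grepl("[^ACGT]", x)
  if (any(bad))
    stop(sprintf("non-ACGT character in %s: '%s'", what, x[bad][1]),
         call. = FALSE)
  invisible(x)
}

#' Classify a single-base substitution into its trinucleotide or
#' pentanucleotide class
#'
#' Applies the pyrimidine-centric convention: when the mutated reference
#' base is a purine, the substitution and its local context are
#' reverse-complemented before labelling, so every substitution maps to one
#' of the 96 (flank = 1) or 1,536 (flank = 2) canonical classes.
#'
#' @param ref,alt single reference and alternate bases.
#' @param context DNA string of length `2 * flank + 1` centred on the
#'   mutated base; its centre must equal `ref`.
#' @param flank 1 (trinucleotide, SBS96) or 2 (pentanucleotide, SBS1536).
#' @return a class label, e.g. `"A[C>A]A"`.
#' @examples
#' classify_sbs("C", "A", "ACA")
#' classify_sbs("G", "A", "AGC")   # reverse-complemented to "G[C>T]T"
#' @export
classify_sbs <- function(ref, alt, context, flank = (nchar(context) - 1L) %/% 2L) {
  context <- toupper(context)
  ref <- toupper(ref); alt <- toupper(alt)
  if (!flank %in% c(1L, 2L)) stop("flank must be 1 or 2", call. = FALSE)
  if (nchar(context) != 2L * flank + 1L)
    stop("context length must be 2*flank + 1", call. = FALSE)
  check_dna(context, "context"); check_dna(ref, "ref"); check_dna(alt, "alt")
  if (ref == alt) stop("ref and alt are identical", call. = FALSE)
  if (substr(context, flank + 1L, flank + 1L) != ref)
    stop("centre of context does not match ref", call. = FALSE)
  if (!is_pyrimidine(ref)) {
    context <- revcomp(context)
    ref <- unname(COMPLEMENT[ref])
    alt <- unname(COMPLEMENT[alt])
  }
  p5 <- substr(context, 1L, flank)
  p3 <- substr(context, flank + 2L, 2L * flank + 1L)
  paste0(p5, "[", ref, ">", alt, "]", p3)
}

#' Classify a substitution by transcriptional strand
#'
#' Returns one of the 192 stranded classes, or `NA` when the position is
#' not covered by any annotated transcript or is covered by transcripts on
#' both strands (ambiguous). A mutation is `Transcribed` when the
#' pyrimidine of the mutated base pair lies on the template (transcribed)
#' strand of the covering gene, `Untranscribed` otherwise.
#'
#' @inheritParams classify_sbs
#' @param chrom,pos coordinates of the substitution (1-based).
#' @param annotation a transcript annotation as returned by
#'   [read_strand_bed()] or a tibble with columns `chrom`, `start`, `end`
#'   (0-based half-open) and `strand` (`"+"`/`"-"`).
#' @return an SBS192 label or `NA_character_`.
#' @export
classify_sbs_stranded <- function(ref, alt, context, chrom, pos, annotation) {
  g <- gene_strand(annotation, chrom, pos)
  if (is.na(g)) return(NA_character_)
  base <- classify_sbs(ref, alt, context, flank = 1L)
  pyr_strand <- if (is_pyrimidine(toupper(ref))) "+" else "-"
  # template strand of a gene is the opposite of its annotated strand
  side <- if (pyr_strand != g) "Transcribed" else "Untranscribed"
  paste0(side, ":", base)
}

# strand of the unique covering interval: "+", "-", or NA (none/both)
gene_strand <- function(annotation, chrom, pos) {
  iv <- annotation[annotation$chrom == chrom &
                     annotation$start < pos & pos <= annotation$end, ,
                   drop = FALSE]
  strands <- unique(iv$strand)
  if (length(strands) != 1L) return(NA_character_)
  strands
}

#' Canonical doublet-base substitution class
#'
#' Collapses the reverse-complement pair \{(ref, alt), (revcomp(ref),
#' revcomp(alt))\} to a single canonical label: the member whose reference
#' dinucleotide is lexicographically smaller; for palindromic references,
#' the lexicographically smaller alternate. Both positions of a doublet
#' must change.
#'
#' @param ref2,alt2 reference and alternate dinucleotides.
#' @return a DBS78 class label such as `"CC>TT"`.
#' @examples
#' classify_dbs("GG", "AA")  # "CC>TT"
#' @export
classify_dbs <- function(ref2, alt2) {
  ref2 <- toupper(ref2); alt2 <- toupper(alt2)
  if (nchar(ref2) != 2L || nchar(alt2) != 2L)
    stop("doublet alleles must have length 2", call. = FALSE)
  check_dna(ref2, "ref2"); check_dna(alt2, "alt2")
  if (ref2 == alt2) stop("ref2 and alt2 are identical", call. = FALSE)
  if (substr(ref2, 1, 1) == substr(alt2, 1, 1) ||
      substr(ref2, 2, 2) == substr(alt2, 2, 2))
    stop("not a true doublet: both positions must change", call. = FALSE)
  canonical_dbs(ref2, alt2)
}

canonical_dbs <- function(ref2, alt2) {
  rr <- revcomp(ref2); ra <- revcomp(alt2)
  if (rr < ref2 || (rr == ref2 && ra < alt2)) {
    ref2 <- rr; alt2 <- ra
  }
  paste0(ref2, ">", alt2)
}

#' Classify a small insertion or deletion into its 83-class scheme
#'
#' Events are assumed left-normalized (see [normalize_mutations()]).
#' 1-bp events are labelled by the pyrimidine of the affected base and a
#' homopolymer-length bin: for deletions the total run length in the
#' reference including the deleted base (bins 1..6+), for insertions the
#' longer of the two flanking runs of the inserted base (bins 0..5+).
#' Longer events are labelled by a length bin (2,3,4,5+) and the number of
#' tandem copies of the event motif in the reference (including the
#' deleted copy for deletions; bins 1..6+ del, 0..5+ ins). Deletions at
#' repeat count 1 whose motif shares sequence with the flank are labelled
#' microhomology (`M`) with the microhomology-length bin.
#'
#' @param kind `"INS"` or `"DEL"`.
#' @param motif the inserted or deleted sequence.
#' @param upstream reference sequence immediately 5' of the event.
#' @param downstream reference sequence immediately 3' of the event (for a
#'   deletion: the sequence following the deleted bases).
#' @return an ID83 class label.
#' @examples
#' classify_indel("DEL", "T", "GGTTTT", "GCACGA")  # run of 5 Ts
#' @export
classify_indel <- function(kind, motif, upstream, downstream) {
  kind <- match.arg(kind, c("INS", "DEL"))
  motif <- toupper(motif)
  upstream <- toupper(upstream); downstream <- toupper(downstream)
  len <- nchar(motif)
  if (len < 1L) stop("empty indel motif", call. = FALSE)
  check_dna(motif, "motif")
  if (nchar(upstream) < 6L * len || nchar(downstream) < 6L * len)
    stop("flanking sequence too short: need at least 6 * event length on each side",
         call. = FALSE)
  check_dna(upstream, "upstream"); check_dna(downstream, "downstream")

  if (len == 1L) {
    run_up <- run_length_back(upstream, motif)
    run_dn <- run_length_fwd(downstream, motif)
    base <- if (is_pyrimidine(motif)) motif else unname(COMPLEMENT[motif])
    if (kind == "DEL") {
      n <- min(run_up + run_dn + 1L, 6L)
      return(paste0("1:Del:", base, ":", n))
    }
    n <- min(max(run_up, run_dn), 5L)
    return(paste0("1:Ins:", base, ":", n))
  }

  lenb <- min(len, 5L)
  reps_up <- motif_copies_back(upstream, motif)
  reps_dn <- motif_copies_fwd(downstream, motif)
  if (kind == "DEL") {
    reps <- reps_up + reps_dn + 1L
    if (reps == 1L) {
      mh <- max(common_prefix(motif, downstream),
                common_suffix(motif, upstream))
      if (mh >= 1L) {
        cap <- if (lenb == 5L) 5L else lenb - 1L
        return(paste0(lenb, ":Del:M:", min(mh, cap)))
      }
    }
    return(paste0(lenb, ":Del:R:", min(reps, 6L)))
  }
  reps <- reps_up + reps_dn
  paste0(lenb, ":Ins:R:", min(reps, 5L))
}

run_length_fwd <- function(seq, base) {
  n <- 0L
  while (n < nchar(seq) && substr(seq, n + 1L, n + 1L) == base) n <- n + 1L
  n
}

run_length_back <- function(seq, base) {
  L <- nchar(seq); n <- 0L
  while (n < L && substr(seq, L - n, L - n) == base) n <- n + 1L
  n
}

motif_copies_fwd <- function(seq, motif) {
  len <- nchar(motif); n <- 0L
  while ((n + 1L) * len <= nchar(seq) &&
         substr(seq, n * len + 1L, (n + 1L) * len) == motif) n <- n + 1L
  n
}

motif_copies_back <- function(seq, motif) {
  len <- nchar(motif); L <- nchar(seq); n <- 0L
  while ((n + 1L) * len <= L &&
         substr(seq, L - (n + 1L) * len + 1L, L - n * len) == motif) n <- n + 1L
  n
}

common_prefix <- function(a, b) {
  n <- min(nchar(a), nchar(b)); i <- 0L
  while (i < n && substr(a, i + 1L, i + 1L) == substr(b, i + 1L, i + 1L))
    i <- i + 1L
  i
}

common_suffix <- function(a, b) {
  na <- nchar(a); nb <- nchar(b); i <- 0L
  while (i < min(na, nb) &&
         substr(a, na - i, na - i) == substr(b, nb - i, nb - i)) i <- i + 1L
  i
}

#' Normalize a table of mutation calls
#'
#' Accepts VCF-style records (indels carry a shared anchor base) or
#' already-trimmed alleles, infers the mutation kind (SBS, DBS, INS, DEL),
#' strips shared flanking bases and left-normalizes indels against the
#' reference (shifting each event to its leftmost equivalent position).
#' Records whose alleles contain characters outside A/C/G/T (e.g. `N`) are
#' returned with `kind = NA` and a reason, to be skipped downstream.
#'
#' @param mutations tibble with columns `sample_id`, `chrom`, `pos`
#'   (1-based), `ref`, `alt`.
#' @param reference named character vector or `Biostrings::DNAStringSet`
#'   of chromosome sequences (required to left-normalize indels).
#' @return the input tibble with `kind` and (for indels) `motif` columns;
#'   `pos` is the first reference base of the event (for insertions, the
#'   base before which the motif is inserted).
#' @export
normalize_mutations <- function(mutations, reference = NULL) {
  if (!nrow(mutations)) {
    return(dplyr::mutate(mutations, kind = character(0),
                         skip_reason = character(0)))
  }
  ref_chr <- reference_as_character(reference)
  rows <- purrr::pmap(
    list(mutations$chrom, mutations$pos, mutations$ref, mutations$alt),
    function(chrom, pos, ref, alt) normalize_one(chrom, pos, ref, alt, ref_chr))
  out <- dplyr::bind_cols(
    dplyr::select(mutations, -"chrom", -"pos", -"ref", -"alt"),
    dplyr::bind_rows(rows))
  dplyr::relocate(out, "chrom", "pos", "ref", "alt", "kind",
                  .after = "sample_id")
}

normalize_one <- function(chrom, pos, ref, alt, ref_chr) {
  ref <- toupper(ref); alt <- toupper(alt)
  out <- tibble::tibble(chrom = chrom, pos = as.integer(pos), ref = ref,
                        alt = alt, kind = NA_character_,
                        skip_reason = NA_character_)
  alleles <- paste0(ref, alt)
  if (grepl("[^ACGTN]", alleles)) {
    out$skip_reason <- "non-ACGTN allele"
    return(out)
  }
  if (grepl("N", alleles, fixed = TRUE)) {
    out$skip_reason <- "allele contains N"
    return(out)
  }
  # strip shared prefix (VCF anchor) then shared suffix
  while (nchar(ref) > 0L && nchar(alt) > 0L &&
         substr(ref, 1, 1) == substr(alt, 1, 1)) {
    ref <- substr(ref, 2, nchar(ref)); alt <- substr(alt, 2, nchar(alt))
    pos <- pos + 1L
  }
  while (nchar(ref) > 0L && nchar(alt) > 0L &&
         substr(ref, nchar(ref), nchar(ref)) ==
           substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1, nchar(ref) - 1L); alt <- substr(alt, 1, nchar(alt) - 1L)
  }
  nr <- nchar(ref); na <- nchar(alt)
  if (nr == 1L && na == 1L) {
    out$kind <- "SBS"
  } else if (nr == 2L && na == 2L &&
             substr(ref, 1, 1) != substr(alt, 1, 1) &&
             substr(ref, 2, 2) != substr(alt, 2, 2)) {
    out$kind <- "DBS"
  } else if (nr == 0L && na >= 1L) {
    out$kind <- "INS"
  } else if (na == 0L && nr >= 1L) {
    out$kind <- "DEL"
  } else {
    out$skip_reason <- "complex or multi-nucleotide variant"
    return(out)
  }
  if (out$kind %in% c("INS", "DEL") && !is.null(ref_chr) &&
      chrom %in% names(ref_chr)) {
    motif <- if (out$kind == "DEL") ref else alt
    shifted <- left_normalize(ref_chr[[chrom]], as.integer(pos), motif)
    pos <- shifted$pos; motif <- shifted$motif
    if (out$kind == "DEL") ref <- motif else alt <- motif
  }
  out$pos <- as.integer(pos); out$ref <- ref; out$alt <- alt
  out
}

# shift an event (deletion of `motif` starting at pos, or insertion of
# `motif` before pos) to its leftmost equivalent position
left_normalize <- function(chrom_seq, pos, motif) {
  len <- nchar(motif)
  while (pos > 1L &&
         substr(chrom_seq, pos - 1L, pos - 1L) == substr(motif, len, len)) {
    pos <- pos - 1L
    motif <- paste0(substr(chrom_seq, pos, pos), substr(motif, 1L, len - 1L))
  }
  list(pos = pos, motif = motif)
}

reference_as_character <- function(reference) {
  if (is.null(reference)) return(NULL)
  if (inherits(reference, "DNAStringSet")) {
    out <- as.character(reference)
    names(out) <- sub("\\s.*$", "", names(reference))
    return(out)
  }
  if (is.character(reference)) {
    if (is.null(names(reference)))
      stop("character reference must be named by chromosome", call. = FALSE)
    return(toupper(reference))
  }
  stop("unsupported reference type", call. = FALSE)
}
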