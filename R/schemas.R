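#' @useDynLib sigtool, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
#' @import tibble
NULL

BASES <- c("A", "C", "G", "T")
PYRIMIDINE_SUBS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse-complement a DNA string
#'
#' @param x character vector of DNA strings (A/C/G/T/N).
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  vapply(strsplit(toupper(x), ""), function(b) {
    paste(rev(unname(COMPLEMENT[b])), collapse = "")
  }, character(1))
}

enumerate_sbs <- function(flank) {
  stopifnot(flank %in% c(1L, 2L))
  labs <- character(0)
  if (flank == 1L) {
    for (sub in PYRIMIDINE_SUBS)
      for (p5 in BASES)
        for (p3 in BASES)
          labs <- c(labs, paste0(p5, "[", sub, "]", p3))
  } else {
    for (sub in PYRIMIDINE_SUBS)
      for (p5a in BASES) for (p5b in BASES)
        for (p3a in BASES) for (p3b in BASES)
          labs <- c(labs, paste0(p5a, p5b, "[", sub, "]", p3a, p3b))
  }
  labs
}

enumerate_dbs <- function() {
  labs <- character(0)
  for (r1 in BASES) for (r2 in BASES)
    for (a1 in BASES) for (a2 in BASES) {
      if (a1 == r1 || a2 == r2) next  # true doublet: both positions change
      labs <- c(labs, canonical_dbs(paste0(r1, r2), paste0(a1, a2)))
    }
  sort(unique(labs))
}

enumerate_id <- function() {
  labs <- character(0)
  for (base in c("C", "T"))
    labs <- c(labs, paste0("1:Del:", base, ":", 1:6))
  for (base in c("C", "T"))
    labs <- c(labs, paste0("1:Ins:", base, ":", 0:5))
  for (len in 2:5)
    labs <- c(labs, paste0(len, ":Del:R:", 1:6))
  for (len in 2:5)
    labs <- c(labs, paste0(len, ":Ins:R:", 0:5))
  mh <- list(`2` = 1L, `3` = 1:2, `4` = 1:3, `5` = 1:5)
  for (len in names(mh))
    labs <- c(labs, paste0(len, ":Del:M:", mh[[len]]))
  labs
}

#' Enumerate the canonical mutation classes of a classification schema
#'
#' Returns the full ordered list of class labels for one of the five
#' supported mutation classification schemas. Substitution classes follow
#' the pyrimidine-centric convention (each base pair is represented by its
#' pyrimidine member); class order is frozen: substitution types
#' C>A, C>G, C>T, T>A, T>C, T>G, then 5' context, then 3' context, bases
#' ordered A < C < G < T. Stranded (SBS192) labels are the 96 trinucleotide
#' classes prefixed `Transcribed:` (all 96), then `Untranscribed:`.
#' Indel (ID83) labels read `<length>:<Del|Ins>:<C|T|R|M>:<bin>`:
#' 1-bp events carry the pyrimidine base and a homopolymer-length bin
#' (deletions 1-6+, counting the deleted base; insertions 0-5+), longer
#' events a length bin (2,3,4,5+) and tandem-repeat-count bin, and
#' microhomology deletions (`M`) a microhomology-length bin.
#'
#' @param schema one of `"SBS96"`, `"SBS192"`, `"SBS1536"`, `"DBS78"`,
#'   `"ID83"`.
#' @return character vector of class labels (length 96, 192, 1536, 78 or
#'   83).
#' @examples
#' length(enumerate_classes("SBS96"))
#' head(enumerate_classes("ID83"))
#' @export
enumerate_classes <- function(schema) {
  schema <- match.arg(schema, c("SBS96", "SBS192", "SBS1536", "DBS78", "ID83"))
  switch(schema,
    SBS96   = enumerate_sbs(1L),
    SBS1536 = enumerate_sbs(2L),
    SBS192  = c(paste0("Transcribed:", enumerate_sbs(1L)),
                paste0("Untranscribed:", enumerate_sbs(1L))),
    DBS78   = enumerate_dbs(),
    ID83    = enumerate_id()
  )
}

#' Number of classes in a schema
#' @param schema schema name as in [enumerate_classes()].
#' @return integer class count.
#' @export
schema_size <- function(schema) length(enumerate_classes(schema))

#' Project SBS1536 class labels onto SBS96
#'
#' Drops the outermost context base on each side; the map is surjective and
#' exactly 16-to-1.
#'
#' @param labels character vector of SBS1536 class labels.
#' @return character vector of SBS96 class labels.
#' @export
project_1536_to_96 <- function(labels) {
  stringr::str_replace(labels,
    "^[ACGT]([ACGT])\\[([CT]>[ACGT])\\]([ACGT])[ACGT]$", "\\1[\\2]\\3")
}
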