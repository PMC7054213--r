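test_that("classify_sbs applies the pyrimidine-centric convention", {
  expect_equal(classify_sbs("C", "A", "ACA"), "A[C>A]A")
  expect_equal(classify_sbs("G", "A", "AGC"), "G[C>T]T")
  # flank 2: purine centre reverse-complemented (TAGCA -> TGCTA)
  expect_equal(classify_sbs("G", "T", "TAGCA"), "TG[C>A]TA")
  expect_error(classify_sbs("C", "A", "ANA"), "non-ACGT")
  expect_error(classify_sbs("C", "A", "ATA"), "centre")
})

test_that("classify_sbs is strand-symmetric over all 96 x contexts", {
  set.seed(7)
  for (i in 1:200) {
    ref <- sample(c("A", "C", "G", "T"), 1)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    ctx <- paste0(sample(c("A", "C", "G", "T"), 1), ref,
                  sample(c("A", "C", "G", "T"), 1))
    lab <- classify_sbs(ref, alt, ctx)
    lab_rc <- classify_sbs(revcomp(ref), revcomp(alt), revcomp(ctx))
    expect_equal(lab, lab_rc)
    expect_true(lab %in% enumerate_classes("SBS96"))
  }
})

test_that("stranded classification follows the template-strand convention", {
  ann <- tibble::tibble(chrom = "chr1", start = c(99L, 500L, 550L),
                        end = c(200L, 600L, 650L),
                        strand = c("+", "+", "-"))
  # pyrimidine on reference strand, + gene: pyrimidine is on the coding
  # (untranscribed) strand
  expect_equal(classify_sbs_stranded("C", "T", "ACA", "chr1", 150L, ann),
               "Untranscribed:A[C>T]A")
  # purine on reference strand: pyrimidine sits on the minus strand,
  # which for a + gene is the template
  expect_equal(classify_sbs_stranded("G", "A", "AGA", "chr1", 150L, ann),
               "Transcribed:T[C>T]T")
  # covered by genes on both strands -> ambiguous
  expect_true(is.na(classify_sbs_stranded("C", "T", "ACA", "chr1", 580L, ann)))
  # intergenic -> no label
  expect_true(is.na(classify_sbs_stranded("C", "T", "ACA", "chr1", 300L, ann)))
})

test_that("classify_dbs canonicalizes reverse-complement pairs", {
  expect_equal(classify_dbs("CC", "TT"), "CC>TT")
  expect_equal(classify_dbs("GG", "AA"), "CC>TT")
  expect_equal(classify_dbs("AT", "TG"), "AT>CA")
  expect_error(classify_dbs("CC", "CC"), "identical")
  expect_error(classify_dbs("CC", "CT"), "true doublet")
  expect_error(classify_dbs("C", "T"), "length")
})

test_that("all 144 raw doublets collapse onto exactly the 78 canonical classes, idempotently", {
  bases <- c("A", "C", "G", "T")
  raw <- list()
  for (r1 in bases) for (r2 in bases)
    for (a1 in setdiff(bases, r1)) for (a2 in setdiff(bases, r2))
      raw[[length(raw) + 1L]] <- c(paste0(r1, r2), paste0(a1, a2))
  expect_length(raw, 144L)
  labs <- vapply(raw, function(p) classify_dbs(p[1], p[2]), character(1))
  expect_setequal(unique(labs), enumerate_classes("DBS78"))
  # both members of each reverse-complement pair give the same label
  for (p in raw) {
    expect_equal(classify_dbs(p[1], p[2]),
                 classify_dbs(revcomp(p[1]), revcomp(p[2])))
  }
})

test_that("all pyrimidine and purine trinucleotide substitutions collapse onto 96 classes", {
  bases <- c("A", "C", "G", "T")
  labs <- character(0)
  for (ref in bases) for (alt in setdiff(bases, ref))
    for (p5 in bases) for (p3 in bases)
      labs <- c(labs, classify_sbs(ref, alt, paste0(p5, ref, p3)))
  expect_length(labs, 192L)  # 6 x 16 pyrimidine + purine mirror images
  expect_setequal(unique(labs), enumerate_classes("SBS96"))
})

test_that("1-bp indels are binned by homopolymer length with pyrimidine collapse", {
  up <- "GGGGGCCA"  # ends in A
  # delete one T from a run of exactly 5 Ts: upstream ...A, downstream TTTT...
  expect_equal(classify_indel("DEL", "T", up, "TTTTGCAGCA"), "1:Del:T:5")
  # delete one A from a run of 3 As (A collapses to T)
  expect_equal(classify_indel("DEL", "A", "GGGGCCTA", "ACGTGCAGCA"),
               "1:Del:T:3")
  # run of >= 6 collapses into the 6+ bin
  expect_equal(classify_indel("DEL", "C", "GGGGCC", "CCCCCCATGA"), "1:Del:C:6")
  # insertion next to no identical base: bin 0
  expect_equal(classify_indel("INS", "T", "GGGGCCA", "GCAGCAG"), "1:Ins:T:0")
  # insertion adjacent to a 2-run on the downstream side
  expect_equal(classify_indel("INS", "T", "GGGGCCA", "TTGAGCA"), "1:Ins:T:2")
  expect_error(classify_indel("DEL", "T", "GG", "TT"), "too short")
})

test_that("longer indels are binned by repeat count and microhomology", {
  pad <- strrep("G", 24)
  padc <- strrep("C", 24)
  # deleted motif present in 3 tandem copies (incl. deleted): repeat bin 3
  expect_equal(classify_indel("DEL", "TA", strrep("G", 12),
                              paste0("TATA", strrep("C", 12))), "2:Del:R:3")
  # no adjacent copy, no shared sequence: repeat bin 1
  expect_equal(classify_indel("DEL", "TAGC", pad, padc), "4:Del:R:1")
  # microhomology: suffix of deleted motif matches following bases
  expect_equal(classify_indel("DEL", "TAGC", pad, paste0("TAGG", padc)),
               "4:Del:M:3")
  expect_equal(classify_indel("DEL", "TAGC", pad, paste0("TGGG", padc)),
               "4:Del:M:1")
  # microhomology on the upstream side counts too (max of both sides)
  expect_equal(classify_indel("DEL", "TAGC", paste0(pad, "AGC"), padc),
               "4:Del:M:3")
  # insertions: tandem copies of the motif next to the insertion point
  expect_equal(classify_indel("INS", "CAT", paste0(pad, "CAT"),
                              paste0("CATCAT", padc)), "3:Ins:R:3")
  expect_equal(classify_indel("INS", "CAT", pad, padc), "3:Ins:R:0")
  # length caps at the 5+ bin
  expect_equal(classify_indel("DEL", "TAGCAA", strrep("G", 36),
                              strrep("C", 36)), "5:Del:R:1")
})

test_that("indel base identity is strand-symmetric", {
  set.seed(11)
  for (i in 1:50) {
    base <- sample(c("A", "C", "G", "T"), 1)
    up <- paste(sample(c("A", "C", "G", "T"), 8, replace = TRUE),
                collapse = "")
    dn <- paste(sample(c("A", "C", "G", "T"), 8, replace = TRUE),
                collapse = "")
    lab <- classify_indel("DEL", base, up, dn)
    lab_rc <- classify_indel("DEL", revcomp(base), revcomp(dn), revcomp(up))
    expect_equal(lab, lab_rc)
  }
})

test_that("normalize_mutations trims VCF anchors and left-normalizes indels", {
  ref <- c(chr1 = "ACGTTTTTGCAAACGATG")
  muts <- tibble::tibble(
    sample_id = "s1", chrom = "chr1",
    pos = c(4L, 8L, 10L, 3L),
    ref = c("T", "TG", "GC", "GTT"),
    alt = c("A", "T", "AT", "G"))
  norm <- normalize_mutations(muts, ref)
  expect_equal(norm$kind, c("SBS", "DEL", "DBS", "DEL"))
  # deletion of G at pos 9 has no shift; deletion of TT shifts to run start
  expect_equal(norm$pos[2], 9L)
  expect_equal(norm$ref[2], "G")
  expect_equal(norm$pos[4], 4L)  # TT deletion left-normalized to pos 4
  expect_equal(norm$ref[4], "TT")
  # insertion left-normalization
  ins <- normalize_mutations(
    tibble::tibble(sample_id = "s1", chrom = "chr1", pos = 7L,
                   ref = "T", alt = "TT"), ref)
  expect_equal(ins$kind, "INS")
  expect_equal(ins$pos, 4L)  # shifted to the start of the T run
  # N-containing alleles are marked for skipping, not errors
  nn <- normalize_mutations(
    tibble::tibble(sample_id = "s1", chrom = "chr1", pos = 4L,
                   ref = "T", alt = "N"), ref)
  expect_true(is.na(nn$kind))
  expect_match(nn$skip_reason, "N")
})
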