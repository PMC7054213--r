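# Ground-truthed synthetic data: catalogues drawn from known signatures
# and exposures, and toy genomes + VCFs with known class tallies.

#' Generate sparse, peaked synthetic signature profiles
#'
#' Profiles concentrate most of their mass on a few "peak" classes over a
#' small uniform background, giving realistic-looking sparse signatures
#' whose pairwise cosines are controlled: a candidate too similar to an
#' already-accepted profile is redrawn.
#'
#' @param schema schema name (class space of the profiles).
#' @param k number of signatures.
#' @param seed integer seed.
#' @param n_peaks number of high-mass classes per signature.
#' @param peak_mass total probability mass on the peaks.
#' @param max_pairwise maximum allowed pairwise cosine between profiles.
#' @return a `signature_set`.
#' @export
synthetic_signatures <- function(schema = "SBS96", k = 3L, seed = 1L,
                                 n_peaks = 6L, peak_mass = 0.8,
                                 max_pairwise = 0.25) {
  classes <- enumerate_classes(schema)
  m <- length(classes)
  set.seed(seed)
  W <- matrix(0, m, k)
  for (s in seq_len(k)) {
    for (try in seq_len(200L)) {
      peaks <- sample.int(m, n_peaks)
      prof <- rep((1 - peak_mass) / (m - n_peaks), m)
      pw <- stats::rgamma(n_peaks, 2)
      prof[peaks] <- peak_mass * pw / sum(pw)
      if (s == 1L ||
          max(cosine_columns(matrix(prof), W[, seq_len(s - 1L),
                                             drop = FALSE])) <= max_pairwise) {
        W[, s] <- prof
        break
      }
      if (try == 200L)
        stop("could not achieve requested pairwise separation", call. = FALSE)
    }
  }
  dimnames(W) <- list(classes, paste0("SynSig", seq_len(k)))
  signature_set(W, schema)
}

#' Define a simulation scenario
#'
#' Bundles the generative model of a synthetic cohort: known signature
#' profiles, a per-sample burden distribution spanning orders of magnitude
#' (log-uniform), Dirichlet signature-mixture weights, an optional
#' hypermutated subpopulation with a burden multiplier, and the noise
#' model.
#'
#' @param signatures a `signature_set` of the true profiles.
#' @param n_samples cohort size.
#' @param burden_range log-uniform bounds for per-sample mutation burdens.
#' @param dirichlet_alpha Dirichlet concentration for mixture weights
#'   (scalar or one value per signature).
#' @param hyper_fraction proportion of hypermutated samples, in `[0, 1)`.
#' @param hyper_multiplier burden multiplier for hypermutated samples.
#' @param noise `"poisson"`, `"multinomial"` or `"none"`.
#' @param seed integer seed.
#' @param name scenario label.
#' @return object of class `simulation_scenario`.
#' @export
simulation_scenario <- function(signatures, n_samples,
                                burden_range = c(1e2, 1e4),
                                dirichlet_alpha = 1,
                                hyper_fraction = 0,
                                hyper_multiplier = 100,
                                noise = c("poisson", "multinomial", "none"),
                                seed = 1L, name = "scenario") {
  noise <- match.arg(noise)
  stopifnot(all(burden_range > 0), hyper_fraction >= 0, hyper_fraction < 1,
            all(dirichlet_alpha > 0))
  k <- n_signatures(signatures)
  alpha <- rep_len(dirichlet_alpha, k)
  structure(list(signatures = signatures, n_samples = as.integer(n_samples),
                 burden_range = burden_range, dirichlet_alpha = alpha,
                 hyper_fraction = hyper_fraction,
                 hyper_multiplier = hyper_multiplier, noise = noise,
                 seed = as.integer(seed), name = name),
            class = "simulation_scenario")
}

#' Simulate a mutation catalogue with known ground truth
#'
#' Per sample: draw a burden log-uniformly (multiplied for hypermutated
#' samples), draw Dirichlet mixture weights over the true signatures,
#' form the expected spectrum `burden * W %*% mixture`, and draw counts
#' under the scenario's noise model. The intended (noise-free) exposures
#' are returned alongside; with multinomial noise the realized total
#' equals the burden exactly, with Poisson noise in expectation.
#'
#' @param scenario a `simulation_scenario`.
#' @param seed optional override of the scenario seed.
#' @return list with `catalogue` (`mutation_catalogue` when the signature
#'   schema is a standard one, otherwise a matrix), `exposures` (true
#'   signatures x samples), `burdens`, `hyper` (logical vector),
#'   `scenario`.
#' @export
simulate_catalogue <- function(scenario, seed = NULL) {
  sc <- scenario
  W <- sc$signatures$W
  k <- ncol(W)
  set.seed(seed %||% sc$seed)
  n <- sc$n_samples
  burdens <- 10^stats::runif(n, log10(sc$burden_range[1]),
                             log10(sc$burden_range[2]))
  n_hyper <- round(sc$hyper_fraction * n)
  hyper <- rep(FALSE, n)
  if (n_hyper > 0) {
    hyper[sample.int(n, n_hyper)] <- TRUE
    burdens[hyper] <- burdens[hyper] * sc$hyper_multiplier
  }
  burdens <- round(burdens)
  mix <- vapply(seq_len(n), function(j) {
    g <- stats::rgamma(k, sc$dirichlet_alpha)
    g / sum(g)
  }, numeric(k))
  mix <- matrix(mix, k, n)  # signatures x samples
  expected <- W %*% (mix * rep(burdens, each = k))
  counts <- switch(sc$noise,
    none = round(expected),
    poisson = matrix(stats::rpois(length(expected), expected),
                     nrow(expected)),
    multinomial = vapply(seq_len(n), function(j)
      as.numeric(stats::rmultinom(1, burdens[j],
                                  pmax(expected[, j], 1e-300))),
      numeric(nrow(expected))))
  counts <- matrix(counts, nrow(W), n,
                   dimnames = list(rownames(W), sprintf("%s_S%03d", sc$name,
                                                        seq_len(n))))
  exposures <- mix * rep(burdens, each = k)
  dimnames(exposures) <- list(colnames(W), colnames(counts))
  cat_obj <- if (!is.na(sc$signatures$schema) &&
                 sc$signatures$schema %in% c("SBS96", "SBS192", "SBS1536",
                                             "DBS78", "ID83"))
    as_catalogue(counts, sc$signatures$schema) else counts
  list(catalogue = cat_obj, exposures = exposures, burdens = burdens,
       hyper = hyper, scenario = sc)
}

#' Simulate a toy genome and matching VCF with known class tallies
#'
#' Writes a random reference contig and places non-overlapping
#' substitution, doublet and indel events on it. Every event's true
#' SBS96/DBS78/ID83 class is computed at generation time (after left
#' normalization), giving a truth table against which
#' [build_catalogue()] output can be compared exactly. Alleles are
#' emitted VCF-style (indels anchored on the preceding base).
#'
#' @param genome_length contig length in bp.
#' @param n_sbs,n_dbs,n_indels event counts.
#' @param seed integer seed (genome and events are byte-reproducible).
#' @param sample_id sample identifier used in the truth table and VCF.
#' @param fasta_path,vcf_path optional output files.
#' @param contig contig name.
#' @return list with `reference` (named character), `mutations` (tibble,
#'   VCF-style), `truth` (named list of class-count tibbles per schema)
#'   and the file paths when written.
#' @export
simulate_genome_and_vcf <- function(genome_length, n_sbs = 0L, n_dbs = 0L,
                                    n_indels = 0L, seed = 1L,
                                    sample_id = "SYN1", fasta_path = NULL,
                                    vcf_path = NULL, contig = "chr1") {
  set.seed(seed)
  L <- as.integer(genome_length)
  genome <- paste(sample(BASES, L, replace = TRUE), collapse = "")
  reference <- stats::setNames(genome, contig)

  max_len <- 4L
  margin <- 6L * max_len + 2L
  need <- n_sbs * 3L + n_dbs * 4L + n_indels * (2L * margin)
  if (need > L - 2L * margin)
    stop("infeasible event density for genome of length ", L, call. = FALSE)

  occupied <- logical(L)
  occupied[seq_len(margin)] <- TRUE
  occupied[(L - margin):L] <- TRUE
  reserve <- function(from, to) {
    if (any(occupied[from:to])) return(FALSE)
    occupied[from:to] <<- TRUE
    TRUE
  }
  draw_pos <- function(width) {
    for (try in seq_len(10000L)) {
      p <- sample.int(L - 2L * margin, 1L) + margin
      if (reserve(p - 1L, p + width)) return(p)
    }
    stop("infeasible event density: placement failed", call. = FALSE)
  }
  base_at <- function(p) substr(genome, p, p)

  muts <- list()
  sbs_lab <- character(0); dbs_lab <- character(0); id_lab <- character(0)

  for (i in seq_len(n_sbs)) {
    p <- draw_pos(1L)
    ref <- base_at(p)
    alt <- sample(setdiff(BASES, ref), 1L)
    ctx <- substr(genome, p - 1L, p + 1L)
    sbs_lab <- c(sbs_lab, classify_sbs(ref, alt, ctx, 1L))
    muts[[length(muts) + 1L]] <- tibble::tibble(
      sample_id = sample_id, chrom = contig, pos = p, ref = ref, alt = alt)
  }
  for (i in seq_len(n_dbs)) {
    p <- draw_pos(2L)
    ref2 <- substr(genome, p, p + 1L)
    alt2 <- paste0(sample(setdiff(BASES, substr(ref2, 1, 1)), 1L),
                   sample(setdiff(BASES, substr(ref2, 2, 2)), 1L))
    dbs_lab <- c(dbs_lab, classify_dbs(ref2, alt2))
    muts[[length(muts) + 1L]] <- tibble::tibble(
      sample_id = sample_id, chrom = contig, pos = p, ref = ref2, alt = alt2)
  }
  for (i in seq_len(n_indels)) {
    len <- sample.int(max_len, 1L, prob = c(0.5, 0.2, 0.2, 0.1))
    is_del <- stats::runif(1) < 0.5
    p <- draw_pos(len + 2L * margin)
    if (is_del) {
      motif <- substr(genome, p, p + len - 1L)
      norm <- left_normalize(genome, p, motif)
      # guard against a long homopolymer shifting the event into the edge
      while (norm$pos - 6L * len < 1L) {
        p <- draw_pos(len + 2L * margin)
        motif <- substr(genome, p, p + len - 1L)
        norm <- left_normalize(genome, p, motif)
      }
      id_lab <- c(id_lab, classify_indel(
        "DEL", norm$motif,
        substr(genome, norm$pos - 6L * len, norm$pos - 1L),
        substr(genome, norm$pos + len, norm$pos + len - 1L + 6L * len)))
      muts[[length(muts) + 1L]] <- tibble::tibble(
        sample_id = sample_id, chrom = contig, pos = p - 1L,
        ref = paste0(base_at(p - 1L), motif), alt = base_at(p - 1L))
    } else {
      motif <- paste(sample(BASES, len, replace = TRUE), collapse = "")
      norm <- left_normalize(genome, p, motif)
      while (norm$pos - 6L * len < 1L) {
        p <- draw_pos(len + 2L * margin)
        motif <- paste(sample(BASES, len, replace = TRUE), collapse = "")
        norm <- left_normalize(genome, p, motif)
      }
      id_lab <- c(id_lab, classify_indel(
        "INS", norm$motif,
        substr(genome, norm$pos - 6L * len, norm$pos - 1L),
        substr(genome, norm$pos, norm$pos - 1L + 6L * len)))
      muts[[length(muts) + 1L]] <- tibble::tibble(
        sample_id = sample_id, chrom = contig, pos = p - 1L,
        ref = base_at(p - 1L), alt = paste0(base_at(p - 1L), motif))
    }
  }

  mutations <- if (length(muts)) dplyr::bind_rows(muts) else
    tibble::tibble(sample_id = character(), chrom = character(),
                   pos = integer(), ref = character(), alt = character())
  truth <- list(
    SBS96 = truth_table(sbs_lab, "SBS96"),
    DBS78 = truth_table(dbs_lab, "DBS78"),
    ID83 = truth_table(id_lab, "ID83"))
  if (!is.null(fasta_path)) write_reference_fasta(reference, fasta_path)
  if (!is.null(vcf_path))
    write_vcf_mutations(mutations, vcf_path, sample_id = sample_id,
                        contigs = stats::setNames(L, contig))
  list(reference = reference, mutations = mutations, truth = truth,
       fasta_path = fasta_path, vcf_path = vcf_path)
}

truth_table <- function(labels, schema) {
  classes <- enumerate_classes(schema)
  counts <- table(factor(labels, levels = classes))
  tibble::tibble(class = classes, count = as.integer(counts))
}

#' Paired synthetic scenario suite
#'
#' Emits the cross-design evaluation scenarios: two distinct synthetic
#' signature sets (A and B) each paired with two exposure models, in all
#' four combinations (A-profiles/A-exposures, A/B, B/A, B/B). At
#' `"desk"` scale each scenario holds at most 300 samples so the full
#' simulate-extract-attribute loop runs on a single CPU in minutes;
#' `"full"` scale enlarges the cohorts proportionally.
#'
#' @param scale `"desk"` or `"full"`.
#' @param schema class space of the scenario profiles.
#' @param seed integer seed.
#' @param profiles optional named list of two `signature_set`s (`A`,
#'   `B`); defaults to the shipped synthetic fixture profiles.
#' @return named list of `simulation_scenario` objects.
#' @export
scenario_suite <- function(scale = c("desk", "full"), schema = "SBS96",
                           seed = 1L, profiles = NULL) {
  scale <- match.arg(scale)
  if (is.null(profiles)) {
    path <- system.file("extdata", "synthetic_signatures_sbs96.csv",
                        package = "sigtool")
    if (!nzchar(path) || !file.exists(path))
      stop("shipped synthetic signature fixture not found", call. = FALSE)
    all_sigs <- read_signatures_csv(path, schema = "SBS96")
    profiles <- list(
      A = signature_set(all_sigs$W[, 1:3, drop = FALSE], all_sigs$schema),
      B = signature_set(all_sigs$W[, 3:5, drop = FALSE], all_sigs$schema))
  }
  n <- if (scale == "desk") 150L else 5800L
  exposure_models <- list(
    A = list(burden_range = c(1e2, 1e4), alpha = 1, hyper = 0),
    B = list(burden_range = c(3e2, 3e3), alpha = 0.5, hyper = 0.05))
  out <- list()
  combos <- expand.grid(prof = c("A", "B"), expo = c("A", "B"),
                        stringsAsFactors = FALSE)
  for (i in seq_len(nrow(combos))) {
    pr <- combos$prof[i]; ex <- combos$expo[i]
    em <- exposure_models[[ex]]
    nm <- paste0("profiles", pr, "_exposures", ex)
    out[[nm]] <- simulation_scenario(
      profiles[[pr]], n, burden_range = em$burden_range,
      dirichlet_alpha = em$alpha, hyper_fraction = em$hyper,
      noise = "poisson", seed = seed + i, name = nm)
  }
  out
}
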