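# Unified pipeline: runs the analysis stages declared in a YAML (or list)
# configuration in dependency order, with one master seed and
# provenance-stamped, byte-reproducible CSV outputs.

PIPELINE_STAGES <- c("catalogue", "extract", "attribute", "clustered",
                     "compare", "agestats")

#' Run the analysis pipeline from a configuration
#'
#' The configuration (YAML file or equivalent nested list) declares a
#' subset of stages and their inputs:
#'
#' * `catalogue`: `vcf` (file or directory of VCFs), `ref` (FASTA),
#'   `schema`, optional `strand_bed`.
#' * `extract`: `kmin`, `kmax`, `iterations`, optional `method`
#'   (`"kl-consensus"` or `"ard"`).
#' * `attribute`: optional `signatures` (CSV; defaults to the extraction
#'   output), optional `sparse` (cosine drop tolerance).
#' * `clustered`: optional `max_dist` (default 1000).
#' * `compare`: `signatures_a`, `signatures_b` (CSV paths).
#' * `agestats`: `metadata` (TSV with `sample_id`, `age`, `cancer_type`).
#'
#' Stage dependencies (`extract`/`attribute`/`clustered` need
#' `catalogue` inputs) are checked before any work; every referenced
#' input path must exist. All CSV outputs carry a provenance comment
#' (tool version, seed, configuration hash) and rerunning with the same
#' configuration and seed reproduces them byte for byte.
#'
#' @param config path to a YAML file or a named list.
#' @param out_dir output directory (created; partial outputs are removed
#'   on failure).
#' @param seed master seed for every stochastic stage.
#' @return invisibly, a named list of written file paths.
#' @export
run_pipeline <- function(config, out_dir, seed = 1L) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  stages <- intersect(PIPELINE_STAGES, names(cfg))
  if (!length(stages)) stop("configuration declares no stages", call. = FALSE)

  # fail fast: validate inputs and dependencies before any work
  needs_catalogue <- intersect(stages, c("extract", "attribute", "clustered"))
  if (length(needs_catalogue) && !"catalogue" %in% stages)
    stop("stage(s) ", paste(needs_catalogue, collapse = ", "),
         " require the catalogue stage", call. = FALSE)
  for (stage in stages) {
    for (key in intersect(names(cfg[[stage]]),
                          c("vcf", "ref", "strand_bed", "signatures",
                            "signatures_a", "signatures_b", "metadata"))) {
      path <- cfg[[stage]][[key]]
      if (!file.exists(path))
        stop("input not found for stage ", stage, ": ", path, call. = FALSE)
    }
  }

  fresh <- !dir.exists(out_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  on_fail <- function(e) {
    file.remove(written[file.exists(written)])
    if (fresh) unlink(out_dir, recursive = TRUE)
    stop(e)
  }

  prov <- sprintf("sigtool %s seed=%d config=%s",
                  as.character(utils::packageVersion("sigtool")), seed,
                  substr(rlang::hash(cfg), 1, 12))
  emit <- function(writer, obj, name, ...) {
    path <- file.path(out_dir, name)
    writer(obj, path, provenance = prov, ...)
    written <<- c(written, path)
    path
  }
  log_msg <- function(...) message("[sigtool] ", sprintf(...))

  out <- list()
  tryCatch({
    mutations <- NULL; reference <- NULL; catalogue <- NULL
    if ("catalogue" %in% stages) {
      st <- cfg$catalogue
      reference <- read_reference_fasta(st$ref)
      vcfs <- if (dir.exists(st$vcf))
        list.files(st$vcf, "\\.vcf$", full.names = TRUE) else st$vcf
      mutations <- dplyr::bind_rows(lapply(vcfs, read_vcf_mutations))
      annotation <- if (!is.null(st$strand_bed)) read_strand_bed(st$strand_bed)
      schema <- st$schema %||% "SBS96"
      log_msg("catalogue: %d mutations, schema %s", nrow(mutations), schema)
      catalogue <- build_catalogue(mutations, reference, schema,
                                   annotation = annotation)
      out$catalogue <- emit(write_catalogue_csv, catalogue,
                            paste0("catalogue_", schema, ".csv"))
    }
    extraction <- NULL
    if ("extract" %in% stages) {
      st <- cfg$extract
      method <- st$method %||% "kl-consensus"
      log_msg("extract: method %s", method)
      if (method == "ard") {
        fit <- ard_nmf(catalogue, k_max = st$kmax %||% 10L, seed = seed,
                       n_restarts = st$restarts %||% 10L)
        extraction <- fit$signatures
      } else {
        ex <- extract_signatures(catalogue,
                                 k_range = (st$kmin %||% 1L):(st$kmax %||% 5L),
                                 n_iterations = st$iterations %||% 1024L,
                                 seed = seed)
        extraction <- solution_at(ex)$signatures
        readr::write_lines(
          c(paste0("# ", prov),
            readr::format_csv(glance(ex))),
          file.path(out_dir, "rank_selection.csv"))
        written <- c(written, file.path(out_dir, "rank_selection.csv"))
        out$rank_selection <- file.path(out_dir, "rank_selection.csv")
      }
      out$signatures <- emit(write_signatures_csv, extraction,
                             "signatures.csv")
    }
    if ("attribute" %in% stages) {
      st <- cfg$attribute
      sigs <- if (!is.null(st$signatures))
        read_signatures_csv(st$signatures) else extraction
      if (is.null(sigs))
        stop("attribute stage needs signatures (from extract or a CSV)",
             call. = FALSE)
      att <- attribute_catalogue(catalogue, sigs,
                                 sparse_tol = st$sparse)
      out$exposures <- emit(write_exposures_csv, att$exposures,
                            "exposures.csv")
    }
    if ("clustered" %in% stages) {
      st <- cfg$clustered
      cc <- clustered_catalogue(mutations, reference,
                                max_dist = st$max_dist %||% 1000L)
      out$clustered <- emit(write_catalogue_csv, cc,
                            "catalogue_clustered_SBS96.csv")
    }
    if ("compare" %in% stages) {
      st <- cfg$compare
      A <- read_signatures_csv(st$signatures_a)
      B <- read_signatures_csv(st$signatures_b)
      pairs <- match_signatures(A, B)
      path <- file.path(out_dir, "signature_matches.csv")
      readr::write_lines(c(paste0("# ", prov), readr::format_csv(pairs)),
                         path)
      written <- c(written, path)
      out$matches <- path
    }
    if ("agestats" %in% stages) {
      st <- cfg$agestats
      meta <- readr::read_tsv(st$metadata, show_col_types = FALSE)
      H <- read_exposures_csv(out$exposures %||%
                                stop("agestats needs the attribute stage",
                                     call. = FALSE))
      scan <- age_scan(H, meta)
      path <- file.path(out_dir, "age_associations.tsv")
      readr::write_lines(c(paste0("# ", prov),
                           readr::format_tsv(tidy(scan))), path)
      written <- c(written, path)
      out$age <- path
    }
  }, error = on_fail)
  invisible(out)
}
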