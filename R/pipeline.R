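#' Configuration for a full screening run
#'
#' All numeric parameters are validated here, before any I/O. Inputs may be
#' given as file paths (genome FASTA, transcript/DE/ortholog/pathway TSV); any
#' input left `NULL` is generated by the synthetic module from `synth`, so a
#' default config runs the whole pipeline self-contained.
#'
#' @param seed Integer seed used for training-set sampling and synthetic
#'   generation.
#' @param genome_a,genes_a Paths to the primary species' genome FASTA and
#'   transcript TSV.
#' @param genome_b,genes_b Paths for the second species (conservation
#'   crossing); optional.
#' @param de Path to the differential-expression TSV.
#' @param orthologs Path to the ortholog map TSV; optional.
#' @param pathways Path to the pathway gene-set TSV; optional.
#' @param spec A [window_spec()].
#' @param constraint A [pair_constraint()].
#' @param tier Screening tier (default `"ppm"`).
#' @param fdr_cut FDR cutoff defining the positive training set.
#' @param n_neg Negative training-set size.
#' @param min_pairs Minimum qualifying pairs per window.
#' @param cooccur_min_pairs,cooccur_min_sites Co-occurrence selection
#'   thresholds.
#' @param universe_size Gene universe for pathway enrichment.
#' @param synth A [synth_config()] used for any input not given as a path.
#' @param out_dir Optional output directory for JSON/TSV reports.
#' @return A validated `ppm_run_config` list.
#' @export
ppm_run_config <- function(seed = 1L,
                           genome_a = NULL, genes_a = NULL,
                           genome_b = NULL, genes_b = NULL,
                           de = NULL, orthologs = NULL, pathways = NULL,
                           spec = window_spec(),
                           constraint = pair_constraint(),
                           tier = "ppm",
                           fdr_cut = 0.01, n_neg = 2000L, min_pairs = 1L,
                           cooccur_min_pairs = 2L, cooccur_min_sites = 3L,
                           universe_size = 25504L,
                           synth = NULL, out_dir = NULL) {
  stopifnot(inherits(spec, "window_spec"), inherits(constraint, "pair_constraint"))
  if (!tier %in% c("ppm", "ls", "vls")) stop("unknown tier", call. = FALSE)
  if (fdr_cut <= 0 || fdr_cut >= 1) stop("fdr_cut must be in (0,1)", call. = FALSE)
  if (n_neg < 1L || min_pairs < 1L || cooccur_min_pairs < 1L ||
      cooccur_min_sites < 2L || universe_size < 2L) {
    stop("invalid size/threshold parameter", call. = FALSE)
  }
  if (is.null(synth)) {
    synth <- synth_config(seed = seed, spec = spec, constraint = constraint)
  }
  structure(
    list(seed = as.integer(seed), genome_a = genome_a, genes_a = genes_a,
         genome_b = genome_b, genes_b = genes_b, de = de,
         orthologs = orthologs, pathways = pathways, spec = spec,
         constraint = constraint, tier = tier, fdr_cut = fdr_cut,
         n_neg = as.integer(n_neg), min_pairs = as.integer(min_pairs),
         cooccur_min_pairs = as.integer(cooccur_min_pairs),
         cooccur_min_sites = as.integer(cooccur_min_sites),
         universe_size = as.integer(universe_size), synth = synth,
         out_dir = out_dir),
    class = "ppm_run_config"
  )
}

pipeline_params <- function(config) {
  list(
    seed = config$seed,
    window = c(-config$spec$upstream, config$spec$downstream),
    distance = c(config$constraint$min_distance,
                 config$constraint$max_distance),
    distance_measure = config$constraint$measure,
    tier = config$tier, fdr_cut = config$fdr_cut, n_neg = config$n_neg,
    min_pairs = config$min_pairs,
    cooccur_min_pairs = config$cooccur_min_pairs,
    cooccur_min_sites = config$cooccur_min_sites,
    universe_size = config$universe_size
  )
}

#' Run the full target-prediction pipeline
#'
#' Executes window extraction and deduplication, training-set construction,
#' model validation, genome-wide screening, cross-species conservation
#' crossing, co-occurrence selection and pathway enrichment, in that order.
#' Inputs not provided as paths in the config are generated synthetically.
#' Reports (JSON + TSV, embedding the full parameter set and seed) are
#' written to `config$out_dir` when set; runs with the same config are
#' byte-identical.
#'
#' @param config A [ppm_run_config()].
#' @param quiet Suppress progress messages (default TRUE).
#' @return A `ppm_pipeline` list: `params`, `training`, `validation` (a
#'   `ppm_validation`), `hits_a`, `hits_b`, `conserved`, `cooccurrence`,
#'   `enrichment`, `n_windows_a`.
#' @export
run_ppm_pipeline <- function(config = ppm_run_config(), quiet = TRUE) {
  stopifnot(inherits(config, "ppm_run_config"))
  say <- function(...) if (!quiet) message(...)
  cfg <- config$synth

  say("stage inputs: loading or generating")
  truth <- orth_pack <- NULL
  if (is.null(config$genome_a) || is.null(config$genes_a)) {
    sp_a <- gen_genome_and_genes(cfg)
    genome_a <- sp_a$genome; genes_a <- sp_a$genes; truth <- sp_a$truth
  } else {
    genome_a <- read_genome(config$genome_a)
    genes_a <- read_gene_table(config$genes_a)
  }
  de <- if (is.null(config$de)) gen_de_table(cfg, truth) else
    read_de_table(config$de)
  if (is.null(config$orthologs) && !is.null(truth)) {
    orth_pack <- gen_orthologs_and_pathways(cfg, truth)
    ortho <- orth_pack$orthologs
    pathways <- orth_pack$pathway
  } else {
    ortho <- if (is.null(config$orthologs)) NULL else
      read_ortholog_map(config$orthologs)
    pathways <- if (is.null(config$pathways)) NULL else
      read_pathway_sets(config$pathways)
  }
  if (is.null(config$genome_b) || is.null(config$genes_b)) {
    sp_b <- if (!is.null(truth)) gen_ortholog_genome(cfg, truth) else NULL
  } else {
    sp_b <- list(genome = read_genome(config$genome_b),
                 genes = read_gene_table(config$genes_b))
  }

  say("stage windows: extract + dedupe")
  windows_a <- dedupe_windows(extract_windows(genes_a, genome_a, config$spec))
  windows_b <- if (!is.null(sp_b)) {
    dedupe_windows(extract_windows(sp_b$genes, sp_b$genome, config$spec))
  }

  say("stage training: positive/negative sets")
  universe <- unique(genes_a$gene_symbol)
  training <- build_training_sets(de, universe, config$fdr_cut, config$n_neg,
                                  config$seed)

  say("stage validate: tiered model validation")
  validation <- validate_ppm(
    windows_a[windows_a$gene_symbol %in% training$positive, ],
    windows_a[windows_a$gene_symbol %in% training$negative, ],
    config$constraint, config$min_pairs
  )

  say("stage screen: genome-wide hits")
  ppm <- ppm_definition(config$tier, config$spec, config$constraint,
                        config$min_pairs)
  hits_a <- screen_genome(windows_a, ppm)
  hits_b <- if (!is.null(windows_b)) screen_genome(windows_b, ppm)

  conserved <- if (!is.null(hits_b) && !is.null(ortho)) {
    say("stage conserve: cross-species intersection")
    conserved_intersection(hits_a, hits_b, ortho)
  }

  say("stage cooccur: pair co-occurrence selection")
  cooccurrence <- cooccurrence_select(hits_a, config$cooccur_min_pairs,
                                      config$cooccur_min_sites)

  enrichment <- NULL
  if (!is.null(pathways) && nrow(cooccurrence) > 0L) {
    say("stage enrich: pathway over-representation")
    enrichment <- pathways |>
      dplyr::group_by(.data$pathway_id) |>
      dplyr::reframe(pathway_enrichment(cooccurrence$gene_symbol,
                                        .data$gene_symbol,
                                        config$universe_size))
  }

  result <- structure(
    list(params = pipeline_params(config),
         training = list(n_positive = length(training$positive),
                         n_negative = length(training$negative)),
         validation = validation,
         hits_a = hits_a, hits_b = hits_b, conserved = conserved,
         cooccurrence = cooccurrence, enrichment = enrichment,
         n_windows_a = nrow(windows_a)),
    class = "ppm_pipeline"
  )
  if (!is.null(config$out_dir)) write_pipeline_reports(result, config$out_dir)
  result
}

#' Write pipeline reports to a directory
#'
#' Writes `report.json` (parameters, training sizes, validation surface,
#' selection summaries), `validation.tsv` (tier-by-column), and TSVs of the
#' screen hits and selections. No timestamps are embedded, so identical
#' configs produce identical report bytes.
#'
#' @param result A `ppm_pipeline` object.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_reports <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(
    params = result$params,
    training = result$training,
    validation = dplyr::select(tidy.ppm_validation(result$validation),
                               !dplyr::ends_with("_pct")),
    n_windows = result$n_windows_a,
    n_hits_a = nrow(result$hits_a),
    n_hits_b = if (!is.null(result$hits_b)) nrow(result$hits_b),
    conserved = result$conserved,
    cooccurrence = dplyr::select(result$cooccurrence, -"transcript_ids"),
    enrichment = result$enrichment
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  write_validation_tsv(result$validation, file.path(out_dir, "validation.tsv"))
  readr::write_tsv(dplyr::select(result$hits_a, -"transcript_ids"),
                   file.path(out_dir, "hits_a.tsv"), progress = FALSE)
  if (!is.null(result$hits_b)) {
    readr::write_tsv(dplyr::select(result$hits_b, -"transcript_ids"),
                     file.path(out_dir, "hits_b.tsv"), progress = FALSE)
  }
  if (!is.null(result$conserved)) {
    readr::write_tsv(result$conserved, file.path(out_dir, "conserved.tsv"),
                     progress = FALSE)
  }
  readr::write_tsv(dplyr::select(result$cooccurrence, -"transcript_ids"),
                   file.path(out_dir, "cooccurrence.tsv"), progress = FALSE)
  invisible(out_dir)
}

#' @export
print.ppm_pipeline <- function(x, ...) {
  cat("Promoter-model screening pipeline (seed ", x$params$seed, ")\n",
      "  windows: ", x$n_windows_a,
      " | training: ", x$training$n_positive, " (+) / ",
      x$training$n_negative, " (-)\n",
      "  screen hits: ", nrow(x$hits_a),
      if (!is.null(x$hits_b)) paste0(" / ", nrow(x$hits_b), " (species B)"),
      "\n", sep = "")
  if (!is.null(x$conserved)) {
    cat("  conserved in both species: ", nrow(x$conserved), "\n", sep = "")
  }
  cat("  co-occurrence selection: ", nrow(x$cooccurrence), "\n\n", sep = "")
  print(x$validation)
  if (!is.null(x$enrichment)) {
    cat("\nPathway enrichment:\n")
    print(as.data.frame(x$enrichment))
  }
  invisible(x)
}
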