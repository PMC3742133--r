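#' Read a differential-expression table
#'
#' TSV with header columns `gene_symbol`, `fold_change`, `direction`, `fdr`
#' (extra columns ignored); the format emulates a moderated-statistics table
#' after multiple-testing correction.
#'
#' @param path Path to a TSV file.
#' @return A tibble.
#' @export
read_de_table <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  needed <- c("gene_symbol", "fold_change", "direction", "fdr")
  missing <- setdiff(needed, names(tbl))
  if (length(missing)) {
    stop("DE table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::tibble(
    gene_symbol = tbl$gene_symbol,
    fold_change = as.numeric(tbl$fold_change),
    direction = tbl$direction,
    fdr = as.numeric(tbl$fdr)
  )
  if (any(is.na(out$fdr)) || any(out$fdr < 0) || any(out$fdr > 1)) {
    stop("fdr must be numeric in [0,1]", call. = FALSE)
  }
  if (any(is.na(out$fold_change)) || any(out$fold_change < 1)) {
    stop("fold_change must be numeric >= 1", call. = FALSE)
  }
  if (!all(out$direction %in% c("up", "down"))) {
    stop("direction must be 'up' or 'down'", call. = FALSE)
  }
  out
}

#' Read a two-column ortholog symbol map
#'
#' TSV with header columns `symbol_a`, `symbol_b`.
#'
#' @param path Path to a TSV file.
#' @return A tibble.
#' @export
read_ortholog_map <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!all(c("symbol_a", "symbol_b") %in% names(tbl))) {
    stop("ortholog map needs columns symbol_a, symbol_b", call. = FALSE)
  }
  tibble::tibble(symbol_a = tbl$symbol_a, symbol_b = tbl$symbol_b)
}

#' Read pathway gene sets
#'
#' TSV with header columns `pathway_id`, `gene_symbol`.
#'
#' @param path Path to a TSV file.
#' @return A tibble.
#' @export
read_pathway_sets <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!all(c("pathway_id", "gene_symbol") %in% names(tbl))) {
    stop("pathway table needs columns pathway_id, gene_symbol", call. = FALSE)
  }
  tibble::tibble(pathway_id = tbl$pathway_id, gene_symbol = tbl$gene_symbol)
}

#' Build positive and negative training gene sets
#'
#' Positives are the genes below the FDR cutoff in the DE table; negatives
#' are sampled uniformly without replacement from the universe excluding the
#' positives, reproducibly under `seed`.
#'
#' @param de A DE tibble (see [read_de_table()]).
#' @param universe Character vector of all candidate gene symbols.
#' @param fdr_cut FDR cutoff for the positive set (default 0.01).
#' @param n_neg Negative-set size (default 2000).
#' @param seed Integer seed.
#' @return A list with `positive`, `negative` (character vectors) and `seed`.
#' @export
build_training_sets <- function(de, universe, fdr_cut = 0.01, n_neg = 2000L,
                                seed = 1L) {
  positive <- unique(de$gene_symbol[de$fdr < fdr_cut])
  if (!all(positive %in% universe)) {
    stop("universe must contain all positive genes", call. = FALSE)
  }
  pool <- setdiff(universe, positive)
  if (length(pool) < n_neg) {
    stop("universe too small: need ", n_neg, " negatives, have ",
         length(pool), call. = FALSE)
  }
  negative <- withr::with_seed(seed, sample(pool, n_neg))
  list(positive = positive, negative = negative, seed = as.integer(seed))
}

tier_labels <- c(ppm = "PPM", ls = "LS-PPM", vls = "VLS-PPM")

gene_level_fits <- function(windows, constraint, min_pairs) {
  classify_windows(windows, constraint, min_pairs) |>
    dplyr::group_by(.data$gene_symbol) |>
    dplyr::summarise(fits_ppm = any(.data$fits_ppm),
                     fits_ls = any(.data$fits_ls),
                     fits_vls = any(.data$fits_vls), .groups = "drop")
}

#' Validate a predictive promoter model against training sets
#'
#' For each tier, counts the genes of each training set whose promoter fits
#' the model (a gene fits if any of its alternative-promoter windows fits),
#' and derives the validation surface: per-set rates, fold enrichment,
#' two-sided Fisher's exact p, and sensitivity/specificity with exact
#' binomial confidence intervals.
#'
#' @param pos_windows,neg_windows Window tibbles for the positive and
#'   negative training sets (deduplicated; see [dedupe_windows()]).
#' @param constraint A [pair_constraint()].
#' @param min_pairs Minimum qualifying pairs per window (default 1).
#' @param conf Confidence level for the interval estimates.
#' @return A `ppm_validation` object; see [tidy.ppm_validation()] and
#'   [glance.ppm_validation()].
#' @export
validate_ppm <- function(pos_windows, neg_windows,
                         constraint = pair_constraint(), min_pairs = 1L,
                         conf = 0.95) {
  if (nrow(pos_windows) == 0L || nrow(neg_windows) == 0L) {
    stop("both training sets must be non-empty", call. = FALSE)
  }
  pos <- gene_level_fits(pos_windows, constraint, min_pairs)
  neg <- gene_level_fits(neg_windows, constraint, min_pairs)
  pos_n <- nrow(pos); neg_n <- nrow(neg)
  rows <- purrr::map(c("ppm", "ls", "vls"), function(tier) {
    col <- paste0("fits_", tier)
    ph <- sum(pos[[col]]); nh <- sum(neg[[col]])
    tab <- contingency_table(ph, pos_n - ph, nh, neg_n - nh)
    ss <- sensitivity_specificity(tab, conf)
    dplyr::bind_cols(
      tibble::tibble(
        tier = tier_labels[[tier]],
        pos_hit = ph, pos_n = pos_n, neg_hit = nh, neg_n = neg_n,
        pos_rate_pct = round_half_up(100 * ph / pos_n),
        neg_rate_pct = round_half_up(100 * nh / neg_n),
        fold = fold_enrichment(ph, pos_n, nh, neg_n),
        fold_rounded = round_half_up(fold_enrichment(ph, pos_n, nh, neg_n)),
        fold_infinite = nh == 0L,
        fisher_p = fisher_exact_two_sided(tab)
      ),
      ss
    )
  }) |> dplyr::bind_rows()
  structure(
    list(report = rows, constraint = constraint, min_pairs = min_pairs,
         conf = conf),
    class = "ppm_validation"
  )
}

#' @export
print.ppm_validation <- function(x, ...) {
  cat("Predictive promoter model validation (",
      x$constraint$min_distance, "-", x$constraint$max_distance,
      " nt spacing, min ", x$min_pairs, " pair(s))\n\n", sep = "")
  r <- x$report
  for (i in seq_len(nrow(r))) {
    cat(sprintf(
      paste0("%-8s (+) %d/%d = %.1f%%  (-) %d/%d = %.1f%%  fold %s",
             "  Fisher p %.2g\n         sensitivity %.1f%% (%.1f-%.1f)",
             "  specificity %.1f%% (%.1f-%.1f)\n"),
      r$tier[i], r$pos_hit[i], r$pos_n[i], r$pos_rate_pct[i],
      r$neg_hit[i], r$neg_n[i], r$neg_rate_pct[i],
      if (r$fold_infinite[i]) "Inf" else format(r$fold_rounded[i]),
      r$fisher_p[i],
      r$sensitivity_pct[i], r$sens_lower_pct[i], r$sens_upper_pct[i],
      r$specificity_pct[i], r$spec_lower_pct[i], r$spec_upper_pct[i]
    ))
  }
  invisible(x)
}

#' Tidy a PPM validation into one row per tier
#'
#' @param x A `ppm_validation` object.
#' @param ... Unused.
#' @return A tibble, one row per tier, with counts, rates, fold enrichment,
#'   Fisher p, and sensitivity/specificity with confidence bounds.
#' @method tidy ppm_validation
#' @export
tidy.ppm_validation <- function(x, ...) x$report

#' One-row summary of a PPM validation (top tier)
#'
#' @param x A `ppm_validation` object.
#' @param ... Unused.
#' @return A one-row tibble for the strictest (PPM) tier.
#' @method glance ppm_validation
#' @export
glance.ppm_validation <- function(x, ...) {
  r <- x$report[x$report$tier == "PPM", ]
  tibble::tibble(
    fold = r$fold, fold_rounded = r$fold_rounded, fisher_p = r$fisher_p,
    sensitivity_pct = r$sensitivity_pct, specificity_pct = r$specificity_pct,
    min_distance = x$constraint$min_distance,
    max_distance = x$constraint$max_distance, min_pairs = x$min_pairs
  )
}

#' Write a validation report as a tier-by-column TSV
#'
#' @param x A `ppm_validation` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_validation_tsv <- function(x, path) {
  r <- tidy.ppm_validation(x)
  long <- tibble::tibble(
    characteristic = c("neg_rate_pct", "pos_rate_pct", "fold", "fisher_p",
                       "sensitivity_pct", "sens_ci", "specificity_pct",
                       "spec_ci")
  )
  for (i in seq_len(nrow(r))) {
    long[[r$tier[i]]] <- c(
      r$neg_rate_pct[i], r$pos_rate_pct[i], r$fold_rounded[i],
      signif(r$fisher_p[i], 2), r$sensitivity_pct[i],
      sprintf("%.1f-%.1f", r$sens_lower_pct[i], r$sens_upper_pct[i]),
      r$specificity_pct[i],
      sprintf("%.1f-%.1f", r$spec_lower_pct[i], r$spec_upper_pct[i])
    )
  }
  readr::write_tsv(long, path, progress = FALSE)
  invisible(path)
}

#' Genome-wide screen for model-fitting genes
#'
#' Classifies every (deduplicated) promoter window and returns one hit per
#' unique gene with at least one window fitting the requested tier. Site and
#' pair counts are taken from the gene's best window (most qualifying pairs;
#' ties broken by canonical site count, then lexicographic window id).
#'
#' @param windows A deduplicated window tibble.
#' @param ppm A [ppm_definition()].
#' @return A tibble of screen hits: `gene_symbol`, `window_id`,
#'   `transcript_ids`, `canonical_site_count`, `admissible_pair_count`.
#' @export
screen_genome <- function(windows, ppm = ppm_definition()) {
  ev <- classify_windows(windows, ppm$constraint, ppm$min_pairs)
  fit_col <- paste0("fits_", ppm$tier)
  pair_col <- paste0("n_pairs_", ppm$tier)
  ev |>
    dplyr::filter(.data[[fit_col]]) |>
    dplyr::mutate(admissible_pair_count = .data[[pair_col]]) |>
    dplyr::group_by(.data$gene_symbol) |>
    dplyr::arrange(dplyr::desc(.data$admissible_pair_count),
                   dplyr::desc(.data$canonical_sites), .data$window_id,
                   .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::transmute(
      gene_symbol = .data$gene_symbol,
      window_id = .data$window_id,
      transcript_ids = .data$transcript_ids,
      canonical_site_count = .data$canonical_sites,
      admissible_pair_count = .data$admissible_pair_count
    ) |>
    dplyr::arrange(.data$gene_symbol)
}

#' Cross-species intersection of screen hits
#'
#' Keeps ortholog pairs where both genes carry the model feature in their
#' own species. Only presence of an admissible pair is required — neither
#' position nor orientation of the sites needs to be conserved.
#'
#' @param hits_a,hits_b Screen-hit tibbles (see [screen_genome()]) for the
#'   two species.
#' @param ortho Ortholog map tibble with columns `symbol_a`, `symbol_b`.
#' @return A tibble with columns `gene_a`, `gene_b`, sorted by `gene_a`.
#' @export
conserved_intersection <- function(hits_a, hits_b, ortho) {
  ortho |>
    dplyr::filter(.data$symbol_a %in% hits_a$gene_symbol,
                  .data$symbol_b %in% hits_b$gene_symbol) |>
    dplyr::transmute(gene_a = .data$symbol_a, gene_b = .data$symbol_b) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$gene_a)
}

#' Select targets by co-occurrence of admissible pairs
#'
#' Keeps screen hits whose best window carries at least `min_sites` canonical
#' sites forming at least `min_pairs` admissible pairs, ranked by pair count
#' (descending), then site count (descending), then gene symbol.
#'
#' @param hits A screen-hit tibble (see [screen_genome()]).
#' @param min_pairs Minimum admissible pair count (default 2).
#' @param min_sites Minimum canonical site count (default 3).
#' @return The selected, ranked subset of `hits`.
#' @export
cooccurrence_select <- function(hits, min_pairs = 2L, min_sites = 3L) {
  hits |>
    dplyr::filter(.data$canonical_site_count >= min_sites,
                  .data$admissible_pair_count >= min_pairs) |>
    dplyr::arrange(dplyr::desc(.data$admissible_pair_count),
                   dplyr::desc(.data$canonical_site_count),
                   .data$gene_symbol)
}

#' Pathway over-representation of a selection
#'
#' Fold enrichment of pathway membership in the selection relative to the
#' gene universe, with a chi-squared test (Yates continuity correction) on
#' the 2x2 table (selected vs rest) x (in pathway vs not).
#'
#' @param selected Character vector of selected gene symbols.
#' @param pathway_genes Character vector of pathway member symbols.
#' @param universe_size Number of unique genes in the universe
#'   (default 25504).
#' @return One-row tibble: `n_selected`, `pathway_size`, `overlap`, `fold`,
#'   `fold_rounded`, `statistic`, `p_value`.
#' @export
pathway_enrichment <- function(selected, pathway_genes,
                               universe_size = 25504L) {
  selected <- unique(selected)
  pathway_genes <- unique(pathway_genes)
  if (length(selected) == 0L) stop("empty selection", call. = FALSE)
  if (length(pathway_genes) == 0L) stop("empty pathway", call. = FALSE)
  if (length(pathway_genes) >= universe_size) {
    stop("pathway must be smaller than the universe", call. = FALSE)
  }
  a <- length(intersect(selected, pathway_genes))
  b <- length(selected) - a
  cc <- length(pathway_genes) - a
  d <- universe_size - a - b - cc
  fold <- (a / length(selected)) / (length(pathway_genes) / universe_size)
  chi <- chi2_yates(matrix(c(a, b, cc, d), 2L, byrow = TRUE))
  tibble::tibble(
    n_selected = length(selected), pathway_size = length(pathway_genes),
    overlap = a, fold = fold, fold_rounded = round_half_up(fold),
    statistic = chi$statistic, p_value = chi$p_value
  )
}
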