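test_that("training sets split positives by FDR and sample negatives", {
  universe <- sprintf("G%05d", 1:3000)
  de <- tibble::tibble(
    gene_symbol = universe[1:200],
    fold_change = 1.5, direction = "up",
    fdr = c(rep(0.005, 30), rep(0.05, 116), rep(0.5, 54))
  )
  ts <- build_training_sets(de, universe, n_neg = 2000, seed = 4)
  expect_length(ts$positive, 30)
  expect_length(ts$negative, 2000)
  expect_length(intersect(ts$positive, ts$negative), 0)
  expect_length(unique(ts$negative), 2000)
  ts2 <- build_training_sets(de, universe, n_neg = 2000, seed = 4)
  expect_identical(ts, ts2)
  expect_error(build_training_sets(de, universe[1:100], n_neg = 2000, seed = 1),
               "universe")
  expect_error(build_training_sets(de, universe[31:1000], n_neg = 2000,
                                   seed = 1),
               "universe")
})

test_that("validation reproduces a constructed 3/30 vs 9/2000 surface", {
  pos <- gen_promoter_set(30, 3, seed = 21)
  neg <- gen_promoter_set(2000, 9, seed = 22)
  v <- validate_ppm(pos$windows, neg$windows)
  r <- tidy(v)
  ppm <- r[r$tier == "PPM", ]
  expect_equal(ppm$pos_hit, 3L)
  expect_equal(ppm$neg_hit, 9L)
  expect_equal(ppm$fold_rounded, 22.2)
  expect_equal(ppm$sensitivity_pct, 10.0)
  expect_equal(ppm$specificity_pct, 99.6)
  expect_equal(signif(ppm$fisher_p, 1), 6e-4)
  # tier sensitivities never decrease from PPM to LS to VLS
  expect_true(all(diff(r$sensitivity) >= 0))
  g <- glance(v)
  expect_equal(g$fold_rounded, 22.2)
})

test_that("identical training sets give fold 1 and Fisher p 1", {
  w <- gen_promoter_set(50, 5, seed = 9)$windows
  w2 <- w
  w2$gene_symbol <- paste0(w$gene_symbol, "_b")
  w2$window_id <- paste0(w$window_id, "_b")
  v <- validate_ppm(w, w2)
  r <- tidy(v)
  expect_true(all(r$fold[!r$fold_infinite] == 1))
  expect_equal(r$fisher_p, rep(1, 3), tolerance = 1e-12)
  expect_error(validate_ppm(w[0, ], w), "non-empty")
})

test_that("gene-level screening uses ANY-window semantics and best window", {
  fit1 <- window_with(site("CAAGTG", 50), site("CACTTG", 190))
  nofit <- strrep("A", 450)
  fit2 <- plant_site_cluster(strrep("T", 450), gaps = c(100, 100),
                             seed = 5)$sequence
  w <- promoter_windows(
    c("gA", "gA", "gB", "gC"), c(nofit, fit1, nofit, fit2),
    transcript_id = c("a.1", "a.2", "b.1", "c.1")
  )
  hits <- screen_genome(w)
  expect_equal(hits$gene_symbol, c("gA", "gC"))
  # gA's evidence comes from its fitting window
  expect_equal(hits$window_id[hits$gene_symbol == "gA"], "a.2")
  expect_equal(hits$admissible_pair_count[hits$gene_symbol == "gC"], 2L)
  expect_equal(hits$canonical_site_count[hits$gene_symbol == "gC"], 3L)
})

test_that("screen hits are monotone in tier", {
  set.seed(55)
  seqs <- c(
    replicate(60, random_window(450, c(A = .3, C = .2, G = .3, T = .2))),
    vapply(1:15, function(i) {
      plant_ppm_instance(random_window(450),
                         sample(c("ppm", "ls", "vls"), 1),
                         sample(90:190, 1))$sequence
    }, "")
  )
  w <- promoter_windows(sprintf("g%02d", seq_along(seqs)), seqs)
  g_ppm <- screen_genome(w, ppm_definition("ppm"))$gene_symbol
  g_ls <- screen_genome(w, ppm_definition("ls"))$gene_symbol
  g_vls <- screen_genome(w, ppm_definition("vls"))$gene_symbol
  expect_true(all(g_ppm %in% g_ls))
  expect_true(all(g_ls %in% g_vls))
})

test_that("conservation crossing keeps only ortholog pairs hit in both", {
  hit <- function(g) tibble::tibble(
    gene_symbol = g, window_id = paste0(g, ".1"),
    transcript_ids = as.list(paste0(g, ".1")),
    canonical_site_count = 2L, admissible_pair_count = 1L
  )
  ortho <- tibble::tibble(symbol_a = c("A", "B"), symbol_b = c("A2", "B2"))
  out <- conserved_intersection(hit(c("A", "B")), hit(c("A2", "C2")), ortho)
  expect_equal(out, tibble::tibble(gene_a = "A", gene_b = "A2"))
  expect_equal(nrow(conserved_intersection(hit("X"), hit("Y"), ortho)), 0L)
  # symmetry: swapping species and inverting the map mirrors the pairs
  inv <- tibble::tibble(symbol_a = ortho$symbol_b, symbol_b = ortho$symbol_a)
  mirrored <- conserved_intersection(hit(c("A2", "C2")), hit(c("A", "B")), inv)
  expect_equal(mirrored, tibble::tibble(gene_a = "A2", gene_b = "A"))
})

test_that("co-occurrence selection filters and ranks by pairs, sites, symbol", {
  hits <- tibble::tibble(
    gene_symbol = c("d", "c", "b", "a", "e"),
    window_id = paste0(letters[c(4, 3, 2, 1, 5)], ".1"),
    transcript_ids = as.list(letters[c(4, 3, 2, 1, 5)]),
    canonical_site_count = c(3L, 3L, 3L, 4L, 2L),
    admissible_pair_count = c(1L, 2L, 2L, 3L, 2L)
  )
  sel <- cooccurrence_select(hits)
  # e fails the >=3 sites filter, d the >=2 pairs filter
  expect_equal(sel$gene_symbol, c("a", "b", "c"))
  expect_equal(nrow(cooccurrence_select(dplyr::mutate(
    hits, admissible_pair_count = 1L))), 0L)
  # ties on pairs are broken by site count, then symbol
  tie <- dplyr::mutate(hits[1:3, ], admissible_pair_count = 2L,
                       canonical_site_count = c(3L, 4L, 3L))
  expect_equal(cooccurrence_select(tie)$gene_symbol, c("c", "b", "d"))
  # subset property against a screen
  w <- gen_promoter_set(40, 6, seed = 17)$windows
  sg <- screen_genome(w)
  expect_true(all(cooccurrence_select(sg)$gene_symbol %in% sg$gene_symbol))
})

test_that("pathway enrichment computes fold and Yates chi-squared", {
  path <- sprintf("pw%03d", 1:135)
  sel <- c(path[1:3], sprintf("x%02d", 1:7))
  e <- pathway_enrichment(sel, path, universe_size = 25504)
  expect_equal(e$fold, (3 / 10) / (135 / 25504))
  expect_equal(e$fold_rounded, 56.7)
  expect_lt(e$p_value, 1e-4)
  # no overlap => fold 0
  e0 <- pathway_enrichment(sprintf("x%02d", 1:10), path)
  expect_equal(e0$fold, 0)
  expect_error(pathway_enrichment(character(0), path), "empty selection")
  expect_error(pathway_enrichment("a", character(0)), "empty pathway")
  expect_error(pathway_enrichment("a", path, universe_size = 100), "universe")
})

test_that("DE, ortholog and pathway readers validate their columns", {
  de_path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(gene_symbol = "g", fold_change = 1.5,
                                  direction = "up", fdr = 0.005), de_path)
  de <- read_de_table(de_path)
  expect_equal(de$fdr, 0.005)
  readr::write_tsv(tibble::tibble(gene_symbol = "g", fold_change = 1.5,
                                  direction = "sideways", fdr = 0.005),
                   de_path)
  expect_error(read_de_table(de_path), "direction")
  readr::write_tsv(tibble::tibble(gene_symbol = "g", fold_change = 1.5,
                                  direction = "up", fdr = 2), de_path)
  expect_error(read_de_table(de_path), "fdr")
  readr::write_tsv(tibble::tibble(a = "x", b = "y"), de_path)
  expect_error(read_de_table(de_path), "missing column")
  expect_error(read_ortholog_map(de_path), "symbol_a")
  expect_error(read_pathway_sets(de_path), "pathway_id")
})
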