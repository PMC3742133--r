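small_cfg <- function(seed = 1, ...) {
  synth_config(seed = seed, n_genes = 100L, fraction_positive = 0.1,
               n_cooccur = 3L, n_conserved = 5L, n_b_specific = 5L,
               n_fdr01 = 6L, n_fdr1 = 20L, n_up_fdr01 = 3L, n_up_fdr1 = 10L,
               planted_in_fdr01 = 3L, pathway_size = 20L,
               n_pathway_planted = 2L, ...)
}

test_that("config validation rejects inconsistent parameters", {
  expect_error(synth_config(base_probs = c(.5, .5, .1, .1)), "summing to 1")
  expect_error(synth_config(n_fdr01 = 200, n_fdr1 = 146), "n_fdr01")
  expect_error(synth_config(n_genes = 100, fraction_positive = 0.1,
                            n_cooccur = 8, n_conserved = 5),
               "n_conserved")
  expect_error(synth_config(pathway_size = 0), "pathway_size")
  expect_error(synth_config(pathway_size = 30000), "pathway_size")
  expect_error(synth_config(fc_range = c(1.0, 2)), "1.2")
  expect_error(synth_config(contig_len = 100), "contig_len")
})

test_that("genome generation plants the configured fraction, reproducibly", {
  cfg <- small_cfg(seed = 7)
  sp <- gen_genome_and_genes(cfg)
  expect_equal(sum(sp$truth$planted), 10L)
  expect_equal(length(sp$genome), 100L)
  sp2 <- gen_genome_and_genes(cfg)
  expect_identical(as.character(sp$genome), as.character(sp2$genome))
  expect_identical(sp$genes, sp2$genes)
  expect_identical(sp$truth$planted, sp2$truth$planted)
})

test_that("planted truth is recovered exactly by scanning", {
  cfg <- small_cfg(seed = 3)
  sp <- gen_genome_and_genes(cfg)
  windows <- dedupe_windows(extract_windows(sp$genes, sp$genome, cfg$spec))
  ev <- classify_windows(windows, cfg$constraint)
  gene_fit <- ev |>
    dplyr::group_by(gene_symbol) |>
    dplyr::summarise(fits = any(fits_ppm))
  truth <- sp$truth[match(gene_fit$gene_symbol, sp$truth$gene_symbol), ]
  expect_identical(gene_fit$fits, truth$planted)
  # planted sites sit at the recorded offsets
  planted <- sp$truth[sp$truth$planted, ]
  hits <- scan_windows(windows, "canonical")
  for (i in seq_len(nrow(planted))) {
    got <- hits$offset[hits$gene_symbol == planted$gene_symbol[i]]
    expect_true(all(planted$site_offsets[[i]] %in% got))
  }
  # pair-planted distances respect the constraint
  dists <- unlist(planted$pair_distances)
  expect_true(all(dists >= 90 & dists <= 190))
})

test_that("pair planting writes sites at the requested spacing", {
  s <- plant_ppm_instance(strrep("A", 450), "ppm", 140, seed = 2)
  expect_equal(diff(s$offsets), 140L)
  ev <- classify_windows(promoter_windows("g", s$sequence))
  expect_true(ev$fits_ppm)
  expect_equal(ev$pairs[[1]]$distance, 140L)

  ls <- plant_ppm_instance(strrep("A", 450), "ls", 100, seed = 2)
  evl <- classify_windows(promoter_windows("g", ls$sequence))
  expect_false(evl$fits_ppm)
  expect_true(evl$fits_ls)

  # determinism and orientation control
  s2 <- plant_ppm_instance(strrep("A", 450), "ppm", 140, seed = 2)
  expect_identical(s, s2)
  sf <- plant_ppm_instance(strrep("A", 450), "ppm", 95,
                           orientations = c("reverse", "reverse"), seed = 1)
  expect_equal(substr(sf$sequence, sf$offsets[1] + 1, sf$offsets[1] + 6),
               "CACTTG")
})

test_that("planting never creates spurious canonical sites", {
  set.seed(90)
  for (i in 1:30) {
    base <- random_window(450, c(A = .3, C = .2, G = .3, T = .2))
    before <- oracle_scan(base, "CAAGTG")
    r <- plant_ppm_instance(base, "ppm", sample(90:190, 1))
    after <- oracle_scan(r$sequence, "CAAGTG")
    expect_true(all(setdiff(after, r$offsets) %in% before))
    expect_true(all(r$offsets %in% after))
  }
})

test_that("DE tables hit the configured FDR strata and direction splits", {
  cfg <- small_cfg(seed = 11)
  sp <- gen_genome_and_genes(cfg)
  de <- gen_de_table(cfg, sp$truth)
  expect_equal(nrow(de), 100L)
  expect_equal(sum(de$fdr < 0.01), 6L)
  expect_equal(sum(de$fdr < 0.1), 20L)
  top <- de[de$fdr < 0.01, ]
  expect_equal(sum(top$direction == "up"), 3L)
  sig <- de[de$fdr < 0.1, ]
  expect_equal(sum(sig$direction == "up"), 10L)
  expect_true(all(sig$fold_change >= 1.2))
  # planted pair genes preferentially in the top stratum
  planted_pairs <- sp$truth$gene_symbol[sp$truth$planted &
                                          sp$truth$kind == "pair"]
  expect_equal(length(intersect(top$gene_symbol, planted_pairs)), 3L)
  expect_identical(de, gen_de_table(cfg, sp$truth))
})

test_that("ortholog maps and pathways carry the planted structure", {
  cfg <- small_cfg(seed = 13)
  sp <- gen_genome_and_genes(cfg)
  op <- gen_orthologs_and_pathways(cfg, sp$truth)
  conserved <- sp$truth$gene_symbol[sp$truth$conserved]
  expect_true(all(conserved %in% op$orthologs$symbol_a))
  expect_identical(op$orthologs$symbol_b, toupper(op$orthologs$symbol_a))
  expect_equal(nrow(op$pathway), 20L)
  cooccur <- sp$truth$gene_symbol[!is.na(sp$truth$kind) &
                                    sp$truth$kind == "cooccur"]
  expect_equal(length(intersect(op$pathway$gene_symbol, cooccur)), 2L)
})

test_that("gen_promoter_set produces exact planted counts", {
  ps <- gen_promoter_set(120, 7, seed = 19)
  ev <- classify_windows(ps$windows)
  expect_equal(sum(ev$fits_ppm), 7L)
  expect_identical(ev$fits_ppm, ps$truth$planted)
  expect_identical(gen_promoter_set(120, 7, seed = 19)$windows$sequence,
                   ps$windows$sequence)
})

test_that("a Markov background biases dinucleotide composition", {
  # strong CC/GG persistence should raise G+C runs relative to iid
  trans <- matrix(0.25, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                              c("A", "C", "G", "T")))
  trans["C", ] <- c(.1, .7, .1, .1)
  trans["G", ] <- c(.1, .1, .7, .1)
  set.seed(6)
  seqs <- ppmscreen:::random_sequences(50, 450, rep(.25, 4), trans)
  cc <- sum(vapply(seqs, function(s) {
    length(oracle_find(s, "CC"))
  }, 0))
  expect_gt(cc / (50 * 449), 0.1)  # iid expectation is 1/16
})
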