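#' Configuration for the synthetic-data generators
#'
#' Defaults emulate the study conditions end-to-end: a 2,500-gene synthetic
#' genome (enough to draw a 2,000-promoter negative training set), 1% of
#' promoters carrying planted binding-site structure (10 multi-site
#' "co-occurrence" promoters — nine with three sites forming two admissible
#' pairs, one with four sites forming three — and pair promoters, ten of
#' which are conserved in a second species), a differential-expression table
#' with 146 genes at FDR<0.1 (70 up, 76 down) of which 30 fall below
#' FDR<0.01 (14 up, 16 down) including 3 planted two-motif genes, uniform
#' base composition (optionally first-order Markov), planted pair distances
#' uniform on the admissible range, a 25,504-gene universe and a 135-gene
#' pathway containing 3 planted targets.
#'
#' @param seed Integer seed; all generators are pure functions of
#'   `(config, seed)`.
#' @param n_genes Number of genes in the synthetic genome.
#' @param base_probs Named per-base probabilities (A, C, G, T), summing to 1.
#' @param markov Optional 4x4 first-order transition matrix (rows/cols
#'   A, C, G, T; rows summing to 1) for dinucleotide-biased background.
#' @param fraction_positive Fraction of genes receiving planted structure.
#' @param planted_tier Tier of planted pair promoters (`"ppm"`, `"ls"`,
#'   `"vls"`).
#' @param constraint A [pair_constraint()]; planted distances are sampled
#'   uniformly from its range.
#' @param spec A [window_spec()].
#' @param n_cooccur Number of multi-site promoters among the planted genes.
#' @param n_conserved Number of planted pair genes also planted in the
#'   second species.
#' @param n_b_specific Second-species-only planted genes (noise for the
#'   conservation crossing).
#' @param n_fdr01,n_fdr1 Genes below FDR 0.01 / 0.1 in the DE table.
#' @param n_up_fdr01,n_up_fdr1 How many of those are upregulated.
#' @param planted_in_fdr01 Planted pair genes placed in the FDR<0.01 stratum.
#' @param fc_range Fold-change range for FDR<0.1 genes (minimum 1.2).
#' @param ortholog_fraction Fraction of genes covered by the ortholog map.
#' @param pathway_size,n_pathway_planted Pathway gene-set size and how many
#'   planted co-occurrence genes it contains.
#' @param universe_size Size of the gene universe for enrichment.
#' @param contig_len Length of each per-gene contig.
#' @param background_fit_rejection Resample non-planted promoters that would
#'   fit the planted tier by chance, so truth tables are exact.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(seed = 1L,
                         n_genes = 2500L,
                         base_probs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                         markov = NULL,
                         fraction_positive = 0.01,
                         planted_tier = "ppm",
                         constraint = pair_constraint(),
                         spec = window_spec(),
                         n_cooccur = 10L,
                         n_conserved = 10L,
                         n_b_specific = 15L,
                         n_fdr01 = 30L, n_fdr1 = 146L,
                         n_up_fdr01 = 14L, n_up_fdr1 = 70L,
                         planted_in_fdr01 = 3L,
                         fc_range = c(1.2, 5),
                         ortholog_fraction = 0.8,
                         pathway_size = 135L,
                         n_pathway_planted = 3L,
                         universe_size = 25504L,
                         contig_len = 700L,
                         background_fit_rejection = TRUE) {
  stopifnot(inherits(constraint, "pair_constraint"), inherits(spec, "window_spec"))
  if (abs(sum(base_probs) - 1) > 1e-8 || length(base_probs) != 4L) {
    stop("base_probs must be 4 probabilities summing to 1", call. = FALSE)
  }
  if (!is.null(markov)) {
    stopifnot(is.matrix(markov), all(dim(markov) == 4L),
              all(abs(rowSums(markov) - 1) < 1e-8))
  }
  n_planted <- round(fraction_positive * n_genes)
  n_cooccur <- min(as.integer(n_cooccur), n_planted)
  n_pairs <- n_planted - n_cooccur
  if (n_conserved > n_pairs) {
    stop("n_conserved exceeds the number of planted pair genes (",
         n_pairs, ")", call. = FALSE)
  }
  if (!(n_fdr01 <= n_fdr1 && n_fdr1 <= n_genes)) {
    stop("need n_fdr01 <= n_fdr1 <= n_genes", call. = FALSE)
  }
  if (n_up_fdr01 > n_fdr01 || n_up_fdr1 > n_fdr1 ||
      n_up_fdr1 - n_up_fdr01 > n_fdr1 - n_fdr01) {
    stop("inconsistent up/down direction counts", call. = FALSE)
  }
  if (planted_in_fdr01 > min(n_fdr01, n_pairs)) {
    stop("planted_in_fdr01 exceeds available planted pair genes", call. = FALSE)
  }
  if (fc_range[1] < 1.2) stop("fold changes below 1.2 are sub-threshold",
                              call. = FALSE)
  if (pathway_size < 1L || pathway_size >= universe_size) {
    stop("pathway_size must be in [1, universe_size)", call. = FALSE)
  }
  if (n_pathway_planted > min(pathway_size, n_cooccur)) {
    stop("n_pathway_planted exceeds pathway or co-occurrence gene count",
         call. = FALSE)
  }
  win_len <- spec$upstream + spec$downstream
  if (contig_len < win_len + 10L) {
    stop("contig_len too short for the promoter window", call. = FALSE)
  }
  structure(
    list(seed = as.integer(seed), n_genes = as.integer(n_genes),
         base_probs = base_probs, markov = markov,
         fraction_positive = fraction_positive, planted_tier = planted_tier,
         constraint = constraint, spec = spec,
         n_planted = as.integer(n_planted), n_cooccur = n_cooccur,
         n_pairs = as.integer(n_pairs), n_conserved = as.integer(n_conserved),
         n_b_specific = as.integer(n_b_specific),
         n_fdr01 = as.integer(n_fdr01), n_fdr1 = as.integer(n_fdr1),
         n_up_fdr01 = as.integer(n_up_fdr01), n_up_fdr1 = as.integer(n_up_fdr1),
         planted_in_fdr01 = as.integer(planted_in_fdr01),
         fc_range = fc_range, ortholog_fraction = ortholog_fraction,
         pathway_size = as.integer(pathway_size),
         n_pathway_planted = as.integer(n_pathway_planted),
         universe_size = as.integer(universe_size),
         contig_len = as.integer(contig_len),
         background_fit_rejection = isTRUE(background_fit_rejection)),
    class = "synth_config"
  )
}

BASES <- c("A", "C", "G", "T")

# n random sequences of length len; iid by default, first-order Markov when
# a transition matrix is supplied. Uses the current RNG state.
random_sequences <- function(n, len, probs = rep(0.25, 4), markov = NULL) {
  if (n == 0L) return(character(0))
  if (is.null(markov)) {
    m <- matrix(sample(BASES, n * len, replace = TRUE, prob = probs),
                nrow = n)
  } else {
    cum <- t(apply(markov, 1L, cumsum))
    m <- matrix("", nrow = n, ncol = len)
    state <- sample.int(4L, n, replace = TRUE, prob = probs)
    m[, 1L] <- BASES[state]
    for (j in seq_len(len - 1L) + 1L) {
      u <- stats::runif(n)
      state <- rowSums(u > cum[state, , drop = FALSE]) + 1L
      m[, j] <- BASES[state]
    }
  }
  do.call(paste0, split(m, col(m)))
}

canonical_offsets <- function(sequence) {
  sort(c(find_exact(sequence, "CAAGTG"), find_exact(sequence, "CACTTG")))
}

write_motif <- function(sequence, offset, oriented) {
  substr(sequence, offset + 1L, offset + nchar(oriented)) <- oriented
  sequence
}

plant_cluster_once <- function(sequence, motifs, orientations, gaps) {
  lens <- vapply(motifs, function(m) m$length, 0L)
  starts_rel <- cumsum(c(0L, gaps))
  span <- starts_rel[length(starts_rel)] + lens[length(lens)]
  max_start <- nchar(sequence) - span
  if (max_start < 0L) return(NULL)
  s1 <- sample.int(max_start + 1L, 1L) - 1L
  starts <- s1 + starts_rel
  before <- canonical_offsets(sequence)
  out <- sequence
  for (i in seq_along(motifs)) {
    oriented <- if (orientations[i] == "forward") motifs[[i]]$forward
                else motifs[[i]]$reverse
    out <- write_motif(out, starts[i], oriented)
  }
  planted_canon <- starts[vapply(motifs, function(m) m$name, "") == "canonical"]
  after <- canonical_offsets(out)
  extra <- setdiff(after, planted_canon)
  if (!all(extra %in% before) || !all(planted_canon %in% after)) return(NULL)
  list(sequence = out, offsets = starts, orientations = orientations)
}

#' Plant a distance-constrained binding-site pair into a window
#'
#' Writes two oriented motif strings whose 5'-most bases are separated by
#' exactly `distance`. Placement is resampled (up to `max_tries`) whenever
#' overwriting would create a canonical site that was not planted and did
#' not pre-exist, keeping truth tables exact. Residual chance core (`CAAG`)
#' sites are permitted.
#'
#' @param sequence Window sequence string.
#' @param tier Planted tier: `"ppm"` (canonical+canonical), `"ls"`
#'   (canonical+core), `"vls"` (core+core).
#' @param distance Start-to-start distance in nt.
#' @param orientations Length-2 character vector (`"forward"`/`"reverse"`);
#'   sampled uniformly when `NULL`.
#' @param seed Optional integer seed; when `NULL` the current RNG state is
#'   used (generators call this inside their own seeded scope).
#' @param max_tries Placement attempts before giving up.
#' @return A list with `sequence` (modified window), `offsets` (two 0-based
#'   starts) and `orientations`.
#' @export
plant_ppm_instance <- function(sequence, tier = c("ppm", "ls", "vls"),
                               distance, orientations = NULL, seed = NULL,
                               max_tries = 100L) {
  tier <- match.arg(tier)
  distance <- as.integer(distance)
  motifs <- switch(tier,
    ppm = list(hmx_motif("canonical"), hmx_motif("canonical")),
    ls = list(hmx_motif("canonical"), hmx_motif("core")),
    vls = list(hmx_motif("core"), hmx_motif("core"))
  )
  run <- function() {
    for (i in seq_len(max_tries)) {
      ori <- if (is.null(orientations)) {
        sample(c("forward", "reverse"), 2L, replace = TRUE)
      } else orientations
      res <- plant_cluster_once(sequence, motifs, ori, gaps = distance)
      if (!is.null(res)) return(res)
    }
    stop("could not place the pair without creating spurious canonical sites",
         call. = FALSE)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Plant a homotypic cluster of canonical sites into a window
#'
#' Writes `length(gaps) + 1` canonical sites at consecutive start-to-start
#' gaps `gaps`, with the same spurious-site rejection as
#' [plant_ppm_instance()].
#'
#' @param sequence Window sequence string.
#' @param gaps Integer vector of consecutive start-to-start gaps (nt).
#' @param orientations Optional orientation vector (length `length(gaps)+1`).
#' @param seed Optional integer seed.
#' @param max_tries Placement attempts before giving up.
#' @return A list with `sequence`, `offsets`, `orientations`.
#' @export
plant_site_cluster <- function(sequence, gaps, orientations = NULL,
                               seed = NULL, max_tries = 100L) {
  k <- length(gaps) + 1L
  motifs <- replicate(k, hmx_motif("canonical"), simplify = FALSE)
  run <- function() {
    for (i in seq_len(max_tries)) {
      ori <- if (is.null(orientations)) {
        sample(c("forward", "reverse"), k, replace = TRUE)
      } else orientations
      res <- plant_cluster_once(sequence, motifs, ori, as.integer(gaps))
      if (!is.null(res)) return(res)
    }
    stop("could not place the cluster without creating spurious canonical sites",
         call. = FALSE)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# Windows (character vector) that fit a tier under the constraint.
which_fit <- function(seqs, tier, constraint, spec) {
  if (length(seqs) == 0L) return(logical(0))
  w <- promoter_windows(sprintf("q%06d", seq_along(seqs)), seqs, spec = spec)
  ev <- classify_windows(w, constraint)
  ev[[paste0("fits_", tier)]]
}

# Background windows, optionally rejection-sampled so none fits `reject_tier`.
background_windows <- function(n, spec, probs, markov = NULL,
                               reject_tier = NULL,
                               constraint = pair_constraint()) {
  len <- spec$upstream + spec$downstream
  seqs <- random_sequences(n, len, probs, markov)
  if (!is.null(reject_tier)) {
    repeat {
      bad <- which_fit(seqs, reject_tier, constraint, spec)
      if (!any(bad)) break
      seqs[bad] <- random_sequences(sum(bad), len, probs, markov)
    }
  }
  seqs
}

# Background windows with no canonical site at all (planting substrate).
clean_windows <- function(n, spec, probs, markov = NULL) {
  len <- spec$upstream + spec$downstream
  seqs <- random_sequences(n, len, probs, markov)
  repeat {
    ncanon <- vapply(seqs, function(s) length(canonical_offsets(s)), 0L,
                     USE.NAMES = FALSE)
    if (all(ncanon == 0L)) break
    seqs[ncanon > 0L] <- random_sequences(sum(ncanon > 0L), len, probs, markov)
  }
  seqs
}

#' Generate a promoter set with an exact number of planted model instances
#'
#' Builds `n` promoter windows of which exactly `n_planted` carry a planted
#' site pair of the given tier (distances sampled uniformly from the
#' constraint range); the remaining windows are background, rejection-sampled
#' so that none fits the tier by chance (set `exact = FALSE` to keep raw
#' background). Used to construct training sets with a prescribed
#' contingency surface.
#'
#' @param n Number of promoters.
#' @param n_planted Number of planted promoters.
#' @param tier Planted tier.
#' @param seed Integer seed.
#' @param constraint A [pair_constraint()].
#' @param spec A [window_spec()].
#' @param base_probs Background base probabilities.
#' @param markov Optional transition matrix.
#' @param exact Reject background windows fitting the tier (default TRUE).
#' @param prefix Gene-symbol prefix.
#' @return A list with `windows` (window tibble) and `truth` (tibble with
#'   `gene_symbol`, `planted`, `offset_a`, `offset_b`, `distance`).
#' @export
gen_promoter_set <- function(n, n_planted, tier = "ppm", seed = 1L,
                             constraint = pair_constraint(),
                             spec = window_spec(),
                             base_probs = rep(0.25, 4), markov = NULL,
                             exact = TRUE, prefix = "P") {
  stopifnot(n_planted <= n)
  withr::with_seed(seed, {
    planted_seqs <- clean_windows(n_planted, spec, base_probs, markov)
    distances <- sample(seq(constraint$min_distance, constraint$max_distance),
                        n_planted, replace = TRUE)
    res <- purrr::map2(planted_seqs, distances, function(s, d) {
      plant_ppm_instance(s, tier, d)
    })
    bg <- background_windows(n - n_planted, spec, base_probs, markov,
                             reject_tier = if (exact) tier else NULL,
                             constraint = constraint)
    seqs <- c(vapply(res, `[[`, "", "sequence"), bg)
    symbols <- sprintf("%s%05d", prefix, seq_len(n))
    windows <- promoter_windows(symbols, seqs, spec = spec)
    truth <- tibble::tibble(
      gene_symbol = symbols,
      planted = c(rep(TRUE, n_planted), rep(FALSE, n - n_planted)),
      offset_a = c(vapply(res, function(p) p$offsets[1L], 0L),
                   rep(NA_integer_, n - n_planted)),
      offset_b = c(vapply(res, function(p) p$offsets[2L], 0L),
                   rep(NA_integer_, n - n_planted)),
      distance = c(distances, rep(NA_integer_, n - n_planted))
    )
    list(windows = windows, truth = truth)
  })
}

# Draw the planted-gene layout for species A: which genes are pair-planted,
# which carry multi-site clusters, which are conserved.
plan_planted <- function(cfg) {
  idx <- sample.int(cfg$n_genes, cfg$n_planted)
  tibble::tibble(
    gene_idx = idx,
    kind = c(rep("cooccur", cfg$n_cooccur), rep("pair", cfg$n_pairs)),
    conserved = c(rep(FALSE, cfg$n_cooccur),
                  seq_len(cfg$n_pairs) <= cfg$n_conserved)
  )
}

# Gaps for a planted multi-site cluster: three-site promoters get two gaps in
# [96, 120] (two admissible pairs, the outer span exceeding the maximum
# distance); the four-site promoter gets gaps (100, 100, 100) (three pairs).
cluster_gaps <- function(i, constraint) {
  if (i == 1L) c(100L, 100L, 100L) else sample(96:120, 2L, replace = TRUE)
}

build_species <- function(cfg, plan, symbols, tx_prefix) {
  n <- cfg$n_genes
  spec <- cfg$spec
  up <- spec$upstream; down <- spec$downstream
  win_len <- up + down
  contigs <- random_sequences(n, cfg$contig_len, cfg$base_probs, cfg$markov)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  lo <- max(down, up + 1L)
  hi <- cfg$contig_len - max(down, up + 1L)
  tss <- sample(seq(lo, hi), n, replace = TRUE)
  get_window <- function(i) {
    if (strand[i] == "+") {
      substr(contigs[i], tss[i] - up, tss[i] + down - 1L)
    } else {
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(
        substr(contigs[i], tss[i] - down + 1L, tss[i] + up)
      )))
    }
  }
  set_window <- function(i, w) {
    if (strand[i] == "+") {
      substr(contigs[i], tss[i] - up, tss[i] + down - 1L) <<- w
    } else {
      substr(contigs[i], tss[i] - down + 1L, tss[i] + up) <<-
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(w)))
    }
  }
  truth <- tibble::tibble(
    gene_symbol = symbols, planted = FALSE, kind = NA_character_,
    conserved = FALSE, site_offsets = vector("list", n),
    pair_distances = vector("list", n)
  )
  # planted promoters start from a canonical-free window
  for (r in seq_len(nrow(plan))) {
    i <- plan$gene_idx[r]
    w <- clean_windows(1L, spec, cfg$base_probs, cfg$markov)
    if (plan$kind[r] == "pair") {
      d <- sample(seq(cfg$constraint$min_distance, cfg$constraint$max_distance),
                  1L)
      res <- plant_ppm_instance(w, cfg$planted_tier, d)
      dists <- d
    } else {
      gaps <- cluster_gaps(r, cfg$constraint)
      res <- plant_site_cluster(w, gaps)
      st <- res$offsets
      dd <- as.integer(utils::combn(st, 2L, function(p) abs(diff(p))))
      dists <- dd[dd >= cfg$constraint$min_distance &
                    dd <= cfg$constraint$max_distance]
    }
    set_window(i, res$sequence)
    truth$planted[i] <- TRUE
    truth$kind[i] <- plan$kind[r]
    truth$conserved[i] <- plan$conserved[r]
    truth$site_offsets[[i]] <- res$offsets
    truth$pair_distances[[i]] <- dists
  }
  # background promoters optionally rejection-sampled to keep truth exact
  if (cfg$background_fit_rejection) {
    bg_idx <- setdiff(seq_len(n), plan$gene_idx)
    repeat {
      ws <- vapply(bg_idx, get_window, "")
      bad <- which_fit(ws, cfg$planted_tier, cfg$constraint, spec)
      if (!any(bad)) break
      for (i in bg_idx[bad]) {
        set_window(i, random_sequences(1L, win_len, cfg$base_probs,
                                       cfg$markov))
      }
    }
  }
  contig_names <- sprintf("ctg_%s", symbols)
  genome <- Biostrings::DNAStringSet(stats::setNames(contigs, contig_names))
  # a twentieth of the genes get a redundant second transcript (same TSS)
  dup <- seq_len(n) %% 20L == 0L
  genes <- tibble::tibble(
    transcript_id = sprintf("%s%05d.1", tx_prefix, seq_len(n)),
    gene_symbol = symbols, contig = contig_names, strand = strand, tss = tss
  )
  genes2 <- genes[dup, ]
  genes2$transcript_id <- sub("\\.1$", ".2", genes2$transcript_id)
  genes <- dplyr::bind_rows(genes, genes2) |>
    dplyr::arrange(.data$gene_symbol, .data$transcript_id)
  list(genome = genome, genes = genes, truth = truth)
}

#' Generate a synthetic genome with planted target promoters
#'
#' One contig per gene; each TSS is placed so its promoter window fits inside
#' the contig. A configured fraction of promoters receives planted
#' binding-site structure (pair promoters and multi-site co-occurrence
#' promoters); the truth table records what was planted where. Fully
#' reproducible under `cfg$seed`.
#'
#' @param cfg A [synth_config()].
#' @return A list with `genome` (`DNAStringSet`), `genes` (transcript
#'   tibble), and `truth` (per-gene tibble with `planted`, `kind`
#'   (`"pair"`/`"cooccur"`), `conserved`, `site_offsets`, `pair_distances`).
#' @export
gen_genome_and_genes <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  withr::with_seed(cfg$seed, {
    plan <- plan_planted(cfg)
    symbols <- sprintf("Gene%05d", seq_len(cfg$n_genes))
    build_species(cfg, plan, symbols, tx_prefix = "tx")
  })
}

#' Generate the ortholog species' genome
#'
#' Builds a second synthetic genome whose gene symbols are the uppercased
#' orthologs of the first species'. The genes flagged `conserved` in `truth`
#' are planted again (pair promoters); `cfg$n_b_specific` additional genes,
#' orthologous to unplanted first-species genes, are planted only here
#' (species-specific noise for the conservation crossing).
#'
#' @param cfg A [synth_config()].
#' @param truth Truth tibble from [gen_genome_and_genes()].
#' @return A list with `genome`, `genes`, `truth` for the second species.
#' @export
gen_ortholog_genome <- function(cfg, truth) {
  stopifnot(inherits(cfg, "synth_config"))
  withr::with_seed(cfg$seed + 1L, {
    symbols_b <- toupper(truth$gene_symbol)
    conserved_idx <- which(truth$conserved)
    pool <- which(!truth$planted)
    specific_idx <- sample(pool, cfg$n_b_specific)
    idx <- c(conserved_idx, specific_idx)
    plan <- tibble::tibble(
      gene_idx = idx,
      kind = "pair",
      conserved = c(rep(TRUE, length(conserved_idx)),
                    rep(FALSE, length(specific_idx)))
    )
    build_species(cfg, plan, symbols_b, tx_prefix = "txb")
  })
}

#' Generate a differential-expression table matching the planted truth
#'
#' Assigns FDR values so that exactly `n_fdr01` genes fall below 0.01 and
#' `n_fdr1` below 0.1, with `planted_in_fdr01` planted pair genes in the
#' FDR<0.01 stratum, direction splits as configured, and fold changes of at
#' least 1.2 for significant genes.
#'
#' @param cfg A [synth_config()].
#' @param truth Truth tibble from [gen_genome_and_genes()].
#' @return A DE tibble (`gene_symbol`, `fold_change`, `direction`, `fdr`)
#'   covering every gene.
#' @export
gen_de_table <- function(cfg, truth) {
  stopifnot(inherits(cfg, "synth_config"))
  withr::with_seed(cfg$seed + 2L, {
    genes <- truth$gene_symbol
    n <- length(genes)
    planted_pairs <- truth$gene_symbol[truth$planted & truth$kind == "pair"]
    top_planted <- sample(planted_pairs, cfg$planted_in_fdr01)
    rest_pool <- setdiff(genes, top_planted)
    top_rest <- sample(rest_pool, cfg$n_fdr01 - cfg$planted_in_fdr01)
    fdr01 <- sample(c(top_planted, top_rest))
    mid_pool <- setdiff(genes, fdr01)
    mid <- sample(mid_pool, cfg$n_fdr1 - cfg$n_fdr01)
    others <- setdiff(genes, c(fdr01, mid))
    fdr <- stats::setNames(numeric(n), genes)
    fdr[fdr01] <- stats::runif(length(fdr01), 1e-5, 0.0099)
    fdr[mid] <- stats::runif(length(mid), 0.011, 0.099)
    fdr[others] <- stats::runif(length(others), 0.11, 0.999)
    dir <- stats::setNames(character(n), genes)
    dir[fdr01] <- sample(c(rep("up", cfg$n_up_fdr01),
                           rep("down", cfg$n_fdr01 - cfg$n_up_fdr01)))
    n_mid_up <- cfg$n_up_fdr1 - cfg$n_up_fdr01
    dir[mid] <- sample(c(rep("up", n_mid_up),
                         rep("down", length(mid) - n_mid_up)))
    dir[others] <- sample(c("up", "down"), length(others), replace = TRUE)
    fc <- stats::setNames(numeric(n), genes)
    sig <- c(fdr01, mid)
    fc[sig] <- stats::runif(length(sig), cfg$fc_range[1], cfg$fc_range[2])
    fc[others] <- stats::runif(length(others), 1, 1.19)
    tibble::tibble(gene_symbol = genes, fold_change = unname(fc[genes]),
                   direction = unname(dir[genes]), fdr = unname(fdr[genes]))
  })
}

#' Generate an ortholog map and a pathway gene set
#'
#' The ortholog map is a 1:1 symbol map (`symbol_b = toupper(symbol_a)`)
#' covering `ortholog_fraction` of genes and always including the conserved
#' planted genes. The pathway contains `n_pathway_planted` planted
#' co-occurrence genes plus filler symbols (universe members outside the
#' synthetic genome) up to `pathway_size`.
#'
#' @param cfg A [synth_config()].
#' @param truth Truth tibble from [gen_genome_and_genes()].
#' @return A list with `orthologs` (tibble `symbol_a`, `symbol_b`),
#'   `pathway` (tibble `pathway_id`, `gene_symbol`) and `universe_size`.
#' @export
gen_orthologs_and_pathways <- function(cfg, truth) {
  stopifnot(inherits(cfg, "synth_config"))
  withr::with_seed(cfg$seed + 3L, {
    genes <- truth$gene_symbol
    n_map <- round(cfg$ortholog_fraction * length(genes))
    mapped <- union(truth$gene_symbol[truth$conserved],
                    sample(genes, n_map))
    orthologs <- tibble::tibble(symbol_a = sort(mapped),
                                symbol_b = toupper(sort(mapped)))
    cooccur <- truth$gene_symbol[truth$planted & truth$kind == "cooccur"]
    in_path <- sample(cooccur, cfg$n_pathway_planted)
    filler <- sprintf("UniverseGene%05d",
                      seq_len(cfg$pathway_size - cfg$n_pathway_planted))
    pathway <- tibble::tibble(
      pathway_id = "path04360",
      gene_symbol = c(sort(in_path), filler)
    )
    list(orthologs = orthologs, pathway = pathway,
         universe_size = cfg$universe_size)
  })
}
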