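mk_hits <- function(offsets, motif = "canonical") {
  tibble::tibble(
    window_id = "w", gene_symbol = "g", motif = motif,
    orientation = "forward", offset = as.integer(offsets),
    length = ifelse(motif == "canonical", 6L, 4L),
    signed_start = offset_to_signed(as.integer(offsets))
  )
}

test_that("pair enumeration honours the distance bounds", {
  expect_equal(nrow(enumerate_admissible_pairs(mk_hits(c(10, 120)))), 1L)
  expect_equal(enumerate_admissible_pairs(mk_hits(c(10, 120)))$distance, 110L)
  expect_equal(nrow(enumerate_admissible_pairs(mk_hits(c(10, 60)))), 0L)
  expect_equal(nrow(enumerate_admissible_pairs(mk_hits(c(10, 250)))), 0L)
  # boundary inclusivity
  expect_equal(nrow(enumerate_admissible_pairs(mk_hits(c(0, 90)))), 1L)
  expect_equal(nrow(enumerate_admissible_pairs(mk_hits(c(0, 190)))), 1L)
  expect_equal(nrow(enumerate_admissible_pairs(mk_hits(c(0, 89)))), 0L)
  expect_equal(nrow(enumerate_admissible_pairs(mk_hits(c(0, 191)))), 0L)
})

test_that("pair enumeration handles equally spaced site triples", {
  p3 <- enumerate_admissible_pairs(mk_hits(c(0, 96, 186)))
  expect_equal(nrow(p3), 3L)
  expect_equal(p3[, c("offset_a", "offset_b")],
               tibble::tibble(offset_a = c(0L, 0L, 96L),
                              offset_b = c(96L, 186L, 186L)))
  # equally spaced at 96 nt: the outer pair spans 192 > 190 and drops out
  expect_equal(nrow(enumerate_admissible_pairs(mk_hits(c(0, 96, 192)))), 2L)
  p2 <- enumerate_admissible_pairs(mk_hits(c(0, 100, 200)))
  expect_equal(nrow(p2), 2L)  # the 0-200 pair exceeds the maximum distance
  expect_error(enumerate_admissible_pairs(mk_hits(c(120, 10))), "sorted")
})

test_that("pair enumeration equals a brute-force double loop on random sets", {
  set.seed(99)
  for (i in 1:300) {
    k <- sample(0:8, 1)
    offsets <- sort(sample(0:444, k))
    got <- nrow(enumerate_admissible_pairs(mk_hits(offsets)))
    expect_equal(got, oracle_pair_count(offsets))
  }
})

test_that("gap measure shortens distances by the upstream motif length", {
  cons <- pair_constraint(90, 190, measure = "gap")
  # start-to-start 96 => gap 90 for a 6-nt motif
  expect_equal(enumerate_admissible_pairs(mk_hits(c(0, 96)), cons)$distance,
               90L)
  expect_equal(nrow(enumerate_admissible_pairs(mk_hits(c(0, 95)), cons)), 0L)
})

test_that("LS/VLS pairs use standalone cores and tiers nest", {
  # canonical + distant standalone core: LS but not PPM
  w_ls <- promoter_windows("g", window_with(site("CAAGTG", 50),
                                            site("CAAG", 150)))
  ev <- classify_windows(w_ls)
  expect_false(ev$fits_ppm)
  expect_true(ev$fits_ls)
  expect_true(ev$fits_vls)
  expect_equal(ev$canonical_sites, 1L)
  expect_equal(ev$core_sites, 1L)

  # two canonicals: their core prefixes are NOT standalone, yet the window
  # still fits every tier (cumulative composition)
  w_ppm <- promoter_windows("g", window_with(site("CAAGTG", 50),
                                             site("CACTTG", 190)))
  ev2 <- classify_windows(w_ppm)
  expect_equal(ev2$core_sites, 0L)
  expect_true(all(c(ev2$fits_ppm, ev2$fits_ls, ev2$fits_vls)))
  expect_equal(ev2$n_pairs_ppm, 1L)
  expect_equal(ev2$n_pairs_ls, 1L)

  # two standalone cores: VLS only
  w_vls <- promoter_windows("g", window_with(site("CAAG", 50),
                                             site("CTTG", 150)))
  ev3 <- classify_windows(w_vls)
  expect_false(ev3$fits_ppm)
  expect_false(ev3$fits_ls)
  expect_true(ev3$fits_vls)

  expect_false(any(unlist(classify_windows(
    promoter_windows("g", strrep("A", 450)))[c("fits_ppm", "fits_ls",
                                               "fits_vls")])))
})

test_that("tier monotonicity holds on random and planted windows", {
  set.seed(2024)
  probs <- c(A = 0.3, C = 0.2, G = 0.3, T = 0.2)
  seqs <- replicate(400, random_window(450, probs))
  planted <- vapply(1:50, function(i) {
    plant_ppm_instance(random_window(450), sample(c("ppm", "ls", "vls"), 1),
                       sample(90:190, 1))$sequence
  }, "")
  w <- promoter_windows(sprintf("g%03d", 1:450), c(seqs, planted))
  ev <- classify_windows(w)
  expect_true(all(!ev$fits_ppm | ev$fits_ls))
  expect_true(all(!ev$fits_ls | ev$fits_vls))
  expect_true(all(ev$n_pairs_ppm <= ev$n_pairs_ls))
  expect_true(all(ev$n_pairs_ls <= ev$n_pairs_vls))
})

test_that("canonical pair distances are invariant under reverse complementation", {
  # start-to-start distances of equal-length site pairs are strand-symmetric;
  # mixed-length (canonical+core) pairs shift by the 2-nt length difference,
  # so the invariance is asserted for the homotypic canonical pairs the model
  # is built on
  set.seed(5)
  for (i in 1:20) {
    s <- plant_ppm_instance(random_window(450), "ppm",
                            sample(90:190, 1))$sequence
    p1 <- classify_windows(promoter_windows("g", s))$pairs[[1]]
    p2 <- classify_windows(promoter_windows("g",
                                            oracle_revcomp(s)))$pairs[[1]]
    expect_setequal(p1$distance[p1$site_type_a == "canonical" &
                                  p1$site_type_b == "canonical"],
                    p2$distance[p2$site_type_a == "canonical" &
                                  p2$site_type_b == "canonical"])
  }
})

test_that("motif histograms bin windows at 0 / 1 / >=2 canonical motifs", {
  set.seed(31)
  zero <- replicate(24, strrep("T", 450))
  one <- vapply(1:3, function(i) window_with(site("CAAGTG", 40 * i)), "")
  two <- vapply(1:3, function(i) {
    window_with(site("CAAGTG", 20), site("CACTTG", 150 + i))
  }, "")
  w <- promoter_windows(sprintf("g%02d", 1:30), c(zero, one, two))
  h <- motif_count_histogram(w)
  expect_equal(h$n_windows, c(24L, 3L, 3L))
  expect_equal(sum(h$n_windows), nrow(w))
  expect_equal(motif_count_histogram(w[0, ])$n_windows, c(0L, 0L, 0L))
  five <- promoter_windows(sprintf("h%d", 1:5), rep(two[1], 5))
  expect_equal(motif_count_histogram(five)$n_windows, c(0L, 0L, 5L))
})

test_that("distance ranges derive by rounding out to the granularity", {
  r <- derive_distance_range(c(93, 131, 187))
  expect_equal(c(r$min_distance, r$max_distance), c(90L, 190L))
  r2 <- derive_distance_range(100)
  expect_equal(c(r2$min_distance, r2$max_distance), c(100L, 100L))
  r3 <- derive_distance_range(95, granularity = 1)
  expect_equal(c(r3$min_distance, r3$max_distance), c(95L, 95L))
  expect_error(derive_distance_range(numeric(0)), "at least one")
  expect_error(derive_distance_range(c(100, -5)), "positive")
})

test_that("maximal simultaneous pair counts match the worked combinatorics", {
  expect_equal(max_simultaneous_pairs(1), 0L)
  expect_equal(max_simultaneous_pairs(2), 1L)
  expect_equal(max_simultaneous_pairs(3), 3L)
  expect_equal(max_simultaneous_pairs(4), 5L)
  expect_error(max_simultaneous_pairs(80), "cannot fit|k <= 6")
  expect_error(max_simultaneous_pairs(3, window_len = 10), "cannot fit")
})

test_that("max pairs is bounded by C(k,2), tight iff (k-1)*min <= max", {
  for (k in 2:5) {
    for (cons in list(pair_constraint(90, 190), pair_constraint(10, 100),
                      pair_constraint(50, 60))) {
      got <- max_simultaneous_pairs(k, cons)
      expect_lte(got, choose(k, 2))
      if ((k - 1) * cons$min_distance <= cons$max_distance) {
        expect_equal(got, choose(k, 2))
      } else {
        expect_lt(got, choose(k, 2))
      }
    }
  }
})

test_that("planted clusters realise the claimed pair counts", {
  set.seed(77)
  base <- strrep("T", 450)  # motif-free substrate: planted truth is exact
  # consecutive 90-nt gaps realise the maximal five pairs for four sites
  r <- plant_site_cluster(base, gaps = c(90, 90, 90))
  ev <- classify_windows(promoter_windows("g", r$sequence))
  expect_equal(ev$n_pairs_ppm, 5L)
  # 96-nt gaps push the span of non-adjacent neighbours past 190: three pairs
  r2 <- plant_site_cluster(base, gaps = c(96, 96, 96))
  ev2 <- classify_windows(promoter_windows("g", r2$sequence))
  expect_equal(ev2$n_pairs_ppm, 3L)
})
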