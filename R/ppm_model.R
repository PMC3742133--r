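#' Spacing constraint for homotypic site pairs
#'
#' A pair of binding sites is admissible when the distance between the
#' 5'-most bases of the two hits (in window orientation) lies in
#' `[min_distance, max_distance]`. The default range 90–190 nt is the
#' framework derived from the two-motif promoters of the positive training
#' set. The measure is configurable for sensitivity analysis:
#' `"start"` (start-to-start, default) or `"gap"` (end of the upstream hit to
#' start of the downstream hit).
#'
#' @param min_distance,max_distance Distance bounds in nt.
#' @param measure `"start"` or `"gap"`.
#' @return A `pair_constraint` list.
#' @export
pair_constraint <- function(min_distance = 90L, max_distance = 190L,
                            measure = c("start", "gap")) {
  measure <- match.arg(measure)
  min_distance <- as.integer(min_distance)
  max_distance <- as.integer(max_distance)
  if (is.na(min_distance) || is.na(max_distance) || min_distance <= 0L ||
      min_distance > max_distance) {
    stop("need 0 < min_distance <= max_distance", call. = FALSE)
  }
  structure(list(min_distance = min_distance, max_distance = max_distance,
                 measure = measure),
            class = "pair_constraint")
}

#' Predictive promoter model definition
#'
#' A PPM tier is defined by the motif composition of a qualifying site pair:
#' `"ppm"` requires two canonical sites, `"ls"` (low-specificity) at least
#' one canonical site (the other may be a standalone core `CAAG`), and
#' `"vls"` (very-low-specificity) any two sites. A window fits a tier when it
#' carries at least `min_pairs` admissible pairs of that tier's composition.
#'
#' @param tier `"ppm"`, `"ls"` or `"vls"`.
#' @param spec A [window_spec()].
#' @param constraint A [pair_constraint()].
#' @param min_pairs Minimum number of qualifying admissible pairs (default 1).
#' @return A `ppm_definition` list.
#' @export
ppm_definition <- function(tier = c("ppm", "ls", "vls"),
                           spec = window_spec(),
                           constraint = pair_constraint(),
                           min_pairs = 1L) {
  tier <- match.arg(tier)
  min_pairs <- as.integer(min_pairs)
  if (is.na(min_pairs) || min_pairs < 1L) {
    stop("min_pairs must be >= 1", call. = FALSE)
  }
  stopifnot(inherits(spec, "window_spec"), inherits(constraint, "pair_constraint"))
  structure(list(tier = tier, spec = spec, constraint = constraint,
                 min_pairs = min_pairs),
            class = "ppm_definition")
}

pair_distance <- function(offset_a, length_a, offset_b, constraint) {
  if (constraint$measure == "start") offset_b - offset_a
  else offset_b - (offset_a + length_a)
}

# Collapse raw hits into physical sites: canonical hits plus "standalone"
# core hits, i.e. cores whose span does not overlap any canonical hit's span
# (a canonical CAAGTG necessarily contains a core CAAG; counting both would
# let one physical site serve as two pair members).
collapse_sites <- function(hits) {
  if (nrow(hits) == 0L) {
    return(dplyr::mutate(hits, site_type = character(0)))
  }
  canon <- dplyr::filter(hits, .data$motif == "canonical")
  core <- dplyr::filter(hits, .data$motif != "canonical")
  if (nrow(core) > 0L && nrow(canon) > 0L) {
    ov <- dplyr::inner_join(
      dplyr::transmute(core, .data$window_id,
                       o = .data$offset, ol = .data$length,
                       .row = dplyr::row_number()),
      dplyr::transmute(canon, .data$window_id,
                       c = .data$offset, cl = .data$length),
      by = "window_id", relationship = "many-to-many"
    ) |>
      dplyr::filter(.data$o < .data$c + .data$cl, .data$c < .data$o + .data$ol)
    core <- core[setdiff(seq_len(nrow(core)), unique(ov$.row)), ]
  }
  dplyr::bind_rows(
    dplyr::mutate(canon, site_type = "canonical"),
    dplyr::mutate(core, site_type = "core")
  ) |>
    dplyr::arrange(.data$window_id, .data$offset)
}

# All admissible site pairs for a multi-window hit table, with tier flags.
pairs_for_windows <- function(hits, constraint = pair_constraint()) {
  sites <- collapse_sites(hits)
  empty <- tibble::tibble(
    window_id = character(), gene_symbol = character(),
    offset_a = integer(), offset_b = integer(),
    motif_a = character(), motif_b = character(),
    site_type_a = character(), site_type_b = character(),
    distance = integer(),
    is_ppm = logical(), is_ls = logical(), is_vls = logical()
  )
  if (nrow(sites) < 2L) return(empty)
  a <- dplyr::transmute(sites, .data$window_id, .data$gene_symbol,
                        offset_a = .data$offset, length_a = .data$length,
                        motif_a = .data$motif, site_type_a = .data$site_type)
  b <- dplyr::transmute(sites, .data$window_id,
                        offset_b = .data$offset, motif_b = .data$motif,
                        site_type_b = .data$site_type)
  pr <- dplyr::inner_join(a, b, by = "window_id",
                          relationship = "many-to-many") |>
    dplyr::filter(.data$offset_b > .data$offset_a) |>
    dplyr::mutate(
      distance = pair_distance(.data$offset_a, .data$length_a,
                               .data$offset_b, constraint)
    ) |>
    dplyr::filter(.data$distance >= constraint$min_distance,
                  .data$distance <= constraint$max_distance) |>
    dplyr::mutate(
      is_ppm = .data$site_type_a == "canonical" &
        .data$site_type_b == "canonical",
      is_ls = .data$site_type_a == "canonical" |
        .data$site_type_b == "canonical",
      is_vls = TRUE
    ) |>
    dplyr::arrange(.data$window_id, .data$offset_a, .data$offset_b) |>
    dplyr::select(-"length_a")
  if (nrow(pr) == 0L) empty else pr
}

#' Enumerate admissible site pairs in one window's hits
#'
#' Takes a hit tibble (as from [scan_windows()], sorted by `offset`) for a
#' single window, collapses hits to physical sites (canonical hits plus
#' cores not overlapping any canonical span), and returns every unordered
#' site pair whose spacing satisfies `constraint` and whose composition
#' matches `tier` (`"ppm"`: both canonical; `"ls"`: at least one canonical;
#' `"vls"`: any two sites). Orientation never filters. Tiers are cumulative,
#' so the pair sets nest: ppm ⊆ ls ⊆ vls.
#'
#' @param hits Hit tibble for one window, sorted by `offset`.
#' @param constraint A [pair_constraint()].
#' @param tier `"ppm"`, `"ls"` or `"vls"`.
#' @return Tibble of pairs sorted by `(offset_a, offset_b)` with the two
#'   sites' offsets, motifs, and the `distance`.
#' @export
enumerate_admissible_pairs <- function(hits, constraint = pair_constraint(),
                                       tier = c("ppm", "ls", "vls")) {
  tier <- match.arg(tier)
  if (nrow(hits) > 0L) {
    if (length(unique(hits$window_id)) > 1L) {
      stop("hits must come from a single window", call. = FALSE)
    }
    if (is.unsorted(hits$offset)) {
      stop("hits must be sorted by offset", call. = FALSE)
    }
  }
  pr <- pairs_for_windows(hits, constraint)
  keep <- switch(tier, ppm = pr$is_ppm, ls = pr$is_ls, vls = pr$is_vls)
  dplyr::select(pr[keep, ], "window_id", "gene_symbol", "offset_a",
                "offset_b", "motif_a", "motif_b", "site_type_a",
                "site_type_b", "distance")
}

#' Classify promoter windows against the PPM tiers
#'
#' Scans each window for canonical and core motifs, enumerates admissible
#' pairs under the spacing constraint, and reports per-window evidence for
#' all three tiers. Because tier composition rules are cumulative, the fits
#' are monotone: `fits_ppm` implies `fits_ls` implies `fits_vls`.
#'
#' @param windows A window tibble.
#' @param constraint A [pair_constraint()].
#' @param min_pairs Minimum number of qualifying pairs for a window to fit a
#'   tier (default 1).
#' @return A tibble with one row per window: hit/site counts
#'   (`canonical_sites`, `core_sites` counts standalone cores only), pair
#'   counts and logical fits per tier, and a `pairs` list column holding each
#'   window's admissible pair table.
#' @export
classify_windows <- function(windows, constraint = pair_constraint(),
                             min_pairs = 1L) {
  min_pairs <- as.integer(min_pairs)
  hits <- scan_windows(windows, c("canonical", "core"))
  sites <- collapse_sites(hits)
  pr <- pairs_for_windows(hits, constraint)
  site_counts <- sites |>
    dplyr::count(.data$window_id, .data$site_type) |>
    tidyr::pivot_wider(names_from = "site_type", values_from = "n",
                       values_fill = 0L)
  for (col in c("canonical", "core")) {
    if (!col %in% names(site_counts)) site_counts[[col]] <- 0L
  }
  pair_counts <- pr |>
    dplyr::group_by(.data$window_id) |>
    dplyr::summarise(n_pairs_ppm = sum(.data$is_ppm),
                     n_pairs_ls = sum(.data$is_ls),
                     n_pairs_vls = sum(.data$is_vls), .groups = "drop")
  pair_split <- split(
    dplyr::select(pr, "offset_a", "offset_b", "motif_a", "motif_b",
                  "site_type_a", "site_type_b", "distance"),
    factor(pr$window_id, levels = windows$window_id)
  )
  out <- windows |>
    dplyr::select("window_id", "gene_symbol", "transcript_ids") |>
    dplyr::left_join(dplyr::select(site_counts, "window_id",
                                   canonical_sites = "canonical",
                                   core_sites = "core"),
                     by = "window_id") |>
    dplyr::left_join(pair_counts, by = "window_id") |>
    dplyr::mutate(
      dplyr::across(c("canonical_sites", "core_sites", "n_pairs_ppm",
                      "n_pairs_ls", "n_pairs_vls"),
                    ~ tidyr::replace_na(as.integer(.x), 0L)),
      fits_ppm = .data$n_pairs_ppm >= min_pairs,
      fits_ls = .data$n_pairs_ls >= min_pairs,
      fits_vls = .data$n_pairs_vls >= min_pairs,
      pairs = unname(pair_split[.data$window_id])
    )
  out
}

#' Count canonical motifs per window, binned 0 / 1 / >=2
#'
#' @param windows A window tibble.
#' @return A tibble with columns `motif_count` (`"0"`, `"1"`, `">=2"`) and
#'   `n_windows`; the counts sum to `nrow(windows)`.
#' @export
motif_count_histogram <- function(windows) {
  hits <- scan_windows(windows, "canonical")
  n <- stats::setNames(integer(nrow(windows)), windows$window_id)
  tab <- table(hits$window_id)
  n[names(tab)] <- as.integer(tab)
  bin <- cut(n, breaks = c(-0.5, 0.5, 1.5, Inf), labels = c("0", "1", ">=2"))
  tibble::tibble(
    motif_count = c("0", "1", ">=2"),
    n_windows = as.integer(table(bin)[c("0", "1", ">=2")])
  )
}

#' Derive a spacing constraint from observed pair distances
#'
#' Rounds the observed minimum down and the maximum up to the given
#' granularity, the procedure that turns the two-motif training promoters'
#' distances into the 90–190 nt framework.
#'
#' @param distances Positive pair distances (nt).
#' @param granularity Rounding granularity in nt (default 10).
#' @param measure Passed to [pair_constraint()].
#' @return A [pair_constraint()].
#' @export
derive_distance_range <- function(distances, granularity = 10L,
                                  measure = "start") {
  if (length(distances) == 0L) {
    stop("need at least one observed distance", call. = FALSE)
  }
  if (any(distances <= 0)) stop("distances must be positive", call. = FALSE)
  g <- as.integer(granularity)
  pair_constraint(floor(min(distances) / g) * g,
                  ceiling(max(distances) / g) * g,
                  measure = measure)
}

# Feasibility of a system of difference constraints s_j - s_i <= c over k
# ordered starts (integer bounds => integral solutions): Floyd-Warshall
# negative-cycle detection.
diffcon_feasible <- function(k, edges) {
  d <- matrix(Inf, k, k)
  diag(d) <- 0
  for (e in seq_len(nrow(edges))) {
    i <- edges[e, 1L]; j <- edges[e, 2L]; c <- edges[e, 3L]
    if (c < d[i, j]) d[i, j] <- c
  }
  for (m in seq_len(k)) {
    d <- pmin(d, outer(d[, m], d[m, ], `+`))
  }
  all(diag(d) >= 0)
}

#' Maximum number of simultaneous admissible pairs for k sites
#'
#' Over all placements of `k` non-overlapping motif starts inside a window,
#' the maximum number of start pairs whose distance lies within the
#' constraint. With the default 90–190 nt range in a 450-nt window, three
#' sites can form three pairs and four sites at most five (the pair spanning
#' sites 1 and 4 is excluded by the maximum distance).
#'
#' The search enumerates subsets of the \eqn{\binom{k}{2}} candidate pairs
#' and checks each subset for realisability as an integer
#' difference-constraint system, which is exact: every placement's pair set
#' is such a subset, and every feasible subset is witnessed by a placement.
#'
#' @param k Number of motifs (1–6).
#' @param constraint A [pair_constraint()] (start-to-start measure).
#' @param window_len Window length in nt (default 450).
#' @param motif_len Motif length in nt (default 6).
#' @return Integer: the maximal simultaneous admissible pair count.
#' @export
max_simultaneous_pairs <- function(k, constraint = pair_constraint(),
                                   window_len = 450L, motif_len = 6L) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be a positive integer", call. = FALSE)
  if (k > 6L) stop("exhaustive subset search supports k <= 6", call. = FALSE)
  if (constraint$measure != "start") {
    stop("max_simultaneous_pairs uses the start-to-start measure",
         call. = FALSE)
  }
  if (k * motif_len > window_len) {
    stop(k, " non-overlapping motifs of length ", motif_len,
         " cannot fit in a ", window_len, "-nt window", call. = FALSE)
  }
  if (k == 1L) return(0L)
  base <- rbind(
    # spacing: s_{i+1} - s_i >= motif_len
    cbind(2:k, 1:(k - 1L), -motif_len),
    # window: s_k - s_1 <= window_len - motif_len
    c(1L, k, window_len - motif_len)
  )
  prs <- utils::combn(k, 2L)
  np <- ncol(prs)
  for (m in np:0L) {
    subs <- utils::combn(np, m)
    for (s in seq_len(ncol(subs))) {
      sel <- subs[, s]
      edges <- base
      if (length(sel)) {
        i <- prs[1L, sel]; j <- prs[2L, sel]
        edges <- rbind(edges,
                       cbind(i, j, constraint$max_distance),
                       cbind(j, i, -constraint$min_distance))
      }
      if (diffcon_feasible(k, edges)) return(as.integer(m))
    }
  }
  0L
}
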