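#' HMX1 binding-site motifs
#'
#' The canonical HMX1 binding site is `CAAGTG` (reverse complement `CACTTG`);
#' the minimal core motif, bound with lower affinity, is `CAAG` (`CTTG`).
#' `binding_motif()` builds a motif object from any forward string over
#' `ACGT`; `hmx_motif()` returns the two built-in tiers.
#'
#' @param name Motif name; for [hmx_motif()] one of `"canonical"`, `"core"`.
#' @param forward Forward-strand motif string (alphabet `ACGT`).
#' @return A `binding_motif` list with `name`, `forward`, `reverse`, `length`.
#' @export
binding_motif <- function(name, forward) {
  forward <- toupper(forward)
  if (!nzchar(forward) || grepl("[^ACGT]", forward)) {
    stop("motif must be a non-empty string over ACGT", call. = FALSE)
  }
  structure(
    list(
      name = name,
      forward = forward,
      reverse = as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(forward))
      ),
      length = nchar(forward)
    ),
    class = "binding_motif"
  )
}

#' @rdname binding_motif
#' @export
hmx_motif <- function(name = c("canonical", "core")) {
  name <- match.arg(name)
  binding_motif(name, switch(name, canonical = "CAAGTG", core = "CAAG"))
}

#' Find all exact occurrences of a pattern
#'
#' Returns every start offset (0-based, ascending) of `pattern` in
#' `sequence`, including overlapping occurrences. Matching is
#' case-insensitive; `N` in the sequence never matches.
#'
#' @param sequence A single nucleotide string.
#' @param pattern A non-empty pattern over `ACGT`.
#' @return Integer vector of 0-based start offsets.
#' @export
find_exact <- function(sequence, pattern) {
  if (length(pattern) != 1L || !nzchar(pattern)) {
    stop("pattern must be a single non-empty string", call. = FALSE)
  }
  pattern <- toupper(pattern)
  if (grepl("[^ACGT]", pattern)) {
    stop("pattern must be over ACGT", call. = FALSE)
  }
  sequence <- toupper(sequence)
  if (nchar(sequence) < nchar(pattern)) return(integer(0))
  m <- Biostrings::matchPattern(pattern, Biostrings::DNAString(sequence),
                                fixed = TRUE)
  as.integer(Biostrings::start(m)) - 1L
}

#' Scan promoter windows for a motif on both orientations
#'
#' Reports all exact occurrences of the forward and the reverse-complement
#' string of `motif` in each window. Orientation is recorded but is never
#' used downstream to filter pairs (the model disregards orientation).
#'
#' @param windows A window tibble (see [extract_windows()]), or a single
#'   sequence string.
#' @param motif A [binding_motif()] / [hmx_motif()], or one of `"canonical"`,
#'   `"core"`, or a character vector of those names to scan several motifs.
#' @return A tibble of hits with columns `window_id`, `gene_symbol`, `motif`,
#'   `orientation` (`forward`/`reverse`), `offset` (0-based start of the
#'   5'-most matched base), `length`, `signed_start` (signed promoter
#'   coordinate of the start). Hits are sorted by window, then `offset`,
#'   forward before reverse on ties.
#' @export
scan_windows <- function(windows, motif = "canonical") {
  if (is.character(windows)) {
    windows <- promoter_windows(
      gene_symbol = paste0("seq", seq_along(windows)),
      sequence = windows,
      spec = window_spec(1L, nchar(windows[1]) - 1L)
    )
  }
  motifs <- if (inherits(motif, "binding_motif")) list(motif) else {
    lapply(motif, hmx_motif)
  }
  subject <- Biostrings::DNAStringSet(toupper(windows$sequence))
  out <- purrr::map(motifs, function(mo) {
    purrr::map2(
      c("forward", "reverse"), c(mo$forward, mo$reverse),
      function(orient, pat) {
        mi <- Biostrings::vmatchPattern(pat, subject, fixed = TRUE)
        st <- Biostrings::startIndex(mi)
        n <- lengths(st)
        idx <- rep.int(seq_len(nrow(windows)), n)
        tibble::tibble(
          window_id = windows$window_id[idx],
          gene_symbol = windows$gene_symbol[idx],
          motif = mo$name,
          orientation = orient,
          offset = unlist(st, use.names = FALSE) - 1L,
          length = mo$length,
          .win = idx,
          .up = windows$upstream[idx]
        )
      }
    ) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  if (nrow(out) == 0L) {
    return(tibble::tibble(
      window_id = character(), gene_symbol = character(), motif = character(),
      orientation = character(), offset = integer(), length = integer(),
      signed_start = integer()
    ))
  }
  out |>
    dplyr::mutate(
      signed_start = offset_to_signed(.data$offset, .data$.up),
      .orient_rank = match(.data$orientation, c("forward", "reverse"))
    ) |>
    dplyr::arrange(.data$.win, .data$offset, .data$.orient_rank) |>
    dplyr::select("window_id", "gene_symbol", "motif", "orientation",
                  "offset", "length", "signed_start")
}

#' Export motif hits as BED
#'
#' Writes hits as 0-based half-open BED records. With
#' `coordinates = "window"`, the chromosome is the window id and start/end
#' are window offsets; with `"genomic"`, hits are mapped back to contig
#' coordinates via the window table (strand-aware).
#'
#' @param hits A hit tibble from [scan_windows()].
#' @param path Output path.
#' @param windows Window tibble; required for `coordinates = "genomic"`.
#' @param coordinates `"window"` or `"genomic"`.
#' @return `path`, invisibly.
#' @export
hits_to_bed <- function(hits, path, windows = NULL,
                        coordinates = c("window", "genomic")) {
  coordinates <- match.arg(coordinates)
  name <- paste(hits$motif, hits$orientation, sep = "/")
  if (coordinates == "window") {
    bed <- tibble::tibble(chrom = hits$window_id, start = hits$offset,
                          end = hits$offset + hits$length, name = name)
  } else {
    stopifnot(!is.null(windows))
    w <- windows[match(hits$window_id, windows$window_id), ]
    plus <- w$strand == "+"
    start0 <- ifelse(
      plus,
      (w$tss - w$upstream - 1L) + hits$offset,
      w$tss + w$upstream - hits$offset - hits$length
    )
    bed <- tibble::tibble(chrom = w$contig, start = start0,
                          end = start0 + hits$length, name = name)
  }
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
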