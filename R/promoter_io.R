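#' Read a genome from a FASTA file
#'
#' Reads a (possibly line-wrapped) multi-record FASTA into a named
#' [Biostrings::DNAStringSet], uppercased. Only the alphabet `ACGTN` is
#' accepted after normalisation; soft-masked (lower-case) bases are kept but
#' uppercased, so masking is ignored.
#'
#' @param path Path to a FASTA file.
#' @return A named `DNAStringSet`, one element per contig.
#' @export
read_genome <- function(path) {
  gs <- Biostrings::readDNAStringSet(path)
  names(gs) <- sub("\\s.*$", "", names(gs))
  as_genome(gs)
}

#' Coerce to a genome object
#'
#' Accepts a named character vector or a `DNAStringSet`; validates contig
#' names and the `ACGTN` alphabet and returns an uppercased `DNAStringSet`.
#'
#' @param x Named character vector of contig sequences, or a `DNAStringSet`.
#' @return A named `DNAStringSet`.
#' @export
as_genome <- function(x) {
  if (is.character(x)) {
    if (is.null(names(x)) || any(!nzchar(names(x)))) {
      stop("genome sequences must be named by contig", call. = FALSE)
    }
    if (any(grepl("[^ACGTN]", toupper(x)))) {
      stop("genome contains letters outside ACGTN", call. = FALSE)
    }
    x <- Biostrings::DNAStringSet(toupper(x))
  }
  if (!methods::is(x, "DNAStringSet")) {
    stop("genome must be a named character vector or a DNAStringSet",
         call. = FALSE)
  }
  if (anyDuplicated(names(x))) stop("duplicated contig names", call. = FALSE)
  if (any(Biostrings::width(x) == 0L)) {
    stop("empty contig sequence", call. = FALSE)
  }
  freq <- Biostrings::alphabetFrequency(x, collapse = TRUE)
  bad <- sum(freq) - sum(freq[c("A", "C", "G", "T", "N")])
  if (bad > 0L) {
    stop("genome contains letters outside ACGTN", call. = FALSE)
  }
  gs <- Biostrings::DNAStringSet(toupper(as.character(x)))
  names(gs) <- names(x)
  gs
}

#' Read a transcript (gene) table
#'
#' Reads a refGene-style TSV with header columns `transcript_id`,
#' `gene_symbol`, `contig`, `strand`, `tss` (extra columns are ignored).
#' `tss` is the 1-based genomic coordinate of the first transcribed base.
#'
#' @param path Path to a tab-separated file with a header row.
#' @return A tibble with one row per transcript, in file order.
#' @export
read_gene_table <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  needed <- c("transcript_id", "gene_symbol", "contig", "strand", "tss")
  missing <- setdiff(needed, names(tbl))
  if (length(missing)) {
    stop("gene table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tbl <- tbl[needed]
  # line numbers count the header as line 1
  line <- seq_len(nrow(tbl)) + 1L
  bad_strand <- !tbl$strand %in% c("+", "-")
  if (any(bad_strand)) {
    stop("invalid strand (must be + or -) on line(s): ",
         paste(line[bad_strand], collapse = ", "), call. = FALSE)
  }
  tss <- suppressWarnings(as.integer(tbl$tss))
  bad_tss <- is.na(tss) | tss < 1L
  if (any(bad_tss)) {
    stop("non-integer or non-positive tss on line(s): ",
         paste(line[bad_tss], collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(tbl$transcript_id)) {
    stop("duplicated transcript_id in gene table", call. = FALSE)
  }
  tibble::tibble(
    transcript_id = tbl$transcript_id,
    gene_symbol = tbl$gene_symbol,
    contig = tbl$contig,
    strand = tbl$strand,
    tss = tss
  )
}

#' Promoter window specification
#'
#' @param upstream Number of bases upstream of the TSS (positive; default 250).
#' @param downstream Number of bases from the TSS inclusive downstream
#'   (positive; default 200). The window covers signed promoter coordinates
#'   `-upstream..-1, +1..+downstream` (no position 0); `+1` is the TSS base.
#' @return A `window_spec` list with elements `upstream` and `downstream`.
#' @export
window_spec <- function(upstream = 250L, downstream = 200L) {
  upstream <- as.integer(upstream)
  downstream <- as.integer(downstream)
  if (is.na(upstream) || upstream < 1L || is.na(downstream) || downstream < 1L) {
    stop("upstream and downstream must be positive integers", call. = FALSE)
  }
  structure(list(upstream = upstream, downstream = downstream),
            class = "window_spec")
}

#' Convert 0-based window offsets to signed promoter coordinates
#'
#' Offsets `0..len-1` map bijectively onto `-upstream..-1, +1..+downstream`;
#' there is no position 0 and `+1` is the TSS base.
#'
#' @param offset Integer vector of 0-based window offsets.
#' @param upstream Upstream extent of the window.
#' @return Integer vector of signed coordinates.
#' @export
offset_to_signed <- function(offset, upstream = 250L) {
  offset <- as.integer(offset)
  ifelse(offset < upstream, offset - upstream, offset - upstream + 1L)
}

#' Convert signed promoter coordinates to 0-based window offsets
#'
#' Inverse of [offset_to_signed()]; signed coordinate 0 is invalid.
#'
#' @param signed Integer vector of signed promoter coordinates (no 0).
#' @param upstream Upstream extent of the window.
#' @return Integer vector of 0-based offsets.
#' @export
signed_to_offset <- function(signed, upstream = 250L) {
  signed <- as.integer(signed)
  if (any(signed == 0L, na.rm = TRUE)) {
    stop("signed promoter coordinates skip 0", call. = FALSE)
  }
  ifelse(signed < 0L, signed + upstream, signed + upstream - 1L)
}

#' Extract TSS-proximal promoter windows
#'
#' For each transcript, extracts the window covering signed coordinates
#' `[-upstream, +downstream]` around the TSS, written 5'->3' on the
#' transcription strand (minus-strand windows are reverse-complemented), so
#' the TSS base is always at 0-based offset `upstream`.
#'
#' @param genes Tibble of transcripts as returned by [read_gene_table()].
#' @param genome A genome as returned by [read_genome()] / [as_genome()], or
#'   a named character vector of contigs.
#' @param spec A [window_spec()].
#' @return A tibble of promoter windows with columns `window_id`,
#'   `gene_symbol`, `transcript_ids` (list column), `contig`, `strand`,
#'   `tss`, `sequence`, `upstream`, `downstream`.
#' @export
extract_windows <- function(genes, genome, spec = window_spec()) {
  stopifnot(inherits(spec, "window_spec"))
  genome <- as_genome(genome)
  up <- spec$upstream
  down <- spec$downstream
  unknown <- setdiff(unique(genes$contig), names(genome))
  if (length(unknown)) {
    stop("contig(s) not in genome: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  clen <- stats::setNames(Biostrings::width(genome), names(genome))[genes$contig]
  plus <- genes$strand == "+"
  start1 <- ifelse(plus, genes$tss - up, genes$tss - down + 1L)
  end1 <- ifelse(plus, genes$tss + down - 1L, genes$tss + up)
  over <- start1 < 1L | end1 > clen
  if (any(over)) {
    stop("window overhangs contig boundary for transcript(s): ",
         paste(genes$transcript_id[over], collapse = ", "), call. = FALSE)
  }
  seqs <- Biostrings::DNAStringSet(
    as.character(genome)[genes$contig],
    start = start1, end = end1
  )
  if (any(!plus)) {
    seqs[!plus] <- Biostrings::reverseComplement(seqs[!plus])
  }
  tibble::tibble(
    window_id = genes$transcript_id,
    gene_symbol = genes$gene_symbol,
    transcript_ids = as.list(genes$transcript_id),
    contig = genes$contig,
    strand = genes$strand,
    tss = genes$tss,
    sequence = unname(as.character(seqs)),
    upstream = up,
    downstream = down
  )
}

#' Build a window table directly from sequences
#'
#' Convenience constructor for promoter windows that do not come from a
#' genome (e.g. simulated sets). Sequences must all have length
#' `upstream + downstream`.
#'
#' @param gene_symbol Character vector of gene symbols.
#' @param sequence Character vector of window sequences (5'->3' on the
#'   transcription strand).
#' @param transcript_id Optional transcript ids (default `gene_symbol.1`).
#' @param spec A [window_spec()].
#' @return A window tibble as from [extract_windows()] (without genomic
#'   coordinates).
#' @export
promoter_windows <- function(gene_symbol, sequence, transcript_id = NULL,
                             spec = window_spec()) {
  sequence <- toupper(sequence)
  if (any(nchar(sequence) != spec$upstream + spec$downstream)) {
    stop("all sequences must have length upstream + downstream", call. = FALSE)
  }
  if (is.null(transcript_id)) transcript_id <- paste0(gene_symbol, ".1")
  tibble::tibble(
    window_id = transcript_id,
    gene_symbol = gene_symbol,
    transcript_ids = as.list(transcript_id),
    contig = NA_character_,
    strand = "+",
    tss = NA_integer_,
    sequence = sequence,
    upstream = spec$upstream,
    downstream = spec$downstream
  )
}

#' Discard redundant promoter windows
#'
#' Windows with identical `(gene_symbol, sequence)` — redundant promoters of
#' alternatively spliced transcripts sharing a TSS — are merged into one
#' record whose `transcript_ids` is the union (first-seen order). Distinct
#' sequences for the same gene (alternative promoters) are all kept.
#'
#' @param windows A window tibble.
#' @return A deduplicated window tibble, first-seen order preserved.
#' @export
dedupe_windows <- function(windows) {
  if (nrow(windows) == 0L) return(windows)
  windows |>
    dplyr::mutate(.ord = dplyr::row_number()) |>
    dplyr::group_by(.data$gene_symbol, .data$sequence) |>
    dplyr::summarise(
      window_id = .data$window_id[1L],
      transcript_ids = list(unique(unlist(.data$transcript_ids))),
      contig = .data$contig[1L],
      strand = .data$strand[1L],
      tss = .data$tss[1L],
      upstream = .data$upstream[1L],
      downstream = .data$downstream[1L],
      .ord = min(.data$.ord),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$.ord) |>
    dplyr::select("window_id", "gene_symbol", "transcript_ids", "contig",
                  "strand", "tss", "sequence", "upstream", "downstream")
}

#' Write promoter windows as FASTA
#'
#' Headers have the form `gene|tx1,tx2|-250..+200`.
#'
#' @param windows A window tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_windows_fasta <- function(windows, path) {
  hdr <- sprintf(
    "%s|%s|-%d..+%d",
    windows$gene_symbol,
    vapply(windows$transcript_ids, paste, "", collapse = ","),
    windows$upstream, windows$downstream
  )
  ss <- Biostrings::DNAStringSet(windows$sequence)
  names(ss) <- hdr
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
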