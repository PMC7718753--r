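# Genome and annotation input: FASTA reading with alphabet normalization,
# TSS extraction from GFF3/BED, and strand-aware promoter-window extraction.
# Internal coordinates are 0-based, half-open throughout; conversion to and
# from 1-based conventions happens only at format boundaries.

#' Read and normalize a genome FASTA file
#'
#' Reads a multi-record FASTA, uppercases every sequence, and normalizes the
#' alphabet to A/C/G/T/N: ambiguity codes (R, Y, S, W, K, M, B, D, H, V) are
#' mapped to N with a warning; any character outside the IUPAC nucleotide
#' alphabet is a hard error naming the contig and offset. Contig IDs are the
#' first whitespace-delimited token of each header and must be unique.
#'
#' @param path Path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet] over the A/C/G/T/N alphabet.
#' @export
read_genome_fasta <- function(path) {
  stopifnot(file.exists(path))
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("no sequences found in '", path, "'")
  ids <- sub("\\s.*$", "", names(raw))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate contig IDs in '", path, "': ",
         paste(unique(dup), collapse = ", "))
  }
  seqs <- toupper(as.character(raw))
  names(seqs) <- ids

  bad_at <- regexpr("[^ACGTNRYSWKMBDHV]", seqs)
  if (any(bad_at > 0L)) {
    i <- which(bad_at > 0L)[1]
    stop(sprintf(
      "contig '%s' contains non-IUPAC character '%s' at offset %d",
      ids[i], substr(seqs[i], bad_at[i], bad_at[i]), bad_at[i] - 1L))
  }
  amb_n <- vapply(gregexpr("[RYSWKMBDHV]", seqs), function(m) {
    if (m[1] == -1L) 0L else length(m)
  }, integer(1))
  if (any(amb_n > 0L)) {
    warning(sprintf(
      "mapped %d ambiguity bases to N (contigs: %s)", sum(amb_n),
      paste(ids[amb_n > 0L], collapse = ", ")), call. = FALSE)
    seqs <- chartr("RYSWKMBDHV", strrep("N", 10L), seqs)
  }
  Biostrings::DNAStringSet(seqs)
}

#' Extract transcription start sites from GFF3 or BED annotations
#'
#' Derives one TSS record per annotated feature. For GFF3 (1-based,
#' inclusive) the TSS of a `+` feature is `start - 1` and of a `-` feature
#' `end - 1` in 0-based coordinates; only `feature_types` rows are used and
#' the gene ID is taken from the `ID` attribute, falling back to `Name`.
#' For BED (0-based, half-open) the TSS is `start` for `+` and `end - 1`
#' for `-`, with the name column as gene ID. Records with missing strand
#' are skipped with a warning; exact duplicates of
#' (gene, contig, strand, position) are collapsed, while distinct TSSs of
#' one gene are kept as separate records.
#'
#' @param path Annotation file path.
#' @param format `"gff3"` or `"bed"`.
#' @param feature_types GFF3 feature types to use (default `"gene"`);
#'   ignored for BED.
#' @param genome Optional [Biostrings::DNAStringSet]; when given, TSS
#'   positions outside their contig are a hard error.
#' @return A data.frame with columns `gene_id`, `contig_id`, `gene_strand`
#'   (`"+"`/`"-"`) and `tss_pos` (0-based index of the first transcribed
#'   base).
#' @export
read_tss <- function(path, format = c("gff3", "bed"),
                     feature_types = "gene", genome = NULL) {
  format <- match.arg(format)
  stopifnot(file.exists(path))
  gr <- rtracklayer::import(path, format = if (format == "gff3") "GFF3" else "BED")

  if (format == "gff3") {
    gr <- gr[as.character(gr$type) %in% feature_types]
    ids <- as.character(gr$ID)
    if ("Name" %in% names(S4Vectors::mcols(gr))) {
      nm <- as.character(gr$Name)
      ids[is.na(ids) | !nzchar(ids)] <- nm[is.na(ids) | !nzchar(ids)]
    }
  } else {
    ids <- if ("name" %in% names(S4Vectors::mcols(gr))) {
      as.character(gr$name)
    } else {
      rep(NA_character_, length(gr))
    }
  }
  no_id <- is.na(ids) | !nzchar(ids)
  if (any(no_id)) {
    warning(sum(no_id), " record(s) without an ID/name skipped",
            call. = FALSE)
    gr <- gr[!no_id]; ids <- ids[!no_id]
  }

  strands <- as.character(BiocGenerics::strand(gr))
  unstranded <- !strands %in% c("+", "-")
  if (any(unstranded)) {
    warning(sum(unstranded), " record(s) with missing strand skipped",
            call. = FALSE)
    gr <- gr[!unstranded]; ids <- ids[!unstranded]
    strands <- strands[!unstranded]
  }

  # rtracklayer returns 1-based inclusive GRanges for both formats, so the
  # same arithmetic yields the 0-based TSS for either input convention.
  tss_pos <- ifelse(strands == "+",
                    BiocGenerics::start(gr) - 1L,
                    BiocGenerics::end(gr) - 1L)
  out <- data.frame(
    gene_id = ids,
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    gene_strand = strands,
    tss_pos = as.integer(tss_pos),
    stringsAsFactors = FALSE
  )
  out <- unique(out)
  rownames(out) <- NULL

  if (!is.null(genome)) {
    lens <- stats::setNames(Biostrings::width(genome), names(genome))
    missing_ctg <- setdiff(out$contig_id, names(lens))
    if (length(missing_ctg) > 0L) {
      stop("annotation references unknown contig(s): ",
           paste(missing_ctg, collapse = ", "))
    }
    off <- out$tss_pos < 0L | out$tss_pos >= lens[out$contig_id]
    if (any(off)) {
      stop("TSS position outside contig for gene(s): ",
           paste(out$gene_id[off], collapse = ", "))
    }
  }
  out
}

#' Write TSS records as BED6
#'
#' Each TSS becomes a 1-bp BED interval whose start (for `+`) or `end - 1`
#' (for `-`) is the TSS, so [read_tss()] on the written file round-trips
#' the records exactly.
#'
#' @param tss Data.frame as returned by [read_tss()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tss_bed <- function(tss, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = tss$contig_id,
    ranges = IRanges::IRanges(start = tss$tss_pos + 1L, width = 1L),
    strand = tss$gene_strand,
    name = tss$gene_id,
    score = 0L
  )
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Extract the promoter scan window around a TSS
#'
#' Returns the contig subsequence covering `upstream_bp` bases upstream to
#' `downstream_bp` bases downstream of the TSS in the direction of
#' transcription, widened by `margin_bp` on both sides so protospacers
#' straddling the nominal boundary are still found. The sequence is always
#' returned in contig (`+`) orientation; for `-` strand genes the window is
#' mirrored in contig coordinates. Windows are clipped at contig edges with
#' `truncated = TRUE`; a window entirely off the contig yields an empty
#' sequence with a warning.
#'
#' @param genome Named [Biostrings::DNAStringSet].
#' @param tss One TSS record: a one-row data.frame or list with `gene_id`,
#'   `contig_id`, `gene_strand`, `tss_pos`.
#' @param upstream_bp,downstream_bp Nonnegative window extents in bp.
#' @param margin_bp Nonnegative margin in bp (default 22 for 20 nt + NGG).
#' @return An object of class `promoter_window`: a list with `gene_id`,
#'   `contig_id`, `gene_strand`, `tss_pos`, `window_start`, `window_end`
#'   (0-based, half-open contig coordinates), `sequence` and `truncated`.
#' @export
extract_promoter_window <- function(genome, tss, upstream_bp = 600,
                                    downstream_bp = 0, margin_bp = 22) {
  stopifnot(upstream_bp >= 0, downstream_bp >= 0, margin_bp >= 0)
  tss <- as.list(tss)
  if (!tss$contig_id %in% names(genome)) {
    stop("contig '", tss$contig_id, "' not present in genome")
  }
  ctg_len <- Biostrings::width(genome)[match(tss$contig_id, names(genome))]
  p <- as.integer(tss$tss_pos)

  if (tss$gene_strand == "+") {
    start0 <- p - upstream_bp - margin_bp
    end0 <- p + downstream_bp + margin_bp
  } else {
    # transcription runs leftward: upstream extends to higher coordinates
    start0 <- p - downstream_bp - margin_bp + 1L
    end0 <- p + upstream_bp + margin_bp + 1L
  }
  cl_start <- max(0L, as.integer(start0))
  cl_end <- min(as.integer(ctg_len), as.integer(end0))
  truncated <- (cl_start != start0) || (cl_end != end0)

  if (cl_start >= cl_end) {
    warning("promoter window for '", tss$gene_id,
            "' lies entirely off contig", call. = FALSE)
    cl_start <- cl_end <- min(max(cl_start, 0L), ctg_len)
    seq <- ""
    truncated <- TRUE
  } else {
    seq <- as.character(Biostrings::subseq(genome[[tss$contig_id]],
                                           start = cl_start + 1L,
                                           end = cl_end))
  }

  structure(list(
    gene_id = tss$gene_id,
    contig_id = tss$contig_id,
    gene_strand = tss$gene_strand,
    tss_pos = p,
    window_start = cl_start,
    window_end = cl_end,
    sequence = seq,
    truncated = truncated
  ), class = "promoter_window")
}
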