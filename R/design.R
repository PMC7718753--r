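# End-to-end pipeline: orchestrate window extraction -> scan -> annotate ->
# filter -> score -> rank per TSS, and write TSV / BED6 reports.

#' Design ranked CRISPRa guides for a set of TSSs
#'
#' For each TSS record the promoter window is extracted, protospacers are
#' enumerated on both strands, candidates are annotated (distance to TSS,
#' GC fraction, strand class), filtered, scored and ranked. Genes whose
#' window yields no reportable candidate appear in the `skipped` table with
#' a reason; a TSS referencing a missing contig is recorded there too and
#' the run continues. Output is sorted by gene ID then rank, so results do
#' not depend on the order of input TSS records or FASTA records.
#'
#' @param genome Named [Biostrings::DNAStringSet] (from
#'   [read_genome_fasta()]).
#' @param tss Data.frame of TSS records (from [read_tss()]).
#' @param cfg A [design_config()].
#' @param top_n Optional per-gene cap on reported candidates; defaults to
#'   `cfg$top_n` (unlimited when `NULL`).
#' @return An object of class `design_report`: a list with `candidates`
#'   (one row per reported guide, scores and rank included), `skipped`
#'   (gene_id + reason), `config`, and `metadata` (tool version, input
#'   summary, strand-naming convention statement).
#' @export
design_guides <- function(genome, tss, cfg = design_config(),
                          top_n = cfg$top_n) {
  if (length(genome) == 0L) stop("empty genome")
  stopifnot(is.data.frame(tss), nrow(tss) >= 1L)

  cand_list <- list()
  skip_list <- list()
  for (i in seq_len(nrow(tss))) {
    rec <- tss[i, , drop = FALSE]
    key <- sprintf("%s@%s:%d", rec$gene_id, rec$contig_id, rec$tss_pos)
    if (!rec$contig_id %in% names(genome)) {
      skip_list[[key]] <- data.frame(
        gene_id = rec$gene_id, reason = "contig not found",
        stringsAsFactors = FALSE)
      next
    }
    win <- withCallingHandlers(
      extract_promoter_window(genome, rec, cfg$upstream_bp,
                              cfg$downstream_bp, cfg$margin_bp),
      warning = function(w) invokeRestart("muffleWarning"))
    raw <- suppressWarnings(
      find_protospacers(win, cfg$spacer_len, cfg$pam))
    if (nrow(raw) == 0L) {
      reason <- if (attr(raw, "n_dropped") > 0L) {
        "all candidates dropped (N in spacer or PAM)"
      } else {
        "no PAM match"
      }
      skip_list[[key]] <- data.frame(gene_id = rec$gene_id, reason = reason,
                                     stringsAsFactors = FALSE)
      next
    }
    cands <- annotate_candidates(raw, win, cfg)
    cands <- apply_filters(cands, cfg, window_truncated = win$truncated)
    if (nrow(cands) == 0L) {
      skip_list[[key]] <- data.frame(
        gene_id = rec$gene_id, reason = "all candidates dropped (polyT)",
        stringsAsFactors = FALSE)
      next
    }
    cands <- rank_candidates(score_candidates(cands, cfg), cfg)
    if (!is.null(top_n)) cands <- utils::head(cands, top_n)
    cand_list[[key]] <- cands
  }

  candidates <- if (length(cand_list) > 0L) {
    do.call(rbind, cand_list[order(names(cand_list))])
  } else {
    empty_candidates()
  }
  rownames(candidates) <- NULL
  skipped <- if (length(skip_list) > 0L) {
    do.call(rbind, skip_list[order(names(skip_list))])
  } else {
    data.frame(gene_id = character(0), reason = character(0),
               stringsAsFactors = FALSE)
  }
  rownames(skipped) <- NULL

  structure(list(
    candidates = candidates,
    skipped = skipped,
    config = cfg,
    metadata = list(
      tool = "crisprascan",
      version = as.character(utils::packageVersion("crisprascan")),
      n_contigs = length(genome),
      genome_bp = sum(Biostrings::width(genome)),
      n_tss = nrow(tss),
      strand_convention = paste(
        "strand_class names the DNA strand the spacer base-pairs with:",
        "NT = non-template (protospacer on the template strand),",
        "T = template (protospacer on the gene's coding strand)")
    )
  ), class = "design_report")
}

empty_candidates <- function() {
  data.frame(
    gene_id = character(0), contig_id = character(0),
    gene_strand = character(0), spacer_seq = character(0),
    pam_seq = character(0), protospacer_strand = character(0),
    protospacer_start = integer(0), d_tss = integer(0),
    strand_class = character(0), gc_fraction = numeric(0),
    flags = character(0), position_score = numeric(0),
    gc_score = numeric(0), nt_indicator = integer(0),
    composite_score = numeric(0), predicted_fold = numeric(0),
    rank = integer(0), stringsAsFactors = FALSE
  )
}

#' @export
print.design_report <- function(x, ...) {
  cat("CRISPRa design report (", x$metadata$tool, " ",
      x$metadata$version, ")\n", sep = "")
  cat(sprintf("  %d guide(s) across %d gene(s); %d gene(s) skipped\n",
              nrow(x$candidates), length(unique(x$candidates$gene_id)),
              nrow(x$skipped)))
  cat("  ", x$metadata$strand_convention, "\n", sep = "")
  if (nrow(x$candidates) > 0L) {
    top <- x$candidates[x$candidates$rank == 1L,
                        c("gene_id", "spacer_seq", "d_tss", "strand_class",
                          "gc_fraction", "composite_score")]
    cat("  top-ranked guide per gene:\n")
    print(top, row.names = FALSE)
  }
  invisible(x)
}

#' Write a design report as TSV
#'
#' One header row, then one row per candidate in report order (gene ID,
#' then rank): gene_id, contig, gene_strand, rank, spacer_seq, pam_seq,
#' protospacer_strand, protospacer_start, d_tss, strand_class, gc_fraction
#' (4 decimals), position_score, composite_score (4 decimals),
#' predicted_fold (2 decimals), flags (semicolon-joined). Re-running on
#' identical inputs yields a byte-identical file.
#'
#' @param report A `design_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_design_tsv <- function(report, path) {
  stopifnot(inherits(report, "design_report"))
  header <- paste(c("gene_id", "contig", "gene_strand", "rank",
                    "spacer_seq", "pam_seq", "protospacer_strand",
                    "protospacer_start", "d_tss", "strand_class",
                    "gc_fraction", "position_score", "composite_score",
                    "predicted_fold", "flags"), collapse = "\t")
  x <- report$candidates
  rows <- if (nrow(x) > 0L) {
    sprintf("%s\t%s\t%s\t%d\t%s\t%s\t%s\t%d\t%d\t%s\t%.4f\t%.1f\t%.4f\t%.2f\t%s",
            x$gene_id, x$contig_id, x$gene_strand, x$rank, x$spacer_seq,
            x$pam_seq, x$protospacer_strand, x$protospacer_start, x$d_tss,
            x$strand_class, x$gc_fraction, x$position_score,
            x$composite_score, x$predicted_fold, x$flags)
  } else {
    character(0)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, rows), con, useBytes = TRUE)
  invisible(path)
}

#' Write a design report as BED6
#'
#' One BED6 line per candidate over the protospacer span (0-based,
#' half-open, PAM excluded): name is `gene_id|rank|strand_class`, score is
#' `round(composite_score * 1000)` clamped to `[0, 1000]`, strand is the
#' protospacer strand. An empty report yields an empty file.
#'
#' @param report A `design_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_design_bed <- function(report, path) {
  stopifnot(inherits(report, "design_report"))
  x <- report$candidates
  rows <- if (nrow(x) > 0L) {
    score <- pmin(1000L, pmax(0L, as.integer(round(x$composite_score * 1000))))
    sprintf("%s\t%d\t%d\t%s|%d|%s\t%d\t%s",
            x$contig_id, x$protospacer_start,
            x$protospacer_start + report$config$spacer_len,
            x$gene_id, x$rank, x$strand_class, score, x$protospacer_strand)
  } else {
    character(0)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(rows, con, useBytes = TRUE)
  invisible(path)
}

#' Score one user-supplied guide
#'
#' Convenience breakdown for a single spacer at a stated distance and
#' strand class, without any genome scan: validates the spacer, computes
#' GC fraction, position / GC / composite scores and predicted
#' fold-activation, and returns the one-row breakdown.
#'
#' @param spacer_seq Spacer sequence (A/C/G/T, `cfg$spacer_len` nt).
#' @param d_tss Signed distance to the TSS (negative upstream).
#' @param strand_class `"NT"` or `"T"`.
#' @param cfg A [design_config()].
#' @return One-row data.frame with the full score breakdown.
#' @export
score_guide <- function(spacer_seq, d_tss, strand_class,
                        cfg = design_config()) {
  spacer_seq <- toupper(spacer_seq)
  stopifnot(strand_class %in% c("NT", "T"))
  if (nchar(spacer_seq) != cfg$spacer_len) {
    stop("spacer must be ", cfg$spacer_len, " nt")
  }
  gc <- gc_fraction(spacer_seq)
  P <- position_score(d_tss, cfg)
  nt <- as.integer(strand_class == "NT")
  flags <- character(0)
  if (cfg$polyT_filter != "off" && grepl("TTTT", spacer_seq, fixed = TRUE)) {
    flags <- c(flags, "polyT")
  }
  if (gc > cfg$gc_anchor_hi[1]) flags <- c(flags, "extrapolated_gc")
  data.frame(
    spacer_seq = spacer_seq, d_tss = as.integer(d_tss),
    strand_class = strand_class, gc_fraction = gc,
    position_score = P, gc_score = gc_score(gc), nt_indicator = nt,
    composite_score = composite_score(P, gc, nt, cfg),
    predicted_fold = predicted_fold_activation(gc, cfg),
    flags = paste(flags, collapse = ";"),
    stringsAsFactors = FALSE
  )
}
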