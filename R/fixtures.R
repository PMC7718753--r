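# Seeded synthetic-genome generator: plants protospacers with controlled
# distance-to-TSS, GC count and strand class into random background
# contigs, emits FASTA + GFF3 + a ground-truth table, and self-verifies by
# re-scanning each promoter window.

DEFAULT_PLANT <- function() {
  data.frame(d_tss = -200L, gc_count = 15L, strand_class = "NT",
             label = "best", stringsAsFactors = FALSE)
}

# Sample a spacer with exactly gc_count G/C bases at random positions.
sample_spacer <- function(spacer_len, gc_count) {
  stopifnot(gc_count >= 0, gc_count <= spacer_len)
  chars <- sample(c("A", "T"), spacer_len, replace = TRUE)
  if (gc_count > 0L) {
    pos <- sample.int(spacer_len, gc_count)
    chars[pos] <- sample(c("G", "C"), gc_count, replace = TRUE)
  }
  paste(chars, collapse = "")
}

# Build one gene: a background contig with the requested plants written in,
# verified by re-scanning the promoter window. Returns contig sequence,
# TSS record and truth rows.
build_planted_gene <- function(gene_id, contig_id, gene_strand, contig_len,
                               tss_pos, background_gc, plants,
                               spacer_len = 20, pam_seq = "TGG",
                               upstream_bp = 600, max_retries = 100) {
  L <- as.integer(spacer_len)
  P <- nchar(pam_seq)
  margin <- L + P - 1L
  n <- nrow(plants)
  if (!"label" %in% names(plants)) {
    plants$label <- c("best", rep("decoy", n - 1L))
  }
  stopifnot(all(plants$strand_class %in% c("NT", "T")),
            all(plants$d_tss < 0))

  # contig coordinates of each plant
  prox <- if (gene_strand == "+") tss_pos + plants$d_tss else
    tss_pos - plants$d_tss
  anti <- if (gene_strand == "+") "-" else "+"
  proto_strand <- ifelse(plants$strand_class == "NT", anti, gene_strand)
  proto_start <- ifelse(proto_strand == "+", prox - L + 1L, prox)
  fp_lo <- ifelse(proto_strand == "+", proto_start, proto_start - P)
  fp_hi <- ifelse(proto_strand == "+", proto_start + L + P - 1L,
                  proto_start + L - 1L)
  if (any(fp_lo < 0L) || any(fp_hi >= contig_len)) {
    stop("plant footprint outside contig for gene '", gene_id, "'")
  }
  # plants must sit inside the scannable promoter window
  win_lo <- if (gene_strand == "+") tss_pos - upstream_bp - margin else
    tss_pos - margin + 1L
  win_hi <- if (gene_strand == "+") tss_pos + margin - 1L else
    tss_pos + upstream_bp + margin
  if (any(fp_lo < win_lo) || any(fp_hi > win_hi)) {
    stop("plant outside the scanned promoter window (upstream_bp = ",
         upstream_bp, ") for gene '", gene_id, "'")
  }
  if (n > 1L) {
    ord <- order(fp_lo)
    if (any(fp_lo[ord][-1L] <= fp_hi[ord][-n])) {
      stop("overlapping plants for gene '", gene_id, "'")
    }
  }

  spacers <- vapply(plants$gc_count, function(g) sample_spacer(L, g),
                    character(1))
  bg_prob <- c((1 - background_gc) / 2, background_gc / 2,
               background_gc / 2, (1 - background_gc) / 2)
  tss_rec <- data.frame(gene_id = gene_id, contig_id = contig_id,
                        gene_strand = gene_strand,
                        tss_pos = as.integer(tss_pos),
                        stringsAsFactors = FALSE)

  for (try in seq_len(max_retries)) {
    contig <- sample(c("A", "C", "G", "T"), contig_len, replace = TRUE,
                     prob = bg_prob)
    for (k in seq_len(n)) {
      if (proto_strand[k] == "+") {
        sp <- strsplit(spacers[k], "")[[1]]
        pm <- strsplit(pam_seq, "")[[1]]
        contig[(proto_start[k] + 1L):(proto_start[k] + L)] <- sp
        contig[(proto_start[k] + L + 1L):(proto_start[k] + L + P)] <- pm
      } else {
        sp <- strsplit(revcomp(spacers[k]), "")[[1]]
        pm <- strsplit(revcomp(pam_seq), "")[[1]]
        contig[(proto_start[k] + 1L):(proto_start[k] + L)] <- sp
        contig[(proto_start[k] - P + 1L):proto_start[k]] <- pm
      }
    }
    seq <- paste(contig, collapse = "")
    genome1 <- Biostrings::DNAStringSet(stats::setNames(seq, contig_id))
    win <- extract_promoter_window(genome1, tss_rec, upstream_bp, 0L, margin)
    found <- find_protospacers(win, L, "NGG")
    ok <- vapply(seq_len(n), function(k) {
      hits <- found[found$spacer_seq == spacers[k], , drop = FALSE]
      nrow(hits) == 1L &&
        hits$protospacer_start == proto_start[k] &&
        hits$protospacer_strand == proto_strand[k]
    }, logical(1))
    if (all(ok)) {
      truth <- data.frame(
        gene_id = gene_id, contig_id = contig_id,
        gene_strand = gene_strand, tss_pos = as.integer(tss_pos),
        d_tss = as.integer(plants$d_tss),
        gc_count = as.integer(plants$gc_count),
        gc_fraction = plants$gc_count / L,
        strand_class = plants$strand_class,
        spacer_seq = spacers, pam_seq = pam_seq,
        protospacer_strand = proto_strand,
        protospacer_start = as.integer(proto_start),
        expected_rank_hint = plants$label,
        stringsAsFactors = FALSE
      )
      return(list(sequence = seq, tss = tss_rec, truth = truth))
    }
  }
  stop("could not place plants without background collisions for gene '",
       gene_id, "' after ", max_retries, " retries")
}

#' Generate a synthetic genome with planted guide candidates
#'
#' Builds `n_genes` single-gene contigs of i.i.d. background sequence
#' (per-base G/C probability `background_gc`), writes the protospacers
#' described by `plant_spec` into each gene's promoter at exact distances,
#' GC counts and strand classes, and verifies by re-scanning each promoter
#' window that every planted spacer is recovered exactly once at its
#' intended position and strand; the background is resampled (bounded
#' retries) on collision, so the emitted ground truth is exact. Gene
#' strands alternate `+`/`-` across genes. Deterministic for a fixed seed.
#'
#' @param n_genes Number of genes (one contig each).
#' @param background_gc Background per-base GC probability in `[0, 1]`
#'   (default 0.5). 0 gives an A/T-only background in which the plants are
#'   the only possible PAM sites.
#' @param seed Integer seed (mandatory).
#' @param plant_spec Data.frame with columns `d_tss` (negative), `gc_count`
#'   (0..`spacer_len`), `strand_class` (`"NT"`/`"T"`) and optionally
#'   `label` (`"best"`/`"decoy"`); applied to every gene. Overlapping
#'   plants are an error.
#' @param contig_len Contig length in bp (default 1500).
#' @param upstream_bp Upstream extent of the promoter window the plants
#'   must fall in (default 600).
#' @param spacer_len,pam_seq Spacer length and the literal PAM written next
#'   to each plant (default 20 nt, "TGG").
#' @return An object of class `crispra_fixture`: list with `genome`
#'   ([Biostrings::DNAStringSet]), `tss` (data.frame as from
#'   [read_tss()]), `truth` (ground-truth table, one row per plant),
#'   `seed`, `background_gc`, `upstream_bp`.
#' @export
make_fixture <- function(n_genes = 1, background_gc = 0.5, seed,
                         plant_spec = DEFAULT_PLANT(), contig_len = 1500,
                         upstream_bp = 600, spacer_len = 20,
                         pam_seq = "TGG") {
  stopifnot(!missing(seed), n_genes >= 1,
            background_gc >= 0, background_gc <= 1)
  set.seed(as.integer(seed))
  genes <- lapply(seq_len(n_genes), function(i) {
    strand <- if (i %% 2L == 1L) "+" else "-"
    tss_pos <- if (strand == "+") 1000L else contig_len - 1001L
    build_planted_gene(
      gene_id = sprintf("g%d", i), contig_id = sprintf("ctg%d", i),
      gene_strand = strand, contig_len = contig_len, tss_pos = tss_pos,
      background_gc = background_gc, plants = plant_spec,
      spacer_len = spacer_len, pam_seq = pam_seq,
      upstream_bp = upstream_bp)
  })
  seqs <- vapply(genes, `[[`, character(1), "sequence")
  names(seqs) <- vapply(genes, function(g) g$tss$contig_id, character(1))
  fx <- list(
    genome = Biostrings::DNAStringSet(seqs),
    tss = do.call(rbind, lapply(genes, `[[`, "tss")),
    truth = do.call(rbind, lapply(genes, `[[`, "truth")),
    seed = as.integer(seed),
    background_gc = background_gc,
    upstream_bp = as.integer(upstream_bp)
  )
  rownames(fx$tss) <- rownames(fx$truth) <- NULL
  class(fx) <- "crispra_fixture"
  fx
}

#' Generate the canonical three-panel test fixture
#'
#' Emits one fixture with three genes, each reproducing one of the ordinal
#' comparisons behind the design rules, on an A/T-only background so the
#' planted guides (plus any candidates internal to them) are the only
#' candidates:
#'
#' * `g_ladder` (+ strand): five NT guides at nearby optimal-window
#'   positions forming a GC ladder (18, 14, 10, 6, 2 of 20); expected rank
#'   order equals GC order, highest-GC guide first.
#' * `g_dominance` (- strand): an in-window 45%-GC guide versus a 75%-GC
#'   guide 700 bp upstream; the in-window guide must win — placement
#'   dominates GC content.
#' * `g_strand` (+ strand): an NT and a T guide of equal GC at nearby
#'   optimal positions; NT must outrank T.
#'
#' The `"best"` plant of every panel sits at -200 bp, the optimum, so it
#' is also first under the distance tie-break. The dominance panel needs a
#' scan reaching -700 bp, so the fixture's recommended configuration
#' (attribute `cfg`, `upstream_bp = 800`) should be used when designing.
#'
#' @param seed Integer seed.
#' @return A `crispra_fixture` with an attached `cfg` attribute.
#' @export
make_panel <- function(seed) {
  stopifnot(!missing(seed))
  set.seed(as.integer(seed))
  up <- 800L
  len <- 1500L
  panels <- list(
    list(gene_id = "g_ladder", contig_id = "ctg_ladder", strand = "+",
         tss = 1000L,
         plants = data.frame(
           d_tss = c(-200L, -230L, -260L, -290L, -320L),
           gc_count = c(18L, 14L, 10L, 6L, 2L),
           strand_class = "NT",
           label = c("best", rep("decoy", 4L)),
           stringsAsFactors = FALSE)),
    list(gene_id = "g_dominance", contig_id = "ctg_dominance", strand = "-",
         tss = 499L,
         plants = data.frame(
           d_tss = c(-200L, -700L), gc_count = c(9L, 15L),
           strand_class = "NT", label = c("best", "decoy"),
           stringsAsFactors = FALSE)),
    list(gene_id = "g_strand", contig_id = "ctg_strand", strand = "+",
         tss = 1000L,
         plants = data.frame(
           d_tss = c(-200L, -240L), gc_count = c(10L, 10L),
           strand_class = c("NT", "T"), label = c("best", "decoy"),
           stringsAsFactors = FALSE))
  )
  genes <- lapply(panels, function(p) {
    build_planted_gene(p$gene_id, p$contig_id, p$strand, len, p$tss,
                       background_gc = 0, plants = p$plants,
                       upstream_bp = up)
  })
  seqs <- vapply(genes, `[[`, character(1), "sequence")
  names(seqs) <- vapply(genes, function(g) g$tss$contig_id, character(1))
  fx <- list(
    genome = Biostrings::DNAStringSet(seqs),
    tss = do.call(rbind, lapply(genes, `[[`, "tss")),
    truth = do.call(rbind, lapply(genes, `[[`, "truth")),
    seed = as.integer(seed),
    background_gc = 0,
    upstream_bp = up
  )
  rownames(fx$tss) <- rownames(fx$truth) <- NULL
  class(fx) <- "crispra_fixture"
  attr(fx, "cfg") <- design_config(upstream_bp = up)
  fx
}

#' Write a fixture to disk as FASTA + GFF3 + truth TSV
#'
#' Writes `<prefix>.fasta`, `<prefix>.gff3` (one `gene` feature per gene,
#' placed so its annotated TSS is the planted one) and
#' `<prefix>.truth.tsv`. Reading the pair back with [read_genome_fasta()]
#' and [read_tss()] reproduces the fixture's genome and TSS records.
#'
#' @param fx A `crispra_fixture`.
#' @param prefix Output path prefix.
#' @return Named character vector of the three paths, invisibly.
#' @export
write_fixture <- function(fx, prefix) {
  stopifnot(inherits(fx, "crispra_fixture"))
  paths <- c(fasta = paste0(prefix, ".fasta"),
             gff3 = paste0(prefix, ".gff3"),
             truth = paste0(prefix, ".truth.tsv"))
  Biostrings::writeXStringSet(fx$genome, paths[["fasta"]])

  lens <- stats::setNames(Biostrings::width(fx$genome), names(fx$genome))
  body <- 200L  # nominal annotated gene length, clipped to the contig
  start1 <- ifelse(fx$tss$gene_strand == "+", fx$tss$tss_pos + 1L,
                   pmax(1L, fx$tss$tss_pos + 2L - body))
  end1 <- ifelse(fx$tss$gene_strand == "+",
                 pmin(lens[fx$tss$contig_id], fx$tss$tss_pos + body),
                 fx$tss$tss_pos + 1L)
  gr <- GenomicRanges::GRanges(
    seqnames = fx$tss$contig_id,
    ranges = IRanges::IRanges(start = start1, end = end1),
    strand = fx$tss$gene_strand)
  gr$source <- "crisprascan"
  gr$type <- "gene"
  gr$ID <- fx$tss$gene_id
  gr$Name <- fx$tss$gene_id
  rtracklayer::export(gr, paths[["gff3"]], format = "GFF3")

  utils::write.table(fx$truth, paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
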