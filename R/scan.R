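# Protospacer enumeration and per-candidate annotation: both-strand PAM
# scanning, distance to the TSS in transcription direction, template /
# non-template strand classification, and spacer GC fraction.

#' Enumerate candidate protospacers in a promoter window
#'
#' Finds every position in the window where `spacer_len` bases are followed
#' immediately 3'-ward by a PAM match, on the contig `+` strand as written
#' and on the `-` strand via reverse complement. Candidates whose spacer or
#' PAM contains N are dropped with a counted warning. Coordinates are
#' reported on the contig, 0-based; `protospacer_start` is always the
#' leftmost protospacer base regardless of strand. Spacer and PAM sequences
#' are reported 5'->3' on the protospacer-bearing strand, i.e. the spacer
#' as it would be synthesized.
#'
#' @param window A `promoter_window` from [extract_promoter_window()], or a
#'   plain character sequence (then treated as a window starting at contig
#'   coordinate 0).
#' @param spacer_len Spacer length in nt (default 20).
#' @param pam PAM as an IUPAC pattern (default "NGG").
#' @return Data.frame with columns `spacer_seq`, `pam_seq`,
#'   `protospacer_strand`, `protospacer_start`, sorted by start then
#'   strand. Attribute `n_dropped` counts N-containing candidates removed.
#' @export
find_protospacers <- function(window, spacer_len = 20, pam = "NGG") {
  if (is.character(window)) {
    window <- structure(list(sequence = toupper(window), window_start = 0L),
                        class = "promoter_window")
  }
  stopifnot(inherits(window, "promoter_window"), spacer_len >= 1)
  L <- as.integer(spacer_len)
  P <- nchar(pam)
  seq <- window$sequence
  w0 <- as.integer(window$window_start)

  empty <- data.frame(
    spacer_seq = character(0), pam_seq = character(0),
    protospacer_strand = character(0), protospacer_start = integer(0),
    stringsAsFactors = FALSE
  )
  if (nchar(seq) < L + P) {
    attr(empty, "n_dropped") <- 0L
    return(empty)
  }

  sub_vec <- function(first, last) {
    if (length(first) == 0L) character(0) else substring(seq, first, last)
  }
  subject <- Biostrings::DNAString(seq)
  pam_fwd <- Biostrings::DNAString(toupper(pam))
  pam_rev <- Biostrings::reverseComplement(pam_fwd)

  # + strand: PAM match at j (1-based in window) with spacer at [j-L, j-1]
  jf <- BiocGenerics::start(Biostrings::matchPattern(pam_fwd, subject,
                                                     fixed = FALSE))
  jf <- jf[jf > L]
  plus <- data.frame(
    spacer_seq = sub_vec(jf - L, jf - 1L),
    pam_seq = sub_vec(jf, jf + P - 1L),
    protospacer_strand = rep("+", length(jf)),
    protospacer_start = w0 + jf - L - 1L,
    stringsAsFactors = FALSE
  )

  # - strand: reverse-complemented PAM at j with protospacer at
  # [j+P, j+P+L-1] on the + strand; report spacer/PAM on the - strand
  jr <- BiocGenerics::start(Biostrings::matchPattern(pam_rev, subject,
                                                     fixed = FALSE))
  jr <- jr[jr + P + L - 1L <= nchar(seq)]
  minus <- data.frame(
    spacer_seq = revcomp(sub_vec(jr + P, jr + P + L - 1L)),
    pam_seq = revcomp(sub_vec(jr, jr + P - 1L)),
    protospacer_strand = rep("-", length(jr)),
    protospacer_start = w0 + jr + P - 1L,
    stringsAsFactors = FALSE
  )

  out <- rbind(plus, minus)
  has_n <- grepl("N", paste0(out$spacer_seq, out$pam_seq), fixed = TRUE)
  n_dropped <- sum(has_n)
  if (n_dropped > 0L) {
    warning("dropped ", n_dropped,
            " candidate(s) containing N in spacer or PAM", call. = FALSE)
    out <- out[!has_n, , drop = FALSE]
  }
  out <- out[order(out$protospacer_start, out$protospacer_strand), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Signed distance from a protospacer to the TSS
#'
#' Distance in bp, measured in the gene's transcription direction, from the
#' TSS to a reference base of the protospacer: negative upstream, 0 the TSS
#' base itself. The default reference is the PAM-proximal base (the
#' protospacer base adjacent to the PAM); `"five_prime"` uses the spacer's
#' 5' end (PAM-distal base) and `"midpoint"` the floor midpoint.
#'
#' @param protospacer_start Integer vector, 0-based leftmost protospacer
#'   base on the contig.
#' @param protospacer_strand Character vector of `"+"`/`"-"`.
#' @param gene_strand `"+"` or `"-"` (recycled).
#' @param tss_pos 0-based TSS position (recycled).
#' @param spacer_len Spacer length in nt.
#' @param reference `"pam_proximal"`, `"midpoint"` or `"five_prime"`.
#' @return Integer vector of signed distances.
#' @export
distance_to_tss <- function(protospacer_start, protospacer_strand,
                            gene_strand, tss_pos, spacer_len = 20,
                            reference = c("pam_proximal", "midpoint",
                                          "five_prime")) {
  reference <- match.arg(reference)
  L <- as.integer(spacer_len)
  s <- as.integer(protospacer_start)
  ref_pos <- switch(reference,
    # + strand protospacer: PAM lies 3' = rightward, proximal base is the
    # rightmost; - strand protospacer: PAM lies leftward, proximal base is
    # the leftmost.
    pam_proximal = ifelse(protospacer_strand == "+", s + L - 1L, s),
    five_prime = ifelse(protospacer_strand == "+", s, s + L - 1L),
    midpoint = s + (L - 1L) %/% 2L
  )
  plus_gene <- rep_len(gene_strand == "+", length(s))
  as.integer(ifelse(plus_gene, ref_pos - rep_len(tss_pos, length(s)),
                    rep_len(tss_pos, length(s)) - ref_pos))
}

#' Classify the DNA strand an sgRNA targets
#'
#' The spacer is identical in sequence to the protospacer and base-pairs
#' with the opposite genomic strand. When the protospacer lies on the
#' gene's own (coding / non-template) strand, the spacer therefore
#' hybridizes with the template strand: class `"T"`. When protospacer and
#' gene strands differ, the spacer pairs with the non-template strand:
#' class `"NT"`. NT-strand guides are the more effective class for CRISPRa.
#'
#' @param protospacer_strand Character vector of `"+"`/`"-"`.
#' @param gene_strand Character vector of `"+"`/`"-"` (recycled).
#' @return Character vector of `"NT"` / `"T"`.
#' @export
classify_strand <- function(protospacer_strand, gene_strand) {
  ifelse(protospacer_strand == gene_strand, "T", "NT")
}

#' GC fraction of spacer sequences
#'
#' @param seq Character vector of nonempty A/C/G/T sequences; any other
#'   letter is an error (N-containing candidates are dropped upstream).
#' @return Numeric vector in `[0, 1]`: (#G + #C) / length.
#' @export
gc_fraction <- function(seq) {
  stopifnot(length(seq) > 0L, all(nchar(seq) > 0L))
  if (any(grepl("[^ACGT]", seq))) {
    stop("gc_fraction: sequences must contain only A/C/G/T")
  }
  x <- Biostrings::DNAStringSet(seq)
  unname(rowSums(Biostrings::letterFrequency(x, c("G", "C"))) /
           Biostrings::width(x))
}

#' Annotate raw protospacer candidates against their TSS
#'
#' Adds gene identity, signed distance to the TSS, strand class and GC
#' fraction to the raw scan output, yielding full guide candidates.
#'
#' @param raw Data.frame from [find_protospacers()].
#' @param window The `promoter_window` the candidates came from.
#' @param cfg A [design_config()].
#' @return Data.frame of guide candidates; zero rows passed through.
#' @export
annotate_candidates <- function(raw, window, cfg = design_config()) {
  n <- nrow(raw)
  out <- data.frame(
    gene_id = rep(window$gene_id, n),
    contig_id = rep(window$contig_id, n),
    gene_strand = rep(window$gene_strand, n),
    raw,
    stringsAsFactors = FALSE
  )
  out$d_tss <- distance_to_tss(out$protospacer_start, out$protospacer_strand,
                               window$gene_strand, window$tss_pos,
                               cfg$spacer_len, cfg$distance_reference)
  out$strand_class <- classify_strand(out$protospacer_strand,
                                      window$gene_strand)
  out$gc_fraction <- if (n > 0L) gc_fraction(out$spacer_seq) else numeric(0)
  out
}
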