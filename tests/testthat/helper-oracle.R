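# Independent oracles and small utilities used across the suite. These stay
# deliberately free of the package's own scanning code: plain string
# reversal plus vectorized regex matching.

# Base-R reverse complement of a single sequence.
rc_chr <- function(seq) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", seq), "")[[1]]),
        collapse = "")
}

# Brute-force regex scan of a window (given in contig orientation) for
# spacer_len bases followed by an NGG PAM, on both strands. Returns the
# same columns as find_protospacers(), in the same sort order.
oracle_scan <- function(seq, spacer_len = 20, window_start = 0) {
  L <- spacer_len
  P <- 3L
  n <- nchar(seq)
  pat <- sprintf("^[ACGT]{%d}[ACGT]GG$", L)
  one_strand <- function(s) {
    if (n < L + P) return(NULL)
    i <- seq_len(n - L - P + 1L)
    full <- substring(s, i, i + L + P - 1L)
    keep <- grepl(pat, full)
    if (!any(keep)) return(NULL)
    data.frame(
      i = i[keep],
      spacer_seq = substring(s, i[keep], i[keep] + L - 1L),
      pam_seq = substring(s, i[keep] + L, i[keep] + L + P - 1L),
      stringsAsFactors = FALSE
    )
  }
  plus <- one_strand(seq)
  if (!is.null(plus)) {
    plus <- data.frame(
      spacer_seq = plus$spacer_seq, pam_seq = plus$pam_seq,
      protospacer_strand = "+",
      protospacer_start = as.integer(window_start + plus$i - 1L),
      stringsAsFactors = FALSE)
  }
  minus <- one_strand(rc_chr(seq))
  if (!is.null(minus)) {
    # position i on the reverse complement: protospacer occupies
    # [i, i+L-1] there, i.e. leftmost forward base n - (i + L - 1) + 1
    minus <- data.frame(
      spacer_seq = minus$spacer_seq, pam_seq = minus$pam_seq,
      protospacer_strand = "-",
      protospacer_start = as.integer(window_start + n -
                                       (minus$i + L - 1L)),
      stringsAsFactors = FALSE)
  }
  out <- rbind(plus, minus)
  if (is.null(out)) {
    out <- data.frame(spacer_seq = character(0), pam_seq = character(0),
                      protospacer_strand = character(0),
                      protospacer_start = integer(0),
                      stringsAsFactors = FALSE)
  }
  out <- out[order(out$protospacer_start, out$protospacer_strand), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# Random ACGT window with a given expected GC fraction.
random_window <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Write a small single-use file under tempdir and return its path.
write_tmp <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
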