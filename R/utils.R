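# Internal helpers shared across modules.

#' Reverse complement of character DNA sequences
#'
#' Thin vectorized wrapper around [Biostrings::reverseComplement()] that keeps
#' plain character vectors in and out.
#'
#' @param x Character vector of DNA sequences (IUPAC letters).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Expand an IUPAC pattern into a character-class regex, e.g. "NGG" ->
# "[ACGT]GG". Used only for validation of config PAMs; the scan itself goes
# through Biostrings.
iupac_regex <- function(pattern) {
  map <- Biostrings::IUPAC_CODE_MAP
  chars <- strsplit(toupper(pattern), "")[[1]]
  bad <- setdiff(chars, names(map))
  if (length(bad) > 0L) {
    stop("invalid IUPAC letters in pattern '", pattern, "': ",
         paste(bad, collapse = ", "))
  }
  paste0(vapply(chars, function(ch) {
    ex <- map[[ch]]
    if (nchar(ex) == 1L) ex else paste0("[", ex, "]")
  }, character(1)), collapse = "")
}

# message() wrapper so all diagnostic output is uniformly prefixed and easy
# to silence with suppressMessages().
log_msg <- function(...) {
  message("[crisprascan] ", ...)
}
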