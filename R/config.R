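#' Design configuration for CRISPRa guide selection
#'
#' Bundles every tunable of the design rules: the promoter scan window, the
#' PAM and spacer geometry, the position-score regions, the composite-score
#' weights, the GC-to-fold-activation calibration anchors, and filtering /
#' tie-break behaviour. All defaults encode the empirical criteria for
#' CRISPRa in the flySAM system: guides are most effective between -450 and
#' -150 bp upstream of the transcription start site (TSS), with an optimum
#' around -200 bp; guides further than 600 bp upstream, or downstream of the
#' TSS, are ineffective regardless of GC content; activation rises
#' monotonically with spacer GC fraction; and guides base-pairing with the
#' non-template (NT) strand outperform template (T) strand guides.
#'
#' Distances to the TSS are signed base pairs in the direction of
#' transcription: negative upstream, 0 the TSS base itself. The flank
#' regions that earn the intermediate position score are derived, not
#' configured: they are the gaps between `hard_cutoff_bp` and the optimal
#' window, and between the optimal window and the TSS.
#'
#' @param upstream_bp Bases upstream of the TSS to scan (default 600, the
#'   distance beyond which guides lose activity).
#' @param downstream_bp Bases downstream of the TSS to scan (default 0;
#'   downstream guides score 0 anyway).
#' @param spacer_len Spacer length in nt (default 20, SpCas9).
#' @param pam PAM as an IUPAC string read 5'->3' on the protospacer strand
#'   (default "NGG", SpCas9).
#' @param optimal_window Length-2 numeric, signed bp: the closed interval of
#'   distances that earn full position score (default `c(-450, -150)`).
#' @param hard_cutoff_bp Signed bp; distances strictly below this score 0
#'   (default -600).
#' @param optimum_center Signed bp used as the ranking tie-break anchor
#'   (default -200).
#' @param w0,w_gc,w_nt Nonnegative composite-score weights summing to 1
#'   (defaults 0.2, 0.6, 0.2). `w0` is the floor earned by placement alone,
#'   `w_gc` scales the GC score and `w_nt` the NT-strand bonus.
#' @param polyT_filter One of `"flag"` (default), `"off"`, `"drop"`: how to
#'   treat spacers containing TTTT, a pol III terminator risk for U6-driven
#'   sgRNA cassettes.
#' @param distance_reference Which protospacer base the distance to the TSS
#'   is measured to: `"pam_proximal"` (default), `"midpoint"` or
#'   `"five_prime"`.
#' @param gc_anchor_lo,gc_anchor_hi Numeric `(gc, fold)` pairs anchoring the
#'   log-linear GC-to-fold-activation calibration. Defaults `(0, 2)` and
#'   `(0.9, 35)`: 2-fold activation at 0% GC rising to 35-fold at 90% GC.
#' @param margin_bp Extra bases added on both sides of the scan window so
#'   protospacers straddling the window edge are still found. Default
#'   `spacer_len + nchar(pam) - 1` (22 for 20 nt + NGG).
#' @param top_n Optional cap on reported candidates per TSS.
#' @return An object of class `design_config` (a validated list).
#' @examples
#' cfg <- design_config()
#' cfg$optimal_window
#' design_config(w0 = 0.1, w_gc = 0.7, w_nt = 0.2)
#' @export
design_config <- function(upstream_bp = 600,
                          downstream_bp = 0,
                          spacer_len = 20,
                          pam = "NGG",
                          optimal_window = c(-450, -150),
                          hard_cutoff_bp = -600,
                          optimum_center = -200,
                          w0 = 0.2,
                          w_gc = 0.6,
                          w_nt = 0.2,
                          polyT_filter = c("flag", "off", "drop"),
                          distance_reference = c("pam_proximal", "midpoint",
                                                 "five_prime"),
                          gc_anchor_lo = c(gc = 0, fold = 2),
                          gc_anchor_hi = c(gc = 0.9, fold = 35),
                          margin_bp = NULL,
                          top_n = NULL) {
  polyT_filter <- match.arg(polyT_filter)
  distance_reference <- match.arg(distance_reference)

  stopifnot(
    length(upstream_bp) == 1L, upstream_bp >= 0,
    length(downstream_bp) == 1L, downstream_bp >= 0,
    length(spacer_len) == 1L, spacer_len >= 1,
    is.character(pam), length(pam) == 1L, nchar(pam) >= 1L,
    length(optimal_window) == 2L,
    length(hard_cutoff_bp) == 1L,
    length(optimum_center) == 1L,
    w0 >= 0, w_gc > 0, w_nt >= 0
  )
  iupac_regex(pam)  # errors on invalid letters
  optimal_window <- sort(as.numeric(optimal_window))
  if (!(hard_cutoff_bp <= optimal_window[1] && optimal_window[2] <= 0)) {
    stop("optimal_window must lie within [hard_cutoff_bp, 0]")
  }
  if (abs(w0 + w_gc + w_nt - 1) > 1e-9) {
    stop("composite weights w0 + w_gc + w_nt must sum to 1")
  }
  anchors <- function(a) {
    a <- unname(as.numeric(a))
    stopifnot(length(a) == 2L, a[1] >= 0, a[1] <= 1, a[2] > 0)
    a
  }
  gc_anchor_lo <- anchors(gc_anchor_lo)
  gc_anchor_hi <- anchors(gc_anchor_hi)
  if (gc_anchor_hi[1] <= gc_anchor_lo[1]) {
    stop("gc_anchor_hi must sit at a higher GC fraction than gc_anchor_lo")
  }
  if (is.null(margin_bp)) margin_bp <- spacer_len + nchar(pam) - 1L
  if (!is.null(top_n)) stopifnot(length(top_n) == 1L, top_n >= 1)

  structure(list(
    upstream_bp = as.integer(upstream_bp),
    downstream_bp = as.integer(downstream_bp),
    spacer_len = as.integer(spacer_len),
    pam = toupper(pam),
    optimal_window = optimal_window,
    hard_cutoff_bp = as.numeric(hard_cutoff_bp),
    optimum_center = as.numeric(optimum_center),
    w0 = w0, w_gc = w_gc, w_nt = w_nt,
    polyT_filter = polyT_filter,
    distance_reference = distance_reference,
    gc_anchor_lo = gc_anchor_lo,
    gc_anchor_hi = gc_anchor_hi,
    margin_bp = as.integer(margin_bp),
    top_n = if (is.null(top_n)) NULL else as.integer(top_n)
  ), class = "design_config")
}

#' @export
print.design_config <- function(x, ...) {
  cat("CRISPRa design configuration\n")
  cat(sprintf("  scan window      : -%d .. +%d bp around TSS (margin %d bp)\n",
              x$upstream_bp, x$downstream_bp, x$margin_bp))
  cat(sprintf("  spacer / PAM     : %d nt / %s\n", x$spacer_len, x$pam))
  cat(sprintf("  optimal window   : [%d, %d] bp (tie-break centre %d)\n",
              x$optimal_window[1], x$optimal_window[2], x$optimum_center))
  cat(sprintf("  hard cutoff      : < %d bp scores 0\n", x$hard_cutoff_bp))
  cat(sprintf("  weights          : w0=%.2f  w_gc=%.2f  w_nt=%.2f\n",
              x$w0, x$w_gc, x$w_nt))
  cat(sprintf("  GC calibration   : fold(%.2f)=%.1f .. fold(%.2f)=%.1f\n",
              x$gc_anchor_lo[1], x$gc_anchor_lo[2],
              x$gc_anchor_hi[1], x$gc_anchor_hi[2]))
  cat(sprintf("  polyT filter     : %s   distance reference: %s\n",
              x$polyT_filter, x$distance_reference))
  invisible(x)
}

#' Read a flat key = value configuration file
#'
#' Parses a plain-text configuration file with one `key = value` pair per
#' line (`#` comments and blank lines ignored) and overlays the values on a
#' base configuration. Two-element fields such as `optimal_window` are given
#' comma-separated, e.g. `optimal_window = -450, -150`. Parsed values are
#' echoed to the message stream.
#'
#' @param path Path to the configuration file.
#' @param base A `design_config` supplying every key the file omits.
#' @return A validated `design_config`.
#' @export
read_design_config <- function(path, base = design_config()) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]

  args <- list(
    upstream_bp = base$upstream_bp, downstream_bp = base$downstream_bp,
    spacer_len = base$spacer_len, pam = base$pam,
    optimal_window = base$optimal_window,
    hard_cutoff_bp = base$hard_cutoff_bp,
    optimum_center = base$optimum_center,
    w0 = base$w0, w_gc = base$w_gc, w_nt = base$w_nt,
    polyT_filter = base$polyT_filter,
    distance_reference = base$distance_reference,
    gc_anchor_lo = base$gc_anchor_lo, gc_anchor_hi = base$gc_anchor_hi,
    margin_bp = base$margin_bp, top_n = base$top_n
  )
  char_keys <- c("pam", "polyT_filter", "distance_reference")
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("malformed config line: '", ln, "'")
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% names(args)) stop("unknown config key: '", key, "'")
    parsed <- if (key %in% char_keys) {
      val
    } else {
      as.numeric(trimws(strsplit(val, ",", fixed = TRUE)[[1]]))
    }
    args[[key]] <- parsed
    log_msg("config: ", key, " = ", paste(parsed, collapse = ", "))
  }
  do.call(design_config, args)
}
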