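# Scoring: position score with hard dominance, monotone GC score, NT-strand
# bonus, composite score, GC-to-fold-activation calibration, filters, and
# deterministic ranking.

#' Position score of a guide relative to the TSS
#'
#' Piecewise-constant score over the signed distance to the TSS: 1.0 inside
#' the optimal window (default \[-450, -150\] bp), 0.5 in the flank regions
#' between the optimal window and the TSS or between the hard cutoff and
#' the optimal window, and 0.0 at or downstream of the TSS (`d >= 0`) or
#' beyond the hard cutoff (`d < -600`). A zero position score zeroes the
#' composite score regardless of GC content or strand: placement dominates.
#'
#' @param d_tss Integer vector of signed distances (negative upstream).
#' @param cfg A [design_config()].
#' @return Numeric vector over `{0, 0.5, 1}`.
#' @export
position_score <- function(d_tss, cfg = design_config()) {
  lo <- cfg$optimal_window[1]; hi <- cfg$optimal_window[2]
  ifelse(d_tss >= lo & d_tss <= hi, 1.0,
         ifelse(d_tss >= 0 | d_tss < cfg$hard_cutoff_bp, 0.0, 0.5))
}

#' GC score of a spacer
#'
#' The identity mapping of GC fraction: strictly monotone in GC and
#' agnostic to where in the spacer the G/C bases sit, since GC placement
#' between the PAM-proximal and PAM-distal halves does not change
#' activation efficiency.
#'
#' @param gc Numeric vector in `[0, 1]`.
#' @return `gc`, unchanged; out-of-range values are an error.
#' @export
gc_score <- function(gc) {
  if (any(gc < 0 | gc > 1)) stop("gc must lie in [0, 1]")
  gc
}

#' Composite design score
#'
#' `S = P * (w0 + w_gc * gc + w_nt * nt)`: the position score multiplies a
#' weighted sum of a placement floor, the GC score and the NT-strand
#' indicator. With default weights S lies in `[0, 1]` and `P = 0` forces
#' `S = 0` for any GC content — guides beyond the cutoff fail even at 75%
#' GC.
#'
#' @param P Position score vector (from [position_score()]).
#' @param gc GC fraction vector in `[0, 1]`.
#' @param nt_indicator 0/1 vector; 1 for NT-strand guides.
#' @param cfg A [design_config()].
#' @return Numeric composite score vector.
#' @export
composite_score <- function(P, gc, nt_indicator, cfg = design_config()) {
  P * (cfg$w0 + cfg$w_gc * gc_score(gc) + cfg$w_nt * nt_indicator)
}

#' Predicted fold-activation from spacer GC content
#'
#' Log-linear interpolation through two calibration anchors — by default
#' 2-fold activation at 0% GC rising to 35-fold at 90% GC, i.e.
#' `fold(g) = 2 * (35/2)^(g / 0.9)`. The prediction is an indicative
#' expectation of relative activation strength, not a guarantee; values
#' above the upper anchor GC are extrapolations and are flagged by
#' [apply_filters()].
#'
#' @param gc Numeric vector in `[0, 1]`.
#' @param cfg A [design_config()] carrying the anchors.
#' @return Numeric vector of predicted fold-activation (>= 1 under default
#'   anchors).
#' @export
predicted_fold_activation <- function(gc, cfg = design_config()) {
  if (any(gc < 0 | gc > 1)) stop("gc must lie in [0, 1]")
  g0 <- cfg$gc_anchor_lo[1]; f0 <- cfg$gc_anchor_lo[2]
  g1 <- cfg$gc_anchor_hi[1]; f1 <- cfg$gc_anchor_hi[2]
  f0 * (f1 / f0)^((gc - g0) / (g1 - g0))
}

#' Apply candidate filters and set flags
#'
#' Adds a semicolon-joined `flags` column: `polyT` when the spacer contains
#' TTTT (pol III terminator risk for U6-driven sgRNA cassettes; such
#' candidates are removed entirely when `cfg$polyT_filter == "drop"`),
#' `extrapolated_gc` when the GC fraction exceeds the upper calibration
#' anchor, and `truncated_window` when the candidate came from a
#' contig-clipped window.
#'
#' @param cands Annotated candidate data.frame (needs `spacer_seq`,
#'   `gc_fraction`).
#' @param cfg A [design_config()].
#' @param window_truncated Logical; inherited from the promoter window.
#' @return The candidate data.frame with a `flags` column (possibly fewer
#'   rows in drop mode).
#' @export
apply_filters <- function(cands, cfg = design_config(),
                          window_truncated = FALSE) {
  n <- nrow(cands)
  flags <- vector("list", n)
  if (n > 0L) {
    polyT <- cfg$polyT_filter != "off" &
      grepl("TTTT", cands$spacer_seq, fixed = TRUE)
    extrap <- cands$gc_fraction > cfg$gc_anchor_hi[1]
    for (i in seq_len(n)) {
      f <- character(0)
      if (polyT[i]) f <- c(f, "polyT")
      if (extrap[i]) f <- c(f, "extrapolated_gc")
      if (window_truncated) f <- c(f, "truncated_window")
      flags[[i]] <- f
    }
    if (cfg$polyT_filter == "drop" && any(polyT)) {
      cands <- cands[!polyT, , drop = FALSE]
      flags <- flags[!polyT]
    }
  }
  cands$flags <- vapply(flags, paste, character(1), collapse = ";")
  rownames(cands) <- NULL
  cands
}

#' Score annotated candidates
#'
#' Computes the full score breakdown for each candidate: position score,
#' GC score, NT indicator, composite score and predicted fold-activation.
#'
#' @param cands Annotated, filtered candidate data.frame.
#' @param cfg A [design_config()].
#' @return The data.frame with columns `position_score`, `gc_score`,
#'   `nt_indicator`, `composite_score`, `predicted_fold` appended.
#' @export
score_candidates <- function(cands, cfg = design_config()) {
  cands$position_score <- position_score(cands$d_tss, cfg)
  cands$gc_score <- gc_score(cands$gc_fraction)
  cands$nt_indicator <- as.integer(cands$strand_class == "NT")
  cands$composite_score <- composite_score(cands$position_score,
                                           cands$gc_fraction,
                                           cands$nt_indicator, cfg)
  cands$predicted_fold <- predicted_fold_activation(cands$gc_fraction, cfg)
  cands
}

#' Rank scored candidates deterministically
#'
#' Total order: composite score descending; then distance to the optimum
#' centre (default -200 bp, the empirically best placement) ascending;
#' then GC fraction descending; then NT before T; then contig coordinate
#' ascending; then protospacer strand `+` before `-`. The order is
#' deterministic and independent of input order.
#'
#' @param scored Scored candidate data.frame from [score_candidates()].
#' @param cfg A [design_config()].
#' @return The data.frame reordered, with a 1-based `rank` column.
#' @export
rank_candidates <- function(scored, cfg = design_config()) {
  if (nrow(scored) == 0L) {
    scored$rank <- integer(0)
    return(scored)
  }
  ord <- order(
    -scored$composite_score,
    abs(scored$d_tss - cfg$optimum_center),
    -scored$gc_fraction,
    scored$strand_class != "NT",   # FALSE (NT) sorts first
    scored$protospacer_start,
    scored$protospacer_strand != "+"
  )
  out <- scored[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
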