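# Position score, GC score, composite score, fold-activation calibration,
# filters and deterministic ranking.

test_that("position score maps distance regions as defined", {
  cfg <- design_config()
  expect_equal(position_score(-300, cfg), 1.0)
  expect_equal(position_score(c(-450, -150), cfg), c(1.0, 1.0))
  expect_equal(position_score(c(-451, -149, -1, -600), cfg),
               c(0.5, 0.5, 0.5, 0.5))
  expect_equal(position_score(c(-601, 0, 50), cfg), c(0, 0, 0))
})

test_that("GC score is the identity on [0, 1]", {
  expect_equal(gc_score(c(0, 0.75, 1)), c(0, 0.75, 1))
  expect_error(gc_score(1.2), "\\[0, 1\\]")
  expect_error(gc_score(-0.1), "\\[0, 1\\]")
})

test_that("composite score multiplies placement into the weighted sum", {
  cfg <- design_config()
  expect_equal(composite_score(1, 1, 1, cfg), 1.0)
  expect_equal(composite_score(0, 0.75, 1, cfg), 0.0)
  expect_equal(composite_score(1, 0.5, 0, cfg), 0.5)
  # dominance floor: any scoring placement beats any zero placement
  expect_true(composite_score(0.5, 0, 0, cfg) >= 0.1)
})

test_that("config validation rejects inconsistent settings", {
  expect_error(design_config(w0 = 0.5, w_gc = 0.6, w_nt = 0.2), "sum to 1")
  expect_error(design_config(optimal_window = c(-700, -150)),
               "hard_cutoff")
  expect_error(design_config(pam = "NQG"), "IUPAC")
})

test_that("fold-activation calibration passes through its anchors", {
  cfg <- design_config()
  expect_equal(predicted_fold_activation(0, cfg), 2, tolerance = 1e-12)
  expect_equal(predicted_fold_activation(0.9, cfg), 35, tolerance = 1e-12)
  # independently derived midpoint: 2 * sqrt(35/2)
  expect_equal(predicted_fold_activation(0.45, cfg), 2 * sqrt(17.5),
               tolerance = 1e-9)
  g <- seq(0, 1, by = 0.01)
  f <- predicted_fold_activation(g, cfg)
  expect_true(all(diff(f) > 0))
  expect_true(all(f >= 1))
})

test_that("filters flag poly-T, GC extrapolation and truncated windows", {
  cands <- data.frame(
    spacer_seq = c(paste0("GCGC", strrep("T", 16)), strrep("GC", 10)),
    gc_fraction = c(0.2, 1.0), stringsAsFactors = FALSE)
  out <- apply_filters(cands, design_config())
  expect_equal(out$flags, c("polyT", "extrapolated_gc"))

  dropped <- apply_filters(cands, design_config(polyT_filter = "drop"))
  expect_equal(nrow(dropped), 1L)
  expect_equal(dropped$spacer_seq, strrep("GC", 10))

  off <- apply_filters(cands, design_config(polyT_filter = "off"))
  expect_false(any(grepl("polyT", off$flags)))

  trunc <- apply_filters(cands, design_config(), window_truncated = TRUE)
  expect_true(all(grepl("truncated_window", trunc$flags)))
})

test_that("composite score is strictly monotone in GC when placement scores", {
  cfg <- design_config()
  gc <- seq(0, 1, by = 0.05)
  for (d in c(-200, -350, -450, -100, -550)) {
    for (nt in c(0, 1)) {
      S <- composite_score(position_score(d, cfg), gc, nt, cfg)
      expect_true(all(diff(S) > 0),
                  label = sprintf("monotone at d=%d nt=%d", d, nt))
    }
  }
})

test_that("NT guides never score below matched T guides", {
  cfg <- design_config()
  set.seed(33)
  d <- sample(seq(-800, 100), 200, replace = TRUE)
  gc <- stats::runif(200)
  P <- position_score(d, cfg)
  gap <- composite_score(P, gc, 1, cfg) - composite_score(P, gc, 0, cfg)
  expect_true(all(gap >= 0))
  expect_true(all(gap[P > 0] > 0))
  expect_equal(gap, P * cfg$w_nt)
})

mock_pool <- function(n, d_range = c(-800, 100)) {
  data.frame(
    gene_id = "g", contig_id = "c", gene_strand = "+",
    spacer_seq = vapply(seq_len(n), function(i) random_window(20, 0.5),
                        character(1)),
    pam_seq = "TGG",
    protospacer_strand = sample(c("+", "-"), n, replace = TRUE),
    protospacer_start = sample.int(5000, n),
    d_tss = sample(seq(d_range[1], d_range[2]), n, replace = TRUE),
    strand_class = sample(c("NT", "T"), n, replace = TRUE),
    stringsAsFactors = FALSE)
}

test_that("ranking is a deterministic total order with the documented tie-breaks", {
  cfg <- design_config()
  pool <- data.frame(
    gene_id = "g", contig_id = "c", gene_strand = "+",
    spacer_seq = strrep("A", 20), pam_seq = "AGG",
    protospacer_strand = c("+", "+", "+", "-", "+", "+"),
    protospacer_start = c(100L, 200L, 300L, 300L, 400L, 500L),
    d_tss = c(-210L, -350L, -300L, -300L, -700L, -700L),
    strand_class = c("NT", "NT", "NT", "T", "NT", "T"),
    stringsAsFactors = FALSE)
  pool$gc_fraction <- c(0.6, 0.6, 0.5, 0.5, 0.4, 0.4)
  scored <- score_candidates(apply_filters(pool, cfg), cfg)
  ranked <- rank_candidates(scored, cfg)
  # equal S at -210 and -350: |d+200| prefers -210
  expect_equal(ranked$d_tss[1], -210L)
  # NT before T at identical S, |d+200| and gc
  i_nt <- which(ranked$strand_class == "NT" & ranked$d_tss == -300L)
  i_t <- which(ranked$strand_class == "T" & ranked$d_tss == -300L)
  expect_true(ranked$composite_score[i_nt] > ranked$composite_score[i_t])
  # genuine tie (both beyond cutoff, S = 0, same |d+200| and gc): NT first
  tied <- ranked[ranked$d_tss == -700L, ]
  expect_equal(tied$strand_class, c("NT", "T"))

  set.seed(44)
  pool2 <- mock_pool(150)
  pool2$gc_fraction <- gc_fraction(pool2$spacer_seq)
  scored2 <- score_candidates(apply_filters(pool2, cfg), cfg)
  ranked2 <- rank_candidates(scored2, cfg)
  for (i in 1:5) {
    perm <- scored2[sample.int(nrow(scored2)), ]
    expect_equal(rank_candidates(perm, cfg), ranked2, ignore_attr = TRUE)
  }
  # the comparator keys never increase down the ranked list
  keys <- with(ranked2, cbind(-composite_score,
                              abs(d_tss - cfg$optimum_center),
                              -gc_fraction, strand_class != "NT",
                              protospacer_start, protospacer_strand != "+"))
  for (r in seq_len(nrow(keys) - 1L)) {
    cmp <- sign(keys[r + 1L, ] - keys[r, ])
    first <- cmp[cmp != 0][1]
    expect_true(is.na(first) || first > 0)
  }
})

test_that("flat key = value config files overlay the defaults", {
  path <- write_tmp(c(
    "# comment",
    "upstream_bp = 800",
    "w0 = 0.1", "w_gc = 0.7", "w_nt = 0.2",
    "optimal_window = -400, -100",
    "polyT_filter = drop"
  ), ".cfg")
  cfg <- suppressMessages(read_design_config(path))
  expect_equal(cfg$upstream_bp, 800L)
  expect_equal(cfg$w_gc, 0.7)
  expect_equal(cfg$optimal_window, c(-400, -100))
  expect_equal(cfg$polyT_filter, "drop")
  bad <- write_tmp("nonsense_key = 3", ".cfg")
  expect_error(suppressMessages(read_design_config(bad)), "unknown config key")
})
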