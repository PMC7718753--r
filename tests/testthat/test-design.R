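# End-to-end pipeline and report writers.

test_that("a planted high-GC NT guide in the optimal window ranks first", {
  fx <- make_fixture(n_genes = 2, background_gc = 0, seed = 9,
                     plant_spec = data.frame(
                       d_tss = c(-200L, -500L, -80L),
                       gc_count = c(15L, 12L, 12L),
                       strand_class = c("NT", "NT", "T"),
                       label = c("best", "decoy", "decoy")))
  rep <- design_guides(fx$genome, fx$tss)
  for (g in unique(fx$truth$gene_id)) {
    best <- fx$truth[fx$truth$gene_id == g &
                       fx$truth$expected_rank_hint == "best", ]
    top <- rep$candidates[rep$candidates$gene_id == g &
                            rep$candidates$rank == 1L, ]
    expect_equal(top$spacer_seq, best$spacer_seq)
    expect_equal(top$d_tss, best$d_tss)
    expect_equal(top$strand_class, "NT")
  }
})

test_that("genes without candidates are reported with a reason", {
  genome <- Biostrings::DNAStringSet(c(c1 = strrep("A", 2000)))
  tss <- data.frame(gene_id = "empty", contig_id = "c1",
                    gene_strand = "+", tss_pos = 1000L,
                    stringsAsFactors = FALSE)
  rep <- design_guides(genome, tss)
  expect_equal(nrow(rep$candidates), 0L)
  expect_equal(rep$skipped$reason, "no PAM match")

  tss2 <- rbind(tss, data.frame(gene_id = "lost", contig_id = "nope",
                                gene_strand = "+", tss_pos = 10L))
  rep2 <- design_guides(genome, tss2)
  expect_equal(sort(rep2$skipped$gene_id), c("empty", "lost"))
  expect_true("contig not found" %in% rep2$skipped$reason)

  expect_error(design_guides(Biostrings::DNAStringSet(), tss), "empty genome")
})

test_that("top_n caps the per-gene report", {
  fx <- make_fixture(n_genes = 1, background_gc = 0.5, seed = 21)
  rep <- design_guides(fx$genome, fx$tss, top_n = 5)
  expect_equal(nrow(rep$candidates), 5L)
  expect_equal(rep$candidates$rank, 1:5)
})

test_that("TSV output is deterministic and permutation invariant", {
  fx <- make_fixture(n_genes = 3, background_gc = 0.5, seed = 77)
  cfg <- design_config()
  rep <- design_guides(fx$genome, fx$tss, cfg)

  p1 <- tempfile(fileext = ".tsv"); p2 <- tempfile(fileext = ".tsv")
  write_design_tsv(rep, p1)
  write_design_tsv(design_guides(fx$genome, fx$tss, cfg), p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_equal(length(readLines(p1)), nrow(rep$candidates) + 1L)

  # shuffle TSS rows and contig order
  set.seed(1)
  perm_rep <- design_guides(fx$genome[sample(length(fx$genome))],
                            fx$tss[sample(nrow(fx$tss)), ], cfg)
  p3 <- tempfile(fileext = ".tsv")
  write_design_tsv(perm_rep, p3)
  expect_identical(readLines(p1), readLines(p3))

  # empty report writes a header-only file
  genomeA <- Biostrings::DNAStringSet(c(c1 = strrep("A", 2000)))
  tssA <- data.frame(gene_id = "e", contig_id = "c1", gene_strand = "+",
                     tss_pos = 1000L, stringsAsFactors = FALSE)
  p4 <- tempfile(fileext = ".tsv")
  write_design_tsv(design_guides(genomeA, tssA), p4)
  expect_equal(length(readLines(p4)), 1L)
})

test_that("BED output scales composite scores to [0, 1000] over the protospacer span", {
  fx <- make_panel(3)
  rep <- design_guides(fx$genome, fx$tss, attr(fx, "cfg"))
  path <- tempfile(fileext = ".bed")
  write_design_bed(rep, path)
  bed <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  expect_equal(nrow(bed), nrow(rep$candidates))
  expect_equal(bed$V3 - bed$V2, rep(20L, nrow(bed)))
  expect_equal(bed$V5, as.integer(round(rep$candidates$composite_score * 1000)))
  expect_true(all(bed$V5 >= 0 & bed$V5 <= 1000))
  expect_equal(bed$V2, rep$candidates$protospacer_start)
  expect_equal(bed$V4, sprintf("%s|%d|%s", rep$candidates$gene_id,
                               rep$candidates$rank,
                               rep$candidates$strand_class))

  empty <- design_guides(
    Biostrings::DNAStringSet(c(c1 = strrep("A", 2000))),
    data.frame(gene_id = "e", contig_id = "c1", gene_strand = "+",
               tss_pos = 1000L, stringsAsFactors = FALSE))
  p2 <- tempfile(fileext = ".bed")
  write_design_bed(empty, p2)
  expect_equal(length(readLines(p2)), 0L)
})

test_that("designing on the reverse-complemented genome mirrors the report", {
  fx <- make_fixture(n_genes = 2, background_gc = 0.5, seed = 55)
  cfg <- design_config()
  fwd <- design_guides(fx$genome, fx$tss, cfg)

  lens <- stats::setNames(Biostrings::width(fx$genome), names(fx$genome))
  rc_genome <- Biostrings::reverseComplement(fx$genome)
  names(rc_genome) <- names(fx$genome)
  rc_tss <- fx$tss
  rc_tss$tss_pos <- lens[rc_tss$contig_id] - 1L - rc_tss$tss_pos
  rc_tss$gene_strand <- ifelse(rc_tss$gene_strand == "+", "-", "+")
  rev <- design_guides(rc_genome, rc_tss, cfg)

  expect_equal(nrow(fwd$candidates), nrow(rev$candidates))
  for (g in unique(fx$tss$gene_id)) {
    a <- fwd$candidates[fwd$candidates$gene_id == g, ]
    b <- rev$candidates[rev$candidates$gene_id == g, ]
    expect_equal(a$spacer_seq, b$spacer_seq)
    expect_equal(a$rank, b$rank)
    expect_equal(a$d_tss, b$d_tss)
    expect_equal(a$strand_class, b$strand_class)
    expect_equal(a$composite_score, b$composite_score)
    n <- unname(lens[a$contig_id])
    expect_equal(b$protospacer_start, n - a$protospacer_start - 20L)
  }
})

test_that("score_guide returns a consistent one-row breakdown", {
  bd <- score_guide(paste0(strrep("G", 10), strrep("A", 10)), -200, "NT")
  expect_equal(bd$gc_fraction, 0.5)
  expect_equal(bd$position_score, 1)
  expect_equal(bd$composite_score, 0.7)
  expect_equal(bd$predicted_fold, predicted_fold_activation(0.5))
  expect_error(score_guide("ACGT", -200, "NT"), "20 nt")
})
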