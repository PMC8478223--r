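ev_row <- function(type, start, end, id = "E1", chrom = "chr1")
  list(event_id = id, event_type = type, chrom = chrom,
       start = start, end = end)

test_that("apply_event rewrites the exon chain per event geometry", {
  tx <- transcript_model("T1", "G1", "chr1", "+",
                         cbind(c(0L, 200L, 400L), c(100L, 300L, 500L)))
  # neoskipping of exon 2
  alt <- apply_event(tx, ev_row("NEOSKIPPING", 100L, 400L))
  expect_equal(unname(alt$exons), cbind(c(0L, 400L), c(100L, 500L)))
  expect_equal(junction_positions(alt), 100L)
  # retention of intron 1 fuses the flanking exons
  alt <- apply_event(tx, ev_row("INTRON_RETENTION", 100L, 200L))
  expect_equal(unname(alt$exons), cbind(c(0L, 400L), c(300L, 500L)))
  expect_equal(length(junction_positions(alt)), 1L)
  # 40-nt exonization inside intron 2 gives a 4-exon chain
  alt <- apply_event(tx, ev_row("EXONIZATION", 330L, 370L))
  expect_equal(nrow(alt$exons), 4L)
  expect_equal(unname(alt$exons[3L, ]), c(330L, 370L))
  # alternative acceptor 37 nt into intron 1 extends exon 2 upstream
  alt <- apply_event(tx, ev_row("ALT_SS", 100L, 163L))
  expect_equal(unname(alt$exons[2L, ]), c(163L, 300L))
  # exon-length bookkeeping: change equals the event's indel size
  expect_equal(sum(alt$exons[, 2L] - alt$exons[, 1L]), 300L + 37L)
  # incompatible anchors are rejected
  expect_error(apply_event(tx, ev_row("NEOSKIPPING", 100L, 300L)),
               "incompatible")
  expect_error(apply_event(tx, ev_row("INTRON_RETENTION", 120L, 180L)),
               "incompatible")
})

test_that("longest ORF selection, start anchoring and rescue", {
  expect_equal(longest_orf("CCATGAAATAGCC")$protein, "MK")
  # longest of two ORFs wins
  seq2 <- paste0("ATGAAATAA", "CC", "ATG",
                 paste(rep("GCT", 30), collapse = ""), "TGA")
  orf <- longest_orf(seq2)
  expect_equal(nchar(orf$protein), 31L)
  # anchored start: translation from the given offset when ATG survives
  orf <- longest_orf(seq2, ref_start_offset = 0L)
  expect_equal(orf$protein, "MK")
  expect_false(orf$start_rescued)
  # destroyed start: closest downstream ATG is used and flagged
  orf <- longest_orf(seq2, ref_start_offset = 2L)
  expect_true(orf$start_rescued)
  expect_equal(substr(orf$protein, 1L, 2L), "MA")
  # no in-frame stop: rejected
  expect_null(longest_orf("ATGAAAGCCGCA"))
  expect_null(longest_orf("CCCCCC"))
})

test_that("NMD rule keeps a 50-nt distance and discards beyond it", {
  # single downstream junction; distance measured from last stop base
  expect_false(nmd_filter(orf_stop_offset = 100L, jpos = 150L))  # 50: keep
  expect_true(nmd_filter(orf_stop_offset = 100L, jpos = 151L))   # 51: drop
  expect_true(nmd_filter(100L, c(30L, 160L)))
  expect_false(nmd_filter(100L, integer()))   # stop in the last exon
})

test_that("in-frame exon skipping deletes residues; UTR events yield no protein", {
  # gene: 4 exons; CDS spans exons 1-3, exon 4 and intron 3 are pure 3' UTR
  utr5 <- "CCCCCC"
  e1_seq <- paste0(utr5, "ATG", strrep("GCT", 19))              # 66 nt
  e2_seq <- strrep("CCT", 30)                                   # 90 nt, in frame
  e3_seq <- paste0(strrep("GAA", 15), "TAA", strrep("T", 20))   # 68 nt
  e4_seq <- strrep("T", 60)
  intron <- paste0("GT", strrep("A", 96), "AG")
  chrom <- paste0(e1_seq, intron, e2_seq, intron, e3_seq, intron, e4_seq)
  genome <- c(chr1 = chrom)
  e1 <- c(0L, 66L); e2 <- c(166L, 256L); e3 <- c(356L, 424L)
  e4 <- c(524L, 584L)
  tx <- transcript_model("T1", "G1", "chr1", "+",
                         rbind(e1, e2, e3, e4), cds = c(6L, 404L))
  ref_prot <- paste0("M", strrep("A", 19), strrep("P", 30), strrep("E", 15))
  proteome <- c(T1 = ref_prot)
  ev <- ev_row("NEOSKIPPING", e1[2L], e3[1L])
  pair <- derive_orf_pair(tx, ev, genome, proteome)
  expect_equal(pair$alt_protein,
               paste0("M", strrep("A", 19), strrep("E", 15)))
  expect_false(pair$flags$nmd_discarded)
  # an event confined to the 3' UTR is flagged and yields no altered protein
  utr_ev <- ev_row("ALT_SS", e3[2L], e4[1L] - 20L)
  pair_utr <- derive_orf_pair(tx, utr_ev, genome, proteome)
  expect_true(pair_utr$flags$utr_only)
  expect_null(pair_utr$alt_protein)
})

test_that("frameshifting retention with an early stop is discarded as NMD", {
  b <- small_fixture()
  res <- small_run()
  flags <- vapply(res$orf_pairs, function(p)
    paste(names(Filter(isTRUE, p$flags)), collapse = ","), "")
  # the planted cohort exercises both NMD discards and surviving ORFs
  expect_true(any(flags == "nmd_discarded"))
  expect_true(any(flags == ""))
  for (p in res$orf_pairs) {
    expect_equal(is.null(p$alt_protein),
                 p$flags$utr_only || p$flags$nmd_discarded ||
                   p$flags$no_orf, info = p$event_id)
    if (!is.null(p$alt_protein))
      expect_false(grepl("*", p$alt_protein, fixed = TRUE))
  }
})

test_that("altered proteins equal the independent splice-and-translate oracle", {
  b <- small_fixture()
  res <- small_run()
  ids <- truth_event_ids(b, res$events)
  lay_by_gene <- setNames(b$layout, vapply(b$layout, `[[`, "", "gene_id"))
  genome <- read_genome(b$paths$genome)
  for (te in b$truth$events) {
    eid <- ids[[paste(te$event_type, te$chrom, te$start, te$end)]]
    pair <- res$orf_pairs[[eid]]
    orc <- oracle_orf(genome, lay_by_gene[[te$gene]], te)
    if (is.null(orc$protein)) {
      expect_null(pair$alt_protein, info = eid)
      expect_true(isTRUE(pair$flags[[orc$reason]]),
                  info = paste(eid, orc$reason))
    } else {
      expect_equal(pair$alt_protein, orc$protein, info = eid)
    }
  }
})
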