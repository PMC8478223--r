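# shared toy annotation: one gene, three exons on the plus strand
toy_tx <- function() list(T1 = transcript_model(
  "T1", "G1", "chr1", "+",
  cbind(c(0L, 200L, 400L), c(100L, 300L, 500L)), cds = c(10L, 480L)))

test_that("junction classification separates ALT_SS and NEOSKIPPING", {
  txs <- toy_tx()
  alt <- data.frame(chrom = "chr1", start = 100L, end = 163L,
                    novelty = "novel_acceptor")   # 37 nt into intron 1
  expect_equal(classify_junction(alt, txs),
               list(type = "ALT_SS", gene = "G1"))
  neo <- data.frame(chrom = "chr1", start = 100L, end = 400L,
                    novelty = "novel_connection") # skips exon 2
  expect_equal(classify_junction(neo, txs),
               list(type = "NEOSKIPPING", gene = "G1"))
  both <- data.frame(chrom = "chr1", start = 130L, end = 170L,
                     novelty = "both_novel")
  expect_equal(classify_junction(both, txs)$type, "unclassified")
  # connections across genes are logged and left unclassified
  txs2 <- c(toy_tx(), list(T2 = transcript_model(
    "T2", "G2", "chr1", "+",
    cbind(c(1000L, 1200L), c(1100L, 1300L)))))
  cross <- data.frame(chrom = "chr1", start = 100L, end = 1200L,
                      novelty = "novel_connection")
  expect_message(res <- classify_junction(cross, txs2), "two genes")
  expect_equal(res$type, "unclassified")
})

test_that("exonization detection enforces length, motif and site-read rules", {
  txs <- toy_tx()
  # intron 1 spans [100, 200); plant a 40-nt exon at [130, 170)
  chrom <- paste(rep("A", 600), collapse = "")
  substr(chrom, 129, 130) <- "AG"   # 2 nt upstream of exon (1-based 129-130)
  substr(chrom, 171, 172) <- "GT"   # 2 nt downstream
  genome <- c(chr1 = chrom)
  novel <- data.frame(chrom = "chr1", start = c(100L, 170L),
                      end = c(130L, 200L), strand = "+",
                      max_tumor_reads = c(8L, 11L),
                      novelty = c("novel_acceptor", "novel_donor"))
  jx <- data.frame(chrom = "chr1", start = c(100L, 170L),
                   end = c(130L, 200L), strand = "+", sample = "T",
                   count = c(8L, 11L), stringsAsFactors = FALSE)
  ev <- detect_exonizations(novel, txs, genome, jx, "T")
  expect_equal(nrow(ev), 1L)
  expect_equal(c(ev$start, ev$end), c(130L, 170L))
  expect_equal(ev$support, 8L)
  # order of the junction input does not matter
  ev2 <- detect_exonizations(novel[2:1, ], txs, genome, jx[2:1, ], "T")
  expect_equal(ev2, ev)
  # exactly 5 reads on one site fails the strictly-greater rule
  jx5 <- transform(jx, count = c(5L, 11L))
  expect_equal(nrow(detect_exonizations(novel, txs, genome, jx5, "T")), 0L)
  # breaking the AG..GT context suppresses the call
  genome_bad <- c(chr1 = paste(rep("A", 600), collapse = ""))
  expect_equal(nrow(detect_exonizations(novel, txs, genome_bad, jx, "T")),
               0L)
  # a 501-nt candidate exceeds the length ceiling while 500 does not
  long_tx <- list(T1 = transcript_model(
    "T1", "G1", "chr1", "+", cbind(c(0L, 700L), c(100L, 800L))))
  mk_case <- function(ex_len) {
    ch <- paste(rep("A", 1000), collapse = "")
    es <- 130L; ee <- es + ex_len
    substr(ch, es - 1L, es) <- "AG"
    substr(ch, ee + 1L, ee + 2L) <- "GT"
    nv <- data.frame(chrom = "chr1", start = c(100L, ee), end = c(es, 700L),
                     strand = "+", max_tumor_reads = 9L,
                     novelty = c("novel_acceptor", "novel_donor"))
    j <- data.frame(chrom = "chr1", start = c(100L, ee), end = c(es, 700L),
                    strand = "+", sample = "T", count = 9L)
    detect_exonizations(nv, long_tx, c(chr1 = ch), j, "T")
  }
  expect_equal(nrow(mk_case(500L)), 1L)
  expect_equal(nrow(mk_case(501L)), 0L)
})

test_that("annotated retained introns are enumerated per gene", {
  txs <- list(
    T1 = transcript_model("T1", "G1", "chr1", "+",
                          cbind(c(0L, 200L), c(100L, 300L))),
    T2 = transcript_model("T2", "G1", "chr1", "+", cbind(0L, 300L)))
  expect_equal(enumerate_annotated_ri(txs), "chr1:100-200")
  # single-transcript gene: nothing to retain
  expect_equal(length(enumerate_annotated_ri(txs["T1"])), 0L)
  # brute force on the fixture: an all-pairs transcript comparison
  b <- small_fixture()
  got <- sort(enumerate_annotated_ri(b$transcripts))
  expected <- character()
  gids <- vapply(b$transcripts, `[[`, "", "gene_id")
  for (gid in unique(gids)) {
    fam <- b$transcripts[gids == gid]
    for (tx in fam) {
      n <- nrow(tx$exons)
      if (n < 2L) next
      for (j in seq_len(n - 1L)) {
        i0 <- tx$exons[j, 2L]; i1 <- tx$exons[j + 1L, 1L]
        for (other in fam) {
          if (any(other$exons[, 1L] <= i0 & other$exons[, 2L] >= i1))
            expected <- c(expected,
                          paste0(tx$chrom, ":", i0, "-", i1))
        }
      }
    }
  }
  expect_equal(got, sort(unique(expected)))
})

test_that("intron retention calling applies ratio, body, exclusion and normals", {
  cov <- function(start, sample, body, flank)
    data.frame(chrom = "chr1", start = start, end = start + 100L,
               gene_id = "G1", strand = "+", sample = sample,
               body = body, flank = flank, stringsAsFactors = FALSE)
  base <- rbind(cov(100L, "T", 50L, 100L),    # ratio 0.5 -> emitted
                cov(300L, "T", 5L, 100L),     # ratio 0.05 -> rejected
                cov(500L, "T", 80L, 100L),    # excluded by annotation
                cov(700L, "T", 40L, 100L),    # retained in a normal too
                cov(700L, "N", 35L, 100L))
  ev <- detect_intron_retention(base, exclusions = "chr1:500-600",
                                tumor_samples = "T")
  expect_equal(ev$start, 100L)
  expect_equal(ev$support, 50L)
  # zero flank with body coverage is +Inf ratio, emitted with a message
  expect_message(
    ev0 <- detect_intron_retention(cov(900L, "T", 30L, 0L),
                                   tumor_samples = "T"),
    "zero flank")
  expect_equal(ev0$start, 900L)
})

test_that("empirical add-one p-value matches the closed form and is calibrated", {
  # all 100 draws from a pool of zeros fall below an observed 40
  expect_equal(empirical_significance(40, rep(0, 50), seed = 1L), 1 / 101)
  # observed equal to every draw gives p = 1
  expect_equal(empirical_significance(7, rep(7, 10), seed = 1L), 1)
  expect_warning(p <- empirical_significance(5, numeric(0)), "empty")
  expect_true(is.na(p))
  # null: the observed value is itself a draw from the pool
  set.seed(99L)
  pool <- runif(200, 0, 100)
  ps <- replicate(1000, empirical_significance(sample(pool, 1L), pool))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("event detection is exclusive per anchor and respects alpha", {
  b <- small_fixture()
  res <- small_run()
  ev <- res$events
  # no junction anchor is reported under two types
  anchor <- paste(ev$chrom, ev$start, ev$end)
  expect_false(any(duplicated(anchor)))
  expect_true(all(ev$untested | ev$empirical_p <= 0.05))
  expect_true(all(ev$event_type %in%
                    c("ALT_SS", "NEOSKIPPING", "EXONIZATION",
                      "INTRON_RETENTION")))
  expect_true(all(ev$support >= 8L))
})
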