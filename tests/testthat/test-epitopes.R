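test_that("k-mer enumeration follows the closed form with set semantics", {
  set.seed(7)
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  prot <- paste(sample(aa20, 20L, TRUE), collapse = "")
  k <- enumerate_kmers(prot)
  expect_equal(length(k), sum(vapply(8:11, function(kk)
    nchar(prot) - kk + 1L, 1L)))   # 13+12+11+10 = 46 when repeat-free
  expect_equal(length(k), 46L)
  expect_setequal(enumerate_kmers(strrep("A", 9)),
                  c(strrep("A", 8), strrep("A", 9)))
  expect_equal(enumerate_kmers("SHORTPEP"), "SHORTPEP")
  expect_equal(length(enumerate_kmers("MINIPEP")), 0L)
})

test_that("reference index agrees with brute-force substring scan", {
  b <- small_fixture()
  prots <- vapply(b$truth$genes[1:12], `[[`, "", "protein")
  names(prots) <- paste0("P", seq_along(prots))
  idx <- build_reference_index(prots)
  set.seed(11)
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  queries <- c(
    # positives: real substrings
    vapply(1:50, function(i) {
      p <- prots[[sample(length(prots), 1L)]]
      k <- sample(8:11, 1L); s <- sample(nchar(p) - k + 1L, 1L)
      substr(p, s, s + k - 1L)
    }, ""),
    # random peptides, almost surely absent
    vapply(1:50, function(i)
      paste(sample(aa20, sample(8:11, 1L), TRUE), collapse = ""), ""))
  brute <- vapply(queries, function(q)
    any(vapply(prots, function(p) grepl(q, p, fixed = TRUE), TRUE)), TRUE)
  expect_equal(peptide_in_index(idx, queries), unname(brute))
  expect_error(build_reference_index(character()), "empty")
})

test_that("epitope calls match brute force and respect the nM boundary", {
  ref <- paste0("M", strrep("A", 12), strrep("K", 12), strrep("E", 12))
  alt <- paste0("M", strrep("A", 12), "WWWWWWWWWW",
                strrep("K", 12), strrep("E", 12))   # 10-aa insertion
  proteome <- c(T0 = ref, T9 = paste0(strrep("G", 15), strrep("S", 15)))
  idx <- build_reference_index(proteome)
  pair <- structure(list(event_id = "E1", ref_protein = ref,
                         alt_protein = alt,
                         flags = list(utr_only = FALSE,
                                      start_rescued = FALSE,
                                      nmd_discarded = FALSE,
                                      no_orf = FALSE),
                         ref_affected_aa = NULL), class = "orf_pair")
  cand <- unique(c(enumerate_kmers(ref), enumerate_kmers(alt)))
  aff <- data.frame(peptide = cand, hla_allele = "HLA-A*02:01",
                    affinity_nm = 100, stringsAsFactors = FALSE)
  calls <- call_epitopes(pair, idx, aff)
  brute <- brute_epitopes(pair, proteome, aff)
  expect_equal(calls[c("peptide", "hla_allele", "epitope_class")],
               brute, ignore_attr = TRUE)
  # only peptides overlapping the insertion are NEO candidates
  neo <- calls$peptide[calls$epitope_class == "SPLICING_NEOEPITOPE"]
  expect_true(all(grepl("W", neo)))
  expect_gt(length(neo), 0L)
  # 500.0 nM is called, 500.1 nM is not
  aff2 <- aff
  aff2$affinity_nm <- ifelse(seq_len(nrow(aff2)) %% 2L == 0L, 500.0, 500.1)
  calls2 <- call_epitopes(pair, idx, aff2)
  expect_true(all(calls2$affinity_nm <= 500))
  expect_true(nrow(calls2) < nrow(calls))
  # identical proteins give zero calls
  pair_same <- pair; pair_same$alt_protein <- ref
  expect_equal(nrow(call_epitopes(pair_same, idx, aff)), 0L)
  # lowering the threshold never adds calls
  calls300 <- call_epitopes(pair, idx, aff2, threshold_nm = 300)
  key <- function(x) paste(x$peptide, x$hla_allele, x$epitope_class)
  expect_true(all(key(calls300) %in% key(calls2)))
})

test_that("event-scoped self calls are restricted to the affected window", {
  ref <- paste0(strrep("M", 1), strrep("A", 20), strrep("K", 20),
                strrep("E", 20))
  pair <- structure(list(event_id = "E2", ref_protein = ref,
                         alt_protein = NULL,
                         flags = list(utr_only = FALSE,
                                      start_rescued = FALSE,
                                      nmd_discarded = TRUE,
                                      no_orf = FALSE),
                         ref_affected_aa = c(22L, 41L)),  # the K block
                    class = "orf_pair")
  idx <- build_reference_index(c(other = strrep("G", 30)))
  cand <- enumerate_kmers(ref)
  aff <- data.frame(peptide = cand, hla_allele = "H", affinity_nm = 50)
  calls <- call_epitopes(pair, idx, aff)
  expect_true(all(calls$epitope_class == "SELF_EPITOPE"))
  expect_true(all(grepl("K", calls$peptide)))
  brute <- brute_epitopes(pair, c(other = strrep("G", 30)), aff)
  expect_equal(calls[c("peptide", "hla_allele", "epitope_class")],
               brute, ignore_attr = TRUE)
  # protein scope widens, never narrows, the call set
  calls_prot <- call_epitopes(pair, idx, aff, self_scope = "protein")
  expect_true(all(calls$peptide %in% calls_prot$peptide))
  expect_gt(nrow(calls_prot), nrow(calls))
})

test_that("surrogate affinity predictor is pure and maps scores to [1, 50000]", {
  peps <- c("SIINFEKLM", "AAAAAAAA", "KVAELVHFL", "YLLPAIVHI")
  a <- predict_affinity_surrogate(peps, c("HLA-A*02:01", "HLA-B*07:02"))
  b <- predict_affinity_surrogate(peps, c("HLA-A*02:01", "HLA-B*07:02"))
  expect_identical(a, b)                      # pure function
  expect_equal(nrow(a), length(peps) * 2L)
  expect_true(all(a$affinity_nm >= 1 & a$affinity_nm <= 50000))
  # different alleles score the same peptide differently
  expect_false(all(a$affinity_nm[a$hla_allele == "HLA-A*02:01"] ==
                     a$affinity_nm[a$hla_allele == "HLA-B*07:02"]))
  expect_error(predict_affinity_surrogate("SIINFEKLM", "HLA-Z*99:99"),
               "shipped alleles")
})

test_that("NetMHC-style tables parse across header dialects", {
  f <- tempfile()
  writeLines(c("Pos Peptide Allele Affinity(nM) Rank",
               "1 SIINFEKLM HLA-A*02:01 43.2 0.2",
               "2 AAAAAAAA HLA-A*02:01 12000 44.0"), f)
  rec <- read_netmhc_output(f)
  expect_equal(rec$peptide, c("SIINFEKLM", "AAAAAAAA"))
  expect_equal(rec$affinity_nm, c(43.2, 12000))
  f2 <- tempfile()
  writeLines(c("Peptide\tMHC\tAff(nM)", "KVAELVHFL\tHLA-B*07:02\t250.5"), f2)
  rec2 <- read_netmhc_output(f2)
  expect_equal(rec2$affinity_nm, 250.5)
  expect_equal(rec2$hla_allele, "HLA-B*07:02")
  f3 <- tempfile(); writeLines(character(), f3)
  expect_equal(nrow(read_netmhc_output(f3)), 0L)
  f4 <- tempfile(); writeLines(c("foo bar baz", "1 2 3"), f4)
  expect_error(read_netmhc_output(f4), "dialect")
})
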