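# Independent splice-and-translate oracle: naive loops over the planted
# altered exon chain, deliberately sharing no code with the package
# implementation beyond the standard genetic-code table.

orc_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1L]]), collapse = "")
}

orc_translate <- function(s) {
  n <- nchar(s) %/% 3L
  aa <- character(n)
  for (i in seq_len(n)) {
    cod <- substr(s, 3L * i - 2L, 3L * i)
    aa[i] <- if (grepl("[^ACGT]", cod)) "X" else
      Biostrings::GENETIC_CODE[[cod]]
  }
  paste(aa, collapse = "")
}

# returns list(protein = <string or NULL>, reason = <flag name or NULL>)
oracle_orf <- function(genome, lay, ev, nmd_window = 50L, min_aa = 25L) {
  cds <- lay$cds
  if (!(ev$start < cds[2L] && ev$end > cds[1L]))
    return(list(protein = NULL, reason = "utr_only"))
  ex <- ev$altered_exons
  chromseq <- genome[[lay$chrom]]
  pieces <- character(nrow(ex))
  for (i in seq_len(nrow(ex)))
    pieces[i] <- substr(chromseq, ex[i, 1L] + 1L, ex[i, 2L])
  seq <- paste(pieces, collapse = "")
  if (lay$strand == "-") seq <- orc_revcomp(seq)
  # genomic coordinate of every transcript base, in 5'->3' order
  coords <- integer(0)
  rows <- if (lay$strand == "+") seq_len(nrow(ex)) else rev(seq_len(nrow(ex)))
  for (i in rows) {
    r <- ex[i, 1L]:(ex[i, 2L] - 1L)
    if (lay$strand == "-") r <- rev(r)
    coords <- c(coords, r)
  }
  g0 <- if (lay$strand == "+") cds[1L] else cds[2L] - 1L
  idx <- match(g0, coords)
  destroyed <- is.na(idx)
  if (destroyed) {
    idx <- if (lay$strand == "+") which(coords >= g0)[1L] else
      which(coords <= g0)[1L]
    if (is.na(idx)) return(list(protein = NULL, reason = "no_orf"))
  }
  stops <- c("TAA", "TAG", "TGA")
  scan_orf <- function(s1) {  # 1-based start; NULL or list(protein, end0)
    k <- s1
    prot <- character(0)
    while (k + 2L <= nchar(seq)) {
      cod <- substr(seq, k, k + 2L)
      if (cod %in% stops)
        return(list(protein = paste(prot, collapse = ""), end0 = k + 2L))
      prot <- c(prot, orc_translate(cod))
      k <- k + 3L
    }
    NULL
  }
  orf <- NULL
  if (!destroyed && substr(seq, idx, idx + 2L) == "ATG") {
    orf <- scan_orf(idx)
  } else {
    for (s1 in idx:(nchar(seq) - 5L)) {
      if (substr(seq, s1, s1 + 2L) == "ATG") {
        orf <- scan_orf(s1)
        if (!is.null(orf)) break
      }
    }
  }
  if (is.null(orf) || nchar(orf$protein) < min_aa)
    return(list(protein = NULL, reason = "no_orf"))
  lens <- integer(0)
  for (i in rows) lens <- c(lens, ex[i, 2L] - ex[i, 1L])
  jpos <- cumsum(lens)
  jpos <- jpos[-length(jpos)]
  if (length(jpos) && max(jpos) - orf$end0 > nmd_window)
    return(list(protein = NULL, reason = "nmd_discarded"))
  list(protein = orf$protein, reason = NULL)
}

# brute-force epitope calling: nested substring loops + linear proteome scan
brute_epitopes <- function(pair, proteome, affinities, threshold_nm = 500,
                           kmin = 8L, kmax = 11L) {
  subs <- function(p) {
    out <- character(0)
    if (is.null(p)) return(out)
    for (k in kmin:kmax)
      if (nchar(p) >= k)
        for (i in 1:(nchar(p) - k + 1L))
          out <- c(out, substr(p, i, i + k - 1L))
    unique(out)
  }
  in_proteome <- function(pep) {
    for (pr in proteome) if (grepl(pep, pr, fixed = TRUE)) return(TRUE)
    FALSE
  }
  ref_k <- subs(pair$ref_protein)
  neo <- self <- character(0)
  if (!is.null(pair$alt_protein)) {
    alt_k <- subs(pair$alt_protein)
    for (p in alt_k)
      if (!(p %in% ref_k) && !in_proteome(p)) neo <- c(neo, p)
    self <- setdiff(ref_k, alt_k)
  } else if (isTRUE(pair$flags$nmd_discarded) || isTRUE(pair$flags$no_orf)) {
    w <- pair$ref_affected_aa
    if (is.null(w)) {
      self <- ref_k
    } else {
      for (k in kmin:kmax)
        if (nchar(pair$ref_protein) >= k)
          for (i in 1:(nchar(pair$ref_protein) - k + 1L))
            if (i <= w[2L] && i + k - 1L >= w[1L])
              self <- c(self, substr(pair$ref_protein, i, i + k - 1L))
      self <- unique(self)
    }
  }
  keep <- function(peps, class) {
    rows <- list()
    for (p in peps) {
      if (grepl("X", p, fixed = TRUE)) next
      hit <- affinities[affinities$peptide == p &
                          affinities$affinity_nm <= threshold_nm, ,
                        drop = FALSE]
      if (nrow(hit))
        rows[[length(rows) + 1L]] <-
          data.frame(peptide = p, hla_allele = hit$hla_allele,
                     epitope_class = class, stringsAsFactors = FALSE)
    }
    if (length(rows)) do.call(rbind, rows) else
      data.frame(peptide = character(), hla_allele = character(),
                 epitope_class = character(), stringsAsFactors = FALSE)
  }
  out <- rbind(keep(neo, "SPLICING_NEOEPITOPE"), keep(self, "SELF_EPITOPE"))
  out[order(out$epitope_class, out$peptide, out$hla_allele), , drop = FALSE]
}
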