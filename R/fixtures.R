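# Synthetic cohort generator: a seeded genome + annotation with planted
# splicing alterations of all four types, decoy evidence violating single
# thresholds, and a machine-readable truth table.  Everything downstream is
# testable against these fixtures with no external data.

.surrogate_alleles <- c("HLA-A*01:01", "HLA-A*02:01", "HLA-A*03:01",
                        "HLA-B*07:02", "HLA-B*08:01", "HLA-C*07:01")

.codons_nonstop <- {
  b <- c("A", "C", "G", "T")
  all_cod <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all_cod, c("TAA", "TAG", "TGA"))
}

rand_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                             collapse = "")

#' Generate a synthetic genome and annotation
#'
#' Builds `n_genes` protein-coding genes (3–8 exons of 60–300 nt, introns of
#' at least 80 nt with canonical GT..AG boundaries, one long intron per gene,
#' an annotated CDS with ATG and in-frame stop of at least 60 codons, both
#' strands) laid out on chromosomes with random spacers.  Every fifth gene
#' additionally gets a second, lowly-expressed transcript that retains its
#' first genomic intron, seeding the annotated-retained-intron exclusion
#' set.  Regeneration with the same seed is byte-identical.
#'
#' @param n_genes number of genes (>= 1).
#' @param seed integer RNG seed (single stream for the whole call).
#' @param tumor_samples,normal_samples sample ids of the cohort.
#' @return A fixture bundle: `genome`, `transcripts`, `expression`,
#'   `layout` (per-gene construction record), `truth` (gene-level truth),
#'   sample ids.
#' @export
make_genome <- function(n_genes = 20L, seed = 1L,
                        tumor_samples = "TUMOR1",
                        normal_samples = c("NORM1", "NORM2", "NORM3")) {
  stopifnot(n_genes >= 1L)
  set.seed(seed)
  samples <- c(tumor_samples, normal_samples)
  genes_per_chrom <- 25L
  chrom_parts <- list()
  chrom_pos <- integer()
  layout <- vector("list", n_genes)
  transcripts <- list()
  expr_rows <- list()

  for (g in seq_len(n_genes)) {
    chrom <- paste0("chr", (g - 1L) %/% genes_per_chrom + 1L)
    if (is.null(chrom_parts[[chrom]])) {
      chrom_parts[[chrom]] <- character()
      chrom_pos[chrom] <- 0L
    }
    strand <- sample(c("+", "-"), 1L)
    n_cod <- sample(60:200, 1L)
    utr5 <- rand_nt(sample(30:90, 1L))
    cds_seq <- paste0("ATG",
                      paste(sample(.codons_nonstop, n_cod, TRUE),
                            collapse = ""),
                      sample(c("TAA", "TAG", "TGA"), 1L))
    utr3 <- rand_nt(sample(40:120, 1L))
    mrna <- paste0(utr5, cds_seq, utr3)
    len <- nchar(mrna)
    n_ex <- sample(max(3L, ceiling(len / 300)):min(8L, len %/% 60L), 1L)
    elens <- NULL
    for (try in 1:200) {
      cuts <- sort(sample(60L:(len - 60L), n_ex - 1L))
      cand <- diff(c(0L, cuts, len))
      if (all(cand >= 60L & cand <= 300L)) { elens <- cand; break }
    }
    if (is.null(elens)) {
      elens <- rep(len %/% n_ex, n_ex)
      elens[1L] <- elens[1L] + len - sum(elens)
    }
    ilens <- sample(80:400, n_ex - 1L, TRUE)
    ilens[sample.int(n_ex - 1L, 1L)] <- sample(560:700, 1L)

    cum_e <- cumsum(elens)
    exon_seqs <- substring(mrna, c(1L, head(cum_e, -1L) + 1L), cum_e)
    intron_seqs <- vapply(ilens, function(l)
      paste0("GT", rand_nt(l - 4L), "AG"), "")
    coding <- paste0(paste0(exon_seqs,
                            c(intron_seqs, "")), collapse = "")
    G <- nchar(coding)
    spacer <- rand_nt(sample(200:500, 1L))
    P <- unname(chrom_pos[chrom]) + nchar(spacer)
    chrom_parts[[chrom]] <- c(chrom_parts[[chrom]], spacer,
                              if (strand == "+") coding else revcomp(coding))
    chrom_pos[chrom] <- P + G

    gstart <- cumsum(c(0L, head(elens, -1L) + ilens))  # coding gene coords
    gend <- gstart + elens
    exons <- if (strand == "+") cbind(P + gstart, P + gend) else
      cbind(P + G - gend, P + G - gstart)[rev(seq_len(n_ex)), , drop = FALSE]

    # CDS transcript span -> coding gene coords -> genomic span
    c0 <- nchar(utr5)
    c1 <- c0 + nchar(cds_seq)
    t2g <- function(t) {          # transcript coord -> coding gene coord
      j <- findInterval(t, c(0L, cum_e), rightmost.closed = FALSE)
      gstart[j] + (t - c(0L, cum_e)[j])
    }
    gc0 <- t2g(c0); gc1 <- t2g(c1 - 1L)
    cds <- if (strand == "+") c(P + gc0, P + gc1 + 1L) else
      c(P + G - 1L - gc1, P + G - gc0)

    tid <- paste0("TX", g); gid <- paste0("G", g)
    transcripts[[tid]] <- transcript_model(tid, gid, chrom, strand, exons,
                                           cds = cds)
    has_ri <- g %% 5L == 0L && n_ex >= 3L
    if (has_ri) {
      ri_ex <- exons
      ri_ex[1L, 2L] <- ri_ex[2L, 2L]
      ri_ex <- ri_ex[-2L, , drop = FALSE]
      transcripts[[paste0(tid, ".RI")]] <-
        transcript_model(paste0(tid, ".RI"), gid, chrom, strand, ri_ex)
    }
    protein <- paste0("M", translate_nt(
      substr(cds_seq, 4L, nchar(cds_seq) - 3L)))
    layout[[g]] <- list(gene_id = gid, transcript_id = tid, chrom = chrom,
                        strand = strand, P = P, G = G, n_ex = n_ex,
                        elens = elens, ilens = ilens, gstart = gstart,
                        exons = exons, cds = cds, protein = protein,
                        has_ri = has_ri)
    expr_rows[[tid]] <- runif(length(samples), 3, 40)
    if (has_ri)
      expr_rows[[paste0(tid, ".RI")]] <- runif(length(samples), 0.01, 0.6)
  }
  genome <- vapply(chrom_parts, paste0, "", collapse = "")
  expression <- do.call(rbind, expr_rows)
  colnames(expression) <- samples
  list(genome = genome, transcripts = transcripts, expression = expression,
       layout = layout, tumor_samples = tumor_samples,
       normal_samples = normal_samples,
       truth = list(seed = seed, n_genes = n_genes,
                    genes = lapply(layout, function(l)
                      l[c("gene_id", "transcript_id", "chrom", "strand",
                          "protein")])))
}

# genomic interval of the j-th coding-order intron of a gene layout
layout_intron <- function(l, j) {
  a <- l$gstart[j] + l$elens[j]
  b <- l$gstart[j + 1L]
  if (l$strand == "+") c(l$P + a, l$P + b) else c(l$P + l$G - b, l$P + l$G - a)
}

#' Plant splicing events and decoy evidence into a fixture bundle
#'
#' For each planted event, junction or coverage evidence exceeding every
#' pipeline threshold is written into the tumor sample (junction reads >= 12,
#' exonization site reads >= 8, intron-retention body/flank ratio >= 0.3),
#' on a baseline of annotated-intron evidence present in all samples and in
#' the normal compendium.  Decoy evidence violating one threshold each (a
#' 501-nt exonization, 5-read exonization sites, a compendium-member
#' junction, a 9-read junction, a sub-ratio retention, an
#' annotation-excluded retention) exercises the filters.
#'
#' @param bundle output of [make_genome()].
#' @param n_per_type events planted per type (each in its own gene).
#' @param seed RNG seed for the planting stream.
#' @param decoys also plant the decoy evidence.
#' @return The bundle extended with `junctions`, `coverage`,
#'   `genic_background`, `compendium`, and `truth$events` / `truth$decoys`.
#' @export
plant_events <- function(bundle, n_per_type = 5L, seed = 1L, decoys = TRUE) {
  set.seed(seed)
  lay <- bundle$layout
  tumor <- bundle$tumor_samples
  normals <- bundle$normal_samples
  samples <- c(tumor, normals)
  types <- c("ALT_SS", "NEOSKIPPING", "EXONIZATION", "INTRON_RETENTION")
  eligible <- which(vapply(lay, function(l) !l$has_ri, TRUE) &
                      seq_along(lay) %% 5L != 0L)
  n_decoy_genes <- if (decoys) 5L else 0L
  need <- 4L * n_per_type + n_decoy_genes
  if (length(eligible) < need)
    stop("not enough genes for planting: need ", need, ", have ",
         length(eligible), " eligible; increase n_genes")
  picked <- sample(eligible, need)
  ev_genes <- if (n_per_type > 0L)
    split(picked[seq_len(4L * n_per_type)],
          rep(types, each = n_per_type)) else
    setNames(rep(list(integer()), 4L), types)
  decoy_genes <- if (decoys) tail(picked, n_decoy_genes) else integer()

  # baseline: every annotated intron of every primary transcript, all samples
  jx <- list(); events <- list(); decoy_list <- list()
  for (g in seq_along(lay)) {
    l <- lay[[g]]
    for (j in seq_len(l$n_ex - 1L)) {
      it <- layout_intron(l, j)
      for (s in samples) {
        cnt <- if (s %in% tumor) sample(4:9, 1L) else sample(10:16, 1L)
        jx[[length(jx) + 1L]] <- data.frame(
          chrom = l$chrom, start = it[1L], end = it[2L], strand = l$strand,
          sample = s, count = cnt, stringsAsFactors = FALSE)
      }
    }
  }
  compendium <- unique(unlist(lapply(lay, function(l)
    vapply(seq_len(l$n_ex - 1L), function(j) {
      it <- layout_intron(l, j)
      junction_key(l$chrom, it[1L], it[2L])
    }, "")), use.names = FALSE))

  add_junction <- function(l, start, end, count, sample = tumor[1L]) {
    jx[[length(jx) + 1L]] <<- data.frame(
      chrom = l$chrom, start = start, end = end, strand = l$strand,
      sample = sample, count = count, stringsAsFactors = FALSE)
  }
  motif_edits <- list()
  plant_exon_motifs <- function(l, es, ee) {
    # canonical AG..GT context on the coding strand
    if (l$strand == "+") {
      motif_edits[[length(motif_edits) + 1L]] <<- list(l$chrom, es - 2L, "AG")
      motif_edits[[length(motif_edits) + 1L]] <<- list(l$chrom, ee, "GT")
    } else {
      motif_edits[[length(motif_edits) + 1L]] <<- list(l$chrom, ee, "CT")
      motif_edits[[length(motif_edits) + 1L]] <<- list(l$chrom, es - 2L, "AC")
    }
  }
  coverage <- list(); genic_bg <- list()
  add_coverage <- function(l, j, sample, body, flank) {
    it <- layout_intron(l, j)
    coverage[[length(coverage) + 1L]] <<- data.frame(
      chrom = l$chrom, start = it[1L], end = it[2L], gene_id = l$gene_id,
      strand = l$strand, sample = sample, body = body, flank = flank,
      stringsAsFactors = FALSE)
  }

  plant_one <- function(type, g) {
    l <- lay[[g]]
    if (type == "ALT_SS") {
      j <- sample.int(l$n_ex - 1L, 1L)
      it <- layout_intron(l, j)
      d <- sample(21:45, 1L)
      side <- sample(c("end", "start"), 1L)
      js <- if (side == "end") it[1L] else it[1L] + d
      je <- if (side == "end") it[2L] - d else it[2L]
      support <- sample(12:40, 1L)
      add_junction(l, js, je, support)
      alt_exons <- alter_exons_altss(l$exons, js, je)
      list(event_type = type, gene = l$gene_id, chrom = l$chrom,
           strand = l$strand, start = js, end = je, support = support,
           sample = tumor[1L], altered_exons = alt_exons)
    } else if (type == "NEOSKIPPING") {
      i <- sample.int(l$n_ex - 2L, 1L)
      js <- l$exons[i, 2L]
      je <- l$exons[i + 2L, 1L]
      support <- sample(12:40, 1L)
      add_junction(l, js, je, support)
      list(event_type = type, gene = l$gene_id, chrom = l$chrom,
           strand = l$strand, start = js, end = je, support = support,
           sample = tumor[1L],
           altered_exons = unname(l$exons[-(i + 1L), , drop = FALSE]))
    } else if (type == "EXONIZATION") {
      j <- which.max(l$ilens)
      it <- layout_intron(l, j)
      ilen <- it[2L] - it[1L]
      L <- sample(60:180, 1L)
      off1 <- sample(22:(ilen - L - 24L), 1L)
      es <- it[1L] + off1; ee <- es + L
      plant_exon_motifs(l, es, ee)
      r1 <- sample(8:20, 1L); r2 <- sample(8:20, 1L)
      add_junction(l, it[1L], es, r1)
      add_junction(l, ee, it[2L], r2)
      for (k in 1:10)
        genic_bg[[length(genic_bg) + 1L]] <<- data.frame(
          gene_id = l$gene_id,
          length = as.integer(round(L * runif(1, 0.85, 1.15))),
          count = sample(0:5, 1L), stringsAsFactors = FALSE)
      alt <- insert_exon(l$exons, es, ee)
      list(event_type = type, gene = l$gene_id, chrom = l$chrom,
           strand = l$strand, start = es, end = ee,
           aux_start = it[1L], aux_end = it[2L],
           support = min(r1, r2), sample = tumor[1L], altered_exons = alt)
    } else {  # INTRON_RETENTION
      j <- sample.int(l$n_ex - 1L, 1L)
      body <- sample(30:60, 1L)
      add_coverage(l, j, tumor[1L], body, sample(90:110, 1L))
      it <- layout_intron(l, j)
      gi <- which(l$exons[, 2L] == it[1L])
      alt <- l$exons
      alt[gi, 2L] <- alt[gi + 1L, 2L]
      alt <- alt[-(gi + 1L), , drop = FALSE]
      list(event_type = type, gene = l$gene_id, chrom = l$chrom,
           strand = l$strand, start = it[1L], end = it[2L], support = body,
           sample = tumor[1L], altered_exons = unname(alt))
    }
  }
  for (type in types) for (g in ev_genes[[type]])
    events[[length(events) + 1L]] <- plant_one(type, g)

  # baseline intron coverage for all genes/samples (below calling thresholds),
  # skipping (gene, intron, sample) combinations already planted
  planted_cov <- vapply(coverage, function(r)
    paste(r$chrom, r$start, r$end, r$sample), "")
  for (g in seq_along(lay)) {
    l <- lay[[g]]
    for (j in seq_len(l$n_ex - 1L)) {
      it <- layout_intron(l, j)
      for (s in samples) {
        if (paste(l$chrom, it[1L], it[2L], s) %in% planted_cov) next
        add_coverage(l, j, s, sample(0:2, 1L), sample(80:120, 1L))
      }
    }
  }
  # generic genic-background regions so the table is not event-specific
  for (g in seq_along(lay))
    for (k in 1:3)
      genic_bg[[length(genic_bg) + 1L]] <- data.frame(
        gene_id = lay[[g]]$gene_id,
        length = sample(60:200, 1L), count = sample(0:5, 1L),
        stringsAsFactors = FALSE)

  if (decoys) {
    dg <- decoy_genes
    l <- lay[[dg[1L]]]   # exonization of length 501: fails only max_exon_len
    j <- which.max(l$ilens); it <- layout_intron(l, j)
    if (it[2L] - it[1L] >= 501L + 46L) {
      es <- it[1L] + 22L; ee <- es + 501L
      plant_exon_motifs(l, es, ee)
      add_junction(l, it[1L], es, sample(6:9, 1L))
      add_junction(l, ee, it[2L], sample(6:9, 1L))
      decoy_list[[length(decoy_list) + 1L]] <- list(
        kind = "exonization_len501", chrom = l$chrom, start = es, end = ee)
    }
    l <- lay[[dg[2L]]]   # exonization sites at exactly 5 reads (not > 5)
    j <- which.max(l$ilens); it <- layout_intron(l, j)
    es <- it[1L] + 25L; ee <- es + 100L
    plant_exon_motifs(l, es, ee)
    add_junction(l, it[1L], es, 5L)
    add_junction(l, ee, it[2L], 5L)
    decoy_list[[length(decoy_list) + 1L]] <- list(
      kind = "exonization_reads5", chrom = l$chrom, start = es, end = ee)
    l <- lay[[dg[3L]]]   # strong junction that is in the normal compendium
    it <- layout_intron(l, 1L)
    js <- it[1L]; je <- it[2L] - 30L
    add_junction(l, js, je, 15L)
    compendium <- c(compendium, junction_key(l$chrom, js, je))
    decoy_list[[length(decoy_list) + 1L]] <- list(
      kind = "compendium_member", chrom = l$chrom, start = js, end = je)
    l <- lay[[dg[4L]]]   # junction below the 10-read novelty threshold
    it <- layout_intron(l, 1L)
    add_junction(l, it[1L], it[2L] - 27L, 9L)
    decoy_list[[length(decoy_list) + 1L]] <- list(
      kind = "lowreads9", chrom = l$chrom, start = it[1L],
      end = it[2L] - 27L)
    l <- lay[[dg[5L]]]   # retention below the body/flank ratio threshold
    cov_sub <- which(vapply(coverage, function(r)
      r$gene_id == l$gene_id && r$sample == tumor[1L] &&
        r$start == layout_intron(l, 1L)[1L], TRUE))
    coverage[[cov_sub[1L]]]$body <- 12L
    coverage[[cov_sub[1L]]]$flank <- 400L
    it <- layout_intron(l, 1L)
    decoy_list[[length(decoy_list) + 1L]] <- list(
      kind = "ir_subratio", chrom = l$chrom, start = it[1L], end = it[2L])
    ri_genes <- which(vapply(lay, function(x) isTRUE(x$has_ri), TRUE))
    if (length(ri_genes)) {     # retention matching the annotated-RI set
      l <- lay[[ri_genes[1L]]]
      j_ri <- if (l$strand == "+") 1L else l$n_ex - 1L  # first genomic intron
      cov_sub <- which(vapply(coverage, function(r)
        r$gene_id == l$gene_id && r$sample == tumor[1L] &&
          r$start == layout_intron(l, j_ri)[1L], TRUE))
      coverage[[cov_sub[1L]]]$body <- 50L
      coverage[[cov_sub[1L]]]$flank <- 100L
      it <- layout_intron(l, j_ri)
      decoy_list[[length(decoy_list) + 1L]] <- list(
        kind = "ir_annotated", chrom = l$chrom, start = it[1L], end = it[2L])
    }
  }

  for (e in motif_edits) {
    seq <- bundle$genome[[e[[1L]]]]
    substr(seq, e[[2L]] + 1L, e[[2L]] + 2L) <- e[[3L]]
    bundle$genome[[e[[1L]]]] <- seq
  }
  bundle$junctions <- do.call(rbind, jx)
  bundle$coverage <- do.call(rbind, coverage)
  bundle$genic_background <- do.call(rbind, genic_bg)
  bundle$compendium <- unique(compendium)
  bundle$truth$events <- events
  bundle$truth$decoys <- decoy_list
  bundle
}

# generator-side edit of an exon matrix for a planted alternative splice site
alter_exons_altss <- function(exons, js, je) {
  i_d <- match(js, exons[, 2L])
  i_a <- match(je, exons[, 1L])
  if (!is.na(i_d) && is.na(i_a)) {
    k <- which(exons[, 1L] > js)[1L]
    exons[k, 1L] <- je
  } else {
    k <- tail(which(exons[, 2L] < je), 1L)
    exons[k, 2L] <- js
  }
  unname(exons)
}

insert_exon <- function(exons, es, ee) {
  i <- which(exons[, 2L] <= es)
  out <- rbind(exons[i, , drop = FALSE], c(es, ee),
               exons[setdiff(seq_len(nrow(exons)), i), , drop = FALSE])
  unname(out[order(out[, 1L]), , drop = FALSE])
}

#' Build an MS peptide list and affinity overrides for validation tests
#'
#' Creates an MS-identified peptide list in which a chosen fraction of the
#' high-affinity pool (and a background fraction of the general pool) is
#' present, plus random decoy peptides, and a matching affinity table that
#' makes the designated high-affinity peptides strong binders.
#'
#' @param peptides_high high-affinity candidate peptides.
#' @param peptides_all the full candidate pool.
#' @param enrichment MS-identification rate in the high-affinity pool.
#' @param background rate in the rest of the pool.
#' @param n_decoys random decoy peptides appended to the MS list.
#' @param allele allele used in the override table.
#' @param seed RNG seed.
#' @return List with `ms_list` and `affinities` (data.frame `peptide`,
#'   `hla_allele`, `affinity_nm`).
#' @export
make_ms_and_affinity <- function(peptides_high, peptides_all,
                                 enrichment = 0.2, background = 0.02,
                                 n_decoys = 50L,
                                 allele = "HLA-A*02:01", seed = 1L) {
  set.seed(seed)
  rest <- setdiff(peptides_all, peptides_high)
  ms <- c(peptides_high[runif(length(peptides_high)) < enrichment],
          rest[runif(length(rest)) < background])
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  dec <- vapply(seq_len(n_decoys), function(i)
    paste(sample(aa20, 9L, TRUE), collapse = ""), "")
  hi <- unique(peptides_high)
  lo <- setdiff(unique(peptides_all), hi)
  aff <- data.frame(
    peptide = c(hi, lo),
    hla_allele = rep(allele, length(hi) + length(lo)),
    affinity_nm = c(round(runif(length(hi), 5, 450), 1),
                    round(runif(length(lo), 600, 45000), 1)),
    stringsAsFactors = FALSE)
  list(ms_list = unique(c(ms, dec)), affinities = aff)
}

#' Write a complete synthetic input set with planted truth
#'
#' Drives [make_genome()], [plant_events()] and [make_ms_and_affinity()] and
#' writes every pipeline input to `dir`: `genome.fa`, `annotation.gtf`,
#' `expression.tsv`, one STAR-style `<sample>.SJ.out.tab` per sample,
#' `intron_coverage.tsv`, `genic_background.tsv`, `normal_junctions.tsv`
#' (the compendium), `hla.tsv`, `ms_peptides.txt`, `biomarkers.tsv` and
#' `truth.json`.  Identical seeds give byte-identical files.
#'
#' @param dir output directory (created).
#' @param n_genes genes in the synthetic genome (default scales with
#'   `n_per_type`).
#' @param n_per_type planted events per type.
#' @param seed master seed; the generator derives one stream per stage.
#' @param decoys plant decoy evidence too.
#' @return Invisibly, the fixture bundle (with `$paths`).
#' @export
generate_fixtures <- function(dir, n_per_type = 5L,
                              n_genes = 5L * n_per_type + 10L,
                              seed = 1L, decoys = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  bundle <- make_genome(n_genes, seed = seed)
  bundle <- plant_events(bundle, n_per_type, seed = seed + 1L,
                         decoys = decoys)
  p <- function(f) file.path(dir, f)
  write_genome(bundle$genome, p("genome.fa"))
  write_gtf(bundle$transcripts, p("annotation.gtf"))
  expr <- data.frame(transcript_id = rownames(bundle$expression),
                     bundle$expression, check.names = FALSE)
  write.table(expr, p("expression.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  samples <- c(bundle$tumor_samples, bundle$normal_samples)
  sj_paths <- setNames(character(length(samples)), samples)
  for (s in samples) {
    sj <- bundle$junctions[bundle$junctions$sample == s, , drop = FALSE]
    sj <- sj[order(sj$chrom, sj$start, sj$end), , drop = FALSE]
    lines <- sprintf("%s\t%d\t%d\t%d\t0\t0\t%d\t0\t20",
                     sj$chrom, sj$start + 1L, sj$end,
                     match(sj$strand, c(".", "+", "-")) - 1L, sj$count)
    sj_paths[s] <- p(paste0(s, ".SJ.out.tab"))
    writeLines(lines, sj_paths[s])
  }
  cov <- bundle$coverage
  cov <- cov[order(cov$chrom, cov$start, cov$sample), , drop = FALSE]
  cov$start <- cov$start + 1L
  write.table(cov, p("intron_coverage.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(bundle$genic_background, p("genic_background.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  comp <- do.call(rbind, strsplit(sort(bundle$compendium), "[:-]"))
  write.table(data.frame(chrom = comp[, 1L],
                         start = as.integer(comp[, 2L]) + 1L,
                         end = as.integer(comp[, 3L])),
              p("normal_junctions.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  set.seed(seed + 2L)
  hla <- data.frame(sample = bundle$tumor_samples[1L],
                    allele = sample(.surrogate_alleles, 3L))
  write.table(hla, p("hla.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  # MS list: some reference-protein 9-mers (candidate self peptides) + decoys
  prot <- vapply(bundle$truth$genes, `[[`, "", "protein")
  pool <- unlist(lapply(prot[seq_len(min(10L, length(prot)))], function(x)
    if (nchar(x) >= 9L)
      substring(x, sample(nchar(x) - 8L, min(5L, nchar(x) - 8L)))),
    use.names = FALSE)
  pool <- substr(pool, 1L, 9L)
  ms <- make_ms_and_affinity(pool[seq_len(length(pool) %/% 2L)], pool,
                             seed = seed + 3L)
  writeLines(sort(ms$ms_list), p("ms_peptides.txt"))
  ev_genes <- vapply(bundle$truth$events, `[[`, "", "gene")
  all_genes <- vapply(bundle$layout, `[[`, "", "gene_id")
  set.seed(seed + 4L)
  bm <- rbind(
    data.frame(set_id = "SET_A",
               gene = unique(c(head(ev_genes, 10L),
                               sample(all_genes, 5L)))),
    data.frame(set_id = "SET_B", gene = sample(all_genes, 8L)))
  write.table(bm, p("biomarkers.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  truth_out <- bundle$truth
  jsonlite::write_json(truth_out, p("truth.json"), auto_unbox = TRUE,
                       digits = NA)
  bundle$paths <- list(
    genome = p("genome.fa"), gtf = p("annotation.gtf"),
    expression = p("expression.tsv"), sj = as.list(sj_paths),
    coverage = p("intron_coverage.tsv"),
    genic_background = p("genic_background.tsv"),
    compendium = p("normal_junctions.tsv"), hla = p("hla.tsv"),
    ms = p("ms_peptides.txt"), biomarkers = p("biomarkers.tsv"),
    truth = p("truth.json"))
  invisible(bundle)
}
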