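#' Classify a novel junction as aberrant splice site or neoskipping
#'
#' A junction with exactly one annotated splice site is an aberrant
#' (alternative) splice site (`ALT_SS`).  A junction whose two sites are both
#' annotated exon boundaries of the same gene, which is not itself an
#' annotated intron, and which spans at least one annotated exon, is a
#' neoskipping (`NEOSKIPPING`).  Anything else (both sites novel, cross-gene
#' connections) is `unclassified`; both-novel junctions are the raw material
#' for exonization pairing (see [detect_exonizations()]).
#'
#' @param junction one row of the table returned by [filter_novel()] (needs
#'   `chrom`, `start`, `end`, `novelty`).
#' @param transcripts annotation (named list of transcript models) or a
#'   prebuilt internal index.
#' @return List with `type` (`"ALT_SS"`, `"NEOSKIPPING"` or
#'   `"unclassified"`) and `gene` (`NA` when unclassified).
#' @export
classify_junction <- function(junction, transcripts) {
  idx <- if (is.list(transcripts) && !is.null(transcripts$donor_sites))
    transcripts else annotation_index(transcripts)
  dkey <- paste0(junction$chrom, ":", junction$start)
  akey <- paste0(junction$chrom, ":", junction$end)
  dgene <- idx$donor_gene[dkey]
  agene <- idx$acceptor_gene[akey]
  unclassified <- list(type = "unclassified", gene = NA_character_)
  if (junction$novelty %in% c("novel_donor", "novel_acceptor")) {
    gene <- if (junction$novelty == "novel_donor") agene else dgene
    # the novel site must still fall inside the host gene's span
    gs <- idx$gene_span[idx$gene_span$gene == gene, , drop = FALSE]
    pos <- if (junction$novelty == "novel_donor") junction$start else junction$end
    if (nrow(gs) == 0L || pos < gs$start || pos > gs$end) {
      message("novel site of junction ", junction$chrom, ":", junction$start,
              "-", junction$end, " outside gene span; unclassified")
      return(unclassified)
    }
    return(list(type = "ALT_SS", gene = unname(gene)))
  }
  if (identical(unname(junction$novelty), "novel_connection")) {
    if (is.na(dgene) || is.na(agene) || dgene != agene) {
      message("junction ", junction$chrom, ":", junction$start, "-",
              junction$end, " connects two genes; unclassified")
      return(unclassified)
    }
    ex <- idx$exon_tbl
    skipped <- ex$gene == dgene & ex$chrom == junction$chrom &
      ex$start > junction$start & ex$end < junction$end
    if (any(skipped))
      return(list(type = "NEOSKIPPING", gene = unname(dgene)))
  }
  unclassified
}

#' Detect de novo exonizations
#'
#' Pairs of tumor-specific junctions splicing from the annotated donor and to
#' the annotated acceptor of the same annotated intron define a candidate new
#' internal exon between the left junction's acceptor and the right
#' junction's donor.  A pair is emitted when the exon is at most
#' `max_exon_len` nt, shows the canonical AG (immediately upstream) .. GT
#' (immediately downstream) context on the gene's coding strand, and each
#' flanking junction is validated by strictly more than `min_site_reads`
#' reads in the sample.
#'
#' @param novel novel-junction table from [filter_novel()].
#' @param transcripts annotation or prebuilt index.
#' @param genome named character vector from [read_genome()].
#' @param junctions long-format per-sample junction table (for per-sample
#'   read validation).
#' @param tumor_samples samples in which events are called.
#' @param max_exon_len maximum new-exon length, default 500 nt.
#' @param min_site_reads per-site read threshold, strictly greater than,
#'   default 5.
#' @return data.frame of `EXONIZATION` events: one row per (new exon, tumor
#'   sample) with both flanking junction coordinates and `support` = the
#'   smaller of the two junction read counts.
#' @export
detect_exonizations <- function(novel, transcripts, genome, junctions,
                                tumor_samples, max_exon_len = 500L,
                                min_site_reads = 5L) {
  idx <- if (is.list(transcripts) && !is.null(transcripts$donor_sites))
    transcripts else annotation_index(transcripts)
  out <- list()
  if (nrow(novel) == 0L) return(empty_events())
  jkey <- junction_key(junctions$chrom, junctions$start, junctions$end)
  intr <- idx$intron_tbl
  for (i in seq_len(nrow(intr))) {
    it <- intr[i, ]
    lefts <- novel[novel$chrom == it$chrom & novel$start == it$start &
                     novel$end > it$start & novel$end < it$end, , drop = FALSE]
    rights <- novel[novel$chrom == it$chrom & novel$end == it$end &
                      novel$start > it$start & novel$start < it$end, ,
                    drop = FALSE]
    if (nrow(lefts) == 0L || nrow(rights) == 0L) next
    for (li in seq_len(nrow(lefts))) for (ri in seq_len(nrow(rights))) {
      ex_start <- lefts$end[li]
      ex_end <- rights$start[ri]
      len <- ex_end - ex_start
      if (len <= 0L || len > max_exon_len) next
      if (!exon_has_canonical_context(genome, it$chrom, ex_start, ex_end,
                                      it$strand)) next
      lkey <- junction_key(it$chrom, lefts$start[li], lefts$end[li])
      rkey <- junction_key(it$chrom, rights$start[ri], rights$end[ri])
      for (s in tumor_samples) {
        cl <- sum(junctions$count[jkey == lkey & junctions$sample == s])
        cr <- sum(junctions$count[jkey == rkey & junctions$sample == s])
        if (cl > min_site_reads && cr > min_site_reads) {
          out[[length(out) + 1L]] <- data.frame(
            event_type = "EXONIZATION", gene_id = it$gene, sample_id = s,
            chrom = it$chrom, start = ex_start, end = ex_end,
            aux_start = lefts$start[li], aux_end = rights$end[ri],
            strand = it$strand, support = min(cl, cr),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) return(empty_events())
  ev <- do.call(rbind, out)
  # the same intron can be annotated in several transcripts; deduplicate
  ev <- ev[!duplicated(ev[c("chrom", "start", "end", "sample_id")]), ,
           drop = FALSE]
  rownames(ev) <- NULL
  ev
}

# AG immediately 5' and GT immediately 3' of the exon on the coding strand
exon_has_canonical_context <- function(genome, chrom, ex_start, ex_end,
                                       strand) {
  if (strand == "+") {
    up <- genome_slice(genome, chrom, ex_start - 2L, ex_start)
    dn <- genome_slice(genome, chrom, ex_end, ex_end + 2L)
  } else {
    up <- revcomp(genome_slice(genome, chrom, ex_end, ex_end + 2L))
    dn <- revcomp(genome_slice(genome, chrom, ex_start - 2L, ex_start))
  }
  up == "AG" && dn == "GT"
}

#' Annotated retained-intron exclusion set
#'
#' An annotated retained intron exists wherever one transcript's intron is
#' fully exonic in another transcript of the same gene (the annotation
#' already encodes the retention as an isoform).  Intron-retention calls
#' matching this set are not tumor specific and are excluded.
#'
#' @param transcripts named list of transcript models.
#' @return Character vector of intron keys (`chrom:start-end`, internal
#'   coordinates).
#' @export
enumerate_annotated_ri <- function(transcripts) {
  idx <- annotation_index(transcripts)
  intr <- idx$intron_tbl
  if (nrow(intr) == 0L) return(character())
  ex <- idx$exon_tbl
  keep <- vapply(seq_len(nrow(intr)), function(i) {
    any(ex$gene == intr$gene[i] & ex$chrom == intr$chrom[i] &
          ex$start <= intr$start[i] & ex$end >= intr$end[i])
  }, TRUE)
  unique(junction_key(intr$chrom[keep], intr$start[keep], intr$end[keep]))
}

#' Call intron retention from body/flank coverage
#'
#' A coverage-ratio caller: an intron is called retained in a sample when its
#' body read count is at least `min_body_reads` and the body/flank ratio is
#' at least `min_ratio`.  Introns in the annotated-RI exclusion set, and
#' introns called retained in any normal sample by the same thresholds, are
#' removed (not tumor specific).
#'
#' @param coverage data.frame with columns `chrom`, `start`, `end` (intron,
#'   internal coordinates), `gene_id`, `strand`, `sample`, `body`, `flank`.
#' @param exclusions annotated-RI keys from [enumerate_annotated_ri()].
#' @param tumor_samples samples in which events are called; remaining
#'   samples act as matched normals.
#' @param min_ratio minimum body/flank ratio, default 0.1.
#' @param min_body_reads minimum intron-body reads, default 10.
#' @return data.frame of `INTRON_RETENTION` events (`support` = body reads).
#' @export
detect_intron_retention <- function(coverage, exclusions = character(),
                                    tumor_samples = unique(coverage$sample),
                                    min_ratio = 0.1, min_body_reads = 10L) {
  if (is.null(coverage) || nrow(coverage) == 0L) return(empty_events())
  key <- junction_key(coverage$chrom, coverage$start, coverage$end)
  ratio <- ifelse(coverage$flank == 0 & coverage$body > 0, Inf,
                  coverage$body / coverage$flank)
  if (any(is.infinite(ratio)))
    message(sum(is.infinite(ratio)),
            " intron(s) with zero flank coverage: ratio treated as +Inf")
  called <- coverage$body >= min_body_reads & ratio >= min_ratio
  normal_keys <- unique(key[called & !(coverage$sample %in% tumor_samples)])
  sel <- called & coverage$sample %in% tumor_samples &
    !(key %in% exclusions) & !(key %in% normal_keys)
  if (!any(sel)) return(empty_events())
  ev <- data.frame(event_type = "INTRON_RETENTION",
                   gene_id = coverage$gene_id[sel],
                   sample_id = coverage$sample[sel],
                   chrom = coverage$chrom[sel],
                   start = coverage$start[sel], end = coverage$end[sel],
                   aux_start = NA_integer_, aux_end = NA_integer_,
                   strand = coverage$strand[sel],
                   support = as.integer(coverage$body[sel]),
                   stringsAsFactors = FALSE)
  rownames(ev) <- NULL
  ev
}

empty_events <- function() {
  data.frame(event_type = character(), gene_id = character(),
             sample_id = character(), chrom = character(), start = integer(),
             end = integer(), aux_start = integer(), aux_end = integer(),
             strand = character(), support = integer(),
             stringsAsFactors = FALSE)
}

#' Empirical read-support significance
#'
#' Controls for locus-wide pre-mRNA processing noise: the event's read
#' support is compared with `n_random` values drawn with replacement from a
#' background pool of read supports from the same gene (other junctions for
#' splice-site/neoskipping events, similar-length genic regions for
#' exonizations, other intron bodies for retention).  The one-sided add-one
#' empirical p-value is
#' `(1 + #draws >= observed) / (1 + n_random)`.
#'
#' @param observed event read support.
#' @param background_pool numeric vector of same-gene background supports.
#' @param n_random number of background draws, default 100.
#' @param seed optional integer seed for the draws (local RNG scope).
#' @return p-value in `(0, 1]`, or `NA` with a warning when the pool is
#'   empty (the caller keeps such events flagged as untested).
#' @export
empirical_significance <- function(observed, background_pool,
                                   n_random = 100L, seed = NULL) {
  if (length(background_pool) == 0L) {
    warning("empty background pool: event untested")
    return(NA_real_)
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
  }
  draws <- sample(background_pool, n_random, replace = TRUE)
  (1 + sum(draws >= observed)) / (1 + n_random)
}

#' Detect all tumor-specific splicing events
#'
#' The full junction-evidence stage: clusters junctions, normalizes and
#' applies the sample QC filter, selects novel tumor-specific junctions,
#' classifies them into the four event types, and scores every event with
#' the empirical same-gene background test.  Events with `empirical_p >
#' alpha` are dropped; events whose background pool is empty are kept with
#' `untested = TRUE`.
#'
#' @param junctions long-format per-sample junction table.
#' @param transcripts named list of transcript models.
#' @param genome named character vector from [read_genome()].
#' @param normals compendium keys from [read_normal_compendium()].
#' @param tumor_samples character vector of tumor sample ids.
#' @param intron_coverage optional coverage table for
#'   [detect_intron_retention()].
#' @param genic_background optional data.frame (`gene_id`, `length`,
#'   `count`) of genic-region read counts used as exonization backgrounds
#'   (regions within ±20% of the new exon's length).
#' @param config a [pipeline_config()].
#' @return data.frame of events: `event_id`, `event_type`, `gene_id`,
#'   `sample_id`, `chrom`, `start`, `end`, `aux_start`, `aux_end`, `strand`,
#'   `support`, `empirical_p`, `untested`.
#' @export
detect_events <- function(junctions, transcripts, genome,
                          normals = character(),
                          tumor_samples = unique(junctions$sample),
                          intron_coverage = NULL, genic_background = NULL,
                          config = pipeline_config()) {
  idx <- annotation_index(transcripts)
  clustered <- cluster_junctions(junctions, config$min_cluster_reads,
                                 config$min_fraction)
  keep_samples <- if (nrow(clustered))
    sample_qc_filter(normalize_cluster(clustered)) else character()
  clustered <- clustered[clustered$sample %in% keep_samples, , drop = FALSE]
  tumor_samples <- intersect(tumor_samples, keep_samples)

  novel <- filter_novel(clustered, idx, normals, tumor_samples,
                        config$novel_min_reads)
  # exonization flanks are validated at >min_site_reads (their own, stricter
  # rule), not at the 10-read novelty threshold
  novel_exo <- filter_novel(clustered, idx, normals, tumor_samples,
                            min_reads = config$min_site_reads + 1L)
  exo <- detect_exonizations(novel_exo, idx, genome, clustered,
                             tumor_samples, config$max_exon_len,
                             config$min_site_reads)
  consumed <- character()
  if (nrow(exo)) {
    consumed <- c(junction_key(exo$chrom, exo$aux_start, exo$start),
                  junction_key(exo$chrom, exo$end, exo$aux_end))
  }

  jkey_all <- junction_key(clustered$chrom, clustered$start, clustered$end)
  rows <- list(exo)
  if (nrow(novel)) {
    nkey <- junction_key(novel$chrom, novel$start, novel$end)
    for (i in seq_len(nrow(novel))) {
      if (nkey[i] %in% consumed) next
      cls <- classify_junction(novel[i, ], idx)
      if (cls$type == "unclassified") next
      strand <- gene_strand(idx, cls$gene)
      for (s in tumor_samples) {
        cnt <- sum(clustered$count[jkey_all == nkey[i] &
                                     clustered$sample == s])
        if (cnt < 1L) next
        rows[[length(rows) + 1L]] <- data.frame(
          event_type = cls$type, gene_id = cls$gene, sample_id = s,
          chrom = novel$chrom[i], start = novel$start[i],
          end = novel$end[i], aux_start = NA_integer_,
          aux_end = NA_integer_, strand = strand, support = cnt,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!is.null(intron_coverage) && nrow(intron_coverage)) {
    excl <- enumerate_annotated_ri(transcripts)
    rows[[length(rows) + 1L]] <- detect_intron_retention(
      intron_coverage, excl, tumor_samples,
      config$ir_min_ratio, config$ir_min_body_reads)
  }
  ev <- do.call(rbind, rows)
  if (is.null(ev) || nrow(ev) == 0L) {
    ev <- empty_events()
    ev$event_id <- character()
    ev$empirical_p <- numeric()
    ev$untested <- logical()
    return(ev)
  }
  ev <- ev[order(ev$event_type, ev$chrom, ev$start, ev$end, ev$sample_id), ,
           drop = FALSE]
  rownames(ev) <- NULL

  # same-gene background pools for the empirical test
  jgene <- junction_gene(idx, clustered)
  set.seed(config$seed %% .Machine$integer.max)
  p <- numeric(nrow(ev))
  untested <- logical(nrow(ev))
  ekey <- junction_key(ev$chrom, ev$start, ev$end)
  for (i in seq_len(nrow(ev))) {
    pool <- switch(
      ev$event_type[i],
      ALT_SS = ,
      NEOSKIPPING = clustered$count[
        !is.na(jgene) & jgene == ev$gene_id[i] &
          clustered$sample == ev$sample_id[i] & jkey_all != ekey[i]],
      EXONIZATION = {
        if (is.null(genic_background)) numeric() else {
          len <- ev$end[i] - ev$start[i]
          genic_background$count[
            genic_background$gene_id == ev$gene_id[i] &
              abs(genic_background$length - len) <= 0.2 * len]
        }
      },
      INTRON_RETENTION = {
        ck <- junction_key(intron_coverage$chrom, intron_coverage$start,
                           intron_coverage$end)
        intron_coverage$body[
          intron_coverage$gene_id == ev$gene_id[i] &
            intron_coverage$sample == ev$sample_id[i] & ck != ekey[i]]
      })
    if (length(pool) == 0L) {
      p[i] <- NA_real_
      untested[i] <- TRUE
    } else {
      p[i] <- suppressWarnings(
        empirical_significance(ev$support[i], pool, config$n_random))
    }
  }
  ev$empirical_p <- p
  ev$untested <- untested
  ev <- ev[untested | (!is.na(p) & p <= config$alpha), , drop = FALSE]
  rownames(ev) <- NULL
  ev$event_id <- sprintf("EV%05d", seq_len(nrow(ev)))
  ev[, c("event_id", setdiff(names(ev), "event_id"))]
}

gene_strand <- function(idx, gene) {
  s <- idx$gene_span$strand[idx$gene_span$gene == gene]
  if (length(s)) s[1L] else "."
}

# assign each junction row a gene by donor/acceptor site, else by span overlap
junction_gene <- function(idx, junctions) {
  dg <- idx$donor_gene[paste0(junctions$chrom, ":", junctions$start)]
  ag <- idx$acceptor_gene[paste0(junctions$chrom, ":", junctions$end)]
  g <- ifelse(!is.na(dg), dg, ag)
  miss <- which(is.na(g))
  if (length(miss)) {
    gs <- idx$gene_span
    for (i in miss) {
      hit <- gs$gene[gs$chrom == junctions$chrom[i] &
                       gs$start <= junctions$start[i] &
                       gs$end >= junctions$end[i]]
      if (length(hit)) g[i] <- hit[1L]
    }
  }
  unname(g)
}

#' Write events as TSV / BED12
#'
#' The TSV carries internal columns with 1-based inclusive coordinates; the
#' BED12 view (0-based half-open, per BED convention) is convenient for
#' genome-browser inspection.
#'
#' @param events events table from [detect_events()].
#' @param path output file.
#' @export
write_events_tsv <- function(events, path) {
  out <- events
  out$start <- out$start + 1L
  out$aux_start <- out$aux_start + 1L
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  ev <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  ev$start <- ev$start - 1L
  ev$aux_start <- ev$aux_start - 1L
  ev
}

#' @rdname write_events_tsv
#' @export
write_events_bed <- function(events, path) {
  col <- c(ALT_SS = "255,0,0", NEOSKIPPING = "0,0,255",
           EXONIZATION = "0,128,0", INTRON_RETENTION = "128,0,128")
  lines <- sprintf("%s\t%d\t%d\t%s|%s\t%d\t%s\t%d\t%d\t%s\t1\t%d\t0",
                   events$chrom, events$start, events$end,
                   events$event_id, events$event_type,
                   pmin(events$support, 1000L), events$strand,
                   events$start, events$end, col[events$event_type],
                   events$end - events$start)
  writeLines(lines, path)
  invisible(path)
}
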