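#' Apply a splicing event to a reference transcript scaffold
#'
#' Rewrites the reference exon chain according to the event geometry:
#' `ALT_SS` moves the affected exon boundary to the novel splice site
#' (extending into the intron or truncating into the exon); `NEOSKIPPING`
#' removes the exons spanned by the junction and joins the flanking exons;
#' `EXONIZATION` inserts the new exon into its host intron;
#' `INTRON_RETENTION` fuses the intron into its two flanking exons.
#'
#' @param tx reference [transcript_model()].
#' @param event one event row (list or one-row data.frame with
#'   `event_type`, `chrom`, `start`, `end`, and `event_id`).
#' @return An `altered_transcript`: like a transcript model but carrying
#'   `base_transcript_id` and `event_id`; usable with [spliced_sequence()].
#' @export
apply_event <- function(tx, event) {
  if (event$chrom != tx$chrom)
    stop("event on ", event$chrom, " incompatible with transcript on ",
         tx$chrom)
  ex <- tx$exons
  n <- nrow(ex)
  js <- event$start; je <- event$end
  bad <- function(why) stop("event ", event$event_id, " (",
                            event$event_type, ") incompatible with ",
                            tx$transcript_id, ": ", why)
  new_ex <- switch(
    as.character(event$event_type),
    ALT_SS = {
      i_d <- match(js, ex[, 2L])   # annotated donor side?
      i_a <- match(je, ex[, 1L])   # annotated acceptor side?
      if (!is.na(i_d) && is.na(i_a)) {
        if (i_d == n) bad("donor on last exon")
        if (je <= ex[i_d, 2L] || je >= ex[i_d + 1L, 2L])
          bad("novel acceptor outside the following intron/exon")
        ex[i_d + 1L, 1L] <- je
        ex
      } else if (is.na(i_d) && !is.na(i_a)) {
        if (i_a == 1L) bad("acceptor on first exon")
        if (js >= ex[i_a, 1L] || js <= ex[i_a - 1L, 1L])
          bad("novel donor outside the preceding intron/exon")
        ex[i_a - 1L, 2L] <- js
        ex
      } else bad("junction does not have exactly one annotated site on tx")
    },
    NEOSKIPPING = {
      i <- match(js, ex[, 2L]); j <- match(je, ex[, 1L])
      if (is.na(i) || is.na(j)) bad("junction sites not on exon boundaries")
      if (j <= i + 1L) bad("no exon skipped")
      ex[c(seq_len(i), j:n), , drop = FALSE]
    },
    EXONIZATION = {
      i <- which(ex[-n, 2L] <= js & ex[-1L, 1L] >= je)
      if (!length(i)) bad("new exon not inside an intron of tx")
      i <- i[1L]
      rbind(ex[seq_len(i), , drop = FALSE], c(js, je),
            ex[(i + 1L):n, , drop = FALSE])
    },
    INTRON_RETENTION = {
      i <- match(js, ex[, 2L])
      if (is.na(i) || i == n || ex[i + 1L, 1L] != je)
        bad("interval is not an intron of tx")
      ex[i, 2L] <- ex[i + 1L, 2L]
      ex[-(i + 1L), , drop = FALSE]
    },
    bad("unknown event type"))
  structure(list(transcript_id = paste0(tx$transcript_id, "|",
                                        event$event_id),
                 base_transcript_id = tx$transcript_id,
                 gene_id = tx$gene_id, chrom = tx$chrom,
                 strand = tx$strand, exons = new_ex, cds = NULL,
                 event_id = event$event_id),
            class = c("altered_transcript", "transcript_model"))
}

#' Transcript-coordinate positions of exon-exon junctions
#'
#' Offsets (0-based, number of transcript bases 5' of the boundary) of each
#' exon-exon junction in 5'→3' transcript order.
#'
#' @param tx transcript model or altered transcript.
#' @return Integer vector of length `nrow(exons) - 1` (possibly empty).
#' @export
junction_positions <- function(tx) {
  lens <- tx$exons[, 2L] - tx$exons[, 1L]
  if (tx$strand == "-") lens <- rev(lens)
  if (length(lens) < 2L) return(integer())
  cumsum(lens)[-length(lens)]
}

#' Longest / reference-anchored open reading frame
#'
#' With no anchor, returns the longest ATG→stop frame (ties broken by the
#' 5'-most start).  With `ref_start_offset`, translation starts at that
#' offset if an ATG survives there; otherwise (reference start destroyed by
#' the event, or `start_destroyed = TRUE`) the closest downstream ATG that
#' reaches an in-frame stop is used and the result is flagged
#' `start_rescued`.  ORFs without an in-frame stop are rejected.
#'
#' @param seq nucleotide string (uppercase ACGTN).
#' @param ref_start_offset optional 0-based transcript offset of the
#'   reference start codon projected onto this sequence.
#' @param start_destroyed set when the projection already knows the original
#'   start codon was deleted.
#' @return `NULL`, or a list with `start` (0-based offset), `end` (offset
#'   one past the stop codon), `protein` (no stop symbol; fuzzy codons as
#'   `X`), and `start_rescued`.
#' @export
longest_orf <- function(seq, ref_start_offset = NULL,
                        start_destroyed = FALSE) {
  atg <- as.integer(gregexpr("ATG", seq, fixed = TRUE)[[1L]])
  if (length(atg) == 1L && atg == -1L) return(NULL)
  atg <- atg - 1L  # to 0-based
  orf_at <- function(s) {
    tail_seq <- substr(seq, s + 1L, nchar(seq))
    n_cod <- nchar(tail_seq) %/% 3L
    if (n_cod < 2L) return(NULL)
    codons <- substring(tail_seq, seq(1L, by = 3L, length.out = n_cod),
                        seq(3L, by = 3L, length.out = n_cod))
    stop_i <- which(codons %in% .stop_codons)
    if (!length(stop_i)) return(NULL)
    k <- stop_i[1L]
    list(start = s, end = s + 3L * k,
         protein = translate_nt(paste(codons[seq_len(k - 1L)],
                                      collapse = "")))
  }
  if (!is.null(ref_start_offset)) {
    if (!start_destroyed &&
        substr(seq, ref_start_offset + 1L, ref_start_offset + 3L) == "ATG") {
      orf <- orf_at(ref_start_offset)
      if (!is.null(orf)) orf$start_rescued <- FALSE
      return(orf)
    }
    for (s in atg[atg >= ref_start_offset]) {
      orf <- orf_at(s)
      if (!is.null(orf)) {
        orf$start_rescued <- TRUE
        return(orf)
      }
    }
    return(NULL)
  }
  best <- NULL
  for (s in atg) {   # atg ascending: first of equal lengths wins (5'-most)
    orf <- orf_at(s)
    if (!is.null(orf) &&
        (is.null(best) || nchar(orf$protein) > nchar(best$protein)))
      best <- orf
  }
  if (!is.null(best)) best$start_rescued <- FALSE
  best
}

#' Nonsense-mediated-decay rule
#'
#' A transcript whose stop codon lies further than `window` nt (default 50)
#' upstream of a downstream exon-exon junction is presumed degraded by NMD.
#' The distance runs from the base after the last stop-codon base to the
#' junction; exactly `window` nt is kept ("further than").
#'
#' @param orf_stop_offset transcript offset one past the stop codon
#'   (`$end` of [longest_orf()]).
#' @param jpos junction offsets from [junction_positions()], or an altered
#'   transcript.
#' @param window distance threshold, default 50 nt.
#' @return `TRUE` when the transcript should be discarded as an NMD target.
#' @export
nmd_filter <- function(orf_stop_offset, jpos, window = 50L) {
  if (is.list(jpos)) jpos <- junction_positions(jpos)
  if (!length(jpos)) return(FALSE)
  max(jpos) - orf_stop_offset > window
}

#' Build the reference/altered protein pair for an event
#'
#' Composes [apply_event()], [spliced_sequence()], [longest_orf()] and
#' [nmd_filter()].  Events whose genomic footprint does not touch the
#' reference CDS span are flagged `utr_only` and produce no altered protein;
#' events whose altered ORF ends more than `nmd_window` nt upstream of a
#' downstream junction are flagged `nmd_discarded`; events with no
#' (sufficiently long) ORF are flagged `no_orf`.  When the altered protein
#' is absent, the residue window of the reference protein touched by the
#' event is recorded for event-scoped self-epitope calling.
#'
#' @param ref_tx the gene's reference transcript (with annotated CDS where
#'   available).
#' @param event one event row.
#' @param genome named character vector from [read_genome()].
#' @param reference_proteome named character vector (transcript id →
#'   protein) from [select_reference_transcriptome()].
#' @param min_orf_aa minimum altered-protein length, default 25 residues.
#' @param nmd_window NMD distance threshold, default 50 nt.
#' @return An `orf_pair` object.
#' @export
derive_orf_pair <- function(ref_tx, event, genome, reference_proteome,
                            min_orf_aa = 25L, nmd_window = 50L) {
  ref_protein <- reference_proteome[[ref_tx$transcript_id]]
  if (is.null(ref_protein))
    stop("transcript ", ref_tx$transcript_id, " absent from the reference ",
         "proteome")
  flags <- list(utr_only = FALSE, start_rescued = FALSE,
                nmd_discarded = FALSE, no_orf = FALSE)
  pair <- function(alt_protein, ref_affected_aa = NULL) {
    structure(list(event_id = event$event_id, ref_protein = ref_protein,
                   alt_protein = alt_protein, flags = flags,
                   ref_affected_aa = ref_affected_aa),
              class = "orf_pair")
  }

  alt_tx <- apply_event(ref_tx, event)
  if (!is.null(ref_tx$cds) &&
      !(event$start < ref_tx$cds[2L] && event$end > ref_tx$cds[1L])) {
    flags$utr_only <- TRUE
    return(pair(NULL))
  }
  seq_alt <- spliced_sequence(alt_tx, genome)

  off <- NULL; destroyed <- FALSE
  if (!is.null(ref_tx$cds)) {
    g0 <- if (ref_tx$strand == "+") ref_tx$cds[1L] else ref_tx$cds[2L] - 1L
    proj <- project_position(alt_tx, g0)
    if (is.null(proj)) {
      flags$no_orf <- TRUE
      return(pair(NULL, ref_affected_aa = event_aa_window(ref_tx, event)))
    }
    off <- proj$offset
    destroyed <- proj$projected
  }
  orf <- longest_orf(seq_alt, off, destroyed)
  if (is.null(orf) || nchar(orf$protein) < min_orf_aa) {
    flags$no_orf <- TRUE
    return(pair(NULL, ref_affected_aa = event_aa_window(ref_tx, event)))
  }
  flags$start_rescued <- isTRUE(orf$start_rescued)
  if (nmd_filter(orf$end, alt_tx, nmd_window)) {
    flags$nmd_discarded <- TRUE
    return(pair(NULL, ref_affected_aa = event_aa_window(ref_tx, event)))
  }
  pair(orf$protein)
}

#' @export
print.orf_pair <- function(x, ...) {
  fl <- names(Filter(isTRUE, x$flags))
  cat(sprintf("<orf_pair %s ref %d aa, alt %s%s>\n", x$event_id,
              nchar(x$ref_protein),
              if (is.null(x$alt_protein)) "absent"
              else paste0(nchar(x$alt_protein), " aa"),
              if (length(fl)) paste0("; ", paste(fl, collapse = ",")) else ""))
  invisible(x)
}

# transcript offset of genomic position g on tx; when g was removed by the
# event, the offset of the first retained base downstream in transcript
# direction (projected = TRUE); NULL when nothing remains downstream
project_position <- function(tx, g) {
  t0 <- genomic_to_transcript(tx, g)
  if (!is.na(t0)) return(list(offset = t0, projected = FALSE))
  ex <- tx$exons
  if (tx$strand == "+") {
    nxt <- which(ex[, 1L] > g)
    if (!length(nxt)) return(NULL)
    list(offset = genomic_to_transcript(tx, ex[min(nxt), 1L]),
         projected = TRUE)
  } else {
    nxt <- which(ex[, 2L] <= g)
    if (!length(nxt)) return(NULL)
    list(offset = genomic_to_transcript(tx, ex[max(nxt), 2L] - 1L),
         projected = TRUE)
  }
}

# 1-based residue window of the reference protein touched by the event's
# genomic footprint (clamped into the CDS); NULL when no CDS or no overlap
event_aa_window <- function(ref_tx, event) {
  if (is.null(ref_tx$cds)) return(NULL)
  fs <- max(event$start, ref_tx$cds[1L])
  fe <- min(event$end, ref_tx$cds[2L])
  if (fs >= fe) return(NULL)
  p1 <- project_position(ref_tx, if (ref_tx$strand == "+") fs else fe - 1L)
  p2 <- project_position(ref_tx, if (ref_tx$strand == "+") fe - 1L else fs)
  if (is.null(p1) || is.null(p2)) return(NULL)
  cds_off <- cds_transcript_offsets(ref_tx)
  lo <- max(min(p1$offset, p2$offset), cds_off[1L])
  hi <- min(max(p1$offset, p2$offset), cds_off[2L] - 1L)
  if (lo > hi) return(NULL)
  c((lo - cds_off[1L]) %/% 3L + 1L, (hi - cds_off[1L]) %/% 3L + 1L)
}

#' Write ORF pairs as paired FASTA plus a flags TSV
#'
#' Emits `>event_id|ref` / `>event_id|alt` records (alt omitted when absent)
#' and a companion TSV with the per-event flags.
#'
#' @param pairs list of `orf_pair` objects.
#' @param fasta_path,flags_path output files.
#' @export
write_orf_pairs <- function(pairs, fasta_path, flags_path) {
  lines <- unlist(lapply(pairs, function(p) {
    out <- c(paste0(">", p$event_id, "|ref"), p$ref_protein)
    if (!is.null(p$alt_protein))
      out <- c(out, paste0(">", p$event_id, "|alt"), p$alt_protein)
    out
  }), use.names = FALSE)
  writeLines(lines, fasta_path)
  fl <- do.call(rbind, lapply(pairs, function(p)
    data.frame(event_id = p$event_id, utr_only = p$flags$utr_only,
               start_rescued = p$flags$start_rescued,
               nmd_discarded = p$flags$nmd_discarded,
               no_orf = p$flags$no_orf,
               alt_len = if (is.null(p$alt_protein)) 0L
               else nchar(p$alt_protein))))
  write.table(fl, flags_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(fasta_path)
}
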